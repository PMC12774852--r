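# Recombination maps: piecewise-linear physical (bp) <-> genetic (cM)
# interpolation, HapMap-style text input, and centimorgan windows.

#' Construct a recombination map
#'
#' @param position strictly increasing bp coordinates (length >= 2).
#' @param map_cm non-decreasing cumulative genetic positions in cM, same
#'   length as `position`.
#' @param rate optional per-interval rates in cM/Mb (length matching
#'   `position`; the last entry is the rate beyond the final position).  If
#'   omitted, rates are derived from differences of `map_cm` (terminal rate =
#'   last interval rate).
#' @param chrom chromosome label (used when writing BED output).
#' @return data.frame of class `recomb_map`.
#' @export
recomb_map <- function(position, map_cm, rate = NULL, chrom = "1") {
  if (length(position) < 2)
    stop("recombination map needs at least 2 points", call. = FALSE)
  if (any(diff(position) <= 0))
    stop("map positions must be strictly increasing", call. = FALSE)
  if (length(map_cm) != length(position) || any(diff(map_cm) < 0))
    stop("map_cm must be non-decreasing and match positions", call. = FALSE)
  if (is.null(rate)) {
    r <- diff(map_cm) / diff(position) * 1e6
    rate <- c(r, r[length(r)])
  }
  structure(data.frame(position = as.numeric(position),
                       rate = as.numeric(rate),
                       map_cm = as.numeric(map_cm)),
            class = c("recomb_map", "data.frame"), chrom = chrom)
}

#' Uniform recombination map
#' @param rate_cm_per_mb constant rate in cM/Mb (1 cM/Mb corresponds to
#'   1e-8 crossovers per bp per generation).
#' @param sequence_length bp length covered.
#' @param chrom chromosome label.
#' @return a `recomb_map`.
#' @export
uniform_recomb_map <- function(rate_cm_per_mb = 1, sequence_length,
                               chrom = "1") {
  recomb_map(position = c(0, sequence_length),
             map_cm = c(0, rate_cm_per_mb * sequence_length / 1e6),
             rate = c(rate_cm_per_mb, rate_cm_per_mb), chrom = chrom)
}

#' Read a HapMap-style recombination map
#'
#' Expects a header line and columns chromosome, position (bp), rate (cM/Mb)
#' and cumulative map (cM), tab- or space-delimited.
#'
#' @param path file path.
#' @return a `recomb_map`.
#' @export
read_hapmap_map <- function(path) {
  df <- utils::read.table(path, header = TRUE, stringsAsFactors = FALSE)
  if (ncol(df) < 4)
    stop("HapMap map must have >= 4 columns (chrom, position, rate, map)",
         call. = FALSE)
  recomb_map(position = as.numeric(df[[2]]), map_cm = as.numeric(df[[4]]),
             rate = as.numeric(df[[3]]), chrom = as.character(df[[1]][1]))
}

#' Physical to genetic position
#'
#' Piecewise-linear interpolation inside the map; constant-rate extrapolation
#' with the terminal rates outside it (with a warning).
#'
#' @param map a `recomb_map`.
#' @param bp physical position(s).
#' @return genetic position(s) in cM.
#' @export
genetic_pos <- function(map, bp) {
  p <- map$position; g <- map$map_cm
  out <- stats::approx(p, g, xout = bp, rule = 2, ties = "ordered")$y
  lo <- bp < p[1]; hi <- bp > p[length(p)]
  if (any(lo)) {
    warning("position(s) before map start: extrapolating with terminal rate")
    out[lo] <- g[1] - (p[1] - bp[lo]) * map$rate[1] / 1e6
  }
  if (any(hi)) {
    warning("position(s) beyond map end: extrapolating with terminal rate")
    out[hi] <- g[length(g)] + (bp[hi] - p[length(p)]) * map$rate[length(p)] / 1e6
  }
  out
}

#' Genetic to physical position
#'
#' Inverse piecewise-linear interpolation.  Within zero-recombination (flat)
#' stretches the leftmost bp is returned.  Genetic positions outside the map
#' are extrapolated with the terminal rates (clamped to the map ends if the
#' terminal rate is zero).
#'
#' @param map a `recomb_map`.
#' @param cm genetic position(s) in cM.
#' @return physical position(s) in bp.
#' @export
physical_pos <- function(map, cm) {
  p <- map$position; g <- map$map_cm
  out <- stats::approx(g, p, xout = cm, rule = 2, ties = min)$y
  lo <- cm < g[1]; hi <- cm > g[length(g)]
  if (any(lo)) {
    r <- map$rate[1]
    out[lo] <- if (r > 0) p[1] - (g[1] - cm[lo]) * 1e6 / r else p[1]
  }
  if (any(hi)) {
    r <- map$rate[length(p)]
    out[hi] <- if (r > 0) p[length(p)] + (cm[hi] - g[length(g)]) * 1e6 / r
               else p[length(p)]
  }
  out
}

#' Centimorgan window around a focal position
#'
#' Returns the bp interval whose genetic endpoints lie `half_width_cm` either
#' side of the focal position's genetic position, clamped to the map bounds
#' (and optionally to a sequence interval).
#'
#' @param map a `recomb_map`.
#' @param focal_position bp.
#' @param half_width_cm window half-width in cM (>= 0).
#' @param sequence_length optional; clamp the window to `[0, sequence_length]`.
#' @return list of class `bp_window` with `left`, `right`, `focal`.
#' @export
cm_window <- function(map, focal_position, half_width_cm,
                      sequence_length = NULL) {
  stopifnot(half_width_cm >= 0)
  gf <- genetic_pos(map, focal_position)
  left <- physical_pos(map, gf - half_width_cm)
  right <- physical_pos(map, gf + half_width_cm)
  # clamp to the map bounds, and to the sequence interval when known
  left <- max(left, map$position[1])
  right <- min(right, map$position[nrow(map)])
  if (!is.null(sequence_length)) {
    left <- max(0, left); right <- min(sequence_length, right)
  }
  left <- min(left, focal_position); right <- max(right, focal_position)
  structure(list(left = left, right = right, focal = focal_position),
            class = "bp_window")
}

#' @export
print.bp_window <- function(x, ...) {
  cat(sprintf("window [%s, %s] around %s\n",
              format(x$left, big.mark = ","), format(x$right, big.mark = ","),
              format(x$focal, big.mark = ",")))
  invisible(x)
}
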