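# Test 2: evidence against unobserved problematic clades.  Hypothetical
# carrier sets close to each target set are enumerated; at each genomic
# position, a candidate can only exist as a clade if it is compatible
# (nested-or-disjoint) with every clade observed there.  The per-position
# minimum of the required omitted-variant effect size over surviving
# candidates maps where phantom epistasis cannot be ruled out.

#' Can two sample sets be clades of the same rooted tree?
#'
#' True iff the sets are nested or disjoint (the laminar condition for
#' clades of a single rooted tree); overlapping, non-nested sets cannot both
#' be subtended at one position.  Uses topology only.
#'
#' @param observed,candidate sample-id vectors (non-empty).
#' @param n total number of samples (unused by the rule; retained for
#'   interface completeness / validation).
#' @return logical.
#' @export
clades_compatible <- function(observed, candidate, n = NULL) {
  if (!length(observed) || !length(candidate))
    stop("sets must be non-empty", call. = FALSE)
  ov <- sum(candidate %in% observed)
  ov == 0L || ov == length(candidate) || ov == length(observed)
}

#' Enumerate candidate clades around a target set
#'
#' All sample sets within symmetric difference `max_edit` of the target
#' (conditional correlation with the target decays monotonically with edit
#' distance).  Each candidate's required omitted-variant effect size
#' `b_required` is its Test 1A b at the configured default probability;
#' candidates with `b_required` above `b_ceiling` are dropped.  Degenerate
#' (empty or complete) sets are excluded.  The target itself (edit distance
#' 0) is always a candidate.
#'
#' @param target 1-based haplotype index vector (a target set).
#' @param pair a [genotype_pair()] over the panel.
#' @param se an [estimate_sigma_s()] result.
#' @param max_edit maximum symmetric-difference size (>= 0), or `NULL` to
#'   choose adaptively: the largest value keeping the raw candidate count at
#'   or below `cap`.
#' @param b_ceiling keep candidates with `b_required <= b_ceiling`.
#' @param config a [test_config()].
#' @param source_target label recorded on each candidate.
#' @param cap combinatorial guard on the raw candidate count.
#' @return list of class `candidate_set`: elements `sets` (list of 1-based
#'   index vectors), `edit_distance`, `beta`, `b_required`, `source_target`.
#' @export
generate_candidates <- function(target, pair, se, max_edit = NULL,
                                b_ceiling = Inf, config = test_config(),
                                source_target = "S", cap = 1e5) {
  stopifnot(inherits(pair, "genotype_pair"))
  n <- pair$n
  target <- sort(as.integer(target))
  k <- length(target)
  comp <- setdiff(seq_len(n), target)
  count_for <- function(e) {
    tot <- 0
    for (r in 0:min(e, k)) for (a in 0:(e - r))
      if (a <= length(comp)) tot <- tot + choose(k, r) * choose(length(comp), a)
    tot
  }
  if (is.null(max_edit)) {
    max_edit <- 0
    while (count_for(max_edit + 1) <= cap && max_edit < n) max_edit <- max_edit + 1
  } else if (count_for(max_edit) > cap) {
    stop(sprintf(paste0("candidate count %.3g exceeds cap %.3g; ",
                        "lower max_edit or raise cap"),
                 count_for(max_edit), cap), call. = FALSE)
  }
  # residualised interaction term: beta for indicator z is sum(rs[z]) / vs
  .design_rank_check(pair)
  qx <- qr(cbind(1, pair$x1, pair$x2))
  rs <- qr.resid(qx, pair$s)
  vs <- sum(rs^2)
  sigma <- .se_sigma(se)
  m_def <- .solve_m_for_probability(config$default_P, config$C)

  sets <- list(); ed <- integer(); beta <- numeric(); breq <- numeric()
  push <- function(set, e) {
    if (!length(set) || length(set) == n) return()
    bt <- sum(rs[set]) / vs
    b <- if (bt == 0) Inf else m_def * sigma / abs(bt)
    if (b > b_ceiling) return()
    i <- length(sets) + 1L
    sets[[i]] <<- set; ed[i] <<- e; beta[i] <<- bt; breq[i] <<- b
  }
  for (r in 0:min(max_edit, k)) {
    rem_sets <- if (r == 0) list(integer(0)) else
      utils::combn(target, r, simplify = FALSE)
    for (rem in rem_sets) {
      base <- setdiff(target, rem)
      for (a in 0:(max_edit - r)) {
        if (a > length(comp)) break
        add_sets <- if (a == 0) list(integer(0)) else
          utils::combn(comp, a, simplify = FALSE)
        for (add in add_sets) push(sort(c(base, add)), r + a)
      }
    }
  }
  structure(list(sets = sets, edit_distance = ed, beta = beta,
                 b_required = breq,
                 source_target = rep(source_target, length(sets))),
            class = "candidate_set")
}

#' @export
print.candidate_set <- function(x, ...) {
  cat(sprintf("candidate_set: %d candidates (source %s), b_required in [%.4g, %.4g]\n",
              length(x$sets), x$source_target[1],
              suppressWarnings(min(x$b_required)),
              suppressWarnings(max(x$b_required))))
  invisible(x)
}

# concatenate candidate sets from several targets
.combine_candidates <- function(cands) {
  structure(list(
    sets = do.call(c, lapply(cands, `[[`, "sets")),
    edit_distance = do.call(c, lapply(cands, `[[`, "edit_distance")),
    beta = do.call(c, lapply(cands, `[[`, "beta")),
    b_required = do.call(c, lapply(cands, `[[`, "b_required")),
    source_target = do.call(c, lapply(cands, `[[`, "source_target"))),
    class = "candidate_set")
}

#' Per-position minimum effect-size profile (Test 2)
#'
#' At each position a candidate clade survives iff it is compatible with
#' every observed clade whose span covers the position; `min_b` is the
#' smallest `b_required` among survivors (Inf where none survive).  The
#' profile is piecewise constant between observed-clade span breakpoints;
#' it is evaluated on those breakpoints plus a uniform grid.
#'
#' Candidate sample sets are matched against observed clades through the
#' panel sample ids, so `panel_samples` must give the id corresponding to
#' each haplotype index.
#'
#' @param observed a [enumerate_clades()] result.
#' @param candidates a [generate_candidates()] result (or several combined).
#' @param windows a `bp_window`, a list of them, or `c(left, right)`.
#' @param grid_step uniform grid spacing in bp.
#' @param band hotspot band: positions with
#'   `min_b <= (1 + band) * global_min` form the hotspot regions.
#' @param panel_samples 0-based sample ids in haplotype-index order.
#' @param count_cap survival counts are computed exactly when the candidate
#'   number is at most this; above it `n_surviving` is `NA` (min_b is exact
#'   regardless).
#' @return data.frame of class `test2_profile` with columns `position`,
#'   `end`, `min_b`, `n_surviving`, `source_target`; attribute `hotspots`
#'   (data.frame start/end/min_b) and `global_min`.
#' @export
test2_profile <- function(observed, candidates, windows, grid_step = 1000,
                          band = 0.05, panel_samples = NULL,
                          count_cap = 2e4) {
  stopifnot(grid_step > 0, band >= 0)
  if (inherits(windows, "bp_window")) windows <- list(windows)
  if (is.numeric(windows)) windows <- list(list(left = windows[1], right = windows[2]))
  ncand <- length(candidates$sets)
  if (!ncand) {
    warning("empty candidate list: profile of sentinels")
  }
  nrec <- length(observed)
  # candidate sets in sample-id space
  if (is.null(panel_samples)) {
    nmax <- if (ncand) max(vapply(candidates$sets, max, 1L)) else 1L
    panel_samples <- 0:(nmax - 1L)
  }
  cand_ids <- lapply(candidates$sets, function(s) sort(panel_samples[s]))
  ord <- order(candidates$b_required)

  # pairwise compatibility memo: candidates x observed records
  compat <- matrix(TRUE, nrow = ncand, ncol = max(nrec, 1L))
  if (ncand && nrec) {
    obs_sets <- lapply(observed, `[[`, "samples")
    for (i in seq_len(ncand)) {
      ci <- cand_ids[[i]]
      for (j in seq_len(nrec)) {
        oj <- obs_sets[[j]]
        ov <- sum(ci %in% oj)
        compat[i, j] <- ov == 0L || ov == length(ci) || ov == length(oj)
      }
    }
  }

  # cells: window intervals cut at every observed span breakpoint
  cells <- NULL
  for (w in windows) {
    wl <- w$left; wr <- w$right
    bp <- c(wl, wr)
    for (r in observed) {
      sp <- r$spans
      bp <- c(bp, sp[, 1], sp[, 2])
    }
    bp <- sort(unique(pmin(pmax(bp, wl), wr)))
    if (length(bp) >= 2)
      cells <- rbind(cells, cbind(bp[-length(bp)], bp[-1]))
  }
  out <- NULL
  count_ok <- ncand <= count_cap
  if (!count_ok)
    message("candidate count exceeds count_cap; n_surviving reported as NA")
  for (ci in seq_len(NROW(cells))) {
    l <- cells[ci, 1]; r <- cells[ci, 2]
    mid <- (l + r) / 2
    active <- which(vapply(observed, function(rec)
      any(rec$spans[, 1] <= mid & mid < rec$spans[, 2]), logical(1)))
    min_b <- Inf; src <- NA_character_; nsurv <- if (count_ok) 0L else NA_integer_
    if (ncand) {
      if (length(active)) {
        surv_mask <- if (count_ok)
          rowSums(!compat[, active, drop = FALSE]) == 0L else NULL
        if (count_ok) {
          nsurv <- sum(surv_mask)
          if (nsurv) {
            idx <- which(surv_mask)
            k <- idx[which.min(candidates$b_required[idx])]
            min_b <- candidates$b_required[k]
            src <- candidates$source_target[k]
          }
        } else {
          for (i in ord) {   # candidates by increasing b: first survivor wins
            if (all(compat[i, active])) {
              min_b <- candidates$b_required[i]
              src <- candidates$source_target[i]
              break
            }
          }
        }
      } else {
        # no observed clade covers the position: nothing rules anything out
        k <- ord[1]
        min_b <- candidates$b_required[k]
        src <- candidates$source_target[k]
        nsurv <- if (count_ok) ncand else NA_integer_
      }
    }
    out <- rbind(out, data.frame(position = l, end = r, min_b = min_b,
                                 n_surviving = nsurv, source_target = src))
  }
  if (is.null(out))
    out <- data.frame(position = numeric(), end = numeric(), min_b = numeric(),
                      n_surviving = integer(), source_target = character())
  # add uniform grid positions (values constant within cells)
  grid_rows <- NULL
  for (w in windows) {
    g <- seq(w$left, w$right, by = grid_step)
    g <- g[!g %in% out$position]
    if (length(g)) {
      ci <- findInterval(g, out$position)
      ok <- ci >= 1 & g < out$end[pmax(ci, 1)]
      if (any(ok)) {
        gr <- out[ci[ok], ]
        gr$position <- g[ok]
        grid_rows <- rbind(grid_rows, gr)
      }
    }
  }
  prof <- rbind(out, grid_rows)
  prof <- prof[order(prof$position), ]
  rownames(prof) <- NULL
  gmin <- suppressWarnings(min(out$min_b))
  hot <- NULL
  if (is.finite(gmin)) {
    sel <- out$min_b <= (1 + band) * gmin
    runs <- rle(sel)
    pos <- cumsum(c(1, runs$lengths))
    for (ri in seq_along(runs$values)) {
      if (runs$values[ri]) {
        i0 <- pos[ri]; i1 <- pos[ri + 1] - 1
        hot <- rbind(hot, data.frame(start = out$position[i0],
                                     end = out$end[i1],
                                     min_b = min(out$min_b[i0:i1])))
      }
    }
  }
  if (is.null(hot)) hot <- data.frame(start = numeric(), end = numeric(),
                                      min_b = numeric())
  attr(prof, "hotspots") <- hot
  attr(prof, "global_min") <- gmin
  attr(prof, "band") <- band
  class(prof) <- c("test2_profile", "data.frame")
  prof
}

#' Hotspot regions of a Test 2 profile
#' @param profile a [test2_profile()] result.
#' @return data.frame with columns start, end, min_b.
#' @export
hotspot_regions <- function(profile) attr(profile, "hotspots")

#' Write a Test 2 profile as TSV
#' @param profile a [test2_profile()] result.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_profile <- function(profile, path) {
  utils::write.table(as.data.frame(profile), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write hotspot regions as BED
#'
#' BED uses 0-based half-open intervals, matching the internal convention.
#'
#' @param profile a [test2_profile()] result.
#' @param path output path.
#' @param chrom chromosome label.
#' @return `path`, invisibly.
#' @export
write_hotspot_bed <- function(profile, path, chrom = "1") {
  hot <- hotspot_regions(profile)
  bed <- data.frame(chrom = rep(chrom, nrow(hot)),
                    start = format(hot$start, scientific = FALSE, trim = TRUE),
                    end = format(hot$end, scientific = FALSE, trim = TRUE),
                    min_b = hot$min_b)
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
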