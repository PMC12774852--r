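# Top-level per-pair analysis: map the two SNPs into the ARG, enumerate
# clades within +/- window_cm of each, run Tests 1A/1B over them, and build
# the Test 2 per-position evidence profile.

#' Assess a reported SNP-pair interaction for phantom epistasis
#'
#' Given a reconstructed ARG (as a [tree_seq()]), a recombination map and a
#' SNP pair with summary statistics from an interaction study, computes the
#' minimum effect size `b` (in phenotype SD units) that an omitted additive
#' variant would need in order to explain the interaction:
#' per existing clade (Tests 1A and 1B) and per genomic position allowing
#' for clades that could exist but were not reconstructed (Test 2).  Small
#' minima mean phantom epistasis cannot be ruled out.
#'
#' @param ts a [tree_seq()] (the reference-panel ARG).
#' @param snp1,snp2 bp positions of the two SNPs; both must map uniquely to
#'   a branch (see [map_snp_to_branch()]).
#' @param study_N sample size of the original interaction study.
#' @param t_stat,p_value the original interaction Z-statistic or its
#'   two-sided p-value (exactly one; may be omitted, disabling Test 1B).
#' @param map a [recomb_map()]; default a uniform 1 cM/Mb map.
#' @param alpha significance level of the original test.
#' @param window_cm clade-search half-window in cM around each SNP.
#' @param P_grid,default_P Test 1A probabilities (see [test_config()]).
#' @param samples optional panel subset of sample ids.
#' @param min_frequency clade frequency filter.
#' @param freq1,freq2 optional study allele frequencies; a mismatch with the
#'   panel frequencies beyond `freq_tol` is warned about.
#' @param freq_tol absolute allele-frequency mismatch tolerance.
#' @param run_test2 compute the Test 2 profile.
#' @param test2_max_edit symmetric-difference radius for candidate clades.
#' @param test2_b_ceiling drop candidates needing larger effect than this.
#' @param test2_band hotspot band (fraction above the global minimum).
#' @param grid_step Test 2 profile grid spacing in bp.
#' @return Object of class `phantom_epistasis` with components `pair`,
#'   `targets`, `se`, `obs`, `windows`, `clades`, `test1` (per-clade table
#'   with `minima` attribute), `test2` (profile or NULL), `config`.
#' @examples
#' fx <- make_fixture("eight_sample")
#' fit <- phantom_epistasis(fx$ts, snp1 = 20, snp2 = 70, study_N = 5000,
#'                          p_value = 1e-8, window_cm = 0.0001)
#' print(fit)
#' @export
phantom_epistasis <- function(ts, snp1, snp2, study_N,
                              t_stat = NULL, p_value = NULL,
                              map = NULL, alpha = 0.05, window_cm = 1,
                              P_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                              default_P = 0.5, samples = NULL,
                              min_frequency = 0,
                              freq1 = NULL, freq2 = NULL, freq_tol = 0.05,
                              run_test2 = TRUE, test2_max_edit = 1,
                              test2_b_ceiling = Inf, test2_band = 0.05,
                              grid_step = 1000) {
  stopifnot(inherits(ts, "tree_seq"))
  if (is.null(map)) map <- uniform_recomb_map(1, ts$sequence_length)
  if (is.null(samples)) samples <- ts$samples
  samples <- sort(as.integer(samples))
  config <- test_config(alpha = alpha, P_grid = P_grid, default_P = default_P)

  b1 <- map_snp_to_branch(ts, snp1, samples = samples)
  b2 <- map_snp_to_branch(ts, snp2, samples = samples)
  for (bb in list(list(b1, freq1, snp1), list(b2, freq2, snp2))) {
    if (!is.null(bb[[2]]) && abs(bb[[1]]$frequency - bb[[2]]) > freq_tol)
      warning(sprintf(
        "allele frequency mismatch at %s: panel %.3f vs study %.3f",
        format(bb[[3]]), bb[[1]]$frequency, bb[[2]]))
  }
  pair <- genotype_pair_from_sets(match(b1$samples, samples),
                                  match(b2$samples, samples),
                                  n = length(samples), m1 = snp1, m2 = snp2)
  targets <- target_sets(pair)
  se <- estimate_sigma_s(pair, study_N = study_N)
  obs <- if (!is.null(t_stat) || !is.null(p_value))
    observed_interaction(t_stat = t_stat, p_value = p_value) else NULL

  w1 <- cm_window(map, snp1, window_cm, sequence_length = ts$sequence_length)
  w2 <- cm_window(map, snp2, window_cm, sequence_length = ts$sequence_length)
  overlap <- w1$right >= w2$left && w2$right >= w1$left
  clades <- if (overlap)
    enumerate_clades(ts, window = c(min(w1$left, w2$left),
                                    max(w1$right, w2$right)),
                     min_frequency = min_frequency, samples = samples)
  else .combine_clade_lists(list(
    enumerate_clades(ts, window = c(w1$left, w1$right),
                     min_frequency = min_frequency, samples = samples),
    enumerate_clades(ts, window = c(w2$left, w2$right),
                     min_frequency = min_frequency, samples = samples)))

  test1 <- run_test1(clades, pair, se, obs = obs, config = config,
                     panel_samples = samples)

  test2 <- NULL
  if (run_test2) {
    cands <- .combine_candidates(lapply(names(targets), function(nm) {
      tg <- targets[[nm]]
      if (length(tg) == 0L)
        return(structure(list(sets = list(), edit_distance = integer(),
                              beta = numeric(), b_required = numeric(),
                              source_target = character()),
                         class = "candidate_set"))
      generate_candidates(tg, pair, se, max_edit = test2_max_edit,
                          b_ceiling = test2_b_ceiling, config = config,
                          source_target = nm)
    }))
    wins <- if (overlap)
      list(structure(list(left = min(w1$left, w2$left),
                          right = max(w1$right, w2$right),
                          focal = snp1), class = "bp_window"))
    else list(w1, w2)
    test2 <- test2_profile(clades, cands, wins, grid_step = grid_step,
                           band = test2_band, panel_samples = samples)
  }
  structure(list(snp1 = snp1, snp2 = snp2, pair = pair, targets = targets,
                 se = se, obs = obs, windows = list(w1, w2),
                 clades = clades, test1 = test1, test2 = test2,
                 config = config, samples = samples),
            class = "phantom_epistasis")
}

#' @export
print.phantom_epistasis <- function(x, ...) {
  m <- attr(x$test1, "minima")
  cat(sprintf("phantom epistasis assessment: SNPs at %s and %s (panel n = %d)\n",
              format(x$snp1, big.mark = ","), format(x$snp2, big.mark = ","),
              x$pair$n))
  cat(sprintf("  clades tested: %d;  sigma_s = %.3g\n",
              nrow(x$test1), x$se$sigma_s))
  if (length(m)) {
    cat(sprintf("  Test 1A min b (P = %s): %.3g\n",
                format(x$config$default_P), m$test1a))
    if (!is.na(m$test1b)) cat(sprintf("  Test 1B min b:          %.3g\n", m$test1b))
  }
  if (!is.null(x$test2))
    cat(sprintf("  Test 2 min b:           %.3g\n",
                attr(x$test2, "global_min")))
  invisible(x)
}

#' @export
summary.phantom_epistasis <- function(object, ...) {
  m <- attr(object$test1, "minima")
  out <- list(
    snp1 = object$snp1, snp2 = object$snp2,
    n_clades = nrow(object$test1),
    sigma_s = object$se$sigma_s,
    test1a_min_b = m$test1a,
    test1a_min_b_supported = m$test1a_supported,
    test1b_min_b = m$test1b,
    test2_min_b = if (is.null(object$test2)) NA_real_
                  else attr(object$test2, "global_min"),
    top_snp = m$top_snp,
    target_sizes = vapply(object$targets, length, 1L))
  class(out) <- "summary.phantom_epistasis"
  out
}

#' @export
print.summary.phantom_epistasis <- function(x, ...) {
  cat(sprintf("SNP pair %s / %s\n", format(x$snp1), format(x$snp2)))
  cat(sprintf("  target set sizes: S=%d K1=%d K2=%d O=%d\n",
              x$target_sizes["S"], x$target_sizes["K1"],
              x$target_sizes["K2"], x$target_sizes["O"]))
  cat(sprintf("  clades tested: %d (sigma_s = %.3g)\n", x$n_clades, x$sigma_s))
  cat(sprintf("  min b  Test 1A: %.3g  (SNP-supported: %.3g)\n",
              x$test1a_min_b, x$test1a_min_b_supported))
  cat(sprintf("         Test 1B: %.3g\n", x$test1b_min_b))
  cat(sprintf("         Test 2 : %.3g\n", x$test2_min_b))
  if (!is.na(x$top_snp)) cat(sprintf("  top SNP: %s\n", format(x$top_snp)))
  invisible(x)
}

#' Plot a phantom-epistasis assessment
#'
#' Per-clade Test 1A effect sizes at their span midpoints, the Test 2
#' minimum-b profile, SNP positions and hotspot regions.
#'
#' @param x a [phantom_epistasis()] result.
#' @param ... passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.phantom_epistasis <- function(x, ...) {
  t1 <- x$test1
  bcol <- paste0("b_1a_P", format(x$config$default_P, trim = TRUE))
  mid <- (t1$span_left + t1$span_right) / 2
  b <- t1[[bcol]]
  fin <- is.finite(b)
  ylim <- range(c(b[fin], if (!is.null(x$test2))
    x$test2$min_b[is.finite(x$test2$min_b)]), na.rm = TRUE)
  graphics::plot(mid[fin] / 1e3, b[fin], pch = 16, cex = 0.5,
                 col = "grey40", xlab = "position (kb)",
                 ylab = "minimum effect size b (SD units)",
                 ylim = ylim, ...)
  if (!is.null(x$test2)) {
    pr <- x$test2
    ok <- is.finite(pr$min_b)
    graphics::lines(pr$position[ok] / 1e3, pr$min_b[ok], col = "firebrick",
                    type = "s")
    hot <- hotspot_regions(pr)
    if (nrow(hot))
      graphics::segments(hot$start / 1e3, ylim[1], hot$end / 1e3, ylim[1],
                         col = "firebrick", lwd = 3)
  }
  graphics::abline(v = c(x$snp1, x$snp2) / 1e3, lty = 2, col = "steelblue")
  invisible(x)
}
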