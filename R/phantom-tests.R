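# Tests 1A and 1B: convert a clade's conditional association with the
# interaction term into the effect size b (in phenotype SD units) that an
# omitted additive variant would need in order to explain the interaction.
#
# Under omission of a variant with carrier vector z and effect b, the
# interaction Z-statistic is asymptotically Normal(m, 1) with noncentrality
# m = b * beta_zs|x / sigma_s, so the probability of (falsely) rejecting the
# interaction null at level alpha is
#   P(m) = Phi(-C - m) + 1 - Phi(C - m),   C = qnorm(1 - alpha/2).

#' Test configuration
#'
#' @param alpha significance level of the original interaction test.
#' @param P_grid probabilities for Test 1A; each must lie in (alpha, 1).
#' @param default_P the probability used for headline Test 1A values.
#' @return list of class `test_config` with `alpha`, `C` (two-sided critical
#'   value), `P_grid`, `default_P`.
#' @export
test_config <- function(alpha = 0.05, P_grid = c(0.1, 0.3, 0.5, 0.7, 0.9),
                        default_P = 0.5) {
  stopifnot(alpha > 0, alpha < 1)
  if (any(P_grid <= alpha | P_grid >= 1))
    stop("every P in P_grid must satisfy alpha < P < 1", call. = FALSE)
  if (default_P <= alpha || default_P >= 1)
    stop("default_P must satisfy alpha < P < 1", call. = FALSE)
  structure(list(alpha = alpha, C = stats::qnorm(1 - alpha / 2),
                 P_grid = sort(unique(c(P_grid, default_P))),
                 default_P = default_P),
            class = "test_config")
}

#' Observed interaction statistic
#'
#' Wraps the original study's interaction Z-statistic, or derives its
#' magnitude from a two-sided p-value via `|t| = qnorm(1 - p/2)` (positive
#' sign by convention).  A p-value of zero is floored at the smallest
#' representable positive value, with a warning.
#'
#' @param t_stat the interaction Z-statistic, or `NULL`.
#' @param p_value two-sided p-value, or `NULL` (exactly one of the two).
#' @return list of class `observed_interaction` with `t_hat` and `source`.
#' @export
observed_interaction <- function(t_stat = NULL, p_value = NULL) {
  if (is.null(t_stat) == is.null(p_value))
    stop("supply exactly one of t_stat, p_value", call. = FALSE)
  if (is.null(t_stat)) {
    if (p_value <= 0) {
      warning("p_value <= 0: flooring at the smallest representable positive value")
      p_value <- .Machine$double.xmin
    }
    if (p_value > 1) stop("p_value must be in (0, 1]", call. = FALSE)
    t_stat <- stats::qnorm(p_value / 2, lower.tail = FALSE)
    src <- "p_value"
  } else {
    if (!is.finite(t_stat)) stop("t_stat must be finite", call. = FALSE)
    src <- "statistic"
  }
  structure(list(t_hat = t_stat, source = src), class = "observed_interaction")
}

.assoc_beta <- function(assoc) {
  if (inherits(assoc, "cond_assoc")) assoc$beta else as.numeric(assoc)
}
.se_sigma <- function(se) {
  if (inherits(se, "interaction_se")) se$sigma_s else as.numeric(se)
}

#' Probability of falsely rejecting the interaction null
#'
#' @param b effect size of the omitted variant (phenotype SD units).
#' @param assoc a [conditional_coefficient()] result, or the coefficient
#'   itself.
#' @param se an [estimate_sigma_s()] result, or the standard error itself.
#' @param config a [test_config()].
#' @return probability in `[alpha, 1)`; equals alpha exactly when
#'   `b * beta == 0`.
#' @export
rejection_probability <- function(b, assoc, se, config = test_config()) {
  sigma <- .se_sigma(se)
  if (sigma <= 0) stop("sigma_s must be positive", call. = FALSE)
  m <- b * .assoc_beta(assoc) / sigma
  C <- config$C
  stats::pnorm(-C - m) + 1 - stats::pnorm(C - m)
}

# solve P(m) = P_target for m >= 0 by bisection (P is strictly increasing in
# m on [0, Inf)); absolute tolerance on P
.solve_m_for_probability <- function(P_target, C, tol = 1e-10) {
  pm <- function(m) stats::pnorm(-C - m) + stats::pnorm(m - C)
  lo <- 0; hi <- 1
  while (pm(hi) < P_target) {
    hi <- hi * 2
    if (hi > 1e8) break
  }
  for (i in 1:200) {
    mid <- (lo + hi) / 2
    pv <- pm(mid)
    if (abs(pv - P_target) <= tol) return(mid)
    if (pv < P_target) lo <- mid else hi <- mid
  }
  (lo + hi) / 2
}

#' Test 1A: effect size yielding a target rejection probability
#'
#' The unique `b >= 0` at which [rejection_probability()] equals `P_target`.
#' A small value means a weak omitted variant suffices to make the
#' interaction appear significant with that probability.
#'
#' @param P_target target probability, in `(alpha, 1)`.
#' @param assoc,se,config as in [rejection_probability()].
#' @return non-negative effect size `b`; `Inf` (sentinel) when the
#'   conditional coefficient is zero (no leverage).
#' @export
test1a_b_for_probability <- function(P_target, assoc, se,
                                     config = test_config()) {
  if (P_target <= config$alpha || P_target >= 1)
    stop("P_target must lie in (alpha, 1)", call. = FALSE)
  beta <- .assoc_beta(assoc); sigma <- .se_sigma(se)
  if (beta == 0) return(Inf)
  m <- .solve_m_for_probability(P_target, config$C)
  m * sigma / abs(beta)
}

#' Test 1B: effect size at which the observed interaction stops being
#' significant
#'
#' Returns `b = max(0, |t| - C) * sigma_s / |beta|`: the omitted-variant
#' effect size that shifts the adjusted null just far enough that the
#' observed statistic sits on the rejection boundary.  Interactions already
#' non-significant give 0.
#'
#' @param obs an [observed_interaction()] (or the Z-statistic itself).
#' @param assoc,se,config as in [rejection_probability()].
#' @return non-negative `b`; `Inf` when the conditional coefficient is zero.
#' @export
test1b_b_threshold <- function(obs, assoc, se, config = test_config()) {
  t_hat <- if (inherits(obs, "observed_interaction")) obs$t_hat
           else as.numeric(obs)
  beta <- .assoc_beta(assoc); sigma <- .se_sigma(se)
  if (beta == 0) return(Inf)
  max(0, abs(t_hat) - config$C) * sigma / abs(beta)
}

#' Run Test 1 over a set of clades
#'
#' For each clade the proxy genotype z is its membership indicator over the
#' panel haplotypes; the conditional coefficient, the Test 1A effect sizes
#' for every probability in the grid, and (when an observed statistic is
#' supplied) the Test 1B threshold are computed.  Clades whose indicator lies
#' exactly in the span of the design (intercept, x1, x2, s) *with a nonzero
#' loading on s* (e.g. a clade equal to a target set) are flagged
#' `unidentifiable` and reported with b = 0: the interaction is then fully
#' explained by the omitted variant and the model containing it would be
#' unidentifiable.  Span members with zero loading on s (such as the SNPs'
#' own clades) carry no leverage and report the infinite sentinel.
#'
#' @param clades a [enumerate_clades()] result (records with 0-based sample
#'   ids drawn from `panel_samples`).
#' @param pair a [genotype_pair()] over the panel haplotypes.
#' @param se an [estimate_sigma_s()] result.
#' @param obs optional [observed_interaction()].
#' @param config a [test_config()].
#' @param panel_samples sample ids (0-based) in the order underlying the
#'   pair's genotype vectors; defaults to `0:(n-1)`.
#' @return data.frame of class `test1_result`, one row per clade, with
#'   attributes `minima` (list with unrestricted and SNP-supported minimum b
#'   per test, plus the minimising clade's span and nearest supporting SNP)
#'   and `config`.
#' @export
run_test1 <- function(clades, pair, se, obs = NULL, config = test_config(),
                      panel_samples = NULL) {
  stopifnot(inherits(pair, "genotype_pair"))
  if (is.null(panel_samples)) panel_samples <- 0:(pair$n - 1L)
  if (!length(clades)) {
    warning("no clades to test; empty result")
    res <- data.frame()
    attr(res, "minima") <- list()
    class(res) <- c("test1_result", "data.frame")
    return(res)
  }
  .design_rank_check(pair)
  qx <- qr(cbind(1, pair$x1, pair$x2))
  rs <- qr.resid(qx, pair$s)
  vs <- sum(rs^2)
  # cell index of each haplotype in the S/K1/K2/O partition; the design's
  # column space is exactly the functions constant on these cells, so a
  # binary proxy lies in span{1, x1, x2, s} iff its carrier set is a union
  # of cells
  cell <- 1L + pair$x1 + 3L * pair$x2 - 2L * pair$s  # S=3, K1=2, K2=4, O=1
  cell_size <- tabulate(cell, 4L)
  sigma <- .se_sigma(se)
  m_grid <- vapply(config$P_grid, .solve_m_for_probability, numeric(1),
                   C = config$C)
  t_hat <- if (!is.null(obs)) {
    if (inherits(obs, "observed_interaction")) obs$t_hat else as.numeric(obs)
  } else NA_real_

  nn <- length(clades)
  beta <- numeric(nn); unident <- logical(nn)
  b1a <- matrix(NA_real_, nn, length(m_grid))
  b1b <- rep(NA_real_, nn)
  n_sup <- integer(nn); top_snp <- rep(NA_real_, nn)
  span_l <- numeric(nn); span_r <- numeric(nn); freq <- numeric(nn)
  nsamp <- integer(nn)
  for (i in seq_len(nn)) {
    r <- clades[[i]]
    idx <- match(r$samples, panel_samples)
    beta[i] <- sum(rs[idx]) / vs
    # exact collinearity with {1, x1, x2, s} *through s*: the proxy equals
    # a0 + a1 x1 + a2 x2 + as s with as != 0, so including it would make the
    # model unidentifiable -- the strongest possible phantom signal.
    # (Proxies inside the span with zero loading on s, e.g. z = x1, carry no
    # leverage on the interaction and fall through to the no-leverage case.)
    tab <- tabulate(cell[idx], 4L)
    in_span <- all(tab == 0L | tab == cell_size)
    # exact span members have integer s-loadings; snap numerical dust to 0
    if (in_span && abs(beta[i]) <= 1e-8) beta[i] <- 0
    if (in_span && abs(beta[i]) > 1e-8) {
      unident[i] <- TRUE
      b1a[i, ] <- 0
      b1b[i] <- 0
    } else if (beta[i] == 0) {
      b1a[i, ] <- Inf
      b1b[i] <- Inf
    } else {
      b1a[i, ] <- m_grid * sigma / abs(beta[i])
      b1b[i] <- max(0, abs(t_hat) - config$C) * sigma / abs(beta[i])
    }
    n_sup[i] <- nrow(r$mutations)
    if (n_sup[i]) {
      # supporting SNP nearest to a focal SNP when positions are known
      pos <- r$mutations$position
      ref <- c(pair$m1, pair$m2)
      top_snp[i] <- if (all(is.na(ref))) pos[1]
                    else pos[which.min(apply(abs(outer(pos, ref[!is.na(ref)], "-")),
                                             1, min))]
    }
    span_l[i] <- r$spans[1, 1]; span_r[i] <- r$spans[nrow(r$spans), 2]
    freq[i] <- r$frequency
    nsamp[i] <- length(r$samples)
  }
  res <- data.frame(clade_id = seq_len(nn), n_samples = nsamp,
                    frequency = freq, span_left = span_l, span_right = span_r,
                    beta_zs_given_x = beta, unidentifiable = unident,
                    supported = n_sup > 0L, n_supporting = n_sup,
                    top_snp = top_snp)
  pd <- format(config$P_grid, trim = TRUE)
  for (j in seq_along(m_grid)) res[[paste0("b_1a_P", pd[j])]] <- b1a[, j]
  res$b_1b <- if (is.null(obs)) NA_real_ else b1b
  jdef <- which(config$P_grid == config$default_P)
  bdef <- b1a[, jdef]
  min_of <- function(v, mask) {
    v <- v[mask]
    if (!length(v) || all(!is.finite(v) & v > 0)) Inf else min(v)
  }
  which_min_of <- function(v, mask) {
    idx <- which(mask)
    if (!length(idx)) return(NA_integer_)
    idx[which.min(v[idx])]
  }
  all_mask <- rep(TRUE, nn); sup_mask <- n_sup > 0L
  i1a <- which_min_of(bdef, all_mask)
  minima <- list(
    test1a = min_of(bdef, all_mask),
    test1a_supported = min_of(bdef, sup_mask),
    test1b = if (is.null(obs)) NA_real_ else min_of(b1b, all_mask),
    test1b_supported = if (is.null(obs)) NA_real_ else min_of(b1b, sup_mask),
    argmin_1a = i1a,
    argmin_1a_supported = which_min_of(bdef, sup_mask),
    top_snp = if (!is.na(which_min_of(bdef, sup_mask)))
                top_snp[which_min_of(bdef, sup_mask)] else NA_real_,
    argmin_span = if (!is.na(i1a)) c(span_l[i1a], span_r[i1a]) else c(NA, NA))
  attr(res, "minima") <- minima
  attr(res, "config") <- config
  class(res) <- c("test1_result", "data.frame")
  res
}

#' @export
print.test1_result <- function(x, ...) {
  m <- attr(x, "minima")
  cat("Test 1 over", nrow(x), "clades\n")
  if (length(m)) {
    cat(sprintf("  min b (Test 1A, P = %s): %.4g  [SNP-supported: %.4g]\n",
                format(attr(x, "config")$default_P), m$test1a,
                m$test1a_supported))
    if (!is.na(m$test1b))
      cat(sprintf("  min b (Test 1B):          %.4g  [SNP-supported: %.4g]\n",
                  m$test1b, m$test1b_supported))
    if (!is.na(m$top_snp))
      cat(sprintf("  top supporting SNP: %s\n", format(m$top_snp)))
  }
  invisible(x)
}
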