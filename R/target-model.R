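# Interaction design and target sets.  The analysis frame is haploid: all
# genotype vectors are indicators over haplotypes; index i refers to the i-th
# haplotype of the panel.  The interaction term is s = x1 * x2 elementwise.

#' Construct a SNP-pair interaction design
#'
#' @param x1,x2 binary vectors of equal length (haplotype carriage of the two
#'   SNPs); neither may be constant (all zero or all one).
#' @param m1,m2 optional bp positions of the two SNPs.
#' @return Object of class `genotype_pair` with elements `x1`, `x2`, `s`
#'   (= x1 * x2), `n`, `m1`, `m2` and carrier index sets `X1`, `X2`
#'   (1-based positions).
#' @export
genotype_pair <- function(x1, x2, m1 = NA_real_, m2 = NA_real_) {
  if (length(x1) != length(x2))
    stop("x1 and x2 must have the same length", call. = FALSE)
  x1 <- as.numeric(x1); x2 <- as.numeric(x2)
  if (!all(x1 %in% c(0, 1)) || !all(x2 %in% c(0, 1)))
    stop("genotype vectors must be binary", call. = FALSE)
  if (all(x1 == 0) || all(x1 == 1) || all(x2 == 0) || all(x2 == 1))
    stop("genotype vectors must not be constant", call. = FALSE)
  structure(list(x1 = x1, x2 = x2, s = x1 * x2, n = length(x1),
                 m1 = m1, m2 = m2,
                 X1 = which(x1 == 1), X2 = which(x2 == 1)),
            class = "genotype_pair")
}

#' Build a genotype pair from carrier sets
#'
#' @param X1,X2 1-based carrier index vectors.
#' @param n number of haplotypes.
#' @param m1,m2 optional bp positions.
#' @return a [genotype_pair()].
#' @export
genotype_pair_from_sets <- function(X1, X2, n, m1 = NA_real_, m2 = NA_real_) {
  x1 <- numeric(n); x1[X1] <- 1
  x2 <- numeric(n); x2[X2] <- 1
  genotype_pair(x1, x2, m1 = m1, m2 = m2)
}

#' @export
print.genotype_pair <- function(x, ...) {
  cat(sprintf("genotype_pair: n = %d haplotypes; |X1| = %d, |X2| = %d, |S| = %d\n",
              x$n, length(x$X1), length(x$X2), sum(x$s)))
  invisible(x)
}

#' Target sets induced by a SNP pair
#'
#' The four-way partition of the samples: `S` carries both SNPs, `K1` only
#' the first, `K2` only the second, `O` neither.  Any of these sets forming a
#' clade (anywhere in the genome) is a candidate source of phantom epistasis.
#'
#' @param pair a [genotype_pair()].
#' @return Named list of class `target_sets` with members `S`, `K1`, `K2`,
#'   `O` (1-based index vectors; possibly empty, flagged via the
#'   `empty_members` attribute).
#' @export
target_sets <- function(pair) {
  stopifnot(inherits(pair, "genotype_pair"))
  S <- intersect(pair$X1, pair$X2)
  K1 <- setdiff(pair$X1, pair$X2)
  K2 <- setdiff(pair$X2, pair$X1)
  O <- setdiff(seq_len(pair$n), union(pair$X1, pair$X2))
  out <- structure(list(S = sort(S), K1 = sort(K1), K2 = sort(K2), O = sort(O)),
                   class = "target_sets")
  attr(out, "empty_members") <- names(out)[vapply(out, length, 1L) == 0L]
  out
}

#' @export
print.target_sets <- function(x, ...) {
  for (nm in names(x))
    cat(sprintf("%-2s (n=%3d): %s\n", nm, length(x[[nm]]),
                paste(utils::head(x[[nm]], 20), collapse = " ")))
  invisible(x)
}

#' Verify the interaction identities
#'
#' Checks, elementwise, that s = x1*x2 = x1 - k1 = x2 - k2 = x1 + x2 + o - 1,
#' where k1, k2, o are the indicator vectors of the target sets.  These
#' identities are why including any one of s, k1, k2, o alongside x1, x2 and
#' an intercept makes the interaction model unidentifiable.
#'
#' @param pair a [genotype_pair()].
#' @param targets target sets (defaults to [target_sets()] of the pair).
#' @return data.frame with columns `identity` and `holds`; all TRUE for a
#'   correctly constructed partition.
#' @export
interaction_identities <- function(pair, targets = target_sets(pair)) {
  n <- pair$n
  ind <- function(set) { v <- numeric(n); v[set] <- 1; v }
  k1 <- ind(targets$K1); k2 <- ind(targets$K2); o <- ind(targets$O)
  s <- pair$s
  checks <- c(
    "s == x1*x2" = all(s == pair$x1 * pair$x2),
    "s == x1 - k1" = all(s == pair$x1 - k1),
    "s == x2 - k2" = all(s == pair$x2 - k2),
    "s == x1 + x2 + o - 1" = all(s == pair$x1 + pair$x2 + o - 1))
  data.frame(identity = names(checks), holds = unname(checks))
}

.design_rank_check <- function(pair) {
  D <- cbind(`(intercept)` = 1, x1 = pair$x1, x2 = pair$x2, s = pair$s)
  q <- qr(D)
  if (q$rank < 4L) {
    dep <- colnames(D)[q$pivot[(q$rank + 1L):4L]]
    stop(errorCondition(
      paste0("unidentifiable design: collinear columns {",
             paste(dep, collapse = ", "), "}"),
      class = c("phantomepi_unidentifiable", "error", "condition")))
  }
  invisible(q)
}

#' Conditional association of a proxy genotype with the interaction term
#'
#' The coefficient of s in the least-squares regression of z on an intercept,
#' x1, x2 and s over the panel haplotypes: equal to the partial covariance of
#' z and s given (x1, x2) divided by the partial variance of s given
#' (x1, x2).  This is the leverage an omitted variant with carrier vector z
#' has on the interaction estimate.
#'
#' @param z binary (or numeric) vector, same length as the pair's genotypes.
#' @param pair a [genotype_pair()].
#' @return list of class `cond_assoc` with `beta` (the coefficient),
#'   `partial_r` (partial correlation, same sign) and `n`.
#' @export
conditional_coefficient <- function(z, pair) {
  stopifnot(inherits(pair, "genotype_pair"))
  if (length(z) != pair$n)
    stop("z must match the pair's haplotype count", call. = FALSE)
  .design_rank_check(pair)
  qx <- qr(cbind(1, pair$x1, pair$x2))
  rs <- qr.resid(qx, pair$s)
  rz <- qr.resid(qx, as.numeric(z))
  vs <- sum(rs^2)
  beta <- sum(z * rs) / vs
  vz <- sum(rz^2)
  partial_r <- if (vz <= .Machine$double.eps * pair$n) 0
               else sum(rz * rs) / sqrt(vz * vs)
  structure(list(beta = beta, partial_r = partial_r, n = pair$n),
            class = "cond_assoc")
}

#' @export
print.cond_assoc <- function(x, ...) {
  cat(sprintf("conditional association: beta_zs|x = %.6g (partial r = %.4f, n = %d)\n",
              x$beta, x$partial_r, x$n))
  invisible(x)
}

#' Genotype-based approximation of the interaction-coefficient standard error
#'
#' Approximates the standard error of the estimated interaction coefficient
#' in the study regression using only the panel genotypes, under a
#' variance-standardised polygenic phenotype (residual variance ~ 1): the
#' (s,s) entry of the inverse second-moment matrix of the centred design
#' (x1, x2, s), divided by the study sample size, square-rooted.  Scales as
#' `study_N^(-1/2)`.
#'
#' @param pair a [genotype_pair()] built from the panel haplotypes.
#' @param study_N the interaction study's sample size (>= 10).
#' @return list of class `interaction_se` with `sigma_s`, `study_N`,
#'   `panel_n`.
#' @export
estimate_sigma_s <- function(pair, study_N) {
  stopifnot(inherits(pair, "genotype_pair"))
  if (study_N < 10) stop("study_N must be at least 10", call. = FALSE)
  .design_rank_check(pair)
  M <- cbind(pair$x1 - mean(pair$x1), pair$x2 - mean(pair$x2),
             pair$s - mean(pair$s))
  Sigma <- crossprod(M) / pair$n
  inv <- solve(Sigma)
  structure(list(sigma_s = sqrt(inv[3, 3] / study_N),
                 study_N = as.integer(study_N), panel_n = pair$n),
            class = "interaction_se")
}

#' @export
print.interaction_se <- function(x, ...) {
  cat(sprintf("sigma_s = %.6g (study N = %d, panel n = %d)\n",
              x$sigma_s, x$study_N, x$panel_n))
  invisible(x)
}

#' Write target-set membership as TSV
#' @param targets a [target_sets()].
#' @param path output path.
#' @param sample_ids optional sample labels (defaults to 1-based indices).
#' @return `path`, invisibly.
#' @export
write_target_sets <- function(targets, path, sample_ids = NULL) {
  rows <- do.call(rbind, lapply(names(targets), function(nm) {
    if (!length(targets[[nm]])) return(NULL)
    ids <- if (is.null(sample_ids)) targets[[nm]] else sample_ids[targets[[nm]]]
    data.frame(sample = ids, set = nm)
  }))
  if (is.null(rows)) rows <- data.frame(sample = integer(), set = character())
  rows <- rows[order(rows$sample), ]
  utils::write.table(rows, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
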