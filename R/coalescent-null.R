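# Neutral-coalescent clade probability: how likely a pre-specified set of k
# out of n samples is to be subtended by a branch of a random coalescent
# topology.  Small probabilities mean an observed matching clade is unlikely
# to be a chance artefact.

#' Probability that a fixed k-subset forms a clade
#'
#' Probability that a pre-specified set of `k` labels is the exact descendant
#' set of some branch in a random labelled coalescent topology on `n` leaves
#' (uniform over coalescent histories).  For `2 <= k <= n-1` the closed form
#' is
#' \deqn{P(n,k) = \frac{2 (n-k)}{(k+1)(n-1)\binom{n-2}{k-1}},}
#' derived from the merge process: the k target lineages must coalesce among
#' themselves before any of them merges with an outside lineage.  The full
#' set (`k = n`) is always a clade (the root).  A single leaf is treated as
#' trivially subtended by its terminal branch (probability 1); set
#' `singleton_is_clade = FALSE` to count singletons as non-clades.
#'
#' @param n tree size (>= 2).
#' @param k subset size, `1 <= k <= n`.
#' @param singleton_is_clade convention for `k = 1`.
#' @return probability in `[0, 1]`.
#' @export
clade_probability <- function(n, k, singleton_is_clade = TRUE) {
  stopifnot(n >= 2)
  if (length(k) > 1)
    return(vapply(k, clade_probability, numeric(1), n = n,
                  singleton_is_clade = singleton_is_clade))
  if (k < 1 || k > n) stop("k must lie in [1, n]", call. = FALSE)
  if (k == n) return(1)
  if (k == 1) return(if (singleton_is_clade) 1 else 0)
  2 * (n - k) / ((k + 1) * (n - 1) * choose(n - 2, k - 1))
}

#' Chance-clade probabilities for the target-set sizes
#'
#' Diagnostic context for interpreting Tests 1 and 2: small target sets can
#' form clades anywhere by chance, so a matching clade is weak evidence of
#' phantom epistasis on its own.
#'
#' @param n tree (panel) size.
#' @param target_sizes integer vector of target-set sizes.
#' @param singleton_is_clade passed to [clade_probability()].
#' @return data.frame with columns `size` and `probability`.
#' @export
expected_problem_clades <- function(n, target_sizes,
                                    singleton_is_clade = TRUE) {
  stopifnot(all(target_sizes >= 1), all(target_sizes <= n))
  data.frame(size = target_sizes,
             probability = vapply(target_sizes, clade_probability, numeric(1),
                                  n = n,
                                  singleton_is_clade = singleton_is_clade))
}

#' Simulate whether a subset forms a clade in random coalescent topologies
#'
#' Monte-Carlo companion to [clade_probability()]: simulates labelled
#' coalescent topologies by uniform pairwise merging and reports the fraction
#' in which leaves `1..k` form a clade.
#'
#' @param n leaves; `k` subset size; `reps` topologies; `seed` RNG seed.
#' @param k,reps,seed see above.
#' @return list with `estimate`, `se`, `reps`.
#' @export
simulate_clade_probability <- function(n, k, reps = 1e4, seed = 1) {
  stopifnot(n >= 2, k >= 1, k <= n)
  set.seed(seed)
  hits <- 0L
  for (r in seq_len(reps)) {
    # lineages labelled by whether they are pure-target, pure-outside, mixed
    sz <- rep(1L, n)                 # target leaves first: 1..k
    is_t <- c(rep(TRUE, k), rep(FALSE, n - k))  # pure target lineage
    is_o <- !is_t
    alive <- rep(TRUE, n)
    ok <- k == 1L
    n_alive <- n
    while (n_alive > 1L) {
      idx <- which(alive)
      pr <- idx[sample.int(n_alive, 2L)]
      a <- pr[1]; b <- pr[2]
      new_t <- is_t[a] && is_t[b]
      new_o <- is_o[a] && is_o[b]
      nsz <- sz[a] + sz[b]
      if (new_t && nsz == k) { ok <- TRUE; break }
      if (!new_t && !new_o && (is_t[a] || is_t[b])) {
        # a target lineage merged outside before completion: clade impossible
        if ((is_t[a] && sz[a] < k) || (is_t[b] && sz[b] < k)) { ok <- FALSE; break }
      }
      alive[b] <- FALSE
      sz[a] <- nsz; is_t[a] <- new_t; is_o[a] <- new_o
      n_alive <- n_alive - 1L
    }
    if (ok) hits <- hits + 1L
  }
  p <- hits / reps
  list(estimate = p, se = sqrt(p * (1 - p) / reps), reps = reps)
}

#' Write a clade-probability table as TSV
#' @param n tree size.
#' @param k_values subset sizes.
#' @param path output path.
#' @param singleton_is_clade convention for k = 1.
#' @return `path`, invisibly.
#' @export
write_clade_probability_table <- function(n, k_values, path,
                                          singleton_is_clade = TRUE) {
  df <- data.frame(n = n, k = k_values,
                   probability = clade_probability(n, k_values,
                                                   singleton_is_clade))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
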