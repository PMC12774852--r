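# Independent oracles used across the suite.  These deliberately avoid the
# package's sweep/closed-form code paths: trees are rebuilt per position from
# the raw edge table, probabilities are computed by exhaustive recursion over
# merge histories, and regressions are solved through the normal equations.

# --- per-tree brute-force clade oracle -------------------------------------
# For each local tree independently, list every internal node's descendant
# sample set, then merge identical sets across adjacent trees.
oracle_clades <- function(ts, window = c(0, ts$sequence_length),
                          samples = ts$samples) {
  bp <- sort(unique(c(0, ts$edges$left, ts$edges$right, ts$sequence_length)))
  bp <- bp[bp >= window[1] & bp <= window[2]]
  bp <- sort(unique(c(window[1], bp, window[2])))
  env <- new.env(parent = emptyenv())
  n <- length(samples)
  for (i in seq_len(length(bp) - 1L)) {
    if (bp[i] >= bp[i + 1]) next
    x <- (bp[i] + bp[i + 1]) / 2
    act <- ts$edges$left <= x & ts$edges$right > x
    par <- rep(NA_integer_, nrow(ts$nodes))
    par[ts$edges$child[act] + 1L] <- ts$edges$parent[act]
    desc <- vector("list", nrow(ts$nodes))
    for (s in samples) desc[[s + 1L]] <- s
    for (v in order(ts$nodes$time)) {
      p <- par[v]
      if (!is.na(p) && length(desc[[v]]))
        desc[[p + 1L]] <- sort(c(desc[[p + 1L]], desc[[v]]))
    }
    for (v in seq_len(nrow(ts$nodes))) {
      d <- desc[[v]]
      if (length(d) >= 2L && length(d) < n) {
        key <- paste(d, collapse = ",")
        cur <- get0(key, envir = env)
        env[[key]] <- rbind(cur, c(bp[i], bp[i + 1]))
      }
    }
  }
  out <- list()
  for (k in ls(env)) {
    m <- env[[k]]
    m <- m[order(m[, 1]), , drop = FALSE]
    res <- m[1, , drop = FALSE]
    if (nrow(m) > 1) for (r in 2:nrow(m)) {
      if (m[r, 1] <= res[nrow(res), 2])
        res[nrow(res), 2] <- max(res[nrow(res), 2], m[r, 2])
      else res <- rbind(res, m[r, , drop = FALSE])
    }
    dimnames(res) <- NULL
    out[[k]] <- res
  }
  out
}

expect_clades_match_oracle <- function(ts, window = c(0, ts$sequence_length),
                                       samples = ts$samples) {
  orc <- oracle_clades(ts, window, samples)
  cl <- enumerate_clades(ts, window = window, samples = samples)
  keys <- vapply(cl, function(r) paste(r$samples, collapse = ","), "")
  expect_setequal(keys, names(orc))
  for (i in seq_along(cl)) {
    sp <- cl[[i]]$spans
    dimnames(sp) <- NULL
    expect_equal(sp, orc[[keys[i]]], info = paste("clade", keys[i]))
  }
  invisible(TRUE)
}

# --- coalescent clade probability oracles ----------------------------------
# Exact probability that the first k labels form a clade, by recursion over
# the merge process: state (a, o) = surviving target / outside lineages.
oracle_clade_prob_recursion <- function(n, k) {
  if (k == n || k == 1) return(1)
  memo <- new.env(parent = emptyenv())
  f <- function(a, o) {
    if (a == 1) return(1)
    key <- paste(a, o)
    v <- get0(key, envir = memo)
    if (!is.null(v)) return(v)
    tot <- choose(a + o, 2)
    v <- (choose(a, 2) * f(a - 1, o) +
            (if (o >= 2) choose(o, 2) * f(a, o - 1) else 0)) / tot
    assign(key, v, envir = memo)
    v
  }
  f(k, n - k)
}

# Raw enumeration over every merge sequence (histories are equiprobable at
# each step choosing a uniform pair); feasible for n <= 6.
oracle_clade_prob_paths <- function(n, k) {
  target <- seq_len(k)
  recurse <- function(lineages, prob) {
    if (length(lineages) == 1L) return(0)
    m <- length(lineages)
    total <- 0
    pr <- prob / choose(m, 2)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      merged <- sort(c(lineages[[i]], lineages[[j]]))
      if (identical(merged, target)) { total <- total + pr; next }
      # a partial target lineage merging outside kills the clade
      ni <- sum(lineages[[i]] %in% target); nj <- sum(lineages[[j]] %in% target)
      if ((ni > 0 || nj > 0) && any(!merged %in% target) &&
          any(merged %in% target)) next
      rest <- lineages[-c(i, j)]
      rest[[length(rest) + 1L]] <- merged
      total <- total + recurse(rest, pr)
    }
    total
  }
  if (k == n || k == 1) return(1)
  recurse(as.list(seq_len(n)), 1)
}

# --- constructive compatibility oracle -------------------------------------
# Enumerate every labelled coalescent history on n leaves and record which
# pairs of sample sets co-occur as clades of one tree (singletons and the
# full set are clades of every tree).
oracle_cooccur_pairs <- function(n) {
  env <- new.env(parent = emptyenv())
  add_family <- function(sets) {
    keys <- vapply(sets, function(s) paste(s, collapse = ","), "")
    for (a in keys) for (b in keys) env[[paste(a, "|", b)]] <- TRUE
  }
  recurse <- function(lineages, clades) {
    if (length(lineages) == 1L) {
      add_family(clades)
      return(invisible())
    }
    m <- length(lineages)
    for (i in 1:(m - 1)) for (j in (i + 1):m) {
      merged <- sort(c(lineages[[i]], lineages[[j]]))
      rest <- lineages[-c(i, j)]
      rest[[length(rest) + 1L]] <- merged
      recurse(rest, c(clades, list(merged)))
    }
  }
  singles <- as.list(seq_len(n))
  recurse(singles, singles)
  env
}

# --- regression oracles -----------------------------------------------------
# s-coefficient of z ~ 1 + x1 + x2 + s via the normal equations directly.
oracle_beta_zs <- function(z, x1, x2) {
  X <- cbind(1, x1, x2, x1 * x2)
  solve(crossprod(X), crossprod(X, z))[4]
}

# random non-degenerate genotype pair over n haplotypes
random_pair <- function(n, p1 = 0.4, p2 = 0.4) {
  repeat {
    x1 <- rbinom(n, 1, p1); x2 <- rbinom(n, 1, p2)
    ok <- var(x1) > 0 && var(x2) > 0 &&
      qr(cbind(1, x1, x2, x1 * x2))$rank == 4
    if (ok) return(genotype_pair(x1, x2))
  }
}
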