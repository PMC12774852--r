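# Coalescent simulation with recombination (sequentially Markov
# approximation), neutral mutations, and the phantom / true epistasis
# phenotype models used by the simulation study.

#' Simulation configuration
#'
#' @param n_study diploid individuals for interaction testing.
#' @param n_panel haplotypes in the held-out panel (whose ARG the tests use).
#' @param sequence_length bp.
#' @param Ne effective population size (constant-size demography).
#' @param mutation_rate per bp per generation.
#' @param recomb_rate crossovers per bp per generation (1e-8 = 1 cM/Mb).
#' @param seed RNG seed.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_study = 2000, n_panel = 200,
                       sequence_length = 5e6, Ne = 1e4,
                       mutation_rate = 2.36e-8, recomb_rate = 1e-8,
                       seed = 1) {
  stopifnot(n_study >= 2, n_panel >= 2, sequence_length > 0,
            mutation_rate > 0, recomb_rate >= 0)
  structure(list(n_study = as.integer(n_study), n_panel = as.integer(n_panel),
                 sequence_length = sequence_length, Ne = Ne,
                 mutation_rate = mutation_rate, recomb_rate = recomb_rate,
                 seed = as.integer(seed)),
            class = "sim_config")
}

#' Read a simulation configuration from a YAML file
#'
#' The file holds any subset of the [sim_config()] fields; unspecified
#' fields take the defaults.  Extra entries matching [phantom_sim_study()]
#' arguments are returned in the `study` attribute.
#'
#' @param path YAML file path.
#' @return a `sim_config`.
#' @export
read_sim_config <- function(path) {
  if (!requireNamespace("yaml", quietly = TRUE))
    stop("the yaml package is required to read config files", call. = FALSE)
  vals <- yaml::read_yaml(path)
  known <- names(formals(sim_config))
  take <- vals[intersect(names(vals), known)]
  # YAML 1.1 only recognises exponents with an explicit sign, so "2.0e5"
  # arrives as character; coerce numerics defensively
  take <- lapply(take, function(v) if (is.character(v)) as.numeric(v) else v)
  cfg <- do.call(sim_config, take)
  attr(cfg, "study") <- vals[setdiff(names(vals), known)]
  cfg
}

#' Simulate an ARG under the sequentially Markov coalescent
#'
#' Simulates the genealogy of `n` haplotypes over a recombining sequence in a
#' constant-size panmictic population: a standard coalescent tree at the left
#' end, then, moving rightwards, recombination events at rate proportional to
#' total branch length detach a lineage at a uniform point and re-coalesce it
#' into the remaining tree (the Markov approximation to the full ancestral
#' recombination graph).  Returns the result as a [tree_seq()] (no
#' mutations; see [sim_mutations()]).
#'
#' @param n haplotypes (>= 2).
#' @param sequence_length bp.
#' @param Ne effective population size.
#' @param recomb_rate crossovers per bp per generation.
#' @return a `tree_seq` with `n` sample nodes.
#' @export
sim_tree_seq <- function(n, sequence_length, Ne = 1e4, recomb_rate = 1e-8) {
  stopifnot(n >= 2, sequence_length > 0)
  L <- sequence_length
  cap <- as.integer(2 * n + 1000)
  time <- numeric(cap); parent <- integer(cap)
  child1 <- integer(cap); child2 <- integer(cap)
  active <- logical(cap); seg_start <- numeric(cap)

  grow <- function() {
    cap2 <- cap * 2L
    length(time) <<- cap2; length(parent) <<- cap2
    length(child1) <<- cap2; length(child2) <<- cap2
    length(active) <<- cap2; length(seg_start) <<- cap2
    time[(cap + 1L):cap2] <<- 0; parent[(cap + 1L):cap2] <<- 0L
    child1[(cap + 1L):cap2] <<- 0L; child2[(cap + 1L):cap2] <<- 0L
    active[(cap + 1L):cap2] <<- FALSE; seg_start[(cap + 1L):cap2] <<- 0
    cap <<- cap2
  }

  # edge buffer
  ecap <- as.integer(4 * n + 1000); ne <- 0L
  eL <- numeric(ecap); eR <- numeric(ecap)
  eP <- integer(ecap); eC <- integer(ecap)
  egrow <- function() {
    ecap2 <- ecap * 2L
    length(eL) <<- ecap2; length(eR) <<- ecap2
    length(eP) <<- ecap2; length(eC) <<- ecap2
    ecap <<- ecap2
  }
  flush_edge <- function(c_, x) {
    if (parent[c_] != 0L && seg_start[c_] < x) {
      if (ne == ecap) egrow()
      ne <<- ne + 1L
      eL[ne] <<- seg_start[c_]; eR[ne] <<- x
      eP[ne] <<- parent[c_]; eC[ne] <<- c_
    }
  }

  # initial coalescent tree at the left edge
  active[1:n] <- TRUE
  lineage <- 1:n; k <- n; t <- 0; nxt <- n
  while (k > 1L) {
    t <- t + stats::rexp(1, k * (k - 1) / 2 / (2 * Ne))
    pick <- sample.int(k, 2L)
    a <- lineage[pick[1]]; b <- lineage[pick[2]]
    nxt <- nxt + 1L
    if (nxt > cap) grow()
    time[nxt] <- t; child1[nxt] <- a; child2[nxt] <- b
    parent[a] <- nxt; parent[b] <- nxt
    active[nxt] <- TRUE
    lineage <- c(lineage[-pick], nxt); k <- k - 1L
  }
  stack <- integer(2 * n)   # reused DFS stack

  x <- 0
  repeat {
    idx <- which(active & parent > 0L)
    bl <- time[parent[idx]] - time[idx]
    tot <- sum(bl)
    dx <- stats::rexp(1, recomb_rate * tot)
    xn <- x + dx
    if (xn >= L) break
    # cut point: branch u at height g
    cb <- cumsum(bl)
    u <- idx[findInterval(stats::runif(1) * tot, cb) + 1L]
    p <- parent[u]; pp <- parent[p]
    g <- stats::runif(1, time[u], time[p])
    sib <- if (child1[p] == u) child2[p] else child1[p]
    # flush edges that change at xn, then contract p away
    flush_edge(u, xn); flush_edge(sib, xn); flush_edge(p, xn)
    parent[sib] <- pp
    if (pp != 0L) {
      if (child1[pp] == p) child1[pp] <- sib else child2[pp] <- sib
      seg_start[sib] <- xn
    }
    active[p] <- FALSE; parent[p] <- 0L; child1[p] <- 0L; child2[p] <- 0L
    parent[u] <- 0L
    # floating subtree under u
    ns <- 1L; stack[1L] <- u
    sub <- logical(cap)
    while (ns > 0L) {
      v <- stack[ns]; ns <- ns - 1L
      sub[v] <- TRUE
      if (child1[v] != 0L) { ns <- ns + 1L; stack[ns] <- child1[v] }
      if (child2[v] != 0L) { ns <- ns + 1L; stack[ns] <- child2[v] }
    }
    rem <- which(active & !sub)
    starts <- time[rem]
    ends <- rep(Inf, length(rem))
    has_p <- parent[rem] > 0L
    ends[has_p] <- time[parent[rem][has_p]]
    # lineage-count profile of the remaining tree above g
    k0 <- sum(starts <= g & ends > g)
    evt <- c(starts[starts > g], ends[ends > g & is.finite(ends)])
    evd <- c(rep(1L, sum(starts > g)), rep(-1L, sum(ends > g & is.finite(ends))))
    o <- order(evt)
    evt <- evt[o]; evd <- evd[o]
    kk <- c(k0, k0 + cumsum(evd))          # count within each epoch
    ep0 <- c(g, evt)                        # epoch left ends
    ep1 <- c(evt, Inf)                      # epoch right ends
    haz <- kk * (ep1 - ep0) / (2 * Ne)
    haz[length(haz)] <- Inf                 # final epoch has k = 1 forever
    E <- stats::rexp(1)
    ch <- cumsum(haz)
    j <- which(ch >= E)[1]
    prev <- if (j > 1L) ch[j - 1L] else 0
    t_co <- ep0[j] + (E - prev) * 2 * Ne / kk[j]
    # target branch crossing t_co
    cross <- rem[starts <= t_co & ends > t_co]
    nxt <- nxt + 1L
    if (nxt > cap) grow()
    w <- nxt
    time[w] <- t_co; active[w] <- TRUE
    if (length(cross) == 0L) {
      # above the remaining root: new root
      rroot <- rem[!is.finite(ends)][1]
      child1[w] <- rroot; child2[w] <- u
      parent[rroot] <- w; seg_start[rroot] <- xn
      parent[w] <- 0L
    } else {
      v <- if (length(cross) == 1L) cross else cross[sample.int(length(cross), 1L)]
      q <- parent[v]
      flush_edge(v, xn)
      child1[w] <- v; child2[w] <- u
      parent[v] <- w; seg_start[v] <- xn
      parent[w] <- q
      if (q != 0L) {
        if (child1[q] == v) child1[q] <- w else child2[q] <- w
        seg_start[w] <- xn
      }
    }
    parent[u] <- w; seg_start[u] <- xn
    x <- xn
  }
  # final flush
  for (c_ in which(active & parent > 0L)) flush_edge(c_, L)

  nodes <- data.frame(id = 0:(nxt - 1L),
                      is_sample = as.integer(seq_len(nxt) <= n),
                      time = time[seq_len(nxt)])
  edges <- data.frame(left = eL[seq_len(ne)], right = eR[seq_len(ne)],
                      parent = eP[seq_len(ne)] - 1L,
                      child = eC[seq_len(ne)] - 1L)
  tree_seq(nodes, edges, sequence_length = L)
}

#' Add neutral mutations to a simulated ARG
#'
#' Poisson mutations on each edge at `rate` per bp per generation, uniform
#' positions (infinite sites: continuous positions, almost surely unique).
#'
#' @param ts a `tree_seq` without sites.
#' @param rate mutation rate per bp per generation.
#' @return a `tree_seq` with sites and mutations.
#' @export
sim_mutations <- function(ts, rate) {
  e <- ts$edges
  area <- (e$right - e$left) *
    (ts$nodes$time[e$parent + 1L] - ts$nodes$time[e$child + 1L])
  counts <- stats::rpois(nrow(e), rate * area)
  tot <- sum(counts)
  if (tot == 0L) return(ts)
  ei <- rep.int(seq_len(nrow(e)), counts)
  pos <- stats::runif(tot, e$left[ei], e$right[ei])
  dup <- duplicated(pos)
  if (any(dup)) { pos <- pos[!dup]; ei <- ei[!dup]; tot <- length(pos) }
  o <- order(pos)
  pos <- pos[o]; ei <- ei[o]
  sites <- data.frame(id = 0:(tot - 1L), position = pos,
                      ancestral_state = rep("0", tot))
  mutations <- data.frame(id = 0:(tot - 1L), site = 0:(tot - 1L),
                          node = e$child[ei], derived_state = rep("1", tot))
  tree_seq(ts$nodes, ts$edges, sites, mutations, ts$sequence_length)
}

#' Simulate a study cohort plus held-out panel from one ARG
#'
#' One coalescent simulation of `2 n_study + n_panel` haplotypes; the first
#' `2 n_study` haplotypes form the (diploid) study cohort (genotypes only,
#' consecutive haplotypes paired into individuals), the remainder the
#' held-out panel whose true ARG the phantom tests use.
#'
#' @param config a [sim_config()].
#' @return list of class `panel_sim` with `ts`, `study_haps`, `panel_haps`,
#'   `config`.
#' @export
simulate_panel <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n_hap <- 2L * config$n_study + config$n_panel
  ts <- sim_tree_seq(n_hap, config$sequence_length, Ne = config$Ne,
                     recomb_rate = config$recomb_rate)
  ts <- sim_mutations(ts, config$mutation_rate)
  structure(list(ts = ts,
                 study_haps = 0:(2L * config$n_study - 1L),
                 panel_haps = (2L * config$n_study):(n_hap - 1L),
                 config = config),
            class = "panel_sim")
}

#' @export
print.panel_sim <- function(x, ...) {
  cat("panel_sim:", length(x$study_haps) / 2, "diploid study individuals,",
      length(x$panel_haps), "panel haplotypes,",
      nrow(x$ts$sites), "sites\n")
  invisible(x)
}

#' Diploid dosages from haplotype carrier sets
#'
#' Consecutive haplotypes (in the order of `hap_ids`) are paired into
#' individuals; the dosage is the number of carried copies (0/1/2).
#'
#' @param carriers sorted haplotype ids carrying the allele.
#' @param hap_ids the cohort's haplotype ids, length 2 x individuals.
#' @return integer dosage vector of length `length(hap_ids) / 2`.
#' @export
hap_dosage <- function(carriers, hap_ids) {
  idx <- match(carriers, hap_ids)
  idx <- idx[!is.na(idx)]
  tabulate((idx + 1L) %/% 2L, nbins = length(hap_ids) %/% 2L)
}

#' Phantom-epistasis phenotype: one masked additive causal variant
#'
#' `y = effect * g + e`, with the residual variance chosen so the causal term
#' explains exactly `h2` of the phenotypic variance.  The causal variant is
#' then masked from the scan genotypes (the caller excludes it).
#'
#' @param g causal-variant dosage (or haploid genotype) vector.
#' @param effect per-allele effect size on the raw genotype scale.
#' @param h2 heritability of the causal term, in `(0, 0.5)`.
#' @return list of class `phenotype_sim`: `phenotype`, `kind`, `effect`,
#'   `h2`, `sd_y`, `b_sd` (the causal effect re-expressed in phenotype SD
#'   units) and `epsilon`.
#' @export
simulate_phantom_phenotype <- function(g, effect = 0.2, h2 = 0.01) {
  if (stats::var(g) == 0)
    stop("monomorphic causal site", call. = FALSE)
  if (h2 <= 0 || h2 >= 0.5)
    stop("h2 out of supported range (0, 0.5)", call. = FALSE)
  gen <- effect * g
  ve <- stats::var(gen) * (1 - h2) / h2
  eps <- stats::rnorm(length(g), 0, sqrt(ve))
  y <- gen + eps
  structure(list(phenotype = y, kind = "phantom", effect = effect, h2 = h2,
                 sd_y = stats::sd(y), b_sd = effect / stats::sd(y),
                 epsilon = eps),
            class = "phenotype_sim")
}

#' Purely epistatic phenotype: interaction effect, zero main effects
#'
#' `y = effect * (g1 * g2) + e`, residual variance scaled so the interaction
#' term explains `h2` of the phenotypic variance.  No additive terms are
#' generated.  Pairs whose interaction is indistinguishable from an additive
#' effect (nested carrier sets, or an interaction product collinear with the
#' main effects) are rejected as degenerate.
#'
#' @param g1,g2 dosage vectors of the two interacting variants.
#' @param effect interaction effect size.
#' @param h2 heritability of the interaction term.
#' @return list of class `phenotype_sim` (kind `"true_epistasis"`).
#' @export
simulate_true_epistasis <- function(g1, g2, effect = 0.2, h2 = 0.01) {
  w <- g1 * g2
  if (all(w == 0)) stop("empty joint-carrier set", call. = FALSE)
  if (h2 <= 0 || h2 >= 0.5)
    stop("h2 out of supported range (0, 0.5)", call. = FALSE)
  if (qr(cbind(1, g1, g2, w))$rank < 4L)
    stop(errorCondition("degenerate pair: interaction collinear with main effects",
                        class = c("phantomepi_degenerate_pair", "error",
                                  "condition")))
  gen <- effect * w
  ve <- stats::var(gen) * (1 - h2) / h2
  eps <- stats::rnorm(length(w), 0, sqrt(ve))
  y <- gen + eps
  structure(list(phenotype = y, kind = "true_epistasis", effect = effect,
                 h2 = h2, sd_y = stats::sd(y), b_sd = effect / stats::sd(y),
                 epsilon = eps),
            class = "phenotype_sim")
}

#' Greedy windowed LD pruning
#'
#' Within each sliding window of `window` variants (advancing by `step`),
#' repeatedly removes one member of the worst pair with squared correlation
#' above `r2_threshold` until none remains.  The member with the smaller
#' variance (lower minor-allele frequency) is removed; ties go to the later
#' index.  Deterministic.
#'
#' @param G numeric matrix, individuals x variants (dosages).
#' @param window window size in variants.
#' @param step step size in variants.
#' @param r2_threshold squared-correlation threshold.
#' @return integer vector of retained variant indices.
#' @export
ld_prune <- function(G, window = 50, step = 5, r2_threshold = 0.7) {
  m <- ncol(G)
  if (m == 0L) return(integer(0))
  keep <- rep(TRUE, m)
  v <- apply(G, 2, stats::var)
  start <- 1L
  repeat {
    idx <- seq.int(start, min(start + window - 1L, m))
    idx <- idx[keep[idx] & v[idx] > 0]
    if (length(idx) >= 2L) {
      repeat {
        C2 <- suppressWarnings(stats::cor(G[, idx, drop = FALSE]))^2
        C2[!is.finite(C2)] <- 0
        diag(C2) <- 0
        mx <- max(C2)
        if (mx <= r2_threshold) break
        w_ <- which(C2 == mx, arr.ind = TRUE)[1, ]
        i <- idx[w_[1]]; j <- idx[w_[2]]
        drop <- if (v[i] < v[j]) i else if (v[j] < v[i]) j else max(i, j)
        keep[drop] <- FALSE
        idx <- idx[idx != drop]
        if (length(idx) < 2L) break
      }
    }
    if (start + window - 1L >= m) break
    start <- start + step
  }
  which(keep)
}

#' Pairwise interaction scan
#'
#' Fits `y ~ g_i + g_j + g_i:g_j` by least squares for every pair of the
#' supplied variants, tests the interaction coefficient with a two-sided
#' Z-test, and applies a Bonferroni correction over the tested pairs.
#' Rank-deficient pair designs are skipped (counted).
#'
#' @param G individuals x variants dosage matrix.
#' @param y phenotype vector.
#' @param positions optional bp positions of the variants (reported back).
#' @param alpha family-wise significance level before correction.
#' @param pairs optional 2-column matrix of variant index pairs to test;
#'   default all pairs.
#' @return list of class `interaction_scan`: `results` (data.frame i, j,
#'   pos_i, pos_j, beta12, se, z, p, significant), `threshold`, `n_tested`,
#'   `n_skipped`, `alpha`.
#' @export
interaction_scan <- function(G, y, positions = NULL, alpha = 0.05,
                             pairs = NULL) {
  m <- ncol(G); n <- nrow(G)
  if (m < 2L) stop("need at least 2 variants", call. = FALSE)
  if (is.null(positions)) positions <- seq_len(m)
  if (is.null(pairs)) {
    pairs <- t(utils::combn(m, 2L))
  }
  H <- G * G
  cs <- colSums(G)
  CGG <- crossprod(G)
  CHG <- crossprod(H, G)
  CHH <- crossprod(H)
  Gy <- as.numeric(crossprod(G, y))
  CGyG <- crossprod(G, G * y)
  sy <- sum(y); yty <- sum(y * y)
  np <- nrow(pairs)
  beta12 <- se <- z <- p <- rep(NA_real_, np)
  skipped <- 0L
  for (r in seq_len(np)) {
    i <- pairs[r, 1]; j <- pairs[r, 2]
    XtX <- matrix(c(n,        cs[i],     cs[j],     CGG[i, j],
                    cs[i],    CGG[i, i], CGG[i, j], CHG[i, j],
                    cs[j],    CGG[i, j], CGG[j, j], CHG[j, i],
                    CGG[i, j], CHG[i, j], CHG[j, i], CHH[i, j]), 4, 4)
    XtY <- c(sy, Gy[i], Gy[j], CGyG[i, j])
    inv <- tryCatch(solve(XtX), error = function(e) NULL)
    if (is.null(inv) || !all(is.finite(inv))) { skipped <- skipped + 1L; next }
    bb <- inv %*% XtY
    rss <- yty - sum(bb * XtY)
    if (rss <= 0) { skipped <- skipped + 1L; next }
    s2 <- rss / (n - 4)
    beta12[r] <- bb[4]
    se[r] <- sqrt(s2 * inv[4, 4])
    z[r] <- beta12[r] / se[r]
    p[r] <- 2 * stats::pnorm(-abs(z[r]))
  }
  tested <- which(!is.na(p))
  threshold <- alpha / max(1L, length(tested))
  res <- data.frame(i = pairs[, 1], j = pairs[, 2],
                    pos_i = positions[pairs[, 1]], pos_j = positions[pairs[, 2]],
                    beta12 = beta12, se = se, z = z, p = p,
                    significant = !is.na(p) & p <= threshold)
  structure(list(results = res, threshold = threshold,
                 n_tested = length(tested), n_skipped = skipped,
                 alpha = alpha),
            class = "interaction_scan")
}

#' @export
print.interaction_scan <- function(x, ...) {
  cat(sprintf("interaction scan: %d pairs tested (%d skipped), Bonferroni threshold %.3g\n",
              x$n_tested, x$n_skipped, x$threshold))
  sig <- x$results[x$results$significant, ]
  cat(sprintf("  %d significant pair(s)\n", nrow(sig)))
  if (nrow(sig)) print(utils::head(sig[order(sig$p), ], 5))
  invisible(x)
}

#' ROC curve for phantom versus true epistasis discrimination
#'
#' Sweeps an upper bound on the "reasonable" omitted-variant effect size:
#' instances with minimum b at or below the bound are classified as phantom.
#' Phantom instances are the positive class.
#'
#' @param phantom_results minimum-b values from phantom-epistasis instances.
#' @param true_results minimum-b values from true-epistasis instances.
#' @return list of class `roc_curve` with `points` (data.frame threshold,
#'   fpr, tpr) and `auc` (trapezoidal; equals the Mann-Whitney statistic
#'   with ties counted half).
#' @export
roc_evaluation <- function(phantom_results, true_results) {
  stopifnot(length(phantom_results) > 0, length(true_results) > 0)
  thr <- sort(unique(c(phantom_results, true_results)))
  tpr <- vapply(thr, function(t) mean(phantom_results <= t), numeric(1))
  fpr <- vapply(thr, function(t) mean(true_results <= t), numeric(1))
  pts <- data.frame(threshold = c(-Inf, thr), fpr = c(0, fpr), tpr = c(0, tpr))
  auc <- sum(diff(pts$fpr) * (utils::head(pts$tpr, -1) + utils::tail(pts$tpr, -1)) / 2)
  structure(list(points = pts, auc = auc), class = "roc_curve")
}

#' @export
print.roc_curve <- function(x, ...) {
  cat(sprintf("ROC: AUC = %.3f over %d thresholds\n", x$auc,
              nrow(x$points) - 1L))
  invisible(x)
}
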