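# The SMC simulator, phenotype models, LD pruning, interaction scan and ROC.

test_that("simulation is deterministic given the seed and splits correctly", {
  cfg <- sim_config(n_study = 25, n_panel = 10, sequence_length = 1e5,
                    seed = 5)
  a <- simulate_panel(cfg)
  b <- simulate_panel(cfg)
  expect_equal(a$ts$edges, b$ts$edges)
  expect_equal(a$ts$sites$position, b$ts$sites$position)
  # split is disjoint and exhaustive
  expect_length(intersect(a$study_haps, a$panel_haps), 0)
  expect_setequal(c(a$study_haps, a$panel_haps), a$ts$samples)
})

test_that("YAML configs round-trip into sim_config", {
  skip_if_not_installed("yaml")
  path <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_study: 50", "n_panel: 12", "sequence_length: 2.0e5",
               "seed: 9", "n_phantom: 3"), path)
  cfg <- read_sim_config(path)
  expect_equal(cfg$n_study, 50L)
  expect_equal(cfg$n_panel, 12L)
  expect_equal(cfg$sequence_length, 2e5)
  expect_equal(attr(cfg, "study")$n_phantom, 3)
  # unspecified fields keep defaults
  expect_equal(cfg$mutation_rate, 2.36e-8)
})

test_that("simulated tree sequences are structurally valid genealogies", {
  set.seed(31)
  ts <- sim_tree_seq(12, 2e5, Ne = 1e4, recomb_rate = 1e-7)
  bp <- tree_breakpoints(ts)
  for (x in (bp[-length(bp)] + bp[-1]) / 2) {
    tr <- local_tree(ts, x)
    # every sample reaches a single common root
    roots <- unique(vapply(ts$samples, function(s) {
      v <- s
      while (!is.na(tr$parent[v + 1L])) v <- tr$parent[v + 1L]
      v
    }, integer(1)))
    expect_length(roots, 1)
  }
})

test_that("segregating sites match the Watterson expectation", {
  Ne <- 1e4; mu <- 2.36e-8; L <- 2e5; n <- 20
  theta <- 4 * Ne * mu * L
  expected <- theta * sum(1 / (1:(n - 1)))
  set.seed(8)
  S <- replicate(5, {
    ts <- sim_tree_seq(n, L, Ne = Ne, recomb_rate = 1e-8)
    nrow(sim_mutations(ts, mu)$sites)
  })
  # coalescent variance of S is large; 5 replicates, generous band
  expect_lt(abs(mean(S) - expected) / expected, 0.35)
})

test_that("phantom phenotypes decompose variance as configured", {
  set.seed(4)
  g <- rbinom(5000, 2, 0.2)
  ph <- simulate_phantom_phenotype(g, effect = 0.2, h2 = 0.01)
  r2 <- summary(lm(ph$phenotype ~ g))$r.squared
  expect_lt(abs(r2 - 0.01), 0.01)
  expect_equal(ph$b_sd, 0.2 / sd(ph$phenotype))
  expect_error(simulate_phantom_phenotype(rep(1, 10)), "monomorphic")
  expect_error(simulate_phantom_phenotype(g, h2 = 0.9), "out of supported")
})

test_that("regression on the unmasked causal genotype recovers the effect", {
  set.seed(12)
  est <- replicate(100, {
    g <- rbinom(800, 2, 0.15)
    ph <- simulate_phantom_phenotype(g, effect = 0.2, h2 = 0.01)
    coef(lm(ph$phenotype ~ g))[2]
  })
  se <- sd(est) / sqrt(length(est))
  expect_lt(abs(mean(est) - 0.2), 2 * se + 0.02)
})

test_that("true-epistasis phenotypes have zero main effects and h2 on the product", {
  set.seed(6)
  g1 <- rbinom(4000, 2, 0.3); g2 <- rbinom(4000, 2, 0.3)
  ph <- simulate_true_epistasis(g1, g2, effect = 0.2, h2 = 0.01)
  fit <- summary(lm(ph$phenotype ~ g1 * g2))
  expect_lt(abs(coef(fit)["g1:g2", 1] - 0.2), 3 * coef(fit)["g1:g2", 2])
  # permuting the phenotype destroys the signal
  perm <- sample(ph$phenotype)
  pfit <- summary(lm(perm ~ g1 * g2))
  expect_gt(coef(pfit)["g1:g2", 4], 1e-4)
  # nested carriers: interaction collinear with a main effect
  gn <- pmin(g1, 1)
  expect_error(simulate_true_epistasis(gn, pmax(gn, g1), effect = 0.2),
               class = "phantomepi_degenerate_pair")
  expect_error(simulate_true_epistasis(g1 * 0, g2), "joint-carrier")
})

test_that("LD pruning retains independent variants and drops duplicates", {
  set.seed(3)
  G <- matrix(rbinom(200 * 10, 2, 0.3), 200, 10)
  expect_equal(ld_prune(G), 1:10)           # independent: all retained
  G2 <- cbind(G[, 1], G[, 1], G[, 2])       # perfect duplicate
  expect_length(ld_prune(G2), 2)
  # post-hoc: no window retains a pair above the threshold
  set.seed(9)
  base <- matrix(rbinom(300 * 40, 2, 0.3), 300, 40)
  Gc <- base[, rep(1:40, each = 5)] + matrix(rbinom(300 * 200, 2, 0.15),
                                             300, 200)
  kept <- ld_prune(Gc, window = 50, step = 5, r2_threshold = 0.7)
  for (start in seq(1, length(kept), by = 5)) {
    idx <- kept[start:min(start + 49, length(kept))]
    win <- which(kept >= min(idx) & kept <= max(idx))
    C2 <- suppressWarnings(cor(Gc[, idx]))^2
    diag(C2) <- 0
    expect_lte(max(C2, na.rm = TRUE), 0.7 + 1e-12)
  }
  # determinism
  expect_equal(ld_prune(Gc), ld_prune(Gc))
})

test_that("interaction scans are calibrated under the null and find planted effects", {
  set.seed(17)
  # family-wise error under pure noise stays at or below alpha
  fwer <- mean(replicate(300, {
    G <- matrix(rbinom(150 * 8, 2, 0.3), 150, 8)
    y <- rnorm(150)
    sc <- interaction_scan(G, y, alpha = 0.05)
    any(sc$results$significant, na.rm = TRUE)
  }))
  expect_lte(fwer, 0.05 + 3 * sqrt(0.05 * 0.95 / 300))
  # a large planted interaction is the top hit
  set.seed(18)
  G <- matrix(rbinom(500 * 10, 2, 0.4), 500, 10)
  y <- 0.8 * G[, 3] * G[, 7] + rnorm(500)
  sc <- interaction_scan(G, y, alpha = 0.05)
  top <- sc$results[which.min(sc$results$p), ]
  expect_equal(sort(c(top$i, top$j)), c(3, 7))
  expect_true(top$significant)
  # threshold is alpha over the tested pairs; significance is p <= threshold
  expect_equal(sc$threshold, 0.05 / sc$n_tested)
  expect_equal(sc$results$significant,
               !is.na(sc$results$p) & sc$results$p <= sc$threshold)
  # determinism on identical input
  expect_equal(interaction_scan(G, y)$results$p, sc$results$p)
})

test_that("interaction-scan coefficients match lm on a pair design", {
  set.seed(21)
  G <- matrix(rbinom(300 * 4, 2, 0.3), 300, 4)
  y <- rnorm(300)
  sc <- interaction_scan(G, y)
  r <- sc$results[sc$results$i == 2 & sc$results$j == 4, ]
  fit <- summary(lm(y ~ G[, 2] * G[, 4]))
  expect_equal(r$beta12, coef(fit)[4, 1], tolerance = 1e-10)
  expect_equal(r$se, coef(fit)[4, 2], tolerance = 1e-3)
})

test_that("ROC evaluation sweeps the effect-size bound correctly", {
  r <- roc_evaluation(c(0.1, 0.2, 0.3), c(0.5, 0.6, 0.7))
  expect_equal(r$auc, 1)
  r2 <- roc_evaluation(c(0.1, 0.2, 0.3), c(0.1, 0.2, 0.3))
  expect_equal(r2$auc, 0.5)
  # infinite sentinels count as "never classified phantom" until the end
  r3 <- roc_evaluation(c(0.1, Inf), c(0.5, Inf))
  expect_gt(r3$auc, 0.5)
  # cross-check against an independent AUC implementation
  skip_if_not_installed("pROC")
  set.seed(2)
  ph <- runif(40); tr <- runif(40) + 0.3
  ours <- roc_evaluation(ph, tr)$auc
  # phantom = positive class, classified positive when value is small
  ref <- as.numeric(pROC::auc(pROC::roc(
    response = c(rep(1, 40), rep(0, 40)), predictor = c(ph, tr),
    direction = ">", quiet = TRUE)))
  expect_equal(ours, ref, tolerance = 1e-12)
})
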