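# The rejection-probability formula and Tests 1A / 1B.

test_that("rejection probability is alpha at b = 0 and symmetric in the bias", {
  cfg <- test_config(alpha = 0.05)
  expect_equal(rejection_probability(0, 0.5, 0.1, cfg), 0.05)
  p1 <- rejection_probability(0.3, 0.7, 0.05, cfg)
  p2 <- rejection_probability(-0.3, -0.7, 0.05, cfg)
  expect_equal(p1, p2)
  # strictly increasing in |m| and bounded in [alpha, 1)
  ms <- seq(0, 6, by = 0.2)
  ps <- vapply(ms, function(m) rejection_probability(m, 1, 1, cfg), numeric(1))
  expect_true(all(diff(ps) > 0))
  expect_true(all(ps >= 0.05 & ps < 1))
})

test_that("rejection probability matches a Monte-Carlo two-sided Z-test", {
  cfg <- test_config(alpha = 0.05)
  set.seed(123)
  m <- 2.5
  draws <- rnorm(1e6, mean = m, sd = 1)
  emp <- mean(abs(draws) > cfg$C)
  ana <- rejection_probability(m, 1, 1, cfg)
  mc_se <- sqrt(emp * (1 - emp) / 1e6)
  expect_lt(abs(emp - ana), 3 * mc_se)
})

test_that("Test 1A inverts the rejection probability", {
  cfg <- test_config(alpha = 0.05)
  for (P in c(0.2, 0.5, 0.8)) {
    for (beta in c(0.3, -0.8)) {
      for (sigma in c(0.01, 0.3)) {
        b <- test1a_b_for_probability(P, beta, sigma, cfg)
        expect_gte(b, 0)
        expect_equal(rejection_probability(b, abs(beta), sigma, cfg), P,
                     tolerance = 1e-8)
        # no smaller solution: a fine grid just below b stays under P
        grid <- seq(max(0, b - 1e-3), b - 1e-6, by = 1e-6)
        if (length(grid))
          expect_true(all(rejection_probability(grid, abs(beta), sigma, cfg) < P))
      }
    }
  }
  # continuity at the null: P -> alpha+ gives b -> 0
  expect_lt(test1a_b_for_probability(0.0501, 1, 1, cfg), 0.05)
  # halving the conditional coefficient doubles b exactly
  b1 <- test1a_b_for_probability(0.5, 0.8, 0.1, cfg)
  b2 <- test1a_b_for_probability(0.5, 0.4, 0.1, cfg)
  expect_equal(b2, 2 * b1)
  # sentinels and domain errors
  expect_identical(test1a_b_for_probability(0.5, 0, 0.1, cfg), Inf)
  expect_error(test1a_b_for_probability(0.04, 1, 0.1, cfg), "P_target")
})

test_that("Test 1B is the clamped boundary-alignment formula", {
  cfg <- test_config(alpha = 0.05)
  expect_equal(test1b_b_threshold(cfg$C, 0.7, 0.05, cfg), 0)
  expect_equal(test1b_b_threshold(1.2, 0.7, 0.05, cfg), 0)   # not significant
  b <- test1b_b_threshold(3.5, 0.7, 0.05, cfg)
  expect_equal(b, (3.5 - qnorm(0.975)) * 0.05 / 0.7)
  expect_equal(round(b, 2), 0.11)
  # sign-flip invariance of (t_hat, beta)
  expect_equal(test1b_b_threshold(-3.5, -0.7, 0.05, cfg), b)
  expect_identical(test1b_b_threshold(3.5, 0, 0.05, cfg), Inf)
})

test_that("observed interactions convert p-values to |Z| with flooring", {
  o <- observed_interaction(p_value = 1e-8)
  expect_equal(o$t_hat, qnorm(1 - 1e-8 / 2))
  expect_equal(o$source, "p_value")
  expect_warning(o0 <- observed_interaction(p_value = 0), "floor")
  expect_true(is.finite(o0$t_hat))
  expect_error(observed_interaction(), "exactly one")
  expect_error(observed_interaction(t_stat = 1, p_value = 0.5), "exactly one")
})

test_that("run_test1 flags target-set clades as unidentifiable with b = 0", {
  fx <- make_fixture("eight_sample")
  ts <- fx$ts
  m1 <- map_snp_to_branch(ts, 20); m2 <- map_snp_to_branch(ts, 70)
  pair <- genotype_pair_from_sets(m1$samples + 1, m2$samples + 1, n = 8,
                                  m1 = 20, m2 = 70)
  se <- estimate_sigma_s(pair, study_N = 5000)
  clades <- enumerate_clades(ts)
  res <- run_test1(clades, pair, se, obs = observed_interaction(p_value = 1e-8),
                   panel_samples = 0:7)
  keys <- vapply(clades, function(r) paste(r$samples, collapse = ","), "")
  # S = {2,5} is a clade of tree 2: perfect phantom candidate
  i_s <- which(keys == "2,5")
  expect_true(res$unidentifiable[i_s])
  expect_equal(res$b_1b[i_s], 0)
  expect_equal(attr(res, "minima")$test1a, 0)
  # the SNPs' own clades carry no leverage on the interaction
  i_x1 <- which(keys == "1,2,3,5")
  expect_false(res$unidentifiable[i_x1])
  expect_identical(res$b_1b[i_x1], Inf)
  # K2 = {6,7} and O = {0,4} are clades too: also unidentifiable
  expect_true(res$unidentifiable[which(keys == "6,7")])
  expect_true(res$unidentifiable[which(keys == "0,4")])
  # supported minimum carries the supporting SNP position
  expect_true(is.finite(attr(res, "minima")$test1a_supported))
})

test_that("run_test1 reports the infinite sentinel when no clade has leverage", {
  # panel where the only clades are the SNPs' own carrier sets
  nodes <- data.frame(id = 0:6, is_sample = c(rep(1, 4), 0, 0, 0),
                      time = c(0, 0, 0, 0, 1, 2, 3))
  edges <- data.frame(left = 0, right = 100,
                      parent = c(4, 4, 5, 5, 6, 6),
                      child = c(0, 1, 2, 4, 3, 5))  # caterpillar ((0,1),2),3
  ts <- tree_seq(nodes, edges, sequence_length = 100)
  # x1 = {0,1} (clade), x2 = {1,2}: s = {1}; clades: {0,1}, {0,1,2}
  pair <- genotype_pair_from_sets(c(1, 2), c(2, 3), n = 4)
  se <- estimate_sigma_s(pair, study_N = 1000)
  clades <- enumerate_clades(ts)
  res <- run_test1(clades, pair, se, panel_samples = 0:3)
  # {0,1} = x1 has no leverage; {0,1,2} = 1 - o has as = ... check output sane
  expect_true(all(res$b_1a_P0.5 >= 0))
  expect_s3_class(res, "test1_result")
})

test_that("empty clade list yields an empty result with a warning", {
  pair <- genotype_pair_from_sets(c(1, 2), c(2, 3), n = 4)
  se <- estimate_sigma_s(pair, study_N = 1000)
  expect_warning(res <- run_test1(structure(list(), class = "clade_list"),
                                  pair, se), "no clades")
  expect_equal(nrow(res), 0)
})
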