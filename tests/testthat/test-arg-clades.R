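test_that("single-tree ARG yields exactly the internal-node clades", {
  fx <- make_fixture("single_tree")
  cl <- enumerate_clades(fx$ts)
  sets <- lapply(cl, `[[`, "samples")
  expect_length(cl, 2)
  expect_setequal(lapply(sets, paste, collapse = ","), list("0,1", "2,3"))
  for (r in cl) expect_equal(unname(r$spans[1, ]), c(0, 100))
  # root included on request
  cl_root <- enumerate_clades(fx$ts, include_root = TRUE)
  expect_length(cl_root, 3)
})

test_that("a two-sample ARG has no non-trivial clades unless the root is included", {
  nodes <- data.frame(id = 0:2, is_sample = c(1, 1, 0), time = c(0, 0, 1))
  edges <- data.frame(left = 0, right = 50, parent = 2, child = 0:1)
  ts <- tree_seq(nodes, edges, sequence_length = 50)
  expect_length(enumerate_clades(ts), 0)
  cl <- enumerate_clades(ts, include_root = TRUE)
  expect_length(cl, 1)
  expect_equal(cl[[1]]$samples, 0:1)
})

test_that("interrupted clades are one record with multiple spans", {
  fx <- make_fixture("span_break")
  cl <- enumerate_clades(fx$ts)
  keys <- vapply(cl, function(r) paste(r$samples, collapse = ","), "")
  r01 <- cl[[which(keys == "0,1")]]
  expect_equal(nrow(r01$spans), 2)
  expect_equal(unname(r01$spans[, 1]), c(0, 60))
  expect_equal(unname(r01$spans[, 2]), c(40, 100))
})

test_that("no two records share a sample set and spans are clipped to the window", {
  set.seed(3)
  ts <- sim_tree_seq(20, 2e5, Ne = 1e4, recomb_rate = 1e-7)
  cl <- enumerate_clades(ts, window = c(5e4, 1.5e5))
  keys <- vapply(cl, function(r) paste(r$samples, collapse = ","), "")
  expect_equal(anyDuplicated(keys), 0L)
  for (r in cl) {
    expect_true(all(r$spans[, 1] >= 5e4 & r$spans[, 2] <= 1.5e5))
    expect_true(all(r$spans[, 1] < r$spans[, 2]))
    if (nrow(r$spans) > 1)                      # spans maximal: no abutting rows
      expect_true(all(r$spans[-1, 1] > r$spans[-nrow(r$spans), 2]))
  }
})

test_that("enumeration equals the per-tree brute-force oracle on simulated ARGs", {
  for (seed in 1:3) {
    set.seed(seed)
    ts <- sim_tree_seq(30, 1e5, Ne = 1e4, recomb_rate = 1e-7)
    expect_clades_match_oracle(ts)
  }
})

test_that("projected enumeration matches the oracle restricted to the subset", {
  set.seed(11)
  ts <- sim_tree_seq(25, 1e5, Ne = 1e4, recomb_rate = 1e-7)
  sub <- c(0:4, 10:14, 20:24)
  expect_clades_match_oracle(ts, samples = sub)
})

test_that("empty window overlap is an empty result, not an error", {
  fx <- make_fixture("single_tree")
  expect_warning(cl <- enumerate_clades(fx$ts, window = c(200, 300)),
                 "window")
  expect_length(cl, 0)
})

test_that("min_frequency filters clades by carrier fraction", {
  fx <- make_fixture("eight_sample")
  cl <- enumerate_clades(fx$ts, min_frequency = 0.4)
  expect_true(all(vapply(cl, `[[`, numeric(1), "frequency") >= 0.4))
  expect_gt(length(enumerate_clades(fx$ts)), length(cl))
})

test_that("supporting mutations are attached to the exact subtending clade", {
  fx <- make_fixture("eight_sample")
  cl <- enumerate_clades(fx$ts)
  keys <- vapply(cl, function(r) paste(r$samples, collapse = ","), "")
  k2 <- cl[[which(keys == "6,7")]]
  expect_equal(k2$mutations$position, 52)
  x1c <- cl[[which(keys == "1,2,3,5")]]
  expect_equal(x1c$mutations$position, 20)
})

test_that("SNPs map to the unique branch carrying their mutation", {
  fx <- make_fixture("eight_sample")
  m <- map_snp_to_branch(fx$ts, 20)
  expect_equal(m$samples, c(1L, 2L, 3L, 5L))
  expect_equal(m$frequency, 0.5)
  m2 <- map_snp_to_branch(fx$ts, 70, alt_carriers = c(2, 5, 6, 7))
  expect_equal(m2$samples, c(2L, 5L, 6L, 7L))
  expect_error(map_snp_to_branch(fx$ts, 33), class = "phantomepi_snp_absent")
  expect_error(map_snp_to_branch(fx$ts, 20, alt_carriers = c(1, 2)),
               class = "phantomepi_carrier_mismatch")
  # recurrent mutation: two mutations at one site
  ts2 <- fx$ts
  ts2$mutations <- rbind(ts2$mutations,
                         data.frame(id = 3, site = 0, node = 12,
                                    derived_state = "1"))
  expect_error(map_snp_to_branch(ts2, 20),
               class = "phantomepi_nonunique_mapping")
})

test_that("centimorgan windows invert the map correctly", {
  map <- uniform_recomb_map(1, 4e6)   # 1 cM/Mb
  w <- cm_window(map, 2e6, 1)
  expect_equal(c(w$left, w$right), c(1e6, 3e6))
  w0 <- cm_window(map, 2e6, 0)
  expect_equal(c(w0$left, w0$right), c(2e6, 2e6))
  # monotone in half-width
  widths <- seq(0, 2, by = 0.25)
  ws <- lapply(widths, function(h) cm_window(map, 2e6, h))
  spans <- vapply(ws, function(w) w$right - w$left, numeric(1))
  expect_true(all(diff(spans) >= 0))
})

test_that("non-uniform map windows match a fine-grid scan oracle", {
  # 3-segment map: 0.5, 3, 1 cM/Mb
  pos <- c(0, 1e6, 2e6, 4e6)
  cm <- c(0, 0.5, 3.5, 5.5)
  map <- recomb_map(pos, cm)
  grid <- seq(0, 4e6, by = 50)
  gcm <- approx(pos, cm, xout = grid)$y
  for (focal in c(5e5, 1.5e6, 2.5e6)) {
    for (h in c(0.3, 1)) {
      w <- cm_window(map, focal, h)
      g0 <- approx(pos, cm, xout = focal)$y
      lo <- grid[which.min(abs(gcm - (g0 - h)))]
      hi <- grid[which.min(abs(gcm - (g0 + h)))]
      expect_lt(abs(w$left - lo), 100)
      expect_lt(abs(w$right - hi), 100)
    }
  }
  expect_error(recomb_map(c(0), c(0)), "at least 2")
})

test_that("positions outside the map extrapolate with terminal rates", {
  map <- recomb_map(c(1e6, 2e6), c(0, 1))   # 1 cM/Mb inside
  expect_warning(g <- genetic_pos(map, 2.5e6), "extrapolat")
  expect_equal(g, 1.5)
  expect_warning(g2 <- genetic_pos(map, 5e5), "extrapolat")
  expect_equal(g2, -0.5)
})

test_that("clade tables flatten and write as TSV", {
  fx <- make_fixture("eight_sample")
  cl <- enumerate_clades(fx$ts)
  df <- as.data.frame(cl)
  expect_true(all(c("clade_id", "n_samples", "frequency", "span_left",
                    "span_right") %in% names(df)))
  path <- withr::local_tempfile(fileext = ".tsv")
  write_clade_table(cl, path)
  back <- read.delim(path)
  expect_equal(nrow(back), nrow(df))
})
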