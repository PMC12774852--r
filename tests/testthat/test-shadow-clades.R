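# Test 2 machinery: candidate clades, rooted-tree compatibility, and the
# per-position minimum-b profile.

test_that("compatibility is the nested-or-disjoint rule", {
  expect_false(clades_compatible(c(2, 3), c(3, 6)))
  expect_true(clades_compatible(c(3, 6), c(3, 6)))
  expect_true(clades_compatible(c(2), c(3, 6)))
  expect_true(clades_compatible(c(3), c(3, 6)))
  expect_true(clades_compatible(c(3, 6, 7), c(3, 6)))
  expect_error(clades_compatible(integer(0), 1), "non-empty")
})

test_that("compatibility is symmetric and reflexive", {
  set.seed(5)
  for (i in 1:100) {
    a <- sample(10, sample(1:6, 1))
    b <- sample(10, sample(1:6, 1))
    expect_identical(clades_compatible(a, b), clades_compatible(b, a))
    expect_true(clades_compatible(a, a))
  }
})

test_that("compatibility agrees with the constructive tree-embedding oracle (n = 5)", {
  env <- oracle_cooccur_pairs(5)
  subsets <- unlist(lapply(1:5, function(k)
    combn(5, k, simplify = FALSE)), recursive = FALSE)
  for (a in subsets) for (b in subsets) {
    key <- paste(paste(a, collapse = ","), "|", paste(b, collapse = ","))
    expect_identical(clades_compatible(a, b),
                     isTRUE(env[[key]]),
                     info = key)
  }
})

test_that("candidate generation enumerates symmetric-difference neighborhoods", {
  pair <- genotype_pair_from_sets(c(2, 3, 4, 6), c(3, 6, 7, 8), n = 8)
  se <- estimate_sigma_s(pair, study_N = 1000)
  tg <- target_sets(pair)
  # |S| = 2, n = 8, max_edit = 1: 1 + 2 + 6 = 9 raw sets
  c0 <- generate_candidates(tg$S, pair, se, max_edit = 1, source_target = "S")
  expect_length(c0$sets, 9)
  expect_true(any(c0$edit_distance == 0))
  # max_edit = 0: the target itself, with the largest |beta|
  c1 <- generate_candidates(tg$S, pair, se, max_edit = 0, source_target = "S")
  expect_length(c1$sets, 1)
  expect_equal(sort(c1$sets[[1]]), sort(tg$S))
  expect_equal(c1$beta[1], 1)   # the target itself is a perfect proxy
  # b_required for the target itself is the Test 1A value at default P
  expect_equal(c1$b_required[1],
               test1a_b_for_probability(0.5, c1$beta[1], se))
  # combinatorial guard
  expect_error(generate_candidates(tg$S, pair, se, max_edit = 3, cap = 10),
               "cap")
})

test_that("candidate generation matches exhaustive enumeration at n = 20", {
  set.seed(2)
  pair <- random_pair(20)
  se <- estimate_sigma_s(pair, study_N = 1000)
  tg <- target_sets(pair)
  got <- generate_candidates(tg$K1, pair, se, max_edit = 2,
                             source_target = "K1")
  # oracle: all subsets within symmetric difference 2, same filtering
  target <- tg$K1
  uni <- 1:20
  all_sets <- list()
  for (rem in c(list(integer(0)),
                combn(target, 1, simplify = FALSE),
                if (length(target) >= 2) combn(target, 2, simplify = FALSE))) {
    base <- setdiff(target, rem)
    left <- 2 - length(rem)
    comp <- setdiff(uni, target)
    adds <- c(list(integer(0)),
              if (left >= 1) combn(comp, 1, simplify = FALSE),
              if (left >= 2) combn(comp, 2, simplify = FALSE))
    for (a in adds) {
      s <- sort(c(base, a))
      if (length(s) && length(s) < 20) all_sets[[length(all_sets) + 1]] <- s
    }
  }
  keys <- unique(vapply(all_sets, paste, "", collapse = ","))
  got_keys <- vapply(got$sets, paste, "", collapse = ",")
  expect_setequal(got_keys, keys)
})

test_that("profile minima, survival and hotspots behave on the toy fixture", {
  fx <- make_fixture("eight_sample")
  ts <- fx$ts
  pair <- genotype_pair_from_sets(c(2, 3, 4, 6), c(3, 6, 7, 8), n = 8,
                                  m1 = 20, m2 = 70)
  se <- estimate_sigma_s(pair, study_N = 5000)
  tg <- target_sets(pair)
  clades <- enumerate_clades(ts)
  cands <- phantomepi:::.combine_candidates(lapply(names(tg), function(nm)
    generate_candidates(tg[[nm]], pair, se, max_edit = 1,
                        source_target = nm)))
  w <- structure(list(left = 0, right = 100, focal = 20), class = "bp_window")
  prof <- test2_profile(clades, cands, w, grid_step = 10, panel_samples = 0:7)
  expect_s3_class(prof, "test2_profile")
  expect_true(all(prof$min_b >= 0))
  # S = {2,5} (0-based {1,4}) is subtended in tree 2: at such positions the
  # profile equals the target's own b (consistency between Tests 1 and 2)
  cand_S <- generate_candidates(tg$S, pair, se, max_edit = 0,
                                source_target = "S")
  at75 <- prof$min_b[prof$position <= 75 & prof$end > 75][1]
  expect_lte(at75, cand_S$b_required[1])
  hot <- hotspot_regions(prof)
  gmin <- attr(prof, "global_min")
  expect_true(all(hot$min_b <= (1 + 0.05) * gmin))
  # hotspot criterion reproducible from the profile itself
  in_hot <- prof$min_b <= 1.05 * gmin
  covered <- vapply(seq_len(nrow(prof)), function(i)
    any(hot$start <= prof$position[i] & prof$position[i] < hot$end),
    logical(1))
  expect_equal(covered, in_hot, ignore_attr = TRUE)
})

test_that("more observed clades can only raise the profile; wider search can only lower it", {
  set.seed(14)
  ts <- sim_tree_seq(16, 5e4, Ne = 1e4, recomb_rate = 1e-7)
  clades <- enumerate_clades(ts)
  pair <- random_pair(16)
  se <- estimate_sigma_s(pair, study_N = 1000)
  tg <- target_sets(pair)
  w <- structure(list(left = 0, right = 5e4, focal = 2e4),
                 class = "bp_window")
  mk_cands <- function(me) phantomepi:::.combine_candidates(
    lapply(names(tg), function(nm) {
      if (!length(tg[[nm]])) return(structure(
        list(sets = list(), edit_distance = integer(), beta = numeric(),
             b_required = numeric(), source_target = character()),
        class = "candidate_set"))
      generate_candidates(tg[[nm]], pair, se, max_edit = me,
                          source_target = nm)
    }))
  cands1 <- mk_cands(1)
  few <- structure(clades[1:2], class = "clade_list")
  prof_few <- test2_profile(few, cands1, w, grid_step = 5e3,
                            panel_samples = 0:15)
  prof_all <- test2_profile(clades, cands1, w, grid_step = 5e3,
                            panel_samples = 0:15)
  common <- intersect(prof_few$position, prof_all$position)
  mf <- prof_few$min_b[match(common, prof_few$position)]
  ma <- prof_all$min_b[match(common, prof_all$position)]
  expect_true(all(ma >= mf - 1e-12))
  # monotone in search breadth
  cands2 <- mk_cands(2)
  prof2 <- test2_profile(clades, cands2, w, grid_step = 5e3,
                         panel_samples = 0:15)
  m2 <- prof2$min_b[match(common, prof2$position)]
  expect_true(all(m2 <= ma + 1e-12))
})

test_that("profiles match a per-position rebuild oracle on a simulated ARG", {
  set.seed(23)
  ts <- sim_tree_seq(20, 4e4, Ne = 1e4, recomb_rate = 1e-7)
  clades <- enumerate_clades(ts)
  pair <- random_pair(20)
  se <- estimate_sigma_s(pair, study_N = 1000)
  tg <- target_sets(pair)
  skip_if(!length(tg$S))
  cands <- generate_candidates(tg$S, pair, se, max_edit = 1,
                               source_target = "S")
  w <- structure(list(left = 0, right = 4e4, focal = 2e4),
                 class = "bp_window")
  prof <- test2_profile(clades, cands, w, grid_step = 2e3,
                        panel_samples = 0:19)
  # oracle: per position, rebuild the local tree and test each candidate
  # for laminar embeddability against its clades
  for (x in c(5e3, 15e3, 25e3, 35e3)) {
    tr <- local_tree(ts, x)
    obs_sets <- list()
    for (v in setdiff(seq_len(nrow(ts$nodes)) - 1L, ts$samples)) {
      d <- tree_descendants(tr, v)
      if (length(d) >= 2 && length(d) < 20)
        obs_sets[[length(obs_sets) + 1L]] <- d
    }
    best <- Inf
    for (ci in seq_along(cands$sets)) {
      cs <- sort(cands$sets[[ci]] - 1L)  # 1-based index -> 0-based sample id
      ok <- all(vapply(obs_sets, function(o) {
        ov <- sum(cs %in% o)
        ov == 0 || ov == length(cs) || ov == length(o)
      }, logical(1)))
      if (ok) best <- min(best, cands$b_required[ci])
    }
    got <- prof$min_b[prof$position <= x & prof$end > x][1]
    expect_equal(got, best, info = paste("position", x))
  }
})

test_that("empty candidate lists give a sentinel profile with a warning", {
  fx <- make_fixture("single_tree")
  clades <- enumerate_clades(fx$ts)
  empty <- structure(list(sets = list(), edit_distance = integer(),
                          beta = numeric(), b_required = numeric(),
                          source_target = character()),
                     class = "candidate_set")
  w <- structure(list(left = 0, right = 100, focal = 50),
                 class = "bp_window")
  expect_warning(prof <- test2_profile(clades, empty, w, grid_step = 50),
                 "empty candidate")
  expect_true(all(is.infinite(prof$min_b)))
})

test_that("profile and hotspot writers emit TSV and BED", {
  fx <- make_fixture("eight_sample")
  pair <- genotype_pair_from_sets(c(2, 3, 4, 6), c(3, 6, 7, 8), n = 8)
  se <- estimate_sigma_s(pair, study_N = 5000)
  tg <- target_sets(pair)
  cands <- generate_candidates(tg$S, pair, se, max_edit = 1,
                               source_target = "S")
  w <- structure(list(left = 0, right = 100, focal = 20),
                 class = "bp_window")
  prof <- test2_profile(enumerate_clades(fx$ts), cands, w, grid_step = 25,
                        panel_samples = 0:7)
  p1 <- withr::local_tempfile(fileext = ".tsv")
  p2 <- withr::local_tempfile(fileext = ".bed")
  write_profile(prof, p1)
  write_hotspot_bed(prof, p2, chrom = "1")
  expect_gt(nrow(read.delim(p1)), 0)
})
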