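# Scaled simulation study: phantom versus true epistasis instances run
# through the full pipeline (simulate, scan, test), with ROC evaluation of
# the minimum omitted-variant effect size as a discriminator.

.study_freq <- function(carriers, n_study_haps) {
  vapply(carriers, function(cc) sum(cc < n_study_haps), numeric(1)) / n_study_haps
}

# pre-extraction cap on scan sites: carriers are materialised only for this
# many sites per replicate (evenly spaced), before LD pruning
.PRE_EXTRACT_CAP <- 400L

# run Tests 1A/1B for one pair against a pre-enumerated panel clade list;
# returns list(b1a, b1b) or NULL if the pair is unusable on the panel
# (degenerate design / constant genotypes)
.test_pair_on_panel <- function(clades, panel_haps, carr1, carr2, pos1, pos2,
                                z_stat, study_N, config) {
  p1 <- intersect(carr1, panel_haps)
  p2 <- intersect(carr2, panel_haps)
  np <- length(panel_haps)
  if (length(p1) %in% c(0L, np) || length(p2) %in% c(0L, np)) return(NULL)
  pair <- tryCatch(
    genotype_pair_from_sets(match(p1, panel_haps), match(p2, panel_haps),
                            n = np, m1 = pos1, m2 = pos2),
    error = function(e) NULL)
  if (is.null(pair)) return(NULL)
  se <- tryCatch(estimate_sigma_s(pair, study_N = study_N),
                 error = function(e) NULL)
  if (is.null(se)) return(NULL)
  if (!length(clades)) return(NULL)
  obs <- observed_interaction(t_stat = abs(z_stat))
  res <- run_test1(clades, pair, se, obs = obs, config = config,
                   panel_samples = panel_haps)
  m <- attr(res, "minima")
  list(b1a = m$test1a, b1b = m$test1b)
}

# evenly thin `idx` to at most `cap` entries, always retaining `keep_idx`
.thin_variants <- function(idx, cap, keep_idx = integer(0)) {
  if (length(idx) <= cap) return(idx)
  sel <- idx[unique(round(seq(1, length(idx), length.out = cap)))]
  sort(unique(c(sel, intersect(keep_idx, idx))))
}

#' Scaled phantom-versus-true epistasis simulation study
#'
#' Each replicate simulates a diploid study cohort plus a held-out haploid
#' panel from one ARG.  Phantom replicates plant a single additive causal
#' variant (frequency within `freq_range`), mask it, scan the surrounding
#' region for pairwise interactions (MAF filter, LD pruning 50/5/0.7,
#' Bonferroni over tested pairs) and run Tests 1A/1B on the top-ranked hits
#' (up to `top_pairs`), recording the smallest minimum-b.  True-epistasis
#' replicates plant a purely epistatic pair `pair_distance` apart (zero main
#' effects, joint-carrier frequency within `freq_range`, pairwise r-squared
#' at most the pruning threshold) and run the tests on that pair.  The
#' minimum-b values then discriminate phantom from true instances (ROC/AUC):
#' a small minimum means a weak omitted variant could explain the signal.
#'
#' @param n_phantom,n_true replicates per condition.
#' @param seed top-level seed; all per-replicate seeds derive from it.
#' @param n_study diploid individuals for interaction testing.
#' @param n_panel held-out panel haplotypes.
#' @param sequence_length bp per replicate.
#' @param Ne,mutation_rate,recomb_rate coalescent parameters.
#' @param effect,h2 causal/interaction effect size and heritability.
#' @param alpha significance level (Bonferroni-corrected over tested pairs
#'   in the scan; nominal for the single planted-pair test).
#' @param freq_range causal-variant (phantom) or joint-carrier (true)
#'   frequency range, on study haplotypes.
#' @param pair_distance bp separation of the planted true-epistasis pair.
#' @param scan_span total genomic span scanned around the masked variant.
#' @param maf_min minor-allele-frequency filter for scan variants.
#' @param max_scan_variants cap on scan variants after pruning (evenly
#'   thinned).
#' @param top_pairs phantom replicates evaluate the tests on up to this many
#'   top-ranked scan pairs and keep the smallest b.
#' @param window_cm clade-search half-window in cM around each SNP.
#' @param require_significant if `TRUE`, phantom replicates only test
#'   Bonferroni-significant pairs (the full-scale design); by default the
#'   top-ranked pairs are tested even when nothing crosses the corrected
#'   threshold, which keeps the discrimination analysis defined at desk
#'   scale where the interaction scan is underpowered.
#' @param out_dir optional directory for replicate/ROC TSVs and the final
#'   replicate's ARG.
#' @param verbose print per-replicate progress.
#' @return list of class `phantom_sim_study`: `replicates` (data.frame),
#'   `roc_1a`, `roc_1b`, `auc_1a`, `auc_1b`, `settings`.
#' @export
phantom_sim_study <- function(n_phantom = 20, n_true = 20, seed = 1,
                              n_study = 2000, n_panel = 200,
                              sequence_length = 1.2e6, Ne = 1e4,
                              mutation_rate = 2.36e-8, recomb_rate = 1e-8,
                              effect = 0.2, h2 = 0.01, alpha = 0.05,
                              freq_range = c(0.05, 0.25),
                              pair_distance = 5e5, scan_span = 4e5,
                              maf_min = 0.05, max_scan_variants = 150,
                              top_pairs = 10, window_cm = 1,
                              require_significant = FALSE,
                              out_dir = NULL, verbose = FALSE) {
  set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_phantom + n_true)
  config <- test_config(alpha = alpha)
  nsh <- 2L * n_study
  rows <- list()
  last_ts <- NULL

  enum_panel <- function(ts, panel_haps, lo, hi) {
    map <- uniform_recomb_map(recomb_rate * 1e8, sequence_length)
    wl <- cm_window(map, lo, window_cm, sequence_length)$left
    wr <- cm_window(map, hi, window_cm, sequence_length)$right
    enumerate_clades(ts, window = c(wl, wr), samples = panel_haps)
  }

  run_one <- function(kind, rep_i, sub_seed) {
    cfg <- sim_config(n_study = n_study, n_panel = n_panel,
                      sequence_length = sequence_length, Ne = Ne,
                      mutation_rate = mutation_rate,
                      recomb_rate = recomb_rate, seed = sub_seed)
    ps <- simulate_panel(cfg)
    last_ts <<- ps$ts
    center <- sequence_length / 2
    row <- data.frame(kind = kind, rep = rep_i, seed = sub_seed,
                      freq = NA_real_, pos1 = NA_real_, pos2 = NA_real_,
                      tested = FALSE, detected = FALSE, scan_p = NA_real_,
                      b_1a = NA_real_, b_1b = NA_real_)

    if (kind == "phantom") {
      win <- c(center - scan_span / 2 - 25e3, center + scan_span / 2 + 25e3)
      scnt <- .site_counts(ps$ts, window = pmax(0, pmin(sequence_length, win)),
                           id_threshold = nsh)
      fr <- scnt$count_sub / nsh
      spos <- scnt$position
      cand <- which(abs(spos - center) <= 25e3 &
                      fr >= freq_range[1] & fr <= freq_range[2])
      if (!length(cand)) return(row)
      ci <- if (length(cand) == 1L) cand else sample(cand, 1L)
      pc <- spos[ci]
      row$freq <- fr[ci]
      in_region <- abs(spos - pc) <= scan_span / 2
      scan_idx <- which(in_region & fr >= maf_min & fr <= 1 - maf_min)
      scan_idx <- setdiff(scan_idx, ci)   # mask the causal variant
      scan_idx <- .thin_variants(scan_idx, .PRE_EXTRACT_CAP)
      if (length(scan_idx) < 2L) return(row)
      carr <- .carriers_for_sites(ps$ts, spos[c(ci, scan_idx)])
      g_causal <- hap_dosage(carr[[1]], ps$study_haps)
      carr <- carr[-1]
      ph <- simulate_phantom_phenotype(g_causal, effect = effect, h2 = h2)
      G <- vapply(carr, function(cc) hap_dosage(cc, ps$study_haps),
                  numeric(n_study))
      kept <- ld_prune(G, window = 50, step = 5, r2_threshold = 0.7)
      kept <- .thin_variants(kept, max_scan_variants)
      if (length(kept) < 2L) return(row)
      G <- G[, kept, drop = FALSE]
      pos <- spos[scan_idx[kept]]
      scan <- interaction_scan(G, ph$phenotype, positions = pos, alpha = alpha)
      res_ok <- scan$results[!is.na(scan$results$p), , drop = FALSE]
      if (!nrow(res_ok)) return(row)
      res_ok <- res_ok[order(res_ok$p), , drop = FALSE]
      sig <- res_ok[res_ok$significant, , drop = FALSE]
      cand_rows <- if (nrow(sig)) utils::head(sig, top_pairs)
        else if (require_significant) NULL
        else utils::head(res_ok, top_pairs)   # scaled stand-in for "hits"
      if (is.null(cand_rows) || !nrow(cand_rows)) return(row)
      clades <- enum_panel(ps$ts, ps$panel_haps,
                           pc - scan_span / 2, pc + scan_span / 2)
      for (r_ in seq_len(nrow(cand_rows))) {
        tst <- .test_pair_on_panel(clades, ps$panel_haps,
                                   carr[[kept[cand_rows$i[r_]]]],
                                   carr[[kept[cand_rows$j[r_]]]],
                                   cand_rows$pos_i[r_], cand_rows$pos_j[r_],
                                   cand_rows$z[r_], study_N = n_study,
                                   config = config)
        if (is.null(tst)) next
        if (!row$tested || tst$b1a < row$b_1a) {
          row$pos1 <- cand_rows$pos_i[r_]; row$pos2 <- cand_rows$pos_j[r_]
          row$scan_p <- cand_rows$p[r_]
        }
        row$tested <- TRUE
        row$detected <- row$detected || cand_rows$significant[r_]
        row$b_1a <- min(row$b_1a, tst$b1a, na.rm = TRUE)
        row$b_1b <- min(row$b_1b, tst$b1b, na.rm = TRUE)
      }
      return(row)
    }

    # true epistasis: plant a pair `pair_distance` apart and test it directly
    p1c <- center - pair_distance / 2; p2c <- center + pair_distance / 2
    win <- c(p1c - 25e3, p2c + 25e3)
    scnt <- .site_counts(ps$ts, window = pmax(0, pmin(sequence_length, win)),
                         id_threshold = nsh)
    fr <- scnt$count_sub / nsh
    spos <- scnt$position
    c1 <- which(abs(spos - p1c) <= 25e3 & fr >= maf_min & fr <= 1 - maf_min)
    c2 <- which(abs(spos - p2c) <= 25e3 & fr >= maf_min & fr <= 1 - maf_min)
    if (!length(c1) || !length(c2)) return(row)
    c1 <- .thin_variants(c1, 40L); c2 <- .thin_variants(c2, 40L)
    cand_carr <- .carriers_for_sites(ps$ts, spos[c(c1, c2)])
    names(cand_carr) <- as.character(c(c1, c2))
    study_carr <- lapply(cand_carr, function(cc) cc[cc < nsh])
    found <- NULL
    tries <- expand.grid(i = c1, j = c2)
    tries <- tries[sample.int(nrow(tries)), , drop = FALSE]
    for (t_ in seq_len(min(nrow(tries), 500L))) {
      i <- tries$i[t_]; j <- tries$j[t_]
      s1 <- study_carr[[as.character(i)]]; s2 <- study_carr[[as.character(j)]]
      joint <- length(intersect(s1, s2)) / nsh
      if (joint < freq_range[1] || joint > freq_range[2]) next
      if (all(s1 %in% s2) || all(s2 %in% s1)) next   # nested: degenerate
      # pairs in strong LD would not survive the scan's own pruning (and
      # are phantom-indistinguishable by construction)
      p1 <- length(s1) / nsh; p2 <- length(s2) / nsh
      r2 <- (joint - p1 * p2)^2 / (p1 * (1 - p1) * p2 * (1 - p2))
      if (!is.finite(r2) || r2 > 0.7) next
      found <- c(i, j); break
    }
    if (is.null(found)) return(row)
    i <- found[1]; j <- found[2]
    row$freq <- length(intersect(study_carr[[as.character(i)]],
                                 study_carr[[as.character(j)]])) / nsh
    g1 <- hap_dosage(cand_carr[[as.character(i)]], ps$study_haps)
    g2 <- hap_dosage(cand_carr[[as.character(j)]], ps$study_haps)
    ph <- tryCatch(simulate_true_epistasis(g1, g2, effect = effect, h2 = h2),
                   error = function(e) NULL)
    if (is.null(ph)) return(row)
    scan <- interaction_scan(cbind(g1, g2), ph$phenotype,
                             positions = spos[c(i, j)], alpha = alpha)
    rr <- scan$results[1, ]
    if (is.na(rr$p)) return(row)
    clades <- enum_panel(ps$ts, ps$panel_haps, spos[i], spos[j])
    tst <- .test_pair_on_panel(clades, ps$panel_haps,
                               cand_carr[[as.character(i)]],
                               cand_carr[[as.character(j)]],
                               spos[i], spos[j], rr$z, study_N = n_study,
                               config = config)
    if (is.null(tst)) return(row)
    row$tested <- TRUE
    row$detected <- rr$p <= alpha
    row$scan_p <- rr$p
    row$pos1 <- spos[i]; row$pos2 <- spos[j]
    row$b_1a <- tst$b1a; row$b_1b <- tst$b1b
    row
  }

  k <- 0L
  for (r in seq_len(n_phantom)) {
    k <- k + 1L
    rows[[k]] <- run_one("phantom", r, seeds[k])
    if (verbose)
      message(sprintf("phantom %d/%d: tested=%s b1a=%.3g", r, n_phantom,
                      rows[[k]]$tested, rows[[k]]$b_1a))
  }
  for (r in seq_len(n_true)) {
    k <- k + 1L
    rows[[k]] <- run_one("true_epistasis", r, seeds[k])
    if (verbose)
      message(sprintf("true %d/%d: tested=%s b1a=%.3g", r, n_true,
                      rows[[k]]$tested, rows[[k]]$b_1a))
  }
  reps <- do.call(rbind, rows)
  ph_b1a <- reps$b_1a[reps$kind == "phantom" & reps$tested]
  tr_b1a <- reps$b_1a[reps$kind == "true_epistasis" & reps$tested]
  ph_b1b <- reps$b_1b[reps$kind == "phantom" & reps$tested]
  tr_b1b <- reps$b_1b[reps$kind == "true_epistasis" & reps$tested]
  roc_1a <- if (length(ph_b1a) && length(tr_b1a))
    roc_evaluation(ph_b1a, tr_b1a) else NULL
  roc_1b <- if (length(ph_b1b) && length(tr_b1b))
    roc_evaluation(ph_b1b, tr_b1b) else NULL
  out <- structure(list(
    replicates = reps,
    roc_1a = roc_1a, roc_1b = roc_1b,
    auc_1a = if (is.null(roc_1a)) NA_real_ else roc_1a$auc,
    auc_1b = if (is.null(roc_1b)) NA_real_ else roc_1b$auc,
    settings = list(n_phantom = n_phantom, n_true = n_true, seed = seed,
                    n_study = n_study, n_panel = n_panel,
                    sequence_length = sequence_length, Ne = Ne,
                    mutation_rate = mutation_rate, recomb_rate = recomb_rate,
                    effect = effect, h2 = h2, alpha = alpha,
                    freq_range = freq_range, pair_distance = pair_distance,
                    scan_span = scan_span, maf_min = maf_min,
                    max_scan_variants = max_scan_variants,
                    top_pairs = top_pairs, window_cm = window_cm)),
    class = "phantom_sim_study")
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    utils::write.table(reps, file.path(out_dir, "replicates.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    for (nm in c("roc_1a", "roc_1b")) {
      rc <- out[[nm]]
      if (!is.null(rc)) {
        df <- rc$points; df$auc <- rc$auc
        utils::write.table(df, file.path(out_dir, paste0(nm, ".tsv")),
                           sep = "\t", quote = FALSE, row.names = FALSE)
      }
    }
    if (!is.null(last_ts))
      write_tree_seq(last_ts, file.path(out_dir, "last_replicate.trees.txt"))
  }
  out
}

#' @export
print.phantom_sim_study <- function(x, ...) {
  r <- x$replicates
  cat("phantom_sim_study:", sum(r$kind == "phantom"), "phantom +",
      sum(r$kind != "phantom"), "true replicates\n")
  det <- tapply(r$tested, r$kind, mean)
  cat("  tested rate:",
      paste(sprintf("%s %.0f%%", names(det), 100 * det), collapse = ", "), "\n")
  cat(sprintf("  AUC (Test 1A min b): %.3f;  AUC (Test 1B min b): %.3f\n",
              x$auc_1a, x$auc_1b))
  invisible(x)
}
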