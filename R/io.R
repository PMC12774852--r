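# Batch interface and tabular IO.

#' Read a SNP-pair summary table
#'
#' TSV with a header; required columns `pos1`, `pos2`, `study_N` and one of
#' `p_value` / `t_stat`; optional `chrom`, `freq1`, `freq2`, `alpha`.
#'
#' @param path file path.
#' @return data.frame.
#' @export
read_snp_pairs <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE)
  need <- c("pos1", "pos2", "study_N")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("missing columns: ", paste(miss, collapse = ", "), call. = FALSE)
  if (!any(c("p_value", "t_stat") %in% names(df)))
    stop("need a p_value or t_stat column", call. = FALSE)
  df
}

#' Batch phantom-epistasis assessment over a SNP-pair table
#'
#' Runs [phantom_epistasis()] for each row; one failing pair (e.g. a SNP
#' absent from the ARG, or mapped to a recurrent mutation) is recorded with
#' a reason code and skipped, never aborting the batch.
#'
#' @param ts a [tree_seq()].
#' @param pairs data.frame as from [read_snp_pairs()].
#' @param map a [recomb_map()] or NULL (uniform 1 cM/Mb).
#' @param out_dir optional output directory; per-pair clade tables and
#'   profiles are written as TSV named by the pair coordinates, plus a batch
#'   `summary.tsv`.
#' @param ... further arguments to [phantom_epistasis()].
#' @return data.frame of class `phantom_epistasis_batch`: one row per pair
#'   with status, minima and top SNP; attribute `fits` holds the successful
#'   `phantom_epistasis` objects.
#' @export
phantom_epistasis_batch <- function(ts, pairs, map = NULL, out_dir = NULL,
                                    ...) {
  if (!is.null(out_dir))
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fits <- list()
  rows <- lapply(seq_len(nrow(pairs)), function(i) {
    pr <- pairs[i, ]
    chrom <- if ("chrom" %in% names(pr)) pr$chrom else "1"
    tag <- sprintf("%s_%s_%s", chrom, format(pr$pos1, scientific = FALSE),
                   format(pr$pos2, scientific = FALSE))
    args <- list(ts = ts, snp1 = pr$pos1, snp2 = pr$pos2,
                 study_N = pr$study_N, map = map, ...)
    if ("p_value" %in% names(pr) && !is.na(pr$p_value))
      args$p_value <- pr$p_value
    else if ("t_stat" %in% names(pr) && !is.na(pr$t_stat))
      args$t_stat <- pr$t_stat
    if ("alpha" %in% names(pr) && !is.na(pr$alpha)) args$alpha <- pr$alpha
    if ("freq1" %in% names(pr)) args$freq1 <- pr$freq1
    if ("freq2" %in% names(pr)) args$freq2 <- pr$freq2
    fit <- tryCatch(do.call(phantom_epistasis, args), error = identity)
    if (inherits(fit, "error")) {
      reason <- if (inherits(fit, "phantomepi_snp_absent")) "snp_absent"
        else if (inherits(fit, "phantomepi_nonunique_mapping")) "non_unique_mapping"
        else if (inherits(fit, "phantomepi_carrier_mismatch")) "carrier_mismatch"
        else if (inherits(fit, "phantomepi_unidentifiable")) "unidentifiable_design"
        else "error"
      return(data.frame(pair = tag, pos1 = pr$pos1, pos2 = pr$pos2,
                        status = reason, message = conditionMessage(fit),
                        test1a_min_b = NA_real_, test1b_min_b = NA_real_,
                        test2_min_b = NA_real_, top_snp = NA_real_))
    }
    fits[[tag]] <<- fit
    sm <- summary(fit)
    if (!is.null(out_dir)) {
      utils::write.table(as.data.frame(fit$test1),
                         file.path(out_dir, paste0(tag, "_clades.tsv")),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      if (!is.null(fit$test2)) {
        write_profile(fit$test2,
                      file.path(out_dir, paste0(tag, "_profile.tsv")))
        write_hotspot_bed(fit$test2,
                          file.path(out_dir, paste0(tag, "_hotspots.bed")),
                          chrom = chrom)
      }
    }
    data.frame(pair = tag, pos1 = pr$pos1, pos2 = pr$pos2, status = "ok",
               message = "", test1a_min_b = sm$test1a_min_b,
               test1b_min_b = sm$test1b_min_b, test2_min_b = sm$test2_min_b,
               top_snp = sm$top_snp)
  })
  res <- do.call(rbind, rows)
  if (!is.null(out_dir))
    utils::write.table(res, file.path(out_dir, "summary.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  attr(res, "fits") <- fits
  class(res) <- c("phantom_epistasis_batch", "data.frame")
  res
}
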