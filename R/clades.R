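# Clade enumeration with genomic spans.  A clade is identified by its set of
# descendant samples; its span is the union of local-tree intervals over which
# some branch subtends exactly that set.  Enumeration runs off incremental
# edge differences between adjacent local trees (see .ts_sweep), never by
# re-traversing each tree.

.normalize_window <- function(ts, window) {
  if (is.null(window)) return(c(0, ts$sequence_length))
  if (inherits(window, "bp_window")) window <- c(window$left, window$right)
  w <- as.numeric(window[1:2])
  c(max(0, w[1]), min(ts$sequence_length, w[2]))
}

.merge_intervals <- function(ivals) {
  # ivals: list of c(left, right); returns matrix with merged, sorted rows
  m <- do.call(rbind, ivals)
  m <- m[order(m[, 1]), , drop = FALSE]
  out_l <- m[1, 1]; out_r <- m[1, 2]
  res <- NULL
  if (nrow(m) > 1) {
    for (i in 2:nrow(m)) {
      if (m[i, 1] <= out_r) out_r <- max(out_r, m[i, 2])
      else { res <- rbind(res, c(out_l, out_r)); out_l <- m[i, 1]; out_r <- m[i, 2] }
    }
  }
  res <- rbind(res, c(out_l, out_r))
  colnames(res) <- c("left", "right")
  res
}

#' Enumerate clades and their genomic spans
#'
#' Lists every sample set subtended by a branch of at least one local tree
#' overlapping the window, together with the union of intervals over which it
#' is subtended (clipped to the window) and the mutations supporting it
#' (mutations falling on a branch that subtends exactly that set, within its
#' span).  A sample set that disappears and later re-forms is reported once,
#' with multiple spans.
#'
#' @param ts a [tree_seq()].
#' @param window `NULL` (whole sequence), a numeric `c(left, right)` or a
#'   window from [cm_window()].  Clipped to the sequence interval; an empty
#'   overlap yields an empty result.
#' @param min_frequency keep clades with carrier frequency at least this
#'   (frequency is relative to the projected sample set).
#' @param samples optional subset of sample ids to project the ARG onto
#'   (descendant sets are intersected with this subset); defaults to all
#'   samples.  Used e.g. to analyse a reference-panel subset of a larger ARG.
#' @param include_root include the clade containing every (projected) sample.
#'   Excluded by default: it cannot drive phantom epistasis conditional on the
#'   intercept.
#' @param include_singletons include single-sample clades.  Excluded by
#'   default; private variants are absorbed per individual.
#' @return An object of class `clade_list`: a list of records, each with
#'   elements `samples` (sorted 0-based sample ids), `spans` (matrix with
#'   columns left/right), `mutations` (data.frame position/site/node) and
#'   `frequency`.
#' @export
enumerate_clades <- function(ts, window = NULL, min_frequency = 0,
                             samples = NULL, include_root = FALSE,
                             include_singletons = FALSE) {
  w <- .normalize_window(ts, window)
  if (is.null(samples)) samples <- ts$samples
  samples <- sort(as.integer(samples))
  n <- length(samples)
  if (n < 2) stop("ARG must have at least 2 (projected) samples", call. = FALSE)
  out <- structure(list(), class = "clade_list")
  attr(out, "n_samples") <- n
  if (w[1] >= w[2]) {
    warning("window does not overlap the sequence interval; empty result")
    return(out)
  }
  sw <- .ts_sweep(ts, left = w[1], right = w[2], samples = samples)
  keys <- ls(sw$sets)
  recs <- vector("list", length(keys))
  keep <- logical(length(keys))
  empty_mut <- data.frame(position = numeric(), site = integer(),
                          node = integer())
  for (i in seq_along(keys)) {
    rec <- get(keys[i], envir = sw$sets)
    k <- length(rec$samples)
    if (k == 1L && !include_singletons) next
    if (k == n && !include_root) next
    if (k / n < min_frequency) next
    recs[[i]] <- list(samples = rec$samples,
                      spans = .merge_intervals(rec$ivals),
                      mutations = empty_mut,
                      frequency = k / n)
    keep[i] <- TRUE
  }
  recs <- recs[keep]; keys <- keys[keep]
  # attach supporting mutations (grouped; one data.frame per supported clade)
  if (nrow(sw$mut) && length(recs)) {
    idx <- match(sw$mut$key, keys)
    ok <- !is.na(idx)
    if (any(ok)) {
      grp <- split(which(ok), idx[ok])
      for (rname in names(grp)) {
        r <- as.integer(rname)
        jj <- grp[[rname]]
        sp <- recs[[r]]$spans
        inside <- vapply(sw$mut$position[jj], function(p)
          any(sp[, 1] <= p & p < sp[, 2]), logical(1))
        if (any(inside)) {
          jj <- jj[inside]
          recs[[r]]$mutations <- data.frame(position = sw$mut$position[jj],
                                            site = sw$mut$site[jj],
                                            node = sw$mut$node[jj])
        }
      }
    }
  }
  if (length(recs)) {
    ord <- order(vapply(recs, function(r) r$spans[1, 1], numeric(1)),
                 vapply(recs, function(r) length(r$samples), integer(1)))
    recs <- recs[ord]
  }
  out[seq_along(recs)] <- recs
  attr(out, "n_samples") <- n
  attr(out, "window") <- w
  class(out) <- "clade_list"
  out
}

#' @export
print.clade_list <- function(x, ...) {
  cat("clade_list:", length(x), "clades over",
      attr(x, "n_samples"), "samples\n")
  if (length(x)) {
    df <- as.data.frame(x)
    print(utils::head(df, 10))
    if (nrow(df) > 10) cat("...", nrow(df) - 10, "more rows\n")
  }
  invisible(x)
}

#' Flatten a clade list to a data frame
#'
#' One row per clade span.
#'
#' @param x a `clade_list`.
#' @param row.names,optional,... ignored (S3 signature).
#' @return data.frame with columns clade_id, n_samples, frequency, span_left,
#'   span_right, n_supporting_mutations, supporting_positions.
#' @export
as.data.frame.clade_list <- function(x, row.names = NULL, optional = FALSE, ...) {
  if (!length(x))
    return(data.frame(clade_id = integer(), n_samples = integer(),
                      frequency = numeric(), span_left = numeric(),
                      span_right = numeric(), n_supporting_mutations = integer(),
                      supporting_positions = character()))
  rows <- lapply(seq_along(x), function(i) {
    r <- x[[i]]
    data.frame(clade_id = i, n_samples = length(r$samples),
               frequency = r$frequency,
               span_left = r$spans[, 1], span_right = r$spans[, 2],
               n_supporting_mutations = nrow(r$mutations),
               supporting_positions = paste(r$mutations$position, collapse = ","))
  })
  do.call(rbind, rows)
}

#' Write a clade table as TSV
#' @param clades a `clade_list`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_clade_table <- function(clades, path) {
  utils::write.table(as.data.frame(clades), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Map a SNP onto an ARG branch
#'
#' Finds the site at `position` and returns the clade of carriers of its
#' unique mutation.  SNPs carried by recurrent mutations (more than one
#' mutation at the site) do not map uniquely to a branch and are rejected.
#'
#' @param ts a [tree_seq()].
#' @param position site position (must match a site exactly).
#' @param alt_carriers optional sorted sample ids; if supplied, the mutation's
#'   carrier set must equal it.
#' @param samples optional sample subset to project carriers onto.
#' @return list with `samples` (carrier ids), `spans` (the local-tree interval
#'   at the site), `site`, `mutation` (ids), `node` and `frequency`.
#' @export
map_snp_to_branch <- function(ts, position, alt_carriers = NULL,
                              samples = NULL) {
  if (position < 0 || position >= ts$sequence_length)
    stop("position outside the sequence interval", call. = FALSE)
  si <- which(ts$sites$position == position)
  if (!length(si))
    stop(errorCondition(sprintf("SNP absent from ARG (no site at %s)", position),
                        class = c("phantomepi_snp_absent", "error", "condition")))
  site_id <- ts$sites$id[si[1]]
  mut <- ts$mutations[ts$mutations$site == site_id, , drop = FALSE]
  if (nrow(mut) == 0L)
    stop(errorCondition(sprintf("SNP absent from ARG (no mutation at site %s)", position),
                        class = c("phantomepi_snp_absent", "error", "condition")))
  if (nrow(mut) > 1L)
    stop(errorCondition(sprintf("non-unique branch mapping at %s (%d mutations)",
                                position, nrow(mut)),
                        class = c("phantomepi_nonunique_mapping", "error", "condition")))
  tr <- local_tree(ts, position)
  if (is.null(samples)) samples <- ts$samples
  carriers <- tree_descendants(tr, mut$node[1], samples = samples)
  if (!is.null(alt_carriers) && !identical(carriers, sort(as.integer(alt_carriers))))
    stop(errorCondition(sprintf("allele/carrier mismatch at %s", position),
                        class = c("phantomepi_carrier_mismatch", "error", "condition")))
  list(samples = carriers,
       spans = matrix(tr$interval, ncol = 2,
                      dimnames = list(NULL, c("left", "right"))),
       site = site_id, mutation = mut$id[1], node = mut$node[1],
       frequency = length(carriers) / length(samples))
}

#' Carrier sets per site
#'
#' Extracts, for every site in the window, the set of (projected) samples
#' carrying the derived allele, using the incremental sweep.  Sites whose
#' carrier set is empty or complete within the projection are still reported.
#'
#' @param ts a [tree_seq()].
#' @param window `NULL` or `c(left, right)`.
#' @param samples optional sample subset.
#' @return list with `sites` (data.frame id/position/node) and `carriers`
#'   (list of sorted sample-id vectors, parallel to `sites`).
#' @export
site_carriers <- function(ts, window = NULL, samples = NULL) {
  w <- .normalize_window(ts, window)
  if (is.null(samples)) samples <- ts$samples
  sw <- .ts_sweep(ts, left = w[1], right = w[2], samples = samples,
                  record_pieces = FALSE)
  carriers <- lapply(sw$mut$key, function(k)
    if (nzchar(k)) as.integer(strsplit(k, ",", fixed = TRUE)[[1]]) else integer(0))
  list(sites = data.frame(id = sw$mut$site, position = sw$mut$position,
                          node = sw$mut$node),
       carriers = carriers)
}

# Fast per-site carrier COUNTS (total and below an id threshold) via a
# count-propagating sweep; used to compute allele frequencies without
# materialising carrier sets.
.site_counts <- function(ts, window = NULL, id_threshold = NULL) {
  w <- .normalize_window(ts, window)
  n_nodes <- nrow(ts$nodes)
  e <- ts$edges; n_edges <- nrow(e)
  ins_ord <- order(e$left); rem_ord <- order(e$right)
  e_left <- e$left[ins_ord]; e_right <- e$right[rem_ord]
  ins_parent <- e$parent[ins_ord] + 1L; ins_child <- e$child[ins_ord] + 1L
  rem_parent <- e$parent[rem_ord] + 1L; rem_child <- e$child[rem_ord] + 1L
  parent <- integer(n_nodes)
  cnt_tot <- numeric(n_nodes); cnt_sub <- numeric(n_nodes)
  samp <- ts$samples
  cnt_tot[samp + 1L] <- 1
  if (!is.null(id_threshold)) cnt_sub[samp[samp < id_threshold] + 1L] <- 1
  else cnt_sub[samp + 1L] <- 1

  mpos <- ts$sites$position[match(ts$mutations$site, ts$sites$id)]
  mord <- order(mpos)
  mpos <- mpos[mord]
  mnode <- ts$mutations$node[mord] + 1L
  msite <- ts$mutations$site[mord]
  n_mut <- length(mpos)
  out_tot <- numeric(n_mut); out_sub <- numeric(n_mut)
  keep <- logical(n_mut)
  mi <- 1L; i_ins <- 1L; i_rem <- 1L; x <- 0
  repeat {
    nx <- Inf
    if (i_rem <= n_edges) nx <- min(nx, e_right[i_rem])
    if (i_ins <= n_edges) nx <- min(nx, e_left[i_ins])
    upto <- min(nx, w[2])
    while (mi <= n_mut && mpos[mi] < upto) {
      if (mpos[mi] >= x && mpos[mi] >= w[1]) {
        out_tot[mi] <- cnt_tot[mnode[mi]]
        out_sub[mi] <- cnt_sub[mnode[mi]]
        keep[mi] <- TRUE
      }
      mi <- mi + 1L
    }
    if (is.infinite(nx) || nx >= w[2]) break
    x <- nx
    while (i_rem <= n_edges && e_right[i_rem] == x) {
      p <- rem_parent[i_rem]; cn <- rem_child[i_rem]
      dt <- cnt_tot[cn]; ds <- cnt_sub[cn]
      if (dt > 0) {
        wk <- p
        while (wk != 0L) {
          cnt_tot[wk] <- cnt_tot[wk] - dt
          cnt_sub[wk] <- cnt_sub[wk] - ds
          wk <- parent[wk]
        }
      }
      parent[cn] <- 0L
      i_rem <- i_rem + 1L
    }
    while (i_ins <= n_edges && e_left[i_ins] == x) {
      p <- ins_parent[i_ins]; cn <- ins_child[i_ins]
      parent[cn] <- p
      dt <- cnt_tot[cn]; ds <- cnt_sub[cn]
      if (dt > 0) {
        wk <- p
        while (wk != 0L) {
          cnt_tot[wk] <- cnt_tot[wk] + dt
          cnt_sub[wk] <- cnt_sub[wk] + ds
          wk <- parent[wk]
        }
      }
      i_ins <- i_ins + 1L
    }
  }
  data.frame(site = msite[keep], position = mpos[keep],
             node = mnode[keep] - 1L,
             count_total = out_tot[keep], count_sub = out_sub[keep])
}

# Exact carrier sets for selected site positions only: edge-diff sweep
# maintaining a children adjacency, with a per-site DFS from the mutation
# node.  Cost is O(edge events + total carriers collected).
.carriers_for_sites <- function(ts, positions) {
  n_nodes <- nrow(ts$nodes)
  e <- ts$edges; n_edges <- nrow(e)
  ins_ord <- order(e$left); rem_ord <- order(e$right)
  e_left <- e$left[ins_ord]; e_right <- e$right[rem_ord]
  ins_parent <- e$parent[ins_ord] + 1L; ins_child <- e$child[ins_ord] + 1L
  rem_parent <- e$parent[rem_ord] + 1L; rem_child <- e$child[rem_ord] + 1L
  kids <- vector("list", n_nodes)
  is_sample <- logical(n_nodes); is_sample[ts$samples + 1L] <- TRUE

  want <- sort(unique(positions))
  si <- match(want, ts$sites$position)
  if (anyNA(si)) stop("position without a site record", call. = FALSE)
  node_at <- integer(length(want))
  for (k in seq_along(want)) {
    mm <- ts$mutations$node[ts$mutations$site == ts$sites$id[si[k]]]
    node_at[k] <- mm[1] + 1L
  }
  res <- vector("list", length(want))
  stack <- integer(2 * length(ts$samples) + 10L)
  wi <- 1L; i_ins <- 1L; i_rem <- 1L; x <- 0
  repeat {
    nx <- Inf
    if (i_rem <= n_edges) nx <- min(nx, e_right[i_rem])
    if (i_ins <= n_edges) nx <- min(nx, e_left[i_ins])
    while (wi <= length(want) && want[wi] < nx && want[wi] >= x) {
      # DFS from the mutation node
      ns <- 1L; stack[1L] <- node_at[wi]
      acc <- integer(0)
      while (ns > 0L) {
        v <- stack[ns]; ns <- ns - 1L
        if (is_sample[v]) acc[length(acc) + 1L] <- v - 1L
        kv <- kids[[v]]
        if (length(kv)) {
          stack[(ns + 1L):(ns + length(kv))] <- kv
          ns <- ns + length(kv)
        }
      }
      res[[wi]] <- sort.int(acc)
      wi <- wi + 1L
    }
    if (is.infinite(nx) || wi > length(want)) break
    x <- nx
    while (i_rem <= n_edges && e_right[i_rem] == x) {
      p <- rem_parent[i_rem]; cn <- rem_child[i_rem]
      kids[[p]] <- kids[[p]][kids[[p]] != cn]
      i_rem <- i_rem + 1L
    }
    while (i_ins <= n_edges && e_left[i_ins] == x) {
      p <- ins_parent[i_ins]; cn <- ins_child[i_ins]
      kids[[p]] <- c(kids[[p]], cn)
      i_ins <- i_ins + 1L
    }
  }
  res[match(positions, want)]
}

# combine clade lists from several windows, merging records by sample set
.combine_clade_lists <- function(lists) {
  env <- new.env(parent = emptyenv())
  n_samp <- attr(lists[[1]], "n_samples")
  for (cl in lists) {
    for (r in cl) {
      key <- paste(r$samples, collapse = ",")
      cur <- get0(key, envir = env)
      if (is.null(cur)) assign(key, r, envir = env)
      else {
        rows <- function(m) lapply(seq_len(nrow(m)), function(i) m[i, ])
        cur$spans <- .merge_intervals(c(rows(cur$spans), rows(r$spans)))
        cur$mutations <- unique(rbind(cur$mutations, r$mutations))
        assign(key, cur, envir = env)
      }
    }
  }
  keys <- ls(env)
  recs <- lapply(keys, get, envir = env)
  if (length(recs)) {
    ord <- order(vapply(recs, function(r) r$spans[1, 1], numeric(1)),
                 vapply(recs, function(r) length(r$samples), integer(1)))
    recs <- recs[ord]
  }
  out <- structure(recs, class = "clade_list", n_samples = n_samp)
  out
}
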