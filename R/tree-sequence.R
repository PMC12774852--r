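# Succinct tree-sequence container: an ARG stored as node / edge / site /
# mutation tables with tskit column semantics.  All genomic coordinates are
# 0-based with half-open intervals [left, right); node ids are 0-based.

#' Construct a tree sequence
#'
#' A tree sequence encodes an ancestral recombination graph (ARG) as a set of
#' tables: nodes (with times), edges (parent-child links with the genomic
#' interval over which they hold), sites (positions with an ancestral state)
#' and mutations (site, node, derived state).  The local genealogical tree at
#' any position is recovered from the edges active there.
#'
#' @param nodes data.frame with columns `id` (0-based, consecutive from 0),
#'   `is_sample` (0/1) and `time` (>= 0, in generations).
#' @param edges data.frame with columns `left`, `right`, `parent`, `child`;
#'   intervals are half-open `[left, right)` and must satisfy
#'   `time[parent] > time[child]`, with non-overlapping intervals per child.
#' @param sites data.frame with columns `id`, `position`, `ancestral_state`,
#'   sorted by position (infinite-sites: positions unique), or `NULL`.
#' @param mutations data.frame with columns `id`, `site`, `node`,
#'   `derived_state`, or `NULL`.
#' @param sequence_length total sequence length in bp.
#' @return An object of class `tree_seq`.
#' @export
tree_seq <- function(nodes, edges, sites = NULL, mutations = NULL,
                     sequence_length) {
  stopifnot(is.data.frame(nodes), is.data.frame(edges),
            is.numeric(sequence_length), sequence_length > 0)
  nodes <- nodes[order(nodes$id), , drop = FALSE]
  if (!identical(as.integer(nodes$id), seq_len(nrow(nodes)) - 1L))
    stop("node ids must be consecutive integers starting at 0", call. = FALSE)
  n_nodes <- nrow(nodes)
  if (nrow(edges)) {
    bad <- edges$left >= edges$right | edges$left < 0 |
      edges$right > sequence_length
    if (any(bad))
      stop("malformed tree sequence: edge intervals must satisfy 0 <= left < right <= sequence_length",
           call. = FALSE)
    if (any(edges$parent < 0 | edges$parent >= n_nodes |
            edges$child < 0 | edges$child >= n_nodes))
      stop("malformed tree sequence: edge references unknown node", call. = FALSE)
    if (any(nodes$time[edges$parent + 1L] <= nodes$time[edges$child + 1L]))
      stop("malformed tree sequence: parent must be older than child", call. = FALSE)
    # per-child intervals must not overlap (a node has one parent at a position)
    ord <- order(edges$child, edges$left)
    ch <- edges$child[ord]; lf <- edges$left[ord]; rt <- edges$right[ord]
    same <- which(ch[-1] == ch[-length(ch)])
    if (length(same) && any(lf[same + 1L] < rt[same]))
      stop("malformed tree sequence: overlapping edges for a child", call. = FALSE)
  }
  if (is.null(sites))
    sites <- data.frame(id = integer(), position = numeric(),
                        ancestral_state = character())
  if (is.null(mutations))
    mutations <- data.frame(id = integer(), site = integer(), node = integer(),
                            derived_state = character())
  if (nrow(sites)) {
    sites <- sites[order(sites$position), , drop = FALSE]
    if (anyDuplicated(sites$position))
      stop("malformed tree sequence: duplicate site positions (infinite sites assumed)",
           call. = FALSE)
    if (any(sites$position < 0 | sites$position >= sequence_length))
      stop("malformed tree sequence: site position outside sequence", call. = FALSE)
  }
  if (nrow(mutations)) {
    if (any(!mutations$site %in% sites$id))
      stop("malformed tree sequence: mutation references unknown site", call. = FALSE)
    if (any(mutations$node < 0 | mutations$node >= n_nodes))
      stop("malformed tree sequence: mutation references unknown node", call. = FALSE)
  }
  nodes$id <- as.integer(nodes$id)
  nodes$is_sample <- as.integer(nodes$is_sample)
  nodes$time <- as.numeric(nodes$time)
  edges$left <- as.numeric(edges$left); edges$right <- as.numeric(edges$right)
  edges$parent <- as.integer(edges$parent)
  edges$child <- as.integer(edges$child)
  if (nrow(sites)) {
    sites$id <- as.integer(sites$id)
    sites$position <- as.numeric(sites$position)
  }
  if (nrow(mutations)) {
    mutations$id <- as.integer(mutations$id)
    mutations$site <- as.integer(mutations$site)
    mutations$node <- as.integer(mutations$node)
  }
  structure(list(nodes = nodes, edges = edges, sites = sites,
                 mutations = mutations,
                 sequence_length = as.numeric(sequence_length),
                 samples = nodes$id[nodes$is_sample == 1L]),
            class = "tree_seq")
}

#' @export
print.tree_seq <- function(x, ...) {
  cat("Tree sequence:", length(x$samples), "samples,",
      nrow(x$nodes), "nodes,", nrow(x$edges), "edges,",
      nrow(x$sites), "sites,", nrow(x$mutations), "mutations\n")
  cat("Sequence length:", format(x$sequence_length, big.mark = ","), "bp;",
      n_local_trees(x), "local trees\n")
  invisible(x)
}

#' Number of distinct local trees
#' @param ts a `tree_seq`.
#' @return Integer count of distinct tree intervals.
#' @export
n_local_trees <- function(ts) length(tree_breakpoints(ts)) - 1L

#' Local tree interval boundaries
#'
#' @param ts a `tree_seq`.
#' @return Sorted numeric vector of breakpoints, starting at 0 and ending at
#'   the sequence length.  Adjacent breakpoints delimit the intervals over
#'   which the local tree is constant.
#' @export
tree_breakpoints <- function(ts) {
  sort(unique(c(0, ts$edges$left, ts$edges$right, ts$sequence_length)))
}

#' Extract the local tree at a genomic position
#'
#' @param ts a `tree_seq`.
#' @param position bp position in `[0, sequence_length)`.
#' @return A list of class `local_tree` with elements `parent` (0-based parent
#'   id per node, `NA` for roots / detached nodes), `interval` (the maximal
#'   interval over which these edges are active) and `position`.
#' @export
local_tree <- function(ts, position) {
  if (position < 0 || position >= ts$sequence_length)
    stop("position outside the sequence interval", call. = FALSE)
  act <- ts$edges$left <= position & ts$edges$right > position
  parent <- rep(NA_integer_, nrow(ts$nodes))
  parent[ts$edges$child[act] + 1L] <- as.integer(ts$edges$parent[act])
  lo <- c(ts$edges$left[!act & ts$edges$left <= position], 0)
  hi <- c(ts$edges$right[!act & ts$edges$right > position], ts$sequence_length)
  iv <- c(max(ts$edges$left[act], lo), min(ts$edges$right[act], hi))
  structure(list(parent = parent, interval = iv, position = position,
                 time = ts$nodes$time, samples = ts$samples),
            class = "local_tree")
}

#' Descendant samples of a node in a local tree
#'
#' @param tree a `local_tree`.
#' @param node 0-based node id.
#' @param samples optional subset of sample ids to project onto.
#' @return Sorted integer vector of descendant sample ids.
#' @export
tree_descendants <- function(tree, node, samples = NULL) {
  if (is.null(samples)) samples <- tree$samples
  # iterative DFS over the children lists implied by the parent vector
  kids <- split(seq_along(tree$parent) - 1L, factor(tree$parent,
                levels = seq_along(tree$parent) - 1L))
  out <- integer(0); stack <- as.integer(node)
  while (length(stack)) {
    v <- stack[length(stack)]; stack <- stack[-length(stack)]
    if (v %in% samples) out <- c(out, v)
    stack <- c(stack, as.integer(kids[[as.character(v)]]))
  }
  sort(unique(out))
}

# ---------------------------------------------------------------------------
# Plain-text interchange format.  One file, sections introduced by '#<name>'
# header lines carrying the column names; whitespace-delimited rows.

#' Write a tree sequence as plain text
#'
#' @param ts a `tree_seq`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_tree_seq <- function(ts, path) {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c("#tree_seq_text v1",
               paste("#sequence_length", format(ts$sequence_length, digits = 17))),
             con)
  dump_tab <- function(name, df) {
    writeLines(paste0("#", name, " ", paste(names(df), collapse = " ")), con)
    if (nrow(df))
      utils::write.table(df, con, quote = FALSE, sep = " ",
                         row.names = FALSE, col.names = FALSE)
  }
  dump_tab("nodes", ts$nodes[c("id", "is_sample", "time")])
  dump_tab("edges", ts$edges[c("left", "right", "parent", "child")])
  dump_tab("sites", ts$sites[c("id", "position", "ancestral_state")])
  dump_tab("mutations", ts$mutations[c("id", "site", "node", "derived_state")])
  invisible(path)
}

#' Read a tree sequence from plain text
#'
#' Reads the table format written by [write_tree_seq()].
#'
#' @param path file path.
#' @return A `tree_seq`.
#' @export
read_tree_seq <- function(path) {
  lines <- readLines(path)
  if (!length(lines) || !startsWith(lines[1], "#tree_seq_text"))
    stop("malformed tree sequence: not a tree_seq_text file", call. = FALSE)
  hdr <- which(startsWith(lines, "#"))
  sec_name <- sub("^#(\\S+).*", "\\1", lines[hdr])
  seq_len_line <- hdr[sec_name == "sequence_length"]
  if (!length(seq_len_line))
    stop("malformed tree sequence: missing #sequence_length", call. = FALSE)
  L <- as.numeric(strsplit(lines[seq_len_line], "\\s+")[[1]][2])
  grab <- function(name) {
    i <- hdr[sec_name == name]
    if (!length(i)) return(NULL)
    cols <- strsplit(sub("^#\\S+\\s*", "", lines[i]), "\\s+")[[1]]
    nxt <- c(hdr, length(lines) + 1L)
    end <- min(nxt[nxt > i]) - 1L
    if (end < i + 1L) {
      df <- as.data.frame(setNames(rep(list(character(0)), length(cols)), cols))
    } else {
      df <- utils::read.table(text = lines[(i + 1L):end], header = FALSE,
                              col.names = cols, stringsAsFactors = FALSE)
    }
    df
  }
  nodes <- grab("nodes"); edges <- grab("edges")
  sites <- grab("sites"); mut <- grab("mutations")
  if (is.null(nodes) || is.null(edges))
    stop("malformed tree sequence: missing nodes or edges section", call. = FALSE)
  num <- function(df, cols) { for (cc in cols) df[[cc]] <- as.numeric(df[[cc]]); df }
  int <- function(df, cols) { for (cc in cols) df[[cc]] <- as.integer(df[[cc]]); df }
  nodes <- int(num(nodes, "time"), c("id", "is_sample"))
  edges <- int(num(edges, c("left", "right")), c("parent", "child"))
  if (!is.null(sites) && nrow(sites)) {
    sites <- int(num(sites, "position"), "id")
    sites$ancestral_state <- as.character(sites$ancestral_state)
  } else sites <- NULL
  if (!is.null(mut) && nrow(mut)) {
    mut <- int(mut, c("id", "site", "node"))
    mut$derived_state <- as.character(mut$derived_state)
  } else mut <- NULL
  tree_seq(nodes, edges, sites, mut, sequence_length = L)
}

# ---------------------------------------------------------------------------
# Incremental sweep engine.  Maintains, for every node, the sorted set of
# descendant samples (projected onto a chosen sample subset), updated through
# edge insertions/removals between adjacent local trees rather than per-tree
# re-traversal.  Used by clade enumeration and by genotype extraction.
#
# Returns a list with:
#   sets    : environment mapping set-key -> list(samples=, ivals=list of c(l,r))
#   mut     : data.frame(site, position, node, key) for mutations in [left,right)
# Keys are the comma-collapsed sorted sample ids.

.ts_sweep <- function(ts, left = 0, right = ts$sequence_length,
                      samples = NULL, record_pieces = TRUE,
                      record_mutations = TRUE) {
  n_nodes <- nrow(ts$nodes)
  if (is.null(samples)) samples <- ts$samples
  samples <- sort(as.integer(samples))

  e <- ts$edges
  n_edges <- nrow(e)
  ins_ord <- order(e$left, ts$nodes$time[e$parent + 1L])
  rem_ord <- order(e$right, -ts$nodes$time[e$parent + 1L])
  e_left <- e$left[ins_ord]; e_right <- e$right[rem_ord]
  ins_parent <- e$parent[ins_ord]; ins_child <- e$child[ins_ord]
  rem_parent <- e$parent[rem_ord]; rem_child <- e$child[rem_ord]

  parent <- rep(NA_integer_, n_nodes)
  desc <- vector("list", n_nodes)
  empty <- integer(0)
  for (v in seq_len(n_nodes)) desc[[v]] <- empty
  for (s in samples) desc[[s + 1L]] <- s

  piece_start <- numeric(n_nodes)
  sets <- new.env(parent = emptyenv(), size = 1024L)

  # mutations ordered by genomic position
  have_mut <- record_mutations && nrow(ts$mutations) > 0L
  if (have_mut) {
    mpos <- ts$sites$position[match(ts$mutations$site, ts$sites$id)]
    mord <- order(mpos)
    mpos <- mpos[mord]
    mnode <- ts$mutations$node[mord]
    msite <- ts$mutations$site[mord]
    mid <- ts$mutations$id[mord]
    n_mut <- length(mpos)
    mut_key <- character(n_mut)
    mut_keep <- logical(n_mut)
  }
  mi <- 1L

  i_ins <- 1L; i_rem <- 1L
  x <- 0

  repeat {
    nx <- Inf
    if (i_rem <= n_edges) nx <- min(nx, e_right[i_rem])
    if (i_ins <= n_edges) nx <- min(nx, e_left[i_ins])
    # emit mutations lying in [x, min(nx, right)) under the current state
    if (have_mut) {
      upto <- min(nx, right)
      while (mi <= n_mut && mpos[mi] < upto) {
        if (mpos[mi] >= x && mpos[mi] >= left) {
          mut_key[mi] <- paste(desc[[mnode[mi] + 1L]], collapse = ",")
          mut_keep[mi] <- TRUE
        }
        mi <- mi + 1L
      }
    }
    if (is.infinite(nx) || nx >= right) break
    x <- nx
    # removals at x (old parent chains, then detach)
    while (i_rem <= n_edges && e_right[i_rem] == x) {
      p <- rem_parent[i_rem]; cnode <- rem_child[i_rem]
      delta <- desc[[cnode + 1L]]
      if (length(delta)) {
        w <- p
        while (!is.na(w)) {
          wi <- w + 1L
          if (record_pieces && piece_start[wi] < x) {
            old <- desc[[wi]]
            if (length(old)) {
              l <- max(piece_start[wi], left)
              if (l < min(x, right)) {
                key <- paste(old, collapse = ",")
                rec <- get0(key, envir = sets)
                if (is.null(rec)) rec <- list(samples = old, ivals = list())
                rec$ivals[[length(rec$ivals) + 1L]] <- c(l, min(x, right))
                assign(key, rec, envir = sets)
              }
            }
            piece_start[wi] <- x
          }
          desc[[wi]] <- desc[[wi]][!(desc[[wi]] %in% delta)]
          w <- parent[wi]
        }
      }
      parent[cnode + 1L] <- NA_integer_
      i_rem <- i_rem + 1L
    }
    # insertions at x
    while (i_ins <= n_edges && e_left[i_ins] == x) {
      p <- ins_parent[i_ins]; cnode <- ins_child[i_ins]
      parent[cnode + 1L] <- p
      delta <- desc[[cnode + 1L]]
      if (length(delta)) {
        w <- p
        while (!is.na(w)) {
          wi <- w + 1L
          if (record_pieces && piece_start[wi] < x) {
            old <- desc[[wi]]
            if (length(old)) {
              l <- max(piece_start[wi], left)
              if (l < min(x, right)) {
                key <- paste(old, collapse = ",")
                rec <- get0(key, envir = sets)
                if (is.null(rec)) rec <- list(samples = old, ivals = list())
                rec$ivals[[length(rec$ivals) + 1L]] <- c(l, min(x, right))
                assign(key, rec, envir = sets)
              }
            }
            piece_start[wi] <- x
          }
          desc[[wi]] <- sort.int(c(desc[[wi]], delta))
          w <- parent[wi]
        }
      }
      i_ins <- i_ins + 1L
    }
  }
  # final flush over [piece_start, right)
  if (record_pieces) {
    for (wi in seq_len(n_nodes)) {
      old <- desc[[wi]]
      if (length(old)) {
        l <- max(piece_start[wi], left)
        if (l < right) {
          key <- paste(old, collapse = ",")
          rec <- get0(key, envir = sets)
          if (is.null(rec)) rec <- list(samples = old, ivals = list())
          rec$ivals[[length(rec$ivals) + 1L]] <- c(l, right)
          assign(key, rec, envir = sets)
        }
      }
    }
  }
  mut <- if (have_mut) {
    keep <- which(mut_keep)
    data.frame(id = mid[keep], site = msite[keep], position = mpos[keep],
               node = mnode[keep], key = mut_key[keep],
               stringsAsFactors = FALSE)
  } else {
    data.frame(id = integer(), site = integer(), position = numeric(),
               node = integer(), key = character(), stringsAsFactors = FALSE)
  }
  list(sets = sets, mut = mut, samples = samples)
}
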