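# Hand-built toy ARGs with documented clades and spans, for tests, examples
# and documentation.

#' Construct a bundled toy ARG fixture
#'
#' Available fixtures:
#' \describe{
#'   \item{`single_tree`}{4 samples, one tree over `[0, 100)` with balanced
#'     topology ((0,1),(2,3)); the two cherries are the only non-root
#'     internal clades.}
#'   \item{`eight_sample`}{8 samples, two local trees over `[0, 50)` and
#'     `[50, 100)`.  SNP1 at position 20 is carried by samples
#'     `{1,2,3,5}` (a clade of tree 1); SNP2 at position 70 by `{2,5,6,7}`
#'     (a clade of tree 2).  The induced target sets are `S = {2,5}`,
#'     `K1 = {1,3}`, `K2 = {6,7}`, `O = {0,4}`; K2 and O are clades in both
#'     trees (spanning `[0, 100)`), and a third mutation at position 52
#'     supports the K2 clade.}
#'   \item{`span_break`}{4 samples, three trees; the set `{0,1}` is a clade
#'     in trees 1 and 3 but not tree 2, so its record carries two disjoint
#'     spans.}
#' }
#'
#' @param name fixture name.
#' @param dir optional directory; if given, the tree sequence and a matching
#'   SNP-pair TSV are written there.
#' @return list with `ts` (a [tree_seq()]) and `pairs` (data.frame; may have
#'   zero rows).
#' @export
make_fixture <- function(name = c("single_tree", "eight_sample", "span_break"),
                         dir = NULL) {
  name <- match.arg(name)
  if (name == "single_tree") {
    nodes <- data.frame(id = 0:6,
                        is_sample = c(1, 1, 1, 1, 0, 0, 0),
                        time = c(0, 0, 0, 0, 1, 1.5, 3))
    edges <- data.frame(left = 0, right = 100,
                        parent = c(4, 4, 5, 5, 6, 6),
                        child = c(0, 1, 2, 3, 4, 5))
    ts <- tree_seq(nodes, edges, sequence_length = 100)
    pairs <- data.frame(chrom = character(), pos1 = numeric(),
                        pos2 = numeric(), study_N = integer(),
                        p_value = numeric())
  } else if (name == "eight_sample") {
    nodes <- data.frame(
      id = 0:19,
      is_sample = c(rep(1, 8), rep(0, 12)),
      time = c(rep(0, 8),
               1, 1.2, 2,      # 8 = (1,2), 9 = (3,5), 10 = {1,2,3,5}
               1.1, 1.3, 2.1,  # 11 = (0,4), 12 = (6,7), 13 = {0,4,6,7}
               3,              # 14 = root of tree 1
               1, 1,           # 15 = (2,5), 16 = (1,3)
               2, 2.2,         # 17 = {2,5,6,7}, 18 = {0,4,1,3}
               3.2))           # 19 = root of tree 2
    edges <- rbind(
      # persistent cherries (0,4) and (6,7): whole sequence
      data.frame(left = 0, right = 100, parent = c(11, 11, 12, 12),
                 child = c(0, 4, 6, 7)),
      # tree 1 only
      data.frame(left = 0, right = 50,
                 parent = c(8, 8, 9, 9, 10, 10, 13, 13, 14, 14),
                 child = c(1, 2, 3, 5, 8, 9, 11, 12, 10, 13)),
      # tree 2 only
      data.frame(left = 50, right = 100,
                 parent = c(15, 15, 16, 16, 17, 17, 18, 18, 19, 19),
                 child = c(2, 5, 1, 3, 15, 12, 11, 16, 17, 18)))
    sites <- data.frame(id = 0:2, position = c(20, 52, 70),
                        ancestral_state = "0")
    mutations <- data.frame(id = 0:2, site = 0:2, node = c(10, 12, 17),
                            derived_state = "1")
    ts <- tree_seq(nodes, edges, sites, mutations, sequence_length = 100)
    pairs <- data.frame(chrom = "1", pos1 = 20, pos2 = 70,
                        freq1 = 0.5, freq2 = 0.5,
                        study_N = 5000L, p_value = 1e-8, alpha = 0.05)
  } else {
    nodes <- data.frame(
      id = 0:12,
      is_sample = c(rep(1, 4), rep(0, 9)),
      time = c(rep(0, 4),
               1, 1.2, 2,    # tree 1: 4 = (0,1), 5 = (2,3), 6 = root
               1, 1.2, 2,    # tree 2: 7 = (0,2), 8 = (1,3), 9 = root
               1, 1.2, 2))   # tree 3: 10 = (0,1), 11 = (2,3), 12 = root
    edges <- rbind(
      data.frame(left = 0, right = 40,
                 parent = c(4, 4, 5, 5, 6, 6), child = c(0, 1, 2, 3, 4, 5)),
      data.frame(left = 40, right = 60,
                 parent = c(7, 7, 8, 8, 9, 9), child = c(0, 2, 1, 3, 7, 8)),
      data.frame(left = 60, right = 100,
                 parent = c(10, 10, 11, 11, 12, 12),
                 child = c(0, 1, 2, 3, 10, 11)))
    ts <- tree_seq(nodes, edges, sequence_length = 100)
    pairs <- data.frame(chrom = character(), pos1 = numeric(),
                        pos2 = numeric(), study_N = integer(),
                        p_value = numeric())
  }
  if (!is.null(dir)) {
    dir.create(dir, showWarnings = FALSE, recursive = TRUE)
    write_tree_seq(ts, file.path(dir, paste0(name, ".trees.txt")))
    utils::write.table(pairs, file.path(dir, paste0(name, "_pairs.tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(ts = ts, pairs = pairs)
}
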