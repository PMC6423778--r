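#' Generate a BioGRID-style interaction file from a planted-partition graph
#'
#' Draws an undirected planted-partition graph: node pairs inside a
#' community are connected with probability `p_in`, pairs across communities
#' with probability `p_out` (`p_in > p_out`). The records mimic the BioGRID
#' TAB layout with official-symbol and taxonomy-id columns, all at the human
#' taxid 9606; optional decoy rows at another taxid exercise the taxonomy
#' filter of [parse_biogrid()]. Ground-truth community labels are returned.
#'
#' @param n_communities number of planted communities.
#' @param sizes integer vector of community sizes (recycled to
#'   `n_communities`); must sum to > 0.
#' @param p_in,p_out within/between edge probabilities, `p_in > p_out`.
#' @param seed integer seed; equal seeds give identical output.
#' @param taxid taxonomy id written on genuine rows (default 9606).
#' @param n_decoys number of decoy rows at `decoy_taxid` appended.
#' @param decoy_taxid taxonomy id of decoy rows (default 10090, mouse).
#' @param path optional TSV path to write the records to.
#' @return list with `records` (data.frame: `official_symbol_a/b`,
#'   `taxid_a/b`), `community_label` (named integer vector), and `n_edges`
#'   (genuine edge count).
#' @export
generate_interaction_file <- function(n_communities, sizes, p_in, p_out,
                                      seed = 1L, taxid = 9606, n_decoys = 5L,
                                      decoy_taxid = 10090, path = NULL) {
  if (p_in <= p_out) stop("p_in must exceed p_out")
  sizes <- rep_len(as.integer(sizes), n_communities)
  if (sum(sizes) == 0L) stop("community sizes sum to 0")
  set.seed(seed)
  labels <- rep(seq_len(n_communities), sizes)
  nodes <- sprintf("P%02d_%03d", labels, unlist(lapply(sizes, seq_len)))
  names(labels) <- nodes
  n <- length(nodes)
  ia <- c(); ib <- c()
  for (i in seq_len(n - 1)) for (j in seq((i + 1), n)) {
    p <- if (labels[i] == labels[j]) p_in else p_out
    if (stats::runif(1) < p) { ia <- c(ia, i); ib <- c(ib, j) }
  }
  rec <- data.frame(official_symbol_a = nodes[ia],
                    official_symbol_b = nodes[ib],
                    taxid_a = taxid, taxid_b = taxid,
                    stringsAsFactors = FALSE)
  if (n_decoys > 0) {
    decoys <- data.frame(
      official_symbol_a = sprintf("MM_%03d", seq_len(n_decoys)),
      official_symbol_b = sprintf("MM_%03d", seq_len(n_decoys) + n_decoys),
      taxid_a = decoy_taxid, taxid_b = decoy_taxid,
      stringsAsFactors = FALSE)
    rec <- rbind(rec, decoys)
  }
  if (!is.null(path))
    utils::write.table(rec, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(records = rec, community_label = labels, n_edges = length(ia))
}
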