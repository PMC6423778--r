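#' Extract the aging and rejuvenation gene signatures from group p-values
#'
#' The two signatures are defined purely by detection-call logic on one
#' detection p-value per gene and group:
#' \describe{
#'   \item{aging}{expressed in parental MSCs but absent in iMSCs and iPSCs:
#'     `p_MSC < expressed_threshold` and `p_iMSC > absent_threshold` and
#'     `p_iPSC > absent_threshold`.}
#'   \item{rejuvenation}{the mirror rule: `p_MSC > absent_threshold`,
#'     `p_iMSC < expressed_threshold`, `p_iPSC < expressed_threshold`.}
#' }
#' All inequalities are strict; genes whose p falls in the dead zone
#' `[expressed_threshold, absent_threshold]` for any group belong to neither
#' set. The two sets are disjoint by construction (the rules demand
#' contradictory MSC states).
#'
#' @param group_p named list with elements `MSC`, `iMSC`, `iPSC`, each a
#'   named numeric vector gene -> detection p (see [group_detection()]; the
#'   `MSC` entry is typically the fMSC+aMSC pool collapsed under one policy).
#' @param expressed_threshold p bound below which a gene counts as expressed
#'   (default 0.001).
#' @param absent_threshold p bound above which a gene counts as absent
#'   (default 0.1); must exceed `expressed_threshold`.
#' @return a `signature_result`: list with character vectors `aging` and
#'   `rejuvenation`, and `per_gene_group_p` (genes x groups matrix).
#' @export
extract_signatures <- function(group_p, expressed_threshold = 0.001,
                               absent_threshold = 0.1) {
  need <- c("MSC", "iMSC", "iPSC")
  if (!all(need %in% names(group_p)))
    stop("group_p must contain groups: ", paste(need, collapse = ", "))
  if (expressed_threshold >= absent_threshold)
    stop("expressed_threshold must be below absent_threshold")
  genes <- Reduce(intersect, lapply(group_p[need], names))
  pm <- vapply(need, function(g) group_p[[g]][genes], numeric(length(genes)))
  if (length(genes) == 1L) pm <- matrix(pm, 1, dimnames = list(genes, need))
  rownames(pm) <- genes
  e <- expressed_threshold; a <- absent_threshold
  aging <- genes[pm[, "MSC"] < e & pm[, "iMSC"] > a & pm[, "iPSC"] > a]
  rejuvenation <- genes[pm[, "MSC"] > a & pm[, "iMSC"] < e & pm[, "iPSC"] < e]
  structure(list(aging = aging, rejuvenation = rejuvenation,
                 per_gene_group_p = pm,
                 expressed_threshold = e, absent_threshold = a),
            class = "signature_result")
}

#' @export
print.signature_result <- function(x, ...) {
  cat("signature_result: ", length(x$aging), " aging, ",
      length(x$rejuvenation), " rejuvenation genes (p < ",
      x$expressed_threshold, " vs p > ", x$absent_threshold, ")\n", sep = "")
  invisible(x)
}

#' Pearson correlation distance between samples
#'
#' `d(i, j) = 1 - r(i, j)` with r the Pearson correlation of the two
#' samples' log2 expression profiles; 0 for affinely identical samples, 2
#' for perfectly anti-correlated ones.
#'
#' @param log2_signals genes x samples matrix (>= 2 samples, >= 2 genes).
#' @return symmetric samples x samples distance matrix with zero diagonal.
#' @export
pearson_distance <- function(log2_signals) {
  m <- as.matrix(log2_signals)
  if (ncol(m) < 2L || nrow(m) < 2L) stop("need >= 2 samples and >= 2 genes")
  v <- apply(m, 2, stats::var)
  if (any(v == 0))
    stop("zero-variance sample(s): ", paste(colnames(m)[v == 0], collapse = ", "))
  d <- 1 - stats::cor(m)
  diag(d) <- 0
  d
}

#' Average-linkage (or other) hierarchical clustering of a distance matrix
#'
#' A thin, convention-fixing wrapper around [stats::hclust()]: returns the
#' merge tree plus helpers to cut it into k clusters and to serialize it as
#' a Newick string.
#'
#' @param dist_matrix symmetric distance matrix (e.g. [pearson_distance()]).
#' @param linkage one of `"average"`, `"complete"`, `"single"`, `"ward.D2"`.
#' @return an object of class `hclust`.
#' @export
hierarchical_cluster <- function(dist_matrix, linkage = "average") {
  linkage <- match.arg(linkage, c("average", "complete", "single", "ward.D2"))
  d <- stats::as.dist(dist_matrix)
  if (attr(d, "Size") < 2L) stop("need >= 2 observations to cluster")
  stats::hclust(d, method = linkage)
}

#' @rdname hierarchical_cluster
#' @param tree an `hclust` object.
#' @param k number of clusters to cut into.
#' @export
cut_clusters <- function(tree, k) stats::cutree(tree, k = k)

#' @rdname hierarchical_cluster
#' @export
tree_newick <- function(tree) {
  stopifnot(inherits(tree, "hclust"))
  ape::write.tree(ape::as.phylo(tree))
}

#' Restrict an expression matrix to a gene list and cluster both axes
#'
#' The heatmap primitive for GO-term (or any) gene subsets: rows are
#' restricted to the intersection of `gene_list` with the matrix; genes
#' absent from the matrix are reported explicitly, never silently dropped.
#'
#' @param log2_signals genes x samples matrix.
#' @param gene_list character vector of gene ids to keep.
#' @return list with `matrix` (the submatrix), `missing` (requested ids not
#'   present), and `row_tree` / `col_tree` (`hclust` trees over 1 - Pearson
#'   distances, `NULL` when an axis is too small to cluster).
#' @export
subset_heatmap_matrix <- function(log2_signals, gene_list) {
  gene_list <- unique(gene_list)
  present <- intersect(gene_list, rownames(log2_signals))
  missing <- setdiff(gene_list, present)
  if (length(present) == 0L) stop("no requested genes present in the matrix")
  sub <- log2_signals[present, , drop = FALSE]
  col_tree <- tryCatch(hierarchical_cluster(pearson_distance(sub)),
                       error = function(e) NULL)
  row_tree <- if (nrow(sub) >= 3L) {
    rv <- apply(sub, 1, stats::var)
    if (all(rv > 0)) hierarchical_cluster(1 - stats::cor(t(sub))) else NULL
  } else NULL
  list(matrix = sub, missing = missing, row_tree = row_tree,
       col_tree = col_tree)
}

#' Hypergeometric over-representation test of a gene set against annotations
#'
#' One-sided hypergeometric upper-tail p-value per annotation term (the
#' probability of seeing at least the observed overlap between the query and
#' the term's genes when drawing `|query|` genes from the background without
#' replacement), with Benjamini-Hochberg adjustment across terms.
#'
#' @param query character vector, must be a subset of `background`.
#' @param annotations named list term -> character vector of genes. Genes
#'   outside the background are clipped with a warning.
#' @param background character vector: the gene universe.
#' @return data.frame with `term`, `term_size`, `overlap`, `p`, `q`.
#' @export
hypergeom_enrichment <- function(query, annotations, background) {
  background <- unique(background)
  query <- unique(query)
  if (!all(query %in% background))
    stop("query must be a subset of the background")
  clipped <- vapply(annotations, function(s) sum(!unique(s) %in% background),
                    integer(1))
  if (any(clipped > 0))
    warning("clipped ", sum(clipped), " annotation gene(s) outside background")
  annotations <- lapply(annotations, function(s) intersect(unique(s), background))
  N <- length(background); k <- length(query)
  res <- lapply(names(annotations), function(term) {
    m <- length(annotations[[term]])
    ov <- length(intersect(query, annotations[[term]]))
    p <- stats::phyper(ov - 1, m, N - m, k, lower.tail = FALSE)
    data.frame(term = term, term_size = m, overlap = ov, p = p)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out[order(out$p), , drop = FALSE]
}
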