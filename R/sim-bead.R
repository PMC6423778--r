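#' Simulation configuration for synthetic bead-summary data
#'
#' Describes a synthetic bead-array experiment over the five cell-type groups
#' of the study design (fetal MSCs, adult MSCs, iPSCs, iMSCs, ESCs), with a
#' log-normal signal model and planted aging / rejuvenation signature genes.
#' Unexpressed genes and negative-control beads share one null distribution,
#' so detection p-values are calibrated by construction.
#'
#' Planted rejuvenation genes are expressed (signal-level draws) in iMSC,
#' iPSC and ESC samples and sit at negative-control level in fMSC/aMSC
#' samples; planted aging genes the converse. All remaining genes are either
#' expressed in every group (with probability `frac_expressed`) or nowhere.
#'
#' @param n_genes number of genes in the universe.
#' @param n_neg_controls negative-control beads per sample. Detection
#'   p-values have granularity 1/(n+1), so n >= 999 is required for the
#'   signature rule's p < 0.001 to be attainable; the default is 1000.
#' @param samples_per_group named integer vector over
#'   `c(fMSC, aMSC, iPSC, iMSC, ESC)`.
#' @param frac_expressed fraction of non-planted genes expressed in all groups.
#' @param planted_aging,planted_rejuvenation disjoint gene-id character vectors
#'   (subsets of the gene universe `G0001 ... G<n>`).
#' @param null_mu,null_sigma log2-scale location/spread of the shared null
#'   (background) distribution for unexpressed genes and control beads.
#' @param signal_mu,signal_sigma log2-scale location/spread of expressed-gene
#'   signals. The default puts expressed genes 4 log2 units above the null.
#' @param noise_sigma log2-scale spread of multiplicative per-measurement noise.
#' @param seed integer seed; equal seeds give bitwise-identical output.
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(n_genes = 1000L,
                       n_neg_controls = 1000L,
                       samples_per_group = c(fMSC = 3L, aMSC = 4L, iPSC = 5L,
                                             iMSC = 3L, ESC = 2L),
                       frac_expressed = 0.4,
                       planted_aging = character(),
                       planted_rejuvenation = character(),
                       null_mu = 7, null_sigma = 0.5,
                       signal_mu = 11, signal_sigma = 0.25,
                       noise_sigma = 0.25,
                       seed = 1L) {
  groups <- c("fMSC", "aMSC", "iPSC", "iMSC", "ESC")
  if (n_genes < 1L || n_neg_controls < 1L)
    stop("n_genes and n_neg_controls must be positive")
  if (!all(groups %in% names(samples_per_group)))
    stop("samples_per_group must name all of: ", paste(groups, collapse = ", "))
  if (any(samples_per_group[groups] < 1L))
    stop("every group needs at least one sample")
  if (frac_expressed <= 0 || frac_expressed >= 1)
    stop("frac_expressed must be in (0, 1)")
  universe <- sprintf("G%04d", seq_len(n_genes))
  if (length(intersect(planted_aging, planted_rejuvenation)) > 0L)
    stop("planted aging and rejuvenation lists must be disjoint")
  if (!all(c(planted_aging, planted_rejuvenation) %in% universe))
    stop("planted gene lists must be drawn from the gene universe (G0001 ...)")
  structure(list(
    n_genes = as.integer(n_genes),
    n_neg_controls = as.integer(n_neg_controls),
    samples_per_group = as.integer(samples_per_group[groups]) |>
      stats::setNames(groups),
    frac_expressed = frac_expressed,
    planted_aging = planted_aging,
    planted_rejuvenation = planted_rejuvenation,
    null_mu = null_mu, null_sigma = null_sigma,
    signal_mu = signal_mu, signal_sigma = signal_sigma,
    noise_sigma = noise_sigma,
    seed = as.integer(seed),
    gene_ids = universe
  ), class = "sim_config")
}

#' Generate a synthetic bead-summary experiment with planted ground truth
#'
#' Draws a genes x samples matrix of linear-scale fluorescence signals plus
#' per-sample negative-control bead signals under the model described in
#' [sim_config()], and records which genes were planted where.
#'
#' @param config a [sim_config()] object.
#' @return a list with elements
#'   \describe{
#'     \item{bead}{a `bead_summary` object: `signals` (genes x samples),
#'       `neg_controls` (control beads x samples), `gene_ids`, `sample_ids`,
#'       and `groups` (named character vector sample -> group).}
#'     \item{truth}{ground truth: `expressed` (genes x groups logical matrix)
#'       and `signature_label` (named vector in aging/rejuvenation/none).}
#'   }
#' @export
generate_bead_summary <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  groups <- names(config$samples_per_group)
  sample_ids <- unlist(lapply(groups, function(g)
    sprintf("%s_%d", g, seq_len(config$samples_per_group[[g]]))))
  group_of <- sub("_[0-9]+$", "", sample_ids) |> stats::setNames(sample_ids)

  genes <- config$gene_ids
  n_g <- length(genes)
  n_s <- length(sample_ids)

  # expressed[g, group]: baseline everywhere-or-nowhere, then planted overrides
  base_expr <- stats::runif(n_g) < config$frac_expressed
  expressed <- matrix(base_expr, n_g, length(groups),
                      dimnames = list(genes, groups))
  expressed[config$planted_rejuvenation, ] <- FALSE
  expressed[config$planted_rejuvenation, c("iPSC", "iMSC", "ESC")] <- TRUE
  expressed[config$planted_aging, ] <- FALSE
  expressed[config$planted_aging, c("fMSC", "aMSC")] <- TRUE

  expr_by_sample <- expressed[, group_of, drop = FALSE]
  log2sig <- matrix(0, n_g, n_s, dimnames = list(genes, sample_ids))
  log2sig[expr_by_sample] <- stats::rnorm(sum(expr_by_sample),
                                          config$signal_mu, config$signal_sigma)
  log2sig[!expr_by_sample] <- stats::rnorm(sum(!expr_by_sample),
                                           config$null_mu, config$null_sigma)
  log2sig <- log2sig + stats::rnorm(n_g * n_s, 0, config$noise_sigma)

  # controls are measured spots too: same null draw plus the same
  # measurement noise, so they share the unexpressed genes' distribution
  n_c <- config$n_neg_controls * n_s
  neg <- matrix(2^(stats::rnorm(n_c, config$null_mu, config$null_sigma) +
                     stats::rnorm(n_c, 0, config$noise_sigma)),
                config$n_neg_controls, n_s,
                dimnames = list(sprintf("NC%04d", seq_len(config$n_neg_controls)),
                                sample_ids))

  label <- rep("none", n_g) |> stats::setNames(genes)
  label[config$planted_aging] <- "aging"
  label[config$planted_rejuvenation] <- "rejuvenation"

  bead <- structure(list(signals = 2^log2sig,
                         neg_controls = neg,
                         gene_ids = genes,
                         sample_ids = sample_ids,
                         groups = group_of),
                    class = "bead_summary")
  list(bead = bead, truth = list(expressed = expressed, signature_label = label))
}

#' @export
print.bead_summary <- function(x, ...) {
  cat("bead_summary:", length(x$gene_ids), "genes x", length(x$sample_ids),
      "samples;", nrow(x$neg_controls), "negative controls/sample\n")
  cat("groups:", paste(sprintf("%s(%d)", names(table(x$groups)),
                               table(x$groups)), collapse = " "), "\n")
  invisible(x)
}

#' Write / read a bead-summary experiment as plain text
#'
#' The on-disk dialect is three files in `dir`: `signals.tsv` (first column
#' `gene_id`, then one column per sample), `neg_controls.tsv` (same layout
#' with control-bead rows) and `groups.json` (sample id -> group map).
#'
#' @param bead a `bead_summary` object.
#' @param dir output directory (created if absent).
#' @return `write_bead_summary` returns `dir` invisibly;
#'   `read_bead_summary` returns a `bead_summary`.
#' @export
write_bead_summary <- function(bead, dir) {
  stopifnot(inherits(bead, "bead_summary"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  sig <- data.frame(gene_id = bead$gene_ids, bead$signals, check.names = FALSE)
  utils::write.table(sig, file.path(dir, "signals.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  nc <- data.frame(control_id = rownames(bead$neg_controls), bead$neg_controls,
                   check.names = FALSE)
  utils::write.table(nc, file.path(dir, "neg_controls.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(bead$groups), file.path(dir, "groups.json"),
                       auto_unbox = TRUE)
  invisible(dir)
}

#' @rdname write_bead_summary
#' @export
read_bead_summary <- function(dir) {
  sig <- utils::read.delim(file.path(dir, "signals.tsv"), check.names = FALSE)
  nc <- utils::read.delim(file.path(dir, "neg_controls.tsv"), check.names = FALSE)
  groups <- unlist(jsonlite::read_json(file.path(dir, "groups.json")))
  signals <- as.matrix(sig[, -1, drop = FALSE])
  rownames(signals) <- sig[[1]]
  ctrl <- as.matrix(nc[, -1, drop = FALSE])
  rownames(ctrl) <- nc[[1]]
  structure(list(signals = signals, neg_controls = ctrl,
                 gene_ids = rownames(signals), sample_ids = colnames(signals),
                 groups = groups[colnames(signals)]),
            class = "bead_summary")
}
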