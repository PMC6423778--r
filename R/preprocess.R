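#' Background-correct a bead-summary matrix against its negative controls
#'
#' Per sample, subtracts the median negative-control signal from every gene
#' signal, flooring the result at a small positive constant `eps` so that
#' downstream log transforms are defined. The control matrix is corrected
#' identically (and floored the same way), so detection p-values computed on
#' the corrected object remain on the same scale as their controls.
#'
#' @param bead a `bead_summary` object.
#' @param eps floor applied after subtraction, in signal units.
#' @return a background-corrected `bead_summary`.
#' @export
background_correct <- function(bead, eps = 1.0) {
  stopifnot(inherits(bead, "bead_summary"))
  if (is.null(bead$neg_controls) || nrow(bead$neg_controls) == 0L)
    stop("background correction requires negative-control signals")
  med <- apply(bead$neg_controls, 2, stats::median)
  bead$signals <- pmax(sweep(bead$signals, 2, med, "-"), eps)
  bead$neg_controls <- pmax(sweep(bead$neg_controls, 2, med, "-"), eps)
  bead
}

#' Quantile-normalize a genes x samples signal matrix
#'
#' Forces every column onto the common reference distribution given by the
#' row-wise mean of the sorted columns, preserving within-column rank order.
#' Tied input values receive the mean of the reference quantiles spanned by
#' their rank run, which makes the result independent of the input order of
#' tied entries. The transform is idempotent.
#'
#' @param signals numeric matrix with at least 2 columns.
#' @return matrix of the same shape; all columns share one sorted profile.
#' @export
quantile_normalize <- function(signals) {
  signals <- as.matrix(signals)
  if (ncol(signals) < 2L) stop("quantile normalization needs >= 2 samples")
  if (anyNA(signals)) stop("missing values are not supported")
  sorted <- apply(signals, 2, sort)
  ref <- rowMeans(sorted)
  out <- signals
  for (j in seq_len(ncol(signals))) {
    x <- signals[, j]
    o <- order(x)
    # mean of reference quantiles over each run of tied values
    v <- stats::ave(ref, match(x[o], x[o]), FUN = mean)
    out[o, j] <- v
  }
  out
}

#' Detection p-values against per-sample negative-control beads
#'
#' For gene g in sample s, `p = (1 + #{controls in s with signal >= x}) /
#' (n_controls + 1)`: the add-one empirical upper-tail p-value of the gene's
#' signal against that sample's negative-control distribution, with ties
#' counted as exceedances. p is therefore always in (0, 1] and monotone
#' nonincreasing in the signal within a sample.
#'
#' @param bead a `bead_summary` object (raw or background-corrected; signals
#'   and controls must be on the same scale).
#' @param alpha detection threshold; a gene is called expressed in a sample
#'   when `p <= alpha` (0.05 in standard bead-array practice).
#' @return a `detection_result`: list with `p` and `expressed` (genes x
#'   samples matrices) and `alpha`.
#' @export
detection_pvalues <- function(bead, alpha = 0.05) {
  stopifnot(inherits(bead, "bead_summary"))
  n <- nrow(bead$neg_controls)
  if (is.null(n) || n == 0L) stop("no negative controls available")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  p <- bead$signals
  for (j in seq_len(ncol(p))) {
    sv <- sort(bead$neg_controls[, j])
    n_lt <- findInterval(bead$signals[, j], sv, left.open = TRUE)
    p[, j] <- (1 + n - n_lt) / (n + 1)
  }
  structure(list(p = p, expressed = p <= alpha, alpha = alpha),
            class = "detection_result")
}

#' Collapse detection p-values to one value per gene for a sample group
#'
#' The signature rules operate on a single detection p-value per gene and
#' group; this operation makes the collapse explicit rather than guessing a
#' per-figure sample choice. Policy `"max"` takes the per-gene maximum p over
#' the group's samples (conservative for "expressed in every sample of the
#' group"), `"min"` the minimum, and `"single:SAMPLE_ID"` returns that
#' sample's column unchanged. One policy is applied uniformly; thresholds on
#' opposite sides are never silently mixed.
#'
#' @param det a `detection_result`.
#' @param groups named character vector mapping sample id -> group name.
#' @param group group name to collapse (samples may belong to several
#'   pooled groups; pass the pooled map, e.g. fMSC+aMSC -> "MSC").
#' @param policy `"max"`, `"min"`, or `"single:SAMPLE_ID"`.
#' @return named numeric vector gene -> p.
#' @export
group_detection <- function(det, groups, group, policy = "max") {
  stopifnot(inherits(det, "detection_result"))
  if (startsWith(policy, "single:")) {
    s <- sub("^single:", "", policy)
    if (!s %in% colnames(det$p)) stop("unknown sample in policy: ", s)
    return(det$p[, s])
  }
  members <- names(groups)[groups == group]
  if (length(members) == 0L) stop("no samples in group: ", group)
  sub <- det$p[, members, drop = FALSE]
  switch(policy,
         max = apply(sub, 1, max),
         min = apply(sub, 1, min),
         stop("unknown policy: ", policy))
}
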