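#' End-to-end signature extraction from a bead-summary experiment
#'
#' The canonical composition: background correction against negative
#' controls, detection p-values, collapse to one p per gene for the pooled
#' parental-MSC group (fMSC + aMSC) and for the iMSC and iPSC groups under
#' one uniform policy, then the detection-call signature rules.
#'
#' @param bead a `bead_summary` object.
#' @param policy group-collapse policy passed to [group_detection()]
#'   (default `"max"`, i.e. a gene counts as expressed in a group only when
#'   it is detected in every sample of the group).
#' @param expressed_threshold,absent_threshold signature rule bounds, see
#'   [extract_signatures()].
#' @param background logical; apply [background_correct()] first.
#' @return a `signature_result`.
#' @export
run_signature_pipeline <- function(bead, policy = "max",
                                   expressed_threshold = 0.001,
                                   absent_threshold = 0.1,
                                   background = TRUE) {
  if (background) bead <- background_correct(bead)
  det <- detection_pvalues(bead)
  pooled <- bead$groups
  pooled[pooled %in% c("fMSC", "aMSC")] <- "MSC"
  group_p <- list(MSC = group_detection(det, pooled, "MSC", policy),
                  iMSC = group_detection(det, pooled, "iMSC", policy),
                  iPSC = group_detection(det, pooled, "iPSC", policy))
  extract_signatures(group_p, expressed_threshold, absent_threshold)
}

#' Normalized log2 expression matrix for clustering and heatmaps
#'
#' Background-corrects, quantile-normalizes and log2(x + 1)-transforms a
#' bead-summary experiment. Detection p-values stay on the linear scale;
#' this transform feeds correlation distances, dendrograms and heatmaps.
#'
#' @param bead a `bead_summary` object.
#' @param background logical; apply [background_correct()] first.
#' @return genes x samples matrix of log2 normalized signals.
#' @export
normalized_log2_matrix <- function(bead, background = TRUE) {
  if (background) bead <- background_correct(bead)
  log2(quantile_normalize(bead$signals) + 1)
}

#' Score recovered signatures against planted ground truth
#'
#' @param result a `signature_result`.
#' @param truth the `truth` element of [generate_bead_summary()] output.
#' @return list: `aging_recovery`, `rejuvenation_recovery` (fractions of the
#'   planted genes recovered), `false_positive_rate` (fraction of unplanted
#'   genes appearing in either signature).
#' @export
score_signatures <- function(result, truth) {
  lab <- truth$signature_label
  planted_a <- names(lab)[lab == "aging"]
  planted_r <- names(lab)[lab == "rejuvenation"]
  unplanted <- names(lab)[lab == "none"]
  fp <- length(intersect(unplanted, c(result$aging, result$rejuvenation)))
  list(
    aging_recovery = if (length(planted_a))
      length(intersect(result$aging, planted_a)) / length(planted_a) else NA_real_,
    rejuvenation_recovery = if (length(planted_r))
      length(intersect(result$rejuvenation, planted_r)) / length(planted_r) else NA_real_,
    false_positive_rate = fp / length(unplanted)
  )
}
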