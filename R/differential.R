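#' Per-gene two-group differential test on log2 signals
#'
#' Unmoderated: the classical two-sample pooled-variance t on log2 signals,
#' referred to its exact t distribution with `na + nb - 2` degrees of
#' freedom. Moderated: an empirical-Bayes variant in which each gene's pooled
#' variance is shrunk toward the across-gene mean variance `s0^2` with a
#' fixed prior weight of `d0` degrees of freedom,
#' `s2_tilde = (d0 * s0^2 + df * s2) / (d0 + df)`, and the t statistic is
#' referred to a t distribution with `df + d0` degrees of freedom. Genes with
#' zero pooled variance and zero mean difference report t = 0, p = 1.
#'
#' @param log2_signals genes x samples numeric matrix (log2 scale).
#' @param group_a,group_b character vectors of column names (or integer
#'   indices) for the two groups.
#' @param moderated logical; use the variance-shrinkage test.
#' @param d0 prior degrees of freedom for moderation.
#' @return data.frame with `gene_id`, `mean_a`, `mean_b`, `t_stat`, `p_diff`.
#' @export
differential_test <- function(log2_signals, group_a, group_b,
                              moderated = FALSE, d0 = 4) {
  x <- log2_signals[, group_a, drop = FALSE]
  y <- log2_signals[, group_b, drop = FALSE]
  na <- ncol(x); nb <- ncol(y)
  if (!moderated && (na < 2L || nb < 2L))
    stop("the unmoderated test needs >= 2 samples per group")
  if (moderated && (na < 1L || nb < 1L || na + nb < 3L))
    stop("too few samples for the moderated test")
  ma <- rowMeans(x); mb <- rowMeans(y)
  df <- na + nb - 2L
  ssa <- rowSums((x - ma)^2); ssb <- rowSums((y - mb)^2)
  s2 <- (ssa + ssb) / df
  if (moderated) {
    s0sq <- mean(s2)
    s2use <- (d0 * s0sq + df * s2) / (d0 + df)
    df_t <- df + d0
  } else {
    s2use <- s2
    df_t <- df
  }
  se <- sqrt(s2use * (1 / na + 1 / nb))
  t_stat <- (ma - mb) / se
  t_stat[se == 0 & ma == mb] <- 0
  p <- 2 * stats::pt(-abs(t_stat), df_t)
  p[se == 0 & ma == mb] <- 1
  data.frame(gene_id = rownames(log2_signals), mean_a = ma, mean_b = mb,
             t_stat = t_stat, p_diff = p, row.names = NULL)
}

#' Classical two-tailed unpaired Student's t test
#'
#' Equal-variance two-sample t via [stats::t.test()]. Degenerate inputs
#' (both samples constant) return p = 1 when the constants are equal, with a
#' warning, and t = +/-Inf, p = 0 when they differ.
#'
#' @param x,y numeric vectors, each of length >= 2.
#' @return list with elements `t` and `p`.
#' @export
ttest_two_tailed <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs >= 2 values")
  if (stats::var(x) == 0 && stats::var(y) == 0) {
    if (mean(x) == mean(y)) {
      warning("zero-variance identical samples; returning p = 1")
      return(list(t = 0, p = 1))
    }
    warning("zero-variance samples with different means; returning p = 0")
    return(list(t = sign(mean(x) - mean(y)) * Inf, p = 0))
  }
  tt <- stats::t.test(x, y, var.equal = TRUE)
  list(t = unname(tt$statistic), p = tt$p.value)
}

#' FDR control: Storey q-values (default) or Benjamini-Hochberg
#'
#' Storey's q-value with pi0 estimated by the natural-spline smoother of
#' `pi0(lambda) = #\{p > lambda\} / (m (1 - lambda))` over
#' `lambda = 0.05, 0.10, ..., 0.95`, evaluated at the largest lambda and
#' clipped to (0, 1]; q-values are `pi0` times the Benjamini-Hochberg
#' step-up adjustment, so they are monotone nondecreasing in p and <= 1.
#'
#' @param p p-values in (0, 1].
#' @param method `"qvalue"` (Storey) or `"bh"`.
#' @param lambda grid for pi0 estimation.
#' @return numeric vector of q-values, same order as `p`.
#' @export
fdr_qvalue <- function(p, method = c("qvalue", "bh"),
                       lambda = seq(0.05, 0.95, by = 0.05)) {
  method <- match.arg(method)
  if (length(p) == 0L) stop("empty p-value vector")
  if (any(!is.finite(p)) || any(p <= 0) || any(p > 1))
    stop("p-values must lie in (0, 1]")
  bh <- stats::p.adjust(p, method = "BH")
  if (method == "bh") return(bh)
  pi0 <- estimate_pi0(p, lambda)
  pmin(1, pi0 * bh)
}

#' @rdname fdr_qvalue
#' @export
estimate_pi0 <- function(p, lambda = seq(0.05, 0.95, by = 0.05)) {
  m <- length(p)
  pi0_l <- vapply(lambda, function(l) sum(p > l) / (m * (1 - l)), numeric(1))
  fit <- stats::smooth.spline(lambda, pi0_l, df = 3)
  pi0 <- stats::predict(fit, x = max(lambda))$y
  min(1, max(pi0, .Machine$double.eps))
}

#' Up/down/unchanged call from a linear-scale ratio and a q-value
#'
#' A gene is called `up` when the ratio of linear-scale group means exceeds
#' 1.33 and the q-value passes the significance gate; `down` when the ratio
#' is below 0.75 with the same gate; otherwise `unchanged`. The boundary
#' ratios 1.33 and 0.75 themselves are not up/down (strict inequalities).
#'
#' @param mean_a,mean_b positive linear-scale group means (ratio = a / b).
#' @param q FDR-adjusted p-value.
#' @param q_threshold significance gate (default 0.05; an unadjusted-p 0.01
#'   gate can be emulated by passing raw p-values and `q_threshold = 0.01`).
#' @param ratio_up,ratio_down call boundaries.
#' @return character vector in `up` / `down` / `unchanged` (vectorized).
#' @export
ratio_call <- function(mean_a, mean_b, q, q_threshold = 0.05,
                       ratio_up = 1.33, ratio_down = 0.75) {
  if (any(mean_a <= 0) || any(mean_b <= 0))
    stop("group means must be positive to form a ratio")
  ratio <- mean_a / mean_b
  out <- rep("unchanged", length(ratio))
  sig <- q <= q_threshold
  out[sig & ratio > ratio_up] <- "up"
  out[sig & ratio < ratio_down] <- "down"
  out
}

#' Exclusive Venn partition of 2 or 3 labelled gene sets
#'
#' Returns every one of the 2^k - 1 regions of the Venn diagram as an
#' exclusive membership list (a gene appears in exactly one region), plus
#' region counts. Region names join the containing set labels with `&`.
#'
#' @param sets named list of 2 or 3 character vectors; labels must be unique.
#' @return list with `counts` (named integer vector) and `members`
#'   (named list of character vectors).
#' @export
venn_partition <- function(sets) {
  k <- length(sets)
  if (k < 2L || k > 3L) stop("venn_partition takes 2 or 3 sets")
  labels <- names(sets)
  if (is.null(labels) || anyDuplicated(labels) || any(labels == ""))
    stop("sets must carry unique non-empty labels")
  sets <- lapply(sets, unique)
  all_genes <- unique(unlist(sets))
  inset <- vapply(sets, function(s) all_genes %in% s, logical(length(all_genes)))
  if (length(all_genes) == 1L) inset <- matrix(inset, nrow = 1)
  members <- list()
  for (mask in seq_len(2^k - 1L)) {
    sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1L)))
    region <- paste(labels[sel], collapse = "&")
    inreg <- rowSums(inset[, sel, drop = FALSE]) == sum(sel) &
      rowSums(inset[, !sel, drop = FALSE]) == 0
    members[[region]] <- all_genes[inreg]
  }
  list(counts = vapply(members, length, integer(1)), members = members)
}

#' Relative expression by the 2^-ddCt method
#'
#' `ddCt = (Ct_target,sample - Ct_reference,sample) -
#' (Ct_target,calibrator - Ct_reference,calibrator)`; relative expression is
#' `2^-ddCt`, i.e. one extra cycle of the target in the sample halves it.
#' The reference gene is the housekeeping normalizer (RPL37A in the assays
#' this mirrors).
#'
#' @param ct_target_sample,ct_ref_sample,ct_target_calibrator,ct_ref_calibrator
#'   finite Ct values (vectorized).
#' @return relative expression level(s), positive reals.
#' @export
ddct <- function(ct_target_sample, ct_ref_sample,
                 ct_target_calibrator, ct_ref_calibrator) {
  cts <- c(ct_target_sample, ct_ref_sample, ct_target_calibrator,
           ct_ref_calibrator)
  if (any(!is.finite(cts))) stop("Ct values must be finite")
  dd <- (ct_target_sample - ct_ref_sample) -
    (ct_target_calibrator - ct_ref_calibrator)
  2^(-dd)
}
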