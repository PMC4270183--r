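#' Disbalance statistic for one transcription-factor pair
#'
#' For two rival cell-fate determinants the stem/progenitor state is assumed
#' balanced and differentiation breaks the balance. The statistic is
#' \deqn{D = (g1_{diff} - g2_{diff}) - (g1_{stem} - g2_{stem})}
#' where each term is the log2 median expression of the gene in that region,
#' i.e. the log2 change of the pair's expression ratio upon differentiation,
#' normalized by the stem-state ratio through the second term. D is
#' antisymmetric in the pair and zero when both ratios are equal.
#'
#' @param summary gene-by-region matrix of log2 median expression
#'   ([summarize_to_gene()] with `log2 = TRUE`).
#' @param gene1,gene2 gene ids.
#' @param stem_region,diff_region region (column) names.
#' @return one-row data.frame with the four log2 values and `D`.
#' @export
pair_statistic <- function(summary, gene1, gene2, stem_region, diff_region) {
  for (g in c(gene1, gene2)) {
    for (r in c(stem_region, diff_region)) {
      if (!g %in% rownames(summary) || !r %in% colnames(summary) ||
          !is.finite(summary[g, r])) {
        stop(sprintf("missing expression for gene '%s' in region '%s'", g, r))
      }
    }
  }
  d <- (summary[gene1, diff_region] - summary[gene2, diff_region]) -
       (summary[gene1, stem_region] - summary[gene2, stem_region])
  data.frame(gene1 = gene1, gene2 = gene2,
             g1_stem = summary[gene1, stem_region],
             g2_stem = summary[gene2, stem_region],
             g1_diff = summary[gene1, diff_region],
             g2_diff = summary[gene2, diff_region],
             D = d, stringsAsFactors = FALSE)
}

#' Disbalance statistics for all TF pairs
#'
#' One row per unordered pair, in canonical orientation (gene1 < gene2
#' lexicographically); row count is `n*(n-1)/2`.
#'
#' @inheritParams pair_statistic
#' @param tf_list character vector of transcription-factor gene ids, no
#'   duplicates, all present in `summary`.
#' @return data.frame of [pair_statistic()] rows.
#' @export
all_pair_statistics <- function(summary, tf_list, stem_region, diff_region) {
  if (anyDuplicated(tf_list)) stop("duplicate ids in tf_list")
  if (length(tf_list) < 2L) stop("need at least two TFs")
  missing <- setdiff(tf_list, rownames(summary))
  if (length(missing)) {
    stop(sprintf("TFs absent from expression: %s",
                 paste(missing, collapse = ", ")))
  }
  tfs <- sort(tf_list)
  n <- length(tfs)
  i <- rep(seq_len(n - 1L), times = (n - 1L):1L)
  j <- unlist(lapply(seq_len(n - 1L), function(a) (a + 1L):n))
  g1 <- tfs[i]
  g2 <- tfs[j]
  s1 <- summary[g1, stem_region]
  s2 <- summary[g2, stem_region]
  d1 <- summary[g1, diff_region]
  d2 <- summary[g2, diff_region]
  data.frame(gene1 = g1, gene2 = g2,
             g1_stem = s1, g2_stem = s2, g1_diff = d1, g2_diff = d2,
             D = (d1 - d2) - (s1 - s2),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Robust z-test with symmetric trimming
#'
#' Location and scale are estimated from the central mass after discarding
#' `trim_fraction` of the values on each side; the same linear z transform is
#' then extrapolated to every value, trimmed ones included, so outliers
#' receive large finite z-scores without inflating the scale estimate. The
#' trimmed standard deviation is divided by the normal consistency factor
#' \eqn{\sqrt{1 - 2 c \phi(c) / (2\Phi(c) - 1)}}, \eqn{c = \Phi^{-1}(1 -
#' trim)}, so that under a normal null the z-scores are standard normal and
#' two-sided p-values are calibrated.
#'
#' @param values numeric vector (>= 20 values) of disbalance statistics.
#' @param trim_fraction fraction trimmed on each side, in `[0, 0.25)`.
#' @return data.frame with columns `value`, `z`, `p`; attributes `location`
#'   and `scale`.
#' @export
robust_z_test <- function(values, trim_fraction = 0.025) {
  values <- check_finite_numeric(values, "values")
  n <- length(values)
  if (n < 20L) stop("robust z-test needs at least 20 values")
  if (trim_fraction < 0 || trim_fraction >= 0.25) {
    stop("trim_fraction must be in [0, 0.25)")
  }
  t <- floor(trim_fraction * n)
  core <- sort(values)[(t + 1L):(n - t)]
  location <- mean(core)
  s <- stats::sd(core)
  if (!is.finite(s) || s == 0) stop("zero scale: trimmed core is constant")
  if (t > 0L) {
    a <- t / n
    cq <- stats::qnorm(1 - a)
    s <- s / sqrt(1 - 2 * cq * stats::dnorm(cq) / (2 * stats::pnorm(cq) - 1))
  }
  z <- (values - location) / s
  out <- data.frame(value = values, z = z, p = 2 * stats::pnorm(-abs(z)))
  attr(out, "location") <- location
  attr(out, "scale") <- s
  out
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment (monotone, capped at 1).
#'
#' @param pvalues numeric vector of p-values in `[0, 1]`.
#' @return adjusted p-values.
#' @export
bh_adjust <- function(pvalues) {
  pvalues <- check_finite_numeric(pvalues, "pvalues")
  if (any(pvalues < 0 | pvalues > 1)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Full disbalance test over all TF pairs
#'
#' Convenience composition: [all_pair_statistics()], optional division of D
#' by the absolute stem ratio (`normalization = "ratio"`; the default
#' `"difference"` treats the stem ratio as already subtracted inside D),
#' [robust_z_test()] and [bh_adjust()].
#'
#' @inheritParams all_pair_statistics
#' @param trim_fraction trimming for the robust z-test.
#' @param alpha significance level on the adjusted p-value.
#' @param normalization `"difference"` or `"ratio"`.
#' @param ratio_floor lower bound on `|stem ratio|` when dividing, guarding
#'   near-zero denominators.
#' @return data.frame with D, z, p, p_adj, significant.
#' @export
fate_pair_test <- function(summary, tf_list, stem_region, diff_region,
                           trim_fraction = 0.025, alpha = 0.05,
                           normalization = c("difference", "ratio"),
                           ratio_floor = 0.25) {
  normalization <- match.arg(normalization)
  tab <- all_pair_statistics(summary, tf_list, stem_region, diff_region)
  stat <- tab$D
  if (normalization == "ratio") {
    stat <- tab$D / pmax(abs(tab$g1_stem - tab$g2_stem), ratio_floor)
  }
  zt <- robust_z_test(stat, trim_fraction = trim_fraction)
  tab$z <- zt$z
  tab$p <- zt$p
  tab$p_adj <- bh_adjust(tab$p)
  tab$significant <- tab$p_adj < alpha
  attr(tab, "alpha") <- alpha
  tab
}

#' Filter significant pairs down to cell-fate-determinant candidates
#'
#' Applies the four network-coupled criteria to the significant pairs:
#' \itemize{
#' \item c1: at least one gene of the pair is differentially up-regulated in
#'   the differentiated cell type (quartile call vs the baseline reference,
#'   `QE_diff - QE_base >= qde_threshold`);
#' \item c2: neither gene is differentially down-regulated in the
#'   stem/progenitor cells (`QE_stem - QE_base <= -qde_threshold` fails it);
#' \item c3: both genes belong to the designated SCC and a direct edge links
#'   them (either direction);
#' \item c4: exactly one gene is in the SCC and a direct prior edge links the
#'   pair.
#' }
#' A pair is kept when adjusted p < alpha and c1 AND c2 AND (c3 OR c4). With
#' `use_baseline = FALSE` the c1/c2 calls are made against the stem region
#' instead of the baseline reference (the cross-region reading). Kept pairs
#' are reported with the differentiated-up gene first.
#'
#' @param results table from [fate_pair_test()].
#' @param qe_stem,qe_diff named QE vectors for the stem and differentiated
#'   regions.
#' @param baseline a [baseline_reference()] (required unless
#'   `use_baseline = FALSE`).
#' @param scc designated SCC: an [find_sccs()] result (largest component
#'   used) or a character vector of node ids.
#' @param prior the [prior_network()] used for direct-interaction lookups.
#' @param alpha adjusted-p significance level.
#' @param qde_threshold quartile-difference threshold for up/down calls.
#' @param use_baseline make c1/c2 calls against the baseline reference
#'   (default) or against the stem region.
#' @return data.frame of all significant pairs with criterion flags; kept
#'   candidates have `passes = TRUE`.
#' @export
filter_candidates <- function(results, qe_stem, qe_diff, baseline, scc,
                              prior, alpha = 0.05, qde_threshold = 2L,
                              use_baseline = TRUE) {
  if (inherits(scc, "scc_result")) {
    if (!length(scc$components)) stop("SCC result has no components")
    scc <- scc$components[[1L]]
  }
  if (!length(scc)) stop("designated SCC is empty")
  if (use_baseline && missing(baseline)) stop("baseline reference required")
  sig <- results[results$p_adj < alpha, , drop = FALSE]
  if (!nrow(sig)) {
    out <- cbind(sig, c1_up_in_diff = logical(0), c2_not_down_in_stem =
                 logical(0), c3_both_in_scc_connected = logical(0),
                 c4_one_in_scc_partner_interacts = logical(0),
                 passes = logical(0))
    return(out)
  }
  ref_qe <- if (use_baseline) baseline$quartile else qe_stem
  up_in_diff <- function(g) {
    g %in% names(qe_diff) && g %in% names(ref_qe) &&
      (qe_diff[g] - ref_qe[g]) >= qde_threshold
  }
  down_ref <- if (use_baseline) baseline$quartile else qe_diff
  down_in_stem <- function(g) {
    g %in% names(qe_stem) && g %in% names(down_ref) &&
      (qe_stem[g] - down_ref[g]) <= -qde_threshold
  }
  ekey <- unique(c(paste(prior$edges$source, prior$edges$target, sep = "\r"),
                   paste(prior$edges$target, prior$edges$source, sep = "\r")))
  direct_edge <- function(g1, g2) paste(g1, g2, sep = "\r") %in% ekey

  n <- nrow(sig)
  c1 <- c2 <- c3 <- c4 <- logical(n)
  for (r in seq_len(n)) {
    g1 <- sig$gene1[r]
    g2 <- sig$gene2[r]
    c1[r] <- up_in_diff(g1) || up_in_diff(g2)
    c2[r] <- !down_in_stem(g1) && !down_in_stem(g2)
    in1 <- g1 %in% scc
    in2 <- g2 %in% scc
    linked <- direct_edge(g1, g2)
    c3[r] <- in1 && in2 && linked
    c4[r] <- xor(in1, in2) && linked
  }
  sig$c1_up_in_diff <- c1
  sig$c2_not_down_in_stem <- c2
  sig$c3_both_in_scc_connected <- c3
  sig$c4_one_in_scc_partner_interacts <- c4
  sig$passes <- c1 & c2 & (c3 | c4)
  # orient kept pairs with the differentiated-up gene first
  for (r in which(sig$passes)) {
    if (!up_in_diff(sig$gene1[r]) && up_in_diff(sig$gene2[r])) {
      sig[r, c("gene1", "gene2")] <- sig[r, c("gene2", "gene1")]
      sig[r, c("g1_stem", "g2_stem")] <- sig[r, c("g2_stem", "g1_stem")]
      sig[r, c("g1_diff", "g2_diff")] <- sig[r, c("g2_diff", "g1_diff")]
      sig$D[r] <- -sig$D[r]
      sig$z[r] <- -sig$z[r]
    }
  }
  rownames(sig) <- NULL
  sig
}
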