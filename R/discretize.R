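#' Summarize probe-level expression to gene-by-region medians
#'
#' For every region, each gene's value is the median over replicates of the
#' median over that gene's probes within each sample. Medians (mean-of-middle
#' for even counts) are used throughout for robustness to outlying probes and
#' replicates. Features without a probe-map entry, and genes left with no
#' mapped probe, are dropped and recorded in the `dropped_features` attribute,
#' never imputed.
#'
#' @param expr an [expression_matrix()].
#' @param probemap a [probe_map()]; may map features to themselves when the
#'   matrix is already gene-level.
#' @param sheet a [sample_sheet()] covering the matrix samples.
#' @param log2 apply `log2` to the summarized values (used for the pair
#'   disbalance statistic, which is defined on log2 medians).
#' @return numeric matrix, genes x regions, with attribute `dropped_features`.
#' @export
summarize_to_gene <- function(expr, probemap, sheet, log2 = FALSE) {
  stopifnot(inherits(expr, "expression_matrix"))
  validate_sheet_covers(sheet, expr)
  vals <- expr$values
  idx <- match(rownames(vals), probemap$feature_id)
  dropped <- rownames(vals)[is.na(idx)]
  keep <- !is.na(idx)
  if (!any(keep)) stop("probe map covers none of the matrix features")
  vals <- vals[keep, , drop = FALSE]
  gene <- factor(probemap$gene_id[idx[keep]])

  regions <- unique(sheet$region)
  sheet <- sheet[sheet$sample_id %in% colnames(vals), , drop = FALSE]
  per_sample <- matrix(NA_real_, nlevels(gene), ncol(vals),
                       dimnames = list(levels(gene), colnames(vals)))
  for (j in seq_len(ncol(vals))) {
    per_sample[, j] <- tapply(vals[, j], gene, mid_median)
  }
  out <- matrix(NA_real_, nlevels(gene), length(regions),
                dimnames = list(levels(gene), regions))
  for (r in regions) {
    cols <- sheet$sample_id[sheet$region == r]
    if (!length(cols)) stop(sprintf("region '%s' has zero samples", r))
    out[, r] <- apply(per_sample[, cols, drop = FALSE], 1L, mid_median)
  }
  if (log2) {
    if (any(out <= 0)) stop("log2 summarization requires positive values")
    out <- log2(out)
  }
  msg("summarize_to_gene: %d genes x %d regions (%d features dropped)",
      nrow(out), ncol(out), length(dropped))
  attr(out, "dropped_features") <- dropped
  out
}

#' Equal-frequency quartile expression (EFD)
#'
#' Assigns each gene a quantile bin 1..k (quartile expression, QE, with the
#' default k = 4) by equal-frequency discretization of one region's summarized
#' values. The assignment is rank-based, so it is invariant to any positive
#' rescaling of the region's values — the property that makes quartile
#' profiles comparable across platforms with different absolute scales.
#'
#' Ties are never split across bins: equal values receive equal QE, and among
#' all monotone tie-respecting assignments the one minimizing the total
#' deviation of bin counts from n/k is chosen (ties between optimal
#' assignments are broken towards the lexicographically smallest QE sequence
#' in value order). For tie-free inputs with n divisible by k this yields
#' exactly n/k genes per bin.
#'
#' @param values named numeric vector of one region's summarized expression.
#' @param k number of intervals (default 4).
#' @return named integer vector of bin assignments in `1..k`.
#' @export
quartile_expression <- function(values, k = 4L) {
  k <- as.integer(k)
  if (k < 2L) stop("k must be >= 2")
  values <- stats::setNames(check_finite_numeric(values, "values"),
                            names(values))
  n <- length(values)
  if (n < k) stop(sprintf("need at least k = %d values, got %d", k, n))
  ord <- order(values)
  sorted <- values[ord]
  blocks <- rle(as.vector(sorted))$lengths
  if (length(blocks) < k) {
    stop(sprintf(
      "degenerate distribution: %d distinct values < k = %d intervals",
      length(blocks), k))
  }
  cuts <- efd_cuts(blocks, n, k)
  bins <- rep.int(seq_len(k), diff(c(0L, cuts, n)))
  out <- integer(n)
  out[ord] <- bins
  stats::setNames(out, names(values))
}

# Optimal monotone tie-respecting cut positions.
#
# Boundary positions are cumulative block sizes; the k-1 cuts minimize
# sum |bin size - n/k|, with ties broken by lexicographically maximal cut
# vector (equivalently lexicographically smallest QE sequence). Exactness is
# kept cheap for large n by restricting each cut's candidates to boundaries
# within U of its ideal position j*n/k, where U is the cost of a greedy
# nearest-boundary solution: any optimal cut satisfies |c_j - j*n/k| <= U
# because sum_{b<=j}(size_b - n/k) telescopes to c_j - j*n/k.
efd_cuts <- function(blocks, n, k) {
  q <- n / k
  bounds <- cumsum(blocks)           # positions where a bin may end (block ends)
  inner <- c(0L, bounds)             # a cut may also coincide (empty bin)

  greedy <- vapply(seq_len(k - 1L), function(j) {
    inner[which.min(abs(inner - j * q))]
  }, numeric(1L))
  greedy <- cummax(greedy)
  U <- sum(abs(diff(c(0, greedy, n)) - q))

  cand <- lapply(seq_len(k - 1L), function(j) {
    cj <- inner[abs(inner - j * q) <= U + 1e-9]
    if (!length(cj)) cj <- inner[which.min(abs(inner - j * q))]
    sort(cj)
  })

  levels <- c(cand, list(n))
  # backward DP: G[[j]][i] = min cost of bins (j+1)..k given cut j at levels[[j]][i]
  G <- vector("list", k)
  G[[k]] <- 0
  for (j in rev(seq_len(k - 1L))) {
    nxt <- levels[[j + 1L]]
    cur <- levels[[j]]
    G[[j]] <- vapply(cur, function(p) {
      ok <- nxt >= p
      if (!any(ok)) return(Inf)
      min(abs(nxt[ok] - p - q) + G[[j + 1L]][ok])
    }, numeric(1L))
  }
  total <- min(abs(levels[[1L]] - q) + G[[1L]])
  # forward reconstruction, taking the largest optimal cut at each level
  cuts <- integer(k - 1L)
  prev <- 0
  acc <- 0
  for (j in seq_len(k - 1L)) {
    cur <- levels[[j]]
    ok <- cur >= prev
    cost <- abs(cur - prev - q) + G[[j]]
    cost[!ok] <- Inf
    opt <- which(abs(acc + cost - total) <= 1e-9)
    pick <- opt[length(opt)]
    cuts[j] <- cur[pick]
    acc <- acc + abs(cur[pick] - prev - q)
    prev <- cur[pick]
  }
  cuts
}

#' Quartile profiles for every region
#'
#' Applies [quartile_expression()] column-wise to a gene-by-region summary.
#'
#' @param summary matrix from [summarize_to_gene()].
#' @param k number of intervals.
#' @return integer matrix, genes x regions, entries in `1..k`.
#' @export
qe_profile <- function(summary, k = 4L) {
  out <- vapply(colnames(summary),
                function(r) quartile_expression(summary[, r], k = k),
                integer(nrow(summary)))
  rownames(out) <- rownames(summary)
  out
}

#' Differential quartile expression between two regions
#'
#' QDE = QE(region X) - QE(region Y), computed over the shared gene universe
#' (genes present on only one platform are dropped and reported, never
#' imputed). A gene is called differentially expressed when |QDE| >= threshold;
#' the default +/-2 avoids calls driven by single-boundary quartile flips.
#'
#' @param qe_x,qe_y named integer vectors of QE values (or single columns of a
#'   [qe_profile()] matrix).
#' @param threshold minimal |QDE| called significant (default 2).
#' @return a list with elements `table` (gene_id, qe_x, qe_y, qde,
#'   significant), `n_up_x`, `n_up_y`, `threshold` and `dropped`.
#' @export
differential_qe <- function(qe_x, qe_y, threshold = 2L) {
  genes <- intersect(names(qe_x), names(qe_y))
  if (!length(genes)) stop("empty gene intersection between profiles")
  dropped <- c(setdiff(names(qe_x), genes), setdiff(names(qe_y), genes))
  qde <- as.integer(qe_x[genes]) - as.integer(qe_y[genes])
  sig <- abs(qde) >= threshold
  tab <- data.frame(gene_id = genes,
                    qe_x = as.integer(qe_x[genes]),
                    qe_y = as.integer(qe_y[genes]),
                    qde = qde, significant = sig,
                    stringsAsFactors = FALSE)
  list(table = tab,
       n_up_x = sum(sig & qde > 0L),
       n_up_y = sum(sig & qde < 0L),
       threshold = as.integer(threshold),
       dropped = dropped)
}

#' Distribution characterization per region
#'
#' Sample skewness and kurtosis (raw by default), quartile boundaries, mean
#' and median per region, used to check that the regions' expression
#' distributions are similar enough in shape for rank-based comparison.
#' Given an [expression_matrix()] plus a sample sheet, each region's samples
#' are pooled (the feature-level expression distribution per region, as a
#' violin plot would show it); given a gene-by-region summary matrix, each
#' column is characterized directly.
#'
#' @param summary gene-by-region matrix from [summarize_to_gene()], or an
#'   [expression_matrix()] (then `sheet` is required).
#' @param excess report excess kurtosis instead of raw.
#' @param sheet a [sample_sheet()] when `summary` is an expression matrix.
#' @return data.frame with one row per region.
#' @export
distribution_stats <- function(summary, excess = FALSE, sheet = NULL) {
  if (inherits(summary, "expression_matrix")) {
    if (is.null(sheet)) stop("a sample sheet is required with a matrix")
    vals <- summary$values
    sheet <- sheet[sheet$sample_id %in% colnames(vals), , drop = FALSE]
    regions <- unique(sheet$region)
    pull <- function(r) {
      as.vector(vals[, sheet$sample_id[sheet$region == r], drop = FALSE])
    }
  } else {
    regions <- colnames(summary)
    pull <- function(r) summary[, r]
  }
  rows <- lapply(regions, function(r) {
    x <- pull(r)
    if (length(unique(x)) < 2L) {
      stop(sprintf("region '%s' is constant: moments undefined", r))
    }
    qs <- stats::quantile(x, c(0.25, 0.5, 0.75), names = FALSE)
    data.frame(region = r,
               skewness = sample_skewness(x),
               kurtosis = sample_kurtosis(x, excess = excess),
               kurtosis_type = if (excess) "excess" else "raw",
               q25 = qs[1L], q50 = qs[2L], q75 = qs[3L],
               mean = mean(x), median = stats::median(x),
               stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
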