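#' Load a dataset bundle from files
#'
#' Assembles the same bundle that [generate_dataset()] produces, from
#' delimited files: two expression matrices, a sample sheet, a probe map, a
#' prior network, a baseline reference and a TF list (one id per line).
#'
#' @param paths named list with elements `expr_a`, `expr_b`, `sheet`,
#'   `probemap`, `network`, `baseline`, `tf_list`.
#' @param platform_a,platform_b platform tags for the two matrices.
#' @return dataset bundle (no ground truth).
#' @export
load_dataset <- function(paths, platform_a = "microarray",
                         platform_b = "rnaseq-fpkm") {
  need <- c("expr_a", "expr_b", "sheet", "probemap", "network", "baseline",
            "tf_list")
  missing <- setdiff(need, names(paths))
  if (length(missing)) {
    stop(sprintf("missing dataset paths: %s", paste(missing, collapse = ", ")))
  }
  list(expr_a = read_expression(paths$expr_a, platform = platform_a),
       expr_b = read_expression(paths$expr_b, platform = platform_b),
       sheet = read_sample_sheet(paths$sheet),
       probemap = read_probe_map(paths$probemap),
       baseline = read_baseline(paths$baseline),
       tf_list = readLines(paths$tf_list),
       prior = read_network(paths$network),
       states = NULL, truth = NULL)
}

#' Write a dataset bundle to a directory
#'
#' Emits the standard-format files consumed by [load_dataset()].
#'
#' @param dataset bundle from [generate_dataset()].
#' @param dir output directory (created if needed).
#' @return named vector of written paths, invisibly.
#' @export
write_dataset <- function(dataset, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(dir, f)
  write_expression(dataset$expr_a, p("expression_siteA.tsv"))
  write_expression(dataset$expr_b, p("expression_siteB.tsv"))
  write_result_table(as.data.frame(dataset$sheet), p("sample_sheet.tsv"))
  write_result_table(as.data.frame(dataset$probemap), p("probe_map.tsv"))
  write_result_table(
    data.frame(gene_id = names(dataset$baseline$values),
               value = unname(dataset$baseline$values)),
    p("baseline.tsv"))
  writeLines(dataset$tf_list, p("tf_list.txt"))
  write_network(dataset$prior, p("prior_network.sif"))
  invisible(c(expr_a = p("expression_siteA.tsv"),
              expr_b = p("expression_siteB.tsv"),
              sheet = p("sample_sheet.tsv"), probemap = p("probe_map.tsv"),
              baseline = p("baseline.tsv"), tf_list = p("tf_list.txt"),
              network = p("prior_network.sif")))
}

#' Run the full comparative GRN analysis
#'
#' Fixed stage order: gene-level summarization -> equal-frequency quartile
#' discretization -> cross-site differential calls -> Booleanization of the
#' two stem phenotypes -> per-region contextualization of the prior network
#' -> SCC extraction, master-regulator ranking and cross-network overlap ->
#' per-site cell-fate-determinant pair discovery. Rerunning with the same
#' inputs and seeds reproduces all outputs exactly.
#'
#' @param dataset bundle from [generate_dataset()] or [load_dataset()].
#' @param ga [ga_params()] for contextualization; region B uses `seed + 1`.
#' @param k quantile intervals.
#' @param qde_threshold differential quartile threshold.
#' @param on_threshold Booleanization threshold (QE >= on_threshold is ON).
#' @param alpha adjusted-p significance level for pairs.
#' @param trim_fraction robust z trimming.
#' @param top_k master regulators flagged per SCC.
#' @param out_dir optional directory; when given, all intermediate tables,
#'   networks and a JSON run report are written there.
#' @return a `run_report` list with per-stage summaries and result tables.
#' @export
run_pipeline <- function(dataset, ga = ga_params(), k = 4L,
                         qde_threshold = 2L, on_threshold = 3L,
                         alpha = 0.05, trim_fraction = 0.025, top_k = 3L,
                         out_dir = NULL) {
  # stage 1: summarize (raw scale for discretization, log2 for pairs)
  sheet <- dataset$sheet
  sheet_a <- sheet[sheet$region %in% c("stemA", "diffA"), ]
  sheet_b <- sheet[sheet$region %in% c("stemB", "diffB"), ]
  sum_a <- summarize_to_gene(dataset$expr_a, dataset$probemap, sheet_a)
  sum_b <- summarize_to_gene(dataset$expr_b, dataset$probemap, sheet_b)
  genes <- intersect(rownames(sum_a), rownames(sum_b))
  summary <- cbind(sum_a[genes, , drop = FALSE], sum_b[genes, , drop = FALSE])
  log2_a <- log2(sum_a[genes, , drop = FALSE])
  log2_b <- log2(sum_b[genes, , drop = FALSE])

  # stage 2: discretize and characterize
  qe <- qe_profile(summary, k = k)
  stats_tab <- distribution_stats(summary)
  de <- differential_qe(qe[, "stemA"], qe[, "stemB"],
                        threshold = qde_threshold)

  # stage 3: Booleanize the stem phenotypes over the prior nodes
  prior <- dataset$prior
  state_a <- booleanize(qe[, "stemA"], genes = prior$nodes,
                        on_threshold = on_threshold, label = "stemA")
  state_b <- booleanize(qe[, "stemB"], genes = prior$nodes,
                        on_threshold = on_threshold, label = "stemB")

  # stage 4: per-region contextualization
  ga_b <- ga
  ga_b$seed <- ga$seed + 1L
  ctx_a <- contextualize(prior, list(state_a), params = ga)
  ctx_b <- contextualize(prior, list(state_b), params = ga_b)

  # stage 5: topology
  scc_a <- find_sccs(ctx_a$network)
  scc_b <- find_sccs(ctx_b$network)
  rank_a <- if (length(scc_a$components)) {
    out_degree_interface(scc_a$components[[1L]], ctx_a$network, top_k = top_k)
  }
  rank_b <- if (length(scc_b$components)) {
    out_degree_interface(scc_b$components[[1L]], ctx_b$network, top_k = top_k)
  }
  overlap <- if (length(scc_a$components) && length(scc_b$components)) {
    compare_sccs(scc_a, scc_b, state_a, state_b)
  }

  # stage 6: cell-fate-determinant pairs per site
  tfs <- intersect(dataset$tf_list, genes)
  pairs_a <- fate_pair_test(log2_a, tfs, "stemA", "diffA",
                            trim_fraction = trim_fraction, alpha = alpha)
  pairs_b <- fate_pair_test(log2_b, tfs, "stemB", "diffB",
                            trim_fraction = trim_fraction, alpha = alpha)
  cand_a <- filter_candidates(pairs_a, qe[, "stemA"], qe[, "diffA"],
                              dataset$baseline, scc_a, prior, alpha = alpha,
                              qde_threshold = qde_threshold)
  cand_b <- filter_candidates(pairs_b, qe[, "stemB"], qe[, "diffB"],
                              dataset$baseline, scc_b, prior, alpha = alpha,
                              qde_threshold = qde_threshold)

  report <- list(
    parameters = list(k = k, qde_threshold = qde_threshold,
                      on_threshold = on_threshold, alpha = alpha,
                      trim_fraction = trim_fraction, top_k = top_k,
                      ga = unclass(ga)),
    version = as.character(utils::packageVersion("nicheGRN")),
    n_genes = length(genes),
    distribution_stats = stats_tab,
    differential = list(n_significant = sum(de$table$significant),
                        n_up_stemA = de$n_up_x, n_up_stemB = de$n_up_y),
    consistency = list(stemA = ctx_a$report$overall,
                       stemB = ctx_b$report$overall),
    edges_removed = list(stemA = ctx_a$report$edges_removed,
                         stemB = ctx_b$report$edges_removed),
    scc = list(
      sizes_a = lengths(scc_a$components),
      sizes_b = lengths(scc_b$components),
      shared = if (!is.null(overlap)) nrow(overlap$shared) else 0L,
      unique_a = if (!is.null(overlap)) length(overlap$unique_a) else 0L,
      unique_b = if (!is.null(overlap)) length(overlap$unique_b) else 0L),
    candidates = list(n_a = sum(cand_a$passes), n_b = sum(cand_b$passes)))
  out <- list(report = report, summary = summary, qe = qe, de = de,
              states = list(stemA = state_a, stemB = state_b),
              ctx_a = ctx_a, ctx_b = ctx_b,
              scc_a = scc_a, scc_b = scc_b,
              rank_a = rank_a, rank_b = rank_b, overlap = overlap,
              pairs_a = pairs_a, pairs_b = pairs_b,
              cand_a = cand_a, cand_b = cand_b)
  class(out) <- "run_report"

  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    p <- function(f) file.path(out_dir, f)
    write_result_table(data.frame(gene_id = rownames(qe), qe), p("qe.tsv"))
    write_result_table(de$table, p("differential.tsv"))
    write_result_table(stats_tab, p("distribution_stats.tsv"))
    write_network(ctx_a$network, p("network_stemA.sif"))
    write_network(ctx_b$network, p("network_stemB.sif"))
    if (!is.null(rank_a)) write_result_table(rank_a, p("ranking_stemA.tsv"))
    if (!is.null(rank_b)) write_result_table(rank_b, p("ranking_stemB.tsv"))
    if (!is.null(overlap)) {
      write_result_table(overlap$shared, p("scc_overlap.tsv"))
    }
    write_result_table(pairs_a, p("pairs_siteA.tsv"))
    write_result_table(pairs_b, p("pairs_siteB.tsv"))
    if (nrow(cand_a)) write_result_table(cand_a, p("candidates_siteA.tsv"))
    if (nrow(cand_b)) write_result_table(cand_b, p("candidates_siteB.tsv"))
    jsonlite::write_json(report, p("run_report.json"), auto_unbox = TRUE,
                         digits = NA, pretty = TRUE, force = TRUE)
  }
  out
}

#' @export
print.run_report <- function(x, ...) {
  r <- x$report
  cat("Comparative GRN analysis run\n")
  cat(sprintf("  genes analysed:          %d\n", r$n_genes))
  cat(sprintf("  differential (|QDE|>=%d): %d (%d up in stemA, %d up in stemB)\n",
              r$parameters$qde_threshold, r$differential$n_significant,
              r$differential$n_up_stemA, r$differential$n_up_stemB))
  cat(sprintf("  consistency stemA/stemB: %.3f / %.3f\n",
              r$consistency$stemA, r$consistency$stemB))
  cat(sprintf("  SCC sizes A: %s | B: %s | shared %d (A-only %d, B-only %d)\n",
              paste(r$scc$sizes_a, collapse = ","),
              paste(r$scc$sizes_b, collapse = ","),
              r$scc$shared, r$scc$unique_a, r$scc$unique_b))
  cat(sprintf("  candidate pairs A/B:     %d / %d\n",
              r$candidates$n_a, r$candidates$n_b))
  invisible(x)
}
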