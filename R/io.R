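#' Expression matrix container
#'
#' Features (probes or genes) in rows, samples in columns. Values must be
#' finite reals on whatever scale the platform delivers (log-intensity-like
#' for microarray, FPKM-like for RNA-seq); the pipeline only ever compares
#' values within one region, so absolute scales never mix.
#'
#' @param values numeric matrix with feature row names and sample column names.
#' @param platform free-text platform tag (e.g. `"microarray"`, `"rnaseq-fpkm"`).
#' @return an `expression_matrix` object.
#' @export
expression_matrix <- function(values, platform = "unspecified") {
  if (!is.matrix(values) || !is.numeric(values)) {
    stop("values must be a numeric matrix")
  }
  if (is.null(rownames(values)) || is.null(colnames(values))) {
    stop("values must carry feature row names and sample column names")
  }
  if (anyDuplicated(rownames(values))) {
    dups <- unique(rownames(values)[duplicated(rownames(values))])
    stop(sprintf("duplicated feature ids: %s", paste(dups, collapse = ", ")))
  }
  if (anyDuplicated(colnames(values))) {
    stop("duplicated sample ids")
  }
  if (anyNA(values) || any(!is.finite(values))) {
    bad <- which(!is.finite(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("non-finite value at feature '%s', sample '%s'",
                 rownames(values)[bad[1L]], colnames(values)[bad[2L]]))
  }
  structure(list(values = values, platform = platform),
            class = "expression_matrix")
}

#' @export
print.expression_matrix <- function(x, ...) {
  cat(sprintf("<expression_matrix> %d features x %d samples (platform: %s)\n",
              nrow(x$values), ncol(x$values), x$platform))
  invisible(x)
}

#' Read a delimited expression matrix
#'
#' Expects a header row of sample ids and one row per feature, first column
#' the feature id. Malformed cells are rejected, never coerced: any
#' non-numeric cell (including literal `NA`) is a parse error naming the cell.
#'
#' @param path file path.
#' @param sep field delimiter; tab by default, `","` accepted.
#' @param features_in_rows if `FALSE` the file is transposed on read.
#' @param platform platform tag stored on the result.
#' @return an [expression_matrix()].
#' @export
read_expression <- function(path, sep = "\t", features_in_rows = TRUE,
                            platform = "unspecified") {
  raw <- utils::read.table(path, sep = sep, header = TRUE,
                           colClasses = "character", check.names = FALSE,
                           quote = "", comment.char = "")
  if (nrow(raw) == 0L) stop("no features: file has a header row only")
  feature_ids <- raw[[1L]]
  if (anyDuplicated(feature_ids)) {
    dups <- unique(feature_ids[duplicated(feature_ids)])
    stop(sprintf("duplicated feature ids: %s", paste(dups, collapse = ", ")))
  }
  cells <- as.matrix(raw[, -1L, drop = FALSE])
  values <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(values)) {
    bad <- which(is.na(values), arr.ind = TRUE)[1L, ]
    stop(sprintf("cannot parse value '%s' at feature '%s', column '%s'",
                 cells[bad[1L], bad[2L]], feature_ids[bad[1L]],
                 colnames(cells)[bad[2L]]))
  }
  dimnames(values) <- list(feature_ids, colnames(cells))
  if (!features_in_rows) values <- t(values)
  out <- expression_matrix(values, platform = platform)
  msg("read_expression: %d features, %d samples from %s",
      nrow(out$values), ncol(out$values), path)
  out
}

#' Write an expression matrix as TSV
#' @param expr an [expression_matrix()].
#' @param path output path.
#' @param sep field delimiter.
#' @return `path`, invisibly.
#' @export
write_expression <- function(expr, path, sep = "\t") {
  stopifnot(inherits(expr, "expression_matrix"))
  df <- data.frame(feature_id = rownames(expr$values), expr$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Sample sheet constructor / validator
#'
#' Assigns every sample to a region (e.g. stem vs differentiated at two
#' anatomical sites) with a replicate index.
#'
#' @param sample_id,region,replicate equal-length vectors.
#' @return a `data.frame` with class `sample_sheet`.
#' @export
sample_sheet <- function(sample_id, region, replicate) {
  sheet <- data.frame(sample_id = as.character(sample_id),
                      region = as.character(region),
                      replicate = as.integer(replicate),
                      stringsAsFactors = FALSE)
  if (anyDuplicated(sheet$sample_id)) stop("duplicated sample ids in sheet")
  if (any(sheet$replicate < 1L)) stop("replicate indices must be >= 1")
  class(sheet) <- c("sample_sheet", "data.frame")
  sheet
}

#' Read a sample sheet (TSV with columns sample_id, region, replicate)
#' @param path file path.
#' @param sep field delimiter.
#' @return a [sample_sheet()].
#' @export
read_sample_sheet <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "")
  need <- c("sample_id", "region", "replicate")
  if (!all(need %in% names(df))) {
    stop(sprintf("sample sheet must have columns: %s",
                 paste(need, collapse = ", ")))
  }
  sample_sheet(df$sample_id, df$region, as.integer(df$replicate))
}

#' @export
#' @rdname sample_sheet
#' @param sheet a sample sheet.
#' @param expr an expression matrix the sheet must cover.
validate_sheet_covers <- function(sheet, expr) {
  missing <- setdiff(colnames(expr$values), sheet$sample_id)
  if (length(missing)) {
    stop(sprintf("samples absent from sheet: %s",
                 paste(missing, collapse = ", ")))
  }
  invisible(TRUE)
}

#' Probe-to-gene map
#'
#' Many-to-one map from platform feature ids (probes) to gene ids. Gene ids
#' are opaque case-sensitive strings; no alias resolution is attempted.
#'
#' @param feature_id,gene_id equal-length character vectors.
#' @return a `data.frame` with class `probe_map`.
#' @export
probe_map <- function(feature_id, gene_id) {
  pm <- data.frame(feature_id = as.character(feature_id),
                   gene_id = as.character(gene_id),
                   stringsAsFactors = FALSE)
  if (anyDuplicated(pm$feature_id)) stop("feature ids mapped more than once")
  class(pm) <- c("probe_map", "data.frame")
  pm
}

#' Read a probe map (TSV with columns feature_id, gene_id)
#' @param path file path.
#' @param sep field delimiter.
#' @return a [probe_map()].
#' @export
read_probe_map <- function(path, sep = "\t") {
  df <- utils::read.table(path, sep = sep, header = TRUE,
                          colClasses = "character", quote = "")
  if (!all(c("feature_id", "gene_id") %in% names(df))) {
    stop("probe map must have columns feature_id, gene_id")
  }
  probe_map(df$feature_id, df$gene_id)
}

#' Baseline (basal) expression reference
#'
#' Per-gene basal expression (median over a reference panel) together with its
#' own equal-frequency quartile assignment, used to call over/under-expression
#' when filtering candidate pairs.
#'
#' @param values named numeric vector, gene id -> basal value.
#' @param k number of quantile intervals for the reference's own discretization.
#' @return a `baseline_reference` with elements `values` and `quartile`.
#' @export
baseline_reference <- function(values, k = 4L) {
  if (is.null(names(values))) stop("baseline values must be named by gene id")
  values <- stats::setNames(check_finite_numeric(values, "baseline values"),
                            names(values))
  structure(list(values = values,
                 quartile = quartile_expression(values, k = k)),
            class = "baseline_reference")
}

#' Read a baseline reference (TSV with columns gene_id, value)
#' @param path file path.
#' @param sep field delimiter.
#' @param k number of quantile intervals.
#' @return a [baseline_reference()].
#' @export
read_baseline <- function(path, sep = "\t", k = 4L) {
  df <- utils::read.table(path, sep = sep, header = TRUE, quote = "",
                          colClasses = c("character", "numeric"))
  if (!all(c("gene_id", "value") %in% names(df))) {
    stop("baseline must have columns gene_id, value")
  }
  baseline_reference(stats::setNames(df$value, df$gene_id), k = k)
}

## ---- networks ---------------------------------------------------------------

GRN_TYPES <- c("transcription_regulation", "binding")
GRN_SIGNS <- c("activation", "inhibition", "unassigned")

#' Prior signed directed interaction network
#'
#' Edges carry an interaction type (transcription regulation or binding) and a
#' sign (activation, inhibition, or unassigned when the literature does not
#' state one). Duplicate edges per (source, target, type) collapse to one;
#' a duplicate with two contradictory fixed signs is an error.
#'
#' @param edges data.frame with columns source, target, type, sign.
#' @param nodes optional character vector of node ids; defaults to the union
#'   of edge endpoints. Extra isolated nodes are allowed.
#' @return a `grn` object with elements `edges` and `nodes`.
#' @export
prior_network <- function(edges, nodes = NULL) {
  edges <- as.data.frame(edges, stringsAsFactors = FALSE)
  need <- c("source", "target", "type", "sign")
  if (!all(need %in% names(edges))) {
    stop(sprintf("edges must have columns: %s", paste(need, collapse = ", ")))
  }
  edges <- edges[need]
  for (cl in need) edges[[cl]] <- as.character(edges[[cl]])
  bad_type <- setdiff(unique(edges$type), GRN_TYPES)
  if (length(bad_type)) {
    stop(sprintf("unknown interaction type(s): %s (kept types: %s)",
                 paste(bad_type, collapse = ", "),
                 paste(GRN_TYPES, collapse = ", ")))
  }
  edges$sign[!edges$sign %in% GRN_SIGNS] <- "unassigned"
  key <- paste(edges$source, edges$target, edges$type, sep = "\r")
  contradict <- vapply(split(edges$sign, key), function(s) {
    fixed <- unique(s[s != "unassigned"])
    length(fixed) > 1L
  }, logical(1L))
  if (any(contradict)) {
    stop(sprintf("contradictory duplicate edge(s): %s",
                 paste(gsub("\r", "->", names(contradict)[contradict]),
                       collapse = "; ")))
  }
  # collapse duplicates; a fixed sign wins over unassigned
  ord <- order(key, match(edges$sign, GRN_SIGNS))
  edges <- edges[ord, , drop = FALSE]
  edges <- edges[!duplicated(key[ord]), , drop = FALSE]
  rownames(edges) <- NULL
  all_nodes <- sort(unique(c(edges$source, edges$target, nodes)))
  structure(list(edges = edges, nodes = all_nodes), class = "grn")
}

#' @export
print.grn <- function(x, ...) {
  cat(sprintf("<%s> %d nodes, %d edges (%d unassigned sign)\n",
              class(x)[1L], length(x$nodes), nrow(x$edges),
              sum(x$edges$sign == "unassigned")))
  invisible(x)
}

#' Read a prior network from a SIF-like signed edge list
#'
#' Each line holds four whitespace- or tab-separated fields:
#' `source interaction_type sign target`. Only the interaction types
#' `transcription_regulation` and `binding` are kept as in the source
#' knowledge-base extraction; any other type is an error. An unknown sign
#' token maps to `unassigned`.
#'
#' @param path file path.
#' @return a [prior_network()].
#' @export
read_network <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) {
    return(prior_network(data.frame(source = character(), target = character(),
                                    type = character(), sign = character())))
  }
  fields <- strsplit(trimws(lines), "[ \t]+")
  nf <- lengths(fields)
  if (any(nf < 4L)) {
    stop(sprintf("line %d: expected 4 fields (source type sign target), got %d",
                 which(nf < 4L)[1L], nf[which(nf < 4L)[1L]]))
  }
  m <- do.call(rbind, fields)
  prior_network(data.frame(source = m[, 1L], type = m[, 2L], sign = m[, 3L],
                           target = m[, 4L], stringsAsFactors = FALSE))
}

#' Write a network as signed SIF or GraphML
#'
#' SIF-signed is the package's canonical 4-column dialect (round-trips through
#' [read_network()]); GraphML is provided for viewers such as Cytoscape.
#' A contextualized network must carry fully assigned signs; writing one with
#' residual `unassigned` edges is an error.
#'
#' @param net a `grn` (prior or contextualized).
#' @param path output path.
#' @param dialect `"sif-signed"` or `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("sif-signed", "graphml")) {
  stopifnot(inherits(net, "grn"))
  dialect <- match.arg(dialect)
  if (inherits(net, "contextualized_grn") &&
      any(net$edges$sign == "unassigned")) {
    stop("contextualized networks must have fully assigned signs")
  }
  if (dialect == "sif-signed") {
    con <- file(path, "w")
    on.exit(close(con))
    if (nrow(net$edges)) {
      writeLines(paste(net$edges$source, net$edges$type, net$edges$sign,
                       net$edges$target, sep = "\t"), con)
    }
  } else {
    g <- as_igraph(net)
    igraph::write_graph(g, path, format = "graphml")
  }
  invisible(path)
}

#' Convert a grn to an igraph object (edge attributes type, sign)
#' @param net a `grn`.
#' @return an igraph graph.
#' @export
as_igraph <- function(net) {
  stopifnot(inherits(net, "grn"))
  igraph::graph_from_data_frame(
    d = data.frame(from = net$edges$source, to = net$edges$target,
                   type = net$edges$type, sign = net$edges$sign,
                   stringsAsFactors = FALSE),
    directed = TRUE,
    vertices = data.frame(name = net$nodes, stringsAsFactors = FALSE))
}

#' Write a result table as TSV
#' @param df data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_result_table <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#' @param path file path.
#' @return data.frame.
#' @export
read_result_table <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, quote = "",
                    stringsAsFactors = FALSE)
}
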