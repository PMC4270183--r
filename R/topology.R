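#' Strongly connected components of a contextualized network
#'
#' SCCs are the network's stability motifs: maximal node sets with directed
#' paths both ways between every pair, the structures able to sustain a
#' cellular identity programme. Components of size 1 are excluded by default
#' (a singleton, even with a self-loop, is not treated as a stability motif);
#' set `include_singletons = TRUE` to keep them.
#'
#' @param net a `grn`.
#' @param include_singletons keep size-1 components.
#' @return list with `components` (list of node-id vectors, largest first),
#'   `membership` (named integer; NA for nodes outside reported components)
#'   and `degrees` (per reported node, within-SCC in/out degree).
#' @export
find_sccs <- function(net, include_singletons = FALSE) {
  stopifnot(inherits(net, "grn"))
  if (!length(net$nodes)) stop("network is empty")
  g <- as_igraph(net)
  comp <- igraph::components(g, mode = "strong")
  sizes <- comp$csize
  keep_ids <- which(sizes >= if (include_singletons) 1L else 2L)
  components <- lapply(keep_ids, function(id) {
    sort(names(comp$membership)[comp$membership == id])
  })
  components <- components[order(-lengths(components),
                                 vapply(components, `[`, character(1L), 1L))]
  membership <- rep(NA_integer_, length(net$nodes))
  names(membership) <- net$nodes
  for (i in seq_along(components)) membership[components[[i]]] <- i
  degrees <- NULL
  if (length(components)) {
    rows <- lapply(seq_along(components), function(i) {
      nodes <- components[[i]]
      e <- net$edges[net$edges$source %in% nodes &
                     net$edges$target %in% nodes, , drop = FALSE]
      data.frame(gene_id = nodes, component = i,
                 in_degree = as.integer(table(factor(e$target,
                                                     levels = nodes))),
                 out_degree = as.integer(table(factor(e$source,
                                                      levels = nodes))),
                 stringsAsFactors = FALSE)
    })
    degrees <- do.call(rbind, rows)
  }
  structure(list(components = components, membership = membership,
                 degrees = degrees, n_nodes = length(net$nodes)),
            class = "scc_result")
}

#' Out-degree-interface ranking of master-regulator candidates
#'
#' Within an SCC, the out-degree interface of a gene is its number of
#' outgoing edges to other members of the same SCC (self-loops included) —
#' genes with many within-motif outgoing edges exert the broadest regulatory
#' influence on the stability motif. The top `top_k` are flagged as
#' master-regulator candidates; ties are broken lexicographically by gene id
#' for determinism.
#'
#' @param scc character vector of the component's node ids (must be one
#'   strongly connected component of `net`).
#' @param net the `grn` the component belongs to.
#' @param top_k how many top-ranked genes to flag (default 3).
#' @return data.frame sorted by decreasing out-degree interface with columns
#'   gene_id, out_degree_interface, in_degree, master_regulator.
#' @export
out_degree_interface <- function(scc, net, top_k = 3L) {
  stopifnot(inherits(net, "grn"))
  scc <- sort(unique(scc))
  if (length(scc) > 1L) {
    sub <- igraph::induced_subgraph(as_igraph(net), scc)
    if (igraph::components(sub, mode = "strong")$no != 1L) {
      stop("node set is not a strongly connected component of the network")
    }
  }
  e <- net$edges[net$edges$source %in% scc & net$edges$target %in% scc, ,
                 drop = FALSE]
  outd <- as.integer(table(factor(e$source, levels = scc)))
  ind <- as.integer(table(factor(e$target, levels = scc)))
  ord <- order(-outd, scc)
  rank <- data.frame(gene_id = scc[ord],
                     out_degree_interface = outd[ord],
                     in_degree = ind[ord],
                     master_regulator = seq_along(scc) <= top_k,
                     stringsAsFactors = FALSE)
  rownames(rank) <- NULL
  rank
}

#' Compare the designated SCCs of two contextualized networks
#'
#' Set algebra over the two components (largest by default) plus per-gene
#' Boolean-state agreement: a shared gene "agrees" when both networks predict
#' the same ON/OFF state for it.
#'
#' @param scc_a,scc_b [find_sccs()] results (or plain node-id vectors).
#' @param state_a,state_b [boolean_state()] objects giving each network's
#'   predicted gene states.
#' @param component_a,component_b which component to compare (default 1 =
#'   largest).
#' @return list with `shared` (data.frame gene_id, state_a, state_b, agree),
#'   `unique_a`, `unique_b`, and per-network counts of ON/OFF genes in the
#'   designated SCC.
#' @export
compare_sccs <- function(scc_a, scc_b, state_a, state_b,
                         component_a = 1L, component_b = 1L) {
  pick <- function(x, i) {
    if (inherits(x, "scc_result")) {
      if (i > length(x$components)) stop("no such component")
      x$components[[i]]
    } else as.character(x)
  }
  a <- pick(scc_a, component_a)
  b <- pick(scc_b, component_b)
  shared_genes <- sort(intersect(a, b))
  shared <- data.frame(gene_id = shared_genes,
                       state_a = as.integer(state_a[shared_genes]),
                       state_b = as.integer(state_b[shared_genes]),
                       stringsAsFactors = FALSE)
  shared$agree <- shared$state_a == shared$state_b
  list(shared = shared,
       unique_a = sort(setdiff(a, b)),
       unique_b = sort(setdiff(b, a)),
       counts = data.frame(
         network = c("A", "B"),
         scc_size = c(length(a), length(b)),
         n_on = c(sum(state_a[a] == 1L), sum(state_b[b] == 1L)),
         n_off = c(sum(state_a[a] == 0L), sum(state_b[b] == 0L)),
         stringsAsFactors = FALSE))
}
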