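# Independent brute-force oracles used to cross-check the implementation.
# These deliberately re-derive every rule naively (loops, enumeration) and
# share no code with the package internals.

# --- majority rule, one gene at a time ---------------------------------------

naive_update <- function(s, edges, nodes, no_input = "hold") {
  out <- integer(length(nodes))
  names(out) <- nodes
  for (g in nodes) {
    inc <- edges[edges$target == g, , drop = FALSE]
    a <- sum(inc$sign == "activation" & s[inc$source] == 1)
    i <- sum(inc$sign == "inhibition" & s[inc$source] == 1)
    out[[g]] <- if (a > i) 1L else if (a + i == 0L) {
      if (no_input == "hold") s[[g]] else 0L
    } else 0L
  }
  out
}

naive_consistency <- function(edges, nodes, states, no_input = "hold") {
  mean(sapply(states, function(s) {
    mean(naive_update(s, edges, nodes, no_input) == s[nodes])
  }))
}

# --- contextualization fitness by exhaustive enumeration ---------------------

naive_fitness <- function(prior, states, keep, signs_u, lambda = 0.1) {
  e <- prior$edges
  u <- which(e$sign == "unassigned")
  if (length(u)) {
    e$sign[u] <- ifelse(signs_u == 1, "activation", "inhibition")
  }
  e <- e[keep == 1, , drop = FALSE]
  naive_consistency(e, prior$nodes, states) -
    lambda * sum(keep == 0) / nrow(prior$edges)
}

exhaustive_best_fitness <- function(prior, states, lambda = 0.1) {
  E <- nrow(prior$edges)
  U <- sum(prior$edges$sign == "unassigned")
  L <- E + U
  best <- -Inf
  for (code in 0:(2^L - 1)) {
    bits <- as.integer(intToBits(code))[seq_len(L)]
    f <- naive_fitness(prior, states, bits[seq_len(E)],
                       if (U) bits[(E + 1):L] else integer(0), lambda)
    if (f > best) best <- f
  }
  best
}

# --- random small instances for the optimality checks ------------------------

random_prior_instance <- function(seed, max_edges = 12L, max_unassigned = 2L) {
  set.seed(seed)
  n <- sample(4:7, 1)
  nodes <- paste0("n", seq_len(n))
  ne <- sample(6:max_edges, 1)
  repeat {
    src <- sample(nodes, ne, replace = TRUE)
    tgt <- sample(nodes, ne, replace = TRUE)
    if (!anyDuplicated(paste(src, tgt))) break
  }
  sign <- sample(c("activation", "inhibition"), ne, replace = TRUE)
  nu <- sample(0:max_unassigned, 1)
  if (nu) sign[sample(ne, nu)] <- "unassigned"
  prior <- prior_network(
    data.frame(source = src, target = tgt,
               type = "transcription_regulation", sign = sign,
               stringsAsFactors = FALSE),
    nodes = nodes)
  states <- lapply(1:2, function(i) {
    boolean_state(stats::setNames(sample(0:1, n, replace = TRUE), nodes),
                  label = paste0("s", i))
  })
  list(prior = prior, states = states)
}

# --- EFD minimal-deviation assignment by enumeration -------------------------

# Enumerates every monotone, tie-respecting assignment of the sorted values'
# tie blocks to bins 1..k (bins may stay empty), scores each by the total
# deviation of bin counts from n/k, and returns the minimizer; ties between
# minimizers break towards the lexicographically smallest QE sequence.
oracle_efd <- function(values, k = 4L) {
  n <- length(values)
  ord <- order(values)
  blocks <- rle(as.vector(values[ord]))$lengths
  m <- length(blocks)
  q <- n / k
  best_cost <- Inf
  best_seq <- NULL
  lex_less <- function(a, b) {
    d <- which(a != b)
    length(d) > 0 && a[d[1L]] < b[d[1L]]
  }
  assign_rec <- function(b, bin, counts) {
    if (b > m) {
      cost <- sum(abs(counts - q))
      seq_full <- rep.int(seq_len(k), counts)
      if (cost < best_cost - 1e-9 ||
          (abs(cost - best_cost) <= 1e-9 && lex_less(seq_full, best_seq))) {
        best_cost <<- cost
        best_seq <<- seq_full
      }
      return(invisible(NULL))
    }
    for (nb in bin:k) {
      counts2 <- counts
      counts2[nb] <- counts2[nb] + blocks[b]
      assign_rec(b + 1L, nb, counts2)
    }
  }
  assign_rec(1L, 1L, integer(k))
  out <- integer(n)
  out[ord] <- best_seq
  stats::setNames(out, names(values))
}

# --- strongly connected components via transitive closure --------------------

oracle_sccs <- function(edges, nodes, min_size = 2L) {
  n <- length(nodes)
  reach <- diag(TRUE, n)
  dimnames(reach) <- list(nodes, nodes)
  for (r in seq_len(nrow(edges))) {
    reach[edges$source[r], edges$target[r]] <- TRUE
  }
  for (k in seq_len(n)) {
    for (i in seq_len(n)) {
      if (reach[i, k]) reach[i, ] <- reach[i, ] | reach[k, ]
    }
  }
  mutual <- reach & t(reach)
  seen <- rep(FALSE, n)
  comps <- list()
  for (i in seq_len(n)) {
    if (!seen[i]) {
      members <- which(mutual[i, ])
      seen[members] <- TRUE
      if (length(members) >= min_size) {
        comps[[length(comps) + 1L]] <- sort(nodes[members])
      }
    }
  }
  comps[order(-lengths(comps),
              vapply(comps, `[`, character(1L), 1L))]
}

random_digraph <- function(seed, max_nodes = 12L) {
  set.seed(seed)
  n <- sample(2:max_nodes, 1)
  nodes <- paste0("v", seq_len(n))
  p <- stats::runif(1, 0.08, 0.35)
  adj <- matrix(stats::runif(n * n) < p, n, n)
  diag(adj) <- FALSE
  idx <- which(adj, arr.ind = TRUE)
  edges <- data.frame(source = nodes[idx[, 1L]], target = nodes[idx[, 2L]],
                      type = rep("transcription_regulation", nrow(idx)),
                      sign = rep("activation", nrow(idx)),
                      stringsAsFactors = FALSE)
  list(net = prior_network(edges, nodes = nodes), edges = edges,
       nodes = nodes)
}
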