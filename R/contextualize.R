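#' Genetic-algorithm parameters for network contextualization
#'
#' The chromosome holds one keep/remove bit per prior edge plus one sign bit
#' per unassigned edge. Fitness is the mean fixed-point consistency across the
#' observed states minus `lambda` times the fraction of edges removed, so a
#' strictly positive `lambda` makes a fully consistent prior its own unique
#' optimum (parsimony: remove no more than the data demand).
#'
#' @param population population size.
#' @param generations number of generations.
#' @param crossover per-couple uniform-crossover probability.
#' @param mutation per-bit mutation probability; default `1/chromosome length`.
#' @param elitism number of best individuals copied unchanged.
#' @param lambda removal-penalty weight per fraction of removed edges.
#' @param seed integer random seed; recorded in every output.
#' @return a `ga_params` list.
#' @export
ga_params <- function(population = 200L, generations = 500L, crossover = 0.8,
                      mutation = NULL, elitism = 2L, lambda = 0.1,
                      seed = 1L) {
  if (population <= 0L || generations <= 0L) {
    stop("population and generations must be positive")
  }
  if (elitism < 0L || elitism >= population) stop("invalid elitism count")
  if (lambda < 0) stop("lambda must be non-negative")
  structure(list(population = as.integer(population),
                 generations = as.integer(generations),
                 crossover = crossover, mutation = mutation,
                 elitism = as.integer(elitism), lambda = lambda,
                 seed = as.integer(seed)),
            class = "ga_params")
}

# Precomputed machinery for vectorized fitness of a population.
# States are stacked; consistency is averaged across them.
fitness_env <- function(prior, states, no_input = "hold") {
  nodes <- prior$nodes
  n <- length(nodes)
  e <- prior$edges
  E <- nrow(e)
  src <- match(e$source, nodes)
  tgt <- match(e$target, nodes)
  sgn <- c(activation = 1L, inhibition = -1L, unassigned = 0L)[e$sign]
  u_idx <- which(sgn == 0L)
  inc <- function(rows) {            # n x |rows| target-incidence matrix
    m <- matrix(0, n, length(rows))
    if (length(rows)) m[cbind(tgt[rows], seq_along(rows))] <- 1
    m
  }
  Tact <- inc(which(sgn > 0L))
  Tinh <- inc(which(sgn < 0L))
  Tun <- inc(u_idx)
  svecs <- lapply(states, function(s) {
    missing <- setdiff(nodes, names(s))
    if (length(missing)) {
      stop(sprintf("state does not cover nodes: %s",
                   paste(missing, collapse = ", ")))
    }
    as.integer(s[nodes])
  })
  list(nodes = nodes, n = n, E = E, src = src, tgt = tgt, sgn = sgn,
       u_idx = u_idx, L = E + length(u_idx),
       Tact = Tact, Tinh = Tinh, Tun = Tun, svecs = svecs,
       no_input = no_input)
}

# pop: L x P matrix of bits. Returns list(fitness, consistency) per column.
population_fitness <- function(fe, pop, lambda) {
  P <- ncol(pop)
  keep <- pop[seq_len(fe$E), , drop = FALSE]
  sbits <- pop[-seq_len(fe$E), , drop = FALSE]   # 0 rows when no unassigned
  cons <- numeric(P)
  for (s in fe$svecs) {
    src_on <- s[fe$src]
    w <- keep * src_on                      # E x P active kept edges
    a <- fe$Tact %*% w[fe$sgn > 0L, , drop = FALSE]
    i <- fe$Tinh %*% w[fe$sgn < 0L, , drop = FALSE]
    if (length(fe$u_idx)) {
      wu <- w[fe$u_idx, , drop = FALSE]
      a <- a + fe$Tun %*% (wu * sbits)
      i <- i + fe$Tun %*% (wu * (1 - sbits))
    }
    nxt <- (a > i) + 0
    none <- (a + i) == 0
    if (fe$no_input == "hold") {
      nxt[none] <- rep(s, P)[none]
    }                                       # decay: stays 0
    cons <- cons + colMeans(nxt == s)
  }
  cons <- cons / length(fe$svecs)
  list(fitness = cons - lambda * colSums(1 - keep) / fe$E,
       consistency = cons)
}

run_ga <- function(fe, params, fitness_fun) {
  L <- fe$L
  P <- params$population
  pmut <- if (is.null(params$mutation)) 1 / L else params$mutation
  # init: biased towards keeping prior edges, unbiased signs
  pop <- matrix(0L, L, P)
  pop[seq_len(fe$E), ] <- (matrix(stats::runif(fe$E * P), fe$E, P) < 0.9) + 0L
  if (L > fe$E) {
    pop[(fe$E + 1L):L, ] <-
      (matrix(stats::runif((L - fe$E) * P), L - fe$E, P) < 0.5) + 0L
  }
  pop[, 1L] <- c(rep(1L, fe$E), rep(0L, L - fe$E))  # seed with the full prior
  fit <- fitness_fun(pop)
  best <- pop[, which.max(fit), drop = TRUE]
  best_fit <- max(fit)
  for (g in seq_len(params$generations)) {
    ord <- order(fit, decreasing = TRUE)
    elite <- pop[, ord[seq_len(params$elitism)], drop = FALSE]
    # binary tournament selection
    n_child <- P - params$elitism
    i1 <- sample.int(P, n_child, replace = TRUE)
    i2 <- sample.int(P, n_child, replace = TRUE)
    parents <- ifelse(fit[i1] >= fit[i2], i1, i2)
    j1 <- sample.int(P, n_child, replace = TRUE)
    j2 <- sample.int(P, n_child, replace = TRUE)
    partners <- ifelse(fit[j1] >= fit[j2], j1, j2)
    A <- pop[, parents, drop = FALSE]
    B <- pop[, partners, drop = FALSE]
    do_x <- stats::runif(n_child) < params$crossover
    mask <- matrix(stats::runif(L * n_child) < 0.5, L, n_child)
    mask[, !do_x] <- FALSE
    child <- A
    child[mask] <- B[mask]
    flip <- matrix(stats::runif(L * n_child) < pmut, L, n_child)
    child[flip] <- 1L - child[flip]
    pop <- cbind(elite, child)
    fit <- fitness_fun(pop)
    if (max(fit) > best_fit) {
      best_fit <- max(fit)
      best <- pop[, which.max(fit), drop = TRUE]
    }
  }
  list(best = best, fitness = best_fit)
}

# Materialize a chromosome into a contextualized network.
apply_chromosome <- function(prior, keep, signs_u) {
  e <- prior$edges
  u_idx <- which(e$sign == "unassigned")
  sign_final <- e$sign
  if (length(u_idx)) {
    sign_final[u_idx] <- ifelse(signs_u == 1L, "activation", "inhibition")
  }
  provenance <- data.frame(source = e$source, target = e$target,
                           type = e$type, prior_sign = e$sign,
                           sign = sign_final, kept = keep == 1L,
                           sign_assigned = seq_len(nrow(e)) %in% u_idx,
                           stringsAsFactors = FALSE)
  kept_edges <- provenance[provenance$kept,
                           c("source", "target", "type", "sign")]
  net <- prior_network(kept_edges, nodes = prior$nodes)
  net$provenance <- provenance
  class(net) <- c("contextualized_grn", class(net))
  net
}

with_seed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

#' Contextualize a prior network to observed Boolean states
#'
#' Prunes edges and assigns unresolved signs so that the observed Boolean
#' phenotype states become fixed points of the synchronous majority-rule
#' dynamics, using a genetic algorithm over one keep/remove bit per edge and
#' one sign bit per unassigned edge. The result is a network grounded in the
#' prior knowledge but customized to the observed condition: fitness rewards
#' fixed-point consistency and penalizes removals by `lambda` per removed
#' fraction, so consistent prior edges are never discarded.
#'
#' Identical `params$seed` yields a bit-identical result.
#'
#' @param prior a [prior_network()], non-empty.
#' @param states list of [boolean_state()] objects covering the prior nodes.
#' @param params a [ga_params()].
#' @param no_input no-active-input rule, see [majority_update()].
#' @return list with `network` (contextualized grn), `report`
#'   (consistency per state, removed edges, assigned signs), `fitness`,
#'   `params`.
#' @export
contextualize <- function(prior, states, params = ga_params(),
                          no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  stopifnot(inherits(prior, "grn"))
  if (!nrow(prior$edges)) stop("prior network has no edges")
  if (!length(states)) stop("need at least one observed state")
  fe <- fitness_env(prior, states, no_input = no_input)
  res <- with_seed(params$seed, {
    run_ga(fe, params,
           function(pop) population_fitness(fe, pop, params$lambda)$fitness)
  })
  keep <- res$best[seq_len(fe$E)]
  signs_u <- res$best[-seq_len(fe$E)]
  net <- apply_chromosome(prior, keep, signs_u)
  rep <- consistency_score(net, states, no_input = no_input)
  rep$edges_removed <- sum(keep == 0L)
  rep$signs_assigned <- length(signs_u)
  rep$seed <- params$seed
  rep$lambda <- params$lambda
  list(network = net, report = rep, fitness = res$fitness, params = params)
}

#' Focused contextualization around one gene
#'
#' Instead of global optimization, the search space is restricted to the
#' edges incident to `focus_gene` (either direction); all other edges pass
#' through unchanged (their unresolved signs are still assigned). The
#' returned network must make `focus_gene` and its first neighbours perfectly
#' consistent in every state; if no keep/sign assignment achieves that, an
#' error of class `nicheGRN_infeasible` is raised carrying the best-found
#' report in its `report` field.
#'
#' @inheritParams contextualize
#' @param focus_gene node around which perfect consistency is required.
#' @return as [contextualize()], plus `neighborhood` (the focus gene and its
#'   prior first neighbours).
#' @export
contextualize_focused <- function(prior, states, focus_gene,
                                  params = ga_params(),
                                  no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  stopifnot(inherits(prior, "grn"))
  if (!focus_gene %in% prior$nodes) {
    stop(sprintf("focus gene '%s' not in prior network", focus_gene))
  }
  e <- prior$edges
  incident <- which(e$source == focus_gene | e$target == focus_gene)
  if (!length(incident)) stop("focus gene has no incident edges")
  neigh <- union(focus_gene,
                 unique(c(e$source[incident], e$target[incident])))
  u_idx <- which(e$sign == "unassigned")

  fe <- fitness_env(prior, states, no_input = no_input)
  n_states <- length(fe$svecs)
  neigh_rows <- match(neigh, fe$nodes)
  # restricted chromosome: keep bits for incident edges, signs for all
  # unassigned edges (the network must come out fully assigned)
  Lr <- length(incident) + length(u_idx)
  fe_r <- fe
  fe_r$L <- Lr
  W <- (1 + params$lambda) * length(neigh) * n_states + 1  # neigh dominates
  expand <- function(pop_r) {
    P <- ncol(pop_r)
    keep <- matrix(1L, fe$E, P)
    keep[incident, ] <- pop_r[seq_along(incident), , drop = FALSE]
    sbits <- pop_r[-seq_along(incident), , drop = FALSE]
    rbind(keep, sbits)
  }
  score <- function(pop_r) {
    pop <- expand(pop_r)
    keep <- pop[seq_len(fe$E), , drop = FALSE]
    sbits <- pop[-seq_len(fe$E), , drop = FALSE]
    P <- ncol(pop)
    cons <- numeric(P)
    ncons <- numeric(P)
    for (s in fe$svecs) {
      src_on <- s[fe$src]
      w <- keep * src_on
      a <- fe$Tact %*% w[fe$sgn > 0L, , drop = FALSE]
      i <- fe$Tinh %*% w[fe$sgn < 0L, , drop = FALSE]
      if (length(fe$u_idx)) {
        wu <- w[fe$u_idx, , drop = FALSE]
        a <- a + fe$Tun %*% (wu * sbits)
        i <- i + fe$Tun %*% (wu * (1 - sbits))
      }
      nxt <- (a > i) + 0
      none <- (a + i) == 0
      if (no_input == "hold") nxt[none] <- rep(s, P)[none]
      ok <- nxt == s
      cons <- cons + colMeans(ok)
      ncons <- ncons + colMeans(ok[neigh_rows, , drop = FALSE])
    }
    cons <- cons / n_states
    ncons <- ncons / n_states
    removed <- colSums(1 - pop_r[seq_along(incident), , drop = FALSE])
    list(fitness = W * ncons + cons - params$lambda * removed /
           length(incident),
         ncons = ncons, cons = cons)
  }
  # run_ga treats fe_r$E as the keep-bit count for initialization bias
  fe_r$E <- length(incident)
  res <- with_seed(params$seed, {
    run_ga(fe_r, params, function(pop) score(pop)$fitness)
  })
  best_r <- matrix(res$best, ncol = 1L)
  sc <- score(best_r)
  pop_full <- expand(best_r)
  keep <- pop_full[seq_len(fe$E), 1L]
  signs_u <- pop_full[-seq_len(fe$E), 1L]
  net <- apply_chromosome(prior, keep, signs_u)
  rep <- consistency_score(net, states, no_input = no_input)
  rep$edges_removed <- sum(keep == 0L)
  rep$signs_assigned <- length(signs_u)
  rep$seed <- params$seed
  rep$neighborhood_consistency <- sc$ncons[1L]
  if (sc$ncons[1L] < 1) {
    stop(errorCondition(
      sprintf("no perfectly consistent neighborhood around '%s' (best: %.3f)",
              focus_gene, sc$ncons[1L]),
      class = "nicheGRN_infeasible", report = rep))
  }
  list(network = net, report = rep, fitness = sc$cons[1L],
       params = params, neighborhood = neigh)
}
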