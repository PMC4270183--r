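fast_ga <- function(seed, ...) {
  ga_params(population = 120L, generations = 150L, seed = seed, ...)
}

test_that("a fully consistent prior is returned untouched", {
  cyc <- toy_net(list("A", "B", "activation"), list("B", "C", "activation"),
                 list("C", "A", "activation"))
  st <- state_of(A = 1, B = 1, C = 1, label = "on")
  res <- contextualize(cyc, list(st), fast_ga(1))
  expect_equal(res$report$overall, 1)
  expect_equal(res$report$edges_removed, 0L)
  expect_equal(res$network$edges, cyc$edges)
  # lambda > 0 makes this the unique optimum
  expect_equal(res$fitness, 1)
})

test_that("a single contradicting edge is pruned, matching exhaustive search", {
  # B is observed OFF in both states while A is ON: the A->B activation is
  # inconsistent; everything else supports the states
  net <- toy_net(list("A", "B", "activation"), list("A", "C", "activation"),
                 list("C", "D", "activation"), list("D", "C", "activation"),
                 list("C", "E", "inhibition"))
  s1 <- state_of(A = 1, B = 0, C = 1, D = 1, E = 0, label = "s1")
  s2 <- state_of(A = 1, B = 0, C = 1, D = 1, E = 0, label = "s2")
  res <- contextualize(net, list(s1, s2), fast_ga(2))
  prov <- res$network$provenance
  expect_equal(prov$source[!prov$kept], "A")
  expect_equal(prov$target[!prov$kept], "B")
  expect_equal(res$report$overall, 1)
  expect_equal(res$fitness, exhaustive_best_fitness(net, list(s1, s2)))
})

test_that("an unassigned sign is resolved to the only consistent choice", {
  # A ON, B OFF: only inhibition makes the state a fixed point
  net <- toy_net(list("A", "B", "unassigned"), list("B", "A", "unassigned"))
  st <- state_of(A = 1, B = 0, label = "obs")
  res <- contextualize(net, list(st), fast_ga(3))
  expect_equal(res$report$overall, 1)
  prov <- res$network$provenance
  expect_equal(prov$sign[prov$source == "A" & prov$kept], "inhibition")
  expect_true(all(res$network$edges$sign != "unassigned"))
})

test_that("GA fitness equals exhaustive enumeration on random small priors", {
  for (s in 1:12) {
    inst <- random_prior_instance(s)
    res <- contextualize(inst$prior, inst$states, fast_ga(s + 500))
    expect_equal(res$fitness,
                 exhaustive_best_fitness(inst$prior, inst$states),
                 tolerance = 1e-12,
                 label = sprintf("instance %d", s))
  }
})

test_that("contextualization is seed-deterministic and reports honestly", {
  inst <- random_prior_instance(99)
  r1 <- contextualize(inst$prior, inst$states, fast_ga(7))
  r2 <- contextualize(inst$prior, inst$states, fast_ga(7))
  expect_identical(r1$network$provenance, r2$network$provenance)
  expect_identical(r1$report, r2$report)
  r3 <- contextualize(inst$prior, inst$states, fast_ga(8))
  expect_identical(dim(r3$network$provenance), dim(r1$network$provenance))

  # monotone feasibility: restoring the removed edges never improves the
  # returned network's consistency
  prov <- r1$network$provenance
  full <- prior_network(prov[, c("source", "target", "type", "sign")],
                        nodes = inst$prior$nodes)
  expect_lte(consistency_score(full, inst$states)$overall,
             r1$report$overall + 1e-12)

  # fixed-point preservation: a claimed consistency of 1 means every state
  # is a fixed point
  if (r1$report$overall == 1) {
    for (st in inst$states) {
      expect_true(is_fixed_point(st, r1$network)$fixed)
    }
  }
  expect_error(contextualize(inst$prior, inst$states,
                             ga_params(population = 0)), "positive")
})

test_that("focused contextualization repairs only the focus neighbourhood", {
  # consistent neighbourhood: identity
  cyc <- toy_net(list("A", "B", "activation"), list("B", "A", "activation"))
  st <- state_of(A = 1, B = 1, label = "on")
  res <- contextualize_focused(cyc, list(st), "A", fast_ga(1))
  expect_equal(res$network$edges, cyc$edges)
  expect_equal(res$report$neighborhood_consistency, 1)

  # star: one incident edge contradicts the hub's observed state; the fix
  # must match exhaustive search over incident-edge subsets
  star <- toy_net(list("h", "x", "activation"), list("x", "h", "activation"),
                  list("y", "h", "inhibition"), list("h", "y", "activation"),
                  list("z", "w", "activation"))
  so <- state_of(h = 1, x = 1, y = 1, z = 0, w = 0, label = "obs")
  # h: activator x ON, inhibitor y ON -> tie -> OFF, contradicting h = 1;
  # removing y -| h restores it. Exhaustive check over the 2^4 incident
  # subsets confirms that is the unique minimal repair.
  res2 <- contextualize_focused(star, list(so), "h", fast_ga(4))
  prov <- res2$network$provenance
  expect_equal(prov$source[!prov$kept], "y")
  expect_equal(prov$target[!prov$kept], "h")
  expect_true("z" == prov$source[prov$kept & prov$target == "w"]) # untouched
  inc <- which(star$edges$source == "h" | star$edges$target == "h")
  best <- -Inf
  best_keep <- NULL
  neigh <- c("h", "x", "y")
  for (code in 0:(2^length(inc) - 1)) {
    keep <- rep(1L, nrow(star$edges))
    keep[inc] <- as.integer(intToBits(code))[seq_along(inc)]
    e <- star$edges[keep == 1, , drop = FALSE]
    upd <- naive_update(so, e, star$nodes)
    if (!all(upd[neigh] == so[neigh])) next
    f <- mean(upd == so[star$nodes]) - 0.1 * sum(keep[inc] == 0) / length(inc)
    if (f > best) {
      best <- f
      best_keep <- keep
    }
  }
  expect_equal(as.integer(res2$network$provenance$kept), best_keep)

  # infeasible: the neighbour B is forced wrong by an edge outside the
  # focus gene's incident set, so no incident subset/sign choice can give a
  # perfectly consistent neighbourhood
  bad <- toy_net(list("A", "B", "activation"), list("C", "B", "activation"))
  s_on <- state_of(A = 1, B = 1, C = 1, label = "on")
  s_off <- state_of(A = 1, B = 0, C = 1, label = "off")
  err <- tryCatch(contextualize_focused(bad, list(s_on, s_off), "A",
                                        fast_ga(5)),
                  nicheGRN_infeasible = function(e) e)
  expect_s3_class(err, "nicheGRN_infeasible")
  expect_lt(err$report$neighborhood_consistency, 1)
})
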