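test_that("booleanization thresholds quartile profiles at QE >= 3", {
  qe <- c(a = 1L, b = 2L, c = 3L, d = 4L)
  st <- booleanize(qe)
  expect_equal(unname(st), c(0L, 0L, 1L, 1L))
  expect_equal(unname(booleanize(qe, on_threshold = 4L)["c"]), 0L)
  expect_error(booleanize(qe, genes = c("a", "zz")), "zz")
})

test_that("majority rule follows activation dominance and tie inhibition", {
  # 3 active activators vs 2 active inhibitors -> ON
  net <- toy_net(list("a1", "g", "activation"), list("a2", "g", "activation"),
                 list("a3", "g", "activation"), list("i1", "g", "inhibition"),
                 list("i2", "g", "inhibition"))
  s <- state_of(a1 = 1, a2 = 1, a3 = 1, i1 = 1, i2 = 1, g = 0)
  expect_equal(unname(majority_update(s, net)["g"]), 1L)
  # 2 vs 2 tie -> inhibition dominates
  net2 <- toy_net(list("a1", "g", "activation"), list("a2", "g", "activation"),
                  list("i1", "g", "inhibition"), list("i2", "g", "inhibition"))
  s2 <- state_of(a1 = 1, a2 = 1, i1 = 1, i2 = 1, g = 1)
  expect_equal(unname(majority_update(s2, net2)["g"]), 0L)
  # OFF regulators exert no influence
  s3 <- state_of(a1 = 1, a2 = 0, i1 = 1, i2 = 0, g = 1)
  expect_equal(unname(majority_update(s3, net2)["g"]), 0L)  # 1 vs 1 tie
  # a gene with no active input holds its value; decay flag switches it off
  iso <- prior_network(toy_edges(list("x", "y", "activation")),
                       nodes = c("x", "y", "z"))
  s4 <- state_of(x = 0, y = 0, z = 1)
  expect_equal(unname(majority_update(s4, iso)["z"]), 1L)
  expect_equal(unname(majority_update(s4, iso, no_input = "decay")["z"]), 0L)
  expect_error(majority_update(state_of(x = 1), iso), "cover")
})

test_that("majority update matches a truth-table oracle for <= 4 regulators", {
  # every split of up to 4 regulators into activators/inhibitors, every
  # combination of their states, both current values of the target
  for (n_reg in 0:4) {
    for (n_act in 0:n_reg) {
      regs <- if (n_reg) paste0("r", seq_len(n_reg)) else character(0)
      signs <- c(rep("activation", n_act),
                 rep("inhibition", n_reg - n_act))
      edges <- if (n_reg) {
        do.call(rbind, lapply(seq_len(n_reg), function(i) {
          data.frame(source = regs[i], target = "g",
                     type = "transcription_regulation", sign = signs[i],
                     stringsAsFactors = FALSE)
        }))
      } else toy_edges()
      net <- prior_network(edges, nodes = c(regs, "g"))
      combos <- expand.grid(rep(list(0:1), n_reg + 1L))
      for (r in seq_len(nrow(combos))) {
        s <- boolean_state(stats::setNames(as.integer(combos[r, ]),
                                           c(regs, "g")))
        got <- majority_update(s, net)["g"]
        want <- naive_update(s, net$edges, net$nodes)["g"]
        expect_identical(got, want)
      }
    }
  }
})

test_that("fixed points are recognized and violators reported", {
  empty <- prior_network(toy_edges(), nodes = c("A", "B"))
  expect_true(is_fixed_point(state_of(A = 1, B = 0), empty)$fixed)
  net <- toy_net(list("A", "B", "activation"))
  fp <- is_fixed_point(state_of(A = 1, B = 0), net)
  expect_false(fp$fixed)
  expect_equal(fp$violating, "B")
  # 3-cycle of activations, all ON: each gene has one active activator
  cyc <- toy_net(list("A", "B", "activation"), list("B", "C", "activation"),
                 list("C", "A", "activation"))
  expect_true(is_fixed_point(state_of(A = 1, B = 1, C = 1), cyc)$fixed)
})

test_that("synchronous simulation classifies terminal behaviour correctly", {
  cyc <- toy_net(list("A", "B", "activation"), list("B", "C", "activation"),
                 list("C", "A", "activation"))
  tr <- simulate_boolean(state_of(A = 1, B = 1, C = 1), cyc)
  expect_equal(tr$classification, "fixed_point")
  expect_equal(nrow(tr$trajectory), 1L)
  expect_equal(tr$period, 1L)

  # mutual inhibition from (1,1): next (0,0) which holds -> fixed point;
  # verified against exhaustive enumeration of the 4-state transition graph
  mi <- toy_net(list("A", "B", "inhibition"), list("B", "A", "inhibition"))
  tr2 <- simulate_boolean(state_of(A = 1, B = 1), mi)
  all_states <- expand.grid(A = 0:1, B = 0:1)
  succ <- apply(all_states, 1L, function(s) {
    paste(naive_update(boolean_state(s), mi$edges, mi$nodes), collapse = "")
  })
  names(succ) <- apply(all_states, 1L, paste, collapse = "")
  path <- "11"
  repeat {
    nxt <- succ[[path[length(path)]]]
    if (nxt %in% path) break
    path <- c(path, nxt)
  }
  expect_equal(nrow(tr2$trajectory), length(path))
  expect_equal(tr2$classification, "fixed_point")
  expect_equal(paste(tr2$trajectory[nrow(tr2$trajectory), ], collapse = ""),
               path[length(path)])

  # pigeonhole: any 5-node trajectory repeats within 2^5 steps
  set.seed(5)
  inst <- random_prior_instance(5)
  st <- inst$states[[1L]]
  edges_assigned <- inst$prior$edges
  edges_assigned$sign[edges_assigned$sign == "unassigned"] <- "activation"
  net5 <- prior_network(edges_assigned, nodes = inst$prior$nodes)
  tr3 <- simulate_boolean(st, net5, max_steps = 2^7)
  expect_true(tr3$classification %in% c("fixed_point", "limit_cycle"))
  expect_lte(nrow(tr3$trajectory), 2^length(inst$prior$nodes))
})

test_that("consistency scores agree with naive recomputation", {
  net <- toy_net(list("A", "B", "activation"), list("B", "C", "inhibition"))
  good <- state_of(A = 0, B = 0, C = 1, label = "ok")
  expect_equal(consistency_score(net, list(good))$overall, 1)
  # one gene forced wrong by its only regulator: 1 - 1/n
  bad <- state_of(A = 1, B = 0, C = 0, label = "bad")
  expect_equal(consistency_score(net, list(bad))$per_state[["bad"]],
               1 - 1 / 3)
  expect_equal(consistency_score(net, list(bad))$inconsistent$bad, "B")
  set.seed(11)
  for (i in 1:25) {
    inst <- random_prior_instance(i)
    e <- inst$prior$edges
    e$sign[e$sign == "unassigned"] <- sample(c("activation", "inhibition"),
                                             sum(e$sign == "unassigned"),
                                             replace = TRUE)
    net_i <- prior_network(e, nodes = inst$prior$nodes)
    cs <- consistency_score(net_i, inst$states)
    expect_equal(cs$overall,
                 naive_consistency(net_i$edges, net_i$nodes, inst$states))
  }
})
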