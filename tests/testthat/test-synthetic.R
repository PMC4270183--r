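test_that("generators are pure functions of configuration and seed", {
  cfg <- quick_config(seed = 5)
  d1 <- generate_dataset(cfg)
  d2 <- generate_dataset(cfg)
  expect_identical(d1$expr_a$values, d2$expr_a$values)
  expect_identical(d1$expr_b$values, d2$expr_b$values)
  expect_identical(d1$prior$edges, d2$prior$edges)
  expect_identical(d1$truth, d2$truth)
  d3 <- generate_dataset(quick_config(seed = 6))
  expect_false(identical(d1$expr_a$values, d3$expr_a$values))
})

test_that("the planted prior carries verifiable ground truth", {
  cfg <- quick_config(seed = 8)
  net <- generate_prior_network(cfg)
  te <- net$truth$edges
  # both planted states are fixed points of the true-signed core network
  core <- prior_network(
    cbind(te[te$role == "core", c("source", "target", "type")],
          sign = te$true_sign[te$role == "core"]),
    nodes = net$prior$nodes)
  for (st in net$states) expect_true(is_fixed_point(st, core)$fixed)
  # each spurious edge, added alone, breaks at least one state
  for (i in which(te$role == "spurious")) {
    aug <- prior_network(rbind(core$edges,
                               te[i, c("source", "target", "type", "sign")]),
                         nodes = net$prior$nodes)
    cs <- consistency_score(aug, net$states)
    expect_lt(cs$overall, 1)
    expect_lt(cs$per_state[[te$violates[i]]], 1)
  }
  # the planted core is one SCC found by the topology module
  scc <- find_sccs(core)
  expect_equal(scc$components[[1L]], net$truth$scc_genes)
  # blinded signs are recorded with their recoverable true value
  blinded <- te[te$sign == "unassigned", ]
  expect_true(all(blinded$true_sign %in% c("activation", "inhibition")))
  expect_equal(nrow(blinded), round(cfg$unassigned_fraction * nrow(te)))
})

test_that("a zero-spurious prior is already fully consistent", {
  cfg <- quick_config(seed = 9, spurious_fraction = 0,
                      unassigned_fraction = 0)
  net <- generate_prior_network(cfg)
  expect_true(all(net$truth$edges$role == "core"))
  expect_equal(consistency_score(net$prior, net$states)$overall, 1)
})

test_that("planted differential genes carry their configured quartile shift", {
  cfg <- quick_config(seed = 10)
  d <- generate_dataset(cfg)
  sheet <- d$sheet
  sum_a <- summarize_to_gene(d$expr_a, d$probemap,
                             sheet[sheet$region %in% c("stemA", "diffA"), ])
  sum_b <- summarize_to_gene(d$expr_b, d$probemap,
                             sheet[sheet$region %in% c("stemB", "diffB"), ])
  genes <- intersect(rownames(sum_a), rownames(sum_b))
  qe <- qe_profile(cbind(sum_a[genes, ], sum_b[genes, ]))
  de <- differential_qe(qe[, "stemA"], qe[, "stemB"])
  truth <- d$truth$de
  hits <- de$table$significant[match(truth$gene_id, de$table$gene_id)]
  expect_gte(mean(hits), 0.9)
  # directions agree for recovered genes
  qde <- de$table$qde[match(truth$gene_id, de$table$gene_id)]
  expect_true(all(sign(qde[hits]) ==
                  sign(truth$qde_stemA_vs_stemB[hits])))
})

test_that("pair planting is balanced in stem and split by the set magnitude", {
  cfg <- quick_config(seed = 11)
  net <- generate_prior_network(cfg)
  expr0 <- generate_expression(cfg, network = net)
  # magnitude zero: nothing changes, true D is zero
  cfg0 <- quick_config(seed = 11, pair_magnitude = 0)
  e0 <- plant_disbalanced_pairs(generate_expression(cfg0, network = net),
                                net, cfg0)
  expect_equal(unique(e0$truth$pairs$true_D), 0)
  expect_identical(e0$expr_a$values,
                   generate_expression(cfg0, network = net)$expr_a$values)
  # default magnitude: pair statistics recover ~2 log2 units
  e2 <- plant_disbalanced_pairs(expr0, net, cfg)
  sheet <- e2$sheet
  sA <- summarize_to_gene(e2$expr_a, e2$probemap,
                          sheet[sheet$region %in% c("stemA", "diffA"), ],
                          log2 = TRUE)
  for (r in seq_len(nrow(e2$truth$pairs))) {
    ps <- pair_statistic(sA, e2$truth$pairs$gene_up[r],
                         e2$truth$pairs$gene_partner[r], "stemA", "diffA")
    expect_equal(ps$D, 2, tolerance = 0.45)
  }
})

test_that("configuration validation rejects impossible designs", {
  expect_error(synth_config(n_pairs_c3 = 3, seed = 1), "at most 2")
  expect_error(synth_config(n_pairs_c3 = 1, n_pairs_c4 = 2, seed = 1),
               "anchored")
  expect_error(synth_config(n_network_genes = 12, seed = 1), "too small")
  expect_error(synth_config(n_network_genes = 400, n_tfs = 300, seed = 1),
               "subset of TFs")
  expect_error(synth_config(de_fraction = 1.2, seed = 1), "fractions")
  # the site-B family cannot reach microarray-like skewness at this size:
  # the generator must refuse rather than deliver an uncalibrated dataset
  cfg_bad <- quick_config(seed = 1, skew_target_b = 25)
  expect_error(generate_expression(cfg_bad), "cannot reach skewness")
})

test_that("generated matrices meet the platform moment bands", {
  cfg <- quick_config(seed = 12)
  d <- generate_dataset(cfg)
  st_a <- distribution_stats(d$expr_a, sheet = d$sheet)
  st_b <- distribution_stats(d$expr_b, sheet = d$sheet)
  skew_a <- st_a$skewness[st_a$region == "stemA"]
  skew_b <- st_b$skewness[st_b$region == "stemB"]
  expect_gte(skew_a, cfg$skew_band_a[1L])
  expect_lte(skew_a, cfg$skew_band_a[2L])
  expect_gte(skew_b, cfg$skew_band_b[1L])
  expect_lte(skew_b, cfg$skew_band_b[2L])
  # the two platforms sit on very different absolute scales
  expect_gt(st_a$median[st_a$region == "stemA"] /
            st_b$median[st_b$region == "stemB"], 5)
})
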