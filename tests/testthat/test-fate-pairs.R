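test_that("the disbalance statistic follows its defining arithmetic", {
  m <- rbind(g1 = c(stem = 3, diff = 5), g2 = c(stem = 3, diff = 1))
  ps <- pair_statistic(m, "g1", "g2", "stem", "diff")
  expect_equal(ps$D, 4)
  same <- rbind(g1 = c(stem = 2, diff = 7), g2 = c(stem = 2, diff = 7))
  expect_equal(pair_statistic(same, "g1", "g2", "stem", "diff")$D, 0)
  expect_error(pair_statistic(m, "g1", "g9", "stem", "diff"), "g9")
  # antisymmetry on random inputs
  set.seed(21)
  for (i in 1:20) {
    mm <- matrix(rnorm(4), 2, 2,
                 dimnames = list(c("a", "b"), c("stem", "diff")))
    expect_equal(pair_statistic(mm, "a", "b", "stem", "diff")$D,
                 -pair_statistic(mm, "b", "a", "stem", "diff")$D)
  }
})

test_that("all-pairs tables enumerate each unordered pair once", {
  set.seed(4)
  m <- matrix(rnorm(20), 10, 2,
              dimnames = list(paste0("tf", 1:10), c("stem", "diff")))
  expect_equal(nrow(all_pair_statistics(m, rownames(m)[1:3], "stem", "diff")),
               3L)
  tab <- all_pair_statistics(m, rownames(m), "stem", "diff")
  expect_equal(nrow(tab), 45L)
  expect_true(all(tab$gene1 < tab$gene2))
  # values agree with per-pair calls
  for (r in sample(nrow(tab), 10)) {
    expect_equal(tab$D[r], pair_statistic(m, tab$gene1[r], tab$gene2[r],
                                          "stem", "diff")$D)
  }
  expect_error(all_pair_statistics(m, c("tf1", "tf1"), "stem", "diff"),
               "duplicate")
  expect_error(all_pair_statistics(m, "tf1", "stem", "diff"), "at least two")
})

test_that("the robust z-test resists outliers and flags degeneracies", {
  x <- c(rnorm(99, sd = 1), 50)
  set.seed(2)
  zt <- robust_z_test(x)
  expect_gt(abs(zt$z[100]), 10)             # outlier gets a large finite z
  expect_lt(attr(zt, "scale"), 2)           # without inflating the scale
  expect_true(all(is.finite(zt$z)))
  expect_error(robust_z_test(rep(1, 50)), "zero scale")
  expect_error(robust_z_test(rnorm(10)), "at least 20")
  expect_error(robust_z_test(rnorm(50), trim_fraction = 0.3), "trim_fraction")
})

test_that("robust z p-values are calibrated under a standard normal null", {
  set.seed(31)
  fr <- replicate(12, mean(robust_z_test(rnorm(10000))$p < 0.05))
  mcse <- sd(fr) / sqrt(length(fr))
  expect_lt(abs(mean(fr) - 0.05), 3 * mcse + 1e-9)
})

test_that("BH adjustment reproduces the step-up rule", {
  expect_equal(bh_adjust(0.03), 0.03)
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(rep(1, 5)), rep(1, 5))
  p <- c(0.001, 0.008, 0.039, 0.041, 0.042, 0.06, 0.074, 0.205, 0.212, 0.216)
  # hand-computed step-up with monotonicity enforcement
  expect_equal(bh_adjust(p),
               c(0.01, 0.04, 0.084, 0.084, 0.084, 0.1, 0.105714285714286,
                 0.216, 0.216, 0.216),
               tolerance = 1e-12)
  expect_error(bh_adjust(c(0.5, 1.2)), "\\[0, 1\\]")
  expect_true(all(bh_adjust(p) >= p))
})

test_that("candidate filtering applies the four criteria and orientation", {
  # engineered universe: sig1/sig2 in the SCC and linked (c3 pair);
  # sig3 outside with a prior edge to hub (c4 pair); decoys fail
  genes <- c("sig1", "sig2", "sig3", "hub", "d1", "d2")
  qe_stem <- stats::setNames(c(3L, 3L, 3L, 3L, 1L, 3L), genes)
  qe_diff <- stats::setNames(c(4L, 3L, 4L, 3L, 4L, 3L), genes)
  baseline <- list(
    values = stats::setNames(rep(1, 6), genes),
    quartile = stats::setNames(c(2L, 2L, 2L, 2L, 4L, 2L), genes))
  class(baseline) <- "baseline_reference"
  prior <- toy_net(list("sig1", "sig2", "activation", "binding"),
                   list("sig2", "hub", "activation"),
                   list("hub", "sig2", "activation"),
                   list("hub", "sig3", "activation", "binding"),
                   list("sig2", "sig1", "activation"))
  scc <- c("sig1", "sig2", "hub")
  results <- data.frame(
    gene1 = c("sig1", "sig3", "d1", "sig1", "d2"),
    gene2 = c("sig2", "hub", "sig2", "d2", "hub"),
    g1_stem = 1, g2_stem = 1, g1_diff = 2, g2_diff = 0,
    D = c(2, 2, 2, 2, 2), z = 5, p = 1e-6,
    p_adj = c(1e-5, 1e-5, 1e-5, 1e-5, 0.2),
    significant = c(TRUE, TRUE, TRUE, TRUE, FALSE),
    stringsAsFactors = FALSE)
  out <- filter_candidates(results, qe_stem, qe_diff, baseline, scc, prior)
  expect_equal(sum(out$passes), 2L)
  kept <- out[out$passes, ]
  expect_setequal(pair_key(kept$gene1, kept$gene2),
                  c(pair_key("sig1", "sig2"), pair_key("sig3", "hub")))
  # d1 pair: d1 is up in diff but fails c2 via qe_stem - baseline <= -2;
  # also neither gene pair is SCC-linked
  d1row <- out[out$gene1 == "d1", ]
  expect_false(d1row$c2_not_down_in_stem)
  # sig1-d2 pair: significant, c1 passes through sig1, but d2 outside the
  # SCC with no direct edge -> both c3 and c4 fail
  sd_row <- out[out$gene1 == "sig1" & out$gene2 == "d2", ]
  expect_true(sd_row$c1_up_in_diff)
  expect_false(sd_row$c3_both_in_scc_connected ||
               sd_row$c4_one_in_scc_partner_interacts)
  # the non-significant row is excluded before filtering
  expect_false("d2" %in% out$gene1[out$gene2 == "hub"])
  # kept pairs are oriented with the differentiated-up gene first
  expect_equal(kept$gene1[pair_key(kept$gene1, kept$gene2) ==
                          pair_key("sig3", "hub")], "sig3")
  # output is always a subset of the significant set
  expect_true(all(out$p_adj < 0.05))
})

test_that("filtering is invariant to which gene is labelled first", {
  genes <- c("a", "b", "hub")
  qe_stem <- stats::setNames(c(3L, 3L, 3L), genes)
  qe_diff <- stats::setNames(c(4L, 3L, 3L), genes)
  baseline <- structure(list(values = stats::setNames(rep(1, 3), genes),
                             quartile = stats::setNames(rep(2L, 3), genes)),
                        class = "baseline_reference")
  prior <- toy_net(list("a", "b", "activation"), list("b", "a", "activation"),
                   list("b", "hub", "activation"),
                   list("hub", "b", "activation"))
  scc <- c("a", "b", "hub")
  base <- data.frame(g1_stem = 1, g2_stem = 1, g1_diff = 3, g2_diff = 1,
                     z = 5, p = 1e-6, p_adj = 1e-5, significant = TRUE,
                     stringsAsFactors = FALSE)
  fwd <- cbind(data.frame(gene1 = "a", gene2 = "b", stringsAsFactors = FALSE),
               base, D = 2)
  rev <- cbind(data.frame(gene1 = "b", gene2 = "a", stringsAsFactors = FALSE),
               base, D = -2)
  of <- filter_candidates(fwd, qe_stem, qe_diff, baseline, scc, prior)
  orv <- filter_candidates(rev, qe_stem, qe_diff, baseline, scc, prior)
  expect_equal(of$passes, orv$passes)
  expect_equal(of$gene1, orv$gene1)    # both oriented up-gene first
  expect_equal(of$D, orv$D)
})
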