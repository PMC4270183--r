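#' Configuration for the synthetic two-niche dataset
#'
#' The generator emulates the structure of the study design the pipeline is
#' built for: two anatomical sites profiled on different platforms — site A
#' microarray-like (heavy-tailed positive intensities, multiple probes per
#' gene) and site B RNA-seq-FPKM-like (moderate tail, gene-level) — each with
#' a stem/progenitor region and a differentiated region, plus a basal
#' reference panel. Ground truth is planted at every level: differential
#' genes between the two stem regions, a signed prior network whose two
#' region phenotypes are exact fixed points of a core subnetwork corrupted by
#' spurious edges and blinded signs, and balanced TF pairs whose expression
#' ratio splits upon differentiation.
#'
#' Platform shape targets are the sample skewness bands reported for the two
#' platforms (site A 6.4-7.18; site B 2.87-2.89, relaxed by +/-0.5 since that
#' printed band reflects one dataset rather than a distributional law — the
#' strict band can be requested via `site_b_strict`). The generator solves
#' for the log-normal `sdlog` (site A) and gamma shape (site B) so the
#' quantile grid it samples from attains the band centre at the configured
#' `n_genes`.
#'
#' @param n_genes number of genes (>= 1000 recommended; moment calibration
#'   assumes a dense grid).
#' @param n_tfs number of transcription factors (the pair-test universe).
#' @param n_network_genes number of prior-network nodes (first
#'   `n_network_genes` TFs).
#' @param core_module_size genes per bistable core module (two modules).
#' @param n_pairs_c3 planted pairs with both genes inside the SCC (max 2).
#' @param n_pairs_c4 planted pairs with one gene outside the SCC (max
#'   `n_pairs_c3`, whose partners anchor them).
#' @param pair_magnitude planted log2 split of a pair upon differentiation.
#' @param de_fraction fraction of non-TF genes planted as differential
#'   between the two stem regions.
#' @param de_shift planted quartile shift of differential genes.
#' @param replicates named counts for regions stemA, diffA, stemB, diffB.
#' @param probe_weights sampling weights for 1, 2 or 3 probes per gene on
#'   site A.
#' @param noise_sd per-measurement log2-normal noise standard deviation.
#' @param spurious_fraction fraction of prior edges that are spurious
#'   (state-violating).
#' @param unassigned_fraction fraction of prior edges with blinded signs.
#' @param skew_target_a,skew_target_b calibration targets for sample
#'   skewness.
#' @param skew_band_a,skew_band_b acceptance bands checked by the generator.
#' @param site_b_strict use the narrow printed band for site B.
#' @param seed mandatory integer seed; identical seeds give identical output.
#' @return a `synth_config` list.
#' @export
synth_config <- function(n_genes = 5000L, n_tfs = 300L,
                         n_network_genes = 30L, core_module_size = 5L,
                         n_pairs_c3 = 2L, n_pairs_c4 = 2L,
                         pair_magnitude = 2,
                         de_fraction = 0.1, de_shift = 2L,
                         replicates = c(stemA = 3L, diffA = 3L,
                                        stemB = 3L, diffB = 3L),
                         probe_weights = c(0.5, 0.3, 0.2),
                         noise_sd = 0.25,
                         spurious_fraction = 0.2,
                         unassigned_fraction = 0.2,
                         skew_target_a = 6.79, skew_target_b = 2.88,
                         skew_band_a = c(6.4, 7.18),
                         skew_band_b = c(2.38, 3.38),
                         site_b_strict = FALSE,
                         seed = 1L) {
  if (missing(seed) || is.null(seed)) stop("seed is mandatory")
  if (de_fraction < 0 || de_fraction > 1 ||
      spurious_fraction < 0 || spurious_fraction >= 1 ||
      unassigned_fraction < 0 || unassigned_fraction > 1) {
    stop("fractions must lie in [0, 1]")
  }
  if (n_pairs_c3 > 2L) {
    stop("at most 2 within-SCC pairs can be anchored on the two core modules")
  }
  if (n_pairs_c4 > 0L && n_pairs_c4 > n_pairs_c3) {
    stop("each out-of-SCC pair is anchored on a within-SCC pair partner: ",
         "n_pairs_c4 must not exceed n_pairs_c3")
  }
  if (core_module_size < 3L) stop("core modules need >= 3 genes")
  n_periph <- n_network_genes - 2L * core_module_size -
    2L * n_pairs_c3 - n_pairs_c4
  if (n_periph < 4L) {
    stop("n_network_genes too small for the core, pairs and periphery; ",
         "increase it or shrink core_module_size")
  }
  if (n_network_genes > n_tfs) stop("network genes must be a subset of TFs")
  if (site_b_strict) skew_band_b <- c(2.87, 2.89)
  structure(list(n_genes = as.integer(n_genes), n_tfs = as.integer(n_tfs),
                 n_network_genes = as.integer(n_network_genes),
                 core_module_size = as.integer(core_module_size),
                 n_pairs_c3 = as.integer(n_pairs_c3),
                 n_pairs_c4 = as.integer(n_pairs_c4),
                 pair_magnitude = pair_magnitude,
                 de_fraction = de_fraction, de_shift = as.integer(de_shift),
                 replicates = replicates, probe_weights = probe_weights,
                 noise_sd = noise_sd,
                 spurious_fraction = spurious_fraction,
                 unassigned_fraction = unassigned_fraction,
                 skew_target_a = skew_target_a,
                 skew_target_b = skew_target_b,
                 skew_band_a = skew_band_a, skew_band_b = skew_band_b,
                 n_periphery = as.integer(n_periph),
                 seed = as.integer(seed)),
            class = "synth_config")
}

# Solve a one-parameter distribution family so the skewness of its n-point
# quantile grid hits `target`. Errors when the family cannot reach the target.
calibrate_grid <- function(qfun, target, n, lower, upper) {
  grid_skew <- function(par) sample_skewness(qfun(stats::ppoints(n), par))
  lo <- grid_skew(lower)
  hi <- grid_skew(upper)
  if ((target - lo) * (target - hi) > 0) {
    stop(sprintf(paste0("distribution family cannot reach skewness %.2f ",
                        "within parameter range [%.3g, %.3g] ",
                        "(attains [%.2f, %.2f]); adjust the target or family"),
                 target, lower, upper, min(lo, hi), max(lo, hi)))
  }
  stats::uniroot(function(p) grid_skew(p) - target,
                 lower = lower, upper = upper, tol = 1e-7)$root
}

synth_gene_ids <- function(config) {
  tf <- sprintf("tf%03d", seq_len(config$n_tfs))
  bg <- sprintf("g%05d", seq_len(config$n_genes - config$n_tfs))
  c(tf, bg)
}

#' Generate the planted prior interaction network
#'
#' Builds a core signed subnetwork admitting two distinct fixed points (the
#' two region phenotypes): two mutually inhibiting activation-ring modules
#' (module 1 ON defines state A, module 2 ON defines state B), always-ON pair
#' appendages wired into the strongly connected core, always-ON out-of-SCC
#' leaves for the one-in-SCC pairs, and state-specific periphery genes fed by
#' the modules. It then adds spurious edges, each of which violates at least
#' one planted state when present (verified edge by edge), and blinds the
#' signs of a fraction of the true edges. Ground truth records the spurious
#' edges that must be removed and the true signs that must be re-assigned
#' for perfect consistency.
#'
#' @param config a [synth_config()].
#' @return list with `prior` (a [prior_network()]), `states` (list of two
#'   [boolean_state()]s, labelled stemA/stemB) and `truth` (core/spurious
#'   edge tables, blinded signs, SCC genes, pair gene roles, per-gene state
#'   table).
#' @export
generate_prior_network <- function(config) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 1L, generate_prior_network_impl(config))
}

generate_prior_network_impl <- function(config) {
  m <- config$core_module_size
  ids <- synth_gene_ids(config)
  take <- local({
    i <- 0L
    function(k) {
      out <- ids[(i + 1L):(i + k)]
      i <<- i + k
      out
    }
  })
  M1 <- take(m)
  M2 <- take(m)
  pair_up <- pair_partner <- character(0L)
  if (config$n_pairs_c3 > 0L) {
    for (p in seq_len(config$n_pairs_c3)) {
      pair_up <- c(pair_up, take(1L))
      pair_partner <- c(pair_partner, take(1L))
    }
  }
  leaf_up <- if (config$n_pairs_c4 > 0L) take(config$n_pairs_c4) else
    character(0L)
  periph <- take(config$n_periphery)
  nA <- ceiling(length(periph) / 2)
  periph_a <- periph[seq_len(nA)]
  periph_b <- periph[-seq_len(nA)]
  nodes <- c(M1, M2, pair_up, pair_partner, leaf_up, periph)

  tr <- "transcription_regulation"
  e <- function(src, tgt, sign, type = tr) {
    data.frame(source = src, target = tgt, type = type, sign = sign,
               stringsAsFactors = FALSE)
  }
  ring <- function(mod) e(mod, mod[c(2:length(mod), 1L)], "activation")
  edges <- rbind(
    ring(M1), ring(M2),
    e(M1[1L], M2[1L], "inhibition"),
    e(M2[1L], M1[1L], "inhibition"),
    if (m >= 4L) rbind(e(M1[2L], M1[4L], "activation"),
                       e(M2[2L], M2[4L], "activation")))
  anchors <- c(M1[1L], M2[1L])
  for (p in seq_along(pair_up)) {
    edges <- rbind(edges,
                   e(pair_up[p], pair_partner[p], "activation", "binding"),
                   e(pair_partner[p], pair_up[p], "activation", "binding"),
                   e(pair_partner[p], anchors[p], "activation"),
                   e(anchors[p], pair_partner[p], "activation"))
  }
  for (p in seq_along(leaf_up)) {
    edges <- rbind(edges,
                   e(pair_partner[p], leaf_up[p], "activation", "binding"))
  }
  feed_a <- M1[1L + (seq_along(periph_a) %% m)]
  feed_b <- M2[1L + (seq_along(periph_b) %% m)]
  edges <- rbind(edges,
                 if (length(periph_a)) e(feed_a, periph_a, "activation"),
                 if (length(periph_b)) e(feed_b, periph_b, "activation"))
  edges$role <- "core"
  edges$violates <- ""

  # two region phenotypes: module 1 defines state A, module 2 state B;
  # pair genes are ON in both, periphery follows its feeding module
  on_a <- c(M1, pair_up, pair_partner, leaf_up, periph_a)
  on_b <- c(M2, pair_up, pair_partner, leaf_up, periph_b)
  state_a <- boolean_state(
    stats::setNames(as.integer(nodes %in% on_a), nodes), label = "stemA")
  state_b <- boolean_state(
    stats::setNames(as.integer(nodes %in% on_b), nodes), label = "stemB")

  # spurious edges: one per target, periphery targets only, each violating
  # exactly one state (tie-breaking inhibition or phantom activation)
  n_true <- nrow(edges)
  n_spur <- round(config$spurious_fraction /
                    (1 - config$spurious_fraction) * n_true)
  avail_a <- sample(periph_a)
  avail_b <- sample(periph_b)
  if (n_spur > length(avail_a) + length(avail_b)) {
    stop("spurious_fraction too high for the available periphery targets; ",
         "increase n_network_genes or lower spurious_fraction")
  }
  spur <- NULL
  for (k in seq_len(n_spur)) {
    mode <- switch(1L + (k - 1L) %% 4L,
                   "inh_a", "inh_b", "act_onto_b", "act_onto_a")
    if (mode %in% c("inh_a", "act_onto_a")) {
      if (!length(avail_a)) { avail_a <- avail_b; avail_b <- character(0) }
      tgt <- avail_a[1L]; avail_a <- avail_a[-1L]
    } else {
      if (!length(avail_b)) { avail_b <- avail_a; avail_a <- character(0) }
      tgt <- avail_b[1L]; avail_b <- avail_b[-1L]
    }
    tgt_on_a <- state_a[tgt] == 1L
    taken <- c(edges$source[edges$target == tgt],
               if (!is.null(spur)) spur$source[spur$target == tgt])
    pick <- function(pool) sample(rep(setdiff(pool, taken), 2L), 1L)
    row <- switch(
      mode,
      inh_a = ,                       # tie-break inhibition where target is ON
      inh_b = e(pick(if (tgt_on_a) M1[-1L] else M2[-1L]), tgt, "inhibition"),
      act_onto_b = ,                  # phantom activation where target is OFF
      act_onto_a = e(pick(if (tgt_on_a) M2[-1L] else M1[-1L]), tgt,
                     "activation"))
    row$role <- "spurious"
    row$violates <- if (row$sign == "inhibition") {
      if (tgt_on_a) "stemA" else "stemB"
    } else {
      if (tgt_on_a) "stemB" else "stemA"
    }
    spur <- rbind(spur, row)
  }
  edges <- rbind(edges, spur)
  rownames(edges) <- NULL

  n_un <- round(config$unassigned_fraction * nrow(edges))
  core_idx <- which(edges$role == "core")
  blind <- sort(sample(core_idx, min(n_un, length(core_idx))))
  true_sign <- edges$sign
  edges$sign[blind] <- "unassigned"

  prior <- prior_network(edges[c("source", "target", "type", "sign")],
                         nodes = nodes)
  # prior_network() sorts/collapses edges; re-align the bookkeeping
  okey <- paste(edges$source, edges$target, edges$type, sep = "\r")
  pkey <- paste(prior$edges$source, prior$edges$target, prior$edges$type,
                sep = "\r")
  ord <- match(pkey, okey)
  stopifnot(!anyNA(ord), length(ord) == nrow(edges))
  truth_edges <- data.frame(prior$edges,
                            role = edges$role[ord],
                            true_sign = true_sign[ord],
                            violates = edges$violates[ord],
                            stringsAsFactors = FALSE)

  truth <- list(
    edges = truth_edges,
    scc_genes = sort(c(M1, M2, pair_up, pair_partner)),
    modules = list(M1 = M1, M2 = M2),
    pair_roles = list(up_in_scc = pair_up, partner = pair_partner,
                      up_leaf = leaf_up),
    periphery = list(a = periph_a, b = periph_b),
    states = list(stemA = state_a, stemB = state_b))

  # self-verification: the core alone holds both states as fixed points and
  # every spurious edge, added alone, breaks at least one of them
  core_net <- prior_network(
    truth_edges[truth_edges$role == "core",
                c("source", "target", "type")] |>
      cbind(sign = truth_edges$true_sign[truth_edges$role == "core"]),
    nodes = nodes)
  cs <- consistency_score(core_net, truth$states)
  if (cs$overall < 1) {
    stop("internal: planted states are not fixed points of the core network")
  }
  for (i in which(truth_edges$role == "spurious")) {
    aug <- prior_network(rbind(core_net$edges,
                               truth_edges[i, c("source", "target", "type",
                                                "sign")]),
                         nodes = nodes)
    if (consistency_score(aug, truth$states)$overall >= 1) {
      stop("internal: a spurious edge does not violate any planted state")
    }
  }
  list(prior = prior, states = truth$states, truth = truth)
}

#' Generate synthetic expression data for both sites
#'
#' Region value distributions are materialized as n-point quantile grids of
#' the calibrated platform families (site A log-normal with large `sdlog`,
#' site B gamma with small shape), so the per-region sample moments are a
#' structural property of the generator rather than of any one random draw;
#' genes are assigned grid ranks by a seeded permutation, and all stochastic
#' variation enters as per-measurement log2-normal noise. Non-differential
#' genes occupy the same rank at both sites and in both regions of a site —
#' the cross-platform comparability the pipeline assumes. Planted structure
#' is expressed in rank space: differential genes sit `de_shift` quartiles
#' apart between the two stem regions (mid-bin, so calls survive the noise),
#' network genes sit high (ON) or low (OFF) according to the planted region
#' phenotypes, and pair genes share one mid-distribution rank.
#'
#' @param config a [synth_config()].
#' @param network optional result of [generate_prior_network()]; when given,
#'   network-gene ranks encode the planted states and pair-gene ranks are
#'   reserved.
#' @return list with `expr_a`, `expr_b` ([expression_matrix()]s, probe-level
#'   for site A), `sheet`, `probemap`, `baseline`
#'   ([baseline_reference()]), `tf_list` and `truth` (differential genes with
#'   directions and expected QDE, per-gene region percentiles).
#' @export
generate_expression <- function(config, network = NULL) {
  stopifnot(inherits(config, "synth_config"))
  with_seed(config$seed + 2L, generate_expression_impl(config, network))
}

generate_expression_impl <- function(config, network) {
  n <- config$n_genes
  ids <- synth_gene_ids(config)
  # probe multiplicities drawn first: site A moments are calibrated on the
  # probe-level grid every sample is normalized onto
  n_probes <- sample(seq_along(config$probe_weights), n, replace = TRUE,
                     prob = config$probe_weights)
  n_probe_rows <- sum(n_probes)
  sdlog_a <- calibrate_grid(function(p, s) stats::qlnorm(p, 0, s),
                            config$skew_target_a, n_probe_rows, 0.3, 2.5)
  shape_b <- calibrate_grid(function(p, k) stats::qgamma(p, shape = k),
                            config$skew_target_b, n, 0.05, 10)
  q_a <- function(p) stats::qlnorm(p, meanlog = 5.5, sdlog = sdlog_a)
  q_b <- function(p) stats::qgamma(p, shape = shape_b,
                                   scale = 20 / shape_b)
  chk <- sample_skewness(q_a(stats::ppoints(n_probe_rows)))
  if (chk < config$skew_band_a[1L] || chk > config$skew_band_a[2L]) {
    stop("site A grid skewness outside its acceptance band after calibration")
  }
  chk <- sample_skewness(q_b(stats::ppoints(n)))
  if (chk < config$skew_band_b[1L] || chk > config$skew_band_b[2L]) {
    stop("site B grid skewness outside its acceptance band after calibration")
  }

  base_pct <- stats::setNames(sample(stats::ppoints(n)), ids)

  net_genes <- if (!is.null(network)) names(network$states$stemA) else
    character(0L)
  pair_genes <- if (!is.null(network)) {
    unlist(network$truth$pair_roles, use.names = FALSE)
  } else character(0L)

  # planted differential genes: non-TF, mid-bin ranks de_shift quartiles apart
  pool <- setdiff(ids, sprintf("tf%03d", seq_len(config$n_tfs)))
  n_de <- round(config$de_fraction * length(pool))
  de_genes <- sample(pool, n_de)
  margin <- 0.06
  lo <- stats::runif(n_de, margin, 0.25 - margin)
  hi <- lo + 0.25 * config$de_shift
  up_site <- rep(c("siteA", "siteB"), length.out = n_de)

  pct <- matrix(base_pct, n, 4L,
                dimnames = list(ids, c("stemA", "diffA", "stemB", "diffB")))
  if (n_de) {
    pct[de_genes[up_site == "siteA"], c("stemA", "diffA")] <-
      hi[up_site == "siteA"]
    pct[de_genes[up_site == "siteA"], c("stemB", "diffB")] <-
      lo[up_site == "siteA"]
    pct[de_genes[up_site == "siteB"], c("stemA", "diffA")] <-
      lo[up_site == "siteB"]
    pct[de_genes[up_site == "siteB"], c("stemB", "diffB")] <-
      hi[up_site == "siteB"]
  }
  if (length(net_genes)) {
    sA <- network$states$stemA
    sB <- network$states$stemB
    on_band <- seq(0.84, 0.97, length.out = length(net_genes))
    off_band <- seq(0.03, 0.16, length.out = length(net_genes))
    pa <- ifelse(sA[net_genes] == 1L, on_band, off_band)
    pb <- ifelse(sB[net_genes] == 1L, on_band, off_band)
    pct[net_genes, c("stemA", "diffA")] <- pa
    pct[net_genes, c("stemB", "diffB")] <- pb
    pct[pair_genes, ] <- 0.62          # balanced rank, clear of the
                                       # Booleanization and quartile cuts
  }

  reps <- config$replicates
  sheet <- sample_sheet(
    sample_id = unlist(lapply(names(reps), function(r)
      sprintf("%s_r%d", r, seq_len(reps[[r]])))),
    region = rep(names(reps), times = unlist(reps)),
    replicate = unlist(lapply(unlist(reps), seq_len)))

  noise <- function(k) 2^stats::rnorm(k, 0, config$noise_sd)

  # site A: probe-level microarray-like intensities. Each sample is
  # quantile-normalized onto the platform grid, as an RMA-style
  # normalization would leave it: noise perturbs probe ranks (log2 sd ~
  # noise_sd at mid-distribution) while every sample shares the platform's
  # value distribution.
  probe_gene <- rep(ids, n_probes)
  probe_id <- paste0(probe_gene, "_p",
                     unlist(lapply(n_probes, seq_len)))
  samples_a <- sheet$sample_id[sheet$region %in% c("stemA", "diffA")]
  probe_grid <- sort(q_a(stats::ppoints(length(probe_id))))
  vals_a <- matrix(0, length(probe_id), length(samples_a),
                   dimnames = list(probe_id, samples_a))
  for (s in samples_a) {
    region <- sheet$region[sheet$sample_id == s]
    raw <- q_a(pct[probe_gene, region]) * noise(length(probe_id))
    vals_a[, s] <- probe_grid[rank(raw, ties.method = "first")]
  }
  expr_a <- expression_matrix(vals_a, platform = "microarray")

  # site B: gene-level FPKM-like values
  samples_b <- sheet$sample_id[sheet$region %in% c("stemB", "diffB")]
  vals_b <- matrix(0, n, length(samples_b),
                   dimnames = list(ids, samples_b))
  for (s in samples_b) {
    region <- sheet$region[sheet$sample_id == s]
    vals_b[, s] <- q_b(pct[, region]) * noise(n)
  }
  expr_b <- expression_matrix(vals_b, platform = "rnaseq-fpkm")

  probemap <- probe_map(c(probe_id, ids), c(probe_gene, ids))

  base_p <- base_pct
  if (n_de) base_p[de_genes] <- lo
  if (length(net_genes)) {
    base_p[net_genes] <- (pct[net_genes, "stemA"] +
                            pct[net_genes, "stemB"]) / 2
  }
  if (length(pair_genes)) base_p[pair_genes] <- 0.30
  baseline <- baseline_reference(stats::setNames(
    stats::qlnorm(base_p, meanlog = 5.0, sdlog = sdlog_a), ids))

  truth <- list(
    de = if (n_de) data.frame(
      gene_id = de_genes, up_in = up_site,
      qde_stemA_vs_stemB = ifelse(up_site == "siteA", config$de_shift,
                                  -config$de_shift),
      stringsAsFactors = FALSE) else NULL,
    percentiles = pct,
    sdlog_a = sdlog_a, shape_b = shape_b)

  list(expr_a = expr_a, expr_b = expr_b, sheet = sheet, probemap = probemap,
       baseline = baseline,
       tf_list = sprintf("tf%03d", seq_len(config$n_tfs)),
       truth = truth)
}

#' Plant disbalanced cell-fate-determinant pairs
#'
#' The pair genes already share one stem-state rank (balanced expression);
#' this step breaks the balance in the differentiated regions by multiplying
#' the up-gene's values by `2^pair_magnitude` in both sites' differentiated
#' samples, so each planted pair's true disbalance D equals `pair_magnitude`
#' exactly. The pair genes' baseline rank (0.30) and stem rank (0.55) put
#' the up gene two quartiles above baseline after the split and keep both
#' genes un-depressed in the stem state, so planted pairs satisfy the
#' candidate filter criteria by construction; the partner stays flat.
#'
#' @param expr result of [generate_expression()] (with `network` supplied).
#' @param network result of [generate_prior_network()].
#' @param config the shared [synth_config()].
#' @return `expr` with modified matrices and an added `truth$pairs` table
#'   (gene_up, gene_partner, criterion, true_D).
#' @export
plant_disbalanced_pairs <- function(expr, network, config) {
  stopifnot(inherits(config, "synth_config"))
  roles <- network$truth$pair_roles
  up_all <- c(roles$up_in_scc, roles$up_leaf)
  if (!length(up_all)) {
    expr$truth$pairs <- NULL
    return(expr)
  }
  if (!all(up_all %in% rownames(expr$truth$percentiles))) {
    stop("pair genes exceed the available TF universe")
  }
  fac <- 2^config$pair_magnitude
  diff_a <- expr$sheet$sample_id[expr$sheet$region == "diffA"]
  diff_b <- expr$sheet$sample_id[expr$sheet$region == "diffB"]
  probe_rows_a <- rownames(expr$expr_a$values)
  probe_of <- sub("_p[0-9]+$", "", probe_rows_a)
  expr$expr_a$values[probe_of %in% up_all, diff_a] <-
    expr$expr_a$values[probe_of %in% up_all, diff_a] * fac
  expr$expr_b$values[up_all, diff_b] <-
    expr$expr_b$values[up_all, diff_b] * fac

  pairs <- rbind(
    if (length(roles$up_in_scc)) data.frame(
      gene_up = roles$up_in_scc,
      gene_partner = roles$partner[seq_along(roles$up_in_scc)],
      criterion = "c3", stringsAsFactors = FALSE),
    if (length(roles$up_leaf)) data.frame(
      gene_up = roles$up_leaf,
      gene_partner = roles$partner[seq_along(roles$up_leaf)],
      criterion = "c4", stringsAsFactors = FALSE))
  pairs$true_D <- config$pair_magnitude
  expr$truth$pairs <- pairs
  expr
}

#' Generate the full synthetic dataset
#'
#' Composes [generate_prior_network()], [generate_expression()] and
#' [plant_disbalanced_pairs()] into one seeded dataset with consolidated
#' ground truth.
#'
#' @param config a [synth_config()].
#' @return list with the expression bundle fields, plus `prior`, `states`
#'   and `truth` (expression and network ground truth merged).
#' @export
generate_dataset <- function(config) {
  net <- generate_prior_network(config)
  expr <- generate_expression(config, network = net)
  expr <- plant_disbalanced_pairs(expr, net, config)
  truth <- expr$truth
  truth$network <- net$truth
  list(expr_a = expr$expr_a, expr_b = expr$expr_b, sheet = expr$sheet,
       probemap = expr$probemap, baseline = expr$baseline,
       tf_list = expr$tf_list, prior = net$prior, states = net$states,
       truth = truth)
}
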