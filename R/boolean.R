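#' Boolean phenotype state
#'
#' Gene -> \{0, 1\} vector used as an attractor target during
#' contextualization.
#'
#' @param x named vector coercible to 0/1.
#' @param label optional phenotype label (e.g. a region name).
#' @return named integer 0/1 vector of class `boolean_state`.
#' @export
boolean_state <- function(x, label = NULL) {
  if (is.null(names(x))) stop("state must be named by gene id")
  v <- as.integer(x)
  if (anyNA(v) || !all(v %in% c(0L, 1L))) stop("state values must be 0 or 1")
  structure(stats::setNames(v, names(x)), class = "boolean_state",
            label = label)
}

#' Booleanize a quartile profile
#'
#' A gene is ON when its quartile expression reaches `on_threshold`
#' (default: upper half, QE >= 3).
#'
#' @param qe named integer vector of QE values for one region.
#' @param genes genes the state must cover (default: all in `qe`).
#' @param on_threshold minimal QE mapped to ON.
#' @param label phenotype label.
#' @return a [boolean_state()].
#' @export
booleanize <- function(qe, genes = names(qe), on_threshold = 3L,
                       label = NULL) {
  missing <- setdiff(genes, names(qe))
  if (length(missing)) {
    stop(sprintf("genes missing from quartile profile: %s",
                 paste(missing, collapse = ", ")))
  }
  boolean_state(stats::setNames(as.integer(qe[genes] >= on_threshold), genes),
                label = label)
}

# Pre-indexed edge representation used by the update rule and the GA.
# sign_num: +1 activation, -1 inhibition, 0 unassigned.
edge_index <- function(net, nodes = net$nodes) {
  e <- net$edges
  list(nodes = nodes,
       n = length(nodes),
       src = match(e$source, nodes),
       tgt = match(e$target, nodes),
       sign = c(activation = 1L, inhibition = -1L,
                unassigned = 0L)[e$sign])
}

majority_next <- function(state_vec, idx, keep = NULL, sign = idx$sign,
                          no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  active <- state_vec[idx$src] == 1L
  if (!is.null(keep)) active <- active & keep
  a <- tabulate(idx$tgt[active & sign > 0L], nbins = idx$n)
  i <- tabulate(idx$tgt[active & sign < 0L], nbins = idx$n)
  nxt <- ifelse(a > i, 1L,
                ifelse(a + i == 0L,
                       if (no_input == "hold") state_vec else 0L,
                       0L))
  as.integer(nxt)
}

#' Synchronous majority-rule update
#'
#' All genes update simultaneously. For each gene the number of activating
#' edges (a) and inhibiting edges (i) whose source is currently ON are
#' compared: the gene switches ON when a > i, OFF when i > a, and OFF on a
#' tie with at least one active input (inhibition dominates ties). A gene
#' with no active input holds its current value by default (`no_input =
#' "hold"`), so an observed state cannot decay spontaneously; `"decay"`
#' switches such genes OFF instead. OFF regulators exert no influence.
#'
#' @param state a [boolean_state()] covering all network nodes.
#' @param net a `grn` with fully assigned signs.
#' @param no_input `"hold"` (default) or `"decay"`.
#' @return the successor [boolean_state()].
#' @export
majority_update <- function(state, net, no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  if (any(net$edges$sign == "unassigned")) {
    stop("majority_update requires fully assigned edge signs")
  }
  missing <- setdiff(net$nodes, names(state))
  if (length(missing)) {
    stop(sprintf("state does not cover nodes: %s",
                 paste(missing, collapse = ", ")))
  }
  idx <- edge_index(net)
  s <- as.integer(state[net$nodes])
  boolean_state(stats::setNames(
    majority_next(s, idx, no_input = no_input), net$nodes),
    label = attr(state, "label"))
}

#' Fixed-point test
#'
#' A state is a fixed point (attractor of the synchronous dynamics) when the
#' majority-rule update reproduces it exactly.
#'
#' @inheritParams majority_update
#' @return list with `fixed` (logical) and `violating` (gene ids whose update
#'   disagrees with the state).
#' @export
is_fixed_point <- function(state, net, no_input = c("hold", "decay")) {
  nxt <- majority_update(state, net, no_input = no_input)
  bad <- net$nodes[nxt[net$nodes] != state[net$nodes]]
  list(fixed = length(bad) == 0L, violating = bad)
}

#' Synchronous Boolean trajectory
#'
#' Iterates the majority-rule update from a start state until a state repeats
#' (guaranteed within 2^n steps) or `max_steps` is exhausted, and classifies
#' the terminal behaviour as a fixed point or a limit cycle with its period.
#'
#' @inheritParams majority_update
#' @param max_steps maximal number of updates (>= 1).
#' @return list with `trajectory` (matrix, one row per visited state),
#'   `classification` (`"fixed_point"`, `"limit_cycle"` or `"truncated"`) and
#'   `period` (1 for a fixed point).
#' @export
simulate_boolean <- function(state, net, max_steps = 1000L,
                             no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  stopifnot(max_steps >= 1L)
  nodes <- net$nodes
  seen <- character(0L)
  traj <- list()
  cur <- boolean_state(state[nodes])
  for (step in seq_len(max_steps + 1L)) {
    key <- paste(cur, collapse = "")
    hit <- match(key, seen)
    if (!is.na(hit)) {
      period <- length(seen) - hit + 1L
      tm <- do.call(rbind, traj)
      colnames(tm) <- nodes
      return(list(trajectory = tm,
                  classification = if (period == 1L) "fixed_point"
                                   else "limit_cycle",
                  period = period))
    }
    seen <- c(seen, key)
    traj[[length(traj) + 1L]] <- as.integer(cur)
    cur <- majority_update(cur, net, no_input = no_input)
  }
  tm <- do.call(rbind, traj)
  colnames(tm) <- nodes
  list(trajectory = tm, classification = "truncated", period = NA_integer_)
}

#' Consistency of a network with observed Boolean states
#'
#' For each observed phenotype state, the fraction of genes whose
#' majority-rule update reproduces their observed value; the overall score is
#' the mean across states. A score of 1 means every state is a fixed point.
#'
#' @param net a `grn` with fully assigned signs.
#' @param states list of [boolean_state()] objects covering the nodes.
#' @param no_input no-active-input rule, see [majority_update()].
#' @return list with `per_state` (named fractions), `overall`,
#'   `inconsistent` (list of violating gene ids per state).
#' @export
consistency_score <- function(net, states, no_input = c("hold", "decay")) {
  no_input <- match.arg(no_input)
  if (!length(states)) stop("need at least one state")
  res <- lapply(states, is_fixed_point, net = net, no_input = no_input)
  frac <- vapply(seq_along(states), function(i) {
    1 - length(res[[i]]$violating) / length(net$nodes)
  }, numeric(1L))
  labels <- vapply(seq_along(states), function(i) {
    lb <- attr(states[[i]], "label")
    if (is.null(lb)) paste0("state", i) else lb
  }, character(1L))
  names(frac) <- labels
  list(per_state = frac, overall = mean(frac),
       inconsistent = stats::setNames(lapply(res, `[[`, "violating"), labels))
}
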