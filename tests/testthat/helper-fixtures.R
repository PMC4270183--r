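# Small builders shared across tests.

toy_edges <- function(...) {
  rows <- list(...)
  if (!length(rows)) {
    return(data.frame(source = character(), target = character(),
                      type = character(), sign = character(),
                      stringsAsFactors = FALSE))
  }
  do.call(rbind, lapply(rows, function(r) {
    data.frame(source = r[[1L]], target = r[[2L]],
               type = if (length(r) >= 4L) r[[4L]] else
                 "transcription_regulation",
               sign = r[[3L]], stringsAsFactors = FALSE)
  }))
}

toy_net <- function(..., nodes = NULL) {
  prior_network(toy_edges(...), nodes = nodes)
}

state_of <- function(..., label = NULL) {
  boolean_state(c(...), label = label)
}

# a configuration small enough for fast tests but structurally complete
quick_config <- function(seed, ...) {
  synth_config(n_genes = 1500L, n_tfs = 150L, seed = seed, ...)
}

pair_key <- function(g1, g2) paste(pmin(g1, g2), pmax(g1, g2))
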