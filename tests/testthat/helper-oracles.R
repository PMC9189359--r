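# Independent oracles and small fixture builders used across the suite.
# These deliberately avoid the package's own code paths.

# Classic two-term running sum: P_hit(i) - P_miss(i).
oracle_es_curve <- function(delta, r, p) {
  n <- length(delta)
  w <- abs(delta)^p
  N_R <- sum(w[r == 1])
  N_H <- sum(r)
  if (N_R == 0) return(numeric(n))
  p_hit <- cumsum(ifelse(r == 1, w, 0)) / N_R
  p_miss <- if (N_H == n) numeric(n) else cumsum(r == 0) / (n - N_H)
  p_hit - p_miss
}

# All simple directed paths of length 1..max_len, by exhaustive DFS over
# an edge list (data frame source/target).
oracle_paths <- function(genes, edges, max_len) {
  out <- list()
  extend <- function(path) {
    out[[length(out) + 1L]] <<- path
    if (length(path) >= max_len) return(invisible())
    last <- path[length(path)]
    nbr <- sort(edges$target[edges$source == last])
    for (g in nbr) if (!g %in% path) extend(c(path, g))
  }
  for (g in genes) extend(g)
  out
}

# String-matching support: pad symbols with separators so contiguous
# subsequence containment becomes substring containment.
oracle_support <- function(candidate, chains) {
  pad <- function(x) paste0(" ", paste(x, collapse = " "), " ")
  sum(vapply(chains, function(t) grepl(pad(candidate), pad(t), fixed = TRUE),
             logical(1L)))
}

# Enumerate-and-threshold frequent chains: every contiguous subchain of
# every transaction, counted by oracle_support, kept at >= min_support.
oracle_frequent <- function(chains, min_support) {
  cand <- list()
  for (t in chains) {
    n <- length(t)
    for (a in seq_len(n)) for (b in a:n)
      cand[[length(cand) + 1L]] <- t[a:b]
  }
  keys <- vapply(cand, paste, character(1L), collapse = " ")
  cand <- cand[!duplicated(keys)]
  supp <- vapply(cand, oracle_support, integer(1L), chains = chains)
  keep <- supp >= min_support
  list(chains = cand[keep], support = supp[keep])
}

chain_keys <- function(chains) sort(vapply(chains, paste, character(1L),
                                           collapse = " "))

# A small counts table written to a temp TSV.
write_counts_tsv <- function(df, path = tempfile(fileext = ".tsv")) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

# The worked-example graph, built once per test that needs it.
wx_graph <- function() build_graph(worked_example()$records)

wx_transactions <- function()
  generate_transactions(c("A", "B", "C", "D"), wx_graph(), max_len = 4)

# Random ranked list with iid normal deltas under the current RNG state.
random_ranked <- function(n) {
  rank_genes(delta_vector(sprintf("g%03d", seq_len(n)), rnorm(n)))
}

# Random signed graph over k nodes at the given directed edge probability.
random_graph_records <- function(k, prob) {
  genes <- LETTERS[seq_len(k)]
  pairs <- expand.grid(source = genes, target = genes,
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$source != pairs$target, ]
  pick <- runif(nrow(pairs)) < prob
  pairs <- pairs[pick, , drop = FALSE]
  if (!nrow(pairs))
    return(interaction_records(character(0), character(0), integer(0)))
  interaction_records(pairs$source, pairs$target,
                      sample(c(-1L, 1L), nrow(pairs), replace = TRUE))
}
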