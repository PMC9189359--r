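# Apriori mining of frequent interaction chains and the d = delta M
# statistic that ranks them.

# is `sub` a contiguous subsequence of `txn`?
.contains_contiguous <- function(sub, txn) {
  k <- length(sub); n <- length(txn)
  if (k > n) return(FALSE)
  for (s in 0:(n - k)) {
    if (all(txn[s + seq_len(k)] == sub)) return(TRUE)
  }
  FALSE
}

#' Support of a candidate chain
#'
#' The number of transactions (over all lengths) that contain the
#' candidate as a contiguous subsequence; each transaction counts at most
#' once. Contiguous containment is anti-monotone: a sub-chain's support is
#' never below that of any chain extending it, which is what the Apriori
#' pruning step relies on.
#'
#' @param candidate character vector (ordered gene chain).
#' @param transactions a `transaction_set` (or plain list of chains).
#' @return nonnegative integer support.
#' @export
chain_support <- function(candidate, transactions) {
  candidate <- as.character(candidate)
  chains <- if (inherits(transactions, "transaction_set"))
    unlist(unclass(transactions), recursive = FALSE) else transactions
  if (is.null(chains)) return(0L)
  sum(vapply(chains, function(t) .contains_contiguous(candidate, t),
             logical(1L)))
}

.chain_key <- function(chain) paste(chain, collapse = "\t")

#' Two-step Apriori over interaction chains
#'
#' Level by level (i = 1 ... t): the level-i candidates are the distinct
#' level-i transactions still present; those with support at or above
#' `min_support` join the frequent set `F`, the rest join the infrequent
#' set `Fbar`. Before the next level is scored, every transaction at
#' level i+1 that contains a member of `Fbar` as a contiguous subsequence
#' is removed (the Apriori principle: a super-pattern of an infrequent
#' pattern cannot be frequent). Support is always counted over the full
#' original transaction set; pruning removes candidates, not occurrences.
#' The iteration stops when a level has no candidates left.
#'
#' @param transactions a `transaction_set` from [generate_transactions()].
#' @param min_support minimum support threshold (default 3).
#' @return a list of class `"apriori_state"`: `F` (list of frequent
#'   chains, level order), `Fbar` (infrequent chains), `support` (named
#'   integer vector keyed by tab-joined chain), `min_support`, and
#'   `trace` (per-level candidates, supports, and removed transactions).
#' @export
apriori <- function(transactions, min_support = 3) {
  stopifnot(inherits(transactions, "transaction_set"))
  if (min_support < 1) stop("min_support must be >= 1")
  min_support <- as.integer(min_support)
  all_chains <- unlist(unclass(transactions), recursive = FALSE)
  if (is.null(all_chains)) all_chains <- list()
  t_max <- length(unclass(transactions))
  current <- unclass(transactions)             # working copy, pruned in place
  F_set <- list(); Fbar <- list()
  supp <- integer(0)
  trace <- list()
  for (i in seq_len(t_max)) {
    level <- current[[i]]
    if (!length(level)) break
    keys <- vapply(level, .chain_key, character(1L))
    cand <- level[!duplicated(keys)]
    cs <- vapply(cand, chain_support, integer(1L),
                 transactions = all_chains)
    names(cs) <- vapply(cand, .chain_key, character(1L))
    supp <- c(supp, cs)
    freq <- cs >= min_support
    F_set <- c(F_set, cand[freq])
    new_infreq <- cand[!freq]
    Fbar <- c(Fbar, new_infreq)
    removed <- character(0)
    if (i < t_max && length(Fbar)) {
      keep <- vapply(current[[i + 1L]], function(txn)
        !any(vapply(Fbar, .contains_contiguous, logical(1L), txn = txn)),
        logical(1L))
      removed <- vapply(current[[i + 1L]][!keep], .chain_key, character(1L))
      current[[i + 1L]] <- current[[i + 1L]][keep]
    }
    trace[[i]] <- list(level = i,
                       candidates = vapply(cand, .chain_key, character(1L)),
                       support = cs, removed_next = removed)
  }
  structure(list(F = F_set, Fbar = Fbar, support = supp,
                 min_support = min_support, trace = trace),
            class = "apriori_state")
}

#' @export
print.apriori_state <- function(x, ...) {
  card <- vapply(x$F, length, integer(1L))
  cat(sprintf("Apriori result: %d frequent chains (min_support = %d)\n",
              length(x$F), x$min_support))
  if (length(card)) print(table(cardinality = card))
  invisible(x)
}

#' The statistic d = delta M
#'
#' Row-vector-times-matrix product of a chain's log2 fold-changes with its
#' signed correlation matrix. Component j of `d` accumulates the deltas of
#' every chain gene acting on gene j (signed), plus gene j's own delta:
#' concordance between prior interaction signs and observed expression
#' changes makes components large, discordance cancels them.
#'
#' @param delta_sub numeric deltas of the chain's genes, in chain order.
#' @param M the chain's [correlation_matrix()].
#' @return numeric vector `d` of the chain's length.
#' @export
d_statistic <- function(delta_sub, M) {
  if (!is.matrix(M) || nrow(M) != ncol(M)) stop("M must be square")
  if (length(delta_sub) != nrow(M))
    stop("delta_sub length does not match M dimension")
  as.vector(delta_sub %*% M)
}

#' Euclidean norm of d
#'
#' For a single gene this reduces to `|delta|`.
#'
#' @param d numeric vector.
#' @return `sqrt(sum(d^2))`.
#' @export
d_norm <- function(d) sqrt(sum(d^2))

#' Rank frequent chains by \|d\| within each cardinality
#'
#' \|d\| grows with chain length, so chains are only comparable within
#' the same cardinality: records are grouped by chain length and sorted by
#' descending \|d\|, ties broken lexicographically by the chain's
#' symbols. No rank is ever assigned across cardinalities.
#'
#' @param records a `frequent_sets` data frame (see [refine()]), or any
#'   data frame with list-column `chain` and columns `cardinality`,
#'   `d_norm`.
#' @return the same frame, reordered, with `rank_within_cardinality`
#'   recomputed.
#' @export
rank_frequent <- function(records) {
  stopifnot(is.data.frame(records),
            all(c("cardinality", "d_norm", "chain") %in% names(records)))
  if (!nrow(records)) {
    records$rank_within_cardinality <- integer(0)
    return(records)
  }
  key <- vapply(records$chain, .chain_key, character(1L))
  ord <- order(records$cardinality, -records$d_norm, key, method = "radix")
  out <- records[ord, , drop = FALSE]
  out$rank_within_cardinality <- stats::ave(
    seq_len(nrow(out)), out$cardinality, FUN = seq_along)
  rownames(out) <- NULL
  out
}

#' Refine a leading-edge union into ranked frequent interaction chains
#'
#' The full refinement stage: generate all interaction chains among the
#' leading-edge genes, mine frequent chains with [apriori()], then score
#' every frequent chain by `d = delta M` and rank within each
#' cardinality. Deterministic given its inputs.
#'
#' @param l a `leading_union` (columns `gene`, `delta`) from
#'   [union_leading_edges()], or a data frame with those columns.
#' @param graph an [build_graph()] result (typically restricted to the
#'   union's genes).
#' @param min_support Apriori support threshold (default 3).
#' @param max_len maximum chain length (default 4).
#' @return a data frame of class `"frequent_sets"` with columns
#'   `cardinality`, `chain` (list-column), `support`, `d_vector`
#'   (list-column), `d_norm`, `rank_within_cardinality`; the
#'   `apriori_state` is carried in the `"state"` attribute.
#' @export
refine <- function(l, graph, min_support = 3, max_len = 4) {
  stopifnot(is.data.frame(l), all(c("gene", "delta") %in% names(l)))
  delta <- stats::setNames(l$delta, l$gene)
  tx <- generate_transactions(l$gene, graph, max_len = max_len)
  st <- apriori(tx, min_support = min_support)
  n <- length(st$F)
  out <- data.frame(cardinality = vapply(st$F, length, integer(1L)),
                    support = unname(st$support[vapply(st$F, .chain_key,
                                                       character(1L))]))
  out$chain <- st$F
  out$d_vector <- lapply(st$F, function(chain) {
    M <- correlation_matrix(chain, graph)
    d_statistic(unname(delta[chain]), M)
  })
  out$d_norm <- vapply(out$d_vector, d_norm, numeric(1L))
  out$rank_within_cardinality <- rep(NA_integer_, nrow(out))
  out <- rank_frequent(out)
  out <- out[, c("cardinality", "chain", "support", "d_vector", "d_norm",
                 "rank_within_cardinality")]
  attr(out, "state") <- st
  class(out) <- c("frequent_sets", "data.frame")
  out
}

#' @export
print.frequent_sets <- function(x, ...) {
  cat(sprintf("Frequent interaction chains: %d records\n", nrow(x)))
  if (nrow(x)) {
    df <- data.frame(cardinality = x$cardinality,
                     chain = vapply(x$chain, paste, character(1L),
                                    collapse = "->"),
                     support = x$support,
                     d_norm = signif(x$d_norm, 6L),
                     rank = x$rank_within_cardinality)
    print(utils::head(df, 12L))
    if (nrow(df) > 12L) cat("...", nrow(df) - 12L, "more rows\n")
  }
  invisible(x)
}
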