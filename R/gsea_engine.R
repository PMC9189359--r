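# Running-sum enrichment engine: ES recurrence, signed maximum, permutation
# null distributions, empirical p-values, leading-edge subsets.

#' Membership indicator over a ranked list
#'
#' Marks each position of the ranked list that belongs to the gene set and
#' carries the two normalising totals used by the running sum: `N_H`, the
#' number of hits, and `N_R = sum(r * |delta|^p)`, the total hit weight.
#' Set members absent from the ranked list are ignored (intersection
#' semantics).
#'
#' @param ranked a `ranked_list`.
#' @param members character vector of set member symbols.
#' @param p weight exponent in `[0, 1]` (default 1).
#' @return a list of class `"indicator"` with fields `r` (0/1 integer
#'   vector), `N_H`, `N_R`, `p`.
#' @export
indicator <- function(ranked, members, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  .check_p(p)
  r <- as.integer(ranked$gene %in% members)
  structure(list(r = r, N_H = sum(r),
                 N_R = sum(r * abs(ranked$delta)^p), p = p),
            class = "indicator")
}

.check_p <- function(p) {
  if (!is.numeric(p) || length(p) != 1L || !is.finite(p) || p < 0 || p > 1)
    stop("weight exponent p must be a single number in [0, 1]")
}

#' Running-sum enrichment score curve
#'
#' Iterates the recurrence `es_i = r_i |delta_i|^p / N_R +
#' (r_i - 1) / (n - N_H) + es_{i-1}` from `es_0 = 0`: hits step up in
#' proportion to their weighted delta, misses step down by the uniform
#' miss penalty. By construction `es_n = 0` whenever `N_R > 0`. When
#' `N_R = 0` (no set member carries weight) the whole curve is defined as
#' zero to avoid the division by zero; when every gene is a hit
#' (`N_H = n`) the miss term is never evaluated.
#'
#' @param delta numeric vector of ranked expression differences.
#' @param r an [indicator()] or a 0/1 vector aligned to `delta`.
#' @param p weight exponent in `[0, 1]`; ignored (taken from `r`) when `r`
#'   is an `indicator`.
#' @return numeric vector `es` of the same length as `delta`.
#' @export
es_curve <- function(delta, r, p = 1) {
  if (inherits(r, "indicator")) { p <- r$p; r <- r$r }
  .check_p(p)
  n <- length(delta)
  if (length(r) != n) stop("delta and r have different lengths")
  r <- as.integer(r)
  N_H <- sum(r)
  w <- abs(delta)^p
  N_R <- sum(r * w)
  if (N_R == 0) return(numeric(n))
  miss <- if (N_H == n) 0 else 1 / (n - N_H)
  es <- numeric(n)
  prev <- 0
  for (i in seq_len(n)) {
    prev <- r[i] * w[i] / N_R + (r[i] - 1) * miss + prev
    es[i] <- prev
  }
  es
}

#' Signed maximum of an ES curve
#'
#' Returns `sign(es_k) * max|es_i|` with `k` the first index attaining the
#' maximum absolute value (ties break to the smallest index). An all-zero
#' curve yields `es_max = 0` at peak index 1.
#'
#' @param curve numeric ES curve.
#' @return list with `es_max` (signed) and `peak_index` (1-based).
#' @export
es_max <- function(curve) {
  if (!length(curve)) stop("empty ES curve")
  k <- which.max(abs(curve))          # first maximum
  list(es_max = curve[k], peak_index = as.integer(k))
}

# Fast |es_max| for permutations: the curve is piecewise linear and only
# needs evaluating at hit positions (curve value there) and just before
# each hit (the local minima). O(N_H) per permutation instead of O(n).
.abs_es_max_at <- function(w, idx, n, N_H, N_R) {
  if (N_H == 0L || N_R == 0) return(0)
  idx <- sort.int(idx)
  k <- seq_len(N_H)
  ch <- cumsum(w[idx]) / N_R
  if (N_H == n) return(max(abs(ch)))
  miss <- 1 / (n - N_H)
  at_hit <- ch - (idx - k) * miss
  before_hit <- c(0, ch[-N_H]) - (idx - k) * miss  # es at position idx-1
  max(abs(at_hit), abs(before_hit))
}

#' Permutation null distribution of |es_max|
#'
#' Draws `v` uniform random reorderings of the gene labels against the
#' fixed delta positions (equivalent to redrawing the hit positions of the
#' indicator vector), records `|es'_max|` for each, and returns them
#' sorted ascending. The generator is seeded, so a given
#' `(ranked, members, v, seed)` always yields the same distribution, and
#' increasing `v` extends rather than reshuffles the sequence.
#'
#' @param ranked a `ranked_list`.
#' @param members gene set member symbols.
#' @param v number of permutations (>= 1).
#' @param seed integer RNG seed.
#' @param p weight exponent in `[0, 1]`.
#' @return a list of class `"null_dist"` with fields `values` (sorted
#'   ascending, length `v`), `v`, `seed`.
#' @export
permutation_null <- function(ranked, members, v, seed, p = 1) {
  stopifnot(inherits(ranked, "ranked_list"))
  if (!is.numeric(v) || v < 1) stop("v must be >= 1")
  v <- as.integer(v)
  .check_p(p)
  n <- nrow(ranked)
  N_H <- sum(ranked$gene %in% members)
  w <- abs(ranked$delta)^p
  vals <- numeric(v)
  if (N_H > 0L && n > 0L) {
    old <- .save_rng()
    on.exit(.restore_rng(old), add = TRUE)
    set.seed(seed)
    for (b in seq_len(v)) {
      idx <- sample.int(n, N_H)
      N_R <- sum(w[idx])
      vals[b] <- .abs_es_max_at(w, idx, n, N_H, N_R)
    }
  }
  structure(list(values = sort(vals), v = v, seed = as.integer(seed)),
            class = "null_dist")
}

.save_rng <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}

.restore_rng <- function(old) {
  if (is.null(old)) {
    if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  } else assign(".Random.seed", old, envir = globalenv())
}

#' Empirical permutation p-value
#'
#' `p = 1 - F_v(observed)` where `F_v` is the empirical CDF of the null
#' `|es'_max|` values: the fraction of null values strictly greater than
#' the observation. The plain empirical CDF is used, so `p = 0` is
#' attainable when the observation exceeds every null value; `v` is kept
#' alongside in the result objects for that reason.
#'
#' @param observed_abs nonnegative observed `|es_max|`.
#' @param null a [permutation_null()] result.
#' @return p-value in `[0, 1]`.
#' @export
empirical_p <- function(observed_abs, null) {
  if (!inherits(null, "null_dist") || length(null$values) == 0L)
    stop("null distribution is empty")
  if (observed_abs < 0) stop("observed |es_max| must be nonnegative")
  mean(null$values > observed_abs)
}

#' Leading-edge subset of a gene set
#'
#' The set members that drive the enrichment signal: for a positive
#' `es_max` the hits at or before the peak, for a negative `es_max` the
#' hits at or after the peak, and the empty set when `es_max = 0`. The
#' `"paper_strict"` mode uses the strictly-before convention (`j < i`) on
#' the positive side, which returns an empty leading edge whenever the
#' peak itself is the first hit; the default `"inclusive"` mode (`j <= i`,
#' the classic GSEA convention) includes the peak hit.
#'
#' @param ranked a `ranked_list`.
#' @param r an [indicator()] or 0/1 vector aligned to `ranked`.
#' @param es_max signed maximum enrichment score.
#' @param peak_index 1-based position of the maximum.
#' @param mode `"inclusive"` (default) or `"paper_strict"`.
#' @return character vector of leading-edge genes in rank order.
#' @export
leading_edge <- function(ranked, r, es_max, peak_index,
                         mode = c("inclusive", "paper_strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranked, "ranked_list"))
  if (inherits(r, "indicator")) r <- r$r
  n <- nrow(ranked)
  if (peak_index < 1L || peak_index > max(n, 1L)) stop("invalid peak index")
  if (es_max == 0) return(character(0))
  keep <- if (es_max > 0) {
    if (mode == "inclusive") which(r == 1L & seq_len(n) <= peak_index)
    else                     which(r == 1L & seq_len(n) <  peak_index)
  } else {
    which(r == 1L & seq_len(n) >= peak_index)
  }
  ranked$gene[keep]
}

#' Run GSEA over a gene set collection
#'
#' For every set: indicator vector, ES curve via the running-sum
#' recurrence, signed maximum, permutation null of size `v`, empirical
#' p-value and leading edge. A Benjamini-Hochberg FDR column is attached
#' as supplementary output but is never used for selection (selection is
#' by raw p-value, see [union_leading_edges()]). Each set draws its
#' permutations from a seed derived deterministically from `seed` and the
#' set's position, so results are reproducible and independent of the
#' collection's other members.
#'
#' @param ranked a `ranked_list`.
#' @param collection a [gene_set_collection()].
#' @param p weight exponent in `[0, 1]` (default 1).
#' @param v permutations per set (default 1000).
#' @param seed integer base seed.
#' @param mode leading-edge mode, `"inclusive"` or `"paper_strict"`.
#' @return a data frame of class `"gsea_result"` with columns `set_id`,
#'   `es_max`, `peak_index`, `p_value`, `bh_fdr`, `n_hits` and the
#'   list-column `leading_edge`; the ranked list, `v`, `p`, `seed` and
#'   `mode` are carried in attributes.
#' @export
run_gsea <- function(ranked, collection, p = 1, v = 1000, seed = 1,
                     mode = c("inclusive", "paper_strict")) {
  mode <- match.arg(mode)
  stopifnot(inherits(ranked, "ranked_list"),
            inherits(collection, "gene_set_collection"))
  .check_p(p)
  ids <- names(collection$sets)
  if (!length(ids)) {
    warning("empty gene set collection; no results")
    out <- data.frame(set_id = character(0), es_max = numeric(0),
                      peak_index = integer(0), p_value = numeric(0),
                      bh_fdr = numeric(0), n_hits = integer(0))
    out$leading_edge <- list()
  } else {
    rows <- vector("list", length(ids))
    for (i in seq_along(ids)) {
      members <- collection$sets[[i]]
      ind <- indicator(ranked, members, p = p)
      curve <- es_curve(ranked$delta, ind)
      pk <- es_max(curve)
      null <- permutation_null(ranked, members, v = v,
                               seed = .derive_seed(seed, members), p = p)
      # a set with no weighted hits carries no evidence: p = 1 by convention
      # (otherwise the all-zero null would make the zero observation "extreme")
      pv <- if (pk$es_max == 0) 1 else empirical_p(abs(pk$es_max), null)
      le <- leading_edge(ranked, ind, pk$es_max, pk$peak_index, mode = mode)
      rows[[i]] <- list(set_id = ids[i], es_max = pk$es_max,
                        peak_index = pk$peak_index, p_value = pv,
                        n_hits = ind$N_H, leading_edge = le)
    }
    out <- data.frame(
      set_id = vapply(rows, `[[`, character(1L), "set_id"),
      es_max = vapply(rows, `[[`, numeric(1L), "es_max"),
      peak_index = vapply(rows, `[[`, integer(1L), "peak_index"),
      p_value = vapply(rows, `[[`, numeric(1L), "p_value"),
      stringsAsFactors = FALSE)
    out$bh_fdr <- stats::p.adjust(out$p_value, method = "BH")
    out$n_hits <- vapply(rows, `[[`, integer(1L), "n_hits")
    out$leading_edge <- lapply(rows, `[[`, "leading_edge")
  }
  attr(out, "ranked") <- ranked
  attr(out, "v") <- as.integer(v)
  attr(out, "p") <- p
  attr(out, "seed") <- as.integer(seed)
  attr(out, "mode") <- mode
  class(out) <- c("gsea_result", "data.frame")
  out
}

# deterministic per-set child seed derived from the base seed and the set's
# membership (so identical sets share a permutation stream regardless of
# their position in the collection); kept inside 32-bit integer range
.derive_seed <- function(seed, members) {
  h <- 5381
  for (code in utf8ToInt(paste(sort(unique(members)), collapse = ",")))
    h <- (h * 33 + code) %% 2147483647
  as.integer((as.numeric(seed) * 48271 + h) %% 2147483647)
}

#' Union of leading-edge subsets over significant pathways
#'
#' Pools the leading-edge genes of every result with raw `p < alpha`,
#' deduplicates, orders by each gene's best (smallest) rank position, and
#' carries each gene's delta along for the downstream `d = delta M`
#' statistic.
#'
#' @param results a `gsea_result` from [run_gsea()].
#' @param alpha raw p-value threshold (default 0.05; `alpha = 1` disables
#'   the filter).
#' @return a data frame of class `"leading_union"` with columns `gene`,
#'   `delta`, `best_rank`.
#' @export
union_leading_edges <- function(results, alpha = 0.05) {
  stopifnot(inherits(results, "gsea_result"))
  ranked <- attr(results, "ranked")
  sig <- results$p_value < alpha
  genes <- unique(unlist(results$leading_edge[sig], use.names = FALSE))
  if (is.null(genes)) genes <- character(0)
  pos <- match(genes, ranked$gene)
  ord <- order(pos)
  out <- data.frame(gene = genes[ord], delta = ranked$delta[pos][ord],
                    best_rank = ranked$rank[pos][ord],
                    stringsAsFactors = FALSE)
  class(out) <- c("leading_union", "data.frame")
  out
}
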