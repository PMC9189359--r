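# Signed interaction graph, correlation matrices, and chain (transaction)
# generation over leading-edge genes.

#' Build a signed directed interaction graph
#'
#' Collapses interaction records into at most one signed edge per ordered
#' gene pair. Concordant duplicates are deduplicated; a pair recorded with
#' both signs is contradictory and resolved to *no* edge with a warning
#' (the conservative reading: evidence cancels). Self-loops are never
#' admitted.
#'
#' @param records an `interaction_records` data frame (see
#'   [read_interaction_network()]).
#' @param restrict_to optional gene set; when given, only edges with both
#'   endpoints in the set are kept and the node set is exactly
#'   `restrict_to`.
#' @return a list of class `"interaction_graph"` with fields `nodes`
#'   (character), `edges` (data frame `source`, `target`, `sign`) and
#'   `adj` (per-node named sign vector of out-neighbours, lexicographic).
#' @export
build_graph <- function(records, restrict_to = NULL) {
  stopifnot(is.data.frame(records),
            all(c("source", "target", "sign") %in% names(records)))
  df <- data.frame(source = as.character(records$source),
                   target = as.character(records$target),
                   sign = as.integer(records$sign), stringsAsFactors = FALSE)
  df <- df[df$source != df$target, , drop = FALSE]
  if (!is.null(restrict_to)) {
    restrict_to <- unique(as.character(restrict_to))
    df <- df[df$source %in% restrict_to & df$target %in% restrict_to, ,
             drop = FALSE]
  }
  key <- paste(df$source, df$target, sep = "\r")
  df <- df[!duplicated(paste(key, df$sign)), , drop = FALSE]
  key <- paste(df$source, df$target, sep = "\r")
  conflict <- key[duplicated(key)]
  if (length(conflict)) {
    warning(length(unique(conflict)),
            " gene pair(s) with contradictory signs removed from the graph")
    df <- df[!key %in% conflict, , drop = FALSE]
  }
  nodes <- if (is.null(restrict_to)) sort(unique(c(df$source, df$target)))
           else restrict_to
  df <- df[order(df$source, df$target), , drop = FALSE]
  rownames(df) <- NULL
  adj <- lapply(split(stats::setNames(df$sign, df$target), df$source),
                function(v) v[order(names(v))])
  structure(list(nodes = nodes, edges = df, adj = adj),
            class = "interaction_graph")
}

#' @export
print.interaction_graph <- function(x, ...) {
  cat(sprintf("Interaction graph: %d nodes, %d signed edges (%d up, %d down)\n",
              length(x$nodes), nrow(x$edges), sum(x$edges$sign == 1L),
              sum(x$edges$sign == -1L)))
  invisible(x)
}

# sign of edge a -> b, or 0L if absent
.edge_sign <- function(graph, a, b) {
  v <- graph$adj[[a]]
  if (is.null(v)) return(0L)
  s <- v[b]
  if (is.na(s)) 0L else as.integer(s)
}

#' Correlation matrix of an ordered gene tuple
#'
#' The k x k matrix `M` over the tuple, with `a_ii = 1` and, for
#' `i != j`, `a_ij = +1` when gene i upregulates gene j, `-1` when it
#' downregulates it, and `0` when it has no recorded effect. All ordered
#' pairs of the tuple are looked up, not only consecutive chain edges, so
#' `M` captures shortcut interactions inside a chain.
#'
#' @param tuple ordered character vector of distinct gene symbols.
#' @param graph an [build_graph()] result.
#' @return integer matrix with `dimnames` equal to the tuple.
#' @export
correlation_matrix <- function(tuple, graph) {
  tuple <- as.character(tuple)
  if (!length(tuple)) stop("tuple must be nonempty")
  if (anyDuplicated(tuple)) stop("repeated gene in tuple")
  k <- length(tuple)
  M <- diag(1L, k)
  for (i in seq_len(k)) for (j in seq_len(k)) if (i != j)
    M[i, j] <- .edge_sign(graph, tuple[i], tuple[j])
  dimnames(M) <- list(tuple, tuple)
  M
}

#' Generate interaction chains (transactions) from a gene vector
#'
#' Level 1 holds one singleton chain per input gene (input order). Level
#' i+1 extends every level-i chain by each out-neighbour of its last gene
#' (lexicographic neighbour order), skipping extensions that would revisit
#' a gene already in the chain, so every chain is a simple signed path.
#' Enumeration order is deterministic, making transaction files
#' byte-stable across runs.
#'
#' @param l gene vector: a character vector or a `leading_union` data
#'   frame (its `gene` column is used).
#' @param graph an [build_graph()] result.
#' @param max_len maximum chain length (default 4).
#' @return a list of class `"transaction_set"`: element i is the list of
#'   length-i chains (character vectors).
#' @export
generate_transactions <- function(l, graph, max_len = 4) {
  if (is.data.frame(l)) l <- l$gene
  l <- as.character(l)
  if (anyDuplicated(l)) stop("duplicate genes in input vector")
  if (max_len < 1) stop("max_len must be >= 1")
  max_len <- as.integer(max_len)
  levels <- vector("list", max_len)
  levels[[1L]] <- lapply(l, function(g) g)
  if (max_len > 1L) for (i in seq_len(max_len - 1L)) {
    nxt <- list()
    for (chain in levels[[i]]) {
      last <- chain[length(chain)]
      nbr <- names(graph$adj[[last]])
      nbr <- nbr[!nbr %in% chain]
      for (g in nbr) nxt[[length(nxt) + 1L]] <- c(chain, g)
    }
    levels[[i + 1L]] <- nxt
    if (!length(nxt)) break
  }
  levels <- levels[!vapply(levels, is.null, logical(1L))]
  structure(levels, class = "transaction_set")
}

#' @export
print.transaction_set <- function(x, ...) {
  cnt <- vapply(unclass(x), length, integer(1L))
  cat("Transaction set:", sum(cnt), "chains (",
      paste(sprintf("len %d: %d", seq_along(cnt), cnt), collapse = ", "), ")\n")
  invisible(x)
}

#' Flatten a transaction set to one chain per row
#'
#' @param transactions a `transaction_set`.
#' @return data frame with columns `length` and `chain` (tab-joined
#'   symbols), in enumeration order.
#' @export
transactions_frame <- function(transactions) {
  chains <- unlist(unclass(transactions), recursive = FALSE)
  if (is.null(chains)) chains <- list()
  data.frame(length = vapply(chains, length, integer(1L)),
             chain = vapply(chains, paste, character(1L), collapse = "\t"),
             stringsAsFactors = FALSE)
}

#' Write transactions to TSV
#'
#' One chain per row: tab-joined gene symbols followed by a length column.
#'
#' @param transactions a `transaction_set`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_transactions <- function(transactions, path) {
  df <- transactions_frame(transactions)
  lines <- c("chain\tlength",
             if (nrow(df)) paste(gsub("\t", ",", df$chain, fixed = TRUE),
                                 df$length, sep = "\t"))
  writeLines(lines, path)
  invisible(path)
}
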