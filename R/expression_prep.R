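# Expression preprocessing: TPM normalisation, low-expression filtering,
# log2 fold-changes, replicate concordance, ranking.

#' TPM-normalise a counts table
#'
#' Per sample: `rate = count / (length_bp/1000)`, then
#' `TPM = rate / sum(rate) * 1e6`, so each sample column sums to one
#' million. Length normalisation removes transcript-length bias; the
#' per-million rescaling removes sequencing-depth differences.
#'
#' @param table an `expr_table` with `unit_state == "counts"`.
#' @return an `expr_table` with `unit_state == "tpm"`.
#' @export
compute_tpm <- function(table) {
  stopifnot(inherits(table, "expr_table"))
  if (unit_state(table) != "counts")
    stop("compute_tpm expects a counts table (unit_state = 'counts')")
  counts <- expr_values(table)
  rate <- counts / (table$length_bp / 1000)
  tot <- colSums(rate)
  if (any(tot == 0))
    stop("sample column(s) with all-zero counts: ",
         paste(colnames(counts)[tot == 0], collapse = ", "))
  tpm <- sweep(rate, 2L, tot, "/") * 1e6
  expression_table(table$gene, table$length_bp, as.data.frame(tpm), unit = "tpm")
}

#' Remove genes with very low expression
#'
#' A gene is retained iff its TPM is at least `floor` in every sample of
#' the table; the boundary value itself is kept. The default floor of
#' 1e-6 TPM removes the irregular low tail of the TPM distribution that
#' cannot be distinguished from noise.
#'
#' @param table an `expr_table` with `unit_state == "tpm"`.
#' @param floor minimum TPM required in every sample (default `1e-6`).
#' @return the filtered `expr_table` (still flagged `tpm`; columns are not
#'   renormalised). A warning is raised when nothing survives.
#' @export
filter_low_expression <- function(table, floor = 1e-6) {
  stopifnot(inherits(table, "expr_table"))
  if (unit_state(table) != "tpm")
    stop("filter_low_expression expects a TPM table")
  keep <- rowSums(expr_values(table) < floor) == 0L
  if (!any(keep)) {
    warning("no genes pass the low-expression floor of ", floor)
  }
  out <- as.data.frame(table)[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "unit_state") <- "tpm"
  class(out) <- c("expr_table", "data.frame")
  out
}

#' Construct a difference vector
#'
#' @param gene unique gene symbols.
#' @param delta finite log2 fold-changes, parallel to `gene`.
#' @return a data frame of class `"delta_vector"` with columns `gene`,
#'   `delta`.
#' @export
delta_vector <- function(gene, delta) {
  gene <- as.character(gene)
  if (anyDuplicated(gene)) stop("duplicate gene symbols in difference vector")
  if (length(gene) != length(delta)) stop("gene and delta lengths differ")
  if (length(delta) && any(!is.finite(delta))) stop("delta values must be finite")
  out <- data.frame(gene = gene, delta = as.numeric(delta),
                    stringsAsFactors = FALSE)
  class(out) <- c("delta_vector", "data.frame")
  out
}

#' Log2 fold-change of TPM between two samples
#'
#' Computes `delta = log2(treatment / control)` per gene shared by both
#' inputs. Both sides must already have passed the low-expression floor,
#' so every value is strictly positive; a zero or negative TPM reaching
#' this step is a contract violation and raises an error. Genes present on
#' only one side are dropped and counted in the `"n_dropped"` attribute.
#'
#' @param treatment,control named numeric TPM vectors (names are gene
#'   symbols), or single-sample `expr_table`s in TPM state.
#' @return a [delta_vector()] over the shared genes, in `treatment` order.
#' @export
log2_fold_change <- function(treatment, control) {
  treatment <- .as_named_tpm(treatment)
  control <- .as_named_tpm(control)
  shared <- intersect(names(treatment), names(control))
  dropped <- (length(treatment) - length(shared)) +
             (length(control) - length(shared))
  tr <- treatment[shared]; ct <- control[shared]
  if (any(tr <= 0) || any(ct <= 0))
    stop("zero or negative TPM reached log2_fold_change; ",
         "apply filter_low_expression first")
  out <- delta_vector(shared, log2(tr / ct))
  attr(out, "n_dropped") <- dropped
  out
}

.as_named_tpm <- function(x) {
  if (inherits(x, "expr_table")) {
    if (unit_state(x) != "tpm") stop("expression table must be in TPM state")
    sn <- sample_names(x)
    if (length(sn) != 1L)
      stop("expected a single-sample table; found ", length(sn), " samples")
    return(stats::setNames(as.data.frame(x)[[sn]], x$gene))
  }
  if (is.numeric(x) && !is.null(names(x))) return(x)
  stop("expected a named numeric vector or a single-sample expr_table")
}

#' Keep genes with a concordant expression trend across replicates
#'
#' A gene survives iff it is present in every replicate difference vector
#' and all its log2 fold-changes share a strict sign (all positive or all
#' negative; an exact zero in any replicate drops the gene). The output
#' delta is the mean across replicates. With a single replicate this is an
#' identity pass-through.
#'
#' @param replicate_deltas nonempty list of [delta_vector()]s.
#' @return a [delta_vector()] of concordant genes (order of the first
#'   replicate).
#' @export
concordance_filter <- function(replicate_deltas) {
  if (!is.list(replicate_deltas) || length(replicate_deltas) == 0L ||
      inherits(replicate_deltas, "data.frame"))
    stop("replicate_deltas must be a nonempty list of delta vectors")
  for (dv in replicate_deltas)
    if (!inherits(dv, "delta_vector")) stop("all inputs must be delta_vector objects")
  shared <- Reduce(intersect, lapply(replicate_deltas, `[[`, "gene"))
  if (!length(shared)) return(delta_vector(character(0), numeric(0)))
  mat <- vapply(replicate_deltas, function(dv)
    stats::setNames(dv$delta, dv$gene)[shared], numeric(length(shared)))
  mat <- matrix(mat, nrow = length(shared),
                dimnames = list(shared, NULL))
  concordant <- rowSums(mat > 0) == ncol(mat) | rowSums(mat < 0) == ncol(mat)
  delta_vector(shared[concordant], rowMeans(mat)[concordant])
}

#' Rank genes by descending expression difference
#'
#' Stable sort with a deterministic tie-break: equal deltas are ordered by
#' ascending gene symbol. Rank positions are 1-based.
#'
#' @param dv a [delta_vector()].
#' @return a data frame of class `"ranked_list"` with columns `rank`,
#'   `gene`, `delta`, `delta` non-increasing.
#' @export
rank_genes <- function(dv) {
  stopifnot(inherits(dv, "delta_vector"))
  ord <- order(-dv$delta, dv$gene, method = "radix")
  out <- data.frame(rank = seq_along(ord), gene = dv$gene[ord],
                    delta = dv$delta[ord], stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}

#' @export
print.ranked_list <- function(x, ...) {
  cat(sprintf("Ranked list: %d genes, delta in [%.4g, %.4g]\n", nrow(x),
              if (nrow(x)) min(x$delta) else NA, if (nrow(x)) max(x$delta) else NA))
  print(utils::head(as.data.frame(x), 5L))
  if (nrow(x) > 5L) cat("...", nrow(x) - 5L, "more rows\n")
  invisible(x)
}

#' Write / read a ranked list as TSV
#'
#' Columns `rank`, `gene`, `delta`; deltas are written with 15 significant
#' digits so ranking inputs round-trip exactly for practical purposes.
#'
#' @param x a `ranked_list`.
#' @param path file path.
#' @return `path` (write) or a `ranked_list` (read).
#' @export
write_ranked_list <- function(x, path) {
  stopifnot(inherits(x, "ranked_list"))
  out <- data.frame(rank = x$rank, gene = x$gene, delta = .fmt_num(x$delta))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_ranked_list
#' @export
read_ranked_list <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("rank", "gene", "delta") %in% names(df)))
  out <- data.frame(rank = as.integer(df$rank), gene = as.character(df$gene),
                    delta = as.numeric(df$delta), stringsAsFactors = FALSE)
  class(out) <- c("ranked_list", "data.frame")
  out
}
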