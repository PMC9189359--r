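# print / summary / plot methods for result objects.

#' @export
print.gsea_result <- function(x, ...) {
  cat(sprintf("GSEA result: %d gene sets, %d permutations, p = %g, seed %d\n",
              nrow(x), attr(x, "v"), attr(x, "p"), attr(x, "seed")))
  if (nrow(x)) {
    df <- as.data.frame(x)[order(x$p_value, -abs(x$es_max)), ]
    df$leading_edge <- vapply(df$leading_edge, function(g)
      if (length(g) > 3L) paste0(paste(g[1:3], collapse = ","), ",...")
      else paste(g, collapse = ","), character(1L))
    print(utils::head(df, 10L), row.names = FALSE)
    if (nrow(df) > 10L) cat("...", nrow(df) - 10L, "more rows\n")
  }
  invisible(x)
}

#' Summarise a GSEA result
#'
#' @param object a `gsea_result`.
#' @param alpha raw p-value threshold used for the significance counts.
#' @param ... unused.
#' @return a list with counts of significant sets by ES sign and the
#'   leading-edge union size, printed compactly.
#' @export
summary.gsea_result <- function(object, alpha = 0.05, ...) {
  sig <- object$p_value < alpha
  un <- union_leading_edges(object, alpha = alpha)
  out <- list(n_sets = nrow(object), alpha = alpha,
              n_significant = sum(sig),
              n_sig_positive = sum(sig & object$es_max > 0),
              n_sig_negative = sum(sig & object$es_max < 0),
              union_size = nrow(un))
  class(out) <- "summary.gsea_result"
  out
}

#' @export
print.summary.gsea_result <- function(x, ...) {
  cat(sprintf(paste0("%d gene sets tested; %d significant at raw p < %g ",
                     "(%d positive ES, %d negative ES)\n",
                     "leading-edge union: %d genes\n"),
              x$n_sets, x$n_significant, x$alpha, x$n_sig_positive,
              x$n_sig_negative, x$union_size))
  invisible(x)
}

#' Plot the running-sum curve of one gene set
#'
#' Recomputes the ES curve for `set_id` from the ranked list carried by
#' the result and draws it with the peak position and hit positions
#' marked.
#'
#' @param x a `gsea_result`.
#' @param set_id which set to plot (default: smallest p-value).
#' @param members the set's member genes; required because the result
#'   object stores only leading edges, not full memberships, unless the
#'   set's hits can be recovered from `leading_edge` (they can when the
#'   curve peak is at the first or last hit). Pass the collection's
#'   member vector for exact redrawing.
#' @param ... passed to [graphics::plot()].
#' @return invisibly, the recomputed curve.
#' @export
plot.gsea_result <- function(x, set_id = NULL, members = NULL, ...) {
  if (!nrow(x)) stop("empty result")
  if (is.null(set_id)) set_id <- x$set_id[which.min(x$p_value)]
  row <- match(set_id, x$set_id)
  if (is.na(row)) stop("unknown set_id: ", set_id)
  ranked <- attr(x, "ranked")
  if (is.null(members)) members <- x$leading_edge[[row]]
  ind <- indicator(ranked, members, p = attr(x, "p"))
  curve <- es_curve(ranked$delta, ind)
  graphics::plot(seq_along(curve), curve, type = "l",
                 xlab = "rank", ylab = "running enrichment score",
                 main = set_id, ...)
  graphics::abline(h = 0, col = "grey70")
  hits <- which(ind$r == 1L)
  graphics::rug(hits)
  graphics::abline(v = x$peak_index[row], lty = 2, col = "red3")
  invisible(curve)
}

#' Plot frequent-chain weights
#'
#' One horizontal bar per frequent chain, grouped by cardinality, length
#' proportional to \|d\|.
#'
#' @param x a `frequent_sets` frame.
#' @param cardinality plot only this chain length (default: all).
#' @param ... passed to [graphics::barplot()].
#' @return invisibly, the plotted heights.
#' @export
plot.frequent_sets <- function(x, cardinality = NULL, ...) {
  df <- as.data.frame(x)
  if (!is.null(cardinality)) df <- df[df$cardinality %in% cardinality, ]
  if (!nrow(df)) stop("nothing to plot")
  labels <- vapply(df$chain, paste, character(1L), collapse = "->")
  ord <- order(df$cardinality, df$d_norm)
  graphics::barplot(df$d_norm[ord], names.arg = labels[ord], horiz = TRUE,
                    las = 1, xlab = "||d||",
                    col = grDevices::grey.colors(max(df$cardinality))[
                      df$cardinality[ord]], ...)
  invisible(df$d_norm[ord])
}

#' @export
print.leading_union <- function(x, ...) {
  cat(sprintf("Leading-edge union: %d genes\n", nrow(x)))
  print(utils::head(as.data.frame(x), 8L))
  if (nrow(x) > 8L) cat("...", nrow(x) - 8L, "more rows\n")
  invisible(x)
}

#' @export
print.null_dist <- function(x, ...) {
  cat(sprintf("Permutation null: v = %d, seed %d, |es'_max| in [%.4g, %.4g]\n",
              x$v, x$seed, min(x$values), max(x$values)))
  invisible(x)
}
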