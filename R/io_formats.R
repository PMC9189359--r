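#' gsear: interaction-based refinement of gene set enrichment results
#'
#' Weighted running-sum GSEA with permutation p-values and leading-edge
#' extraction, followed by Apriori mining of frequent signed interaction
#' chains among leading-edge genes, scored by the norm of the statistic
#' d = delta M.
#'
#' @section Pipeline:
#' `read_expression_table()` -> `compute_tpm()` -> `filter_low_expression()`
#' -> `log2_fold_change()` -> `concordance_filter()` -> `rank_genes()` ->
#' `run_gsea()` -> `union_leading_edges()` -> `build_graph()` -> `refine()`.
#' `run_all()` orchestrates the whole chain from a `run_config()`.
#'
#' @keywords internal
"_PACKAGE"

# ---- ExpressionTable ------------------------------------------------------

#' Construct an expression table
#'
#' An expression table holds one gene per row: symbol, transcript length in
#' base pairs, and one nonnegative expression value per sample (either raw
#' read counts or TPM, tracked by the `unit` flag).
#'
#' @param gene character vector of unique gene symbols.
#' @param length_bp positive integer transcript lengths (base pairs).
#' @param values data frame or matrix of nonnegative per-sample values, one
#'   row per gene, at least one column.
#' @param unit `"counts"` or `"tpm"`. For `"tpm"` every sample column must
#'   sum to 1e6 (relative tolerance 1e-9).
#' @return a data frame of class `"expr_table"` with columns `gene`,
#'   `length_bp` and the sample columns; the unit is stored in the
#'   `"unit_state"` attribute.
#' @seealso [read_expression_table()], [compute_tpm()]
#' @export
expression_table <- function(gene, length_bp, values, unit = c("counts", "tpm")) {
  unit <- match.arg(unit)
  gene <- as.character(gene)
  values <- as.data.frame(values, optional = TRUE)
  if (length(gene) == 0L) stop("expression table has no data rows")
  if (anyDuplicated(gene)) {
    dup <- unique(gene[duplicated(gene)])
    stop("duplicated gene symbol(s): ", paste(dup, collapse = ", "))
  }
  if (length(length_bp) != length(gene) || nrow(values) != length(gene))
    stop("gene, length_bp and values must have matching lengths")
  if (ncol(values) < 1L) stop("at least one sample column is required")
  if (any(!is.finite(length_bp)) || any(length_bp <= 0))
    stop("all transcript lengths must be positive")
  vm <- as.matrix(values)
  if (!is.numeric(vm) || any(!is.finite(vm)))
    stop("all expression values must be finite numbers")
  if (any(vm < 0)) {
    bad <- which(rowSums(vm < 0) > 0)[1L]
    stop("negative expression value for gene ", gene[bad])
  }
  if (unit == "tpm") {
    tot <- colSums(vm)
    if (any(abs(tot - 1e6) > 1e-9 * 1e6))
      stop("tpm sample columns must sum to 1e6")
  }
  out <- data.frame(gene = gene, length_bp = as.numeric(length_bp),
                    values, check.names = FALSE, stringsAsFactors = FALSE)
  attr(out, "unit_state") <- unit
  class(out) <- c("expr_table", "data.frame")
  out
}

#' Unit state of an expression table
#' @param x an `expr_table`.
#' @return `"counts"` or `"tpm"`.
#' @export
unit_state <- function(x) attr(x, "unit_state")

#' Sample column names of an expression table
#' @param x an `expr_table`.
#' @return character vector of sample names.
#' @export
sample_names <- function(x) setdiff(colnames(x), c("gene", "length_bp"))

#' Per-sample value matrix of an expression table
#' @param x an `expr_table`.
#' @return numeric matrix, genes in rows (rownames = symbols).
#' @export
expr_values <- function(x) {
  m <- as.matrix(as.data.frame(x)[, sample_names(x), drop = FALSE])
  rownames(m) <- x$gene
  m
}

#' @export
print.expr_table <- function(x, ...) {
  cat(sprintf("Expression table: %d genes, %d sample(s), unit = %s\n",
              nrow(x), length(sample_names(x)), unit_state(x)))
  print(utils::head(as.data.frame(x), 6L))
  if (nrow(x) > 6L) cat("...", nrow(x) - 6L, "more rows\n")
  invisible(x)
}

#' Read a tab-separated expression table
#'
#' Expects a header row with columns `gene`, `length_bp` and at least one
#' sample column. Duplicate gene symbols, nonpositive lengths and negative
#' or non-numeric values are rejected with the offending symbol or line
#' number in the message.
#'
#' @param path path to a TSV file.
#' @param unit unit of the value columns, `"counts"` or `"tpm"`.
#' @return an [expression_table()].
#' @export
read_expression_table <- function(path, unit = c("counts", "tpm")) {
  unit <- match.arg(unit)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) < 2L) stop("no data rows in ", path)
  header <- strsplit(lines[[1L]], "\t", fixed = TRUE)[[1L]]
  if (length(header) < 3L || header[1L] != "gene" || header[2L] != "length_bp")
    stop("header must start with 'gene', 'length_bp' and name >=1 sample column")
  fields <- strsplit(lines[-1L], "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf != length(header))) {
    bad <- which(nf != length(header))[1L]
    stop("malformed row at line ", bad + 1L, ": expected ",
         length(header), " fields, found ", nf[bad])
  }
  m <- do.call(rbind, fields)
  gene <- m[, 1L]
  num <- suppressWarnings(apply(m[, -1L, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num)) {
    bad <- which(rowSums(is.na(num)) > 0)[1L]
    stop("malformed row at line ", bad + 1L, ": non-numeric value")
  }
  if (any(num[, -1L, drop = FALSE] < 0)) {
    bad <- which(rowSums(num[, -1L, drop = FALSE] < 0) > 0)[1L]
    stop("negative value at line ", bad + 1L, " (gene ", gene[bad], ")")
  }
  vals <- as.data.frame(num[, -1L, drop = FALSE])
  colnames(vals) <- header[-(1:2)]
  expression_table(gene, num[, 1L], vals, unit = unit)
}

#' Write an expression table to TSV
#'
#' @param x an `expr_table`.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_expression_table <- function(x, path) {
  stopifnot(inherits(x, "expr_table"))
  df <- as.data.frame(x)
  num <- vapply(df, is.numeric, logical(1L))
  df[num] <- lapply(df[num], function(v) sprintf("%.15g", v))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# ---- GeneSetCollection ----------------------------------------------------

#' Construct a gene set collection
#'
#' @param sets named list of character vectors (member gene symbols); names
#'   are the unique set ids.
#' @param name optional display names, parallel to `sets`.
#' @param category_path optional list of character vectors giving each set's
#'   hierarchy labels (outermost first).
#' @return an object of class `"gene_set_collection"`.
#' @export
gene_set_collection <- function(sets, name = NULL, category_path = NULL) {
  if (is.null(names(sets)) || anyDuplicated(names(sets)))
    stop("set ids must be unique and non-empty")
  if (any(lengths(sets) == 0L)) stop("every gene set must be nonempty")
  sets <- lapply(sets, as.character)
  if (is.null(name)) name <- names(sets)
  if (is.null(category_path)) category_path <- rep(list(character(0)), length(sets))
  structure(list(sets = sets, name = stats::setNames(name, names(sets)),
                 category_path = stats::setNames(category_path, names(sets))),
            class = "gene_set_collection")
}

#' @export
length.gene_set_collection <- function(x) length(x$sets)

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("Gene set collection: %d sets, sizes %s\n", length(x),
              if (length(x)) paste(range(lengths(x$sets)), collapse = "-") else "-"))
  invisible(x)
}

#' Read a gene set collection
#'
#' Two dialects are supported: standard GMT
#' (`set_id<TAB>description<TAB>gene1<TAB>gene2...`) and a KEGG
#' ko00001-style nested JSON hierarchy in which every node carries a
#' `"name"` field and interior nodes carry `"children"` arrays. In the JSON
#' dialect a node whose children are all leaves is taken as one gene set:
#' its first whitespace-delimited token is the set id, the remainder the
#' display name, and the ancestor node names form the category path. A leaf
#' name is parsed as `<id> <symbol1>[, <symbol2>...][; description]`; if it
#' has a single token, that token is the member symbol.
#'
#' Sets whose category path contains any label in `exclude_categories` are
#' removed (this is how whole hierarchy branches, e.g. disease categories,
#' are dropped before enrichment).
#'
#' @param path input file.
#' @param dialect `"gmt"` or `"kegg_json"`.
#' @param exclude_categories character vector of hierarchy labels to drop.
#' @return a [gene_set_collection()].
#' @export
read_gene_sets <- function(path, dialect = c("gmt", "kegg_json"),
                           exclude_categories = character(0)) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  coll <- switch(dialect,
                 gmt = .read_gmt(path),
                 kegg_json = .read_kegg_json(path))
  if (length(exclude_categories)) {
    keep <- !vapply(coll$category_path,
                    function(p) any(p %in% exclude_categories), logical(1L))
    coll <- gene_set_collection(coll$sets[keep], coll$name[keep],
                                coll$category_path[keep])
  }
  coll
}

.read_gmt <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (!length(lines)) stop("no gene sets in ", path)
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(fields) < 3L))
    stop("malformed GMT line ", which(lengths(fields) < 3L)[1L],
         ": need id, description and >=1 gene")
  ids <- vapply(fields, `[[`, character(1L), 1L)
  descr <- vapply(fields, `[[`, character(1L), 2L)
  sets <- lapply(fields, function(f) unique(f[-(1:2)]))
  gene_set_collection(stats::setNames(sets, ids), descr)
}

.read_kegg_json <- function(path) {
  root <- jsonlite::read_json(path, simplifyVector = FALSE)
  acc <- new.env(parent = emptyenv())
  acc$ids <- character(0); acc$name <- character(0)
  acc$sets <- list(); acc$paths <- list()
  .walk_kegg(root, character(0), acc)
  if (!length(acc$ids)) stop("no gene sets found in ", path)
  gene_set_collection(stats::setNames(acc$sets, acc$ids), acc$name, acc$paths)
}

.walk_kegg <- function(node, path, acc) {
  kids <- node[["children"]]
  if (is.null(kids)) return(invisible())
  leaf <- vapply(kids, function(k) is.null(k[["children"]]), logical(1L))
  if (all(leaf) && length(kids)) {
    # a pathway node: children are gene entries
    nm <- node[["name"]]
    toks <- strsplit(nm, "\\s+")[[1L]]
    id <- toks[1L]
    genes <- unique(unlist(lapply(kids, function(k) .kegg_leaf_genes(k[["name"]]))))
    genes <- genes[nzchar(genes)]
    if (length(genes)) {
      acc$ids <- c(acc$ids, id)
      acc$name <- c(acc$name, paste(toks[-1L], collapse = " "))
      acc$sets <- c(acc$sets, list(genes))
      acc$paths <- c(acc$paths, list(path))
    }
  } else {
    for (k in kids) .walk_kegg(k, c(path, node[["name"]]), acc)
  }
  invisible()
}

.kegg_leaf_genes <- function(name) {
  # "<id> <sym1>, <sym2>; description" -> symbols; single token -> itself
  name <- sub(";.*$", "", name)
  toks <- strsplit(trimws(name), "\\s+")[[1L]]
  if (length(toks) <= 1L) return(toks)
  syms <- paste(toks[-1L], collapse = " ")
  trimws(strsplit(syms, ",", fixed = TRUE)[[1L]])
}

# ---- Interaction networks -------------------------------------------------

# direction token -> list of (from_col, to_col, sign); from/to are 1 or 2
.DIRECTION_TOKENS <- list(
  "->"  = list(c(1L, 2L,  1L)),
  "-|"  = list(c(1L, 2L, -1L)),
  "<-"  = list(c(2L, 1L,  1L)),
  "|-"  = list(c(2L, 1L, -1L)),
  "<->" = list(c(1L, 2L,  1L), c(2L, 1L,  1L)),
  "|-|" = list(c(1L, 2L, -1L), c(2L, 1L, -1L)),
  "<-|" = list(c(2L, 1L,  1L), c(1L, 2L, -1L)),
  "|->" = list(c(1L, 2L,  1L), c(2L, 1L, -1L))
)

#' Read a signed functional-interaction network
#'
#' Parses the Reactome `FIsInGene ... with annotations` tab-separated
#' dialect: columns `gene1`, `gene2`, `annotation`, `direction`, `score` (a
#' header row is tolerated). Direction tokens map to signed directed
#' records: `->` activates gene1 -> gene2, `-|` inhibits it, `<-`/`|-` act
#' in the reverse orientation, `<->`/`|-|` produce one record per
#' direction, and `<-|`/`|->` produce one record per side with its own
#' sign. The undirected token `-` carries no sign and is dropped; the count
#' of dropped rows is reported and stored in the `"dropped_undirected"`
#' attribute. Self-interactions are dropped likewise
#' (`"dropped_self"`).
#'
#' @param path input file.
#' @param strict if `TRUE`, an unknown direction token is an error;
#'   otherwise the row is dropped with a warning (count in
#'   `"dropped_unknown"`).
#' @return a data frame of class `"interaction_records"` with columns
#'   `source`, `target`, `sign` (+1/-1) and `provenance`.
#' @export
read_interaction_network <- function(path, strict = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  if (length(fields) && identical(tolower(fields[[1L]][1L]), "gene1"))
    fields <- fields[-1L]
  if (any(lengths(fields) < 4L))
    stop("malformed network row ", which(lengths(fields) < 4L)[1L],
         ": need gene1, gene2, annotation, direction")
  n_und <- 0L; n_unk <- 0L; n_self <- 0L
  src <- tgt <- prov <- character(0); sgn <- integer(0)
  for (f in fields) {
    token <- f[[4L]]
    if (identical(token, "-")) { n_und <- n_und + 1L; next }
    map <- .DIRECTION_TOKENS[[token]]
    if (is.null(map)) {
      if (strict) stop("unknown direction token '", token, "'")
      n_unk <- n_unk + 1L
      next
    }
    for (m in map) {
      a <- f[[m[1L]]]; b <- f[[m[2L]]]
      if (identical(a, b)) { n_self <- n_self + 1L; next }
      src <- c(src, a); tgt <- c(tgt, b)
      sgn <- c(sgn, m[3L]); prov <- c(prov, f[[3L]])
    }
  }
  if (n_unk > 0L)
    warning(n_unk, " row(s) with unknown direction token dropped")
  if (n_und > 0L)
    message(n_und, " undirected/unsigned row(s) dropped (no sign available)")
  out <- data.frame(source = src, target = tgt, sign = sgn,
                    provenance = prov, stringsAsFactors = FALSE)
  attr(out, "dropped_undirected") <- n_und
  attr(out, "dropped_unknown") <- n_unk
  attr(out, "dropped_self") <- n_self
  class(out) <- c("interaction_records", "data.frame")
  out
}

#' Construct interaction records directly
#'
#' @param source,target gene symbols (self-pairs are rejected).
#' @param sign +1 (upregulation) or -1 (downregulation) per record.
#' @param provenance free-text annotation.
#' @return an `"interaction_records"` data frame.
#' @export
interaction_records <- function(source, target, sign,
                                provenance = rep("", length(source))) {
  sign <- as.integer(sign)
  if (!all(sign %in% c(-1L, 1L))) stop("sign must be +1 or -1")
  if (any(source == target)) stop("self-interactions are not allowed")
  out <- data.frame(source = as.character(source), target = as.character(target),
                    sign = sign, provenance = provenance,
                    stringsAsFactors = FALSE)
  class(out) <- c("interaction_records", "data.frame")
  out
}

# ---- Result reports -------------------------------------------------------

.fmt_num <- function(x) sprintf("%.15g", x)

#' Write an analysis report
#'
#' Serialises enrichment results (class `"gsea_result"`) or frequent-set
#' rankings (class `"frequent_sets"`) to TSV or JSON. Numeric fields
#' round-trip through either format to at least 12 significant digits;
#' gene lists are comma-joined in TSV. Use [read_report()] to read a
#' report back.
#'
#' @param results a `gsea_result` or `frequent_sets` object.
#' @param path output path.
#' @param format `"tsv"` or `"json"`.
#' @param allow_empty write a header-only report when `results` has no
#'   rows (otherwise an error).
#' @return `path`, invisibly.
#' @export
write_report <- function(results, path, format = c("tsv", "json"),
                         allow_empty = FALSE) {
  format <- match.arg(format)
  type <- if (inherits(results, "gsea_result")) "enrichment"
          else if (inherits(results, "frequent_sets")) "frequent"
          else stop("unsupported results class: ", paste(class(results), collapse = "/"))
  df <- .report_frame(results, type)
  if (nrow(df) == 0L && !allow_empty)
    stop("refusing to write an empty report (set allow_empty = TRUE)")
  if (format == "tsv") {
    num <- vapply(df, is.numeric, logical(1L))
    out <- df
    out[num] <- lapply(df[num], .fmt_num)
    utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  } else {
    jsonlite::write_json(list(type = type, records = df), path,
                         auto_unbox = TRUE, digits = NA, dataframe = "rows")
  }
  invisible(path)
}

.report_frame <- function(results, type) {
  if (type == "enrichment") {
    data.frame(set_id = results$set_id,
               es_max = results$es_max,
               peak_index = results$peak_index,
               p_value = results$p_value,
               bh_fdr = results$bh_fdr,
               n_hits = results$n_hits,
               leading_edge = vapply(results$leading_edge, paste,
                                     character(1L), collapse = ","),
               stringsAsFactors = FALSE)
  } else {
    data.frame(cardinality = results$cardinality,
               chain = vapply(results$chain, paste, character(1L), collapse = ","),
               support = results$support,
               d_vector = vapply(results$d_vector, function(v)
                 paste(.fmt_num(v), collapse = ","), character(1L)),
               d_norm = results$d_norm,
               rank_within_cardinality = results$rank_within_cardinality,
               stringsAsFactors = FALSE)
  }
}

#' Read an analysis report written by [write_report()]
#'
#' @param path report path.
#' @param format `"tsv"` or `"json"`.
#' @param type `"enrichment"` or `"frequent"`; for JSON the stored type is
#'   used and checked when given.
#' @return a `gsea_result` or `frequent_sets` object (without attributes
#'   that only the computing run knows, e.g. the ranked list).
#' @export
read_report <- function(path, format = c("tsv", "json"), type = NULL) {
  format <- match.arg(format)
  if (format == "tsv") {
    df <- utils::read.delim(path, stringsAsFactors = FALSE)
    if (is.null(type))
      type <- if ("set_id" %in% names(df)) "enrichment" else "frequent"
  } else {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    if (!is.null(type) && !identical(obj$type, type))
      stop("report type mismatch: file holds '", obj$type, "'")
    type <- obj$type
    df <- as.data.frame(obj$records, stringsAsFactors = FALSE)
  }
  split_cs <- function(s) if (is.na(s) || !nzchar(s)) character(0)
                          else strsplit(s, ",", fixed = TRUE)[[1L]]
  if (type == "enrichment") {
    df$leading_edge <- lapply(as.character(df$leading_edge), split_cs)
    class(df) <- c("gsea_result", "data.frame")
  } else {
    df$chain <- lapply(as.character(df$chain), split_cs)
    df$d_vector <- lapply(as.character(df$d_vector),
                          function(s) as.numeric(split_cs(s)))
    class(df) <- c("frequent_sets", "data.frame")
  }
  df
}
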