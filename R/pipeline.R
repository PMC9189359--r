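# End-to-end orchestration: configuration, validation, and the
# prep -> gsea -> chains -> refine -> report pipeline.

#' Pipeline configuration
#'
#' Collects every tunable of the pipeline with its default: TPM floor
#' 1e-6, weight exponent 1, 1000 permutations, raw-p significance level
#' 0.05, Apriori support threshold 3, maximum chain length 4, inclusive
#' leading edges. Configurations round-trip through YAML via
#' [write_run_config()] / [read_run_config()].
#'
#' @param counts_treatment,counts_control paths to counts TSVs (replicate
#'   sample columns are paired by position).
#' @param gene_sets path to the gene set collection.
#' @param gene_sets_dialect `"gmt"` or `"kegg_json"`.
#' @param exclude_categories hierarchy labels to drop on read.
#' @param network path to the signed interaction network.
#' @param outdir output directory.
#' @param tpm_floor low-expression floor (TPM).
#' @param weight_p ES weight exponent in `[0, 1]`.
#' @param permutations permutations per gene set.
#' @param alpha raw p-value threshold for the leading-edge union.
#' @param min_support Apriori support threshold.
#' @param max_chain_len maximum interaction-chain length.
#' @param leading_edge_mode `"inclusive"` or `"paper_strict"`.
#' @param seed integer seed for all randomness.
#' @return a list of class `"run_config"`.
#' @export
run_config <- function(counts_treatment = NULL, counts_control = NULL,
                       gene_sets = NULL, gene_sets_dialect = "gmt",
                       exclude_categories = character(0), network = NULL,
                       outdir = NULL, tpm_floor = 1e-6, weight_p = 1,
                       permutations = 1000, alpha = 0.05, min_support = 3,
                       max_chain_len = 4,
                       leading_edge_mode = "inclusive", seed = 1) {
  structure(list(counts_treatment = counts_treatment,
                 counts_control = counts_control, gene_sets = gene_sets,
                 gene_sets_dialect = gene_sets_dialect,
                 exclude_categories = exclude_categories, network = network,
                 outdir = outdir, tpm_floor = tpm_floor, weight_p = weight_p,
                 permutations = permutations, alpha = alpha,
                 min_support = min_support, max_chain_len = max_chain_len,
                 leading_edge_mode = leading_edge_mode, seed = seed),
            class = "run_config")
}

#' Validate a pipeline configuration
#'
#' @param config a [run_config()].
#' @return character vector of problems; empty when the configuration is
#'   valid.
#' @export
validate_config <- function(config) {
  problems <- character(0)
  chk <- function(cond, msg) if (!isTRUE(cond)) problems <<- c(problems, msg)
  num1 <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
  chk(num1(config$weight_p) && config$weight_p >= 0 && config$weight_p <= 1,
      "weight_p must be in [0, 1]")
  chk(num1(config$permutations) && config$permutations >= 1,
      "permutations must be >= 1")
  chk(num1(config$alpha) && config$alpha > 0 && config$alpha <= 1,
      "alpha must be in (0, 1]")
  chk(num1(config$min_support) && config$min_support >= 1,
      "min_support must be >= 1")
  chk(num1(config$max_chain_len) && config$max_chain_len >= 1,
      "max_chain_len must be >= 1")
  chk(num1(config$tpm_floor) && config$tpm_floor >= 0,
      "tpm_floor must be >= 0")
  chk(config$leading_edge_mode %in% c("inclusive", "paper_strict"),
      "leading_edge_mode must be 'inclusive' or 'paper_strict'")
  chk(config$gene_sets_dialect %in% c("gmt", "kegg_json"),
      "gene_sets_dialect must be 'gmt' or 'kegg_json'")
  chk(num1(config$seed), "seed must be a single number")
  problems
}

#' Write / read a configuration as YAML
#' @param config a [run_config()].
#' @param path YAML file path.
#' @return `path` (write) or a `run_config` (read).
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

#' @rdname write_run_config
#' @export
read_run_config <- function(path) {
  vals <- yaml::read_yaml(path)
  vals <- vals[!vapply(vals, is.null, logical(1L))]
  # YAML has no empty character vector: [] comes back as an empty list
  if (!is.null(vals$exclude_categories))
    vals$exclude_categories <- as.character(unlist(vals$exclude_categories))
  do.call(run_config, vals)
}

.stage <- function(name, expr) {
  tryCatch(expr, error = function(e)
    stop("stage '", name, "' failed: ", conditionMessage(e), call. = FALSE))
}

#' Run the full pipeline
#'
#' Executes prep (TPM, low-expression filter, fold-changes, replicate
#' concordance, ranking), GSEA with permutation p-values, leading-edge
#' union, chain generation over the restricted interaction graph, Apriori
#' refinement and report writing, all under the configured seed. Writes
#' `ranked.tsv`, `enrich.tsv`, `transactions.tsv`, `frequent.tsv` and
#' `run_log.yaml` (the exact configuration used, defaults included, plus
#' package version) into `config$outdir`. Any stage failure aborts with
#' the stage name and the underlying cause.
#'
#' @param config a [run_config()] with all input paths set.
#' @return invisibly, a list with the in-memory stage results: `ranked`,
#'   `enrichment`, `union`, `graph`, `transactions`, `frequent`.
#' @export
run_all <- function(config) {
  stopifnot(inherits(config, "run_config"))
  problems <- validate_config(config)
  if (length(problems))
    stop("invalid configuration: ", paste(problems, collapse = "; "))

  ranked <- .stage("prep", {
    trt <- read_expression_table(config$counts_treatment, unit = "counts")
    ctl <- read_expression_table(config$counts_control, unit = "counts")
    if (length(sample_names(trt)) != length(sample_names(ctl)))
      stop("treatment and control must have the same number of sample columns")
    trt_tpm <- compute_tpm(trt)
    ctl_tpm <- compute_tpm(ctl)
    deltas <- lapply(seq_along(sample_names(trt)), function(j) {
      a <- .single_sample(trt_tpm, j)
      b <- .single_sample(ctl_tpm, j)
      log2_fold_change(
        .as_named_tpm(filter_low_expression(a, config$tpm_floor)),
        .as_named_tpm(filter_low_expression(b, config$tpm_floor)))
    })
    rank_genes(concordance_filter(deltas))
  })

  enrichment <- .stage("gsea", {
    collection <- read_gene_sets(config$gene_sets,
                                 dialect = config$gene_sets_dialect,
                                 exclude_categories = config$exclude_categories)
    run_gsea(ranked, collection, p = config$weight_p,
             v = config$permutations, seed = config$seed,
             mode = config$leading_edge_mode)
  })

  le_union <- union_leading_edges(enrichment, alpha = config$alpha)

  chains <- .stage("chains", {
    records <- read_interaction_network(config$network)
    graph <- build_graph(records, restrict_to = le_union$gene)
    list(graph = graph,
         transactions = generate_transactions(le_union, graph,
                                              max_len = config$max_chain_len))
  })

  frequent <- .stage("refine",
    refine(le_union, chains$graph, min_support = config$min_support,
           max_len = config$max_chain_len))

  .stage("report", {
    dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
    write_ranked_list(ranked, file.path(config$outdir, "ranked.tsv"))
    write_report(enrichment, file.path(config$outdir, "enrich.tsv"),
                 format = "tsv", allow_empty = TRUE)
    write_transactions(chains$transactions,
                       file.path(config$outdir, "transactions.tsv"))
    write_report(frequent, file.path(config$outdir, "frequent.tsv"),
                 format = "tsv", allow_empty = TRUE)
    log <- c(unclass(config),
             list(package_version = as.character(utils::packageVersion("gsear")),
                  r_version = R.version.string))
    yaml::write_yaml(log, file.path(config$outdir, "run_log.yaml"))
  })

  invisible(list(ranked = ranked, enrichment = enrichment, union = le_union,
                 graph = chains$graph, transactions = chains$transactions,
                 frequent = frequent))
}

.single_sample <- function(tbl, j) {
  sn <- sample_names(tbl)[j]
  expression_table(tbl$gene, tbl$length_bp,
                   stats::setNames(as.data.frame(tbl)[sn], sn), unit = "tpm")
}
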