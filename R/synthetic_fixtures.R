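# Built-in worked example and seeded simulations with planted enrichment
# and a planted high-weight interaction chain.

#' The built-in four-gene worked example
#'
#' A constant fixture: genes A-D with signed relations
#' A->B (+), A->C (-), A->D (+), B->C (-), C->D (+), together with the
#' reference values every downstream stage should reproduce - the
#' transaction levels I1..I4, the support table, the 4x4 correlation
#' matrix and the closed form of `d = delta M`. The stored support value
#' for the pair (B,C) is 2 and is flagged `known_discrepancy`: no
#' containment rule consistent with the other eight stored supports
#' yields 2, and contiguous-subsequence counting (used throughout this
#' package) gives 4. Tests assert both the package's rule and this
#' documented divergence.
#'
#' @return a list of class `"worked_example"` with fields `genes`,
#'   `records` (an `interaction_records` frame), `transactions` (list of
#'   levels I1..I4), `support` (data frame `chain`, `support`,
#'   `known_discrepancy`), `M` (the printed matrix for tuple (A,B,C,D)),
#'   and `d_closed_form(delta)` returning `(a, a+b, -a-b+c, a+c+d)`.
#' @export
worked_example <- function() {
  records <- interaction_records(
    source = c("A", "A", "A", "B", "C"),
    target = c("B", "C", "D", "C", "D"),
    sign   = c(1L, -1L, 1L, -1L, 1L),
    provenance = rep("worked example", 5L))
  transactions <- list(
    I1 = list("A", "B", "C", "D"),
    I2 = list(c("A", "B"), c("A", "C"), c("A", "D"), c("B", "C"), c("C", "D")),
    I3 = list(c("A", "B", "C"), c("A", "C", "D"), c("B", "C", "D")),
    I4 = list(c("A", "B", "C", "D")))
  support <- data.frame(
    chain = c("A", "B", "C", "D", "A,B", "A,C", "A,D", "B,C", "C,D"),
    support = c(7L, 6L, 8L, 6L, 3L, 2L, 1L, 2L, 4L),
    known_discrepancy = c(rep(FALSE, 7L), TRUE, FALSE),
    stringsAsFactors = FALSE)
  M <- matrix(c(1L, 1L, -1L, 1L,
                0L, 1L, -1L, 0L,
                0L, 0L,  1L, 1L,
                0L, 0L,  0L, 1L),
              nrow = 4L, byrow = TRUE,
              dimnames = list(c("A", "B", "C", "D"), c("A", "B", "C", "D")))
  structure(list(
    genes = c("A", "B", "C", "D"),
    records = records,
    transactions = transactions,
    support = support,
    M = M,
    d_closed_form = function(delta) {
      stopifnot(length(delta) == 4L)
      a <- delta[1L]; b <- delta[2L]; c <- delta[3L]; d <- delta[4L]
      c(a, a + b, -a - b + c, a + c + d)
    }),
    class = "worked_example")
}

#' Specify a synthetic experiment
#'
#' Parameters of [simulate_experiment()]. The defaults describe the study
#' conditions the package is validated under: 2000 genes, 50 pathways of
#' 40 genes, one planted pathway whose members are shifted by 2.0 log2
#' units, per-gene Gaussian log2 noise of sd 0.3, a sparse random signed
#' background network, and one planted concordant 3-gene chain (effect
#' 3.0 log2 units) inside the planted pathway whose head is fed by two
#' forced upstream activators so the chain can become frequent.
#'
#' @param n_genes gene universe size.
#' @param n_pathways number of gene sets (the first is the planted one).
#' @param pathway_size 2-vector, min/max members per pathway.
#' @param planted_pathway_effect mean log2 shift of planted members.
#' @param noise_sd sd of the per-gene Gaussian log2 noise, applied to all
#'   genes.
#' @param network_edge_prob probability of each background directed edge
#'   (random sign) among the gene universe's first `network_nodes` genes.
#' @param network_nodes number of genes eligible for background edges
#'   (edges are only informative near the leading edge; a full 2000^2
#'   Bernoulli draw would be wasteful).
#' @param chain_len length of the planted chain (>= 2).
#' @param chain_effect log2 shift of planted chain genes (feeders carry the
#'   ordinary pathway effect; they are support scaffolding, not signal).
#' @param n_feeders forced upstream activators of the chain head.
#' @param seed integer seed fixing all randomness.
#' @return a list of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_genes = 2000, n_pathways = 50,
                            pathway_size = c(40, 40),
                            planted_pathway_effect = 2.0, noise_sd = 0.3,
                            network_edge_prob = 0.01, network_nodes = 300,
                            chain_len = 3, chain_effect = 3.0,
                            n_feeders = 2, seed = 1) {
  spec <- list(n_genes = as.integer(n_genes),
               n_pathways = as.integer(n_pathways),
               pathway_size = as.integer(pathway_size),
               planted_pathway_effect = planted_pathway_effect,
               noise_sd = noise_sd,
               network_edge_prob = network_edge_prob,
               network_nodes = as.integer(network_nodes),
               chain_len = as.integer(chain_len),
               chain_effect = chain_effect,
               n_feeders = as.integer(n_feeders),
               seed = as.integer(seed))
  if (any(unlist(spec[c("n_genes", "n_pathways", "chain_len")]) < 1L) ||
      any(spec$pathway_size < 1L) || spec$n_feeders < 0L)
    stop("all sizes must be positive")
  if (!all(is.finite(c(spec$planted_pathway_effect, spec$noise_sd,
                       spec$network_edge_prob, spec$chain_effect))))
    stop("effect parameters must be finite")
  if (max(spec$pathway_size) > spec$n_genes)
    stop("pathway larger than the gene universe")
  if (spec$chain_len + spec$n_feeders > min(spec$pathway_size))
    stop("planted chain and feeders do not fit in the planted pathway")
  class(spec) <- "simulation_spec"
  spec
}

#' Simulate a two-condition expression experiment with planted signal
#'
#' Control expression follows a heavy-tailed positive distribution
#' (log-normal abundances), matching the long right tail of real TPM
#' data; counts are Poisson draws around length-scaled abundances so the
#' full counts -> TPM -> fold-change pipeline is exercised. Treatment
#' abundances are the control abundances shifted on the log2 scale by the
#' planted effects plus `N(0, noise_sd)` noise: members of the planted
#' pathway get `planted_pathway_effect`, planted chain genes get
#' `chain_effect` (sign-consistent with their +1 edges), everything
#' else 0. The background network is Erdos-Renyi with random signs over
#' the first `network_nodes` genes, with the planted chain's edges (and
#' the feeder edges into its head) forced in with sign +1.
#'
#' @param spec a [simulation_spec()].
#' @return a list with elements `treatment` and `control` (single-sample
#'   counts `expr_table`s), `collection` (a [gene_set_collection()]),
#'   `network` (an `interaction_records` frame) and `truth` (list:
#'   `planted_pathway`, `planted_chain`, `feeders`, `effects`).
#' @export
simulate_experiment <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  old <- .save_rng()
  on.exit(.restore_rng(old), add = TRUE)
  set.seed(spec$seed)
  n <- spec$n_genes
  genes <- sprintf("g%04d", seq_len(n))
  length_bp <- round(stats::runif(n, 500, 3000))

  # planted identities: chain + feeders sit inside the planted pathway
  chain <- genes[seq_len(spec$chain_len)]
  feeders <- if (spec$n_feeders > 0L)
    genes[spec$chain_len + seq_len(spec$n_feeders)] else character(0)
  sz_range <- seq(spec$pathway_size[1L], spec$pathway_size[2L])
  sizes <- if (length(sz_range) == 1L) rep(sz_range, spec$n_pathways)
           else sample(sz_range, spec$n_pathways, replace = TRUE)
  planted_members <- c(chain, feeders,
                       sample(setdiff(genes, c(chain, feeders)),
                              sizes[1L] - length(chain) - length(feeders)))
  sets <- vector("list", spec$n_pathways)
  sets[[1L]] <- planted_members
  if (spec$n_pathways > 1L) for (k in 2:spec$n_pathways)
    sets[[k]] <- sample(genes, sizes[k])
  names(sets) <- sprintf("path%03d", seq_len(spec$n_pathways))

  # log2 shifts
  shift <- stats::setNames(numeric(n), genes)
  # feeders are scaffolding (they exist to give the chain enough support)
  # and carry only the ordinary pathway effect, so the planted chain is the
  # unique strong concordant chain in the construct
  shift[planted_members] <- spec$planted_pathway_effect
  shift[chain] <- spec$chain_effect
  shift <- shift + stats::rnorm(n, 0, spec$noise_sd)

  # abundances and counts; planted genes are given solid base expression
  # so they are not lost to the low-expression floor
  mu <- exp(stats::rnorm(n, 2, 1.2))
  planted_idx <- match(c(chain, feeders, planted_members), genes)
  mu[planted_idx] <- exp(stats::rnorm(length(planted_idx), 3, 0.5))
  lam_ctrl <- mu * (length_bp / 1000) * 30
  lam_trt <- lam_ctrl * 2^shift
  control <- stats::rpois(n, lam_ctrl)
  treatment <- stats::rpois(n, lam_trt)

  # background network over the first network_nodes genes, random signs
  nn <- min(spec$network_nodes, n)
  pool <- genes[seq_len(nn)]
  m_possible <- nn * (nn - 1L)
  n_edges <- stats::rbinom(1L, m_possible, spec$network_edge_prob)
  idx <- sample.int(m_possible, n_edges)
  src_i <- (idx - 1L) %/% (nn - 1L) + 1L
  off <- (idx - 1L) %% (nn - 1L) + 1L
  tgt_i <- ifelse(off >= src_i, off + 1L, off)
  bg <- data.frame(source = pool[src_i], target = pool[tgt_i],
                   sign = sample(c(-1L, 1L), n_edges, replace = TRUE),
                   stringsAsFactors = FALSE)
  forced <- data.frame(
    source = c(chain[-length(chain)], feeders),
    target = c(chain[-1L], rep(chain[1L], length(feeders))),
    sign = 1L, stringsAsFactors = FALSE)
  # forced planted edges override any conflicting background draw
  bg_key <- paste(bg$source, bg$target)
  bg <- bg[!bg_key %in% paste(forced$source, forced$target), , drop = FALSE]
  net <- rbind(forced, bg)
  network <- interaction_records(net$source, net$target, net$sign,
                                 provenance = c(rep("planted", nrow(forced)),
                                                rep("background", nrow(bg))))

  list(
    treatment = expression_table(genes, length_bp,
                                 data.frame(trt = treatment), unit = "counts"),
    control = expression_table(genes, length_bp,
                               data.frame(ctl = control), unit = "counts"),
    collection = gene_set_collection(sets),
    network = network,
    truth = list(planted_pathway = names(sets)[1L],
                 planted_chain = chain, feeders = feeders,
                 effects = list(pathway = spec$planted_pathway_effect,
                                chain = spec$chain_effect,
                                noise_sd = spec$noise_sd)))
}

#' Write a simulated experiment to disk
#'
#' Emits `treatment.tsv` and `control.tsv` (counts tables), `sets.gmt`,
#' `network.txt` (functional-interaction dialect, `->` / `-|` tokens) and
#' `truth.json` under `outdir`.
#'
#' @param sim a [simulate_experiment()] result.
#' @param outdir output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_simulation <- function(sim, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  write_expression_table(sim$treatment, file.path(outdir, "treatment.tsv"))
  write_expression_table(sim$control, file.path(outdir, "control.tsv"))
  gmt <- vapply(names(sim$collection$sets), function(id)
    paste(c(id, sim$collection$name[[id]], sim$collection$sets[[id]]),
          collapse = "\t"), character(1L))
  writeLines(gmt, file.path(outdir, "sets.gmt"))
  net <- sim$network
  writeLines(c("gene1\tgene2\tannotation\tdirection\tscore",
               paste(net$source, net$target, net$provenance,
                     ifelse(net$sign == 1L, "->", "-|"), "1.00", sep = "\t")),
             file.path(outdir, "network.txt"))
  jsonlite::write_json(sim$truth, file.path(outdir, "truth.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(outdir)
}
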