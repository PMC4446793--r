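#' Estimate per-gene evolutionary rates on a reference topology
#'
#' For each gene, branch lengths are re-optimized on the fixed reference
#' topology pruned to the taxa with data for that gene; the gene's tree
#' length is the sum of optimized branch lengths and its relative rate is
#' the tree length divided by the mean tree length, so relative rates
#' average exactly 1.
#'
#' @param matrix a [supermatrix()].
#' @param reference_tree `ape::phylo` spanning the matrix taxa, with branch
#'   lengths (used as the optimization start).
#' @param model a [substitution_model()].
#' @param min_taxa genes with data for fewer taxa are excluded with a
#'   warning (their rate cannot be estimated).
#' @param ... passed to [optimize_branch_lengths()] (e.g. `max_sweeps`).
#' @return object of class `"rate_table"`: `table` (data frame `gene_id`,
#'   `tree_length`, `relative_rate`) and `excluded` (character).
#' @export
estimate_gene_rates <- function(matrix, reference_tree, model,
                                min_taxa = 4L, ...) {
  stopifnot(inherits(matrix, "supermatrix"))
  taxa <- taxa_of(matrix)
  if (!all(taxa %in% reference_tree$tip.label))
    stop("reference tree does not span the matrix taxa")
  reference_tree <- ape::unroot(ape::keep.tip(reference_tree, taxa))
  p <- matrix$partitions
  tl <- rep(NA_real_, nrow(p))
  for (i in seq_len(nrow(p))) {
    block <- slice_columns(matrix, p$start[i]:(p$end[i] - 1L))
    with_data <- taxa[rowSums(!is.na(block$x)) > 0L]
    if (length(with_data) < min_taxa) next
    sub <- ape::keep.tip(reference_tree, with_data)
    block$x <- block$x[with_data, , drop = FALSE]
    fit <- optimize_branch_lengths(sub, block, model, ...)
    tl[i] <- sum(fit$tree$edge.length)
  }
  excluded <- p$gene_id[is.na(tl)]
  if (length(excluded))
    warning("rate unestimable (fewer than ", min_taxa,
            " taxa with data), excluded: ", paste(excluded, collapse = ", "))
  ok <- !is.na(tl)
  structure(list(table = data.frame(gene_id = p$gene_id[ok],
                                    tree_length = tl[ok],
                                    relative_rate = tl[ok] / mean(tl[ok])),
                 excluded = excluded),
            class = "rate_table")
}

#' Construct a rate table from known relative rates
#' @param gene_id gene identifiers.
#' @param tree_length per-gene tree lengths (any positive scale).
#' @return object of class `"rate_table"`.
#' @export
rate_table <- function(gene_id, tree_length) {
  stopifnot(all(tree_length > 0), !anyDuplicated(gene_id))
  structure(list(table = data.frame(gene_id = as.character(gene_id),
                                    tree_length = tree_length,
                                    relative_rate = tree_length / mean(tree_length)),
                 excluded = character(0)),
            class = "rate_table")
}

#' Split a supermatrix into four gene-rate quartile datasets
#'
#' Genes are sorted by ascending relative rate (ties broken by gene id) and
#' assigned greedily to Q1..Q4 so that each quartile's cumulative column
#' count first reaches its share of the total: "equal-sized" means equal in
#' amino-acid columns (gene-count mode via `size_mode = "genes"`). Quartile
#' summaries report the column-weighted mean relative rate, percent
#' missing, column and gene counts; mean rates are non-decreasing Q1 to Q4
#' by construction.
#'
#' @param matrix a [supermatrix()].
#' @param rates a [rate_table()] covering the matrix genes (genes without a
#'   rate are dropped with a warning).
#' @param size_mode `"columns"` (default) or `"genes"`.
#' @return object of class `"quartile_split"`: `matrices` (list Q1..Q4),
#'   `summary` (data frame), `genes` (list of gene-id vectors).
#' @export
partition_quartiles <- function(matrix, rates,
                                size_mode = c("columns", "genes")) {
  stopifnot(inherits(matrix, "supermatrix"), inherits(rates, "rate_table"))
  size_mode <- match.arg(size_mode)
  p <- matrix$partitions
  rt <- rates$table
  unrated <- setdiff(p$gene_id, rt$gene_id)
  if (length(unrated))
    warning("genes without a rate dropped: ", paste(unrated, collapse = ", "))
  p <- p[p$gene_id %in% rt$gene_id, , drop = FALSE]
  if (nrow(p) < 4L) stop("quartile split needs at least 4 rated genes")
  rr <- rt$relative_rate[match(p$gene_id, rt$gene_id)]
  ord <- order(rr, p$gene_id, method = "radix")
  p <- p[ord, , drop = FALSE]; rr <- rr[ord]
  len <- p$end - p$start
  total <- if (size_mode == "columns") sum(len) else nrow(p)
  sizes <- if (size_mode == "columns") len else rep(1L, nrow(p))
  q <- integer(nrow(p)); cur <- 1L; cum <- 0
  for (i in seq_len(nrow(p))) {
    q[i] <- cur
    cum <- cum + sizes[i]
    if (cur < 4L && cum >= total * cur / 4) cur <- cur + 1L
  }
  mats <- vector("list", 4L); genes <- vector("list", 4L)
  summary <- data.frame(quartile = paste0("Q", 1:4), n_genes = 0L,
                        n_columns = 0L, relative_rate = NA_real_,
                        pct_missing = NA_real_)
  for (k in 1:4) {
    sel <- which(q == k)
    if (!length(sel)) stop("empty quartile (degenerate gene sizes)")
    cols <- unlist(lapply(sel, function(i) p$start[i]:(p$end[i] - 1L)))
    mats[[k]] <- slice_columns(matrix, cols)
    genes[[k]] <- p$gene_id[sel]
    summary$n_genes[k] <- length(sel)
    summary$n_columns[k] <- length(cols)
    summary$relative_rate[k] <- sum(rr[sel] * len[sel]) / sum(len[sel])
    summary$pct_missing[k] <- 100 - completeness_stats(mats[[k]])$overall
  }
  names(mats) <- names(genes) <- paste0("Q", 1:4)
  structure(list(matrices = mats, summary = summary, genes = genes),
            class = "quartile_split")
}

#' @export
print.quartile_split <- function(x, ...) {
  print(x$summary)
  invisible(x)
}

#' Run independent inferences on the four rate quartiles
#'
#' The configured inference (maximum likelihood: NJ start then NNI
#' hill-climbing; or Bayesian: profile-mixture MCMC with posterior
#' consensus) is run independently on Q1..Q4, and the pairwise symmetric
#' differences between the quartile trees' split sets are reported —
#' the instrument for diagnosing rate-dependent artifacts such as
#' long-branch attraction.
#'
#' @param matrix a [supermatrix()].
#' @param rates a [rate_table()].
#' @param model a [substitution_model()] for the inference.
#' @param method `"ml"` or `"mcmc"`.
#' @param mcmc_config an [mcmc_config()] when `method = "mcmc"`.
#' @param ... passed to the ML optimizer.
#' @return object of class `"dissection_result"`: `split` (the
#'   [partition_quartiles()] output), `trees` (list Q1..Q4), `supports`
#'   (list of [split_support()] or `NULL` for ML), `report` (data frame of
#'   pairwise split differences: columns `pair`, `split`, `in_a`, `in_b`).
#' @export
dissection_experiment <- function(matrix, rates, model,
                                  method = c("ml", "mcmc"),
                                  mcmc_config = NULL, ...) {
  method <- match.arg(method)
  split <- partition_quartiles(matrix, rates)
  trees <- vector("list", 4L); supports <- vector("list", 4L)
  for (k in 1:4) {
    mk <- split$matrices[[k]]
    if (method == "ml") {
      start <- nj_tree(mk, model)
      fit <- nni_search(start, mk, model, ...)
      trees[[k]] <- fit$tree
    } else {
      if (is.null(mcmc_config)) stop("mcmc method needs an mcmc_config")
      cfg <- mcmc_config
      cfg$seed <- derive_seed(cfg$seed, paste0("quartile", k))
      chains <- mcmc_run(mk, cfg, model)
      supports[[k]] <- posterior_supports(unlist(chains, recursive = FALSE))
      trees[[k]] <- majority_consensus(
        lapply(unlist(chains, recursive = FALSE), function(s) s$tree))
    }
  }
  names(trees) <- paste0("Q", 1:4)
  report <- data.frame(pair = character(0), split = character(0),
                       in_a = logical(0), in_b = logical(0))
  for (a in 1:3) for (b in (a + 1):4) {
    sa <- tree_splits(trees[[a]]); sb <- tree_splits(trees[[b]])
    sd_ <- union(setdiff(sa, sb), setdiff(sb, sa))
    if (length(sd_))
      report <- rbind(report,
                      data.frame(pair = paste0("Q", a, "-Q", b), split = sd_,
                                 in_a = sd_ %in% sa, in_b = sd_ %in% sb))
  }
  structure(list(split = split, trees = trees, supports = supports,
                 report = report),
            class = "dissection_result")
}
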