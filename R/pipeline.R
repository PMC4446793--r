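## Pipeline: simulate -> assemble -> rates -> dissect -> jackknife -> mcmc
## -> detect -> dollo, with a digest manifest.

fmt_num <- function(x) sprintf("%.6g", x)

write_tsv_hash <- function(df, path) {
  is_num <- vapply(df, is.numeric, logical(1)) &
    !vapply(df, is.integer, logical(1))
  for (j in which(is_num)) df[[j]] <- fmt_num(df[[j]])
  writeLines(c(paste0("#", paste(names(df), collapse = "\t")),
               do.call(paste, c(df, list(sep = "\t")))), path)
  invisible(path)
}

#' Simulate per-taxon protein sets containing diverged marker copies
#'
#' Generates one random ancestral sequence per marker; every taxon in
#' which the marker survives (per Dollo losses and false-negative noise,
#' see [simulate_dollo_characters()]) receives a copy with residues
#' substituted independently at rate `divergence`, hidden among
#' `n_decoys` unrelated sequences drawn from the same residue pool.
#'
#' @param tree rooted `ape::phylo`.
#' @param markers marker ids.
#' @param loss_branches named list marker -> branch ids (see
#'   [simulate_dollo_characters()]).
#' @param fn_rate false-negative (transcriptome dropout) probability.
#' @param divergence per-residue substitution probability of marker copies.
#' @param n_decoys unrelated sequences per taxon.
#' @param seq_length marker and decoy length (residues).
#' @param seed integer seed.
#' @return list with `sequence_sets` (taxon -> character vector),
#'   `references` (marker -> ancestral sequence), and `truth` (the
#'   generating [presence_absence_matrix()]).
#' @export
simulate_marker_sequences <- function(tree, markers, loss_branches = list(),
                                      fn_rate = 0, divergence = 0.1,
                                      n_decoys = 2L, seq_length = 120L,
                                      seed = 1L) {
  truth <- simulate_dollo_characters(tree, markers, loss_branches, fn_rate,
                                     seed)
  with_stream(seed, "marker_sequences", {
    rseq <- function() paste(sample(AA_ALPHABET, seq_length, replace = TRUE),
                             collapse = "")
    refs <- setNames(vapply(markers, function(m) rseq(), character(1)),
                     markers)
    mutate <- function(s) {
      ch <- strsplit(s, "")[[1]]
      hit <- runif(length(ch)) < divergence
      ch[hit] <- sample(AA_ALPHABET, sum(hit), replace = TRUE)
      paste(ch, collapse = "")
    }
    sets <- lapply(tree$tip.label, function(tx) {
      seqs <- vapply(seq_len(n_decoys), function(i) rseq(), character(1))
      for (m in markers)
        if (truth$states[tx, m] == "present")
          seqs <- c(seqs, mutate(refs[[m]]))
      seqs
    })
    names(sets) <- tree$tip.label
    list(sequence_sets = sets, references = as.list(refs), truth = truth)
  })
}

#' Pipeline configuration
#'
#' @param outdir output directory.
#' @param seed master seed; every stage derives its own stream from it.
#' @param sim_spec a [simulation_spec()]; default [preset_desk()].
#' @param exchangeabilities `"poisson"` or `"LG"` for the inference model.
#' @param stages stages to run, in order, from `c("simulate", "rates",
#'   "dissect", "jackknife", "mcmc", "detect")`.
#' @param rates_sweeps branch-optimization sweeps for gene-rate estimation.
#' @param jackknife_columns,jackknife_replicates jackknife protocol (desk
#'   defaults; the study-scale protocol is 20000 columns x 100 replicates).
#' @param jackknife_infer `"nj"` (fast) or `"ml"` (NJ start + NNI) per
#'   replicate.
#' @param mcmc_columns columns subsampled for the MCMC stage.
#' @param mcmc an [mcmc_config()] for the MCMC stage.
#' @param markers,loss_branches,marker_fn_rate detect-stage scenario.
#' @return list of class `"pipeline_config"`.
#' @export
pipeline_config <- function(outdir, seed = 1L,
                            sim_spec = preset_desk(seed),
                            exchangeabilities = "poisson",
                            stages = c("simulate", "rates", "dissect",
                                       "jackknife", "mcmc", "detect"),
                            rates_sweeps = 3L,
                            jackknife_columns = 1000L,
                            jackknife_replicates = 20L,
                            jackknife_infer = c("nj", "ml"),
                            mcmc_columns = 150L,
                            mcmc = mcmc_config(n_profiles = 4L,
                                               n_iterations = 150L,
                                               burnin_fraction = 0.3,
                                               move_weights = c(allocation = 1,
                                                                profile = 1,
                                                                branch = 4,
                                                                alpha = 1,
                                                                topology = 1),
                                               seed = seed),
                            markers = c("mk1", "mk2", "mk3"),
                            loss_branches = NULL,
                            marker_fn_rate = 0.05) {
  stages <- match.arg(stages, several.ok = TRUE)
  structure(list(outdir = outdir, seed = as.integer(seed),
                 sim_spec = sim_spec,
                 exchangeabilities = exchangeabilities, stages = stages,
                 rates_sweeps = rates_sweeps,
                 jackknife_columns = as.integer(jackknife_columns),
                 jackknife_replicates = as.integer(jackknife_replicates),
                 jackknife_infer = match.arg(jackknife_infer),
                 mcmc_columns = as.integer(mcmc_columns), mcmc = mcmc,
                 markers = markers, loss_branches = loss_branches,
                 marker_fn_rate = marker_fn_rate),
            class = "pipeline_config")
}

#' Run the configured pipeline
#'
#' Executes the requested stages in order, writing each stage's artifacts
#' under `outdir/<stage>/` and a manifest (`manifest.tsv`: relative path
#' and md5 digest of every artifact). Identical configuration and seed
#' reproduce identical digests. A stage failure aborts with the stage
#' name and cause; outputs of the failed stage are kept under a
#' `failed_<stage>` directory.
#'
#' @param config a [pipeline_config()].
#' @return the manifest data frame (invisibly also written to
#'   `outdir/manifest.tsv`).
#' @export
run_pipeline <- function(config) {
  stopifnot(inherits(config, "pipeline_config"))
  out <- config$outdir
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  model <- substitution_model(config$exchangeabilities,
                              alpha = config$sim_spec$alpha)
  env <- new.env()
  stage <- function(name, fun) {
    if (!name %in% config$stages) return(invisible(NULL))
    sdir <- file.path(out, name)
    dir.create(sdir, showWarnings = FALSE)
    message("pipeline stage: ", name)
    tryCatch(fun(sdir), error = function(e) {
      file.rename(sdir, file.path(out, paste0("failed_", name)))
      stop("stage ", name, " failed: ", conditionMessage(e), call. = FALSE)
    })
  }

  stage("simulate", function(sdir) {
    sim <- simulate_supermatrix(config$sim_spec, model)
    env$matrix <- sim$matrix
    env$truth <- sim$truth
    write_phylip(sim$matrix, file.path(sdir, "supermatrix.phy"))
    write_partition_tsv(sim$matrix, file.path(sdir, "partitions.tsv"))
    ape::write.tree(sim$truth$true_tree, file.path(sdir, "true_tree.nwk"))
    cs <- completeness_stats(sim$matrix)
    write_tsv_hash(data.frame(taxon = names(cs$per_taxon),
                              pct_complete = as.numeric(cs$per_taxon)),
                   file.path(sdir, "completeness.tsv"))
    jsonlite::write_json(list(gene_rates = as.list(sim$truth$gene_rates),
                              overall_completeness = cs$overall),
                         file.path(sdir, "truth.json"), auto_unbox = TRUE,
                         digits = NA)
  })

  stage("rates", function(sdir) {
    ref <- ape::unroot(env$truth$true_tree)
    env$rates <- estimate_gene_rates(env$matrix, ref, model,
                                     max_sweeps = config$rates_sweeps)
    write_tsv_hash(env$rates$table, file.path(sdir, "gene_rates.tsv"))
  })

  stage("dissect", function(sdir) {
    res <- dissection_experiment(env$matrix, env$rates, model,
                                 method = "ml", tol = 1e-4,
                                 max_sweeps = config$rates_sweeps)
    env$dissection <- res
    write_tsv_hash(res$split$summary, file.path(sdir, "quartile_summary.tsv"))
    for (k in 1:4) {
      write_phylip(res$split$matrices[[k]],
                   file.path(sdir, paste0("Q", k, ".phy")))
      write_partition_tsv(res$split$matrices[[k]],
                          file.path(sdir, paste0("Q", k, ".partitions.tsv")))
    }
    ape::write.tree(do.call(c, unname(res$trees)),
                    file.path(sdir, "quartile_trees.nwk"))
    if (nrow(res$report)) write_tsv_hash(res$report,
                                         file.path(sdir, "report.tsv"))
    else writeLines("#pair\tsplit\tin_a\tin_b", file.path(sdir, "report.tsv"))
  })

  stage("jackknife", function(sdir) {
    cfg <- jackknife_config(min(config$jackknife_columns, ncol(env$matrix$x)),
                            config$jackknife_replicates,
                            seed = derive_seed(config$seed, "jackknife"))
    reps <- jackknife_replicates(env$matrix, cfg)
    trees <- lapply(reps, function(r) {
      if (config$jackknife_infer == "nj") nj_tree(r, model)
      else nni_search(nj_tree(r, model), r, model, max_sweeps = 2L)$tree
    })
    ape::write.tree(do.call(c, trees), file.path(sdir, "replicate_trees.nwk"))
    sup <- split_frequencies(trees)
    write_tsv_hash(data.frame(split = names(sup$freq),
                              frequency = as.numeric(sup$freq)),
                   file.path(sdir, "split_supports.tsv"))
    cons <- majority_consensus(trees)
    ape::write.tree(cons, file.path(sdir, "consensus.nwk"))
    env$jackknife <- sup
  })

  stage("mcmc", function(sdir) {
    cols <- with_stream(derive_seed(config$seed, "mcmc_subsample"), "cols",
                        sort(sample.int(ncol(env$matrix$x),
                                        min(config$mcmc_columns,
                                            ncol(env$matrix$x)))) - 1L)
    sub <- slice_columns(env$matrix, cols)
    chains <- mcmc_run(sub, config$mcmc, model)
    for (i in seq_along(chains)) {
      tr <- data.frame(iteration = vapply(chains[[i]], `[[`, 0, "iteration"),
                       lnL = vapply(chains[[i]], `[[`, 0, "lnL"),
                       alpha = vapply(chains[[i]], `[[`, 0, "alpha"),
                       tree_length = vapply(chains[[i]], function(s)
                         sum(s$tree$edge.length), 0))
      write_tsv_hash(tr, file.path(sdir, paste0("chain", i, "_trace.tsv")))
      ape::write.tree(do.call(c, lapply(chains[[i]], `[[`, "tree")),
                      file.path(sdir, paste0("chain", i, "_trees.nwk")))
    }
    if (length(chains) >= 2) {
      cr <- convergence_report(chains)
      env$convergence <- cr
      writeLines(c(sprintf("MaxDiff\t%s", fmt_num(cr$max_diff)),
                   sprintf("MeanDiff\t%s", fmt_num(cr$mean_diff))),
                 file.path(sdir, "convergence.txt"))
      write_tsv_hash(cr$table, file.path(sdir, "convergence_splits.tsv"))
    }
  })

  stage("detect", function(sdir) {
    tree <- ensure_node_labels(env$truth$true_tree)
    loss <- config$loss_branches
    if (is.null(loss)) {
      # default scenario: one marker lost on the stem of an internal clade,
      # one on a terminal branch, one never lost
      ids <- branch_ids(tree)
      internal <- ids[tree$edge[, 2] > length(tree$tip.label)]
      loss <- list()
      if (length(internal)) loss[[config$markers[1]]] <- internal[[1]]
      if (length(config$markers) > 1)
        loss[[config$markers[2]]] <- tree$tip.label[1]
    }
    ms <- simulate_marker_sequences(tree, config$markers, loss,
                                    fn_rate = config$marker_fn_rate,
                                    seed = derive_seed(config$seed, "markers"))
    pam <- detect_presence(ms$sequence_sets, ms$references)
    rec <- dollo_map(tree, pam)
    env$detect <- list(pam = pam, reconstruction = rec, truth = ms$truth)
    write_tsv_hash(data.frame(taxon = rep(rownames(pam$states),
                                          ncol(pam$states)),
                              marker = rep(colnames(pam$states),
                                           each = nrow(pam$states)),
                              state = as.vector(pam$states),
                              best_score = as.vector(pam$scores)),
                   file.path(sdir, "presence_absence.tsv"))
    loss_df <- data.frame(
      marker = rep(names(rec$losses),
                   vapply(rec$losses, length, integer(1))),
      branch = unlist(rec$losses, use.names = FALSE))
    if (nrow(loss_df)) write_tsv_hash(loss_df, file.path(sdir, "losses.tsv"))
    else writeLines("#marker\tbranch", file.path(sdir, "losses.tsv"))
    ape::write.tree(tree, file.path(sdir, "labeled_tree.nwk"))
  })

  files <- sort(list.files(out, recursive = TRUE, full.names = FALSE),
                method = "radix")
  files <- setdiff(files, "manifest.tsv")
  manifest <- data.frame(path = files,
                         md5 = as.character(tools::md5sum(
                           file.path(out, files))))
  write_tsv_hash(manifest, file.path(out, "manifest.tsv"))
  invisible(manifest)
}
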