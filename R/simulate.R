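#' Specification of a synthetic supermatrix simulation
#'
#' Collects every knob of the generator: taxon count and topology shape,
#' designated long-branch taxa with their terminal-branch multiplier,
#' gene count and length distribution (negative binomial), the gene-rate
#' law (gamma with mean fixed at 1), among-site gamma shape, the number and
#' concentration of equilibrium-frequency profiles, the target completeness
#' (fraction of cells with data), and the master seed.
#'
#' @param n_taxa number of taxa (`>= 4`).
#' @param topology_mode `"balanced"`, `"caterpillar"`, or `"newick"`.
#' @param newick explicit Newick string when `topology_mode = "newick"`.
#' @param long_branch_taxa taxa whose terminal branches are elongated.
#' @param long_branch_scale multiplier (`>= 1`) for those terminals.
#' @param n_genes number of genes.
#' @param gene_length_mean,gene_length_dispersion negative-binomial mean and
#'   size for gene lengths (columns; floored at 10).
#' @param gene_rate_shape shape of the gamma law for per-gene rate
#'   multipliers; the rate equals the shape so the mean is 1.
#' @param alpha gamma shape for among-site rate variation.
#' @param n_profiles number of site frequency profiles K.
#' @param profile_concentration symmetric Dirichlet concentration for
#'   profile sampling (small = spiky, strong site heterogeneity).
#' @param target_completeness fraction of cells with data, in `(0, 1]`.
#' @param per_taxon_spread dispersion of per-taxon completeness around the
#'   target (0 = identical for all taxa).
#' @param branch_length_mean mean of the exponential law for base branch
#'   lengths (substitutions/site).
#' @param seed master seed; all operation streams derive from it.
#' @return object of class `"simulation_spec"`.
#' @export
simulation_spec <- function(n_taxa = 24L,
                            topology_mode = c("balanced", "caterpillar", "newick"),
                            newick = NULL,
                            long_branch_taxa = character(0),
                            long_branch_scale = 1,
                            n_genes = 400L,
                            gene_length_mean = 270,
                            gene_length_dispersion = 10,
                            gene_rate_shape = 2,
                            alpha = 1,
                            n_profiles = 10L,
                            profile_concentration = 0.3,
                            target_completeness = 0.72,
                            per_taxon_spread = 0.02,
                            branch_length_mean = 0.1,
                            seed = 1L) {
  topology_mode <- match.arg(topology_mode)
  if (n_taxa < 4) stop("n_taxa must be >= 4")
  if (long_branch_scale < 1) stop("long_branch_scale must be >= 1")
  if (!(target_completeness > 0 && target_completeness <= 1))
    stop("target_completeness must lie in (0, 1]")
  if (topology_mode == "newick" && is.null(newick))
    stop("topology_mode 'newick' requires a newick string")
  structure(list(n_taxa = as.integer(n_taxa), topology_mode = topology_mode,
                 newick = newick,
                 long_branch_taxa = as.character(long_branch_taxa),
                 long_branch_scale = long_branch_scale,
                 n_genes = as.integer(n_genes),
                 gene_length_mean = gene_length_mean,
                 gene_length_dispersion = gene_length_dispersion,
                 gene_rate_shape = gene_rate_shape, alpha = alpha,
                 n_profiles = as.integer(n_profiles),
                 profile_concentration = profile_concentration,
                 target_completeness = target_completeness,
                 per_taxon_spread = per_taxon_spread,
                 branch_length_mean = branch_length_mean,
                 seed = as.integer(seed)),
            class = "simulation_spec")
}

balanced_newick <- function(names) {
  if (length(names) == 1L) return(names)
  h <- ceiling(length(names) / 2)
  paste0("(", balanced_newick(names[seq_len(h)]), ",",
         balanced_newick(names[-seq_len(h)]), ")")
}

caterpillar_newick <- function(names) {
  s <- paste0("(", names[1], ",", names[2], ")")
  for (nm in names[-(1:2)]) s <- paste0("(", s, ",", nm, ")")
  s
}

#' Build the generating tree of a simulation
#'
#' Topology per `topology_mode`; base branch lengths are iid exponential
#' draws with mean `branch_length_mean` (an explicit Newick keeps the
#' lengths it carries). The terminal branches of `long_branch_taxa` equal
#' their base draw multiplied by `long_branch_scale`.
#'
#' @param spec a [simulation_spec()].
#' @return a rooted `ape::phylo` tree.
#' @export
build_tree <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  if (spec$topology_mode == "newick") {
    tree <- ape::read.tree(text = spec$newick)
  } else {
    taxa <- sprintf("t%02d", seq_len(spec$n_taxa))
    nwk <- if (spec$topology_mode == "balanced") balanced_newick(taxa)
           else caterpillar_newick(taxa)
    tree <- ape::read.tree(text = paste0(nwk, ";"))
  }
  nedge <- nrow(tree$edge)
  if (is.null(tree$edge.length)) {
    tree$edge.length <- with_stream(spec$seed, "build_tree",
                                    rexp(nedge, rate = 1 / spec$branch_length_mean))
  } else if (anyNA(tree$edge.length)) {
    draw <- with_stream(spec$seed, "build_tree",
                        rexp(nedge, rate = 1 / spec$branch_length_mean))
    tree$edge.length[is.na(tree$edge.length)] <- draw[is.na(tree$edge.length)]
  }
  if (length(spec$long_branch_taxa)) {
    miss <- setdiff(spec$long_branch_taxa, tree$tip.label)
    if (length(miss))
      stop("long_branch_taxa not in tree: ", paste(miss, collapse = ", "))
    tip_edge <- match(match(spec$long_branch_taxa, tree$tip.label),
                      tree$edge[, 2])
    tree$edge.length[tip_edge] <- tree$edge.length[tip_edge] *
      spec$long_branch_scale
  }
  tree
}

# Exact CTMC evolution along one branch by uniformization, vectorized over
# columns. states: parent states; lam: per-column expected event count
# (mu * t_eff); J: jump matrix of the uniformized chain.
evolve_states <- function(states, lam, J) {
  A <- nrow(J)
  nev <- stats::rpois(length(states), lam)
  active <- which(nev > 0L)
  while (length(active)) {
    cur <- states[active]              # snapshot: one jump per round
    new <- integer(length(active))
    for (s in unique(cur)) {
      at <- which(cur == s)
      new[at] <- sample.int(A, length(at), replace = TRUE, prob = J[s, ])
    }
    states[active] <- new
    nev[active] <- nev[active] - 1L
    active <- active[nev[active] > 0L]
  }
  states
}

#' Simulate a partitioned supermatrix under a profile-mixture model
#'
#' Each column is assigned a frequency profile (from the model's profiles
#' or freshly sampled per the spec) and a discrete-gamma rate category;
#' each gene carries a rate multiplier drawn from the spec's gamma law.
#' Root states are drawn from the column's profile and evolved along every
#' branch with effective length `branch * gene_rate * category_rate`
#' (exactly, via uniformization of the normalized generator). If the spec's
#' `target_completeness` is below 1, [apply_missing_mask()] is applied.
#'
#' @param spec a [simulation_spec()].
#' @param model a [substitution_model()]; its exchangeabilities, alpha and
#'   (if present) profiles are used.
#' @return list with `matrix` (a [supermatrix()]) and `truth` (class
#'   `"truth_record"`: `true_tree`, `gene_rates`, `site_profile_assignments`,
#'   `site_rate_categories`, `missing_mask`, `profiles`).
#' @export
simulate_supermatrix <- function(spec, model = substitution_model("poisson")) {
  stopifnot(inherits(spec, "simulation_spec"),
            inherits(model, "substitution_model"))
  tree <- build_tree(spec)
  profiles <- model$profiles
  if (is.null(profiles))
    profiles <- sample_profiles(spec$n_profiles, spec$profile_concentration,
                                derive_seed(spec$seed, "profiles"),
                                alphabet = model$alphabet)
  K <- nrow(profiles$profiles)
  model <- substitution_model(model$exchangeabilities,
                              model$frequencies, alpha = spec$alpha,
                              n_categories = model$n_categories,
                              profiles = profiles, alphabet = model$alphabet)
  A <- length(model$alphabet)
  g <- discrete_gamma_rates(spec$alpha, model$n_categories)

  lens <- with_stream(spec$seed, "gene_lengths",
                      pmax(10L, stats::rnbinom(spec$n_genes,
                                               mu = spec$gene_length_mean,
                                               size = spec$gene_length_dispersion)))
  gene_ids <- sprintf("g%04d", seq_len(spec$n_genes))
  rates <- with_stream(spec$seed, "gene_rates",
                       rgamma(spec$n_genes, shape = spec$gene_rate_shape,
                              rate = spec$gene_rate_shape))
  names(rates) <- gene_ids
  total <- sum(lens)
  col_gene <- rep.int(seq_len(spec$n_genes), lens)
  assign <- with_stream(spec$seed, "site_assignments", {
    list(profile = sample.int(K, total, replace = TRUE,
                              prob = profiles$weights),
         category = sample.int(length(g$rates), total, replace = TRUE))
  })

  # per-profile generator, uniformized
  Qs <- lapply(seq_len(K), function(c_idx) rate_matrix(model, c_idx))
  mus <- vapply(Qs, function(z) max(-diag(z$Q)), numeric(1))
  Js <- lapply(seq_len(K), function(c_idx) {
    J <- Qs[[c_idx]]$Q / mus[c_idx]
    diag(J) <- diag(J) + 1
    J[J < 0] <- 0
    J
  })

  po <- tree_postorder(tree)
  edges <- po$edges
  blen <- po$len
  ntip <- length(po$tree$tip.label)
  nnodes <- max(edges) + 1L
  root <- edges[nrow(edges), 1] + 1L
  col_rate <- rates[col_gene] * g$rates[assign$category]

  states <- matrix(0L, nnodes, total)
  states[root, ] <- with_stream(spec$seed, "root_states", {
    s <- integer(total)
    for (c_idx in seq_len(K)) {
      cols <- which(assign$profile == c_idx)
      s[cols] <- sample.int(A, length(cols), replace = TRUE,
                            prob = profiles$profiles[c_idx, ])
    }
    s
  })
  states <- with_stream(spec$seed, "evolve", {
    for (e in rev(seq_len(nrow(edges)))) {       # preorder
      par <- edges[e, 1] + 1L; chd <- edges[e, 2] + 1L
      for (c_idx in seq_len(K)) {
        cols <- which(assign$profile == c_idx)
        states[chd, cols] <- evolve_states(states[par, cols],
                                           mus[c_idx] * blen[e] * col_rate[cols],
                                           Js[[c_idx]])
      }
    }
    states
  })
  x <- states[seq_len(ntip), , drop = FALSE]
  rownames(x) <- po$tree$tip.label
  partitions <- data.frame(gene_id = gene_ids,
                           start = cumsum(c(0L, lens[-length(lens)])),
                           end = cumsum(lens))
  mat <- supermatrix(x, partitions, model$alphabet)

  mask <- matrix(FALSE, ntip, spec$n_genes,
                 dimnames = list(po$tree$tip.label, gene_ids))
  if (spec$target_completeness < 1) {
    mat <- apply_missing_mask(mat, spec$target_completeness,
                              spec$per_taxon_spread,
                              derive_seed(spec$seed, "mask"))
    mask <- attr(mat, "missing_mask")
  }
  truth <- structure(list(true_tree = tree, gene_rates = rates,
                          site_profile_assignments = assign$profile,
                          site_rate_categories = assign$category,
                          missing_mask = mask, profiles = profiles),
                     class = "truth_record")
  list(matrix = mat, truth = truth)
}

#' Drop whole gene blocks to emulate transcriptome incompleteness
#'
#' Each (taxon, gene) block is removed independently; the per-taxon keep
#' probability is the target completeness, optionally jittered across taxa
#' by a beta law with dispersion `per_taxon_spread` (matching the study-like
#' structure in which some taxa are much less complete than others). Every
#' taxon retains at least one gene. The realized taxon-by-gene dropout mask
#' is attached as attribute `"missing_mask"`.
#'
#' @param matrix a [supermatrix()].
#' @param target_completeness fraction in `(0, 1]`.
#' @param per_taxon_spread beta dispersion of per-taxon completeness
#'   (0 = none).
#' @param seed integer seed.
#' @return the masked [supermatrix()] with attribute `missing_mask`.
#' @export
apply_missing_mask <- function(matrix, target_completeness,
                               per_taxon_spread = 0, seed = 1L) {
  stopifnot(inherits(matrix, "supermatrix"))
  if (!(target_completeness > 0 && target_completeness <= 1))
    stop("target_completeness must lie in (0, 1]")
  p <- matrix$partitions
  taxa <- taxa_of(matrix)
  ngene <- nrow(p)
  mask <- matrix(FALSE, length(taxa), ngene,
                 dimnames = list(taxa, p$gene_id))
  if (target_completeness < 1) {
    mask <- with_stream(seed, "apply_missing_mask", {
      keep_p <- if (per_taxon_spread > 0) {
        nu <- 1 / per_taxon_spread
        stats::rbeta(length(taxa), target_completeness * nu,
                     (1 - target_completeness) * nu)
      } else rep(target_completeness, length(taxa))
      m <- matrix(runif(length(taxa) * ngene), length(taxa), ngene) >
        rep(keep_p, ngene)
      for (i in which(rowSums(!m) == 0L))
        m[i, sample.int(ngene, 1L)] <- FALSE
      dimnames(m) <- list(taxa, p$gene_id)
      m
    })
    x <- matrix$x
    for (gi in seq_len(ngene)) {
      drop <- which(mask[, gi])
      if (length(drop))
        x[drop, (p$start[gi] + 1L):p$end[gi]] <- NA_integer_
    }
    matrix$x <- x
  }
  attr(matrix, "missing_mask") <- mask
  matrix
}

#' Simulate marker-gene presence/absence with clade losses and noise
#'
#' A marker is present in a taxon iff no loss branch lies on the
#' root-to-taxon path; each present cell then flips to "undetected"
#' independently with probability `fn_rate`, emulating false negatives from
#' incomplete transcriptomes.
#'
#' Branches are identified by the label of the node below them (tip labels
#' for terminal branches, node labels for internal ones; unlabeled internal
#' nodes are auto-labeled `nd<number>` via [ensure_node_labels()]).
#'
#' @param tree rooted, node-labeled `ape::phylo` tree.
#' @param markers character vector of marker ids.
#' @param loss_branches named list: marker -> character vector of branch ids
#'   (markers without an entry suffer no loss).
#' @param fn_rate false-negative probability in `[0, 1)`.
#' @param seed integer seed.
#' @return a [presence_absence_matrix()] (scores `NA`).
#' @export
simulate_dollo_characters <- function(tree, markers, loss_branches = list(),
                                      fn_rate = 0, seed = 1L) {
  if (!ape::is.rooted(tree)) stop("tree must be rooted")
  if (!(fn_rate >= 0 && fn_rate < 1)) stop("fn_rate must lie in [0, 1)")
  tree <- ensure_node_labels(tree)
  ids <- branch_ids(tree)
  taxa <- tree$tip.label
  st <- matrix("present", length(taxa), length(markers),
               dimnames = list(taxa, markers))
  for (mk in names(loss_branches)) {
    if (!mk %in% markers) stop("loss for unknown marker: ", mk)
    for (br in loss_branches[[mk]]) {
      e <- match(br, ids)
      if (is.na(e)) stop("unknown branch id: ", br)
      st[tips_below_edge(tree, e), mk] <- "undetected"
    }
  }
  if (fn_rate > 0) {
    st <- with_stream(seed, "simulate_dollo_characters", {
      flip <- matrix(runif(length(st)) < fn_rate, nrow(st), ncol(st))
      st[st == "present" & flip] <- "undetected"
      st
    })
  }
  presence_absence_matrix(st)
}

## ---- presets ---------------------------------------------------------------

#' Simulation presets
#'
#' `preset_flatworm()` echoes the shape of a transcriptome-derived flatworm
#' supermatrix at desk scale: 24 taxa, 400 genes of mean length 270
#' (about 108,000 columns), 72% target completeness, four long-branch taxa,
#' 10 spiky frequency profiles. `preset_lba_demo()` is a Felsenstein-zone
#' quartet (two long non-sister terminals, short internal branch, strong
#' gene-rate spread and site heterogeneity) whose fast-rate genes push
#' homogeneous inference toward long-branch attraction.
#' `preset_desk()` is a small general-purpose preset used by the default
#' pipeline (12 taxa, 60 genes).
#'
#' @param seed master seed.
#' @return a [simulation_spec()].
#' @export
preset_flatworm <- function(seed = 1L) {
  simulation_spec(n_taxa = 24L, topology_mode = "balanced",
                  long_branch_taxa = c("t03", "t09", "t15", "t21"),
                  long_branch_scale = 5, n_genes = 400L,
                  gene_length_mean = 270, gene_length_dispersion = 10,
                  gene_rate_shape = 2, alpha = 1, n_profiles = 10L,
                  profile_concentration = 0.3, target_completeness = 0.72,
                  per_taxon_spread = 0.02, branch_length_mean = 0.08,
                  seed = seed)
}

#' @rdname preset_flatworm
#' @export
preset_lba_demo <- function(seed = 1L) {
  simulation_spec(n_taxa = 4L, topology_mode = "newick",
                  newick = "((t1:0.04,t2:0.05):0.02,(t3:0.04,t4:0.05):0.02);",
                  long_branch_taxa = c("t1", "t3"), long_branch_scale = 12.5,
                  n_genes = 100L, gene_length_mean = 100,
                  gene_length_dispersion = 20, gene_rate_shape = 2,
                  alpha = 1, n_profiles = 8L, profile_concentration = 0.2,
                  target_completeness = 1, seed = seed)
}

#' @rdname preset_flatworm
#' @export
preset_desk <- function(seed = 1L) {
  simulation_spec(n_taxa = 8L, topology_mode = "balanced",
                  long_branch_taxa = c("t03", "t07"), long_branch_scale = 4,
                  n_genes = 40L, gene_length_mean = 100,
                  gene_length_dispersion = 10, gene_rate_shape = 2,
                  alpha = 1, n_profiles = 5L, profile_concentration = 0.3,
                  target_completeness = 0.72, per_taxon_spread = 0.02,
                  branch_length_mean = 0.08, seed = seed)
}
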