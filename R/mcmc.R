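#' Configuration of the profile-mixture MCMC
#'
#' Priors: branch lengths iid exponential (mean `bl_prior_mean`), gamma
#' shape alpha exponential (mean `alpha_prior_mean`), profile frequency
#' vectors flat Dirichlet(1,...,1), topology uniform over unrooted
#' binary topologies; mixture weights are fixed uniform at 1/K.
#'
#' @param n_profiles number of mixture profiles K (`>= 1`).
#' @param n_iterations MCMC iterations per chain.
#' @param burnin_fraction fraction of iterations discarded, in `[0, 1)`.
#' @param sample_thinning record every `sample_thinning`-th post-burn-in
#'   iteration.
#' @param n_chains number of independent chains (default 2, so the
#'   between-chain split diagnostic is defined).
#' @param move_weights named counts of proposal attempts per iteration:
#'   `allocation` (Gibbs site reallocation passes), `profile` (Dirichlet
#'   proposals per profile), `branch` (random branch multiplier moves; 0
#'   means one move per branch), `alpha`, `topology` (NNI). A 0 disables
#'   the move type (`branch = -1` disables branch moves entirely).
#' @param bl_prior_mean,alpha_prior_mean prior means.
#' @param seed master seed; chain i uses the stream `"chain<i>"`.
#' @return object of class `"mcmc_config"`.
#' @export
mcmc_config <- function(n_profiles = 10L, n_iterations = 1000L,
                        burnin_fraction = 0.25, sample_thinning = 1L,
                        n_chains = 2L,
                        move_weights = c(allocation = 1, profile = 1,
                                         branch = 0, alpha = 1, topology = 1),
                        bl_prior_mean = 0.1, alpha_prior_mean = 1,
                        seed = 1L) {
  stopifnot(n_profiles >= 1, burnin_fraction >= 0, burnin_fraction < 1,
            n_iterations >= 1, sample_thinning >= 1, n_chains >= 1)
  structure(list(n_profiles = as.integer(n_profiles),
                 n_iterations = as.integer(n_iterations),
                 burnin_fraction = burnin_fraction,
                 sample_thinning = as.integer(sample_thinning),
                 n_chains = as.integer(n_chains),
                 move_weights = move_weights,
                 bl_prior_mean = bl_prior_mean,
                 alpha_prior_mean = alpha_prior_mean,
                 seed = as.integer(seed)),
            class = "mcmc_config")
}

ldirichlet <- function(x, a) {
  sum((a - 1) * log(pmax(x, 1e-300))) + lgamma(sum(a)) - sum(lgamma(a))
}

rdirichlet1 <- function(a) {
  g <- rgamma(length(a), shape = a, rate = 1)
  g / sum(g)
}

#' Run the profile-mixture MCMC
#'
#' Metropolis-within-Gibbs under a finite K-profile site-heterogeneous
#' mixture with discrete-gamma rates: (i) Gibbs reallocation of every site
#' to a profile proportionally to mixture weight times the site likelihood
#' under that profile; (ii) Dirichlet random-walk proposals on each
#' profile's frequencies; (iii) log-scale multiplier proposals on branch
#' lengths and alpha; (iv) NNI topology proposals. Exchangeabilities stay
#' fixed at the supplied model's (the main simplification relative to a
#' full CAT+GTR sampler). Proposal windows are tuned during burn-in only
#' and frozen afterwards. Samples are recorded after burn-in at the
#' thinning interval.
#'
#' @param matrix a [supermatrix()] (`>= 4` taxa).
#' @param config an [mcmc_config()].
#' @param model a [substitution_model()] supplying the fixed
#'   exchangeabilities and the alphabet.
#' @return object of class `"mcmc_chains"`: a list of chains, each a list
#'   of samples with fields `iteration`, `tree`, `alpha`, `profiles`,
#'   `site_allocations`, `lnL`, `ln_prior`.
#' @export
mcmc_run <- function(matrix, config, model = substitution_model("poisson")) {
  stopifnot(inherits(matrix, "supermatrix"), inherits(config, "mcmc_config"))
  if (nrow(matrix$x) < 4L) stop("MCMC needs >= 4 taxa")
  chains <- lapply(seq_len(config$n_chains), function(i)
    run_chain(matrix, config, model,
              derive_seed(config$seed, paste0("chain", i))))
  structure(chains, class = "mcmc_chains")
}

run_chain <- function(matrix, config, model, chain_seed) {
  withr::with_seed(chain_seed, {
    taxa <- taxa_of(matrix)
    A <- length(model$alphabet)
    K <- config$n_profiles
    ncat <- model$n_categories
    nsite <- ncol(matrix$x)
    x <- matrix$x - 1L                # 0-based states for the pruning core
    x[is.na(x)] <- -1L
    cp <- compress_patterns(x)        # rows in `taxa` order
    npat <- length(cp$weights)
    mw <- config$move_weights

    # initial state from the priors
    tree <- ape::unroot(ape::rtree(length(taxa), tip.label = sample(taxa)))
    tree$edge.length <- rexp(nrow(tree$edge), 1 / config$bl_prior_mean)
    alpha <- rexp(1, 1 / config$alpha_prior_mean)
    profiles <- t(vapply(seq_len(K), function(i) rdirichlet1(rep(1, A)),
                         numeric(A)))
    alloc <- sample.int(K, nsite, replace = TRUE)

    exch <- model$exchangeabilities
    qcache <- lapply(seq_len(K), function(c_idx) {
      pi <- profiles[c_idx, ]
      Q <- exch %*% diag(pi); diag(Q) <- 0; diag(Q) <- -rowSums(Q)
      sc <- -sum(pi * diag(Q))
      edecomp(Q / sc, pi)
    })

    # per-pattern log-likelihood under each profile, K x npat
    compute_llk <- function(po, tipmat, eds, alpha) {
      g <- discrete_gamma_rates(alpha, ncat)
      out <- vapply(eds, function(ed) {
        nedge <- nrow(po$edges)
        P <- array(0, c(A, A, nedge * length(g$rates)))
        for (e in seq_len(nedge))
          for (k in seq_along(g$rates))
            P[, , (e - 1L) * length(g$rates) + k] <-
              pmat_from_edecomp(ed, po$len[e] * g$rates[k])
        as.numeric(plik_patterns_cpp(po$edges, P, tipmat, ed$pi, g$weights))
      }, numeric(npat))
      matrix(out, length(eds), npat, byrow = TRUE)
    }
    new_po <- function(tree) {
      po <- tree_postorder(tree)
      list(po = po,
           tipmat = cp$pat[match(po$tree$tip.label, taxa), , drop = FALSE])
    }
    st <- new_po(tree)
    llk <- compute_llk(st$po, st$tipmat, qcache, alpha)
    if (any(!is.finite(llk[cbind(alloc, cp$index)]))) {
      bad <- which(!is.finite(llk[cbind(alloc, cp$index)]))[1]
      stop("non-finite likelihood at initialization (column ", bad, ")")
    }
    joint_ll <- function(llk, alloc) sum(llk[cbind(alloc, cp$index)])
    ln_prior <- function(tree, alpha) {
      sum(dexp(tree$edge.length, 1 / config$bl_prior_mean, log = TRUE)) +
        dexp(alpha, 1 / config$alpha_prior_mean, log = TRUE)
    }
    cur_ll <- joint_ll(llk, alloc)

    win_bl <- 1; win_alpha <- 0.8; win_prof <- 200
    acc_bl <- att_bl <- acc_a <- att_a <- 0L
    burn_end <- floor(config$burnin_fraction * config$n_iterations)
    samples <- list()
    nedge <- nrow(tree$edge)

    for (iter in seq_len(config$n_iterations)) {
      # window tuning during burn-in only (frozen after, so retained
      # samples obey detailed balance)
      if (iter <= burn_end && iter %% 50L == 0L) {
        if (att_bl > 0) {
          r <- acc_bl / att_bl
          if (r > 0.45) win_bl <- min(win_bl * 1.3, 5)
          if (r < 0.15) win_bl <- max(win_bl / 1.3, 0.05)
        }
        if (att_a > 0) {
          r <- acc_a / att_a
          if (r > 0.45) win_alpha <- min(win_alpha * 1.3, 5)
          if (r < 0.15) win_alpha <- max(win_alpha / 1.3, 0.05)
        }
        acc_bl <- att_bl <- acc_a <- att_a <- 0L
      }
      ## (i) Gibbs site reallocation
      if (mw[["allocation"]] > 0) {
        lw <- llk[, cp$index, drop = FALSE] + log(1 / K)
        gum <- -log(-log(matrix(runif(K * nsite), K, nsite)))
        alloc <- max.col(t(lw + gum))
        cur_ll <- joint_ll(llk, alloc)
      }
      ## (ii) profile frequency updates
      if (mw[["profile"]] > 0) for (c_idx in seq_len(K)) {
        pi0 <- profiles[c_idx, ]
        a_fwd <- win_prof * pi0 + 0.05
        pi1 <- rdirichlet1(a_fwd)
        a_bwd <- win_prof * pi1 + 0.05
        sites_c <- which(alloc == c_idx)
        Q <- exch %*% diag(pi1); diag(Q) <- 0; diag(Q) <- -rowSums(Q)
        sc <- -sum(pi1 * diag(Q))
        ed1 <- edecomp(Q / sc, pi1)
        llk_c <- compute_llk(st$po, st$tipmat, list(ed1), alpha)
        d_ll <- sum(llk_c[1, cp$index[sites_c]]) -
          sum(llk[c_idx, cp$index[sites_c]])
        d_hast <- ldirichlet(pi0, a_bwd) - ldirichlet(pi1, a_fwd)
        if (log(runif(1)) < d_ll + d_hast) {
          profiles[c_idx, ] <- pi1
          qcache[[c_idx]] <- ed1
          llk[c_idx, ] <- llk_c[1, ]
          cur_ll <- cur_ll + d_ll
        }
      }
      ## (iii) branch length multipliers
      if (mw[["branch"]] >= 0) {
        idx <- if (mw[["branch"]] == 0) seq_len(nedge)
               else sample.int(nedge, min(nedge, mw[["branch"]]))
        for (e in idx) {
          t0 <- tree$edge.length[e]
          t1 <- t0 * exp(win_bl * (runif(1) - 0.5))
          tree1 <- tree; tree1$edge.length[e] <- t1
          st1 <- new_po(tree1)
          llk1 <- compute_llk(st1$po, st1$tipmat, qcache, alpha)
          d <- joint_ll(llk1, alloc) - cur_ll +
            dexp(t1, 1 / config$bl_prior_mean, log = TRUE) -
            dexp(t0, 1 / config$bl_prior_mean, log = TRUE) +
            log(t1) - log(t0)
          att_bl <- att_bl + 1L
          if (log(runif(1)) < d) {
            acc_bl <- acc_bl + 1L
            tree <- tree1; st <- st1; llk <- llk1
            cur_ll <- joint_ll(llk, alloc)
          }
        }
      }
      ## (iii') alpha multiplier
      if (mw[["alpha"]] > 0) {
        a1 <- alpha * exp(win_alpha * (runif(1) - 0.5))
        llk1 <- compute_llk(st$po, st$tipmat, qcache, a1)
        d <- joint_ll(llk1, alloc) - cur_ll +
          dexp(a1, 1 / config$alpha_prior_mean, log = TRUE) -
          dexp(alpha, 1 / config$alpha_prior_mean, log = TRUE) +
          log(a1) - log(alpha)
        att_a <- att_a + 1L
        if (log(runif(1)) < d) {
          acc_a <- acc_a + 1L
          alpha <- a1; llk <- llk1; cur_ll <- joint_ll(llk, alloc)
        }
      }
      ## (iv) NNI topology proposal (uniform over the 2*(n-3) rearrangements)
      if (mw[["topology"]] > 0 && length(taxa) >= 4L) {
        nbs <- phangorn::nni(tree)
        pick <- nbs[[sample.int(length(nbs), 1)]]
        if (is.null(pick$edge.length))
          pick$edge.length <- rep(config$bl_prior_mean, nrow(pick$edge))
        st1 <- new_po(pick)
        llk1 <- compute_llk(st1$po, st1$tipmat, qcache, alpha)
        d <- joint_ll(llk1, alloc) - cur_ll +
          sum(dexp(pick$edge.length, 1 / config$bl_prior_mean, log = TRUE)) -
          sum(dexp(tree$edge.length, 1 / config$bl_prior_mean, log = TRUE))
        if (log(runif(1)) < d) {
          tree <- pick; st <- st1; llk <- llk1
          cur_ll <- joint_ll(llk, alloc)
        }
      }
      if (iter > burn_end &&
          (iter - burn_end) %% config$sample_thinning == 0L) {
        samples[[length(samples) + 1L]] <-
          list(iteration = iter, tree = tree, alpha = alpha,
               profiles = profile_set(profiles),
               site_allocations = alloc, lnL = cur_ll,
               ln_prior = ln_prior(tree, alpha))
      }
    }
    samples
  })
}

#' Posterior bipartition supports from MCMC samples
#'
#' @param samples a list of chain samples (one chain), or all chains
#'   flattened.
#' @param burnin_fraction additional fraction of the given samples to drop
#'   from the front (the sampler has usually discarded its burn-in
#'   already); `0.5` on 100 samples keeps exactly the last 50.
#' @return a [split_support()].
#' @export
posterior_supports <- function(samples, burnin_fraction = 0) {
  stopifnot(burnin_fraction >= 0, burnin_fraction < 1)
  drop_n <- floor(burnin_fraction * length(samples))
  if (length(samples) - drop_n < 1L) stop("no post-burn-in samples")
  kept <- samples[(drop_n + 1L):length(samples)]
  split_frequencies(lapply(kept, function(s) s$tree))
}

#' Between-chain convergence report (MaxDiff / MeanDiff)
#'
#' Applies [chain_compare()] to the posterior supports of independent
#' chains; with more than two chains, reports the pairwise maximum of both
#' statistics and the per-split table of the worst pair.
#'
#' @param chains an `"mcmc_chains"` object (or list of sample lists),
#'   `>= 2` chains.
#' @param burnin_fraction passed to [posterior_supports()].
#' @return list with `max_diff`, `mean_diff`, `table`.
#' @export
convergence_report <- function(chains, burnin_fraction = 0) {
  if (length(chains) < 2L) stop("need >= 2 chains")
  sups <- lapply(chains, posterior_supports, burnin_fraction = burnin_fraction)
  best <- NULL
  for (i in seq_len(length(sups) - 1L)) for (j in (i + 1L):length(sups)) {
    cc <- chain_compare(sups[[i]], sups[[j]])
    if (is.null(best) || cc$max_diff > best$max_diff ||
        (cc$max_diff == best$max_diff && cc$mean_diff > best$mean_diff))
      best <- cc
  }
  best
}
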