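#' @useDynLib phylosect, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats optimize qgamma pgamma rgamma rexp runif rbinom rnbinom
#'   rmultinom setNames dexp ks.test
NULL

#' The 20 amino acids in PAML order
#'
#' The order in which empirical exchangeability matrices are published.
#' @export
AA_ALPHABET <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
                 "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

#' Construct a time-reversible substitution model
#'
#' Houses the exchangeabilities `r_ij`, stationary frequencies `pi`, the
#' discrete-gamma shape `alpha` with its number of categories, and an
#' optional set of equilibrium-frequency profiles for site-heterogeneous
#' (CAT-style) likelihoods.
#'
#' @param exchangeabilities symmetric positive matrix of relative rates
#'   (diagonal ignored), or the string `"poisson"` (all equal) or `"LG"`
#'   (the Le–Gascuel empirical matrix, taken from the installed phangorn).
#' @param frequencies stationary frequencies summing to 1; defaults to
#'   uniform for `"poisson"` and the LG frequencies for `"LG"`.
#' @param alpha gamma shape for among-site rate variation (`> 0`).
#' @param n_categories number of equal-weight discrete gamma categories.
#' @param profiles optional [profile_set()] for site-heterogeneous models.
#' @param alphabet character vector of states; default the 20 amino acids.
#' @return an object of class `"substitution_model"`.
#' @export
substitution_model <- function(exchangeabilities = "poisson",
                               frequencies = NULL,
                               alpha = 1,
                               n_categories = 4L,
                               profiles = NULL,
                               alphabet = AA_ALPHABET) {
  n <- length(alphabet)
  if (is.character(exchangeabilities)) {
    key <- match.arg(tolower(exchangeabilities), c("poisson", "lg"))
    if (key == "poisson") {
      exch <- matrix(1, n, n)
      if (is.null(frequencies)) frequencies <- rep(1 / n, n)
    } else {
      if (n != 20L)
        stop("the LG matrix is defined for the 20 amino-acid alphabet")
      lg <- lg_model()
      exch <- lg$exchangeabilities
      if (is.null(frequencies)) frequencies <- lg$frequencies
    }
  } else {
    exch <- as.matrix(exchangeabilities)
    if (!isTRUE(all.equal(exch, t(exch), tolerance = 1e-10)))
      stop("exchangeabilities must be symmetric")
    if (any(exch[upper.tri(exch)] <= 0))
      stop("exchangeabilities must be positive")
    if (is.null(frequencies)) frequencies <- rep(1 / n, n)
  }
  frequencies <- check_simplex(frequencies, n, "frequencies")
  stopifnot(alpha > 0, n_categories >= 1)
  if (!is.null(profiles)) {
    stopifnot(inherits(profiles, "profile_set"))
    if (ncol(profiles$profiles) != n)
      stop("profile alphabet size does not match model alphabet")
  }
  diag(exch) <- 0
  structure(list(exchangeabilities = exch,
                 frequencies = frequencies,
                 alpha = alpha,
                 n_categories = as.integer(n_categories),
                 profiles = profiles,
                 alphabet = alphabet),
            class = "substitution_model")
}

check_simplex <- function(p, n, what) {
  p <- as.numeric(p)
  if (length(p) != n) stop(what, " must have length ", n)
  if (any(p < 0) || abs(sum(p) - 1) > 1e-8)
    stop(what, " must be a simplex (non-negative, summing to 1)")
  p / sum(p)
}

# LG exchangeabilities + frequencies from the installed phangorn namespace.
# phangorn stores the lower triangle column-wise in PAML order.
lg_model <- function() {
  lg <- get(".LG", envir = asNamespace("phangorn"))
  n <- 20L
  exch <- matrix(0, n, n, dimnames = list(AA_ALPHABET, AA_ALPHABET))
  exch[lower.tri(exch)] <- lg$Q
  exch <- exch + t(exch)
  freqs <- as.numeric(lg$bf)
  list(exchangeabilities = exch, frequencies = freqs / sum(freqs))
}

#' Build the normalized rate matrix Q of a model
#'
#' Off-diagonal entries are `Q_ij = r_ij * pi_j`, the diagonal makes rows
#' sum to zero, and the whole matrix is scaled so the expected substitution
#' rate at stationarity, `-sum_i pi_i Q_ii`, equals 1 (branch lengths are
#' then in expected substitutions per site).
#'
#' @param model a [substitution_model()].
#' @param profile_index optional index into `model$profiles`; if given, the
#'   profile's frequencies replace `model$frequencies`.
#' @return list with `Q` (the normalized rate matrix) and `pi` (the
#'   frequencies used).
#' @export
rate_matrix <- function(model, profile_index = NULL) {
  stopifnot(inherits(model, "substitution_model"))
  pi <- model$frequencies
  if (!is.null(profile_index)) {
    if (is.null(model$profiles)) stop("model carries no profiles")
    pi <- model$profiles$profiles[profile_index, ]
  }
  pi <- check_simplex(pi, length(model$alphabet), "frequencies")
  Q <- model$exchangeabilities %*% diag(pi)
  diag(Q) <- 0
  diag(Q) <- -rowSums(Q)
  scale <- -sum(pi * diag(Q))
  if (scale <= 0) stop("degenerate rate matrix (zero expected rate)")
  list(Q = Q / scale, pi = pi)
}

# Symmetric eigendecomposition of a reversible Q for fast P(t).
# Q = diag(1/d) V diag(lambda) t(V) diag(d), with d = sqrt(pi).
edecomp <- function(Q, pi) {
  d <- sqrt(pi)
  B <- (d * Q) %*% diag(1 / d)   # diag(d) %*% Q %*% diag(1/d)
  B <- (B + t(B)) / 2
  e <- eigen(B, symmetric = TRUE)
  list(L = (1 / d) * e$vectors,          # diag(1/d) %*% V
       R = t(e$vectors * d),             # t(V) %*% diag(d)
       lambda = e$values, pi = pi)
}

pmat_from_edecomp <- function(ed, t) {
  P <- ed$L %*% (exp(ed$lambda * t) * ed$R)
  P[P < 0] <- 0
  P
}

#' Transition probability matrix P(t) = exp(Qt)
#'
#' Computed by symmetric eigendecomposition of the reversible generator.
#' Small negative entries from floating-point round-off are clamped to 0.
#'
#' @param Q rate matrix (or the list returned by [rate_matrix()]).
#' @param t branch length, `>= 0`.
#' @param pi stationary frequencies of `Q`; required when `Q` is a bare
#'   matrix.
#' @return the transition matrix, rows summing to 1.
#' @export
transition_probabilities <- function(Q, t, pi = NULL) {
  if (is.list(Q)) { pi <- Q$pi; Q <- Q$Q }
  if (is.null(pi)) stop("pi required")
  if (t < 0) stop("branch length must be non-negative")
  pmat_from_edecomp(edecomp(Q, pi), t)
}

#' Discrete-gamma rate categories (mean-of-bin discretization)
#'
#' Rates are the conditional means of a Gamma(shape = alpha, rate = alpha)
#' distribution over its `n_categories` equal-probability quantile bins, so
#' the weighted mean rate is exactly 1.
#'
#' @param alpha gamma shape, `> 0`.
#' @param n_categories number of categories, `>= 1`.
#' @return list with `rates` and (equal) `weights`.
#' @export
discrete_gamma_rates <- function(alpha, n_categories = 4L) {
  stopifnot(alpha > 0, n_categories >= 1)
  n <- as.integer(n_categories)
  if (n == 1L) return(list(rates = 1, weights = 1))
  q <- qgamma(seq_len(n - 1L) / n, shape = alpha, rate = alpha)
  # E[X; a<X<b] for X~Gamma(alpha, alpha) is F_{alpha+1,alpha}(b) - F(a)
  cum <- c(0, pgamma(q, shape = alpha + 1, rate = alpha), 1)
  rates <- n * diff(cum)
  rates <- rates / mean(rates)   # pin the mean at exactly 1
  list(rates = rates, weights = rep(1 / n, n))
}

#' Sample a set of equilibrium-frequency profiles
#'
#' Draws `K` frequency vectors over the amino-acid alphabet from a
#' symmetric Dirichlet. Small `concentration` gives spiky profiles (strong
#' site heterogeneity), large `concentration` near-uniform ones. Mixture
#' weights are uniform.
#'
#' @param K number of profiles, `>= 1`.
#' @param concentration symmetric Dirichlet concentration, `> 0`.
#' @param seed integer seed.
#' @param alphabet state alphabet.
#' @return object of class `"profile_set"`: `profiles` (K x alphabet matrix,
#'   rows summing to 1) and `weights`.
#' @export
sample_profiles <- function(K, concentration, seed,
                            alphabet = AA_ALPHABET) {
  if (!is.numeric(K) || K < 1) stop("K must be a positive count")
  if (!is.numeric(concentration) || concentration <= 0)
    stop("concentration must be positive")
  K <- as.integer(K)
  n <- length(alphabet)
  profs <- with_stream(seed, "sample_profiles", {
    g <- matrix(rgamma(K * n, shape = concentration, rate = 1), K, n)
    g / rowSums(g)
  })
  colnames(profs) <- alphabet
  profile_set(profs)
}

#' Construct a profile set
#' @param profiles K x alphabet matrix, rows summing to 1.
#' @param weights mixture weights; default uniform.
#' @return object of class `"profile_set"`.
#' @export
profile_set <- function(profiles, weights = NULL) {
  profiles <- as.matrix(profiles)
  if (any(profiles < 0) || any(abs(rowSums(profiles) - 1) > 1e-8))
    stop("each profile must be a simplex")
  profiles <- profiles / rowSums(profiles)
  K <- nrow(profiles)
  if (is.null(weights)) weights <- rep(1 / K, K)
  weights <- check_simplex(weights, K, "weights")
  structure(list(profiles = profiles, weights = weights),
            class = "profile_set")
}
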