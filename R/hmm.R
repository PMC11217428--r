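#' Euclidean distance between two points
#'
#' @param p,q Numeric 3-vectors (Angstrom).
#' @return Scalar distance in Angstrom.
#' @export
pairwise_distance <- function(p, q) sqrt(sum((as.numeric(p) - as.numeric(q))^2))

#' Scaled Gaussian transition density
#'
#' The density used to convert an inter-atom distance into an (unnormalized)
#' transition probability: a Gaussian PDF centered at the consecutive
#' C-alpha distance `mu` whose standard deviation is inflated by the scale
#' factor `lambda`, i.e. effective spread `lambda * sigma`:
#' `f(x) = exp(-(x - mu)^2 / (2 (lambda sigma)^2)) / (lambda sigma sqrt(2 pi))`.
#'
#' @param x Distance(s) in Angstrom.
#' @param mu Mean consecutive C-alpha distance (default 3.8047 Angstrom).
#' @param sigma Standard deviation of that distance (default 0.036 Angstrom).
#' @param lambda Dimensionless spread scale (default 10).
#' @return Density value(s).
#' @export
#' @examples
#' gaussian_transition_density(3.8047)  # peak value 1 / (0.36 sqrt(2 pi))
gaussian_transition_density <- function(x, mu = 3.8047, sigma = 0.036, lambda = 10) {
  if (sigma <= 0 || lambda <= 0) abort("`sigma` and `lambda` must be positive.")
  stats::dnorm(x, mean = mu, sd = lambda * sigma)
}

log_gaussian_transition <- function(x, mu, sigma, lambda) {
  s <- lambda * sigma
  -((x - mu)^2) / (2 * s^2) - log(s) - 0.5 * log(2 * pi)
}

#' Build the HMM transition matrix from atom geometry
#'
#' `gamma[i, j]` is the scaled Gaussian density of the distance between atoms
#' i and j, zero on the diagonal (a residue cannot succeed itself), with each
#' row normalized to sum 1. Rows are computed in log space so that a row
#' whose densities all underflow still normalizes cleanly.
#'
#' @param atoms A `ca_atom_set` (or any tibble with `x`, `y`, `z`).
#' @inheritParams gaussian_transition_density
#' @return A `hmm_transition` list: `log_gamma` (K x K, diagonal `-Inf`) and
#'   `gamma` (the linear-space stochastic matrix).
#' @export
build_transition <- function(atoms, mu = 3.8047, sigma = 0.036, lambda = 10) {
  K <- nrow(atoms)
  if (K < 2L) abort("at least two atoms are required to build transitions.")
  xyz <- as.matrix(atoms[, c("x", "y", "z")])
  d <- unname(as.matrix(dist(xyz)))
  lg <- log_gaussian_transition(d, mu, sigma, lambda)
  diag(lg) <- -Inf
  lg <- lg - apply(lg, 1L, logsumexp)        # row-normalize in log space
  list(log_gamma = lg, gamma = exp(lg))
}

logsumexp <- function(x) {
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Build the HMM emission matrix
#'
#' Emission of amino acid v from state i is the normalized geometric mean of
#' the state's predicted amino-acid probability `a_iv` and the background
#' frequency `b_v`: `delta[i, v] = sqrt(a_iv b_v) / sum_w sqrt(a_iw b_w)`.
#' A state whose products are all zero receives a uniform row with a warning.
#'
#' @param atoms A `ca_atom_set` with an `aa_probs` (n x 20) matrix column.
#' @param background Length-20 background frequencies summing to 1
#'   (default [aa_background()]).
#' @return K x 20 row-stochastic emission matrix.
#' @export
build_emission <- function(atoms, background = aa_background()) {
  background <- as.numeric(background)
  if (length(background) != 20L || any(background < 0) ||
      abs(sum(background) - 1) > 1e-6) {
    abort("`background` must be 20 non-negative frequencies summing to 1.")
  }
  a <- atoms$aa_probs
  g <- sqrt(sweep(a, 2L, background, "*"))
  rs <- rowSums(g)
  dead <- rs <= 0
  if (any(dead)) {
    warn(sprintf("%d state(s) with all-zero emission products; using uniform rows.", sum(dead)))
    g[dead, ] <- 1 / 20
    rs[dead] <- 1
  }
  g / rs
}

#' Build the initial state distribution
#'
#' The initial probability of state i is its emission probability of the
#' chain's first amino acid, normalized over states:
#' `pi_i = delta[i, o1] / sum_k delta[k, o1]`.
#'
#' @param delta Emission matrix from [build_emission()].
#' @param first_symbol One-letter code of the chain's first residue, or its
#'   index in 1..20.
#' @return Length-K probability vector.
#' @export
build_initial <- function(delta, first_symbol) {
  v <- if (is.character(first_symbol)) aa_index(first_symbol) else as.integer(first_symbol)
  col <- delta[, v]
  s <- sum(col)
  if (s <= 0) {
    warn("all-zero emission column for the first symbol; using a uniform initial distribution.")
    return(rep(1 / nrow(delta), nrow(delta)))
  }
  col / s
}

#' Assemble the HMM over a set of predicted C-alpha atoms
#'
#' One hidden state per atom; transitions from geometry
#' ([build_transition()]), emissions from predicted amino-acid probabilities
#' and background frequencies ([build_emission()]). The initial distribution
#' is built per chain at alignment time from the chain's first residue.
#'
#' @param atoms A `ca_atom_set`.
#' @inheritParams gaussian_transition_density
#' @inheritParams build_emission
#' @return A `ca_hmm` list: `atoms`, `log_gamma`, `gamma`, `delta`,
#'   `mu`, `sigma`, `lambda`, `background`.
#' @export
build_hmm <- function(atoms, mu = 3.8047, sigma = 0.036, lambda = 10,
                      background = aa_background()) {
  tr <- build_transition(atoms, mu, sigma, lambda)
  delta <- build_emission(atoms, background)
  structure(list(atoms = atoms,
                 log_gamma = tr$log_gamma, gamma = tr$gamma, delta = delta,
                 mu = mu, sigma = sigma, lambda = lambda,
                 background = as.numeric(background)),
            class = "ca_hmm")
}

#' @export
print.ca_hmm <- function(x, ...) {
  cat(sprintf("<ca_hmm> %d hidden states over 20 symbols (mu %.4f A, sigma %.3f A, lambda %g)\n",
              nrow(x$delta), x$mu, x$sigma, x$lambda))
  invisible(x)
}

#' Serialize a small HMM to JSON (debugging aid)
#'
#' @param hmm A `ca_hmm`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hmm_json <- function(hmm, path) {
  if (nrow(hmm$delta) > 200L) abort("refusing to dump an HMM with more than 200 states.")
  jsonlite::write_json(
    list(mu = hmm$mu, sigma = hmm$sigma, lambda = hmm$lambda,
         background = hmm$background,
         gamma = hmm$gamma, delta = hmm$delta,
         coordinates = as.matrix(hmm$atoms[, c("x", "y", "z")])),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
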