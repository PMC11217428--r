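# Shared fixtures and independent oracles used across the suite.

# internal helpers referenced by tests, resolved against the installed package
aa_index <- voxtrace:::aa_index
AA_ALPHABET <- voxtrace:::AA_ALPHABET
AA_BACKGROUND <- voxtrace:::AA_BACKGROUND

# a tiny atom set with given coordinates and amino-acid probability rows
make_atoms <- function(xyz, aa_probs = NULL, ca_prob = NULL) {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(aa_probs)) aa_probs <- matrix(1 / 20, n, 20)
  if (is.null(ca_prob)) ca_prob <- rep(0.9, n)
  out <- tibble::tibble(x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                        ca_prob = ca_prob,
                        aa_probs = aa_probs,
                        cluster_size = rep(1L, n))
  class(out) <- c("ca_atom_set", class(out))
  out
}

# random small HMM instance: K atoms in a 10 A box, random emission rows
random_hmm_instance <- function(K, seed) {
  set.seed(seed)
  xyz <- matrix(runif(3 * K, 0, 10), K, 3)
  aa <- matrix(runif(20 * K), K, 20)
  aa <- aa / rowSums(aa)
  build_hmm(make_atoms(xyz, aa))
}

# Independent reference implementation of the greedy-commit no-repeat
# recurrence, written in linear probability space with plain loops (valid for
# tiny instances where nothing underflows). Mirrors the documented
# semantics: committed states are frozen; the first path state is the
# backpointer of the second column's commit and is itself committed.
ref_greedy_viterbi <- function(gamma, delta, pi0, obs) {
  K <- nrow(gamma); Tn <- length(obs)
  T1 <- matrix(0, K, Tn)
  T2 <- matrix(0L, K, Tn)
  T1[, 1] <- pi0 * delta[, obs[1]]
  visited <- rep(FALSE, K)
  z <- integer(Tn)
  x1 <- NA_integer_
  if (Tn == 1L) {
    return(which.max(T1[, 1]))
  }
  for (j in 2:Tn) {
    for (i in 1:K) {
      if (visited[i]) { T1[i, j] <- -Inf; next }
      best <- -Inf; arg <- 0L
      for (k in 1:K) {
        s <- T1[k, j - 1] * gamma[k, i]
        if (s > best) { best <- s; arg <- k }
      }
      T1[i, j] <- best * delta[i, obs[j]]
      T2[i, j] <- arg
    }
    cand <- which(!visited)
    zj <- cand[which.max(T1[cand, j])]
    z[j] <- zj
    visited[zj] <- TRUE
    if (j == 2L) {
      x1 <- T2[zj, 2L]
      visited[x1] <- TRUE
    }
  }
  c(x1, z[2:Tn])
}

# exact optimum over all simple (non-repeating) state paths, by enumeration
best_simple_path_logprob <- function(log_gamma, log_delta, log_pi, obs) {
  K <- nrow(log_gamma); Tn <- length(obs)
  best <- -Inf
  recurse <- function(path, lp) {
    j <- length(path)
    if (j == Tn) {
      if (lp > best) best <<- lp
      return(invisible())
    }
    for (s in setdiff(seq_len(K), path)) {
      recurse(c(path, s),
              lp + log_gamma[path[j], s] + log_delta[s, obs[j + 1]])
    }
  }
  for (s in seq_len(K)) {
    recurse(s, log_pi[s] + log_delta[s, obs[1]])
  }
  best
}

# log-probability of a path under the model (same scoring as the decoder)
path_logprob <- function(log_gamma, log_delta, log_pi, obs, path) {
  lp <- log_pi[path[1]] + log_delta[path[1], obs[1]]
  for (j in seq_along(obs)[-1]) {
    lp <- lp + log_gamma[path[j - 1], path[j]] + log_delta[path[j], obs[j]]
  }
  lp
}

# brute-force maximum-cardinality matching under a distance cutoff
brute_max_matching <- function(dmat, cutoff) {
  n <- nrow(dmat); m <- ncol(dmat)
  best <- 0L
  recurse <- function(i, used, count) {
    if (count + (n - i + 1L) <= best) return(invisible())
    if (i > n) { best <<- max(best, count); return(invisible()) }
    recurse(i + 1L, used, count)               # leave model residue i unmatched
    for (j in seq_len(m)) {
      if (!used[j] && dmat[i, j] <= cutoff) {
        used[j] <- TRUE
        recurse(i + 1L, used, count + 1L)
        used[j] <- FALSE
      }
    }
  }
  recurse(1L, rep(FALSE, m), 0L)
  best
}

# a small structure model from a coordinate matrix
make_model <- function(xyz, aa = NULL, chain = "A") {
  xyz <- matrix(xyz, ncol = 3)
  n <- nrow(xyz)
  if (is.null(aa)) aa <- rep("A", n)
  structure_model(tibble::tibble(chain_id = chain, resno = seq_len(n),
                                 x = xyz[, 1], y = xyz[, 2], z = xyz[, 3],
                                 aa = aa))
}

# toy network specification small enough for fast tests
toy_spec <- function(C = 4L) {
  network_spec(C, embed_dim = 24L, num_blocks = 4L, tap_blocks = 1:4,
               num_heads = 3L, mlp_dim = 32L,
               decoder_widths = c(6L, 5L, 4L, 4L),
               decoder_feature_size = 4L, dropout = 0)
}
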