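test_that("pairwise distance is Euclidean and symmetric", {
  expect_equal(pairwise_distance(c(0, 0, 0), c(0, 0, 0)), 0)
  expect_equal(pairwise_distance(c(0, 0, 0), c(3, 4, 0)), 5)
  set.seed(1)
  for (i in 1:5) {
    p <- rnorm(3); q <- rnorm(3)
    expect_equal(pairwise_distance(p, q), pairwise_distance(q, p))
  }
})

test_that("the scaled Gaussian transition density behaves as a widened normal", {
  # peak value 1 / (lambda sigma sqrt(2 pi)) with lambda sigma = 0.36
  expect_equal(gaussian_transition_density(3.8047), 1 / (0.36 * sqrt(2 * pi)))
  expect_equal(gaussian_transition_density(3.8047), 1.1081, tolerance = 1e-4)
  d <- 0.7
  expect_equal(gaussian_transition_density(3.8047 + d),
               gaussian_transition_density(3.8047 - d))
  x <- seq(3.8047, 8, by = 0.1)
  expect_true(all(diff(gaussian_transition_density(x)) < 0))
  expect_error(gaussian_transition_density(1, sigma = 0), "positive")
})

test_that("transition rows are normalized with a zero diagonal", {
  # K = 2: the single off-diagonal entry normalizes to 1 regardless of distance
  tr2 <- build_transition(make_atoms(rbind(c(0, 0, 0), c(50, 0, 0))))
  expect_equal(tr2$gamma, matrix(c(0, 1, 1, 0), 2), ignore_attr = TRUE)

  # three collinear atoms one bond apart: from an end atom nearly all mass
  # goes to the middle; the far atom gets the Eq-4 density ratio
  tr3 <- build_transition(make_atoms(rbind(c(0, 0, 0), c(3.8047, 0, 0),
                                           c(7.6094, 0, 0))))
  f_near <- gaussian_transition_density(3.8047)
  f_far <- gaussian_transition_density(7.6094)
  expect_equal(tr3$gamma[1, 2], f_near / (f_near + f_far))
  expect_equal(tr3$gamma[1, 3], f_far / (f_near + f_far))
  expect_lt(tr3$gamma[1, 3], 1e-24)

  set.seed(8)
  for (i in 1:5) {
    tr <- build_transition(make_atoms(matrix(runif(3 * 6, 0, 15), 6, 3)))
    expect_equal(rowSums(tr$gamma), rep(1, 6))
    expect_equal(diag(tr$gamma), rep(0, 6))
  }
})

test_that("emissions are normalized geometric means with the background", {
  uni <- make_atoms(c(0, 0, 0), matrix(1 / 20, 1, 20))
  expect_equal(build_emission(uni, rep(1 / 20, 20))[1, ], rep(1 / 20, 20))

  onehot <- matrix(0, 1, 20); onehot[1, 1] <- 1
  d <- build_emission(make_atoms(c(0, 0, 0), onehot))
  expect_equal(d[1, 1], 1)

  # a == b: the geometric mean of identical vectors renormalizes to a itself
  b <- aa_background()
  d2 <- build_emission(make_atoms(c(0, 0, 0), matrix(b, 1)), b)
  expect_equal(d2[1, ], unname(b))
  # all-zero product row falls back to uniform with a warning
  z <- matrix(0, 1, 20); z[1, 1] <- 1
  bg0 <- c(0, rep(1 / 19, 19))
  expect_warning(d3 <- build_emission(make_atoms(c(0, 0, 0), z), bg0), "uniform")
  expect_equal(d3[1, ], rep(1 / 20, 20))
})

test_that("the initial distribution is the normalized first-symbol emission", {
  delta <- rbind(c(0.1, 0.9, rep(0, 18)) / 1,
                 c(0.3, 0.7, rep(0, 18)),
                 c(0.6, 0.4, rep(0, 18)))
  atoms <- make_atoms(matrix(rnorm(9), 3, 3), delta)
  pi0 <- build_initial(delta, "A")
  expect_equal(pi0, c(0.1, 0.3, 0.6))
  expect_equal(sum(build_initial(delta, "C")), 1)
  # identical rows give a uniform start
  same <- rbind(delta[1, ], delta[1, ])
  expect_equal(build_initial(same, "A"), c(0.5, 0.5))
})

test_that("single-observation decoding picks the best initial state", {
  one <- build_hmm(make_atoms(rbind(c(0, 0, 0), c(3.8, 0, 0))))
  res1 <- modified_viterbi(one, "A", available = 1L)
  expect_equal(res1$path, 1L)

  # asymmetric emissions: state 2 wins both the prior and the emission
  aa <- rbind(c(0.2, rep(0.8 / 19, 19)), c(0.8, rep(0.2 / 19, 19)))
  hm <- build_hmm(make_atoms(rbind(c(0, 0, 0), c(3.8, 0, 0)), aa))
  expect_equal(modified_viterbi(hm, "A")$path, 2L)
})

test_that("infeasible alignments fail with actionable errors", {
  hm <- random_hmm_instance(3, seed = 2)
  expect_error(modified_viterbi(hm, "ACDE"), "lower the C-alpha")
  chains <- chain_sequence_set(c("A", "B"), c("ACD", "EF"))
  expect_error(align_all_chains(hm, chains), "infeasible")
})

test_that("the decoder matches an independent reference and never beats the simple-path optimum", {
  n_checked <- 0
  for (seed in 1:200) {
    set.seed(seed)
    K <- sample(2:7, 1)
    Tn <- sample(1:min(4, K), 1)
    hm <- random_hmm_instance(K, seed = 1000 + seed)
    obs <- sample.int(20, Tn, replace = TRUE)
    res <- modified_viterbi(hm, obs)
    # (a) no repeated state
    expect_false(anyDuplicated(res$path) > 0)
    # (c) identical to the independently coded greedy-commit reference
    pi0 <- build_initial(hm$delta, obs[1])
    ref <- ref_greedy_viterbi(hm$gamma, hm$delta, pi0, obs)
    expect_equal(res$path, as.integer(ref))
    # (b) log-probability never exceeds the exhaustive simple-path optimum
    lg <- log(hm$gamma); ld <- log(hm$delta); lp <- log(pi0)
    opt <- best_simple_path_logprob(lg, ld, lp, obs)
    got <- path_logprob(lg, ld, lp, obs, res$path)
    expect_lte(got, opt + 1e-9)
    expect_equal(got, res$log_prob, tolerance = 1e-9)
    n_checked <- n_checked + 1
  }
  expect_equal(n_checked, 200)
})

test_that("chains are aligned longest-first without state reuse", {
  hm <- random_hmm_instance(8, seed = 77)
  chains <- chain_sequence_set(c("A", "B"), c("ACD", "EFGHI"))
  res <- align_all_chains(hm, chains)
  states <- unlist(lapply(res, `[[`, "path"))
  expect_equal(sort(states), 1:8)                    # 3 + 5 states, all distinct
  expect_equal(lengths(lapply(res, `[[`, "path")), c(3L, 5L))
  # determinism
  res2 <- align_all_chains(hm, chains)
  expect_identical(lapply(res, `[[`, "path"), lapply(res2, `[[`, "path"))
})

test_that("a synthetic backbone trace is recovered almost perfectly", {
  hits_pos <- numeric(20); hits_aa <- numeric(20)
  for (s in 1:20) {
    prot <- generate_protein(1, 30, seed = 300 + s)
    n <- nrow(prot)
    aa_true <- aa_index(prot$aa)
    aaprob <- matrix(0.1 / 20, n, 20)
    aaprob[cbind(1:n, aa_true)] <- aaprob[cbind(1:n, aa_true)] + 0.9
    atoms <- make_atoms(as.matrix(prot[, c("x", "y", "z")]), aaprob)
    hm <- build_hmm(atoms)
    res <- align_all_chains(hm, protein_sequences(prot))
    hits_pos[s] <- mean(res[[1]]$path == 1:n)
    hits_aa[s] <- mean(prot$aa[res[[1]]$path] == prot$aa)
  }
  expect_gte(mean(hits_pos), 0.95)
  expect_gte(mean(hits_aa), 0.95)
})

test_that("degenerate flat models still yield valid non-repeating paths", {
  # lambda sigma huge: transitions flat; uniform emissions
  atoms <- make_atoms(matrix(runif(3 * 6, 0, 20), 6, 3), matrix(1 / 20, 6, 20))
  hm <- build_hmm(atoms, lambda = 1e9)
  res <- modified_viterbi(hm, "AAAA")
  expect_length(res$path, 4L)
  expect_false(anyDuplicated(res$path) > 0)
})

test_that("aligned paths assemble into a per-chain residue table", {
  hm <- random_hmm_instance(5, seed = 9)
  chains <- chain_sequence_set("A", "KVR")
  res <- list(structure(list(chain_id = "A", path = c(3L, 1L, 2L),
                             emission_prob = c(0.2, 0.3, 0.4)),
                        class = "ca_alignment"))
  model <- paths_to_structure(res, hm$atoms, chains)
  expect_equal(nrow(model), 3L)
  expect_equal(model$aa, c("K", "V", "R"))
  expect_equal(model$x, hm$atoms$x[c(3, 1, 2)])
  expect_equal(model$atom_index, c(3L, 1L, 2L))
  f <- withr::local_tempfile(fileext = ".pdb")
  write_pdb(model, f)
  back <- read_reference_pdb(f)
  expect_equal(back$x, model$x, tolerance = 1e-3)
  expect_equal(back$aa, model$aa)
})

test_that("stochastic-matrix invariants survive state removal and renormalization", {
  for (i in 1:10) {
    hm <- random_hmm_instance(10, seed = 400 + i)
    expect_equal(rowSums(hm$gamma), rep(1, 10))
    expect_equal(rowSums(hm$delta), rep(1, 10))
    keep <- sort(sample(10, 6))
    sub <- build_transition(hm$atoms[keep, ])        # rebuild == renormalize
    expect_equal(rowSums(sub$gamma), rep(1, 6), tolerance = 1e-9)
    pi0 <- build_initial(hm$delta[keep, ], sample.int(20, 1))
    expect_equal(sum(pi0), 1, tolerance = 1e-9)
  }
})
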