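make_preds <- function(dims, ca = list(), aa_at = list()) {
  # ca: list of list(idx = c(i,j,k) 1-based, p = prob)
  atom <- array(0, c(dims, 4)); atom[, , , 4] <- 1
  aa <- array(0, c(dims, 21)); aa[, , , 21] <- 1
  for (s in ca) {
    v <- s$idx
    atom[v[1], v[2], v[3], ] <- c(s$p, 0, 0, 1 - s$p)
  }
  for (s in aa_at) {
    v <- s$idx
    aa[v[1], v[2], v[3], ] <- s$vec
  }
  prediction_grids(atom, aa)
}

test_that("C-alpha voxels are selected above a strict threshold", {
  g <- density_grid(array(0, c(8, 8, 8)))
  p <- make_preds(c(8, 8, 8), ca = list(list(idx = c(2, 3, 4), p = 0.9)))
  out <- select_ca_voxels(p, g, 0.4)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ca_prob, 0.9)
  expect_equal(c(out$x, out$y, out$z), c(1, 2, 3))   # 0-based voxel at 1 A size

  # exactly-at-threshold voxels are NOT selected ("higher than")
  p2 <- make_preds(c(8, 8, 8), ca = list(list(idx = c(2, 3, 4), p = 0.4)))
  expect_equal(nrow(select_ca_voxels(p2, g, 0.4)), 0L)
})

test_that("amino-acid vectors drop the unknown class and renormalize", {
  g <- density_grid(array(0, c(4, 4, 4)))
  vec <- c(0.5, rep(0, 19), 0.5)                     # half ALA, half none
  p <- make_preds(c(4, 4, 4),
                  ca = list(list(idx = c(2, 2, 2), p = 0.8)),
                  aa_at = list(list(idx = c(2, 2, 2), vec = vec)))
  out <- select_ca_voxels(p, g)
  expect_equal(out$aa_probs[1, 1], 1)
  expect_equal(sum(out$aa_probs[1, ]), 1)
})

test_that("clustering merges nearby voxels with medoid representatives", {
  # two voxels 1.5 A apart: one atom, averaged probability, medoid = higher prob
  cand <- tibble::tibble(voxel_index = rbind(c(0L, 0L, 0L), c(0L, 0L, 2L)),
                         x = c(0, 1.5), y = 0, z = 0,
                         ca_prob = c(0.6, 0.8),
                         aa_probs = matrix(1 / 20, 2, 20))
  out <- cluster_ca(cand, radius = 2)
  expect_equal(nrow(out), 1L)
  expect_equal(out$ca_prob, 0.7)
  expect_equal(out$x, 1.5)                           # the 0.8 voxel wins the tie
  expect_equal(out$cluster_size, 2L)

  # two voxels 3 A apart stay separate
  cand2 <- dplyr::mutate(cand, x = c(0, 3))
  expect_equal(nrow(cluster_ca(cand2, radius = 2)), 2L)

  # single-linkage chain 0 / 1.5 / 3.0 A: one cluster, middle voxel is the
  # medoid (brute force: summed distances are 4.5, 3.0, 4.5)
  cand3 <- tibble::tibble(voxel_index = matrix(0L, 3, 3),
                          x = c(0, 1.5, 3), y = 0, z = 0,
                          ca_prob = c(0.9, 0.5, 0.9),
                          aa_probs = matrix(1 / 20, 3, 20))
  out3 <- cluster_ca(cand3, radius = 2)
  expect_equal(nrow(out3), 1L)
  expect_equal(out3$x, 1.5)
})

test_that("clustering is order-invariant and conserves voxel counts", {
  set.seed(14)
  n <- 40
  cand <- tibble::tibble(voxel_index = matrix(0L, n, 3),
                         x = runif(n, 0, 20), y = runif(n, 0, 20),
                         z = runif(n, 0, 20),
                         ca_prob = runif(n, 0.4, 1),
                         aa_probs = matrix(runif(n * 20), n, 20))
  cand$aa_probs <- cand$aa_probs / rowSums(cand$aa_probs)
  out <- cluster_ca(cand, radius = 2)
  expect_equal(sum(out$cluster_size), n)
  for (i in 1:3) {
    perm <- sample(n)
    out2 <- cluster_ca(cand[perm, ], radius = 2)
    expect_equal(out2$x, out$x)
    expect_equal(out2$ca_prob, out$ca_prob)
    expect_equal(out2$aa_probs, out$aa_probs)
  }
  # with a vanishing radius clustering is the identity
  tiny <- cluster_ca(cand, radius = 1e-9)
  expect_equal(nrow(tiny), n)
  expect_equal(sort(tiny$x), sort(cand$x))
})

test_that("extraction recovers exactly one atom per true C-alpha", {
  prot <- generate_protein(1, 15, seed = 44)
  bundle <- rasterize(prot, padding = 5)
  preds <- simulate_predictions(bundle, correct_prob = 1, fp_rate = 0)
  atoms <- extract_ca_atoms(preds, bundle$grid)
  expect_equal(nrow(atoms), nrow(prot))
  truth <- as.matrix(prot[, c("x", "y", "z")])
  got <- as.matrix(atoms[, c("x", "y", "z")])
  # every true atom has a recovered atom within half a voxel diagonal
  for (r in seq_len(nrow(truth))) {
    d <- sqrt(min(colSums((t(got) - truth[r, ])^2)))
    expect_lt(d, sqrt(3) / 2 + 1e-9)
  }
})
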