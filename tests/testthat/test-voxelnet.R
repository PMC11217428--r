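test_that("class weights follow the one-minus-share rule", {
  expect_equal(class_weights(c(50, 50))$weight, c(0.5, 0.5))
  expect_equal(class_weights(c(90, 10))$weight, c(0.1, 0.9))
  expect_equal(class_weights(7)$weight, 0)
  expect_error(class_weights(c(0, 0)), "positive")
  # weights of C classes always sum to C - 1
  set.seed(1)
  for (i in 1:20) {
    cnt <- rpois(sample(2:21, 1), lambda = 50)
    cnt[1] <- cnt[1] + 1                      # ensure positive total
    cw <- class_weights(cnt)
    expect_equal(sum(cw$weight), length(cnt) - 1)
  }
})

test_that("weighted cross-entropy matches closed forms and the unweighted mean", {
  expect_equal(weighted_ce_loss(matrix(0, 1, 4), 1L, rep(1, 4)), log(4))
  expect_equal(weighted_ce_loss(matrix(0, 1, 2), 2L, c(0.3, 0.7)), 0.7 * log(2))
  expect_equal(weighted_ce_loss(matrix(rnorm(10), 5, 2), rep(1:2, c(2, 3)),
                                c(0, 0)), 0)
  expect_error(weighted_ce_loss(matrix(0, 1, 4), 5L, rep(1, 4)), "labels")
  # uniform unit weights reduce to the plain mean cross-entropy
  set.seed(2)
  for (i in 1:10) {
    n <- sample(1:30, 1); C <- sample(2:6, 1)
    lg <- matrix(rnorm(n * C), n, C)
    lab <- sample.int(C, n, replace = TRUE)
    plain <- mean(vapply(seq_len(n), function(r) {
      -log(exp(lg[r, lab[r]]) / sum(exp(lg[r, ])))
    }, numeric(1)))
    expect_equal(weighted_ce_loss(lg, lab, rep(1, C)), plain, tolerance = 1e-12)
  }
})

test_that("only the prediction head depends on the class count", {
  n4 <- build_network(toy_spec(4L), seed = 1)
  n21 <- build_network(toy_spec(21L), seed = 1)
  fs <- toy_spec(4L)$decoder_feature_size
  expect_equal(count_parameters(n21) - count_parameters(n4), 17 * (fs + 1))
  # count is invariant to the initialization seed
  expect_equal(count_parameters(build_network(toy_spec(4L), seed = 99)),
               count_parameters(n4))
  # a 1x1x1 convolution from 16 to 4 channels in isolation
  expect_equal(length(array(0, c(16, 4))) + 4, 68)
})

test_that("the forward pass produces finite voxel-wise logits", {
  net <- build_network(toy_spec(4L), seed = 7)
  out <- voxtrace:::vnet_forward(net, array(0, c(32, 32, 32)))
  expect_equal(dim(out$logits), c(32, 32, 32, 4))
  expect_true(all(is.finite(out$logits)))
})

test_that("analytic gradients agree with finite differences", {
  net <- build_network(toy_spec(3L), seed = 42)
  set.seed(7)
  x <- array(runif(32^3), c(32, 32, 32))
  lab <- sample.int(3, 32^3, replace = TRUE)
  w <- c(0.5, 0.8, 0.7)
  lossfun <- function(n) {
    lg <- voxtrace:::vnet_forward(n, x)$logits
    weighted_ce_loss(matrix(lg, length(lab), 3), lab, w)
  }
  fw <- voxtrace:::vnet_forward(net, x)
  dl <- voxtrace:::weighted_ce_grad(matrix(fw$logits, length(lab), 3), lab, w)
  G <- voxtrace:::vnet_backward(net, fw$cache, array(dl, dim(fw$logits)))
  eps <- 1e-5
  probes <- list(list(\(p, e) { p$head_W[2] <- p$head_W[2] + e; p },
                      \(g) g$head_W[2]),
                 list(\(p, e) { p$convD_W[10] <- p$convD_W[10] + e; p },
                      \(g) g$convD_W[10]),
                 list(\(p, e) { p$pos[5] <- p$pos[5] + e; p },
                      \(g) g$pos[5]),
                 list(\(p, e) { p$blocks[[2]]$W1[7] <- p$blocks[[2]]$W1[7] + e; p },
                      \(g) g$blocks[[2]]$W1[7]),
                 list(\(p, e) { p$inB_g[1] <- p$inB_g[1] + e; p },
                      \(g) g$inB_g[1]))
  for (pr in probes) {
    n2 <- net
    n2$params <- pr[[1]](net$params, eps);  f1 <- lossfun(n2)
    n2$params <- pr[[1]](net$params, -eps); f0 <- lossfun(n2)
    num <- (f1 - f0) / (2 * eps)
    ana <- pr[[2]](G)
    expect_equal(ana, num, tolerance = 5e-2)
  }
})

test_that("toy training overfits a small synthetic set deterministically", {
  prot <- generate_protein(1, 12, seed = 21)
  samples <- head(training_samples(rasterize(prot, padding = 4), "atom"), 2)
  net <- build_network(toy_spec(4L), seed = 5)
  tr <- train_toy(net, samples, epochs = 6, lr = 2e-3, seed = 9)
  expect_lt(tr$history$loss[nrow(tr$history)], tr$history$loss[1])
  tr2 <- train_toy(net, samples, epochs = 6, lr = 2e-3, seed = 9)
  expect_identical(tr$history, tr2$history)
  expect_s3_class(tidy(tr), "tbl_df")
  expect_equal(glance(tr)$epochs, 6)
})

test_that("the learning rate drops by 10x after five epochs without improvement", {
  prot <- generate_protein(1, 8, seed = 22)
  samples <- training_samples(rasterize(prot, padding = 4), "atom")[1]
  net <- build_network(toy_spec(4L), seed = 5)
  lr0 <- 1e-13                                # effectively frozen: no improvement
  tr <- train_toy(net, samples, epochs = 7, lr = lr0, seed = 9)
  expect_equal(tr$history$lr[1:5], rep(lr0, 5))
  expect_equal(tr$history$lr[6], 0.1 * lr0)
})

test_that("prediction grids are voxel-wise probability simplices", {
  prot <- generate_protein(1, 10, seed = 31)
  bundle <- rasterize(prot, padding = 4)
  onehot <- simulate_predictions(bundle, correct_prob = 1, fp_rate = 0)
  # identity surrogate: one-hot labels pass through predict_grids unchanged
  out <- predict_grids(onehot, bundle$grid)
  expect_identical(out$atom_probs, onehot$atom_probs)
  am <- matrix(out$atom_probs, ncol = 4)
  expect_true(all(abs(rowSums(am) - 1) < 1e-6))
  expect_error(prediction_grids(out$atom_probs[1:5, , , , drop = FALSE],
                                out$aa_probs), "mismatch")
})

test_that("network inference stitches tiled outputs to the map shape", {
  net4 <- build_network(toy_spec(4L), seed = 1)
  net21 <- build_network(toy_spec(21L), seed = 2)
  grid <- density_grid(array(runif(33 * 40 * 32), c(33, 40, 32)))
  pg <- predict_grids(list(atom = net4, aa = net21), grid)
  expect_equal(dim(pg$atom_probs), c(33, 40, 32, 4))
  expect_equal(dim(pg$aa_probs), c(33, 40, 32, 21))
  am <- matrix(pg$atom_probs, ncol = 4)
  expect_true(max(abs(rowSums(am) - 1)) < 1e-6)
})

test_that("checkpoints round-trip network weights", {
  net <- build_network(toy_spec(4L), seed = 3)
  f <- withr::local_tempfile(fileext = ".rds")
  save_network(net, f)
  net2 <- load_network(f)
  expect_identical(net2$params, net$params)
  expect_error(suppressWarnings(load_network(withr::local_tempfile(fileext = ".rds"))))
})
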