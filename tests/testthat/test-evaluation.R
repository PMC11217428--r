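test_that("matching is one-to-one within the cutoff", {
  xyz <- cbind(seq(0, 90, by = 10), 0, 0)        # residues 10 A apart
  m <- make_model(xyz)
  # identical structures: everything matches at distance zero
  full <- match_ca(m, m)
  expect_equal(full$n_matched, 10L)
  expect_equal(full$pairs$distance, rep(0, 10))
  # a rigid 5 A translation kills every match at the 3 A cutoff
  shifted <- make_model(sweep(xyz, 2, c(5, 0, 0), "+"))
  expect_equal(match_ca(shifted, m)$n_matched, 0L)
  # two model residues near one reference residue: exactly one pair
  ref1 <- make_model(c(0, 0, 0))
  two <- make_model(rbind(c(1, 0, 0), c(0, 1, 0)))
  mt <- match_ca(two, ref1)
  expect_equal(mt$n_matched, 1L)
  expect_equal(mt$pairs$model_idx, 1L)       # equal distances: lowest model index
  expect_error(match_ca(m, make_model(matrix(numeric(), 0, 3))), "residues")
})

test_that("metrics reproduce the fragmented-model worked example", {
  # 392-residue model, 42.3% Ca match, 2934-residue reference -> quality 0.06
  n_model <- 392L; n_reference <- 2934L
  n_matched <- round(0.423 * n_model)
  mt <- structure(list(pairs = NULL, n_model = n_model,
                       n_reference = n_reference, n_matched = n_matched,
                       n_type_matched = round(0.116 * n_matched), cutoff = 3),
                  class = "ca_match_result")
  met <- compute_metrics(mt)
  expect_equal(round(met$ca_quality_score, 2), 0.06)
  expect_equal(met$ca_match_score, 100 * n_matched / n_model)
  expect_equal(sprintf("%.2f", met$ca_quality_score), "0.06")
})

test_that("metric identities hold exactly", {
  mt <- structure(list(pairs = NULL, n_model = 50L, n_reference = 100L,
                       n_matched = 40L, n_type_matched = 30L, cutoff = 3),
                  class = "ca_match_result")
  met <- compute_metrics(mt)
  expect_equal(met$recall * met$n_reference, met$n_matched)
  expect_equal(met$precision * met$n_model, met$n_matched)
  expect_equal(met$sequence_match_score, 75)
  # harmonic mean: precision 0.8, recall 0.4 -> 8/15
  mt2 <- structure(list(pairs = NULL, n_model = 50L, n_reference = 100L,
                        n_matched = 40L, n_type_matched = 0L, cutoff = 3),
                   class = "ca_match_result")
  expect_equal(compute_metrics(mt2)$f1, 2 * 0.8 * 0.4 / (0.8 + 0.4))
  # a perfect model scores 1 everywhere
  m <- make_model(matrix(runif(15, 0, 30), 5, 3), aa = c("A", "C", "D", "E", "F"))
  met3 <- evaluate_model(m, m)
  expect_equal(met3$recall, 1)
  expect_equal(met3$f1, 1)
  expect_equal(met3$ca_quality_score, 1)
  expect_equal(met3$sequence_match_score, 100)
})

test_that("metrics are invariant under rigid motion of both structures", {
  set.seed(12)
  mdl <- matrix(runif(24, 0, 30), 8, 3)
  ref <- mdl + matrix(rnorm(24, sd = 1), 8, 3)
  base <- evaluate_model(make_model(mdl), make_model(ref))
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1))
  shift <- c(12, -5, 3)
  rot <- evaluate_model(make_model(sweep(mdl %*% R, 2, shift, "+")),
                        make_model(sweep(ref %*% R, 2, shift, "+")))
  expect_equal(rot$n_matched, base$n_matched)
  expect_equal(rot$recall, base$recall, tolerance = 1e-12)
})

test_that("greedy matching attains the optimal cardinality on backbone-like instances", {
  # instances mimic real evaluations: a reference backbone (atoms >= 3 A
  # apart) and a model that perturbs, drops and adds residues
  for (seed in 1:40) {
    set.seed(500 + seed)
    ref <- as.matrix(generate_protein(1, 8, seed = 520 + seed)[, c("x", "y", "z")])
    keep <- sort(sample(8, sample(4:8, 1)))
    mdl <- ref[keep, , drop = FALSE] + matrix(rnorm(3 * length(keep), sd = 1),
                                              ncol = 3)
    extra <- matrix(runif(3 * sample(0:2, 1), 0, 30), ncol = 3)
    mdl <- rbind(mdl, sweep(extra, 2, ref[1, ], "+"))
    mt <- match_ca(make_model(mdl), make_model(ref))
    dmat <- unname(as.matrix(dist(rbind(mdl, ref))))[seq_len(nrow(mdl)),
                                                     nrow(mdl) + seq_len(nrow(ref)),
                                                     drop = FALSE]
    expect_equal(mt$n_matched, brute_max_matching(dmat, 3))
  }
})

test_that("quality scores above one are clamped with a warning", {
  # with a consistent one-to-one matching, quality = n_matched / n_reference
  # <= 1 always; clamping guards hand-built inconsistent records (e.g. match
  # counts imported from an external comparison tool)
  mt <- structure(list(pairs = NULL, n_model = 200L, n_reference = 100L,
                       n_matched = 150L, n_type_matched = 0L, cutoff = 3),
                  class = "ca_match_result")
  expect_warning(met <- compute_metrics(mt), "clamp")
  expect_equal(met$ca_quality_score, 1)
})

test_that("reports render as JSON and fixed-precision text", {
  m <- make_model(matrix(runif(15, 0, 30), 5, 3))
  met <- evaluate_model(m, m)
  js <- report_metrics(met, "json")
  parsed <- jsonlite::fromJSON(js)
  expect_equal(parsed$recall, 1)
  expect_true(all(c("recall", "precision", "f1", "ca_match_score",
                    "sequence_match_score", "ca_quality_score") %in% names(parsed)))
  txt <- report_metrics(met, "text")
  expect_match(txt, "Ca quality score     1.00")
  f <- withr::local_tempfile(fileext = ".json")
  report_metrics(met, "json", f)
  expect_equal(jsonlite::read_json(f)$n_model, 5)
})
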