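#' Logistic confidence model
#'
#' A plain logistic regression `P(y = 1 | x) = 1 / (1 + exp(-(b0 + b . x)))`
#' used to convert pipeline quantities into per-residue confidence scores.
#'
#' @param coefficients Numeric vector: intercept followed by one weight per
#'   feature.
#' @param feature_schema Character vector of feature names (ordered).
#' @return A `logistic_model` object.
#' @export
logistic_model <- function(coefficients, feature_schema) {
  if (length(coefficients) != length(feature_schema) + 1L) {
    abort("need one coefficient per feature plus an intercept.")
  }
  structure(list(coefficients = as.numeric(coefficients),
                 feature_schema = as.character(feature_schema)),
            class = "logistic_model")
}

#' @export
print.logistic_model <- function(x, ...) {
  cat(sprintf("<logistic_model> %d feature(s): %s\n",
              length(x$feature_schema),
              paste(utils::head(x$feature_schema, 5), collapse = ", ")))
  invisible(x)
}

#' Score feature vectors with a logistic model
#'
#' @param model A [logistic_model()].
#' @param features Numeric matrix (rows = observations) or data frame whose
#'   columns match the model's feature schema.
#' @return Probability vector in (0, 1).
#' @export
logistic_score <- function(model, features) {
  X <- as.matrix(features)
  if (ncol(X) != length(model$feature_schema)) {
    abort(sprintf("feature schema mismatch: model expects %d feature(s) (%s), got %d.",
                  length(model$feature_schema),
                  paste(model$feature_schema, collapse = ", "), ncol(X)))
  }
  eta <- model$coefficients[1] + X %*% model$coefficients[-1]
  as.numeric(plogis(eta))
}

#' Per-residue features for the C-alpha confidence classifier
#'
#' The single feature is the clustered C-alpha probability predicted by the
#' voxel classifier for the atom each residue was placed on.
#'
#' @param model A [structure_model()] carrying a `ca_prob` column (as built
#'   by [paths_to_structure()]).
#' @return One-column matrix `ca_prob`, one row per residue.
#' @export
make_ca_features <- function(model) {
  if (!"ca_prob" %in% names(model)) abort("model lacks a `ca_prob` column.")
  matrix(model$ca_prob, ncol = 1L, dimnames = list(NULL, "ca_prob"))
}

#' Per-residue features for the amino-acid confidence classifier
#'
#' 22 features per residue: the HMM emission probability used at the aligned
#' position, the atom's C-alpha probability, and a 20-dimensional one-hot
#' encoding of the assigned amino-acid type.
#'
#' @param model A [structure_model()] carrying `ca_prob`, `emission_prob`
#'   and `aa` columns.
#' @return n x 22 feature matrix.
#' @export
make_aa_features <- function(model) {
  need <- c("ca_prob", "emission_prob", "aa")
  if (!all(need %in% names(model))) {
    abort("model lacks the emission/probability columns from paths_to_structure().")
  }
  onehot <- matrix(0, nrow(model), 20L, dimnames = list(NULL, AA_ALPHABET))
  onehot[cbind(seq_len(nrow(model)), aa_index(model$aa))] <- 1
  cbind(emission_prob = model$emission_prob,
        ca_prob = model$ca_prob,
        onehot)
}

#' Binary training labels from a reference structure
#'
#' A residue receives `ca_label = 1` when the 3-Angstrom one-to-one matching
#' ([match_ca()]) pairs it with a reference residue, else 0. `aa_label = 1`
#' only when the residue is matched AND its amino-acid type equals its
#' partner's; unmatched residues get `aa_label = 0`.
#'
#' @param model,reference [structure_model()] objects.
#' @param cutoff Match cutoff in Angstrom (default 3).
#' @return A tibble with columns `ca_label`, `aa_label` (one row per model
#'   residue).
#' @export
make_labels <- function(model, reference, cutoff = 3) {
  mt <- match_ca(model, reference, cutoff)
  ca <- integer(nrow(model))
  aa <- integer(nrow(model))
  ca[mt$pairs$model_idx] <- 1L
  aa[mt$pairs$model_idx[mt$pairs$type_match]] <- 1L
  tibble(ca_label = ca, aa_label = aa)
}

#' Fit a logistic confidence classifier
#'
#' Maximum-likelihood logistic regression via [stats::glm()]. When the fit
#' does not converge or diverges (separable data), the model is refit with a
#' small L2 ridge penalty (`ridge`, default 1e-6) using iteratively
#' reweighted least squares, which always yields a finite deterministic fit.
#'
#' @param features Numeric matrix or data frame of predictors.
#' @param labels Binary vector (0/1), both classes present.
#' @param ridge L2 penalty used only for the stabilized refit.
#' @return A [logistic_model()].
#' @export
fit_confidence <- function(features, labels, ridge = 1e-6) {
  X <- as.matrix(features)
  y <- as.integer(labels)
  if (length(unique(y)) < 2L) {
    abort("degenerate fit: both classes must be present in `labels`.")
  }
  schema <- colnames(X) %||% paste0("x", seq_len(ncol(X)))
  fit <- suppressWarnings(glm.fit(cbind(1, X), y, family = binomial()))
  co <- fit$coefficients
  diverged <- !fit$converged || anyNA(co) || any(abs(co) > 15)
  if (diverged) {
    co <- ridge_logistic(cbind(1, X), y, ridge)
  }
  logistic_model(unname(co), schema)
}

# ridge-penalized logistic regression by IRLS (penalty excluded from the
# intercept); used only when the unpenalized MLE is degenerate
ridge_logistic <- function(X, y, lambda, maxit = 100, tol = 1e-10) {
  p <- ncol(X)
  beta <- numeric(p)
  pen <- diag(c(0, rep(lambda, p - 1L)), p)
  for (it in seq_len(maxit)) {
    eta <- as.numeric(X %*% beta)
    mu <- plogis(eta)
    W <- mu * (1 - mu)
    W <- pmax(W, 1e-10)
    grad <- crossprod(X, y - mu) - pen %*% beta
    H <- crossprod(X * W, X) + pen
    step <- solve(H, grad)
    beta <- beta + as.numeric(step)
    if (max(abs(step)) < tol) break
  }
  beta
}

#' Apply confidence models to a structure
#'
#' Fills the `ca_conf` and `aa_conf` columns with the scores of the two
#' logistic classifiers; structure-level confidences are their means.
#'
#' @param model A [structure_model()] from [paths_to_structure()].
#' @param ca_model,aa_model [logistic_model()] objects (either may be NULL to
#'   leave that column untouched).
#' @return The annotated [structure_model()]; overall means are attached as
#'   attributes `overall_ca_confidence` / `overall_aa_confidence`.
#' @export
apply_confidence <- function(model, ca_model = NULL, aa_model = NULL) {
  if (!is.null(ca_model)) {
    model$ca_conf <- logistic_score(ca_model, make_ca_features(model))
  }
  if (!is.null(aa_model)) {
    model$aa_conf <- logistic_score(aa_model, make_aa_features(model))
  }
  attr(model, "overall_ca_confidence") <- mean(model$ca_conf)
  attr(model, "overall_aa_confidence") <- mean(model$aa_conf)
  model
}

#' Serialize / restore a logistic model as JSON
#'
#' @param model A [logistic_model()].
#' @param path File path.
#' @return `write_logistic_json()` returns `path` invisibly;
#'   `read_logistic_json()` a [logistic_model()].
#' @export
write_logistic_json <- function(model, path) {
  jsonlite::write_json(list(feature_schema = model$feature_schema,
                            coefficients = model$coefficients),
                       path, auto_unbox = FALSE, digits = NA)
  invisible(path)
}

#' @rdname write_logistic_json
#' @export
read_logistic_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  logistic_model(x$coefficients, x$feature_schema)
}

# ---- broom-style accessors --------------------------------------------------

#' Tidy a logistic confidence model
#'
#' @param x A [logistic_model()].
#' @param ... Unused.
#' @return A tibble with one row per term (`term`, `estimate`).
#' @export
tidy.logistic_model <- function(x, ...) {
  tibble(term = c("(Intercept)", x$feature_schema),
         estimate = x$coefficients)
}

#' Glance at a logistic confidence model
#'
#' @param x A [logistic_model()].
#' @param ... Unused.
#' @return A one-row tibble (`n_features`).
#' @export
glance.logistic_model <- function(x, ...) {
  tibble(n_features = length(x$feature_schema))
}

#' Tidy / glance a toy training run
#'
#' @param x A `vox_training` from [train_toy()].
#' @param ... Unused.
#' @return `tidy()`: the per-epoch history tibble. `glance()`: one row with
#'   the final loss, best validation F1 and epoch count.
#' @export
tidy.vox_training <- function(x, ...) x$history

#' @rdname tidy.vox_training
#' @export
glance.vox_training <- function(x, ...) {
  tibble(epochs = nrow(x$history),
         final_loss = x$history$loss[nrow(x$history)],
         best_val_f1 = max(x$history$val_f1),
         final_lr = x$history$lr[nrow(x$history)])
}
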