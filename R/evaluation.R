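#' Match model residues to reference residues within a distance cutoff
#'
#' Greedy globally-nearest one-to-one matching: the closest unmatched
#' (model, reference) residue pair with distance at most `cutoff` is paired
#' repeatedly until no pair remains. Ties are broken deterministically by
#' model index, then reference index. Matching uses positions only (not
#' residue numbering or chain direction).
#'
#' @param model,reference [structure_model()] objects.
#' @param cutoff Match cutoff in Angstrom (default 3).
#' @return A `ca_match_result` list: `pairs` (tibble: `model_idx`,
#'   `reference_idx`, `distance`, `type_match`), `n_model`, `n_reference`,
#'   `n_matched`, `n_type_matched`, `cutoff`.
#' @export
match_ca <- function(model, reference, cutoff = 3) {
  if (nrow(model) == 0L) abort("`model` has no residues.")
  if (nrow(reference) == 0L) abort("`reference` has no residues.")
  mx <- as.matrix(model[, c("x", "y", "z")])
  rx <- as.matrix(reference[, c("x", "y", "z")])
  # all candidate pairs within the cutoff, sorted by (distance, model, ref)
  d2cut <- cutoff^2
  cand <- vector("list", nrow(mx))
  for (i in seq_len(nrow(mx))) {
    d2 <- colSums((t(rx) - mx[i, ])^2)
    j <- which(d2 <= d2cut)
    if (length(j) > 0L) {
      cand[[i]] <- cbind(i, j, sqrt(d2[j]))
    }
  }
  cand <- do.call(rbind, cand)
  pairs <- NULL
  if (!is.null(cand) && nrow(cand) > 0L) {
    ord <- order(cand[, 3], cand[, 1], cand[, 2])
    cand <- cand[ord, , drop = FALSE]
    used_m <- logical(nrow(mx)); used_r <- logical(nrow(rx))
    keep <- logical(nrow(cand))
    for (r in seq_len(nrow(cand))) {
      i <- cand[r, 1]; j <- cand[r, 2]
      if (!used_m[i] && !used_r[j]) {
        keep[r] <- TRUE
        used_m[i] <- TRUE; used_r[j] <- TRUE
      }
    }
    sel <- cand[keep, , drop = FALSE]
    pairs <- tibble(model_idx = as.integer(sel[, 1]),
                    reference_idx = as.integer(sel[, 2]),
                    distance = sel[, 3],
                    type_match = model$aa[sel[, 1]] == reference$aa[sel[, 2]])
  } else {
    pairs <- tibble(model_idx = integer(), reference_idx = integer(),
                    distance = numeric(), type_match = logical())
  }
  structure(list(pairs = pairs,
                 n_model = nrow(model),
                 n_reference = nrow(reference),
                 n_matched = nrow(pairs),
                 n_type_matched = sum(pairs$type_match),
                 cutoff = cutoff),
            class = "ca_match_result")
}

#' @export
print.ca_match_result <- function(x, ...) {
  cat(sprintf("<ca_match_result> %d/%d model residues matched to %d reference residues (cutoff %g A)\n",
              x$n_matched, x$n_model, x$n_reference, x$cutoff))
  invisible(x)
}

#' Model-quality metrics from a match result
#'
#' * recall: matched residues / reference residues.
#' * precision (= C-alpha match score / 100): matched residues / model residues.
#' * F1: harmonic mean of precision and recall (0 if either is 0).
#' * sequence match score: percentage of matched residues whose amino-acid
#'   type equals the reference's (0 when nothing matches).
#' * C-alpha quality score: (C-alpha match score / 100) x
#'   (model residues / reference residues), clamped to `[0, 1]` — a
#'   precision-times-coverage summary in `[0, 1]`.
#'
#' @param match A [match_ca()] result.
#' @return A one-row `metric_report` tibble: `recall`, `precision`, `f1`,
#'   `ca_match_score` (percent), `sequence_match_score` (percent),
#'   `ca_quality_score`, plus the counts.
#' @export
#' @examples
#' # the fragmented-model worked example: 42.3% match, 392 of 2934 residues
#' m <- list(n_matched = round(0.423 * 392), n_type_matched = 0,
#'           n_model = 392, n_reference = 2934,
#'           pairs = data.frame(), cutoff = 3)
#' class(m) <- "ca_match_result"
#' compute_metrics(m)$ca_quality_score  # ~0.06
compute_metrics <- function(match) {
  recall <- match$n_matched / match$n_reference
  precision <- match$n_matched / match$n_model
  f1 <- if (precision + recall > 0) 2 * precision * recall / (precision + recall) else 0
  seq_match <- if (match$n_matched > 0) match$n_type_matched / match$n_matched else 0
  quality <- precision * match$n_model / match$n_reference
  if (quality > 1) {
    warn("C-alpha quality score exceeded 1; clamping.")
    quality <- 1
  }
  out <- tibble(recall = recall,
                precision = precision,
                f1 = f1,
                ca_match_score = 100 * precision,
                sequence_match_score = 100 * seq_match,
                ca_quality_score = quality,
                n_matched = match$n_matched,
                n_type_matched = match$n_type_matched,
                n_model = match$n_model,
                n_reference = match$n_reference)
  class(out) <- c("metric_report", class(out))
  out
}

#' Evaluate a model against a reference structure
#'
#' Convenience wrapper: [match_ca()] then [compute_metrics()].
#'
#' @inheritParams match_ca
#' @return A `metric_report` tibble.
#' @export
evaluate_model <- function(model, reference, cutoff = 3) {
  compute_metrics(match_ca(model, reference, cutoff))
}

#' Render a metric report
#'
#' @param metrics A `metric_report`.
#' @param format `"json"` (machine-readable) or `"text"` (human-readable
#'   table; percentages to 1 decimal place, scores to 2).
#' @param path Optional output file; when NULL the report is returned as a
#'   character string.
#' @return The report text, invisibly when written to `path`.
#' @export
report_metrics <- function(metrics, format = c("json", "text"), path = NULL) {
  format <- match.arg(format)
  txt <- if (format == "json") {
    jsonlite::toJSON(as.list(metrics[1, ]), auto_unbox = TRUE, digits = NA)
  } else {
    paste(
      sprintf("recall               %.3f", metrics$recall),
      sprintf("precision            %.3f", metrics$precision),
      sprintf("F1                   %.3f", metrics$f1),
      sprintf("Ca match score       %.1f%%", metrics$ca_match_score),
      sprintf("sequence match score %.1f%%", metrics$sequence_match_score),
      sprintf("Ca quality score     %.2f", metrics$ca_quality_score),
      sprintf("matched / model / reference   %d / %d / %d",
              metrics$n_matched, metrics$n_model, metrics$n_reference),
      sep = "\n")
  }
  if (!is.null(path)) {
    writeLines(txt, path)
    return(invisible(txt))
  }
  txt
}
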