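#' Plot a metric report
#'
#' Bar chart of the reference-based quality metrics, all on a 0-1 scale.
#'
#' @param object A `metric_report` from [compute_metrics()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.metric_report <- function(object, ...) {
  df <- tibble(metric = factor(c("recall", "precision", "F1",
                                 "sequence match", "quality"),
                               levels = c("recall", "precision", "F1",
                                          "sequence match", "quality")),
               value = c(object$recall, object$precision, object$f1,
                         object$sequence_match_score / 100,
                         object$ca_quality_score))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$metric, y = .data$value)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = NULL, y = "score",
                  title = "Model quality vs reference") +
    ggplot2::theme_minimal()
}

#' Plot a toy training history
#'
#' Training and validation loss per epoch, with the validation macro F1 on a
#' secondary panel.
#'
#' @param object A `vox_training` from [train_toy()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.vox_training <- function(object, ...) {
  h <- tidyr::pivot_longer(object$history, c("loss", "val_loss"),
                           names_to = "series", values_to = "value")
  ggplot2::ggplot(h, ggplot2::aes(x = .data$epoch, y = .data$value,
                                  colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::labs(y = "weighted cross-entropy", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an extracted C-alpha atom set
#'
#' 2D projection (x-y) of the clustered atoms, sized by cluster size and
#' colored by C-alpha probability.
#'
#' @param object A `ca_atom_set`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ca_atom_set <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y,
                               size = .data$cluster_size,
                               colour = .data$ca_prob)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)", colour = "P(CA)",
                  size = "voxels") +
    ggplot2::theme_minimal()
}

#' Plot a backbone model
#'
#' 2D projection of the traced backbone, one path per chain, colored by
#' per-residue amino-acid confidence.
#'
#' @param object A [structure_model()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.structure_model <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x, y = .data$y, group = .data$chain_id,
                               colour = .data$aa_conf)) +
    ggplot2::geom_path(linewidth = 0.4) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (A)", y = "y (A)", colour = "AA confidence") +
    ggplot2::theme_minimal()
}
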