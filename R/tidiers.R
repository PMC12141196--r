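#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

count_params <- function(x) length(unlist(x, use.names = FALSE))

#' Tidy a fitted fusion model into one row per component
#'
#' @param x A `fuseomics_model`.
#' @param ... Unused.
#' @return Tibble with `component`, `type` and `n_parameters`.
#' @method tidy fuseomics_model
#' @export
tidy.fuseomics_model <- function(x, ...) {
  rows <- list()
  for (nm in names(x$encoders)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = nm, type = "encoder",
      n_parameters = count_params(x$encoders[[nm]]$params))
  }
  for (enm in names(x$edges)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = enm, type = "cross_attention",
      n_parameters = count_params(x$edges[[enm]]$params))
  }
  for (b in names(x$branches)) {
    rows[[length(rows) + 1L]] <- tibble::tibble(
      component = b, type = "fusion_branch",
      n_parameters = count_params(x$branches[[b]]$attn))
  }
  rows[[length(rows) + 1L]] <- tibble::tibble(
    component = "predictor", type = "predictor",
    n_parameters = count_params(x$predictor))
  dplyr::bind_rows(rows)
}

#' One-row summary of a fitted fusion model
#'
#' @param x A `fuseomics_model`.
#' @param ... Unused.
#' @return One-row tibble: modalities, edges, branches, classes, parameter
#'   counts (total / frozen encoder / trainable multimodal).
#' @method glance fuseomics_model
#' @export
glance.fuseomics_model <- function(x, ...) {
  enc_n <- count_params(lapply(x$encoders, `[[`, "params"))
  mm_n <- count_params(mm_params(x))
  tibble::tibble(
    n_modalities = length(x$encoders),
    n_edges = length(x$edges),
    n_branches = length(x$branch_order),
    n_classes = length(x$class_names),
    n_parameters = enc_n + mm_n,
    n_encoder_parameters = enc_n,
    n_multimodal_parameters = mm_n
  )
}

#' Tidy a relevance report into a long tibble
#'
#' @param x A `relevance_report`.
#' @param level `"class"` (default), `"sample"` or `"cohort"`.
#' @param ... Unused.
#' @return Long tibble of relevance scores at the requested level.
#' @method tidy relevance_report
#' @export
tidy.relevance_report <- function(x, level = c("class", "sample", "cohort"),
                                  ...) {
  level <- match.arg(level)
  switch(level, class = x$class_means, sample = x$samples, cohort = x$cohort)
}

#' Heatmap of per-class interaction importance
#'
#' @param object A `relevance_report`.
#' @param ... Unused.
#' @return A ggplot: classes x edges tile plot of mean LRP relevance.
#' @method autoplot relevance_report
#' @export
autoplot.relevance_report <- function(object, ...) {
  ggplot2::ggplot(object$class_means,
                  ggplot2::aes(x = .data$edge, y = .data$class,
                               fill = .data$mean_relevance)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b", midpoint = 0) +
    ggplot2::labs(x = "interaction edge", y = "class",
                  fill = "mean LRP\nrelevance",
                  title = "Interaction importance by class") +
    ggplot2::theme_minimal()
}

#' Accuracy under missingness patterns, by number of missing modalities
#'
#' @param object A [missingness_grid()] tibble.
#' @param ... Unused.
#' @return A ggplot: accuracy distribution per count of missing modalities.
#' @method autoplot missingness_grid
#' @export
autoplot.missingness_grid <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = factor(.data$n_missing),
                                       y = .data$accuracy)) +
    ggplot2::geom_boxplot(outlier.shape = NA) +
    ggplot2::geom_jitter(width = 0.1, height = 0, alpha = 0.6) +
    ggplot2::labs(x = "missing modalities", y = "accuracy",
                  title = "Robustness to missing modalities") +
    ggplot2::theme_minimal()
}

#' Training curves
#'
#' @param history A history tibble from [train_phase1()] or [train_phase2()].
#' @return A ggplot of train/validation loss per epoch, faceted by modality.
#' @export
plot_training_history <- function(history) {
  long <- tidyr::pivot_longer(history, c("train_loss", "val_loss"),
                              names_to = "split", values_to = "loss")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$epoch, y = .data$loss,
                                     colour = .data$split)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~modality, scales = "free_y") +
    ggplot2::labs(x = "epoch", y = "weighted cross-entropy") +
    ggplot2::theme_minimal()
}
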