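#' Plot normalized features by truth genotype
#'
#' The visual counterpart of the classifier's premise: per-feature
#' distributions split by genotype. For deletions the normalized region
#' depth should order g0 > g1 > g2, discordant support the other way
#' around.
#'
#' @param features Feature tibble from [extract_features()].
#' @param truth Truth tibble (`sample`, `site_id`, `genotype`).
#' @return A ggplot object.
#' @export
plot_feature_separation <- function(features, truth) {
  kind <- unique(features$kind)
  if (base::length(kind) > 1) abort("plot one indel kind at a time")
  labs <- feature_names_for(kind)
  df <- features %>%
    inner_join(select(truth, "sample", "site_id", "genotype"),
               by = c("sample", "site_id")) %>%
    tidyr::pivot_longer(all_of(feature_cols), names_to = "feature",
                        values_to = "value") %>%
    mutate(feature = factor(labs[match(.data$feature, feature_cols)],
                            levels = labs),
           genotype = factor(.data$genotype))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genotype, y = .data$value,
                                   fill = .data$genotype)) +
    ggplot2::geom_boxplot(outlier.size = 0.4, show.legend = FALSE) +
    ggplot2::facet_wrap(~feature, scales = "free_y") +
    ggplot2::labs(x = "truth genotype",
                  y = "normalized feature value",
                  title = paste0(kind, " feature separation by genotype"))
}

#' Heatmap of the genotyper's grid search
#'
#' @param object A `genotype_model`.
#' @param ... Unused.
#' @return A ggplot object (CV accuracy over the `(cost, gamma)` lattice,
#'   winner marked).
#' @export
autoplot.genotype_model <- function(object, ...) {
  if (is.null(object$cv_table))
    abort("this model carries no grid-search table (loaded from file?)")
  ggplot2::ggplot(object$cv_table,
                  ggplot2::aes(x = log2(.data$cost), y = log2(.data$gamma),
                               fill = .data$accuracy)) +
    ggplot2::geom_tile() +
    ggplot2::annotate("point", x = log2(object$cost),
                      y = log2(object$gamma), shape = 4, size = 3) +
    ggplot2::labs(x = "log2 cost", y = "log2 gamma",
                  fill = "CV accuracy",
                  title = sprintf("grid search (%d-fold CV), winner cost=%g gamma=%g",
                                  object$folds, object$cost, object$gamma))
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Bar chart of stratified genotype accuracy
#'
#' @param acc Output of [stratified_accuracy()].
#' @return A ggplot object.
#' @export
plot_accuracy <- function(acc) {
  df <- acc %>% filter(!is.na(.data$accuracy))
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$stratum,
                                              levels = .data$stratum),
                                   y = .data$accuracy)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.3f", .data$accuracy)),
                       vjust = -0.4, size = 3) +
    ggplot2::coord_cartesian(ylim = c(0, 1.05)) +
    ggplot2::labs(x = "stratum", y = "genotype accuracy")
}
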