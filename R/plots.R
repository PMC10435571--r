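# ggplot2 views of the result objects.

#' @describeIn ols_dose_regression Coefficient plot with confidence
#'   intervals (intercept omitted).
#' @param object An `assoc_ols` object.
#' @param ... Unused.
#' @method autoplot assoc_ols
#' @export
autoplot.assoc_ols <- function(object, ...) {
  d <- filter(object$coefficients, .data$term != "(Intercept)")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed", colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.15
    ) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(
      x = sprintf("coefficient (%d%% CI)", round(object$conf_level * 100)),
      y = NULL, title = "Genotype-dose OLS coefficients"
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn anova_bonferroni Boxplot of values by group with the overall
#'   ANOVA p-value in the subtitle.
#' @param object An `assoc_anova` object.
#' @param ... Unused.
#' @method autoplot assoc_anova
#' @export
autoplot.assoc_anova <- function(object, ...) {
  ggplot2::ggplot(object$data, ggplot2::aes(x = factor(.data$group), y = .data$value)) +
    ggplot2::geom_boxplot(outlier.shape = 21) +
    ggplot2::labs(
      x = "group", y = "value",
      subtitle = sprintf("one-way ANOVA p = %.3g (Bonferroni m = %d)",
                         object$overall$p_value, object$m)
    ) +
    ggplot2::theme_minimal()
}

#' @describeIn estimate_haplotypes Bar chart of the four haplotype
#'   frequencies.
#' @param object A `haplotype_freq` object.
#' @param ... Unused.
#' @method autoplot haplotype_freq
#' @export
autoplot.haplotype_freq <- function(object, ...) {
  d <- tidy(object)
  d$haplotype <- factor(d$haplotype, levels = HAPLOTYPES)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$haplotype, y = .data$frequency)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(
      x = "haplotype (locus1/locus2, upper case = major allele)",
      y = "frequency",
      subtitle = sprintf("n = %d samples, mode = %s", object$n, object$mode)
    ) +
    ggplot2::theme_minimal()
}

#' Plot candidate sites by overlap count and motif score
#'
#' @param candidates A ranked candidate tibble from [mine_candidates()].
#' @return A ggplot object.
#' @export
plot_candidates <- function(candidates) {
  ggplot2::ggplot(
    candidates,
    ggplot2::aes(x = .data$reference_score, y = factor(.data$k),
                 colour = .data$best_relative_score)
  ) +
    ggplot2::geom_point(size = 2, alpha = 0.8) +
    ggplot2::scale_colour_viridis_c(name = "best relative\nmotif score", limits = c(0, 1)) +
    ggplot2::labs(x = "reference peak score", y = "datasets overlapping (k)") +
    ggplot2::theme_minimal()
}
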