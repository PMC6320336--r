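#' Forest plot of standardised effect sizes
#'
#' One point per (model, term) with its 95% CI, the usual compact display
#' for a battery of standardised mixed models. Estimates significant after
#' FDR (when a `p_fdr` column is present) are drawn filled.
#'
#' @param estimates Effects tibble from [adjust_pvalues()] or
#'   [fit_model_battery()].
#' @return A ggplot object.
#' @export
plot_effects <- function(estimates) {
  est <- estimates %>%
    mutate(significant = if ("p_fdr" %in% names(estimates)) {
      .data$p_fdr < 0.05
    } else .data$p_raw < 0.05)
  ggplot2::ggplot(est, ggplot2::aes(x = .data$estimate, y = .data$model)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$conf_low, xmax = .data$conf_high),
      height = 0.2) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$significant),
                        shape = 21, size = 2) +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::facet_wrap(~term, scales = "free_x") +
    ggplot2::labs(x = "standardised effect (2-SD scale)", y = NULL)
}

#' @method autoplot egg_lmm
#' @export
autoplot.egg_lmm <- function(object, ...) {
  plot_effects(tidy(object))
}

#' Enrichment overview plot
#'
#' Cluster-by-term grid with enriched pairs drawn as filled rectangles.
#' @param object An `egg_enrichment` tibble from [funcat_enrichment()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot egg_enrichment
#' @export
autoplot.egg_enrichment <- function(object, ...) {
  df <- as_tibble(object)
  if ("compartment" %in% names(df)) {
    df$cluster <- paste(df$compartment, df$cluster)
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$term_id,
                                   y = factor(.data$cluster))) +
    ggplot2::geom_tile(ggplot2::aes(fill = .data$enriched),
                       colour = "grey80") +
    ggplot2::scale_fill_manual(values = c(`TRUE` = "black",
                                          `FALSE` = "white"),
                               guide = "none") +
    ggplot2::labs(x = "functional term", y = "protein cluster") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Cluster assignment plot
#'
#' Items ordered by cluster with exemplars highlighted.
#' @param object An `ap_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ap_result
#' @export
autoplot.ap_result <- function(object, ...) {
  df <- tidy(object) %>% arrange(.data$cluster)
  df$item_id <- factor(df$item_id, levels = df$item_id)
  ggplot2::ggplot(df, ggplot2::aes(x = factor(.data$cluster),
                                   y = .data$item_id)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$exemplar,
                                     size = .data$exemplar)) +
    ggplot2::scale_size_manual(values = c(`TRUE` = 3, `FALSE` = 1.5),
                               guide = "none") +
    ggplot2::labs(x = "cluster", y = NULL, colour = "exemplar")
}
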