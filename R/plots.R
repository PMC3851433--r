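#' MA plot of one array
#'
#' Scatter of per-spot log-ratio M against mean log-intensity A, with a
#' LOWESS trend through the good-flagged spots; the standard diagnostic
#' for intensity-dependent dye bias.
#'
#' @param records Tibble from [threshold_and_log()] (before or after
#'   [lowess_normalize()]).
#' @param span LOWESS span for the overlaid trend (default 0.3).
#' @return A ggplot object.
#' @export
plot_ma <- function(records, span = 0.3) {
  stopifnot(all(c("M", "A", "flag") %in% names(records)))
  ggplot2::ggplot(records, ggplot2::aes(x = .data$A, y = .data$M)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$flag),
                        size = 0.4, alpha = 0.4) +
    ggplot2::geom_smooth(data = records[records$flag == "G", ],
                         method = "loess", span = span, se = FALSE,
                         formula = y ~ x, colour = "black") +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::labs(x = "A (mean log2 intensity)",
                  y = "M (log2 sample/reference)")
}

#' @export
autoplot.hybrid_pca <- function(object, components = c(1, 2), ...) {
  cn <- paste0("PC", components)
  ve <- 100 * object$variance_explained[components]
  ggplot2::ggplot(object$coordinates,
                  ggplot2::aes(x = .data[[cn[1]]], y = .data[[cn[2]]],
                               colour = .data$group)) +
    ggplot2::geom_point(size = 2.5) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", cn[1], ve[1]),
                  y = sprintf("%s (%.1f%%)", cn[2], ve[2]))
}

#' @export
autoplot.hybrid_de <- function(object, alpha = 0.05, fc_threshold = 2, ...) {
  counts <- de_counts(significant_entities(object, alpha, fc_threshold)) %>%
    tidyr::pivot_longer(c("n_up", "n_down"), names_to = "direction",
                        values_to = "n") %>%
    dplyr::mutate(pairing = paste(.data$group1, "vs", .data$group2),
                  direction = ifelse(.data$direction == "n_up", "up", "down"))
  ggplot2::ggplot(counts, ggplot2::aes(x = .data$pairing, y = .data$n,
                                       fill = .data$direction)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::labs(x = NULL, y = "significant mRNAs",
                  title = sprintf("P <= %g, fold change >= %g",
                                  alpha, fc_threshold)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Dose-response profile of selected entities
#'
#' Group-mean normalized expression against domesticated-genome dose
#' (0/50/100%), one line per wild reference -- the standard visual for
#' judging additive / dominant / recessive patterns.
#'
#' @param em An `expr_mat`.
#' @param entities Probe ids to show.
#' @return A ggplot object.
#' @export
plot_dose_profile <- function(em, entities) {
  stopifnot(inherits(em, "expr_mat"))
  df <- tidy(em) %>%
    dplyr::filter(.data$probe_id %in% entities) %>%
    dplyr::left_join(em$design[c("sample_id", "dose")], by = "sample_id") %>%
    dplyr::mutate(wild_ref = dplyr::case_when(
      .data$group == "Wa" ~ "Wa", .data$group == "Ws" ~ "Ws",
      TRUE ~ "both")) %>%
    tidyr::uncount(weights = ifelse(.data$wild_ref == "both", 2, 1),
                   .id = "copy") %>%
    dplyr::mutate(wild_ref = ifelse(.data$wild_ref == "both",
                                    ifelse(.data$copy == 1, "Wa", "Ws"),
                                    .data$wild_ref)) %>%
    dplyr::group_by(.data$probe_id, .data$wild_ref, .data$dose) %>%
    dplyr::summarise(value = mean(.data$value), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dose, y = .data$value,
                                   linetype = .data$wild_ref)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~probe_id, scales = "free_y") +
    ggplot2::labs(x = "domesticated genome (%)",
                  y = "normalized log2 expression", linetype = "wild group")
}
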