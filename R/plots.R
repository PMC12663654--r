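#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a category summary
#'
#' Bar chart of the six-category composition as percentages of all
#' identified Dicers.
#'
#' @param object A `dcr_summary` from [summarize_categories()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dcr_summary
#' @export
autoplot.dcr_summary <- function(object, ...) {
  ggplot2::ggplot(object$categories,
                  ggplot2::aes(x = .data$category, y = .data$percent)) +
    ggplot2::geom_col(fill = "#4C72B0") +
    ggplot2::geom_text(ggplot2::aes(label = sprintf("%.1f%%", .data$percent)),
                       vjust = -0.4, size = 3) +
    ggplot2::labs(x = NULL, y = "% of identified Dcr proteins",
                  title = sprintf("Dcr architecture categories (n = %d)",
                                  object$total)) +
    ggplot2::theme_minimal()
}

#' Plot a clustering's size distribution
#'
#' @param object A `dcr_clustering` from [cluster_components()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot dcr_clustering
#' @export
autoplot.dcr_clustering <- function(object, ...) {
  ggplot2::ggplot(object$clusters,
                  ggplot2::aes(x = factor(.data$cluster), y = .data$size)) +
    ggplot2::geom_col(fill = "#55A868") +
    ggplot2::labs(x = "cluster", y = "members",
                  title = sprintf("%d connected-component clusters (%s network)",
                                  object$n_clusters, object$mode)) +
    ggplot2::theme_minimal()
}

#' Plot the ER-Mk likelihood profile
#'
#' Log-likelihood over a rate grid spanning the fitted `q_hat` (marked).
#'
#' @param object An `mk_er_fit` from [fit_mk_er()].
#' @param n_grid Grid points.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot mk_er_fit
#' @export
autoplot.mk_er_fit <- function(object, n_grid = 100, ...) {
  qs <- exp(seq(log(max(object$q_hat / 20, 1e-6)),
                log(object$q_hat * 20 + 1e-6), length.out = n_grid))
  ll <- vapply(qs, function(q) {
    mk_er_loglik(object$tree, object$tip_states, q, object$root_prior)
  }, numeric(1))
  ggplot2::ggplot(tibble::tibble(q = qs, loglik = ll),
                  ggplot2::aes(x = .data$q, y = .data$loglik)) +
    ggplot2::geom_line(color = "#4C72B0") +
    ggplot2::geom_vline(xintercept = object$q_hat, linetype = 2,
                        color = "#C44E52") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ER rate q", y = "log-likelihood",
                  title = sprintf("q_hat = %.4g", object$q_hat)) +
    ggplot2::theme_minimal()
}

#' Terminal-length distributions by category
#'
#' Boxplots of N- and C-terminal lengths (to the DUF283 and RNase IIIb
#' anchors) across Dicer categories — the truncation diagnostic for the
#' smaller nonC/nonE proteins.
#'
#' @param records Classified records from [classify_architectures()].
#' @return A ggplot object.
#' @export
plot_terminal_lengths <- function(records) {
  long <- records |>
    dplyr::filter(.data$is_dcr) |>
    dplyr::select("category", "n_term_len", "c_term_len") |>
    tidyr::pivot_longer(-"category", names_to = "terminus",
                        values_to = "length") |>
    dplyr::filter(!is.na(.data$length)) |>
    dplyr::mutate(terminus = dplyr::recode(.data$terminus,
                                           n_term_len = "N-terminal",
                                           c_term_len = "C-terminal"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$category, y = .data$length)) +
    ggplot2::geom_boxplot(fill = "#8172B2", alpha = 0.6) +
    ggplot2::facet_wrap(~terminus, scales = "free_y") +
    ggplot2::labs(x = NULL, y = "length (aa)") +
    ggplot2::theme_minimal()
}
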