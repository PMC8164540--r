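# ggplot2 diagnostics for the fitted objects.

#' Plot the ICL model-selection curve
#'
#' ICL (penalized deviance form; lower is better) against the number of
#' clusters, with the chosen G marked.
#'
#' @param object An `icl_table` from [select_G()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.icl_table <- function(object, ...) {
  tab <- object$table
  ggplot2::ggplot(tab, ggplot2::aes(x = .data$G, y = .data$icl)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = tab[tab$G == object$best_G, , drop = FALSE],
                        colour = "red", size = 3) +
    ggplot2::scale_x_continuous(breaks = tab$G) +
    ggplot2::labs(x = "number of clusters G",
                  y = "ICL (lower is better)",
                  title = sprintf("ICL selects G = %d", object$best_G)) +
    ggplot2::theme_minimal()
}

#' Plot the EM objective trace of a mixture-ERGM fit
#'
#' @param object A `mixture_ergm` fit.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.mixture_ergm <- function(object, ...) {
  df <- tibble::tibble(iteration = seq_along(object$logpl_trace),
                       L_C = object$logpl_trace)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$iteration, y = .data$L_C)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1.5) +
    ggplot2::labs(x = "EM iteration",
                  y = "classification log-pseudolikelihood",
                  title = sprintf("mixture-ERGM fit, G = %d", object$G)) +
    ggplot2::theme_minimal()
}

#' Plot posterior hub marginals
#'
#' Nodes ordered by posterior marginal, with the 0.5 call threshold.
#'
#' @param object A `hub_posterior` from [gibbs_posterior()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.hub_posterior <- function(object, ...) {
  df <- tidy(object)
  df$node_id <- factor(df$node_id,
                       levels = df$node_id[order(df$posterior_marginal)])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$node_id,
                                   y = .data$posterior_marginal,
                                   fill = .data$hub_call)) +
    ggplot2::geom_col() +
    ggplot2::geom_hline(yintercept = 0.5, linetype = 2, colour = "grey40") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "posterior P(hub)", fill = "hub call") +
    ggplot2::theme_minimal()
}
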