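#' @export
autoplot.relevance_fit <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$frame, y = .data$joint,
                                   fill = .data$w)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white",
                                  high = "#b2182b") +
    ggplot2::labs(x = "frame", y = NULL, fill = "W",
                  title = "Motion-to-performance relevance map") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.task_modules <- function(object, modules = seq_len(min(2, object$rank)),
                                  ...) {
  df <- tidy(object) |>
    dplyr::filter(.data$module %in% modules)
  sp <- dplyr::filter(df, .data$component == "spatial")
  te <- dplyr::filter(df, .data$component == "temporal")
  p1 <- ggplot2::ggplot(sp, ggplot2::aes(x = .data$label, y = .data$value)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = "weight", title = "Task-relevant spatial modules") +
    ggplot2::theme_minimal()
  p2 <- ggplot2::ggplot(te, ggplot2::aes(x = .data$index, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~module, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "frame", y = "weight",
                  title = "Task-relevant temporal modules") +
    ggplot2::theme_minimal()
  list(spatial = p1, temporal = p2)
}

#' Cumulative contribution curves of module families
#'
#' Plots cumulative variance fractions (motion variance by motion-relevant
#' modules, or predicted-performance variance by task-relevant modules) as
#' the standard non-decreasing curves ending at 1.
#'
#' @param ... Named tibbles with columns `modules` and `fraction`, e.g. the
#'   outputs of [motion_variance_explained()],
#'   [performance_variance_explained()] and
#'   [motion_variance_explained_by_task_modules()].
#' @return A ggplot object.
#' @export
plot_contribution_curves <- function(...) {
  curves <- list(...)
  nm <- names(curves) %||% paste0("curve", seq_along(curves))
  df <- purrr::imap_dfr(curves, function(cv, name) {
    tibble::tibble(curve = name, modules = cv$modules, fraction = cv$fraction)
  })
  ggplot2::ggplot(df, ggplot2::aes(x = .data$modules, y = .data$fraction,
                                   colour = .data$curve)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(x = "number of modules", y = "cumulative fraction",
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.module_fragments <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$trial, y = .data$yhat,
                               colour = factor(.data$module))) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "trial", y = "predicted-performance fragment",
                  colour = "module") +
    ggplot2::theme_minimal()
}
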