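# broom-style accessors and ggplot2 views for fitted models and metric
# reports.

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Tidy the training log of a fitted model
#'
#' @param x a `gcdm_model`.
#' @param ... unused.
#' @return tibble with `step` and running `loss`.
#' @method tidy gcdm_model
#' @export
tidy.gcdm_model <- function(x, ...) x$log

#' One-row summary of a fitted model
#'
#' @param x a `gcdm_model`.
#' @param ... unused.
#' @return tibble with layer count, parameter count, schedule length,
#'   conditioning, and final training loss.
#' @method glance gcdm_model
#' @export
glance.gcdm_model <- function(x, ...) {
  tibble::tibble(
    n_layers = x$config$n_layers,
    n_parameters = n_parameters(x$params),
    T = x$schedule$T,
    schedule_kind = x$schedule$kind,
    conditional = !is.null(x$property_stats),
    final_loss = if (nrow(x$log)) utils::tail(x$log$loss, 1) else NA_real_)
}

#' Long-format view of a stability report
#'
#' @param x a `stability_report` from [evaluate_molecules()].
#' @param ... unused.
#' @return tibble with `metric` and `value` (percent) columns.
#' @method tidy stability_report
#' @export
tidy.stability_report <- function(x, ...) {
  keep <- setdiff(names(x), c("unique_smiles", "n_molecules"))
  tibble::tibble(metric = keep,
                 value = vapply(keep, function(k) as.numeric(x[[k]]), numeric(1)))
}

#' Training-loss curve
#'
#' @param object a `gcdm_model`.
#' @param ... unused.
#' @return a ggplot object.
#' @method autoplot gcdm_model
#' @export
autoplot.gcdm_model <- function(object, ...) {
  ggplot2::ggplot(object$log, ggplot2::aes(x = .data$step, y = .data$loss)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "gradient step", y = "running loss",
                  title = "Denoising objective") +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data
NULL
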