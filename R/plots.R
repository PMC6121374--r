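#' Bar chart of a census's per-type composition
#'
#' @param object An `ffl_census`.
#' @param ... Unused.
#' @return A ggplot object: loop counts per FFL type, filled by
#'   single-Y/multi-Y arity.
#' @export
autoplot.ffl_census <- function(object, ...) {
  inst <- object$instances |>
    dplyr::mutate(type = factor(.data$type, levels = ffl_types()$type))
  ggplot2::ggplot(inst, ggplot2::aes(x = .data$type, fill = .data$arity_class)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = "FFL type", y = "loops", fill = "arity") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Mean dose-response profiles of labelled groups
#'
#' Plots each group's mean log2 fold-change curve over the positive dose
#' grid (log10 dose axis), faceted nowhere, coloured by group and
#' annotated with the shape label.
#'
#' @param groups Group tibble from [profile_groups()] (carries the dose
#'   grid as an attribute).
#' @return A ggplot object.
#' @export
plot_group_profiles <- function(groups) {
  doses <- attr(groups, "doses")
  stopifnot(!is.null(doses))
  long <- groups |>
    dplyr::mutate(curve = purrr::map(.data$mean_profile, function(p) {
      tibble::tibble(dose = doses, log2fc = as.numeric(p))
    })) |>
    dplyr::select("group_id", "shape", "curve") |>
    tidyr::unnest("curve")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dose, y = .data$log2fc,
                                     colour = .data$group_id)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "cAMP dose (mM)", y = "mean log2 fold change vs 0 mM",
                  colour = "group",
                  subtitle = paste(unique(paste0(long$group_id, ": ", long$shape)),
                                   collapse = "  ")) +
    ggplot2::theme_minimal()
}
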