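# ggplot2 figures for the main result types.

#' Plot a penetration profile
#'
#' Bar chart of the percentage of carrier signal per compartment, the
#' standard presentation of a penetration profile.
#'
#' @param object a [penetration_profile_new()] tibble.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.penetration_profile <- function(object, ...) {
  df <- dplyr::mutate(object,
                      compartment = factor(.data$compartment,
                                           levels = .data$compartment))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$compartment,
                                   y = .data$fraction_pct)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "distance from vessel lumen (µm)",
                  y = "carrier signal (% of total)") +
    ggplot2::theme_minimal()
}

#' Plot cohort penetration profiles as mean ± SD bars by condition
#'
#' @param cohort a [run_cohort()] (or combined) tibble with `pct_*` columns
#'   and, optionally, a `condition` column.
#' @return A ggplot object.
#' @export
plot_cohort_profiles <- function(cohort) {
  pct_cols <- grep("^pct_", names(cohort), value = TRUE)
  if (!length(pct_cols)) abort("no profile columns (pct_*) in cohort")
  if (!"condition" %in% names(cohort)) cohort$condition <- "cohort"
  long <- tidyr::pivot_longer(cohort, dplyr::all_of(pct_cols),
                              names_to = "compartment",
                              values_to = "pct") |>
    dplyr::mutate(compartment = factor(sub("^pct_", "", .data$compartment),
                                       levels = sub("^pct_", "", pct_cols)))
  summ <- long |>
    dplyr::group_by(.data$condition, .data$compartment) |>
    dplyr::summarise(mean = mean(.data$pct), sd = sd(.data$pct),
                     .groups = "drop")
  ggplot2::ggplot(summ, ggplot2::aes(x = .data$compartment, y = .data$mean,
                                     fill = .data$condition)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.9)) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd,
                   ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.9), width = 0.3) +
    ggplot2::labs(x = "compartment (µm from vessel lumen)",
                  y = "carrier signal (% of total, mean ± SD)") +
    ggplot2::theme_minimal()
}

#' Raster view of a 2D shell map
#'
#' @param shells a [build_shells()] result for a 2D field.
#' @return A ggplot object with lumen, shells and the beyond-shell region.
#' @export
plot_shells <- function(shells) {
  comp <- shells$compartments
  if (length(dim(comp)) != 2L) abort("plot_shells() expects a 2D shell map")
  labs <- shells$per_compartment$label
  ids <- shells$per_compartment$compartment
  df <- tibble(
    y = rep(seq_len(nrow(comp)), ncol(comp)),
    x = rep(seq_len(ncol(comp)), each = nrow(comp)),
    compartment = factor(as.vector(comp), levels = ids, labels = labs)
  )
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y,
                                   fill = .data$compartment)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "compartment") +
    ggplot2::theme_void()
}
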