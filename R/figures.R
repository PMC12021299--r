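# Figure builders.  Figure data are always emitted as CSV by the pipeline;
# rendering to files is best-effort so headless environments without a
# graphics device never fail a run.

#' Binned-scatterplot figure
#'
#' @param binned A `binned_series` (violation probability vs persons
#'   present).
#' @param xlab,ylab Axis labels.
#' @return A ggplot object.
#' @export
plot_binscatter <- function(binned, xlab = "Persons present",
                            ylab = "P(distancing violation)") {
  df <- as_tibble_binned(binned)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$bin_x_mean,
                                   y = .data$bin_y_mean)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(alpha = 0.4) +
    ggplot2::labs(x = xlab, y = ylab) +
    ggplot2::theme_minimal()
}

#' Frame-level association figure
#'
#' Mean violator count by crowd size with the pooled OLS line.
#'
#' @param frame_table Frame summaries.
#' @param fit An `agg_fit` from [fit_frame_ols()].
#' @return A ggplot object.
#' @export
plot_frame_association <- function(frame_table, fit) {
  df <- frame_table |>
    dplyr::group_by(.data$n_present) |>
    dplyr::summarise(mean_violators = mean(.data$n_violators),
                     .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n_present,
                                   y = .data$mean_violators)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_abline(intercept = fit$intercept, slope = fit$slope,
                         colour = "steelblue") +
    ggplot2::labs(x = "Persons present", y = "Violators per frame") +
    ggplot2::theme_minimal()
}

#' Observed-vs-null overlay figure
#'
#' Observed mean violating-pair counts by crowd size over the simulated
#' random-placement curves (one per area).
#'
#' @param comparison Output of [compare_observed_to_null()].
#' @return A ggplot object.
#' @export
plot_null_overlay <- function(comparison) {
  on_grid <- comparison[!is.na(comparison$null_mean_pairs), , drop = FALSE]
  ggplot2::ggplot(comparison, ggplot2::aes(x = .data$n)) +
    ggplot2::geom_line(data = on_grid,
                       ggplot2::aes(y = .data$null_mean_pairs,
                                    colour = factor(.data$area_m2)),
                       linetype = "dashed") +
    ggplot2::geom_line(ggplot2::aes(y = .data$obs_mean_pairs),
                       linewidth = 1) +
    ggplot2::labs(x = "Persons present", y = "Violating pairs per frame",
                  colour = "Null area (m²)") +
    ggplot2::theme_minimal()
}

save_figure <- function(plot, dir, name, width = 6, height = 4) {
  saved <- character(0)
  pdf_path <- file.path(dir, paste0(name, ".pdf"))
  ok <- tryCatch({
    grDevices::pdf(pdf_path, width = width, height = height)
    print(plot)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    warning("could not render ", name, ".pdf: ", conditionMessage(e),
            call. = FALSE)
    FALSE
  })
  if (ok) saved <- c(saved, pdf_path)
  if (isTRUE(capabilities("png"))) {
    png_path <- file.path(dir, paste0(name, ".png"))
    ok <- tryCatch({
      grDevices::png(png_path, width = width * 100, height = height * 100)
      print(plot)
      grDevices::dev.off()
      TRUE
    }, error = function(e) FALSE)
    if (ok) saved <- c(saved, png_path)
  }
  saved
}

render_figures <- function(binned_person, frame_table, frame_fit,
                           comparison, dir) {
  figs <- list(
    fig_person_binscatter = plot_binscatter(binned_person),
    fig_frame_association = plot_frame_association(frame_table, frame_fit),
    fig_null_overlay = plot_null_overlay(comparison)
  )
  unlist(lapply(names(figs), function(nm) {
    save_figure(figs[[nm]], dir, nm)
  }))
}
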