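# Figure helpers (ggplot2, Suggests-only).

need_ggplot <- function() {
  if (!requireNamespace("ggplot2", quietly = TRUE))
    stop_invalid("ggplot2 is required for plotting")
}

#' Group-average ITPC versus gap width
#'
#' One panel per age group x modulation depth, curves by genotype (or sex),
#' mirroring the standard population-summary layout for gap-ASSR data.
#'
#' @param itpc_table output of [itpc_group_table()].
#' @param colour factor mapped to colour (`"genotype"` or `"sex"`).
#' @return a ggplot object.
#' @export
plot_itpc_curves <- function(itpc_table, colour = "genotype") {
  need_ggplot()
  agg <- stats::aggregate(
    list(itpc = itpc_table$itpc),
    by = list(group = itpc_table[[colour]], channel = itpc_table$channel,
              age_group = itpc_table$age_group,
              mod_depth_pct = itpc_table$mod_depth_pct,
              gap_width_ms = itpc_table$gap_width_ms),
    FUN = mean)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$gap_width_ms, y = .data$itpc,
                                    colour = .data$group,
                                    linetype = .data$channel)) +
    ggplot2::geom_line() + ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(age_group ~ mod_depth_pct,
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = "gap width (ms)", y = "mean 40 Hz ITPC",
                  colour = colour) +
    ggplot2::theme_minimal()
}

#' Time-frequency ITPC heat map
#'
#' @param surface an `itpc_surface`.
#' @return a ggplot object.
#' @export
plot_itpc_surface <- function(surface) {
  need_ggplot()
  df <- expand.grid(time_ms = surface$times_ms, freq_hz = surface$freqs_hz)
  df$itpc <- as.vector(t(surface$itpc))
  df$itpc[!as.vector(t(surface$valid))] <- NA
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$freq_hz,
                                   fill = .data$itpc)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(na.value = "grey90", limits = c(0, 1)) +
    ggplot2::labs(x = "time from segment onset (ms)", y = "frequency (Hz)",
                  fill = "ITPC") +
    ggplot2::theme_minimal()
}

#' Grand-average ERP waveforms
#'
#' @param erps named list of `erp_waveform` objects (e.g. one per channel).
#' @return a ggplot object.
#' @export
plot_erp <- function(erps) {
  need_ggplot()
  df <- do.call(rbind, lapply(erps, function(e) {
    data.frame(channel = e$channel, time_ms = e$time_ms, uv = e$mean_uv)
  }))
  ggplot2::ggplot(df, ggplot2::aes(.data$time_ms, .data$uv)) +
    ggplot2::geom_vline(xintercept = 0, linetype = "dashed",
                        colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time from sound onset (ms)", y = "amplitude (µV)") +
    ggplot2::theme_minimal()
}
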