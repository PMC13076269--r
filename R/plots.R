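# Figures. Every plot is a pure view of an emitted result table: the values
# rendered are exactly the columns of the corresponding CSV.

#' Sex-differential volcano plot
#'
#' Plots the log2 male-to-female ROR ratio against -log10 of the
#' BH-adjusted p-value, one point per preferred term, with dashed guides at
#' the fold-change thresholds and the q cutoff. Points are classed
#' significant-male / significant-female / non-significant by the same
#' thresholds used in [ror_ratio_test()].
#'
#' @param sexdiff A tibble from [ror_ratio_test()].
#' @param q_cut,lfc_cut Significance thresholds (dashed guide lines).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
make_volcano <- function(sexdiff, q_cut = 0.05, lfc_cut = 1, title = NULL) {
  df <- sexdiff[sexdiff$testable & !is.na(sexdiff$q), , drop = FALSE]
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no testable PTs") +
             ggplot2::theme_void())
  }
  df$class <- factor(ifelse(df$direction == "male-biased", "significant-male",
                     ifelse(df$direction == "female-biased",
                            "significant-female", "non-significant")),
                     levels = c("significant-male", "significant-female",
                                "non-significant"))
  df$neglog10q <- -log10(pmax(df$q, 1e-300))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$log2_ratio, y = .data$neglog10q,
                                   colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::geom_vline(xintercept = c(-lfc_cut, lfc_cut), linetype = "dashed") +
    ggplot2::geom_hline(yintercept = -log10(q_cut), linetype = "dashed") +
    ggplot2::scale_colour_manual(values = c(
      "significant-male" = "#2166AC", "significant-female" = "#B2182B",
      "non-significant" = "grey60"), drop = FALSE) +
    ggplot2::labs(x = "log2(ROR male / ROR female)",
                  y = "-log10 adjusted p", colour = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' Sex-stratified forest plot
#'
#' Male and female RORs with 95% confidence intervals per preferred term,
#' against a unity reference line.
#'
#' @param sexdiff A tibble from [ror_ratio_test()].
#' @param max_pts Show at most this many PTs (largest |log2 ratio| first).
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
make_forest <- function(sexdiff, max_pts = 25L, title = NULL) {
  df <- sexdiff[sexdiff$testable, , drop = FALSE]
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0, label = "no testable PTs") +
             ggplot2::theme_void())
  }
  df <- df[order(-abs(df$log2_ratio)), , drop = FALSE]
  df <- df[seq_len(min(nrow(df), max_pts)), , drop = FALSE]
  long <- dplyr::bind_rows(
    tibble::tibble(pt = df$pt, sex = "male", ror = df$ror_m,
                   lo = df$ror_m_lo95, hi = df$ror_m_hi95),
    tibble::tibble(pt = df$pt, sex = "female", ror = df$ror_f,
                   lo = df$ror_f_lo95, hi = df$ror_f_hi95))
  long$pt <- factor(long$pt, levels = rev(df$pt))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$ror, y = .data$pt,
                                     colour = .data$sex)) +
    ggplot2::geom_vline(xintercept = 1, linetype = "dashed") +
    ggplot2::geom_point(position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$lo, xmax = .data$hi),
      height = 0.3, position = ggplot2::position_dodge(width = 0.6)) +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "ROR (log scale)", y = NULL, title = title) +
    ggplot2::theme_minimal()
}

#' SOC-level log2-ROR heatmap
#'
#' Diverging colour scale centred at 0 (ROR = 1); one tile per
#' (system organ class, stratum) combination, missing combinations blank.
#'
#' @param soc_signals A tibble with columns `soc`, `stratum`, `log2_ror`.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
make_heatmap <- function(soc_signals, title = NULL) {
  df <- soc_signals[c("soc", "stratum", "log2_ror")]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$stratum, y = .data$soc,
                                   fill = .data$log2_ror)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "#2166AC", mid = "white",
                                  high = "#B2182B", midpoint = 0) +
    ggplot2::labs(x = NULL, y = NULL, fill = "log2 ROR", title = title) +
    ggplot2::theme_minimal()
}

#' Time-to-onset scatter-box plot
#'
#' Per-case onset days overlaid on median/IQR boxes, one panel position per
#' cohort; only included records are drawn.
#'
#' @param tto_records A tibble from [compute_tto()] with a `cohort` column.
#' @param title Optional plot title.
#' @return A ggplot object.
#' @export
make_tto_plot <- function(tto_records, title = NULL) {
  df <- tto_records[tto_records$status == "included", , drop = FALSE]
  if (!"cohort" %in% names(df)) df$cohort <- "all"
  if (nrow(df) == 0L) {
    return(ggplot2::ggplot() +
             ggplot2::annotate("text", x = 0, y = 0,
                               label = "no included records") +
             ggplot2::theme_void())
  }
  ggplot2::ggplot(df, ggplot2::aes(x = .data$cohort, y = .data$tto_days)) +
    ggplot2::geom_boxplot(outlier.shape = NA, width = 0.5) +
    ggplot2::geom_jitter(width = 0.15, alpha = 0.3, size = 0.6) +
    ggplot2::scale_y_continuous(trans = "log1p") +
    ggplot2::labs(x = NULL, y = "time to onset (days)", title = title) +
    ggplot2::theme_minimal()
}

# Write a plot as vector PDF always, and raster PNG when a device exists.
save_plot <- function(p, stem, width = 7, height = 5) {
  pdf_path <- paste0(stem, ".pdf")
  grDevices::pdf(pdf_path, width = width, height = height)
  print(p)
  grDevices::dev.off()
  png_path <- paste0(stem, ".png")
  ok <- tryCatch({
    grDevices::png(png_path, width = width * 100, height = height * 100)
    print(p)
    grDevices::dev.off()
    TRUE
  }, error = function(e) {
    try(grDevices::dev.off(), silent = TRUE)
    FALSE
  })
  c(pdf_path, if (ok) png_path)
}
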