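# ggplot2 displays for fits, studies and metric reports.

#' @importFrom ggplot2 ggplot aes geom_line geom_raster geom_col facet_wrap
#'   scale_fill_gradient labs theme_minimal coord_fixed autoplot
NULL

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

mat_to_df <- function(mat, label) {
  tibble(row = rep(seq_len(nrow(mat)), times = ncol(mat)),
         col = rep(seq_len(ncol(mat)), each = nrow(mat)),
         intensity = as.vector(mat), image = label)
}

#' Plot the three modalities of a study (optionally with a synthesis)
#'
#' @param study A \code{study_triplet}.
#' @param synth Optional synthetic T1ce matrix on \code{[0,255]}.
#' @return A ggplot object of intensity rasters.
#' @export
plot_study <- function(study, synth = NULL) {
  df <- bind_rows(mat_to_df(study$t1pre$intensities, "T1pre"),
                  mat_to_df(study$t2$intensities, "T2"),
                  mat_to_df(study$t1ce$intensities, "T1ce (real)"))
  if (!is.null(synth)) df <- bind_rows(df, mat_to_df(synth, "T1ce (synthetic)"))
  ggplot(df, aes(x = .data$col, y = -.data$row, fill = .data$intensity)) +
    geom_raster() +
    scale_fill_gradient(low = "black", high = "white", limits = c(0, 255)) +
    facet_wrap(~image, nrow = 1) +
    coord_fixed() +
    labs(x = NULL, y = NULL, fill = "intensity", title = study$study_id) +
    theme_minimal()
}

#' Training curves of a fit
#'
#' Validation MSE and the loss decomposition per epoch.
#'
#' @param object A \code{cesynth_fit}.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.cesynth_fit <- function(object, ...) {
  long <- tidy(object)
  keep <- c("val_mse", "val_psnr", "val_ssim", "l_l1", "l_gr", "total_g", "total_d")
  long <- long[long$term %in% keep & is.finite(long$value), ]
  ggplot(long, aes(x = .data$epoch, y = .data$value)) +
    geom_line() +
    facet_wrap(~term, scales = "free_y") +
    labs(x = "epoch", y = NULL,
         title = sprintf("training history (%s)", object$config$ablation)) +
    theme_minimal()
}

#' Per-rater Turing-test scores
#'
#' @param object A [turing_score()] result.
#' @param ... Unused.
#' @return A ggplot bar chart of percent correct per rater.
#' @export
autoplot.turing_score <- function(object, ...) {
  df <- object$per_rater
  if (!"rater" %in% names(df)) df$rater <- seq_len(nrow(df))
  ggplot(df, aes(x = factor(.data$rater), y = .data$pct_correct)) +
    geom_col() +
    labs(x = "rater", y = "% correct",
         title = sprintf("Turing test: %.2f%% +/- %.2f",
                         object$mean_pct, object$sd_pct)) +
    theme_minimal()
}
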