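#' Plot a repeatability curve with its exponential fit
#'
#' Points are the mean r_spat per scan time with +/- 1 SD error bars; the
#' fitted curve r_spatmax - exp(-t / a) is drawn when the fit converged.
#'
#' @param object an `rspat_curve` from [repeatability_curve()].
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.rspat_curve <- function(object, ...) {
  pts <- object$points
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$scan_time_min,
                                         y = .data$r_spat_mean)) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$r_spat_mean - .data$r_spat_sd,
                                        ymax = .data$r_spat_mean + .data$r_spat_sd),
                           width = 0.3, na.rm = TRUE) +
    ggplot2::geom_point(size = 2) +
    ggplot2::labs(x = "Scan time (min)", y = expression(r[spat]),
                  title = "Within-subject repeatability vs scan time") +
    ggplot2::theme_minimal()
  fit <- object$fit
  if (!is.null(fit) && isTRUE(fit$converged)) {
    tt <- seq(min(pts$scan_time_min) * 0.5, max(pts$scan_time_min) * 1.3,
              length.out = 200)
    curve_df <- tibble::tibble(t = tt, r = fit$r_spatmax - exp(-tt / fit$a))
    p <- p + ggplot2::geom_line(data = curve_df,
                                ggplot2::aes(x = .data$t, y = .data$r),
                                colour = "steelblue")
  }
  p
}

#' @rdname autoplot.rspat_curve
#' @export
autoplot.rspat_fit <- function(object, ...) {
  d <- object$data
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$t, y = .data$r)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "Scan time (min)", y = expression(r[spat])) +
    ggplot2::theme_minimal()
  if (isTRUE(object$converged)) {
    tt <- seq(min(d$t) * 0.5, max(d$t) * 1.3, length.out = 200)
    p <- p + ggplot2::geom_line(
      data = tibble::tibble(t = tt, r = object$r_spatmax - exp(-tt / object$a)),
      ggplot2::aes(x = .data$t, y = .data$r), colour = "steelblue")
  }
  p
}

#' Axial-slice heatmap of a voxel map
#'
#' @param object a `voxel_map` (connectivity, target or overlap map).
#' @param slice_z 0-based axial slice index; defaults to the slice containing
#'   the map maximum.
#' @param ... unused.
#' @return A ggplot.
#' @export
autoplot.voxel_map <- function(object, slice_z = NULL, ...) {
  g <- object$grid
  if (is.null(slice_z)) {
    amax <- which.max(abs(object$values))
    slice_z <- linear_to_voxel(amax, g)[1, 3]
  }
  arr <- array(object$values, dim = g$shape)
  sl <- arr[, , slice_z + 1]
  df <- expand.grid(i = 0:(g$shape[1] - 1), j = 0:(g$shape[2] - 1))
  mm <- cbind(df$i, df$j, slice_z, 1) %*% t(g$affine)
  df$x <- mm[, 1]; df$y <- mm[, 2]; df$value <- as.vector(sl)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "blue", mid = "white", high = "red",
                                  na.value = "grey85") +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (mm)", y = "y (mm)",
                  title = sprintf("%s, axial slice z = %g mm", class(object)[1],
                                  voxel_to_mni(c(0, 0, slice_z), g)[3])) +
    ggplot2::theme_minimal()
}
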