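## Figures: double-angle plots, SEQ rainclouds, axis-SD envelope.

#' Double-angle plot of astigmatic power vectors
#'
#' Scatter of (C0, C45) with the location estimate (medoid or centroid)
#' and the 95% region boundary; the axes are the 0/90 and 45/135 degree
#' astigmatism projections, so axis angles appear doubled and 0/180
#' coincide.
#'
#' @param sample data frame or matrix with columns `C0`, `C45`.
#' @param summary optional [summarize_population()] result to overlay.
#' @param main plot title.
#' @export
plot_double_angle <- function(sample, summary = NULL, main = "Double-angle plot") {
  x <- as_astig_matrix(sample)
  lim <- max(abs(x), 0.1) * 1.15
  plot(x[, 1L], x[, 2L], pch = 16, col = adjustcolor("steelblue", 0.5),
       xlim = c(-lim, lim), ylim = c(-lim, lim), asp = 1,
       xlab = "C0 [D]", ylab = "C45 [D]", main = main)
  abline(h = 0, v = 0, col = "grey70")
  if (!is.null(summary)) {
    bnd <- summary$region$boundary
    polygon(bnd[, 1L], bnd[, 2L], border = "magenta", lwd = 2)
    points(summary$location[1L], summary$location[2L], pch = 3, cex = 1.6,
           lwd = 2, col = "red")
    legend("topleft", bty = "n", cex = 0.8, legend = sprintf(
      "%s (%.2f, %.2f) D; CR %.2f D^2",
      if (summary$branch == "hull") "medoid" else "centroid",
      summary$location[1L], summary$location[2L], summary$region$area))
  }
  invisible(NULL)
}

#' Raincloud-style plot of a univariate distribution
#'
#' Density curve, box (interquartile range with median), whiskers at the
#' 2.5%/97.5% quantiles, and the jittered data scatter.
#'
#' @param values numeric vector (e.g. per-eye mean SEQ in dioptres).
#' @param main,xlab plot annotation.
#' @export
plot_raincloud <- function(values, main = "Distribution", xlab = "value") {
  values <- values[is.finite(values)]
  d <- density(values)
  q <- quantile(values, c(0.025, 0.25, 0.5, 0.75, 0.975))
  ymax <- max(d$y)
  plot(d$x, d$y, type = "l", lwd = 2, col = "steelblue", main = main,
       xlab = xlab, ylab = "density", ylim = c(-0.7 * ymax, ymax))
  polygon(d$x, d$y, col = adjustcolor("steelblue", 0.3), border = NA)
  yb <- -0.25 * ymax
  rect(q[2L], yb - 0.08 * ymax, q[4L], yb + 0.08 * ymax,
       col = "white", border = "black")
  segments(q[3L], yb - 0.08 * ymax, q[3L], yb + 0.08 * ymax, lwd = 2)
  segments(q[1L], yb, q[2L], yb)
  segments(q[4L], yb, q[5L], yb)
  points(values, runif(length(values), -0.6 * ymax, -0.4 * ymax),
         pch = 16, cex = 0.5, col = adjustcolor("grey30", 0.5))
  invisible(NULL)
}

#' Plot axis repeatability versus radius difference with fitted envelope
#'
#' @param axis_sds,dR per-record axis SDs (degrees) and radius differences
#'   (mm), as supplied to [axis_sd_vs_dR_envelope()].
#' @param envelope an [axis_sd_vs_dR_envelope()] fit to overlay.
#' @param main plot title.
#' @export
plot_axis_envelope <- function(axis_sds, dR, envelope = NULL,
                               main = "Axis SD vs radius difference") {
  keep <- is.finite(axis_sds) & is.finite(dR)
  plot(dR[keep], axis_sds[keep], pch = 16, cex = 0.6,
       col = adjustcolor("grey30", 0.6),
       xlab = "R1 - R2 of mean fit [mm]", ylab = "SD of axis A1 [deg]",
       main = main)
  if (!is.null(envelope)) {
    xx <- seq(max(min(dR[keep]), 1e-3), max(dR[keep]), length.out = 200)
    lines(xx, envelope$fn(xx), col = "magenta", lwd = 2, lty = 2)
  }
  invisible(NULL)
}

write_report_figures <- function(report, out_dir) {
  for (key in names(report$astig)) {
    a <- report$astig[[key]]
    mm <- report$means[report$means$roi == a$roi &
                         report$means$model == a$model &
                         report$means$surface == a$surface, ]
    samp <- data.frame(C0 = mm$C0, C45 = mm$C45, laterality = mm$laterality)
    if (report$config$mirror) samp <- mirror_left_eyes(samp)
    png(file.path(out_dir, sprintf("double_angle_%s.png", key)),
        width = 640, height = 640)
    plot_double_angle(samp, summary = list(branch = a$branch,
                                           location = a$location,
                                           region = a$region),
                      main = sprintf("%s, %s, ROI %g mm",
                                     a$surface, a$model, a$roi))
    dev.off()
    png(file.path(out_dir, sprintf("seq_raincloud_%s.png", key)),
        width = 640, height = 480)
    plot_raincloud(mm$SEQ, main = sprintf("SEQ: %s, %s, ROI %g mm",
                                          a$surface, a$model, a$roi),
                   xlab = "SEQ [D]")
    dev.off()
  }
  for (key in names(report$envelopes)) {
    parts <- strsplit(key, "_", fixed = TRUE)[[1L]]
    mm <- report$means[report$means$roi == as.numeric(parts[1L]) &
                         report$means$surface == parts[2L], ]
    png(file.path(out_dir, sprintf("axis_sd_envelope_%s.png", key)),
        width = 640, height = 480)
    plot_axis_envelope(mm$axis_sd, mm$dR, report$envelopes[[key]],
                       main = sprintf("Axis SD vs dR: %s, ROI %s mm",
                                      parts[2L], parts[1L]))
    dev.off()
  }
  invisible(NULL)
}
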