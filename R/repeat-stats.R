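## Aggregation of repeat-measurement triples and descriptive repeatability.

#' A triple of repeat results for one eye and surface
#'
#' Holds the three per-repeat fit results (surface parameters and power
#' vectors) for one eye, surface, model and ROI.
#'
#' @param repeats list of exactly 3 elements, each a list with `params`
#'   (a canonical [surface_params()]) and `pv` (a power vector as returned
#'   by [to_power_vector()]).
#' @param eye,surface optional identifying labels.
#' @param index_step refractive index step across the surface (used to
#'   re-derive mean radii from the mean power vector); inferred from the
#'   first repeat when omitted.
#' @return An object of class `repeat_triple`.
#' @export
repeat_triple <- function(repeats, eye = NA_character_,
                          surface = NA_character_, index_step = NULL) {
  if (!is.list(repeats) || length(repeats) != 3L)
    stop("a repeat triple holds exactly 3 repeat results")
  for (r in repeats) {
    if (!inherits(r$params, "surface_params"))
      stop("each repeat needs a 'params' surface_params entry")
    if (!all(c("SEQ", "C0", "C45") %in% names(unlist(r$pv))))
      stop("each repeat needs a 'pv' power vector entry")
  }
  models <- vapply(repeats, function(r) r$params$model, character(1))
  if (length(unique(models)) != 1L)
    stop("all repeats must use the same surface model")
  if (is.null(index_step)) {
    # The flat (larger-radius) meridian carries power dn/R1.  For dn > 0
    # that is the lower principal power, whose axis from_power_vector
    # reports at the geometric flat axis; for dn < 0 it is reported 90
    # degrees away.  The angular offset therefore identifies the branch.
    p1 <- repeats[[1L]]$params
    fp <- from_power_vector(repeats[[1L]]$pv)
    dth <- abs(((fp[["A1"]] - p1$A1 + 90) %% 180) - 90)
    index_step <- if (dth <= 45) fp[["F_flat"]] * p1$R1 / 1000
                  else fp[["F_steep"]] * p1$R1 / 1000
  }
  structure(list(repeats = repeats, eye = eye, surface = surface,
                 model = models[1L], index_step = index_step),
            class = "repeat_triple")
}

triple_components <- function(triple) {
  t(vapply(triple$repeats, function(r) {
    p <- r$params
    pv <- unlist(r$pv)
    c(R1 = p$R1, R2 = p$R2, A1 = p$A1, Q1 = p$Q1, Q2 = p$Q2,
      X0 = p$X0, Y0 = p$Y0, Z0 = p$Z0,
      SEQ = pv[["SEQ"]], C0 = pv[["C0"]], C45 = pv[["C45"]])
  }, numeric(11)))
}

#' Mean of three repeat results
#'
#' Averages component-wise in power-vector and asphericity space (SEQ, C0,
#' C45, Q1, Q2, apex position), which is well defined even when net
#' astigmatism and axis vary between repeats.  Mean radii and the mean flat
#' axis are then re-derived from the mean power vector via the surface's
#' index step (`radii = "power"`, the default), or taken as arithmetic
#' means of the per-repeat radii with a doubled-angle circular mean axis
#' (`radii = "arithmetic"`).
#'
#' @param triple a [repeat_triple()].
#' @param radii `"power"` or `"arithmetic"` (see Details).
#' @return A list with mean `SEQ`, `C0`, `C45`, `Q1`, `Q2`, `X0`, `Y0`,
#'   `Z0`, `R1`, `R2`, `A1` and the `radii` method used.
#' @export
mean_of_repeats <- function(triple, radii = c("power", "arithmetic")) {
  stopifnot(inherits(triple, "repeat_triple"))
  radii <- match.arg(radii)
  comp <- triple_components(triple)
  m <- colMeans(comp)
  pv_mean <- c(SEQ = m[["SEQ"]], C0 = m[["C0"]], C45 = m[["C45"]])
  if (radii == "power") {
    geo <- radii_from_power_vector(pv_mean, triple$index_step)
  } else {
    a2 <- comp[, "A1"] * 2 * pi / 180
    amean <- wrap_axis(atan2(mean(sin(a2)), mean(cos(a2))) * 90 / pi)
    geo <- c(R1 = m[["R1"]], R2 = m[["R2"]], A1 = amean)
  }
  list(model = triple$model, eye = triple$eye, surface = triple$surface,
       SEQ = m[["SEQ"]], C0 = m[["C0"]], C45 = m[["C45"]],
       Q1 = m[["Q1"]], Q2 = m[["Q2"]],
       X0 = m[["X0"]], Y0 = m[["Y0"]], Z0 = m[["Z0"]],
       R1 = geo[["R1"]], R2 = geo[["R2"]], A1 = geo[["A1"]],
       radii = radii)
}

#' Deviations of the three repeats from their mean
#'
#' Per component (radii, asphericities, apex, power vector) the deviation
#' `d_i = x_i - mean(x)`; the three deviations of every component sum to
#' zero exactly (up to floating point).  The periodic axis A1 is excluded
#' (linear deviations of a 180-degree-periodic quantity are not
#' meaningful; see [axis_sd()]).
#'
#' @param triple a [repeat_triple()].
#' @return A 3-row data frame of deviations with columns `R1`, `R2`, `Q1`,
#'   `Q2`, `X0`, `Y0`, `Z0`, `SEQ`, `C0`, `C45`.
#' @export
deviations_from_mean <- function(triple) {
  stopifnot(inherits(triple, "repeat_triple"))
  comp <- triple_components(triple)
  comp <- comp[, setdiff(colnames(comp), "A1"), drop = FALSE]
  as.data.frame(sweep(comp, 2L, colMeans(comp)))
}

#' Descriptive summary row: mean, SD, median, 2.5% and 97.5% quantiles
#'
#' The table row format used throughout the study reports: arithmetic
#' mean, sample SD (n - 1 denominator), median, and the empirical 2.5% and
#' 97.5% quantiles (linear interpolation of the empirical CDF, the default
#' quantile type) as the bounds of the 95% range.
#'
#' @param values numeric vector, length >= 2.
#' @return One-row data frame with columns `n`, `mean`, `sd`, `median`,
#'   `q2.5`, `q97.5`.
#' @export
descriptive_table <- function(values) {
  values <- as.numeric(values)
  values <- values[is.finite(values)]
  if (length(values) < 2L)
    stop("insufficient data: need at least 2 finite values")
  q <- unname(quantile(values, c(0.025, 0.975), type = 7))
  data.frame(n = length(values), mean = mean(values), sd = sd(values),
             median = median(values), q2.5 = q[1L], q97.5 = q[2L])
}

#' Standard deviation of axis angles on the doubled-angle circle
#'
#' Axes are 180-degree periodic, so an ordinary SD is meaningless near the
#' wrap.  Each axis `a` is mapped to the doubled angle `2a`, the circular
#' mean direction is taken, every doubled angle is unwrapped to its
#' nearest representative about that mean, and the ordinary sample SD of
#' the unwrapped values is halved.  Invariant under adding 180 degrees to
#' any input and equivariant under global rotation.
#'
#' If the doubled angles have (numerically) zero resultant length there is
#' no preferred axis; the returned value carries the attribute
#' `maximal_dispersion = TRUE`.
#'
#' @param axes numeric vector of axis angles in degrees.
#' @return SD in degrees (attribute `maximal_dispersion` flags a uniform
#'   axis triad).
#' @export
axis_sd <- function(axes) {
  axes <- as.numeric(axes)
  if (length(axes) < 2L) stop("need at least 2 axis values")
  d <- 2 * axes  # degrees on the doubled circle
  s <- mean(sin(d * pi / 180))
  cth <- mean(cos(d * pi / 180))
  maximal <- sqrt(s^2 + cth^2) < 1e-9
  mu <- if (maximal) 0 else atan2(s, cth) * 180 / pi
  unwrapped <- mu + ((d - mu + 180) %% 360) - 180
  out <- sd(unwrapped) / 2
  attr(out, "maximal_dispersion") <- maximal
  out
}

#' Envelope of axis repeatability versus astigmatic radius difference
#'
#' The axis of a nearly spherical surface is ill-defined, so the SD of the
#' fitted flat axis across repeats blows up as the radius difference
#' `dR = R1 - R2` of the mean fit approaches zero.  This fits that trend:
#' records are binned by `dR`, the root-mean-square of the axis SDs is
#' taken per bin, and a monotonically decreasing curve
#' `s(dR) = a / (dR + b) + c` (a >= 0) is least-squares fitted to the
#' binned RMS values.
#'
#' @param axis_sds per-record axis SDs in degrees (e.g. from [axis_sd()]
#'   over the three repeats, merged across surface models).
#' @param dR per-record radius differences `R1 - R2` in mm of the mean fit.
#' @param bin_width bin width in mm.
#' @return An object of class `axis_envelope`: coefficients `a`, `b`, `c`,
#'   the binned RMS table, and `fn(dR)` evaluating the fitted curve.
#' @export
axis_sd_vs_dR_envelope <- function(axis_sds, dR, bin_width = 0.05) {
  stopifnot(length(axis_sds) == length(dR), bin_width > 0)
  keep <- is.finite(axis_sds) & is.finite(dR)
  axis_sds <- axis_sds[keep]; dR <- dR[keep]
  if (length(dR) < 20L)
    stop("need at least 20 records to fit an envelope")
  breaks <- seq(0, max(dR) + bin_width, by = bin_width)
  bin <- cut(dR, breaks, include.lowest = TRUE)
  rms <- tapply(axis_sds, bin, function(v) sqrt(mean(v^2)))
  nbin <- tapply(axis_sds, bin, length)
  mids <- (breaks[-1L] + breaks[-length(breaks)]) / 2
  ok <- !is.na(rms)
  bins <- data.frame(mid = mids[ok], rms = as.numeric(rms[ok]),
                     n = as.integer(nbin[ok]))
  if (nrow(bins) < 3L)
    stop("degenerate binning (", nrow(bins),
         " non-empty bins); use wider bins")
  start <- c(a = max(bins$rms) * bin_width, b = bin_width, c = min(bins$rms))
  fitres <- nls.lm(par = start, lower = c(0, 1e-6, 0),
                   upper = c(Inf, Inf, Inf),
                   fn = function(p) bins$rms - (p[1] / (bins$mid + p[2]) + p[3]),
                   control = nls.lm.control(maxiter = 500))
  cf <- setNames(as.numeric(fitres$par), c("a", "b", "c"))
  structure(list(
    coefficients = cf, bins = bins, n = length(dR),
    fn = function(x) cf[["a"]] / (x + cf[["b"]]) + cf[["c"]]
  ), class = "axis_envelope")
}

#' @export
print.axis_envelope <- function(x, ...) {
  cat(sprintf(
    "Axis-SD envelope s(dR) = a/(dR + b) + c: a = %.4g, b = %.4g, c = %.4g (%d records, %d bins)\n",
    x$coefficients[["a"]], x$coefficients[["b"]], x$coefficients[["c"]],
    x$n, nrow(x$bins)))
  invisible(x)
}
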