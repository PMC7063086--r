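#' Attenuation profile container
#'
#' Ordered (distance, value) samples of a quantity measured along the main
#' axon (subthreshold voltage change, spike-area increase, overshoot
#' increase), with the source value at the origin.
#'
#' @param distance path distances (um), strictly increasing
#' @param value profile values (positive)
#' @param origin source value; defaults to the first sample
#' @param quantity label
#' @return data frame of class \code{attenuation_profile}
#' @export
attenuation_profile <- function(distance, value, origin = value[1], quantity = "") {
  if (length(distance) != length(value)) stop("distance/value length mismatch")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  if (!is.finite(origin) || origin <= 0) stop("origin value must be positive")
  structure(
    data.frame(distance = distance, value = value),
    origin = origin, quantity = quantity,
    class = c("attenuation_profile", "data.frame")
  )
}

#' Space constant by the 37 percent rule
#'
#' The distance at which the profile decays to 37 percent of its origin
#' value, linearly interpolated between the bracketing samples. Profiles
#' that do not decay monotonically (biphasic profiles, e.g. the spike-area
#' increase along a myelinated axon) are refused: no space constant is
#' reported for them. Profiles that never reach 37 percent within the
#' sampled extent are flagged instead of extrapolated.
#'
#' @param profile \code{\link{attenuation_profile}}
#' @param fraction decay fraction defining the constant (0.37)
#' @param rise_tol tolerated sample-to-sample rise, as a fraction of the
#'   origin value, before a profile is declared biphasic
#' @return list of class \code{space_constant}: \code{value} (um or NA),
#'   \code{status} ("ok", "biphasic", "no_crossing"), \code{threshold}
#' @export
space_constant <- function(profile, fraction = 0.37, rise_tol = 0.005) {
  d <- profile$distance
  v <- profile$value
  origin <- attr(profile, "origin")
  thr <- fraction * origin
  out <- function(value, status) {
    structure(list(value = value, status = status, threshold = thr,
                   origin = origin), class = "space_constant")
  }
  rises <- diff(v) > rise_tol * origin
  if (any(rises)) {
    return(out(NA_real_, "biphasic"))
  }
  below <- which(v < thr)
  if (!length(below)) {
    return(out(NA_real_, "no_crossing"))
  }
  i <- below[1]
  if (i == 1) {
    # already below at the first sample: crossing lies between origin and it
    lam <- d[1] * (origin - thr) / (origin - v[1])
    return(out(lam, "ok"))
  }
  lam <- d[i - 1] + (v[i - 1] - thr) * (d[i] - d[i - 1]) / (v[i - 1] - v[i])
  out(lam, "ok")
}

#' @export
print.space_constant <- function(x, ...) {
  if (x$status == "ok") {
    cat(sprintf("space constant: %.1f um (37%% threshold %.3g)\n", x$value, x$threshold))
  } else {
    cat("space constant not reported:", x$status, "\n")
  }
  invisible(x)
}

#' Facilitation at one site
#'
#' Conditioned EPSP as a percentage of the control EPSP.
#'
#' @param control,conditioned EPSP amplitudes (mV), control > 0
#' @return facilitation (percent; 100 = no change)
#' @export
adf_at_site <- function(control, conditioned) {
  if (any(control <= 0)) stop("control EPSP must be positive")
  100 * conditioned / control
}

#' Spatial extent of facilitation (105 percent crossing)
#'
#' Distance at which the facilitation curve, sampled at the first
#' presynaptic site of each collateral and ordered by distance, last crosses
#' downward through the level (105 percent by default), linearly
#' interpolated. A curve entirely at or above the level is flagged
#' unbounded; one entirely below gives 0.
#'
#' @param distance first-site distances (um), increasing
#' @param adf_pct facilitation values (percent)
#' @param level crossing level (percent)
#' @return list of class \code{adf_extent}: \code{value} (um; Inf when
#'   unbounded), \code{status} ("ok", "unbounded", "none")
#' @export
adf_spatial_extent <- function(distance, adf_pct, level = 105) {
  if (length(distance) < 2) stop("need at least two collateral first sites")
  if (any(diff(distance) <= 0)) stop("distances must be strictly increasing")
  if (all(adf_pct < level)) {
    return(structure(list(value = 0, status = "none", level = level),
                     class = "adf_extent"))
  }
  if (adf_pct[length(adf_pct)] >= level) {
    return(structure(list(value = Inf, status = "unbounded", level = level),
                     class = "adf_extent"))
  }
  dn <- which(adf_pct[-length(adf_pct)] >= level & adf_pct[-1] < level)
  i <- dn[length(dn)]
  x <- distance[i] + (adf_pct[i] - level) * (distance[i + 1] - distance[i]) /
    (adf_pct[i] - adf_pct[i + 1])
  structure(list(value = x, status = "ok", level = level), class = "adf_extent")
}

#' Fraction of presynaptic sites above a facilitation threshold
#'
#' @param adf_pct per-site facilitation (percent), all evaluated sites
#' @param distance per-site path distances (um)
#' @param threshold minimum facilitation above control, percent (5 means
#'   sites at >= 105 percent qualify)
#' @return list: \code{fraction_pct}, \code{mean_dist}, \code{sd_dist},
#'   \code{n_sites}, \code{n_qualifying}
#' @export
site_fraction_ge <- function(adf_pct, distance, threshold = 5) {
  if (!length(adf_pct)) stop("empty site set")
  q <- adf_pct >= 100 + threshold
  list(
    fraction_pct = 100 * mean(q),
    mean_dist = if (any(q)) mean(distance[q]) else NA_real_,
    sd_dist = if (sum(q) > 1) stats::sd(distance[q]) else NA_real_,
    n_sites = length(adf_pct),
    n_qualifying = sum(q)
  )
}

#' Fit the space-constant vs wrap-number curve
#'
#' Least-squares fit of sp(N) = a + b (1 - exp(-c N)) to space constants
#' measured at several myelin wrap counts.
#'
#' @param n_wraps wrap counts (must include 0; at least 4 points)
#' @param sp space constants (um)
#' @return list of class \code{wraps_curve_fit}: coefficients \code{a},
#'   \code{b}, \code{c}, fitted values, residuals and the nls object
#' @export
fit_wraps_curve <- function(n_wraps, sp) {
  if (length(n_wraps) < 4 || !any(n_wraps == 0)) {
    stop("need >= 4 (N, sp) points including N = 0")
  }
  df <- data.frame(N = n_wraps, sp = sp)
  fit <- minpack.lm::nlsLM(
    sp ~ a + b * (1 - exp(-cc * N)),
    data = df,
    start = list(a = min(sp), b = diff(range(sp)), cc = 0.2),
    control = minpack.lm::nls.lm.control(maxiter = 200)
  )
  co <- stats::coef(fit)
  if (co[["b"]] <= 0 || co[["cc"]] <= 0) {
    warning("fitted curve is not increasing in N (b or c <= 0)")
  }
  structure(
    list(
      a = co[["a"]], b = co[["b"]], c = co[["cc"]],
      fitted = stats::fitted(fit), residuals = stats::residuals(fit),
      fit = fit
    ),
    class = "wraps_curve_fit"
  )
}

#' @export
print.wraps_curve_fit <- function(x, ...) {
  cat(sprintf(
    "sp(N) = %.2f + %.2f * (1 - exp(-%.3f N)); RMS residual %.2f um\n",
    x$a, x$b, x$c, sqrt(mean(x$residuals^2))
  ))
  invisible(x)
}
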