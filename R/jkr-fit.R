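#' JKR indentation depth as a function of load
#'
#' The depth-load relation of the Johnson-Kendall-Roberts adhesive contact
#' model, as used throughout this package:
#' \deqn{h_t - h_0 = \frac{a_0^2}{R} m^{4/3} - \frac{2}{3}\frac{a_0^2}{R} m^{1/3},
#'       \quad m = \frac{1 + \sqrt{1 - P/P_{adh}}}{2},}
#' where \eqn{a_0} is the contact radius at zero load, \eqn{R} the tip radius,
#' \eqn{P_{adh} \le 0} the pull-off force and \eqn{h_0} the contact point.
#' At `P = 0` the depth is `a0^2/(3R)`; at `P = P_adh` it is
#' `-0.13228 a0^2/R`.
#'
#' @param P Load (N); must satisfy `P >= P_adh`.
#' @param a0 Zero-load contact radius (m).
#' @param R Tip radius (m).
#' @param P_adh Pull-off force (N, negative).
#' @param h0 Contact point offset (m).
#' @return Indentation depth `h_t` (m).
#' @export
jkr_depth <- function(P, a0, R, P_adh, h0 = 0) {
  if (P_adh >= 0) stop("P_adh must be negative (adhesive contact)")
  arg <- 1 - P / P_adh
  if (any(arg < -1e-9)) stop("loads below the pull-off force are unphysical")
  arg[arg < 0] <- 0
  m <- (1 + sqrt(arg)) / 2
  h0 + (a0^2 / R) * m^(4 / 3) - (2 / 3) * (a0^2 / R) * m^(1 / 3)
}

# basis function multiplying a0^2/R in the depth-load relation
.jkr_g <- function(P, P_adh) {
  arg <- pmax(1 - P / P_adh, 0)
  m <- (1 + sqrt(arg)) / 2
  m^(4 / 3) - (2 / 3) * m^(1 / 3)
}

#' Detect the pull-off force on a retract segment
#'
#' Returns the most negative force on the retract segment (sign convention:
#' adhesion is negative).  If no negative force occurs, the pull-off force is
#' reported as 0 with `no_adhesion = TRUE`.  Optional Savitzky-Golay smoothing
#' (requires the `signal` package) can be applied before taking the minimum to
#' reduce the low-bias of the minimum statistic under noise.
#'
#' @param x A `force_separation` object (its retract segment is used) or a
#'   data frame with a `force` column.
#' @param smooth Logical; smooth forces before locating the minimum
#'   (default `FALSE`).
#' @param window Odd smoothing window length (points) when `smooth = TRUE`.
#' @return List with `P_adh` (N, `<= 0`), `no_adhesion` flag and `index` of
#'   the minimum.
#' @export
detect_pull_off <- function(x, smooth = FALSE, window = 11L) {
  retract <- if (inherits(x, "force_separation")) x$retract else x
  if (!is.data.frame(retract) || !"force" %in% names(retract) ||
      nrow(retract) == 0)
    stop("retract segment must be a non-empty data frame with a `force` column")
  f <- retract$force
  if (smooth) {
    if (!requireNamespace("signal", quietly = TRUE))
      stop("smoothing requires the `signal` package")
    window <- min(window, nrow(retract) - (1 - nrow(retract) %% 2))
    if (window >= 5) f <- signal::sgolayfilt(f, p = 2, n = window)
  }
  i <- which.min(f)
  if (f[i] >= 0)
    return(list(P_adh = 0, no_adhesion = TRUE, index = i))
  list(P_adh = f[i], no_adhesion = FALSE, index = i)
}

#' Work of adhesion from the pull-off force
#'
#' Inverts the JKR pull-off relation \eqn{P_{adh} = -\frac{3}{2}\pi \Delta r R}
#' to recover the interfacial work of adhesion
#' \eqn{\Delta r = -2 P_{adh} / (3 \pi R)} (units N/m).
#'
#' @param P_adh Pull-off force (N, `<= 0`).
#' @param R Tip radius (m, `> 0`).
#' @return Work of adhesion (N/m, `>= 0`).
#' @export
#' @examples
#' delta_r_from_pull_off(-3.18e-7, 20e-9)  # ~3.37 N/m
delta_r_from_pull_off <- function(P_adh, R) {
  if (!is.numeric(R) || any(R <= 0)) stop("R must be positive")
  if (any(P_adh > 0))
    stop("P_adh must be <= 0 (adhesion is negative by convention)")
  -2 * P_adh / (3 * pi * R)
}

#' Fit the JKR model to a retract segment
#'
#' Fits the depth-load relation (see [jkr_depth()]) to calibrated retract data
#' by least squares over `(a0, h0)` and converts the zero-load contact radius
#' into Young's modulus via \eqn{E_{JKR} = 9 \pi R^2 \Delta r / (2 a_0^3)}.
#' By default this is a two-stage fit: the pull-off force is detected first,
#' the work of adhesion is fixed from it through the pull-off relation, and
#' only `(a0, h0)` are then estimated.  With the pull-off force fixed the
#' model is linear in `(h0, a0^2/R)`, so the least-squares problem is solved
#' exactly (no iteration; `converged` reports whether the solution maps back
#' to a physical `a0 > 0`).  With `co_estimate = TRUE` the pull-off force is
#' instead co-estimated by a one-dimensional search wrapped around the same
#' exact solve.
#'
#' @param x A [force_curve()] (converted internally via
#'   [to_force_separation()]), a `force_separation` object, or a data frame
#'   with columns `separation` (m) and `force` (N) holding the calibrated
#'   retract segment restricted to the contact region.
#' @param R Tip radius (m); taken from `x` when available.
#' @param P_adh Pull-off force (N, negative).  Detected with
#'   [detect_pull_off()] when `NULL`.
#' @param co_estimate Logical; co-estimate the pull-off force instead of
#'   fixing it from the detected minimum.
#' @param min_points Minimum number of usable points; the fit is refused below
#'   this (default 5).
#' @param ... Passed to [detect_pull_off()].
#' @return An object of class `jkr_fit` with elements `E_jkr` (Pa),
#'   `delta_r` (N/m), `P_adh` (N), `a0` (m), `h0` (m), `h_t_max` (m), `rss`,
#'   `n_fit_points`, `converged`, plus the fitting data and calibration.
#' @seealso [coef.jkr_fit()], [predict.jkr_fit()], [simulate.jkr_fit()]
#' @export
#' @examples
#' cfg <- jkr_sim_config(E = 41.6e6, delta_r = 3.37)
#' fit <- fit_jkr(simulate_jkr_curve(cfg))
#' coef(fit)["E_jkr"] / 1e6  # MPa, recovers 41.6
fit_jkr <- function(x, R = NULL, P_adh = NULL, co_estimate = FALSE,
                    min_points = 5L, ...) {
  fs <- NULL
  if (inherits(x, "force_curve")) fs <- to_force_separation(x)
  else if (inherits(x, "force_separation")) fs <- x
  if (!is.null(fs)) {
    retract <- fs$retract
    if (is.null(R)) R <- fs$R
  } else {
    retract <- x
  }
  if (is.null(R) || !is.finite(R) || R <= 0)
    stop("tip radius `R` must be supplied (positive, in metres)")
  if (!is.data.frame(retract) ||
      !all(c("separation", "force") %in% names(retract)))
    stop("retract data must have columns `separation` and `force`")
  if (is.null(P_adh)) {
    po <- detect_pull_off(retract, ...)
    if (po$no_adhesion)
      stop("no adhesion detected on the retract segment; ",
           "the JKR fit requires a negative pull-off force")
    P_adh <- po$P_adh
  }
  if (P_adh >= 0) stop("P_adh must be negative")

  solve_lin <- function(Pa) {
    use <- retract$force >= Pa - abs(Pa) * 1e-9
    P <- retract$force[use]
    h <- -retract$separation[use]
    if (length(P) < min_points)
      return(list(ok = FALSE, n = length(P)))
    g <- .jkr_g(P, Pa)
    ft <- stats::lm.fit(cbind(1, g), h)
    list(ok = TRUE, h0 = ft$coefficients[[1]], B = ft$coefficients[[2]],
         rss = sum(ft$residuals^2), n = length(P), P = P, h = h,
         fitted = ft$fitted.values)
  }

  if (co_estimate) {
    # objective clips (rather than drops) loads below the trial pull-off so
    # the RSS is continuous in P_adh and its minimum interior to the bracket
    f_min <- min(retract$force)
    rss_of <- function(Pa) {
      h <- -retract$separation
      g <- .jkr_g(retract$force, Pa)
      ft <- stats::lm.fit(cbind(1, g), h)
      if (ft$coefficients[[2]] <= 0) return(Inf)
      sum(ft$residuals^2)
    }
    opt <- stats::optimize(rss_of, interval = c(1.5 * f_min, 0.5 * f_min),
                           tol = abs(f_min) * 1e-9)
    P_adh <- opt$minimum
  }
  sol <- solve_lin(P_adh)
  if (!sol$ok)
    stop("fit refused: only ", sol$n, " usable point(s), need >= ", min_points)
  delta_r <- delta_r_from_pull_off(P_adh, R)
  converged <- is.finite(sol$B) && sol$B > 0
  a0 <- if (converged) sqrt(sol$B * R) else NA_real_
  E <- if (converged) 9 * pi * R^2 * delta_r / (2 * a0^3) else NA_real_
  structure(list(
    E_jkr = E, delta_r = delta_r, P_adh = P_adh, a0 = a0, h0 = sol$h0,
    h_t_max = max(sol$h) - sol$h0, rss = sol$rss, n_fit_points = sol$n,
    converged = converged, co_estimated = isTRUE(co_estimate), R = R,
    data = data.frame(load = sol$P, depth = sol$h),
    fitted_depth = sol$fitted,
    calibration = if (!is.null(fs)) list(k = fs$k) else NULL
  ), class = "jkr_fit")
}

#' @export
print.jkr_fit <- function(x, ...) {
  cat("JKR contact-mechanics fit\n")
  if (x$converged)
    cat(sprintf("  E_JKR = %.4g MPa,  delta_r = %.4g N/m\n",
                x$E_jkr / 1e6, x$delta_r))
  else cat("  <not converged>\n")
  cat(sprintf("  P_adh = %.4g nN, a0 = %.4g nm, h0 = %.4g nm  (%d points, rss = %.3g)\n",
              x$P_adh * 1e9, x$a0 * 1e9, x$h0 * 1e9, x$n_fit_points, x$rss))
  invisible(x)
}

#' @export
coef.jkr_fit <- function(object, ...) {
  c(E_jkr = object$E_jkr, delta_r = object$delta_r, P_adh = object$P_adh,
    a0 = object$a0, h0 = object$h0)
}

#' @export
summary.jkr_fit <- function(object, ...) {
  structure(list(fit = object), class = "summary.jkr_fit")
}

#' @export
print.summary.jkr_fit <- function(x, ...) {
  f <- x$fit
  print(f)
  res <- f$data$depth - f$fitted_depth
  cat(sprintf("  depth residuals (nm): min %.3g / median %.3g / max %.3g\n",
              min(res) * 1e9, stats::median(res) * 1e9, max(res) * 1e9))
  cat(sprintf("  max depth %.4g nm, tip radius %g nm%s\n",
              f$h_t_max * 1e9, f$R * 1e9,
              if (f$co_estimated) ", pull-off co-estimated" else ""))
  invisible(x)
}

#' Predicted indentation depth at given loads
#'
#' @param object A `jkr_fit`.
#' @param newdata Data frame with a `load` column (N); defaults to the loads
#'   used in the fit.
#' @param ... Unused.
#' @return Predicted depths (m).
#' @export
predict.jkr_fit <- function(object, newdata = NULL, ...) {
  if (!object$converged) stop("cannot predict from a non-converged fit")
  P <- if (is.null(newdata)) object$data$load else newdata$load
  jkr_depth(P, object$a0, object$R, object$P_adh, object$h0)
}

#' @export
fitted.jkr_fit <- function(object, ...) object$fitted_depth

#' @export
residuals.jkr_fit <- function(object, ...)
  object$data$depth - object$fitted_depth

#' @export
plot.jkr_fit <- function(x, ...) {
  graphics::plot(x$data$depth * 1e9, x$data$load * 1e9,
                 xlab = "indentation depth (nm)", ylab = "load (nN)",
                 main = "JKR fit", ...)
  if (x$converged) {
    P <- seq(x$P_adh, max(x$data$load), length.out = 200)
    graphics::lines(jkr_depth(P, x$a0, x$R, x$P_adh, x$h0) * 1e9, P * 1e9,
                    col = "firebrick")
  }
  invisible(x)
}

#' Simulate force curves from a fitted JKR model
#'
#' Generates synthetic approach/retract pairs parameterized by the fitted
#' `(E_jkr, delta_r)`, closing the generator/analyzer loop.
#'
#' @param object A converged `jkr_fit`.
#' @param nsim Number of curves.
#' @param seed Optional seed.
#' @param ... Overrides passed to [jkr_sim_config()] (e.g. `noise_sd`, `k`).
#' @return List of [force_curve()] objects.
#' @export
simulate.jkr_fit <- function(object, nsim = 1, seed = NULL, ...) {
  if (!object$converged) stop("cannot simulate from a non-converged fit")
  dots <- list(...)
  args <- list(E = object$E_jkr, delta_r = object$delta_r, R = object$R)
  if (!is.null(object$calibration$k) && is.null(dots$k))
    args$k <- object$calibration$k
  args[names(dots)] <- dots
  if (!is.null(seed)) set.seed(seed)
  lapply(seq_len(nsim), function(i) {
    simulate_jkr_curve(do.call(jkr_sim_config, args))
  })
}

#' Hysteresis work of adhesion of an approach/retract pair
#'
#' Computes the area enclosed between the approach and retract force curves by
#' trapezoidal integration on the union depth grid (linear interpolation of
#' each segment), and normalizes it by the probe-sample contact area
#' \eqn{a_0 = \pi R h_t} with \eqn{h_t} the maximum indentation depth of the
#' pair, giving a work of adhesion in N/m (J/m^2).
#'
#' @param x A `force_separation` object, or an approach data frame (columns
#'   `separation`, `force`) when `retract` is supplied separately.
#' @param retract Optional retract data frame (same columns).
#' @param R Tip radius (m); taken from `x` when available.
#' @param h_t_max Indentation depth used for the contact-area normalization
#'   (m); defaults to the maximum depth of the pair relative to `h0`.
#' @param h0 Contact-point offset subtracted before computing depths
#'   (default 0).
#' @return An object of class `adhesion_result`: list with `hysteresis_area`
#'   (J), `contact_area` (m^2), `W` (N/m) and `h_t_max` (m).
#' @export
work_of_adhesion <- function(x, retract = NULL, R = NULL, h_t_max = NULL,
                             h0 = 0) {
  if (inherits(x, "force_separation")) {
    approach <- x$approach; retract <- x$retract
    if (is.null(R)) R <- x$R
  } else approach <- x
  if (is.null(R) || !is.finite(R) || R <= 0)
    stop("tip radius `R` must be supplied (positive, in metres)")
  for (seg in list(approach, retract))
    if (!is.data.frame(seg) ||
        !all(c("separation", "force") %in% names(seg)))
      stop("segments must have columns `separation` and `force`")
  ha <- -approach$separation - h0
  hr <- -retract$separation - h0
  lo <- max(min(ha), min(hr)); hi <- min(max(ha), max(hr))
  if (!(hi > lo))
    stop("approach and retract segments do not overlap in separation")
  grid <- sort(unique(c(ha[ha >= lo & ha <= hi], hr[hr >= lo & hr <= hi],
                        lo, hi)))
  fa <- stats::approx(ha, approach$force, xout = grid, ties = mean)$y
  fr <- stats::approx(hr, retract$force, xout = grid, ties = mean)$y
  d <- fa - fr
  area <- abs(sum(diff(grid) * (d[-1] + d[-length(d)]) / 2))
  if (is.null(h_t_max)) h_t_max <- max(c(ha, hr))
  if (!is.finite(h_t_max) || h_t_max <= 0)
    stop("h_t_max must be positive; check the contact-point offset")
  contact_area <- pi * R * h_t_max
  structure(list(hysteresis_area = area, contact_area = contact_area,
                 W = area / contact_area, h_t_max = h_t_max),
            class = "adhesion_result")
}

#' @export
print.adhesion_result <- function(x, ...) {
  cat(sprintf(
    "work of adhesion: W = %.4g N/m  (area %.4g J over %.4g m^2, h_t = %.4g nm)\n",
    x$W, x$hysteresis_area, x$contact_area, x$h_t_max * 1e9))
  invisible(x)
}

#' Summarize per-curve measurements for one sample
#'
#' Mean, sample standard deviation (n-1 denominator) and standard error
#' (SD/sqrt(n)) of a set of per-curve measurements.
#'
#' @param values Numeric vector, `length >= 2`.
#' @return Object of class `sample_summary`: list with `values`, `mean`,
#'   `sd`, `se`, `n`.
#' @export
#' @examples
#' sample_summary(c(1, 2, 3))$se  # 1/sqrt(3)
sample_summary <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2 || any(!is.finite(values)))
    stop("need at least two finite measurements")
  n <- length(values)
  s <- stats::sd(values)
  structure(list(values = values, mean = mean(values), sd = s,
                 se = s / sqrt(n), n = n),
            class = "sample_summary")
}

#' @export
print.sample_summary <- function(x, ...) {
  cat(sprintf("n = %d: mean = %.4g +/- %.3g (SE; SD = %.4g)\n",
              x$n, x$mean, x$se, x$sd))
  invisible(x)
}
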