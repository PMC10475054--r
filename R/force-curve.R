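#' Construct an AFM force curve in instrument units
#'
#' A force curve is one approach/retract indentation pair recorded in
#' instrument units (piezo position in metres, cantilever deflection in volts
#' or metres) together with the calibration metadata needed to convert it to
#' force vs tip-sample separation: the cantilever spring constant `k`, the
#' deflection sensitivity `defl_sens`, and the tip radius `R`.
#'
#' @param approach,retract Data frames with columns `piezo_position` (m) and
#'   `deflection` (V or m, see `deflection_unit`).
#' @param k Spring constant (N/m).
#' @param defl_sens Deflection sensitivity (m/V); ignored when deflection is
#'   already in metres.
#' @param R Tip radius (m).
#' @param deflection_unit `"V"` or `"m"`.
#' @return An object of class `force_curve`.
#' @export
force_curve <- function(approach, retract, k, defl_sens = NA_real_, R,
                        deflection_unit = c("V", "m")) {
  deflection_unit <- match.arg(deflection_unit)
  for (nm in c("k", "R")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1 || !is.finite(v) || v <= 0)
      stop("calibration field `", nm, "` must be a positive number")
  }
  if (deflection_unit == "V" &&
      (!is.numeric(defl_sens) || !is.finite(defl_sens) || defl_sens <= 0))
    stop("calibration field `defl_sens` must be a positive number when ",
         "deflection is recorded in volts")
  chk <- function(seg, what) {
    if (!is.data.frame(seg) ||
        !all(c("piezo_position", "deflection") %in% names(seg)))
      stop("`", what, "` must have columns piezo_position and deflection")
    seg[, c("piezo_position", "deflection")]
  }
  structure(
    list(approach = chk(approach, "approach"),
         retract = chk(retract, "retract"),
         k = k, defl_sens = defl_sens, R = R,
         deflection_unit = deflection_unit),
    class = "force_curve"
  )
}

#' @export
print.force_curve <- function(x, ...) {
  cat(sprintf(
    "AFM force curve: %d approach + %d retract points\n  k = %g N/m, sensitivity = %s, R = %g nm, deflection in %s\n",
    nrow(x$approach), nrow(x$retract), x$k,
    if (is.na(x$defl_sens)) "NA" else sprintf("%g nm/V", x$defl_sens * 1e9),
    x$R * 1e9, x$deflection_unit))
  invisible(x)
}

#' Convert a force curve to calibrated force vs tip-sample separation
#'
#' Applies the standard AFM conversion: force `F = k * defl_sens * deflection`
#' (volts) or `F = k * deflection` (metres); tip-sample separation
#' `s = piezo_position - F/k` (piezo travel corrected for cantilever bending).
#' The non-contact baseline force -- the mean force over the fraction
#' `baseline_frac` of approach points at largest separation -- is subtracted
#' from both segments.  (The retract segment of an indentation typically has
#' no non-contact region of its own, so the approach-derived baseline is used
#' for both.)
#'
#' @param curve A [force_curve()].
#' @param baseline_frac Fraction of approach points (taken at largest
#'   separation) used to estimate the baseline; default 0.1.
#' @return An object of class `force_separation`: list with data frames
#'   `approach` and `retract` (columns `separation` (m), `force` (N)), the tip
#'   radius `R`, spring constant `k`, and the subtracted `baseline` (N).
#' @export
#' @examples
#' cfg <- jkr_sim_config(E = 41.6e6, delta_r = 3.37)
#' fs <- to_force_separation(simulate_jkr_curve(cfg))
#' range(fs$retract$force)
to_force_separation <- function(curve, baseline_frac = 0.1) {
  if (!inherits(curve, "force_curve"))
    stop("`curve` must be a force_curve object")
  conv <- function(seg) {
    F_raw <- if (curve$deflection_unit == "V")
      curve$k * curve$defl_sens * seg$deflection
    else curve$k * seg$deflection
    s_raw <- seg$piezo_position - F_raw / curve$k
    data.frame(separation = s_raw, force = F_raw)
  }
  app <- conv(curve$approach)
  ret <- conv(curve$retract)
  n_base <- max(1L, ceiling(baseline_frac * nrow(app)))
  baseline <- mean(app$force[order(app$separation,
                                   decreasing = TRUE)][seq_len(n_base)])
  app$force <- app$force - baseline
  ret$force <- ret$force - baseline
  structure(list(approach = app, retract = ret, R = curve$R, k = curve$k,
                 baseline = baseline),
            class = "force_separation")
}

#' Write / read force curves as delimited text
#'
#' The on-disk format is a TSV with a `# key: value` header block carrying the
#' calibration (spring constant, deflection sensitivity, tip radius,
#' deflection unit) followed by the columns `segment` (approach/retract),
#' `piezo_position_nm` and `deflection_V` (or `deflection_nm`).
#'
#' @param curve A [force_curve()].
#' @param path File path.
#' @return `write_force_curve()` returns `path` invisibly;
#'   `read_force_curve()` returns a [force_curve()].
#' @export
write_force_curve <- function(curve, path) {
  stopifnot(inherits(curve, "force_curve"))
  defl_col <- if (curve$deflection_unit == "V") "deflection_V" else "deflection_nm"
  hdr <- c(
    sprintf("# spring_constant_n_per_m: %.10g", curve$k),
    sprintf("# defl_sens_nm_per_v: %.10g",
            if (is.na(curve$defl_sens)) NA else curve$defl_sens * 1e9),
    sprintf("# radius_nm: %.10g", curve$R * 1e9),
    sprintf("# deflection_unit: %s", curve$deflection_unit)
  )
  fmt <- function(seg, label) {
    defl <- if (curve$deflection_unit == "V") seg$deflection else seg$deflection * 1e9
    sprintf("%s\t%.12e\t%.12e", label, seg$piezo_position * 1e9, defl)
  }
  writeLines(c(hdr, paste("segment", "piezo_position_nm", defl_col, sep = "\t"),
               fmt(curve$approach, "approach"), fmt(curve$retract, "retract")),
             path)
  invisible(path)
}

#' @rdname write_force_curve
#' @param k,defl_sens,R Calibration overrides for files lacking a header
#'   (permissive two-column instrument exports): spring constant (N/m),
#'   deflection sensitivity (m/V), tip radius (m).
#' @export
read_force_curve <- function(path, k = NULL, defl_sens = NULL, R = NULL) {
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- trimws(sub(":.*$", "", kv))
    val <- trimws(sub("^[^:]*:", "", kv))
    meta[[key]] <- val
  }
  num <- function(key) if (!is.null(meta[[key]])) as.numeric(meta[[key]]) else NA_real_
  k2 <- if (!is.null(k)) k else num("spring_constant_n_per_m")
  sens2 <- if (!is.null(defl_sens)) defl_sens else num("defl_sens_nm_per_v") * 1e-9
  R2 <- if (!is.null(R)) R else num("radius_nm") * 1e-9
  unit <- if (!is.null(meta$deflection_unit)) meta$deflection_unit else "V"
  body <- lines[!grepl("^#", lines)]
  tab <- utils::read.table(text = body, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  if (!"segment" %in% names(tab)) tab$segment <- "retract"
  defl_col <- intersect(c("deflection_V", "deflection_nm"), names(tab))
  if (length(defl_col) != 1 || !"piezo_position_nm" %in% names(tab))
    stop("unrecognized force-curve file layout in ", path)
  defl <- if (defl_col == "deflection_V") tab[[defl_col]] else tab[[defl_col]] * 1e-9
  seg <- function(lbl) data.frame(
    piezo_position = tab$piezo_position_nm[tab$segment == lbl] * 1e-9,
    deflection = defl[tab$segment == lbl])
  force_curve(seg("approach"), seg("retract"), k = k2, defl_sens = sens2,
              R = R2,
              deflection_unit = if (defl_col == "deflection_V") "V" else "m")
}

#' @export
plot.force_curve <- function(x, ...) {
  fs <- to_force_separation(x)
  plot(fs, ...)
}

#' @export
plot.force_separation <- function(x, xlab = "separation (nm)",
                                  ylab = "force (nN)", main = "force curve",
                                  ...) {
  xs <- rbind(x$approach, x$retract)
  graphics::plot(xs$separation * 1e9, xs$force * 1e9, type = "n",
                 xlab = xlab, ylab = ylab, main = main, ...)
  graphics::lines(x$approach$separation * 1e9, x$approach$force * 1e9,
                  col = "steelblue")
  graphics::lines(x$retract$separation * 1e9, x$retract$force * 1e9,
                  col = "firebrick")
  graphics::legend("topright", c("approach", "retract"), lty = 1,
                   col = c("steelblue", "firebrick"), bty = "n")
  invisible(x)
}
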