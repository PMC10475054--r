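#' Configuration for the synthetic JKR force-curve generator
#'
#' Defaults reflect the instrument used for the snail-mucus indentation study:
#' tip radius 20 nm, spring constant 0.139 N/m, deflection sensitivity
#' 40.7 nm/V.
#'
#' @param E True Young's modulus (Pa, `> 0`).
#' @param delta_r True interfacial work of adhesion (N/m, `>= 0`).
#' @param R Tip radius (m).
#' @param k Cantilever spring constant (N/m).
#' @param defl_sens Deflection sensitivity (m/V).
#' @param n_points Samples per segment (`>= 20`).
#' @param noise_sd Standard deviation of additive Gaussian force noise (N),
#'   applied after ideal-curve generation.
#' @param p_max Maximum load (N); default `p_max_factor * |P_adh|`, or, for an
#'   adhesionless configuration, the Hertzian load at depth `R/2`.
#' @param p_max_factor Multiple of `|P_adh|` used when `p_max` is `NULL`.
#' @param h0 True contact point (m).
#' @param seed Optional integer seed.
#' @return A validated list of class `jkr_sim_config`.
#' @export
jkr_sim_config <- function(E, delta_r, R = 20e-9, k = 0.139,
                           defl_sens = 40.7e-9, n_points = 200L,
                           noise_sd = 0, p_max = NULL, p_max_factor = 5,
                           h0 = 0, seed = NULL) {
  if (!is.numeric(E) || E <= 0) stop("E must be positive (non-physical config)")
  if (!is.numeric(delta_r) || delta_r < 0) stop("delta_r must be >= 0")
  if (R <= 0 || k <= 0 || defl_sens <= 0) stop("R, k and defl_sens must be positive")
  if (n_points < 20) stop("n_points must be >= 20")
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  structure(list(E = E, delta_r = delta_r, R = R, k = k,
                 defl_sens = defl_sens, n_points = as.integer(n_points),
                 noise_sd = noise_sd, p_max = p_max,
                 p_max_factor = p_max_factor, h0 = h0, seed = seed),
            class = "jkr_sim_config")
}

#' Simulate an ideal JKR approach/retract force curve
#'
#' Runs the JKR model generatively: the zero-load contact radius is obtained
#' by inverting \eqn{E = 9\pi R^2 \Delta r/(2 a_0^3)}, the pull-off force from
#' \eqn{P_{adh} = -\frac{3}{2}\pi\Delta r R}, loads are sampled uniformly on
#' `[P_adh, p_max]`, depths evaluated with [jkr_depth()], and forces converted
#' to instrument units (piezo position, deflection in volts) with the spring
#' constant and deflection sensitivity, so that the analysis stage must
#' perform the full conversion.  The approach is generated from the same
#' single-valued JKR branch restricted to loads `P >= 0`, preceded by a flat
#' non-contact baseline; the retract terminates at the pull-off force.  With
#' `delta_r = 0` the relation degenerates (`a0 = 0`) and the generator uses
#' the adhesionless Hertzian law `P = (4/3) E sqrt(R) h^(3/2)`, so approach
#' and retract coincide (zero hysteresis, zero pull-off).
#'
#' @param cfg A [jkr_sim_config()].
#' @return A [force_curve()]; the true parameters are attached as attribute
#'   `truth` (list with `E`, `delta_r`, `a0`, `P_adh`, `h0`, `force`).
#' @export
#' @examples
#' curve <- simulate_jkr_curve(jkr_sim_config(E = 41.6e6, delta_r = 3.37))
#' attr(curve, "truth")$P_adh  # -(3/2) * pi * 3.37 * 20e-9
simulate_jkr_curve <- function(cfg) {
  stopifnot(inherits(cfg, "jkr_sim_config"))
  if (!is.null(cfg$seed)) set.seed(cfg$seed)
  n <- cfg$n_points
  R <- cfg$R

  if (cfg$delta_r > 0) {
    a0 <- (9 * pi * R^2 * cfg$delta_r / (2 * cfg$E))^(1 / 3)
    P_adh <- -1.5 * pi * cfg$delta_r * R
    p_max <- if (!is.null(cfg$p_max)) cfg$p_max else cfg$p_max_factor * abs(P_adh)
    depth <- function(P) jkr_depth(P, a0, R, P_adh, cfg$h0)
    P_ret <- seq(p_max, P_adh, length.out = n)
    P_app <- seq(0, p_max, length.out = n)
    h_contact0 <- depth(0)           # approach contact begins at zero load
  } else {
    a0 <- 0
    P_adh <- 0
    p_max <- if (!is.null(cfg$p_max)) cfg$p_max else
      (4 / 3) * cfg$E * sqrt(R) * (R / 2)^1.5
    depth <- function(P) cfg$h0 + (3 * P / (4 * cfg$E * sqrt(R)))^(2 / 3)
    P_ret <- seq(p_max, 0, length.out = n)
    P_app <- seq(0, p_max, length.out = n)
    h_contact0 <- depth(0)
  }

  h_max <- depth(p_max)
  span <- max(h_max - cfg$h0, abs(a0^2 / R), 1e-9)   # baseline extent
  n_base <- max(10L, ceiling(0.25 * n))
  # separation coordinate: s = -depth; baseline at zero force
  s_base <- seq(-h_contact0 + span, -h_contact0, length.out = n_base + 1)[1:n_base]

  F_app <- c(rep(0, n_base), P_app)
  s_app <- c(s_base, -depth(P_app))
  F_ret <- P_ret
  s_ret <- -depth(P_ret)

  noisy <- function(f) if (cfg$noise_sd > 0)
    f + stats::rnorm(length(f), sd = cfg$noise_sd) else f
  F_app_n <- noisy(F_app)
  F_ret_n <- noisy(F_ret)

  # piezo = separation + ideal cantilever bending; measured deflection noisy
  seg <- function(s, F_ideal, F_meas) data.frame(
    piezo_position = s + F_ideal / cfg$k,
    deflection = F_meas / (cfg$k * cfg$defl_sens))
  curve <- force_curve(seg(s_app, F_app, F_app_n),
                       seg(s_ret, F_ret, F_ret_n),
                       k = cfg$k, defl_sens = cfg$defl_sens, R = R,
                       deflection_unit = "V")
  attr(curve, "truth") <- list(E = cfg$E, delta_r = cfg$delta_r, a0 = a0,
                               P_adh = P_adh, h0 = cfg$h0, p_max = p_max,
                               force = list(approach = F_app, retract = F_ret))
  curve
}

#' Specification of a synthetic glycan profile
#'
#' @param compositions List of [glycan_composition()] objects.
#' @param fractions Relative abundances; non-negative, summing to 1.
#' @param intensity_scale Total intensity distributed over the peaks
#'   (arbitrary units).
#' @param mz_jitter Half-width (Da) of uniform m/z jitter applied per peak and
#'   run (default 0: exact theoretical m/z).
#' @param seed Optional integer seed.
#' @return A validated list of class `glycan_profile_spec`.
#' @export
glycan_profile_spec <- function(compositions, fractions,
                                intensity_scale = 1e4, mz_jitter = 0,
                                seed = NULL) {
  if (!is.list(compositions) ||
      !all(vapply(compositions, inherits, logical(1), "glycan_composition")))
    stop("`compositions` must be a list of glycan_composition objects")
  if (length(fractions) != length(compositions))
    stop("`fractions` must match `compositions` in length")
  if (any(fractions < 0)) stop("abundance fractions must be >= 0")
  if (abs(sum(fractions) - 1) > 1e-9)
    stop("abundance fractions must sum to 1 (got ", sum(fractions), ")")
  if (mz_jitter < 0) stop("mz_jitter must be >= 0")
  structure(list(compositions = compositions, fractions = fractions,
                 intensity_scale = intensity_scale, mz_jitter = mz_jitter,
                 seed = seed),
            class = "glycan_profile_spec")
}

#' Simulate paired light/heavy permethylation MALDI peak lists
#'
#' Each composition yields one `[M+Na]+` peak per run at its theoretical m/z
#' -- light: all methyls CH3; heavy: added methyls CD3, native methyls CH3 --
#' with intensity proportional to its abundance fraction.  Peaks that land on
#' exactly the same m/z (methylation variants of one residue composition are
#' mass-degenerate in the light run) are merged by summing their intensities,
#' as they would be in a real spectrum.
#'
#' @param spec A [glycan_profile_spec()].
#' @return List of class `peaklist_pair` with data frames `light` and `heavy`
#'   (columns `mz`, `intensity`, sorted by m/z).
#' @export
#' @examples
#' prof <- profile_compositions(oglycan_reference_profiles()$protective)
#' pk <- simulate_peaklists(glycan_profile_spec(prof$compositions, prof$fractions))
#' pk$light
simulate_peaklists <- function(spec) {
  stopifnot(inherits(spec, "glycan_profile_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  one_run <- function(run) {
    mz <- vapply(spec$compositions, permethylated_mass, numeric(1), run = run)
    if (spec$mz_jitter > 0)
      mz <- mz + stats::runif(length(mz), -spec$mz_jitter, spec$mz_jitter)
    intensity <- spec$fractions * spec$intensity_scale
    agg <- stats::aggregate(intensity, by = list(mz = round(mz, 9)), FUN = sum)
    out <- data.frame(mz = agg$mz, intensity = agg$x)
    out[order(out$mz), , drop = FALSE]
  }
  structure(list(light = one_run("light"), heavy = one_run("heavy")),
            class = "peaklist_pair")
}

#' Write / read a peak list as two-column TSV
#'
#' @param peaks Data frame with columns `mz`, `intensity`.
#' @param path File path.
#' @export
write_peaklist <- function(peaks, path) {
  utils::write.table(format(peaks, digits = 12, scientific = FALSE,
                            trim = TRUE),
                     path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_peaklist
#' @export
read_peaklist <- function(path) {
  out <- utils::read.table(path, header = TRUE, sep = "\t")
  if (!all(c("mz", "intensity") %in% names(out)))
    stop("peak list must have columns `mz` and `intensity`: ", path)
  out
}

#' Simulate an EDX element-abundance table
#'
#' Inverse of the weight-percent normalization: produces raw per-element
#' abundances that, when passed through [normalize_wt_pct()] with the same
#' convention, return the input wt% exactly (noiseless mode) or a multinomial
#' count perturbation of it (noisy mode).
#'
#' @param wt_pcts Named numeric vector, element symbol -> wt% (`>= 0`, not
#'   all zero).
#' @param total_counts Total raw counts distributed over elements.
#' @param noisy Logical; draw multinomial counts instead of exact values.
#' @param convention Normalization convention to invert; see
#'   [normalize_wt_pct()].
#' @param seed Optional integer seed.
#' @return Data frame with columns `element`, `abundance`.
#' @export
simulate_edx <- function(wt_pcts, total_counts = 1e6, noisy = FALSE,
                         convention = c("as_printed", "conventional"),
                         seed = NULL) {
  convention <- match.arg(convention)
  if (is.null(names(wt_pcts))) stop("`wt_pcts` must be a named vector")
  if (any(wt_pcts < 0)) stop("wt% values must be >= 0")
  if (sum(wt_pcts) == 0) stop("all-zero wt% input")
  if (!is.null(seed)) set.seed(seed)
  mass <- .atomic_weight(names(wt_pcts))
  raw <- if (convention == "as_printed") wt_pcts * mass else wt_pcts / mass
  p <- raw / sum(raw)
  abundance <- if (noisy) as.numeric(stats::rmultinom(1, total_counts, p))
  else p * total_counts
  data.frame(element = names(wt_pcts), abundance = abundance,
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Specification of a synthetic protein-identification table
#'
#' @param n_true Number of genuine proteins (pass every identification
#'   filter).
#' @param n_marginal Number of marginal proteins, each failing exactly one
#'   filter criterion.
#' @param category_mix Named probabilities over functional categories,
#'   summing to 1.
#' @param samples Sample names receiving MS/MS spectral counts.
#' @param mean_msms Mean spectral count per protein and sample.
#' @param seed Optional integer seed.
#' @return A validated list of class `id_table_spec`.
#' @export
id_table_spec <- function(n_true, n_marginal = 0L,
                          category_mix = c(matrix = 0.45, glycoprotein = 0.15,
                                           enzyme = 0.10, lectin = 0.10,
                                           inhibitor = 0.05, mucin = 0.05,
                                           `ion-binder` = 0.05,
                                           `Snail/Unknown` = 0.05),
                          samples = c("adhesive", "lubricating", "protective"),
                          mean_msms = 30, seed = NULL) {
  if (n_true < 0 || n_marginal < 0) stop("counts must be >= 0")
  if (is.null(names(category_mix)) || any(category_mix < 0) ||
      abs(sum(category_mix) - 1) > 1e-9)
    stop("`category_mix` must be named, non-negative and sum to 1")
  structure(list(n_true = as.integer(n_true),
                 n_marginal = as.integer(n_marginal),
                 category_mix = category_mix, samples = samples,
                 mean_msms = mean_msms, seed = seed),
            class = "id_table_spec")
}

#' Simulate a protein-identification table with planted pass/fail structure
#'
#' Genuine records satisfy every acceptance filter (at least two peptides,
#' local FDR below 1%, peptide probability at least 95%, protein probability
#' clearing the threshold under either selectable rule); each marginal record
#' fails exactly one randomly chosen criterion.  The planted status is
#' recorded in the `planted_pass` column so filter recall/precision is
#' checkable.
#'
#' @param spec An [id_table_spec()].
#' @return Data frame with columns `protein_id`, `category`, `n_peptides`,
#'   `peptide_prob`, `protein_prob`, `local_fdr`, `planted_pass`, and one
#'   `msms_<sample>` spectral-count column per sample.
#' @export
simulate_id_table <- function(spec) {
  stopifnot(inherits(spec, "id_table_spec"))
  if (!is.null(spec$seed)) set.seed(spec$seed)
  n <- spec$n_true + spec$n_marginal
  if (n == 0) {
    out <- data.frame(protein_id = character(), category = character(),
                      n_peptides = integer(), peptide_prob = numeric(),
                      protein_prob = numeric(), local_fdr = numeric(),
                      planted_pass = logical())
    for (s in spec$samples) out[[paste0("msms_", s)]] <- integer()
    return(out)
  }
  out <- data.frame(
    protein_id = sprintf("prot%03d", seq_len(n)),
    category = sample(names(spec$category_mix), n, replace = TRUE,
                      prob = spec$category_mix),
    n_peptides = sample(2:12, n, replace = TRUE),
    peptide_prob = stats::runif(n, 0.95, 1),
    protein_prob = stats::runif(n, 0.95, 1),
    local_fdr = stats::runif(n, 0, 0.009),
    planted_pass = rep(c(TRUE, FALSE), c(spec$n_true, spec$n_marginal)),
    stringsAsFactors = FALSE
  )
  if (spec$n_marginal > 0) {
    idx <- which(!out$planted_pass)
    breakage <- sample(c("peptides", "fdr", "pep_prob", "prot_prob"),
                       length(idx), replace = TRUE)
    out$n_peptides[idx[breakage == "peptides"]] <- 1L
    out$local_fdr[idx[breakage == "fdr"]] <-
      stats::runif(sum(breakage == "fdr"), 0.011, 0.2)
    out$peptide_prob[idx[breakage == "pep_prob"]] <-
      stats::runif(sum(breakage == "pep_prob"), 0.5, 0.94)
    # fails both the as-printed (>= 0.05) and complement (>= 0.95) rules
    out$protein_prob[idx[breakage == "prot_prob"]] <-
      stats::runif(sum(breakage == "prot_prob"), 0, 0.049)
  }
  for (s in spec$samples)
    out[[paste0("msms_", s)]] <- stats::rpois(n, spec$mean_msms)
  out
}
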