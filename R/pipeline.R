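# 32-bit FNV-1a over a string; used to fingerprint the run configuration in
# the log (avoids precision loss by 16-bit limb multiplication)
.fnv1a <- function(s) {
  mul32 <- function(a, b) {
    lo <- (a %% 65536) * b
    hi <- ((a %/% 65536) * b) %% 65536
    (lo + hi * 65536) %% 4294967296
  }
  h <- 2166136261
  for (b in utf8ToInt(s)) {
    lo <- bitwXor(as.integer(h %% 65536), as.integer(b %% 65536))
    h <- mul32((h %/% 65536) * 65536 + lo, 16777619)
  }
  sprintf("%04x%04x", as.integer(h %/% 65536), as.integer(h %% 65536))
}

#' Default pipeline configuration
#'
#' Assembles the configuration consumed by [run_pipeline()].  Stage blocks:
#' `jkr` (calibration and curve counts), `glyco` (tolerance), `edx`
#' (convention), `filters` (identification thresholds), `id_table`
#' (synthetic proteomics table size).  Secretion-level ground truth defaults
#' to the package reference tables ([mucus_mechanics_reference()],
#' [oglycan_reference_profiles()], [snail_edx_reference()]).
#'
#' @param seed Integer seed driving every stochastic stage.
#' @param out_dir Output directory (created if needed).
#' @param n_curves Indentations per secretion; `NULL` uses the reference `n`
#'   (36/51/59).
#' @param noise_sd Force noise of the curve generator (N).
#' @param between_curve_sd Logical; draw per-curve true `(E, W)` from normal
#'   distributions matching the reference per-sample spread (`SE * sqrt(n)`),
#'   emulating material heterogeneity.
#' @param log_level `"info"` or `"quiet"`.
#' @return Configuration list of class `mucomics_config`.
#' @export
default_run_config <- function(seed = 1L, out_dir = tempfile("mucomics_"),
                               n_curves = NULL, noise_sd = 0,
                               between_curve_sd = TRUE,
                               log_level = c("info", "quiet")) {
  structure(list(
    seed = as.integer(seed),
    out_dir = out_dir,
    simulate = TRUE,
    curves_dir = NULL,
    log_level = match.arg(log_level),
    jkr = list(R = 20e-9, k = 0.139, defl_sens = 40.7e-9,
               n_points = 200L, n_curves = n_curves, noise_sd = noise_sd,
               between_curve_sd = between_curve_sd),
    glyco = list(tolerance = 0.2, mz_jitter = 0, intensity_scale = 1e4),
    edx = list(convention = "as_printed", noisy = FALSE, total_counts = 1e6),
    filters = list(min_peptides = 2, max_fdr = 0.01, peptide_prob_min = 0.95,
                   protein_threshold = 0.05, protein_rule = "as_printed"),
    id_table = list(n_true = 50L, n_marginal = 20L)
  ), class = "mucomics_config")
}

#' Load a pipeline configuration from a YAML file
#'
#' Values in the file override the defaults of [default_run_config()];
#' unknown keys are an error.
#'
#' @param path YAML file.
#' @param ... Further overrides applied after the file.
#' @return Configuration list of class `mucomics_config`.
#' @export
load_run_config <- function(path, ...) {
  cfg <- default_run_config()
  usr <- yaml::read_yaml(path)
  merge_into <- function(base, new, where = "") {
    for (k in names(new)) {
      if (!k %in% names(base))
        stop("unknown configuration key `", where, k, "`")
      base[[k]] <- if (is.list(base[[k]]) && is.list(new[[k]]))
        merge_into(base[[k]], new[[k]], paste0(where, k, "."))
      else new[[k]]
    }
    base
  }
  cfg <- merge_into(unclass(cfg), usr)
  dots <- list(...)
  if (length(dots)) cfg <- merge_into(cfg, dots)
  structure(cfg, class = "mucomics_config")
}

.pipe_log <- function(config, fmt, ...) {
  if (identical(config$log_level, "quiet")) return(invisible())
  message(sprintf(paste0("[mucomics] ", fmt), ...))
}

.write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# draw per-curve true parameters for one secretion (heterogeneous material)
.draw_curve_params <- function(ref_row, n, heterogeneous) {
  if (!heterogeneous)
    return(data.frame(E = rep(ref_row$E_mpa * 1e6, n),
                      delta_r = rep(ref_row$W_nm, n)))
  sdE <- ref_row$E_se_mpa * sqrt(ref_row$n) * 1e6
  sdW <- ref_row$W_se_nm * sqrt(ref_row$n)
  data.frame(
    E = pmax(stats::rnorm(n, ref_row$E_mpa * 1e6, sdE), 0.05 * ref_row$E_mpa * 1e6),
    delta_r = pmax(stats::rnorm(n, ref_row$W_nm, sdW), 0.05 * ref_row$W_nm))
}

#' Run the full comparative pipeline on synthetic data
#'
#' Orchestrates all stages: generates force curves, MALDI peak-list pairs,
#' EDX tables and an identification table for the three secretions (or reads
#' force curves from `config$curves_dir` when `config$simulate` is `FALSE`),
#' runs the JKR, glycan-annotation, EDX and protein-profiling stages, writes
#' every intermediate as TSV under `config$out_dir`, and assembles a
#' comparative per-secretion report.  The run is deterministic given the
#' configuration and seed; the log records the package version, a
#' configuration fingerprint and the seed.
#'
#' @param config A [default_run_config()] / [load_run_config()] list.
#' @return Object of class `mucomics_report`: list with `summary` (one row
#'   per secretion), `jkr` (per-curve results), `glycans` (annotated
#'   profiles), `edx` (wt% profiles), `proteins` (category profile) and
#'   `paths` of all written files.
#' @export
#' @examples
#' \donttest{
#' rep <- run_pipeline(default_run_config(seed = 1, n_curves = 8))
#' rep$summary
#' }
run_pipeline <- function(config = default_run_config()) {
  if (!inherits(config, "mucomics_config"))
    stop("`config` must be created by default_run_config()/load_run_config()")
  hashed <- unclass(config)
  hashed$out_dir <- hashed$curves_dir <- hashed$log_level <- NULL
  t_hash <- .fnv1a(paste(deparse(hashed), collapse = ""))
  .pipe_log(config, "mucomics %s | seed %d | config %s",
            as.character(utils::packageVersion("mucomics")),
            config$seed, t_hash)
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)
  paths <- list()
  ref <- mucus_mechanics_reference()
  secretions <- ref$secretion
  set.seed(config$seed)

  ## ---- stage 1: inputs (simulated or on disk) --------------------------
  curves <- list()
  if (isTRUE(config$simulate)) {
    cdir <- file.path(config$out_dir, "curves")
    dir.create(cdir, showWarnings = FALSE)
    for (i in seq_along(secretions)) {
      sec <- secretions[i]
      n <- if (!is.null(config$jkr$n_curves)) config$jkr$n_curves else ref$n[i]
      pars <- .draw_curve_params(ref[i, ], n, config$jkr$between_curve_sd)
      curves[[sec]] <- lapply(seq_len(n), function(j) {
        cv <- simulate_jkr_curve(jkr_sim_config(
          E = pars$E[j], delta_r = pars$delta_r[j],
          R = config$jkr$R, k = config$jkr$k,
          defl_sens = config$jkr$defl_sens,
          n_points = config$jkr$n_points, noise_sd = config$jkr$noise_sd))
        write_force_curve(cv, file.path(cdir, sprintf("%s_%03d.tsv", sec, j)))
        cv
      })
    }
    paths$curves <- cdir
  } else {
    cdir <- config$curves_dir
    if (is.null(cdir) || !dir.exists(cdir))
      stop("stage jkr: curve directory not found: ",
           if (is.null(cdir)) "<unset>" else cdir)
    for (sec in secretions) {
      files <- list.files(cdir, pattern = paste0("^", sec, ".*\\.tsv$"),
                          full.names = TRUE)
      if (!length(files))
        stop("stage jkr: no curve files for secretion `", sec,
             "` under ", cdir)
      curves[[sec]] <- lapply(files, read_force_curve)
    }
  }

  ## ---- stage 2: JKR mechanics ------------------------------------------
  .pipe_log(config, "jkr: fitting %s curves",
            paste(vapply(curves, length, integer(1)), collapse = "/"))
  per_curve <- do.call(rbind, lapply(secretions, function(sec) {
    do.call(rbind, lapply(seq_along(curves[[sec]]), function(j) {
      fs <- to_force_separation(curves[[sec]][[j]])
      fit <- fit_jkr(fs)
      wa <- work_of_adhesion(fs, h0 = fit$h0)
      data.frame(secretion = sec, curve = j,
                 E_mpa = fit$E_jkr / 1e6, delta_r_nm = fit$delta_r,
                 W_hyst_nm = wa$W, P_adh_nN = fit$P_adh * 1e9,
                 a0_nm = fit$a0 * 1e9, rss = fit$rss,
                 converged = fit$converged)
    }))
  }))
  paths$jkr <- .write_tsv(per_curve, file.path(config$out_dir, "jkr_per_curve.tsv"))
  jkr_summary <- do.call(rbind, lapply(secretions, function(sec) {
    sub <- per_curve[per_curve$secretion == sec & per_curve$converged, ]
    sE <- sample_summary(sub$E_mpa); sW <- sample_summary(sub$delta_r_nm)
    sH <- sample_summary(sub$W_hyst_nm)
    data.frame(secretion = sec, n = sE$n,
               E_mean_mpa = sE$mean, E_se_mpa = sE$se,
               W_fit_mean_nm = sW$mean, W_fit_se_nm = sW$se,
               W_hyst_mean_nm = sH$mean, W_hyst_se_nm = sH$se)
  }))
  paths$jkr_summary <- .write_tsv(jkr_summary,
                                  file.path(config$out_dir, "jkr_summary.tsv"))

  ## ---- stage 3: glycan annotation --------------------------------------
  .pipe_log(config, "glyco: annotating O-glycan profiles")
  profiles_ref <- oglycan_reference_profiles()
  pdir <- file.path(config$out_dir, "peaks")
  dir.create(pdir, showWarnings = FALSE)
  glycans <- list()
  for (sec in secretions) {
    pr <- profile_compositions(profiles_ref[[sec]])
    pk <- simulate_peaklists(glycan_profile_spec(
      pr$compositions, pr$fractions,
      intensity_scale = config$glyco$intensity_scale,
      mz_jitter = config$glyco$mz_jitter))
    write_peaklist(pk$light, file.path(pdir, paste0(sec, "_light.tsv")))
    write_peaklist(pk$heavy, file.path(pdir, paste0(sec, "_heavy.tsv")))
    glycans[[sec]] <- annotate_glycans(pk, tolerance = config$glyco$tolerance)
  }
  gly_tab <- do.call(rbind, lapply(secretions, function(sec) {
    g <- glycans[[sec]]
    data.frame(secretion = sec, glycan = g$label,
               abundance_pct = 100 * g$fraction, major = g$major,
               n_native_me = g$n_native_me)
  }))
  paths$glycans <- .write_tsv(gly_tab,
                              file.path(config$out_dir, "glycan_profiles.tsv"))

  ## ---- stage 4: EDX ------------------------------------------------------
  .pipe_log(config, "edx: normalizing elemental profiles (%s)",
            config$edx$convention)
  edx_ref <- snail_edx_reference()
  edx <- list()
  for (sec in secretions) {
    wt <- stats::setNames(edx_ref[[sec]], edx_ref$element)
    raw <- simulate_edx(wt[wt > 0], total_counts = config$edx$total_counts,
                        noisy = config$edx$noisy,
                        convention = config$edx$convention)
    .write_tsv(raw, file.path(config$out_dir, paste0("edx_", sec, "_raw.tsv")))
    edx[[sec]] <- normalize_wt_pct(raw, convention = config$edx$convention)
  }
  edx_tab <- do.call(rbind, lapply(secretions, function(sec)
    data.frame(secretion = sec, edx[[sec]],
               organic_pct = organic_content(edx[[sec]]))))
  paths$edx <- .write_tsv(edx_tab, file.path(config$out_dir, "edx_wtpct.tsv"))

  ## ---- stage 5: protein profiling ---------------------------------------
  .pipe_log(config, "proteins: filtering identifications")
  id_tab <- simulate_id_table(id_table_spec(
    n_true = config$id_table$n_true, n_marginal = config$id_table$n_marginal,
    samples = secretions))
  paths$id_table <- .write_tsv(id_tab,
                               file.path(config$out_dir, "id_table.tsv"))
  accepted <- do.call(filter_identifications,
                      c(list(records = id_tab), config$filters))
  prof <- category_profile(accepted)
  cat_tab <- data.frame(secretion = rownames(prof$percent),
                        prof$percent, check.names = FALSE)
  paths$proteins <- .write_tsv(cat_tab,
                               file.path(config$out_dir, "category_profile.tsv"))

  ## ---- stage 6: comparative report --------------------------------------
  summarize_sec <- function(sec) {
    g <- glycans[[sec]]
    top_gly <- sprintf("%s (%.0f%%)", g$label[1], 100 * g$fraction[1])
    topcat <- names(which.max(prof$percent[sec, ]))
    js <- jkr_summary[jkr_summary$secretion == sec, ]
    data.frame(
      secretion = sec, n_indent = js$n,
      E_mpa = js$E_mean_mpa, E_se_mpa = js$E_se_mpa,
      W_nm = js$W_fit_mean_nm, W_se_nm = js$W_fit_se_nm,
      top_glycan = top_gly,
      organic_pct = organic_content(edx[[sec]]),
      Ca_pct = edx[[sec]]$wt_pct[edx[[sec]]$element == "Ca"],
      top_category = sprintf("%s (%.0f%%)", topcat, prof$percent[sec, topcat]))
  }
  summary <- do.call(rbind, lapply(secretions, summarize_sec))
  paths$report <- .write_tsv(summary, file.path(config$out_dir, "report.tsv"))
  txt <- file.path(config$out_dir, "report.txt")
  writeLines(c("Comparative mucomics report",
               sprintf("seed %d | config %s", config$seed, t_hash), "",
               utils::capture.output(print(summary, row.names = FALSE))), txt)
  paths$report_txt <- txt

  structure(list(summary = summary, jkr = per_curve,
                 jkr_summary = jkr_summary, glycans = glycans, edx = edx,
                 proteins = prof, accepted = accepted, paths = paths,
                 seed = config$seed, config_hash = t_hash),
            class = "mucomics_report")
}

#' @export
print.mucomics_report <- function(x, ...) {
  cat("Comparative mucomics report (seed ", x$seed, ", config ",
      x$config_hash, ")\n\n", sep = "")
  print(x$summary, row.names = FALSE)
  invisible(x)
}
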