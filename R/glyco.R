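#' Default per-residue enumeration bounds for mass decomposition
#'
#' Generous enough to cover every composition reported for snail mucus
#' O- and N-glycans (largest: a sialylated, doubly fucosylated pentasaccharide
#' and tri-sialylated N-glycans).
#'
#' @return Named integer vector of maximum residue counts.
#' @export
default_residue_bounds <- function() {
  c(Hex = 10L, HexNAc = 6L, dHex = 4L, Pent = 3L, Neu5Ac = 3L, Neu5Gc = 2L)
}

# Enumerate all residue compositions within bounds and precompute light-run
# theoretical m/z.  Returns a data.frame with one row per composition.
.composition_table <- function(bounds, glycan_class) {
  bounds <- bounds[bounds > 0]
  unknown <- setdiff(names(bounds), .residues$name)
  if (length(unknown)) stop("unknown residue(s) in bounds: ",
                            paste(unknown, collapse = ", "))
  grid <- do.call(expand.grid, lapply(bounds, function(b) 0:b))
  grid <- grid[rowSums(grid) >= 1, , drop = FALSE]
  idx <- match(names(bounds), .residues$name)
  res_mass <- .formula_mass(.residues$C[idx], .residues$H[idx],
                            .residues$N[idx], .residues$O[idx])
  n_res <- rowSums(grid)
  sites <- as.integer(as.matrix(grid) %*% .residues$free_sites[idx] -
                        2L * (n_res - 1L))
  if (glycan_class == "O-alditol") sites <- sites + 1L
  mass <- as.numeric(as.matrix(grid) %*% res_mass) + .mass_H2O +
    (if (glycan_class == "O-alditol") .mass_H2 else 0) +
    sites * .mass_CH2 + .atomic_mass[["Na"]]
  out <- as.data.frame(grid)
  out$n_residues <- n_res
  out$sites <- sites
  out$mz_light <- mass
  out
}

.row_to_composition <- function(row, bounds_names, glycan_class,
                                n_native_me = 0L) {
  counts <- unlist(row[bounds_names])
  glycan_composition(counts[counts > 0], n_native_me = n_native_me,
                     glycan_class = glycan_class)
}

#' Decompose an observed m/z into candidate glycan compositions
#'
#' Exhaustive bounded enumeration of residue compositions whose light-run
#' (CH3 permethylation) theoretical `[M+Na]+` m/z lies within `tolerance` of
#' the observed value.  Candidates are sorted by absolute mass error, ties
#' broken by fewer residues, then fewer native methyls.  Because native and
#' added methyls have identical mass in the light run, native-methyl counts
#' are mass-degenerate there; by default each composition is returned once
#' with `n_native_me = 0` and the count is resolved later from the heavy run
#' (see [infer_native_methylation()]).  Set `enumerate_native = TRUE` to
#' expand every candidate over native-methyl counts `0..sites`.
#'
#' @param mz_obs Observed m/z values (Da).
#' @param tolerance Matching tolerance (Da, `> 0`).
#' @param bounds Named maximum residue counts; see [default_residue_bounds()].
#' @param glycan_class `"O-alditol"` or `"N-free"`.
#' @param enumerate_native Expand candidates over native-methyl counts.
#' @return For a single `mz_obs`, a data frame of candidates (residue counts,
#'   `n_native_me`, `sites`, `mz_theoretical`, `error`, `label`), possibly
#'   with zero rows (peak unassigned); for a vector, a list of such frames.
#' @export
#' @examples
#' core1 <- glycan_composition(c(Hex = 1, HexNAc = 1))
#' decompose_mass(permethylated_mass(core1))[1, ]
decompose_mass <- function(mz_obs, tolerance = 0.2,
                           bounds = default_residue_bounds(),
                           glycan_class = c("O-alditol", "N-free"),
                           enumerate_native = FALSE) {
  glycan_class <- match.arg(glycan_class)
  if (!is.numeric(tolerance) || tolerance < 0)
    stop("tolerance must be >= 0")
  tab <- .composition_table(bounds, glycan_class)
  bn <- intersect(names(bounds), names(tab))
  one <- function(mz) {
    err <- tab$mz_light - mz
    hit <- which(abs(err) <= tolerance)
    out <- tab[hit, , drop = FALSE]
    out$error <- err[hit]
    out$n_native_me <- integer(nrow(out))
    if (enumerate_native && nrow(out)) {
      out <- out[rep(seq_len(nrow(out)), out$sites + 1L), , drop = FALSE]
      out$n_native_me <- unlist(lapply(tab$sites[hit], function(s) 0:s))
    }
    # compare errors at micro-Da granularity so exact degeneracies (e.g.
    # permethylated Pent + one extra methyl == Hex) fall through to the
    # parsimony tie-breaks instead of floating-point noise
    out <- out[order(round(abs(out$error), 6), out$n_residues,
                     out$n_native_me), , drop = FALSE]
    rownames(out) <- NULL
    if (nrow(out))
      out$label <- vapply(seq_len(nrow(out)), function(i)
        format(.row_to_composition(out[i, ], bn, glycan_class,
                                   out$n_native_me[i])), character(1))
    else out$label <- character(0)
    names(out)[names(out) == "mz_light"] <- "mz_theoretical"
    out
  }
  if (length(mz_obs) == 1) one(mz_obs) else lapply(mz_obs, one)
}

#' Infer the native-methyl count from a light/heavy peak pair
#'
#' Each derivatization site filled during permethylation adds CD3 instead of
#' CH3 in the heavy (iodomethane-D3) run, shifting the mass by
#' `3.01883 Da` per *added* methyl; sites already occupied by native methyls
#' do not shift.  The number of added methyls is the rounded mass shift over
#' 3.01883, and `n_native = sites - n_added`.
#'
#' @param light_mz,heavy_mz Observed m/z of the same composition in the light
#'   and heavy runs (Da).
#' @param comp The assigned [glycan_composition()].
#' @param tolerance Maximum rounding residual (Da) before the pair is flagged
#'   inconsistent.
#' @return List with `n_native`, `n_added`, `residual` (Da) and `consistent`.
#'   A negative native count after rounding is an error.
#' @export
infer_native_methylation <- function(light_mz, heavy_mz, comp,
                                     tolerance = 0.2) {
  stopifnot(inherits(comp, "glycan_composition"))
  shift <- heavy_mz - light_mz
  n_added <- round(shift / .mass_cd3_shift)
  residual <- shift - n_added * .mass_cd3_shift
  sites <- methylation_sites(comp)
  n_native <- sites - n_added
  if (n_native < 0)
    stop("inconsistent light/heavy pair: inferred ", n_added,
         " added methyls exceeds the ", sites, " sites of ", format(comp))
  list(n_native = as.integer(n_native), n_added = as.integer(n_added),
       residual = residual, consistent = abs(residual) <= tolerance)
}

#' Relative-abundance profile of assigned peaks
#'
#' Normalizes assigned-peak intensities to fractions of the total assigned
#' intensity and splits the assignments into major (fraction above 5%) and
#' trace entries, as in standard glycomic profiling reports.
#'
#' @param assignments Data frame with at least `label` and `intensity`
#'   columns (one row per assigned glycan; see [annotate_glycans()]).
#' @param major_threshold Fraction above which a glycan is "major"
#'   (default 0.05, strict inequality).
#' @return Object of class `glycan_profile`: the input with added `fraction`
#'   and `major` columns, sorted by decreasing fraction.
#' @export
relative_abundance <- function(assignments, major_threshold = 0.05) {
  if (!is.data.frame(assignments) ||
      !all(c("label", "intensity") %in% names(assignments)))
    stop("`assignments` needs columns `label` and `intensity`")
  if (nrow(assignments) == 0) stop("no assigned peaks")
  total <- sum(assignments$intensity)
  if (total <= 0) stop("zero total intensity over assigned peaks")
  out <- assignments
  out$fraction <- out$intensity / total
  out$major <- out$fraction > major_threshold
  out <- out[order(-out$fraction), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, class = c("glycan_profile", "data.frame"))
}

#' @export
print.glycan_profile <- function(x, digits = 3, ...) {
  cat("Glycan relative-abundance profile (", sum(x$major), " major / ",
      nrow(x) - sum(x$major), " trace)\n", sep = "")
  show <- data.frame(glycan = x$label,
                     `abundance %` = round(100 * x$fraction, digits),
                     major = ifelse(x$major, "*", ""),
                     check.names = FALSE)
  print(show, row.names = FALSE)
  invisible(x)
}

#' Annotate paired light/heavy MALDI peak lists
#'
#' The full annotation stage: every light-run peak is decomposed into its
#' best-matching residue composition ([decompose_mass()]); when a heavy-run
#' peak list is supplied, each composition's predicted heavy m/z is evaluated
#' over all native-methyl counts `0..sites` and matched against the heavy
#' peaks, resolving the native-methyl count ([infer_native_methylation()]).
#' Methylation variants of one residue composition share a single
#' (mass-degenerate) light peak; its intensity is apportioned across the
#' matched variants in proportion to their heavy-run intensities.  Relative
#' abundances are computed from the light run (the light total is
#' authoritative) via [relative_abundance()].
#'
#' @param light Data frame (`mz`, `intensity`) of the CH3 run, or a
#'   `peaklist_pair` (in which case `heavy` is taken from it too).
#' @param heavy Optional data frame (`mz`, `intensity`) of the CD3 run.
#' @param tolerance m/z matching tolerance (Da).
#' @param bounds,glycan_class Passed to [decompose_mass()].
#' @param major_threshold Passed to [relative_abundance()].
#' @return A `glycan_profile` with columns `mz`, `intensity`, `label`,
#'   residue counts, `n_native_me`, `mz_theoretical`, `error`, `heavy_mz`,
#'   `fraction`, `major`; unassigned peaks are kept in the attribute
#'   `unassigned`.
#' @export
annotate_glycans <- function(light, heavy = NULL, tolerance = 0.2,
                             bounds = default_residue_bounds(),
                             glycan_class = c("O-alditol", "N-free"),
                             major_threshold = 0.05) {
  glycan_class <- match.arg(glycan_class)
  if (inherits(light, "peaklist_pair")) {
    heavy <- light$heavy
    light <- light$light
  }
  stopifnot(is.data.frame(light), all(c("mz", "intensity") %in% names(light)))
  tab <- .composition_table(bounds, glycan_class)
  bn <- intersect(names(bounds), names(tab))

  rows <- list()
  unassigned <- list()
  for (i in seq_len(nrow(light))) {
    err <- tab$mz_light - light$mz[i]
    hit <- which(abs(err) <= tolerance)
    if (!length(hit)) {
      unassigned[[length(unassigned) + 1L]] <- light[i, ]
      next
    }
    best <- hit[order(round(abs(err[hit]), 6), tab$n_residues[hit])][1]
    rows[[length(rows) + 1L]] <- list(
      mz = light$mz[i], intensity = light$intensity[i],
      row = tab[best, bn, drop = FALSE], sites = tab$sites[best],
      mz_theoretical = tab$mz_light[best], error = err[best],
      variants = data.frame(n_native_me = NA_integer_,
                            heavy_mz = NA_real_, weight = 1))
  }
  if (!length(rows)) stop("no peak could be assigned a composition")

  if (!is.null(heavy)) {
    # Match heavy peaks globally: every (light assignment, native-methyl
    # count) slot predicts one heavy m/z; each heavy peak is granted to the
    # best-fitting slot only, so a foreign heavy peak that happens to fall
    # near some other composition's predicted variant cannot siphon
    # intensity from it.
    cand <- do.call(rbind, lapply(seq_along(rows), function(i) {
      nn <- 0:rows[[i]]$sites
      pred <- rows[[i]]$mz_theoretical +
        (rows[[i]]$sites - nn) * .mass_cd3_shift
      do.call(rbind, lapply(seq_len(nrow(heavy)), function(j) {
        d <- abs(heavy$mz[j] - pred)
        k <- which.min(d)
        if (d[k] <= tolerance)
          data.frame(i = i, j = j, n_native_me = nn[k], err = d[k])
        else NULL
      }))
    }))
    if (!is.null(cand) && nrow(cand)) {
      cand <- cand[order(round(cand$err, 6), cand$n_native_me), , drop = FALSE]
      used_heavy <- logical(nrow(heavy))
      matches <- vector("list", length(rows))
      for (r in seq_len(nrow(cand))) {
        j <- cand$j[r]
        if (used_heavy[j]) next
        used_heavy[j] <- TRUE
        i <- cand$i[r]
        matches[[i]] <- rbind(matches[[i]], data.frame(
          n_native_me = cand$n_native_me[r], heavy_mz = heavy$mz[j],
          weight = heavy$intensity[j]))
      }
      for (i in seq_along(rows))
        if (!is.null(matches[[i]])) rows[[i]]$variants <- matches[[i]]
    }
  }

  assignments <- do.call(rbind, lapply(rows, function(b) {
    v <- b$variants
    w <- v$weight / sum(v$weight)
    out <- v
    out$mz <- b$mz
    out$intensity <- b$intensity * w   # split shared light peak by heavy run
    out$mz_theoretical <- b$mz_theoretical
    out$error <- b$error
    for (cn in names(b$row)) out[[cn]] <- b$row[[cn]]
    out$label <- vapply(seq_len(nrow(out)), function(k)
      format(.row_to_composition(b$row, names(b$row), glycan_class,
                                 max(0L, out$n_native_me[k], na.rm = TRUE))),
      character(1))
    out$weight <- NULL
    out
  }))
  prof <- relative_abundance(assignments, major_threshold = major_threshold)
  attr(prof, "unassigned") <- if (length(unassigned))
    do.call(rbind, unassigned) else light[0, ]
  attr(prof, "glycan_class") <- glycan_class
  prof
}
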