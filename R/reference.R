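#' Reference mechanical parameters of the three snail mucus secretions
#'
#' Mean Young's modulus E, work of adhesion W, their standard errors, and the
#' number of indentations per secretion for *Cornu aspersum* adhesive,
#' lubricating and protective mucus, as determined by AFM nanoindentation with
#' a 20 nm tip, 0.139 N/m cantilever and 40.7 nm/V deflection sensitivity.
#' These values parameterize the synthetic force-curve generator defaults.
#'
#' @return Data frame with columns `secretion`, `E_mpa`, `E_se_mpa`, `W_nm`
#'   (N/m), `W_se_nm`, `n`.
#' @export
#' @examples
#' mucus_mechanics_reference()
mucus_mechanics_reference <- function() {
  data.frame(
    secretion = c("adhesive", "lubricating", "protective"),
    E_mpa     = c(41.6, 132, 162),
    E_se_mpa  = c(2.03, 12.0, 18.6),
    W_nm      = c(3.37, 2.39, 17.2),
    W_se_nm   = c(0.498, 0.268, 2.63),
    n         = c(36L, 51L, 59L),
    stringsAsFactors = FALSE
  )
}

#' Reference EDX elemental composition of the three secretions
#'
#' Weight-percent elemental composition of adhesive, lubricating and
#' protective snail mucus from SEM-EDX. Elements not detected in a sample are
#' recorded as 0.  The attribute `printed_organic` carries the organic
#' (C+O+N) content percentages as originally reported alongside the table;
#' note that the adhesive column sums to about 83.0, not the reported 84.7 --
#' [organic_content()] recomputes the sum and the pipeline reports the
#' discrepancy rather than silently correcting either number.
#'
#' @return Data frame with columns `element`, `adhesive`, `lubricating`,
#'   `protective` (wt%).
#' @export
snail_edx_reference <- function() {
  out <- data.frame(
    element     = c("C", "O", "N", "Cl", "K", "Na", "Ca", "S", "Mg", "P", "Si"),
    adhesive    = c(58.0, 15.6, 9.38, 4.50, 4.11, 2.96, 1.93, 1.80, 0.90, 0.64, 0),
    lubricating = c(79.5, 8.29, 4.61, 1.15, 3.00, 0.46, 0.92, 0,    1.15, 0,    0.92),
    protective  = c(62.2, 18.8, 0,    5.87, 2.55, 3.57, 3.32, 1.53, 1.53, 0.26, 0.38),
    stringsAsFactors = FALSE
  )
  attr(out, "printed_organic") <-
    c(adhesive = 84.7, lubricating = 92.4, protective = 82.52)
  out
}

#' Reference O-glycan profiles of the three secretions
#'
#' Relative-abundance profiles of the major O-glycan alditols in each mucus,
#' used as defaults by [simulate_peaklists()].  The dominant entries carry the
#' reported percentages (core-1 T-antigen at 52% in adhesive and 69% in
#' lubricating; the dimethylated trisaccharide (MeHex)2HexNAc-ol at 48% in
#' protective; two sialylated O-glycans totalling 7% in adhesive; extended
#' galactosylated glycans around 8% in lubricating).  The remaining fractions
#' are package choices made once so that each profile sums to 1 while
#' respecting every reported ordering constraint; see the methods vignette.
#'
#' @return Named list of data frames (`adhesive`, `lubricating`,
#'   `protective`) with residue-count columns, `n_native_me` and `fraction`.
#' @seealso [profile_compositions()] to convert a profile into
#'   [glycan_composition()] objects.
#' @export
oglycan_reference_profiles <- function() {
  list(
    adhesive = data.frame(
      Hex     = c(1, 2, 2, 2, 1, 1),
      HexNAc  = c(1, 1, 1, 1, 2, 2),
      dHex    = c(0, 0, 0, 0, 0, 2),
      Neu5Ac  = c(0, 0, 0, 0, 1, 1),
      n_native_me = c(0, 2, 1, 0, 0, 0),
      fraction    = c(0.52, 0.27, 0.08, 0.06, 0.04, 0.03)
    ),
    lubricating = data.frame(
      Hex     = c(1, 2, 2, 2, 3, 2, 1),
      HexNAc  = c(1, 1, 1, 1, 2, 2, 1),
      dHex    = c(0, 0, 0, 0, 0, 1, 1),
      Neu5Ac  = c(0, 0, 0, 0, 0, 0, 0),
      n_native_me = c(0, 2, 1, 0, 0, 0, 0),
      fraction    = c(0.69, 0.10, 0.05, 0.03, 0.05, 0.03, 0.05)
    ),
    protective = data.frame(
      Hex     = c(2, 1, 1, 0),
      HexNAc  = c(1, 1, 1, 2),
      dHex    = c(0, 0, 1, 0),
      Neu5Ac  = c(0, 0, 0, 0),
      n_native_me = c(2, 0, 0, 0),
      fraction    = c(0.48, 0.30, 0.12, 0.10)
    )
  )
}

#' Convert a profile data frame into compositions and fractions
#'
#' @param profile One element of [oglycan_reference_profiles()], or any data
#'   frame with residue-count columns (matching `residue_table()$name`),
#'   `n_native_me` and `fraction`.
#' @param glycan_class Glycan class for every entry.
#' @return List with `compositions` (list of [glycan_composition()]) and
#'   `fractions` (numeric).
#' @export
profile_compositions <- function(profile, glycan_class = "O-alditol") {
  res_cols <- intersect(names(profile), .residues$name)
  comps <- lapply(seq_len(nrow(profile)), function(i) {
    counts <- unlist(profile[i, res_cols, drop = TRUE])
    glycan_composition(counts[counts > 0],
                       n_native_me = profile$n_native_me[i],
                       glycan_class = glycan_class)
  })
  list(compositions = comps, fractions = profile$fraction)
}
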