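# Monoisotopic atomic masses (Da). CODATA/IUPAC values; D = deuterium.
.atomic_mass <- c(
  H  = 1.0078250319,
  D  = 2.0141017780,
  C  = 12.0,
  N  = 14.0030740052,
  O  = 15.9949146221,
  Na = 22.98976928
)

.mass_H2O <- 2 * .atomic_mass[["H"]] + .atomic_mass[["O"]]
.mass_H2  <- 2 * .atomic_mass[["H"]]
# one added methyl replaces H with CH3, net +CH2
.mass_CH2 <- .atomic_mass[["C"]] + 2 * .atomic_mass[["H"]]
# CD3 vs CH3: 3 x (D - H)
.mass_cd3_shift <- 3 * (.atomic_mass[["D"]] - .atomic_mass[["H"]])

# Glycosidically linked residue formulas (monosaccharide minus water) and the
# number of derivatizable positions (OH + amide NH + carboxyl) on the FREE
# monosaccharide.  Each glycosidic bond in a glycan consumes two positions
# (the anomeric OH of one partner and a hydroxyl of the other).
.residues <- data.frame(
  name   = c("Hex", "HexNAc", "dHex", "Pent", "Neu5Ac", "Neu5Gc"),
  C      = c(6, 8, 6, 5, 11, 11),
  H      = c(10, 13, 10, 8, 17, 17),
  N      = c(0, 1, 0, 0, 1, 1),
  O      = c(5, 5, 4, 4, 8, 9),
  free_sites = c(5, 5, 4, 4, 7, 8),
  stringsAsFactors = FALSE
)

.formula_mass <- function(C, H, N, O) {
  C * .atomic_mass[["C"]] + H * .atomic_mass[["H"]] +
    N * .atomic_mass[["N"]] + O * .atomic_mass[["O"]]
}

#' Monosaccharide residue table
#'
#' Residues supported by the glycan-annotation stage, with the elemental
#' formula of the glycosidically linked residue (monosaccharide minus water),
#' its monoisotopic mass, and the number of derivatizable positions
#' (hydroxyl, amide NH and carboxyl hydrogens) on the free monosaccharide.
#' `Hex` covers all hexoses (Gal/Man/Glc), `HexNAc` both GalNAc and GlcNAc,
#' `dHex` deoxyhexoses such as fucose, and `Pent` pentoses such as xylose:
#' these isomer families are mass-degenerate and cannot be distinguished by
#' MALDI composition profiling.
#'
#' @return A data frame with columns `name`, `C`, `H`, `N`, `O`, `mass`
#'   (monoisotopic residue mass, Da) and `free_sites`.
#' @export
#' @examples
#' residue_table()
residue_table <- function() {
  out <- .residues
  out$mass <- .formula_mass(out$C, out$H, out$N, out$O)
  out[, c("name", "C", "H", "N", "O", "mass", "free_sites")]
}

#' Construct a glycan composition
#'
#' A glycan composition is a multiset of monosaccharide residues together with
#' a count of *native* methyl groups (methyls present on the glycan in vivo,
#' which occupy derivatization sites and therefore reduce the heavy-vs-light
#' permethylation mass shift) and a glycan class.  O-glycans released by
#' reductive beta-elimination are open-ring alditols (`"O-alditol"`);
#' PNGase-released N-glycans retain a free reducing end (`"N-free"`).
#'
#' @param counts Named integer vector of residue counts; names must be a
#'   subset of `residue_table()$name`.
#' @param n_native_me Number of native methyl groups (default 0).  Must not
#'   exceed [methylation_sites()] of the composition.
#' @param glycan_class `"O-alditol"` or `"N-free"`.
#' @return An object of class `glycan_composition`.
#' @seealso [permethylated_mass()], [methylation_sites()]
#' @export
#' @examples
#' core1 <- glycan_composition(c(Hex = 1, HexNAc = 1))  # T-antigen alditol
#' methylation_sites(core1)
glycan_composition <- function(counts, n_native_me = 0L,
                               glycan_class = c("O-alditol", "N-free")) {
  glycan_class <- match.arg(glycan_class)
  if (is.null(names(counts)) || any(!nzchar(names(counts))))
    stop("`counts` must be a named vector of residue counts")
  unknown <- setdiff(names(counts), .residues$name)
  if (length(unknown))
    stop("unknown residue(s): ", paste(unknown, collapse = ", "),
         "; supported residues are: ", paste(.residues$name, collapse = ", "))
  counts <- counts[counts > 0]
  if (any(counts != round(counts)) || any(counts < 0))
    stop("residue counts must be non-negative integers")
  if (sum(counts) < 1) stop("a composition needs at least one residue")
  comp <- structure(
    list(counts = vapply(counts, as.integer, integer(1)),
         n_native_me = as.integer(n_native_me),
         glycan_class = glycan_class),
    class = "glycan_composition"
  )
  sites <- methylation_sites(comp)
  if (sites == 0 && comp$n_native_me > 0)
    stop("composition has no methylation sites but nonzero native methyls")
  if (comp$n_native_me < 0 || comp$n_native_me > sites)
    stop("n_native_me must lie in [0, ", sites, "] for this composition")
  comp
}

#' Number of derivatizable (methylation) sites of a composition
#'
#' Total free-monosaccharide sites minus two per glycosidic bond
#' (`n_residues - 1` bonds for any tree topology), plus one extra hydroxyl for
#' the open-ring alditol terminus of reduced O-glycans.
#'
#' @param comp A [glycan_composition()].
#' @return Integer site count.
#' @export
methylation_sites <- function(comp) {
  stopifnot(inherits(comp, "glycan_composition"))
  idx <- match(names(comp$counts), .residues$name)
  n_res <- sum(comp$counts)
  sites <- sum(comp$counts * .residues$free_sites[idx]) - 2L * (n_res - 1L)
  if (comp$glycan_class == "O-alditol") sites <- sites + 1L
  as.integer(sites)
}

# neutral monoisotopic mass of the fully (per)methylated glycan, light run
.neutral_permethylated_mass <- function(comp) {
  idx <- match(names(comp$counts), .residues$name)
  res_mass <- .formula_mass(.residues$C[idx], .residues$H[idx],
                            .residues$N[idx], .residues$O[idx])
  m <- sum(comp$counts * res_mass) + .mass_H2O
  if (comp$glycan_class == "O-alditol") m <- m + .mass_H2
  m + methylation_sites(comp) * .mass_CH2
}

#' Theoretical m/z of a permethylated glycan
#'
#' Computes the `[M+Na]+` m/z of a permethylated composition.  In the light
#' run every methyl is CH3, so native and added methyls are indistinguishable
#' and the mass does not depend on `n_native_me`.  In the heavy run the
#' *added* methyls are CD3 (iodomethane-D3) while native methyls remain CH3,
#' so each added site contributes an extra `3 x (m(2H) - m(1H)) = 3.01883` Da.
#'
#' @param comp A [glycan_composition()].
#' @param run `"light"` (CH3I) or `"heavy"` (CD3I).
#' @return Theoretical m/z (Da) of the sodiated, singly charged ion.  The
#'   electron mass is neglected, as in standard permethylated-glycan tables.
#' @export
#' @examples
#' core1 <- glycan_composition(c(Hex = 1, HexNAc = 1))
#' permethylated_mass(core1)            # ~534.29
#' permethylated_mass(core1, "heavy")   # shifted by 9 added CD3
permethylated_mass <- function(comp, run = c("light", "heavy")) {
  run <- match.arg(run)
  stopifnot(inherits(comp, "glycan_composition"))
  m <- .neutral_permethylated_mass(comp) + .atomic_mass[["Na"]]
  if (run == "heavy") {
    n_added <- methylation_sites(comp) - comp$n_native_me
    m <- m + n_added * .mass_cd3_shift
  }
  m
}

#' @export
format.glycan_composition <- function(x, ...) {
  me <- if (x$n_native_me == 1) "(Me)" else
    if (x$n_native_me > 1) sprintf("(Me%d)", x$n_native_me) else ""
  ord <- c("Neu5Ac", "Neu5Gc", "dHex", "Pent", "Hex", "HexNAc")
  cn <- x$counts[order(match(names(x$counts), ord))]
  body <- paste0(vapply(seq_along(cn), function(i) {
    if (cn[i] == 1) names(cn)[i] else sprintf("%s%d", names(cn)[i], cn[i])
  }, character(1)), collapse = "")
  paste0(me, body, if (x$glycan_class == "O-alditol") "-ol" else "")
}

#' @export
print.glycan_composition <- function(x, ...) {
  cat(format(x), " [", x$glycan_class, ", ",
      methylation_sites(x), " sites, ", x$n_native_me, " native Me]\n",
      sep = "")
  invisible(x)
}

#' @export
as.character.glycan_composition <- function(x, ...) format(x)
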