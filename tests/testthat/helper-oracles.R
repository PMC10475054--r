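# Independent oracles used across the suite.  Everything here is computed by
# a different route than the package code (explicit formula strings, direct
# quadrature, row-by-row predicates) so the two can disagree.

# -- elemental-formula mass oracle ----------------------------------------
# monoisotopic masses typed independently (NIST listing, more digits kept)
.orc_atomic <- c(H = 1.00782503207, D = 2.01410177785, C = 12.0,
                 N = 14.0030740048, O = 15.9949146196, Na = 22.9897692809)

# parse "C23H45NO11Na" -> mass
oracle_formula_mass <- function(formula) {
  m <- gregexpr("([A-Z][a-z]?)([0-9]*)", formula)[[1]]
  parts <- regmatches(formula, gregexpr("([A-Z][a-z]?)([0-9]*)", formula))[[1]]
  total <- 0
  for (p in parts) {
    sym <- gsub("[0-9]", "", p)
    cnt <- gsub("[^0-9]", "", p)
    cnt <- if (nzchar(cnt)) as.numeric(cnt) else 1
    if (!sym %in% names(.orc_atomic)) stop("oracle: unknown element ", sym)
    total <- total + cnt * .orc_atomic[[sym]]
  }
  total
}

# residue formulas written out from the underivatized structures
oracle_residue_formulas <- c(
  Hex = "C6H10O5", HexNAc = "C8H13NO5", dHex = "C6H10O4",
  Pent = "C5H8O4", Neu5Ac = "C11H17NO8", Neu5Gc = "C11H17NO9"
)

oracle_cd3_shift <- 3 * (.orc_atomic[["D"]] - .orc_atomic[["H"]])

# -- JKR closed forms ------------------------------------------------------
oracle_a0 <- function(E, delta_r, R) (9 * pi * R^2 * delta_r / (2 * E))^(1 / 3)
oracle_pull_off <- function(delta_r, R) -1.5 * pi * delta_r * R

# enclosed hysteresis area of the reversible JKR loop (quadrature, not
# trapezoids on the sampled grid): A = (3/4) * pi * delta_r * a0^2 * I
oracle_loop_area <- function(E, delta_r, R) {
  a0 <- oracle_a0(E, delta_r, R)
  I <- integrate(function(u) {
    m <- (1 + u) / 2
    (1 - u^2) * ((4 / 3) * m^(1 / 3) - (2 / 9) * m^(-2 / 3))
  }, 0, 1, rel.tol = 1e-12)$value
  (3 / 4) * pi * delta_r * a0^2 * I
}

# depth at load P, direct evaluation
oracle_depth <- function(P, E, delta_r, R) {
  a0 <- oracle_a0(E, delta_r, R)
  Pa <- oracle_pull_off(delta_r, R)
  m <- (1 + sqrt(1 - P / Pa)) / 2
  (a0^2 / R) * m^(4 / 3) - (2 / 3) * (a0^2 / R) * m^(1 / 3)
}

# -- brute-force identification filters ------------------------------------
oracle_filter_ids <- function(records, min_peptides = 2, max_fdr = 0.01,
                              peptide_prob_min = 0.95,
                              protein_threshold = 0.05,
                              protein_rule = "as_printed") {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    ok <- TRUE
    if (r$n_peptides < min_peptides) ok <- FALSE
    if (!(r$local_fdr < max_fdr)) ok <- FALSE
    if (r$peptide_prob < peptide_prob_min) ok <- FALSE
    need <- if (protein_rule == "as_printed") protein_threshold
    else 1 - protein_threshold
    if (r$protein_prob < need) ok <- FALSE
    keep[i] <- ok
  }
  records[keep, , drop = FALSE]
}

oracle_filter_glyco <- function(records, min_log_prob = 3,
                                min_delta_mod = 50) {
  keep <- logical(nrow(records))
  for (i in seq_len(nrow(records))) {
    keep[i] <- records$log_prob_abs[i] >= min_log_prob &&
      records$delta_mod_score[i] >= min_delta_mod
  }
  records[keep, , drop = FALSE]
}

# -- random generators -----------------------------------------------------
random_composition <- function(bounds = default_residue_bounds()) {
  repeat {
    counts <- vapply(bounds, function(b) sample(0:min(b, 3), 1), integer(1))
    if (sum(counts) >= 1 && sum(counts) <= 7) break
  }
  cls <- sample(c("O-alditol", "N-free"), 1)
  comp0 <- glycan_composition(counts[counts > 0], glycan_class = cls)
  glycan_composition(counts[counts > 0],
                     n_native_me = sample(0:methylation_sites(comp0), 1),
                     glycan_class = cls)
}

random_id_table <- function(n) {
  data.frame(
    protein_id = sprintf("r%04d", seq_len(n)),
    category = sample(c("matrix", "lectin", "enzyme", "mucin"), n, TRUE),
    n_peptides = sample(0:6, n, TRUE),
    peptide_prob = runif(n),
    protein_prob = runif(n),
    local_fdr = runif(n, 0, 0.05),
    msms_adhesive = rpois(n, 20) + 1L,
    msms_protective = rpois(n, 20) + 1L
  )
}
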