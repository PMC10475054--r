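test_that("residue masses agree with the elemental-formula oracle", {
  tab <- residue_table()
  for (i in seq_len(nrow(tab))) {
    expect_lt(abs(tab$mass[i] -
                    oracle_formula_mass(oracle_residue_formulas[[tab$name[i]]])),
              1e-4)
  }
  # frozen literature residue masses as a second, independent anchor
  lit <- c(Hex = 162.0528, HexNAc = 203.0794, dHex = 146.0579,
           Pent = 132.0423, Neu5Ac = 291.0954, Neu5Gc = 307.0903)
  expect_equal(setNames(tab$mass, tab$name)[names(lit)], lit,
               tolerance = 1e-6)
})

test_that("permethylated masses follow the derivatization arithmetic", {
  # core-1 alditol: C14H27NO11 free-reduced glycan + 9 CH2 = C23H45NO11, +Na
  core1 <- glycan_composition(c(Hex = 1, HexNAc = 1))
  expect_identical(methylation_sites(core1), 9L)
  expect_lt(abs(permethylated_mass(core1) -
                  (oracle_formula_mass("C23H45NO11") + .orc_atomic[["Na"]])),
            1e-4)
  expect_equal(permethylated_mass(core1), 534.3, tolerance = 1e-4)
  # heavy-minus-light shift is 3.01883 per added methyl
  for (nn in 0:3) {
    cmp <- glycan_composition(c(Hex = 2, HexNAc = 1), n_native_me = nn)
    expect_equal(permethylated_mass(cmp, "heavy") - permethylated_mass(cmp),
                 (methylation_sites(cmp) - nn) * oracle_cd3_shift,
                 tolerance = 1e-9)
  }
  # fully natively methylated: heavy == light
  cN <- glycan_composition(c(Hex = 1), n_native_me = 6)
  expect_identical(methylation_sites(cN), 6L)  # alditol single hexose
  expect_equal(permethylated_mass(cN, "heavy"), permethylated_mass(cN))
  # N-free glycans lack the alditol corrections
  cfree <- glycan_composition(c(Hex = 1, HexNAc = 1), glycan_class = "N-free")
  expect_identical(methylation_sites(cfree), 8L)
  expect_lt(permethylated_mass(cfree), permethylated_mass(core1))
})

test_that("compositions validate residues and native-methyl bounds", {
  expect_error(glycan_composition(c(Glc = 1)), "supported residues")
  expect_error(glycan_composition(c(Hex = 0)), "at least one")
  expect_error(glycan_composition(c(Hex = 1), n_native_me = 7), "n_native_me")
  expect_match(format(glycan_composition(c(Hex = 2, HexNAc = 1),
                                         n_native_me = 2)),
               "^\\(Me2\\)Hex2HexNAc-ol$")
})

test_that("mass decomposition ranks the true composition first", {
  truth <- glycan_composition(c(Hex = 1, HexNAc = 1))  # (Gal)GalNAc-ol
  cand <- decompose_mass(permethylated_mass(truth), tolerance = 0.2)
  expect_gt(nrow(cand), 0)
  expect_identical(cand$label[1], "HexHexNAc-ol")
  expect_lt(abs(cand$error[1]), 1e-9)
  # zero tolerance rejects any jittered input; negative tolerance is an error
  expect_identical(nrow(decompose_mass(permethylated_mass(truth) + 1e-3,
                                       tolerance = 0)), 0L)
  expect_error(decompose_mass(534.3, tolerance = -0.1), "tolerance")
  off <- decompose_mass(permethylated_mass(truth) + 0.15, tolerance = 0.05)
  expect_identical(nrow(off), 0L)
  # native-methyl enumeration expands each candidate over 0..sites
  full <- decompose_mass(permethylated_mass(truth), tolerance = 0.2,
                         enumerate_native = TRUE)
  expect_setequal(full$n_native_me[full$Hex == 1 & full$HexNAc == 1 &
                                     full$dHex == 0], 0:9)
  expect_gt(nrow(full), nrow(cand))
})

test_that("decomposition round trip contains every random composition", {
  set.seed(1203)
  for (rep in 1:60) {
    comp <- random_composition()
    cand <- decompose_mass(permethylated_mass(comp), tolerance = 0.2,
                           glycan_class = comp$glycan_class)
    counts <- setNames(rep(0L, 6), residue_table()$name)
    counts[names(comp$counts)] <- comp$counts
    hit <- vapply(seq_len(nrow(cand)), function(i)
      all(unlist(cand[i, names(counts)]) == counts), logical(1))
    expect_true(any(hit), label = format(comp))
  }
})

test_that("native methylation is inferred from the heavy-light shift", {
  comp <- glycan_composition(c(Hex = 2, HexNAc = 1))  # 12 sites
  base <- permethylated_mass(comp)
  # all methyls added
  r0 <- infer_native_methylation(base, base + 12 * oracle_cd3_shift, comp)
  expect_identical(r0$n_native, 0L)
  expect_true(r0$consistent)
  # shift smaller by exactly 2 x 3.01883 -> two native methyls
  r2 <- infer_native_methylation(base, base + 10 * oracle_cd3_shift, comp)
  expect_identical(r2$n_native, 2L)
  # rounding residual flagged
  rr <- infer_native_methylation(base, base + 10 * oracle_cd3_shift + 0.9,
                                 comp, tolerance = 0.2)
  expect_false(rr$consistent)
  # more added methyls than sites is an inconsistency error
  expect_error(
    infer_native_methylation(base, base + 13 * oracle_cd3_shift, comp),
    "inconsistent")
})

test_that("simulated light/heavy pairs recover planted native-methyl counts", {
  set.seed(77)
  done <- 0
  while (done < 40) {
    comp <- random_composition()
    pk <- simulate_peaklists(glycan_profile_spec(list(comp), 1))
    cand <- decompose_mass(pk$light$mz, tolerance = 0.2,
                           glycan_class = comp$glycan_class)
    counts <- setNames(rep(0L, 6), residue_table()$name)
    counts[names(comp$counts)] <- comp$counts
    hit <- which(vapply(seq_len(nrow(cand)), function(i)
      all(unlist(cand[i, names(counts)]) == counts), logical(1)))[1]
    expect_false(is.na(hit))
    inf <- infer_native_methylation(pk$light$mz, pk$heavy$mz, comp)
    expect_identical(inf$n_native, comp$n_native_me)
    expect_true(inf$consistent)
    done <- done + 1
  }
})

test_that("relative abundances conserve intensity and apply the 5% rule", {
  one <- relative_abundance(data.frame(label = "x", intensity = 3))
  expect_equal(one$fraction, 1)
  mixed <- relative_abundance(data.frame(
    label = c("a", "b", "c"), intensity = c(90.2, 4.9, 4.9)))
  expect_equal(sum(mixed$fraction), 1, tolerance = 1e-12)
  expect_identical(mixed$major, c(TRUE, FALSE, FALSE))  # 4.9% kept as trace
  expect_identical(nrow(mixed), 3L)
  expect_error(relative_abundance(data.frame(label = "a", intensity = 0)),
               "zero total")
})

test_that("annotation resolves mass-degenerate methylation variants", {
  # the three methylation states of Hex2HexNAc-ol share one light peak;
  # the heavy run must split them back into 27/8/6
  prf <- profile_compositions(oglycan_reference_profiles()$adhesive)
  pk <- simulate_peaklists(glycan_profile_spec(prf$compositions, prf$fractions))
  expect_lt(nrow(pk$light), length(prf$compositions))  # merged light peaks
  g <- annotate_glycans(pk)
  got <- setNames(round(100 * g$fraction, 6), g$label)
  expect_equal(got[["HexHexNAc-ol"]], 52)
  expect_equal(got[["(Me2)Hex2HexNAc-ol"]], 27)
  expect_equal(got[["(Me)Hex2HexNAc-ol"]], 8)
  expect_equal(got[["Hex2HexNAc-ol"]], 6)
  expect_equal(sum(g$fraction), 1, tolerance = 1e-12)
  expect_setequal(g$label[g$major],
                  c("HexHexNAc-ol", "(Me2)Hex2HexNAc-ol",
                    "(Me)Hex2HexNAc-ol", "Hex2HexNAc-ol"))
})

test_that("inferred methylation is invariant to intensity rescaling", {
  prf <- profile_compositions(oglycan_reference_profiles()$protective)
  pk <- simulate_peaklists(glycan_profile_spec(prf$compositions, prf$fractions,
                                               intensity_scale = 1e4))
  pk2 <- pk
  pk2$light$intensity <- pk2$light$intensity * 7.5
  pk2$heavy$intensity <- pk2$heavy$intensity * 0.3
  g1 <- annotate_glycans(pk)
  g2 <- annotate_glycans(pk2)
  expect_identical(setNames(g1$n_native_me, g1$label),
                   setNames(g2$n_native_me, g2$label))
  expect_equal(g1$fraction, g2$fraction, tolerance = 1e-12)
})
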