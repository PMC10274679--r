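test_that("FPOP offset table has the 14 standard rows with 4-dp masses", {
  offs <- fpopOffsetTable()
  expect_length(offs, 14L)
  expect_true(all(vapply(offs, modClass, character(1L)) == "offset"))
  byName <- setNames(offs, vapply(offs, modName, character(1L)))
  expect_equal(massDelta(byName[["Oxidation"]]), 15.9949)
  expect_setequal(modResidues(byName[["Oxidation"]]),
                  strsplit("MFHILVWYADEKNPQR", "")[[1L]])
  expect_equal(massDelta(byName[["Arg deguanidation"]]), -43.0534)
  expect_equal(modResidues(byName[["Arg deguanidation"]]), "R")
  expect_equal(massDelta(byName[["Dioxidation"]]), 31.9898)
  expect_equal(massDelta(byName[["CO2 loss"]]), -43.9898)
  expect_equal(massDelta(byName[["Carbonylation"]]), 13.9793)
  ## stored masses round-trip at the printed 4-decimal precision
  printed <- c(15.9949, 31.9898, 47.9847, 13.9793, -43.0534, -22.0320,
               -23.0160, -10.0320, 4.9735, -30.0106, -27.9949, -43.9898,
               -25.0316, -9.0367)
  expect_equal(round(vapply(offs, massDelta, numeric(1L)), 4L), printed)
})

test_that("carbamidomethyl-adjusted Cys oxidation offsets match printed values", {
  chem <- list(
    Modification("C dioxidation", 2 * 15.994915, "C", modClass = "offset"),
    Modification("C trioxidation", 3 * 15.994915, "C", modClass = "offset"),
    ## multi-residue oxidation must pass through unchanged (not Cys-only)
    Modification("Dioxidation", 31.9898, "CFMWY", modClass = "offset"))
  adj <- adjustOffsetsForFixedMods(chem, list(camC))
  expect_equal(round(massDelta(adj[[1L]]), 4L), -25.0316)
  expect_equal(round(massDelta(adj[[2L]]), 4L), -9.0367)
  expect_equal(massDelta(adj[[3L]]), 31.9898)
  ## identity with no fixed mods
  expect_equal(vapply(adjustOffsetsForFixedMods(chem, list()), massDelta,
                      numeric(1L)),
               vapply(chem, massDelta, numeric(1L)))
  ## near-collision on a shared residue is flagged
  near <- list(
    Modification("x", 10.0000, "CW", modClass = "offset"),  # passes through
    Modification("y", 10.0003 + 57.021464, "C", modClass = "offset"))
  expect_warning(adjustOffsetsForFixedMods(near, list(camC)), "collides")
})

test_that("search-space combinatorics reproduce the worked 20-mer example", {
  spec20 <- c(M = 1, S = 3, other = 16)
  expect_identical(countConfigurations(spec20, list(metOx)), 2)
  expect_identical(countConfigurations(spec20, list(metOx, serPhospho)), 16)
  m1 <- Modification("m1", 1.0, "A"); m2 <- Modification("m2", 2.0, "A")
  expect_identical(countConfigurations(c(A = 20), list(m1, m2)), 3486784401)
  expect_error(countConfigurations(c(M = -1), list(metOx)), "negative")
})

test_that("offset-only and residue-spec counting agree with concrete forms", {
  diox <- Modification("Dioxidation", 31.9898, "CFMWY", modClass = "offset")
  ## offset-only: 1 unmodified + 1 per applicable offset
  expect_identical(countConfigurations("MWK", list(metOx, diox),
                                       scheme = "offset_only"), 3)
  expect_identical(countConfigurations("AGK", list(metOx, diox),
                                       scheme = "offset_only"), 1)
  ## residue-count spec equals an equivalent concrete sequence under hybrid
  mods <- list(metOx, diox)
  expect_identical(
    countConfigurations(c(M = 1, W = 2, A = 3), mods, scheme = "hybrid",
                        maxVarMods = 3),
    countConfigurations("MWWAAA", mods, scheme = "hybrid", maxVarMods = 3))
})

test_that("capped counts and concrete sequences agree with enumeration", {
  sp <- smallHybridSpace()
  for (seq in c("MKSSSR", "PEPTIDE", "MWMWR", "ACDMFK", "WRRMMK")) {
    mods <- c(variableMods(sp),
              Filter(function(m) massDelta(m) != 0, massOffsets(sp)))
    expect_identical(
      countConfigurations(seq, mods, scheme = "hybrid",
                          maxVarMods = maxVarMods(sp)),
      as.numeric(length(enumeratePeptidoforms(seq, sp))),
      info = seq)
  }
})

test_that("peptidoform enumeration follows the hybrid constraint", {
  ## no variable mods + only zero offset: exactly the unmodified form
  expect_length(enumeratePeptidoforms("PEPTIDE", ModificationSpace()), 1L)
  ## 1 Met, Met-ox variable, zero offset only: modified + unmodified
  sp <- ModificationSpace(variable = metOx)
  expect_length(enumeratePeptidoforms("MKSSSR", sp), 2L)
  ## unknown residue is rejected naming the character
  expect_error(enumeratePeptidoforms("PEPTIDEB", sp), "'B'")
  ## at most one non-zero offset anywhere in the space
  pfs <- enumeratePeptidoforms("MWMWR", smallHybridSpace())
  nOffsets <- vapply(pfs, function(pf)
    sum(massDelta(appliedOffset(pf)) != 0), numeric(1L))
  expect_true(all(nOffsets <= 1L))
  ## no duplicate site assignments
  keys <- vapply(pfs, function(pf) {
    vm <- varModSites(pf)
    paste(pepSequence(pf), paste(vm$pos, vm$mass, collapse = "|"),
          modName(appliedOffset(pf)))
  }, character(1L))
  expect_false(anyDuplicated(keys) > 0L)
  ## total mass identity to 1e-4 Da
  for (pf in pfs[1:5]) {
    vm <- varModSites(pf)
    expected <- peptideMass(pepSequence(pf)) + sum(vm$mass) +
      massDelta(appliedOffset(pf))
    expect_equal(totalMass(pf), expected, tolerance = 1e-4)
  }
})

test_that("enumeration count matches an independent exhaustive oracle", {
  set.seed(401)
  offsets <- list(
    Modification("Dioxidation", 31.9898, "CFMWY", modClass = "offset"),
    Modification("Deguanidation", -43.0534, "R", modClass = "offset"))
  for (rep in 1:12) {
    len <- sample(4:9, 1L)
    seq <- paste(sample(c("M", "S", "W", "R", "A", "G", "K"), len,
                        replace = TRUE), collapse = "")
    cap <- sample(0:3, 1L)
    sp <- ModificationSpace(variable = list(metOx, serPhospho),
                            offsets = offsets, maxVarMods = cap)
    expect_identical(
      length(enumeratePeptidoforms(seq, sp)),
      as.integer(bruteForceHybridCount(seq, list(metOx, serPhospho),
                                       offsets, cap)),
      info = sprintf("%s cap=%d", seq, cap))
  }
})

test_that("hybrid count is bounded by the all-variable count and is monotone", {
  set.seed(402)
  a <- Modification("a", 1.0, "MW"); b <- Modification("b", 2.0, "WR")
  for (rep in 1:10) {
    len <- sample(4:8, 1L)
    seq <- paste(sample(c("M", "W", "R", "A", "K"), len, replace = TRUE),
                 collapse = "")
    hybrid <- countConfigurations(
      seq, list(a, Modification("b", 2.0, "WR", modClass = "offset")),
      scheme = "hybrid", maxVarMods = Inf)
    allVar <- countConfigurations(seq, list(a, b),
                                  scheme = "variable_only", maxVarMods = Inf)
    expect_lte(hybrid, allVar)
    ## promoting b from offset to variable never decreases the count
    ## (at unlimited cap)
    expect_gte(allVar, hybrid)
    ## moving a mod from offsets to variable, other mod fixed as variable
    offOnly <- countConfigurations(
      seq, list(Modification("a", 1.0, "MW", modClass = "offset"),
                Modification("b", 2.0, "WR", modClass = "offset")),
      scheme = "hybrid", maxVarMods = Inf)
    expect_gte(hybrid, offOnly)
  }
})

test_that("modification space enforces its structural invariants", {
  expect_error(
    ModificationSpace(variable = metOx,
                      offsets = list(
                        Modification("Ox", 15.9949, "M",
                                     modClass = "offset"))),
    "both variable and offsets")
  sp <- ModificationSpace(variable = metOx)
  expect_equal(sum(vapply(massOffsets(sp), function(m) massDelta(m) == 0,
                          logical(1L))), 1L)
  expect_error(Modification("bad", 0, "M", modClass = "variable"))
})
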