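peps1 <- data.frame(sequence = "PEPTIDEK", parent_accession = "P1",
                    missed_cleavages = 0L, is_nterm_of_protein = FALSE,
                    is_decoy = FALSE)
peps1$mass <- peptideMass("PEPTIDEK")

test_that("fragment index stores every fragment retrievably in one bin", {
  idx <- buildFragmentIndex(peps1, ModificationSpace(), binWidth = 0.02,
                            maxFragmentCharge = 1L)
  expect_s4_class(idx, "FragmentIndex")
  expect_length(idx@entryMz, 14L)   # 7 b + 7 y at charge 1
  ## self-lookup: every fragment found by querying its own m/z
  for (mz in idx@entryMz) {
    hit <- queryFragmentIndex(idx, mz)
    expect_true(any(abs(hit$mz - mz) < 1e-9))
  }
  ## doubling the bin width never increases the occupied-bin count
  idx2 <- buildFragmentIndex(peps1, ModificationSpace(), binWidth = 0.04,
                             maxFragmentCharge = 1L)
  expect_lte(binCount(idx2), binCount(idx))
})

test_that("precursor matching applies offsets with residue specificity", {
  sp <- ModificationSpace(
    fixed = list(camC),
    offsets = list(Modification("Dioxidation", 31.9898, "CFMWY",
                                modClass = "offset")))
  peps <- data.frame(
    sequence = c("PEPTIDEK", "PEWTIDEK"),   # only the second contains W
    parent_accession = "P1", missed_cleavages = 0L,
    is_nterm_of_protein = FALSE, is_decoy = FALSE)
  peps$mass <- vapply(peps$sequence, peptideMass, numeric(1L))
  idx <- buildFragmentIndex(peps, sp)
  mkSpec <- function(M) Spectrum("q", (M + 2 * 1.00727646688) / 2, 2L,
                                 500, 10)
  ## exact mass: zero-offset candidate
  cand <- matchPrecursor(mkSpec(peps$mass[1L]), idx, sp)
  expect_true(any(cand$sequence == "PEPTIDEK" & cand$delta == 0))
  ## +31.9898 on the W-containing peptide: dioxidation candidate
  cand <- matchPrecursor(mkSpec(peps$mass[2L] + 31.9898), idx, sp)
  expect_true(any(cand$sequence == "PEWTIDEK" &
                    cand$offsetName == "Dioxidation"))
  ## +31.9898 on a peptide without C/F/M/W/Y: not a candidate
  cand <- matchPrecursor(mkSpec(peps$mass[1L] + 31.9898), idx, sp)
  expect_false(any(cand$sequence == "PEPTIDEK"))
})

test_that("hyperscore is zero without matches and permutation-invariant", {
  pf <- enumeratePeptidoforms("PEPTIDEK", ModificationSpace())[[1L]]
  empty <- Spectrum("e", 500, 2L, c(3000, 3100), c(5, 5))
  expect_equal(scorePsm(empty, pf)$score, 0)
  clean <- cleanSpectrum("PEPTIDEK")
  s1 <- scorePsm(clean, pf)
  expect_gt(s1$score, 0)
  expect_gte(s1$matchedPeaks, 14L)   # all 14 charge-1 ions present
  ## permuting peak order does not change the score
  pk <- peaks(clean)
  perm <- sample(nrow(pk))
  shuffled <- Spectrum("e2", precursorMz(clean), 2L, pk[perm, 1L],
                       pk[perm, 2L])
  expect_equal(scorePsm(shuffled, pf)$score, s1$score)
})

test_that("a peptidoform outscores decoy peptidoforms on its own spectrum", {
  set.seed(405)
  for (seq in c("PEPTIDEKR", "MWNTYAGLK", "ACDEFGHIK")) {
    pf <- enumeratePeptidoforms(seq, ModificationSpace(
      fixed = list(camC)))[[1L]]
    clean <- cleanSpectrum(seq)
    sTrue <- scorePsm(clean, pf)$score
    rev1 <- paste(rev(strsplit(seq, "")[[1L]]), collapse = "")
    pfRev <- enumeratePeptidoforms(rev1, ModificationSpace(
      fixed = list(camC)))[[1L]]
    expect_gt(sTrue, scorePsm(clean, pfRev)$score)
  }
})

test_that("delta-mass localization recovers planted sites and reports ties", {
  diox <- Modification("Dioxidation", 31.9898, "CFMWY", modClass = "offset")
  spc <- ModificationSpace(fixed = list(camC), offsets = list(diox))
  ## unique W carries the planted dioxidation
  seq <- "PEWTIDAK"
  site <- numeric(nchar(seq)); site[3L] <- 31.9898
  spec <- cleanSpectrum(seq, site)
  pfs <- enumeratePeptidoforms(seq, spc)
  pf <- pfs[[which(vapply(pfs, function(p)
    modName(appliedOffset(p)) == "Dioxidation", logical(1L)))]]
  loc <- localizeDeltaMass(spec, pf)
  expect_equal(loc$position, 2L)   # 0-based position of W
  ## single eligible site returned directly
  expect_length(loc$siteScores, 1L)
  ## two symmetric eligible sites with symmetric fragments tie
  seqSym <- "AWGGGWA"
  pfs <- enumeratePeptidoforms(seqSym, spc)
  pfSym <- pfs[[which(vapply(pfs, function(p)
    modName(appliedOffset(p)) == "Dioxidation", logical(1L)))]]
  ## spectrum with no peaks at all: every placement scores 0
  blank <- Spectrum("blank", (totalMass(pfSym) + 2 * 1.00727646688) / 2, 2L,
                    3000, 1)
  locSym <- localizeDeltaMass(blank, pfSym)
  expect_true(is.na(locSym$position))
  expect_length(locSym$siteScores, 2L)
  ## no eligible site is an error
  pfNone <- enumeratePeptidoforms("PEPTIDAK", ModificationSpace(
    fixed = list(camC)))[[1L]]
  pfBad <- new("Peptidoform", sequence = "PEPTIDAK",
               varModSites = varModSites(pfNone), offset = diox,
               offsetSite = NA_integer_,
               totalMass = totalMass(pfNone) + 31.9898, isNterm = FALSE)
  expect_error(localizeDeltaMass(blank, pfBad), "no eligible site")
})

test_that("indexed and naive searches return identical rank-1 PSMs", {
  bench <- smallBenchmark(nProteins = 3L, nSpectra = 50L, seed = 31L)
  ## restrict to <= 500 peptidoforms for the exhaustive oracle
  peps <- bench$peptides[seq_len(min(60L, nrow(bench$peptides))), ]
  cfg <- workflowConfig("SS_H-I")
  tbl <- fpopseek:::buildPeptidoformTable(peps, cfg$space)
  expect_lte(nrow(tbl), 500L)
  psI <- searchDataset(bench$spectra, peps, cfg$space, cfg$params,
                       method = "index")
  psN <- searchDataset(bench$spectra, peps, cfg$space, cfg$params,
                       method = "naive")
  expect_identical(psI, psN)
})

test_that("noise-free spectra are identified at rank 1 nearly always", {
  bench <- smallBenchmark(
    nProteins = 5L, nSpectra = 100L, seed = 32L,
    noise = noiseModel(mzJitterSd = 0, dropout = 0, nNoisePeaks = 0L,
                       precursorPpmSd = 0))
  cfg <- workflowConfig("SS_H-II")
  psms <- searchDataset(bench$spectra, bench$peptides, cfg$space, cfg$params)
  m <- merge(psms, bench$truth, by.x = "scan", by.y = "scan_id")
  correct <- m$sequence.x == m$sequence.y &
    abs(m$precursor_delta) < 0.01
  expect_gte(sum(correct), 95L)
  ## empty spectra list gives an empty PSM table
  expect_equal(nrow(searchDataset(list(), bench$peptides, cfg$space,
                                  cfg$params)), 0L)
})

test_that("hybrid space covers one rare offset but never two", {
  spc <- smallHybridSpace()
  pfs <- enumeratePeptidoforms("MWRAGK", spc)
  masses <- vapply(pfs, function(p) massDelta(appliedOffset(p)), numeric(1L))
  ## single rare offsets present
  expect_true(any(abs(masses - 31.9898) < 1e-6))
  expect_true(any(abs(masses + 43.0534) < 1e-6))
  ## no peptidoform carries two non-zero offsets (total offset mass is one
  ## delta, never a sum of two)
  expect_false(any(abs(masses - (31.9898 - 43.0534)) < 1e-6))
})
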