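test_that("MGF round-trips spectra and honors default charges", {
  sps <- list(
    Spectrum("scan_1", 500.25, 2L, c(200.1, 300.2, 400.3), c(10, 20, 30),
             12.5),
    Spectrum("scan_2", 612.8312, 3L, c(150.55, 900.12), c(5, 7)),
    Spectrum("scan_3", 433.21, 2L, numeric(), numeric()))
  mgf <- withr::local_tempfile(fileext = ".mgf")
  writeMgf(sps, mgf)
  back <- readSpectra(mgf)
  expect_length(back, 3L)
  expect_equal(scanId(back[[2L]]), "scan_2")
  expect_equal(precursorCharge(back[[2L]]), 3L)
  expect_equal(peaks(back[[1L]])[, 1L], peaks(sps[[1L]])[, 1L],
               tolerance = 1e-4)
  expect_equal(peaks(back[[1L]])[, 2L], peaks(sps[[1L]])[, 2L],
               tolerance = 1e-2)
  ## charge-unassigned block expands to the default charges 2 and 3
  noz <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=x", "PEPMASS=500.5",
               "100.1 5", "END IONS"), noz)
  got <- readSpectra(noz)
  expect_length(got, 2L)
  expect_equal(vapply(got, precursorCharge, integer(1L)), c(2L, 3L))
  ## malformed block is rejected with the block named
  bad <- withr::local_tempfile(fileext = ".mgf")
  writeLines(c("BEGIN IONS", "TITLE=broken", "100.1 5", "END IONS"), bad)
  expect_error(readSpectra(bad), "broken")
})

test_that("mzML twin of an MGF file parses to identical spectra", {
  sps <- smallBenchmark(nProteins = 2L, nSpectra = 4L, seed = 21L)$spectra
  mgf <- withr::local_tempfile(fileext = ".mgf")
  mzml <- withr::local_tempfile(fileext = ".mzML")
  writeMgf(sps, mgf)
  writeMzml(sps, mzml)
  a <- readSpectra(mgf)
  b <- readSpectra(mzml)
  expect_length(b, length(a))
  for (i in seq_along(a)) {
    expect_equal(precursorCharge(b[[i]]), precursorCharge(a[[i]]))
    expect_equal(precursorMz(b[[i]]), precursorMz(a[[i]]), tolerance = 1e-5)
    expect_equal(peaks(b[[i]])[, 1L], peaks(a[[i]])[, 1L], tolerance = 1e-4)
  }
})

test_that("peak filtering keeps top-N by intensity with deterministic ties", {
  sp <- Spectrum("s", 500, 2L, mz = seq(150, 349), intensity = rep(1, 200))
  f <- preprocessSpectrum(sp, topN = 150L, minMz = 100)
  expect_equal(nrow(peaks(f)), 150L)
  ## all-equal intensities: lowest m/z retained
  expect_equal(peaks(f)[, 1L], seq(150, 299))
  ## idempotent
  expect_identical(preprocessSpectrum(f, 150L, 100), f)
  ## topN larger than peak count leaves the spectrum unchanged
  expect_equal(nrow(peaks(preprocessSpectrum(sp, 1000L, 100))), 200L)
  ## minMz removes low peaks
  expect_true(all(peaks(preprocessSpectrum(sp, 150L, 200))[, 1L] >= 200))
})

test_that("theoretical b/y fragments obey counts, shifts and the sum rule", {
  sp <- ModificationSpace(fixed = list(camC), variable = metOx)
  pf0 <- enumeratePeptidoforms("PEPTIDEK", ModificationSpace())[[1L]]
  fr <- theoreticalFragments(pf0, maxFragmentCharge = 1L)
  expect_equal(sum(fr$series == "b"), 7L)
  expect_equal(sum(fr$series == "y"), 7L)
  ## sum rule: b_i + y_(n-i) = M + 2 protons (charge 1)
  b <- fr$mz[fr$series == "b"][order(fr$index[fr$series == "b"])]
  y <- fr$mz[fr$series == "y"][order(fr$index[fr$series == "y"])]
  expect_equal(b + rev(y),
               rep(totalMass(pf0) + 2 * 1.00727646688, 7L),
               tolerance = 1e-3)
  ## Met-ox on the first residue shifts every b ion and no y ion (y_1..y_8
  ## never contain the first residue of a 9-mer)
  pfs <- enumeratePeptidoforms("MPEPTIDEK", sp)
  ox <- pfs[[which(vapply(pfs, function(p) nrow(varModSites(p)) == 1L,
                          logical(1L)))[1L]]]
  un <- pfs[[which(vapply(pfs, function(p) nrow(varModSites(p)) == 0L,
                          logical(1L)))[1L]]]
  fo <- theoreticalFragments(ox, 1L); fu <- theoreticalFragments(un, 1L)
  db <- fo$mz[fo$series == "b"] - fu$mz[fu$series == "b"]
  dy <- fo$mz[fo$series == "y"] - fu$mz[fu$series == "y"]
  expect_equal(db, rep(15.994915, 8L), tolerance = 1e-6)
  expect_equal(dy, rep(0, 8L), tolerance = 1e-6)
})

test_that("fragment m/z agrees with a hand-coded mass table on references", {
  ## independent hand computation from residue masses
  handBY <- function(seq, camFixed = TRUE) {
    masses <- c(G = 57.021464, A = 71.037114, S = 87.032028, P = 97.052764,
                V = 99.068414, T = 101.047678, C = 103.009185,
                L = 113.084064, I = 113.084064, N = 114.042927,
                D = 115.026943, Q = 128.058578, K = 128.094963,
                E = 129.042593, M = 131.040485, H = 137.058912,
                F = 147.068414, R = 156.101111, Y = 163.063329,
                W = 186.079313)
    ch <- strsplit(seq, "")[[1L]]
    r <- masses[ch] + if (camFixed) 57.021464 * (ch == "C") else 0
    n <- length(r)
    list(b = cumsum(r)[-n] + 1.00727646688,
         y = rev(sum(r) - cumsum(r)[-n]) + 18.0105646 + 1.00727646688)
  }
  for (seq in c("PEPTIDEK", "ACDEFGHIK", "MWNTYR")) {
    pf <- enumeratePeptidoforms(seq, ModificationSpace(
      fixed = list(camC)))[[1L]]
    fr <- theoreticalFragments(pf, 1L)
    hb <- handBY(seq)
    expect_equal(fr$mz[fr$series == "b"][order(fr$index[fr$series == "b"])],
                 unname(hb$b), tolerance = 1e-4, info = seq)
    expect_equal(fr$mz[fr$series == "y"][order(fr$index[fr$series == "y"])],
                 unname(hb$y), tolerance = 1e-4, info = seq)
  }
})
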