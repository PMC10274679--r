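## Shared fixtures and independent oracles for the test suite.

metOx <- Modification("Oxidation", 15.994915, "M")
serPhospho <- Modification("Phospho", 79.966331, "S")
camC <- Modification("Carbamidomethyl", 57.021464, "C", modClass = "fixed")

## A small hybrid space: Met oxidation variable, Trp dioxidation and Arg
## deguanidation as offsets.
smallHybridSpace <- function(maxVarMods = 3L) {
  ModificationSpace(
    fixed = list(camC),
    variable = list(metOx),
    offsets = list(
      Modification("Dioxidation", 31.9898, "CFMWY", modClass = "offset"),
      Modification("Arg deguanidation", -43.0534, "R", modClass = "offset")),
    maxVarMods = maxVarMods)
}

## Independent exhaustive oracle for the hybrid peptidoform count: enumerate
## all site assignments by brute force over the power structure, without
## using the package's DP or enumerator internals.
bruteForceHybridCount <- function(sequence, variable, offsets, cap) {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  ## options per position: 0 = free, k = variable mod k
  perPos <- lapply(seq_len(n), function(p) {
    c(0L, which(vapply(variable, function(m)
      chars[p] %in% modResidues(m), logical(1L))))
  })
  grid <- expand.grid(perPos, KEEP.OUT.ATTRS = FALSE)
  keep <- rowSums(grid != 0L) <= cap
  grid <- grid[keep, , drop = FALSE]
  total <- 0L
  for (i in seq_len(nrow(grid))) {
    occupied <- which(unlist(grid[i, ]) != 0L)
    total <- total + 1L   # no offset
    for (off in offsets) {
      if (massDelta(off) == 0) next
      elig <- which(chars %in% modResidues(off))
      if (length(setdiff(elig, occupied)) > 0L) total <- total + 1L
    }
  }
  total
}

## Independent O(n^2) q-value oracle: literal per-threshold counting.
naiveQvalues <- function(score, isDecoy) {
  n <- length(score)
  if (!any(!isDecoy)) return(rep(1, n))
  fdrAt <- vapply(seq_len(n), function(i) {
    above <- score >= score[i]
    sum(isDecoy & above) / max(1, sum(!isDecoy & above))
  }, numeric(1L))
  vapply(seq_len(n), function(i) {
    min(1, min(fdrAt[score <= score[i]]))
  }, numeric(1L))
}

## Render one perfectly clean spectrum (charge-1 b/y, no jitter, no noise)
## for a concrete peptidoform description.
cleanSpectrum <- function(sequence, siteDeltas = numeric(nchar(sequence)),
                         charge = 2L, scan = "clean_1") {
  chars <- strsplit(sequence, "", fixed = TRUE)[[1L]]
  res <- unname(fpopseek:::AA_MASSES[chars]) +
    57.021464 * (chars == "C")
  tot <- res + siteDeltas
  pre <- cumsum(tot)
  n <- length(chars)
  b <- pre[-n] + fpopseek:::MASS_PROTON
  y <- rev(pre[n] - pre[-n]) + 18.0105646 + fpopseek:::MASS_PROTON
  M <- pre[n] + 18.0105646
  Spectrum(scan, (M + charge * fpopseek:::MASS_PROTON) / charge, charge,
           c(b, y), rep(1000, 2L * (n - 1L)))
}

## Modification composition (multiset of event masses) of a PSM row and of a
## truth record; recovery of a planted peptidoform requires the identified
## composition to match, not just the total delta (a 2x oxidation peptide
## identified as one dioxidation offset is NOT a recovery of the planted
## form).
psmEventMasses <- function(psm) {
  ev <- numeric()
  if (nzchar(psm$var_mods)) {
    ev <- vapply(strsplit(psm$var_mods, ",", fixed = TRUE)[[1L]],
                 function(tok) as.numeric(sub(".*/", "", tok)), numeric(1L),
                 USE.NAMES = FALSE)
  }
  if (psm$offset_mass != 0) ev <- c(ev, psm$offset_mass)
  sort(ev)
}

truthEventMasses <- function(mods) {
  if (!nzchar(mods)) return(numeric())
  sort(vapply(strsplit(mods, ";", fixed = TRUE)[[1L]],
              function(tok) as.numeric(strsplit(tok, ":")[[1L]][2L]),
              numeric(1L), USE.NAMES = FALSE))
}

compositionMatches <- function(psm, mods, tol = 0.002) {
  a <- psmEventMasses(psm); b <- truthEventMasses(mods)
  length(a) == length(b) && (length(a) == 0L || all(abs(a - b) <= tol))
}

## Recovery table: passing PSMs joined to truth with composition check.
recoveryTable <- function(psms, truth, assignedMods = "M:15.9949,n:42.0106",
                          threshold = 0.01) {
  f <- groupFdrFilter(psms, assignedMods, threshold)
  pass <- f[f$passes, , drop = FALSE]
  m <- merge(pass, truth, by.x = "scan", by.y = "scan_id")
  m$recovered <- m$sequence.x == m$sequence.y &
    vapply(seq_len(nrow(m)), function(i)
      compositionMatches(m[i, ], m$mods[i]), logical(1L))
  m
}

## Small deterministic synthetic dataset reused across search/FDR tests.
smallBenchmark <- function(nProteins = 5L, nSpectra = 60L, seed = 11L,
                           profile = fpopProfile(), noise = noiseModel()) {
  proteins <- generateProteome(nProteins, 200L, seed = seed)
  peptides <- digestDatabase(appendDecoys(proteins))
  truth <- plantModifications(peptides, nSpectra, profile, seed = seed + 1L)
  spectra <- renderSpectra(truth, noise, seed = seed + 2L)
  list(proteins = proteins, peptides = peptides,
       truth = attr(spectra, "truth"), spectra = spectra)
}
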