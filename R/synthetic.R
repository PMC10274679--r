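## Ground-truthed synthetic FPOP data.  The generator states a world with the
## qualitative structure reported for in-vivo FPOP datasets: modified spectra
## are a minority of all scans (20% by default), methionine oxidation is far
## more abundant than every other FPOP modification (50x by default, within
## the reported 26-90x band), and rare modifications are drawn from the
## standard FPOP offset table.  A small fraction of modified peptides (2%)
## carries two rare modifications at once, the hybrid method's documented
## blind spot.

withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()))
  }
  set.seed(seed)
  expr
}

## UniProt-style average amino-acid frequencies; K+R ~11% keeps tryptic
## peptides of length 7-50 abundant.
AA_FREQS <- c(
  A = 8.25, R = 5.53, N = 4.06, D = 5.45, C = 1.37, Q = 3.93, E = 6.75,
  G = 7.07, H = 2.27, I = 5.96, L = 9.66, K = 5.84, M = 2.42, F = 3.86,
  P = 4.70, S = 6.56, T = 5.34, W = 1.08, Y = 2.92, V = 6.87
) / 100

#' Generate a random protein database
#'
#' Random sequences with realistic amino-acid frequencies, always starting
#' with methionine; deterministic for a given seed (byte-identical FASTA on
#' re-run when written).
#'
#' @param nProteins Number of proteins (>= 1).
#' @param meanLength Mean protein length (lengths are normal with sd
#'   `meanLength / 4`, floored at 50).
#' @param seed Integer RNG seed.
#' @param path Optional FASTA output path.
#' @return Protein data.frame (see [readProteinFasta()]); written to `path`
#'   when given.
#' @export
generateProteome <- function(nProteins = 50L, meanLength = 300L, seed = 42L,
                             path = NULL) {
  if (nProteins < 1L) stop("nProteins must be >= 1", call. = FALSE)
  proteins <- withSeed(seed, {
    lens <- pmax(50L, round(stats::rnorm(nProteins, meanLength,
                                         meanLength / 4)))
    seqs <- vapply(lens, function(n) {
      paste0("M", paste(sample(names(AA_FREQS), n - 1L, replace = TRUE,
                               prob = AA_FREQS), collapse = ""))
    }, character(1L))
    data.frame(
      accession = sprintf("syn|P%04d", seq_len(nProteins)),
      description = sprintf("synthetic protein %d", seq_len(nProteins)),
      sequence = seqs, is_decoy = FALSE, is_contaminant = FALSE,
      stringsAsFactors = FALSE)
  })
  if (!is.null(path)) writeProteinFasta(proteins, path)
  proteins
}

#' Modification-abundance profile for the synthetic generator
#'
#' @param pModified Fraction of spectra carrying any modification (default
#'   0.2: modified PSMs are a minority).
#' @param metOxWeight Relative abundance of Met oxidation vs each other FPOP
#'   modification type (default 50, within the reported 26-90x band).
#' @param pExtraEvent Probability that a modified peptide attempts additional
#'   modification events (up to 3 total); an attempt is skipped when the
#'   drawn modification has no free eligible residue on the peptide.
#' @param pDoubleRare Fraction of modified peptides forced to carry two
#'   distinct rare (non-oxidation) modifications — unidentifiable under the
#'   hybrid single-offset constraint (default 0.02).
#' @return Named list of profile parameters plus the modification universe.
#' @export
fpopProfile <- function(pModified = 0.2, metOxWeight = 50,
                        pExtraEvent = 0.35, pDoubleRare = 0.02) {
  stopifnot(pModified >= 0, pModified <= 1, metOxWeight > 0)
  offs <- fpopOffsetTable()
  labels <- vapply(offs, modName, character(1L))
  ## split oxidation into Met and non-Met types so the abundance weight
  ## targets methionine specifically
  oxi <- which(labels == "Oxidation")
  universe <- list(list(label = "Oxidation", mass = offs[[oxi]]@massDelta,
                        residues = "M", weight = metOxWeight,
                        rare = FALSE))
  universe[[2L]] <- list(label = "Oxidation", mass = offs[[oxi]]@massDelta,
                         residues = setdiff(offs[[oxi]]@residues, "M"),
                         weight = 1, rare = FALSE)
  for (i in setdiff(seq_along(offs), oxi)) {
    universe[[length(universe) + 1L]] <-
      list(label = labels[i], mass = offs[[i]]@massDelta,
           residues = offs[[i]]@residues, weight = 1, rare = TRUE)
  }
  list(pModified = pModified, metOxWeight = metOxWeight,
       pExtraEvent = pExtraEvent, pDoubleRare = pDoubleRare,
       universe = universe)
}

## Free eligible 0-based positions of a universe entry on a sequence.
eligiblePositions <- function(chars, entry, occupied) {
  setdiff(which(chars %in% entry$residues) - 1L, occupied)
}

#' Plant modifications on peptides: ground-truth peptidoforms
#'
#' Draws `n` ground-truth peptidoforms from the target peptides.  Each
#' spectrum slot is modified with probability `pModified`; a modified slot
#' first draws a modification type by abundance weight and then a host
#' peptide carrying a free eligible residue, so type abundances follow the
#' profile rather than residue availability.  Extra events (at most 3 total,
#' at most 1 rare modification unless the slot is a forced double-rare case)
#' are attempted with probability `pExtraEvent` each.
#'
#' @param peptides Digested target-peptide data.frame (decoys excluded
#'   automatically).
#' @param n Number of ground-truth records (spectra) to draw.
#' @param profile Profile from [fpopProfile()].
#' @param seed Integer RNG seed.
#' @return Data.frame of ground-truth records: `scan_id`, `sequence`,
#'   `parent_accession`, `mods` (semicolon-separated `pos1based:mass:label`,
#'   empty for unmodified), `n_ox`, `n_rare`, `n_events`, `total_delta`,
#'   `base_mass`.
#' @export
plantModifications <- function(peptides, n, profile = fpopProfile(),
                               seed = 1L) {
  w <- vapply(profile$universe, function(u) u$weight, numeric(1L))
  if (any(w < 0) || all(w == 0))
    stop("abundances must be >= 0 and not all zero", call. = FALSE)
  peptides <- peptides[!peptides$is_decoy, , drop = FALSE]
  if (nrow(peptides) == 0L) stop("no target peptides", call. = FALSE)
  uni <- profile$universe
  rareIdx <- which(vapply(uni, function(u) u$rare, logical(1L)))
  charsList <- strsplit(peptides$sequence, "", fixed = TRUE)
  ## precompute, per universe entry, which peptides carry an eligible residue
  hosts <- lapply(uni, function(u) {
    which(vapply(charsList, function(ch) any(ch %in% u$residues),
                 logical(1L)))
  })
  ## entries without any host peptide can never be drawn
  w <- w * (lengths(hosts) > 0L)
  if (all(w == 0))
    stop("no modification in the profile is placeable on these peptides",
         call. = FALSE)
  rareIdx <- rareIdx[lengths(hosts)[rareIdx] > 0L]
  withSeed(seed, {
    recs <- vector("list", n)
    for (i in seq_len(n)) {
      modified <- stats::runif(1L) < profile$pModified
      events <- list()   # each: list(pos (0-based), mass, label, rare)
      if (!modified) {
        p <- sample.int(nrow(peptides), 1L)
      } else if (stats::runif(1L) < profile$pDoubleRare &&
                 length(rareIdx) >= 2L) {
        ## forced double-rare: two distinct rare modifications, one peptide
        e1 <- rareIdx[sample.int(length(rareIdx), 1L)]
        p <- hosts[[e1]][sample.int(length(hosts[[e1]]), 1L)]
        ch <- charsList[[p]]
        pos1 <- eligiblePositions(ch, uni[[e1]], integer())
        pos1 <- pos1[sample.int(length(pos1), 1L)]
        events[[1L]] <- list(pos = pos1, mass = uni[[e1]]$mass,
                             label = uni[[e1]]$label, rare = TRUE)
        cands <- setdiff(rareIdx, e1)
        for (e2 in cands[sample.int(length(cands))]) {
          pos2 <- eligiblePositions(ch, uni[[e2]], pos1)
          if (length(pos2)) {
            events[[2L]] <- list(pos = pos2[sample.int(length(pos2), 1L)],
                                 mass = uni[[e2]]$mass,
                                 label = uni[[e2]]$label, rare = TRUE)
            break
          }
        }
      } else {
        e1 <- sample.int(length(uni), 1L, prob = w)
        p <- hosts[[e1]][sample.int(length(hosts[[e1]]), 1L)]
        ch <- charsList[[p]]
        pos1 <- eligiblePositions(ch, uni[[e1]], integer())
        pos1 <- pos1[sample.int(length(pos1), 1L)]
        events[[1L]] <- list(pos = pos1, mass = uni[[e1]]$mass,
                             label = uni[[e1]]$label, rare = uni[[e1]]$rare)
        ## extra events: global-abundance draws, skipped when not placeable
        while (length(events) < 3L &&
               stats::runif(1L) < profile$pExtraEvent) {
          ee <- sample.int(length(uni), 1L, prob = w)
          nRare <- sum(vapply(events, function(x) x$rare, logical(1L)))
          if (uni[[ee]]$rare && nRare >= 1L) break
          occ <- vapply(events, function(x) x$pos, integer(1L))
          pos <- eligiblePositions(ch, uni[[ee]], occ)
          if (length(pos) == 0L) break
          events[[length(events) + 1L]] <-
            list(pos = pos[sample.int(length(pos), 1L)],
                 mass = uni[[ee]]$mass, label = uni[[ee]]$label,
                 rare = uni[[ee]]$rare)
        }
      }
      nOx <- sum(vapply(events, function(x) x$label == "Oxidation",
                        logical(1L)))
      nRare <- sum(vapply(events, function(x) x$rare, logical(1L)))
      modsStr <- if (length(events)) {
        paste(vapply(events, function(x)
          sprintf("%d:%.4f:%s", x$pos + 1L, x$mass, x$label),
          character(1L)), collapse = ";")
      } else ""
      recs[[i]] <- data.frame(
        scan_id = sprintf("syn_%05d", i),
        sequence = peptides$sequence[p],
        parent_accession = peptides$parent_accession[p],
        mods = modsStr, n_ox = nOx, n_rare = nRare,
        n_events = length(events),
        total_delta = sum(vapply(events, function(x) x$mass, numeric(1L))),
        base_mass = peptides$mass[p],
        stringsAsFactors = FALSE)
    }
    do.call(rbind, recs)
  })
}

#' Noise model for spectrum rendering
#'
#' @param mzJitterSd Fragment m/z jitter sd in Da (default 0.003).
#' @param dropout Fraction of fragment peaks dropped (default 0.15).
#' @param nNoisePeaks Count of uniform-m/z noise peaks (default 30).
#' @param intensityMeanLog,intensitySdLog Log-normal fragment intensity
#'   parameters.
#' @param precursorPpmSd Precursor m/z jitter sd in ppm (default 3).
#' @return Named list of noise parameters.
#' @export
noiseModel <- function(mzJitterSd = 0.003, dropout = 0.15, nNoisePeaks = 30L,
                       intensityMeanLog = log(1000), intensitySdLog = 0.5,
                       precursorPpmSd = 3) {
  list(mzJitterSd = mzJitterSd, dropout = dropout,
       nNoisePeaks = as.integer(nNoisePeaks),
       intensityMeanLog = intensityMeanLog, intensitySdLog = intensitySdLog,
       precursorPpmSd = precursorPpmSd)
}

#' Render ground-truth peptidoforms into MS/MS spectra
#'
#' Renders charge-1 b/y fragments of each true peptidoform with m/z jitter
#' and peak dropout, adds uniform noise peaks, and sets the precursor m/z
#' from the true peptidoform mass (with small ppm jitter).  Precursor charge
#' is 2 (70%) or 3 (30%).
#'
#' @param truth Ground-truth data.frame from [plantModifications()].
#' @param noise Noise parameters from [noiseModel()].
#' @param seed Integer RNG seed.
#' @param mgfPath Optional MGF output path (byte-deterministic per seed).
#' @param truthPath Optional TSV output path for the truth table.
#' @return List of [Spectrum-class] objects; the truth table (with a `charge`
#'   column added) is attached as attribute `"truth"`.
#' @export
renderSpectra <- function(truth, noise = noiseModel(), seed = 1L,
                          mgfPath = NULL, truthPath = NULL) {
  spectra <- withSeed(seed, {
    out <- vector("list", nrow(truth))
    charge <- integer(nrow(truth))
    for (i in seq_len(nrow(truth))) {
      seqi <- truth$sequence[i]
      chars <- strsplit(seqi, "", fixed = TRUE)[[1L]]
      nres <- length(chars)
      res <- unname(AA_MASSES[chars]) + MASS_CARBAMIDOMETHYL * (chars == "C")
      site <- numeric(nres)
      if (nzchar(truth$mods[i])) {
        for (tok in strsplit(truth$mods[i], ";", fixed = TRUE)[[1L]]) {
          kv <- strsplit(tok, ":", fixed = TRUE)[[1L]]
          pos <- as.integer(kv[1L])
          site[pos] <- site[pos] + as.numeric(kv[2L])
        }
      }
      fm <- fragmentNeutralMasses(res, site, 0)
      theo <- c(fm$b, fm$y) + MASS_PROTON
      keep <- stats::runif(length(theo)) >= noise$dropout
      mz <- theo[keep] + stats::rnorm(sum(keep), 0, noise$mzJitterSd)
      int <- stats::rlnorm(sum(keep), noise$intensityMeanLog,
                           noise$intensitySdLog)
      if (noise$nNoisePeaks > 0L) {
        nz <- stats::runif(noise$nNoisePeaks, 100, 1600)
        mz <- c(mz, nz)
        int <- c(int, 0.3 * stats::rlnorm(noise$nNoisePeaks,
                                          noise$intensityMeanLog,
                                          noise$intensitySdLog))
      }
      z <- if (stats::runif(1L) < 0.7) 2L else 3L
      charge[i] <- z
      M <- truth$base_mass[i] + truth$total_delta[i]
      pmz <- (M + z * MASS_PROTON) / z
      pmz <- pmz * (1 + stats::rnorm(1L, 0, noise$precursorPpmSd) * 1e-6)
      out[[i]] <- Spectrum(truth$scan_id[i], pmz, z, mz, int,
                           retentionTime = 60 * i / nrow(truth) * 10)
    }
    attr(out, "charge") <- charge
    out
  })
  truth$charge <- attr(spectra, "charge")
  attr(spectra, "charge") <- NULL
  if (!is.null(mgfPath)) writeMgf(spectra, mgfPath)
  if (!is.null(truthPath)) {
    utils::write.table(truth, truthPath, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  attr(spectra, "truth") <- truth
  spectra
}

#' Generate a complete synthetic FPOP benchmark
#'
#' Convenience wrapper: proteome, digested target peptides, planted
#' ground-truth peptidoforms, rendered spectra and truth table.  The default
#' arguments are the package's fixed-seed benchmark (50 proteins of mean
#' length 300, 2000 spectra, seed 42).
#'
#' @param nProteins,meanLength,nSpectra,seed,profile,noise Generator
#'   parameters.
#' @param dir Optional output directory for `proteome.fasta`, `spectra.mgf`
#'   and `truth.tsv`.
#' @return List with `proteins`, `peptides` (digested targets), `truth`,
#'   `spectra`, and (when `dir` is given) the written `paths`.
#' @export
generateBenchmark <- function(nProteins = 50L, meanLength = 300L,
                              nSpectra = 2000L, seed = 42L,
                              profile = fpopProfile(), noise = noiseModel(),
                              dir = NULL) {
  proteins <- generateProteome(nProteins, meanLength, seed = seed)
  peptides <- digestDatabase(proteins)
  truth <- plantModifications(peptides, nSpectra, profile, seed = seed + 1L)
  paths <- NULL
  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    paths <- list(fasta = file.path(dir, "proteome.fasta"),
                  mgf = file.path(dir, "spectra.mgf"),
                  truth = file.path(dir, "truth.tsv"))
    writeProteinFasta(proteins, paths$fasta)
  }
  spectra <- renderSpectra(truth, noise, seed = seed + 2L,
                           mgfPath = paths$mgf, truthPath = paths$truth)
  list(proteins = proteins, peptides = peptides,
       truth = attr(spectra, "truth"), spectra = spectra, paths = paths)
}
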