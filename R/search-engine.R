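## Fragment-indexed hybrid search.  Variable-modification-resolved
## peptidoforms are indexed by neutral mass and by fragment m/z; mass offsets
## are applied at query time as precursor-level shifts (never stored per
## offset), and non-zero offsets are localized by rescoring with shifted
## fragment series at each candidate site.

#' Search parameter set
#'
#' @param precursorTolPpm Precursor mass tolerance in ppm (default 20).
#' @param fragmentTolDa Fragment matching tolerance in Da (default 0.02).
#' @param binWidth Fragment index bin width in Da (default 0.02).
#' @param maxFragmentCharge Highest fragment charge scored (default 2; never
#'   exceeding the precursor charge minus one).
#' @param topN,minMz Peak filtering (see [preprocessSpectrum()]).
#' @param minMatchedPeaks Minimum matched fragment count for a candidate to
#'   be reported at all (default 4): zero-evidence matches otherwise pass
#'   target-decoy filtering through deterministic tie-breaking alone.
#' @return Named list of parameters.
#' @export
searchParams <- function(precursorTolPpm = 20, fragmentTolDa = 0.02,
                         binWidth = 0.02, maxFragmentCharge = 2L,
                         topN = 150L, minMz = 100, minMatchedPeaks = 4L) {
  list(precursorTolPpm = precursorTolPpm, fragmentTolDa = fragmentTolDa,
       binWidth = binWidth, maxFragmentCharge = as.integer(maxFragmentCharge),
       topN = as.integer(topN), minMz = minMz,
       minMatchedPeaks = as.integer(minMatchedPeaks))
}

## ---------------------------------------------------------------------------
## Peptidoform table: variable-mod-resolved forms of a peptide set
## ---------------------------------------------------------------------------

## Enumerate the variable-mod configurations (positions + mod indices) of all
## peptides under `space`, sorted ascending by neutral mass.  Offsets are NOT
## expanded here; they are handled at query time.
buildPeptidoformTable <- function(peptides, space) {
  variable <- space@variable
  cap <- space@maxVarMods
  n <- nrow(peptides)
  pepIdxL <- vector("list", n); massL <- vector("list", n)
  posL <- vector("list", n); modL <- vector("list", n)
  for (i in seq_len(n)) {
    chars <- strsplit(peptides$sequence[i], "", fixed = TRUE)[[1L]]
    sites <- varModSiteStructure(chars, variable,
                                 isNterm = peptides$is_nterm_of_protein[i])
    configs <- list(list(pos = integer(0L), mod = integer(0L), m = 0))
    for (s in sites) {
      add <- list()
      for (cfg in configs) {
        if (length(cfg$pos) >= cap) next
        for (mi in s$mods) {
          add[[length(add) + 1L]] <- list(
            pos = c(cfg$pos, s$pos), mod = c(cfg$mod, mi),
            m = cfg$m + variable[[mi]]@massDelta)
        }
      }
      configs <- c(configs, add)
    }
    nc <- length(configs)
    pepIdxL[[i]] <- rep.int(i, nc)
    massL[[i]] <- peptides$mass[i] +
      vapply(configs, function(cfg) cfg$m, numeric(1L))
    posL[[i]] <- lapply(configs, function(cfg) cfg$pos)
    modL[[i]] <- lapply(configs, function(cfg) cfg$mod)
  }
  pepIdx <- unlist(pepIdxL)
  mass <- unlist(massL)
  posList <- do.call(c, posL)
  modList <- do.call(c, modL)
  o <- order(mass, peptides$sequence[pepIdx], pepIdx)
  tbl <- data.frame(
    pfId = seq_along(o),
    pepIdx = pepIdx[o],
    mass = mass[o],
    stringsAsFactors = FALSE
  )
  tbl$sitesPos <- posList[o]
  tbl$sitesMod <- modList[o]
  tbl$sequence <- peptides$sequence[tbl$pepIdx]
  tbl$isDecoy <- peptides$is_decoy[tbl$pepIdx]
  tbl$isNterm <- peptides$is_nterm_of_protein[tbl$pepIdx]
  tbl
}

## Materialize one row of a peptidoform table as a Peptidoform object.
pfFromTableRow <- function(tbl, row, space, offset = NULL,
                           offsetSite = NA_integer_) {
  variable <- space@variable
  pos <- tbl$sitesPos[[row]]
  mod <- tbl$sitesMod[[row]]
  vm <- data.frame(
    pos = as.integer(pos),
    mass = vapply(mod, function(i) variable[[i]]@massDelta, numeric(1L)),
    name = vapply(mod, function(i) variable[[i]]@name, character(1L)),
    stringsAsFactors = FALSE)
  if (is.null(offset)) offset <- zeroOffset()
  new("Peptidoform", sequence = tbl$sequence[row], varModSites = vm,
      offset = offset, offsetSite = as.integer(offsetSite),
      totalMass = tbl$mass[row] + offset@massDelta,
      isNterm = tbl$isNterm[row])
}

## ---------------------------------------------------------------------------
## FragmentIndex
## ---------------------------------------------------------------------------

#' FragmentIndex: binned fragment ions over a peptidoform table
#'
#' Holds the variable-mod-resolved peptidoform table sorted ascending by
#' neutral mass, the concatenated per-form neutral b/y fragment-mass arrays,
#' and a binned fragment m/z table of fixed bin width mapping each fragment
#' to its (peptidoform, series, index, charge) entry.  Offset mass shifts are
#' applied at query time, never stored per offset.
#'
#' @slot pfTable Peptidoform table (see details), sorted ascending by mass.
#' @slot binWidth Bin width in Da.
#' @slot maxFragmentCharge Highest indexed fragment charge.
#' @slot bMass,yMass Concatenated neutral fragment masses.
#' @slot fragStart Integer offsets: fragments of form i occupy
#'   `fragStart[i] + 1 .. fragStart[i + 1]` in `bMass`/`yMass`.
#' @slot entryMz,entryPf,entrySeries,entryIndex,entryCharge Parallel vectors
#'   of all binned fragment entries, sorted ascending by m/z.
#'
#' @exportClass FragmentIndex
setClass("FragmentIndex",
  representation(
    pfTable = "data.frame",
    binWidth = "numeric",
    maxFragmentCharge = "integer",
    bMass = "numeric",
    yMass = "numeric",
    fragStart = "integer",
    entryMz = "numeric",
    entryPf = "integer",
    entrySeries = "integer",
    entryIndex = "integer",
    entryCharge = "integer"
  )
)

setValidity("FragmentIndex", function(object) {
  msg <- character()
  if (object@binWidth <= 0) msg <- c(msg, "binWidth must be > 0")
  if (nrow(object@pfTable) && is.unsorted(object@pfTable$mass))
    msg <- c(msg, "peptidoform table must be sorted ascending by mass")
  if (length(object@entryMz) > 1L && is.unsorted(object@entryMz))
    msg <- c(msg, "fragment entries must be sorted ascending by m/z")
  if (length(msg)) msg else TRUE
})

setMethod("show", "FragmentIndex", function(object) {
  cat(sprintf(paste0("FragmentIndex: %d peptidoforms, %d fragment entries, ",
                     "bin width %.3f Da, fragment charges 1-%d\n"),
              nrow(object@pfTable), length(object@entryMz),
              object@binWidth, object@maxFragmentCharge))
})

#' Build a fragment-ion index
#'
#' Indexes all unshifted b/y fragments of the variable-mod-resolved
#' peptidoforms of `peptides` under `space`.  Offset shifts are applied at
#' query time (shifted lookup), so the index size is independent of the
#' number of mass offsets searched.
#'
#' @param peptides Digested peptide data.frame (see [digestDatabase()]), or a
#'   prebuilt peptidoform table.
#' @param space A [ModificationSpace-class].
#' @param binWidth Fragment m/z bin width in Da (default 0.02).
#' @param maxFragmentCharge Highest fragment charge indexed (default 2).
#' @param storeEntries Build the binned fragment entry table (default TRUE).
#'   Candidate-driven scoring only needs the per-form fragment arrays, so
#'   [searchDataset()] skips the entry table on large instances.
#' @return A [FragmentIndex-class].
#' @export
buildFragmentIndex <- function(peptides, space, binWidth = 0.02,
                               maxFragmentCharge = 2L, storeEntries = TRUE) {
  stopifnot(binWidth > 0)
  tbl <- if (!is.null(peptides$pfId)) peptides
         else buildPeptidoformTable(peptides, space)
  if (nrow(tbl) == 0L) stop("no peptidoforms to index", call. = FALSE)
  variable <- space@variable
  fixed <- space@fixed
  nf <- nrow(tbl)
  lens <- nchar(tbl$sequence)
  fragStart <- c(0L, cumsum(lens - 1L))
  bAll <- numeric(fragStart[nf + 1L])
  yAll <- numeric(fragStart[nf + 1L])
  ## per-peptide residue-mass cache (fixed mods applied)
  resCache <- new.env(parent = emptyenv())
  varMasses <- vapply(variable, function(m) m@massDelta, numeric(1L))
  for (r in seq_len(nf)) {
    seqr <- tbl$sequence[r]
    res <- get0(seqr, envir = resCache)
    if (is.null(res)) {
      chars <- strsplit(seqr, "", fixed = TRUE)[[1L]]
      res <- unname(AA_MASSES[chars])
      for (fx in fixed) res <- res + fx@massDelta * (chars %in% fx@residues)
      assign(seqr, res, envir = resCache)
    }
    nres <- length(res)
    site <- numeric(nres)
    nterm <- 0
    pos <- tbl$sitesPos[[r]]
    if (length(pos)) {
      dm <- varMasses[tbl$sitesMod[[r]]]
      resi <- pos >= 0L
      if (any(resi)) site[pos[resi] + 1L] <- site[pos[resi] + 1L] + dm[resi]
      nterm <- sum(dm[!resi])
    }
    if (fragStart[r + 1L] > fragStart[r]) {
      fm <- fragmentNeutralMasses(res, site, nterm)
      ix <- (fragStart[r] + 1L):fragStart[r + 1L]
      bAll[ix] <- fm$b
      yAll[ix] <- fm$y
    }
  }
  ## binned entry table over all charges
  if (storeEntries) {
    nfr <- fragStart[nf + 1L]
    pfOfFrag <- rep.int(seq_len(nf), lens - 1L)
    idxOfFrag <- sequence(lens - 1L)
    zs <- seq_len(maxFragmentCharge)
    entryMz <- c(vapply(zs, function(z) (bAll + z * MASS_PROTON) / z,
                        numeric(nfr)),
                 vapply(zs, function(z) (yAll + z * MASS_PROTON) / z,
                        numeric(nfr)))
    entryPf <- rep.int(pfOfFrag, 2L * length(zs))
    entrySeries <- rep(1:2, each = nfr * length(zs))   # 1 = b, 2 = y
    entryIndex <- rep.int(idxOfFrag, 2L * length(zs))
    entryCharge <- rep(rep(zs, each = nfr), 2L)
    o <- order(entryMz)
  } else {
    entryMz <- numeric(); entryPf <- integer(); entrySeries <- integer()
    entryIndex <- integer(); entryCharge <- integer()
    o <- integer()
  }
  new("FragmentIndex",
      pfTable = tbl, binWidth = binWidth,
      maxFragmentCharge = as.integer(maxFragmentCharge),
      bMass = bAll, yMass = yAll, fragStart = fragStart,
      entryMz = entryMz[o], entryPf = entryPf[o],
      entrySeries = entrySeries[o], entryIndex = entryIndex[o],
      entryCharge = entryCharge[o])
}

#' Query a fragment index bin
#'
#' Returns all fragment entries in the bin containing `mz`
#' (bin = `floor(mz / binWidth)`).
#'
#' @param index A [FragmentIndex-class].
#' @param mz Query m/z.
#' @return Data.frame of entries (`mz`, `pfId`, `series`, `index`, `charge`).
#' @export
queryFragmentIndex <- function(index, mz) {
  key <- floor(mz / index@binWidth)
  lo <- key * index@binWidth
  hi <- (key + 1) * index@binWidth
  i0 <- findInterval(lo, index@entryMz, left.open = TRUE) + 1L
  i1 <- findInterval(hi, index@entryMz, left.open = TRUE)
  if (i1 < i0) {
    return(data.frame(mz = numeric(), pfId = integer(), series = character(),
                      index = integer(), charge = integer()))
  }
  sel <- i0:i1
  data.frame(mz = index@entryMz[sel], pfId = index@entryPf[sel],
             series = c("b", "y")[index@entrySeries[sel]],
             index = index@entryIndex[sel],
             charge = index@entryCharge[sel], stringsAsFactors = FALSE)
}

#' Number of occupied bins in a fragment index
#'
#' @param index A [FragmentIndex-class].
#' @return Integer count of distinct occupied m/z bins.
#' @export
binCount <- function(index) {
  length(unique(floor(index@entryMz / index@binWidth)))
}

## ---------------------------------------------------------------------------
## Precursor matching
## ---------------------------------------------------------------------------

## Free eligible 0-based positions of offset `off` on a pfTable row.
freeOffsetSites <- function(chars, occupiedPos, off) {
  elig <- which(chars %in% off@residues) - 1L
  setdiff(elig, occupiedPos[occupiedPos >= 0L])
}

#' Precursor-level candidate generation
#'
#' Returns every indexed variable-mod form whose neutral mass `M` satisfies
#' `|observed - (M + delta)| <= tol` for some allowed offset `delta`
#' (including zero), where a non-zero offset additionally requires at least
#' one eligible residue not occupied by a variable modification in that form.
#'
#' @param spectrum A [Spectrum-class].
#' @param index A [FragmentIndex-class].
#' @param space The [ModificationSpace-class] whose offsets are searched.
#' @param precursorTolPpm Tolerance in ppm of the observed neutral mass.
#' @return Data.frame with columns `pfId`, `sequence`, `offsetIdx` (index
#'   into `massOffsets(space)`), `offsetName`, `delta`.
#' @export
matchPrecursor <- function(spectrum, index, space, precursorTolPpm = 20) {
  stopifnot(precursorTolPpm > 0)
  tbl <- index@pfTable
  pepChars <- lapply(tbl$sequence, function(s)
    strsplit(s, "", fixed = TRUE)[[1L]])
  matchPrecursorCore(precursorMass(spectrum), tbl, space, precursorTolPpm,
                     pepChars, charsByRow = TRUE)
}

## Shared candidate generation over the mass-sorted peptidoform table.
## `pepChars` is indexed by tbl$pepIdx (default) or by table row.
matchPrecursorCore <- function(obs, tbl, space, precursorTolPpm, pepChars,
                               charsByRow = FALSE) {
  tol <- precursorTolPpm * 1e-6 * obs
  masses <- tbl$mass
  out <- list()
  for (oi in seq_along(space@offsets)) {
    off <- space@offsets[[oi]]
    d <- off@massDelta
    i0 <- findInterval(obs - d - tol, masses, left.open = TRUE) + 1L
    i1 <- findInterval(obs - d + tol, masses)
    if (i1 < i0) next
    rows <- i0:i1
    if (d != 0) {
      keep <- vapply(rows, function(r) {
        chars <- if (charsByRow) pepChars[[r]] else pepChars[[tbl$pepIdx[r]]]
        length(freeOffsetSites(chars, tbl$sitesPos[[r]], off)) > 0L
      }, logical(1L))
      rows <- rows[keep]
    }
    if (length(rows)) {
      out[[length(out) + 1L]] <- data.frame(
        pfId = tbl$pfId[rows], sequence = tbl$sequence[rows],
        offsetIdx = oi, offsetName = off@name, delta = d,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(pfId = integer(), sequence = character(),
                  offsetIdx = integer(), offsetName = character(),
                  delta = numeric(), stringsAsFactors = FALSE)
}

## ---------------------------------------------------------------------------
## Scoring
## ---------------------------------------------------------------------------

FACTORIAL_CAP <- 20L

## Hyperscore from neutral b/y arrays against a spectrum's peaks.  Each
## theoretical ion (both series, charges 1..maxZ) is matched to its nearest
## peak within tolDa, ties to the lower-m/z peak.  Thin wrapper over the
## compiled kernel.
scoreArrays <- function(peakMz, peakInt, b, y, tolDa, maxZ) {
  v <- .scoreArraysCpp(peakMz, peakInt, b, y, tolDa, as.integer(maxZ))
  list(score = v[1L], matched = as.integer(v[2L]))
}

#' Score one peptide-spectrum match
#'
#' X!Tandem-style hyperscore:
#' `ln(Nb! * Ny! * max(1, sum I_b) * max(1, sum I_y))` where `Nb`/`Ny` count
#' matched b/y fragments (factorials capped at 20!) and the sums are matched
#' peak intensities.  Deterministic; zero matched peaks give score 0.
#'
#' @param spectrum A [Spectrum-class] (preprocessed).
#' @param peptidoform A [Peptidoform-class] with a concrete fragment set
#'   (zero offset, or a localized offset).
#' @param fragmentTolDa Fragment tolerance in Da (default 0.02).
#' @param maxFragmentCharge Highest fragment charge scored (default 2).
#' @return List with elements `score` and `matchedPeaks`.
#' @export
scorePsm <- function(spectrum, peptidoform, fragmentTolDa = 0.02,
                     maxFragmentCharge = 2L) {
  fm <- fragmentArraysForForm(peptidoform)
  pk <- spectrum@peaks
  s <- scoreArrays(pk[, 1L], pk[, 2L], fm$b, fm$y, fragmentTolDa,
                   maxFragmentCharge)
  list(score = s$score, matchedPeaks = s$matched)
}

## Localization over explicit arrays: place delta at each candidate 0-based
## site, shifting fragments containing it, and score.
localizeArrays <- function(peakMz, peakInt, b, y, n, delta, sites, tolDa,
                           maxZ) {
  loc <- .localizeArraysCpp(peakMz, peakInt, b, y, as.integer(n), delta,
                            as.integer(sites), tolDa, as.integer(maxZ))
  names(loc$siteScores) <- as.character(sites)
  loc
}

#' Localize an unlocalized mass offset against a spectrum
#'
#' Rescores the peptidoform with its offset placed at each candidate site —
#' every residue matching the offset's specificity and not already carrying a
#' variable modification — shifting exactly the fragments containing that
#' site.  Returns the best-scoring site; if two or more sites tie within
#' 1e-6, the offset stays unlocalized and the tied set is reported.
#'
#' @param spectrum A [Spectrum-class].
#' @param peptidoform A [Peptidoform-class] with a non-zero, unlocalized
#'   offset.
#' @param fragmentTolDa Fragment tolerance in Da (default 0.02).
#' @param maxFragmentCharge Highest fragment charge scored (default 2).
#' @return List with `position` (0-based site, or `NA` for an unresolved
#'   tie), `score`, and `siteScores` (named by 0-based candidate site).
#' @export
localizeDeltaMass <- function(spectrum, peptidoform, fragmentTolDa = 0.02,
                              maxFragmentCharge = 2L) {
  off <- peptidoform@offset
  if (off@massDelta == 0 || !is.na(peptidoform@offsetSite))
    stop("peptidoform must carry a non-zero, unlocalized offset",
         call. = FALSE)
  chars <- strsplit(peptidoform@sequence, "", fixed = TRUE)[[1L]]
  sites <- freeOffsetSites(chars, peptidoform@varModSites$pos, off)
  if (length(sites) == 0L)
    stop("no eligible site for offset '", off@name, "' on ",
         peptidoform@sequence, call. = FALSE)
  fm <- fragmentArraysForForm(peptidoform)   # offset unapplied (unlocalized)
  pk <- spectrum@peaks
  loc <- localizeArrays(pk[, 1L], pk[, 2L], fm$b, fm$y, length(chars),
                        off@massDelta, sites, fragmentTolDa,
                        maxFragmentCharge)
  loc[c("position", "score", "siteScores")]
}

## ---------------------------------------------------------------------------
## Dataset search
## ---------------------------------------------------------------------------

psmTableSkeleton <- function() {
  data.frame(
    scan = character(), charge = integer(), sequence = character(),
    pf_id = integer(), var_mods = character(), offset_label = character(),
    offset_mass = numeric(), offset_pos = integer(), score = numeric(),
    matched_peaks = integer(), precursor_delta = numeric(),
    is_decoy = logical(), parent_accession = character(),
    stringsAsFactors = FALSE)
}

varModString <- function(sequence, pos, masses) {
  if (length(pos) == 0L) return("")
  lab <- ifelse(pos < 0L, "N-term",
                paste0(substring(sequence, pos + 1L, pos + 1L), pos + 1L))
  paste(sprintf("%s/%.4f", lab, masses), collapse = ",")
}

#' Search a spectrum dataset against a hybrid peptidoform space
#'
#' For every scan, generates precursor-level candidates (variable-mod forms
#' combined with at most one mass offset), scores them (localizing non-zero
#' offsets via shifted fragment series), and retains the rank-1 PSM.
#' Candidates matching fewer than `minMatchedPeaks` fragments are discarded
#' (scans whose best candidate falls below the floor yield no PSM).  Score
#' ties are broken deterministically by higher matched-peak count, then
#' lexicographic peptide sequence, then target before decoy, then lower
#' peptidoform id.  With `method = "naive"` the same result is computed by an
#' exhaustive per-candidate scorer without the fragment index (oracle
#' equivalence contract: both methods return identical rank-1 PSMs).
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param peptides Digested peptide data.frame (see [digestDatabase()]).
#' @param space A [ModificationSpace-class].
#' @param params Parameter list from [searchParams()].
#' @param method `"index"` (fragment-indexed) or `"naive"` (exhaustive).
#' @return PSM data.frame, one row per scan with at least one candidate:
#'   columns `scan`, `charge`, `sequence`, `pf_id`, `var_mods`,
#'   `offset_label`, `offset_mass`, `offset_pos` (1-based, `NA` =
#'   unlocalized/none), `score`, `matched_peaks`, `precursor_delta`,
#'   `is_decoy`, `parent_accession`.
#' @export
searchDataset <- function(spectra, peptides, space, params = searchParams(),
                          method = c("index", "naive")) {
  method <- match.arg(method)
  if (length(spectra) == 0L || nrow(peptides) == 0L)
    return(psmTableSkeleton())
  tbl <- buildPeptidoformTable(peptides, space)
  index <- if (method == "index") {
    buildFragmentIndex(tbl, space, binWidth = params$binWidth,
                       maxFragmentCharge = params$maxFragmentCharge,
                       storeEntries = FALSE)
  }
  offsets <- space@offsets
  varMasses <- vapply(space@variable, function(m) m@massDelta, numeric(1L))
  offDeltas <- vapply(offsets, function(m) m@massDelta, numeric(1L))
  ## dataset-level caches: per-peptide characters, and per (offset, peptide)
  ## eligible 0-based positions
  pepChars <- strsplit(peptides$sequence, "", fixed = TRUE)
  eligPos <- lapply(offsets, function(off) {
    if (off@massDelta == 0) return(NULL)
    lapply(pepChars, function(ch) which(ch %in% off@residues) - 1L)
  })
  ## local copies: repeated data.frame column extraction is a hot-path cost
  tblMass <- tbl$mass; tblSeq <- tbl$sequence; tblPep <- tbl$pepIdx
  tblSites <- tbl$sitesPos; tblSitesMod <- tbl$sitesMod
  tblDecoy <- tbl$isDecoy
  tolPpm <- params$precursorTolPpm
  fragTol <- params$fragmentTolDa
  maxZ <- params$maxFragmentCharge
  if (!is.null(index)) {
    fragStart <- index@fragStart; bMass <- index@bMass; yMass <- index@yMass
  }

  rows <- vector("list", length(spectra))
  for (si in seq_along(spectra)) {
    sp <- preprocessSpectrum(spectra[[si]], params$topN, params$minMz)
    obs <- precursorMass(sp)
    ## fragment charge never reaches the precursor charge
    zEff <- max(1L, min(maxZ, sp@precursorCharge - 1L))
    if (method == "index") {
      tol <- tolPpm * 1e-6 * obs
      candPf <- integer(); candOff <- integer()
      candSites <- list()
      for (oi in seq_along(offsets)) {
        d <- offDeltas[oi]
        w <- .massWindowCpp(tblMass, obs - d - tol, obs - d + tol)
        i0 <- w[1L]; i1 <- w[2L]
        if (i1 < i0) next
        for (r in i0:i1) {
          if (d != 0) {
            occ <- tblSites[[r]]
            sites <- eligPos[[oi]][[tblPep[r]]]
            if (length(occ)) sites <- setdiff(sites, occ)
            if (length(sites) == 0L) next
            candSites[[length(candPf) + 1L]] <- sites
          } else {
            candSites[length(candPf) + 1L] <- list(NULL)
          }
          candPf[length(candPf) + 1L] <- r
          candOff[length(candOff) + 1L] <- oi
        }
      }
      cand <- data.frame(pfId = candPf, offsetIdx = candOff)
    } else {
      cand <- naiveMatchPrecursor(obs, tbl, space, tolPpm)
      candSites <- NULL
    }
    if (nrow(cand) == 0L) next
    pk <- sp@peaks
    pkMz <- pk[, 1L]; pkInt <- pk[, 2L]
    nc <- nrow(cand)
    score <- numeric(nc); matched <- integer(nc); offPos <- rep(NA_integer_, nc)
    for (ci in seq_len(nc)) {
      r <- cand$pfId[ci]
      off <- offsets[[cand$offsetIdx[ci]]]
      if (method == "index") {
        ix <- (fragStart[r] + 1L):fragStart[r + 1L]
        b <- bMass[ix]; y <- yMass[ix]
        if (off@massDelta == 0) {
          s <- scoreArrays(pkMz, pkInt, b, y, fragTol, zEff)
          score[ci] <- s$score; matched[ci] <- s$matched
        } else {
          loc <- localizeArrays(pkMz, pkInt, b, y, length(ix) + 1L,
                                off@massDelta, candSites[[ci]], fragTol,
                                zEff)
          score[ci] <- loc$score; matched[ci] <- loc$matched
          offPos[ci] <- loc$position
        }
      } else {
        if (off@massDelta == 0) {
          pf <- pfFromTableRow(tbl, r, space)
          s <- scorePsm(sp, pf, params$fragmentTolDa, zEff)
          score[ci] <- s$score; matched[ci] <- s$matchedPeaks
        } else {
          pf <- pfFromTableRow(tbl, r, space, offset = off)
          loc <- localizeDeltaMass(sp, pf, params$fragmentTolDa, zEff)
          score[ci] <- loc$score
          offPos[ci] <- loc$position
          pfLoc <- if (is.na(loc$position)) pf else
            pfFromTableRow(tbl, r, space, offset = off,
                           offsetSite = loc$position)
          matched[ci] <- if (is.na(loc$position)) {
            ## count at the first tied site, as in the indexed path
            firstTied <- as.integer(names(loc$siteScores))[
              loc$siteScores >= max(loc$siteScores) - 1e-6][1L]
            scorePsm(sp, pfFromTableRow(tbl, r, space, offset = off,
                                        offsetSite = firstTied),
                     params$fragmentTolDa, zEff)$matchedPeaks
          } else {
            scorePsm(sp, pfLoc, params$fragmentTolDa, zEff)$matchedPeaks
          }
        }
      }
    }
    ## evidence floor: candidates below the matched-fragment minimum are
    ## never reported
    keepC <- matched >= params$minMatchedPeaks
    if (!any(keepC)) next
    score[!keepC] <- -Inf
    best <- order(-score, -matched, tblSeq[cand$pfId], tblDecoy[cand$pfId],
                  cand$pfId, cand$offsetIdx)[1L]
    r <- cand$pfId[best]
    off <- offsets[[cand$offsetIdx[best]]]
    pos <- tblSites[[r]]
    rows[[si]] <- data.frame(
      scan = sp@scanId, charge = sp@precursorCharge,
      sequence = tblSeq[r], pf_id = r,
      var_mods = varModString(tblSeq[r], pos, varMasses[tblSitesMod[[r]]]),
      offset_label = if (off@massDelta == 0) "" else off@name,
      offset_mass = off@massDelta,
      offset_pos = if (is.na(offPos[best])) NA_integer_
                   else offPos[best] + 1L,
      score = score[best], matched_peaks = matched[best],
      precursor_delta = obs - (tblMass[r] + off@massDelta),
      is_decoy = tblDecoy[r],
      parent_accession = peptides$parent_accession[tblPep[r]],
      stringsAsFactors = FALSE)
  }
  rows <- rows[!vapply(rows, is.null, logical(1L))]
  if (length(rows) == 0L) return(psmTableSkeleton())
  psms <- do.call(rbind, rows)
  ## one rank-1 PSM per scan id (charge-ambiguous scans expand to several
  ## query spectra; keep the best interpretation)
  o <- order(psms$scan, -psms$score, -psms$matched_peaks, psms$sequence,
             psms$is_decoy, psms$pf_id)
  psms <- psms[o, , drop = FALSE]
  psms <- psms[!duplicated(psms$scan), , drop = FALSE]
  rownames(psms) <- NULL
  psms
}

## Exhaustive precursor matching without the sorted-mass lookup; used by the
## naive oracle path.
naiveMatchPrecursor <- function(obs, tbl, space, precursorTolPpm) {
  tol <- precursorTolPpm * 1e-6 * obs
  out <- list()
  for (oi in seq_along(space@offsets)) {
    off <- space@offsets[[oi]]
    for (r in seq_len(nrow(tbl))) {
      if (abs(obs - (tbl$mass[r] + off@massDelta)) > tol) next
      if (off@massDelta != 0) {
        chars <- strsplit(tbl$sequence[r], "", fixed = TRUE)[[1L]]
        if (length(freeOffsetSites(chars, tbl$sitesPos[[r]], off)) == 0L)
          next
      }
      out[[length(out) + 1L]] <- data.frame(
        pfId = tbl$pfId[r], sequence = tbl$sequence[r], offsetIdx = oi,
        offsetName = off@name, delta = off@massDelta,
        stringsAsFactors = FALSE)
    }
  }
  if (length(out)) do.call(rbind, out)
  else data.frame(pfId = integer(), sequence = character(),
                  offsetIdx = integer(), offsetName = character(),
                  delta = numeric(), stringsAsFactors = FALSE)
}
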