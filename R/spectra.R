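## Tandem-spectrum I/O and fragment-ion chemistry.  MGF is the required
## text format; a minimal uncompressed mzML reader/writer is provided behind
## the same interface.  Only b/y ions are modeled (tryptic HCD-style data).

#' Read tandem mass spectra
#'
#' @param path File path.
#' @param format `"mgf"` or `"mzml"`; default guessed from the extension.
#' @param defaultCharges Integer vector of charge states assumed for spectra
#'   without a charge annotation; each such scan yields one [Spectrum-class]
#'   per default charge (default `c(2L, 3L)`).
#' @return List of [Spectrum-class] objects.
#' @export
readSpectra <- function(path, format = c("auto", "mgf", "mzml"),
                        defaultCharges = c(2L, 3L)) {
  format <- match.arg(format)
  if (format == "auto") {
    format <- if (grepl("\\.mzml$", path, ignore.case = TRUE)) "mzml"
              else "mgf"
  }
  if (!file.exists(path))
    stop("spectrum file not found: ", path, call. = FALSE)
  switch(format,
         mgf = readMgf(path, defaultCharges),
         mzml = readMzml(path, defaultCharges))
}

readMgf <- function(path, defaultCharges) {
  lines <- readLines(path)
  begins <- which(lines == "BEGIN IONS")
  ends <- which(lines == "END IONS")
  if (length(begins) != length(ends) || any(ends < begins))
    stop("malformed MGF '", path, "': unbalanced BEGIN/END IONS at line ",
         if (length(begins)) begins[1L] else 1L, call. = FALSE)
  out <- list()
  for (k in seq_along(begins)) {
    block <- lines[(begins[k] + 1L):(ends[k] - 1L)]
    keyed <- grepl("=", block, fixed = TRUE)
    keys <- block[keyed]
    peakLines <- block[!keyed & nzchar(block)]
    getKey <- function(key) {
      hit <- keys[startsWith(keys, paste0(key, "="))]
      if (length(hit)) sub("^[^=]+=", "", hit[1L]) else NA_character_
    }
    title <- getKey("TITLE")
    if (is.na(title)) title <- sprintf("scan_%d", k)
    pepmass <- suppressWarnings(
      as.numeric(strsplit(getKey("PEPMASS"), "\\s+")[[1L]][1L]))
    if (!is.finite(pepmass))
      stop("malformed MGF '", path, "': block ", k,
           " ('", title, "') lacks a numeric PEPMASS", call. = FALSE)
    rt <- suppressWarnings(as.numeric(getKey("RTINSECONDS")))
    chg <- getKey("CHARGE")
    charges <- if (is.na(chg)) defaultCharges
               else as.integer(sub("\\+$", "", chg))
    pk <- if (length(peakLines)) {
      m <- do.call(rbind, lapply(strsplit(peakLines, "\\s+"), function(x)
        as.numeric(x[1:2])))
      if (anyNA(m))
        stop("malformed MGF '", path, "': non-numeric peak in block ", k,
             " ('", title, "')", call. = FALSE)
      m
    } else matrix(numeric(), ncol = 2L)
    for (z in charges) {
      out[[length(out) + 1L]] <-
        Spectrum(title, pepmass, z, pk[, 1L], pk[, 2L], rt)
    }
  }
  out
}

#' Write spectra to MGF
#'
#' Deterministic text serialization (fixed number formatting), so identical
#' spectra always produce byte-identical files.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMgf <- function(spectra, path) {
  con <- file(path, "wb")   # binary: fixed "\n" line endings
  on.exit(close(con))
  for (sp in spectra) {
    pk <- sp@peaks
    lines <- c(
      "BEGIN IONS",
      paste0("TITLE=", sp@scanId),
      paste0("PEPMASS=", formatC(sp@precursorMz, digits = 5L,
                                 format = "f")),
      paste0("CHARGE=", sp@precursorCharge, "+"),
      if (is.finite(sp@retentionTime))
        paste0("RTINSECONDS=", formatC(sp@retentionTime, digits = 2L,
                                       format = "f")),
      if (nrow(pk)) paste(formatC(pk[, 1L], digits = 5L, format = "f"),
                          formatC(pk[, 2L], digits = 2L, format = "f")),
      "END IONS",
      ""
    )
    writeLines(lines, con)
  }
  invisible(path)
}

## -- minimal mzML support (uncompressed, 64-bit little-endian arrays) -------

encodeB64Doubles <- function(x) {
  jsonlite::base64_enc(writeBin(as.numeric(x), raw(), size = 8L,
                                endian = "little"))
}

decodeB64Doubles <- function(txt, precision = 64L) {
  raw <- jsonlite::base64_dec(gsub("\\s", "", txt))
  readBin(raw, "numeric", n = length(raw) %/% (precision %/% 8L),
          size = precision %/% 8L, endian = "little")
}

#' Write spectra to a minimal mzML file
#'
#' Uncompressed 64-bit little-endian peak arrays; enough mzML structure for
#' [readSpectra()] and typical viewers, not a fully accessioned document.
#'
#' @param spectra List of [Spectrum-class] objects.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeMzml <- function(spectra, path) {
  esc <- function(x) gsub("&", "&amp;", gsub("<", "&lt;", x, fixed = TRUE),
                          fixed = TRUE)
  specXml <- vapply(seq_along(spectra), function(i) {
    sp <- spectra[[i]]
    pk <- sp@peaks
    paste0(
      sprintf('<spectrum index="%d" id="%s" defaultArrayLength="%d">',
              i - 1L, esc(sp@scanId), nrow(pk)),
      '<cvParam accession="MS:1000511" name="ms level" value="2"/>',
      '<precursorList count="1"><precursor><selectedIonList count="1">',
      sprintf(paste0('<selectedIon><cvParam accession="MS:1000744" ',
                     'name="selected ion m/z" value="%.6f"/>',
                     '<cvParam accession="MS:1000041" name="charge state" ',
                     'value="%d"/></selectedIon>'),
              sp@precursorMz, sp@precursorCharge),
      '</selectedIonList></precursor></precursorList>',
      '<binaryDataArrayList count="2">',
      '<binaryDataArray><cvParam accession="MS:1000514" name="m/z array"/>',
      '<cvParam accession="MS:1000523" name="64-bit float"/>',
      '<binary>', encodeB64Doubles(pk[, 1L]), '</binary></binaryDataArray>',
      '<binaryDataArray><cvParam accession="MS:1000515" name="intensity array"/>',
      '<cvParam accession="MS:1000523" name="64-bit float"/>',
      '<binary>', encodeB64Doubles(pk[, 2L]), '</binary></binaryDataArray>',
      '</binaryDataArrayList></spectrum>'
    )
  }, character(1L))
  doc <- paste0(
    '<?xml version="1.0" encoding="utf-8"?>',
    '<mzML xmlns="http://psi.hupo.org/ms/mzml" version="1.1.0">',
    sprintf('<run id="run"><spectrumList count="%d">', length(spectra)),
    paste(specXml, collapse = ""),
    '</spectrumList></run></mzML>'
  )
  writeLines(doc, path)
  invisible(path)
}

readMzml <- function(path, defaultCharges) {
  doc <- tryCatch(xml2::read_xml(path),
                  error = function(e) stop("malformed mzML '", path, "': ",
                                           conditionMessage(e), call. = FALSE))
  xml2::xml_ns_strip(doc)
  specs <- xml2::xml_find_all(doc, ".//spectrum")
  out <- list()
  for (sn in specs) {
    id <- xml2::xml_attr(sn, "id")
    mzNode <- xml2::xml_find_first(
      sn, ".//binaryDataArray[cvParam/@accession='MS:1000514']/binary")
    intNode <- xml2::xml_find_first(
      sn, ".//binaryDataArray[cvParam/@accession='MS:1000515']/binary")
    if (is.na(mzNode) || is.na(intNode))
      stop("malformed mzML '", path, "': spectrum '", id,
           "' lacks peak arrays", call. = FALSE)
    mz <- decodeB64Doubles(xml2::xml_text(mzNode))
    ii <- decodeB64Doubles(xml2::xml_text(intNode))
    pmz <- as.numeric(xml2::xml_attr(xml2::xml_find_first(
      sn, ".//cvParam[@accession='MS:1000744']"), "value"))
    chg <- as.integer(xml2::xml_attr(xml2::xml_find_first(
      sn, ".//cvParam[@accession='MS:1000041']"), "value"))
    charges <- if (is.na(chg)) defaultCharges else chg
    for (z in charges)
      out[[length(out) + 1L]] <- Spectrum(id, pmz, z, mz, ii)
  }
  out
}

#' Filter a spectrum to its most intense peaks
#'
#' Keeps the `topN` most intense peaks with m/z above `minMz`; peak order is
#' restored ascending by m/z.  Intensity ties are broken deterministically in
#' favor of the lower-m/z peak.  The operation is idempotent.
#'
#' @param spectrum A [Spectrum-class].
#' @param topN Number of peaks to retain (default 150).
#' @param minMz Minimum m/z retained (default 100).
#' @return A filtered [Spectrum-class].
#' @export
preprocessSpectrum <- function(spectrum, topN = 150L, minMz = 100) {
  stopifnot(topN >= 1L)
  pk <- spectrum@peaks
  pk <- pk[pk[, 1L] >= minMz, , drop = FALSE]
  if (nrow(pk) > topN) {
    keep <- order(-pk[, 2L], pk[, 1L])[seq_len(topN)]
    pk <- pk[sort(keep), , drop = FALSE]
  }
  initialize(spectrum, peaks = pk)
}

## Neutral b/y fragment masses of one concrete form.  `siteMasses` is a
## numeric vector of per-position deltas (length n; terminal deltas folded
## into position 1's prefix via `ntermMass`).
fragmentNeutralMasses <- function(residueMasses, siteMasses = NULL,
                                  ntermMass = 0) {
  n <- length(residueMasses)
  tot <- residueMasses
  if (!is.null(siteMasses)) tot <- tot + siteMasses
  pre <- cumsum(tot) + ntermMass
  b <- pre[-n]
  y <- (pre[n] - pre[-n]) + MASS_WATER
  list(b = b, y = rev(y) * 1)   # y[j] = last j residues
}

#' Theoretical b/y fragment ions of a peptidoform
#'
#' Generates all b and y ions at charges 1..`maxFragmentCharge`.  Every
#' site-localized delta (variable modification, or a localized mass offset)
#' shifts exactly the fragments containing that site; an unlocalized offset
#' is not applied to any fragment (localization rescoring places it
#' explicitly, see [localizeDeltaMass()]).
#'
#' @param peptidoform A [Peptidoform-class].
#' @param maxFragmentCharge Highest fragment charge generated (default 2).
#' @return Data.frame with columns `series` ("b"/"y"), `index`, `charge`,
#'   `mz`, `carries_offset`.
#' @export
theoreticalFragments <- function(peptidoform, maxFragmentCharge = 2L) {
  chars <- checkResidues(peptidoform@sequence)
  n <- length(chars)
  fm <- fragmentArraysForForm(peptidoform)
  out <- list()
  for (z in seq_len(maxFragmentCharge)) {
    out[[length(out) + 1L]] <- data.frame(
      series = "b", index = seq_len(n - 1L), charge = z,
      mz = (fm$b + z * MASS_PROTON) / z,
      carries_offset = fm$bShifted, stringsAsFactors = FALSE)
    out[[length(out) + 1L]] <- data.frame(
      series = "y", index = seq_len(n - 1L), charge = z,
      mz = (fm$y + z * MASS_PROTON) / z,
      carries_offset = fm$yShifted, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

## b/y neutral-mass arrays of a Peptidoform, applying fixed mods, variable
## mods and a *localized* offset; returns shift indicators per fragment.
fragmentArraysForForm <- function(pf, fixedMods = defaultFixedMods()) {
  chars <- strsplit(pf@sequence, "", fixed = TRUE)[[1L]]
  n <- length(chars)
  res <- unname(AA_MASSES[chars])
  for (fx in fixedMods) res <- res + fx@massDelta * (chars %in% fx@residues)
  site <- numeric(n)
  nterm <- 0
  vm <- pf@varModSites
  if (nrow(vm)) {
    resPos <- vm$pos[vm$pos >= 0L]
    site[resPos + 1L] <- site[resPos + 1L] + vm$mass[vm$pos >= 0L]
    nterm <- sum(vm$mass[vm$pos < 0L])
  }
  offPos <- pf@offsetSite
  hasLocOffset <- pf@offset@massDelta != 0 && !is.na(offPos)
  if (hasLocOffset) site[offPos + 1L] <- site[offPos + 1L] + pf@offset@massDelta
  fm <- fragmentNeutralMasses(res, site, nterm)
  bShifted <- rep(FALSE, n - 1L)
  yShifted <- rep(FALSE, n - 1L)
  if (hasLocOffset) {
    bShifted <- seq_len(n - 1L) >= (offPos + 1L)
    yShifted <- seq_len(n - 1L) >= (n - offPos)
  }
  list(b = fm$b, y = fm$y, bShifted = bShifted, yShifted = yShifted)
}
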