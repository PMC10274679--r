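#' @import methods
NULL

## ---------------------------------------------------------------------------
## Modification
## ---------------------------------------------------------------------------

#' Modification: a named mass delta with residue/terminus specificity
#'
#' A `Modification` describes one chemical modification as a signed
#' monoisotopic mass delta together with the residues (and/or terminus) it may
#' occupy, and its search class: `"fixed"` (applied unconditionally),
#' `"variable"` (enumerated combinatorially up to a per-peptide cap) or
#' `"offset"` (searched as a precursor mass offset, at most one per peptide).
#'
#' @slot name Character scalar, short label (e.g. `"Oxidation"`).
#' @slot massDelta Numeric scalar, monoisotopic mass delta in Da (signed).
#' @slot residues Character vector of single-letter residue codes the
#'   modification may occupy; may be empty for purely terminal modifications.
#' @slot terminus One of `"none"`, `"peptide-N"`, `"protein-N"`.
#' @slot modClass One of `"fixed"`, `"variable"`, `"offset"`.
#'
#' @seealso [Modification()], [fpopOffsetTable()]
#' @exportClass Modification
setClass("Modification",
  representation(
    name = "character",
    massDelta = "numeric",
    residues = "character",
    terminus = "character",
    modClass = "character"
  )
)

setValidity("Modification", function(object) {
  msg <- character()
  if (length(object@name) != 1L || !nzchar(object@name))
    msg <- c(msg, "name must be a non-empty character scalar")
  if (length(object@massDelta) != 1L || !is.finite(object@massDelta))
    msg <- c(msg, "massDelta must be a finite numeric scalar")
  if (!object@terminus %in% c("none", "peptide-N", "protein-N"))
    msg <- c(msg, "terminus must be 'none', 'peptide-N' or 'protein-N'")
  if (!object@modClass %in% c("fixed", "variable", "offset"))
    msg <- c(msg, "modClass must be 'fixed', 'variable' or 'offset'")
  if (object@modClass %in% c("variable", "fixed") && object@massDelta == 0)
    msg <- c(msg, "mass_delta must be nonzero for fixed/variable modifications")
  if (length(object@residues) == 0L && object@terminus == "none")
    msg <- c(msg, "residues must be nonempty unless the modification is terminus-specific")
  if (any(nchar(object@residues) != 1L))
    msg <- c(msg, "residues must be single-letter codes")
  if (length(msg)) msg else TRUE
})

#' Construct a Modification
#'
#' @param name Short label.
#' @param massDelta Monoisotopic mass delta in Da.
#' @param residues Character vector of single-letter residues, or a single
#'   string such as `"MFHILVWY"` which is split into letters.
#' @param terminus `"none"` (default), `"peptide-N"` or `"protein-N"`.
#' @param modClass `"fixed"`, `"variable"` or `"offset"`.
#' @return A [Modification-class] object.
#' @examples
#' Modification("Oxidation", 15.994915, "MFHILVWY", modClass = "variable")
#' @export
Modification <- function(name, massDelta, residues = character(),
                         terminus = c("none", "peptide-N", "protein-N"),
                         modClass = c("variable", "fixed", "offset")) {
  terminus <- match.arg(terminus)
  modClass <- match.arg(modClass)
  if (length(residues) == 1L && nchar(residues) > 1L)
    residues <- strsplit(residues, "", fixed = TRUE)[[1L]]
  new("Modification", name = name, massDelta = massDelta,
      residues = unique(residues), terminus = terminus, modClass = modClass)
}

setMethod("show", "Modification", function(object) {
  res <- if (length(object@residues)) paste(object@residues, collapse = "")
         else object@terminus
  cat(sprintf("Modification '%s' (%s): %+0.4f Da on %s\n",
              object@name, object@modClass, object@massDelta, res))
})

#' @describeIn Modification-class label accessor
#' @param object A `Modification`.
#' @export
setGeneric("modName", function(object) standardGeneric("modName"))
#' @export
setMethod("modName", "Modification", function(object) object@name)

#' @describeIn Modification-class mass-delta accessor (Da)
#' @export
setGeneric("massDelta", function(object) standardGeneric("massDelta"))
#' @export
setMethod("massDelta", "Modification", function(object) object@massDelta)

#' @describeIn Modification-class residue-specificity accessor
#' @export
setGeneric("modResidues", function(object) standardGeneric("modResidues"))
#' @export
setMethod("modResidues", "Modification", function(object) object@residues)

#' @describeIn Modification-class search-class accessor
#' @export
setGeneric("modClass", function(object) standardGeneric("modClass"))
#' @export
setMethod("modClass", "Modification", function(object) object@modClass)

#' @describeIn Modification-class terminus accessor
#' @export
setGeneric("modTerminus", function(object) standardGeneric("modTerminus"))
#' @export
setMethod("modTerminus", "Modification", function(object) object@terminus)

## ---------------------------------------------------------------------------
## ModificationSpace
## ---------------------------------------------------------------------------

#' ModificationSpace: the hybrid search space definition
#'
#' Bundles the fixed modifications, the variable modifications (enumerated up
#' to `maxVarMods` per peptide) and the mass-offset list (searched at most one
#' non-zero offset per peptide).  The offsets list always contains exactly one
#' zero-mass entry so that unmodified and variable-only peptidoforms are
#' always part of the search space.
#'
#' @slot fixed List of [Modification-class], class `"fixed"`.
#' @slot variable List of [Modification-class], class `"variable"`.
#' @slot offsets List of [Modification-class], class `"offset"`, including the
#'   zero entry.
#' @slot maxVarMods Integer cap on variable modifications per peptide.
#'
#' @seealso [ModificationSpace()], [enumeratePeptidoforms()]
#' @exportClass ModificationSpace
setClass("ModificationSpace",
  representation(
    fixed = "list",
    variable = "list",
    offsets = "list",
    maxVarMods = "integer"
  )
)

zeroOffset <- function() {
  new("Modification", name = "none", massDelta = 0,
      residues = LETTERS, terminus = "none", modClass = "offset")
}

setValidity("ModificationSpace", function(object) {
  msg <- character()
  allmods <- c(object@fixed, object@variable, object@offsets)
  if (!all(vapply(allmods, is, logical(1L), "Modification")))
    msg <- c(msg, "all entries must be Modification objects")
  if (object@maxVarMods < 0L)
    msg <- c(msg, "maxVarMods must be >= 0")
  nzero <- sum(vapply(object@offsets, function(m) m@massDelta == 0, logical(1L)))
  if (nzero != 1L)
    msg <- c(msg, "offsets must contain exactly one zero-mass entry")
  ## no (residue, mass) pair in both variable and offsets
  pairKey <- function(mods) {
    unlist(lapply(mods, function(m)
      if (m@massDelta != 0) paste0(m@residues, "@", round(m@massDelta, 3L))))
  }
  dup <- intersect(pairKey(object@variable), pairKey(object@offsets))
  if (length(dup))
    msg <- c(msg, paste0("(residue, mass) pair present in both variable and ",
                         "offsets lists: ", paste(dup, collapse = ", ")))
  if (length(msg)) msg else TRUE
})

#' Construct a ModificationSpace
#'
#' @param fixed,variable,offsets Lists of [Modification-class] objects (a bare
#'   `Modification` is wrapped).  The zero offset entry is appended
#'   automatically if absent.
#' @param maxVarMods Cap on variable modifications per peptide (default 3).
#' @return A [ModificationSpace-class] object.
#' @examples
#' sp <- ModificationSpace(
#'   fixed = list(Modification("Carbamidomethyl", 57.021464, "C",
#'                             modClass = "fixed")),
#'   variable = list(Modification("Oxidation", 15.994915, "M")),
#'   offsets = fpopOffsetTable()[-1]
#' )
#' @export
ModificationSpace <- function(fixed = list(), variable = list(),
                              offsets = list(), maxVarMods = 3L) {
  wrap <- function(x) if (is(x, "Modification")) list(x) else x
  fixed <- wrap(fixed); variable <- wrap(variable); offsets <- wrap(offsets)
  hasZero <- any(vapply(offsets, function(m) m@massDelta == 0, logical(1L)))
  if (!hasZero) offsets <- c(list(zeroOffset()), offsets)
  new("ModificationSpace", fixed = fixed, variable = variable,
      offsets = offsets, maxVarMods = as.integer(maxVarMods))
}

setMethod("show", "ModificationSpace", function(object) {
  cat(sprintf(paste0("ModificationSpace: %d fixed, %d variable (max %d per ",
                     "peptide), %d mass offsets (incl. zero)\n"),
              length(object@fixed), length(object@variable),
              object@maxVarMods, length(object@offsets)))
})

#' @describeIn ModificationSpace-class cap on variable mods per peptide
#' @param object A `ModificationSpace`.
#' @export
setGeneric("maxVarMods", function(object) standardGeneric("maxVarMods"))
#' @export
setMethod("maxVarMods", "ModificationSpace", function(object) object@maxVarMods)

#' @describeIn ModificationSpace-class fixed-modification list
#' @export
setGeneric("fixedMods", function(object) standardGeneric("fixedMods"))
#' @export
setMethod("fixedMods", "ModificationSpace", function(object) object@fixed)

#' @describeIn ModificationSpace-class variable-modification list
#' @export
setGeneric("variableMods", function(object) standardGeneric("variableMods"))
#' @export
setMethod("variableMods", "ModificationSpace", function(object) object@variable)

#' @describeIn ModificationSpace-class mass-offset list (zero entry included)
#' @export
setGeneric("massOffsets", function(object) standardGeneric("massOffsets"))
#' @export
setMethod("massOffsets", "ModificationSpace", function(object) object@offsets)

## ---------------------------------------------------------------------------
## Peptidoform
## ---------------------------------------------------------------------------

#' Peptidoform: a peptide with a concrete modification assignment
#'
#' A digested peptide plus one assignment of variable modifications (0-based
#' site positions) and at most one mass offset.  The offset site may be a
#' 0-based position (localized) or `NA` (unlocalized); localization is
#' performed against spectra by [localizeDeltaMass()].
#'
#' @slot sequence Uppercase amino-acid string.
#' @slot varModSites Data frame with columns `pos` (0-based integer; -1
#'   denotes the N-terminus), `mass` (Da) and `name`; one row per occupied
#'   site.
#' @slot offset The applied [Modification-class] mass offset (possibly the
#'   zero entry).
#' @slot offsetSite Integer, 0-based localized position, or `NA_integer_` for
#'   an unlocalized offset.
#' @slot totalMass Monoisotopic neutral mass in Da including fixed mods,
#'   variable mods and the offset.
#' @slot isNterm Logical, whether the peptide starts at a protein N-terminus
#'   (eligible for protein N-terminal modifications).
#'
#' @exportClass Peptidoform
setClass("Peptidoform",
  representation(
    sequence = "character",
    varModSites = "data.frame",
    offset = "Modification",
    offsetSite = "integer",
    totalMass = "numeric",
    isNterm = "logical"
  )
)

setValidity("Peptidoform", function(object) {
  msg <- character()
  if (length(object@sequence) != 1L || !nzchar(object@sequence))
    msg <- c(msg, "sequence must be a non-empty string")
  vm <- object@varModSites
  if (nrow(vm)) {
    if (anyDuplicated(vm$pos))
      msg <- c(msg, "each site position may be occupied at most once")
    if (any(vm$pos < -1L | vm$pos >= nchar(object@sequence)))
      msg <- c(msg, "site positions out of range")
  }
  if (length(msg)) msg else TRUE
})

setMethod("show", "Peptidoform", function(object) {
  vm <- object@varModSites
  mods <- if (nrow(vm)) {
    paste(sprintf("%s%d%+0.4f", substring(object@sequence, vm$pos + 1L,
                                          vm$pos + 1L), vm$pos + 1L, vm$mass),
          collapse = ", ")
  } else "none"
  off <- if (object@offset@massDelta == 0) "none" else
    sprintf("%s (%+0.4f Da, site %s)", object@offset@name,
            object@offset@massDelta,
            if (is.na(object@offsetSite)) "unlocalized"
            else as.character(object@offsetSite + 1L))
  cat(sprintf("Peptidoform %s  mass %.4f Da\n  variable mods: %s\n  offset: %s\n",
              object@sequence, object@totalMass, mods, off))
})

#' @describeIn Peptidoform-class peptide sequence accessor
#' @param object A `Peptidoform`.
#' @export
setGeneric("pepSequence", function(object) standardGeneric("pepSequence"))
#' @export
setMethod("pepSequence", "Peptidoform", function(object) object@sequence)

#' @describeIn Peptidoform-class neutral monoisotopic mass (Da)
#' @export
setGeneric("totalMass", function(object) standardGeneric("totalMass"))
#' @export
setMethod("totalMass", "Peptidoform", function(object) object@totalMass)

#' @describeIn Peptidoform-class variable-modification site table
#' @export
setGeneric("varModSites", function(object) standardGeneric("varModSites"))
#' @export
setMethod("varModSites", "Peptidoform", function(object) object@varModSites)

#' @describeIn Peptidoform-class applied mass offset (zero entry if none)
#' @export
setGeneric("appliedOffset", function(object) standardGeneric("appliedOffset"))
#' @export
setMethod("appliedOffset", "Peptidoform", function(object) object@offset)

## ---------------------------------------------------------------------------
## Spectrum
## ---------------------------------------------------------------------------

#' Spectrum: a centroided MS/MS scan
#'
#' @slot scanId Character scan identifier.
#' @slot precursorMz Precursor m/z in Da per charge.
#' @slot precursorCharge Integer precursor charge (>= 1).
#' @slot peaks Two-column numeric matrix (`mz`, `intensity`), sorted ascending
#'   by m/z.
#' @slot retentionTime Seconds (NA if unknown).
#'
#' @exportClass Spectrum
setClass("Spectrum",
  representation(
    scanId = "character",
    precursorMz = "numeric",
    precursorCharge = "integer",
    peaks = "matrix",
    retentionTime = "numeric"
  )
)

setValidity("Spectrum", function(object) {
  msg <- character()
  p <- object@peaks
  if (ncol(p) != 2L) msg <- c(msg, "peaks must have two columns (mz, intensity)")
  if (nrow(p) > 1L && is.unsorted(p[, 1L]))
    msg <- c(msg, "peaks must be sorted ascending by m/z")
  if (nrow(p) && any(p[, 2L] < 0)) msg <- c(msg, "intensities must be >= 0")
  if (object@precursorCharge < 1L) msg <- c(msg, "precursorCharge must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct a Spectrum
#'
#' @param scanId Scan identifier.
#' @param precursorMz Precursor m/z.
#' @param precursorCharge Precursor charge state.
#' @param mz,intensity Numeric vectors of equal length; peaks are sorted by
#'   m/z on construction.
#' @param retentionTime Seconds (optional).
#' @return A [Spectrum-class] object.
#' @export
Spectrum <- function(scanId, precursorMz, precursorCharge, mz,
                     intensity, retentionTime = NA_real_) {
  o <- order(mz)
  peaks <- cbind(mz = as.numeric(mz)[o], intensity = as.numeric(intensity)[o])
  new("Spectrum", scanId = as.character(scanId),
      precursorMz = as.numeric(precursorMz),
      precursorCharge = as.integer(precursorCharge),
      peaks = peaks, retentionTime = as.numeric(retentionTime))
}

setMethod("show", "Spectrum", function(object) {
  cat(sprintf("Spectrum %s: precursor %.4f m/z (%d+), %d peaks\n",
              object@scanId, object@precursorMz, object@precursorCharge,
              nrow(object@peaks)))
})

#' @describeIn Spectrum-class peak matrix accessor
#' @param object A `Spectrum`.
#' @export
setGeneric("peaks", function(object) standardGeneric("peaks"))
#' @export
setMethod("peaks", "Spectrum", function(object) object@peaks)

#' @describeIn Spectrum-class precursor m/z accessor
#' @export
setGeneric("precursorMz", function(object) standardGeneric("precursorMz"))
#' @export
setMethod("precursorMz", "Spectrum", function(object) object@precursorMz)

#' @describeIn Spectrum-class precursor charge accessor
#' @export
setGeneric("precursorCharge", function(object) standardGeneric("precursorCharge"))
#' @export
setMethod("precursorCharge", "Spectrum", function(object) object@precursorCharge)

#' @describeIn Spectrum-class scan identifier accessor
#' @export
setGeneric("scanId", function(object) standardGeneric("scanId"))
#' @export
setMethod("scanId", "Spectrum", function(object) object@scanId)

#' Neutral precursor mass of a spectrum
#'
#' @param object A [Spectrum-class].
#' @return Neutral monoisotopic mass in Da:
#'   `precursorMz * z - z * proton`.
#' @export
setGeneric("precursorMass", function(object) standardGeneric("precursorMass"))
#' @export
setMethod("precursorMass", "Spectrum", function(object) {
  z <- object@precursorCharge
  object@precursorMz * z - z * MASS_PROTON
})
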