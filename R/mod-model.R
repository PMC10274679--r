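## The FPOP modification universe and the hybrid search-space combinatorics.
##
## The hybrid scheme enumerates common modifications as variable mods (up to a
## per-peptide cap) and admits at most ONE rare modification per peptide as a
## precursor mass offset, pruning combinations of rare modifications from the
## search space.

#' The FPOP mass-offset table
#'
#' Returns the standard set of 14 FPOP-induced mass offsets with their
#' residue specificities, as offset-class [Modification-class] records.  The
#' two cysteine oxidation entries are expressed relative to fixed
#' carbamidomethylation (the oxidized thiol cannot carry the alkyl group, so
#' the apparent delta is the chemical oxidation mass minus the
#' carbamidomethyl mass): C dioxidation -25.0316 Da and C trioxidation
#' -9.0367 Da.
#'
#' @return List of 14 [Modification-class] objects with `modClass = "offset"`.
#' @examples
#' offs <- fpopOffsetTable()
#' vapply(offs, modName, character(1))
#' @export
fpopOffsetTable <- function() {
  rows <- list(
    list("Oxidation",         15.9949, "MFHILVWYADEKNPQR"),
    list("Dioxidation",       31.9898, "CFMWY"),
    list("Trioxidation",      47.9847, "CFWY"),
    list("Carbonylation",     13.9793, "EIKLPQRV"),
    list("Arg deguanidation", -43.0534, "R"),
    list("H to D",            -22.0320, "H"),
    list("H to N",            -23.0160, "H"),
    list("H -10",             -10.0320, "H"),
    list("H + 5",               4.9735, "H"),
    list("Decarboxylation",   -30.0106, "DE"),
    list("CO loss",           -27.9949, "DE"),
    list("CO2 loss",          -43.9898, "DE"),
    list("C dioxidation",     -25.0316, "C"),
    list("C trioxidation",     -9.0367, "C")
  )
  lapply(rows, function(r)
    Modification(r[[1L]], r[[2L]], r[[3L]], modClass = "offset"))
}

#' Express mass offsets relative to fixed modifications
#'
#' A mass offset that chemically replaces a fixed modification on its target
#' residue must be searched as (chemical delta - fixed delta), because the
#' fixed delta is already included in every candidate peptide mass.  An
#' offset is treated as replacing a fixed modification when its residue set
#' is entirely contained in that fixed modification's residue set (e.g. a
#' Cys-only oxidation under fixed Cys carbamidomethylation).  All other
#' offsets pass through unchanged.  Full floating-point precision is retained
#' before any display rounding.
#'
#' @param offsets List of offset-class [Modification-class] objects carrying
#'   unadjusted chemical deltas.
#' @param fixed List of fixed-class [Modification-class] objects.
#' @return The offset list with adjusted `massDelta` values.  A warning is
#'   raised for any adjusted offset whose mass collides within 0.0005 Da with
#'   another offset sharing a target residue.
#' @examples
#' chem <- list(
#'   Modification("C dioxidation", 2 * 15.994915, "C", modClass = "offset"),
#'   Modification("C trioxidation", 3 * 15.994915, "C", modClass = "offset")
#' )
#' cam <- list(Modification("Carbamidomethyl", 57.021464, "C",
#'                          modClass = "fixed"))
#' vapply(adjustOffsetsForFixedMods(chem, cam), massDelta, numeric(1))
#' @export
adjustOffsetsForFixedMods <- function(offsets, fixed) {
  if (length(fixed) == 0L) return(offsets)
  out <- lapply(offsets, function(off) {
    if (off@massDelta == 0) return(off)
    for (fx in fixed) {
      if (length(off@residues) &&
          all(off@residues %in% fx@residues)) {
        off@massDelta <- off@massDelta - fx@massDelta
        break
      }
    }
    off
  })
  ## collision check among offsets sharing a residue
  n <- length(out)
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in seq.int(i + 1L, n)) {
        if (length(intersect(out[[i]]@residues, out[[j]]@residues)) &&
            abs(out[[i]]@massDelta - out[[j]]@massDelta) < 0.0005) {
          warning(sprintf(
            "adjusted offset '%s' (%.5f) collides with '%s' (%.5f) on shared residues",
            out[[i]]@name, out[[i]]@massDelta,
            out[[j]]@name, out[[j]]@massDelta), call. = FALSE)
        }
      }
    }
  }
  out
}

## Build the per-position site structure for a sequence and a list of
## variable modifications: a list with one entry per candidate site, holding
## the 0-based position (-1 for the N-terminus) and the indices of the mods
## applicable there.  One site carries at most one delta.
varModSiteStructure <- function(chars, variable, isNterm = FALSE) {
  npos <- length(chars)
  sites <- list()
  ## residue sites
  for (p in seq_len(npos)) {
    idx <- which(vapply(variable, function(m)
      m@terminus == "none" && chars[p] %in% m@residues, logical(1L)))
    if (length(idx))
      sites[[length(sites) + 1L]] <- list(pos = p - 1L, mods = idx)
  }
  ## terminal site
  idx <- which(vapply(variable, function(m)
    m@terminus == "peptide-N" ||
      (m@terminus == "protein-N" && isNterm), logical(1L)))
  if (length(idx))
    sites[[length(sites) + 1L]] <- list(pos = -1L, mods = idx)
  sites
}

## Multiply truncated occupancy polynomials: each site contributes
## (1 + k_site * x); coefficient of x^j = number of ways to occupy exactly j
## sites.  `force` indexes sites that MUST be occupied (factor k_site * x).
occupancyPolynomial <- function(siteK, cap, force = integer()) {
  poly <- 1
  for (s in seq_along(siteK)) {
    k <- siteK[s]
    fac <- if (s %in% force) c(0, k) else c(1, k)
    poly <- convolveTrunc(poly, fac, cap)
  }
  poly
}

convolveTrunc <- function(a, b, cap) {
  out <- numeric(min(length(a) + length(b) - 1L, cap + 1L))
  for (i in seq_along(a)) {
    jmax <- min(length(b), length(out) - i + 1L)
    if (jmax >= 1L)
      out[i:(i + jmax - 1L)] <- out[i:(i + jmax - 1L)] + a[i] * b[seq_len(jmax)]
  }
  out
}

#' Count modification configurations of a peptide
#'
#' Exact count of the distinct modification configurations (including the
#' unmodified form) of a peptide under a variable-modification,
#' offset-only, or hybrid search scheme.  The count grows exponentially with
#' the number of modifiable sites under a pure variable-modification scheme
#' — a 20-mer with two possible modifications on every residue has
#' \eqn{3^{20} \approx 3.5\times10^9} configurations — which is the
#' motivation for the hybrid scheme.
#'
#' Under `scheme = "hybrid"` every variable-modification configuration may
#' additionally carry at most one (unlocalized) mass offset, and an offset is
#' applicable only when the peptide retains at least one eligible residue not
#' occupied by a variable modification in that configuration.
#'
#' @param sequenceSpec Either a concrete uppercase peptide sequence, or a
#'   named numeric vector of residue counts (names that are not standard
#'   single-letter residue codes, e.g. `"other"`, count as inert positions).
#' @param mods List of [Modification-class] objects.  For
#'   `scheme = "variable_only"` all are treated as variable; for
#'   `"offset_only"` all as offsets; for `"hybrid"` their `modClass` decides.
#' @param scheme `"variable_only"`, `"offset_only"` or `"hybrid"`.
#' @param maxVarMods Per-peptide cap on variable modifications; `Inf` for
#'   unlimited.
#' @param isNterm For a concrete sequence, whether it sits at a protein
#'   N-terminus (enables protein-N-terminal variable mods).
#' @return A single numeric count, exact (all counts here are far below
#'   2^53).
#' @examples
#' metOx <- Modification("Oxidation", 15.994915, "M")
#' serPh <- Modification("Phospho", 79.966331, "S")
#' ## a 20-mer with 1 Met and 3 Ser:
#' countConfigurations(c(M = 1, S = 3, other = 16), list(metOx))         # 2
#' countConfigurations(c(M = 1, S = 3, other = 16), list(metOx, serPh)) # 16
#' @export
countConfigurations <- function(sequenceSpec, mods,
                                scheme = c("variable_only", "offset_only",
                                           "hybrid"),
                                maxVarMods = Inf, isNterm = FALSE) {
  scheme <- match.arg(scheme)
  if (is.numeric(sequenceSpec)) {
    if (any(sequenceSpec < 0))
      stop("negative residue counts are not allowed", call. = FALSE)
    counts <- sequenceSpec
    chars <- rep(names(counts), times = counts)
  } else {
    chars <- checkResidues(sequenceSpec)
  }
  reclass <- function(m, cls) { m@modClass <- cls; validObject(m); m }
  variable <- switch(scheme,
    variable_only = lapply(mods, reclass, "variable"),
    offset_only = list(),
    hybrid = Filter(function(m) m@modClass == "variable", mods))
  offsets <- switch(scheme,
    variable_only = list(),
    offset_only = lapply(mods, reclass, "offset"),
    hybrid = Filter(function(m) m@modClass == "offset" && m@massDelta != 0,
                    mods))

  sites <- varModSiteStructure(chars, variable, isNterm = isNterm)
  siteK <- vapply(sites, function(s) length(s$mods), numeric(1L))
  cap <- if (is.finite(maxVarMods)) as.integer(maxVarMods)
         else length(sites)
  V <- sum(occupancyPolynomial(siteK, cap))
  if (length(offsets) == 0L) return(V)

  ## Each configuration contributes 1 (no offset) plus one configuration per
  ## applicable offset.  Offset o is applicable unless every o-eligible
  ## residue position is occupied by a variable mod (or absent).
  total <- V
  sitePos <- vapply(sites, function(s) s$pos, integer(1L))
  for (o in offsets) {
    elig <- which(chars %in% o@residues) - 1L      # 0-based positions
    if (length(elig) == 0L) next                    # never applicable
    ## positions eligible for o that are also candidate var-mod sites
    blocked <- which(sitePos %in% elig)
    free_always <- length(elig) - length(blocked)   # o-residues no var mod hits
    if (free_always > 0L) {
      total <- total + V                            # always applicable
    } else {
      B <- sum(occupancyPolynomial(siteK, cap, force = blocked))
      total <- total + (V - B)
    }
  }
  total
}

#' Enumerate the hybrid peptidoform space of one peptide
#'
#' Generates every peptidoform of `sequence` under a
#' [ModificationSpace-class]: all assignments of at most `maxVarMods`
#' variable modifications to eligible sites (one delta per site), each
#' combined with either no mass offset or exactly one non-zero offset.  A
#' non-zero offset is emitted only when the configuration retains at least
#' one eligible residue not occupied by a variable modification; the offset
#' site is left unlocalized (localization is spectrum-driven, see
#' [localizeDeltaMass()]).  The fully unmodified form is always included.
#'
#' @param sequence Uppercase peptide string.
#' @param space A [ModificationSpace-class].
#' @param isNterm Whether the peptide starts at a protein N-terminus.
#' @return List of [Peptidoform-class] objects; no duplicates.
#' @examples
#' sp <- ModificationSpace(variable = Modification("Oxidation", 15.994915, "M"))
#' length(enumeratePeptidoforms("MKSSSR", sp))  # 2: with and without Met-ox
#' @export
enumeratePeptidoforms <- function(sequence, space, isNterm = FALSE) {
  chars <- checkResidues(sequence)
  variable <- space@variable
  sites <- varModSiteStructure(chars, variable, isNterm = isNterm)
  cap <- min(space@maxVarMods, length(sites))
  baseMass <- peptideMass(sequence, space@fixed)

  ## enumerate site assignments: per site, either empty or one applicable mod
  configs <- list(list(pos = integer(0L), mod = integer(0L)))
  for (s in sites) {
    newConfigs <- configs
    for (cfg in configs) {
      if (length(cfg$pos) >= cap) next
      for (mi in s$mods) {
        newConfigs[[length(newConfigs) + 1L]] <-
          list(pos = c(cfg$pos, s$pos), mod = c(cfg$mod, mi))
      }
    }
    configs <- newConfigs
  }

  nzOffsets <- Filter(function(m) m@massDelta != 0, space@offsets)
  zOff <- space@offsets[[which(vapply(space@offsets, function(m)
    m@massDelta == 0, logical(1L)))]]

  out <- vector("list", 0L)
  for (cfg in configs) {
    vm <- data.frame(
      pos = cfg$pos,
      mass = vapply(cfg$mod, function(i) variable[[i]]@massDelta, numeric(1L)),
      name = vapply(cfg$mod, function(i) variable[[i]]@name, character(1L)),
      stringsAsFactors = FALSE
    )
    vmMass <- sum(vm$mass)
    out[[length(out) + 1L]] <- new("Peptidoform",
      sequence = sequence, varModSites = vm, offset = zOff,
      offsetSite = NA_integer_, totalMass = baseMass + vmMass,
      isNterm = isNterm)
    occupied <- cfg$pos[cfg$pos >= 0L]
    for (off in nzOffsets) {
      elig <- which(chars %in% off@residues) - 1L
      elig <- setdiff(elig, occupied)
      if (length(elig) == 0L) next
      out[[length(out) + 1L]] <- new("Peptidoform",
        sequence = sequence, varModSites = vm, offset = off,
        offsetSite = NA_integer_,
        totalMass = baseMass + vmMass + off@massDelta,
        isNterm = isNterm)
    }
  }
  out
}
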