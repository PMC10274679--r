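## Group-based target-decoy FDR control.  PSMs are separated into three
## categories — unmodified, assigned modifications (a user-supplied
## residue/mass list), and other modifications — and each group receives its
## own score threshold at the nominal PSM-level FDR.  In datasets where
## modified spectra are a minority with a much larger effective search space,
## pooled filtering sets a threshold appropriate for neither category.

ASSIGNED_MOD_TOL <- 0.001

#' Parse an assigned-modification specification
#'
#' Accepts the filter-command syntax `"M:15.9949,n:42.0106"` (residue letter
#' or `n` for the peptide/protein N-terminus, colon, mass), or a data.frame
#' with columns `site` and `mass`, and returns the normalized data.frame.
#'
#' @param mods Character scalar or data.frame.
#' @return Data.frame with columns `site`, `mass`.
#' @examples
#' parseAssignedMods("M:15.9949,n:42.0106")
#' @export
parseAssignedMods <- function(mods) {
  if (is.data.frame(mods)) {
    stopifnot(all(c("site", "mass") %in% names(mods)))
    return(mods[c("site", "mass")])
  }
  if (length(mods) == 1L && grepl(",", mods)) {
    mods <- strsplit(mods, ",", fixed = TRUE)[[1L]]
  }
  parts <- strsplit(trimws(mods), ":", fixed = TRUE)
  bad <- vapply(parts, length, integer(1L)) != 2L
  if (any(bad))
    stop("malformed assigned-modification entry: '", mods[bad][1L], "'",
         call. = FALSE)
  data.frame(
    site = vapply(parts, `[`, character(1L), 1L),
    mass = as.numeric(vapply(parts, `[`, character(1L), 2L)),
    stringsAsFactors = FALSE)
}

## Decompose a PSM row's modifications into (site, mass) pairs.  Fixed mods
## never appear here (they are part of the base peptide mass).  An offset
## localized to a site contributes that residue; an unlocalized offset
## contributes site "?".
psmModPairs <- function(psm) {
  pairs <- list()
  if (nzchar(psm$var_mods)) {
    for (tok in strsplit(psm$var_mods, ",", fixed = TRUE)[[1L]]) {
      kv <- strsplit(tok, "/", fixed = TRUE)[[1L]]
      site <- if (kv[1L] == "N-term") "n" else substr(kv[1L], 1L, 1L)
      pairs[[length(pairs) + 1L]] <- list(site = site,
                                          mass = as.numeric(kv[2L]))
    }
  }
  if (psm$offset_mass != 0) {
    site <- if (is.na(psm$offset_pos)) "?" else
      substr(psm$sequence, psm$offset_pos, psm$offset_pos)
    pairs[[length(pairs) + 1L]] <- list(site = site, mass = psm$offset_mass)
  }
  pairs
}

#' Assign PSMs to FDR groups
#'
#' A PSM is `"unmodified"` iff it carries no variable modification and a zero
#' offset (fixed modifications are ignored); `"assigned"` iff every
#' modification it carries matches an entry of the assigned list by site and
#' mass (tolerance 0.001 Da); `"other"` otherwise — a single modification
#' outside the list, including any non-zero offset not listed, forces
#' `"other"`.
#'
#' @param psms PSM data.frame (see [searchDataset()]), or a single row.
#' @param assignedMods Assigned list, string or data.frame (see
#'   [parseAssignedMods()]); default `"M:15.9949,n:42.0106"` — methionine
#'   oxidation is kept apart from the rarer footprinting modifications
#'   because its large artifactual background would otherwise inflate the
#'   confidence of the rare-modification group.
#' @return Character vector of group labels, one per PSM.
#' @export
assignGroups <- function(psms, assignedMods = "M:15.9949,n:42.0106") {
  assigned <- parseAssignedMods(assignedMods)
  vapply(seq_len(nrow(psms)), function(i) {
    pairs <- psmModPairs(psms[i, ])
    if (length(pairs) == 0L) return("unmodified")
    ok <- vapply(pairs, function(p) {
      any(assigned$site == p$site &
            abs(assigned$mass - p$mass) <= ASSIGNED_MOD_TOL)
    }, logical(1L))
    if (all(ok)) "assigned" else "other"
  }, character(1L))
}

#' Target-decoy q-values
#'
#' PSMs are sorted by score descending; at each threshold the FDR estimate is
#' `#decoys / max(1, #targets)` among PSMs at or above the threshold, and the
#' q-value is the running minimum taken from the bottom of the list.  Equal
#' scores share one threshold.  A set without any target gets q = 1
#' throughout.
#'
#' @param score Numeric scores (higher = better).
#' @param isDecoy Logical decoy flags.
#' @return Numeric q-values in the input order.
#' @export
computeQvalues <- function(score, isDecoy) {
  n <- length(score)
  if (n == 0L) return(numeric())
  if (!any(!isDecoy)) return(rep(1, n))
  o <- order(score, decreasing = TRUE)
  d <- cumsum(isDecoy[o])
  t <- cumsum(!isDecoy[o])
  fdr <- d / pmax(1, t)
  ## equal scores share one threshold: each tie group takes the estimate at
  ## its last (lowest) element
  s <- score[o]
  grpEnd <- seq_len(n)
  if (n > 1L) {
    for (i in seq.int(n - 1L, 1L))
      if (s[i] == s[i + 1L]) grpEnd[i] <- grpEnd[i + 1L]
  }
  fdr <- fdr[grpEnd]
  q <- rev(cummin(rev(fdr)))
  out <- numeric(n)
  out[o] <- pmin(q, 1)
  out
}

#' Group-based FDR filtering
#'
#' Computes q-values independently within each of the three groups
#' (unmodified / assigned / other) and passes a PSM iff its q-value is at or
#' below `threshold` within its own group.  Decoy PSMs are used for
#' estimation but never pass.  The per-group minimum passing score is
#' attached as the `"thresholds"` attribute.
#'
#' @param psms PSM data.frame.
#' @param assignedMods See [assignGroups()].
#' @param threshold Nominal PSM-level FDR (default 0.01).
#' @return The PSM data.frame with added columns `group`, `q_value`,
#'   `passes`.
#' @export
groupFdrFilter <- function(psms, assignedMods = "M:15.9949,n:42.0106",
                           threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(psms) == 0L) {
    psms$group <- character(); psms$q_value <- numeric()
    psms$passes <- logical()
    attr(psms, "thresholds") <- numeric()
    return(psms)
  }
  psms$group <- assignGroups(psms, assignedMods)
  psms$q_value <- NA_real_
  for (g in unique(psms$group)) {
    sel <- psms$group == g
    psms$q_value[sel] <- computeQvalues(psms$score[sel], psms$is_decoy[sel])
  }
  psms$passes <- psms$q_value <= threshold & !psms$is_decoy
  thr <- vapply(sort(unique(psms$group)), function(g) {
    s <- psms$score[psms$group == g & psms$passes]
    if (length(s)) min(s) else NA_real_
  }, numeric(1L))
  attr(psms, "thresholds") <- thr
  psms
}

#' Regular (pooled) FDR filtering
#'
#' The same q-value estimator applied to the pooled PSM set, provided for
#' comparison with [groupFdrFilter()]: in mixtures where modified PSMs have a
#' much larger search space, the pooled threshold is appropriate for neither
#' category.  Group labels are still annotated for reporting.
#'
#' @inheritParams groupFdrFilter
#' @return The PSM data.frame with added columns `group`, `q_value`,
#'   `passes`.
#' @export
regularFdrFilter <- function(psms, assignedMods = "M:15.9949,n:42.0106",
                             threshold = 0.01) {
  stopifnot(threshold > 0, threshold <= 1)
  if (nrow(psms) == 0L) {
    psms$group <- character(); psms$q_value <- numeric()
    psms$passes <- logical()
    attr(psms, "thresholds") <- numeric()
    return(psms)
  }
  psms$group <- assignGroups(psms, assignedMods)
  psms$q_value <- computeQvalues(psms$score, psms$is_decoy)
  psms$passes <- psms$q_value <= threshold & !psms$is_decoy
  s <- psms$score[psms$passes]
  attr(psms, "thresholds") <- c(pooled = if (length(s)) min(s) else NA_real_)
  psms
}
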