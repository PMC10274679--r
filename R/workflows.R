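## End-to-end workflow orchestration and reporting.  Built-in workflow
## configurations mirror the standard FPOP single-search family: SS_MO (mass
## offsets only), and the hybrid workflows SS_H-I/II/III which promote
## oxidation on progressively more residues (M, MFHILVWY, MFHILVWYPR) from
## the offset list to the variable-modification list.  When a residue is
## promoted, it is removed from the oxidation offset's residue list rather
## than dropping the offset: the remaining residues stay searchable as
## offsets.

WORKFLOW_NAMES <- c("SS_MO", "SS_H-I", "SS_H-II", "SS_H-III")

oxVarResidues <- function(name) {
  switch(name,
         "SS_MO" = "",
         "SS_H-I" = "M",
         "SS_H-II" = "MFHILVWY",
         "SS_H-III" = "MFHILVWYPR",
         stop("unknown workflow name: '", name, "' (expected one of ",
              paste(WORKFLOW_NAMES, collapse = ", "), ")", call. = FALSE))
}

#' Built-in or file-based workflow configuration
#'
#' Returns a workflow configuration: a [ModificationSpace-class] (fixed Cys
#' carbamidomethylation; protein-N-terminal acetylation plus the workflow's
#' oxidation residues as variable modifications, max 3 per peptide; the FPOP
#' offset table with promoted residues removed from the oxidation offset),
#' the assigned-modification list for group FDR, and search parameters.
#'
#' @param workflow One of `"SS_MO"`, `"SS_H-I"`, `"SS_H-II"`, `"SS_H-III"`,
#'   or a path to a configuration file (see [parseWorkflowConfig()]).
#' @param params Search parameters ([searchParams()]).
#' @return List with elements `name`, `space`, `assignedMods`, `params`.
#' @examples
#' cfg <- workflowConfig("SS_H-II")
#' cfg$space
#' @export
workflowConfig <- function(workflow, params = searchParams()) {
  if (file.exists(workflow) && !workflow %in% WORKFLOW_NAMES)
    return(parseWorkflowConfig(workflow, params))
  oxres <- oxVarResidues(workflow)
  variable <- list(Modification("Acetyl", MASS_ACETYL, character(),
                                terminus = "protein-N",
                                modClass = "variable"))
  if (nzchar(oxres)) {
    variable <- c(variable, list(
      Modification("Oxidation", 15.994915, oxres, modClass = "variable")))
  }
  offsets <- fpopOffsetTable()
  if (nzchar(oxres)) {
    promoted <- strsplit(oxres, "", fixed = TRUE)[[1L]]
    offsets <- lapply(offsets, function(off) {
      if (off@name == "Oxidation") {
        off@residues <- setdiff(off@residues, promoted)
      }
      off
    })
  }
  space <- ModificationSpace(fixed = defaultFixedMods(), variable = variable,
                             offsets = offsets, maxVarMods = 3L)
  list(name = workflow, space = space,
       assignedMods = "M:15.9949,n:42.0106", params = params)
}

#' Serialize a workflow configuration to a plain-text file
#'
#' Key/value format mirroring the standard varmods syntax — residues, slash,
#' mass, parenthesized max count (`MFHILVWY/15.994915 (3)`; `N-term` for
#' protein-N-terminal) — plus an offsets block of mass, residue string and
#' label.  [parseWorkflowConfig()] round-trips this exactly.
#'
#' @param config Configuration list from [workflowConfig()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeWorkflowConfig <- function(config, path) {
  sp <- config$space
  lines <- c(
    paste0("name = ", config$name),
    paste0("max_var_mods = ", sp@maxVarMods),
    paste0("assigned_mods = ", config$assignedMods),
    vapply(sp@fixed, function(m) sprintf("fixedmod = %s/%.6f %s",
                                         paste(m@residues, collapse = ""),
                                         m@massDelta, m@name),
           character(1L)),
    vapply(sp@variable, function(m) {
      res <- if (m@terminus != "none") "N-term"
             else paste(m@residues, collapse = "")
      cap <- if (m@terminus != "none") 1L else sp@maxVarMods
      sprintf("varmod = %s/%.6f (%d) %s", res, m@massDelta, cap, m@name)
    }, character(1L)),
    vapply(Filter(function(m) m@massDelta != 0, sp@offsets), function(m)
      sprintf("offset = %.4f %s %s", m@massDelta,
              paste(m@residues, collapse = ""), m@name),
      character(1L))
  )
  writeLines(lines, path)
  invisible(path)
}

#' Parse a workflow configuration file
#'
#' @param path Configuration file written by [writeWorkflowConfig()] (or by
#'   hand in the same key/value syntax).
#' @param params Search parameters attached to the returned configuration.
#' @return Configuration list (see [workflowConfig()]).
#' @export
parseWorkflowConfig <- function(path, params = searchParams()) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- regmatches(lines, regexec("^\\s*([a-z_]+)\\s*=\\s*(.*)$", lines))
  keys <- vapply(kv, `[`, character(1L), 2L)
  vals <- trimws(vapply(kv, `[`, character(1L), 3L))
  getAll <- function(k) vals[keys == k]
  get1 <- function(k, default = NA) {
    v <- getAll(k); if (length(v)) v[1L] else default
  }
  name <- get1("name", "custom")
  cap <- as.integer(get1("max_var_mods", "3"))
  parseVarmod <- function(v) {
    m <- regexec("^(\\S+)/(-?[0-9.]+)\\s*\\((\\d+)\\)\\s*(.*)$", v)[[1L]]
    p <- regmatches(v, list(m))[[1L]]
    if (length(p) < 4L) stop("malformed varmod line: '", v, "'",
                             call. = FALSE)
    res <- p[2L]; mass <- as.numeric(p[3L])
    label <- if (length(p) >= 5L && nzchar(p[5L])) p[5L] else "varmod"
    if (res == "N-term") {
      Modification(label, mass, character(), terminus = "protein-N",
                   modClass = "variable")
    } else {
      Modification(label, mass, res, modClass = "variable")
    }
  }
  parseFixed <- function(v) {
    p <- strsplit(v, "[/ ]+")[[1L]]
    Modification(if (length(p) >= 3L) paste(p[-(1:2)], collapse = " ")
                 else "fixed",
                 as.numeric(p[2L]), p[1L], modClass = "fixed")
  }
  parseOffset <- function(v) {
    p <- strsplit(v, "\\s+")[[1L]]
    Modification(if (length(p) >= 3L) paste(p[-(1:2)], collapse = " ")
                 else "offset",
                 as.numeric(p[1L]), p[2L], modClass = "offset")
  }
  space <- ModificationSpace(
    fixed = lapply(getAll("fixedmod"), parseFixed),
    variable = lapply(getAll("varmod"), parseVarmod),
    offsets = lapply(getAll("offset"), parseOffset),
    maxVarMods = cap)
  list(name = name, space = space,
       assignedMods = get1("assigned_mods", "M:15.9949,n:42.0106"),
       params = params)
}

#' Write a PSM table as tab-separated psm.tsv
#'
#' @param psms PSM data.frame (filtered tables carry `group`, `q_value`,
#'   `passes`).
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writePsmTable <- function(psms, path) {
  out <- data.frame(
    scan = psms$scan,
    peptide = psms$sequence,
    assigned_modifications = psms$var_mods,
    offset_label = psms$offset_label,
    offset_mass = sprintf("%.4f", psms$offset_mass),
    localized_position = ifelse(is.na(psms$offset_pos), "unlocalized",
                                as.character(psms$offset_pos)),
    score = sprintf("%.4f", psms$score),
    q_value = if (!is.null(psms$q_value)) sprintf("%.6f", psms$q_value)
              else "",
    group = if (!is.null(psms$group)) psms$group else "",
    decoy = psms$is_decoy,
    stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run an end-to-end FPOP search workflow
#'
#' Reads the protein database and spectra, appends reversed decoys (unless
#' the database already contains them), digests, searches the hybrid
#' peptidoform space, applies group-based FDR filtering, and writes
#' `psm.tsv`, `psm_filtered.tsv` and `summary.txt` to `outDir`.
#' Deterministic: identical inputs and configuration give byte-identical
#' outputs.
#'
#' @param workflow Workflow name, configuration file path, or configuration
#'   list from [workflowConfig()].
#' @param fasta Path to the protein FASTA (target-only or target+decoy).
#' @param spectra Path to an MGF/mzML file, or a list of
#'   [Spectrum-class] objects.
#' @param outDir Output directory (created if needed); `NULL` for no files.
#' @param fdrThreshold Nominal PSM-level FDR (default 0.01).
#' @param decoyPrefix Decoy accession prefix (default `"rev_"`).
#' @return List with `psms` (all rank-1 PSMs), `filtered` (group-FDR
#'   annotated), `summary` (see [summarizeModifications()]) and `config`.
#' @export
runWorkflow <- function(workflow, fasta, spectra, outDir = NULL,
                        fdrThreshold = 0.01, decoyPrefix = "rev_") {
  config <- if (is.list(workflow)) workflow else workflowConfig(workflow)
  proteins <- if (is.data.frame(fasta)) fasta
              else readProteinFasta(fasta, decoyPrefix)
  if (!any(proteins$is_decoy))
    proteins <- appendDecoys(proteins, decoyPrefix)
  peptides <- digestDatabase(proteins)
  if (!is.list(spectra) || is.data.frame(spectra))
    spectra <- readSpectra(spectra)
  psms <- searchDataset(spectra, peptides, config$space, config$params)
  filtered <- groupFdrFilter(psms, config$assignedMods, fdrThreshold)
  summary <- summarizeModifications(filtered[filtered$passes, , drop = FALSE])
  ## spectra with no explaining PSM (e.g. deltas outside the hybrid space,
  ## such as peptides carrying two rare modifications) are reported
  allScans <- unique(vapply(spectra, scanId, character(1L)))
  summary$nScans <- length(allScans)
  summary$unexplainedScans <- setdiff(allScans,
                                      filtered$scan[filtered$passes])
  if (!is.null(outDir)) {
    if (!dir.exists(outDir)) dir.create(outDir, recursive = TRUE)
    writePsmTable(psms, file.path(outDir, "psm.tsv"))
    writePsmTable(filtered[filtered$passes, , drop = FALSE],
                  file.path(outDir, "psm_filtered.tsv"))
    writeSummary(summary, config, file.path(outDir, "summary.txt"))
  }
  list(psms = psms, filtered = filtered, summary = summary, config = config)
}

#' Per-group and per-modification PSM counts
#'
#' @param psms A (typically filtered) PSM data.frame; a `group` column is
#'   added if absent.
#' @return List with `byGroup` (PSM counts per FDR group; sums to the table
#'   row count) and `byModification` (counts per modification label +
#'   residue pair; one multi-modified PSM contributes to several rows).
#' @export
summarizeModifications <- function(psms) {
  groups <- c("unmodified", "assigned", "other")
  if (nrow(psms) == 0L) {
    return(list(
      byGroup = data.frame(group = groups, n = 0L),
      byModification = data.frame(label = character(), residue = character(),
                                  n = integer())))
  }
  if (is.null(psms$group)) psms$group <- assignGroups(psms)
  byGroup <- data.frame(
    group = groups,
    n = vapply(groups, function(g) sum(psms$group == g), integer(1L)),
    row.names = NULL)
  mods <- list()
  for (i in seq_len(nrow(psms))) {
    if (nzchar(psms$var_mods[i])) {
      for (tok in strsplit(psms$var_mods[i], ",", fixed = TRUE)[[1L]]) {
        kv <- strsplit(tok, "/", fixed = TRUE)[[1L]]
        res <- if (kv[1L] == "N-term") "N-term" else substr(kv[1L], 1L, 1L)
        label <- if (res == "N-term") "Acetyl"
                 else sprintf("varmod %.4f", as.numeric(kv[2L]))
        if (abs(as.numeric(kv[2L]) - 15.9949) < 0.001) label <- "Oxidation"
        mods[[length(mods) + 1L]] <- c(label, res)
      }
    }
    if (psms$offset_mass[i] != 0) {
      res <- if (is.na(psms$offset_pos[i])) "?"
             else substr(psms$sequence[i], psms$offset_pos[i],
                         psms$offset_pos[i])
      mods[[length(mods) + 1L]] <- c(psms$offset_label[i], res)
    }
  }
  byModification <- if (length(mods)) {
    m <- do.call(rbind, mods)
    agg <- stats::aggregate(list(n = rep(1L, nrow(m))),
                            by = list(label = m[, 1L], residue = m[, 2L]),
                            FUN = sum)
    agg[order(-agg$n, agg$label, agg$residue), , drop = FALSE]
  } else {
    data.frame(label = character(), residue = character(), n = integer())
  }
  rownames(byModification) <- NULL
  list(byGroup = byGroup, byModification = byModification)
}

writeSummary <- function(summary, config, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(
    paste0("workflow: ", config$name),
    paste0("assigned_mods: ", config$assignedMods),
    "",
    "PSMs per FDR group:",
    sprintf("  %-12s %d", summary$byGroup$group, summary$byGroup$n),
    "",
    sprintf("scans without a confident PSM (unexplained): %d of %d",
            length(summary$unexplainedScans), summary$nScans),
    "",
    "PSMs per modification (label residue count):",
    if (nrow(summary$byModification))
      sprintf("  %-28s %-7s %d", summary$byModification$label,
              summary$byModification$residue, summary$byModification$n)
    else "  (none)"
  ), con)
  invisible(path)
}
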