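## Protein database handling: FASTA I/O, reversed-sequence decoys and
## in-silico tryptic digestion.

#' Read a protein FASTA database
#'
#' One entry per record; the header token before the first whitespace is the
#' accession, the remainder the description.  Sequences are uppercased and
#' trailing/embedded `*` stop codons are stripped.
#'
#' @param path Path to a FASTA file.
#' @param decoyPrefix Accessions starting with this prefix are flagged as
#'   decoys.
#' @return A data.frame with columns `accession`, `description`, `sequence`,
#'   `is_decoy`, `is_contaminant`.
#' @export
readProteinFasta <- function(path, decoyPrefix = "rev_") {
  if (!file.exists(path))
    stop("FASTA file not found: ", path, call. = FALSE)
  aas <- tryCatch(Biostrings::readAAStringSet(path),
                  error = function(e) stop("malformed FASTA file '", path,
                                           "': ", conditionMessage(e),
                                           call. = FALSE))
  if (length(aas) == 0L)
    stop("FASTA file '", path, "' contains no records", call. = FALSE)
  headers <- names(aas)
  acc <- sub("\\s.*$", "", headers)
  desc <- ifelse(grepl("\\s", headers), sub("^\\S+\\s+", "", headers), "")
  seqs <- toupper(gsub("*", "", as.character(aas), fixed = TRUE))
  if (any(!nzchar(seqs)))
    stop("FASTA record with empty sequence: ", acc[!nzchar(seqs)][1L],
         call. = FALSE)
  data.frame(
    accession = acc, description = desc, sequence = unname(seqs),
    is_decoy = startsWith(acc, decoyPrefix),
    is_contaminant = startsWith(acc, "contam_"),
    stringsAsFactors = FALSE
  )
}

#' Write protein entries to FASTA
#'
#' @param proteins Data.frame as returned by [readProteinFasta()].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
writeProteinFasta <- function(proteins, path) {
  hdr <- ifelse(nzchar(proteins$description),
                paste(proteins$accession, proteins$description),
                proteins$accession)
  lines <- as.vector(rbind(paste0(">", hdr), proteins$sequence))
  writeLines(lines, path)
  invisible(path)
}

#' Append reversed-sequence decoys
#'
#' Appends one full-sequence-reversal decoy per target protein, with the
#' decoy accession formed as `prefix + target accession`.  Decoys carry the
#' same length and amino-acid composition as their source; pairing is stable
#' (decoy i corresponds to target i).
#'
#' @param proteins Target protein data.frame.
#' @param prefix Decoy accession prefix (default `"rev_"`).
#' @return Data.frame of length `2 * nrow(proteins)`: targets then decoys.
#' @export
appendDecoys <- function(proteins, prefix = "rev_") {
  if (any(startsWith(proteins$accession, prefix)))
    stop("decoy prefix '", prefix, "' collides with existing accessions",
         call. = FALSE)
  rev1 <- function(x) paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]),
                            collapse = "")
  decoys <- proteins
  decoys$accession <- paste0(prefix, proteins$accession)
  decoys$sequence <- vapply(proteins$sequence, rev1, character(1L),
                            USE.NAMES = FALSE)
  decoys$is_decoy <- TRUE
  rbind(proteins, decoys)
}

#' In-silico tryptic digestion
#'
#' Digests one protein with the `stricttrypsin` rule: cleavage C-terminal to
#' every K or R, with no proline exception.  Peptides with 0 to
#' `missedCleavages` missed cleavage sites and lengths within
#' `[minLength, maxLength]` are returned.  When the protein starts with
#' methionine and `clipNtermMet = TRUE`, peptides are additionally generated
#' from the Met-clipped form; peptides beginning at the protein N-terminus
#' (of either form) are flagged `is_nterm_of_protein` and are thereby
#' eligible for protein-N-terminal modifications.  Duplicates by
#' `(sequence, missed_cleavages)` are collapsed.
#'
#' @param sequence Protein sequence string (or a one-row protein data.frame).
#' @param accession Parent accession recorded on each peptide.
#' @param missedCleavages Maximum missed cleavages (default 2).
#' @param minLength,maxLength Peptide length bounds (defaults 7 and 50).
#' @param clipNtermMet Generate peptides from the Met-clipped protein form
#'   when the sequence starts with M (default TRUE).
#' @return Data.frame with columns `sequence`, `parent_accession`,
#'   `missed_cleavages`, `is_nterm_of_protein`.
#' @export
digestProtein <- function(sequence, accession = "protein",
                          missedCleavages = 2L, minLength = 7L,
                          maxLength = 50L, clipNtermMet = TRUE) {
  if (is.data.frame(sequence)) {
    accession <- sequence$accession[1L]
    sequence <- sequence$sequence[1L]
  }
  digestOne <- function(seq, ntermOffset) {
    chars <- strsplit(seq, "", fixed = TRUE)[[1L]]
    n <- length(chars)
    cut <- which(chars %in% c("K", "R"))      # cleave after these positions
    bounds <- unique(c(0L, cut[cut < n], n))  # segment boundaries
    nseg <- length(bounds) - 1L
    res <- list()
    for (i in seq_len(nseg)) {
      for (mc in 0:missedCleavages) {
        j <- i + mc
        if (j > nseg) break
        from <- bounds[i] + 1L
        to <- bounds[j + 1L]
        len <- to - from + 1L
        if (len < minLength || len > maxLength) next
        res[[length(res) + 1L]] <- data.frame(
          sequence = substr(seq, from, to),
          missed_cleavages = mc,
          is_nterm_of_protein = (from == 1L),
          stringsAsFactors = FALSE
        )
      }
    }
    if (length(res)) do.call(rbind, res)
    else data.frame(sequence = character(), missed_cleavages = integer(),
                    is_nterm_of_protein = logical())
  }
  peps <- digestOne(sequence, 0L)
  if (clipNtermMet && startsWith(sequence, "M") && nchar(sequence) > 1L) {
    clipped <- digestOne(substr(sequence, 2L, nchar(sequence)), 1L)
    peps <- rbind(peps, clipped)
  }
  if (nrow(peps) == 0L) {
    peps$parent_accession <- character()
    return(peps)
  }
  key <- paste(peps$sequence, peps$missed_cleavages)
  ## collapse duplicates (e.g. identical peptide from clipped + unclipped form)
  agg <- !duplicated(key)
  nterm <- tapply(peps$is_nterm_of_protein, key, any)
  peps <- peps[agg, , drop = FALSE]
  peps$is_nterm_of_protein <- as.logical(nterm[paste(peps$sequence,
                                                     peps$missed_cleavages)])
  peps$parent_accession <- accession
  rownames(peps) <- NULL
  peps
}

#' Digest a whole protein database
#'
#' Applies [digestProtein()] to every entry and collapses duplicate
#' `(sequence, missed_cleavages)` pairs across proteins, merging parent
#' accessions (semicolon-separated).  A peptide is a decoy peptide iff all
#' of its parents are decoys.
#'
#' @param proteins Protein data.frame (see [readProteinFasta()]).
#' @param ... Passed to [digestProtein()].
#' @return Data.frame with columns `sequence`, `parent_accession`,
#'   `missed_cleavages`, `is_nterm_of_protein`, `is_decoy`, `mass` (with
#'   fixed Cys carbamidomethylation applied).
#' @export
digestDatabase <- function(proteins, ...) {
  parts <- lapply(seq_len(nrow(proteins)), function(i) {
    p <- digestProtein(proteins$sequence[i], proteins$accession[i], ...)
    if (nrow(p)) p$is_decoy <- proteins$is_decoy[i]
    else p$is_decoy <- logical()
    p
  })
  peps <- do.call(rbind, parts)
  if (is.null(peps) || nrow(peps) == 0L)
    return(data.frame(sequence = character(), parent_accession = character(),
                      missed_cleavages = integer(),
                      is_nterm_of_protein = logical(), is_decoy = logical(),
                      mass = numeric()))
  key <- paste(peps$sequence, peps$missed_cleavages)
  parent <- tapply(peps$parent_accession, key,
                   function(x) paste(unique(x), collapse = ";"))
  nterm <- tapply(peps$is_nterm_of_protein, key, any)
  decoy <- tapply(peps$is_decoy, key, all)
  peps <- peps[!duplicated(key), , drop = FALSE]
  k <- paste(peps$sequence, peps$missed_cleavages)
  peps$parent_accession <- as.character(parent[k])
  peps$is_nterm_of_protein <- as.logical(nterm[k])
  peps$is_decoy <- as.logical(decoy[k])
  peps$mass <- vapply(peps$sequence, peptideMass, numeric(1L),
                      USE.NAMES = FALSE)
  rownames(peps) <- NULL
  peps
}

#' Monoisotopic peptide mass
#'
#' Sum of residue masses plus water, plus the deltas of any fixed
#' modifications applied at each eligible residue.  The default fixed
#' modification is Cys carbamidomethylation (+57.021464 Da), the standard
#' alkylation from sample preparation.
#'
#' @param sequence Peptide string.
#' @param fixedMods List of fixed-class [Modification-class] objects; the
#'   default applies carbamidomethylation of cysteine.
#' @return Neutral monoisotopic mass in Da.
#' @examples
#' peptideMass("GG")   # 132.0535
#' @export
peptideMass <- function(sequence, fixedMods = defaultFixedMods()) {
  chars <- checkResidues(sequence)
  m <- sum(AA_MASSES[chars]) + MASS_WATER
  for (fx in fixedMods)
    m <- m + fx@massDelta * sum(chars %in% fx@residues)
  m
}

#' Default fixed-modification list (Cys carbamidomethylation)
#'
#' @return List with the single fixed carbamidomethyl-C modification.
#' @export
defaultFixedMods <- function() {
  list(Modification("Carbamidomethyl", MASS_CARBAMIDOMETHYL, "C",
                    modClass = "fixed"))
}
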