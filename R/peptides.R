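#' Create a peptide record
#'
#' A peptide record bundles a mature (leaderless) core peptide with an
#' optional leader sequence and a human-readable variant name. The core
#' peptide is the secreted antimicrobial portion of a lanthipeptide
#' precursor after cleavage of the N-terminal leader.
#'
#' @param id Short unique label (e.g. `"nisA"`).
#' @param core_seq Mature core peptide, one-letter amino-acid codes.
#' @param variant_name Free-text variant name (e.g. `"nisin A"`);
#'   defaults to `id`.
#' @param leader_seq Optional leader peptide; may be empty.
#' @return An object of class `peptide_record`.
#' @examples
#' peptide_record("nisA", "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK",
#'                variant_name = "nisin A")
#' @export
peptide_record <- function(id, core_seq, variant_name = id,
                           leader_seq = "") {
  stopifnot(is.character(id), length(id) == 1L, nzchar(id))
  .assert_aa_string(core_seq, "core_seq")
  if (nzchar(leader_seq)) .assert_aa_string(leader_seq, "leader_seq")
  structure(
    list(id = id, variant_name = variant_name,
         leader_seq = leader_seq, core_seq = core_seq),
    class = "peptide_record"
  )
}

#' @export
print.peptide_record <- function(x, ...) {
  cat(sprintf("<peptide_record> %s (%s)\n", x$id, x$variant_name))
  if (nzchar(x$leader_seq))
    cat(sprintf("  leader: %s\n", x$leader_seq))
  cat(sprintf("  core:   %s (%d aa)\n", x$core_seq, nchar(x$core_seq)))
  invisible(x)
}

.as_core_seq <- function(x) {
  if (inherits(x, "peptide_record")) return(x$core_seq)
  .assert_aa_string(x)
  x
}

.check_unique_ids <- function(peptides) {
  ids <- vapply(peptides, function(p) p$id, character(1))
  if (anyDuplicated(ids))
    stop("duplicate peptide ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "),
         call. = FALSE)
  ids
}

#' Read peptides from a FASTA file
#'
#' The first whitespace-delimited token of each description line is taken
#' as the record id; the remainder (if any) as the variant name.
#'
#' @param path Path to a protein FASTA file.
#' @return A named list of [peptide_record()] objects.
#' @export
read_peptide_fasta <- function(path) {
  aa <- Biostrings::readAAStringSet(path)
  if (length(aa) == 0L) stop("no sequences in ", path, call. = FALSE)
  peptides <- lapply(seq_along(aa), function(i) {
    header <- names(aa)[i]
    id <- sub("\\s.*$", "", header)
    rest <- sub("^\\S+\\s*", "", header)
    peptide_record(id, as.character(aa[[i]]),
                   variant_name = if (nzchar(rest)) rest else id)
  })
  names(peptides) <- vapply(peptides, function(p) p$id, character(1))
  .check_unique_ids(peptides)
  peptides
}

#' Write peptides to a FASTA file
#'
#' @param peptides A list of [peptide_record()] objects.
#' @param path Output path.
#' @param what Write the `"core"` (default) or the `"precursor"`
#'   (leader + core) sequence.
#' @return `path`, invisibly.
#' @export
write_peptide_fasta <- function(peptides, path, what = c("core", "precursor")) {
  what <- match.arg(what)
  if (inherits(peptides, "peptide_record")) peptides <- list(peptides)
  .check_unique_ids(peptides)
  seqs <- vapply(peptides, function(p) {
    if (what == "precursor") paste0(p$leader_seq, p$core_seq) else p$core_seq
  }, character(1))
  aa <- Biostrings::AAStringSet(seqs)
  names(aa) <- vapply(peptides, function(p)
    paste(p$id, p$variant_name), character(1))
  Biostrings::writeXStringSet(aa, path)
  invisible(path)
}

#' Packaged nisin core peptide references
#'
#' Mature core peptides of nisin A and of variants derived from it by
#' published edit lists: nisin Z (the single substitution His27Asn),
#' nisin E (two deletions, Ser29 and Ile30, plus eight substitutions,
#' reference-numbered on nisin A), and nisin U (reconstructed from nisin E
#' by Ala15Ile, Ile21Leu and removal of the C-terminal Asn32). The
#' variants are built programmatically with [apply_edits()] so the edit
#' lists themselves are the source of truth.
#'
#' The nisin A leader peptide is included on the `nisA` record; leaders of
#' the other variants are not carried.
#'
#' @return A named list of [peptide_record()] objects
#'   (`nisA`, `nisZ`, `nisE`, `nisU`).
#' @examples
#' refs <- nisin_reference_peptides()
#' nchar(refs$nisE$core_seq)  # 32
#' @export
nisin_reference_peptides <- function() {
  nisA <- "ITSISLCTPGCKTGALMGCNMKTATCHCSIHVSK"
  nisA_leader <- "MSTKDFNLDLVSVSKKDSGASPR"

  edits_Z <- data.frame(kind = "substitution", ref_pos = 27L,
                        ref_aa = "H", alt_aa = "N",
                        stringsAsFactors = FALSE)
  nisZ <- apply_edits(nisA, edits_Z)

  edits_E <- data.frame(
    kind = c("substitution", "substitution", "substitution", "substitution",
             "substitution", "deletion", "deletion", "substitution",
             "substitution", "substitution"),
    ref_pos = c(4L, 18L, 20L, 21L, 27L, 29L, 30L, 32L, 33L, 34L),
    ref_aa = c("I", "G", "N", "M", "H", "S", "I", "V", "S", "K"),
    alt_aa = c("K", "T", "P", "I", "G", "", "", "F", "G", "N"),
    stringsAsFactors = FALSE
  )
  nisE <- apply_edits(nisA, edits_E)

  # nisin U, reconstructed relative to nisin E: Ala15Ile, Ile21Leu,
  # and the C-terminal Asn32 of nisin E is absent from nisin U.
  edits_U <- data.frame(
    kind = c("substitution", "substitution", "deletion"),
    ref_pos = c(15L, 21L, 32L),
    ref_aa = c("A", "I", "N"),
    alt_aa = c("I", "L", ""),
    stringsAsFactors = FALSE
  )
  nisU <- apply_edits(nisE, edits_U)

  list(
    nisA = peptide_record("nisA", nisA, "nisin A", leader_seq = nisA_leader),
    nisZ = peptide_record("nisZ", nisZ, "nisin Z"),
    nisE = peptide_record("nisE", nisE, "nisin E"),
    nisU = peptide_record("nisU", nisU, "nisin U")
  )
}
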