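## Edit lists: reference-numbered substitutions, deletions and insertions.
##
## Conventions:
##   * ref_pos is 1-based in the numbering of the ORIGINAL reference;
##     deletions never shift the coordinates of later edits.
##   * an insertion with ref_pos = p places the new residue immediately
##     before reference position p; a C-terminal extension therefore has
##     ref_pos = nchar(ref) + 1, and is named by the reference-extended
##     position (e.g. "insAsn32" for an extra residue after a 31-mer).
##   * names use three-letter codes: "Ile4Lys", "ΔSer29", "insAsn32".

.EDIT_KINDS <- c("substitution", "deletion", "insertion")

.validate_edits <- function(edits, ref_len, ref_chars = NULL) {
  if (is.null(edits) || (is.data.frame(edits) && nrow(edits) == 0L)) {
    return(data.frame(kind = character(), ref_pos = integer(),
                      ref_aa = character(), alt_aa = character(),
                      stringsAsFactors = FALSE))
  }
  stopifnot(is.data.frame(edits),
            all(c("kind", "ref_pos", "ref_aa", "alt_aa") %in% names(edits)))
  edits <- edits[, c("kind", "ref_pos", "ref_aa", "alt_aa")]
  edits$ref_pos <- as.integer(edits$ref_pos)
  bad_kind <- setdiff(unique(edits$kind), .EDIT_KINDS)
  if (length(bad_kind))
    stop("unknown edit kind(s): ", paste(bad_kind, collapse = ", "),
         call. = FALSE)
  ins <- edits$kind == "insertion"
  if (any(edits$ref_pos[!ins] < 1L) || any(edits$ref_pos[!ins] > ref_len))
    stop("edit ref_pos outside 1..", ref_len, call. = FALSE)
  if (any(edits$ref_pos[ins] < 1L) || any(edits$ref_pos[ins] > ref_len + 1L))
    stop("insertion ref_pos outside 1..", ref_len + 1L, call. = FALSE)
  if (anyDuplicated(edits$ref_pos[!ins]))
    stop("duplicate edit position in reference numbering", call. = FALSE)
  sub <- edits$kind == "substitution"
  if (any(edits$alt_aa[edits$kind == "deletion"] != ""))
    stop("deletions must have empty alt_aa", call. = FALSE)
  if (any(edits$ref_aa[ins] != ""))
    stop("insertions must have empty ref_aa", call. = FALSE)
  if (any(edits$ref_aa[sub] == edits$alt_aa[sub]))
    stop("substitution with identical ref_aa and alt_aa", call. = FALSE)
  for (aa in c(edits$ref_aa[!ins], edits$alt_aa[sub | ins]))
    if (!aa %in% AA1)
      stop("non-canonical residue in edit list: ", aa, call. = FALSE)
  if (!is.null(ref_chars)) {
    chk <- !ins
    mism <- edits$ref_aa[chk] != ref_chars[edits$ref_pos[chk]]
    if (any(mism)) {
      p <- edits$ref_pos[chk][mism][1]
      stop(sprintf(
        "edit list expects %s at reference position %d but found %s %s",
        edits$ref_aa[chk][mism][1], p, ref_chars[p],
        "(wrong reference or numbering?)"), call. = FALSE)
    }
  }
  edits[order(edits$ref_pos, match(edits$kind, .EDIT_KINDS)), , drop = FALSE]
}

#' Apply a reference-numbered edit list to a peptide
#'
#' Applies substitutions, deletions and insertions expressed in the
#' coordinates of the original reference sequence. Because positions are
#' resolved on the reference before any deletion shifts coordinates, the
#' published style of edit list (e.g. the ten differences that turn
#' mature nisin A into mature nisin E) can be applied verbatim.
#'
#' @param ref_core Reference core peptide (string or [peptide_record()]).
#' @param edits Data frame with columns `kind`
#'   (`substitution`/`deletion`/`insertion`), `ref_pos`, `ref_aa`,
#'   `alt_aa`; or a [diff_variants()] result.
#' @return The edited amino-acid string.
#' @examples
#' apply_edits("ITSISL", data.frame(kind = "substitution", ref_pos = 4,
#'                                  ref_aa = "I", alt_aa = "K"))
#' @export
apply_edits <- function(ref_core, edits) {
  ref <- .as_core_seq(ref_core)
  chars <- strsplit(ref, "")[[1]]
  n <- length(chars)
  edits <- .validate_edits(edits, n, ref_chars = chars)
  if (nrow(edits) == 0L) return(ref)
  out <- character(0)
  for (p in seq_len(n + 1L)) {
    here <- edits[edits$ref_pos == p, , drop = FALSE]
    ins <- here[here$kind == "insertion", , drop = FALSE]
    if (nrow(ins)) out <- c(out, ins$alt_aa)
    if (p > n) break
    if (nrow(here[here$kind == "deletion", , drop = FALSE])) next
    s <- here[here$kind == "substitution", , drop = FALSE]
    out <- c(out, if (nrow(s)) s$alt_aa[1] else chars[p])
  }
  paste(out, collapse = "")
}

#' Format edit names in three-letter code
#'
#' Substitutions are written `Ile4Lys`, deletions `ΔSer29`, and
#' insertions `insAsn32`, always in reference numbering.
#'
#' @param edits Edit data frame (see [apply_edits()]).
#' @return Character vector of names, one per edit.
#' @export
format_edit_names <- function(edits) {
  if (nrow(edits) == 0L) return(character(0))
  vapply(seq_len(nrow(edits)), function(i) {
    e <- edits[i, ]
    switch(e$kind,
      substitution = paste0(AA3[[e$ref_aa]], e$ref_pos, AA3[[e$alt_aa]]),
      deletion     = paste0("\u0394", AA3[[e$ref_aa]], e$ref_pos),
      insertion    = paste0("ins", AA3[[e$alt_aa]], e$ref_pos))
  }, character(1))
}

#' Parse a three-letter-code edit name
#'
#' Inverse of [format_edit_names()]: `"Ile4Lys"`, `"ΔSer29"` and
#' `"insAsn32"` parse back to their `(kind, ref_pos, ref_aa, alt_aa)`
#' tuples.
#'
#' @param name A single edit name.
#' @return One-row edit data frame.
#' @export
parse_edit_name <- function(name) {
  stopifnot(is.character(name), length(name) == 1L)
  aa3_rx <- "([A-Z][a-z]{2})"
  row <- function(kind, ref_pos, ref_aa, alt_aa)
    data.frame(kind = kind, ref_pos = as.integer(ref_pos),
               ref_aa = ref_aa, alt_aa = alt_aa, stringsAsFactors = FALSE)
  to1 <- function(x) {
    if (is.na(match(x, names(AA3_TO_1))))
      stop("unknown three-letter code: ", x, call. = FALSE)
    AA3_TO_1[[x]]
  }
  if (grepl(paste0("^\u0394", aa3_rx, "([0-9]+)$"), name)) {
    m <- regmatches(name, regexec(paste0("^\u0394", aa3_rx, "([0-9]+)$"), name))[[1]]
    return(row("deletion", m[3], to1(m[2]), ""))
  }
  if (grepl(paste0("^ins", aa3_rx, "([0-9]+)$"), name)) {
    m <- regmatches(name, regexec(paste0("^ins", aa3_rx, "([0-9]+)$"), name))[[1]]
    return(row("insertion", m[3], "", to1(m[2])))
  }
  if (grepl(paste0("^", aa3_rx, "([0-9]+)", aa3_rx, "$"), name)) {
    m <- regmatches(name,
                    regexec(paste0("^", aa3_rx, "([0-9]+)", aa3_rx, "$"), name))[[1]]
    return(row("substitution", m[3], to1(m[2]), to1(m[4])))
  }
  stop("cannot parse edit name: ", name, call. = FALSE)
}

#' Derive the edit list between two core peptides
#'
#' Globally aligns the query to the reference (see [global_align()]) and
#' reads the substitutions, deletions and insertions off the alignment
#' columns. Positions and names use 1-based reference numbering, so
#' applying the result with [apply_edits()] reproduces the query exactly.
#'
#' @param ref,query Peptide records or amino-acid strings; `ref` defines
#'   the numbering.
#' @param ... Passed to [global_align()].
#' @return A `variant_diff`: an edit data frame with a `name` column and
#'   attributes `ref_id`, `query_id`.
#' @examples
#' refs <- nisin_reference_peptides()
#' diff_variants(refs$nisA, refs$nisE)
#' @export
diff_variants <- function(ref, query, ...) {
  ref_id <- if (inherits(ref, "peptide_record")) ref$id else "ref"
  query_id <- if (inherits(query, "peptide_record")) query$id else "query"
  aln <- global_align(ref, query, ...)
  ra <- strsplit(aln$aligned_ref, "")[[1]]
  qa <- strsplit(aln$aligned_query, "")[[1]]
  kind <- character(0); pos <- integer(0)
  raa <- character(0); qaa <- character(0)
  rp <- 0L
  for (k in seq_along(ra)) {
    if (ra[k] != "-") rp <- rp + 1L
    if (qa[k] == "-") {
      kind <- c(kind, "deletion"); pos <- c(pos, rp)
      raa <- c(raa, ra[k]); qaa <- c(qaa, "")
    } else if (ra[k] == "-") {
      kind <- c(kind, "insertion"); pos <- c(pos, rp + 1L)
      raa <- c(raa, ""); qaa <- c(qaa, qa[k])
    } else if (ra[k] != qa[k]) {
      kind <- c(kind, "substitution"); pos <- c(pos, rp)
      raa <- c(raa, ra[k]); qaa <- c(qaa, qa[k])
    }
  }
  edits <- data.frame(kind = kind, ref_pos = pos, ref_aa = raa,
                      alt_aa = qaa, stringsAsFactors = FALSE)
  edits$name <- format_edit_names(edits)
  structure(edits, class = c("variant_diff", "data.frame"),
            ref_id = ref_id, query_id = query_id)
}

#' @export
print.variant_diff <- function(x, ...) {
  cat(sprintf("<variant_diff> %s -> %s: %d edit(s)\n",
              attr(x, "ref_id"), attr(x, "query_id"), nrow(x)))
  if (nrow(x)) print.data.frame(x, row.names = FALSE)
  invisible(x)
}

#' Write a variant diff to TSV
#'
#' @param diff A [diff_variants()] result.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_variant_diff_tsv <- function(diff, path) {
  out <- data.frame(ref_id = attr(diff, "ref_id") %||% "ref",
                    query_id = attr(diff, "query_id") %||% "query",
                    as.data.frame(diff), stringsAsFactors = FALSE)
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Extract the hinge region of a nisin-like core peptide
#'
#' The hinge is the flexible tripeptide at nisin A positions 20-22 that
#' links the lipid-II-binding and pore-forming halves of the peptide
#' (NMK in nisin A, PIK in nisin E, PLK in nisin U). The query is
#' globally aligned to the reference and the residues aligned to the
#' reference hinge positions are returned.
#'
#' @param core Query core peptide (string or [peptide_record()]).
#' @param ref Reference core defining the numbering; defaults to mature
#'   nisin A.
#' @param positions Reference positions of the hinge (default 20:22).
#' @param ... Passed to [global_align()].
#' @return Three-character hinge string.
#' @examples
#' hinge_region(nisin_reference_peptides()$nisE)  # "PIK"
#' @export
hinge_region <- function(core, ref = nisin_reference_peptides()$nisA,
                         positions = 20:22, ...) {
  aln <- global_align(ref, core, ...)
  ra <- strsplit(aln$aligned_ref, "")[[1]]
  qa <- strsplit(aln$aligned_query, "")[[1]]
  rp <- cumsum(ra != "-")
  out <- vapply(positions, function(p) {
    k <- which(rp == p & ra != "-")
    if (length(k) != 1L)
      stop("reference position ", p, " not present in alignment",
           call. = FALSE)
    qa[k]
  }, character(1))
  if (any(out == "-"))
    stop("hinge position(s) ",
         paste(positions[out == "-"], collapse = ", "),
         " deleted in query", call. = FALSE)
  paste(out, collapse = "")
}
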