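## Bacterial ORF calling on both strands.
##
## Conventions (bacterial genetic code, translation table 11):
##   * start codons ATG, GTG, TTG, always translated as Met;
##   * stop codons TAA, TAG, TGA;
##   * an ORF is the longest open frame per stop codon per frame (the
##     first start codon after the previous stop), must end in a stop,
##     and spans start codon through stop codon inclusive;
##   * codons containing ambiguous bases act as frame breakers: they
##     terminate the current open segment and never appear inside a
##     reported ORF.

.START_CODONS <- c("ATG", "GTG", "TTG")
.STOP_CODONS <- c("TAA", "TAG", "TGA")

.genetic_code <- function() {
  if (is.null(.lantivar_cache$gencode)) {
    gc <- Biostrings::GENETIC_CODE
    .lantivar_cache$gencode <- setNames(as.character(gc), names(gc))
  }
  .lantivar_cache$gencode
}

.translate_codons <- function(codons) {
  aa <- .genetic_code()[codons]
  aa[is.na(aa)] <- "X"
  aa
}

.scan_orfs_one_strand <- function(s, min_aa) {
  n <- nchar(s)
  out <- list()
  for (frame in 0:2) {
    usable <- n - frame
    n_codons <- usable %/% 3L
    if (n_codons < 2L) next
    starts_nt <- frame + 1L + 3L * (seq_len(n_codons) - 1L)
    codons <- substring(s, starts_nt, starts_nt + 2L)
    is_stop <- codons %in% .STOP_CODONS
    is_start <- codons %in% .START_CODONS
    has_n <- grepl("N", codons, fixed = TRUE)
    # segment boundaries: stops and ambiguous codons close segments
    boundary <- which(is_stop | has_n)
    seg_open <- 1L
    for (b in c(boundary, n_codons + 1L)) {
      if (b > n_codons) break_at_stop <- FALSE else
        break_at_stop <- is_stop[b]
      if (break_at_stop && b > seg_open) {
        seg <- seg_open:(b - 1L)
        first_start <- seg[is_start[seg]][1]
        if (!is.na(first_start)) {
          aa_len <- b - first_start  # codons incl. start, excl. stop
          if (aa_len >= min_aa) {
            prot <- c("M", .translate_codons(
              codons[seq(first_start + 1L, length.out = aa_len - 1L)]))
            out[[length(out) + 1L]] <- list(
              start = starts_nt[first_start],
              end = starts_nt[b] + 2L,
              protein = paste(prot, collapse = ""))
          }
        }
      }
      seg_open <- b + 1L
      if (seg_open > n_codons) break
    }
  }
  out
}

#' Find open reading frames on both strands
#'
#' Calls maximal bacterial ORFs (see the conventions in the source
#' header: translation-table-11 starts `ATG`/`GTG`/`TTG` translated as
#' Met, stops `TAA`/`TAG`/`TGA`, one ORF per stop per frame, stop
#' required). Coordinates are 1-based inclusive on the forward strand
#' and span the full codon range including the stop codon.
#'
#' @param seq Contig nucleotide string over `ACGTN`.
#' @param min_aa Minimum protein length in residues, counting the
#'   initiator Met but not the stop (default 50).
#' @param contig Contig name for the output.
#' @return Data frame `contig`, `start`, `end`, `strand`, `protein`,
#'   ordered by start coordinate then strand.
#' @examples
#' find_orfs("ATGGCTGCTGCTTAA", min_aa = 3)
#' @export
find_orfs <- function(seq, min_aa = 50L, contig = "contig1") {
  .assert_dna_string(seq)
  n <- nchar(seq)
  fw <- .scan_orfs_one_strand(seq, min_aa)
  rv <- .scan_orfs_one_strand(.revcomp(seq), min_aa)
  rows <- list()
  for (o in fw)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = o$start, end = o$end, strand = "+",
      protein = o$protein, stringsAsFactors = FALSE)
  for (o in rv)
    rows[[length(rows) + 1L]] <- data.frame(
      contig = contig, start = n - o$end + 1L, end = n - o$start + 1L,
      strand = "-", protein = o$protein, stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      protein = character(), stringsAsFactors = FALSE))
  orfs <- do.call(rbind, rows)
  orfs <- orfs[order(orfs$start, orfs$end, orfs$strand), , drop = FALSE]
  rownames(orfs) <- NULL
  orfs
}
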