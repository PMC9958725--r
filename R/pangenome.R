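## Reference protein lengths (residues) per cluster role, scaled-down
## but rank-realistic for a nisin-type operon.
.REF_LENGTHS <- c(B = 320L, T = 280L, C = 260L, I = 110L, P = 300L,
                  R = 120L, K = 220L, F = 140L, E = 130L, G = 120L)

#' Synthetic nisin-cluster reference proteins
#'
#' A deterministic, synthetic set of reference proteins for the eleven
#' cluster roles, used as the homology bait in the pangenome screen and
#' as the coding payload of the synthetic-genome generator. The role-A
#' reference is a composite precursor: a synthetic leader followed by
#' the reconstructed mature nisin E core. All other roles are synthetic
#' stand-in proteins (fixed random sequences of rank-realistic length)
#' — they are not the biological nse gene products, and screens against
#' them only demonstrate the machinery, not real-genome results.
#'
#' @return Named character vector of protein sequences, one per role
#'   label in `A B T C I P R K F E G`.
#' @export
nisin_cluster_references <- function() {
  if (!is.null(.lantivar_cache$references))
    return(.lantivar_cache$references)
  refs <- .with_seed(60317L, {
    out <- character(0)
    core <- nisin_reference_peptides()$nisE$core_seq
    leader <- paste0("M", paste(sample(AA1, 22L, replace = TRUE),
                                collapse = ""))
    out["A"] <- paste0(leader, core)
    for (role in names(.REF_LENGTHS)) {
      body <- paste(sample(AA1, .REF_LENGTHS[[role]] - 1L,
                           replace = TRUE), collapse = "")
      out[role] <- paste0("M", body)
    }
    out[CLUSTER_ROLES]
  })
  .lantivar_cache$references <- refs
  refs
}

#' Assign ORFs to cluster roles by protein identity
#'
#' For each reference role the best-identity ORF (global protein
#' alignment, [percent_identity()] convention) is reported when it
#' reaches `id_threshold`. ORFs whose length is far outside the
#' reference length (ratio outside `length_ratio`) are skipped before
#' alignment — at a 90% identity threshold such pairs cannot qualify.
#' If two roles are best served by the same ORF with tied identity the
#' hit is flagged.
#'
#' @param orfs ORF data frame from [find_orfs()].
#' @param references Named character vector role -> protein; defaults to
#'   [nisin_cluster_references()].
#' @param id_threshold Minimum percent identity (default 90).
#' @param length_ratio Admissible ORF/reference length ratio window
#'   (default `c(0.6, 1.67)`).
#' @return Data frame `role`, `orf`, `contig`, `start`, `end`, `strand`,
#'   `percent_identity`, `tied`; one row per role with a qualifying hit.
#' @export
assign_homologs <- function(orfs, references = nisin_cluster_references(),
                            id_threshold = 90,
                            length_ratio = c(0.6, 1.67)) {
  stopifnot(length(references) > 0L, !is.null(names(references)))
  empty <- data.frame(role = character(), orf = integer(),
                      contig = character(), start = integer(),
                      end = integer(), strand = character(),
                      percent_identity = numeric(), tied = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(orfs)) return(empty)
  orf_len <- nchar(orfs$protein)
  rows <- list()
  best_orf <- integer(0)
  for (role in names(references)) {
    ref <- references[[role]]
    rl <- nchar(ref)
    cand <- which(orf_len >= length_ratio[1] * rl &
                    orf_len <= length_ratio[2] * rl)
    if (!length(cand)) next
    ids <- vapply(cand, function(k)
      percent_identity(ref, orfs$protein[k]), numeric(1))
    top <- which.max(ids)
    if (ids[top] < id_threshold) next
    k <- cand[top]
    rows[[role]] <- data.frame(
      role = role, orf = k, contig = orfs$contig[k],
      start = orfs$start[k], end = orfs$end[k], strand = orfs$strand[k],
      percent_identity = ids[top], tied = FALSE, stringsAsFactors = FALSE)
    best_orf <- c(best_orf, k)
  }
  if (!length(rows)) return(empty)
  hits <- do.call(rbind, rows)
  dup <- hits$orf %in% hits$orf[duplicated(hits$orf)]
  hits$tied <- dup
  rownames(hits) <- NULL
  hits
}

.read_genome_contigs <- function(genome) {
  if (is.character(genome) && length(genome) == 1L && file.exists(genome)) {
    dna <- Biostrings::readDNAStringSet(genome)
    if (length(dna) == 0L)
      stop("empty genome FASTA: ", genome, call. = FALSE)
    contigs <- setNames(as.character(dna),
                        sub("\\s.*$", "", names(dna)))
  } else if (is.character(genome) && length(genome) >= 1L) {
    contigs <- genome
    if (is.null(names(contigs)))
      names(contigs) <- paste0("contig", seq_along(contigs))
  } else stop("genome must be a FASTA path or a character vector",
              call. = FALSE)
  if (any(!nzchar(contigs))) stop("empty contig sequence", call. = FALSE)
  toupper(contigs)
}

#' Classify a genome's nisin-cluster gene content
#'
#' Calls ORFs on every contig ([find_orfs()]), assigns them to reference
#' cluster roles by protein identity ([assign_homologs()]), and
#' classifies the detected role set with [classify_cluster()]:
#' `full_production`, `immunity_sensing_subset`, `partial` or `none`.
#'
#' @param genome Path to a (multi-)FASTA file, or a named character
#'   vector of contig sequences.
#' @param references Named protein vector role -> sequence.
#' @param id_threshold Minimum percent identity for a role call
#'   (default 90, the homolog criterion for the immunity/sensing
#'   subset).
#' @param min_aa Minimum ORF length passed to [find_orfs()].
#' @param genome_id Label for the result (defaults to the file name or
#'   `"genome"`).
#' @return A `genome_classification`: list with `genome_id`, `category`,
#'   `present_roles` and the `role_hits` data frame.
#' @export
classify_genome <- function(genome, references = nisin_cluster_references(),
                            id_threshold = 90, min_aa = 50L,
                            genome_id = NULL) {
  if (is.null(genome_id))
    genome_id <- if (is.character(genome) && length(genome) == 1L &&
                     file.exists(genome))
      sub("\\.[^.]*$", "", basename(genome)) else "genome"
  contigs <- .read_genome_contigs(genome)
  orfs <- do.call(rbind, lapply(names(contigs), function(nm)
    find_orfs(contigs[[nm]], min_aa = min_aa, contig = nm)))
  hits <- assign_homologs(orfs, references, id_threshold = id_threshold)
  cls <- classify_cluster(hits$role, cluster_id = genome_id)
  structure(list(genome_id = genome_id, category = cls$category,
                 present_roles = cls$present_roles, role_hits = hits),
            class = "genome_classification")
}

#' @export
print.genome_classification <- function(x, ...) {
  cat(sprintf("<genome_classification> %s: %s (roles: %s)\n",
              x$genome_id, x$category,
              if (length(x$present_roles))
                paste(x$present_roles, collapse = "") else "-"))
  invisible(x)
}

#' Summarize a pangenome screen
#'
#' @param classifications List of [classify_genome()] results (or a
#'   character vector of categories).
#' @return Data frame `category`, `count`, `fraction` over the four
#'   categories; counts sum to the number of genomes and fractions to 1.
#' @export
summarize_pangenome <- function(classifications) {
  cats <- if (is.character(classifications)) classifications else
    vapply(classifications, function(x) x$category, character(1))
  if (!length(cats)) stop("no genomes to summarize", call. = FALSE)
  levels <- c("full_production", "immunity_sensing_subset", "partial",
              "none")
  bad <- setdiff(unique(cats), levels)
  if (length(bad))
    stop("unknown category: ", paste(bad, collapse = ", "), call. = FALSE)
  counts <- vapply(levels, function(l) sum(cats == l), integer(1))
  data.frame(category = levels, count = counts,
             fraction = counts / length(cats),
             stringsAsFactors = FALSE, row.names = NULL)
}
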