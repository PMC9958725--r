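## Seeded generators for synthetic peptides, regulatory sequences, gene
## clusters and pangenomes, each paired with a truth manifest. All
## outputs are pure functions of (parameters, seed): generation runs
## under a temporary RNG state (Mersenne-Twister via set.seed), and
## retry loops derive attempt sub-seeds as seed + attempt * 10007.

.random_dna <- function(n) paste(sample(DNA_BASES, n, replace = TRUE),
                                 collapse = "")

.random_protein <- function(n_aa)
  paste0("M", paste(sample(AA1, n_aa - 1L, replace = TRUE), collapse = ""))

.codon_choices <- function() {
  if (is.null(.lantivar_cache$codons)) {
    gc <- .genetic_code()
    gc <- gc[gc != "*"]
    .lantivar_cache$codons <- split(names(gc), gc)
  }
  .lantivar_cache$codons
}

## Back-translate a protein with a flat synonymous-codon choice.
## The initiator Met is always encoded ATG (a guaranteed start codon);
## a random stop codon is appended.
.back_translate <- function(protein) {
  chars <- strsplit(protein, "")[[1]]
  choices <- .codon_choices()
  codons <- vapply(chars, function(a) {
    cs <- choices[[a]]
    cs[sample.int(length(cs), 1L)]
  }, character(1))
  if (chars[1] == "M") codons[1] <- "ATG"
  paste0(paste(codons, collapse = ""),
         sample(.STOP_CODONS, 1L))
}

## Amino-acid level point mutation; position 1 (the initiator Met) is
## never touched so the gene keeps its start codon.
.mutate_protein <- function(protein, rate) {
  if (rate <= 0) return(protein)
  chars <- strsplit(protein, "")[[1]]
  n <- length(chars)
  if (n < 2L) return(protein)
  hit <- which(stats::runif(n - 1L) < rate) + 1L
  for (p in hit) chars[p] <- sample(setdiff(AA1, chars[p]), 1L)
  paste(chars, collapse = "")
}

#' Generate a mutated peptide with a known edit list
#'
#' Samples `n_subs` substitution and `n_dels` deletion positions
#' uniformly and without overlap on the reference, applies them with
#' [apply_edits()], and returns both the mutant sequence and the true
#' edit list in reference numbering — the planted truth for validating
#' [diff_variants()].
#'
#' @param ref Reference core peptide (string or [peptide_record()]).
#' @param n_subs,n_dels Numbers of substitutions and deletions
#'   (`n_subs + n_dels < nchar(ref)`).
#' @param seed Integer seed; identical seeds give identical output.
#' @return List with `sequence` and `edits` (data frame with `name`
#'   column).
#' @export
mutate_peptide <- function(ref, n_subs, n_dels, seed = NULL) {
  ref <- .as_core_seq(ref)
  n <- nchar(ref)
  n_subs <- as.integer(n_subs); n_dels <- as.integer(n_dels)
  stopifnot(n_subs >= 0L, n_dels >= 0L)
  if (n_subs + n_dels >= n)
    stop("n_subs + n_dels must be smaller than the peptide length",
         call. = FALSE)
  .with_seed(seed, {
    chars <- strsplit(ref, "")[[1]]
    pos <- sort(sample.int(n, n_subs + n_dels))
    is_sub <- rep(FALSE, length(pos))
    if (n_subs > 0L)
      is_sub[sample.int(length(pos), n_subs)] <- TRUE
    edits <- data.frame(
      kind = ifelse(is_sub, "substitution", "deletion"),
      ref_pos = pos,
      ref_aa = chars[pos],
      alt_aa = ifelse(is_sub,
                      vapply(pos, function(p)
                        sample(setdiff(AA1, chars[p]), 1L), character(1)),
                      ""),
      stringsAsFactors = FALSE)
    edits$name <- format_edit_names(edits)
    list(sequence = apply_edits(ref, edits), edits = edits)
  })
}

## Search for a hairpin cassette whose free energy lands in a target
## window. Returns list(cassette, arm, loop, dg, offset of the left-arm
## start within the cassette). Cassette layout:
##   C (guard) | left arm | loop (A-rich, ends cannot pair) | right arm
##   (revcomp of left) | TTTTTTTT (U-tract)
.design_hairpin <- function(dg_min, dg_max, max_tries = 5000L) {
  loops <- c("AACA", "AAGAA", "ACAA")
  for (t in seq_len(max_tries)) {
    k <- sample(4:9, 1L)
    arm <- paste(sample(DNA_BASES, k, replace = TRUE), collapse = "")
    l <- loops[[sample.int(length(loops), 1L)]]
    left <- strsplit(arm, "")[[1]]
    dg <- hairpin_delta_g(
      data.frame(left = left, right = DNA_COMPLEMENT[left],
                 stringsAsFactors = FALSE),
      nchar(l))
    if (dg >= dg_min && dg <= dg_max) {
      cassette <- paste0("C", arm, l, .revcomp(arm),
                         strrep("T", 8L))
      return(list(cassette = cassette, stem_len = k,
                  loop_len = nchar(l), dg = dg, arm_offset = 2L))
    }
  }
  stop("could not design a hairpin in [", dg_min, ", ", dg_max, "]",
       call. = FALSE)
}

.HAIRPIN_CLASSES <- list(
  strong    = c(-18.0, -11.0),   # well below the -10 strength boundary
  candidate = c(-9.5, -6.0),     # reported, but not strong
  sub       = c(-4.9, -3.0)      # just above the -5 reporting threshold
)

.promoter_site <- function(model) {
  paste0(model$box35,
         .random_dna(model$spacer),
         model$box10)
}

.repeat_site <- function(motif = "TCT", gap = 8L)
  paste0(motif, .random_dna(gap), motif)

#' Generate a sequence with planted regulatory features
#'
#' Builds a random background of the requested length and plants up to
#' three features at fixed, non-overlapping offsets: one promoter site
#' (exact consensus boxes at the model's exact spacer), one TCT-N8-TCT
#' direct repeat, and one designed hairpin terminator cassette whose
#' free energy falls in the window of the requested class (`strong`
#' below -10, `candidate` between -10 and -5, or `sub` just above the
#' -5 reporting threshold, hence designed NOT to be reported).
#'
#' The construction is rejection-sampled: the finished sequence is
#' re-scanned with the packaged promoter models (zero mismatches, zero
#' spacer slack, both strands), the repeat finder and the default
#' terminator scanner, and rebuilt under a derived attempt seed until
#' the hit set equals the manifest exactly. The planted truth therefore
#' holds by construction, with no accidental look-alike sites.
#'
#' @param length Background length in nucleotides (default 200).
#' @param promoter A [promoter_model()] to plant, or `NULL`.
#' @param with_repeat Plant a TCT-N8-TCT repeat (default TRUE).
#' @param hairpin One of `"strong"`, `"candidate"`, `"sub"`, or `NULL`.
#' @param seed Integer seed.
#' @param max_attempts Rejection-sampling cap (default 80).
#' @return List with `seq` and `manifest` (data frame: `feature`,
#'   `start`, `end`, `strand`, `detail`, `reported`).
#' @export
make_regulatory_sequence <- function(length = 200L, promoter = NULL,
                                     with_repeat = TRUE, hairpin = NULL,
                                     seed = NULL, max_attempts = 80L) {
  stopifnot(length >= 120L)
  if (!is.null(hairpin))
    hairpin <- match.arg(hairpin, names(.HAIRPIN_CLASSES))
  models <- nisin_promoter_models(p_type_spacer = 20L)
  for (attempt in seq_len(max_attempts) - 1L) {
    sub_seed <- if (is.null(seed)) NULL else seed + attempt * 10007L
    out <- .with_seed(sub_seed, {
      bg <- strsplit(.random_dna(length), "")[[1]]
      manifest <- list()
      splice <- function(site, at) {
        stopifnot(at + nchar(site) - 1L <= length)
        bg[at:(at + nchar(site) - 1L)] <<- strsplit(site, "")[[1]]
      }
      cursor <- 8L
      if (!is.null(promoter)) {
        site <- .promoter_site(promoter)
        splice(site, cursor)
        manifest$promoter <- data.frame(
          feature = "promoter", start = cursor,
          end = cursor + nchar(site) - 1L, strand = "+",
          detail = promoter$name, reported = TRUE,
          stringsAsFactors = FALSE)
        cursor <- cursor + nchar(site) + 12L
      }
      if (with_repeat) {
        site <- .repeat_site()
        splice(site, cursor)
        manifest$repeat_ <- data.frame(
          feature = "direct_repeat", start = cursor,
          end = cursor + nchar(site) - 1L, strand = "+",
          detail = "TCT-N8-TCT", reported = TRUE,
          stringsAsFactors = FALSE)
        cursor <- cursor + nchar(site) + 12L
      }
      if (!is.null(hairpin)) {
        win <- .HAIRPIN_CLASSES[[hairpin]]
        hp <- .design_hairpin(win[1], win[2])
        splice(hp$cassette, cursor)
        arm_start <- cursor + hp$arm_offset - 1L
        manifest$terminator <- data.frame(
          feature = "terminator", start = arm_start,
          end = arm_start + 2L * hp$stem_len + hp$loop_len - 1L,
          strand = "+", detail = sprintf("%s dG=%.2f", hairpin, hp$dg),
          reported = hairpin != "sub", stringsAsFactors = FALSE)
      }
      list(seq = paste(bg, collapse = ""),
           manifest = do.call(rbind, c(manifest,
                                       list(make.row.names = FALSE))))
    })
    if (.regulatory_truth_holds(out$seq, out$manifest, models))
      return(out)
  }
  stop("failed to build a clean planted sequence in ", max_attempts,
       " attempts", call. = FALSE)
}

## verify that scanning recovers exactly the reported manifest rows
.regulatory_truth_holds <- function(seq, manifest, models) {
  if (is.null(manifest))
    manifest <- data.frame(feature = character(), start = integer(),
                           end = integer(), reported = logical())
  want <- manifest[manifest$reported, , drop = FALSE]
  prom <- do.call(rbind, lapply(models, function(m)
    scan_promoters(seq, m, max_mismatch_per_box = 0L, spacer_slack = 0L)))
  wp <- want[want$feature == "promoter", , drop = FALSE]
  if (nrow(prom) != nrow(wp)) return(FALSE)
  if (nrow(wp) &&
      !all(sort(prom$start) == sort(wp$start) &
             sort(prom$end) == sort(wp$end))) return(FALSE)
  reps <- find_direct_repeats(seq)
  wr <- want[want$feature == "direct_repeat", , drop = FALSE]
  if (nrow(reps) != nrow(wr)) return(FALSE)
  if (nrow(wr) && !all(sort(reps$start) == sort(wr$start))) return(FALSE)
  term <- find_terminators(seq)
  wt <- want[want$feature == "terminator", , drop = FALSE]
  if (nrow(term) != nrow(wt)) return(FALSE)
  if (nrow(wt) &&
      !all(sort(term$start) == sort(wt$start) &
             sort(term$end) == sort(wt$end))) return(FALSE)
  TRUE
}

#' Generate a gene-cluster contig with planted regulatory features
#'
#' Back-translates the reference proteins of the requested layout into
#' a single forward-strand contig (flat synonymous-codon choice, ATG
#' starts, random stops), separated by random intergenic gaps, and
#' plants promoter sites and designed terminator cassettes into named
#' intergenic gaps. The gene coordinates, layout and planted features
#' are returned as truth.
#'
#' Unlike [make_regulatory_sequence()], the coding regions are not
#' scrubbed of regulatory look-alikes (long coding sequence can and
#' does contain chance motif matches, as in real operons); the
#' construction only guarantees that every planted feature is recovered
#' exactly by the scanners at default settings.
#'
#' @param layout Role string, e.g. `"PRKAFEGBTCI"`; may be empty.
#' @param promoters List of placements `list(model = <promoter_model>,
#'   before_role = "R")`.
#' @param terminators List of placements `list(after_role = "I",
#'   class = "strong")`.
#' @param references Named role -> protein vector.
#' @param seed Integer seed.
#' @param flank Flanking background length either side (default 150).
#' @param contig_name Contig label.
#' @param max_attempts Rejection-sampling cap (default 40).
#' @return List with `seq` (named character), `cluster`
#'   ([gene_cluster()]), and `manifest` (list with `genes` and
#'   `features` data frames).
#' @export
make_cluster_sequence <- function(layout, promoters = list(),
                                  terminators = list(),
                                  references = nisin_cluster_references(),
                                  seed = NULL, flank = 150L,
                                  contig_name = "synthetic_cluster",
                                  max_attempts = 40L) {
  roles <- strsplit(layout, "")[[1]]
  bad <- setdiff(roles, CLUSTER_ROLES)
  if (length(bad))
    stop("unknown role(s) in layout: ", paste(bad, collapse = ", "),
         call. = FALSE)
  if (anyDuplicated(roles))
    stop("duplicate role in layout", call. = FALSE)
  for (p in promoters)
    if (!p$before_role %in% roles)
      stop("promoter placement before_role '", p$before_role,
           "' not in layout", call. = FALSE)
  for (tt in terminators)
    if (!tt$after_role %in% roles)
      stop("terminator placement after_role '", tt$after_role,
           "' not in layout", call. = FALSE)
  models <- nisin_promoter_models(p_type_spacer = 20L)
  for (attempt in seq_len(max_attempts) - 1L) {
    sub_seed <- if (is.null(seed)) NULL else seed + attempt * 10007L
    out <- .with_seed(sub_seed,
      .build_cluster_once(roles, promoters, terminators, references,
                          flank, contig_name))
    ok <- .cluster_truth_holds(out, models)
    if (ok) return(out)
  }
  stop("failed to build a recoverable cluster sequence in ",
       max_attempts, " attempts", call. = FALSE)
}

.build_cluster_once <- function(roles, promoters, terminators,
                                references, flank, contig_name) {
  pieces <- character(0)
  pos <- 0L
  add <- function(x) {
    pieces[[length(pieces) + 1L]] <<- x
    pos <<- pos + nchar(x)
  }
  genes <- list()
  features <- list()
  add(.random_dna(flank))
  for (role in roles) {
    # intergenic gap before this gene, with optional planted features
    add(.random_dna(25L + sample.int(20L, 1L)))
    for (p in promoters) {
      if (identical(p$before_role, role)) {
        site <- .promoter_site(p$model)
        features[[length(features) + 1L]] <- data.frame(
          feature = "promoter", start = pos + 1L,
          end = pos + nchar(site), strand = "+", detail = p$model$name,
          reported = TRUE, stringsAsFactors = FALSE)
        add(site)
        add(.random_dna(10L))
      }
    }
    gene_dna <- .back_translate(references[[role]])
    genes[[length(genes) + 1L]] <- data.frame(
      role = role, contig = contig_name, start = pos + 1L,
      end = pos + nchar(gene_dna), strand = "+",
      stringsAsFactors = FALSE)
    add(gene_dna)
    for (tt in terminators) {
      if (identical(tt$after_role, role)) {
        win <- .HAIRPIN_CLASSES[[match.arg(tt$class,
                                           names(.HAIRPIN_CLASSES))]]
        hp <- .design_hairpin(win[1], win[2])
        add(.random_dna(8L))
        arm_start <- pos + hp$arm_offset
        features[[length(features) + 1L]] <- data.frame(
          feature = "terminator", start = arm_start,
          end = arm_start + 2L * hp$stem_len + hp$loop_len - 1L,
          strand = "+", detail = sprintf("%s dG=%.2f", tt$class, hp$dg),
          reported = tt$class != "sub", stringsAsFactors = FALSE)
        add(hp$cassette)
      }
    }
  }
  add(.random_dna(flank))
  genes_df <- if (length(genes)) do.call(rbind, genes) else
    data.frame(role = character(), contig = character(),
               start = integer(), end = integer(), strand = character(),
               stringsAsFactors = FALSE)
  features_df <- if (length(features)) do.call(rbind, features) else
    data.frame(feature = character(), start = integer(),
               end = integer(), strand = character(),
               detail = character(), reported = logical(),
               stringsAsFactors = FALSE)
  list(seq = setNames(paste(pieces, collapse = ""), contig_name),
       cluster = gene_cluster(contig_name, genes_df),
       manifest = list(genes = genes_df, features = features_df))
}

## planted features must each be recovered exactly (extra chance hits in
## coding sequence are tolerated; see make_cluster_sequence docs)
.cluster_truth_holds <- function(out, models) {
  seq <- unname(out$seq)
  feats <- out$manifest$features
  fp <- feats[feats$feature == "promoter" & feats$reported, , drop = FALSE]
  if (nrow(fp)) {
    prom <- do.call(rbind, lapply(models, function(m)
      scan_promoters(seq, m, max_mismatch_per_box = 0L,
                     spacer_slack = 0L)))
    for (r in seq_len(nrow(fp)))
      if (!any(prom$start == fp$start[r] & prom$end == fp$end[r] &
                 prom$model == fp$detail[r])) return(FALSE)
  }
  ft <- feats[feats$feature == "terminator" & feats$reported, , drop = FALSE]
  if (nrow(ft)) {
    term <- find_terminators(seq)
    for (r in seq_len(nrow(ft)))
      if (!any(term$start == ft$start[r] & term$end == ft$end[r]))
        return(FALSE)
  }
  TRUE
}

#' Generate a synthetic pangenome with a truth manifest
#'
#' Emulates a pangenome presence/absence screen: `n_full` genomes carry
#' the complete production operon (layout `PRKAFEGBTCI`), `n_subset`
#' carry only the immunity/sensing genes `RKFEG`, and the remainder
#' carry unrelated decoy genes only. Coding sequences are mutated at
#' the amino-acid level at `mutation_rate` (the initiator Met is kept)
#' before back-translation, so planted role identities stay near
#' `100 * (1 - mutation_rate)` percent. Category assignment is
#' shuffled across genome ids under the seed.
#'
#' @param n_genomes Total genomes (default 44).
#' @param n_full Genomes with the full operon (default 6).
#' @param n_subset Genomes with the `RKFEG` subset (default 20).
#' @param mutation_rate Amino-acid mutation rate in `[0, 0.1]`
#'   (default 0.02).
#' @param seed Integer seed.
#' @param references Named role -> protein vector.
#' @return List with `genomes` (named list; each a named character
#'   vector of contigs) and `manifest` (data frame `genome_id`,
#'   `category`).
#' @export
make_pangenome <- function(n_genomes = 44L, n_full = 6L, n_subset = 20L,
                           mutation_rate = 0.02, seed = NULL,
                           references = nisin_cluster_references()) {
  n_genomes <- as.integer(n_genomes)
  stopifnot(n_genomes >= 1L, n_full >= 0L, n_subset >= 0L,
            mutation_rate >= 0, mutation_rate <= 0.1)
  if (n_full + n_subset > n_genomes)
    stop("n_full + n_subset exceeds n_genomes", call. = FALSE)
  .with_seed(seed, {
    cats <- sample(c(rep("full_production", n_full),
                     rep("immunity_sensing_subset", n_subset),
                     rep("none", n_genomes - n_full - n_subset)))
    ids <- sprintf("genome%02d", seq_len(n_genomes))
    genomes <- vector("list", n_genomes)
    names(genomes) <- ids
    for (g in seq_len(n_genomes)) {
      roles <- switch(cats[g],
                      full_production = strsplit("PRKAFEGBTCI", "")[[1]],
                      immunity_sensing_subset = IMMUNITY_SENSING_ROLES,
                      none = character(0))
      pieces <- c(.random_dna(200L))
      for (role in roles) {
        prot <- .mutate_protein(references[[role]], mutation_rate)
        pieces <- c(pieces, .random_dna(30L + sample.int(60L, 1L)),
                    .back_translate(prot))
      }
      # unrelated decoy genes in every genome
      for (d in seq_len(2L)) {
        decoy <- .random_protein(sample(80:200, 1L))
        pieces <- c(pieces, .random_dna(30L + sample.int(60L, 1L)),
                    .back_translate(decoy))
      }
      pieces <- c(pieces, .random_dna(200L))
      genomes[[g]] <- setNames(paste(pieces, collapse = ""),
                               paste0(ids[g], "_c1"))
    }
    list(genomes = genomes,
         manifest = data.frame(genome_id = ids, category = cats,
                               stringsAsFactors = FALSE))
  })
}

#' Write a synthetic pangenome to disk
#'
#' One FASTA per genome plus a `manifest.json`.
#'
#' @param pangenome A [make_pangenome()] result.
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_pangenome_fasta <- function(pangenome, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (id in names(pangenome$genomes)) {
    dna <- Biostrings::DNAStringSet(pangenome$genomes[[id]])
    Biostrings::writeXStringSet(dna, file.path(dir, paste0(id, ".fasta")))
  }
  jsonlite::write_json(pangenome$manifest,
                       file.path(dir, "manifest.json"),
                       dataframe = "rows", auto_unbox = TRUE)
  invisible(dir)
}

#' Read a pangenome truth manifest
#'
#' @param path Path to a `manifest.json` written by
#'   [write_pangenome_fasta()].
#' @return Data frame `genome_id`, `category`.
#' @export
read_pangenome_manifest <- function(path) {
  df <- jsonlite::fromJSON(path)
  stopifnot(all(c("genome_id", "category") %in% names(df)))
  df
}
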