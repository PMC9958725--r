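## End-to-end convenience stages over the component modules. Each stage
## optionally writes its tables (TSV + JSON) plus an echo of its
## configuration into an output directory, so runs are self-describing.

.write_stage_outputs <- function(out_dir, tables, config) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(tables)) {
    tab <- tables[[nm]]
    write.table(tab, file.path(out_dir, paste0(nm, ".tsv")),
                sep = "\t", quote = FALSE, row.names = FALSE)
    jsonlite::write_json(tab, file.path(out_dir, paste0(nm, ".json")),
                         dataframe = "rows", auto_unbox = TRUE,
                         digits = NA)
  }
  config$package_version <-
    as.character(utils::packageVersion("lantivar"))
  jsonlite::write_json(config, file.path(out_dir, "run_config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(out_dir)
}

#' Characterize query peptides against a reference
#'
#' For each query core peptide: the reference-numbered edit list and
#' its three-letter-code names, percent identity, the hinge tripeptide
#' (residues aligned to nisin A positions 20-22), the unmodified
#' average mass, and — when an observed mass is supplied — the inferred
#' dehydration count. Percent identities and masses are reported to one
#' decimal.
#'
#' @param reference A [peptide_record()] or FASTA path with exactly one
#'   sequence.
#' @param queries A list of peptide records, a single record, or a
#'   FASTA path with one or more sequences.
#' @param observed_masses Optional numeric vector of observed masses
#'   (Da), recycled or named by query id.
#' @param mass_tolerance Tolerance passed to [infer_dehydrations()].
#' @param out_dir Optional output directory for TSV/JSON reports.
#' @return Data frame with one row per query: `query_id`, `ref_id`,
#'   `n_edits`, `edit_names`, `percent_identity`, `hinge`,
#'   `unmodified_mass`, `observed_mass`, `n_dehydrations`,
#'   `dehydrated_mass`.
#' @examples
#' refs <- nisin_reference_peptides()
#' characterize_variants(refs$nisA, refs$nisE, observed_masses = 3100.8)
#' @export
characterize_variants <- function(reference, queries,
                                  observed_masses = NULL,
                                  mass_tolerance = 1.5, out_dir = NULL) {
  if (is.character(reference) && file.exists(reference)) {
    refs <- read_peptide_fasta(reference)
    if (length(refs) != 1L)
      stop("reference FASTA must contain exactly one sequence",
           call. = FALSE)
    reference <- refs[[1]]
  }
  if (is.character(queries) && length(queries) == 1L &&
      file.exists(queries))
    queries <- read_peptide_fasta(queries)
  if (inherits(queries, "peptide_record")) queries <- list(queries)
  if (!length(queries)) stop("no query peptides", call. = FALSE)
  qids <- unname(vapply(queries, function(q)
    if (inherits(q, "peptide_record")) q$id else "query", character(1)))
  if (!is.null(observed_masses)) {
    if (!is.null(names(observed_masses)))
      observed_masses <- unname(observed_masses[qids])
    else observed_masses <- rep_len(observed_masses, length(queries))
  }
  all_edits <- list()
  rows <- lapply(seq_along(queries), function(i) {
    q <- queries[[i]]
    d <- diff_variants(reference, q)
    if (nrow(d)) {
      ed <- as.data.frame(d)
      rownames(ed) <- NULL
      all_edits[[i]] <<- data.frame(query_id = qids[i], ed,
                                    stringsAsFactors = FALSE)
    }
    hinge <- tryCatch(hinge_region(q), error = function(e) NA_character_)
    mass <- peptide_mass(q, "average")
    obs <- if (is.null(observed_masses)) NA_real_ else observed_masses[i]
    nd <- NA_integer_; dm <- NA_real_
    if (!is.na(obs)) {
      nd <- as.integer(infer_dehydrations(q, obs,
                                          tolerance = mass_tolerance))
      dm <- modified_mass(q, nd)
    }
    data.frame(
      query_id = qids[i],
      ref_id = if (inherits(reference, "peptide_record"))
        reference$id else "ref",
      n_edits = nrow(d),
      edit_names = paste(d$name, collapse = ","),
      percent_identity = round(percent_identity(reference, q), 1),
      hinge = hinge,
      unmodified_mass = round(mass, 1),
      observed_mass = obs,
      n_dehydrations = nd,
      dehydrated_mass = round(dm, 1),
      stringsAsFactors = FALSE)
  })
  report <- do.call(rbind, rows)
  .write_stage_outputs(out_dir,
                       list(variant_report = report,
                            variant_edits = do.call(rbind, all_edits)),
                       list(stage = "characterize",
                            mass_tolerance = mass_tolerance))
  report
}

#' Annotate a genome for cluster content and regulatory elements
#'
#' Classifies the genome's nisin-cluster gene content
#' ([classify_genome()]), derives the cluster layout string from the
#' detected role hits in genomic order, and scans every contig for
#' promoter models, TCT-N8-TCT repeats and Rho-independent terminators.
#'
#' @inheritParams classify_genome
#' @param promoter_models Named list of [promoter_model()] objects
#'   (default: the packaged models, P type at spacer 20).
#' @param max_mismatch_per_box,spacer_slack Promoter scan budgets.
#' @param dg_threshold Terminator reporting threshold (kcal/mol).
#' @param out_dir Optional output directory (writes the classification,
#'   hits tables, a BED track and the run config).
#' @return List with `classification`, `layout`, `promoters`,
#'   `repeats`, `terminators`.
#' @export
annotate_genome <- function(genome,
                            references = nisin_cluster_references(),
                            promoter_models =
                              nisin_promoter_models(p_type_spacer = 20L),
                            max_mismatch_per_box = 1L, spacer_slack = 1L,
                            dg_threshold = -5.0, id_threshold = 90,
                            min_aa = 50L, genome_id = NULL,
                            out_dir = NULL) {
  cls <- classify_genome(genome, references, id_threshold = id_threshold,
                         min_aa = min_aa, genome_id = genome_id)
  hits <- cls$role_hits
  layout <- if (nrow(hits)) {
    ordered <- hits[order(match(hits$contig, unique(hits$contig)),
                          hits$start), ]
    paste(ordered$role, collapse = "")
  } else ""
  contigs <- .read_genome_contigs(genome)
  prom <- list(); reps <- list(); term <- list()
  for (nm in names(contigs)) {
    s <- contigs[[nm]]
    for (m in promoter_models)
      prom[[length(prom) + 1L]] <-
        scan_promoters(s, m, max_mismatch_per_box, spacer_slack,
                       contig = nm)
    reps[[length(reps) + 1L]] <- find_direct_repeats(s, contig = nm)
    term[[length(term) + 1L]] <-
      find_terminators(s, dg_threshold = dg_threshold, contig = nm)
  }
  res <- list(
    classification = cls,
    layout = layout,
    promoters = do.call(rbind, prom),
    repeats = do.call(rbind, reps),
    terminators = do.call(rbind, term))
  if (!is.null(out_dir)) {
    cls_df <- data.frame(genome_id = cls$genome_id,
                         category = cls$category, layout = layout,
                         roles = paste(cls$present_roles, collapse = ""),
                         stringsAsFactors = FALSE)
    .write_stage_outputs(out_dir,
                         list(classification = cls_df,
                              role_hits = hits,
                              promoters = res$promoters,
                              repeats = res$repeats,
                              terminators = res$terminators),
                         list(stage = "annotate",
                              max_mismatch_per_box = max_mismatch_per_box,
                              spacer_slack = spacer_slack,
                              dg_threshold = dg_threshold,
                              id_threshold = id_threshold))
    tracks <- list(res$promoters, res$repeats, res$terminators)
    tracks <- tracks[vapply(tracks, function(x)
      !is.null(x) && nrow(x) > 0, logical(1))]
    if (length(tracks)) {
      bed_rows <- do.call(rbind, lapply(tracks, function(x)
        x[, c("kind", "contig", "strand", "start", "end"),
          drop = FALSE]))
      write_hits_bed(cbind(bed_rows), file.path(out_dir,
                                                "regulatory.bed"))
    }
  }
  res
}

#' Screen a set of genomes for nisin-cluster gene content
#'
#' Classifies every genome ([classify_genome()]) and tabulates the
#' category counts ([summarize_pangenome()]).
#'
#' @param genomes A directory of FASTA files (`.fa`/`.fasta`/`.fna`), a
#'   character vector of FASTA paths, or a named list of contig vectors
#'   (as produced by [make_pangenome()]).
#' @inheritParams classify_genome
#' @param out_dir Optional output directory.
#' @return List with `classifications` (data frame: `genome_id`,
#'   `category`, `roles`, `identities`) and `summary` (from
#'   [summarize_pangenome()]).
#' @export
screen_pangenome <- function(genomes,
                             references = nisin_cluster_references(),
                             id_threshold = 90, min_aa = 50L,
                             out_dir = NULL) {
  if (is.character(genomes) && length(genomes) == 1L &&
      dir.exists(genomes)) {
    genomes <- list.files(genomes, pattern = "\\.(fa|fasta|fna)$",
                          full.names = TRUE)
    if (!length(genomes))
      stop("no FASTA files found in directory", call. = FALSE)
  }
  if (is.character(genomes)) {
    ids <- sub("\\.[^.]*$", "", basename(genomes))
    inputs <- setNames(as.list(genomes), ids)
  } else if (is.list(genomes)) {
    if (!length(genomes)) stop("no genomes to screen", call. = FALSE)
    if (is.null(names(genomes)))
      stop("genome list must be named", call. = FALSE)
    inputs <- genomes
  } else stop("unsupported 'genomes' argument", call. = FALSE)
  if (!length(inputs)) stop("no genomes to screen", call. = FALSE)
  cls <- lapply(names(inputs), function(id)
    classify_genome(inputs[[id]], references,
                    id_threshold = id_threshold, min_aa = min_aa,
                    genome_id = id))
  per_genome <- do.call(rbind, lapply(cls, function(x) data.frame(
    genome_id = x$genome_id, category = x$category,
    roles = paste(x$present_roles, collapse = ""),
    identities = paste(sprintf("%s:%.1f", x$role_hits$role,
                               x$role_hits$percent_identity),
                       collapse = ","),
    stringsAsFactors = FALSE)))
  summary <- summarize_pangenome(cls)
  .write_stage_outputs(out_dir,
                       list(pangenome_classifications = per_genome,
                            pangenome_summary = summary),
                       list(stage = "screen",
                            id_threshold = id_threshold,
                            min_aa = min_aa))
  list(classifications = per_genome, summary = summary)
}
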