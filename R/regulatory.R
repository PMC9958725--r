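#' Define a promoter consensus model
#'
#' A bacterial promoter model here is a pair of hexamer boxes (the -35
#' and -10 elements recognised by RNA polymerase) separated by a spacer
#' of fixed length. Nisin-cluster promoters use non-canonical boxes and
#' unusually rigid spacers, so the scanner matches each box by Hamming
#' distance and the spacer exactly (plus an optional slack).
#'
#' @param name Model name.
#' @param box35,box10 Hexamer consensus strings over `ACGT`.
#' @param spacer Exact spacer length in nucleotides (between the boxes).
#' @return A `promoter_model` object.
#' @export
promoter_model <- function(name, box35, box10, spacer) {
  stopifnot(is.character(name), length(name) == 1L)
  for (b in list(box35, box10)) {
    if (nchar(b) != 6L || !all(strsplit(b, "")[[1]] %in% DNA_BASES))
      stop("promoter boxes must be hexamers over ACGT", call. = FALSE)
  }
  spacer <- as.integer(spacer)
  stopifnot(length(spacer) == 1L, !is.na(spacer), spacer >= 0L)
  structure(list(name = name, box35 = box35, box10 = box10,
                 spacer = spacer),
            class = "promoter_model")
}

#' Packaged nisin-cluster promoter models
#'
#' The promoter consensus models observed across nisin-type gene
#' clusters:
#' \describe{
#'   \item{S_type_R}{streptococcal-type regulator (nisR-like) promoter:
#'     `TGCACA` / `TATTAC`, spacer 15.}
#'   \item{core_A}{core-peptide (nisA-like) promoter: `CTGAAC` /
#'     `TACAAT`, non-canonical spacer 20.}
#'   \item{F_type}{transport/immunity (nisF-like) promoter: `TGAACA` /
#'     `TATACT`, spacer 19.}
#'   \item{P_type}{peptidase (nisP-like) promoter boxes `CTGAAC` /
#'     `TAAAAT`; its spacer length is not established, so the model is
#'     only returned when `p_type_spacer` is supplied explicitly.}
#' }
#' The lactococcal-type regulator promoter (L type) has no established
#' consensus boxes here; build one with [promoter_model()] if needed.
#'
#' @param p_type_spacer Optional explicit spacer for the P-type model.
#' @return Named list of [promoter_model()] objects.
#' @export
nisin_promoter_models <- function(p_type_spacer = NULL) {
  models <- list(
    S_type_R = promoter_model("S_type_R", "TGCACA", "TATTAC", 15L),
    core_A   = promoter_model("core_A",   "CTGAAC", "TACAAT", 20L),
    F_type   = promoter_model("F_type",   "TGAACA", "TATACT", 19L)
  )
  if (!is.null(p_type_spacer))
    models$P_type <- promoter_model("P_type", "CTGAAC", "TAAAAT",
                                    p_type_spacer)
  models
}

.hamming_profile <- function(chars, box, positions) {
  # mismatches of box (character vector) against chars starting at each
  # of `positions`; 'N' in the sequence never matches
  mm <- integer(length(positions))
  for (o in seq_along(box))
    mm <- mm + (chars[positions + o - 1L] != box[o])
  mm
}

#' Scan for promoter consensus hits
#'
#' Slides a [promoter_model()] over both strands, reporting every site
#' whose -35 and -10 boxes each match within `max_mismatch_per_box`
#' Hamming mismatches (an `N` never matches) and whose spacer lies
#' within `spacer_slack` of the model's exact spacer. Coordinates are
#' 1-based inclusive on the forward strand, spanning the -35 through the
#' -10 box; hits are sorted by position.
#'
#' @param seq Nucleotide string over `ACGTN`.
#' @param model A [promoter_model()].
#' @param max_mismatch_per_box Mismatch budget per box (default 1).
#' @param spacer_slack Allowed deviation from the exact spacer
#'   (default 1).
#' @param contig Contig name for the output.
#' @param both_strands Scan the reverse strand too (default TRUE).
#' @return Data frame: `kind`, `contig`, `strand`, `start`, `end`,
#'   `model`, `mismatches_35`, `mismatches_10`, `spacer`.
#' @export
scan_promoters <- function(seq, model, max_mismatch_per_box = 1L,
                           spacer_slack = 1L, contig = "seq1",
                           both_strands = TRUE) {
  .assert_dna_string(seq)
  stopifnot(inherits(model, "promoter_model"),
            max_mismatch_per_box >= 0L, spacer_slack >= 0L)
  n <- nchar(seq)
  spacers <- (model$spacer - spacer_slack):(model$spacer + spacer_slack)
  spacers <- spacers[spacers >= 0L]
  if (n < 12L + min(spacers))
    stop("sequence shorter than one full promoter site", call. = FALSE)
  b35 <- strsplit(model$box35, "")[[1]]
  b10 <- strsplit(model$box10, "")[[1]]
  scan_one <- function(s, strand) {
    chars <- strsplit(s, "")[[1]]
    out <- list()
    for (d in spacers) {
      site <- 12L + d
      if (n < site) next
      p <- seq_len(n - site + 1L)
      mm35 <- .hamming_profile(chars, b35, p)
      mm10 <- .hamming_profile(chars, b10, p + 6L + d)
      keep <- mm35 <= max_mismatch_per_box & mm10 <= max_mismatch_per_box
      if (!any(keep)) next
      p <- p[keep]
      st <- p; en <- p + site - 1L
      if (strand == "-") {
        tmp <- st
        st <- n - en + 1L
        en <- n - tmp + 1L
      }
      out[[length(out) + 1L]] <- data.frame(
        kind = "promoter", contig = contig, strand = strand,
        start = st, end = en, model = model$name,
        mismatches_35 = mm35[keep], mismatches_10 = mm10[keep],
        spacer = d, stringsAsFactors = FALSE)
    }
    if (length(out)) do.call(rbind, out) else NULL
  }
  res <- scan_one(seq, "+")
  if (both_strands)
    res <- rbind(res, scan_one(.revcomp(seq), "-"))
  if (is.null(res))
    return(data.frame(kind = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), model = character(),
                      mismatches_35 = integer(), mismatches_10 = integer(),
                      spacer = integer(), stringsAsFactors = FALSE))
  res <- res[order(res$start, res$end, res$strand), , drop = FALSE]
  rownames(res) <- NULL
  res
}

#' Find direct repeats (motif-N(gap)-motif)
#'
#' Reports every position where `motif` occurs twice separated by
#' exactly `gap` nucleotides — by default the TCT-N8-TCT direct repeat
#' conserved in NisRK-regulated nisin promoters. Overlapping occurrences
#' are all reported.
#'
#' @param seq Nucleotide string.
#' @param motif Repeat unit (default `"TCT"`).
#' @param gap Exact gap between the two copies (default 8).
#' @param contig Contig name for the output.
#' @return Data frame: `kind`, `contig`, `strand`, `start`, `end`,
#'   `pos1`, `pos2` (starts of the two copies).
#' @examples
#' find_direct_repeats("GGTCTAACCAAGGTCTGG")
#' @export
find_direct_repeats <- function(seq, motif = "TCT", gap = 8L,
                                contig = "seq1") {
  .assert_dna_string(seq)
  stopifnot(nchar(motif) > 0L, gap >= 0L)
  chars <- strsplit(seq, "")[[1]]
  mot <- strsplit(motif, "")[[1]]
  m <- length(mot)
  span <- 2L * m + gap
  n <- length(chars)
  if (n < span)
    return(data.frame(kind = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), pos1 = integer(),
                      pos2 = integer(), stringsAsFactors = FALSE))
  p <- seq_len(n - span + 1L)
  hit1 <- .hamming_profile(chars, mot, p) == 0L
  hit2 <- .hamming_profile(chars, mot, p + m + gap) == 0L
  p <- p[hit1 & hit2]
  data.frame(kind = rep("direct_repeat", length(p)),
             contig = rep(contig, length(p)),
             strand = rep("+", length(p)),
             start = p, end = p + span - 1L,
             pos1 = p, pos2 = p + m + gap,
             stringsAsFactors = FALSE)
}

.stack_table <- function() {
  if (is.null(.lantivar_cache$stacks)) {
    path <- system.file("extdata", "stack_energies.tsv",
                        package = "lantivar", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .lantivar_cache$stacks <- setNames(tab$delta_g, tab$stack)
  }
  .lantivar_cache$stacks
}

.loop_table <- function() {
  if (is.null(.lantivar_cache$loops)) {
    path <- system.file("extdata", "loop_penalties.tsv",
                        package = "lantivar", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    .lantivar_cache$loops <- setNames(tab$delta_g,
                                      as.character(tab$loop_length))
  }
  .lantivar_cache$loops
}

.loop_penalty <- function(loop_length) {
  tab <- .loop_table()
  mx <- max(as.integer(names(tab)))
  if (loop_length <= mx) return(tab[[as.character(loop_length)]])
  # Jacobson-Stockmayer extrapolation beyond the tabulated range
  tab[[as.character(mx)]] +
    1.75 * 0.0019872 * 310.15 * log(loop_length / mx)
}

.is_wc_pair <- function(x, y) DNA_COMPLEMENT[x] == y & x != "N"

.is_wobble_pair <- function(x, y)
  (x == "G" & y == "T") | (x == "T" & y == "G")

.normalize_stem_pairs <- function(stem_pairs) {
  if (is.character(stem_pairs)) {
    parts <- strsplit(stem_pairs, ":", fixed = TRUE)
    stopifnot(all(lengths(parts) == 2L))
    stem_pairs <- data.frame(left = vapply(parts, `[`, "", 1L),
                             right = vapply(parts, `[`, "", 2L),
                             stringsAsFactors = FALSE)
  }
  stem_pairs <- as.data.frame(stem_pairs)
  stopifnot(all(c("left", "right") %in% names(stem_pairs)))
  stem_pairs
}

#' Hairpin free energy from a nearest-neighbour model
#'
#' Free energy (kcal/mol) of a terminator-style hairpin: the sum of
#' nearest-neighbour stacking energies over consecutive stem base pairs
#' plus a loop-initiation penalty, both read from plain-text parameter
#' tables shipped with the package. More negative means a stronger
#' hairpin.
#'
#' @param stem_pairs Ordered base pairs from the outermost (bottom of
#'   the stem) to the innermost (next to the loop): either a data frame
#'   with `left`/`right` columns or a character vector like
#'   `c("G:C", "C:G")`. `left` is the upstream arm read 5'->3'.
#' @param loop_length Loop length in nucleotides (>= 3).
#' @param allow_gu Permit G:T (G:U in the transcript) wobble pairs in
#'   the stem (default FALSE); stack steps involving a wobble use a flat
#'   tabulated energy.
#' @return Free energy in kcal/mol.
#' @examples
#' hairpin_delta_g(c("G:C", "G:C", "G:C", "G:C"), 4)
#' @export
hairpin_delta_g <- function(stem_pairs, loop_length, allow_gu = FALSE) {
  sp <- .normalize_stem_pairs(stem_pairs)
  k <- nrow(sp)
  if (k < 2L)
    stop("a stem needs at least 2 consecutive base pairs", call. = FALSE)
  if (loop_length < 3L)
    stop("loop_length must be >= 3", call. = FALSE)
  wc <- .is_wc_pair(sp$left, sp$right)
  wob <- .is_wobble_pair(sp$left, sp$right)
  if (any(!wc & !wob) || (!allow_gu && any(wob)))
    stop("non-complementary base pair in stem", call. = FALSE)
  stacks <- .stack_table()
  e <- 0
  for (i in seq_len(k - 1L)) {
    e <- e + if (wob[i] || wob[i + 1L]) stacks[["wobble"]] else
      stacks[[paste0(sp$left[i], sp$left[i + 1L])]]
  }
  e + .loop_penalty(as.integer(loop_length))
}

#' Predict Rho-independent terminators
#'
#' Enumerates hairpin candidates on the given strand: for every loop
#' length in `3..max_loop` and every innermost base pair, the stem is
#' extended outwards as far as complementarity allows (maximal stems
#' only). Candidates with at least `min_stem` pairs are scored with
#' [hairpin_delta_g()]; those stronger (more negative) than
#' `dg_threshold` and followed by a U-tract (at least `min_u` T's within
#' `u_window` nt downstream of the stem) are kept. Overlapping
#' candidates are resolved to the locally strongest. Hits with free
#' energy stronger than -10 kcal/mol are classed `strong`, the rest
#' `candidate`.
#'
#' @param seq Nucleotide string (the strand to be scanned, 5'->3').
#' @param dg_threshold Report only hits with free energy strictly below
#'   this value (default -5.0 kcal/mol).
#' @param min_stem Minimum stem length in base pairs (default 4).
#' @param max_loop Maximum loop length in nucleotides (default 10).
#' @param u_window Window downstream of the stem searched for the
#'   U-tract (default 8 nt).
#' @param min_u Minimum T count within `u_window` (default 3).
#' @param allow_gu Permit wobble pairs in stems (default FALSE).
#' @param contig Contig name for the output.
#' @param strand Strand label attached to the hits (default `"+"`).
#' @return Data frame: `kind`, `contig`, `strand`, `start`, `end`,
#'   `stem_len`, `loop_len`, `delta_g`, `u_count`, `strength`, sorted by
#'   position.
#' @export
find_terminators <- function(seq, dg_threshold = -5.0, min_stem = 4L,
                             max_loop = 10L, u_window = 8L, min_u = 3L,
                             allow_gu = FALSE, contig = "seq1",
                             strand = "+") {
  .assert_dna_string(seq)
  stopifnot(min_stem >= 2L, max_loop >= 3L, u_window >= 1L)
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  pair_ok <- function(x, y)
    .is_wc_pair(x, y) | (allow_gu & .is_wobble_pair(x, y))
  cand <- list()
  for (l in 3:max_loop) {
    if (n < 2L * min_stem + l) next
    i_max <- n - l - 1L
    i_all <- seq_len(i_max)
    seed <- i_all[pair_ok(chars[i_all], chars[i_all + l + 1L])]
    for (i in seed) {
      k <- 1L
      while (i - k >= 1L && i + l + 1L + k <= n &&
             pair_ok(chars[i - k], chars[i + l + 1L + k]))
        k <- k + 1L
      if (k < min_stem) next
      left <- chars[(i - k + 1L):i]
      right <- chars[(i + l + k):(i + l + 1L)]
      dg <- hairpin_delta_g(data.frame(left = left, right = right,
                                       stringsAsFactors = FALSE),
                            l, allow_gu = allow_gu)
      if (!(dg < dg_threshold)) next
      tail_start <- i + l + k + 1L
      tail_end <- min(n, i + l + k + u_window)
      u_count <- if (tail_start > n) 0L else
        sum(chars[tail_start:tail_end] == "T")
      if (u_count < min_u) next
      cand[[length(cand) + 1L]] <- data.frame(
        kind = "terminator", contig = contig, strand = strand,
        start = i - k + 1L, end = i + l + k,
        stem_len = k, loop_len = l, delta_g = dg, u_count = u_count,
        strength = if (dg < -10.0) "strong" else "candidate",
        stringsAsFactors = FALSE)
    }
  }
  empty <- data.frame(kind = character(), contig = character(),
                      strand = character(), start = integer(),
                      end = integer(), stem_len = integer(),
                      loop_len = integer(), delta_g = numeric(),
                      u_count = integer(), strength = character(),
                      stringsAsFactors = FALSE)
  if (!length(cand)) return(empty)
  hits <- do.call(rbind, cand)
  # locally strongest wins among overlapping candidates
  hits <- hits[order(hits$delta_g, hits$start, hits$end), , drop = FALSE]
  kept <- logical(0)
  keep_rows <- integer(0)
  for (r in seq_len(nrow(hits))) {
    ov <- FALSE
    for (q in keep_rows) {
      if (hits$start[r] <= hits$end[q] && hits$end[r] >= hits$start[q]) {
        ov <- TRUE; break
      }
    }
    if (!ov) keep_rows <- c(keep_rows, r)
  }
  hits <- hits[keep_rows, , drop = FALSE]
  hits <- hits[order(hits$start), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

#' Write regulatory hits as BED-like TSV
#'
#' Six columns: contig, 0-based start, end, name, score, strand. The
#' score is `-delta_g` for terminators and the total mismatch count for
#' promoters (0 for repeats).
#'
#' @param hits A hit data frame from [scan_promoters()],
#'   [find_direct_repeats()] or [find_terminators()] (or several
#'   row-bound together after aligning columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_hits_bed <- function(hits, path) {
  if (!nrow(hits)) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  name <- if ("model" %in% names(hits)) {
    ifelse(hits$kind == "promoter", hits$model, hits$kind)
  } else hits$kind
  score <- rep(0, nrow(hits))
  if ("delta_g" %in% names(hits)) {
    t_rows <- hits$kind == "terminator"
    score[t_rows] <- -hits$delta_g[t_rows]
  }
  if ("mismatches_35" %in% names(hits)) {
    p_rows <- hits$kind == "promoter"
    score[p_rows] <- hits$mismatches_35[p_rows] + hits$mismatches_10[p_rows]
  }
  bed <- data.frame(hits$contig, hits$start - 1L, hits$end, name,
                    score, hits$strand)
  write.table(bed, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}
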