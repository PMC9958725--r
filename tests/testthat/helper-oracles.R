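# Independent oracles used across the suite. These deliberately share no
# code path with the package implementation they check.

AA20 <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
          "M", "F", "P", "S", "T", "W", "Y", "V")
BASES <- c("A", "C", "G", "T")
COMP <- c(A = "T", C = "G", G = "C", T = "A")

blosum62 <- local({
  env <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = env)
  env$BLOSUM62
})

rand_protein <- function(n) paste(sample(AA20, n, replace = TRUE),
                                  collapse = "")
rand_dna <- function(n) paste(sample(BASES, n, replace = TRUE),
                              collapse = "")

# Exhaustive global-alignment score: enumerates every monotone alignment
# path, scoring a gap run of length L as open + L * ext, and keeps the
# maximum. Only usable for short sequences.
oracle_align_score <- function(a, b, sm = blosum62, open = 10, ext = 0.5) {
  A <- strsplit(a, "")[[1]]
  B <- strsplit(b, "")[[1]]
  na <- length(A); nb <- length(B)
  best <- -Inf
  rec <- function(i, j, score, prev) {
    if (i > na && j > nb) {
      if (score > best) best <<- score
      return(invisible(NULL))
    }
    if (i <= na && j <= nb)
      rec(i + 1L, j + 1L, score + sm[A[i], B[j]], "M")
    if (i <= na)
      rec(i + 1L, j, score - if (prev == "X") ext else open + ext, "X")
    if (j <= nb)
      rec(i, j + 1L, score - if (prev == "Y") ext else open + ext, "Y")
  }
  rec(1L, 1L, 0, "M")
  best
}

# Brute-force intrinsic-terminator enumerator: tests every
# (start, stem, loop) window explicitly, requires Watson-Crick pairing
# throughout, maximality (no outward extension possible), the free-energy
# threshold and the U-tract, then resolves overlaps strongest-first.
# Energies come from the same published parameter tables (via
# hairpin_delta_g) — the enumeration, not the energy table, is under test.
oracle_terminators <- function(seq, dg_threshold = -5, min_stem = 4,
                               max_loop = 10, u_window = 8, min_u = 3) {
  chars <- strsplit(seq, "")[[1]]
  n <- length(chars)
  rows <- list()
  for (start in seq_len(n)) {
    k_max <- floor((n - start + 1L - 3L) / 2)
    if (k_max < min_stem) next
    for (k in min_stem:k_max) {
      for (l in 3:max_loop) {
        end <- start + 2L * k + l - 1L
        if (end > n) next
        # cheap prechecks on the outermost and innermost pairs
        if (!chars[start] %in% BASES ||
            COMP[chars[start]] != chars[end]) next
        if (COMP[chars[start + k - 1L]] != chars[start + k + l]) next
        left <- chars[start:(start + k - 1L)]
        right <- chars[end:(end - k + 1L)]
        if (any(!left %in% BASES) || any(COMP[left] != right)) next
        if (start > 1L && end < n &&
            chars[start - 1L] %in% BASES &&
            COMP[chars[start - 1L]] == chars[end + 1L]) next  # not maximal
        dg <- hairpin_delta_g(data.frame(left = left, right = right,
                                         stringsAsFactors = FALSE), l)
        if (!(dg < dg_threshold)) next
        tail <- chars[seq(end + 1L, min(n, end + u_window))]
        if (end + 1L > n || sum(tail == "T") < min_u) next
        rows[[length(rows) + 1L]] <-
          data.frame(start = start, end = end, stem_len = k,
                     loop_len = l, delta_g = dg)
      }
    }
  }
  if (!length(rows)) return(data.frame(start = integer(), end = integer(),
                                       stem_len = integer(),
                                       loop_len = integer(),
                                       delta_g = numeric()))
  cand <- do.call(rbind, rows)
  cand <- cand[order(cand$delta_g, cand$start, cand$end), , drop = FALSE]
  keep <- integer(0)
  for (r in seq_len(nrow(cand))) {
    clash <- FALSE
    for (q in keep)
      if (cand$start[r] <= cand$end[q] && cand$end[r] >= cand$start[q]) {
        clash <- TRUE; break
      }
    if (!clash) keep <- c(keep, r)
  }
  cand <- cand[keep, , drop = FALSE]
  cand[order(cand$start), , drop = FALSE]
}

# Six-frame brute-force ORF oracle: enumerates every start-codon position,
# walks codon by codon to the first in-frame stop, keeps the ORF only if
# no other start precedes it inside the same stop-bounded segment, and
# translates with Biostrings (start forced to Met).
oracle_orfs <- function(seq, min_aa = 50) {
  starts <- c("ATG", "GTG", "TTG")
  stops <- c("TAA", "TAG", "TGA")
  revcomp <- function(x)
    paste(rev(COMP[strsplit(x, "")[[1]]]), collapse = "")
  scan <- function(s) {
    n <- nchar(s)
    found <- list()
    for (p in seq_len(max(0, n - 5))) {
      if (!substring(s, p, p + 2) %in% starts) next
      q <- p
      stop_at <- NA
      while (q + 5 <= n) {
        q <- q + 3
        cd <- substring(s, q, q + 2)
        if (grepl("N", cd)) break
        if (cd %in% stops) { stop_at <- q; break }
      }
      if (is.na(stop_at)) next
      # longest-per-stop: reject if an earlier start in the same segment
      earlier <- FALSE
      r <- p - 3
      while (r >= 1) {
        cd <- substring(s, r, r + 2)
        if (cd %in% stops || grepl("N", cd)) break
        if (cd %in% starts) { earlier <- TRUE; break }
        r <- r - 3
      }
      if (earlier) next
      aa_len <- (stop_at - p) / 3
      if (aa_len < min_aa) next
      body <- substring(s, p + 3, stop_at - 1)
      prot <- if (nchar(body))
        as.character(Biostrings::translate(Biostrings::DNAString(body),
                                           no.init.codon = TRUE))
      else ""
      found[[length(found) + 1L]] <-
        data.frame(start = p, end = stop_at + 2,
                   protein = paste0("M", prot))
    }
    found
  }
  n <- nchar(seq)
  fw <- scan(seq)
  rv <- scan(revcomp(seq))
  rows <- list()
  for (o in fw) rows[[length(rows) + 1L]] <-
    cbind(o, strand = "+", stringsAsFactors = FALSE)
  for (o in rv) rows[[length(rows) + 1L]] <-
    data.frame(start = n - o$end + 1, end = n - o$start + 1,
               protein = o$protein, strand = "-",
               stringsAsFactors = FALSE)
  if (!length(rows))
    return(data.frame(start = integer(), end = integer(),
                      protein = character(), strand = character()))
  out <- do.call(rbind, rows)
  out[order(out$start, out$end, out$strand), c("start", "end", "strand",
                                               "protein")]
}
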