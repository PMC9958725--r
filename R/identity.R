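#' Pairwise percent-identity matrix
#'
#' All pairwise [percent_identity()] values between the core peptides of
#' a collection, from global alignments under the default scoring.
#'
#' @param peptides List of [peptide_record()] objects (>= 2) with unique
#'   ids, or a named character vector of sequences.
#' @param ... Passed to [global_align()].
#' @return An `identity_matrix`: a symmetric numeric matrix of percent
#'   identities with a diagonal of 100 and peptide ids as dimnames.
#' @examples
#' refs <- nisin_reference_peptides()
#' identity_matrix(refs[c("nisA", "nisE")])
#' @export
identity_matrix <- function(peptides, ...) {
  if (is.character(peptides)) {
    ids <- names(peptides)
    if (is.null(ids) || any(!nzchar(ids)))
      stop("sequences must be named", call. = FALSE)
    seqs <- unname(peptides)
  } else {
    ids <- .check_unique_ids(peptides)
    seqs <- vapply(peptides, function(p) p$core_seq, character(1))
  }
  if (anyDuplicated(ids))
    stop("duplicate peptide ids", call. = FALSE)
  k <- length(seqs)
  if (k < 2L) stop("need at least two peptides", call. = FALSE)
  m <- diag(100, k)
  for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
    m[i, j] <- m[j, i] <- percent_identity(seqs[i], seqs[j], ...)
  }
  dimnames(m) <- list(ids, ids)
  structure(m, class = c("identity_matrix", "matrix", "array"))
}

#' Write an identity matrix to TSV
#'
#' @param im An [identity_matrix()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_identity_matrix_tsv <- function(im, path) {
  df <- data.frame(id = rownames(im), round(unclass(im), 1),
                   check.names = FALSE, stringsAsFactors = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

.as_identity_distance <- function(x) {
  m <- unclass(x)
  if (!is.matrix(m) || nrow(m) != ncol(m))
    stop("need a square matrix", call. = FALSE)
  if (max(abs(m - t(m))) > 1e-8)
    stop("matrix is not symmetric", call. = FALSE)
  if (is.null(rownames(m))) rownames(m) <- colnames(m) <- paste0("t", seq_len(nrow(m)))
  d <- 100 - m
  diag(d) <- 0
  d
}

#' Neighbour-joining tree from an identity matrix
#'
#' Builds an unrooted neighbour-joining tree on the distance
#' `100 - percent identity`. The agglomeration is deterministic: when
#' the NJ criterion ties, the pair whose (lexicographically sorted)
#' labels come first is joined, internal nodes inheriting the smallest
#' leaf label for comparison. Negative branch lengths, which NJ can
#' produce on non-additive distances, are clamped to zero.
#'
#' @param x An [identity_matrix()] (or a symmetric percent-identity
#'   matrix with dimnames).
#' @return A Newick string (terminated by `;`), readable with
#'   `ape::read.tree`.
#' @examples
#' im <- identity_matrix(nisin_reference_peptides())
#' nj_tree(im)
#' @export
nj_tree <- function(x) {
  d <- .as_identity_distance(x)
  n <- nrow(d)
  if (n < 3L) stop("neighbour joining needs at least 3 taxa", call. = FALSE)
  labels <- rownames(d)
  frag <- labels     # newick fragment per active node
  rep_lab <- labels  # smallest leaf label per active node (tie-break)
  fmt <- function(v) formatC(max(v, 0), digits = 6, format = "fg")
  while (length(frag) > 3L) {
    k <- nrow(d)
    r <- rowSums(d)
    best <- NULL
    for (i in seq_len(k - 1L)) for (j in (i + 1L):k) {
      q <- (k - 2) * d[i, j] - r[i] - r[j]
      key <- sort(c(rep_lab[i], rep_lab[j]))
      better <- is.null(best) || q < best$q - 1e-9 ||
        (abs(q - best$q) <= 1e-9 &&
           (key[1] < best$key[1] ||
              (key[1] == best$key[1] && key[2] < best$key[2])))
      if (better) best <- list(q = q, i = i, j = j, key = key)
    }
    i <- best$i; j <- best$j
    vi <- 0.5 * d[i, j] + (r[i] - r[j]) / (2 * (k - 2))
    vj <- d[i, j] - vi
    newfrag <- sprintf("(%s:%s,%s:%s)", frag[i], fmt(vi), frag[j], fmt(vj))
    newrep <- min(rep_lab[i], rep_lab[j])
    dn <- 0.5 * (d[i, ] + d[j, ] - d[i, j])
    dn <- pmax(dn, 0)
    keep <- setdiff(seq_len(k), c(i, j))
    d <- rbind(cbind(d[keep, keep, drop = FALSE], dn[keep]),
               c(dn[keep], 0))
    frag <- c(frag[keep], newfrag)
    rep_lab <- c(rep_lab[keep], newrep)
  }
  # final three-way join at the central node
  va <- 0.5 * (d[1, 2] + d[1, 3] - d[2, 3])
  vb <- 0.5 * (d[1, 2] + d[2, 3] - d[1, 3])
  vc <- 0.5 * (d[1, 3] + d[2, 3] - d[1, 2])
  ord <- order(rep_lab)
  v <- c(va, vb, vc)[ord]
  f <- frag[ord]
  sprintf("(%s:%s,%s:%s,%s:%s);", f[1], fmt(v[1]), f[2], fmt(v[2]),
          f[3], fmt(v[3]))
}

#' UPGMA dendrogram from an identity matrix
#'
#' Average-linkage (UPGMA) alternative to [nj_tree()], via
#' `stats::hclust` on the `100 - identity` distance.
#'
#' @inheritParams nj_tree
#' @return A Newick string.
#' @export
upgma_tree <- function(x) {
  d <- .as_identity_distance(x)
  hc <- stats::hclust(stats::as.dist(d), method = "average")
  ape::write.tree(ape::as.phylo(hc))
}
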