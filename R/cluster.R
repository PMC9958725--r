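#' Construct a gene cluster model
#'
#' A nisin-type gene cluster is modelled as an ordered set of genes with
#' canonical single-letter role labels: A (structural peptide), B/C
#' (dehydratase/cyclase), T (transporter), I (immunity lipoprotein),
#' P (leader peptidase), R/K (response regulator/histidine kinase) and
#' F/E/G (ABC-transporter immunity).
#'
#' @param cluster_id Cluster label.
#' @param genes Data frame with columns `role`, `contig`, `start`, `end`,
#'   `strand` (1-based inclusive coordinates, strand `+`/`-`).
#' @return A `gene_cluster` object.
#' @export
gene_cluster <- function(cluster_id, genes) {
  stopifnot(is.character(cluster_id), length(cluster_id) == 1L)
  if (nrow(genes)) {
    stopifnot(all(c("role", "contig", "start", "end", "strand") %in%
                    names(genes)))
    bad <- setdiff(genes$role, CLUSTER_ROLES)
    if (length(bad))
      stop("unknown role label(s): ", paste(bad, collapse = ", "),
           call. = FALSE)
    if (any(genes$start > genes$end))
      stop("gene with start > end", call. = FALSE)
    if (!all(genes$strand %in% c("+", "-")))
      stop("strand must be '+' or '-'", call. = FALSE)
  }
  structure(list(cluster_id = cluster_id,
                 genes = as.data.frame(genes)),
            class = "gene_cluster")
}

#' @export
print.gene_cluster <- function(x, ...) {
  cat(sprintf("<gene_cluster> %s: %d gene(s)", x$cluster_id,
              nrow(x$genes)))
  if (nrow(x$genes)) cat(" [", layout_string(x), "]", sep = "")
  cat("\n")
  invisible(x)
}

#' Read gene clusters from TSV
#'
#' Expects tab-separated columns `cluster_id`, `role`, `contig`, `start`,
#' `end`, `strand` with 1-based inclusive coordinates.
#'
#' @param path Input path.
#' @return Named list of [gene_cluster()] objects.
#' @export
read_gene_clusters <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("cluster_id", "role", "contig", "start", "end",
                  "strand") %in% names(tab)))
  out <- lapply(split(tab, tab$cluster_id), function(g)
    gene_cluster(g$cluster_id[1], g[, -1]))
  out[unique(tab$cluster_id)]
}

#' Gene-cluster layout string
#'
#' Concatenates the role labels in genomic order (contigs in order of
#' appearance, leftmost start coordinate first within a contig). The
#' nisin E cluster reads `"PRKAFEGBTCI"`; the nisin A cluster
#' `"ABTCIPRKFEG"`.
#'
#' @param cluster A [gene_cluster()] object.
#' @return Single string of role labels (empty for an empty cluster).
#' @export
layout_string <- function(cluster) {
  g <- cluster$genes
  if (!nrow(g)) return("")
  if (anyDuplicated(g$role))
    stop("duplicate role label in cluster ", cluster$cluster_id,
         call. = FALSE)
  g <- g[order(match(g$contig, unique(g$contig)), g$start), ]
  paste(g$role, collapse = "")
}

.adjacency_set <- function(layout) {
  roles <- strsplit(layout, "")[[1]]
  if (length(roles) < 2L) return(character(0))
  a <- roles[-length(roles)]
  b <- roles[-1]
  unique(ifelse(a < b, paste0(a, b), paste0(b, a)))
}

#' Compare two gene-cluster layouts
#'
#' Treats each layout as its set of unordered neighbouring role pairs
#' (adjacencies), so the comparison is orientation-insensitive: a layout
#' and its reversal are identical. Breakpoints count the adjacencies of
#' the first layout missing from the second — a synteny dissimilarity.
#'
#' @param c1,c2 [gene_cluster()] objects or layout strings over the same
#'   role alphabet.
#' @return List with `shared_adjacencies` and `breakpoints` counts.
#' @examples
#' compare_layouts("ABTCIPRKFEG", "PRKAFEGBTCI")  # 7 shared, 3 breakpoints
#' @export
compare_layouts <- function(c1, c2) {
  l1 <- if (inherits(c1, "gene_cluster")) layout_string(c1) else c1
  l2 <- if (inherits(c2, "gene_cluster")) layout_string(c2) else c2
  r1 <- sort(strsplit(l1, "")[[1]])
  r2 <- sort(strsplit(l2, "")[[1]])
  if (!identical(r1, r2))
    stop("layouts are over different role alphabets", call. = FALSE)
  a1 <- .adjacency_set(l1)
  a2 <- .adjacency_set(l2)
  list(shared_adjacencies = length(intersect(a1, a2)),
       breakpoints = length(setdiff(a1, a2)))
}

#' Classify a cluster by its present roles
#'
#' Categories: `full_production` when all eleven canonical roles are
#' present; `immunity_sensing_subset` when the present roles are exactly
#' the regulator/kinase/ABC-immunity set `{R,K,F,E,G}` (production
#' machinery absent); `none` when no role is present; otherwise
#' `partial`.
#'
#' @param present_roles Character vector of role labels (possibly empty),
#'   or a [gene_cluster()] object.
#' @param cluster_id Optional label carried into the result.
#' @return A `cluster_classification`: list with `cluster_id`,
#'   `category`, `present_roles`, `missing_roles`.
#' @examples
#' classify_cluster(c("R", "K", "F", "E", "G"))$category
#' @export
classify_cluster <- function(present_roles, cluster_id = "cluster") {
  if (inherits(present_roles, "gene_cluster")) {
    cluster_id <- present_roles$cluster_id
    present_roles <- present_roles$genes$role
  }
  present <- unique(as.character(present_roles))
  bad <- setdiff(present, CLUSTER_ROLES)
  if (length(bad))
    stop("unknown role label(s): ", paste(bad, collapse = ", "),
         call. = FALSE)
  category <- if (length(present) == 0L) {
    "none"
  } else if (setequal(present, CLUSTER_ROLES)) {
    "full_production"
  } else if (setequal(present, IMMUNITY_SENSING_ROLES)) {
    "immunity_sensing_subset"
  } else {
    "partial"
  }
  structure(list(cluster_id = cluster_id, category = category,
                 present_roles = sort(present),
                 missing_roles = sort(setdiff(CLUSTER_ROLES, present))),
            class = "cluster_classification")
}

#' @export
print.cluster_classification <- function(x, ...) {
  cat(sprintf("<cluster_classification> %s: %s\n", x$cluster_id,
              x$category))
  cat("  present:", if (length(x$present_roles))
    paste(x$present_roles, collapse = ""), "\n")
  cat("  missing:", if (length(x$missing_roles))
    paste(x$missing_roles, collapse = ""), "\n")
  invisible(x)
}
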