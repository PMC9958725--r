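#' Residue mass table
#'
#' Average and monoisotopic residue masses (Da) for the twenty canonical
#' amino acids, plus the mass of water, read from the plain-text table
#' shipped with the package (`extdata/residue_masses.tsv`). Residue
#' masses are monomer masses minus one water, so an unmodified linear
#' peptide weighs the residue sum plus one water.
#'
#' @return Data frame with columns `residue`, `average`, `monoisotopic`;
#'   the water row carries residue label `"water"`.
#' @export
residue_mass_table <- function() {
  if (is.null(.lantivar_cache$residue_masses)) {
    path <- system.file("extdata", "residue_masses.tsv",
                        package = "lantivar", mustWork = TRUE)
    tab <- read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
    stopifnot(all(AA1 %in% tab$residue), "water" %in% tab$residue,
              all(tab$average > 0), all(tab$monoisotopic > 0))
    .lantivar_cache$residue_masses <- tab
  }
  .lantivar_cache$residue_masses
}

.mass_lookup <- function(kind) {
  tab <- residue_mass_table()
  setNames(tab[[kind]], tab$residue)
}

#' Unmodified peptide mass
#'
#' Sum of residue masses plus one water. The average-mass prediction for
#' the reconstructed mature nisin E core is 3245.9 Da.
#'
#' @param seq Amino-acid string or [peptide_record()].
#' @param kind `"average"` (default) or `"monoisotopic"`.
#' @return Mass in Da.
#' @examples
#' peptide_mass("G")  # 75.07
#' @export
peptide_mass <- function(seq, kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  s <- .as_core_seq(seq)
  m <- .mass_lookup(kind)
  sum(m[strsplit(s, "")[[1]]]) + m[["water"]]
}

.count_dehydratable <- function(seq) {
  chars <- strsplit(seq, "")[[1]]
  sum(chars %in% c("S", "T"))
}

#' Dehydration-modified peptide mass
#'
#' Lanthipeptide maturation dehydrates Ser/Thr residues (to Dha/Dhb),
#' each event removing one water; the subsequent thioether
#' (lanthionine/methyllanthionine) ring formation with Cys is
#' mass-neutral. The modified mass is therefore the unmodified mass
#' minus `n_dehydrations` waters, and `n_dehydrations` can never exceed
#' the number of Ser plus Thr residues.
#'
#' @inheritParams peptide_mass
#' @param n_dehydrations Non-negative integer count of dehydration events.
#' @return Mass in Da.
#' @examples
#' refs <- nisin_reference_peptides()
#' modified_mass(refs$nisE, 8)  # ~3101.7
#' @export
modified_mass <- function(seq, n_dehydrations,
                          kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  s <- .as_core_seq(seq)
  n <- as.integer(n_dehydrations)
  stopifnot(length(n) == 1L, !is.na(n), n >= 0L)
  max_n <- .count_dehydratable(s)
  if (n > max_n)
    stop("n_dehydrations (", n, ") exceeds Ser+Thr count (", max_n, ")",
         call. = FALSE)
  peptide_mass(s, kind) - n * .mass_lookup(kind)[["water"]]
}

#' Infer the dehydration count from an observed mass
#'
#' Finds the unique number of dehydrations `n` in `0..(#Ser + #Thr)`
#' whose predicted [modified_mass()] is closest to the observed mass,
#' requiring the residual to fall within `tolerance`. The default
#' tolerance of 1.5 Da suits linear-MALDI-scale measurements.
#'
#' @inheritParams peptide_mass
#' @param observed_mass Observed mass in Da.
#' @param tolerance Maximum acceptable |predicted - observed| in Da.
#' @return Integer dehydration count, with attribute `residual`
#'   (predicted minus observed, Da).
#' @examples
#' refs <- nisin_reference_peptides()
#' infer_dehydrations(refs$nisE, 3100.8)  # 8
#' @export
infer_dehydrations <- function(seq, observed_mass, tolerance = 1.5,
                               kind = c("average", "monoisotopic")) {
  kind <- match.arg(kind)
  stopifnot(is.numeric(observed_mass), length(observed_mass) == 1L,
            is.numeric(tolerance), tolerance > 0)
  s <- .as_core_seq(seq)
  ns <- 0:.count_dehydratable(s)
  pred <- vapply(ns, function(n) modified_mass(s, n, kind), numeric(1))
  resid <- abs(pred - observed_mass)
  ord <- order(resid)
  if (resid[ord[1]] > tolerance)
    stop(sprintf(
      "no dehydration count within %.3g Da of observed %.4f (best: n=%d, off by %.3f)",
      tolerance, observed_mass, ns[ord[1]], resid[ord[1]]), call. = FALSE)
  if (length(ord) > 1L && resid[ord[2]] <= tolerance &&
      abs(resid[ord[2]] - resid[ord[1]]) < 1e-9)
    stop("ambiguous: two dehydration counts fit equally well within tolerance",
         call. = FALSE)
  structure(ns[ord[1]], residual = pred[ord[1]] - observed_mass)
}
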