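refs <- nisin_reference_peptides()

test_that("published edit list reconstructs mature nisin E from nisin A", {
  expect_identical(refs$nisE$core_seq, "ITSKSLCTPGCKTGALMTCPIKTATCGCHFGN")
  expect_identical(nchar(refs$nisE$core_seq), 32L)
  # identity case
  expect_identical(apply_edits(refs$nisA, NULL), refs$nisA$core_seq)
  # reversing the E -> U relation gives the 31-mer nisin U core
  expect_identical(refs$nisU$core_seq, "ITSKSLCTPGCKTGILMTCPLKTATCGCHFG")
})

test_that("apply_edits validates reference residues and positions", {
  expect_error(
    apply_edits("ITSISL", data.frame(kind = "substitution", ref_pos = 4,
                                     ref_aa = "K", alt_aa = "R")),
    "wrong reference")
  expect_error(
    apply_edits("ITSISL", data.frame(kind = "deletion", ref_pos = 9,
                                     ref_aa = "I", alt_aa = "")),
    "outside")
  dup <- data.frame(kind = c("substitution", "deletion"),
                    ref_pos = c(3, 3), ref_aa = c("S", "S"),
                    alt_aa = c("A", ""))
  expect_error(apply_edits("ITSISL", dup), "duplicate")
  expect_error(
    apply_edits("ITSISL", data.frame(kind = "substitution", ref_pos = 2,
                                     ref_aa = "T", alt_aa = "T")),
    "identical")
})

test_that("the E-vs-A alignment places one gapped block at ref 29-30", {
  aln <- global_align(refs$nisA, refs$nisE)
  expect_identical(aln$aligned_query,
                   "ITSKSLCTPGCKTGALMTCPIKTATCGC--HFGN")
  expect_identical(aln$identities, 24L)
  expect_identical(aln$compared_columns, 32L)
})

test_that("diff_variants reports the ten printed nisin E differences", {
  d <- diff_variants(refs$nisA, refs$nisE)
  expect_identical(nrow(d), 10L)
  expect_identical(
    d$name,
    c("Ile4Lys", "Gly18Thr", "Asn20Pro", "Met21Ile", "His27Gly",
      "ΔSer29", "ΔIle30", "Val32Phe", "Ser33Gly", "Lys34Asn"))
  expect_identical(sum(d$kind == "substitution"), 8L)
  expect_identical(sum(d$kind == "deletion"), 2L)
  # trivial self-diff
  expect_identical(nrow(diff_variants(refs$nisA, refs$nisA)), 0L)
})

test_that("nisin U differs from nisin E by two substitutions and one
           C-terminal insertion", {
  d <- diff_variants(refs$nisU, refs$nisE)
  expect_identical(nrow(d), 3L)
  expect_setequal(d$kind, c("substitution", "insertion"))
  expect_identical(d$name[d$kind == "insertion"], "insAsn32")
  expect_identical(sort(d$ref_pos[d$kind == "substitution"]), c(15L, 21L))
})

test_that("diff/apply round-trips on random seeded mutants", {
  for (s in 1:25) {
    mut <- mutate_peptide(refs$nisA, n_subs = sample(0:8, 1),
                          n_dels = sample(0:3, 1), seed = s)
    expect_identical(apply_edits(refs$nisA, diff_variants(
      refs$nisA$core_seq, mut$sequence)), mut$sequence)
  }
})

test_that("edit-name formatting is bijective", {
  set.seed(42)
  for (i in 1:50) {
    kind <- sample(c("substitution", "deletion", "insertion"), 1)
    ref_aa <- if (kind == "insertion") "" else sample(AA20, 1)
    alt_aa <- if (kind == "deletion") "" else
      if (kind == "substitution") sample(setdiff(AA20, ref_aa), 1) else
        sample(AA20, 1)
    e <- data.frame(kind = kind, ref_pos = sample(1:99, 1),
                    ref_aa = ref_aa, alt_aa = alt_aa,
                    stringsAsFactors = FALSE)
    back <- parse_edit_name(format_edit_names(e))
    expect_identical(back, e)
  }
  expect_error(parse_edit_name("NotAnEdit"), "parse")
})

test_that("percent identity follows the residue-column convention", {
  expect_equal(percent_identity(refs$nisA, refs$nisE), 75.0)
  expect_equal(percent_identity(refs$nisA, refs$nisZ), 100 * 33 / 34)
  expect_equal(percent_identity(refs$nisE, refs$nisU), 100 * 29 / 31)
  # symmetry and the identity case
  set.seed(7)
  for (i in 1:10) {
    a <- rand_protein(sample(5:30, 1))
    b <- rand_protein(sample(5:30, 1))
    expect_equal(percent_identity(a, b), percent_identity(b, a))
  }
  expect_equal(percent_identity("ACDEF", "ACDEF"), 100)
})

test_that("alignment score matches Biostrings pairwiseAlignment", {
  set.seed(11)
  for (i in 1:20) {
    a <- rand_protein(sample(8:40, 1))
    b <- rand_protein(sample(8:40, 1))
    ours <- global_align(a, b)$score
    theirs <- Biostrings::pairwiseAlignment(
      a, b, type = "global", substitutionMatrix = blosum62,
      gapOpening = 10, gapExtension = 0.5, scoreOnly = TRUE)
    expect_equal(ours, theirs)
  }
})

test_that("alignment handles forced terminal gaps and bad input", {
  aln <- global_align("AC", "A")
  expect_identical(aln$aligned_ref, "AC")
  expect_identical(aln$aligned_query, "A-")
  expect_error(global_align("ACX?", "AC"), "residue")
  expect_error(global_align("", "AC"), "non-empty")
})

test_that("hinge extraction matches the natural variants", {
  expect_identical(hinge_region(refs$nisA), "NMK")
  expect_identical(hinge_region(refs$nisE), "PIK")
  expect_identical(hinge_region(refs$nisU), "PLK")
  # deleting a hinge position is an error
  no_hinge <- apply_edits(refs$nisA, data.frame(
    kind = "deletion", ref_pos = 21, ref_aa = "M", alt_aa = ""))
  expect_error(hinge_region(no_hinge), "deleted")
})

test_that("identity matrices are symmetric with a diagonal of 100", {
  im <- identity_matrix(refs)
  expect_true(all(diag(unclass(im)) == 100))
  expect_equal(unclass(im), t(unclass(im)))
  expect_true(all(im >= 0 & im <= 100))
  expect_equal(im["nisA", "nisE"], 75.0)
  expect_equal(im["nisA", "nisZ"], 100 * 33 / 34, tolerance = 1e-10)
  dup <- list(refs$nisA, refs$nisA)
  expect_error(identity_matrix(dup), "duplicate")
  expect_error(identity_matrix(refs[1]), "at least two")
})

test_that("nj_tree validates input and resolves three equidistant taxa", {
  m <- matrix(c(100, 90, 90, 90, 100, 90, 90, 90, 100), 3,
              dimnames = list(c("a", "b", "c"), c("a", "b", "c")))
  nwk <- nj_tree(m)
  tr <- ape::read.tree(text = nwk)
  expect_identical(ape::Ntip(tr), 3L)
  expect_true(all(abs(tr$edge.length - 5) < 1e-9))
  expect_error(nj_tree(m[1:2, 1:2]), "at least 3")
  m2 <- m; m2[1, 2] <- 80
  expect_error(nj_tree(m2), "symmetric")
})

test_that("nj recovers additively generated five-taxon topologies", {
  for (s in 1:10) {
    set.seed(s)
    tr <- ape::rtree(5, br = function(n) runif(n, 0.5, 3))
    d <- ape::cophenetic.phylo(tr)
    ours <- ape::read.tree(text = nj_tree(100 - d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(tr),
                                           ape::unroot(ours))), 0)
    # and agrees topologically with ape's own NJ
    theirs <- ape::nj(stats::as.dist(d))
    expect_equal(as.numeric(ape::dist.topo(ape::unroot(ours),
                                           ape::unroot(theirs))), 0)
  }
})

test_that("upgma_tree produces a readable ultrametric-style newick", {
  im <- identity_matrix(refs)
  tr <- ape::read.tree(text = upgma_tree(im))
  expect_setequal(tr$tip.label, names(refs))
})
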