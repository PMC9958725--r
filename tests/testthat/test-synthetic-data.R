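refs <- nisin_reference_peptides()

test_that("mutate_peptide plants the requested edit counts,
           deterministically", {
  m <- mutate_peptide(refs$nisA, n_subs = 8, n_dels = 2, seed = 5)
  expect_identical(nchar(m$sequence), 32L)
  expect_identical(nrow(m$edits), 10L)
  expect_identical(sum(m$edits$kind == "substitution"), 8L)
  expect_identical(sum(m$edits$kind == "deletion"), 2L)
  expect_false(anyDuplicated(m$edits$ref_pos) > 0)
  # applying the returned edits reproduces the returned sequence
  expect_identical(apply_edits(refs$nisA, m$edits), m$sequence)
  # determinism and the trivial case
  expect_identical(mutate_peptide(refs$nisA, 8, 2, seed = 5), m)
  zero <- mutate_peptide(refs$nisA, 0, 0, seed = 5)
  expect_identical(zero$sequence, refs$nisA$core_seq)
  expect_identical(nrow(zero$edits), 0L)
  expect_error(mutate_peptide("ACDE", 3, 1), "smaller")
})

test_that("planted regulatory sequences scan back to their manifest", {
  models <- nisin_promoter_models(p_type_spacer = 20L)
  rs <- make_regulatory_sequence(200, promoter = models$S_type_R,
                                 with_repeat = TRUE, hairpin = "strong",
                                 seed = 97)
  expect_identical(rs, make_regulatory_sequence(
    200, promoter = models$S_type_R, with_repeat = TRUE,
    hairpin = "strong", seed = 97))
  man <- rs$manifest
  prom <- scan_promoters(rs$seq, models$S_type_R, 0, 0)
  expect_identical(prom$start,
                   man$start[man$feature == "promoter"])
  expect_identical(find_direct_repeats(rs$seq)$start,
                   man$start[man$feature == "direct_repeat"])
  term <- find_terminators(rs$seq)
  expect_identical(term$start, man$start[man$feature == "terminator"])
  expect_identical(term$strength, "strong")
  # a sub-threshold hairpin is planted but correctly not reported
  rs_sub <- make_regulatory_sequence(200, hairpin = "sub",
                                     with_repeat = FALSE, seed = 131)
  expect_false(rs_sub$manifest$reported[
    rs_sub$manifest$feature == "terminator"])
  expect_identical(nrow(find_terminators(rs_sub$seq)), 0L)
})

test_that("cluster sequences carry recoverable genes and features", {
  models <- nisin_promoter_models()
  out <- make_cluster_sequence(
    "PRKAFEGBTCI",
    promoters = list(list(model = models$S_type_R, before_role = "R")),
    terminators = list(list(after_role = "I", class = "strong")),
    seed = 77)
  expect_identical(layout_string(out$cluster), "PRKAFEGBTCI")
  # every manifest gene ends at a called ORF stop whose frame covers it
  # (an in-frame upstream start in the intergenic gap may extend the ORF
  # 5' of the planted start, which the identity convention tolerates)
  orfs <- find_orfs(unname(out$seq), min_aa = 50)
  g <- out$manifest$genes
  for (r in seq_len(nrow(g)))
    expect_true(any(orfs$end == g$end[r] & orfs$start <= g$start[r] &
                      orfs$strand == "+"))
  # planted promoter and terminator recovered at exact coordinates
  f <- out$manifest$features
  fp <- f[f$feature == "promoter", ]
  prom <- scan_promoters(unname(out$seq), models$S_type_R, 0, 0)
  expect_true(all(paste(fp$start, fp$end) %in%
                    paste(prom$start, prom$end)))
  ft <- f[f$feature == "terminator", ]
  term <- find_terminators(unname(out$seq))
  expect_true(all(paste(ft$start, ft$end) %in%
                    paste(term$start, term$end)))
  expect_true("strong" %in%
                term$strength[term$start %in% ft$start])
  # determinism; empty layout degenerates to plain background
  expect_identical(out$seq, make_cluster_sequence(
    "PRKAFEGBTCI",
    promoters = list(list(model = models$S_type_R, before_role = "R")),
    terminators = list(list(after_role = "I", class = "strong")),
    seed = 77)$seq)
  empty <- make_cluster_sequence("", seed = 3)
  expect_identical(nrow(empty$manifest$genes), 0L)
  expect_error(make_cluster_sequence(
    "AB", promoters = list(list(model = models$S_type_R,
                                before_role = "R"))), "not in layout")
})

test_that("pangenome generation is seeded, sized and labelled correctly", {
  pg <- make_pangenome(6, 1, 2, mutation_rate = 0.02, seed = 19)
  expect_identical(length(pg$genomes), 6L)
  expect_identical(sum(pg$manifest$category == "full_production"), 1L)
  expect_identical(sum(pg$manifest$category == "immunity_sensing_subset"),
                   2L)
  expect_identical(sum(pg$manifest$category == "none"), 3L)
  pg2 <- make_pangenome(6, 1, 2, mutation_rate = 0.02, seed = 19)
  expect_identical(pg, pg2)
  expect_error(make_pangenome(3, 2, 2), "exceeds")
  # all-empty pangenome classifies as none
  pg0 <- make_pangenome(2, 0, 0, mutation_rate = 0, seed = 23)
  for (g in pg0$genomes)
    expect_identical(classify_genome(g)$category, "none")
})

test_that("pangenome FASTA + manifest round-trip through disk", {
  pg <- make_pangenome(3, 1, 1, seed = 29)
  dir <- withr::local_tempdir()
  write_pangenome_fasta(pg, dir)
  expect_identical(sort(list.files(dir, pattern = "fasta$")),
                   paste0(sort(names(pg$genomes)), ".fasta"))
  man <- read_pangenome_manifest(file.path(dir, "manifest.json"))
  expect_identical(man$genome_id, pg$manifest$genome_id)
  expect_identical(man$category, pg$manifest$category)
  # and the written genomes screen back to the manifest
  res <- screen_pangenome(dir)
  got <- setNames(res$classifications$category,
                  res$classifications$genome_id)
  expect_identical(unname(got[pg$manifest$genome_id]),
                   pg$manifest$category)
})
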