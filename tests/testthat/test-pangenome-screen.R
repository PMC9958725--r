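refs_prot <- nisin_cluster_references()

back_translate_plain <- function(protein) {
  # independent minimal back-translation for planting test genes
  code <- Biostrings::GENETIC_CODE
  inv <- split(names(code), as.character(code))
  chars <- strsplit(protein, "")[[1]]
  codons <- vapply(chars, function(a) inv[[a]][1], character(1))
  codons[1] <- "ATG"
  paste0(paste(codons, collapse = ""), "TAA")
}

test_that("a planted gene is recovered on either strand with exact
           coordinates", {
  set.seed(14)
  prot <- rand_protein(60)
  substr(prot, 1, 1) <- "M"
  gene <- back_translate_plain(prot)
  left <- rand_dna(101)
  contig <- paste0(left, gene, rand_dna(97))
  orfs <- find_orfs(contig, min_aa = 50)
  fwd <- orfs[orfs$strand == "+" & orfs$start == 102, ]
  expect_identical(nrow(fwd), 1L)
  expect_identical(fwd$end, 101L + nchar(gene))
  expect_identical(fwd$protein, prot)
  # reverse strand
  rc <- paste(rev(COMP[strsplit(contig, "")[[1]]]), collapse = "")
  orfs_rc <- find_orfs(rc, min_aa = 50)
  hit <- orfs_rc[orfs_rc$strand == "-" & orfs_rc$protein == prot, ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$start, nchar(contig) - (101L + nchar(gene)) + 1L)
  # a 20-codon ORF is excluded at min_aa 50
  short <- paste0(rand_dna(50), back_translate_plain(
    paste0("M", rand_protein(19))), rand_dna(50))
  expect_false(any(nchar(find_orfs(short, min_aa = 50)$protein) < 50))
})

test_that("ORF calling agrees with the six-frame brute-force oracle", {
  set.seed(23)
  for (i in 1:6) {
    contig <- rand_dna(1500)
    got <- find_orfs(contig, min_aa = 20)
    want <- oracle_orfs(contig, min_aa = 20)
    rownames(got) <- rownames(want) <- NULL
    expect_equal(got[, c("start", "end", "strand", "protein")], want)
  }
})

test_that("homolog assignment respects the identity threshold", {
  set.seed(41)
  # plant a lightly mutated F gene: ~5% substitutions
  protF <- refs_prot[["F"]]
  chars <- strsplit(protF, "")[[1]]
  hit_pos <- sample(2:length(chars), round(0.05 * length(chars)))
  for (p in hit_pos) chars[p] <- sample(setdiff(AA20, chars[p]), 1)
  mutF <- paste(chars, collapse = "")
  contig <- paste0(rand_dna(80), back_translate_plain(mutF),
                   rand_dna(80))
  orfs <- find_orfs(contig, min_aa = 50)
  hits <- assign_homologs(orfs, refs_prot)
  expect_identical(hits$role, "F")
  expect_gte(hits$percent_identity, 90)
  expect_lt(hits$percent_identity, 100)
  # an unrelated random protein is never assigned
  decoy <- paste0(rand_dna(80),
                  back_translate_plain(rand_protein(140)),
                  rand_dna(80))
  expect_identical(nrow(assign_homologs(find_orfs(decoy, 50),
                                        refs_prot)), 0L)
  # the exact reference scores 100
  exact <- paste0(rand_dna(80), back_translate_plain(refs_prot[["G"]]),
                  rand_dna(80))
  hitsG <- assign_homologs(find_orfs(exact, 50), refs_prot)
  expect_identical(hitsG$role, "G")
  expect_equal(hitsG$percent_identity, 100)
})

test_that("genome classification recovers planted truth and is invariant
           to contig order and operon strand", {
  full <- make_cluster_sequence("PRKAFEGBTCI", seed = 61)
  decoy_contig <- setNames(rand_dna(600), "decoy")
  g1 <- c(full$seq, decoy_contig)
  g2 <- rev(g1)
  c1 <- classify_genome(g1)
  c2 <- classify_genome(g2)
  expect_identical(c1$category, "full_production")
  expect_identical(c2$category, "full_production")
  expect_setequal(c1$present_roles, strsplit("PRKAFEGBTCI", "")[[1]])
  # same operon on the reverse strand
  rc <- paste(rev(COMP[strsplit(unname(full$seq), "")[[1]]]),
              collapse = "")
  expect_identical(classify_genome(c(flipped = rc))$category,
                   "full_production")
  # subset and empty genomes
  subset_ <- make_cluster_sequence("RKFEG", seed = 62)
  expect_identical(classify_genome(subset_$seq)$category,
                   "immunity_sensing_subset")
  expect_identical(classify_genome(c(bare = rand_dna(900)))$category,
                   "none")
})

test_that("pangenome summaries count every genome exactly once", {
  cats <- c("full_production", "immunity_sensing_subset", "partial",
            "none")
  s <- summarize_pangenome(cats)
  expect_identical(s$count, rep(1L, 4))
  expect_equal(sum(s$fraction), 1)
  s2 <- summarize_pangenome(rep("none", 5))
  expect_identical(s2$count[s2$category == "none"], 5L)
  expect_equal(s2$fraction[s2$category == "none"], 1)
  expect_error(summarize_pangenome(character(0)), "no genomes")
  expect_error(summarize_pangenome("weird"), "unknown category")
})
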