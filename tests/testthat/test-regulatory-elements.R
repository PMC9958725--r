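models <- nisin_promoter_models(p_type_spacer = 20L)

test_that("planted consensus promoters are found with exact coordinates", {
  set.seed(21)
  for (m in models) {
    site <- paste0(m$box35, rand_dna(m$spacer), m$box10)
    seq <- paste0(rand_dna(40), site, rand_dna(40))
    hits <- scan_promoters(seq, m, max_mismatch_per_box = 0,
                           spacer_slack = 0)
    planted <- hits[hits$strand == "+", ]
    expect_true(nrow(planted) >= 1)
    expect_true(any(planted$start == 41 &
                      planted$end == 40 + nchar(site) &
                      planted$spacer == m$spacer &
                      planted$mismatches_35 == 0 &
                      planted$mismatches_10 == 0))
  }
})

test_that("mismatch budgets and spacer slack behave as documented", {
  m <- models$S_type_R
  box35_mut <- "TGCACT"  # one substitution in the -35
  seq <- paste0("GGGGGGGG", box35_mut, strrep("A", 15), m$box10,
                "GGGGGGGG")
  expect_identical(nrow(scan_promoters(seq, m, 0, 0)), 0L)
  hit <- scan_promoters(seq, m, 1, 0)
  hit <- hit[hit$strand == "+", ]
  expect_identical(nrow(hit), 1L)
  expect_identical(hit$mismatches_35, 1L)
  # spacer off by one needs slack
  seq16 <- paste0("GGGGGGGG", m$box35, strrep("A", 16), m$box10,
                  "GGGGGGGG")
  expect_identical(nrow(scan_promoters(seq16, m, 0, 0)), 0L)
  expect_identical(
    scan_promoters(seq16, m, 0, 1)$spacer[1], 16L)
  expect_error(scan_promoters("ACGT", m), "shorter")
})

test_that("relaxing budgets never removes a promoter hit", {
  set.seed(33)
  for (i in 1:5) {
    seq <- rand_dna(400)
    strict <- scan_promoters(seq, models$core_A, 1, 1)
    loose <- scan_promoters(seq, models$core_A, 2, 2)
    if (nrow(strict)) {
      key <- function(h) paste(h$start, h$end, h$strand)
      expect_true(all(key(strict) %in% key(loose)))
    } else succeed()
  }
})

test_that("promoter scanning is strand-symmetric", {
  set.seed(8)
  m <- models$F_type
  site <- paste0(m$box35, rand_dna(m$spacer), m$box10)
  seq <- paste0(rand_dna(30), site, rand_dna(50))
  rc <- paste(rev(COMP[strsplit(seq, "")[[1]]]), collapse = "")
  fwd <- scan_promoters(seq, m, 0, 0)
  rev_ <- scan_promoters(rc, m, 0, 0)
  n <- nchar(seq)
  expect_identical(nrow(fwd), nrow(rev_))
  expect_setequal(paste(n - fwd$end + 1, n - fwd$start + 1,
                        ifelse(fwd$strand == "+", "-", "+")),
                  paste(rev_$start, rev_$end, rev_$strand))
})

test_that("TCT-N8-TCT repeats are found, including overlapping copies", {
  hit <- find_direct_repeats("GGTCTAACCAAGGTCTGG")
  expect_identical(hit$pos1, 3L)
  expect_identical(hit$pos2, 14L)
  expect_identical(nrow(find_direct_repeats("ACGTACGTACGT")), 0L)
  # only the second/third TCT pair is spaced by exactly 8
  tri <- find_direct_repeats("TCTTCTNNNNNNNNTCT")
  expect_identical(nrow(tri), 1L)
  expect_identical(tri$pos1, 4L)
  expect_identical(tri$pos2, 15L)
})

test_that("hairpin energies equal hand sums over the shipped tables", {
  stacks <- read.delim(system.file("extdata", "stack_energies.tsv",
                                   package = "lantivar"),
                       comment.char = "#")
  loops <- read.delim(system.file("extdata", "loop_penalties.tsv",
                                  package = "lantivar"),
                      comment.char = "#")
  lookup <- setNames(stacks$delta_g, stacks$stack)
  loop4 <- loops$delta_g[loops$loop_length == 4]
  # 8 consecutive G:C pairs, loop 4
  gc8 <- data.frame(left = rep("G", 8), right = rep("C", 8))
  expect_equal(hairpin_delta_g(gc8, 4), 7 * lookup[["GG"]] + loop4)
  # 2 A:T pairs, loop 3: weak
  at2 <- data.frame(left = c("A", "A"), right = c("T", "T"))
  expect_equal(hairpin_delta_g(at2, 3),
               lookup[["AA"]] + loops$delta_g[loops$loop_length == 3])
  expect_gt(hairpin_delta_g(at2, 3), -5)
  # random mixed stems against an independent sum
  set.seed(13)
  for (i in 1:10) {
    k <- sample(2:10, 1)
    left <- sample(c("A", "C", "G", "T"), k, replace = TRUE)
    sp <- data.frame(left = left, right = COMP[left])
    loop_len <- sample(3:10, 1)
    hand <- sum(lookup[paste0(left[-k], left[-1])]) +
      loops$delta_g[loops$loop_length == loop_len]
    expect_equal(hairpin_delta_g(sp, loop_len), hand)
  }
})

test_that("hairpin energy rejects invalid stems and handles wobble", {
  expect_error(hairpin_delta_g(data.frame(left = "G", right = "C"), 4),
               "at least 2")
  expect_error(hairpin_delta_g(data.frame(left = c("G", "G"),
                                          right = c("C", "A")), 4),
               "non-complementary")
  gt <- data.frame(left = c("G", "G"), right = c("C", "T"))
  expect_error(hairpin_delta_g(gt, 4), "non-complementary")
  # one wobble-containing stack (-1.0) plus the loop-4 penalty (5.6)
  expect_equal(hairpin_delta_g(gt, 4, allow_gu = TRUE), 4.6)
  expect_error(hairpin_delta_g(data.frame(left = c("G", "G"),
                                          right = c("C", "C")), 2),
               "loop_length")
})

test_that("a designed strong hairpin is reported as strong and a
           boundary hairpin is excluded", {
  set.seed(17)
  strong <- paste0(rand_dna(30), "C", strrep("G", 8), "AACA",
                   strrep("C", 8), strrep("T", 8), rand_dna(30))
  hits <- find_terminators(strong)
  expect_identical(nrow(hits), 1L)
  expect_identical(hits$strength, "strong")
  expect_lt(hits$delta_g, -10)
  expect_identical(nrow(find_terminators(strrep("A", 300))), 0L)
  # no U-tract, no call
  no_tail <- paste0(rand_dna(30), "C", strrep("G", 8), "AACA",
                    strrep("C", 8), strrep("G", 8), rand_dna(20))
  expect_identical(nrow(find_terminators(no_tail)), 0L)
})

test_that("terminator scanning equals the brute-force enumerator", {
  set.seed(29)
  n_checked <- 0L
  for (i in 1:12) {
    seq <- if (i <= 4) rand_dna(150) else {
      cls <- c("strong", "candidate", "sub")[(i %% 3) + 1]
      make_regulatory_sequence(180, hairpin = cls, with_repeat = FALSE,
                               seed = 1000 + i)$seq
    }
    got <- find_terminators(seq)
    want <- oracle_terminators(seq)
    expect_identical(nrow(got), nrow(want))
    if (nrow(got)) {
      expect_identical(got$start, want$start)
      expect_identical(got$end, want$end)
      expect_equal(got$delta_g, want$delta_g)
      n_checked <- n_checked + nrow(got)
    }
  }
  expect_gt(n_checked, 0L)
})

test_that("reported terminators satisfy their own invariants", {
  set.seed(31)
  for (i in 1:6) {
    seq <- make_regulatory_sequence(
      200, hairpin = sample(c("strong", "candidate"), 1),
      with_repeat = FALSE, seed = 5000 + i)$seq
    hits <- find_terminators(seq)
    expect_true(all(hits$delta_g < -5.0))
    expect_identical(hits$strength, ifelse(hits$delta_g < -10.0,
                                           "strong", "candidate"))
    # relaxing the threshold never removes hits
    loose <- find_terminators(seq, dg_threshold = -3.0)
    expect_true(all(paste(hits$start, hits$end) %in%
                      paste(loose$start, loose$end)))
  }
})

test_that("BED export uses 0-based starts and sensible scores", {
  seq <- paste0(rand_dna(20), "C", strrep("G", 8), "AACA",
                strrep("C", 8), strrep("T", 8), rand_dna(10))
  hits <- find_terminators(seq)
  path <- withr::local_tempfile(fileext = ".bed")
  write_hits_bed(hits, path)
  bed <- read.delim(path, header = FALSE)
  expect_identical(bed$V2, hits$start - 1L)
  expect_identical(bed$V3, hits$end)
  expect_equal(bed$V5, -hits$delta_g)
})
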