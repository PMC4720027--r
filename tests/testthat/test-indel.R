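test_that("a perfect read aligns gap-free at full score", {
  ref <- "ACGTACGGTTAGCATCGATTACG"
  aln <- align_reads(ref, ref)
  expect_equal(aln$score, 2 * nchar(ref))
  expect_equal(nrow(aln$events[[1]]), 0L)
  expect_equal(aln$ref_start, 0L)
})

test_that("a clean internal deletion yields one deletion event", {
  ref <- "ACGTACGGTTAGCATCGATTACGGATCCA"
  read <- paste0(substr(ref, 1, 12), substr(ref, 16, nchar(ref)))
  aln <- align_reads(read, ref)
  ev <- aln$events[[1]]
  ev <- ev[ev$type == "del", ]
  expect_equal(nrow(ev), 1L)
  expect_equal(ev$length, 3L)
  expect_equal(sum(aln$events[[1]]$type == "ins"), 0L)
})

test_that("alignment scores equal the exhaustive Gotoh oracle", {
  set.seed(40)
  for (i in 1:60) {
    read <- random_dna(sample(3:12, 1))
    ref <- random_dna(sample(3:12, 1))
    got <- align_reads(read, ref)$score
    want <- oracle_align_score(read, ref)
    expect_equal(got, want, info = paste(read, ref))
  }
})

test_that("empty inputs are rejected", {
  expect_error(align_reads("", "ACGT"), "nonempty")
  expect_error(align_reads(character(0), "ACGT"), "nonempty")
})

test_that("indel calls classify frame from net length in the window", {
  ref <- toy_amplicon()
  cut <- ref$guides$cut_site[[1]]
  n <- nchar(ref$sequence)
  wt_read <- ref$sequence
  del3 <- paste0(substr(ref$sequence, 1, cut - 1),
                 substr(ref$sequence, cut + 3, n))
  del76 <- paste0(substr(ref$sequence, 1, cut - 38),
                  substr(ref$sequence, cut + 39, n))
  aln <- align_reads(c(wt_read, del3, del76), ref)
  calls <- call_indels(aln, ref)
  expect_equal(calls$classification, c("WT", "indel", "indel"))
  expect_equal(calls$frame, c(NA, "in_frame", "frameshift"))
  expect_equal(calls$net_length, c(0L, -3L, -76L))
})

test_that("substitutions never trigger the indel classification", {
  ref <- toy_amplicon()
  cut <- ref$guides$cut_site[[1]]
  mut <- ref$sequence
  substr(mut, cut, cut) <- setdiff(c("A", "C", "G", "T"),
                                   substr(ref$sequence, cut, cut))[1]
  calls <- call_indels(align_reads(mut, ref), ref)
  expect_equal(calls$classification, "WT")
})

test_that("indels outside the cut-site window do not count", {
  ref <- toy_amplicon()   # cut at 100, 200 bp
  # deletion at positions 21-23 (0-based 20..22), window is [50, 150)
  read <- paste0(substr(ref$sequence, 1, 20), substr(ref$sequence, 24, 200))
  calls <- call_indels(align_reads(read, ref), ref)
  expect_equal(calls$classification, "WT")
  calls_wide <- call_indels(align_reads(read, ref), ref, window_nt = 190)
  expect_equal(calls_wide$classification, "indel")
  expect_error(call_indels(align_reads(read, ref), 500L, ref_length = 200L),
               "window")
})

test_that("summaries partition reads and recover simulated fractions", {
  ref <- toy_amplicon()
  set.seed(41)
  sim <- simulate_amplicon_reads(ref, read_sim_config(n_reads = 600,
                                                      edit_fraction = 0.5))
  calls <- call_indels(align_reads(sim$reads, ref), ref)
  s <- summarize_edits(calls)
  expect_equal(s$frac_wt + s$frac_indel, 1)
  expect_lte(s$frac_inframe, s$frac_indel)
  k <- round(s$frac_indel * 600)
  expect_true(k >= qbinom(0.005, 600, 0.5) && k <= qbinom(0.995, 600, 0.5))
  # calls agree with per-read ground truth
  cm <- table(calls$classification, sim$truth$label != "WT")
  expect_equal(sum(calls$classification == "indel" & sim$truth$label == "WT"),
               0L)
  expect_error(summarize_edits(calls[0, ]), "empty")
})

test_that("per-base profile is all ones for clean wild-type reads", {
  ref <- toy_amplicon()
  reads <- rep(ref$sequence, 5)
  prof <- per_base_profile(align_reads(reads, ref), ref)
  expect_true(all(prof$match_freq == 1))
  expect_equal(sum(prof$masked), 40L)
})

test_that("a shared deletion zeroes exactly its positions", {
  ref <- toy_amplicon()
  p <- 120L  # 0-based deletion start, [120, 124)
  read <- paste0(substr(ref$sequence, 1, p), substr(ref$sequence, p + 5, 200))
  prof <- per_base_profile(align_reads(rep(read, 4), ref), ref)
  expect_true(all(prof$match_freq[prof$position %in% p:(p + 3)] == 0))
  expect_true(all(prof$match_freq[!prof$position %in% p:(p + 3)] == 1))
})

test_that("gel genotyping applies the band-presence rule", {
  des <- toy_designs()
  expect_equal(genotype_from_gel(1000, des)$call, "WT")
  expect_equal(genotype_from_gel(c(1000, 700), des)$call, "monoallelic")
  expect_equal(genotype_from_gel(c(700, 640), des)$call, "biallelic")
  expect_equal(genotype_from_gel(c(1000, 250), des)$call, "no_call")
  expect_warning(g <- genotype_from_gel(integer(0), des), "No bands")
  expect_equal(g$call, "no_call")
  # tolerance: within 10% of the predicted size by default
  expect_equal(genotype_from_gel(1060, des)$call, "WT")
  expect_equal(genotype_from_gel(1060, des, tol_bp = 20)$call, "no_call")
})

test_that("genotyping a simulated gel recovers every clone's genotype", {
  set.seed(42)
  des <- toy_designs()
  sim <- simulate_gel_table(150, c(WT = 0.2, monoallelic = 0.45,
                                   biallelic = 0.35), des)
  calls <- genotype_clones(sim$bands, des)
  joined <- dplyr::left_join(calls, sim$truth, by = "clone_id")
  expect_equal(joined$call, joined$genotype)
})

test_that("chance in-frame fraction enumerates the length distribution", {
  expect_equal(expected_inframe_fraction(1:30), 10 / 30)
  expect_equal(expected_inframe_fraction(3), 1)
  expect_equal(expected_inframe_fraction(1:31), 10 / 31)
  expect_equal(expected_inframe_fraction(c(2, 3), c(0.25, 0.75)), 0.75)
  expect_error(expected_inframe_fraction(integer(0)), "nonempty")
})
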