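test_that("homopolymer sequences with no PAM yield no candidates", {
  expect_equal(nrow(find_targets(strrep("A", 30))), 0L)
})

test_that("a lone 23-nt window ending in NGG gives one plus-strand hit", {
  seqchr <- paste0(strrep("AT", 10), "TGG")  # 23 nt, ends TGG, no CC
  tg <- find_targets(seqchr)
  expect_equal(nrow(tg), 1L)
  expect_equal(tg$strand, "+")
  expect_equal(tg$spacer, strrep("AT", 10))
  expect_equal(tg$pam, "TGG")
  expect_equal(tg$cut_site, 17L)  # bond between the 3rd and 4th nt from PAM
})

test_that("target scan matches the brute-force window oracle", {
  set.seed(20)
  for (len in c(23, 40, 80, 200)) {
    for (rep in 1:5) {
      seqchr <- random_dna(len)
      got <- find_targets(seqchr)
      want <- oracle_find_targets(seqchr)
      got <- got[order(got$cut_site, got$strand, got$spacer), ]
      want <- want[order(want$cut_site, want$strand, want$spacer), ]
      expect_equal(got$spacer, want$spacer)
      expect_equal(got$cut_site, want$cut_site)
      expect_equal(got$strand, want$strand)
    }
  }
})

test_that("candidate sets map one-to-one under reverse complement", {
  set.seed(21)
  for (rep in 1:5) {
    seqchr <- random_dna(120)
    rc <- chartr("ACGT", "TGCA",
                 paste(rev(strsplit(seqchr, "")[[1]]), collapse = ""))
    a <- find_targets(seqchr)
    b <- find_targets(rc)
    expect_equal(nrow(a), nrow(b))
    expect_equal(sort(a$spacer), sort(b$spacer))
    expect_equal(sum(a$strand == "+"), sum(b$strand == "-"))
  }
})

test_that("ambiguous bases skip overlapping candidates with a warning", {
  seqchr <- paste0(strrep("AT", 10), "TGG")
  substr(seqchr, 5, 5) <- "N"
  expect_warning(tg <- find_targets(seqchr), "ambiguous")
  expect_equal(nrow(tg), 0L)
})

test_that("forward primer assembly follows the G-prefix rule", {
  sc <- scaffold_template()
  t7 <- T7_MINIMAL
  sp_g <- "GACGTACGTTACGATCGATC"
  sp_a <- "AACGTACGTTACGATCGATC"
  expect_equal(nchar(assemble_forward_primer(sp_g, sc, t7)),
               nchar(t7) + 20L + nchar(sc$overlap_region))
  expect_equal(nchar(assemble_forward_primer(sp_a, sc, t7)),
               nchar(t7) + 21L + nchar(sc$overlap_region))
  expect_true(startsWith(assemble_forward_primer(sp_a, sc, t7),
                         paste0(t7, "G", sp_a)))
  expect_error(assemble_forward_primer("", sc, t7), "20 nt")
  expect_error(assemble_forward_primer("ACGTACGTACGTACGTACGX", sc, t7),
               "outside")
})

test_that("primer assembly is injective in the spacer", {
  set.seed(22)
  spacers <- unique(replicate(40, random_dna(20)))
  primers <- vapply(spacers, assemble_forward_primer, character(1))
  expect_equal(anyDuplicated(primers), 0L)
})

test_that("predicted sgRNA is RNA of spacer plus scaffold", {
  sc <- scaffold_template()
  sp1 <- "GACGTACGTTACGATCGATC"
  sp2 <- "GTTTACGGACGATCGATCAA"
  r1 <- predict_sgrna(sp1, sc)
  r2 <- predict_sgrna(sp2, sc)
  expect_false(grepl("T", r1))
  expect_true(grepl("^[ACGU]+$", r1))
  expect_equal(nchar(r1), 20L + sc$length_bp)
  expect_equal(nchar(predict_sgrna(paste0("A", substr(sp1, 2, 20)), sc)),
               21L + sc$length_bp)
  # products differ only in their 5' target-derived portion
  expect_equal(substr(r1, 21, nchar(r1)), substr(r2, 21, nchar(r2)))
  expect_false(substr(r1, 1, 20) == substr(r2, 1, 20))
})

test_that("96-well layout fills column-major with replicates and spillover", {
  p <- plate_layout_96(paste0("sg", 1:6), replicates = 4)
  expect_equal(nrow(p), 24L)
  expect_equal(p$well[1:9], c("A1", "B1", "C1", "D1", "E1", "F1", "G1", "H1",
                              "A2"))
  expect_equal(nrow(plate_layout_96(character(0))), 0L)
  spill <- plate_layout_96(paste0("d", 1:97))
  expect_equal(sum(spill$plate == 2L), 1L)
  expect_equal(spill$well[spill$plate == 2L], "A1")
})

test_that("paired deletions are cut-site arithmetic on the amplicon", {
  sg_a <- tibble::tibble(cut_site = 100L)
  sg_b <- tibble::tibble(cut_site = 400L)
  d <- predict_pair_deletion(sg_a, sg_b, wt_amplicon_bp = 1000L)
  expect_equal(d$expected_deletion_bp, 300L)
  expect_equal(d$edited_amplicon_bp, 700L)
  expect_error(predict_pair_deletion(sg_a, sg_a, wt_amplicon_bp = 1000L),
               "identical")
  expect_error(
    predict_pair_deletion(sg_a, tibble::tibble(cut_site = 1200L),
                          wt_amplicon_bp = 1000L),
    "inside")
  # three guides give three distinct pairwise deletions
  cuts <- c(100L, 400L, 650L)
  dels <- utils::combn(cuts, 2, function(p) {
    predict_pair_deletion(tibble::tibble(cut_site = p[1]),
                          tibble::tibble(cut_site = p[2]),
                          wt_amplicon_bp = 1000L)$expected_deletion_bp
  })
  expect_equal(length(unique(dels)), 3L)
})

test_that("order sheets carry one assembled primer per well", {
  designs <- tibble::tibble(name = c("g1", "g2"),
                            spacer = c("GACGTACGTTACGATCGATC",
                                       "ATTTACGGACGATCGATCAA"))
  sheet <- order_sheet(designs, replicates = 2)
  expect_equal(nrow(sheet), 4L)
  expect_true(all(startsWith(sheet$primer, T7_MINIMAL)))
  expect_equal(dplyr::n_distinct(sheet$primer), 2L)
})
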