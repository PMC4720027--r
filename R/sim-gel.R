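#' Simulate a genotyping-gel band table for paired-guide deletions
#'
#' Clones screened by PCR across a paired-guide locus show a wild-type-length
#' band for unedited alleles and a shortened band for alleles carrying the
#' excision. Genotypes are drawn from `genotype_fractions`; per genotype the
#' bands are: WT — the full amplicon only; monoallelic — WT plus one deletion
#' product; biallelic — deletion products on both alleles (the two alleles
#' draw designs independently, so a homozygous clone shows a single shortened
#' band and a compound heterozygote shows two). Optional Gaussian sizing
#' noise emulates the semi-quantitative nature of agarose gels.
#'
#' @param n_clones Number of clones.
#' @param genotype_fractions Named numeric vector over
#'   `c("WT", "monoallelic", "biallelic")` (any subset), summing to 1.
#' @param designs Tibble of paired-deletion designs as returned by
#'   [predict_pair_deletion()] (one row per guide pair); required whenever a
#'   non-WT fraction is positive.
#' @param wt_amplicon_bp Wild-type amplicon size; defaults to
#'   `designs$wt_amplicon_bp[1]`.
#' @param size_noise_sd SD (bp) of Gaussian band-sizing noise (default 0).
#' @return A list with `bands` (tibble: `clone_id`, `band_bp`, one row per
#'   band) and `truth` (tibble: `clone_id`, `genotype`).
#' @examples
#' des <- tibble::tibble(expected_deletion_bp = c(300L, 360L),
#'                       wt_amplicon_bp = 1000L,
#'                       edited_amplicon_bp = c(700L, 640L))
#' simulate_gel_table(4, c(WT = 0.25, monoallelic = 0.5, biallelic = 0.25), des)
#' @export
simulate_gel_table <- function(n_clones, genotype_fractions, designs = NULL,
                               wt_amplicon_bp = NULL, size_noise_sd = 0) {
  assert_scalar_number(n_clones, "n_clones", min = 1)
  geno_levels <- c("WT", "monoallelic", "biallelic")
  stopifnot(is.numeric(genotype_fractions),
            all(names(genotype_fractions) %in% geno_levels))
  if (abs(sum(genotype_fractions) - 1) > 1e-6) {
    abort("`genotype_fractions` must sum to 1.")
  }
  p <- setNames(rep(0, 3), geno_levels)
  p[names(genotype_fractions)] <- genotype_fractions
  if (sum(p[c("monoallelic", "biallelic")]) > 0 &&
      (is.null(designs) || nrow(designs) == 0L)) {
    abort("Non-WT genotype fractions require at least one deletion design.")
  }
  if (is.null(wt_amplicon_bp)) {
    if (is.null(designs)) abort("Provide `wt_amplicon_bp` or `designs`.")
    wt_amplicon_bp <- designs$wt_amplicon_bp[[1]]
  }

  genotype <- sample(geno_levels, n_clones, replace = TRUE, prob = p)
  bands <- vector("list", n_clones)
  for (i in seq_len(n_clones)) {
    b <- switch(
      genotype[i],
      WT = wt_amplicon_bp,
      monoallelic = c(
        wt_amplicon_bp,
        designs$edited_amplicon_bp[sample.int(nrow(designs), 1L)]),
      biallelic = unique(
        designs$edited_amplicon_bp[sample.int(nrow(designs), 2L,
                                              replace = TRUE)])
    )
    if (size_noise_sd > 0) b <- round(b + rnorm(length(b), 0, size_noise_sd))
    bands[[i]] <- tibble(clone_id = sprintf("clone_%03d", i),
                         band_bp = as.integer(sort(unique(b))))
  }
  list(
    bands = dplyr::bind_rows(bands),
    truth = tibble(clone_id = sprintf("clone_%03d", seq_len(n_clones)),
                   genotype = genotype)
  )
}
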