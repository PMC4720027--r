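#' Conserved sgRNA scaffold template
#'
#' The double-stranded DNA template encoding the conserved (non-targeting)
#' region of the sgRNA, amplified together with the target-specific forward
#' primer during one-pot PCR/transcription. The default is a synthetic
#' stand-in: the canonical S. pyogenes sgRNA scaffold followed by a poly-T
#' terminator. Any template can be supplied (e.g. read from FASTA with
#' [Biostrings::readDNAStringSet()]) — the forward primer's 3' overlap must
#' be a prefix of it.
#'
#' @param sequence Template DNA (sense strand, 5'->3' in transcript
#'   orientation).
#' @param overlap_length Length of the forward-primer overlap region, taken
#'   as a prefix of `sequence` (default 15 nt).
#' @return An object of class `scaffold_template` with fields `sequence`,
#'   `overlap_region`, `length_bp`.
#' @export
scaffold_template <- function(
    sequence = paste0(
      "GTTTTAGAGCTAGAAATAGCAAGTTAAAATAAGGCTAGTCCGTTATCA",
      "ACTTGAAAAAGTGGCACCGAGTCGGTGCTTTTTTT"),
    overlap_length = 15L) {
  assert_dna(sequence)
  assert_scalar_number(overlap_length, "overlap_length", min = 1,
                       max = nchar(sequence))
  structure(
    list(
      sequence = sequence,
      overlap_region = substr(sequence, 1L, overlap_length),
      length_bp = nchar(sequence)
    ),
    class = "scaffold_template"
  )
}

#' Minimal T7 promoter used in one-pot forward primers
#'
#' The standard minimal bacteriophage T7 promoter including the +1 G at which
#' transcription initiates. Configurable wherever it is consumed.
#' @export
T7_MINIMAL <- "TAATACGACTCACTATAG"

#' Scan a sequence for Cas9 targets (NGG PAM)
#'
#' Enumerates every 23-nt window, on both strands, whose last three bases
#' match NGG: the first 20 nt are the spacer, the last 3 the PAM. Coordinates
#' are 0-based, half-open, and always reported on the + strand. The cut site
#' is the blunt double-strand break between the 3rd and 4th nucleotide
#' upstream of the PAM, encoded as the 0-based index of the base immediately
#' 3' of the cut (equivalently, the number of + strand bases to its left).
#'
#' Windows containing ambiguous bases (N etc.) are skipped with a warning.
#'
#' @param sequence DNA string (may contain N).
#' @return A tibble with one row per candidate: `spacer`, `pam`, `strand`
#'   (`"+"`/`"-"`), `pam_start` (0-based + strand start of the PAM trinucleotide
#'   for + candidates, of its reverse complement for - candidates), and
#'   `cut_site`.
#' @examples
#' find_targets("GACGTACGTTACGATCGATCCGGATATTTT")
#' @export
find_targets <- function(sequence) {
  assert_dna(sequence, allow_n = TRUE)
  n <- nchar(sequence)
  if (n < 23L) abort("`sequence` must be at least 23 nt long.")
  s <- strsplit(sequence, "")[[1]]
  skipped <- 0L
  rows <- list()

  # + strand: PAM at 0-based [p, p+3), spacer [p-20, p), cut between p-4, p-3
  p_all <- which(s == "G" & dplyr::lead(s) == "G") - 1L  # 1-based PAM start
  p_all <- p_all[p_all >= 21L & p_all + 2L <= n]
  for (p1 in p_all) {
    win <- substr(sequence, p1 - 20L, p1 + 2L)
    if (grepl("N", win, fixed = TRUE)) { skipped <- skipped + 1L; next }
    p0 <- p1 - 1L
    rows[[length(rows) + 1L]] <- tibble(
      spacer = substr(sequence, p1 - 20L, p1 - 1L),
      pam = substr(sequence, p1, p1 + 2L),
      strand = "+", pam_start = p0, cut_site = p0 - 3L
    )
  }

  # - strand: + sequence CCN at [q, q+3), protospacer [q+3, q+23),
  # cut between + positions q+5 and q+6
  q_all <- which(s == "C" & dplyr::lead(s) == "C")       # 1-based CC start
  q_all <- q_all[!is.na(q_all) & q_all + 22L <= n]
  for (q1 in q_all) {
    win <- substr(sequence, q1, q1 + 22L)
    if (grepl("N", win, fixed = TRUE)) { skipped <- skipped + 1L; next }
    q0 <- q1 - 1L
    rows[[length(rows) + 1L]] <- tibble(
      spacer = revcomp(substr(sequence, q1 + 3L, q1 + 22L)),
      pam = revcomp(substr(sequence, q1, q1 + 2L)),
      strand = "-", pam_start = q0, cut_site = q0 + 6L
    )
  }

  if (skipped > 0L) {
    warn(sprintf("Skipped %d candidate window(s) overlapping ambiguous bases.",
                 skipped))
  }
  if (length(rows) == 0L) {
    return(tibble(spacer = character(), pam = character(), strand = character(),
                  pam_start = integer(), cut_site = integer()))
  }
  dplyr::arrange(dplyr::bind_rows(rows), .data$cut_site, .data$strand)
}

g_prefix <- function(spacer) {
  if (substr(spacer, 1L, 1L) == "G") spacer else paste0("G", spacer)
}

#' Assemble the one-pot forward primer
#'
#' The forward primer is the only target-specific oligo in one-pot sgRNA
#' production: minimal T7 promoter, then the spacer (prefixed with G when it
#' does not already start with one, as T7 initiation requires a 5' G), then
#' the overlap region annealing to the conserved scaffold template.
#'
#' @param spacer 20-nt DNA spacer.
#' @param scaffold A [scaffold_template()].
#' @param t7_min Minimal T7 promoter sequence (default [T7_MINIMAL]).
#' @return The forward primer as a DNA string.
#' @examples
#' assemble_forward_primer("GACGTACGTTACGATCGATC")
#' @export
assemble_forward_primer <- function(spacer, scaffold = scaffold_template(),
                                    t7_min = T7_MINIMAL) {
  assert_dna(spacer)
  assert_dna(t7_min, "t7_min")
  stopifnot(inherits(scaffold, "scaffold_template"))
  if (nchar(spacer) != 20L) {
    abort("`spacer` must be exactly 20 nt.")
  }
  paste0(t7_min, g_prefix(spacer), scaffold$overlap_region)
}

#' Predict the one-pot transcribed sgRNA product
#'
#' The T7 transcript is the (G-prefixed) spacer followed by the conserved
#' scaffold, as RNA. One-pot transcription yields this single product.
#'
#' @param spacer 20-nt DNA spacer (or a one-row design tibble from
#'   [find_targets()], whose `spacer` column is used).
#' @param scaffold A [scaffold_template()].
#' @return The predicted sgRNA as an RNA string.
#' @export
predict_sgrna <- function(spacer, scaffold = scaffold_template()) {
  if (is.data.frame(spacer)) {
    stopifnot(nrow(spacer) == 1L, "spacer" %in% names(spacer))
    spacer <- spacer$spacer
  }
  assert_dna(spacer)
  if (nchar(spacer) != 20L) abort("`spacer` must be exactly 20 nt.")
  stopifnot(inherits(scaffold, "scaffold_template"))
  dna <- paste0(g_prefix(spacer), scaffold$sequence)
  chartr("T", "U", dna)
}

#' Lay designs out on 96-well order plates
#'
#' Fills wells column-major (A1, B1, ..., H1, A2, ...), expanding each design
#' into `replicates` adjacent wells, spilling onto further plates past 96
#' wells. Deterministic given the input order.
#'
#' @param designs A data frame of designs with at least a `name` column
#'   (other columns are carried along), or a character vector of names.
#' @param replicates Number of replicate wells per design (default 1).
#' @return A tibble with columns `plate`, `well`, `replicate`, and the design
#'   columns; zero rows for empty input.
#' @examples
#' plate_layout_96(paste0("sg", 1:6), replicates = 4)
#' @export
plate_layout_96 <- function(designs, replicates = 1L) {
  assert_scalar_number(replicates, "replicates", min = 1)
  if (is.character(designs)) designs <- tibble(name = designs)
  stopifnot(is.data.frame(designs))
  if (nrow(designs) == 0L) {
    return(tibble(plate = integer(), well = character(), replicate = integer()))
  }
  expanded <- tidyr::uncount(as_tibble(designs), as.integer(replicates),
                             .id = "replicate")
  idx <- seq_len(nrow(expanded)) - 1L
  wells <- paste0(LETTERS[idx %% 8L + 1L], idx %/% 8L %% 12L + 1L)
  dplyr::bind_cols(
    tibble(plate = as.integer(idx %/% 96L + 1L), well = wells),
    expanded
  )
}

#' Predict the deletion made by a pair of sgRNAs
#'
#' Two guides cutting the same locus excise the intervening segment when both
#' breaks are repaired by end joining; the expected deletion is the distance
#' between the two blunt cut sites, and the diagnostic genotyping amplicon
#' shrinks by exactly that amount.
#'
#' Supply either `wt_amplicon_bp` directly (cut sites then in amplicon
#' coordinates), or `reference` plus `genotyping_primers`, in which case the
#' amplicon is located by exact primer match (forward primer on +, reverse
#' primer as given 5'->3' on the - strand) and cut sites are in reference
#' coordinates.
#'
#' @param sg_a,sg_b One-row design tibbles (as returned by [find_targets()])
#'   with distinct `cut_site` values.
#' @param wt_amplicon_bp Length of the wild-type genotyping amplicon.
#' @param reference Optional reference DNA string containing the amplicon.
#' @param genotyping_primers Optional character vector of length 2,
#'   `c(forward, reverse)`.
#' @return A one-row tibble: `cut_a`, `cut_b`, `expected_deletion_bp`,
#'   `wt_amplicon_bp`, `edited_amplicon_bp`.
#' @examples
#' sgs <- find_targets(paste(rep("GACGTACGTTACGATCGATCCGGAT", 8), collapse = ""))
#' predict_pair_deletion(sgs[1, ], sgs[3, ], wt_amplicon_bp = 1000)
#' @export
predict_pair_deletion <- function(sg_a, sg_b, wt_amplicon_bp = NULL,
                                  reference = NULL, genotyping_primers = NULL) {
  stopifnot(is.data.frame(sg_a), is.data.frame(sg_b),
            nrow(sg_a) == 1L, nrow(sg_b) == 1L)
  cut_a <- sg_a$cut_site
  cut_b <- sg_b$cut_site
  if (cut_a == cut_b) abort("The two guides have identical cut sites.")

  amp_start <- 0L
  if (!is.null(reference) && !is.null(genotyping_primers)) {
    assert_dna(reference, "reference")
    fwd <- genotyping_primers[[1]]
    rev <- genotyping_primers[[2]]
    i <- regexpr(fwd, reference, fixed = TRUE)
    j <- regexpr(revcomp(rev), reference, fixed = TRUE)
    if (i < 0L || j < 0L) abort("Genotyping primers not found in reference.")
    amp_start <- as.integer(i) - 1L
    amp_end <- as.integer(j) - 1L + nchar(rev)   # 0-based half-open
    wt_amplicon_bp <- amp_end - amp_start
  } else if (is.null(wt_amplicon_bp)) {
    abort("Provide `wt_amplicon_bp`, or `reference` with `genotyping_primers`.")
  }
  lo <- amp_start
  hi <- amp_start + wt_amplicon_bp
  if (any(c(cut_a, cut_b) <= lo) || any(c(cut_a, cut_b) >= hi)) {
    abort("Both cut sites must lie strictly inside the genotyping amplicon.")
  }
  del <- abs(cut_b - cut_a)
  tibble(
    cut_a = cut_a, cut_b = cut_b,
    expected_deletion_bp = del,
    wt_amplicon_bp = as.integer(wt_amplicon_bp),
    edited_amplicon_bp = as.integer(wt_amplicon_bp) - del
  )
}

#' Write a primer order sheet
#'
#' Combines [plate_layout_96()] with [assemble_forward_primer()] to produce
#' the CSV an oligo vendor consumes: one row per well with the assembled
#' forward primer.
#'
#' @param designs Design tibble with `name` and `spacer` columns.
#' @param path Output CSV path (optional; the tibble is returned either way).
#' @inheritParams assemble_forward_primer
#' @inheritParams plate_layout_96
#' @return A tibble `plate`, `well`, `name`, `primer`.
#' @export
order_sheet <- function(designs, path = NULL, replicates = 1L,
                        scaffold = scaffold_template(), t7_min = T7_MINIMAL) {
  stopifnot(is.data.frame(designs), all(c("name", "spacer") %in% names(designs)))
  laid <- plate_layout_96(designs, replicates = replicates)
  out <- laid |>
    dplyr::mutate(primer = purrr::map_chr(
      .data$spacer, assemble_forward_primer,
      scaffold = scaffold, t7_min = t7_min)) |>
    dplyr::select("plate", "well", "name", "primer")
  if (!is.null(path)) readr::write_csv(out, path)
  out
}
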