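#' Amplicon reference for indel quantification
#'
#' Bundles the amplicon sequence, the guide design(s) targeting it, and the
#' PCR primer lengths. Primer regions at either end are masked in per-base
#' profiles because every read carries the primer sequence verbatim.
#'
#' @param name Amplicon name.
#' @param sequence Uppercase ACGT amplicon sequence.
#' @param guides Design tibble (from [find_targets()] or built by hand) with
#'   at least a `cut_site` column; cut sites must lie between the primers.
#' @param primer_lengths Integer vector `c(left, right)` of PCR primer
#'   lengths (default `c(20, 20)`).
#' @return An object of class `amplicon_reference`.
#' @export
amplicon_reference <- function(name, sequence, guides,
                               primer_lengths = c(20L, 20L)) {
  assert_dna(sequence)
  if (sequence != toupper(sequence)) abort("`sequence` must be uppercase.")
  stopifnot(is.data.frame(guides), "cut_site" %in% names(guides),
            length(primer_lengths) == 2L)
  n <- nchar(sequence)
  lo <- primer_lengths[[1]]
  hi <- n - primer_lengths[[2]]
  if (any(guides$cut_site < lo) || any(guides$cut_site >= hi)) {
    abort("Every cut_site must lie within [left primer end, length - right primer).")
  }
  structure(
    list(name = name, sequence = sequence, guides = as_tibble(guides),
         primer_lengths = as.integer(primer_lengths)),
    class = "amplicon_reference"
  )
}

#' @export
print.amplicon_reference <- function(x, ...) {
  cat(sprintf("<amplicon_reference> %s: %d bp, %d guide(s), cut site(s) %s\n",
              x$name, nchar(x$sequence), nrow(x$guides),
              paste(x$guides$cut_site, collapse = ", ")))
  invisible(x)
}

#' Configuration for the amplicon read simulator
#'
#' Indels are centred on the blunt Cas9 cut site with signed Gaussian
#' positional jitter. Among edited reads, a fraction
#' `p_deletion_given_indel` carry a deletion and the rest an insertion
#' (default 0.85:0.15, the empirically observed NHEJ mixture); lengths are
#' drawn from `indel_length_dist` (default uniform on 1..30 nt, under which
#' a third of indels are in-frame by chance). Sequencing errors are
#' substitutions only by default so that every called indel is attributable
#' to an edit; `error_indels = TRUE` adds rare 1-nt indel errors for
#' robustness testing.
#'
#' @param n_reads Number of reads.
#' @param edit_fraction Fraction of reads carrying an indel, in `[0,1]`.
#' @param p_deletion_given_indel P(deletion | indel) (default 0.85).
#' @param indel_lengths Integer vector of possible indel lengths
#'   (default `1:30`).
#' @param indel_length_probs Probabilities for `indel_lengths` (default
#'   uniform).
#' @param cut_offset_from_pam Distance in nt from the PAM to the cut bond
#'   (default 3; informational — cut sites come from the guide design).
#' @param positional_jitter_sd SD (nt) of the signed Gaussian jitter applied
#'   to the indel centre (default 1).
#' @param seq_error_rate Per-base substitution error rate (default 0.001).
#' @param error_indels Also simulate rare 1-nt sequencing indel errors at
#'   `seq_error_rate / 10` per base (default `FALSE`).
#' @param read_length Read length; `NULL` (default) means reads span the
#'   full amplicon.
#' @return An object of class `read_sim_config`.
#' @export
read_sim_config <- function(n_reads = 10000L, edit_fraction = 0.5,
                            p_deletion_given_indel = 0.85,
                            indel_lengths = 1:30,
                            indel_length_probs = NULL,
                            cut_offset_from_pam = 3L,
                            positional_jitter_sd = 1,
                            seq_error_rate = 0.001,
                            error_indels = FALSE,
                            read_length = NULL) {
  assert_scalar_number(n_reads, "n_reads", min = 1)
  assert_scalar_number(edit_fraction, "edit_fraction", min = 0, max = 1)
  assert_scalar_number(p_deletion_given_indel, "p_deletion_given_indel",
                       min = 0, max = 1)
  stopifnot(is.numeric(indel_lengths), all(indel_lengths >= 1))
  if (is.null(indel_length_probs)) {
    indel_length_probs <- rep(1 / length(indel_lengths), length(indel_lengths))
  }
  stopifnot(length(indel_length_probs) == length(indel_lengths),
            abs(sum(indel_length_probs) - 1) < 1e-8)
  assert_scalar_number(positional_jitter_sd, "positional_jitter_sd", min = 0)
  assert_scalar_number(seq_error_rate, "seq_error_rate", min = 0, max = 1)
  structure(
    list(n_reads = as.integer(n_reads), edit_fraction = edit_fraction,
         p_deletion_given_indel = p_deletion_given_indel,
         indel_lengths = as.integer(indel_lengths),
         indel_length_probs = indel_length_probs,
         cut_offset_from_pam = as.integer(cut_offset_from_pam),
         positional_jitter_sd = positional_jitter_sd,
         seq_error_rate = seq_error_rate,
         error_indels = isTRUE(error_indels),
         read_length = read_length),
    class = "read_sim_config"
  )
}

# substitution errors: each selected base replaced by a different base
apply_substitutions <- function(seq, rate) {
  if (rate <= 0) return(seq)
  chars <- strsplit(seq, "")[[1]]
  hit <- which(runif(length(chars)) < rate)
  if (length(hit) == 0L) return(seq)
  bases <- c("A", "C", "G", "T")
  for (i in hit) {
    chars[i] <- sample(setdiff(bases, chars[i]), 1L)
  }
  paste(chars, collapse = "")
}

#' Simulate amplicon sequencing reads over a Cas9 cut site
#'
#' Each read is the amplicon with, for a Bernoulli(`edit_fraction`) subset,
#' one deletion or insertion whose centre is the guide's blunt cut site plus
#' signed Gaussian jitter. Ground-truth labels accompany every read; the
#' quantification operations never see them.
#'
#' @param ref An [amplicon_reference()] (its first guide's `cut_site` is
#'   used).
#' @param config A [read_sim_config()].
#' @return A list with `reads` (tibble: `read_id`, `sequence`) and `truth`
#'   (tibble: `read_id`, `label` in WT/deletion/insertion, `indel_length`,
#'   `indel_pos` — 0-based reference start of the deleted block, or the
#'   insertion bond).
#' @examples
#' ref <- amplicon_reference(
#'   "toy", paste(rep("ACGTACGGTTAGCATCGA", 10), collapse = ""),
#'   guides = tibble::tibble(cut_site = 90L))
#' sim <- simulate_amplicon_reads(ref, read_sim_config(n_reads = 5))
#' sim$truth
#' @export
simulate_amplicon_reads <- function(ref, config = read_sim_config()) {
  stopifnot(inherits(ref, "amplicon_reference"),
            inherits(config, "read_sim_config"))
  seq <- ref$sequence
  n <- nchar(seq)
  cut <- ref$guides$cut_site[[1]]
  if (cut <= 0L || cut >= n) abort("Cut site outside the reference.")
  read_len <- config$read_length
  if (!is.null(read_len)) {
    if (read_len > n) abort("`read_length` exceeds the reference length.")
    if (cut >= read_len) abort("Cut site must lie strictly inside the read window.")
  }

  n_reads <- config$n_reads
  edited <- runif(n_reads) < config$edit_fraction
  is_del <- edited & (runif(n_reads) < config$p_deletion_given_indel)
  lens <- config$indel_lengths[sample.int(length(config$indel_lengths),
                                          n_reads, replace = TRUE,
                                          prob = config$indel_length_probs)]
  jitter <- round(rnorm(n_reads, 0, config$positional_jitter_sd))

  seqs <- character(n_reads)
  label <- character(n_reads)
  indel_length <- rep(NA_integer_, n_reads)
  indel_pos <- rep(NA_integer_, n_reads)
  bases <- c("A", "C", "G", "T")

  for (i in seq_len(n_reads)) {
    if (!edited[i]) {
      seqs[i] <- seq
      label[i] <- "WT"
    } else if (is_del[i]) {
      l <- lens[i]
      # deletion block spans the (jittered) cut bond
      start <- cut + jitter[i] - l %/% 2L           # 0-based start
      start <- min(max(start, 1L), n - l - 1L)
      seqs[i] <- paste0(substr(seq, 1L, start), substr(seq, start + l + 1L, n))
      label[i] <- "deletion"
      indel_length[i] <- l
      indel_pos[i] <- start
    } else {
      l <- lens[i]
      at <- cut + jitter[i]                          # insertion bond
      at <- min(max(at, 1L), n - 1L)
      ins <- paste(sample(bases, l, replace = TRUE), collapse = "")
      seqs[i] <- paste0(substr(seq, 1L, at), ins, substr(seq, at + 1L, n))
      label[i] <- "insertion"
      indel_length[i] <- l
      indel_pos[i] <- at
    }
    if (config$seq_error_rate > 0) {
      seqs[i] <- apply_substitutions(seqs[i], config$seq_error_rate)
    }
    if (config$error_indels) {
      seqs[i] <- apply_error_indels(seqs[i], config$seq_error_rate / 10)
    }
    if (!is.null(read_len)) {
      seqs[i] <- substr(seqs[i], 1L, read_len)
    }
  }

  list(
    reads = tibble(read_id = sprintf("read_%05d", seq_len(n_reads)),
                   sequence = seqs),
    truth = tibble(read_id = sprintf("read_%05d", seq_len(n_reads)),
                   label = label, indel_length = indel_length,
                   indel_pos = indel_pos)
  )
}

# rare 1-nt sequencing indel errors (robustness testing only)
apply_error_indels <- function(seq, rate) {
  chars <- strsplit(seq, "")[[1]]
  keep <- runif(length(chars)) >= rate
  chars <- chars[keep]
  ins_at <- which(runif(length(chars)) < rate)
  for (i in rev(ins_at)) {
    chars <- append(chars, sample(c("A", "C", "G", "T"), 1L), after = i)
  }
  paste(chars, collapse = "")
}

#' Read and write FASTQ / FASTA for amplicon reads
#'
#' Thin wrappers over Biostrings. Written FASTQ uses Phred+33 with a constant
#' quality (the simulator does not model quality decay).
#'
#' @param reads Tibble with `read_id` and `sequence` columns.
#' @param path File path.
#' @param quality_char Constant per-base quality character (default `"F"`,
#'   Q37).
#' @return `write_fastq()`/`write_fasta()` return `path` invisibly;
#'   `read_fastq()` returns a `reads` tibble.
#' @export
write_fastq <- function(reads, path, quality_char = "F") {
  sset <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  qual <- Biostrings::BStringSet(strrep(quality_char, nchar(reads$sequence)))
  qsset <- Biostrings::QualityScaledDNAStringSet(
    sset, Biostrings::PhredQuality(qual))
  Biostrings::writeQualityScaledXStringSet(qsset, path)
  invisible(path)
}

#' @rdname write_fastq
#' @export
read_fastq <- function(path) {
  sset <- Biostrings::readDNAStringSet(path, format = "fastq")
  tibble(read_id = names(sset), sequence = unname(as.character(sset)))
}

#' @rdname write_fastq
#' @export
write_fasta <- function(reads, path) {
  sset <- Biostrings::DNAStringSet(setNames(reads$sequence, reads$read_id))
  Biostrings::writeXStringSet(sset, path)
  invisible(path)
}
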