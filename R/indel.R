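#' Align amplicon reads to a reference
#'
#' Optimal semi-global pairwise alignment: the read aligns end-to-end while
#' the reference contributes free end gaps, which suits amplicon reads that
#' may be truncated relative to the reference. Scoring is affine
#' (match +2, mismatch -4, gap open -8, gap extend -1; a gap of length L
#' costs open + L * extend). Alignment is computed with
#' [Biostrings::pairwiseAlignment()]; indel events are extracted in 0-based
#' reference coordinates, left-aligned within repeats by the aligner's
#' deterministic tie-breaking.
#'
#' @param reads Character vector of read sequences, or a `reads` tibble with
#'   `read_id` and `sequence` columns (e.g. from
#'   [simulate_amplicon_reads()] or [read_fastq()]).
#' @param ref Reference DNA string or an [amplicon_reference()].
#' @param match,mismatch,gap_open,gap_extend Scoring parameters.
#' @return A tibble with one row per read: `read_id`, `score`,
#'   `ref_start` (0-based start of the aligned reference span),
#'   `aligned_read`, `aligned_ref` (equal-length gapped strings), and an
#'   `events` list column of tibbles (`type` in ins/del/sub, `ref_pos`
#'   0-based, `length`).
#' @examples
#' align_reads("ACGTAGTT", "ACGTACGTT")
#' @export
align_reads <- function(reads, ref, match = 2, mismatch = -4,
                        gap_open = -8, gap_extend = -1) {
  if (inherits(ref, "amplicon_reference")) ref <- ref$sequence
  assert_dna(ref, "ref", allow_n = TRUE)
  if (is.data.frame(reads)) {
    ids <- reads$read_id
    seqs <- reads$sequence
  } else {
    seqs <- reads
    ids <- sprintf("read_%05d", seq_along(seqs))
  }
  if (length(seqs) == 0L || any(!nzchar(seqs)) || !nzchar(ref)) {
    abort("Reads and reference must be nonempty sequences.")
  }

  mat <- Biostrings::nucleotideSubstitutionMatrix(
    match = match, mismatch = mismatch, baseOnly = FALSE)
  aln <- Biostrings::pairwiseAlignment(
    Biostrings::DNAStringSet(seqs), Biostrings::DNAString(ref),
    type = "global-local", substitutionMatrix = mat,
    gapOpening = -gap_open, gapExtension = -gap_extend)

  ap <- as.character(Biostrings::pattern(aln))
  ar <- as.character(Biostrings::subject(aln))
  ref_start <- Biostrings::start(Biostrings::subject(aln)) - 1L  # 0-based

  events <- purrr::pmap(list(ap, ar, ref_start), extract_events)
  tibble(read_id = ids, score = Biostrings::score(aln),
         ref_start = ref_start, aligned_read = unname(ap),
         aligned_ref = unname(ar), events = events)
}

# walk one gapped alignment and emit (type, ref_pos, length) events;
# ref_pos is the 0-based reference coordinate of the event start (for
# insertions, the bond before which the bases are inserted)
extract_events <- function(aligned_read, aligned_ref, ref_start) {
  rd <- strsplit(aligned_read, "")[[1]]
  rf <- strsplit(aligned_ref, "")[[1]]
  state <- dplyr::case_when(
    rf == "-" ~ "ins",
    rd == "-" ~ "del",
    rd != rf ~ "sub",
    .default = "m"
  )
  # reference position of each column (0-based; insertions take the bond)
  ref_pos <- ref_start + cumsum(rf != "-") - (rf != "-")
  r <- rle(state)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values != "m"
  if (!any(keep)) {
    return(tibble(type = character(), ref_pos = integer(), length = integer()))
  }
  tibble(
    type = r$values[keep],
    ref_pos = as.integer(ref_pos[starts[keep]]),
    length = as.integer(r$lengths[keep])
  )
}

#' Call indels in a window around the expected cut site
#'
#' A read is classified `indel` when any insertion or deletion event in its
#' alignment intersects the window around the Cas9 cut site (default a
#' 100-nt window, i.e. +/-50 nt, half-open); substitutions never trigger the
#' indel classification. The net length is the signed sum over counted
#' events (insertions positive, deletions negative) and the reading frame is
#' `in_frame` when the net length is divisible by 3, else `frameshift`
#' (`NA` for WT reads).
#'
#' @param alignments Tibble from [align_reads()].
#' @param ref An [amplicon_reference()] (its first guide's cut site is used)
#'   or an integer cut-site coordinate, in which case `ref_length` must be
#'   supplied.
#' @param window_nt Total window width in nt (default 100).
#' @param ref_length Reference length (taken from `ref` when it is an
#'   `amplicon_reference`).
#' @return A tibble with one row per read: `read_id`, `classification`
#'   (WT/indel), `frame` (in_frame/frameshift/NA), `net_length`,
#'   `n_events_in_window`.
#' @export
call_indels <- function(alignments, ref, window_nt = 100L, ref_length = NULL) {
  if (inherits(ref, "amplicon_reference")) {
    cut <- ref$guides$cut_site[[1]]
    ref_length <- nchar(ref$sequence)
  } else {
    cut <- as.integer(ref)
    if (is.null(ref_length)) abort("`ref_length` is required with a bare cut site.")
  }
  half <- window_nt / 2
  lo <- cut - half
  hi <- cut + half          # half-open [lo, hi)
  if (hi <= 0 || lo >= ref_length) {
    abort("The cut-site window lies outside the reference.")
  }

  calls <- purrr::map(alignments$events, function(ev) {
    if (nrow(ev) == 0L) {
      return(list(cls = "WT", net = 0L, n = 0L))
    }
    indel <- ev[ev$type != "sub", , drop = FALSE]
    if (nrow(indel) == 0L) {
      return(list(cls = "WT", net = 0L, n = 0L))
    }
    # event interval on the reference: deletions span length bases,
    # insertions sit on a bond (zero reference width)
    ev_lo <- indel$ref_pos
    ev_hi <- ifelse(indel$type == "del", indel$ref_pos + indel$length,
                    indel$ref_pos)
    in_win <- ev_hi > lo & ev_lo < hi | (indel$type == "ins" &
                                           ev_lo >= lo & ev_lo < hi)
    hit <- indel[in_win, , drop = FALSE]
    if (nrow(hit) == 0L) {
      return(list(cls = "WT", net = 0L, n = 0L))
    }
    net <- sum(ifelse(hit$type == "ins", hit$length, -hit$length))
    list(cls = "indel", net = as.integer(net), n = nrow(hit))
  })

  cls <- purrr::map_chr(calls, "cls")
  net <- purrr::map_int(calls, "net")
  tibble(
    read_id = alignments$read_id,
    classification = cls,
    frame = dplyr::case_when(
      cls == "WT" ~ NA_character_,
      net %% 3L == 0L ~ "in_frame",
      .default = "frameshift"
    ),
    net_length = net,
    n_events_in_window = purrr::map_int(calls, "n")
  )
}

#' Summarise indel calls over a read set
#'
#' Fractions partition the reads into wild type and indel-containing
#' (`frac_wt + frac_indel = 1`); the in-frame fraction counts indel reads
#' whose net length is divisible by 3. A read tallies as a deletion or
#' insertion read by the sign of its net length; indel reads with net length
#' zero are counted in `frac_indel` (in frame) but excluded from the
#' deletion/insertion tallies, with a note.
#'
#' @param calls Tibble from [call_indels()].
#' @return A one-row tibble: `n_reads`, `frac_wt`, `frac_indel`,
#'   `frac_inframe`, `n_deletion_reads`, `n_insertion_reads`,
#'   `del_ins_ratio`, `pct_deletion_of_indel`.
#' @export
summarize_edits <- function(calls) {
  if (nrow(calls) == 0L) abort("`calls` is empty.")
  n <- nrow(calls)
  is_indel <- calls$classification == "indel"
  n_del <- sum(is_indel & calls$net_length < 0L)
  n_ins <- sum(is_indel & calls$net_length > 0L)
  n_net0 <- sum(is_indel & calls$net_length == 0L)
  if (n_net0 > 0L) {
    inform(sprintf(
      "%d indel read(s) with net length 0 excluded from del/ins tallies.",
      n_net0))
  }
  tibble(
    n_reads = n,
    frac_wt = mean(!is_indel),
    frac_indel = mean(is_indel),
    frac_inframe = mean(is_indel & calls$frame == "in_frame", na.rm = FALSE),
    n_deletion_reads = n_del,
    n_insertion_reads = n_ins,
    del_ins_ratio = if (n_ins > 0L) n_del / n_ins else Inf,
    pct_deletion_of_indel = if (n_del + n_ins > 0L) {
      100 * n_del / (n_del + n_ins)
    } else {
      NA_real_
    }
  )
}

#' Per-base frequency of matches to the wild-type sequence
#'
#' For every reference position, the fraction of covering reads whose
#' aligned base matches the reference (a gap or substitution is a
#' non-match). The first and last `primer_lengths` positions are flagged as
#' masked: reads carry the PCR primer sequence there regardless of the
#' underlying genotype, so those positions are uninformative.
#'
#' @param alignments Tibble from [align_reads()].
#' @param ref An [amplicon_reference()], or a reference string (then
#'   `primer_lengths` applies directly).
#' @param primer_lengths Integer `c(left, right)` mask widths (default from
#'   `ref`, else `c(0, 0)`).
#' @return A tibble with one row per reference position: `position`
#'   (0-based), `match_freq`, `n_covering`, `masked`.
#' @export
per_base_profile <- function(alignments, ref, primer_lengths = NULL) {
  if (inherits(ref, "amplicon_reference")) {
    primer_lengths <- primer_lengths %||% ref$primer_lengths
    ref <- ref$sequence
  }
  primer_lengths <- primer_lengths %||% c(0L, 0L)
  n <- nchar(ref)
  if (nrow(alignments) == 0L) abort("Need at least one alignment.")

  matches <- integer(n)
  covering <- integer(n)
  for (i in seq_len(nrow(alignments))) {
    rd <- strsplit(alignments$aligned_read[i], "")[[1]]
    rf <- strsplit(alignments$aligned_ref[i], "")[[1]]
    ref_col <- rf != "-"
    pos <- alignments$ref_start[i] + cumsum(ref_col)   # 1-based ref position
    pos <- pos[ref_col]
    rd_at <- rd[ref_col]
    rf_at <- rf[ref_col]
    covering[pos] <- covering[pos] + 1L
    ok <- rd_at == rf_at
    posm <- pos[ok]
    matches[posm] <- matches[posm] + 1L
  }
  tibble(
    position = seq_len(n) - 1L,
    match_freq = ifelse(covering > 0L, matches / covering, NA_real_),
    n_covering = covering,
    masked = (seq_len(n) - 1L) < primer_lengths[[1]] |
      (seq_len(n) - 1L) >= n - primer_lengths[[2]]
  )
}

#' Genotype a clone from its gel bands
#'
#' Applies the paired-guide screening rule: a wild-type-length band means at
#' least one unedited allele; a predicted deletion-product band means an
#' excised allele. So WT band only is `WT`; WT band plus a deletion band is
#' `monoallelic`; deletion band(s) without a WT band is `biallelic`; any
#' other band pattern is `no_call`. Band sizes match within `tol_bp`
#' (default 10% of the predicted size, reflecting the semi-quantitative
#' sizing of agarose gels).
#'
#' @param bands_bp Positive integer band sizes for one clone.
#' @param designs Tibble of paired-deletion designs (needs
#'   `wt_amplicon_bp` and `edited_amplicon_bp` columns), e.g. rows from
#'   [predict_pair_deletion()].
#' @param tol_bp Absolute size tolerance; `NULL` (default) uses 10% of each
#'   predicted size.
#' @return A one-row tibble: `call` (WT/monoallelic/biallelic/no_call),
#'   `has_wt_band`, `n_deletion_bands`, `n_unexplained_bands`.
#' @examples
#' des <- tibble::tibble(wt_amplicon_bp = 1000L,
#'                       edited_amplicon_bp = c(700L, 640L))
#' genotype_from_gel(c(1000, 700), des)   # monoallelic
#' @export
genotype_from_gel <- function(bands_bp, designs, tol_bp = NULL) {
  stopifnot(is.data.frame(designs),
            all(c("wt_amplicon_bp", "edited_amplicon_bp") %in% names(designs)))
  if (length(bands_bp) == 0L || all(is.na(bands_bp))) {
    warn("No bands observed: no_call.")
    return(tibble(call = "no_call", has_wt_band = FALSE,
                  n_deletion_bands = 0L, n_unexplained_bands = 0L))
  }
  stopifnot(all(bands_bp > 0))
  wt <- designs$wt_amplicon_bp[[1]]
  dels <- unique(designs$edited_amplicon_bp)
  tol_for <- function(size) if (is.null(tol_bp)) 0.1 * size else tol_bp

  is_wt <- abs(bands_bp - wt) <= tol_for(wt)
  is_del <- vapply(bands_bp, function(b) {
    any(abs(b - dels) <= tol_for(dels))
  }, logical(1))
  unexplained <- !is_wt & !is_del

  call <- if (any(unexplained)) {
    "no_call"
  } else if (any(is_wt) && any(is_del)) {
    "monoallelic"
  } else if (any(is_wt)) {
    "WT"
  } else if (any(is_del)) {
    "biallelic"
  } else {
    "no_call"
  }
  tibble(call = call, has_wt_band = any(is_wt),
         n_deletion_bands = sum(is_del),
         n_unexplained_bands = sum(unexplained))
}

#' Genotype every clone in a gel band table
#'
#' @param gel Tibble with `clone_id` and `band_bp` columns (one row per
#'   band), e.g. `simulate_gel_table()$bands` or a CSV read with
#'   [readr::read_csv()].
#' @inheritParams genotype_from_gel
#' @return A tibble with one row per clone: `clone_id` plus the
#'   [genotype_from_gel()] columns.
#' @export
genotype_clones <- function(gel, designs, tol_bp = NULL) {
  stopifnot(all(c("clone_id", "band_bp") %in% names(gel)))
  gel |>
    dplyr::group_by(.data$clone_id) |>
    dplyr::summarise(genotype_from_gel(.data$band_bp, designs, tol_bp),
                     .groups = "drop")
}

#' Chance fraction of in-frame indels under a length distribution
#'
#' The probability that an indel length drawn from the given distribution is
#' divisible by 3, by exact enumeration over the (finite) support. Under the
#' default uniform 1-30 nt length model this is 1/3 — the random-chance
#' in-frame rate against which observed in-frame fractions are judged.
#'
#' @param lengths Positive integer support.
#' @param probs Probabilities (default uniform over `lengths`).
#' @return A single probability.
#' @examples
#' expected_inframe_fraction(1:30)    # 1/3
#' expected_inframe_fraction(1:31)    # 10/31
#' @export
expected_inframe_fraction <- function(lengths = 1:30, probs = NULL) {
  if (length(lengths) == 0L) abort("`lengths` must be a nonempty support.")
  stopifnot(is.numeric(lengths), all(lengths >= 1), all(lengths == round(lengths)))
  if (is.null(probs)) probs <- rep(1 / length(lengths), length(lengths))
  stopifnot(length(probs) == length(lengths), all(probs >= 0),
            abs(sum(probs) - 1) < 1e-8)
  sum(probs[lengths %% 3 == 0])
}
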