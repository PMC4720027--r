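# Independent oracles and small fixture builders used across the suite.

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Gotoh three-state dynamic program for semi-global alignment (read global,
# reference free end gaps), written independently of the package's aligner.
# A gap of length L costs gap_open + L * gap_extend (penalties positive).
oracle_align_score <- function(read, ref, match = 2, mismatch = -4,
                               gap_open = 8, gap_extend = 1) {
  rd <- strsplit(read, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  m <- length(rd)
  n <- length(rf)
  NEG <- -1e9
  M <- matrix(NEG, m + 1, n + 1)  # read i aligned to ref j
  X <- matrix(NEG, m + 1, n + 1)  # gap in ref (insertion in read)
  Y <- matrix(NEG, m + 1, n + 1)  # gap in read (deletion)
  H0 <- function(i, j) {          # best state, with free leading ref skip
    if (i == 0) return(0)
    max(M[i + 1, j + 1], X[i + 1, j + 1], Y[i + 1, j + 1])
  }
  for (i in 1:m) {
    for (j in 0:n) {
      if (j > 0) {
        s <- if (rd[i] == rf[j]) match else mismatch
        M[i + 1, j + 1] <- s + H0(i - 1, j - 1)
        Y[i + 1, j + 1] <- max(
          max(M[i + 1, j], X[i + 1, j]) - gap_open - gap_extend,
          Y[i + 1, j] - gap_extend
        )
      }
      X[i + 1, j + 1] <- max(
        max(if (i == 1) 0 else NEG, M[i, j + 1], Y[i, j + 1]) -
          gap_open - gap_extend,
        X[i, j + 1] - gap_extend
      )
    }
  }
  max(vapply(0:n, function(j) {
    max(M[m + 1, j + 1], X[m + 1, j + 1], Y[m + 1, j + 1])
  }, numeric(1)))
}

# Brute-force Cas9 target scan: check every 23-nt window on both strands.
oracle_find_targets <- function(sequence) {
  rc <- function(x) chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]),
                                                 collapse = ""))
  n <- nchar(sequence)
  out <- list()
  for (start in seq_len(n - 22L)) {        # 1-based window start
    win <- substr(sequence, start, start + 22L)
    if (grepl("[^ACGT]", win)) next
    if (substr(win, 22L, 23L) == "GG") {
      out[[length(out) + 1L]] <- data.frame(
        spacer = substr(win, 1L, 20L), strand = "+",
        cut_site = (start - 1L) + 17L)     # bond before the 4th-from-PAM base
    }
    rwin <- rc(win)
    if (substr(rwin, 22L, 23L) == "GG") {
      out[[length(out) + 1L]] <- data.frame(
        spacer = substr(rwin, 1L, 20L), strand = "-",
        cut_site = (start - 1L) + 6L)
    }
  }
  if (length(out) == 0L) {
    return(data.frame(spacer = character(), strand = character(),
                      cut_site = integer()))
  }
  do.call(rbind, out)
}

# Small amplicon with one + strand guide: PAM begins 3 nt after the cut bond.
toy_amplicon <- function(len = 200L, cut = 100L, seed = 101L) {
  withr::with_seed(seed, {
    repeat {
      seqchr <- random_dna(len)
      # force an NGG PAM so the guide is genuine: PAM at [cut+3, cut+6)
      substr(seqchr, cut + 5L, cut + 6L) <- "GG"
      tg <- find_targets(seqchr)
      tg <- tg[tg$strand == "+" & tg$cut_site == cut, ]
      if (nrow(tg) >= 1L) {
        return(amplicon_reference("toy", seqchr, tg[1, ],
                                  primer_lengths = c(20L, 20L)))
      }
    }
  })
}

# Paired-deletion design table used by the gel tests (three guide pairs).
toy_designs <- function() {
  tibble::tibble(
    wt_amplicon_bp = 1000L,
    edited_amplicon_bp = c(700L, 640L, 580L),
    expected_deletion_bp = c(300L, 360L, 420L)
  )
}
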