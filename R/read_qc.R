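# Paired-read quality control for two-enzyme GBS libraries.
#
# Rule order is fixed: (0) both mates must begin with a cut-site remnant;
# (0b) reads with more than 5% ambiguous bases are removed; then
# (1) reads whose mean quality is below 20 are discarded; (2) trailing 5 bp
# windows with mean quality below 20 are trimmed from the 3' end; (3) pairs
# with a mate shorter than 50 bp after trimming are removed. Any failing
# mate drops the whole pair.

#' Site-prefix check for a read pair
#'
#' Keeps a pair only if each mate begins with one of the allowed cut-site
#' remnants (default EcoRI `AATTC` and NlaIII `CATG`), case-insensitively.
#' With `both_mates = FALSE` only the first mate is checked.
#'
#' @param seq1,seq2 Mate sequences (character scalars).
#' @param prefixes Allowed prefixes.
#' @param both_mates Check both mates (default) or only mate 1.
#' @return `TRUE` to keep, `FALSE` to drop.
#' @export
check_site_prefix <- function(seq1, seq2,
                              prefixes = c("AATTC", "CATG"),
                              both_mates = TRUE) {
  if (nchar(seq1) == 0L || nchar(seq2) == 0L) return(FALSE)
  starts_with <- function(s) {
    any(vapply(toupper(prefixes), function(p) {
      substr(toupper(s), 1L, nchar(p)) == p
    }, logical(1)))
  }
  if (both_mates) starts_with(seq1) && starts_with(seq2) else starts_with(seq1)
}

#' Ambiguous-base filter for one read
#'
#' Drops a read whose fraction of `N` bases strictly exceeds `max_frac`
#' ("more than 5% of N"); a read with exactly 5% N is kept. Empty reads are
#' dropped with reason `"empty"`.
#'
#' @param seq Read sequence (character scalar).
#' @param max_frac Maximum tolerated N fraction (default 0.05).
#' @return List with `keep` (logical) and `reason` (`"ok"`, `"n_fraction"`
#'   or `"empty"`).
#' @export
filter_n_fraction <- function(seq, max_frac = 0.05) {
  len <- nchar(seq)
  if (len == 0L) return(list(keep = FALSE, reason = "empty"))
  n_count <- lengths(regmatches(seq, gregexpr("N", toupper(seq), fixed = TRUE)))
  if (n_count / len > max_frac) {
    list(keep = FALSE, reason = "n_fraction")
  } else {
    list(keep = TRUE, reason = "ok")
  }
}

# Trim trailing windows with mean quality below the threshold; windows are
# non-overlapping 5 bp blocks from the 3' end, with a final partial window.
.trim_tail <- function(qual, window = 5L, min_window_q = 20) {
  len <- length(qual)
  while (len > 0L) {
    w <- min(window, len)
    if (mean(qual[(len - w + 1L):len]) < min_window_q) {
      len <- len - w
    } else {
      break
    }
  }
  len
}

#' Quality-clean a read pair
#'
#' Applies the three printed cleaning rules in order: (1) drop the pair if a
#' mate's mean Phred quality is below `min_read_q`; (2) trim trailing
#' `window`-bp blocks whose mean quality is below `min_window_q` from each
#' mate's 3' end; (3) drop the pair if a trimmed mate is shorter than
#' `min_len`. "Quality lower than 20" is read as mean per-read quality (a
#' per-base reading would discard nearly all real reads).
#'
#' @param seq1,seq2 Mate sequences.
#' @param qual1,qual2 Integer Phred vectors matching the sequences.
#' @param min_read_q Minimum mean read quality (rule 1; default 20).
#' @param window Trimming window size in bp (rule 2; default 5).
#' @param min_window_q Minimum mean window quality (rule 2; default 20).
#' @param min_len Minimum mate length after trimming (rule 3; default 50).
#' @return List with `keep`, `reason` (`"ok"`, `"low_mean_quality"` or
#'   `"short_after_trim"`), and when kept the trimmed `seq1`, `qual1`,
#'   `seq2`, `qual2`.
#' @export
quality_clean <- function(seq1, qual1, seq2, qual2,
                          min_read_q = 20, window = 5L,
                          min_window_q = 20, min_len = 50L) {
  stopifnot(nchar(seq1) == length(qual1), nchar(seq2) == length(qual2))
  if (mean(qual1) < min_read_q || mean(qual2) < min_read_q) {
    return(list(keep = FALSE, reason = "low_mean_quality"))
  }
  l1 <- .trim_tail(qual1, window, min_window_q)
  l2 <- .trim_tail(qual2, window, min_window_q)
  if (l1 < min_len || l2 < min_len) {
    return(list(keep = FALSE, reason = "short_after_trim"))
  }
  list(keep = TRUE, reason = "ok",
       seq1 = substr(seq1, 1L, l1), qual1 = qual1[seq_len(l1)],
       seq2 = substr(seq2, 1L, l2), qual2 = qual2[seq_len(l2)])
}

#' Run the full QC pipeline on paired reads
#'
#' Applies, in order: site-prefix retention, the N-fraction filter (either
#' mate failing drops the pair), and the three quality-cleaning rules. The
#' log records each pair's fate and the first failing rule.
#'
#' @param reads A `gbs_reads`-style list (`id`, `seq1`, `seq2`, `qual1`,
#'   `qual2`), e.g. from [simulate_reads()] or [read_fastq_pairs()].
#' @param prefixes Allowed site prefixes (see [check_site_prefix()]).
#' @param both_mates Prefix check on both mates (default) or mate 1 only.
#' @param max_n_frac Maximum N fraction (see [filter_n_fraction()]).
#' @param min_read_q,window,min_window_q,min_len See [quality_clean()].
#' @return List with `kept` (a `gbs_reads` of retained, trimmed pairs) and
#'   `log` (`data.frame` of `id`, `kept`, `reason`).
#' @export
qc_read_pairs <- function(reads,
                          prefixes = c("AATTC", "CATG"), both_mates = TRUE,
                          max_n_frac = 0.05,
                          min_read_q = 20, window = 5L, min_window_q = 20,
                          min_len = 50L) {
  n <- length(reads$id)
  reason <- character(n)
  keep <- logical(n)
  out_seq1 <- character(n); out_seq2 <- character(n)
  out_q1 <- vector("list", n); out_q2 <- vector("list", n)
  for (i in seq_len(n)) {
    if (!check_site_prefix(reads$seq1[i], reads$seq2[i], prefixes, both_mates)) {
      reason[i] <- "prefix"
      next
    }
    n1 <- filter_n_fraction(reads$seq1[i], max_n_frac)
    n2 <- filter_n_fraction(reads$seq2[i], max_n_frac)
    if (!n1$keep || !n2$keep) {
      reason[i] <- if (n1$reason == "empty" || n2$reason == "empty") "empty"
                   else "n_fraction"
      next
    }
    qc <- quality_clean(reads$seq1[i], reads$qual1[[i]],
                        reads$seq2[i], reads$qual2[[i]],
                        min_read_q, window, min_window_q, min_len)
    if (!qc$keep) {
      reason[i] <- qc$reason
      next
    }
    keep[i] <- TRUE
    reason[i] <- "ok"
    out_seq1[i] <- qc$seq1; out_q1[[i]] <- qc$qual1
    out_seq2[i] <- qc$seq2; out_q2[[i]] <- qc$qual2
  }
  kept <- structure(list(
    id = reads$id[keep],
    seq1 = out_seq1[keep], seq2 = out_seq2[keep],
    qual1 = out_q1[keep], qual2 = out_q2[keep]
  ), class = "gbs_reads")
  list(kept = kept,
       log = data.frame(id = reads$id, kept = keep, reason = reason,
                        stringsAsFactors = FALSE))
}
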