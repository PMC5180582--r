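# In silico restriction digestion: cut mapping, double digestion, size
# selection and fragment length histograms.
#
# Coordinates are 0-based half-open throughout, matching BED. Cut positions
# are computed on the top strand only; for the built-in palindromic enzymes
# the bottom strand yields the same restriction map, so this is exact. For a
# user-supplied non-palindromic enzyme the map is top-strand only (documented
# limitation).

.as_dnastring <- function(sequence) {
  if (methods::is(sequence, "DNAString")) return(sequence)
  Biostrings::DNAString(toupper(as.character(sequence)))
}

#' Find restriction cut positions on a sequence
#'
#' Scans the top strand for matches of the enzyme's recognition site with
#' IUPAC expansion (W matches A or T, etc.). An `N` in the sequence never
#' satisfies a non-N pattern position. Overlapping site matches are all
#' reported. The returned coordinates are 0-based positions of the cut
#' itself, i.e. `match_start + cut_offset`.
#'
#' @param sequence Character scalar or `Biostrings::DNAString` over
#'   A/C/G/T/N (case-insensitive).
#' @param enzyme A [enzyme()] object or built-in enzyme name.
#' @return Strictly increasing integer vector of 0-based cut coordinates.
#' @examples
#' find_cut_positions("AAGAATTCAA", "EcoRI")  # 3
#' @export
find_cut_positions <- function(sequence, enzyme) {
  enz <- get_enzyme(enzyme)
  subject <- .as_dnastring(sequence)
  if (length(subject) == 0L) stop("sequence must be non-empty")
  hits <- Biostrings::matchPattern(
    Biostrings::DNAString(enz$site), subject,
    fixed = "subject"
  )
  cuts <- BiocGenerics::start(hits) - 1L + enz$cut_offset
  sort(unique(as.integer(cuts)))
}

#' Double (or single) restriction digestion of one sequence
#'
#' Merges the cut sets of two enzymes and returns the fragments bounded by
#' consecutive cuts and the sequence termini. Each fragment end is labelled
#' with the name of the enzyme that produced it, or `"terminus"` at the
#' sequence ends. When both enzymes cut at the same coordinate a single cut
#' is kept and the first enzyme (`enzA`) takes labelling priority.
#' Passing the same enzyme twice reduces to a single digestion.
#'
#' Fragments tile the sequence: they are contiguous, non-overlapping, and
#' their lengths sum to the sequence length. Cuts falling exactly on a
#' terminus (possible only for offset-0 or full-length-offset sites) are
#' dropped so that every fragment has positive length.
#'
#' @param sequence Character scalar or `DNAString`.
#' @param enzA,enzB Enzymes ([enzyme()] objects or built-in names).
#' @param seq_id Sequence name recorded in the output.
#' @return A `data.frame` with columns `seq_id`, `start`, `end` (0-based
#'   half-open), `left_end`, `right_end` (enzyme name or `"terminus"`),
#'   `length`, `n_frac` (fraction of N bases) and `n_flagged`
#'   (`n_frac > 0.5`; flagged, not removed). The enzyme names are stored in
#'   `attr(, "enzymes")`.
#' @examples
#' double_digest("AAGAATTCAACATGAA", "EcoRI", "NlaIII")
#' @export
double_digest <- function(sequence, enzA, enzB, seq_id = "seq1") {
  enzA <- get_enzyme(enzA)
  enzB <- get_enzyme(enzB)
  subject <- .as_dnastring(sequence)
  n <- length(subject)

  cuts_a <- find_cut_positions(subject, enzA)
  cuts_b <- find_cut_positions(subject, enzB)
  # enzA labelling priority on coincident cuts
  cuts_b <- setdiff(cuts_b, cuts_a)
  cuts <- c(cuts_a, cuts_b)
  labels <- c(rep(enzA$name, length(cuts_a)), rep(enzB$name, length(cuts_b)))
  keep <- cuts > 0L & cuts < n
  cuts <- cuts[keep]
  labels <- labels[keep]
  ord <- order(cuts)
  cuts <- cuts[ord]
  labels <- labels[ord]

  bounds <- c(0L, cuts, n)
  blabels <- c("terminus", labels, "terminus")
  k <- length(bounds) - 1L
  start <- bounds[seq_len(k)]
  end <- bounds[seq_len(k) + 1L]

  frag_seqs <- Biostrings::extractAt(
    subject, IRanges::IRanges(start = start + 1L, end = end)
  )
  n_counts <- Biostrings::vcountPattern("N", frag_seqs, fixed = TRUE)
  n_frac <- n_counts / (end - start)

  out <- data.frame(
    seq_id = rep(seq_id, k),
    start = start,
    end = end,
    left_end = blabels[seq_len(k)],
    right_end = blabels[seq_len(k) + 1L],
    length = end - start,
    n_frac = n_frac,
    n_flagged = n_frac > 0.5,
    stringsAsFactors = FALSE
  )
  attr(out, "enzymes") <- c(enzA$name, enzB$name)
  out
}

#' Digest every record of a genome
#'
#' @param genome A FASTA path or a named `Biostrings::DNAStringSet`.
#' @param enzA,enzB Enzymes as in [double_digest()].
#' @return Row-bound fragment table over all records (see [double_digest()]).
#' @export
digest_genome <- function(genome, enzA, enzB) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
  }
  if (!methods::is(genome, "DNAStringSet")) {
    stop("genome must be a FASTA path or a DNAStringSet")
  }
  ids <- names(genome)
  if (is.null(ids)) ids <- paste0("seq", seq_along(genome))
  ids <- sub("\\s.*$", "", ids)
  parts <- lapply(seq_along(genome), function(i) {
    double_digest(genome[[i]], enzA, enzB, seq_id = ids[i])
  })
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  attr(out, "enzymes") <- attr(parts[[1]], "enzymes")
  out
}

#' Size-select fragments for library construction
#'
#' Retains fragments whose length lies in the inclusive window
#' `[min_len, max_len]` and whose ends satisfy `end_filter`:
#' * `"any"` — no end constraint (the default used for fragment-distribution
#'   assessment);
#' * `"both_sites"` — neither end is a sequence terminus;
#' * `"mixed_ends"` — one end from each of the two digestion enzymes
#'   (the classic rare/common two-enzyme GBS library).
#'
#' @param fragments Fragment table from [double_digest()]/[digest_genome()].
#' @param min_len,max_len Inclusive length bounds in bp (default 200-300).
#' @param end_filter One of `"any"`, `"both_sites"`, `"mixed_ends"`.
#' @param enzymes Length-2 character of enzyme names for `"mixed_ends"`;
#'   taken from `attr(fragments, "enzymes")` when omitted.
#' @return The retained subset of `fragments`.
#' @export
size_select <- function(fragments, min_len = 200L, max_len = 300L,
                        end_filter = c("any", "both_sites", "mixed_ends"),
                        enzymes = NULL) {
  end_filter <- match.arg(end_filter)
  if (min_len <= 0L || min_len > max_len) {
    stop("size window requires 0 < min_len <= max_len")
  }
  keep <- fragments$length >= min_len & fragments$length <= max_len
  if (end_filter == "both_sites") {
    keep <- keep & fragments$left_end != "terminus" &
      fragments$right_end != "terminus"
  } else if (end_filter == "mixed_ends") {
    if (is.null(enzymes)) enzymes <- attr(fragments, "enzymes")
    if (is.null(enzymes) || length(enzymes) != 2L) {
      stop("mixed_ends requires the two enzyme names (see 'enzymes')")
    }
    keep <- keep & ((fragments$left_end == enzymes[1] &
                       fragments$right_end == enzymes[2]) |
                      (fragments$left_end == enzymes[2] &
                         fragments$right_end == enzymes[1]))
  }
  out <- fragments[keep, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "enzymes") <- attr(fragments, "enzymes")
  out
}

#' Fragment length histogram with an overflow bar
#'
#' Bins fragment lengths into `(edge_i, edge_{i+1}]` intervals and pools
#' everything longer than the last edge into a final overflow bar, the
#' convention used when comparing enzyme combinations (100 bp bins with all
#' fragments beyond 1 kb accumulated in the last bar). The total count is
#' always preserved.
#'
#' @param fragments Fragment table or numeric vector of lengths.
#' @param bin_edges Increasing numeric vector of bin edges
#'   (default `seq(0, 1000, 100)`).
#' @param overflow_at Lengths greater than this are pooled in the overflow
#'   bin; must be at least the last edge (values between the last edge and
#'   `overflow_at` also fall in the overflow bin).
#' @return `data.frame` with `bin_low`, `bin_high`, `label`, `count`; the
#'   last row is the overflow bin.
#' @export
length_histogram <- function(fragments, bin_edges = seq(0, 1000, by = 100),
                             overflow_at = max(bin_edges)) {
  lengths <- if (is.data.frame(fragments)) fragments$length else as.numeric(fragments)
  if (is.unsorted(bin_edges, strictly = TRUE)) {
    stop("bin_edges must be strictly increasing")
  }
  last <- bin_edges[length(bin_edges)]
  if (overflow_at < last) stop("overflow_at must be >= the last bin edge")
  k <- length(bin_edges) - 1L
  counts <- integer(k)
  if (length(lengths) > 0L) {
    inbin <- lengths <= last
    if (any(inbin)) {
      idx <- findInterval(lengths[inbin], bin_edges, left.open = TRUE,
                          rightmost.closed = FALSE)
      idx[idx == 0L] <- 1L  # lengths at or below the first edge
      counts <- tabulate(idx, nbins = k)
    }
    overflow <- sum(!inbin)
  } else {
    overflow <- 0L
  }
  data.frame(
    bin_low = c(bin_edges[seq_len(k)], last),
    bin_high = c(bin_edges[-1L], Inf),
    label = c(
      sprintf("(%g,%g]", bin_edges[seq_len(k)], bin_edges[-1L]),
      sprintf(">%g", last)
    ),
    count = c(counts, overflow),
    stringsAsFactors = FALSE
  )
}

#' Write fragments as BED6
#'
#' Standard BED: 0-based half-open coordinates, `name` the left/right end
#' classes joined by `_`, `score` the fragment length, strand `"."`.
#'
#' @param fragments Fragment table.
#' @param path Output file.
#' @return `path`, invisibly.
#' @export
write_fragments_bed <- function(fragments, path) {
  bed <- data.frame(
    chrom = fragments$seq_id,
    start = fragments$start,
    end = fragments$end,
    name = paste(fragments$left_end, fragments$right_end, sep = "_"),
    score = fragments$length,
    strand = "."
  )
  utils::write.table(bed, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
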