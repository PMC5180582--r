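test_that("cut positions match hand scans and IUPAC expansion", {
  expect_identical(find_cut_positions("AAGAATTCAA", "EcoRI"), 3L)
  expect_identical(find_cut_positions("ACGTACGT", "EcoRI"), integer(0))
  expect_identical(find_cut_positions("GCAGCATGC", "ApeKI"), 1L)
  # N never satisfies a non-N pattern position
  expect_identical(find_cut_positions("GANTTC", "EcoRI"), integer(0))
  # overlapping degenerate matches are all reported
  expect_identical(find_cut_positions("GCTGCAGC", "ApeKI"), c(1L, 4L))
})

test_that("enzyme construction validates sites and offsets", {
  expect_error(enzyme("bad", "GAXTTC", 1), "IUPAC")
  expect_error(enzyme("bad", "GAATTC", 7), "cut_offset")
  expect_error(get_enzyme("NoSuchEnzyme"), "unknown enzyme")
  # the five built-ins are palindromic under IUPAC-aware reverse complement
  for (e in builtin_enzymes()) {
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(e$site)))
    expect_identical(rc, e$site)
  }
})

test_that("double digestion labels ends and tiles the sequence", {
  fr <- double_digest("AAGAATTCAACATGAA", "EcoRI", "NlaIII")
  expect_equal(fr$start, c(0, 3, 14))
  expect_equal(fr$end, c(3, 14, 16))
  expect_equal(fr$left_end, c("terminus", "EcoRI", "NlaIII"))
  expect_equal(fr$right_end, c("EcoRI", "NlaIII", "terminus"))
  expect_equal(sum(fr$length), 16)

  # site-free sequence: one fragment spanning the whole sequence
  fr0 <- double_digest("ACGTACGTACGT", "EcoRI", "NlaIII")
  expect_equal(nrow(fr0), 1L)
  expect_equal(fr0$length, 12)
  expect_equal(fr0$left_end, "terminus")

  # single-enzyme equivalence: E+E gives the same intervals as E alone
  set.seed(101)
  s <- random_dna(3000)
  fr_ee <- double_digest(s, "NlaIII", "NlaIII")
  cuts <- find_cut_positions(s, "NlaIII")
  expect_equal(fr_ee$start, c(0L, cuts))
  expect_equal(fr_ee$end, c(cuts, 3000L))
})

test_that("digestion agrees with a naive sliding-window oracle on random sequences", {
  set.seed(42)
  combos <- list(c("ApeKI", "PstI"), c("EcoRI", "BstNI"),
                 c("EcoRI", "NlaIII"), c("PstI", "NlaIII"))
  for (i in 1:20) {
    s <- random_dna(sample(200:3000, 1))
    cmb <- combos[[(i %% 4) + 1]]
    expect_identical(find_cut_positions(s, cmb[1]),
                     naive_cut_positions(s, cmb[1]))
    fr <- double_digest(s, cmb[1], cmb[2])
    orc <- naive_digest(s, cmb[1], cmb[2])
    expect_equal(fr$start, orc$start)
    expect_equal(fr$end, orc$end)
    expect_equal(fr$left_end, orc$left_end)
    expect_equal(fr$right_end, orc$right_end)
    # tiling invariant
    expect_equal(sum(fr$length), nchar(s))
    expect_equal(fr$start[-1], fr$end[-nrow(fr)])
  }
})

test_that("digestion is strand-symmetric up to the cut-offset shift", {
  # For a palindromic site of width w cut at offset o, a top-strand cut at c
  # maps on the reverse complement to L - c - (w - 2o): site positions mirror
  # exactly, cut positions shift by the overhang w - 2o. Only blunt cutters
  # (o = w/2) mirror the fragment length multiset exactly.
  set.seed(7)
  for (e in builtin_enzymes()) {
    s <- random_dna(3000)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    fwd <- find_cut_positions(s, e)
    rev <- find_cut_positions(rc, e)
    shift <- nchar(e$site) - 2L * e$cut_offset
    expect_identical(sort(as.integer(3000L - fwd - shift)), rev)
  }
  # blunt palindromic cutter: mirrored fragment length multiset
  ecorv <- enzyme("EcoRV", "GATATC", 3L)
  for (i in 1:5) {
    s <- random_dna(2000)
    rc <- as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
    f1 <- double_digest(s, ecorv, ecorv)
    f2 <- double_digest(rc, ecorv, ecorv)
    expect_equal(sort(f1$length), sort(f2$length))
  }
})

test_that("size selection applies inclusive bounds and end filters", {
  fr <- data.frame(
    seq_id = "s", start = 0, end = 1,
    left_end = c("EcoRI", "EcoRI", "NlaIII", "terminus", "EcoRI"),
    right_end = c("NlaIII", "EcoRI", "EcoRI", "EcoRI", "NlaIII"),
    length = c(150, 200, 250, 300, 301)
  )
  attr(fr, "enzymes") <- c("EcoRI", "NlaIII")
  expect_equal(size_select(fr, 200, 300, "any")$length, c(200, 250, 300))
  # terminus-ended fragment excluded under both_sites
  expect_false("terminus" %in% size_select(fr, 100, 400, "both_sites")$left_end)
  # mixed ends requires one end from each enzyme
  mixed <- size_select(fr, 100, 400, "mixed_ends")
  expect_equal(nrow(mixed), 3L)
  expect_true(all(mixed$left_end != mixed$right_end))
  # monotonicity: widening the window never loses fragments
  n1 <- nrow(size_select(fr, 220, 260, "any"))
  n2 <- nrow(size_select(fr, 200, 300, "any"))
  n3 <- nrow(size_select(fr, 100, 400, "any"))
  expect_true(n1 <= n2 && n2 <= n3)
  expect_error(size_select(fr, 0, 10), "min_len")
})

test_that("length histogram bins, overflows and conserves counts", {
  h <- length_histogram(c(50, 150, 2000))
  expect_equal(h$count[1], 1)
  expect_equal(h$count[2], 1)
  expect_equal(h$count[nrow(h)], 1)
  expect_equal(sum(h$count), 3)
  # bin edges are right-closed: a 100 bp fragment is in the first bin
  h2 <- length_histogram(c(100, 101))
  expect_equal(h2$count[1:2], c(1, 1))
  # conservation + brute-force binning oracle on a random set
  set.seed(3)
  lens <- sample(1:2500, 1000, replace = TRUE)
  h3 <- length_histogram(lens)
  expect_equal(sum(h3$count), 1000)
  edges <- seq(0, 1000, by = 100)
  brute <- integer(11)
  for (l in lens) {
    if (l > 1000) brute[11] <- brute[11] + 1L
    else {
      for (b in 1:10) {
        if (l > edges[b] && l <= edges[b + 1]) brute[b] <- brute[b] + 1L
      }
    }
  }
  expect_equal(h3$count, brute)
  # empty input: all-zero histogram
  expect_true(all(length_histogram(numeric(0))$count == 0))
})

test_that("fragments export as BED6 text", {
  fr <- double_digest("AAGAATTCAACATGAA", "EcoRI", "NlaIII")
  path <- tempfile(fileext = ".bed")
  write_fragments_bed(fr, path)
  bed <- read.table(path, sep = "\t")
  expect_equal(nrow(bed), 3L)
  expect_equal(bed$V2, fr$start)
  expect_equal(bed$V3, fr$end)
  expect_equal(bed$V4[2], "EcoRI_NlaIII")
  expect_equal(bed$V5, fr$length)
})
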