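# Independent oracles and fixture builders used across the test suite.

IUPAC_SETS <- list(
  A = "A", C = "C", G = "G", T = "T",
  R = c("A", "G"), Y = c("C", "T"), S = c("C", "G"), W = c("A", "T"),
  K = c("G", "T"), M = c("A", "C"),
  B = c("C", "G", "T"), D = c("A", "G", "T"), H = c("A", "C", "T"),
  V = c("A", "C", "G"), N = c("A", "C", "G", "T")
)

# Naive sliding-window IUPAC matcher (no Biostrings), position-by-position.
naive_cut_positions <- function(seq, enz) {
  enz <- get_enzyme(enz)
  chars <- strsplit(toupper(seq), "")[[1]]
  pat <- strsplit(enz$site, "")[[1]]
  n <- length(chars)
  m <- length(pat)
  if (n < m) return(integer(0))
  ok <- rep(TRUE, n - m + 1L)
  for (j in seq_len(m)) {
    ok <- ok & chars[j:(n - m + j)] %in% IUPAC_SETS[[pat[j]]]
  }
  sort(which(ok) - 1L + enz$cut_offset)
}

# Hand digestion oracle built on the naive matcher.
naive_digest <- function(seq, enzA, enzB) {
  enzA <- get_enzyme(enzA); enzB <- get_enzyme(enzB)
  ca <- naive_cut_positions(seq, enzA)
  cb <- setdiff(naive_cut_positions(seq, enzB), ca)
  cuts <- c(ca, cb)
  lab <- c(rep(enzA$name, length(ca)), rep(enzB$name, length(cb)))
  n <- nchar(seq)
  keep <- cuts > 0L & cuts < n
  cuts <- cuts[keep]; lab <- lab[keep]
  o <- order(cuts)
  b <- c(0L, cuts[o], n)
  bl <- c("terminus", lab[o], "terminus")
  k <- length(b) - 1L
  data.frame(start = b[seq_len(k)], end = b[-1L],
             left_end = bl[seq_len(k)], right_end = bl[-1L],
             stringsAsFactors = FALSE)
}

random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# Closed-form normal-equations OLS oracle for y ~ 1 + g + sex.
ols_oracle <- function(y, g, sex) {
  X <- cbind(1, g, sex)
  XtXi <- solve(t(X) %*% X)
  b <- XtXi %*% t(X) %*% y
  r <- y - X %*% b
  df <- length(y) - 3L
  s2 <- sum(r^2) / df
  se <- sqrt(diag(XtXi) * s2)
  tval <- b[2] / se[2]
  list(beta = unname(b[2]), se = unname(se[2]), t = unname(tval),
       p = 2 * stats::pt(-abs(unname(tval)), df))
}

# Classical MDS oracle: explicit double-centering + eigendecomposition.
mds_oracle <- function(d, k = 2L) {
  d <- as.matrix(d)
  n <- nrow(d)
  J <- diag(n) - matrix(1 / n, n, n)
  B <- -0.5 * J %*% (d^2) %*% J
  ev <- eigen((B + t(B)) / 2, symmetric = TRUE)
  keep <- seq_len(k)
  ev$vectors[, keep, drop = FALSE] %*% diag(sqrt(pmax(ev$values[keep], 0)), k)
}

# Toy annotated genome: three genes on a 300 bp chromosome.
#   gene1 (+):  5'UTR 21-30, CDS 31-60, 3'UTR 61-80
#   gene2 (-):  3'UTR 121-140, CDS 141-170, 5'UTR 171-180
#   gene3 (+):  two CDS exons 221-235 / 241-255 (intron 236-240), no UTRs
# All three code the same 30 bp ORF (codons ATG GAA TAT CCC GGG AAA TTT CTG
# CAT TAA) on the coding strand.
toy_gene_fixture <- function() {
  coding <- "ATGGAATATCCCGGGAAATTTCTGCATTAA"
  chars <- rep("A", 300)
  put <- function(chars, at, s) {
    chars[at:(at + nchar(s) - 1L)] <- strsplit(s, "")[[1]]
    chars
  }
  revcomp <- function(s) {
    as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
  }
  chars <- put(chars, 31, coding)
  chars <- put(chars, 141, revcomp(coding))
  chars <- put(chars, 221, substr(coding, 1, 15))
  chars <- put(chars, 241, substr(coding, 16, 30))
  genome <- Biostrings::DNAStringSet(paste(chars, collapse = ""))
  names(genome) <- "chr1"
  gff <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ttoy\tgene\t21\t80\t.\t+\t.\tID=gene1",
    "chr1\ttoy\tmRNA\t21\t80\t.\t+\t.\tID=tx1;Parent=gene1",
    "chr1\ttoy\tfive_prime_UTR\t21\t30\t.\t+\t.\tParent=tx1",
    "chr1\ttoy\tCDS\t31\t60\t.\t+\t0\tID=cds1;Parent=tx1",
    "chr1\ttoy\tthree_prime_UTR\t61\t80\t.\t+\t.\tParent=tx1",
    "chr1\ttoy\tgene\t121\t180\t.\t-\t.\tID=gene2",
    "chr1\ttoy\tmRNA\t121\t180\t.\t-\t.\tID=tx2;Parent=gene2",
    "chr1\ttoy\tthree_prime_UTR\t121\t140\t.\t-\t.\tParent=tx2",
    "chr1\ttoy\tCDS\t141\t170\t.\t-\t0\tID=cds2;Parent=tx2",
    "chr1\ttoy\tfive_prime_UTR\t171\t180\t.\t-\t.\tParent=tx2",
    "chr1\ttoy\tgene\t221\t260\t.\t+\t.\tID=gene3",
    "chr1\ttoy\tmRNA\t221\t260\t.\t+\t.\tID=tx3;Parent=gene3",
    "chr1\ttoy\tCDS\t221\t235\t.\t+\t0\tID=cds3a;Parent=tx3",
    "chr1\ttoy\tCDS\t241\t255\t.\t+\t0\tID=cds3b;Parent=tx3"
  ), gff)
  list(genome = genome, gff = gff, coding = coding)
}

# Hand-built 12-record VCF (10 samples) with pre-enumerated fates under the
# default policy (DP >= 5, QUAL >= 100, call rate >= 0.8). The `good`
# argument is the number of samples with DP >= 5 and a called genotype.
hand_vcf_fixture <- function() {
  samples <- sprintf("S%02d", 1:10)
  cells <- function(good, dp_low = 0L, gt_missing = 0L) {
    # `good` passing calls, then dp_low calls at DP 4, then missing GTs at
    # high depth; pad with passing calls never reached (good+dp_low+gt_missing = 10)
    c(rep("0/1:20", good), rep("0/1:4", dp_low), rep("./.:20", gt_missing))
  }
  rec <- function(id, pos, qual, cells, ref = "A", alt = "C") {
    paste(c("chr1", pos, id, ref, alt, qual, "PASS", ".", "GT:DP", cells),
          collapse = "\t")
  }
  lines <- c(
    "##fileformat=VCFv4.2",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            "FORMAT", samples), collapse = "\t"),
    rec("rec01", 100, "150",   cells(10)),            # retained
    rec("rec02", 200, "100",   cells(8, 2)),          # retained (both boundaries)
    rec("rec03", 300, "99",    cells(10)),            # rejected: quality
    rec("rec04", 400, "150",   cells(7, 3)),          # rejected: callrate
    rec("rec05", 500, "50",    cells(2, 8)),          # rejected: quality (first rule)
    rec("rec06", 600, "150",   cells(8, 2)),          # retained; 2 calls masked
    rec("rec07", 700, "150",   cells(9, 0, 1)),       # retained (9 >= 8)
    rec("rec08", 800, "150",   cells(7, 0, 3)),       # rejected: callrate
    rec("rec09", 900, "101",   cells(10)),            # retained
    rec("rec10", 1000, "99.99", cells(10)),           # rejected: quality
    rec("rec11", 1100, "150",  cells(10), ref = "AT", alt = "A"),   # indel passthrough
    rec("rec12", 1200, "150",  cells(10), alt = "A,G")              # multiallelic passthrough
  )
  path <- tempfile(fileext = ".vcf")
  writeLines(lines, path)
  list(path = path,
       retained = c("rec01", "rec02", "rec06", "rec07", "rec09"),
       reject_quality = 3L, reject_callrate = 2L,
       passthrough = c("rec11", "rec12"))
}
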