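# Text-format IO: genotype call codes, VCF 4.2 writing/reading, paired FASTQ.
#
# VCF output is written as plain (uncompressed) VCF 4.2 text so that
# downstream tools and tests can inspect it directly; reading goes through
# vcfR.

#' Convert between 0/1/2/NA dose matrices and AA/AB/BB/NN call matrices
#'
#' Genotypes are handled internally as integer alternate-allele doses
#' (0 = AA, 1 = AB, 2 = BB, `NA` = NN/missing).
#'
#' @param g Integer dose matrix (or vector).
#' @return Character matrix (or vector) over `{"AA","AB","BB","NN"}`.
#' @export
dose_to_calls <- function(g) {
  out <- c("AA", "AB", "BB")[g + 1L]
  out[is.na(out)] <- "NN"
  if (is.matrix(g)) out <- matrix(out, nrow(g), ncol(g), dimnames = dimnames(g))
  out
}

#' @rdname dose_to_calls
#' @param calls Character matrix/vector over `{"AA","AB","BB","NN"}`.
#' @export
calls_to_dose <- function(calls) {
  map <- c(AA = 0L, AB = 1L, BB = 2L, NN = NA_integer_)
  bad <- !(calls %in% names(map))
  if (any(bad)) {
    stop("unknown genotype symbol(s): ", paste(unique(calls[bad]), collapse = ", "))
  }
  out <- map[calls]
  if (is.matrix(calls)) {
    out <- matrix(out, nrow(calls), ncol(calls), dimnames = dimnames(calls))
  } else {
    names(out) <- NULL
  }
  out
}

.vcf_header <- function(sample_ids, contigs = NULL, with_dp = FALSE) {
  h <- c("##fileformat=VCFv4.2", "##source=gbskit")
  if (!is.null(contigs)) {
    h <- c(h, sprintf("##contig=<ID=%s,length=%d>", names(contigs),
                      as.integer(contigs)))
  }
  h <- c(h, "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">")
  if (with_dp) {
    h <- c(h, "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">")
  }
  c(h, paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
               "FORMAT", sample_ids), collapse = "\t"))
}

.gt_strings <- function(g) {
  out <- c("0/0", "0/1", "1/1")[g + 1L]
  out[is.na(out)] <- "./."
  matrix(out, nrow(g), ncol(g))
}

#' Write a true genotype matrix as VCF 4.2
#'
#' @param pop A `gbs_population` from [simulate_population()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_truth_vcf <- function(pop, path) {
  gt <- t(.gt_strings(pop$genotypes))  # loci x samples
  body <- cbind(pop$loci$chrom, pop$loci$pos, pop$loci$id, pop$loci$ref,
                pop$loci$alt, ".", "PASS", ".", "GT", gt)
  lines <- c(.vcf_header(pop$sample_ids),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Write an observed genotype matrix (GT:DP, QUAL) as VCF 4.2
#'
#' @param obs A `gbs_observation` from [simulate_observations()].
#' @param path Output VCF path.
#' @return `path`, invisibly.
#' @export
write_observed_vcf <- function(obs, path) {
  gt <- .gt_strings(obs$genotypes)
  cells <- matrix(paste(gt, obs$depth, sep = ":"),
                  nrow(obs$genotypes), ncol(obs$genotypes))
  body <- cbind(obs$loci$chrom, obs$loci$pos, obs$loci$id, obs$loci$ref,
                obs$loci$alt, sprintf("%.2f", obs$qual), "PASS", ".",
                "GT:DP", t(cells))
  lines <- c(.vcf_header(obs$sample_ids, with_dp = TRUE),
             apply(body, 1L, paste, collapse = "\t"))
  writeLines(lines, path)
  invisible(path)
}

#' Read a VCF into dose/depth matrices
#'
#' Thin front end over `vcfR::read.vcfR()` returning the matrix form used by
#' [apply_snp_filter()]. Indel and multiallelic records are identified but
#' not converted.
#'
#' @param path VCF file (plain or gzipped).
#' @return List with `genotypes` (samples x loci dose matrix), `depth`
#'   (samples x loci, `NA` when the VCF has no DP), `qual` (per-locus),
#'   `loci` (`data.frame`), and `biallelic_snp` (logical per locus).
#' @export
read_vcf_matrix <- function(path) {
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  fix <- as.data.frame(vcfR::getFIX(v), stringsAsFactors = FALSE)
  gt_raw <- vcfR::extract.gt(v, element = "GT")
  gt <- matrix(NA_integer_, nrow(gt_raw), ncol(gt_raw), dimnames = dimnames(gt_raw))
  clean <- gsub("\\|", "/", gt_raw)
  gt[clean == "0/0"] <- 0L
  gt[clean %in% c("0/1", "1/0")] <- 1L
  gt[clean == "1/1"] <- 2L
  dp <- tryCatch(
    vcfR::extract.gt(v, element = "DP", as.numeric = TRUE),
    error = function(e) NULL
  )
  if (is.null(dp)) {
    dp <- matrix(NA_real_, nrow(gt), ncol(gt), dimnames = dimnames(gt))
  }
  biallelic <- !grepl(",", fix$ALT) & nchar(fix$REF) == 1L &
    nchar(fix$ALT) == 1L & fix$ALT %in% c("A", "C", "G", "T")
  loci <- data.frame(chrom = fix$CHROM, pos = as.integer(fix$POS),
                     id = fix$ID, ref = fix$REF, alt = fix$ALT,
                     stringsAsFactors = FALSE)
  list(genotypes = t(gt), depth = t(dp),
       qual = suppressWarnings(as.numeric(fix$QUAL)),
       loci = loci, biallelic_snp = biallelic)
}

.phred_string <- function(q) {
  rawToChar(as.raw(pmin(pmax(q, 0L), 60L) + 33L))
}

.phred_ints <- function(s) {
  as.integer(charToRaw(s)) - 33L
}

#' Write paired reads as FASTQ (Phred+33)
#'
#' @param reads A `gbs_reads` object (see [simulate_reads()]) or any list
#'   with `id`, `seq1`, `seq2`, `qual1`, `qual2`.
#' @param r1_path,r2_path Output FASTQ paths for the two mates.
#' @return `c(r1_path, r2_path)`, invisibly.
#' @export
write_fastq_pairs <- function(reads, r1_path, r2_path) {
  write_one <- function(seqs, quals, path) {
    x <- Biostrings::QualityScaledDNAStringSet(
      Biostrings::DNAStringSet(seqs),
      Biostrings::PhredQuality(vapply(quals, .phred_string, character(1)))
    )
    names(x) <- reads$id
    Biostrings::writeQualityScaledXStringSet(x, path)
  }
  write_one(reads$seq1, reads$qual1, r1_path)
  write_one(reads$seq2, reads$qual2, r2_path)
  invisible(c(r1_path, r2_path))
}

#' Read paired FASTQ into the in-memory read-pair structure
#'
#' @param r1_path,r2_path FASTQ paths (plain or gzipped), mates in the same
#'   order.
#' @return A `gbs_reads`-style list (`id`, `seq1`, `seq2`, `qual1`, `qual2`).
#' @export
read_fastq_pairs <- function(r1_path, r2_path) {
  # suppressed warning: the reader drops (empty) metadata columns
  r1 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r1_path))
  r2 <- suppressWarnings(Biostrings::readQualityScaledDNAStringSet(r2_path))
  if (length(r1) != length(r2)) stop("mate files differ in read count")
  qual_ints <- function(x) {
    unname(lapply(as.character(Biostrings::quality(x)), .phred_ints))
  }
  structure(list(
    id = sub("\\s.*$", "", names(r1)),
    seq1 = unname(as.character(r1)), seq2 = unname(as.character(r2)),
    qual1 = qual_ints(r1), qual2 = qual_ints(r2)
  ), class = "gbs_reads")
}
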