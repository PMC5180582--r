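# SNP genomic-context and coding-effect classification against GFF3 gene
# models, plus gene-window lookup around association hits.
#
# GFF3 coordinates are 1-based inclusive; they are used as imported by
# rtracklayer (GRanges are 1-based closed), while the digest module's
# fragment tables are BED-style 0-based half-open. SNP positions here are
# 1-based, matching VCF.

.as_gene_models <- function(models) {
  if (methods::is(models, "GRanges")) return(models)
  if (is.character(models) && length(models) == 1L) {
    return(rtracklayer::import(models, format = "gff3"))
  }
  stop("gene models must be a GRanges or a GFF3 path")
}

.loci_granges <- function(loci) {
  GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(start = loci$pos, width = 1L)
  )
}

.feature_ids <- function(gr) {
  md <- S4Vectors::mcols(gr)
  if (!is.null(md$ID) && !all(is.na(md$ID))) as.character(md$ID)
  else if (!is.null(md$Name)) as.character(md$Name)
  else paste0("feature", seq_along(gr))
}

#' Classify SNP genomic locations
#'
#' Assigns each locus one class with the precedence CDS-exon > UTR > intron
#' > intergenic: a locus overlapping a CDS feature is `"exon"`; otherwise an
#' overlap with a `five_prime_UTR`/`three_prime_UTR` feature (strand already
#' resolved in the GFF) gives `"5UTR"`/`"3UTR"`; otherwise a locus inside a
#' gene span is `"intron"`; everything else is `"intergenic"`.
#'
#' @param loci `data.frame` with `chrom` and `pos` (1-based SNP positions).
#' @param models Gene models: a GFF3 path or an imported `GRanges` with a
#'   `type` column covering `gene`, `CDS` and (optionally) UTR features.
#' @param seqlengths Optional named vector of chromosome lengths; loci
#'   beyond a chromosome end raise a coordinate error.
#' @return Character vector of location classes, one per locus.
#' @export
classify_location <- function(loci, models, seqlengths = NULL) {
  gr <- .loci_granges(loci)
  models <- .as_gene_models(models)
  if (!is.null(seqlengths)) {
    len <- seqlengths[as.character(loci$chrom)]
    bad <- which(!is.na(len) & loci$pos > len)
    if (length(bad) > 0L) {
      stop("locus beyond chromosome length at row ", bad[1])
    }
  }
  type <- as.character(models$type)
  out <- rep("intergenic", nrow(loci))
  hit <- function(subset) {
    IRanges::overlapsAny(gr, models[type %in% subset], ignore.strand = TRUE)
  }
  in_gene <- hit(c("gene"))
  out[in_gene] <- "intron"
  utr5 <- hit("five_prime_UTR")
  utr3 <- hit("three_prime_UTR")
  out[utr3] <- "3UTR"
  out[utr5] <- "5UTR"
  out[hit("CDS")] <- "exon"
  out
}

# Severity order for multi-transcript reconciliation.
.EFFECT_SEVERITY <- c("stop_gained", "frameshift", "start_lost", "stop_lost",
                      "missense", "synonymous")

# Effect of a single substitution on one transcript's spliced CDS.
.effect_one_transcript <- function(cds, pos, ref, alt, genome) {
  ord <- order(BiocGenerics::start(cds))
  cds <- cds[ord]
  strand <- as.character(BiocGenerics::strand(cds))[1]
  widths <- BiocGenerics::width(cds)
  total <- sum(widths)
  if (total %% 3L != 0L) {
    warning("CDS length not divisible by 3; effect set to NA")
    return(NA_character_)
  }
  chrom <- as.character(GenomicRanges::seqnames(cds))[1]
  pieces <- Biostrings::extractAt(
    genome[[chrom]],
    IRanges::IRanges(BiocGenerics::start(cds), BiocGenerics::end(cds))
  )
  coding <- Biostrings::DNAString(paste(as.character(pieces), collapse = ""))
  # offset of the locus within the genomic-order concatenation
  idx <- which(BiocGenerics::start(cds) <= pos & BiocGenerics::end(cds) >= pos)
  if (length(idx) == 0L) return("non_coding")
  off <- sum(widths[seq_len(idx - 1L)]) + (pos - BiocGenerics::start(cds)[idx] + 1L)
  if (strand == "-") {
    coding <- Biostrings::reverseComplement(coding)
    cpos <- total - off + 1L
    comp <- function(b) as.character(Biostrings::reverseComplement(
      Biostrings::DNAString(b)))
    ref <- comp(ref); alt <- comp(alt)
  } else {
    cpos <- off
  }
  genome_base <- as.character(coding[cpos])
  if (genome_base != toupper(ref)) {
    warning("reference allele disagrees with the genome at the locus; ",
            "using the genome base")
    ref <- genome_base
  }
  ci <- (cpos - 1L) %/% 3L
  codon <- as.character(Biostrings::subseq(coding, ci * 3L + 1L, ci * 3L + 3L))
  in_codon <- cpos - ci * 3L
  alt_codon <- codon
  substr(alt_codon, in_codon, in_codon) <- toupper(alt)
  aa_ref <- Biostrings::GENETIC_CODE[[codon]]
  aa_alt <- Biostrings::GENETIC_CODE[[alt_codon]]
  if (ci == 0L && aa_ref == "M" && aa_alt != "M") return("start_lost")
  if (aa_ref != "*" && aa_alt == "*") return("stop_gained")
  if (aa_ref == "*" && aa_alt != "*") return("stop_lost")
  if (aa_ref == aa_alt) return("synonymous")
  "missense"
}

#' Classify the coding effect of variants
#'
#' For each variant inside a CDS, the reference and alternate codons are
#' built on the coding strand and translated with the standard genetic code.
#' Substitutions classify as synonymous/missense/stop_gained/stop_lost/
#' start_lost; length-changing alleles whose length difference is not a
#' multiple of 3 are `frameshift` (in-frame indels are returned `NA`);
#' variants outside every CDS are `non_coding`. Against multiple overlapping
#' transcripts the most severe class is reported (stop_gained > frameshift >
#' start_lost > stop_lost > missense > synonymous).
#'
#' @param loci `data.frame` with `chrom`, `pos` (1-based), `ref`, `alt`.
#' @param genome Named `DNAStringSet` (or FASTA path).
#' @param models Gene models (GFF3 path or `GRanges`) with CDS features
#'   carrying `Parent` transcript identifiers.
#' @return Character vector of effect classes, one per locus.
#' @export
classify_effect <- function(loci, genome, models) {
  if (is.character(genome) && length(genome) == 1L) {
    genome <- Biostrings::readDNAStringSet(genome)
    names(genome) <- sub("\\s.*$", "", names(genome))
  }
  models <- .as_gene_models(models)
  cds <- models[as.character(models$type) == "CDS"]
  parent <- S4Vectors::mcols(cds)$Parent
  parent <- if (is.null(parent)) rep("tx1", length(cds))
            else vapply(as.list(parent), function(p) {
              if (length(p) == 0L) "tx1" else as.character(p[[1]])
            }, character(1))
  out <- character(nrow(loci))
  for (i in seq_len(nrow(loci))) {
    ref <- toupper(loci$ref[i]); alt <- toupper(loci$alt[i])
    if (nchar(ref) != nchar(alt)) {
      delta <- abs(nchar(ref) - nchar(alt))
      # indel effect only matters inside a CDS
      gr <- GenomicRanges::GRanges(loci$chrom[i],
                                   IRanges::IRanges(loci$pos[i], width = 1L))
      inside <- IRanges::overlapsAny(gr, cds, ignore.strand = TRUE)
      out[i] <- if (!inside) "non_coding"
                else if (delta %% 3L != 0L) "frameshift"
                else NA_character_
      next
    }
    hits <- which(as.character(GenomicRanges::seqnames(cds)) == loci$chrom[i] &
                    BiocGenerics::start(cds) <= loci$pos[i] &
                    BiocGenerics::end(cds) >= loci$pos[i])
    if (length(hits) == 0L) {
      out[i] <- "non_coding"
      next
    }
    txs <- unique(parent[hits])
    effects <- vapply(txs, function(tx) {
      .effect_one_transcript(cds[parent == tx], loci$pos[i], ref, alt, genome)
    }, character(1))
    effects <- effects[!is.na(effects)]
    out[i] <- if (length(effects) == 0L) NA_character_
              else .EFFECT_SEVERITY[min(match(effects, .EFFECT_SEVERITY))]
  }
  out
}

#' Protein-coding genes within a window of each locus
#'
#' Returns, per locus, the genes whose span intersects
#' `[pos - window, pos + window]` (inclusive bounds; a gene exactly
#' `window` bp away is included, `window + 1` bp away is not).
#'
#' @param loci `data.frame` with `chrom`, `pos` (1-based).
#' @param models Gene models (GFF3 path or `GRanges`) with `gene` features.
#' @param window Flank size in bp (default 50,000).
#' @return List (one element per locus) of deduplicated gene identifiers in
#'   genomic order.
#' @export
genes_near <- function(loci, models, window = 50000L) {
  models <- .as_gene_models(models)
  genes <- models[as.character(models$type) == "gene"]
  genes <- genes[order(as.character(GenomicRanges::seqnames(genes)),
                       BiocGenerics::start(genes))]
  ids <- .feature_ids(genes)
  gr <- GenomicRanges::GRanges(
    seqnames = loci$chrom,
    ranges = IRanges::IRanges(pmax(1L, loci$pos - as.integer(window)),
                              loci$pos + as.integer(window))
  )
  hits <- GenomicRanges::findOverlaps(gr, genes, ignore.strand = TRUE)
  lapply(seq_len(nrow(loci)), function(i) {
    unique(ids[S4Vectors::subjectHits(hits)[S4Vectors::queryHits(hits) == i]])
  })
}
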