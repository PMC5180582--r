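# Composite SNP filtering: per-genotype depth masking, site quality and
# population call rate.
#
# Threshold semantics: "depth higher than 5" and "depth threshold of 5" are
# used interchangeably in GBS practice; comparisons here are inclusive
# (DP >= min_depth, QUAL >= min_qual). The population criterion "at least
# 80% of individuals" (400 of 500) uses ceiling(min_callrate * n).

#' Filtering policy
#'
#' @param min_depth Minimum per-genotype depth (default 5); genotypes below
#'   it are masked to missing when `mask_below_depth` is `TRUE`.
#' @param min_qual Minimum site quality (default 100).
#' @param min_callrate Minimum fraction of samples with a (depth-passing)
#'   non-missing call (default 0.8).
#' @param mask_below_depth Mask sub-threshold genotypes to missing before
#'   counting calls (default `TRUE`).
#' @return A list of class `filter_policy`.
#' @export
filter_policy <- function(min_depth = 5L, min_qual = 100, min_callrate = 0.8,
                          mask_below_depth = TRUE) {
  if (min_depth < 0L) stop("min_depth must be >= 0")
  if (min_callrate <= 0 || min_callrate > 1) stop("min_callrate must be in (0, 1]")
  structure(list(min_depth = as.integer(min_depth), min_qual = min_qual,
                 min_callrate = min_callrate,
                 mask_below_depth = isTRUE(mask_below_depth)),
            class = "filter_policy")
}

#' Apply the composite SNP filter to genotype matrices
#'
#' Genotypes with depth below `min_depth` are masked to missing (when
#' `mask_below_depth`); a locus is retained iff its QUAL is at least
#' `min_qual` and the number of remaining non-missing calls is at least
#' `ceiling(min_callrate * n_samples)`. Removed loci are partitioned by the
#' first failing rule (quality before call rate).
#'
#' @param genotypes Samples x loci dose matrix (0/1/2/`NA`) — see
#'   [read_vcf_matrix()] or [simulate_observations()].
#' @param depth Samples x loci depth matrix; required (an error names the
#'   field if absent or all-`NA`).
#' @param qual Per-locus quality vector.
#' @param policy A [filter_policy()].
#' @return List with `genotypes` (masked, retained loci only), `retained`
#'   (logical per locus), `call_counts` (per-locus non-missing calls after
#'   masking), `rejections` (`data.frame` of `rule`, `n`).
#' @export
apply_snp_filter <- function(genotypes, depth, qual, policy = filter_policy()) {
  if (missing(depth) || is.null(depth) || all(is.na(depth))) {
    stop("per-genotype depth (DP) is required by the filter but is missing")
  }
  stopifnot(identical(dim(genotypes), dim(depth)),
            length(qual) == ncol(genotypes))
  n <- nrow(genotypes)
  g <- genotypes
  if (policy$mask_below_depth) {
    g[depth < policy$min_depth] <- NA_integer_
  }
  call_counts <- colSums(!is.na(g))
  need <- ceiling(policy$min_callrate * n)
  pass_qual <- qual >= policy$min_qual
  pass_call <- call_counts >= need
  retained <- pass_qual & pass_call
  rejections <- data.frame(
    rule = c("quality", "callrate"),
    n = c(sum(!pass_qual), sum(pass_qual & !pass_call))
  )
  list(genotypes = g[, retained, drop = FALSE],
       retained = retained,
       call_counts = call_counts,
       rejections = rejections)
}

#' Filter a VCF file with the composite policy
#'
#' Reads the VCF through [read_vcf_matrix()], applies [apply_snp_filter()]
#' to the biallelic SNP records, and passes indel/multiallelic records
#' through untouched with a warning.
#'
#' @param path VCF path.
#' @param policy A [filter_policy()].
#' @return The [apply_snp_filter()] result plus `loci` (retained biallelic
#'   loci), `passthrough` (untouched non-SNP records).
#' @export
filter_vcf <- function(path, policy = filter_policy()) {
  v <- read_vcf_matrix(path)
  if (any(!v$biallelic_snp)) {
    warning(sum(!v$biallelic_snp),
            " indel/multiallelic record(s) passed through unfiltered")
  }
  snp <- v$biallelic_snp
  res <- apply_snp_filter(v$genotypes[, snp, drop = FALSE],
                          v$depth[, snp, drop = FALSE],
                          v$qual[snp], policy)
  res$loci <- v$loci[snp, , drop = FALSE][res$retained, , drop = FALSE]
  res$passthrough <- v$loci[!snp, , drop = FALSE]
  res
}

#' Retained-SNP counts over depth and call-rate grids
#'
#' For every combination of depth threshold and required call-rate, counts
#' the loci that [apply_snp_filter()] would retain. Counts are non-increasing
#' along both axes — the shape of the shared-SNP surface against sequencing
#' depth and completeness.
#'
#' @param genotypes,depth As in [apply_snp_filter()].
#' @param depth_grid Integer vector of depth thresholds.
#' @param callrate_grid Numeric vector of call-rate requirements in (0, 1].
#' @param qual,min_qual Optional site-quality pre-filter applied before
#'   counting (loci with `qual < min_qual` never counted).
#' @return Integer matrix, rows = depth thresholds, cols = call rates.
#' @export
shared_count_table <- function(genotypes, depth, depth_grid, callrate_grid,
                               qual = NULL, min_qual = NULL) {
  n <- nrow(genotypes)
  keep_qual <- if (!is.null(qual) && !is.null(min_qual)) qual >= min_qual
               else rep(TRUE, ncol(genotypes))
  out <- matrix(0L, length(depth_grid), length(callrate_grid),
                dimnames = list(paste0("depth>=", depth_grid),
                                paste0("callrate>=", callrate_grid)))
  nonmiss <- !is.na(genotypes)
  for (i in seq_along(depth_grid)) {
    cnt <- colSums(nonmiss & depth >= depth_grid[i])
    for (j in seq_along(callrate_grid)) {
      need <- ceiling(callrate_grid[j] * n)
      out[i, j] <- sum(keep_qual & cnt >= need)
    }
  }
  out
}
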