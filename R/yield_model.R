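# Closed-form expected marker yield and shared-SNP retention models.
#
# Sequencing depth per locus per sample is modelled as Poisson with a common
# mean (an overdispersed negative-binomial alternative is available);
# samples are independent, so the number of samples reaching the depth
# threshold at a locus is binomial. Both assumptions are approximations and
# are stated as such in the methods vignette.

#' Expected SNP yield of a reduced-representation library
#'
#' The back-of-envelope design estimate: number of sequenced fragments times
#' fragment length times the per-bp SNP rate. With 1.5 million fragments of
#' 200 bp at 1 SNP per 1,000 bp this gives 300,000 expected markers.
#'
#' @param n_fragments Number of fragments in the library.
#' @param fragment_len Representative fragment length in bp; the default is
#'   the lower bound of the 200-300 bp size-selection window.
#' @param snp_rate Expected SNPs per bp (default 0.001).
#' @return Expected SNP count (numeric).
#' @examples
#' expected_snp_yield(1.5e6, 200, 0.001)  # 300000
#' @export
expected_snp_yield <- function(n_fragments, fragment_len = 200, snp_rate = 0.001) {
  stopifnot(n_fragments >= 0, fragment_len >= 0, snp_rate >= 0, snp_rate < 1)
  n_fragments * fragment_len * snp_rate
}

#' Probability that one sample reaches the depth threshold at a locus
#'
#' Upper tail `P(D >= t)` with `D ~ Poisson(lambda)`, or negative binomial
#' with the same mean when `overdispersion` (the NB size parameter) is given.
#'
#' @param depth_mean Mean reads per locus per sample (lambda >= 0).
#' @param depth_threshold Minimum depth `t` (non-negative integer);
#'   vectorised over both arguments.
#' @param overdispersion Optional negative-binomial size; `NULL` (default)
#'   uses the Poisson model.
#' @return Probability in `[0, 1]`.
#' @examples
#' detection_prob(5, 5)  # ~0.5595
#' @export
detection_prob <- function(depth_mean, depth_threshold, overdispersion = NULL) {
  stopifnot(all(depth_mean >= 0), all(depth_threshold >= 0))
  t <- as.integer(round(depth_threshold))
  if (is.null(overdispersion)) {
    p <- stats::ppois(t - 1L, lambda = depth_mean, lower.tail = FALSE)
  } else {
    p <- stats::pnbinom(t - 1L, size = overdispersion, mu = depth_mean,
                        lower.tail = FALSE)
  }
  # t = 0 is certain regardless of lambda
  p[t <= 0L] <- 1
  p
}

#' Expected number of loci genotyped in at least m of n samples
#'
#' With per-sample detection probability `p = detection_prob(lambda, t)` and
#' independence across samples, the number of samples covering a locus is
#' `Binomial(n, p)`; the expected count of loci shared by at least `m`
#' samples is `L * P(Binomial(n, p) >= m)`.
#'
#' @param n_loci Number of polymorphic loci `L` in the library.
#' @param n_samples Population size `n`.
#' @param depth_mean,depth_threshold,overdispersion See [detection_prob()].
#' @param min_samples Required number of covered samples `m` (`<= n`);
#'   vectorised.
#' @return Expected retained locus count.
#' @export
shared_snp_expectation <- function(n_loci, n_samples, depth_mean,
                                   depth_threshold, min_samples,
                                   overdispersion = NULL) {
  stopifnot(n_loci >= 0, n_samples >= 1, all(min_samples <= n_samples))
  p <- detection_prob(depth_mean, depth_threshold, overdispersion)
  m <- as.integer(round(min_samples))
  tail <- stats::pbinom(m - 1L, size = n_samples, prob = p, lower.tail = FALSE)
  tail[m <= 0L] <- 1
  n_loci * tail
}

#' Expected discovered SNPs versus sequencing amount
#'
#' Converts per-sample sequencing amount into mean locus depth
#' (`lambda = amount / library_bp`, with `library_bp` the total bp of
#' size-selected library fragments) and evaluates
#' [shared_snp_expectation()] on a grid. The curve is non-decreasing in the
#' sequencing amount and plateaus at `n_loci`.
#'
#' @param seq_amounts Numeric vector of per-sample sequencing amounts (bp).
#' @param library_bp Total library size in bp (> 0).
#' @param n_loci,n_samples,depth_threshold,min_samples,overdispersion As in
#'   [shared_snp_expectation()].
#' @return `data.frame` with `seq_amount`, `depth_mean`, `expected_snps`.
#' @export
saturation_curve <- function(seq_amounts, library_bp, n_loci, n_samples,
                             depth_threshold, min_samples,
                             overdispersion = NULL) {
  stopifnot(library_bp > 0, all(seq_amounts >= 0))
  lambda <- seq_amounts / library_bp
  esnp <- vapply(lambda, function(l) {
    shared_snp_expectation(n_loci, n_samples, l, depth_threshold,
                           min_samples, overdispersion)
  }, numeric(1))
  data.frame(seq_amount = seq_amounts, depth_mean = lambda,
             expected_snps = esnp)
}
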