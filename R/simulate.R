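# Synthetic-data generators: genome with planted enzyme sites, biallelic SNP
# population, depth/error observation model, quantitative phenotype with a
# sparse causal architecture, and paired site-prefix reads with truth labels.
#
# Every generator is deterministic given `seed`; each one re-seeds from
# `seed` plus a fixed per-generator offset so generators are individually
# reproducible and composable in any order.

#' Configuration for the synthetic-data generators
#'
#' Defaults are desk-scale but preserve the study ratios of a 500-sample GBS
#' population: 1 SNP per kb, a quantitative trait with mean 21.5 and SD 4.1
#' (mg/g scale), 39 causal loci carrying ~63% of the marker-explained
#' genetic variance, and Poisson sequencing depth.
#'
#' @param genome_len Total genome length in bp (default 2 Mb).
#' @param n_chroms Number of chromosomes (equal lengths).
#' @param site_density Expected planted enzyme sites per kb, split evenly
#'   between the two enzymes (default 2/kb).
#' @param enzymes Length-2 character: the two built-in enzymes whose sites
#'   are planted and whose cut-site remnants prefix simulated reads.
#' @param n_samples Population size (study scale 500).
#' @param snp_rate Expected SNPs per bp (default 0.001).
#' @param maf_low,maf_high Uniform bounds for the alternate-allele frequency.
#' @param depth_mean Mean per-call sequencing depth (Poisson lambda).
#' @param het_miscall_rate Probability a true heterozygote is observed as a
#'   homozygote (the dominant discordance mode in GBS validation data).
#' @param missing_rate Additional missing-call probability beyond depth-0.
#' @param qual_below_frac Fraction of site QUAL values falling below 100
#'   under the lognormal QUAL model.
#' @param n_causal Number of causal loci for the phenotype (study analogue 39).
#' @param target_var_fraction Share of total additive genetic variance
#'   carried by the causal subset (study analogue ~0.63).
#' @param heritability Proportion of (non-sex) phenotypic variance that is
#'   genetic (default 0.5).
#' @param pheno_mean,pheno_sd Marginal trait mean and SD (21.5, 4.1 mg/g).
#' @param sex_effect Additive fixed effect of sex on the trait (mg/g).
#' @param read_len Simulated read length in bp.
#' @param n_read_pairs Number of simulated read pairs.
#' @param qc_violation_rates Named numeric: fractions of read pairs injected
#'   with each QC violation (`bad_prefix`, `high_n`, `low_mean_quality`,
#'   `short_after_trim`).
#' @param seed Integer RNG seed (`NULL` leaves the RNG state alone).
#' @return A list of class `sim_config`.
#' @export
sim_config <- function(genome_len = 2e6,
                       n_chroms = 2L,
                       site_density = 2,
                       enzymes = c("EcoRI", "NlaIII"),
                       n_samples = 500L,
                       snp_rate = 0.001,
                       maf_low = 0.05,
                       maf_high = 0.5,
                       depth_mean = 10,
                       het_miscall_rate = 0.05,
                       missing_rate = 0.02,
                       qual_below_frac = 0.05,
                       n_causal = 39L,
                       target_var_fraction = 0.63,
                       heritability = 0.5,
                       pheno_mean = 21.5,
                       pheno_sd = 4.1,
                       sex_effect = 0.5,
                       read_len = 100L,
                       n_read_pairs = 2000L,
                       qc_violation_rates = c(bad_prefix = 0, high_n = 0,
                                              low_mean_quality = 0,
                                              short_after_trim = 0),
                       seed = 1L) {
  cfg <- list(
    genome_len = genome_len, n_chroms = as.integer(n_chroms),
    site_density = site_density, enzymes = enzymes,
    n_samples = as.integer(n_samples), snp_rate = snp_rate,
    maf_low = maf_low, maf_high = maf_high, depth_mean = depth_mean,
    het_miscall_rate = het_miscall_rate, missing_rate = missing_rate,
    qual_below_frac = qual_below_frac, n_causal = as.integer(n_causal),
    target_var_fraction = target_var_fraction, heritability = heritability,
    pheno_mean = pheno_mean, pheno_sd = pheno_sd, sex_effect = sex_effect,
    read_len = as.integer(read_len), n_read_pairs = as.integer(n_read_pairs),
    qc_violation_rates = qc_violation_rates, seed = seed
  )
  rates <- c(cfg$snp_rate, cfg$maf_low, cfg$maf_high, cfg$het_miscall_rate,
             cfg$missing_rate, cfg$qual_below_frac, cfg$target_var_fraction,
             cfg$heritability)
  if (any(rates < 0 | rates > 1)) stop("rates and fractions must lie in [0, 1]")
  if (cfg$maf_low > cfg$maf_high) stop("maf_low must be <= maf_high")
  if (cfg$depth_mean < 0) stop("depth_mean must be >= 0")
  structure(cfg, class = "sim_config")
}

.sim_seed <- function(cfg, offset) {
  if (!is.null(cfg$seed)) set.seed(as.integer(cfg$seed) + offset)
  invisible(NULL)
}

.rand_bases <- function(n) {
  sample(c("A", "C", "G", "T"), n, replace = TRUE)
}

# Concretise IUPAC letters of a site into random compatible bases.
.concrete_site <- function(site) {
  letters <- strsplit(site, "")[[1]]
  vapply(letters, function(l) {
    opts <- strsplit(IUPAC_CODES[[l]], "")[[1]]
    if (length(opts) == 1L) opts else sample(opts, 1L)
  }, character(1))
}

# Mutate one base inside every site match that is not a planted (truth) site,
# iterating until the only matches left are the planted ones.
.scrub_sites <- function(chars, enzymes, keep_starts = NULL, max_iter = 25L) {
  seq_str <- paste(chars, collapse = "")
  subject <- Biostrings::DNAString(seq_str)
  for (iter in seq_len(max_iter)) {
    dirty <- FALSE
    for (enz in enzymes) {
      hits <- Biostrings::matchPattern(
        Biostrings::DNAString(enz$site), subject, fixed = "subject")
      starts <- BiocGenerics::start(hits)
      truth <- keep_starts[[enz$name]]
      extra <- if (is.null(truth)) starts else setdiff(starts, truth)
      if (length(extra) == 0L) next
      dirty <- TRUE
      protected <- integer(0)
      if (!is.null(keep_starts)) {
        for (nm in names(keep_starts)) {
          w <- nchar(Filter(function(e) e$name == nm, enzymes)[[1]]$site)
          protected <- c(protected,
                         unlist(lapply(keep_starts[[nm]], function(s) s:(s + w - 1L))))
        }
      }
      w <- nchar(enz$site)
      for (s in extra) {
        span <- setdiff(s:(s + w - 1L), protected)
        if (length(span) == 0L) next  # fully inside planted sites; leave it
        pos <- span[ceiling(length(span) / 2)]
        old <- chars[pos]
        chars[pos] <- sample(setdiff(c("A", "C", "G", "T"), old), 1L)
      }
    }
    if (!dirty) break
    subject <- Biostrings::DNAString(paste(chars, collapse = ""))
  }
  chars
}

#' Simulate a genome with planted restriction sites
#'
#' Generates random A/C/G/T chromosomes, removes every accidental occurrence
#' of the two configured enzyme sites, then plants sites at the configured
#' density and records their coordinates. The resulting truth map is exact:
#' [find_cut_positions()] on the simulated genome recovers precisely the
#' planted cut coordinates, which makes the genome a digestion oracle.
#'
#' @param cfg A [sim_config()].
#' @param fasta Optional path; when given the genome is also written as FASTA.
#' @return List with `genome` (named `DNAStringSet`), `sites` (`data.frame`
#'   of `seq_id`, `enzyme`, `start` (0-based site start), `cut` (0-based cut
#'   coordinate)) and `cfg`.
#' @export
simulate_genome <- function(cfg, fasta = NULL) {
  .sim_seed(cfg, 0L)
  enzs <- lapply(cfg$enzymes, get_enzyme)
  chrom_len <- as.integer(round(cfg$genome_len / cfg$n_chroms))
  max_site <- max(vapply(enzs, function(e) nchar(e$site), integer(1)))
  if (cfg$site_density > 0 && chrom_len < max_site) {
    stop("genome too small to hold a single enzyme site")
  }
  seqs <- character(cfg$n_chroms)
  sites <- vector("list", cfg$n_chroms)
  for (ch in seq_len(cfg$n_chroms)) {
    chars <- .rand_bases(chrom_len)
    chars <- .scrub_sites(chars, enzs)
    planted <- list()
    if (cfg$site_density > 0) {
      per_enz <- stats::rpois(length(enzs), chrom_len / 1000 * cfg$site_density /
                                length(enzs))
      # draw non-overlapping planting positions for all enzymes jointly
      widths <- vapply(enzs, function(e) nchar(e$site), integer(1))
      need <- sum(per_enz)
      cand <- sort(sample.int(chrom_len - max_site + 1L,
                              min(need * 3L, chrom_len - max_site + 1L)))
      cand <- cand[c(TRUE, diff(cand) >= max_site + 2L)]
      cand <- cand[seq_len(min(need, length(cand)))]
      cand <- sample(cand)  # shuffle before assigning to enzymes
      used <- 0L
      for (i in seq_along(enzs)) {
        k <- min(per_enz[i], length(cand) - used)
        pos <- sort(cand[used + seq_len(k)])
        used <- used + k
        for (p in pos) {
          chars[p:(p + widths[i] - 1L)] <- .concrete_site(enzs[[i]]$site)
        }
        planted[[enzs[[i]]$name]] <- pos
      }
      chars <- .scrub_sites(chars, enzs, keep_starts = planted)
    }
    seqs[ch] <- paste(chars, collapse = "")
    site_df <- do.call(rbind, lapply(seq_along(enzs), function(i) {
      pos <- planted[[enzs[[i]]$name]]
      if (is.null(pos) || length(pos) == 0L) return(NULL)
      data.frame(seq_id = paste0("chr", ch), enzyme = enzs[[i]]$name,
                 start = sort(pos) - 1L,
                 cut = sort(pos) - 1L + enzs[[i]]$cut_offset,
                 stringsAsFactors = FALSE)
    }))
    sites[[ch]] <- site_df
  }
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- paste0("chr", seq_len(cfg$n_chroms))
  sites <- do.call(rbind, sites)
  if (is.null(sites)) {
    sites <- data.frame(seq_id = character(0), enzyme = character(0),
                        start = integer(0), cut = integer(0))
  }
  rownames(sites) <- NULL
  if (!is.null(fasta)) Biostrings::writeXStringSet(genome, fasta)
  list(genome = genome, sites = sites, cfg = cfg)
}

#' Simulate a biallelic SNP population under Hardy-Weinberg equilibrium
#'
#' Places loci along the genome at `snp_rate` per bp (Poisson count, uniform
#' positions), draws each locus's alternate-allele frequency uniformly in
#' `[maf_low, maf_high]`, and samples genotypes as Binomial(2, p). Genotypes
#' are coded 0/1/2 alternate-allele doses (`NA` = missing).
#'
#' @param cfg A [sim_config()].
#' @param genome Optional result of [simulate_genome()]; when given,
#'   reference alleles are taken from the genome sequence.
#' @return List of class `gbs_population`: `genotypes` (samples x loci
#'   integer matrix), `loci` (`data.frame` of `chrom`, `pos` (1-based), `id`,
#'   `ref`, `alt`, `af`), `sample_ids`, `cfg`.
#' @export
simulate_population <- function(cfg, genome = NULL) {
  .sim_seed(cfg, 1L)
  if (!is.null(genome)) {
    gseq <- genome$genome
    chrom_names <- names(gseq)
    chrom_lens <- BiocGenerics::width(gseq)
  } else {
    gseq <- NULL
    chrom_names <- paste0("chr", seq_len(cfg$n_chroms))
    chrom_lens <- rep(as.integer(round(cfg$genome_len / cfg$n_chroms)),
                      cfg$n_chroms)
  }
  loci <- do.call(rbind, lapply(seq_along(chrom_names), function(ch) {
    n_loc <- stats::rpois(1L, chrom_lens[ch] * cfg$snp_rate)
    n_loc <- min(n_loc, chrom_lens[ch])
    if (n_loc == 0L) return(NULL)
    pos <- sort(sample.int(chrom_lens[ch], n_loc))
    ref <- if (!is.null(gseq)) {
      as.character(Biostrings::extractAt(gseq[[ch]],
                                         IRanges::IRanges(pos, width = 1L)))
    } else {
      .rand_bases(n_loc)
    }
    alt <- vapply(ref, function(r) sample(setdiff(c("A", "C", "G", "T"), r), 1L),
                  character(1), USE.NAMES = FALSE)
    data.frame(chrom = chrom_names[ch], pos = pos,
               id = paste0(chrom_names[ch], "_", pos),
               ref = ref, alt = alt,
               af = stats::runif(n_loc, cfg$maf_low, cfg$maf_high),
               stringsAsFactors = FALSE)
  }))
  if (is.null(loci) || nrow(loci) == 0L) stop("no loci simulated; increase genome_len or snp_rate")
  rownames(loci) <- NULL
  n <- cfg$n_samples
  L <- nrow(loci)
  G <- matrix(stats::rbinom(n * L, 2L, rep(loci$af, each = n)), nrow = n, ncol = L)
  sample_ids <- sprintf("S%04d", seq_len(n))
  dimnames(G) <- list(sample_ids, loci$id)
  structure(list(genotypes = G, loci = loci, sample_ids = sample_ids, cfg = cfg),
            class = "gbs_population")
}

#' Observe a true genotype matrix through a depth/error model
#'
#' Per-call depth is Poisson(`depth_mean`); depth-0 calls are missing; true
#' heterozygotes are miscalled to a random homozygote with
#' `het_miscall_rate` (heterozygote dropout being the dominant GBS
#' discordance mode); extra calls go missing at `missing_rate`; site QUAL is
#' lognormal with a `qual_below_frac` lower tail below 100.
#'
#' @param pop A `gbs_population` from [simulate_population()].
#' @param cfg A [sim_config()] (defaults to `pop$cfg`).
#' @return List of class `gbs_observation`: `genotypes` (observed, `NA` =
#'   missing), `depth`, `qual`, `loci`, `sample_ids`, `truth` (the input
#'   matrix), `cfg`.
#' @export
simulate_observations <- function(pop, cfg = pop$cfg) {
  .sim_seed(cfg, 2L)
  G <- pop$genotypes
  n <- nrow(G); L <- ncol(G)
  dp <- matrix(stats::rpois(n * L, cfg$depth_mean), n, L, dimnames = dimnames(G))
  obs <- G
  obs[dp == 0L] <- NA_integer_
  het <- which(!is.na(obs) & obs == 1L)
  if (length(het) > 0L && cfg$het_miscall_rate > 0) {
    flip <- het[stats::runif(length(het)) < cfg$het_miscall_rate]
    obs[flip] <- sample(c(0L, 2L), length(flip), replace = TRUE)
  }
  if (cfg$missing_rate > 0) {
    drop <- which(stats::runif(n * L) < cfg$missing_rate)
    obs[drop] <- NA_integer_
  }
  sigma <- 0.5
  mu <- log(100) - sigma * stats::qnorm(cfg$qual_below_frac)
  qual <- stats::rlnorm(L, meanlog = mu, sdlog = sigma)
  names(qual) <- colnames(G)
  structure(list(genotypes = obs, depth = dp, qual = qual, loci = pop$loci,
                 sample_ids = pop$sample_ids, truth = G, cfg = cfg),
            class = "gbs_observation")
}

#' Simulate a quantitative phenotype with a sparse causal architecture
#'
#' Builds `y = mu + sum_j beta_j g_j + delta * sex + e` with genotype doses
#' `g in {0,1,2}`. `n_causal` loci receive large effects and all remaining
#' loci a small polygenic background, rescaled so the causal subset carries
#' `target_var_fraction` of the total additive variance; environmental noise
#' is scaled for heritability `heritability`; the whole trait is scaled to
#' marginal mean `pheno_mean` and SD `pheno_sd`. Sex is Bernoulli(0.5).
#'
#' @param pop A `gbs_population`.
#' @param cfg A [sim_config()] (defaults to `pop$cfg`).
#' @return List of class `gbs_phenotype`: `pheno` (`data.frame` of
#'   `sample_id`, `trait`, `sex`), `effects` (per-locus trait-scale effects),
#'   `causal` (causal locus ids), `var_fraction` (realised causal share of
#'   additive variance), `heritability` (realised), `cfg`.
#' @export
simulate_phenotype <- function(pop, cfg = pop$cfg) {
  .sim_seed(cfg, 3L)
  G <- pop$genotypes
  n <- nrow(G); L <- ncol(G)
  if (cfg$n_causal > L) stop("n_causal exceeds the number of simulated loci")
  sex <- stats::rbinom(n, 1L, 0.5)
  causal_idx <- if (cfg$n_causal > 0L) sort(sample.int(L, cfg$n_causal)) else integer(0)
  beta <- numeric(L)

  g_causal <- rep(0, n)
  if (length(causal_idx) > 0L) {
    beta_c <- stats::rnorm(length(causal_idx))
    g_causal <- drop(G[, causal_idx, drop = FALSE] %*% beta_c)
    beta[causal_idx] <- beta_c
  }
  g_back <- rep(0, n)
  back_idx <- setdiff(seq_len(L), causal_idx)
  f <- cfg$target_var_fraction
  if (length(back_idx) > 0L && length(causal_idx) > 0L && f < 1) {
    beta_b <- stats::rnorm(length(back_idx))
    g_back <- drop(G[, back_idx, drop = FALSE] %*% beta_b)
    vb <- stats::var(g_back)
    if (vb > 0) {
      s_b <- sqrt(stats::var(g_causal) * (1 - f) / (f * vb))
      g_back <- g_back * s_b
      beta[back_idx] <- beta_b * s_b
    }
  }
  g_tot <- g_causal + g_back
  var_g <- stats::var(g_tot)
  h2 <- cfg$heritability
  e <- stats::rnorm(n)
  var_e <- if (var_g > 0 && h2 > 0) var_g * (1 - h2) / h2 else 1
  e <- e * sqrt(var_e) / stats::sd(e)
  z <- g_tot + e
  target_var <- cfg$pheno_sd^2 - cfg$sex_effect^2 * 0.25
  if (target_var <= 0) stop("sex_effect too large for the requested pheno_sd")
  s <- sqrt(target_var / stats::var(z))
  y <- cfg$pheno_mean + cfg$sex_effect * (sex - 0.5) + s * (z - mean(z))

  realised_fraction <- if (var_g > 0) stats::var(g_causal) / var_g else NA_real_
  realised_h2 <- if (var_g > 0) stats::var(s * g_tot) / stats::var(y) else 0
  structure(list(
    pheno = data.frame(sample_id = pop$sample_ids, trait = y, sex = sex,
                       stringsAsFactors = FALSE),
    effects = data.frame(id = pop$loci$id, beta = beta * s,
                         causal = seq_len(L) %in% causal_idx,
                         stringsAsFactors = FALSE),
    causal = pop$loci$id[causal_idx],
    var_fraction = realised_fraction,
    heritability = realised_h2,
    cfg = cfg
  ), class = "gbs_phenotype")
}

#' Simulate paired site-prefix reads with QC-violation truth labels
#'
#' Draws read pairs from size-selected fragments. Each mate starts with the
#' post-cut remnant of the enzyme at its fragment end (`AATTC` for EcoRI,
#' `CATG` for NlaIII), followed by fragment sequence, padded with random
#' bases to `read_len`. Configured fractions of pairs are injected with one
#' QC violation each (non-site prefix; >5% N; mean quality < 20; a
#' low-quality tail long enough that trimming leaves < 50 bp), and every
#' pair carries a truth label naming its violation (or `"none"`).
#'
#' @param genome Result of [simulate_genome()] (or a `DNAStringSet`).
#' @param fragments Fragment table from [digest_genome()], typically after
#'   [size_select()]; only fragments with two enzyme ends are used.
#' @param cfg A [sim_config()].
#' @return List of class `gbs_reads`: `id`, `seq1`, `seq2` (character),
#'   `qual1`, `qual2` (lists of integer Phred vectors), `truth`
#'   (`data.frame` of `id`, `violation`).
#' @export
simulate_reads <- function(genome, fragments, cfg) {
  .sim_seed(cfg, 4L)
  gseq <- if (methods::is(genome, "DNAStringSet")) genome else genome$genome
  prefix_map <- c(EcoRI = "AATTC", NlaIII = "CATG", PstI = "G", ApeKI = "CWGC",
                  BstNI = "WGG")
  ok <- fragments$left_end %in% names(prefix_map) &
    fragments$right_end %in% names(prefix_map)
  frg <- fragments[ok, , drop = FALSE]
  if (nrow(frg) == 0L) stop("no fragments with two enzyme ends to sequence")

  n_pairs <- cfg$n_read_pairs
  rl <- cfg$read_len
  rates <- cfg$qc_violation_rates
  kinds <- c("none", names(rates))
  probs <- c(max(0, 1 - sum(rates)), rates)
  violation <- sample(kinds, n_pairs, replace = TRUE, prob = probs)
  pick <- sample.int(nrow(frg), n_pairs, replace = TRUE)

  make_read <- function(prefix, body) {
    s <- paste0(prefix, body)
    if (nchar(s) < rl) {
      s <- paste0(s, paste(.rand_bases(rl - nchar(s)), collapse = ""))
    }
    substr(s, 1L, rl)
  }
  seq1 <- character(n_pairs); seq2 <- character(n_pairs)
  qual1 <- vector("list", n_pairs); qual2 <- vector("list", n_pairs)
  for (i in seq_len(n_pairs)) {
    fr <- frg[pick[i], ]
    body <- as.character(Biostrings::subseq(gseq[[fr$seq_id]],
                                            fr$start + 1L, fr$end))
    seq1[i] <- make_read(prefix_map[[fr$left_end]], body)
    seq2[i] <- make_read(prefix_map[[fr$right_end]],
                         as.character(Biostrings::reverseComplement(
                           Biostrings::DNAString(body))))
    qual1[[i]] <- sample(33:40, rl, replace = TRUE)
    qual2[[i]] <- sample(33:40, rl, replace = TRUE)
    v <- violation[i]
    if (v == "bad_prefix") {
      substr(seq1[i], 1L, 5L) <- "TTTTT"
    } else if (v == "high_n") {
      k <- ceiling(0.05 * rl) + 2L
      pos <- 6L:(5L + k)
      for (p in pos) substr(seq1[i], p, p) <- "N"
    } else if (v == "low_mean_quality") {
      qual1[[i]] <- rep(10L, rl)
    } else if (v == "short_after_trim") {
      n_tail <- ceiling(0.56 * rl)
      qual1[[i]] <- c(rep(45L, rl - n_tail), rep(2L, n_tail))
    }
  }
  ids <- sprintf("pair%06d", seq_len(n_pairs))
  structure(list(id = ids, seq1 = seq1, seq2 = seq2,
                 qual1 = qual1, qual2 = qual2,
                 truth = data.frame(id = ids, violation = violation,
                                    stringsAsFactors = FALSE)),
            class = "gbs_reads")
}
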