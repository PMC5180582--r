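test_that("simulated genomes are deterministic with an exact site truth map", {
  cfg <- sim_config(genome_len = 2e5, n_chroms = 2, seed = 21)
  g1 <- simulate_genome(cfg)
  g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_identical(g1$sites, g2$sites)
  # every planted cut is found, and nothing else, for both enzymes
  for (enz in c("EcoRI", "NlaIII")) {
    for (ch in names(g1$genome)) {
      truth <- sort(g1$sites$cut[g1$sites$enzyme == enz & g1$sites$seq_id == ch])
      found <- find_cut_positions(g1$genome[[ch]], enz)
      expect_identical(as.integer(truth), as.integer(found))
    }
  }
  # FASTA round-trip is byte-identical under the same seed
  f1 <- tempfile(fileext = ".fa"); f2 <- tempfile(fileext = ".fa")
  simulate_genome(cfg, fasta = f1)
  simulate_genome(cfg, fasta = f2)
  expect_identical(readLines(f1), readLines(f2))
})

test_that("site density zero gives one fragment per chromosome", {
  cfg <- sim_config(genome_len = 1e5, n_chroms = 3, site_density = 0, seed = 5)
  g <- simulate_genome(cfg)
  fr <- digest_genome(g$genome, "EcoRI", "NlaIII")
  expect_equal(nrow(fr), 3L)
  expect_true(all(fr$left_end == "terminus" & fr$right_end == "terminus"))
})

test_that("population simulation places loci at the SNP rate under HWE", {
  cfg <- sim_config(genome_len = 1e6, n_chroms = 1, n_samples = 200, seed = 13)
  pop <- simulate_population(cfg)
  L <- ncol(pop$genotypes)
  expect_lt(abs(L - 1000), 3 * sqrt(1000))
  expect_true(all(pop$genotypes %in% 0:2))
  expect_true(all(pop$loci$ref != pop$loci$alt))
  # determinism
  pop2 <- simulate_population(cfg)
  expect_identical(pop$genotypes, pop2$genotypes)
  expect_identical(pop$loci, pop2$loci)
  # allele frequency 0.5 everywhere: mean heterozygosity ~ 2pq = 0.5
  cfg5 <- sim_config(genome_len = 2e5, n_chroms = 1, n_samples = 500,
                     maf_low = 0.5, maf_high = 0.5, seed = 13)
  pop5 <- simulate_population(cfg5)
  expect_lt(abs(mean(pop5$genotypes == 1) - 0.5), 0.02)
  # truth VCF round-trips through the reader
  vf <- tempfile(fileext = ".vcf")
  write_truth_vcf(pop, vf)
  back <- read_vcf_matrix(vf)
  expect_identical(unname(back$genotypes), unname(pop$genotypes))
})

test_that("observation model reproduces its error rates", {
  cfg <- sim_config(genome_len = 4e5, n_chroms = 1, n_samples = 200,
                    maf_low = 0.4, maf_high = 0.5, seed = 31,
                    het_miscall_rate = 0.1, missing_rate = 0.05)
  pop <- simulate_population(cfg)
  obs <- simulate_observations(pop)

  # high depth + zero error rates: observation is the truth
  cfg0 <- sim_config(genome_len = 2e5, n_chroms = 1, n_samples = 100,
                     depth_mean = 1000, het_miscall_rate = 0,
                     missing_rate = 0, seed = 31)
  pop0 <- simulate_population(cfg0)
  obs0 <- simulate_observations(pop0)
  expect_identical(obs0$genotypes, pop0$genotypes)

  # heterozygote miscalls: binomial check on observed hets turned homozygous
  # (the missing-rate mask is independent of the flip, so the rate among
  # non-missing cells is still het_miscall_rate)
  het_truth <- pop$genotypes == 1 & !is.na(obs$genotypes)
  n_het <- sum(het_truth)
  n_flip <- sum(obs$genotypes[het_truth] != 1, na.rm = TRUE)
  expect_gt(n_het, 10000)
  expect_lt(abs(n_flip - n_het * 0.1), 3 * sqrt(n_het * 0.1 * 0.9))

  # overall missingness: depth-0 (negligible at lambda 10) + missing_rate
  frac_miss <- mean(is.na(obs$genotypes))
  n_cells <- length(obs$genotypes)
  p_miss <- 0.05 + dpois(0, 10)
  expect_lt(abs(frac_miss - p_miss), 3 * sqrt(p_miss * (1 - p_miss) / n_cells))

  # QUAL lower tail: configured fraction below 100
  expect_lt(abs(mean(obs$qual < 100) - cfg$qual_below_frac),
            3 * sqrt(0.05 * 0.95 / length(obs$qual)) + 0.01)
})

test_that("phenotype simulation hits the trait scale and causal variance share", {
  cfg <- sim_config(genome_len = 2e6, n_chroms = 2, n_samples = 500, seed = 8)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotype(pop)
  expect_equal(nrow(ph$pheno), 500)
  expect_lt(abs(mean(ph$pheno$trait) - 21.5), 0.5)
  expect_lt(abs(sd(ph$pheno$trait) - 4.1), 0.5)
  expect_equal(length(ph$causal), 39)
  # realised causal share of additive variance near the target
  expect_lt(abs(ph$var_fraction - 0.63), 0.05)
  # recompute the causal share from the truth effects as an independent check
  cg <- pop$genotypes[, ph$effects$causal, drop = FALSE] %*%
    ph$effects$beta[ph$effects$causal]
  ag <- pop$genotypes %*% ph$effects$beta
  expect_lt(abs(var(cg) / var(ag) - ph$var_fraction), 0.02)
  # determinism
  ph2 <- simulate_phenotype(pop)
  expect_identical(ph$pheno, ph2$pheno)

  # no causal loci: pure noise at the requested scale
  cfg0 <- sim_config(genome_len = 2e5, n_chroms = 1, n_samples = 500,
                     n_causal = 0, seed = 8)
  pop0 <- simulate_population(cfg0)
  ph0 <- simulate_phenotype(pop0)
  expect_lt(abs(mean(ph0$pheno$trait) - 21.5), 0.6)
  expect_lt(abs(sd(ph0$pheno$trait) - 4.1), 0.6)
})

test_that("simulated reads carry site prefixes and violation truth labels", {
  cfg <- sim_config(genome_len = 3e5, n_chroms = 1, seed = 17,
                    n_read_pairs = 500)
  g <- simulate_genome(cfg)
  fr <- size_select(digest_genome(g$genome, "EcoRI", "NlaIII"),
                    100, 500, "both_sites")
  rd <- simulate_reads(g, fr, cfg)
  # zero injected violations: every read starts with a cut-site remnant
  expect_true(all(grepl("^(AATTC|CATG)", rd$seq1)))
  expect_true(all(grepl("^(AATTC|CATG)", rd$seq2)))
  expect_true(all(rd$truth$violation == "none"))
  # and the full QC pipeline keeps everything
  qc <- qc_read_pairs(rd)
  expect_equal(length(qc$kept$id), 500L)
  # FASTQ round trip preserves reads and qualities
  r1 <- tempfile(fileext = ".fq"); r2 <- tempfile(fileext = ".fq")
  write_fastq_pairs(rd, r1, r2)
  back <- read_fastq_pairs(r1, r2)
  expect_identical(back$seq1, rd$seq1)
  expect_identical(back$seq2, rd$seq2)
  expect_identical(back$qual1, lapply(rd$qual1, as.integer))
})
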