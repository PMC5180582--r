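test_that("IBS distances match hand computation and handle missingness", {
  G <- rbind(S1 = c(0L, 1L, 2L, 0L),
             S2 = c(0L, 1L, 2L, 0L),
             S3 = c(2L, 1L, 0L, 2L))
  d <- ibs_distance(G)
  expect_equal(diag(d), c(S1 = 0, S2 = 0, S3 = 0))
  expect_equal(d["S1", "S2"], 0)
  # S1 vs S3: |0-2| + |1-1| + |2-0| + |0-2| = 6 over 8 compared alleles
  expect_equal(d["S1", "S3"], 6 / 8)
  expect_equal(d, t(d))
  # opposite homozygotes at every locus: distance 1
  G2 <- rbind(a = rep(0L, 5), b = rep(2L, 5))
  expect_equal(ibs_distance(G2)["a", "b"], 1)
  # missing genotypes are excluded pairwise
  G3 <- rbind(a = c(0L, NA, 2L), b = c(0L, 2L, 0L))
  expect_equal(ibs_distance(G3)["a", "b"], (0 + 2) / 4)
  # no comparable loci: NA with a warning
  G4 <- rbind(a = c(0L, NA), b = c(NA, 1L))
  expect_warning(d4 <- ibs_distance(G4), "no comparable loci")
  expect_true(is.na(d4["a", "b"]))
})

test_that("classical MDS recovers configurations", {
  # three equidistant points embed as an equilateral triangle
  d <- matrix(1, 3, 3) - diag(3)
  pts <- mds(d, 2)
  dd <- as.matrix(dist(pts))
  expect_equal(dd[upper.tri(dd)], rep(1, 3), tolerance = 1e-8)
  # round trip from known 2-D coordinates
  set.seed(4)
  xy <- matrix(rnorm(20), 10, 2)
  d2 <- as.matrix(dist(xy))
  rec <- mds(d2, 2)
  expect_equal(as.matrix(dist(rec)), d2, tolerance = 1e-8,
               ignore_attr = TRUE)
  # agreement with an explicit double-centering oracle (up to sign)
  orc <- mds_oracle(d2, 2)
  for (k in 1:2) {
    expect_equal(abs(rec[, k]), abs(orc[, k]), tolerance = 1e-6,
                 ignore_attr = TRUE)
  }
  # identical samples collapse to one point (degenerate: warnings expected)
  d3 <- matrix(0, 3, 3)
  pts3 <- suppressWarnings(mds(d3, 2))
  expect_lt(max(dist(pts3)), 1e-10)
  expect_error(mds(matrix(c(0, 1, 2, 0), 2, 2)), "symmetric")
})

test_that("the association scan equals the normal-equations oracle", {
  set.seed(61)
  for (rep in 1:5) {
    n <- 12
    G <- matrix(rbinom(n * 6, 2, 0.4), n,
                dimnames = list(sprintf("s%02d", 1:n), paste0("L", 1:6)))
    ph <- data.frame(sample_id = rownames(G),
                     trait = rnorm(n, 21.5, 4.1), sex = rbinom(n, 1, 0.5))
    res <- gwas_scan(G, ph)
    for (j in 1:6) {
      if (var(G[, j]) == 0) {
        expect_true(is.na(res$p[j]))
        next
      }
      orc <- ols_oracle(ph$trait, G[, j], ph$sex)
      expect_equal(res$beta[j], orc$beta, tolerance = 1e-10)
      expect_equal(res$se[j], orc$se, tolerance = 1e-10)
      expect_equal(res$p[j], orc$p, tolerance = 1e-10)
    }
  }
})

test_that("the scan handles noise-free, monomorphic and missing loci", {
  set.seed(62)
  n <- 60
  g <- rbinom(n, 2, 0.5)
  sex <- rbinom(n, 1, 0.5)
  ph <- data.frame(sample_id = sprintf("s%02d", 1:n),
                   trait = 2.5 * g + 21.5, sex = sex)
  G <- cbind(sig = g, mono = rep(1L, n), miss = ifelse(seq_len(n) <= 5, NA, g))
  rownames(G) <- ph$sample_id
  res <- gwas_scan(G, ph)
  expect_equal(res$beta[1], 2.5, tolerance = 1e-8)
  expect_lt(res$p[1], 1e-30)
  expect_true(is.na(res$p[2]))
  expect_equal(res$note[2], "monomorphic")
  # missing-genotype path agrees with lm on complete rows
  fit <- lm(trait ~ g + sex, data = data.frame(trait = ph$trait[-(1:5)],
                                               g = g[-(1:5)],
                                               sex = sex[-(1:5)]))
  expect_equal(res$beta[3], unname(coef(fit)["g"]), tolerance = 1e-10)
  expect_equal(res$n_used[3], n - 5L)
  # fewer than 4 usable samples
  G2 <- cbind(few = c(0L, 1L, 2L, rep(NA_integer_, n - 3)))
  rownames(G2) <- ph$sample_id
  res2 <- gwas_scan(G2, ph)
  expect_true(is.na(res2$p[1]))
  expect_equal(res2$note[1], "too_few_samples")
})

test_that("significance uses an inclusive threshold and exports cleanly", {
  res <- structure(
    data.frame(locus = c("a", "b", "c", "d"),
               beta = 1, se = 1, t = 1,
               p = c(1e-4, 2e-4, 1e-5, NA), n_used = 10, note = ""),
    class = c("assoc_result", "data.frame")
  )
  hits <- significant_hits(res, 1e-4)
  expect_equal(hits$locus, c("c", "a"))  # p = 1e-4 exactly is included
  expect_equal(nrow(significant_hits(res[0, ], 1e-4)), 0L)
  # Bonferroni option tightens the set (only p = 1e-5 survives x4 scaling)
  expect_equal(significant_hits(res, 1e-4, adjust = "bonferroni")$locus, "c")
  # Manhattan export reproduces the scan p-values
  loci <- data.frame(id = c("a", "b", "c", "d"), chrom = "chr1",
                     pos = 1:4)
  man <- manhattan_table(res, loci)
  expect_equal(man$neg_log10_p, -log10(res$p))
  expect_equal(man$pos, 1:4)
})

test_that("the GRM is a VanRaden kernel: PSD, unit-scale diagonal, hand-checkable", {
  set.seed(63)
  G <- matrix(rbinom(4 * 6, 2, 0.5), 4, 6)
  G[1, 1] <- NA  # mean-imputed
  K <- suppressWarnings(grm(G))  # tiny panel: incidental fixed loci excluded
  # hand computation of the same kernel (fixed and zero-variance loci out)
  p <- colMeans(G, na.rm = TRUE) / 2
  vr <- apply(G, 2, var, na.rm = TRUE)
  keep <- p > 0 & p < 1 & vr > 0
  Z <- sweep(G[, keep, drop = FALSE], 2, 2 * p[keep])
  Z[is.na(Z)] <- 0
  K_hand <- Z %*% t(Z) / (2 * sum(p[keep] * (1 - p[keep])))
  expect_equal(unname(K), unname(K_hand), tolerance = 1e-12)
  expect_equal(K, t(K))
  expect_gt(min(eigen(K, symmetric = TRUE)$values), -1e-8)
  # duplicated samples: off-diagonal ~ diagonal
  G2 <- rbind(G, G[4, ])
  K2 <- suppressWarnings(grm(G2))
  expect_equal(K2[4, 5], K2[4, 4], tolerance = 1e-8)
  # larger random panel: mean diagonal near 1
  G3 <- matrix(rbinom(200 * 500, 2, rep(runif(500, 0.1, 0.5), each = 200)),
               200, 500)
  expect_lt(abs(mean(diag(grm(G3))) - 1), 0.1)
  expect_warning(grm(cbind(G, 1L)), "monomorphic")
  expect_error(suppressWarnings(grm(matrix(1L, 5, 3))), "polymorphic")
})

test_that("REML recovers variance components and flags degenerate kernels", {
  set.seed(64)
  # parameter recovery: h2 = 0.5, n = 400, mean over seeds within 0.1
  n <- 400
  h2_hat <- replicate(8, {
    G <- matrix(rbinom(n * 600, 2, rep(runif(600, 0.1, 0.5), each = n)), n, 600)
    K <- grm(G)
    u <- drop(G %*% rnorm(600))
    u <- u / sd(u)
    y <- u + rnorm(n)
    reml_varcomp(y, K)$h2
  })
  expect_lt(abs(mean(h2_hat) - 0.5), 0.1)
  # pure noise: sigma_g2 near zero on average
  K <- grm(matrix(rbinom(100 * 300, 2, 0.3), 100, 300))
  sg <- replicate(10, reml_varcomp(rnorm(100), K)$sigma_g2)
  expect_lt(mean(sg), 0.25)
  # zero kernel: hard error
  expect_error(reml_varcomp(rnorm(20), matrix(0, 20, 20)), "zero")
})

test_that("variance-explained ratio separates causal subsets from noise", {
  cfg <- sim_config(genome_len = 1e6, n_chroms = 1, n_samples = 400, seed = 65)
  pop <- simulate_population(cfg)
  ph <- simulate_phenotype(pop)
  X <- cbind(1, ph$pheno$sex)
  # subset = all markers: ratio ~ 1
  all_ids <- colnames(pop$genotypes)
  ver_all <- variance_explained_ratio(ph$pheno$trait, pop$genotypes,
                                      all_ids, X)
  expect_equal(ver_all$ratio, 1, tolerance = 1e-6)
  # causal subset: ratio near the realised causal fraction
  ver <- variance_explained_ratio(ph$pheno$trait, pop$genotypes,
                                  ph$causal, X)
  expect_true(ver$defined)
  expect_lt(abs(ver$ratio - ph$var_fraction), 0.2)
  # a weak-signal subset (smallest true effects) explains far less
  ord <- order(abs(ph$effects$beta))
  null_ids <- ph$effects$id[ord[1:39]]
  ver0 <- variance_explained_ratio(ph$pheno$trait, pop$genotypes,
                                   null_ids, X)
  expect_lt(ver0$ratio, ver$ratio)
})

test_that("KS normality wraps the one-sample test against fitted normals", {
  x <- c(20.1, 22.3, 19.8, 21.5, 23.0, 18.9, 21.1, 20.5, 22.8, 21.9)
  res <- ks_normality(x)
  # hand oracle: maximum ECDF deviation against the fitted normal
  xs <- sort(x)
  F0 <- pnorm(xs, mean(x), sd(x))
  D_hand <- max(pmax(abs((1:10) / 10 - F0), abs((0:9) / 10 - F0)))
  expect_equal(res$D, D_hand, tolerance = 1e-12)
  # sanity: large normal sample accepted, exponential rejected
  set.seed(66)
  expect_gt(ks_normality(rnorm(1000))$p, 0.05)
  expect_lt(ks_normality(rexp(500))$p, 0.01)
  expect_error(ks_normality(rep(1, 10)), "constant")
  expect_error(ks_normality(1:3), "at least 5")
})
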