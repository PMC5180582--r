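# Association toolkit: IBS distances, classical MDS, single-marker OLS scan
# with a sex covariate, fixed-threshold significance, VanRaden GRM, and
# EMMA-style REML variance components with a subset/all variance-explained
# ratio.

#' Pairwise identity-by-state distances
#'
#' For samples i and j, `d = 1 - shared_alleles / (2 * compared_loci)` where
#' a locus contributes `2 - |g_i - g_j|` shared alleles under 0/1/2 dose
#' coding and loci missing in either sample are excluded for that pair.
#' A pair with no comparable loci gets `NA` (flagged with a warning).
#'
#' @param genotypes Samples x loci dose matrix (0/1/2/`NA`).
#' @return Symmetric matrix of distances in `[0, 1]`, zero diagonal.
#' @export
ibs_distance <- function(genotypes) {
  n <- nrow(genotypes)
  if (n < 2L) stop("at least two samples required")
  ok <- !is.na(genotypes)
  ind <- lapply(0:2, function(v) {
    m <- matrix(0, nrow(genotypes), ncol(genotypes))
    m[ok & genotypes == v] <- 1
    m
  })
  # sum over loci of |gi - gj| decomposed over dose-pair counts
  absdiff <- matrix(0, n, n)
  for (a in 0:2) {
    for (b in 0:2) {
      if (a == b) next
      absdiff <- absdiff + abs(a - b) * (ind[[a + 1L]] %*% t(ind[[b + 1L]]))
    }
  }
  compared <- (ok * 1) %*% t(ok * 1)
  d <- absdiff / (2 * compared)
  if (any(compared == 0)) {
    warning("sample pair(s) with no comparable loci; distance set to NA")
    d[compared == 0] <- NA_real_
  }
  diag(d) <- 0
  dimnames(d) <- list(rownames(genotypes), rownames(genotypes))
  d
}

#' Classical multidimensional scaling of a distance matrix
#'
#' Classical (Torgerson) MDS: double-centre the squared distances and take
#' the top eigenvectors. When fewer than `k` positive eigenvalues exist the
#' dimensionality is reduced with a warning.
#'
#' @param d Symmetric distance matrix with zero diagonal.
#' @param k Number of dimensions (default 2).
#' @return Numeric matrix of sample coordinates (n x k' with k' <= k), with
#'   the eigenvalues in `attr(, "eig")`.
#' @export
mds <- function(d, k = 2L) {
  d <- as.matrix(d)
  if (!isTRUE(all.equal(d, t(d), tolerance = 1e-8)) ||
      any(abs(diag(d)) > 1e-12)) {
    stop("d must be symmetric with a zero diagonal")
  }
  fit <- stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE)
  pos <- sum(fit$eig > max(fit$eig, 0) * 1e-12)
  if (pos < k) {
    warning("only ", pos, " positive eigenvalue(s); returning ",
            max(pos, 1L), " dimension(s)")
  }
  pts <- fit$points
  if (ncol(pts) == 0L || pos == 0L) {
    # fully degenerate configuration: all samples at the origin
    pts <- matrix(0, nrow(d), 1L, dimnames = list(rownames(d), NULL))
  }
  attr(pts, "eig") <- fit$eig
  pts
}

# Per-locus OLS of y ~ 1 + covariates + g, vectorised over loci without
# missing genotypes; loci with missingness fall back to a per-locus fit.
.scan_block <- function(G, y, X) {
  n <- length(y)
  q <- ncol(X)
  XtXi <- solve(crossprod(X))
  resid_on_X <- function(v) v - X %*% (XtXi %*% crossprod(X, v))
  yt <- drop(resid_on_X(y))
  Gt <- G - X %*% (XtXi %*% crossprod(X, G))
  gg <- colSums(Gt^2)
  gy <- colSums(Gt * yt)
  yy <- sum(yt^2)
  df <- n - q - 1L
  beta <- gy / gg
  rss <- yy - beta^2 * gg
  se <- sqrt(pmax(rss, 0) / df / gg)
  tval <- beta / se
  p <- 2 * stats::pt(-abs(tval), df)
  mono <- gg < 1e-12
  beta[mono] <- NA_real_; se[mono] <- NA_real_
  tval[mono] <- NA_real_; p[mono] <- NA_real_
  list(beta = beta, se = se, t = tval, p = p,
       n_used = rep(n, ncol(G)), note = ifelse(mono, "monomorphic", ""))
}

.scan_one_missing <- function(g, y, X) {
  use <- !is.na(g)
  n_used <- sum(use)
  if (n_used < 4L) {
    return(c(beta = NA, se = NA, t = NA, p = NA, n_used = n_used))
  }
  res <- tryCatch(
    .scan_block(matrix(g[use], ncol = 1L), y[use], X[use, , drop = FALSE]),
    error = function(e) list(beta = NA_real_, se = NA_real_,
                             t = NA_real_, p = NA_real_)
  )
  c(beta = res$beta, se = res$se, t = res$t, p = res$p, n_used = n_used)
}

#' Single-marker association scan
#'
#' Ordinary least squares of the trait on each locus's additive dose
#' (AA = 0, AB = 1, BB = 2) with sex as a covariate:
#' `y ~ 1 + g + sex`, two-sided t test on the genotype coefficient.
#' Missing genotypes are excluded per locus; monomorphic loci and loci with
#' fewer than 4 usable samples return `NA` with a reason. Population-
#' structure axes from [mds()] can be supplied as extra covariates but are
#' not included by default.
#'
#' @param genotypes Samples x loci dose matrix.
#' @param pheno `data.frame` with `sample_id`, `trait` and `sex` (0/1)
#'   columns; rows are matched to `rownames(genotypes)` by `sample_id`
#'   (samples missing a phenotype are dropped).
#' @param covariates Optional extra covariate matrix (rows matching
#'   `pheno`).
#' @return `data.frame` of class `assoc_result`: `locus`, `beta`, `se`,
#'   `t`, `p`, `n_used`, `note`.
#' @export
gwas_scan <- function(genotypes, pheno, covariates = NULL) {
  stopifnot(all(c("sample_id", "trait", "sex") %in% names(pheno)))
  ids <- rownames(genotypes)
  if (is.null(ids)) ids <- pheno$sample_id
  m <- match(pheno$sample_id, ids)
  if (anyNA(m)) stop("phenotype sample(s) absent from the genotype matrix")
  G <- genotypes[m, , drop = FALSE]
  y <- pheno$trait
  X <- cbind(intercept = 1, sex = pheno$sex)
  if (!is.null(covariates)) X <- cbind(X, as.matrix(covariates))
  L <- ncol(G)
  loci <- colnames(G)
  if (is.null(loci)) loci <- paste0("locus", seq_len(L))

  has_na <- colSums(is.na(G)) > 0L
  beta <- se <- tval <- p <- rep(NA_real_, L)
  n_used <- integer(L)
  note <- character(L)
  if (any(!has_na)) {
    idx <- which(!has_na)
    # chunk to bound memory on large scans
    step <- 20000L
    for (s in seq(1L, length(idx), by = step)) {
      block <- idx[s:min(s + step - 1L, length(idx))]
      res <- .scan_block(G[, block, drop = FALSE], y, X)
      beta[block] <- res$beta; se[block] <- res$se
      tval[block] <- res$t; p[block] <- res$p
      n_used[block] <- res$n_used; note[block] <- res$note
    }
  }
  for (j in which(has_na)) {
    res <- .scan_one_missing(G[, j], y, X)
    beta[j] <- res["beta"]; se[j] <- res["se"]; tval[j] <- res["t"]
    p[j] <- res["p"]; n_used[j] <- res["n_used"]
    note[j] <- if (res["n_used"] < 4L) "too_few_samples"
               else if (is.na(res["beta"])) "monomorphic" else ""
  }
  out <- data.frame(locus = loci, beta = beta, se = se, t = tval, p = p,
                    n_used = n_used, note = note, stringsAsFactors = FALSE)
  class(out) <- c("assoc_result", "data.frame")
  out
}

#' Significant markers at a fixed p-value threshold
#'
#' Inclusive threshold (`p <= alpha`), no multiple-testing correction by
#' default; Bonferroni or Benjamini-Hochberg adjusted thresholds are
#' available via `adjust`.
#'
#' @param results An `assoc_result` from [gwas_scan()].
#' @param alpha Significance threshold (default 1e-4).
#' @param adjust `"none"` (default), `"bonferroni"` or `"BH"`.
#' @return The significant subset, sorted by p-value.
#' @export
significant_hits <- function(results, alpha = 1e-4,
                             adjust = c("none", "bonferroni", "BH")) {
  adjust <- match.arg(adjust)
  p <- results$p
  keep <- switch(adjust,
    none = !is.na(p) & p <= alpha,
    bonferroni = !is.na(p) & stats::p.adjust(p, "bonferroni") <= alpha,
    BH = !is.na(p) & stats::p.adjust(p, "BH") <= alpha
  )
  out <- results[keep, , drop = FALSE]
  out[order(out$p), , drop = FALSE]
}

#' Manhattan-plot table
#'
#' Joins scan results with locus coordinates into a `(chrom, pos,
#' neg_log10_p)` table.
#'
#' @param results An `assoc_result`.
#' @param loci `data.frame` with `id`, `chrom`, `pos` matching
#'   `results$locus`.
#' @return `data.frame` with `chrom`, `pos`, `locus`, `p`, `neg_log10_p`.
#' @export
manhattan_table <- function(results, loci) {
  m <- match(results$locus, loci$id)
  data.frame(chrom = loci$chrom[m], pos = loci$pos[m],
             locus = results$locus, p = results$p,
             neg_log10_p = -log10(results$p), stringsAsFactors = FALSE)
}

#' Genomic relationship matrix (VanRaden)
#'
#' Centred, allele-frequency-scaled genotype cross-product:
#' `K = Z Z' / (2 * sum(p * (1 - p)))` with `Z = G - 2p`. Missing genotypes
#' are mean-imputed per locus; monomorphic and all-missing loci are excluded
#' with a warning. K is symmetric positive semidefinite with mean diagonal
#' near 1.
#'
#' @param genotypes Samples x loci dose matrix.
#' @return n x n relationship matrix.
#' @export
grm <- function(genotypes) {
  G <- genotypes
  p <- colMeans(G, na.rm = TRUE) / 2
  v <- colMeans(G^2, na.rm = TRUE) - colMeans(G, na.rm = TRUE)^2
  informative <- !is.na(p) & p > 0 & p < 1 & !is.na(v) & v > 0
  if (any(!informative)) {
    warning(sum(!informative), " monomorphic/all-missing locus(i) excluded from the GRM")
  }
  G <- G[, informative, drop = FALSE]
  p <- p[informative]
  if (ncol(G) < 2L) stop("at least two polymorphic loci required")
  Z <- sweep(G, 2L, 2 * p)
  if (anyNA(Z)) {
    Z[is.na(Z)] <- 0  # mean imputation after centring
  }
  K <- tcrossprod(Z) / (2 * sum(p * (1 - p)))
  dimnames(K) <- list(rownames(genotypes), rownames(genotypes))
  K
}

#' REML variance components on a relationship kernel
#'
#' Fits `y = Xb + u + e` with `u ~ N(0, sigma_g2 * K)` and
#' `e ~ N(0, sigma_e2 * I)` by maximising the restricted likelihood over the
#' variance ratio on the spectral decomposition of the projected kernel
#' (the EMMA formulation): with `S` the projection orthogonal to `X` and
#' `xi, U` the non-null eigenpairs of `S(K + I)S` minus one, the restricted
#' likelihood is a one-dimensional function of `delta = sigma_e2/sigma_g2`,
#' maximised by Brent search on the log scale.
#'
#' @param y Numeric response.
#' @param K Symmetric positive semidefinite kernel (e.g. from [grm()]).
#' @param X Fixed-effect design matrix (default intercept only).
#' @param interval Search interval for `log(delta)`.
#' @param tol Brent tolerance on `log(delta)` (default 1e-8).
#' @return List of class `varcomp_fit`: `sigma_g2`, `sigma_e2`,
#'   `h2 = sigma_g2/(sigma_g2+sigma_e2)`, `loglik`, `boundary` (`TRUE` when
#'   the optimum sits at the edge of the search interval, i.e. a variance
#'   component is effectively 0), `converged`.
#' @export
reml_varcomp <- function(y, K, X = NULL, interval = c(-25, 25), tol = 1e-8) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1L)
  X <- as.matrix(X)
  q <- qr(X)$rank
  if (n < q + 2L) stop("too few samples for the fixed effects")
  stopifnot(nrow(K) == n, ncol(K) == n)
  if (max(abs(K)) < 1e-12) stop("kernel is (numerically) zero; no genetic signal to fit")
  XtXi <- solve(crossprod(X))
  S <- diag(n) - X %*% XtXi %*% t(X)
  B <- S %*% (K + diag(n)) %*% S
  B <- (B + t(B)) / 2
  ev <- eigen(B, symmetric = TRUE)
  keep <- seq_len(n - q)
  xi <- pmax(ev$values[keep] - 1, 0)
  U <- ev$vectors[, keep, drop = FALSE]
  eta2 <- drop(crossprod(U, y))^2
  nq <- n - q

  negll <- function(logdelta) {
    delta <- exp(logdelta)
    denom <- xi + delta
    R <- sum(eta2 / denom)
    -0.5 * (nq * (log(nq / (2 * pi)) - 1 - log(R)) - sum(log(denom)))
  }
  opt <- stats::optimize(negll, interval = interval, tol = tol)
  # compare against the interval edges to catch boundary solutions
  cand <- c(opt$minimum, interval)
  vals <- c(opt$objective, negll(interval[1]), negll(interval[2]))
  best <- cand[which.min(vals)]
  boundary <- min(abs(best - interval)) < 1e-6
  delta <- exp(best)
  sigma_g2 <- sum(eta2 / (xi + delta)) / nq
  sigma_e2 <- delta * sigma_g2
  if (best >= interval[2] - 1e-6) sigma_g2 <- 0  # delta -> Inf limit
  structure(list(
    sigma_g2 = sigma_g2, sigma_e2 = sigma_e2,
    h2 = if (sigma_g2 + sigma_e2 > 0) sigma_g2 / (sigma_g2 + sigma_e2) else NA_real_,
    loglik = -min(vals), log_delta = best,
    boundary = boundary, converged = TRUE
  ), class = "varcomp_fit")
}

#' Ratio of genetic variance explained by a marker subset
#'
#' Fits [reml_varcomp()] twice with identical covariates — once with the GRM
#' built from the marker subset, once with the GRM from all markers — and
#' reports `sigma_g2(subset) / sigma_g2(all)`. When either fit puts the
#' genetic variance at the zero boundary the ratio is `NA` and flagged.
#'
#' @param y Trait values.
#' @param genotypes Samples x loci dose matrix (all markers).
#' @param subset Column indices or names of the marker subset.
#' @param X Fixed-effect design (default intercept; supply sex as used in
#'   the scan).
#' @return List with `ratio`, `fit_subset`, `fit_all`, `defined`.
#' @export
variance_explained_ratio <- function(y, genotypes, subset, X = NULL) {
  if (is.character(subset)) subset <- match(subset, colnames(genotypes))
  if (anyNA(subset)) stop("subset markers absent from the genotype matrix")
  K_sub <- grm(genotypes[, subset, drop = FALSE])
  K_all <- grm(genotypes)
  fit_sub <- reml_varcomp(y, K_sub, X)
  fit_all <- reml_varcomp(y, K_all, X)
  defined <- fit_all$sigma_g2 > 0 && !fit_all$boundary && !fit_sub$boundary
  list(ratio = if (defined) fit_sub$sigma_g2 / fit_all$sigma_g2 else NA_real_,
       fit_subset = fit_sub, fit_all = fit_all, defined = defined)
}

#' Kolmogorov-Smirnov normality check
#'
#' One-sample KS statistic of the trait against a normal distribution with
#' the sample mean and SD (no small-sample correction for the estimated
#' parameters), asymptotic p-value from the Kolmogorov distribution.
#'
#' @param x Numeric vector (`n >= 5`, non-constant).
#' @return List with `D` and `p`.
#' @export
ks_normality <- function(x) {
  x <- x[!is.na(x)]
  if (length(x) < 5L) stop("need at least 5 observations")
  if (stats::sd(x) == 0) stop("constant trait vector")
  kt <- suppressWarnings(stats::ks.test(x, "pnorm", mean(x), stats::sd(x)))
  list(D = unname(kt$statistic), p = unname(kt$p.value))
}
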