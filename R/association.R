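# SNP filtering, SNP-in-locus annotation with exon/intron context,
# observed heterozygosity, VanRaden kinship, EMMA-style REML variance
# components, and the Q+K mixed-linear-model association scan.

#' Per-SNP call rate, minor allele frequency and heterozygosity
#'
#' @param gt a `GenotypeTable`.
#' @return data.frame: snp_id, call_rate, maf, het (observed
#'   heterozygosity among non-missing calls; `NA` for all-missing SNPs).
#' @export
snp_stats <- function(gt) {
  stopifnot(inherits(gt, "GenotypeTable"))
  calls <- gt$calls
  n <- ncol(calls)
  nm <- rowSums(!is.na(calls))
  nb <- rowSums(calls == "AB", na.rm = TRUE) +
    2L * rowSums(calls == "BB", na.rm = TRUE)
  f <- ifelse(nm > 0L, nb / (2L * nm), NA_real_)
  data.frame(snp_id = gt$snps$snp_id,
             call_rate = nm / n,
             maf = pmin(f, 1 - f),
             het = ifelse(nm > 0L,
                          rowSums(calls == "AB", na.rm = TRUE) / nm,
                          NA_real_),
             stringsAsFactors = FALSE)
}

#' Filter SNPs on minor allele frequency and call rate
#'
#' Retains SNPs with `MAF > maf_min` and call rate `> call_rate_min`,
#' both strict; MAF is computed on non-missing calls only.
#'
#' @param gt a `GenotypeTable`.
#' @param maf_min minimum MAF, exclusive (default 0.05).
#' @param call_rate_min minimum call rate, exclusive (default 0.80).
#' @return The filtered `GenotypeTable` (possibly empty).
#' @export
filter_snps <- function(gt, maf_min = 0.05, call_rate_min = 0.80) {
  st <- snp_stats(gt)
  keep <- !is.na(st$maf) & st$maf > maf_min & st$call_rate > call_rate_min
  genotype_table(gt$snps[keep, , drop = FALSE],
                 gt$calls[keep, , drop = FALSE])
}

#' Observed heterozygosity of one SNP
#'
#' Fraction of non-missing individuals that are heterozygous.
#'
#' @param calls character vector of `"AA"`/`"AB"`/`"BB"`/`NA` calls.
#' @return Het in `[0, 1]`.
#' @export
observed_heterozygosity <- function(calls) {
  nm <- !is.na(calls)
  if (!any(nm)) stop("all calls missing: heterozygosity undefined")
  mean(calls[nm] == "AB")
}

#' Locate SNPs within lncRNA loci
#'
#' A SNP is assigned to every locus whose span contains its position (the
#' same position can annotate two overlapping loci). The context is
#' `exon` when the position falls inside the union of member-transcript
#' exons of that locus, else `intron`.
#'
#' @param gt a `GenotypeTable`.
#' @param loci an `LncRnaLociSet`.
#' @param ts the `TranscriptSet` the loci were built from.
#' @return data.frame of `SnpRecord` rows: snp_id, locus_id, chrom, pos,
#'   context, maf, call_rate, het.
#' @export
snps_in_lncrna <- function(gt, loci, ts) {
  stopifnot(inherits(gt, "GenotypeTable"), inherits(loci, "LncRnaLociSet"))
  st <- snp_stats(gt)
  lx <- locus_exons(loci, ts)
  out <- list()
  for (j in seq_len(nrow(loci$loci))) {
    l <- loci$loci[j, ]
    hit <- which(gt$snps$chrom == l$chrom & gt$snps$pos >= l$start &
                   gt$snps$pos <= l$end)
    if (!length(hit)) next
    le <- lx[lx$locus_id == l$locus_id, , drop = FALSE]
    in_exon <- vapply(gt$snps$pos[hit], function(p)
      any(p >= le$start & p <= le$end), NA)
    out[[length(out) + 1L]] <- data.frame(
      snp_id = gt$snps$snp_id[hit], locus_id = l$locus_id,
      chrom = l$chrom, pos = gt$snps$pos[hit],
      context = ifelse(in_exon, "exon", "intron"),
      maf = st$maf[hit], call_rate = st$call_rate[hit], het = st$het[hit],
      stringsAsFactors = FALSE)
  }
  if (!length(out))
    return(data.frame(snp_id = character(0), locus_id = character(0),
                      chrom = character(0), pos = integer(0),
                      context = character(0), maf = numeric(0),
                      call_rate = numeric(0), het = numeric(0),
                      stringsAsFactors = FALSE))
  res <- do.call(rbind, out)
  res <- res[order(res$locus_id, res$pos), , drop = FALSE]
  rownames(res) <- NULL
  res
}

.dosage_imputed <- function(gt) {
  d <- genotype_dosage(gt)
  mu <- rowMeans(d, na.rm = TRUE)
  for (i in seq_len(nrow(d)))
    if (anyNA(d[i, ])) d[i, is.na(d[i, ])] <- mu[i]
  storage.mode(d) <- "double"
  d
}

#' VanRaden kinship matrix
#'
#' Centered-genotype cross-product: with dosage matrix `X` (individuals x
#' SNPs, missing calls mean-imputed per SNP) and allele frequencies `p`,
#' `K = (X - 2p)(X - 2p)' / (2 * sum(p * (1 - p)))`. Monomorphic SNPs are
#' dropped.
#'
#' @param gt a `GenotypeTable` (typically already filtered).
#' @return Symmetric `n x n` kinship matrix with individual dimnames.
#' @export
kinship_matrix <- function(gt) {
  d <- .dosage_imputed(gt)           # SNPs x individuals
  p <- rowMeans(d) / 2
  poly <- p > 0 & p < 1
  if (!any(poly)) stop("no polymorphic SNPs: kinship undefined")
  d <- d[poly, , drop = FALSE]
  p <- p[poly]
  z <- t(d - 2 * p)                  # individuals x SNPs, centered
  k <- z %*% t(z) / (2 * sum(p * (1 - p)))
  (k + t(k)) / 2
}

# profile REML log-likelihood for lambda = sg2/se2 given the spectral
# decomposition of K (EMMA-style)
.reml_ll <- function(log_lambda, d, yt, xt) {
  lambda <- exp(log_lambda)
  w <- 1 / (lambda * d + 1)
  n <- length(yt); p <- ncol(xt)
  xtw <- xt * w
  xwx <- crossprod(xt, xtw)
  beta <- tryCatch(solve(xwx, crossprod(xtw, yt)),
                   error = function(e) NULL)
  if (is.null(beta)) return(-Inf)
  r <- yt - xt %*% beta
  rss <- sum(w * r^2)
  if (!is.finite(rss) || rss <= 0) return(-Inf)
  ld <- determinant(xwx, logarithm = TRUE)$modulus
  -0.5 * ((n - p) * log(rss) + sum(log(lambda * d + 1)) + as.numeric(ld))
}

#' REML variance components under a kinship random effect
#'
#' Fits `y = X b + g + e` with `g ~ N(0, sg2 K)` and `e ~ N(0, se2 I)` by
#' restricted maximum likelihood: the profile likelihood in
#' `lambda = sg2 / se2` is evaluated on a log-spaced grid via the
#' spectral decomposition of `K`, then refined with Brent search in the
#' best bracket. Deterministic for fixed inputs.
#'
#' @param y numeric phenotype vector.
#' @param X fixed-effect design matrix (intercept plus covariates); a
#'   plain vector is treated as a one-column matrix. `NULL` means
#'   intercept only.
#' @param K symmetric kinship matrix.
#' @return List: `sg2`, `se2`, `lambda`, `h2` (`sg2 / (sg2 + se2)`), and
#'   the eigen decomposition reused by [mlm_scan()].
#' @export
reml_variance_components <- function(y, X = NULL, K) {
  n <- length(y)
  if (is.null(X)) X <- matrix(1, n, 1)
  X <- as.matrix(X)
  if (!all(abs(K - t(K)) < 1e-8)) stop("K must be symmetric")
  if (n < ncol(X) + 2L) stop("too few observations for the fixed effects")
  if (qr(X)$rank < ncol(X)) stop("fixed-effect design is rank deficient")
  ek <- eigen(K, symmetric = TRUE)
  d <- pmax(ek$values, 0)
  yt <- drop(crossprod(ek$vectors, y))
  xt <- crossprod(ek$vectors, X)
  grid <- seq(log(1e-5), log(1e5), length.out = 61L)
  ll <- vapply(grid, .reml_ll, 0, d = d, yt = yt, xt = xt)
  if (all(!is.finite(ll)))
    stop("non-finite REML likelihood over the whole lambda bracket [",
         format(exp(grid[1L])), ", ", format(exp(grid[length(grid)])), "]")
  i <- which.max(ll)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(length(grid), i + 1L)]
  opt <- optimize(.reml_ll, c(lo, hi), d = d, yt = yt, xt = xt,
                  maximum = TRUE, tol = 1e-8)
  lambda <- exp(opt$maximum)
  # boundary: effectively no genetic variance
  if (.reml_ll(log(1e-8), d, yt, xt) >= opt$objective) lambda <- 0
  w <- 1 / (lambda * d + 1)
  xtw <- xt * w
  beta <- solve(crossprod(xt, xtw), crossprod(xtw, yt))
  rss <- sum(w * (yt - xt %*% beta)^2)
  se2 <- rss / (n - ncol(X))
  sg2 <- lambda * se2
  list(sg2 = sg2, se2 = se2, lambda = lambda, h2 = sg2 / (sg2 + se2),
       eigen = ek)
}

#' Q+K mixed-linear-model association scan
#'
#' Per-SNP generalized least squares under covariance
#' `sg2 * K + se2 * I`, with fixed effects intercept, population
#' covariates Q (last column dropped against the intercept) and the SNP
#' dosage (0/1/2, missing mean-imputed). Variance components are
#' estimated once under the null model and reused for every SNP
#' (EMMA/EMMAX-style). The SNP coefficient is Wald-tested with a t
#' reference on `n - p` degrees of freedom, so with `sg2 = 0` the scan
#' reduces exactly to ordinary regression.
#'
#' @param y named or plain numeric phenotype vector (one trait).
#' @param gt a `GenotypeTable` of filtered SNPs (same individuals,
#'   same order).
#' @param Q population-membership matrix (rows sum to 1), or `NULL` for
#'   no structure covariates.
#' @param K kinship matrix; `NULL` computes it from `gt` with
#'   [kinship_matrix()].
#' @param cutoff significance cutoff on the p-value (default 1e-3,
#'   strict `<`).
#' @param trait trait name recorded in the output.
#' @return data.frame of `AssociationResult` rows sorted by p-value:
#'   snp_id, trait, effect, stat, p_value, neglog10_p, significant.
#'   Monomorphic SNPs are skipped with a warning.
#' @export
mlm_scan <- function(y, gt, Q = NULL, K = NULL, cutoff = 1e-3,
                     trait = "trait") {
  stopifnot(inherits(gt, "GenotypeTable"))
  n <- length(y)
  if (ncol(gt$calls) != n)
    stop("phenotype and genotype individual counts differ")
  if (is.null(K)) K <- kinship_matrix(gt)
  X0 <- matrix(1, n, 1)
  if (!is.null(Q)) {
    Q <- as.matrix(Q)
    if (ncol(Q) > 1L) Q <- Q[, -ncol(Q), drop = FALSE]
    X0 <- cbind(X0, Q)
  }
  vc <- reml_variance_components(y, X0, K)
  ek <- vc$eigen
  w <- 1 / (vc$sg2 * pmax(ek$values, 0) + vc$se2)
  yt <- drop(crossprod(ek$vectors, y))
  x0t <- crossprod(ek$vectors, X0)
  dos <- .dosage_imputed(gt)
  res <- vector("list", nrow(dos))
  for (i in seq_len(nrow(dos))) {
    x <- dos[i, ]
    if (var(x) == 0) {
      warning("skipping monomorphic SNP ", gt$snps$snp_id[i])
      next
    }
    xt <- cbind(x0t, drop(crossprod(ek$vectors, x)))
    p <- ncol(xt)
    xtw <- xt * w
    xwx <- crossprod(xt, xtw)
    beta <- solve(xwx, crossprod(xtw, yt))
    r <- yt - xt %*% beta
    scale <- sum(w * r^2) / (n - p)
    covb <- solve(xwx) * scale
    eff <- beta[p]
    se <- sqrt(covb[p, p])
    tstat <- eff / se
    pval <- 2 * pt(-abs(tstat), n - p)
    res[[i]] <- data.frame(snp_id = gt$snps$snp_id[i], trait = trait,
                           effect = eff, stat = tstat, p_value = pval,
                           neglog10_p = -log10(pval),
                           significant = pval < cutoff,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  if (is.null(out))
    return(data.frame(snp_id = character(0), trait = character(0),
                      effect = numeric(0), stat = numeric(0),
                      p_value = numeric(0), neglog10_p = numeric(0),
                      significant = logical(0), stringsAsFactors = FALSE))
  out <- out[order(out$p_value), , drop = FALSE]
  rownames(out) <- NULL
  out
}
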