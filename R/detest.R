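#' Trimmed mean of M-values normalization factors
#'
#' Re-implementation of TMM scaling for count matrices: a reference sample is
#' chosen as the one whose upper-quartile (of library-scaled counts) is
#' closest to the mean upper-quartile; per sample, genewise log-ratios (M)
#' and average log-abundances (A) against the reference are doubly trimmed
#' (30% of M tails, 5% of A tails) and the factor is the precision-weighted
#' mean of the remaining M values. Factors are scaled so their geometric mean
#' is 1.
#'
#' @param mat Count matrix, genes x samples (>= 2 samples).
#' @param lib_sizes Library sizes (default column sums).
#' @return Named numeric vector of normalization factors.
#' @export
tmm_factors <- function(mat, lib_sizes = colSums(mat)) {
  if (ncol(mat) < 2) stop("need >= 2 samples")
  if (any(lib_sizes == 0)) stop("sample with all-zero counts")
  mat <- mat[rowSums(mat) > 0, , drop = FALSE]
  prop <- sweep(mat, 2, lib_sizes, "/")
  uq <- apply(prop, 2, stats::quantile, probs = 0.75)
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(mat)), function(j) {
    if (j == ref) return(1)
    y_s <- mat[, j]; y_r <- mat[, ref]
    keep <- y_s > 0 & y_r > 0
    if (!any(keep)) return(1)
    y_s <- y_s[keep]; y_r <- y_r[keep]
    N_s <- lib_sizes[j]; N_r <- lib_sizes[ref]
    M <- log2((y_s / N_s) / (y_r / N_r))
    A <- 0.5 * log2((y_s / N_s) * (y_r / N_r))
    if (max(abs(M)) < 1e-10) return(1)
    n <- length(M)
    loM <- floor(n * 0.3) + 1; hiM <- n + 1 - loM
    loA <- floor(n * 0.05) + 1; hiA <- n + 1 - loA
    rM <- rank(M, ties.method = "first")
    rA <- rank(A, ties.method = "first")
    keep2 <- rM >= loM & rM <= hiM & rA >= loA & rA <= hiA
    if (!any(keep2)) return(1)
    w <- 1 / ((N_s - y_s) / (N_s * y_s) + (N_r - y_r) / (N_r * y_r))[keep2]
    2^(sum(w * M[keep2]) / sum(w))
  }, 0)
  f <- f / exp(mean(log(f)))
  stats::setNames(f, colnames(mat))
}

#' Common NB dispersion by conditional maximum likelihood
#'
#' Counts are scaled to a common effective library size (the geometric mean
#' of `lib_sizes * factors`) and rounded; the dispersion maximizing the
#' summed conditional NB log-likelihood (conditioning on each gene's
#' within-group total) is found by golden-section search on [1e-6, 5].
#'
#' @param mat Count matrix, genes x samples.
#' @param groups Factor of group membership per sample.
#' @param factors Normalization factors (default 1).
#' @param lib_sizes Library sizes (default column sums).
#' @return Dispersion phi >= 0 (variance = mu + phi mu^2).
#' @export
estimate_common_dispersion <- function(mat, groups, factors = rep(1, ncol(mat)),
                                       lib_sizes = colSums(mat)) {
  groups <- as.factor(groups)
  sizes <- table(groups)
  if (all(sizes < 2)) {
    warning("no group with >= 2 replicates; returning phi = 0")
    return(0)
  }
  eff <- lib_sizes * factors
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(mat, 2, common / eff, "*"))
  cll <- function(phi) {
    r <- 1 / phi
    tot <- 0
    for (g in levels(groups)) {
      cols <- which(groups == g)
      n <- length(cols)
      if (n < 2) next
      y <- pseudo[, cols, drop = FALSE]
      z <- rowSums(y)
      tot <- tot + sum(rowSums(lgamma(y + r)) - n * lgamma(r) +
                         lgamma(n * r) - lgamma(z + n * r))
    }
    tot
  }
  opt <- stats::optimize(cll, interval = c(1e-6, 5), maximum = TRUE, tol = 1e-8)
  # profile can be monotone decreasing (Poisson-like data): check the boundary
  if (cll(1e-6) >= opt$objective) return(1e-6)
  opt$maximum
}

#' Negative binomial conditional exact test
#'
#' Two-sided exact test of equal means between two groups of NB counts with
#' known common dispersion, on counts already equalized to a common library
#' size. Conditioning on the total `S = s1 + s2` of the group sums, each
#' split follows the convolution of the two group-sum NB distributions; the
#' p-value is the total conditional probability of all splits no more
#' probable than the observed one (ties included). At `dispersion = 0` the
#' conditional law is Binomial(S, n1/(n1+n2)).
#'
#' @param counts_g1,counts_g2 Equalized count vectors for the two groups.
#' @param dispersion Common NB dispersion phi.
#' @return Two-sided p-value in (0, 1].
#' @export
nb_exact_test <- function(counts_g1, counts_g2, dispersion = 0) {
  if (any(counts_g1 < 0) || any(counts_g2 < 0)) stop("negative counts")
  s1 <- sum(counts_g1); s2 <- sum(counts_g2)
  n1 <- length(counts_g1); n2 <- length(counts_g2)
  S <- s1 + s2
  if (S == 0) return(1)
  k <- 0:S
  m <- S / (n1 + n2)
  if (dispersion == 0) {
    lf <- stats::dbinom(k, S, n1 / (n1 + n2), log = TRUE)
  } else {
    r <- 1 / dispersion
    lf <- stats::dnbinom(k, size = n1 * r, mu = n1 * m, log = TRUE) +
      stats::dnbinom(S - k, size = n2 * r, mu = n2 * m, log = TRUE)
  }
  lf <- lf - max(lf)
  f <- exp(lf)
  obs <- f[s1 + 1L]
  p <- sum(f[f <= obs * (1 + 1e-10)]) / sum(f)
  min(p, 1)
}

#' Benjamini-Hochberg q-values
#'
#' Step-up FDR adjustment; NAs are preserved and excluded from the
#' adjustment.
#'
#' @param p Vector of p-values in [0, 1] (NA allowed).
#' @return Vector of q-values, same length and order.
#' @export
bh_fdr <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("p-values must lie in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

#' Run a two-group differential-expression contrast
#'
#' TMM normalization, common-dispersion estimation and the NB conditional
#' exact test, per gene, with BH FDR. Counts are equalized to the geometric
#' mean effective library size before testing. Genes below `min_count`
#' summed raw counts across the contrast's units are returned as NA
#' (degenerate for the exact test); `genes` restricts the tested universe
#' (e.g. to presence-filtered genes).
#'
#' @param uc A [unit_counts()] object (or a bare count matrix with unit ids
#'   as column names).
#' @param group1,group2 Disjoint character vectors of unit ids.
#' @param genes Optional gene universe to test (default: all genes).
#' @param dispersion Common dispersion; estimated from the data when NULL.
#' @param min_count Minimum summed raw count for a gene to be tested.
#' @param fdr Significance threshold on the q-value (default 0.05).
#' @return Data.frame of class `de_result`: gene_id, logFC (group2 over
#'   group1, pseudocount 0.5), p, q, call; attributes `dispersion` and
#'   `factors`.
#' @export
run_contrast <- function(uc, group1, group2, genes = NULL, dispersion = NULL,
                         min_count = 5, fdr = 0.05) {
  mat <- if (inherits(uc, "unit_counts")) uc$counts else uc
  if (length(group1) == 0 || length(group2) == 0) stop("empty contrast group")
  if (length(intersect(group1, group2))) stop("contrast groups must be disjoint")
  miss <- setdiff(c(group1, group2), colnames(mat))
  if (length(miss)) stop("unknown units: ", paste(miss, collapse = ", "))
  lib_all <- if (inherits(uc, "unit_counts")) uc$lib_sizes else colSums(mat)
  cols <- c(group1, group2)
  sub <- mat[, cols, drop = FALSE]
  lib <- lib_all[cols]
  if (!is.null(genes)) sub_t <- sub[rownames(sub) %in% genes, , drop = FALSE]
  else sub_t <- sub
  f <- tmm_factors(sub, lib)
  eff <- lib * f
  common <- exp(mean(log(eff)))
  pseudo <- round(sweep(sub_t, 2, common / eff, "*"))
  grp <- factor(rep(c(1, 2), c(length(group1), length(group2))))
  if (is.null(dispersion)) {
    dispersion <- estimate_common_dispersion(sub_t, grp, factors = f, lib_sizes = lib)
  }
  i1 <- seq_along(group1)
  i2 <- length(group1) + seq_along(group2)
  tested <- rowSums(sub_t) >= min_count
  p <- rep(NA_real_, nrow(sub_t))
  for (g in which(tested)) {
    p[g] <- nb_exact_test(pseudo[g, i1], pseudo[g, i2], dispersion)
  }
  m1 <- rowMeans(pseudo[, i1, drop = FALSE])
  m2 <- rowMeans(pseudo[, i2, drop = FALSE])
  logFC <- log2((m2 + 0.5) / (m1 + 0.5))
  q <- bh_fdr(p)
  out <- data.frame(gene_id = rownames(sub_t), logFC = logFC, p = p, q = q,
                    call = !is.na(q) & q < fdr,
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  attr(out, "factors") <- f
  class(out) <- c("de_result", "data.frame")
  out
}
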