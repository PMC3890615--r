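#' Build a genes x analysis-units count matrix
#'
#' Analysis units are `(accession, partition, replicate)` columns derived
#' from the read-class counts: partition `A` takes `n_A`, partition `D`
#' takes `n_D`, and partition `total` takes `n_A + n_D + n_N`. Chimeric (X)
#' reads are flagged artifacts and excluded from totals by default. Diploids
#' contribute only `total` units; polyploids contribute `A`, `D` and `total`.
#' Library sizes are column sums (all assigned reads of that partition in
#' that sample).
#'
#' @param counts Long class-count data.frame (gene_id, sample_id, n_A..n_N).
#' @param meta A [sample_meta()] for the samples present.
#' @param polyploids Accessions that carry both subgenomes.
#' @param include_X Whether chimeric reads enter `total` units (default
#'   FALSE).
#' @return A list of class `unit_counts`: `counts` (integer matrix genes x
#'   units), `units` (data.frame unit_id, accession, partition, replicate),
#'   `lib_sizes` (named numeric).
#' @export
unit_counts <- function(counts, meta, polyploids, include_X = FALSE) {
  genes <- unique(counts$gene_id)
  cn <- list()
  units <- list()
  for (i in seq_len(nrow(meta))) {
    s <- meta$sample_id[i]
    acc <- meta$accession[i]
    rows <- counts[counts$sample_id == s, ]
    rows <- rows[match(genes, rows$gene_id), ]
    tot <- rows$n_A + rows$n_D + rows$n_N + if (include_X) rows$n_X else 0L
    parts <- if (acc %in% polyploids) {
      list(A = rows$n_A, D = rows$n_D, total = tot)
    } else {
      list(total = tot)
    }
    for (p in names(parts)) {
      uid <- paste(acc, p, meta$replicate[i], sep = "_")
      cn[[uid]] <- parts[[p]]
      units[[uid]] <- data.frame(unit_id = uid, accession = acc, partition = p,
                                 replicate = meta$replicate[i],
                                 stringsAsFactors = FALSE)
    }
  }
  m <- do.call(cbind, cn)
  rownames(m) <- genes
  m[is.na(m)] <- 0L
  structure(list(counts = m, units = do.call(rbind, c(units, make.row.names = FALSE)),
                 lib_sizes = colSums(m)),
            class = "unit_counts")
}

# select unit ids by accession and partition
unit_ids <- function(uc, accession, partition) {
  u <- uc$units
  u$unit_id[u$accession == accession & u$partition == partition]
}

#' Reads per kilobase per million mapped reads
#'
#' `rpkm = 1e9 * count / (gene_length * library_size)`.
#'
#' @param count Raw read count (vector or matrix).
#' @param gene_length_bp Gene length in bp (summed exon length), >= 1.
#' @param library_size Mapped reads in the unit's library, >= 1.
#' @return RPKM on the same shape as `count`.
#' @export
rpkm <- function(count, gene_length_bp, library_size) {
  if (any(library_size < 1)) stop("library_size must be >= 1")
  if (any(gene_length_bp < 1)) stop("gene_length_bp must be >= 1")
  1e9 * count / (gene_length_bp * library_size)
}

#' RPKM matrix for a unit-count object
#'
#' @param uc A [unit_counts()] object.
#' @param gene_lengths Named vector of gene lengths (bp).
#' @param log2 If TRUE return `log2(RPKM + 1)`.
#' @return Numeric matrix, genes x units.
#' @export
rpkm_matrix <- function(uc, gene_lengths, log2 = FALSE) {
  len <- gene_lengths[rownames(uc$counts)]
  if (anyNA(len)) stop("gene lengths missing for some genes")
  m <- rpkm(uc$counts, matrix(len, nrow(uc$counts), ncol(uc$counts)),
            matrix(uc$lib_sizes, nrow(uc$counts), ncol(uc$counts), byrow = TRUE))
  if (log2) base::log2(m + 1) else m
}

#' Fit a two-component Gaussian mixture of expressed vs background genes
#'
#' An EM fit on per-accession mean `log2(RPKM+1)` values: the component with
#' the lower mean is labelled background, and the posterior probability of
#' the high component is the per-gene probability of expression. EM runs to a
#' relative log-likelihood change below `tol` (or `max_iter`), from five
#' deterministic quantile-spread initializations, keeping the best
#' likelihood. Component variances are floored at 1e-6.
#'
#' @param x Numeric vector (>= 50 values) of mean log2(RPKM+1) per gene.
#' @param tol Relative log-likelihood convergence tolerance.
#' @param max_iter Maximum EM iterations per start.
#' @return List: `pi`, `mu`, `sigma` (ordered background, expressed),
#'   `posterior` (P(expressed | x) per gene), `loglik`.
#' @export
fit_presence_mixture <- function(x, tol = 1e-8, max_iter = 500) {
  if (length(x) < 50) stop("need >= 50 genes to fit the presence mixture")
  if (stats::sd(x) == 0) stop("no expression signal: all values identical")
  starts <- list(c(0.1, 0.9), c(0.2, 0.8), c(0.3, 0.7), c(0.25, 0.95), c(0.05, 0.75))
  best <- NULL
  for (qq in starts) {
    mu <- stats::quantile(x, qq, names = FALSE)
    if (diff(mu) < 1e-6) mu <- mu + c(-1, 1) * stats::sd(x) / 2
    sig <- rep(max(stats::sd(x) / 2, 1e-3), 2)
    pi_k <- c(0.5, 0.5)
    ll_old <- -Inf
    for (it in seq_len(max_iter)) {
      d1 <- pi_k[1] * stats::dnorm(x, mu[1], sig[1])
      d2 <- pi_k[2] * stats::dnorm(x, mu[2], sig[2])
      tot <- d1 + d2
      tot[tot == 0] <- .Machine$double.xmin
      ll <- sum(log(tot))
      g2 <- d2 / tot
      g1 <- 1 - g2
      n1 <- sum(g1); n2 <- sum(g2)
      if (n1 < 1e-10 || n2 < 1e-10) break
      pi_k <- c(n1, n2) / length(x)
      mu <- c(sum(g1 * x) / n1, sum(g2 * x) / n2)
      sig <- sqrt(pmax(c(sum(g1 * (x - mu[1])^2) / n1,
                         sum(g2 * (x - mu[2])^2) / n2), 1e-6))
      if (is.finite(ll_old) && abs(ll - ll_old) < tol * abs(ll)) break
      ll_old <- ll
    }
    if (is.null(best) || ll > best$loglik) {
      best <- list(pi = pi_k, mu = mu, sigma = sig, loglik = ll)
    }
  }
  # order components: background = lower mean
  o <- order(best$mu)
  pi_k <- best$pi[o]; mu <- best$mu[o]; sig <- best$sigma[o]
  d1 <- pi_k[1] * stats::dnorm(x, mu[1], sig[1])
  d2 <- pi_k[2] * stats::dnorm(x, mu[2], sig[2])
  post <- d2 / (d1 + d2)
  post[(d1 + d2) == 0] <- as.numeric(x[(d1 + d2) == 0] > mean(mu))
  list(pi = pi_k, mu = mu, sigma = sig, posterior = post, loglik = best$loglik)
}

#' Per-accession presence calls
#'
#' Fits the presence mixture to each accession's mean log2(RPKM+1) over its
#' `total`-partition replicates and returns posterior probabilities of
#' expression with `active` (> `active_threshold`) and high-confidence
#' (>= `hi_threshold`) calls.
#'
#' @param uc A [unit_counts()] object.
#' @param gene_lengths Named gene length vector (bp).
#' @param active_threshold Posterior for an `active` call (default 0.5).
#' @param hi_threshold Posterior for a high-confidence call (default 0.99).
#' @return A list of class `presence_calls`: `posterior` (genes x accessions
#'   matrix), `active`, `high_conf` (logical matrices), `fits`.
#' @export
presence_calls <- function(uc, gene_lengths, active_threshold = 0.5,
                           hi_threshold = 0.99) {
  lr <- rpkm_matrix(uc, gene_lengths, log2 = TRUE)
  accs <- unique(uc$units$accession)
  post <- matrix(NA_real_, nrow(lr), length(accs),
                 dimnames = list(rownames(lr), accs))
  fits <- list()
  for (a in accs) {
    cols <- uc$units$unit_id[uc$units$accession == a & uc$units$partition == "total"]
    mx <- rowMeans(lr[, cols, drop = FALSE])
    f <- fit_presence_mixture(mx)
    post[, a] <- f$posterior
    fits[[a]] <- f[c("pi", "mu", "sigma", "loglik")]
  }
  structure(list(posterior = post, active = post > active_threshold,
                 high_conf = post >= hi_threshold, fits = fits),
            class = "presence_calls")
}

#' Expressed and commonly expressed gene sets
#'
#' @param pc A [presence_calls()] object.
#' @param accessions Accessions to consider (default: all columns).
#' @param high_conf Use the high-confidence calls instead of `active`.
#' @param n_annotated Total annotated genes, for the percent-expressed
#'   summary (default: number of rows).
#' @return List: `expressed` (named list of gene-id vectors), `common`
#'   (intersection across accessions), `summary` (data.frame accession,
#'   n_expressed, pct_expressed).
#' @export
expressed_sets <- function(pc, accessions = colnames(pc$posterior),
                           high_conf = FALSE, n_annotated = nrow(pc$posterior)) {
  m <- if (high_conf) pc$high_conf else pc$active
  sets <- lapply(accessions, function(a) rownames(m)[m[, a]])
  names(sets) <- accessions
  common <- Reduce(intersect, sets)
  summary <- data.frame(
    accession = accessions,
    n_expressed = lengths(sets),
    pct_expressed = round(lengths(sets) / n_annotated * 100, 1),
    stringsAsFactors = FALSE, row.names = NULL)
  list(expressed = sets, common = common, summary = summary)
}
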