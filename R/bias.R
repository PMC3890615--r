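#' Call homoeolog expression bias for one accession
#'
#' Contrasts the accession's A-partition units against its D-partition units
#' with the NB exact test, and attaches the signed degree of bias: the mean
#' over replicates of `log2(RPKM_A + 1) - log2(RPKM_D + 1)`. Direction is A
#' when the gene is significant (q below `fdr`) with positive degree, D when
#' negative, `none` otherwise. The tested universe defaults to the
#' accession's high-confidence expressed genes when presence calls are
#' supplied.
#'
#' @param uc A [unit_counts()] object.
#' @param gene_lengths Named gene-length vector (bp) for the degree scale.
#' @param accession A polyploid accession present in `uc`.
#' @param presence Optional [presence_calls()]; genes passing the
#'   high-confidence filter in this accession define the universe.
#' @param dispersion,min_count,fdr Passed to [run_contrast()].
#' @return Data.frame of class `bias_result`: gene_id, degree, logFC, p, q,
#'   direction.
#' @export
call_bias <- function(uc, gene_lengths, accession, presence = NULL,
                      dispersion = NULL, min_count = 5, fdr = 0.05) {
  gA <- unit_ids(uc, accession, "A")
  gD <- unit_ids(uc, accession, "D")
  if (length(gA) == 0 || length(gD) == 0) {
    stop(accession, " has no A/D partition units (diploid accession?)")
  }
  genes <- NULL
  if (!is.null(presence)) {
    genes <- rownames(presence$high_conf)[presence$high_conf[, accession]]
  }
  de <- run_contrast(uc, group1 = gD, group2 = gA, genes = genes,
                     dispersion = dispersion, min_count = min_count, fdr = fdr)
  lr <- rpkm_matrix(uc, gene_lengths, log2 = TRUE)
  lr <- lr[de$gene_id, , drop = FALSE]
  uA <- lr[, gA, drop = FALSE]
  uD <- lr[, gD, drop = FALSE]
  # pair replicates positionally (same library split into two partitions)
  reps <- min(ncol(uA), ncol(uD))
  degree <- rowMeans(uA[, seq_len(reps), drop = FALSE] -
                     uD[, seq_len(reps), drop = FALSE])
  out <- data.frame(gene_id = de$gene_id, degree = degree, logFC = de$logFC,
                    p = de$p, q = de$q,
                    direction = ifelse(de$call, ifelse(degree > 0, "A", "D"), "none"),
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- attr(de, "dispersion")
  class(out) <- c("bias_result", "data.frame")
  out
}

#' Accession-level bias summary
#'
#' Counts of expressed, biased, A-biased and D-biased genes, the percent
#' biased (1 decimal) and the bias ratio A/D (2 decimals).
#'
#' @param bias A `bias_result` (or anything with a `direction` column).
#' @param n_expressed Number of expressed genes in the accession (default:
#'   rows of `bias`).
#' @return One-row data.frame: n_expressed, n_biased, pct_biased, n_A_bias,
#'   n_D_bias, bias_ratio (Inf when no D-biased genes).
#' @export
bias_summary <- function(bias, n_expressed = nrow(bias)) {
  nA <- sum(bias$direction == "A")
  nD <- sum(bias$direction == "D")
  nb <- nA + nD
  data.frame(n_expressed = n_expressed, n_biased = nb,
             pct_biased = round(nb / n_expressed * 100, 1),
             n_A_bias = nA, n_D_bias = nD,
             bias_ratio = if (nD > 0) round(nA / nD, 2) else Inf)
}

#' Venn region counts over k gene sets
#'
#' Every gene in the union is placed in exactly one of the `2^k - 1` regions
#' named by the `&`-joined member sets.
#'
#' @param sets Named list (k >= 2) of gene-id vectors.
#' @return Data.frame: region, count (all regions, including empty ones).
#' @export
venn_partition <- function(sets) {
  if (length(sets) < 2) stop("need >= 2 sets")
  if (is.null(names(sets))) names(sets) <- paste0("set", seq_along(sets))
  univ <- unique(unlist(sets))
  memb <- vapply(sets, function(s) univ %in% s, logical(length(univ)))
  if (length(univ) == 1L) memb <- matrix(memb, nrow = 1, dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), length(sets)))[-1, , drop = FALSE]
  region <- apply(combos, 1, function(z) paste(names(sets)[unlist(z)], collapse = "&"))
  count <- apply(combos, 1, function(z) {
    sum(apply(memb, 1, function(r) all(r == unlist(z))))
  })
  data.frame(region = region, count = as.integer(count),
             stringsAsFactors = FALSE, row.names = NULL)
}

#' Direction conservation of bias across accessions
#'
#' Restricted to genes biased in every accession, counts those consistently
#' A-biased and consistently D-biased, and lists per accession the
#' "contrarian" genes whose direction opposes the unanimous direction of all
#' other accessions.
#'
#' @param bias_list Named list of `bias_result` tables, one per accession.
#' @return List: `all_biased` (genes biased everywhere), `consistent_A`,
#'   `consistent_D` (gene-id vectors), `contrarian` (named list per
#'   accession), `counts` (data.frame summary).
#' @export
conserved_direction <- function(bias_list) {
  dirs <- lapply(bias_list, function(b) {
    stats::setNames(b$direction, b$gene_id)
  })
  biased_sets <- lapply(dirs, function(d) names(d)[d != "none"])
  all_biased <- Reduce(intersect, biased_sets)
  dmat <- vapply(dirs, function(d) d[all_biased], character(length(all_biased)))
  if (length(all_biased) == 1L) {
    dmat <- matrix(dmat, nrow = 1, dimnames = list(all_biased, names(dirs)))
  }
  cons_A <- all_biased[rowSums(dmat == "A") == ncol(dmat)]
  cons_D <- all_biased[rowSums(dmat == "D") == ncol(dmat)]
  contrarian <- lapply(seq_along(bias_list), function(j) {
    others <- dmat[, -j, drop = FALSE]
    unanimous_A <- rowSums(others == "A") == ncol(others)
    unanimous_D <- rowSums(others == "D") == ncol(others)
    all_biased[(unanimous_A & dmat[, j] == "D") | (unanimous_D & dmat[, j] == "A")]
  })
  names(contrarian) <- names(bias_list)
  list(all_biased = all_biased, consistent_A = cons_A, consistent_D = cons_D,
       contrarian = contrarian,
       counts = data.frame(n_all_biased = length(all_biased),
                           n_consistent_A = length(cons_A),
                           n_consistent_D = length(cons_D),
                           n_conserved = length(cons_A) + length(cons_D)))
}

#' Compare the degree of bias between two gene sets
#'
#' Fold difference of mean absolute degree (set1 over set2) with a two-sided
#' Mann-Whitney U test on the absolute degrees.
#'
#' @param set1,set2 Non-empty gene-id vectors.
#' @param bias A `bias_result` table providing the degrees.
#' @return List: `fold`, `p`, `mean_abs_1`, `mean_abs_2`.
#' @export
compare_bias_degree <- function(set1, set2, bias) {
  if (length(set1) == 0 || length(set2) == 0) stop("empty gene set")
  deg <- stats::setNames(abs(bias$degree), bias$gene_id)
  d1 <- deg[intersect(set1, names(deg))]
  d2 <- deg[intersect(set2, names(deg))]
  if (length(d1) == 0 || length(d2) == 0) stop("no degrees available for a set")
  p <- if (identical(sort(unname(d1)), sort(unname(d2)))) 1 else
    suppressWarnings(stats::wilcox.test(d1, d2)$p.value)
  list(fold = mean(d1) / mean(d2), p = p,
       mean_abs_1 = mean(d1), mean_abs_2 = mean(d2))
}

#' Correlation between per-chromosome gene totals and biased-gene counts
#'
#' @param biased_genes Gene-id vector of biased genes.
#' @param gene_models A [read_gene_models()] result (the gene catalog).
#' @return List: `r` (Pearson), `p` (two-sided), `table` (per-chromosome
#'   counts).
#' @export
chromosome_bias_correlation <- function(biased_genes, gene_models) {
  g <- gene_models$genes
  chroms <- sort(unique(g$chrom))
  if (length(chroms) < 3) stop("need >= 3 chromosomes")
  total <- as.integer(table(factor(g$chrom, levels = chroms)))
  biased <- as.integer(table(factor(g$chrom[g$gene_id %in% biased_genes],
                                    levels = chroms)))
  if (stats::sd(total) == 0 || stats::sd(biased) == 0) {
    r <- 0; p <- 1  # no variation to correlate
  } else {
    ct <- stats::cor.test(total, biased)
    r <- unname(ct$estimate); p <- ct$p.value
  }
  list(r = r, p = p,
       table = data.frame(chrom = chroms, n_genes = total, n_biased = biased))
}

#' Distance from each gene to the nearest TE interval
#'
#' Distances are measured from the gene span (0 for overlap).
#'
#' @param gene_models A [read_gene_models()] result.
#' @param te A `GRanges` of TE intervals.
#' @return Named integer vector of distances (NA when no TE on the
#'   chromosome).
#' @export
te_distances <- function(gene_models, te) {
  g <- gene_models$genes
  gr <- GenomicRanges::GRanges(g$chrom, IRanges::IRanges(g$start, g$end))
  hit <- GenomicRanges::distanceToNearest(gr, te)
  d <- rep(NA_integer_, nrow(g))
  d[S4Vectors::queryHits(hit)] <- S4Vectors::mcols(hit)$distance
  stats::setNames(d, g$gene_id)
}

#' Association between bias degree and TE proximity
#'
#' Spearman rank correlation (two-sided) between the signed degree of bias
#' and the distance to the nearest TE; a linear-regression alternative is
#' available via `method = "lm"`. The returned `data` (degree on x, distance
#' on y) supports scatter plotting.
#'
#' @param bias A `bias_result` table.
#' @param te A `GRanges` of TE intervals.
#' @param gene_models A [read_gene_models()] result.
#' @param method `"spearman"` (default) or `"lm"`.
#' @return List: `statistic` (rho or slope), `p`, `data`.
#' @export
te_proximity_association <- function(bias, te, gene_models,
                                     method = c("spearman", "lm")) {
  method <- match.arg(method)
  if (length(te) == 0) stop("no TE intervals")
  d <- te_distances(gene_models, te)[bias$gene_id]
  keep <- !is.na(d)
  x <- bias$degree[keep]; y <- unname(d[keep])
  if (method == "spearman") {
    ct <- suppressWarnings(stats::cor.test(x, y, method = "spearman"))
    stat <- unname(ct$estimate); p <- ct$p.value
  } else {
    fit <- summary(stats::lm(y ~ x))
    stat <- fit$coefficients["x", "Estimate"]
    p <- fit$coefficients["x", "Pr(>|t|)"]
  }
  list(statistic = stat, p = p,
       data = data.frame(gene_id = bias$gene_id[keep], degree = x, te_distance = y))
}
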