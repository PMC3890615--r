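#' Cross-classification of diploid differential expression vs polyploid bias
#'
#' Tallies the shared gene universe into the 2x2 of (differentially
#' expressed between the diploids?) x (homoeolog-biased in the polyploid?),
#' and, within the Different/Different cell, counts genes whose direction
#' flipped: "A_to_D" means higher A-expression in the diploids but a D-bias
#' in the polyploid, and vice versa.
#'
#' @param diploid_de A `de_result` from the A2-vs-D5 contrast with logFC
#'   oriented A over D (positive = A higher).
#' @param polyploid_bias A `bias_result` for one polyploid.
#' @return One-row data.frame: equal_equal, equal_diff, diff_equal,
#'   diff_diff, change_A_to_D, change_D_to_A, n_genes.
#' @export
diploid_polyploid_matrix <- function(diploid_de, polyploid_bias) {
  if (!setequal(diploid_de$gene_id, polyploid_bias$gene_id)) {
    stop("diploid and polyploid call sets cover different gene universes")
  }
  b <- polyploid_bias[match(diploid_de$gene_id, polyploid_bias$gene_id), ]
  d_sig <- diploid_de$call
  p_sig <- b$direction != "none"
  d_dir <- ifelse(diploid_de$logFC > 0, "A", "D")
  dd <- d_sig & p_sig
  data.frame(
    equal_equal = sum(!d_sig & !p_sig),
    equal_diff = sum(!d_sig & p_sig),
    diff_equal = sum(d_sig & !p_sig),
    diff_diff = sum(dd),
    change_A_to_D = sum(dd & d_dir == "A" & b$direction == "D"),
    change_D_to_A = sum(dd & d_dir == "D" & b$direction == "A"),
    n_genes = nrow(diploid_de))
}

#' Aggregate cross-classification rows over accessions
#'
#' Arithmetic means of per-accession counts, rounded half-up to integers
#' (the convention for "natural polyploid average" rows).
#'
#' @param rows Data.frame of per-accession count rows (numeric columns).
#' @return One-row data.frame of rounded means.
#' @export
average_counts_row <- function(rows) {
  m <- colMeans(rows[vapply(rows, is.numeric, TRUE)])
  as.data.frame(as.list(floor(m + 0.5)))
}

#' Per-genome expression change from diploid to tetraploid
#'
#' Contrasts the polyploid's A-partition units against the whole A-genome
#' diploid and its D-partition units against the D-genome diploid, counting
#' genes up (tetraploid higher) and down at the FDR threshold. Normalization
#' factors absorb the partition's lower effective depth.
#'
#' @param uc A [unit_counts()] object.
#' @param polyploid The polyploid accession.
#' @param diploids Named (`A`, `D`) diploid accessions.
#' @param genes Optional gene universe.
#' @param dispersion,min_count,fdr Passed to [run_contrast()].
#' @return One-row data.frame: A_up, A_down, D_up, D_down, total.
#' @export
genome_change_table <- function(uc, polyploid, diploids = c(A = "A2", D = "D5"),
                                genes = NULL, dispersion = NULL, min_count = 5,
                                fdr = 0.05) {
  uPA <- unit_ids(uc, polyploid, "A")
  uPD <- unit_ids(uc, polyploid, "D")
  uA2 <- unit_ids(uc, diploids[["A"]], "total")
  uD5 <- unit_ids(uc, diploids[["D"]], "total")
  if (!length(uPA) || !length(uPD)) stop("missing polyploid partition units")
  if (!length(uA2) || !length(uD5)) stop("missing diploid units")
  deA <- run_contrast(uc, group1 = uA2, group2 = uPA, genes = genes,
                      dispersion = dispersion, min_count = min_count, fdr = fdr)
  deD <- run_contrast(uc, group1 = uD5, group2 = uPD, genes = genes,
                      dispersion = dispersion, min_count = min_count, fdr = fdr)
  out <- data.frame(
    A_up = sum(deA$call & deA$logFC > 0), A_down = sum(deA$call & deA$logFC < 0),
    D_up = sum(deD$call & deD$logFC > 0), D_down = sum(deD$call & deD$logFC < 0))
  out$total <- out$A_up + out$A_down + out$D_up + out$D_down
  out
}
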