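#' The twelve expression-level-dominance categories
#'
#' Mapping from the sign triple `(t_AD, t_AP, t_DP)` to the Roman-numeral
#' category, where `t_AD = sign(A2 - D5)`, `t_AP = sign(P - A2)`,
#' `t_DP = sign(P - D5)` and 0 means not significant. Thirteen triples map to
#' the twelve categories plus NoChange; the remaining fourteen triples are
#' internally contradictory and classified Ambiguous. Categories II/IV are
#' "up" dominance (polyploid matches the higher parent), IX/XI "down"
#' dominance, V/VI/VIII transgressive up, III/VII/X transgressive down,
#' I/XII additive.
#'
#' @format A data.frame with columns `category`, `t_AD`, `t_AP`, `t_DP`.
#' @export
eld_category_table <- function() {
  data.frame(
    category = c("I", "XII", "II", "XI", "IV", "IX", "V", "VI", "VIII",
                 "III", "X", "VII", "NoChange"),
    t_AD = c(+1, -1, -1, +1, +1, -1, -1, +1, 0, -1, +1, 0, 0),
    t_AP = c(-1, +1, +1, -1, 0, 0, +1, +1, +1, -1, -1, -1, 0),
    t_DP = c(+1, -1, 0, 0, +1, -1, +1, +1, +1, -1, -1, -1, 0),
    stringsAsFactors = FALSE)
}

#' Classify sign triples into ELD categories
#'
#' @param t_AD,t_AP,t_DP Integer vectors in `{-1, 0, +1}`: thresholded signs
#'   of (A2 - D5), (P - A2), (P - D5).
#' @return Character vector of categories (`I`..`XII`, `NoChange`,
#'   `Ambiguous`).
#' @export
classify_eld <- function(t_AD, t_AP, t_DP) {
  ok <- function(v) all(v %in% c(-1L, 0L, 1L))
  if (!ok(t_AD) || !ok(t_AP) || !ok(t_DP)) {
    stop("sign components must be -1, 0 or +1")
  }
  tab <- eld_category_table()
  key <- paste(t_AD, t_AP, t_DP)
  map <- stats::setNames(tab$category, paste(tab$t_AD, tab$t_AP, tab$t_DP))
  out <- unname(map[key])
  out[is.na(out)] <- "Ambiguous"
  out
}

#' Pairwise significance signs and ELD categories for one polyploid
#'
#' Runs the three contrasts (A2 vs D5 totals; polyploid total vs A2;
#' polyploid total vs D5) with the NB exact test, thresholds each at the
#' FDR, takes the sign from the fold-change direction, and classifies every
#' gene. Genes without expression (per the presence filter) are excluded.
#'
#' @param uc A [unit_counts()] object.
#' @param polyploid The polyploid accession.
#' @param diploids Named character vector (`A`, `D`) of diploid accessions.
#' @param presence Optional [presence_calls()]; the universe is genes active
#'   in the polyploid and both diploids.
#' @param dispersion,min_count,fdr Passed to [run_contrast()].
#' @return Data.frame of class `eld_call`: gene_id, t_AD, t_AP, t_DP,
#'   category.
#' @export
eld_calls <- function(uc, polyploid, diploids = c(A = "A2", D = "D5"),
                      presence = NULL, dispersion = NULL, min_count = 5,
                      fdr = 0.05) {
  uA <- unit_ids(uc, diploids[["A"]], "total")
  uD <- unit_ids(uc, diploids[["D"]], "total")
  uP <- unit_ids(uc, polyploid, "total")
  if (length(uA) == 0 || length(uD) == 0) stop("missing diploid units")
  if (length(uP) == 0) stop("missing polyploid units")
  genes <- NULL
  if (!is.null(presence)) {
    act <- presence$active
    genes <- rownames(act)[act[, polyploid] & act[, diploids[["A"]]] & act[, diploids[["D"]]]]
  }
  sgn <- function(de) {
    s <- integer(nrow(de))
    s[de$call & de$logFC > 0] <- 1L
    s[de$call & de$logFC < 0] <- -1L
    stats::setNames(s, de$gene_id)
  }
  # logFC is group2/group1, so order groups to give the wanted sign directly
  de_AD <- run_contrast(uc, group1 = uD, group2 = uA, genes = genes,
                        dispersion = dispersion, min_count = min_count, fdr = fdr)
  de_AP <- run_contrast(uc, group1 = uA, group2 = uP, genes = genes,
                        dispersion = dispersion, min_count = min_count, fdr = fdr)
  de_DP <- run_contrast(uc, group1 = uD, group2 = uP, genes = genes,
                        dispersion = dispersion, min_count = min_count, fdr = fdr)
  gid <- de_AD$gene_id
  t_AD <- sgn(de_AD)[gid]
  t_AP <- sgn(de_AP)[gid]
  t_DP <- sgn(de_DP)[gid]
  out <- data.frame(gene_id = gid, t_AD = unname(t_AD), t_AP = unname(t_AP),
                    t_DP = unname(t_DP),
                    category = classify_eld(unname(t_AD), unname(t_AP), unname(t_DP)),
                    stringsAsFactors = FALSE, row.names = NULL)
  class(out) <- c("eld_call", "data.frame")
  out
}

#' D-dominance ELD ratio
#'
#' `(n_II + n_XI) / (n_IV + n_IX)`: the relative frequency of D-matching vs
#' A-matching dominance categories.
#'
#' @param category_counts Named counts (or an `eld_call` table).
#' @return The ratio (error on a zero denominator).
#' @export
eld_ratio <- function(category_counts) {
  if (is.data.frame(category_counts)) {
    category_counts <- table(category_counts$category)
  }
  n <- function(k) if (k %in% names(category_counts)) as.numeric(category_counts[[k]]) else 0
  den <- n("IV") + n("IX")
  if (den == 0) stop("zero denominator: no genes in categories IV or IX")
  (n("II") + n("XI")) / den
}

#' High- and low-expression category group counts
#'
#' "High" categories are those where polyploid expression is at least the
#' higher diploid (II, IV, V, VI, VIII); "low" where it is at most the lower
#' diploid (III, VII, IX, X, XI).
#'
#' @param eld An `eld_call` table (or named category counts).
#' @return List: `high`, `low`, `ratio` (high/low; Inf when low = 0).
#' @export
category_group_counts <- function(eld) {
  cc <- if (is.data.frame(eld)) table(eld$category) else eld
  n <- function(k) if (k %in% names(cc)) as.numeric(cc[[k]]) else 0
  high <- sum(vapply(c("II", "IV", "V", "VI", "VIII"), n, 0))
  low <- sum(vapply(c("III", "VII", "IX", "X", "XI"), n, 0))
  list(high = high, low = low, ratio = if (low > 0) high / low else Inf)
}

#' Homoeolog-bias composition of each ELD category
#'
#' For each category, counts member genes by their homoeolog-bias direction
#' in the same accession.
#'
#' @param eld An `eld_call` table.
#' @param bias A `bias_result` table for the same accession.
#' @return Data.frame: category, n, n_A_bias, n_D_bias, n_unbiased.
#' @export
category_bias_composition <- function(eld, bias) {
  dir <- stats::setNames(bias$direction, bias$gene_id)
  d <- dir[eld$gene_id]
  d[is.na(d)] <- "none"
  cats <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X",
            "XI", "XII", "NoChange", "Ambiguous")
  out <- do.call(rbind, lapply(cats, function(k) {
    in_k <- eld$category == k
    data.frame(category = k, n = sum(in_k),
               n_A_bias = sum(d[in_k] == "A"),
               n_D_bias = sum(d[in_k] == "D"),
               n_unbiased = sum(d[in_k] == "none"),
               stringsAsFactors = FALSE)
  }))
  rownames(out) <- NULL
  out
}
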