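#' Simulation configuration
#'
#' Defines the study layout and generative parameters for a synthetic
#' allopolyploid expression experiment: two diploid progenitors (A- and
#' D-genome), a diploid F1 hybrid and natural polyploid accessions, each with
#' replicated libraries; per-gene negative binomial counts; homoeolog bias
#' with configurable direction conservation; and expression-level-dominance
#' (ELD) category assignments realized in the underlying means.
#'
#' `depth` is the expected number of subgenome-informative reads per gene per
#' sample (reads assignable to A or D for a polyploid; assigned reads for a
#' diploid). Uninformative (N) and chimeric (X) reads are generated on top of
#' this according to `class_probs`, so the default per-origin mix of 50%
#' assigned / 2% chimeric / 48% uninformative yields overall read-class
#' proportions of roughly 25/25/2/48 (A/D/X/N) in a balanced polyploid.
#'
#' @param n_genes Number of genes.
#' @param n_chromosomes Number of reference chromosomes (genes round-robin).
#' @param polyploids Accessions carrying both subgenomes (the diploid F1
#'   hybrid partitions identically and is listed here).
#' @param diploids Named character vector: the A-genome and D-genome diploid.
#' @param replicates Biological replicates per accession.
#' @param depth Mean informative reads per gene per sample.
#' @param phi Negative binomial dispersion (variance = mu + phi mu^2).
#' @param frac_silent Fraction of genes not expressed in the tissue.
#' @param frac_biased Fraction of expressed genes with homoeolog bias.
#' @param frac_conserved Of biased genes, fraction biased in every polyploid
#'   with a conserved direction; the remainder are biased in a random proper
#'   subset of polyploids.
#' @param bias_log2 Log2 magnitude of homoeolog bias (A_T/D_T or inverse).
#' @param eld_fractions Named fractions of expressed genes assigned to each
#'   ELD category I..XII; the remainder is NoChange.
#' @param eld_fold Fold step separating unequal expression levels in the ELD
#'   mean construction (2 = two-fold).
#' @param class_probs Per-origin-read class probabilities: `assign` (carries a
#'   scorable diagnostic allele), `chimera`, `uninformative`.
#' @param depth_sd_log2 SD of per-gene log2 expression spread around `depth`
#'   (default 1, giving a realistic dynamic range; 0 gives uniform depth for
#'   targeted power experiments, but collapses the expressed component of
#'   the presence mixture to a spike).
#' @param libsize_spread Max ratio between library sizes, drawn log-uniform
#'   (1 = equal libraries).
#' @param silent_leak Expression of silent genes as a fraction of `depth`
#'   (small but nonzero: background transcriptional leak).
#' @param snp_per_kb Diagnostic SNP density per kb of exon (read simulation).
#' @param gene_length,intron_length Exonic bp per gene (two equal exons) and
#'   intron bp between them.
#' @param read_length Simulated read length (bp).
#' @param error_rate Per-base error rate applied at SNP positions.
#' @param read_chimera_rate Fraction of reads planted as A-then-D chimeras.
#' @param te_max_distance Max truth-assigned distance (bp) from gene to TE.
#' @param seed Mandatory integer seed; all stages derive from it.
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(n_genes = 2000,
                       n_chromosomes = 13,
                       polyploids = c("F1", "Maxxa", "Tx", "Tom"),
                       diploids = c(A = "A2", D = "D5"),
                       replicates = 3,
                       depth = 200,
                       phi = 0.05,
                       frac_silent = 0.2,
                       frac_biased = 0.2,
                       frac_conserved = 0.7,
                       bias_log2 = 1,
                       eld_fractions = stats::setNames(rep(0.02, 12),
                         c("I", "II", "III", "IV", "V", "VI", "VII", "VIII",
                           "IX", "X", "XI", "XII")),
                       eld_fold = 2,
                       class_probs = c(assign = 0.5, chimera = 0.02,
                                       uninformative = 0.48),
                       depth_sd_log2 = 1,
                       libsize_spread = 1,
                       silent_leak = 0.002,
                       snp_per_kb = 10,
                       gene_length = 600,
                       intron_length = 100,
                       read_length = 50,
                       error_rate = 0.005,
                       read_chimera_rate = 0.02,
                       te_max_distance = 5000,
                       seed) {
  if (missing(seed) || !is.numeric(seed)) stop("seed is mandatory")
  fr <- c(frac_silent, frac_biased, frac_conserved, eld_fractions)
  if (any(fr < 0 | fr > 1)) stop("fractions must lie in [0, 1]")
  if (sum(eld_fractions) > 1) stop("eld_fractions sum exceeds 1")
  if (!all(c("A", "D") %in% names(diploids))) stop("diploids must be named A and D")
  if (phi < 0) stop("phi must be >= 0")
  if (read_length < 1) stop("read length must be >= 1")
  if (abs(sum(class_probs) - 1) > 1e-8) stop("class_probs must sum to 1")
  cats <- c("I", "II", "III", "IV", "V", "VI", "VII", "VIII", "IX", "X", "XI", "XII")
  if (!all(names(eld_fractions) %in% cats)) stop("unknown ELD category in eld_fractions")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

# Expression-level multipliers (A2, D5, P) realizing each ELD sign triple,
# in units of fold step f. P sits at the geometric mean for the additive
# categories, at one parent for dominance, outside both for transgression.
eld_mean_multipliers <- function(f) {
  list(
    NoChange = c(1,     1,     1),
    I        = c(f^2,   1,     f),     # A > D, P intermediate
    XII      = c(1,     f^2,   f),     # D > A, P intermediate
    II       = c(1,     f,     f),     # D > A, P = D (up-dominant)
    XI       = c(f,     1,     1),     # A > D, P = D (down-dominant)
    IV       = c(f,     1,     f),     # A > D, P = A (up-dominant)
    IX       = c(1,     f,     1),     # D > A, P = A (down-dominant)
    V        = c(1,     f,     f^2),   # D > A, P above both
    VI       = c(f,     1,     f^2),   # A > D, P above both
    VIII     = c(1,     1,     f),     # A = D, P above both (transgressive up)
    III      = c(1,     f,     1 / f), # D > A, P below both
    X        = c(f,     1,     1 / f), # A > D, P below both
    VII      = c(1,     1,     1 / f)  # A = D, P below both (transgressive down)
  )
}

#' Generate per-gene ground truth
#'
#' Assigns every gene a chromosome, silent/expressed status, an ELD category
#' realized in the diploid and polyploid-total means, a homoeolog bias
#' direction and magnitude per polyploid (split of the polyploid total into
#' A_T and D_T means), and a TE distance. Deterministic given the seed.
#'
#' @param config A [sim_config()].
#' @return A list of class `sim_truth`: `genes` (per-gene data.frame),
#'   `mu_A`, `mu_D` (gene x polyploid matrices of homoeolog means),
#'   `bias_dir` (gene x polyploid matrix in `{"A","D","none"}`), and
#'   `config`.
#' @export
generate_truth <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  set.seed(config$seed)
  n <- config$n_genes
  polys <- config$polyploids
  gene_id <- sprintf("g%05d", seq_len(n))
  chrom <- sprintf("Chr%02d", (seq_len(n) - 1L) %% config$n_chromosomes + 1L)

  silent <- seq_len(n) %in% sample.int(n, round(config$frac_silent * n))
  expressed <- which(!silent)

  base <- config$depth * 2^stats::rnorm(n, 0, config$depth_sd_log2)
  base[silent] <- config$depth * config$silent_leak

  # ELD category assignment among expressed genes
  cat_names <- names(config$eld_fractions)
  probs <- c(config$eld_fractions, NoChange = 1 - sum(config$eld_fractions))
  eld <- rep(NA_character_, n)
  eld[expressed] <- sample(names(probs), length(expressed), replace = TRUE, prob = probs)

  mult <- eld_mean_multipliers(config$eld_fold)
  mm <- do.call(rbind, mult[ifelse(is.na(eld), "NoChange", eld)])
  mu_A2 <- base * mm[, 1]
  mu_D5 <- base * mm[, 2]
  mu_P  <- base * mm[, 3]
  mu_A2[silent] <- base[silent]
  mu_D5[silent] <- base[silent]
  mu_P[silent]  <- base[silent]

  # homoeolog bias: conserved genes biased everywhere, same direction;
  # non-conserved genes biased in a random proper subset of polyploids
  n_b <- round(config$frac_biased * length(expressed))
  biased <- sample(expressed, n_b)
  n_cons <- round(config$frac_conserved * n_b)
  cons <- biased[seq_len(n_cons)]
  rest <- setdiff(biased, cons)
  bias_dir <- matrix("none", n, length(polys), dimnames = list(gene_id, polys))
  dir_of <- function(k) sample(c("A", "D"), k, replace = TRUE)
  bias_dir[cons, ] <- dir_of(length(cons))
  for (g in rest) {
    k <- if (length(polys) > 1) sample.int(length(polys) - 1L, 1L) else 1L
    in_acc <- sample(polys, k)
    bias_dir[g, in_acc] <- dir_of(1L)
  }

  w <- 2^config$bias_log2 / (1 + 2^config$bias_log2)  # A_T share when A-biased
  share <- matrix(0.5, n, length(polys))
  share[bias_dir == "A"] <- w
  share[bias_dir == "D"] <- 1 - w
  mu_A <- mu_P * share
  mu_D <- mu_P * (1 - share)
  dimnames(mu_A) <- dimnames(mu_D) <- list(gene_id, polys)

  te_distance <- sample.int(config$te_max_distance + 1L, n, replace = TRUE) - 1L

  truth <- list(
    genes = data.frame(gene_id = gene_id, chrom = chrom, silent = silent,
                       base_mean = base, eld_category = eld,
                       mu_A2 = mu_A2, mu_D5 = mu_D5, mu_P = mu_P,
                       te_distance = te_distance, stringsAsFactors = FALSE),
    mu_A = mu_A, mu_D = mu_D, bias_dir = bias_dir, config = config)
  class(truth) <- "sim_truth"
  truth
}

# NB draws that degrade to Poisson at phi = 0
rnb <- function(n, mu, phi) {
  if (phi == 0) stats::rpois(n, mu) else stats::rnbinom(n, mu = mu, size = 1 / phi)
}

#' Generate read-class count tables
#'
#' For each sample and gene, per-origin read totals are drawn from a negative
#' binomial with the truth-assigned mean and the configured dispersion; each
#' origin read is then assigned (A or D), chimeric (X) or uninformative (N)
#' with the configured class probabilities. Binomial thinning preserves the
#' NB size parameter, so the informative class counts remain NB with the same
#' dispersion. Diploid reads classify only to their own genome or N.
#'
#' @param truth A [generate_truth()] result.
#' @param config The same [sim_config()].
#' @return A list: `counts` (long data.frame gene_id, sample_id, n_A, n_D,
#'   n_X, n_N), `meta` (a [sample_meta()]), `lib_factors` (per-sample relative
#'   library scale).
#' @export
generate_counts <- function(truth, config = truth$config) {
  stopifnot(inherits(truth, "sim_truth"))
  set.seed(config$seed + 1L)
  n <- config$n_genes
  p_assign <- config$class_probs[["assign"]]
  p_x <- config$class_probs[["chimera"]]
  accs <- c(unname(config$diploids), config$polyploids)
  meta <- sample_meta(
    sample_id = as.vector(t(outer(accs, seq_len(config$replicates),
                                  function(a, r) paste0(a, "_r", r)))),
    accession = rep(accs, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(accs)))
  s <- config$libsize_spread
  lib_f <- stats::setNames(s^stats::runif(nrow(meta), -0.5, 0.5), meta$sample_id)
  if (s == 1) lib_f[] <- 1

  split_origin <- function(o, own_p_x) {
    assigned <- stats::rbinom(n, o, p_assign)
    left <- o - assigned
    x <- stats::rbinom(n, left, own_p_x / (1 - p_assign))
    cbind(assigned = assigned, x = x, nn = left - x)
  }
  res <- vector("list", nrow(meta))
  for (i in seq_len(nrow(meta))) {
    acc <- meta$accession[i]
    lf <- lib_f[[meta$sample_id[i]]]
    if (acc == config$diploids[["A"]]) {
      o <- rnb(n, truth$genes$mu_A2 / p_assign * lf, config$phi)
      sp <- split_origin(o, 0)
      nA <- sp[, 1]; nD <- integer(n); nX <- integer(n); nN <- sp[, 3]
    } else if (acc == config$diploids[["D"]]) {
      o <- rnb(n, truth$genes$mu_D5 / p_assign * lf, config$phi)
      sp <- split_origin(o, 0)
      nD <- sp[, 1]; nA <- integer(n); nX <- integer(n); nN <- sp[, 3]
    } else {
      oA <- rnb(n, truth$mu_A[, acc] / p_assign * lf, config$phi)
      oD <- rnb(n, truth$mu_D[, acc] / p_assign * lf, config$phi)
      spA <- split_origin(oA, p_x)
      spD <- split_origin(oD, p_x)
      nA <- spA[, 1]; nD <- spD[, 1]
      nX <- spA[, 2] + spD[, 2]; nN <- spA[, 3] + spD[, 3]
    }
    res[[i]] <- data.frame(gene_id = truth$genes$gene_id,
                           sample_id = meta$sample_id[i],
                           n_A = nA, n_D = nD, n_X = nX, n_N = nN,
                           stringsAsFactors = FALSE)
  }
  list(counts = do.call(rbind, res), meta = meta, lib_factors = lib_f)
}

#' Generate a read-level study: reference, annotation, SNP index, alignments
#'
#' Writes a complete small-scale study to `out_dir`: a random reference
#' (FASTA), two-exon gene models (GFF3), a diagnostic SNP index (TSV, D
#' allele = reference base), TE intervals at the truth-assigned distances
#' (BED3), and one SAM file per sample in which every read carries its true
#' origin in an `XO` tag and the origin's allele at each covered SNP (subject
#' to the configured error rate); chimeric reads carry A- then D-alleles.
#' Output is byte-deterministic given the seed.
#'
#' @param truth A [generate_truth()] result (small scale: <= 500 genes).
#' @param config The same [sim_config()].
#' @param out_dir Output directory (created if missing).
#' @return A list of file paths: `fasta`, `gff3`, `snps`, `te_bed`, `sam`
#'   (named per sample), plus `meta`.
#' @export
generate_reads <- function(truth, config = truth$config, out_dir) {
  stopifnot(inherits(truth, "sim_truth"))
  if (config$n_genes > 500) stop("read-level simulation is desk-scale: use <= 500 genes")
  if (config$read_length < 1) stop("read length must be >= 1")
  if (config$read_length > config$gene_length / 2) {
    stop("read length exceeds exon length")
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(config$seed + 2L)
  bases <- c("A", "C", "G", "T")
  exon_len <- config$gene_length / 2
  unit <- config$gene_length + config$intron_length + 400L  # gene + spacer
  n <- config$n_genes
  chroms <- sort(unique(truth$genes$chrom))

  # lay out genes; chromosome length covers genes, TEs and margins
  idx_on <- split(seq_len(n), truth$genes$chrom)
  gene_start <- integer(n)
  chrom_len <- stats::setNames(integer(length(chroms)), chroms)
  for (ch in chroms) {
    ii <- idx_on[[ch]]
    gene_start[ii] <- 200L + (seq_along(ii) - 1L) * unit
    chrom_len[ch] <- 200L + length(ii) * unit + config$te_max_distance + 400L
  }
  seqs <- lapply(chrom_len, function(L) sample(bases, L, replace = TRUE))

  g <- truth$genes
  e1s <- gene_start; e1e <- gene_start + exon_len - 1L
  e2s <- e1e + config$intron_length + 1L; e2e <- e2s + exon_len - 1L
  gm <- list(
    genes = data.frame(gene_id = g$gene_id, chrom = g$chrom, strand = "+",
                       start = e1s, end = e2e,
                       length = as.integer(2 * exon_len), stringsAsFactors = FALSE),
    exons = GenomicRanges::GRanges(rep(g$chrom, 2),
                                   IRanges::IRanges(c(e1s, e2s), c(e1e, e2e)),
                                   gene_id = rep(g$gene_id, 2)))
  class(gm) <- "gene_models"

  # SNPs every (1000/snp_per_kb) bp within exons, offset to sit mid-exon
  step <- max(1L, round(1000 / config$snp_per_kb))
  snp_rows <- list()
  for (i in seq_len(n)) {
    pos <- c(seq(e1s[i] + 20L, e1e[i], by = step), seq(e2s[i] + 20L, e2e[i], by = step))
    ref <- vapply(pos, function(p) seqs[[g$chrom[i]]][p], "")
    alt <- bases[match(ref, bases) %% 4L + 1L]
    snp_rows[[i]] <- data.frame(chrom = g$chrom[i], pos = pos,
                                allele_A = alt, allele_D = ref,
                                stringsAsFactors = FALSE)
  }
  snps <- do.call(rbind, snp_rows)
  idx <- snp_index(snps$chrom, snps$pos, snps$allele_A, snps$allele_D)

  te <- GenomicRanges::GRanges(g$chrom,
    IRanges::IRanges(e2e + g$te_distance + 1L, width = 200L))

  paths <- list(
    fasta = file.path(out_dir, "reference.fa"),
    gff3 = file.path(out_dir, "genes.gff3"),
    snps = file.path(out_dir, "snps.tsv"),
    te_bed = file.path(out_dir, "te.bed"))
  fa <- file(paths$fasta, "w")
  for (ch in chroms) {
    writeLines(paste0(">", ch), fa)
    s <- paste(seqs[[ch]], collapse = "")
    writeLines(substring(s, seq(1, nchar(s), 60), pmin(nchar(s), seq(60, nchar(s) + 59, 60))), fa)
  }
  close(fa)
  write_gff3(gm, paths$gff3)
  write_snp_index(idx, paths$snps)
  write_bed(te, paths$te_bed)

  # per-chromosome SNP lookup and sequence strings for fast read construction
  snp_by_chrom <- split(snps, snps$chrom)
  chrom_str <- lapply(seqs, paste, collapse = "")

  accs <- c(unname(config$diploids), config$polyploids)
  meta <- sample_meta(
    sample_id = as.vector(t(outer(accs, seq_len(config$replicates),
                                  function(a, r) paste0(a, "_r", r)))),
    accession = rep(accs, each = config$replicates),
    replicate = rep(seq_len(config$replicates), length(accs)))

  rl <- config$read_length
  qual <- strrep("I", rl)
  sam_paths <- character(0)
  for (i in seq_len(nrow(meta))) {
    acc <- meta$accession[i]
    if (acc == config$diploids[["A"]]) {
      muA <- truth$genes$mu_A2; muD <- rep(0, n)
    } else if (acc == config$diploids[["D"]]) {
      muA <- rep(0, n); muD <- truth$genes$mu_D5
    } else {
      muA <- truth$mu_A[, acc]; muD <- truth$mu_D[, acc]
    }
    p_assign <- config$class_probs[["assign"]]
    recs_by_gene <- vector("list", n)
    rid <- 0L
    for (gi in seq_len(n)) {
      counts <- c(A = rnb(1, muA[gi] / p_assign, config$phi),
                  D = rnb(1, muD[gi] / p_assign, config$phi))
      ch <- g$chrom[gi]
      in_gene <- snp_by_chrom[[ch]]$pos >= e1s[gi] & snp_by_chrom[[ch]]$pos <= e2e[gi]
      snp_pos <- snp_by_chrom[[ch]]$pos[in_gene]
      snp_A <- snp_by_chrom[[ch]]$allele_A[in_gene]
      gene_recs <- character(0)
      for (origin in c("A", "D")) {
        k <- counts[[origin]]
        if (k == 0) next
        # place each read fully inside one exon
        exon <- sample(1:2, k, replace = TRUE)
        start <- ifelse(exon == 1L,
                        e1s[gi] + floor(stats::runif(k) * (exon_len - rl + 1)),
                        e2s[gi] + floor(stats::runif(k) * (exon_len - rl + 1)))
        chim <- stats::runif(k) < config$read_chimera_rate
        sq <- substring(chrom_str[[ch]], start, start + rl - 1L)
        n_cov <- integer(k)
        for (s in seq_along(snp_pos)) {
          covers <- start <= snp_pos[s] & snp_pos[s] <= start + rl - 1L
          if (!any(covers)) next
          n_cov[covers] <- n_cov[covers] + 1L
          # plant the origin allele (reference base already encodes D);
          # chimera-flagged reads that end up covering >= 2 SNPs are
          # rebuilt below, so planting them here is harmless
          if (origin == "A") {
            idx <- which(covers)
            if (length(idx)) {
              o <- snp_pos[s] - start[idx] + 1L
              substr(sq[idx], o, o) <- snp_A[s]
            }
          }
          # sequencing errors at the SNP column
          err <- which(covers)[stats::runif(sum(covers)) < config$error_rate]
          for (j in err) {
            o <- snp_pos[s] - start[j] + 1L
            b <- sample(setdiff(bases, substr(sq[j], o, o)), 1L)
            substr(sq[j], o, o) <- b
          }
        }
        # chimeras: A allele at the first covered SNP, D (reference) after
        tag <- rep(origin, k)
        is_x <- chim & n_cov >= 2L
        for (j in which(is_x)) {
          # rebuild from reference, then plant A at the first covered SNP
          sq[j] <- substring(chrom_str[[ch]], start[j], start[j] + rl - 1L)
          cov <- which(snp_pos >= start[j] & snp_pos <= start[j] + rl - 1L)
          o <- snp_pos[cov[1L]] - start[j] + 1L
          substr(sq[j], o, o) <- snp_A[cov[1L]]
          tag[j] <- "X"
        }
        gene_recs <- c(gene_recs, paste(
          paste0(meta$sample_id[i], ".", rid + seq_len(k)), 0L, ch, start, 60L,
          paste0(rl, "M"), "*", 0L, 0L, sq, qual,
          paste0("XO:Z:", tag), sep = "\t"))
        rid <- rid + k
      }
      recs_by_gene[[gi]] <- gene_recs
    }
    p <- file.path(out_dir, paste0(meta$sample_id[i], ".sam"))
    con <- file(p, "w")
    writeLines("@HD\tVN:1.6\tSO:unknown", con)
    for (ch in chroms) writeLines(paste0("@SQ\tSN:", ch, "\tLN:", chrom_len[[ch]]), con)
    writeLines(unlist(recs_by_gene), con)
    close(con)
    sam_paths[meta$sample_id[i]] <- p
  }
  c(paths, list(sam = sam_paths, meta = meta, gene_models = gm))
}
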