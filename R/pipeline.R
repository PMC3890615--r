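#' Pipeline run configuration
#'
#' Bundles the simulation layout with the analysis thresholds: FDR 0.05 for
#' every significance call, presence posterior 0.5 (active) and 0.99
#' (high-confidence, used for bias calling), minimum base quality 20 for
#' allele votes, and a minimum summed count of 5 for the exact test.
#'
#' @param sim A [sim_config()].
#' @param fdr FDR threshold for all calls.
#' @param active_threshold,hi_threshold Presence posterior thresholds.
#' @param min_baseq Minimum base quality for the read classifier.
#' @param min_count Minimum summed raw counts per tested gene.
#' @param with_reads Also run the read-level simulation and partition stage
#'   (desk scale; requires <= 500 genes).
#' @return A validated list of class `run_config`.
#' @export
run_config <- function(sim, fdr = 0.05, active_threshold = 0.5,
                       hi_threshold = 0.99, min_baseq = 20, min_count = 5,
                       with_reads = FALSE) {
  stopifnot(inherits(sim, "sim_config"))
  if (fdr <= 0 || fdr >= 1) stop("fdr must lie in (0, 1)")
  if (active_threshold <= 0 || active_threshold >= 1 ||
      hi_threshold <= 0 || hi_threshold > 1) stop("presence thresholds out of range")
  if (with_reads && sim$n_genes > 500) {
    stop("read-level stage enabled but n_genes > 500")
  }
  structure(list(sim = sim, fdr = fdr, active_threshold = active_threshold,
                 hi_threshold = hi_threshold, min_baseq = min_baseq,
                 min_count = min_count, with_reads = with_reads),
            class = "run_config")
}

#' Read a pipeline configuration from YAML
#'
#' Top-level keys `sim` (arguments to [sim_config()]) and `run` (arguments
#' to [run_config()] other than `sim`).
#'
#' @param path YAML file path.
#' @return A [run_config()].
#' @export
read_run_config <- function(path) {
  y <- yaml::read_yaml(path)
  sim_args <- y$sim
  if (!is.null(sim_args$eld_fractions)) {
    sim_args$eld_fractions <- unlist(sim_args$eld_fractions)
  }
  if (!is.null(sim_args$class_probs)) sim_args$class_probs <- unlist(sim_args$class_probs)
  if (!is.null(sim_args$diploids)) sim_args$diploids <- unlist(sim_args$diploids)
  sim <- do.call(sim_config, sim_args)
  do.call(run_config, c(list(sim = sim), y$run))
}

#' Run the full analysis pipeline on a simulated study
#'
#' Simulation, optional read-level partition, quantification and presence
#' calling, homoeolog-bias calling with all bias summaries, ELD
#' classification, diploid-vs-polyploid cross-classifications, and both
#' expression phylogenies. All result tables are written as TSV (one-line
#' headers, fixed column order) plus Newick trees and a manifest of output
#' checksums; reruns with the same seed are byte-identical.
#'
#' @param cfg A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every intermediate and result object.
#' @export
run_pipeline <- function(cfg, out_dir) {
  stopifnot(inherits(cfg, "run_config"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  sim <- cfg$sim
  polys <- sim$polyploids

  truth <- generate_truth(sim)
  gc <- generate_counts(truth, sim)
  write_counts(gc$counts, file.path(out_dir, "counts.tsv"))
  utils::write.table(gc$meta, file.path(out_dir, "meta.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  part_summary <- NULL
  if (cfg$with_reads) {
    rd <- generate_reads(truth, sim, file.path(out_dir, "reads"))
    snps <- read_snp_index(rd$snps)
    gm <- read_gene_models(rd$gff3)
    pcounts <- partition_samples(rd$sam, gm, snps, min_baseq = cfg$min_baseq)
    write_counts(pcounts, file.path(out_dir, "partition_counts.tsv"))
    part_summary <- summarize_partition(pcounts)
    utils::write.table(part_summary, file.path(out_dir, "partition_summary.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }

  gene_lengths <- stats::setNames(rep(sim$gene_length, sim$n_genes),
                                  truth$genes$gene_id)
  uc <- unit_counts(gc$counts, gc$meta, polyploids = polys)
  pc <- presence_calls(uc, gene_lengths, active_threshold = cfg$active_threshold,
                       hi_threshold = cfg$hi_threshold)
  es <- expressed_sets(pc, n_annotated = sim$n_genes)
  utils::write.table(es$summary, file.path(out_dir, "expressed_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  bias <- list()
  bias_sum <- list()
  for (a in polys) {
    b <- call_bias(uc, gene_lengths, a, presence = pc, min_count = cfg$min_count,
                   fdr = cfg$fdr)
    bias[[a]] <- b
    bias_sum[[a]] <- cbind(accession = a,
                           bias_summary(b, n_expressed = sum(pc$active[, a])))
    utils::write.table(b, file.path(out_dir, paste0("bias_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  bias_sum <- do.call(rbind, bias_sum)
  utils::write.table(bias_sum, file.path(out_dir, "bias_summary.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  biased_sets <- lapply(bias, function(b) {
    intersect(b$gene_id[b$direction != "none"], es$common)
  })
  venn <- venn_partition(biased_sets)
  utils::write.table(venn, file.path(out_dir, "bias_venn.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cons <- conserved_direction(bias)
  utils::write.table(cons$counts, file.path(out_dir, "bias_conserved.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  eld <- list()
  for (a in polys) {
    e <- eld_calls(uc, a, diploids = sim$diploids, presence = pc,
                   min_count = cfg$min_count, fdr = cfg$fdr)
    eld[[a]] <- e
    utils::write.table(e, file.path(out_dir, paste0("eld_", a, ".tsv")),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  eld_sum <- do.call(rbind, lapply(polys, function(a) {
    tab <- table(factor(eld[[a]]$category,
                        levels = c("I", "II", "III", "IV", "V", "VI", "VII",
                                   "VIII", "IX", "X", "XI", "XII", "NoChange",
                                   "Ambiguous")))
    cbind(accession = a, as.data.frame(rbind(as.integer(tab)),
                                       col.names = names(tab)))
  }))
  names(eld_sum) <- c("accession", "I", "II", "III", "IV", "V", "VI", "VII",
                      "VIII", "IX", "X", "XI", "XII", "NoChange", "Ambiguous")
  utils::write.table(eld_sum, file.path(out_dir, "eld_summary.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)

  # cross-classification on the commonly expressed universe
  uA2 <- unit_ids(uc, sim$diploids[["A"]], "total")
  uD5 <- unit_ids(uc, sim$diploids[["D"]], "total")
  diploid_de <- run_contrast(uc, group1 = uD5, group2 = uA2, genes = es$common,
                             min_count = cfg$min_count, fdr = cfg$fdr)
  cross4 <- do.call(rbind, lapply(polys, function(a) {
    univ <- intersect(diploid_de$gene_id, bias[[a]]$gene_id)
    cbind(accession = a,
          diploid_polyploid_matrix(
            diploid_de[diploid_de$gene_id %in% univ, ],
            bias[[a]][bias[[a]]$gene_id %in% univ, ]))
  }))
  utils::write.table(cross4, file.path(out_dir, "cross_declass.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  cross5 <- do.call(rbind, lapply(polys, function(a) {
    cbind(accession = a,
          genome_change_table(uc, a, diploids = sim$diploids, genes = es$common,
                              min_count = cfg$min_count, fdr = cfg$fdr))
  }))
  utils::write.table(cross5, file.path(out_dir, "cross_genome_change.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  prof <- expression_profiles(uc, gene_lengths, genes = es$common)
  tree_expr <- neighbor_joining(ssd_distance(prof))
  write_newick(tree_expr, file.path(out_dir, "tree_expression.nwk"))
  tree_diff <- NULL
  if (length(polys) >= 3) {
    dprof <- homoeolog_diff_profiles(uc, gene_lengths, genes = es$common)
    tree_diff <- neighbor_joining(ssd_distance(dprof))
    write_newick(tree_diff, file.path(out_dir, "tree_homoeolog_diff.nwk"))
  }

  # manifest: parameters and checksums of every artifact
  files <- sort(setdiff(list.files(out_dir, recursive = TRUE), "manifest.txt"))
  sums <- tools::md5sum(file.path(out_dir, files))
  manifest <- c(paste0("seed\t", sim$seed),
                paste0("n_genes\t", sim$n_genes),
                paste0("fdr\t", cfg$fdr),
                paste(unname(sums), files, sep = "\t"))
  writeLines(manifest, file.path(out_dir, "manifest.txt"))

  invisible(list(truth = truth, counts = gc, units = uc, presence = pc,
                 expressed = es, bias = bias, bias_summary = bias_sum,
                 venn = venn, conserved = cons, eld = eld,
                 eld_summary = eld_sum, diploid_de = diploid_de,
                 cross_declass = cross4, cross_genome_change = cross5,
                 tree_expression = tree_expr, tree_homoeolog_diff = tree_diff,
                 partition_summary = part_summary))
}
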