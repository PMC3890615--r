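#' Read a homoeo-SNP index
#'
#' Parses a four-column TSV of diagnostic SNPs that distinguish the A- and
#' D-subgenome copies of each gene on the D reference: reference sequence
#' name, 1-based position, A-genome allele, D-genome allele. A header line is
#' auto-detected (first row whose position column is not an integer).
#'
#' @param path Path to a tab-separated file.
#' @return A `data.frame` of class `snp_index` with columns `chrom`, `pos`
#'   (1-based), `allele_A`, `allele_D`, sorted by `(chrom, pos)`.
#' @export
read_snp_index <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0L) {
    return(snp_index(character(), integer(), character(), character()))
  }
  first <- strsplit(lines[1L], "\t", fixed = TRUE)[[1L]]
  skip <- if (length(first) >= 2L && is.na(suppressWarnings(as.integer(first[2L])))) 1L else 0L
  if (skip == 1L && length(lines) == 1L) {
    return(snp_index(character(), integer(), character(), character()))
  }
  x <- utils::read.table(text = lines, sep = "\t", skip = skip,
                         colClasses = c("character", "integer", "character", "character"),
                         col.names = c("chrom", "pos", "allele_A", "allele_D"))
  idx <- snp_index(x$chrom, x$pos, toupper(x$allele_A), toupper(x$allele_D),
                   line_offset = skip)
  idx
}

#' Construct and validate a SNP index
#'
#' @param chrom,pos,allele_A,allele_D Parallel vectors of SNP records.
#' @param line_offset Internal; shifts line numbers in error messages.
#' @return A validated, sorted `snp_index` data.frame.
#' @export
snp_index <- function(chrom, pos, allele_A, allele_D, line_offset = 0L) {
  x <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                  allele_A = as.character(allele_A), allele_D = as.character(allele_D),
                  stringsAsFactors = FALSE)
  if (nrow(x) > 0L) {
    bases <- c("A", "C", "G", "T")
    bad <- which(!(x$allele_A %in% bases) | !(x$allele_D %in% bases))
    if (length(bad)) {
      stop("SNP index line ", bad[1L] + line_offset, ": alleles must be one of A,C,G,T")
    }
    same <- which(x$allele_A == x$allele_D)
    if (length(same)) {
      stop("SNP index line ", same[1L] + line_offset,
           ": allele_A equals allele_D (", x$allele_A[same[1L]], ")")
    }
    if (any(x$pos < 1L)) stop("SNP positions must be >= 1 (1-based)")
    key <- paste(x$chrom, x$pos)
    dup <- which(duplicated(key))
    if (length(dup)) {
      stop("SNP index line ", dup[1L] + line_offset, ": duplicate position ",
           x$chrom[dup[1L]], ":", x$pos[dup[1L]])
    }
    x <- x[order(x$chrom, x$pos), , drop = FALSE]
    rownames(x) <- NULL
  }
  class(x) <- c("snp_index", "data.frame")
  x
}

#' Write a SNP index as TSV
#' @param x A `snp_index`.
#' @param path Output path.
#' @export
write_snp_index <- function(x, path) {
  utils::write.table(as.data.frame(x), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = c("chrom", "pos", "allele_A", "allele_D"))
  invisible(path)
}

#' Read gene models from GFF3
#'
#' Imports `gene` and `exon` features and resolves exon `Parent` attributes
#' (directly, or through an intermediate mRNA feature) to genes. Exons of one
#' gene are unioned, so overlapping annotation does not double-count length.
#' A gene without any resolvable exon falls back to its own span as a single
#' exon (with a message). Coordinates are held 1-based closed (the GFF3 and
#' GRanges convention); conversion to other conventions happens only at
#' format boundaries.
#'
#' @param path Path to a GFF3 file.
#' @return A list of class `gene_models` with elements `genes` (data.frame:
#'   `gene_id`, `chrom`, `strand`, `start`, `end`, `length` = summed exon bp)
#'   and `exons` (a `GRanges` with a `gene_id` metadata column).
#' @export
read_gene_models <- function(path) {
  gr <- rtracklayer::import(path, format = "gff3")
  type <- as.character(gr$type)
  genes <- gr[type == "gene"]
  if (length(genes) == 0L) stop("no gene features in ", path)
  gene_ids <- as.character(genes$ID)
  if (anyNA(gene_ids)) stop("gene feature without ID attribute in ", path)

  # map transcript-level features to their parent gene
  tx <- gr[!(type %in% c("gene", "exon"))]
  tx_parent <- vapply(as.list(tx$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
  tx_map <- stats::setNames(tx_parent, as.character(tx$ID))

  exons <- gr[type == "exon"]
  if (length(exons)) {
    par <- vapply(as.list(exons$Parent), function(p) if (length(p)) p[[1L]] else NA_character_, "")
    gene_of <- ifelse(par %in% gene_ids, par,
                      ifelse(par %in% names(tx_map), unname(tx_map[par]), NA_character_))
    orphan <- is.na(gene_of) | !(gene_of %in% gene_ids)
    if (any(orphan)) {
      warning(sum(orphan), " exon(s) with unresolvable Parent skipped")
      exons <- exons[!orphan]
      gene_of <- gene_of[!orphan]
    }
    exons$gene_id <- gene_of
  } else {
    gene_of <- character()
  }

  # union exon intervals per gene; genes with no exons use their span
  ex_list <- vector("list", length(gene_ids))
  names(ex_list) <- gene_ids
  if (length(exons)) {
    spl <- split(IRanges::ranges(exons), exons$gene_id)
    red <- lapply(spl, IRanges::reduce)
    ex_list[names(red)] <- red
  }
  no_exon <- vapply(ex_list, is.null, TRUE)
  if (any(no_exon)) {
    message(sum(no_exon), " gene(s) without exons: using gene span")
    for (i in which(no_exon)) {
      ex_list[[i]] <- IRanges::ranges(genes[i])
    }
  }
  widths <- vapply(ex_list, function(r) sum(IRanges::width(r)), 0)
  chroms <- as.character(GenomicRanges::seqnames(genes))
  ex_gr <- GenomicRanges::GRanges(
    rep(chroms, lengths(ex_list)),
    unlist(IRanges::IRangesList(ex_list), use.names = FALSE),
    gene_id = rep(gene_ids, lengths(ex_list)))
  gm <- list(
    genes = data.frame(gene_id = gene_ids, chrom = chroms,
                       strand = as.character(GenomicRanges::strand(genes)),
                       start = GenomicRanges::start(genes), end = GenomicRanges::end(genes),
                       length = as.integer(widths), stringsAsFactors = FALSE),
    exons = ex_gr)
  class(gm) <- "gene_models"
  gm
}

#' Write gene models as GFF3
#'
#' Inverse of [read_gene_models()]: emits one `gene` feature per gene and one
#' `exon` feature per exon interval, 1-based closed per the GFF3 standard.
#'
#' @param gm A `gene_models` object.
#' @param path Output path.
#' @export
write_gff3 <- function(gm, path) {
  g <- gm$genes
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  ex <- gm$exons
  ex_by <- split(seq_along(ex), ex$gene_id)
  for (i in seq_len(nrow(g))) {
    writeLines(paste(g$chrom[i], "homeolyze", "gene", g$start[i], g$end[i], ".",
                     g$strand[i], ".", paste0("ID=", g$gene_id[i]), sep = "\t"), con)
    for (j in ex_by[[g$gene_id[i]]]) {
      writeLines(paste(g$chrom[i], "homeolyze", "exon",
                       GenomicRanges::start(ex)[j], GenomicRanges::end(ex)[j], ".",
                       g$strand[i], ".",
                       paste0("ID=", g$gene_id[i], ".e", j, ";Parent=", g$gene_id[i]),
                       sep = "\t"), con)
    }
  }
  invisible(path)
}

#' Read transposable-element intervals from BED3
#'
#' BED is 0-based half-open on disk; the returned `GRanges` is 1-based closed.
#'
#' @param path Path to a BED3 file.
#' @return A `GRanges` of TE intervals.
#' @export
read_te_bed <- function(path) {
  x <- utils::read.table(path, sep = "\t",
                         colClasses = c("character", "integer", "integer"),
                         col.names = c("chrom", "start0", "end0"))
  GenomicRanges::GRanges(x$chrom, IRanges::IRanges(x$start0 + 1L, x$end0))
}

#' Write intervals as BED3
#' @param gr A `GRanges` (1-based closed; written 0-based half-open).
#' @param path Output path.
#' @export
write_bed <- function(gr, path) {
  utils::write.table(
    data.frame(as.character(GenomicRanges::seqnames(gr)),
               GenomicRanges::start(gr) - 1L, GenomicRanges::end(gr)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Serialize a tree to Newick
#'
#' @param tree An `ape::phylo` tree with leaf labels and branch lengths.
#' @param path Optional output path; when `NULL` the Newick string is returned.
#' @param digits Significant digits for branch lengths (default 10).
#' @return The Newick string, invisibly when written to `path`.
#' @export
write_newick <- function(tree, path = NULL, digits = 10) {
  stopifnot(inherits(tree, "phylo"))
  if (anyDuplicated(tree$tip.label)) stop("duplicate leaf labels in tree")
  bad <- grepl("[(),:;'\"[:space:]]", tree$tip.label)
  if (any(bad)) {
    stop("leaf label not representable in Newick: ",
         tree$tip.label[bad][1L])
  }
  txt <- ape::write.tree(tree, digits = digits)
  if (is.null(path)) return(txt)
  writeLines(txt, path)
  invisible(txt)
}

#' Read a Newick tree
#' @param path Path to a Newick file (or a Newick string via `text`).
#' @param text Optional Newick string instead of a file.
#' @return An `ape::phylo` tree.
#' @export
read_newick <- function(path = NULL, text = NULL) {
  if (is.null(text)) ape::read.tree(path) else ape::read.tree(text = text)
}

#' Write a long-format class-count table as TSV
#'
#' Column order is fixed: `gene_id`, `sample_id`, `n_A`, `n_D`, `n_X`, `n_N`.
#' @param counts Long data.frame of per-gene, per-sample class counts.
#' @param path Output path.
#' @export
write_counts <- function(counts, path) {
  cols <- c("gene_id", "sample_id", "n_A", "n_D", "n_X", "n_N")
  stopifnot(all(cols %in% names(counts)))
  utils::write.table(counts[, cols], path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a class-count table written by [write_counts()]
#' @param path TSV path.
#' @return Long data.frame of class counts.
#' @export
read_counts <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
}

#' Sample metadata constructor
#'
#' @param sample_id,accession,replicate Parallel vectors; one row per
#'   sequenced library.
#' @return A validated data.frame of class `sample_meta`.
#' @export
sample_meta <- function(sample_id, accession, replicate) {
  x <- data.frame(sample_id = as.character(sample_id),
                  accession = as.character(accession),
                  replicate = as.integer(replicate), stringsAsFactors = FALSE)
  if (anyDuplicated(x$sample_id)) stop("duplicate sample_id")
  if (anyDuplicated(x[, c("accession", "replicate")])) {
    stop("duplicate (accession, replicate)")
  }
  class(x) <- c("sample_meta", "data.frame")
  x
}
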