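#' Load primary mapped alignments from SAM/BAM
#'
#' SAM input is converted on the fly via [Rsamtools::asBam()]. Secondary,
#' supplementary and unmapped records are dropped; duplicates are kept (no
#' deduplication is applied).
#'
#' @param path Path to a `.sam` or `.bam` file.
#' @return A data.frame with columns `qname`, `chrom`, `pos` (1-based
#'   leftmost), `cigar`, `seq`, `qual` (ASCII phred+33), and `tag_xo` (origin
#'   tag when present, else `NA`).
#' @export
load_alignments <- function(path) {
  bam <- path
  if (grepl("\\.sam$", path, ignore.case = TRUE)) {
    dest <- tempfile(fileext = "")
    bam <- suppressMessages(Rsamtools::asBam(path, destination = dest,
                                             overwrite = TRUE, indexDestination = FALSE))
  }
  flag <- Rsamtools::scanBamFlag(isUnmappedQuery = FALSE,
                                 isSecondaryAlignment = FALSE,
                                 isSupplementaryAlignment = FALSE)
  param <- Rsamtools::ScanBamParam(
    flag = flag, what = c("qname", "rname", "pos", "cigar", "seq", "qual"),
    tag = "XO")
  x <- Rsamtools::scanBam(bam, param = param)[[1L]]
  xo <- x$tag$XO
  if (is.null(xo)) xo <- rep(NA_character_, length(x$qname))
  data.frame(qname = x$qname, chrom = as.character(x$rname), pos = x$pos,
             cigar = x$cigar, seq = as.character(x$seq),
             qual = as.character(x$qual), tag_xo = xo, stringsAsFactors = FALSE)
}

# Map query base offsets to reference positions for the aligned (M/=/X)
# part of one CIGAR. Insertions and soft clips consume query only, D/N
# reference only, so no allele is ever called through an indel.
cigar_aligned_pairs <- function(cigar, pos) {
  if (grepl("^[0-9]+M$", cigar)) {
    w <- as.integer(sub("M", "", cigar, fixed = TRUE))
    return(list(qpos = seq_len(w), rpos = seq.int(pos, length.out = w)))
  }
  lens <- as.integer(regmatches(cigar, gregexpr("[0-9]+", cigar))[[1L]])
  ops <- regmatches(cigar, gregexpr("[MIDNSHP=X]", cigar))[[1L]]
  qpos <- integer(0); rpos <- integer(0)
  q <- 1L; r <- pos
  for (k in seq_along(ops)) {
    L <- lens[k]
    op <- ops[k]
    if (op %in% c("M", "=", "X")) {
      qpos <- c(qpos, seq.int(q, length.out = L))
      rpos <- c(rpos, seq.int(r, length.out = L))
      q <- q + L; r <- r + L
    } else if (op %in% c("I", "S")) {
      q <- q + L
    } else if (op %in% c("D", "N")) {
      r <- r + L
    } # H, P consume neither
  }
  list(qpos = qpos, rpos = rpos)
}

#' Classify aligned reads by homoeo-SNP alleles
#'
#' For each read, every index SNP covered by an aligned base with base
#' quality at or above `min_baseq` casts a vote: A if the base equals the
#' A-genome allele, D if it equals the D-genome allele; bases matching
#' neither allele abstain (treated as sequencing error). A read with at least
#' one A vote and no D votes is class A (and vice versa); one of each makes a
#' chimeric X read; no votes at all leaves the read uninformative (N). Reads
#' on a reference sequence absent from the index are N (counted in the
#' `unknown_chrom` attribute).
#'
#' @param aln Alignments from [load_alignments()] (mapped, primary).
#' @param snps A [snp_index()].
#' @param min_baseq Minimum base quality for a vote (default 20).
#' @return Character vector in `{"A","D","X","N"}`, one element per read,
#'   with attribute `unknown_chrom` (count of reads on chromosomes not in the
#'   index).
#' @export
classify_reads <- function(aln, snps, min_baseq = 20) {
  n <- nrow(aln)
  out <- rep("N", n)
  snp_chr <- split(seq_len(nrow(snps)), snps$chrom)
  known <- names(snp_chr)
  unknown <- 0L
  for (i in seq_len(n)) {
    ch <- aln$chrom[i]
    if (!(ch %in% known)) {
      if (nrow(snps) > 0L) unknown <- unknown + 1L
      next
    }
    rows <- snp_chr[[ch]]
    pr <- cigar_aligned_pairs(aln$cigar[i], aln$pos[i])
    if (!length(pr$rpos)) next
    hit <- rows[snps$pos[rows] >= pr$rpos[1L] & snps$pos[rows] <= pr$rpos[length(pr$rpos)]]
    if (!length(hit)) next
    m <- match(snps$pos[hit], pr$rpos)
    keep <- !is.na(m)
    hit <- hit[keep]; m <- m[keep]
    if (!length(hit)) next
    qoff <- pr$qpos[m]
    qv <- utf8ToInt(aln$qual[i])[qoff] - 33L
    ok <- qv >= min_baseq
    if (!any(ok)) next
    base <- substring(aln$seq[i], qoff[ok], qoff[ok])
    a_votes <- sum(base == snps$allele_A[hit[ok]])
    d_votes <- sum(base == snps$allele_D[hit[ok]])
    out[i] <- if (a_votes > 0 && d_votes == 0) "A"
              else if (d_votes > 0 && a_votes == 0) "D"
              else if (a_votes > 0 && d_votes > 0) "X"
              else "N"
  }
  if (unknown > 0L) warning(unknown, " read(s) on chromosomes absent from the SNP index")
  attr(out, "unknown_chrom") <- unknown
  out
}

#' Assign reads to genes and tally read classes per gene
#'
#' Each primary alignment is assigned to the gene whose exons it overlaps
#' most (bp of aligned overlap); ties and zero-overlap reads stay unassigned
#' but are still tallied in the `unassigned` attribute so that class totals
#' are conserved.
#'
#' @param aln Alignments from [load_alignments()].
#' @param gene_models A [read_gene_models()] result.
#' @param snps A [snp_index()].
#' @param min_baseq Minimum base quality for an allele vote.
#' @param sample_id Sample label recorded in the output.
#' @return A data.frame (gene_id, sample_id, n_A, n_D, n_X, n_N), one row per
#'   gene, with attribute `unassigned` = named class totals of reads not
#'   assigned to any gene.
#' @export
count_reads_by_gene <- function(aln, gene_models, snps, min_baseq = 20,
                                sample_id = "sample") {
  if (is.null(gene_models) || nrow(gene_models$genes) == 0L) stop("no genes loaded")
  cls <- classify_reads(aln, snps, min_baseq)
  n <- nrow(aln)
  gene_of <- rep(NA_character_, n)
  if (n > 0L) {
    blocks <- lapply(seq_len(n), function(i) {
      pr <- cigar_aligned_pairs(aln$cigar[i], aln$pos[i])
      if (!length(pr$rpos)) return(IRanges::IRanges())
      IRanges::reduce(IRanges::IRanges(pr$rpos, width = 1L))
    })
    nb <- vapply(blocks, length, 0L)
    rgr <- GenomicRanges::GRanges(rep(aln$chrom, nb),
                                  unlist(IRanges::IRangesList(blocks), use.names = FALSE))
    read_of_block <- rep(seq_len(n), nb)
    ov <- GenomicRanges::findOverlaps(rgr, gene_models$exons)
    if (length(ov)) {
      w <- IRanges::width(IRanges::pintersect(
        IRanges::ranges(rgr)[S4Vectors::queryHits(ov)],
        IRanges::ranges(gene_models$exons)[S4Vectors::subjectHits(ov)]))
      key <- paste(read_of_block[S4Vectors::queryHits(ov)],
                   gene_models$exons$gene_id[S4Vectors::subjectHits(ov)], sep = "\r")
      tot <- rowsum(w, key)
      parts <- strsplit(rownames(tot), "\r", fixed = TRUE)
      ridx <- as.integer(vapply(parts, `[`, "", 1L))
      gids <- vapply(parts, `[`, "", 2L)
      ww <- tot[, 1L]
      # per read: max-overlap gene, ties discarded
      o <- order(ridx, -ww)
      ridx <- ridx[o]; gids <- gids[o]; ww <- ww[o]
      first <- which(!duplicated(ridx))
      nxt <- first + 1L
      tied <- nxt <= length(ridx) &
        ridx[pmin(nxt, length(ridx))] == ridx[first] &
        ww[pmin(nxt, length(ridx))] == ww[first]
      gene_of[ridx[first][!tied]] <- gids[first][!tied]
    }
  }
  lev <- c("A", "D", "X", "N")
  assigned <- !is.na(gene_of)
  tab <- table(factor(gene_of[assigned], levels = gene_models$genes$gene_id),
               factor(cls[assigned], levels = lev))
  out <- data.frame(gene_id = gene_models$genes$gene_id, sample_id = sample_id,
                    n_A = as.integer(tab[, "A"]), n_D = as.integer(tab[, "D"]),
                    n_X = as.integer(tab[, "X"]), n_N = as.integer(tab[, "N"]),
                    stringsAsFactors = FALSE)
  una <- table(factor(cls[!assigned], levels = lev))
  attr(out, "unassigned") <- stats::setNames(as.integer(una), lev)
  out
}

#' Partition a set of samples
#'
#' Runs [count_reads_by_gene()] on one SAM/BAM per sample.
#'
#' @param sam_paths Named character vector of file paths (names = sample ids).
#' @param gene_models,snps,min_baseq See [count_reads_by_gene()].
#' @return Long count data.frame across samples with attribute `unassigned`
#'   (sample x class matrix).
#' @export
partition_samples <- function(sam_paths, gene_models, snps, min_baseq = 20) {
  res <- vector("list", length(sam_paths))
  una <- matrix(0L, length(sam_paths), 4L,
                dimnames = list(names(sam_paths), c("A", "D", "X", "N")))
  for (i in seq_along(sam_paths)) {
    aln <- load_alignments(sam_paths[[i]])
    res[[i]] <- count_reads_by_gene(aln, gene_models, snps, min_baseq,
                                    sample_id = names(sam_paths)[i])
    una[i, ] <- attr(res[[i]], "unassigned")
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  attr(out, "unassigned") <- una
  out
}

#' Per-sample read-class accounting
#'
#' Totals per class (genic plus unassigned tallies when supplied), the mapped
#' total, and the percent of mapped reads categorized to a subgenome or as
#' chimeric (A+D+X), mirroring a read-accounting table.
#'
#' @param counts Long per-gene class-count data.frame.
#' @param unassigned Optional sample x class matrix of unassigned-read
#'   tallies (as attached by [partition_samples()]).
#' @return A data.frame: sample_id, A, D, X, N, mapped, pct_categorized.
#' @export
summarize_partition <- function(counts, unassigned = attr(counts, "unassigned")) {
  agg <- rowsum(counts[, c("n_A", "n_D", "n_X", "n_N")], counts$sample_id)
  m <- as.matrix(agg)
  colnames(m) <- c("A", "D", "X", "N")
  if (!is.null(unassigned)) {
    m <- m + unassigned[rownames(m), , drop = FALSE]
  }
  mapped <- rowSums(m)
  pct <- ifelse(mapped > 0, (m[, "A"] + m[, "D"] + m[, "X"]) / mapped * 100, 0)
  data.frame(sample_id = rownames(m), A = m[, "A"], D = m[, "D"], X = m[, "X"],
             N = m[, "N"], mapped = mapped, pct_categorized = pct,
             row.names = NULL, stringsAsFactors = FALSE)
}
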