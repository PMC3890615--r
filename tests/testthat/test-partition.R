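# A tiny hand-built alignment fixture on one 200-bp chromosome with SNPs at
# positions 50 (A allele G, D allele T) and 70 (A allele A, D allele C).
fixture_snps <- function() {
  snp_index(c("chr1", "chr1"), c(50L, 70L), c("G", "A"), c("T", "C"))
}

fixture_aln <- function() {
  base <- strrep("C", 41)
  q40 <- strrep("I", 41)
  recs <- data.frame(
    qname = c("rA", "rX", "rN", "rMM", "rLQ", "rIndel", "r2"),
    flag = 0L, chrom = "chr1",
    pos = c(40L, 40L, 120L, 40L, 40L, 40L, 40L),
    cigar = c("41M", "41M", "41M", "41M", "41M", "10M5D31M", "41M"),
    # pos 40..80 covers both SNPs at offsets 11 and 31
    seq = c(
      sub("^(.{10}).(.{19}).(.*)$", "\\1G\\2A\\3", base),   # A at both -> A
      sub("^(.{10}).(.{19}).(.*)$", "\\1G\\2C\\3", base),   # A then D -> X
      base,                                                  # no SNP overlap
      sub("^(.{10}).(.{19}).(.*)$", "\\1T\\2C\\3", base),   # D at both, but
      sub("^(.{10}).(.{19}).(.*)$", "\\1G\\2A\\3", base),   # A alleles, low qual
      # 10M5D31M: query base 11 sits at ref 56 (post-deletion); SNP 50 falls in
      # the deletion shadow of nothing -- ref positions 40..49 then 55..85, so
      # SNP 50 is skipped and SNP 70 maps to query offset 26
      sub("^(.{25}).(.*)$", "\\1A\\2", base),               # A vote at SNP 70
      sub("^(.{30}).(.*)$", "\\1G\\2", base)),              # C/G: match neither
    qual = c(q40, q40, q40, q40, strrep("#", 41), q40, q40),
    stringsAsFactors = FALSE)
  write_test_sam(recs, c(chr1 = 200L))
}

test_that("read classification follows the allele-vote rules", {
  aln <- load_alignments(fixture_aln())
  cls <- classify_reads(aln, fixture_snps(), min_baseq = 20)
  got <- setNames(as.character(cls), aln$qname)
  expect_equal(got[["rA"]], "A")     # A alleles at both SNPs
  expect_equal(got[["rX"]], "X")     # one A and one D vote: chimeric
  expect_equal(got[["rN"]], "N")     # overlaps no SNP
  expect_equal(got[["rMM"]], "D")    # D alleles at both SNPs
  expect_equal(got[["rLQ"]], "N")    # votes blocked by base quality
  expect_equal(got[["rIndel"]], "A") # deletion skips SNP 50; SNP 70 votes A
  expect_equal(got[["r2"]], "N")     # bases match neither allele: abstain
})

test_that("raising the base-quality threshold never creates new calls", {
  cfg <- sim_config(n_genes = 15, depth = 20, error_rate = 0.05, seed = 77)
  out <- generate_reads(generate_truth(cfg), cfg, tempfile())
  aln <- load_alignments(out$sam[["Tx_r1"]])
  snps <- read_snp_index(out$snps)
  lo <- classify_reads(aln, snps, min_baseq = 10)
  hi <- classify_reads(aln, snps, min_baseq = 41)
  expect_true(all(lo[hi != "N"] != "N"))
  expect_true(all(hi[lo == "N"] == "N"))
})

test_that("reads on chromosomes outside the index are N with a warning", {
  recs <- data.frame(qname = "r1", flag = 0L, chrom = "chrZ", pos = 10L,
                     cigar = "5M", seq = "ACGTA", qual = "IIIII",
                     stringsAsFactors = FALSE)
  aln <- load_alignments(write_test_sam(recs, c(chrZ = 100L)))
  expect_warning(cls <- classify_reads(aln, fixture_snps()), "absent from the SNP index")
  expect_equal(as.character(cls), "N")
  expect_equal(attr(cls, "unknown_chrom"), 1L)
})

test_that("gene assignment uses maximum exon overlap and drops ties", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c(
    "##gff-version 3",
    "chr1\ts\tgene\t1\t60\t.\t+\t.\tID=G1",
    "chr1\ts\texon\t1\t60\t.\t+\t.\tID=G1.e;Parent=G1",
    "chr1\ts\tgene\t61\t120\t.\t+\t.\tID=G2",
    "chr1\ts\texon\t61\t120\t.\t+\t.\tID=G2.e;Parent=G2"), p)
  gm <- read_gene_models(p)
  sq <- strrep("A", 40); q <- strrep("I", 40)
  recs <- data.frame(
    qname = c("in1", "span", "tie", "sec"),
    flag = c(0L, 0L, 0L, 256L),
    chrom = "chr1",
    pos = c(10L, 31L, 41L, 10L),  # span: 30 bp in G1, 10 bp in G2
    cigar = "40M", seq = sq, qual = q, stringsAsFactors = FALSE)
  aln <- load_alignments(write_test_sam(recs, c(chr1 = 200L)))
  expect_equal(nrow(aln), 3L)  # secondary alignment dropped at load
  cnt <- count_reads_by_gene(aln, gm, fixture_snps(), sample_id = "s")
  expect_equal(cnt$n_N[cnt$gene_id == "G1"], 1L)  # in1 (covers no SNP)
  expect_equal(cnt$n_A[cnt$gene_id == "G1"], 1L)  # span: 30 bp > 10 bp, A vote
  expect_equal(sum(cnt[cnt$gene_id == "G2", c("n_A", "n_D", "n_X", "n_N")]), 0L)
  expect_equal(sum(attr(cnt, "unassigned")), 1L)  # the 20/20 tie read
})

test_that("per-gene class tallies match a hand count", {
  p <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               "chr1\ts\tgene\t30\t100\t.\t+\t.\tID=G",
               "chr1\ts\texon\t30\t100\t.\t+\t.\tID=G.e;Parent=G"), p)
  gm <- read_gene_models(p)
  base <- strrep("C", 41); q40 <- strrep("I", 41)
  mk <- function(qn, seq) data.frame(qname = qn, flag = 0L, chrom = "chr1",
                                     pos = 40L, cigar = "41M", seq = seq,
                                     qual = q40, stringsAsFactors = FALSE)
  recs <- rbind(
    mk("a1", sub("^(.{10}).(.{19}).(.*)$", "\\1G\\2A\\3", base)),
    mk("a2", sub("^(.{10}).(.{19}).(.*)$", "\\1G\\2G\\3", base)),  # A + abstain
    mk("d1", sub("^(.{10}).(.{19}).(.*)$", "\\1T\\2C\\3", base)),
    mk("n1", sub("^(.{30}).(.*)$", "\\1G\\2", base)))  # neither allele: abstains
  aln <- load_alignments(write_test_sam(recs, c(chr1 = 200L)))
  cnt <- count_reads_by_gene(aln, gm, fixture_snps(), sample_id = "s")
  expect_equal(cnt[cnt$gene_id == "G", c("n_A", "n_D", "n_X", "n_N")],
               data.frame(n_A = 2L, n_D = 1L, n_X = 0L, n_N = 1L),
               ignore_attr = TRUE)
})

test_that("classification is exact on error-free planted reads", {
  cfg <- sim_config(n_genes = 25, depth = 25, error_rate = 0,
                    read_chimera_rate = 0, seed = 201)
  out <- generate_reads(generate_truth(cfg), cfg, tempfile())
  snps <- read_snp_index(out$snps)
  for (s in c("A2_r1", "Maxxa_r2")) {
    aln <- load_alignments(out$sam[[s]])
    cls <- classify_reads(aln, snps)
    informative <- cls != "N"
    expect_true(all(cls[informative] == aln$tag_xo[informative]))
  }
})

test_that("planted chimeras classify as X when SNPs are dense enough", {
  cfg <- sim_config(n_genes = 15, depth = 20, error_rate = 0,
                    read_chimera_rate = 0.5, snp_per_kb = 50, seed = 17)
  out <- generate_reads(generate_truth(cfg), cfg, tempfile())
  aln <- load_alignments(out$sam[["Tom_r1"]])
  cls <- classify_reads(aln, read_snp_index(out$snps))
  planted_x <- aln$tag_xo == "X"
  expect_gt(sum(planted_x), 20)
  expect_true(all(cls[planted_x] == "X"))
  expect_true(all(cls[!planted_x & cls != "N"] == aln$tag_xo[!planted_x & cls != "N"]))
})

test_that("class totals are conserved through counting and summary", {
  cfg <- sim_config(n_genes = 20, depth = 20, seed = 55)
  out <- generate_reads(generate_truth(cfg), cfg, tempfile())
  snps <- read_snp_index(out$snps)
  gm <- read_gene_models(out$gff3)
  paths <- out$sam[c("F1_r1", "F1_r2")]
  counts <- partition_samples(paths, gm, snps)
  sm <- summarize_partition(counts)
  for (s in names(paths)) {
    n_reads <- nrow(load_alignments(paths[[s]]))
    expect_equal(sm$mapped[sm$sample_id == s], n_reads)
    per_gene <- counts[counts$sample_id == s, ]
    expect_equal(sum(per_gene[, c("n_A", "n_D", "n_X", "n_N")]) +
                   sum(attr(counts, "unassigned")[s, ]), n_reads)
  }
})

test_that("per-sample accounting reproduces printed-style percentages", {
  # a sample with 8 + 8.4 + 0.1 categorized of 31.6 mapped (millions)
  sm <- data.frame(sample_id = "F1", A = 8, D = 8.4, X = 0.1, N = 15.1)
  pct <- (sm$A + sm$D + sm$X) / (sm$A + sm$D + sm$X + sm$N) * 100
  expect_equal(round(pct, 1), 52.2)
  # all-N sample: nothing categorized
  counts <- make_counts_long("g1", "s1", n_A = 0, n_D = 0, n_X = 0, n_N = 10)
  out <- summarize_partition(counts)
  expect_equal(out$pct_categorized, 0)
})
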