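test_that("bias calling recovers planted direction and skips diploids", {
  cfg <- sim_config(n_genes = 600, frac_biased = 0.3, frac_conserved = 1,
                    seed = 71)
  tr <- generate_truth(cfg)
  gc <- generate_counts(tr, cfg)
  uc <- unit_counts(gc$counts, gc$meta, cfg$polyploids)
  gl <- setNames(rep(cfg$gene_length, cfg$n_genes), tr$genes$gene_id)
  b <- call_bias(uc, gl, "Tom")
  truthdir <- tr$bias_dir[, "Tom"]
  called <- b$direction != "none"
  truly <- truthdir[b$gene_id] != "none"
  # calls on truly biased genes always carry the planted direction
  expect_true(all(b$direction[called & truly] == truthdir[b$gene_id][called & truly]))
  expect_gt(mean(called[truly]), 0.5)
  expect_lt(mean(called[!truly]), 0.05)
  expect_error(call_bias(uc, gl, "A2"), "no A/D partition units")
})

test_that("identical homoeolog counts give zero degree and no call", {
  counts <- make_counts_long(paste0("g", 1:60), "P_r1",
                             n_A = rep(30L, 60), n_D = rep(30L, 60))
  counts <- rbind(counts,
                  make_counts_long(paste0("g", 1:60), "P_r2",
                                   n_A = rep(28L, 60), n_D = rep(28L, 60)))
  meta <- sample_meta(c("P_r1", "P_r2"), c("P", "P"), 1:2)
  uc <- unit_counts(counts, meta, polyploids = "P")
  gl <- setNames(rep(1000L, 60), paste0("g", 1:60))
  b <- call_bias(uc, gl, "P")
  expect_true(all(b$degree == 0))
  expect_true(all(b$direction == "none"))
})

test_that("presence filtering restricts the tested universe", {
  cfg <- sim_config(n_genes = 400, frac_silent = 0.4, seed = 72)
  tr <- generate_truth(cfg)
  gc <- generate_counts(tr, cfg)
  uc <- unit_counts(gc$counts, gc$meta, cfg$polyploids)
  gl <- setNames(rep(cfg$gene_length, cfg$n_genes), tr$genes$gene_id)
  pc <- presence_calls(uc, gl)
  b <- call_bias(uc, gl, "Maxxa", presence = pc)
  hi <- rownames(pc$high_conf)[pc$high_conf[, "Maxxa"]]
  expect_setequal(b$gene_id, hi)
})

test_that("bias summaries reproduce ratio and percentage arithmetic", {
  b <- make_bias_table(paste0("g", 1:3000),
                       c(rep("A", 1027), rep("D", 1033), rep("none", 940)))
  s <- bias_summary(b, n_expressed = 15471)
  expect_equal(s$bias_ratio, 0.99)
  expect_equal(s$pct_biased, 13.3)
  expect_equal(s$n_A_bias + s$n_D_bias, s$n_biased)
  # zero D-biased genes: ratio degenerates to the infinity marker
  b2 <- make_bias_table(paste0("g", 1:10), c(rep("A", 4), rep("none", 6)))
  expect_equal(bias_summary(b2)$bias_ratio, Inf)
})

test_that("Venn regions partition the union", {
  v <- venn_partition(list(x = c("1", "2"), y = c("2", "3")))
  expect_equal(setNames(v$count, v$region), c(x = 1L, y = 1L, `x&y` = 1L))
  # identical sets put all mass in the joint region
  v2 <- venn_partition(list(a = c("1", "2"), b = c("1", "2")))
  expect_equal(v2$count[v2$region == "a&b"], 2L)
  expect_equal(sum(v2$count), 2L)
  # four random sets cross-checked against brute-force membership
  set.seed(9)
  sets <- lapply(1:4, function(i) sample(paste0("g", 1:100), 40))
  names(sets) <- paste0("s", 1:4)
  v4 <- venn_partition(sets)
  expect_equal(sum(v4$count), length(unique(unlist(sets))))
  for (g in unique(unlist(sets))) {
    reg <- paste(names(sets)[vapply(sets, function(s) g %in% s, TRUE)],
                 collapse = "&")
    expect_gte(v4$count[v4$region == reg], 1L)
  }
})

test_that("direction conservation counts and contrarians follow definitions", {
  gid <- paste0("g", 1:8)
  b1 <- make_bias_table(gid, c("A", "A", "D", "D", "A", "none", "A", "D"))
  b2 <- make_bias_table(gid, c("A", "A", "D", "D", "D", "A", "A", "D"))
  b3 <- make_bias_table(gid, c("A", "A", "D", "A", "D", "A", "A", "D"))
  cons <- conserved_direction(list(acc1 = b1, acc2 = b2, acc3 = b3))
  expect_setequal(cons$all_biased, c("g1", "g2", "g3", "g4", "g5", "g7", "g8"))
  expect_setequal(cons$consistent_A, c("g1", "g2", "g7"))
  expect_setequal(cons$consistent_D, c("g3", "g8"))
  expect_equal(cons$counts$n_conserved, 5L)
  # g4: D in acc1+acc2 but A in acc3; g5: A in acc1 only
  expect_setequal(cons$contrarian$acc3, "g4")
  expect_setequal(cons$contrarian$acc1, "g5")
  expect_length(cons$contrarian$acc2, 0)
  # unanimity everywhere leaves no contrarians
  cons2 <- conserved_direction(list(a = b1, b = b1))
  expect_true(all(lengths(cons2$contrarian) == 0))
})

test_that("degree comparisons report fold and exact-tie convention", {
  b <- make_bias_table(paste0("g", 1:4), rep("A", 4), degrees = c(2, 2, 1, 1))
  cmp <- compare_bias_degree(c("g1", "g2"), c("g3", "g4"), b)
  expect_equal(cmp$fold, 2)
  tie <- compare_bias_degree(c("g1", "g2"), c("g1", "g2"), b)
  expect_equal(tie$fold, 1)
  expect_equal(tie$p, 1)
  expect_error(compare_bias_degree(character(0), "g1", b), "empty")
})

test_that("separated degree distributions yield the expected fold and p", {
  set.seed(33)
  gid <- paste0("g", 1:800)
  deg <- c(abs(rnorm(400, 1.5, 0.4)), abs(rnorm(400, 1.0, 0.4)))
  b <- make_bias_table(gid, rep("A", 800), degrees = deg)
  cmp <- compare_bias_degree(gid[1:400], gid[401:800], b)
  expect_gt(cmp$fold, 1.3); expect_lt(cmp$fold, 1.7)
  expect_lt(cmp$p, 0.001)
})

test_that("chromosome correlation hits the closed-form extremes", {
  p <- tempfile(fileext = ".gff3")
  lines <- "##gff-version 3"
  n_per <- c(10, 20, 30, 40)
  gid <- 0
  for (i in seq_along(n_per)) {
    for (k in seq_len(n_per[i])) {
      gid <- gid + 1
      lines <- c(lines, sprintf("chr%02d\ts\tgene\t%d\t%d\t.\t+\t.\tID=g%03d",
                                i, k * 100, k * 100 + 50, gid))
    }
  }
  writeLines(lines, p)
  gm <- suppressMessages(read_gene_models(p))
  # biased counts exactly proportional to totals
  biased <- unlist(lapply(seq_along(n_per), function(i) {
    gm$genes$gene_id[gm$genes$chrom == sprintf("chr%02d", i)][seq_len(n_per[i] / 2)]
  }))
  r1 <- chromosome_bias_correlation(biased, gm)
  expect_equal(r1$r, 1)
  # constant biased counts while totals vary
  biased2 <- unlist(lapply(seq_along(n_per), function(i) {
    gm$genes$gene_id[gm$genes$chrom == sprintf("chr%02d", i)][1:5]
  }))
  r2 <- chromosome_bias_correlation(biased2, gm)
  expect_lt(abs(r2$r), 1e-8)
  expect_equal(r2$p, 1)
  gm1 <- gm; gm1$genes <- gm1$genes[gm1$genes$chrom == "chr01", ]
  expect_error(chromosome_bias_correlation(biased, gm1), ">= 3 chromosomes")
})

test_that("uniformly sampled biased genes correlate with chromosome size", {
  cfg <- sim_config(n_genes = 5000, seed = 90)
  tr <- generate_truth(cfg)
  # chromosome sizes vary when genes are assigned proportional to a gradient
  set.seed(90)
  chrom <- sample(sprintf("Chr%02d", 1:13), 5000, replace = TRUE,
                  prob = 1:13)
  gm <- list(genes = data.frame(gene_id = tr$genes$gene_id, chrom = chrom,
                                strand = "+", start = 1L, end = 100L,
                                length = 100L))
  class(gm) <- "gene_models"
  biased <- sample(tr$genes$gene_id, 1000)
  r <- chromosome_bias_correlation(biased, gm)
  expect_gt(r$r, 0.8)
  expect_lt(r$p, 0.005)
})

test_that("TE proximity association detects construction and controls the null", {
  gid <- sprintf("g%03d", 1:500)
  gm <- list(genes = data.frame(gene_id = gid, chrom = "chr1", strand = "+",
                                start = (1:500) * 10000L,
                                end = (1:500) * 10000L + 500L,
                                length = 500L))
  class(gm) <- "gene_models"
  # distance a strictly monotone function of degree
  deg <- seq(-2, 2, length.out = 500)
  dist <- 100L + as.integer(rank(deg)) * 3L
  te <- GenomicRanges::GRanges("chr1",
          IRanges::IRanges(gm$genes$end + dist + 1L, width = 50L))
  b <- make_bias_table(gid, rep("A", 500), degrees = deg)
  assoc <- te_proximity_association(b, te, gm)
  expect_gte(abs(assoc$statistic), 0.95)
  expect_lt(assoc$p, 1e-6)
  expect_true(all(assoc$data$te_distance == dist))
  # gene overlapping a TE sits at distance zero
  te0 <- GenomicRanges::GRanges("chr1", IRanges::IRanges(gm$genes$start[1], width = 600L))
  expect_equal(unname(te_distances(gm, te0)[1]), 0L)
  expect_error(te_proximity_association(b, te[0], gm), "no TE")
})

test_that("TE association p-values are calibrated under independence", {
  set.seed(55)
  gid <- sprintf("g%03d", 1:200)
  gm <- list(genes = data.frame(gene_id = gid, chrom = "chr1", strand = "+",
                                start = (1:200) * 10000L,
                                end = (1:200) * 10000L + 500L, length = 500L))
  class(gm) <- "gene_models"
  rej <- vapply(1:200, function(i) {
    deg <- rnorm(200)
    dist <- sample.int(5000, 200)
    te <- GenomicRanges::GRanges("chr1",
            IRanges::IRanges(gm$genes$end + dist + 1L, width = 10L))
    te_proximity_association(make_bias_table(gid, rep("A", 200), degrees = deg),
                             te, gm)$p < 0.05
  }, TRUE)
  expect_gt(mean(rej), 0.01)
  expect_lt(mean(rej), 0.10)
})
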