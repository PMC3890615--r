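# Independent oracles and fixture builders shared across the suite.

# PMF of the sum of n iid NB(mu, phi) variables on 0..S by explicit
# convolution of per-replicate pmfs -- deliberately avoids the closed-form
# group-sum NB used by the implementation.
oracle_group_pmf <- function(n, mu, phi, S) {
  base <- if (phi == 0) dpois(0:S, mu) else dnbinom(0:S, size = 1 / phi, mu = mu)
  pmf <- base
  if (n > 1) {
    for (k in 2:n) {
      pmf <- vapply(0:S, function(s) sum(pmf[1:(s + 1)] * base[(s + 1):1]), 0)
    }
  }
  pmf
}

# Conditional exact p-value by brute-force enumeration over all splits.
oracle_nb_exact <- function(s1, s2, n1, n2, phi) {
  S <- s1 + s2
  if (S == 0) return(1)
  m <- S / (n1 + n2)
  p1 <- oracle_group_pmf(n1, n1 * m / n1, phi, S)
  p2 <- oracle_group_pmf(n2, n2 * m / n2, phi, S)
  joint <- p1 * rev(p2)
  obs <- joint[s1 + 1]
  sum(joint[joint <= obs * (1 + 1e-10)]) / sum(joint)
}

# Write a small SAM file from a record data.frame (qname, flag, chrom, pos,
# cigar, seq, qual) with the given reference lengths.
write_test_sam <- function(records, seqlens, path = tempfile(fileext = ".sam")) {
  con <- file(path, "w")
  writeLines("@HD\tVN:1.6\tSO:unknown", con)
  for (ch in names(seqlens)) {
    writeLines(paste0("@SQ\tSN:", ch, "\tLN:", seqlens[[ch]]), con)
  }
  for (i in seq_len(nrow(records))) {
    r <- records[i, ]
    writeLines(paste(r$qname, r$flag, r$chrom, r$pos, 60, r$cigar, "*", 0, 0,
                     r$seq, r$qual, sep = "\t"), con)
  }
  close(con)
  path
}

# Long class-count table for hand-built unit matrices.
make_counts_long <- function(gene_ids, samples, n_A, n_D, n_X = 0, n_N = 0) {
  expand <- expand.grid(gene_id = gene_ids, sample_id = samples,
                        stringsAsFactors = FALSE)
  expand$n_A <- as.vector(n_A)
  expand$n_D <- as.vector(n_D)
  expand$n_X <- as.vector(n_X)
  expand$n_N <- as.vector(n_N)
  expand
}

# A minimal bias_result table from direction assignments.
make_bias_table <- function(gene_ids, directions, degrees = NULL) {
  if (is.null(degrees)) {
    degrees <- ifelse(directions == "A", 1, ifelse(directions == "D", -1, 0))
  }
  structure(data.frame(gene_id = gene_ids, degree = degrees, logFC = degrees,
                       p = ifelse(directions == "none", 0.5, 1e-4),
                       q = ifelse(directions == "none", 0.9, 1e-3),
                       direction = directions, stringsAsFactors = FALSE),
            class = c("bias_result", "data.frame"))
}
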