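#' Expression profiles per accession-genome leaf
#'
#' Builds one profile per leaf by averaging `log2(RPKM+1)` over replicates:
#' polyploids contribute one A- and one D-partition leaf (named e.g.
#' `Maxxa_A`), diploids one total leaf, over a supplied gene universe
#' (typically the commonly expressed set).
#'
#' @param uc A [unit_counts()] object.
#' @param gene_lengths Named gene-length vector (bp).
#' @param genes Gene universe for the profiles (default: all genes).
#' @param include_diploids Include diploid total leaves (default TRUE).
#' @param scale `"log2"` (default) or `"rpkm"` (raw RPKM).
#' @return Numeric matrix, genes x leaves.
#' @export
expression_profiles <- function(uc, gene_lengths, genes = NULL,
                                include_diploids = TRUE,
                                scale = c("log2", "rpkm")) {
  scale <- match.arg(scale)
  m <- rpkm_matrix(uc, gene_lengths, log2 = (scale == "log2"))
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  u <- uc$units
  leaves <- list()
  for (a in unique(u$accession)) {
    parts <- setdiff(unique(u$partition[u$accession == a]), "total")
    if (length(parts) == 0) {
      if (!include_diploids) next
      cols <- u$unit_id[u$accession == a & u$partition == "total"]
      leaves[[a]] <- rowMeans(m[, cols, drop = FALSE])
    } else {
      for (p in c("A", "D")) {
        cols <- u$unit_id[u$accession == a & u$partition == p]
        leaves[[paste(a, p, sep = "_")]] <- rowMeans(m[, cols, drop = FALSE])
      }
    }
  }
  do.call(cbind, leaves)
}

#' Homoeolog expression-difference profiles
#'
#' One profile per polyploid accession: the mean over replicates of
#' `log2(RPKM_A + 1) - log2(RPKM_D + 1)` per gene.
#'
#' @param uc A [unit_counts()] object.
#' @param gene_lengths Named gene-length vector (bp).
#' @param genes Gene universe (default: all genes).
#' @return Numeric matrix, genes x polyploid accessions.
#' @export
homoeolog_diff_profiles <- function(uc, gene_lengths, genes = NULL) {
  m <- rpkm_matrix(uc, gene_lengths, log2 = TRUE)
  if (!is.null(genes)) m <- m[rownames(m) %in% genes, , drop = FALSE]
  u <- uc$units
  polys <- unique(u$accession[u$partition == "A"])
  if (length(polys) == 0) stop("no accession with A/D partitions (diploids only?)")
  prof <- lapply(polys, function(a) {
    cA <- u$unit_id[u$accession == a & u$partition == "A"]
    cD <- u$unit_id[u$accession == a & u$partition == "D"]
    reps <- min(length(cA), length(cD))
    rowMeans(m[, cA[seq_len(reps)], drop = FALSE] -
             m[, cD[seq_len(reps)], drop = FALSE])
  })
  names(prof) <- polys
  do.call(cbind, prof)
}

#' Sum-of-squared-differences distance matrix
#'
#' `d(i, j) = sum_g (x_gi - x_gj)^2` over the profile rows.
#'
#' @param profiles Numeric matrix, genes x leaves.
#' @return Symmetric matrix with zero diagonal, labelled by leaf.
#' @export
ssd_distance <- function(profiles) {
  if (is.null(dim(profiles))) stop("profiles must be a matrix")
  n <- ncol(profiles)
  d <- matrix(0, n, n, dimnames = list(colnames(profiles), colnames(profiles)))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      d[i, j] <- d[j, i] <- sum((profiles[, i] - profiles[, j])^2)
    }
  }
  d
}

#' Neighbor-joining tree construction
#'
#' The Saitou-Nei agglomerative algorithm: iteratively join the leaf pair
#' minimizing the Q-criterion, with branch lengths from the standard NJ
#' formulas. Ties are broken deterministically by lexicographic label order.
#' Negative branch lengths are clamped to zero with the deficit transferred
#' to the sibling branch (preserving the path length through the joined
#' pair). `n = 2` returns the single-edge tree.
#'
#' @param d Symmetric distance matrix with leaf labels.
#' @return An unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(d) {
  labels <- colnames(d)
  n <- length(labels)
  if (is.null(labels) || n < 2) stop("need a labelled matrix with >= 2 leaves")
  if (anyDuplicated(labels)) stop("duplicate leaf labels")
  if (max(abs(d - t(d))) > 1e-12 || any(diag(d) != 0)) {
    stop("distance matrix must be symmetric with zero diagonal")
  }
  if (n == 2) {
    tree <- list(edge = matrix(c(3L, 1L, 3L, 2L), 2, 2, byrow = TRUE),
                 edge.length = c(d[1, 2] / 2, d[1, 2] / 2),
                 tip.label = labels, Nnode = 1L)
    class(tree) <- "phylo"
    return(tree)
  }
  # agglomerate on a shrinking active matrix, recording joins; tree node
  # indices (tips 1..n, internals n+1 .. 2n-2) are assigned afterwards
  act <- d
  joins <- list()
  while (nrow(act) > 3) {
    m <- nrow(act)
    r <- rowSums(act)
    Q <- (m - 2) * act - outer(r, r, "+")
    diag(Q) <- Inf
    # deterministic tie-break: smallest Q, then lexicographic label pair
    idx <- which(Q == min(Q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    pair_lab <- apply(idx, 1, function(z) {
      paste(sort(rownames(act)[z]), collapse = "\r")
    })
    best <- idx[order(pair_lab)[1], ]
    i <- best[1]; j <- best[2]
    li <- 0.5 * act[i, j] + (r[i] - r[j]) / (2 * (m - 2))
    lj <- act[i, j] - li
    # clamp negatives, moving the deficit to the sibling
    if (li < 0) { lj <- lj + li; li <- 0 }
    if (lj < 0) { li <- li + lj; lj <- 0 }
    joins[[length(joins) + 1]] <- list(a = rownames(act)[i], b = rownames(act)[j],
                                       la = li, lb = lj)
    new_lab <- paste0("\001nj", length(joins))
    dn <- 0.5 * (act[i, ] + act[j, ] - act[i, j])
    keep <- setdiff(seq_len(m), c(i, j))
    act2 <- rbind(cbind(act[keep, keep, drop = FALSE], dn[keep]),
                  c(dn[keep], 0))
    rownames(act2) <- colnames(act2) <- c(rownames(act)[keep], new_lab)
    act <- act2
  }
  # final 3-leaf star: exact three-point branch lengths
  labs3 <- rownames(act)
  la <- (act[1, 2] + act[1, 3] - act[2, 3]) / 2
  lb <- (act[1, 2] + act[2, 3] - act[1, 3]) / 2
  lc <- (act[1, 3] + act[2, 3] - act[1, 2]) / 2
  star <- pmax(c(la, lb, lc), 0)

  # build the phylo edge table: internal node numbering n+1 .. 2n-2
  # ape convention: the root carries index n + 1
  n_internal <- length(joins) + 1L
  join_labs <- if (length(joins)) paste0("\001nj", seq_along(joins)) else character(0)
  internal_id <- stats::setNames(n + seq_len(n_internal), c("\001njroot", join_labs))
  id_of <- function(lab) {
    if (lab %in% labels) match(lab, labels) else unname(internal_id[lab])
  }
  edge <- matrix(0L, 0, 2); elen <- numeric(0)
  for (k in seq_along(joins)) {
    jn <- joins[[k]]
    parent <- internal_id[[paste0("\001nj", k)]]
    edge <- rbind(edge, c(parent, id_of(jn$a)), c(parent, id_of(jn$b)))
    elen <- c(elen, jn$la, jn$lb)
  }
  root <- internal_id[["\001njroot"]]
  for (t in 1:3) {
    edge <- rbind(edge, c(root, id_of(labs3[t])))
    elen <- c(elen, star[t])
  }
  tree <- list(edge = edge, edge.length = unname(elen), tip.label = labels,
               Nnode = n_internal)
  class(tree) <- "phylo"
  ape::reorder.phylo(tree, "cladewise")
}

#' Path-length (patristic) distances on a tree
#'
#' Brute-force sum of branch lengths along the unique leaf-to-leaf paths;
#' serves as the oracle for tree-metric faithfulness.
#'
#' @param tree An `ape::phylo` tree.
#' @return Symmetric matrix of path lengths over the leaf labels.
#' @export
tree_path_distances <- function(tree) {
  n <- length(tree$tip.label)
  # adjacency over all nodes
  nn <- max(tree$edge)
  adj <- vector("list", nn)
  for (e in seq_len(nrow(tree$edge))) {
    a <- tree$edge[e, 1]; b <- tree$edge[e, 2]; w <- tree$edge.length[e]
    adj[[a]] <- rbind(adj[[a]], c(b, w))
    adj[[b]] <- rbind(adj[[b]], c(a, w))
  }
  d <- matrix(0, n, n, dimnames = list(tree$tip.label, tree$tip.label))
  for (s in seq_len(n)) {
    dist <- rep(NA_real_, nn)
    dist[s] <- 0
    queue <- s
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      for (k in seq_len(NROW(adj[[v]]))) {
        u <- adj[[v]][k, 1]; w <- adj[[v]][k, 2]
        if (is.na(dist[u])) {
          dist[u] <- dist[v] + w
          queue <- c(queue, u)
        }
      }
    }
    d[s, ] <- dist[seq_len(n)]
  }
  d
}
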