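# Distance-based phylogenetics: K2P distance matrices, neighbor-joining
# with deterministic tie-breaking, bootstrap support, and
# Robinson-Foulds congruence between the transposase tree and the
# concatenated viral-gene tree.

#' K2P distance matrix from a multiple alignment
#'
#' Entries are pairwise [k2p_distance()] values with pairwise deletion.
#'
#' @param aligned_seqs named character vector of equal-length aligned
#'   sequences.
#' @param metric distance model; only "K2P" is provided.
#' @return symmetric distance matrix with zero diagonal.
#' @export
distance_matrix <- function(aligned_seqs, metric = "K2P") {
  metric <- match.arg(metric, "K2P")
  stopifnot(length(aligned_seqs) >= 2L,
            length(unique(nchar(aligned_seqs))) == 1L)
  ids <- names(aligned_seqs)
  n <- length(ids)
  d <- matrix(0, n, n, dimnames = list(ids, ids))
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      est <- tryCatch(
        k2p_distance(list(a = aligned_seqs[[i]], b = aligned_seqs[[j]])),
        error = function(e) stop("saturated pair (", ids[i], ", ", ids[j],
                                 "): ", conditionMessage(e)))
      d[i, j] <- d[j, i] <- est$d
    }
  }
  d
}

#' Neighbor-joining tree from a distance matrix
#'
#' Saitou-Nei agglomeration with the Q criterion; ties broken
#' deterministically by the lowest index pair; negative branch-length
#' estimates are clamped to zero.
#'
#' @param D symmetric distance matrix with labels as dimnames.
#' @return an unrooted `ape::phylo` tree.
#' @export
neighbor_joining <- function(D) {
  stopifnot(is.matrix(D), nrow(D) == ncol(D))
  n <- nrow(D)
  if (n < 3L) stop("neighbor joining requires at least 3 taxa")
  labels <- rownames(D)
  if (is.null(labels)) labels <- paste0("t", seq_len(n))
  frag <- labels  # newick fragment per active node
  d <- D
  while (nrow(d) > 3L) {
    m <- nrow(d)
    r <- rowSums(d)
    q <- (m - 2) * d - outer(r, r, "+")
    diag(q) <- Inf
    # lowest-index pair among minima (row-major order)
    idx <- which(q == min(q), arr.ind = TRUE)
    idx <- idx[idx[, 1] < idx[, 2], , drop = FALSE]
    idx <- idx[order(idx[, 1], idx[, 2]), , drop = FALSE]
    i <- idx[1, 1]; j <- idx[1, 2]
    bi <- d[i, j] / 2 + (r[i] - r[j]) / (2 * (m - 2))
    bj <- d[i, j] - bi
    bi <- max(bi, 0); bj <- max(bj, 0)
    new_frag <- sprintf("(%s:%.10g,%s:%.10g)", frag[i], bi, frag[j], bj)
    du <- (d[i, ] + d[j, ] - d[i, j]) / 2
    keep <- setdiff(seq_len(m), c(i, j))
    d2 <- rbind(cbind(d[keep, keep, drop = FALSE], du[keep]),
                c(du[keep], 0))
    frag <- c(frag[keep], new_frag)
    d <- d2
  }
  b1 <- max((d[1, 2] + d[1, 3] - d[2, 3]) / 2, 0)
  b2 <- max((d[1, 2] + d[2, 3] - d[1, 3]) / 2, 0)
  b3 <- max((d[1, 3] + d[2, 3] - d[1, 2]) / 2, 0)
  nwk <- sprintf("(%s:%.10g,%s:%.10g,%s:%.10g);",
                 frag[1], b1, frag[2], b2, frag[3], b3)
  ape::read.tree(text = nwk)
}

#' Bootstrap support for a neighbor-joining tree
#'
#' Alignment columns are resampled with replacement; an NJ tree is built
#' per replicate and the support of each split of the point-estimate
#' tree is the percentage of replicates containing it.  Replicates whose
#' resampled alignment yields a saturated pair are dropped (the support
#' denominator shrinks accordingly).
#'
#' @param alignment named character vector of equal-length aligned
#'   sequences.
#' @param n_replicates bootstrap replicates.
#' @param seed integer seed.
#' @return the point-estimate tree with node labels holding support
#'   percentages in [0, 100].
#' @export
bootstrap_support <- function(alignment, n_replicates = 1000L, seed = 1L) {
  stopifnot(length(alignment) >= 3L)
  len <- unique(nchar(alignment))
  stopifnot(length(len) == 1L, len >= 2L)
  mat <- do.call(rbind, strsplit(alignment, ""))
  rownames(mat) <- names(alignment)
  point <- neighbor_joining(distance_matrix(alignment))
  with_seed(seed, {
    boots <- list()
    for (b in seq_len(n_replicates)) {
      cols <- sample.int(len, len, replace = TRUE)
      rs <- setNames(apply(mat[, cols, drop = FALSE], 1L, paste,
                           collapse = ""), names(alignment))
      tr <- tryCatch(neighbor_joining(distance_matrix(rs)),
                     error = function(e) NULL)
      if (!is.null(tr)) boots[[length(boots) + 1L]] <- tr
    }
    if (!length(boots)) stop("all bootstrap replicates failed")
    class(boots) <- "multiPhylo"
    cnt <- ape::prop.clades(point, boots, rooted = FALSE)
    cnt[is.na(cnt)] <- 0L
    point$node.label <- round(100 * cnt / length(boots), 1)
    point
  })
}

#' Robinson-Foulds congruence between two trees
#'
#' Both trees are pruned to their shared leaf set; rf is the size of the
#' symmetric difference of the non-trivial bipartition sets, normalized
#' by 2(n - 3).
#'
#' @param t1,t2 `ape::phylo` trees.
#' @return list with rf, rf_normalized and shared_leaf_set (class
#'   `congruence_result`).
#' @export
robinson_foulds <- function(t1, t2) {
  shared <- intersect(t1$tip.label, t2$tip.label)
  if (length(shared) < 4L) stop("fewer than 4 shared leaves")
  p1 <- ape::unroot(ape::keep.tip(t1, shared))
  p2 <- ape::unroot(ape::keep.tip(t2, shared))
  rf <- as.numeric(phangorn::RF.dist(p1, p2, normalize = FALSE,
                                     check.labels = TRUE))
  n <- length(shared)
  structure(list(rf = rf, rf_normalized = rf / (2 * (n - 3)),
                 shared_leaf_set = shared),
            class = "congruence_result")
}

#' Concatenate per-gene alignments column-wise
#'
#' @param alignments list of named character vectors (same taxa).
#' @param order optional gene order for the join.
#' @return one named character vector of concatenated rows.
#' @export
concat_alignments <- function(alignments, order = NULL) {
  if (!is.null(order)) {
    missing <- setdiff(order, names(alignments))
    if (length(missing)) stop("missing gene alignment: ", missing[1])
    alignments <- alignments[order]
  }
  taxa <- Reduce(intersect, lapply(alignments, names))
  if (!length(taxa)) stop("no shared taxa across gene alignments")
  out <- setNames(rep("", length(taxa)), taxa)
  for (al in alignments) out <- paste0(out, al[taxa])
  setNames(out, taxa)
}

#' Topology congruence between transposase and viral-gene trees
#'
#' Builds the transposase NJ tree and the concatenated viral-gene NJ
#' tree (concatenation order pol, hel, ter, mcp, mem when those genes
#' are present), prunes both to the shared taxa, and reports the
#' Robinson-Foulds distance.
#'
#' @param transposase_seqs named character vector: aligned transposase
#'   sequences per taxon.
#' @param viral_gene_seqs list of named character vectors, one aligned
#'   gene per entry; or a single named character vector (already
#'   concatenated).
#' @param shared_taxa taxa that must be present in both alignments
#'   (default: all transposase taxa).
#' @return list with `congruence` (a `congruence_result`),
#'   `tree_transposase`, `tree_viral`.
#' @export
congruence_test <- function(transposase_seqs, viral_gene_seqs,
                            shared_taxa = NULL) {
  if (is.list(viral_gene_seqs)) {
    ord <- intersect(c("pol", "hel", "ter", "mcp", "mem"),
                     names(viral_gene_seqs))
    if (length(ord) == 0L) ord <- NULL
    viral <- concat_alignments(viral_gene_seqs, order = ord)
  } else viral <- viral_gene_seqs
  if (is.null(shared_taxa)) shared_taxa <- names(transposase_seqs)
  miss_t <- setdiff(shared_taxa, names(transposase_seqs))
  if (length(miss_t)) stop("taxon missing from transposase alignment: ",
                           miss_t[1])
  miss_v <- setdiff(shared_taxa, names(viral))
  if (length(miss_v)) stop("taxon missing from viral alignment: ", miss_v[1])
  t_tp <- neighbor_joining(distance_matrix(transposase_seqs[shared_taxa]))
  t_vi <- neighbor_joining(distance_matrix(viral[shared_taxa]))
  structure(list(congruence = robinson_foulds(t_tp, t_vi),
                 tree_transposase = t_tp, tree_viral = t_vi),
            class = "congruence_test")
}
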