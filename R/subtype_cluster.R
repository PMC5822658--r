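# Subtype clustering of element copies: single-linkage connected
# components of the pairwise-identity graph at the > 90% threshold, one
# representative per subtype for phylogenetics.

#' Pairwise identity matrix for a set of sequences
#'
#' Identities come from global alignment ([global_align_nt()]) and
#' [pairwise_identity()].
#'
#' @param seqs named character vector of nucleotide sequences.
#' @param ... alignment parameters passed to [global_align_nt()].
#' @return symmetric matrix of identities with unit diagonal.
#' @export
identity_matrix <- function(seqs, ...) {
  n <- length(seqs)
  ids <- names(seqs)
  m <- matrix(1, n, n, dimnames = list(ids, ids))
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        aln <- global_align_nt(seqs[[i]], seqs[[j]], ...)
        m[i, j] <- m[j, i] <- pairwise_identity(aln)
      }
    }
  }
  m
}

#' Cluster element copies into subtypes by pairwise identity
#'
#' Single-linkage connected components of the graph whose edges join
#' pairs with identity strictly above `same_subtype_threshold`;
#' sequences above 90% identity belong to one subtype.  Labels are
#' deterministic: clusters are ordered by their smallest member id.
#'
#' @param seqs named character vector of copy sequences.
#' @param same_subtype_threshold identity threshold (strict).
#' @param identity optional precomputed identity matrix.
#' @param ... alignment parameters passed to [identity_matrix()].
#' @return object of class `subtype_clustering`: list with `clusters`
#'   (named list of member-id vectors), `labels` (subtype label per
#'   member), `representatives` (member id per cluster) and
#'   `identity_matrix`.
#' @export
cluster_subtypes <- function(seqs, same_subtype_threshold = 0.90,
                             identity = NULL, ...) {
  stopifnot(is.character(seqs), length(seqs) >= 1L,
            !is.null(names(seqs)), !anyDuplicated(names(seqs)))
  ids <- names(seqs)
  if (is.null(identity)) identity <- identity_matrix(seqs, ...)
  n <- length(ids)
  # union-find over the thresholded identity graph
  parent <- seq_len(n)
  find <- function(i) { while (parent[i] != i) i <- parent[i]; i }
  if (n > 1L) {
    for (i in seq_len(n - 1L)) {
      for (j in (i + 1L):n) {
        if (!is.na(identity[i, j]) &&
            identity[i, j] > same_subtype_threshold) {
          ri <- find(i); rj <- find(j)
          if (ri != rj) parent[rj] <- ri
        }
      }
    }
  }
  root <- vapply(seq_len(n), find, integer(1))
  comp <- split(ids, root)
  # order clusters by smallest member id
  comp <- comp[order(vapply(comp, function(x) min(x), character(1)))]
  names(comp) <- sprintf("subtype_%d", seq_along(comp))
  labels <- setNames(rep(names(comp), lengths(comp)), unlist(comp))[ids]
  reps <- vapply(comp, select_representative, character(1), seqs = seqs)
  structure(list(clusters = comp, labels = labels,
                 representatives = reps, identity_matrix = identity),
            class = "subtype_clustering")
}

#' Pick the representative copy of a subtype
#'
#' The longest ungapped sequence; ties broken lexicographically by id.
#'
#' @param cluster character vector of member ids.
#' @param seqs named character vector covering the members.
#' @return the representative member id.
#' @export
select_representative <- function(cluster, seqs) {
  stopifnot(length(cluster) >= 1L)
  lens <- nchar(gsub("-", "", seqs[cluster], fixed = TRUE))
  cand <- sort(cluster[lens == max(lens)])
  cand[1]
}

#' Warn on within-subtype pairs below the expected identity
#'
#' In the regime the analysis assumes, copies within one subtype exceed
#' 95% identity; pairs below `min_within_identity` are flagged as
#' non-fatal warnings.
#'
#' @param clustering a `subtype_clustering`.
#' @param min_within_identity expected within-subtype identity floor.
#' @return character vector of warnings (empty when all pairs conform).
#' @export
validate_within_subtype <- function(clustering, min_within_identity = 0.95) {
  out <- character(0)
  im <- clustering$identity_matrix
  for (cl in names(clustering$clusters)) {
    mem <- clustering$clusters[[cl]]
    if (length(mem) < 2L) next
    for (i in seq_len(length(mem) - 1L)) {
      for (j in (i + 1L):length(mem)) {
        idv <- im[mem[i], mem[j]]
        if (!is.na(idv) && idv < min_within_identity) {
          out <- c(out, sprintf(
            "%s: pair (%s, %s) identity %.3f below %.2f",
            cl, mem[i], mem[j], idv, min_within_identity))
        }
      }
    }
  }
  out
}

#' Write a subtype clustering as TSV
#' @param clustering a `subtype_clustering`.
#' @param path output path for the membership table.
#' @param identity_path optional output path for the identity matrix.
#' @export
write_subtypes_tsv <- function(clustering, path, identity_path = NULL) {
  df <- data.frame(member_id = names(clustering$labels),
                   subtype = unname(clustering$labels))
  df$representative <- df$member_id %in% clustering$representatives
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  if (!is.null(identity_path)) {
    write.table(clustering$identity_matrix, identity_path, sep = "\t",
                quote = FALSE, col.names = NA)
  }
  invisible(path)
}
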