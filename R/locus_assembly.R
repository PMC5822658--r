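# Assembly of per-gene hits into candidate element loci and core-gene
# presence classification: hits within 60 kb of one another are merged,
# the merged region is extracted with 40-kb flanks, and a genome is
# called positive when at least 8 of the 13 core genes have a hit below
# the E-value threshold.

#' Merge translated-search hits into candidate loci
#'
#' Two hit intervals on the same contig belong to one locus iff they are
#' connected by a chain of gaps of at most `merge_distance` bp (gap
#' measured between hit envelopes; strand-agnostic, since viral genes
#' occur on both strands within one element).
#'
#' @param hits hit data frame from [search_genome()].
#' @param merge_distance maximum envelope gap in bp (inclusive bound).
#' @return list of loci, each a list with contig_id, core_start,
#'   core_end and member_hits (the hits data frame subset); sorted by
#'   contig then start.
#' @export
merge_hit_loci <- function(hits, merge_distance = 60000L) {
  if (is.null(hits) || nrow(hits) == 0L) return(list())
  loci <- list()
  for (cn in sort(unique(hits$contig_id))) {
    h <- hits[hits$contig_id == cn, , drop = FALSE]
    h <- h[order(h$nt_start, h$nt_end), , drop = FALSE]
    group <- integer(nrow(h))
    gid <- 1L
    group[1] <- gid
    env_end <- h$nt_end[1]
    for (i in seq_len(nrow(h))[-1]) {
      if (h$nt_start[i] - env_end <= merge_distance) {
        group[i] <- gid
        env_end <- max(env_end, h$nt_end[i])
      } else {
        gid <- gid + 1L
        group[i] <- gid
        env_end <- h$nt_end[i]
      }
    }
    for (g in seq_len(gid)) {
      m <- h[group == g, , drop = FALSE]
      loci[[length(loci) + 1L]] <- structure(
        list(contig_id = cn, core_start = min(m$nt_start),
             core_end = max(m$nt_end), member_hits = m),
        class = "terat_locus")
    }
  }
  loci
}

#' Extract a locus sequence with flanks
#'
#' @param genome named character vector of contigs.
#' @param locus a locus from [merge_hit_loci()].
#' @param flank flank size in bp, clipped to the contig.
#' @return the locus with flank_start, flank_end and sequence fields
#'   added.
#' @export
extract_locus_sequence <- function(genome, locus, flank = 40000L) {
  cn <- locus$contig_id
  if (!cn %in% names(genome)) stop("unknown contig: ", cn)
  L <- nchar(genome[[cn]])
  locus$flank_start <- max(0L, locus$core_start - flank)
  locus$flank_end <- min(L, locus$core_end + flank)
  locus$sequence <- substr(genome[[cn]], locus$flank_start + 1L,
                           locus$flank_end)
  locus
}

#' Core-gene presence record for one genome
#'
#' @param hits hit data frame from [search_genome()].
#' @param core_genes gene names defining the presence vector (defaults
#'   to the 13 alloherpesvirus core genes).
#' @return named numeric vector of best (smallest) E-value per core
#'   gene; NA where the gene has no hit.
#' @export
presence_record <- function(hits, core_genes = core_gene_names()) {
  best <- setNames(rep(NA_real_, length(core_genes)), core_genes)
  if (!is.null(hits) && nrow(hits)) {
    h <- hits[hits$gene_name %in% core_genes, , drop = FALSE]
    if (nrow(h)) {
      agg <- tapply(h$evalue, h$gene_name, min)
      best[names(agg)] <- agg
    }
  }
  best
}

#' Classify a genome by core-gene presence
#'
#' Positive when at least `min_genes` of the 13 core genes have a best
#' E-value below `evalue_threshold`.
#'
#' @param presence named best-E-value vector from [presence_record()],
#'   built against exactly the 13 core genes.
#' @param min_genes minimum number of present core genes.
#' @param evalue_threshold significance cutoff.
#' @return list with classification ("positive"/"negative"),
#'   n_genes_present, and the logical per-gene presence vector.
#' @export
classify_species <- function(presence, min_genes = 8L,
                             evalue_threshold = 1e-3) {
  if (!setequal(names(presence), core_gene_names())) {
    stop("presence record must be built against the 13 core genes")
  }
  present <- !is.na(presence) & presence < evalue_threshold
  n <- sum(present)
  list(classification = if (n >= min_genes) "positive" else "negative",
       n_genes_present = n, present = present)
}

#' Write loci as BED tracks (core and flanked intervals)
#' @param loci list of loci (flanked or not).
#' @param path_core,path_flank output BED paths (flank track skipped for
#'   loci without flanks).
#' @export
write_loci_bed <- function(loci, path_core, path_flank = NULL) {
  core <- do.call(rbind, lapply(seq_along(loci), function(i) {
    l <- loci[[i]]
    data.frame(contig_id = l$contig_id, start = l$core_start,
               end = l$core_end, gene_id = sprintf("locus_%03d", i),
               stringsAsFactors = FALSE)
  }))
  write_bed(core, path_core)
  if (!is.null(path_flank) && all(vapply(loci, function(l)
    !is.null(l$flank_start), logical(1)))) {
    fl <- do.call(rbind, lapply(seq_along(loci), function(i) {
      l <- loci[[i]]
      data.frame(contig_id = l$contig_id, start = l$flank_start,
                 end = l$flank_end, gene_id = sprintf("locus_%03d", i),
                 stringsAsFactors = FALSE)
    }))
    write_bed(fl, path_flank)
  }
  invisible(path_core)
}
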