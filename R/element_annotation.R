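# Annotation of candidate element loci: ORF calling, intactness
# assessment, terminal-inverted-repeat detection, target-site
# duplication check, and fusion classification of the piggyBac-like
# transposase relative to the viral genes.

#' Call ATG-to-stop ORFs on both strands of a sequence
#'
#' All maximal ORFs (first ATG after the previous in-frame stop, through
#' the next stop) of at least `min_length_aa` amino acids, over all six
#' frames.  Coordinates are 0-based half-open on the forward strand and
#' include the stop codon.
#'
#' @param seq nucleotide string.
#' @param min_length_aa minimum protein length (excluding the stop).
#' @return data frame: start, end, strand, frame, length_aa, protein.
#' @export
call_orfs <- function(seq, min_length_aa = 100L) {
  L <- nchar(seq)
  out <- list()
  k <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else revcomp(seq)
    for (frame in 0:2) {
      prot <- translate_nt(substr(s, frame + 1L, L))
      if (!nzchar(prot)) next
      m <- gregexpr("M[^*]*\\*", prot)[[1]]
      if (m[1] == -1) next
      for (x in seq_along(m)) {
        aa_start <- as.integer(m[x]) - 1L          # 0-based, incl M
        aa_len <- attr(m, "match.length")[x] - 1L  # protein length, no stop
        if (aa_len < min_length_aa) next
        aa_end <- aa_start + aa_len + 1L           # incl stop codon
        nt <- frame_aa_to_genome(L, strand, frame, aa_start, aa_end)
        k <- k + 1L
        out[[k]] <- data.frame(
          start = nt[1], end = nt[2], strand = strand, frame = frame,
          length_aa = aa_len,
          protein = substr(prot, aa_start + 1L, aa_start + aa_len),
          stringsAsFactors = FALSE)
      }
    }
  }
  if (k == 0L) {
    return(data.frame(start = integer(0), end = integer(0),
                      strand = character(0), frame = integer(0),
                      length_aa = integer(0), protein = character(0),
                      stringsAsFactors = FALSE))
  }
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Convert genome-coordinate hits to locus-local coordinates.
hits_to_locus_coords <- function(hits, locus) {
  h <- hits[hits$contig_id == locus$contig_id &
              hits$nt_start >= locus$flank_start &
              hits$nt_end <= locus$flank_end, , drop = FALSE]
  h$nt_start <- h$nt_start - locus$flank_start
  h$nt_end <- h$nt_end - locus$flank_start
  h
}

#' Assess ORF intactness of the viral genes at a locus
#'
#' A gene is intact when an ORF overlapping its hit reaches at least
#' `min_fraction` of the expected protein length, degraded otherwise
#' (a premature stop or frameshift truncates the longest ORF below the
#' threshold).  Element verdict: intact when all genes are intact,
#' degraded when none is, partially_degraded otherwise.
#'
#' @param locus a flanked locus (with sequence) from
#'   [extract_locus_sequence()].
#' @param viral_hits hits of the viral gene queries (genome
#'   coordinates).
#' @param expected_lengths named vector of expected protein lengths
#'   (aa) per gene.
#' @param min_fraction intact threshold on ORF length / expected length.
#' @return list with per_gene (data frame gene, orf_fraction, status)
#'   and verdict.
#' @export
assess_intactness <- function(locus, viral_hits, expected_lengths,
                              min_fraction = 0.8) {
  h <- hits_to_locus_coords(viral_hits, locus)
  genes <- unique(h$gene_name)
  unknown <- setdiff(genes, names(expected_lengths))
  if (length(unknown)) stop("unknown gene in expected_lengths: ", unknown[1])
  orfs <- call_orfs(locus$sequence,
                    min_length_aa = max(10L, floor(0.2 * min(expected_lengths))))
  rows <- list()
  for (g in genes) {
    hg <- h[h$gene_name == g, , drop = FALSE]
    hg <- hg[which.max(hg$raw_score), , drop = FALSE]
    ov <- orfs[orfs$start < hg$nt_end & orfs$end > hg$nt_start, ,
               drop = FALSE]
    frac <- if (nrow(ov)) max(ov$length_aa) / expected_lengths[[g]] else 0
    status <- if (frac >= min_fraction) "intact" else "degraded"
    rows[[g]] <- data.frame(gene = g, orf_fraction = frac, status = status,
                            stringsAsFactors = FALSE)
  }
  per_gene <- do.call(rbind, rows)
  verdict <- if (all(per_gene$status == "intact")) "intact"
    else if (!any(per_gene$status == "intact")) "degraded"
    else "partially_degraded"
  list(per_gene = per_gene, verdict = verdict)
}

#' Find terminal inverted repeats at the ends of an element sequence
#'
#' The best-scoring pair (longest, then fewest mismatches, then
#' leftmost) of inverted repeats with the left repeat starting within
#' the first `window` bp and the right repeat ending within the last
#' `window` bp.
#'
#' @param element_seq element nucleotide sequence (longer than
#'   2 * window).
#' @param min_len,max_len TIR length bounds in bp.
#' @param max_mismatch maximum mismatches between the left repeat and
#'   the reverse complement of the right repeat.
#' @param window terminal search window in bp.
#' @return list (left_start, left_end, right_start, right_end, length,
#'   mismatches) or NULL when no TIR is found.
#' @export
find_tirs <- function(element_seq, min_len = 10L, max_len = 40L,
                      max_mismatch = 1L, window = 200L) {
  if (nchar(element_seq) <= 2L * window) {
    stop("element shorter than twice the search window")
  }
  res <- cpp_find_tirs(element_seq, as.integer(min_len),
                       as.integer(max_len), as.integer(max_mismatch),
                       as.integer(window))
  if (!isTRUE(res$found)) return(NULL)
  res$found <- NULL
  res
}

#' Detect the TTAA-style target-site duplication of an inserted element
#'
#' Returns the 4-mer immediately 5' of the element iff it equals the
#' 4-mer immediately 3' of the element (the duplicated target site).
#'
#' @param contig_seq the contig carrying the element.
#' @param start,end element boundaries (0-based half-open).
#' @return the duplicated 4-mer, or NA when boundaries touch the contig
#'   edge or the two contexts differ.
#' @export
detect_tsd <- function(contig_seq, start, end) {
  L <- nchar(contig_seq)
  if (start < 4L || end + 4L > L) return(NA_character_)
  left <- substr(contig_seq, start - 3L, start)
  right <- substr(contig_seq, end + 1L, end + 4L)
  if (left == right) left else NA_character_
}

#' Classify the transposase-element fusion status of a locus
#'
#' fused_internal: the transposase hit lies between two viral gene hits
#' inside the locus core; fused_edge: at an end of the element (inside
#' the core with a core boundary as one ordered neighbor, or abutting
#' the core within `edge_margin` bp — the core envelope is built from
#' viral gene hits only, so a terminal transposase sits just outside
#' it); co_localized: within the flank but clearly separated from the
#' core; none: no transposase hit at the locus.
#'
#' @param locus a flanked locus.
#' @param transposase_hits hits of the transposase query (genome
#'   coordinates).
#' @param viral_hits hits of the viral gene queries.
#' @param edge_margin maximum gap (bp) between the transposase hit and
#'   the core envelope for an edge fusion; larger gaps co-localize.
#' @return object of class `fusion_call`: list with status,
#'   neighbor_genes (left, right; element-boundary markers "5'" / "3'"),
#'   transposase_interval, distance_to_element.
#' @export
classify_fusion <- function(locus, transposase_hits, viral_hits,
                            edge_margin = 1000L) {
  none <- structure(list(status = "none",
                         neighbor_genes = c(NA_character_, NA_character_),
                         transposase_interval = NULL,
                         distance_to_element = NA_real_),
                    class = "fusion_call")
  if (is.null(transposase_hits) || nrow(transposase_hits) == 0L) return(none)
  tp <- transposase_hits[transposase_hits$contig_id == locus$contig_id &
                           transposase_hits$nt_start >= locus$flank_start &
                           transposase_hits$nt_end <= locus$flank_end, ,
                         drop = FALSE]
  if (nrow(tp) == 0L) return(none)
  tp <- tp[which.max(tp$bitscore), , drop = FALSE]
  tp_mid <- (tp$nt_start + tp$nt_end) / 2
  inside <- tp_mid >= locus$core_start && tp_mid < locus$core_end
  if (!inside) {
    before <- tp_mid < locus$core_start
    dist <- max(if (before) locus$core_start - tp$nt_end
                else tp$nt_start - locus$core_end, 0)
    if (dist > edge_margin) {
      return(structure(list(status = "co_localized",
                            neighbor_genes = c(NA_character_, NA_character_),
                            transposase_interval = c(tp$nt_start, tp$nt_end),
                            distance_to_element = dist),
                       class = "fusion_call"))
    }
    # terminal transposase abutting the viral gene envelope
    vh0 <- viral_hits[viral_hits$contig_id == locus$contig_id, , drop = FALSE]
    vh0 <- vh0[order(vh0$nt_start), , drop = FALSE]
    nb <- if (before) c("5'", if (nrow(vh0)) vh0$gene_name[1] else "3'")
          else c(if (nrow(vh0)) vh0$gene_name[nrow(vh0)] else "5'", "3'")
    return(structure(list(status = "fused_edge", neighbor_genes = nb,
                          transposase_interval = c(tp$nt_start, tp$nt_end),
                          distance_to_element = dist),
                     class = "fusion_call"))
  }
  # order the best hit per viral gene along the core, tie-break by score
  vh <- viral_hits[viral_hits$contig_id == locus$contig_id &
                     viral_hits$nt_start >= locus$core_start &
                     viral_hits$nt_end <= locus$core_end, , drop = FALSE]
  if (nrow(vh)) {
    best <- do.call(rbind, lapply(split(vh, vh$gene_name), function(d)
      d[which.max(d$bitscore), , drop = FALSE]))
    best$mid <- (best$nt_start + best$nt_end) / 2
    best <- best[order(best$mid, -best$bitscore), , drop = FALSE]
  } else best <- vh
  left_genes <- if (nrow(best)) best$gene_name[best$mid < tp_mid] else character(0)
  right_genes <- if (nrow(best)) best$gene_name[best$mid > tp_mid] else character(0)
  left <- if (length(left_genes)) tail(left_genes, 1L) else "5'"
  right <- if (length(right_genes)) right_genes[1L] else "3'"
  status <- if (length(left_genes) && length(right_genes)) "fused_internal"
            else "fused_edge"
  structure(list(status = status, neighbor_genes = c(left, right),
                 transposase_interval = c(tp$nt_start, tp$nt_end),
                 distance_to_element = 0),
            class = "fusion_call")
}

#' Write locus annotations as GFF3
#'
#' Hits, ORFs and TIRs on locus-local coordinates.
#'
#' @param locus a flanked locus.
#' @param path output file path.
#' @param orfs optional ORF table from [call_orfs()].
#' @param tir optional TIR call from [find_tirs()].
#' @export
write_locus_gff3 <- function(locus, path, orfs = NULL, tir = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  seqid <- sprintf("%s_%d_%d", locus$contig_id, locus$flank_start,
                   locus$flank_end)
  emit <- function(type, start, end, strand, attr) {
    writeLines(paste(seqid, "teratornscan", type, start + 1L, end,
                     ".", strand, ".", attr, sep = "\t"), con)
  }
  h <- hits_to_locus_coords(locus$member_hits, locus)
  for (i in seq_len(nrow(h))) {
    emit("protein_match", h$nt_start[i], h$nt_end[i], h$strand[i],
         sprintf("ID=hit%d;Name=%s;evalue=%.3g", i, h$gene_name[i],
                 h$evalue[i]))
  }
  if (!is.null(orfs)) {
    for (i in seq_len(nrow(orfs))) {
      emit("ORF", orfs$start[i], orfs$end[i], orfs$strand[i],
           sprintf("ID=orf%d;length_aa=%d", i, orfs$length_aa[i]))
    }
  }
  if (!is.null(tir)) {
    emit("terminal_inverted_repeat", tir$left_start, tir$left_end, "+",
         "ID=tir_left")
    emit("terminal_inverted_repeat", tir$right_start, tir$right_end, "-",
         "ID=tir_right")
  }
  invisible(path)
}
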