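# Six-frame translated homology search of viral protein queries against
# nucleotide contigs: exact-word seeding, ungapped X-drop triggering,
# gapped local extension under BLOSUM62, and Karlin-Altschul E-values.

SEARCH_ALPHABET <- "ARNDCQEGHILKMFPSTWYVBZX*"

blosum62_matrix <- function() {
  data("BLOSUM62", package = "Biostrings", envir = environment())
  m <- get("BLOSUM62", envir = environment())
  ab <- strsplit(SEARCH_ALPHABET, "")[[1]]
  out <- matrix(-4L, length(ab), length(ab), dimnames = list(ab, ab))
  common <- intersect(ab, rownames(m))
  out[common, common] <- m[common, common]
  storage.mode(out) <- "integer"
  out
}

#' Six-frame translation with coordinate maps
#'
#' @param contig nucleotide string (length >= 3).
#' @return data frame with one row per frame: strand, frame, protein.
#'   Map amino-acid coordinates back to forward-genome bp with
#'   [frame_aa_to_genome()].
#' @export
six_frame_translate <- function(contig) {
  if (!nzchar(contig) || nchar(contig) < 3L) {
    stop("contig must be at least 3 bp")
  }
  L <- nchar(contig)
  rc <- revcomp(contig)
  rows <- list()
  i <- 0L
  for (strand in c("+", "-")) {
    s <- if (strand == "+") contig else rc
    for (frame in 0:2) {
      i <- i + 1L
      rows[[i]] <- data.frame(
        strand = strand, frame = frame,
        protein = translate_nt(substr(s, frame + 1L, L)),
        stringsAsFactors = FALSE)
    }
  }
  do.call(rbind, rows)
}

#' Map an amino-acid interval in a frame translation to forward-genome bp
#'
#' @param contig_length contig length in bp.
#' @param strand "+" or "-".
#' @param frame frame offset 0, 1 or 2.
#' @param aa_start,aa_end 0-based half-open amino-acid interval.
#' @return integer vector (nt_start, nt_end), 0-based half-open on the
#'   forward strand.
#' @export
frame_aa_to_genome <- function(contig_length, strand, frame, aa_start, aa_end) {
  nt_s <- frame + 3L * aa_start
  nt_e <- frame + 3L * aa_end
  if (strand == "+") c(nt_s, nt_e) else c(contig_length - nt_e,
                                          contig_length - nt_s)
}

#' Karlin-Altschul E-value for an ungapped-statistics local alignment
#'
#' E = K * m * n * exp(-lambda * S) with m the query length (aa), n the
#' searched database length (aa).
#'
#' @param raw_score alignment raw score S.
#' @param query_length query length in aa.
#' @param database_length total translated database length in aa.
#' @param K,lambda Karlin-Altschul parameters (ungapped BLOSUM62
#'   defaults).
#' @return the expected number of chance hits at this score or better.
#' @export
estimate_evalue <- function(raw_score, query_length, database_length,
                            K = 0.134, lambda = 0.3176) {
  if (K <= 0 || lambda <= 0) stop("K and lambda must be positive")
  if (any(query_length <= 0) || any(database_length <= 0)) {
    stop("lengths must be positive")
  }
  K * query_length * database_length * exp(-lambda * raw_score)
}

bit_score <- function(raw_score, K = 0.134, lambda = 0.3176) {
  (lambda * raw_score - log(K)) / log(2)
}

#' Default translated-search parameters
#' @export
search_params <- function(word_size = 4L, gap_open = -11L, gap_extend = -1L,
                          x_drop = 20L, evalue_keep = 1e-3,
                          ungapped_trigger = 25L,
                          K = 0.134, lambda = 0.3176) {
  list(word_size = word_size, gap_open = gap_open, gap_extend = gap_extend,
       x_drop = x_drop, evalue_keep = evalue_keep,
       ungapped_trigger = ungapped_trigger, K = K, lambda = lambda)
}

# Merge overlapping hits within one (contig, strand, frame), keeping the
# best-scoring extension per overlapping set.
merge_frame_hits <- function(df) {
  if (nrow(df) <= 1L) return(df)
  df <- df[order(df$nt_start, -df$raw_score), , drop = FALSE]
  keep <- logical(nrow(df))
  cur_end <- -1L
  cur_best <- -1L
  groups <- integer(nrow(df))
  gid <- 0L
  for (i in seq_len(nrow(df))) {
    if (df$nt_start[i] >= cur_end) {
      gid <- gid + 1L
      cur_end <- df$nt_end[i]
    } else {
      cur_end <- max(cur_end, df$nt_end[i])
    }
    groups[i] <- gid
  }
  picked <- vapply(split(seq_len(nrow(df)), groups), function(ix) {
    ix[which.max(df$raw_score[ix])]
  }, integer(1))
  df[sort(picked), , drop = FALSE]
}

#' Translated search of protein queries against a genome assembly
#'
#' The in-house counterpart of a tblastn screen: every query is searched
#' against all six reading frames of every contig with exact word
#' seeding, ungapped X-drop triggering and gapped Smith-Waterman
#' extension; hits at or above the E-value cutoff are discarded.
#'
#' @param queries named character vector of protein sequences.
#' @param genome named character vector of contigs.
#' @param params parameter list from [search_params()].
#' @return data frame of hits sorted by bitscore (descending): gene_name,
#'   contig_id, strand, frame, nt_start, nt_end (0-based half-open,
#'   forward strand), aa_query_start, aa_query_end, raw_score, bitscore,
#'   evalue, aligned_identity.
#' @export
search_genome <- function(queries, genome, params = search_params()) {
  stopifnot(is.character(queries), !is.null(names(queries)))
  genome <- genome_assembly(genome)
  if (any(nchar(queries) < params$word_size)) {
    stop("query shorter than word_size")
  }
  submat <- blosum62_matrix()
  frames <- lapply(genome, six_frame_translate)
  db_len <- sum(vapply(frames, function(f) sum(nchar(f$protein)), numeric(1)))
  out <- list()
  k <- 0L
  for (cn in names(genome)) {
    L <- nchar(genome[[cn]])
    fr <- frames[[cn]]
    for (qi in seq_along(queries)) {
      qname <- names(queries)[qi]
      qseq <- queries[[qi]]
      for (r in seq_len(nrow(fr))) {
        raw <- cpp_search_frame(qseq, fr$protein[r], submat, SEARCH_ALPHABET,
                                params$word_size, params$gap_open,
                                params$gap_extend, params$x_drop,
                                params$ungapped_trigger)
        if (nrow(raw) == 0L) next
        for (h in seq_len(nrow(raw))) {
          nt <- frame_aa_to_genome(L, fr$strand[r], fr$frame[r],
                                   raw$sstart[h], raw$send[h])
          k <- k + 1L
          out[[k]] <- data.frame(
            gene_name = qname, contig_id = cn, strand = fr$strand[r],
            frame = fr$frame[r], nt_start = nt[1], nt_end = nt[2],
            aa_query_start = raw$qstart[h], aa_query_end = raw$qend[h],
            raw_score = raw$score[h],
            aligned_identity = raw$matches[h] / raw$align_length[h],
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  if (k == 0L) return(empty_hits())
  hits <- do.call(rbind, out)
  # merge overlapping same-frame hits (best-scoring wins)
  key <- interaction(hits$gene_name, hits$contig_id, hits$strand, hits$frame,
                     drop = TRUE)
  hits <- do.call(rbind, lapply(split(hits, key), merge_frame_hits))
  hits$evalue <- estimate_evalue(hits$raw_score, nchar(queries[hits$gene_name]),
                                 db_len, params$K, params$lambda)
  hits$bitscore <- bit_score(hits$raw_score, params$K, params$lambda)
  hits <- hits[hits$evalue < params$evalue_keep, , drop = FALSE]
  hits <- hits[order(-hits$bitscore), , drop = FALSE]
  rownames(hits) <- NULL
  hits
}

empty_hits <- function() {
  data.frame(gene_name = character(0), contig_id = character(0),
             strand = character(0), frame = integer(0),
             nt_start = integer(0), nt_end = integer(0),
             aa_query_start = integer(0), aa_query_end = integer(0),
             raw_score = numeric(0), aligned_identity = numeric(0),
             evalue = numeric(0), bitscore = numeric(0),
             stringsAsFactors = FALSE)
}

#' Write hits as a BLAST outfmt-6-like table
#'
#' Columns: query, subject, percent identity, alignment length (aa),
#' query start/end (1-based), subject start/end (1-based bp), evalue,
#' bitscore, strand, frame.
#'
#' @param hits hit data frame from [search_genome()].
#' @param path output file path.
#' @export
write_hits_tsv <- function(hits, path) {
  df <- data.frame(
    query = hits$gene_name, subject = hits$contig_id,
    pident = round(100 * hits$aligned_identity, 2),
    length = hits$aa_query_end - hits$aa_query_start,
    qstart = hits$aa_query_start + 1L, qend = hits$aa_query_end,
    sstart = hits$nt_start + 1L, send = hits$nt_end,
    evalue = hits$evalue, bitscore = round(hits$bitscore, 1),
    strand = hits$strand, frame = hits$frame)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
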