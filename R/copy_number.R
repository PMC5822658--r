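# Coverage-ratio copy-number estimation: element copies are masked from
# the assembly and a single element reference appended, reads are mapped
# to the reconstructed reference, and copy number is the ratio of mean
# per-base depth over viral CDSs to mean depth over host CDSs.

#' Build a mask-and-append reference
#'
#' Element copies in the assembly are replaced by runs of N (so reads
#' from any copy cannot map there) and one contig carrying the element
#' reference sequence is appended; multi-copy read depth then collapses
#' onto the single appended target.
#'
#' @param genome named character vector of contigs.
#' @param element_intervals data frame (contig_id, start, end; 0-based
#'   half-open) locating the element copies to mask; may be empty.
#' @param element_seq element reference sequence to append (a named
#'   character vector appends several, e.g. one per subtype).
#' @return the reconstructed assembly.
#' @export
build_masked_reference <- function(genome, element_intervals, element_seq) {
  genome <- genome_assembly(genome)
  if (!is.null(element_intervals) && nrow(element_intervals)) {
    for (i in seq_len(nrow(element_intervals))) {
      cn <- element_intervals$contig_id[i]
      s <- element_intervals$start[i]
      e <- element_intervals$end[i]
      if (!cn %in% names(genome)) stop("unknown contig: ", cn)
      if (s < 0 || e > nchar(genome[[cn]]) || s >= e) {
        stop("interval outside genome: ", cn, ":", s, "-", e)
      }
      substr(genome[[cn]], s + 1L, e) <- paste(rep("N", e - s), collapse = "")
    }
  }
  if (is.null(names(element_seq))) {
    names(element_seq) <- if (length(element_seq) == 1L) "element_ref"
      else sprintf("element_ref_%d", seq_along(element_seq))
  }
  genome_assembly(c(genome, element_seq))
}

#' Map reads to a reference by k-mer seeding and Hamming verification
#'
#' Candidate placements come from exact seed k-mers at the read start,
#' middle and end (both strands); each candidate is verified over the
#' full read length (N never matches) and the placement with the fewest
#' mismatches is kept, provided it has at most `max_mismatches`.  Among
#' equal-best placements one is chosen uniformly at random under the
#' stated seed.
#'
#' @param reads named character vector of read sequences.
#' @param reference named character vector of contigs.
#' @param seed_kmer seed k-mer length (< read length).
#' @param max_mismatches maximum Hamming mismatches for a valid
#'   placement.
#' @param seed integer seed for multi-mapping tie-breaks.
#' @return data frame (read_id, contig, start, strand, mismatches);
#'   start is 0-based, unplaced reads are absent.
#' @export
map_reads <- function(reads, reference, seed_kmer = 21L,
                      max_mismatches = 4L, seed = 1L) {
  if (!length(reference)) stop("reference is empty")
  if (min(nchar(reads)) <= seed_kmer) {
    stop("read length must exceed seed_kmer")
  }
  with_seed(seed, {
    pl <- cpp_map_reads(unname(reads), unname(reference),
                        as.integer(seed_kmer), as.integer(max_mismatches))
    data.frame(read_id = names(reads)[pl$read],
               contig = names(reference)[pl$contig],
               start = pl$start,
               strand = ifelse(pl$strand == 0L, "+", "-"),
               mismatches = pl$mismatches,
               read_length = nchar(reads)[pl$read],
               stringsAsFactors = FALSE)
  })
}

#' Per-base depth over a set of intervals
#'
#' depth[i] = number of placements overlapping base i (exact integer
#' counts).
#'
#' @param placements data frame from [map_reads()] (read_length column
#'   required, or pass `read_length`).
#' @param intervals data frame (contig_id, start, end, gene_id, class)
#'   with class in "viral"/"host".
#' @param read_length fallback read length when the placements carry
#'   none.
#' @return object of class `coverage_profile`: list with `intervals` and
#'   `depth` (list of integer vectors, one per interval).
#' @export
per_base_depth <- function(placements, intervals, read_length = NULL) {
  if (!"read_length" %in% names(placements)) {
    if (is.null(read_length)) stop("read_length required")
    placements$read_length <- read_length
  }
  cov_by_contig <- list()
  for (cn in unique(intervals$contig_id)) {
    p <- placements[placements$contig == cn, , drop = FALSE]
    if (nrow(p)) {
      ir <- IRanges::IRanges(start = p$start + 1L,
                             width = p$read_length)
      cov_by_contig[[cn]] <- as.integer(IRanges::coverage(ir))
    } else {
      cov_by_contig[[cn]] <- integer(0)
    }
  }
  depth <- vector("list", nrow(intervals))
  for (i in seq_len(nrow(intervals))) {
    cn <- intervals$contig_id[i]
    s <- intervals$start[i]; e <- intervals$end[i]
    cv <- cov_by_contig[[cn]]
    v <- integer(e - s)
    upto <- min(e, length(cv))
    if (upto > s) v[seq_len(upto - s)] <- cv[(s + 1L):upto]
    depth[[i]] <- v
  }
  structure(list(intervals = intervals, depth = depth),
            class = "coverage_profile")
}

#' Write a coverage profile as a per-position depth table
#'
#' Three columns (contig, 1-based position, depth), the de-facto depth
#' dialect of samtools depth / coverageBed -d.
#'
#' @param profile a `coverage_profile`.
#' @param path output file path.
#' @export
write_depth_table <- function(profile, path) {
  rows <- lapply(seq_len(nrow(profile$intervals)), function(i) {
    iv <- profile$intervals[i, ]
    data.frame(contig = iv$contig_id,
               pos = seq.int(iv$start + 1L, iv$end),
               depth = profile$depth[[i]])
  })
  write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a per-position depth table into a coverage profile
#'
#' Rows are (contig, 1-based position, depth), sorted by contig and
#' position; 1-based file positions map to 0-based internal coordinates
#' (position 1 is index 0).  Contiguous runs per contig become
#' intervals; supply `intervals` to relabel them with gene metadata.
#'
#' @param path input TSV path.
#' @param intervals optional interval data frame (contig_id, start, end,
#'   gene_id, class) to slice the depths by.
#' @return a `coverage_profile`.
#' @export
read_depth_table <- function(path, intervals = NULL) {
  lines <- readLines(path)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  for (i in seq_along(parts)) {
    p <- parts[[i]]
    if (length(p) != 3L || is.na(suppressWarnings(as.integer(p[2]))) ||
        is.na(suppressWarnings(as.numeric(p[3])))) {
      stop("malformed depth table row at line ", i)
    }
  }
  df <- data.frame(contig = vapply(parts, `[`, character(1), 1L),
                   pos = as.integer(vapply(parts, `[`, character(1), 2L)),
                   depth = as.integer(vapply(parts, `[`, character(1), 3L)),
                   stringsAsFactors = FALSE)
  if (is.null(intervals)) {
    ivs <- list(); dps <- list()
    for (cn in unique(df$contig)) {
      d <- df[df$contig == cn, , drop = FALSE]
      if (is.unsorted(d$pos, strictly = TRUE)) {
        stop("positions not strictly increasing for contig ", cn)
      }
      run <- cumsum(c(1L, diff(d$pos) != 1L))
      for (r in unique(run)) {
        dd <- d[run == r, , drop = FALSE]
        s <- dd$pos[1] - 1L  # 1-based file position -> 0-based index
        e <- dd$pos[nrow(dd)]
        ivs[[length(ivs) + 1L]] <- data.frame(
          contig_id = cn, start = s, end = e,
          gene_id = sprintf("%s:%d-%d", cn, s, e), class = NA_character_,
          stringsAsFactors = FALSE)
        dps[[length(dps) + 1L]] <- dd$depth
      }
    }
    structure(list(intervals = do.call(rbind, ivs), depth = dps),
              class = "coverage_profile")
  } else {
    dps <- lapply(seq_len(nrow(intervals)), function(i) {
      iv <- intervals[i, ]
      d <- df[df$contig == iv$contig_id & df$pos > iv$start &
                df$pos <= iv$end, , drop = FALSE]
      v <- integer(iv$end - iv$start)
      v[d$pos - iv$start] <- d$depth
      v
    })
    structure(list(intervals = intervals, depth = dps),
              class = "coverage_profile")
  }
}

#' Coverage-ratio copy-number estimate
#'
#' copy_number = mean per-base depth over all viral-CDS bases divided by
#' mean depth over all host-CDS bases (pooled grand means).  A bootstrap
#' over genes within each class gives a 95% confidence interval.
#'
#' @param profile a `coverage_profile` whose intervals carry gene_id and
#'   class columns.
#' @param viral_genes,host_genes gene_id vectors defining the two
#'   classes (default: intervals with class "viral"/"host").
#' @param n_bootstrap bootstrap replicates.
#' @param seed integer seed for the bootstrap.
#' @return object of class `copy_number_estimate`: list with
#'   mean_viral_depth, mean_host_depth, copy_number, bootstrap_ci,
#'   per_gene_means.
#' @export
estimate_copy_number <- function(profile, viral_genes = NULL,
                                 host_genes = NULL, n_bootstrap = 1000L,
                                 seed = 1L) {
  iv <- profile$intervals
  if (is.null(viral_genes)) viral_genes <- iv$gene_id[iv$class == "viral"]
  if (is.null(host_genes)) host_genes <- iv$gene_id[iv$class == "host"]
  if (!length(viral_genes) || !length(host_genes)) {
    stop("both gene classes must be non-empty")
  }
  vi <- which(iv$gene_id %in% viral_genes)
  hi <- which(iv$gene_id %in% host_genes)
  pooled_mean <- function(ix) {
    tot <- sum(vapply(profile$depth[ix], sum, numeric(1)))
    len <- sum(vapply(profile$depth[ix], length, numeric(1)))
    tot / len
  }
  mv <- pooled_mean(vi)
  mh <- pooled_mean(hi)
  if (mh == 0) stop("zero host depth: copy-number ratio undefined")
  est <- mv / mh
  ci <- c(NA_real_, NA_real_)
  if (n_bootstrap > 0L) {
    ci <- with_seed(seed, {
      reps <- vapply(seq_len(n_bootstrap), function(b) {
        bv <- sample(vi, length(vi), replace = TRUE)
        bh <- sample(hi, length(hi), replace = TRUE)
        denom <- pooled_mean(bh)
        if (denom == 0) NA_real_ else pooled_mean(bv) / denom
      }, numeric(1))
      unname(quantile(reps, c(0.025, 0.975), na.rm = TRUE))
    })
  }
  per_gene <- data.frame(
    gene_id = iv$gene_id[c(vi, hi)],
    class = c(rep("viral", length(vi)), rep("host", length(hi))),
    mean_depth = vapply(profile$depth[c(vi, hi)], mean, numeric(1)))
  structure(list(mean_viral_depth = mv, mean_host_depth = mh,
                 copy_number = est, bootstrap_ci = ci,
                 per_gene_means = per_gene),
            class = "copy_number_estimate")
}
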