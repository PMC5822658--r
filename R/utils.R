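#' @useDynLib teratornscan, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats runif rbinom rpois setNames median quantile
#' @importFrom utils read.table write.table head tail
NULL

DNA_BASES <- c("A", "C", "G", "T")

# Evaluate expr under a temporary RNG seed, restoring global RNG state after.
with_seed <- function(seed, expr) {
  if (!is.null(seed)) {
    has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
    old <- if (has_old) get(".Random.seed", envir = globalenv()) else NULL
    on.exit({
      if (has_old) {
        assign(".Random.seed", old, envir = globalenv())
      } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    }, add = TRUE)
    set.seed(as.integer(seed))
  }
  force(expr)
}

# Derive a stage seed from a run seed; stays below 2^31 - 1.
derive_seed <- function(seed, offset) {
  as.integer((as.numeric(seed) * 7919 + offset * 104729) %% 2147483647L)
}

#' Reverse complement of a nucleotide string
#'
#' @param x a single nucleotide string over A, C, G, T, N.
#' @return the reverse complement as a character scalar.
#' @export
revcomp <- function(x) {
  stopifnot(is.character(x), length(x) == 1L)
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

rand_dna <- function(n, gc = 0.5) {
  if (n <= 0) return("")
  p <- c((1 - gc) / 2, gc / 2, gc / 2, (1 - gc) / 2)
  paste(sample(DNA_BASES, n, replace = TRUE, prob = p), collapse = "")
}

check_dna_alphabet <- function(x, allow_n = TRUE, what = "sequence") {
  pat <- if (allow_n) "[^ACGTN]" else "[^ACGT]"
  if (any(grepl(pat, x))) {
    stop(what, " contains characters outside the {A,C,G,T",
         if (allow_n) ",N" else "", "} alphabet")
  }
  invisible(TRUE)
}

#' Validate and construct a genome assembly
#'
#' A genome assembly is represented as a named character vector of
#' uppercase contig sequences over the alphabet A, C, G, T, N.
#'
#' @param contigs named character vector of contig sequences.
#' @return the validated named character vector.
#' @export
genome_assembly <- function(contigs) {
  stopifnot(is.character(contigs))
  if (is.null(names(contigs)) || anyDuplicated(names(contigs)) ||
      any(!nzchar(names(contigs)))) {
    stop("contigs must carry unique non-empty names")
  }
  if (any(!nzchar(contigs))) stop("contig sequences must be non-empty")
  contigs <- toupper(contigs)
  check_dna_alphabet(contigs, allow_n = TRUE, what = "contig")
  contigs
}

# Translate a nucleotide string; codons containing N become X, stops are '*'.
translate_nt <- function(seq) {
  n <- nchar(seq) - nchar(seq) %% 3L
  if (n < 3L) return("")
  as.character(Biostrings::translate(Biostrings::DNAString(substr(seq, 1L, n)),
                                     if.fuzzy.codon = "X",
                                     no.init.codon = TRUE))
}

codon_split <- function(seq) {
  n <- nchar(seq)
  if (n %% 3L != 0L) stop("sequence length not divisible by 3")
  substring(seq, seq(1L, n, 3L), seq(3L, n, 3L))
}

GENETIC_CODE_STD <- local({
  gc <- Biostrings::GENETIC_CODE
  setNames(as.character(gc), names(gc))
})

is_stop_codon <- function(codon) {
  !is.na(GENETIC_CODE_STD[codon]) & GENETIC_CODE_STD[codon] == "*"
}

#' Write sequences to a FASTA file
#' @param seqs named character vector of sequences.
#' @param path output file path.
#' @export
write_fasta <- function(seqs, path) {
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs), filepath = path)
  invisible(path)
}

#' Read a FASTA file into a named character vector
#' @param path input file path.
#' @param type "dna" or "protein".
#' @export
read_fasta <- function(path, type = c("dna", "protein")) {
  type <- match.arg(type)
  x <- if (type == "dna") Biostrings::readDNAStringSet(path)
       else Biostrings::readAAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write reads to a FASTQ file with a fixed quality string
#' @param reads named character vector of read sequences.
#' @param path output file path.
#' @param quality_char single quality character applied to every base.
#' @export
write_fastq <- function(reads, path, quality_char = "I") {
  ids <- names(reads)
  qual <- vapply(nchar(reads), function(n)
    paste(rep(quality_char, n), collapse = ""), character(1))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("@", ids, "\n", reads, "\n+\n", qual), con)
  invisible(path)
}

#' Read a FASTQ file into a named character vector of read sequences
#' @param path input file path.
#' @export
read_fastq <- function(path) {
  lines <- readLines(path)
  if (length(lines) %% 4L != 0L) stop("malformed FASTQ: line count not a multiple of 4")
  ids <- sub("^@", "", lines[seq(1L, length(lines), 4L)])
  ids <- sub("\\s.*$", "", ids)
  setNames(lines[seq(2L, length(lines), 4L)], ids)
}

#' Write intervals as a BED file (0-based half-open)
#' @param intervals data frame with columns contig_id, start, end and
#'   optionally gene_id and strand.
#' @param path output file path.
#' @export
write_bed <- function(intervals, path) {
  df <- data.frame(chrom = intervals$contig_id,
                   start = intervals$start,
                   end = intervals$end,
                   name = if ("gene_id" %in% names(intervals)) intervals$gene_id else ".",
                   score = 0L,
                   strand = if ("strand" %in% names(intervals)) intervals$strand else "+")
  write.table(df, path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a BED file into an interval data frame (0-based half-open)
#' @param path input file path.
#' @export
read_bed <- function(path) {
  df <- read.table(path, sep = "\t", header = FALSE, stringsAsFactors = FALSE)
  out <- data.frame(contig_id = df[[1]], start = df[[2]], end = df[[3]],
                    stringsAsFactors = FALSE)
  if (ncol(df) >= 4) out$gene_id <- df[[4]]
  if (ncol(df) >= 6) out$strand <- df[[6]]
  out
}
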