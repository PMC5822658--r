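# Pairwise nucleotide divergence: global alignment, identity, Kimura
# 2-parameter distance, alignment trimming, and modified Nei-Gojobori
# dN/dS with transition/transversion bias R = 2.

#' Global pairwise nucleotide alignment (Needleman-Wunsch, affine gaps)
#'
#' A gap of length L costs `gap_open + (L - 1) * gap_extend` (both
#' negative).  Alignment is delegated to Biostrings' optimal global
#' aligner; ties between equal-scoring alignments are resolved by its
#' deterministic traceback, so results are reproducible.
#'
#' @param a,b nucleotide strings over A, C, G, T, N.
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend gap scores (negative).
#' @return object of class `pairwise_alignment`: list with `a`, `b`
#'   (aligned strings with "-" gaps) and `score`.
#' @export
global_align_nt <- function(a, b, match = 1, mismatch = -1,
                            gap_open = -5, gap_extend = -1) {
  if (!nzchar(a) || !nzchar(b)) stop("sequences must be non-empty")
  check_dna_alphabet(c(a, b), allow_n = TRUE)
  ab <- c("A", "C", "G", "T", "N")
  sm <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(sm) <- match
  sm["N", ] <- mismatch
  sm[, "N"] <- mismatch
  pa <- Biostrings::pairwiseAlignment(
    Biostrings::DNAString(a), Biostrings::DNAString(b),
    type = "global", substitutionMatrix = sm,
    gapOpening = gap_extend - gap_open, gapExtension = -gap_extend)
  structure(list(a = as.character(Biostrings::alignedPattern(pa)),
                 b = as.character(Biostrings::alignedSubject(pa)),
                 score = Biostrings::score(pa)),
            class = "pairwise_alignment")
}

aln_columns <- function(alignment) {
  x <- strsplit(alignment$a, "")[[1]]
  y <- strsplit(alignment$b, "")[[1]]
  if (length(x) != length(y)) stop("aligned sequences differ in length")
  list(a = x, b = y)
}

#' Fraction of identical residues over non-gap columns
#'
#' @param alignment a `pairwise_alignment`.
#' @param mode gap handling; columns with a gap in either row are
#'   excluded.
#' @return identity in [0, 1]; NA when no non-gap column exists.
#' @export
pairwise_identity <- function(alignment, mode = "exclude_gap_columns") {
  mode <- match.arg(mode, "exclude_gap_columns")
  cc <- aln_columns(alignment)
  ok <- cc$a != "-" & cc$b != "-"
  if (!any(ok)) return(NA_real_)
  mean(cc$a[ok] == cc$b[ok])
}

is_transition_pair <- function(x, y) {
  (x == "A" & y == "G") | (x == "G" & y == "A") |
    (x == "C" & y == "T") | (x == "T" & y == "C")
}

#' Kimura 2-parameter distance from a pairwise alignment
#'
#' d = -1/2 log((1 - 2P - Q) sqrt(1 - 2Q)) with P and Q the transition
#' and transversion difference fractions over compared columns (pairwise
#' deletion of gap and ambiguous columns).
#'
#' @param alignment a `pairwise_alignment`, or a list/character vector of
#'   two equal-length aligned strings.
#' @return list with d, P, Q (class `k2p_estimate`).
#' @export
k2p_distance <- function(alignment) {
  if (is.character(alignment) && length(alignment) == 2L) {
    alignment <- list(a = alignment[[1]], b = alignment[[2]])
  }
  cc <- aln_columns(alignment)
  ok <- cc$a %in% DNA_BASES & cc$b %in% DNA_BASES
  n <- sum(ok)
  if (n == 0L) stop("no comparable columns")
  x <- cc$a[ok]; y <- cc$b[ok]
  diff <- x != y
  P <- sum(diff & is_transition_pair(x, y)) / n
  Q <- sum(diff & !is_transition_pair(x, y)) / n
  w1 <- 1 - 2 * P - Q
  w2 <- 1 - 2 * Q
  if (w1 <= 0 || w2 <= 0) {
    stop("saturated pair: K2P distance undefined (1-2P-Q or 1-2Q <= 0)")
  }
  structure(list(d = -0.5 * log(w1 * sqrt(w2)), P = P, Q = Q),
            class = "k2p_estimate")
}

# ---- modified Nei-Gojobori -------------------------------------------

# Weighted synonymous site count of one codon: each of the three
# positions contributes the R-weighted fraction of its non-nonsense
# single-nucleotide changes that are synonymous.  Changes to stop codons
# are excluded from numerator and denominator, so S + N = 3 per codon.
ng_codon_sites <- function(codon, R = 2) {
  aa0 <- GENETIC_CODE_STD[codon]
  if (is.na(aa0) || aa0 == "*") return(c(S = 0, N = 0))
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  s_total <- 0
  for (j in 1:3) {
    ref <- substr(codon, j, j)
    wsum <- 0; wsyn <- 0
    for (b in setdiff(DNA_BASES, ref)) {
      mut <- codon
      substr(mut, j, j) <- b
      aa1 <- GENETIC_CODE_STD[mut]
      if (aa1 == "*") next
      w <- if (b == ts_map[ref]) R else 1
      wsum <- wsum + w
      if (aa1 == aa0) wsyn <- wsyn + w
    }
    if (wsum > 0) s_total <- s_total + wsyn / wsum
  }
  c(S = s_total, N = 3 - s_total)
}

# Pathway-averaged synonymous/nonsynonymous difference counts between
# two codons: minimal mutational paths (permutations of the differing
# positions), excluding paths through stop codons (all paths used when
# every path is blocked), equally weighted.
ng_codon_diffs <- function(c1, c2) {
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(Sd = 0, Nd = 0))
  perms <- if (nd == 1L) list(pos) else {
    if (nd == 2L) list(pos, rev(pos)) else {
      idx <- list(c(1, 2, 3), c(1, 3, 2), c(2, 1, 3),
                  c(2, 3, 1), c(3, 1, 2), c(3, 2, 1))
      lapply(idx, function(i) pos[i])
    }
  }
  path_counts <- function(order) {
    cur <- c1
    sd <- 0; nd_ <- 0
    for (p in order) {
      nxt <- cur
      substr(nxt, p, p) <- substr(c2, p, p)
      aa_cur <- GENETIC_CODE_STD[cur]
      aa_nxt <- GENETIC_CODE_STD[nxt]
      if (aa_nxt == "*" && nxt != c2) return(NULL)  # blocked path
      if (aa_nxt == "*" || aa_cur == "*") return(NULL)
      if (aa_nxt == aa_cur) sd <- sd + 1 else nd_ <- nd_ + 1
      cur <- nxt
    }
    c(sd, nd_)
  }
  res <- lapply(perms, path_counts)
  res <- res[!vapply(res, is.null, logical(1))]
  if (!length(res)) {
    # all paths pass through a stop; fall back to counting through them
    path_counts_any <- function(order) {
      cur <- c1; sd <- 0; nd_ <- 0
      for (p in order) {
        nxt <- cur
        substr(nxt, p, p) <- substr(c2, p, p)
        if (GENETIC_CODE_STD[nxt] == GENETIC_CODE_STD[cur]) sd <- sd + 1
        else nd_ <- nd_ + 1
        cur <- nxt
      }
      c(sd, nd_)
    }
    res <- lapply(perms, path_counts_any)
  }
  m <- do.call(rbind, res)
  c(Sd = mean(m[, 1]), Nd = mean(m[, 2]))
}

#' Modified Nei-Gojobori dN/dS for an aligned codon pair
#'
#' Site counting weights transitional changes by the
#' transition/transversion bias R (default 2) relative to
#' transversional changes; difference counting averages over equally
#' weighted minimal mutational pathways; pN and pS are Jukes-Cantor
#' corrected.  Codon columns containing gaps are excluded.
#'
#' @param cds_a,cds_b aligned in-frame coding sequences of equal length
#'   (length divisible by 3; "-" gaps allowed in whole-codon runs).
#' @param R transition/transversion bias for site counting.
#' @return list with dN, dS, ratio (NA when dS = 0), and the underlying
#'   counts (S, N, Sd, Nd, pS, pN); class `dnds_estimate`.
#' @export
ng_dnds <- function(cds_a, cds_b, R = 2) {
  if (nchar(cds_a) != nchar(cds_b)) stop("aligned sequences differ in length")
  if (nchar(cds_a) %% 3L != 0L) stop("alignment length not divisible by 3")
  ca <- codon_split(cds_a)
  cb <- codon_split(cds_b)
  keep <- !grepl("-", ca, fixed = TRUE) & !grepl("-", cb, fixed = TRUE) &
    !grepl("N", ca, fixed = TRUE) & !grepl("N", cb, fixed = TRUE)
  ca <- ca[keep]; cb <- cb[keep]
  # drop a trailing aligned stop codon; flag internal stops
  n <- length(ca)
  if (n == 0L) stop("no comparable codons")
  if (is_stop_codon(ca[n]) || is_stop_codon(cb[n])) {
    ca <- ca[-n]; cb <- cb[-n]; n <- n - 1L
  }
  bad <- which(is_stop_codon(ca) | is_stop_codon(cb))
  if (length(bad)) stop("internal stop codon at codon index ", bad[1])
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_len(n)) {
    st_a <- ng_codon_sites(ca[i], R)
    st_b <- ng_codon_sites(cb[i], R)
    S <- S + (st_a["S"] + st_b["S"]) / 2
    N <- N + (st_a["N"] + st_b["N"]) / 2
    df <- ng_codon_diffs(ca[i], cb[i])
    Sd <- Sd + df["Sd"]
    Nd <- Nd + df["Nd"]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) {
    if (p >= 0.75) stop("saturated: Jukes-Cantor correction undefined")
    -0.75 * log(1 - 4 * p / 3)
  }
  dS <- jc(pS)
  dN <- jc(pN)
  structure(list(dN = unname(dN), dS = unname(dS),
                 ratio = if (dS > 0) unname(dN / dS) else NA_real_,
                 S = unname(S), N = unname(N),
                 Sd = unname(Sd), Nd = unname(Nd),
                 pS = unname(pS), pN = unname(pN)),
            class = "dnds_estimate")
}

#' Remove gappy columns from a multiple alignment
#'
#' @param msa named character vector of equal-length aligned sequences.
#' @param max_gap_fraction columns with a gap fraction above this are
#'   removed.
#' @param codon if TRUE, removal acts on whole codons: a codon is
#'   dropped when any of its three columns is flagged.
#' @return the trimmed alignment (same names).
#' @export
trim_alignment <- function(msa, max_gap_fraction = 0.5, codon = FALSE) {
  stopifnot(is.character(msa), length(msa) >= 2L)
  lens <- unique(nchar(msa))
  if (length(lens) != 1L) stop("alignment is not rectangular")
  m <- do.call(rbind, strsplit(msa, ""))
  gap_frac <- colMeans(m == "-")
  drop <- gap_frac > max_gap_fraction
  if (codon) {
    if (lens %% 3L != 0L) stop("codon trimming requires length divisible by 3")
    cod <- rep(seq_len(lens %/% 3L), each = 3L)
    drop <- rep(tapply(drop, cod, any), each = 3L)
  }
  if (all(drop)) stop("all columns removed by trimming")
  setNames(apply(m[, !drop, drop = FALSE], 1L, paste, collapse = ""),
           names(msa))
}
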