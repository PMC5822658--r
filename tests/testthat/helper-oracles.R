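# Independent brute-force oracles against which the implementation is
# validated.  These deliberately use naive algorithms (full dynamic
# programming, exhaustive enumeration, per-base recounting) and share no
# code with the package internals.

# Full Smith-Waterman score (affine gaps; a gap of length L costs
# gap_open + (L - 1) * gap_extend, both negative), computed over the
# complete DP matrix with no seeding or windowing.
sw_score_oracle <- function(q, s, submat, gap_open = -11, gap_extend = -1) {
  qv <- strsplit(q, "")[[1]]
  sv <- strsplit(s, "")[[1]]
  m <- length(qv); n <- length(sv)
  NEG <- -1e9
  M <- matrix(0, m + 1, n + 1)
  Ix <- matrix(NEG, m + 1, n + 1)
  Iy <- matrix(NEG, m + 1, n + 1)
  best <- 0
  for (i in 2:(m + 1)) {
    for (j in 2:(n + 1)) {
      Ix[i, j] <- max(M[i - 1, j] + gap_open, Ix[i - 1, j] + gap_extend)
      Iy[i, j] <- max(M[i, j - 1] + gap_open, Iy[i, j - 1] + gap_extend)
      sc <- submat[qv[i - 1], sv[j - 1]]
      M[i, j] <- max(0, M[i - 1, j - 1] + sc, Ix[i - 1, j - 1] + sc,
                     Iy[i - 1, j - 1] + sc)
      if (M[i, j] > best) best <- M[i, j]
    }
  }
  best
}

# Exhaustive enumeration of all global alignments (affine gap scoring as
# above); exponential, for sequences of length <= 8 only.
nw_enum_score <- function(a, b, match = 1, mismatch = -1,
                          gap_open = -5, gap_extend = -1) {
  na <- nchar(a); nb <- nchar(b)
  rec <- function(i, j, last) {
    if (i > na && j > nb) return(0)
    best <- -Inf
    if (i <= na && j <= nb) {
      sc <- if (substr(a, i, i) == substr(b, j, j)) match else mismatch
      best <- max(best, sc + rec(i + 1L, j + 1L, 0L))
    }
    if (i <= na) {
      g <- if (last == 1L) gap_extend else gap_open
      best <- max(best, g + rec(i + 1L, j, 1L))
    }
    if (j <= nb) {
      g <- if (last == 2L) gap_extend else gap_open
      best <- max(best, g + rec(i, j + 1L, 2L))
    }
    best
  }
  rec(1L, 1L, 0L)
}

# O(n^2) transitive-closure grouping of hit intervals; returns a group
# id per row.
merge_oracle_groups <- function(hits, merge_distance) {
  n <- nrow(hits)
  adj <- matrix(FALSE, n, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (hits$contig_id[i] == hits$contig_id[j]) {
        gap <- max(hits$nt_start[i], hits$nt_start[j]) -
          min(hits$nt_end[i], hits$nt_end[j])
        if (gap <= merge_distance) adj[i, j] <- TRUE
      }
    }
  }
  repeat {
    nxt <- adj | ((adj %*% adj) > 0)
    if (all(nxt == adj)) break
    adj <- nxt
  }
  match(apply(adj, 1, function(r) paste(which(r), collapse = ",")),
        unique(apply(adj, 1, function(r) paste(which(r), collapse = ","))))
}

# Independent modified Nei-Gojobori enumeration: per-codon weighted site
# counts and pathway-averaged difference counts, built from scratch on
# the standard genetic code.
ng_oracle <- function(s1, s2, R = 2) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  bases <- c("A", "C", "G", "T")
  transition_of <- c(A = "G", C = "T", G = "A", T = "C")
  split_codons <- function(s) substring(s, seq(1, nchar(s), 3),
                                        seq(3, nchar(s), 3))
  c1 <- split_codons(s1); c2 <- split_codons(s2)
  keep <- gc[c1] != "*" & gc[c2] != "*" & !is.na(gc[c1]) & !is.na(gc[c2])
  c1 <- c1[keep]; c2 <- c2[keep]
  sites <- function(cod) {
    aa <- gc[cod]
    total_syn <- 0
    for (p in 1:3) {
      ref <- substr(cod, p, p)
      wden <- 0; wnum <- 0
      for (b in bases[bases != ref]) {
        mut <- paste0(substr(cod, 1, p - 1), b, substr(cod, p + 1, 3))
        if (gc[mut] == "*") next
        w <- if (b == transition_of[[ref]]) R else 1
        wden <- wden + w
        if (gc[mut] == aa) wnum <- wnum + w
      }
      if (wden > 0) total_syn <- total_syn + wnum / wden
    }
    c(total_syn, 3 - total_syn)
  }
  perms_of <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (k in seq_along(v)) {
      for (rest in perms_of(v[-k])) out[[length(out) + 1L]] <- c(v[k], rest)
    }
    out
  }
  diffs <- function(a, b) {
    pos <- which(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])
    if (!length(pos)) return(c(0, 0))
    walk <- function(order, allow_stop) {
      cur <- a; sd <- 0; nd <- 0
      for (p in order) {
        nxt <- paste0(substr(cur, 1, p - 1), substr(b, p, p),
                      substr(cur, p + 1, 3))
        if (!allow_stop && gc[nxt] == "*") return(NULL)
        if (gc[nxt] == gc[cur]) sd <- sd + 1 else nd <- nd + 1
        cur <- nxt
      }
      c(sd, nd)
    }
    paths <- lapply(perms_of(pos), walk, allow_stop = FALSE)
    paths <- paths[!vapply(paths, is.null, logical(1))]
    if (!length(paths)) paths <- lapply(perms_of(pos), walk, allow_stop = TRUE)
    colMeans(do.call(rbind, paths))
  }
  S <- 0; N <- 0; Sd <- 0; Nd <- 0
  for (i in seq_along(c1)) {
    sa <- sites(c1[i]); sb <- sites(c2[i])
    S <- S + (sa[1] + sb[1]) / 2
    N <- N + (sa[2] + sb[2]) / 2
    d <- diffs(c1[i], c2[i])
    Sd <- Sd + d[1]; Nd <- Nd + d[2]
  }
  pS <- if (S > 0) Sd / S else 0
  pN <- if (N > 0) Nd / N else 0
  jc <- function(p) -0.75 * log(1 - 4 * p / 3)
  list(S = S, N = N, Sd = Sd, Nd = Nd, pS = pS, pN = pN,
       dS = jc(pS), dN = jc(pN))
}

# Brute-force per-base depth recount.
depth_recount_oracle <- function(placements, interval) {
  v <- integer(interval$end - interval$start)
  for (r in seq_len(nrow(placements))) {
    if (placements$contig[r] != interval$contig_id) next
    s <- placements$start[r]
    e <- s + placements$read_length[r]
    lo <- max(s, interval$start); hi <- min(e, interval$end)
    if (hi > lo) {
      ix <- (lo - interval$start + 1L):(hi - interval$start)
      v[ix] <- v[ix] + 1L
    }
  }
  v
}

# All-pairs inverted-repeat scan (naive) mirroring the TIR definition.
tir_oracle <- function(seq, min_len, max_len, max_mismatch, window) {
  comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
  x <- strsplit(seq, "")[[1]]
  L <- length(x)
  for (len in seq(min(max_len, window), min_len)) {
    best <- NULL
    for (a in 0:(window - len)) {
      for (b in (L - window):(L - len)) {
        mm <- sum(x[b + len - (0:(len - 1))] != comp[x[a + (1:len)]])
        if (mm <= max_mismatch) {
          if (is.null(best) || mm < best$mm ||
              (mm == best$mm && (a < best$a || (a == best$a && b < best$b)))) {
            best <- list(a = a, b = b, mm = mm)
          }
        }
      }
    }
    if (!is.null(best)) {
      return(list(left_start = best$a, left_end = best$a + len,
                  right_start = best$b, right_end = best$b + len,
                  length = len, mismatches = best$mm))
    }
  }
  NULL
}

# Naive six-frame ORF scan by codon walking (ATG to stop, maximal).
orf_oracle <- function(seq, min_length_aa) {
  gc <- as.character(Biostrings::GENETIC_CODE)
  names(gc) <- names(Biostrings::GENETIC_CODE)
  rc <- function(s) {
    comp <- c(A = "T", C = "G", G = "C", T = "A", N = "N")
    paste(rev(comp[strsplit(s, "")[[1]]]), collapse = "")
  }
  L <- nchar(seq)
  out <- list()
  for (strand in c("+", "-")) {
    s <- if (strand == "+") seq else rc(seq)
    for (frame in 0:2) {
      ncod <- (L - frame) %/% 3
      if (ncod < 1) next
      cods <- substring(s, frame + 1 + 3 * (0:(ncod - 1)),
                        frame + 3 * (1:ncod))
      aas <- gc[cods]
      aas[is.na(aas)] <- "X"
      start_at <- NA
      for (k in seq_len(ncod)) {
        if (is.na(start_at) && aas[k] == "M") start_at <- k
        if (!is.na(start_at) && aas[k] == "*") {
          len_aa <- k - start_at
          if (len_aa >= min_length_aa) {
            aa_s <- start_at - 1L
            nt <- c(frame + 3 * aa_s, frame + 3 * k)
            if (strand == "-") nt <- c(L - nt[2], L - nt[1])
            out[[length(out) + 1L]] <- data.frame(
              start = nt[1], end = nt[2], strand = strand,
              length_aa = len_aa)
          }
          start_at <- NA
        }
      }
    }
  }
  if (!length(out)) return(data.frame(start = integer(0), end = integer(0),
                                      strand = character(0),
                                      length_aa = integer(0)))
  df <- do.call(rbind, out)
  df[order(df$start, df$end), , drop = FALSE]
}

# Single-linkage components by repeated flooding on a thresholded
# identity matrix.
cluster_oracle <- function(im, threshold) {
  n <- nrow(im)
  comp <- seq_len(n)
  repeat {
    changed <- FALSE
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && im[i, j] > threshold && comp[j] != comp[i]) {
          comp[comp == comp[j]] <- comp[i]
          changed <- TRUE
        }
      }
    }
    if (!changed) break
  }
  match(comp, unique(comp))
}
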