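# Synthetic genomes with planted Teratorn-like elements.
#
# The generator emulates the statistical structure the downstream analysis
# assumes: a host genome with single-copy CDSs, a viral element carrying an
# ordered gene set (optionally fused with a piggyBac-like transposase and
# bordered by TIRs), multicopy insertion at TTAA sites with target-site
# duplication, subtype structure, optional ORF degradation, and
# uniform-coverage error-bearing short reads.  Every operation records a
# truth table for parameter-recovery tests.

#' Names of the 13 alloherpesvirus core genes used for detection
#'
#' DNA polymerase (pol), DNA helicase (hel), primase (pri), major capsid
#' protein (mcp), capsid triplex protein (tri), membrane protein (mem),
#' DNA packaging terminase (ter), capsid maturation protease (pro) and
#' ORFs 37, 54, 56, 60 and 64.
#'
#' @return character vector of length 13.
#' @export
core_gene_names <- function() {
  c("pol", "hel", "pri", "mcp", "tri", "mem", "ter", "pro",
    "orf37", "orf54", "orf56", "orf60", "orf64")
}

#' Default viral gene catalog for the synthetic element
#'
#' The 13 core genes plus two accessory ORFs (orf34, orf44), optionally
#' with a piggyBac-like transposase (tpase).  Protein lengths are
#' deliberately scaled down from the full-length element so that
#' simulation studies run at desk scale; the relative ordering of gene
#' sizes follows the biology (capsid and polymerase genes largest).
#'
#' @param include_transposase add the tpase entry.
#' @param include_extra add the two accessory ORFs.
#' @param scale multiplier applied to all protein lengths.
#' @return data frame with columns name, aa_length.
#' @export
default_gene_catalog <- function(include_transposase = FALSE,
                                 include_extra = FALSE, scale = 1) {
  core <- data.frame(
    name = core_gene_names(),
    aa_length = c(300, 260, 220, 360, 240, 200, 260, 160,
                  180, 200, 160, 180, 220),
    stringsAsFactors = FALSE)
  if (include_extra) {
    core <- rbind(core, data.frame(name = c("orf34", "orf44"),
                                   aa_length = c(150, 150)))
  }
  if (include_transposase) {
    core <- rbind(core, data.frame(name = "tpase", aa_length = 220))
  }
  core$aa_length <- pmax(30L, as.integer(round(core$aa_length * scale)))
  core
}

# Uniform-codon back-translation of a protein (no terminal stop added).
back_translate <- function(protein) {
  aa <- strsplit(protein, "")[[1]]
  codons <- vapply(aa, function(a) {
    cands <- names(GENETIC_CODE_STD)[GENETIC_CODE_STD == a]
    if (length(cands) == 0L) stop("cannot back-translate residue: ", a)
    if (length(cands) == 1L) cands else sample(cands, 1L)
  }, character(1))
  paste(codons, collapse = "")
}

random_protein <- function(aa_length) {
  aa20 <- setdiff(unique(GENETIC_CODE_STD), "*")
  paste0("M", paste(sample(aa20, aa_length - 1L, replace = TRUE), collapse = ""))
}

# Random CDS: ATG + (aa_length - 1) random codons + one stop codon.
random_cds <- function(aa_length) {
  prot <- random_protein(aa_length)
  stop_codon <- sample(c("TAA", "TAG", "TGA"), 1L)
  list(protein = prot, cds = paste0(back_translate(prot), stop_codon))
}

#' Simulate a host genome with planted single-copy CDSs
#'
#' Nucleotides are i.i.d. at the stated GC fraction; host genes are
#' non-overlapping CDS intervals overwritten into the background and
#' recorded in the truth table.
#'
#' @param n_contigs number of contigs.
#' @param contig_length length of each contig in bp.
#' @param gc_fraction G+C fraction in (0, 1).
#' @param n_host_genes total number of host CDSs to plant.
#' @param seed integer seed; identical seeds reproduce identical output.
#' @param gene_length_aa range (min, max) of host protein lengths.
#' @return list with elements `genome` (named character vector) and
#'   `host_cds` (data frame contig_id, start, end, gene_id, strand;
#'   0-based half-open).
#' @export
simulate_host_genome <- function(n_contigs = 1L, contig_length = 1e6,
                                 gc_fraction = 0.5, n_host_genes = 20L,
                                 seed = 1L, gene_length_aa = c(200L, 400L)) {
  stopifnot(n_contigs >= 1L, gc_fraction > 0, gc_fraction < 1)
  max_gene_nt <- 3L * (max(gene_length_aa) + 1L)
  if (contig_length < 10L * max_gene_nt) {
    stop("contig_length must be at least 10x the longest planted gene (",
         10L * max_gene_nt, " bp)")
  }
  with_seed(seed, {
    contigs <- setNames(
      vapply(seq_len(n_contigs), function(i) rand_dna(contig_length, gc_fraction),
             character(1)),
      sprintf("contig_%02d", seq_len(n_contigs)))
    cds <- list()
    if (n_host_genes > 0L) {
      per_contig <- tabulate(rep_len(seq_len(n_contigs), n_host_genes),
                             nbins = n_contigs)
      g <- 0L
      for (ci in seq_len(n_contigs)) {
        placed <- integer(0)  # interleaved starts/ends
        occupied <- data.frame(start = integer(0), end = integer(0))
        for (k in seq_len(per_contig[ci])) {
          aa <- sample(seq(gene_length_aa[1], gene_length_aa[2]), 1L)
          len <- 3L * (aa + 1L)
          ok <- FALSE
          for (try in 1:1000) {
            s <- sample.int(contig_length - len, 1L) - 1L
            e <- s + len
            if (!any(s < occupied$end & e > occupied$start)) { ok <- TRUE; break }
          }
          if (!ok) stop("placement failure: too many host genes for contig length")
          g <- g + 1L
          strand <- sample(c("+", "-"), 1L)
          cdsk <- random_cds(aa)$cds
          ins <- if (strand == "+") cdsk else revcomp(cdsk)
          substr(contigs[[ci]], s + 1L, e) <- ins
          occupied <- rbind(occupied, data.frame(start = s, end = e))
          cds[[g]] <- data.frame(contig_id = names(contigs)[ci], start = s,
                                 end = e, gene_id = sprintf("host_%03d", g),
                                 strand = strand, stringsAsFactors = FALSE)
        }
      }
    }
    host_cds <- if (length(cds)) do.call(rbind, cds) else
      data.frame(contig_id = character(0), start = integer(0),
                 end = integer(0), gene_id = character(0),
                 strand = character(0), stringsAsFactors = FALSE)
    list(genome = genome_assembly(contigs), host_cds = host_cds)
  })
}

#' Build a synthetic Teratorn-like element template
#'
#' CDSs are uniform-codon back-translations of random proteins of the
#' catalog lengths, separated by i.i.d. intergenic spacers and optionally
#' bordered by terminal inverted repeats.  When the transposase is placed
#' internally its ordered neighbors are orf60 and orf54; when placed at
#' the edge it is the first gene of the element.
#'
#' @param gene_catalog data frame (name, aa_length); see
#'   [default_gene_catalog()].
#' @param transposase_placement one of "internal", "edge", "absent".
#' @param tir_length TIR length in bp (0 for no TIRs).
#' @param spacer_length intergenic spacer length in bp.
#' @param seed integer seed.
#' @return an object of class `element_template`: list with `seq`,
#'   `genes` (data frame name, start, end, strand, aa_length, protein,
#'   cds; element-local 0-based half-open coordinates), `tir` (list or
#'   NULL), `transposase_placement`, `total_length`.
#' @export
build_viral_element <- function(gene_catalog = default_gene_catalog(),
                                transposase_placement = c("internal", "edge", "absent"),
                                tir_length = 13L, spacer_length = 100L,
                                seed = 1L) {
  transposase_placement <- match.arg(transposase_placement)
  stopifnot(is.data.frame(gene_catalog),
            all(c("name", "aa_length") %in% names(gene_catalog)))
  has_tp <- "tpase" %in% gene_catalog$name
  if (transposase_placement != "absent" && !has_tp) {
    gene_catalog <- rbind(gene_catalog,
                          data.frame(name = "tpase", aa_length = 220L))
  }
  if (transposase_placement == "internal" &&
      !all(c("orf60", "orf54") %in% gene_catalog$name)) {
    stop("internal transposase placement requires orf60 and orf54 in the catalog")
  }
  nm <- gene_catalog$name
  order_names <- switch(transposase_placement,
    internal = c(setdiff(nm, c("orf60", "tpase", "orf54")),
                 "orf60", "tpase", "orf54"),
    edge = c("tpase", setdiff(nm, "tpase")),
    absent = setdiff(nm, "tpase"))
  cat_ord <- gene_catalog[match(order_names, gene_catalog$name), , drop = FALSE]

  with_seed(seed, {
    pieces <- character(0)
    genes <- list()
    pos <- 0L
    tir <- NULL
    if (tir_length > 0L) {
      left <- rand_dna(tir_length)
      pieces <- c(pieces, left)
      tir <- list(left_seq = left, right_seq = revcomp(left))
      pos <- pos + tir_length
    }
    for (i in seq_len(nrow(cat_ord))) {
      sp <- rand_dna(spacer_length)
      pieces <- c(pieces, sp)
      pos <- pos + spacer_length
      rc <- random_cds(cat_ord$aa_length[i])
      strand <- if (cat_ord$name[i] %in% c("tpase", "orf60", "orf54")) "+"
                else sample(c("+", "-"), 1L, prob = c(0.7, 0.3))
      ins <- if (strand == "+") rc$cds else revcomp(rc$cds)
      pieces <- c(pieces, ins)
      genes[[i]] <- data.frame(name = cat_ord$name[i], start = pos,
                               end = pos + nchar(rc$cds), strand = strand,
                               aa_length = cat_ord$aa_length[i],
                               protein = rc$protein, cds = rc$cds,
                               stringsAsFactors = FALSE)
      pos <- pos + nchar(rc$cds)
    }
    pieces <- c(pieces, rand_dna(spacer_length))
    pos <- pos + spacer_length
    if (!is.null(tir)) {
      pieces <- c(pieces, tir$right_seq)
      tir$left_start <- 0L
      tir$left_end <- tir_length
      tir$right_start <- pos
      tir$right_end <- pos + tir_length
      pos <- pos + tir_length
    }
    structure(list(seq = paste(pieces, collapse = ""),
                   genes = do.call(rbind, genes),
                   tir = tir,
                   transposase_placement = transposase_placement,
                   total_length = pos),
              class = "element_template")
  })
}

#' Protein queries from an element template
#'
#' @param template an `element_template`.
#' @param genes optional subset of gene names.
#' @return named character vector of protein sequences, suitable as
#'   queries for [search_genome()].
#' @export
element_queries <- function(template, genes = NULL) {
  df <- template$genes
  if (!is.null(genes)) df <- df[df$name %in% genes, , drop = FALSE]
  setNames(df$protein, df$name)
}

# K2P per-site substitution probabilities at branch length d (subs/site)
# and transition:transversion count ratio R (alpha/(2 beta)).
k2p_site_probs <- function(branch_length, ts_tv_ratio) {
  beta_t <- branch_length / (2 * ts_tv_ratio + 2)
  alpha_t <- 2 * ts_tv_ratio * beta_t
  p_ts <- 0.25 + 0.25 * exp(-4 * beta_t) - 0.5 * exp(-2 * (alpha_t + beta_t))
  p_tv <- 0.5 - 0.5 * exp(-4 * beta_t)  # total over both transversions
  c(ts = p_ts, tv = p_tv)
}

#' Evolve a nucleotide sequence under the Kimura 2-parameter process
#'
#' Each site is substituted independently with the exact K2P transition
#' probabilities for the requested branch length and
#' transition:transversion count bias R (at R = 2 substitutions are
#' twice as often transitions as transversions, matching the bias
#' assumed by the divergence estimators downstream).
#'
#' @param seq nucleotide string (N sites are left unchanged).
#' @param branch_length expected substitutions per site (>= 0).
#' @param ts_tv_ratio transition:transversion count ratio R.
#' @param seed integer seed.
#' @return the evolved nucleotide string.
#' @export
evolve_sequence <- function(seq, branch_length, ts_tv_ratio = 2, seed = 1L) {
  if (branch_length < 0) stop("branch_length must be non-negative")
  if (branch_length == 0) return(seq)
  pr <- k2p_site_probs(branch_length, ts_tv_ratio)
  with_seed(seed, {
    x <- strsplit(seq, "")[[1]]
    n <- length(x)
    u <- runif(n)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tv1 <- c(A = "C", G = "C", C = "A", T = "A")
    tv2 <- c(A = "T", G = "T", C = "G", T = "G")
    base <- x %in% DNA_BASES
    do_ts <- base & u < pr["ts"]
    do_tv <- base & !do_ts & u < pr["ts"] + pr["tv"]
    x[do_ts] <- ts_map[x[do_ts]]
    pick2 <- runif(sum(do_tv)) < 0.5
    x[do_tv] <- ifelse(pick2, tv1[x[do_tv]], tv2[x[do_tv]])
    paste(x, collapse = "")
  })
}

# Expected acceptance fraction of proposed K2P substitutions on a CDS
# under purifying selection: synonymous accepted, nonsense rejected,
# missense accepted with probability omega.
cds_accept_fraction <- function(cds, ts_tv_ratio, omega) {
  codons <- codon_split(cds)
  p_ts <- 2 * ts_tv_ratio / (2 * ts_tv_ratio + 2)
  p_tv_each <- 1 / (2 * ts_tv_ratio + 2)
  ts_map <- c(A = "G", G = "A", C = "T", T = "C")
  tot <- 0
  n_pos <- 0L
  for (cd in unique(codons)) {
    aa0 <- GENETIC_CODE_STD[cd]
    if (is.na(aa0) || aa0 == "*") next
    w <- sum(codons == cd)
    for (j in 1:3) {
      ref <- substr(cd, j, j)
      for (b in setdiff(DNA_BASES, ref)) {
        mut <- cd
        substr(mut, j, j) <- b
        aa1 <- GENETIC_CODE_STD[mut]
        acc <- if (aa1 == "*") 0 else if (aa1 == aa0) 1 else omega
        p <- if (b == ts_map[ref]) p_ts else p_tv_each
        tot <- tot + w * p * acc
      }
      n_pos <- n_pos + w
    }
  }
  if (n_pos == 0L) return(1)
  tot / n_pos
}

#' Evolve a coding sequence under K2P mutation with purifying selection
#'
#' Substitution events are proposed sequentially under the K2P process
#' and accepted according to their coding effect: synonymous changes are
#' always accepted, nonsense changes never, and missense changes with
#' probability `omega` (10-fold suppression at the default 0.1).  The
#' proposal rate is inflated so that the expected number of accepted
#' substitutions per site equals `branch_length`.  The initial ATG and
#' the terminal stop codon are held fixed.
#'
#' @param cds in-frame coding sequence (ATG...stop).
#' @param branch_length target accepted substitutions per site.
#' @param ts_tv_ratio transition:transversion count ratio R.
#' @param omega missense acceptance probability in [0, 1].
#' @param seed integer seed.
#' @return the evolved coding sequence (same length, still stop-free
#'   internally).
#' @export
evolve_cds <- function(cds, branch_length, ts_tv_ratio = 2, omega = 0.1,
                       seed = 1L) {
  if (branch_length < 0) stop("branch_length must be non-negative")
  if (branch_length == 0) return(cds)
  n <- nchar(cds)
  if (n %% 3L != 0L) stop("cds length not divisible by 3")
  f_acc <- cds_accept_fraction(cds, ts_tv_ratio, omega)
  if (f_acc <= 0) return(cds)
  with_seed(seed, {
    x <- strsplit(cds, "")[[1]]
    n_codon <- n %/% 3L
    mutable <- if (n_codon > 2L) 4L:(n - 3L) else integer(0)
    if (!length(mutable)) return(cds)
    n_events <- rpois(1L, length(mutable) * branch_length / f_acc)
    if (n_events == 0L) return(cds)
    p_ts <- 2 * ts_tv_ratio / (2 * ts_tv_ratio + 2)
    ts_map <- c(A = "G", G = "A", C = "T", T = "C")
    tvs <- list(A = c("C", "T"), G = c("C", "T"),
                C = c("A", "G"), T = c("A", "G"))
    sites <- sample(mutable, n_events, replace = TRUE)
    kinds <- runif(n_events)
    for (e in seq_len(n_events)) {
      i <- sites[e]
      ref <- x[i]
      if (!ref %in% DNA_BASES) next
      b <- if (kinds[e] < p_ts) ts_map[[ref]] else sample(tvs[[ref]], 1L)
      ci <- (i - 1L) %/% 3L
      cod <- paste(x[(ci * 3L + 1L):(ci * 3L + 3L)], collapse = "")
      aa0 <- GENETIC_CODE_STD[cod]
      mut <- cod
      substr(mut, (i - 1L) %% 3L + 1L, (i - 1L) %% 3L + 1L) <- b
      aa1 <- GENETIC_CODE_STD[mut]
      if (is.na(aa1) || aa1 == "*") next
      if (aa1 == aa0 || runif(1L) < omega) x[i] <- b
    }
    paste(x, collapse = "")
  })
}

# Evolve a full element sequence: CDS regions under purifying selection,
# intergenic regions (and left TIR) neutrally; the right TIR is kept as
# the reverse complement of the evolved left TIR, as transposition
# requires complementary termini.
evolve_element <- function(seq, genes, tir, branch_length, ts_tv_ratio = 2,
                           omega = 0.1, seed = 1L) {
  if (branch_length == 0) return(seq)
  with_seed(seed, {
    out <- evolve_sequence(seq, branch_length, ts_tv_ratio,
                           seed = sample.int(2^31 - 2, 1L))
    for (i in seq_len(nrow(genes))) {
      s <- genes$start[i]; e <- genes$end[i]
      cds <- substr(seq, s + 1L, e)
      if (genes$strand[i] == "-") cds <- revcomp(cds)
      ev <- evolve_cds(cds, branch_length, ts_tv_ratio, omega,
                       seed = sample.int(2^31 - 2, 1L))
      if (genes$strand[i] == "-") ev <- revcomp(ev)
      substr(out, s + 1L, e) <- ev
    }
    if (!is.null(tir)) {
      left <- substr(out, tir$left_start + 1L, tir$left_end)
      substr(out, tir$right_start + 1L, tir$right_end) <- revcomp(left)
    }
    out
  })
}

# Apply degradation to a copy sequence: a premature stop (codon replaced
# by TAA at the CDS midpoint) or a 1-bp deletion at the CDS midpoint.
degrade_copy <- function(seq, genes, gene_name, mode = c("stop", "frameshift")) {
  mode <- match.arg(mode)
  g <- genes[genes$name == gene_name, , drop = FALSE]
  if (nrow(g) != 1L) stop("unknown gene for degradation: ", gene_name)
  n_codon <- (g$end - g$start) %/% 3L
  mid_codon <- n_codon %/% 2L
  if (g$strand == "+") {
    pos <- g$start + 3L * mid_codon  # 0-based start of midpoint codon
    if (mode == "stop") {
      substr(seq, pos + 1L, pos + 3L) <- "TAA"
      seq
    } else {
      paste0(substr(seq, 1L, pos), substr(seq, pos + 2L, nchar(seq)))
    }
  } else {
    # midpoint codon of the minus-strand CDS, in forward coordinates
    pos <- g$end - 3L * (mid_codon + 1L)
    if (mode == "stop") {
      substr(seq, pos + 1L, pos + 3L) <- "TTA"  # revcomp of TAA
      seq
    } else {
      paste0(substr(seq, 1L, pos), substr(seq, pos + 2L, nchar(seq)))
    }
  }
}

#' Insert evolved element copies into a genome at TTAA sites
#'
#' Each subtype descends from an ancestor evolved from the template by
#' `between_divergence` substitutions/site; each copy further diverges by
#' `within_divergence / 2`, so within-subtype pairwise divergence is
#' approximately `within_divergence` and between-subtype divergence
#' approximately the sum of the two subtype branches.  Copies are
#' inserted at TTAA sites with target-site duplication, so every copy is
#' flanked by TTAA on both sides.  Degraded copies receive a premature
#' stop or a 1-bp frameshift deletion at the midpoint of one viral CDS.
#'
#' @param genome named character vector of contigs.
#' @param template an `element_template`.
#' @param subtype_spec data frame with columns n_copies,
#'   between_divergence, within_divergence (one row per subtype).
#' @param degrade character vector of copy ids (e.g. "s1c2") to degrade.
#' @param degrade_mode "stop" or "frameshift", recycled over `degrade`.
#' @param host_cds optional host CDS intervals to avoid when choosing
#'   insertion sites.
#' @param min_spacing minimum distance in bp between insertion sites on
#'   one contig.
#' @param omega missense acceptance probability for CDS evolution.
#' @param ts_tv_ratio transition:transversion count ratio R.
#' @param seed integer seed.
#' @return list with `genome` (post-insertion assembly), `truth` (data
#'   frame: contig_id, position (pre-insertion element start),
#'   final_start, final_end, subtype, copy_id, degraded, degrade_mode,
#'   degraded_gene, tsd, length) and `copies` (named character vector of
#'   inserted copy sequences).
#' @export
insert_element_copies <- function(genome, template, subtype_spec,
                                  degrade = character(0),
                                  degrade_mode = "stop",
                                  host_cds = NULL, min_spacing = 0L,
                                  omega = 0.1, ts_tv_ratio = 2, seed = 1L) {
  subtype_spec <- as.data.frame(subtype_spec)
  stopifnot(all(c("n_copies", "between_divergence", "within_divergence")
                %in% names(subtype_spec)))
  with_seed(seed, {
    # grow copy sequences
    copies <- list()
    meta <- list()
    dm <- rep_len(degrade_mode, max(1L, length(degrade)))
    for (s in seq_len(nrow(subtype_spec))) {
      anc <- evolve_element(template$seq, template$genes, template$tir,
                            subtype_spec$between_divergence[s],
                            ts_tv_ratio, omega,
                            seed = sample.int(2^31 - 2, 1L))
      for (k in seq_len(subtype_spec$n_copies[s])) {
        cid <- sprintf("s%dc%d", s, k)
        cp <- evolve_element(anc, template$genes, template$tir,
                             subtype_spec$within_divergence[s] / 2,
                             ts_tv_ratio, omega,
                             seed = sample.int(2^31 - 2, 1L))
        deg <- cid %in% degrade
        dgene <- NA_character_
        dmode <- NA_character_
        if (deg) {
          dmode <- dm[match(cid, degrade)]
          viral <- setdiff(template$genes$name, "tpase")
          dgene <- viral[1L]
          cp <- degrade_copy(cp, template$genes, dgene, dmode)
        }
        copies[[cid]] <- cp
        meta[[cid]] <- data.frame(subtype = sprintf("subtype_%d", s),
                                  copy_id = cid, degraded = deg,
                                  degrade_mode = dmode,
                                  degraded_gene = dgene,
                                  length = nchar(cp),
                                  stringsAsFactors = FALSE)
      }
    }
    copy_ids <- names(copies)
    n_total <- length(copy_ids)

    # choose TTAA sites on the pre-insertion genome
    sites <- list()
    for (cn in names(genome)) {
      m <- gregexpr("TTAA", genome[[cn]], fixed = TRUE)[[1]]
      pos <- if (m[1] == -1) integer(0) else as.integer(m) - 1L  # 0-based
      if (!is.null(host_cds)) {
        hc <- host_cds[host_cds$contig_id == cn, , drop = FALSE]
        if (nrow(hc)) {
          bad <- vapply(pos, function(p)
            any(p < hc$end & (p + 4L) > hc$start), logical(1))
          pos <- pos[!bad]
        }
      }
      sites[[cn]] <- pos
    }
    avail <- vapply(sites, length, integer(1))
    if (all(avail == 0L)) {
      stop("no TTAA site available on contig ", names(genome)[1])
    }
    # assign copies to contigs proportional to available sites
    contig_of <- sample(names(genome), n_total, replace = TRUE,
                        prob = avail / sum(avail))
    chosen <- list()
    for (cn in unique(contig_of)) {
      need <- sum(contig_of == cn)
      pos <- sort(sites[[cn]])
      if (length(pos) == 0L) stop("no TTAA site available on contig ", cn)
      picked <- NULL
      for (try in 1:25) {  # greedy random packing; retry on dead ends
        sel <- integer(0)
        cand <- pos
        while (length(sel) < need && length(cand)) {
          p <- sample(cand, 1L)
          sel <- c(sel, p)
          cand <- cand[abs(cand - p) >= max(min_spacing, 4L)]
        }
        if (length(sel) == need) { picked <- sel; break }
      }
      if (is.null(picked)) {
        stop("not enough spaced TTAA sites on contig ", cn)
      }
      chosen[[cn]] <- sort(picked)
    }
    # build truth rows: assign copies to chosen sites in order
    truth <- list()
    idx <- 1L
    for (cn in names(chosen)) {
      ids_here <- copy_ids[contig_of == cn]
      for (j in seq_along(chosen[[cn]])) {
        cid <- ids_here[j]
        p <- chosen[[cn]][j]  # TTAA starts at p (0-based)
        truth[[idx]] <- cbind(
          data.frame(contig_id = cn, position = p + 4L,
                     stringsAsFactors = FALSE),
          meta[[cid]][, c("subtype", "copy_id", "degraded", "degrade_mode",
                          "degraded_gene", "length")])
        idx <- idx + 1L
      }
    }
    truth <- do.call(rbind, truth)
    truth$tsd <- "TTAA"

    # perform insertions, descending position per contig, and compute
    # final coordinates by ascending offset
    truth$final_start <- NA_integer_
    truth$final_end <- NA_integer_
    out <- genome
    for (cn in unique(truth$contig_id)) {
      rows <- which(truth$contig_id == cn)
      rows <- rows[order(truth$position[rows])]
      offset <- 0L
      seq0 <- out[[cn]]
      pieces <- character(0)
      last <- 0L
      for (r in rows) {
        p <- truth$position[r]  # element begins here pre-insertion
        cp <- copies[[truth$copy_id[r]]]
        pieces <- c(pieces, substr(seq0, last + 1L, p), cp, "TTAA")
        truth$final_start[r] <- p + offset
        truth$final_end[r] <- p + offset + nchar(cp)
        offset <- offset + nchar(cp) + 4L
        last <- p
      }
      pieces <- c(pieces, substr(seq0, last + 1L, nchar(seq0)))
      out[[cn]] <- paste(pieces, collapse = "")
    }
    host_cds_shifted <- if (is.null(host_cds)) NULL else
      shift_intervals(host_cds, truth)
    list(genome = genome_assembly(out), truth = truth,
         copies = unlist(copies), host_cds = host_cds_shifted)
  })
}

#' Shift pre-insertion intervals to post-insertion coordinates
#'
#' Each interval moves right by the total length (element + one extra
#' TSD) of all insertions at or before its start on the same contig.
#' Intervals are assumed not to span an insertion site (the generator
#' avoids host CDSs when placing elements).
#'
#' @param intervals data frame with contig_id, start, end (0-based
#'   half-open, pre-insertion).
#' @param truth insertion truth table from [insert_element_copies()].
#' @return the intervals with shifted start/end.
#' @export
shift_intervals <- function(intervals, truth) {
  out <- intervals
  for (i in seq_len(nrow(out))) {
    tr <- truth[truth$contig_id == out$contig_id[i] &
                  truth$position <= out$start[i], , drop = FALSE]
    off <- sum(tr$length + 4L)
    out$start[i] <- out$start[i] + off
    out$end[i] <- out$end[i] + off
  }
  out
}

#' Simulate uniform-coverage single-end short reads
#'
#' Read start positions are uniform over each contig, strands
#' equiprobable, with i.i.d. substitution errors and a fixed quality
#' string.  The read count per contig is `mean_depth * length /
#' read_length` (rounded).
#'
#' @param genome named character vector of contigs.
#' @param mean_depth target fold-coverage (> 0).
#' @param read_length read length in bp (at most the shortest contig).
#' @param error_rate per-base substitution error probability.
#' @param seed integer seed.
#' @return named character vector of read sequences (names encode the
#'   read id); write with [write_fastq()].
#' @export
simulate_reads <- function(genome, mean_depth, read_length = 100L,
                           error_rate = 0.005, seed = 1L) {
  if (mean_depth <= 0) stop("mean_depth must be positive")
  if (read_length > min(nchar(genome))) {
    stop("read_length exceeds the shortest contig")
  }
  with_seed(seed, {
    all_reads <- character(0)
    for (cn in names(genome)) {
      L <- nchar(genome[[cn]])
      n_reads <- as.integer(round(mean_depth * L / read_length))
      if (n_reads == 0L) next
      starts <- sample.int(L - read_length + 1L, n_reads, replace = TRUE)
      seqs <- substring(genome[[cn]], starts, starts + read_length - 1L)
      rc <- runif(n_reads) < 0.5
      if (any(rc)) {
        seqs[rc] <- as.character(Biostrings::reverseComplement(
          Biostrings::DNAStringSet(seqs[rc])))
      }
      if (error_rate > 0) {
        n_err <- rbinom(n_reads, read_length, error_rate)
        for (i in which(n_err > 0L)) {
          pp <- sample.int(read_length, n_err[i])
          for (p in pp) {
            ref <- substr(seqs[i], p, p)
            substr(seqs[i], p, p) <- sample(setdiff(DNA_BASES, ref), 1L)
          }
        }
      }
      names(seqs) <- sprintf("%s_read_%06d", cn, seq_len(n_reads))
      all_reads <- c(all_reads, seqs)
    }
    all_reads
  })
}

#' Evolve a sequence down a phylogeny
#'
#' The root sequence evolves along every branch of `tree` under the K2P
#' process; coding regions, when `genes` is supplied, evolve under
#' purifying selection as in [evolve_cds()].  Used to co-simulate gene
#' histories sharing one topology (e.g. transposase and viral genes of
#' co-inherited elements).
#'
#' @param seq root nucleotide sequence.
#' @param tree an `ape::phylo` tree with branch lengths in
#'   substitutions/site.
#' @param genes optional gene table as in an `element_template` (CDS
#'   regions then evolve under selection).
#' @param tir optional TIR description (kept complementary).
#' @param omega missense acceptance probability.
#' @param ts_tv_ratio transition:transversion count ratio R.
#' @param seed integer seed.
#' @return named character vector of tip sequences (names = tip labels).
#' @export
evolve_along_tree <- function(seq, tree, genes = NULL, tir = NULL,
                              omega = 0.1, ts_tv_ratio = 2, seed = 1L) {
  stopifnot(inherits(tree, "phylo"))
  with_seed(seed, {
    n_tip <- length(tree$tip.label)
    root <- n_tip + 1L
    node_seq <- vector("list", n_tip + tree$Nnode)
    node_seq[[root]] <- seq
    # traverse edges parent->child in preorder
    eo <- ape::reorder.phylo(tree, "cladewise")
    for (k in seq_len(nrow(eo$edge))) {
      par <- eo$edge[k, 1]; chl <- eo$edge[k, 2]
      bl <- eo$edge.length[k]
      s0 <- node_seq[[par]]
      node_seq[[chl]] <- if (is.null(genes)) {
        evolve_sequence(s0, bl, ts_tv_ratio, seed = sample.int(2^31 - 2, 1L))
      } else {
        evolve_element(s0, genes, tir, bl, ts_tv_ratio, omega,
                       seed = sample.int(2^31 - 2, 1L))
      }
    }
    setNames(unlist(node_seq[seq_len(n_tip)]), tree$tip.label)
  })
}
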