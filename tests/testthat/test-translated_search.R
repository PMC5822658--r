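test_that("six-frame translation and coordinate maps are exact", {
  expect_error(six_frame_translate("AT"), "at least 3")
  fr <- six_frame_translate("ATGGCC")
  f0 <- fr[fr$strand == "+" & fr$frame == 0, ]
  expect_identical(f0$protein, "MA")

  # reverse strand of CAT frame 0 is ATG -> M
  fr2 <- six_frame_translate("CAT")
  expect_identical(fr2[fr2$strand == "-" & fr2$frame == 0, "protein"], "M")

  # coordinate map round-trip and monotonicity on a random contig
  set.seed(11)
  ctg <- teratornscan:::rand_dna(3000)
  L <- nchar(ctg)
  fr3 <- six_frame_translate(ctg)
  for (r in seq_len(nrow(fr3))) {
    np <- nchar(fr3$protein[r])
    starts <- vapply(seq_len(np) - 1L, function(i)
      frame_aa_to_genome(L, fr3$strand[r], fr3$frame[r], i, i + 1L)[1],
      numeric(1))
    if (fr3$strand[r] == "+") {
      expect_true(all(diff(starts) == 3))
    } else {
      expect_true(all(diff(starts) == -3))
    }
    # round trip: translating the mapped codon reproduces the residue
    i <- np %/% 2L
    nt <- frame_aa_to_genome(L, fr3$strand[r], fr3$frame[r], i, i + 1L)
    codon <- substr(ctg, nt[1] + 1L, nt[2])
    if (fr3$strand[r] == "-") codon <- revcomp(codon)
    expect_identical(teratornscan:::translate_nt(codon),
                     substr(fr3$protein[r], i + 1L, i + 1L))
  }
})

test_that("Karlin-Altschul E-values behave as the closed form", {
  expect_error(estimate_evalue(10, -1, 100), "positive")
  e1 <- estimate_evalue(40, 300, 1e6)
  expect_equal(e1, 0.134 * 300 * 1e6 * exp(-0.3176 * 40))
  # linear in database size
  expect_equal(estimate_evalue(40, 300, 2e6), 2 * e1)
  # strictly decreasing in score, to zero
  scores <- seq(10, 200, by = 10)
  ev <- estimate_evalue(scores, 300, 1e6)
  expect_true(all(diff(ev) < 0))
  expect_lt(estimate_evalue(1e4, 300, 1e6), 1e-300)
})

test_that("a planted ORF is recovered exactly on both strands", {
  set.seed(21)
  prot <- teratornscan:::random_protein(120)
  cds <- teratornscan:::back_translate(prot)
  left <- teratornscan:::rand_dna(1500)
  right <- teratornscan:::rand_dna(1500)
  gplus <- c(ctg = paste0(left, cds, right))
  hits <- search_genome(c(gene = prot), gplus)
  expect_gte(nrow(hits), 1L)
  top <- hits[1, ]
  expect_identical(top$strand, "+")
  expect_equal(top$nt_start, 1500)
  expect_equal(top$nt_end, 1500 + nchar(cds))
  expect_equal(top$aligned_identity, 1.0)

  gminus <- c(ctg = revcomp(gplus[[1]]))
  hits2 <- search_genome(c(gene = prot), gminus)
  top2 <- hits2[1, ]
  expect_identical(top2$strand, "-")
  # same interval mirrored through the contig length
  Lc <- nchar(gminus[[1]])
  expect_equal(top2$nt_start, Lc - top$nt_end)
  expect_equal(top2$nt_end, Lc - top$nt_start)
  expect_equal(top2$raw_score, top$raw_score)
  expect_error(search_genome(c(g = "MK"), gplus), "word_size")
})

test_that("the E-value cutoff excludes weak hits", {
  set.seed(33)
  # a short degenerate query yields a weak hit whose E-value sits
  # between 1e-3 and a permissive cutoff
  prot <- teratornscan:::random_protein(30)
  cds <- teratornscan:::back_translate(prot)
  g <- c(ctg = paste0(teratornscan:::rand_dna(2000),
                      cds, teratornscan:::rand_dna(2000)))
  mut <- prot
  for (p in seq(3, 27, by = 3)) {
    substr(mut, p, p) <- sample(setdiff(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]],
                                        substr(mut, p, p)), 1)
  }
  loose <- search_genome(c(q = mut), g,
                         search_params(evalue_keep = 1e6,
                                       ungapped_trigger = 15))
  expect_gte(nrow(loose), 1L)
  ev <- loose$evalue[1]
  strict_cut <- ev / 10
  strict <- search_genome(c(q = mut), g,
                          search_params(evalue_keep = strict_cut,
                                        ungapped_trigger = 15))
  expect_false(any(strict$evalue >= strict_cut))
  expect_false(loose$raw_score[1] %in% strict$raw_score)
})

test_that("best-hit raw scores equal full Smith-Waterman on small instances", {
  submat <- teratornscan:::blosum62_matrix()
  set.seed(55)
  for (case in 1:8) {
    qlen <- sample(40:100, 1)
    prot <- teratornscan:::random_protein(qlen)
    cds <- teratornscan:::back_translate(prot)
    ctg <- paste0(teratornscan:::rand_dna(600), cds,
                  teratornscan:::rand_dna(600))
    # mutate the query so the alignment is non-trivial
    q <- prot
    for (p in sample(seq_len(qlen), ceiling(qlen / 8))) {
      substr(q, p, p) <- sample(strsplit("ARNDCQEGHILKMFPSTWYV", "")[[1]], 1)
    }
    hits <- search_genome(c(q = q), c(ctg = ctg),
                          search_params(evalue_keep = 1e6))
    expect_gte(nrow(hits), 1L)
    frames <- six_frame_translate(ctg)
    oracle <- max(vapply(frames$protein, function(s)
      sw_score_oracle(q, s, submat, -11, -1), numeric(1)))
    expect_equal(max(hits$raw_score), oracle)
  }
})

test_that("search is strand-symmetric and clean on null sequence", {
  set.seed(77)
  q <- teratornscan:::random_protein(150)
  g <- c(ctg = teratornscan:::rand_dna(3e5))
  hits <- search_genome(c(q = q), g)
  # null calibration: essentially no hits below 1e-3 on random sequence
  expect_lte(nrow(hits), 1L)

  cds <- teratornscan:::back_translate(q)
  g2 <- c(ctg = paste0(teratornscan:::rand_dna(5000), cds,
                       teratornscan:::rand_dna(5000)))
  h_fwd <- search_genome(c(q = q), g2)
  h_rev <- search_genome(c(q = q), c(ctg = revcomp(g2[[1]])))
  expect_equal(nrow(h_fwd), nrow(h_rev))
  Lc <- nchar(g2[[1]])
  expect_setequal(h_rev$nt_start, Lc - h_fwd$nt_end)
  expect_setequal(h_rev$raw_score, h_fwd$raw_score)
})
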