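test_that("ORF calling finds planted genes at exact coordinates", {
  set.seed(81)
  rc <- teratornscan:::random_cds(300)
  # in-frame stop just upstream so the planted ATG is the maximal start
  left <- paste0(teratornscan:::rand_dna(497), "TAA")
  right <- teratornscan:::rand_dna(500)
  seq <- paste0(left, rc$cds, right)
  orfs <- call_orfs(seq, min_length_aa = 250)
  expect_equal(nrow(orfs), 1L)
  expect_equal(orfs$start, 500)
  expect_equal(orfs$end, 500 + nchar(rc$cds))
  expect_identical(orfs$strand, "+")
  expect_identical(orfs$protein, rc$protein)

  expect_equal(nrow(call_orfs(paste(rep("C", 500), collapse = ""), 10)), 0L)
})

test_that("ORF calling matches the naive six-frame oracle", {
  set.seed(83)
  for (case in 1:3) {
    seq <- teratornscan:::rand_dna(3000)
    got <- call_orfs(seq, min_length_aa = 20)
    want <- orf_oracle(seq, 20)
    expect_equal(nrow(got), nrow(want))
    expect_equal(got$start, want$start)
    expect_equal(got$end, want$end)
    expect_identical(got$strand, want$strand)

    # strand symmetry: ORFs of the reverse complement mirror-map
    L <- nchar(seq)
    rc_orfs <- call_orfs(revcomp(seq), min_length_aa = 20)
    expect_equal(sort(L - got$end), sort(rc_orfs$start))
  }
})

test_that("TIR detection recovers a planted repeat and matches brute force", {
  set.seed(87)
  tir <- "CCCTAGAAATTGC"
  mid <- teratornscan:::rand_dna(1500)
  el <- paste0(tir, mid, revcomp(tir))
  hit <- find_tirs(el, min_len = 10, max_len = 40, max_mismatch = 0,
                   window = 100)
  expect_false(is.null(hit))
  expect_equal(hit$left_start, 0L)
  expect_equal(hit$left_end, nchar(tir))
  expect_equal(hit$right_end, nchar(el))
  expect_equal(hit$mismatches, 0L)

  # null model: random sequence rarely carries a 10+ bp exact TIR
  nulls <- vapply(1:20, function(s) {
    set.seed(s + 500)
    !is.null(find_tirs(teratornscan:::rand_dna(1500), 10, 40, 0, 150))
  }, logical(1))
  expect_lte(sum(nulls), 1L)

  # exhaustive all-pairs oracle on 2-kb toys, with and without planted TIRs
  for (case in 1:4) {
    set.seed(case + 900)
    base <- teratornscan:::rand_dna(2000)
    seq <- if (case %% 2 == 0) {
      t <- teratornscan:::rand_dna(12)
      paste0(substr(base, 1, 30), t, substr(base, 31, 1950),
             revcomp(t), substr(base, 1951, 2000))
    } else base
    got <- find_tirs(seq, 8, 30, 1, 120)
    want <- tir_oracle(seq, 8, 30, 1, 120)
    if (is.null(want)) {
      expect_null(got)
    } else {
      expect_equal(got$left_start, want$left_start)
      expect_equal(got$right_start, want$right_start)
      expect_equal(got$length, want$length)
      expect_equal(got$mismatches, want$mismatches)
    }
  }
  expect_error(find_tirs("ACGT", window = 200), "window")
})

test_that("TSD detection requires an exact duplicated 4-mer", {
  ctg <- paste0(strrep("C", 10), "TTAA", strrep("G", 10), "TTAA",
                strrep("C", 10))
  start <- 14L; end <- 24L
  expect_identical(detect_tsd(ctg, start, end), "TTAA")
  # 1-bp boundary shift breaks the duplication (TAAG vs TAAC)
  expect_true(is.na(detect_tsd(ctg, start + 1L, end + 1L)))
  # non-inserted control interval
  expect_true(is.na(detect_tsd(ctg, 5L, 9L)))
  expect_true(is.na(detect_tsd(ctg, 2L, 8L)))  # contig edge
})

test_that("fusion classification distinguishes internal, edge and co-localized", {
  mkhit <- function(gene, s, e, score = 500) {
    data.frame(gene_name = gene, contig_id = "c", strand = "+", frame = 0L,
               nt_start = s, nt_end = e, aa_query_start = 0L,
               aa_query_end = 10L, raw_score = score,
               aligned_identity = 1, evalue = 1e-30, bitscore = score / 2,
               stringsAsFactors = FALSE)
  }
  viral <- rbind(mkhit("mcp", 10000, 11000), mkhit("orf60", 12000, 12800),
                 mkhit("orf54", 13600, 14400), mkhit("pol", 15000, 16000))
  locus <- structure(list(contig_id = "c", core_start = 10000,
                          core_end = 16000, flank_start = 0,
                          flank_end = 56000,
                          member_hits = viral,
                          sequence = paste(rep("A", 56000), collapse = "")),
                     class = "terat_locus")

  internal <- classify_fusion(locus, mkhit("tpase", 12900, 13500), viral)
  expect_identical(internal$status, "fused_internal")
  expect_identical(internal$neighbor_genes, c("orf60", "orf54"))

  edge <- classify_fusion(locus, mkhit("tpase", 10100, 10800),
                          viral[-1, ])  # tpase before the first viral gene
  expect_identical(edge$status, "fused_edge")
  expect_identical(edge$neighbor_genes[1], "5'")

  co <- classify_fusion(locus, mkhit("tpase", 36000, 36700), viral)
  expect_identical(co$status, "co_localized")
  expect_equal(co$distance_to_element, 36000 - 16000)

  none <- classify_fusion(locus, NULL, viral)
  expect_identical(none$status, "none")
})

test_that("degraded copies are flagged by the intactness round trip", {
  host <- simulate_host_genome(1, 3e5, 0.41, 4, seed = 91,
                               gene_length_aa = c(100, 150))
  cat_mini <- data.frame(name = c("pol", "mcp", "hel"),
                         aa_length = c(120, 140, 100))
  tmpl <- build_viral_element(cat_mini, "absent", tir_length = 13,
                              spacer_length = 60, seed = 92)
  for (mode in c("stop", "frameshift")) {
    ins <- insert_element_copies(host$genome, tmpl,
             data.frame(n_copies = 2, between_divergence = 0.02,
                        within_divergence = 0.01),
             degrade = "s1c2", degrade_mode = mode,
             host_cds = host$host_cds, min_spacing = 70000, seed = 93)
    hits <- search_genome(element_queries(tmpl), ins$genome)
    loci <- lapply(merge_hit_loci(hits), function(l)
      extract_locus_sequence(ins$genome, l))
    expect_length(loci, 2L)
    expected <- setNames(tmpl$genes$aa_length, tmpl$genes$name)
    tr <- ins$truth[order(ins$truth$final_start), ]
    for (i in 1:2) {
      res <- assess_intactness(loci[[i]], hits, expected)
      if (tr$degraded[i]) {
        expect_identical(res$verdict, "partially_degraded")
        expect_identical(
          res$per_gene$status[res$per_gene$gene == tr$degraded_gene[i]],
          "degraded")
      } else {
        expect_identical(res$verdict, "intact")
      }
    }
  }
  expect_error(assess_intactness(loci[[1]], hits, c(bogus = 100)),
               "unknown gene")
})
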