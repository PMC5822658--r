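test_that("host genome simulation is deterministic and respects GC", {
  a <- simulate_host_genome(1, 1e5, 0.5, 5, seed = 7,
                            gene_length_aa = c(100, 200))
  b <- simulate_host_genome(1, 1e5, 0.5, 5, seed = 7,
                            gene_length_aa = c(100, 200))
  expect_identical(a$genome, b$genome)
  expect_identical(a$host_cds, b$host_cds)

  g <- simulate_host_genome(1, 1e6, 0.5, 0, seed = 1)
  expect_equal(nrow(g$host_cds), 0L)
  gc_obs <- mean(strsplit(g$genome[[1]], "")[[1]] %in% c("G", "C"))
  # binomial oracle: 3 sd of Binomial(1e6, 0.5)/1e6
  expect_lt(abs(gc_obs - 0.5), 3 * sqrt(0.25 / 1e6))
})

test_that("host gene placement fails loudly when impossible", {
  expect_error(simulate_host_genome(1, 11000, 0.5, 50, seed = 1,
                                    gene_length_aa = c(300, 400)),
               "10x the longest")
  expect_error(simulate_host_genome(1, 40000, 0.5, 200, seed = 1,
                                    gene_length_aa = c(100, 120)),
               "placement failure")
})

test_that("planted host CDSs are genuine coding sequences", {
  g <- simulate_host_genome(1, 1e5, 0.45, 4, seed = 5,
                            gene_length_aa = c(100, 150))
  for (i in seq_len(nrow(g$host_cds))) {
    cds <- substr(g$genome[[1]], g$host_cds$start[i] + 1L, g$host_cds$end[i])
    if (g$host_cds$strand[i] == "-") cds <- revcomp(cds)
    expect_identical(substr(cds, 1, 3), "ATG")
    prot <- teratornscan:::translate_nt(cds)
    expect_identical(substr(prot, nchar(prot), nchar(prot)), "*")
    expect_false(grepl("\\*", substr(prot, 1, nchar(prot) - 1)))
  }
})

test_that("element template obeys the placement and TIR rules", {
  cat13 <- default_gene_catalog()
  internal <- build_viral_element(cat13, "internal", tir_length = 13, seed = 2)
  ord <- internal$genes$name
  i60 <- which(ord == "orf60")
  expect_identical(ord[i60 + 1L], "tpase")
  expect_identical(ord[i60 + 2L], "orf54")

  edge <- build_viral_element(cat13, "edge", tir_length = 13, seed = 2)
  expect_identical(edge$genes$name[1], "tpase")

  # right TIR is the reverse complement of the left TIR
  L <- internal$total_length
  expect_identical(substr(internal$seq, L - 12L, L),
                   revcomp(substr(internal$seq, 1L, 13L)))

  # every CDS: length divisible by 3, ATG start, single terminal stop
  for (i in seq_len(nrow(internal$genes))) {
    g <- internal$genes[i, ]
    cds <- substr(internal$seq, g$start + 1L, g$end)
    if (g$strand == "-") cds <- revcomp(cds)
    expect_identical(cds, g$cds)
    expect_equal(nchar(cds) %% 3L, 0L)
    prot <- teratornscan:::translate_nt(cds)
    expect_match(prot, "^M[^*]*\\*$")
  }

  expect_error(build_viral_element(cat13[cat13$name != "orf60", ],
                                   "internal", seed = 1),
               "orf60")
})

test_that("K2P sequence evolution has the stated rate and bias", {
  s <- teratornscan:::rand_dna(1e5)
  expect_identical(evolve_sequence(s, 0, seed = 1), s)
  expect_error(evolve_sequence(s, -0.1), "non-negative")

  e <- evolve_sequence(s, 0.1, ts_tv_ratio = 2, seed = 42)
  k <- k2p_distance(list(a = s, b = e))
  # estimator-consistency oracle: K2P estimate within 3 sd of the truth
  se <- sqrt(0.1 / 1e5)
  expect_lt(abs(k$d - 0.1), 3 * 2 * se)
  # transition:transversion count ratio ~ 2
  expect_gt(k$P / k$Q, 1.7)
  expect_lt(k$P / k$Q, 2.3)
})

test_that("CDS evolution under selection preserves the reading frame", {
  cds <- teratornscan:::random_cds(200)$cds
  ev <- evolve_cds(cds, 0.1, omega = 0.1, seed = 3)
  expect_equal(nchar(ev), nchar(cds))
  prot <- teratornscan:::translate_nt(ev)
  expect_match(prot, "^M[^*]*\\*$")
  # realized divergence close to the target despite rejection
  k <- k2p_distance(list(a = cds, b = ev))
  expect_gt(k$d, 0.05)
  expect_lt(k$d, 0.16)
})

test_that("element insertion records truth and duplicates the TTAA site", {
  host <- simulate_host_genome(1, 2e5, 0.41, 5, seed = 3,
                               gene_length_aa = c(100, 150))
  cat_mini <- data.frame(name = c("pol", "mcp"), aa_length = c(100, 120))
  tmpl <- build_viral_element(cat_mini, "absent", tir_length = 13,
                              spacer_length = 50, seed = 4)
  spec <- data.frame(n_copies = c(5, 5),
                     between_divergence = c(0.08, 0.08),
                     within_divergence = c(0.01, 0.01))
  ins <- insert_element_copies(host$genome, tmpl, spec,
                               host_cds = host$host_cds, seed = 6)
  expect_equal(nrow(ins$truth), 10L)
  expect_equal(length(unique(ins$truth$subtype)), 2L)

  # TTAA context on both sides of every copy
  for (i in seq_len(nrow(ins$truth))) {
    tr <- ins$truth[i, ]
    ctg <- ins$genome[[tr$contig_id]]
    expect_identical(substr(ctg, tr$final_start - 3L, tr$final_start), "TTAA")
    expect_identical(substr(ctg, tr$final_end + 1L, tr$final_end + 4L), "TTAA")
  }

  # conservation: post length = pre length + sum(copy lengths + TSD)
  expect_equal(nchar(ins$genome[[1]]),
               nchar(host$genome[[1]]) + sum(ins$truth$length + 4L))

  # no-TTAA contig errors by name
  g2 <- c(bare = paste(rep("C", 5000), collapse = ""))
  expect_error(insert_element_copies(g2, tmpl, spec[1, ], seed = 1),
               "TTAA")
})

test_that("paper-regime copies satisfy the subtype identity bands", {
  tmpl <- build_viral_element(data.frame(name = "pol", aa_length = 150),
                              "absent", tir_length = 13,
                              spacer_length = 50, seed = 9)
  host <- c(ctg = paste0(teratornscan:::rand_dna(20000), "TTAA",
                         teratornscan:::rand_dna(20000), "TTAA",
                         teratornscan:::rand_dna(20000), "TTAA",
                         teratornscan:::rand_dna(20000)))
  spec <- data.frame(n_copies = c(2, 2),
                     between_divergence = c(0.08, 0.08),
                     within_divergence = c(0.01, 0.01))
  ins <- insert_element_copies(host, tmpl, spec, seed = 21)
  im <- identity_matrix(ins$copies)
  lab <- sub("c[0-9]+$", "", names(ins$copies))
  within <- im[outer(lab, lab, "==") & upper.tri(im)]
  between <- im[outer(lab, lab, "!=") & upper.tri(im)]
  expect_true(all(within > 0.95))
  expect_true(all(between < 0.90))
})

test_that("read simulation matches the stated coverage model", {
  g <- c(ctg = teratornscan:::rand_dna(1e5))
  expect_error(simulate_reads(g, 0), "positive")
  reads <- simulate_reads(g, 20, 100, error_rate = 0, seed = 5)
  expect_equal(length(reads), 20 * 1e5 / 100)

  # error-free reads are exact substrings (or reverse complements)
  for (r in reads[seq(1, length(reads), by = 4000)]) {
    found <- grepl(r, g[[1]], fixed = TRUE) ||
      grepl(revcomp(r), g[[1]], fixed = TRUE)
    expect_true(found)
  }

  # Poisson coverage oracle over a 10-kb window
  pl <- map_reads(reads, g, 21, 0, seed = 6)
  prof <- per_base_depth(pl, data.frame(contig_id = "ctg", start = 45000,
                                        end = 55000, gene_id = "w",
                                        class = "host"))
  m <- mean(prof$depth[[1]])
  expect_lt(abs(m - 20), 3 * sqrt(20 / (10000 / 100)))
})

test_that("interval shifting maps pre-insertion to final coordinates", {
  truth <- data.frame(contig_id = "c", position = c(1000L, 5000L),
                      length = c(200L, 300L))
  iv <- data.frame(contig_id = "c", start = c(100L, 2000L, 6000L),
                   end = c(200L, 2100L, 6100L))
  out <- shift_intervals(iv, truth)
  expect_equal(out$start, c(100L, 2000L + 204L, 6000L + 204L + 304L))
  expect_equal(out$end - out$start, iv$end - iv$start)
})
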