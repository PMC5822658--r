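test_that("mask-and-append reference construction", {
  g <- c(c1 = teratornscan:::rand_dna(10000))
  iv <- data.frame(contig_id = "c1", start = 2000, end = 3000)
  el <- teratornscan:::rand_dna(1000)
  ref <- build_masked_reference(g, iv, c(element_ref = el))
  expect_equal(nchar(ref[["c1"]]), 10000L)
  expect_length(ref, 2L)
  expect_identical(substr(ref[["c1"]], 2001, 3000),
                   paste(rep("N", 1000), collapse = ""))
  expect_identical(ref[["element_ref"]], el)

  # degenerate: no intervals
  ref2 <- build_masked_reference(g, NULL, c(element_ref = el))
  expect_identical(ref2[["c1"]], g[["c1"]])
  expect_error(build_masked_reference(g, data.frame(contig_id = "c1",
                                                    start = 9000,
                                                    end = 11000), el),
               "outside")
})

test_that("reads from masked copies map to the appended element", {
  set.seed(43)
  g <- c(c1 = teratornscan:::rand_dna(20000))
  el <- teratornscan:::rand_dna(2000)
  gi <- c(c1 = paste0(substr(g[[1]], 1, 10000), el,
                      substr(g[[1]], 10001, 20000)))
  iv <- data.frame(contig_id = "c1", start = 10000, end = 12000)
  ref <- build_masked_reference(gi, iv, c(element_ref = el))
  reads <- simulate_reads(gi, 5, 100, 0, seed = 44)
  pl <- map_reads(reads, ref, 21, 2, seed = 45)
  from_el <- pl[pl$contig == "element_ref", ]
  expect_gt(nrow(from_el), 50)
  # nothing maps inside the masked window
  in_mask <- pl$contig == "c1" & pl$start + 100 > 10000 & pl$start < 12000
  expect_equal(sum(in_mask), 0L)
})

test_that("mapping equals an exhaustive substring-search oracle", {
  set.seed(47)
  g <- c(a = teratornscan:::rand_dna(30000), b = teratornscan:::rand_dna(9000))
  reads <- simulate_reads(g, 8, 60, 0, seed = 48)
  pl <- map_reads(reads, g, 21, 0, seed = 49)
  expect_equal(nrow(pl), length(reads))
  idx <- sample.int(nrow(pl), 400)
  for (i in idx) {
    r <- reads[[pl$read_id[i]]]
    target <- if (pl$strand[i] == "+") r else revcomp(r)
    # oracle: exhaustive match over both contigs
    m <- lapply(g, function(s)
      as.integer(gregexpr(target, s, fixed = TRUE)[[1]]))
    hit_ctgs <- names(m)[vapply(m, function(x) x[1] != -1, logical(1))]
    expect_true(pl$contig[i] %in% hit_ctgs)
    expect_true((pl$start[i] + 1L) %in% m[[pl$contig[i]]])
  }
  # read spanning a masked N region is never placed
  gN <- g
  substr(gN[["a"]], 15000, 15200) <- paste(rep("N", 201), collapse = "")
  rN <- substr(g[["a"]], 15050, 15149)
  plN <- map_reads(c(x = rN), gN, 21, 3, seed = 50)
  expect_equal(nrow(plN), 0L)
})

test_that("per-base depth is an exact count", {
  pl <- data.frame(read_id = "r1", contig = "c", start = 10,
                   strand = "+", mismatches = 0L, read_length = 100L)
  iv <- data.frame(contig_id = "c", start = 0, end = 200, gene_id = "g",
                   class = "host")
  prof <- per_base_depth(pl, iv)
  expect_equal(sum(prof$depth[[1]]), 100L)
  expect_true(all(prof$depth[[1]][11:110] == 1L))
  expect_true(all(prof$depth[[1]][c(1:10, 111:200)] == 0L))

  # conservation and brute-force recount on random placements
  set.seed(51)
  n <- 1000
  pl2 <- data.frame(read_id = sprintf("r%d", 1:n), contig = "c",
                    start = sample.int(5000, n) - 1L, strand = "+",
                    mismatches = 0L,
                    read_length = sample(50:150, n, replace = TRUE))
  iv2 <- data.frame(contig_id = "c", start = 1000, end = 4000,
                    gene_id = "g", class = "host")
  prof2 <- per_base_depth(pl2, iv2)
  expect_equal(prof2$depth[[1]], depth_recount_oracle(pl2, iv2[1, ]))
  full <- data.frame(contig_id = "c", start = 0, end = 5200,
                     gene_id = "all", class = "host")
  prof3 <- per_base_depth(pl2, full)
  expect_equal(sum(prof3$depth[[1]]), sum(pl2$read_length))
})

test_that("depth tables round-trip with the 1-based position convention", {
  tmp <- tempfile(fileext = ".tsv")
  writeLines(c("ctg\t1\t5", "ctg\t2\t6", "ctg\t3\t7"), tmp)
  prof <- read_depth_table(tmp)
  expect_equal(nrow(prof$intervals), 1L)
  expect_equal(prof$intervals$start, 0L)  # position 1 -> index 0
  expect_equal(prof$intervals$end, 3L)
  expect_equal(prof$depth[[1]], c(5L, 6L, 7L))

  writeLines(c("ctg\t1\t5", "ctg\tx\t6"), tmp)
  expect_error(read_depth_table(tmp), "line 2")

  # write -> read is the identity on a computed profile
  set.seed(53)
  pl <- data.frame(read_id = "r", contig = "c", start = c(0, 50),
                   strand = "+", mismatches = 0L, read_length = 100L)
  iv <- data.frame(contig_id = "c", start = 10, end = 120, gene_id = "g",
                   class = "viral")
  prof1 <- per_base_depth(pl, iv)
  tmp2 <- tempfile(fileext = ".tsv")
  write_depth_table(prof1, tmp2)
  prof2 <- read_depth_table(tmp2, intervals = prof1$intervals)
  expect_equal(prof2$depth, prof1$depth)
})

test_that("the copy-number ratio is means of pooled depths", {
  prof <- structure(list(
    intervals = data.frame(contig_id = c("e", "c"), start = 0,
                           end = 100, gene_id = c("v1", "h1"),
                           class = c("viral", "host")),
    depth = list(rep(300L, 100), rep(30L, 100))),
    class = "coverage_profile")
  est <- estimate_copy_number(prof, n_bootstrap = 0)
  expect_equal(est$copy_number, 10)

  prof$depth[[1]] <- rep(0L, 100)
  expect_equal(estimate_copy_number(prof, n_bootstrap = 0)$copy_number, 0)

  prof$depth[[2]] <- rep(0L, 100)
  expect_error(estimate_copy_number(prof, n_bootstrap = 0), "zero host")
  expect_error(estimate_copy_number(prof, viral_genes = character(0),
                                    host_genes = "h1"), "non-empty")
})

test_that("a single-copy control estimates copy number near one", {
  host <- simulate_host_genome(1, 80000, 0.45, 8, seed = 55,
                               gene_length_aa = c(120, 200))
  reads <- simulate_reads(host$genome, 25, 100, 0.005, seed = 56)
  pl <- map_reads(reads, host$genome, 21, 4, seed = 57)
  hc <- host$host_cds
  iv <- data.frame(contig_id = hc$contig_id, start = hc$start,
                   end = hc$end, gene_id = hc$gene_id,
                   class = c("viral", rep("host", nrow(hc) - 1L)))
  prof <- per_base_depth(pl, iv)
  est <- estimate_copy_number(prof, n_bootstrap = 200, seed = 58)
  expect_gt(est$copy_number, 0.85)
  expect_lt(est$copy_number, 1.15)
  expect_true(est$bootstrap_ci[1] <= est$copy_number &&
                est$copy_number <= est$bootstrap_ci[2])
})

test_that("estimation without mask-and-append underestimates copy number", {
  # reads from 5 identical copies split across loci when the copies are
  # left in the reference, deflating depth on any single copy
  set.seed(59)
  host <- c(ctg = paste0(teratornscan:::rand_dna(30000),
                         paste(replicate(5, paste0("TTAA",
                           teratornscan:::rand_dna(8000))), collapse = "")))
  tmpl <- build_viral_element(data.frame(name = "pol", aa_length = 130),
                              "absent", tir_length = 13, spacer_length = 40,
                              seed = 60)
  spec <- data.frame(n_copies = 5, between_divergence = 0.001,
                     within_divergence = 0.001)
  ins <- insert_element_copies(host, tmpl, spec, seed = 61)
  reads <- simulate_reads(ins$genome, 20, 100, 0, seed = 62)
  hc <- data.frame(contig_id = "ctg", start = 1000, end = 9000,
                   gene_id = "host_block", class = "host")
  hc_shift <- shift_intervals(hc, ins$truth)

  # masked reference: all copies collapse onto the appended element
  mask <- data.frame(contig_id = ins$truth$contig_id,
                     start = ins$truth$final_start,
                     end = ins$truth$final_end)
  ref <- build_masked_reference(ins$genome, mask,
                                c(element_ref = ins$copies[[1]]))
  iv_el <- data.frame(contig_id = "element_ref", start = 0,
                      end = nchar(ins$copies[[1]]), gene_id = "elem",
                      class = "viral")
  pl_m <- map_reads(reads, ref, 21, 4, seed = 63)
  est_m <- estimate_copy_number(per_base_depth(pl_m, rbind(iv_el, hc_shift)),
                                n_bootstrap = 0)

  # unmasked reference: the same reads spread over the in-place copies
  iv_one <- data.frame(contig_id = "ctg",
                       start = ins$truth$final_start[1],
                       end = ins$truth$final_end[1], gene_id = "elem",
                       class = "viral")
  pl_u <- map_reads(reads, ins$genome, 21, 4, seed = 64)
  est_u <- estimate_copy_number(per_base_depth(pl_u, rbind(iv_one, hc_shift)),
                                n_bootstrap = 0)

  expect_gt(est_m$copy_number, 4.2)
  expect_lt(est_u$copy_number, 0.55 * est_m$copy_number)
})
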