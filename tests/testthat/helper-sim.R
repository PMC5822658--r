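# Shared simulation helpers for recovery studies.

# One copy-number recovery run: 10 planted copies (two subtypes of 5) of
# a small element in a 120-kb host, 30x reads, mask-and-append with one
# representative per subtype; returns the summed copy-number estimate.
copy_number_run <- function(seed, n_per_subtype = 5L, mean_depth = 30) {
  host <- simulate_host_genome(1, 120000, 0.41, 8, seed = derive2(seed, 1),
                               gene_length_aa = c(120, 200))
  catalog <- data.frame(name = c("pol", "mcp", "ter", "hel"),
                        aa_length = c(120, 140, 110, 100))
  tmpl <- build_viral_element(catalog, "absent", tir_length = 13,
                              spacer_length = 60, seed = derive2(seed, 2))
  spec <- data.frame(n_copies = rep(n_per_subtype, 2),
                     between_divergence = 0.08,
                     within_divergence = 0.01)
  ins <- insert_element_copies(host$genome, tmpl, spec,
                               host_cds = host$host_cds,
                               seed = derive2(seed, 3))
  reads <- simulate_reads(ins$genome, mean_depth, 100, 0.005,
                          seed = derive2(seed, 4))
  mask <- data.frame(contig_id = ins$truth$contig_id,
                     start = pmax(0L, ins$truth$final_start - 4L),
                     end = ins$truth$final_end + 4L)
  reps <- c(element_s1 = unname(ins$copies[sprintf("s1c%d", 1L)]),
            element_s2 = unname(ins$copies[sprintf("s2c%d", 1L)]))
  ref <- build_masked_reference(ins$genome, mask, reps)
  viral_iv <- do.call(rbind, lapply(names(reps), function(nm)
    data.frame(contig_id = nm, start = tmpl$genes$start,
               end = tmpl$genes$end,
               gene_id = paste0(nm, "_", tmpl$genes$name),
               class = "viral", stringsAsFactors = FALSE)))
  hc <- ins$host_cds
  host_iv <- data.frame(contig_id = hc$contig_id, start = hc$start,
                        end = hc$end, gene_id = hc$gene_id, class = "host",
                        stringsAsFactors = FALSE)
  pl <- map_reads(reads, ref, 21, 5, seed = derive2(seed, 5))
  prof <- per_base_depth(pl, rbind(viral_iv, host_iv))
  per_subtype <- vapply(names(reps), function(nm) {
    estimate_copy_number(prof,
                         viral_genes = viral_iv$gene_id[viral_iv$contig_id == nm],
                         host_genes = host_iv$gene_id,
                         n_bootstrap = 0)$copy_number
  }, numeric(1))
  list(total = sum(per_subtype), per_subtype = per_subtype)
}

# One subtype-recovery run in the regime the analysis assumes
# (within-subtype identity > 0.95, between-subtype < 0.90).
subtype_run <- function(seed, n_per_subtype = 5L) {
  tmpl <- build_viral_element(data.frame(name = "pol", aa_length = 300),
                              "absent", tir_length = 13, spacer_length = 40,
                              seed = derive2(seed, 1))
  host <- c(ctg = paste0(teratornscan:::rand_dna(3000),
                         paste(replicate(12, paste0("TTAA",
                           teratornscan:::rand_dna(2000))), collapse = "")))
  spec <- data.frame(n_copies = rep(n_per_subtype, 2),
                     between_divergence = 0.08, within_divergence = 0.01)
  ins <- insert_element_copies(host, tmpl, spec, seed = derive2(seed, 2))
  cluster_subtypes(ins$copies)
}

# One fusion/TIR annotation run: a single planted element with the
# transposase internal or at the edge, searched and annotated end to
# end; returns the annotation plus the planted truth.
fusion_run <- function(seed, placement) {
  host <- simulate_host_genome(1, 80000, 0.41, 0, seed = derive2(seed, 1))
  catalog <- data.frame(name = c("pol", "mcp", "orf60", "orf54"),
                        aa_length = c(120, 140, 110, 100))
  tmpl <- build_viral_element(catalog, placement, tir_length = 13,
                              spacer_length = 80, seed = derive2(seed, 2))
  ins <- insert_element_copies(host$genome, tmpl,
           data.frame(n_copies = 1, between_divergence = 0.05,
                      within_divergence = 0.01),
           seed = derive2(seed, 3))
  hits <- search_genome(element_queries(tmpl), ins$genome)
  viral_hits <- hits[hits$gene_name != "tpase", , drop = FALSE]
  loci <- merge_hit_loci(viral_hits)
  if (length(loci) != 1L) return(NULL)
  locus <- extract_locus_sequence(ins$genome, loci[[1]])
  ann <- teratornscan:::annotate_locus(
    locus, ins$genome, hits,
    setNames(tmpl$genes$aa_length, tmpl$genes$name), run_config())
  list(annotation = ann, truth = ins$truth, template = tmpl)
}

derive2 <- function(seed, k) as.integer((seed * 131 + k * 7919) %% 2147483647)
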