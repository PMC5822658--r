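# End-to-end orchestration: simulate -> search -> classify -> loci ->
# annotate -> subtype -> copy number (-> marker-gene tree), with a
# single declarative config, per-stage seeds derived from the run seed,
# and a species-level summary table.

run_config_defaults <- function() {
  list(
    species_id = "synthetic_sp1",
    seed = 1L,
    # synthetic genome
    n_contigs = 1L,
    contig_length = 1e6,
    gc_fraction = 0.41,
    n_host_genes = 20L,
    gene_scale = 0.5,
    element_genes = NULL,          # NULL = full default catalog
    transposase_placement = "internal",
    tir_length = 13L,
    spacer_length = 100L,
    subtypes = list(list(n_copies = 2L, between_divergence = 0.08,
                         within_divergence = 0.01),
                    list(n_copies = 2L, between_divergence = 0.08,
                         within_divergence = 0.01)),
    degrade = character(0),
    degrade_mode = "stop",
    min_spacing = 20000L,
    omega = 0.1,
    ts_tv_ratio = 2,
    # reads
    mean_depth = 20,
    read_length = 100L,
    error_rate = 0.005,
    # translated search (thresholds of the published screen)
    evalue = 1e-3,
    word_size = 4L,
    gap_open = -11L,
    gap_extend = -1L,
    x_drop = 20L,
    ungapped_trigger = 25L,
    # locus assembly / classification
    merge_distance = 60000L,
    flank = 40000L,
    min_genes = 8L,
    # subtyping
    subtype_threshold = 0.90,
    within_subtype_identity = 0.95,
    marker_gene = "pol",
    # annotation
    intact_fraction = 0.8,
    tir_min_len = 10L,
    tir_max_len = 40L,
    tir_max_mismatch = 1L,
    tir_margin = 300L,
    # copy number
    seed_kmer = 21L,
    max_mismatches = 4L,
    n_bootstrap_cn = 200L,
    # marker-gene tree
    run_phylo = FALSE,
    n_bootstrap = 1000L,
    write_reads = FALSE)
}

#' Build a validated pipeline configuration
#'
#' Defaults equal the published screen's thresholds (E-value 1e-3, 60-kb
#' merging, 40-kb flanks, >= 8 of 13 core genes, 90% subtype identity
#' threshold, 95% within-subtype check, transition/transversion bias 2,
#' 1000 bootstraps).  Unknown keys are rejected.
#'
#' @param ... overrides of the default keys.
#' @return object of class `run_config` (a named list).
#' @export
run_config <- function(...) {
  cfg <- run_config_defaults()
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown)) stop("unknown config key: ", unknown[1])
  cfg[names(over)] <- over
  structure(cfg, class = "run_config")
}

#' Read / write a pipeline configuration as YAML
#' @param path YAML file path.
#' @export
read_run_config <- function(path) {
  do.call(run_config, yaml::read_yaml(path))
}

#' @rdname read_run_config
#' @param config a `run_config`.
#' @export
write_run_config <- function(config, path) {
  yaml::write_yaml(unclass(config), path)
  invisible(path)
}

# Annotate one flanked locus: fusion, TIR, TSD, intactness.
annotate_locus <- function(locus, genome, hits, template_lengths, cfg) {
  tp_hits <- hits[hits$gene_name == "tpase", , drop = FALSE]
  viral_hits <- hits[hits$gene_name != "tpase", , drop = FALSE]
  fusion <- classify_fusion(locus, tp_hits, viral_hits)
  loc_len <- nchar(locus$sequence)
  # element envelope: viral gene core plus a fused terminal transposase
  env_start <- locus$core_start
  env_end <- locus$core_end
  if (fusion$status %in% c("fused_internal", "fused_edge")) {
    env_start <- min(env_start, fusion$transposase_interval[1])
    env_end <- max(env_end, fusion$transposase_interval[2])
  }
  rs <- max(0L, env_start - locus$flank_start - cfg$tir_margin)
  re <- min(loc_len, env_end - locus$flank_start + cfg$tir_margin)
  sub <- substr(locus$sequence, rs + 1L, re)
  win <- min(cfg$tir_margin + 250L, (nchar(sub) - 2L) %/% 2L)
  tir <- NULL
  if (win >= cfg$tir_min_len) {
    # exact repeats define boundaries most precisely; fall back to the
    # configured mismatch allowance
    for (mm in unique(c(0L, cfg$tir_max_mismatch))) {
      tir <- tryCatch(find_tirs(sub, cfg$tir_min_len, cfg$tir_max_len,
                                mm, window = win),
                      error = function(e) NULL)
      if (!is.null(tir)) break
    }
  }
  el_start <- el_end <- tsd <- NA
  if (!is.null(tir)) {
    # a TTAA target-site duplication is reverse-complement palindromic,
    # so it joins (and may slightly extend) the terminal inverted
    # repeat; locate the TTAA inside the repeat prefix and strip
    # through it so the element boundaries exclude the duplicated site
    left_rep <- substr(sub, tir$left_start + 1L,
                       tir$left_start + tir$length)
    j <- as.integer(regexpr("TTAA", substr(left_rep, 1L,
                                           min(12L, tir$length)),
                            fixed = TRUE)) - 1L
    if (j >= 0L && tir$length - j - 4L >= cfg$tir_min_len) {
      tir$left_start <- tir$left_start + j + 4L
      tir$right_end <- tir$right_end - j - 4L
      tir$length <- tir$length - j - 4L
    }
    el_start <- locus$flank_start + rs + tir$left_start
    el_end <- locus$flank_start + rs + tir$right_end
    tsd <- detect_tsd(genome[[locus$contig_id]], el_start, el_end)
  }
  intact <- assess_intactness(locus, viral_hits, template_lengths,
                              min_fraction = cfg$intact_fraction)
  list(fusion = fusion, tir = tir, element_start = el_start,
       element_end = el_end, tsd = tsd, intactness = intact)
}

#' Run the full synthetic-screen pipeline
#'
#' Simulates a host genome with planted element copies, searches the
#' element's protein set against the assembly, classifies the species by
#' core-gene presence, merges hits into loci, annotates fusion / TIR /
#' TSD / intactness, clusters marker-gene copies into subtypes,
#' estimates copy number from simulated reads against a mask-and-append
#' reference, and returns a species-level summary.
#'
#' @param config a `run_config`.
#' @param outdir optional output directory for stage artifacts.
#' @return list with `summary` (one-row data frame), `truth`,
#'   `template`, `hits`, `loci`, `annotations`, `clustering`,
#'   `copy_number`, `tree`.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  cfg <- config
  stopifnot(inherits(cfg, "run_config"))
  if (!is.null(outdir) && !dir.exists(outdir)) {
    dir.create(outdir, recursive = TRUE)
  }
  log_lines <- c(sprintf("run_pipeline species=%s seed=%d", cfg$species_id,
                         as.integer(cfg$seed)),
                 sprintf("thresholds: evalue<%g merge<=%d flank=%d min_genes>=%d subtype>%g",
                         cfg$evalue, as.integer(cfg$merge_distance),
                         as.integer(cfg$flank), as.integer(cfg$min_genes),
                         cfg$subtype_threshold))

  # --- simulate -------------------------------------------------------
  host <- simulate_host_genome(cfg$n_contigs, cfg$contig_length,
                               cfg$gc_fraction, cfg$n_host_genes,
                               seed = derive_seed(cfg$seed, 1L))
  catalog <- default_gene_catalog(
    include_transposase = cfg$transposase_placement != "absent",
    scale = cfg$gene_scale)
  if (!is.null(cfg$element_genes)) {
    catalog <- catalog[catalog$name %in%
                         c(cfg$element_genes,
                           if (cfg$transposase_placement != "absent") "tpase"),
                       , drop = FALSE]
  }
  template <- build_viral_element(catalog, cfg$transposase_placement,
                                  tir_length = cfg$tir_length,
                                  spacer_length = cfg$spacer_length,
                                  seed = derive_seed(cfg$seed, 2L))
  if (length(cfg$subtypes)) {
    spec <- do.call(rbind, lapply(cfg$subtypes, as.data.frame))
    ins <- insert_element_copies(host$genome, template, spec,
                                 degrade = cfg$degrade,
                                 degrade_mode = cfg$degrade_mode,
                                 host_cds = host$host_cds,
                                 min_spacing = cfg$min_spacing,
                                 omega = cfg$omega,
                                 ts_tv_ratio = cfg$ts_tv_ratio,
                                 seed = derive_seed(cfg$seed, 3L))
  } else {
    # negative control: no element planted
    ins <- list(genome = host$genome,
                truth = data.frame(contig_id = character(0),
                                   position = integer(0)),
                copies = character(0), host_cds = host$host_cds)
  }
  genome <- ins$genome
  log_lines <- c(log_lines, sprintf("simulated %d copies in %d subtypes",
                                    nrow(ins$truth), length(cfg$subtypes)))

  # --- translated search and classification ---------------------------
  queries <- element_queries(template)
  params <- search_params(word_size = cfg$word_size,
                          gap_open = cfg$gap_open,
                          gap_extend = cfg$gap_extend, x_drop = cfg$x_drop,
                          evalue_keep = cfg$evalue,
                          ungapped_trigger = cfg$ungapped_trigger)
  hits <- search_genome(queries, genome, params)
  pres <- presence_record(hits)
  cls <- classify_species(pres, min_genes = cfg$min_genes,
                          evalue_threshold = cfg$evalue)

  # --- loci and annotation --------------------------------------------
  viral_hits <- hits[hits$gene_name != "tpase", , drop = FALSE]
  loci <- merge_hit_loci(viral_hits, cfg$merge_distance)
  loci <- lapply(loci, function(l)
    extract_locus_sequence(genome, l, flank = cfg$flank))
  expected <- setNames(template$genes$aa_length, template$genes$name)
  annotations <- lapply(loci, annotate_locus, genome = genome, hits = hits,
                        template_lengths = expected, cfg = cfg)

  # --- subtype clustering on marker-gene copies -----------------------
  marker <- cfg$marker_gene
  mh <- hits[hits$gene_name == marker, , drop = FALSE]
  clustering <- NULL
  if (nrow(mh) >= 1L) {
    seqs <- setNames(substring(genome[mh$contig_id], mh$nt_start + 1L,
                               mh$nt_end),
                     sprintf("%s_%s_%d", mh$contig_id, marker,
                             seq_len(nrow(mh))))
    clustering <- cluster_subtypes(seqs, cfg$subtype_threshold)
  }

  # --- copy number -----------------------------------------------------
  copy_number <- NULL
  if (cfg$mean_depth > 0 && length(loci)) {
    reads <- simulate_reads(genome, cfg$mean_depth, cfg$read_length,
                            cfg$error_rate,
                            seed = derive_seed(cfg$seed, 4L))
    mask <- do.call(rbind, lapply(seq_along(loci), function(i) {
      l <- loci[[i]]; a <- annotations[[i]]
      s <- if (!is.na(a$element_start)) a$element_start
           else max(0L, l$core_start - cfg$tir_margin)
      e <- if (!is.na(a$element_end)) a$element_end
           else min(nchar(genome[[l$contig_id]]), l$core_end + cfg$tir_margin)
      data.frame(contig_id = l$contig_id, start = s, end = e)
    }))
    # representative element sequence per subtype cluster
    rep_seqs <- character(0)
    if (!is.null(clustering)) {
      rep_ids <- clustering$representatives
      rep_locus <- match(rep_ids, names(clustering$labels))
    }
    # appended reference: the full element region of one locus per subtype
    el_of_locus <- function(i) {
      l <- loci[[i]]; a <- annotations[[i]]
      s <- if (!is.na(a$element_start)) a$element_start else l$core_start
      e <- if (!is.na(a$element_end)) a$element_end else l$core_end
      substring(genome[[l$contig_id]], s + 1L, e)
    }
    # map marker hits to loci to choose one locus per subtype
    rep_seqs <- list()
    if (!is.null(clustering) && nrow(mh)) {
      mh$mid <- (mh$nt_start + mh$nt_end) / 2
      locus_of_hit <- vapply(seq_len(nrow(mh)), function(k) {
        for (i in seq_along(loci)) {
          l <- loci[[i]]
          if (mh$contig_id[k] == l$contig_id && mh$mid[k] >= l$core_start &&
              mh$mid[k] < l$core_end) return(i)
        }
        NA_integer_
      }, integer(1))
      for (s in names(clustering$clusters)) {
        rep_id <- clustering$representatives[[s]]
        li <- locus_of_hit[match(rep_id, names(clustering$labels))]
        if (!is.na(li)) rep_seqs[[s]] <- el_of_locus(li)
      }
    }
    if (!length(rep_seqs)) rep_seqs <- list(subtype_1 = el_of_locus(1L))
    ref <- build_masked_reference(genome, mask,
                                  setNames(unlist(rep_seqs),
                                           paste0("element_ref_",
                                                  names(rep_seqs))))
    # viral gene intervals on the appended contigs
    ref_names <- paste0("element_ref_", names(rep_seqs))
    vq <- queries[setdiff(names(queries), "tpase")]
    rh <- search_genome(vq, ref[ref_names], params)
    viral_iv <- if (nrow(rh)) data.frame(
      contig_id = rh$contig_id, start = rh$nt_start, end = rh$nt_end,
      gene_id = sprintf("%s|%s", rh$contig_id, rh$gene_name),
      class = "viral", stringsAsFactors = FALSE) else NULL
    hc <- ins$host_cds  # post-insertion coordinates
    host_iv <- data.frame(contig_id = hc$contig_id, start = hc$start,
                          end = hc$end, gene_id = hc$gene_id,
                          class = "host", stringsAsFactors = FALSE)
    pl <- map_reads(reads, ref, cfg$seed_kmer, cfg$max_mismatches,
                    seed = derive_seed(cfg$seed, 5L))
    prof <- per_base_depth(pl, rbind(viral_iv, host_iv))
    copy_number <- list()
    for (s in names(rep_seqs)) {
      vg <- viral_iv$gene_id[viral_iv$contig_id == paste0("element_ref_", s)]
      copy_number[[s]] <- estimate_copy_number(
        prof, viral_genes = vg, host_genes = host_iv$gene_id,
        n_bootstrap = cfg$n_bootstrap_cn,
        seed = derive_seed(cfg$seed, 6L))
    }
  }

  # --- marker-gene tree ------------------------------------------------
  tree <- NULL
  if (isTRUE(cfg$run_phylo) && !is.null(clustering)) {
    mh2 <- hits[hits$gene_name == marker, , drop = FALSE]
    if (nrow(mh2) >= 3L) {
      sq <- setNames(substring(genome[mh2$contig_id], mh2$nt_start + 1L,
                               mh2$nt_end),
                     sprintf("%s_%s_%d", mh2$contig_id, marker,
                             seq_len(nrow(mh2))))
      if (length(unique(nchar(sq))) == 1L) {
        tree <- tryCatch(
          bootstrap_support(sq, n_replicates = cfg$n_bootstrap,
                            seed = derive_seed(cfg$seed, 7L)),
          error = function(e) NULL)
      }
    }
  }

  # --- summary ---------------------------------------------------------
  fusion_modes <- vapply(annotations, function(a) a$fusion$status,
                         character(1))
  fusion_status <- if (!length(fusion_modes)) NA_character_ else
    names(sort(table(fusion_modes), decreasing = TRUE))[1]
  verdicts <- vapply(annotations, function(a) a$intactness$verdict,
                     character(1))
  tir_found <- vapply(annotations, function(a) !is.null(a$tir), logical(1))
  tsds <- vapply(annotations, function(a)
    if (is.na(a$tsd)) NA_character_ else as.character(a$tsd), character(1))
  cn_str <- if (is.null(copy_number)) NA_character_ else
    paste(sprintf("%s=%.2f", names(copy_number),
                  vapply(copy_number, function(x) x$copy_number,
                         numeric(1))), collapse = ",")
  summary <- data.frame(
    species_id = cfg$species_id,
    n_genes_present = cls$n_genes_present,
    classification = cls$classification,
    n_loci = length(loci),
    n_subtypes = if (is.null(clustering)) NA_integer_
                 else length(clustering$clusters),
    copy_number = cn_str,
    fusion_status = fusion_status,
    intactness = if (length(verdicts)) paste(verdicts, collapse = ",")
                 else NA_character_,
    tir_detected = if (length(tir_found)) sum(tir_found) else 0L,
    tsd = if (all(is.na(tsds))) NA_character_ else
      paste(unique(tsds[!is.na(tsds)]), collapse = ","),
    stringsAsFactors = FALSE)
  pres_df <- as.data.frame(as.list(
    setNames(as.integer(cls$present), paste0("gene_", names(cls$present)))))
  summary <- cbind(summary, pres_df)

  result <- list(summary = summary, truth = ins$truth, template = template,
                 host = host, genome = genome, hits = hits, presence = pres,
                 loci = loci, annotations = annotations,
                 clustering = clustering, copy_number = copy_number,
                 tree = tree, config = cfg, log = log_lines)
  if (!is.null(outdir)) {
    write_run_config(cfg, file.path(outdir, "config.yaml"))
    write_fasta(genome, file.path(outdir, "genome.fa"))
    write_fasta(c(element_template = template$seq),
                file.path(outdir, "element_template.fa"))
    if (nrow(hits)) write_hits_tsv(hits, file.path(outdir, "hits.tsv"))
    if (length(loci)) {
      write_loci_bed(loci, file.path(outdir, "loci_core.bed"),
                     file.path(outdir, "loci_flank.bed"))
    }
    if (!is.null(clustering)) {
      write_subtypes_tsv(clustering, file.path(outdir, "subtypes.tsv"),
                         file.path(outdir, "identity_matrix.tsv"))
    }
    if (!is.null(tree)) {
      ape::write.tree(tree, file.path(outdir, "marker_gene_nj.nwk"))
    }
    write_summary(summary, file.path(outdir, "summary.tsv"))
    files <- list.files(outdir, full.names = TRUE)
    sums <- tools::md5sum(files[basename(files) != "run.log"])
    log_lines <- c(log_lines, sprintf("md5 %s %s", basename(names(sums)),
                                      unname(sums)))
    writeLines(log_lines, file.path(outdir, "run.log"))
  }
  result
}

#' Write the species-level summary table
#'
#' One row per species; fixed column order (species_id,
#' n_genes_present, classification, n_loci, n_subtypes, copy_number,
#' fusion_status, intactness, tir_detected, tsd, then the 13 per-gene
#' presence indicators).  Missing stages appear as NA, never dropped.
#'
#' @param summary summary data frame (rows from one or more
#'   [run_pipeline()] results).
#' @param path output TSV path.
#' @param report_path optional human-readable report path.
#' @export
write_summary <- function(summary, path, report_path = NULL) {
  write.table(summary, path, sep = "\t", quote = FALSE, row.names = FALSE,
              na = "NA")
  if (!is.null(report_path)) {
    lines <- c("Teratorn-like element screen summary",
               strrep("-", 40))
    for (i in seq_len(nrow(summary))) {
      r <- summary[i, ]
      lines <- c(lines, sprintf(
        "%s: %s (%d/13 core genes), %d loci, %s subtypes, copy number %s, fusion %s",
        r$species_id, r$classification, r$n_genes_present, r$n_loci,
        ifelse(is.na(r$n_subtypes), "NA", r$n_subtypes),
        ifelse(is.na(r$copy_number), "NA", r$copy_number),
        ifelse(is.na(r$fusion_status), "NA", r$fusion_status)))
    }
    writeLines(lines, report_path)
  }
  invisible(path)
}
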