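species_id: synthetic_sp1
seed: 1
n_contigs: 1
contig_length: 1000000.0
gc_fraction: 0.41
n_host_genes: 20
gene_scale: 0.5
element_genes: ~
transposase_placement: internal
tir_length: 13
spacer_length: 100
subtypes:
- n_copies: 2
  between_divergence: 0.08
  within_divergence: 0.01
- n_copies: 2
  between_divergence: 0.08
  within_divergence: 0.01
degrade: []
degrade_mode: stop
min_spacing: 20000
omega: 0.1
ts_tv_ratio: 2.0
mean_depth: 20.0
read_length: 100
error_rate: 0.005
evalue: 0.001
word_size: 4
gap_open: -11
gap_extend: -1
x_drop: 20
ungapped_trigger: 25
merge_distance: 60000
flank: 40000
min_genes: 8
subtype_threshold: 0.9
within_subtype_identity: 0.95
marker_gene: pol
intact_fraction: 0.8
tir_min_len: 10
tir_max_len: 40
tir_max_mismatch: 1
tir_margin: 300
seed_kmer: 21
max_mismatches: 4
n_bootstrap_cn: 200
run_phylo: no
n_bootstrap: 1000
write_reads: no
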