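---
title: "Detecting Teratorn-like endogenous herpesviruses: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting Teratorn-like endogenous herpesviruses: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(teratornscan)
```

# Scope

`teratornscan` implements a screen for *Teratorn*-like endogenous
herpesvirus elements (EVEs) in teleost genome assemblies: translated
homology detection of the 13 alloherpesvirus core genes, assembly of
gene hits into candidate element loci, subtype clustering, depth-ratio
copy-number estimation, annotation of the *piggyBac*-transposase fusion
with its terminal inverted repeats (TIRs) and target-site duplication
(TSD), and distance-based phylogenetics including congruence testing
between the transposase and viral-gene trees. Because the real inputs
are large public assemblies and read archives, the package ships a
synthetic-genome generator that reproduces the statistical structure
the screen assumes and records a truth table, so that every stage is
validated by parameter recovery rather than by fixtures.

This vignette documents the models, the tunable parameters and their
defaults, the numerical conventions, and what the synthetic studies do
and do not demonstrate about real data.

# The detection model

## Translated search

Queries are protein sequences; the database is the six-frame
translation of every contig. The search is seeded by exact 4-mer word
matches (one-hit trigger), each seed is extended without gaps under an
X-drop rule, and seeds whose ungapped score reaches a trigger threshold
(default 25) are re-aligned by banded, gapped Smith–Waterman (BLOSUM62,
affine gaps, gap of length $L$ costing $g_o + (L-1)g_e$ with defaults
$g_o=-11$, $g_e=-1$) in a window around the seed diagonal. Overlapping
hits in the same frame keep the best-scoring extension. Significance
uses the ungapped Karlin–Altschul statistics

$$E = K\,m\,n\,e^{-\lambda S},\qquad K = 0.134,\ \lambda = 0.3176,$$

with $m$ the query length and $n$ the total translated database length
in amino acids. Applying ungapped parameters to gapped scores is a
knowing approximation: E-values here are used only to threshold
(default $E < 10^{-3}$), and the tests verify threshold behavior, not
E-value calibration against BLAST. On small instances the best hit's
raw score equals full Smith–Waterman (verified against an independent
full-DP oracle); a 300-aa random query against hundreds of kilobases of
i.i.d. sequence yields essentially no hits below $10^{-3}$, so the
false-locus rate of the screen on synthetic genomes is ~0.

Coordinates are 0-based, half-open, on the forward strand everywhere;
minus-strand hits are mapped back through the frame coordinate maps
(`frame_aa_to_genome()`), whose monotonicity and round-tripping are
property-tested.

## Locus assembly and classification

Hits on one contig merge into one locus when connected by a chain of
envelope gaps of at most 60 kb; the bound is inclusive (gap = 60,000
merges) because the source procedure does not state the comparison
operator, and merging is strand-agnostic since viral genes lie on both
strands within one element. Loci are extracted with 40-kb flanks
clipped at contig ends. A genome is called positive when at least 8 of
the 13 core genes have a best E-value below threshold; the threshold is
$\geq 8$, not $> 8$, so that a species with exactly 8 detected genes
counts as positive.

# Divergence and phylogenetics

## Distances

Pairwise identity is computed over non-gap columns of a global
alignment (Needleman–Wunsch with affine gaps, delegated to
`Biostrings::pairwiseAlignment`; its traceback is deterministic, which
is what reproducibility requires — the specific tie-break order among
co-optimal alignments is the library's, not a hand-written
diagonal-first rule). The Kimura two-parameter distance is

$$d = -\tfrac12 \ln\!\big((1 - 2P - Q)\sqrt{1 - 2Q}\big)$$

with $P$ and $Q$ the transition and transversion difference fractions
under pairwise deletion (gap or ambiguous columns excluded per pair,
matching the MEGA convention). Saturated pairs
($1-2P-Q \le 0$ or $1-2Q \le 0$) raise an error naming the pair rather
than returning a number.

## Modified Nei–Gojobori dN/dS

Synonymous site counts weight transitional changes by the
transition/transversion bias $R$ (default 2) relative to
transversional ones: at each codon position the synonymous fraction is
the weighted share of non-nonsense single-nucleotide changes that
preserve the amino acid; changes to stop codons are excluded from both
numerator and denominator, so each codon still contributes exactly 3
sites. Difference counts average over all minimal mutational pathways
(permutations of the differing positions), excluding pathways through
stop codons (if every pathway is blocked, all are used). $p_N$ and
$p_S$ are Jukes–Cantor corrected; a pair with $d_S = 0$ reports an
undefined ratio (`NA`) rather than infinity. The implementation is
checked against an independently written enumeration oracle to
$10^{-9}$ on hundreds of random codon pairs.

## Trees

Neighbor joining is implemented in the package with the Saitou–Nei
$Q$ criterion, deterministic lowest-index tie-breaking, and negative
branch-length estimates clamped to zero (a common convention; the
choice only affects degenerate inputs). It recovers the generating
topology exactly on additive matrices — the property that matters for
the screen — and agrees topologically with `ape::nj` on random additive
inputs. Bootstrap support resamples alignment columns with
replacement (default 1000 replicates), rebuilds the NJ tree per
replicate, and reports the percentage of replicates containing each
split of the point-estimate tree; replicates that saturate are dropped
from the denominator.

Topological congruence between the transposase tree and the viral-gene
tree is reported as the Robinson–Foulds distance on the shared leaf
set, normalized by $2(n-3)$ (via `phangorn::RF.dist`). RF is a
formalization of "the two topologies are (nearly) identical"; the
expectation RF = 0 applies to the simulator's co-inheritance regime,
in which both gene sets evolve down one tree — it is not a claim about
any particular empirical data set. The viral concatenation order is
fixed (pol, hel, ter, mcp, mem).

# Copy number

The estimator is the depth ratio

$$\widehat{CN} = \frac{\text{mean depth over viral CDS bases}}
                     {\text{mean depth over host CDS bases}},$$

computed from reads mapped to a *mask-and-append* reference: every
known element copy is replaced by N runs and one element reference per
subtype is appended, so multi-copy coverage collapses onto a single
target. Both means are pooled grand means over all bases of the class
(not means of per-gene means): the source description says only
"average coverage", and the pooled mean is the variance-minimizing
reading; the per-gene means are also reported. A bootstrap over genes
within each class gives a 95% CI — an extension beyond the point
estimates the original analysis reports.

The internal mapper indexes reference 21-mers, generates candidate
placements from seeds at the read start, middle and end on both
strands, verifies candidates by full-read Hamming distance (N never
matches), keeps the fewest-mismatch placement, and breaks exact ties
uniformly at random under the run seed. With mask-and-append the
multi-map path is rarely exercised, but it must be deterministic per
seed and is.

Two design points matter in the multi-subtype case. First, the
appended references are *realized copies* (one representative per
subtype), not the ancestral template: subtypes sit at ~15% mutual
divergence, so reads only map to a reference from their own subtype at
any realistic mismatch cap, and a single diverged reference would lose
most element reads. Total copy number is the sum of per-subtype
ratios. Second, a regression test demonstrates why masking matters:
against the unmasked assembly the same reads split across the in-place
copies and the single-locus estimate collapses toward 1.

# The synthetic-data generator

The generator is first-class, tested code; its defaults encode the
regime the screen assumes.

- **Host genome**: i.i.d. nucleotides at a stated GC fraction (default
  0.41, a typical teleost value), with non-overlapping single-copy host
  CDSs (ATG + uniform codons + stop) planted and recorded.
- **Element template**: an ordered gene set (scaled-down versions of
  the 13 core genes, optionally two accessory ORFs and a transposase),
  uniform-codon back-translations of random proteins separated by
  i.i.d. spacers, and a terminal inverted repeat pair (right TIR the
  reverse complement of the left). An internal transposase is placed
  between ORF60 and ORF54; an edge transposase is the first gene.
- **Evolution**: intergenic sequence evolves under the exact
  Kimura two-parameter per-site substitution process at
  transition:transversion count bias $R=2$ (the generative counterpart
  of the K2P/modified-NG assumptions downstream). Coding sequence
  evolves under the same mutation process filtered by purifying
  selection: synonymous changes always accepted, nonsense never,
  missense with probability $\omega$ (default 0.1, i.e. 10-fold
  suppression), with the proposal rate inflated so the expected
  accepted substitutions per site match the requested branch length.
  Without selection, paper-regime divergences would plant premature
  stops in nearly every "intact" copy and push dN/dS toward 1 — the
  opposite of the biology being emulated. TIR complementarity is
  re-imposed after evolution, as transposition requires paired termini.
- **Insertion**: each copy inserts at a TTAA site with target-site
  duplication, so copies are flanked by TTAA on both sides — the
  canonical *piggyBac* integration signature, adopted as a simulator
  convention to give the TSD detector a testable signal. Subtype
  structure: each subtype ancestor diverges from the template by
  `between_divergence` substitutions/site and each copy by
  `within_divergence / 2` from its ancestor, so within-subtype
  divergence ≈ `within_divergence` and between-subtype divergence ≈
  the sum of the two subtype branches. The default regime (0.08 /
  0.01) yields within-identity ≈ 0.99 and between-identity ≈ 0.85,
  inside the > 95% / < 90% bands the subtype rule assumes.
- **Degradation**: a degraded copy receives either a premature stop
  (midpoint codon set to TAA) or a 1-bp deletion at the CDS midpoint of
  one viral gene — the two ORF-degradation evidence classes the screen
  must recognize.
- **Reads**: single-end, uniform starts, both strands equiprobable,
  i.i.d. substitution errors (default 0.5%), fixed quality string.
  Indel errors, paired ends and GC bias are deliberately absent: the
  copy-number estimator consumes depth only.

Every operation is seed-deterministic; truth tables record insertion
positions (pre- and post-insertion coordinates), subtype labels,
degradation, and the TSD.

# Annotation conventions

- **ORFs** are maximal ATG-to-stop spans (first ATG after the previous
  in-frame stop) of at least `min_length_aa` (default 100 aa in the
  user-facing caller; the intactness assessor lowers this bound) on all
  six frames; coordinates include the stop codon. A gene is *intact*
  when an ORF overlapping its hit reaches 80% of the expected protein
  length (the 0.8 fraction is this package's operationalization of
  "degraded" — the source reports verdicts without a numeric rule —
  and is configurable); the element verdict is intact / degraded /
  partially degraded accordingly. Intron-containing genes are not
  modeled; the simulator plants intronless genes, a declared
  limitation.
- **TIRs**: the best pair of inverted repeats (longest, then fewest
  mismatches, then leftmost) with the left repeat inside the first
  `window` bp and the right repeat inside the last `window` bp. For
  boundary definition the pipeline first looks for exact repeats and
  only then allows mismatches: the planted TIR pair stays exactly
  complementary (both by simulator construction and in real elements,
  where transposition enforces it), and exact detection localizes
  boundaries to the base. A TTAA TSD is its own reverse complement, so
  it fuses with the TIR into one longer repeat; the pipeline locates
  the TTAA inside the detected repeat's prefix and strips through it,
  reporting element boundaries that exclude the duplicated site. The
  TSD check then requires the 4-mer immediately 5' of the element to
  equal the 4-mer immediately 3' of it.
- **Fusion**: hits are ordered by midpoint along the locus (per-gene
  best hit, ties by bitscore). `fused_internal` means the transposase
  lies between two viral gene hits inside the core envelope;
  `fused_edge` means it is terminal — first/last inside the core *or*
  just outside it (within 1 kb), since the core envelope is built from
  viral-gene hits only and a terminal transposase necessarily
  protrudes; `co_localized` means present in the 40-kb flank at larger
  separation, with the gap reported. When TIRs are absent the element
  "core" is the merged hit envelope, which may truncate true termini —
  reported as coordinates, not as biology.

# Pipeline, configuration, reproducibility

`run_config()` carries every tunable with defaults equal to the
published screen's values (E-value $10^{-3}$, 60-kb merge, 40-kb
flank, ≥ 8 of 13 genes, 90% subtype threshold, 95% within-subtype
check, $R = 2$, 1000 bootstraps) and rejects unknown keys; it
serializes to YAML alongside the run artifacts. `run_pipeline()`
derives per-stage seeds deterministically from the run seed, so a
config + seed pair reproduces byte-identical summaries; the run log
records parameters and per-artifact checksums. Subtype clustering in
the pipeline operates on the copies of a single marker gene (default
`pol`) — the same convention as clustering per-gene blast hits — which
also keeps pairwise global alignment affordable.

# Problem sizes and what the tests show

The validation studies run at desk scale by design: detection on a
5-Mb genome with a full and a 6-gene control element; copy-number
recovery with 10 planted copies (two subtypes of five) at 30×
simulated depth, recovered within ±15%; subtype recovery on ~1-kb
marker copies (a shorter marker lets sampling noise brush the 90%
threshold; the rule operates on multi-kb copies in practice, where
identity concentrates); fusion/TIR/TSD recovery over 50 seeded
single-copy genomes; NJ consistency on 100 random additive matrices
(4–12 taxa); congruence on co-simulated 8-taxon histories.

Passing these studies shows the pipeline recovers what the generator
plants under the stated statistical assumptions — uniform coverage,
substitution-only divergence, intronless genes, a single repeat family.
Real assemblies add fragmentation, gaps, repeat landscapes, GC bias
and intron-containing genes; the package surfaces raw per-gene and
per-locus evidence (hit tables, per-gene depths, identity matrices,
warnings from `validate_within_subtype()`) precisely so such deviations
are visible rather than absorbed. Cross-contig locus stitching is out
of scope and flagged, not automated; maximum-likelihood and Bayesian
tree inference are likewise out of scope (NJ serves as the
distance-based workhorse here).
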