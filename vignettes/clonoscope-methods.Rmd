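---
title: "Methods: clonality, specificity grouping and epitope linkage in clonoscope"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: clonality, specificity grouping and epitope linkage in clonoscope}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

`clonoscope` analyses paired-chain T cell receptor (TCR) repertoires from
single-cell V(D)J sequencing of case/control cohorts sampled in two
compartments (blood and cerebrospinal fluid, CSF). This vignette is the
package's own account of the statistics it computes, the conventions it
adopts where the methodology is underdetermined, and what its synthetic-data
tests do and do not demonstrate.

## Clonotype calling

Cell Ranger-style contig tables are collapsed to one cell per
`(barcode, sample)` with at most one TRA and one TRB contig. When several
productive contigs of one chain compete within a cell, the package keeps the
highest-UMI contig, breaking ties by longer CDR3 and then lexicographically
smallest CDR3. Sequencing pipelines do not define this choice; any fixed
rule works, and this one makes the result order-independent and exactly
reproducible.

A *clonotype* is the set of cells sharing identical alpha **and** beta CDR3
amino-acid sequences, pooled across all samples and tissues so that one
clonotype may span compartments and individuals. Identity is at the
amino-acid level only: cells with the same CDR3s but different V genes are
the same clonotype (the modal V genes are recorded for downstream grouping),
and nucleotide sequences are ignored. Cells without a complete alpha-beta
pair — gamma/delta cells and single-chain dropouts — are never clonotyped;
they form the "NA" stratum carried through all composition summaries.

## D50 diversity

For a sample with clonotype frequencies sorted in non-increasing order
$N_1 \ge N_2 \ge \dots \ge N_n$, the D50 index is

$$\mathrm{D50} = \frac{100\,k^*}{n}, \qquad
k^* = \min\Big\{k : \sum_{i=1}^{k} N_i \ge \tfrac12 \sum_{i=1}^{n} N_i\Big\}.$$

A perfectly even repertoire gives 50; dominance by few clones drives the
value toward $100/n$. A cumulative sum hitting exactly half the total counts
as reached, which is what "accounting for the cumulative 50%" means; for odd
totals the smallest even split overshoots by one cell, so uniform
repertoires with odd $n$ can exceed 50 by less than one rank
($\mathrm{D50} \le 50 + 100/n$ always, $\le 50$ whenever an even split is
attainable). By default D50 is computed on paired-chain clonotype
frequencies, with `level = "beta"` available to count beta CDR3s instead,
since single-chain repertoire studies often do the latter.

`compare_diversity()` compares per-sample D50 between two groups with a
two-sided Wilcoxon rank-sum test by default; a Welch t-test is also exposed
because both are in routine use for this comparison and give different
small-sample behavior. The package takes no position on which is "correct";
the default follows the rank-based convention for small cohort sizes.

## Downsampling comparison of clonal expansion

Comparing clone-size distributions between groups is biased by the number of
detected cells, so `downsample_compare()` equalizes depth: in each
iteration it draws $m = \min(|A|, |B|)$ cells without replacement from each
group, recomputes clonotype sizes *within the draw*, tabulates the number of
clonotypes at each clone size over the union of sizes observed in either
draw (absent sizes count 0), and applies a two-sided paired Wilcoxon
signed-rank test across the matched clone-size bins. The default is 100
iterations and the median p-value is reported. Counts are compared raw;
`log_counts = TRUE` applies `log1p` first for users who prefer comparing on
the logarithmic scale of typical clone-size plots.

Conventions: sampling is at the cell level (matching "number of detected
cells"); an iteration whose matched bins are all identical returns $p = 1$;
an iteration with fewer than two bins in the union is recorded as `NA` and
excluded from the median with a warning. Each (iteration, group) draw uses
an RNG substream derived from the root seed, the iteration index, and a
content hash of the group's clonotype keys — results are therefore
bit-for-bit reproducible and exactly symmetric under swapping the groups.

**Resolution limit.** The signed-rank statistic operates on one observation
per occupied clone-size bin. Small repertoires (a few hundred cells under a
geometric-like law) occupy only ~5–7 sizes, and the smallest attainable
two-sided exact p-value with $B$ informative bins is $2^{1-B}$ — about
0.03–0.06 at that scale. Consequently the test is *conservative* on small
inputs and achieves very small p-values only when one group out-populates
the other at many clone sizes simultaneously, as large cohort repertoires
with long expansion tails do. Analyses of desk-scale simulations should
expect blunted p-values from this statistic; this is a property of the
bin-paired design, not of the implementation.

## Strata and enrichment

Clone-size strata follow the conventional cut points NA / $=1$ / $\ge 2$ /
$\ge 20$ / $\ge 100$ cells. Both the cumulative view (as usually printed)
and disjoint bands (NA, 1, 2–19, 20–99, $\ge 100$; summing to 100% per
sample) are emitted, because the cumulative view alone cannot be
re-normalized by downstream code.

Clonal expansion is defined as clone size $\ge 2$ — the boundary between
single-use and repeated use of a receptor. `cluster_expansion_enrichment()`
tests each transcriptomic cluster with Fisher's exact test and adjusts
p-values across the cluster family by Benjamini–Hochberg. Two table designs
are exposed, because "expansion enriched in cluster X of patients" admits
both readings: the default compares condition × expanded within each
cluster (is expansion stronger in cases than controls, cluster by
cluster?); `pd_by_cluster` restricts to case cells and compares in-cluster ×
expanded (is expansion concentrated in this cluster among cases?). Clusters
with an empty table margin are reported with $p = 1$, an `NA` odds ratio,
and a degenerate flag rather than being dropped, so the output always covers
the full cluster family.

## Specificity groups

Beta-chain receptors are grouped into putative antigen-specificity clusters
under three conditions: at most one amino-acid mismatch on the CDR3, at most
one insertion/deletion, and identical V genes. The package reads the first
two conditions as mutually exclusive per pair — total edit distance at most
one — because that is the strictest reading and matches gap-free
similarity-grouping practice; `strict = FALSE` relaxes a length-difference-1
pair to tolerate one additional substitution for users who want the
permissive reading. V genes are compared at gene level with allele suffixes
(`*01`) stripped, since allele calls are pipeline artifacts and groups are
meant to span individuals. CDR3s are compared full-length, including the
conserved framing residues.

Members are distinct (CDR3, V gene, sample) tuples — the same receptor seen
in two samples is two members — and groups are single-linkage connected
components of the pairwise match graph with at least two members. Candidate
pairs are enumerated only inside buckets of (V gene, length) and
(V gene, length ± 1) using one-position masks and deletion variants, which
reproduces the exhaustive all-pairs grouping (tested against an independent
edit-distance oracle) at near-linear cost. Group identifiers are
deterministic: rank by member count, ties by smallest member CDR3.

A group is *PD-specific* when it contains at least one member from patient
blood and one from patient CSF — receptors plausibly patrolling between the
periphery and the central nervous system in cases.

## Lineage evidence and embeddings

Clonotypes whose cells occupy several transcriptomic clusters are treated as
lineage evidence connecting those clusters. `shared_clonotypes()` reports
clonotypes covering a full target cluster set, with optional restriction to
a condition/tissue before evaluation; the restriction is exposed rather than
fixed because published counts of this kind rarely state the restriction
used. Clonotype centroids are arithmetic means of member-cell embedding
coordinates, optionally per cluster. `grid_composition()` divides an
embedding into $k \times k$ equal-width bins spanning the data range per
axis (right-closed last bin; a degenerate axis collapses to one bin with a
warning) and reports per-bin sample or condition composition. Trajectory or
embedding coordinates are consumed as input; the package computes none.

## HLA and epitope linkage

Candidate peptides are all 9-mer and 15-mer sliding windows (stride 1) of
the supplied proteins, after exact-sequence deduplication; windows containing
non-standard residues are dropped, and each peptide retains its source
accessions. Binding predictions are consumed, never computed: the binding
table schema (peptide, allele, score, rank percent, binder flag) is the
interface to external class I/II predictors, and 9-mers pair only with
class I alleles, 15-mers only with class II.

A specificity group links to an HLA allele when *every* sample contributing
a receptor to the group carries the allele and the group spans at least
`min_shared = 2` typed samples. Full containment with a two-sample floor is
the strictest operationalization of "strong sample sharing"; both knobs are
arguments. Binder peptides attach to each link via the binder flag, or via
`rank_percent <= rank_threshold` when a positive threshold is given — no
default cutoff is imposed because predictor rank conventions differ.

## The synthetic-data generator

`simulate_repertoire()` emulates the statistical structure the analyses
assume, with complete ground truth:

* **Cohort layout** — 8 case and 8 control blood samples, 6 case and 9
  control CSF samples by default, mirroring a typical two-compartment
  case/control immune-profiling cohort; 3000 cells per blood sample and 300
  per CSF sample by default (CSF yields far fewer T cells).
* **Clone-size laws** — controls draw clone sizes as $1 + \mathrm{Geom}(0.7)$;
  cases additionally place 5% of their cells in large clones of 20–150
  cells, a qualitative rendering of the heavier case expansion tail (the
  magnitudes are modeling choices, not measured values). A big-clone cell
  budget smaller than the minimum size 20 is bumped up to one minimum-size
  clone so the law's support is honored.
* **NA stratum** — 7% of cells are emitted as gamma/delta-only contig rows
  with no alpha-beta receptor.
* **CDR3s** — random sequences over the 20-letter alphabet with conserved
  C…F framing, lengths 10–20 with a mode near 14, as in human beta-chain
  repertoires. Planted motif families are single-substitution variants of a
  family center sharing one V gene; bridging families place members in both
  case blood and case CSF. At these lengths, accidental 1-edit collisions
  between random receptors and planted families have negligible probability,
  so planted memberships are exactly recoverable.
* **Lineage plants** — clonotypes whose cells are spread to cover a target
  cluster set (default five clonotypes over the three-cluster memory →
  transitional → effector path). All *non-planted* clonotypes keep one
  cluster per clonotype — clonal phenotypic coherence — which both reflects
  the strong cluster concordance of real clones and makes planted spans
  exactly identifiable.
* **HLA and epitopes** — per-sample allotypes drawn from a 12-allele pool,
  with planted group–allele co-carriage; toy proteins (synthetic stand-ins
  tagged as such) carry known epitope windows that are marked as binders in
  the generated binding table.

The generator does **not** model V(D)J recombination biology, sequencing
error, contig assembly ambiguity, transcriptome structure, or HLA linkage
disequilibrium. Passing recovery tests therefore demonstrates that the
pipeline's logic is exact on data matching its assumptions — not that those
assumptions hold in any real cohort.

## Numerical and testing choices

Root seeds fix everything: generator output is byte-identical across runs,
and resampling substreams are derived per iteration and group content. Unit
and property tests run the generator at a few hundred cells per sample and
the oracle-equivalence suites at 500–10,000 elements; these sizes were
chosen so the full suite exercises every code path on a single CPU in about
a minute while leaving planted-structure recovery exact. Known limitations:
the bin-paired Wilcoxon's conservativeness on small repertoires (above);
single-linkage grouping can chain distance-2 receptors through an
intermediate variant (inherent to the grouping rules); and full-containment
linkage is sensitive to missing HLA typing, which is why untyped samples are
dropped with an explicit warning rather than silently.
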