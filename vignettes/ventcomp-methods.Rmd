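---
title: "Comparative and population-genomic methods in ventcomp"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Comparative and population-genomic methods in ventcomp}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ventcomp)
```

`ventcomp` packages the comparative and population analyses that recur in
chromosome-level genome studies of deep-sea hydrothermal-vent annelids
(Pompeii worms and their relatives): orthology by reciprocal best hits,
amino-acid composition PCA across species, collagen Gly-X-Y repeat
scanning, screening for bacterial contamination among predicted proteins,
gene-family and GO enrichment, genome-wide and windowed genotype PCA with
observed heterozygosity and window trees, and orthology-anchored
macrosynteny. Every stage has a synthetic-data generator with known truth,
so the pipeline can be exercised and validated at desk scale without any
of the original sequencing data.

## Orthology: Smith–Waterman scores and reciprocal best hits

Protein pairs are scored with a Smith–Waterman local alignment under
BLOSUM62 and affine gaps, where a gap of length $L$ costs
`gap_open` $+ L \cdot$ `gap_extend` (defaults 11 and 1, the common
protein-search defaults; the original searches in this field are run with
`ssearch36` or DIAMOND, whose exact parameterisation varies). The unknown
residue `X` scores 0 against everything: masking a residue should neither
reward nor punish an alignment. The scorer is implemented in C++ and
checked against a brute-force dynamic-programming oracle written in pure R.

A pair $(a, b)$ is a reciprocal best hit (RBH) when $b$ is the unique
best-scoring partner of $a$ in the other proteome and vice versa. Ties for
the best score drop the gene rather than being broken arbitrarily: RBH is
used as an orthology proxy, and a gene whose best hit is ambiguous is not
trustworthy evidence. For more than two species, `consistent_rbh()` keeps
a candidate group only when every pairwise RBH relation among its members
holds — clique semantics. This is a deliberately conservative
approximation chosen because consistency-based RBH methods differ in
detail; a clique requirement can only lose groups relative to looser
definitions, never invent them.

Scores can also be imported from a 12-column tabular search output
(`scores_from_hit_table()`, bitscore column), so external search tools can
stand in for the built-in scorer at scale.

## Amino-acid composition and its PCA

The composition matrix uses a species-pair-averaged ("averaging of
averages") scheme: for each species pair, the per-species mean of the
per-protein amino-acid frequency vectors over that pair's orthologs is
computed; each species' final composition is the unweighted mean of its
per-pair averages. Restricting to orthologs shared by a pair controls for
gene-content differences between genomes; the second averaging keeps any
one partner species from dominating. Per-protein vectors are averaged
unweighted rather than length-pooled — short and long proteins count
equally — because the quantity of interest is the typical protein's
composition, not the residue pool; a `pooled = TRUE` option provides the
alternative, and in practice the two give very similar first axes.

PCA of the matrix is centred and unscaled (`prcomp` semantics). Sign
ambiguity of principal components is resolved deterministically: each
loading vector is flipped so that its largest-magnitude entry is positive.
A constant matrix yields zero scores and zero explained fractions rather
than an error. The dominant axis of such matrices tracks the GC content
of the codons encoding each amino acid; `amino_acid_gc_table()` computes
per-amino-acid mean codon GC from the standard genetic code with equal
codon weights (no codon-usage data required), which places Y, F, I, N, K
at the AT end and G, A, R, P at the GC end. On synthetic proteomes with a
planted GC-bias gradient, the correlation between PC1 loadings and this
table exceeds 0.8 in absolute value — that is the level at which the
qualitative claim "PC1 is a GC axis" is testable.

The tube-composition screen ranks proteins by Euclidean distance between
their amino-acid frequencies and a target composition over a residue
subset. The default target is the published biochemical composition of
the Pompeii worm's parchment tube: serine 25%, glycine 20.6%, alanine
11.8%. Distance is computed over exactly the targeted residues (S, G, A);
frequencies of the remaining residues are unconstrained.

`genome_windows()` supports the genome-overview track: GC fraction per
non-overlapping window ((G+C)/(A+C+G+T), N excluded; the last window of a
chromosome may be short) and the percentage of window bases covered by
the union of gene intervals. Intervals are 0-based half-open throughout
the package; VCF positions stay 1-based at the boundary.

## Collagen Gly-X-Y repeat scanning

Collagens are runs of Gly-Xaa-Yaa triplets; proline at the Y position
(hydroxylated in vivo) correlates with triple-helix thermal stability,
while proline at X does not. `scan_gxy()` counts a central G-X-Y triplet
only when its glycine sits inside a frame of four G's at spacing 3
(`Gxx·GXY·GxxG`): the two X/Y positions are only meaningful when the
glycine periodicity is locally intact. Overlapping frames all count, and
the proline fractions at X and Y are computed over counted triplets only
(the "proportion of repeats" convention). The flank requirement — one
frame glycine before and two after — is exposed as `flank_before` /
`flank_after` parameters, because the exact frame convention is the one
genuinely open choice in this analysis; the defaults are what the
accompanying generator (`simulate_collagen_protein()`) guarantees, which
constructs `flank + (G,X,Y)×(k+3) + flank` with glycine-free flanks so
that exactly `k` central triplets are counted. Real collagen-like
proteins of the scale reported for vent annelids (thousands of repeats)
are far beyond anything a random proteome produces: 50 consecutive frame
repeats never arise by chance in random sequence, which is what makes
`proteome_collagen_table(min_repeats = ...)` a meaningful screen.

## Bacterial-contamination screening

The decision rule is deliberately minimal: after removing hits to species
excluded a priori (typically the query species itself when it is already
in the search database, since self-hits would mask contaminants), a query
protein is called a putative bacterial contaminant iff it has **no**
significant metazoan hit and **at least one** significant bacterial hit,
with significance defined as e-value strictly below $10^{-20}$. Hits to
taxa outside Metazoa and Bacteria neither rescue nor condemn a query —
the rule names only those two groups, and extending it silently would
change its meaning. Queries with no hits at all are non-contaminant. A
`best_hit_only` mode restricts the rule to each query's single best
significant hit, for workflows phrased in terms of "bacterial best hits";
with well-separated e-values the two modes agree. The partition summary
(`partition_by_scaffold()`) splits calls by pseudo-chromosome membership,
the signature used to distinguish bacterial contigs from candidate
horizontal transfer: contaminants concentrating on unplaced scaffolds are
contigs, not integrated genes.

## Enrichment

Family enrichment between a focal species and a pooled comparator uses
the Pearson chi-squared statistic on the 2×2 table of family counts
against totals, 1 df, without continuity correction (the correction is a
small-sample conservatism not part of the classical test; a switch is
provided), and Benjamini–Hochberg control across all tested families at
$\alpha = 0.01$. "Significant" means adjusted $p < \alpha$; because the
chi-squared test is two-sided, the scan by default additionally requires
the focal proportion to exceed the pool proportion, matching the
"overrepresented families" framing under which such tables are reported.
GO-term enrichment of a study set against a population uses the one-sided
hypergeometric tail, optionally after propagating annotations to
ancestors along child→parent ontology edges (propagation is optional
because term-for-term semantics without propagation are also in wide
use). BH adjustment is `p.adjust(method = "BH")` behind the module
surface; the test suite pins it to the brute-force step-up definition.

## Population structure from resequencing data

Variant filtering reproduces standard practice for ~15× resequencing
data: biallelic SNPs only; site QUAL ≥ 30; every genotype's depth in
[5, 50]; no missing genotypes; and SNPs within 5 bp of an indel's
reference span removed (alignment artefacts concentrate next to indels).
Each rule's drop count is logged. Filters are applied independently, so
filtering is idempotent.

Global PCA operates on the samples × dosage matrix with sites mean
centred. Local PCA repeats this in windows (default 100 kb,
non-overlapping; the step is configurable because "sliding" windows are
sometimes overlapped). Each window's PC1 is sign-polarised so that its
correlation with the global PC1 sample scores is non-negative — PC sign
is arbitrary per window, and without polarisation window tracks are
uninterpretable. The alternative (chaining each window to the previous
one) propagates errors across low-information windows, so the global
anchor was preferred. Windows with fewer than 10 SNPs are flagged and
skipped: a 6-sample PCA on fewer sites is noise.

`window_assignment_score()` operationalises "this sample sits mid-way
between the two populations in this window": the focal sample's window
PC1 score is placed on the segment between the two population centroids
(computed without the focal sample), clipped to [0, 1]. An index near 0
is home-like, near 1 donor-like; 0.5 is the natural calling threshold for
introgressed windows. Observed heterozygosity is the pooled fraction of
genotype calls equal to dosage 1 (not a per-site average of per-sample
rates); pooling was chosen because with complete genotype matrices the
two definitions coincide up to weighting and the pooled form is the one
that decomposes cleanly by chromosome. Window trees use the
allele-sharing distance (mean per-site absolute dosage difference / 2,
so opposite homozygotes at every site give distance 1) and
neighbor-joining via `ape::nj`, with negative branch lengths clamped to
zero. Allele-sharing was chosen because it is model-free and additive in
expectation for diverged populations; on exactly additive matrices NJ
reproduces topology and branch lengths exactly.

## Macrosynteny

Oxford grids cross-tabulate RBH pairs by chromosome pair; the grid total
equals the number of positioned pairs by construction. Association
significance per cell uses the one-sided hypergeometric tail given the
margins with BH adjustment — the display-oriented tools in this area do
not define a test, and the hypergeometric on margins is the standard
choice for "more shared orthologs than expected". Ancestral linkage group
(ALG) painting transfers labels from an ALG-annotated reference through
the ortholog map; a chromosome carrying ≥ 2 ALGs with ≥ `min_genes`
(default 10) genes each is called a fusion, and one ALG dominating two
chromosomes is flagged as a split candidate — the signature of an
artefactual assembly break. The `min_genes` threshold is a package
choice: it must be large enough that stray mis-mapped orthologs cannot
fake a fusion, and 10 genes is far above the mis-assignment noise of RBH
maps at these scales.

## Synthetic data: what it emulates, and what it does not

The generators are pure functions of their parameters and a mandatory
seed.

* `simulate_proteome_family()` draws an ancestor i.i.d. over the 20
  amino acids and derives species by per-site substitution, with a
  per-species GC bias that tilts residue sampling along the codon-GC
  scale (weight $\propto \exp(\beta\,(gc_a - \overline{gc}))$). It
  emulates divergence and compositional drift, not insertions/deletions,
  domain shuffling, gene duplication or rate heterogeneity — so RBH
  recovery rates on it are upper bounds for messy real proteomes.
* `simulate_collagen_protein()` is constructive: the scan's answer is
  known exactly, making it a calibration object, not a model of real
  collagen evolution.
* `simulate_two_pop_genotypes()` uses the Balding–Nichols model:
  ancestral frequency $p \sim U(0.05, 0.95)$, population frequencies
  $\sim \mathrm{Beta}(p\frac{1-F}{F}, (1-p)\frac{1-F}{F})$, genotypes
  binomial. It was chosen as the minimal model producing PCA-separable
  populations with tunable divergence and heterozygosity. The default
  divergence is $F = 0.2$ (strong, consistent with populations that
  remain separated across a hybrid zone); the barrier chromosome uses a
  larger $F$ (default 0.6) and ancestral frequencies near fixation,
  which jointly depress heterozygosity — emulating a low-diversity
  chromosome acting as a barrier to gene flow. Introgression is planted
  as blocks in which one sample draws from the donor population's
  frequencies. There is no linkage, recombination map or coalescent
  structure: sites are independent given the frequencies, so
  window-level statistics are better behaved than in real data, and
  passing tests demonstrate correctness of the machinery, not power on
  real genomes.
* `simulate_hit_table()` and `simulate_family_annotations()` plant
  truth labels with configurable e-value ranges and fold enrichments;
  boundary cases (e-value exactly at the threshold) are constructible.

## Numerical and operating choices

* Problem sizes used in the test-suite and acceptance computations —
  50-gene proteomes at 0.2 substitutions/site, 10k SNPs for global PCA,
  40 windows × 200 SNPs for the introgression scan, 100 replicates for
  rate estimates, 200 null scans of 500 families — were chosen as the
  smallest sizes at which the statistical claims are crisp (e.g.
  chi-squared power ≈ 1 for a 10-fold effect at n ≈ 40, complete PCA
  separation at $F = 0.2$).
* Exact binomial 99% intervals are used to check simulated proline
  fractions; over many draws the *miss count*, not each draw, is the
  calibrated quantity.
* Degenerate inputs are defined, not errors, wherever a downstream stage
  can proceed: constant matrices give zero-score PCAs, zero-margin
  chi-squared tables give $p = 1$, empty hit sets classify as clean.
* Tie-breaks are deterministic everywhere (gene id ordering in ranked
  outputs, tie-drop in RBH, largest-loading sign convention in PCA), so
  identical inputs and seeds give byte-identical outputs.

## Limitations

The Gly-X-Y frame convention was fixed from the published pattern
(`GxxGXYGxxG`) and the constructive generator; calibrating it against a
deposited proteome's published repeat counts requires the deposition
itself and is left to users with the data in hand. The consistent-RBH
clique rule is stricter than some published consistency methods. The
contamination screen classifies; it does not adjudicate horizontal gene
transfer. H_obs and the hybrid index are defined on complete dosage
matrices only — run the filters first.
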