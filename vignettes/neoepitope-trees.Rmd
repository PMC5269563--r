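---
title: "Building cancer neo-epitope trees: models, assumptions and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Building cancer neo-epitope trees: models, assumptions and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(neoepitree)
```

## The problem

Tumors are mosaics of subclones. An immunotherapy that targets a
mutation-derived epitope carried by only one subclone leaves the others
free to grow, so target selection should be informed by where a mutation
sits in the tumor's clonal hierarchy: mutations in the founding ("trunk")
clone are carried by essentially all tumor cells, mutations in a large
descendant lineage ("major branch") by most. neoepitree composes the
analyses needed to produce that picture from a single tumor sample's
somatic mutation calls: germline-polymorphism filtering, neo-epitope
calling, subclonal phylogeny reconstruction, pathway-alteration
enrichment, and HPV genotyping/integration screening (cervical tumors
being the motivating tissue), integrated into a per-patient annotated
"neo-epitope tree" with a ranked target list.

## Population-panel filtering

Somatic callers leak germline polymorphisms. A variant is removed when
any supplied population panel (1000 Genomes-style TSVs of
chrom/pos/ref/alt/MAF) records its key at a minor allele frequency at or
above the threshold, default 0.1. Both the threshold and its strictness
are explicit arguments because reasonable pipelines disagree on whether
"present in a panel" alone should disqualify a call; the default removes
only common polymorphisms and keeps rare panel variants, which is the
behaviour most compatible with retaining genuinely somatic hotspot
mutations.

## Neo-epitope calling

For each missense mutation the mutated residue is extracted with eight
flanking residues per side — a 17-mer in the protein body, truncated at
termini. MHC class I presents 8–11-mers, so the caller slides fixed-length
windows (default 9) across the pair; mutant and wild-type windows always
share the same start coordinate. The mutation is called immunogenic when
some HLA allele and window satisfies both halves of the binding rule:

* mutant affinity < 50 nM (strong binder), and
* wild-type affinity > 500 nM (non-binder).

Affinities are IC50 nanomolar, lower meaning stronger, and come from a
pluggable `function(peptide, allele)` so any NetMHC-family tool can be
adapted. Whether the original analyses scored the 17-mer once or per
window is not documented anywhere we could verify; per-window scoring at
shared starts is the strictest reading of "the same peptide position" and
is what we implement. Patient HLA types are likewise an explicit input
(a three-allele fixture set by default) since they are rarely distributed
with mutation tables. Nonsense and indel mutations are never scored: the
rule is defined on single-residue substitutions.

The packaged predictor is a deterministic mock: a stable nonlinear hash
of (peptide, allele) mapped onto the nM scale, with region masses
calibrated so a designed fraction (default 55%) of missense mutations
passes the rule under the default window-by-allele grid. Two details
matter. First, purity: identical inputs give identical affinities, so
call sets are byte-reproducible. Second, linearity: a plain polynomial
hash would give mutant/wild-type windows (strings differing at exactly
one residue) a deterministic hash offset shared across alleles,
correlating grid events and biasing the realised fraction low; the mock
therefore re-hashes the digits of a first-round hash, which is nonlinear
and restores approximate independence. The calibration solves
`1 - (1 - q)^(windows x alleles) = fraction` for the per-pair success
mass `q` and splits it between the strong-binder and non-binder region
masses.

## Subclonal phylogeny

Under a diploid heterozygous model (no copy-number simulation or
correction — a deliberate scope decision), a mutation in a subclone of
cancer cell fraction $\phi$ in a tumor of purity $\rho$ has expected
variant allele fraction $\rho\phi/2$, so alt counts are
$\mathrm{Binomial}(d,\ \rho\phi/2)$. Reconstruction proceeds in two
stages:

1. **Clustering.** A finite binomial mixture over alt/depth counts is
   fitted by EM for $K = 1..6$, each with ten seeded restarts
   (first restart initialised at VAF quantiles, the rest randomised),
   and $K$ is chosen by BIC with $2K - 1$ free parameters. Mutations are
   hard-assigned to their maximum-responsibility cluster and clusters
   are relabelled `C1, C2, ...` by decreasing CCF, which makes all
   downstream output invariant to input order.
2. **Tree search.** All rooted trees over the clusters (a non-pathogenic
   normal root with CCF 1) are enumerated — at most a few thousand parent
   vectors for $K \le 6$ — and trees violating the prevalence sum rule
   `CCF(parent) >= sum(CCF(children)) - epsilon` are discarded
   (`epsilon = 0.05` absorbs binomial noise in fitted CCFs). Survivors
   are scored by the binomial likelihood of the read counts under
   constraint-projected CCFs and the maximum is returned, ties broken by
   lexicographic parent-vector order.

This replaces an MCMC sampler over tree-structured stick-breaking priors
with a deterministic, exhaustively checkable procedure. At the scale this
package targets (one to at most six subclones per tumor) the two
approaches explore the same decision surface, but the exhaustive search
is reproducible bit for bit and can be verified against brute force,
which the test suite does.

A genuine limitation surfaces here: a single sample cannot distinguish a
chain `C1 -> C2 -> C3` from the sibling split `C1 -> {C2, C3}` whenever
the children's CCFs also fit side by side under the parent — both
topologies then achieve the identical likelihood maximum. `fit_tree()`
therefore retains every maximum-likelihood-tying parent map in
`$ml_trees` alongside its deterministic selection; simulation recovery is
judged by membership in that set, and whenever the set is a singleton the
selection matches the simulated truth in our sweeps. Multi-region
sampling, not a better scorer, is what would resolve the remaining
ambiguity.

Clones are then labelled chronologically by depth: children of the normal
root are *ancestor* subclones, their children *descendants*, anything
deeper *later* — the vocabulary the epitope tree reuses as trunk/branch
tiers.

## Pathway enrichment

The per-pathway statistic is the number of patients whose
nonsynonymously mutated genes intersect the pathway. The null resamples
gene sets of the same size (after intersecting the pathway with the
universe) uniformly without replacement from the universe, 10,000 times
by default, and `p` is the proportion of draws with a strictly greater
patient count. Strict inequality follows the source definition of the
test; an add-one correction is available but off by default, and `p = 0`
is exported as `< 1/n_perm` in text output. The universe defaults to the
genes present in the supplied annotation and is overridable by file,
because "all genes in the genome" is a data choice, not a code choice.
Benjamini–Hochberg adjustment (via `stats::p.adjust`) runs across the
tested pathways — those with nonzero universe overlap — and significance
is adjusted `p < 0.1`.

The uniformity (calibration) check in the test suite runs at 200
synthetic patients rather than the 23 of the motivating cohort: with 23
patients the count statistic takes a handful of values and the
strict-tail p is too discrete for a Kolmogorov–Smirnov uniformity test to
be informative; the property under test is the validity of the
permutation machinery, not the cohort size.

## HPV genotyping and integration screening

References (a host contig and ~8 kb viral genomes) are small enough that
a naive seed-and-extend matcher suffices: exact 31-mer seeds at
overlapping read offsets against an indexed reference set, ungapped
extension at the implied offset, best reference by matched fraction,
both strands searched; below a matched fraction of 0.8 a read is
unmapped. Genotype counts consider only reads that fail to match the
host; integration evidence is a read pair with one end matching host and
the other an HPV genotype, both at or above threshold. Evidence stays at
pair granularity — no breakpoint refinement — because that is the
granularity the underlying claim ("pairs with one end in each genome")
supports. `k = 31` with 100 bp reads makes random seed collisions against
~44 kb of reference essentially impossible (expected rate well below
one in 10^9 per read), which is what drives the observed perfect
specificity; overlapping seeds every 15 bp keep the chance that every
seed straddles a 1% substitution error negligible.

## The synthetic cohort

The generator emulates the statistical shape of the motivating study:
23 tumors, Poisson-distributed mutation counts averaging 117 per tumor,
Poisson depths averaging 181X (floored at 10), purity 1 by default, one
to three subclones with pairwise CCF gaps of at least 0.15 under an
exactly enforced sum rule, consequence classes drawn at the cohort's
published mix (synonymous:nonsynonymous = 730:1934, with 18 deletions
and 9 insertions per 2691; missense 72% of nonsynonymous), a 55%
designed immunogenic fraction, 10% extra population-panel contaminants
per tumor (panel MAF above threshold) plus a 5% slice of true somatic
calls present in the panel below threshold, HPV read mixtures with
genotype weights 18:3:1 across HPV-16/18/33 and five chimeric pairs in
~74% of tumors. Mutations are split uniformly across clones (each clone
keeps at least one marker) and each clone's parent is drawn uniformly
among nodes with spare prevalence — both free parameters, as no
per-clone distribution is published. All randomness flows from one run
seed through hashed per-tumor substreams, so cohorts are byte-reproducible
and independent of evaluation order.

What the generator does *not* emulate — copy-number variation, subclonal
copy number, sequencing error in mutation calls, indel realism,
tumor-in-normal contamination, real HPV genome sequence (its references
are synthetic stand-ins under the real genotype names), and any
correlation structure between genes — bounds what passing tests show:
they demonstrate the pipeline recovers the truth of its own generative
model, not that it is robust to the full messiness of real exomes.
Ground truth (trees, clone assignments, immunogenic flags, injected
panel keys, chimeric pair ids) is emitted alongside the data, and the
truth immunogenic flags are by construction what the epitope caller
returns under the mock predictor.

## Numerical and degenerate-input choices

* Coordinates are 1-based and closed everywhere; `ref != alt`,
  `alt_count <= depth` and per-sample key uniqueness are enforced at
  every read.
* EM runs to a log-likelihood change below 1e-8 (max 500 iterations);
  component probabilities are clamped to `[1e-4, purity/2]`; empty
  components are dropped before relabelling.
* BIC decides K; a one-mutation tumor yields K = 1 trivially.
* Tree-search ties are exact (difference below 1e-9) and resolved
  lexicographically; the tie set is preserved.
* Simulated alt counts are floored at one read: a called somatic
  mutation with zero supporting reads is not a realisable input.
* Peptides shorter than the scoring window yield no windows and cannot
  be immunogenic; proteins absent from the proteome cause the mutation
  to be skipped and logged, not silently dropped.
* Percentages printed in summaries round half-up to one decimal, the
  convention that reproduces published recurrence percentages such as
  4/23 = 17.4%.

## Problem sizes in the test suite

The suite regenerates everything it tests: recovery sweeps use 100
tumors at 35 mutations per clone and depth 181; the epitope-rule
equivalence check scores 1,000 missense mutations against a brute-force
re-scan; HPV specificity is measured on 1,000 chimera-free pairs and
sensitivity on 100 chimeric pairs at 1% substitution noise; calibration
uses 500 null pathways at 250 permutations over a 2,000-gene universe;
and the determinism check runs the full 23-tumor pipeline twice and
compares every output byte. These sizes were chosen to give each
statistical assertion enough resolution while keeping a full check of
the package routine on a laptop.

## Known limitations

Single-sample phylogenies are ambiguous in the ways described above;
CCF estimation ignores copy number, so amplified loci would bias
prevalences in real data; the mock predictor shares nothing with real
MHC binding chemistry beyond its output scale and thresholds, so
biological conclusions require plugging in a real predictor; and the
enrichment test treats genes exchangeably, ignoring gene length and
mutability, which inflates significance for long-gene pathways on real
cohorts.
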