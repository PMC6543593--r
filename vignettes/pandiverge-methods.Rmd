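---
title: "Methods: pan-genome divergence analysis with pandiverge"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: pan-genome divergence analysis with pandiverge}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pandiverge)
```

# Scope and model

`pandiverge` implements the comparative-genomics workflow used to study
divergence and speciation within a bacterial genus (the motivating system is
the sulfur-oxidizing acidophile *Acidithiobacillus*): a 16S rRNA marker-gene
pipeline, whole-genome average nucleotide identity (ANI), ortholog
clustering into core/accessory/strain-specific gene families, pan-genome
rarefaction with Heaps'-law model fitting, Wagner-parsimony gene gain/loss
reconstruction, and composition-vector (CV) alignment-free phylogenomics.
Every stage can be exercised on synthetic clades with known ground truth, so
the pipeline is testable without downloading public genomes.

## Marker-gene pipeline

16S rRNA records are filtered to an inclusive near-full-length window
(default 1,300–1,550 bp) with exact-duplicate removal. The window bounds
are treated as inclusive; the redundancy rule is exact sequence identity —
clustering length variants of identical genes is a stricter alternative we
deliberately did not adopt, since it requires an arbitrary containment rule.

Pairwise distances use the Tamura–Nei (TN93) estimator, which separates
A&harr;G transitions (proportion $P_1$), C&harr;T transitions ($P_2$) and
transversions ($Q$) under unequal base frequencies:

$$ d = -k_1 \ln w_1 - k_2 \ln w_2 - k_3 \ln w_3, $$

with $w_1 = 1 - \frac{\pi_R P_1}{2\pi_A\pi_G} - \frac{Q}{2\pi_R}$ (and
symmetrically for pyrimidines), $w_3 = 1 - \frac{Q}{2\pi_R\pi_Y}$. Sites
with a gap or ambiguity in either sequence are excluded pairwise (complete
deletion would discard most sites on ragged public data). When any
logarithm argument is non-positive the estimator is saturated; the result
is an explicit `NA` sentinel carried through downstream tables, never a
silently dropped pair. In the equal-frequency, $P_1 = P_2$ limit the
estimator reduces to Kimura's two-parameter form, which the tests verify to
1e-12.

Substitution saturation is assessed per pair by comparing the transition
proportion $s = P_1 + P_2$ with the transversion proportion $v = Q$: an
alignment retaining phylogenetic signal shows transitions above
transversions; at stationarity (fully randomized sequences) transversions
dominate because twice as many base pairs are transversional. We
operationalize the classical visual test with a majority rule: the verdict
is `saturated` when at least half of pairs have $v \ge s$ (identical pairs
at $s = v = 0$ count as unsaturated). Xia's information-theoretic index is
out of scope.

Trees are built by neighbor joining on the TN93 (or CV) distance matrix.
NJ substitutes for a maximum-likelihood search: the likelihood heuristics
are outside this package's acceptance surface, while NJ on TN93 distances
preserves the substitution model and recovers any additive matrix exactly
(property-tested on random trees with n up to 12, branch lengths to 1e-9).
Negative branch lengths on non-additive input are clamped to zero with a
warning. Rooting on an outgroup splits the outgroup's pendant edge at its
midpoint.

## ANIb

Query genomes are cut into consecutive non-overlapping 1,020 bp fragments
(a trailing fragment is kept iff at least half a window — stated because
fragment counts affect the mean); each fragment is aligned to the subject
genome and accepted when the best hit reaches 30% identity over at least
70% of the fragment. ANI is the mean identity of accepted fragments; two
genomes are called the same species at ANI &ge; 95%. The BLASTN step of
classical ANIb is replaced by an in-package k-mer-seeded (k = 11, both
strands) local alignment of the fragment against the best seed-diagonal
window (match +1, mismatch −1, gap open −5, gap extend −2). At desk scale
(&le; 200 kb synthetic genomes) ANI is insensitive to aligner details at
the &plusmn;0.5% level tested. ANI is direction-dependent; both directions
are always reported along with their mean rather than silently averaged.

## Ortholog clustering

Genes whose annotation products match mobile-genetic-element keywords
(transposase, integrase, insertion sequence, IS family, phage, prophage,
recombinase; case-insensitive substrings) are excluded before clustering,
since lineage-specific MGE expansions distort family statistics. Clustering
is greedy centroid (USEARCH-style): proteins sorted by length descending
(ties by gene id) each join the first centroid reaching 50% global-alignment
identity with 50% coverage, else found a new family. Identity is matches
over alignment columns excluding terminal gaps (identity denominators
differ between tools, so ours is stated); coverage is aligned residue pairs
over the shorter length, a behavioral stand-in for the conventional BLAST
E-value cutoff, which we do not compute. The global length sort makes the
partition independent of genome input order. A shared-tetramer prefilter
(&ge; 2 shared 4-mers) skips hopeless centroid comparisons; at 40%+
identity the expected number of shared tetramers is far above the
threshold, so the prefilter is lossless where it matters. Paralogs
co-cluster, so pan-matrix cells may exceed 1; presence is thresholded at
&ge; 1. No manual-correction step is modeled: published pipelines that
"manually inspected" clusters give no reproducible rule.

## Pan-genome models

Rarefaction adds genomes in random orders (default 100 permutations;
exhaustive enumeration of all $N!$ orders is available up to 8 genomes) and
reports median pan and core sizes per added genome, following the standard
protocol of medians rather than means. The pan-genome curve is fitted by
Heaps' law, $P_s(n) = \kappa n^\gamma$, via least squares on the log-log
scale — deterministic and exact on noiseless power-law data. The core curve
is fitted by $F_c(n) = \kappa_c e^{-n/\tau_c} + \Omega$ with nonlinear
least squares from three documented starts (log-linear regression,
first/last two-point slope, flat start), polished by Nelder–Mead then BFGS
at relative tolerance 1e-12; both the two-parameter form ($\Omega = 0$, as
usually printed) and the three-parameter form are supported. A constant
core series makes the decay unidentifiable and returns the flat solution
explicitly. An exponent $0 < \gamma < 1$ classifies the pan-genome as open
(unbounded growth), $\gamma < 0$ as closed; the boundaries are reported as
`indeterminate` rather than silently assigned, since the convention is
silent there.

Published two-parameter core fits can be inconsistent with the printed
asymptotic core size (a two-parameter curve with the printed parameters
does not level off at the printed core count); this is expected when a
fitted offset $\Omega$ is omitted from the printed equation. The package
therefore supports both forms and makes no attempt to reconstruct an
unprinted offset.

## Gene turnover

Ancestral gene-family counts on the rooted reference tree are reconstructed
by Wagner (linear-cost) parsimony using Farris intervals: bottom-up, a
node's interval is the intersection of its children's intervals or the gap
between them; top-down, each node takes the value in its interval closest
to its parent. The root takes its interval's *minimum* — gains are counted
from the minimum number of family members at ancestral nodes. Equal
gain/loss costs are used (the method is named without costs); per-branch
gains and losses are summed family-count differences, and dividing by
branch length gives per-branch turnover rates, the free-rates analogue of
likelihood birth–death models, which are deliberately not reimplemented.
Zero-length branches yield `NA` rates with a warning. The implementation
requires a rooted binary tree (what `nj_tree()` + `root_by_outgroup()`
produce); polytomies raise an error rather than applying a generalized
median rule. Exhaustive enumeration on 500 random instances confirms the
reconstruction attains the minimum total change. Parsimony systematically
undercounts events on dense histories — it can never infer more change than
actually occurred — which the tests assert directly.

## Composition vectors

Each proteome is summarized by the frequencies of length-$K$ amino-acid
tuples (default $K = 6$; windows never span protein boundaries), minus a
$(K-2)$-order Markov background
$f_0(a_1..a_K) = f(a_1..a_{K-1}) f(a_2..a_K) / f(a_2..a_{K-1})$ that
absorbs compositional bias; components are $a(t) = (f - f_0)/f_0$ with
$a = 0$ where $f_0 = 0$. Distances are $(1 - \cos\theta)/2 \in [0, 1]$ over
the union of tuples (the originating web service does not state its
distance formula; this is the published CVTree convention). Protein mode
only; nucleotide-mode CV trees are out of scope.

# The synthetic clade generator

`simulate_clade()` produces a rooted Yule tree rescaled to unit height, a
gene gain/loss history (per branch: `Poisson(gain_rate * length)` new
families; each present family lost with probability
`1 - exp(-loss_rate * length)`; infinite-alleles, so a lost family is never
re-gained and the parsimony ground truth is well defined), a gapless marker
alignment evolved under closed-form TN93 transition probabilities, and
per-genome proteomes evolved from per-family ancestral proteins by i.i.d.
site substitution without indels, so within-family identity decays
analytically with tree distance. A seeded fraction of genes receives
MGE-like product strings for exclusion testing.

Defaults describe a small clade in the open-pan-genome regime: 10 genomes,
120 ancestral families, gain rate 30 and loss rate 0.1 per unit branch
length, a 1,500 bp marker at 0.05 substitutions/site per unit branch length
(16S-like divergence, transition-biased with rRNA-like base frequencies
(0.254, 0.229, 0.313, 0.204) and transition factors 2 (A&harr;G) and 4
(C&harr;T)), 120-residue proteins with identity decay 0.15 per unit branch
length (within-family identity roughly 74–97%, comfortably above the 50%
clustering cutoff), and 5% MGE-labelled genes. These are plausible
desk-scale stand-ins, not estimates from any particular dataset.

What the generator does *not* emulate: indels and alignment error,
rearrangements, intragenomic 16S heterogeneity, horizontal transfer of
*existing* families (re-gain), plasmids, and paralog expansion. A green
test therefore establishes algorithmic correctness against a clean known
truth, not robustness to every artifact of real survey data.

Reproducibility: the seed is part of the configuration and each simulation
stage derives its stream from it, so identical configurations give
byte-identical outputs.

# Numerical and design choices

- Undefined quantities (saturated TN93 pairs, ANI with no accepted
  fragments, rates on zero-length branches) are explicit `NA` sentinels.
- Out-of-alphabet residues are replaced (`N`/`X`) with a warning on read,
  not rejected: public marker data is dirty.
- The topology-recovery property for CV/NJ is evaluated on trees whose
  internal branches are all at least 2% of the tree height: a branch
  carrying no substitutions is unresolvable by any method, so replicates
  without divergence spread would measure the tree prior, not the method.
- Scaled-down property checks: the law-of-large-numbers check for CV
  deviations runs at ~2 &times; 10^5 residues and the TN93 consistency
  check at 20 kb (5% tolerance); both scale with budget, not with the
  method.

# Worked example

```{r example, eval = FALSE}
cfg <- sim_config(n_genomes = 10, seed = 1)
clade <- simulate_clade(cfg)

og  <- cluster_orthogroups(clade$proteomes,
                           exclude = flag_mge(clade$annotations))
pan <- build_pan_matrix(og, names(clade$proteomes))
partition_pangenome(pan)

rc  <- rarefaction_curves(pan, n_permutations = 100, seed = 1)
fit <- fit_power_law(rc)
classify_openness(fit)
autoplot(rc, power_fit = fit, core_fit = fit_core_exponential(rc))

turn <- gene_turnover(clade$tree, pan)
tidy(turn)
```

# Known limitations

- The greedy clustering is a single-linkage-free heuristic: families whose
  members straddle the identity cutoff asymmetrically may split; no
  Markov-cluster refinement is attempted.
- ANI values at desk scale rest on a seeded heuristic aligner; they are not
  expected to match BLAST-based services beyond ~0.5 percentage points.
- Parsimony turnover underestimates event counts when multiple events per
  family per branch are common; rates should be read comparatively, not as
  absolute birth–death estimates.
- The marker pipeline takes an alignment as input; multiple sequence
  alignment itself (and ML tree search, bootstrap support, ANIm,
  database-driven functional annotation) is out of scope.
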