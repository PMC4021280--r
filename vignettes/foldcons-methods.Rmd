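---
title: "Methods: structural sensitivity and conservation of synonymous sites"
author: "foldcons"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: structural sensitivity and conservation of synonymous sites}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The question and the two per-site scores

Functional mRNA secondary structure constrains coding-sequence evolution: if
a synonymous mutation would disrupt a local structural element, purifying
selection should remove it, and such *structurally sensitive* sites should
show less divergence across species than structurally inert ones. `foldcons`
quantifies both properties per site and tests their association. The
analysis is restricted to 4-fold degenerate third codon positions (codon
families GCN, CGN, GGN, CTN, CCN, TCN, ACN, GTN), where every substitution
is synonymous, so protein-level selection cannot confound the signal.

**Conservation** of a site is the weighted entropy of its alignment column,

$$E_w = -\sum_{i \in N} p_i \log_2 p_i,$$

where $p_i$ is the weighted fraction of orthologs carrying nucleotide $i$.
The weights are *equal-split* phylogenetic weights: each branch length of
the species tree is divided equally among its descendant leaves, a leaf's
raw weight is the sum of its shares, and weights normalize to one. This
down-weights clusters of close relatives, so a nucleotide shared only
within one clade does not masquerade as deep conservation. $E_w = 0$ means
an invariant column; 2 bits is the maximum. Sites with $E_w < 0.5$
(strictly) are classified conserved. We render the tool-defined weighting
of the original workflow as the equal-split measure because it is exactly
reproducible from topology and branch lengths alone.

Gapped rows are excluded from a column and the remaining weights
renormalized, which preserves $\sum p_i = 1$ and the $[0, 2]$ range; a
gap is evidence of alignment uncertainty, not of a fifth character state.
Columns that are entirely gaps are undefined and dropped. Sites whose
orthologs have gaps are kept (only the reference row defines sites).

**Structural sensitivity** of a site is a mutation scan. The local window
(`flank` nucleotides each side, clipped at the ends) is folded once for the
wild type and once for each of the three possible point mutations, giving
base-pair probability matrices $P$. One mutation's disruption is

$$d_{max} = \max_{[a,b]:\, b-a+1 \ge \ell} \frac{1}{b-a+1}
\sqrt{\sum_{a \le i < j \le b} (P^{wt}_{ij} - P^{mut}_{ij})^2},$$

the length-normalized Euclidean distance between the two pairing ensembles,
maximized over subintervals of length at least $\ell$ (`d_min_span`,
default 10 nt). Normalizing per interval keeps a short, completely
rearranged hairpin visible next to a long unchanged context — the locality
idea behind SNP-screening folding tools. The site's sensitivity is the
arithmetic mean of its three $d_{max}$ values, and a site is *sensitive*
when the mean exceeds 0.1 (strictly). Because our locality convention sets
its own scale, the cutoff is also exposed as a calibratable quantile
(`calibrate_sensitivity_cutoff()` picks the cutoff giving a target
sensitive fraction); with the defaults the literal 0.1 yields median
per-gene sensitive fractions around 18% on random coding sequences, below
the ~25% plausibility bound implied by the rule of thumb that fewer than
8–9% of point mutations are structurally disruptive.

## The folding engine

Pair probabilities come from an exact McCaskill inside–outside dynamic
program over all nested secondary structures with canonical pairs (AU/AT,
GC, GU/GT) and hairpin loops of at least `min_hairpin = 3` unpaired bases.
The energy model (`simple_stack`) assigns one free energy per pair type
(defaults $-2$, $-3$, $-1$ kcal/mol for AU, GC, GU) plus a stacking bonus
($-1$ kcal/mol) when a pair sits directly on another, with Boltzmann
factors $e^{-E/RT}$ at 310.15 K. This is deliberately simpler than a full
nearest-neighbour parameter set: the downstream statistic depends on
probability *differences* between wild type and mutant, not on absolute
folding accuracy, and a compact model keeps an exhaustive enumeration
oracle feasible (the test suite verifies the dynamic program against
brute-force enumeration to $10^{-10}$ for all sequences up to 20 nt).
Partition functions are rescaled per nucleotide adaptively, so long or very
stable windows (e.g. 400-nt GC-rich contexts) do not overflow; probabilities
are scale-invariant. Pseudoknots and suboptimal-structure statistics beyond
pair probabilities are out of scope.

`fold_params()` defaults to `flank = 200` nt of context, a typical
local-fold setting; the simulator and pipeline default to 60 nt, which
keeps the mutation scan near-interactive while still covering hairpin-scale
structure. Simulation studies in the test suite use 40 nt, their documented
study condition.

## Association statistics

Per gene, sites are cross-classified sensitive/non-sensitive $\times$
conserved/non-conserved (both cutoffs strict) into a 2x2 table
$(a_i, b_i, c_i, d_i)$, and the tables combine across genes by the
Mantel–Haenszel procedure,

$$OR_{MH} = \frac{\sum_i a_i d_i / s_i}{\sum_i b_i c_i / s_i},$$

with the continuity-corrected MH chi-square (correction not applied past
zero), a two-sided p-value from the 1-df chi-square tail, and a 95% CI from
the Robins–Breslow–Greenland variance of $\log OR_{MH}$. Strata with fewer
than two sites are skipped and counted. The implementation is by the
formulas above; the test suite cross-checks statistic, p and CI against
`stats::mantelhaen.test(correct = TRUE)` to $10^{-10}$ on random strata.
$OR_{MH} > 1$ means sensitive sites are more often conserved.

Three refinements reuse the same machinery:

* **Stratified reruns** split genes at the median of expression or of ENC'
  (`median_split`: stable ordering by value then gene id, the lower half
  takes any extra gene) and report each half separately. For ENC' the
  interesting half is the *lowest* values (strongest codon bias); the
  output labels this mapping explicitly.
* **Sliding windows** (36 nt, step 12, starts up to 109, i.e. 10 windows;
  or 45/15/121 for 9) rerun the MH combination on the sites inside each
  window; a site belongs to every window covering it, since the overlapping
  design implies multi-membership.
* **Regional tests** restrict to nucleotides 1–60 (translation initiation)
  or 91–150 (elongation).

**The constrained permutation test** uses both scores continuously. The
statistic is the mean over genes of the per-gene Pearson correlation
between sensitivity and $E_w$; its null distribution reshuffles, within
each gene, the $E_w$ values only among sites sharing the same reference
nucleotide (classes with fewer than two sites are fixed points). The
constraint preserves each gene's amino acid sequence, codon usage and
nucleotide composition, so compositional covariates cannot manufacture a
signal. The p-value is left-tailed (the alternative is a *negative* mean
correlation) and uses the add-one estimator
$p = (1 + \#\{\bar r^{perm} \le \bar r^{obs}\})/(1 + B)$, which is a valid
test at finite $B$ and can never return zero. Genes need at least three
usable sites and variance in both scores; exclusions are counted, never
silent. "Identical nucleotide" is taken as the reference-species
nucleotide — it is the quantity that also drives the folding, and the
per-site interface records it; a consensus-based variant would need the
full column composition and is not provided.

## ENC' (codon bias)

Wright-style effective number of codons with the homozygosity statistic
replaced by a chi-square deviation from background-derived expected codon
frequencies: for a family with $k$ codons and $n$ observations,
$X^2 = n \sum_i (p_i - e_i)^2 / e_i$ and $F' = (X^2 + n - k)/(k(n-1))$,
with $ENC' = 2 + 9/\bar F'_2 + 1/\bar F'_3 + 5/\bar F'_4 + 3/\bar F'_6$,
a missing 3-fold class interpolated as $(\bar F'_2 + \bar F'_4)/2$, and
clipping to $[20, 61]$. The background is the gene's own overall
nucleotide composition (simplest defensible choice; `background = "third"`
restricts it to third positions), and expected family frequencies are
products of background frequencies over the positions at which the
family's codons differ, renormalized within the family. Class averages are
count-weighted by default (`averaging = "family"` gives the unweighted
variant; published formulations differ in this detail). Families with
fewer than two observations, or with non-positive $F'$ (possible when $n <
k$), are dropped. Under a uniform background the statistic reduces exactly
to Wright's classic ENC, which the test suite verifies against an
independent homozygosity-based implementation.

## The synthetic-data generator

The generator produces data with precisely the statistical structure the
analysis assumes, plus one planted, tunable coupling:

1. A rooted binary tree over `sp1..spN` (Yule or balanced topology), branch
   lengths i.i.d. exponential with mean `branch_scale` (default 0.15
   expected substitutions/site over 8 species — a moderately diverged
   ortholog panel).
2. Per gene, a random in-frame root CDS (ATG start, stop-free, G+C bias
   0.5, 150 codons by default), whose 4-fold sites are scored by the
   folding engine exactly as in the analysis.
3. Planted rates: non-sensitive 4-fold sites evolve at `syn_rate_mean`
   (default 1 per unit branch length, chosen so a typical site sees on the
   order of one substitution opportunity across the tree and the conserved
   fraction sits near 40% — informative contrast on both sides of the 0.5
   bit cutoff); sensitive sites at `syn_rate_mean / (1 + effect_beta)`.
   `effect_beta = 0` makes all 4-fold rates equal, so site labels are
   exchangeable and the permutation null holds exactly; increasing `beta`
   maps monotonically to larger expected log odds ratios. An optional
   region restricts the effect (e.g. to nucleotides 1–60) for the
   5'-pattern experiments.
4. Evolution along each branch is a single draw per site: substitution
   probability $1 - e^{-rt}$, then a uniform choice among the three
   alternative nucleotides. All non-4-fold positions are frozen, so the
   protein is invariant and alignments are gap-free by construction. The
   single-draw model ignores multiple hits within one branch; at
   `branch_scale` $\le$ 0.3 the discrepancy from a full continuous-time
   chain is negligible, and in exchange the two-leaf divergence has a
   closed form the tests verify by simulation.
5. Log-normal expression values (meanlog 0, sdlog 1).

The focal species `sp1` carries the root CDS itself (its terminal branch is
frozen). This makes the planted truth and the analysis agree exactly — the
labels were computed from the very sequence the analysis folds — and it
makes replication cheap: `resimulate_alignments()` redraws only the
substitution process, and `set_planted_effect()` changes `beta` without
refolding, so a 1,000-replicate calibration study folds each gene exactly
once. Under the null this costs no generality (all 4-fold sites of a
nucleotide class remain exchangeable).

What the generator does *not* emulate: indels and alignment error, codon
models with transition/transversion or nonsynonymous dynamics, selection
heterogeneity beyond the planted effect, expression measured with noise,
and any correlation between expression and codon bias. Passing tests
demonstrate that the statistics are calibrated and directionally correct
under the stated generative model, not that real genomes satisfy that
model.

## Reproducibility and numerical choices

Every stochastic function takes an explicit seed; one master seed derives
per-gene substreams by counter-style splitting, so individual genes are
reproducible independently and results do not depend on iteration order.
Seeds are forced before the generator snapshots the caller's RNG state, so
constructs like `seed = sample.int(...)` behave correctly. Ties in
`median_split` break by gene id; both classification cutoffs are strict at
the boundary; IEEE negative zero is normalized in entropy output. The
dynamic programs (folding, and the prefix-sum interval scan inside
`d_max`) are exact, not heuristic, and each is tested against a
brute-force oracle.

Problem sizes used by the packaged checks: folding-oracle equivalence on
200 random sequences up to 20 nt; null calibration on 50 genes x 100
codons x 8 species with 1,000 evolution replicates (type-I error of the MH
test within [0.035, 0.065] at $\alpha = 0.05$) and 200 datasets for
permutation-p uniformity (200 permutations each); power and 5'-pattern
recovery at `beta = 4` over 100 and 50 replicates. Full dataset generation
at the documented defaults (200 genes x 150 codons, flank 60) is dominated
by folding and takes a few minutes on one CPU; `flank = 40` roughly halves
it.

## Known limitations

* The sensitivity scale is tied to this package's locality convention
  (`d_min_span`, interval normalization); absolute values are not
  comparable to other tools' disruption scores, only the induced ranking
  and the calibrated cutoff are.
* The simple_stack energy model reproduces ensemble *shape*, not
  thermodynamic accuracy; stems of real mRNAs will differ in detail.
* Equal-split weights are one defensible rendering of tree-aware sequence
  weighting; other weighting schemes change $E_w$ slightly but not its
  invariances.
* The MH test treats genes as independent strata; shared phylogenetic
  error across genes is not modelled (the permutation test's within-gene
  constraint is the mitigation).
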