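---
title: "Feed-forward loops in the CRP regulon: census, dose-response profiles and functional groups"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Feed-forward loops in the CRP regulon}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crpffl)
library(dplyr)
```

## The problem

The cAMP receptor protein (CRP) is a global *Escherichia coli*
transcription factor: when intracellular cAMP rises, the cAMP--CRP complex
regulates several hundred genes, many of them through feed-forward loops
(FFLs) in which CRP (X) regulates an intermediate TF (Y) and both regulate
a target gene (Z). With signed edges (activation $+1$, repression $-1$)
there are eight FFL wiring types. A loop is *coherent* when the direct
sign equals the product of the two indirect signs,

$$s_{XZ} = s_{XY}\, s_{YZ},$$

and *incoherent* otherwise, giving Coh1--Coh4 and InCoh1--InCoh4. Targets
regulated by exactly one CRP-regulated TF sit in single-Y loops (sFFLs);
targets reached through two or more such TFs sit in multi-Y loops
(mFFLs). `crpffl` implements the full analysis chain for this setting:
signing an interaction table, enumerating and classifying every loop
through a master TF, turning a dose-response expression matrix into
per-gene log2 fold-change profiles, filtering, clustering, shape
labelling, functional-group merging and hypergeometric term
over-representation -- plus seeded generators that make each stage
testable without any external download.

## Signing the network

Interaction tables in the RegulonDB/EcoCyc style carry an effect per
(regulator, target) row. `build_network()` resolves each distinct ordered
pair to a single sign. Pairs whose records are dual or unknown carry no
usable sign and are excluded, as are pairs with *conflicting*
activation/repression records: a conflict is semantically the same
situation as a recorded dual regulator, so it is excluded under the same
rule rather than resolved by majority. The excluded-pair ledger and the
resolved edge map always partition the distinct input pairs, which the
test suite asserts as an invariant. Evidence filtering
(`min_evidence = "strong"`) is available but off by default, since both
strong and weak evidence classes are accepted by the source databases;
we found no principled reason to down-weight weak records and therefore
expose the switch without changing the default.

Identifier matching is case-insensitive while display casing is
preserved: gene symbols are printed case-sensitively but databases mix
cases, and silently treating `CRP` and `crp` as different nodes is a much
worse failure mode than folding them together.

## Enumerating and classifying loops

`enumerate_ffls()` considers every ordered pair (Y, Z) with Y in the TF
set: an instance exists exactly when the three signed edges X→Y, Y→Z and
X→Z are all resolved. Self-loops are ignored (a triangle needs three
distinct nodes) and a Z that is itself a TF is a legitimate target -- the
published census contains TF targets such as *gadX* and *mtlR*. The
classifier is the eight-row sign table above; a property test checks on
every enumerated instance that the label's coherence agrees with the
sign-product predicate, and the whole enumeration is checked against an
independently written brute-force triple scan on one hundred random
signed networks.

Y-arity (single-Y versus multi-Y) is computed per target across **all**
types jointly: a gene appearing in triangles of two types is one target
regulated by two CRP-regulated TFs, so it is a multi-Y gene. This is the
reading under which the single/multi split of the packaged census table
is well defined.

### The packaged census table and a printed-number discrepancy

`read_crp_census()` ships the published census of 202 CRP-anchored
loops as printed: per-type instance lists with duplicates preserved. Its
arithmetic reproduces the published totals -- 202 instances, 147 distinct
genes, 87 InCoh1 loops, 10 distinct Coh2 genes, and 34% of the 432
CRP-regulated genes engaged in loops. One printed claim does **not**
follow from the printed lists: the text reports a 101/101 single-Y/multi-Y
instance split, while gene multiplicity over the printed lists yields
103/99 (and, relatedly, the printed multi-Y gene counts per group sum to
45 where the lists imply 44). `fixture_stats()` reports what the lists
imply rather than forcing agreement with the headline split; the
corresponding acceptance test records the published numbers and is
expected to flag this discrepancy.

## Dose-response profiles and the responsiveness filter

Expression is measured on a log2 scale over the cAMP dose grid 0, 0.01,
0.03, 0.1, 0.3, 1, 3, 10 mM, in duplicate. For each gene and positive
dose $d$,

$$\mathrm{log_2FC}(d) = \overline{x}_{d} - \overline{x}_{0},$$

replicates averaged on the log2 scale before the ratio. Missing values
are rejected at validation, never imputed. A gene passes the
responsiveness filter when $\max_d |\mathrm{log_2FC}(d)| \ge 0.5$; the
boundary is inclusive (the filter removes genes *below* 0.5), and the
default "any dose" criterion drops a gene only when every dose is
sub-threshold. A stricter "all doses" mode is exposed as a configuration
switch because the two published phrasings of the rule differ slightly;
"any" is the reading consistent with dropping only uniformly flat genes.

## Clustering, shapes and functional groups

Profiles are compared by Pearson correlation distance $1 - r$, so two
genes with the same shape at different amplitudes are close -- the right
notion of similarity for dose-response *patterns*. A zero-variance
profile carries no shape information; its distance to anything is defined
as 1 and logged. Agglomerative clustering uses average linkage, and the
tree is cut to a fixed number of flat groups: 5 for single-Y targets and
6 for multi-Y targets by default. These defaults are the group counts the
reference analysis settled on; since no selection criterion for "the
optimal number of clusters" is published, k is an explicit parameter
rather than something the package silently optimises. Determinism is
enforced by sorting genes lexicographically before clustering and by
relabelling groups 1..k by descending size (ties by smallest gene name),
so outputs are byte-stable under permutation of the input.

Group mean profiles are labelled with one of five canonical shapes,
rules evaluated in order: *bell* (unique interior maximum, both ends at
least 0.5 log2 units below the peak -- expression peaking near 0.1--0.3
mM), *inverse bell*, *monotone down* (non-increasing within a 0.1
tolerance, total drop at least 0.5 -- log-linear repression), *sigmoid
threshold* (non-decreasing with at least 70% of the rise at doses
$\ge$ 0.3 mM -- switch-like catabolite-repression behaviour), and
*saturating up* (non-decreasing with at least half the rise reached by
0.1 mM, plateauing around 1 mM -- trace-cAMP activation, the TCA-cycle
pattern), else *unclassified*. The 0.5 span, 0.1 tolerance, 70%/50%
fractions and the 0.1/0.3 mM anchors are package choices pinned to the
dose landmarks the underlying biology names (a 0.3 mM switch point, a
0.1--0.3 mM peak, a 1 mM plateau); all are arguments to `label_shape()`.
The relative-rise rules are invariant to additive offsets and positive
rescaling; the two span-based rules are deliberately anchored to the
absolute 0.5 log2 scale of the responsiveness filter.

Single-Y and multi-Y group sets are merged into functional groups by
mean-profile correlation: every SG group seeds a functional group, each
MG group joins the best-correlated SG group if $r \ge 0.8$, and MG groups
that attach nowhere either join an already-formed functional group by
the same rule or seed their own. The 0.8 floor operationalises "similar
profiles", which is otherwise unquantified; it sits well above chance
correlation on seven-point curves yet below the within-shape correlations
(~0.99) observed on synthetic data. The published SG/MG *numbering*
cannot be recovered from printed material and is not claimed; labels here
are size-ordered.

Because one gene can sit in several loops, the package clusters *genes*
(each distinct responsive target once) and then annotates every loop
instance with its gene's group, rather than clustering instances -- the
alternative would weight a gene's profile by its loop count. A
`cohesion` statistic (mean pairwise $r$ within a group) is reported so
the tightness claims that motivated the reference grouping can be checked
on synthetic data.

## Enrichment

Over-representation of a term with $K$ carriers in an $N$-gene universe,
observing $k$ carriers in an $n$-gene group, is the upper-tail
hypergeometric probability $P(X \ge k)$, computed with `stats::phyper`
and cross-checked in the tests against the one-sided exact test on the
same margins. Significance is raw $p \le 0.01$ with no multiple-testing
correction by default, matching the published rule; Bonferroni and
Benjamini-Hochberg switches exist but are off. The default universe is
the gene set of the expression matrix, the natural background for an
array experiment; it is overridable. When annotations carry a namespace
column only the biological-process namespace is consulted. True-path
propagation (`propagate_annotations()`) closes gene-term sets under an
acyclic parent relation so leaf annotations count toward ancestors.

## What the synthetic generators emulate

`generate_network()` plants a requested per-type loop composition around
a master TF: each planted loop gets a fresh intermediate TF, and with
probability `multi_y_fraction` it reuses an existing target with a
compatible master-edge sign, creating multi-Y genes. Decoy edges are
constrained -- by a structural check on the three roles an edge could
play in a triangle, not by re-running the enumerator -- never to complete
an unplanned loop, so the planted ledger is exact ground truth; an
unconstrained decoy mode exists for stress-testing enumeration against
the brute-force oracle.

`generate_expression()` emits `baseline + curve + noise` with one
deterministic base curve per shape (exponential saturation with a 0.05 mM
scale; a Hill-type sigmoid centred at 0.3 mM; a log10-linear decline from
0.01 mM; a log-Gaussian bell centred at 0.2 mM; its mirror), i.i.d.
Gaussian noise per replicate on the log2 scale, and duplicate arrays by
default. The default study conditions used throughout the tests are
amplitude 2 log2 units, noise sd 0.1 and 8 genes per shape -- a clearly
responsive regulon measured on a quiet array. These curves emulate the
*shapes and dose landmarks* of real dose-response data; they do not
emulate probe-level effects, heteroscedastic noise, correlated replicate
error, or genes whose shape sits between archetypes. Passing recovery
tests therefore demonstrates that the chain of methods is implemented
correctly and is well-conditioned under realistic signal-to-noise, not
that real microarray data would cluster this cleanly.

`generate_annotations()` plants one designated term per gene group at
`enrich_factor` times a background annotation rate (defaults: factor 5
over rate 0.1 in a 500-gene universe), the regime in which the
hypergeometric test at $p \le 0.01$ detects the planted term in well
over 90% of replicates.

## Numerical and design choices, in brief

* Effect-token parsing is case-insensitive and accepts symbol forms
  (`+`, `-`, `+-`); unrecognised tokens become `unknown` with a warning
  rather than an error, so one bad row cannot silence a whole table.
* Conflicting signs for one pair are excluded as dual, never resolved by
  vote; the ledger records the reason per pair.
* `hierarchical_groups()` errors when `k` exceeds the profile count;
  `run_pipeline()` caps each split's k at its gene count so small
  synthetic runs work end to end.
* Ties everywhere break lexicographically; all outputs are byte-stable
  across reruns, which the pipeline tests assert literally.
* Problem sizes in the tests (networks up to ~50 nodes for oracle
  equivalence, 40-gene expression sets, 20 clustering and 50 enrichment
  replicates, complete hypergeometric margin sweeps for universes up to
  15 with random margins up to 60) were chosen as the smallest sizes at
  which the checked properties are non-trivial.

## Known limitations

* The package starts from a normalised gene-level log2 matrix; probe
  summarisation and RMA normalisation are upstream concerns.
* No motif-significance testing against randomised networks and no
  kinetic simulation of loop dynamics.
* The published clustering memberships and enrichment p-values are not
  reproducible from printed material (the microarray was not deposited
  and GO results depend on the annotation release); the package
  reproduces the published *combinatorial* results exactly and validates
  the statistical machinery on synthetic data instead.
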