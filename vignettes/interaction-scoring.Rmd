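---
title: "Scoring interspecific molecular interactions in a microbiome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring interspecific molecular interactions in a microbiome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(interflora)
```

## The model

Metabolic hand-offs between different bacterial species leave two
complementary statistical footprints in community sequencing data. If an
enzyme pair (A, B) sits on adjacent steps of a pathway but the reaction is
split *between* species, then (i) the genera that carry A tend not to
carry B — their **phylogenetic profiles** (binary genus-presence vectors)
anti-correlate — and (ii) the two functions must still meet in the same
gut, so their **co-occurrence profiles** (relative abundance across
donors) correlate positively.

`interflora` scores every pathway-adjacent KO pair by the product

$$ S = D \cdot R, \qquad D = \frac{1 - \phi(p_A, p_B)}{2}, $$

where $\phi$ is the phi (Pearson) correlation of the binary genus
profiles, $D \in [0, 1]$ is the phylogenetic dissimilarity, and $R$ is
the Pearson (optionally Spearman) correlation of the two KOs'
sample-abundance profiles. $S \ge \tau$ with $\tau = 0.6$ flags a
candidate interspecific interaction pair.

The candidate universe comes from the KEGG pathway network: KGML maps are
parsed ([parse_kgml()]), merged into one undirected KO graph over `ECrel`
and `maplink` relations ([build_graph()]), and each edge that carries at
least one intermediate compound becomes a scored pair
([enumerate_pairs()]).

### Why $D = (1 - r)/2$

An "inverse correlation" signal needs a dissimilarity that is bounded,
monotone decreasing in $r$, and maximal for perfect complementarity.
A literal reciprocal $1/r$ is unbounded and changes sign, which is
incompatible with a fixed decision threshold on the product score.
$D = (1-r)/2$ maps $r \in [-1, 1]$ onto $[0, 1]$, makes $S \in [-1, 1]$,
and places the working threshold $\tau = 0.6$ inside the meaningful range
(it then requires simultaneously $D \gtrsim 0.8$ and $R \gtrsim 0.75$).
`one_minus_r` ($D = 1-r$) and `neg_r` ($D = -r$) are available for
sensitivity analyses; all statements about bounds in the documentation
refer to the default.

### Tunable parameters

| parameter | default | meaning |
|---|---|---|
| `presence_epsilon` | 0 | genus-level abundance strictly above this counts as presence (dimensionless relative abundance) |
| `tau` | 0.6 | score threshold, inclusive ($S \ge \tau$); `strict = TRUE` for $S > \tau$ |
| `mode` | `half_one_minus_r` | dissimilarity map |
| `cooccurrence` | `pearson` | abundance correlation; `spearman` for rank-based |
| `window_width` | 0.1 | score-window width for the module-linkage validation |
| `common_fraction` | 0.9 | donor-presence fraction above which a genus pair counts as "common to almost all individuals" |
| `edge_min_aggregate` | 15 | minimum within-cluster aggregate score for a displayed network edge |
| `detect_rate` | 0.9 | per-KO detection prevalence defining donor KO universes |

Undefined correlations (a KO present in every genus, or with constant
abundance) do not get an imputed value: the pair is carried with
`defined = FALSE` and excluded from thresholded output. Exclusion is
conservative — there is no evidence for or against interaction — and the
skip count is reported.

The threshold comparison is inclusive ($\ge \tau$) because the selection
step is described as "a score of 0.6 or higher"; a strict flag exists
because the validation narrative also uses "> 0.6".

## Validation analyses

Two internal consistency checks accompany the score.

**Boundary pairs.** Transporter and channel proteins are the interface
between intracellular and extracellular metabolism. A producer enzyme on
a metabolic map, linked through a shared compound to an uptake KO that
occurs only on the transporter maps (ABC transporters 02010,
two-component system 02020, phosphotransferase system 02060), forms a
*metabolic–non-metabolic* boundary pair; pairs wholly inside metabolic
maps are *metabolic–metabolic*. If the score means what it claims,
boundary pairs should score stochastically higher — tested one-sided by
Kolmogorov–Smirnov in [compare_boundary_scores()]. The transporter map
list is configurable because map numbering is a database convention, not
part of the method.

**Module termini.** Pathway modules have terminal compounds (initial
substrates, final products — "edge") and internal intermediates
("non-edge"). High-scoring pairs should be linked through module termini
(they connect modules across species) rather than through internal
compounds. [module_linkage_by_window()] bins pairs into score windows of
width 0.1 over $[-1, 1]$ (half-open $[lo, hi)$, last window closed) and
[edge_vs_nonedge_test()] runs a one-sided Mann–Whitney test of edge- vs
non-edge-linked pair scores. A compound that is a terminus in one module
and internal in another counts as a terminus: any module end can link
modules. The alternative reading of the test — comparing per-window edge
fractions above vs below $\tau$ — is available as `mode = "fractions"`.

## Null models

[draw_genome_set()] emulates a community assembled without ecological
selection: draw a genome count uniformly, draw that many catalog genomes
without replacement (a genus may contribute several genomes — the
restriction is on the genus list, not multiplicity), and accept the draw
iff its unique-KO count falls inside the envelope observed across the
real donors. The genome-count law is uniform because nothing stronger is
warranted; the rejection cap (10,000 per accepted draw) exists only to
fail loudly on infeasible envelopes. [draw_gene_set()] additionally
destroys genome co-membership by sampling KOs directly from the accepted
genome set's KO pool, with the set size uniform over the same envelope —
the envelope law is an assumption, stated here because no stronger law is
implied by the construction. The interacting-pair list is computed once
from the structured community and reused for every draw; the comparison
([compare_three_groups()]) is one-way ANOVA plus one-sided pairwise
Mann–Whitney tests in the expected order
structured > genome-null > gene-null.

## Donor clustering and networks

Interacting KO pairs are projected to genus pairs
([ko_pairs_to_genus_pairs()]): (A, B) supports genus pair (g, h), g ≠ h,
whenever g carries A and h carries B or vice versa. The default does not
demand that g lack B (strict complementarity) because genus-level
presence aggregates many strains; `strict_complement = TRUE` enforces it.
Genus pairs present in ≥ 90% of donors are "common to almost all
individuals" and are set aside; donors are clustered on the remaining
group-specific pairs with Jaccard distance and average linkage — the
natural choice for sparse binary presence data — and the tree is cut at a
user-chosen `n_clusters` (a data-driven outcome, not a method constant; a
height cut is also provided). Donor rows are put into canonical sorted
order before clustering so that tied binary distances cannot make the
result depend on input order.

Cluster networks weight an edge by the genus pair's within-cluster
aggregate score: the sum of supporting KO-pair scores accumulated over
the cluster donors in which the pair is present. Because individual pair
scores are at most 1, the display threshold of 15 is necessarily a
threshold on such an aggregate, not on a single score. Node weight is the
sum of displayed incident edge weights.

## Cohort comparison

[shared_pairs()] joins two cohorts' score tables on the pair key (only
pairs defined in both) and [specific_pairs()] applies the
two-standard-deviation rule to the score differences
$\delta = S_h - S_d$: healthy-specific means
$\delta > \mu + 2\sigma$ *and* $S_h > 0.6$, disease-specific the mirror
image. $\sigma$ is the sample (n−1) standard deviation. The $\tau$
condition applies to the favored cohort's score only; requiring the other
cohort to sit at or below $\tau$ is optional (`require_other_below`)
since the rule is about differences, not absence.

## The synthetic-data generator

[generate_dataset()] builds a self-contained community whose ground truth
is known, so that every claim above is testable without any database
download:

* **Pathway**: two metabolic maps as `ECrel` chains with one compound per
  edge, joined by a `maplink`; planted pairs occupy dedicated chain
  edges; a transporter map (02010) holds producer/uptake relations that
  form planted boundary pairs. Planted-pair compounds are declared module
  termini, remaining chain compounds are grouped into five-compound
  modules (two termini, three internal).
* **Genus content**: every KO is carried by a balanced half of the
  genera — a stylized core/accessory pattern chosen so that planted and
  background KOs have identical marginal prevalence, which keeps the
  null-model comparison honest. A planted pair occupies complementary
  halves, blended genus-by-genus towards independent coin flips as
  `complementarity_strength` drops from 1 to 0; at strength 1 the phi
  correlation is exactly −1, at strength 0 the expected dissimilarity is
  0.5.
* **Sample abundance**: log-normal. The two members of a planted pair
  share a latent per-sample factor with weight `cooccurrence_strength`
  (residual variance scaled so the log-scale variance is constant), plus
  independent log-normal noise of standard deviation `noise_sd`. At
  strength 1 and zero noise the two abundance vectors are identical and
  the pair scores exactly 1.
* **Donors**: each donor has one of `n_community_types` planted types;
  it carries a genus with probability 0.9 inside its type's genus group
  and 0.1 outside. Per-donor KO×genus tables are the genus table masked
  by carriage; the genome catalog holds `genomes_per_genus` genomes per
  genus, each retaining a random 90% of the genus' KOs (strain
  variation).

Coupling strengths default to 0.9/0.9 with `noise_sd = 0.3`: strong
enough that planted pairs score around 0.6–0.75, weak enough that the
background distribution is not trivially separated — a regime comparable
to deciding at the working threshold.

What the generator does **not** emulate: compositional closure of
relative abundances (profiles are generated on an absolute log-normal
scale), read-level noise and annotation error, phylogenetic correlation
among genera, and any coupling between a donor's genus carriage and its
abundance profile — sample profiles come directly from the latent-factor
model. Passing tests therefore demonstrate the statistical machinery
under the model's own assumptions, not performance on real gut
metagenomes.

## Numerical choices and degenerate inputs

* Correlations use `stats::cor`; zero-variance vectors yield an
  undefined (`NA`) correlation rather than a warning or an imputed 0.
* KO and compound identifiers are canonicalized to `K%05d` / `C%05d`;
  the pair key is the lexicographically sorted tuple, so all pair-level
  operations are orientation-invariant.
* Multi-KO KGML entries expand to all KO×KO combinations with self-pairs
  dropped; edge records merge across maps with compound and map sets
  unioned, so graph construction is order-invariant.
* The KS test uses the asymptotic approximation unless `exact` is
  requested; Mann–Whitney switches to the normal approximation under
  ties (base-R behaviour).
* Selection sorts by descending score with lexicographic tie-break, so
  output order is deterministic.
* `specific_pairs()` refuses degenerate cohorts ($\sigma = 0$) and
  tables with fewer than 3 shared pairs.

## Problem sizes used in the test suite

The shipped tests and the acceptance script run entirely on synthetic
communities: the "small" preset (20 genera × 300 KOs × 60 donors, 10
planted pairs) for scoring and recovery checks over 20 seeded
replicates; 100 donors and 60 planted pairs for the null-model
comparison with 100 accepted draws per null; 30 donors × 120 KOs for
clustering recovery over 10 seeds. These sizes give stable statistics at
desk scale while every algorithmic path stays identical to what larger
inputs would use.

## Known limitations

* Reaction directionality, stoichiometry and flux are out of scope; the
  pathway graph is undirected.
* No multiple-testing control is applied to pair scores; the threshold
  is a calibrated decision rule, not a significance level.
* Whether `maplink` edges should carry intermediate compounds is a
  dialect question; they do here whenever the linking entry is a
  compound.
* Genus-level aggregation hides strain heterogeneity; the strict
  complement option only partially addresses this.
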