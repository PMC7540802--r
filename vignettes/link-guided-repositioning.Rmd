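---
title: "Link-guided drug repositioning: model, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Link-guided drug repositioning: model, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(linkscreen)
```

## The problem

A disease state (the motivating case is TGF-β-induced fibrosis in ocular
fibroblasts) shifts the expression of many genes at once. Rather than rank
genes one by one, linkscreen scores the *interactions* between genes: an
interaction along which both partners move is more informative about the
perturbed machinery than either gene alone. Candidate drugs are then the
perturbation signatures (one differential-expression profile per
drug/concentration/cell-line experiment, as in Connectivity-Map-style
compendia) whose interaction-level changes run *opposite* to the disease's.

## Scores

For a link between genes $a$ and $b$ with log-fold changes $\Delta_a$,
$\Delta_b$:

* **LinkScore (LS)** — $\Delta_a + \Delta_b$ for an activating (or
  unknown-type) interaction; $\Delta_a - \Delta_b$ for an inhibition. A
  strongly positive LS marks a jointly up-regulated activation (or an
  inhibition whose source rises while its target falls), and symmetrically
  for negative LS.
* **InteractionScore (IS)** — within each condition, sum the expression of
  the two genes; the IS is the smaller of the two condition sums. It flags
  pairs that are well expressed under *both* conditions, so requires raw
  two-condition expression and is skipped for profiles that arrive as
  log-fold changes only (typical for drug libraries).
* **Single-gene fold change** — each gene's own $\Delta$.

The inhibition difference needs an orientation. For directed links it is
source minus target; for undirected links we use the lexicographically
smaller gene id minus the larger. Because filtering always takes *both*
quantile tails, flipping the orientation flips the LS sign but never changes
which links are selected; the convention only fixes reported signs, and it is
recorded in every output.

## Filtering to the relevant link set

For each criterion, the top and bottom `ceiling(q * n)` of its own eligible
population are kept (`q` = `quantile_fraction`; links for LS and IS, genes
for the fold-change criterion, which then lifts to links by incidence: a link
passes if at least one member gene is in a tail). Boundary ties are broken by
lexicographic link (or gene) identity, so selection is deterministic and
independent of input order.

The three criteria can combine as a **union** (default: a link is relevant if
any criterion fires — the reading of "a set of highest-scoring links"
covering three distinct notions of relevance) or **sequentially** (a link
must pass every applied criterion; available as `mode = "sequential"` since
the criteria are described as applied one after the other and both readings
are defensible).

`q` defaults to `1e-4` (0.01%), the threshold used on a genome-scale
protein-interaction network of ~10^6 links where it keeps on the order of a
hundred links per tail and criterion. On the synthetic networks generated
here (~2000 links) that tail would keep a single link, so the simulation
defaults and all recovery analyses use `q = 1e-2`; the same scale-dependence
applies to any small user-supplied network.

## Comparing disease and drugs

The disease selection's LinkScores are **inverted** (negated) so that a drug
that reverses the disease correlates *positively* with it. Each drug is then
compared two ways:

* **Jaccard index** of the two selected link sets, $|A \cap B| / |A \cup B|$
  (0 when both sets are empty). A `sign_aware_jaccard` variant counts only
  intersection links whose drug LS agrees in sign with the inverted disease
  LS; it is off by default because the plain set overlap is the primary
  definition, but direction arguably matters for interpretation.
* **Pearson correlation on the union** of the two selected link sets, with
  scores looked up in the *full* unfiltered score maps so that links selected
  by only one side still contribute a pair — i.e. the correlation runs over
  every link for which at least one of the two experiments pushed a
  LinkScore past its threshold. Unions smaller than 3, or zero variance on
  either side, yield an explicit `NA` that sorts to the bottom of the
  ranking rather than being dropped silently.

The Pearson ranking table reports both signed `r` and `r_squared`: published
tables of this kind have been headed either way, the two orderings coincide
for non-negative correlations, and emitting both preserves either reading.
Ranking ties break by experiment id, ascending.

## Differential-network views

The `top_k` links by absolute disease LinkScore (default `k = 47`, the size
used in the motivating figure) are decomposed into connected components,
ordered by link count (ties: gene count, then smallest gene id), and coloured
by a linear green–white–red interpolation in RGB: white at LS 0, saturating
at LS ±0.5, clamped beyond, channels rounded half-up. Node colours use the
same map with a data-driven centre (the mean of the node values, so a gene at
the dataset mean is white) and a halfwidth reaching the more distant extreme.
Linear RGB with a pure-green anchor is our documented choice; the original
visualization tool's exact hue and colour space are not specified anywhere.
The head-to-head view re-scores the *same* link set from a second
experiment's log-fold changes, so disease and drug panels differ only in
scores and colours.

## The synthetic study

`sim_config()` defaults define the conditions every recovery claim is tested
under: 500 genes; three 30-gene modules (the second down-regulated, the other
two up-regulated — the same up/down/up module structure as the fibrosis
signature: an actin-like and a cytokine-like induction plus a CD34-like
loss); 2000 links with within-module pairs 20× more likely than background;
20% inhibitory links; control expression Normal(1.68, 0.3) on a log-like
scale floored at 0 (1.68 is the normalized-expression scale the method is
usually displayed on); a ±2 log2-unit disease effect with fresh Normal(0,
0.3) noise on the perturbed condition; and a 50-experiment drug library of
pure-noise profiles plus one planted reverser whose log-fold changes are
−0.9 × the disease's plus the same noise.

Two consequences of these choices are worth knowing. First, flooring at 0
truncates part of the −2 effect for down-module genes (baseline 1.68), so
their realized log-fold changes average nearer −1.7; the planted reverser is
built from the *realized* disease log-fold changes, so recovery is
unaffected. Second, the generator emulates the statistical structure the
method assumes — module-enriched topology, additive log-scale effects,
Gaussian noise, one true reverser — and *not* real transcriptomes: no
negative-binomial count noise, no cell-line or batch structure, no partially
reversing drugs. Passing recovery tests therefore demonstrate the pipeline's
mechanics (scoring, filtering, inversion, ranking) at realistic effect/noise
ratios, not performance on real compendia.

Every generator draws from its own stream seeded from `(seed, stage)`, so
networks, disease profiles and drug libraries are independently
bit-reproducible.

## Numerical and degenerate-input choices

* Self-loops are rejected at load (their LS degenerates to $2\Delta$ or 0);
  duplicate links collapse under the identity rule.
* A link whose gene lacks a log-fold change is excluded from scoring for
  that experiment, never imputed as 0 (imputation would bias LinkScores
  toward 0); exclusion counts are reported.
* Expression tables are taken as already log-scale; the provided path from
  raw counts is RPKM (`count · 10^9 / (length_bp · library_size)`) followed
  by `log2(x + 1)` — log2 being the transcriptomics convention, since the
  log base is otherwise unstated.
* All-equal scores fall back wholly to lexicographic tie-breaking; the tail
  size stays `ceiling(q·n)` per tail.
* Inverting a selection toggles an `_inverted` suffix on the experiment id,
  making double inversion an exact identity.

## Problem sizes

The shipped tests and the acceptance script run the full screen at the
default study size (500 genes, 2000 links, 50 drugs, 50 replicate seeds,
`q = 1e-2`), about half a second per replicate; oracle-equivalence checks use
200 networks of up to 50 links against a brute-force sort-and-take-tails
reference. These sizes were chosen so the whole validation runs in well under
a minute of compute per stage while leaving the tail arithmetic
(`ceiling(q·n)` > 1) non-trivial.

## Limitations

Scoring is strictly local to each link — no diffusion, shortest paths or
edge-confidence weighting (the method is defined over all network edges,
unweighted). Ranking scores are raw similarities: no permutation p-values or
multiple-testing control are attached, and concentration–response structure
across a drug's experiments is not modelled.
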