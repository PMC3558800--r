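---
title: "Scoring amino acid substitutions with profile HMM match states"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Scoring amino acid substitutions with profile HMM match states}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(hmmvar)
```

## The model

A profile hidden Markov model represents a protein family as a chain of
match, insert and delete states; each match state emits the twenty amino
acids with position-specific probabilities estimated from a multiple
sequence alignment. `hmmvar` predicts the functional impact of a missense
substitution by interrogating those match-state emissions directly: if the
mutant residue is much less probable than the wild-type residue at the
aligned match state, the substitution is likely to damage the protein.

For a substitution at a protein position covered by one or more domain
models, the pipeline is:

1. **Significance filter.** Keep domain assignments with e-value ≤ 0.01
   (boundary inclusive).
2. **Match-state resolution.** Keep only assignments whose alignment maps
   the substituted position onto a *match* state; positions emitted by
   insert states carry no family-level signal and yield no candidate.
3. **Model selection.** Among the candidate (model, match state) pairs,
   select the most informative one: the match state with the largest
   Kullback–Leibler information content
   $\mathrm{IC} = \sum_a p(a)\,\ln\frac{p(a)}{q(a)}$
   against a background amino acid composition $q$.
4. **Scoring.** With $P_w$ and $P_m$ the emission probabilities of the
   wild-type and mutant residues at the selected state, the unweighted
   score is
   $$S = \ln\frac{P_m}{P_w},$$
   negative when the substitution is unfavorable, zero when the
   probabilities are equal, positive when the mutant is the more likely
   residue.
5. **Classification.** A substitution is called *damaging* when its score
   falls strictly below the threshold; ties are *tolerated*. The default
   thresholds are −3.0 (unweighted) and −1.5 (weighted), the points at
   which sensitivity and specificity are jointly maximized on a
   disease/neutral calibration set.

### Pathogenicity weights

For species with curated variant catalogues, domain-level pathogenicity
weights sharpen the prediction. Every disease-associated and every neutral
substitution in the training catalogue is mapped onto the domain models it
falls in (same significance filter, same match-state requirement), giving
per-model counts $c_d$ and $c_n$. With a pseudo-count of 1.0 to avoid
division by zero, the default weights are $W_d = c_d + 1$,
$W_n = c_n + 1$, and the weighted score is

$$S_w = \ln\frac{P_m \, W_n}{P_w \, W_d} = S + \ln\frac{W_n}{W_d}.$$

A domain enriched for disease mutations shifts all of its scores downward.
Because only the ratio $W_n/W_d$ enters the score, the alternative
relative-frequency weight form $W = (c+1)/(T+1)$ (with $T$ the catalogue
total; available via `normalized = TRUE` in `weights_for()`) differs from
the default by a single constant applied to every weighted score, and
therefore re-ranks nothing; we default to the unnormalized form because it
leaves the zero-count case exactly neutral ($W_d = W_n = 1$).

Weighted scoring is deliberately restricted to library domain models:
weights exist only where training variants could be counted, so an
ab initio whole-protein model never enters the weighted candidate set.
This buys precision at the cost of coverage — substitutions outside
annotated domains receive `no_prediction` in weighted mode.

To avoid circularity when a scored substitution is itself part of the
training catalogue, `leave_one_out()` removes that record's own
contribution from the counts of every model it was counted into before
scoring it, and restores nothing when the record is absent from training.

### Score strategies

The package treats the scoring formula as a pluggable strategy with a
fixed contract — zero at $P_m = P_w$ under neutral weights, strictly
increasing in $P_m$, strictly decreasing in $P_w$, antisymmetric under
argument swap — and ships two algebraic forms satisfying it: the default
log-ratio above and a log-odds-ratio form
$S = \ln\frac{P_m/(1-P_m)}{P_w/(1-P_w)}$ (`formula = "odds"`). The
contract, not the algebra, is what the calibrated thresholds and the
evaluation machinery rely on, and the property tests pin the contract for
both forms.

## Evaluation machinery

`metrics()` computes the six standard measures — accuracy, precision,
specificity, sensitivity, NPV and MCC — from a 2×2 confusion matrix.
Benchmark tables in this field are usually reported on *normalized*
counts: each class is rescaled to unit mass
($tp' = tp/(tp+fn)$, $tn' = tn/(tn+fp)$), which makes metrics comparable
across datasets with different disease/neutral ratios. Two identities
follow and are tested exactly: normalized accuracy equals balanced
accuracy $(\mathrm{TPR}+\mathrm{TNR})/2$, and normalized MCC is a closed
form in TPR/TNR alone.

`roc_curve()` sweeps all candidate thresholds (midpoints between adjacent
distinct scores, plus sentinels) under the same strict-inequality calling
rule, with the orientation convention that more negative scores are more
disease-like; `calibrate_threshold()` returns the threshold maximizing
$\min(\text{sensitivity}, \text{specificity})$, breaking ties toward the
larger sensitivity+specificity and then the larger threshold, so the
result is deterministic. `method_overlap()` counts every Venn region of
two or three sets of correctly identified positives.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `e_threshold` | 0.01 | inclusive e-value bound for a significant domain hit |
| `threshold` | −3.0 / −1.5 | damaging call boundary, unweighted / weighted (log units) |
| `pseudo_count` | 1.0 | additive count in $W_d$, $W_n$ |
| `epsilon` | 1e-10 | floor for zero emission probabilities (keeps scores finite; flagged `low_support`) |
| `formula` | `"ratio"` | score strategy (`"ratio"` or `"odds"`) |
| `window` | 1 | states averaged for information content; 1 compares the single aligned state |
| `background` | per-model | global composition file overriding each model's COMPO line |

Information is measured in nats (natural log) so the KL selection and the
scores share one base. Each candidate model is ranked against its own
COMPO background when no global composition is supplied; supplying one
(e.g. a large-database amino acid composition such as the packaged
`example_background_composition.txt`) makes information values comparable
across models and is recommended when mixing model libraries. Ties in
information content break by library priority (SUPERFAMILY > Pfam-A >
Pfam-B > ab initio), then model id — an arbitrary but deterministic rule.

## The synthetic benchmark generator

`synth_benchmark()` builds the study conditions used throughout the test
suite: 20-residue-alphabet models whose match states mix a point mass on
a consensus residue (weight = conservation) with a uniform remainder; half
the models highly conserved (0.99), half weakly conserved (0.1); one
full-length, identity-mapped domain hit per model; disease records planted
as consensus→rare substitutions on conserved states and neutral records as
arbitrary substitutions on unconserved states. The default acceptance runs
use 20 models × 50 states and 500 disease + 500 neutral records — small
enough to score in seconds, large enough for stable rates.

What the generator emulates: input formats, the significance filter, the
match/insert distinction, overlapping domains, and a conservation-driven
score separation. What it does not emulate: realistic family emission
profiles (no Dirichlet-mixture estimation — `profile_from_msa()` uses
plain pseudo-counts), correlated neighbouring states, alignment
uncertainty, or database-scale label noise. Passing the planted-separation
benchmark therefore demonstrates that the pipeline is wired correctly and
is sensitive to planted conservation signal; it does not certify accuracy
on real disease variants, which depends on real model libraries and
curated catalogues.

## Numerical choices and degenerate inputs

- HMMER3 stores emissions as negative natural logs; `*` denotes
  probability exactly zero and parses to 0, contributing 0 to KL sums.
  Parsed rows are renormalized (deviations ≤ 1e−4 are format rounding);
  the writer prints scores at 9 decimals so a write→read→write cycle is
  stable to ~1e−9.
- Zero probabilities are floored at `epsilon` with a warning rather than
  producing infinite scores: ROC sweeps and threshold calibration need
  finite values. A floored wild-type sets the `low_support` flag.
- `classify()` treats a score exactly at the threshold as tolerated
  (strict inequality for damaging).
- Empty candidate sets are values (`no_prediction`), not errors; an empty
  class in metric computation is an error naming the metric.
- Seeded generators use R's default RNG via `set.seed(seed)` only, no
  locale- or platform-dependent I/O, so the same seed reproduces a bundle
  byte-identically.

## Known limitations

- Only HMMER3 ASCII models are read; older-format libraries must be
  converted upstream (`hmmconvert`).
- Overlapping hits from different libraries are all candidates and
  information content alone decides; no envelope merging or library
  reconciliation is attempted.
- Ontology annotation transfers precomputed domain→term mappings as-is
  (optionally expanding `is_a` ancestors from an OBO file); it performs no
  statistical inference of new associations, and domain-level terms can be
  coarser than the specific substitution consequence.
- The evaluation utilities assume binary disease/neutral labels.
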