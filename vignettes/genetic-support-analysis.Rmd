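---
title: "Measuring the genetic-support advantage in drug development"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring the genetic-support advantage in drug development}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(genesupport)
```

## The model

A drug development programme is a target gene paired with an indication
(a T–I pair) that climbs an ordered phase ladder: preclinical → phase I →
II → III → launched. Success at a transition means reaching the later phase;
a pair's highest phase reached determines all of its transition outcomes, so
launched pairs count as successes at every upstream transition and pairs
stalled at phase *k* — whether historically terminated or still active —
count as non-successes at *k*. Both statuses are pooled: treating active
programmes as censored would require time-to-event data the programme tables
do not carry, and the pooled convention matches how these analyses are
reported in the field.

Genetic support is a property of the pair, not the gene: the target must be
genetically associated with a trait that is *similar enough* to the
indication. Similarity is computed on a rooted disease-ontology DAG with
annotation counts. Information content is
$IC(t) = -\ln\left(\mathrm{cumcount}(t)/\mathrm{cumcount}(root)\right)$
in nats; the cumulative count of a term sums intrinsic annotation counts
over the term and all its descendants (counted once each in a DAG). Resnik
similarity of two terms is the IC of their most informative common ancestor
(MICA); because the root is always a common ancestor it is never negative,
and any sentinel "infinite distance" value is mapped to 0. Lin similarity is
$2\,IC(\mathrm{MICA})/(IC(a)+IC(b))$, already in $[0,1]$. Ties among
equally informative ancestors are irrelevant because only the IC value is
used. The base of the logarithm cancels in Lin and is absorbed by
calibration for Resnik, so natural logs are used throughout.

The two scores are then **combined**. Raw Resnik lives in IC units, so it is
rescaled by one multiplier $m = 1/\hat\beta$, where $\hat\beta$ is the
least-squares slope *through the origin* of raw Resnik on Lin across all
indication × trait pairs in play; rescaled values are clipped to $[0,1]$ and
averaged with Lin. Two genuinely open choices are made here and exposed in
the code: the regression is origin-anchored (an intercept would let the
"slope 1" requirement be met while the scores still disagree at 0), and its
direction is Resnik-on-Lin (so the multiplier is applied to the score that
needs rescaling). A single multiplier cannot simultaneously force slope 1
and keep every rescaled value at or below 1: deep identity-like pairs can
exceed 1 and are clipped, which means a refit on the *clipped* values can
sit slightly off 1, and a shallow term's self-similarity can fall below 1
when $m \cdot IC(a) < 1$. The slope-1 property therefore refers to the
unclipped rescaled scores, which is what the multiplier controls.

A T–I pair **has genetic support** when the maximum combined similarity
between the indication and any trait associated with the target is at least
$\tau = 0.8$ (inclusive). The threshold is sweepable; raising it can only
shrink the supported set.

## Evidence filters

Each association source has its own inclusion rules, applied before any
similarity matching; every filter logs per-rule drop counts that sum exactly
to input minus output.

* **Mendelian catalogue** — keep phenotype mapping code 3 (molecular basis
  known) with phenotype ID, gene and trait mapping present; drop labels
  containing "somatic", "susceptibility" (outside brace flags) or
  "response", questionable ("?") and non-disease ("[") flags; drop
  susceptibility-brace ("{") labels *except* cancer/neoplasm/tumor/malignant
  ones that are not somatic — those reflect germline loss-of-function in
  tumour suppressors and are retained. Matching is case-insensitive
  substring matching at any position. Deduplicate on (gene ID, phenotype
  ID), then (gene, trait).
* **GWAS** — a gene's locus-to-gene (L2G) share at a hit is its score over
  the summed scores of all candidate genes there (shares sum to 1 per hit);
  keep $P < 5\times10^{-8}$ (strict, as printed) and share $\ge 0.5$
  (inclusive). Exact 0.5/0.5 ties keep both genes.
* **Colocalization** — GWAS $P < 5\times10^{-8}$, eQTL $P < 1\times10^{-5}$
  (both strict), posterior $H4 \ge 0.9$ (inclusive).
* **Exome burden** — $P < 1\times10^{-5}$ in any of pLoF/missense|LC ×
  SKAT/burden; boundary values are dropped (strict `<`, logged as such);
  unknown model labels are rejected; one association per gene–trait.
* **Somatic drivers** — each gene takes its modal classification across
  cancer cohorts; exact ties are labelled "ambiguous" and excluded from
  direction-of-effect groupings (the convention is ours; the underlying
  resource does not specify one).

An indication has **genetic insight** — its genetics has been successfully
studied — if some Mendelian/somatic disease, or some GWAS trait with at
least 3 independent loci (lead positions rounded half-up to the nearest
megabase, counted per chromosome), is ≥ 0.8 similar. Restricting RS
denominators to insight-flagged indications focuses the comparison on
indications where genetic support was discoverable at all; the filter is on
by default and switchable.

## The synthetic study

`synth_config()` fixes the study conditions; its defaults are the conditions
under which the package's properties are verified:

| parameter | default | meaning |
|---|---|---|
| `baseline_ps` | (0.6, 0.3, 0.5, 0.6) | per-transition success probability without support, ordered preclinical→I, I→II, II→III, III→launch; values chosen to bracket typical industry attrition |
| `injected_rs` | 2 | multiplier on each transition probability for supported pairs, capped at `min(1, p·rs)` |
| `support_prevalence` | 0.1 | probability a candidate gene–indication pair is supported |
| `active_fraction` | 0.25 | probability a stalled programme is censored as "active" |
| `n_genes`, `n_indications`, `n_drugs` | 150 / 40 / 500 | scale of the default bundle |

The generated ontology places each indication leaf next to a trait leaf
under a shared low-count "disease group" parent, so the pair's MICA is deep
and their combined similarity exceeds 0.8 by construction, while traits in
other groups or hung directly under the top-level branches fall well below
it. Leaves carry small positive intrinsic counts and internal terms carry
zero, so every term's *cumulative* count — the IC input — is positive and
the root's cumulative count is the sum over leaves. Support truth is sampled
at the gene–indication level and *realized* through ontology placement: the
generator emits passing associations to the paired trait for supported
pairs, then recomputes the support verdicts through the package's own
similarity module and records the realized flags as the ground truth the
success simulation uses. Decoy records violating each filter rule one at a
time (a "somatic" label, a $10^{-6}$ GWAS hit, a 0.3 L2G share, $H4=0.5$, a
$10^{-4}$ exome P, an unknown model, …) are injected alongside, with
bookkeeping pass-lists so tests can demand exact set equality between what
the filters retain and what was constructed to pass.

Effect sizes have no public reference distribution, so the generator
documents its own: betas lognormal, odds ratios lognormal around 1, MAF
log-uniform on $[10^{-4}, 0.5]$.

What the generator does *not* emulate: realistic therapy-area mix, the
drugs-per-target distribution, correlated phase durations, or any marginal
distribution of the proprietary programme databases. Passing tests
demonstrate the statistical machinery and filter logic, not real-world
effect sizes.

### A note on the unit of analysis

The injected multiplier acts on each *programme's* Bernoulli ladder. The
analysis unit, however, is the T–I pair, and a pair backed by several drugs
takes the maximum phase over its drugs — the maximum of several draws
succeeds more often than one draw, which attenuates the pair-level ratio
toward 1 relative to the injected per-programme value. Parameter-recovery
checks therefore measure at programme level (while still taking the support
verdicts from the full filter + similarity path); pair-level results on
bundles with multiple drugs per pair sit systematically below the injected
multiplier, which is a property of the design, not an estimation error.
With the default conditions the capped effective ratio
$\min(1, p_k \cdot 2)/p_k$ equals 2 only for the I→II and II→III
transitions (baselines 0.3 and 0.5); the cap makes 1/0.6 the truth for the
other two, so coverage of the value 2 is asserted where 2 is in fact the
truth.

## Numerical and degenerate-input conventions

* Katz CIs are undefined when either arm has zero successes; the result
  carries a `degenerate` flag instead of a 0.5-count correction, which
  would silently shift estimates. Empty arms ($N=0$) are errors.
* The CMH statistic is computed in its standard hypergeometric form without
  continuity correction (switchable behaviour was considered and rejected:
  the single-stratum equivalence `(n−1)/n ×` Pearson's $\chi^2$ makes the
  uncorrected form the auditable one). The usual library implementation
  refuses single-stratum arrays, which the analysis needs, hence the direct
  form; a multi-stratum test cross-checks it against
  `stats::mantelhaen.test(correct = FALSE)`.
* Weighted Pearson correlation normalizes weights to mean 1 and uses the
  t-test on the raw observation count, so equal weights reduce exactly to
  `cor.test`.
* Logistic trend tests flag complete separation (no Wald p is reported);
  the ordinal progression model is `MASS::polr` with `Hess = TRUE`,
  reporting `exp(coef)` for the support term.
* Quartile covariate bins assign boundary ties to the lower bin; MAF bins
  are `floor(log10 MAF)`; odds ratios standardize to `max(OR, 1/OR)`.
  "Excluding replications" when dating a pair's first GWAS support keeps
  only the earliest association per gene–trait.
* Argmax ties in the most-similar-indication restriction retain all tied
  indications and are logged; the "many GWAS hits" removal threshold is an
  explicit parameter with no default, since no principled default exists.
* All estimates are invariant to input row order, and identical
  configuration + seed reproduces bundles byte for byte.

## Problem sizes used in the checks

The bundled verification suite runs at deliberately modest scale — bundles
of 40–150 genes, 12–40 indications, 150–4,000 programmes; similarity-oracle
corpora of 100 DAGs with at most 12 terms; coverage runs of 100 seeds at
10,000 programmes each — sizes at which every property being asserted is
already identifiable while a full run stays in the minutes range on one
core. The pipeline itself has no scale-specific logic; larger inputs only
cost time.

## Known limitations

* The IC corpus question is open in general: here IC always derives from
  the annotation counts supplied with the ontology (an intrinsic,
  descendant-count-based IC could be substituted by supplying those counts).
* Trait-to-ontology term mappings arrive as input tables; no cross-ontology
  mapping or label text-mining is attempted.
* No time-to-event modelling of phase durations, and no attempt to
  reproduce the marginals of proprietary pipeline databases; headline
  real-data values therefore cannot be recomputed here and are not claimed.
* The proportional-odds and logistic models assume their usual link and
  independence structure; drugs contributing several indications violate
  independence mildly, as they do in the field's standard treatment.
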