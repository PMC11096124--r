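# genesupport

Drug mechanisms backed by human genetic evidence succeed more often in
clinical development. `genesupport` implements the full analysis framework
needed to quantify that advantage: it matches drug indications to genetically
associated traits through ontology semantic similarity, applies each
evidence source's inclusion rules, and measures how genetic support
differentiates phase-transition success — with the stratified, trend and
enrichment analyses that surround the headline statistic. A synthetic-data
generator with known ground truth makes the whole pipeline testable without
access to proprietary drug-pipeline databases.

It is intended for drug-discovery informaticians and statistical geneticists
who want to run, extend or stress-test this class of analysis on their own
programme and association tables.

## The statistics at the core

For a set of target–indication (T–I) pairs, with `N` the number of pairs
that reached a reference phase and `X` the number of those advancing to a
later phase, and subscripts `G`/`!G` marking presence/absence of genetic
support:

- **P(G)** = `N_G / (N_G + N_!G)` — proportion of programmes with genetic
  support (Wilson 95% CI);
- **P(S)** = `(X_G + X_!G) / (N_G + N_!G)` — probability of success for one
  phase transition; overall phase I→launch P(S) is the product of the
  per-phase probabilities (Wald CI on the log scale);
- **RS** = `(X_G/N_G) / (X_!G/N_!G)` — relative success, a risk ratio, with
  the Katz 95% CI `exp(ln RS ± 1.96·√(1/X_G − 1/N_G + 1/X_!G − 1/N_!G))`.

A T–I pair *has genetic support* when its target gene carries a filtered
association to a trait whose combined ontology similarity to the indication
is ≥ 0.8. Combined similarity is the mean of Lin similarity and a rescaled
Resnik similarity, both built on information content
`IC(t) = −ln(cumcount(t)/cumcount(root))` over a rooted disease-ontology
DAG; the Resnik scores are multiplied by a single factor so that their
origin-anchored regression on Lin has slope 1, then clipped to [0, 1].

Supporting analyses include per-source evidence filters (Mendelian
catalogue label rules, GWAS P < 5×10⁻⁸ with locus-to-gene share ≥ 0.5,
colocalization H4 ≥ 0.9, exome burden/SKAT P < 1×10⁻⁵, somatic driver
roles), "genetic insight" denominator filtering, Cochran–Mantel–Haenszel
tests across therapy areas, logistic trend tests, weighted Pearson
correlations, a proportional-odds model of drug–indication progression, and
enumeration of the full gene×indication universe with Fisher enrichment of
clinical pursuit among supported pairs.

## Worked example

Generate a synthetic study with a known injected effect (relative success
multiplier 2 per transition, capped at probability 1), run the pipeline, and
read off the per-transition statistics:

```r
library(genesupport)

bundle <- synth_bundle(synth_config(n_genes = 150, n_indications = 40,
                                    n_drugs = 2000, injected_rs = 2,
                                    support_prevalence = 0.25, seed = 1))
dir <- file.path(tempdir(), "bundle"); out <- file.path(tempdir(), "out")
write_bundle(bundle, dir)
res <- run_pipeline(run_config(dir, out))
res$stats[, c("label", "X_G", "N_G", "X_notG", "N_notG",
              "rs", "ci_low", "ci_high")]
#>            label X_G N_G X_notG N_notG   rs ci_low ci_high
#> 1 preclinical->I 169 169    438    510 1.16   1.12    1.21
#> 2          I->II 136 169    209    438 1.69   1.49    1.91
#> 3        II->III 136 136    113    209 1.85   1.63    2.10
#> 4  III->launched 136 136     71    113 1.59   1.38    1.83
#> 5    I->launched 136 169     71    438 4.96   3.96    6.22
```

Each row is one phase transition: `N` counts T–I pairs at or beyond the
"from" phase, `X` those at or beyond the "to" phase, split by support. With
baseline transition probabilities (0.6, 0.3, 0.5, 0.6) and multiplier 2,
supported pairs hit the probability cap at the first and last transitions
(the supported arms advance almost surely, e.g. `X_G = N_G = 136` at
II→III where 0.5×2 = 1), so the measured pair-level ratios sit where the
capped effective effect puts them, and the overall I→launch ratio is their
compounding. Utilization of the supported universe:

```r
u <- res$utilization
sprintf("pursued|supported = %.1f%%  OR = %.2f  (Fisher P = %.2g)",
        100 * u$pursued_given_supported, u$odds_ratio, u$p_value)
#> "pursued|supported = 35.8%  OR = 6.48  (Fisher P = 2.7e-57)"
```

meaning 35.8% of genetically supported gene–indication pairs have a
programme at phase I or beyond, a 6.5-fold enrichment over chance.

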