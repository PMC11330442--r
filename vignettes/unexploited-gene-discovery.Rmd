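---
title: "Discovering unexploited disease genes: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering unexploited disease genes: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unexploitr)
```

## The problem

Gene–disease association databases are incomplete. A gene can be
repeatedly implicated in a disease by expression studies and even carry an
explicit mechanistic statement in a published article, yet have no record
in Open Targets, DisGeNET, miRTex, RNADisease or PubChem — because the
source article was filtered out of a text-mining corpus, because manual
curation lags, or simply because nobody registered it. `unexploitr` hunts
these *unexploited genes*: database false negatives with genuine
literature support. The package targets stress-associated disease biology
— the motivating case is oxidative stress in Parkinson's disease, where
paired stressed/normal expression data from brain-derived cultured cells
are abundant — but every stage is parameterised by disease ID, search term
and thresholds.

## The vote-counting meta-analysis

The first stage condenses many independent paired stress/control
expression datasets into one per-gene statistic without fitting a
distributional model. For gene $g$ and pair $i$,

$$\mathrm{ONratio}_{gi} = \frac{T^{stress}_{gi} + 1}{T^{control}_{gi} + 1},$$

on TPM-scale values. The pair votes **up** when the ratio reaches the fold
threshold $f$, **down** when it falls to $1/f$, otherwise **unchanged**,
and the gene's score is

$$\mathrm{ONscore}_g = \#\mathrm{up}_g - \#\mathrm{down}_g .$$

Vote counting deliberately trades per-dataset efficiency for robustness:
each pair contributes at most one vote regardless of its magnitude or
library size, so a single aberrant dataset cannot dominate, and datasets
from heterogeneous platforms, stressors and cell types can be combined
without cross-normalisation. The assumptions are correspondingly mild:
values are on a common within-pair scale (TPM), and a biologically
dysregulated gene shifts by at least $f$-fold in an appreciable fraction
of pairs.

Numerical and boundary choices:

* **Pseudocount.** The $+1$ keeps ratios finite and pins silent genes
  (0 vs 0) at ratio exactly 1. A side effect is shrinkage for
  low-expressed genes: a gene needs baseline TPM above
  $0.5/(f - 1.5)$-ish levels before a genuine fold change can cross the
  1.5 cutoff. This is intentional — calls on sub-TPM genes are noise.
* **Inclusive boundary.** A ratio exactly equal to $f$ counts as up (and
  $1/f$ as down), so the two cutoffs are exactly symmetric under
  reciprocals and noise-free fixtures with exact ratios are classifiable.
  With the reciprocal symmetry of the ratio this yields an exact
  invariant: swapping every stress/control pair negates every score.
* **Missing values.** A gene absent in one pair votes "unchanged" there
  (vote-counting robustness); a strict mode errors instead for pipelines
  that want hard guarantees.

### Selecting stress DEGs

The selection is purely rank-based: the top $m$ and bottom $m$ genes by
score, with $m = \mathrm{round}(\textit{fraction}/2 \times G)$ and halves
rounding up (so $G = 62{,}266$ at the default fraction 0.05 gives
$m = 1557$). A score cutoff was considered and rejected as the primary
rule: the integer score's ties make a cutoff either too permissive or too
strict at small pair counts, whereas a rank rule yields a fixed, budgeted
selection; an optional `min_abs_score` filter remains for users who want
an absolute floor. Ties at the selection boundary are broken by larger
mean $|\log \mathrm{ONratio}|$ (prefer larger average effects), then
lexicographic gene ID — fully deterministic, and the tie-break also
rescues genuinely shifted but low-expressed genes (positive mean absolute
log-ratio) ahead of flat ones (exactly zero) in degenerate noise-free
data. The up-selection is chosen first and the down-selection is drawn
from the remainder, so the two lists are disjoint by construction even
when the universe is tie-heavy.

## Disease evidence integration

Per-study DEG lists are unioned with TWAS evidence into a wide table with
one fold-change column per study plus TWAS flag/Z/source columns.
Decisions here:

* Duplicate (gene, study) rows with identical fold changes collapse;
  conflicting ones are an error — silent averaging would hide upstream
  curation problems.
* Conflicting fold-change *signs across studies* are preserved
  unreconciled; the table is evidence bookkeeping, not a consensus
  estimate.
* TWAS genes join the union because genetically regulated expression is
  disease evidence of the same kind for this purpose, but they stay
  flagged so the candidate filter can distinguish the evidence types.
* Gene identity is the Ensembl-style ID; symbols are display-only.

## Offline database linkage

Snapshots — frozen local TSV extracts of the five databases — replace live
API queries, making runs reproducible and auditable. A record hits a gene
when its key matches *any* identifier form of the gene (Ensembl, symbol,
Entrez; real databases key inconsistently), its disease ID matches
*exactly* one of the configured IDs (per-source ontology synonyms are
supplied via configuration, not guessed), and its score, if present, meets
the per-database threshold. Defaults: threshold 0 for every database — any
evidence counts, which is the conservative choice when hunting false
negatives, because an aggressive threshold would manufacture "unlinked"
genes out of weakly-scored true links. A scored hit with no PMIDs still
links the gene (some sources are score-only) but contributes nothing to
the evidence-PMID list. Unmapped genes classify as unlinked with a warning
rather than erroring: annotation gaps must not halt a long pipeline, but
they must be visible. Linked and unlinked always partition the input
exactly, and the verdicts are invariant to row and gene order.

## Candidate refinement and adjudication

An unlinked gene becomes a candidate when it (a) has a TWAS Z score — mere
presence, any sign, since both risk directions are informative and the
magnitude was already filtered by the TWAS's own significance criteria —
or (b) appears in at least `min_studies = 2` study lists. Requiring two
independent expression studies (rather than three or more) balances
false-positive control against the small size of typical unlinked sets; it
is configurable. A gene meeting both criteria appears once with both
reasons recorded, so the inclusion–exclusion identity
$|\mathrm{twas}| + |\mathrm{multi}| - |\mathrm{both}| = |\mathrm{candidates}|$
is checkable on every run.

The final judgement — does the literature contain a *mechanistic*
statement tying the gene to the disease, as opposed to a mere DEG-list
mention? — is inherently a curation decision. The package therefore does
not text-mine; it emits a worksheet with one ready-made PubMed Central
query per candidate (`SYMBOL[All Fields] AND parkinson[All Fields]`,
lowercase disease term by display convention; the search itself is
case-insensitive) and validates the returned evidence table: a gene can
only be ruled unexploited if its functional-statement flag is set *and* a
supporting PMCID with at least one publication backs it. Zero search
results force "no".

## Overlap statistics

Selection validity checks use the exact upper-tail hypergeometric
probability $P(X \ge k)$, computed from log-gamma binomial coefficients
combined with log-sum-exp — direct factorials overflow around $N \approx
170$, while the log-space sum is exact to full double precision at
$N = 10^6$. The test is one-sided (enrichment); for tables as extreme as
those worth reporting, the opposite tail contributes nothing at any
printed precision, so the value coincides with the two-sided Fisher test
(asserted numerically in the test suite). P-values are displayed to three
significant figures in scientific notation.

## What the synthetic generator emulates — and what it does not

Real inputs for this pipeline are curated external datasets, so the
package generates every input synthetically with known ground truth:

* **Expression.** Per-gene lognormal baselines
  ($e^{N(\log 100,\, 1)}$ TPM), planted up/down genes multiplied/divided
  by `fold_effect` in a Bernoulli(`response_prob`) subset of pairs, and
  independent lognormal noise (`noise_sd` on the log scale) on every
  value. Lognormal multiplicative noise keeps values positive and matches
  the scale behaviour of quantified TPM data. Partial response encodes
  the reality that a stress gene does not respond in every dataset.
* **Study lists.** Each true disease gene captured per study with
  probability `study_capture_prob` and a direction-consistent log2 fold
  change; `study_fp_count` random bystanders per study. TWAS hits drawn
  sparsely with direction-consistent Z scores (the filter never uses the
  sign).
* **Annotations.** Database-linked genes drawn with `db_link_prob` and
  registered under each database's own key vocabulary (Ensembl, Entrez or
  symbol), with decoy records for an unrelated disease ID; functional
  literature genes drawn with `lit_functional_prob`; an ID map with
  deliberate Entrez gaps; a gene2pubmed-style table.

Defaults (2000 genes, 50 pairs, 50 planted per direction, 2-fold effect,
80% response, noise sd 0.25, 3 studies) are the package's standing study
conditions: large enough that recovery statistics are stable, small
enough that the full funnel runs in seconds. One global seed drives a
separate derived stream per generator, so regenerating one input does not
perturb the others.

The generator does **not** simulate read-level data, batch effects,
library-size artefacts, correlated genes, or the heavy-tailed
overdispersion of real counts. Consequently, passing tests demonstrate
that the pipeline's logic is correct and its statistics calibrated under
the stated generative model — not that the ON-score's operating
characteristics on real heterogeneous RNA-seq match the synthetic ones.
Real-data thresholds (fold cutoff, selection fraction, database score
thresholds) still need sensitivity analysis by the user.

## Test and verification sizes

The oracle-equivalence tests recount scores with a naive double loop on
random matrices up to 50 genes × 20 pairs (hundreds of instances), and
check the hypergeometric tail against exact rational-arithmetic values
(30 frozen instances, $N \le 60$, agreement to 10 significant figures)
plus several hundred random comparisons against the distribution function.
Recovery and end-to-end checks run at the 2000 × 50 default; the
deterministic end-to-end fixture (no noise, full response, full study
capture) makes the planted unlinked-but-functional set an exact oracle for
the pipeline's output.

## Known limitations

* The linkage verdict is only as good as the snapshots; the package
  defines the snapshot contract but building faithful extracts from
  database dumps is the user's task.
* Disease-ID matching is exact-string; ontology cross-walks must be
  supplied in configuration.
* The literature stage structures a human judgement; it cannot detect a
  mechanistic statement the curator missed, and provides no inter-rater
  machinery.
* Vote counting discards effect magnitudes beyond the threshold; genes
  with strong but rare responses rank below genes with weak consistent
  ones. That is the intended bias, but it is a bias.
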