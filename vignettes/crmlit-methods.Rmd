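---
title: "Methods: screening the literature for CRM target genes and regulatory TFs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: screening the literature for CRM target genes and regulatory TFs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crmlit)
```

# The problem

Databases of cis-regulatory modules (CRMs) — enhancers and silencers built
from clustered transcription-factor binding sites — are curated by people
reading papers. Two questions dominate that reading: *does this article
describe modular transcription regulation at all?* and, if so, *which gene
is the CRM's target, and which transcription factors (TFs) act on it?*
`crmlit` automates both as a four-step pipeline: abstract triage, full-text
retrieval, per-paragraph gene-role labeling, and per-article summarization.
This vignette explains the models, the parameters that matter, the
synthetic corpus the package is validated on, and the numerical and design
choices a maintainer should know about.

# Step 1: triage under extreme class imbalance

Curated CRM-positive articles number in the hundreds; candidate articles in
the hundreds of thousands. Training one classifier on such data either
drowns the positives or discards most negatives. The pipeline instead
trains `k = 5` base classifiers, each on **all** positives plus a different
negative subset of the same size, sampled without replacement within a
subset (`sample_bootstrap_sets()`). The five base probabilities are then
aggregated by an AdaBoost model — 150 trees of maximum depth 2, learning
rate 0.2 — fitted on a held-out *ensemble* split that the base classifiers
never saw. Keeping the aggregator's training data disjoint from the bases'
is essential: base probabilities on their own training data are
overconfident, and an aggregator fitted to them learns that overconfidence.

Each base classifier is `encoder -> linear head -> softmax`, trained with
categorical cross-entropy for 3 epochs at batch size 16 under cosine
learning-rate decay, with dropout 0.1 on the encoded features and 0.4
before the head. The decision threshold is 0.5 with a `>=` tie rule.

## The encoder contract and the desk-scale default

Everything trainable sits behind a small contract: an encoder is any object
with `$dim` and `$encode(texts)` returning one fixed-length vector per text
(the pooled "CLS" analog of sequence encoders). The default is a **hashed
bag-of-n-grams** encoder: lowercased word unigrams and bigrams hashed into
2048 buckets, `log1p`-transformed counts, L2-normalized. It needs no fitted
vocabulary, no downloads, and is deterministic. The width of 2048 was
chosen once so that hash collisions stay rare relative to desk-scale
vocabularies (a few thousand distinct grams); at 512 buckets collision
noise measurably degrades the base classifiers. A transformer adapter can
implement the same contract; the training code does not change.

Two training defaults deliberately differ from what one would use with a
large pretrained encoder. First, the maximum learning rate defaults to
0.05: a from-scratch linear/tanh head needs steps orders of magnitude
larger than the fine-tuning rates appropriate for a pretrained transformer.
Second, epochs are configurable and the package's own studies train longer
(30 epochs) than the 3-epoch fine-tuning default, because the desk-scale
model starts from random weights. Both are `triage_config()` /
`labeler_config()` parameters.

## Aggregator output granularity

A boosted-tree margin is piecewise constant, with few pieces when the
ensemble split is small or the base probabilities nearly separate it. In
the degenerate limit — one depth-2 tree classifies the ensemble split
perfectly — every boosting round repeats that tree and the aggregated
probability collapses to two values, which destroys ROC resolution even
though decisions are fine. The aggregator therefore emits

\[ P = (1-\gamma)\,\sigma(2F) + \gamma\,\bar P, \qquad \gamma = 0.05, \]

where \(F\) is the boosted margin and \(\bar P\) the mean base probability.
Because \(\gamma < 0.5\), the ranking across margin levels is unchanged and
0.5-threshold decisions are unchanged whenever the margin is confident; the
blend only orders articles that land in the same leaves of every tree.

One more boosting note: with the aggregator's default shrinkage (learning
rate 0.2), boosting stalls on a pure XOR problem — the greedy first split
has no gain, rounds barely reweight, and accuracy stays near chance. This
is not an implementation artifact (reference gradient/AdaBoost
implementations behave identically); at unit learning rate the same 150
depth-2 trees fit XOR exactly. The test suite therefore checks the XOR
representation property at learning rate 1, while the pipeline default
stays at 0.2.

# Steps 2-3: retrieval, mention pairing, and the weighted loss

Retrieval is isolated behind a transport contract (`get(pmid)` returning
XML or `NULL`), with a local-directory implementation matching the PMC OA
package layout. Three outcomes are kept distinct: *unavailable* (fall back
to the abstract as a single paragraph), *malformed* (parse error; the
article is skipped and logged), and *transport failure* (retriable error).
Batch runs never abort on a per-article problem.

Sections titled Methods/Materials and Methods, Abbreviations,
Acknowledg(e)ments, References or Supplementary are dropped before pairing
(case-insensitive substring matching on punctuation-stripped titles, which
absorbs the spelling variants); these sections mention genes for reasons
unrelated to the regulatory conclusions.

Gene mentions are found by dictionary matching against a synonym lexicon.
Matching is token-boundary based ("fly" never matches inside "butterfly"),
longest-match-first then leftmost, with matched tokens consumed so mentions
never overlap. Surface forms containing an uppercase letter match
case-sensitively (fly symbols are case-meaningful); all-lowercase forms
match case-insensitively. A surface form claimed by two symbols is dropped
as ambiguous at load time, and forms identical to common English words are
removed by a stoplist. These matching rules are package decisions — the
underlying curation practice does not document its exact matching — and are
therefore stated here rather than assumed to be externally fixed.

Each retained (gene, paragraph) pair is windowed to 256 word pieces on each
side of the mention when the paragraph exceeds 512 pieces; shorter
paragraphs pass through untouched. At the paragraph edges the window
*shifts* toward the available side rather than padding, preserving maximal
context; the mention's own pieces do not count against the flanks, so a
multi-piece name can make a window slightly exceed 512. Windowing is
idempotent, and the budget is configurable because it is not documented
whether the limit includes special markers in the original setting.

The two-label model (target gene / TF; both may hold, so two sigmoids, not
a softmax) is trained with the weighted binary cross-entropy

\[ \mathrm{WBCE}(S_i) = -\,w_i \sum_{c=1}^{2}\big(p_c\, y_{c,i}\log L_i[c]
   + (1-y_{c,i})\log(1-L_i[c])\big). \]

Note the leading minus: the loss is implemented as the negative of the
printed sum of log-probabilities so that minimizing it maximizes the
likelihood; without it "optimization" would maximize the error.
Probabilities are clamped to `[1e-7, 1 - 1e-7]` so the loss stays finite at
saturated outputs. The per-pair reduction is a sum, with a mean option.

Three dataset-construction rules matter:

* **Label propagation.** Ground truth is article-level (a gene is *the*
  target of the CRMs studied in an article); every paragraph pair of that
  gene in that article inherits the label. A truth entry with neither role
  is treated as unlabeled, not as a labeled negative.
* **Negative down-sampling.** Per article, pairs of unlabeled genes are
  down-sampled to that article's count of target-gene pairs (all kept if
  fewer exist), seeded and reproducible.
* **Instance weights.** \(w_i\) is the reciprocal of the number of retained
  paragraphs mentioning the same gene in the same article, computed *after*
  down-sampling so that each (article, gene) group contributes exactly
  total weight 1 — long papers do not dominate the loss. The post-sampling
  ordering is a package decision; it is what makes the unit-mass property
  exact.

The positive weights default to the negative/positive pair-count ratio on
the training data (`weights_mode = "ratio"`), with a fixed mode
(`1.39` target, `4.35` TF) preserving the constants used in the original
curation-scale setting, whose derivation split is not documented. Doubling
all instance weights leaves the fitted predictions essentially unchanged
(adaptive-gradient training is scale-invariant up to its epsilon), which
the tests verify.

# Step 4 and evaluation

A gene is reported for a role iff at least one of its pairs clears the 0.7
threshold; the article-level score is the max over the gene's paragraph
probabilities, which reproduces the at-least-one rule at every threshold
and makes summaries permutation-invariant and monotone in the threshold.
The name-occurrence baseline scores a gene by its total mention count
across the article's retained paragraphs (decision: count strictly greater
than a threshold) and is evaluated per label against each truth set.

Evaluation implements precision, recall, F1, TNR = 1 − FPR; ROC by
threshold sweep with ties grouped (the trapezoidal area equals the
Mann-Whitney statistic, which the tests check to 1e-9); PR with step-wise
integration (linear PR interpolation overstates area); and macro metrics as
unweighted means of the two labels' values. Zero-denominator ratios are
reported as 0 with a degeneracy flag instead of propagating NaN into macro
means.

Macro ROC/PR curves use a **shared threshold sweep** over the union of both
labels' scores, with the macro recall/FPR/precision at each threshold being
the mean of the two labels' values. One consequence worth stating: the area
under the shared-threshold macro curve is *not* in general the mean of the
two one-label areas. For one perfectly separated label (scores at 0/1) and
one uninformative label (uniform scores), the macro curve runs
(0,0) → (0,½) → (½,1) → (1,1), area 7/8 — whereas the mean of the areas is
¾. Both quantities are computable with the package; the curves follow the
shared-threshold definition because that is the construction the macro
curve is defined by. A label with no predicted positives at some threshold
contributes precision 1 at that point (the empty-prediction limit), which
anchors the PR curve at recall 0.

# The synthetic corpus: what it emulates, and what it does not

`generate_corpus()` builds, from one seed and byte-reproducibly: a
PubMed-style abstract CSV, JATS full texts for the CRM-positive articles, a
symbol → synonyms TSV, a stoplist, and complete ground truth. Its
statistical structure mirrors the assumptions the pipeline exploits:

* CRM-positive abstracts carry a multiword CRM cue phrase with probability
  `cue_strength` *and* draw part of their vocabulary from a small
  regulation-topic word set; negatives leak both at `leak_rate` (default
  0.02). The topical tilt reflects that CRM papers differ in overall
  vocabulary, not by a single phrase; it also means a cue-presence rule
  alone is not Bayes-optimal unless `cue_strength = 1, leak_rate = 0`.
* Inside positive articles, each gene's role (target with probability 0.6,
  TF with 0.35, independently — so some genes carry both) plants a role cue
  phrase adjacent to the mention. The *first* paragraph of a labeled gene
  always carries its cue, further ones with probability `cue_strength`, so
  a perfect comprehender can reach recall 1.
* Role cues are planted independently of how often a gene is mentioned,
  which is exactly what the occurrence-counting baseline cannot see — the
  baseline comparison is meaningful by construction, not by accident.
* Methods and Acknowledgements sections contain decoy mentions that must
  never reach the pair dataset, and a configurable fraction of genes gets a
  stoplist-colliding synonym, exercising the ambiguity filters.
* `corruption_suite()` plants exact counts of blanked abstracts, malformed
  XML files and synonym collisions, returning the manifest so robustness
  tests can assert that precisely the planted defects are skipped.

What the generator does **not** emulate: linguistic realism (backgrounds
are random tokens from a synthetic vocabulary), sub-word token statistics
of biomedical text, co-occurring genes within one paragraph (each generated
paragraph mentions one gene, so role cues are never attributed to a
bystander gene), negation or coreference, and the long-tailed section
structures of real JATS. Passing the end-to-end checks therefore
demonstrates that the pipeline's machinery — imbalance handling, pairing,
weighting, thresholding, aggregation, evaluation — recovers planted
structure; it does not certify extraction accuracy on real prose, which
depends on the encoder one plugs in.

# Problem sizes and defaults used in the package's own studies

The shipped studies (test suite and `scripts/acceptance.R`) use a
300-article corpus at 20% CRM prevalence with `cue_strength = 0.9` for the
end-to-end check (60/20/20 train/ensemble/test split for Step 1, 30
training epochs for both models), and a 2,200-article corpus (200
positives, 2,000 negatives) for the imbalance/ensemble study. These sizes
were chosen as the smallest at which the ensemble statistics are stable;
all are parameters, not constants.

# Known limitations

* The default encoder ignores word order beyond bigrams; the comprehension
  model cannot distinguish "A regulates B" from "B regulates A" inside one
  window unless a stronger encoder is supplied through the contract.
* The aggregator's probability blend (γ = 0.05) is a ranking refinement,
  not a calibration; aggregated probabilities should not be read as
  calibrated posteriors.
* Regulatory direction (activator/repressor) and CRM sequence extraction
  are out of scope; the pipeline stops at per-article gene/TF lists with
  supporting paragraphs.
* PDF and supplementary-file parsing are not attempted; an article is
  either JATS XML or abstract-only.
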