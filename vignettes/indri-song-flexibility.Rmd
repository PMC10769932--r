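---
title: "Quantifying vocal-sequence flexibility in indri songs"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying vocal-sequence flexibility in indri songs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## The problem

Indris (*Indri indri*) are the only singing lemurs. Family groups produce
loud territorial songs — duets of the reproductive (dominant) pair, often
joined by non-dominant group members in choruses. Each singer's
*contribution* to a song can be transcribed as a sequence of phrase-type
tokens over a closed six-symbol alphabet: the single unit `SU` and
descending phrases of two to six notes, `DP2` … `DP6`. Other annotation
labels (e.g. long notes, `LN`) fall outside the analysis alphabet and are
filtered out on ingest.

`indriflex` quantifies how *flexibly* singers concatenate these phrases,
along three complementary axes, and provides the statistical comparisons
across sex and social status (dominant female, dominant male,
non-dominant):

1. **Concatenation flexibility** — Jaro similarity between contributions,
   pooled into a pairwise matrix, expanded into a dyadic within/between
   dataset, and modelled with a linear mixed model.
2. **Phrase diversity** — normalized diversity (distinct phrase types over
   contribution length), modelled with a mixed model and tested for
   covariation between duetting dominants.
3. **Predictability** — the entropy rate of a first-order Markov chain
   fitted to each singer's phrase transitions.

A synthetic-corpus generator reproduces the statistical structure these
analyses assume, so the whole pipeline is testable without field
recordings.

## The statistics

### Jaro similarity over token sequences

For token sequences $a$, $b$, symbols match when equal and within the
window $w = \lfloor \max(|a|,|b|)/2 \rfloor - 1$ (floored at 0), assigned
greedily left to right. With $m$ matches and $t$ transpositions (half the
number of matched symbols out of order),

$$\mathrm{sim}(a,b) = \frac{1}{3}\left(\frac{m}{|a|} + \frac{m}{|b|} +
\frac{m-t}{m}\right), \qquad \mathrm{sim} = 0 \text{ when } m = 0.$$

We store the *similarity* orientation (1 = complete match): lower values
mean greater flexibility. Matching is **token-level** by default — each
phrase type is one symbol. Character-level matching on the pipe-delimited
text (`level = "character"`) is available for compatibility with generic
string-distance tooling, but it overweights multi-character labels
(`"DP3"` and `"DP5"` share the substring `"DP"` despite being distinct
phrases), so the token mode is canonical here. Plain Jaro is the default;
a Winkler prefix boost is available behind `winkler_p` but off by default.

Every unordered pair of contributions yields one record in the dyadic
dataset: the dyad of singers, the distance type (`within` if both
contributions came from the same individual), and a combined factor with
up to nine levels — `WDF, WDM, WND` (within-individual, by category),
`BDF, BDM, BND` (between individuals of the same category), and
`B-DF-DM, B-DF-ND, B-DM-ND` (between categories). Within-individual pairs
pool contributions across all of a singer's songs. Only the upper
triangle is kept: the matrix is symmetric and mirroring records would
duplicate every observation.

The model (`fit_distance_lmm`) is $\sqrt{\mathrm{JD}} \sim
\text{factor} + (1\,|\,\text{dyad})$, fitted by maximum likelihood and
tested against the random-effect-only null with a likelihood-ratio test
(9 levels $\Rightarrow$ df $= 8$), followed by Tukey-adjusted all-pairs
contrasts with Kenward–Roger denominator degrees of freedom where
available (Satterthwaite otherwise; the report names the method used —
Kenward–Roger's marginal-covariance computation is quadratic in the
number of records, so the fallback engages automatically on large dyadic
datasets).

### Normalized diversity

For one contribution, $\mathrm{ND} = \text{distinct phrase types} /
\text{length in tokens}$: `DP2|DP3|DP3|DP5|DP4` has 4 types over 5
tokens, $\mathrm{ND} = 0.8$. The token count is the denominator
throughout — it is the only operational definition available, and a
duration-based variant would require acoustic timing that sequence data
do not carry. ND is order-free (a permutation of the tokens leaves it
unchanged — the deliberate contrast with Jaro similarity, which is
order-sensitive), bounded by $(0, 1]$, and saturates at $6/\text{length}$
for contributions longer than six tokens because the alphabet is closed:
a combinatorial ceiling that compresses differences between long
contributions.

`fit_diversity_lmm` models $\log \mathrm{ND}$ (natural log; the base only
rescales the response) on singer category with crossed random intercepts
for singer and song. Duet covariation (`group_covariation`) is the
Spearman rank correlation, within each group, between the dominant
female's and the dominant male's ND over the songs in which both sang
(chorus songs included; non-dominant presence does not exclude a song).
Groups with fewer than three shared songs are reported `untested` rather
than silently dropped.

### Markov entropy rate

Each singer's contributions are pooled into an empirical first-order
transition matrix; transitions never span contribution boundaries. With
stationary distribution $\pi$ ($\pi P = \pi$),

$$H = -\sum_i \pi_i \sum_j P_{ij} \log P_{ij}, \qquad 0 \log 0 \equiv 0,$$

in nats by default (`log_base = 2` gives bits; category comparisons are
base-invariant). $H = 0$ for deterministic cycling, $H = \log k$ for
iid-uniform emission over $k$ states; higher $H$ means less predictable,
more flexible singing. The analytic computation is canonical; a
simulation-based estimator (`simulate_entropy_rate`, which re-estimates
the matrix from long simulated realizations and averages the plug-in
rates) mirrors the simulation procedure common in the field and doubles
as a validation path — the two agree within Monte-Carlo error on
irreducible chains.

Sparse empirical chains are often reducible (absorbing states from short
sequences). The stationary distribution restricts to the recurrent
communicating class; with several recurrent classes there is no unique
$\pi$ and `stationary_distribution` raises a diagnostic naming the
classes, while the per-singer table (`entropy_table`) restricts to the
class carrying the most observed transitions — the pragmatic choice for
small samples. Optional add-$\alpha$ smoothing (`alpha`, default 0)
restores irreducibility instead when full 6-state support is wanted.
Observed-state support without smoothing is the default because it adds
no pseudo-observations to small samples.

Entropy rates are compared across the three categories with a
Kruskal–Wallis rank-sum test (df $= 2$), and between the paired dominants
of each group with a Spearman correlation.

### SVM classification

`svm_classify_categories` asks whether category membership is decodable
from concatenation style alone. Each contribution is represented by its
row of Jaro similarities to the training reference set (the training
strings themselves), classified with an RBF-kernel SVM. $(C, \sigma)$ are
tuned by grid search — powers of 4 spanning $2^{-5}..2^{15}$ and
$2^{-15}..2^{3}$ respectively — ranked by 10-fold cross-validated
accuracy within a stratified 70% training split, then scored on the
held-out 30%. The feature construction is a design choice (the
similarity-profile reading of "classification from JD values"); a
precomputed-kernel alternative that feeds the similarity matrix directly
to the SVM is available behind `kernel_mode = "precomputed"`, with the
caveat that a Jaro similarity matrix is not guaranteed positive
semi-definite. All randomness (split, folds) is seeded.

## The synthetic generator

`synthetic_config()` / `generate_corpus()` emulate the study population
the analyses were designed for: 10 groups (default), each with one
dominant female, one dominant male and 0–3 non-dominants (default 2), 60
songs per group — about 600 songs and 1200+ dominant contributions, the
scale of the real corpus (599 songs; 599/566/363 strings from dominant
females/males/non-dominants across 39 singers). The female sings in
every song; the male joins with probability `p_dominant_male_sing`
(default 1), each non-dominant with `p_nondominant_sing` (default 0.3,
matching the observed ~0.6 non-dominant strings per song with two
candidates per group).

Emission is a first-order Markov chain per singer — the same model class
the entropy analysis fits, so parameter recovery is exactly testable.
Category structure enters through symmetric-Dirichlet concentrations
(default DF 1.0, DM 0.8, ND 1.3, mirroring the flexibility ordering the
analyses are designed to detect: small concentration = peaked,
stereotyped rows). By default each singer draws their *own* matrix from
the category's concentration (`matrix_level = "singer"`): individual
vocal signatures are what the within- vs between-individual contrast
presupposes, and a generator without them cannot produce that contrast.
A `"category"` mode (one shared matrix per category) provides the
exchangeable regime used for null calibration. Initial tokens are drawn
from the stationary distribution of the emitting matrix, avoiding
transient bias. Contribution lengths are `1 + ` geometric with mean 12
tokens by default (a negative-binomial option gives tighter dispersion);
the per-contribution length distribution of the real corpus is not
reported, so this is a modeling choice, not an inference.

**Duet coupling.** The covariation analysis needs a generator that can
induce rank correlation between the paired dominants' per-song
diversity. Each song draws a bivariate-normal latent pair
$(z_f, z_m)$ with correlation `duet_coupling` (default 0.6 — moderate
positive, consistent with most duetting pairs covarying). A singer's
latent level acts through two channels, both monotone in ND: a low level
(a) mixes the singer's matrix toward pure repetition of their *anchor
phrase* — the modal state of their stationary distribution — with weight
up to `coupling_w_max` (default 0.5), and (b) lengthens the expected
contribution on the log scale by `coupling_length_sigma` (default 0.4):
low-diversity songs are long and repetitive, high-diversity songs
concise and varied. An earlier single-channel design that only flattened
the transition rows toward uniform turned out to barely move ND —
richness is governed by the stationary distribution rather than row
entropy, and independent length noise in ND's denominator swamps the
rest — so the two-channel construction is deliberate. With
`duet_coupling = 0` the latent levels are independent and per-group
Spearman correlations center on zero (verified by simulation); setting
`coupling_w_max` and `coupling_length_sigma` to 0 switches the
modulation off entirely, the configuration used for calibration studies.

What the generator does **not** emulate: acoustic realism, timing and
overlap, ontogenetic change in non-dominants, song-level repertoire
drift, and any dependence between a singer's consecutive songs beyond
the shared matrix. Passing tests therefore certify the statistical
machinery under the stated model, not the biology of real corpora.

## Calibration findings and problem sizes

The test suite calibrates both mixed-model pipelines by simulation.
Sizes were chosen to keep each replicate's fit well-posed while giving
the power studies headroom: the distance pipeline uses 5 groups × 6
songs with 2 non-dominants (≈ 90 contributions, ≈ 4000 dyadic records
per replicate; 200 replicates per arm), the diversity pipeline 6 groups
× 8 songs (200 replicates per arm), entropy recovery 10^5-token chains.
Injected effects (a strongly stereotyped non-dominant category,
concentration 0.05 vs 1.0 at category level for distances; 0.03 vs 1.0
at singer level for diversity) are detected in well over 90% of
replicates, and the diversity model's matched-generator null rejects at
the nominal 5%.

One calibration result deserves emphasis. Under a matched-generator null
the **distance** model's likelihood-ratio test is strongly
anticonservative (empirical type-I error ≈ 0.3–0.5, growing with corpus
size). This is not a fitting artifact — replacing the response with iid
noise on the same design yields exactly the nominal 5% — but a property
of the dyadic expansion itself: every contribution appears in $n-1$
records, and the dyad random intercept cannot absorb the resulting
cross-record dependence, because each dyad occupies exactly one factor
level. Any implementation of this model inherits the effect, and
omnibus $\chi^2$ values from full dyadic expansions should be read
accordingly. `thin_dyad_records(mode = "disjoint")` — which keeps a
maximal set of records with pairwise-disjoint contributions — restores
near-nominal calibration at the cost of discarding most records, and is
the recommended companion analysis when type-I control matters.

## Numerical choices and degenerate inputs

* Jaro: computed in C++ on integer-coded tokens; the 1528×1528
  study-scale matrix builds in about a second. Empty sequences are
  errors; length-1 contributions are retained in the corpus (their Jaro
  values are well-defined) while entropy estimation, which needs at
  least one transition, drops such singers with a warning.
* Stationary distributions: dominant left eigenvector, power-iteration
  fallback (tolerance 1e-12, ≤ 1e5 iterations); periodic irreducible
  chains are handled by the eigen route.
* Contribution order is significant everywhere; within-contribution
  silent gaps are not modelled — each contribution is one unbroken
  sequence.
* TextGrid ingest accepts both text dialects and UTF-8/16 encodings;
  song ids default to file base names; unmapped tiers are skipped with a
  warning rather than an error.
* Ties in Spearman correlations use midranks (`exact = FALSE`).
* All simulation entry points take explicit seeds and restore the
  caller's RNG state.

## Known limitations

* The dyadic distance model replicates the published analysis structure,
  including its pseudo-replication (see above); the package documents
  rather than silently corrects it.
* ND conflates repertoire use with contribution length by construction;
  the combinatorial ceiling makes long contributions look uniformly
  "undiverse".
* Entropy rates from singers with few transitions are noisy, and
  restriction to the dominant recurrent class discards rare-phrase
  structure; the per-singer transition counts are reported so users can
  filter.
* The SVM feature construction is one defensible reading of
  "classification from distance values"; results can differ under the
  precomputed-kernel alternative.
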