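---
title: "Extracting skeleton-specific MS/MS signatures and compiling MassQL queries"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Extracting skeleton-specific MS/MS signatures}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(spectrasig)
```

## The model

`spectrasig` treats an annotated spectral library as a supervised
classification problem over *signals*. A signal is either a fragment ion
m/z or a neutral-loss value (`precursor − fragment`), harmonized to a
shared 4-decimal representation across the library. Each spectrum carries
one expert skeleton label (or none); a skeleton's *spectrometric signature*
is a small conjunctive set of signals that retrieves that group's spectra
and little else.

The assumptions behind this model are worth stating:

* **Single collision energy, positive mode, charge 1.** Signals are only
  comparable across spectra when fragmentation conditions match; the
  library is assumed homogeneous. Neutral-loss computation and deisotoping
  assume singly protonated precursors.
* **One skeleton per spectrum.** Multimeric compounds containing two
  different skeleton units would break the group partition; libraries
  should be restricted to monomeric entries before extraction.
* **Conjunctive queries.** A query matches a spectrum only if *every* one
  of its signals matches within tolerance. Adding a signal can therefore
  never grow the retrieved set — recall is non-increasing and precision
  tends to rise, which motivates the two-stage scoring below.

## The two F-scores

Candidate signals are scored per skeleton with

$$F_\beta = (1+\beta^2)\,\frac{P\cdot R}{\beta^2 P + R},$$

where for a signal, \(P = tp/occ\) (its in-group occurrences over all its
occurrences) and \(R = tp/G\) (over the group size). Stage one uses
\(\beta = 2\): recall matters more, because a low-precision signal can be
rescued by conjunction with others, while a low-recall signal poisons
every combination it joins. Stage two scores whole queries against the
*raw* library with \(\beta = 0.5\): once combinations are on the table,
precision is the scarce commodity.

Worked numbers: a fragment found in 16 spectra, 11 of them inside a
12-member group, has \(P = 11/16\), \(R = 11/12\), and

```{r}
fbeta(11 / 16, 11 / 12, beta = 2)
```

The source publication prints "= 0.90" for this same example; its displayed
formula, which this package implements, evaluates to 0.859375. We follow
the formula (verified against an independently coded oracle in the test
suite) and note the discrepancy rather than reproducing the printed
rounding.

## The extraction pipeline

1. **Deisotoping.** A peak one or two ¹³C spacings (1.00336 Da) above a
   more intense peak, within tolerance, is removed. The upstream tool's
   exact algorithm is not public; this single-pass, charge-1 rule is a
   documented stand-in and can be disabled (`deisotope_enabled = FALSE`).
2. **Concurrent-fragment reduction.** Peaks chained within the tolerance
   window collapse to the most intense member; at equal intensity the lower
   m/z wins (determinism).
3. **Precursor-region removal.** Peaks at or above the precursor are
   dropped; spectra emptied here are excluded from the matrices and logged.
4. **Normalisation** to the base peak, so losses inherit comparable
   intensities.
5. **Harmonization.** All values of one kind are pooled, sorted, and
   clustered by a greedy single-linkage scan under the tolerance window;
   each cluster is represented by the intensity-weighted mean m/z rounded
   half-away-from-zero to 4 decimals. Weighted mean (vs median) was an open
   choice; it is stable, cheap, and respects intensity-carrying peaks.
6. **Candidate scoring and combination search** as described above, with
   queries evaluated by conjunctive tolerance matching against the raw,
   unprocessed spectra.

### Tunable parameters

| parameter | default | unit | rationale |
|---|---|---|---|
| `tolerance$absolute` | 0.010 | Da | QTOF-class accuracy; combined with ppm by `max` (the permissive reading of "10 mDa or 25 ppm"; the two agree at m/z 400) |
| `tolerance$ppm` | 25 | ppm | as above |
| `min_occurrence` | 3 | spectra | signals rarer than 3 occurrences cannot be distinguished from noise |
| `max_rank` | 10 | candidates | caps combination search at \(\sum_k \binom{n}{k}\) subsets; 10 keeps exhaustive search tractable |
| `max_signals` | 10 | signals/query | avoids over-specific, uninterpretable queries |
| `min_group` | 5 | spectra | below 5 members, F-scores are too coarse to rank queries |
| `min_score` | 0 | F₂ | optional floor on candidate quality |
| `beta_candidates` / `beta_query` | 2 / 0.5 | — | recall-weighted selection, precision-weighted evaluation |

### Numerical choices and degenerate inputs

* Rounding of representative m/z is half-away-from-zero (base R `round()`
  is half-to-even, which would make bin representatives depend on the
  parity of the fourth decimal).
* `fbeta(0, 0, beta)` is 0 by convention; `beta <= 0` is an error.
* Queries whose retrieved set is empty score 0 and are not reported;
  supersets of an empty-retrieval query are pruned (provably loss-free, and
  checked against a brute-force enumerator in the tests). If *nothing*
  scores above 0 the skeleton yields an empty result with a notice.
* Tie reporting is exhaustive and deterministic: all queries within 1e-12
  of the best F₀.₅ are returned, sorted by size then by signal m/z.
* Universal in-group signals do not consume top-10 ranking slots, and
  precision-1 ("specificity 1") signals are always kept at least as
  standalone queries — they need no combination to be useful.
* Fragments and losses compete in one pooled candidate set per skeleton
  (the cap is not per kind); this was an open reading, decided in favour of
  the pooled set because the two kinds are interchangeable in queries.

## Similarity analyses

**Structures.** Skeleton SMILES are fingerprinted with the Morgan algorithm
(radius 2, 2048 bits — ECFP4-equivalent) and compared with the Tanimoto
coefficient; both-empty fingerprints score 1 by convention. RDKit performs
the SMILES chemistry through the bundled Python helper; similarity and
clustering are R code. The dendrogram uses average linkage (UPGMA) on
1 − similarity — the linkage is not dictated by the method and is exposed
as an argument — with a canonical flip rule (lighter subtree first, ties by
smallest label) so the heatmap leaf order is reproducible under any label
permutation.

**Spectra.** The classic cosine matches peaks directly within tolerance;
the modified cosine additionally allows matches offset by the precursor
mass difference, recognising analogues that differ by one substituent. Both
use greedy one-to-one assignment by descending intensity product — the
standard construction in networking tools. Greedy assignment is the
documented contract; an adversarial arrangement of conflicting direct and
shifted matches could in principle score a modified cosine below the
classic one, but this does not arise on realistic (or random) spectra and
the `modified >= classic` invariant is asserted over random pairs in the
tests. The default heatmap tolerance is 0.02 Da, the conventional
networking value, wider than the extraction tolerance.

## What the synthetic generator emulates — and what it does not

`simulate_library()` produces the statistical structure the algorithm
consumes: groups of spectra sharing planted group-specific fragments and
losses (the stated clean world: 4 groups × 8 members, 2 fragments + 1 loss
each, 30 noise peaks per spectrum, jitter sd 2 mDa, no dropout, no
overlap), plus parameterized degradation (dropout of planted signals,
decoy leakage into out-groups). Guards keep the clean regime actually
clean: planted m/z values are separated by > 3 tolerance windows, noise
avoids ±2.1 Da around planted fragments (covering the ¹³C spacings the
deisotoper looks at), and precursors are rejected near `fragment + loss`
sums, which would otherwise alias one group's loss onto another group's
fragment. Intensities are exponential with the base peak planted only half
the time, so normalisation stays nontrivial.

It does **not** imitate real fragmentation chemistry: no correlated
fragment series, no isotope envelopes beyond what deisotoping needs, no
retention time, no intensity structure tied to chemistry. A green
end-to-end test therefore establishes that the machinery is correct on its
stated statistical world — not that any particular real library will yield
high-F queries.

`simulate_extract()` plays the role of a multi-extract feature dataset:
spiked features carry a full group signature, background features avoid all
signature neighborhoods, and each feature carries plant/genus metadata so
the genus-attribution summary (`genus_attribution()`, duplicate plant
columns merged by mean before aggregation) can be exercised end to end.

## Evaluation vocabulary

`retrieval_metrics()` computes precision over *reference-annotated*
retrieved features and recall over *reference-annotated* relevant features.
The source evaluation labels the former "accuracy"; its arithmetic
(true positives over annotated retrieved items) is a precision, and the
package reports it as such. Zero denominators yield `NA`, never 0.

## Known limitations

* Exhaustive combination search is exponential in the candidate count; the
  top-10 cap keeps it tractable, but libraries whose groups have many
  universal signals can still enumerate large tie sets (an all-identical
  degenerate library ties every subset).
* No charge deconvolution beyond 1+, no profile-mode centroiding, no
  mzML/mzXML input — MGF only.
* The native MassQL runner interprets only the `MS2PROD`/`MS2NL`
  conjunctions it emits; emitted statements carry the absolute tolerance
  component only.
* Embedding-based spectral scores (Spec2Vec, MS2DeepScore) are pretrained
  external models and are out of scope; `similarity_heatmap()` accepts only
  the two cosine variants.
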