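---
title: "Discriminative n-gram motif discovery: model, parameters, and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discriminative n-gram motif discovery}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(motifgram)
```

## The model

`motifgram` treats a protein sequence of length $k$ as the bag of its
$k - n + 1$ overlapping n-grams and asks, for each n-gram, whether its
occurrence frequency is concentrated in a single class. The discriminative
n-grams of a class, mapped back onto its sequences and merged, are short
class-specific motifs. The method is deliberately alignment-free: it assumes
nothing about motif position, gaps, or domain architecture, only that a
class-specific signal recurs as a (nearly) exact short string.

Occurrences are counted individually: an n-gram appearing twice in one
sequence contributes 2 to its class count. This matches the frequency
interpretation of the selection rule ("appears more than $T$ times the mean
of its occurrence elsewhere") and makes per-class totals obey the exact
conservation identity $\sum_i (k_i - n + 1)$.

### Substitution combining (SF1 vs SF2)

Two n-grams of the same size are *similar* when they differ at exactly one
position and the differing residue pair $(\alpha, \beta)$ scores at least 1
in BLOSUM62. For every observed n-gram, taken as the seed of its own group,
the raw class counts of all its similar n-grams *present in the data* are
summed into the seed's enriched counts; the group is displayed in bracket
notation (`TL[SN][NDS]PK`). Three choices here were genuinely open and are
fixed as follows:

* **Seed-centric, overlapping groups.** Every n-gram gets its own group;
  groups are not merged transitively. Transitive closure would chain
  unrelated n-grams through intermediate neighbors and blur the class
  signal.
* **Observed neighbors only.** The $19n$ theoretical single-substitution
  variants are not enumerated into the counts; only variants that occur in
  the dataset contribute (they are the only ones with counts at all).
* **Grouping always uses raw counts.** When a constituent later serves as
  the seed of its own group, its neighbors' *raw* counts are summed —
  enriched counts are never fed back, which would double-count shared
  neighbors.

When a combined n-gram qualifies as discriminative, all its constituents
are emitted as discriminative with the combined DR — the group, not the
individual string, is the unit of evidence. Disabling the combining step
entirely gives the SF2 variant, useful as an ablation.

### Dampening

Counts are multiplied by $\ln(|C| / (k - 0.1))$, with $k$ the number of
classes the n-gram occurs in. This is the inverse-document-frequency idea:
an n-gram confined to one of 10 classes is boosted by $\ln(10/0.9) \approx
2.41$, one present everywhere is shrunk to $\ln(10/9.9) \approx 0.01$. The
$-0.1$ exists because $\ln(|C|/|C|) = 0$ would erase ubiquitous n-grams
entirely; it is applied uniformly at every $k$ (not only at $k = |C|$) so
the factor stays strictly decreasing with no discontinuity. Presence $k$ is
computed from *raw* counts: substitution pooling already spreads counts
across classes, and letting it also inflate presence would dampen exactly
the variants the combining step is meant to rescue. Per-class sequence
counts are deliberately not used for normalization — n-gram frequencies are
not uniform in nature even in balanced data.

### The discriminative ratio and its degenerate cases

With dampened weights sorted $w_1 \ge w_2 \ge w_3$ (larger classes ignored),
$DR = w_1 / \bar w$ where $\bar w = (w_2 + w_3)/2$, subject to, in order:

1. $w_2 = w_3 = 0 \Rightarrow \bar w = 1$ (avoids division by zero);
2. only $w_3 = 0 \Rightarrow \bar w = w_2$;
3. $0 < \bar w < 1 \Rightarrow \bar w = 1$.

Rule 3 is applied *after* rules 1–2, so a sub-1 second-highest weight from
rule 2 is also floored; without that ordering a weight of 0.01 in the
second class could inflate DR a hundredfold. Consequences worth knowing:

* The statistic needs at least 3 classes. Two-class datasets are rejected
  with an explicit error rather than silently redefining the denominator.
* A top weight tied across two classes can never be selected (the ratio
  collapses to $\le 1 < T$); the implementation also excludes ties
  explicitly.
* Selection uses $DR \ge T$, threshold included.
* Cross-class duplicates keep the record with the highest DR; exact DR ties
  go to the lexicographically smaller class label, then the smaller seed,
  making output order fully deterministic.

### Post-processing

Selected n-grams of all sizes (default 4–8) are pooled per class and
substrings of longer survivors removed — a discriminative 5-gram inside a
discriminative 7-gram is redundant. Survivors are located in their own
class's sequences only (1-based inclusive coordinates); per sequence, hits
sorted by start (ties by descending end, so the longest hit anchors) are
swept left to right and merged whenever a hit starts at most one past the
running end, i.e. overlapping, abutting, *or separated by no residue*.
The pairwise rule is iterated to a fixed point, so chains like
[1,5], [5,9], [10,14] collapse to [1,14], and surviving motifs are pairwise
separated by at least 2. Masking then flips every position outside a motif
to `X`, preserving length and coordinates.

### Patterns

NLSdb-dialect (`KKPx{6,9}Kx{1,3}RK`) and PROSITE-dialect
(`G-S-x(2)-M-x-{RS}-K-x-N`) patterns are converted to standard regular
expressions (`KKP.{6,9}K.{1,3}RK`, `GS.{2}M.[^RS]K.N`). The PROSITE subset
covers literals, `x` wildcards, `(a)`/`(a,b)` repeats, `[..]` classes,
`{..}` exclusions and `<`/`>` anchors; anything else fails loudly with the
offending element. When matching against masked sequences, the `.` wildcard
may by default match the mask character `X` — a wildcard position of a real
signal can legitimately fall in a masked gap — and
`wildcard_matches_mask = FALSE` restricts wildcards to `[^X]` for the
stricter reading. Coverage is the any-pattern fraction of subjects;
per-pattern counts are reported separately by `pattern_matches()`.

## Tunable parameters

| Parameter | Default | Meaning |
|---|---|---|
| `n_min`, `n_max` | 4, 8 | n-gram sizes mined; cost grows steeply with size, and beyond 8 the space is so sparse that counts lose meaning (a warning is emitted) |
| `threshold` (T) | 5 | minimum DR; 5–10 is the useful range, higher is stricter |
| `blosum_threshold` | 1 | minimum BLOSUM62 score for a residue pair to count as similar (1 = any positive score) |
| `substitution` | TRUE | SF1 (with combining) vs SF2 (exact n-grams) |
| `wildcard_matches_mask` | TRUE | whether `.` may match `X` in masked subjects |
| `min_length` | 1 | dataset ingestion filter; curated compendia typically drop sequences under 10 residues |

Non-standard residue codes (B, J, O, U, X, Z, `*`) have no BLOSUM62 column
and no biological reading in this model; records carrying them are dropped
with a warning by default (`nonstandard = "reject"` turns this into an
error).

## The synthetic benchmark

`simulate_dataset()` emulates the structure the scoring function exploits:
several classes of very different sizes (default 30/50/80/120/200), i.i.d.
background residues (uniform by default — the least informative background,
and hence the most sensitive test of the scoring itself; a natural-frequency
preset exists), and per class a small number of class-exclusive motifs
planted into a fixed fraction of sequences. A planted instance carries at
most one BLOSUM62-positive substitution (probability `mutation_rate`),
mirroring the single-substitution combining assumption. Class exclusivity
is enforced by rejection sampling, so ground truth is unambiguous;
generation is fully determined by one seed.

What it does **not** emulate: domain architecture, compositional bias,
homologous background similarity between classes, multi-substitution motif
variants, or motif occurrence count variation within a sequence. Passing
recovery tests here shows the scoring function does what it claims on its
own assumptions — not that those assumptions hold in any particular curated
dataset.

Recovery is scored two ways. A planted motif is *recovered* when a
discriminative n-gram of the correct class occurs entirely inside one of
its planted intervals. A discriminative n-gram is *background* when every
occurrence in its assigned class is disjoint from all planted intervals.
The distinction matters because of junction n-grams — windows spanning a
motif boundary plus flanking residues, which recur at rates governed by the
20-letter flank distribution and are genuine (if partial) signal: they
overlap planted intervals and are therefore counted as neither recovery nor
background.

The packaged benchmark (acceptance script and recovery tests) plants 8-mers
and runs discovery at $n = 8$, the planted length. This is a deliberate
choice: at $n = 4$ the degenerate-case floor ($\bar w = 1$) makes any
4-gram with three-plus occurrences confined to one class discriminative, so
a uniform background of this size yields hundreds of sporadic 4-gram
discoveries *by design* — the method's large real-data harvests at small
$n$ show the same behavior. Planted-length recovery is the property the
benchmark can measure cleanly. The problem sizes used (480 sequences ×
300 residues; 100 reference-comparison datasets of ≤ 35 sequences × ≤ 50
residues) keep the full suite and the acceptance script comfortably fast
while exercising every stage at non-trivial scale.

## Numerical and degenerate-input choices

* All weights are double precision; counts are summed as integers before
  the single multiplication by the dampening factor, so SF1/SF2 results are
  reproducible bit-for-bit across runs and platforms.
* Sequences shorter than $n$ contribute no windows and no error.
* An empty selection propagates as empty tibbles through mapping, merging
  and masking (a sequence without motifs masks to all-`X`).
* Discriminative n-grams that occur in no evaluation sequence are counted
  as false negatives of their class in the confusion matrix, tracked
  separately from the matrix cells; zero-denominator sensitivity or
  specificity is reported `NA`, never coerced to 0.
* ROC curves are anchored at (0,0) and (1,1) and integrated by the
  trapezoidal rule after sorting by FPR; duplicated operating points do not
  change the area.

## Known limitations

* The discriminative ratio is undefined for fewer than three classes; the
  package refuses rather than approximates.
* Substring removal keeps only maximal strings; a shorter n-gram that is
  discriminative for a *different* class than its superstring is still
  removed within its own class pool, but kept if it survives in another
  class.
* Combining considers Hamming distance 1 only. Motif variants with two or
  more substitutions fragment into separate groups and need lower
  thresholds to surface.
* The masking step assumes merged (non-overlapping) motifs and will refuse
  otherwise rather than guess.
* Pattern conversion covers the common PROSITE constructs; exotic
  extensions (repeats on bracket classes, profile syntax) are rejected, not
  silently mis-parsed.
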