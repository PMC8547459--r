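---
title: "Benchmarking 16S classification schemes: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Benchmarking 16S classification schemes: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(schemeval)
```

## The problem

Targeted amplicon sequencing of the 16S rRNA gene identifies bacteria by
amplifying a short variable region of the gene and matching it against a
reference database. Whether that identification reaches the *species* level
depends on three coupled choices — together a **classification scheme**:

* the **database** (which species it contains, and how they are annotated),
* the **identifier** (which variable region, or span of regions, is
  amplified), and
* the **classifier** (the algorithm that assigns a taxon to a read).

`schemeval` evaluates such schemes end to end. Because real reference
databases are large, versioned downloads, the package ships a synthetic
16S-world generator whose ground truth makes every pipeline stage testable,
and it keeps every stage — amplicon extraction, classification, evaluation —
usable on real inputs too (FASTA with Greengenes-, Silva-, or NCBI-style
annotations).

## Region variability: gap-weighted entropy

Whether a region can discriminate species is quantified on a multiple
sequence alignment by per-column Shannon entropy,
$H = -\sum_{b \in \{A,C,G,T\}} p_b \log_2 p_b$, where the $p_b$ are taken
over concrete residues only. $H$ is 0 when a column is perfectly conserved
and 2 bits when all four nucleotides occur equally. Alignment columns
dominated by gaps would otherwise masquerade as conserved sequence, so the
reported value is weighted by the concrete-residue fraction:

$$H_w = H \cdot \frac{n_{ACGT}}{n_\text{rows}}.$$

Ambiguity codes are excluded from the probabilities (keeping the 2-bit bound
exact) but count in the weight's denominator, like gaps. The weighting
function is one of several defensible choices; it is the simplest one that
satisfies the intent, and it is isolated behind `gap_weighted_entropy()` so
it can be swapped. Sliding windows (`sliding_window_profile()`) default to
30 columns with step 1 — narrow enough to resolve individual variable
regions, wide enough to smooth single-column noise; both are parameters, not
claims.

All coordinates in the package are 1-based closed intervals, the convention
of R and of the Bioconductor containers this package interoperates with.

## In silico PCR

`extract_amplicons()` mirrors the anchored extraction procedure: primer
sites are located only on the designated ungapped reference row of the MSA
(an *E. coli*-like anchor), the bracketed interval is mapped to alignment
columns, and every row contributes the degapped slice of those columns.
Matching is exact-length and zero-mismatch with IUPAC degeneracy honored on
the primer side; this finds coordinates, and deliberately does not model
annealing thermodynamics, so primers that would fail in a real reaction can
still "amplify" here. The seven published/designed primer pairs (V1-V3,
V2-V3, V3, V3-V4, V4, V4-V6, V6) ship in `inst/extdata/primers.tsv`.
Whether primer footprints are part of the amplicon is exposed as
`include_primers` (default `FALSE`); on multiple reference sites the default
is an error, with `first_site = TRUE` as a logged opt-in.

## The classifiers

Both classifiers are deliberately small, fully specified
re-implementations of the two classifier *families* used in practice; no
numeric equivalence with any external tool is claimed.

**k-mer naive Bayes** (`train_nb()`, `classify_nb()`). Training records
word *presence per training sequence* (not counts), RDP-style, with
$P(w\mid s) = (m_{ws} + p_w)/(M_s + 1)$ and word prior
$p_w = (n_w + 0.5)/(N + 1)$. The smoothing keeps every probability strictly
inside $(0,1)$, so unseen words penalize but never veto. The full-data label
maximizes $\sum_w \log P(w\mid s)$ over the query's distinct valid words;
`k = 8` is the default word length — large enough to be discriminative at
desk scale, small enough that short amplicons still carry hundreds of words.

**Alignment-based Bayesian LCA style** (`classify_blca()`). The query is
locally aligned (Smith–Waterman, affine gaps: +1/−1, open −2, extend −1)
against every species-labelled record; hits are kept when their *query
coverage identity* — matched columns divided by query length — reaches
`identity_min = 0.80`. A plain local-alignment column identity was rejected
here: any two random sequences share a short perfect local match, so a
column-identity floor filters nothing. The species posterior is
$\propto \sum_\text{hits} e^{\,\text{score}/T}$ over the `top_n = 10`
retained hits ($T = 10$ flattens the softmax enough that near-ties share
posterior mass).

**Bootstrap confidence.** Both classifiers report the percentage of 100
bootstrap replicates that reproduce the full-data label — word subsamples of
size $\lceil W/8 \rceil$ for naive Bayes; query columns resampled with
replacement and hits rescored for the alignment classifier (per-column score
contributions are pre-decomposed so resampling is exact and cheap). The
0–100 scale matches the conventional confidence thresholds (ignore / 50 /
80). All classification is deterministic under a seed.

## The evaluation framework

Per-query assignments are expanded onto the **record-pair grid**: each query
against each distinct species label in the database. An assignment of query
$q$ to label $L$ makes $(q, L)$ an assigned match and all other pairs of $q$
nonmatches. Pairs are scored as:

* **true match** — assigned, and the label is the query's true species;
* **false match** — assigned, any other label;
* **false nonmatch** — the pair $(q, \text{truth}(q))$ left unassigned
  *while the truth species is present in the database*;
* **true nonmatch** — everything else (tabulated for conservation checks,
  excluded from all metrics).

Precision is $TM/(TM+FM)$, recall $TM/(TM+FNM)$, and F their harmonic mean;
each is flagged undefined (`NA`) when its denominator vanishes rather than
silently coerced to 0. Label equality is synonym-aware everywhere
(`synonym_table()` stores transitively closed groups; equality of canonical
group representatives is an equivalence relation by construction). The
synonym check is applied *inside* the equality predicate — before
tabulation — so a nomenclature change can never create a false match and a
false nonmatch from the same pair. Confidence thresholds are strict:
assignments with confidence *below* τ become unclassified, ties at τ are
retained, and thresholding is pure post-processing of a single
classification pass (`run_benchmark()` never re-classifies per threshold).
Genus-only database records contribute no label to the pair grid; their
count is reported. Cohen's kappa (`cohens_kappa()`) handles the binary
agreement tables of validation comparisons, with the degenerate
$p_e = 1$ case defined as 1 under perfect agreement and undefined otherwise.

## The synthetic world

`generate_world()` emulates the statistical structure of a type-strain 16S
set: an ancestral sequence evolves into genus ancestors and then species,
with Jukes–Cantor-style uniform substitution at per-site rates
$\mu_c = 0.01$ in conserved and $\mu_v = 0.15$ in variable blocks, split
half/half between the genus and species levels. The default world has 12
genera × 3 species (36 species — the scale of a curated isolate collection)
over eight alternating 120-nt blocks. Two primer pairs are planted in
conserved blocks: one bracketing a single variable block (`"V1"`) and one
spanning two variable blocks plus the conserved block between them
(`"V2-V3"`), so the single- versus multi-region contrast is testable.
Planted primers are widened at three positions into two-fold IUPAC codes
(exercising degenerate matching) and their footprints are
mutation-protected, so every species matches exactly.

Design choices worth stating plainly:

* **Column-preserving generation.** Indels are *deletions only*, rendered
  as gaps; insertions would break exact column bookkeeping. The true MSA is
  therefore exact by construction and no aligner enters the test loop.
* **Dropout databases** (`make_database()`) remove a uniform
  `round(d · S)` species, recording the mask — emulating databases that
  lack most species of a niche.
* **Query noise** (`make_queries()`) adds i.i.d. substitutions, extending
  the purely computational amplicons toward (but not to) real read noise.

What the generator does *not* emulate — rate heterogeneity beyond the
block dichotomy, chimeras, PCR bias, length variation between species,
palindromic k-mer dependence — bounds what green tests mean: they validate
the *framework* (extraction, classification mechanics, tabulation,
thresholds), not classifier performance on real data.

## Problem sizes and numerical choices

The packaged analyses run at desk scale: the 36-species default world, full
benchmark grids of 2 databases × 2 regions × 2 classifiers × 3 thresholds
(24 scheme results), 100 bootstrap replicates, and 1,000-case brute-force
oracle comparisons. Ties in any argmax are broken lexicographically and
logged, which makes every code path deterministic under a seed. Undefined
metrics propagate as `NA` with explicit flags rather than sentinel zeros.
Display rounding is two decimals; full precision is kept internally.

## Known limitations

* Zero-mismatch primer matching overstates amplification relative to real
  PCR (a stated property of the anchored-coordinate procedure, not a bug).
* The classifiers are desk-scale: no k-mer hashing, no BLAST prefilter; a
  database of 10^5+ records would need both.
* Synonymy applies at species level only; genus renames are out of scope.
* Species-absent (genus-only) reference records can never produce a true
  match; they are surfaced and excluded from the label grid rather than
  guessed at.
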