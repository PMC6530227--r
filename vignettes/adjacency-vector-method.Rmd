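---
title: "Adjacency vectors and group representatives: the method behind ProtAdjacency"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Adjacency vectors and group representatives}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(ProtAdjacency)
```

## The model

ProtAdjacency compares protein sequences without alignment. The premise
is that the local order of residues — which amino acid follows which —
carries enough family signal that a sequence can be reduced to the counts
of its ordered adjacent pairs.

**Adjacency vector.** Fix the 20 canonical amino acids in the order
`r paste(residueOrder(), collapse = ", ")` (alphabetical by the residues'
full names). A sequence of length $L$ is read left to right with a
sliding window of width 2 and step 1, giving $L-1$ ordered pairs; the
adjacency vector $A_x \in \mathbb{N}^{400}$ counts each of the $20
\times 20$ ordered pairs, with element $20i + j$ (zero-based) the count
of (residue $i$, residue $j$). Pairs that never occur count 0, so
$\sum_k A_x[k] = L - 1$. The layout is exactly the flattened $20\times20$
pair matrix: elements 1–20 are `AA`...`AV`, element 400 is `VV`;
`pairIndex()`/`pairLabel()` convert between pairs and layout positions.

**Group representative.** A family sample $\{A_{x_1},\dots,A_{x_n}\}$ is
summarised by the vector $GR_y$ whose $k$-th element is the *median* of
$A_{x_1}[k],\dots,A_{x_n}[k]$. The median is preferred over the mean as
the central-tendency summary because it is insensitive to extreme
members: replacing one member by an arbitrary outlier moves each element
by at most one order-statistic step. The package uses the standard
median convention — middle order statistic for odd $n$, mean of the two
central order statistics for even $n$ — so even-$n$ representatives may
contain half-integers. Values are kept exact and never rounded, because
the similarity statistics consume them directly. (Alternative
representatives such as the mean or a trimmed mean are deliberately not
offered: the elementwise median *is* the method.)

**Similarity statistics.** Each member is scored against a
representative by

* the magnitude $D_{xy} = \lVert A_x - GR_y \rVert$ (Euclidean norm of
  the difference), and
* the angle $\theta_{xy} = \cos^{-1}\!\big(A_x \cdot GR_y / (\lVert A_x
  \rVert\,\lVert GR_y \rVert)\big)$ in radians.

$\theta$ is invariant under positive rescaling of either vector, hence
insensitive to sequence length; $D$ is not. Scoring a sample of $n$
sequences costs exactly $n$ evaluations per statistic (the
"similarity/dissimilarity vector"), versus $n(n-1)/2$ for the
conventional all-pairs matrix, which `pairwiseMatrix()` provides for
contrast (both modes count their evaluations, and the tests assert the
counts). `crossGroup()` scores a sample against a *foreign* family's
representative; the distortion relative to the own-group angles
demonstrates each family's individuality.

## Assumptions and what the method ignores

The descriptor discards everything beyond first-order adjacency:
long-range context, position, physicochemical similarity between
residues (no substitution matrix is involved) and any notion of gaps.
Two sequences with identical pair composition are indistinguishable even
if their global arrangements differ. The family sample is taken as
given; the representative is only as good as the sample's homogeneity.

## Tunable parameters

* **Residue policy** (`strict`, default; `mask`; `drop`). The descriptor
  assumes exactly the 20-letter alphabet, and published datasets in this
  line of work are curated to it, so `strict` — an error naming the
  record and position of the first non-canonical character — is the
  default. `mask` keeps ambiguous characters (`X`, `B`, `Z`, ...) in the
  sequence but skips every window touching one, recording the skipped
  count (so the sum invariant becomes $L-1-\text{skipped}$). `drop`
  deletes them before pairing, which joins their neighbours into a new —
  possibly artefactual — pair. `*` and `-` are never canonical. How to
  treat ambiguous residues is genuinely open in this method family;
  these three policies make the choice explicit and auditable.
* **`normalize`** (`none`, default; `unit`; `length`) affects only $D$.
  The default is the literal formula on raw counts. The optional modes —
  dividing each vector by its Euclidean norm, or by its total pair
  count — are exploratory dials for comparing families of very different
  lengths, where raw $D$ is dominated by length. They are off by default
  because the plain Euclidean magnitude is the defined statistic;
  $\theta$, being scale-free, is the preferred statistic whenever
  lengths differ (and is the acceptance surface of the test suite, see
  below).
* **`precision`** (default 4 decimals) controls table rendering only;
  all computation is done in full double precision, and representative
  export/import is exact.
* **Sorting**: result tables preserve input order; ordering is only
  applied when `sort = TRUE` is passed, and ties then keep input order.

## Numerical choices

* $\theta$ is evaluated in the chord form $2\arcsin(\lVert u - v
  \rVert/2)$ on max-scaled, unit-normalised vectors, with the argument
  clamped to $[0, 1]$. This is algebraically the arccosine of the cosine
  similarity but (i) returns exactly 0 for identical count vectors,
  (ii) keeps full relative accuracy for tiny angles where the naive
  $\arccos$ loses about half the significand, (iii) cannot produce `NaN`
  from floating-point overshoot at either limit, and (iv) survives
  inputs near the overflow threshold because each vector is first scaled
  by its largest component.
* Degenerate inputs: an empty sequence is an error; a length-1 sequence
  yields the all-zero adjacency vector with a warning, keeping the
  counting stage total, and the undefined-angle case is rejected — by
  record name — only where it matters, in `angleTheta()`. A single-member
  family gets a representative equal to its one vector, with a warning,
  and a similarity vector of exactly $(D, \theta) = (0, 0)$.
* The pipeline contains no randomness; reruns of `runGroupAnalysis()`
  with the same configuration are byte-identical, and the run log
  records input hashes, policy, normalisation and versions.

## The class-coherence rule

For labelled families (e.g. coronavirus spike classes), "each class is
coherent" is operationalised as *non-overlapping $\theta$ intervals*:
`runClassReport()` computes each class's $\theta$ range and flags every
sequence whose angle falls outside the range of its *other* class
members (leave-one-out, so a sequence cannot cover itself) but inside
another class's full range. Singleton classes are never flagged. The
leave-one-out refinement matters: without it no sequence could ever be
outside its own range. A flagged sequence is one the method would place
in the other class — the published spike benchmark has exactly one such
virus (MHVJHM, a class II murine hepatitis strain whose angle sits among
the class I values), and the test suite checks that the rule reproduces
that flag from the published angle column. No quantitative assignment
rule exists in this method family; the interval rule is this package's
explicit choice, and the report states its inputs so the rule can be
audited.

## The synthetic family generator

`makeFamily()` draws a uniform-random ancestor over the 20 residues and
derives each member by substituting every site independently with
probability `substitutionRate` to a uniformly chosen *different*
residue; the ancestor is kept as the first member and everything is
deterministic given `seed`. The generator emulates exactly what the
method needs from a family — shared pair composition plus per-copy
noise — and nothing else: there is no substitution matrix, no indels, no
rate heterogeneity, no phylogenetic structure, and uniform composition
unlike real proteomes. Passing tests on these fixtures therefore shows
that the statistics behave as designed under clean group structure
(angles grow with substitution rate; own-group angles beat foreign-group
angles), not that the method resolves real, subtly diverged families.
The real-data checks live in the accession-based tests, which require a
one-time download of the published benchmark FASTAs
(`inst/scripts/fetch-ncbi.R`); the canonical human beta globin sequence
is embedded directly and its published A-row is asserted offline.

Problem sizes used by the test suite and the acceptance script —
families of 5–9 members, 100–150 residues, 20 seeded trials for the
cross-group frequency, 100 random sequences against the brute-force
counting oracle — were chosen as the smallest sizes at which every
property is comfortably away from its decision boundary.

## Known limitations

* Printed $D$ values in the published benchmark tables are not
  reproducible from the literal formula on raw counts (three beta
  globins of different lengths share $D = 0.5568$, smaller than any
  possible distance between distinct integer vectors), indicating an
  undocumented normalisation there; $D$ is therefore validated by its
  metric axioms and an independent oracle, and $\theta$ — which is
  normalisation-free — is the quantitative acceptance surface.
* The descriptor is first-order only; `k`-mer orders above 2, gap-aware
  counting and weighting schemes are out of scope.
* Cross-group results are reported as computed; no significance
  calibration is attempted.
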