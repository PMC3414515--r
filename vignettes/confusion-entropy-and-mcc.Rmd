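---
title: "Confusion entropy, the multiclass Matthews correlation, and the transform linking them"
author: "mccen package"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Confusion entropy, the multiclass Matthews correlation, and the transform linking them}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mccen)
```

## The measures

A classifier on $k$ classes evaluated on $S$ samples yields a confusion
matrix $C$, where $C_{ij}$ counts samples of true class $i$ assigned to
class $j$ (rows = true, columns = predicted, throughout). Accuracy,
$\mathrm{ACC} = \operatorname{tr}(C)/S$, ignores how the errors are
distributed; the two measures this package centres on do not.

**Multiclass MCC.** Encode predictions and truth as $S \times k$ indicator
matrices $X$ and $Y$; the Matthews Correlation Coefficient is the
correlation $\operatorname{cov}(X,Y) /
\sqrt{\operatorname{cov}(X,X)\operatorname{cov}(Y,Y)}$, summing
column-wise covariances. `mcc()` evaluates the equivalent closed form

$$\mathrm{MCC} = \frac{S\,\operatorname{tr}(C) - \sum_i t_i p_i}
{\sqrt{S^2 - \sum_i p_i^2}\,\sqrt{S^2 - \sum_i t_i^2}},$$

with $t_i$ the row sums and $p_i$ the column sums. (The indicator-matrix
definition is kept in the test suite as an independent oracle; the two
routes agree to $10^{-10}$ on randomised sweeps.) MCC is 1 for perfect
classification and 0 for no-information classifiers. When the denominator
vanishes — all mass in one row or one column, or a constant matrix — the
value is defined to be 0, consistent with the limiting no-information
behaviour of those cases.

**Confusion entropy.** For class $j$ let $d_j$ be its row-plus-column mass
$\sum_l (C_{jl} + C_{lj})$ (the diagonal entry counted twice). The
misclassification probabilities *subject to class $j$* are
$P^j_{j,i} = C_{ji}/d_j$ and $P^j_{i,j} = C_{ij}/d_j$ for $i \neq j$, and
the confusion probability of the class is $P_j = d_j / (2S)$ (so
$\sum_j P_j = 1$). Then

$$\mathrm{CEN} = \sum_j P_j\, \mathrm{CEN}_j, \qquad
\mathrm{CEN}_j = -\sum_{i \neq j}\left[
P^j_{j,i} \log_{2(k-1)} P^j_{j,i} + P^j_{i,j} \log_{2(k-1)} P^j_{i,j}
\right],$$

with $0 \log 0 = 0$, implemented by skipping zero terms rather than by an
epsilon shift (the convention is the limit $x\log x \to 0$, and an epsilon
would bias small-count matrices). The logarithm base $2(k-1)$ is the
number of off-diagonal cells a class can confuse into, which normalises
CEN to $[0,1]$ for $k \ge 3$: 0 exactly on diagonal matrices, 1 for the
balanced complete misclassification matrix (zero diagonal, constant
off-diagonal). At $k = 2$ the base degenerates to 2 and CEN can exceed 1:
for matrices $\begin{pmatrix} t & n \\ n & 0\end{pmatrix}$ this happens
exactly when $t/n < 1$ (e.g. `binaryMetrics(1, 2, 2, 0)` gives
CEN $\approx 1.034$), one reason CEN is a poor yardstick for binary tasks.

Classes with $d_j = 0$ never occur and are excluded: $P_j = 0$ forces a
zero contribution under the limit convention. One edge case is worth
knowing: a class whose entire mass sits in a *single* off-diagonal cell
has zero entropy (the confusion is deterministic), so CEN can be 0 on a
non-diagonal matrix such as $\bigl(\begin{smallmatrix}0 & 1\\ 0 &
0\end{smallmatrix}\bigr)$. For matrices with a positive diagonal, CEN = 0
if and only if the matrix is diagonal.

Both measures are invariant under multiplication of $C$ by a positive
scalar — which is why `ConfusionMatrix` accepts real-valued entries — and
equivariant under simultaneous row/column permutations.

## The transform: tMCC

On the *uniform off-diagonal* family (diagonal $N$, all off-diagonal
entries $n$), both measures collapse to one-parameter closed forms:
$\mathrm{MCC} = (N-n)/r$ and
$\mathrm{CEN} = (k-1)\frac{n}{r}\log_{2(k-1)}\frac{2r}{n}$ with
$r = N + (k-1)n$. Substituting $n/r = (1-\mathrm{MCC})/k$ eliminates the
family parameters:

$$\mathrm{CEN} \;=\; \frac{k-1}{k}\,(1-\mathrm{MCC})\,
\log_{2(k-1)}\frac{2k}{1-\mathrm{MCC}} \;=\; \mathrm{tMCC}.$$

`tmcc()` is this right-hand member. On the family the identity is exact
(`tmcc(mcc(M), k) == cen(M)` to machine precision); on general matrices it
is an approximation whose quality is the subject of the relation study
below. The transform's natural domain is
$-1/(k-1) \le \mathrm{MCC} \le 1$: the upper end maps to CEN 0, the lower
end (the family's complete-misclassification limit) maps to CEN 1. More
negative MCC values do not arise from the family and the transform is not
meaningful there; `tmcc()` raises a classed domain error by default, or
clamps to the boundary under `policy = "clamp"`. `metricsReport()` records
NA in that regime.

## Limit-case families

Three constructors provide analytic anchors (each closed form is
implemented separately from the generic measures, so the pair
cross-checks both):

* `makeUniformOffdiag(k, N, n)` — the exact-identity family above.
* `makeSingleCorner(k, w)` — all ones except entry $(k, 1) = w$. Accuracy
  $k/(k^2 - 1 + w)$ and MCC ($\to -1/(2(k-1))$) decrease monotonically in
  $w$, while CEN *also* decreases, towards 0: an arbitrarily badly
  performing classifier with arbitrarily small confusion entropy, because
  the error mass concentrates in one deterministic cell.
* `makeDice(k, m)` — all ones with last row $m$: a no-information
  ("dice rolling") classifier on classes unbalanced by $m$. MCC is
  identically 0 on this family, but CEN varies with $m$, decreasing to
  the limit `diceCenLimit(k)` $= \frac{k-1}{2k}\log_{2(k-1)}(k+1)$, which
  increases with $k$ towards $1/2$ (for $k \ge 3$; the binary base makes
  $k = 2$ sit above the $k = 3$ value). Randomised-label sanity checks
  thus have a single MCC reference value but no unique CEN value.

## Comparing measures: discriminancy and consistency

For two measures evaluated on the same collection,
`degreeOfDiscriminancy(f, g)` is $|\{$pairs $g$ ties, $f$ separates$\}| /
|\{$pairs $f$ ties, $g$ separates$\}|$, and `degreeOfConsistency` is the
fraction of concordantly ordered pairs among all pairs ordered by both
(lower-better measures are negated first, so an error measure can be
compared with a quality measure).

Tie detection is a real design point. Measure values of small integer
matrices tie through exact algebraic coincidence; the default tolerance
$10^{-9}$ bins values coarsely enough that floating-point noise cannot
split a true tie, and finely enough that distinct algebraic values of
such enumerations never merge (the worked example below is stable from
$10^{-8}$ through $10^{-10}$). For *continuous*-valued studies over many
thousands of random matrices the opposite danger dominates: at
$n = 2\times 10^5$, binning $10^9$ cells creates spurious birthday-collision
ties, so the relation study uses exact equality (`tieTol = 0`), under
which no ties occur and the discriminancy is undefined — as it should be.

The worked discriminancy example, `discriminancyStudy(c(7, 3, 1))`,
exhaustively enumerates all `r countFixedRowSums(c(7, 3, 1))` three-class
matrices with per-class counts (7, 3, 1) — a small, strongly unbalanced
sample typical of the regime where the question matters — and counts tie
pairs by grouping, never materialising the $O(n^2)$ pair set. CEN
separates about six times more pairs than MCC does (the computed degree
is 6.096). Balanced counts behave very differently: symmetry manufactures
huge numbers of MCC ties, e.g. degree $\approx 180$ at (3, 3, 3), which
is why the worked example uses an unbalanced case.

## Enumeration

`enumerateFixedRowSums()` streams every matrix with prescribed per-class
(row) sums — fixing row sums and not column sums, since true-class counts
are what an experiment fixes — in a documented deterministic order:
row 1's composition advances fastest, each row running through the
colexicographic order of `compositions()`. The closed-form count
$\prod_i \binom{s_i + k - 1}{k - 1}$ (`countFixedRowSums()`) is asserted
against the stream in tests. The cumulative binary enumeration
(`enumerateBinaryCumulative()`, closed form $\binom{T+4}{4} - 1$) covers
all 2×2 matrices with totals up to $T$; the default study bound
$T = 100$ gives 4 598 125 matrices. Matrices with zero rows or columns
are included — they are valid confusion matrices — and the measures
handle them by the conventions above.

## The relation studies

`runMulticlassRelationStudy()` generates random confusion matrices and
summarises how tMCC tracks CEN. One matrix is drawn as: dimension $k$
uniform on 3–30; each diagonal entry uniform on 1–1000; a per-matrix
misclassification parameter $a$ uniform on $(0, 0.1)$ (small-to-moderate
misclassification: MCC stays roughly within 0.2–1); each off-diagonal
entry of row $i$ a uniform integer in $[1, \lceil a\,d_i\rceil]$ with
$d_i$ the row's diagonal. The bound rule is isolated in one internal
function precisely because it is the one place where the generation
scheme could be varied. The generator takes a single mandatory seed and
produces an identical stream for identical configurations, with the
shorter stream a prefix of the longer.

Because CEN's logarithm base depends on $k$ while the study mixes
dimensions, the comparison uses the dimension-scaled entropy
$\frac{k}{k-1}\mathrm{CEN}$ (`scaledCen()`); the factor is the same
$\frac{k-1}{k}$ prefactor that appears in the transform, moved to the
CEN side so that matrices of different dimension are commensurable. At
the default study size of 200 000 matrices the package computes a
Pearson correlation of about 0.994 between tMCC and scaled CEN, a mean
elementwise ratio tMCC/(scaled CEN) of 1.0000 with a 95% Student
bootstrap half-width of about $3\times10^{-4}$ (1000 replicates,
seed-deterministic), and a pairwise consistency degree of about 0.975 on
a 2000-item subsample (computing all $2\times10^{10}$ pairs exactly is
pointless; the subsampled estimate is stable across seeds). The ratio is
tightly centred but its per-matrix spread is real ($\mathrm{sd} \approx
0.07$): the transform is exchangeable with CEN *in aggregate*, not
matrix-by-matrix.

`runBinaryStudy()` computes MCC and CEN for the full cumulative binary
enumeration in vectorised per-total chunks with online accumulation of
the correlation sums, so the 4.6-million-matrix study runs in seconds
and constant memory (the per-matrix table is only materialised on
request, for small bounds). The cumulative Pearson correlation is about
$-0.63$ — far from the multiclass study's 0.994, and negative because
CEN is an error measure. The contrast is the point: the tMCC–CEN
relation is a genuinely multiclass phenomenon, and CEN's behaviour for
two classes (poor correlation, values above 1) argues against its use
there.

## What the generator does and does not emulate

The synthetic scheme produces diagonally dominant matrices with
row-dependent, moderately sized off-diagonal noise: plausible confusion
matrices of reasonably performing classifiers over a wide range of class
counts and imbalances. It does not emulate structured confusion
(block-confusable class groups), systematically asymmetric errors, or
very poor classifiers (MCC near or below 0) — the transform's accuracy
in those regimes is checked only by the analytic families, and the
domain policy makes the boundary explicit. Passing studies here
demonstrate the measure relation under the stated ensemble, not
classifier behaviour on any particular real dataset.

## Numerical choices, in one place

* $0\log 0 = 0$ by term skipping, never epsilon.
* MCC denominator 0 $\Rightarrow$ MCC $= 0$ exactly.
* Zero-mass classes are excluded from CEN denominators and contribute 0.
* Tie tolerance: $10^{-9}$ binning for enumerations of small integer
  matrices; exact equality for continuous-valued studies.
* tMCC outside $[-1/(k-1), 1]$: classed error by default, optional
  clamping; NA inside `metricsReport`.
* Floating-point test tolerances: $10^{-10}$ for closed-form versus
  generic agreement, $10^{-12}$ for binary/multiclass agreement,
  asymptotic limits checked at parameter $10^6$ with tolerance $10^{-3}$.
* Problem sizes: the shipped tests run the relation study at 200 000
  (with a 20 000 confirmation run) and the binary study at the full
  bound 100; both complete in about two minutes together.
* Bootstrap: 1000 replicates, Student-t interval on the mean ratio,
  seed mandatory.

## Worked example

```{r example}
m <- makeUniformOffdiag(3, 5, 1)
metricsReport(m)
abs(tmcc(mcc(m), 3) - cen(m))  # identity, exact on this family

d <- discriminancyStudy(c(7, 3, 1))
unlist(d)
```
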