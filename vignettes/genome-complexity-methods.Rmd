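---
title: "Measuring genome complexity with GS and Biobit: models, choices, limits"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Measuring genome complexity with GS and Biobit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(gsbb)
```

This vignette is the package's own account of the models it implements, the
parameters that matter, the numerical choices behind the code, and what its
synthetic data can and cannot show. The README holds a quick worked example;
here we go through the reasoning.

## 1. The Genomic Signature

For a word length $k$, every window of $k$ consecutive bases (step 1,
forward strand, no window across a contig junction, windows containing an
ambiguity code skipped) contributes to a sparse frequency table with counts
$n_i$ and total $W = \sum_j n_j$. Against the uniform expectation
$EV = W/4^k$ the per-$k$ signature is

$$GS_k = \frac{1}{W}\sum_{i=1}^{4^k} \lvert n_i - EV\rvert ,$$

where absent words contribute $EV$ each; that mass is evaluated in closed
form as $(4^k - d)\,EV$ for $d$ distinct observed words, never by dense
enumeration. The absolute value is essential: the signed deviations sum to
zero identically ($\sum_i n_i = W = 4^k\,EV$), so a signed version of the
statistic would be constant at zero. The package asserts this identity in
its tests and exposes no signed alternative.

$GS_k$ alone is dominated by base composition: an AT-rich genome has
AT-rich words far above $EV$ regardless of any biological structure. The
metric therefore subtracts the same quantity computed on a seeded,
composition-preserving *shuffle* of the genome ($GS_r$), giving
$GS_p = GS_g - GS_r$, and reports $GS = \max_k GS_p$ over $k = 2..16$
(ties, which essentially never occur, resolve to the smallest $k$). The
shuffle preserves length and base multiset exactly, which is why we use a
permutation rather than i.i.d. resampling from the measured composition:
it removes the compositional contribution with no estimation error of its
own. A `replicates` option averages $GS_r$ over several independent
shuffles, which is worth doing for genomes below ~50 kb where the shuffle
noise is comparable to the signal.

Two consequences deserve emphasis because they drive the package's design:

* **A genome that is exchangeable with its shuffle has $GS \approx 0$.**
  An i.i.d. random sequence *is* statistically exchangeable with its own
  permutation, so its $GS_p$ is zero-mean noise at every $k$ and every
  composition. GS detects structure *beyond* composition — repeats,
  periodicity, word-usage bias — not composition itself.
* **The visibility of fixed structure peaks at 50% GC.** Take genomes that
  all carry the same repeated elements and vary only the background
  composition. At even composition the background word counts hug $EV$,
  so the repeat-induced excess stands out in full; at biased composition
  the background deviations grow and the same structural excess is
  partially absorbed (some repeat words sit below $EV$ and move toward
  it). Empirically this produces a concave profile of mean GS against GC
  content with its maximum at 0.5 — the quadratic relationship the
  package's acceptance checks reproduce.

This is why `gs_gc_profile()` — the function behind the GC-gradient
experiment — generates genomes with a fixed structural complement by
default: 8 copies of one 500 bp element per 100 kb genome, the same
insertion-sequence scale used throughout the package. Setting
`repeat_copies = 0` produces pure i.i.d. genomes, and the profile
degenerates into flat noise around zero, which is itself a useful negative
control (and a property test in the suite).

## 2. Biobit

Biobit compares a genome's $k$-mer entropy with the two extremes attainable
at its own length $G$ (unambiguous bases only). With $L = \log_4 G$, the
empirical Shannon entropy $E_{2L}$ in bits, measured at the single word
length $k_{BB} = \mathrm{round}(2L)$, ranges from $L$ (a maximally
repetitive genome) to $2L$ (a fully random genome, where essentially every
window is unique and the entropy saturates at $\log_2$ of the window
count). The decomposition

$$E(G) = E_{2L} - L, \qquad A(G) = 2L - E_{2L}, \qquad E + A = L$$

splits $L$ into an entropic and an anti-entropic part, and with $x = A/L$

$$BB = L\,\bigl(x(1 - 2x)\bigr)^{1/3}.$$

$BB$ vanishes at both extremes ($x = 0$: fully random; $x = 1/2$:
entropy at the repetitive floor) and peaks at $x = 1/4$, where its maximal
value is $L/2$. The measurement is made at the one word length where a
random genome's entropy saturates, because that is where repeats bite:
every extra copy of an element converts unique $k_{BB}$-mers into repeated
ones, depressing $E_{2L}$ below $2L$ and raising $A$ — which is also why
$BB$ moves inversely to the hapax percentage.

Numerical choices:

* $E_{2L}$ is clamped into $[L, 2L]$ before decomposition; short or highly
  repetitive genomes can violate the theoretical bounds empirically. After
  clamping $E + A = L$ holds exactly and $BB \ge 0$; a degenerate genome
  (a homopolymer, say) clamps to $x = 1$ and returns $BB = 0$ rather than
  erroring.
* The inner product $x(1-2x)$ is clamped at 0 from below before the cube
  root.
* The combination formula's exponent placement is typographically
  ambiguous in the literature the metric descends from; the package
  defaults to the plain reading above and retains
  $L\,(x(1-2x)^2)^{1/3}$ behind `variant = "squared"`. The two agree at
  both zeros and differ only in the interior scale, so every qualitative
  statement in this vignette holds for either.
* Word lengths are capped at $k = 26$ so 2-bit packed word codes survive
  the C++/R round trip through doubles exactly; $k_{BB}$ for bacterial
  genomes (even 100 Mb) stays far below the cap.

## 3. Hapax statistics and genome parameters

A hapax is a word with absolute frequency 1 in the frequency table. The
percentage is reported relative to the number of *distinct* words (table
rows), not windows — the two coincide in the all-hapax random limit, and
the table-row reading matches the frequency-table framing of the
definition. The word length defaults to each genome's $k_{BB}$ so the
BB–hapax coupling is measured at a single consistent scale; `hapax_k`
overrides.

The six annotation parameters are feature arithmetic on a GFF3 file: gene
and rRNA counts by feature type, CDS counts after merging rows that share
an `ID` (multi-line CDS features count once; ID-less rows count
individually), mean gene length as `end − start + 1` averaged over `gene`
features (strand ignored; lengths are strand-symmetric), total genome
length including ambiguity codes, and GC content over unambiguous bases
only (ambiguity codes carry no composition information, so they are
excluded from numerator and denominator alike; the *reported* genome
length still counts them, while the metrics use the effective length).

## 4. Phylogenetically informed statistics

All cross-species analyses work on the Brownian variance–covariance matrix
$C$ of a user-supplied rooted tree with branch lengths:
$C_{ij}$ is the shared root-to-tip path length of tips $i, j$, and Pagel's
$\lambda$ rescales the off-diagonal entries. $\lambda$ is estimated by
maximizing the profile log-likelihood of a Brownian model (GLS root state
and ML rate profiled out) by bounded scalar search on $[0,1]$ with
tolerance $10^{-6}$, endpoints checked explicitly. One $\lambda$ is fitted
per trait pair for correlations and once for the whole matrix for the PCA
— the two usages are deliberately distinct. On a star tree the likelihood
is flat in $\lambda$; the fit flags this rather than pretending the
boundary value is informative.

* **Correlations** are GLS evolutionary correlations under $C(\hat\lambda)$,
  tested with $t = r\sqrt{n-2}/\sqrt{1-r^2}$ against Student's $t$ with
  $n-2$ df, Holm–Bonferroni corrected across the trait pairs. The plain
  Pearson correlation is emitted alongside, since ordinary and
  phylogenetic correlations answer slightly different questions and
  readers may want both.
* **Phylogenetic ANOVA** keeps the ordinary one-way $F$ as the observed
  statistic but replaces its null distribution with $F$ values from
  Brownian traits simulated on the tree at the GLS-estimated rate, group
  labels held fixed. The p-value uses the add-one estimator
  $(1 + \#\{F_{sim} \ge F_{obs}\})/(1 + n_{sim})$ so it can never be
  exactly zero. Default $n_{sim} = 1000$.
* **Blomberg's K** is the MSE ratio normalized by its Brownian
  expectation; $K = 1$ under Brownian evolution, and the permutation test
  (default 1000 seeded tip shuffles) reports the fraction of permutations
  whose phylogenetic MSE is at most the observed one.
* **Phylogenetic PCA** eigendecomposes the evolutionary *correlation*
  matrix (the traits' scales differ by orders of magnitude), with scores
  centred on the GLS ancestral means and standardized by the evolutionary
  variances. Signs are fixed so each component's largest-magnitude loading
  is positive. Exactly collinear traits make the likelihood and the
  decomposition singular; the error names the offending pairs.

With $C = I$ (a star tree with unit branches) every one of these reduces
to its ordinary counterpart — Pearson correlation, classical ANOVA $F$,
standard correlation PCA — and the test suite asserts those reductions to
$10^{-10}$.

Degenerate geometry is handled explicitly: zero-length terminal branches
are bumped by $10^{-8}\times$ tree height before inversion; trees with
tips missing from the trait table are pruned with a warning, while traits
lacking tips are an error (permissive tree, strict data).

## 5. What the synthetic data emulates — and what it does not

`make_fixture_dataset()` stands in for a two-lifestyle panel of real
bacterial genomes. Its defaults are the package's statement of the study
conditions at desk scale: 10 free-living + 10 endosymbiont genomes of
~100 kb (real panels are an order of magnitude larger in both counts and
genome size; everything scales), free-living GC 0.5, endosymbionts eroded
toward GC 0.25 with ~30% of the ancestral sequence deleted (matching the
AT-rich, shrunken genomes of obligate endosymbionts), and a two-clade
ultrametric Yule tree so the habitat signal is phylogenetically structured
— which is precisely what makes the phylogenetic ANOVA differ from the
ordinary one. All endosymbionts derive from one shared ancestor, so their
resemblance is inherited, not independent.

Every genome carries a baseline complement of repeated elements (8 copies
of a 500 bp element, jittered genome sizes, pseudogene-like gaps in the
GFF stubs): real genomes are never structureless, and a fixture of pure
i.i.d. sequences would — by the exchangeability argument of Section 1 —
make GS identically zero-mean in *both* habitats and the lifestyle
contrast meaningless. One endosymbiont optionally receives a fresh repeat
expansion (default 20 extra copies), reproducing the "transitional"
high-BB outlier phenotype: repeat proliferation during early
endosymbiosis lowers the hapax percentage and raises BB, making a genome
that is biologically degenerate look complex to the entropy balance. The
package's tests check this as a ranking (the transitional genome tops the
endosymbiont BB list) and as a monotone dose response (hapax % strictly
falls and BB strictly rises over 0, 2, 4, 8 copies).

What the generator does **not** emulate: codon structure, operons, real
IS-element sequences, indel models beyond block deletion, horizontal
transfer, assembly gaps, or annotation noise. Passing tests on these
fixtures therefore demonstrate the *mechanisms* — composition erosion
lowers GS, repeat gain raises BB — not the empirical effect sizes of any
real dataset; on real genomes the structural signal is richer and the GS
values correspondingly larger.

## 6. Determinism and problem sizes

Every stochastic step takes an explicit seed, evaluated under a
save/restore of the global RNG state, and the pipeline derives per-genome
and per-test substreams from one root seed, so identical configurations
give byte-identical outputs. The test suite and the acceptance script run
their simulations at sizes chosen to make the statistical assertions
stable — 100-tip trees with 200–500 replicates for the
$\lambda$-recovery, ANOVA-size and Blomberg-K checks; 45 genomes of
100 kb for the GC gradient — and the tolerances asserted there (e.g. mean
$K = 1 \pm 0.1$, type-I error within [0.025, 0.075] at $\alpha = 0.05$)
are the Monte-Carlo precision of those sizes, not claims about asymptotic
behavior.

## 7. Known limitations

* GS and BB are single-strand metrics; no reverse-complement folding is
  applied anywhere, so strand-asymmetric genomes are measured as given.
  This keeps the genome and its shuffle baseline strictly comparable.
* The hapax word length and denominator are conventions (see Section 3);
  other choices shift the absolute percentages, though not the direction
  of any comparison made here.
* $\lambda$ is bounded to $[0,1]$; trees whose traits are *more*
  correlated than Brownian expectation pin the estimate at 1.
* The phylogenetic ANOVA conditions on the observed group labels; with
  two groups no post-hoc machinery is needed or provided.
* For genomes below a few tens of kilobases the single-shuffle GS
  baseline is noisy; raise `replicates`.
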