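---
title: "Models and methods behind aptevo"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind aptevo}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(aptevo)
```

`aptevo` bundles the comparative-genomic analyses used to characterize
nocturnal adaptation in flightless birds: selection screens on coding
genes, dating of gene inactivation, copy-number and diversity profiling
of sensory gene families, k-mer genome profiling, category enrichment,
and a conservation screen of non-coding elements. This vignette explains
each model, its assumptions, the tunable parameters, and the design
choices made where reasonable alternatives existed.

## The codon substitution model

Selection is measured on the 61 sense codons of the universal code under
a Goldman–Yang style model. For codons $i \ne j$ differing at exactly
one nucleotide,

$$q_{ij} = \pi_j \cdot \kappa^{[\text{transition}]} \cdot
\omega^{[\text{nonsynonymous}]},$$

zero for multi-step changes, with the diagonal closing the rows and the
matrix rescaled so branch lengths are expected substitutions per codon.
$\omega = dN/dS$ below 1 indicates purifying selection, 1 neutrality,
above 1 positive selection. Codons are ordered lexicographically over
T, C, A, G — the CODEML convention — so fitted matrices can be compared
against that program directly.

Equilibrium frequencies default to **F3×4** (position-specific
nucleotide frequencies of the alignment, with a half-count pseudocount
so no sense codon gets probability zero); `uniform` and `empirical`
codon frequencies are available through `codon_frequencies()`. Columns
containing a gap or unresolved codon in *any* taxon are excluded from
the likelihood (complete-column analysis). This matches the intent of
the pre-filters (below), keeps the pruning kernel simple, and makes the
brute-force test oracle exact; the cost is discarding partial
information in ragged alignments.

The likelihood is computed by Felsenstein pruning with per-pattern
rescaling; transition matrices come from a symmetric eigendecomposition,
valid because the model is time-reversible. The kernel is written in
C++ (RcppArmadillo); the exported R primitives `build_rate_matrix()` and
`transition_probabilities()` implement the same quantities independently
and serve as the oracle in the test suite (explicit state enumeration on
small star trees, rerooting invariance, stationarity).

### Branch models and the LRT

`fit_model()` fits either one $\omega$ for all branches or a
foreground/background pair (`two-ratio`), with $\kappa$, $\omega$(s) and
all branch lengths maximized jointly by bounded L-BFGS-B on log-scale
parameters; branch lengths are re-optimized under each model.
Convergence tolerance is ~1e-6 relative on lnL; bounds are
$\kappa \in [10^{-2}, 99]$, $\omega \in [10^{-4}, 40]$, branch lengths
$\in [10^{-7}, 30]$.

The default is a single data-informed start (branch lengths from the
mean codon p-distance, $\kappa = 2$, $\omega = 0.3$) rather than a
multi-start sweep: the profiled surface of this model family is
unimodal in practice, and the screen warm-starts every two-ratio fit
from the one-ratio MLE, which both accelerates convergence and
guarantees the nesting inequality $\ln L_1 \ge \ln L_0$ numerically.
`n_starts = 3` restores deterministic extra starts at $\omega = 0.05$
and $1.0$ for surfaces one does not trust.

`branch_lrt()` forms $2(\ln L_1 - \ln L_0)$, clamped at zero, against
$\chi^2_1$: one extra parameter, critical value 3.84 at the 5 % level.
The test suite calibrates the empirical size on 200 null simulations
(8 taxa, 300 codons) and requires it to sit inside the 95 % binomial
band around 5 %; this problem size keeps a full calibration run in the
minutes range while giving the binomial check reasonable resolution.

Pairwise `pairwise_kaks()` is the same ML fit on a two-taxon tree; Ka
and Ks then decompose the fitted branch length using substitution-flux
proportions, with site opportunities evaluated at $\omega = 1$, so that
Ka/Ks reproduces the fitted $\omega$ exactly. Identical sequences
return Ka = Ks = 0 with the ratio flagged undefined rather than NaN.

### Alignment pre-filters

Two filters precede any fit. `filter_set1()` passes only alignments in
which every gap run is a multiple of 3 and no internal frame-1 stop
exists — the frameshift-free set. Failing alignments fall back to
`longest_clean_block()`: the longest run of columns with no gap and no
unresolved base in any sequence, trimmed to codon boundaries, kept only
if at least 200 aligned bases, ties broken leftmost. Absence of such a
block is a legitimate result, not an error.

## Dating loss of function

When a gene's foreground $\omega$ is elevated but branch-site evidence
of positive selection is absent, the parsimonious reading is loss of
constraint: the branch splits into a constrained era at
$\omega_c$ and a neutral era at $\omega = 1$. With branch duration $T$
(My) and time since loss $t$,

$$\omega_{obs}\,T = \omega_c (T - t) + 1 \cdot t
\quad\Longrightarrow\quad
t = T\,\frac{\omega_{obs} - \omega_c}{1 - \omega_c},$$

clamped to $[0, T]$. The identity assumes the measured branch-average
$\omega$ is the *time*-weighted average of era $\omega$s, which holds
when the synonymous rate is clock-like across the branch.
$\omega_{obs} > 1$ is rejected outright — the mixture cannot exceed
neutrality, and a ratio above 1 signals positive selection, for which
this model is wrong. $\omega_{obs} < \omega_c$ returns 0 with a
warning. $T$ is an explicit user input (for the kiwi lineage a natural
bound is the < 50 My since arrival in New Zealand); the estimate is
linear in $T$, so any revised duration rescales the date directly.
$\omega_c$ may be either a fitted background $\omega$ or an externally
averaged lineage value; both are accepted because published analyses
have used both readings.

The generator closes the loop: `simulate_codon_alignment(shift = ...)`
splits the focal branch into the two eras. The shift fraction is a
fraction of clock time, so the neutral segment's length in its own
scaled units is inflated by the total-rate ratio
$R(1)/R(\omega_c)$ — both eras share the synonymous clock. Without this
correction a "40 % of the branch" shift would mean 40 % of
*substitutions*, which under strong constraint is a much shorter time.
The end-to-end test plants a shift at 40 % of a 50 My branch, refits,
dates, and requires recovery within ±15 %; at 2,000 codons the
remaining discrepancy is dominated by the fact that a single-ω model is
only an approximation to the two-era process, not by optimizer noise.

## Repertoire copy number and diversity

### GC-corrected copy number

Collapsed duplications inflate read depth. `gc_binned_baseline()`
stratifies genome-wide depth into GC bins (width 0.01 — fine enough to
track avian GC heterogeneity, coarse enough that bins stay populated);
`correction_factor()` divides a region's depth by its bin's mean. An
empty bin is an error naming the bin; nearest-occupied-bin fallback
exists but only by explicit request, because silently borrowing a
baseline across GC classes is exactly the bias the correction removes.
A region at 105-fold depth over a 35-fold bin yields factor 3.

`estimate_copy_number()` totals `max(round(c_f), 1)` per annotated gene
(round half up): copy numbers are integers and a low factor still
represents the one annotated copy. Because rounding debates are
legitimate, the unrounded sum is also reported as the upper-bound
reading. The recovery test plants copy numbers on simulated Poisson
coverage (82 annotated genes, truth 141 copies in the canonical
configuration) and requires the total within 10 %.

### Intact / pseudogene classification

`classify_gene()` calls a copy a pseudogene for any of: length not a
multiple of 3 (frameshift proxy), internal stop before the final codon,
or translated length below 0.8 of the family reference (truncation).
The 0.8 threshold is configurable; published criteria say "truncations"
without a cutoff, and 80 % keeps honestly shortened-but-complete genes
intact while catching fragment annotations. `intact_fraction()` reports
both full precision and the integer percent (86 of 141 → 61 %).

### Entropy profiling

`column_entropy()` is Shannon entropy in bits over residues at one
column — 0 for a conserved position, $\log_2 20 = 4.322$ at the uniform
maximum, which forces base 2. Gaps are excluded from the frequencies by
default (`treat-as-21st-symbol` available); an all-gap column is
skipped and counted. `species_entropy_summary()` reports mean, SD *and*
SE of per-column H, because a bare "±" in a summary is ambiguous and
the two readings differ by $\sqrt{n}$.

`wilcoxon_signed_rank()` compares paired diversity values exactly: zero
differences dropped (Wilcoxon's policy), mid-ranks for ties, and the
null distribution of $W^+$ built by generating-function convolution
over doubled ranks — exact even with ties — for $n \le 25$, normal
approximation with tie correction above. The suite checks it against
full $2^n$ enumeration and against `stats::wilcox.test` on tie-free
data. The pairing scheme (per-species means vs per-position values) is
the caller's choice; the function takes explicit differences.

## Genome profiling

`kmer_histogram()` counts canonical k-mers (lexicographic min of
forward and reverse complement), dropping any containing N.
`estimate_genome_size()` takes the first strict local minimum of the
spectrum as the error cutoff and locates the coverage peak as the modal
multiplicity above it (on a 3-point smoothed spectrum). Because an
integer mode carries ±1 discretization error — enough to move a
30×/100 kb recovery by ~5 % on its own — the reported $c_k$ is refined
to the count-weighted centroid of a ±2 window around the mode, which is
exact for symmetric peaks and reduces to the spike position for a
degenerate spectrum. Genome size is
$\sum_{m > cutoff} m \cdot n_m / c_k$. A
spectrum that rises from the start (error-free reads) gets cutoff 0; a
monotonically falling spectrum has no separable peak and errors with a
diagnostic. Since it is unresolved whether published figures divide by
k-mer or base coverage, passing `read_length` adds the
read-length-corrected size using $c = c_k R/(R-k+1)$. No
heterozygosity or repeat-peak modeling is attempted — a documented
limitation; the estimator is the single-peak one. The recovery test
uses a 100 kb genome at 30× (k = 19), sized so the full
simulate-count-estimate loop runs in seconds while leaving the peak
position sharp. `n50()` is the standard weighted-median summary.

## Enrichment screening

`hypergeometric_enrichment()` computes the upper-tail probability
$P(X \ge k)$ per category (the one-sided test appropriate for
over-representation; the under-representation screen is run by passing
the slower-gene list). Gene lists must lie inside the annotation
universe; outsiders are an error naming them. Ancestral ontology terms
are honored only if the input annotation is pre-propagated — the
package deliberately does not traverse the GO graph. Family-wise
correction is Bonferroni by default with Holm available. When nothing
survives FWER — the expected outcome at genome scale — the relaxed
three-criterion filter applies: raw $p < 0.05$, at least 3 significant
genes in the category, and significant genes at least 5 % of the
category (boundary semantics exact: $k = 2$ always fails, $k/K = 0.05$
passes, $p = 0.05$ fails). Per-gene significance feeding the screen is
deliberately uncorrected — the two-stage design places the multiplicity
burden at the category level. `species_specific_categories()` then
separates focal-only categories from those shared with named other
species.

## The conserved-element screen

`validate_catalog()` enforces the element definition (strictly longer
than 200 bp, pure ACGT). `variation_fraction()` aligns the ortholog
globally (match +1, mismatch −1, gap open −5, extend −1, via
`Biostrings::pairwiseAlignment`) and reports
(mismatches + gap columns) / reference length, flagging strictly above
5 %. Counting gap columns as differences is the conservative reading
of "mismatches" from an anchored-alignment pipeline and can be turned
off. The flat 5 % threshold can be overridden per element, covering
the reading where each element carries its own expected identity.
Ortholog retrieval is the caller's job; missing orthologs are counted,
never imputed.

## Synthetic data: what it does and does not show

Every generator is a pure function of its seed and emits a truth
record. The coverage generator uses Poisson depth noise — the minimal
model for pile-up counts; real libraries are overdispersed, so the
recovery tolerances here are optimistic for real data. The read
generator produces uniform error-free or substitution-only reads with
no quality strings or indels. The codon generator draws per-branch
transitions at the column level (no within-branch trajectory is needed
because the likelihood only sees endpoints). The element-divergence
generator plants an exact substitution count, `round(rate × length)`,
at distinct positions, so the planted divergence is the realized
divergence and screen recovery can be scored deterministically.

Passing tests therefore demonstrate internal consistency — estimator
meets generator under the stated model — not robustness to alignment
error, assembly artifacts, annotation noise, or overdispersed coverage,
none of which the generators emulate.

## Problem sizes and numerics

Defaults throughout are sized for complete runs on a single CPU in
minutes: LRT calibration 200 replicates × 300 codons × 8 taxa; dating
recovery 2,000 codons; genome recovery 100 kb at 30×; element screen
100 elements × 10 seeds. Likelihood tolerance is ~1e-6 relative;
LRT statistics are clamped at 0; transition-matrix entries are clamped
at 0 and rows renormalized; all-gap likelihood input is an error, not a
silent zero.

## Known limitations

* No branch-site or site-heterogeneity models: a gene under positive
  selection at a few sites is invisible to the branch screen.
* Complete-column exclusion discards information in ragged alignments.
* The dating mixture assumes an abrupt constraint loss and a clock-like
  synonymous rate; gradual relaxation biases the date late.
* The genome-size estimator ignores heterozygosity and repeat peaks.
* The enrichment module treats annotations as flat sets.
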