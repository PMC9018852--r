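---
title: "Methods: variable chromatin modules, activity QTLs and allele-specific chromatin"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: variable chromatin modules, activity QTLs and allele-specific chromatin}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

This vignette records the statistical model behind each `vcmod` step, the
design of the synthetic generators used to validate them, the numerical
conventions the package commits to, and known limitations. Code chunks
are illustrative and not evaluated at build time; the same computations
run, with assertions, in the package's test suite.

## 1. The object of study

A *variable chromatin module* (VCM) is a set of nearby cis-regulatory
elements — ChIP-seq or ATAC-seq peaks — whose activity covaries across
individuals in a population panel. Covariation arises because the
elements respond to a shared regulator: a genetic variant, a looping
contact, a common TF. The package's pipeline mirrors how such modules
are dissected experimentally:

1. normalise per-sample peak quantifications,
2. group correlated peaks into modules,
3. summarise each module's activity per sample and map it to genotype,
4. for a candidate variant, test allele-specific chromatin, scan for
   created/destroyed TF motifs, and compare 3D conformation between
   alleles.

## 2. Normalisation chain

Raw fragment counts per peak and sample are carried through a fixed
chain, with each matrix tagged by a *layer*
(`raw → size-normalized → residual → int-transformed`). Functions check
the tag of their input and refuse layers they were not designed for, so
a matrix cannot be, say, INT-transformed twice or correlated before
normalisation.

* **Library size.** Median-of-ratios size factors (the DESeq estimator):
  for sample $j$, $s_j = \operatorname{median}_i \, k_{ij} / g_i$ with
  $g_i$ the row geometric mean over samples where $k_{ij}>0$ for all.
  Counts from paired-end assays are doubled first so fragment counts are
  comparable with single-end read counts. The test suite checks the
  hand-rolled estimator against `DESeq2::estimateSizeFactorsForMatrix`.
* **Covariates.** Known covariates (sex, batch, ancestry PCs) are removed
  by OLS residualisation per peak, computed via the QR decomposition
  (`qr.resid`); a rank-deficient design is an error that names the
  offending column rather than a silent drop.
* **Rank inverse normal transform.** Per peak (or per sample, selectable),
  $x_{(r)} \mapsto \Phi^{-1}\!\big((r - 3/8)/(n + 1/4)\big)$ — the Blom
  offsets. This makes every peak marginally standard normal, so the
  downstream Pearson correlations and OLS tests are not driven by count
  heavy tails. Constant rows are an error: their ranks are undefined.

## 3. Module calling

For peaks on the same chromosome whose midpoints are within a 2 Mb
window, the package computes all pairwise Pearson correlations with the
exact $t$ test p-value ($t = r\sqrt{(n-2)/(1-r^2)}$ on $n-2$ df).
Modules are connected components (via `igraph`) of the graph whose
edges are:

* **FDR caller**: pairs with Benjamini–Hochberg $q \le 10^{-3}$
  (adjusted per chromosome over all tested pairs) and $r > 0$; or
* **r-threshold caller**: pairs with $r \ge 0.5$.

A third, **hierarchical** caller cuts an average-linkage tree on the
distance $1 - r$ and keeps the maximal nodes whose mean within-node
$|r|$ exceeds a cut; it exists as a structurally different route to the
same biology and is held to a slightly looser recovery standard in the
tests. Modules from different datasets covering overlapping spans can be
merged by consensus span overlap. Recovery against planted truth is
scored with the adjusted Rand index (`mclust::adjustedRandIndex`), with
unassigned peaks kept as singletons so that both lumping and splitting
are penalised.

Because components are the inferential core, the tests re-derive them
with an independent breadth-first search oracle on the same edge lists
and require exact agreement across hundreds of random instances.

## 4. Module activity and QTLs

The **aVCM score** of a module is the first principal component of the
samples × member-peaks submatrix (columns scaled), computed by SVD. PC1
sign is arbitrary, so the score is oriented to correlate positively with
the mean member signal (falling back to the highest-|loading| peak if
that mean is degenerate), then re-standardised. Higher score means more
active chromatin, which makes QTL effect signs interpretable.

QTL tests are closed-form OLS of score on allelic dosage:
$\hat\beta$, its standard error, the $t$ p-value on $n-2$ df, then BH
adjustment across the *declared universe* of tests — adjusting only the
tests you ran invites selection bias, so the universe is an explicit
argument. Variants with constant dosage or fewer than `min_n` complete
observations are reported with an `untestable` status rather than
dropped, keeping the universe accountable. A three-way screen
intersects vcmQTLs with eQTLs and TF-binding QTLs at a common FDR to
nominate variants that move a module, a gene, and a binding event
together.

## 5. Allele-specific chromatin

Reads over phased heterozygous sites are aggregated per assay and
half-open region `[start, end)`. Allelic imbalance at total depth $n$
with $x$ alternate reads is tested against the input-derived expected
fraction $p_0$ (correcting reference-mapping bias) with an exact
binomial test. Two two-sided conventions are provided and tested
against a brute-force enumeration oracle:

* `minlike` (default, matches `binom.test`): sum of all outcome
  probabilities no larger than the observed one;
* `double`: twice the smaller tail, capped at 1.

Regions with fewer than 6 reads total are reported as
`filtered_low_reads` — below that depth even a fully skewed region
cannot reach $p < 0.05$ (the worked case: 10 reads, 0 alternate, gives
$p = 2/1024 \approx 0.002$; 5 reads cannot). BH adjustment is applied
within region across assays. Log2 fold changes over input use a
half-read pseudocount only when a zero count requires it. If no input
is available the expected fraction falls back to 0.5 and the row is
flagged. TF-binding density tracks (how many assays show a bound site
per window) are computed with `IRanges` overlap machinery.

## 6. Motif gain/loss

PWMs are $4 \times L$ log-odds matrices (from counts with a
pseudocount, from a consensus with peak probability 0.8 ≈ 1.3
bits/position, or parsed from JASPAR-style text). Scanning scores every
length-$L$ window on both strands — the reverse strand by scoring with
the reverse-complemented matrix, which the tests verify against a naive
string-reversal scanner — and skips windows containing non-ACGT bases.

Raw top scores are not comparable across PWMs of different length and
information content, so each TF's top score is standardised against its
own background distribution: the max score over each of $N$ background
regions gives a mean and (n−1) SD, and
$z = (\text{top} - \text{mean})/\text{SD}$. For a variant, the ranking
statistic is $\Delta z = z_\text{ALT} - z_\text{REF}$ computed on
variant-centred windows sharing flanks; TFs not expressed in the cell
type (mean expression < 0.5) can be filtered before ranking, and ties
break lexicographically for stability. The package default is 5000
background regions of 757 bp; smaller backgrounds are fine for
development and are what the acceptance script uses (250–300 per seed)
— the $z$ estimate's SE scales as $1/\sqrt{N}$ and rank-1 recovery is
insensitive to this choice.

## 7. Chromatin conformation

**Tracing ensembles** (ORCA-style) are long tibbles of pairwise 3D
distances per cell and segment pair. Summaries are the median-distance
matrix (pairs observed in fewer than `min_obs` cells are masked `NA`)
and the contact fraction with a strict `< 150 nm` cutoff and an
NA-aware denominator. Allele-specific compaction is tested by a sign
test on per-pair median differences (ALT − REF): under the null the
number of negative differences is Binomial(m, ½); all-zero differences
give $p = 1$ by convention. The recovered compaction factor is the
median of per-pair medians' ratio and should match the generative
factor.

**Capture-C** profiles are per-fragment counts around a viewpoint.
Normalisation excludes ±1 kb around the viewpoint midpoint, scales
counts to sum to one within the TAD, and re-bins to 5 kb half-open bins
anchored at the TAD start — so bin mass is conserved to machine
precision, which the tests check at $10^{-12}$. Per-bin log2 fold
changes between alleles use $\varepsilon$ = the smallest positive
normalised value to guard zeros. A planted 2× contact boost should
return $\log_2\text{FC} \approx 1$.

## 8. Synthetic generators

All generators are driven by one integer seed through deterministic,
key-hashed substreams, so adding one component (e.g. more noise peaks)
does not perturb another's draws, and the CLI is byte-reproducible.

* **Peak cohort.** Modules are equicorrelated Gaussian blocks: member
  $k$ of a module with target correlation $\rho$ is
  $y_k = a f + e_k$ with shared factor $f$, $a = \sqrt{\rho/(1-\rho)}$,
  giving pairwise correlation exactly $\rho$ in expectation. A planted
  variant with Hardy–Weinberg genotype dosages (default MAF 0.27) adds
  $\beta \cdot \text{dosage}$ (default $\beta = 0.5$) to the module
  factor. Noise peaks are independent. Defaults (300 samples, 60 peaks)
  match a realistic LCL panel scale while keeping tests fast.
* **Indel sequences.** A REF sequence whose deletion of 5 bp fuses two
  flanks into a complete 10-bp consensus site on ALT, plus decoy PWMs
  and background regions. REF candidates are rejected if any window on
  either strand matches the planted consensus at $\ge L-1$ positions —
  otherwise a chance near-site on REF would break the planted truth
  condition the generator promises.
* **Tracing.** Expected distance grows as $120 \cdot d^{1/3}$ nm with
  genomic separation $d$ (polymer-like scaling), ALT distances scaled by
  a compaction factor 0.9, Gaussian noise 25 nm, 20% missing
  observations.
* **Capture-C.** Exponential contact decay with distance from the
  viewpoint (rate $5\times10^{-5}$/bp), multinomial read sampling at
  fixed depth, optional planted boost bin, three replicates.

Problem sizes in the tests and acceptance script (cohort sizes, numbers
of seeds, background regions) are the package's own choices, set to
give tight Monte-Carlo error within a CPU-minute budget.

## 9. Numerical conventions

* Blom offsets (3/8, 1/4) in the INT; frozen expected values for tiny
  $n$ are asserted in the tests.
* BH is implemented once (`fdr_adjust`) and verified against both a
  literal step-up oracle and `p.adjust(..., "BH")`.
* Exact binomial p-values are compared to enumeration with a relative
  tolerance of $10^{-7}$ to absorb `dbinom` rounding at the equality
  boundary.
* Contact calling uses strict `<`; region intervals are half-open;
  seeds are kept below $2^{31}$ so they survive `as.integer`.

## 10. Limitations

* The equicorrelated-block cohort has no linkage disequilibrium,
  trans effects, or mixed peak widths; recovery rates on it are upper
  bounds on real-data performance.
* OLS QTLs assume an additive dosage effect and exchangeable samples —
  no kinship or population-structure correction is included.
* The PC1 activity score is a unit-variance reconstruction of the
  latent module factor, so $\hat\beta$ on the score is mildly
  attenuated relative to the planted effect on the factor; the
  validation battery checks recovery of the planted effect in
  expectation over many simulations, with a tolerance that absorbs
  both attenuation and per-simulation sampling noise.
* The sign test for compaction ignores dependence between segment
  pairs; its p-values are calibrated for detection, not for effect
  inference.
* Motif log-odds scanning assumes independent positions (no dinucleotide
  structure) and a uniform background.
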