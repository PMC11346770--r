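---
title: "Allele-specific copy-number calling from cell-by-bin matrices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Allele-specific copy-number calling from cell-by-bin matrices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Low-coverage single-cell whole-genome sequencing of tumors yields, per cell,
a vector of read counts over fixed genomic bins and, where phased SNPs are
available, a B-allele frequency (BAF) per bin. From these, `scacn` estimates
for every cell $i$ and bin $j$ an unordered pair of allele-specific copy
numbers $\{c'_{ij}, c''_{ij}\}$ and a cell ploidy $p_i$ (the genome-wide
mean total copy number). The package starts where the matrices exist;
alignment, binning, SNP calling and phasing are upstream concerns.

Two derived features carry the signal:

* the **read-depth ratio (RDR)** $\hat X_{ij} = X_{ij} / \bar X_i$, the
  normalized count divided by the cell mean, proportional to
  $(c'+c'')/p_i$; and
* the **mirrored BAF (mBAF)** $\hat Y_{ij} = \min(Y_{ij}, 1-Y_{ij}) \in
  [0, 0.5]$, which removes the arbitrary labeling of the two haplotypes and
  equals $\min(c',c'')/(c'+c'')$ in expectation.

A copy-number state therefore sits at a predictable location in the
(RDR, mBAF) plane: state $\{c',c''\}$ at ploidy $p$ is expected at
$((c'+c'')/p,\; \min(c',c'')/(c'+c''))$, with the total-0 state assigned
mBAF 0.5 (it carries no allelic signal, and this keeps nullisomic bins from
attracting extreme-mBAF data).

## Pipeline

### Normalization

Bins with extreme GC (<0.2 or >0.8) or poor mappability (<0.9) are masked
and excluded — never imputed — from every downstream mean, fit and
likelihood. Normal (diploid) cells are identified by a low Gini coefficient
of their bin counts; per-bin factors $\lambda_j$ are the average count
ratio of the normal cells, and tumor counts are divided by them. Without
normal cells, $\lambda_j$ falls back to a lowess fit of the cross-cell
median count ratio on GC, scaled by mappability.

Two robustness choices depart from the plain formulation and are the
pipeline defaults (`preprocess()` exposes both; the low-level functions
keep the plain behavior):

* **Normal-cell rule.** An absolute Gini cutoff cannot work across
  coverages: Poisson counting noise alone sets a coverage-dependent Gini
  floor for perfectly flat cells. The `"cluster"` rule keeps cells within
  0.02 of the sample's minimum Gini (still under the absolute cap, default
  0.12), anchoring the decision on the flattest cells present.
* **Median factors.** $\lambda_j$ uses the per-bin median rather than mean
  over the normal set. For a clean normal set the two coincide (every
  normal cell has the same expected ratio); when a near-flat aneuploid
  cell slips through, the median keeps its CNAs from imprinting on the
  factors of every other cell.

### Global segmentation: mixture model over (RDR, mBAF)

All unmasked bins of all cells are pooled and fit with a $K$-component
bivariate Gaussian mixture by EM, under the assumption that bins sharing a
latent copy-number state share a component. $K$ is chosen by BIC over a
range (default 8–25). Implementation choices that matter:

* Duplicate feature values are collapsed into weighted points — an exact
  reformulation of the likelihood that conditions EM well in the
  low-noise limit, where thousands of bins share a handful of locations.
* Each $K$ gets `n_restarts` (5) EM runs: two warm starts from the best
  $(K-1)$-fit with its widest component bisected along its principal axis
  (weight times covariance trace ranks the candidates), one k-means start,
  and random starts. The warm starts are what reliably split heavy pooled
  components that k-means misses.
* A BIC minimum sitting exactly at the top of the range triggers extension
  of the scan (a boundary optimum means the range was too small); five
  consecutive non-improving values end it. Data beyond 8000 weighted
  points are scanned on a seeded subsample with a full-data refit of the
  winner.
* Covariances are full 2×2 with a diagonal ridge of $10^{-6}$.

Over-clustering is corrected by **weighted component merging** under the
distance $\sqrt{(\Delta\text{RDR})^2 + w_b(\Delta\text{mBAF})^2}$ with
$w_b = 0.5$ (BAF is the noisier axis at low coverage) and threshold
$\delta = 0.1$. Merging is complete-linkage: a group merges only while all
members are mutually within $\delta$, which bounds the merged diameter.
Single-link chaining was rejected because cross-clone state ladders
interleave at spacings below $\delta$; a chain then fuses genuinely
different states, and a merged component can carry only one state per cell
downstream. Merged weight is the sum, the mean the weight-proportional
average, the covariance the moment-matched mixture covariance.

Because the mixture treats bins as exchangeable, a bin lying between two
overlapping components flips assignment independently of its neighbors. A
single-bin flip whose two same-chromosome neighbors agree is corrected
back — but only when the bin's own component explains it weakly (within 6
nats of the neighbor component), so decisively assigned focal events and
all noiseless data are untouched.

Per-cell candidate breakpoints are the positions where consecutive
same-chromosome unmasked assignments change. The package-wide breakpoint
convention is the **0-based index of the left bin** of the changed pair; a
change across a masked gap is reported at the left unmasked bin.

### Local segmentation: CBS

Each cell's RDR is segmented per chromosome by circular binary
segmentation, implemented from scratch: the arc maximizing the pooled
two-sample t statistic against its complement is found by exhaustive
enumeration (validated against an independent brute-force oracle in the
tests), assessed by a permutation test (default 1000 shuffles), and
accepted splits recurse. Numerical choices:

* Significance counts strict exceedances ($t_{perm} > t_{obs}$). With
  noiseless two-level data the observed maximum is tied by every
  permutation that keeps the level circularly contiguous; counting ties
  would make obviously perfect splits "insignificant".
* Pooled variances are floored at $10^{-10}$ of the signal's mean square
  so perfect splits evaluate as infinite t reproducibly under floating
  point; signals are centered first, making results shift-invariant.
* Arcs and every fragment a split creates must span at least 2 bins.
* Each recursion node derives its permutation seed from the node
  boundaries, so a node's decision does not depend on how many draws other
  nodes consumed (and lowering $\alpha$ prunes monotonically).
* Segmentation runs on RDR only; allelic imbalance enters through the
  mixture model.

### Ensemble

A cell's final breakpoints are the candidates shared by at least $t$ cells
(default 5; $t=1$ disables filtering) plus any candidate confirmed by that
cell's CBS, regardless of frequency. Frequencies count exact index matches.
Final breakpoints plus chromosome ends tile the genome into segments with
RDR/mBAF means over their unmasked bins.

### Ploidy and allele-specific states

Segments are assigned to the nearest component (Euclidean distance in the
feature plane; ties to the larger weight, then the lower index). Candidate
ploidies come from the cell's *balanced* components (mean mBAF within 0.05
of 0.5 and mean RDR above 0.1 — a zero-copy component shows BAF 0.5 only
for lack of reads): among them, the one holding most of the cell's bins
anchors the scale, and with $\hat x$ the mean RDR of that cell's own bins
in it, the candidates are $2^{w+1}/\hat x$ for $w = 0..\texttt{max\_wgd}$.
Using the cell's own bins matters because subclones of different ploidy
share merged components; the pooled mean would bias every clone.

For each candidate $p$, every component holding cell segments picks the
state in $\Omega$ (all pairs with total $\le$ 10 by default) maximizing
the summed bin log-density around the state's expected location, giving
the likelihood $L(p)$; the weighted BIC
$\phi(p)\,\ln(m)\,|\Omega| - 2L(p)$ scores the candidate. Three
noise-driven corrections to the naive likelihood proved essential:

* **Folding.** Mirroring maps BAF noise around 0.5 downward: a balanced
  state's observed mBAF concentrates at $0.5 - \sigma\sqrt{2/\pi}$, not
  0.5. Expected mBAFs are folded-normal means; without this, odd-total
  states just below 0.5 (e.g. {4,5}) systematically out-fit the true
  balanced state and ploidy selection drifts toward spurious doublings.
  The correction vanishes as the variance goes to zero.
* **A global noise floor.** State discrimination uses one diagonal noise
  scale — per axis, the weight-weighted lower quartile of component
  standard deviations. Merged or budget-limited components have inflated,
  correlated covariances; at face value they flatten the RDR axis and let
  distant states "explain" data through the off-diagonal term.
* **$\phi$ on CBS segment means.** $\phi(p) = \sum_z n_z (p\bar x_z -
  \text{round}(p \bar x_z))^2$ over the cell's CBS segments with at least
  5 bins. Per-bin residuals are uniform once per-bin noise reaches half a
  copy; ensemble segments fragment under assignment flicker; and
  per-component cell means carry selection bias (bins end up in a
  component *because* noise moved them). CBS segments are per-cell,
  noise-calibrated by their permutation test, and spatially defined, so
  their means stay pure.

Scale selection itself is guarded: the state space at ploidy $2p$ contains
every state of ploidy $p$ doubled, so $L$ never decreases under doubling.
Candidates are scanned in increasing order and a larger one wins only if
(i) its state map is not a plain integer multiple of the current one (a
multiple is the same profile at another scale; parsimony keeps the
smaller) and (ii) its likelihood gain exceeds $\ln(m)\,|\Omega|/2$, a
BIC-type charge for unlocking the refined grid. Genuine duplications clear
the hurdle easily — odd-total segments fit the halved scale miserably —
while noise and segmentation artifacts fall short. Exact ties go to the
smaller ploidy.

Finally, a **consensus pass** extends the cross-cell ensemble idea to
ploidy: a cell whose selected scale is about double or half the median
scale of its profile-correlated peers (RDR correlation ≥ 0.8, ≥ 3 peers)
is re-called at the peer scale. Cells of one clone carry near-identical
profiles, so a within-clone minority at twice the majority scale is almost
always a scale artifact.

Per-bin states inherit their segment's component's state, except that
segments with at least 5 unmasked bins re-pick their own best state (they
carry enough evidence, and this corrects components that pool neighboring
states across clones). The reported `ploidy` is the genome-wide mean of
the called totals — the ploidy the called profile implies, which matches
the definition used for the simulated truth and is far more stable than
the raw scaling candidate (kept as `scale_ploidy`). With externally
measured ploidies (e.g. FACS), `known_ploidy` bypasses candidate
enumeration entirely.

## The synthetic-data generator

`simulate_truth()` grows a random clone tree from a diploid genome:
the founder branch first applies the ploidy mode (tetraploid doubles both
alleles; triploid adds one; hypodiploid deletes one allele over two large
regions) and then CNA events accumulate along branches — a uniform segment
of 5–25 bins, one allele, ±1–2 copies (single-copy with probability 0.7),
floored at zero. Defaults: 4 events per clone branch plus 8 truncal events
on the founder, matching the observation that most copy-number burden in
real tumors is truncal; the resulting genome-wide aneuploidy is also what
separates tumor from normal count profiles. The first event on every
branch is forced single-copy: a genome with only even totals is
mathematically indistinguishable from its halved version, so this keeps
the whole-genome-duplication scale identifiable. A configurable fraction
of cells are normal ({1,1} everywhere). True ploidy is the mean total copy
number; true breakpoints are the adjacent-bin state changes.

`simulate_matrices()` draws counts as Poisson with mean
`coverage_scale × total/2`, optionally jittered by a multiplicative
Gaussian of sd `rdr_noise_sd`; `coverage_scale` defaults to 1000 reads per
diploid bin, roughly 0.1X short-read coverage at 1 Mb bins (or 0.02X at
5 Mb), so counting noise is minor and `rdr_noise_sd` is the effective RDR
noise level. BAF is the allelic fraction of a uniformly chosen haplotype
(mirroring-equivalent, as in real data) plus truncated Gaussian noise
reflected into [0, 1]; total-0 bins emit 0.5. `count_model = "exact"`
emits the deterministic expectations — the idealized zero-noise regime
under which exact end-to-end recovery is a meaningful test.

What the generator does *not* emulate: GC/mappability bias on counts (the
factors it would calibrate are tested separately), read-level sampling,
segmentation-scale mismatch between CNA boundaries and bin boundaries,
doublets, replication or cell-cycle artifacts. Passing tests therefore
validate the statistical machinery, not robustness to every artifact of
real libraries.

## Problem sizes and runtime

The test suite and the acceptance script run populations of 100 cells over
2 chromosomes × 100 bins with 4 clones and 25% normal cells — large enough
that clonal structure, frequency filtering and consensus are exercised,
small enough that the full suite completes in minutes on one CPU. Noise
levels 0.1 (RDR) / 0.05 (BAF) represent a challenging low-coverage
setting; at these levels the adjacent-state separation is about 2σ for
near-tetraploid cells.

## Known limitations

* Components closer than the merge threshold to a *different* state of the
  same cell cannot be distinguished (e.g. {2,6} vs {3,5}: same total,
  mBAF 0.125 apart); the affected bins take the majority state.
* The mixture's K selection under noise legitimately pools cross-clone
  ladders; per-segment refinement recovers long segments but short
  segments keep the pooled component's state.
* An all-even-total tetraploid cell is unidentifiable from a diploid one;
  parsimony calls it diploid.
* The consensus pass assumes clones are represented by several cells;
  singleton cells with a genuine private WGD would be pulled to their
  neighbors' scale.
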