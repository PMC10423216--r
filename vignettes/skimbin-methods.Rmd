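---
title: "Methods: skim-sequencing genotyping and bin mapping of biparental RIL populations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: skim-sequencing genotyping and bin mapping}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

A large biparental recombinant inbred line (RIL) population can be genotyped
for a few dollars per line by *skim-sequencing*: whole-genome sequencing at
0.03-0.2x coverage. At that depth each line is typed at only ~2-20% of the
segregating sites, almost always by a single read, so the raw data are a very
sparse, noisy matrix of parental-allele observations. `skimbin` turns that
matrix into (i) crossover breakpoints per line, (ii) a 1-Mb consensus bin
map, (iii) an imputed full-density genotype matrix, (iv) genetic-map
statistics and (v) simplified trait scans — together with a simulator that
generates the whole data world with known truth, so every stage is testable
without external data.

## The simulator: a stated world

The generator emulates a selfed cross between a wild and a domesticated
diploid inbred:

* **Parental key.** Biallelic sites placed by a Poisson process at a
  configurable density (scaled preset: 7 x 100 Mb at 1 site / 20 kb; a
  full-scale preset approximates a 5.1 Gb genome with 16.6 M sites). Every
  site is homozygous-different between the parents. The "wild-like" parent
  carries the reference allele at 87.5% of sites, reproducing the
  reference-allele asymmetry of calling a wild parent against a wild
  assembly.
* **Meiosis.** Crossovers per gamete are Poisson(L) with L the chromosome
  map length in Morgans (no interference; an obligate-crossover flag
  exists but defaults off so the Poisson count stays exact). Positions
  avoid a central *recombination desert* covering 50% of the chromosome
  around the centromere and follow a symmetric Beta(0.5, 0.5) within each
  arm — the U-shaped, telomere-biased placement typical of Triticeae.
* **Selfing.** The F1 is selfed explicitly for `generations - 1` rounds
  (default 6, i.e. F6), with two independent meioses per round, so residual
  heterozygosity arises naturally and decays as (1/2)^(g-1) (~3% at F6).
  The selfed-RIL map expansion follows: observable crossovers per
  chromosome converge to 2L.
* **Reads.** Reads per site per line are Poisson(coverage); a site is typed
  if at least one read lands (missingness = exp(-coverage), ~97% at 0.03x).
  Each read reports the true parental allele with probability 1 - error
  (default 0.002); heterozygous blocks emit either allele per read with
  probability 1/2. All-one-parent reads code the site P1 or P2, mixed reads
  code H.
* **Phenotypes.** `y = mu + sum(a_k x_k) + sum(aa_ij x_i x_j) + year +
  N(0, sigma^2)` with x in {-1, 0, +1}; qualitative traits threshold the
  latent value into ordinal scores 1/2/3. `effect_for_pve()` converts a
  target proportion of variance explained into an additive effect via
  `a^2 / (a^2 + sigma^2)` for a balanced 1:1 locus.

What the generator does *not* emulate: alignment artifacts and reference
bias (the 85-92% alignment asymmetry of real wild/domesticated data),
per-batch coverage mixtures, structural variation, and segregation
distortion. A green test therefore establishes algorithmic correctness under
the stated statistical regime, not robustness to alignment pathology.

One deliberate scaled-world choice: the scaled preset thins the parental key
~60-fold relative to the real data. The quantity that drives window-based
detection and binning is the *typed-site spacing per line* (~19 kb in real
skim-seq RIL datasets). Tests of those stages therefore raise the coverage
(1-3x on the thinned key) so the typed spacing matches real data, instead of
simulating an unrealistically sparse regime the method was never designed
for. Imputation tests keep the true 0.03x regime, which is where imputation
matters.

## Parental key and progeny coding

Parental variants are retained only if both parents are called homozygous
and non-missing, total depth lies in [6, 100], the called allele has depth
>= 3, and the parents differ. The allele-depth rule is read as applying to
each parent's *supporting* allele: requiring both alleles at >= 3 reads in
one sample would contradict the removal of heterozygous calls. Indels and
multi-allelic records are dropped and counted. Every retained site is fully
informative: one error-free progeny read identifies parental origin.

Progeny genotypes are matched to the key (hom-ref/hom-alt to the owning
parent, het to H); calls matching neither allele are counted and dropped.
Lines whose H fraction among typed sites strictly exceeds 0.10 are removed —
published analyses of such populations report removing a handful of
highly heterozygous lines without stating the threshold; 0.10 is ~4x the F6 expectation and is configurable.

## Bin consensus

1-Mb half-open windows (0-based starts, final partial bin kept) are coded by
the proportion rule: with n = nP1 + nP2 informative sites, a bin is P1 if
nP1/n >= 0.7, P2 if nP2/n >= 0.7, else H; bins with n < 5 are NA. The
literal ratio form "P1/P2 >= 0.7" is self-contradictory (both directions can
hold at once) and is interpreted as the proportion, consistent with the
threshold's published description. Two additions: a bin whose observed-H
codes outnumber its parental codes is called H outright (H-dominated bins
should not be forced to a parent), and the 5-site minimum — not part of the
original description — keeps the NA rate below ~10% at realistic typed
densities.

## Roaming-score breakpoint detection

The exact original score lives in unpublished supplementary code; the score
here is an explicit substitute with the stated property (more contrast, more
support, higher score):

    s(x) = |pL - pR| * sqrt(nL * nR / (nL + nR)) / sqrt(n_min)

evaluated on paired 6.5-Mb windows left/right of x, where p is the P1
proportion among parental codes and n the parental-code count. Windows
classify as P1 (p >= 0.9), P2 (p <= 0.1), H (p in [0.4, 0.6], or observed-H
codes dominating the parental codes), else NA; windows with fewer than 10
parental sites are NA. Classification is implemented with count
comparisons so it is exactly symmetric under P1/P2 relabeling. Candidates
are midpoints between consecutive typed sites of differing code — the score
is piecewise constant between typed sites, so nothing else needs evaluating.

**Pass 1** greedily accepts the best-scoring candidate with differing,
non-NA flank classes and score >= 0.5, suppressing candidates within one
window width. **Pass 2** makes the segmentation self-consistent:

1. every accepted breakpoint is re-classified with windows truncated at its
   accepted neighbours, trying halved widths (6.5, 3.25, ... 0.41 Mb) until
   both flanks classify; breakpoints whose flanks then agree are dropped;
2. a flank classified H is re-examined on the two nearest disjoint blocks of
   10 parental sites: if both read the same pure parent (and observed-H
   codes do not dominate the span) the H is overridden — a genuine 1:1
   block passes that test only with probability ~(2 n 2^-n)^2, while a
   window that merely straddles a further crossover resolves immediately;
3. segments whose boundary states disagree, whose composition contradicts
   the expected class, or which contain a run of >= 4 opposite parental
   codes (adaptively longer inside expected-H segments, where runs occur by
   chance) are re-scanned with the largest window the surroundings allow,
   shrinking on failure; a short hidden block flagged by a run gets *both*
   boundaries inserted at once, since either alone would be rejected on
   re-classification.

Final crossover boundaries are emitted at the minimum-misfit changepoint of
the local codes (a CUSUM over the two flank classes), so an isolated
miscalled site near the junction cannot drag the flanking markers off the
true crossover. Transitions involving an H state are emitted as state
changes but excluded from crossover counts: in a selfed RIL an H boundary
delimits residual heterozygosity, not a countable crossover. The reverse
map length is `100 * crossovers / lines` cM, the RIL-scale convention.

Known limitation: crossovers leaving fewer than ~4 typed sites of evidence
(within ~4 spacings of a telomere, or double-crossover blocks shorter than
~4 spacings) are undetectable in principle; with U-shaped placement this is
~3-5% of all crossovers at study-like spacing, which bounds the achievable
count recovery.

## HMM imputation

A 3-state (P1/P2/H) hidden Markov model runs over each line's typed sites.
The switch probability over distance d between parental states is
`t(d) = (1 - exp(-2 d / D)) / 2` with D = 1 Mb, the recombination-distance
scale conventionally used by low-coverage imputers for such data; entry into H is scaled by
the heterozygous prior (0.03, the F6 expectation). Emissions: the opposite
parental code appears with the assumed error rate (0.01 by default —
deliberately different from the simulator's 0.002, so mild model
misspecification is always exercised), an observed H code in a parental
state with error^2 (a two-read, one-error event), and H-state sites show
code H with probability 0.1 and either parental code with (1 - 0.1)/2.
Viterbi decoding (log domain, ties toward the previous state) is the
default, matching hard-assignment conflict resolution; forward-backward
posterior mode is available. Key sites between typed sites take the decoded
state of the nearest typed neighbour (ties left); sites outside the typed
span stay missing. Hold-out validation masks floor(3% x typed) codes per
chromosome per line, re-decodes, and averages per-line accuracy — the same
protocol and averaging convention used for real skim-seq validation; note the held-out *observed*
code is the scoring target, so read errors bound the ceiling below 100%.

## Genetic map

Bin markers are dropped for segregation distortion (chi-square 1-df against
1:1, p < 0.001, H/NA excluded) or missingness > 20%. Adjacent-bin
recombination fractions R (differing / informative lines, H excluded, capped
at 0.4999) are corrected to meiotic fractions by the Haldane-Waddington
inversion `r = R / (2 (1 - R))` and accumulated through the Kosambi function
`d = 25 ln((1 + 2r) / (1 - 2r))` cM. Both corrected and uncorrected totals
are reported, since linkage-mapping software conventions differ. Linkage
grouping and marker ordering are not reimplemented: bins are already
physically ordered on the assembly.

A property of this estimator worth knowing: a crossover near the middle of
a bin leaves that bin with a near-1:1 composition, so its consensus is H and
the line drops out of both adjacent comparisons — the crossover is never
counted. Bin-level map totals are therefore compressed roughly two-fold
relative to the meiotic expectation (point-genotype recombination fractions,
as tested, are unbiased). This is not an artifact of this implementation:
1-Mb bin maps of large RIL populations in the literature show the same
compression relative to reverse crossover-count estimates. Use the reverse
map length from the breakpoint module when the genome-wide recombination
rate itself is the quantity of interest.

## Trait scans

Dedicated interval-mapping software is replaced by documented
simplifications: per-bin least squares `y = mu + beta g` (g in {+1, -1}, H
excluded by default) with `LOD = (n/2) log10(RSS0/RSS1)` capped at 300,
`PVE = 1 - RSS1/RSS0`, genome-wide significance from seeded phenotype
permutations (threshold = the ceiling((1-alpha) x N)-th order statistic of
per-permutation max LOD), pairwise interaction F-tests on candidate bins
with the sign of the interaction coefficient reported, and a per-site
regression scan on a seeded 10% subsample of imputed sites with
Benjamini-Hochberg control. At RIL bin densities single-marker regression
and interval mapping are near-equivalent (adjacent-bin R ~ 0.01), and a
biparental RIL population has no structure a kinship model must absorb;
multi-QTL PVE from a cofactor model would still differ from single-marker
PVE when several QTL segregate — a documented, unreconciled difference.
Positional resolution inside the recombination desert is undefined by
construction (all bins there are in complete LD), so recovery tests place
loci on chromosome arms.

## Numerical and design choices

* Window classification uses count comparisons with a 1e-9 epsilon so exact
  boundary proportions (e.g. 7/10 at threshold 0.7) behave as documented
  and P1/P2 symmetry is exact.
* All randomness flows from one master seed through `derive_seed()` (an
  affine mix, exact in doubles, below 2^31), so stages are independently
  reproducible.
* Viterbi ties break toward the previous state; masking uses
  floor(fraction x typed) per line-chromosome and skips pairs with nothing
  maskable.
* The pipeline writes plain TSV/VCF/JSON between stages, each stage runnable
  alone; the run manifest records MD5 checksums and wall-clock per stage,
  and identical configurations reproduce identical checksums.
* Configuration JSON is validated with unknown-key rejection; invalid
  values fail at validation time through the same constructors the API
  uses.
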