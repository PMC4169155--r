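---
title: "Methods: models, parameters and design choices in sweepqtl"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in sweepqtl}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

# Scope

`sweepqtl` implements, as one tested pipeline, the analyses needed to
dissect a QTL with combined quantitative and population genetics:
deficiency-based complementation mapping of chill-coma recovery time
(CCRT), windowed diversity statistics over population sequence alignments,
a composite-likelihood sweep scan with a simulation-calibrated threshold,
a per-SNP differentiation scan with cline regression, and qPCR
relative-expression analysis. A synthetic-data module generates every
input the pipeline consumes. This vignette records the models, the
parameters that matter, the numerical choices, and the places where the
design was genuinely open.

# Alignment handling and site classification

Inputs are haploid consensus alignments (one FASTA record per strain) with
an optional per-base PHRED matrix. The pipeline order is fixed: *mask,
then classify, then filter*. Masking sets every base with quality strictly
below `min_phred = 21` to N and is idempotent. Classification is pooled
across all rows passed in: a site is excluded when its N fraction is
*strictly* above `max_missing_frac = 0.10` (the rule is worded as "higher
than", so the boundary value 10% survives), or when it falls in an excluded
coordinate interval (e.g. low-recombination telomere/centromere stretches);
otherwise the count of distinct non-N bases makes it monomorphic,
biallelic, or multiallelic. Three conventions apply package-wide:

* gap characters `-` count as missing (conservative; the input format is
  consensus sequence, where a gap is an absent call);
* multiallelic sites are excluded from every downstream statistic (this
  matches the SNP-scan exclusion rule and keeps the SFS machinery
  biallelic);
* an outgroup N at a site disables polarization there, and a site whose
  outgroup base matches neither sample allele is dropped from spectrum
  construction with a polarization-failure counter.

Coordinates are 1-based inclusive throughout; interval lengths are
`end - start + 1`.

# Windowed estimators with missing data

All windowed estimators use the per-site valid sample size `n_i`, the main
decision the underlying methods leave open under missing data. Per
segregating site with minor/derived count `x`:
`pi_i = 2x(n_i - x) / (n_i (n_i - 1))`; theta-pi is `sum(pi_i) / L_valid`
with `L_valid` the number of valid sites, so monomorphic sites contribute
0 to the numerator and 1 to the denominator. Watterson's estimator sums
`1 / a(n_i)` over segregating sites (`a(m)` the (m−1)-th harmonic number).
D<sub>xy</sub> averages the fraction of sample alleles differing from the
outgroup base over sites with a callable outgroup. Tajima's D needs one
sample size for its constants; the rounded-down *median* `n_i` over the
window's segregating sites is used (robust to a few low-coverage sites),
with the mean available by configuration. Sites with `n_i < 2` contribute
nothing and leave `L_valid`. Windows with under 50% valid sites are
reported but flagged low-confidence. Pairwise window F<sub>ST</sub> uses
the Hudson-style normalized form `(H_B - mean(H_W)) / H_B`, aggregated as
a ratio of window sums; the "normalized distance" wording admits several
formulations differing in sample-size corrections, and this form was
chosen because it reduces exactly to the within/between pairwise-difference
contrast that a brute-force pair enumeration checks. Negative estimates are
reported as computed with a clipped companion value.

The default window is 2 kb, matching the scale at which the candidate
region's diversity was summarized.

# The CLR sweep scan

## Extended spectrum

The background SFS carries classes `1..n-1`; the extended spectrum adds
classes 0 and n. In the real-data route these invariant classes are
populated *only* by sites monomorphic in the focal sample and polymorphic
in a reference sample (`extend_sfs_invariant_classes`), the conditioning
that gives the scan power where variation is depleted. The two classes are
kept split (ancestral-fixed vs derived-fixed) rather than pooled; pooling
would discard the polarization information the outgroup already paid for.
Mixed-coverage sites are projected to the spectrum's sample size by
hypergeometric downsampling; sites below the target size are dropped and
counted.

## Sweep transform

At escape probability `p_e` (`p_e = 1 - exp(-alpha d)` at distance `d`
from the sweep for intensity `alpha` per bp), the number of escaping
lineages is `B ~ Binomial(n, p_e)`; the `n - B` trapped lineages descend
from a single ancestor, so the pre-sweep sample has `B + 1` lineages
(`B` when `B = n`) whose derived count follows the background projected to
that size; a uniformly chosen representative transmits its state to all
trapped lineages. The implementation accumulates this law in closed form;
the test suite checks it against an explicit enumeration over all subsets
and representative choices (`combn`-based) to 1e-10 for `n <= 6`, and
checks normalization and continuity in `p_e`.

## Likelihood and maximization

`Lambda = clr_scale * (max_alpha l_sweep - l_neutral)`, floored at 0, with
`clr_scale = 2` by default so the statistic sits on the conventional
likelihood-ratio scale; the factor is a configuration constant because
published CLR implementations differ in it, and thresholds quoted on
either scale should be matchable. Alpha is maximized over a log-spaced
grid (default 64 points over 1e-8..1e-2 per bp; the scan studies use 16)
rather than by continuous optimization — reproducible, robust, and refined
by densifying the grid. The scan core precomputes the transformed spectrum
on an escape-probability grid (128–256 bins; the binned scan is checked
against an exact per-site reference implementation) and runs in compiled
code. Sites whose class has zero background probability are excluded from
both likelihoods with a warning.

## Threshold calibration

The significance threshold is the 95th quantile of max-CLR over batches of
neutral simulations, computed per region length with the asymptote taken
as the chromosomal threshold. The plateau is declared at the first length
whose quantile changes by less than 5% relative to the previous one; if no
plateau is reached the largest-length quantile is returned with an honest
`no_plateau` flag. Two empirical facts shaped the study settings:

* the max-CLR distribution under a bottleneck is heavy-tailed, so the
  quantile of a 50-replicate batch is noisy; the calibration studies use
  batches of 100 (the batch size of the original calibration procedure),
  while the function's desk default stays at 50;
* over desk-scale lengths (50–500 kb) the quantile curve keeps creeping in
  an extreme-value, roughly logarithmic fashion; growth over a tenfold
  length range stays far below proportionality (the acceptance checks
  assert rank-correlation > 0 and a q95 ratio below 3), but the strict 5%
  rule does not always trigger. Declaring the plateau at chromosome scale,
  as the original procedure does at 5 Mb, is reachable by configuration.

## Synthetic study conditions

The synthetic sweep and threshold studies need an extended background. It
is built by aggregating the polymorphic spectrum of neutral replicates
under the study demography and assigning the invariant classes a fixed
`invariant_mass = 0.4` of total site mass, split 7:1 ancestral:derived —
chosen once to emulate a bottlenecked focal sample conditioned on a
reference population with several-fold higher diversity, where
ancestral-state invariant sites vastly outnumber recent fixations. Neutral
scan datasets then include conditioned-invariant sites at the rate the
background implies, exactly as real extended-SFS inputs do. The sweep-scan
studies use `n = 19` haploid genomes, the size of a pooled European sample
of 11 + 8 lines.

# The coalescent simulator

`simulate_neutral_haplotypes` is a Hudson-style ancestral recombination
graph: lineages carry their ancestral-material segments (as 64-bit sample
masks, capping `n` at 64), recombination splits a lineage at rate
`rho/2` per bp of gross span, coalescence merges two lineages at rate
`1/size` per pair under the piecewise-constant size history (ms `-eN`
convention: sizes are relative to the reference size defining theta and
rho; time is in units of 2N<sub>ref</sub> generations). Segment stretches
that reach their MRCA are retired. Infinite-sites mutations fall on the
recorded lineage exposures at `theta/2` per bp per time unit; continuous
positions are snapped to unique integer coordinates with collisions
resolved by rejection sampling (redraw within the same ancestral stretch),
which preserves the expected mutation count — dropping colliding mutations
instead would bias diversity down by about `S^2/(2L)` sites, a measurable
2% at the default densities.

ARG cost grows superlinearly with `rho * L`, so lengths above
`max_block = 100 kb` are simulated as independently stitched blocks and
flagged approximate. At the default `rho = 0.01`/bp, loci one block apart
satisfy `4Nr d >> 1` and are effectively unlinked, so the stitching
discards negligible long-range correlation; the block size is
configurable upward when long-range linkage itself is under study.

Defaults `theta = rho = 0.01` per bp and `n = 20` are desk-scale choices
of the same order as X-linked diversity in large Drosophila population
samples. The bundled bottleneck demography (a recent tenfold reduction
lasting 0.2 time units) is deliberately a *toy*, labelled synthetic in its
name: the demographic parameters actually fitted for European populations
are not bundled, and a realistic model should be supplied through
`demography_model()` when one is available. The simulator is validated
against closed forms (E[pi] = theta, E[S] = theta L a(n)) and the
qualitative bottleneck diversity reduction.

# Deficiency mapping

CCRT minutes are natural-log transformed (the base cannot change F
statistics; natural log is recorded for definiteness) and fitted with
`lm(log(ccrt) ~ line * background)`; p-values come from Type-II sums of
squares (`car::Anova`), the standard choice for unbalanced two-way designs
without a factor hierarchy — with balanced cells Types I/II/III coincide,
which the tests exploit by checking against an explicit normal-equations
oracle. Per-fly data behind published panels are generally unavailable, so
printed p-values are inputs, not reproduction targets; the bundled panel
table carries the printed genotype-cell means, SDs and p-values.

The decision rule: `fail_high` needs both the line and interaction
p-values below 0.01 and the direction conditions (|Δdef| > |Δbal|,
Δdef < 0, i.e. the European chromosome over the deletion recovers faster);
`fail_marginal` needs both below 0.05; anything else complements. The
published analysis quotes its high-significance calls at a raw *P* < 0.01,
so the Bonferroni divisor defaults to 1 and is exposed as configuration
(with 24 tested deletions the divided cut would reclassify one of the two
highly significant deletions, contradicting the published calls — the raw
cut is therefore the faithful default). Interval refinement is closed
inclusive set-subtraction via IRanges; gene overlap needs at least 1 bp.

# Differentiation scan and clines

The multi-population scan keeps biallelic SNPs with at least 50% valid
calls in *every* population, then computes Nei-style
`F_ST = (H_T - H_S) / H_T` per SNP with sample-size-weighted pooled
frequencies. The model-based decomposition used in the original
outlier analysis (reversible-jump MCMC with locus effects and q-values) is
deliberately *not* reimplemented; the scan substitutes the direct
F<sub>ST</sub> statistic with empirical upper-quantile flagging (ties at
the cutoff all flagged), clearly labelled as a ranking rather than a
model-based false-discovery rate. Cline regression fits frequency on
|latitude| separately for the populations at or north and at or south of
the equator ("two antiparallel clines" = two hemisphere fits), with a
joint signed-latitude fit available by configuration; equatorial
populations enter both fits.

# qPCR expression analysis

Technical replicates are averaged on the Cq scale first (qBase practice;
averaging after conversion is available by configuration and documented to
change results). `RQ = E^(Cq_cal - Cq_sample)` per gene with efficiency
`E` in (1, 2]; `NRQ` divides by the geometric mean of the reference-gene
RQs per sample; `CNRQ` rescales each gene by the geometric mean of a
calibration group (e.g. the tropical-population controls). Technical
variance propagates on the log scale
(`var(log NRQ) = var(log RQ) + sum(var(log RQ_ref))/R^2`) and yields
confidence bounds `cnrq * exp(±t * sqrt(var))` with the 97.5% Student
quantile at `n_tech - 1` degrees of freedom — an explicit construction
choice for "rescaled confidence intervals". The fold-change screen tests
only contrasts whose |log fold| exceeds `screen_k = 2` technical log-SDs
(i.e. a fold threshold of `exp(2 sd_tech)`; both the factor and the scale
are configuration since only "defined by the variance between technical
replicates" is specified); Welch t-tests run on log CNRQ with
Benjamini–Hochberg correction across all performed tests and display
tiers at 0.05/0.01/0.001.

The Cq generator writes `Cq = intercept - log_E(Q) + N(0, tech_sd)` with
`Q = 2^(log2 fold)`; pool-to-pool variation beyond technical noise is off
by default (`pool_sd = 0`) so the generator matches this law exactly, and
can be switched on for realism.

# What the generators do and do not emulate

The coalescent module emulates neutral genealogical noise, recombination,
missing-data-free haplotypes and bottleneck-distorted spectra; it does not
emulate base-calling error, alignment gaps, reference bias, or selection
acting on linked sites (sweep data come from the spectrum transform, not a
trajectory model — matching the scan's own model, which is exactly what a
self-consistency power study needs, but not an independent forward
simulation). The phenotype generator draws log-normal scores with exact
2x2 effects; real CCRT distributions may be skewed differently and contain
censoring at the observation horizon. The Cq generator assumes a single
run (no inter-run calibration) and shared efficiency across samples of a
gene. Passing tests therefore demonstrate internal correctness and
calibration under these idealized conditions, not performance on raw
sequencing or plate data.

# Problem sizes used by the tests and acceptance studies

Chosen as desk-scale package defaults: estimator recovery uses 500 neutral
replicates of 50 kb at `n = 20`; the threshold study uses lengths
50–500 kb with batches of 100; neutral exceedance uses 100 fresh 50-kb
scans; localization uses 50 sweep replicates over 100 kb (`alpha = 2e-4`,
1500 sites); the null complementation study uses 1000 phenotype
replicates; spectrum-transform enumeration runs at `n <= 6`. The original
chromosome-scale settings (5-Mb simulations, 500,000 grid points) are
reachable by configuration but are not defaults.

# Known limitations

* The ARG simulator caps `n` at 64 haploid genomes and stitches blocks
  above 100 kb; chromosome-scale single-ARG simulation is out of reach.
* The CLR scan's invariant-class handling for synthetic studies fixes the
  conditioned-invariant mass at a chosen constant rather than deriving it
  from a joint two-population simulation.
* The threshold plateau rule may legitimately not trigger at desk-scale
  lengths; the reported threshold is then the largest-length quantile,
  flagged.
* The FST outlier flags are an empirical ranking, not posterior
  probabilities; q-value-style interpretation is not supported.
* FASTQ quality input is not parsed; qualities enter as a parallel PHRED
  text matrix or a programmatic matrix.
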