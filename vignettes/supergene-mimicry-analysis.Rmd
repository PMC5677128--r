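---
title: "Models and methods behind mimicrysim"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind mimicrysim}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mimicrysim)
```

`mimicrysim` is an analysis toolkit for the population genetics and
perceptual ecology of supergene mimicry in *Papilio* swallowtails, where a
single inverted *doublesex* haplotype controls female-limited mimetic
polymorphism. The package asks four questions on synthetic data with known
truth: when does the interplay of negative frequency-dependent selection
(NFDS), positive selection for mimicry, and genetic drift destroy a
balanced polymorphism; what pattern of coding-sequence variation does a
founder/hitchhiking origin of the mimetic haplotype leave behind; how are
morph-specific SNPs identified on phased haplotype panels; and how
conspicuous is a wing pattern to a bird or human observer under a
receptor-noise-limited (RNL) vision model. This vignette documents the
models, parameter choices, numerical conventions, and limitations.

## 1. The NFDS + drift model

A single biallelic locus with mimetic allele `m` (dominant: heterozygotes
are mimetic) and non-mimetic allele `n`. With genotype frequencies
$f_{mm}, f_{mn}, f_{nn}$, genotype fitnesses are

$$w_{mm} = a\,(1 - z f_{mm} - z f_{mn}), \qquad
  w_{mn} = b\,(1 - z f_{mm} - z f_{mn}), \qquad
  w_{nn} = 1 - z f_{nn}.$$

The dimensionless $z \in [0,1)$ is the strength of frequency dependence:
each phenotype loses fitness in proportion to its own phenotype frequency
(the mimetic phenotype frequency is $f_{mm} + f_{mn}$, because mimicry is
dominant). The multipliers $a$ (homozygous mimetic) and $b$ (heterozygote)
add a frequency-independent benefit to mimicry; $a = b = 1$ is pure NFDS.
Genotypes are reconstituted by random mating each generation
($f_{mm} = p^2$, $f_{mn} = 2pq$, $f_{nn} = q^2$), so the state is the
single allele frequency $p$.

The deterministic update is
$p' = (p^2 w_{mm} + pq\,w_{mn}) / \bar W$ with
$\bar W = p^2 w_{mm} + 2pq\,w_{mn} + q^2 w_{nn}$. A note on normalization:
the mean-fitness expression could also be written with post-selection
frequencies, but that form is circular when substituted into the update.
We normalize by the current-generation Hardy–Weinberg mean fitness, which
guarantees $p' + q' = 1$ exactly; since any common normalizer cancels from
the ratio $p'/q'$, equilibria and fixation behaviour are unaffected by
this choice. Drift is Wright–Fisher: the next generation binomially
resamples $2N_e$ allele copies with success probability $p'$.

Two analytic fixed points anchor the implementation. For $a = b = 1$ the
interior equilibrium is phenotype-frequency parity
($f_{mm} + f_{mn} = f_{nn}$), i.e. $p^* = 1 - \sqrt{1/2} \approx
0.292893$, independent of $z$; for $a = b$ with an interior equilibrium,
$q^{*2} = (1 - a + a z)/(z (a + 1))$. Both are verified to $10^{-6}$ by
iterating the map.

The dynamics near fixation explain the selection-by-drift interaction that
the fixation experiment (`analysis/01_nfds_fixation.R`) demonstrates:
because mimicry is dominant, selection against the rare `n` allele is
recessive — for $a = b = 2$, $z = 0.25$ the deterministic map still holds
$q \approx 0.0076$ after 400 generations. A small population
($N_e = 10^2$, about 1.5 remaining copies) then loses `n` by drift almost
surely, while a large one ($N_e = 10^5$, about 1500 copies) essentially
never does; and pure NFDS restores the interior equilibrium at every
$N_e$. Terminal states after the fixed horizon are reported as
fixed/lost/segregating rather than forcing absorption. Replicate `i` of a
run uses child seed `seed + i`, so replicate sets are reproducible and
independently extensible.

## 2. Forward-in-time codon simulator

The molecular-evolution scenarios are re-expressed forward in time rather
than through a coalescent machinery. A population is a multiset of haploid
coding haplotypes (integer-coded nucleotides). Each generation: offspring
pick parents uniformly with replacement (Wright–Fisher); with probability
$r \times (\text{sites} - 1)$ an offspring splices two parents at a
uniform breakpoint; mutations are then proposed per copy and site at rate
$\mu \times$ site rate, with the transition weighted $\kappa$ (default 2;
unspecified in the source material for this system) against each
transversion.

Selection uses substitution-model semantics rather than a forward fitness
cost: a proposed change that is synonymous in its current codon context is
always accepted, a non-synonymous change is accepted with probability
$\omega$, and changes creating a stop codon are always rejected. This
makes $\omega$ directly interpretable as dN/dS, handles the founder phase
naturally, and keeps the simulator at desk scale. Proposals are applied
sequentially so that each sees the up-to-date codon context. Among-site
rate variation is a discrete gamma ($K$ equal-probability categories,
category rates are the bin means of the mean-one gamma density, so they
average exactly 1; default $K = 3$, $\alpha = 0.8$) assigned per codon and
fixed for a run.

Two scenario presets mirror the study designs. The non-mimetic scenario is
a single constant-size population evolving from a known grand most recent
common ancestor (GMRCA) under strong purifying selection
($\omega = 0.05$). The mimetic scenario appends a second phase: one
haplotype drawn uniformly from the end of phase 1 founds a new population
that grows logistically from the single founder to $N_m$ (default over
10% of phase 2), then stays constant, while the non-mimetic population
continues in parallel; both are sampled (20 haplotypes each) at the end.
Every variant the founder carries is instantly fixed in the new
population — genetic hitchhiking at the origin of the inversion — so the
mimetic sample shows more fixed differences (synonymous *and*
non-synonymous) and less internal diversity than the matched non-mimetic
sample, without any excess of fixed non-synonymous variation relative to
polymorphism (the McDonald–Kreitman signature of adaptive evolution stays
absent).

**Desk-scale study conditions.** The default conditions are $N = 500$
haploid copies, $L = 300$ codons, $\mu = 1.5\times10^{-4}$ per nucleotide
per generation, phase 1 = 1000 generations, phase 2 = 50 generations with
growth over 5. The mutation rate is deliberately elevated, the standard desk-scale
rescaling for forward simulators, and was fixed by a design-stage pilot so that standing variation is at drift–mutation
equilibrium scale ($\theta = 2N\mu \approx 0.15$ per site) and a founder
haplotype typically carries several non-synonymous standing variants;
with substantially lower $\mu$ the hitchhiking contrast in the
non-synonymous class drowns in Poisson noise at this population size.
Recombination defaults to $r = 0$ (the inversion does not recombine); a
per-adjacent-site rate can be supplied and is interpreted per site pair
per generation.

## 3. McDonald–Kreitman statistics

`classify_sites()` compares an aligned sample against the known ancestor.
Per nucleotide site, each derived allele with sample frequency $f$ (among
non-missing calls) is **fixed** if $f \ge 1 - c$, **polymorphic** if
$c \le f < 1 - c$, and ignored below the minor-allele-frequency cutoff
$c = 0.05$; the same cutoff governs both classes. Each counted change is
classified synonymous/non-synonymous in its codon context with the other
two positions held at their ancestral state. Missing data are excluded
from a site's frequency denominator.

The exact tests are authored in the package with explicit conventions:
two-sided p-values by the probability method (sum of the probabilities of
all tables, at the observed margins, no more probable than the observed
table); degenerate margins give $p = 1$; the $r \times c$ test enumerates
all tables when fewer than $10^7$ exist and otherwise falls back to
Monte-Carlo over margin-preserving Patefield draws with a reported
standard error. Tests cross-check the 2×2 path against full
hypergeometric enumeration and `stats::fisher.test`.

Ka/Ks uses Nei–Gojobori counting: per-codon synonymous site fractions
averaged between the two sequences, observed differences resolved by
equal-weighted shortest mutational pathways (pathways through stop codons
dropped when any stop-free pathway exists; changes to stops count as
non-synonymous for site counting), and the Jukes–Cantor correction
$d = -\tfrac34 \ln(1 - \tfrac43 p)$, undefined for $p \ge 3/4$ and
reported as missing. The counting estimator is biased at low divergence,
which is why parameter recovery of $\omega = 0.05$ is checked against a
wide band (0.02–0.10) rather than a tight tolerance. Summaries across
haplotypes report mean ± standard error with undefined values excluded
and counted.

## 4. Morph-specific SNPs and association

Haplotype panels are phased alleles (VCF codes: 0 reference, 1+
alternative, missing) over strictly increasing 1-based positions on one
contig, with free group labels per haplotype — group composition is
arbitrary, so taxa can be pooled exactly as an analyst chooses. A site is
**morph-specific** for a target group when the group carries a common
allele with at most `max_exceptions_target` haplotypes missing or
discordant (the "one missing or alternative count" tolerance is read as
*per site*, the only reading under which per-site counting is well
defined), and no more than `max_exceptions_ref` reference haplotypes
(default 0) carry that allele; reference missing calls are ignored. When
several target alleles fit the budget the site qualifies if any passes,
and the best-supported one is reported.

Per-site association between two haplotype groups cross-tabulates alleles
against groups (2×k over non-missing calls), applies the exact test, and
adjusts with Benjamini–Hochberg step-up across all sites; monomorphic
sites report $p = 1$. Exact-test p-values are discrete and conservative
(super-uniform under the null), so the permutation check in the test
suite verifies one-sided calibration — the empirical CDF of
label-permuted p-values never exceeds the uniform CDF beyond sampling
slack — rather than a two-sided distributional test that any correct
discrete test would fail.

## 5. Receptor-noise-limited vision analysis

Scenes are radiance cubes (default 16 bands, 360–660 nm) with a logical
butterfly mask. Luminance is the per-pixel band sum; percent luminance
change is measured per butterfly pixel against the mean background
luminance. Pattern granularity mean-subtracts the region, zero-fills its
complement on the full image canvas, and bins 2-D Fourier power into 7
equal-width radial frequency bands from the full-image scale
($1/\max(H,W)$ cycles/pixel) to Nyquist (0.5). Anchoring the bands to the
full masked image keeps butterfly and background spectra on identical
edges and therefore directly comparable; "equipartition" is read as
equal-width in frequency (the band count is configurable). Constant
regions return a uniform spectrum with a degeneracy flag instead of an
error. KL divergence is computed butterfly‖background after additive
smoothing ($\varepsilon = 10^{-9}$, renormalized).

Chromatic discriminability uses the general $n$-class RNL quadratic form.
With quantum catches $Q_i = \sum_b \text{radiance}(b)\, S_i(b)\,
\Delta\lambda_b$ and log contrasts $\Delta f_i = \ln(Q_i/Q_i^{\text{ref}})$
against the mean background spectrum,

$$\mathrm{JND}^2 = \frac{\sum_{i<j} \big(\prod_{k \ne i,j} e_k\big)^2
  (\Delta f_i - \Delta f_j)^2}{\sum_i \big(\prod_{k \ne i} e_k\big)^2},$$

which reduces to the familiar dichromatic, trichromatic and
tetrachromatic formulas and is exactly invariant under global radiance
scaling (the model is chromatic-only; achromatic/luminance contrast is
analysed separately, matching a colour-opponent mechanism independent of
achromatic luminosity). Receptor noise is $e_i = \nu \sqrt{\eta_{\rm
ref}/\eta_i}$ with Weber fraction $\nu = 0.05$ of the most abundant
class. The shipped observers are **synthetic placeholders** — Gaussian
pigment templates (tetrachromat 370/445/508/565 nm, abundances 1:2:2:4;
trichromat 420/534/564 nm, abundances 1:2:4, a plain geometric halving of
the tetrachromat ladder) — because real sensitivity curves and cone
ratios are instrument- and species-specific inputs; any observer can be
supplied as wavelengths, peaks/sensitivities, abundances and Weber
fraction. Pixels with non-positive catches are excluded and counted.

## 6. Synthetic data and what passing tests mean

Generators are pure functions of spec + seed (byte-reproducible).
Haplotype panels parameterize between-haplogroup divergence directly as a
per-site probability instead of simulating a coalescent history: truth
records stay exact, at the cost of no linkage disequilibrium, no allele
frequency spectrum realism, and no shared genealogy across sites. Planted
morph-specific sites are constructed to satisfy the filter predicate
exactly (no missing data is injected at planted sites). Scenes use
isotropic 1/f amplitude texture as a minimal leaf-litter stand-in and
noiseless radiance; there is no camera noise, no illumination gradient,
and no real spectral database. Consequently, passing tests demonstrate
the *mechanisms* — founder hitchhiking produces the fixed-variation
pattern, the filter recovers exactly what its predicate defines, a
spectrally matched butterfly is chromatically invisible — not empirical
claims about real butterflies, cameras, or predators.

## 7. Problem sizes and numerical conventions

- Fixation experiments: 100 replicate runs per parameter set, 400
  generations; neutral-fixation checks run 2000 replicates to absorption
  at $N_e = 50$.
- Hitchhiking experiments: 20 replicates of the two-phase scenario at the
  desk-scale conditions of §2; the analysis driver uses 5 replicates for
  its per-replicate tables.
- Association and morph-SNP panels: 2000 sites with 110 (six-haplotype
  design) or 107 (two-haplotype design) planted morph-specific sites.
- Scenes: 64×64×16; granularity uses 7 bands.
- Exact tests switch from enumeration to Monte-Carlo above $10^7$ tables
  ($10^5$ draws). Tie-breaking in the probability method uses a relative
  tolerance of $10^{-7}$ on table probabilities, matching standard
  practice.
- The deterministic equilibrium iterates to $|\Delta p| < 10^{-12}$.

## 8. Known limitations

The NFDS model tracks allele frequencies only (no explicit diploid
individuals, spatial structure, or gene surfing, and no inference of
$(z,a,b)$ from data). The codon simulator has no indels, no amino-acid
fitness landscape, and no ancestral-recombination-graph machinery; its
$\omega$-as-acceptance semantics equals a substitution model, not a
selection coefficient. The MK module does not infer ancestors (the GMRCA
is an input) and does not fit maximum-likelihood codon models. The vision
module does not model motion, viewing geometry, or calibrated real
imagery.
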