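---
title: "Methods and design notes for msatpop"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods and design notes for msatpop}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(msatpop)
```

# Scope and data model

`msatpop` analyses codominant diploid genotypes at multiallelic
microsatellite loci sampled from many populations, possibly spanning
several closely related species. The universal container is the
`genotype_dataset`: an individuals × loci grid of unordered allele-size
pairs with per-individual population and species labels. A genotype is
either fully typed or fully missing — half-missing calls are rejected at
parse time, because every estimator here defines its sample size by whole
typed genotypes ("typed n"), and a missing genotype contributes nothing
to allele counts. GENEPOP files (2- or 3-digit allele codes,
auto-detected; `00`/`000` missing; populations named from the trailing
token of each block's last individual unless supplied explicitly) and a
long-format CSV are supported and round-trip exactly.

# Diversity statistics

Per population and locus the package reports the observed allele count
*A*, the effective allele count $A_E = 1/\sum_i p_i^2$, observed
heterozygosity $H_O$, and expected heterozygosity in two variants: the
plug-in gene diversity $1 - \sum p_i^2$ and Nei's unbiased estimator
$\frac{2n}{2n-1}(1 - \sum p_i^2)$. Table-style reports use the unbiased
variant in the $H_E$ column and standard errors across loci, which is the
convention of the classic reporting tools; both variants are returned so
either can be tabulated.

Allelic richness is standardised by hypergeometric rarefaction to a fixed
number of diploids $g$ (default 10, i.e. $2g = 20$ gene copies):
$$A_R = \sum_i \left[1 - \binom{N - n_i}{2g}\Big/\binom{N}{2g}\right],$$
the expected number of distinct alleles in a random draw of $2g$ copies
from the $N$ sampled ones. A population's $A_R$ is reported as `NA`
whenever any typed locus carries fewer than $2g$ copies, so samples below
the standard size are never silently extrapolated. The implementation is
validated against exhaustive enumeration of all subsamples on small loci.

Two multilocus inbreeding estimators are exposed because the field's
standard tools disagree on which one backs a published $F_{IS}$ column:
the Weir–Cockerham variance-components $f$ (default; ratio of summed
among-/within-individual components over alleles and loci) and the Nei
ratio $1 - \bar H_O / \bar H_E$. The outcrossing rate is the equilibrium
transform $t = (1 - F_{IS})/(1 + F_{IS})$; it legitimately exceeds 1 when
$F_{IS} < 0$ and is undefined at $F_{IS} \le -1$. The identity
$t(1 + F_{IS}) = 1 - F_{IS}$ is asserted to machine precision on every
emitted record.

At the species level, $H_S$ is the mean over populations of the unbiased
within-population gene diversity and $H_T$ is the gene diversity of the
unweighted mean allele frequencies. For the decomposition
$F_{ST} = (H_T - H_S)/H_T$ the *plug-in* $H_S$ is used: mixing the
unbiased $H_S$ with a plug-in $H_T$ can push $H_S$ above $H_T$ on
degenerate inputs (identical populations), whereas the plug-in pair obeys
$H_S \le H_T$ by Jensen's inequality. The multilocus Weir–Cockerham
$\theta$ is always reported alongside, and is the estimator used for all
pairwise differentiation.

# Exact Hardy–Weinberg tests

Tests condition on the observed allele counts (Levene distribution). When
the space of genotype tables has at most $10^5$ members (the
`enum_cap`), the p-value is computed by complete enumeration; this covers
most 2–3-allele cases at realistic sample sizes. Otherwise a Markov chain
over genotype configurations is run. The chain swaps one randomly chosen
allele copy between two randomly chosen individuals; on the space of
ordered arrangements of the $2n$ gene copies this is a random-transposition
walk, which is doubly stochastic and therefore uniform at stationarity, and
its projection onto genotype tables is exactly the Levene distribution
(every proposal is accepted — the $2^{\Delta h}$ target ratio is cancelled
by the proposal asymmetry). Default chain parameters are 10,000
dememorization steps and 1,000 batches of 10,000 iterations; the p-value
is the mean batch indicator frequency and its Monte-Carlo standard error
is the standard error of the batch means. The per-locus two-sided test
orders tables by conditional probability (ties within $10^{-9}$ on the
log scale count as equal); the one-sided deficiency test orders tables by
total heterozygote count, with fewer heterozygotes more extreme — a
transparent one-sided ordering that reduces to the textbook 2-allele test.
The global per-population deficiency test advances independent per-locus
chains in lock step and uses the summed heterozygote count as the
multilocus statistic. Sequential Bonferroni correction is Holm's
step-down procedure via `stats::p.adjust`, applied within species in the
pipeline.

# Null alleles

The EM estimator fits the one-null-allele model: a null/visible genotype
is scored as a visible homozygote and null/null is a blank. Blanks are
attributed entirely to null homozygosity by default; a `failure_mix`
parameter discounts a fraction of them as technical failures for assays
where that is known. The E-step splits apparent homozygotes between true
homozygotes and visible/null heterozygotes, the M-step re-estimates all
frequencies including the null's; the likelihood trace is returned and is
non-decreasing by construction. Near the boundary $r = 0$ EM converges
sublinearly, so the default parameter-change tolerance is $10^{-6}$ and
estimates at exact Hardy–Weinberg proportions come out at the $10^{-4}$
scale rather than exactly zero; tests compare against a grid-search
maximiser of the same likelihood at $10^{-3}$ resolution.

The ENA-corrected $\theta$ rebuilds the per-population, per-locus
frequency vectors from the EM fit with the null carried as an extra
allelic state, augments the heterozygote proportions with the expected
hidden visible/null heterozygotes, and excludes the null state's variance
components from the numerator and denominator sums. Loci whose null
estimates are numerically zero take the uncorrected code path, making the
correction exactly the identity there. Simulation shows the correction
matters in the strongly differentiated regime (multilocus
$\theta \gtrsim 0.3$) and is mostly noise at weak differentiation, which
is consistent with how the correction is used in practice.

Two diagnostics address the chronic confounding of inbreeding with null
alleles. The regression diagnostic pools per-(population, locus) points
of the single-locus Nei-style $F_{IS}$ (the per-locus variance-components
$f$ is too unstable at these sample sizes) against the EM null frequency;
a significantly positive slope indicates null-driven heterozygote
deficits. The heterogeneity screen classifies one population at a time:
inbreeding shifts $F_{IS}$ at *every* locus, so the lower quartile of the
per-locus values sits above the near-zero band (default ±0.05) —
"inbreeding-like"; null alleles elevate only carrier loci, leaving the
bulk near zero while loci with $\hat r \ge 0.05$ are elevated —
"null-artifact-like". The quartile is tested first because EM null
estimates are themselves inflated under genuine inbreeding and cannot
define a clean "null-free" locus set there. The screen presumes a
population already showing a heterozygote deficit worth explaining; on
populations with no deficit it returns "inconclusive" or, occasionally,
a spurious label, so it should be read together with the global
heterozygote-deficiency test.

# Differentiation, permutation tests and trees

$\theta$ is the Weir–Cockerham ratio-of-sums estimator over alleles and
loci; populations enter a locus only with at least two typed individuals.
Pairwise significance comes from permuting whole multilocus genotypes
between the two populations (add-one p-values), with Bonferroni families
defined within species. $R_{ST}$ applies the same variance-components
logic to allele sizes (one-way ANOVA of gene-copy sizes, among- and
within-population components summed over loci), making it sensitive to
stepwise-mutation memory. The allele-size permutation test shuffles the
size labels among the distinct allelic states at each locus — genotype
identity structure is untouched — and recomputes $R_{ST}$; the mean of
the permutation null is a size-blind, $F_{ST}$-like quantity, and a
significantly larger observed $R_{ST}$ indicates phylogeographically
accumulated mutation signal rather than drift alone.

Genetic distances default to Nei's $D_A$
($1 - \tfrac1L \sum_l \sum_i \sqrt{x_{li} y_{li}}$), which is bounded,
robust to non-shared alleles and the common choice for population trees;
the standard 1972 distance is available behind a flag. Neighbor joining
is implemented with the Q-criterion, deterministic lexicographic
tie-breaking on population labels (so input order never changes the
tree), and negative branch lengths clamped to zero with the deficit
transferred to the sister edge; raw lengths are kept in an attribute. On
additive matrices the algorithm is exact, which the tests verify on 4–8
taxon instances alongside an independent implementation. Bootstrap
supports resample loci with replacement and report the percentage of
replicates containing each internal bipartition of the full-data tree.

# The synthetic-data generator

`simulate_genotypes()` is a forward Wright–Fisher simulator with
non-overlapping generations: each offspring selfs with probability $s$
(equilibrium $F_{IS} = s/(2-s)$), otherwise draws two parents; each
parent is a migrant from a uniformly chosen other deme with probability
$m$ (island model); gametes segregate independently per locus and mutate
by ±1 repeat unit with probability $\mu$, reflecting at the 80–400 bp
bounds; founder bottlenecks restrict a deme's parent pool at scheduled
generations. All demes start from a common ancestral pool of equally
frequent stepwise states, so differentiation is generated, not assumed.
Null alleles are injected as hidden allelic *states* shared identically
across demes — the subset of states whose pooled frequency best matches
the per-locus target — so the EM model's assumptions are matched exactly
and the realized per-population null frequency is recorded as truth.

The presets encode the regimes the analysis is designed around:
`fragmented_drift` (8 demes of 50, $m = 0.006$, 300 generations,
$4Nm \approx 1.2$) settles at multilocus $\theta$ in the 0.3–0.6 band
with within-population $H_E$ roughly 0.15–0.65, the signature regime of
strongly drift-structured species; `core_panmictic` gives $\theta \approx
0$; `peripheral_founder` adds serial 3-founder bottlenecks to half the
demes; `selfing_mixed` uses $s = 0.2$ (equilibrium $t \approx 0.8$);
`null_artifact` puts nulls at 4 of 13 loci under random mating. Sample
sizes default to 16 diploids per deme (presets range 16–24), matching the
6–32 per-population range typical of field studies. The generator
reproduces drift, migration-drift balance, inbreeding equilibrium,
stepwise mutation and the null-allele observation model; it does not
emulate linkage, allele-size homoplasy constraints beyond reflecting
bounds, scoring error/stutter, or spatially explicit dispersal — so
passing recovery tests demonstrates estimator correctness under the
stated model, not robustness to those artifacts.

# Numerical choices and problem sizes

Enumeration is capped at $10^5$ tables; chain tie comparisons use a
$10^{-9}$ log-scale tolerance with the chain's log-probability refreshed
from counts once per batch to prevent floating-point drift. EM runs to a
$10^{-6}$ parameter-change tolerance with a 2,000-iteration cap. All
stochastic stages take explicit integer seeds, and the pipeline derives
per-stage seeds from one master seed, making full reports byte-identical
under a fixed seed. The test suite scales the study-sized settings down
to keep a laptop run in minutes: Markov chains of a few hundred thousand
steps (the estimand is the same; only the Monte-Carlo error grows, and
comparisons are made in units of the reported MC standard error),
permutation and bootstrap counts in the tens to hundreds, and recovery
studies of 25–50 replicates at deme sizes of 50–150. Production defaults
remain the classical settings (10,000/1,000/10,000 chains, 10,000
permutations, 10,000 bootstrap replicates).

# Known limitations

* The deficiency-direction ordering uses the heterozygote count rather
  than a frequency-weighted score; for highly asymmetric allele
  frequencies the two orderings can differ slightly.
* The EM null model assumes random mating within populations; under
  strong inbreeding its estimates absorb part of the inbreeding signal,
  which is precisely why the heterogeneity screen leads with the
  $F_{IS}$ quartile rather than the null estimates.
* `f_is` at a single locus with very small typed samples is noisy; the
  regression diagnostic therefore uses the ratio form throughout.
* The ENA correction targets frequency distortion from nulls; it cannot
  repair loci where the null is near fixation (such loci are dropped with
  a warning).
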