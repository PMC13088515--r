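---
title: "Discovering recessive lethal haplotypes from phased genotypes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Discovering recessive lethal haplotypes from phased genotypes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(haplolethal)
```

## The problem

A recessive lethal allele kills only homozygotes, often before birth.
Carriers are healthy, so in a closed breed with heavy use of popular sires
and a small effective population size such alleles drift to carrier
frequencies of 10–20% before selection against the (dead, unobserved)
homozygotes balances the drift. The phenotype of an early-acting lethal is
nothing more than a mating that produces no foal, which is why these alleles
hide in fertility statistics rather than veterinary records.

Genotype data expose them anyway: a haplotype carried by hundreds of living
heterozygotes that is never — or almost never — seen homozygous is out of
Hardy–Weinberg equilibrium in a very specific direction. `haplolethal`
implements that missing-homozygosity scan, the fertility contrasts that
corroborate a hit, and the sequenced-sire concordance filter that narrows a
deficient region to candidate causal variants.

## The scan model

For each sliding window (1 Mb and 2 Mb, advancing by half the window size)
every distinct phased allele string is tallied over the `2N` chromosomes.
For a haplotype with frequency `q = k / 2N`, Hardy–Weinberg predicts
`E = N q²` homozygous animals. The test statistic is the exact binomial
lower tail

    p = P(X ≤ O),   X ~ Binomial(N, q²),

one-sided because only a *deficit* of homozygotes indicates a linked lethal;
an excess has no interpretation under this model and is not tested.
Haplotypes with `q ≤ 0.5%` are excluded (phasing artefacts, no power) as are
haplotypes with more than 30 observed homozygotes (no plausible lethal), and
the Bonferroni denominator is the number of haplotypes actually tested after
those filters, pooled over both window sizes. Adjacent or overlapping
significant windows on one chromosome are merged into a region whose
representative haplotype is the most significant record.

Why two window sizes: linkage disequilibrium varies along the genome, so a
fixed grid at a single scale either splinters a long shared haplotype into
low-frequency fragments or dilutes a short one with flanking markers. The
half-window step guarantees every locus is interior to some window.

Conventions worth stating once: marker positions are 1-based; windows are
half-open `[start, end)`; a window needs at least two markers to define a
haplotype; carrier frequency is reported as the fraction of heterozygous
animals (`het / N`), and a reported carrier frequency `c` converts back to a
haplotype frequency through the minor root of `c = 2q(1 − q)`. Expected
homozygote counts are reported rounded to integers in tables but kept exact
internally. Scans require complete phased input; missing or unphased
genotypes are a hard error, because phasing is an upstream concern.

## Fertility phenotypes of risk matings

Three phenotypes are computed from breeding records:

* **insemination success** — the fraction of insemination events that
  produce a registered foal; matings of the same sire–dam pair within 10
  days of the previous one are the same event (chains collapse transitively
  and keep the first date);
* **stillbirth rate** — foals flagged dead at birth or dying on their birth
  day, over all foals;
* **juvenile mortality** — deaths within 365 days of birth over all foals;
  day-0 deaths count here too, since every case of death counts. The overlap
  with the stillbirth phenotype is deliberate.

A foal is attributed to the latest insemination event of its dam that lies
300–400 days before its birth (gestation is ~340 days in the horse); foals
with no matching event still count in the foal-level phenotypes.

Matings are classified per region: **risk1** is carrier sire × genotyped
carrier dam; **risk2** is carrier sire × ungenotyped dam whose own sire (the
maternal grandsire) is a carrier — a genotyped non-carrier dam removes the
mating from risk2 even when the grandsire carries, and a genotyped carrier
dam belongs to risk1 only. **Non-risk** matings are the same dam groups under
genotyped non-carrier sires. "Carrier" always means a genotyped heterozygous
or homozygous call; an unknown status never counts as non-carrier, and
matings whose sire is ungenotyped are excluded from every contrast.
Independently, all matings of carrier sires are contrasted with all matings
of non-carrier sires, which trades specificity for counts.

Group rates are compared with the pooled two-proportion z-test (two-tailed,
no continuity correction; zero pooled variance returns p = 1 by convention)
and summarised as relative differences
`(rate_ref − rate_cmp) / rate_ref × 100`. Under full embryonic lethality a
carrier×carrier mating loses a quarter of its conceptions, so risk1
insemination success should sit 25% (relative) below the reference, and
all matings of carrier sires should sit `0.25 × carrier frequency` below
non-carrier sires. Semen-quality parameters, which are skewed, are compared
between carrier and non-carrier sires by Wilcoxon rank-sum tests on medians
with a Bonferroni correction across parameters.

## Candidate causal variants

For a deficient region, sequenced sires with known haplotype status act as a
truth panel. A variant is concordant with the region's lethal when

1. it lies within 4 Mb of the region boundaries,
2. every sequenced haplotype-carrier sire is heterozygous for it — a missing
   call fails conservatively — and at most one sequenced sire is homozygous
   for the alternate allele (tolerating one genotyping error), and
3. at most three sequenced non-carrier sires carry the alternate allele at
   all (heterozygous or homozygous).

Whether the one-homozygote allowance counts carriers only or all sequenced
sires is genuinely ambiguous; it is applied to all sequenced sires here and
recorded in the output. Passing variants are tiered by consequence:
frameshift, stop gained/lost, start lost, splice donor/acceptor and inframe
indels are loss-of-function, as is any structural variant overlapping at
least one bp of an exon; missense calls are deleterious at SIFT ≤ 0.05 and
tolerated above it, and a missense variant without a SIFT score falls to the
lowest tier with a warning rather than silently counting as deleterious.
Within a tier, a variant seen homozygous in variant databases or sitting at
a non-conserved site is demoted; remaining ties break by genomic coordinate
so output order is deterministic. SIFT, CADD, conservation and
database-homozygosity are consumed as annotations, never computed.

Because the scan works on haplotypes, a homozygous *haplotype* call does not
guarantee a homozygous *variant*: recombination (or an identical-by-state
lookalike haplotype) can separate the two. `check_haplotype_variant_discordance()`
reports exactly those animals — homozygous for the haplotype yet not
homozygous for the variant, and the converse — which is also the natural
validation readout when candidate variants are genotyped directly.

## What the simulator emulates, and what it does not

The generator exists so every stage is testable against known ground truth:

* a multi-generation pedigree in which a configurable fraction of males are
  heavily used sires (the default weighting gives the top tenth of males
  roughly 70% of matings);
* founder haplotypes with neutral allele frequencies Uniform(0.05, 0.95) —
  so the QC filters have real work to do — and a planted lethal haplotype at
  an exact founder chromosome count; under lethal penetrance the lethal
  chromosomes go to distinct founders, since a founder is by definition a
  living animal (at founder frequencies above ~0.3 this deliberately
  overshoots the Hardy–Weinberg carrier fraction; the study range is
  0.05–0.13 where the distortion is negligible);
* gene drop with exactly one crossover per meiosis at a uniform position —
  the simplest model that preserves Mb-scale haplotype blocks; genetic map
  realism is out of scope;
* a causal variant placed *off-chip* at the centre of the planted region, so
  crossovers between the variant and the region edge create the
  haplotype/variant discordance seen in real data. The breakage probability
  is configured geometrically (region span relative to genome length) rather
  than by a separate dial;
* mating records in which each breeding attempt succeeds with the baseline
  probability (default 0.65, within the 0.6–0.77 per-cycle range typical of
  horses), conceptions homozygous for the causal variant die before birth
  under embryonic penetrance (the 25% conditional loss), failed attempts
  spawn a re-mating record 1–10 days later with probability 0.5, and every
  mating reaches the output file with probability 0.9 (registration is
  incomplete in real studbooks);
* stillbirth and juvenile penetrance variants, plus baseline rates of both,
  with dead animals excluded from the genotyped set — which is precisely
  what creates the homozygote deficit for later-acting stages.

A dam is bred at most once per generation (a mare cannot carry two
overlapping conceptions), one autosome is simulated, dates are integer day
offsets with a fixed 340-day gestation, and re-mating records never carry
their own conception — they model registration noise and are collapsed by
the phenotype module, so the success statistic is unaffected. Because every
living animal is genotyped, risk2 matings (which require ungenotyped dams)
are rare in simulated data; the risk2 logic is exercised by constructed
fixtures instead. The simulator makes no attempt at seasonality, mare age,
selection on breeding-goal traits or heterozygote advantage. Passing tests
on this generator therefore demonstrate the statistical machinery, not the
demographic realism of any particular breed.

The distribution of matings per sire and dam per year in real studbooks is
unknown to us; the defaults are configurable, not calibrated.

## Numerical and design choices

* The exact binomial tail is computed by `stats::pbinom`; tests hold it to
  an independent log-space summation oracle at 1e-12 relative tolerance up
  to N = 10,000.
* The exact Hardy–Weinberg marker test (QC) is the conditional-on-allele-
  counts enumeration test implemented in-package and checked against a
  direct enumeration oracle; thresholds default to MAF > 1%, marker call
  rate > 90%, animal call rate > 70% (applied first), HWE p ≥ 1e-8.
* Bonferroni: `p_adj = min(1, m·p)` with `m` the number of post-filter
  tests. The 30-homozygote ceiling and the frequency floor are both applied
  before counting `m`; their order does not change the result set.
* Window enumeration stops on each chromosome once a window has covered the
  last marker, so a chromosome shorter than the window yields exactly one
  window.
* Region representative: smallest adjusted p, ties by coordinate then
  haplotype string.
* Per-stage seeds in the pipeline derive deterministically from one global
  seed, so stages can be re-run in isolation.

## Problem sizes used by the test-suite

The suite checks the power property at roughly the published scale — about
5,000 genotyped animals on a 10-Mb autosome at 18 markers/Mb (the post-QC
density of a 70K equine chip), planted founder frequency 7%, 20 replicate
seeds — where the planted region must reach Bonferroni significance with
zero observed homozygotes in at least 19 of 20. Family-wise error is checked
on 100 neutral replicates of a smaller population (~800 animals), and the
25% risk1 effect on a single large population contributing over 10,000
carrier×carrier matings at a planted founder frequency of 0.25 (chosen to
make both risk and reference groups large; the per-mating loss is 25%
regardless of frequency). These sizes are the package's own choice of
smallest-scale-that-demonstrates-the-property.

## Known limitations

Haplotype-based carrier status is not fully reliable — that is a finding,
not a bug, and the discordance report quantifies it. The scan assumes the
deficit is driven by a single lethal per region; two linked lethals in
repulsion would confuse the carrier sets. Bonferroni over heavily
overlapping windows is conservative. The phenotype contrasts are raw
proportions without covariate adjustment (mare age, season, year), matching
the design they mirror; and registration incompleteness is simulated but
not corrected for, which biases insemination success upward in small
categories.
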