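---
title: "Detecting runs of homozygosity and genomic inbreeding with rohscan"
author: "rohscan"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting runs of homozygosity and genomic inbreeding with rohscan}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rohscan)
```

## The problem

When both copies of a chromosomal segment descend from a single ancestral
haplotype, the segment is autozygous and appears in SNP-array data as a
run of homozygosity (ROH): a long stretch of homozygous genotypes. The
length distribution of ROH carries demographic information — recent
inbreeding leaves long runs, ancient inbreeding short ones — and the
genome-wide ROH fraction is a direct estimate of the inbreeding
coefficient. Regions where many animals in a population share ROH ("ROH
islands" or hotspots) mark putative targets of selection. `rohscan`
implements this analysis for diploid autosomal genotypes on medium-density
arrays (tens of thousands of markers), the setting typical of sheep and
cattle breeding studies.

Genotypes are coded as minor-allele dosage 0/1/2 with `NA` for missing
calls; only homozygous/heterozygous/missing status matters downstream, so
the tie-break used to pick the "minor" allele (lexicographic on allele
label) cannot change any result. Coordinates are 1-based physical bp as in
PLINK MAP/BIM files, and every interval length in the package is
`end − start`, not `end − start + 1`; a "region" consisting of a single
marker therefore has length 0. This one convention is applied everywhere
(segment lengths, chromosome extents, hotspot regions) so that ratios of
lengths are internally consistent.

## Quality control

`apply_qc()` first removes samples with call rate ≤ 0.9, then, on the
survivors, markers with call rate < 0.95, minor allele frequency < 0.01,
or exact Hardy–Weinberg p ≤ 10⁻⁶ (each removed marker is tallied under the
first criterion it fails, in that order). The sample filter runs first
because a few badly genotyped animals otherwise drag down many markers'
call rates; this mirrors PLINK's `--mind`-before-`--geno` behaviour.

The Hardy–Weinberg test (`hwe_exact_p()`) is the exact conditional test:
fixing the observed allele counts, the probability of every possible
heterozygote count is evaluated (by a log-space recurrence), and the
p-value sums the probabilities of all configurations no more probable than
the observed one. Two numerical details are deliberate: probabilities are
normalized after the recurrence rather than computed from factorials, and
configurations within a relative 10⁻¹⁰ of the observed probability count
as ties and are included. Without the tie margin, mathematically equal
probabilities computed by different routes could fall on different sides
of the ≤ comparison and change the p-value by a whole term. There is no
mid-p correction: the threshold semantics are plain `p ≤ 10⁻⁶ removes`.

## The scanning-window detector

`detect_roh()` reproduces the PLINK `--homozyg` logic. Per sample and
chromosome:

1. A window of `window_snp = 50` consecutive markers slides one marker at
   a time. A window *qualifies* if it contains at most
   `window_max_het = 1` heterozygote and `window_max_missing = 5` missing
   calls.
2. Each marker's *hit rate* is the fraction of windows covering it that
   qualify; markers with hit rate ≥ `window_hit_threshold = 0.05` are
   run-eligible. The comparison is `≥`, matching PLINK's "at least"
   semantics.
3. Maximal stretches of consecutive run-eligible markers are candidate
   runs, split wherever consecutive markers are more than
   `max_gap_kb = 1000` apart (a gap above the maximum can never be
   bridged, so splitting happens before the size filters).
4. Candidates survive if they have ≥ `min_snp = 40` markers, span
   ≥ `min_length_kb = 1000`, and average ≤ `max_density_kb_per_snp = 100`
   kb per SNP.

The window size and hit threshold are PLINK v1.9 defaults; the five run
criteria (1 Mb, 40 SNPs, 1 het + 5 missing per window, 100 kb/SNP, 1 Mb
gap) are the standard choices for ovine 50K data. All eight are
parameters of `roh_params()`. Because eligibility is window-smoothed, a
reported run may contain interior heterozygous or missing calls; the
per-window allowances, not a per-segment cap, control how many.
Chromosomes with fewer markers than one window use a single window of all
available markers.

A second, intentionally naive implementation (`brute_force_roh()`)
evaluates the same contract by explicit enumeration of every window and
every hit rate. It exists purely as a test oracle: the suite checks
set-equality of the two implementations on hundreds of randomized
fixtures, which pins the boundary behaviour (threshold `≥`, gap strictly
`>`, filters `≥`/`≤`) far more tightly than individual examples could.

## Inbreeding coefficients

For each animal, F<sub>ROH</sub> = L<sub>ROH</sub> / L<sub>AUT</sub>.
L<sub>AUT</sub> is the summed per-chromosome span (last − first
QC-passing marker); using the post-QC span keeps the denominator
self-contained, and `autosome_extent()` accepts nominal chromosome lengths
instead when a fixed denominator is preferred. Per length category (bins
[1,5), [5,10), [10,20), [20,∞) Mb, left-closed) the same ratio is
restricted to runs in the bin, so category values sum exactly to the
total; per chromosome, F<sub>ROHOAR</sub> divides by that chromosome's
span, and the per-chromosome lengths sum exactly to L<sub>ROH</sub>. Both
identities are enforced by tests. Category descriptive statistics (mean,
median, min, max, CV = 100·sd/mean) are computed over animals having at
least one run in the category, which is why the "number of animals"
differs per row of the category summary.

## Hotspots

`snp_incidence()` counts, per marker, the animals whose runs span it
(each animal at most once), as a percentage of the cohort.
`call_hotspots()` selects the top 1% of markers by the nearest-rank rule:
the threshold is the smallest incidence among the top ⌈0.01·m⌉ markers
and every marker at or above it is selected, so ties never depend on input
order. Two qualifications:

* Markers with zero incidence are never selected. When most of the genome
  has no ROH at all, the nearest-rank threshold collapses to 0 and would
  otherwise select *everything*; requiring positive incidence makes the
  degenerate all-zero track return an empty table, which is the only
  sensible reading of "hotspot".
* Selected markers merge into one region only when consecutive in the
  QC-passing marker sequence — a bp-distance rule would silently bridge
  nearby-but-separate islands.

Gene counts use closed-interval overlap (a gene abutting the region
boundary counts). The mean recombination rate of a region is
(cM(stop) − cM(start)) / Mb with genetic positions linearly interpolated
between map anchors and held constant beyond them; for single-marker
regions the rate is undefined and rendered `/` in the formatted table.

## Dating ROH

An autozygous tract of genetic length ℓ cM has expected time to the most
recent common ancestor of g = 100/(2ℓ) generations. `classify_segments()`
bins run genetic lengths into the conventional classes > 10 cM (< 5
generations), (5,10] (5–10), (2.5,5] (10–20), (1.25,2.5] (20–40), with
≤ 1.25 cM left "unresolved" — a medium-density array cannot reliably
detect tracts that short, so assigning them a date would be spurious
precision. Classes are left-open/right-closed so every length has exactly
one class; the boundaries are configurable.

## The synthetic cohort generator

`simulate_cohort()` provides ground truth for every stage. Its defaults
*are* the study conditions the package is validated under: 200 animals,
26 autosomes of 100 Mb with 2000 markers each (52k markers, one per 50 kb
— the scale of an ovine 50K array after QC), allele frequencies
Uniform(0.05, 0.5), background genotypes in Hardy–Weinberg proportions,
5% of each genome covered by planted autozygous tracts whose genetic
lengths follow Exp(mean 100/(2g)) cM at generation depth g = 6, a 0.1%
rate of heterozygous miscalls inside tracts, 2% missingness, and a uniform
1 cM/Mb map. Within a tract one haplotype is drawn and doubled, so tract
markers are homozygous but still frequency-realistic. Tracts are placed
uniformly and rejected on overlap; an optional hotspot specification
plants one identical interval into a chosen fraction of animals. The
per-sample truth (tract list and autozygous fraction) is returned
alongside the genotypes.

Two things the generator deliberately does **not** emulate: background
linkage disequilibrium (markers are independent given allele frequencies)
and a non-uniform recombination map. Passing recovery tests therefore
shows the detector and its statistics are correct under the stated model,
not that real sheep LD cannot produce additional chance runs; on real
data, short-ROH counts are expected to be noisier than in simulation.

## What the validation computes

The test suite and `scripts/acceptance.R` recompute, at run time:
exact region-length conventions on fixed coordinates (including the
length-0 single-SNP case); full equivalence of the scanning-window
detector with the brute-force oracle on 200 random fixtures; exact
agreement of the HWE test with enumeration for all genotype
configurations up to 30 diploids; and parameter recovery at study scale —
mean F<sub>ROH</sub> within ±0.015 of the planted mean autozygous
fraction, and a 3 Mb tract shared by 30% of the cohort recovered as one
region covering ≥ 90% of its markers. These sizes (200 × 52k, one
detection pass in ~10 s) were chosen so the whole validation runs on a
laptop in well under a minute.

One interaction deserves emphasis because it is a genuine property of the
method, not an artifact: the hotspot-recovery check disables the
Hardy–Weinberg filter (`qc_params(min_hwe_p = 0)`). A tract shared
identically by 30% of a cohort produces a real heterozygote deficit at
its markers (median exact p near 10⁻⁶ at n = 200), and an equilibrium
filter reads exactly the strongest selection footprints as genotyping
artifacts, deletes enough of their markers to push the surviving run
below the 40-SNP minimum, and erases the island. Incidences in the single
digits of percent — the level typical of real sheep cohorts — do not
trigger this, but simulated hotspots strong enough to be unambiguous do.
Selection scans on real data face the same trade-off, which is why many
ROH studies run detection without an HWE filter. The inbreeding-recovery
check keeps the full default QC.

## Known limitations

* Likelihood/HMM-based ROH callers, phased-IBD methods and sex
  chromosomes are out of scope; detection is the window heuristic only.
* F<sub>ROH</sub> from 50K-density data underestimates autozygosity held
  in tracts shorter than the 1 Mb / 40-SNP floor; the simulator makes
  this visible (planted F_true minus recovered F_ROH is positive and
  grows as generation depth increases).
* The exact replication of any particular published cohort's headline
  numbers requires that cohort's genotypes; the package validates
  conventions and algorithms, and its simulator emulates scale, not a
  specific population's allele-frequency and LD structure.
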