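---
title: "Models and conventions behind tillkit"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and conventions behind tillkit}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tillkit)
```

# The problem

A TILLING resource is judged by its induced mutation density: how many
base pairs of screened sequence, on average, separate two induced
mutations in the M2 generation. `tillkit` implements the two estimators
used to measure that density in practice, a forward simulator that
generates populations with a *known* density so the whole
screen-and-estimate loop can be validated, effect classification of the
recovered mutations, and the bookkeeping around phenotype censuses. This
vignette records the models, their assumptions, and every numerical
convention the package commits to.

# Mutagenesis model

EMS alkylates guanine; mispairing of O6-ethylguanine fixes almost
exclusively G:C→A:T transitions. The simulator enforces this spectrum
exactly: every simulated mutation has reference base G (→A) or C (→T) as
observed on the reference strand, mirroring how mutation tables are
written (`C1687T`, `G2309A`); the complementary-strand event is not
tracked separately. A reference without any G or C cannot realize a
positive density and is rejected rather than silently violating the
spectrum.

Mutations are independent Bernoulli events across eligible (G/C) sites.
The per-site probability is rescaled so that the *genome-wide* expected
density — mutations per bp of total sequence, A:T sites included — equals
the requested `target_density`. EMS is reported to prefer 5′-PuG-3′
contexts; since no quantitative weight is established, the
`context_bias_weight` parameter defaults to 1 (off), and when set above 1
the reweighted site probabilities are renormalized so the genome-wide
expectation is unchanged. Only the *placement* of mutations shifts, never
the total.

## Breeding and chimerism

Each induced mutation is modeled as heterozygous in the M1 germ line
(alkylation modifies single strands, and observed M2 segregation of
screened mutations is consistent with M1 heterozygosity). Selfing an M1
heterozygote gives M2 genotypes hom\_alt : het : hom\_ref = 1 : 2 : 1 at
each site, drawn independently per sampled sibling.

An M1 plant is optionally chimeric: `sectors_per_m1` independent meristem
sectors each receive their own mutation set, and each sampled M2 sibling
descends from exactly one sector. Siblings from different sectors of the
same M1 plant therefore share *no* induced mutations — the pattern
occasionally seen in real screens when two siblings of one line carry
disjoint mutations. The default is one sector (chimerism is rare), and
the model does not resolve whether siblings come from one tiller or
several; the sector abstraction deliberately leaves that open.

## Which generation does the density describe?

A screen measures M2 plants, but mutations are induced in M1. An M1-het
site is carried (het or hom\_alt) by a given M2 sibling with probability
3/4, so the per-M2-genome density is 3/4 of the M1 induction density.
`sim_config(density_basis = "m2")` (the default) therefore scales the
induction rate by 4/3 so that `target_density` means "detectable
mutations per bp per screened individual" — the quantity the estimators
report and the only basis on which simulated-vs-estimated comparisons are
meaningful. `density_basis = "m1"` disables the calibration;
`induce_ems_mutations()` itself always realizes exactly
`density × length` expected events.

A related subtlety: discoveries are conventionally counted once per M2
*line* (a mutation re-found in two siblings is one allele). With *k*
siblings per line, a site is discovered in at least one sibling with
probability `1 − (1/4)^k`, so the line-deduplicated count per screened
plant is `(1 − 4^{-k})/k × ` (M1 density) — for k = 2 about 0.47 of it,
below the true per-plant carrier density of 0.75. Screening siblings
finds *more alleles per line* but makes the per-plant density estimate
conservative, which is why published densities from multi-sibling designs
are naturally quoted as lower bounds ("at least 1/47 kb"). The package's
parameter-recovery validation uses one sibling per line, where the
estimator is unbiased; the default `siblings_per_line = 2` matches the
bundled population's design (2610 M2 plants from 1350 lines).

# Screen model

An amplicon is a coordinate window (0-based, half-open); no
nucleotide-level PCR is simulated. Three mechanisms gate detection:

1. **Dead zones.** Cleavage fragments within `end_trim` bp (default 100)
   of either amplicon end cannot be sized reliably on a gel, so only the
   effective region `[start + end_trim, end − end_trim)` is scannable —
   and only the effective length enters the density denominator.
2. **Heteroduplex formation.** After re-annealing, a pool yields a
   mismatch substrate only if it contains both alleles. An all-wild-type
   pool and an all-homozygous-mutant pool are equally silent. During
   deconvolution each member is re-tested singly *mixed with wild-type
   DNA*, so homozygous carriers remain detectable; specificity is fixed
   at 1 (calls are treated as sequencing-confirmed; no false-positive
   mechanism is modeled).
3. **Detection sensitivity.** Each (pool, site) signal survives an
   independent Bernoulli draw at the gel system's sensitivity. Defaults
   are the relative recovery of the three systems screened head-to-head
   on one amplicon — silver-stained PAGE 1.0, ethidium-bromide agarose
   14/15, ethidium-bromide PAGE 11/15 — and are configurable, since they
   are relative rates from one comparison, not physical constants.

Cleavage at a site inside amplicon `[start, end)` yields fragments of
`site − start` and `end − site` bp; their sum equals the amplicon length,
the signature by which genuine bands are recognized, and an invariant the
tests enforce on every call. Two mutations in one pool and amplicon are
treated as independently detectable (band co-migration is not modeled).

# Estimators

**Band survey (RAPD/ISJ).** Each band routinely amplified in the wild
type scans two primer-binding sites of `L` bp per line:
`bp/mutation = (2L)(B·N)/m`. Gains and losses of bands count identically,
and `m` is a plain event count (one line may contribute several). The
per-primer estimates are aggregated by averaging their *reported kb*
values (each primer is one genome-wide probe); pooling scanned bp and
bands across primers is also implemented (`method = "pooled"`) and gives
a smaller, band-weighted answer — the per-primer mean is the default
because it is the convention under which such surveys are reported.

**Amplicon screen.** `bp/mutation = effective_bp × n_plants /
n_mutations` per amplicon; across amplicons, scanned bp and mutation
counts are summed before dividing, so the pooled estimate weights
amplicons by scanned sequence. The estimator is undefined at zero
mutations (it errors rather than returning infinity).

**Reporting conventions.** Three distinct roundings are used, each
matching how the corresponding quantity is conventionally printed:
densities are reported as `1/⌊bp/1000⌋ kb` (floor — truncation reproduces
published per-primer and per-amplicon values where half-up rounding would
not, e.g. 10,500 bp → 10 kb and 31,500 bp → 31 kb); census percentages
round half-up to two decimals (8/2610 → 0.31%); the genome-wide load
`genome_size / bp_per_mutation` is reported to two significant figures
(1.6×10¹⁰ / 47,000 → 340,000). The exact values are always kept alongside
the report forms.

# Effect classification

The gene model is an ordered chain of disjoint exons with a reading-frame
offset and a residue-numbering anchor; minus-strand genes are handled by
reverse-complementing the concatenated exon sequence. Classes are
exhaustive and mutually exclusive:

- intronic positions within 2 bp of an internal exon boundary are
  `splice_junction` (the canonical GT/AG dinucleotides; the window is a
  package choice, configurable via `splice_window`);
- other non-exonic positions are `intron`;
- exonic positions are classified by translating the affected codon
  before and after with the standard nuclear genetic code: `silent`,
  `nonsense` (stop gained), else `missense`, with notation like `T438M`
  numbered from the model's anchor. Residue numbers for the bundled
  wheat records follow the published table; they depend on the full-gene
  CDS, which is outside the modeled region, so they are consumed as
  given rather than recomputed.

Records identical in (site, ref, alt) within one M2 line collapse to one
unique mutation (sibling re-discoveries of a segregating allele); the
same substitution in two different lines counts twice, since independent
origin is the parsimonious reading and hitting the same base twice is
plausible at these densities. Imported PSSM/SIFT severity scores are
carried as opaque fields (the conventional damage thresholds are PSSM
> 10 or SIFT < 0.05); the package never computes them.

# What the simulator does and does not emulate

It emulates: the transition spectrum, configurable density with optional
context bias, M1 chimerism, 1:2:1 segregation with 2–3 sampled siblings,
fourfold (up to eightfold) pooling, amplicon dead zones, per-method
sensitivity, and deconvolution. It does not emulate: EMS dose–response
and germination, PCR chemistry and primer binding, gel physics and band
intensity, nuclease kinetics, false positives, phenotypes, or linkage
(sites are independent; real mutations on one chromosome cosegregate).
Passing recovery tests therefore validates the estimator arithmetic and
the screening geometry under idealized detection — not the wet-lab error
modes of a real screen.

# Reproducibility and problem sizes

Every stochastic operation takes an explicit seed; pipelines derive
per-stage sub-streams deterministically from one master seed, so a
configuration reproduces bit-identically. The validation suite uses
problem sizes chosen to keep Monte-Carlo error well inside the asserted
tolerances while running in minutes: density calibration on a 5 Mb
reference over 20 replicates (±5%); expected-count checks on 10 Mb
(3 standard errors); parameter recovery with 512 single-sibling lines
over sixteen 1.7 kb amplicons (24 kb effective) at sensitivity 1.0,
averaged over 20 seeds (±10% of 1/47 kb); and 1:2:1 segregation by
chi-square at α = 0.01 across 100 seeded runs, tolerating the handful of
rejections that the test level itself implies.

# Known limitations

- Site independence ignores linkage between mutations of one M1 genome.
- The band-survey estimator inherits the formula's idealizations (every
  binding-site mutation changes banding; mutations elsewhere never do);
  it underestimates density to the extent that 5′-end mismatches are
  tolerated.
- Pool deconvolution is modeled as always performed and always correct.
- The line-level discovery dedup makes multi-sibling density estimates
  conservative (see above); the package reports what the convention
  reports rather than attempting a correction.
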