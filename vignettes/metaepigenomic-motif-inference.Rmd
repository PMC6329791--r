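---
title: "Metaepigenomic motif inference: models, parameters, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metaepigenomic motif inference: models, parameters, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metaepi)
```

## The problem

Prokaryotes methylate their genomes at short, sequence-specific recognition
sites — N6-methyladenine (m6A), N4-methylcytosine (m4C) and 5-methylcytosine
(m5C) — mostly through restriction–modification (RM) systems and orphan
methyltransferases (MTases). Single-molecule sequencing detects these
modifications kinetically: a modified template base delays the polymerase,
inflating the interpulse duration (IPD) at that position. Applied to a
metagenome, this yields a *metaepigenome*: per-contig, per-strand kinetic
signals over the assembled genomes of a mixed, largely uncultured community,
from which methylated motifs can be inferred genome by genome and matched
against annotated MTase genes.

This package implements that inference chain as testable units:

1. a degenerate **IUPAC motif algebra** (matching, reverse complement,
   position-wise comparison, novelty against a reference, motif-set
   reduction);
2. a seeded **synthetic community generator** producing contigs, planted
   methylation systems and per-site kinetic summaries;
3. a per-site **modification caller** producing Phred-scaled modification
   QVs;
4. greedy **motif discovery** from called-site contexts with
   occurrence/fraction filters;
5. per-contig **methylation profiles** and a binning-congruence score;
6. **MTase–motif congruence** over an RM-gene table, with RM-system
   neighborhood detection and orphan-pairing proposals.

A bundled pair of reference tables — 29 detected methylated motifs across 10
draft genomes, and 28 RM-system genes (20 of them MTases) from a freshwater
lake community survey — exercises the algebra and congruence modules at their
published scale.

## Kinetic model and the site caller

The generator emits, for every contig position and strand, the summary
statistics of the subreads covering that site: a Poisson coverage $n$ (mean
set by the genome's abundance-scaled depth), and the sample mean and standard
deviation of per-subread log2 IPD ratios, drawn from the exact sampling
distributions of a Normal($\mu$, $\sigma^2$) sample — so emitting summaries
is distributionally identical to simulating subreads. Unmethylated sites have
$\mu = 0$; methylated sites are shifted by a modification-type effect:

| parameter | default | meaning |
|---|---|---|
| `ipd_delta["m6A"]` | 1.3 | mean log2 IPD-ratio shift at m6A sites |
| `ipd_delta["m4C"]` | 0.8 | shift at m4C sites |
| `ipd_delta["m5C"]` | 0.25 | shift at m5C sites |
| `ipd_sigma` | 1.0 | per-subread log2 IPD-ratio standard deviation |

No published kinetic effect sizes exist at this level of abstraction; the
deltas are free parameters chosen once to reproduce the qualitative
detectability ordering m6A > m4C > m5C that single-molecule kinetics is known
to exhibit — m6A near-saturating at recommended coverage, m4C detectable with
moderate loss, m5C largely invisible without conversion chemistry.

The caller tests each site's mean log2 IPD ratio against zero with a
one-sided one-sample t statistic,
$t = \bar{x}\sqrt{n} / \max(s, s_{\text{floor}})$ on $n - 1$ degrees of
freedom, and reports $\mathrm{QV} = -10 \log_{10} p$ capped at 1000. The
vendor pipelines delegate this scoring to proprietary in-silico kinetic
reference models; a t statistic on log ratios is the simplest defensible
replacement and is exactly testable against an independent numerical tail
integral (the suite checks agreement to $10^{-6}$ over 1000 random sites).
Defaults: `sd_floor = 0.1` (guards degenerate zero-variance sites),
`min_cov_per_strand = 25` (the community-standard >25x-per-strand guidance
for reliable modification detection), `qv_min = 20` ($p = 0.01$, far below
the mean QVs of confidently detected motifs, which sit at 38–350).

## Motif discovery

Contexts of ±10 bases around called sites (reverse-complemented for
minus-strand calls, methylated base centred) feed a greedy, one-motif-at-a-time
extraction:

1. **Seeding.** Repeatedly take the flanking offset with the highest
   information content (IC, $2 - H$ in bits) at or above `ic_min = 0.5`, fix
   it to its majority base, and restrict the pool — recomputing IC on the
   restricted subset. Restriction separates co-planted motifs: offsets that
   look degenerate in a mixture become pure once one motif's positions are
   fixed, while chance contexts are filtered multiplicatively.
2. **Generalisation.** For each fixed offset, recollect the contexts matching
   the seed at the *other* fixed positions and take the minimal IUPAC code
   covering at least $1 - \varepsilon$ of them ($\varepsilon = 0.05$), after
   discarding bases below `min_share = 0.15` of the column as noise. This
   recovers genuinely degenerate positions (W, R, B codes) while the share
   floor keeps contaminating minority bases — contexts of a second motif that
   slip through the recollection — out of the code.
3. Offsets that never reach `ic_min` stay `N`, so bipartite spacer motifs
   (GAANNNNTTC-like) arise without special-casing. The centre base is forced
   to the majority of A/C, and the motif's modification type follows from it
   (A → m6A, C → m4C by default): kinetics-only typing of cytosine
   modifications is out of scope, as in motif tables generally.
4. Contexts matching the finished degenerate motif are removed and the search
   repeats, up to `max_motifs = 20` or until no offset is informative with at
   least `min_sites = 20` contexts remaining.

Discovery reads contexts at a stricter QV floor (`qv_floor = 30`,
$p = 10^{-3}$) than the caller emits. Scanning a genome at $p = 0.01$ admits
roughly one chance context per 100 testable sites, which in a 200 kb genome
outnumbers the contexts of a typical motif and dilutes every offset below
`ic_min`; one extra decade of stringency restores a clean seed pool while
barely touching true m6A/m4C sites. The thresholds of the original vendor
tooling are unpublished, so these values are this package's own calibration,
exposed in the configuration and validated by the seeded recovery tests.

Candidates are then summarised per genome (strand-specific occurrence count,
coinciding called sites, methylation ratio) and filtered by the survey's
published rule: candidates with fewer than 50 occurrences or a methylated
fraction below 1% are excluded, with both boundaries inclusive on the keep
side.

**Two ratios.** The reported `ratio_pct` divides methylated sites by *all*
motif occurrences — the convention of published motif tables, which
understates the true methylated fraction whenever some occurrences lack
usable coverage (with Poisson coverage at mean 30 and a floor of 25, about a
sixth of occurrences are never tested). `ratio_testable_pct` divides by
occurrences that reached the coverage floor and is the estimator the
fraction-recovery tests use; it tracks planted fractions to within a few
points, the residual gap being the caller's miss rate at the weaker effect
sizes.

## The synthetic community

`community_spec()` defaults describe the desk-scale study community: four
genomes of 200 kb, GC contents 35–65% (order-0 composition by default;
higher-order Markov kernels with per-genome Dirichlet-sampled transitions are
available), abundances 8:4:2:1, community-mean coverage 30 subreads per
strand — so the abundant genomes (64x, 32x) exceed the >25x guidance while
the rare genomes (16x, 8x) drop below it, making detection dropout of rare
community members observable. Each genome carries its own methylation system
at a partial methylation fraction (0.85–0.95, within the broad range
published motif tables report); self-reverse-complementary motifs are
methylated jointly on both strands of a duplex site, as RM-system MTases do.
Contigs have log-normal lengths (median 30 kb, minimum 5 kb), giving several
contigs per genome for the profile-congruence analysis.

`example_recovery_spec()` is the parameter-recovery benchmark: equal
abundances at exactly 30x per strand, fractions spanning 0.80–0.95, and each
motif planted in a genome whose base composition suits it (an AT-rich motif
in the AT-rich genome, and so on). Recovery there measures detection power;
planting an AT-rich motif in a 65% GC genome instead starves it of
occurrences until chance contexts outnumber motif contexts — a real failure
mode of the method on rare or compositionally extreme targets, but not the
quantity the benchmark is meant to measure.

What the generator does *not* emulate: sequencing error and base-calling,
read-level data and assembly artefacts, context-dependent kinetic baselines
(real IPDs vary with local sequence), partial hemimethylation, contamination
and strain mixtures. Passing recovery tests therefore demonstrate the
statistical machinery under the stated noise model, not performance on real
instrument output.

## Motif-set reduction and novelty

Across genomes the same system recurs, one system leaves duplex partner
motifs on the two strands, and incomplete detection splinters one motif into
near-duplicates. `dedupe_and_group()` reduces a per-genome motif table in
three steps: exact-pattern deduplication; reference marking (a motif is
*known* iff its pattern or reverse complement exactly equals a reference
pattern — degenerate subsumption deliberately does not confer known status,
matching how motif repositories report exact recognition sequences); and
single-linkage merging of the remaining novel motifs under two relations:

- **Duplex partners** (`rc_compatible`): the reverse complement of one
  pattern matches the other position by position with no conflicting base
  set, and both motifs carry the same modification class. Patterns are
  aligned end to end. Anchoring this comparison at the methylated bases
  instead would be wrong: reverse complementing maps the methylated offset
  onto the *paired* base on the other strand (a T for m6A motifs), whereas a
  duplex partner methylates its own adenine in the opposite half-site.
- **Near-duplicates** (`similarity_mergeable`): same modification type and,
  aligned at the methylated bases, at most one conflicting position.

Both relations allow at most **one unaligned overhang base in total**. This
budget is the smallest that merges the published BS12-style trio (whose third
member carries one extra flanking base) and the length-15/16 duplex pair;
unlimited overhangs would instead let long spacer motifs merge through their
N runs — aligning two different bipartite motifs so that one's specific bases
sit inside the other's spacer costs nothing — collapsing genuinely distinct
systems into one group. On the bundled table the rules reproduce both
published tallies: 29 rows → 22 distinct motifs → 9 novel groups (one
similarity trio, five duplex pairs, three singletons). The published account
does not state its exact reduction rule, so this is a reconstruction that
recovers the printed counts, not a transcription of the original procedure.

## Profiles and binning congruence

Per contig and per panel motif, the profile entry is the methylated fraction
of the motif's occurrences on that contig; entries are undefined when fewer
than `min_occ = 10` occurrences are *testable* (kinetic coverage at or above
the caller floor) — a contig without usable coverage yields no evidence, not
evidence of absence. Distances between contigs are mean absolute differences
over pairwise-defined entries, undefined below 3 shared entries; the
congruence score is the mean silhouette of contigs under their bin labels.
The published observation this quantifies — contigs of a draft genome share a
methylation pattern — appears in the default community as a score near 1 for
true labels and at or below 0 for permuted labels, computed over the contigs
of the well-covered genomes (rare-genome contigs drop out as undefined). The
original heatmap-based account defines no metric or normalisation; raw
fractions with an L1 silhouette are this package's choice.

## MTase–motif congruence

An M-role gene is *congruent* when its closest-match recognition motif
exactly equals (up to reverse complement) a motif detected in the same genome
with the same modification type; `"?"` specificities are unresolved, and a
`"Nonspecific"` closest match is incongruent at this stage. RM-system
detection flags an MTase with an REase within `window = 5` gene indices on
the same contig, a fused restriction–methylation top hit (`RM.` prefix), or —
for Type I systems — a specificity subunit within the window. The window
value covers the published operon spans (gene-index gaps of 1–4) while
excluding the distant REases that do not form systems; it is exposed in the
configuration. Orphan proposal then pairs unexplained motifs with incongruent
MTases of matching type (`"Nonspecific"` is compatible with anything here),
requiring uniqueness or an REase-target tiebreak — the reasoning that
assigned the novel GCWGC, ACGAG, GAANNNNTTC and TANGGAB specificities in the
survey, all of which the bundled tables reproduce. On those tables 7 of the
20 MTases are congruent and 9 constitute RM systems.

One orphan pairing deserves a note: the rule also proposes the single
leftover MTase–motif pair in the BS8 genome, which the survey left
unassigned (its Type I MTase's specificity is set by a separate subunit).
The proposal stage is deliberately mechanical; `via` records whether a
pairing rests on uniqueness or on REase-target evidence so downstream users
can weight them.

## Numerical and interface conventions

- Coordinates are 0-based half-open internally; occurrence positions are
  forward-strand coordinates of the pattern start, and methylated-base
  positions map through strand geometry (`p + L - 1 - \text{offset}` on the
  minus strand). 1-based coordinates appear only in rendered reports.
- Occurrence counting is strand-specific: palindromic motifs contribute two
  entries per duplex site. Published occurrence magnitudes (thousands of
  GATC-family sites per ~1.5 Mb genome) are consistent only with per-strand
  counting.
- Non-ACGT characters in sequences never match, including against pattern
  `N`.
- Ratios are rounded half-away to one decimal, matching the printed tables;
  all 29 bundled rows recompute exactly.
- Ties in discovery fall to the smaller offset magnitude, negative side
  first, then alphabetical base order; single-linkage grouping sorts patterns
  lexicographically. Reruns of any stage under the same seed are
  byte-identical.
- The motif text syntax marks the methylated base with a preceding lowercase
  `m` (`GmANTC` = GANTC methylated at offset 1).

## Problem sizes

The test suite and analysis scripts run the generator at its default scale
(four genomes × 200 kb ≈ 1.6 million kinetic site records per community,
simulated and called in seconds) and the discovery benchmarks on one seeded
community per condition; the motif-algebra property tests sweep random
motifs up to length 16 against 10 kb sequences with a brute-force window
oracle. These sizes were chosen so the full chain — generation through
congruence — exercises every code path at magnitudes where binomial
tolerances are tight, while a complete check remains an interactive-length
run.

## Known limitations

- The caller's QV is not the vendor modification QV; published per-motif mean
  QVs are therefore not comparable quantities (their coverage and ratio
  columns are).
- m5C recall is structurally low under the kinetic model, mirroring the
  technology; no conversion-based rescue is modelled.
- Discovery assumes one methylated base per motif and no overlapping
  explanations; heterogeneous motif mixtures within one bin (strain
  variation) are resolved only down to near-duplicate groups.
- Congruence is exact-match by design; a divergent MTase whose true
  specificity is a degenerate superset of a detected motif will be called
  incongruent.
- The binning-congruence score is diagnostic; no re-binning is attempted.
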