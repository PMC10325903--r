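---
title: "Predicting cooperative homodimer DNA binding from HT-SELEX data"
author: "coopselex"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting cooperative homodimer DNA binding from HT-SELEX data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(coopselex)
```

## The problem

Homeodomain transcription factors bind short, highly similar AT-rich core
motifs (canonically `TAAT`), yet regulate distinct target genes. One route
to specificity is cooperative homodimer binding: two copies of the factor
occupy two core sites at a precise spacing and orientation, and the first
binding event facilitates the second. HT-SELEX — iterative rounds of
protein-driven selection on a random synthetic DNA library, with
sequencing of every round's pool — contains enough information to detect
this: a cooperatively bound dimer configuration gains stability from
protein–protein contacts, so it should out-enrich its constituent monomer
sites round over round, and it should do so at one specific spacer length.

`coopselex` turns those two ideas into a decision pipeline. The package's
entry point is `coop_predict()`, which takes a set of per-cycle read pools
(`selex_cycles()`), screens candidate long motifs for dimer sites, fits
enrichment slopes, profiles spacer lengths and returns a classed fit
object; the underlying stages are exported individually.

## Dimer-site screening

Candidate dimer sites come from long (16–18 bp) position weight matrices,
either supplied externally (`read_homer_motif()`) or discovered internally
(below). Because a long enriched motif may equally represent one protein on
a long site, each candidate is reduced to its two strongest 4-mer windows:
`extract_core_sites()` maximizes the summed mean per-column information
content (IC, $2 + \sum_b p_b \log_2 p_b$ bits) over all non-overlapping
window pairs at least 2 bp apart. Three criteria then gate the candidate
(`screen_dimer()`):

1. **Core information.** Both cores' mean IC must exceed 0.6 bits. Below
   that, a "core" is barely distinguishable from background and the motif
   is unlikely to represent two positioned binding sites.
2. **Core-to-surround contrast.** Each core's mean IC must be at least 1.5
   times the mean IC of the remaining motif columns. PCR over-amplification
   of a handful of sequences produces motifs with uniformly high IC across
   the whole PWM; requiring contrast between cores and surround rejects
   them. The surround defaults to all non-core columns pooled (flanks and
   spacer); `surround = "flanks_only"` and `"spacer_only"` are available
   because the pooling choice is a genuine judgment call.
3. **Abundance.** The motif must occur in at least 5% of the final-cycle
   reads, removing rare binding events. With a supplied match-score
   threshold (a Homer header) the full PWM is scanned on both strands. For
   motifs without one — including all internally discovered motifs — a read
   counts when it contains the core configuration (site1 consensus, spacer,
   site2 consensus, on either strand). We deliberately avoid deriving a
   scalar threshold for seed-anchored PWMs: once the flank score spread
   exceeds the core mismatch gap, no single cutoff separates core-exact
   from core-broken matches, and an AT-rich pool then inflates abundance
   catastrophically.

A screened candidate becomes a `dimer_model()`: two 4-mer consensus sites,
a spacer, an orientation (`FF` head-to-tail, `FR` head-to-head, `RF` its
mirror; tail-to-tail is the reverse complement of `FF` and is folded into
it).

## Enrichment curves and the enrichment factor

For every cycle, `enrichment_curve()` counts the fraction of reads
containing the dimer configuration and — after masking every
dimer-containing read — the fractions containing each core 4-mer alone.
Masking matters: a dimer site contains two monomer sites, so unmasked
monomer counts would be contaminated by the dimer's own enrichment.
Fractions rather than raw counts normalize unequal pool sizes.

Selection plus PCR makes enrichment exponential, so fold changes against
cycle 0 are linearized with the natural logarithm and fitted by ordinary
least squares on cycle index. Numerical choices:

* **Pseudocount.** Long configurations are often absent from a 50,000-read
  cycle-0 sample; half a read (`0.5 / pool size`) is added to numerator
  and denominator fractions so the cycle-0 reference is finite.
* **Free intercept.** PCR-efficiency offsets between cycle 0 and cycle 1
  shift every series by a constant; leaving the intercept free absorbs
  them, and because dimer and monomer fits share the treatment the slope
  comparison stays fair. It also makes the fitted slope insensitive to
  sampling noise in the cycle-0 reference, which shifts all points of a
  series equally.

The **enrichment factor** is
$\mathrm{EF} = s_\mathrm{dimer} / \tfrac12 (s_\mathrm{site1} + s_\mathrm{site2})$.
EF > 2 gates a cooperative prediction: finding the dimer configuration was
more likely than finding its two monomer sites independently. A mean
monomer slope at or below zero leaves EF undefined (`NA` with a reason
attribute) — a negative ratio must never masquerade as a cooperative call.

## Spacer-length specificity

Fast dimer enrichment alone could reflect any-two-sites selection.
Cooperative complexes, by contrast, require a particular geometry.
`count_spacers()` counts, for every spacer length (default 0–20 bp) and
orientation, the reads containing the two-site configuration; a read
contributes at most once per cell, and a configuration and its full
reverse complement are one event. Cells whose configuration cannot fit the
read length are marked unobservable (`NA`) rather than zero — zero-filling
would fabricate outlier evidence.

Two tests then run per orientation (`call_spacer_specificity()`):

* **Grubbs one-sided max-outlier test** on the final-cycle counts:
  $G = (\max - \bar x)/s$, with the p-value from the t-distribution form
  with $n$ = observable cells. Implemented from the formula (no installed
  package provides it); the test suite checks it against published
  critical values and an independently coded reference, and verifies its
  type-I error by simulation under its normal null.
* **Chi-square test of independence** between the cycle-0 and final-cycle
  count vectors (2 × K table, no continuity correction), after pooling
  cells with expected count < 1 into a neighbor toward the center of the
  range — the standard validity repair, which also removes the undefined
  statistic a zero-expected cell would cause.

The orientation with the smallest Grubbs p is reported and both p-values
are Bonferroni-corrected by the number of orientations tested (Grubbs
itself is already a single-max test, so no correction is applied across
spacers). A spacer is called only when both corrected p-values fall below
α = 0.05; the call is the maximal cell. The final per-model decision
(`classify_cooperativity()`) is a pure conjunction: screen passed, EF > 2,
both spacer tests significant. When several long motifs yield models for
one TF, each is classified independently and the TF is cooperative if any
model is — shifted PWMs representing the same arrangement are collapsed
during discovery.

## Internal motif discovery

`discover_long_motifs()` is a deliberately lightweight, seeded stand-in
for a full de novo motif search; externally produced Homer motifs remain
the first-class input for faithful reruns. It enumerates every gapped
4-mer-pair seed (4-mer, spacer 2–12 bp, 4-mer) in the final cycle and
keeps seeds that satisfy three conditions:

* **Support**: present in ≥ 0.1% of final-cycle reads.
* **Cycle enrichment**: final-cycle frequency at least 5× the cycle-0
  frequency (half-read pseudocount), ranked by the Poisson log-tail
  significance of the final-cycle count given the cycle-0 frequency. The
  significance ranking, not the raw ratio, decides order: a raw ratio
  would be dominated by shifted variant seeds whose cycle-0 count happens
  to be zero.
* **Pairing lift**: the observed seed read count must exceed twice the
  count expected from the two 4-mers' per-position final-cycle
  frequencies, and be significant under a Bonferroni-corrected Poisson
  tail over the whole seed enumeration. Selection on monomer sites makes
  any two co-resident sites co-enrich, so gapped pairs appear "enriched"
  in a monomer-only pool; pairing lift asks the sharper question — do
  these two 4-mers co-occur at this spacing more often than their
  individual occurrence rates predict?

Each surviving seed is turned into a 16 or 18 bp PWM by aligning the
final-cycle reads on their first seed occurrence (reverse-strand
occurrences are reverse complemented first), with quarter pseudocounts per
column. Near-duplicate seeds — 1-mismatch or 1-bp-shift variants of either
4-mer with a spacer within ±2 bp, or the reverse complement arrangement —
are collapsed into the best-ranked representative.

Discovery is specified for pools of a few tens of thousands of reads. In
much smaller pools two failure modes appear: the 0.1% support floor drops
to a handful of reads and admits Poisson flukes, and descendants of a
single PCR founder can exceed the 5% abundance gate. The package's
reference conditions (50,000 reads per cycle, the subsample size also used
on real data) sit comfortably inside the stable regime.

## Tau from EMSA band proportions

An electrophoretic mobility shift assay resolves free probe $[D]$,
monomer-bound $[PD]$ and dimer-bound $[P_2D]$ bands. With band
proportions per lane, the cooperativity factor is

$$\tau = \frac{4\,[P_2D]\,[D]}{[PD]^2},$$

the fold by which the first binding event facilitates the second (the
coefficient relating the two dissociation constants; the constants
themselves are never estimated). For independent sites with per-site
occupancy $p$ the proportions are $(p^2,\, 2p(1-p),\, (1-p)^2)$ and
$\tau \equiv 1$ for every $p$ — the identity the test suite checks across
an occupancy grid. Lanes whose monomer band falls below 1% of the probe
are excluded from summaries, since $\tau$ diverges as $[PD] \to 0$.
Groups of per-lane $\tau$ values are compared with a two-sided unpaired
Student t-test (equal variance; Welch available via `var_equal = FALSE`,
since the equal-variance reading of "Student" is a choice).

`simulate_emsa_lanes()` generates lanes from the sequential equilibrium
model ($D \propto 1$, $PD \propto 2[P]/K_{d1}$,
$P_2D \propto \omega ([P]/K_{d1})^2$), for which $\tau = \omega$ holds
identically without noise — an algebraic anchor for the whole module.

## The synthetic SELEX generator

`simulate_selex()` emulates the experiment the pipeline consumes: a
uniform random library of fixed-length reads (default 50,000 × 20-mers,
matching the read lengths and subsample size of the emulated assays), then
per round (i) weighted retention of a fixed fraction of the pool and (ii)
PCR-style multinomial resampling back to constant depth. Retention weight
per read is

$$w = 1 + q\,m + q\,\omega\,d,$$

with $q$ the monomer weight (default 5), $m$ the number of 4-mer site
matches outside planted configurations (site1/site2 pooled, identical
sites counted once), $d$ the number of planted spacer-and-orientation
configurations and $\omega$ the cooperativity multiplier. The defining
property of this parameterization is its independence baseline: at
$\omega = 1$ a planted configuration carries exactly the weight of a
single monomer event, so dimer and monomer categories enrich at the same
expected rate and the enrichment factor centers on 1 — which is what an
"independent binding" ground truth must mean to the statistic that
consumes it. A weight in which the dimer term scales with $q^2$ at
$\omega = 1$ would build a two-fold EF bias into the null. $\omega$ is a
dial on the data-generating truth, not on the pipeline.

Weighted retention uses exponential-key (Efraimidis–Spirakis) sampling
without replacement, equivalent in distribution to sequential weighted
draws but $O(n \log n)$. Amplification noise can be disabled, replacing
multinomial resampling with deterministic replication.

What the generator does **not** emulate: polymerase substitution errors,
sequencing error or quality, sequence-dependent PCR efficiency (a GC-bias
hook exists in concept but the default has none), affinity differences
among non-consensus sites, and carrier effects between reads. Tests
passing on simulated pools therefore demonstrate the pipeline's behavior
under idealized selection statistics, not performance on any particular
real dataset; reproducing the published per-TF numbers requires the
original read archives and Homer motif inputs.

### Operating characteristics

Two properties of the generator's default conditions are worth stating
because they bound what any consumer of its output can see:

* **Founder dispersion.** A random 50,000-read 20-mer library contains on
  average only ~9 reads with a `TAAT`-7bp-`TAAT` configuration (12
  placements × 4⁻⁸ per read). The dimer trajectory is a branching process
  on those founders, so at $\omega = 1$ the *replicate-level* EF scatters
  substantially (standard deviation near 0.45) even though its mean sits
  at 1; the mean-level identity is the meaningful null property, and that
  is what the test suite asserts. At $\omega = 50$ the planted
  configuration sweeps the pool and the EF distribution concentrates well
  above 2.
* **Detection power.** With monomer selection active, any two co-resident
  sites co-enrich and small-spacer configurations additionally overlap
  AT-rich runs, so the spacer tests fire at modest rates even at
  $\omega = 1$; the EF > 2 gate is what keeps the false cooperative-call
  rate at the percent level. Power analysis at the default conditions
  places reliable detection (call rate near 1) at $\omega \gtrsim 20$,
  with partial power between $\omega \approx 2$ and 10. The property tests
  therefore assert ground-truth recovery at $\omega \in \{1, 20, 50\}$.

## Conventions and problem sizes

All coordinates are 0-based, half-open (BED convention), including scan
positions. `N` bases are retained in reads but never match a motif core
position; Biostrings does the matching with IUPAC-degenerate patterns
against literal subjects. Consensus-to-PWM expansion uses an off-consensus
probability of ε = 0.001 with the match threshold midway between the worst
allowed and best disallowed scores, which reproduces mismatch-ball
semantics exactly for 4-mers at any mismatch budget they admit. Scores are
natural-log odds against a uniform background, the background of a
synthetic random library.

The test suite runs simulations at 20,000 reads for unit-level checks and
50,000 reads × 20 replicates for the end-to-end recovery checks, with
10,000-replicate Monte-Carlo loops for the type-I error of the statistical
tests; these sizes keep every distributional claim at three standard
errors or better while completing in minutes.

## Known limitations

* The internal discovery is seed-based and will not find dimer sites whose
  cores are poorly represented by any exact 4-mer pair, spacers outside
  2–12 bp, or spacers with informative content (the screen assumes
  low-information spacers by construction).
* Homodimers only: heterodimer discovery (two different factors) needs
  paired assays and is out of scope.
* The spacer profile inherits COSMO's read-level counting: one read, one
  vote per cell; no weighting by match quality.
* Grubbs assumes approximate normality of per-cell counts; heavily skewed
  count profiles (tiny pools) inflate its nominal significance slightly.
* EF is undefined when monomer sites fail to enrich — a TF that binds
  exclusively as a dimer needs the spacer module alone.
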