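# coopselex

Predicting cooperative homodimer DNA binding from HT-SELEX data.

Most homeodomain transcription factors bind near-identical AT-rich 4-mer
cores (e.g. `TAAT`) as monomers, yet some gain specificity by binding DNA
as cooperative homodimers: two copies on two core sites at a precise
spacer and orientation. `coopselex` detects this from multi-cycle HT-SELEX
read pools using two independent signals:

* **Enrichment factor (EF).** Per cycle, the fraction of reads containing
  the dimer configuration and — after masking dimer-containing reads — the
  fractions containing each core 4-mer are linearized by natural-log fold
  change against the initial library and fitted by OLS. EF is the dimer
  slope over the mean of the two monomer-site slopes:

  `EF = s_dimer / ((s_site1 + s_site2) / 2)`

  EF > 2 means the full configuration was easier to find than its two
  parts independently — the signature of cooperative stabilization.
* **Spacer-length specificity.** Two-site configurations are counted at
  every spacer length and orientation (COSMO-style; one vote per read, a
  configuration equals its reverse complement). A one-sided Grubbs
  max-outlier test on the final-cycle counts and a chi-square test of
  independence between cycle 0 and the final cycle must both reject
  (α = 0.05, Bonferroni over orientations) for a spacer to be called.

A transcription factor is predicted cooperative on a dimer model only when
the dimer screen (core information content > 0.6 bits, core-to-surround IC
ratio ≥ 1.5, abundance ≥ 5% of cycle-4 reads), the EF gate and both spacer
tests all pass. The package also quantifies cooperativity from EMSA band
proportions via

`tau = 4 [P2D][D] / [PD]^2`

(`tau` = 1 for independent binding), and ships a ground-truth synthetic
SELEX/EMSA simulator so the whole pipeline is testable at desk scale.

## Worked example

Simulate a strongly cooperative factor (planted `TAAT`-7bp-`TAAT`,
cooperativity multiplier ω = 50, 50,000 reads × 4 cycles) and run the
predictor end to end, including internal motif discovery:

```r
library(coopselex)

params <- selex_sim_params(library_size = 50000, omega = 50, seed = 1)
cycles <- simulate_selex(params)
fit <- coop_predict(cycles, tf_name = "simTF", seed = 1)
fit
#> Cooperativity prediction for simTF: COOPERATIVE
#>   3 candidate long motif(s), cycles 0,1,2,3,4
#> simTF: COOPERATIVE
#>   dimer TAAT-7N-TAAT | EF 3.13 (>2: yes) | Grubbs p 0.000362 | chi2 p 2.18e-17 | spacer 7 bp
#> simTF: not cooperative
#>   no dimer site detected: motif abundance below threshold
#> simTF: not cooperative
#>   no dimer site detected: core-to-surround IC ratio below threshold; motif abundance below threshold

coef(fit)
#> slope_dimer slope_site1 slope_site2          ef
#>   1.5422258   0.4923075   0.4923075   3.1326476
```

Reading the output: discovery proposed three long motifs; the top one
passed all three screen criteria and reduced to the planted
`TAAT`-7bp-`TAAT` model. Its dimer configuration enriched at 1.54 ln-units
per cycle versus 0.49 for the masked monomer sites (EF 3.13 > 2), and only
the 7-bp spacer cell was a significant outlier whose proportion shifted
between cycle 0 and cycle 4 — so the factor is called cooperative with a
7-bp spacer. The two rejected motifs show the screen doing its job on
shifted/over-amplified variants. `summary(fit)` returns the table as a
data frame, `plot(fit)` draws the enrichment curves and spacer profile,
and `write_coop_report(fit, dir)` emits deterministic JSON/TSV reports.

The EMSA side, on simulated lanes from the two-step equilibrium model:

```r
lanes <- simulate_emsa_lanes(kd1 = 10, omega = 100,
                             protein_concs = c(5, 10, 20, 40))
s <- summarize_tau(lanes)
#> mean tau = 100.0 (n = 6)   (lanes with monomer band < 1% excluded)
compare_tau(c(180, 195, 192), c(1.1, 0.9, 1.2))$p   # Student t, two-sided
```

A thin command-line front end is installed at `inst/cli/coopselex.R`
(subcommands `simulate`, `run`, `cosmo`, `tau`); real HT-SELEX pools come
in through `read_cycle_reads()` (FASTA/FASTQ), Homer motifs through
`read_homer_motif()`, and peak analyses through
`extract_region_sequences()` + `count_spacers_in_regions()`.

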