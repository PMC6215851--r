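# microneutral

Cross-scale neutrality testing for microbial community assembly.

Is a microbial community — say, the gut microbiome of lean and obese hosts —
assembled by *stochastic neutral* processes (random birth, death and
immigration of ecologically equivalent taxa) or by *deterministic*
host/niche effects? `microneutral` answers this question from OTU count
tables at two complementary scales:

* **Community scale (discrete model).** Each sample's species-abundance
  distribution D = (n₁, …, n_S) is scored with the dispersal-limited
  neutral sampling formula

  P(D | θ, m, J) = J! / (∏ᵢ nᵢ ∏ⱼ φⱼ!) · θ^S / (I)_J · Σ_{A=S}^{J} K(D, A) I^A / (θ)_A,

  where θ is the fundamental biodiversity number, m = I/(I + J − 1) the
  immigration probability, A the number of immigrant ancestors and K(D, A)
  an ancestry weight built from unsigned Stirling numbers of the first
  kind. The package fits (θ, m) by maximum likelihood, simulates neutral
  communities by the exact sequential urn, and runs the *exact neutrality
  test*: the fitted sample's log-likelihood L₀ is compared with the mean
  log-likelihood L₁ of 100 simulated neutral communities through the
  deviation q = 2 |ln L₁ − ln L₀|, referred to a χ²(1) upper tail; p > 0.05
  means the whole community is consistent with neutral assembly.

* **Species scale (continuous model).** The local community of N_T
  individuals is reassembled by a death–immigration–reproduction cycle
  whose stationary relative abundance of taxon i follows
  Beta(N_T m pᵢ, N_T m (1 − pᵢ)), with pᵢ the taxon's abundance in the
  source pool. The single migration parameter m is fitted by least squares
  to the observed occurrence frequencies xᵢ = n/N across samples, and every
  taxon is classified neutral / above / below against a 95% prediction
  interval around its model-predicted occurrence frequency. Balanced
  resampled designs (e.g. 50 samples per group, 30 repeats) aggregate the
  per-repeat fits.

Synthetic-data generators with known ground truth (neutral by either route,
and niche-structured with tunable selection strength and group-level
composition shifts) make every stage testable without external data, and a
pipeline orchestrates both scales into per-sample (`table1.tsv`) and
per-design (`table2.tsv`) reports.

## Worked example

```r
library(microneutral)

# a two-group neutral dataset with known truth (theta = 30, m = 0.15)
des <- synthetic_design(n_groups = 2, samples_per_group = 30, J = 1000,
                        mode = "sloan_neutral", theta = 30, m = 0.15, seed = 1)
dat <- generate_neutral_dataset(des)
dat$table
#> OTU table: 60 samples x 203 taxa, 60,726 reads total

# community scale: exact neutrality test of one sample
sad <- sample_to_sad(dat$table, "s1")
exact_neutrality_test(sad, n_sim = 100, seed = 7)
#> Exact neutrality test: logL0 = -55.872, logL1 = -57.176 (n_sim = 100)
#>   q = 2.609, p = 0.1063 -> neutral (pass)

# species scale: occurrence-frequency fit within the lean group
lean <- dat$groups$sample_id[dat$groups$group == "lean"]
st  <- occurrence_stats(dat$table, lean, lean)
fit_sloan(st$p, st$x, st$N_T, st$n_dest,
          detection_threshold = st$detection_threshold)
#> Continuous neutral-model fit: m = 0.1416, R2 = 0.969, N_T = 1010, 179 taxa
#>   neutral 84.9% | above 8.4% | below 6.7%  (d = 0.00099, wilson CI)

# balanced resampled cross-group design
resampled_sloan_analysis(dat$table, dat$groups, "lean", "obese",
                         n_per_group = 25, n_repeats = 10, seed = 3)
#> lean -> obese (10 repeats x 25 samples/group):
#>   N = 1014, m = 0.1229 +- 0.0069, R2 = 0.926, neutral 68.8% +- 1.7%
```

Reading the output: the exact test finds sample `s1` no less likely than
typical neutral replicates simulated at its own fitted (θ̂, m̂), so it
passes (p > 0.05). The species-scale fit recovers the generating migration
rate (m̂ = 0.142 vs truth 0.15) with a tight occurrence curve (R² = 0.97),
and ~85% of taxa fall inside their neutral prediction intervals. The
cross-group design (lean as source pool, obese as destination) shows a
lower neutral percentage — occurrence in one group is predicted less well
from the other group's abundances, as expected when the draw of source and
destination samples differs.

A shell entry point for both the pipeline and the simulators is installed
at `inst/scripts/neutrality-pipeline.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("scripts/neutrality-pipeline.R",
                                       package = "microneutral"))')" \
  run --otu otu.tsv --groups groups.tsv --out-dir results --seed 1
```

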