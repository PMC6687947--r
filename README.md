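# rbmycnv

Copy-number variation analysis of the human *RBMY1* gene family — read-depth
copy-number estimation, fibre-FISH calibration, phylogenetic mutation-rate
estimation, selection tests and droplet digital PCR quantification.

## The problem

*RBMY1* is a multi-copy, testis-expressed gene family on the human Y
chromosome: six active copies in four clusters in the reference sequence,
with extensive copy-number variation (roughly 3–13 copies) in worldwide
populations. Because the copies are >98% identical, short reads mis-map
freely among them, and standard per-locus genotyping fails. This package
implements the full analysis chain for such a gene family:

1. **Read-depth copy number** (`load_depth_windows`, `region_depth_ratio`,
   `rough_copy_number`): mean depth in 5 kb windows over the gene clusters,
   normalized by a nearby single-copy region. Under the read-pooling model
   the reference footprint holds 7 copy-equivalents (6 genes + pseudogenes
   worth ~1), so a ratio change of 1/7 ≈ 0.14 equals one gene copy:
   `CN = round(ratio × 7 − 1)`.
2. **Calibration** (`fit_ols`, `predict_cn`, `split_validation`): ordinary
   least squares against fibre-FISH gold-standard counts (14 validated
   samples ship with the package, `gold_standard_table()`).
3. **Mutation rate from a phylogeny** (`min_event_labeling`,
   `cn_mutation_rate`): unit-cost parsimony counts the minimum number of
   copy-number change events on a Y-SNV phylogeny (any change = one event);
   SNV branch lengths convert to generations through the molecular clock
   (0.76 × 10⁻⁹ /bp/yr over 10.3 Mb, 30-yr generations ⇒ 4.26
   generations/SNV), giving events per father-to-son transmission:
   r = K·μ·L·g / S.
4. **Selection tests** (`direction_bias_test`, `simulate_neutral`,
   `variance_percentile_test`): exact binomial test of increase vs decrease
   event counts, and a neutral Monte-Carlo null that scatters the inferred
   event set over the tree in proportion to branch length and compares the
   across-tip copy-number variance against it.
5. **ddPCR quantification** (`droplet_concentration`, `assay_copy_number`,
   `ddpcr_quant`): Poisson inversion λ = −ln(1 − positives/total) per
   channel, copy number as the target/reference concentration ratio, the
   0.8-copy replicate-discrepancy rule, and totals as T-assay + C-assay.
6. **Synthetic data with ground truth** (`simulate_tree`, `evolve_cn`,
   `emulate_depth`, `emulate_droplets`, `make_father_son`, `simulate_all`)
   for parameter-recovery testing of every stage.

## Worked example

```r
library(rbmycnv)

# tree-based mutation rate from the genome-wide event and SNV counts
cn_mutation_rate(562, 60084)
#> CN mutation rate: 562 events / 255851 generations (60084 SNVs)
#>   rate = 0.0022 per transmission (95% CI 0.00194 - 0.00249)

# father-son transmissions: 1 mutation in 77, exact Clopper-Pearson CI
unlist(transmission_rate_ci(1, 77)[c("point", "ci_low", "ci_high")])
#>        point       ci_low      ci_high
#> 0.0129870130 0.0003287487 0.0702470606

# ddPCR totals regressed on fibre-FISH gold standards (14 samples)
g <- gold_standard_table()
fit_ols(g$total_fibre_fish, g$cn_ddpcr)
#> OLS calibration: y = 0.9582 x + 0.1943 (R^2 = 0.981, n = 14)

# depth ratio -> rough copy number at the observed extremes
rough_copy_number(c(0.62, 1.89))
#> [1]  3 12
```

The rate estimate reads: 562 change events over a total branch length of
255 851 generations is 2.2 × 10⁻³ mutations per father-to-son transmission,
with the CI obtained by substituting the SNV-rate CI bounds. The OLS line
shows ddPCR and fibre-FISH copy numbers agree to within a copy across the
validated range (5–13 copies).

An end-to-end run on synthetic data:

```r
simulate_all("bundle", seed = 7, n_tips = 100)
report <- run_pipeline(run_config(
  tree = "bundle/tree.nwk", cn_states = "bundle/cn.tsv",
  depth_dir = "bundle/depth", wells = "bundle/wells.csv",
  trios = "bundle/trios.tsv", out_dir = "bundle/run", seed = 7))
```

There is also a CLI: `Rscript -e 'rbmycnv::rbmycnv_cli()' rate --events 562
--snvs 60084`.

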