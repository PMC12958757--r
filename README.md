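# radspectra

Germline variant spectrum comparison for radiation-exposed cohorts.

Populations on high natural background radiation (HLNRA) coasts receive
chronic gamma doses ~30x normal (NLNRA) levels. `radspectra` implements the
downstream analysis used to ask whether such exposure leaves a germline
imprint in small matched cohorts:

* **Consensus filtering** — per-caller GATK-style hard filters (SNVs:
  QD < 2, QUAL < 30, SOR > 3, FS > 60, MQ < 40, MQRankSum < -12.5,
  ReadPosRankSum < -8; indels: QD < 2, QUAL < 30, FS > 200,
  ReadPosRankSum < -20, alt support > 20 reads), two-caller intersection on
  normalized `(chrom, pos, ref, alt)` keys, and removal of polymorphisms
  with minor allele frequency > 1% in either of two population panels.
* **Mutation spectrum** — pyrimidine-normalized six-class substitution
  spectra (C>A, C>G, C>T, T>A, T>C, T>G), CpG vs non-CpG context of C>T
  transitions resolved against the reference sequence, and 5-mer context
  labels such as `CA[C>T]GG`.
* **Group statistics** — per-individual counts; group-unique variants
  (carried by >= 2 individuals of one group, none of the other); two-sided
  Mann-Whitney U with complete enumeration of the exact null for small
  tie-free samples; Benjamini-Hochberg FDR; PCA over context matrices;
  variants per megabase.
* **Consequence triage** — protein-affecting mutations (PAM: missense /
  stop gained / frameshift / in-frame deletion / stop loss / splice site
  with HIGH or MODERATE impact), REVEL > 0.5 pathogenic candidates, ALoFT
  high-confidence truncations, gene-set Venn partitions and
  cancer-predisposition list overlap.
* **Dosimetry** — annual dose = 0.0767 x occupancy-weighted gamma dose
  rate (mGy/year).
* **Synthetic cohorts** — a generator that emits a reference contig
  (Markov chain with exact GC and CpG density), per-individual two-caller
  VCFs with clean/artifact quality mixtures, frequency panels and
  VEP-style consequence tables, with a plantable C>T-at-CpG enrichment and
  full truth labels, so every stage is testable without restricted data.

## Worked example

Simulate a 6 vs 6 cohort with a 3x C>T-at-CpG enrichment planted in the
exposed group and run the full pipeline:

```r
library(radspectra)

cfg <- as_pipeline_config(list(
  ref_length = 300000, n_variants_per_individual = 1000,
  n_indels_per_individual = 100, common_fraction = 0.5,
  cpg_ct_multiplier_by_group = c(NLNRA = 1, HLNRA = 3),
  seed = 7, target_size_mb = 0.3))

report <- run_pipeline(cfg, "demo_run")

report$per_group_counts
#>   group mean_snv median_snv mean_indel median_indel
#> 1 HLNRA 438.1667      439.5   40.83333         41.5
#> 2 NLNRA 438.0000      442.0   40.66667         41.0

report$cpg_ct_comparison
#>           mode statistic     p_value
#> 1          all         0 0.004998125
#> 2 group_unique         0 0.004998125

round(unlist(report$mutation_type_fractions), 3)
#>   C>A:CpG   C>G:CpG   C>T:CpG   T>A:CpG   T>C:CpG   T>G:CpG C>A:other
#>     0.000     0.000     0.251     0.000     0.000     0.000     0.074
#> C>G:other C>T:other T>A:other T>C:other T>G:other
#>     0.064     0.295     0.054     0.200     0.063
```

Reading the output: total rare-variant burden is indistinguishable between
groups (~438 SNVs and ~41 indels per individual in both), as expected —
the planted effect changes *where* C>T mutations fall, not how many
variants there are.  The C>T class dominates the spectrum (~55% combined),
and with the 3x enrichment the exposed group's C>T-at-CpG counts separate
completely from the control group's, so the two-sided exact Mann-Whitney
p-value reaches 0.005 in both the all-variants and group-unique modes.
Under the default null configuration (both multipliers 1) the same
comparisons are non-significant.

`demo_run/` also contains the filtered variant table, per-stage filter
log, raw and row-normalized spectrum matrices, PCA scores, the PAM and
top-REVEL tables, `report.json`, and a `manifest.json` with per-file
checksums; two runs with the same config and seed are byte-identical.

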