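---
title: "radspectra: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{radspectra: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## The problem this package addresses

Populations living on high natural background radiation (HLNRA) coasts
receive chronic gamma doses tens of times above normal (NLNRA) levels.  A
standard way to ask whether that exposure leaves a germline imprint is to
compare rare variants between small matched cohorts: call variants per
individual with two independent callers, keep only high-quality consensus
calls, discard common polymorphisms, and then compare the groups on summary
statistics — per-individual counts, the six-class substitution spectrum, the
CpG context of C>T transitions, 5-mer sequence context, and the burden of
protein-affecting and predicted-pathogenic mutations.

`radspectra` implements that downstream comparison as a reusable, tested
pipeline, together with a synthetic cohort generator so that every stage can
be validated against known truth.  The generator is first-class: raw cohort
data of this kind are typically not publicly deposited, so the package's
evidence of correctness is property-based, on simulated cohorts whose
generative parameters mirror the study design the analysis was built for
(two groups of 6 male individuals, ~29,000 raw variants each collapsing to
~1,300 rare SNVs and ~145 rare indels after filtering, a spectrum with
roughly half C>T).

## The filtering cascade

Variants flow through a fixed, logged cascade, one individual at a time:

1. **Per-caller hard filters.**  SNVs fail on QD < 2.0, QUAL < 30.0,
   SOR > 3.0, FS > 60.0, MQ < 40.0, MQRankSum < -12.5 or
   ReadPosRankSum < -8.0; indels fail on QD < 2.0, QUAL < 30.0, FS > 200.0,
   ReadPosRankSum < -20.0, or alternate-allele support of 20 reads or fewer
   (the "greater than 20" rule is strict).  An absent annotation never fails
   a filter: these are GATK-style rules that only fire on present values.
   The Strelka-like caller's own non-PASS records are dropped at read time.
2. **Two-caller intersection** on the normalized `(chrom, pos, ref, alt)`
   key.  Multiallelic records are split per alternate allele first, and
   indel alleles are reduced to their minimal left-aligned representation
   (shared suffix trimmed, then shared prefix, anchor base kept) so the
   key-based intersection is well defined.  When both callers report a key
   the surviving record carries the second caller's metrics — no metric is
   reused downstream, so any single consistent source suffices.
3. **Polymorphism removal.**  A variant is removed iff its minor allele
   frequency exceeds 1% in *at least one* of the two population panels (the
   stricter reading of "overlapped ... with MAF > 1%"); a key absent from
   both panels is treated as rare and retained; MAF exactly at the
   threshold is retained.

Every removed variant is returned with the stage and first violated rule,
and the per-stage in/out counts are logged, so conservation (input =
retained + removed) is checkable at every stage.

## Spectrum and sequence context

Substitutions are pyrimidine-normalized: when the reference base is a
purine, both alleles are complemented, collapsing the twelve substitutions
into the conventional six classes (C>A, C>G, C>T, T>A, T>C, T>G).  CpG
status is computed from the reference sequence itself, not from annotation
tracks: a site is CpG when, on the strand where the mutated base reads as
C, the 3' neighbor is G.  k-mer context (default k = 5) takes the flanking
reference bases around the variant, reverse-complemented as needed so the
central base is a pyrimidine, and renders labels such as `CA[C>T]GG`.
Positions lacking a full flank are excluded and counted, never padded —
padding would fabricate context.  Spectrum matrices are per-sample count
matrices over class-by-context categories; a row-normalized (frequency)
view is emitted alongside raw counts because published heatmaps are
ambiguous about which is shown.

## Group statistics

The unit of statistical comparison is the per-individual count (6 vs 6);
only per-individual units make a two-group rank test well posed.  The
Mann-Whitney test enumerates the complete null distribution (all
`choose(12, 6)` labelings) whenever both groups have at most 8 tie-free
observations — the realistic code path at this design — and otherwise uses
the normal approximation with tie and continuity correction.  The
two-sided p doubles the smaller tail, capped at 1.  "FDR adjusted" is
implemented as the Benjamini-Hochberg step-up rule.  PCA on context
matrices defaults to centered, unscaled frequency rows (frequencies are
already commensurate); unit-variance scaling is a flag.

The headline contrast, `compare_cpg_ct()`, is a composition: optionally
restrict to group-unique variants (carried by at least two individuals of
one group and none of the other), partition each sample's SNVs into C>T at
CpG / C>T elsewhere / other, and test the per-sample C>T-at-CpG counts.
Both the all-variants and group-unique modes are always reported side by
side, mirroring the published contrast in which only the group-unique
comparison reaches significance.

## The synthetic cohort generator

**Reference.**  A single synthetic contig ("chrS1", 1-based coordinates as
in VCF) is drawn from a first-order Markov chain over A/C/G/T.  The chain's
transition matrix is solved in closed form so that the stationary base
composition equals the requested GC fraction *exactly* and the stationary
CpG dinucleotide density equals the requested `cpg_rate` exactly.  This
matters because vertebrate genomes are CpG-depleted: independent sampling
at GC 0.41 would give ~4x the realistic CpG density, and no post-hoc
patching scheme hits both targets cleanly.  Defaults are GC 0.41 and CpG
density 0.01, close to the human genome.

**Variants.**  Each SNV is drawn from a seven-category spectrum: the six
classes with C>T split into CpG/other context, because the CpG axis is
where the plantable group effect acts.  The exposed group's C>T-at-CpG
weight is multiplied by a configurable enrichment (1 = null) and the vector
renormalized, so planted truth proportions are known in closed form.  Sites
are sampled without replacement across the entire cohort; recurrence across
individuals happens only through a per-group shared pool from which a
configurable fraction of each individual's variants is drawn.  Group-unique
truth is therefore exact: a variant carried by two or more individuals of
one group is never present in the other.  Non-C>T substitutions are placed
at non-CpG cytosines, so the planted CpG signal is carried entirely by the
C>T class — the only class whose CpG partition the analysis uses.  Indels
(1-10 bp, per-individual) never enter spectrum truth.

**Exact planting in the shared pool.**  Pool category counts are allocated
by largest-remainder quota on the group weights; only their order and
genomic positions are random.  This is deliberate: if the pool composition
were itself multinomially sampled, its realized C>T-at-CpG fraction would
act as a group-level random effect shared by every individual of the
group.  Per-individual counts of group-unique variants would then be
strongly correlated within groups, and the rank test — whose null assumes
exchangeability across all twelve individuals — would reject far too often
under the null.  With composition planted exactly, the generator's null is
the test's null, and the measured type-I error sits at the nominal level.
This is also the honest reading of "planting" an effect: the spectrum is a
parameter of the simulation, not a latent draw.

A corollary worth stating: on *real* cohorts, shared haplotype structure
can reintroduce exactly that within-group correlation, and the
group-unique comparison inherits it.  Passing calibration on simulated
cohorts shows the statistical machinery is sound under the stated model;
it does not certify the model against population structure, which the
generator deliberately does not simulate (no linkage, no inheritance, no
population history).

**Caller emulation.**  Each truth variant appears in both simulated callers
with probability `caller_concordance`, else in one chosen uniformly.
Quality annotations come from two explicit mixtures: "clean" draws always
satisfy every hard filter; "artifact" draws (fraction `artifact_fraction`)
push exactly one randomly chosen metric into its failing range, so every
filter branch fires in tests.  Artifact records also carry a non-PASS
FILTER in the Strelka-like file.  Rank-sum annotations are genuinely
missing for a share of clean records, exercising the absent-metric rule.
Frequency panels give a `common_fraction` of keys MAF > 1% in at least one
panel; half of the rare keys are absent from both.  The consequence table
assigns genes from a 20-kb window partition of the contig, consequence
terms from class-appropriate mixtures with consistent impact levels, REVEL
scores to missense records (above 0.5 with the configured pathogenic
fraction), ALoFT confidence to truncating records, and a milder second
transcript record to ~10% of coding variants to exercise the severity
collapse.

**Dispersion.**  The study reports only medians and means of per-individual
counts, not a variance model, so per-individual counts are exact by
default with a negative-binomial `dispersion` knob rather than an asserted
variance.

## Consequence triage

A record is a protein-affecting mutation (PAM) iff its term is missense,
stop gained, frameshift, in-frame deletion, stop loss, or a splice
donor/acceptor *and* its predicted impact is HIGH or MODERATE.  Unknown
terms warn and classify as non-PAM rather than crash — annotation
vocabularies drift.  REVEL > 0.5 (strict; a score exactly at 0.5 is
excluded) flags pathogenic missense candidates, ranked by score; ALoFT
keeps only high-confidence truncations.  When a variant has several
transcript records, the region distribution uses the most severe term
under a documented ranking (splice/stop/frameshift > in-frame > missense >
synonymous > intron > ncRNA/regulatory); gene-level sets keep all records.
Gene symbols are compared case-insensitively after whitespace stripping,
with no alias resolution (alias mapping would need an external database).
The shipped cancer-predisposition list is a small synthetic illustration,
clearly labelled as such; real analyses should supply a curated list.

## Dosimetry

Annual absorbed dose is `0.0767 x (occupancy_indoor x indoor_rate +
(1 - occupancy_indoor) x outdoor_rate)` in mGy/year, where 0.0767 is the
published survey conversion factor (the standard 0.876 air-kerma
coefficient times 8,760 hours per year, scaled by 1e-5 and rounded to four
decimals).  Occupancy factors are per-individual inputs, not constants:
age- and sex-specific values come from survey literature and are not
reproduced here.

## Parameters that matter

| parameter | default | meaning |
|---|---|---|
| `n_per_group` | 6 | individuals per group |
| `ref_length` | 5e6 | synthetic contig length (bases) |
| `gc_fraction` / `cpg_rate` | 0.41 / 0.01 | reference composition targets |
| `n_variants_per_individual` | 29,000 | raw SNVs per individual |
| `common_fraction` | 0.955 | keys with panel MAF > 1% (removed later) |
| `base_spectrum` | C>T = 0.49, T>C = 0.23, ... | six-class weights |
| `ct_cpg_fraction` | 0.30 | share of C>T at CpG under the null |
| `cpg_ct_multiplier_by_group` | 1, 1 | planted CpG C>T enrichment |
| `shared_variant_fraction` | 0.40 | drawn from the group pool |
| `caller_concordance` | 0.95 | probability a variant is in both callers |
| `artifact_fraction` | 0.10 | records drawn from the failing mixture |
| hard-filter thresholds | QD 2, QUAL 30, SOR 3, FS 60/200, MQ 40, MQRankSum -12.5, ReadPosRankSum -8/-20, support 20 | see cascade above |
| `maf` | 0.01 | polymorphism cutoff |
| `min_carriers` | 2 | group-unique carrier threshold |
| `kmer_k` | 5 | context width |
| `target_size_mb` | config input | per-megabase denominator (never a constant: the target size of a capture design is a property of the data, not of the method) |

`ct_cpg_fraction = 0.30` is a package choice: the share of germline C>T
occurring at CpG sites is not published for this design, and 0.30 is a
realistic value for CpG-depleted genomes with strongly elevated
deamination rates at methylated CpGs.  It was chosen once and is a config
knob, not a fitted quantity.

## Validation study sizes

The test suite validates at sizes chosen to make binomial/enumeration
arguments sharp while keeping the suite quick: module tests run on 12
individuals x 600 variants; spectrum conservation and strand symmetry on
5,000 SNVs; exact Mann-Whitney against a complete-enumeration oracle on
500 random tie-free instances (n <= 6 per arm); BH against an independent
reference on 1,000 random vectors; power of the group-unique CpG C>T
comparison on 100 simulated cohorts of 6 vs 6 x 5,000 variants with a 3x
planted enrichment (rejection rate 1.00 in the shipped configuration), and
type-I error on 200 null cohorts (rejection at nominal 5%).  End-to-end
determinism is checked by checksum equality of two full pipeline runs
under one seed.

## Known limitations

* No linkage, population structure, inheritance, or sequencing-error
  model; caller internals are emulated only at the level of concordance
  and annotation mixtures.
* The group-unique comparison assumes exchangeable per-individual counts;
  see the exact-planting discussion above for why real haplotype sharing
  can violate this.
* Gene symbols are matched literally (case-insensitive); no alias
  resolution.
* The per-megabase denominator and occupancy factors must be supplied by
  the user; reported doses are illustrative otherwise.
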