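test_that("reference generator hits composition targets and is seeded", {
  ref <- generate_reference(50000, 0.41, 0.01, 7)
  expect_equal(nchar(ref$sequence), 50000)
  cr <- charToRaw(ref$sequence)
  gc <- mean(cr %in% charToRaw("GC"))
  expect_lt(abs(gc - 0.41), 0.02)
  cpg <- sum(cr[-length(cr)] == charToRaw("C") & cr[-1] == charToRaw("G"))
  expect_gte(cpg, 400)
  expect_lte(cpg, 600)

  # seeded determinism
  r1 <- generate_reference(10000, 0.41, 0.01, 7)
  r2 <- generate_reference(10000, 0.41, 0.01, 7)
  expect_identical(r1$sequence, r2$sequence)
  r3 <- generate_reference(10000, 0.41, 0.01, 8)
  expect_false(identical(r1$sequence, r3$sequence))

  # zero GC forces an AT-only sequence
  at <- generate_reference(10000, 0, 0, 3)
  expect_true(all(strsplit(at$sequence, "")[[1]] %in% c("A", "T")))
})

test_that("reference generator rejects infeasible configurations", {
  expect_error(generate_reference(500, 0.4, 0.01, 1),
               class = "radspectra_invalid_config")
  expect_error(generate_reference(10000, 0.4, 0.25, 1),
               class = "radspectra_invalid_config")
})

test_that("simulation config validates its invariants", {
  expect_error(simulation_config(base_spectrum = c("C>A" = 0.5, "C>G" = 0.5,
                                                   "C>T" = 0.1, "T>A" = 0,
                                                   "T>C" = 0, "T>G" = 0)),
               class = "radspectra_invalid_config")
  expect_error(simulation_config(common_fraction = 1.2),
               class = "radspectra_invalid_config")
  expect_error(simulation_config(cpg_ct_multiplier_by_group =
                                   c(NLNRA = 0, HLNRA = 1)),
               class = "radspectra_invalid_config")
  expect_error(simulation_config(ref_length = 10000,
                                 n_variants_per_individual = 5000),
               class = "radspectra_invalid_config")
})

test_that("simulated variants match the reference and recorded truth", {
  fx <- shared_fixture()
  v <- fx$cohort$variants
  expect_true(all(substring(fx$ref$sequence, v$pos,
                            v$pos + nchar(v$ref) - 1L) == v$ref))
  # CpG truth labels agree with the reference-derived context
  snv <- v[v$vclass == "SNV", ]
  ctx <- cpg_context(fx$ref, snv$chrom, snv$pos, snv$ref)
  expect_identical(ctx == "CpG", snv$is_cpg)
  # class truth agrees with pyrimidine-normalized classification
  expect_identical(classify_substitution(snv$ref, snv$alt), snv$class6)
})

test_that("planted spectrum converges and the CpG multiplier orders groups", {
  fx <- shared_fixture()
  snv <- fx$cohort$variants[fx$cohort$variants$vclass == "SNV", ]
  for (g in fx$cfg$groups) {
    w <- fx$cohort$truth$weights_by_group[[g]]
    cat7 <- snv$category[snv$group == g]
    n <- length(cat7)
    emp <- table(factor(cat7, levels = names(w))) / n
    se <- sqrt(w * (1 - w) / n)
    expect_true(all(abs(as.numeric(emp) - w) <= 3 * se + 1e-12),
                label = sprintf("spectrum convergence for %s", g))
  }
  frac <- tapply(snv$is_cpg, snv$group, mean)
  expect_gt(frac[["HLNRA"]], frac[["NLNRA"]])
})

test_that("null multipliers give no group difference in CpG C>T truth", {
  cfg <- small_config(seed = 21L)
  ref <- generate_reference(cfg$ref_length, cfg$gc_fraction, cfg$cpg_rate,
                            cfg$seed)
  co <- simulate_cohort(ref, cfg)
  snv <- co$variants[co$variants$vclass == "SNV", ]
  frac <- tapply(snv$is_cpg, snv$group, mean)
  n <- min(table(snv$group))
  p0 <- co$truth$cpg_ct_fraction_by_group[[1]]
  se <- sqrt(2 * p0 * (1 - p0) / n)
  expect_lt(abs(frac[[1]] - frac[[2]]), 3 * se)
})

test_that("shared pool controls cross-individual recurrence", {
  cfg <- small_config(seed = 31L, shared_variant_fraction = 0)
  ref <- generate_reference(cfg$ref_length, cfg$gc_fraction, cfg$cpg_rate,
                            cfg$seed)
  co <- simulate_cohort(ref, cfg)
  keys <- variant_key(co$variants)
  expect_false(any(duplicated(keys)))

  fx <- shared_fixture()   # shared_variant_fraction 0.40
  cv <- cohort_variants(fx$cohort$variants, fx$cohort$samples)
  multi <- cv[cv$n_NLNRA + cv$n_HLNRA >= 2L, ]
  expect_gt(nrow(multi), 0)
  # without-replacement sampling + disjoint pools: never in both groups
  expect_true(all(multi$n_NLNRA == 0L | multi$n_HLNRA == 0L))
})

test_that("infeasible CpG demand raises an explicit simulation error", {
  cfg <- simulation_config(ref_length = 20000, n_variants_per_individual = 2000,
                           n_indels_per_individual = 0,
                           cpg_ct_multiplier_by_group = c(NLNRA = 8, HLNRA = 8),
                           seed = 5)
  ref <- generate_reference(cfg$ref_length, cfg$gc_fraction, 0.001, cfg$seed)
  expect_error(simulate_cohort(ref, cfg), class = "radspectra_simulation_error")
})

test_that("caller concordance governs the shared key fraction", {
  fx <- shared_fixture()
  dir0 <- withr::local_tempdir()
  ev1 <- emit_caller_vcfs(fx$cohort, file.path(dir0, "c1"), concordance = 1)
  expect_true(all(ev1$presence$in_a & ev1$presence$in_b))
  ev0 <- emit_caller_vcfs(fx$cohort, file.path(dir0, "c0"), concordance = 0)
  expect_false(any(ev0$presence$in_a & ev0$presence$in_b))
  ev8 <- emit_caller_vcfs(fx$cohort, file.path(dir0, "c8"), concordance = 0.8)
  shared <- mean(ev8$presence$in_a & ev8$presence$in_b)
  expect_gt(shared, 0.78)
  expect_lt(shared, 0.82)
})

test_that("emitted VCFs round-trip through read_vcf with truth keys", {
  fx <- shared_fixture()
  dir0 <- withr::local_tempdir()
  ev <- emit_caller_vcfs(fx$cohort, dir0)
  sm <- names(fx$cohort$samples)[1]
  va <- read_vcf(file.path(dir0, sprintf("%s.caller_a.vcf", sm)), sm, "caller_a")
  vb <- read_vcf(file.path(dir0, sprintf("%s.caller_b.vcf", sm)), sm, "caller_b")
  pres <- ev$presence[ev$presence$sample == sm, ]
  truth_v <- fx$cohort$variants[fx$cohort$variants$sample == sm, ]
  art <- truth_v$artifact[match(pres$key, variant_key(truth_v))]
  # caller_a drops its own non-PASS (artifact) records at read time
  expect_setequal(variant_key(va), pres$key[pres$in_a & !art])
  expect_setequal(variant_key(vb), pres$key[pres$in_b])
  # clean records pass the hard filters in full
  vsnv <- vb[vb$vclass == "SNV", ]
  clean <- !truth_v$artifact[match(variant_key(vsnv), variant_key(truth_v))]
  expect_true(all(snv_hard_filter(vsnv)$pass[clean]))
})

test_that("frequency panel plants the configured common fraction", {
  fx <- shared_fixture()
  pan <- make_frequency_panel(fx$cohort, common_fraction = 0.9)
  keys <- unique(variant_key(fx$cohort$variants))
  n <- length(keys)
  flt <- filter_polymorphisms(
    fx$cohort$variants[!duplicated(variant_key(fx$cohort$variants)), ],
    pan$panel)
  removed_frac <- nrow(flt$removed) / n
  se <- sqrt(0.9 * 0.1 / n)
  expect_lt(abs(removed_frac - 0.9), 4 * se)
  # removal agrees with the recorded truth labels exactly
  expect_setequal(variant_key(flt$removed), pan$truth$key[pan$truth$is_common])

  pan0 <- make_frequency_panel(fx$cohort, common_fraction = 0)
  flt0 <- filter_polymorphisms(fx$cohort$variants, pan0$panel)
  expect_equal(nrow(flt0$removed), 0)
  pan1 <- make_frequency_panel(fx$cohort, common_fraction = 1)
  flt1 <- filter_polymorphisms(fx$cohort$variants, pan1$panel)
  expect_equal(nrow(flt1$retained), 0)
})

test_that("consequence table respects configured fractions and consistency", {
  fx <- shared_fixture()
  csq <- make_consequence_table(fx$cohort)
  tab <- csq$table
  # impact consistent with term everywhere
  imp_map <- c(missense = "MODERATE", inframe_deletion = "MODERATE",
               stop_gained = "HIGH", stop_lost = "HIGH", frameshift = "HIGH",
               splice_donor = "HIGH", splice_acceptor = "HIGH",
               synonymous = "LOW", intron = "MODIFIER",
               regulatory = "MODIFIER", ncRNA = "MODIFIER")
  expect_true(all(tab$Vep_impact == imp_map[tab$Vep_consequence]))
  # REVEL present only on missense records
  expect_true(all(tab$Vep_consequence[!is.na(tab$Revel_score)] == "missense"))
  # pathogenic-missense fraction within binomial error of the config (0.1)
  mis <- tab[tab$Vep_consequence == "missense", ]
  m <- nrow(mis)
  npath <- sum(mis$Revel_score > 0.5)
  expect_lt(abs(npath / m - 0.1), 4 * sqrt(0.1 * 0.9 / m))
  # ALoFT confined to truncating terms
  hc <- tab$Aloft == "high_confidence_truncation"
  expect_true(all(tab$Vep_consequence[hc] %in% c("stop_gained", "frameshift")))
})

test_that("study directory emission is deterministic per seed", {
  cfg <- simulation_config(ref_length = 60000, n_variants_per_individual = 150L,
                           n_indels_per_individual = 15L, n_per_group = 2L,
                           seed = 42L)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  f1 <- list.files(d1, recursive = TRUE)
  expect_setequal(f1, list.files(d2, recursive = TRUE))
  for (f in f1) {
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = sprintf("checksum of %s", f))
  }
})
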