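test_that("read_vcf splits multiallelics, normalizes alleles, drops non-PASS", {
  path <- withr::local_tempfile(fileext = ".vcf")
  write_toy_vcf(path, "S1", c(
    toy_record(100, "A", "C"),
    "chrS1\t200\t.\tG\tA,T\t90\tPASS\tQD=8;MQ=55\tGT:AD\t0/1:30,12,9",
    toy_record(300, "C", "T", filter = "LowQual"),
    toy_record(400, "ATT", "AT"),          # right-trim then anchor: pos 400 AT>A
    toy_record(500, "TGG", "TG")
  ))
  v <- read_vcf(path, "S1", "caller_a")
  expect_equal(nrow(v), 5L)  # multiallelic split into 2, non-PASS dropped
  m <- v[v$pos == 200, ]
  expect_equal(nrow(m), 2L)
  expect_setequal(m$alt, c("A", "T"))
  expect_equal(m$support_reads[m$alt == "A"], 12L)
  expect_equal(m$support_reads[m$alt == "T"], 9L)
  expect_false(any(v$pos == 300))
  expect_equal(v$ref[v$pos == 400], "AT")
  expect_equal(v$alt[v$pos == 400], "A")
  # "TGG" -> "TG": shared suffix G trimmed, anchor kept
  expect_equal(v$ref[v$pos == 500], "TG")
  expect_equal(v$alt[v$pos == 500], "T")
  expect_true(all(v$vclass == c("SNV", "SNV", "SNV", "indel", "indel")))
})

test_that("malformed or truncated VCFs raise named parse errors", {
  path <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
               "chrS1\t100\t.\tA"), path)
  expect_error(read_vcf(path, "S1", "caller_a"),
               regexp = "line 3", class = "radspectra_parse_error")
  path2 <- withr::local_tempfile(fileext = ".vcf")
  writeLines(c("##fileformat=VCFv4.2",
               "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER"), path2)
  expect_error(read_vcf(path2, "S1", "caller_a"),
               class = "radspectra_format_error")
})

test_that("SNV hard filter fires on each threshold and tolerates absence", {
  mk <- function(...) {
    base <- data.frame(chrom = "chrS1", pos = 1L, ref = "A", alt = "C",
                       vclass = "SNV", sample = "S1", caller = "x",
                       qd = 10, qual = 100, sor = 1, fs = 5, mq = 60,
                       mqranksum = 0, readposranksum = 0, support_reads = 40L,
                       stringsAsFactors = FALSE)
    over <- list(...)
    base[names(over)] <- over
    base
  }
  cases <- list(
    list(v = mk(qd = 1.5), reason = "QD"),
    list(v = mk(qual = 29), reason = "QUAL"),
    list(v = mk(sor = 3.1), reason = "SOR"),
    list(v = mk(fs = 61), reason = "FS"),
    list(v = mk(mq = 39), reason = "MQ"),
    list(v = mk(mqranksum = -12.6), reason = "MQRankSum"),
    list(v = mk(readposranksum = -8.1), reason = "ReadPosRankSum")
  )
  for (cs in cases) {
    verdict <- snv_hard_filter(cs$v)
    expect_false(verdict$pass)
    expect_equal(verdict$reason, cs$reason)
  }
  # boundary values pass (strict inequalities)
  expect_true(snv_hard_filter(mk(qd = 2, qual = 30, sor = 3, fs = 60,
                                 mq = 40, mqranksum = -12.5,
                                 readposranksum = -8))$pass)
  expect_true(snv_hard_filter(mk())$pass)
  # all metrics absent -> pass
  expect_true(snv_hard_filter(mk(qd = NA, qual = NA, sor = NA, fs = NA,
                                 mq = NA, mqranksum = NA,
                                 readposranksum = NA))$pass)
  expect_error(snv_hard_filter(mk(vclass = "indel")),
               class = "radspectra_contract_violation")
})

test_that("indel hard filter enforces the strict >20 read-support rule", {
  mk <- function(...) {
    base <- data.frame(chrom = "chrS1", pos = 1L, ref = "AT", alt = "A",
                       vclass = "indel", sample = "S1", caller = "x",
                       qd = 5, qual = 50, sor = NA_real_, fs = 10,
                       mq = NA_real_, mqranksum = NA_real_,
                       readposranksum = 0, support_reads = 40L,
                       stringsAsFactors = FALSE)
    over <- list(...)
    base[names(over)] <- over
    base
  }
  v20 <- indel_hard_filter(mk(support_reads = 20L))
  expect_false(v20$pass)
  expect_equal(v20$reason, "read support")
  expect_true(indel_hard_filter(mk(support_reads = 21L))$pass)
  expect_false(indel_hard_filter(mk(support_reads = 0L))$pass)
  expect_false(indel_hard_filter(mk(fs = 201))$pass)
  expect_true(indel_hard_filter(mk(fs = 199))$pass)
  expect_false(indel_hard_filter(mk(readposranksum = -20.1))$pass)
  expect_false(indel_hard_filter(mk(qd = 1.9))$pass)
  expect_false(indel_hard_filter(mk(qual = 29))$pass)
  expect_error(indel_hard_filter(mk(vclass = "SNV")),
               class = "radspectra_contract_violation")
})

test_that("caller intersection matches brute force and its contracts", {
  mkv <- function(pos, ref, alt, sample = "S1", caller = "a") {
    data.frame(chrom = "chrS1", pos = pos, ref = ref, alt = alt,
               vclass = ifelse(nchar(ref) == 1 & nchar(alt) == 1, "SNV", "indel"),
               sample = sample, caller = caller, qd = 10, qual = 100, sor = 1,
               fs = 5, mq = 60, mqranksum = 0, readposranksum = 0,
               support_reads = 40L, stringsAsFactors = FALSE)
  }
  a <- mkv(c(1, 2), c("A", "C"), c("C", "T"))
  b <- mkv(c(2, 3), c("C", "G"), c("T", "A"), caller = "b")
  out <- intersect_callers(a, b)
  expect_equal(variant_key(out), "chrS1:2:C:T")
  expect_identical(variant_key(intersect_callers(a, a)), variant_key(a))
  expect_equal(nrow(intersect_callers(mkv(1, "A", "C"), mkv(9, "A", "C",
                                                            caller = "b"))), 0L)
  expect_error(intersect_callers(a, mkv(1, "A", "C", sample = "S2")),
               class = "radspectra_contract_violation")

  # brute-force double-loop equivalence on a random instance
  set.seed(4)
  pa <- sample(1000, 400); pb <- sample(1000, 400)
  A <- mkv(pa, "A", "C"); B <- mkv(pb, "A", "C", caller = "b")
  brute <- sort(unlist(lapply(seq_len(nrow(A)), function(i) {
    for (j in seq_len(nrow(B)))
      if (A$pos[i] == B$pos[j] && A$ref[i] == B$ref[j] && A$alt[i] == B$alt[j])
        return(variant_key(A[i, ]))
    NULL
  })))
  expect_identical(sort(variant_key(intersect_callers(A, B))), brute)
})

test_that("polymorphism filter removes MAF > threshold in either panel only", {
  vs <- data.frame(chrom = "chrS1", pos = 1:4, ref = "A", alt = "C",
                   vclass = "SNV", sample = "S1", caller = "b",
                   stringsAsFactors = FALSE)
  panel <- data.frame(chrom = "chrS1", pos = 1:3, ref = "A", alt = "C",
                      maf_panel1 = c(0.02, 0.01, NA),
                      maf_panel2 = c(NA, 0.01, 0.005),
                      stringsAsFactors = FALSE)
  res <- filter_polymorphisms(vs, panel)
  expect_equal(res$removed$pos, 1L)          # 0.02 in one panel -> removed
  expect_setequal(res$retained$pos, 2:4)     # exactly 0.01 and absent -> kept
  expect_equal(nrow(res$retained) + nrow(res$removed), nrow(vs))
  expect_error(filter_polymorphisms(vs, panel, threshold = 0),
               class = "radspectra_invalid_config")
})

test_that("cascade conserves variants per stage and recovers common_fraction", {
  fx <- shared_fixture()
  dir0 <- withr::local_tempdir()
  ev <- emit_caller_vcfs(fx$cohort, dir0)
  pan <- make_frequency_panel(fx$cohort)
  sm <- names(fx$cohort$samples)[2]
  va <- read_vcf(file.path(dir0, sprintf("%s.caller_a.vcf", sm)), sm, "caller_a")
  vb <- read_vcf(file.path(dir0, sprintf("%s.caller_b.vcf", sm)), sm, "caller_b")
  res <- consensus_filter(va, vb, pan$panel)
  # conservation: every input record is either retained or removed-with-reason;
  # variants surviving the intersection account for one record per caller
  expect_equal(nrow(res$retained) * 2 + nrow(res$removed) +
                 sum(res$removed$stage == "polymorphism"),
               nrow(va) + nrow(vb))
  with(res$log, {
    expect_equal(n_out[stage == "hard_filter_a"] +
                   sum(res$removed$stage == "hard_filter" &
                         res$removed$caller == "caller_a"), nrow(va))
    expect_equal(n_in[stage == "polymorphism"],
                 n_out[stage == "intersection"])
  })
  # survivors are the truth variants that are clean, in both callers, and rare
  truth_v <- fx$cohort$variants[fx$cohort$variants$sample == sm, ]
  pres <- ev$presence[ev$presence$sample == sm, ]
  tk <- variant_key(truth_v)
  expected <- tk[!truth_v$artifact &
                   pres$in_a[match(tk, pres$key)] &
                   pres$in_b[match(tk, pres$key)] &
                   !pan$truth$is_common[match(tk, pan$truth$key)]]
  expect_setequal(variant_key(res$retained), expected)
})

test_that("hard filtering and polymorphism filtering commute", {
  fx <- shared_fixture()
  dir0 <- withr::local_tempdir()
  emit_caller_vcfs(fx$cohort, dir0)
  pan <- make_frequency_panel(fx$cohort)
  sm <- names(fx$cohort$samples)[3]
  vb <- read_vcf(file.path(dir0, sprintf("%s.caller_b.vcf", sm)), sm, "caller_b")
  snv <- vb[vb$vclass == "SNV", ]
  hard_then_maf <- filter_polymorphisms(snv[snv_hard_filter(snv)$pass, ],
                                        pan$panel)$retained
  maf_first <- filter_polymorphisms(snv, pan$panel)$retained
  maf_then_hard <- maf_first[snv_hard_filter(maf_first)$pass, ]
  expect_setequal(variant_key(hard_then_maf), variant_key(maf_then_hard))
})

test_that("variant tables round-trip through TSV", {
  fx <- shared_fixture()
  v <- fx$cohort$variants[1:50, c("chrom", "pos", "ref", "alt", "vclass",
                                  "sample")]
  path <- withr::local_tempfile(fileext = ".tsv")
  write_variant_table(v, path)
  v2 <- read_variant_table(path)
  expect_identical(variant_key(v), variant_key(v2))
})
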