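# Shared fixtures and independent oracles, all built in code.

# small study configuration used across module tests
small_config <- function(seed = 11L, ...) {
  simulation_config(ref_length = 150000, n_variants_per_individual = 600L,
                    n_indels_per_individual = 60L, seed = seed, ...)
}

# one shared small cohort per session (cached; tests treat it as read-only)
.fixture_env <- new.env(parent = emptyenv())
shared_fixture <- function() {
  if (is.null(.fixture_env$fx)) {
    cfg <- small_config(cpg_ct_multiplier_by_group = c(NLNRA = 1, HLNRA = 3))
    ref <- generate_reference(cfg$ref_length, cfg$gc_fraction, cfg$cpg_rate,
                              cfg$seed)
    cohort <- simulate_cohort(ref, cfg)
    .fixture_env$fx <- list(cfg = cfg, ref = ref, cohort = cohort)
  }
  .fixture_env$fx
}

# Independent Mann-Whitney oracle: enumerate every assignment of the pooled
# values to the two groups and count pairwise wins directly (no ranks).
mw_enum_oracle <- function(a, b) {
  n1 <- length(a); n2 <- length(b)
  x <- c(a, b); N <- n1 + n2
  u_of <- function(ia) {
    xa <- x[ia]; xb <- x[-ia]
    sum(outer(xa, xb, ">")) + 0.5 * sum(outer(xa, xb, "=="))
  }
  u_obs <- u_of(seq_len(n1))
  us <- apply(combn(N, n1), 2, u_of)
  min(1, 2 * min(mean(us <= u_obs), mean(us >= u_obs)))
}

# literal single-sample VCF writer for hand-built fixtures
write_toy_vcf <- function(path, sample, records) {
  hdr <- c("##fileformat=VCFv4.2",
           "##contig=<ID=chrS1,length=100000>",
           "##INFO=<ID=QD,Number=1,Type=Float,Description=\"QD\">",
           "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"SOR\">",
           "##INFO=<ID=FS,Number=1,Type=Float,Description=\"FS\">",
           "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"MQ\">",
           "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQRS\">",
           "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"RPRS\">",
           "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"GT\">",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t",
                  sample))
  writeLines(c(hdr, records), path)
  path
}

# toy record line with clean defaults, overridable per metric
toy_record <- function(pos, ref, alt, qual = 100, filter = "PASS", qd = 10,
                       sor = 1, fs = 5, mq = 60, mqrs = 0, rprs = 0,
                       support = 40) {
  info <- sprintf("QD=%g;SOR=%g;FS=%g;MQ=%g;MQRankSum=%g;ReadPosRankSum=%g",
                  qd, sor, fs, mq, mqrs, rprs)
  sprintf("chrS1\t%d\t.\t%s\t%s\t%g\t%s\t%s\tGT:AD\t0/1:%d,%d",
          pos, ref, alt, qual, filter, info, support, support)
}

# reverse-complemented view of a reference with mirrored variant coordinates
revcomp_ref_and_variants <- function(ref, vs) {
  L <- nchar(ref$sequence)
  rc_seq <- paste(rev(strsplit(chartr("ACGT", "TGCA", ref$sequence), "",
                               fixed = TRUE)[[1]]), collapse = "")
  rc <- structure(list(name = ref$name, sequence = rc_seq), class = "ref_seq")
  vs_rc <- vs
  vs_rc$pos <- L - vs$pos + 1L
  vs_rc$ref <- chartr("ACGT", "TGCA", vs$ref)
  vs_rc$alt <- chartr("ACGT", "TGCA", vs$alt)
  list(ref = rc, variants = vs_rc)
}
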