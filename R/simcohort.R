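# Synthetic two-group cohort generator: reference contig, per-individual
# two-caller VCFs, population frequency panels, consequence tables, with
# recorded truth so every downstream stage can be tested against known labels.

#' Simulation configuration for a synthetic two-group cohort
#'
#' Defaults emulate the study conditions the analysis was designed for: two
#' groups of 6 male individuals (control NLNRA vs radiation-exposed HLNRA),
#' ~29,000 raw variants per individual of which ~95.5% are common
#' polymorphisms (leaving ~1,300 rare SNVs and ~145 rare indels after
#' filtering), and a substitution spectrum dominated by C>T (~49%).
#'
#' @param n_per_group individuals per group.
#' @param groups character vector of the two group labels.
#' @param ref_name synthetic contig name.
#' @param ref_length reference length in bases.
#' @param gc_fraction target GC fraction of the reference, in [0,1].
#' @param cpg_rate target CpG dinucleotide density (CpG count / length).
#' @param n_variants_per_individual raw SNVs simulated per individual.
#' @param n_indels_per_individual raw indels simulated per individual.
#' @param base_spectrum named probability vector over the six
#'   pyrimidine-normalized substitution classes; must sum to 1.
#' @param ct_cpg_fraction share of C>T mass falling at CpG sites under the
#'   null (multiplier 1).
#' @param cpg_ct_multiplier_by_group named vector, multiplicative enrichment
#'   of C>T-at-CpG per group (1 = null).
#' @param shared_variant_fraction fraction of each individual's variants drawn
#'   from a group-level shared pool (creates carriers in >= 2 individuals).
#' @param common_fraction fraction of variant keys assigned panel MAF > 1%.
#' @param caller_concordance probability a variant appears in both callers.
#' @param artifact_fraction fraction of variants given filter-failing quality
#'   annotations (exercises every hard-filter branch).
#' @param pathogenic_missense_fraction fraction of missense records with
#'   REVEL > 0.5 in the synthetic consequence table.
#' @param aloft_high_confidence_fraction fraction of truncating records with
#'   a high-confidence ALoFT call.
#' @param dispersion per-individual count dispersion; 0 gives exact counts,
#'   otherwise counts are negative-binomial with size 1/dispersion.
#' @param group_dose_mean,group_dose_sd named vectors of annual-dose targets
#'   (mGy/year) used for the synthetic dosimetry metadata.
#' @param occupancy_indoor indoor occupancy fraction used in dose metadata.
#' @param seed integer seed; identical config + seed reproduces outputs
#'   byte-identically.
#' @return a validated `simulation_config` list.
#' @export
simulation_config <- function(n_per_group = 6L,
                              groups = c("NLNRA", "HLNRA"),
                              ref_name = "chrS1",
                              ref_length = 5e6,
                              gc_fraction = 0.41,
                              cpg_rate = 0.01,
                              n_variants_per_individual = 29000L,
                              n_indels_per_individual = 3200L,
                              base_spectrum = c("C>A" = 0.08, "C>G" = 0.07,
                                                "C>T" = 0.49, "T>A" = 0.06,
                                                "T>C" = 0.23, "T>G" = 0.07),
                              ct_cpg_fraction = 0.30,
                              cpg_ct_multiplier_by_group = c(NLNRA = 1, HLNRA = 1),
                              shared_variant_fraction = 0.40,
                              common_fraction = 0.955,
                              caller_concordance = 0.95,
                              artifact_fraction = 0.10,
                              pathogenic_missense_fraction = 0.10,
                              aloft_high_confidence_fraction = 0.60,
                              dispersion = 0,
                              group_dose_mean = c(NLNRA = 0.9, HLNRA = 31.8),
                              group_dose_sd = c(NLNRA = 0.2, HLNRA = 5.4),
                              occupancy_indoor = 0.8,
                              seed = 1L) {
  cfg <- list(
    n_per_group = as.integer(n_per_group), groups = groups,
    ref_name = ref_name, ref_length = as.integer(ref_length),
    gc_fraction = gc_fraction, cpg_rate = cpg_rate,
    n_variants_per_individual = as.integer(n_variants_per_individual),
    n_indels_per_individual = as.integer(n_indels_per_individual),
    base_spectrum = base_spectrum, ct_cpg_fraction = ct_cpg_fraction,
    cpg_ct_multiplier_by_group = cpg_ct_multiplier_by_group,
    shared_variant_fraction = shared_variant_fraction,
    common_fraction = common_fraction,
    caller_concordance = caller_concordance,
    artifact_fraction = artifact_fraction,
    pathogenic_missense_fraction = pathogenic_missense_fraction,
    aloft_high_confidence_fraction = aloft_high_confidence_fraction,
    dispersion = dispersion,
    group_dose_mean = group_dose_mean, group_dose_sd = group_dose_sd,
    occupancy_indoor = occupancy_indoor,
    seed = as.integer(seed)
  )
  class(cfg) <- "simulation_config"
  validate_simulation_config(cfg)
  cfg
}

#' @rdname simulation_config
#' @param cfg a `simulation_config`.
#' @export
validate_simulation_config <- function(cfg) {
  chk_frac <- function(x, nm) {
    if (any(!is.finite(x)) || any(x < 0) || any(x > 1))
      rad_abort(sprintf("%s must lie in [0,1]", nm), "invalid_config")
  }
  if (length(cfg$groups) != 2L || anyDuplicated(cfg$groups))
    rad_abort("exactly two distinct group labels are required", "invalid_config")
  if (cfg$n_per_group < 1L) rad_abort("n_per_group must be >= 1", "invalid_config")
  sp <- cfg$base_spectrum
  if (!identical(sort(names(sp)), sort(SUBSTITUTION_CLASSES)))
    rad_abort("base_spectrum must be named by the six substitution classes",
              "invalid_config")
  if (any(sp < 0) || abs(sum(sp) - 1) > 1e-9)
    rad_abort("base_spectrum must be nonnegative and sum to 1 (tol 1e-9)",
              "invalid_config")
  chk_frac(cfg$gc_fraction, "gc_fraction")
  chk_frac(cfg$cpg_rate, "cpg_rate")
  chk_frac(cfg$ct_cpg_fraction, "ct_cpg_fraction")
  chk_frac(cfg$shared_variant_fraction, "shared_variant_fraction")
  chk_frac(cfg$common_fraction, "common_fraction")
  chk_frac(cfg$caller_concordance, "caller_concordance")
  chk_frac(cfg$artifact_fraction, "artifact_fraction")
  chk_frac(cfg$pathogenic_missense_fraction, "pathogenic_missense_fraction")
  chk_frac(cfg$aloft_high_confidence_fraction, "aloft_high_confidence_fraction")
  chk_frac(cfg$occupancy_indoor, "occupancy_indoor")
  mult <- cfg$cpg_ct_multiplier_by_group
  if (!all(cfg$groups %in% names(mult)))
    rad_abort("cpg_ct_multiplier_by_group must name every group", "invalid_config")
  if (any(mult <= 0)) rad_abort("CpG multipliers must be > 0", "invalid_config")
  if (cfg$n_variants_per_individual > cfg$ref_length / 10)
    rad_abort("n_variants_per_individual must be <= ref_length / 10",
              "invalid_config")
  invisible(cfg)
}

#' Generate a synthetic reference contig
#'
#' Samples a first-order Markov chain over A/C/G/T whose stationary base
#' composition matches `gc_fraction` exactly and whose C-to-G transition
#' probability is solved in closed form so that the stationary CpG
#' dinucleotide density equals `cpg_rate` exactly.  (Vertebrate genomes are
#' CpG-depleted relative to independent sampling, so an iid draw cannot hit a
#' realistic CpG density; the chain can.)
#'
#' @param length sequence length in bases (>= 1000).
#' @param gc_fraction target GC content in [0,1].
#' @param cpg_rate target CpG dinucleotide density; must not exceed
#'   `gc_fraction / 2`.
#' @param seed integer seed.
#' @param name contig name.
#' @return a `ref_seq`: list with `name` and `sequence` (character scalar).
#' @examples
#' ref <- generate_reference(10000, 0.41, 0.01, seed = 7)
#' substr(ref$sequence, 1, 60)
#' @export
generate_reference <- function(length, gc_fraction, cpg_rate, seed,
                               name = "chrS1") {
  if (length < 1000) rad_abort("reference length must be >= 1000", "invalid_config")
  if (gc_fraction < 0 || gc_fraction > 1 || cpg_rate < 0 || cpg_rate > 1)
    rad_abort("gc_fraction and cpg_rate must lie in [0,1]", "invalid_config")
  if (cpg_rate > gc_fraction / 2)
    rad_abort("cpg_rate > gc_fraction/2 is infeasible", "invalid_config")
  set.seed(as.integer(seed))
  pi_c <- gc_fraction / 2
  pi_at <- (1 - gc_fraction) / 2
  stat <- c(A = pi_at, C = pi_c, G = pi_c, T = pi_at)
  if (pi_c == 0) {
    # AT-only sequence; no C state, iid draw
    trans <- matrix(rep(stat, 4), nrow = 4, byrow = TRUE)
  } else {
    # r = P(G | C) chosen so stationary CpG density pi_C * r = cpg_rate;
    # remaining row masses solved so the stationary law is exactly `stat`.
    r <- cpg_rate / pi_c
    qg <- (pi_c - pi_c * r) / (1 - pi_c)       # P(G | not C)
    beta <- (1 - r) / (1 - qg)
    denom <- (1 - pi_c) + pi_c * beta
    q <- c(A = pi_at, C = pi_c, T = pi_at) / denom
    row_other <- c(A = q[["A"]], C = q[["C"]], G = qg, T = q[["T"]])
    row_c <- c(A = beta * q[["A"]], C = beta * q[["C"]], G = r,
               T = beta * q[["T"]])
    trans <- rbind(row_other, row_c, row_other, row_other)
  }
  seqc <- markov_sequence_cpp(as.integer(length), unname(stat), unname(trans))
  structure(list(name = name, sequence = seqc), class = "ref_seq")
}

#' @export
print.ref_seq <- function(x, ...) {
  cat(sprintf("<ref_seq> %s: %d bp\n", x$name, nchar(x$sequence)))
  invisible(x)
}

# Positions eligible for each planted site type:
#  cpg     - C of a CpG, or G of a CpG (pyrimidine on the minus strand)
#  c_other - C or G outside any CpG
#  t       - T or A anywhere
reference_site_pools <- function(ref) {
  cr <- charToRaw(ref$sequence)
  L <- length(cr)
  isC <- cr == as.raw(67L); isG <- cr == as.raw(71L)
  cpg_c <- which(isC[-L] & isG[-1L])
  cpg_sites <- sort(c(cpg_c, cpg_c + 1L))
  cg_all <- which(isC | isG)
  list(cpg = cpg_sites,
       c_other = setdiff(cg_all, cpg_sites),
       t = which(cr == as.raw(84L) | cr == as.raw(65L)))
}

# exact integer allocation of n items to categories by largest remainder
quota_categories <- function(w, n) {
  exact <- w * n
  cnt <- floor(exact)
  short <- n - sum(cnt)
  if (short > 0) {
    extra <- order(exact - cnt, decreasing = TRUE)[seq_len(short)]
    cnt[extra] <- cnt[extra] + 1
  }
  rep(names(w), cnt)
}

# Seven planting categories: the C>T class is split by CpG context because
# that is the axis the planted group effect acts on.
CAT7 <- c("C>A", "C>G", "C>T:CpG", "C>T:other", "T>A", "T>C", "T>G")
cat7_class <- function(cat) sub(":.*$", "", cat)
cat7_site_type <- function(cat) {
  ifelse(cat == "C>T:CpG", "cpg",
         ifelse(cat %in% c("C>A", "C>G", "C>T:other"), "c_other", "t"))
}

# Planted 7-category weights for one group: the group's multiplier scales the
# C>T-at-CpG mass, then the vector is renormalized.
planted_weights <- function(cfg, group) {
  p <- cfg$base_spectrum
  s0 <- cfg$ct_cpg_fraction
  m <- cfg$cpg_ct_multiplier_by_group[[group]]
  w <- c(p[["C>A"]], p[["C>G"]], m * p[["C>T"]] * s0, p[["C>T"]] * (1 - s0),
         p[["T>A"]], p[["T>C"]], p[["T>G"]])
  names(w) <- CAT7
  w / sum(w)
}

#' Simulate a two-group variant cohort with known truth
#'
#' Plants per-individual SNVs (and indels) on a reference contig.  Each SNV is
#' drawn from a seven-category spectrum (the six substitution classes with
#' C>T split into CpG / non-CpG context); the exposed group's C>T-at-CpG mass
#' is multiplied by its configured enrichment.  A configurable fraction of
#' each individual's variants comes from a group-level shared pool, so some
#' variants recur in >= 2 individuals of one group and never in the other;
#' all remaining positions are sampled without replacement across the whole
#' cohort, so cross-group recurrence never happens and group-unique truth is
#' exact.  Indels (1-10 bp) are placed at otherwise unused positions and never
#' enter spectrum truth.
#'
#' @param ref a `ref_seq` from [generate_reference()].
#' @param config a `simulation_config`.
#' @return a `sim_cohort`: list with `variants` (one row per sample-variant:
#'   chrom, pos, ref, alt, vclass, sample, group, class6, category, is_cpg,
#'   pool_id, artifact), `truth` (planted per-group category weights and
#'   expected C>T-at-CpG fractions), `samples` (sample -> group map) and the
#'   echoed `config`.
#' @export
simulate_cohort <- function(ref, config) {
  validate_simulation_config(config)
  if (config$n_variants_per_individual > nchar(ref$sequence) / 10)
    rad_abort("reference too short for requested variant density",
              "invalid_config")
  set.seed(config$seed)
  pools <- reference_site_pools(ref)
  seqs <- ref$sequence

  samples <- unlist(lapply(config$groups, function(g)
    paste0(g, "_", seq_len(config$n_per_group))))
  sample_group <- setNames(rep(config$groups, each = config$n_per_group),
                           samples)

  draw_count <- function(n, k) {
    if (config$dispersion > 0)
      pmax(10L, rnbinom(k, mu = n, size = 1 / config$dispersion))
    else rep(as.integer(n), k)
  }

  # --- per-group variant requests (categories), pool first then privates ----
  req <- list()   # one element per group: list(pool_cat, priv_cat_by_sample, picks)
  for (g in config$groups) {
    w <- planted_weights(config, g)
    g_samples <- samples[sample_group[samples] == g]
    n_i <- draw_count(config$n_variants_per_individual, length(g_samples))
    s_i <- round(config$shared_variant_fraction * n_i)
    p_i <- n_i - s_i
    pool_size <- if (sum(s_i) > 0) max(max(s_i), ceiling(sum(s_i) / 3)) else 0L
    # Pool category counts are planted exactly (largest-remainder quota on
    # the group weights) and only the order is shuffled: the group-shared
    # pool then carries no compositional noise, so cohort-level sampling
    # variation cannot masquerade as a planted group effect in the
    # group-unique comparisons.
    pool_cat <- if (pool_size > 0) sample(quota_categories(w, pool_size))
                else character(0)
    picks <- lapply(seq_along(g_samples), function(i)
      if (s_i[i] > 0) sample.int(pool_size, s_i[i]) else integer(0))
    priv <- lapply(seq_along(g_samples), function(i)
      if (p_i[i] > 0) sample(CAT7, p_i[i], replace = TRUE, prob = w)
      else character(0))
    req[[g]] <- list(samples = g_samples, pool_cat = pool_cat, picks = picks,
                     priv = priv)
  }

  # --- global site assignment, without replacement across the cohort -------
  all_cats <- unlist(lapply(config$groups, function(g)
    c(req[[g]]$pool_cat, unlist(req[[g]]$priv))), use.names = FALSE)
  types <- cat7_site_type(all_cats)
  need <- table(factor(types, levels = c("cpg", "c_other", "t")))
  for (tp in names(need)) {
    if (need[[tp]] > length(pools[[tp]])) {
      msg <- if (tp == "cpg")
        sprintf("too few eligible CpG sites (%d) for requested C>T-at-CpG mass (%d)",
                length(pools$cpg), need[[tp]])
      else sprintf("too few eligible '%s' sites for requested variants", tp)
      rad_abort(msg, "simulation_error")
    }
  }
  site_of <- integer(length(all_cats))
  for (tp in c("cpg", "c_other", "t")) {
    idx <- which(types == tp)
    if (length(idx)) site_of[idx] <- sample(pools[[tp]], length(idx))
  }

  # cursor over all_cats / site_of in the same deterministic order
  cursor <- 0L
  take <- function(k) {
    out <- (cursor + 1L):(cursor + k)
    cursor <<- cursor + k
    out
  }

  base_at <- function(pos) {
    if (length(pos)) substring(seqs, pos, pos) else character(0)
  }
  alt_for <- function(cat, base) {
    target <- substr(cat7_class(cat), 3L, 3L)
    ifelse(base %in% PYRIMIDINES, target, comp_base(target))
  }

  rows <- list()
  pool_offset <- 0L
  for (g in config$groups) {
    rg <- req[[g]]
    npool <- length(rg$pool_cat)
    pool_idx <- if (npool > 0) take(npool) else integer(0)
    pool_pos <- site_of[pool_idx]
    pool_base <- base_at(pool_pos)
    pool_alt <- alt_for(rg$pool_cat, pool_base)
    pool_art <- runif(npool) < config$artifact_fraction
    for (i in seq_along(rg$samples)) {
      sm <- rg$samples[i]
      pk <- rg$picks[[i]]
      pv <- rg$priv[[i]]
      npv <- length(pv)
      pv_idx <- if (npv > 0) take(npv) else integer(0)
      pv_pos <- site_of[pv_idx]
      pv_base <- base_at(pv_pos)
      cat_all <- c(rg$pool_cat[pk], pv)
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = ref$name,
        pos = c(pool_pos[pk], pv_pos),
        ref = c(pool_base[pk], pv_base),
        alt = c(pool_alt[pk], alt_for(pv, pv_base)),
        vclass = "SNV",
        sample = sm, group = g,
        class6 = cat7_class(cat_all),
        category = cat_all,
        is_cpg = cat_all == "C>T:CpG",
        pool_id = c(pk + pool_offset, rep(NA_integer_, npv)),
        artifact = c(pool_art[pk], runif(npv) < config$artifact_fraction),
        stringsAsFactors = FALSE
      )
    }
    pool_offset <- pool_offset + npool
  }
  snvs <- do.call(rbind, rows)

  # --- indels: private, 1-10 bp, at positions unused by any SNV -------------
  L <- nchar(seqs)
  used <- unique(c(site_of))
  n_ind <- draw_count(config$n_indels_per_individual, length(samples))
  total_ind <- sum(n_ind)
  ind_rows <- NULL
  if (total_ind > 0) {
    cand <- setdiff(sample.int(L - 30L, min(L - 30L, total_ind * 3L)) + 10L, used)
    if (length(cand) < total_ind)
      rad_abort("too few free positions for requested indels", "simulation_error")
    ipos <- cand[seq_len(total_ind)]
    ilen <- sample.int(10L, total_ind, replace = TRUE)
    is_del <- runif(total_ind) < 0.5
    anchor <- substring(seqs, ipos, ipos)
    iref <- ifelse(is_del, substring(seqs, ipos, ipos + ilen), anchor)
    rand_ins <- vapply(ilen, function(l)
      paste(sample(BASES, l, replace = TRUE), collapse = ""), character(1))
    ialt <- ifelse(is_del, anchor, paste0(anchor, rand_ins))
    ind_rows <- data.frame(
      chrom = ref$name, pos = ipos, ref = iref, alt = ialt, vclass = "indel",
      sample = rep(samples, n_ind), group = rep(sample_group[samples], n_ind),
      class6 = NA_character_, category = NA_character_, is_cpg = NA,
      pool_id = NA_integer_, artifact = runif(total_ind) < config$artifact_fraction,
      stringsAsFactors = FALSE
    )
  }
  variants <- rbind(snvs, ind_rows)
  variants <- variants[order(variants$sample, variants$pos), , drop = FALSE]
  rownames(variants) <- NULL

  truth <- list(
    weights_by_group = lapply(setNames(config$groups, config$groups),
                              function(g) planted_weights(config, g)),
    cpg_ct_fraction_by_group = vapply(config$groups, function(g)
      planted_weights(config, g)[["C>T:CpG"]], numeric(1))
  )
  structure(list(variants = variants, truth = truth,
                 samples = sample_group, ref_name = ref$name, config = config),
            class = "sim_cohort")
}

#' @export
print.sim_cohort <- function(x, ...) {
  v <- x$variants
  cat(sprintf("<sim_cohort> %d samples, %d SNV rows, %d indel rows\n",
              length(x$samples), sum(v$vclass == "SNV"),
              sum(v$vclass == "indel")))
  invisible(x)
}

# Quality-annotation mixtures. "Clean" draws always satisfy every hard
# filter; "artifact" draws start clean and then push exactly one randomly
# chosen metric into its failing range, so every filter branch fires.
simulate_metrics <- function(n, vclass, artifact) {
  m <- data.frame(
    qd = runif(n, 5, 30), qual = runif(n, 50, 500), sor = runif(n, 0.3, 2.5),
    fs = runif(n, 0, 20), mq = runif(n, 50, 60),
    mqranksum = runif(n, -3, 3), readposranksum = runif(n, -3, 3),
    support_reads = sample(25:80, n, replace = TRUE)
  )
  # rank-sum annotations are genuinely missing for a share of clean records
  m$mqranksum[runif(n) < 0.1] <- NA_real_
  m$readposranksum[runif(n) < 0.1] <- NA_real_
  snv_rules <- c("qd", "qual", "sor", "fs", "mq", "mqranksum", "readposranksum")
  indel_rules <- c("qd", "qual", "fs", "readposranksum", "support_reads")
  for (i in which(artifact)) {
    rule <- if (vclass[i] == "SNV") sample(snv_rules, 1) else sample(indel_rules, 1)
    m[i, rule] <- switch(rule,
      qd = runif(1, 0, 1.9), qual = runif(1, 0, 29), sor = runif(1, 3.1, 6),
      fs = if (vclass[i] == "SNV") runif(1, 61, 150) else runif(1, 201, 400),
      mq = runif(1, 10, 39), mqranksum = runif(1, -20, -12.6),
      readposranksum = if (vclass[i] == "SNV") runif(1, -15, -8.1)
                       else runif(1, -30, -20.1),
      support_reads = sample(0:20, 1))
  }
  m
}

write_simple_vcf <- function(df, path, sample, ref_name, ref_length) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", ref_name, ref_length),
    "##INFO=<ID=QD,Number=1,Type=Float,Description=\"Quality by depth\">",
    "##INFO=<ID=SOR,Number=1,Type=Float,Description=\"Strand odds ratio\">",
    "##INFO=<ID=FS,Number=1,Type=Float,Description=\"Fisher strand (Phred)\">",
    "##INFO=<ID=MQ,Number=1,Type=Float,Description=\"Mapping quality\">",
    "##INFO=<ID=MQRankSum,Number=1,Type=Float,Description=\"MQ rank sum\">",
    "##INFO=<ID=ReadPosRankSum,Number=1,Type=Float,Description=\"Read position rank sum\">",
    "##FILTER=<ID=LowQual,Description=\"Failed caller quality model\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample)
  )
  df <- df[order(df$pos), , drop = FALSE]
  fmt1 <- function(x) ifelse(is.na(x), NA, sprintf("%.2f", x))
  info_part <- function(tag, x) ifelse(is.na(x), NA, paste0(tag, "=", fmt1(x)))
  parts <- cbind(info_part("QD", df$qd), info_part("SOR", df$sor),
                 info_part("FS", df$fs), info_part("MQ", df$mq),
                 info_part("MQRankSum", df$mqranksum),
                 info_part("ReadPosRankSum", df$readposranksum))
  info <- apply(parts, 1, function(p) paste(p[!is.na(p)], collapse = ";"))
  info[info == ""] <- "."
  ad <- paste0(df$support_reads, ",", df$support_reads)
  lines <- paste(df$chrom, df$pos, ".", df$ref, df$alt,
                 sprintf("%.2f", df$qual), df$filter, info, "GT:AD",
                 paste0("0/1:", ad), sep = "\t")
  writeLines(c(hdr, lines), path)
  invisible(path)
}

#' Emit two simulated caller VCFs per individual
#'
#' Each truth variant appears in both callers' files with probability
#' `concordance`, otherwise in exactly one (chosen uniformly).  Records carry
#' QD/QUAL/SOR/FS/MQ/MQRankSum/ReadPosRankSum and supporting-read depths drawn
#' from clean/artifact mixtures so both branches of every hard filter are
#' exercised; artifact records additionally carry a non-PASS FILTER in the
#' caller_a (Strelka-like) file.  Output is sorted single-sample VCFv4.2.
#'
#' @param cohort a `sim_cohort`.
#' @param dir output directory (created if needed).
#' @param concordance probability in [0,1]; defaults to the cohort config.
#' @param seed seed for presence/metric draws; defaults to config seed + 1.
#' @return list with `files` (data.frame sample, caller, path) and `presence`
#'   (per sample-variant row: in_a, in_b).
#' @export
emit_caller_vcfs <- function(cohort, dir,
                             concordance = NULL, seed = NULL) {
  cfg <- cohort$config
  concordance <- concordance %||% cfg$caller_concordance
  if (concordance < 0 || concordance > 1)
    rad_abort("concordance must lie in [0,1]", "invalid_config")
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    rad_abort(sprintf("cannot create output directory '%s'", dir), "io_error")
  set.seed(as.integer(seed %||% (cfg$seed + 1L)))
  v <- cohort$variants
  n <- nrow(v)
  both <- runif(n) < concordance
  a_side <- runif(n) < 0.5
  in_a <- both | a_side
  in_b <- both | !a_side
  ref_len <- cfg$ref_length
  files <- list()
  for (sm in names(cohort$samples)) {
    sel <- which(v$sample == sm)
    vm <- cbind(v[sel, c("chrom", "pos", "ref", "alt", "vclass", "artifact")],
                simulate_metrics(length(sel), v$vclass[sel], v$artifact[sel]))
    for (caller in c("caller_a", "caller_b")) {
      keep <- if (caller == "caller_a") in_a[sel] else in_b[sel]
      dfc <- vm[keep, , drop = FALSE]
      # Strelka-like caller exposes its own PASS/fail verdict; GATK-like
      # caller leaves FILTER unset and relies on downstream hard filters.
      dfc$filter <- if (caller == "caller_a")
        ifelse(dfc$artifact, "LowQual", "PASS") else "."
      path <- file.path(dir, sprintf("%s.%s.vcf", sm, caller))
      write_simple_vcf(dfc, path, sm, cohort$ref_name, ref_len)
      files[[length(files) + 1L]] <- data.frame(
        sample = sm, caller = caller, path = path, n_records = nrow(dfc),
        stringsAsFactors = FALSE)
    }
  }
  list(files = do.call(rbind, files),
       presence = data.frame(sample = v$sample, key = variant_key(v),
                             in_a = in_a, in_b = in_b,
                             stringsAsFactors = FALSE))
}

#' Build synthetic population frequency panels
#'
#' Assigns each unique variant key a minor allele frequency in two emulated
#' population panels.  A `common_fraction` of keys gets MAF > 1% in at least
#' one panel (and is therefore removed by the polymorphism filter); the rest
#' get MAF <= 1% or are absent from both panels.
#'
#' @param cohort a `sim_cohort`.
#' @param common_fraction fraction in [0,1]; defaults to the cohort config.
#' @param seed seed; defaults to config seed + 2.
#' @param path optional TSV output path (chrom, pos, ref, alt, maf_panel1,
#'   maf_panel2).
#' @return list with `panel` (data.frame) and `truth` (key, is_common).
#' @export
make_frequency_panel <- function(cohort, common_fraction = NULL, seed = NULL,
                                 path = NULL) {
  cfg <- cohort$config
  common_fraction <- common_fraction %||% cfg$common_fraction
  if (common_fraction < 0 || common_fraction > 1)
    rad_abort("common_fraction must lie in [0,1]", "invalid_config")
  set.seed(as.integer(seed %||% (cfg$seed + 2L)))
  v <- cohort$variants
  keys <- variant_key(v)
  u <- !duplicated(keys)
  uk <- data.frame(chrom = v$chrom[u], pos = v$pos[u], ref = v$ref[u],
                   alt = v$alt[u], stringsAsFactors = FALSE)
  n <- nrow(uk)
  is_common <- runif(n) < common_fraction
  maf1 <- rep(NA_real_, n); maf2 <- rep(NA_real_, n)
  which_panel <- sample.int(3L, n, replace = TRUE)  # 1, 2 or both
  val <- ifelse(is_common, runif(n, 0.0101, 0.5), runif(n, 0, 0.0099))
  present <- is_common | runif(n) < 0.5  # half the rare keys are absent
  p1 <- present & which_panel != 2L
  p2 <- present & which_panel != 1L
  maf1[p1] <- val[p1]; maf2[p2] <- val[p2]
  panel <- cbind(uk, maf_panel1 = maf1, maf_panel2 = maf2)
  panel <- panel[!(is.na(panel$maf_panel1) & is.na(panel$maf_panel2)), ,
                 drop = FALSE]
  if (!is.null(path))
    write.table(panel, path, sep = "\t", quote = FALSE, row.names = FALSE)
  list(panel = panel,
       truth = data.frame(key = variant_key(uk), is_common = is_common,
                          stringsAsFactors = FALSE))
}

# consequence-term machinery shared with the consequence module
SNV_TERM_PROBS <- c(intron = 0.44, regulatory = 0.15, ncRNA = 0.08,
                    synonymous = 0.12, missense = 0.17, splice_donor = 0.01,
                    splice_acceptor = 0.01, stop_gained = 0.015,
                    stop_lost = 0.005)
INDEL_TERM_PROBS <- c(frameshift = 0.35, inframe_deletion = 0.25,
                      intron = 0.30, regulatory = 0.10)
TERM_IMPACT <- c(missense = "MODERATE", inframe_deletion = "MODERATE",
                 stop_gained = "HIGH", stop_lost = "HIGH", frameshift = "HIGH",
                 splice_donor = "HIGH", splice_acceptor = "HIGH",
                 synonymous = "LOW", intron = "MODIFIER",
                 regulatory = "MODIFIER", ncRNA = "MODIFIER")
TRUNCATING_TERMS <- c("stop_gained", "frameshift")

#' Build a synthetic consequence-annotation table
#'
#' Emulates VEP-style output for every unique simulated variant: a gene label
#' from a window partition of the reference, a consequence term with a
#' consistent impact level, a REVEL score for missense records (pathogenic,
#' i.e. > 0.5, with probability `pathogenic_missense_fraction`) and an ALoFT
#' confidence for truncating records.  A tenth of coding records get a second,
#' milder transcript record, exercising the per-variant severity collapse.
#'
#' @param cohort a `sim_cohort`.
#' @param seed seed; defaults to config seed + 3.
#' @param path optional TSV output path.
#' @return list with `table` (the consequence data.frame) and `truth`
#'   (per-key term, PAM flag, REVEL-pathogenic flag, ALoFT-LoF flag).
#' @export
make_consequence_table <- function(cohort, seed = NULL, path = NULL) {
  cfg <- cohort$config
  set.seed(as.integer(seed %||% (cfg$seed + 3L)))
  v <- cohort$variants
  keys <- variant_key(v)
  u <- !duplicated(keys)
  uv <- v[u, c("chrom", "pos", "ref", "alt", "vclass", "group")]
  n <- nrow(uv)
  gene <- sprintf("GS%04d", (uv$pos - 1L) %/% 20000L + 1L)
  term <- character(n)
  snv <- uv$vclass == "SNV"
  term[snv] <- sample(names(SNV_TERM_PROBS), sum(snv), replace = TRUE,
                      prob = SNV_TERM_PROBS)
  term[!snv] <- sample(names(INDEL_TERM_PROBS), sum(!snv), replace = TRUE,
                       prob = INDEL_TERM_PROBS)
  impact <- unname(TERM_IMPACT[term])
  revel <- rep(NA_real_, n)
  mis <- which(term == "missense")
  path_mis <- runif(length(mis)) < cfg$pathogenic_missense_fraction
  revel[mis] <- ifelse(path_mis, runif(length(mis), 0.5, 1),
                       runif(length(mis), 0, 0.5))
  aloft <- rep("not_applicable", n)
  trunc <- which(term %in% TRUNCATING_TERMS)
  aloft[trunc] <- ifelse(runif(length(trunc)) < cfg$aloft_high_confidence_fraction,
                         "high_confidence_truncation", "low_confidence")
  aa <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L", "M", "N", "P",
          "Q", "R", "S", "T", "V", "W", "Y")
  prot <- rep(NA_character_, n)
  coding <- term %in% c("missense", "stop_gained", "stop_lost")
  prot[coding] <- paste0(sample(aa, sum(coding), TRUE),
                         uv$pos[coding] %% 997L + 1L,
                         sample(aa, sum(coding), TRUE))
  tab <- data.frame(
    Chromosome = uv$chrom, Position = uv$pos, Ref = uv$ref, Alt = uv$alt,
    Vep_gene = gene, Vep_consequence = term, Vep_impact = impact,
    Transcript_id = paste0("TS_", gene, ".1"), Protein_change = prot,
    Group = uv$group, Revel_score = revel, Aloft = aloft,
    stringsAsFactors = FALSE
  )
  # secondary milder transcript records for ~10% of coding variants
  sec <- which(coding & runif(n) < 0.1)
  if (length(sec)) {
    extra <- tab[sec, , drop = FALSE]
    extra$Vep_consequence <- "intron"
    extra$Vep_impact <- "MODIFIER"
    extra$Transcript_id <- paste0("TS_", gene[sec], ".2")
    extra$Protein_change <- NA_character_
    extra$Revel_score <- NA_real_
    extra$Aloft <- "not_applicable"
    tab <- rbind(tab, extra)
  }
  tab <- tab[order(tab$Position, tab$Transcript_id), , drop = FALSE]
  rownames(tab) <- NULL
  if (!is.null(path))
    write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- data.frame(
    key = variant_key(data.frame(chrom = uv$chrom, pos = uv$pos,
                                 ref = uv$ref, alt = uv$alt)),
    term = term,
    is_pam = term %in% c("missense", "stop_gained", "frameshift",
                         "inframe_deletion", "stop_lost", "splice_donor",
                         "splice_acceptor") & impact %in% c("HIGH", "MODERATE"),
    revel_pathogenic = !is.na(revel) & revel > 0.5,
    aloft_lof = aloft == "high_confidence_truncation",
    stringsAsFactors = FALSE
  )
  list(table = tab, truth = truth)
}

#' Write a full synthetic study directory
#'
#' Runs the whole generator and writes: reference FASTA with a plain-text
#' `.fai` index, two caller VCFs per individual, the frequency-panel TSV, the
#' consequence TSV, dosimetry metadata and a JSON truth summary.
#'
#' @param config a `simulation_config`.
#' @param dir output directory.
#' @return (invisibly) a list with the in-memory `ref`, `cohort`, emitted
#'   file manifest, `panel`, `consequence`, `metadata` and file `paths`.
#' @export
simulate_to_dir <- function(config, dir) {
  validate_simulation_config(config)
  if (!dir.exists(dir) && !dir.create(dir, recursive = TRUE))
    rad_abort(sprintf("cannot create output directory '%s'", dir), "io_error")
  ref <- generate_reference(config$ref_length, config$gc_fraction,
                            config$cpg_rate, config$seed, config$ref_name)
  fa <- file.path(dir, "reference.fa")
  dss <- Biostrings::DNAStringSet(setNames(ref$sequence, ref$name))
  Biostrings::writeXStringSet(dss, fa, width = 70L)
  writeLines(paste(ref$name, config$ref_length, nchar(ref$name) + 2L, 70L, 71L,
                   sep = "\t"), paste0(fa, ".fai"))
  cohort <- simulate_cohort(ref, config)
  vcfs <- emit_caller_vcfs(cohort, file.path(dir, "vcf"))
  panel <- make_frequency_panel(cohort, path = file.path(dir, "frequency_panel.tsv"))
  csq <- make_consequence_table(cohort, path = file.path(dir, "consequences.tsv"))
  meta <- simulate_metadata(config)
  write.table(meta, file.path(dir, "metadata.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)
  write.table(cohort$variants, file.path(dir, "truth_variants.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  truth <- list(
    planted_cpg_ct_fraction = cohort$truth$cpg_ct_fraction_by_group,
    weights_by_group = cohort$truth$weights_by_group,
    n_variants = nrow(cohort$variants),
    common_fraction = config$common_fraction
  )
  jsonlite::write_json(truth, file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  invisible(list(ref = ref, cohort = cohort, vcfs = vcfs, panel = panel,
                 consequence = csq, metadata = meta,
                 paths = list(dir = dir, fasta = fa,
                              panel = file.path(dir, "frequency_panel.tsv"),
                              consequences = file.path(dir, "consequences.tsv"),
                              metadata = file.path(dir, "metadata.tsv"))))
}

# Synthetic dosimetry metadata: indoor/outdoor dose rates solved so that the
# computed annual dose matches the per-group target distribution.
simulate_metadata <- function(config) {
  set.seed(config$seed + 4L)
  samples <- unlist(lapply(config$groups, function(g)
    paste0(g, "_", seq_len(config$n_per_group))))
  groups <- rep(config$groups, each = config$n_per_group)
  dose <- pmax(0.05, rnorm(length(samples),
                           config$group_dose_mean[groups],
                           config$group_dose_sd[groups]))
  f <- conversion_factor()
  o <- config$occupancy_indoor
  rate <- dose / f
  delta <- runif(length(samples), -0.2, 0.2)
  indoor <- rate * (1 + delta * (1 - o))
  outdoor <- rate * (1 - delta * o)
  data.frame(sample = samples, group = groups,
             indoor_rate = indoor, outdoor_rate = outdoor,
             occupancy_indoor = o,
             annual_dose = annual_dose(indoor, outdoor, o),
             stringsAsFactors = FALSE)
}
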