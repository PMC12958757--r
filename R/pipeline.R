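# End-to-end orchestration: dosimetry arithmetic, YAML configuration,
# the simulate -> filter -> spectrum -> statistics -> consequence run,
# and the reproducibility manifest.

#' Gamma dose-rate conversion factor
#'
#' The published survey factor converting a measured ambient gamma dose rate
#' to an annual absorbed dose in mGy/year: 0.0767, i.e. the standard
#' air-kerma coefficient 0.876 x 24 h x 365 days x 1e-5 rounded to four
#' decimals.
#'
#' @return the conversion factor (numeric scalar).
#' @export
conversion_factor <- function() 0.0767

#' Annual absorbed dose from indoor/outdoor dose rates
#'
#' `dose = factor * (occupancy_indoor * indoor_rate +
#' (1 - occupancy_indoor) * outdoor_rate)`.  Occupancy is a per-individual
#' input (age- and sex-specific values come from survey references, not from
#' this package).
#'
#' @param indoor_rate,outdoor_rate measured dose rates (>= 0).
#' @param occupancy_indoor indoor occupancy fraction in [0,1].
#' @return annual dose in mGy/year.
#' @export
annual_dose <- function(indoor_rate, outdoor_rate, occupancy_indoor) {
  if (any(indoor_rate < 0) || any(outdoor_rate < 0))
    rad_abort("dose rates must be nonnegative", "contract_violation")
  if (any(occupancy_indoor < 0 | occupancy_indoor > 1))
    rad_abort("occupancy_indoor must lie in [0,1]", "contract_violation")
  conversion_factor() *
    (occupancy_indoor * indoor_rate + (1 - occupancy_indoor) * outdoor_rate)
}

#' Read/write a pipeline configuration
#'
#' The YAML config mirrors [simulation_config()] plus pipeline settings
#' (`thresholds`, `min_carriers`, `target_size_mb`, `kmer_k`).  Unknown keys
#' are rejected; a missing or invalid value fails validation before any stage
#' runs.
#'
#' @param path YAML file.
#' @return a validated config list (class `pipeline_config`).
#' @export
read_pipeline_config <- function(path) {
  raw <- yaml::read_yaml(path)
  as_pipeline_config(raw)
}

#' @rdname read_pipeline_config
#' @param x a plain list (e.g. from [simulation_config()] defaults).
#' @export
as_pipeline_config <- function(x) {
  sim_args <- names(formals(simulation_config))
  pipe_keys <- c("thresholds", "min_carriers", "target_size_mb", "kmer_k")
  unknown <- setdiff(names(x), c(sim_args, pipe_keys))
  if (length(unknown))
    rad_abort(sprintf("unknown config key(s): %s",
                      paste(unknown, collapse = ", ")), "invalid_config")
  # YAML maps arrive as named lists; the config wants named vectors
  for (f in c("base_spectrum", "cpg_ct_multiplier_by_group",
              "group_dose_mean", "group_dose_sd", "groups"))
    if (!is.null(x[[f]])) x[[f]] <- unlist(x[[f]])
  sim <- do.call(simulation_config, x[intersect(names(x), sim_args)])
  thr <- default_thresholds()
  if (!is.null(x$thresholds)) {
    bad <- setdiff(names(x$thresholds), names(thr))
    if (length(bad))
      rad_abort(sprintf("unknown threshold(s): %s", paste(bad, collapse = ", ")),
                "invalid_config")
    thr[names(x$thresholds)] <- x$thresholds
  }
  cfg <- list(sim = sim, thresholds = thr,
              min_carriers = as.integer(x$min_carriers %||% 2L),
              target_size_mb = x$target_size_mb %||% (sim$ref_length / 1e6),
              kmer_k = as.integer(x$kmer_k %||% 5L))
  class(cfg) <- "pipeline_config"
  cfg
}

#' @rdname read_pipeline_config
#' @param cfg a `pipeline_config`.
#' @export
write_pipeline_config <- function(cfg, path) {
  sim <- unclass(cfg$sim)
  # write named vectors as YAML maps so names survive the round trip
  for (f in c("base_spectrum", "cpg_ct_multiplier_by_group",
              "group_dose_mean", "group_dose_sd"))
    sim[[f]] <- as.list(sim[[f]])
  yaml::write_yaml(c(sim, list(thresholds = cfg$thresholds,
                               min_carriers = cfg$min_carriers,
                               target_size_mb = cfg$target_size_mb,
                               kmer_k = cfg$kmer_k)), path)
  invisible(path)
}

#' Run the full analysis pipeline on a simulated study
#'
#' Fixed, logged stage order: simulate -> per-caller hard filters ->
#' two-caller intersection -> polymorphism (MAF) filter -> spectrum ->
#' group statistics -> consequence triage -> report.  Every random element
#' derives from the config seed, so two runs with the same config produce
#' byte-identical result bundles.  Writes, under `out_dir`: the simulated
#' study (`sim/`), `filtered_variants.tsv`, `filter_log.tsv`, spectrum
#' matrices, `comparisons.tsv`, `pca_scores.tsv`, `pam_table.tsv`,
#' `revel_top.tsv`, `report.json` and `manifest.json` (with per-file md5
#' checksums).
#'
#' @param config a `pipeline_config`, a plain list coercible to one, or a
#'   YAML path.
#' @param out_dir output directory.
#' @param cancer_gene_list path to a predisposition gene list; defaults to
#'   the illustrative synthetic list shipped with the package.
#' @return (invisibly) the report list.
#' @export
run_pipeline <- function(config, out_dir,
                         cancer_gene_list = system.file(
                           "extdata", "cancer_predisposition_genes_synthetic.txt",
                           package = "radspectra")) {
  cfg <- if (inherits(config, "pipeline_config")) config
         else if (is.character(config)) read_pipeline_config(config)
         else as_pipeline_config(config)
  if (!dir.exists(out_dir) && !dir.create(out_dir, recursive = TRUE))
    rad_abort(sprintf("cannot create output directory '%s'", out_dir), "io_error")
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      rad_abort(sprintf("stage '%s' failed: %s", name, conditionMessage(e)),
                "stage_error"))
  }

  # --- simulate -------------------------------------------------------------
  sim <- stage("simulate", simulate_to_dir(cfg$sim, file.path(out_dir, "sim")))
  ref <- sim$ref
  groups <- sim$cohort$samples
  panel <- sim$panel$panel

  # --- filtering cascade per individual ------------------------------------
  filt <- stage("filter", {
    res <- lapply(names(groups), function(sm) {
      va <- read_vcf(file.path(out_dir, "sim", "vcf",
                               sprintf("%s.caller_a.vcf", sm)), sm, "caller_a")
      vb <- read_vcf(file.path(out_dir, "sim", "vcf",
                               sprintf("%s.caller_b.vcf", sm)), sm, "caller_b")
      consensus_filter(va, vb, panel, cfg$thresholds)
    })
    list(retained = do.call(rbind, lapply(res, `[[`, "retained")),
         log = do.call(rbind, Map(cbind, sample = names(groups),
                                  lapply(res, `[[`, "log"))))
  })
  retained <- filt$retained
  write_variant_table(retained, file.path(out_dir, "filtered_variants.tsv"))
  write.table(filt$log, file.path(out_dir, "filter_log.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)

  snvs <- retained[retained$vclass == "SNV", , drop = FALSE]

  # --- spectrum -------------------------------------------------------------
  spec_d <- stage("spectrum", build_spectrum(snvs, ref, "dinucleotide",
                                             groups = groups,
                                             samples = names(groups)))
  spec_k <- stage("spectrum", build_spectrum(snvs, ref, "kmer", k = cfg$kmer_k,
                                             groups = groups,
                                             samples = names(groups)))
  write_spectrum(spec_d, file.path(out_dir, "spectrum_dinucleotide.tsv"))
  write_spectrum(spec_k, file.path(out_dir, sprintf("spectrum_%dmer.tsv",
                                                    cfg$kmer_k)))
  write_spectrum(spec_d, file.path(out_dir, "spectrum_dinucleotide_freq.tsv"),
                 normalized = TRUE)

  # --- group statistics -----------------------------------------------------
  stats <- stage("statistics", {
    counts <- per_sample_counts(retained, groups = groups)
    cmp <- compare_cpg_ct(snvs, ref, groups, mode = c("all", "group_unique"),
                          min_carriers = cfg$min_carriers)
    cv <- cohort_variants(snvs, groups)
    gu <- group_unique_variants(cv, cfg$min_carriers)
    pca <- pca_contexts(spec_k)
    tot <- mann_whitney(counts$n_snv[groups[counts$sample] == cfg$sim$groups[1]],
                        counts$n_snv[groups[counts$sample] == cfg$sim$groups[2]])
    list(counts = counts, cmp = cmp, unique_counts = vapply(gu, nrow, 0L),
         pca = pca, total_snv_test = tot)
  })
  write.table(stats$counts, file.path(out_dir, "per_sample_counts.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  cmp_tab <- rbind(
    data.frame(comparison = "total_snv_count", mode = "all",
               statistic = stats$total_snv_test$statistic,
               p_value = stats$total_snv_test$p_value),
    data.frame(comparison = "cpg_ct_count", mode = stats$cmp$mode,
               statistic = stats$cmp$statistic, p_value = stats$cmp$p_value)
  )
  cmp_tab$p_adjusted <- fdr_adjust(cmp_tab$p_value)
  write.table(cmp_tab, file.path(out_dir, "comparisons.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(data.frame(sample = rownames(stats$pca$scores),
                         stats$pca$scores[, seq_len(min(4, ncol(stats$pca$scores))),
                                          drop = FALSE]),
              file.path(out_dir, "pca_scores.tsv"), sep = "\t", quote = FALSE,
              row.names = FALSE)

  # --- consequence triage ---------------------------------------------------
  csq <- stage("consequence", {
    tab <- sim$consequence$table
    retained_keys <- variant_key(data.frame(chrom = retained$chrom,
                                            pos = retained$pos,
                                            ref = retained$ref,
                                            alt = retained$alt))
    tk <- variant_key(data.frame(chrom = tab$Chromosome, pos = tab$Position,
                                 ref = tab$Ref, alt = tab$Alt))
    tab <- tab[tk %in% retained_keys, , drop = FALSE]
    tab$is_pam <- classify_pam(tab$Vep_consequence, tab$Vep_impact)
    pam <- tab[tab$is_pam, , drop = FALSE]
    by_grp <- split(pam$Vep_gene, pam$Group)
    glev <- cfg$sim$groups
    venn <- gene_set_report(by_grp[[glev[1]]] %||% character(0),
                            by_grp[[glev[2]]] %||% character(0))
    cancer <- cancer_gene_overlap(
      lapply(glev, function(g) by_grp[[g]] %||% character(0)) |>
        setNames(glev), cancer_gene_list)
    list(table = tab, pam = pam, venn = venn,
         revel = revel_triage(tab, cfg$thresholds$revel %||% 0.5),
         lof = aloft_triage(tab),
         region = region_distribution(tab), cancer = cancer)
  })
  write.table(csq$pam, file.path(out_dir, "pam_table.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  write.table(head(csq$revel, 20L), file.path(out_dir, "revel_top.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)

  # --- report + manifest ----------------------------------------------------
  meta <- sim$metadata
  dose_by_group <- lapply(split(meta$annual_dose, meta$group), function(d)
    list(mean = mean(d), sd = sd(d)))
  gsum <- attr(stats$counts, "group_summary")
  report <- list(
    groups = cfg$sim$groups,
    per_group_counts = gsum,
    snv_per_megabase_by_group = setNames(
      per_megabase_rate(gsum$mean_snv, cfg$target_size_mb), gsum$group),
    total_snv_p = stats$total_snv_test$p_value,
    mutation_type_fractions = colSums(spec_d$counts) / sum(spec_d$counts),
    cpg_ct_comparison = stats$cmp[, c("mode", "statistic", "p_value")],
    group_unique_snvs = as.list(stats$unique_counts),
    pam_count_by_group = as.list(table(csq$pam$Group)),
    venn_genes = list(unique_a = length(csq$venn$unique_to_a),
                      unique_b = length(csq$venn$unique_to_b),
                      common = length(csq$venn$common)),
    revel_pathogenic_by_group = as.list(table(csq$revel$Group)),
    aloft_lof_by_group = as.list(table(csq$lof$Group)),
    region_distribution = csq$region,
    dose_mGy_per_year = dose_by_group,
    seed = cfg$sim$seed
  )
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = 10, pretty = TRUE)
  outputs <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  outputs <- setdiff(outputs, file.path(out_dir, "manifest.json"))
  manifest <- list(
    package_version = as.character(utils::packageVersion("radspectra")),
    seed = cfg$sim$seed,
    config = c(unclass(cfg$sim), list(thresholds = cfg$thresholds,
                                      min_carriers = cfg$min_carriers,
                                      target_size_mb = cfg$target_size_mb,
                                      kmer_k = cfg$kmer_k)),
    checksums = as.list(setNames(unname(tools::md5sum(outputs)),
                                 sub(paste0("^", out_dir, "/?"), "", outputs)))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(report)
}
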