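# VCF ingestion and the consensus filtering cascade:
# per-caller hard filters -> two-caller intersection -> MAF-based
# polymorphism removal.

#' Default filtering thresholds
#'
#' GATK-style hard-filter thresholds for SNVs and indels, the supporting-read
#' rule for indels, and the population-frequency cutoff.  All are exposed so
#' any threshold can be overridden per call.
#' @return named list of thresholds.
#' @export
default_thresholds <- function() {
  list(qd = 2.0, qual = 30.0, sor = 3.0, fs = 60.0, mq = 40.0,
       mqranksum = -12.5, readposranksum = -8.0,
       fs_indel = 200.0, readposranksum_indel = -20.0,
       indel_support = 20L, maf = 0.01)
}

# left-align to minimal representation: trim shared suffix, then shared
# prefix, always keeping an anchor base (D1)
normalize_alleles <- function(pos, ref, alt) {
  for (i in seq_along(pos)) {
    r <- ref[i]; a <- alt[i]; p <- pos[i]
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, nchar(r), nchar(r)) == substr(a, nchar(a), nchar(a))) {
      r <- substr(r, 1L, nchar(r) - 1L)
      a <- substr(a, 1L, nchar(a) - 1L)
    }
    while (nchar(r) > 1L && nchar(a) > 1L &&
           substr(r, 1L, 1L) == substr(a, 1L, 1L)) {
      r <- substr(r, 2L, nchar(r)); a <- substr(a, 2L, nchar(a)); p <- p + 1L
    }
    ref[i] <- r; alt[i] <- a; pos[i] <- p
  }
  list(pos = pos, ref = ref, alt = alt)
}

#' Read a single-sample caller VCF into a variant table
#'
#' Parses a VCFv4.x file (via vcfR), splits multiallelic records into one row
#' per alternate allele, normalizes indel alleles to their minimal left-aligned
#' representation, maps QD/SOR/FS/MQ/MQRankSum/ReadPosRankSum annotations (an
#' absent annotation stays `NA`), and derives the alternate-supporting read
#' depth from the AD genotype field.  Records whose FILTER column is neither
#' `PASS` nor `.` are dropped (the Strelka-like caller's own quality verdict;
#' GATK-like files carry `.` and are filtered downstream instead).
#'
#' @param path VCF file path (plain or gzipped).
#' @param sample individual id to stamp on every row.
#' @param caller caller id (e.g. "caller_a", "caller_b").
#' @return data.frame with columns chrom, pos, ref, alt, vclass, sample,
#'   caller, qd, qual, sor, fs, mq, mqranksum, readposranksum, support_reads.
#' @export
read_vcf <- function(path, sample, caller) {
  if (!file.exists(path))
    rad_abort(sprintf("VCF '%s' not found", path), "io_error")
  lines <- readLines(path, warn = FALSE)
  body <- which(!startsWith(lines, "#"))
  nf <- lengths(strsplit(lines[body], "\t", fixed = TRUE))
  if (any(nf < 8L))
    rad_abort(sprintf("malformed VCF line %d in '%s' (fewer than 8 columns)",
                      body[which(nf < 8L)[1]], path), "parse_error")
  hdr <- grep("^#CHROM", lines, value = TRUE)
  if (length(hdr) != 1L)
    rad_abort(sprintf("'%s' lacks a #CHROM header line", path), "format_error")
  need <- c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO")
  have <- strsplit(hdr, "\t", fixed = TRUE)[[1]]
  if (!all(need %in% have))
    rad_abort(sprintf("'%s' is missing required columns: %s", path,
                      paste(setdiff(need, have), collapse = ", ")),
              "format_error")
  v <- tryCatch(vcfR::read.vcfR(path, verbose = FALSE),
                error = function(e)
                  rad_abort(sprintf("failed to parse '%s': %s", path,
                                    conditionMessage(e)), "parse_error"))
  fix <- vcfR::getFIX(v)
  if (is.null(dim(fix)) || nrow(fix) == 0L) {
    out <- empty_variants()
    return(out)
  }
  keep <- fix[, "FILTER"] %in% c("PASS", ".", NA)
  num_info <- function(tag) suppressWarnings(
    as.numeric(vcfR::extract.info(v, element = tag)))
  qd <- num_info("QD"); sor <- num_info("SOR"); fs <- num_info("FS")
  mq <- num_info("MQ"); mqrs <- num_info("MQRankSum")
  rprs <- num_info("ReadPosRankSum")
  qual <- suppressWarnings(as.numeric(fix[, "QUAL"]))
  ad <- tryCatch(vcfR::extract.gt(v, element = "AD")[, 1L],
                 error = function(e) rep(NA_character_, nrow(fix)))
  alts <- strsplit(fix[, "ALT"], ",", fixed = TRUE)
  n_alt <- lengths(alts)
  idx <- rep(seq_len(nrow(fix)), n_alt)
  alt_rank <- sequence(n_alt)
  ad_split <- strsplit(ifelse(is.na(ad), "", ad), ",", fixed = TRUE)
  support <- vapply(seq_along(idx), function(j) {
    parts <- ad_split[[idx[j]]]
    if (length(parts) > alt_rank[j])
      suppressWarnings(as.integer(parts[alt_rank[j] + 1L]))
    else NA_integer_
  }, integer(1))
  norm <- normalize_alleles(as.integer(fix[idx, "POS"]),
                            fix[idx, "REF"], unlist(alts))
  out <- data.frame(
    chrom = fix[idx, "CHROM"], pos = norm$pos, ref = norm$ref, alt = norm$alt,
    vclass = ifelse(is_snv(norm$ref, norm$alt), "SNV", "indel"),
    sample = sample, caller = caller,
    qd = qd[idx], qual = qual[idx], sor = sor[idx], fs = fs[idx], mq = mq[idx],
    mqranksum = mqrs[idx], readposranksum = rprs[idx],
    support_reads = support, stringsAsFactors = FALSE
  )
  out <- out[keep[idx], , drop = FALSE]
  rownames(out) <- NULL
  out
}

# generic verdict builder: checks is a named list of logical fail vectors in
# priority order; returns pass + first violated rule
first_violation <- function(n, checks) {
  reason <- rep(NA_character_, n)
  for (nm in rev(names(checks))) {
    bad <- checks[[nm]]
    bad[is.na(bad)] <- FALSE  # absent metrics never fail (D2)
    reason[bad] <- nm
  }
  data.frame(pass = is.na(reason), reason = reason, stringsAsFactors = FALSE)
}

#' Hard-filter verdicts for SNVs
#'
#' Fails a variant iff any *present* metric violates QD < 2, QUAL < 30,
#' SOR > 3, FS > 60, MQ < 40, MQRankSum < -12.5 or ReadPosRankSum < -8.
#' Absent annotations never cause failure.  The verdict names the first
#' violated rule.
#'
#' @param v variant data.frame (all rows must be SNVs).
#' @param thresholds threshold list, see [default_thresholds()].
#' @return data.frame with columns `pass` (logical) and `reason`.
#' @export
snv_hard_filter <- function(v, thresholds = default_thresholds()) {
  if (any(v$vclass != "SNV"))
    rad_abort("snv_hard_filter called on non-SNV rows", "contract_violation")
  t <- thresholds
  first_violation(nrow(v), list(
    QD = v$qd < t$qd, QUAL = v$qual < t$qual, SOR = v$sor > t$sor,
    FS = v$fs > t$fs, MQ = v$mq < t$mq,
    MQRankSum = v$mqranksum < t$mqranksum,
    ReadPosRankSum = v$readposranksum < t$readposranksum))
}

#' Hard-filter verdicts for indels
#'
#' Fails a variant iff QD < 2, QUAL < 30, FS > 200, ReadPosRankSum < -20, or
#' the alternate allele is supported by 20 or fewer reads (the "greater than
#' 20 reads" rule is strict: exactly 20 fails).
#'
#' @inheritParams snv_hard_filter
#' @return data.frame with columns `pass` and `reason`.
#' @export
indel_hard_filter <- function(v, thresholds = default_thresholds()) {
  if (any(v$vclass != "indel"))
    rad_abort("indel_hard_filter called on non-indel rows", "contract_violation")
  t <- thresholds
  first_violation(nrow(v), list(
    QD = v$qd < t$qd, QUAL = v$qual < t$qual, FS = v$fs > t$fs_indel,
    ReadPosRankSum = v$readposranksum < t$readposranksum_indel,
    `read support` = v$support_reads <= t$indel_support))
}

#' Intersect the variant sets of two callers
#'
#' Returns variants whose `(chrom, pos, ref, alt)` key occurs in both input
#' tables for the same sample.  The surviving record carries the caller_b
#' metrics when both callers report the key (a single consistent source; no
#' metric is re-used downstream).
#'
#' @param set_a,set_b variant data.frames from the two callers, same sample.
#' @return data.frame, a subset of `set_b` rows (key-wise also of `set_a`).
#' @export
intersect_callers <- function(set_a, set_b) {
  sa <- unique(set_a$sample); sb <- unique(set_b$sample)
  if (length(sa) > 1L || length(sb) > 1L ||
      (length(sa) == 1L && length(sb) == 1L && sa != sb))
    rad_abort("intersect_callers requires both sets from one common sample",
              "contract_violation")
  out <- set_b[variant_key(set_b) %in% variant_key(set_a), , drop = FALSE]
  out <- out[order(out$chrom, out$pos, out$ref, out$alt), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Read a population frequency panel
#'
#' @param path TSV with columns chrom, pos, ref, alt, maf_panel1, maf_panel2
#'   (NA where a key is absent from a panel).
#' @return data.frame; frequencies validated to lie in [0,1].
#' @export
read_frequency_panel <- function(path) {
  p <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "pos", "ref", "alt", "maf_panel1", "maf_panel2")
  if (!all(need %in% names(p)))
    rad_abort(sprintf("frequency panel '%s' is missing columns: %s", path,
                      paste(setdiff(need, names(p)), collapse = ", ")),
              "format_error")
  mafs <- c(p$maf_panel1, p$maf_panel2)
  if (any(mafs < 0 | mafs > 1, na.rm = TRUE))
    rad_abort("panel frequencies must lie in [0,1]", "format_error")
  p
}

#' Remove common polymorphisms by panel frequency
#'
#' A variant is removed iff its MAF exceeds `threshold` in at least one panel
#' (the stricter either-panel reading).  The inequality is strict: MAF exactly
#' at the threshold is retained.  Variants absent from both panels are treated
#' as rare and retained.
#'
#' @param vs variant data.frame.
#' @param panel frequency panel data.frame (see [read_frequency_panel()]).
#' @param threshold MAF cutoff in (0,1); default 0.01.
#' @return list with `retained` and `removed` data.frames
#'   (disjoint, union = input).
#' @export
filter_polymorphisms <- function(vs, panel, threshold = 0.01) {
  if (threshold <= 0 || threshold >= 1)
    rad_abort("threshold must lie in (0,1)", "invalid_config")
  pk <- variant_key(panel)
  i <- match(variant_key(vs), pk)
  m1 <- panel$maf_panel1[i]; m2 <- panel$maf_panel2[i]
  common <- (!is.na(m1) & m1 > threshold) | (!is.na(m2) & m2 > threshold)
  common[is.na(common)] <- FALSE
  list(retained = vs[!common, , drop = FALSE],
       removed = vs[common, , drop = FALSE])
}

#' Run the full consensus filtering cascade for one sample
#'
#' Stage order: per-caller hard filters (SNV and indel rules separately) ->
#' two-caller key intersection -> polymorphism removal by panel MAF.  Every
#' removed variant is returned with the stage and rule that removed it, and
#' the per-stage in/out counts are logged, so input = retained + removed at
#' every stage.
#'
#' @param set_a,set_b variant tables for the two callers (one sample).
#' @param panel frequency panel data.frame.
#' @param thresholds threshold list, see [default_thresholds()].
#' @return list: `retained` (final variants), `removed` (with stage, reason),
#'   `log` (stage, n_in, n_out).
#' @export
consensus_filter <- function(set_a, set_b, panel,
                             thresholds = default_thresholds()) {
  hard <- function(vs) {
    snv <- vs[vs$vclass == "SNV", , drop = FALSE]
    ind <- vs[vs$vclass == "indel", , drop = FALSE]
    vsnv <- snv_hard_filter(snv, thresholds)
    vind <- indel_hard_filter(ind, thresholds)
    tag <- function(d, stage, reason)
      if (nrow(d)) cbind(d, stage = stage, reason = reason) else NULL
    list(pass = rbind(snv[vsnv$pass, , drop = FALSE],
                      ind[vind$pass, , drop = FALSE]),
         fail = rbind(tag(snv[!vsnv$pass, , drop = FALSE], "hard_filter",
                          vsnv$reason[!vsnv$pass]),
                      tag(ind[!vind$pass, , drop = FALSE], "hard_filter",
                          vind$reason[!vind$pass])))
  }
  ha <- hard(set_a); hb <- hard(set_b)
  inter <- intersect_callers(ha$pass, hb$pass)
  dropped_a <- ha$pass[!(variant_key(ha$pass) %in% variant_key(hb$pass)), ,
                       drop = FALSE]
  dropped_b <- hb$pass[!(variant_key(hb$pass) %in% variant_key(ha$pass)), ,
                       drop = FALSE]
  maf <- filter_polymorphisms(inter, panel, thresholds$maf)
  removed <- rbind(
    ha$fail, hb$fail,
    if (nrow(dropped_a)) cbind(dropped_a, stage = "intersection",
                               reason = "single caller"),
    if (nrow(dropped_b)) cbind(dropped_b, stage = "intersection",
                               reason = "single caller"),
    if (nrow(maf$removed)) cbind(maf$removed, stage = "polymorphism",
                                 reason = sprintf("MAF > %g", thresholds$maf))
  )
  if (is.null(removed))
    removed <- data.frame(empty_variants(), stage = character(0),
                          reason = character(0))
  log <- data.frame(
    stage = c("hard_filter_a", "hard_filter_b", "intersection", "polymorphism"),
    n_in = c(nrow(set_a), nrow(set_b), nrow(ha$pass) + nrow(hb$pass),
             nrow(inter)),
    n_out = c(nrow(ha$pass), nrow(hb$pass), nrow(inter), nrow(maf$retained)),
    stringsAsFactors = FALSE
  )
  list(retained = maf$retained, removed = removed, log = log)
}

#' Write a flat variant table
#'
#' @param vs variant data.frame.
#' @param path output TSV path.
#' @export
write_variant_table <- function(vs, path) {
  write.table(vs, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a flat variant table written by [write_variant_table()]
#' @param path TSV path.
#' @return variant data.frame.
#' @export
read_variant_table <- function(path) {
  read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
             colClasses = c(chrom = "character", ref = "character",
                            alt = "character"))
}
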