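# Cohort-level aggregation and group statistics: per-sample counts,
# group-unique variants, exact Mann-Whitney, BH FDR, PCA over context
# matrices, and the CpG C>T group comparison.

#' Per-sample variant counts
#'
#' Exact multiset tallies of SNVs, indels and the six substitution classes
#' per individual.  When `groups` is supplied, per-group means and medians of
#' the SNV/indel counts are attached as attribute `"group_summary"`.
#'
#' @param vs variant data.frame (chrom, pos, ref, alt, vclass, sample).
#' @param groups optional named vector sample -> group; every sample in `vs`
#'   must be present in it.
#' @param samples optional character vector fixing the row set.
#' @return data.frame: sample, n_snv, n_indel, and one column per class.
#' @export
per_sample_counts <- function(vs, groups = NULL, samples = NULL) {
  samples <- samples %||% (if (!is.null(groups)) names(groups)
                           else sort(unique(vs$sample)))
  if (!is.null(groups) && !all(vs$sample %in% names(groups)))
    rad_abort(sprintf("unknown sample id(s): %s",
                      paste(setdiff(unique(vs$sample), names(groups)),
                            collapse = ", ")), "metadata_error")
  sm <- factor(vs$sample, levels = samples)
  out <- data.frame(
    sample = samples,
    n_snv = as.integer(table(sm[vs$vclass == "SNV"])),
    n_indel = as.integer(table(sm[vs$vclass == "indel"])),
    stringsAsFactors = FALSE
  )
  snv <- vs$vclass == "SNV"
  cls <- factor(classify_substitution(vs$ref[snv], vs$alt[snv]),
                levels = SUBSTITUTION_CLASSES)
  cls_tab <- table(sm[snv], cls)
  out <- cbind(out, as.data.frame.matrix(cls_tab))
  rownames(out) <- NULL
  if (!is.null(groups)) {
    g <- groups[out$sample]
    gs <- do.call(rbind, lapply(split(out, g), function(d)
      data.frame(group = unique(g[out$sample %in% d$sample]),
                 mean_snv = mean(d$n_snv), median_snv = median(d$n_snv),
                 mean_indel = mean(d$n_indel), median_indel = median(d$n_indel))))
    rownames(gs) <- NULL
    attr(out, "group_summary") <- gs
  }
  out
}

#' Variants per megabase
#'
#' @param count variant count.
#' @param target_size_mb sequencing target size in megabases (> 0); the
#'   denominator is a required input, not a constant.
#' @return rate = count / target_size_mb.
#' @export
per_megabase_rate <- function(count, target_size_mb) {
  if (any(target_size_mb <= 0))
    rad_abort("target_size_mb must be positive", "invalid_config")
  count / target_size_mb
}

#' Collapse per-sample variants into a cohort carrier map
#'
#' @param vs variant data.frame with a `sample` column.
#' @param groups named vector sample -> group.
#' @return data.frame: key, chrom, pos, ref, alt and one carrier-count column
#'   `n_<group>` per group.
#' @export
cohort_variants <- function(vs, groups) {
  if (!all(vs$sample %in% names(groups)))
    rad_abort("every sample in the variant table must appear in `groups`",
              "metadata_error")
  uv <- unique(vs[, c("chrom", "pos", "ref", "alt", "sample")])
  key <- variant_key(uv)
  glev <- unique(unname(groups))
  tab <- table(key, factor(groups[uv$sample], levels = glev))
  uk <- !duplicated(key)
  cv <- uv[uk, c("chrom", "pos", "ref", "alt")]
  cv <- cbind(key = key[uk], cv, stringsAsFactors = FALSE)
  i <- match(cv$key, rownames(tab))
  for (g in glev) cv[[paste0("n_", g)]] <- as.integer(tab[i, g])
  rownames(cv) <- NULL
  cv
}

#' Group-unique variants
#'
#' A variant is unique to group g iff it is carried by at least `min_carriers`
#' individuals of g and by no individual of any other group.  Assignments are
#' mutually exclusive by construction.
#'
#' @param cv cohort carrier map from [cohort_variants()].
#' @param min_carriers minimum carrier count within the group (default 2).
#' @return named list (one per group) of subsets of `cv`.
#' @export
group_unique_variants <- function(cv, min_carriers = 2L) {
  if (min_carriers < 1L)
    rad_abort("min_carriers must be >= 1", "invalid_config")
  gcols <- grep("^n_", names(cv), value = TRUE)
  out <- list()
  for (gc in gcols) {
    others <- setdiff(gcols, gc)
    sel <- cv[[gc]] >= min_carriers &
      rowSums(as.matrix(cv[, others, drop = FALSE])) == 0L
    out[[sub("^n_", "", gc)]] <- cv[sel, , drop = FALSE]
  }
  out
}

#' Two-sided Mann-Whitney U test
#'
#' Exact null distribution by complete enumeration of all rank labelings when
#' both samples have at most 8 observations and there are no ties; otherwise
#' a normal approximation with tie and continuity correction.  U is reported
#' for the first sample; the two-sided p doubles the smaller tail (capped at
#' 1).
#'
#' @param a,b numeric vectors (nonempty).
#' @return a `group_comparison`: list(statistic, p_value, method, sidedness,
#'   n_a, n_b).
#' @export
mann_whitney <- function(a, b) {
  if (!length(a) || !length(b))
    rad_abort("both samples must be nonempty", "contract_violation")
  n1 <- length(a); n2 <- length(b); N <- n1 + n2
  x <- c(a, b)
  r <- rank(x)
  U <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  ties <- anyDuplicated(x) > 0L
  if (!ties && n1 <= 8L && n2 <= 8L) {
    rank_sums <- colSums(combn(N, n1))
    usum <- rank_sums - n1 * (n1 + 1) / 2
    p <- min(1, 2 * min(mean(usum <= U), mean(usum >= U)))
    method <- "exact (complete enumeration)"
  } else {
    mu <- n1 * n2 / 2
    tt <- table(x)
    sig2 <- n1 * n2 / 12 * ((N + 1) - sum(tt^3 - tt) / (N * (N - 1)))
    if (sig2 <= 0) {
      p <- 1
    } else {
      z <- (U - mu - sign(U - mu) * 0.5) / sqrt(sig2)
      p <- min(1, 2 * pnorm(-abs(z)))
    }
    method <- "normal approximation (tie and continuity corrected)"
  }
  structure(list(statistic = U, p_value = p, method = method,
                 sidedness = "two-sided", n_a = n1, n_b = n2),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("Mann-Whitney U = %g (n = %d vs %d), two-sided p = %.4g [%s]\n",
              x$statistic, x$n_a, x$n_b, x$p_value, x$method))
  invisible(x)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjustment: `adj_(i) = min_{j >= i} m * p_(j) / j`, capped at 1,
#' returned in the input order.
#'
#' @param p_values numeric vector of p-values in [0,1].
#' @return adjusted p-values, same length and order.
#' @export
fdr_adjust <- function(p_values) {
  if (any(!is.finite(p_values) | p_values < 0 | p_values > 1))
    rad_abort("p-values must lie in [0,1]", "contract_violation")
  m <- length(p_values)
  if (m == 0L) return(numeric(0))
  o <- order(p_values)
  ps <- p_values[o]
  adj <- numeric(m)
  running <- 1
  for (j in m:1) {
    running <- min(running, m * ps[j] / j)
    adj[j] <- running
  }
  out <- numeric(m)
  out[o] <- adj
  out
}

#' PCA over a spectrum/context matrix
#'
#' Principal components of the per-sample category matrix.  Rows are
#' converted to per-sample frequencies by default (samples with different
#' totals stay commensurate); columns are centered, and scaled to unit
#' variance when `normalize` is set (constant columns are dropped before
#' scaling).
#'
#' @param m a `spectrum_matrix` or a plain numeric matrix (samples x
#'   categories).
#' @param normalize also scale columns to unit variance.
#' @param frequencies divide each row by its total first (default TRUE;
#'   ignored for plain matrices already holding frequencies).
#' @return list: `scores` (samples x components), `loadings`,
#'   `variance_fraction` (sums to 1 over retained components), `center`,
#'   `scale`.
#' @export
pca_contexts <- function(m, normalize = FALSE, frequencies = TRUE) {
  X <- if (inherits(m, "spectrum_matrix")) {
    if (frequencies) normalize_spectrum(m) else m$counts
  } else as.matrix(m)
  if (nrow(X) < 2L)
    rad_abort("PCA requires at least 2 samples", "contract_violation")
  if (ncol(X) < 2L)
    rad_abort("PCA requires at least 2 categories", "contract_violation")
  if (normalize) {
    keep <- apply(X, 2, function(col) sd(col) > 0)
    X <- X[, keep, drop = FALSE]
  }
  pc <- prcomp(X, center = TRUE, scale. = normalize)
  vf <- pc$sdev^2 / sum(pc$sdev^2)
  list(scores = pc$x, loadings = pc$rotation, variance_fraction = vf,
       center = pc$center, scale = pc$scale)
}

#' Compare per-sample C>T-at-CpG counts between groups
#'
#' The pipeline composition behind the study's headline contrast: optionally
#' restrict to group-unique variants (carried by >= `min_carriers`
#' individuals of one group and none of the other), partition each sample's
#' SNVs into C>T at CpG / C>T other / non-C>T against the reference, and run
#' a two-sided Mann-Whitney test on the per-sample C>T-at-CpG counts.  Both
#' the all-variants and group-unique modes are reported side by side by
#' default.
#'
#' @param vs filtered SNV data.frame (with `sample` column).
#' @param ref a `ref_seq`.
#' @param groups named vector sample -> group (exactly two groups).
#' @param mode character subset of c("all", "group_unique").
#' @param min_carriers carrier threshold for the group-unique restriction.
#' @return data.frame with one row per mode: mode, statistic, p_value,
#'   method, plus attribute `"per_sample"` (named list of the per-sample
#'   C>T-at-CpG count tables).  U is reported for the first group level.
#' @export
compare_cpg_ct <- function(vs, ref, groups,
                           mode = c("all", "group_unique"),
                           min_carriers = 2L) {
  mode <- match.arg(mode, several.ok = TRUE)
  glev <- unique(unname(groups))
  if (length(glev) != 2L)
    rad_abort("compare_cpg_ct requires exactly two groups", "contract_violation")
  vs <- vs[vs$vclass == "SNV", , drop = FALSE]
  per_sample <- list()
  rows <- list()
  for (md in mode) {
    use <- vs
    if (md == "group_unique") {
      cv <- cohort_variants(vs, groups)
      gu <- group_unique_variants(cv, min_carriers)
      allowed <- lapply(gu, function(d) d$key)
      use <- vs[variant_key(vs) %in% unlist(allowed), , drop = FALSE]
      # keep only rows whose sample belongs to the group the key is unique to
      kg <- rep(names(allowed), lengths(allowed))
      names(kg) <- unlist(allowed)
      use <- use[kg[variant_key(use)] == groups[use$sample], , drop = FALSE]
    }
    sp <- build_spectrum(use, ref, mode = "dinucleotide",
                         samples = names(groups), groups = groups)
    part <- cpg_ct_partition(sp)
    part$group <- unname(groups[part$sample])
    per_sample[[md]] <- part
    cmp <- mann_whitney(part$ct_cpg[part$group == glev[1]],
                        part$ct_cpg[part$group == glev[2]])
    rows[[md]] <- data.frame(mode = md, statistic = cmp$statistic,
                             p_value = cmp$p_value, method = cmp$method,
                             stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "per_sample") <- per_sample
  attr(out, "groups") <- glev
  out
}

#' Rejection rate of the CpG C>T group comparison over simulated cohorts
#'
#' Repeats the whole generative experiment over a vector of seeds — simulate
#' a cohort on a fixed reference, run [compare_cpg_ct()] in the requested
#' mode — and reports the fraction of seeds whose two-sided p-value falls at
#' or below `alpha`.  With the null configuration (all multipliers 1) this
#' estimates the test's type-I error; with an enriched group it estimates
#' power.
#'
#' @param ref a `ref_seq` shared across seeds.
#' @param config a `simulation_config`; its `seed` is overridden per run.
#' @param seeds integer vector of simulation seeds.
#' @param alpha significance level (default 0.05).
#' @param mode "all" or "group_unique" (default), see [compare_cpg_ct()].
#' @param min_carriers carrier threshold for the group-unique restriction.
#' @return list: `p_values`, `rejection_rate`, `alpha`, `n_seeds`.
#' @export
cpg_ct_rejection_rate <- function(ref, config, seeds, alpha = 0.05,
                                  mode = "group_unique", min_carriers = 2L) {
  ps <- vapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    co <- simulate_cohort(ref, cfg)
    snv <- co$variants[co$variants$vclass == "SNV", , drop = FALSE]
    compare_cpg_ct(snv, ref, co$samples, mode = mode,
                   min_carriers = min_carriers)$p_value
  }, numeric(1))
  list(p_values = ps, rejection_rate = mean(ps <= alpha), alpha = alpha,
       n_seeds = length(seeds))
}
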