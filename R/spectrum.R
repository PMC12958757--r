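# Substitution classification, CpG / k-mer sequence context against the
# reference, and per-sample spectrum matrices.

#' Classify a substitution into the six pyrimidine-normalized classes
#'
#' When the reference base is a purine both alleles are complemented (the
#' standard mutation-spectrum convention), so every SNV maps to exactly one of
#' C>A, C>G, C>T, T>A, T>C, T>G.
#'
#' @param ref_base,alt_base single-base character vectors (A/C/G/T).
#' @return character vector of classes.
#' @examples
#' classify_substitution("G", "A")  # "C>T"
#' @export
classify_substitution <- function(ref_base, alt_base) {
  if (length(ref_base) == 0L) return(character(0))
  if (any(nchar(ref_base) != 1L | nchar(alt_base) != 1L) ||
      any(!ref_base %in% BASES) || any(!alt_base %in% BASES))
    rad_abort("ref and alt must be single bases in {A,C,G,T}",
              "contract_violation")
  if (any(ref_base == alt_base))
    rad_abort("ref and alt must differ", "contract_violation")
  purine <- !(ref_base %in% PYRIMIDINES)
  r <- ifelse(purine, comp_base(ref_base), ref_base)
  a <- ifelse(purine, comp_base(alt_base), alt_base)
  paste0(r, ">", a)
}

ref_base_at <- function(ref, pos) substring(ref$sequence, pos, pos)

check_ref_site <- function(ref, chrom, pos, ref_base) {
  if (any(chrom != ref$name))
    rad_abort(sprintf("variant contig does not match reference '%s'",
                      ref$name), "consistency_error")
  L <- nchar(ref$sequence)
  if (any(pos < 1L | pos > L))
    rad_abort("position outside reference contig", "bounds_error")
  have <- ref_base_at(ref, pos)
  if (any(have != ref_base))
    rad_abort("reference allele does not match reference sequence",
              "consistency_error")
  invisible(L)
}

#' CpG context of a variant position
#'
#' A position is "CpG" iff, on the strand where the mutated base reads as the
#' pyrimidine C, the 3' neighbor is G: reference context `C G` starting at
#' `pos` when the reference base is C, or ending at `pos` (preceding base C)
#' when it is G.  T/A reference bases, and contig-edge positions lacking the
#' needed neighbor, are "other".
#'
#' @param ref a `ref_seq`.
#' @param chrom contig id (must match the reference).
#' @param pos 1-based positions.
#' @param ref_base reference alleles at `pos` (validated).
#' @return character vector, "CpG" or "other".
#' @export
cpg_context <- function(ref, chrom, pos, ref_base) {
  L <- check_ref_site(ref, chrom, pos, ref_base)
  nxt <- ifelse(pos < L, substring(ref$sequence, pos + 1L, pos + 1L), "")
  prv <- ifelse(pos > 1L, substring(ref$sequence, pos - 1L, pos - 1L), "")
  ifelse(ref_base == "C" & nxt == "G", "CpG",
         ifelse(ref_base == "G" & prv == "C", "CpG", "other"))
}

#' k-mer sequence context of a substitution
#'
#' Extracts the k-mer centered on the variant; when the reference base is a
#' purine the k-mer is reverse-complemented (and the alternate complemented)
#' so the central base is a pyrimidine.  Positions with fewer than (k-1)/2
#' flanking bases on either side are excluded (`NA`), never padded.
#'
#' @inheritParams cpg_context
#' @param alt_base alternate alleles.
#' @param k odd integer >= 3; default 5.
#' @return character vector of labels like `"CA[C>T]GG"`; `NA` for excluded
#'   edge positions.
#' @export
kmer_context <- function(ref, chrom, pos, ref_base, alt_base, k = 5L) {
  if (k %% 2L != 1L || k < 3L)
    rad_abort("k must be an odd integer >= 3", "contract_violation")
  L <- check_ref_site(ref, chrom, pos, ref_base)
  fl <- (k - 1L) %/% 2L
  ok <- pos - fl >= 1L & pos + fl <= L
  out <- rep(NA_character_, length(pos))
  if (!any(ok)) return(out)
  km <- substring(ref$sequence, pos[ok] - fl, pos[ok] + fl)
  alt <- alt_base[ok]
  purine <- !(ref_base[ok] %in% PYRIMIDINES)
  km[purine] <- revcomp(km[purine])
  alt[purine] <- comp_base(alt[purine])
  left <- substr(km, 1L, fl)
  center <- substr(km, fl + 1L, fl + 1L)
  right <- substr(km, fl + 2L, k)
  out[ok] <- paste0(left, "[", center, ">", alt, "]", right)
  out
}

dinuc_categories <- function() {
  as.vector(outer(SUBSTITUTION_CLASSES, c("CpG", "other"),
                  function(cl, cx) paste0(cl, ":", cx)))
}

#' Build a per-sample substitution-spectrum matrix
#'
#' Counts every SNV once by (sample, substitution class, context).  In
#' `dinucleotide` mode the context is CpG vs other (all 12 class:context
#' columns always present); in `kmer` mode the context is the k-mer label and
#' edge positions without full flanks are excluded and tallied separately.
#'
#' @param vs SNV data.frame (columns chrom, pos, ref, alt, sample).
#' @param ref a `ref_seq`.
#' @param mode "dinucleotide" or "kmer".
#' @param k k-mer width (odd), used in kmer mode.
#' @param groups optional named vector sample -> group, carried on the object.
#' @param samples optional character vector fixing the row set (samples with
#'   no variants get zero rows).
#' @return a `spectrum_matrix`: list with `counts` (samples x categories
#'   integer matrix), `mode`, `k`, `groups`, `excluded` (per-sample excluded
#'   SNV counts).
#' @export
build_spectrum <- function(vs, ref, mode = c("dinucleotide", "kmer"), k = 5L,
                           groups = NULL, samples = NULL) {
  mode <- match.arg(mode)
  if (any(vs$vclass != "SNV"))
    rad_abort("build_spectrum accepts SNVs only", "contract_violation")
  samples <- samples %||% sort(unique(vs$sample))
  if (nrow(vs) == 0L) {
    cats <- if (mode == "dinucleotide") dinuc_categories() else character(0)
    counts <- matrix(0L, length(samples), length(cats),
                     dimnames = list(samples, cats))
    return(structure(list(counts = counts, mode = mode, k = k, groups = groups,
                          excluded = setNames(rep(0L, length(samples)), samples)),
                     class = "spectrum_matrix"))
  }
  cls <- classify_substitution(vs$ref, vs$alt)
  if (mode == "dinucleotide") {
    ctx <- cpg_context(ref, vs$chrom, vs$pos, vs$ref)
    cat <- paste0(cls, ":", ctx)
    cats <- dinuc_categories()
    excluded_flag <- rep(FALSE, nrow(vs))
  } else {
    lab <- kmer_context(ref, vs$chrom, vs$pos, vs$ref, vs$alt, k)
    excluded_flag <- is.na(lab)
    cat <- lab
    cats <- sort(unique(lab[!excluded_flag]))
  }
  keep <- !excluded_flag
  tab <- table(factor(vs$sample[keep], levels = samples),
               factor(cat[keep], levels = cats))
  counts <- matrix(as.integer(tab), nrow = length(samples),
                   dimnames = list(samples, cats))
  excl <- table(factor(vs$sample[!keep], levels = samples))
  structure(list(counts = counts, mode = mode, k = k, groups = groups,
                 excluded = setNames(as.integer(excl), samples)),
            class = "spectrum_matrix")
}

#' @export
print.spectrum_matrix <- function(x, ...) {
  cat(sprintf("<spectrum_matrix> %s mode: %d samples x %d categories (%d excluded)\n",
              x$mode, nrow(x$counts), ncol(x$counts), sum(x$excluded)))
  invisible(x)
}

#' Row-normalized view of a spectrum matrix
#'
#' @param m a `spectrum_matrix`.
#' @return numeric matrix whose rows sum to 1 (all-zero rows stay zero).
#' @export
normalize_spectrum <- function(m) {
  rs <- rowSums(m$counts)
  out <- m$counts / ifelse(rs == 0, 1, rs)
  out
}

#' Partition per-sample counts into C>T at CpG / C>T other / non-C>T
#'
#' @param m a `spectrum_matrix` in dinucleotide mode.
#' @return data.frame: sample, ct_cpg, ct_other, non_ct (rows sum to the
#'   sample totals).
#' @export
cpg_ct_partition <- function(m) {
  if (!inherits(m, "spectrum_matrix") || m$mode != "dinucleotide")
    rad_abort("cpg_ct_partition requires a dinucleotide-mode spectrum_matrix",
              "contract_violation")
  cts <- m$counts
  data.frame(
    sample = rownames(cts),
    ct_cpg = as.integer(cts[, "C>T:CpG"]),
    ct_other = as.integer(cts[, "C>T:other"]),
    non_ct = as.integer(rowSums(cts) - cts[, "C>T:CpG"] - cts[, "C>T:other"]),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Write spectrum matrices as TSV
#' @param m a `spectrum_matrix`.
#' @param path output path.
#' @param normalized write per-sample frequencies instead of raw counts.
#' @export
write_spectrum <- function(m, path, normalized = FALSE) {
  x <- if (normalized) normalize_spectrum(m) else m$counts
  write.table(data.frame(sample = rownames(x), x, check.names = FALSE),
              path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
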