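# Protein-affecting mutation (PAM) classification, REVEL/ALoFT pathogenicity
# triage, genomic-region distributions and gene-set intersections.

PAM_TERMS <- c("missense", "stop_gained", "frameshift", "inframe_deletion",
               "stop_lost", "splice_donor", "splice_acceptor")
KNOWN_TERMS <- c(PAM_TERMS, "synonymous", "intron", "regulatory", "ncRNA")

# tolerate VEP-style vocabulary ("missense_variant", "intron_variant", ...)
normalize_term <- function(term) {
  t <- sub("_variant$", "", tolower(term))
  map <- c(missense = "missense", stop_gained = "stop_gained",
           frameshift = "frameshift", inframe_deletion = "inframe_deletion",
           stop_lost = "stop_lost", splice_donor = "splice_donor",
           splice_acceptor = "splice_acceptor", synonymous = "synonymous",
           intron = "intron", intronic = "intron", regulatory = "regulatory",
           regulatory_region = "regulatory", ncrna = "ncRNA",
           non_coding_transcript = "ncRNA", non_coding_transcript_exon = "ncRNA")
  out <- unname(map[t])
  out[is.na(out)] <- term[is.na(out)]
  out
}

#' Classify protein-affecting mutations (PAMs)
#'
#' A record is a PAM iff its consequence term is one of missense, stop
#' gained, frameshift, in-frame deletion, stop loss, splice donor or splice
#' acceptor AND its predicted impact is HIGH or MODERATE.  Unknown terms
#' produce one warning and classify as non-PAM.
#'
#' @param term consequence terms (VEP-style suffixes tolerated).
#' @param impact impact levels (HIGH/MODERATE/LOW/MODIFIER).
#' @return logical vector.
#' @export
classify_pam <- function(term, impact) {
  t <- normalize_term(term)
  unknown <- !(t %in% KNOWN_TERMS)
  if (any(unknown))
    warning(sprintf("unknown consequence term(s) treated as non-PAM: %s",
                    paste(unique(term[unknown]), collapse = ", ")),
            call. = FALSE)
  t %in% PAM_TERMS & toupper(impact) %in% c("HIGH", "MODERATE")
}

#' Read a consequence-annotation table
#'
#' @param path TSV with (at least) columns Chromosome, Position, Ref, Alt,
#'   Vep_gene, Vep_consequence, Vep_impact, Transcript_id, Revel_score;
#'   `col_map` can rename nonstandard headers (named vector new = old).
#' @param col_map optional named character vector mapping standard names to
#'   the file's column names.
#' @return data.frame.
#' @export
read_consequence_table <- function(path, col_map = NULL) {
  tab <- read.table(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    quote = "", na.strings = c("NA", "", "."))
  if (!is.null(col_map)) {
    for (std in names(col_map)) {
      if (!col_map[[std]] %in% names(tab))
        rad_abort(sprintf("column '%s' not found in '%s'", col_map[[std]], path),
                  "format_error")
      names(tab)[names(tab) == col_map[[std]]] <- std
    }
  }
  need <- c("Chromosome", "Position", "Ref", "Alt", "Vep_gene",
            "Vep_consequence", "Vep_impact")
  if (!all(need %in% names(tab)))
    rad_abort(sprintf("consequence table '%s' is missing columns: %s", path,
                      paste(setdiff(need, names(tab)), collapse = ", ")),
              "format_error")
  tab
}

#' REVEL pathogenicity triage
#'
#' Keeps records whose REVEL score is present and strictly greater than
#' `cutoff` (scores exactly at the cutoff are excluded), ranked by descending
#' score.
#'
#' @param recs consequence data.frame with a `Revel_score` column.
#' @param cutoff score cutoff in (0,1); default 0.5.
#' @return subset of `recs`, ordered by decreasing Revel_score.
#' @export
revel_triage <- function(recs, cutoff = 0.5) {
  if (cutoff <= 0 || cutoff >= 1)
    rad_abort("cutoff must lie in (0,1)", "invalid_config")
  out <- recs[!is.na(recs$Revel_score) & recs$Revel_score > cutoff, ,
              drop = FALSE]
  out <- out[order(-out$Revel_score), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' ALoFT loss-of-function triage
#'
#' Keeps records predicted to cause protein truncation with high confidence.
#'
#' @param recs consequence data.frame with an `Aloft` column.
#' @return subset of `recs`.
#' @export
aloft_triage <- function(recs) {
  out <- recs[!is.na(recs$Aloft) & recs$Aloft == "high_confidence_truncation", ,
              drop = FALSE]
  rownames(out) <- NULL
  out
}

# severity ranking used to collapse multiple transcript records per variant:
# splice/stop/frameshift > in-frame > missense > synonymous > intron >
# regulatory/ncRNA
TERM_SEVERITY <- c(splice_donor = 1, splice_acceptor = 1, stop_gained = 2,
                   frameshift = 3, stop_lost = 4, inframe_deletion = 5,
                   missense = 6, synonymous = 7, intron = 8, ncRNA = 9,
                   regulatory = 10)

#' Genomic-region distribution of variants
#'
#' Collapses multiple transcript records per variant to the most severe term,
#' then tallies the region categories missense / synonymous / regulatory /
#' intronic / ncRNA / splicing / other with their fractions.
#'
#' @param recs consequence data.frame (Chromosome, Position, Ref, Alt,
#'   Vep_consequence).
#' @return data.frame: category, count, fraction (fractions sum to 1 unless
#'   input is empty).
#' @export
region_distribution <- function(recs) {
  cats <- c("missense", "synonymous", "regulatory", "intronic", "ncRNA",
            "splicing", "other")
  if (nrow(recs) == 0L)
    return(data.frame(category = cats, count = 0L, fraction = NA_real_))
  term <- normalize_term(recs$Vep_consequence)
  sev <- TERM_SEVERITY[term]
  sev[is.na(sev)] <- 99
  key <- variant_key(data.frame(chrom = recs$Chromosome, pos = recs$Position,
                                ref = recs$Ref, alt = recs$Alt))
  o <- order(key, sev)
  pick <- o[!duplicated(key[o])]
  t1 <- term[pick]
  region <- ifelse(t1 == "missense", "missense",
            ifelse(t1 == "synonymous", "synonymous",
            ifelse(t1 == "regulatory", "regulatory",
            ifelse(t1 == "intron", "intronic",
            ifelse(t1 == "ncRNA", "ncRNA",
            ifelse(t1 %in% c("splice_donor", "splice_acceptor"), "splicing",
                   "other"))))))
  cnt <- table(factor(region, levels = cats))
  data.frame(category = cats, count = as.integer(cnt),
             fraction = as.numeric(cnt) / sum(cnt), stringsAsFactors = FALSE)
}

#' Partition two gene sets
#'
#' @param genes_a,genes_b character vectors of gene symbols.
#' @return a `gene_set_report`: list(unique_to_a, unique_to_b, common) —
#'   pairwise disjoint, union = all observed genes.
#' @export
gene_set_report <- function(genes_a, genes_b) {
  a <- unique(genes_a); b <- unique(genes_b)
  structure(list(unique_to_a = setdiff(a, b), unique_to_b = setdiff(b, a),
                 common = intersect(a, b)), class = "gene_set_report")
}

#' @export
print.gene_set_report <- function(x, ...) {
  cat(sprintf("<gene_set_report> unique A: %d, unique B: %d, common: %d\n",
              length(x$unique_to_a), length(x$unique_to_b), length(x$common)))
  invisible(x)
}

#' Read a gene list file
#'
#' One symbol per line; `#` comments and blank lines are ignored.
#' @param path text file.
#' @return character vector of symbols.
#' @export
read_gene_list <- function(path) {
  lines <- trimws(readLines(path, warn = FALSE))
  lines <- lines[lines != "" & !startsWith(lines, "#")]
  if (length(lines) == 0L)
    rad_abort(sprintf("gene list '%s' is empty", path), "invalid_config")
  lines
}

#' Overlap of PAM genes with a cancer-predisposition gene list
#'
#' Case-insensitive symbol intersection (whitespace stripped; no alias
#' resolution) of each group's PAM gene set with a user-supplied
#' predisposition/DNA-repair list, plus the common/unique breakdown between
#' groups.  An illustrative synthetic list ships at
#' `system.file("extdata", "cancer_predisposition_genes_synthetic.txt",
#' package = "radspectra")`.
#'
#' @param pam_genes_by_group named list (one character vector of gene symbols
#'   per group).
#' @param list_file path to the predisposition gene list.
#' @return list: `matched` (named list per group, symbols as supplied),
#'   `breakdown` (a `gene_set_report` over the matched sets when there are
#'   two groups, else NULL).
#' @export
cancer_gene_overlap <- function(pam_genes_by_group, list_file) {
  genes <- toupper(trimws(read_gene_list(list_file)))
  matched <- lapply(pam_genes_by_group, function(g) {
    g <- unique(trimws(g))
    g[toupper(g) %in% genes]
  })
  breakdown <- if (length(matched) == 2L)
    gene_set_report(toupper(matched[[1]]), toupper(matched[[2]])) else NULL
  list(matched = matched, breakdown = breakdown)
}
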