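#' Consequence terms ranked by severity
#'
#' The standard Ensembl/VEP consequence severity ordering, most severe
#' first. Used to reduce a variant's set of per-transcript consequences
#' to its most severe one.
#'
#' @return Character vector of consequence terms, most severe first.
#' @export
consequence_severity_order <- function() {
  c("transcript_ablation", "splice_acceptor_variant", "splice_donor_variant",
    "stop_gained", "frameshift_variant", "stop_lost", "start_lost",
    "transcript_amplification", "feature_elongation", "feature_truncation",
    "inframe_insertion", "inframe_deletion", "missense_variant",
    "protein_altering_variant", "splice_donor_5th_base_variant",
    "splice_region_variant", "splice_donor_region_variant",
    "splice_polypyrimidine_tract_variant", "incomplete_terminal_codon_variant",
    "start_retained_variant", "stop_retained_variant", "synonymous_variant",
    "coding_sequence_variant", "mature_miRNA_variant", "5_prime_UTR_variant",
    "3_prime_UTR_variant", "non_coding_transcript_exon_variant",
    "intron_variant", "NMD_transcript_variant", "non_coding_transcript_variant",
    "coding_transcript_variant", "upstream_gene_variant",
    "downstream_gene_variant", "TFBS_ablation", "TFBS_amplification",
    "TF_binding_site_variant", "regulatory_region_ablation",
    "regulatory_region_amplification", "regulatory_region_variant",
    "intergenic_variant", "sequence_variant")
}

#' The consequences retained by default
#'
#' The seven protein-impacting consequence terms kept by the default
#' post-processing cascade: missense_variant, start_lost, stop_lost,
#' stop_gained, splice_acceptor_variant, splice_donor_variant and
#' splice_donor_5th_base_variant.
#'
#' @return Character vector of the seven allowed terms.
#' @export
allowed_consequences <- function() {
  c("missense_variant", "start_lost", "stop_lost", "stop_gained",
    "splice_acceptor_variant", "splice_donor_variant",
    "splice_donor_5th_base_variant")
}

#' Most severe of a set of consequence terms
#'
#' @param consequences Character vector (or comma/ampersand-separated
#'   string) of consequence terms.
#' @return The single most severe term under
#'   [consequence_severity_order()]. Unknown terms are an error.
#' @export
most_severe_consequence <- function(consequences) {
  terms <- unlist(strsplit(as.character(consequences), "[,&]"))
  terms <- trimws(terms[nzchar(trimws(terms))])
  rank <- match(terms, consequence_severity_order())
  if (anyNA(rank))
    stop(sprintf("unknown consequence term(s): %s",
                 paste(unique(terms[is.na(rank)]), collapse = ", ")))
  terms[which.min(rank)]
}

#' Read a consequence annotation table
#'
#' Reads a tab-separated, VEP-style annotation table with columns
#' `chrom`, `pos`, `ref`, `alt`, `consequence` (the last may hold
#' several comma- or `&`-separated per-transcript terms). Rows are
#' reduced to one most-severe consequence per variant key.
#'
#' @param path Path to the TSV file.
#' @return Data frame with columns `key` and `most_severe`.
#' @export
read_consequences <- function(path) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "")
  needed <- c("chrom", "pos", "ref", "alt", "consequence")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop(sprintf("consequence table '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0)
    return(data.frame(key = character(0), most_severe = character(0)))
  key <- variant_key(tab$chrom, tab$pos, tab$ref, tab$alt)
  agg <- tapply(tab$consequence, key, function(cs)
    most_severe_consequence(paste(cs, collapse = ",")))
  data.frame(key = names(agg), most_severe = unname(agg),
             stringsAsFactors = FALSE)
}

#' Keep variants with a protein-impacting consequence
#'
#' Keeps calls whose most severe consequence is one of the allowed
#' terms. Calls with no annotation are removed and counted in the log
#' attribute.
#'
#' @param calls A calls data frame.
#' @param annotations Data frame from [read_consequences()] (columns
#'   `key`, `most_severe`).
#' @param allowed Allowed consequence terms (default
#'   [allowed_consequences()]).
#' @return The kept calls, with attribute `n_unannotated`.
#' @export
consequence_filter <- function(calls, annotations,
                               allowed = allowed_consequences()) {
  unknown <- setdiff(annotations$most_severe, consequence_severity_order())
  if (length(unknown) > 0)
    stop(sprintf("unknown consequence term(s): %s",
                 paste(unknown, collapse = ", ")))
  sev <- annotations$most_severe[match(call_keys(calls), annotations$key)]
  n_unannotated <- sum(is.na(sev))
  if (n_unannotated > 0)
    message(sprintf("consequence_filter: %d unannotated call(s) removed",
                    n_unannotated))
  out <- calls[!is.na(sev) & sev %in% allowed, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_unannotated") <- n_unannotated
  out
}

#' Keep variants seen in at least one cancer cohort
#'
#' Keeps calls whose key is present in at least one of the supplied
#' cohort variant sets (e.g. breast-cancer cohorts from TCGA, a
#' whole-genome study, and ICGC BRCA-FR). Variants absent from all sets
#' are considered unlikely to be tumor-derived and removed.
#'
#' @param calls A calls data frame.
#' @param cohort_sets List of [membership_set()] objects (at least one).
#' @return The kept calls.
#' @export
cohort_filter <- function(calls, cohort_sets) {
  if (length(cohort_sets) == 0)
    stop("cohort_filter: at least one cohort set is required")
  keys <- call_keys(calls)
  in_any <- Reduce(`|`, lapply(cohort_sets, has_key, keys = keys),
                   init = rep(FALSE, nrow(calls)))
  out <- calls[in_any, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Configuration of the post-processing cascade
#'
#' Bundles everything [run_cascade()] needs. The defaults reproduce the
#' standard cascade: consequence filter (seven protein-impacting terms),
#' then cohort-presence filter, then dbSNP + germline-VAF filter. Each
#' step can be toggled or reordered; the final kept set is the
#' intersection of the three keep-sets, so the order affects only the
#' step counts in the log.
#'
#' @param annotations Data frame from [read_consequences()].
#' @param cohort_sets List of [membership_set()] cohort variant sets.
#' @param dbsnp dbSNP [membership_set()].
#' @param intervals A `germline_intervals` object (default: the
#'   published defaults, [default_germline_intervals()]).
#' @param allowed Allowed consequence terms.
#' @param order Step order, a permutation of
#'   `c("consequence", "cohort", "germline")`.
#' @return A `cascade_config` list.
#' @export
cascade_config <- function(annotations, cohort_sets, dbsnp,
                           intervals = default_germline_intervals(),
                           allowed = allowed_consequences(),
                           order = c("consequence", "cohort", "germline")) {
  stopifnot(setequal(order, c("consequence", "cohort", "germline")))
  structure(list(annotations = annotations, cohort_sets = cohort_sets,
                 dbsnp = dbsnp, intervals = intervals, allowed = allowed,
                 order = order),
            class = "cascade_config")
}

#' Run the post-processing cascade
#'
#' Applies the consequence, cohort-presence and dbSNP/germline-VAF
#' filters sequentially (in `config$order`), recording in/out counts at
#' each step. Every step is a pure set-selection on the variant key and
#' its annotations, so the final kept set is independent of the order.
#'
#' @param calls A calls data frame (typically the classifier's output).
#' @param config A [cascade_config()].
#' @return The kept calls, with attribute `step_log` (data frame of
#'   per-step counts).
#' @export
run_cascade <- function(calls, config) {
  stopifnot(inherits(config, "cascade_config"))
  out <- calls
  steps <- list()
  for (s in config$order) {
    n_in <- nrow(out)
    out <- switch(s,
      consequence = consequence_filter(out, config$annotations, config$allowed),
      cohort = cohort_filter(out, config$cohort_sets),
      germline = {
        flagged <- flag_germline(out, config$intervals, config$dbsnp)
        kept <- out[!flagged, , drop = FALSE]
        rownames(kept) <- NULL
        kept
      })
    steps[[s]] <- data.frame(step = s, n_in = n_in, n_out = nrow(out))
  }
  log <- do.call(rbind, steps)
  rownames(log) <- NULL
  message(sprintf("run_cascade: %d -> %d calls (%s)", nrow(calls), nrow(out),
                  paste(sprintf("%s %d->%d", log$step, log$n_in, log$n_out),
                        collapse = "; ")))
  attr(out, "step_log") <- log
  out
}

#' Matched-germline subtraction
#'
#' The comparator to tumor-only filtering when matched germline DNA is
#' available: any variant called in the cfDNA sample but absent from the
#' matched germline sample is labelled somatic. Matching is by full
#' variant key, so different ALT alleles at one site are distinct
#' events.
#'
#' @param cf_calls cfDNA calls data frame.
#' @param germline_calls Matched germline (e.g. white-blood-cell) calls.
#' @param cf_patient,germline_patient Optional patient identifiers; if
#'   both are given they must match.
#' @return The cfDNA calls not present in the germline call set.
#' @export
germline_subtraction <- function(cf_calls, germline_calls,
                                 cf_patient = NULL, germline_patient = NULL) {
  if (!is.null(cf_patient) && !is.null(germline_patient) &&
      cf_patient != germline_patient)
    stop(sprintf("germline_subtraction: patient mismatch ('%s' vs '%s')",
                 cf_patient, germline_patient))
  keep <- !(call_keys(cf_calls) %in% call_keys(germline_calls))
  out <- cf_calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("germline_subtraction: %d cfDNA calls -> %d somatic-labeled",
                  nrow(cf_calls), nrow(out)))
  out
}
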