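# In-code fixtures shared across test files. Everything is generated at
# test time; no binary data on disk.

# A calls data frame built directly (bypassing VCF parsing) with sensible
# defaults; override any column via ...
make_test_calls <- function(n = 1, ...) {
  df <- data.frame(
    sample_id = rep("S1", n), chrom = rep("chr1", n),
    pos = seq(1000L, by = 100L, length.out = n),
    id = rep(NA_character_, n),
    ref = rep("A", n), alt = rep("G", n),
    qual = rep(50, n), genotype = rep("0/1", n),
    ref_umi = rep(900L, n), alt_umi = rep(100L, n),
    dp = rep(2000, n), sgb = rep(-0.69, n),
    rpb = rep(0.9, n), mqb = rep(0.9, n), mqsb = rep(0.9, n),
    bqb = rep(0.9, n), ac = rep(1, n), mq = rep(60, n),
    ref_fwd = rep(450, n), ref_rev = rep(450, n),
    alt_fwd = rep(50, n), alt_rev = rep(50, n),
    allele_call = rep(NA_character_, n),
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) df[[nm]] <- over[[nm]]
  df
}

# One region covering positions 1..1e6 of chr1 (1-based), as 0-based BED.
wide_region <- function(chrom = "chr1") {
  data.frame(chrom = chrom, start = 0L, end = 1000000L)
}

# Membership set containing exactly the keys of the given calls.
cosmic_of <- function(calls) membership_set(call_keys(calls), "cosmic")

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}

# Tiny VCF with given body records (header includes the full INFO dialect).
write_test_vcf <- function(records) {
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=SGB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=MQSB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=BQB,Number=1,Type=Float,Description=\"d\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"d\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"d\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"d\">",
    "##INFO=<ID=ALLELE_CALL,Number=1,Type=String,Description=\"d\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"d\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"d\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", "S1", sep = "\t")
  )
  write_lines_tmp(c(hdr, records), ext = ".vcf")
}

# Independent literal transcription of the five evaluation formulas,
# used as the oracle against compute_metrics.
oracle_metrics <- function(tp, fp, tn, fn) {
  pr <- if (tp + fp > 0) tp / (tp + fp) else 0
  rc <- if (tp + fn > 0) tp / (tp + fn) else 0
  f1 <- if (pr + rc > 0) 2 * pr * rc / (pr + rc) else 0
  den <- sqrt((tp + fp) * (tp + fn) * (tn + fp) * (tn + fn))
  mcc <- if (den > 0) (tp * tn - fp * fn) / den else 0
  sp <- if (tn + fp > 0) tn / (tn + fp) else 0
  list(precision = pr, recall = rc, f1 = f1, mcc = mcc, youden_j = rc + sp - 1)
}

# Small SVM configuration grid for tests where tuning speed matters and
# the full 132-point grid is exercised elsewhere.
small_svm_grid <- function() svm_config_grid(cost_grid = c(0.1, 1, 10))

# A small, well-separated cohort + its labeled training data, memoised per
# test run to avoid regenerating.
.fixture_env <- new.env(parent = emptyenv())
separable_cohort <- function() {
  if (is.null(.fixture_env$co)) {
    .fixture_env$co <- make_cohort(n_patients = 6, separation = 4, seed = 42)
    .fixture_env$td <- suppressMessages(
      cohort_training_data(.fixture_env$co))
  }
  list(cohort = .fixture_env$co, td = .fixture_env$td)
}
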