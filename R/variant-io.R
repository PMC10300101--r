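#' @importFrom vcfR read.vcfR getFIX extract.gt extract.info
NULL

# Canonical column set of a calls data.frame. One row per called ALT allele.
# Annotation columns hold NA when the caller did not emit the tag; they are
# imputed (and masked) only at feature-extraction time, never here.
.call_columns <- c(
  "sample_id", "chrom", "pos", "id", "ref", "alt", "qual", "genotype",
  "ref_umi", "alt_umi", "dp", "sgb", "rpb", "mqb", "mqsb", "bqb",
  "ac", "mq", "ref_fwd", "ref_rev", "alt_fwd", "alt_rev", "allele_call"
)

#' An empty table of variant calls
#'
#' Returns the zero-row data frame with the canonical call columns used
#' throughout the package: one row per called ALT allele, with genomic key
#' (`chrom`, `pos`, `ref`, `alt`), `qual`, `genotype`, unique-molecule
#' allelic depths (`ref_umi`, `alt_umi`) and the pileup-style annotation
#' columns (`dp`, `sgb`, bias p-values `rpb`/`mqb`/`mqsb`/`bqb`, `ac`,
#' `mq`, strand-specific high-quality support `ref_fwd`/`ref_rev`/
#' `alt_fwd`/`alt_rev`, and a hotspot-panel `allele_call` text field).
#'
#' @return A zero-row data frame with the canonical columns.
#' @export
empty_calls <- function() {
  df <- data.frame(
    sample_id = character(0), chrom = character(0), pos = integer(0),
    id = character(0), ref = character(0), alt = character(0),
    qual = numeric(0), genotype = character(0),
    ref_umi = integer(0), alt_umi = integer(0), dp = numeric(0),
    sgb = numeric(0), rpb = numeric(0), mqb = numeric(0), mqsb = numeric(0),
    bqb = numeric(0), ac = numeric(0), mq = numeric(0),
    ref_fwd = numeric(0), ref_rev = numeric(0), alt_fwd = numeric(0),
    alt_rev = numeric(0), allele_call = character(0),
    stringsAsFactors = FALSE
  )
  df
}

#' Variant allele frequency of each call
#'
#' VAF is computed from unique-molecule allelic depths as
#' `alt_umi / (ref_umi + alt_umi)`; `NA` when the denominator is zero.
#'
#' @param calls A calls data frame.
#' @return Numeric vector of VAFs in `[0, 1]`.
#' @export
call_vaf <- function(calls) {
  denom <- calls$ref_umi + calls$alt_umi
  ifelse(denom > 0, calls$alt_umi / denom, NA_real_)
}

#' Unique-molecule coverage of each call
#'
#' @param calls A calls data frame.
#' @return `ref_umi + alt_umi` per call.
#' @export
call_coverage <- function(calls) {
  calls$ref_umi + calls$alt_umi
}

#' Keys of each call
#'
#' @param calls A calls data frame.
#' @return Character vector of canonical [variant_key()] strings.
#' @export
call_keys <- function(calls) {
  if (nrow(calls) == 0) return(character(0))
  variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
}

.info_num <- function(vcf, tag, n) {
  v <- suppressWarnings(vcfR::extract.info(vcf, tag, as.numeric = TRUE))
  if (is.null(v)) rep(NA_real_, n) else as.numeric(v)
}

#' Read variant calls from a VCF file
#'
#' Parses a VCF 4.x file produced by UMI-consensus amplicon calling into
#' the canonical calls data frame, one row per ALT allele per record.
#' Unique-molecule allelic depths come from `FORMAT/AD` (ref depth first,
#' then one depth per ALT allele). The pileup annotations `DP`, `SGB`,
#' `RPB`, `MQB`, `MQSB`, `BQB`, `AC`, `MQ`, `DP4` and a hotspot-panel
#' `ALLELE_CALL` tag are extracted from INFO when present; absent tags are
#' recorded as `NA`, never invented. Records with more than one ALT allele
#' yield one row per allele, all with genotype `"1/2"`.
#'
#' Records without an `AD` field cannot provide unique-molecule depths and
#' are excluded; the number excluded is reported in a message and stored in
#' the `n_missing_ad` attribute of the result.
#'
#' @param path Path to a VCF file (single-sample).
#' @param sample_id Sample identifier stored in the `sample_id` column;
#'   defaults to the sample name in the VCF header.
#' @return A calls data frame (see [empty_calls()]) with attribute
#'   `n_missing_ad`.
#' @export
read_variant_vcf <- function(path, sample_id = NULL) {
  if (!file.exists(path)) stop(sprintf("cannot read VCF '%s': no such file", path))
  vcf <- tryCatch(
    vcfR::read.vcfR(path, verbose = FALSE),
    error = function(e) stop(sprintf("malformed VCF '%s': %s", path,
                                     conditionMessage(e)))
  )
  fix <- vcfR::getFIX(vcf)
  n <- nrow(vcf@fix)
  if (is.null(n) || n == 0) {
    out <- empty_calls()
    attr(out, "n_missing_ad") <- 0L
    return(out)
  }
  fix <- matrix(fix, nrow = n, dimnames = list(NULL, colnames(vcf@fix)[1:7]))
  if (is.null(sample_id)) {
    sids <- colnames(vcf@gt)
    sample_id <- if (length(sids) >= 2) sids[2] else "sample"
  }

  gt <- tryCatch(as.vector(vcfR::extract.gt(vcf, "GT")),
                 error = function(e) rep(NA_character_, n))
  ad <- tryCatch(as.vector(vcfR::extract.gt(vcf, "AD")),
                 error = function(e) rep(NA_character_, n))

  dp   <- .info_num(vcf, "DP", n)
  sgb  <- .info_num(vcf, "SGB", n)
  rpb  <- .info_num(vcf, "RPB", n)
  mqb  <- .info_num(vcf, "MQB", n)
  mqsb <- .info_num(vcf, "MQSB", n)
  bqb  <- .info_num(vcf, "BQB", n)
  mq   <- .info_num(vcf, "MQ", n)
  ac_raw  <- suppressWarnings(vcfR::extract.info(vcf, "AC"))
  dp4_raw <- suppressWarnings(vcfR::extract.info(vcf, "DP4"))
  allele_call <- suppressWarnings(vcfR::extract.info(vcf, "ALLELE_CALL"))
  # extract.info yields logical NA vectors when a tag is absent everywhere
  ac_raw <- if (is.null(ac_raw)) rep(NA_character_, n) else as.character(ac_raw)
  dp4_raw <- if (is.null(dp4_raw)) rep(NA_character_, n) else as.character(dp4_raw)
  allele_call <- if (is.null(allele_call)) rep(NA_character_, n)
                 else as.character(allele_call)

  rows <- vector("list", n)
  n_missing_ad <- 0L
  for (i in seq_len(n)) {
    alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
    alts <- alts[!is.na(alts) & alts != "."]
    if (length(alts) == 0) next
    ad_i <- if (is.na(ad[i])) NULL else
      suppressWarnings(as.integer(strsplit(ad[i], ",", fixed = TRUE)[[1]]))
    if (is.null(ad_i) || length(ad_i) < 1 + length(alts) || anyNA(ad_i)) {
      n_missing_ad <- n_missing_ad + 1L
      next
    }
    gt_i <- gt[i]
    multi <- length(alts) > 1
    geno <- if (multi) "1/2" else {
      g <- gsub("|", "/", gt_i, fixed = TRUE)
      if (is.na(g)) "other"
      else if (g %in% c("0/0", "0/1", "1/0", "1/1", "1/2", "2/1")) {
        if (g == "1/0") "0/1" else if (g == "2/1") "1/2" else g
      } else "other"
    }
    ac_i <- if (is.na(ac_raw[i])) NA_real_ else
      suppressWarnings(as.numeric(strsplit(ac_raw[i], ",", fixed = TRUE)[[1]]))
    dp4_i <- if (is.na(dp4_raw[i])) rep(NA_real_, 4) else
      suppressWarnings(as.numeric(strsplit(dp4_raw[i], ",", fixed = TRUE)[[1]]))
    if (length(dp4_i) != 4 || anyNA(dp4_i)) dp4_i <- rep(NA_real_, 4)
    rows[[i]] <- data.frame(
      row.names = NULL,
      sample_id = sample_id,
      chrom = fix[i, "CHROM"],
      pos = as.integer(fix[i, "POS"]),
      id = ifelse(is.na(fix[i, "ID"]) | fix[i, "ID"] == ".",
                  NA_character_, fix[i, "ID"]),
      ref = fix[i, "REF"],
      alt = alts,
      qual = suppressWarnings(as.numeric(fix[i, "QUAL"])),
      genotype = geno,
      ref_umi = ad_i[1],
      alt_umi = ad_i[1 + seq_along(alts)],
      dp = dp[i], sgb = sgb[i], rpb = rpb[i], mqb = mqb[i],
      mqsb = mqsb[i], bqb = bqb[i],
      ac = if (length(ac_i) >= 1) ac_i[pmin(seq_along(alts), length(ac_i))]
           else NA_real_,
      mq = mq[i],
      ref_fwd = dp4_i[1], ref_rev = dp4_i[2],
      alt_fwd = dp4_i[3], alt_rev = dp4_i[4],
      allele_call = allele_call[i],
      stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) out <- empty_calls()
  rownames(out) <- NULL
  if (n_missing_ad > 0)
    message(sprintf("read_variant_vcf: excluded %d record(s) without FORMAT/AD in '%s'",
                    n_missing_ad, path))
  attr(out, "n_missing_ad") <- n_missing_ad
  out
}

#' Write variant calls to a VCF file
#'
#' Emits the VCF 4.2 dialect that [read_variant_vcf()] consumes: the
#' pileup-style INFO annotations plus `GT:AD` with unique-molecule allelic
#' depths. Rows sharing (`chrom`, `pos`, `ref`) with genotype `"1/2"` are
#' merged back into one multi-allelic record. Round-trips with
#' [read_variant_vcf()].
#'
#' @param calls A calls data frame.
#' @param path Output path.
#' @param sample_id Sample column name in the header; defaults to the
#'   first `sample_id` in `calls`.
#' @return `path`, invisibly.
#' @export
write_variant_vcf <- function(calls, path, sample_id = NULL) {
  if (is.null(sample_id))
    sample_id <- if (nrow(calls) > 0) calls$sample_id[1] else "sample"
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=panelsift",
    "##INFO=<ID=DP,Number=1,Type=Integer,Description=\"Raw read depth\">",
    "##INFO=<ID=SGB,Number=1,Type=Float,Description=\"Segregation-based metric\">",
    "##INFO=<ID=RPB,Number=1,Type=Float,Description=\"Read position bias p-value\">",
    "##INFO=<ID=MQB,Number=1,Type=Float,Description=\"Mapping quality bias p-value\">",
    "##INFO=<ID=MQSB,Number=1,Type=Float,Description=\"Mapping quality vs strand bias p-value\">",
    "##INFO=<ID=BQB,Number=1,Type=Float,Description=\"Base quality bias p-value\">",
    "##INFO=<ID=AC,Number=A,Type=Integer,Description=\"Allele count in genotypes\">",
    "##INFO=<ID=MQ,Number=1,Type=Integer,Description=\"RMS mapping quality\">",
    "##INFO=<ID=DP4,Number=4,Type=Integer,Description=\"High-quality ref-fwd, ref-rev, alt-fwd, alt-rev bases\">",
    "##INFO=<ID=ALLELE_CALL,Number=1,Type=String,Description=\"Hotspot panel allele call\">",
    "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Unique-molecule allelic depths\">",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          "FORMAT", sample_id, sep = "\t")
  )
  body <- character(0)
  if (nrow(calls) > 0) {
    site <- paste(calls$chrom, calls$pos, calls$ref, sep = "\t")
    fmt1 <- function(x) ifelse(is.na(x), NA_character_,
                               formatC(x, format = "fg", digits = 6))
    recs <- lapply(split(seq_len(nrow(calls)), factor(site, levels = unique(site))),
                   function(idx) {
      r1 <- calls[idx[1], ]
      alts <- calls$alt[idx]
      info <- c(
        if (!is.na(r1$dp)) sprintf("DP=%d", as.integer(round(r1$dp))),
        if (!is.na(r1$sgb)) sprintf("SGB=%s", fmt1(r1$sgb)),
        if (!is.na(r1$rpb)) sprintf("RPB=%s", fmt1(r1$rpb)),
        if (!is.na(r1$mqb)) sprintf("MQB=%s", fmt1(r1$mqb)),
        if (!is.na(r1$mqsb)) sprintf("MQSB=%s", fmt1(r1$mqsb)),
        if (!is.na(r1$bqb)) sprintf("BQB=%s", fmt1(r1$bqb)),
        if (!all(is.na(calls$ac[idx])))
          sprintf("AC=%s", paste(as.integer(round(calls$ac[idx])), collapse = ",")),
        if (!is.na(r1$mq)) sprintf("MQ=%d", as.integer(round(r1$mq))),
        if (!is.na(r1$ref_fwd))
          sprintf("DP4=%d,%d,%d,%d", as.integer(round(r1$ref_fwd)),
                  as.integer(round(r1$ref_rev)), as.integer(round(r1$alt_fwd)),
                  as.integer(round(r1$alt_rev))),
        if (!is.na(r1$allele_call)) sprintf("ALLELE_CALL=%s", r1$allele_call)
      )
      if (length(info) == 0) info <- "."
      ad <- paste(c(r1$ref_umi, calls$alt_umi[idx]), collapse = ",")
      paste(r1$chrom, r1$pos,
            ifelse(is.na(r1$id), ".", r1$id), r1$ref,
            paste(alts, collapse = ","),
            ifelse(is.na(r1$qual), ".", formatC(r1$qual, format = "fg", digits = 6)),
            ".", paste(info, collapse = ";"),
            "GT:AD", paste0(r1$genotype, ":", ad), sep = "\t")
    })
    body <- unlist(recs, use.names = FALSE)
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read panel target regions from a BED file
#'
#' Reads a BED3+ file (0-based, half-open intervals). `track`, `browser`
#' and `#` comment lines and empty lines are skipped. Overlapping regions
#' are kept as-is (no merging). A line whose start is not strictly less
#' than its end is an error naming the line.
#'
#' @param path Path to a BED file.
#' @return Data frame with columns `chrom` (character), `start`, `end`
#'   (0-based half-open integers).
#' @export
read_regions <- function(path) {
  if (!file.exists(path)) stop(sprintf("cannot read BED '%s': no such file", path))
  lines <- readLines(path)
  keep <- !grepl("^(track|browser|#)", lines) & nzchar(trimws(lines))
  idx <- which(keep)
  if (length(idx) == 0)
    return(data.frame(chrom = character(0), start = integer(0), end = integer(0)))
  parts <- strsplit(lines[idx], "\t", fixed = TRUE)
  rows <- lapply(seq_along(idx), function(j) {
    p <- parts[[j]]
    if (length(p) < 3)
      stop(sprintf("BED line %d of '%s': fewer than 3 fields", idx[j], path))
    s <- suppressWarnings(as.integer(p[2])); e <- suppressWarnings(as.integer(p[3]))
    if (is.na(s) || is.na(e))
      stop(sprintf("BED line %d of '%s': non-integer coordinates", idx[j], path))
    if (s >= e)
      stop(sprintf("BED line %d of '%s': start %d >= end %d", idx[j], path, s, e))
    data.frame(chrom = p[1], start = s, end = e, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Write regions to a BED3 file
#'
#' @param regions Data frame with `chrom`, `start`, `end` (0-based half-open).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_regions <- function(regions, path) {
  utils::write.table(regions[, c("chrom", "start", "end")], path,
                     sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

.in_regions <- function(chrom, pos, regions) {
  # VCF pos is 1-based; regions are 0-based half-open, so test pos-1.
  cn <- normalize_chrom(chrom)
  rn <- normalize_chrom(regions$chrom)
  p0 <- as.integer(pos) - 1L
  vapply(seq_along(cn), function(i) {
    any(rn == cn[i] & regions$start <= p0[i] & p0[i] < regions$end)
  }, logical(1))
}

#' Basic pre-model filtering of large-panel calls
#'
#' Applies the pre-model filters used on the large-panel (UMI-consensus)
#' calls: keep single-nucleotide variants on chromosomes 1–22 or X that
#' fall inside a panel target region and whose key is present in the
#' COSMIC membership set, then remove homozygous calls (genotype `1/1`
#' from unique molecules) and multi-allelic sites (genotype `1/2`).
#' Genotype `0/0` calls with non-zero ALT support are retained: they carry
#' information the downstream classifier uses. Missing annotations never
#' cause removal here.
#'
#' @param calls A calls data frame.
#' @param regions Panel target regions from [read_regions()].
#' @param cosmic A COSMIC [membership_set()].
#' @return The kept calls, with attribute `step_log` — a data frame of
#'   per-step in/out counts.
#' @export
basic_filter <- function(calls, regions, cosmic) {
  steps <- list()
  n0 <- nrow(calls)
  log_step <- function(name, n_in, n_out)
    data.frame(step = name, n_in = n_in, n_out = n_out)

  is_snv <- calls$ref %in% c("A", "C", "G", "T") &
    calls$alt %in% c("A", "C", "G", "T")
  calls1 <- calls[is_snv, , drop = FALSE]
  steps[[1]] <- log_step("snv", n0, nrow(calls1))

  ok_chrom <- normalize_chrom(calls1$chrom) %in% c(as.character(1:22), "X")
  calls2 <- calls1[ok_chrom, , drop = FALSE]
  steps[[2]] <- log_step("chromosome", nrow(calls1), nrow(calls2))

  in_reg <- if (nrow(calls2) > 0) .in_regions(calls2$chrom, calls2$pos, regions)
            else logical(0)
  calls3 <- calls2[in_reg, , drop = FALSE]
  steps[[3]] <- log_step("target_regions", nrow(calls2), nrow(calls3))

  in_cosmic <- has_key(cosmic, call_keys(calls3))
  calls4 <- calls3[in_cosmic, , drop = FALSE]
  steps[[4]] <- log_step("cosmic", nrow(calls3), nrow(calls4))

  ok_gt <- !(calls4$genotype %in% c("1/1", "1/2"))
  out <- calls4[ok_gt, , drop = FALSE]
  steps[[5]] <- log_step("genotype", nrow(calls4), nrow(out))

  rownames(out) <- NULL
  log <- do.call(rbind, steps)
  message(sprintf("basic_filter: %d -> %d calls (%s)", n0, nrow(out),
                  paste(sprintf("%s %d->%d", log$step, log$n_in, log$n_out),
                        collapse = "; ")))
  attr(out, "step_log") <- log
  out
}

#' Hotspot-panel ground-truth filtering
#'
#' Filters small hotspot-panel calls to the set used as ground truth:
#' single-nucleotide variants whose allele call is neither `"absent"` nor
#' `"no call"`, with PHRED quality at least 20, supported by at least 4
#' unique molecules, and whose key is not on the homopolymer blacklist.
#'
#' @param calls A calls data frame carrying an `allele_call` annotation.
#' @param blacklist Optional [membership_set()] of excluded keys
#'   (homopolymer artifacts).
#' @return The kept calls, with a `step_log` attribute.
#' @export
hotspot_panel_filter <- function(calls, blacklist = NULL) {
  n0 <- nrow(calls)
  is_snv <- calls$ref %in% c("A", "C", "G", "T") &
    calls$alt %in% c("A", "C", "G", "T")
  ok_call <- is.na(calls$allele_call) |
    !(tolower(calls$allele_call) %in% c("absent", "no call"))
  ok_qual <- !is.na(calls$qual) & calls$qual >= 20
  ok_umi <- calls$alt_umi >= 4
  ok_bl <- if (is.null(blacklist)) rep(TRUE, n0)
           else !has_key(blacklist, call_keys(calls))
  out <- calls[is_snv & ok_call & ok_qual & ok_umi & ok_bl, , drop = FALSE]
  rownames(out) <- NULL
  message(sprintf("hotspot_panel_filter: %d -> %d calls", n0, nrow(out)))
  attr(out, "step_log") <- data.frame(step = "hotspot_panel",
                                      n_in = n0, n_out = nrow(out))
  out
}
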