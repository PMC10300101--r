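#' Names of the 22 model features, in their fixed order
#'
#' Sixteen variant-call features followed by six sequence-context
#' features. The order is the contract used by every matrix in the
#' package and is stored with trained models.
#'
#' Call features: `qual` (PHRED call quality), `segregation`
#' (segregation-based metric), the four bias p-values `read_pos_bias`,
#' `mapq_bias`, `mapq_strand_bias`, `baseq_bias`, `allele_count`, the
#' strand-specific high-quality support counts `ref_fwd`, `ref_rev`,
#' `alt_fwd`, `alt_rev`, `mapq`, `gt_ref_alleles` (number of reference
#' alleles in the called genotype: 2 for `0/0`, 1 for `0/1`), `coverage`,
#' `vaf`, and `alt_umi` (unique molecules supporting the variant).
#'
#' Sequence features over the 60 bp window around the variant (30 bp
#' upstream + 30 bp downstream, variant base excluded): `n_A`, `n_C`,
#' `n_G`, `n_T`, `gc_fraction`, `repeat_fraction`.
#'
#' @return Character vector of length 22.
#' @export
feature_names <- function() {
  c("qual", "segregation", "read_pos_bias", "mapq_bias", "mapq_strand_bias",
    "baseq_bias", "allele_count", "ref_fwd", "ref_rev", "alt_fwd", "alt_rev",
    "mapq", "gt_ref_alleles", "coverage", "vaf", "alt_umi",
    "n_A", "n_C", "n_G", "n_T", "gc_fraction", "repeat_fraction")
}

#' Extract the 16 variant-call features
#'
#' Maps each call to the 16 call-level features in the order documented
#' in [feature_names()]. Calls must have genotype `0/0` or `0/1` (others
#' are removed by [basic_filter()]); the `gt_ref_alleles` feature is 2
#' for `0/0` and 1 for `0/1`.
#'
#' Missing annotations are imputed and flagged in the mask: bias p-values
#' to 1 (no evidence of bias), the segregation metric to 0, mapping
#' quality to the median of the non-missing mapping qualities in `calls`
#' (60 if all are missing), coverage to the unique-molecule total,
#' allele count to 1, and absent strand-split support counts to an even
#' split of the unique-molecule depths.
#'
#' @param calls A calls data frame that passed [basic_filter()].
#' @return List with `features` (numeric matrix, n x 16) and `mask`
#'   (logical matrix, `TRUE` where a value was imputed).
#' @export
extract_call_features <- function(calls) {
  n <- nrow(calls)
  bad <- !(calls$genotype %in% c("0/0", "0/1"))
  if (any(bad))
    stop(sprintf("extract_call_features: genotype(s) %s outside {0/0, 0/1}; run basic_filter first",
                 paste(unique(calls$genotype[bad]), collapse = ", ")))
  cols <- feature_names()[1:16]
  f <- matrix(NA_real_, n, 16, dimnames = list(NULL, cols))
  m <- matrix(FALSE, n, 16, dimnames = list(NULL, cols))
  if (n == 0) return(list(features = f, mask = m))

  fill <- function(name, x, impute) {
    miss <- is.na(x)
    x[miss] <- impute[miss]
    f[, name] <<- x
    m[, name] <<- miss
  }
  rep_n <- function(v) rep(v, length.out = n)

  fill("qual", calls$qual, rep_n(0))
  fill("segregation", calls$sgb, rep_n(0))
  fill("read_pos_bias", calls$rpb, rep_n(1))
  fill("mapq_bias", calls$mqb, rep_n(1))
  fill("mapq_strand_bias", calls$mqsb, rep_n(1))
  fill("baseq_bias", calls$bqb, rep_n(1))
  fill("allele_count", calls$ac, rep_n(1))
  fill("ref_fwd", calls$ref_fwd, floor(calls$ref_umi / 2))
  fill("ref_rev", calls$ref_rev, ceiling(calls$ref_umi / 2))
  fill("alt_fwd", calls$alt_fwd, floor(calls$alt_umi / 2))
  fill("alt_rev", calls$alt_rev, ceiling(calls$alt_umi / 2))
  mq_med <- stats::median(calls$mq, na.rm = TRUE)
  if (is.na(mq_med)) mq_med <- 60
  fill("mapq", calls$mq, rep_n(mq_med))
  f[, "gt_ref_alleles"] <- ifelse(calls$genotype == "0/0", 2, 1)
  fill("coverage", calls$dp, call_coverage(calls))
  vaf <- call_vaf(calls)
  fill("vaf", vaf, rep_n(0))
  f[, "alt_umi"] <- calls$alt_umi
  list(features = f, mask = m)
}

#' Read a soft-masked reference sequence
#'
#' Reads a FASTA file preserving case: lowercase bases mark positions
#' annotated as repetitive (soft-masking).
#'
#' @param path Path to a FASTA file.
#' @return Named character vector, one element per sequence.
#' @export
read_masked_reference <- function(path) {
  seqs <- Biostrings::readBStringSet(path)
  out <- as.character(seqs)
  names(out) <- sub("\\s.*$", "", names(seqs))
  out
}

#' Write a soft-masked reference sequence
#'
#' @param reference Named character vector of sequences.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_masked_reference <- function(reference, path) {
  Biostrings::writeXStringSet(Biostrings::BStringSet(reference), path)
  invisible(path)
}

#' Extract the 6 sequence-context features
#'
#' Features of the 60 bp window around each variant position — 30 bases
#' upstream plus 30 bases downstream, the variant base itself excluded:
#' the number of occurrences of A, C, G and T (case-insensitive), the GC
#' fraction, and the fraction of soft-masked (lowercase, repeat-annotated)
#' bases. `N` bases fall in no nucleotide bin but stay in the denominator
#' of both fractions, so the four counts sum to the window length minus
#' the `N` count. Windows are truncated at chromosome ends and fractions
#' use the truncated length.
#'
#' @param reference Named character vector from [read_masked_reference()].
#' @param chrom Chromosome name(s).
#' @param pos 1-based variant position(s).
#' @param flank Bases on each side of the variant (default 30).
#' @return Numeric matrix (n x 6) with columns `n_A`, `n_C`, `n_G`,
#'   `n_T`, `gc_fraction`, `repeat_fraction`.
#' @export
extract_sequence_features <- function(reference, chrom, pos, flank = 30L) {
  stopifnot(length(chrom) == length(pos))
  ref_names <- names(reference)
  cn <- as.character(chrom)
  # accept either naming convention on both sides
  resolve <- function(ch) {
    if (ch %in% ref_names) return(ch)
    alt <- if (grepl("^chr", ch)) sub("^chr", "", ch) else paste0("chr", ch)
    if (alt %in% ref_names) return(alt)
    stop(sprintf("unknown chromosome '%s' (reference has: %s)", ch,
                 paste(utils::head(ref_names, 5), collapse = ", ")))
  }
  out <- matrix(NA_real_, length(pos), 6,
                dimnames = list(NULL, feature_names()[17:22]))
  for (i in seq_along(pos)) {
    ch <- resolve(cn[i])
    sq <- reference[[ch]]
    len <- nchar(sq)
    p <- as.integer(pos[i])
    if (p < 1 || p > len)
      stop(sprintf("position %d outside chromosome '%s' (length %d)", p, ch, len))
    up <- if (p > 1) substr(sq, max(1L, p - flank), p - 1L) else ""
    dn <- if (p < len) substr(sq, p + 1L, min(len, p + flank)) else ""
    win <- paste0(up, dn)
    wlen <- nchar(win)
    chars <- strsplit(win, "", fixed = TRUE)[[1]]
    upper <- toupper(chars)
    nA <- sum(upper == "A"); nC <- sum(upper == "C")
    nG <- sum(upper == "G"); nT <- sum(upper == "T")
    n_low <- sum(chars %in% c("a", "c", "g", "t", "n"))
    out[i, ] <- c(nA, nC, nG, nT,
                  if (wlen > 0) (nC + nG) / wlen else 0,
                  if (wlen > 0) n_low / wlen else 0)
  }
  out
}

#' Build the full 22-column feature matrix
#'
#' Combines [extract_call_features()] and [extract_sequence_features()]
#' into the n x 22 matrix fed to the classifier, plus the missing-value
#' mask (sequence features are never missing).
#'
#' @param calls A calls data frame that passed [basic_filter()].
#' @param reference Named character vector from [read_masked_reference()].
#' @return List with `features` (n x 22 matrix, columns
#'   [feature_names()]) and `mask` (n x 22 logical matrix).
#' @export
build_feature_matrix <- function(calls, reference) {
  cf <- extract_call_features(calls)
  sf <- extract_sequence_features(reference, calls$chrom, calls$pos)
  features <- cbind(cf$features, sf)
  mask <- cbind(cf$mask, matrix(FALSE, nrow(sf), 6,
                                dimnames = list(NULL, colnames(sf))))
  stopifnot(ncol(features) == 22)
  list(features = features, mask = mask)
}

#' Fit a per-feature standardizer
#'
#' Computes per-column mean and population standard deviation (divisor
#' n, not n - 1) on training rows only, so that standardized training
#' columns have exactly zero mean and unit population variance. A
#' degenerate (zero-variance) column gets divisor 1 and is flagged in
#' `constant`.
#'
#' @param x Numeric matrix of training feature rows (>= 2 rows).
#' @return Object of class `standardizer` with `center`, `scale`,
#'   `constant`.
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2) stop("fit_standardizer: need at least 2 rows")
  center <- colMeans(x)
  scale <- sqrt(colMeans(sweep(x, 2, center, "-")^2))  # population sd
  constant <- !is.finite(scale) | scale <= 0
  scale[constant] <- 1
  structure(list(center = center, scale = scale, constant = constant),
            class = "standardizer")
}

#' Apply a fitted standardizer
#'
#' @param s A `standardizer` from [fit_standardizer()].
#' @param x Numeric matrix with the same columns as the training matrix.
#' @return The standardized matrix; constant columns map to 0.
#' @export
apply_standardizer <- function(s, x) {
  stopifnot(inherits(s, "standardizer"))
  x <- as.matrix(x)
  if (ncol(x) != length(s$center))
    stop(sprintf("apply_standardizer: %d columns, expected %d",
                 ncol(x), length(s$center)))
  out <- sweep(sweep(x, 2, s$center, "-"), 2, s$scale, "/")
  if (any(s$constant)) out[, s$constant] <- 0
  out
}
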