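#' Canonical variant keys
#'
#' A variant key identifies a site + alternate allele as the string
#' `"chrom:pos:ref:alt"` with the chromosome name normalized (leading
#' `"chr"` stripped, case preserved otherwise). Keys are used for all
#' membership tests (COSMIC, dbSNP, cancer-cohort sets, blacklists,
#' matched-germline subtraction) so that VCFs with and without the
#' `"chr"` prefix compare equal.
#'
#' @param chrom Chromosome name(s), with or without a `"chr"` prefix.
#' @param pos 1-based position(s).
#' @param ref Reference allele(s).
#' @param alt Alternate allele(s).
#' @return Character vector of canonical keys.
#' @examples
#' variant_key("chr3", 100, "A", "G") == variant_key("3", 100, "A", "G")
#' @export
variant_key <- function(chrom, pos, ref, alt) {
  paste(normalize_chrom(chrom), as.integer(pos), toupper(ref), toupper(alt),
        sep = ":")
}

#' Normalize chromosome names
#'
#' Strips a leading `"chr"` (any case) so `"chr17"` and `"17"` compare equal.
#'
#' @param chrom Character vector of chromosome names.
#' @return Character vector without the `"chr"` prefix.
#' @export
normalize_chrom <- function(chrom) {
  sub("^[Cc][Hh][Rr]", "", as.character(chrom))
}

#' Construct a membership set
#'
#' A named, deduplicated set of variant keys standing in for a variant
#' database (COSMIC, dbSNP, a cancer-cohort variant list, or a blacklist).
#'
#' @param keys Character vector of keys as produced by [variant_key()].
#' @param name Name of the set (used in logs).
#' @return An object of class `membership_set`.
#' @export
membership_set <- function(keys, name = "set") {
  structure(list(name = name, keys = unique(as.character(keys))),
            class = "membership_set")
}

#' @export
length.membership_set <- function(x) length(x$keys)

#' @export
print.membership_set <- function(x, ...) {
  cat(sprintf("<membership_set '%s': %d keys>\n", x$name, length(x$keys)))
  invisible(x)
}

#' Test keys for membership
#'
#' @param set A [membership_set()].
#' @param keys Character vector of variant keys.
#' @return Logical vector, `TRUE` where the key is in the set.
#' @export
has_key <- function(set, keys) {
  stopifnot(inherits(set, "membership_set"))
  keys %in% set$keys
}

#' Read a membership table
#'
#' Reads a tab-separated table with (at least) columns `chrom`, `pos`,
#' `ref`, `alt` (header required; an optional `id` column is ignored for
#' keying) and returns the deduplicated key set.
#'
#' @param path Path to the TSV file.
#' @param name Name for the resulting set.
#' @return A [membership_set()].
#' @export
read_membership <- function(path, name = basename(path)) {
  tab <- utils::read.delim(path, header = TRUE, sep = "\t",
                           colClasses = "character", comment.char = "")
  needed <- c("chrom", "pos", "ref", "alt")
  missing_cols <- setdiff(needed, names(tab))
  if (length(missing_cols) > 0)
    stop(sprintf("membership table '%s' is missing column(s): %s",
                 path, paste(missing_cols, collapse = ", ")))
  if (nrow(tab) == 0) return(membership_set(character(0), name))
  membership_set(variant_key(tab$chrom, tab$pos, tab$ref, tab$alt), name)
}

#' Write a membership table
#'
#' Inverse of [read_membership()]: writes keys back to the TSV dialect
#' (`chrom` without the `"chr"` prefix).
#'
#' @param set A [membership_set()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_membership <- function(set, path) {
  stopifnot(inherits(set, "membership_set"))
  parts <- do.call(rbind, strsplit(set$keys, ":", fixed = TRUE))
  df <- if (length(set$keys) == 0) {
    data.frame(chrom = character(0), pos = character(0),
               ref = character(0), alt = character(0))
  } else {
    data.frame(chrom = parts[, 1], pos = parts[, 2],
               ref = parts[, 3], alt = parts[, 4])
  }
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
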