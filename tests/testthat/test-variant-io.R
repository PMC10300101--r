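test_that("VCF records map to calls with unique-molecule depths and VAF", {
  f <- write_test_vcf(paste("chr1", 100, "rs1", "A", "G", "55.3", ".",
    "DP=100;SGB=-0.6;RPB=0.8;MQB=1;MQSB=0.9;BQB=0.5;AC=1;MQ=60;DP4=40,40,10,10",
    "GT:AD", "0/1:95,5", sep = "\t"))
  calls <- read_variant_vcf(f, sample_id = "S1")
  expect_equal(nrow(calls), 1)
  expect_equal(calls$ref_umi, 95)
  expect_equal(calls$alt_umi, 5)
  expect_equal(call_vaf(calls), 0.05)
  expect_equal(calls$genotype, "0/1")
  expect_equal(calls$qual, 55.3)
  expect_equal(calls$rpb, 0.8)
  expect_equal(calls$ref_fwd, 40)
  expect_equal(calls$alt_rev, 10)
  expect_equal(calls$id, "rs1")
})

test_that("empty VCF body gives an empty call table", {
  f <- write_test_vcf(character(0))
  calls <- read_variant_vcf(f, sample_id = "S1")
  expect_equal(nrow(calls), 0)
  expect_true(all(c("chrom", "pos", "ref", "alt", "ref_umi") %in% names(calls)))
})

test_that("a 1/2 record with two ALT alleles yields two calls, both genotype 1/2", {
  # hand-enumerated: AD=30,10,12 -> (ref 30, alt T 10), (ref 30, alt G 12)
  f <- write_test_vcf(paste("chr1", 200, ".", "C", "T,G", "12", ".",
    "DP=50;AC=1,1;MQ=58", "GT:AD", "1/2:30,10,12", sep = "\t"))
  calls <- read_variant_vcf(f, "S1")
  expect_equal(nrow(calls), 2)
  expect_equal(calls$alt, c("T", "G"))
  expect_equal(calls$alt_umi, c(10, 12))
  expect_equal(calls$ref_umi, c(30, 30))
  expect_equal(calls$genotype, c("1/2", "1/2"))
})

test_that("records without allelic depth are excluded and counted", {
  f <- write_test_vcf(c(
    paste("chr1", 100, ".", "A", "G", "50", ".", "DP=100", "GT:AD",
          "0/1:95,5", sep = "\t"),
    paste("chr1", 200, ".", "C", "T", "50", ".", "DP=100", "GT", "0/1",
          sep = "\t")))
  expect_message(calls <- read_variant_vcf(f, "S1"), "without FORMAT/AD")
  expect_equal(nrow(calls), 1)
  expect_equal(attr(calls, "n_missing_ad"), 1L)
})

test_that("missing INFO annotations stay missing rather than being invented", {
  f <- write_test_vcf(paste("chr1", 100, ".", "A", "G", "50", ".", ".",
                            "GT:AD", "0/1:95,5", sep = "\t"))
  calls <- read_variant_vcf(f, "S1")
  expect_true(is.na(calls$rpb))
  expect_true(is.na(calls$sgb))
  expect_true(is.na(calls$ref_fwd))
})

test_that("malformed or absent VCF files raise parse errors", {
  expect_error(read_variant_vcf(tempfile(fileext = ".vcf")), "no such file")
})

test_that("BED regions are read as 0-based half-open and kept verbatim", {
  f <- write_lines_tmp(c("track name=panel", "# a comment",
                         "chr3\t100\t200", "chr3\t150\t250", ""), ".bed")
  r <- read_regions(f)
  expect_equal(nrow(r), 2)  # overlap kept, no merging
  expect_equal(r$chrom, c("chr3", "chr3"))
  expect_equal(r$start, c(100L, 150L))
  expect_equal(r$end, c(200L, 250L))
})

test_that("a BED line with start >= end errors naming the line", {
  f <- write_lines_tmp(c("chr1\t10\t20", "chr1\t30\t30"), ".bed")
  expect_error(read_regions(f), "line 2")
})

test_that("membership tables deduplicate and support key lookups", {
  f <- write_lines_tmp(c("chrom\tpos\tref\talt",
                         "chr1\t100\tA\tG",
                         "1\t100\tA\tG",   # same key, different prefix
                         "chr2\t50\tC\tT"))
  set <- read_membership(f, "cosmic")
  expect_equal(length(set), 2)
  expect_true(has_key(set, variant_key("1", 100, "A", "G")))
  expect_false(has_key(set, variant_key("1", 101, "A", "G")))

  f2 <- write_lines_tmp("chrom\tpos\tref\talt")
  expect_equal(length(read_membership(f2)), 0)

  f3 <- write_lines_tmp(c("chrom\tpos\tref", "chr1\t1\tA"))
  expect_error(read_membership(f3), "alt")
})

test_that("basic_filter enforces chromosome, region, COSMIC and genotype rules", {
  base <- make_test_calls(6,
    chrom = c("chr1", "chrY", "chr1", "chr1", "chr1", "chr1"),
    genotype = c("0/1", "0/1", "1/1", "1/2", "0/0", "0/1"),
    pos = c(1000L, 1000L, 1100L, 1200L, 1300L, 5000000L))
  cosmic <- cosmic_of(base)
  kept <- suppressMessages(basic_filter(base, wide_region(), cosmic))
  # chrY removed, 1/1 removed, 1/2 removed, out-of-region removed;
  # 0/1 and 0/0 (with alt support) retained
  expect_equal(kept$pos, c(1000L, 1300L))
  expect_equal(kept$genotype, c("0/1", "0/0"))
})

test_that("basic_filter requires COSMIC membership and normalizes chr prefixes", {
  calls <- make_test_calls(2, chrom = c("chr1", "1"), pos = c(1000L, 2000L))
  cosmic <- membership_set(variant_key("1", 1000, "A", "G"))  # no chr prefix
  kept <- suppressMessages(basic_filter(calls, wide_region("1"), cosmic))
  expect_equal(nrow(kept), 1)
  expect_equal(kept$pos, 1000L)
  expect_true(all(has_key(cosmic, call_keys(kept))))
})

test_that("basic_filter removes indels and is idempotent and order-invariant", {
  calls <- make_test_calls(4, ref = c("A", "AT", "C", "G"),
                           alt = c("G", "A", "CT", "T"))
  cosmic <- cosmic_of(calls)
  kept <- suppressMessages(basic_filter(calls, wide_region(), cosmic))
  expect_equal(kept$ref, c("A", "G"))  # SNVs only

  twice <- suppressMessages(basic_filter(kept, wide_region(), cosmic))
  expect_equal(twice[, names(twice)], kept[, names(kept)])

  rev_kept <- suppressMessages(
    basic_filter(calls[rev(seq_len(nrow(calls))), ], wide_region(), cosmic))
  expect_setequal(call_keys(rev_kept), call_keys(kept))
})

test_that("hotspot panel filter applies quality, support and blacklist rules", {
  calls <- make_test_calls(5,
    qual = c(19.9, 20, 50, 50, 50),
    alt_umi = c(100L, 100L, 3L, 4L, 100L),
    allele_call = c("heterozygous", "heterozygous", "heterozygous",
                    "heterozygous", "absent"))
  kept <- suppressMessages(hotspot_panel_filter(calls))
  expect_equal(kept$pos, calls$pos[c(2, 4)])  # 19.9 out, 20 in; 3 out, 4 in

  bl <- membership_set(call_keys(calls[2, ]), "homopolymer")
  kept_bl <- suppressMessages(hotspot_panel_filter(calls, bl))
  expect_equal(kept_bl$pos, calls$pos[4])
})

test_that("written VCFs round-trip through the reader", {
  co <- separable_cohort()$cohort
  p1 <- co$calls[co$calls$patient == "P001", ]
  p1 <- p1[order(p1$pos), ]
  f <- tempfile(fileext = ".vcf")
  write_variant_vcf(p1, f, sample_id = "P001")
  back <- read_variant_vcf(f, sample_id = "P001")
  expect_equal(nrow(back), nrow(p1))
  expect_setequal(call_keys(back), call_keys(p1))
  m <- match(call_keys(p1), call_keys(back))
  expect_equal(back$ref_umi[m], p1$ref_umi)
  expect_equal(back$alt_umi[m], p1$alt_umi)
  expect_equal(back$genotype[m], p1$genotype)
  expect_equal(back$qual[m], p1$qual, tolerance = 1e-6)
  expect_equal(back$rpb[m], p1$rpb, tolerance = 1e-6)
})
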