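test_that("genotype encodes as the number of reference alleles", {
  calls <- make_test_calls(2, genotype = c("0/0", "0/1"))
  cf <- extract_call_features(calls)
  expect_equal(unname(cf$features[, "gt_ref_alleles"]), c(2, 1))
})

test_that("VAF and unique-molecule features come from allelic depths", {
  calls <- make_test_calls(1, ref_umi = 95L, alt_umi = 5L)
  cf <- extract_call_features(calls)
  expect_equal(unname(cf$features[1, "vaf"]), 0.05)
  expect_equal(unname(cf$features[1, "alt_umi"]), 5)
})

test_that("missing bias p-values impute to 1 with the mask set", {
  calls <- make_test_calls(1, rpb = NA_real_, mqb = NA_real_,
                           mqsb = NA_real_, bqb = NA_real_)
  cf <- extract_call_features(calls)
  bias_cols <- c("read_pos_bias", "mapq_bias", "mapq_strand_bias", "baseq_bias")
  expect_equal(unname(cf$features[1, bias_cols]), rep(1, 4))
  expect_true(all(cf$mask[1, bias_cols]))
  expect_false(any(cf$mask[1, setdiff(colnames(cf$mask), bias_cols)]))
})

test_that("missing segregation, mapq and coverage impute as documented", {
  calls <- make_test_calls(3, sgb = NA_real_, dp = NA_real_,
                           mq = c(NA, 50, 58))
  cf <- extract_call_features(calls)
  expect_equal(unname(cf$features[1, "segregation"]), 0)
  expect_equal(unname(cf$features[, "coverage"]), rep(1000, 3))  # umi total
  expect_equal(unname(cf$features[1, "mapq"]), 54)  # batch median of 50, 58
  expect_true(cf$mask[1, "mapq"])
  expect_false(cf$mask[2, "mapq"])
})

test_that("genotypes outside 0/0 and 0/1 are rejected at feature extraction", {
  expect_error(extract_call_features(make_test_calls(1, genotype = "1/1")),
               "basic_filter")
})

test_that("sequence features count the 60 bp window excluding the variant base", {
  # 30 A's + center C + 30 A's: window is 60 A's
  ref <- setNames(paste0(strrep("A", 30), "C", strrep("A", 30)), "chr1")
  sf <- extract_sequence_features(ref, "chr1", 31)
  expect_equal(unname(sf[1, ]), c(60, 0, 0, 0, 0, 0))

  # fully lowercase gc window
  ref2 <- setNames(paste0(strrep("gc", 15), "A", strrep("gc", 15)), "chr1")
  sf2 <- extract_sequence_features(ref2, "chr1", 31)
  expect_equal(unname(sf2[1, c("n_C", "n_G")]), c(30, 30))
  expect_equal(unname(sf2[1, "gc_fraction"]), 1)
  expect_equal(unname(sf2[1, "repeat_fraction"]), 1)
})

test_that("windows truncate at chromosome ends and fractions use the short length", {
  # 50-base chromosome, variant at position 10: 9 upstream + 30 downstream = 39
  ref <- setNames(strrep("G", 50), "chr1")
  sf <- extract_sequence_features(ref, "chr1", 10)
  expect_equal(unname(sf[1, "n_G"]), 39)
  expect_equal(unname(sf[1, "gc_fraction"]), 1)
})

test_that("N bases stay in the fraction denominators but in no nucleotide bin", {
  ref <- setNames(paste0(strrep("N", 30), "A", strrep("C", 30)), "chr1")
  sf <- extract_sequence_features(ref, "chr1", 31)
  expect_equal(unname(sf[1, c("n_A", "n_C", "n_G", "n_T")]), c(0, 30, 0, 0))
  expect_equal(unname(sf[1, "gc_fraction"]), 30 / 60)
  expect_equal(sum(sf[1, 1:4]), 60 - 30)  # counts sum to window minus N
})

test_that("sequence features depend only on position, never on the alleles", {
  ref <- separable_cohort()$cohort$reference
  a <- extract_sequence_features(ref, "chr1", 500)
  b <- extract_sequence_features(ref, "chr1", 500)
  expect_identical(a, b)
  expect_error(extract_sequence_features(ref, "chr9", 500), "unknown chromosome")
})

test_that("every call yields a 22-entry vector in the documented order", {
  td <- separable_cohort()$td
  expect_equal(ncol(td$features), 22)
  expect_equal(colnames(td$features), feature_names())
  expect_false(anyNA(td$features))
  expect_true(all(td$features[, "gc_fraction"] >= 0 &
                    td$features[, "gc_fraction"] <= 1))
  expect_true(all(td$features[, "repeat_fraction"] >= 0 &
                    td$features[, "repeat_fraction"] <= 1))
})

test_that("standardizer maps training data to zero mean and unit variance", {
  x <- rbind(rep(0, 5), rep(2, 5))
  s <- fit_standardizer(x)
  z <- apply_standardizer(s, x)
  expect_equal(unname(z), rbind(rep(-1, 5), rep(1, 5)))

  set.seed(1)
  x2 <- matrix(rnorm(200), 20)
  s2 <- fit_standardizer(x2)
  z2 <- apply_standardizer(s2, x2)
  expect_equal(unname(colMeans(z2)), rep(0, 10), tolerance = 1e-12)
  pop_var <- colMeans(sweep(z2, 2, colMeans(z2), "-")^2)
  expect_equal(unname(pop_var), rep(1, 10), tolerance = 1e-12)
})

test_that("constant feature columns get divisor 1, map to 0 and are flagged", {
  x <- cbind(c(1, 1, 1), c(0, 1, 2))
  s <- fit_standardizer(x)
  expect_true(s$constant[1])
  expect_false(s$constant[2])
  z <- apply_standardizer(s, x)
  expect_equal(unname(z[, 1]), rep(0, 3))
  expect_error(fit_standardizer(x[1, , drop = FALSE]), "2 rows")
})
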