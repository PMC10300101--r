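test_that("reference generation is seeded and hits the masked fraction", {
  r0 <- make_reference(1000, repeat_fraction = 0, seed = 1)
  expect_false(grepl("[acgt]", r0[[1]]))
  expect_identical(make_reference(1000, 0.3, seed = 5),
                   make_reference(1000, 0.3, seed = 5))
  r5 <- make_reference(10000, repeat_fraction = 0.5, seed = 2)
  n_low <- sum(strsplit(r5[[1]], "")[[1]] %in% c("a", "c", "g", "t"))
  expect_gte(n_low, 4900)
  expect_lte(n_low, 5100)
})

test_that("mixture sampling respects weights and keeps truth labels", {
  s <- make_mixture_sample(c(2, 5, 45, 90), c(8, 5, 45, 2),
                           c(1, 0, 0, 0), n = 100, seed = 3)
  expect_true(all(s$component == 1))
  s0 <- make_mixture_sample(c(2, 5, 45, 90), c(8, 5, 45, 2),
                            c(0.25, 0.25, 0.25, 0.25), n = 0, seed = 3)
  expect_length(s0$vaf, 0)
  n <- 4000
  s2 <- make_mixture_sample(c(2, 5, 45, 90), c(8, 5, 45, 2),
                            c(0.1, 0.2, 0.3, 0.4), n = n, seed = 4)
  props <- tabulate(s2$component, 4) / n
  expect_true(all(abs(props - c(0.1, 0.2, 0.3, 0.4)) <= 3 / sqrt(n)))
})

test_that("a germline-het-only cohort draws VAFs around one half", {
  co <- make_cohort(n_patients = 4, n_somatic = 0, n_het = 250, n_hom = 0,
                    n_error = 0, n_noncosmic = 0, n_multiallelic = 0,
                    ref_length = 2000000, seed = 17)
  vafs <- call_vaf(co$calls)
  expect_true(all(vafs > 0 & vafs < 1))
  expect_equal(mean(vafs), 0.5, tolerance = 0.02)
})

test_that("basic filtering removes exactly the generated control classes", {
  co <- separable_cohort()$cohort
  kept <- suppressMessages(basic_filter(co$calls, co$regions, co$cosmic))
  kept_id <- paste(kept$patient, call_keys(kept))
  truth_id <- paste(co$truth$patient, co$truth$key)
  removed_cls <- co$truth$class[!(truth_id %in% kept_id)]
  expect_setequal(unique(removed_cls),
                  c("noncosmic", "germline_hom", "multiallelic"))
  kept_cls <- co$truth$class[truth_id %in% kept_id]
  expect_setequal(unique(kept_cls), c("somatic", "germline_het", "error"))
})

test_that("membership tables are consistent with the truth labels", {
  co <- separable_cohort()$cohort
  tr <- co$truth
  expect_true(all(has_key(co$cosmic, tr$key[tr$class != "noncosmic"])))
  expect_false(any(has_key(co$cosmic, tr$key[tr$class == "noncosmic"])))
  germ <- tr$key[tr$class %in% c("germline_het", "germline_hom")]
  expect_true(all(has_key(co$dbsnp, germ)))
  som <- unique(tr$key[tr$class == "somatic"])
  in_any <- Reduce(`|`, lapply(co$cohort_sets, has_key, keys = som))
  expect_true(all(in_any))
  # decoys exist but never collide with cohort calls
  expect_gt(length(co$cosmic), length(unique(tr$key[tr$class != "noncosmic"])))
  expect_true(all(co$consequences$key %in% tr$key))
})

test_that("every truth row corresponds to exactly one generated call", {
  co <- separable_cohort()$cohort
  expect_equal(nrow(co$truth), nrow(co$calls))
  expect_identical(co$truth$key, call_keys(co$calls))
  expect_identical(co$truth$patient, co$calls$patient)
})

test_that("cohort file output is byte-identical across runs with one seed", {
  d1 <- file.path(tempdir(), "coh-a")
  d2 <- file.path(tempdir(), "coh-b")
  unlink(c(d1, d2), recursive = TRUE)
  make_cohort(n_patients = 2, seed = 13, dir = d1)
  make_cohort(n_patients = 2, seed = 13, dir = d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)),
                     label = f)
  }
  diff_seed <- file.path(tempdir(), "coh-c")
  unlink(diff_seed, recursive = TRUE)
  make_cohort(n_patients = 2, seed = 14, dir = diff_seed)
  expect_false(identical(readLines(file.path(d1, "P001.vcf")),
                         readLines(file.path(diff_seed, "P001.vcf"))))
})

test_that("a written cohort loads back equal to the in-memory cohort", {
  d <- file.path(tempdir(), "coh-load")
  unlink(d, recursive = TRUE)
  co <- make_cohort(n_patients = 3, seed = 23, dir = d)
  back <- suppressMessages(load_cohort_dir(d))
  expect_equal(nrow(back$calls), nrow(co$calls))
  expect_setequal(paste(back$calls$patient, call_keys(back$calls)),
                  paste(co$calls$patient, call_keys(co$calls)))
  expect_equal(back$regions, co$regions)
  expect_identical(back$reference, co$reference)
  expect_setequal(back$cosmic$keys, co$cosmic$keys)
  expect_setequal(back$dbsnp$keys, co$dbsnp$keys)
  m <- match(back$consequences$key, co$consequences$key)
  expect_identical(back$consequences$most_severe, co$consequences$most_severe[m])
})

test_that("an infeasible cohort spec errors", {
  expect_error(make_cohort(n_patients = 0), "infeasible")
  expect_error(make_cohort(n_patients = 1, n_somatic = 0, n_het = 0,
                           n_hom = 0, n_error = 0, n_noncosmic = 0,
                           n_multiallelic = 0), "infeasible")
})
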