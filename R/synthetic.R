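#' Generate a seeded soft-masked reference sequence
#'
#' Uniform random bases over A/C/G/T with a seeded subset of positions
#' lowercased so that the lowercase (repeat-masked) fraction matches
#' `repeat_fraction` exactly (to rounding).
#'
#' @param length Sequence length (>= 200).
#' @param repeat_fraction Target fraction of soft-masked bases.
#' @param seed Integer seed; identical seed gives an identical sequence.
#' @param chrom Sequence name.
#' @return Named character vector of length 1 (usable with
#'   [extract_sequence_features()]).
#' @export
make_reference <- function(length = 10000, repeat_fraction = 0.2, seed = 1,
                           chrom = "chr1") {
  stopifnot(length >= 200, repeat_fraction >= 0, repeat_fraction <= 1)
  set.seed(seed)
  bases <- sample(c("A", "C", "G", "T"), length, replace = TRUE)
  n_low <- round(repeat_fraction * length)
  if (n_low > 0) {
    low_idx <- sample.int(length, n_low)
    bases[low_idx] <- tolower(bases[low_idx])
  }
  stats::setNames(paste(bases, collapse = ""), chrom)
}

#' Sample VAFs from a known beta mixture
#'
#' Seeded ancestral sampling from a weighted beta mixture, keeping the
#' component truth labels. Feeds parameter-recovery tests of
#' [fit_beta_mixture()].
#'
#' @param alpha,beta Component shape parameters (equal length).
#' @param weight Component weights (sum to 1).
#' @param n Number of draws.
#' @param seed Integer seed.
#' @return List with `vaf` (numeric) and `component` (integer truth).
#' @export
make_mixture_sample <- function(alpha, beta, weight, n, seed = 1) {
  k <- length(alpha)
  stopifnot(length(beta) == k, length(weight) == k,
            abs(sum(weight) - 1) < 1e-8, all(alpha > 0), all(beta > 0))
  set.seed(seed)
  if (n == 0) return(list(vaf = numeric(0), component = integer(0)))
  comp <- sample.int(k, n, replace = TRUE, prob = weight)
  vaf <- stats::rbeta(n, alpha[comp], beta[comp])
  list(vaf = vaf, component = comp)
}

.class_vaf_params <- function() {
  list(error = c(1, 200), noncosmic = c(1, 200), somatic = c(2, 8),
       germline_het = c(45, 45), germline_hom = c(90, 2))
}

#' Generate a synthetic cfDNA cohort
#'
#' Builds a seeded multi-patient cohort with the statistical structure
#' the pipeline assumes: per-patient calls of four classes — true
#' somatic variants, germline heterozygous and homozygous variants, and
#' sequencing errors — plus non-COSMIC control calls and one
#' multi-allelic error record per patient, on a shared soft-masked
#' reference and panel regions, with membership tables consistent with
#' the truth labels (all non-control calls in COSMIC, germline calls in
#' dbSNP, somatic calls in at least one cancer-cohort set) and a
#' consequence annotation per variant.
#'
#' Class-conditional VAF laws: errors Beta(1, 200), somatic Beta(2, 8),
#' germline-het Beta(45, 45), germline-hom Beta(90, 2). Unique-molecule
#' coverage is negative-binomial with mean `coverage_mean`. Call quality
#' and bias annotations separate real variants from errors to a degree
#' set by `separation`: real calls have quality about
#' `20 + 10 * separation` versus 20 for errors, cleaner bias p-values,
#' higher mapping quality and balanced strand support.
#'
#' The truth label (`label`) is whether the call is a real variant — the
#' calls a high-depth hotspot assay would also make — i.e. class somatic
#' or germline; errors and controls are `FALSE`.
#'
#' @param n_patients Number of patients.
#' @param n_somatic,n_het,n_hom,n_error Per-patient counts of true
#'   somatic, germline heterozygous, germline homozygous and error calls.
#' @param n_noncosmic Per-patient non-COSMIC control calls (error-like,
#'   absent from the COSMIC table).
#' @param n_multiallelic Per-patient multi-allelic error records
#'   (genotype 1/2, two ALT alleles).
#' @param separation Class-separation knob (>= 0) for the quality/bias
#'   features.
#' @param ref_length Reference length; panel regions are laid out inside
#'   it.
#' @param repeat_fraction Soft-masked fraction of the reference.
#' @param coverage_mean Mean unique-molecule coverage.
#' @param synonymous_fraction Fraction of variants annotated with a
#'   synonymous (non-kept) consequence.
#' @param n_decoy_cosmic,n_decoy_dbsnp Membership-table decoy keys never
#'   called in the cohort.
#' @param seed Integer seed; identical spec + seed give byte-identical
#'   outputs.
#' @param dir If non-NULL, write all fixture files (per-patient VCFs,
#'   BED, FASTA, membership and annotation TSVs, truth table) there.
#' @return List with `calls` (combined calls data frame with a `patient`
#'   column), `truth` (per-call key/class/label table), `regions`,
#'   `reference`, `cosmic`, `dbsnp`, `cohort_sets` (list: tcga, basis,
#'   icgc), `consequences`, `params` and (when `dir` is given) `files`.
#' @export
make_cohort <- function(n_patients = 70,
                        n_somatic = 2, n_het = 2, n_hom = 1, n_error = 4,
                        n_noncosmic = 1, n_multiallelic = 1,
                        separation = 2,
                        ref_length = 50000, repeat_fraction = 0.2,
                        coverage_mean = 800,
                        synonymous_fraction = 0.25,
                        n_decoy_cosmic = 20, n_decoy_dbsnp = 20,
                        seed = 1, dir = NULL) {
  per_patient <- n_somatic + n_het + n_hom + n_error + n_noncosmic +
    n_multiallelic
  if (n_patients < 1 || per_patient == 0)
    stop("make_cohort: infeasible spec (no patients or no calls)")

  reference <- make_reference(ref_length, repeat_fraction, seed = seed,
                              chrom = "chr1")
  set.seed(seed + 1)

  # panel regions: tiled 400 bp windows with gaps, away from sequence ends
  n_regions <- max(4L, ref_length %/% 1250L)
  starts <- seq(100, ref_length - 500, length.out = n_regions)
  regions <- data.frame(chrom = "chr1", start = as.integer(starts),
                        end = as.integer(starts) + 400L)

  pool <- unlist(lapply(seq_len(nrow(regions)), function(i)
    (regions$start[i] + 1L):regions$end[i]))  # 1-based positions in regions
  pool <- pool[pool > 31 & pool <= ref_length - 31]
  n_sites <- n_patients * (n_somatic + n_het + n_hom + n_error +
                             n_noncosmic) + n_patients * n_multiallelic +
    n_decoy_cosmic + n_decoy_dbsnp
  if (length(pool) < n_sites)
    stop("make_cohort: reference too short for the requested number of calls")
  sites <- sample(pool, n_sites)
  site_cursor <- 0L
  take_sites <- function(n) {
    out <- sites[site_cursor + seq_len(n)]
    site_cursor <<- site_cursor + n
    out
  }

  ref_base_at <- function(pos)
    toupper(substr(reference[[1]], pos, pos))
  other_base <- function(ref)
    vapply(ref, function(b) sample(setdiff(c("A", "C", "G", "T"), b), 1),
           character(1), USE.NAMES = FALSE)

  gen_calls <- function(patient, class, n) {
    if (n == 0) return(NULL)
    pos <- take_sites(n)
    ref <- ref_base_at(pos)
    alt <- other_base(ref)
    vp <- .class_vaf_params()[[class]]
    vaf <- stats::rbeta(n, vp[1], vp[2])
    cov <- 50L + stats::rnbinom(n, mu = coverage_mean, size = 10)
    alt_umi <- pmax(1L, stats::rbinom(n, cov, vaf))
    ref_umi <- cov - alt_umi
    real <- class %in% c("somatic", "germline_het", "germline_hom")
    qual <- pmax(0.1, stats::rnorm(n, if (real) 20 + 10 * separation else 20, 8))
    sgb <- stats::rnorm(n, if (real) -0.69 else -0.3, 0.1)
    rb <- function() if (real) stats::rbeta(n, 5, 1) else
      stats::rbeta(n, 1, 1 + separation)
    mq <- pmin(60, stats::rnorm(n, if (real) 58 else 58 - 3 * separation,
                                if (real) 2 else 4))
    dp <- round(cov * stats::runif(n, 1.8, 2.5))
    ref_reads <- round(dp * (1 - alt_umi / cov))
    alt_reads <- dp - ref_reads
    strand_p <- if (real) 0.5 else 0.85
    alt_fwd <- stats::rbinom(n, alt_reads, strand_p)
    ref_fwd <- stats::rbinom(n, ref_reads, 0.5)
    genotype <- switch(class,
      germline_hom = rep("1/1", n),
      error = ifelse(stats::runif(n) < 0.3, "0/0", "0/1"),
      rep("0/1", n))
    id <- if (class %in% c("germline_het", "germline_hom"))
      sprintf("rs%07d", pos) else NA_character_
    data.frame(
      sample_id = patient, chrom = "chr1", pos = pos, id = id,
      ref = ref, alt = alt, qual = round(qual, 2), genotype = genotype,
      ref_umi = ref_umi, alt_umi = alt_umi, dp = dp,
      sgb = round(sgb, 4), rpb = round(rb(), 4), mqb = round(rb(), 4),
      mqsb = round(rb(), 4), bqb = round(rb(), 4),
      ac = ifelse(genotype == "0/0", 0, ifelse(genotype == "1/1", 2, 1)),
      mq = round(mq), ref_fwd = ref_fwd, ref_rev = ref_reads - ref_fwd,
      alt_fwd = alt_fwd, alt_rev = alt_reads - alt_fwd,
      allele_call = NA_character_, class = class,
      stringsAsFactors = FALSE
    )
  }

  gen_multiallelic <- function(patient, n) {
    if (n == 0) return(NULL)
    pos <- take_sites(n)
    rows <- lapply(seq_len(n), function(i) {
      ref <- ref_base_at(pos[i])
      alts <- sample(setdiff(c("A", "C", "G", "T"), ref), 2)
      cov <- 50L + stats::rnbinom(1, mu = coverage_mean, size = 10)
      a1 <- max(1L, stats::rbinom(1, cov, 0.02))
      a2 <- max(1L, stats::rbinom(1, cov, 0.02))
      data.frame(
        sample_id = patient, chrom = "chr1", pos = pos[i],
        id = NA_character_, ref = ref, alt = alts,
        qual = round(pmax(0.1, stats::rnorm(1, 15, 5)), 2),
        genotype = "1/2", ref_umi = cov - a1 - a2, alt_umi = c(a1, a2),
        dp = round(cov * 2), sgb = round(stats::rnorm(1, -0.3, 0.1), 4),
        rpb = round(stats::rbeta(1, 1, 2), 4),
        mqb = round(stats::rbeta(1, 1, 2), 4),
        mqsb = round(stats::rbeta(1, 1, 2), 4),
        bqb = round(stats::rbeta(1, 1, 2), 4),
        ac = 1, mq = 55, ref_fwd = (cov - a1 - a2) %/% 2,
        ref_rev = (cov - a1 - a2) - (cov - a1 - a2) %/% 2,
        alt_fwd = c(a1, a2) %/% 2 + c(a1, a2) %% 2,
        alt_rev = c(a1, a2) %/% 2,
        allele_call = NA_character_, class = "multiallelic",
        stringsAsFactors = FALSE
      )
    })
    do.call(rbind, rows)
  }

  patients <- sprintf("P%03d", seq_len(n_patients))
  calls <- do.call(rbind, unlist(lapply(patients, function(p) {
    list(gen_calls(p, "somatic", n_somatic),
         gen_calls(p, "germline_het", n_het),
         gen_calls(p, "germline_hom", n_hom),
         gen_calls(p, "error", n_error),
         gen_calls(p, "noncosmic", n_noncosmic),
         gen_multiallelic(p, n_multiallelic))
  }), recursive = FALSE))
  rownames(calls) <- NULL

  key <- variant_key(calls$chrom, calls$pos, calls$ref, calls$alt)
  truth <- data.frame(patient = calls$sample_id, chrom = calls$chrom,
                      pos = calls$pos, ref = calls$ref, alt = calls$alt,
                      key = key, class = calls$class,
                      label = calls$class %in%
                        c("somatic", "germline_het", "germline_hom"),
                      stringsAsFactors = FALSE)

  decoy_keys <- function(n) {
    if (n == 0) return(character(0))
    pos <- take_sites(n)
    ref <- ref_base_at(pos)
    variant_key("chr1", pos, ref, other_base(ref))
  }
  cosmic <- membership_set(
    c(key[calls$class != "noncosmic"], decoy_keys(n_decoy_cosmic)), "cosmic")
  dbsnp <- membership_set(
    c(key[calls$class %in% c("germline_het", "germline_hom")],
      decoy_keys(n_decoy_dbsnp)), "dbsnp")

  somatic_keys <- unique(key[calls$class == "somatic"])
  assign <- lapply(somatic_keys, function(k) {
    sets <- c("tcga", "basis", "icgc")
    sets[stats::runif(3) < c(0.6, 0.5, 0.4)]
  })
  # guarantee membership in at least one cohort set
  empty <- vapply(assign, length, integer(1)) == 0
  assign[empty] <- lapply(which(empty), function(i)
    sample(c("tcga", "basis", "icgc"), 1))
  cohort_sets <- lapply(c(tcga = "tcga", basis = "basis", icgc = "icgc"),
                        function(s) membership_set(
                          somatic_keys[vapply(assign, function(a) s %in% a,
                                              logical(1))], s))

  all_keys <- unique(key)
  syn <- stats::runif(length(all_keys)) < synonymous_fraction
  cons <- ifelse(syn, "synonymous_variant",
                 sample(c("missense_variant", "stop_gained", "intron_variant"),
                        length(all_keys), replace = TRUE,
                        prob = c(0.75, 0.10, 0.15)))
  consequences <- data.frame(key = all_keys, most_severe = cons,
                             stringsAsFactors = FALSE)

  out <- list(calls = calls[, setdiff(names(calls), "class")],
              truth = truth, regions = regions, reference = reference,
              cosmic = cosmic, dbsnp = dbsnp, cohort_sets = cohort_sets,
              consequences = consequences,
              params = list(n_patients = n_patients, n_somatic = n_somatic,
                            n_het = n_het, n_hom = n_hom, n_error = n_error,
                            n_noncosmic = n_noncosmic,
                            n_multiallelic = n_multiallelic,
                            separation = separation, ref_length = ref_length,
                            repeat_fraction = repeat_fraction,
                            coverage_mean = coverage_mean,
                            synonymous_fraction = synonymous_fraction,
                            seed = seed))
  out$calls$patient <- calls$sample_id

  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list()
    for (p in patients) {
      pc <- out$calls[out$calls$patient == p, , drop = FALSE]
      pc <- pc[order(pc$pos), , drop = FALSE]
      f <- file.path(dir, paste0(p, ".vcf"))
      write_variant_vcf(pc, f, sample_id = p)
      files[[p]] <- f
    }
    files$regions <- write_regions(regions, file.path(dir, "regions.bed"))
    files$reference <- write_masked_reference(reference,
                                              file.path(dir, "reference.fa"))
    files$cosmic <- write_membership(cosmic, file.path(dir, "cosmic.tsv"))
    files$dbsnp <- write_membership(dbsnp, file.path(dir, "dbsnp.tsv"))
    for (s in names(cohort_sets))
      files[[s]] <- write_membership(cohort_sets[[s]],
                                     file.path(dir, paste0(s, ".tsv")))
    tr <- truth
    utils::write.table(tr, file.path(dir, "truth.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$truth <- file.path(dir, "truth.tsv")
    cq <- consequences
    parts <- do.call(rbind, strsplit(cq$key, ":", fixed = TRUE))
    cq_out <- data.frame(chrom = parts[, 1], pos = parts[, 2],
                         ref = parts[, 3], alt = parts[, 4],
                         consequence = cq$most_severe)
    utils::write.table(cq_out, file.path(dir, "consequences.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE)
    files$consequences <- file.path(dir, "consequences.tsv")
    out$files <- files
  }
  out
}

#' Labeled training data from a synthetic cohort
#'
#' Convenience wrapper: applies [basic_filter()] to a cohort's calls,
#' joins the truth labels by variant key within patient, and builds the
#' 22-column feature matrix — the inputs [lopo_evaluate()] and
#' [train_final()] expect.
#'
#' @param cohort A cohort from [make_cohort()].
#' @return List with `calls`, `features` (n x 22 matrix), `labels`
#'   (logical), `patients` (character).
#' @export
cohort_training_data <- function(cohort) {
  kept <- basic_filter(cohort$calls, cohort$regions, cohort$cosmic)
  idx <- match(paste(kept$patient, call_keys(kept)),
               paste(cohort$truth$patient, cohort$truth$key))
  labels <- cohort$truth$label[idx]
  fm <- build_feature_matrix(kept, cohort$reference)
  list(calls = kept, features = fm$features, mask = fm$mask,
       labels = labels, patients = kept$patient)
}
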