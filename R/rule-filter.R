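#' The exhaustive grid of rule-based filters
#'
#' The rule-based baseline thresholds unique-molecule coverage, VAF and
#' call quality. The grid crosses 9 coverage values (10, 20, 50, 75, 100,
#' 150, 200, 500, 1000 unique molecules), 11 VAF values (0.1%, 0.5%, 1%,
#' 2%, 3%, 4%, 5%, 7.5%, 10%, 15%, 20%) and 10 quality values (1, 2, 5,
#' 10, 15, 20, 25, 30, 40, 50): 990 rules in total, in deterministic
#' coverage-major order (then VAF, then quality).
#'
#' @return Data frame with columns `min_coverage`, `min_vaf`,
#'   `min_quality`; 990 rows.
#' @export
generate_grid <- function() {
  coverage <- c(10, 20, 50, 75, 100, 150, 200, 500, 1000)
  vaf <- c(0.001, 0.005, 0.01, 0.02, 0.03, 0.04, 0.05, 0.075, 0.10, 0.15, 0.20)
  quality <- c(1, 2, 5, 10, 15, 20, 25, 30, 40, 50)
  g <- expand.grid(min_quality = quality, min_vaf = vaf, min_coverage = coverage,
                   KEEP.OUT.ATTRS = FALSE)
  out <- g[, c("min_coverage", "min_vaf", "min_quality")]
  rownames(out) <- NULL
  out
}

.rule_keep <- function(calls, min_coverage, min_vaf, min_quality) {
  cov <- call_coverage(calls)
  vaf <- call_vaf(calls)
  !is.na(cov) & !is.na(vaf) & !is.na(calls$qual) &
    cov >= min_coverage & vaf >= min_vaf & calls$qual >= min_quality
}

#' Apply one filter rule
#'
#' Keeps calls whose unique-molecule coverage, VAF and quality are all at
#' least the rule's thresholds (inclusive minima).
#'
#' @param rule One-row data frame (or list) with `min_coverage`,
#'   `min_vaf`, `min_quality`.
#' @param calls A calls data frame.
#' @return The kept calls.
#' @export
apply_rule <- function(rule, calls) {
  keep <- .rule_keep(calls, rule$min_coverage, rule$min_vaf, rule$min_quality)
  out <- calls[keep, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Stratified fold assignment
#'
#' Assigns observations to `k` folds preserving class proportions.
#' If a draw leaves some fold without both classes, the assignment is
#' re-drawn with the next seed (logged), up to 25 attempts.
#'
#' @param labels Logical class labels.
#' @param k Number of folds.
#' @param seed Integer seed for the assignment.
#' @return Integer vector of fold ids in `1..k`.
#' @export
stratified_folds <- function(labels, k = 4, seed = 1) {
  n <- length(labels)
  if (n < k) stop("stratified_folds: fewer observations than folds")
  if (length(unique(labels)) < 2)
    stop("stratified_folds: both classes must be present")
  for (attempt in 0:24) {
    set.seed(seed + attempt)
    fold <- integer(n)
    for (cls in unique(labels)) {
      idx <- which(labels == cls)
      fold[idx] <- sample(rep_len(seq_len(k), length(idx)))
    }
    ok <- all(vapply(seq_len(k), function(f)
      length(unique(labels[fold == f])) == 2, logical(1)))
    if (ok || min(table(labels)) < k) {
      if (attempt > 0)
        message(sprintf("stratified_folds: re-drew folds %d time(s) to avoid single-class folds",
                        attempt))
      return(fold)
    }
  }
  fold
}

.rule_cv_f1 <- function(calls, labels, grid, fold, k) {
  cov <- call_coverage(calls)
  vaf <- call_vaf(calls)
  qual <- calls$qual
  mean_f1 <- numeric(nrow(grid))
  for (r in seq_len(nrow(grid))) {
    keep <- !is.na(cov) & !is.na(vaf) & !is.na(qual) &
      cov >= grid$min_coverage[r] & vaf >= grid$min_vaf[r] &
      qual >= grid$min_quality[r]
    f1s <- vapply(seq_len(k), function(f) {
      te <- fold == f
      m <- metrics_from_decisions(labels[te], keep[te])
      m$f1
    }, numeric(1))
    mean_f1[r] <- mean(f1s)
  }
  mean_f1
}

#' Select the best filter rule by cross-validated F1
#'
#' Evaluates all 990 rules of [generate_grid()] by stratified k-fold
#' cross-validation on pooled labeled calls and returns the rule with the
#' highest mean held-out F1 score. Ties are broken by grid order (first
#' rule wins), making selection deterministic given the fold seed.
#'
#' @param calls A calls data frame.
#' @param labels Logical truth labels, one per call.
#' @param folds Number of folds (default 4).
#' @param seed Fold-assignment seed.
#' @param grid Rule grid; defaults to [generate_grid()].
#' @return The selected rule (one-row data frame) with attributes
#'   `mean_f1` (of the winner) and `cv_f1` (per-rule mean F1).
#' @export
select_rule_cv <- function(calls, labels, folds = 4, seed = 1,
                           grid = generate_grid()) {
  stopifnot(nrow(calls) == length(labels))
  if (length(unique(labels)) < 2)
    stop("select_rule_cv: need both classes in the labels")
  fold <- stratified_folds(labels, k = folds, seed = seed)
  mean_f1 <- .rule_cv_f1(calls, labels, grid, fold, folds)
  best <- which.max(mean_f1)  # first maximum = grid order tie-break
  out <- grid[best, , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "mean_f1") <- mean_f1[best]
  attr(out, "cv_f1") <- mean_f1
  out
}
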