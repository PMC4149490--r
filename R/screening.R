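# Screening statistics: percent-positive matrix assembly, the 1% nominal
# detection limit, the dual >=5-percentage-point / >=2-fold
# treatment-lability classifier, replicate reproducibility, and
# differential candidate ranking.

#' Screening criteria
#'
#' @param detection_limit_percent Nominal limit of detection: antigens below
#'   1 percent positive are treated as undetected.
#' @param min_absolute_delta_percent Minimum absolute change (percentage
#'   points) for a treatment effect.
#' @param min_fold_change Minimum fold change (bidirectional max/min ratio)
#'   for a treatment effect.
#' @param fold_floor_percent Denominator clamp for the fold change; defaults
#'   to the detection limit so sub-detection values cannot blow up ratios.
#' @return An object of class `screen_criteria`.
#' @export
screen_criteria <- function(detection_limit_percent = 1.0,
                            min_absolute_delta_percent = 5.0,
                            min_fold_change = 2.0,
                            fold_floor_percent = detection_limit_percent) {
  stopifnot(detection_limit_percent > 0, min_absolute_delta_percent > 0,
            min_fold_change > 1, fold_floor_percent > 0)
  structure(list(detection_limit_percent = detection_limit_percent,
                 min_absolute_delta_percent = min_absolute_delta_percent,
                 min_fold_change = min_fold_change,
                 fold_floor_percent = fold_floor_percent),
            class = "screen_criteria")
}

#' Assemble a percent-positive matrix from gate summaries
#'
#' One row per sample (or sample/population), one column per antigen.
#' QC-failed wells become missing values, never zero.
#'
#' @param summaries Named list, row identifier -> gate-summary data frame
#'   from [gate_plate()] (columns `antigen`, `percent_positive`, `qc_pass`).
#' @param map Optional [plate_map]; when given, columns are ordered by the
#'   panel's antibody order and completeness is checked.
#' @return Numeric matrix (class `percent_positive_matrix`), rows = samples,
#'   columns = antigens, `NA` for QC failures.
#' @export
assemble_matrix <- function(summaries, map = NULL) {
  stopifnot(length(summaries) >= 1L, !is.null(names(summaries)))
  antigens <- if (!is.null(map)) {
    map$wells$antigen[map$wells$antigen != "CONTROL"]
  } else {
    unique(unlist(lapply(summaries, `[[`, "antigen")))
  }
  out <- matrix(NA_real_, nrow = length(summaries), ncol = length(antigens),
                dimnames = list(names(summaries), antigens))
  for (s in names(summaries)) {
    g <- summaries[[s]]
    if (anyDuplicated(g$antigen)) {
      stop("antigen measured twice for sample ", s, ": ",
           paste(unique(g$antigen[duplicated(g$antigen)]), collapse = ", "))
    }
    miss <- setdiff(antigens, g$antigen)
    if (length(miss)) {
      stop("sample ", s, " has no gate summary for: ",
           paste(miss, collapse = ", "))
    }
    v <- g$percent_positive[match(antigens, g$antigen)]
    v[!g$qc_pass[match(antigens, g$antigen)]] <- NA_real_
    out[s, ] <- v
  }
  class(out) <- c("percent_positive_matrix", class(out))
  out
}

#' Antigens detected above the nominal limit
#'
#' @param profile Named numeric vector (one matrix row), percents.
#' @param criteria A [screen_criteria].
#' @return Character vector of antigens with value >= the detection limit
#'   (inclusive); missing values count as undetected.
#' @export
detectability_filter <- function(profile, criteria = screen_criteria()) {
  stopifnot(length(profile) >= 1L)
  names(profile)[!is.na(profile) &
                 profile >= criteria$detection_limit_percent]
}

#' Classify a treatment effect on one antigen
#'
#' An antigen is called labile ("both") when the absolute change is at least
#' `min_absolute_delta_percent` percentage points and the bidirectional fold
#' change at least `min_fold_change`. Fold change is max/min of the two
#' values after clamping below at `fold_floor_percent`, so gains and losses
#' are treated symmetrically and zeros stay finite.
#'
#' @param untreated,treated Percent-positive values.
#' @param criteria A [screen_criteria].
#' @return One-row data frame: untreated_percent, treated_percent,
#'   absolute_delta, fold_change, direction (`"up"`/`"down"`/`"none"`),
#'   category in undetected / unaffected / abs_only / fold_only / both /
#'   missing.
#' @export
classify_treatment_effect <- function(untreated, treated,
                                      criteria = screen_criteria()) {
  if (is.na(untreated) || is.na(treated)) {
    return(data.frame(untreated_percent = untreated,
                      treated_percent = treated,
                      absolute_delta = NA_real_, fold_change = NA_real_,
                      direction = NA_character_, category = "missing",
                      stringsAsFactors = FALSE))
  }
  delta <- abs(treated - untreated)
  u <- max(untreated, criteria$fold_floor_percent)
  t <- max(treated, criteria$fold_floor_percent)
  fold <- max(u, t) / min(u, t)
  abs_hit <- delta >= criteria$min_absolute_delta_percent
  fold_hit <- fold >= criteria$min_fold_change
  category <- if (untreated < criteria$detection_limit_percent &&
                  treated < criteria$detection_limit_percent) {
    "undetected"
  } else if (abs_hit && fold_hit) "both"
  else if (abs_hit) "abs_only"
  else if (fold_hit) "fold_only"
  else "unaffected"
  data.frame(untreated_percent = untreated, treated_percent = treated,
             absolute_delta = delta, fold_change = fold,
             direction = if (treated > untreated) "up"
                         else if (treated < untreated) "down" else "none",
             category = category, stringsAsFactors = FALSE)
}

#' Screen a treated profile against its untreated reference
#'
#' @param untreated,treated Named percent-positive vectors (matrix rows)
#'   sharing antigen names.
#' @param criteria A [screen_criteria].
#' @param treatment Label recorded in the result.
#' @return Data frame (class `screen_result`), one row per shared antigen.
#' @export
screen_treatment <- function(untreated, treated,
                             criteria = screen_criteria(),
                             treatment = NA_character_) {
  shared <- intersect(names(untreated), names(treated))
  if (!length(shared)) stop("no shared antigens")
  rows <- lapply(shared, function(ag) {
    classify_treatment_effect(unname(untreated[[ag]]), unname(treated[[ag]]),
                              criteria)
  })
  out <- do.call(rbind, rows)
  out <- cbind(data.frame(antigen = shared, treatment = treatment,
                          stringsAsFactors = FALSE), out)
  class(out) <- c("screen_result", class(out))
  out
}

#' Summarize a screen by lability category
#'
#' @param results A `screen_result` data frame (possibly several treatments
#'   row-bound together).
#' @return List with `counts` (named, per category), `per_treatment` (table
#'   of category by treatment), `n_detected` (antigens not undetected or
#'   missing), `n_influenced` (abs_only + fold_only + both) and
#'   `influenced_percent` (integer percent, truncated toward zero as the
#'   screen reports it: 79 of 258 prints as 30).
#' @export
screen_summary <- function(results) {
  cats <- c("undetected", "unaffected", "abs_only", "fold_only", "both",
            "missing")
  counts <- vapply(cats, function(cc) sum(results$category == cc), 0L)
  n_detected <- sum(!results$category %in% c("undetected", "missing"))
  n_influenced <- sum(results$category %in% c("abs_only", "fold_only", "both"))
  list(counts = counts,
       per_treatment = if (nrow(results)) {
         table(results$treatment, results$category)
       } else table(character(), character()),
       n_detected = n_detected,
       n_influenced = n_influenced,
       influenced_percent = if (n_detected > 0) {
         trunc(100 * n_influenced / n_detected)
       } else NA_real_)
}

# rho and p-value for Spearman's rank correlation; exact two-sided
# permutation p for n <= 8, t approximation otherwise
.spearman <- function(x, y) {
  rx <- rank(x); ry <- rank(y)   # average-rank ties
  n <- length(x)
  rho <- stats::cor(rx, ry)
  if (n <= 8) {
    perms <- .permutations(n)
    null_rho <- apply(perms, 1L, function(p) stats::cor(rx, ry[p]))
    p <- mean(abs(null_rho) >= abs(rho) - 1e-12)
    method <- "exact permutation"
  } else {
    tstat <- rho * sqrt((n - 2) / (1 - rho^2))
    p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    method <- "t approximation"
  }
  list(rho = rho, p_value = min(1, p), n = n, method = method)
}

.permutations <- function(n) {
  if (n == 1L) return(matrix(1L, 1, 1))
  sub <- .permutations(n - 1L)
  do.call(rbind, lapply(seq_len(n), function(i) {
    cbind(i, sub + (sub >= i))
  }))
}

#' Replicate-run reproducibility
#'
#' Spearman rank correlation of percent-positive profiles from two runs of
#' the same sample, over antigens observed in both. Ties take average
#' ranks; the two-sided p-value is by exact permutation for n <= 8 shared
#' antigens and by the t approximation otherwise (method reported).
#'
#' @param run_a,run_b Named percent-positive vectors.
#' @return List with `rho`, `p_value`, `n` (shared antigens) and `method`.
#' @export
replicate_reproducibility <- function(run_a, run_b) {
  shared <- intersect(names(run_a)[!is.na(run_a)],
                      names(run_b)[!is.na(run_b)])
  if (length(shared) < 3L) {
    stop("need >= 3 shared non-missing antigens (got ", length(shared), ")")
  }
  .spearman(as.numeric(run_a[shared]), as.numeric(run_b[shared]))
}

#' Rank candidate markers enriched in a reference population
#'
#' Differential selection of surface markers highly expressed on a pure
#' reference population (e.g. cultured cancer-associated fibroblasts) but
#' low on a comparison fraction (e.g. the CD45/CD31-negative fraction of
#' primary tumors): candidates must average at least
#' `min_reference_percent` in the reference rows and at most
#' `max_target_percent` in the target rows, ranked by the mean difference
#' (ties broken alphabetically).
#'
#' @param reference Matrix rows (or named-vector list) of reference
#'   profiles.
#' @param target Matrix rows of comparison profiles.
#' @param min_reference_percent Minimum mean reference expression.
#' @param max_target_percent Maximum mean target expression.
#' @return Data frame: antigen, reference_mean, target_mean, score
#'   (reference - target), ordered by decreasing score.
#' @export
rank_candidates <- function(reference, target,
                            min_reference_percent = 50,
                            max_target_percent = 20) {
  reference <- rbind(reference)
  target <- rbind(target)
  shared <- intersect(colnames(reference), colnames(target))
  if (!length(shared)) stop("no shared antigens")
  ref_mean <- colMeans(reference[, shared, drop = FALSE], na.rm = TRUE)
  tgt_mean <- colMeans(target[, shared, drop = FALSE], na.rm = TRUE)
  keep <- !is.na(ref_mean) & !is.na(tgt_mean) &
    ref_mean >= min_reference_percent & tgt_mean <= max_target_percent
  out <- data.frame(antigen = shared[keep],
                    reference_mean = unname(ref_mean[keep]),
                    target_mean = unname(tgt_mean[keep]),
                    score = unname(ref_mean[keep] - tgt_mean[keep]),
                    stringsAsFactors = FALSE)
  out[order(-out$score, out$antigen), , drop = FALSE]
}
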