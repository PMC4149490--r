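mk_summary <- function(antigens, values, qc = TRUE) {
  data.frame(antigen = antigens, percent_positive = values,
             qc_pass = qc, stringsAsFactors = FALSE)
}

test_that("matrix assembly maps wells to cells and missingness correctly", {
  map <- demo_plate_map()
  ags <- map$wells$antigen[map$wells$antigen != "CONTROL"]
  sums <- list(S1 = mk_summary(ags, seq_along(ags)),
               S2 = mk_summary(rev(ags), rev(seq_along(ags))),
               S3 = mk_summary(ags, seq_along(ags) + 1))
  m <- assemble_matrix(sums, map)
  expect_equal(dim(m), c(3L, 24L))
  # permuting input well order leaves the matrix unchanged
  expect_equal(m["S1", ], m["S2", ])

  # qc failure becomes NA, not zero
  qc <- rep(TRUE, 24); qc[3] <- FALSE
  m2 <- assemble_matrix(list(S1 = mk_summary(ags, seq_along(ags), qc)), map)
  expect_true(is.na(m2[1, ags[3]]))
  expect_false(any(is.na(m2[1, -3])))

  dup <- mk_summary(c(ags, ags[1]), c(seq_along(ags), 99))
  expect_error(assemble_matrix(list(S1 = dup), map), "twice")
})

test_that("detectability filter applies the 1% limit inclusively", {
  prof <- c(A = 0.9, B = 1.0, C = 50, D = 0, E = NA)
  det <- detectability_filter(prof, screen_criteria())
  expect_equal(det, c("B", "C"))   # 1.0 is included, 0.9 and NA are not
  expect_equal(detectability_filter(c(A = 0, B = 0)), character(0))
})

test_that("dual-criterion classifier reproduces the worked categories", {
  cr <- screen_criteria()
  r <- classify_treatment_effect(40, 10, cr)
  expect_equal(r$absolute_delta, 30)
  expect_equal(r$fold_change, 4)
  expect_equal(r$category, "both")
  expect_equal(r$direction, "down")

  r2 <- classify_treatment_effect(4, 1, cr)
  expect_equal(r2$fold_change, 4)
  expect_equal(r2$category, "fold_only")

  r3 <- classify_treatment_effect(50, 44, cr)
  expect_equal(r3$absolute_delta, 6)
  expect_equal(r3$category, "abs_only")

  expect_equal(classify_treatment_effect(0.4, 0.8, cr)$category, "undetected")
  expect_equal(classify_treatment_effect(NA, 10, cr)$category, "missing")
})

test_that("classifier is symmetric up to direction and folds stay finite", {
  cr <- screen_criteria()
  set.seed(42)
  for (i in 1:50) {
    u <- runif(1, 0, 100); t <- runif(1, 0, 100)
    a <- classify_treatment_effect(u, t, cr)
    b <- classify_treatment_effect(t, u, cr)
    expect_equal(a$category, b$category)
    expect_equal(a$absolute_delta, b$absolute_delta)
    expect_equal(a$fold_change, b$fold_change)
    expect_gte(a$fold_change, 1)
  }
  # clamping at the detection limit keeps zero denominators finite
  expect_equal(classify_treatment_effect(0, 50, cr)$fold_change, 50)
})

test_that("screen summary counts categories and the influenced fraction", {
  # printed-arithmetic check: 79 influenced of 258 detected is 30%
  res <- data.frame(
    antigen = sprintf("A%03d", 1:258),
    treatment = "digestion",
    category = c(rep("both", 22), rep("abs_only", 30), rep("fold_only", 27),
                 rep("unaffected", 179)),
    stringsAsFactors = FALSE)
  s <- screen_summary(res)
  expect_equal(s$n_detected, 258L)
  expect_equal(s$n_influenced, 79L)
  expect_equal(s$influenced_percent, 30)

  # counts partition the detected set
  expect_equal(sum(s$counts[c("unaffected", "abs_only", "fold_only", "both")]),
               s$n_detected)

  empty <- screen_summary(res[0, ])
  expect_true(all(empty$counts == 0))

  # invariant to antigen order
  s2 <- screen_summary(res[sample(nrow(res)), ])
  expect_equal(s2$counts, s$counts)
})

test_that("Spearman reproducibility matches rank-formula and stats oracles", {
  a <- c(A = 1, B = 2, C = 3, D = 4, E = 5)
  expect_equal(replicate_reproducibility(a, a)$rho, 1)
  expect_equal(replicate_reproducibility(a, setNames(rev(unname(a)),
                                                     names(a)))$rho, -1)

  x <- c(A = 3, B = 10, C = 2, D = 55, E = 4)
  y <- c(A = 12, B = 90, C = 1, D = 30, E = 3)
  r <- replicate_reproducibility(x, y)
  expect_equal(r$rho, spearman_d2(x, y))
  expect_equal(r$rho, unname(cor(x, y, method = "spearman")))
  expect_equal(r$method, "exact permutation")
  # exact permutation p agrees with cor.test's exact p (tie-free, n = 5)
  ct <- suppressWarnings(cor.test(x, y, method = "spearman", exact = TRUE))
  expect_equal(r$p_value, ct$p.value, tolerance = 1e-12)

  big <- setNames(rnorm(20), paste0("g", 1:20))
  big2 <- big + rnorm(20, sd = 0.2)
  rb <- replicate_reproducibility(big, big2)
  expect_equal(rb$method, "t approximation")
  expect_equal(rb$rho, unname(cor(big, big2, method = "spearman")))

  expect_error(replicate_reproducibility(a[1:2], a[1:2]), ">= 3")
  # missing values are dropped pairwise
  xm <- x; xm["B"] <- NA
  expect_equal(replicate_reproducibility(xm, y)$n, 4L)
})

test_that("candidate ranking selects reference-high, target-low antigens", {
  ref <- rbind(c(CAF1 = 90, X = 90, Y = 10), c(90, 80, 12))
  colnames(ref) <- c("A", "B", "C")
  tgt <- rbind(c(A = 5, B = 80, C = 5))
  out <- rank_candidates(ref, tgt)
  expect_equal(out$antigen, "A")       # B fails max_target, C fails min_ref
  expect_equal(out$score, 85)

  # planted recovery: 5 reference-specific antigens among 24
  set.seed(7)
  ags <- sprintf("AG%02d", 1:24)
  planted <- ags[c(2, 7, 11, 18, 23)]
  ref2 <- matrix(runif(24 * 3, 0, 15), 3, dimnames = list(NULL, ags))
  tgt2 <- matrix(runif(24 * 4, 0, 15), 4, dimnames = list(NULL, ags))
  ref2[, planted] <- runif(15, 70, 95)
  out2 <- rank_candidates(ref2, tgt2)
  expect_setequal(out2$antigen, planted)
  # ranked by descending reference - target difference
  expect_true(all(diff(out2$score) <= 0))
})

test_that("single-seed planted lability screen recovers the planted set", {
  # one untreated/digested plate pair; the 20-seed sensitivity/specificity
  # sweep lives with the acceptance properties
  tr <- demo_digestion_treatment()
  u <- demo_profile_row(seed = 5001)
  t <- demo_profile_row(seed = 6001, treatment = tr)
  res <- screen_treatment(u, t, screen_criteria(), treatment = tr$label)
  expect_setequal(res$antigen[res$category == "both"], attr(tr, "labile"))
})
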