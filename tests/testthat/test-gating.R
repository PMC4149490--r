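test_that("FMO threshold uses the documented interpolation quantile", {
  mk <- function(v) event_table(matrix(v, ncol = 1,
                                       dimnames = list(NULL, "PE-A")))
  v100 <- c(1:97, 1, 2, 3)
  expect_equal(fmo_threshold(mk(v100), "PE-A", 100), 97)
  expect_equal(fmo_threshold(mk(rep(7, 150)), "PE-A", 99.9), 7)
  expect_equal(fmo_threshold(mk(rep(7, 150)), "PE-A", 75), 7)

  # against a full-sort linear-interpolation oracle
  set.seed(1)
  x <- rlnorm(10000)
  s <- sort(x)
  h <- (10000 - 1) * 0.999 + 1
  oracle <- s[floor(h)] + (h - floor(h)) * (s[floor(h) + 1] - s[floor(h)])
  expect_equal(fmo_threshold(mk(x), "PE-A", 99.9), oracle)

  expect_error(fmo_threshold(mk(1:50), "PE-A", 99.9), "QC error")
  expect_error(fmo_threshold(mk(v100), "FITC-A", 99.9), "not present")
})

test_that("viability gate keeps dye-low events and is monotone in percentile", {
  ev <- simulate_well(single_pop(c(X = 0)),
                      NULL, technical_noise(2000, dead_fraction = 0.25,
                                            doublet_fraction = 0,
                                            spillover = spillover_matrix("PE-A"),
                                            intensity_jitter_sd = 0),
                      seed = 2)
  expect_true(all(gate_viable(ev, gate_config(), threshold = Inf)))
  expect_error(gate_viable(ev, gate_config(viability_channel = "LIVE-A"),
                           threshold = 1), "missing viability channel")

  ctrl <- simulate_well(single_pop(c(X = 0)), NULL, quiet_noise(2000),
                        seed = 3, viability_stain = FALSE)
  t1 <- fmo_threshold(ctrl, "DAPI-A", 99)
  t2 <- fmo_threshold(ctrl, "DAPI-A", 99.9)
  expect_gte(sum(gate_viable(ev, gate_config(), t2)),
             sum(gate_viable(ev, gate_config(), t1)))
})

test_that("singlet gate excludes area-doubled doublets", {
  noise <- technical_noise(10000, dead_fraction = 0, doublet_fraction = 0.10,
                           spillover = spillover_matrix("PE-A"),
                           intensity_jitter_sd = 0)
  ev <- simulate_well(single_pop(c(X = 0)), NULL, noise, seed = 4)
  truth <- attr(ev, "metadata")$truth
  mask <- gate_singlets(ev, gate_config())
  # planted doublets excluded, singlets retained, within 3 binomial SEs
  expect_lt(abs(mean(!mask) - 0.10), 3 * sqrt(0.1 * 0.9 / 10000) + 0.001)
  expect_gt(mean(mask[!truth$doublet]), 0.999)
  expect_lt(mean(mask[truth$doublet]), 0.001)

  one <- event_table(matrix(c(1, 1, 1), 1,
                            dimnames = list(NULL, c("FSC-H", "FSC-W", "DAPI-A"))))
  expect_true(gate_singlets(one, gate_config()))
})

test_that("gate chain is ordered and counts are non-increasing", {
  noise <- technical_noise(5000, dead_fraction = 0.1, doublet_fraction = 0.1,
                           spillover = spillover_matrix("PE-A"),
                           intensity_jitter_sd = 0)
  ev <- simulate_well(single_pop(c(X = 0.5)), antibody("X", "PE"),
                      noise, seed = 5)
  ctrl <- simulate_well(single_pop(c(X = 0)), NULL, noise, seed = 6,
                        viability_stain = FALSE)
  via <- fmo_threshold(ctrl, "DAPI-A", 99.9)
  g <- gate_events(ev, gate_config(min_events = 1000), via,
                   channel = "PE-A", threshold = 1e3)
  cn <- g$counts
  expect_true(cn[["total"]] >= cn[["viable"]] &&
              cn[["viable"]] >= cn[["analysis"]] &&
              cn[["analysis"]] >= cn[["positive"]])
  expect_true(g$qc_pass)
  g2 <- gate_events(ev, gate_config(min_events = 4999), via)
  expect_false(g2$qc_pass)   # ~19% of events fail viability or singlet gates
})

test_that("percent-positive arithmetic and monotonicity", {
  vals <- c(rep(0, 9750), rep(10, 250))
  ev <- event_table(cbind(`PE-A` = vals, `FSC-H` = 1, `FSC-W` = 1,
                          `DAPI-A` = 0))
  g <- gate_events(ev, gate_config(min_events = 1), viability_threshold = 1,
                   channel = "PE-A", threshold = 5)
  expect_equal(percent_positive(ev, g, "PE-A", 5), 2.5)
  expect_equal(percent_positive(ev, g, "PE-A", 11), 0)    # above max
  expect_equal(percent_positive(ev, g, "PE-A", -1), 100)  # below min
  thr <- c(-1, 0, 5, 11)
  pp <- sapply(thr, function(t) percent_positive(ev, g, "PE-A", t))
  expect_true(all(diff(pp) <= 0))
})

test_that("FMO false-positive contract: ~0.1% positives in control wells at 99.9", {
  pops <- single_pop(c(X = 0))
  hits <- sapply(1:10, function(s) {
    ctrl <- simulate_well(pops, NULL, quiet_noise(10000), seed = 300 + s)
    test <- simulate_well(pops, NULL, quiet_noise(10000), seed = 400 + s)
    thr <- fmo_threshold(ctrl, "PE-A", 99.9)
    mean(test[, "PE-A"] > thr)
  })
  expect_lt(abs(mean(hits) - 0.001), 3 * sqrt(0.001 * 0.999 / 1e5))
})

test_that("compensation: identity is a no-op and the 2x2 case is closed-form", {
  ev <- event_table(cbind(`PE-A` = c(100, 50), `FITC-A` = c(20, 10),
                          `FSC-H` = 1, `FSC-W` = 1, `DAPI-A` = 0))
  id <- spillover_matrix(c("PE-A", "FITC-A"))
  expect_equal(unclass(apply_compensation(ev, id))[, 1:2], unclass(ev)[, 1:2])

  # 10% one-way spill PE -> FITC: S = [[1, .1], [0, 1]]
  S <- matrix(c(1, 0, 0.1, 1), 2, dimnames = list(c("PE-A", "FITC-A"),
                                                  c("PE-A", "FITC-A")))
  spill <- spillover_matrix(c("PE-A", "FITC-A"), S)
  obs <- event_table(cbind(`PE-A` = 100, `FITC-A` = 30))
  comp <- apply_compensation(obs, spill)
  # inverse of [[1,.1],[0,1]] is [[1,-.1],[0,1]]: true FITC = 30 - 10
  expect_equal(unname(comp[1, "PE-A"]), 100)
  expect_equal(unname(comp[1, "FITC-A"]), 20)

  Sbad <- matrix(c(1, 1, 1, 1), 2)
  expect_error(spillover_matrix(c("A", "B"), Sbad), "singular|off-diag|1")
})

test_that("lineage deconvolution follows ordered rules and recovers abundances", {
  thr <- c("APC-Cy7-A" = 10, "PE-Cy7-A" = 10, "PerCP-Cy5.5-A" = 10,
           "eFluor450-A" = 10)
  spec <- costain_gate_spec()

  # CD45-bright, CD31-bright: first matching rule (immune) wins
  ev <- event_table(cbind(`APC-Cy7-A` = 100, `PE-Cy7-A` = 100,
                          `PerCP-Cy5.5-A` = 1, `eFluor450-A` = 1))
  m <- deconvolve_lineages(ev, spec, thr)
  expect_true(m$immune[1]); expect_false(m$endothelial[1])

  # below every threshold: quad-negative cancer rule
  ev2 <- event_table(cbind(`APC-Cy7-A` = 1, `PE-Cy7-A` = 1,
                           `PerCP-Cy5.5-A` = 1, `eFluor450-A` = 1))
  m2 <- deconvolve_lineages(ev2, spec, thr)
  expect_true(m2$cancer[1])

  expect_error(deconvolve_lineages(ev2, spec, thr[-1]), "no threshold")

  # planted 4-population mixture at (0.4, 0.1, 0.1, 0.4)
  noise <- demo_tumor_noise(events_per_well = 10000, dead_fraction = 0,
                            doublet_fraction = 0, intensity_jitter_sd = 0)
  pops <- demo_tumor_populations()
  ev3 <- simulate_well(pops, NULL, noise, seed = 77,
                       costains = demo_costains())
  ctrl <- simulate_well(pops, NULL, noise, seed = 78)
  thr3 <- sapply(names(thr), function(ch) fmo_threshold(ctrl, ch, 99.9))
  m3 <- deconvolve_lineages(apply_compensation(ev3, noise$spillover),
                            spec, thr3)
  planted <- c(immune = 0.4, endothelial = 0.1, fibroblast = 0.1,
               cancer = 0.4)
  for (p in names(planted)) {
    tol <- 3 * sqrt(planted[[p]] * (1 - planted[[p]]) / 10000) + 0.005
    expect_lt(abs(mean(m3[[p]]) - planted[[p]]), tol)
  }
  # masks are disjoint and cover everything with "unassigned"
  tot <- Reduce(`+`, m3)
  expect_true(all(tot == 1))
})
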