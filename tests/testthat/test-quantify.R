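test_that("XIC sums peaks within tolerance per scan", {
  run <- structure(list(ms1_scans = lapply(1:5, function(i)
    list(rt = i, mz = c(500.0, 600.0), intensity = c(i * 10, 1))),
    ms2_spectra = list(), metadata = list()), class = "annotated_run")
  tr <- xic(run, 500.0, tol_ppm = 10)
  expect_equal(tr$intensity, (1:5) * 10)
  # nothing in tolerance: all-zero trace
  tr <- xic(run, 450.0, tol_ppm = 10)
  expect_equal(tr$intensity, rep(0, 5))
  # empty window
  expect_equal(nrow(xic(run, 500.0, rt_window = c(100, 200))), 0L)
  expect_error(xic(run, 500.0, tol_ppm = 0), "positive")
})

test_that("trapezoidal area matches closed forms", {
  expect_equal(auc(data.frame(rt = c(0, 2), intensity = c(3, 3))), 6)  # rectangle
  expect_equal(auc(data.frame(rt = c(0, 1, 2), intensity = c(0, 5, 0))), 5)  # triangle
  expect_equal(auc(data.frame(rt = 1, intensity = 10)), 0)  # single point
  expect_error(auc(data.frame(rt = c(2, 1), intensity = c(1, 1))), "sorted")
})

test_that("XIC area of a synthetic Gaussian elution recovers the abundance", {
  tr <- ground_truth(list(peptide("LVATMPLFANADPNFVTAMLSK", 469L)),
                     list(list()), abundance = 5e5, charges = 2L, seed = 2L)
  gen <- generate_run(tr)
  target <- gen$truth_record$mz_z2[1]
  area <- auc(xic(gen$run, target, tol_ppm = 20))
  expect_equal(area, 5e5, tolerance = 0.005)
})

test_that("labeling efficiency follows the shared-denominator convention", {
  expect_equal(labeling_efficiency(80, 20, 0),
               c(singly_percent = 20, doubly_percent = 0))
  expect_equal(labeling_efficiency(0, 0, 50),
               c(singly_percent = 0, doubly_percent = 100))
  expect_equal(labeling_efficiency(80, 15, 5),
               c(singly_percent = 15, doubly_percent = 5))
  expect_error(labeling_efficiency(0, 0, 0), "undefined")
  expect_error(labeling_efficiency(-1, 1, 0), "non-negative")

  # bounds and scale invariance
  set.seed(9)
  for (r in 1:25) {
    a <- runif(3, 0, 100)
    e <- labeling_efficiency(a[1], a[2], a[3])
    expect_true(all(e >= 0 & e <= 100))
    expect_lte(sum(e), 100 + 1e-12)
    expect_equal(e, labeling_efficiency(7.3 * a[1], 7.3 * a[2], 7.3 * a[3]))
  }
})

test_that("competition test reproduces hand-computed ANOVA and flags only true competitors", {
  groups <- list(control = c(18, 19, 18.5),
                 propofol = c(0.5, 0.6, 0.7),
                 cAMP = c(18.2, 18.9, 18.4))
  res <- competition_test(groups, control_label = "control")

  # independent one-way ANOVA F from explicit sums of squares
  vals <- unlist(groups)
  gmean <- mean(vals)
  ssb <- sum(vapply(groups, function(g) length(g) * (mean(g) - gmean)^2, numeric(1)))
  ssw <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  f_oracle <- (ssb / 2) / (ssw / 6)
  expect_equal(res$anova_F, f_oracle, tolerance = 1e-10)

  dn <- res$dunnett
  expect_true(dn$prevented[dn$condition == "propofol"])
  expect_false(dn$prevented[dn$condition == "cAMP"])
  expect_lt(dn$p_adjusted[dn$condition == "propofol"], 0.05)
  expect_gt(dn$p_adjusted[dn$condition == "cAMP"], 0.05)

  # near-identical groups: F near zero, nothing flagged
  flat <- list(control = c(10, 10.01, 9.99), a = c(10.0, 10.02, 9.98),
               b = c(10.01, 9.99, 10.0))
  res <- competition_test(flat, "control")
  expect_lt(res$anova_F, 3)
  expect_false(any(res$dunnett$prevented))

  expect_error(competition_test(list(control = c(1, 2), x = 3), "control"),
               "replicate")
  expect_error(competition_test(list(a = c(1, 2), b = c(1, 2)), "control"),
               "not found")
})

test_that("condition scalers propagate to quantified efficiencies end to end", {
  tr <- ground_truth(list(peptide("SWFVVDFISSIPVDYIFLIVEK", 220L)),
                     list(list(list(sites = 234L, fraction = 0.159))),
                     condition_scalers = c(control = 1, propofol = 0.05,
                                           cAMP = 1.0),
                     intensity_cv = 0.02, ppm_sd = 5, seed = 6L)
  effs <- sapply(c("control", "propofol", "cAMP"), function(cond) {
    gen <- generate_run(tr, condition = cond, seed = 10L + nchar(cond))
    quantify_peptide(gen$run, tr$peptides[[1]])$singly_percent
  })
  expect_equal(unname(effs["control"]), 15.9, tolerance = 0.1)
  expect_equal(unname(effs["propofol"]), 15.9 * 0.05, tolerance = 0.1)
  expect_equal(unname(effs["cAMP"]), 15.9, tolerance = 0.1)
})
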