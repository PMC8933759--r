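# The generator is ground truth for the rest of the pipeline: these tests
# pin down its covariance construction, determinism and statistical
# behaviour at small scale.

test_that("null population matrix is invariant under the homotopic swap", {
  at <- demo_atlas(4, n_midline = 1)
  d <- cohort_design(groups = c(HC = 2), n_timepoints = 100, random_seed = 3)
  S <- build_population_covariance(d, "HC", at)
  sw <- ifelse(is.na(at$homotopic_partner), at$roi_id, at$homotopic_partner)
  expect_lt(max(abs(S[sw, sw] - S)), 1e-12)
  # homotopic entries carry the stated coupling exactly (pre group effects)
  for (i in which(at$hemisphere == "L")) {
    expect_equal(S[at$roi_id[i], at$homotopic_partner[i]],
                 d$homotopic_correlation, tolerance = 1e-6)
  }
  # valid correlation matrix
  expect_equal(diag(S), setNames(rep(1, nrow(at)), at$roi_id))
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
})

test_that("group edge effects are additive before repair", {
  at <- demo_atlas(5)
  eff <- data.frame(group = "RMTLE", roi_a = "R_r1", roi_b = "L_r2",
                    delta = -0.2)
  d <- cohort_design(groups = c(HC = 2, RMTLE = 2), n_timepoints = 200,
                     group_edge_effects = eff, random_seed = 5)
  S_hc <- build_population_covariance(d, "HC", at, repair = FALSE)
  S_rm <- build_population_covariance(d, "RMTLE", at, repair = FALSE)
  expect_equal(S_hc["R_r1", "L_r2"] - S_rm["R_r1", "L_r2"], 0.2,
               tolerance = 1e-12)
  # only that pair differs
  diff <- abs(S_hc - S_rm)
  diff["R_r1", "L_r2"] <- diff["L_r2", "R_r1"] <- 0
  expect_equal(max(diff), 0)
})

test_that("AI targeting realizes the profile on the population matrix", {
  # strong coupling keeps every entry clear of the r > 0.25 threshold, so
  # the hard-thresholded AI of the population matrix and the expected
  # sampled AI coincide and both sit on the target
  at <- default_atlas()
  d <- cohort_design(groups = c(HC = 2), n_timepoints = 1000,
                     base_correlation = 0.5, homotopic_correlation = 0.7,
                     asymmetry_profile = c(L_hippo = 50), random_seed = 2)
  S <- build_population_covariance(d, "HC", at)
  ai <- matrix_asymmetry(S, at)
  expect_true(abs(ai$AI[ai$roi_id == "L_hippo"] - 50) <= 2)
  expect_gte(min(eigen(S, symmetric = TRUE, only.values = TRUE)$values), -1e-10)
  # untargeted ROIs keep near-symmetric profiles
  expect_lt(max(abs(ai$AI[!ai$roi_id %in% c("L_hippo", "R_hippo")])), 15)
})

test_that("infeasible AI targets raise a classed error with the range", {
  # a lone homotopic pair has no left-hemisphere targets for L_A, so its
  # AI can only be 200 (or undefined): a mid-range target is unreachable
  at <- atlas2()
  d <- cohort_design(groups = c(HC = 2), n_timepoints = 100,
                     cross_correlation = 0.3,
                     asymmetry_profile = c(L_A = 50), random_seed = 4)
  err <- tryCatch(build_population_covariance(d, "HC", at), error = identity)
  expect_s3_class(err, "hemifc_error_infeasible_ai")
  expect_match(conditionMessage(err), "achievable range|undefined")
})

test_that("design validation rejects malformed inputs", {
  expect_error(cohort_design(groups = c(3, 2)), class = "hemifc_error_design")
  expect_error(cohort_design(groups = c(BAD = 3)), class = "hemifc_error_design")
  expect_error(cohort_design(n_timepoints = 2), class = "hemifc_error_design")
  expect_error(cohort_design(ar1_coefficient = 1), class = "hemifc_error_design")
  expect_error(cohort_design(asymmetry_profile = c(L_r1 = 300)),
               class = "hemifc_error_design")
  expect_error(cohort_design(asymmetry_profile = 10),
               class = "hemifc_error_design")
})

test_that("simulation is deterministic and matches the manifest contract", {
  at <- demo_atlas(3)
  d <- cohort_design(groups = c(LMTLE = 3, RMTLE = 2, HC = 4),
                     n_timepoints = 40, cross_correlation = 0.3,
                     random_seed = 9)
  ch1 <- simulate_cohort(d, at)
  ch2 <- simulate_cohort(d, at)
  expect_identical(ch1$subjects[["LMTLE_02"]]$data,
                   ch2$subjects[["LMTLE_02"]]$data)
  expect_identical(ch1$manifest, ch2$manifest)

  # byte-identical files on disk
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  write_cohort(ch1, d1); write_cohort(ch2, d2)
  for (f in list.files(d1)) {
    expect_identical(readLines(file.path(d1, f)), readLines(file.path(d2, f)))
  }

  # patient groups carry clinical covariates, HC does not
  man <- ch1$manifest
  expect_equal(nrow(man), 9)
  expect_true(all(is.na(man$onset_age[man$group == "HC"])))
  expect_true(all(!is.na(man$onset_age[man$group != "HC"])))
  expect_true(all(man$onset_age >= 0, na.rm = TRUE))
  expect_true(all(man$duration >= 0, na.rm = TRUE))

  # different seed changes the data
  ch3 <- simulate_cohort(cohort_design(groups = c(LMTLE = 3, RMTLE = 2, HC = 4),
                                       n_timepoints = 40,
                                       cross_correlation = 0.3,
                                       random_seed = 10), at)
  expect_false(identical(ch1$subjects[[1]]$data, ch3$subjects[[1]]$data))
})

test_that("a full-size cohort has the stated dimensions", {
  at <- default_atlas()
  d <- cohort_design(random_seed = 1)  # defaults: 12/11/23 subjects, T = 230
  ch <- simulate_cohort(d, at)
  expect_equal(length(ch$subjects), 46)
  expect_equal(dim(ch$subjects[[1]]$data), c(230, 105))
  expect_equal(as.vector(table(ch$manifest$group)[c("LMTLE", "RMTLE", "HC")]),
               c(12, 11, 23))
})

test_that("sample correlation converges to the population matrix", {
  at <- demo_atlas(3)
  d <- cohort_design(groups = c(HC = 1), n_timepoints = 50000,
                     ar1_coefficient = 0, cross_correlation = 0.3,
                     random_seed = 42)
  S <- build_population_covariance(d, "HC", at)
  ch <- simulate_cohort(d, at)
  r_hat <- cor(ch$subjects[[1]]$data)
  expect_lt(max(abs(r_hat - S)), 0.02)
})

test_that("AR(1) inflates variance but does not bias the sample correlation", {
  at <- demo_atlas(2)
  mk <- function(phi, seed) {
    d <- cohort_design(groups = c(HC = 60), n_timepoints = 150,
                       ar1_coefficient = phi, cross_correlation = 0.2,
                       random_seed = seed)
    ch <- simulate_cohort(d, at)
    vapply(ch$subjects, function(s) cor(s$data[, 1], s$data[, 2]), numeric(1))
  }
  r0 <- mk(0, 21); r6 <- mk(0.6, 22)
  # same mean within Monte Carlo error
  se <- sqrt(var(r0) / length(r0) + var(r6) / length(r6))
  expect_lt(abs(mean(r0) - mean(r6)), 4 * se + 0.01)
  expect_gt(var(r6), var(r0))
})

test_that("cohorts round-trip through write_cohort / read_cohort", {
  at <- demo_atlas(2)
  d <- cohort_design(groups = c(LMTLE = 2, HC = 2), n_timepoints = 30,
                     cross_correlation = 0.3, random_seed = 8)
  ch <- simulate_cohort(d, at)
  dir <- withr::local_tempdir()
  write_cohort(ch, dir)
  back <- read_cohort(dir)
  expect_equal(names(back$subjects), names(ch$subjects))
  expect_equal(back$subjects[[1]]$data, ch$subjects[[1]]$data,
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(back$manifest$group, ch$manifest$group)
  expect_equal(back$roi_order, at$roi_id)
})

test_that("expected_edge_weight matches a Monte Carlo estimate", {
  set.seed(31)
  Tn <- 60; rho <- 0.3; nrep <- 3000
  x <- matrix(rnorm(nrep * Tn), nrep, Tn)
  y <- rho * x + sqrt(1 - rho^2) * matrix(rnorm(nrep * Tn), nrep, Tn)
  r <- vapply(seq_len(nrep), function(i) cor(x[i, ], y[i, ]), numeric(1))
  emp <- mean(abs(atanh(r)) * (r > 0.25))
  expect_equal(expected_edge_weight(rho, Tn), emp, tolerance = 0.02)
})
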