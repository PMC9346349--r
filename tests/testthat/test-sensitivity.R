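test_that("local sweeps vary one parameter around the averages", {
  # a degenerate single-point sweep reproduces the plain detection result
  sw <- local_sweep("Q_N", 3.1e-4)
  expect_equal(sw$V_d_ml, detect(default_parameters(), 0.12)$V_d)

  # more biomarker per dying cell means earlier crossing
  sw <- local_sweep("Q_N", c(1.3e-4, 2.2e-4, 3.1e-4, 4.4e-4, 5.7e-4))
  expect_true(all(diff(sw$V_d_ml) < 0))
  expect_true(all(sw$status == "crossed"))

  # published scenarios step outside the ranges: warn, don't fail
  expect_warning(local_sweep("R_N", 0.013), "outside the published range")
  expect_error(local_sweep("not_a_parameter", 1), "unknown parameter")
})

test_that("detection volume responds monotonically to key parameters", {
  # larger transfer fraction ceiling: earlier detection
  sw <- kt_sweep(K_max_values = c(0.3, 0.55, 0.8), K_half_values = 225,
                 h_values = 7)
  expect_true(all(diff(sw$V_d_ml) < 0))

  # later necrosis onset: later detection (Vn0 sweeps the tied pair)
  sw <- local_sweep("Vn0", c(0.1, 0.5, 5, 20))
  expect_true(all(diff(sw$V_d_ml) > 0))
})

test_that("factorial transfer-fraction sweeps summarise the detection spread", {
  one <- kt_sweep(0.5, 225, 7)
  expect_equal(summary(one)$delta_V_d, 0)
  expect_equal(one$V_d_ml, detect(default_parameters(), 0.12)$V_d)

  sw <- kt_sweep(K_max_values = c(0.3, 0.8), K_half_values = c(100, 300),
                 h_values = c(3, 9))
  s <- summary(sw)
  expect_equal(s$n, 8)
  expect_equal(s$delta_V_d, s$max_V_d - s$min_V_d)
  expect_gte(s$delta_V_d, 0)

  # a denser grid can only widen the observed spread
  dense <- kt_sweep(K_max_values = seq(0.3, 0.8, length.out = 4),
                    K_half_values = c(100, 300), h_values = c(3, 9))
  expect_gte(summary(dense)$delta_V_d, s$delta_V_d - 1e-9)
})

test_that("growth/necrosis sweeps exclude uncontained combinations", {
  sw <- growth_necrosis_sweep(
    data.frame(V_Tmax = c(72, 158), R_T = 0.008),
    data.frame(V_Nmax = c(70, 150), R_N = 0.009, Vn0 = 0.5))
  # V_Nmax = 150 inside V_Tmax = 72 violates containment
  bad <- sw$V_Tmax == 72 & sw$V_Nmax == 150
  expect_true(all(sw$status[bad] == "excluded"))
  expect_true(all(is.na(sw$V_d_ml[bad])))
  expect_true(all(sw$status[!bad] == "crossed"))

  # faster tumour growth with fixed necrosis: detected at a larger volume
  sw <- growth_necrosis_sweep(
    data.frame(V_Tmax = 158, R_T = c(0.004, 0.008, 0.01)),
    data.frame(V_Nmax = 150, R_N = 0.009, Vn0 = 0.5))
  expect_true(all(diff(sw$V_d_ml) > 0))
})

test_that("baseline sweeps cover the patient-side parameters", {
  one <- baseline_sweep(0.012, 0.7)
  expect_equal(summary(one)$delta_V_d, 0)

  # higher healthy baseline: smaller tumour contribution needed, earlier
  sw <- baseline_sweep(c(0, 0.04, 0.08, 0.11), 0.7)
  expect_true(all(diff(sw$V_d_ml) < 0))

  expect_error(baseline_sweep(c(0.05, 0.13), 0.7, threshold = 0.12),
               "\\[0, threshold\\)")
})

test_that("merging sweeps never shrinks the detection-volume spread", {
  a <- local_sweep("Q_N", c(2e-4, 3.1e-4))
  b <- local_sweep("Q_N", c(4e-4, 5e-4))
  merged <- rbind(as.data.frame(a)["V_d_ml"], as.data.frame(b)["V_d_ml"])
  expect_gte(diff(range(merged$V_d_ml)),
             max(summary(a)$delta_V_d, summary(b)$delta_V_d))
})

test_that("cohort sampling is seeded, admissible and leaves the RNG alone", {
  a <- sample_cohort(5, seed = 42)
  b <- sample_cohort(5, seed = 42)
  expect_identical(a$draws, b$draws)
  expect_false(identical(a$draws, sample_cohort(5, seed = 43)$draws))

  co <- sample_cohort(50, seed = 1)
  for (p in co$params) expect_silent(validate_parameters(p, strict = TRUE))
  expect_true(all(co$draws$Vk0 == co$draws$Vn0))

  set.seed(99); before <- .Random.seed
  invisible(sample_cohort(3, seed = 1))
  expect_identical(.Random.seed, before)
})

test_that("cohort draws are uniform where unconstrained, shifted where constrained", {
  co <- sample_cohort(200, seed = 1)
  rng <- parameter_ranges()
  mid <- function(nm) {
    r <- rng[rng$parameter == nm, ]
    (r$low + r$high) / 2
  }
  # parameters untouched by the admissibility constraints: uniform midpoints
  for (nm in c("R_N", "h", "K_max", "gamma", "C_H", "Q_N"))
    expect_lt(abs(mean(co$draws[[nm]]) - mid(nm)) / mid(nm), 0.1)
  # rejection on K_half > Tk0 and V_Nmax < V_Tmax shifts the others:
  # slow-growing tumours and late onsets are culled, long half-times kept
  expect_gt(mean(co$draws$R_T), mid("R_T"))
  expect_lt(mean(co$draws$Vn0), mid("Vn0"))
  expect_gt(mean(co$draws$K_half), mid("K_half"))
  expect_lt(mean(co$draws$V_Nmax), mid("V_Nmax"))
})

test_that("cohort members start their serum at their own baseline", {
  co <- sample_cohort(3, seed = 11)
  for (p in co$params) {
    tr <- solve_serum(p, t_end = 30)
    expect_equal(tr$C_ng_per_ml[1], p$C_H)
    expect_true(all(tr$C_ng_per_ml >= 0))
  }
})
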