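test_that("transfer fraction is a gated Hill function of model time", {
  p <- default_parameters()
  Tk0 <- onset_time(p$Vk0, p)
  expect_equal(transfer_fraction(Tk0 - 1, p), 0)
  expect_equal(transfer_fraction(p$K_half, p), p$K_max / 2)  # half-saturation
  expect_equal(transfer_fraction(1e6, p), p$K_max, tolerance = 1e-9)

  k <- transfer_fraction(seq(0, 2000, by = 1), p)
  expect_true(all(diff(k) >= 0))
  expect_true(all(k >= p$K_min & k <= p$K_max))
  expect_error(transfer_fraction(-5, p), "non-negative")
})

test_that("production rate matches the analytic necrosis derivative", {
  p <- default_parameters()
  Tn0 <- onset_time(p$Vn0, p)
  expect_equal(production_rate(Tn0 - 1, p), 0)

  # hand evaluation at a known necrotic burden
  t_star <- 317.7
  nn <- cells_from_volume(necrotic_volume(t_star, p), p$delta_N)
  expect_equal(nn, 1.53e7, tolerance = 0.01)
  by_hand <- p$Q_N * p$R_N * log(p$V_Nmax * p$delta_N / nn) * nn
  expect_equal(production_rate(t_star, p), by_hand)

  # cross-check against Q_N * delta_N * dV_N/dt by central differences
  for (t in c(250, 400, 600)) {
    h <- 1e-3
    dvdt <- (necrotic_volume(t + h, p) - necrotic_volume(t - h, p)) / (2 * h)
    expect_equal(production_rate(t, p), p$Q_N * p$delta_N * dvdt,
                 tolerance = 1e-6)
  }

  # production stops at the necrotic plateau
  expect_equal(production_rate(1e5, p), 0, tolerance = 1e-6)
})

test_that("serum stays at the healthy steady state without tumour input", {
  tr <- solve_serum(no_necrosis_params(), t_end = 1000)
  expect_equal(tr$C_ng_per_ml, rep(0.012, nrow(tr)))
})

test_that("constant-input serum matches the closed-form linear ODE solution", {
  p <- default_parameters()
  for (case in list(c(K = 0.4, U = 500), c(K = 0.1, U = 2000))) {
    tr <- solve_serum_constant(case["K"], case["U"], p, t_end = 30, Q0 = 0)
    expected <- analytic_constant_serum(tr$time_days, case["K"], case["U"], p)
    expect_lt(max(abs(tr$C_ng_per_ml - expected)), 1e-6)
  }
})

test_that("the default serum trajectory starts at baseline and stays sane", {
  p <- default_parameters()
  tr <- solve_serum(p, t_end = 1500)
  expect_equal(tr$C_ng_per_ml[1], p$C_H)
  expect_true(all(tr$C_ng_per_ml >= 0))
  expect_true(all(tr$K_T >= p$K_min & tr$K_T <= p$K_max))
  expect_true(all(tr$U_T_ng_per_day >= 0))

  # non-decreasing from necrosis onset until production peaks: for a
  # Gompertzian core, U_T is maximal at V_N = V_Nmax/e, and the serum (with
  # its short elimination lag) cannot turn over before production does
  Tn0 <- attr(tr, "Tn0")
  rising <- tr$time_days >= Tn0 & tr$V_N_ml <= p$V_Nmax / exp(1)
  expect_true(all(diff(tr$C_ng_per_ml[rising]) >= 0))
})

test_that("fast elimination collapses the serum onto the quasi-steady limit", {
  p <- default_parameters()
  p$gamma <- 10
  tr <- solve_serum(p, t_end = 400)
  sub <- tr[tr$time_days > 250 & tr$time_days < 400, ]
  qss <- p$C_H + sub$K_T * sub$U_T_ng_per_day / (p$gamma * p$V_p)
  expect_lt(max(abs(sub$C_ng_per_ml - qss) / qss), 0.02)
})

test_that("halving solver tolerances leaves the trajectory unchanged", {
  p <- default_parameters()
  a <- solve_serum(p, t_end = 800, rtol = 1e-8, atol = 1e-8)
  b <- solve_serum(p, t_end = 800, rtol = 5e-9, atol = 5e-9)
  expect_lt(max(abs(a$C_ng_per_ml - b$C_ng_per_ml) / pmax(b$C_ng_per_ml, 1e-12)),
            1e-4)
})

test_that("the baseline is invariant to gamma when the healthy input is rederived", {
  p <- default_parameters()
  p$gamma <- 1.4  # doubled; K_H*U_H is derived from C_H so baseline is fixed
  expect_equal(healthy_baseline(p), 0.012)
  p$C_H <- 0
  expect_equal(healthy_baseline(p), 0)
})
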