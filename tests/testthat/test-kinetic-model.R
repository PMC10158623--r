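# Rate laws, carrying capacity, the ODE integrator and trajectory metrics.

test_that("xv_max: arithmetic, zero carriers, linearity", {
  carrier <- carrier_spec("toy", area_per_gram = 1000,
                          max_area_density = 1e5)
  s2 <- culture_setup(c_MC = 2, seed_density = 6000, c_Glc = 25, c_Gln = 12,
                      carrier = carrier)
  # 2 g/L * 1000 cm^2/g * 1e5 cells/cm^2 = 2e8 cells/L = 2e5 cells/mL
  expect_equal(xv_max(s2), 2e5)
  s0 <- culture_setup(c_MC = 0, seed_density = 6000, c_Glc = 25, c_Gln = 12,
                      carrier = carrier)
  expect_equal(xv_max(s0), 0)
  s4 <- culture_setup(c_MC = 4, seed_density = 6000, c_Glc = 25, c_Gln = 12,
                      carrier = carrier)
  expect_equal(xv_max(s4), 2 * xv_max(s2))
  expect_error(culture_setup(c_MC = -1, seed_density = 6000, c_Glc = 25,
                             c_Gln = 12, carrier = carrier), "c_MC")
  expect_error(carrier_spec("bad", -10, 1e5), "area_per_gram")
})

test_that("specific growth rate: Monod zero, space limit, half-saturation", {
  p <- kinetic_params()
  xvm <- 1e6
  expect_equal(specific_growth_rate(0, 0, xvm, p), 0)
  expect_equal(specific_growth_rate(1, xvm, xvm, p), 0)
  expect_equal(specific_growth_rate(p[["K_S_LS"]], 0, xvm, p),
               p[["mu_max"]] / 2)
  expect_error(specific_growth_rate(1, 0, 0, p), "degenerate")
  # stays within [0, mu_max] over a grid
  for (ls in c(0, 0.01, 0.5, 1, 100)) for (xv in c(0, 1e5, 9e5, 1e6)) {
    mu <- specific_growth_rate(ls, xv, xvm, p)
    expect_gte(mu, 0); expect_lte(mu, p[["mu_max"]])
  }
})

test_that("specific death rate: limits, half-saturation, both orientations", {
  p <- kinetic_params()
  lo <- p[["mu_d_min"]]; hi <- p[["mu_d_min"]] + p[["mu_d_max"]]
  expect_equal(specific_death_rate(0, p), lo)
  expect_equal(specific_death_rate(1e12, p), hi, tolerance = 1e-9)
  expect_equal(specific_death_rate(p[["K_d_LS"]], p),
               lo + p[["mu_d_max"]] / 2)
  # inverse orientation mirrors the limits
  expect_equal(specific_death_rate(0, p, mode = "inverse"), hi)
  expect_equal(specific_death_rate(1e12, p, mode = "inverse"), lo,
               tolerance = 1e-9)
  expect_equal(specific_death_rate(p[["K_d_LS"]], p, mode = "inverse"),
               lo + p[["mu_d_max"]] / 2)
})

test_that("attachment rate: window edges", {
  p <- kinetic_params()
  expect_equal(attachment_rate(0, p), p[["k_att_max"]])
  expect_equal(attachment_rate(p[["t_att"]] - 1e-9, p), p[["k_att_max"]])
  expect_equal(attachment_rate(p[["t_att"]], p), 0)  # right-closed at zero
  p0 <- as_kinetic_params(`[<-`(unclass(p), "t_att", 0))
  expect_equal(attachment_rate(c(0, 5, 100), p0), c(0, 0, 0))
})

test_that("uptake rates: zero substrate, growth coupling, half-saturation", {
  p <- kinetic_params()
  xvm <- 1e6
  st <- c(X_t = 1e5, X_V = 5e4, X_Sus = 0, c_Glc = 0, c_Gln = 5,
          c_LS = 1, c_Lac = 0, c_Amm = 0)
  expect_equal(uptake_rates(st, xvm, p)[["q_Glc"]], 0)
  # mu = 0 (no LS) kills the growth-coupled rates but not q_LS
  st2 <- st; st2[["c_Glc"]] <- 20; st2[["c_LS"]] <- 0
  q <- uptake_rates(st2, xvm, p)
  expect_equal(q[["q_Glc"]], 0)
  expect_equal(q[["q_Gln"]], 0)
  expect_equal(q[["q_LS"]], 0)  # Monod in LS too
  st3 <- st; st3[["c_Glc"]] <- 20; st3[["c_LS"]] <- p[["k_LS"]]
  # q_LS at its half-saturation; growth Monod uses K_S_LS, independent
  expect_equal(uptake_rates(st3, xvm, p)[["q_LS"]], p[["q_LS_max"]] / 2)
})

test_that("derivatives match a hand-arithmetic oracle to 10 digits", {
  p <- kinetic_params()
  setup <- fix_setup(c_MC = 10)
  xvm <- xv_max(setup)
  st <- c(X_t = 2e5, X_V = 1.5e5, X_Sus = 2e4, c_Glc = 20, c_Gln = 8,
          c_LS = 0.6, c_Lac = 3, c_Amm = 1)
  t <- 10  # inside the attachment window

  # oracle: plain scalar arithmetic, one line per equation
  sf <- (xvm - st[["X_V"]]) / xvm
  mu <- p[["mu_max"]] * 0.6 / (0.6 + p[["K_S_LS"]]) * sf
  mud <- p[["mu_d_min"]] + p[["mu_d_max"]] * 0.6 / (0.6 + p[["K_d_LS"]])
  qglc <- mu / p[["Y_X_Glc"]] * 20 / (20 + p[["k_Glc"]]) * sf
  qgln <- mu / p[["Y_X_Gln"]] * 8 / (8 + p[["k_Gln"]]) * sf
  qls <- p[["q_LS_max"]] * 0.6 / (0.6 + p[["k_LS"]])
  att <- p[["k_att_max"]] * sf * st[["X_Sus"]]
  oracle <- c(
    X_t = mu * st[["X_V"]] - p[["K_Lys"]] * (st[["X_t"]] - st[["X_V"]]),
    X_V = (mu - mud) * st[["X_V"]] + att,
    X_Sus = mud * st[["X_V"]] - att,
    c_Glc = -qglc * st[["X_V"]],
    c_Gln = -qgln * st[["X_V"]],
    c_LS = -qls * st[["X_V"]],
    c_Lac = p[["Y_Lac_Glc"]] * qglc * st[["X_V"]],
    c_Amm = p[["Y_Amm_Gln"]] * qgln * st[["X_V"]])

  expect_equal(derivatives(t, st, setup, p), oracle, tolerance = 1e-10)
  # the compiled right-hand side is an independent implementation
  dy <- mdoecarrier:::.rhs_cpp(t, unname(st), as.numeric(p), xvm)
  expect_equal(unname(dy), unname(oracle), tolerance = 1e-10)
  # after the window the attachment flux is gone
  d2 <- derivatives(25, st, setup, p)
  expect_equal(d2[["X_Sus"]], mud * st[["X_V"]], tolerance = 1e-10)
})

test_that("all-zero cell state with zero substrates is a fixed point", {
  p <- kinetic_params()
  setup <- fix_setup()
  st <- setNames(rep(0, 8), c("X_t", "X_V", "X_Sus", "c_Glc", "c_Gln",
                              "c_LS", "c_Lac", "c_Amm"))
  expect_equal(unname(derivatives(0, st, setup, p)), rep(0, 8))
})

test_that("simulate_batch: zero inoculum stays zero, substrates constant", {
  s <- culture_setup(c_MC = 10, seed_density = 0, c_Glc = 25, c_Gln = 12,
                     carrier = fix_carrier())
  tr <- simulate_batch(s, kinetic_params(), t_grid = seq(0, 200, by = 20))
  expect_true(all(tr$X_t == 0 & tr$X_V == 0 & tr$X_Sus == 0))
  expect_true(all(tr$c_Glc == 25 & tr$c_Gln == 12 & tr$c_LS == 1))
})

test_that("unlimited regime matches the closed-form exponential to 1e-4", {
  # no attachment (t_att = 0), LS effectively unlimited for growth and
  # constant (negligible uptake), far from the space limit
  p <- kinetic_params(mu_max = 0.03, K_S_LS = 1e-9, mu_d_min = 0.005,
                      mu_d_max = 0.005, K_d_LS = 1e-9, t_att = 0,
                      q_LS_max = 1e-30, k_att_max = 1e-30)
  y0 <- c(100, 100, 0, 25, 12, 1, 0, 0)
  tg <- seq(0, 200, by = 10)
  m <- mdoecarrier:::.simulate_cpp(y0, as.numeric(p), 1e12, tg,
                                   1e-8, 1e-10, FALSE)
  mu_net <- 0.03 * 1 / (1 + 1e-9) - (0.005 + 0.005 * 1 / (1 + 1e-9))
  expect_equal(m[, 2], 100 * exp(mu_net * tg), tolerance = 1e-4)
})

test_that("stoichiometric couplings hold along every trajectory", {
  p <- kinetic_params()
  for (s in list(fix_setup(c_MC = 10), fix_setup(c_MC = 1, c_Gln = 4))) {
    tr <- simulate_batch(s, p, t_grid = seq(0, 336, by = 12))
    expect_equal(tr$c_Lac - tr$c_Lac[1],
                 p[["Y_Lac_Glc"]] * (tr$c_Glc[1] - tr$c_Glc),
                 tolerance = 1e-6)
    expect_equal(tr$c_Amm - tr$c_Amm[1],
                 p[["Y_Amm_Gln"]] * (tr$c_Gln[1] - tr$c_Gln),
                 tolerance = 1e-6)
  }
})

test_that("trajectory invariants: monotone substrates, bounds, positivity", {
  p <- kinetic_params()
  for (s in table1_setups()) {
    tr <- simulate_batch(s, p, t_grid = seq(0, 336, by = 8))
    eps <- 1e-8 * max(abs(tr$c_Glc))
    expect_true(all(diff(tr$c_Glc) <= eps))
    expect_true(all(diff(tr$c_Gln) <= eps))
    expect_true(all(diff(tr$c_LS) <= 1e-10))
    expect_true(all(diff(tr$c_Lac) >= -eps))
    expect_true(all(diff(tr$c_Amm) >= -eps))
    expect_true(all(tr$X_V <= xv_max(s) * (1 + 1e-8)))
    expect_true(all(tr$X_t >= tr$X_V - 1e-6 * max(tr$X_t)))
    expect_true(all(as.matrix(tr[, -1]) >= -1e-9))
  }
})

test_that("attachment conserves X_V + X_Sus when growth/death/lysis are off", {
  p <- kinetic_params(mu_max = 1e-30, mu_d_min = 1e-30, mu_d_max = 1e-30,
                      K_Lys = 1e-30, k_att_max = 0.3)
  s <- fix_setup(c_MC = 5)
  tr <- simulate_batch(s, p, t_grid = seq(0, 100, by = 5))
  total <- tr$X_V + tr$X_Sus
  expect_equal(total, rep(total[1], length(total)), tolerance = 1e-8)
  # and attachment actually happened
  expect_gt(max(tr$X_V), 0.9 * total[1])
})

test_that("per-cm^2 maximum is non-increasing in carrier concentration", {
  p <- kinetic_params()
  yields <- sapply(c(1, 2, 5, 10, 20), function(cmc) {
    s <- fix_setup(c_MC = cmc)
    culture_metrics(simulate_batch(s, p, t_grid = seq(0, 336, by = 8)),
                    s)$X_max_per_cm2
  })
  expect_true(all(diff(yields) <= 0))
})

test_that("culture metrics reproduce the multiplication-factor arithmetic", {
  s <- fix_setup(c_MC = 1)
  area <- carrier_area(s)
  mk_traj <- function(x_area_max) {
    data.frame(time_h = c(0, 100, 216, 300),
               X_V = c(0, 0.4, 1, 0.8) * x_area_max * area)
  }
  m8 <- culture_metrics(mk_traj(39.8e4), s)
  expect_equal(m8$VF, 39.8e4 / 6000, tolerance = 1e-12)  # 66.33
  expect_equal(m8$t_at_max, 216)
  m7 <- culture_metrics(mk_traj(22.5e4), s)
  expect_equal(m7$VF, 37.5)
  expect_equal(m7$PD, log2(37.5))
  # X_max equal to the seed density: VF = 1, PD = 0
  m1 <- culture_metrics(mk_traj(6000), s)
  expect_equal(m1$VF, 1); expect_equal(m1$PD, 0)
  s0 <- culture_setup(c_MC = 1, seed_density = 0, c_Glc = 25, c_Gln = 4,
                      carrier = fix_carrier())
  expect_error(culture_metrics(mk_traj(1e4), s0), "seed_density")
})

test_that("simulate_batch rejects bad grids and reports failures with setup", {
  s <- fix_setup()
  p <- kinetic_params()
  expect_error(simulate_batch(s, p, t_grid = c(1, 2, 3)), "start at 0")
  expect_error(simulate_batch(s, p, t_grid = c(0, 10, 10)), "increasing")
})
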