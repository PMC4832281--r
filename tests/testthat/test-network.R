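test_that("rhs conserves CaM and CAMTA algebraically for arbitrary states", {
  m <- default_model()
  set.seed(11)
  for (i in 1:10) {
    s <- runif(19, 0, 5)
    d <- binding_rhs(s, ca = runif(1, 0, 5), m)
    scale <- max(abs(d))  # fluxes reach O(10^3) uM/s; zero up to roundoff
    expect_lt(abs(sum(d[1:18])), 1e-12 * scale)           # CaM species
    expect_lt(abs(sum(d[c(10:18, 19)])), 1e-12 * scale)   # CAMTA-containing
  }
})

test_that("rhs reproduces a single hand-computed flux", {
  m <- default_model()
  s <- setNames(numeric(19), m$species$name)
  s["M00"] <- 1; s["X"] <- 1
  d <- binding_rhs(s, ca = 1, m)
  # only outgoing fluxes from apo-CaM: first N (kon 100), first C (kon 4),
  # CAMTA association (kon 1/Q = 1); everything else is empty
  expect_equal(d[["M10"]], 100 * 1 * 1)
  expect_equal(d[["M01"]], 4)
  expect_equal(d[["M00X"]], 1)
  expect_equal(d[["M00"]], -(100 + 4 + 1))
})

test_that("rhs vanishes at the relaxed steady state", {
  m <- default_model()
  ss <- control_state()
  d <- binding_rhs(as.numeric(ss), ca = m$control_ca, m)
  expect_lt(max(abs(d)), 1e-9 * max(ss))
})

test_that("ODE steady state matches the partition-function oracle", {
  m <- default_model()
  expect_rel_equal(as.numeric(control_state()),
                   as.numeric(equilibrium_oracle(m)), 1e-6)
})

test_that("oracle equivalence holds across random parameters and calcium", {
  set.seed(42)
  for (i in 1:8) {
    b <- base_parameters(p = runif(1, 0.05, 1),
                         kon_camta = 10^runif(1, -1, 1),
                         q = 10^runif(1, -0.5, 0.5),
                         cam_total = runif(1, 1, 30),
                         camta_total = runif(1, 1, 30))
    m <- cam_model(base = b)
    ca <- 10^runif(1, -2, 0.7)
    expect_rel_equal(as.numeric(steady_state(m, ca)),
                     as.numeric(equilibrium_oracle(m, ca)), 1e-6)
  }
})

test_that("zero-calcium equilibrium reduces to the single-site partition", {
  m <- default_model()
  for (route in list(steady_state(m, 0), equilibrium_oracle(m, 0))) {
    y <- as.numeric(route)
    expect_rel_equal(y[1] + y[10] + y[19],
                     m$base$cam_total + m$base$camta_total - y[10], 1e-6)
    expect_lt(max(y[-c(1, 10, 19)]), 1e-12)  # no Ca-loaded species
    # apo partition solves the binding quadratic at Kd(R15)
    kd15 <- m$base$kd_camta / m$base$p
    expect_rel_equal(y[1] * y[19] / y[10], kd15, 1e-6)
  }
})

test_that("vanishing CaM leaves all CAMTA free", {
  m <- cam_model(cam_total = 1e-10, camta_total = 10)
  y <- equilibrium_oracle(m, 0.5)
  expect_lt(sum(y[1:18]), 1e-9)
  expect_rel_equal(y[["X"]], 10, 1e-6)
})

test_that("active complex increases monotonically with clamped calcium", {
  m <- default_model()
  ca <- c(0.05, 0.1, 0.2, 0.4, 0.8, 1.6, 3.2, 6.4, 10)
  m22 <- vapply(ca, function(x) equilibrium_oracle(m, x)[["M22X"]],
                numeric(1))
  expect_true(all(diff(m22) > 0))
  # cross-check one interior point against the dynamic route
  expect_rel_equal(steady_state(m, 0.4)[["M22X"]], m22[4], 1e-6)
})

test_that("unsaturated four-site ladder approaches the f^4 power law", {
  m <- default_model()
  for (ca0 in c(0.005, 0.02)) {
    f <- 2
    fold <- equilibrium_oracle(m, ca0 * f)[["M22X"]] /
      equilibrium_oracle(m, ca0)[["M22X"]]
    expect_lt(abs(fold - f^4) / f^4, 0.25)
  }
})

test_that("constant control input leaves the trajectory flat", {
  m <- default_model()
  tr <- ca_trace(c(0, 500), rep(m$control_ca, 2))
  traj <- simulate_binding(tr, m, out_dt = 1, init = control_state())
  expect_rel_equal(as.numeric(traj[nrow(traj), -1]),
                   as.numeric(control_state()), 1e-5)
  expect_true(check_conservation(traj))
})

test_that("a held calcium step relaxes onto the new equilibrium", {
  m <- default_model()
  tr <- ca_trace(c(0, 2e4), c(0.52, 0.52))
  traj <- simulate_binding(tr, m, out_dt = 50, init = control_state())
  target <- equilibrium_oracle(m, 0.52)[["M22X"]]
  expect_rel_equal(traj$M22X[nrow(traj)], target, 1e-3)
  expect_true(check_conservation(traj))
})

test_that("a periodic input drives a periodic active-complex response", {
  m <- default_model()
  tr <- reference_piecewise(period = 40, duration = 400)
  traj <- simulate_binding(tr, m, out_dt = 0.05, init = control_state())
  expect_true(check_conservation(traj))
  # per-cycle maxima settle onto a repeating value after the first cycles
  peaks <- vapply(5:9, function(k) {
    win <- traj$time_s >= k * 40 & traj$time_s < (k + 1) * 40
    max(traj$M22X[win])
  }, numeric(1))
  expect_rel_equal(peaks[-1], rep(peaks[1], 4), 1e-3)
})

test_that("steady-state failures and bad inputs surface as errors", {
  m <- default_model()
  expect_error(steady_state(m, -1))
  expect_error(simulate_binding(ca_trace(c(0, 10), c(0.1, 0.1)), m,
                                t_end = -5), "exceed")
})
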