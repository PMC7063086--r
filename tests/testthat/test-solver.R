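test_that("discretization respects the segment-length caps", {
  m <- passive_cable_morph(axon_length = 1000)
  mod <- discretize(m, passive_preset(),
                    max_seg = list(soma = 10, dendrite = 10, hillock = 10,
                                   ais = 10, internode = 10, node = 1.5,
                                   collateral = 10))
  expect_true(all(mod$comp_len <= 10 + 1e-9))
  # a 100 um section capped at 10 um becomes exactly 10 compartments
  i100 <- which(m$sections$role == "main_axon_internode" &
                  abs(m$sections$length - 100) < 5)[1]
  expect_equal(sum(mod$comp_sec == i100), ceiling(m$sections$length[i100] / 10))
  m_bad <- m
  m_bad$sections$length[2] <- 0
  expect_error(discretize(m_bad, passive_preset()), "zero- or negative-length")
})

test_that("passive single compartment follows the RC closed form", {
  # an electrotonically compact passive blob behaves as one RC compartment
  m <- passive_cable_morph(axon_length = 10, diam = 10)
  mod <- discretize(m, passive_preset(),
                    max_seg = list(soma = 10, dendrite = 10, hillock = 10,
                                   ais = 10, internode = 10, node = 1.5,
                                   collateral = 10))
  r <- rest_state(mod)
  # lumped RC: tau = Rm * Cm = 30.03 kOhm cm^2 * 1 uF/cm^2 = 30.03 ms
  tau <- (1 / 0.333) * 1e4 * 1e-3 # ms
  rin <- 1 / sum(mod$G[, "leak"]) # MOhm (uS^-1)
  amp <- 0.01
  out <- run_sim(mod, r, dt = 0.01, t_ms = tau,
                 inj = data.frame(comp = mod$soma_comp, amp = amp),
                 record = mod$soma_comp)
  dv_end <- out$V[1, ncol(out$V)] - r$V[mod$soma_comp]
  # after exactly one time constant the step response is (1 - 1/e) of final
  expect_equal(dv_end, amp * rin * (1 - exp(-1)), tolerance = 1e-3)
})

test_that("steady profile on a long passive cylinder matches cable theory", {
  m <- passive_cable_morph(axon_length = 20000)
  mod <- discretize(m, passive_preset(),
                    max_seg = list(soma = 1, dendrite = 1, hillock = 1,
                                   ais = 1, internode = 20, node = 1.5,
                                   collateral = 8))
  r <- rest_state(mod)
  st <- steady_state(mod, data.frame(comp = mod$soma_comp, amp = 0.1), v0 = r$V)
  dv <- st$V - r$V
  x <- mod$comp_path
  sel <- !is.na(x) & x > 2000 & x < 10000
  lam_fit <- -1 / stats::coef(stats::lm(log(dv[sel]) ~ x[sel]))[[2]]
  # lambda = sqrt(Rm d / 4 Ri), Rm = 1/0.333 pS/um^2 = 30.03 kOhm cm^2
  lam_theory <- sqrt((1e4 / 0.333) * 1.14e-4 / (4 * 150)) * 1e4
  expect_equal(lam_fit, lam_theory, tolerance = 0.005)
  # flat profile with no injection
  expect_true(all(abs(rest_state(mod)$V + 70) < 1e-6))
})

test_that("two discretizations agree on input resistance and profile", {
  m <- passive_cable_morph(axon_length = 5000)
  mk <- function(h) discretize(m, passive_preset(),
    max_seg = list(soma = 1, dendrite = 1, hillock = 1, ais = 1,
                   internode = h, node = 1.5, collateral = 8))
  rin <- function(mod) {
    r <- rest_state(mod)
    st <- steady_state(mod, data.frame(comp = mod$soma_comp, amp = 0.05), v0 = r$V)
    (st$V[mod$soma_comp] - r$V[mod$soma_comp]) / 0.05
  }
  expect_equal(rin(mk(20)), rin(mk(10)), tolerance = 1e-3)
})

test_that("active model is self-convergent in mesh and time step", {
  mod <- small_active_model()
  r <- small_rest(mod)
  # dt halving changes the AP peak by < 0.5 percent
  pk <- function(dt) {
    s1 <- run_sim(mod, r, dt, 3,
                  inj = data.frame(comp = mod$soma_comp, amp = 3),
                  record = mod$node_comp[1])
    s2 <- run_sim(mod, s1$state, dt, 9, record = mod$node_comp[1])
    max(c(s1$V[1, ], s2$V[1, ]))
  }
  p1 <- pk(6.25e-3)
  p2 <- pk(3.125e-3)
  expect_lt(abs(p1 - p2) / abs(p1), 0.005)
  # halving max segment length moves the steady somatic potential < 0.1 mV
  cfg <- morph_config(axon_length = 4000, collateral_distances = c(128.5, 300.9),
                      collateral_lengths = 500, dend_diam = 9.37)
  m <- build_default_morphology(cfg, 100)
  modf <- discretize(m, load_preset("NonMyelinated"),
                     max_seg = list(soma = 17, dendrite = 50, hillock = 2.5,
                                    ais = 2.5, internode = 12.5, node = 0.75,
                                    collateral = 4))
  dvs <- function(mm) {
    rr <- rest_state(mm)
    st <- steady_state(mm, data.frame(comp = mm$soma_comp, amp = 0.322), v0 = rr$V)
    st$V[mm$soma_comp] - rr$V[mm$soma_comp]
  }
  expect_lt(abs(dvs(mod) - dvs(modf)), 0.1)
})

test_that("steady-state fast path matches the time-domain solution", {
  mod <- small_active_model()
  r <- small_rest(mod)
  st <- steady_state(mod, data.frame(comp = mod$soma_comp, amp = 0.1), v0 = r$V)
  # Kv1 slow inactivation has tau 1.5 s: compare against a long relaxation
  out <- run_sim(mod, r, dt = 0.5, t_ms = 12000,
                 inj = data.frame(comp = mod$soma_comp, amp = 0.1))
  expect_lt(max(abs(out$state$V - st$V)), 0.2)
  # at steady state the membrane-current residual (charge balance) vanishes
  # relative to the injected current
  parts <- adfsim:::.steady_matrix_parts(mod)
  ch <- adfsim:::.steady_channel_terms(mod, st$V)
  n <- mod$n
  f <- as.numeric(parts$A0 %*% c(st$V, st$W[mod$is_sheath == 1])) +
    c(ch$gtot * st$V - ch$ge, numeric(parts$nw))
  f[mod$soma_comp] <- f[mod$soma_comp] - 0.1
  expect_lt(max(abs(f)) / 0.1, 0.001)
})

test_that("steady-state solver refuses suprathreshold injections", {
  mod <- small_active_model()
  r <- small_rest(mod)
  expect_error(
    steady_state(mod, data.frame(comp = mod$soma_comp, amp = 3), v0 = r$V),
    "run_sim"
  )
})

test_that("double-cable internode saturates with wrap count and respects stability", {
  cfg <- morph_config(axon_length = 3000, collateral_distances = c(500, 1000),
                      collateral_lengths = 200, dend_diam = 9.37)
  m <- build_default_morphology(cfg, 100)
  att <- function(wraps) {
    p <- load_preset("Myelin1")
    p$wraps <- wraps
    p$sheath <- myelin_sheath(n = wraps)
    mod <- discretize(m, p)
    r <- rest_state(mod)
    st <- steady_state(mod, data.frame(comp = mod$soma_comp, amp = 0.1), v0 = r$V)
    dv <- st$V - r$V
    dv[mod$node_comp[length(mod$node_comp)]] / dv[mod$soma_comp]
  }
  a <- vapply(c(2, 15, 1e4, 1e5), att, 0)
  expect_true(all(diff(a) > 0)) # less sheath leak -> less attenuation
  # with an (effectively) lossless sheath the attenuation saturates at the
  # purely axial-loss limit: doubling n by 10x changes nothing
  expect_lt(abs(a[4] - a[3]) / a[3], 1e-3)
  # the explicit periaxonal axial term bounds the usable time step
  p15 <- load_preset("Myelin1")
  mod <- discretize(m, p15)
  r <- rest_state(mod)
  expect_error(run_sim(mod, r, dt = 0.5, t_ms = 1), "stability bound")
})

test_that("passive steady profile is direction-symmetric on a uniform cable", {
  m <- passive_cable_morph(axon_length = 6000)
  mod <- discretize(m, passive_preset(),
                    max_seg = list(soma = 1, dendrite = 1, hillock = 1,
                                   ais = 1, internode = 20, node = 1.5,
                                   collateral = 8))
  r <- rest_state(mod)
  on_ax <- which(!is.na(mod$comp_path))
  far <- on_ax[which.max(mod$comp_path[on_ax])]
  near <- on_ax[which.min(mod$comp_path[on_ax])]
  a <- steady_state(mod, data.frame(comp = near, amp = 0.05), v0 = r$V)
  b <- steady_state(mod, data.frame(comp = far, amp = 0.05), v0 = r$V)
  expect_equal(a$V[far] - r$V[far], b$V[near] - r$V[near], tolerance = 0.02)
})

test_that("conduction velocity is distance over peak-time difference", {
  t <- seq(0, 10, by = 0.01)
  v1 <- -70 + 100 * exp(-((t - 3) / 0.3)^2)
  v2 <- -70 + 100 * exp(-((t - 5) / 0.3)^2)
  expect_equal(conduction_velocity(t, v1, v2, 1000), 0.5) # 1 mm / 2 ms
  expect_error(conduction_velocity(t, v1, v1, 1000), "identical")
  expect_error(conduction_velocity(t, rep(-70, length(t)), v2, 1000), "no spike")
})
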