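test_that("region classification applies the oxygen thresholds", {
  # all well-oxygenated: everything in the mask proliferates
  sigma <- matrix(0.9, 5, 5)
  mask <- matrix(TRUE, 5, 5)
  q_ol <- matrix(0.5, 5, 5)
  reg <- classify_regions(sigma, mask, q_ol, 0.3)
  expect_true(all(reg == REGION_PROLIF))

  # oxygen ramp over 11 in-mask nodes: 0.0,0.1,...,1.0 against thresholds
  # 0.3 (necrotic) and 0.5 (quiescence): 3 necrotic, 2 hypoxic, 6 proliferating
  sigma <- matrix(seq(0, 1, by = 0.1), 1, 11)
  mask <- matrix(TRUE, 1, 11)
  q_ol <- matrix(0.5, 1, 11)
  reg <- classify_regions(sigma, mask, q_ol, 0.3)
  expect_equal(sum(reg == REGION_NECROTIC), 3)
  expect_equal(sum(reg == REGION_HYPOXIC), 2)
  expect_equal(sum(reg == REGION_PROLIF), 6)
  expect_true(all(reg[!mask] == REGION_NORMAL))
})

test_that("necrosis is irreversible even if oxygen recovers", {
  mask <- matrix(TRUE, 3, 3)
  q_ol <- matrix(0.5, 3, 3)
  low <- matrix(0.1, 3, 3)
  reg1 <- classify_regions(low, mask, q_ol, 0.3)
  expect_true(all(reg1 == REGION_NECROTIC))
  high <- matrix(0.95, 3, 3)
  reg2 <- classify_regions(high, mask, q_ol, 0.3, previous_region = reg1)
  expect_true(all(reg2 == REGION_NECROTIC))
  # whereas hypoxic tissue may recover to proliferating
  mid <- matrix(0.4, 3, 3)
  regh <- classify_regions(mid, mask, q_ol, 0.3)
  expect_true(all(regh == REGION_HYPOXIC))
  regr <- classify_regions(high, mask, q_ol, 0.3, previous_region = regh)
  expect_true(all(regr == REGION_PROLIF))
})

test_that("the proliferation law evaluates exactly per region", {
  region <- matrix(c(REGION_NORMAL, REGION_PROLIF, REGION_HYPOXIC,
                     REGION_NECROTIC), 2, 2)
  sigma <- matrix(c(0.5, 1, 0.4, 0.2), 2, 2)
  m1 <- matrix(c(0, 0, 0.66, 0), 2, 2)
  m2 <- matrix(c(0, 0, 0.2, 0), 2, 2)
  tp <- list(lambda_M = 1, lambda_A = 0.05, G_N = 0.3)

  lp <- proliferation_field(region, sigma, m1, m2, tp)
  expect_equal(lp[1, 1], 0)                      # normal tissue
  expect_equal(lp[2, 1], (1 + 0) * 1 - 0.05)     # proliferating, sigma = 1
  expect_equal(lp[1, 2], 0.2 * 0.4 - 0.71)       # hypoxic hand value -0.63
  expect_equal(lp[1, 2], -0.63)
  expect_equal(lp[2, 2], -0.3)                   # necrotic: -G_N

  # identity case: lambda_M = 1, sigma = 1, no other effects
  lp2 <- proliferation_field(matrix(REGION_PROLIF, 1, 1), matrix(1, 1, 1),
                             matrix(0, 1, 1), matrix(0, 1, 1),
                             list(lambda_M = 1, lambda_A = 0, G_N = 0))
  expect_equal(lp2[1, 1], 1)
})

test_that("the M2 proliferation boost follows its logistic law", {
  # F = 0: unchanged
  l0 <- matrix(0.1, 2, 2)
  expect_equal(update_m2_rate(l0, matrix(0, 2, 2), 1, 0.5, 0.1), l0)

  # at the ceiling lambda_M + lambda_M2 = 1: unchanged
  lc <- matrix(0.5, 2, 2)
  expect_equal(update_m2_rate(lc, matrix(1, 2, 2), 1, 0.5, 0.1), lc)

  # hand Euler step: lambda_F=1, F=0.5, lambda_M=0.5, lambda_M2=0, dt=0.1
  out <- update_m2_rate(matrix(0, 1, 1), matrix(0.5, 1, 1), 1, 0.5, 0.1)
  expect_equal(out[1, 1], 0.025)

  # clamping: never exceeds 1 - lambda_M for any F sequence
  set.seed(4)
  lam <- matrix(0, 3, 3)
  for (i in 1:200) {
    lam <- update_m2_rate(lam, matrix(runif(9), 3, 3), 2, 0.6, 0.2)
    expect_true(all(lam >= 0 & lam <= 0.4 + 1e-12))
  }
})

test_that("the quiescence threshold relaxes, lowers, and clamps", {
  tp <- list(lambda_OL = 1, lambda_OT = 1, Q_OL_bar = 0.5, Q_OL_min = 0.2)

  # F = 0 at the standard level: fixed point
  q <- matrix(0.5, 2, 2)
  expect_equal(update_quiescence(q, matrix(0, 2, 2), tp, 0.01), q)

  # single hand Euler step: F=1 from Q=0.5 with Q_min=0.2, dt=0.01
  out <- update_quiescence(matrix(0.5, 1, 1), matrix(1, 1, 1), tp, 0.01)
  expect_equal(out[1, 1], 0.497)

  # long-time limit under constant F equals the closed-form fixed point
  for (Fv in c(0.2, 0.5, 0.8)) {
    q <- matrix(0.5, 1, 1)
    for (i in 1:3000) q <- update_quiescence(q, matrix(Fv, 1, 1), tp, 0.01)
    fixed <- (tp$lambda_OL * (1 - Fv) * tp$Q_OL_bar +
                tp$lambda_OT * Fv * tp$Q_OL_min) /
      (tp$lambda_OL * (1 - Fv) + tp$lambda_OT * Fv)
    expect_equal(q[1, 1], fixed, tolerance = 1e-6)
  }

  # clamped into [Q_OL_min, Q_OL_bar] for arbitrary F sequences
  set.seed(8)
  q <- matrix(0.35, 2, 2)
  for (i in 1:200) {
    q <- update_quiescence(q, matrix(runif(4), 2, 2), tp, 0.5)
    expect_true(all(q >= 0.2 & q <= 0.5))
  }
})

test_that("ECM dynamics follow the production/degradation balance", {
  params <- list(lambda_production = 1, lambda_sprout_production = 0.5,
                 lambda_degradation = 2, k_p = 1, k_d = 1)
  zero <- matrix(0, 3, 3)

  # nothing viable, no MDE: unchanged
  E <- matrix(0.4, 3, 3)
  expect_equal(step_ecm(E, zero, zero, zero, params, 0.1), E)

  # hand Euler: E0=0, k_p=1, lambda_prod=1, dt=0.1 -> 0.1 at the viable node
  viable <- zero
  viable[2, 2] <- 1
  out <- step_ecm(matrix(0, 3, 3), zero, viable, zero, params, 0.1)
  expect_equal(out[2, 2], 0.1)
  expect_equal(sum(out), 0.1)

  # iterated map converges to the steady state found by bisection
  m_star <- 0.6
  E <- matrix(0.05, 1, 1)
  M <- matrix(m_star, 1, 1)
  v1 <- matrix(1, 1, 1)
  for (i in 1:40000) E <- step_ecm(E, M, v1, matrix(0, 1, 1), params, 0.05)
  oracle <- ecm_steady_bisect(1, 2, m_star, 1, 1)
  expect_equal(E[1, 1], oracle, tolerance = 1e-6)
  expect_true(all(E >= 0))
})

test_that("the tumor interface advances, regresses and stays put correctly", {
  n <- 21
  h <- 0.1
  region <- matrix(REGION_NORMAL, n, n)
  region[9:13, 9:13] <- REGION_PROLIF
  zero_vel <- list(vx = matrix(0, n, n - 1), vy = matrix(0, n - 1, n))
  debt <- matrix(0, n, n)

  # no velocity, no proliferation: unchanged
  set.seed(2)
  adv <- advance_tumor(region, zero_vel, matrix(0, n, n), debt, h, 0.1)
  expect_identical(adv$region, region)

  # uniform positive proliferation: area strictly increases over 10 steps
  cfgm <- list(mu = 1, chi_E = 0)
  reg <- region
  set.seed(3)
  for (i in 1:10) {
    lp <- matrix(0, n, n)
    lp[reg != REGION_NORMAL] <- 0.8
    vel <- solve_pressure_velocity(lp, matrix(0.4, n, n), cfgm, h)
    adv <- advance_tumor(reg, vel, lp, debt, h, 0.5)
    reg <- adv$region
    debt <- adv$debt
  }
  expect_gt(sum(reg != REGION_NORMAL), 25)

  # strongly negative proliferation everywhere: area non-increasing
  reg2 <- region
  debt2 <- matrix(0, n, n)
  set.seed(4)
  for (i in 1:10) {
    lp <- matrix(0, n, n)
    lp[reg2 != REGION_NORMAL] <- -1.5
    vel <- solve_pressure_velocity(lp, matrix(0.4, n, n), cfgm, h)
    adv <- advance_tumor(reg2, vel, lp, debt2, h, 0.5)
    expect_lte(sum(adv$region != REGION_NORMAL), sum(reg2 != REGION_NORMAL))
    reg2 <- adv$region
    debt2 <- adv$debt
  }
  expect_lt(sum(reg2 != REGION_NORMAL), 25)
})

test_that("necrotic area never decreases during a short simulation", {
  cfg <- tiny_config(n = 41, t_end = 3, tumor_type = "primary")
  cfg$tumor$necrotic_threshold <- 0.4  # provoke early necrosis
  cfg$tumor$Q_OL_min <- 0.42
  cfg$tumor$Q_OL_bar <- 0.6
  set.seed(cfg$rng_seed)
  st <- build_state(cfg)
  prev <- sum(st$region == REGION_NECROTIC)
  for (i in 1:30) {
    st <- step_simulation(st)
    cur <- sum(st$region == REGION_NECROTIC)
    expect_gte(cur, prev)
    prev <- cur
  }
  expect_gt(prev, 0)
})
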