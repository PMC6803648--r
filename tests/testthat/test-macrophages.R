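test_that("extravasation is gradient-driven with binomial statistics", {
  n <- 21
  h <- 0.1
  params <- macro_params(extravasation_rate = 2)
  net <- build_vessel_grid(n, 5)

  # uniform chemoattractant: zero gradient, no spawns
  set.seed(1)
  out <- extravasate(net, matrix(0.5, n, n), params, h, dt = 1)
  expect_equal(nrow(out), 0)

  # no vessels: no agents
  empty <- net
  empty$pre[] <- FALSE
  grad_field <- outer(rep(1, n), seq(0, 1, length.out = n))
  expect_equal(nrow(extravasate(empty, grad_field, params, h, dt = 1)), 0)

  # doubling the gradient doubles the expected spawn count (below cap):
  # compare Monte-Carlo means against the binomial expectation
  shallow <- outer(rep(1, n), seq(0, 0.2, length.out = n))
  steep <- 2 * shallow
  n_trials <- 1000
  set.seed(7)
  c1 <- replicate(n_trials, nrow(extravasate(net, shallow, params, h, 0.05)))
  c2 <- replicate(n_trials, nrow(extravasate(net, steep, params, h, 0.05)))
  expect_equal(mean(c2) / mean(c1), 2, tolerance = 0.05)

  # spawned agents are naive and placed on vessel nodes
  set.seed(2)
  ag <- extravasate(net, steep, params, h, dt = 1, next_id = 10L)
  expect_true(all(ag$phenotype == "naive"))
  expect_true(all(vessel_indicator(net)[cbind(ag$y, ag$x)] == 1))
  expect_equal(ag$id[1], 10L)
})

test_that("migration is unbiased on flat fields and respects bounds", {
  n <- 61
  flat <- matrix(0.5, n, n)
  params <- macro_params(motility = 1)
  agents <- data.frame(id = 1L, x = 31L, y = 31L, phenotype = "naive",
                       age = 0, stringsAsFactors = FALSE)
  set.seed(13)
  dx <- numeric(2500)
  dy <- numeric(2500)
  for (i in seq_along(dx)) {
    moved <- migrate(agents, flat, flat, flat, matrix(0, n, n), params, dt = 4)
    dx[i] <- moved$x - 31
    dy[i] <- moved$y - 31
  }
  # each trial is a 4-step random walk; mean displacement within 3 SE of 0
  se <- sd(dx) / sqrt(length(dx))
  expect_lt(abs(mean(dx)), 3 * se)
  se_y <- sd(dy) / sqrt(length(dy))
  expect_lt(abs(mean(dy)), 3 * se_y)
})

test_that("M1 agents drift toward the lesion center through the bias field", {
  n <- 41
  region <- matrix(REGION_NORMAL, n, n)
  ii <- row(region); jj <- col(region)
  region[(ii - 21)^2 + (jj - 21)^2 <= 12^2] <- REGION_HYPOXIC
  bias <- center_bias_field(region)
  expect_equal(bias[21, 21], max(bias))
  expect_true(all(bias[region == REGION_NORMAL] == 0))

  flat <- matrix(0.5, n, n)
  params <- macro_params(motility = 2, m1_center_bias_weight = 5)
  set.seed(17)
  toward <- 0
  for (i in 1:1000) {
    ag <- data.frame(id = 1L, x = 29L, y = 21L, phenotype = "M1",
                     age = 0, stringsAsFactors = FALSE)
    for (s in 1:5) ag <- migrate(ag, flat, flat, flat, bias, params, dt = 1)
    if (ag$x < 29) toward <- toward + 1
  }
  expect_gt(toward / 1000, 0.6)  # mean displacement points to the centroid
})

test_that("agents never leave the lattice", {
  n <- 16
  flat <- matrix(0, n, n)
  params <- macro_params(motility = 50)
  agents <- data.frame(id = 1:4, x = c(1L, n, 1L, n), y = c(1L, 1L, n, n),
                       phenotype = "naive", age = 0, stringsAsFactors = FALSE)
  set.seed(3)
  for (i in 1:20) {
    agents <- migrate(agents, flat, flat, flat, flat, params, dt = 1)
    expect_true(all(agents$x >= 1 & agents$x <= n &
                      agents$y >= 1 & agents$y <= n))
  }
})

test_that("polarization follows thresholds, tie-breaks and terminality", {
  params <- macro_params(tnf_threshold = 0.2, tgf_threshold = 0.1,
                         polarization_prob = 10)
  set.seed(5)
  # neither cytokine present: stays naive
  expect_equal(polarize_one("naive", 0, 0, params, 1), "naive")
  # only TNF above threshold: M1
  expect_equal(polarize_one("naive", 0.5, 0.05, params, 1), "M1")
  # only TGF above threshold: M2
  expect_equal(polarize_one("naive", 0.1, 0.5, params, 1), "M2")
  # both at twice their thresholds: equal normalized excess, tie goes to M1
  expect_equal(polarize_one("naive", 0.4, 0.2, params, 1), "M1")
  # larger TGF excess wins
  expect_equal(polarize_one("naive", 0.21, 0.9, params, 1), "M2")
  # polarization is terminal: contract violation on non-naive agents
  expect_error(polarize_one("M1", 0.5, 0.5, params, 1), "non-naive")

  # vectorized form: only agents inside the microenvironment polarize
  n <- 9
  microenv <- matrix(FALSE, n, n)
  microenv[1:4, ] <- TRUE
  agents <- data.frame(id = 1:2, x = c(2L, 8L), y = c(2L, 8L),
                       phenotype = "naive", age = 0, stringsAsFactors = FALSE)
  high <- matrix(0.9, n, n)
  low <- matrix(0, n, n)
  out <- polarize(agents, high, low, microenv, params, dt = 1)
  expect_equal(out$phenotype, c("M1", "naive"))
})

test_that("no agent ever de-polarizes or switches phenotype in a run", {
  cfg <- tiny_config(n = 41, t_end = 4)
  cfg$macrophage$extravasation_rate <- 5
  set.seed(cfg$rng_seed)
  st <- build_state(cfg)
  seen <- character(0)
  for (i in 1:40) {
    st <- step_simulation(st)
    ph <- setNames(st$agents$phenotype, st$agents$id)
    common <- intersect(names(seen), names(ph))
    was_polarized <- common[seen[common] != "naive"]
    expect_true(all(ph[was_polarized] == seen[was_polarized]))
    seen <- ph
  }
  expect_gt(length(seen), 0)
})

test_that("the M1 effector field is local and additive", {
  params <- macro_params(lambda_NO = 0.66, m1_neighborhood = 0)
  none <- data.frame(id = integer(0), x = integer(0), y = integer(0),
                     phenotype = character(0), age = numeric(0))
  expect_true(all(m1_effect_field(none, 9, params) == 0))

  one <- data.frame(id = 1L, x = 4L, y = 6L, phenotype = "M1", age = 0,
                    stringsAsFactors = FALSE)
  f <- m1_effect_field(one, 9, params)
  expect_equal(f[6, 4], 0.66)
  expect_equal(sum(f), 0.66)

  # radius 1 covers the Chebyshev 3x3 box
  params1 <- macro_params(lambda_NO = 0.5, m1_neighborhood = 1)
  f1 <- m1_effect_field(one, 9, params1)
  expect_true(all(f1[5:7, 3:5] == 0.5))
  expect_equal(sum(f1), 0.5 * 9)

  # two agents on one node add their contributions
  two <- rbind(one, one)
  f2 <- m1_effect_field(two, 9, params)
  expect_equal(f2[6, 4], 2 * 0.66)

  # naive and M2 agents contribute nothing
  mixed <- data.frame(id = 1:2, x = c(2L, 3L), y = c(2L, 3L),
                      phenotype = c("naive", "M2"), age = 0,
                      stringsAsFactors = FALSE)
  expect_true(all(m1_effect_field(mixed, 9, params) == 0))
})

test_that("population fractions partition the agent set", {
  agents <- data.frame(
    id = 1:4, x = 1L, y = 1L,
    phenotype = c("naive", "M1", "M1", "M2"), age = 0,
    stringsAsFactors = FALSE)
  fr <- population_fractions(agents)
  expect_equal(unname(fr), c(0.25, 0.5, 0.25), ignore_attr = TRUE)
  expect_false(attr(fr, "empty"))
  expect_equal(sum(fr), 1)

  all_naive <- agents
  all_naive$phenotype <- "naive"
  expect_equal(unname(population_fractions(all_naive)), c(1, 0, 0),
               ignore_attr = TRUE)

  none <- agents[0, ]
  fr0 <- population_fractions(none)
  expect_true(attr(fr0, "empty"))
  expect_equal(unname(fr0), c(0, 0, 0), ignore_attr = TRUE)
})

test_that("polarization disabled keeps every agent naive", {
  cfg <- tiny_config(n = 41, t_end = 4, polarization_enabled = FALSE)
  cfg$macrophage$extravasation_rate <- 5
  r <- run_simulation(cfg)
  expect_gt(r$series$n_agents[nrow(r$series)], 0)
  expect_equal(r$series$f_naive[nrow(r$series)], 1)
  expect_true(all(r$final$agents$phenotype == "naive"))
})
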