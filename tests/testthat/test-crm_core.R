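test_that("uptake matrix generation follows the theta sparsity rule", {
  U0 <- generate_uptake_matrix(4, 6, 0, theta = 0, seed = 1)
  expect_true(all(U0$C == 0))

  U1 <- generate_uptake_matrix(4, 6, 2, theta = 1, uptake_scale = 2e-3,
                               seed = 1)
  expect_true(all(U1$C > 0))
  expect_true(all(U1$C <= 2e-3))
  expect_equal(dim(U1$C), c(4, 8))

  # per-species theta: rows obey their own probability
  Um <- generate_uptake_matrix(2, 5000, 0, theta = c(0.2, 0.9), seed = 2)
  fr <- rowMeans(Um$C > 0)
  expect_equal(fr[1], 0.2, tolerance = 0.05)
  expect_equal(fr[2], 0.9, tolerance = 0.05)

  # binomial count check at the experimental scale: 13 x 32, theta = 0.5
  set.seed(3)
  nz <- replicate(20, sum(generate_uptake_matrix(13, 32, 0, 0.5)$C > 0))
  expect_equal(mean(nz), 208, tolerance = 4 * 10.2 / sqrt(20) / 208)

  expect_error(generate_uptake_matrix(4, 6, 0, theta = 1.2), "theta")
})

test_that("byproduct tensor is column-normalized and mass-conserving", {
  D0 <- generate_byproduct_tensor(3, 5, 4, transition_probability = 0, seed = 1)
  expect_true(all(D0 == 0))

  D1 <- generate_byproduct_tensor(3, 5, 4, transition_probability = 1, seed = 1)
  expect_true(all(D1 == 0.25))  # forced normalization: 4 entries of 1/4

  # single byproduct: columns are exactly 0 or 1
  Db <- generate_byproduct_tensor(4, 50, 1, transition_probability = 0.25,
                                  seed = 2)
  expect_true(all(Db %in% c(0, 1)))
  expect_equal(mean(Db), 0.25, tolerance = 0.15)

  # generic: every column sums to 0 or 1
  D <- generate_byproduct_tensor(5, 7, 3, seed = 3)
  sums <- apply(D, c(2, 3), sum)
  expect_true(all(abs(sums) < 1e-12 | abs(sums - 1) < 1e-12))

  expect_error(generate_byproduct_tensor(2, 3, 1, transition_probability = 2),
               "probability")
})

test_that("the dynamics right-hand side matches closed forms", {
  p <- crm_params(g = 1, w = 10, m = 0, l = 0.2, k = 5)
  U <- fixed_uptake(matrix(c(0.3, 0.1), 1, 2))

  # at R = k the Monod factor is exactly 1/2
  r <- crm_rhs(N = 2, R = c(5, 5), U, params = p)
  expect_equal(r$dR, -c(0.3, 0.1) * 2 * 0.5)
  expect_equal(r$dN, 2 * sum(10 * 0.8 * c(0.3, 0.1) * 0.5))

  # no resources, positive maintenance: pure exponential decay
  p2 <- crm_params(g = 2, w = 10, m = 0.3, l = 0.2, k = 5)
  r2 <- crm_rhs(N = 4, R = c(0, 0), U, params = p2)
  expect_equal(r2$dN, -2 * 0.3 * 4)
  expect_equal(r2$dR, c(0, 0))

  # single species / single resource, m = 0: dN/dR = -w(1-l) everywhere
  U1 <- fixed_uptake(matrix(0.2, 1, 1))
  for (R in c(0.1, 1, 7)) {
    r3 <- crm_rhs(N = 3, R = R, U1, params = p)
    expect_equal(r3$dN / r3$dR, -10 * (1 - 0.2))
  }

  expect_error(crm_rhs(N = c(1, 1), R = 1, U1), "dimensions")
})

test_that("compiled integrator agrees with the pure-R right-hand side", {
  set.seed(4)
  p <- crm_params(g = 1.3, w = 8, m = 0.05, l = 0.6, k = 3, dt = 0.01)
  U <- generate_uptake_matrix(3, 4, 2, theta = 0.8, uptake_scale = 0.5)
  D <- generate_byproduct_tensor(3, 4, 2)
  N0 <- runif(3, 0.5, 2); R0 <- runif(6, 0.2, 1)
  # one Euler step by hand from the R oracle
  rhs <- crm_rhs(N0, R0, U, D, p)
  step <- integrate_batch(N0, R0, U, D, p, duration = p$dt)
  expect_equal(step$N, pmax(N0 + p$dt * rhs$dN, 0), tolerance = 1e-12)
  expect_equal(step$R, pmax(R0 + p$dt * rhs$dR, 0), tolerance = 1e-12)
})

test_that("batch integration satisfies the yield conservation law", {
  # single species, single resource, no maintenance, no byproducts:
  # every unit of resource becomes g*w*(1-l) units of biomass
  p <- crm_params(g = 1, w = 1e8, m = 0, l = 0.8, k = 1e4, dt = 0.01)
  U <- fixed_uptake(matrix(5e-4, 1, 1))
  out <- integrate_batch(N0 = 6e6, R0 = 1.5, U, params = p, duration = 48)
  dN <- out$N - 6e6
  dR <- 1.5 - out$R
  expect_gt(dN, 0)
  expect_equal(dN, 1 * 1e8 * (1 - 0.8) * dR, tolerance = 1e-6)

  # trajectory bookkeeping: includes t = 0 and t = duration
  tr <- integrate_batch(6e6, 1.5, U, params = p, duration = 48, thin = 400)
  expect_equal(tr$times[1], 0)
  expect_equal(tr$times[length(tr$times)], 48)
  expect_equal(tr$N_traj[nrow(tr$N_traj), 1], tr$N)

  # zero duration returns the state unchanged
  z <- integrate_batch(6e6, 1.5, U, params = p, duration = 0)
  expect_equal(z$N, 6e6)
})

test_that("no uptake means a frozen community; m = 0 means nondecreasing N", {
  p <- fast_params(m = 0)
  U0 <- generate_uptake_matrix(3, 4, 0, theta = 0, seed = 5)
  out <- integrate_batch(rep(1, 3), rep(0.375, 4), U0, params = p,
                         duration = 48)
  expect_equal(out$N, rep(1, 3))
  expect_equal(out$R, rep(0.375, 4))

  set.seed(6)
  U <- generate_uptake_matrix(3, 4, 0, theta = 0.8, uptake_scale = 1)
  tr <- integrate_batch(rep(1, 3), rep(0.375, 4), U, params = p,
                        duration = 8, thin = 50)
  expect_true(all(diff(tr$N_traj) >= -1e-12))
})

test_that("halving the timestep barely moves the endpoint (step robustness)", {
  set.seed(7)
  U <- generate_uptake_matrix(13, 32, 5, theta = 0.5)
  D <- generate_byproduct_tensor(13, 32, 5)
  R0 <- c(rep(1.5 / 32, 32), numeric(5))
  o1 <- integrate_batch(rep(6e6, 13), R0, U, D, crm_params(dt = 0.01),
                        duration = 48)
  o2 <- integrate_batch(rep(6e6, 13), R0, U, D, crm_params(dt = 0.005),
                        duration = 48)
  expect_equal(sum(o1$N), sum(o2$N), tolerance = 1e-3)
})

test_that("byproduct production never exceeds the leaked primary flux", {
  set.seed(8)
  p <- fast_params(l = 0.6)
  U <- generate_uptake_matrix(4, 5, 3, theta = 0.9, uptake_scale = 1)
  D <- generate_byproduct_tensor(4, 5, 3, transition_probability = 0.8)
  N <- runif(4, 0.5, 2); R <- runif(8, 0.1, 1)
  r <- crm_rhs(N, R, U, D, p)
  mon <- R / (5 + R)
  primary_out <- sum((t(U$C[, 1:5]) %*% N) * mon[1:5])
  byproduct_in <- sum(r$dR[6:8] + (t(U$C[, 6:8]) %*% N) * mon[6:8])
  expect_lte(byproduct_in, 0.6 * primary_out + 1e-12)
})

test_that("serial passaging dilutes, resets resources and washes out nonusers", {
  # dilution_factor = 1, single passage reduces to one batch
  p <- fast_params(dilution_factor = 1, n_passages = 1)
  set.seed(9)
  U <- generate_uptake_matrix(3, 4, 0, theta = 0.7, uptake_scale = 1)
  conc <- equal_carbon_concentrations(1:4, 1.5)
  sim <- simulate_passaged(conc, U, params = p)
  direct <- integrate_batch(rep(p$N0, 3), rep(0.375, 4), U, params = p,
                            duration = p$passage_interval)
  expect_equal(sim$N, direct$N)
  expect_equal(sim$yield, sum(direct$N) - 3 * p$N0)

  # species with no usable resource decays below the dilution bound
  C <- rbind(c(1, 1, 1, 1), c(0, 0, 0, 0))
  U2 <- fixed_uptake(C)
  p2 <- fast_params(m = 0.2, n_passages = 3, dilution_factor = 0.1)
  sim2 <- simulate_passaged(conc, U2, params = p2)
  expect_lt(sim2$N[2], p2$N0 * p2$dilution_factor^(p2$n_passages - 1))
  expect_false(2 %in% sim2$survivors)

  # unknown resource ids are rejected
  expect_error(simulate_passaged(c("9" = 1.5), U2, params = p2),
               "map onto columns")
})

test_that("passage bookkeeping records per-batch biomass", {
  p <- fast_params(n_passages = 3)
  set.seed(10)
  U <- generate_uptake_matrix(2, 4, 0, theta = 1, uptake_scale = 1)
  sim <- simulate_passaged(equal_carbon_concentrations(1:4, 1.5), U,
                           params = p)
  expect_equal(nrow(sim$passages), 3)
  expect_equal(sim$passages$biomass_start[1], 2 * p$N0)
  # dilution links consecutive batches
  expect_equal(sim$passages$biomass_start[2],
               sim$passages$biomass_end[1] * p$dilution_factor)
  expect_equal(sim$yield, sim$passages$yield[3])
})

test_that("parameter validation catches invalid settings", {
  expect_error(crm_params(l = 1.2), "leakage")
  expect_error(crm_params(dt = 0), "dt")
  expect_error(crm_params(dilution_factor = 0), "dilution_factor")
  expect_error(crm_params(m = -1), "m")
  expect_error(crm_params(w = -1), "> 0")
})
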