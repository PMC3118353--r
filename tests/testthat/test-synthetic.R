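test_that("toy networks are deterministic functions of their arguments", {
  expect_true(plpath:::networks_equal(make_toy_network("random", 10, seed = 5),
                                      make_toy_network("random", 10, seed = 5)))
  expect_false(plpath:::networks_equal(make_toy_network("random", 10, seed = 5),
                                       make_toy_network("random", 10, seed = 6)))
  expect_equal(n_reactions(make_toy_network("chain", 5)), 5)
  expect_equal(enumerate_ems(make_toy_network("branch", 2))$n_modes, 2)
  # every random network admits at least one mode
  for (s in 1:5)
    expect_gte(enumerate_ems(make_toy_network("random", 8, seed = s))$n_modes, 1)
})

test_that("datasets are reproducible and respect the noise switch", {
  b <- branch20()
  tr <- ground_truth(active = c(3, 8, 15), noise_sd = 0.05)
  d1 <- simulate_dataset(b$net, tr, np = 30, nx = 8, seed = 42)
  d2 <- simulate_dataset(b$net, tr, np = 30, nx = 8, seed = 42)
  expect_identical(d1$X, d2$X)
  expect_identical(d1$R, d2$R)
  # zero noise: rows lie exactly in the span of the active modes
  tr0 <- ground_truth(active = c(3, 8, 15), noise_sd = 0)
  d0 <- simulate_dataset(b$net, tr0, np = 30, nx = 8, seed = 42)
  E_act <- b$ems$E[, c(3, 8, 15)]
  proj <- E_act %*% solve(crossprod(E_act), crossprod(E_act, t(d0$R)))
  expect_lt(max(abs(t(proj) - d0$R)), 1e-10)
  # fixing the weight model: different seeds share the noiseless part
  trf <- ground_truth(active = c(3, 8), noise_sd = 0.05,
                      intercepts = c(2, 3),
                      coefs = matrix(c(1, rep(0, 7), 0, 1, rep(0, 6)), 2,
                                     byrow = TRUE))
  da <- simulate_dataset(b$net, trf, np = 30, nx = 8, seed = 1)
  db <- simulate_dataset(b$net, trf, np = 30, nx = 8, seed = 2)
  expect_false(identical(da$R, db$R))
  expect_error(simulate_dataset(b$net, ground_truth(active = 999), np = 10,
                                nx = 3, seed = 1), "unknown mode")
})

test_that("simulated measurement noise matches its nominal relative sd", {
  b <- branch20()
  tr <- ground_truth(active = 3, noise_sd = 0.05, intercepts = 5,
                     coefs = matrix(0, 1, 3))
  ds <- simulate_dataset(b$net, tr, np = 10000, nx = 3, seed = 9)
  rel <- ds$R[, "r0"] / ds$R_noiseless[, "r0"]
  expect_lt(abs(sd(log(rel)) - 0.05) / 0.05, 0.1)
})

test_that("simulated batch cultures match the closed-form solution", {
  q <- c(Glc = -150)
  mu <- 0.02
  cult <- simulate_culture(rates = q, mu = mu, init = c(Glc = 25),
                           times = seq(0, 48, 4), noise_sd = 0,
                           Xv0 = 0.3, V0 = 1000)
  tt <- cult$time
  # amount balance: A(t) = A0 + q/1000 * X0 V0 (e^{mu t} - 1)/mu   [umol]
  A <- 25 * 1000 + q[["Glc"]] / 1000 * 0.3 * 1000 * (exp(mu * tt) - 1) / mu
  expect_equal(cult$factors$Glc, A / 1000, tolerance = 1e-6)
  expect_equal(cult$viable_cells, 0.3 * exp(mu * tt), tolerance = 1e-6)
  # zero growth: flat viable cells
  flat <- simulate_culture(rates = c(Glc = -10), mu = 0, init = c(Glc = 30),
                           times = seq(0, 24, 4), noise_sd = 0)
  expect_lt(diff(range(flat$viable_cells)), 1e-8)
  # running into substrate exhaustion is diagnosed
  expect_error(simulate_culture(rates = c(Glc = -500), mu = 0.03,
                                init = c(Glc = 1), times = seq(0, 100, 5)),
               "negative concentrations")
})

test_that("rate estimation closes the loop on simulated cultures", {
  q <- c(Glc = -150, Lac = 280)
  err <- replicate(5, {
    s <- sample.int(1000, 1)
    cult <- simulate_culture(rates = q, mu = 0.02, init = c(Glc = 25, Lac = 1),
                             times = seq(0, 48, 3), noise_sd = 0.02, seed = s)
    est <- estimate_specific_rates(cult, phase_window(0, 48),
                                   compounds = names(q))
    max(abs(est$rates - q) / abs(q))
  })
  expect_lt(median(err), 0.1)   # within the 2% noise propagation envelope
})

test_that("fixtures load as typed objects with the printed values", {
  t7 <- load_fixture("table7_rates")
  expect_equal(t7[["Fed-batch 1"]][["Ph I"]]$rates[["rGlc"]], -190.33)
  expect_equal(t7[["Fed-batch 3"]][["Ph V"]]$rates[["mu"]], 0.008)
  expect_equal(length(t7[["Fed-batch 2"]]), 5)   # five phases
  expect_equal(length(t7[["Fed-batch 1"]][["Ph II"]]$rates), 24)
  feeds <- load_fixture("table1_feeds")
  expect_equal(feeds$value_mM[feeds$culture == "Fed-batch 1" &
                                feeds$item == "feed1" &
                                feeds$compound == "Gln"], 15.0)
  sel <- load_fixture("em_selections")
  expect_length(sel$selections, 3)
  expect_equal(sel$selections[["Fed-batch 3"]][["Ph I"]][1], 110)
  expect_error(load_fixture("bhk_network"), "fixture pending")
  expect_error(load_fixture("nope"), "table7_rates")
})
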