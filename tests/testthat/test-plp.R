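test_that("explained variance follows its defining formula", {
  R <- diag(2)
  expect_equal(explained_variance(R, R), 100)
  expect_equal(explained_variance(R, 0 * R), 0)
  expect_equal(explained_variance(R, matrix(c(1, 0, 0, 0), 2)), 50)
  expect_error(explained_variance(0 * R, R), "zero denominator")
})

test_that("a noise-free single-mode construction is fit perfectly", {
  b <- branch20()
  set.seed(8)
  X <- matrix(rnorm(60 * 5), 60, 5, dimnames = list(NULL, paste0("x", 1:5)))
  cvec <- c(1.5, -0.7, 0, 0.4, 0)
  Lam <- X %*% cvec
  e1 <- b$ems$E[, 1]
  R <- Lam %*% t(e1)
  colnames(R) <- rownames(b$ems$E)
  ds <- list(X = X, R = R, scaling = NULL)
  m <- plp_fit(ds, b$ems, config = plp_config(max_components = 1))
  expect_equal(m$selected$mode, 1L)
  expect_equal(m$selected$cumulative_variance, 100, tolerance = 1e-8)
  # FEM column is proportional to the generating coefficients
  fem <- build_fem(m)
  cs <- sum(fem$raw[, 1] * cvec) / sqrt(sum(fem$raw[, 1]^2) * sum(cvec^2))
  expect_gte(abs(cs), 0.999)
  # unselected columns exactly zero
  expect_true(all(fem$raw[, -1] == 0))
  # flipping the sign of an envirome column flips the matching FEM row
  X2 <- X; X2[, 2] <- -X2[, 2]
  m2 <- plp_fit(list(X = X2, R = R, scaling = NULL), b$ems,
                config = plp_config(max_components = 1))
  fem2 <- build_fem(m2)
  expect_equal(fem2$raw[2, 1], -fem$raw[2, 1], tolerance = 1e-8)
  expect_equal(fem2$raw[-2, 1], fem$raw[-2, 1], tolerance = 1e-8)
})

test_that("the first selection attains the maximum single-mode variance", {
  b <- branch20()
  tr <- ground_truth(active = c(2, 9, 17), noise_sd = 0.05)
  ds <- simulate_dataset(b$net, tr, np = 60, nx = 12, seed = 5)
  m <- plp_fit(ds, b$ems, config = plp_config(max_components = 1))
  # independent scan: per mode, regress R e on X by lm() and score the
  # rank-one reconstruction
  Em <- b$ems$E[colnames(ds$R), ]
  Eu <- sweep(Em, 2, sqrt(colSums(Em^2)), "/")
  scan <- vapply(seq_len(ncol(Eu)), function(j) {
    u <- as.numeric(ds$R %*% Eu[, j])
    uhat <- fitted(lm(u ~ ds$X))
    explained_variance(ds$R, outer(uhat, Eu[, j]))
  }, numeric(1))
  expect_equal(m$selected$mode[1], which.max(scan))
  expect_equal(m$selected$cumulative_variance[1], max(scan), tolerance = 1e-6)
})

test_that("planted modes are recovered from noisy envirome data", {
  b <- branch20()
  hits <- 0
  gaps <- numeric(0)
  for (r in 1:20) {
    tr <- ground_truth(active = c(3, 8, 15), noise_sd = 0.05)
    ds <- simulate_dataset(b$net, tr, np = 100, nx = 27, seed = 100 + r)
    m <- plp_fit(ds, b$ems)
    if (setequal(m$selected$mode[1:3], c(3, 8, 15))) hits <- hits + 1
    # noise-free share under the same weight model
    ds0 <- simulate_dataset(b$net,
                            ground_truth(active = c(3, 8, 15), noise_sd = 0,
                                         intercepts = ds$truth$intercepts,
                                         coefs = ds$truth$coefs),
                            np = 100, nx = 27, seed = 100 + r)
    m0 <- plp_fit(ds0, b$ems, config = plp_config(max_components = 3,
                                                  min_variance_gain = 0))
    gaps <- c(gaps, abs(m$selected$cumulative_variance[3] -
                          m0$selected$cumulative_variance[3]))
  }
  expect_gte(hits, 19)
  expect_lt(median(gaps), 3)
})

test_that("cumulative variance is non-decreasing and exact noise-free", {
  b <- branch20()
  for (s in c(1, 2, 3)) {
    tr <- ground_truth(active = c(1, 6, 11, 19), noise_sd = 0.08)
    ds <- simulate_dataset(b$net, tr, np = 50, nx = 10, seed = s)
    m <- plp_fit(ds, b$ems, config = plp_config(min_variance_gain = 0,
                                                max_components = 10))
    expect_true(all(diff(m$selected$cumulative_variance) >= -1e-9))
    expect_true(all(m$selected$gain >= -1e-9))
  }
  tr0 <- ground_truth(active = c(2, 5, 9), noise_sd = 0)
  ds0 <- simulate_dataset(b$net, tr0, np = 80, nx = 15, seed = 4)
  m0 <- plp_fit(ds0, b$ems, config = plp_config(max_components = 3,
                                                min_variance_gain = 0))
  expect_equal(utils::tail(m0$selected$cumulative_variance, 1), 100,
               tolerance = 1e-6)
})

test_that("prediction reproduces training data and transfers out of sample", {
  b <- branch20()
  tr <- ground_truth(active = c(4, 12, 18), noise_sd = 0.05)
  ds <- simulate_dataset(b$net, tr, np = 120, nx = 20, seed = 42)
  train <- list(X = ds$X[1:80, ], R = ds$R[1:80, ], scaling = NULL)
  m <- plp_fit(train, b$ems)
  # reconstruction identity on the training rows
  expect_lt(max(abs(predict(m, train$X, scaled = TRUE) - m$fitted)), 1e-10)
  lam_e <- m$Lambda_hat %*%
    t(sweep(b$ems$E[m$measured, m$selected$mode, drop = FALSE], 2,
            m$selected$sign, "*"))
  expect_lt(max(abs(lam_e - m$fitted)), 1e-10)
  # out-of-sample explained variance within 5 points of in-sample
  in_var <- explained_variance(train$R, m$fitted)
  out_var <- explained_variance(ds$R[81:120, ],
                                predict(m, ds$X[81:120, ], scaled = TRUE))
  expect_lt(abs(in_var - out_var), 5)
  expect_error(predict(m, ds$X[, 1:3]), "columns")
})

test_that("reversed fully reversible modes are reported with sign -1", {
  net <- network_from_equations(c("r1", "r2", "r3"),
                                c("A_ext <-> M", "M <-> B_ext", "C_ext -> M"))
  ems <- enumerate_ems(net)
  fri <- which(ems$fully_reversible)[1]
  tr <- ground_truth(active = fri, signs = -1, noise_sd = 0)
  ds <- simulate_dataset(net, tr, np = 50, nx = 5, seed = 3)
  m <- plp_fit(ds, ems, config = plp_config(max_components = 1))
  expect_equal(m$selected$mode, fri)
  expect_equal(m$selected$sign, -1L)
})

test_that("degenerate inputs raise clear errors", {
  b <- branch20()
  X <- matrix(rnorm(20), 10, 2)
  expect_error(plp_fit(list(X = X, R = matrix(0, 10, 3)), b$ems), "all-zero")
  ds <- simulate_dataset(b$net, ground_truth(1, noise_sd = 0), np = 10,
                         nx = 3, seed = 1)
  empty <- elementary_mode_set(b$ems$E[, 0, drop = FALSE], logical(0))
  expect_error(plp_fit(ds, empty), "empty")
})

test_that("consistency-stopped reconstruction reduces the network", {
  net <- make_toy_network("branch", 8)
  ems <- enumerate_ems(net)
  tr <- ground_truth(active = c(2, 5, 7, 8), noise_sd = 0.02)
  ds <- simulate_dataset(net, tr, np = 60, nx = 10, seed = 17)
  fc <- plp_fit_consistent(ds, ems, net)
  expect_true(fc$consistent)
  expect_lte(fc$n_modes, 6)
  expect_true(isTRUE(fc$mfa$consistent))
  expect_lte(n_reactions(fc$network), n_reactions(net))
  # noise-free single active mode stops immediately
  tr1 <- ground_truth(active = 3, noise_sd = 0)
  ds1 <- simulate_dataset(net, tr1, np = 30, nx = 6, seed = 2)
  fc1 <- plp_fit_consistent(ds1, ems, net)
  expect_equal(fc1$n_modes, 1)
})

test_that("moving-window analysis measures pathway conservation", {
  net <- make_toy_network("branch", 8)
  ems <- enumerate_ems(net)
  tr <- ground_truth(active = c(2, 5, 7), noise_sd = 0.05)
  ds <- simulate_dataset(net, tr, np = 60, nx = 10, seed = 23)
  ds$meta <- data.frame(culture = "c1", phase = rep(c("P1", "P2"), each = 30))
  mw <- plp_moving_window(ds, ems, plp_config(max_components = 4))
  expect_equal(mw$report$within_culture_pct, 100)
  # an undersized phase is skipped with a warning
  ds$meta$phase[60] <- "P3"
  expect_warning(plp_moving_window(ds, ems, plp_config(max_components = 4)),
                 "fewer than 2")
})

test_that("conservation report reproduces the published statistics", {
  sel <- load_fixture("em_selections")$selections
  rep <- conservation_report(sel)
  expect_equal(rep$within_culture_pct, 42.1, tolerance = 0.01)
  expect_equal(rep$between_cultures_pct, 37.5, tolerance = 1e-9)
  # two identical phase lists give full conservation
  expect_equal(conservation_report(list(a = list(p1 = c(1, -2), p2 = c(1, -2))))$
                 within_culture_pct, 100)
})
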