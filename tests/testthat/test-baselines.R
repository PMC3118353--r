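test_that("minimum-norm weights solve trivial decompositions", {
  net <- dof2_net()
  ems <- enumerate_ems(net)
  E <- ems$E
  # single mode: r = 2 e1
  s1 <- min_norm_weights(E[, 1, drop = FALSE], 2 * E[, 1], FALSE, mode = "hard")
  expect_equal(s1$lambda, 2, tolerance = 1e-8)
  expect_lt(s1$residual_norm, 1e-8)
  # two disjoint-support modes: unique decomposition (1, 3)
  s2 <- min_norm_weights(E, E[, 1] + 3 * E[, 2], ems$fully_reversible,
                         mode = "hard")
  expect_equal(unname(s2$lambda), c(1, 3), tolerance = 1e-8)
})

test_that("min-norm matches a brute-force oracle on a degenerate instance", {
  # e3 = e1 + e2: decompositions of r = e1 + e2 form a line; the QP picks
  # the point of smallest sum of squares, found here by direct grid search
  E <- cbind(c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 1))
  E <- cbind(E, E[, 1] + E[, 2])
  r <- E[, 1] + E[, 2]
  sol <- min_norm_weights(E, r, rep(FALSE, 3), mode = "hard")
  grid <- seq(0, 1, by = 1e-4)
  obj <- (1 - grid)^2 + (1 - grid)^2 + grid^2
  t_star <- grid[which.min(obj)]
  oracle <- c(1 - t_star, 1 - t_star, t_star)
  expect_equal(unname(sol$lambda), oracle, tolerance = 1e-3)
  expect_lt(max(abs(E %*% sol$lambda - r)), 1e-6)
  expect_true(kkt_check(E, sol$lambda, rep(FALSE, 3)))
  expect_lte(sol$objective, min(obj) + 1e-6)
})

test_that("hard mode reports infeasibility; soft mode always answers", {
  E <- cbind(c(1, 1, 0), c(0, 1, 1))   # irreversible modes only
  r_out <- c(-1, -2, -1)               # outside the non-negative cone
  hard <- min_norm_weights(E, r_out, rep(FALSE, 2), mode = "hard")
  expect_false(hard$feasible)
  soft <- min_norm_weights(E, r_out, rep(FALSE, 2), mode = "soft")
  expect_true(soft$feasible)
  # soft residual equals the non-negative least-squares optimum
  nn <- pracma::lsqnonneg(E, r_out)
  expect_equal(soft$residual_norm, sqrt(sum((E %*% nn$x - r_out)^2)),
               tolerance = 1e-6)
})

test_that("KKT conditions hold at min-norm solutions across instances", {
  for (s in 1:5) {
    net <- make_toy_network("random", 9, seed = s)
    ems <- enumerate_ems(net)
    if (ems$n_modes < 2) next
    set.seed(s)
    lam_true <- runif(ems$n_modes, 0, 2)
    lam_true[ems$fully_reversible] <- lam_true[ems$fully_reversible] - 1
    r <- as.numeric(ems$E %*% lam_true)
    sol <- min_norm_weights(ems$E, r, ems$fully_reversible, mode = "hard")
    expect_true(sol$feasible)
    expect_true(kkt_check(ems$E, sol$lambda, ems$fully_reversible))
  }
})

test_that("the alpha-spectrum brackets feasible weights", {
  net <- dof2_net()
  ems <- enumerate_ems(net)
  r <- ems$E[, 1] * 2 + ems$E[, 2] * 0.5
  asp <- alpha_spectrum(ems$E, r, ems$fully_reversible)
  expect_true(all(asp$feasible))
  # unique decomposition: min = max = the weight
  expect_equal(asp$min, c(2, 0.5), tolerance = 1e-6)
  expect_equal(asp$max, c(2, 0.5), tolerance = 1e-6)
  # degenerate instance: ranges bracket the min-norm point
  E <- cbind(c(1, 1, 0, 0, 1), c(0, 0, 1, 1, 1))
  E <- cbind(E, E[, 1] + E[, 2])
  rr <- E[, 1] + E[, 2]
  sol <- min_norm_weights(E, rr, rep(FALSE, 3), mode = "hard")
  asp2 <- alpha_spectrum(E, rr, rep(FALSE, 3))
  expect_true(all(sol$lambda >= asp2$min - 1e-6))
  expect_true(all(sol$lambda <= asp2$max + 1e-6))
  expect_equal(asp2$min, c(0, 0, 0), tolerance = 1e-6)
  expect_equal(asp2$max, c(1, 1, 1), tolerance = 1e-6)
  # infeasible target flags every mode
  asp3 <- alpha_spectrum(ems$E, -r, ems$fully_reversible)
  expect_false(any(asp3$feasible))
})

test_that("the census counts active modes and is threshold-monotone", {
  mk <- function(lam) structure(list(lambda = lam), class = "weight_solution")
  zero <- replicate(3, mk(rep(0, 4)), simplify = FALSE)
  expect_equal(unname(weight_census(zero)$counts), c(0, 0))
  sols <- list(mk(c(2, 0.05, 0, 1.5)), mk(c(1.8, 0, 0.5, 0.2)))
  cen <- weight_census(sols, thresholds = c(0.1, 1))
  expect_equal(unname(cen$counts[["0.1"]]), 3)
  expect_equal(unname(cen$counts[["1"]]), 2)
  expect_lte(cen$counts[["1"]], cen$counts[["0.1"]])
})

test_that("census on seeded synthetic data finds exactly the planted modes", {
  b <- branch20()
  tr <- ground_truth(active = c(3, 8, 15), noise_sd = 0.05)
  ds <- simulate_dataset(b$net, tr, np = 20, nx = 10, seed = 11)
  Em <- b$ems$E[colnames(ds$R), ]
  sols <- lapply(seq_len(nrow(ds$R)), function(i)
    min_norm_weights(Em, ds$R[i, ], b$ems$fully_reversible, mode = "soft"))
  cen <- weight_census(sols, thresholds = c(0.1, 1), E = Em, R = ds$R)
  expect_equal(unname(cen$counts[["0.1"]]), 3)
  # variance ranking puts the planted modes first
  expect_setequal(cen$variance_ranking$mode[1:3], paste0("m", c(3, 8, 15)))
})
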