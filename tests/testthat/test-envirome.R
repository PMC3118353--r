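test_that("batch specific rates have the closed form -1000 k / X0", {
  tt <- seq(0, 48, 4)
  cs <- culture_time_series(tt, rep(2, length(tt)), rep(1000, length(tt)),
                            data.frame(temperature = 37, pH = 7.1,
                                       osmolality = 300, Glc = 10 - 0.1 * tt))
  est <- estimate_specific_rates(cs, phase_window(0, 48))
  expect_equal(unname(est$rates["Glc"]), -1000 * 0.1 / 2, tolerance = 1e-12)
  expect_equal(est$mu, 0, tolerance = 1e-12)
})

test_that("rates are exact on data from the estimator's own balance", {
  # build amounts from the discrete fed-batch balance the estimator inverts
  tt <- seq(0, 60, 5)
  q <- c(Glc = -120, Lac = 200)
  mu <- 0.02
  V <- 1000 + 2 * tt
  Xv <- 0.4 * exp(mu * tt) * 1000 / V
  feeds <- data.frame(time = 0, rate = 2, Glc = 150)
  xvv <- Xv * V
  cum <- c(0, cumsum(diff(tt) * (head(xvv, -1) + tail(xvv, -1)) / 2))
  conc <- sapply(names(q), function(cmp) {
    fed <- if (cmp == "Glc") 2 * 150 * tt else 0   # umol fed in
    (20 * 1000 + q[[cmp]] * cum / 1000 + fed) / V  # amounts in umol -> mM
  })
  cs <- culture_time_series(tt, Xv, V,
                            cbind(data.frame(temperature = 37, pH = 7.1,
                                             osmolality = 300),
                                  as.data.frame(conc)), feeds = feeds)
  est <- estimate_specific_rates(cs, phase_window(0, 60))
  expect_equal(unname(est$rates[names(q)]), unname(q), tolerance = 1e-9)
  expect_equal(est$mu, mu, tolerance = 1e-9)
})

test_that("rate estimation enforces its preconditions", {
  tt <- seq(0, 48, 4)
  cs <- culture_time_series(tt, rep(2, length(tt)), rep(1000, length(tt)),
                            data.frame(Glc = 10 - 0.1 * tt))
  expect_error(estimate_specific_rates(cs, phase_window(0, 5)), "3 samples")
  cs2 <- culture_time_series(tt, c(rep(2, 12), 0), rep(1000, length(tt)),
                             data.frame(Glc = 10 - 0.1 * tt))
  expect_error(estimate_specific_rates(cs2, phase_window(0, 48)), "viable")
})

test_that("manual breakpoints are honoured verbatim", {
  tt <- seq(21, 118, length.out = 30)
  cs <- culture_time_series(tt, rep(2, 30), rep(1000, 30),
                            data.frame(Glc = 10 - 0.05 * tt))
  ph <- segment_phases(cs, breakpoints = c(45, 70, 95))
  expect_length(ph, 4)
  expect_equal(vapply(ph, `[[`, numeric(1), "start"), c(21, 45, 70, 95))
  expect_equal(vapply(ph, `[[`, numeric(1), "end"), c(45, 70, 95, 118))
  expect_error(segment_phases(cs, breakpoints = 200), "outside")
})

test_that("automatic segmentation finds the rate change, not phantoms", {
  hits <- 0
  for (rep in 1:20) {
    set.seed(rep)
    tt <- seq(0, 150, 5)
    conc <- ifelse(tt <= 75, 20 - 0.1 * tt, 12.5 - 0.25 * (tt - 75)) *
      (1 + rnorm(length(tt), 0, 0.02))
    cs <- culture_time_series(tt, rep(2, length(tt)), rep(1000, length(tt)),
                              data.frame(temperature = 37, pH = 7.1,
                                         osmolality = 300, Glc = conc))
    ph <- segment_phases(cs)
    bounds <- setdiff(unlist(lapply(ph, function(p) c(p$start, p$end))),
                      c(0, 150))
    if (any(abs(bounds - 75) <= 5)) hits <- hits + 1
    # never overlapping, always inside the observed range
    starts <- vapply(ph, `[[`, numeric(1), "start")
    ends <- vapply(ph, `[[`, numeric(1), "end")
    expect_true(all(starts < ends))
    expect_true(all(starts >= 0) && all(ends <= 150))
    if (length(ph) > 1) expect_true(all(diff(starts) > 0))
  }
  expect_gte(hits, 19)
  # constant-rate culture stays one phase
  set.seed(1)
  tt <- seq(0, 150, 5)
  cs <- culture_time_series(tt, rep(2, length(tt)), rep(1000, length(tt)),
                            data.frame(Glc = (20 - 0.1 * tt) *
                                         (1 + rnorm(length(tt), 0, 0.02))))
  expect_length(segment_phases(cs), 1)
})

test_that("assembled datasets scale, flag zero variance, and de-scale", {
  X <- cbind(a = rnorm(30, 5, 2), b = rnorm(30), const = rep(3, 30))
  R <- cbind(r1 = rnorm(30))
  ds <- envirome_dataset(X, R, scaling = "autoscale")
  expect_lt(max(abs(colMeans(ds$X))), 1e-12)
  expect_equal(unname(apply(ds$X[, 1:2], 2, sd)), c(1, 1), tolerance = 1e-12)
  expect_equal(unname(ds$scaling$zero_variance), c(FALSE, FALSE, TRUE))
  expect_true("const" %in% colnames(ds$X))  # retained, not dropped
  expect_lt(max(abs(descale_X(ds) - X)), 1e-10)
  expect_error(envirome_dataset(X, R[1:10, , drop = FALSE]), "row count")
})

test_that("assemble_envirome pairs phase rates with factor rows", {
  tt <- seq(0, 48, 4)
  mk <- function(id) culture_time_series(
    tt, 2 * exp(0.02 * tt), rep(1000, length(tt)),
    data.frame(temperature = 37, pH = 7.1, osmolality = 300,
               Glc = 20 - 0.2 * tt), id = id)
  phases <- list(phase_window(0, 24, "PhI"), phase_window(24, 48, "PhII"))
  ds <- assemble_envirome(list(mk("c1"), mk("c2")), list(phases, phases))
  expect_equal(ncol(ds$X), 4)
  expect_equal(nrow(ds$X), nrow(ds$R))
  expect_setequal(unique(ds$meta$culture), c("c1", "c2"))
  expect_true(all(c("mu", "Glc") %in% colnames(ds$R)))
  dsm <- assemble_envirome(list(mk("c1")), list(phases),
                           granularity = "phase_mean")
  expect_equal(nrow(dsm$X), 2)
  bad <- mk("c3"); names(bad$factors)[4] <- "Gluc"
  expect_error(assemble_envirome(list(mk("c1"), bad), list(phases, phases)),
               "inconsistent factor names")
})
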