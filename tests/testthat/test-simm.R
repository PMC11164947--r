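test_that("log posterior is maximized at the symmetric mixture", {
  src <- symmetric_sources()
  spec <- simm_spec(src, tef = tef_spec(c(0, 0), c(0, 0)))
  x <- symmetric_consumers()
  # grid search over p1 at resolution 0.001
  p1 <- seq(0.001, 0.999, by = 0.001)
  lp <- vapply(p1, function(a) {
    simm_log_posterior(c(a, 1 - a), c(0.1, 0.1), spec, x)
  }, numeric(1))
  expect_equal(p1[which.max(lp)], 0.5, tolerance = 1e-3)
  # flat Dirichlet(1) prior contributes nothing that varies with p:
  # with no data the log density is constant across the simplex
  empty <- matrix(numeric(0), 0, 2)
  vals <- vapply(c(0.1, 0.3, 0.5, 0.9), function(a) {
    simm_log_posterior(c(a, 1 - a), c(1, 1), spec, empty)
  }, numeric(1))
  expect_equal(max(vals) - min(vals), 0)
  # duplicated noiseless source: the mixture mean (and hence the noiseless
  # forward draw) is mu + lambda independently of p
  dup <- data.frame(label = c("s1", "s2"), d13c_mean = -15, d13c_sd = 0,
                    d15n_mean = 3, d15n_sd = 0)
  dtef <- tef_spec(c(1.3, 3.4), c(0, 0))
  x_a <- simulate_consumers(dup, c(0.9, 0.1), n = 3, eps = c(0, 0),
                            seed = 1, tef = dtef)
  x_b <- simulate_consumers(dup, c(0.2, 0.8), n = 3, eps = c(0, 0),
                            seed = 1, tef = dtef)
  expect_equal(x_a, x_b)
  expect_equal(unname(x_a[1, ]), c(-13.7, 6.4))
  # domain errors
  dspec <- simm_spec(dup, tef = dtef)
  expect_error(simm_log_posterior(c(0.7, 0.7), c(1, 1), spec, x), "simplex")
  expect_error(simm_log_posterior(c(0.5, 0.5), c(0, 0), dspec, x),
               "degenerate variance")
})

test_that("sampler recovers the symmetric posterior mean within 3 MCSE", {
  src <- symmetric_sources()
  spec <- simm_spec(src, tef = tef_spec(c(0, 0), c(0, 0)))
  fit <- simm_fit(symmetric_consumers(), spec, chains = 2, iter = 4000,
                  burn = 1000, seed = 31)
  ess <- fit$diagnostics$ess[fit$diagnostics$parameter == "left"]
  mcse <- sd(fit$p[, "left"]) / sqrt(ess)
  expect_lt(abs(coef(fit)[["left"]] - 0.5), 3 * mcse + 1e-3)
  expect_true(all(fit$diagnostics$rhat < 1.05))
})

test_that("fits are reproducible for a fixed seed and chain settings", {
  x <- simulate_consumers(toy3_sources(), p = c(0.5, 0.3, 0.2), n = 8,
                          eps = c(0.5, 0.5), seed = 4)
  f1 <- simm_fit(x, toy3_sources(), chains = 2, iter = 1500, burn = 500,
                 seed = 77)
  f2 <- simm_fit(x, toy3_sources(), chains = 2, iter = 1500, burn = 500,
                 seed = 77)
  expect_identical(f1$p, f2$p)
  expect_identical(f1$eps, f2$eps)
})

test_that("MCMC posterior means agree with the grid oracle", {
  set.seed(5)
  x <- simulate_consumers(toy3_sources(), p = c(0.5, 0.3, 0.2), n = 10,
                          eps = c(0.5, 0.5))
  fit <- simm_fit(x, toy3_sources(), seed = 11)
  g <- simm_grid(x, toy3_sources(), resolution = 0.01)
  expect_lt(max(abs(coef(fit) - g$means)), 0.02)
  # the oracle itself is resolution-stable
  g2 <- simm_grid(x, toy3_sources(), resolution = 0.02)
  expect_lt(max(abs(g2$means - g$means)), 0.005)
  # oracle refuses unsupported dimensions
  five <- data.frame(label = letters[1:5], d13c_mean = seq(-25, -10, len = 5),
                     d13c_sd = 1, d15n_mean = seq(0, 8, len = 5), d15n_sd = 1)
  expect_error(simm_grid(x[, 1:2], five), "at most 4")
})

test_that("posterior reverts to the Dirichlet prior mean without data", {
  empty <- matrix(numeric(0), 0, 2)
  fit <- simm_fit(empty, toy3_sources(), chains = 2, iter = 6000,
                  burn = 1000, seed = 13)
  expect_lt(max(abs(coef(fit) - 1 / 3)), 0.02)
  # asymmetric prior
  fit2 <- simm_fit(empty, toy3_sources(), prior_alpha = c(4, 2, 2),
                   chains = 2, iter = 6000, burn = 1000, seed = 13)
  expect_lt(max(abs(coef(fit2) - c(0.5, 0.25, 0.25))), 0.02)
})

test_that("source order permutation permutes the posterior identically", {
  set.seed(6)
  x <- simulate_consumers(toy3_sources(), p = c(0.6, 0.3, 0.1), n = 12,
                          eps = c(0.5, 0.5))
  perm <- c(3, 1, 2)
  # exact equivariance on the deterministic integrator
  g1 <- simm_grid(x, toy3_sources(), resolution = 0.02)
  g2 <- simm_grid(x, toy3_sources()[perm, ], resolution = 0.02)
  expect_equal(unname(g2$means), unname(g1$means[perm]), tolerance = 1e-10)
  # and within Monte-Carlo error on the sampler
  f1 <- suppressWarnings(simm_fit(x, toy3_sources(), chains = 2,
                                  iter = 4000, burn = 1500, seed = 21))
  f2 <- suppressWarnings(simm_fit(x, toy3_sources()[perm, ], chains = 2,
                                  iter = 4000, burn = 1500, seed = 21))
  expect_lt(max(abs(unname(coef(f2)) - unname(coef(f1)[perm]))), 0.05)
})

test_that("simulate_consumers obeys the forward model", {
  src <- toy3_sources()
  expect_equal(nrow(simulate_consumers(src, c(1, 0, 0), n = 0)), 0)
  # noiseless limit: every observation is exactly the shifted mixture mean
  x0 <- simulate_consumers(src, c(0, 1, 0), n = 5, eps = c(0, 0), seed = 2,
                           tef = tef_spec(c(1.3, 3.4), c(0, 0)))
  # zero sigma sources needed for an exact check: use a degenerate copy
  src0 <- src
  src0$d13c_sd <- src0$d15n_sd <- 0
  x0 <- simulate_consumers(src0, c(0, 1, 0), n = 5, eps = c(0, 0), seed = 2,
                           tef = tef_spec(c(1.3, 3.4), c(0, 0)))
  expect_true(all(x0[, 1] == -16 + 1.3) && all(x0[, 2] == 6 + 3.4))
  # law of large numbers at the default TEF
  p <- c(0.5, 0.3, 0.2)
  x <- simulate_consumers(src, p, n = 1e5, eps = c(0.4, 0.4), seed = 3)
  spec <- simm_spec(src)
  m_th <- c(sum(p * (src$d13c_mean + 1.3)), sum(p * (src$d15n_mean + 3.4)))
  v_th <- c(sum(p^2 * (src$d13c_sd^2 + 0.4^2)) + 0.16,
            sum(p^2 * (src$d15n_sd^2 + 1.0^2)) + 0.16)
  se <- sqrt(v_th / 1e5)
  expect_true(all(abs(colMeans(x) - m_th) < 3 * se))
})

test_that("pseudo-individuals reproduce the published moments exactly", {
  x <- pseudo_individuals(c(-14.7, -1.85), c(0.7, 0.6), n = 5, seed = 1)
  expect_equal(colMeans(x), c(d13c = -14.7, d15n = -1.85))
  expect_equal(apply(x, 2, sd), c(d13c = 0.7, d15n = 0.6))
  # n = 1 or zero SD collapse to the mean
  expect_equal(unname(pseudo_individuals(c(-12.8, 2.1), c(NA, NA), 1)[1, ]),
               c(-12.8, 2.1))
  x0 <- pseudo_individuals(c(-14, 1), c(0, 0.5), n = 4, seed = 2)
  expect_true(all(x0[, 1] == -14))
})

test_that("summary, coef and the other methods are mutually consistent", {
  set.seed(8)
  x <- simulate_consumers(toy3_sources(), p = c(0.5, 0.3, 0.2), n = 10,
                          eps = c(0.5, 0.5))
  fit <- simm_fit(x, toy3_sources(), chains = 2, iter = 2000, burn = 500,
                  seed = 15)
  # simplex conservation: every draw and the posterior mean sum to 1
  expect_true(all(abs(rowSums(fit$p) - 1) < 1e-10))
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-10)
  s <- summary(fit)
  expect_equal(sum(s$table$mean[1:3]), 1, tolerance = 1e-10)
  expect_named(s$table, c("parameter", "mean", "sd", "q2.5", "q50", "q97.5"))
  pr <- predict(fit)
  expect_equal(pr$mean,
               unname(colMeans(fit$data) - colMeans(residuals(fit))))
  sims <- simulate(fit, nsim = 3, seed = 1)
  expect_length(sims, 3)
  expect_equal(dim(sims[[1]]), dim(fit$data))
  # plotting runs silently on a null device
  pdf(NULL)
  on.exit(dev.off())
  expect_no_error(plot(fit))
  expect_no_error(plot(fit, type = "isospace"))
  expect_no_error(plot(fit, type = "trace"))
})

test_that("moment mode inflates the variance by sd^2/n", {
  src <- toy3_sources()
  row_mean <- c(-16, 5)
  x1 <- matrix(row_mean, 1, 2)
  spec <- simm_spec(src)
  l_plain <- simm_log_posterior(c(0.4, 0.4, 0.2), c(1, 1), spec, x1)
  l_moment <- simm_log_posterior(c(0.4, 0.4, 0.2), c(1, 1), spec, x1,
                                 extra_var = c(2^2 / 8, 1.5^2 / 8))
  expect_false(isTRUE(all.equal(l_plain, l_moment)))
  fit <- simm_fit(x1, src, chains = 2, iter = 2000, burn = 500, seed = 3,
                  extra_var = c(0.5, 0.28))
  expect_equal(sum(coef(fit)), 1, tolerance = 1e-10)
})
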