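test_that("the toy posterior matches the analytic truncated Gaussian", {
  model <- toy_model()
  post <- posterior_for(tibble::tibble(x1 = 0.5), model)
  s <- posterior_sample(post, 2000, seed = 31)
  truth <- toy_true_posterior(0.5, 0.1)
  expect_lt(abs(mean(s$theta1) - truth$mean), 0.03)
  expect_lt(abs(sd(s$theta1) - truth$sd) / truth$sd, 0.3)
  expect_true(all(s$theta1 >= 0 & s$theta1 <= 1))
})

test_that("training is reproducible and guards its preconditions", {
  ts <- make_fixture("toy-simulator", n = 600, seed = 14)
  m1 <- train_nde(ts, seed = 9, n_transforms = 2, hidden = 12,
                  max_epochs = 25, patience = 30)
  m2 <- train_nde(ts, seed = 9, n_transforms = 2, hidden = 12,
                  max_epochs = 25, patience = 30)
  probes <- tibble::tibble(theta1 = seq(0.05, 0.95, length.out = 10))
  pa <- posterior_log_prob(posterior_for(tibble::tibble(x1 = 0.4), m1),
                           probes)
  pb <- posterior_log_prob(posterior_for(tibble::tibble(x1 = 0.4), m2),
                           probes)
  expect_identical(pa, pb)
  # minimum training-set size
  small <- make_fixture("toy-simulator", n = 100, seed = 2)
  expect_error(train_nde(small), "at least")
  # constant feature column is named in the error
  bad <- make_fixture("toy-simulator", n = 600, seed = 3)
  bad$x[, 1] <- 1
  bad$standardizer$sd[1] <- 0
  expect_error(train_nde(bad, min_n = 100), "x1")
})

test_that("evaluation is amortized: new observations reuse one model", {
  model <- toy_model()
  p1 <- posterior_for(tibble::tibble(x1 = 0.2), model)
  p2 <- posterior_for(tibble::tibble(x1 = 0.8), model)
  expect_identical(p1$model, p2$model)  # no retraining happened
  m1 <- mean(posterior_sample(p1, 500, seed = 1)$theta1)
  m2 <- mean(posterior_sample(p2, 500, seed = 1)$theta1)
  expect_lt(m1, 0.5)
  expect_gt(m2, 0.5)
  # far-out-of-range features warn about misspecification
  expect_warning(posterior_for(tibble::tibble(x1 = 50), model),
                 "misspecification")
})

test_that("the joint mode lands on the analytic MAP of the toy posterior", {
  model <- toy_model()
  post <- posterior_for(tibble::tibble(x1 = 0.5), model)
  mode <- posterior_mode(post, n_samples = 4000, seed = 17)
  expect_lt(abs(mode$theta1 - 0.5), 0.03)
})

test_that("conditioning is inert for an independent product posterior", {
  model <- toy2d_model()
  post <- posterior_for(tibble::tibble(x1 = 0.5, x2 = 0.5), model)
  s <- posterior_sample(post, 2000, seed = 23)
  cond <- conditional_posterior(post, c(theta2 = 0.45), "theta1")
  g <- cond$grid[[1]]
  cmean <- sum(g * cond$density)
  csd <- sqrt(sum(g^2 * cond$density) - cmean^2)
  expect_lt(abs(cmean - mean(s$theta1)), 0.03)
  expect_lt(abs(csd - sd(s$theta1)), 0.03)
  expect_error(conditional_posterior(post, c(theta2 = 0.5),
                                     c("theta1", "theta2", "x")),
               "1 or 2")
})

test_that("conditional narrowing matches the analytic Gaussian factor", {
  post <- gaussian_posterior(rho = 0.9, sd = 0.08)
  s <- posterior_sample(post, 4000, seed = 3)
  marg_sd <- sd(s$theta1)
  cond <- conditional_posterior(post, c(theta2 = 0.5), "theta1",
                                n_grid = 200)
  g <- cond$grid[[1]]
  cmean <- sum(g * cond$density)
  csd <- sqrt(sum(g^2 * cond$density) - cmean^2)
  ratio <- csd / marg_sd
  expect_lt(abs(ratio - sqrt(1 - 0.9^2)), 0.15)
})

test_that("conditional correlations expose constraints and respect nulls", {
  # deterministic constraint theta1 + theta2 = 1
  post_c <- cached("constraint_posterior", function() {
    set.seed(33)
    n <- 4000
    z <- runif(n, 0.15, 0.85)
    theta <- tibble::tibble(theta1 = z,
                            theta2 = 1 - z + rnorm(n, 0, 0.01))
    ranges <- tibble::tibble(parameter = c("theta1", "theta2"),
                             lower = 0, upper = 1, unit = "-",
                             description = "constraint toy")
    ts <- build_training_set(theta,
                             features = tibble::tibble(x1 = rnorm(n)),
                             ranges = ranges)
    model <- train_nde(ts, seed = 6, n_transforms = 3, hidden = 24,
                       max_epochs = 150, patience = 15)
    posterior_for(tibble::tibble(x1 = 0), model)
  })
  cc <- conditional_corr_matrix(post_c, n_conditionals = 20,
                                n_points = 50, n_grid = 50, seed = 2)
  expect_lt(cc$mean_r["theta1", "theta2"], -0.8)
  expect_equal(diag(cc$mean_r), c(theta1 = 1, theta2 = 1))
  # independent product posterior: no significant conditional correlation
  post_i <- posterior_for(tibble::tibble(x1 = 0.5, x2 = 0.5), toy2d_model())
  cci <- conditional_corr_matrix(post_i, n_conditionals = 20,
                                 n_points = 50, n_grid = 50, seed = 2)
  expect_lt(abs(cci$mean_r["theta1", "theta2"]), 0.25)
})

test_that("sensitivity scores rank narrow directions above flat ones", {
  post <- cached("aniso_posterior", function() {
    set.seed(41)
    n <- 4000
    theta <- tibble::tibble(theta1 = 0.5 + 0.01 * rnorm(n),
                            theta2 = 0.5 + 0.1 * rnorm(n))
    stopifnot(all(theta >= 0 & theta <= 1))
    ranges <- tibble::tibble(parameter = c("theta1", "theta2"),
                             lower = 0, upper = 1, unit = "-",
                             description = "anisotropic toy")
    ts <- build_training_set(theta,
                             features = tibble::tibble(x1 = rnorm(n)),
                             ranges = ranges)
    model <- train_nde(ts, seed = 8, n_transforms = 3, hidden = 24,
                       max_epochs = 150, patience = 15)
    posterior_for(tibble::tibble(x1 = 0), model)
  })
  sc <- sensitivity_scores(post, n_samples = 200, seed = 5)
  expect_equal(sc$parameter[which.max(sc$score)], "theta1")
  expect_lt(sc$score[sc$parameter == "theta2"], 0.5)
})

test_that("posterior-predictive checks pass at truth and fail far away", {
  model <- toy_model()
  ok <- ppc_check(model, list(theta1 = 0.5), seed = 1,
                  features = tibble::tibble(x1 = 0.5))
  expect_true(ok$pass)
  expect_true(all(ok$univariate$ratio >= 0.5))
  bad <- ppc_check(model, list(theta1 = 0.05), seed = 1,
                   features = tibble::tibble(x1 = 0.95))
  expect_false(bad$pass)
})

test_that("parameter recovery error matches its uniform-marginal values", {
  ranges <- tibble::tibble(parameter = "theta1", lower = 0, upper = 1,
                           unit = "-", description = "toy")
  set.seed(12)
  u <- tibble::tibble(theta1 = runif(20000))
  mid <- parameter_recovery_error(u, list(theta1 = 0.5), ranges)
  expect_equal(mid$pre, 0.25, tolerance = 0.01)
  edge <- parameter_recovery_error(u, list(theta1 = 0), ranges)
  expect_equal(edge$pre, 0.5, tolerance = 0.01)
  point <- parameter_recovery_error(
    tibble::tibble(theta1 = rep(0.3, 100)), list(theta1 = 0.3), ranges)
  expect_equal(point$pre, 0)
})

test_that("simulation-based calibration ranks are uniform on the toy model", {
  model <- toy_model()
  set.seed(55)
  n_rep <- 100
  L <- 100
  ranks <- vapply(seq_len(n_rep), function(i) {
    theta_star <- runif(1)
    x_o <- theta_star + rnorm(1, 0, 0.1)
    post <- suppressWarnings(
      posterior_for(tibble::tibble(x1 = x_o), model))
    s <- posterior_sample(post, L)$theta1
    sum(s < theta_star)
  }, numeric(1))
  u <- (ranks + runif(n_rep)) / (L + 1)
  expect_gt(ks.test(u, "punif")$p.value, 0.01)
})

test_that("tidy and glance summarize posteriors and models", {
  model <- toy_model()
  post <- posterior_for(tibble::tibble(x1 = 0.3), model)
  td <- tidy(post, n_samples = 500, seed = 2)
  expect_identical(td$parameter, "theta1")
  expect_true(td$q05 < td$median && td$median < td$q95)
  gl <- glance(model)
  expect_identical(gl$n_train, 5000L)
  expect_identical(gl$n_parameters, 1L)
  expect_true(is.finite(gl$val_nll))
})
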