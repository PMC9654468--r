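test_that("shrinkage has the closed linear-credibility form", {
  comp <- manual_components(mu = 0, sigma2_b = 1, sigma2_w = 1)
  expect_equal(shrink_mean(2, 1, comp), 1.0)     # factor 1/(1+1)
  expect_equal(shrink_mean(2, 0, comp), 0)       # no data -> population mean

  comp0 <- manual_components(mu = 3, sigma2_b = 0, sigma2_w = 1)
  expect_equal(shrink_mean(c(-5, 0, 7), c(1, 2, 3), comp0), rep(3, 3))

  compL <- manual_components(mu = 1, sigma2_b = 0.5, sigma2_w = 0.5)
  expect_lt(abs(shrink_mean(4, 1e6, compL) - 4), 1e-5)
})

test_that("shrinkage contracts toward the mean and preserves order", {
  set.seed(21)
  comp <- manual_components(mu = 2, sigma2_b = 0.3, sigma2_w = 0.7)
  xbar <- rnorm(200, 2, 1)
  n <- sample(1:3, 200, replace = TRUE)
  t <- shrink_mean(xbar, n, comp)
  expect_true(all(abs(t - 2) <= abs(xbar - 2) + 1e-12))
  expect_lt(var(t), var(xbar))
  # strictly increasing in xbar for fixed n
  xs <- sort(rnorm(50))
  expect_true(all(diff(shrink_mean(xs, 2, comp)) > 0))
})

test_that("consumption probability shrinks toward the pooled fraction", {
  expect_equal(consumption_probability(1, 2, p_bar = 0.5, m = 2), 0.5)
  # all-consumers: pooled fraction 1 makes every estimate exactly 1
  expect_equal(consumption_probability(c(1, 2), c(1, 2), p_bar = 1, m = 1e6),
               c(1, 1))
  # daily variables bypass estimation
  comp <- manual_components(episodic = FALSE)
  expect_equal(consumption_probability(c(0, 1), c(2, 2), comp), c(1, 1))
  expect_error(consumption_probability(0, 0, p_bar = 0.5, m = 1),
               "at least one")
})

test_that("beta-binomial shrinkage beats the raw fraction on beta(2,2) truth", {
  set.seed(4)
  n <- 500
  sim <- simulate_intake_days(n, days = 2, episodic = TRUE,
                              p_shape1 = 2, p_shape2 = 2)
  c_i <- tapply(sim$days$value, sim$days$participant_id,
                function(v) sum(v > 0))
  n_i <- tapply(sim$days$value, sim$days$participant_id, length)
  ids <- names(c_i)
  truth <- sim$truth$p_consume[match(ids, sim$truth$participant_id)]
  comp <- fit_intake_components(sim$days, episodic = TRUE)
  p_hat <- consumption_probability(as.numeric(c_i), as.numeric(n_i), comp)
  mae_shrunk <- mean(abs(p_hat - truth))
  mae_raw <- mean(abs(as.numeric(c_i) / as.numeric(n_i) - truth))
  expect_lt(mae_shrunk, mae_raw)
})

test_that("Box-Cox profile likelihood matches an independent oracle", {
  skip_if_not_installed("MASS")
  set.seed(7)
  df <- data.frame(x = exp(rnorm(300, 2, 0.5)))
  x <- df$x
  grid <- c(0, 0.25, 1/3, 0.5, 1)
  sel <- select_lambda(x, grid = grid)
  bc <- MASS::boxcox(x ~ 1, data = df, lambda = grid, plotit = FALSE)
  expect_equal(sel$lambda, bc$x[which.max(bc$y)])
  # log-normal data prefer the log transform
  expect_equal(sel$lambda, 0)
  # profile shapes agree up to an additive constant
  d <- sel$loglik - bc$y
  expect_lt(diff(range(d)), 1e-6)
})

test_that("variance components recover simulated truth", {
  set.seed(12)
  sim <- simulate_intake_days(1000, days = 2, mu_log = log(30),
                              sigma_b = 0.4, sigma_w = 0.6)
  comp <- fit_intake_components(sim$days)
  expect_equal(comp$lambda, 0)
  expect_lt(abs(comp$sigma2_b - 0.16) / 0.16, 0.25)
  expect_lt(abs(comp$sigma2_w - 0.36) / 0.36, 0.15)
  expect_lt(abs(comp$mu - log(30)), 0.1)
})

test_that("shifting one participant on the transformed scale moves only the between component", {
  set.seed(5)
  days <- data.frame(participant_id = rep(sprintf("P%02d", 1:40), each = 2),
                     value = 50 + rnorm(80, 0, 3))
  f0 <- fit_intake_components(days, lambda_grid = 1)
  days2 <- days
  shift <- days2$participant_id == "P01"
  days2$value[shift] <- days2$value[shift] + 10
  f1 <- fit_intake_components(days2, lambda_grid = 1)
  expect_equal(f1$sigma2_w, f0$sigma2_w)
  expect_gt(f1$sigma2_b, f0$sigma2_b)
})

test_that("degenerate and unidentifiable inputs raise the documented errors", {
  days_const <- data.frame(participant_id = rep(1:10, each = 2), value = 5)
  expect_error(fit_intake_components(days_const), "within-person variance")
  fl <- fit_intake_components(days_const, sigma_w_floor = 1e-8)
  expect_equal(fl$sigma2_w, 1e-8)

  days_single <- data.frame(participant_id = 1:10, value = exp(rnorm(10)))
  expect_error(fit_intake_components(days_single), "unidentifiable")

  days_zero <- data.frame(participant_id = rep(1:5, each = 2),
                          value = c(0, exp(rnorm(9))))
  expect_error(fit_intake_components(days_zero), "episodic")
})

test_that("a linear transform back-transforms the shrunken mean without bias correction", {
  set.seed(8)
  b <- rep(rnorm(50, 0, 3), each = 2)
  days <- data.frame(participant_id = rep(sprintf("Q%02d", 1:50), each = 2),
                     value = 20 + b + rnorm(100, 0, 2))
  comp <- fit_intake_components(days, lambda_grid = 1)
  expect_gt(comp$sigma2_b, 0)
  ui <- usual_intake(days, comp)
  xbar <- tapply(box_cox(days$value, 1), days$participant_id, mean)
  t_i <- shrink_mean(as.numeric(xbar[ui$participant_id]), 2, comp)
  # lambda = 1 is affine: curvature (and hence the Taylor correction) is
  # zero and the inverse transform just undoes the unit shift
  expect_equal(ui$usual_amount, box_cox_inv(t_i, 1), tolerance = 1e-12)
  expect_equal(ui$usual, ui$p_consume * ui$usual_amount)
  # shrunken usual amounts vary across participants and contract the spread
  expect_gt(stats::var(ui$usual_amount), 0)
  expect_lt(stats::var(ui$usual_amount), stats::var(as.numeric(xbar)))
})

test_that("usual intake tracks the habitual truth better than a single day", {
  set.seed(31)
  sim <- simulate_intake_days(500, days = 2, mu_log = log(25),
                              sigma_b = 0.4, sigma_w = 0.6)
  comp <- fit_intake_components(sim$days)
  ui <- usual_intake(sim$days, comp)
  truth <- sim$truth$true_usual[match(ui$participant_id,
                                      sim$truth$participant_id)]
  day1 <- sim$days$value[sim$days$day_index == 1]
  day1 <- day1[match(ui$participant_id,
                     sim$days$participant_id[sim$days$day_index == 1])]
  expect_gt(cor(ui$usual, truth, method = "spearman"),
            cor(day1, truth, method = "spearman"))
  expect_true(all(ui$usual >= 0))
})

test_that("zero-consumers get the population fallback scaled by a small probability", {
  set.seed(14)
  sim <- simulate_intake_days(400, days = 2, episodic = TRUE,
                              p_shape1 = 2, p_shape2 = 2)
  comp <- fit_intake_components(sim$days, episodic = TRUE)
  ui <- usual_intake(sim$days, comp)
  zc <- ui[ui$n_consuming == 0, ]
  expect_gt(nrow(zc), 0)
  expect_true(all(zc$p_consume > 0 & zc$p_consume < 0.5))
  expect_true(all(zc$usual > 0))
  # episodic usual = p * amount everywhere
  expect_equal(ui$usual, pmax(ui$p_consume * ui$usual_amount, 0))
})

test_that("estimate_usual handles several variables at once", {
  set.seed(16)
  s1 <- simulate_intake_days(120, days = 2, sigma_b = 0.4, sigma_w = 0.5)
  s2 <- simulate_intake_days(120, days = 2, episodic = TRUE,
                             p_shape1 = 5, p_shape2 = 2)
  dl <- rbind(cbind(s1$days, variable = "a"),
              cbind(s2$days, variable = "b"))
  est <- estimate_usual(dl, episodic = "b")
  expect_named(est$usual, c("participant_id", "a", "b"))
  expect_false(est$components$a$episodic)
  expect_true(est$components$b$episodic)
  expect_true(all(est$usual$a > 0))
})
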