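test_that("Bartlett sphericity is exactly null on an identity correlation", {
  adq <- factor_adequacy(diag(5), n = 50)
  expect_equal(adq$bartlett$chisq, 0)
  expect_equal(adq$bartlett$df, 10)
  expect_equal(adq$bartlett$p_value, 1)
})

test_that("KMO on an equicorrelated matrix matches the closed form", {
  p <- 4; r <- 0.5
  R <- matrix(r, p, p); diag(R) <- 1
  # exchangeable partial correlation: q = r / (1 + (p-2) r) = 0.25
  q <- r / (1 + (p - 2) * r)
  kmo_expected <- (p * (p - 1) * r^2) / (p * (p - 1) * r^2 +
                                           p * (p - 1) * q^2)
  adq <- factor_adequacy(R, n = 100)
  expect_equal(adq$kmo, kmo_expected, tolerance = 1e-10)
  expect_equal(unname(adq$msa), rep(kmo_expected, p), tolerance = 1e-10)
  expect_equal(kmo_expected, 0.8)
})

test_that("singular correlation matrices are rejected with advice", {
  R <- matrix(1, 3, 3)
  expect_error(factor_adequacy(R, 10), "singular")
})

test_that("planted two-factor structure is recovered", {
  set.seed(41)
  L <- matrix(0, 6, 2)
  L[1:3, 1] <- 0.8; L[4:6, 2] <- 0.8
  rownames(L) <- paste0("g", 1:6)
  sim <- simulate_pattern_grams(500, L)
  model <- extract_patterns(sim$grams, msa_cut = NULL)
  expect_equal(model$retained_k, 2)
  cg <- factor_congruence(L, model$loadings)
  expect_true(all(cg$matched > 0.9))
  # all sampling adequacies healthy on structured data
  expect_true(all(model$msa > 0.5))
})

test_that("eigenvalue bookkeeping satisfies the trace identity", {
  set.seed(43)
  sim <- simulate_pattern_grams(300, default_pattern_model()$loadings)
  model <- extract_patterns(sim$grams, msa_cut = NULL)
  p <- length(model$variables)
  expect_lt(abs(sum(model$eigenvalues) - p), 1e-8)
  # percentage variance over ALL components sums to 100
  expect_equal(sum(model$eigenvalues) / p * 100, 100, tolerance = 1e-8)
  expect_true(all(diff(model$eigenvalues) <= 1e-12))
})

test_that("rotation preserves communalities and total retained variance", {
  set.seed(47)
  sim <- simulate_pattern_grams(400, default_pattern_model()$loadings)
  X <- sim$grams
  R <- stats::cor(X)
  eig <- eigen(R, symmetric = TRUE)
  k <- sum(eig$values > 1)
  L_unrot <- eig$vectors[, 1:k] %*% diag(sqrt(eig$values[1:k]))
  model <- extract_patterns(X, msa_cut = NULL)
  expect_equal(model$retained_k, k)
  expect_equal(rowSums(model$loadings^2), unname(rowSums(L_unrot^2)),
               tolerance = 1e-8, ignore_attr = TRUE)
  expect_equal(sum(model$pct_variance),
               sum(eig$values[1:k]) / ncol(X) * 100, tolerance = 1e-8)
})

test_that("varimax leaves an already-simple structure essentially unchanged", {
  set.seed(53)
  L <- matrix(0, 8, 2)
  L[1:4, 1] <- c(0.9, 0.85, 0.8, 0.75)
  L[5:8, 2] <- c(0.9, 0.85, 0.8, 0.75)
  rownames(L) <- paste0("g", 1:8)
  sim <- simulate_pattern_grams(800, L)
  R <- stats::cor(sim$grams)
  eig <- eigen(R, symmetric = TRUE)
  model <- extract_patterns(sim$grams, msa_cut = NULL)
  # rotated loadings recover the planted simple structure directly
  cg <- factor_congruence(L, model$loadings)
  expect_true(all(cg$matched > 0.98))
})

test_that("regression scores are centred, bounded and zero at the centroid", {
  set.seed(59)
  sim <- simulate_pattern_grams(400, default_pattern_model()$loadings)
  X <- sim$grams
  # plant participant 1 exactly at the variable means: setting the row to
  # the mean of the others makes it the overall column mean too
  X[1, ] <- colMeans(X[-1, , drop = FALSE])
  model <- extract_patterns(X, msa_cut = NULL)
  expect_true(all(abs(colMeans(model$scores)) < 1e-8))
  expect_true(all(apply(model$scores, 2, stats::var) <= 1 + 1e-8))
  expect_true(all(abs(model$scores[1, ]) < 1e-6))
  # scores correlate strongly with the planted factor truth
  cg <- abs(stats::cor(model$scores, sim$scores))
  expect_true(all(apply(cg, 2, max) > 0.8))
})

test_that("pattern_scores reproduces the model's own scores", {
  set.seed(61)
  sim <- simulate_pattern_grams(200, default_pattern_model()$loadings)
  model <- extract_patterns(sim$grams, msa_cut = NULL)
  S <- pattern_scores(model, sim$grams)
  expect_equal(unname(S), unname(model$scores), tolerance = 1e-10)
  expect_error(pattern_scores(model, sim$grams[, 1:3]), "lack model variables")
})

test_that("attribution assigns each food group to at most one factor", {
  L <- rbind(c(0.84, 0.30), c(0.10, 0.15), c(0.5, -0.5), c(-0.35, 0.1))
  rownames(L) <- c("a", "b", "c", "d")
  expect_message(att <- attribute_loadings(L), "tie")
  expect_equal(att$factor[att$variable == "a"], 1L)
  expect_true(is.na(att$factor[att$variable == "b"]))
  expect_equal(att$factor[att$variable == "c"], 1L)   # tie -> lowest index
  # negative loadings keep their sign in the report
  expect_equal(att$loading[att$variable == "d"], -0.35)
  expect_equal(att$factor[att$variable == "d"], 1L)
  # threshold is strict
  L2 <- matrix(c(0.2, 0.1), 1, 2)
  expect_true(is.na(attribute_loadings(L2)$factor))
})

test_that("zero-variance columns are dropped with a message", {
  set.seed(67)
  X <- cbind(matrix(rnorm(300), 100, 3), dead = 1)
  colnames(X) <- c("a", "b", "c", "dead")
  expect_message(model <- extract_patterns(X, msa_cut = NULL),
                 "zero-variance")
  expect_false("dead" %in% model$variables)
  expect_match(model$dropped, "dead", all = FALSE)
})

test_that("factor sign convention puts the dominant variable positive", {
  set.seed(71)
  sim <- simulate_pattern_grams(300, default_pattern_model()$loadings)
  model <- extract_patterns(sim$grams, msa_cut = NULL)
  for (j in seq_len(model$retained_k)) {
    expect_gt(model$loadings[which.max(abs(model$loadings[, j])), j], 0)
  }
})
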