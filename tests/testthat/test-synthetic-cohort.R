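test_that("generation is deterministic under a fixed seed", {
  a <- generate_cohort(cohort_spec(n_participants = 40, seed = 5))
  b <- generate_cohort(cohort_spec(n_participants = 40, seed = 5))
  expect_identical(a$responses, b$responses)
  expect_identical(a$recalls, b$recalls)
  expect_identical(a$participants, b$participants)
  expect_identical(a$truth$participants, b$truth$participants)
  c <- generate_cohort(cohort_spec(n_participants = 40, seed = 6))
  expect_false(identical(a$recalls, c$recalls))
})

test_that("zero trait targets produce near-zero sub-score correlations", {
  tm <- default_trait_model()
  tm$rho <- 0
  co <- generate_cohort(cohort_spec(n_participants = 1000, seed = 8,
                                    trait_model = tm))
  sc <- score_cohort(dhq_default_schema(), co$responses)
  merged <- merge(sc, co$truth$true_usual, by = "participant_id")
  for (i in seq_len(nrow(tm))) {
    rho <- spearman_cor(merged[[paste0("sub_", tm$sub_score[i])]],
                        merged[[tm$variable[i]]])$rho
    expect_lt(abs(rho), 0.1)
  }
})

test_that("repeat-recall participant count sits in the binomial band", {
  co <- generate_cohort(cohort_spec(n_participants = 96, p_repeat = 0.3125,
                                    seed = 10))
  n_rep <- sum(co$participants$n_days >= 2)
  # 95% band around 30 of 96 (sd ~ 4.54)
  expect_gte(n_rep, 21)
  expect_lte(n_rep, 39)
})

test_that("generated between/within log-amount variances match the generator parameters", {
  im <- default_intake_model()
  row <- im[im$variable == "fruit_veg_serves", ]
  rel_err <- sapply(1:3, function(s) {
    co <- generate_cohort(cohort_spec(n_participants = 2000, p_repeat = 1,
                                      seed = 100 + s))
    rc <- co$recalls[co$recalls$food_code == "C_FV", ]
    lv <- log(rc$grams * 1.35 / 100)
    # person effects are known from the truth table, so the decomposition
    # of the generated log amounts is direct, not estimated
    b <- log(co$truth$true_usual$fruit_veg_serves) -
      row$mu_log - row$sigma_w^2 / 2
    names(b) <- co$truth$true_usual$participant_id
    within <- lv - row$mu_log - b[rc$participant_id]
    c(abs(stats::var(b) - row$sigma_b^2) / row$sigma_b^2,
      abs(mean(within^2) - row$sigma_w^2) / row$sigma_w^2)
  })
  expect_lt(mean(rel_err[1, ]), 0.05)
  expect_lt(mean(rel_err[2, ]), 0.05)
})

test_that("attained sub-score correlation hits the planted target at scale", {
  co <- generate_cohort(cohort_spec(n_participants = 2000, seed = 33))
  sc <- score_cohort(dhq_default_schema(), co$responses)
  # fiber path end-to-end: carrier rows -> day table -> two-part model
  rc <- co$recalls[co$recalls$food_code == "C_FIB", ]
  days <- daily_intakes(rc, co$composition)
  comp <- fit_intake_components(
    data.frame(participant_id = days$participant_id, value = days$fiber_g))
  ui <- usual_intake(
    data.frame(participant_id = days$participant_id, value = days$fiber_g),
    comp)
  merged <- merge(sc, ui, by = "participant_id")
  rho <- spearman_cor(merged$sub_fiber, merged$usual)$rho
  target <- default_trait_model()$rho[default_trait_model()$sub_score ==
                                        "fiber"]
  expect_lt(abs(rho - target), 0.05)
})

test_that("infeasible correlation targets fail with the attainable bound", {
  tm <- default_trait_model()
  tm$rho[tm$sub_score == "fiber"] <- 0.95
  expect_error(generate_cohort(cohort_spec(n_participants = 20, seed = 1,
                                           trait_model = tm)),
               "not attainable")
})

test_that("planted factor structure survives the full recall round trip", {
  co <- generate_cohort(cohort_spec(n_participants = 500, seed = 12))
  days <- daily_intakes(co$recalls, co$composition)
  first <- days[!duplicated(days$participant_id), ]
  G <- as.matrix(first[, paste0("grams_", 11:27)])
  colnames(G) <- as.character(11:27)
  model <- extract_patterns(G, msa_cut = NULL)
  cg <- factor_congruence(default_pattern_model()$loadings, model$loadings)
  expect_true(all(cg$matched > 0.9))
})

test_that("the miniature fixture carries its hand-computed values", {
  fx <- fixture_small()
  exp_v <- fx$expected
  sc <- score_cohort(dhq_default_schema(), fx$responses)
  expect_equal(sc$total[sc$participant_id == "P1"], exp_v$p1_total)
  expect_equal(sc$total[sc$participant_id == "P2"], exp_v$p2_total)
  expect_equal(sc$total[sc$participant_id == "P3"], exp_v$p3_total)

  d11 <- fx$recalls[fx$recalls$participant_id == "P1" &
                      fx$recalls$day_index == 1, c("food_code", "grams")]
  di <- day_intake(d11, fx$composition)
  expect_equal(di$discretionary_serves,
               exp_v$p1_day1_discretionary_serves)
  expect_equal(di$nutrients[["fiber_g"]], exp_v$p1_day1_fiber_g)
  expect_equal(di$group_serves[["vegetables"]] + di$group_serves[["fruits"]],
               exp_v$p1_day1_fruit_veg_serves)

  # nested composite conserves grams
  out <- deconstruct("C_MIX2", 120, fx$composition)
  expect_equal(sum(out$grams), 120)
})

test_that("cohorts round-trip through the delimited-text writers", {
  co <- generate_cohort(cohort_spec(n_participants = 25, seed = 15))
  dir <- withr::local_tempdir()
  write_cohort(co, dir)
  expect_true(all(file.exists(file.path(
    dir, c("participants.csv", "responses.csv", "recalls.csv",
           "foods.csv", "components.csv", "truth.json")))))
  tab <- read_composition(file.path(dir, "foods.csv"),
                          file.path(dir, "components.csv"))
  expect_equal(nrow(tab$foods), nrow(co$composition$foods))
  rc <- utils::read.csv(file.path(dir, "recalls.csv"))
  expect_equal(nrow(rc), nrow(co$recalls))
  expect_equal(sum(rc$grams), sum(co$recalls$grams), tolerance = 1e-9)
})
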