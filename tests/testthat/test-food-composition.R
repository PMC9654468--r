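test_that("deconstruction splits composites by mass fraction", {
  tab <- tiny_table()
  out <- deconstruct("MIX", 200, tab)
  expect_setequal(out$food_code, c("VEG", "FIB1"))
  expect_equal(sort(out$grams), c(100, 100))

  # non-composite food returns itself
  out1 <- deconstruct("VEG", 100, tab)
  expect_equal(out1$food_code, "VEG")
  expect_equal(out1$grams, 100)
})

test_that("nested deconstruction expands recursively and conserves grams", {
  foods <- data.frame(
    food_code = c("A", "B", "C", "D", "E"),
    description = letters[1:5],
    major_group_code = "11",
    energy_kj_100g = c(1000, 1000, 1000, 1000, 1000),
    discretionary = FALSE, stringsAsFactors = FALSE)
  components <- data.frame(
    parent_code = c("A", "A", "B", "B"),
    component_code = c("B", "E", "C", "D"),
    fraction = c(0.5, 0.5, 0.5, 0.5), stringsAsFactors = FALSE)
  tab <- food_table(foods, components)
  out <- deconstruct("A", 80, tab)
  got <- tapply(out$grams, out$food_code, sum)
  # hand expansion: 80 g A -> 40 g B (-> 20 g C + 20 g D) + 40 g E
  expect_equal(got[["C"]], 20)
  expect_equal(got[["D"]], 20)
  expect_equal(got[["E"]], 40)
  expect_equal(sum(out$grams), 80)
})

test_that("deconstruction errors name missing codes and detect cycles", {
  foods <- data.frame(
    food_code = c("A", "B"), description = c("a", "b"),
    major_group_code = "11", energy_kj_100g = 100,
    discretionary = FALSE, stringsAsFactors = FALSE)
  comp_missing <- data.frame(parent_code = "A",
                             component_code = "NOPE", fraction = 1)
  tab <- food_table(foods, comp_missing)
  expect_error(deconstruct("A", 10, tab), "NOPE")

  comp_cycle <- data.frame(parent_code = c("A", "B"),
                           component_code = c("B", "A"), fraction = 1)
  tab2 <- food_table(foods, comp_cycle)
  expect_error(deconstruct("A", 10, tab2), "cycle")
})

test_that("grams and energy are conserved on randomized composite tables", {
  for (seed in 1:20) {
    tab <- random_composite_table(seed)
    comps <- unique(tab$components$parent_code)
    for (code in comps) {
      grams <- runif(1, 10, 500)
      out <- deconstruct(code, grams, tab)
      expect_lt(abs(sum(out$grams) - grams) / grams, 1e-9)
      # energy is mass-consistent by fixture construction
      e_direct <- grams * tab$foods[code, "energy_kj_100g"] / 100
      e_expanded <- sum(out$grams *
                          tab$foods[out$food_code, "energy_kj_100g"] / 100)
      expect_lt(abs(e_expanded - e_direct) / e_direct, 1e-9)
    }
  }
})

test_that("day intake computes serves, nutrients and group grams", {
  tab <- tiny_table()
  # 150 g of a food where 75 g is one vegetable serve -> 2 serves
  di <- day_intake(data.frame(food_code = "VEG", grams = 150), tab)
  expect_equal(di$group_serves[["vegetables"]], 2.0)

  # empty day -> all zeros
  d0 <- day_intake(data.frame(food_code = character(),
                              grams = numeric()), tab)
  expect_equal(d0$energy_kj, 0)
  expect_true(all(unlist(d0$nutrients) == 0))
  expect_equal(d0$discretionary_serves, 0)

  # fiber additivity: densities 5 and 10 g/100 g at 100 g each -> 15 g
  df <- day_intake(data.frame(food_code = c("FIB1", "FIB2"),
                              grams = c(100, 100)), tab)
  expect_equal(df$nutrients[["fiber_g"]], 15)

  # group grams use the as-consumed food's major group (no deconstruction)
  dm <- day_intake(data.frame(food_code = "MIX", grams = 200), tab)
  expect_equal(dm$group_grams[["31"]], 200)
  # but nutrients flow through the components
  expect_equal(dm$nutrients[["fiber_g"]], 100 * 5 / 100)

  expect_error(day_intake(data.frame(food_code = "VEG", grams = -5), tab),
               "non-negative")
  expect_error(day_intake(data.frame(food_code = "ZZZ", grams = 5), tab),
               "unknown food code")
})

test_that("discretionary serves follow the 600 kJ / 10 g alcohol definition", {
  tab <- tiny_table()
  # 100 g discretionary snack at 1500 kJ/100 g -> 1500/600 = 2.5 serves
  expect_equal(discretionary_serves(
    data.frame(food_code = "DISC", grams = 100), tab), 2.5)
  # 500 g beer at 5 g alcohol/100 g -> 25 g alcohol -> 2.5 serves
  expect_equal(discretionary_serves(
    data.frame(food_code = "ALC", grams = 500), tab,
    include_alcohol = TRUE), 2.5)
  # alcohol ignored unless enabled
  expect_equal(discretionary_serves(
    data.frame(food_code = "ALC", grams = 500), tab), 0)
  # 600 kJ discretionary + 10 g alcohol -> 1 + 1 = 2 serves
  expect_equal(discretionary_serves(
    data.frame(food_code = c("DISC", "ALC"), grams = c(40, 200)), tab,
    include_alcohol = TRUE), 2.0)
})

test_that("day intake is homogeneous and additive in grams", {
  tab <- tiny_table()
  recs <- data.frame(food_code = c("VEG", "FIB1", "DISC", "MIX"),
                     grams = c(120, 80, 50, 60))
  d1 <- day_intake(recs, tab, include_alcohol = TRUE)
  recs2 <- recs; recs2$grams <- recs2$grams * 2
  d2 <- day_intake(recs2, tab, include_alcohol = TRUE)
  expect_equal(d2$energy_kj, 2 * d1$energy_kj)
  expect_equal(unlist(d2$nutrients), 2 * unlist(d1$nutrients))
  expect_equal(unlist(d2$group_serves), 2 * unlist(d1$group_serves))
  expect_equal(d2$discretionary_serves, 2 * d1$discretionary_serves)
  expect_equal(unlist(d2$group_grams), 2 * unlist(d1$group_grams))
  expect_true(all(unlist(d1$nutrients) >= 0) && d1$energy_kj >= 0)
})

test_that("daily intake table covers every participant-day", {
  fx <- fixture_small()
  days <- daily_intakes(fx$recalls, fx$composition)
  expect_equal(nrow(days), 8)  # 6 participants, two with 2 days
  expect_equal(days$discretionary_serves[days$participant_id == "P1" &
                                           days$day_index == 1], 2.0)
  expect_equal(days$discretionary_serves[days$participant_id == "P4"], 1.0)
  expect_equal(days$fiber_g[days$participant_id == "P1" &
                              days$day_index == 1], 25)
  expect_equal(days$omega3_mg[days$participant_id == "P3" &
                                days$day_index == 2], 800)
  fv <- days$serve_vegetables + days$serve_fruits
  expect_equal(fv[days$participant_id == "P1" & days$day_index == 1],
               150 * 1.35 / 100)
})

test_that("composition table validation rejects malformed inputs", {
  foods <- data.frame(food_code = "A", description = "a",
                      major_group_code = "11", energy_kj_100g = 100,
                      discretionary = FALSE)
  bad_frac <- data.frame(parent_code = "A", component_code = "A",
                         fraction = 0.7)
  expect_error(food_table(foods, bad_frac), "sum to 1")
  expect_error(food_table(foods[, -1]), "missing columns")
  foods2 <- rbind(foods, foods)
  expect_error(food_table(foods2), "duplicated")
})
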