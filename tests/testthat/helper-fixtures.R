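# In-code fixtures shared across the suite.

# minimal table: one vegetable food where 75 g is one serve, two fiber
# sources, a discretionary food, an alcoholic beverage and a composite
tiny_table <- function() {
  foods <- data.frame(
    food_code = c("VEG", "FIB1", "FIB2", "DISC", "ALC", "MIX"),
    description = c("vegetable", "fiber source 1", "fiber source 2",
                    "discretionary snack", "beer", "veg-fiber blend"),
    major_group_code = c("13", "11", "11", "29", "25", "31"),
    energy_kj_100g = c(160, 1400, 900, 1500, 350, 0.5 * 160 + 0.5 * 1400),
    discretionary = c(FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE)
  foods[["nutrient.fiber_g"]] <- c(0, 5, 10, 0, 0, 0)
  foods[["nutrient.alcohol_g"]] <- c(0, 0, 0, 0, 5, 0)
  foods[["serve.vegetables"]] <- c(100 / 75, 0, 0, 0, 0, 0)
  components <- data.frame(
    parent_code = c("MIX", "MIX"),
    component_code = c("VEG", "FIB1"),
    fraction = c(0.5, 0.5),
    stringsAsFactors = FALSE)
  food_table(foods, components)
}

# randomized composite table with a directed acyclic decomposition and
# mass-consistent energies (parent energy = fraction-weighted child energy)
random_composite_table <- function(seed, n_terminal = 5, n_composite = 4) {
  set.seed(seed)
  codes <- paste0("T", seq_len(n_terminal))
  foods <- data.frame(
    food_code = codes,
    description = paste("terminal", codes),
    major_group_code = "11",
    energy_kj_100g = round(runif(n_terminal, 100, 3000), 3),
    discretionary = FALSE,
    stringsAsFactors = FALSE)
  components <- NULL
  for (i in seq_len(n_composite)) {
    code <- paste0("X", i)
    pool <- foods$food_code
    kids <- sample(pool, min(length(pool), sample(2:4, 1)))
    fr <- runif(length(kids))
    fr <- fr / sum(fr)
    energy <- sum(fr * foods$energy_kj_100g[match(kids, foods$food_code)])
    foods <- rbind(foods, data.frame(
      food_code = code, description = paste("composite", code),
      major_group_code = "31", energy_kj_100g = energy,
      discretionary = FALSE, stringsAsFactors = FALSE))
    components <- rbind(components, data.frame(
      parent_code = code, component_code = kids, fraction = fr,
      stringsAsFactors = FALSE))
  }
  food_table(foods, components)
}

# answers vector hitting a chosen points level on every scored item
answers_at_level <- function(schema, level) {
  out <- character(0)
  for (it in schema$items) {
    eff <- if (it$reversed) 6L - it$points else it$points
    pick <- which(eff == level)
    if (length(pick) == 0L) pick <- which.min(abs(eff - level))
    out[it$item_id] <- it$categories[pick[1]]
  }
  out
}

# uniformly random valid answers for all items
random_answers <- function(schema) {
  vapply(schema$items, function(it) sample(it$categories, 1), character(1))
}

# intake_components object with prescribed values (for closed-form checks)
manual_components <- function(mu = 0, sigma2_b = 1, sigma2_w = 1,
                              lambda = 1, delta = 0, episodic = FALSE,
                              p_bar = 1, m = Inf) {
  structure(list(variable = "test", episodic = episodic, lambda = lambda,
                 delta = delta, mu = mu, sigma2_b = sigma2_b,
                 sigma2_w = sigma2_w, n_repeat = 2, p_bar = p_bar, m = m),
            class = "intake_components")
}
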