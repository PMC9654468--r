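# Synthetic cohorts with known ground truth.
#
# A latent diet-quality trait drives both questionnaire category choices and
# habitual intake levels, so target correlations between sub-scores and
# usual-intake variables can be planted; positive amounts are log-normal with
# separate between- and within-person components; episodic consumption is
# beta-distributed across people; major-food-group gram totals mix planted
# orthogonal factor scores.  Everything is reproducible under a fixed seed.

# ---------------------------------------------------------------------------
# default composition fixture (synthetic; schema mirrors a hierarchical
# national food classification with 17 major groups used for pattern analysis
# plus four extra groups hosting single-nutrient "carrier" foods)

MAJOR_GROUPS <- data.frame(
  code = as.character(11:27),
  name = c("Cereals and cereal products",
           "Fruit products and dishes",
           "Vegetable products and dishes",
           "Milk products and dishes",
           "Meat, poultry and game products and dishes",
           "Fish and seafood products and dishes",
           "Special dietary foods",
           "Legume and pulse products and dishes",
           "Seed and nut products and dishes",
           "Fats and oils",
           "Soup",
           "Sugar products and dishes",
           "Confectionery and cereal/nut/fruit/seed bars",
           "Non-alcoholic beverages",
           "Alcoholic beverages",
           "Dairy and meat substitutes",
           "Miscellaneous"),
  gram_mean = c(160, 180, 250, 220, 120, 90, 40, 80, 30, 25, 150, 40,
                35, 800, 150, 60, 20),
  energy_kj_100g = c(1400, 280, 160, 300, 800, 600, 1200, 400, 2400, 3300,
                     200, 1500, 1900, 120, 350, 350, 900),
  stringsAsFactors = FALSE)

#' Bundled synthetic composition table
#'
#' Seventeen marker foods (one per major food group used for pattern
#' analysis), six single-nutrient carrier foods in four further groups, and
#' two composite dishes with a nested decomposition.  All entries are
#' synthetic: densities and serve weights are chosen to be dietetically
#' plausible, not copied from any reference database.
#'
#' @return A `food_table`.
#' @export
default_composition <- function() {
  markers <- data.frame(
    food_code = paste0("M", MAJOR_GROUPS$code),
    description = paste0(MAJOR_GROUPS$name, " marker (synthetic)"),
    major_group_code = MAJOR_GROUPS$code,
    energy_kj_100g = MAJOR_GROUPS$energy_kj_100g,
    discretionary = FALSE,
    stringsAsFactors = FALSE)
  carriers <- data.frame(
    food_code = c("C_FIB", "C_CER", "C_FV", "C_FAT", "C_O3", "C_DISC"),
    description = c("High-bran cereal mix (synthetic)",
                    "Multigrain bread roll (synthetic)",
                    "Garden salad with fruit (synthetic)",
                    "Dressing and oil blend (synthetic)",
                    "Grilled oily fish fillet (synthetic)",
                    "Savoury pastry snack (synthetic)"),
    major_group_code = c("28", "28", "31", "30", "31", "29"),
    energy_kj_100g = c(1450, 1100, 250, 3700, 850, 1800),
    discretionary = c(FALSE, FALSE, FALSE, FALSE, FALSE, TRUE),
    stringsAsFactors = FALSE)
  composites <- data.frame(
    food_code = c("C_MIX1", "C_MIX2"),
    description = c("Vegetable pasta bake (synthetic)",
                    "Fish and salad plate (synthetic)"),
    major_group_code = c("31", "31"),
    energy_kj_100g = c(0.5 * 160 + 0.5 * 1400, 0.5 * 780 + 0.5 * 850),
    discretionary = FALSE,
    stringsAsFactors = FALSE)
  foods <- rbind(markers, carriers, composites)

  foods[["nutrient.fiber_g"]] <- 0
  foods[["nutrient.fat_total_g"]] <- 0
  foods[["nutrient.omega3_mg"]] <- 0
  foods[["nutrient.alcohol_g"]] <- 0
  foods[["serve.vegetables"]] <- 0
  foods[["serve.fruits"]] <- 0
  foods[["serve.grains"]] <- 0
  foods[["serve.milk_alt"]] <- 0
  foods[["serve.meat_alt"]] <- 0
  set <- function(code, col, value) {
    foods[foods$food_code == code, col] <<- value
  }
  set("C_FIB", "nutrient.fiber_g", 25)
  set("C_FAT", "nutrient.fat_total_g", 100)
  set("C_O3", "nutrient.omega3_mg", 1600)
  set("C_O3", "serve.meat_alt", 0.9)
  set("M25", "nutrient.alcohol_g", 5)
  set("C_CER", "serve.grains", 1.3)
  set("C_FV", "serve.vegetables", 1.0)
  set("C_FV", "serve.fruits", 0.35)
  set("M14", "serve.milk_alt", 0.4)
  set("M15", "serve.meat_alt", 0.5)

  components <- data.frame(
    parent_code = c("C_MIX1", "C_MIX1", "C_MIX2", "C_MIX2"),
    component_code = c("M13", "M11", "C_MIX1", "C_O3"),
    fraction = c(0.5, 0.5, 0.5, 0.5),
    stringsAsFactors = FALSE)
  food_table(foods, components)
}

# grams of carrier food needed to deliver one unit of each trait variable
carrier_map <- function(table) {
  f <- table$foods
  dens <- function(code, col) f[f$food_code == code, col]
  data.frame(
    variable = c("fiber_g", "fat_total_g", "omega3_mg", "cereal_serves",
                 "fruit_veg_serves", "discretionary_serves"),
    food_code = c("C_FIB", "C_FAT", "C_O3", "C_CER", "C_FV", "C_DISC"),
    grams_per_unit = c(
      100 / dens("C_FIB", "nutrient.fiber_g"),
      100 / dens("C_FAT", "nutrient.fat_total_g"),
      100 / dens("C_O3", "nutrient.omega3_mg"),
      100 / dens("C_CER", "serve.grains"),
      100 / (dens("C_FV", "serve.vegetables") + dens("C_FV", "serve.fruits")),
      100 * 600 / dens("C_DISC", "energy_kj_100g")),
    stringsAsFactors = FALSE)
}

# ---------------------------------------------------------------------------
# default model components of a cohort specification

#' Default per-variable intake model
#'
#' Log-scale means and between/within standard deviations, episodic
#' consumption-probability distributions (beta), and loadings tying each
#' variable to the latent diet-quality trait.
#'
#' @return Data frame, one row per intake variable.
#' @export
default_intake_model <- function() {
  data.frame(
    variable = c("fiber_g", "fat_total_g", "omega3_mg", "cereal_serves",
                 "fruit_veg_serves", "discretionary_serves"),
    episodic = c(FALSE, FALSE, TRUE, TRUE, FALSE, TRUE),
    mu_log = c(log(28), log(65), log(300), log(5), log(8), log(2.5)),
    sigma_b = c(0.40, 0.35, 0.80, 0.45, 0.45, 0.50),
    sigma_w = c(0.50, 0.45, 0.90, 0.55, 0.55, 0.70),
    p_shape1 = c(NA, NA, 7, 19, NA, 8.5),
    p_shape2 = c(NA, NA, 3, 1, NA, 1.5),
    p_loading = c(0, 0, 0.7, 0.3, 0, -0.4),
    b_loading = c(0.9, 0.9, 0.9, 0.9, 0.9, -0.7),
    stringsAsFactors = FALSE)
}

#' Default trait model: target sub-score / intake correlations
#'
#' Target Spearman correlations between each questionnaire sub-score and its
#' matching usual-intake variable, as planted by the generator.
#'
#' @return Data frame with columns `sub_score`, `variable`, `rho`.
#' @export
default_trait_model <- function() {
  data.frame(
    sub_score = c("cereal", "fruit_veg", "takeaway", "fiber", "fat",
                  "omega3", "food_choices", "food_preparation"),
    variable = c("cereal_serves", "fruit_veg_serves", "discretionary_serves",
                 "fiber_g", "fat_total_g", "omega3_mg", "fat_total_g",
                 "fat_total_g"),
    rho = c(0.395, 0.436, -0.25, 0.505, -0.086, 0.512, -0.10, -0.10),
    stringsAsFactors = FALSE)
}

#' Default planted dietary-pattern structure
#'
#' Five orthogonal factors over the 17 major food groups, in disjoint blocks
#' of 4/4/3/3/3 groups with primary loadings 0.8.
#'
#' @return List with `loadings` (17 x 5, rownames are group codes),
#'   `gram_mean` and `gram_sd` (named per group).
#' @export
default_pattern_model <- function() {
  blocks <- list(1:4, 5:8, 9:11, 12:14, 15:17)
  L <- matrix(0, nrow = 17, ncol = 5,
              dimnames = list(MAJOR_GROUPS$code, paste0("F", 1:5)))
  for (j in seq_along(blocks)) L[blocks[[j]], j] <- 0.8
  list(loadings = L,
       gram_mean = stats::setNames(MAJOR_GROUPS$gram_mean, MAJOR_GROUPS$code),
       gram_sd = stats::setNames(0.3 * MAJOR_GROUPS$gram_mean,
                                 MAJOR_GROUPS$code))
}

#' Specification of a synthetic cohort
#'
#' @param n_participants Cohort size.
#' @param p_repeat Probability that a participant contributes a second
#'   recall day (default 0.3125, i.e. 30 of 96 in expectation).
#' @param seed Seed controlling every random draw of [generate_cohort()].
#' @param trait_model See [default_trait_model()].
#' @param intake_model See [default_intake_model()].
#' @param pattern_model See [default_pattern_model()].
#' @param demographics List with `p_female` and age-band sampling
#'   (`age_bands` as rows of min/max, `age_probs`).
#' @return Object of class `cohort_spec`.
#' @export
cohort_spec <- function(n_participants = 96,
                        p_repeat = 0.3125,
                        seed = 1,
                        trait_model = default_trait_model(),
                        intake_model = default_intake_model(),
                        pattern_model = default_pattern_model(),
                        demographics = list(
                          p_female = 0.823,
                          age_bands = data.frame(min = c(33, 45, 65),
                                                 max = c(44, 64, 86)),
                          age_probs = c(0.208, 0.698, 0.094))) {
  stopifnot(n_participants >= 1,
            p_repeat >= 0, p_repeat <= 1,
            demographics$p_female >= 0, demographics$p_female <= 1,
            abs(sum(demographics$age_probs) - 1) < 1e-6,
            all(trait_model$rho > -1), all(trait_model$rho < 1),
            all(intake_model$sigma_b >= 0), all(intake_model$sigma_w > 0))
  missing_vars <- setdiff(trait_model$variable, intake_model$variable)
  if (length(missing_vars) > 0L) {
    stop("trait model references unknown intake variables: ",
         paste(missing_vars, collapse = ", "))
  }
  structure(list(n_participants = n_participants, p_repeat = p_repeat,
                 seed = seed, trait_model = trait_model,
                 intake_model = intake_model, pattern_model = pattern_model,
                 demographics = demographics),
            class = "cohort_spec")
}

# ---------------------------------------------------------------------------
# trait calibration: choose the item-side loading so that the end-to-end
# observable correlation (sub-score vs shrinkage-estimated usual intake under
# the cohort's recall design) hits the target

.calib_cache <- new.env(parent = emptyenv())

with_internal_rng <- function(seed, fn) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(seed)
  fn()
}

discretize5 <- function(u) {
  out <- findInterval(u, stats::qnorm(c(0.2, 0.4, 0.6, 0.8))) + 1L
  if (is.matrix(u)) dim(out) <- dim(u)
  out
}

# number of scored items per sub-score in the default schema
sub_score_sizes <- function(schema) {
  scored <- Filter(function(it) it$scored, schema$items)
  subs <- vapply(scored, `[[`, character(1), "sub_score")
  table(factor(subs, levels = SUB_SCORES))
}

calibrate_one <- function(target, J, var_row, p_repeat, n_sim = 20000L) {
  key <- paste(format(c(target, J, p_repeat,
                        var_row$mu_log, var_row$sigma_b, var_row$sigma_w,
                        var_row$p_shape1, var_row$p_shape2,
                        var_row$p_loading, var_row$b_loading,
                        as.numeric(var_row$episodic), n_sim),
                      digits = 12), collapse = "|")
  if (!is.null(.calib_cache[[key]])) return(.calib_cache[[key]])

  res <- with_internal_rng(760421L, function() {
    z <- stats::rnorm(n_sim)
    E <- matrix(stats::rnorm(n_sim * J), n_sim, J)
    eta <- stats::rnorm(n_sim)
    u_w <- stats::rnorm(n_sim)
    n_i <- 1L + stats::rbinom(n_sim, 1L, p_repeat)
    s_b <- var_row$sigma_b; s_w <- var_row$sigma_w
    b <- s_b * (var_row$b_loading * z +
                  sqrt(1 - var_row$b_loading^2) * eta)
    if (var_row$episodic) {
      xi <- stats::rnorm(n_sim)
      p_i <- stats::qbeta(stats::pnorm(var_row$p_loading * z +
                                         sqrt(1 - var_row$p_loading^2) * xi),
                          var_row$p_shape1, var_row$p_shape2)
      c_i <- stats::rbinom(n_sim, n_i, p_i)
      p_bar <- sum(c_i) / sum(n_i)
      m <- bb_prior_strength(c_i, n_i)
      p_hat <- (c_i + m * p_bar) / (n_i + m)
    } else {
      c_i <- n_i
      p_hat <- rep(1, n_sim)
    }
    pos <- c_i > 0
    xbar <- ifelse(pos, b + s_w * u_w / sqrt(pmax(c_i, 1)), 0)
    f <- ifelse(pos, s_b^2 / (s_b^2 + s_w^2 / pmax(c_i, 1)), 0)
    usual <- p_hat * exp(f * xbar)
    r_usual <- rank(usual)

    attained <- function(a) {
      S <- rowMeans(discretize5(a * z + sqrt(1 - a^2) * E))
      stats::cor(rank(S), r_usual)
    }
    lo <- -0.999; hi <- 0.999
    alo <- attained(lo); ahi <- attained(hi)
    # direction of the monotone response depends on the sign of the
    # variable's own trait loading
    increasing <- ahi >= alo
    if (target > max(alo, ahi) + 0.02 || target < min(alo, ahi) - 0.02) {
      stop("target correlation ", format(target, digits = 3),
           " is not attainable with this category ladder; attainable range ",
           "is approximately [", format(min(alo, ahi), digits = 3), ", ",
           format(max(alo, ahi), digits = 3), "]")
    }
    for (i in 1:40) {
      mid <- (lo + hi) / 2
      amid <- attained(mid)
      if (abs(amid - target) < 0.002) return(list(a = mid, attained = amid))
      if (xor(amid < target, !increasing)) lo <- mid else hi <- mid
    }
    mid <- (lo + hi) / 2
    list(a = mid, attained = attained(mid))
  })
  .calib_cache[[key]] <- res
  res
}

calibrate_trait_loadings <- function(spec, schema, n_sim = 20000L) {
  sizes <- sub_score_sizes(schema)
  rows <- lapply(seq_len(nrow(spec$trait_model)), function(i) {
    tr <- spec$trait_model[i, ]
    vr <- spec$intake_model[spec$intake_model$variable == tr$variable, ]
    cal <- calibrate_one(tr$rho, as.integer(sizes[[tr$sub_score]]), vr,
                         spec$p_repeat, n_sim = n_sim)
    data.frame(sub_score = tr$sub_score, variable = tr$variable,
               rho_target = tr$rho, loading = cal$a,
               rho_attained = cal$attained, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

# ---------------------------------------------------------------------------
# stand-alone simulators (also used directly in tests)

#' Simulate repeated recall-day values for one variable
#'
#' Log-normal positive amounts with between-person component `sigma_b` and
#' within-person component `sigma_w`; optionally episodic with per-person
#' beta-distributed consumption probabilities.
#'
#' @param n Participants.
#' @param days Recall days per participant (scalar or vector).
#' @param mu_log Log-scale population mean.
#' @param sigma_b,sigma_w Between/within log-scale standard deviations.
#' @param episodic Zero-inflate days?
#' @param p_shape1,p_shape2 Beta parameters of the per-person consumption
#'   probability (episodic only).
#' @return List with `days` (data frame `participant_id`, `day_index`,
#'   `value`) and `truth` (per participant: `b`, the person effect, and
#'   `p_consume`).
#' @export
simulate_intake_days <- function(n, days = 2, mu_log = log(30),
                                 sigma_b = 0.4, sigma_w = 0.6,
                                 episodic = FALSE,
                                 p_shape1 = 2, p_shape2 = 2) {
  n_days <- rep_len(days, n)
  ids <- sprintf("P%04d", seq_len(n))
  b <- stats::rnorm(n, 0, sigma_b)
  p <- if (episodic) stats::rbeta(n, p_shape1, p_shape2) else rep(1, n)
  rows <- lapply(seq_len(n), function(i) {
    consumed <- stats::runif(n_days[i]) < p[i]
    value <- ifelse(consumed,
                    exp(mu_log + b[i] + sigma_w * stats::rnorm(n_days[i])),
                    0)
    data.frame(participant_id = ids[i], day_index = seq_len(n_days[i]),
               value = value, stringsAsFactors = FALSE)
  })
  list(days = do.call(rbind, rows),
       truth = data.frame(participant_id = ids, b = b, p_consume = p,
                          true_usual = p * exp(mu_log + b + sigma_w^2 / 2),
                          stringsAsFactors = FALSE))
}

#' Simulate food-group gram intakes with a planted factor structure
#'
#' `grams = pmax(0, mean + sd * (F loadings' + unique noise))` with
#' orthonormal standard-normal factor scores `F`.
#'
#' @param n Participants.
#' @param loadings Variables x factors loading matrix (columns orthogonal by
#'   construction of disjoint blocks; row sums of squares <= 1).
#' @param gram_mean,gram_sd Named per-variable location and scale.
#' @return List with `grams` (n x variables) and `scores` (n x factors, the
#'   true factor scores).
#' @export
simulate_pattern_grams <- function(n, loadings,
                                   gram_mean = NULL, gram_sd = NULL) {
  L <- as.matrix(loadings)
  p <- nrow(L); k <- ncol(L)
  if (is.null(gram_mean)) gram_mean <- rep(200, p)
  if (is.null(gram_sd)) gram_sd <- 0.3 * gram_mean
  uniq <- pmax(1 - rowSums(L^2), 0.02)
  FS <- matrix(stats::rnorm(n * k), n, k)
  Y <- FS %*% t(L) + matrix(stats::rnorm(n * p), n, p) %*% diag(sqrt(uniq), p)
  G <- sweep(sweep(Y, 2, gram_sd, "*"), 2, gram_mean, "+")
  G <- pmax(G, 0)
  colnames(G) <- rownames(L)
  colnames(FS) <- colnames(L)
  list(grams = G, scores = FS)
}

# ---------------------------------------------------------------------------
# full cohort generation

#' Generate a synthetic cohort
#'
#' Produces questionnaire responses, recall records, the composition table
#' and a ground-truth table under the design encoded in the `cohort_spec`:
#' a latent diet-quality trait shifts ordinal item propensities (loadings
#' calibrated internally so that the planted sub-score/usual-intake
#' correlations are attained by the downstream pipeline), positive amounts
#' are log-normal with between/within components, episodic variables are
#' zero-inflated via beta-distributed consumption probabilities, and major
#' food-group gram totals mix planted orthogonal factor scores.
#'
#' @param spec A [cohort_spec()].
#' @return Object of class `synthetic_cohort`: `participants`, `responses`,
#'   `recalls`, `composition` (a `food_table`), `truth` (list with
#'   per-participant latent values and the calibration table) and `spec`.
#' @export
generate_cohort <- function(spec = cohort_spec()) {
  stopifnot(inherits(spec, "cohort_spec"))
  schema <- dhq_default_schema()
  calib <- calibrate_trait_loadings(spec, schema)
  set.seed(spec$seed)

  n <- spec$n_participants
  table <- default_composition()
  cmap <- carrier_map(table)

  ids <- sprintf("P%03d", seq_len(n))
  sex <- ifelse(stats::runif(n) < spec$demographics$p_female,
                "female", "male")
  band_idx <- sample.int(nrow(spec$demographics$age_bands), n, replace = TRUE,
                         prob = spec$demographics$age_probs)
  age <- floor(stats::runif(n,
                            spec$demographics$age_bands$min[band_idx],
                            spec$demographics$age_bands$max[band_idx] + 1))
  age_band <- paste0(spec$demographics$age_bands$min[band_idx], "_",
                     spec$demographics$age_bands$max[band_idx])
  n_days <- 1L + stats::rbinom(n, 1L, spec$p_repeat)
  participants <- data.frame(participant_id = ids, sex = sex, age = age,
                             age_band = age_band, n_days = n_days,
                             stringsAsFactors = FALSE)

  z <- stats::rnorm(n)

  # --- questionnaire responses -------------------------------------------
  sub_loading <- stats::setNames(calib$loading, calib$sub_score)
  resp <- list()
  for (it in schema$items) {
    if (it$scored && it$sub_score %in% names(sub_loading)) {
      a <- sub_loading[[it$sub_score]]
      lvl <- discretize5(a * z + sqrt(1 - a^2) * stats::rnorm(n))
      want <- if (it$reversed) 6L - lvl else lvl
      cat_idx <- vapply(want, function(L) which(it$points == L)[1], integer(1))
      category <- it$categories[cat_idx]
    } else {
      category <- sample(it$categories, n, replace = TRUE)
    }
    resp[[it$item_id]] <- data.frame(participant_id = ids,
                                     item_id = it$item_id,
                                     category = category,
                                     stringsAsFactors = FALSE)
  }
  responses <- do.call(rbind, resp)
  responses <- responses[order(responses$participant_id), , drop = FALSE]
  rownames(responses) <- NULL

  # --- per-variable intake amounts ---------------------------------------
  im <- spec$intake_model
  b_mat <- matrix(0, n, nrow(im), dimnames = list(ids, im$variable))
  p_mat <- matrix(1, n, nrow(im), dimnames = list(ids, im$variable))
  for (j in seq_len(nrow(im))) {
    v <- im[j, ]
    b_mat[, j] <- v$sigma_b * (v$b_loading * z +
                                 sqrt(1 - v$b_loading^2) * stats::rnorm(n))
    if (v$episodic) {
      p_mat[, j] <- stats::qbeta(
        stats::pnorm(v$p_loading * z +
                       sqrt(1 - v$p_loading^2) * stats::rnorm(n)),
        v$p_shape1, v$p_shape2)
    }
  }

  # --- planted factor structure over major-group grams -------------------
  pm <- spec$pattern_model
  L <- as.matrix(pm$loadings)
  k <- ncol(L)
  FS <- matrix(stats::rnorm(n * k), n, k,
               dimnames = list(ids, colnames(L)))
  uniq <- pmax(1 - rowSums(L^2), 0.02)

  # --- assemble recall records -------------------------------------------
  group_codes <- rownames(L)
  marker_codes <- paste0("M", group_codes)
  day_rows <- vector("list", sum(n_days))
  ri <- 0L
  for (i in seq_len(n)) {
    types <- if (n_days[i] == 2L) c("week", "weekend") else {
      sample(c("week", "weekend"), 1L, prob = c(5 / 7, 2 / 7))
    }
    for (d in seq_len(n_days[i])) {
      Yd <- as.numeric(L %*% FS[i, ]) +
        sqrt(uniq) * stats::rnorm(length(group_codes))
      grams_g <- pmax(pm$gram_mean[group_codes] +
                        pm$gram_sd[group_codes] * Yd, 0)
      keep <- grams_g > 0
      rows <- data.frame(participant_id = ids[i], day_index = d,
                         day_type = types[d],
                         food_code = marker_codes[keep],
                         grams = unname(grams_g[keep]),
                         stringsAsFactors = FALSE)
      for (j in seq_len(nrow(im))) {
        v <- im[j, ]
        if (stats::runif(1) < p_mat[i, j]) {
          amount <- exp(v$mu_log + b_mat[i, j] +
                          v$sigma_w * stats::rnorm(1))
          cm <- cmap[cmap$variable == v$variable, ]
          rows <- rbind(rows, data.frame(
            participant_id = ids[i], day_index = d, day_type = types[d],
            food_code = cm$food_code,
            grams = amount * cm$grams_per_unit,
            stringsAsFactors = FALSE))
        }
      }
      ri <- ri + 1L
      day_rows[[ri]] <- rows
    }
  }
  recalls <- do.call(rbind, day_rows)
  rownames(recalls) <- NULL

  true_usual <- sweep(exp(sweep(b_mat, 2, im$mu_log + im$sigma_w^2 / 2, "+")),
                      1, 1, "*") * p_mat
  truth <- list(
    participants = data.frame(participant_id = ids, z = z,
                              stringsAsFactors = FALSE),
    true_usual = data.frame(participant_id = ids, true_usual,
                            stringsAsFactors = FALSE, check.names = FALSE),
    factor_scores = data.frame(participant_id = ids, FS,
                               stringsAsFactors = FALSE),
    consumption_probability = data.frame(participant_id = ids, p_mat,
                                         stringsAsFactors = FALSE,
                                         check.names = FALSE),
    calibration = calib)

  structure(list(participants = participants, responses = responses,
                 recalls = recalls, composition = table, truth = truth,
                 spec = spec),
            class = "synthetic_cohort")
}

#' @export
print.synthetic_cohort <- function(x, ...) {
  cat("<synthetic_cohort>", nrow(x$participants), "participants,",
      nrow(x$recalls), "recall rows,",
      sum(x$participants$n_days >= 2), "with repeated recalls\n")
  invisible(x)
}

#' Write a cohort to delimited-text files
#'
#' Writes `participants.csv`, `responses.csv`, `recalls.csv`, `foods.csv`,
#' `components.csv` and `truth.json` into `dir` in the schemas consumed by
#' the analysis functions.
#'
#' @param cohort A `synthetic_cohort` (or the [fixture_small()] list).
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  wcsv <- function(df, name) {
    utils::write.csv(df, file.path(dir, name), row.names = FALSE,
                     quote = TRUE, fileEncoding = "UTF-8")
  }
  wcsv(cohort$participants, "participants.csv")
  wcsv(cohort$responses, "responses.csv")
  wcsv(cohort$recalls, "recalls.csv")
  wcsv(cohort$composition$foods, "foods.csv")
  wcsv(cohort$composition$components, "components.csv")
  if (!is.null(cohort$truth)) {
    jsonlite::write_json(cohort$truth, file.path(dir, "truth.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  invisible(dir)
}

# ---------------------------------------------------------------------------
# deterministic miniature fixture with hand-verifiable values

#' Miniature deterministic cohort fixture
#'
#' Six participants with handcrafted questionnaire answers and recall
#' records over the bundled synthetic composition table, designed so that
#' serve counts, discretionary energy and questionnaire totals can be
#' verified by hand (P1 answers everything at the maximum category, P2 at
#' the minimum, P3 follows a fixed mixed sheet that sums to 68 points).
#'
#' @return A list shaped like a `synthetic_cohort` (class
#'   `synthetic_cohort`), with an `expected` element of hand-computed
#'   values.
#' @export
fixture_small <- function() {
  schema <- dhq_default_schema()
  table <- default_composition()

  max_cat <- function(it) it$categories[which.max(if (it$reversed) 6L - it$points else it$points)]
  min_cat <- function(it) it$categories[which.min(if (it$reversed) 6L - it$points else it$points)]
  p3_sheet <- c(
    cereal_highfibre_breakfast_freq = "3_4_per_week",
    cereal_wholemeal_bread_freq = "6_plus_per_week",
    cereal_other_wholegrain_freq = "lt1_per_week",
    fruit_quantity = "2_plus_pieces_daily",
    vegetable_quantity = "2_3_serves",
    vegetable_types = "2_types",
    takeaway_freq = "1_2_per_week",
    pastries_sweet_biscuits_freq = "6_plus_per_week",
    salty_snack_freq = "lt1_per_week",
    legumes_freq = "1_2_per_week",
    nuts_seeds_freq = "5_per_week",
    reduced_fat_dairy_freq = "3_4_per_week",
    cooking_fat_type = "monounsat_oil",
    fish_freq = "1_2_per_week",
    processed_meat_freq = "3_4_per_week",
    spread_type = "polyunsat_margarine",
    dressing_type = "none_or_vinegar",
    cooking_sauce_type = "tomato_based",
    cooking_method = "grilled_or_stirfry",
    meat_fat_trim = "always_trim_or_no_meat",
    water_intake = "5_6_glasses",
    supplement_use = "never",
    special_diet = "no_special_diet",
    meals_out_freq = "1_2_per_week")

  resp_rows <- list()
  for (it in schema$items) {
    cats <- it$categories
    # P4/P5/P6: fixed positions on each ladder (varied but deterministic)
    resp_rows[[it$item_id]] <- data.frame(
      participant_id = paste0("P", 1:6),
      item_id = it$item_id,
      category = c(max_cat(it), min_cat(it), unname(p3_sheet[[it$item_id]]),
                   cats[min(2L, length(cats))],
                   cats[min(4L, length(cats))],
                   cats[min(3L, length(cats))]),
      stringsAsFactors = FALSE)
  }
  responses <- do.call(rbind, resp_rows)
  responses <- responses[order(responses$participant_id), , drop = FALSE]
  rownames(responses) <- NULL

  rec <- function(pid, day, type, code, grams) {
    data.frame(participant_id = pid, day_index = day, day_type = type,
               food_code = code, grams = grams, stringsAsFactors = FALSE)
  }
  recalls <- rbind(
    rec("P1", 1, "week", "C_FV", 150),
    rec("P1", 1, "week", "C_DISC", 1200 / 18),   # 1200 kJ discretionary
    rec("P1", 1, "week", "C_FIB", 100),
    rec("P1", 1, "week", "M13", 200),
    rec("P1", 2, "weekend", "C_MIX2", 120),      # nested composite
    rec("P1", 2, "weekend", "M24", 500),
    rec("P2", 1, "week", "M11", 100),
    rec("P2", 1, "week", "M13", 150),
    rec("P2", 1, "week", "C_CER", 100),
    rec("P3", 1, "week", "C_MIX1", 200),
    rec("P3", 1, "week", "C_FAT", 20),
    rec("P3", 1, "week", "M25", 150),
    rec("P3", 2, "weekend", "C_FIB", 60),
    rec("P3", 2, "weekend", "C_O3", 50),
    rec("P4", 1, "week", "M14", 250),
    rec("P4", 1, "week", "M15", 120),
    rec("P4", 1, "week", "C_DISC", 600 / 18),    # exactly one serve
    rec("P5", 1, "weekend", "M12", 150),
    rec("P5", 1, "weekend", "M22", 50),
    rec("P5", 1, "weekend", "M24", 400),
    rec("P6", 1, "week", "M21", 300))

  participants <- data.frame(
    participant_id = paste0("P", 1:6),
    sex = c("female", "male", "female", "female", "male", "female"),
    age = c(40, 50, 55, 70, 45, 38),
    age_band = c("33_44", "45_64", "45_64", "65_86", "45_64", "33_44"),
    n_days = c(2L, 1L, 2L, 1L, 1L, 1L),
    stringsAsFactors = FALSE)

  expected <- list(
    p1_total = 100, p2_total = 20, p3_total = 68,
    p3_sub_scores = c(cereal = 3, fruit_veg = 10 / 3, takeaway = 10 / 3,
                      fiber = 3, fat = 3.5, omega3 = 2.5,
                      food_choices = 4, food_preparation = 4.5),
    p1_day1_discretionary_serves = 2.0,
    p4_day1_discretionary_serves = 1.0,
    p1_day1_fruit_veg_serves = 150 * 1.35 / 100,
    p1_day1_fiber_g = 25,
    p3_day2_omega3_mg = 50 * 16)

  structure(list(participants = participants, responses = responses,
                 recalls = recalls, composition = table, truth = NULL,
                 expected = expected, spec = NULL),
            class = "synthetic_cohort")
}
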