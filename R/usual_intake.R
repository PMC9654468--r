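# Usual (habitual) intake from repeated 24-h recall day values.
#
# Two-part shrinkage model: a Box-Cox transformed amount part with
# between/within variance components estimated by unbalanced one-way
# method-of-moments ANOVA, and (for episodically consumed variables) a
# beta-binomial empirical-Bayes consumption-probability part.  Usual intake
# is the product of the shrunken back-transformed amount and the consumption
# probability.

#' Box-Cox transform
#'
#' `lambda = 0` means the natural logarithm.  `delta` is an additive offset
#' applied before transforming.
#'
#' @param x Positive values (after adding `delta`).
#' @param lambda Box-Cox exponent.
#' @param delta Offset added to `x` before transforming.
#' @return Transformed values.
#' @export
box_cox <- function(x, lambda, delta = 0) {
  y <- x + delta
  if (any(y <= 0)) stop("Box-Cox transform needs positive values (after offset)")
  if (lambda == 0) log(y) else (y^lambda - 1) / lambda
}

#' Inverse Box-Cox transform
#' @param t Transformed values.
#' @inheritParams box_cox
#' @return Values on the original scale.
#' @export
box_cox_inv <- function(t, lambda, delta = 0) {
  if (lambda == 0) exp(t) - delta else {
    base <- lambda * t + 1
    base[base < 0] <- 0
    base^(1 / lambda) - delta
  }
}

# second derivative of the inverse transform, for the Taylor bias correction
box_cox_inv_dd <- function(t, lambda) {
  if (lambda == 0) return(exp(t))
  if (lambda == 1) return(rep(0, length(t)))
  base <- lambda * t + 1
  base[base < 0] <- 0
  (1 - lambda) * base^(1 / lambda - 2)
}

#' Profile log-likelihood choice of the Box-Cox exponent
#'
#' Maximizes the normal profile log-likelihood of the transformed positive
#' amounts over a fixed exponent grid.
#'
#' @param x Positive amounts.
#' @param grid Candidate exponents; 0 means log.
#' @param delta Offset, see [box_cox()].
#' @return List with `lambda` (selected), `loglik` (per grid point, named).
#' @export
select_lambda <- function(x, grid = c(0, 0.25, 1/3, 0.5, 1), delta = 0) {
  x <- x[!is.na(x)]
  n <- length(x)
  if (n < 3L) stop("need at least 3 positive values to select lambda")
  ll <- vapply(grid, function(lam) {
    z <- box_cox(x, lam, delta)
    s2 <- mean((z - mean(z))^2)
    -n / 2 * log(s2) + (lam - 1) * sum(log(x + delta))
  }, numeric(1))
  names(ll) <- as.character(grid)
  list(lambda = grid[which.max(ll)], loglik = ll)
}

# Unbalanced one-way method-of-moments (ANOVA) variance components.
# values: transformed amounts; ids: participant labels.  Only participants
# with >= 2 values identify the within component.
mom_components <- function(values, ids) {
  ids <- as.character(ids)
  counts <- table(ids)
  rep_ids <- names(counts)[counts >= 2]
  if (length(rep_ids) < 2L) {
    stop("shrinkage is unidentifiable: need at least 2 participants with ",
         ">= 2 positive-consumption days (repeated recalls)")
  }
  keep <- ids %in% rep_ids
  v <- values[keep]
  g <- factor(ids[keep])
  k <- nlevels(g)
  n_i <- as.numeric(table(g))
  N <- sum(n_i)
  means <- tapply(v, g, mean)
  grand <- sum(n_i * means) / N
  ssw <- sum((v - means[g])^2)
  ssb <- sum(n_i * (means - grand)^2)
  msw <- ssw / (N - k)
  msb <- ssb / (k - 1)
  c_coef <- (N - sum(n_i^2) / N) / (k - 1)
  sigma2_b <- max(0, (msb - msw) / c_coef)
  list(sigma2_b = sigma2_b, sigma2_w = msw, n_repeat = k)
}

#' Fit two-part usual-intake model components for one variable
#'
#' The amount part selects a Box-Cox exponent on the positive-consumption
#' amounts, then estimates the population mean and the between- and
#' within-person variance components by unbalanced one-way method-of-moments
#' ANOVA on the repeat subsample (participants with two or more
#' positive-consumption days).  For episodic variables the probability part
#' pools consuming-day fractions and derives a beta-binomial prior strength
#' from the between-person overdispersion of those fractions.
#'
#' @param days Data frame with columns `participant_id` and `value`, one row
#'   per recall day.
#' @param episodic Is the variable episodically consumed (zero days allowed
#'   and modelled)?  Daily variables must be strictly positive.
#' @param lambda_grid Candidate Box-Cox exponents.
#' @param delta Offset, see [box_cox()].
#' @param sigma_w_floor Lower bound applied to the within-person variance;
#'   `NULL` (default) treats a zero within variance as an error.
#' @param sigma_b_floor Lower bound applied to the (zero-truncated)
#'   between-person variance.  The default `1e-8` is an order-preserving
#'   tie-break: when the method-of-moments estimate truncates to zero the
#'   shrunken values still collapse onto the population mean for all
#'   practical purposes, but the ranking of person means survives instead
#'   of degenerating to a constant.
#' @param variable Optional variable name carried in the result.
#' @return Object of class `intake_components`.
#' @export
fit_intake_components <- function(days, episodic = FALSE,
                                  lambda_grid = c(0, 0.25, 1/3, 0.5, 1),
                                  delta = 0, sigma_w_floor = NULL,
                                  sigma_b_floor = 1e-8,
                                  variable = NULL) {
  days <- as.data.frame(days, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "value") %in% names(days)))
  days$participant_id <- as.character(days$participant_id)
  days$value <- as.numeric(days$value)
  if (any(is.na(days$value))) stop("missing day values")
  if (any(days$value < 0)) stop("negative day values")
  if (!episodic && any(days$value <= 0) && delta <= 0) {
    stop("zero day values in a daily-consumed variable; mark it episodic ",
         "or supply a positive delta offset")
  }

  pos <- days[days$value > 0, , drop = FALSE]
  sel <- select_lambda(pos$value, grid = lambda_grid, delta = delta)
  z <- box_cox(pos$value, sel$lambda, delta)
  comp <- mom_components(z, pos$participant_id)
  if (comp$sigma2_w <= 0) {
    if (is.null(sigma_w_floor)) {
      stop("within-person variance is zero (identical replicates); ",
           "supply sigma_w_floor to proceed")
    }
    comp$sigma2_w <- sigma_w_floor
  } else if (!is.null(sigma_w_floor)) {
    comp$sigma2_w <- max(comp$sigma2_w, sigma_w_floor)
  }
  comp$sigma2_b <- max(comp$sigma2_b, sigma_b_floor)
  person_means <- tapply(z, pos$participant_id, mean)
  mu <- mean(person_means)

  p_bar <- 1
  m <- Inf
  if (episodic) {
    n_i <- tapply(days$value, days$participant_id, length)
    c_i <- tapply(days$value, days$participant_id, function(v) sum(v > 0))
    p_bar <- sum(c_i) / sum(n_i)
    m <- bb_prior_strength(as.numeric(c_i), as.numeric(n_i))
  }

  structure(
    list(variable = variable, episodic = episodic,
         lambda = sel$lambda, delta = delta, loglik = sel$loglik,
         mu = mu, sigma2_b = comp$sigma2_b, sigma2_w = comp$sigma2_w,
         n_repeat = comp$n_repeat, p_bar = p_bar, m = m),
    class = "intake_components")
}

# Beta-binomial prior strength by method of moments on per-person consuming
# fractions; floored at 1, capped when no overdispersion is detectable.
bb_prior_strength <- function(c_i, n_i, m_floor = 1, m_cap = 1e6) {
  p_i <- c_i / n_i
  p_bar <- sum(c_i) / sum(n_i)
  if (p_bar <= 0 || p_bar >= 1 || length(p_i) < 2L) return(m_cap)
  m1 <- mean(1 / n_i)
  if (1 - m1 <= 0) return(m_cap)  # no repeats: fraction variance uninformative
  v <- stats::var(p_i)
  rho <- (v / (p_bar * (1 - p_bar)) - m1) / (1 - m1)
  if (!is.finite(rho) || rho <= 0) return(m_cap)
  min(m_cap, max(m_floor, (1 - rho) / rho))
}

#' @export
print.intake_components <- function(x, ...) {
  cat("<intake_components>",
      if (!is.null(x$variable)) x$variable else "", "\n",
      " lambda =", format(x$lambda, digits = 3),
      " mu =", format(x$mu, digits = 4),
      " sigma2_b =", format(x$sigma2_b, digits = 4),
      " sigma2_w =", format(x$sigma2_w, digits = 4),
      " n_repeat =", x$n_repeat, "\n")
  if (x$episodic) {
    cat("  episodic: p_bar =", format(x$p_bar, digits = 3),
        " prior strength m =", format(x$m, digits = 3), "\n")
  }
  invisible(x)
}

#' Shrink a participant mean toward the population mean
#'
#' `t_i = mu + (xbar_i - mu) * sigma2_b / (sigma2_b + sigma2_w / n_i)`.
#' With `n = 0` the population mean is returned (fallback for
#' never-consumers).
#'
#' @param xbar Participant mean on the transformed scale (vectorized).
#' @param n Number of contributing days per participant.
#' @param components An `intake_components` object.
#' @return Shrunken transformed-scale values.
#' @export
shrink_mean <- function(xbar, n, components) {
  len <- max(length(xbar), length(n))
  xbar <- rep_len(xbar, len)
  n <- rep_len(n, len)
  s2b <- components$sigma2_b
  s2w <- components$sigma2_w
  t <- ifelse(n > 0,
              components$mu + (xbar - components$mu) * s2b / (s2b + s2w / n),
              components$mu)
  unname(t)
}

#' Empirical-Bayes consumption probability
#'
#' Beta-binomial shrinkage `p_i = (c_i + m * p_bar) / (n_i + m)` of the
#' per-participant consuming-day fraction toward the pooled fraction.
#'
#' @param consuming Consuming days per participant (vectorized).
#' @param days Total recall days per participant.
#' @param components An `intake_components` object, or `NULL` when `p_bar`
#'   and `m` are supplied directly.
#' @param p_bar,m Pooled fraction and prior strength overrides.
#' @return Probabilities in `[0, 1]`; identically 1 for daily variables.
#' @export
consumption_probability <- function(consuming, days, components = NULL,
                                    p_bar = NULL, m = NULL) {
  if (!is.null(components)) {
    if (!components$episodic) return(rep(1, length(consuming)))
    if (is.null(p_bar)) p_bar <- components$p_bar
    if (is.null(m)) m <- components$m
  }
  if (any(days < 1)) stop("each participant needs at least one recall day")
  if (is.infinite(m)) return(rep(p_bar, length(consuming)))
  unname((consuming + m * p_bar) / (days + m))
}

#' Usual intake for every participant of one variable
#'
#' Combines the shrunken back-transformed amount (with a second-order Taylor
#' bias correction for the curvature of the inverse transform) and the
#' consumption probability.  Usual intake is floored at zero.
#'
#' @param days Data frame with columns `participant_id`, `value` (one row
#'   per recall day).
#' @param components An `intake_components` fit, usually from
#'   [fit_intake_components()] on the same data.
#' @param bias_correction Apply the Taylor back-transform correction?
#' @return Data frame with one row per participant: `participant_id`,
#'   `n_days`, `n_consuming`, `p_consume`, `usual_amount` (per consuming
#'   day) and `usual` (= `p_consume * usual_amount`).
#' @export
usual_intake <- function(days, components, bias_correction = TRUE) {
  stopifnot(inherits(components, "intake_components"))
  days <- as.data.frame(days, stringsAsFactors = FALSE)
  days$participant_id <- as.character(days$participant_id)
  ids <- sort(unique(days$participant_id))
  n_days <- as.numeric(tapply(days$value, days$participant_id, length)[ids])
  n_cons <- as.numeric(tapply(days$value, days$participant_id,
                              function(v) sum(v > 0))[ids])
  xbar <- vapply(ids, function(pid) {
    v <- days$value[days$participant_id == pid]
    v <- v[v > 0]
    if (length(v) == 0L) NA_real_
    else mean(box_cox(v, components$lambda, components$delta))
  }, numeric(1))

  t_i <- shrink_mean(ifelse(is.na(xbar), components$mu, xbar),
                     ifelse(is.na(xbar), 0, n_cons), components)
  amount <- box_cox_inv(t_i, components$lambda, components$delta)
  if (bias_correction) {
    f <- ifelse(n_cons > 0,
                components$sigma2_b /
                  (components$sigma2_b + components$sigma2_w / pmax(n_cons, 1)),
                0)
    amount <- amount + 0.5 * box_cox_inv_dd(t_i, components$lambda) *
      components$sigma2_b * (1 - f)
  }
  amount <- pmax(amount, 0)
  p <- consumption_probability(n_cons, n_days, components)

  data.frame(participant_id = ids,
             n_days = n_days,
             n_consuming = n_cons,
             p_consume = p,
             usual_amount = amount,
             usual = pmax(p * amount, 0),
             stringsAsFactors = FALSE)
}

#' Usual intake across many variables
#'
#' @param days_long Data frame with columns `participant_id`, `day_index`,
#'   `variable`, `value` (and optionally `day_type`).
#' @param episodic Character vector of variable names treated as episodic;
#'   all others are daily-consumed.
#' @param lambda_grid,delta,sigma_w_floor,bias_correction Passed through to
#'   [fit_intake_components()] / [usual_intake()].
#' @return List with `usual` (wide data frame, participants x variables) and
#'   `components` (named list of `intake_components`).
#' @export
estimate_usual <- function(days_long, episodic = character(),
                           lambda_grid = c(0, 0.25, 1/3, 0.5, 1),
                           delta = 0, sigma_w_floor = NULL,
                           bias_correction = TRUE) {
  days_long <- as.data.frame(days_long, stringsAsFactors = FALSE)
  stopifnot(all(c("participant_id", "variable", "value") %in% names(days_long)))
  vars <- unique(as.character(days_long$variable))
  ids <- sort(unique(as.character(days_long$participant_id)))
  usual <- data.frame(participant_id = ids, stringsAsFactors = FALSE)
  components <- list()
  for (v in vars) {
    d <- days_long[days_long$variable == v, c("participant_id", "value")]
    comp <- fit_intake_components(d, episodic = v %in% episodic,
                                  lambda_grid = lambda_grid, delta = delta,
                                  sigma_w_floor = sigma_w_floor, variable = v)
    ui <- usual_intake(d, comp, bias_correction = bias_correction)
    usual[[v]] <- ui$usual[match(ids, ui$participant_id)]
    components[[v]] <- comp
  }
  list(usual = usual, components = components)
}

#' Long per-day variable table from a wide daily-intake table
#'
#' @param days_wide Output of [daily_intakes()].
#' @param variables Columns to keep as variables; default all numeric intake
#'   columns except the major-group gram columns.
#' @return Long data frame with `participant_id`, `day_index`, `day_type`,
#'   `variable`, `value`.
#' @export
intake_long <- function(days_wide, variables = NULL) {
  idc <- c("participant_id", "day_index", "day_type")
  if (is.null(variables)) {
    variables <- setdiff(names(days_wide), idc)
    variables <- variables[!grepl("^grams_", variables)]
  }
  pieces <- lapply(variables, function(v) {
    data.frame(participant_id = days_wide$participant_id,
               day_index = days_wide$day_index,
               day_type = days_wide$day_type,
               variable = v,
               value = days_wide[[v]],
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  out
}
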