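# Questionnaire scoring: 24 items, 20 scored, eight sub-scores on a 1-5
# scale, totals on 20-100, cohort-relative quartiles.

SUB_SCORES <- c("cereal", "fruit_veg", "takeaway", "fiber",
                "fat", "omega3", "food_choices", "food_preparation")

#' Read a questionnaire scoring schema
#'
#' The schema is a JSON document describing each item: its ordered category
#' codes, the 1-5 points assigned to each category, whether the score ladder
#' is reversed (discretionary items), and which of the eight sub-scores the
#' item feeds.  The schema is data, not code: a different scoring proforma
#' with the same shape can be dropped in.
#'
#' @param path Path to a schema JSON file.
#' @return An object of class `dhq_schema` (list of item definitions).
#' @export
read_dhq_schema <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = FALSE)
  items <- lapply(raw$items, function(it) {
    list(item_id = it$item_id,
         class = it$class,
         sub_score = if (is.null(it$sub_score)) NA_character_ else it$sub_score,
         scored = isTRUE(it$scored),
         reversed = isTRUE(it$reversed),
         categories = vapply(it$categories, as.character, character(1)),
         points = vapply(it$points, as.integer, integer(1)))
  })
  names(items) <- vapply(items, `[[`, character(1), "item_id")
  schema <- structure(list(name = raw$name, items = items), class = "dhq_schema")
  validate_dhq_schema(schema)
  schema
}

#' Default bundled scoring schema
#' @return A `dhq_schema` object.
#' @export
dhq_default_schema <- function() {
  read_dhq_schema(system.file("extdata", "dhq_schema.json",
                              package = "dhqvalidate", mustWork = TRUE))
}

validate_dhq_schema <- function(schema) {
  items <- schema$items
  if (length(items) != 24L) {
    stop("schema must define 24 items, got ", length(items))
  }
  scored <- Filter(function(it) it$scored, items)
  if (length(scored) != 20L) {
    stop("schema must mark exactly 20 items as scored, got ", length(scored))
  }
  for (it in items) {
    if (length(it$categories) != length(it$points)) {
      stop("item ", it$item_id, ": categories and points differ in length")
    }
    if (anyDuplicated(it$categories)) {
      stop("item ", it$item_id, ": duplicated category codes")
    }
    if (min(it$points) != 1L || max(it$points) != 5L) {
      stop("item ", it$item_id, ": points must attain both 1 and 5")
    }
    if (any(it$points < 1L | it$points > 5L)) {
      stop("item ", it$item_id, ": points outside 1..5")
    }
    if (it$scored && !(it$sub_score %in% SUB_SCORES)) {
      stop("item ", it$item_id, ": unknown sub-score '", it$sub_score, "'")
    }
  }
  subs <- vapply(scored, `[[`, character(1), "sub_score")
  missing_subs <- setdiff(SUB_SCORES, subs)
  if (length(missing_subs) > 0L) {
    stop("sub-scores with no scored items: ",
         paste(missing_subs, collapse = ", "))
  }
  invisible(schema)
}

#' @export
print.dhq_schema <- function(x, ...) {
  n_scored <- sum(vapply(x$items, `[[`, logical(1), "scored"))
  cat("<dhq_schema>", x$name, "-", length(x$items), "items,",
      n_scored, "scored,", length(SUB_SCORES), "sub-scores\n")
  invisible(x)
}

#' Score one item response
#'
#' Returns the points the schema assigns to the chosen category; for reversed
#' (discretionary) items the ladder is flipped as `6 - points`.
#'
#' @param item One item definition from a `dhq_schema`.
#' @param category Category code chosen by the participant.
#' @return Integer points in 1..5.
#' @export
score_item <- function(item, category) {
  idx <- match(as.character(category), item$categories)
  if (is.na(idx)) {
    stop("item ", item$item_id, ": unknown category '", category,
         "'; valid codes: ", paste(item$categories, collapse = ", "))
  }
  p <- item$points[idx]
  if (item$reversed) 6L - p else p
}

#' Score one participant
#'
#' @param schema A `dhq_schema`.
#' @param answers Named character vector (or single-participant data frame
#'   with columns `item_id`, `category`) mapping item ids to category codes.
#' @param missing Policy for unanswered scored items: `"reject"` (error) or
#'   `"prorate"` (total rescaled by 20/answered; sub-scores averaged over
#'   answered items).
#' @return List with `item_points` (named integer), `sub_scores` (named
#'   numeric, 1-5 scale), `total` (20-100) and `n_answered`.
#' @export
score_participant <- function(schema, answers,
                              missing = c("reject", "prorate")) {
  missing <- match.arg(missing)
  if (is.data.frame(answers)) {
    answers <- stats::setNames(as.character(answers$category),
                               as.character(answers$item_id))
  }
  scored_items <- Filter(function(it) it$scored, schema$items)
  pts <- stats::setNames(rep(NA_integer_, length(scored_items)),
                         vapply(scored_items, `[[`, character(1), "item_id"))
  for (it in scored_items) {
    if (it$item_id %in% names(answers) && !is.na(answers[[it$item_id]])) {
      pts[it$item_id] <- score_item(it, answers[[it$item_id]])
    }
  }
  n_answered <- sum(!is.na(pts))
  if (n_answered < length(pts) && missing == "reject") {
    stop("unanswered scored items: ",
         paste(names(pts)[is.na(pts)], collapse = ", "))
  }
  if (n_answered == 0L) stop("no scored items answered")

  subs <- vapply(scored_items, `[[`, character(1), "sub_score")
  sub_scores <- vapply(SUB_SCORES, function(s) {
    v <- pts[subs == s]
    mean(v, na.rm = TRUE)
  }, numeric(1))
  total <- sum(pts, na.rm = TRUE) * length(pts) / n_answered

  list(item_points = pts, sub_scores = sub_scores,
       total = total, n_answered = n_answered)
}

#' Score a cohort of questionnaire responses
#'
#' @param schema A `dhq_schema`.
#' @param responses Long data frame with columns `participant_id`,
#'   `item_id`, `category`.
#' @param missing Missing-answer policy, see [score_participant()].
#'   With `"reject"`, participants with unanswered scored items are dropped
#'   (listed in the `rejected` attribute) rather than aborting the cohort.
#' @return Data frame with one row per participant: `participant_id`, one
#'   `sub_<name>` column per sub-score, `total` and `n_answered`.
#' @export
score_cohort <- function(schema, responses, missing = c("reject", "prorate")) {
  missing <- match.arg(missing)
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  by_pid <- split(responses, as.character(responses$participant_id))
  rejected <- character()
  rows <- list()
  for (pid in names(by_pid)) {
    res <- tryCatch(
      score_participant(schema, by_pid[[pid]], missing = missing),
      error = function(e) e)
    if (inherits(res, "error")) {
      rejected <- c(rejected, pid)
      next
    }
    row <- data.frame(participant_id = pid, stringsAsFactors = FALSE)
    for (s in SUB_SCORES) row[[paste0("sub_", s)]] <- res$sub_scores[[s]]
    row$total <- res$total
    row$n_answered <- res$n_answered
    rows[[pid]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "rejected") <- rejected
  out
}

#' Assign cohort-relative quartiles of the total score
#'
#' Cut points are the 25/50/75 linear-interpolation sample quantiles
#' (`stats::quantile` type 7).  Values at or below a cut point go to the
#' lower quartile, so Q1 is the lowest diet quality and Q4 the highest.
#'
#' @param totals Numeric vector of total scores (length >= 4).
#' @return Integer vector of quartile indices 1..4.
#' @export
assign_quartiles <- function(totals) {
  totals <- as.numeric(totals)
  if (length(totals) < 4L) stop("need at least 4 participants for quartiles")
  if (any(is.na(totals))) stop("missing total scores")
  cuts <- stats::quantile(totals, probs = c(0.25, 0.5, 0.75), type = 7,
                          names = FALSE)
  1L + (totals > cuts[1]) + (totals > cuts[2]) + (totals > cuts[3])
}
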