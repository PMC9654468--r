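# Food composition tables, composite deconstruction and per-day intake totals.
#
# Conventions: all densities are per 100 g of food as eaten; serve weights are
# dietary-guideline serves contributed per 100 g of food, so that per-day
# quantities are linear in grams consumed.

#' Construct a food composition table
#'
#' Builds the lookup object used by [day_intake()] and [deconstruct()] from a
#' food data frame and an optional composite-ingredient table.
#'
#' @param foods Data frame with columns `food_code`, `description`,
#'   `major_group_code`, `energy_kj_100g`, `discretionary` (logical or 0/1),
#'   plus any number of nutrient density columns named `nutrient.<name>`
#'   (amount per 100 g) and serve-weight columns named `serve.<group>`
#'   (guideline serves contributed per 100 g) for the five guideline groups
#'   `vegetables`, `fruits`, `grains`, `milk_alt`, `meat_alt`.
#' @param components Optional data frame with columns `parent_code`,
#'   `component_code`, `fraction` describing composite foods.  Mass fractions
#'   must sum to 1 per parent (tolerance `1e-9`).  A composite food's serve
#'   weights are derived through its components, so its own `serve.*` entries
#'   must be zero or absent.
#' @return An object of class `food_table`.
#' @export
food_table <- function(foods, components = NULL) {
  required <- c("food_code", "description", "major_group_code",
                "energy_kj_100g", "discretionary")
  missing_cols <- setdiff(required, names(foods))
  if (length(missing_cols) > 0L) {
    stop("composition table is missing columns: ",
         paste(missing_cols, collapse = ", "))
  }
  foods <- as.data.frame(foods, stringsAsFactors = FALSE)
  foods$food_code <- as.character(foods$food_code)
  foods$major_group_code <- as.character(foods$major_group_code)
  foods$discretionary <- as.logical(foods$discretionary)
  if (anyDuplicated(foods$food_code)) {
    stop("duplicated food_code entries in composition table")
  }
  nutrient_cols <- grep("^nutrient\\.", names(foods), value = TRUE)
  serve_cols <- grep("^serve\\.", names(foods), value = TRUE)
  for (cc in c("energy_kj_100g", nutrient_cols, serve_cols)) {
    foods[[cc]] <- as.numeric(foods[[cc]])
    foods[[cc]][is.na(foods[[cc]])] <- 0
    if (any(foods[[cc]] < 0)) stop("negative density in column ", cc)
  }
  rownames(foods) <- foods$food_code

  if (!is.null(components) && nrow(components) > 0L) {
    components <- as.data.frame(components, stringsAsFactors = FALSE)
    comp_required <- c("parent_code", "component_code", "fraction")
    if (!all(comp_required %in% names(components))) {
      stop("components table needs columns: ",
           paste(comp_required, collapse = ", "))
    }
    components$parent_code <- as.character(components$parent_code)
    components$component_code <- as.character(components$component_code)
    components$fraction <- as.numeric(components$fraction)
    if (any(components$fraction < 0 | components$fraction > 1)) {
      stop("component mass fractions must lie in [0, 1]")
    }
    sums <- tapply(components$fraction, components$parent_code, sum)
    bad <- names(sums)[abs(sums - 1) > 1e-9]
    if (length(bad) > 0L) {
      stop("component mass fractions do not sum to 1 for: ",
           paste(bad, collapse = ", "))
    }
    unknown_parent <- setdiff(components$parent_code, foods$food_code)
    if (length(unknown_parent) > 0L) {
      stop("components reference unknown parent food_code: ",
           paste(unknown_parent, collapse = ", "))
    }
    # composites must not carry their own serve weights
    if (length(serve_cols) > 0L) {
      parents <- unique(components$parent_code)
      own <- rowSums(foods[parents, serve_cols, drop = FALSE])
      if (any(own > 0)) {
        stop("composite foods must not carry serve weights directly: ",
             paste(parents[own > 0], collapse = ", "))
      }
    }
  } else {
    components <- data.frame(parent_code = character(),
                             component_code = character(),
                             fraction = numeric(),
                             stringsAsFactors = FALSE)
  }

  structure(
    list(foods = foods,
         components = components,
         nutrient_cols = nutrient_cols,
         serve_cols = serve_cols),
    class = "food_table"
  )
}

#' Read a composition table from delimited text
#'
#' @param foods_csv Path to the foods CSV (schema as in [food_table()]).
#' @param components_csv Optional path to the composite-ingredient CSV with
#'   columns `parent_code`, `component_code`, `fraction`.
#' @return A `food_table` object.
#' @export
read_composition <- function(foods_csv, components_csv = NULL) {
  foods <- utils::read.csv(foods_csv, stringsAsFactors = FALSE,
                           check.names = FALSE, fileEncoding = "UTF-8")
  components <- NULL
  if (!is.null(components_csv) && file.exists(components_csv)) {
    components <- utils::read.csv(components_csv, stringsAsFactors = FALSE,
                                  check.names = FALSE, fileEncoding = "UTF-8")
  }
  food_table(foods, components)
}

#' @export
print.food_table <- function(x, ...) {
  cat("<food_table>", nrow(x$foods), "foods,",
      nrow(x$components), "component links,",
      length(x$nutrient_cols), "nutrients,",
      length(x$serve_cols), "serve groups\n")
  invisible(x)
}

is_composite <- function(code, table) {
  code %in% table$components$parent_code
}

lookup_food <- function(code, table) {
  if (!code %in% rownames(table$foods)) {
    stop("unknown food code: ", code)
  }
  table$foods[code, , drop = FALSE]
}

#' Deconstruct a composite food into terminal ingredients
#'
#' Recursively expands a food into its terminal (non-composite) ingredients
#' by mass fraction.  Grams are conserved exactly: the returned grams sum to
#' the input grams.
#'
#' @param food_code Food code to expand.
#' @param grams Grams consumed (>= 0).
#' @param table A `food_table`.
#' @return Data frame with columns `food_code` and `grams`, one row per
#'   terminal ingredient (a non-composite food returns itself).
#' @export
deconstruct <- function(food_code, grams, table) {
  stopifnot(inherits(table, "food_table"))
  if (!is.finite(grams) || grams < 0) stop("grams must be non-negative")
  out <- deconstruct_rec(as.character(food_code), grams, table, character())
  rownames(out) <- NULL
  out
}

deconstruct_rec <- function(code, grams, table, path) {
  if (code %in% path) {
    stop("cycle in composite decomposition at food code: ", code)
  }
  if (!code %in% rownames(table$foods)) {
    stop("unknown food code: ", code)
  }
  if (!is_composite(code, table)) {
    return(data.frame(food_code = code, grams = grams,
                      stringsAsFactors = FALSE))
  }
  comp <- table$components[table$components$parent_code == code, , drop = FALSE]
  pieces <- lapply(seq_len(nrow(comp)), function(i) {
    deconstruct_rec(comp$component_code[i], grams * comp$fraction[i],
                    table, c(path, code))
  })
  do.call(rbind, pieces)
}

#' Nutrient, serve and gram totals for one participant-day
#'
#' Nutrient totals and guideline-group serves are computed on deconstructed
#' (terminal) foods; major-food-group gram totals are aggregated on the foods
#' as reported, without deconstruction.  Discretionary serves combine energy
#' from discretionary-flagged terminal foods (600 kJ per serve) and,
#' optionally, ethanol mass (10 g per serve) read from the `nutrient.alcohol_g`
#' density column.
#'
#' @param records Data frame with columns `food_code` and `grams` for one
#'   participant-day (zero rows allowed).
#' @param table A `food_table`.
#' @param include_alcohol Count alcohol serves (10 g ethanol each) in
#'   `discretionary_serves`?  Default `FALSE`.
#' @return A list of class `day_intake` with elements `energy_kj`,
#'   `nutrients` (named numeric), `group_serves` (named numeric, guideline
#'   groups), `discretionary_serves`, `alcohol_g` and `group_grams` (named by
#'   `major_group_code`).
#' @export
day_intake <- function(records, table, include_alcohol = FALSE) {
  stopifnot(inherits(table, "food_table"))
  nutrient_names <- sub("^nutrient\\.", "", table$nutrient_cols)
  serve_names <- sub("^serve\\.", "", table$serve_cols)
  empty <- structure(
    list(energy_kj = 0,
         nutrients = stats::setNames(numeric(length(nutrient_names)), nutrient_names),
         group_serves = stats::setNames(numeric(length(serve_names)), serve_names),
         discretionary_serves = 0,
         alcohol_g = 0,
         group_grams = stats::setNames(numeric(0), character(0))),
    class = "day_intake")
  if (is.null(records) || nrow(records) == 0L) return(empty)

  records <- as.data.frame(records, stringsAsFactors = FALSE)
  records$food_code <- as.character(records$food_code)
  records$grams <- as.numeric(records$grams)
  if (any(!is.finite(records$grams)) || any(records$grams < 0)) {
    stop("grams must be non-negative")
  }
  unknown <- setdiff(records$food_code, rownames(table$foods))
  if (length(unknown) > 0L) {
    stop("unknown food code: ", paste(unique(unknown), collapse = ", "))
  }

  # terminal (deconstructed) rows for nutrient / serve / discretionary work
  terminal <- do.call(rbind, lapply(seq_len(nrow(records)), function(i) {
    deconstruct(records$food_code[i], records$grams[i], table)
  }))
  tf <- table$foods[terminal$food_code, , drop = FALSE]
  w <- terminal$grams / 100

  energy_kj <- sum(w * tf$energy_kj_100g)
  nutrients <- stats::setNames(numeric(length(nutrient_names)), nutrient_names)
  for (i in seq_along(table$nutrient_cols)) {
    nutrients[i] <- sum(w * tf[[table$nutrient_cols[i]]])
  }
  group_serves <- stats::setNames(numeric(length(serve_names)), serve_names)
  for (i in seq_along(table$serve_cols)) {
    group_serves[i] <- sum(w * tf[[table$serve_cols[i]]])
  }
  disc_energy <- sum(w * tf$energy_kj_100g * as.numeric(tf$discretionary))
  alcohol_g <- if ("nutrient.alcohol_g" %in% table$nutrient_cols) {
    sum(w * tf[["nutrient.alcohol_g"]])
  } else 0
  disc_serves <- disc_energy / 600 + if (include_alcohol) alcohol_g / 10 else 0

  # as-consumed major-group grams (no deconstruction)
  gg <- tapply(records$grams, table$foods[records$food_code, "major_group_code"], sum)
  group_grams <- stats::setNames(as.numeric(gg), names(gg))

  structure(
    list(energy_kj = energy_kj,
         nutrients = nutrients,
         group_serves = group_serves,
         discretionary_serves = disc_serves,
         alcohol_g = alcohol_g,
         group_grams = group_grams),
    class = "day_intake")
}

#' Discretionary serves for one participant-day
#'
#' One discretionary serve is 600 kJ from discretionary-flagged foods; one
#' alcohol serve is 10 g ethanol.  Discretionary attribution happens after
#' composite deconstruction, at the terminal-food level.
#'
#' @inheritParams day_intake
#' @return Serves per day (numeric scalar).
#' @export
discretionary_serves <- function(records, table, include_alcohol = FALSE) {
  day_intake(records, table, include_alcohol = include_alcohol)$discretionary_serves
}

#' Per-day intake table for a whole recall file
#'
#' Applies [day_intake()] to every participant-day of a long recall table and
#' returns one wide row per day: energy, nutrient columns (named as in the
#' composition table), `serve_<group>` columns, `discretionary_serves` and
#' `grams_<major_group_code>` columns.
#'
#' @param recalls Data frame with columns `participant_id`, `day_index`,
#'   optionally `day_type`, `food_code`, `grams`.
#' @param table A `food_table`.
#' @param include_alcohol Passed to [day_intake()].
#' @return Wide data frame with one row per participant-day.
#' @export
daily_intakes <- function(recalls, table, include_alcohol = FALSE) {
  stopifnot(inherits(table, "food_table"))
  recalls <- as.data.frame(recalls, stringsAsFactors = FALSE)
  needed <- c("participant_id", "day_index", "food_code", "grams")
  if (!all(needed %in% names(recalls))) {
    stop("recall table needs columns: ", paste(needed, collapse = ", "))
  }
  if (!"day_type" %in% names(recalls)) recalls$day_type <- NA_character_
  recalls$participant_id <- as.character(recalls$participant_id)

  key <- interaction(recalls$participant_id, recalls$day_index, drop = TRUE)
  days <- split(recalls, key)
  group_codes <- sort(unique(table$foods$major_group_code))
  rows <- lapply(days, function(d) {
    di <- day_intake(d[, c("food_code", "grams")], table,
                     include_alcohol = include_alcohol)
    grams <- stats::setNames(numeric(length(group_codes)),
                             paste0("grams_", group_codes))
    got <- di$group_grams
    if (length(got) > 0L) grams[paste0("grams_", names(got))] <- got
    out <- data.frame(participant_id = d$participant_id[1],
                      day_index = d$day_index[1],
                      day_type = d$day_type[1],
                      energy_kj = di$energy_kj,
                      stringsAsFactors = FALSE)
    for (nm in names(di$nutrients)) out[[nm]] <- di$nutrients[[nm]]
    for (nm in names(di$group_serves)) out[[paste0("serve_", nm)]] <- di$group_serves[[nm]]
    out$discretionary_serves <- di$discretionary_serves
    for (nm in names(grams)) out[[nm]] <- grams[[nm]]
    out
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$participant_id, out$day_index), , drop = FALSE]
  rownames(out) <- NULL
  out
}
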