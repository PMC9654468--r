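# End-to-end orchestration: input validation, stage execution, report
# assembly.  All tabular I/O is UTF-8 CSV; configuration round-trips through
# JSON.

#' Build a run configuration
#'
#' @param recalls,responses,foods Paths to the recall, questionnaire and
#'   composition CSV files.
#' @param components Optional path to the composite-ingredient CSV.
#' @param participants Optional path to a demographics CSV
#'   (`participant_id`, `sex`, `age_band`).
#' @param schema Optional path to a scoring-schema JSON; `NULL` uses the
#'   bundled default.
#' @param out_dir Output directory.
#' @param episodic Variables treated as episodically consumed.
#' @param lambda_grid Box-Cox exponent grid for the usual-intake model.
#' @param include_alcohol Count alcohol serves in discretionary serves?
#' @param missing_policy Questionnaire missing-answer policy
#'   (`"reject"`/`"prorate"`).
#' @param normality_alpha Shapiro-Wilk gate threshold in `(0, 1)`.
#' @param eigen_cut,msa_cut,loading_cut Pattern-analysis thresholds.
#' @param pca_groups Major-group codes entering the pattern analysis;
#'   `NULL` uses every group present.
#' @param sigma_w_floor Optional floor for the within-person variance.
#' @param seed Seed recorded with the run (the pipeline itself is
#'   deterministic).
#' @return Object of class `run_config`.
#' @export
run_config <- function(recalls, responses, foods, components = NULL,
                       participants = NULL, schema = NULL,
                       out_dir = "dhq_output",
                       episodic = c("omega3_mg", "cereal_serves",
                                    "discretionary_serves"),
                       lambda_grid = c(0, 0.25, 1/3, 0.5, 1),
                       include_alcohol = FALSE,
                       missing_policy = "reject",
                       normality_alpha = 0.05,
                       eigen_cut = 1, msa_cut = 0.5, loading_cut = 0.2,
                       pca_groups = as.character(11:27),
                       sigma_w_floor = NULL,
                       seed = 1L) {
  cfg <- list(recalls = recalls, responses = responses, foods = foods,
              components = components, participants = participants,
              schema = schema, out_dir = out_dir, episodic = episodic,
              lambda_grid = lambda_grid, include_alcohol = include_alcohol,
              missing_policy = missing_policy,
              normality_alpha = normality_alpha, eigen_cut = eigen_cut,
              msa_cut = msa_cut, loading_cut = loading_cut,
              pca_groups = pca_groups, sigma_w_floor = sigma_w_floor,
              seed = as.integer(seed))
  validate_run_config(cfg)
  structure(cfg, class = "run_config")
}

validate_run_config <- function(cfg) {
  chk <- function(ok, field, what) {
    if (!ok) stop("invalid config field '", field, "': ", what, call. = FALSE)
  }
  chk(is.character(cfg$recalls) && length(cfg$recalls) == 1L,
      "recalls", "must be a single path")
  chk(is.character(cfg$responses) && length(cfg$responses) == 1L,
      "responses", "must be a single path")
  chk(is.character(cfg$foods) && length(cfg$foods) == 1L,
      "foods", "must be a single path")
  chk(is.numeric(cfg$normality_alpha) && cfg$normality_alpha > 0 &&
        cfg$normality_alpha < 1, "normality_alpha", "must lie in (0, 1)")
  chk(is.numeric(cfg$eigen_cut) && cfg$eigen_cut >= 0,
      "eigen_cut", "must be >= 0")
  chk(is.null(cfg$msa_cut) ||
        (is.numeric(cfg$msa_cut) && cfg$msa_cut >= 0 && cfg$msa_cut <= 1),
      "msa_cut", "must lie in [0, 1] or be null")
  chk(is.numeric(cfg$loading_cut) && cfg$loading_cut >= 0 &&
        cfg$loading_cut <= 1, "loading_cut", "must lie in [0, 1]")
  chk(cfg$missing_policy %in% c("reject", "prorate"),
      "missing_policy", "must be 'reject' or 'prorate'")
  chk(is.numeric(cfg$lambda_grid) && length(cfg$lambda_grid) >= 1L,
      "lambda_grid", "must be a non-empty numeric vector")
  invisible(cfg)
}

#' Read a run configuration from JSON
#' @param path Path to a JSON file whose fields match [run_config()].
#' @return A `run_config` object.
#' @export
read_run_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- names(formals(run_config))
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0L) {
    stop("invalid config field '", unknown[1], "': unknown field",
         call. = FALSE)
  }
  do.call(run_config, raw)
}

#' Write a run configuration to JSON
#' @param cfg A `run_config`.
#' @param path Output path.
#' @export
write_run_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE, null = "null")
  invisible(path)
}

#' Validate pipeline inputs and build the exclusion table
#'
#' A valid recall day has at least one food record and positive total
#' energy.  Participants with no valid day are excluded; participants whose
#' scored questionnaire items are incomplete are excluded under the
#' `"reject"` policy.  Days that are invalid for a participant who also has
#' a valid day are dropped (the participant is kept as a 1-recall
#' participant).
#'
#' @param recalls Recall data frame (`participant_id`, `day_index`,
#'   `food_code`, `grams`).
#' @param responses Questionnaire response data frame.
#' @param schema A `dhq_schema`.
#' @param table A `food_table`.
#' @param missing_policy Questionnaire missing-answer policy.
#' @return List with `exclusions` (data frame `participant_id`, `reason`),
#'   `valid_days` (participant/day pairs kept), `unknown_codes`,
#'   `analysis_ids`.
#' @export
validate_inputs <- function(recalls, responses, schema, table,
                            missing_policy = "reject") {
  recalls <- as.data.frame(recalls, stringsAsFactors = FALSE)
  responses <- as.data.frame(responses, stringsAsFactors = FALSE)
  recalls$participant_id <- as.character(recalls$participant_id)
  responses$participant_id <- as.character(responses$participant_id)

  unknown_codes <- setdiff(unique(recalls$food_code),
                           rownames(table$foods))
  if (length(unknown_codes) > 0L) {
    stop("unknown food code: ", paste(unknown_codes, collapse = ", "))
  }

  key <- interaction(recalls$participant_id, recalls$day_index, drop = TRUE)
  day_energy <- vapply(split(recalls, key), function(d) {
    day_intake(d[, c("food_code", "grams")], table)$energy_kj
  }, numeric(1))
  day_info <- do.call(rbind, lapply(split(recalls, key), function(d) {
    data.frame(participant_id = d$participant_id[1],
               day_index = d$day_index[1], stringsAsFactors = FALSE)
  }))
  day_info$energy_kj <- day_energy
  day_info$valid <- day_info$energy_kj > 0

  all_ids <- sort(union(unique(recalls$participant_id),
                        unique(responses$participant_id)))
  valid_by_id <- tapply(day_info$valid, day_info$participant_id, sum)

  scored_ids <- vapply(Filter(function(it) it$scored, schema$items),
                       `[[`, character(1), "item_id")
  answered <- tapply(responses$item_id, responses$participant_id,
                     function(x) sum(scored_ids %in% x))

  exclusions <- list()
  for (pid in all_ids) {
    nv <- valid_by_id[pid]
    if (is.na(nv) || nv == 0L) {
      exclusions[[pid]] <- data.frame(participant_id = pid,
                                      reason = "no_valid_recall",
                                      stringsAsFactors = FALSE)
      next
    }
    na <- answered[pid]
    if ((is.na(na) || na < length(scored_ids)) &&
        missing_policy == "reject") {
      exclusions[[pid]] <- data.frame(participant_id = pid,
                                      reason = "incomplete_questionnaire",
                                      stringsAsFactors = FALSE)
    }
  }
  exclusions <- if (length(exclusions) > 0L) {
    do.call(rbind, exclusions)
  } else {
    data.frame(participant_id = character(), reason = character(),
               stringsAsFactors = FALSE)
  }
  rownames(exclusions) <- NULL
  analysis_ids <- setdiff(all_ids, exclusions$participant_id)
  valid_days <- day_info[day_info$valid &
                           day_info$participant_id %in% analysis_ids,
                         c("participant_id", "day_index")]
  rownames(valid_days) <- NULL
  list(exclusions = exclusions, valid_days = valid_days,
       unknown_codes = unknown_codes, analysis_ids = analysis_ids)
}

# variables with enough repeated positive days to identify the shrinkage
usable_variables <- function(days_long) {
  vars <- unique(days_long$variable)
  ok <- vapply(vars, function(v) {
    d <- days_long[days_long$variable == v & days_long$value > 0, ]
    if (nrow(d) < 3L) return(FALSE)
    counts <- table(d$participant_id)
    sum(counts >= 2) >= 2 && length(unique(d$value)) >= 3
  }, logical(1))
  vars[ok]
}

#' Run the full analysis pipeline
#'
#' Stage order: input validation and exclusions; per-day serve/nutrient
#' calculation; questionnaire scoring and quartiles; usual-intake
#' estimation; construct-validity and internal-consistency statistics;
#' dietary-pattern extraction from single-day (first valid recall)
#' major-group grams.  Every stage writes its tabular output under
#' `cfg$out_dir`; a plain-text summary indexes the stages.  Re-running with
#' unchanged inputs and configuration rewrites byte-identical outputs.
#'
#' @param cfg A `run_config`.
#' @return The report (list) invisibly: `exclusions`, `days`, `scores`,
#'   `usual`, `components`, `validity`, `patterns`, `files`.
#' @export
run_pipeline <- function(cfg) {
  stopifnot(inherits(cfg, "run_config"))
  set.seed(cfg$seed)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  log_path <- file.path(cfg$out_dir, "pipeline.log")
  logf <- function(stage, ...) {
    cat(sprintf("[%s] %s\n", stage, paste0(...)), file = log_path,
        append = TRUE)
  }
  cat("", file = log_path)  # truncate

  schema <- if (is.null(cfg$schema)) dhq_default_schema() else
    read_dhq_schema(cfg$schema)
  table <- read_composition(cfg$foods, cfg$components)
  recalls <- utils::read.csv(cfg$recalls, stringsAsFactors = FALSE,
                             fileEncoding = "UTF-8")
  responses <- utils::read.csv(cfg$responses, stringsAsFactors = FALSE,
                               fileEncoding = "UTF-8")
  demographics <- if (!is.null(cfg$participants)) {
    utils::read.csv(cfg$participants, stringsAsFactors = FALSE,
                    fileEncoding = "UTF-8")
  } else NULL

  # --- stage: validation --------------------------------------------------
  val <- validate_inputs(recalls, responses, schema, table,
                         missing_policy = cfg$missing_policy)
  logf("validate", nrow(val$exclusions), " participants excluded; ",
       length(val$analysis_ids), " in analysis set")
  utils::write.csv(val$exclusions, file.path(cfg$out_dir, "exclusions.csv"),
                   row.names = FALSE)

  recalls$participant_id <- as.character(recalls$participant_id)
  keep_key <- paste(val$valid_days$participant_id, val$valid_days$day_index)
  recalls <- recalls[paste(recalls$participant_id, recalls$day_index) %in%
                       keep_key, , drop = FALSE]

  # --- stage: serves / nutrients -----------------------------------------
  days <- daily_intakes(recalls, table, include_alcohol = cfg$include_alcohol)
  days$fruit_veg_serves <- days$serve_vegetables + days$serve_fruits
  days$cereal_serves <- days$serve_grains
  logf("serves", nrow(days), " participant-days computed")
  utils::write.csv(days, file.path(cfg$out_dir, "daily_intakes.csv"),
                   row.names = FALSE)

  # --- stage: questionnaire scoring --------------------------------------
  responses <- responses[responses$participant_id %in% val$analysis_ids, ]
  scores <- score_cohort(schema, responses, missing = cfg$missing_policy)
  scores$quartile <- assign_quartiles(scores$total)
  logf("score", nrow(scores), " participants scored; median total ",
       format(stats::median(scores$total), digits = 4))
  utils::write.csv(scores, file.path(cfg$out_dir, "dhq_scores.csv"),
                   row.names = FALSE)

  # --- stage: usual intake ------------------------------------------------
  days_long <- intake_long(days)
  vars <- usable_variables(days_long)
  skipped <- setdiff(unique(days_long$variable), vars)
  if (length(skipped) > 0L) {
    logf("usual", "skipped (insufficient repeated positive days): ",
         paste(skipped, collapse = ", "))
  }
  # a configured-daily variable with observed zero days is demoted to
  # episodic rather than aborting the stage
  has_zero <- vapply(vars, function(v) {
    any(days_long$value[days_long$variable == v] <= 0)
  }, logical(1))
  episodic <- union(cfg$episodic, vars[has_zero])
  demoted <- setdiff(intersect(vars[has_zero], vars), cfg$episodic)
  if (length(demoted) > 0L) {
    logf("usual", "treated as episodic (zero days observed): ",
         paste(demoted, collapse = ", "))
  }
  est <- estimate_usual(days_long[days_long$variable %in% vars, ],
                        episodic = episodic,
                        lambda_grid = cfg$lambda_grid,
                        sigma_w_floor = cfg$sigma_w_floor)
  logf("usual", length(vars), " variables modelled")
  utils::write.csv(est$usual, file.path(cfg$out_dir, "usual_intake.csv"),
                   row.names = FALSE)
  comp_json <- lapply(est$components, function(cc) {
    cc <- unclass(cc)
    cc$m <- if (is.infinite(cc$m)) "Inf" else cc$m
    cc$loglik <- NULL
    cc
  })
  jsonlite::write_json(comp_json,
                       file.path(cfg$out_dir, "usual_components.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)

  # --- stage: psychometrics ----------------------------------------------
  pairs <- data.frame(
    component = c("total", "total", "total", "cereal", "fruit_veg",
                  "takeaway", "fiber", "fat", "omega3"),
    variable = c("cereal_serves", "fruit_veg_serves", "fiber_g",
                 "cereal_serves", "fruit_veg_serves", "discretionary_serves",
                 "fiber_g", "fat_total_g", "omega3_mg"),
    stringsAsFactors = FALSE)
  pairs <- pairs[pairs$variable %in% names(est$usual), , drop = FALSE]
  rep_v <- validity_report(scores, est$usual, pairs,
                           demographics = demographics,
                           normality_alpha = cfg$normality_alpha)
  logf("psychometrics", nrow(rep_v$pairs), " validity pairs; alpha_std ",
       format(rep_v$alpha$alpha_standardized, digits = 4))
  utils::write.csv(rep_v$pairs, file.path(cfg$out_dir, "validity_pairs.csv"),
                   row.names = FALSE)
  if (!is.null(rep_v$trend)) {
    utils::write.csv(rep_v$trend,
                     file.path(cfg$out_dir, "quartile_trends.csv"),
                     row.names = FALSE)
  }
  jsonlite::write_json(
    list(pairs = rep_v$pairs, alpha = rep_v$alpha, trend = rep_v$trend,
         group_tests = rep_v$group_tests),
    file.path(cfg$out_dir, "validity.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null",
    na = "null", force = TRUE)

  # --- stage: dietary patterns -------------------------------------------
  first_day <- days[!duplicated(days$participant_id), , drop = FALSE]
  gram_cols <- grep("^grams_", names(first_day), value = TRUE)
  if (!is.null(cfg$pca_groups)) {
    gram_cols <- intersect(paste0("grams_", cfg$pca_groups), gram_cols)
  }
  G <- as.matrix(first_day[, gram_cols, drop = FALSE])
  colnames(G) <- sub("^grams_", "", colnames(G))
  rownames(G) <- first_day$participant_id
  patterns <- extract_patterns(G, eigen_cut = cfg$eigen_cut,
                               msa_cut = cfg$msa_cut,
                               loading_cut = cfg$loading_cut)
  logf("patterns", patterns$retained_k, " factors retained; ",
       format(sum(patterns$pct_variance), digits = 4),
       " % variance explained")
  loadings_df <- data.frame(food_group = rownames(patterns$loadings),
                            patterns$loadings, check.names = FALSE)
  utils::write.csv(loadings_df,
                   file.path(cfg$out_dir, "pattern_loadings.csv"),
                   row.names = FALSE)
  utils::write.csv(data.frame(participant_id = rownames(patterns$scores),
                              patterns$scores, check.names = FALSE),
                   file.path(cfg$out_dir, "pattern_scores.csv"),
                   row.names = FALSE)
  utils::write.csv(patterns$scree, file.path(cfg$out_dir, "scree.csv"),
                   row.names = FALSE)
  jsonlite::write_json(
    list(kmo = patterns$kmo, msa = as.list(patterns$msa),
         bartlett = patterns$bartlett, retained_k = patterns$retained_k,
         pct_variance = patterns$pct_variance,
         attribution = patterns$attribution, dropped = patterns$dropped),
    file.path(cfg$out_dir, "pattern_adequacy.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE, na = "null")

  # --- summary ------------------------------------------------------------
  summary_lines <- c(
    "dhqvalidate pipeline summary",
    "============================",
    paste0("participants in analysis set: ", length(val$analysis_ids)),
    paste0("participants excluded: ", nrow(val$exclusions)),
    paste0("participant-days: ", nrow(days)),
    paste0("median total score: ",
           format(stats::median(scores$total), digits = 6)),
    paste0("usual-intake variables: ", length(vars)),
    paste0("standardized Cronbach alpha: ",
           format(rep_v$alpha$alpha_standardized, digits = 6)),
    paste0("retained dietary patterns: ", patterns$retained_k),
    paste0("variance explained by retained patterns (%): ",
           format(sum(patterns$pct_variance), digits = 6)))
  writeLines(summary_lines, file.path(cfg$out_dir, "summary.txt"))

  report <- list(exclusions = val$exclusions, days = days, scores = scores,
                 usual = est$usual, components = est$components,
                 validity = rep_v, patterns = patterns,
                 files = list.files(cfg$out_dir))
  invisible(report)
}
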