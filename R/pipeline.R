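#' Validate a pipeline configuration
#'
#' A pipeline config is a named list (or a YAML/JSON file) with either a
#' `simulate` block (arguments to [study_config()]) or input paths
#' (`responses_from`, `responses_to`, `item_meta_from`, `item_meta_to`), plus
#' options: `selection` (logical, default `TRUE`), `linking_method`,
#' `equating_method`, `alpha`, `anchor_ratio`, `norm_levels`, `out_dir`,
#' `seed`. All schema violations are reported at once.
#'
#' @param config A named list, or a path to a YAML or JSON file.
#' @return A tibble of violations (`field`, `problem`); zero rows when valid.
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- read_pipeline_config(config)
  v <- list()
  add <- function(field, problem) v[[length(v) + 1]] <<- tibble(field = field, problem = problem)
  if (!is.list(config)) {
    return(tibble(field = "(root)", problem = "config must be a named list"))
  }
  has_sim <- !is.null(config$simulate)
  paths <- c("responses_from", "responses_to")
  if (!has_sim) {
    for (p in paths) {
      if (is.null(config[[p]])) add(p, "required when no `simulate` block is given")
      else if (!file.exists(config[[p]])) add(p, paste0("file not found: ", config[[p]]))
    }
  } else {
    probs <- tryCatch({
      do.call(study_config, config$simulate)
      character(0)
    }, error = function(e) conditionMessage(e))
    for (pr in probs) add("simulate", pr)
  }
  lm_ok <- c("mean_mean", "mean_sigma", "haebara", "stocking_lord")
  if (!is.null(config$linking_method) && !config$linking_method %in% lm_ok) {
    add("linking_method", paste0("must be one of: ", paste(lm_ok, collapse = ", ")))
  }
  if (!is.null(config$equating_method) && !config$equating_method %in% c("OSE", "TSE")) {
    add("equating_method", "must be \"OSE\" or \"TSE\"")
  }
  if (!is.null(config$alpha) && (config$alpha <= 0 || config$alpha >= 1)) {
    add("alpha", "must lie in (0, 1)")
  }
  if (!is.null(config$anchor_ratio) && (config$anchor_ratio <= 0 || config$anchor_ratio > 1)) {
    add("anchor_ratio", "must lie in (0, 1]")
  }
  if (!is.null(config$seed) && (!is.numeric(config$seed) || config$seed != round(config$seed))) {
    add("seed", "must be an integer")
  }
  if (length(v) == 0) tibble(field = character(0), problem = character(0)) else bind_rows(v)
}

read_pipeline_config <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("Config file not found: ", path), class = "neatlink_io_error")
  }
  if (grepl("\\.json$", path, ignore.case = TRUE)) jsonlite::fromJSON(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
}

pipeline_log <- function(verbose, stage, msg) {
  if (verbose) message(sprintf("[%s] %s: %s", format(Sys.time(), "%H:%M:%S"), stage, msg))
}

#' Run the full equating pipeline
#'
#' Executes, in order: per-form 2PL calibration, a local-independence
#' residual scan of each form, optional content-paired item selection,
#' recalibration of the reduced forms, linking by all four methods,
#' parameter transformation with the chosen method, true-score and
#' observed-score equating tables, and age-percentile norms on the to-form
#' scale. Every stage's artifacts are written under `out_dir` in the
#' package's CSV/JSON formats, and a JSON manifest records options, the seed,
#' completed stages and file hashes. Any stage failure aborts with the stage
#' name; artifacts already written are retained.
#'
#' @param config Named list or YAML/JSON path (see [validate_config()]).
#' @param verbose Log stage progress to stderr (default `FALSE`).
#' @return The manifest, invisibly, as a list; also written to
#'   `out_dir/manifest.json`.
#' @export
run_pipeline <- function(config, verbose = FALSE) {
  if (is.character(config)) config <- read_pipeline_config(config)
  violations <- validate_config(config)
  if (nrow(violations) > 0) {
    abort(paste0("Invalid pipeline config:\n",
                 paste(sprintf("- %s: %s", violations$field, violations$problem),
                       collapse = "\n")), class = "neatlink_invalid_argument")
  }
  out_dir <- config$out_dir %||% tempfile("neatlink_run_")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seed <- as.integer(config$seed %||% 1L)
  linking_method <- config$linking_method %||% "stocking_lord"
  alpha <- config$alpha %||% 0.05
  do_selection <- isTRUE(config$selection %||% TRUE)
  norm_levels <- config$norm_levels %||% c(2.5, 10, 25, 50, 75, 90)
  grid <- ability_grid()
  manifest <- list(package = "neatlink",
                   version = as.character(utils::packageVersion("neatlink")),
                   seed = seed,
                   options = list(linking_method = linking_method, alpha = alpha,
                                  selection = do_selection),
                   stages = list(), files = list())
  stage <- function(name, expr) {
    pipeline_log(verbose, name, "start")
    res <- tryCatch(expr, error = function(e) {
      abort(paste0("Pipeline stage `", name, "` failed: ", conditionMessage(e)),
            class = "neatlink_stage_error")
    })
    manifest$stages[[name]] <<- "complete"
    pipeline_log(verbose, name, "done")
    res
  }
  emit <- function(name, path) manifest$files[[name]] <<- path

  # inputs
  if (!is.null(config$simulate)) {
    sim_args <- config$simulate
    sim_args$seed <- sim_args$seed %||% seed
    study <- generate_neat_study(do.call(study_config, sim_args))
    responses_from <- study$responses_from
    responses_to <- study$responses_to
    meta_from <- study$bank_from[c("item_id", "text_id", "question_type", "is_anchor")]
    meta_to <- study$bank_to[c("item_id", "text_id", "question_type", "is_anchor")]
    write_study(study, file.path(out_dir, "simulated_input"))
    emit("simulated_input", file.path(out_dir, "simulated_input"))
  } else {
    responses_from <- read_responses(config$responses_from)
    responses_to <- read_responses(config$responses_to)
    meta_from <- if (!is.null(config$item_meta_from))
      readr::read_csv(config$item_meta_from, show_col_types = FALSE) else NULL
    meta_to <- if (!is.null(config$item_meta_to))
      readr::read_csv(config$item_meta_to, show_col_types = FALSE) else NULL
  }

  fits <- stage("calibration", {
    f <- fit_2pl(responses_from, grid, form_id = "A", item_meta = meta_from)
    t_ <- fit_2pl(responses_to, grid, form_id = "B", item_meta = meta_to)
    write_item_bank(f$bank, file.path(out_dir, "bank_from_full.csv"))
    write_item_bank(t_$bank, file.path(out_dir, "bank_to_full.csv"))
    write_run_report(f, file.path(out_dir, "calibration_from.json"))
    write_run_report(t_, file.path(out_dir, "calibration_to.json"))
    emit("bank_from_full", file.path(out_dir, "bank_from_full.csv"))
    emit("bank_to_full", file.path(out_dir, "bank_to_full.csv"))
    list(from = f, to = t_)
  })

  stage("local_independence", {
    for (side in c("from", "to")) {
      scan <- residual_scan(fits[[side]]$bank,
                            if (side == "from") responses_from else responses_to,
                            grid, alpha)
      write_residual_scan(scan,
                          file.path(out_dir, paste0("residuals_", side, ".csv")),
                          file.path(out_dir, paste0("residuals_", side, "_summary.json")))
      emit(paste0("residuals_", side), file.path(out_dir, paste0("residuals_", side, ".csv")))
    }
  })

  banks <- stage("selection", {
    if (do_selection && !is.null(fits$from$bank$text_id) &&
        !anyNA(fits$from$bank$text_id)) {
      sel <- select_items(fits$from$bank, fits$to$bank,
                          plan = if (!is.null(config$plan)) read_selection_plan(config$plan)
                                 else default_selection_plan())
      readr::write_csv(sel$dropped, file.path(out_dir, "dropped_items.csv"), na = "")
      emit("dropped_items", file.path(out_dir, "dropped_items.csv"))
      list(from = sel$bank_from, to = sel$bank_to, reduced = TRUE)
    } else {
      list(from = fits$from$bank, to = fits$to$bank, reduced = FALSE)
    }
  })

  refits <- stage("recalibration", {
    if (banks$reduced) {
      f <- fit_2pl(responses_from[c("examinee_id", banks$from$item_id)], grid,
                   form_id = "A-R", item_meta = banks$from)
      t_ <- fit_2pl(responses_to[c("examinee_id", banks$to$item_id)], grid,
                    form_id = "B-R", item_meta = banks$to)
      list(from = f$bank, to = t_$bank, eap_to = f$eap)
    } else {
      list(from = banks$from, to = banks$to)
    }
  })

  links <- stage("linking", {
    af <- filter(refits$from, .data$is_anchor)
    at <- filter(refits$to, .data$is_anchor)
    tab <- linking_table(af, at, grid, se = isTRUE(config$linking_se %||% FALSE),
                         n_boot = config$n_boot %||% 500, seed = seed)
    readr::write_csv(tab, file.path(out_dir, "linking_coefficients.csv"), na = "")
    emit("linking_coefficients", file.path(out_dir, "linking_coefficients.csv"))
    tab
  })

  transformed <- stage("transform", {
    row <- links[links$method == linking_method, ]
    bank_from_on_to <- transform_parameters(refits$from, row$A, row$B)
    write_item_bank(bank_from_on_to, file.path(out_dir, "bank_from_on_to_scale.csv"))
    emit("bank_from_on_to_scale", file.path(out_dir, "bank_from_on_to_scale.csv"))
    bank_from_on_to
  })

  equatings <- stage("equating", {
    tse <- true_score_equating(transformed, refits$to)
    ose <- observed_score_equating(transformed, refits$to, grid)
    write_equating_table(tse, file.path(out_dir, "equating_tse.csv"), "from_to_to")
    write_equating_table(ose, file.path(out_dir, "equating_ose.csv"), "from_to_to")
    emit("equating_tse", file.path(out_dir, "equating_tse.csv"))
    emit("equating_ose", file.path(out_dir, "equating_ose.csv"))
    list(TSE = tse, OSE = ose)
  })

  stage("norms", {
    # raw scores on the to-form metric with ages, for the reference model
    eq_method <- config$equating_method %||% "OSE"
    scores_to <- rowSums(responses_to[, refits$to$item_id], na.rm = TRUE)
    ages <- if (!is.null(config$simulate)) {
      study$examinees$age[study$examinees$group == "to"]
    } else if (!is.null(config$examinees)) {
      ex <- readr::read_csv(config$examinees, show_col_types = FALSE)
      ex$age[match(responses_to$examinee_id, ex$examinee_id)]
    } else NULL
    if (is.null(ages)) {
      pipeline_log(verbose, "norms", "no ages available; skipping")
    } else {
      ref <- fit_reference(tibble(age = ages, score = scores_to))
      tab <- norm_table(ref, ages = seq(ceiling(min(ages)), floor(max(ages))),
                        levels = norm_levels, max_score = nrow(refits$to))
      readr::write_csv(tab, file.path(out_dir, "norm_table.csv"))
      emit("norm_table", file.path(out_dir, "norm_table.csv"))
      jsonlite::write_json(list(model = ref$model_id, r_squared = ref$r_squared,
                                equating_method = eq_method),
                           file.path(out_dir, "norm_model.json"),
                           auto_unbox = TRUE, digits = NA)
    }
  })

  manifest$files <- purrr::map(manifest$files, function(p) {
    list(path = p, md5 = if (dir.exists(p)) NA else unname(tools::md5sum(p)))
  })
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, null = "null", na = "null")
  invisible(manifest)
}

write_run_report <- function(fit, path) {
  jsonlite::write_json(
    list(log_likelihood = fit$loglik, trace = fit$loglik_trace,
         n_cycles = fit$n_cycles, converged = fit$converged,
         excluded = fit$excluded$item_id),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
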