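# Parameter spelling used in configuration files: dotted names map onto the
# argument names of ni_design()/calculate_size().
normalize_param_names <- function(x) {
  nm <- names(x)
  nm <- gsub(".", "_", nm, fixed = TRUE)
  names(x) <- nm
  if (!is.null(x$censoring_rate) && is.character(x$censoring_rate) &&
      !identical(x$censoring_rate, "AC.only")) {
    x$censoring_rate <- as.numeric(x$censoring_rate)
  }
  x
}

#' Read a scenario configuration file
#'
#' Reads a YAML or JSON file describing one scenario or a list of
#' scenarios. Keys use the design parameter names (`n`, `r`, `m1`, `m2`,
#' `shape`, `f1`, `m0`, `f2`, `margin`, `ps`, `rs`, `rho_s`, `s_dist`,
#' `censoring_rate`, `Ta`, `Te`, `tau`, `one_sided_alpha`, `TXswitch`,
#' `n_simulations`, `seed`, plus `nL`, `nU`, `B`, `epwr` for a size
#' search); dots in keys are accepted and mapped to underscores.
#' `censoring_rate` may be the string `"AC.only"` or a number.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A list of scenario parameter lists.
#' @export
read_scenario_config <- function(path) {
  if (!file.exists(path)) abort(sprintf("config file not found: %s", path))
  ext <- tolower(tools::file_ext(path))
  raw <- switch(ext,
    yaml = ,
    yml = yaml::read_yaml(path),
    json = jsonlite::read_json(path, simplifyVector = TRUE,
                               simplifyDataFrame = FALSE),
    abort(sprintf("unsupported config format: .%s (use YAML or JSON)", ext))
  )
  if (!is.list(raw)) abort("config must be a mapping or a list of mappings")
  scenarios <- if (!is.null(names(raw))) list(raw) else raw
  lapply(scenarios, normalize_param_names)
}

run_one_scenario <- function(params) {
  params <- normalize_param_names(as.list(params))
  params <- params[!vapply(params, function(v)
    length(v) == 0 || (length(v) == 1 && is.na(v)), TRUE)]
  task <- params$task %||% if (!is.null(params$epwr)) "size" else "power"
  n_simulations <- params$n_simulations %||% 5000
  seed <- params$seed %||% 1
  size_args <- c("task", "n_simulations", "seed", "nL", "nU", "B", "epwr")
  design <- do.call(ni_design, params[setdiff(names(params), size_args)])
  if (task == "power") {
    pw <- calculate_power(design, n_simulations = n_simulations, seed = seed)
    tibble::tibble(task = "power", n = design$n1, n_required = NA_integer_,
                   power = pw$power, mc_se = pw$mc_se,
                   E1 = pw$E1, E2 = pw$E2, delta = design$delta, seed = seed)
  } else if (task == "size") {
    sz <- calculate_size(design, nL = params$nL, nU = params$nU,
                         epwr = params$epwr, B = params$B %||% 10,
                         n_simulations = n_simulations, seed = seed)
    at_n <- sz$grid[which.min(abs(sz$grid$n - sz$n_required)), ]
    tibble::tibble(task = "size", n = design$n1, n_required = sz$n_required,
                   power = sz$curve$fun(sz$n_required), mc_se = at_n$mc_se,
                   E1 = at_n$E1, E2 = at_n$E2, delta = design$delta,
                   seed = seed)
  } else {
    abort(sprintf("unknown task \"%s\" (use \"power\" or \"size\")", task))
  }
}

#' Run a batch of scenarios
#'
#' Evaluates power or sample size for each scenario in a table or a
#' configuration file. A failing scenario is recorded in its row's `error`
#' column and the batch continues.
#'
#' @param scenarios A data frame with one scenario per row (columns named
#'   as in [read_scenario_config()], including an optional `task` column,
#'   `"power"` (default) or `"size"`), or a path to a YAML/JSON config.
#' @return A tibble with one row per scenario: `scenario`, `task`, `n`,
#'   `n_required`, `power`, `mc_se`, `E1`, `E2`, `delta`, `seed`,
#'   `elapsed` (seconds), `error` (`NA` on success).
#' @examples
#' scen <- data.frame(n = c(40, 60), m1 = 6, m2 = 6.4, Ta = 0, Te = 26,
#'                    tau = 12, f1 = 0.8, one_sided_alpha = 0.005,
#'                    n_simulations = 50, seed = 1)
#' run_scenario_batch(scen)
#' @export
run_scenario_batch <- function(scenarios) {
  if (is.character(scenarios) && length(scenarios) == 1L) {
    scenarios <- read_scenario_config(scenarios)
  }
  if (is.data.frame(scenarios)) {
    scenarios <- lapply(seq_len(nrow(scenarios)), function(i)
      as.list(scenarios[i, , drop = FALSE]))
  }
  if (length(scenarios) == 0L) {
    return(tibble::tibble(
      scenario = integer(), task = character(), n = integer(),
      n_required = integer(), power = numeric(), mc_se = numeric(),
      E1 = numeric(), E2 = numeric(), delta = numeric(), seed = numeric(),
      elapsed = numeric(), error = character()
    ))
  }
  rows <- purrr::imap(scenarios, function(params, i) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(
      cbind_err(run_one_scenario(params), NA_character_),
      error = function(e) {
        empty <- tibble::tibble(
          task = NA_character_, n = NA_integer_, n_required = NA_integer_,
          power = NA_real_, mc_se = NA_real_, E1 = NA_real_, E2 = NA_real_,
          delta = NA_real_, seed = NA_real_
        )
        cbind_err(empty, conditionMessage(e))
      }
    )
    res$elapsed <- proc.time()[["elapsed"]] - t0
    res$scenario <- as.integer(i)
    res
  })
  out <- dplyr::bind_rows(rows)
  dplyr::relocate(out, "scenario")
}

cbind_err <- function(df, msg) {
  df$error <- msg
  df
}

#' Write a result object to JSON or CSV
#'
#' Single results (`"ni_power"`, `"ni_size"`, `"drmst_ni"`) serialize to
#' JSON through their [glance()] row; tables (batch results, power grids)
#' serialize to CSV.
#'
#' @param x Result object or data frame.
#' @param path Output path; format follows the extension (`.json`/`.csv`).
#' @return `path`, invisibly.
#' @export
write_result <- function(x, path) {
  ext <- tolower(tools::file_ext(path))
  if (ext == "json") {
    row <- if (is.data.frame(x)) x else glance(x)
    jsonlite::write_json(as.list(row), path, auto_unbox = TRUE, digits = NA)
  } else if (ext == "csv") {
    df <- if (is.data.frame(x)) x else tidy(x)
    utils::write.csv(df, path, row.names = FALSE)
  } else {
    abort(sprintf("unsupported output format: .%s (use .json or .csv)", ext))
  }
  invisible(path)
}
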