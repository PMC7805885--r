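#' Experiment configurations
#'
#' An experiment configuration names a preset and carries the parameter grids,
#' strategy set, sample count and seed that drive it. Presets correspond to
#' the package's four headline analyses: the minimum stabilizing apology cost
#' against fakers across interaction lengths (`"min_cost"`), the minimum
#' interaction length against non-faker invaders across costs (`"min_n"`),
#' the guilt-prone basin of attraction across equal costs (`"basin_cost"`),
#' and the basin across faker-only costs `d > c` (`"basin_faker_cost"`).
#' Preset aliases `fig2`--`fig5` map to these in that order.
#'
#' @param experiment Preset name (or `fig2`..`fig5` alias).
#' @param n,a,p,c,d Parameter grids (numeric vectors); presets fill defaults
#'   for any left `NULL`.
#' @param strategies Strategy set for basin presets.
#' @param samples Simplex starts per stochastic grid point.
#' @param seed Integer seed (mandatory for stochastic experiments).
#' @param output Optional path stem: results are written to `<output>.csv`
#'   with a `<output>.json` metadata sidecar.
#' @param faker_apology_policy,gp_apology_policy Passed through to
#'   [model_params()].
#' @return An `experiment_config` object (a validated list).
#' @export
experiment_config <- function(experiment,
                              n = NULL, a = NULL, p = NULL,
                              c = NULL, d = NULL,
                              strategies = NULL,
                              samples = 1000, seed = 1,
                              output = NULL,
                              faker_apology_policy = "always",
                              gp_apology_policy = "always") {
  aliases <- base::c(fig2 = "min_cost", fig3 = "min_n",
                     fig4 = "basin_cost", fig5 = "basin_faker_cost")
  if (experiment %in% names(aliases)) experiment <- aliases[[experiment]]
  valid <- base::c("min_cost", "min_n", "basin_cost", "basin_faker_cost")
  if (!experiment %in% valid) {
    stop("unknown experiment preset: ", experiment, " (expected one of ",
         paste(base::c(valid, names(aliases)), collapse = ", "), ")",
         call. = FALSE)
  }
  cfg <- list(experiment = experiment, n = n, a = a, p = p, c = c, d = d,
              strategies = strategies, samples = samples,
              seed = as.integer(seed), output = output,
              faker_apology_policy = faker_apology_policy,
              gp_apology_policy = gp_apology_policy)
  cfg <- .fill_preset_defaults(cfg)
  .validate_config(cfg)
  structure(cfg, class = "experiment_config")
}

.fill_preset_defaults <- function(cfg) {
  dflt <- function(x, value) if (is.null(x)) value else x
  cfg$a <- dflt(cfg$a, 0.01)
  switch(cfg$experiment,
    min_cost = {
      cfg$n <- dflt(cfg$n, base::c(0.8, 0.85, 0.9, 0.95, 0.99))
      cfg$p <- dflt(cfg$p, base::c(0.5, 0.7, 0.8, 0.9, 0.95, 1.0))
      cfg$strategies <- dflt(cfg$strategies, base::c("GP", "F"))
    },
    min_n = {
      cfg$c <- dflt(cfg$c, base::c(0, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0))
      cfg$p <- dflt(cfg$p, 0.95)
      cfg$strategies <- dflt(cfg$strategies, base::c("C", "D", "GT"))
    },
    basin_cost = {
      cfg$n <- dflt(cfg$n, 0.95)
      cfg$p <- dflt(cfg$p, base::c(0.1, 0.5, 0.9, 0.95))
      cfg$c <- dflt(cfg$c, base::c(0.005, 0.1, 0.2, 0.4, 0.6, 0.8, 1.0))
      cfg$strategies <- dflt(cfg$strategies, base::c("C", "D", "GP", "F"))
    },
    basin_faker_cost = {
      cfg$n <- dflt(cfg$n, 0.95)
      cfg$p <- dflt(cfg$p, 0.95)
      cfg$c <- dflt(cfg$c, base::c(0, 0.2))
      cfg$d <- dflt(cfg$d, base::c(0.01, 0.1, 0.21, 0.3, 0.45, 0.6, 0.75, 0.9))
      cfg$strategies <- dflt(cfg$strategies, base::c("C", "D", "GP", "F"))
    }
  )
  cfg
}

.validate_config <- function(cfg) {
  grids <- cfg[base::c("n", "a", "p", "c", "d")]
  grids <- grids[!vapply(grids, is.null, logical(1))]
  if (any(vapply(grids, length, integer(1)) == 0L)) {
    stop("empty parameter grid in experiment config", call. = FALSE)
  }
  ok <- base::c(
    all(cfg$n >= 0 & cfg$n < 1),
    all(cfg$a >= 0 & cfg$a < 0.5),
    all(cfg$p > 0 & cfg$p <= 1),
    is.null(cfg$c) || all(cfg$c >= 0),
    is.null(cfg$d) || all(cfg$d >= 0)
  )
  if (!all(ok)) {
    stop("experiment grid values violate parameter constraints", call. = FALSE)
  }
  if (length(cfg$seed) != 1L || is.na(cfg$seed)) {
    stop("a single integer seed is required", call. = FALSE)
  }
  invisible(cfg)
}

#' Read an experiment configuration from a YAML file
#'
#' The file may contain any of the [experiment_config()] fields; missing ones
#' take preset defaults.
#'
#' @param path Path to a YAML file with an `experiment` field.
#' @return An `experiment_config` object.
#' @export
read_experiment_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (is.null(raw$experiment)) {
    stop("config file must name an `experiment` preset", call. = FALSE)
  }
  known <- base::c("experiment", "n", "a", "p", "c", "d", "strategies",
                   "samples", "seed", "output", "faker_apology_policy",
                   "gp_apology_policy")
  unknown <- setdiff(names(raw), known)
  if (length(unknown) > 0) {
    stop("unknown config fields: ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  do.call(experiment_config, raw)
}

.result_row <- function(experiment, params, strategies, samples, seed,
                        metric_name, value, ci_low = NA_real_,
                        ci_high = NA_real_) {
  data.frame(
    experiment = experiment,
    n = params$n, a = params$a, p = params$p, c = params$c, d = params$d,
    strategy_set = paste(strategies, collapse = "+"),
    samples = samples, seed = seed,
    metric_name = metric_name, value = value,
    ci_low = ci_low, ci_high = ci_high,
    stringsAsFactors = FALSE
  )
}

#' Run a preset experiment
#'
#' Dispatches an [experiment_config()] to its preset, producing one result row
#' per grid point. Deterministic presets (the ESS boundary searches) report
#' `NA` confidence bounds; basin presets report 95 percent binomial intervals
#' and use one derived seed per grid point (`seed + row index`), so identical
#' configs reproduce identical tables. When the config names an `output`
#' stem, the table is written to `<output>.csv` and a JSON sidecar
#' (`<output>.json`) records the full config, package version and timestamp.
#'
#' @param config An `experiment_config` (or preset name, forwarded to
#'   [experiment_config()] with defaults).
#' @param quiet Suppress per-grid-point progress messages.
#' @return A data frame with columns `experiment, n, a, p, c, d, strategy_set,
#'   samples, seed, metric_name, value, ci_low, ci_high`, invisibly carrying
#'   the config as attribute `"config"`.
#' @export
run_experiment <- function(config, quiet = FALSE) {
  if (is.character(config)) config <- experiment_config(config)
  stopifnot(inherits(config, "experiment_config"))
  say <- function(...) if (!quiet) message(sprintf(...))
  rows <- list()
  row_id <- 0L
  add <- function(row) {
    row_id <<- row_id + 1L
    rows[[row_id]] <<- row
  }

  if (config$experiment == "min_cost") {
    for (p in config$p) {
      for (n in config$n) {
        cost <- min_cost_for_ess_vs_faker(p = p, n = n, a = config$a)
        say("min_cost: p=%g n=%g -> c*=%g", p, n, cost)
        params <- model_params(n = n, a = config$a, p = p,
                               c = max(cost, 0, na.rm = TRUE),
                               d = max(cost, 0, na.rm = TRUE))
        params$c <- params$d <- cost  # report the searched value, NA if none
        add(.result_row(config$experiment, params, config$strategies,
                        NA_integer_, config$seed, "min_cost_ess_vs_F", cost))
      }
    }
  } else if (config$experiment == "min_n") {
    for (invader in config$strategies) {
      for (cost in config$c) {
        nstar <- min_continuation_for_ess(invader, cost = cost, a = config$a,
                                          p = config$p[1])
        say("min_n: invader=%s c=%g -> n*=%g", invader, cost, nstar)
        params <- model_params(n = 0, a = config$a, p = config$p[1],
                               c = cost, d = cost)
        params$n <- nstar
        add(.result_row(config$experiment, params, invader, NA_integer_,
                        config$seed, paste0("min_n_vs_", invader), nstar))
      }
    }
  } else if (config$experiment == "basin_cost") {
    i <- 0L
    for (p in config$p) {
      for (cost in config$c) {
        i <- i + 1L
        seed_i <- config$seed + i - 1L
        params <- model_params(n = config$n[1], a = config$a, p = p,
                               c = cost, d = cost,
                               faker_apology_policy =
                                 config$faker_apology_policy,
                               gp_apology_policy = config$gp_apology_policy)
        est <- estimate_basin(params, strategies = config$strategies,
                              samples = config$samples, seed = seed_i)
        say("basin_cost: p=%g c=d=%g -> GP basin %.3f (unresolved %.3f)",
            p, cost, est$fractions["GP"], est$unresolved)
        add(.result_row(config$experiment, params, config$strategies,
                        config$samples, seed_i, "gp_basin_fraction",
                        unname(est$fractions["GP"]),
                        unname(est$ci["GP", "low"]),
                        unname(est$ci["GP", "high"])))
      }
    }
  } else if (config$experiment == "basin_faker_cost") {
    i <- 0L
    for (cost_gp in config$c) {
      for (cost_f in config$d) {
        if (cost_f < cost_gp) next # this preset explores d >= c only
        i <- i + 1L
        seed_i <- config$seed + i - 1L
        params <- model_params(n = config$n[1], a = config$a,
                               p = config$p[1], c = cost_gp, d = cost_f,
                               faker_apology_policy =
                                 config$faker_apology_policy,
                               gp_apology_policy = config$gp_apology_policy)
        est <- estimate_basin(params, strategies = config$strategies,
                              samples = config$samples, seed = seed_i)
        say("basin_faker_cost: c=%g d=%g -> GP basin %.3f", cost_gp, cost_f,
            est$fractions["GP"])
        add(.result_row(config$experiment, params, config$strategies,
                        config$samples, seed_i, "gp_basin_fraction",
                        unname(est$fractions["GP"]),
                        unname(est$ci["GP", "low"]),
                        unname(est$ci["GP", "high"])))
      }
    }
  }

  table <- do.call(rbind, rows)
  attr(table, "config") <- config
  if (!is.null(config$output)) {
    csv_path <- paste0(config$output, ".csv")
    utils::write.csv(table, csv_path, row.names = FALSE)
    meta <- list(
      experiment = config$experiment,
      config = unclass(config)[!vapply(unclass(config), is.null, logical(1))],
      package_version = as.character(utils::packageVersion("meaculpa")),
      timestamp = format(Sys.time(), tz = "UTC", usetz = TRUE),
      rows = nrow(table)
    )
    jsonlite::write_json(meta, paste0(config$output, ".json"),
                         auto_unbox = TRUE, digits = NA)
    say("wrote %s (+ JSON sidecar)", csv_path)
  }
  table
}

#' Plot an experiment result table
#'
#' Renders the standard figure for each preset: boundary curves for the ESS
#' searches (minimum cost against `n`, one line per `p`; minimum `n` against
#' cost, one line per invader) and basin curves for the basin presets (GP
#' basin fraction against cost, one line per `p` or per guilt-prone cost).
#' Cosmetic only: no numbers are derived from the plot.
#'
#' @param table A [run_experiment()] result.
#' @param experiment Preset name; defaults to the one recorded in the table.
#' @param file Optional path; when given the plot is saved there via
#'   [ggplot2::ggsave()].
#' @return The ggplot object, invisibly when saved to `file`.
#' @export
plot_results <- function(table, experiment = NULL, file = NULL) {
  if (is.null(table) || !is.data.frame(table) || nrow(table) == 0L) {
    stop("empty result table", call. = FALSE)
  }
  if (is.null(experiment)) {
    experiment <- unique(table$experiment)
  }
  if (length(experiment) != 1L || !all(table$experiment == experiment)) {
    stop("result table does not match a single experiment preset",
         call. = FALSE)
  }
  gg <- switch(experiment,
    min_cost = ggplot2::ggplot(table,
        ggplot2::aes(x = .data$n, y = .data$value,
                     colour = factor(.data$p))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "continuation probability n",
                    y = "minimum apology cost c for GP to be an ESS vs F",
                    colour = "fakeability p"),
    min_n = ggplot2::ggplot(table,
        ggplot2::aes(x = .data$c, y = .data$value,
                     colour = .data$metric_name)) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::labs(x = "apology cost c",
                    y = "minimum n for GP to be an ESS",
                    colour = "invader"),
    basin_cost = ggplot2::ggplot(table,
        ggplot2::aes(x = .data$c, y = .data$value,
                     colour = factor(.data$p))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high,
                                        fill = factor(.data$p)),
                           alpha = 0.15, colour = NA) +
      ggplot2::labs(x = "apology cost c = d",
                    y = "GP basin of attraction",
                    colour = "fakeability p", fill = "fakeability p"),
    basin_faker_cost = ggplot2::ggplot(table,
        ggplot2::aes(x = .data$d, y = .data$value,
                     colour = factor(.data$c))) +
      ggplot2::geom_line() + ggplot2::geom_point() +
      ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$ci_low,
                                        ymax = .data$ci_high,
                                        fill = factor(.data$c)),
                           alpha = 0.15, colour = NA) +
      ggplot2::labs(x = "faker apology cost d",
                    y = "GP basin of attraction",
                    colour = "GP cost c", fill = "GP cost c"),
    stop("unknown experiment preset: ", experiment, call. = FALSE)
  )
  gg <- gg + ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 7, height = 5)
    return(invisible(gg))
  }
  gg
}
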