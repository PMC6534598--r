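# Scenario runner: end-to-end simulate -> score -> report pipelines with a
# serialisable config, so every analysis in the package can be reproduced
# from a persisted YAML/JSON config alone.

.SCENARIOS <- c("mixed_pollination", "screen", "reversion", "qpcr",
                "divergence")

.load_config <- function(config) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("config file not found: ", config)
    config <- if (grepl("\\.ya?ml$", config, ignore.case = TRUE)) {
      yaml::read_yaml(config)
    } else {
      jsonlite::read_json(config, simplifyVector = TRUE)
    }
  }
  if (!is.list(config)) stop("config must be a list or a YAML/JSON file path")
  config
}

.validate_config <- function(config) {
  problems <- character()
  if (is.null(config$scenario)) {
    problems <- c(problems, "scenario: missing (one of: " %+%
                    paste(.SCENARIOS, collapse = ", ") %+% ")")
  } else if (!config$scenario %in% .SCENARIOS) {
    problems <- c(problems,
                  "scenario: unknown value '" %+% config$scenario %+% "'")
  }
  if (is.null(config$seed)) {
    problems <- c(problems, "seed: missing (an integer seed is mandatory)")
  } else if (!is.numeric(config$seed) || length(config$seed) != 1L) {
    problems <- c(problems, "seed: must be a single integer")
  }
  if (!is.null(config$params) && !is.list(config$params)) {
    problems <- c(problems, "params: must be a named list")
  }
  if (identical(config$scenario, "divergence")) {
    p <- config$params
    if (is.null(p$fasta) && (is.null(p$n_diff) || is.null(p$n_sites))) {
      problems <- c(problems,
                    "params.fasta: missing (or give params.n_diff + params.n_sites)")
    }
  }
  if (identical(config$scenario, "qpcr") &&
      is.null(config$params$ct_table)) {
    problems <- c(problems, "params.ct_table: missing (path to a Ct TSV)")
  }
  problems
}

`%+%` <- function(a, b) paste0(a, b)

.take <- function(params, allowed) {
  extra <- setdiff(names(params), allowed)
  if (length(extra) > 0L) {
    stop("unknown params for this scenario: ",
         paste0("params.", extra, collapse = ", "))
  }
  params[intersect(allowed, names(params))]
}

.as_bias <- function(x) {
  if (is.null(x)) return(NULL)
  out <- unlist(x)
  names(out) <- names(x)
  .check_bias(out)
}

.run_mixed_pollination <- function(params, seed) {
  p <- .take(params, c("mix_weight", "leak", "acceptance_bias", "n_kernels"))
  bias <- .as_bias(p$acceptance_bias)
  args <- list(
    test_female = plant_genotype("Tcb1-s", "Tcb1-s"),
    donorA = plant_genotype("tcb1", "tcb1", r1 = c("R1-sc", "R1-sc")),
    donorB = plant_genotype("Tcb1-s", "Tcb1-s", r1 = c("r1-r", "r1-r")),
    seed = seed
  )
  for (nm in c("mix_weight", "leak", "n_kernels")) {
    if (!is.null(p[[nm]])) args[[nm]] <- p[[nm]]
  }
  if (!is.null(bias)) args$acceptance_bias <- bias
  ears <- do.call(simulate_mixed_pollination, args)
  test <- ears[ears$receiver_class == "test", ]
  neutral <- ears[ears$receiver_class == "neutral", ]
  cls <- classify_ear(test, neutral)
  mix_w <- if (is.null(p$mix_weight)) 0.5 else p$mix_weight
  bias_hat <- estimate_acceptance_bias(neutral$n_purple, neutral$n_yellow,
                                       mix_weight = mix_w)
  list(
    ears = ears,
    test_vs_neutral = list(p_value = cls$p_value, tier = cls$tier,
                           barrier_strength = cls$barrier_strength),
    estimates = list(
      acceptance_bias_tcb1 = unname(bias_hat["tcb1"]),
      leak = as.numeric(estimate_leak(test, neutral))
    )
  )
}

.run_screen <- function(params, seed) {
  p <- .take(params, c("n_plants", "kernels_per_ear", "r", "leak",
                       "knockout_fraction", "alpha"))
  alpha <- if (is.null(p$alpha)) 0.05 else p$alpha
  p$alpha <- NULL
  args <- c(p, list(seed = seed))
  ears <- do.call(simulate_open_pollinated_screen, args)
  r <- if (is.null(p$r)) 0.06 else p$r
  flagged <- flag_screen_outliers(ears, null_fraction = r / 2, alpha = alpha)
  ko <- !flagged$barrier
  list(
    n_ears = nrow(flagged),
    n_flagged = sum(flagged$flagged),
    mean_sugary_fraction_barrier = mean(flagged$sugary_fraction[flagged$barrier]),
    mean_sugary_fraction_knockout = if (any(ko)) {
      mean(flagged$sugary_fraction[ko])
    } else NA_real_,
    sensitivity = if (any(ko)) mean(flagged$flagged[ko]) else NA_real_,
    false_flag_rate = mean(flagged$flagged[flagged$barrier]),
    ears = flagged
  )
}

.run_reversion <- function(params, seed) {
  p <- .take(params, c("n_females", "reversion_prob", "n_kernels",
                       "expression_base", "expression_reverted",
                       "partial_leak_band"))
  if (!is.null(p$partial_leak_band)) {
    p$partial_leak_band <- unlist(p$partial_leak_band)
  }
  res <- do.call(simulate_reversion_experiment, c(p, list(seed = seed)))
  detected <- res$tier != "none"
  list(
    n_females = nrow(res),
    n_reverted_truth = sum(res$reverted),
    tier_counts = as.list(table(factor(res$tier,
                                       c("strong", "partial", "none")))),
    sensitivity = if (any(res$reverted)) {
      mean(detected[res$reverted])
    } else NA_real_,
    specificity = if (any(!res$reverted)) {
      mean(!detected[!res$reverted])
    } else NA_real_,
    females = res
  )
}

.run_qpcr <- function(params, seed) {
  p <- .take(params, c("ct_table", "strengths_table", "threshold"))
  ct <- read_ct_table(p$ct_table)
  summaries <- summarize_expression(ct)
  out <- list(expression_summaries = summaries)
  if (!is.null(p$strengths_table)) {
    strengths <- .read_tsv(p$strengths_table)
    thr <- if (is.null(p$threshold)) 0.1 else p$threshold
    assoc <- expression_barrier_association(summaries, strengths,
                                            threshold = thr)
    out$association <- list(rho = assoc$rho, n = assoc$n,
                            threshold_consistent = assoc$threshold_consistent)
  }
  out
}

.run_divergence <- function(params, seed) {
  p <- .take(params, c("fasta", "n_diff", "n_sites", "mu", "splits"))
  mu <- if (is.null(p$mu)) 3.3e-8 else p$mu
  splits <- if (is.null(p$splits)) {
    c("mexicana-parviglumis" = 60000, "parviglumis-luxurians" = 140000)
  } else {
    unlist(p$splits)
  }
  res <- if (!is.null(p$fasta)) {
    date_divergence(p$fasta, mu = mu, splits = splits)
  } else {
    years <- divergence_time(p$n_diff, p$n_sites, mu)
    structure(list(n_diff = p$n_diff, n_sites = p$n_sites,
                   divergence = p$n_diff / p$n_sites, mu = mu, years = years,
                   splits = place_against_splits(years, splits)),
              class = "dating_result")
  }
  list(n_diff = res$n_diff, n_sites = res$n_sites,
       divergence = res$divergence, mu = res$mu, years = res$years,
       splits = res$splits)
}

#' Run an end-to-end analysis scenario
#'
#' Executes one of the named scenarios (`"mixed_pollination"`, `"screen"`,
#' `"reversion"`, `"qpcr"`, `"divergence"`) from a config that is a list or
#' a YAML/JSON file with fields `scenario`, `seed` and an optional `params`
#' block of scenario-specific parameters. The returned report carries the
#' config it was produced from, all raw counts and all derived statistics
#' (p-values, tiers, barrier strengths, expression summaries, dating
#' results), so a run is reproducible — and its figures re-plottable — from
#' the persisted report alone.
#'
#' @param config A list, or a path to a YAML/JSON config file.
#' @param out_dir Optional directory; if given, the report is written there
#'   as `report.json` plus a human-readable `summary.txt`.
#' @return A list of class `scenario_report`: `scenario`, `seed`, `config`,
#'   `results`.
#' @examples
#' rep <- run_scenario(list(scenario = "divergence", seed = 1,
#'                          params = list(n_diff = 15, n_sites = 1296)))
#' rep$results$years
#' @export
run_scenario <- function(config, out_dir = NULL) {
  config <- .load_config(config)
  problems <- .validate_config(config)
  if (length(problems) > 0L) {
    stop("invalid scenario config:\n  - ",
         paste(problems, collapse = "\n  - "))
  }
  seed <- as.integer(config$seed)
  params <- if (is.null(config$params)) list() else config$params
  runner <- switch(config$scenario,
    mixed_pollination = .run_mixed_pollination,
    screen            = .run_screen,
    reversion         = .run_reversion,
    qpcr              = .run_qpcr,
    divergence        = .run_divergence
  )
  results <- runner(params, seed)
  report <- structure(
    list(scenario = config$scenario, seed = seed, config = config,
         results = results),
    class = "scenario_report"
  )
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(unclass(report),
                         file.path(out_dir, "report.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE,
                         force = TRUE)
    con <- file(file.path(out_dir, "summary.txt"), "w")
    sink(con)
    print(report)
    sink()
    close(con)
  }
  report
}

#' @export
print.scenario_report <- function(x, ...) {
  cat(sprintf("scenario '%s' (seed %d)\n", x$scenario, x$seed))
  scalars <- Filter(function(v) is.atomic(v) && length(v) == 1L, x$results)
  for (nm in names(scalars)) {
    cat(sprintf("  %s: %s\n", nm, format(scalars[[nm]])))
  }
  nested <- Filter(function(v) is.list(v) && !is.data.frame(v), x$results)
  for (nm in names(nested)) {
    inner <- Filter(function(v) is.atomic(v) && length(v) == 1L, nested[[nm]])
    if (length(inner) > 0L) {
      cat(sprintf("  %s: %s\n", nm,
                  paste(sprintf("%s=%s", names(inner),
                                vapply(inner, format, character(1))),
                        collapse = ", ")))
    }
  }
  invisible(x)
}
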