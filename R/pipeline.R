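#' Study configuration
#'
#' Fully determines a run of [run_study()]: where the responses come from
#' (a CSV path or a simulation spec), the money-perception exponents to sweep,
#' the classification thresholds, the seeds and restart budget, and where
#' artifacts go.
#'
#' @param input Path to a responses CSV, a `matching_responses` data.frame,
#'   or `NULL` to simulate.
#' @param simulate Named list passed to [simulate_cohort()] when `input` is
#'   `NULL` (e.g. `list(n_participants = 35, K_true = -1, noise_sigma = 0.05)`).
#' @param alpha_grid Money-perception exponents; a sweep re-fits the whole
#'   cohort at every value (classification labels are expected to be
#'   invariant, since distances scale linearly in alpha).
#' @param kappa0 Near-zero curvature threshold.
#' @param tie_threshold Relative fit-ratio improvement counted as a tie.
#' @param seed Master seed for fitting (and simulation when used).
#' @param n_restarts,sann_iter Optimizer budget per fit.
#' @param out_dir Directory for artifacts, or `NULL` to skip writing.
#' @return An object of class `study_config`.
#' @export
study_config <- function(input = NULL, simulate = list(),
                         alpha_grid = 1, kappa0 = 0.01, tie_threshold = 0.01,
                         seed = 1, n_restarts = 10, sann_iter = 150,
                         out_dir = NULL) {
  structure(list(input = input, simulate = simulate, alpha_grid = alpha_grid,
                 kappa0 = kappa0, tie_threshold = tie_threshold, seed = seed,
                 n_restarts = n_restarts, sann_iter = sann_iter,
                 out_dir = out_dir),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Keys mirror the arguments of [study_config()].
#'
#' @param path Path to a YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  if (is.null(y)) y <- list()
  known <- names(formals(study_config))
  unknown <- setdiff(names(y), known)
  if (length(unknown)) {
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  }
  do.call(study_config, y)
}

# Fit both geometries and classify every participant at one alpha.
classify_cohort <- function(responses, alpha, config) {
  Ds <- participant_distances(responses, alpha = alpha)
  opts <- fit_options(n_restarts = config$n_restarts,
                      sann_iter = config$sann_iter)
  set.seed(config$seed)
  seeds <- sample.int(2^31 - 1, length(Ds))
  rows <- lapply(seq_along(Ds), function(i) {
    f_nc <- fit_negative_curvature(Ds[[i]], opts, seed = seeds[i])
    f_e <- fit_euclidean(Ds[[i]], opts, seed = seeds[i])
    cl <- classify_participant(f_nc, f_e, kappa0 = config$kappa0,
                               tie_threshold = config$tie_threshold)
    data.frame(participant_id = names(Ds)[i],
               ratio_NC = f_nc$fit_ratio, ratio_E = f_e$fit_ratio,
               K_hat = f_nc$K_hat, margin = cl$margin, label = cl$label)
  })
  do.call(rbind, rows)
}

#' Run the full study pipeline
#'
#' Load (or simulate) matching responses, apply the exclusion rules, infer
#' each retained participant's latent distance matrix, fit the
#' negative-curvature and Euclidean embeddings, classify every participant,
#' and aggregate the cohort chi-square. When `alpha_grid` has more than one
#' value the whole fit-and-classify stage is repeated per alpha and a
#' robustness table of classification counts is returned; the primary results
#' are those at the alpha closest to 1.
#'
#' @param config A [study_config()] (or path to a YAML file).
#' @return A list of class `study_result`: `participants` (per-participant
#'   table at the primary alpha), `cohort` (a `cohort_result`), `excluded`,
#'   `robustness` (counts per alpha, `NULL` for a single alpha), `config`.
#'   With `out_dir` set, writes `participants.csv`, `cohort.json`,
#'   `excluded.csv` and, for sweeps, `robustness.csv`.
#' @export
run_study <- function(config) {
  if (is.character(config)) config <- read_study_config(config)
  stopifnot(inherits(config, "study_config"))
  responses <- if (is.null(config$input)) {
    args <- config$simulate
    if (is.null(args$seed)) args$seed <- config$seed
    do.call(simulate_cohort, args)
  } else {
    load_responses(config$input)
  }
  excl <- apply_exclusions(responses)
  if (nrow(excl$retained) == 0) stop("empty cohort: all participants excluded")

  sweeps <- lapply(config$alpha_grid, function(a) {
    classify_cohort(excl$retained, a, config)
  })
  primary <- which.min(abs(config$alpha_grid - 1))
  participants <- sweeps[[primary]]
  cohort <- aggregate_chi_square(participants$label)

  robustness <- NULL
  if (length(config$alpha_grid) > 1) {
    robustness <- do.call(rbind, lapply(seq_along(sweeps), function(i) {
      tab <- table(factor(sweeps[[i]]$label,
                          levels = c("NC_better", "tie", "Euclidean_better")))
      data.frame(alpha = config$alpha_grid[i],
                 NC_better = as.integer(tab["NC_better"]),
                 tie = as.integer(tab["tie"]),
                 Euclidean_better = as.integer(tab["Euclidean_better"]))
    }))
  }

  result <- structure(list(participants = participants, cohort = cohort,
                           excluded = excl$excluded, robustness = robustness,
                           config = config),
                      class = "study_result")
  if (!is.null(config$out_dir)) write_study_result(result, config$out_dir)
  result
}

#' @export
print.study_result <- function(x, ...) {
  cat(sprintf("<study_result> %d retained, %d excluded\n",
              nrow(x$participants), nrow(x$excluded)))
  print(x$cohort)
  if (!is.null(x$robustness)) {
    cat("alpha-sweep classification counts:\n")
    print(x$robustness, row.names = FALSE)
  }
  invisible(x)
}

# Write study artifacts (CSV tables, JSON cohort summary) to a directory.
write_study_result <- function(result, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  fmt <- function(df) {
    num <- vapply(df, is.numeric, logical(1))
    df[num] <- lapply(df[num], signif, digits = 6)
    df
  }
  utils::write.csv(fmt(result$participants),
                   file.path(out_dir, "participants.csv"), row.names = FALSE)
  utils::write.csv(result$excluded, file.path(out_dir, "excluded.csv"),
                   row.names = FALSE)
  co <- result$cohort
  jsonlite::write_json(
    list(a_NC_better = co$a, b_rest = co$b, N = co$N,
         chi2 = signif(co$chi2, 6), p = round(co$p, 4),
         labels = as.list(co$labels), seed = result$config$seed,
         n_restarts = result$config$n_restarts),
    file.path(out_dir, "cohort.json"), auto_unbox = TRUE, digits = NA)
  if (!is.null(result$robustness)) {
    utils::write.csv(fmt(result$robustness),
                     file.path(out_dir, "robustness.csv"), row.names = FALSE)
  }
  invisible(out_dir)
}

#' Read model parameters (curvature, leak, perception) from YAML
#'
#' Keys: `K`, `psi`, `money_form`, `alpha`, `time_form`, `beta`. Returns the
#' pair of specs the discounting functions take.
#'
#' @param path Path to a YAML file.
#' @return List with `disc` (a `discount_spec`) and `spec`
#'   (a `perception_spec`).
#' @export
read_model_config <- function(path) {
  y <- yaml::read_yaml(path)
  spec <- perception_spec(money_form = y$money_form %||% "linear",
                          alpha = y$alpha %||% 1,
                          time_form = y$time_form %||% "linear",
                          beta = y$beta %||% 1)
  disc <- discount_spec(K = y$K %||% -1, psi = y$psi %||% 1)
  list(disc = disc, spec = spec)
}

#' Run the standard phenomena battery
#'
#' Executes all six phenomenon demonstrations at their default study
#' parameters under a given model configuration and returns the reports.
#'
#' @param disc A `discount_spec`.
#' @param spec A `perception_spec`.
#' @return Named list of `phenomenon_report`s.
#' @export
run_phenomena <- function(disc = discount_spec(), spec = perception_spec()) {
  list(
    preference_reversal = find_preference_reversal(
      100, 1, 150, 12, disc, spec),
    temporal_subadditivity = subadditivity_gap(
      12, 12, fixed = 100, axis = "time", spec = spec, K = disc$K,
      psi = disc$psi),
    monetary_subadditivity = subadditivity_gap(
      200, 300, fixed = 12, axis = "money", spec = spec, K = disc$K,
      psi = disc$psi),
    magnitude_effect = magnitude_effect_curve(disc = disc, spec = spec),
    improving_sequences = sequence_preference(disc = disc, spec = spec),
    distant_subadditivity = distant_subadditivity_profile(
      spec = spec, K = disc$K),
    loss_gain_asymmetry = loss_gain_curvature_check(spec = spec,
                                                    psi = disc$psi)
  )
}
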