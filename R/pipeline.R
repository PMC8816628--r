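# End-to-end pipeline runners: each writes plain TSV/CSV outputs plus a JSON
# run manifest (config, seed, package version) sufficient to reproduce the
# outputs bit-for-bit.

#' Derive a deterministic child seed for a pipeline stage
#'
#' One global seed expands into independent per-stage seeds by a documented
#' arithmetic scheme (`(seed + 1000003 * stage) mod (2^31 - 1)`), so stages
#' can be re-run independently and still reproduce a full-pipeline run.
#'
#' @param seed Global integer seed.
#' @param stage Stage index (>= 1).
#' @return An integer seed.
#' @export
child_seed <- function(seed, stage) {
  as.integer((as.double(seed) + 1000003 * as.double(stage)) %% (2^31 - 1))
}

write_manifest <- function(outdir, stage, config, seed) {
  manifest <- list(
    stage = stage,
    config = config,
    seed = seed,
    package_version = as.character(utils::packageVersion("reachclust")),
    r_version = R.version.string
  )
  jsonlite::write_json(manifest, file.path(outdir, paste0(stage, "_manifest.json")),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
}

#' Run the functional-curve simulation stage
#'
#' Generates the labelled curve dataset and writes it as TSV
#' (`curves.tsv`: obs_id, true_label, v1..vT) with a manifest.
#'
#' @param outdir Output directory (created if missing).
#' @param groups Group specification (default [curve_groups()]).
#' @param n_per_group Observations per group (default 1500).
#' @param t_total,t_split Curve geometry (defaults 120 / 60).
#' @param seed Integer seed (default 1).
#' @return The dataset tibble, invisibly.
#' @export
run_curve_simulation <- function(outdir, groups = curve_groups(),
                                 n_per_group = 1500, t_total = 120,
                                 t_split = 60, seed = 1) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  dataset <- simulate_curves(groups, n_per_group, t_total, t_split, seed = seed)
  write_curve_dataset(dataset, file.path(outdir, "curves.tsv"))
  write_manifest(outdir, "simulate_curves",
                 list(n_per_group = n_per_group, t_total = t_total,
                      t_split = t_split, groups = groups), seed)
  message(sprintf("simulate_curves: wrote %d observations x %d time points",
                  nrow(dataset), t_total))
  invisible(dataset)
}

#' Run the synthetic reaching-session simulation stage
#'
#' Simulates one session per participant under the given schedules and
#' writes tidy trajectory samples and per-trial tables per participant,
#' plus a manifest.
#'
#' @param outdir Output directory.
#' @param n_participants Sessions to simulate (default 4).
#' @param condition `"Fixed"` or `"LS"`.
#' @param policy A [reach_policy()].
#' @param seed Integer seed (default 1); participant p uses
#'   `child_seed(seed, p)`.
#' @return A tibble of all sessions, invisibly.
#' @export
run_reach_simulation <- function(outdir, n_participants = 4,
                                 condition = c("Fixed", "LS"),
                                 policy = reach_policy(), seed = 1) {
  condition <- match.arg(condition)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  sessions <- purrr::map_dfr(seq_len(n_participants), function(p) {
    s <- child_seed(seed, p)
    schedule <- if (condition == "Fixed") {
      make_schedule("Fixed")
    } else {
      withr::with_seed(s, make_schedule(
        "LS", baseline_pd = rnorm(50, 0, 0.89)
      ))
    }
    simulate_session(policy, schedule, participant = sprintf("P%02d", p),
                     seed = child_seed(s, 1))
  })
  for (p in unique(sessions$participant)) {
    write_session(sessions[sessions$participant == p, ],
                  file.path(outdir, paste0("session_", p)))
  }
  write_manifest(outdir, "simulate_reaching",
                 list(n_participants = n_participants, condition = condition,
                      policy = unclass(policy)), seed)
  message(sprintf("simulate_reaching: wrote %d sessions x %d trials",
                  n_participants, nrow(sessions) / n_participants))
  invisible(sessions)
}

#' Run the clustering + exploration analysis stage
#'
#' Vectorizes sessions, fits the mixture over a K grid, selects K by the
#' BIC first-plateau rule, orders clusters left to right, and writes: the
#' pooled feature matrix + metadata with cluster assignments, the criteria
#' table, the fitted model (JSON), per-session EER, transition counts, and
#' visited-cluster counts, plus a manifest.
#'
#' @param sessions Session tibble (with `samples` list-column).
#' @param outdir Output directory.
#' @param K_grid K grid for model selection (default `2:6`).
#' @param plateau_frac BIC plateau threshold (default 0.05).
#' @param seed Integer seed (default 1).
#' @param ... Passed to [fit_gmm_grid()].
#' @return A list with `fit`, `K`, `assignments`, invisibly.
#' @export
run_clustering_analysis <- function(sessions, outdir, K_grid = 2:6,
                                    plateau_frac = 0.05, seed = 1, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  tm <- build_trial_matrix(sessions)
  grid <- fit_gmm_grid(trial_features(tm), K_grid = K_grid, seed = seed, ...)
  K_star <- select_K(grid, plateau_frac)
  fit <- order_clusters(grid$fits[[paste0("K", K_star)]])
  assigned <- assign_clusters(tm, fit)
  readr::write_tsv(grid$criteria, file.path(outdir, "criteria.tsv"))
  write_gmm_json(fit, file.path(outdir, "model.json"))
  write_trial_matrix(assigned, file.path(outdir, "trials"))
  per_session <- assigned |>
    dplyr::group_by(.data$participant, .data$condition) |>
    dplyr::reframe(
      visited = visited_clusters(.data$cluster),
      eer(.data$cluster)[, c("n_explore", "n_exploit", "eer")]
    )
  readr::write_tsv(per_session, file.path(outdir, "session_eer.tsv"))
  trans <- assigned |>
    dplyr::group_by(.data$condition) |>
    dplyr::reframe(transition_counts(.data$cluster, K = fit$K))
  readr::write_tsv(trans, file.path(outdir, "transitions.tsv"))
  write_manifest(outdir, "analyze",
                 list(K_grid = K_grid, plateau_frac = plateau_frac,
                      K_selected = as.integer(K_star)), seed)
  message(sprintf("analyze: %d trials, selected K = %d", nrow(tm), K_star))
  invisible(list(fit = fit, K = as.integer(K_star), assignments = assigned))
}

#' Run the four-case bootstrap validation study
#'
#' Executes [run_case_validation()] for every sampling rule and writes the
#' replicate log (`validation_replicates.tsv`), the Table-2-style summary
#' (`validation_summary.tsv`), and a manifest recording all seeds.
#'
#' @param outdir Output directory.
#' @param dataset Labelled curve dataset; generated from [curve_groups()]
#'   with `n_per_group` observations when omitted.
#' @param rules Sampling-rule tibble (default [sampling_rules()]).
#' @param B Bootstrap replicates per case (default 500).
#' @param cases Which case ids to run (default all).
#' @param n_per_group Dataset size when `dataset` is omitted (default 1500).
#' @param seed Integer seed (default 1); case i uses `child_seed(seed, i)`.
#' @param ... Passed to [run_case_validation()] (e.g. `K_grid`,
#'   `n_restarts`).
#' @return The summary tibble, invisibly.
#' @export
run_validation_study <- function(outdir, dataset = NULL,
                                 rules = sampling_rules(), B = 500,
                                 cases = rules$case, n_per_group = 1500,
                                 seed = 1, ...) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  if (is.null(dataset)) {
    dataset <- simulate_curves(n_per_group = n_per_group,
                               seed = child_seed(seed, 0))
  }
  rules <- rules[rules$case %in% cases, ]
  results <- purrr::pmap(rules, function(case, clusters, probs, K, length) {
    run_case_validation(
      dataset, probs = probs, clusters = clusters, B = B, length = length,
      case_id = case, seed = child_seed(seed, case), ...
    )
  })
  summary <- summarize_validation(results)
  readr::write_tsv(validation_replicates(results),
                   file.path(outdir, "validation_replicates.tsv"))
  readr::write_tsv(summary, file.path(outdir, "validation_summary.tsv"))
  write_manifest(outdir, "validate",
                 list(B = B, cases = cases, n_per_group = n_per_group,
                      case_seeds = vapply(cases, function(i) child_seed(seed, i),
                                          integer(1))),
                 seed)
  message(sprintf("validate: %d cases x %d replicates", nrow(rules), B))
  invisible(summary)
}
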