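#' Configure a simulation grid
#'
#' A run configuration fixes everything a replicate grid needs: the datasets
#' (paths to corpus files or [synthetic_spec()]s), the prior fractions, the
#' number of replicates per dataset x fraction cell, the base seed and the
#' screener settings. The seed of replicate `k` at fraction `j` of dataset
#' `i` is `mix_seed(base_seed, i, j, k)`, so every cell is independently
#' reproducible.
#'
#' @param datasets Named list; each element a [synthetic_spec()] or a file
#'   path readable by [read_labeled_corpus()].
#' @param prior_fractions Numeric vector in (0, 1). Default: the seven
#'   levels 1%, 5%, 10%, 15%, 20%, 25% and 30%.
#' @param replicates Independent simulations per cell (default 1000).
#' @param base_seed Integer base seed.
#' @param retrain_every,alpha,prior_policy Screener settings, see
#'   [simulate_screening()].
#' @return A `run_config` list.
#' @export
run_config <- function(datasets,
                       prior_fractions = c(0.01, 0.05, 0.10, 0.15, 0.20, 0.25, 0.30),
                       replicates = 1000L,
                       base_seed = 1L,
                       retrain_every = 1L,
                       alpha = 1,
                       prior_policy = "resample") {
  if (is.null(names(datasets)) || any(names(datasets) == "")) {
    stop("datasets must be a named list")
  }
  if (replicates < 1) stop("replicates must be >= 1")
  if (any(prior_fractions <= 0 | prior_fractions >= 1)) {
    stop("prior fractions must lie in (0, 1)")
  }
  structure(list(datasets = datasets, prior_fractions = prior_fractions,
                 replicates = as.integer(replicates),
                 base_seed = as.integer(base_seed),
                 retrain_every = as.integer(retrain_every), alpha = alpha,
                 prior_policy = prior_policy),
            class = "run_config")
}

#' Demonstration-scale configuration
#'
#' A desk-scale grid exercising the whole pipeline in minutes: two synthetic
#' datasets of 500 records at the prevalence extremes of the study corpora
#' (1.0% and 7.6%), three prior fractions (1%, 10%, 30%) and 20 replicates
#' per cell. The full study-scale grid (five datasets, seven fractions,
#' 1,000 replicates) is configuration, not code.
#'
#' @param base_seed Integer base seed.
#' @param replicates Replicates per cell.
#' @return A `run_config`.
#' @export
demo_run_config <- function(base_seed = 1L, replicates = 20L) {
  run_config(
    datasets = list(
      lowprev = synthetic_spec(N = 500, prevalence_pct = 1.0,
                               seed = mix_seed(base_seed, 101)),
      highprev = synthetic_spec(N = 500, prevalence_pct = 7.6,
                                seed = mix_seed(base_seed, 102))
    ),
    prior_fractions = c(0.01, 0.10, 0.30),
    replicates = replicates,
    base_seed = base_seed
  )
}

#' Expected number of trajectories of a configuration
#'
#' @param config A `run_config`.
#' @return `|datasets| * |fractions| * replicates`.
#' @export
grid_size <- function(config) {
  length(config$datasets) * length(config$prior_fractions) * config$replicates
}

load_dataset <- function(x, name) {
  co <- if (inherits(x, "synthetic_spec")) generate_corpus(x)
        else read_labeled_corpus(x)
  attr(co, "dataset_name") <- name
  check_screenable(co)
  co
}

#' Run the full replicate grid
#'
#' Simulates every dataset x prior-fraction x replicate cell of the
#' configuration, evaluates each trajectory, and writes per-cell statistics
#' plus a manifest under `out_dir`. Cells whose output file already exists
#' with the expected row count are skipped, so an interrupted run resumes
#' without recomputing completed cells (every cell is fully determined by
#' its own seeds).
#'
#' Outputs under `out_dir`: `cells/<dataset>_f<pct>.csv` (one row per run,
#' the columns of [trajectory_stats()]) and `manifest.json` (configuration
#' echo, seeds, grid-cardinality assertion, per-cell completion).
#'
#' @param config A [run_config()].
#' @param out_dir Output directory (created if needed).
#' @param quiet Suppress per-cell progress lines on stderr.
#' @return Tibble of all per-run statistics, invisibly; also on disk.
#' @export
run_grid <- function(config, out_dir, quiet = FALSE) {
  stopifnot(inherits(config, "run_config"))
  dir.create(file.path(out_dir, "cells"), recursive = TRUE, showWarnings = FALSE)
  corpora <- lapply(seq_along(config$datasets), function(i) {
    load_dataset(config$datasets[[i]], names(config$datasets)[i])
  })
  feats <- lapply(corpora, featurize)
  cells <- list()
  for (i in seq_along(corpora)) {
    dname <- names(config$datasets)[i]
    for (j in seq_along(config$prior_fractions)) {
      f <- config$prior_fractions[j]
      cell_file <- file.path(out_dir, "cells",
                             sprintf("%s_f%02d.csv", dname, round(f * 100)))
      done <- file.exists(cell_file) &&
        nrow(readr::read_csv(cell_file, show_col_types = FALSE,
                             progress = FALSE)) == config$replicates
      if (!done) {
        if (!quiet) {
          message(sprintf("[%s] cell %s f=%g: %d replicates",
                          format(Sys.time(), "%H:%M:%S"), dname, f,
                          config$replicates))
        }
        rows <- lapply(seq_len(config$replicates), function(k) {
          traj <- simulate_screening(
            corpora[[i]], f = f, seed = mix_seed(config$base_seed, i, j, k),
            retrain_every = config$retrain_every, alpha = config$alpha,
            prior_policy = config$prior_policy, features = feats[[i]]
          )
          trajectory_stats(traj)
        })
        readr::write_csv(dplyr::bind_rows(rows), cell_file, progress = FALSE)
      }
      cells[[length(cells) + 1]] <- readr::read_csv(
        cell_file, show_col_types = FALSE, progress = FALSE,
        col_types = readr::cols(dataset = readr::col_character(),
                                c1_outcome = readr::col_character())
      )
    }
  }
  stats <- dplyr::bind_rows(cells)
  stopifnot(nrow(stats) == grid_size(config))
  manifest <- list(
    config = config_echo(config),
    config_hash = rlang::hash(config_echo(config)),
    n_trajectories = nrow(stats),
    grid_size_expected = grid_size(config),
    cells = unique(stats[c("dataset", "f")]),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z")
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(stats)
}

config_echo <- function(config) {
  list(
    datasets = lapply(config$datasets, function(d) {
      if (inherits(d, "synthetic_spec")) unclass(d) else as.character(d)
    }),
    prior_fractions = config$prior_fractions,
    replicates = config$replicates,
    base_seed = config$base_seed,
    retrain_every = config$retrain_every,
    alpha = config$alpha,
    prior_policy = config$prior_policy
  )
}

#' Summarize a completed grid run
#'
#' Builds the three report tables and the estimate-outcome shares from the
#' per-run statistics of [run_grid()] and writes them as plain text and CSV
#' under `out_dir` (`table3.txt`, `table4.txt`, `table5.txt`,
#' `c1_outcome_shares.csv`, `run_stats.csv`).
#'
#' @param stats Per-run statistics tibble from [run_grid()].
#' @param out_dir Output directory.
#' @return List with elements `t3`, `t4`, `t5` (character line vectors) and
#'   `shares` (tibble), invisibly; also on disk.
#' @export
report_grid <- function(stats, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  t3 <- render_tables(stats, "t3", file.path(out_dir, "table3.txt"))
  t4 <- render_tables(stats, "t4", file.path(out_dir, "table4.txt"))
  t5 <- render_tables(stats, "t5", file.path(out_dir, "table5.txt"))
  shares <- c1_outcome_shares(stats)
  readr::write_csv(shares, file.path(out_dir, "c1_outcome_shares.csv"),
                   progress = FALSE)
  readr::write_csv(stats, file.path(out_dir, "run_stats.csv"), progress = FALSE)
  invisible(list(t3 = t3, t4 = t4, t5 = t5, shares = shares))
}
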