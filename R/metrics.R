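#' Percent of the dataset screened until the last relevant record
#'
#' The theoretical upper bound of savings for one run: the 1-based position
#' of the final relevant record in the trajectory (prior phase included),
#' expressed as a percentage of the dataset size. A screen stopped at
#' exactly this fraction finds every relevant record; any earlier stop
#' misses at least one. Bounded below by `100 * R / N` (one cannot finish
#' before screening at least `R` records).
#'
#' @param traj A `screen_trajectory` with `R >= 1`.
#' @return Percentage in `(0, 100]`.
#' @export
pct_to_last_relevant <- function(traj) {
  if (traj$R < 1) stop("trajectory has no relevant records")
  last <- max(which(traj$label == 1L))
  last / traj$N * 100
}

#' Per-trajectory evaluation statistics
#'
#' Computes, for one recorded screening run, every statistic the replicate
#' grid aggregates: the screened-percent-to-last-relevant, the largest
#' interior irrelevant gap (count and percent, active-phase scope), the
#' relevant-count estimate extrapolated from the run's own prior sample,
#' its relative error and outcome category.
#'
#' @param traj A `screen_trajectory` carrying its prior-sample statistics.
#' @return One-row tibble.
#' @export
trajectory_stats <- function(traj) {
  gap <- minimal_safe_streak(traj)
  R_hat <- estimate_relevant_total(traj$n_s, traj$r_s, traj$N)
  tibble::tibble(
    dataset = traj$dataset,
    f = traj$f,
    seed = traj$seed,
    N = traj$N,
    R = traj$R,
    n_s = traj$n_s,
    r_s = traj$r_s,
    resamples = traj$resamples,
    pct_to_last_relevant = pct_to_last_relevant(traj),
    g = gap$g,
    g_pct = gap$g_pct,
    R_hat = R_hat,
    relative_error_pct = relative_estimation_error(R_hat, traj$R),
    c1_outcome = classify_c1_outcome(R_hat, traj$R)
  )
}

#' Replicate-grid aggregates
#'
#' Min / max / mean / sample standard deviation (n - 1 denominator) of one
#' statistic per group, the layout of the study's summary tables.
#'
#' @param stats Data frame of per-run statistics (e.g. rows of
#'   [trajectory_stats()]).
#' @param value Name of the statistic column to aggregate.
#' @param by Character vector of grouping columns (default dataset).
#' @return Tibble with the grouping columns plus `n_runs`, `min`, `max`,
#'   `mean`, `sd`.
#' @export
aggregate_stats <- function(stats, value, by = "dataset") {
  if (nrow(stats) == 0) stop("no rows to aggregate")
  stats |>
    dplyr::group_by(dplyr::across(dplyr::all_of(by))) |>
    dplyr::summarise(
      n_runs = dplyr::n(),
      min = min(.data[[value]]),
      max = max(.data[[value]]),
      mean = mean(.data[[value]]),
      sd = stats::sd(.data[[value]]),
      .groups = "drop"
    )
}

#' Outcome shares of the count-based stop rule
#'
#' Share of runs (in percent) falling in each estimate-outcome category.
#'
#' @param stats Data frame with a `c1_outcome` column.
#' @return Tibble with columns `outcome`, `n`, `share_pct`, covering all
#'   four categories (zero-filled); shares sum to 100.
#' @export
c1_outcome_shares <- function(stats) {
  if (nrow(stats) == 0) stop("no rows")
  lev <- c("overestimate", "exact", "miss_one", "miss_many")
  n <- unname(vapply(lev, function(l) sum(stats$c1_outcome == l), integer(1)))
  tibble::tibble(outcome = lev, n = n, share_pct = n / sum(n) * 100)
}

#' Render a plain-text report table
#'
#' Formats grid aggregates into the three report layouts: `"t3"` — mean and
#' SD of the relative estimation error per dataset and prior fraction, plus
#' a `Total` row pooling all runs; `"t4"` — min/max/mean/SD of the screened
#' percent to the last relevant record per dataset; `"t5"` — the same for
#' the largest irrelevant gap in percent. All values one-decimal. Rendering
#' is deterministic: identical input gives a byte-identical file.
#'
#' @param stats Per-run statistics (rows of [trajectory_stats()]).
#' @param table `"t3"`, `"t4"` or `"t5"`.
#' @param path Optional output file; when `NULL` the lines are returned.
#' @param fractions For `"t3"`, the expected prior fractions (defaults to
#'   those present); an incomplete dataset x fraction grid is an error.
#' @return Character vector of table lines, invisibly if written to `path`.
#' @export
render_tables <- function(stats, table = c("t3", "t4", "t5"), path = NULL,
                          fractions = NULL) {
  table <- match.arg(table)
  fmt <- function(x) sprintf("%.1f", round_half_up(x, 1))
  lines <- if (table == "t3") {
    fr <- sort(fractions %||% unique(stats$f))
    datasets <- unique(stats$dataset)
    have <- unique(stats[c("dataset", "f")])
    want <- expand.grid(dataset = datasets, f = fr, stringsAsFactors = FALSE)
    holes <- dplyr::anti_join(want, have, by = c("dataset", "f"))
    if (nrow(holes) > 0) {
      stop("incomplete grid; missing cells: ",
           paste(sprintf("(%s, f=%g)", holes$dataset, holes$f), collapse = ", "))
    }
    agg <- aggregate_stats(stats, "relative_error_pct", by = c("dataset", "f"))
    header <- c("Relative error of estimated relevant count (%), by prior fraction",
                paste(c(sprintf("%-24s", "Dataset"),
                        sprintf("%8s %8s", paste0("M@", fr * 100, "%"), "SD")),
                      collapse = " "))
    body <- vapply(datasets, function(d) {
      row <- agg[agg$dataset == d, ][match(fr, agg$f[agg$dataset == d]), ]
      paste(c(sprintf("%-24s", d),
              sprintf("%8s %8s", fmt(row$mean), fmt(row$sd))), collapse = " ")
    }, character(1))
    tot <- paste(c(sprintf("%-24s", "Total"), vapply(fr, function(ff) {
      v <- stats$relative_error_pct[stats$f == ff]
      sprintf("%8s %8s", fmt(mean(v)), fmt(stats::sd(v)))
    }, character(1))), collapse = " ")
    c(header, body, tot)
  } else {
    value <- if (table == "t4") "pct_to_last_relevant" else "g_pct"
    title <- if (table == "t4") {
      "Screening percentage to identify all relevant records, per dataset"
    } else {
      "Largest irrelevant gap between relevant records (% of dataset), per dataset"
    }
    agg <- aggregate_stats(stats, value, by = "dataset")
    c(title,
      sprintf("%-24s %6s %8s %8s %8s %8s", "Dataset", "n", "Min", "Max",
              "Mean", "SD"),
      vapply(seq_len(nrow(agg)), function(i) {
        sprintf("%-24s %6d %8s %8s %8s %8s", agg$dataset[i], agg$n_runs[i],
                fmt(agg$min[i]), fmt(agg$max[i]), fmt(agg$mean[i]),
                fmt(agg$sd[i]))
      }, character(1)))
  }
  if (!is.null(path)) {
    writeLines(lines, path)
    return(invisible(lines))
  }
  lines
}
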