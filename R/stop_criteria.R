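new_stop_outcome <- function(stop_index, triggered, traj) {
  found <- sum(traj$label[seq_len(stop_index)])
  structure(list(
    stop_index = as.integer(stop_index),
    triggered = triggered,
    found_relevant = as.integer(found),
    missed = as.integer(traj$R - found),
    recall = if (traj$R > 0) found / traj$R else 1,
    work_saved_pct = (1 - stop_index / traj$N) * 100
  ), class = "stop_outcome")
}

#' @exportS3Method base::print
print.stop_outcome <- function(x, ...) {
  cat(sprintf(
    "<stop_outcome> stop at %d (%s), recall %.3f, missed %d, work saved %.1f%%\n",
    x$stop_index, if (x$triggered) "triggered" else "never fired",
    x$recall, x$missed, x$work_saved_pct))
  invisible(x)
}

#' Extrapolate the total number of relevant records from a sample
#'
#' The estimator behind the count-based stop rule: if `r_s` of `n_s`
#' randomly sampled records are relevant, the full dataset of `N` records is
#' estimated to hold `round(r_s / n_s * N)` relevant records (half-up
#' rounding). E.g. 5 relevant among a sample of 100 from 10,000 records
#' extrapolates to 500.
#'
#' @param n_s Sample size (>= 1).
#' @param r_s Relevant records in the sample.
#' @param N Dataset size.
#' @return Integer estimate `R_hat`.
#' @export
estimate_relevant_total <- function(n_s, r_s, N) {
  if (n_s < 1) stop("n_s must be >= 1")
  if (r_s < 0 || r_s > n_s) stop("need 0 <= r_s <= n_s")
  as.integer(round_half_up(r_s / n_s * N))
}

#' Stop criterion 1: stop at the estimated number of relevant records
#'
#' Halts the screen at the first position where the cumulative count of
#' relevant records reaches `R_hat`. An estimate of 0 fires before any
#' record is screened (stop index 0); an estimate above the true `R` never
#' fires and the full dataset is screened.
#'
#' @param traj A `screen_trajectory`.
#' @param R_hat Estimated total number of relevant records (>= 0).
#' @return A `stop_outcome`.
#' @export
apply_criterion1 <- function(traj, R_hat) {
  if (R_hat < 0) stop("R_hat must be >= 0")
  if (R_hat == 0) return(new_stop_outcome(0L, TRUE, traj))
  cum <- cumsum(traj$label)
  hit <- which(cum >= R_hat)
  if (length(hit) == 0) new_stop_outcome(traj$N, FALSE, traj)
  else new_stop_outcome(hit[1], TRUE, traj)
}

#' Stop criterion 2: stop after a run of consecutive irrelevant records
#'
#' Halts when `c` irrelevant records have been screened in succession
#' without a relevant record between them; the streak resets on every
#' relevant record. With `scope = "active-only"` (default) streak counting
#' starts after the prior phase — runs inside the randomly ordered prior
#' sample say nothing about the ranker; `scope = "full"` counts from the
#' first screened record.
#'
#' @param traj A `screen_trajectory`.
#' @param c Consecutive-irrelevant threshold (>= 1).
#' @param scope `"active-only"` or `"full"`.
#' @return A `stop_outcome`; `stop_index = N` if the streak never occurs.
#' @export
apply_criterion2 <- function(traj, c, scope = c("active-only", "full")) {
  scope <- match.arg(scope)
  if (c < 1) stop("c must be >= 1")
  start <- if (scope == "active-only") traj$prior_len + 1L else 1L
  streak <- 0L
  if (start <= traj$N) {
    for (i in start:traj$N) {
      streak <- if (traj$label[i] == 0L) streak + 1L else 0L
      if (streak >= c) return(new_stop_outcome(i, TRUE, traj))
    }
  }
  new_stop_outcome(traj$N, FALSE, traj)
}

#' Stop criterion 3: stop after a fixed fraction of the dataset
#'
#' Halts once `ceiling(p * N)` records have been screened, prior phase
#' included.
#'
#' @param traj A `screen_trajectory`.
#' @param p Screened-fraction threshold in (0, 1].
#' @return A `stop_outcome`.
#' @export
apply_criterion3 <- function(traj, p) {
  if (p <= 0 || p > 1) stop("p must be in (0, 1]")
  new_stop_outcome(as.integer(ceiling(p * traj$N)), TRUE, traj)
}

#' Largest irrelevant gap between relevant records
#'
#' The per-run break-even of the consecutive-irrelevant stop rule: `g` is
#' the longest run of irrelevant records occurring strictly between two
#' relevant records in the trajectory (runs before the first and after the
#' last relevant are excluded, matching how the gap is defined for a ranked
#' screen). A threshold of `g + 1` never fires inside any interior gap and
#' so misses nothing on this trajectory (provided the run preceding the
#' first counted relevant is shorter than the threshold), while `g` fires
#' inside the widest gap and misses at least one record.
#'
#' With `scope = "active-only"` (default) the gap is measured over the
#' model-ranked phase only, mirroring [apply_criterion2()]'s default.
#'
#' @param traj A `screen_trajectory` with at least one relevant record.
#' @param scope `"active-only"` or `"full"`.
#' @return List with `g` (count) and `g_pct` (`g / N * 100`). If the scoped
#'   label sequence holds fewer than two relevant records, `g = 0`.
#' @export
minimal_safe_streak <- function(traj, scope = c("active-only", "full")) {
  scope <- match.arg(scope)
  if (traj$R < 1) stop("trajectory has no relevant records")
  start <- if (scope == "active-only") traj$prior_len + 1L else 1L
  lab <- if (start <= traj$N) traj$label[start:traj$N] else integer(0)
  g <- interior_gap(lab)
  list(g = g, g_pct = g / traj$N * 100)
}

# longest zero-run strictly between two ones
interior_gap <- function(lab) {
  ones <- which(lab == 1L)
  if (length(ones) < 2) return(0L)
  as.integer(max(diff(ones)) - 1L)
}

#' Classify a count-estimate outcome
#'
#' Categorizes the count-based stop rule's estimate against the true number
#' of relevant records: `overestimate` (`R_hat > R`, the rule never fires
#' early), `exact` (`R_hat = R`, the only reliable case), `miss_one`
#' (`R_hat = R - 1`, one record erroneously excluded) or `miss_many`
#' (`R_hat < R - 1`).
#'
#' @param R_hat Estimated relevant count.
#' @param R True relevant count (>= 1).
#' @return One of `"overestimate"`, `"exact"`, `"miss_one"`, `"miss_many"`.
#' @export
classify_c1_outcome <- function(R_hat, R) {
  if (R < 1) stop("R must be >= 1")
  if (R_hat > R) "overestimate"
  else if (R_hat == R) "exact"
  else if (R_hat == R - 1) "miss_one"
  else "miss_many"
}

#' Relative estimation error of the relevant-count extrapolation
#'
#' `(R_hat - R) / R * 100`: positive means the sample extrapolation assumed
#' more relevant records than exist (the rule never stops early), negative
#' means relevant records would be erroneously excluded.
#'
#' @param R_hat Estimated relevant count.
#' @param R True relevant count (>= 1).
#' @return Percentage error.
#' @export
relative_estimation_error <- function(R_hat, R) {
  if (R < 1) stop("R must be >= 1")
  (R_hat - R) / R * 100
}
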