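# Evaluation against manual labels, mirroring the two-step protocol used to
# validate feeder-camera pipelines: (1) compare the number of distinct heads
# seen in the tracking area with the labeled count; (2) compare estimated
# feeding time with labeled feeding frames, overall and visit by visit.
# Accuracy is 100 * (1 - relative absolute error), clamped at 0 -- the
# simplest formula consistent with count-versus-count comparison; the visit
# matching is greedy by frame overlap. Both conventions are this package's
# choices and are stated in every report.

.bt_rel_acc <- function(est, truth) {
  100 * max(0, 1 - abs(est - truth) / truth)
}

#' Head-count accuracy
#'
#' @param estimated Number of distinct identities the pipeline produced.
#' @param truth Labeled number of distinct heads; must be positive.
#' @return Percent in `[0, 100]`: `100 * max(0, 1 - |est - truth| / truth)`.
#' @export
head_count_accuracy <- function(estimated, truth) {
  if (truth <= 0) stop("true head count must be positive")
  .bt_rel_acc(estimated, truth)
}

#' Overall feeding-time accuracy
#'
#' @param estimated_total_s Estimated total feeding time, seconds.
#' @param true_total_s Labeled total feeding time, seconds; must be positive.
#' @return Percent in `[0, 100]`.
#' @export
overall_time_accuracy <- function(estimated_total_s, true_total_s) {
  if (true_total_s <= 0) stop("true total feeding time must be positive")
  .bt_rel_acc(estimated_total_s, true_total_s)
}

#' Per-visit feeding-time accuracy
#'
#' Estimated visits are matched to labeled visits greedily by maximal
#' frame-interval overlap (each visit used at most once; ties broken by the
#' earlier true start, then the earlier estimated start). Each matched pair
#' scores `100 * max(0, 1 - |est_dur - true_dur| / true_dur)`; unmatched true
#' visits score 0. The result is the mean over all true visits.
#'
#' @param est_visits Estimated visit table (`start_frame`, `end_frame`,
#'   `duration_s`).
#' @param true_visits Ground-truth intervals (`start_frame`, `end_frame`,
#'   0-based inclusive).
#' @param fps Frames per second, to convert true intervals to seconds.
#' @return Percent in `[0, 100]`.
#' @export
per_visit_time_accuracy <- function(est_visits, true_visits, fps) {
  if (nrow(true_visits) == 0) stop("at least one true visit is required")
  if (fps <= 0) stop("fps must be positive")
  true_dur <- (true_visits$end_frame - true_visits$start_frame + 1) / fps
  scores <- numeric(nrow(true_visits))
  if (nrow(est_visits)) {
    ov <- outer(seq_len(nrow(true_visits)), seq_len(nrow(est_visits)),
                function(i, j) {
                  pmax(0, pmin(true_visits$end_frame[i],
                               est_visits$end_frame[j]) -
                          pmax(true_visits$start_frame[i],
                               est_visits$start_frame[j]) + 1)
                })
    cand <- which(ov > 0, arr.ind = TRUE)
    if (nrow(cand)) {
      ord <- order(-ov[cand],
                   true_visits$start_frame[cand[, 1]],
                   est_visits$start_frame[cand[, 2]])
      used_t <- logical(nrow(true_visits))
      used_e <- logical(nrow(est_visits))
      for (k in ord) {
        ti <- cand[k, 1]; ei <- cand[k, 2]
        if (used_t[ti] || used_e[ei]) next
        used_t[ti] <- TRUE; used_e[ei] <- TRUE
        scores[ti] <- 100 * max(0, 1 - abs(est_visits$duration_s[ei] -
                                             true_dur[ti]) / true_dur[ti])
      }
    }
  }
  mean(scores)
}

#' Mean visit duration
#'
#' @param visits Visit table with a `duration_s` column; must be non-empty.
#' @return Arithmetic mean of `duration_s`, seconds.
#' @export
mean_duration_per_visit <- function(visits) {
  if (nrow(visits) == 0) stop("no visits to average")
  mean(visits$duration_s)
}

#' Evaluate a pipeline run against ground truth
#'
#' @param est_visits Estimated visit table ([segment_all_visits()] output).
#' @param est_head_count Number of distinct identities produced.
#' @param true_visits Labeled intervals (`bird_id`, `start_frame`,
#'   `end_frame`).
#' @param true_head_count Labeled number of distinct heads.
#' @param fps Frames per second.
#' @return An object of class `bt_eval_report`: `head_count_accuracy`,
#'   `overall_time_accuracy`, `per_visit_time_accuracy`,
#'   `mean_duration_per_visit_s`, counts, and the accuracy conventions used.
#' @export
evaluate_run <- function(est_visits, est_head_count, true_visits,
                         true_head_count, fps) {
  est_total <- sum(est_visits$duration_s)
  true_total <- sum(true_visits$end_frame - true_visits$start_frame + 1) / fps
  structure(list(
    head_count_accuracy = head_count_accuracy(est_head_count,
                                              true_head_count),
    overall_time_accuracy = overall_time_accuracy(est_total, true_total),
    per_visit_time_accuracy = per_visit_time_accuracy(est_visits,
                                                      true_visits, fps),
    mean_duration_per_visit_s = if (nrow(est_visits))
      mean_duration_per_visit(est_visits) else NA_real_,
    est_head_count = est_head_count, true_head_count = true_head_count,
    est_total_s = est_total, true_total_s = true_total,
    n_est_visits = nrow(est_visits), n_true_visits = nrow(true_visits),
    conventions = paste("accuracy = 100*(1 - relative absolute error),",
                        "clamped at 0; visits matched greedily by maximal",
                        "frame overlap")),
    class = "bt_eval_report")
}

#' @export
print.bt_eval_report <- function(x, ...) {
  cat("Feeding-time evaluation\n")
  cat(sprintf("  head-count accuracy:      %6.1f %% (%d est / %d true)\n",
              x$head_count_accuracy, x$est_head_count, x$true_head_count))
  cat(sprintf("  overall time accuracy:    %6.1f %% (%.2f s est / %.2f s true)\n",
              x$overall_time_accuracy, x$est_total_s, x$true_total_s))
  cat(sprintf("  per-visit time accuracy:  %6.1f %% (%d est / %d true visits)\n",
              x$per_visit_time_accuracy, x$n_est_visits, x$n_true_visits))
  if (!is.na(x$mean_duration_per_visit_s))
    cat(sprintf("  mean duration per visit:  %6.2f s\n",
                x$mean_duration_per_visit_s))
  invisible(x)
}
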