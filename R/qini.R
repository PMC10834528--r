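#' Qini curve of an uplift scoring
#'
#' Subjects are ranked by descending uplift score. At a threshold `phi`, with
#' `S_T, S_C` the cumulative successes and `N_T, N_C` the cumulative counts
#' among subjects scoring `>= phi` in each arm, the curve plots the
#' incremental success `S_T - S_C * N_T / N_C` against rank. Until the first
#' control subject enters (`N_C = 0`) the control correction is undefined and
#' the curve equals `S_T`, the limit of the formula; such points are flagged.
#' The diagonal is the chord from (0, 0) to (n, final incremental success) —
#' the incremental success expected if treatment effect were homogeneous
#' across the ranking (random allocation of the targeting).
#'
#' Tied scores are processed as a block and the curve is evaluated only at
#' block boundaries, so the result is invariant to the ordering of tied
#' subjects.
#'
#' @param scores Numeric uplift scores, one per subject.
#' @param arms `"treatment"`/`"control"` per subject.
#' @param successes Binary 0/1 per subject.
#' @return A `qini_curve` data.frame with columns `rank`, `threshold_phi`,
#'   `s_t`, `s_c`, `n_t`, `n_c`, `qini_value`, `diagonal_value`,
#'   `control_prefix` (logical: `n_c == 0`); attribute `n_total`.
#' @export
compute_qini_curve <- function(scores, arms, successes) {
  n <- length(scores)
  stopifnot(length(arms) == n, length(successes) == n, n >= 1,
            all(arms %in% c("treatment", "control")),
            all(successes %in% c(0, 1)))
  if (!any(arms == "treatment") || !any(arms == "control"))
    stop("both arms must be present to build a Qini curve", call. = FALSE)

  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  trt <- arms[ord] == "treatment"
  y <- successes[ord]

  n_t <- cumsum(trt)
  n_c <- cumsum(!trt)
  s_t <- cumsum(y * trt)
  s_c <- cumsum(y * !trt)

  # block boundaries: last position of each run of equal scores
  ends <- which(c(s[-1] != s[-n], TRUE))

  q <- ifelse(n_c[ends] == 0, s_t[ends],
              s_t[ends] - s_c[ends] * n_t[ends] / n_c[ends])
  final_q <- q[length(q)]
  out <- data.frame(rank = ends,
                    threshold_phi = s[ends],
                    s_t = s_t[ends], s_c = s_c[ends],
                    n_t = n_t[ends], n_c = n_c[ends],
                    qini_value = q,
                    diagonal_value = ends / n * final_q,
                    control_prefix = n_c[ends] == 0)
  attr(out, "n_total") <- n
  class(out) <- c("qini_curve", "data.frame")
  out
}

#' Qini coefficient: signed area between curve and diagonal
#'
#' Trapezoidal integral over rank of `qini_value - diagonal_value`, starting
#' from the implicit origin (0, 0). Positive when the scoring concentrates
#' treatment benefit in the top ranks better than random allocation. The raw
#' (unnormalized) area is returned; `normalize = TRUE` divides by the number
#' of subjects for cross-cohort comparison.
#'
#' @param points A `qini_curve`.
#' @param normalize Divide the area by the cohort size? Default `FALSE`.
#' @return Numeric coefficient.
#' @export
qini_coefficient <- function(points, normalize = FALSE) {
  stopifnot(inherits(points, "qini_curve"), nrow(points) >= 1)
  x <- c(0, points$rank)
  d <- c(0, points$qini_value - points$diagonal_value)
  area <- sum(diff(x) * (d[-1] + d[-length(d)]) / 2)
  if (normalize) area / attr(points, "n_total") else area
}

#' Optimal uplift-score cutoff from a Qini curve
#'
#' The cutoff is the score at the rank maximizing the curve's lead over the
#' diagonal, `qini_value - diagonal_value`; ties break toward the smaller
#' rank (the stricter cutoff). When the maximum lead is not positive, no
#' score stratum beats random targeting: the returned cutoff is `+Inf`
#' (selecting nobody) with attribute `no_benefit = TRUE`.
#'
#' @param points A `qini_curve`.
#' @return Numeric cutoff `phi*` with attributes `no_benefit` (logical) and,
#'   when benefit exists, `rank` (the maximizing rank).
#' @export
select_optimal_cutoff <- function(points) {
  stopifnot(inherits(points, "qini_curve"), nrow(points) >= 1)
  lead <- points$qini_value - points$diagonal_value
  i <- which.max(lead)  # first maximum = smallest rank
  if (lead[i] <= 0)
    return(structure(Inf, no_benefit = TRUE))
  structure(points$threshold_phi[i], no_benefit = FALSE,
            rank = points$rank[i])
}

#' Summarize an uplift scoring on a validation cohort
#'
#' Convenience wrapper building the Qini curve, coefficient and optimal
#' cutoff for one candidate model.
#'
#' @param scores Numeric uplift scores.
#' @param arms,successes Per-subject arm and success indicators.
#' @param classifier_id Candidate label carried through model selection.
#' @return A `qini_summary` list: `points`, `qini_coefficient`,
#'   `optimal_cutoff`, `classifier_id`.
#' @export
qini_summary <- function(scores, arms, successes, classifier_id = NA_character_) {
  points <- compute_qini_curve(scores, arms, successes)
  structure(list(points = points,
                 qini_coefficient = qini_coefficient(points),
                 optimal_cutoff = select_optimal_cutoff(points),
                 classifier_id = classifier_id),
            class = "qini_summary")
}

#' @export
print.qini_summary <- function(x, ...) {
  cat("qini_summary:", x$classifier_id,
      sprintf("| coefficient %.4f | cutoff %s\n", x$qini_coefficient,
              if (isTRUE(attr(x$optimal_cutoff, "no_benefit"))) "no-benefit"
              else format(as.numeric(x$optimal_cutoff), digits = 4)))
  invisible(x)
}

#' Select the best-performing candidate by Qini coefficient
#'
#' Argmax of the Qini coefficient across candidates evaluated on the same
#' validation cohort; exact ties break deterministically by classifier
#' registry order.
#'
#' @param summaries List of `qini_summary` objects.
#' @return The `classifier_id` of the winner.
#' @export
select_best_model <- function(summaries) {
  if (length(summaries) == 0) stop("no candidate summaries", call. = FALSE)
  stopifnot(all(vapply(summaries, inherits, logical(1), "qini_summary")))
  coefs <- vapply(summaries, `[[`, numeric(1), "qini_coefficient")
  ids <- vapply(summaries, `[[`, character(1), "classifier_id")
  reg_pos <- match(ids, available_classifiers()$id)
  reg_pos[is.na(reg_pos)] <- Inf
  best <- order(-coefs, reg_pos)[1]
  unname(ids[best])
}

#' Plot Qini curves of one or more candidates
#'
#' Rank on the horizontal axis (descending-score order), cumulative
#' incremental success on the vertical; the dashed diagonal is the
#' random-allocation reference.
#'
#' @param summaries A `qini_summary` or list of them.
#' @param main Plot title.
#' @return Invisibly, `NULL`.
#' @export
plot_qini_curves <- function(summaries, main = "Qini curves") {
  if (inherits(summaries, "qini_summary")) summaries <- list(summaries)
  all_pts <- lapply(summaries, `[[`, "points")
  ymax <- max(vapply(all_pts, function(p) max(p$qini_value, 0), numeric(1)))
  ymin <- min(vapply(all_pts, function(p) min(p$qini_value, 0), numeric(1)))
  xmax <- max(vapply(all_pts, function(p) max(p$rank), numeric(1)))
  graphics::plot(NULL, xlim = c(0, xmax), ylim = c(ymin, ymax),
                 xlab = "rank (descending uplift score)",
                 ylab = "cumulative incremental success", main = main)
  for (i in seq_along(summaries)) {
    p <- all_pts[[i]]
    graphics::lines(c(0, p$rank), c(0, p$qini_value), col = i, lwd = 2)
  }
  p1 <- all_pts[[1]]
  graphics::segments(0, 0, max(p1$rank),
                     p1$qini_value[nrow(p1)], lty = 2, col = "grey40")
  ids <- vapply(summaries, function(s) s$classifier_id %||% "?", character(1))
  graphics::legend("topleft", legend = ids, col = seq_along(summaries),
                   lwd = 2, bty = "n", cex = 0.8)
  invisible(NULL)
}

#' Export a Qini curve as CSV
#' @param points A `qini_curve`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_qini_curve <- function(points, path) {
  utils::write.csv(as.data.frame(points), path, row.names = FALSE)
  invisible(path)
}
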