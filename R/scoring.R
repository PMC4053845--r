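#' Metric weight grids explored when ranking tools
#'
#' Candidate integer weights per metric: correct joins 10/20/40/80/160,
#' incorrect ("bad") joins 10/20/40/80/160, lost tags 20/40/80/160, skipped
#' tags 10/20/40/80/160, total CPU time 1-5.
#'
#' @return A named list of integer vectors in the metric order
#'   (correct, incorrect, lost, skipped, cpu).
#' @export
default_weight_grids <- function() {
  list(correct = c(10L, 20L, 40L, 80L, 160L),
       incorrect = c(10L, 20L, 40L, 80L, 160L),
       lost = c(20L, 40L, 80L, 160L),
       skipped = c(10L, 20L, 40L, 80L, 160L),
       cpu = 1:5)
}

#' The single reference weighting emphasising error penalties
#'
#' Weights 80 (correct joins), 160 (incorrect joins), 160 (lost tags),
#' 40 (skipped tags), 1 (CPU time).
#'
#' @return A named integer weight vector.
#' @export
reference_weighting <- function() {
  weight_vector(80L, 160L, 160L, 40L, 1L)
}

#' Build a five-metric weight vector
#'
#' @param correct,incorrect,lost,skipped,cpu Positive integer weights.
#' @return A named integer vector
#'   (`correct`, `incorrect`, `lost`, `skipped`, `cpu`).
#' @export
weight_vector <- function(correct, incorrect, lost, skipped, cpu) {
  w <- c(correct = correct, incorrect = incorrect, lost = lost,
         skipped = skipped, cpu = cpu)
  if (any(w <= 0) || any(w != as.integer(w))) {
    stop("weights must be positive integers")
  }
  stats::setNames(as.integer(w), names(w))
}

#' Check the accuracy-emphasising weight constraints
#'
#' A weighting is retained only when (1) the incorrect-join ("bad join")
#' weight is at least the correct-join weight, (2) at least twice the
#' skipped-tag weight, and (3) the lost-tag weight is at least the
#' correct-join weight.
#'
#' @param w A [weight_vector()].
#' @return TRUE/FALSE.
#' @export
is_valid_weighting <- function(w) {
  w[["incorrect"]] >= w[["correct"]] &&
    w[["incorrect"]] >= 2 * w[["skipped"]] &&
    w[["lost"]] >= w[["correct"]]
}

.gcd2 <- function(a, b) if (b == 0L) a else .gcd2(b, a %% b)

#' Reduce a weight vector to its canonical (gcd-normalised) form
#'
#' Two weightings that are positive scalar multiples of each other produce
#' identical summary scores; dividing by the greatest common divisor keeps
#' integer arithmetic exact and picks one representative per equivalence
#' class.
#'
#' @param w A [weight_vector()].
#' @return The gcd-normalised weight vector.
#' @export
canonical_weighting <- function(w) {
  d <- Reduce(.gcd2, as.integer(w))
  stats::setNames(as.integer(w) %/% d, names(w))
}

#' Enumerate all valid, canonical weightings over the grids
#'
#' Takes the Cartesian product of the grids, keeps combinations satisfying
#' the three constraints of [is_valid_weighting()], normalises each by its
#' gcd and deduplicates, keeping one canonical representative per scale
#' class, in deterministic (lexicographic) order.
#'
#' @param grids Named list of candidate weights, see
#'   [default_weight_grids()].
#' @return A data.frame with integer columns correct, incorrect, lost,
#'   skipped, cpu; the number of pre-deduplication valid combinations in
#'   attribute `"n_valid"`.
#' @export
enumerate_weightings <- function(grids = default_weight_grids()) {
  stopifnot(identical(names(grids),
                      c("correct", "incorrect", "lost", "skipped", "cpu")),
            all(lengths(grids) > 0))
  g <- expand.grid(grids, KEEP.OUT.ATTRS = FALSE)
  keep <- g$incorrect >= g$correct & g$incorrect >= 2 * g$skipped &
    g$lost >= g$correct
  g <- g[keep, , drop = FALSE]
  n_valid <- nrow(g)
  canon <- t(apply(as.matrix(g), 1L, function(v) {
    d <- Reduce(.gcd2, as.integer(v))
    as.integer(v) %/% d
  }))
  colnames(canon) <- names(grids)
  canon <- unique(as.data.frame(canon))
  canon <- canon[do.call(order, canon), , drop = FALSE]
  rownames(canon) <- NULL
  attr(canon, "n_valid") <- n_valid
  canon
}

#' Min-max scale one metric column across tools
#'
#' The best tool scores 1, the worst 0 and the rest are linearly scaled
#' between them. When all tools tie, every tool scores 1: no tool is worst.
#'
#' @param values Raw metric values (>= 2 finite non-negative numbers).
#' @param direction `"higher_better"` (correct joins) or `"lower_better"`
#'   (incorrect joins, lost tags, skipped tags, CPU time).
#' @return Scores in \[0, 1\], one per value.
#' @export
scale_metric <- function(values, direction = c("higher_better",
                                               "lower_better")) {
  direction <- match.arg(direction)
  if (length(values) < 2L) {
    stop("scaling requires at least two tools")
  }
  if (any(!is.finite(values)) || any(values < 0)) {
    stop("metric values must be finite and non-negative")
  }
  rng <- range(values)
  if (rng[1L] == rng[2L]) return(rep(1, length(values)))
  s <- (values - rng[1L]) / (rng[2L] - rng[1L])
  if (direction == "lower_better") s <- 1 - s
  s
}

#' Weighted summary score of five scaled metrics
#'
#' @param scores Five scaled scores in \[0, 1\], ordered (correct,
#'   incorrect, lost, skipped, cpu).
#' @param w A [weight_vector()].
#' @param check_valid Reject weightings failing [is_valid_weighting()].
#' @return `sum(w * scores) / sum(w)`, a number in \[0, 1\].
#' @export
summary_score <- function(scores, w, check_valid = FALSE) {
  if (length(scores) != 5L || any(!is.finite(scores)) ||
        any(scores < 0 | scores > 1)) {
    stop("scores must be five numbers in [0, 1]")
  }
  if (check_valid && !is_valid_weighting(w)) {
    stop("weighting violates the accuracy constraints")
  }
  sum(w * scores) / sum(w)
}

.METRIC_COLS <- c(correct = "correct_joins", incorrect = "incorrect_joins",
                  lost = "lost_tags", skipped = "skipped_tags",
                  cpu = "cpu_seconds")

#' Scale and score a dataset's metrics table
#'
#' Scales each of the five metric columns across tools ([scale_metric()];
#' correct joins higher-better, the rest lower-better), computes each
#' tool's summary score under every weighting and summarises the resulting
#' distribution (min, quartiles, max), alongside the single summary under
#' the reference weighting. Scoring consumes raw counts, never derived
#' percentages, so a tool that made no joins scores via its zero
#' incorrect/lost/skipped counts.
#'
#' @param metrics data.frame with a `tool` column and the five metric
#'   columns `correct_joins`, `incorrect_joins`, `lost_tags`,
#'   `skipped_tags`, `cpu_seconds`; at least two rows.
#' @param weightings Weightings data.frame from [enumerate_weightings()].
#' @param reference A [weight_vector()] reported separately.
#' @return A `score_table` data.frame: tool, the five scaled scores
#'   (`score_correct`, ...), distribution columns `summary_min`,
#'   `summary_q1`, `summary_median`, `summary_q3`, `summary_max` and
#'   `summary_reference`; the full tools x weightings summary matrix is in
#'   attribute `"summaries"`.
#' @export
score_dataset <- function(metrics, weightings = enumerate_weightings(),
                          reference = reference_weighting()) {
  stopifnot(is.data.frame(metrics), "tool" %in% colnames(metrics),
            all(.METRIC_COLS %in% colnames(metrics)))
  if (nrow(metrics) < 2L) stop("scaling requires at least two tools")
  scaled <- cbind(
    higher_better = scale_metric(metrics[[.METRIC_COLS[["correct"]]]],
                                 "higher_better"),
    vapply(.METRIC_COLS[-1L], function(col) {
      scale_metric(metrics[[col]], "lower_better")
    }, numeric(nrow(metrics))))
  colnames(scaled) <- names(.METRIC_COLS)

  wm <- as.matrix(weightings[, names(.METRIC_COLS)])
  summaries <- scaled %*% t(wm) / rep(rowSums(wm), each = nrow(scaled))
  qs <- t(apply(summaries, 1L, stats::quantile,
                probs = c(0, 0.25, 0.5, 0.75, 1), names = FALSE))
  out <- data.frame(tool = metrics$tool, stringsAsFactors = FALSE)
  for (m in names(.METRIC_COLS)) out[[paste0("score_", m)]] <- scaled[, m]
  out$summary_min <- qs[, 1L]
  out$summary_q1 <- qs[, 2L]
  out$summary_median <- qs[, 3L]
  out$summary_q3 <- qs[, 4L]
  out$summary_max <- qs[, 5L]
  out$summary_reference <- apply(scaled, 1L, summary_score,
                                 w = reference)
  attr(out, "summaries") <- summaries
  class(out) <- c("score_table", class(out))
  out
}

#' Boxplot of summary-score distributions with the reference weighting
#'
#' One box per tool over all weightings, with a white circle marking the
#' summary under the reference weighting.
#'
#' @param scores A `score_table` from [score_dataset()].
#' @param ... Passed to [graphics::boxplot()].
#' @return `scores`, invisibly.
#' @export
plot_score_distribution <- function(scores, ...) {
  summaries <- attr(scores, "summaries")
  if (is.null(summaries)) stop("score table lacks the summaries attribute")
  graphics::boxplot(t(summaries), names = scores$tool, ylim = c(0, 1),
                    ylab = "summary score", las = 2, ...)
  graphics::points(seq_len(nrow(scores)), scores$summary_reference,
                   pch = 21, bg = "white", cex = 1.3)
  invisible(scores)
}
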