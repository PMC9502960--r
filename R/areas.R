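# Physical area measurement and the paired statistics used for area
# comparisons (paired t, Wilcoxon signed rank).

#' Measure lesion areas in physical units
#'
#' One measurement per ROI in the set: the even-odd polygon area in px^2
#' converted to mm^2 through the frame's field of view.
#'
#' @param set an [annotation_set].
#' @param frame an [image_frame] with a physical field of view.
#' @return data.frame with columns eye_id, timepoint, group, grader, label,
#'   area_px, area_mm2 (zero rows for an empty set).
#' @export
measure_areas <- function(set, frame) {
  stopifnot(inherits(set, "annotation_set"), inherits(frame, "image_frame"))
  s <- px_area_mm2(frame)
  if (!is.finite(s) || s <= 0)
    oc_stop("configuration_error", "frame has no usable physical scale")
  rows <- lapply(set$rois, function(r) {
    apx <- polygon_area_px(r)
    data.frame(eye_id = set$eye_id, timepoint = set$timepoint,
               group = set$group, grader = r$grader %||% set$grader,
               label = r$label %||% NA_character_,
               area_px = apx, area_mm2 = apx * s,
               stringsAsFactors = FALSE)
  })
  if (!length(rows))
    return(data.frame(eye_id = character(), timepoint = integer(),
                      group = character(), grader = character(),
                      label = character(), area_px = numeric(),
                      area_mm2 = numeric(), stringsAsFactors = FALSE))
  do.call(rbind, rows)
}

#' Cohort summary statistics
#'
#' `MEAN_SD`: arithmetic mean and sample SD. `MEDIAN_IQR`: median with the
#' 25th/75th percentiles under linear interpolation between order statistics
#' (quantile type 7), the convention fixed for reproducible IQRs.
#'
#' @param x numeric vector of measurements (e.g. `area_mm2`).
#' @param statistic_kind `"MEAN_SD"` or `"MEDIAN_IQR"`.
#' @param label optional label carried into the output.
#' @return list with `label`, `statistic_kind`, `center`, `spread_low`,
#'   `spread_high`, `n`, `n1_flag`.
#' @export
summarize_areas <- function(x, statistic_kind = c("MEDIAN_IQR", "MEAN_SD"),
                            label = NA_character_) {
  statistic_kind <- match.arg(statistic_kind)
  x <- as.numeric(x)
  if (!length(x)) oc_stop("empty_input_error", "nothing to summarize")
  if (statistic_kind == "MEAN_SD") {
    s <- if (length(x) > 1) sd(x) else 0
    out <- list(center = mean(x), spread_low = mean(x) - s,
                spread_high = mean(x) + s)
  } else {
    q <- unname(quantile(x, c(0.25, 0.5, 0.75), type = 7))
    out <- list(center = q[2], spread_low = q[1], spread_high = q[3])
  }
  c(list(label = label, statistic_kind = statistic_kind), out,
    list(n = length(x), n1_flag = length(x) == 1))
}

#' Paired comparison of two area series
#'
#' `T_TEST`: the paired Student t statistic with n - 1 degrees of freedom;
#' identical series give t = 0, p = 1. `WILCOXON`: the Wilcoxon signed-rank
#' test with Wilcoxon's original zero-handling (zero differences dropped and
#' counted), midranks for tied magnitudes, the exact null distribution for
#' n <= `exact_max` without ties, and the normal approximation with
#' continuity and tie correction otherwise. Two-sided p values.
#'
#' @param x,y paired numeric vectors of equal length.
#' @param test `"WILCOXON"` (default for areas) or `"T_TEST"`.
#' @param exact_max largest n for which the exact signed-rank null is used.
#' @return list with `test`, `statistic` (t, or W = sum of positive-
#'   difference ranks), `p_value`, `n_used`, `n_zero_dropped`, `exact`.
#' @export
compare_paired_areas <- function(x, y, test = c("WILCOXON", "T_TEST"),
                                 exact_max = 20L) {
  test <- match.arg(test)
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) != length(y))
    oc_stop("configuration_error", "paired series differ in length")
  d <- x - y
  if (test == "T_TEST") {
    n <- length(d)
    if (n < 2)
      oc_stop("degenerate_input_error", "paired t test needs n >= 2")
    sdd <- sd(d)
    if (sdd == 0) {
      stat <- 0; p <- 1
    } else {
      stat <- mean(d) / (sdd / sqrt(n))
      p <- 2 * pt(-abs(stat), df = n - 1)
    }
    return(list(test = "T_TEST", statistic = stat, p_value = p,
                n_used = n, n_zero_dropped = 0L, exact = NA))
  }
  nz <- d[d != 0]
  n_zero <- length(d) - length(nz)
  n <- length(nz)
  if (n < 1)
    oc_stop("degenerate_input_error",
            "all paired differences are zero; signed-rank test undefined")
  r <- rank(abs(nz))                  # midranks for ties
  W <- sum(r[nz > 0])
  ties <- any(duplicated(r))
  if (n <= exact_max && !ties) {
    p <- min(1, 2 * min(psignrank(W, n), 1 - psignrank(W - 1, n)))
    exact <- TRUE
  } else {
    mu <- n * (n + 1) / 4
    tie_tab <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 -
      sum(tie_tab^3 - tie_tab) / 48
    z <- (W - mu - sign(W - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    exact <- FALSE
  }
  list(test = "WILCOXON", statistic = W, p_value = p,
       n_used = n, n_zero_dropped = n_zero, exact = exact)
}
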