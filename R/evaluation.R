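#' Match detections to ground-truth lunge times
#'
#' One-to-one greedy matching by ascending absolute time difference: the
#' closest detection/truth pair is matched first, each detection and each
#' truth time is used at most once, and a pair only counts when
#' `|difference| <= tolerance_s` (10 s by default, the audit tolerance of the
#' source study). Ties in distance break toward the earlier truth time, then
#' the earlier detection.
#'
#' @param detections Numeric vector of detection times (s), or a tibble with
#'   `time_s`.
#' @param truth Numeric vector of ground-truth lunge times (s), or a tibble
#'   with `time_s`.
#' @param tolerance_s Match tolerance, seconds. Default 10.
#' @return A tibble of matched pairs: `detection_s`, `truth_s`, `dt_s`.
#' @examples
#' match_detections(c(100, 104), c(101), tolerance_s = 10) # one match, at 100
#' @export
match_detections <- function(detections, truth, tolerance_s = 10) {
  dt_times <- if (is.data.frame(detections)) detections$time_s else as.numeric(detections)
  tr_times <- if (is.data.frame(truth)) truth$time_s else as.numeric(truth)
  empty <- tibble(detection_s = numeric(0), truth_s = numeric(0), dt_s = numeric(0))
  if (length(dt_times) == 0L || length(tr_times) == 0L) return(empty)

  pairs <- expand.grid(di = seq_along(dt_times), ti = seq_along(tr_times))
  pairs$dt <- dt_times[pairs$di] - tr_times[pairs$ti]
  pairs <- pairs[abs(pairs$dt) <= tolerance_s, , drop = FALSE]
  if (nrow(pairs) == 0L) return(empty)
  pairs <- pairs[order(abs(pairs$dt), tr_times[pairs$ti], dt_times[pairs$di]), , drop = FALSE]

  used_d <- logical(length(dt_times))
  used_t <- logical(length(tr_times))
  keep <- logical(nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    di <- pairs$di[k]; ti <- pairs$ti[k]
    if (!used_d[di] && !used_t[ti]) {
      keep[k] <- TRUE
      used_d[di] <- TRUE
      used_t[ti] <- TRUE
    }
  }
  m <- pairs[keep, , drop = FALSE]
  m <- m[order(m$ti), , drop = FALSE]
  tibble(
    detection_s = dt_times[m$di],
    truth_s = tr_times[m$ti],
    dt_s = m$dt
  )
}

#' True-positive and false-positive rates from event counts
#'
#' `tp_rate = 100 * n_correct / n_truth` (the fraction of manually audited
#' lunges the detector recovered) and
#' `fp_rate = 100 * (n_detected - n_correct) / n_detected` (the fraction of
#' detections that are spurious). A rate whose denominator is zero is
#' undefined and returned as `NA`: a whale with no true lunges has no TP
#' rate, one with no detections has no FP rate. Vectorized.
#'
#' @param n_truth,n_detected,n_correct Integer counts;
#'   `n_correct <= min(n_truth, n_detected)` must hold element-wise.
#' @return A tibble with columns `tp_rate` and `fp_rate` (percent).
#' @examples
#' compute_rates(175, 195, 172) # 98.3 / 11.8
#' @export
compute_rates <- function(n_truth, n_detected, n_correct) {
  if (any(n_correct > pmin(n_truth, n_detected))) {
    abort("`n_correct` cannot exceed min(n_truth, n_detected).")
  }
  if (any(c(n_truth, n_detected, n_correct) < 0)) abort("Counts must be non-negative.")
  tibble(
    tp_rate = ifelse(n_truth > 0, 100 * n_correct / n_truth, NA_real_),
    fp_rate = ifelse(n_detected > 0, 100 * (n_detected - n_correct) / n_detected, NA_real_)
  )
}

#' Score detections against ground truth
#'
#' Matches detections to manually audited lunge times within each depth
#' category (shallow/deep) separately, using [match_detections()], and
#' tabulates counts and rates per category and for the whole record (totals
#' are sums over categories). Rates follow [compute_rates()]; a category's
#' `fp_is_100_no_feeding` flag marks the degenerate case of spurious
#' detections in a record with no true feeding in that category, where a
#' single false alarm already makes the FP rate 100%.
#'
#' @param detections A `lunge_detections` tibble (or any tibble with
#'   `time_s` and `category`).
#' @param truth Ground-truth tibble with `time_s` and `category` (see
#'   [read_detections()] for the file format).
#' @param tolerance_s Match tolerance, seconds. Default 10.
#' @param whale_id Optional label carried into the report.
#' @return A `lunge_eval` object; `tidy()` returns the per-category tibble
#'   (`category`, `n_truth`, `n_detected`, `n_correct`, `tp_rate`,
#'   `fp_rate`, `fp_is_100_no_feeding`), `glance()` the one-row totals.
#' @export
evaluate_detections <- function(detections, truth, tolerance_s = 10, whale_id = NA_character_) {
  for (nm in list(detections, truth)) {
    if (!all(c("time_s", "category") %in% names(nm))) {
      abort("`detections` and `truth` need columns time_s and category.")
    }
  }
  per_cat <- lapply(c("shallow", "deep"), function(cat) {
    d <- detections$time_s[detections$category == cat]
    tr <- truth$time_s[truth$category == cat]
    m <- match_detections(d, tr, tolerance_s)
    tibble(
      category = cat, n_truth = length(tr), n_detected = length(d),
      n_correct = nrow(m)
    )
  })
  counts <- bind_rows(per_cat)
  counts <- bind_rows(
    counts,
    tibble(
      category = "total",
      n_truth = sum(counts$n_truth),
      n_detected = sum(counts$n_detected),
      n_correct = sum(counts$n_correct)
    )
  )
  rates <- compute_rates(counts$n_truth, counts$n_detected, counts$n_correct)
  out <- dplyr::bind_cols(counts, rates)
  out$fp_is_100_no_feeding <- out$n_truth == 0 & out$n_detected > 0
  structure(
    list(whale_id = whale_id, tolerance_s = tolerance_s, table = out),
    class = "lunge_eval"
  )
}

#' @export
print.lunge_eval <- function(x, ...) {
  cat(sprintf(
    "<lunge_eval>%s tolerance %g s\n",
    if (!is.na(x$whale_id)) sprintf(" whale '%s',", x$whale_id) else "",
    x$tolerance_s
  ))
  tab <- x$table
  tab$tp_rate <- round(tab$tp_rate, 1)
  tab$fp_rate <- round(tab$fp_rate, 1)
  print(as.data.frame(tab), row.names = FALSE)
  invisible(x)
}

#' @rdname evaluate_detections
#' @param x A `lunge_eval` object.
#' @param ... Unused.
#' @method tidy lunge_eval
#' @export
tidy.lunge_eval <- function(x, ...) {
  out <- x$table
  if (!is.na(x$whale_id)) out <- dplyr::mutate(out, whale_id = x$whale_id, .before = 1)
  out
}

#' @rdname evaluate_detections
#' @method glance lunge_eval
#' @export
glance.lunge_eval <- function(x, ...) {
  tot <- x$table[x$table$category == "total", , drop = FALSE]
  select(tot, -"category")
}

#' Cohort-level detector performance
#'
#' Averages per-whale rates across a cohort, per category, the way multi-
#' deployment detector studies report them: unweighted mean and sample SD
#' over whales, with undefined rates omitted. TP statistics average over
#' whales with true lunges in the category. FP statistics come in two
#' flavors: the *full* FP rate averages over every whale with detections,
#' while the *adjusted* FP rate additionally drops whales whose 100% FP rate
#' arises from a record with no true feeding in that category (where a single
#' false alarm forces 100% and skews the cohort mean).
#'
#' @param counts A tibble with one row per whale x category:
#'   `whale` (or `whale_id`), `category`, `n_truth`, `n_detected`,
#'   `n_correct`. If columns `tp_rate`/`fp_rate` are already present (e.g.
#'   published rate tables), they are used as-is instead of being recomputed
#'   from the counts.
#' @return A tibble per category: `n_tp_whales`, `tp_mean`, `tp_sd`,
#'   `n_fp_adj_whales`, `fp_adjusted_mean`, `fp_adjusted_sd`,
#'   `n_fp_full_whales`, `fp_full_mean`, `fp_full_sd`. SDs are `NA` for
#'   single-whale cohorts.
#' @examples
#' counts <- tibble::tibble(
#'   whale = c("a", "b"), category = "deep",
#'   n_truth = c(40, 0), n_detected = c(42, 3), n_correct = c(39, 0)
#' )
#' cohort_summary(counts)
#' @export
cohort_summary <- function(counts) {
  need <- c("category", "n_truth", "n_detected")
  if (!all(need %in% names(counts))) {
    abort("`counts` needs columns category, n_truth, n_detected (+ n_correct or tp_rate/fp_rate).")
  }
  df <- as_tibble(counts)
  if (!all(c("tp_rate", "fp_rate") %in% names(df))) {
    if (!"n_correct" %in% names(df)) {
      abort("`counts` needs n_correct when tp_rate/fp_rate are absent.")
    }
    df <- dplyr::bind_cols(df, compute_rates(df$n_truth, df$n_detected, df$n_correct))
  }
  msd <- function(x) {
    x <- x[!is.na(x)]
    tibble(
      n = length(x),
      mean = if (length(x) > 0) mean(x) else NA_real_,
      sd = if (length(x) > 1) sd(x) else NA_real_
    )
  }
  df %>%
    group_by(.data$category) %>%
    summarise(
      tp = msd(.data$tp_rate[.data$n_truth > 0]),
      fp_adj = msd(.data$fp_rate[.data$n_detected > 0 & .data$n_truth > 0]),
      fp_full = msd(.data$fp_rate[.data$n_detected > 0]),
      .groups = "drop"
    ) %>%
    tidyr::unpack(c("tp", "fp_adj", "fp_full"), names_sep = "_") %>%
    rename(
      n_tp_whales = "tp_n", tp_mean = "tp_mean", tp_sd = "tp_sd",
      n_fp_adj_whales = "fp_adj_n", fp_adjusted_mean = "fp_adj_mean",
      fp_adjusted_sd = "fp_adj_sd",
      n_fp_full_whales = "fp_full_n", fp_full_mean = "fp_full_mean",
      fp_full_sd = "fp_full_sd"
    )
}
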