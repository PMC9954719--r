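#' Pair recordings across two pulse shapes
#'
#' The cohort comparisons are paired: the same cortical recording is
#' quantified under the rectangular reference and under a ramped shape,
#' and only recordings providing significant responses to BOTH shapes
#' enter the comparison (this is the `n` of the published cohort
#' tables).
#'
#' @param quant per-recording quantification table from
#'   [quantify_recordings()] (or rbind of [extract_params()] rows),
#'   containing both shapes.
#' @param shape_id ramped shape to compare.
#' @param ref_shape_id reference shape (default `"Rec-C"`).
#' @param parameters which parameter columns to carry into long format.
#' @return A `paired_cohort` data frame in long format: `recording_id`,
#'   `parameter`, `ref` (value under the reference), `shape` (value
#'   under `shape_id`), with attributes `shape_id`, `ref_shape_id`,
#'   `n` (recordings included).
#' @export
pair_recordings <- function(quant, shape_id, ref_shape_id = "Rec-C",
                            parameters = c("max_fr_Hz", "threshold_nC",
                                           "charge_at_max_nC", "dyn_range_nC",
                                           "dyn_range80_nC")) {
  assert_cols(quant, c("recording_id", "shape_id", "significant", parameters),
              "quantification table")
  a <- quant[quant$shape_id == ref_shape_id, , drop = FALSE]
  b <- quant[quant$shape_id == shape_id, , drop = FALSE]
  ids <- intersect(a$recording_id, b$recording_id)
  if (length(ids) == 0)
    stop_input("cohort error: no recordings shared between ",
               ref_shape_id, " and ", shape_id)
  a <- a[match(ids, a$recording_id), , drop = FALSE]
  b <- b[match(ids, b$recording_id), , drop = FALSE]
  keep <- a$significant & b$significant
  if (!any(keep))
    stop_input("cohort error: no recording significant under both shapes")
  a <- a[keep, , drop = FALSE]
  b <- b[keep, , drop = FALSE]
  out <- do.call(rbind, lapply(parameters, function(p)
    data.frame(recording_id = a$recording_id, parameter = p,
               ref = a[[p]], shape = b[[p]])))
  rownames(out) <- NULL
  structure(out, shape_id = shape_id, ref_shape_id = ref_shape_id,
            n = sum(keep), class = c("paired_cohort", "data.frame"))
}

# exact null distribution of the signed-rank statistic W+ for given
# absolute-value ranks (average ranks allowed), by convolution over the
# 2^n equally likely sign assignments; returns P(W+ = w) on a grid of
# 2*W values so half-integer ranks stay exact
signed_rank_null <- function(ranks) {
  r2 <- as.integer(round(2 * ranks))      # doubled ranks are integers
  total <- sum(r2)
  p <- numeric(total + 1)                 # index i <-> doubled statistic i-1
  p[1] <- 1
  for (r in r2) {
    shifted <- c(numeric(r), p[seq_len(total + 1 - r)])
    p <- (p + shifted) / 2
  }
  p
}

#' Wilcoxon signed-rank test for paired values
#'
#' Two-tailed signed-rank test of the paired differences
#' `shape - ref`. Zero differences are dropped before ranking
#' (Wilcoxon's original treatment) and tied absolute differences
#' receive average ranks. For `n <= exact_max` pairs (default 25) the
#' p-value is exact, computed from the full null distribution of the
#' statistic over all sign assignments (which remains exact under
#' ties); beyond that, the normal approximation with tie correction and
#' continuity correction is used.
#'
#' @param x,y paired vectors (`x` = shape values, `y` = reference), or
#'   `x` alone as the vector of differences.
#' @param exact_max largest n for which the exact null is enumerated.
#' @return List: `statistic` (V, sum of positive ranks), `p_value`
#'   (two-tailed), `n` (non-zero pairs), `method` (`"exact"` or
#'   `"normal"`).
#' @examples
#' signed_rank_test(c(1, 2, 3, 4, 5))   # all-positive: p = 1/16
#' @export
signed_rank_test <- function(x, y = NULL, exact_max = 25) {
  d <- if (is.null(y)) x else {
    if (length(x) != length(y)) stop_input("x and y must have equal length")
    x - y
  }
  d <- d[!is.na(d)]
  d <- d[d != 0]
  n <- length(d)
  if (n == 0) stop_input("undefined test: all differences are zero")
  r <- rank(abs(d))
  V <- sum(r[d > 0])
  if (n <= exact_max) {
    null <- signed_rank_null(r)
    v2 <- as.integer(round(2 * V))
    lower <- sum(null[seq_len(v2 + 1)])            # P(W <= V)
    upper <- sum(null[seq.int(v2 + 1, length(null))])  # P(W >= V)
    p <- min(1, 2 * min(lower, upper))
    method <- "exact"
  } else {
    mu <- n * (n + 1) / 4
    ties <- table(r)
    sig2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
    z <- (V - mu - sign(V - mu) * 0.5) / sqrt(sig2)
    p <- min(1, 2 * pnorm(-abs(z)))
    method <- "normal"
  }
  list(statistic = V, p_value = p, n = n, method = method)
}

#' Count paired points relative to the identity diagonal
#'
#' In the scattergram view of a paired cohort (shape value against
#' reference value), points above the diagonal have a larger value
#' under the ramped shape.
#'
#' @param shape,ref paired vectors.
#' @return List: `above` (`shape > ref`), `below`, `ties`, `n`.
#' @examples
#' diagonal_counts(shape = c(2, 1, 3), ref = c(1, 2, 3))
#' @export
diagonal_counts <- function(shape, ref) {
  if (length(shape) != length(ref)) stop_input("paired vectors required")
  ok <- !(is.na(shape) | is.na(ref))
  shape <- shape[ok]; ref <- ref[ok]
  list(above = sum(shape > ref), below = sum(shape < ref),
       ties = sum(shape == ref), n = length(shape))
}

#' Summarize a paired cohort, one row per parameter
#'
#' Mirrors the layout of the published comparison tables: per parameter,
#' mean and standard error under the reference and under the ramped
#' shape, the two-tailed signed-rank p-value, the number of pairs, and
#' the above/below-diagonal counts. Parameters that are `NA` for a
#' recording (e.g. dynamic range of a recording whose 80-percent level
#' is undefined) are dropped pairwise. The 80-percent dynamic range row
#' is flagged `reported = FALSE`: it is computed here but was not part
#' of the published tables.
#'
#' @param cohort a [pair_recordings()] result.
#' @param alpha significance level for the `significant` flag.
#' @return A `comparison_summary` data frame: `shape_id`,
#'   `ref_shape_id`, `parameter`, `n`, `mean_ref`, `sem_ref`,
#'   `mean_shape`, `sem_shape`, `p_value`, `significant`, `above`,
#'   `below`, `ties`, `reported`.
#' @export
summarize_comparison <- function(cohort, alpha = 0.05) {
  stopifnot(inherits(cohort, "paired_cohort"))
  sem <- function(v) if (length(v) > 1) sd(v) / sqrt(length(v)) else 0
  res <- lapply(split(cohort, cohort$parameter), function(d) {
    ok <- !(is.na(d$ref) | is.na(d$shape))
    d <- d[ok, , drop = FALSE]
    n <- nrow(d)
    dg <- diagonal_counts(d$shape, d$ref)
    p <- if (n >= 5 && any(d$shape != d$ref))
      signed_rank_test(d$shape, d$ref)$p_value else NA_real_
    data.frame(shape_id = attr(cohort, "shape_id"),
               ref_shape_id = attr(cohort, "ref_shape_id"),
               parameter = d$parameter[1],
               n = n,
               mean_ref = mean(d$ref), sem_ref = sem(d$ref),
               mean_shape = mean(d$shape), sem_shape = sem(d$shape),
               p_value = p,
               significant = !is.na(p) & p < alpha,
               above = dg$above, below = dg$below, ties = dg$ties,
               reported = d$parameter[1] != "dyn_range80_nC")
  })
  ord <- c("max_fr_Hz", "threshold_nC", "charge_at_max_nC", "dyn_range_nC",
           "dyn_range80_nC")
  res <- do.call(rbind, res[order(match(names(res), ord))])
  rownames(res) <- NULL
  class(res) <- c("comparison_summary", "data.frame")
  res
}

#' Compare every ramped shape against the rectangular reference
#'
#' Runs [pair_recordings()] and [summarize_comparison()] for each
#' non-reference shape present in the quantification table and stacks
#' the results — the full analogue of the published comparison tables.
#'
#' @inheritParams pair_recordings
#' @param alpha significance level.
#' @return A `comparison_summary` data frame covering all shapes.
#' @examples
#' co <- simulate_cohort(8, effects_by_shape = default_shape_effects()[c("Rec-C", "FS80-C")],
#'                       seed = 11)
#' q <- quantify_recordings(co$events, make_schedule())
#' compare_shapes(q)
#' @export
compare_shapes <- function(quant, ref_shape_id = "Rec-C", alpha = 0.05) {
  shapes <- setdiff(unique(quant$shape_id), ref_shape_id)
  if (!ref_shape_id %in% quant$shape_id)
    stop_input("reference shape ", ref_shape_id, " absent from the table")
  if (length(shapes) == 0)
    stop_input("no non-reference shape to compare")
  out <- do.call(rbind, lapply(shapes, function(sh)
    summarize_comparison(pair_recordings(quant, sh, ref_shape_id), alpha)))
  rownames(out) <- NULL
  out
}

#' Render a comparison summary as a Markdown table
#'
#' One block per ramped shape, rows in the order of the published
#' tables; means are shown as `mean (+/- sem)`.
#'
#' @param summary a [compare_shapes()] result.
#' @return Character vector of Markdown lines, invisibly printed with
#'   `cat()` when interactive.
#' @export
format_comparison_md <- function(summary) {
  stopifnot(inherits(summary, "comparison_summary") || is.data.frame(summary))
  pretty <- c(max_fr_Hz = "Maximal firing rate (AP/s)",
              threshold_nC = "Threshold (nC)",
              charge_at_max_nC = "Charge level at MaxFR (nC)",
              dyn_range_nC = "Dynamic range (nC)",
              dyn_range80_nC = "DynRange80 (nC)")
  lines <- character(0)
  for (sh in unique(summary$shape_id)) {
    d <- summary[summary$shape_id == sh, , drop = FALSE]
    lines <- c(lines,
               sprintf("### %s vs. %s (n = %d)", d$ref_shape_id[1], sh,
                       max(d$n)),
               "",
               "| Parameter | Reference | Ramped | p (WSR) |",
               "|---|---|---|---|")
    for (i in seq_len(nrow(d))) {
      lines <- c(lines, sprintf(
        "| %s | %.2f (+/- %.2f) | %.2f (+/- %.2f) | %s |",
        pretty[d$parameter[i]], d$mean_ref[i], d$sem_ref[i],
        d$mean_shape[i], d$sem_shape[i],
        if (is.na(d$p_value[i])) "n/a" else sprintf("%.4g", d$p_value[i])))
    }
    lines <- c(lines, "")
  }
  lines
}
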