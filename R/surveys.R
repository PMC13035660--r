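TLX_ITEMS <- c("tlx_mental", "tlx_physical", "tlx_time", "tlx_performance",
               "tlx_effort", "tlx_frustration")
SURVEY_ITEMS <- c("confidence_anatomy", "confidence_approach", TLX_ITEMS,
                  "conference_mental_demand")

#' Read pre/post survey responses
#'
#' One row per (session, phase). Confidence items are 1-5 Likert; the six
#' NASA-TLX dimensions and the surgical-conference mental-demand item are
#' 1-10 and collected post-session only (blank cells mark items not
#' collected).
#'
#' @param path CSV with header `session_id,phase,confidence_anatomy,
#'   confidence_approach,tlx_mental,tlx_physical,tlx_time,tlx_performance,
#'   tlx_effort,tlx_frustration,conference_mental_demand`.
#' @return data.frame of class `survey_responses`.
#' @export
read_surveys <- function(path) {
  if (!file.exists(path)) stop("survey file not found: ", path)
  df <- read.csv(path, stringsAsFactors = FALSE)
  validate_surveys(df)
}

#' Validate a survey response table
#'
#' @param df data.frame in the [read_surveys()] layout.
#' @return `df` with class `survey_responses`.
#' @export
validate_surveys <- function(df) {
  need <- c("session_id", "phase")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("survey table missing column(s): ",
                         paste(miss, collapse = ", "))
  for (it in SURVEY_ITEMS) if (is.null(df[[it]])) df[[it]] <- NA_real_
  bad <- setdiff(unique(df$phase), c("pre", "post"))
  if (length(bad)) stop("phase must be 'pre' or 'post', got '", bad[1L], "'")
  chk <- function(col, lo, hi) {
    v <- df[[col]]
    out <- which(!is.na(v) & (v < lo | v > hi))
    if (length(out)) stop("survey row ", out[1L], ": ", col,
                          " outside [", lo, ", ", hi, "]")
  }
  chk("confidence_anatomy", 1, 5); chk("confidence_approach", 1, 5)
  for (it in c(TLX_ITEMS, "conference_mental_demand")) chk(it, 1, 10)
  pre_tlx <- df$phase == "pre" &
    rowSums(!is.na(df[TLX_ITEMS])) > 0
  if (any(pre_tlx)) stop("survey row ", which(pre_tlx)[1L],
                         ": NASA-TLX items are post-session only")
  class(df) <- c("survey_responses", "data.frame")
  df
}

#' Median and IQR summary of one survey item
#'
#' Medians use the midpoint-of-middle-two convention; the IQR is Q3 - Q1
#' with linearly interpolated quantiles (`quantile type = 7`, the common
#' spreadsheet and R default), the convention under which reported Likert
#' IQRs such as 0.75 arise at n = 10.
#'
#' @param responses a `survey_responses` table (or any data.frame with the
#'   item column).
#' @param item column name, e.g. `"tlx_mental"` or `"confidence_anatomy"`.
#' @param phase optionally restrict to `"pre"` or `"post"` rows.
#' @param quantile_type quantile algorithm passed to [stats::quantile()].
#' @return data.frame row: `item`, `n`, `median`, `iqr`.
#' @export
summarize_item <- function(responses, item, phase = NULL, quantile_type = 7) {
  if (is.null(responses[[item]])) stop("unknown survey item: ", item)
  df <- responses
  if (!is.null(phase)) df <- df[df$phase == phase, , drop = FALSE]
  v <- df[[item]]
  v <- v[!is.na(v)]
  if (!length(v)) stop("item '", item, "' absent from all selected responses")
  q <- quantile(v, c(0.25, 0.75), type = quantile_type, names = FALSE)
  data.frame(item = item, n = length(v), median = median(v),
             iqr = q[2L] - q[1L])
}

#' Welch's unequal-variance t test
#'
#' Two-sided two-sample t test without the equal-variance assumption,
#' degrees of freedom by Welch-Satterthwaite. Degenerate inputs (both
#' samples constant) are handled explicitly: equal means give `t = 0,
#' p = 1`; unequal means are flagged `degenerate` with an infinite
#' statistic.
#'
#' @param x,y numeric samples, each of length >= 2.
#' @return list `t`, `df`, `p`, `degenerate`.
#' @export
welch_t <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (var(x) == 0 && var(y) == 0) {
    if (mean(x) == mean(y)) {
      return(list(t = 0, df = length(x) + length(y) - 2, p = 1,
                  degenerate = FALSE))
    }
    warning("both samples constant with unequal means; p undefined")
    return(list(t = sign(mean(x) - mean(y)) * Inf,
                df = NA_real_, p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::t.test(x, y, var.equal = FALSE)
  list(t = unname(ht$statistic), df = unname(ht$parameter),
       p = ht$p.value, degenerate = FALSE)
}

#' F test for equality of two variances
#'
#' `F = var(x) / var(y)` with `(n_x - 1, n_y - 1)` degrees of freedom and a
#' two-sided p-value.
#'
#' @param x,y numeric samples, each of length >= 2 with positive variance.
#' @return list `F`, `df1`, `df2`, `p`, `degenerate`.
#' @export
f_var_test <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("each sample needs n >= 2")
  if (var(x) == 0 || var(y) == 0) {
    warning("zero variance; F test undefined")
    return(list(F = NA_real_, df1 = length(x) - 1L, df2 = length(y) - 1L,
                p = NA_real_, degenerate = TRUE))
  }
  ht <- stats::var.test(x, y)
  list(F = unname(ht$statistic), df1 = unname(ht$parameter[1L]),
       df2 = unname(ht$parameter[2L]), p = ht$p.value, degenerate = FALSE)
}

#' Pre/post confidence change table
#'
#' Pairs each session's pre and post responses, tallies sessions whose
#' rating increased / stayed the same / decreased for each confidence item,
#' and runs the Welch t test (pre vs post vectors, the unpaired form) and
#' the F variance test on each. Sessions missing either phase are excluded
#' and flagged. A paired t test is available as a documented alternative
#' (`paired = TRUE`), since pre/post responses from the same session are
#' paired by design.
#'
#' @param responses a `survey_responses` table with pre and post rows.
#' @param items confidence item columns to tabulate.
#' @param paired use a paired t test instead of Welch's unpaired test.
#' @return list of class `confidence_change`: per-item list with `deltas`
#'   (named per session), counts `increased`/`unchanged`/`decreased`,
#'   `welch` (or paired t) and `f_test` results; plus `excluded_sessions`.
#' @export
confidence_change_table <- function(responses,
                                    items = c("confidence_anatomy",
                                              "confidence_approach"),
                                    paired = FALSE) {
  pre <- responses[responses$phase == "pre", , drop = FALSE]
  post <- responses[responses$phase == "post", , drop = FALSE]
  common <- intersect(pre$session_id, post$session_id)
  excluded <- setdiff(unique(responses$session_id), common)
  if (length(excluded)) warning("session(s) missing a phase, excluded: ",
                                paste(excluded, collapse = ", "))
  if (!length(common)) stop("no session has both pre and post responses")
  pre <- pre[match(common, pre$session_id), , drop = FALSE]
  post <- post[match(common, post$session_id), , drop = FALSE]
  out <- lapply(items, function(it) {
    d <- post[[it]] - pre[[it]]
    names(d) <- common
    tt <- if (paired) {
      if (var(d) == 0) {
        list(t = if (all(d == 0)) 0 else NA_real_, df = length(d) - 1,
             p = if (all(d == 0)) 1 else NA_real_, degenerate = any(d != 0))
      } else {
        ht <- stats::t.test(post[[it]], pre[[it]], paired = TRUE)
        list(t = unname(ht$statistic), df = unname(ht$parameter),
             p = ht$p.value, degenerate = FALSE)
      }
    } else {
      welch_t(pre[[it]], post[[it]])
    }
    ft <- f_var_test(pre[[it]], post[[it]])
    list(item = it, deltas = d,
         increased = sum(d > 0), unchanged = sum(d == 0),
         decreased = sum(d < 0), test = tt, f_test = ft)
  })
  names(out) <- items
  structure(list(items = out, n_sessions = length(common),
                 excluded_sessions = excluded, paired = paired),
            class = "confidence_change")
}

#' @export
print.confidence_change <- function(x, ...) {
  cat("<confidence_change> ", x$n_sessions, " paired session(s)",
      if (x$paired) ", paired t test" else ", Welch t test", "\n", sep = "")
  for (it in x$items) {
    cat(sprintf("  %-20s up %d / same %d / down %d; p = %.4g; F-test p = %.4g\n",
                it$item, it$increased, it$unchanged, it$decreased,
                it$test$p, it$f_test$p))
  }
  if (length(x$excluded_sessions)) {
    cat("  excluded:", paste(x$excluded_sessions, collapse = ", "), "\n")
  }
  invisible(x)
}

#' Survey summary tables
#'
#' Median (IQR) rows for the six NASA-TLX dimensions (post-session) and for
#' pre/post confidence with the Welch t test p-value per confidence item —
#' the standard pre/post questionnaire summary layout.
#'
#' @param responses a `survey_responses` table.
#' @param quantile_type quantile algorithm for the IQR.
#' @return list with data.frames `tlx` (item, n, median, iqr) and
#'   `confidence` (item, pre/post medians and IQRs, Welch p).
#' @export
survey_summary <- function(responses, quantile_type = 7) {
  tlx <- do.call(rbind, lapply(TLX_ITEMS, function(it)
    summarize_item(responses, it, phase = "post",
                   quantile_type = quantile_type)))
  conf <- do.call(rbind, lapply(
    c("confidence_anatomy", "confidence_approach"), function(it) {
      s_pre <- summarize_item(responses, it, "pre", quantile_type)
      s_post <- summarize_item(responses, it, "post", quantile_type)
      w <- welch_t(responses[[it]][responses$phase == "pre"],
                   responses[[it]][responses$phase == "post"])
      data.frame(item = it,
                 pre_median = s_pre$median, pre_iqr = s_pre$iqr,
                 post_median = s_post$median, post_iqr = s_post$iqr,
                 p_welch = w$p)
    }))
  list(tlx = tlx, confidence = conf)
}
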