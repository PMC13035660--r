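#' Unitize a session under a reference coder
#'
#' Agreement is assessed over units defined by the reference coder: the
#' session is tiled into 5-second frames and each (frame, active reference
#' code) pair becomes one unit, so overlapping reference codes yield one
#' unit each rather than forcing a primary-code choice. Frames exist only
#' where the reference has at least one active code. A zero-length event
#' occupies its start frame.
#'
#' @param ann a [session_annotations] object.
#' @param reference a coder id in `ann$coders`.
#' @param grid frame width in seconds (default 5).
#' @return data.frame with columns `t` (frame start, multiple of `grid`) and
#'   `code_id`, ordered by `t` then `code_id`; zero rows when the reference
#'   coded nothing.
#' @export
unitize_reference <- function(ann, reference, grid = 5) {
  stopifnot(inherits(ann, "session_annotations"))
  if (!reference %in% ann$coders) stop("unknown reference coder: ", reference)
  ev <- coder_events(ann, reference)
  if (!nrow(ev)) {
    return(data.frame(t = numeric(), code_id = integer()))
  }
  frames <- do.call(rbind, lapply(seq_len(nrow(ev)), function(i) {
    s <- ev$start_s[i]; e <- ev$end_s[i]
    ts <- if (e > s) seq(s, e - grid, by = grid) else s
    data.frame(t = ts, code_id = ev$code_id[i])
  }))
  frames <- unique(frames)
  frames[order(frames$t, frames$code_id), , drop = FALSE]
}

# Window covered by a reference frame starting at t:
#   symmetric: [t - window, t + window + grid)  (window s on either side of
#              the frame)
#   trailing:  [t - window, t + grid)           (window s before, through the
#              frame itself)
frame_window <- function(t, window, grid, window_mode) {
  switch(window_mode,
         symmetric = cbind(lo = t - window, hi = t + window + grid),
         trailing = cbind(lo = t - window, hi = t + grid),
         stop("window_mode must be 'symmetric' or 'trailing'"))
}

#' Align one reference frame against another coder
#'
#' Implements the windowed matching rule: if the other coder has the
#' reference code active anywhere within the window around the frame, the
#' frame is an agreement and the reference code is returned. Otherwise, if
#' the other coder has any code active in the window, the differing code
#' with the greatest overlap with the window is recorded (ties broken
#' toward the smaller code id). If the other coder identified nothing in
#' the window, the reserved code 0 is returned.
#'
#' @param ann a [session_annotations] object.
#' @param frame a list or one-row data.frame with fields `t` (frame start)
#'   and `code_id` (the reference code), as produced by
#'   [unitize_reference()].
#' @param other the coder being compared to the reference.
#' @param window window half-width in seconds (default 10).
#' @param grid frame width in seconds.
#' @param window_mode `"symmetric"` (window s on either side of the frame)
#'   or `"trailing"` (window s before, through the frame).
#' @return A single code id; 0 means the other coder identified no code in
#'   the window.
#' @export
align_frame <- function(ann, frame, other, window = 10, grid = 5,
                        window_mode = "symmetric") {
  fr <- data.frame(t = as.numeric(frame$t),
                   code_id = as.integer(frame$code_id))
  align_frames(ann, fr, other, window, grid, window_mode)[1L]
}

# Vectorized alignment of all reference frames against one other coder.
align_frames <- function(ann, frames, other, window, grid, window_mode) {
  if (window < 0) stop("window must be non-negative")
  if (!other %in% ann$coders) stop("unknown coder: ", other)
  n_f <- nrow(frames)
  if (!n_f) return(integer())
  ev <- coder_events(ann, other)
  if (!nrow(ev)) return(rep(0L, n_f))
  w <- frame_window(frames$t, window, grid, window_mode)
  # overlap[f, e]: seconds of event e inside the window of frame f
  ov <- pmax(outer(w[, "hi"], ev$end_s, pmin) -
               outer(w[, "lo"], ev$start_s, pmax), 0)
  zero_len <- ev$start_s == ev$end_s
  if (any(zero_len)) {
    # a zero-length event is "identified in the window" when its instant
    # falls inside it, though it contributes no overlap duration
    inside <- outer(w[, "lo"], ev$start_s, `<=`) &
      outer(w[, "hi"], ev$start_s, `>`)
    present <- ov > 0 | (inside & rep(zero_len, each = n_f))
  } else {
    present <- ov > 0
  }
  same <- present & outer(frames$code_id, ev$code_id, `==`)
  agree <- rowSums(same) > 0
  out <- rep(0L, n_f)
  out[agree] <- frames$code_id[agree]
  todo <- which(!agree & rowSums(present) > 0)
  if (length(todo)) {
    # per-code overlap totals; epsilon marks presence with zero duration so
    # zero-length identifications still beat absence
    eff <- ov + 1e-9 * (present & ov <= 0)
    eff[!present] <- 0
    cods <- sort(unique(ev$code_id))
    ind <- outer(ev$code_id, cods, `==`) + 0
    bycode <- eff[todo, , drop = FALSE] %*% ind
    pick <- max.col(bycode, ties.method = "first")  # columns in ascending id
    out[todo] <- cods[pick]
  }
  out
}

#' Build the units-by-categories agreement matrix for a reference coder
#'
#' Each unit (frame) of the reference coder receives one rating per coder:
#' the reference's own code plus the [align_frame()] result for every other
#' coder. Ratings are tallied over the category set = all codebook ids plus
#' the reserved 0 ("no code in window"), giving the count matrix Fleiss'
#' kappa expects; every row sums to the number of coders.
#'
#' @inheritParams align_frame
#' @param reference the reference coder defining the units.
#' @param codebook a [codebook] giving the category set.
#' @return An object of class `agreement_matrix`: an integer matrix (units
#'   x categories, category columns named by code id with `"0"` first) with
#'   attributes `n_raters`, `frames`, `reference`, `session_id`.
#' @export
build_agreement_matrix <- function(ann, reference, codebook, window = 10,
                                   grid = 5, window_mode = "symmetric") {
  stopifnot(inherits(ann, "session_annotations"),
            inherits(codebook, "codebook"))
  if (length(ann$coders) < 2L) stop("agreement needs at least 2 coders")
  frames <- unitize_reference(ann, reference, grid)
  cats <- c(0L, sort(codebook$id))
  n_raters <- length(ann$coders)
  m <- matrix(0L, nrow = nrow(frames), ncol = length(cats),
              dimnames = list(NULL, as.character(cats)))
  if (nrow(frames)) {
    tally <- function(codes) {
      i <- match(codes, cats)
      if (anyNA(i)) stop("rating outside codebook category set")
      i
    }
    idx <- tally(frames$code_id)
    m[cbind(seq_len(nrow(frames)), idx)] <-
      m[cbind(seq_len(nrow(frames)), idx)] + 1L
    for (other in setdiff(ann$coders, reference)) {
      r <- align_frames(ann, frames, other, window, grid, window_mode)
      i <- tally(r)
      m[cbind(seq_len(nrow(frames)), i)] <-
        m[cbind(seq_len(nrow(frames)), i)] + 1L
    }
  }
  structure(m, n_raters = n_raters, frames = frames, reference = reference,
            session_id = ann$session_id, class = c("agreement_matrix", class(m)))
}

#' Fleiss' kappa for a fixed number of raters
#'
#' The chance-corrected multi-rater agreement statistic. For a units x
#' categories count matrix with every row summing to the rater count n:
#' per-unit agreement `P_i = (sum_j n_ij (n_ij - 1)) / (n (n - 1))`,
#' observed agreement `Pbar = mean(P_i)`, chance agreement
#' `Pe = sum_j p_j^2` with `p_j` the pooled category proportions, and
#' `kappa = (Pbar - Pe) / (1 - Pe)`. 1 is perfect agreement, 0 agreement at
#' the chance rate, negative systematic disagreement.
#'
#' @param m an [build_agreement_matrix()] result or any non-negative integer
#'   matrix with constant row sums >= 2.
#' @return The kappa statistic in `[-1, 1]`; `NA` (with a warning) for a
#'   matrix with no units; 1 (with a warning) in the degenerate limit where
#'   all ratings fall in one category (`Pe = 1`).
#' @export
fleiss_kappa <- function(m) {
  m <- unclass(m)
  attributes(m)[setdiff(names(attributes(m)), "dim")] <- NULL
  if (is.null(dim(m)) || nrow(m) == 0L) {
    warning("agreement matrix has no units; kappa undefined")
    return(NA_real_)
  }
  rs <- rowSums(m)
  n <- rs[1L]
  if (n < 2) stop("Fleiss' kappa needs at least 2 raters per unit")
  if (any(rs != n)) stop("all units must have the same number of ratings")
  if (any(m < 0)) stop("negative rating counts")
  N <- nrow(m)
  P_i <- (rowSums(m^2) - n) / (n * (n - 1))
  Pbar <- mean(P_i)
  p_j <- colSums(m) / (N * n)
  Pe <- sum(p_j^2)
  if (Pe >= 1 - 1e-15) {
    warning("all ratings in a single category; returning kappa = 1")
    return(1)
  }
  (Pbar - Pe) / (1 - Pe)
}

#' Per-reference kappa range for a session
#'
#' Fleiss' kappa is computed once per reference coder (each reference
#' defines its own units); the session is summarized by the minimum and
#' maximum over references, the form in which multi-coder reliability is
#' reported per session. References with zero coded events are excluded and
#' flagged.
#'
#' @inheritParams build_agreement_matrix
#' @return An object of class `kappa_result`: list with `session_id`,
#'   `per_reference` (named numeric vector), `min_k`, `max_k`,
#'   `interpretation` (bands of min and max), `excluded` (references with no
#'   events).
#' @export
kappa_range <- function(ann, codebook, window = 10, grid = 5,
                        window_mode = "symmetric") {
  stopifnot(inherits(ann, "session_annotations"))
  if (length(ann$coders) < 2L) stop("agreement needs at least 2 coders")
  has_events <- vapply(ann$coders, function(cd)
    nrow(coder_events(ann, cd)) > 0L, logical(1))
  excluded <- ann$coders[!has_events]
  refs <- ann$coders[has_events]
  if (!length(refs)) {
    warning("no reference coder has any events; kappa undefined")
    return(structure(list(session_id = ann$session_id,
                          per_reference = setNames(numeric(), character()),
                          min_k = NA_real_, max_k = NA_real_,
                          interpretation = c(min = NA, max = NA),
                          excluded = excluded),
                     class = "kappa_result"))
  }
  ks <- vapply(refs, function(r) {
    fleiss_kappa(build_agreement_matrix(ann, r, codebook, window, grid,
                                        window_mode))
  }, numeric(1))
  structure(list(session_id = ann$session_id, per_reference = ks,
                 min_k = min(ks), max_k = max(ks),
                 interpretation = c(min = interpret_kappa(min(ks)),
                                    max = interpret_kappa(max(ks))),
                 excluded = excluded),
            class = "kappa_result")
}

#' Interpretation band for a kappa value
#'
#' The conventional scale: below 0.2 very poor, 0.2-0.4 fair, 0.4-0.6
#' moderate, 0.6-0.8 substantial, 0.8-1.0 almost perfect. Band boundaries
#' belong to the upper band (0.4 is "moderate").
#'
#' @param k kappa value(s) in `[-1, 1]`.
#' @return Character vector of band labels.
#' @export
interpret_kappa <- function(k) {
  if (any(k < -1 | k > 1, na.rm = TRUE)) stop("kappa must lie in [-1, 1]")
  labs <- c("very poor", "fair", "moderate", "substantial", "almost perfect")
  labs[findInterval(k, c(0.2, 0.4, 0.6, 0.8)) + 1L]
}

#' @export
print.kappa_result <- function(x, ...) {
  cat("<kappa_result> session '", x$session_id, "'\n", sep = "")
  if (length(x$per_reference)) {
    for (r in names(x$per_reference)) {
      cat(sprintf("  reference %-10s kappa = %.3f (%s)\n", r,
                  x$per_reference[[r]],
                  interpret_kappa(x$per_reference[[r]])))
    }
    cat(sprintf("  range: %.3f (%s) - %.3f (%s)\n", x$min_k,
                x$interpretation[["min"]], x$max_k,
                x$interpretation[["max"]]))
  } else {
    cat("  no usable reference coders\n")
  }
  if (length(x$excluded)) {
    cat("  excluded (no events):", paste(x$excluded, collapse = ", "), "\n")
  }
  invisible(x)
}
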