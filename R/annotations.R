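#' Round a time to the annotation grid
#'
#' Times are rounded to the nearest multiple of `grid` seconds; exact halves
#' round up (away from zero), the common spreadsheet convention.
#'
#' @param t non-negative time(s) in seconds.
#' @param grid grid spacing in seconds (default 5).
#' @return `t` rounded to the nearest multiple of `grid`.
#' @examples
#' round_to_grid(c(12, 13, 12.5))  # 10 15 15
#' @export
round_to_grid <- function(t, grid = 5) {
  if (grid <= 0) stop("grid must be positive")
  t <- as.numeric(t)
  if (any(t < 0, na.rm = TRUE)) stop("negative times not supported")
  grid * floor(t / grid + 0.5)
}

#' Assemble session annotations
#'
#' A `session_annotations` object holds every coder's timestamped code
#' events for one session. Events are intervals `[start_s, end_s)` on the
#' 5-second grid; events of one coder may overlap (each coder sets their own
#' dynamic unit of analysis).
#'
#' @param events data.frame with columns `session_id`, `coder_id`,
#'   `code_id`, `start_s`, `end_s`. Times are grid-rounded on construction.
#' @param session_id session identifier; inferred from `events` when `NULL`.
#' @param coders coder roster; inferred from `events` when `NULL` (pass
#'   explicitly to retain coders with zero events).
#' @param duration_s session length in seconds; defaults to the largest
#'   rounded event end.
#' @param grid grid spacing in seconds.
#' @return An object of class `session_annotations` with fields
#'   `session_id`, `coders`, `events`, `duration_s`.
#' @export
session_annotations <- function(events, session_id = NULL, coders = NULL,
                                duration_s = NULL, grid = 5) {
  need <- c("session_id", "coder_id", "code_id", "start_s", "end_s")
  miss <- setdiff(need, names(events))
  if (length(miss)) stop("events missing column(s): ",
                         paste(miss, collapse = ", "))
  events <- as.data.frame(events)[need]
  events$coder_id <- as.character(events$coder_id)
  events$session_id <- as.character(events$session_id)
  events$code_id <- as.integer(events$code_id)
  if (nrow(events)) {
    bad <- which(events$end_s < events$start_s)
    if (length(bad)) stop("event row ", bad[1L], ": end before start")
    had_length <- events$end_s > events$start_s
    events$start_s <- round_to_grid(events$start_s, grid)
    events$end_s <- round_to_grid(events$end_s, grid)
    ncollapsed <- sum(had_length & events$end_s == events$start_s)
    if (ncollapsed) {
      warning(ncollapsed, " zero-length event(s) after rounding; ",
              "retained (each occupies its start frame)")
    }
  }
  sid <- session_id %||% (if (nrow(events)) events$session_id[1L] else
    stop("session_id required for an empty session"))
  if (nrow(events) && !all(events$session_id == sid)) {
    stop("events span more than one session_id")
  }
  events$session_id <- rep(sid, nrow(events))
  coders <- sort(unique(c(as.character(coders %||% character()),
                          events$coder_id)))
  dmax <- if (nrow(events)) max(events$end_s) else 0
  duration_s <- duration_s %||% dmax
  if (duration_s < dmax) stop("duration_s is shorter than the last event end")
  structure(list(session_id = sid, coders = coders, events = events,
                 duration_s = duration_s, grid = grid),
            class = "session_annotations")
}

#' Read per-coder annotations for one session
#'
#' The canonical interchange format is a UTF-8 CSV with header
#' `session_id,coder_id,code_id,start_s,end_s`, one coded interval per row,
#' times in seconds. Start and end times are rounded to the grid on read;
#' overlapping events are preserved.
#'
#' @param path path to the annotation CSV.
#' @param codebook a [codebook]; every `code_id` must resolve in it.
#' @param grid grid spacing in seconds (default 5).
#' @return A [session_annotations] object.
#' @export
read_annotations <- function(path, codebook, grid = 5) {
  if (!file.exists(path)) stop("annotation file not found: ", path)
  stopifnot(inherits(codebook, "codebook"))
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("session_id", "coder_id", "code_id", "start_s", "end_s")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation CSV missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df)) {
    unk <- which(!(as.integer(df$code_id) %in% codebook$id))
    if (length(unk)) stop("annotation row ", unk[1L], ": code id ",
                          df$code_id[unk[1L]], " not in codebook")
    bad <- which(df$end_s < df$start_s)
    if (length(bad)) stop("annotation row ", bad[1L], ": end before start")
  }
  session_annotations(df, grid = grid)
}

#' Write session annotations to CSV
#'
#' Times are already on the grid, so [read_annotations()] of the written
#' file reproduces the event multiset exactly.
#'
#' @param ann a [session_annotations] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(ann, path) {
  stopifnot(inherits(ann, "session_annotations"))
  write.csv(ann$events, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Codes active for a coder at a time point
#'
#' Intervals are half-open `[start_s, end_s)`: a code ending at `t` is not
#' active at `t`. Zero-length events are active only at their start.
#'
#' @param ann a [session_annotations] object.
#' @param coder a coder id present in the session.
#' @param t time in seconds (need not be on the grid).
#' @return Sorted integer vector of active code ids (possibly empty).
#' @export
active_codes <- function(ann, coder, t) {
  stopifnot(inherits(ann, "session_annotations"))
  if (!coder %in% ann$coders) stop("unknown coder: ", coder)
  ev <- ann$events[ann$events$coder_id == coder, , drop = FALSE]
  hit <- (ev$start_s <= t & t < ev$end_s) |
    (ev$start_s == ev$end_s & ev$start_s == t)
  sort(unique(ev$code_id[hit]))
}

coder_events <- function(ann, coder) {
  ann$events[ann$events$coder_id == coder, , drop = FALSE]
}

#' @export
print.session_annotations <- function(x, ...) {
  cat("<session_annotations> session '", x$session_id, "': ",
      length(x$coders), " coders, ", nrow(x$events), " events, ",
      x$duration_s, " s\n", sep = "")
  invisible(x)
}
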