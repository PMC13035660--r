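#' Extract code transitions for one coder
#'
#' A transition is an ordered pair (from-code, to-code) where the to-code
#' begins at least 5 s after the from-code began. Events are grouped by
#' grid-rounded start time into co-start groups; codes starting together are
#' never transitions of one another, but each transitions to every code in
#' the immediately following co-start group (the "previous code" is read as
#' the adjacent group, not all earlier codes). After rounding, distinct
#' starts always differ by at least the 5-s grid, so adjacency is
#' sufficient.
#'
#' @param ann a [session_annotations] object.
#' @param coder a coder id in the session.
#' @return An object of class `transition_table` with `scope = "per-coder"`:
#'   a data.frame `from_code`, `to_code`, `count` (the transition multiset,
#'   aggregated), ordered by descending count.
#' @export
extract_transitions <- function(ann, coder) {
  stopifnot(inherits(ann, "session_annotations"))
  if (!coder %in% ann$coders) stop("unknown coder: ", coder)
  ev <- coder_events(ann, coder)
  pairs <- transition_pairs(ev$code_id, ev$start_s)
  new_transition_table(pairs, scope = "per-coder", sessions = ann$session_id,
                       coder = coder)
}

# core co-start grouping rule; codes/starts are parallel vectors
transition_pairs <- function(codes, starts) {
  if (length(codes) < 2L) {
    return(data.frame(from_code = integer(), to_code = integer(),
                      count = integer()))
  }
  o <- order(starts)
  codes <- codes[o]; starts <- starts[o]
  groups <- split(codes, starts)  # split orders by start value
  if (length(groups) < 2L) {
    return(data.frame(from_code = integer(), to_code = integer(),
                      count = integer()))
  }
  out <- vector("list", length(groups) - 1L)
  for (i in seq_len(length(groups) - 1L)) {
    out[[i]] <- expand.grid(from_code = groups[[i]],
                            to_code = groups[[i + 1L]],
                            KEEP.OUT.ATTRS = FALSE)
  }
  tally_transitions(do.call(rbind, out))
}

tally_transitions <- function(pairs) {
  if (!nrow(pairs)) {
    return(data.frame(from_code = integer(), to_code = integer(),
                      count = integer()))
  }
  agg <- aggregate(list(count = rep(1L, nrow(pairs))),
                   by = list(from_code = pairs$from_code,
                             to_code = pairs$to_code), FUN = sum)
  agg[order(-agg$count, agg$from_code, agg$to_code), , drop = FALSE]
}

new_transition_table <- function(df, scope, sessions, coder = NULL) {
  rownames(df) <- NULL
  structure(df, scope = scope, sessions = sessions, coder = coder,
            class = c("transition_table", "data.frame"))
}

#' Shared transition counts across coder pairs and sessions
#'
#' For every session and every unordered pair of coders, the intersection of
#' the two coders' transition collections is taken; the intersection counts
#' are summed over all pairs and all sessions. `A -> B` and `B -> A` are
#' tallied separately. With the default multiset intersection a transition
#' seen `a` times by one coder and `b` times by the other contributes
#' `min(a, b)` per pair; `intersection = "set"` reduces that to 1 (presence
#' in both).
#'
#' @param sessions a [session_annotations] object or a list of them; each
#'   needs at least 2 coders.
#' @param intersection `"multiset"` (per-transition minimum of the pair's
#'   counts, the default) or `"set"` (membership only).
#' @return A `transition_table` with `scope = "shared"`, ordered by
#'   descending count.
#' @export
shared_transition_counts <- function(sessions,
                                     intersection = c("multiset", "set")) {
  intersection <- match.arg(intersection)
  if (inherits(sessions, "session_annotations")) sessions <- list(sessions)
  acc <- list()
  sids <- character()
  for (ann in sessions) {
    stopifnot(inherits(ann, "session_annotations"))
    if (length(ann$coders) < 2L) stop("session '", ann$session_id,
                                      "': shared counts need >= 2 coders")
    sids <- c(sids, ann$session_id)
    per <- lapply(ann$coders, function(cd)
      as.data.frame(extract_transitions(ann, cd)))
    names(per) <- ann$coders
    cds <- ann$coders
    for (i in seq_along(cds)[-length(cds)]) {
      for (j in seq((i + 1L), length(cds))) {
        a <- per[[i]]; b <- per[[j]]
        if (!nrow(a) || !nrow(b)) next
        key_a <- paste(a$from_code, a$to_code)
        key_b <- paste(b$from_code, b$to_code)
        common <- intersect(key_a, key_b)
        if (!length(common)) next
        ia <- match(common, key_a); ib <- match(common, key_b)
        cnt <- pmin(a$count[ia], b$count[ib])
        if (intersection == "set") cnt <- pmin(cnt, 1L)
        acc[[length(acc) + 1L]] <- data.frame(
          from_code = a$from_code[ia], to_code = a$to_code[ia], count = cnt)
      }
    }
  }
  if (!length(acc)) {
    tab <- data.frame(from_code = integer(), to_code = integer(),
                      count = integer())
  } else {
    all <- do.call(rbind, acc)
    tab <- aggregate(list(count = all$count),
                     by = list(from_code = all$from_code,
                               to_code = all$to_code), FUN = sum)
    tab <- tab[order(-tab$count, tab$from_code, tab$to_code), , drop = FALSE]
  }
  new_transition_table(tab, scope = "shared", sessions = unique(sids))
}

#' Restrict a transition table to transitions involving one code
#'
#' @param table a `transition_table`.
#' @param code a code id; entries with `from_code == code` or
#'   `to_code == code` are retained, ordered by descending count.
#' @return A `transition_table` of the same scope.
#' @export
filter_transitions <- function(table, code) {
  stopifnot(inherits(table, "transition_table"))
  code <- as.integer(code)
  keep <- table$from_code == code | table$to_code == code
  out <- as.data.frame(table)[keep, , drop = FALSE]
  out <- out[order(-out$count, out$from_code, out$to_code), , drop = FALSE]
  new_transition_table(out, scope = attr(table, "scope"),
                       sessions = attr(table, "sessions"),
                       coder = attr(table, "coder"))
}

#' Directional asymmetry of a transition pair
#'
#' Compares the counts of `a -> b` and `b -> a` in a transition table and
#' reports their ratio; sequences between two codes are often one-sided and
#' the ratio quantifies that.
#'
#' @param table a `transition_table`.
#' @param a,b distinct code ids.
#' @return list with `count_ab`, `count_ba`, `ratio` (`count_ab / count_ba`;
#'   `NA` with `ratio_defined = FALSE` when `count_ba` is 0).
#' @export
transition_asymmetry <- function(table, a, b) {
  stopifnot(inherits(table, "transition_table"))
  if (a == b) stop("a and b must be distinct codes")
  get <- function(f, t) {
    i <- which(table$from_code == f & table$to_code == t)
    if (length(i)) sum(table$count[i]) else 0L
  }
  ab <- get(a, b); ba <- get(b, a)
  list(count_ab = ab, count_ba = ba,
       ratio = if (ba > 0) ab / ba else NA_real_,
       ratio_defined = ba > 0)
}

#' Attach code names to a transition table
#'
#' @param table a `transition_table`.
#' @param codebook a [codebook] resolving every code id in the table.
#' @return The table with added `from` and `to` name columns.
#' @export
label_transitions <- function(table, codebook) {
  stopifnot(inherits(table, "transition_table"))
  out <- as.data.frame(table)
  out$from <- if (nrow(out)) code_name(codebook, out$from_code) else character()
  out$to <- if (nrow(out)) code_name(codebook, out$to_code) else character()
  out[, c("from", "to", "from_code", "to_code", "count")]
}

#' @export
as.data.frame.transition_table <- function(x, ...) {
  data.frame(from_code = x$from_code, to_code = x$to_code, count = x$count)
}

#' @export
print.transition_table <- function(x, n = 10, ...) {
  cat("<transition_table> scope: ", attr(x, "scope"),
      if (!is.null(attr(x, "coder"))) paste0(" (coder ", attr(x, "coder"), ")"),
      ", ", length(attr(x, "sessions")), " session(s), ",
      nrow(x), " distinct transitions\n", sep = "")
  if (nrow(x)) print(utils::head(as.data.frame(x), n))
  invisible(x)
}
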