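#' Timeline plot of one session's coding
#'
#' One horizontal-bar panel per coder, time on the x axis (min:sec), bars
#' colored by code. The legend always lists every codebook code, whether or
#' not it was identified in the session, and overlapping events are stacked
#' within a coder's panel so nothing is hidden.
#'
#' @param ann a [session_annotations] with at least one event.
#' @param codebook a [codebook].
#' @param out optional path; when given the plot is written there (format by
#'   extension, e.g. `.png` or `.svg`) and the path returned invisibly.
#' @param width,height device size in inches when writing.
#' @return The ggplot object (invisibly when `out` is given).
#' @export
plot_timeline <- function(ann, codebook, out = NULL, width = 9, height = 7) {
  stopifnot(inherits(ann, "session_annotations"),
            inherits(codebook, "codebook"))
  ev <- ann$events
  if (!nrow(ev)) stop("session '", ann$session_id, "' has no events to plot")
  ev$code <- factor(code_name(codebook, ev$code_id),
                    levels = codebook$name[order(codebook$id)])
  # stack overlapping events within each coder panel
  ev <- ev[order(ev$coder_id, ev$start_s, ev$end_s), , drop = FALSE]
  ev$lane <- unlist(lapply(split(seq_len(nrow(ev)), ev$coder_id), function(i) {
    ends <- numeric()
    lane <- integer(length(i))
    for (k in seq_along(i)) {
      s <- ev$start_s[i[k]]
      e <- max(ev$end_s[i[k]], s + ann$grid)  # zero-length occupies a frame
      free <- which(ends <= s)
      if (length(free)) {
        lane[k] <- free[1L]
        ends[free[1L]] <- e
      } else {
        ends <- c(ends, e)
        lane[k] <- length(ends)
      }
    }
    lane
  }))
  ev$draw_end <- pmax(ev$end_s, ev$start_s + ann$grid)
  mmss <- function(t) sprintf("%d:%02d", t %/% 60, t %% 60)
  p <- ggplot2::ggplot(ev) +
    ggplot2::geom_rect(ggplot2::aes(xmin = .data$start_s,
                                    xmax = .data$draw_end,
                                    ymin = .data$lane - 0.45,
                                    ymax = .data$lane + 0.45,
                                    fill = .data$code)) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$coder_id)) +
    ggplot2::scale_fill_viridis_d(drop = FALSE, name = "Code") +
    ggplot2::scale_x_continuous(labels = mmss, name = "Time (min:sec)",
                                limits = c(0, max(ann$duration_s,
                                                  ev$draw_end))) +
    ggplot2::scale_y_continuous(breaks = NULL, name = NULL) +
    ggplot2::labs(title = paste0("Session ", ann$session_id,
                                 ": codes identified in time, per coder")) +
    ggplot2::theme_minimal()
  if (!is.null(out)) {
    ggplot2::ggsave(out, p, width = width, height = height)
    return(invisible(p))
  }
  p
}

#' Study configuration
#'
#' @param codebook_path path to the codebook file.
#' @param annotation_paths character vector of annotation CSVs, one session
#'   each.
#' @param survey_path optional survey CSV.
#' @param out_dir report output directory.
#' @param grid grid spacing in seconds.
#' @param window alignment window half-width in seconds.
#' @param window_mode `"symmetric"` or `"trailing"`.
#' @param intersection `"multiset"` or `"set"` shared-count rule.
#' @param filter_code optional code name for the focused transition table.
#' @param quantile_type quantile algorithm for survey IQRs.
#' @return list of class `study_config`.
#' @export
study_config <- function(codebook_path, annotation_paths, survey_path = NULL,
                         out_dir = "report", grid = 5, window = 10,
                         window_mode = "symmetric",
                         intersection = "multiset",
                         filter_code = "Mental Model", quantile_type = 7) {
  for (p in c(codebook_path, annotation_paths, survey_path)) {
    if (!is.null(p) && !file.exists(p)) stop("file not found: ", p)
  }
  stopifnot(grid > 0, window >= 0,
            window_mode %in% c("symmetric", "trailing"),
            intersection %in% c("multiset", "set"))
  structure(list(codebook_path = codebook_path,
                 annotation_paths = annotation_paths,
                 survey_path = survey_path, out_dir = out_dir, grid = grid,
                 window = window, window_mode = window_mode,
                 intersection = intersection, filter_code = filter_code,
                 quantile_type = quantile_type),
            class = "study_config")
}

#' Read a study configuration from YAML
#'
#' Keys mirror the [study_config()] arguments (`codebook`, `annotations` as
#' a list, `surveys`, `out_dir`, and the analysis parameters).
#'
#' @param path YAML file.
#' @return A `study_config`.
#' @export
read_study_config <- function(path) {
  y <- yaml::read_yaml(path)
  base <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p)) return(NULL)
    ifelse(grepl("^/", p), p, file.path(base, p))
  }
  study_config(codebook_path = resolve(y$codebook),
               annotation_paths = resolve(unlist(y$annotations)),
               survey_path = resolve(y$surveys),
               out_dir = y$out_dir %||% "report",
               grid = y$grid %||% 5, window = y$window %||% 10,
               window_mode = y$window_mode %||% "symmetric",
               intersection = y$intersection %||% "multiset",
               filter_code = y$filter_code %||% "Mental Model",
               quantile_type = y$quantile_type %||% 7)
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
}

#' Run the full study pipeline and write a report directory
#'
#' Loads the codebook, each session's annotations and (optionally) the
#' surveys, then writes: `kappa.tsv` (per-session per-reference kappas with
#' min/max and interpretation), `transitions_shared.tsv` (ranked shared
#' counts over all sessions), `transitions_filtered.tsv` (shared counts
#' involving `filter_code`), `survey_tlx.tsv` / `survey_confidence.tsv` /
#' `confidence_change.tsv` when surveys are supplied, one timeline PNG per
#' session under `timelines/`, and `run_log.json` recording every resolved
#' parameter. Any stage failure aborts and removes partial outputs.
#'
#' @param cfg a [study_config] or path to its YAML file.
#' @return The output directory path, invisibly.
#' @export
run_study <- function(cfg) {
  if (is.character(cfg)) cfg <- read_study_config(cfg)
  stopifnot(inherits(cfg, "study_config"))
  out <- cfg$out_dir
  created <- !dir.exists(out)
  dir.create(out, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out, "timelines"), showWarnings = FALSE)
  ok <- FALSE
  on.exit(if (!ok && created) unlink(out, recursive = TRUE))

  cb <- load_codebook(cfg$codebook_path)
  sessions <- lapply(cfg$annotation_paths, read_annotations, codebook = cb,
                     grid = cfg$grid)

  kap <- do.call(rbind, lapply(sessions, function(ann) {
    kr <- kappa_range(ann, cb, window = cfg$window, grid = cfg$grid,
                      window_mode = cfg$window_mode)
    data.frame(session_id = kr$session_id,
               reference = names(kr$per_reference),
               kappa = unname(kr$per_reference),
               min_k = kr$min_k, max_k = kr$max_k,
               interpretation = interpret_kappa(unname(kr$per_reference)))
  }))
  write_tsv(kap, file.path(out, "kappa.tsv"))

  shared <- shared_transition_counts(sessions, intersection = cfg$intersection)
  write_tsv(label_transitions(shared, cb),
            file.path(out, "transitions_shared.tsv"))
  if (!is.null(cfg$filter_code) && cfg$filter_code %in% cb$name) {
    filt <- filter_transitions(shared, code_id(cb, cfg$filter_code))
    write_tsv(label_transitions(filt, cb),
              file.path(out, "transitions_filtered.tsv"))
  }

  if (!is.null(cfg$survey_path)) {
    sv <- read_surveys(cfg$survey_path)
    ss <- survey_summary(sv, quantile_type = cfg$quantile_type)
    write_tsv(ss$tlx, file.path(out, "survey_tlx.tsv"))
    write_tsv(ss$confidence, file.path(out, "survey_confidence.tsv"))
    cc <- confidence_change_table(sv)
    ccdf <- do.call(rbind, lapply(cc$items, function(it)
      data.frame(item = it$item, increased = it$increased,
                 unchanged = it$unchanged, decreased = it$decreased,
                 t = it$test$t, df = it$test$df, p_welch = it$test$p,
                 F = it$f_test$F, p_f = it$f_test$p)))
    write_tsv(ccdf, file.path(out, "confidence_change.tsv"))
  }

  for (ann in sessions) {
    plot_timeline(ann, cb,
                  out = file.path(out, "timelines",
                                  paste0(ann$session_id, ".png")))
  }

  log <- list(
    parameters = cfg[setdiff(names(cfg), NULL)],
    n_sessions = length(sessions),
    session_ids = vapply(sessions, `[[`, "", "session_id"),
    n_events = vapply(sessions, function(a) nrow(a$events), integer(1)),
    codebook_version = attr(cb, "version"),
    n_codes = nrow(cb))
  jsonlite::write_json(log, file.path(out, "run_log.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  ok <- TRUE
  invisible(out)
}

#' @importFrom ggplot2 .data
NULL
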