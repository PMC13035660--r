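# Evaluate expr under a private RNG stream, leaving the caller's RNG alone.
with_local_seed <- function(seed, expr) {
  old <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    get(".Random.seed", envir = globalenv())
  } else NULL
  on.exit({
    if (is.null(old)) {
      if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
        rm(".Random.seed", envir = globalenv())
      }
    } else {
      assign(".Random.seed", old, envir = globalenv())
    }
  })
  set.seed(as.integer(seed %% 2147483629))
  expr
}

# deterministic per-(seed, stream) sub-seed, kept below 2^31
derive_seed <- function(seed, stream) {
  as.integer((as.double(seed) * 48271 + as.double(stream) * 16807 + 1) %%
               2147483629)
}

#' Default truth transition kernel
#'
#' A row-stochastic matrix over the codebook used as the semi-Markov truth
#' kernel. Every ordered pair of distinct codes has baseline weight 1;
#' pairs that dominate real coded sessions (3D exploration feeding anatomy
#' discussion, anatomy feeding confirmation/planning, confirmation feeding
#' mental-model statements at twice the reverse rate, frustration tied to
#' tool usage) are up-weighted, then rows are normalized. Self-transitions
#' have weight 0.
#'
#' @param codebook a [codebook]; boosts apply where the default code names
#'   are present, so any codebook works.
#' @return A `nrow(codebook)` square matrix with rows summing to 1,
#'   dimnames = code ids.
#' @export
default_transition_matrix <- function(codebook = default_codebook()) {
  n <- nrow(codebook)
  ids <- as.character(sort(codebook$id))
  W <- matrix(1, n, n, dimnames = list(ids, ids))
  diag(W) <- 0
  boost <- function(from, to, w) {
    if (from %in% codebook$name && to %in% codebook$name) {
      W[as.character(code_id(codebook, from)),
        as.character(code_id(codebook, to))] <<- w
    }
  }
  boost("3D Manipulation", "Anatomy", 9)
  boost("Tool Usage", "3D Manipulation", 9)
  boost("Orienting", "Tool Usage", 8)
  boost("Orienting", "Anatomy", 8)
  boost("Anatomy", "Confirmation", 7)
  boost("Orienting", "3D Manipulation", 6)
  boost("3D Manipulation", "Orienting", 5)
  boost("Anatomy", "Planning", 5)
  boost("Tool Usage", "Anatomy", 5)
  boost("Anatomy", "Orienting", 4)
  boost("Mental Model", "Anatomy", 5)
  boost("3D Manipulation", "Mental Model", 4)
  boost("Anatomy", "Mental Model", 4)
  boost("Confirmation", "Mental Model", 4)
  boost("Mental Model", "Confirmation", 2)  # half the reverse direction
  boost("Anatomy", "Excitement", 4)
  boost("Planning", "Excitement", 3)
  boost("Planning", "Confirmation", 3)
  boost("Anatomy", "Uncertainty", 4)
  boost("Uncertainty", "3D Manipulation", 3)
  boost("Tool Usage", "Frustration", 3)
  boost("Anatomy", "Path Finding", 4)
  boost("Path Finding", "Mental Model", 2)
  sweep(W, 1, rowSums(W), "/")
}

#' Generator configuration
#'
#' Bundles the latent truth process and the rater noise model used by the
#' synthetic session generator. Defaults emulate the study conditions the
#' analyses assume: 13-minute sessions, 5 coders, the 12-code default
#' framework, overlapping events on a 5-second grid, and noise calibrated so
#' per-session Fleiss' kappa ranges land in the moderate-to-substantial band
#' observed for real multi-coder sessions (roughly 0.47-0.82).
#'
#' @param codebook a [codebook].
#' @param session_length_s session length in seconds (default 780 s, the
#'   ~13-minute typical session).
#' @param transition_matrix row-stochastic truth kernel over the codebook's
#'   codes (rows/cols ordered by code id).
#' @param dwell_mean_s mean event duration, exponential dwell (default 20 s).
#' @param gap_mean_s mean gap between one event's end and the next event's
#'   start (default 5 s).
#' @param co_start_prob probability the next event starts simultaneously
#'   with the current one, creating overlap (default 0.1).
#' @param n_coders number of simulated coders (default 5).
#' @param p_miss per-event probability a coder misses the event.
#' @param p_sub per-event probability a coder records a different
#'   (uniformly random) code.
#' @param jitter_sd_s standard deviation of the Gaussian timing noise added
#'   to each endpoint before grid rounding.
#' @param insertion_rate_per_min rate of spurious extra events per coder.
#' @param survey_pre_center named pre-session response centers.
#' @param survey_shift named additive post-session shifts.
#' @param survey_sd response noise standard deviation on the Likert scales.
#' @param seed default seed used by the generator functions.
#' @return list of class `generator_config`.
#' @export
generator_config <- function(codebook = default_codebook(),
                             session_length_s = 780,
                             transition_matrix =
                               default_transition_matrix(codebook),
                             dwell_mean_s = 20,
                             gap_mean_s = 5,
                             co_start_prob = 0.1,
                             n_coders = 5,
                             p_miss = 0.10,
                             p_sub = 0.10,
                             jitter_sd_s = 3,
                             insertion_rate_per_min = 0.5,
                             survey_pre_center = c(confidence_anatomy = 4,
                                                   confidence_approach = 4),
                             survey_shift = c(confidence_anatomy = 1,
                                              confidence_approach = 0.25),
                             survey_sd = 0.75,
                             seed = 1L) {
  stopifnot(inherits(codebook, "codebook"), session_length_s > 0,
            dwell_mean_s > 0, gap_mean_s >= 0, n_coders >= 1)
  tm <- as.matrix(transition_matrix)
  if (nrow(tm) != nrow(codebook) || ncol(tm) != nrow(codebook)) {
    stop("transition_matrix must be square over the codebook's codes")
  }
  if (any(tm < 0) || any(abs(rowSums(tm) - 1) > 1e-9)) {
    stop("transition_matrix rows must be non-negative and sum to 1")
  }
  probs <- c(co_start_prob, p_miss, p_sub)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  if (jitter_sd_s < 0 || insertion_rate_per_min < 0) {
    stop("noise magnitudes must be non-negative")
  }
  structure(list(codebook = codebook, session_length_s = session_length_s,
                 transition_matrix = tm, dwell_mean_s = dwell_mean_s,
                 gap_mean_s = gap_mean_s, co_start_prob = co_start_prob,
                 n_coders = n_coders, p_miss = p_miss, p_sub = p_sub,
                 jitter_sd_s = jitter_sd_s,
                 insertion_rate_per_min = insertion_rate_per_min,
                 survey_pre_center = survey_pre_center,
                 survey_shift = survey_shift, survey_sd = survey_sd,
                 seed = as.integer(seed)),
            class = "generator_config")
}

#' Generate a latent truth event stream
#'
#' A semi-Markov process: codes follow the transition kernel, event
#' durations are exponential with mean `dwell_mean_s`, consecutive events
#' are separated by an exponential gap with mean `gap_mean_s`, and with
#' probability `co_start_prob` the next event starts simultaneously with the
#' current one (producing the overlap structure coders create). Times are
#' continuous; grid rounding happens downstream.
#'
#' @param cfg a [generator_config].
#' @param seed overrides `cfg$seed`.
#' @return object of class `truth_stream`: list with `events` (data.frame
#'   `code_id`, `start_s`, `end_s`, starts non-decreasing) and
#'   `session_length_s`.
#' @export
generate_truth <- function(cfg, seed = cfg$seed) {
  stopifnot(inherits(cfg, "generator_config"))
  ids <- sort(cfg$codebook$id)
  L <- cfg$session_length_s
  with_local_seed(derive_seed(seed, 0L), {
    code <- sample(ids, 1L)
    t <- 0
    codes <- integer(); starts <- numeric(); ends <- numeric()
    repeat {
      dwell <- rexp(1, 1 / cfg$dwell_mean_s)
      codes <- c(codes, code)
      starts <- c(starts, t)
      ends <- c(ends, min(t + dwell, L))
      nxt <- sample(ids, 1L,
                    prob = cfg$transition_matrix[match(code, ids), ])
      if (runif(1) < cfg$co_start_prob) {
        t_next <- t
      } else {
        t_next <- t + dwell + rexp(1, 1 / max(cfg$gap_mean_s, 1e-9))
      }
      if (t_next >= L) break
      code <- nxt
      t <- t_next
    }
    structure(list(events = data.frame(code_id = codes, start_s = starts,
                                       end_s = ends),
                   session_length_s = L),
              class = "truth_stream")
  })
}

#' Transition multiset of a truth stream
#'
#' Applies the same co-start grouping rule the analysis applies to coded
#' annotations (grid-rounded starts, adjacent-group cross products), so
#' zero-noise coder streams reproduce these counts exactly.
#'
#' @param truth a `truth_stream`.
#' @param grid grid spacing in seconds.
#' @return data.frame `from_code`, `to_code`, `count`.
#' @export
truth_transitions <- function(truth, grid = 5) {
  stopifnot(inherits(truth, "truth_stream"))
  transition_pairs(truth$events$code_id,
                   round_to_grid(truth$events$start_s, grid))
}

#' Corrupt a truth stream into one coder's event list
#'
#' Independently per truth event: dropped with probability `p_miss`; its
#' code replaced by a uniformly random different code with probability
#' `p_sub`; both endpoints jittered by centered Gaussian noise with sd
#' `jitter_sd_s` (start clamped to >= 0, length clamped to >= 0). Spurious
#' events are then added as a Poisson process at `insertion_rate_per_min`
#' with uniform codes and exponential dwells. Jitter precedes grid rounding
#' so the rounding path is exercised. Deterministic given (seed,
#' coder_index); adding a coder never perturbs earlier coders' streams.
#'
#' @param truth a `truth_stream`.
#' @param cfg a [generator_config].
#' @param coder_index 1-based coder number, `<= cfg$n_coders`.
#' @param seed overrides `cfg$seed`.
#' @return data.frame `code_id`, `start_s`, `end_s` (unrounded).
#' @export
corrupt_stream <- function(truth, cfg, coder_index, seed = cfg$seed) {
  stopifnot(inherits(truth, "truth_stream"),
            inherits(cfg, "generator_config"))
  if (coder_index < 1 || coder_index > cfg$n_coders) {
    stop("coder_index must be in 1..n_coders")
  }
  ids <- sort(cfg$codebook$id)
  ev <- truth$events
  L <- truth$session_length_s
  with_local_seed(derive_seed(seed, coder_index), {
    keep <- runif(nrow(ev)) >= cfg$p_miss
    ev <- ev[keep, , drop = FALSE]
    if (nrow(ev)) {
      sub <- runif(nrow(ev)) < cfg$p_sub
      if (any(sub) && length(ids) > 1L) {
        ev$code_id[sub] <- vapply(ev$code_id[sub], function(cd)
          sample(setdiff(ids, cd), 1L), integer(1))
      }
      if (cfg$jitter_sd_s > 0) {
        ev$start_s <- pmax(0, ev$start_s + rnorm(nrow(ev), 0, cfg$jitter_sd_s))
        ev$end_s <- ev$end_s + rnorm(nrow(ev), 0, cfg$jitter_sd_s)
        ev$end_s <- pmax(ev$end_s, ev$start_s)
      }
    }
    n_ins <- rpois(1, cfg$insertion_rate_per_min * L / 60)
    if (n_ins > 0) {
      s <- runif(n_ins, 0, L)
      d <- rexp(n_ins, 1 / cfg$dwell_mean_s)
      ins <- data.frame(code_id = sample(ids, n_ins, replace = TRUE),
                        start_s = s, end_s = pmin(s + d, L))
      ev <- rbind(ev, ins)
    }
    ev <- ev[order(ev$start_s, ev$end_s, ev$code_id), , drop = FALSE]
    rownames(ev) <- NULL
    ev
  })
}

#' Generate one multi-coder synthetic session
#'
#' Draws a truth stream, corrupts it once per coder, grid-rounds and
#' assembles the result into a [session_annotations] object. The truth
#' stream and its transition counts are returned for oracle comparisons.
#' Zero-length events arising from jitter plus rounding are retained
#' silently here (they are an expected product of the noise model).
#'
#' @param cfg a [generator_config].
#' @param session_id session identifier.
#' @param seed overrides `cfg$seed`.
#' @param grid grid spacing in seconds.
#' @return list with `annotations` ([session_annotations]), `truth`
#'   (`truth_stream`) and `truth_transitions` (data.frame).
#' @export
generate_session <- function(cfg, session_id = "s1", seed = cfg$seed,
                             grid = 5) {
  truth <- generate_truth(cfg, seed)
  coders <- sprintf("coder%d", seq_len(cfg$n_coders))
  rows <- lapply(seq_len(cfg$n_coders), function(i) {
    ev <- corrupt_stream(truth, cfg, i, seed)
    if (!nrow(ev)) return(NULL)
    data.frame(session_id = session_id, coder_id = coders[i],
               code_id = ev$code_id, start_s = ev$start_s, end_s = ev$end_s)
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows)) {
    rows <- data.frame(session_id = character(), coder_id = character(),
                       code_id = integer(), start_s = numeric(),
                       end_s = numeric())
  }
  ann <- suppressWarnings(session_annotations(
    rows, session_id = session_id, coders = coders,
    duration_s = max(round_to_grid(cfg$session_length_s, grid),
                     if (nrow(rows)) max(round_to_grid(rows$end_s, grid))
                     else 0),
    grid = grid))
  list(annotations = ann, truth = truth,
       truth_transitions = truth_transitions(truth, grid))
}

#' Generate a multi-session synthetic study
#'
#' Session lengths are drawn log-normally around the configured typical
#' length and clamped to the 6-45 minute range real sessions span; each
#' session uses an independent derived seed.
#'
#' @param cfg a [generator_config].
#' @param n_sessions number of sessions (default 10).
#' @param seed overrides `cfg$seed`.
#' @param vary_length draw per-session lengths (default `TRUE`); when
#'   `FALSE` every session uses `cfg$session_length_s`.
#' @return list of [generate_session()] results, named by session id.
#' @export
generate_study <- function(cfg, n_sessions = 10, seed = cfg$seed,
                           vary_length = TRUE) {
  lengths <- if (vary_length) {
    with_local_seed(derive_seed(seed, 900001L), {
      pmin(pmax(stats::rlnorm(n_sessions, log(cfg$session_length_s), 0.5),
                360), 2700)
    })
  } else rep(cfg$session_length_s, n_sessions)
  out <- lapply(seq_len(n_sessions), function(i) {
    cfg_i <- cfg
    cfg_i$session_length_s <- lengths[i]
    generate_session(cfg_i, session_id = sprintf("s%02d", i),
                     seed = derive_seed(seed, 1000L + i))
  })
  names(out) <- sprintf("s%02d", seq_len(n_sessions))
  out
}

#' Generate synthetic pre/post survey responses
#'
#' Pre-session confidence is drawn around the configured centers on the 1-5
#' scale; post-session responses add the configured item-wise shift, with
#' everything rounded and clamped to scale. NASA-TLX dimensions are drawn
#' post-session around centers typical of a low-workload VR review (mental
#' 3, physical 2.5, time 1, performance 10, effort 3, frustration 1);
#' the surgical-conference mental-demand item (center 6) is emitted for the
#' final 7 sessions only, mirroring its partial collection.
#'
#' @param cfg a [generator_config].
#' @param n_sessions number of sessions.
#' @param seed overrides `cfg$seed`.
#' @return A `survey_responses` data.frame with one pre and one post row per
#'   session.
#' @export
generate_surveys <- function(cfg, n_sessions = 10, seed = cfg$seed) {
  stopifnot(n_sessions >= 1)
  tlx_centers <- c(tlx_mental = 3, tlx_physical = 2.5, tlx_time = 1,
                   tlx_performance = 10, tlx_effort = 3, tlx_frustration = 1)
  clamp <- function(v, lo, hi) pmin(pmax(round(v), lo), hi)
  with_local_seed(derive_seed(seed, 424243L), {
    sid <- sprintf("s%02d", seq_len(n_sessions))
    pre_an <- clamp(rnorm(n_sessions, cfg$survey_pre_center[["confidence_anatomy"]],
                          cfg$survey_sd), 1, 5)
    pre_ap <- clamp(rnorm(n_sessions, cfg$survey_pre_center[["confidence_approach"]],
                          cfg$survey_sd), 1, 5)
    post_an <- clamp(pre_an + cfg$survey_shift[["confidence_anatomy"]] +
                       rnorm(n_sessions, 0, cfg$survey_sd / 2), 1, 5)
    post_ap <- clamp(pre_ap + cfg$survey_shift[["confidence_approach"]] +
                       rnorm(n_sessions, 0, cfg$survey_sd / 2), 1, 5)
    tlx <- vapply(tlx_centers, function(cc)
      clamp(rnorm(n_sessions, cc, 1), 1, 10), numeric(n_sessions))
    tlx <- matrix(tlx, nrow = n_sessions,
                  dimnames = list(NULL, names(tlx_centers)))
    conf_md <- rep(NA_real_, n_sessions)
    late <- seq_len(n_sessions) > max(0, n_sessions - 7)
    conf_md[late] <- clamp(rnorm(sum(late), 6, 1), 1, 10)
    pre <- data.frame(session_id = sid, phase = "pre",
                      confidence_anatomy = pre_an,
                      confidence_approach = pre_ap,
                      tlx_mental = NA_real_, tlx_physical = NA_real_,
                      tlx_time = NA_real_, tlx_performance = NA_real_,
                      tlx_effort = NA_real_, tlx_frustration = NA_real_,
                      conference_mental_demand = NA_real_)
    post <- data.frame(session_id = sid, phase = "post",
                       confidence_anatomy = post_an,
                       confidence_approach = post_ap)
    post <- cbind(post, as.data.frame(tlx))
    post$conference_mental_demand <- conf_md
    validate_surveys(rbind(pre, post))
  })
}

#' @export
print.generator_config <- function(x, ...) {
  cat("<generator_config> ", nrow(x$codebook), " codes, ",
      x$n_coders, " coders, ", x$session_length_s, " s sessions\n",
      "  noise: p_miss = ", x$p_miss, ", p_sub = ", x$p_sub,
      ", jitter_sd = ", x$jitter_sd_s, " s, insertions = ",
      x$insertion_rate_per_min, "/min\n", sep = "")
  invisible(x)
}
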