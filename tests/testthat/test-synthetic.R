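test_that("generator config validates its kernel and probabilities", {
  cb <- tiny_codebook()
  km <- matrix(c(0, .5, .5, .25, 0, .75, .5, .5, 0), 3, byrow = TRUE)
  cfg <- generator_config(cb, transition_matrix = km)
  expect_s3_class(cfg, "generator_config")
  bad <- km; bad[1, 1] <- 0.2
  expect_error(generator_config(cb, transition_matrix = bad), "sum to 1")
  expect_error(generator_config(cb, transition_matrix = km[1:2, 1:2]),
               "square")
  expect_error(generator_config(cb, transition_matrix = km, p_sub = 1.2),
               "\\[0, 1\\]")
  dm <- default_transition_matrix(default_codebook())
  expect_equal(unname(rowSums(dm)), rep(1, 12), tolerance = 1e-12)
  expect_true(all(diag(dm) == 0))
})

test_that("truth generation is deterministic and respects an absorbing kernel", {
  cb <- tiny_codebook()
  absorbing <- diag(3)  # every code maps to itself
  cfg <- generator_config(cb, transition_matrix = absorbing,
                          session_length_s = 300)
  tr <- generate_truth(cfg, seed = 4)
  expect_equal(length(unique(tr$events$code_id)), 1L)
  expect_true(all(diff(tr$events$start_s) >= 0))
  expect_true(all(tr$events$end_s > tr$events$start_s))
  expect_true(max(tr$events$end_s) <= 300)

  cfg2 <- generator_config(cb, session_length_s = 600)
  expect_identical(generate_truth(cfg2, seed = 9)$events,
                   generate_truth(cfg2, seed = 9)$events)
  expect_false(identical(generate_truth(cfg2, seed = 9)$events,
                         generate_truth(cfg2, seed = 10)$events))
})

test_that("an asymmetric kernel produces asymmetric truth transition counts", {
  cb <- tiny_codebook()
  # P(1 -> 2) twice P(2 -> 1)
  km <- matrix(c(0, 2 / 3, 1 / 3,
                 1 / 3, 0, 2 / 3,
                 1 / 2, 1 / 2, 0), 3, byrow = TRUE)
  cfg <- generator_config(cb, transition_matrix = km,
                          session_length_s = 780, co_start_prob = 0)
  tot <- c(ab = 0, ba = 0)
  for (s in 1:100) {
    tt <- truth_transitions(generate_truth(cfg, seed = s))
    tot["ab"] <- tot["ab"] + sum(tt$count[tt$from_code == 1 & tt$to_code == 2])
    tot["ba"] <- tot["ba"] + sum(tt$count[tt$from_code == 2 & tt$to_code == 1])
  }
  expect_gt(tot[["ab"]], tot[["ba"]])
})

test_that("corruption is the identity at zero noise and total loss at p_miss = 1", {
  cfg <- generator_config(session_length_s = 400, p_miss = 0, p_sub = 0,
                          jitter_sd_s = 0, insertion_rate_per_min = 0,
                          co_start_prob = 0)
  tr <- generate_truth(cfg, seed = 2)
  for (i in c(1, 3)) {
    expect_equal(corrupt_stream(tr, cfg, i, seed = 2),
                 tr$events[, c("code_id", "start_s", "end_s")],
                 ignore_attr = TRUE)
  }
  cfg_all <- generator_config(session_length_s = 400, p_miss = 1, p_sub = 0,
                              jitter_sd_s = 0, insertion_rate_per_min = 0)
  expect_equal(nrow(corrupt_stream(tr, cfg_all, 1, seed = 2)), 0L)
  expect_error(corrupt_stream(tr, cfg, 9, seed = 2), "coder_index")
})

test_that("substitution noise hits its nominal per-event rate", {
  cfg <- generator_config(session_length_s = 600, p_miss = 0, p_sub = 0.2,
                          jitter_sd_s = 0, insertion_rate_per_min = 0,
                          co_start_prob = 0)
  changed <- 0L; total <- 0L
  for (s in 1:100) {
    tr <- generate_truth(cfg, seed = s)
    cs <- corrupt_stream(tr, cfg, 1, seed = s)
    changed <- changed + sum(cs$code_id != tr$events$code_id)
    total <- total + nrow(tr$events)
  }
  rate <- changed / total
  se <- sqrt(0.2 * 0.8 / total)
  expect_lt(abs(rate - 0.2), 4 * se)
})

test_that("per-coder streams depend only on (seed, coder index)", {
  cfg <- generator_config(session_length_s = 400)
  tr <- generate_truth(cfg, seed = 3)
  a1 <- corrupt_stream(tr, cfg, 1, seed = 3)
  cfg_more <- generator_config(session_length_s = 400, n_coders = 7)
  expect_identical(a1, corrupt_stream(tr, cfg_more, 1, seed = 3))
  expect_false(identical(a1, corrupt_stream(tr, cfg, 2, seed = 3)))
})

test_that("a zero-noise session gives kappa 1 for every reference and exact shared counts", {
  cfg <- generator_config(p_miss = 0, p_sub = 0, jitter_sd_s = 0,
                          insertion_rate_per_min = 0, session_length_s = 600)
  g <- generate_session(cfg, seed = 5)
  kr <- kappa_range(g$annotations, cfg$codebook)
  expect_equal(unname(kr$per_reference), rep(1, 5))
  sh <- shared_transition_counts(g$annotations)
  truth <- g$truth_transitions
  m <- merge(as.data.frame(sh), truth, by = c("from_code", "to_code"),
             all = TRUE)
  expect_false(anyNA(m))
  expect_equal(m$count.x, choose(5, 2) * m$count.y)
})

test_that("generated sessions are on-grid, deterministic and carry the full roster", {
  cfg <- generator_config(session_length_s = 300, n_coders = 4, seed = 8)
  g <- generate_session(cfg, session_id = "sX")
  ann <- g$annotations
  expect_equal(ann$coders, sprintf("coder%d", 1:4))
  expect_true(all(ann$events$start_s %% 5 == 0))
  expect_true(all(ann$events$end_s %% 5 == 0))
  expect_identical(generate_session(cfg, session_id = "sX")$annotations$events,
                   ann$events)
  # a single-coder session still supports transition extraction
  cfg1 <- generator_config(session_length_s = 300, n_coders = 1)
  g1 <- generate_session(cfg1, seed = 2)
  expect_error(kappa_range(g1$annotations, cfg1$codebook), "2 coders")
  expect_s3_class(extract_transitions(g1$annotations, "coder1"),
                  "transition_table")
})

test_that("study generation varies session lengths within the 6-45 min range", {
  cfg <- generator_config(seed = 12)
  st <- generate_study(cfg, n_sessions = 6)
  expect_equal(names(st), sprintf("s%02d", 1:6))
  durs <- vapply(st, function(g) g$truth$session_length_s, numeric(1))
  expect_true(all(durs >= 360 & durs <= 2700))
  expect_gt(length(unique(durs)), 1L)
})

test_that("synthetic surveys honor shifts, scales and partial collection", {
  cfg <- generator_config(survey_shift = c(confidence_anatomy = 0,
                                           confidence_approach = 0),
                          survey_sd = 0)
  sv <- generate_surveys(cfg, n_sessions = 10, seed = 1)
  pre <- sv[sv$phase == "pre", ]
  post <- sv[sv$phase == "post", ]
  expect_equal(post$confidence_anatomy, pre$confidence_anatomy)  # zero shift
  cfg1 <- generator_config(survey_shift = c(confidence_anatomy = 1,
                                            confidence_approach = 0),
                           survey_sd = 0)
  sv1 <- generate_surveys(cfg1, n_sessions = 10, seed = 1)
  expect_equal(median(sv1$confidence_anatomy[sv1$phase == "post"]) -
                 median(sv1$confidence_anatomy[sv1$phase == "pre"]), 1)
  expect_true(all(sv1$confidence_anatomy <= 5))
  # conference mental demand collected for the last 7 sessions only
  expect_equal(sum(!is.na(sv1$conference_mental_demand[sv1$phase == "post"])), 7L)
  expect_identical(generate_surveys(cfg1, 10, seed = 4),
                   generate_surveys(cfg1, 10, seed = 4))
})

test_that("a post shift on anatomy only is detected more often on anatomy", {
  cfg <- generator_config(survey_shift = c(confidence_anatomy = 1,
                                           confidence_approach = 0),
                          survey_sd = 0.75)
  wins <- 0L
  n_rep <- 60
  for (s in seq_len(n_rep)) {
    sv <- generate_surveys(cfg, n_sessions = 10, seed = s)
    cc <- suppressWarnings(confidence_change_table(sv))
    p_an <- cc$items$confidence_anatomy$test$p
    p_ap <- cc$items$confidence_approach$test$p
    if (is.na(p_ap) || (!is.na(p_an) && p_an < p_ap)) wins <- wins + 1L
  }
  expect_gte(wins / n_rep, 0.9)
})
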