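test_that("unitization tiles half-open events into per-code 5-s frames", {
  s <- make_session(list(ref = ev(1L, 10, 25), other = ev(1L, 10, 25)))
  fr <- unitize_reference(s, "ref")
  expect_equal(fr$t, c(10, 15, 20))
  expect_equal(fr$code_id, rep(1L, 3))

  s2 <- make_session(list(ref = ev(c(1L, 2L), c(10, 15), c(20, 25)),
                          other = ev(1L, 0, 5)))
  fr2 <- unitize_reference(s2, "ref")
  expect_equal(fr2$t, c(10, 15, 15, 20))
  expect_equal(fr2$code_id, c(1L, 1L, 2L, 2L))

  s3 <- make_session(list(ref = ev(integer(), numeric(), numeric()),
                          other = ev(1L, 0, 5)), coders = c("ref", "other"))
  expect_equal(nrow(unitize_reference(s3, "ref")), 0L)
})

test_that("windowed alignment returns agreement, best differing code, or 0", {
  # same code starting 8 s after the frame: agreement within the 10 s window
  s <- make_session(list(ref = ev(1L, 10, 15), other = ev(1L, 18, 30)))
  fr <- list(t = 10, code_id = 1L)
  expect_equal(align_frame(s, fr, "other"), 1L)
  # nothing identified in the window: reserved 0
  s0 <- make_session(list(ref = ev(1L, 10, 15), other = ev(1L, 50, 60)))
  expect_equal(align_frame(s0, fr, "other"), 0L)
  # only a different code in the window: that code is recorded
  sB <- make_session(list(ref = ev(1L, 10, 15), other = ev(2L, 5, 30)))
  expect_equal(align_frame(sB, fr, "other"), 2L)
  # several differing codes: maximal window overlap wins
  sC <- make_session(list(ref = ev(1L, 10, 15),
                          other = ev(c(2L, 3L), c(0, 10), c(10, 25))))
  expect_equal(align_frame(sC, fr, "other"), 3L)
  # exact overlap tie between differing codes: smaller code id wins
  sD <- make_session(list(ref = ev(1L, 10, 15),
                          other = ev(c(3L, 2L), c(10, 10), c(25, 25))))
  expect_equal(align_frame(sD, fr, "other"), 2L)
})

test_that("window mode bounds are respected", {
  # other's code lies 12 s after the frame start: inside the symmetric
  # window [t-10, t+15) only
  s <- make_session(list(ref = ev(1L, 20, 25), other = ev(1L, 32, 40)))
  fr <- list(t = 20, code_id = 1L)
  expect_equal(align_frame(s, fr, "other", window_mode = "symmetric"), 1L)
  expect_equal(align_frame(s, fr, "other", window_mode = "trailing"), 0L)
  # 8 s before the frame: inside both
  s2 <- make_session(list(ref = ev(1L, 20, 25), other = ev(1L, 10, 12)))
  expect_equal(align_frame(s2, fr, "other", window_mode = "trailing"), 1L)
  expect_equal(align_frame(s2, fr, "other", window = 0), 0L)
})

test_that("agreement matrix rows always sum to the coder count", {
  cb <- tiny_codebook()
  # two coders, the other silent: every row is {ref_code: 1, 0: 1}
  s <- make_session(list(ref = ev(1L, 0, 20), other = ev(1L, 300, 310)),
                    duration_s = 310)
  m <- build_agreement_matrix(s, "ref", cb)
  expect_equal(unname(rowSums(m)), rep(2L, 4))
  expect_equal(unname(m[, "0"]), rep(1L, 4))
  expect_equal(unname(m[, "1"]), rep(1L, 4))

  # five identical coders: full count lands in the reference code column
  same <- ev(c(1L, 2L), c(0, 30), c(20, 50))
  s5 <- make_session(setNames(rep(list(same), 5), paste0("c", 1:5)))
  m5 <- build_agreement_matrix(s5, "c1", cb)
  expect_equal(unname(rowSums(m5)), rep(5L, nrow(m5)))
  expect_true(all(m5[cbind(seq_len(nrow(m5)),
                           match(attr(m5, "frames")$code_id,
                                 as.integer(colnames(m5))))] == 5L))

  # synthetic noisy 5-coder session: rows still sum to 5
  cfg <- generator_config(session_length_s = 300, seed = 3)
  ann <- generate_session(cfg, seed = 3)$annotations
  mN <- build_agreement_matrix(ann, "coder3", default_codebook())
  expect_equal(unname(rowSums(mN)), rep(5L, nrow(mN)))

  s1c <- make_session(list(only = ev(1L, 0, 10)))
  expect_error(build_agreement_matrix(s1c, "only", cb), "2 coders")
})

test_that("Fleiss' kappa matches the hand-computed worked example", {
  # 4 units, 3 raters, 2 categories: P_i = 1, 1/3, 1/3, 1; pooled
  # proportions 1/2 each, so Pbar = 2/3, Pe = 1/2, kappa = 1/3
  m <- rbind(c(3, 0), c(2, 1), c(1, 2), c(0, 3))
  expect_equal(fleiss_kappa(m), 1 / 3, tolerance = 1e-15)
})

test_that("Fleiss' kappa hits its anchor values and degenerate limits", {
  expect_equal(fleiss_kappa(rbind(c(4, 0), c(0, 4), c(4, 0))), 1)
  # engineered so observed agreement equals chance agreement: kappa = 0
  m0 <- rbind(c(2, 0), c(0, 2), c(1, 1), c(1, 1))
  expect_equal(fleiss_kappa(m0), 0)
  expect_warning(k1 <- fleiss_kappa(rbind(c(3, 0), c(3, 0))),
                 "single category")
  expect_equal(k1, 1)
  expect_warning(kNA <- fleiss_kappa(matrix(integer(), 0, 3)), "no units")
  expect_true(is.na(kNA))
  expect_error(fleiss_kappa(rbind(c(2, 1), c(2, 0))), "same number")
  expect_error(fleiss_kappa(rbind(c(1, 0), c(0, 1))), "at least 2 raters")
})

test_that("kappa is invariant under row and column permutations and stays in [-1, 1]", {
  set.seed(42)
  for (i in 1:25) {
    n_cat <- sample(2:5, 1)
    n_r <- sample(2:6, 1)
    m <- random_rating_matrix(sample(2:12, 1), n_r, n_cat)
    k <- suppressWarnings(fleiss_kappa(m))
    expect_true(is.na(k) || (k >= -1 - 1e-12 && k <= 1 + 1e-12))
    kp <- suppressWarnings(
      fleiss_kappa(m[sample(nrow(m)), sample(ncol(m)), drop = FALSE]))
    expect_equal(kp, k, tolerance = 1e-12)
    # unanimity iff kappa == 1
    expect_equal(isTRUE(all.equal(k, 1)),
                 all(apply(m, 1, max) == rowSums(m)[1]))
  }
})

test_that("kappa matches the brute-force pair-counting oracle on enumerated matrices", {
  # exhaustive 2-unit matrices over all rating compositions
  for (dims in list(c(3, 2), c(3, 3), c(4, 3))) {
    rows <- compositions(dims[1], dims[2])
    for (i in seq_len(nrow(rows))) {
      for (j in seq_len(nrow(rows))) {
        m <- rbind(rows[i, ], rows[j, ])
        expect_equal(suppressWarnings(fleiss_kappa(m)),
                     suppressWarnings(oracle_fleiss(m)), tolerance = 1e-12)
      }
    }
  }
})

test_that("per-session kappa range covers every usable reference and excludes silent coders", {
  cb <- tiny_codebook()
  same <- ev(c(1L, 2L, 3L), c(0, 30, 60), c(20, 50, 80))
  s5 <- make_session(setNames(rep(list(same), 5), paste0("c", 1:5)))
  kr <- kappa_range(s5, cb)
  expect_equal(unname(kr$per_reference), rep(1, 5))
  expect_equal(kr$min_k, 1)
  expect_equal(kr$max_k, 1)
  expect_equal(unname(kr$interpretation), rep("almost perfect", 2))

  per <- setNames(rep(list(same), 5), paste0("c", 1:5))
  per$c5 <- ev(integer(), numeric(), numeric())
  s4 <- make_session(per, coders = paste0("c", 1:5))
  kr4 <- kappa_range(s4, cb)
  expect_equal(length(kr4$per_reference), 4L)
  expect_equal(kr4$excluded, "c5")
  expect_true(kr4$min_k <= kr4$max_k)
})

test_that("kappa interpretation bands assign boundaries upward", {
  expect_equal(interpret_kappa(0.75), "substantial")
  expect_equal(interpret_kappa(-0.3), "very poor")
  expect_equal(interpret_kappa(1.0), "almost perfect")
  expect_equal(interpret_kappa(c(0.2, 0.4, 0.6, 0.8)),
               c("fair", "moderate", "substantial", "almost perfect"))
  expect_error(interpret_kappa(1.2), "\\[-1, 1\\]")
})
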