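# Small codebooks and hand-built sessions used across tests.

tiny_codebook <- function() {
  codebook(id = 1:3, name = c("A", "B", "C"),
           category = c("Cognition", "Emotion", "3D Interaction"))
}

# build a session from per-coder event lists given as
# list(coder1 = data.frame(code_id, start_s, end_s), ...)
make_session <- function(per_coder, session_id = "s1", coders = NULL,
                         duration_s = NULL) {
  rows <- do.call(rbind, lapply(names(per_coder), function(cd) {
    ev <- per_coder[[cd]]
    if (!nrow(ev)) return(NULL)
    data.frame(session_id = session_id, coder_id = cd,
               code_id = ev$code_id, start_s = ev$start_s, end_s = ev$end_s)
  }))
  if (is.null(rows)) {
    rows <- data.frame(session_id = character(), coder_id = character(),
                       code_id = integer(), start_s = numeric(),
                       end_s = numeric())
  }
  suppressWarnings(session_annotations(
    rows, session_id = session_id,
    coders = if (is.null(coders)) names(per_coder) else coders,
    duration_s = duration_s))
}

ev <- function(code_id, start_s, end_s) {
  data.frame(code_id = code_id, start_s = start_s, end_s = end_s)
}

# Brute-force Fleiss' kappa: per-unit agreement by enumerating ordered rater
# pairs over expanded label vectors; chance agreement by an explicit loop.
# Independent of the vectorized implementation under test.
oracle_fleiss <- function(m) {
  n <- sum(m[1L, ])
  N <- nrow(m)
  P_i <- apply(m, 1, function(row) {
    labels <- rep(seq_along(row), row)
    agree <- 0L
    for (i in seq_len(n)) {
      for (j in seq_len(n)) {
        if (i != j && labels[i] == labels[j]) agree <- agree + 1L
      }
    }
    agree / (n * (n - 1))
  })
  Pe <- 0
  for (j in seq_len(ncol(m))) {
    p_j <- sum(m[, j]) / (N * n)
    Pe <- Pe + p_j^2
  }
  if (1 - Pe < 1e-15) return(1)  # unanimity limit, same convention as tested
  (mean(P_i) - Pe) / (1 - Pe)
}

# all ways to split n ratings over k categories (compositions of n)
compositions <- function(n, k) {
  if (k == 1L) return(matrix(n, 1L, 1L))
  out <- list()
  for (first in 0:n) {
    rest <- compositions(n - first, k - 1L)
    out[[length(out) + 1L]] <- cbind(first, rest)
  }
  unname(do.call(rbind, out))
}

# five coders label every frame of a common grid i.i.d. uniformly; the
# agreement matrix is tallied directly from the per-frame ratings
random_rating_matrix <- function(n_frames, n_raters, n_codes) {
  m <- matrix(0L, n_frames, n_codes)
  for (r in seq_len(n_raters)) {
    lab <- sample.int(n_codes, n_frames, replace = TRUE)
    m[cbind(seq_len(n_frames), lab)] <- m[cbind(seq_len(n_frames), lab)] + 1L
  }
  m
}
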