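# Independent oracles and small fixture builders shared across tests.

# Brute-force gliding-window SD scan: for every channel and every window
# offset, the population SD computed directly (two-pass, via embed), no
# running sums. Returns TRUE if any window on any channel exceeds its
# channel-role threshold.
oracle_reject_epoch <- function(epoch_mat, roles, w, sd_eog, sd_scalp) {
  thr <- ifelse(roles == "eog", sd_eog, sd_scalp)
  for (j in seq_len(nrow(epoch_mat))) {
    X <- stats::embed(epoch_mat[j, ], w)   # one row per window, reversed cols
    sds <- sqrt(rowMeans((X - rowMeans(X))^2))
    if (any(sds > thr[j])) return(TRUE)
  }
  FALSE
}

# Textbook cell-means mixed-ANOVA oracle for the 2 (between) x 2 x 2 (within)
# balanced design, written as explicit marginal-mean formulas over a wide
# matrix: rows = subjects, cols = the 4 within cells in the order
# (a1b1, a2b1, a1b2, a2b2) — i.e. factor A varies fastest, as produced by
# expand.grid(A, B).
oracle_anova_2x2x2 <- function(wide, group) {
  n <- sum(group == unique(group)[1])
  stopifnot(nrow(wide) == 2 * n, ncol(wide) == 4)
  a_of <- c(1, 2, 1, 2); b_of <- c(1, 1, 2, 2)
  grand <- mean(wide)
  m_s <- rowMeans(wide)
  gl <- unique(group)
  m_g <- sapply(gl, function(g) mean(wide[group == g, ]))
  m_a <- sapply(1:2, function(a) mean(wide[, a_of == a]))
  m_b <- sapply(1:2, function(b) mean(wide[, b_of == b]))
  m_ga <- outer(gl, 1:2, Vectorize(function(g, a) mean(wide[group == g, a_of == a])))
  m_gb <- outer(gl, 1:2, Vectorize(function(g, b) mean(wide[group == g, b_of == b])))
  m_ab <- outer(1:2, 1:2, Vectorize(function(a, b) mean(wide[, a_of == a & b_of == b])))
  m_gab <- array(0, c(2, 2, 2))
  for (gi in 1:2) for (a in 1:2) for (b in 1:2)
    m_gab[gi, a, b] <- mean(wide[group == gl[gi], a_of == a & b_of == b])
  m_sa <- sapply(1:2, function(a) rowMeans(wide[, a_of == a]))
  m_sb <- sapply(1:2, function(b) rowMeans(wide[, b_of == b]))
  gi_of_s <- match(group, gl)

  ss <- list()
  ss$G <- 4 * n * sum((m_g - grand)^2)
  ss$subj <- 4 * sum((m_s - grand)^2) - ss$G
  ss$A <- 4 * n * sum((m_a - grand)^2)
  ss$B <- 4 * n * sum((m_b - grand)^2)
  ss$GA <- 2 * n * sum((m_ga - outer(m_g, m_a, `+`) + grand)^2)
  ss$GB <- 2 * n * sum((m_gb - outer(m_g, m_b, `+`) + grand)^2)
  ss$AB <- 2 * n * sum((m_ab - outer(m_a, m_b, `+`) + grand)^2)
  ss$GAB <- 0
  for (gi in 1:2) for (a in 1:2) for (b in 1:2)
    ss$GAB <- ss$GAB + n * (m_gab[gi, a, b] - m_ga[gi, a] - m_gb[gi, b] -
                              m_ab[a, b] + m_g[gi] + m_a[a] + m_b[b] - grand)^2
  ss <- lapply(ss, unname)
  ss$Asubj <- 2 * sum((m_sa - m_s - m_ga[gi_of_s, ] +
                         matrix(m_g[gi_of_s], 2 * n, 2))^2)
  ss$Bsubj <- 2 * sum((m_sb - m_s - m_gb[gi_of_s, ] +
                         matrix(m_g[gi_of_s], 2 * n, 2))^2)
  ss$total <- sum((wide - grand)^2)
  ss$ABsubj <- ss$total - Reduce(`+`, ss[c("G", "subj", "A", "B", "GA", "GB",
                                           "AB", "GAB", "Asubj", "Bsubj")])
  df_err <- 2 * (n - 1)
  Fs <- c(G = (ss$G / 1) / (ss$subj / df_err),
          A = (ss$A / 1) / (ss$Asubj / df_err),
          GA = (ss$GA / 1) / (ss$Asubj / df_err),
          B = (ss$B / 1) / (ss$Bsubj / df_err),
          GB = (ss$GB / 1) / (ss$Bsubj / df_err),
          AB = (ss$AB / 1) / (ss$ABsubj / df_err),
          GAB = (ss$GAB / 1) / (ss$ABsubj / df_err))
  list(ss = ss, F = Fs, df_error = df_err)
}

# Exact two-sided signed-rank p by enumerating all 2^n sign assignments of
# the absolute differences (no-tie case).
oracle_signed_rank_p <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_obs <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  w_all <- as.vector(signs %*% r)
  p_le <- mean(w_all <= w_obs)
  p_ge <- mean(w_all >= w_obs)
  min(1, 2 * min(p_le, p_ge))
}

# Long-format 2x2(x2) design data with Gaussian dv, for ANOVA tests.
make_design_data <- function(n_per_group, within = c("name", "hemisphere"),
                             effects = list(), sd = 1) {
  levs <- list(name = c("own", "stranger"), hemisphere = c("left", "right"))
  grid <- expand.grid(c(list(subject = sprintf("s%02d", 1:(2 * n_per_group))),
                        levs[within]), stringsAsFactors = FALSE)
  grid$group <- ifelse(as.integer(sub("s", "", grid$subject)) <= n_per_group,
                       "ten", "one")
  grid$value <- stats::rnorm(nrow(grid), 0, sd)
  for (nm in names(effects))
    grid$value <- grid$value + effects[[nm]](grid)
  grid
}

# Minimal erp_epochs object built directly from a trials x channels x samples
# array (for measurement/rejection unit tests without the simulator).
make_epochs <- function(data, fs = 250, t0_ms = -200,
                        conditions = rep("own", dim(data)[1]),
                        channels = build_montage()$channels) {
  stopifnot(dim(data)[2] == nrow(channels))
  n <- dim(data)[1]
  structure(list(
    data = data, channels = channels,
    times_ms = t0_ms + (0:(dim(data)[3] - 1)) * 1000 / fs,
    sampling_rate = fs, modality = "auditory",
    trials = data.frame(trial = seq_len(n), condition = conditions),
    dropped = data.frame(trial = integer(0), reason = character(0)),
    rejection = data.frame(trial = seq_len(n), rejected = FALSE,
                           reason = NA_character_, channel = NA_character_,
                           window_start_ms = NA_real_, sd_uV = NA_real_)
  ), class = "erp_epochs")
}

# ERP average built from a channels x samples matrix.
make_average <- function(data, fs = 250, t0_ms = -200,
                         channels = build_montage()$channels) {
  rownames(data) <- channels$label
  structure(list(data = data, channels = channels,
                 times_ms = t0_ms + (0:(ncol(data) - 1)) * 1000 / fs,
                 sampling_rate = fs, n_trials = 10, condition = "own",
                 modality = "auditory"),
            class = "erp_average")
}

# Noise-free, artifact-free simulation config for identity tests.
clean_config <- function(n_trials = 20, subject_sd = 0, ...) {
  simulation_config(
    n_trials = n_trials, subject_sd = subject_sd, artifacts = FALSE,
    noise = noise_spec(rms_uV = 0, blink_rate_per_min = 0,
                       movement_rate_per_min = 0), ...)
}

# Simulate + preprocess a cohort into the shape build_measurement_table wants.
process_cohort <- function(config) {
  lapply(simulate_cohort(config), function(s) list(
    subject_id = s$subject_id, group = s$group,
    epochs = preprocess_subject(s$recording, not_looking = s$not_looking)))
}
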