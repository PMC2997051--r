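# Mixed-design statistical battery: balanced mixed ANOVA with partial eta
# squared, Scheffe and t post hocs, Wilcoxon signed-rank, split-half and
# median-split (signal-to-noise) controls.

# Means of dv over combinations of factor columns.
cell_means <- function(data, dv, by) {
  agg <- stats::aggregate(data[[dv]], data[by], mean)
  names(agg)[ncol(agg)] <- "m"
  agg
}

lookup <- function(agg, ...) {
  key <- list(...)
  sel <- rep(TRUE, nrow(agg))
  for (nm in names(key)) sel <- sel & agg[[nm]] == key[[nm]]
  agg$m[sel]
}

#' Balanced mixed-design ANOVA (one between factor, 1-2 within factors)
#'
#' From-scratch sums-of-squares decomposition for the balanced two-group
#' repeated-measures designs used here: one 2-level between-subjects factor
#' and one or two 2-level within-subjects factors, equal n per group, every
#' subject observed once in every within-cell. Each within-subject effect
#' (and its interaction with the between factor) is tested against its own
#' factor-by-subject-within-group error stratum; the between effect is
#' tested against subjects-within-groups. All within factors have two
#' levels, so sphericity corrections do not arise. Reports F, exact p, and
#' partial eta squared `SS_effect / (SS_effect + SS_error)` per effect.
#'
#' @param data Long data.frame, one row per subject x within-cell.
#' @param dv Name of the dependent-variable column.
#' @param subject Name of the subject-identifier column.
#' @param between Name of the between-subjects factor column (2 levels), or
#'   `NULL` for a pure within-subject (one group) design with a single
#'   within factor — in that case the within F equals the squared paired t
#'   on the same data.
#' @param within Character vector of 1 or 2 within-subjects factor columns
#'   (2 levels each).
#' @return An `anova_table` data.frame: `effect`, `df_effect`, `df_error`,
#'   `SS_effect`, `SS_error`, `F`, `p`, `partial_eta_sq`.
#' @export
mixed_anova <- function(data, dv = "value", subject = "subject",
                        between = "group", within) {
  stopifnot(length(within) %in% 1:2)
  if (is.null(between)) return(within_anova_1f(data, dv, subject, within))
  for (f in c(between, within)) {
    if (length(unique(data[[f]])) != 2)
      stop("factor ", f, " must have exactly 2 levels")
  }
  subjects <- unique(data[c(subject, between)])
  if (anyDuplicated(subjects[[subject]]))
    stop("each subject must belong to exactly one group")
  n_cells <- prod(rep(2, length(within)))
  tab <- table(data[[subject]])
  if (any(tab != n_cells)) stop("missing within-cells: design must be complete")
  g_n <- table(subjects[[between]])
  if (length(unique(g_n)) != 1) stop("groups must have equal n")
  n <- unname(g_n[1])

  y <- data[[dv]]
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)

  m_subj <- cell_means(data, dv, subject)
  m_g <- cell_means(data, dv, between)
  ss_between_subj <- n_cells * sum((m_subj$m - grand)^2)
  ss_G <- n * n_cells * sum((m_g$m - grand)^2)
  ss_subj_g <- ss_between_subj - ss_G
  df_subj_g <- 2 * (n - 1)

  rows <- list()
  add_row <- function(effect, df_e, df_err, ss_e, ss_err) {
    ss_e <- max(ss_e, 0); ss_err <- max(ss_err, 0)
    if (ss_e <= 1e-12 * max(ss_total, 1)) {
      f <- 0; p <- 1
    } else if (ss_err <= 0) {
      f <- Inf; p <- 0
    } else {
      f <- (ss_e / df_e) / (ss_err / df_err)
      p <- stats::pf(f, df_e, df_err, lower.tail = FALSE)
    }
    eta <- if (ss_e + ss_err > 0) ss_e / (ss_e + ss_err) else 0
    rows[[length(rows) + 1L]] <<- data.frame(
      effect = effect, df_effect = df_e, df_error = df_err,
      SS_effect = ss_e, SS_error = ss_err, F = f, p = p,
      partial_eta_sq = eta)
  }
  add_row(between, 1, df_subj_g, ss_G, ss_subj_g)

  grp_of <- stats::setNames(subjects[[between]], subjects[[subject]])
  ss_within_err <- list()
  for (w in within) {
    m_w <- cell_means(data, dv, w)
    m_gw <- cell_means(data, dv, c(between, w))
    m_sw <- cell_means(data, dv, c(subject, w))
    other <- n_cells / 2
    ss_W <- 2 * n * other * sum((m_w$m - grand)^2)
    ss_GW <- n * other * sum(vapply(seq_len(nrow(m_gw)), function(i) {
      gi <- m_gw[[between]][i]; wi <- m_gw[[w]][i]
      (m_gw$m[i] - m_g$m[m_g[[between]] == gi] - m_w$m[m_w[[w]] == wi] + grand)^2
    }, 0))
    ss_Wsubj <- other * sum(vapply(seq_len(nrow(m_sw)), function(i) {
      si <- m_sw[[subject]][i]; wi <- m_sw[[w]][i]; gi <- grp_of[[as.character(si)]]
      (m_sw$m[i] - m_subj$m[m_subj[[subject]] == si] -
         m_gw$m[m_gw[[between]] == gi & m_gw[[w]] == wi] +
         m_g$m[m_g[[between]] == gi])^2
    }, 0))
    df_err <- 2 * (n - 1)
    add_row(w, 1, df_err, ss_W, ss_Wsubj)
    add_row(paste0(between, ":", w), 1, df_err, ss_GW, ss_Wsubj)
    ss_within_err[[w]] <- ss_Wsubj
  }

  if (length(within) == 2) {
    a <- within[1]; b <- within[2]
    m_a <- cell_means(data, dv, a); m_b <- cell_means(data, dv, b)
    m_ab <- cell_means(data, dv, c(a, b))
    m_gab <- cell_means(data, dv, c(between, a, b))
    m_ga <- cell_means(data, dv, c(between, a))
    m_gb <- cell_means(data, dv, c(between, b))
    ss_AB <- 2 * n * sum(vapply(seq_len(nrow(m_ab)), function(i) {
      ai <- m_ab[[a]][i]; bi <- m_ab[[b]][i]
      (m_ab$m[i] - m_a$m[m_a[[a]] == ai] - m_b$m[m_b[[b]] == bi] + grand)^2
    }, 0))
    ss_GAB <- n * sum(vapply(seq_len(nrow(m_gab)), function(i) {
      gi <- m_gab[[between]][i]; ai <- m_gab[[a]][i]; bi <- m_gab[[b]][i]
      (m_gab$m[i] -
         m_ga$m[m_ga[[between]] == gi & m_ga[[a]] == ai] -
         m_gb$m[m_gb[[between]] == gi & m_gb[[b]] == bi] -
         m_ab$m[m_ab[[a]] == ai & m_ab[[b]] == bi] +
         m_g$m[m_g[[between]] == gi] + m_a$m[m_a[[a]] == ai] +
         m_b$m[m_b[[b]] == bi] - grand)^2
    }, 0))
    accounted <- ss_between_subj +
      sum(vapply(rows[-1], function(r) r$SS_effect, 0)) +
      sum(unlist(ss_within_err)) + ss_AB + ss_GAB
    ss_ABsubj <- ss_total - accounted
    df_err <- 2 * (n - 1)
    add_row(a %+% ":" %+% b, 1, df_err, ss_AB, ss_ABsubj)
    add_row(between %+% ":" %+% a %+% ":" %+% b, 1, df_err, ss_GAB, ss_ABsubj)
  }

  out <- do.call(rbind, rows)
  class(out) <- c("anova_table", "data.frame")
  out
}

`%+%` <- function(a, b) paste0(a, b)

# One-group, one within-factor repeated-measures ANOVA (used for the
# F = t^2 identity and as a degenerate case of the mixed design).
within_anova_1f <- function(data, dv, subject, within) {
  stopifnot(length(within) == 1)
  w <- within
  if (length(unique(data[[w]])) != 2) stop("factor ", w, " must have 2 levels")
  n <- length(unique(data[[subject]]))
  y <- data[[dv]]
  grand <- mean(y)
  ss_total <- sum((y - grand)^2)
  m_subj <- cell_means(data, dv, subject)
  m_w <- cell_means(data, dv, w)
  ss_subj <- 2 * sum((m_subj$m - grand)^2)
  ss_W <- n * sum((m_w$m - grand)^2)
  ss_err <- ss_total - ss_subj - ss_W
  df_err <- n - 1
  if (ss_W <= 1e-12 * max(ss_total, 1)) {
    f <- 0; p <- 1
  } else if (ss_err <= 0) {
    f <- Inf; p <- 0
  } else {
    f <- ss_W / (ss_err / df_err)
    p <- stats::pf(f, 1, df_err, lower.tail = FALSE)
  }
  out <- data.frame(effect = w, df_effect = 1, df_error = df_err,
                    SS_effect = ss_W, SS_error = max(ss_err, 0), F = f, p = p,
                    partial_eta_sq = if (ss_W + ss_err > 0)
                      ss_W / (ss_W + max(ss_err, 0)) else 0)
  class(out) <- c("anova_table", "data.frame")
  out
}

#' @export
print.anova_table <- function(x, ...) {
  for (i in seq_len(nrow(x)))
    cat(sprintf("%-28s F(%d,%d) = %.2f, P = %.4g, eta_p^2 = %.3f\n",
                x$effect[i], x$df_effect[i], x$df_error[i], x$F[i], x$p[i],
                x$partial_eta_sq[i]))
  invisible(x)
}

#' 2 (Group) x 2 (Name) x 2 (Hemisphere) mixed ANOVA
#'
#' @param data Long data.frame with columns `subject`, `group`, `name`,
#'   `hemisphere`, and the dependent variable.
#' @param dv Dependent-variable column name (default "value").
#' @return An `anova_table`.
#' @export
mixed_anova_2x2x2 <- function(data, dv = "value") {
  mixed_anova(data, dv = dv, subject = "subject", between = "group",
              within = c("name", "hemisphere"))
}

#' 2 (Group) x 2 (Name) mixed ANOVA
#'
#' @param data Long data.frame with columns `subject`, `group`, `name`, and
#'   the dependent variable.
#' @param dv Dependent-variable column name (default "value").
#' @return An `anova_table`.
#' @export
mixed_anova_2x2 <- function(data, dv = "value") {
  mixed_anova(data, dv = dv, subject = "subject", between = "group",
              within = "name")
}

# ---- Post hocs -------------------------------------------------------------

#' Paired and independent t post hoc comparisons
#'
#' @param x,y Numeric vectors (paired: equal length, per-subject values).
#' @param type `"paired"` or `"independent"` (classic equal-variance t).
#' @return List: `t`, `df`, `p`, `degenerate` (TRUE when the relevant
#'   variance is zero; then `t` is 0 and `p` 1 for identical samples).
#' @export
posthoc_tests <- function(x, y, type = c("paired", "independent")) {
  type <- match.arg(type)
  if (type == "paired") {
    stopifnot(length(x) == length(y))
    d <- x - y
    n <- length(d)
    if (stats::sd(d) == 0) {
      if (all(d == 0)) return(list(t = 0, df = n - 1, p = 1, degenerate = TRUE))
      return(list(t = sign(mean(d)) * Inf, df = n - 1, p = 0, degenerate = TRUE))
    }
    t <- mean(d) / (stats::sd(d) / sqrt(n))
    df <- n - 1
  } else {
    n1 <- length(x); n2 <- length(y)
    sp2 <- ((n1 - 1) * stats::var(x) + (n2 - 1) * stats::var(y)) / (n1 + n2 - 2)
    if (sp2 == 0) {
      if (mean(x) == mean(y)) return(list(t = 0, df = n1 + n2 - 2, p = 1,
                                          degenerate = TRUE))
      return(list(t = sign(mean(x) - mean(y)) * Inf, df = n1 + n2 - 2, p = 0,
                  degenerate = TRUE))
    }
    t <- (mean(x) - mean(y)) / sqrt(sp2 * (1 / n1 + 1 / n2))
    df <- n1 + n2 - 2
  }
  list(t = t, df = df, p = 2 * stats::pt(-abs(t), df), degenerate = FALSE)
}

#' Scheffe-adjusted test of a cell-mean contrast
#'
#' Tests `sum(contrast * cell_means) = 0` with the Scheffe adjustment over
#' all contrasts among the `k` cells: the contrast F is referred to
#' `(k - 1) * F(k - 1, df_error)`. The error term is the pooled within-cell
#' mean square supplied by the caller (for mixed designs, the pooled error
#' of the relevant strata; documented choice).
#'
#' @param means Numeric vector of k cell means.
#' @param contrast Numeric contrast coefficients (sum to 0).
#' @param n_per_cell Observations per cell (scalar or length k).
#' @param ms_error Pooled error mean square.
#' @param df_error Error degrees of freedom.
#' @return List: `estimate`, `F`, `p_scheffe`, `p_unadjusted`.
#' @export
scheffe_test <- function(means, contrast, n_per_cell, ms_error, df_error) {
  stopifnot(length(means) == length(contrast),
            abs(sum(contrast)) < 1e-8, ms_error >= 0)
  k <- length(means)
  n <- rep_len(n_per_cell, k)
  est <- sum(contrast * means)
  se2 <- ms_error * sum(contrast^2 / n)
  if (se2 == 0) return(list(estimate = est, F = if (est == 0) 0 else Inf,
                            p_scheffe = if (est == 0) 1 else 0,
                            p_unadjusted = if (est == 0) 1 else 0))
  f <- est^2 / se2
  list(estimate = est, F = f,
       p_scheffe = stats::pf(f / (k - 1), k - 1, df_error, lower.tail = FALSE),
       p_unadjusted = stats::pf(f, 1, df_error, lower.tail = FALSE))
}

# ---- Wilcoxon signed rank --------------------------------------------------

#' Wilcoxon signed-rank test on per-subject condition differences
#'
#' Counts how many subjects show the effect in the predicted direction
#' (strict sign; zeros count as not showing), then tests the differences
#' with Wilcoxon's signed-rank test. Zero differences are dropped before
#' ranking (Wilcoxon's original procedure). The p-value is exact (via the
#' signed-rank distribution) for n <= 25 without ties, otherwise a
#' tie-corrected, continuity-corrected normal approximation. `z` follows the
#' classic reporting convention of basing the statistic on the smaller of
#' the two rank sums, so it is always <= 0 ("k out of n showed the effect,
#' Z = -x.xx").
#'
#' @param differences Per-subject condition differences.
#' @param direction `"positive"` or `"negative"`: the predicted sign.
#' @return List: `n_positive` (subjects showing the effect), `n_total`, `z`,
#'   `p`, `method` ("exact"/"normal").
#' @export
wilcoxon_effect <- function(differences, direction = c("positive", "negative")) {
  direction <- match.arg(direction)
  stopifnot(length(differences) >= 1)
  if (all(differences == 0)) stop("all differences are zero")
  shown <- if (direction == "positive") differences > 0 else differences < 0
  d <- differences[differences != 0]
  n <- length(d)
  r <- rank(abs(d))
  w_pos <- sum(r[d > 0])
  mu <- n * (n + 1) / 4
  ties <- table(abs(d))
  sigma2 <- n * (n + 1) * (2 * n + 1) / 24 - sum(ties^3 - ties) / 48
  # statistic based on the smaller rank sum; continuity correction toward mu
  w_min <- min(w_pos, n * (n + 1) / 2 - w_pos)
  z <- min(0, (w_min - mu + 0.5) / sqrt(sigma2))
  has_ties <- any(ties > 1)
  if (n <= 25 && !has_ties) {
    p <- min(1, 2 * min(stats::psignrank(w_pos, n),
                        stats::psignrank(w_pos - 1, n, lower.tail = FALSE)))
    method <- "exact"
  } else {
    p <- 2 * stats::pnorm(z)
    method <- "normal"
  }
  list(n_positive = sum(shown), n_total = length(differences),
       z = z, p = p, method = method)
}

# ---- Split-half control ----------------------------------------------------

#' Split-half (fast-learning) control analysis
#'
#' Splits every subject's retained trials into the first and second half of
#' the experiment (by original trial index), recomputes the component
#' measure per half and condition, and runs a mixed ANOVA with the added
#' 2-level within factor `half`. A time-stationary effect should show no
#' interaction involving `half`.
#'
#' @param processed Per-subject list entries with `subject_id`, `group`,
#'   `epochs` (as produced by the pipeline).
#' @param modality `"auditory"` or `"visual"`.
#' @param rois List of [roi_spec()]s whose measures are averaged into one
#'   value (e.g. left+right fronto-central for the anterior shift).
#' @param window Numeric `c(t_start, t_end)` ms.
#' @param measure `"mean_amplitude"` or `"negative_peak"` (peak amplitude).
#' @param n_trials_total Total trials per subject (defines the half
#'   boundary; default 200).
#' @param min_half Minimum retained trials per half x condition for a
#'   subject to enter (default 5); subjects below it are dropped and listed.
#' @return List: `anova` (`anova_table` with factors group, name, half),
#'   `table` (the long data), `dropped_subjects`,
#'   `half_interaction_significant` (any `half` interaction with p < .05).
#' @export
split_half_analysis <- function(processed, modality, rois, window,
                                measure = "mean_amplitude",
                                n_trials_total = 200, min_half = 5) {
  boundary <- n_trials_total / 2
  rows <- list(); dropped <- character(0)
  for (s in processed) {
    ep <- s$epochs[[modality]]
    ok <- TRUE
    svals <- list()
    for (half in c("first", "second")) {
      in_half <- if (half == "first") ep$trials$trial <= boundary
                 else ep$trials$trial > boundary
      for (cond in c("own", "stranger")) {
        idx <- intersect(retained_epochs(ep, cond), which(in_half))
        if (length(idx) < min_half) { ok <- FALSE; break }
        sub <- ep
        sub$data <- ep$data[idx, , , drop = FALSE]
        sub$trials <- ep$trials[idx, ]
        sub$rejection <- ep$rejection[idx, ]
        erp <- average_epochs(sub, cond)
        val <- mean(vapply(rois, function(r) {
          if (measure == "mean_amplitude") mean_amplitude(erp, r, window)
          else unname(negative_peak(erp, r, window)["amplitude_uV"])
        }, 0))
        svals[[length(svals) + 1L]] <- data.frame(
          subject = s$subject_id, group = s$group, name = cond, half = half,
          value = val)
      }
      if (!ok) break
    }
    if (ok) rows <- c(rows, svals) else dropped <- c(dropped, s$subject_id)
  }
  tab <- do.call(rbind, rows)
  if (is.null(tab)) stop("no subject has enough trials per half")
  # the balanced ANOVA needs equal n: trim the larger group (highest IDs
  # first) if exclusions unbalanced it, recording the trimmed subjects
  subj <- unique(tab[c("subject", "group")])
  gtab <- table(subj$group)
  if (length(gtab) != 2 || min(gtab) < 2)
    stop("too few subjects with enough trials per half")
  if (gtab[1] != gtab[2]) {
    big <- names(gtab)[which.max(gtab)]
    excess <- sort(subj$subject[subj$group == big], decreasing = TRUE)
    excess <- excess[seq_len(max(gtab) - min(gtab))]
    tab <- tab[!(tab$subject %in% excess), ]
    dropped <- c(dropped, paste0(excess, " (trimmed for balance)"))
  }
  an <- mixed_anova(tab, dv = "value", within = c("name", "half"))
  half_int <- grepl("half", an$effect) & an$effect != "half"
  list(anova = an, table = tab, dropped_subjects = dropped,
       half_interaction_significant = any(an$p[half_int] < 0.05))
}

#' Median-split signal-to-noise control
#'
#' Splits the cohort at the median of retained trial counts and compares the
#' component measure between the below-median and at/above-median subgroups
#' with an independent t-test. A null result argues against the effect being
#' driven by poor signal-to-noise in low-trial subjects.
#'
#' @param values Per-subject measure (e.g. mean over all anterior-shift
#'   electrodes and both conditions).
#' @param trial_counts Per-subject retained trial counts, same order.
#' @return List: `median`, `n_below`, `n_above`, `t`, `df`, `p`.
#' @export
median_split_snr_check <- function(values, trial_counts) {
  stopifnot(length(values) == length(trial_counts))
  med <- stats::median(trial_counts)
  below <- trial_counts < med
  if (sum(below) == 0 || sum(!below) == 0)
    stop("median split produced an empty subgroup")
  tt <- posthoc_tests(values[below], values[!below], type = "independent")
  list(median = med, n_below = sum(below), n_above = sum(!below),
       t = tt$t, df = tt$df, p = tt$p)
}
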