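# Mixed ANOVA, post hocs, Wilcoxon signed-rank, split-half, median split.

test_that("constant dv gives F = 0, p = 1 everywhere", {
  d <- make_design_data(4)
  d$value <- 3.14
  a <- mixed_anova_2x2x2(d)
  expect_true(all(a$F == 0))
  expect_true(all(a$p == 1))
  expect_true(all(a$partial_eta_sq == 0))
})

test_that("one-group within F equals the squared paired t", {
  set.seed(41)
  n <- 12
  own <- stats::rnorm(n, 0.6); str <- stats::rnorm(n)
  d <- data.frame(subject = rep(sprintf("s%02d", 1:n), 2),
                  name = rep(c("own", "stranger"), each = n),
                  value = c(own, str))
  a <- mixed_anova(d, between = NULL, within = "name")
  tt <- stats::t.test(own, str, paired = TRUE)
  expect_equal(a$F[1], unname(tt$statistic)^2, tolerance = 1e-10)
  expect_equal(a$p[1], tt$p.value, tolerance = 1e-10)
})

test_that("2x2x2 SS and F match the independent cell-means oracle", {
  for (seed in 1:5) {
    set.seed(seed)
    n <- if (seed %% 2) 4 else 6
    d <- make_design_data(n)
    d$value <- d$value + (d$name == "own") * 0.8 +
      (d$group == "ten") * (d$hemisphere == "left") * 0.5
    a <- mixed_anova_2x2x2(d)
    # oracle wants subjects x (4 within cells) wide
    wide <- matrix(0, 2 * n, 4)
    subj <- sprintf("s%02d", 1:(2 * n))
    cells <- expand.grid(name = c("own", "stranger"),
                         hemisphere = c("left", "right"))
    for (j in 1:4)
      for (i in seq_along(subj))
        wide[i, j] <- d$value[d$subject == subj[i] &
                                d$name == cells$name[j] &
                                d$hemisphere == cells$hemisphere[j]]
    grp <- ifelse(seq_along(subj) <= n, "ten", "one")
    o <- oracle_anova_2x2x2(wide, grp)
    rel <- function(x, y) abs(x - y) / max(abs(y), 1e-12)
    expect_lt(rel(a$SS_effect[a$effect == "group"], o$ss$G), 1e-8)
    expect_lt(rel(a$SS_effect[a$effect == "name"], o$ss$A), 1e-8)
    expect_lt(rel(a$SS_effect[a$effect == "group:name"], o$ss$GA), 1e-8)
    expect_lt(rel(a$SS_effect[a$effect == "hemisphere"], o$ss$B), 1e-8)
    expect_lt(rel(a$SS_effect[a$effect == "name:hemisphere"], o$ss$AB), 1e-8)
    expect_lt(rel(a$SS_effect[a$effect == "group:name:hemisphere"], o$ss$GAB), 1e-8)
    expect_lt(rel(a$F[a$effect == "group"], o$F[["G"]]), 1e-8)
    expect_lt(rel(a$F[a$effect == "name"], o$F[["A"]]), 1e-8)
    expect_lt(rel(a$F[a$effect == "group:name"], o$F[["GA"]]), 1e-8)
    expect_lt(rel(a$F[a$effect == "group:name:hemisphere"], o$F[["GAB"]]), 1e-8)
  }
})

test_that("2x2x2 and 2x2 agree with aov() error strata", {
  set.seed(43)
  d <- make_design_data(5)
  a <- mixed_anova_2x2x2(d)
  fit <- stats::aov(value ~ group * name * hemisphere +
                      Error(subject / (name * hemisphere)), data = d)
  s <- summary(fit)
  pick <- function(stratum, effect) {
    tab <- s[[stratum]][[1]]
    tab[trimws(rownames(tab)) == effect, "F value"]
  }
  expect_equal(a$F[a$effect == "group"], pick("Error: subject", "group"),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "name"], pick("Error: subject:name", "name"),
               tolerance = 1e-10)
  expect_equal(a$F[a$effect == "group:name"],
               pick("Error: subject:name", "group:name"), tolerance = 1e-10)
  expect_equal(a$F[a$effect == "name:hemisphere"],
               pick("Error: subject:name:hemisphere", "name:hemisphere"),
               tolerance = 1e-10)

  d2 <- make_design_data(6, within = "name")
  a2 <- mixed_anova_2x2(d2)
  fit2 <- stats::aov(value ~ group * name + Error(subject / name), data = d2)
  s2 <- summary(fit2)
  expect_equal(a2$F[a2$effect == "name"],
               s2[["Error: subject:name"]][[1]]["name", "F value"],
               tolerance = 1e-10)
})

test_that("SS decomposition is exhaustive and partial eta sq is in [0,1]", {
  set.seed(44)
  d <- make_design_data(4)
  a <- mixed_anova_2x2x2(d)
  ss_total <- sum((d$value - mean(d$value))^2)
  # error strata: subj(G) + name x subj + hemi x subj + name:hemi x subj
  ss_all <- sum(a$SS_effect) + sum(unique(a$SS_error))
  expect_equal(ss_all, ss_total, tolerance = 1e-10)
  expect_true(all(a$partial_eta_sq >= 0 & a$partial_eta_sq <= 1))
  # eta = 1 iff error SS = 0: noise-free additive design
  d0 <- make_design_data(3, sd = 1e-30)
  d0$value <- (d0$name == "own") * 2
  a0 <- mixed_anova_2x2x2(d0)
  expect_equal(a0$partial_eta_sq[a0$effect == "name"], 1)
})

test_that("design validation rejects malformed inputs", {
  d <- make_design_data(4)
  expect_error(mixed_anova_2x2x2(d[-1, ]), "complete")
  d2 <- make_design_data(4)
  d2$group[d2$subject == "s01"] <- "one"   # unbalanced groups
  expect_error(mixed_anova_2x2x2(d2), "equal n")
  d3 <- make_design_data(4)
  d3$name <- "own"
  expect_error(mixed_anova_2x2x2(d3), "2 levels")
})

test_that("post hoc t-tests: identical, degenerate and textbook cases", {
  x <- c(1, 2, 3, 4)
  same <- posthoc_tests(x, x, "paired")
  expect_equal(same$t, 0); expect_equal(same$p, 1)
  expect_true(same$degenerate)
  shifted <- posthoc_tests(x, x + 1, "paired")  # constant nonzero difference
  expect_true(shifted$degenerate)
  expect_equal(shifted$p, 0)

  set.seed(45)
  a <- stats::rnorm(10); b <- stats::rnorm(10, 0.5)
  got <- posthoc_tests(a, b, "paired")
  ref <- stats::t.test(a, b, paired = TRUE)
  expect_equal(got$t, unname(ref$statistic), tolerance = 1e-12)
  expect_equal(got$p, ref$p.value, tolerance = 1e-12)
  got2 <- posthoc_tests(a, b, "independent")
  ref2 <- stats::t.test(a, b, var.equal = TRUE)
  expect_equal(got2$t, unname(ref2$statistic), tolerance = 1e-12)
  expect_equal(got2$p, ref2$p.value, tolerance = 1e-12)
})

test_that("Scheffe p is never smaller than the unadjusted p", {
  set.seed(46)
  for (rep in 1:20) {
    k <- sample(3:6, 1)
    means <- stats::rnorm(k)
    contrast <- stats::rnorm(k); contrast <- contrast - mean(contrast)
    r <- scheffe_test(means, contrast, n_per_cell = 8,
                      ms_error = stats::runif(1, 0.5, 2), df_error = 28)
    expect_gte(r$p_scheffe, r$p_unadjusted)
  }
  z <- scheffe_test(c(1, 1, 1), c(1, -2, 1), 5, 1, 12)
  expect_equal(z$F, 0); expect_equal(z$p_scheffe, 1)
})

test_that("wilcoxon_effect counts directions and matches oracles", {
  all_pos <- wilcoxon_effect(seq_len(15), "positive")
  expect_equal(all_pos$n_positive, 15)
  expect_equal(all_pos$n_total, 15)
  expect_lt(all_pos$p, 0.01)
  expect_lte(all_pos$z, 0)

  # zeros count as not showing the effect, in either direction
  mix <- wilcoxon_effect(c(-2, 0, 1, 3, 4), "positive")
  expect_equal(mix$n_positive, 3)
  expect_error(wilcoxon_effect(rep(0, 5)), "zero")

  # exact p equals full 2^6 sign enumeration at n = 6
  d6 <- c(1.3, -0.4, 2.2, 0.8, -1.7, 3.1)
  got <- wilcoxon_effect(d6, "positive")
  expect_equal(got$method, "exact")
  expect_equal(got$p, oracle_signed_rank_p(d6), tolerance = 1e-12)

  # and wilcox.test agrees on no-tie samples
  set.seed(47)
  for (rep in 1:5) {
    d <- round(stats::rnorm(12), 3)
    expect_equal(wilcoxon_effect(d, "positive")$p,
                 stats::wilcox.test(d, exact = TRUE)$p.value,
                 tolerance = 1e-12)
  }
})

test_that("median split partitions the cohort and is null on identical data", {
  counts <- c(20, 25, 27, 28, 29, 33, 40, 55, 60, 79)
  r <- median_split_snr_check(stats::rnorm(10), counts)
  expect_equal(r$n_below + r$n_above, 10)
  expect_identical(r$n_below, sum(counts < stats::median(counts)))
  same <- median_split_snr_check(rep(2.5, 10), counts)
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
})

test_that("split-half assigns every trial to exactly one half and detects stationarity", {
  cfg <- clean_config(n_trials = 20, n_subjects_per_group = 2, seed = 51)
  processed <- process_cohort(cfg)
  rois <- default_rois()
  sh <- split_half_analysis(processed, "auditory",
                            rois[c("left_fc", "right_fc")], c(100, 380),
                            n_trials_total = 20, min_half = 3)
  # partition: per subject, first-half + second-half trials = all trials
  ep <- processed[[1]]$epochs$auditory
  expect_equal(sum(ep$trials$trial <= 10) + sum(ep$trials$trial > 10),
               nrow(ep$trials))
  expect_s3_class(sh$anova, "anova_table")
  expect_true(all(c("name", "half", "name:half") %in% sh$anova$effect))
  # noise-free stationary effects: no half interaction
  expect_false(sh$half_interaction_significant)
  tab <- sh$table
  expect_equal(nrow(tab), 4 * 2 * 2)  # subject x name x half
})
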