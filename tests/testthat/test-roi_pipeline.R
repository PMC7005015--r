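cfg <- analysis_config()

toy_fixations <- function(rows) {
  out <- do.call(rbind, lapply(rows, function(r) {
    data.frame(participant = "p1", task = "introduction",
               t_start = r[[1]], t_end = r[[2]],
               duration = r[[2]] - r[[1]], label = r[[3]])
  }))
  tibble::as_tibble(out)
}

toy_periods <- function(t0, t1, role = "speaking") {
  tibble::tibble(participant = "p1", task = "introduction", role = role,
                 t_start = t0, t_end = t1, segment_index = 1L)
}

test_that("proportions follow the valid-fixation-time arithmetic on a toy cell", {
  # one 10 s period: 2 s upper + 1 s lower + 1 s outside fixations, rest loss
  fx <- toy_fixations(list(list(0, 2000, "upper"),
                           list(3000, 4000, "lower"),
                           list(5000, 6000, "outside")))
  gaze <- tibble::tibble(participant = "p1", task = "introduction",
                         t = (0:599) * (1000 / 60), x = 0, y = 0,
                         valid = rep(c(TRUE, FALSE), c(540, 60)))
  out <- compute_proportions(fx, toy_periods(0, 10000), gaze, cfg)
  expect_equal(out$face_prop, 3000 / 4000)   # face time over classified time
  expect_equal(out$upper_prop, 2000 / 3000)
  expect_equal(out$fix_time, 4000)
  expect_equal(out$loss_frac, 1 - 540 * (1000 / 60) / 10000)
})

test_that("degenerate cells behave as specified", {
  all_up <- toy_fixations(list(list(0, 1000, "upper"), list(2000, 2500, "upper")))
  out <- compute_proportions(all_up, toy_periods(0, 5000), config = cfg)
  expect_equal(out$face_prop, 1)
  expect_equal(out$upper_prop, 1)
  none <- toy_fixations(list(list(0, 1000, "outside")))
  out2 <- compute_proportions(none, toy_periods(0, 5000), config = cfg)
  expect_equal(out2$face_prop, 0)
  expect_true(is.na(out2$upper_prop))
  # zero classified time flags the cell missing
  uncl <- toy_fixations(list(list(0, 1000, "unclassifiable")))
  out3 <- compute_proportions(uncl, toy_periods(0, 5000), config = cfg)
  expect_true(out3$missing)
})

test_that("fixations straddling a period boundary are clipped", {
  fx <- toy_fixations(list(list(9000, 12000, "upper")))
  out <- compute_proportions(fx, toy_periods(0, 10000), config = cfg)
  expect_equal(out$fix_time, 1000)  # only the in-period second counts
  expect_equal(out$face_prop, 1)
})

test_that("the mixed ANOVA matches the hand sums-of-squares oracle", {
  set.seed(101)
  for (rep in 1:3) {
    d <- expand.grid(participant = paste0("s", 1:6),
                     speech = c("speaking", "listening"),
                     task = c("introduction", "storytelling"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(d$participant %in% paste0("s", 1:3), "A", "B")
    d$y <- rnorm(nrow(d)) + ifelse(d$speech == "listening", 0.5, 0)
    outcomes <- tibble::tibble(participant = d$participant, group = d$group,
                               task = d$task, speech_state = d$speech,
                               face_prop = d$y, upper_prop = d$y,
                               missing = FALSE)
    got <- mixed_anova_2x2x2(outcomes, "face_prop")
    d2 <- d; names(d2)[names(d2) == "speech"] <- "speech"
    want <- oracle_mixed_anova(d)
    for (eff in names(want)) {
      expect_equal(got$F[got$effect == eff], unname(want[[eff]]),
                   tolerance = 1e-8, label = paste("F for", eff))
    }
    expect_true(all(got$df1 == 1) && all(got$df2 == 4))
    expect_true(all(got$partial_eta_sq >= 0 & got$partial_eta_sq <= 1))
  }
})

test_that("the ANOVA is invariant to adding a constant", {
  set.seed(7)
  d <- expand.grid(participant = paste0("s", 1:8),
                   speech_state = c("speaking", "listening"),
                   task = c("introduction", "storytelling"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant %in% paste0("s", 1:4), "A", "B")
  d$face_prop <- rnorm(nrow(d))
  d$missing <- FALSE
  a <- mixed_anova_2x2x2(tibble::as_tibble(d), "face_prop")
  d$face_prop <- d$face_prop + 5
  b <- mixed_anova_2x2x2(tibble::as_tibble(d), "face_prop")
  expect_equal(a$F, b$F)
})

test_that("null-simulation p-values are uniform (distributional sanity check)", {
  set.seed(42)
  ps <- replicate(120, {
    d <- expand.grid(participant = paste0("s", 1:12),
                     speech_state = c("speaking", "listening"),
                     task = c("introduction", "storytelling"),
                     stringsAsFactors = FALSE)
    d$group <- ifelse(d$participant %in% paste0("s", 1:6), "A", "B")
    subj_eff <- rnorm(12)[match(d$participant, paste0("s", 1:12))]
    d$face_prop <- subj_eff + rnorm(nrow(d))
    d$missing <- FALSE
    res <- mixed_anova_2x2x2(tibble::as_tibble(d), "face_prop")
    res$p[res$effect == "Speech"]
  })
  ks <- stats::ks.test(ps, "punif")
  expect_gt(ks$p.value, 0.01)
})

test_that("listwise deletion removes participants with missing cells", {
  d <- expand.grid(participant = paste0("s", 1:6),
                   speech_state = c("speaking", "listening"),
                   task = c("introduction", "storytelling"),
                   stringsAsFactors = FALSE)
  d$group <- ifelse(d$participant %in% paste0("s", 1:3), "A", "B")
  set.seed(1)
  d$face_prop <- rnorm(nrow(d))
  d$missing <- d$participant == "s1" & d$speech_state == "speaking" &
    d$task == "introduction"
  res <- mixed_anova_2x2x2(tibble::as_tibble(d), "face_prop")
  expect_equal(attr(res, "n_included"), 5)
  d$missing <- d$participant %in% c("s1", "s2")
  expect_error(mixed_anova_2x2x2(tibble::as_tibble(d), "face_prop"),
               class = "dyadscan_insufficient-data")
})

test_that("signed-rank and Mann-Whitney match their enumeration oracles", {
  got <- wilcoxon_signed_rank(c(2, 4, 6), c(1, 2, 3))
  expect_equal(got$p, 0.25)
  expect_equal(got$V, 6)
  got2 <- mann_whitney_u(1:3, 4:6)
  expect_equal(got2$U, 0)
  expect_equal(got2$p, 0.1)
  set.seed(11)
  for (rep in 1:5) {
    x <- round(rnorm(7), 1)  # rounding induces occasional ties
    y <- round(rnorm(7), 1)
    o <- oracle_signed_rank(x, y)
    g <- wilcoxon_signed_rank(x, y)
    expect_equal(g$V, o$V)
    expect_equal(g$p, o$p, tolerance = 1e-12)
    a <- round(rnorm(6), 1); b <- round(rnorm(5), 1)
    om <- oracle_mann_whitney(a, b)
    gm <- mann_whitney_u(a, b)
    expect_equal(gm$U, om$U)
    expect_equal(gm$p, om$p, tolerance = 1e-12)
  }
})

test_that("rank tests agree with the base R routines on tie-free data", {
  set.seed(13)
  x <- rnorm(12); y <- rnorm(12)
  expect_equal(wilcoxon_signed_rank(x, y)$p,
               wilcox.test(x, y, paired = TRUE, exact = TRUE)$p.value)
  a <- rnorm(8); b <- rnorm(9)
  expect_equal(mann_whitney_u(a, b)$p,
               wilcox.test(a, b, exact = TRUE)$p.value)
})

test_that("degenerate rank-test inputs are signalled or give p near 1", {
  expect_error(wilcoxon_signed_rank(1:4, 1:4), class = "dyadscan_degenerate-data")
  same <- c(1, 2, 3, 4, 5)
  expect_gte(mann_whitney_u(same, same)$p, 1 - 1e-9)
})

test_that("Spearman correlation matches the 5!-enumeration oracle", {
  expect_equal(spearman_cor(1:6, (1:6)^2)$rho, 1)
  expect_equal(spearman_cor(1:6, -(1:6)^3)$rho, -1)
  set.seed(17)
  for (rep in 1:4) {
    x <- rnorm(5); y <- rnorm(5)
    o <- oracle_spearman(x, y)
    g <- spearman_cor(x, y)
    expect_equal(g$rho, o$rho)
    expect_equal(g$p, o$p, tolerance = 1e-10)
  }
  expect_error(spearman_cor(rep(1, 5), rnorm(5)),
               class = "dyadscan_undefined-correlation")
})

test_that("trait analysis reports group differences and per-group correlations", {
  spec <- cohort_spec(n_per_group = 8, session_duration_s = 25, seed = 33)
  co <- generate_cohort(spec, trait_links = c(aq = -0.8))
  res <- run_roi_pipeline(co, cfg)
  ta <- trait_analysis(res$outcomes, co$traits, cfg)
  expect_equal(nrow(ta$group_tests), 2)
  expect_equal(ta$group_tests$df, c(14, 14))  # pooled df n1 + n2 - 2
  expect_true(all(c("rho", "p", "n") %in% names(ta$correlations)))
  expect_true(all(ta$correlations$rho >= -1 & ta$correlations$rho <= 1))
  # the summary table covers every condition cell
  st <- roi_summary_table(res$outcomes)
  expect_equal(nrow(st), 8)
  expect_true(all(st$median_pct >= 0 & st$median_pct <= 100))
})

test_that("follow-up contrasts run on pipeline outcomes", {
  spec <- cohort_spec(n_per_group = 6, session_duration_s = 25, seed = 44)
  co <- generate_cohort(spec)
  res <- run_roi_pipeline(co, cfg)
  f1 <- followup_tests(res$outcomes, "face_prop", "speech")
  expect_lt(f1$p, 0.05)  # the listening > speaking gap is built in
  f2 <- followup_tests(res$outcomes, "face_prop", "group")
  expect_true(f2$p >= 0 && f2$p <= 1)
  sw <- shapiro_screen(res$outcomes, "face_prop")
  expect_equal(nrow(sw), 8)
})
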