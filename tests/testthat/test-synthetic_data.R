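cfg <- analysis_config()

test_that("cohort specs can be fixed from a YAML file", {
  f <- withr::local_tempfile(fileext = ".yaml")
  writeLines(c("n_per_group: 5", "loss_rate: 0.02", "seed: 42"), f)
  sp <- cohort_spec(file = f)
  expect_equal(sp$n_per_group, 5)
  expect_equal(sp$loss_rate, 0.02)
  expect_equal(sp$seed, 42L)
  # explicit arguments win over the file
  expect_equal(cohort_spec(n_per_group = 3, file = f)$n_per_group, 3)
  writeLines("bogus_field: 1", f)
  expect_error(cohort_spec(file = f), class = "dyadscan_config-error")
})

test_that("specifications validate their invariants", {
  expect_error(cohort_spec(n_per_group = 1), class = "dyadscan_invalid-argument")
  expect_error(cohort_spec(loss_rate = 1), class = "dyadscan_invalid-argument")
  expect_error(cohort_spec(session_duration_s = 0),
               class = "dyadscan_invalid-argument")
  expect_error(gaze_profile(list(list(center = c(5, 5), spread = 1, weight = 0.5)),
                            off_face_weight = 0.2),
               class = "dyadscan_invalid-argument")  # weights must sum to 1
  expect_error(gaze_profile(list(list(center = c(5, 5), spread = 0, weight = 0.8)),
                            off_face_weight = 0.2),
               class = "dyadscan_invalid-argument")
  p <- default_profiles()
  for (g in p) for (pr in g) {
    w <- sum(vapply(pr$components, function(cc) cc$weight, numeric(1)))
    expect_equal(w + pr$off_face_weight, 1)
  }
})

test_that("effect injection keeps the mixture normalised", {
  pr <- default_profiles()$A$listening
  pe <- profile_with_effect(pr, list(center = c(5.5, 10.5), magnitude = 0.25))
  w <- vapply(pe$components, function(cc) cc$weight, numeric(1))
  expect_equal(sum(w) + pe$off_face_weight, 1)
  expect_equal(w[length(w)], 0.25)
  expect_equal(pe$off_face_weight, pr$off_face_weight * 0.75)
})

test_that("sessions are seed-reproducible and sampled at exactly 60 Hz", {
  tr <- generate_face_track(240, 20, seed = 3)
  s1 <- generate_session(tr, default_profiles()$A$listening, loss_rate = 0.1,
                         seed = 9)
  s2 <- generate_session(tr, default_profiles()$A$listening, loss_rate = 0.1,
                         seed = 9)
  expect_identical(s1$gaze, s2$gaze)
  expect_identical(s1$ground_truth, s2$ground_truth)
  expect_equal(diff(s1$gaze$t), rep(1000 / 60, nrow(s1$gaze) - 1))
  expect_error(generate_session(NULL, default_profiles()$A$listening),
               class = "dyadscan_invalid-argument")
})

test_that("the loss process hits its target rate with contiguous runs", {
  tr <- generate_face_track(24 * 100, 15, seed = 4)
  ses <- generate_session(tr, default_profiles()$B$listening, loss_rate = 0.12,
                          seed = 14)
  n <- nrow(ses$gaze)
  frac <- mean(!ses$gaze$valid)
  # within binomial-ish error of the target (runs inflate the variance; the
  # bound uses the effective number of runs rather than samples)
  expect_lt(abs(frac - 0.12), 0.05)
  runs <- rle(ses$gaze$valid)
  expect_gt(mean(runs$lengths[!runs$values]), 2)  # contiguous loss episodes
  # degenerate rate: no loss at all
  ses0 <- generate_session(tr, default_profiles()$B$listening, loss_rate = 0,
                           seed = 15)
  expect_true(all(ses0$gaze$valid))
})

test_that("a pure upper-face profile yields upper-classified fixations downstream", {
  prof <- gaze_profile(list(list(center = c(5.5, 3.5), spread = 0.7, weight = 1)),
                       off_face_weight = 0)
  tr <- generate_face_track(24 * 90, 20, seed = 5)
  ses <- generate_session(tr, prof, seed = 6)
  fx <- detect_fixations(ses$gaze, cfg)$fixations
  lab <- classify_fixations(fx, tr$boxes, cfg)
  expect_gt(nrow(lab), 100)
  expect_gte(mean(lab$label == "upper"), 0.99)
})

test_that("the remapped on-face sample density matches the generating mixture", {
  # one long session, ~50k samples; compare coarse-binned template densities
  # of the session against direct draws from the same (clamped) mixture
  prof <- default_profiles()$B$listening
  tr <- generate_face_track(24 * 850, 0, seed = 7)  # static box: exact remap
  ses <- generate_session(tr, prof, seed = 8)
  expect_gte(nrow(ses$gaze), 50000)
  box <- dyadscan:::track_box_at(tr, 0)
  gt <- ses$ground_truth
  on <- gt[!is.na(gt$template_x_deg), ]
  # weight each generated fixation by its sample count
  wts <- round((on$t_end - on$t_start) / (1000 / 60)) + 1
  bx <- findInterval(on$template_x_deg, 0:11, all.inside = TRUE)
  by <- findInterval(on$template_y_deg, 0:14, all.inside = TRUE)
  emp <- tapply(wts, list(factor(bx, 1:11), factor(by, 1:14)), sum)
  emp[is.na(emp)] <- 0
  emp <- emp / sum(emp)
  # reference: direct draws from the clamped mixture
  set.seed(99)
  ndraw <- 50000
  w <- vapply(prof$components, function(cc) cc$weight, numeric(1))
  comp <- sample.int(length(w), ndraw, replace = TRUE, prob = w / sum(w))
  cx <- vapply(prof$components, function(cc) cc$center[1], numeric(1))[comp]
  cy <- vapply(prof$components, function(cc) cc$center[2], numeric(1))[comp]
  sp <- vapply(prof$components, function(cc) cc$spread, numeric(1))[comp]
  dx <- pmin(pmax(rnorm(ndraw, cx, sp), 0.3), 10.7)
  dy <- pmin(pmax(rnorm(ndraw, cy, sp), 0.3), 13.7)
  rx <- findInterval(dx, 0:11, all.inside = TRUE)
  ry <- findInterval(dy, 0:14, all.inside = TRUE)
  ref <- tapply(rep(1, ndraw), list(factor(rx, 1:11), factor(ry, 1:14)), sum)
  ref[is.na(ref)] <- 0
  ref <- ref / sum(ref)
  tv <- 0.5 * sum(abs(emp - ref))
  expect_lt(tv, 0.08)
})

test_that("cohorts are balanced, deterministic, and carry ground truth", {
  spec <- cohort_spec(n_per_group = 2, session_duration_s = 20, seed = 12)
  co <- generate_cohort(spec)
  expect_equal(nrow(co$traits), 4)
  streams <- dplyr::distinct(co$gaze, participant, task)
  expect_equal(nrow(streams), 4 * 2)  # 2 x 2 participants x 2 tasks
  co2 <- generate_cohort(spec)
  expect_identical(co$gaze, co2$gaze)
  expect_identical(co$traits, co2$traits)
  expect_identical(co$ground_truth, co2$ground_truth)
  expect_true(all(co$traits$aq >= 0 & co$traits$aq <= 50))
  expect_true(all(co$traits$lsas >= 0 & co$traits$lsas <= 144))
})

test_that("trait links induce the requested association direction", {
  spec <- cohort_spec(n_per_group = 30, session_duration_s = 20, seed = 90)
  co <- generate_cohort(spec, trait_links = c(aq = -0.9))
  # the latent factor raises the eye weight when AQ is low; check against the
  # generator's own per-participant upper-face ground truth share
  gt <- co$ground_truth
  up <- tapply(gt$label == "upper", gt$participant,
               function(v) mean(v))
  aq <- setNames(co$traits$aq, co$traits$participant)[names(up)]
  gr <- setNames(co$traits$group, co$traits$participant)[names(up)]
  rho <- cor(aq[gr == "A"], up[gr == "A"], method = "spearman")
  expect_lt(rho, 0)
})
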