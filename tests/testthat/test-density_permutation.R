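cfg <- analysis_config()
tpl <- face_template(cfg)

test_that("box corners anchor to the template corners", {
  box <- random_convex_quad()
  expect_equal(remap_to_template(box[1, 1], box[1, 2], box, tpl)[1, ],
               c(tx = 0, ty = 0))
  expect_equal(remap_to_template(box[3, 1], box[3, 2], box, tpl)[1, ],
               c(tx = 110, ty = 140))
  # parallelogram centroid maps to the template centre
  par <- rbind(c(0, 0), c(200, 40), c(260, 320), c(60, 280))
  ctr <- colMeans(par)
  expect_equal(remap_to_template(ctr[1], ctr[2], par, tpl)[1, ],
               c(tx = 55, ty = 70), tolerance = 1e-9)
  # far points are outside
  expect_true(all(is.na(remap_to_template(500, 5, par, tpl))))
})

test_that("remapping inverts the forward bilinear map on random quads", {
  set.seed(23)
  for (rep in 1:10) {
    box <- random_convex_quad()
    u <- runif(1000); v <- runif(1000)
    for (i in seq_len(50)) {
      p <- oracle_forward_bilinear(u[i], v[i], box)
      tp <- remap_to_template(p[1], p[2], box, tpl)
      expect_equal(unname(tp[1, ]), c(u[i] * 110, v[i] * 140), tolerance = 1e-7)
      back <- oracle_forward_bilinear(tp[1, 1] / 110, tp[1, 2] / 140, box)
      expect_equal(unname(back), unname(p), tolerance = 1e-7)
    }
  }
})

test_that("density accumulation deposits duration at the remapped centroid", {
  box <- rbind(c(500, 300), c(720, 300), c(720, 580), c(500, 580))
  boxes <- dyadscan:::box_to_row(box, 0L, "detected")
  ctr <- colMeans(box)
  fx <- tibble::tibble(frame = 0L, x = ctr[1], y = ctr[2], duration = 200,
                       label = "upper")
  m <- accumulate_density(fx, boxes, tpl, cfg)
  expect_equal(sum(m), 200)
  expect_equal(unclass(m)[71, 56], 200)  # template (55, 70) -> pixel (56, 71)
  expect_false(attr(m, "missing"))
  # off-face fixations contribute nothing and flag the map missing
  fx2 <- tibble::tibble(frame = 0L, x = ctr[1], y = ctr[2], duration = 200,
                        label = "outside")
  m2 <- accumulate_density(fx2, boxes, tpl, cfg)
  expect_equal(sum(m2), 0)
  expect_true(attr(m2, "missing"))
})

test_that("the accumulated peak sits near the generating centre", {
  prof <- gaze_profile(list(list(center = c(5.5, 10.5), spread = 0.6, weight = 1)),
                       off_face_weight = 0)
  tr <- generate_face_track(24 * 120, 20, seed = 61)
  ses <- generate_session(tr, prof, seed = 62)
  fx <- detect_fixations(ses$gaze, cfg)$fixations
  lab <- classify_fixations(fx, tr$boxes, cfg)
  m <- accumulate_density(lab, tr$boxes, tpl, cfg)
  sm <- smooth_map(m, tpl, cfg)
  peak <- which(unclass(sm) == max(sm), arr.ind = TRUE)[1, ]
  peak_deg <- c((peak["col"] - 0.5) * tpl$scale_deg_px,
                (peak["row"] - 0.5) * tpl$scale_deg_px)
  expect_lt(sqrt(sum((peak_deg - c(5.5, 10.5))^2)), 1)
})

test_that("smoothing conserves mass, is linear, and matches the Gaussian", {
  set.seed(3)
  raw <- matrix(rexp(140 * 110), 140, 110)
  sm <- smooth_map(raw, tpl, cfg, normalize = FALSE)
  expect_equal(sum(sm), sum(raw), tolerance = 1e-9)
  # linearity
  raw2 <- matrix(rexp(140 * 110), 140, 110)
  s_sum <- smooth_map(raw + raw2, tpl, cfg, normalize = FALSE)
  expect_equal(unclass(s_sum),
               unclass(smooth_map(raw, tpl, cfg, normalize = FALSE)) +
                 unclass(smooth_map(raw2, tpl, cfg, normalize = FALSE)),
               tolerance = 1e-9)
  # a centred point mass reproduces the closed-form Gaussian in the interior
  pm <- matrix(0, 140, 110); pm[70, 55] <- 1
  smp <- unclass(smooth_map(pm, tpl, cfg, normalize = FALSE))
  sigma_px <- cfg$kernel_width_deg / tpl$scale_deg_px
  for (off in list(c(0, 0), c(5, 3), c(-8, 10), c(15, -12))) {
    r2 <- sum(off^2)
    expect_equal(smp[70 + off[1], 55 + off[2]] / smp[70, 55],
                 exp(-r2 / (2 * sigma_px^2)), tolerance = 1e-6)
  }
  # radial symmetry
  expect_equal(smp[70 + 7, 55], smp[70 - 7, 55], tolerance = 1e-9)
  expect_equal(max(smp), smp[70, 55])
})

test_that("pixelwise t has the pooled-variance form and its symmetries", {
  set.seed(9)
  mk <- function(v) dyadscan:::new_density_map(matrix(v, 2, 2),
                                               list(width_px = 2, height_px = 2,
                                                    scale_deg_px = 1))
  A <- list(mk(c(1, 2, 3, 4)), mk(c(2, 3, 4, 5)))
  B <- list(mk(c(5, 5, 0, 1)), mk(c(7, 6, 1, 0)))
  res <- pixelwise_t(A, B, cfg)
  # hand arithmetic for pixel (1,1): A = {1,2}, B = {5,7}
  sp2 <- (0.5 + 2) / 2
  t_hand <- (1.5 - 6) / sqrt(sp2 * (1 / 2 + 1 / 2))
  expect_equal(res$t_map[1, 1], t_hand)
  expect_equal(res$df, 2)
  # identical sets give t = 0; swapping groups negates t
  expect_true(all(pixelwise_t(A, A, cfg)$t_map == 0))
  expect_equal(pixelwise_t(B, A, cfg)$t_map, -res$t_map)
  # zero pooled variance with different means gives the Inf sentinel
  C <- list(mk(rep(0, 4)), mk(rep(0, 4)))
  D <- list(mk(rep(1, 4)), mk(rep(1, 4)))
  expect_true(all(is.infinite(pixelwise_t(C, D, cfg)$t_map)))
  expect_true(all(pixelwise_t(C, C, cfg)$t_map == 0))
})

test_that("cluster finding matches the flood-fill oracle", {
  # constructed 3x3 block
  tm <- matrix(0, 20, 20)
  tm[5:7, 5:7] <- 10
  cl <- find_clusters(tm, 3, cfg)
  expect_equal(nrow(cl$clusters), 1)
  expect_equal(cl$clusters$size, 9)
  expect_equal(cl$clusters$sign, "positive")
  expect_equal(nrow(find_clusters(matrix(0.1, 20, 20), 3, cfg)$clusters), 0)
  set.seed(29)
  for (conn in c(4, 8)) {
    cfgc <- analysis_config(connectivity = conn)
    for (rep in 1:5) {
      tm <- matrix(rnorm(30 * 25, sd = 3), 30, 25)
      cl <- find_clusters(tm, 3, cfgc)
      pos_or <- oracle_components(tm > 3, conn)
      neg_or <- oracle_components(tm < -3, conn)
      got_pos <- cl$labels * (cl$labels > 0)
      got_neg <- -cl$labels * (cl$labels < 0)
      expect_true(same_partition(got_pos, pos_or))
      expect_true(same_partition(got_neg, neg_or))
      # sizes agree with the oracle components
      expect_setequal(cl$clusters$size,
                      c(tabulate(pos_or[pos_or > 0]), tabulate(neg_or[neg_or > 0])))
    }
  }
})

test_that("identical maps across participants give an empty result", {
  m <- simulate_template_maps(1, default_profiles()$A$listening, 100, tpl,
                              cfg, seed = 5)[[1]]
  maps <- lapply(1:6, function(i) m)
  res <- permutation_test(maps, rep(c("A", "B"), 3),
                          analysis_config(n_permutations = 50, rng_seed = 1))
  expect_equal(nrow(res$clusters), 0)
})

test_that("Monte Carlo p-values agree with exhaustive enumeration on 3 vs 3", {
  cfgs <- analysis_config(template_px = c(22, 28), n_permutations = 10000,
                          rng_seed = 77)
  tps <- face_template(cfgs)
  prof <- default_profiles()$A$listening
  maps <- simulate_template_maps(6, prof, 60, tps, cfgs, seed = 55)
  # induce a modest group difference so some clusters form
  maps[[1]][, ] <- maps[[1]] + 3e-4
  maps[[2]][, ] <- maps[[2]] + 3e-4
  groups <- rep(c("A", "B"), each = 3)
  ex <- permutation_test(maps, groups, cfgs, exhaustive = TRUE)
  mc <- permutation_test(maps, groups, cfgs)
  expect_equal(ex$n_permutations, choose(6, 3))
  expect_gt(nrow(mc$clusters), 0)
  expect_lt(max(abs(mc$clusters$p - ex$clusters$p)), 0.02)  # absolute agreement
})

test_that("permutation p-values live in [1/(B+1), 1] and seeding reproduces them", {
  cfgs <- analysis_config(template_px = c(22, 28), n_permutations = 200,
                          rng_seed = 7)
  tps <- face_template(cfgs)
  mapsA <- simulate_template_maps(5, default_profiles()$A$listening, 80, tps,
                                  cfgs, seed = 1)
  mapsB <- simulate_template_maps(5, default_profiles()$B$listening, 80, tps,
                                  cfgs, seed = 2)
  res1 <- permutation_test(c(mapsA, mapsB), rep(c("A", "B"), each = 5), cfgs)
  res2 <- permutation_test(c(mapsA, mapsB), rep(c("A", "B"), each = 5), cfgs)
  expect_identical(res1$null_max, res2$null_max)
  if (nrow(res1$clusters)) {
    expect_true(all(res1$clusters$p >= 1 / 201 & res1$clusters$p <= 1))
  }
  msk <- significance_mask(res1)
  expect_true(all(msk %in% c(-1L, 0L, 1L)))
})

test_that("an injected group effect is detected and localised end to end", {
  spec <- cohort_spec(n_per_group = 14, seed = 202)
  eff <- list(center = c(5.5, 10.5), magnitude = 0.4)
  prof <- default_profiles()
  co <- generate_cohort(spec, profile_group_A = prof$A,
                        profile_group_B = prof$A, injected_effect = eff)
  res <- run_roi_pipeline(co, analysis_config(), density = TRUE)
  maps <- res$maps$listening
  groups <- res$map_groups[names(maps)]
  pr <- permutation_test(maps, groups,
                         analysis_config(n_permutations = 500, rng_seed = 3))
  sig <- pr$clusters[pr$clusters$significant, ]
  expect_gt(nrow(sig), 0)
  # the largest significant cluster in the injected direction (group B looked
  # at the mouth more, so the A-minus-B contrast is negative there) sits over
  # the injected location; per-participant normalisation also produces a
  # compensating opposite-sign cluster elsewhere, which is not the one checked
  neg <- sig[sig$sign == "negative", ]
  expect_gt(nrow(neg), 0)
  top <- neg$id[which.max(neg$stat)]
  sel <- which(pr$labels == top, arr.ind = TRUE)
  cen <- c(mean(sel[, "col"]), mean(sel[, "row"])) * 0.1
  expect_lt(sqrt(sum((cen - c(5.5, 10.5))^2)), 2)
})
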