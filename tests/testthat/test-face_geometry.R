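cfg <- analysis_config()

test_that("classify_point splits an axis-aligned box at the midline", {
  box <- rbind(c(0, 0), c(100, 0), c(100, 140), c(0, 140))
  expect_equal(classify_point(50, 35, box), "upper")
  expect_equal(classify_point(50, 105, box), "lower")
  expect_equal(classify_point(500, 500, box), "outside")
  expect_equal(classify_point(50, 70, box), "upper")   # midline tie-break
  expect_equal(classify_point(0, 0, box), "upper")     # edge counts as inside
})

test_that("classify_point matches a ray-casting oracle on random points", {
  set.seed(31)
  for (rep in 1:5) {
    box <- random_convex_quad()
    px <- runif(2000, 300, 1000)
    py <- runif(2000, 100, 900)
    got <- classify_point(px, py, box)
    want <- vapply(seq_along(px), function(i) oracle_classify(px[i], py[i], box),
                   character(1))
    # the two boundary conventions may disagree only on exact edges, which
    # have measure zero for continuous draws
    expect_equal(got, want)
  }
})

test_that("classify_point is invariant under joint similarity transforms", {
  set.seed(5)
  box <- random_convex_quad()
  px <- runif(500, 400, 900); py <- runif(500, 200, 800)
  base <- classify_point(px, py, box)
  for (params in list(c(1, 0, 0, 0), c(2, 0.4, 100, -50), c(0.5, -1.1, -30, 70))) {
    s <- params[1]; th <- params[2]
    a <- complex(modulus = s, argument = th)
    b <- complex(real = params[3], imaginary = params[4])
    tp <- a * complex(real = px, imaginary = py) + b
    tb <- a * complex(real = box[, 1], imaginary = box[, 2]) + b
    got <- classify_point(Re(tp), Im(tp), cbind(Re(tb), Im(tb)))
    expect_equal(got, base)
  }
})

test_that("upper and lower partition the quadrilateral interior", {
  set.seed(6)
  box <- random_convex_quad()
  px <- runif(5000, 300, 1000); py <- runif(5000, 100, 900)
  lab <- classify_point(px, py, box)
  inside <- dyadscan:::points_in_quad(px, py, box)
  expect_true(all(lab[inside] %in% c("upper", "lower")))
  expect_true(all(lab[!inside] == "outside"))
  expect_gt(sum(lab == "upper"), 0)
  expect_gt(sum(lab == "lower"), 0)
})

test_that("propagate_box applies the exact similarity on noiseless tracks", {
  set.seed(7)
  box <- random_convex_quad()
  pts <- cbind(runif(20, 450, 850), runif(20, 250, 750))
  # identity correspondences leave the box unchanged
  expect_equal(propagate_box(pts, pts, box, 0, cfg), box)
  # known similarity is recovered to numerical precision
  a <- complex(modulus = 1.03, argument = 0.05)
  b <- complex(real = 12, imaginary = -7)
  z <- complex(real = pts[, 1], imaginary = pts[, 2])
  moved <- a * z + b
  bz <- a * complex(real = box[, 1], imaginary = box[, 2]) + b
  got <- propagate_box(pts, cbind(Re(moved), Im(moved)), box, 0, cfg)
  expect_equal(got, cbind(Re(bz), Im(bz)), tolerance = 1e-10)
})

test_that("propagation refuses too few points or an exhausted frame budget", {
  box <- rbind(c(500, 300), c(740, 300), c(740, 600), c(500, 600))
  pts <- cbind(runif(14, 500, 740), runif(14, 300, 600))
  res <- propagate_box(pts, pts, box, 0, cfg)
  expect_true(is_redetect(res))
  expect_equal(res$reason, "too-few-points")
  pts15 <- rbind(pts, c(600, 450))
  expect_false(is_redetect(propagate_box(pts15, pts15, box, 149, cfg)))
  res2 <- propagate_box(pts15, pts15, box, 150, cfg)
  expect_true(is_redetect(res2))
  expect_equal(res2$reason, "frame-budget")
  expect_error(propagate_box(pts[1:2, ], pts[1:2, ], box, 0, cfg),
               class = "dyadscan_invalid-argument")
})

test_that("stepwise propagation composes like the composite motion", {
  tr <- generate_face_track(120, 40, seed = 13)
  box <- dyadscan:::track_box_at(tr, 0)
  for (f in 1:119) {
    box <- propagate_box(tr$points[[f]], tr$points[[f + 1]], box, 0, cfg)
  }
  expect_equal(box, dyadscan:::track_box_at(tr, 119), tolerance = 1e-6)
})

test_that("a zero-motion track repeats one identical quadrilateral", {
  tr <- generate_face_track(50, 0, seed = 2)
  first <- dyadscan:::track_box_at(tr, 0)
  for (f in 1:49) expect_equal(dyadscan:::track_box_at(tr, f), first)
})

test_that("forced point dropout is flagged for re-detection by the track walk", {
  sched <- rep(30L, 60)
  sched[25] <- 10L
  tr <- generate_face_track(60, 10, dropout_schedule = sched, seed = 3)
  res <- propagate_track(tr, cfg)
  expect_true(24 %in% res$redetections$frame)  # 0-based frame 24
  expect_equal(res$boxes$source[25], "detected")
  # stored correspondences are exact images of the anchors per frame
  for (f in c(1, 30, 60)) {
    trf <- tr$transforms[[f]]
    az <- complex(real = tr$anchors[, 1], imaginary = tr$anchors[, 2])
    w <- trf$a * az + trf$b
    k <- nrow(tr$points[[f]])
    expect_equal(tr$points[[f]], cbind(Re(w), Im(w))[seq_len(k), , drop = FALSE])
  }
})

test_that("track determinism: same seed gives byte-identical output", {
  t1 <- generate_face_track(80, 25, seed = 99)
  t2 <- generate_face_track(80, 25, seed = 99)
  expect_identical(t1$boxes, t2$boxes)
  expect_identical(t1$points, t2$points)
  expect_error(generate_face_track(0), class = "dyadscan_invalid-argument")
})

test_that("fixations are classified against the nearest box within tolerance", {
  tr <- generate_face_track(100, 0, seed = 4)
  boxes <- tr$boxes
  ctr <- c(mean(boxes$x_tl[1] + boxes$x_br[1]) / 2,
           mean(boxes$y_tl[1] + boxes$y_br[1]) / 2)
  fx <- tibble::tibble(frame = c(10L, 50L), x = ctr[1], y = ctr[2],
                       t_start = 0, t_end = 1, duration = 1)
  lab <- classify_fixations(fx, boxes, cfg)
  expect_true(all(lab$label %in% c("upper", "lower")))
  # a fixation far beyond any stored box frame is unclassifiable
  fx2 <- tibble::tibble(frame = 500L, x = ctr[1], y = ctr[2],
                        t_start = 0, t_end = 1, duration = 1)
  expect_equal(classify_fixations(fx2, boxes, cfg)$label, "unclassifiable")
})

test_that("classification recovers the generating region labels", {
  tr <- generate_face_track(24 * 60, 20, seed = 21)
  ses <- generate_session(tr, default_profiles()$B$listening, seed = 22)
  fx <- detect_fixations(ses$gaze, cfg)$fixations
  lab <- classify_fixations(fx, tr$boxes, cfg)
  # match detected fixations to generated ones by midpoint containment,
  # keeping only targets generated strictly inside one region (>= 0.5 deg
  # from the midline and the box edge)
  gt <- ses$ground_truth
  mid <- (lab$t_start + lab$t_end) / 2
  hit <- findInterval(mid, gt$t_start)
  ok <- hit >= 1 & mid <= gt$t_end[hit]
  strict <- ok & !is.na(gt$template_x_deg[hit]) &
    gt$template_x_deg[hit] > 0.5 & gt$template_x_deg[hit] < 10.5 &
    abs(gt$template_y_deg[hit] - 7) > 0.5 &
    gt$template_y_deg[hit] > 0.5 & gt$template_y_deg[hit] < 13.5
  agree <- lab$label[strict] == gt$label[hit[strict]]
  expect_gt(sum(strict), 50)
  expect_gte(mean(agree), 0.99)
})
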