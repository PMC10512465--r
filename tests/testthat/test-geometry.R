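test_that("deg_to_screen is tan-based and exactly invertible", {
  geom <- viewing_geometry(view_distance_m = 0.2)
  expect_equal(deg_to_screen(0, geom), 0)
  expect_equal(deg_to_screen(45, geom), 0.2)
  expect_equal(deg_to_screen(-45, geom), -0.2)

  angles <- seq(-89, 89, by = 0.5)
  expect_equal(screen_to_deg(deg_to_screen(angles, geom), geom), angles,
               tolerance = 1e-12)
  expect_error(deg_to_screen(90, geom), "< 90")
})

test_that("form display pairs are oriented toward the FoE", {
  geom <- viewing_geometry()
  # every constructed pair's direction is parallel to (FoE - center)
  d <- make_form_display(0, n_pairs = 30, geom = geom, seed = 1)
  dx <- d$pairs$dot2_x_m - d$pairs$dot1_x_m
  dy <- d$pairs$dot2_y_m - d$pairs$dot1_y_m
  tx <- 0 - d$pairs$center_x_m
  ty <- 0 - d$pairs$center_y_m
  expect_equal(dx * ty - dy * tx, rep(0, 30), tolerance = 1e-15)

  # hand checks of the orientation rule: with the FoE at 0 deg, a pair at
  # (10, 0) deg lies horizontal and a pair at (10, 10) deg points along
  # the unit vector toward the screen center, (-sqrt(2)/2, -sqrt(2)/2)
  cx <- deg_to_screen(10, geom); cy <- deg_to_screen(10, geom)
  expect_equal(c(0 - cx, 0) / abs(cx), c(-1, 0))
  u <- c(0 - cx, 0 - cy) / sqrt(cx^2 + cy^2)
  expect_equal(u, -c(sqrt(2) / 2, sqrt(2) / 2))

  # the density presets carry the documented dot counts
  expect_equal(density_dot_count("form", "high"), 45)
  expect_equal(density_dot_count("form", "low"), 14)
  expect_equal(density_dot_count("motion", "high"), 90)
  expect_equal(density_dot_count("motion", "low"), 28)
  d45 <- make_form_display(5, n_pairs = 45, seed = 2)
  expect_equal(2 * d45$n_pairs, 90)
})

test_that("form displays satisfy collinearity, separation and field bounds", {
  geom <- viewing_geometry()
  sep <- deg_to_screen(1, geom)
  for (seed in 1:20) {
    set.seed(seed)
    foe <- sample(-45:45, 1)
    d <- make_form_display(foe, n_pairs = 45, geom = geom, seed = seed)
    expect_lt(form_collinearity_error(d), 1e-9)
    gap <- sqrt((d$pairs$dot2_x_m - d$pairs$dot1_x_m)^2 +
                  (d$pairs$dot2_y_m - d$pairs$dot1_y_m)^2)
    expect_equal(gap, rep(sep, 45), tolerance = 1e-12)
    expect_true(all(abs(d$pairs$center_x_deg) <= 56))
    expect_true(all(abs(d$pairs$center_y_deg) <= 40))
  }
  expect_error(make_form_display(0, n_pairs = 1e6), "n_pairs too large")
})

test_that("motion display kinematics match hand calculation", {
  # straight-ahead heading: a dot at depth 1 m advances to 1 - 1.5/120 m
  geom <- viewing_geometry()
  m <- make_motion_display(0, n_dots = 5, geom = geom, seed = 1)
  f1 <- m$frames[m$frames$frame == 1, ]
  f2 <- m$frames[m$frames$frame == 2, ]
  not_recycled <- !f2$recycled
  expect_equal(f2$Z[not_recycled], f1$Z[not_recycled] - 1.5 / 120)
  expect_equal(f2$X[not_recycled], f1$X[not_recycled])

  # heading 0 puts the FoE at the screen center
  est <- estimate_motion_foe(m)
  expect_equal(est$x_m, 0, tolerance = 1e-9)
  expect_equal(est$y_m, 0, tolerance = 1e-9)

  expect_equal(m$n_frames, round(0.5 * 120))
  expect_error(make_motion_display(0, speed_m_s = 0), "positive")
  expect_error(make_motion_display(0, duration_s = -1), "positive")
})

test_that("flow lines pass through the FoE and depths stay in range", {
  for (seed in 1:10) {
    set.seed(seed)
    heading <- runif(1, -45, 45)
    m <- make_motion_display(heading, n_dots = 28, seed = seed)
    expect_true(all(m$frames$Z >= 0.2 & m$frames$Z <= 5))
    est <- estimate_motion_foe(m)
    expect_equal(est$x_deg, heading, tolerance = 1e-6)
    expect_lt(est$max_line_dist_m, 1e-9)
  }
})

test_that("displays are deterministic in the seed and report density", {
  a <- make_form_display(12, 45, seed = 99)
  b <- make_form_display(12, 45, seed = 99)
  expect_identical(a$pairs, b$pairs)
  ma <- make_motion_display(-20, 90, seed = 7)
  mb <- make_motion_display(-20, 90, seed = 7)
  expect_identical(ma$frames, mb$frames)

  expect_equal(signif(display_density(ma), 2), 0.01)
  low <- make_motion_display(0, n_dots = 28, seed = 1)
  expect_equal(signif(display_density(low), 1), 0.003)
  form_low <- make_form_display(0, n_pairs = 14, seed = 1)
  expect_equal(signif(display_density(form_low), 1), 0.003)
})

test_that("display specs export to JSON", {
  d <- make_form_display(3, n_pairs = 14, seed = 5)
  path <- withr::local_tempfile(fileext = ".json")
  write_display_spec(d, path)
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  expect_equal(x$type, "form")
  expect_equal(x$foe_deg, 3)
  expect_equal(nrow(x$pairs), 14)
})
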