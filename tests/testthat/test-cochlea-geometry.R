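test_that("membrane surface spans turns x 360 degrees and rises H360 over the first turn", {
  tpl <- fixture_template(turns = 2.75, h360 = 2.8)
  expect_equal(range(tpl$angular_coord), c(0, 990))

  # z at 360 minus z at 0 along the mid-line equals H360
  g <- tpl$grid
  mid <- (g$n_width + 1L) %/% 2L
  z_of <- function(angle) {
    i <- which(g$theta_deg == angle)
    tpl$vertices[(i - 1L) * g$n_width + mid, 3]
  }
  expect_equal(z_of(360) - z_of(0), 2.8)

  # mid-line angular coordinate strictly increases along the spiral
  expect_true(all(diff(g$theta_deg) > 0))
  # duplicate angles occur only across the ribbon width
  expect_equal(sum(tpl$angular_coord == 0), g$n_width)

  # normals lean toward the scala vestibuli everywhere
  fn <- scalafit:::face_normals(tpl$vertices, tpl$faces)
  expect_true(all(fn[, 3] > 0))
})

test_that("invalid spiral parameters are rejected", {
  expect_error(spiral_params(-1, 0.25, 2.75, 2.8), "basal_radius_a")
  expect_error(spiral_params(5, 0.25, 2.0, 2.8), "turns")
  expect_error(spiral_params(5, 0.25, 2.75, 2.8, total_height = 2.0), "height_h360")
  expect_error(spiral_params(5, NaN, 2.75, 2.8), "finite")
  expect_error(make_membrane_surface(fixture_params(), angular_step = 20), "angular_step")
})

test_that("left and right cochleae are mirror images, not rotations of each other", {
  pr <- fixture_params(side = "right")
  pl <- fixture_params(side = "left")
  tr <- make_membrane_surface(pr)
  tl <- make_membrane_surface(pl)

  # explicit reflection through the xz-plane maps one onto the other exactly
  expect_equal(tl$vertices, tr$vertices * matrix(c(1, -1, 1), nrow(tr$vertices), 3, byrow = TRUE))

  # the best-fit orthogonal map between the vertex sets is improper (det -1)
  Xc <- scale(tr$vertices, scale = FALSE)
  Yc <- scale(tl$vertices, scale = FALSE)
  sv <- svd(crossprod(Yc, Xc))
  expect_equal(det(sv$u %*% t(sv$v)), -1, tolerance = 1e-9)

  # no proper rotation achieves a near-zero residual: the landmark fit warns
  expect_warning(fit <- fit_landmark_transform(tr$landmarks, tl$landmarks),
                 "chirality")
  expect_gt(fit$rms_residual, 0.1)

  # mirroring a template round-trips
  expect_equal(mirror_template(mirror_template(tr))$vertices, tr$vertices)
})

test_that("extracted landmarks match the closed-form spiral", {
  p <- fixture_params()
  tpl <- make_membrane_surface(p, angular_step = 5)
  lm <- tpl$landmarks

  r_of <- function(theta) p$basal_radius_a * exp(-p$decay_b * theta)
  w <- p$duct_width
  # lateral wall at 180 degrees: planar radius r(pi) + w/2 on the -x axis
  expect_equal(unname(lm["lw180", ]),
               c(-(r_of(pi) + w / 2), 0, p$height_h360 / 2), tolerance = 1e-9)
  expect_equal(unname(lm["lw90", ]),
               c(0, r_of(pi / 2) + w / 2, p$height_h360 / 4), tolerance = 1e-9)
  expect_equal(unname(lm["rw_center", ]),
               c(p$basal_radius_a, 0, 0), tolerance = 1e-9)

  # planar radius of the lateral-wall point equals r + w/2 even off the mesh rings
  expect_equal(sqrt(sum(lm["lw270", 1:2]^2)), r_of(3 * pi / 2) + w / 2,
               tolerance = 1e-9)
})

test_that("landmark extraction is equivariant under rigid motion and demands coverage", {
  tpl <- fixture_template()
  set.seed(31)
  motion <- random_similarity()
  motion$scale <- 1
  moved <- transform_template(motion, tpl)
  expect_equal(unclass(extract_landmarks(moved)),
               unclass(apply_transform(motion, tpl$landmarks)),
               tolerance = 1e-9)

  cropped <- crop_by_angle(tpl, 90, 540)
  expect_error(extract_landmarks(cropped), "coverage")
})

test_that("electrode simulation places arrays with correct ground truth per pattern", {
  tpl <- fixture_template()

  none <- synth_electrode_array(tpl, "midscala_like", translocation_spec("none"),
                                seed = 3, jitter_sd = 0)
  expect_identical(as.character(none$truth_calls), rep("ST", 16))
  expect_equal(none$array$n_electrodes, 16L)

  prox <- synth_electrode_array(tpl, "midscala_like",
                                translocation_spec("proximal_crossing", 180),
                                seed = 3, jitter_sd = 0)
  apical <- prox$angles_deg > 180
  expect_true(all(as.character(prox$truth_calls)[apical] == "SV"))
  expect_true(all(as.character(prox$truth_calls)[!apical] == "ST"))

  dist_sim <- synth_electrode_array(tpl, "evo_like",
                                    translocation_spec("distal_bending", 310),
                                    seed = 3, jitter_sd = 0)
  expect_equal(dist_sim$array$n_electrodes, 20L)
  expect_false(any(dist_sim$truth_calls == "SV"))
  expect_true(any(dist_sim$truth_calls == "INT"))
  # intermediate contacts sit within a contact radius of the membrane
  radius <- dist_sim$array$contact_diameter / 2
  int_idx <- dist_sim$truth_calls == "INT"
  expect_true(all(abs(dist_sim$signed_offsets[int_idx]) < radius))
})

test_that("electrode simulation is deterministic in the seed and validates inputs", {
  tpl <- fixture_template()
  a1 <- synth_electrode_array(tpl, "evo_like", seed = 7)
  a2 <- synth_electrode_array(tpl, "evo_like", seed = 7)
  expect_identical(a1$array$centers, a2$array$centers)
  a3 <- synth_electrode_array(tpl, "evo_like", seed = 8)
  expect_false(identical(a1$array$centers, a3$array$centers))

  expect_error(synth_electrode_array(tpl, "cochlear_like"), "unknown electrode model")
  expect_error(synth_electrode_array(tpl, "evo_like", depth_angle = 2000), "span")
  expect_error(synth_electrode_array(tpl, "evo_like",
                                     translocation_spec("distal_bending", 440),
                                     depth_angle = 430),
               "outside the array")
  expect_error(translocation_spec("proximal_crossing", 300), "180")
  expect_error(translocation_spec("distal_bending", 200), "300")
})

test_that("correctly placed arrays are fully under the membrane (simulator-classifier tie)", {
  tpl <- fixture_template()
  sim <- synth_electrode_array(tpl, "evo_like", translocation_spec("none"),
                               seed = 5, jitter_sd = 0, clearance = 0.5)
  radius <- sim$array$contact_diameter / 2
  expect_true(all(sim$signed_offsets <= -radius))
  expect_true(all(fraction_under(sim$signed_offsets, radius) == 1))
})

test_that("cohort sampler matches the stated population distribution", {
  n <- 400
  dims <- sample_cochlear_dims(n, seed = 21)
  expect_lt(abs(mean(dims$A) - 9.1), 3 * 0.30 / sqrt(n))
  expect_lt(abs(mean(dims$B) - 6.8), 3 * 0.32 / sqrt(n))
  expect_lt(abs(mean(dims$h360) - 2.8), 3 * 0.21 / sqrt(n))
  expect_error(sample_cochlear_dims(0), "n must be")
})

test_that("synthetic cohorts are reproducible and honor the noise setting", {
  c1 <- synth_cohort(4, noise_sd = 0.1, seed = 77)
  c2 <- synth_cohort(4, noise_sd = 0.1, seed = 77)
  expect_identical(c1[[3]]$array$centers, c2[[3]]$array$centers)
  expect_identical(unclass(c1[[2]]$landmarks_noisy), unclass(c2[[2]]$landmarks_noisy))

  c0 <- synth_cohort(2, noise_sd = 0, seed = 5)
  expect_equal(unclass(c0[[1]]$landmarks_noisy),
               unclass(extract_landmarks(c0[[1]]$template)), tolerance = 1e-12)
  expect_error(synth_cohort(0), "n must be")

  # perimodiolar-like arrays never receive the distal pattern
  big <- synth_cohort(30, seed = 3)
  pats <- vapply(big, function(cs) cs$pattern, character(1))
  mods <- vapply(big, function(cs) cs$model_name, character(1))
  expect_false(any(pats == "distal_bending" & mods == "midscala_like"))
})
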