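# Independent scalar closest-point-on-triangle oracle (Ericson's region-based
# algorithm, plain loops) used to validate the vectorized mesh query.
oracle_closest_on_triangle <- function(p, a, b, c_) {
  ab <- b - a; ac <- c_ - a; ap <- p - a
  d1 <- sum(ab * ap); d2 <- sum(ac * ap)
  if (d1 <= 0 && d2 <= 0) return(a)
  bp <- p - b
  d3 <- sum(ab * bp); d4 <- sum(ac * bp)
  if (d3 >= 0 && d4 <= d3) return(b)
  vc <- d1 * d4 - d3 * d2
  if (vc <= 0 && d1 >= 0 && d3 <= 0) return(a + ab * d1 / (d1 - d3))
  cp <- p - c_
  d5 <- sum(ab * cp); d6 <- sum(ac * cp)
  if (d6 >= 0 && d5 <= d6) return(c_)
  vb <- d5 * d2 - d1 * d6
  if (vb <= 0 && d2 >= 0 && d6 <= 0) return(a + ac * d2 / (d2 - d6))
  va <- d3 * d6 - d5 * d4
  if (va <= 0 && (d4 - d3) >= 0 && (d5 - d6) >= 0)
    return(b + (c_ - b) * (d4 - d3) / ((d4 - d3) + (d5 - d6)))
  denom <- 1 / (va + vb + vc)
  a + ab * (vb * denom) + ac * (vc * denom)
}

oracle_mesh_distance <- function(p, vertices, faces) {
  best <- Inf
  for (i in seq_len(nrow(faces))) {
    q <- oracle_closest_on_triangle(p, vertices[faces[i, 1], ],
                                    vertices[faces[i, 2], ], vertices[faces[i, 3], ])
    best <- min(best, sqrt(sum((p - q)^2)))
  }
  best
}

test_that("mesh signed distances match a brute-force per-triangle oracle", {
  tpl <- fixture_template(angular_step = 12)
  set.seed(83)
  pts <- tpl$vertices[sample(nrow(tpl$vertices), 25), ] +
    matrix(rnorm(75, 0, 0.5), 25L)
  res <- signed_distance_to_membrane(pts, tpl)
  for (i in seq_len(nrow(pts))) {
    expect_equal(abs(res$signed_distance[i]),
                 oracle_mesh_distance(pts[i, ], tpl$vertices, tpl$faces),
                 tolerance = 1e-9)
  }
})

test_that("points on and normally offset from the surface get exact signed distances", {
  tpl <- fixture_template(angular_step = 10)
  fn <- scalafit:::face_normals(tpl$vertices, tpl$faces)
  # stay inside the clinically used window (< 450 degrees): apical windings
  # of a real cochlea stack closer together than the probe offset
  face_angle <- tpl$angular_coord[tpl$faces[, 1]]
  usable <- which(face_angle > 90 & face_angle < 450)
  set.seed(89)
  for (f in sample(usable, 12)) {
    tri <- tpl$vertices[tpl$faces[f, ], ]
    centroid <- colMeans(tri)
    on_surface <- signed_distance_to_membrane(centroid, tpl)
    expect_equal(on_surface$signed_distance, 0, tolerance = 1e-9)

    up <- centroid + 0.25 * fn[f, ]    # toward scala vestibuli
    down <- centroid - 0.25 * fn[f, ]  # toward scala tympani
    d_up <- signed_distance_to_membrane(up, tpl)$signed_distance
    d_down <- signed_distance_to_membrane(down, tpl)$signed_distance
    expect_equal(d_up, 0.25, tolerance = 0.01)   # facet curvature bounds exactness
    expect_equal(d_down, -0.25, tolerance = 0.01)
    expect_gt(d_up, 0)
    expect_lt(d_down, 0)
  }
})

test_that("queries overhanging the ribbon edge are flagged as edge-extrapolated", {
  tpl <- crop_by_angle(fixture_template(), 90, 540)
  # a point well beyond the basal cut: nearest surface point lies on the boundary
  lm <- extract_landmarks(fixture_template())
  basal_out <- unclass(lm)["rw_center", ] + c(3, 0, -1)
  res <- signed_distance_to_membrane(basal_out, tpl)
  expect_true(res$edge)
  # a point above the middle of the ribbon is not flagged
  mid_face <- tpl$faces[floor(nrow(tpl$faces) / 2), ]
  inner <- colMeans(tpl$vertices[mid_face, ]) + c(0, 0, 0.2)
  expect_false(signed_distance_to_membrane(inner, tpl)$edge)
})

test_that("spherical-cap coverage fractions are exact", {
  r <- 0.25
  expect_equal(fraction_under(0, r), 0.5)
  expect_equal(fraction_under(-r, r), 1.0)
  expect_equal(fraction_under(r, r), 0.0)
  expect_equal(fraction_under(r / 2, r), 5 / 32)
  expect_equal(fraction_under(-2 * r, r), 1.0)  # clamped below
  expect_equal(fraction_under(10 * r, r), 0.0)  # clamped above

  # continuous, strictly decreasing across (-r, r), 1/2 at 0
  d <- seq(-r, r, length.out = 401)
  f <- fraction_under(d, r)
  expect_true(all(diff(f) < 0))
  expect_true(all(f >= 0 & f <= 1))
  expect_error(fraction_under(0, -1), "radius")
})

test_that("category thresholds include boundaries exactly as defined", {
  expect_identical(as.character(classify_electrode(c(0.50, 0.499999))), c("ST", "INT"))
  expect_identical(as.character(classify_electrode(c(0.10, 0.0999))), c("INT", "SV"))
  expect_identical(as.character(classify_electrode(c(1, 0))), c("ST", "SV"))
  expect_error(classify_electrode(1.2), "0, 1")
  expect_error(classify_electrode(0.4, thresholds = c(st = 0.5, sv = 0.7)), "thresholds")
})

test_that("array classification reproduces simulator truth in the noise-free loop", {
  tpl <- fixture_template()

  none <- synth_electrode_array(tpl, "midscala_like", translocation_spec("none"),
                                jitter_sd = 0)
  call_none <- classify_array(none$array, tpl)
  expect_identical(as.character(call_none$calls$category), rep("ST", 16))
  expect_false(call_none$translocated)
  expect_true(is.na(call_none$first_sv_angle))

  prox <- synth_electrode_array(tpl, "midscala_like",
                                translocation_spec("proximal_crossing", 180),
                                jitter_sd = 0)
  call_prox <- classify_array(prox$array, tpl)
  expect_identical(as.character(call_prox$calls$category),
                   as.character(prox$truth_calls))
  expect_true(call_prox$translocated)
  spacing <- diff(prox$angles_deg)[1]
  expect_lt(abs(call_prox$first_sv_angle - 180), spacing + 1e-6)

  distal <- synth_electrode_array(tpl, "evo_like",
                                  translocation_spec("distal_bending", 310),
                                  jitter_sd = 0)
  call_distal <- classify_array(distal$array, tpl)
  expect_identical(as.character(call_distal$calls$category),
                   as.character(distal$truth_calls))
  affected <- call_distal$calls$category == "INT"
  expect_true(any(affected))
  expect_false(any(call_distal$calls$category == "SV"))
  # intermediate calls concentrate at the membrane
  radius <- distal$array$contact_diameter / 2
  expect_true(all(abs(call_distal$calls$signed_distance_mm[affected]) < radius))
})

test_that("classification is invariant under a common rigid motion of array and template", {
  tpl <- fixture_template()
  sim <- synth_electrode_array(tpl, "evo_like",
                               translocation_spec("distal_bending", 320),
                               jitter_sd = 0)
  base <- classify_array(sim$array, tpl)
  set.seed(97)
  motion <- random_similarity()
  motion$scale <- 1
  moved_tpl <- transform_template(motion, tpl)
  moved_array <- electrode_array(apply_transform(motion, sim$array$centers),
                                 sim$array$contact_diameter, sim$array$model_name)
  moved <- classify_array(moved_array, moved_tpl)
  expect_identical(as.character(moved$calls$category),
                   as.character(base$calls$category))
  expect_equal(moved$calls$signed_distance_mm, base$calls$signed_distance_mm,
               tolerance = 1e-9)
})

test_that("the registered-frame path equals the shared-frame path", {
  tpl <- fixture_template()
  sim <- synth_electrode_array(tpl, "midscala_like", jitter_sd = 0)
  set.seed(101)
  pose <- random_similarity()  # template -> case, scale included
  case_array <- electrode_array(apply_transform(pose, sim$array$centers) ,
                                sim$array$contact_diameter * pose$scale,
                                sim$array$model_name)
  via_transform <- classify_array(case_array, tpl, transform = pose)
  direct <- classify_array(sim$array, tpl)
  expect_equal(via_transform$calls$fraction_under, direct$calls$fraction_under,
               tolerance = 1e-9)
})
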