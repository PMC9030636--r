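# Parametric cochlear geometry and synthetic-data generation.
#
# The basilar-membrane mid-surface (the middle plane of the cochlear duct,
# spiral lamina included) is modeled as a ribbon swept along a logarithmic
# planar spiral r(theta) = a * exp(-b * theta) with a monotone piecewise-linear
# height profile pinned so that the rise over the first full turn equals H360.
# The frame is right-handed: modiolar axis = +z, base plane z = 0, theta = 0
# at the round-window center, increasing toward the apex; a right cochlea
# winds counterclockwise seen from the apex and a left cochlea is its mirror
# image through the xz-plane.

#' Spiral parameters of a synthetic cochlea
#'
#' @param basal_radius_a Planar spiral scale `a` in mm (mid-line radius at the
#'   round window, theta = 0).
#' @param decay_b Dimensionless per-radian decay of the logarithmic spiral.
#' @param turns Number of cochlear turns, in \[2.25, 3\].
#' @param height_h360 Vertical rise (mm) of the duct mid-line from the base
#'   plane at 360 degrees.
#' @param total_height Total rise (mm) at the apex; must exceed `height_h360`.
#' @param duct_width Radial extent (mm) of the mid-surface ribbon at the base,
#'   lateral wall to modiolar edge. The ribbon tapers apically where the
#'   spiral radius becomes small (capped at 1.5 x the local mid-line radius).
#' @param side `"right"` or `"left"`.
#' @return An object of class `spiral_params`.
#' @export
spiral_params <- function(basal_radius_a, decay_b, turns, height_h360,
                          total_height = 1.35 * height_h360,
                          duct_width = 1.0, side = c("right", "left")) {
  side <- match.arg(side)
  vals <- c(basal_radius_a, decay_b, turns, height_h360, total_height, duct_width)
  if (!all(is.finite(vals))) stop("spiral parameters must be finite")
  if (basal_radius_a <= 0) stop("basal_radius_a must be > 0")
  if (decay_b <= 0) stop("decay_b must be > 0")
  if (turns < 2.25 || turns > 3.0) stop("turns must lie in [2.25, 3.0]")
  if (height_h360 <= 0 || height_h360 >= total_height)
    stop("height_h360 must satisfy 0 < height_h360 < total_height")
  if (duct_width <= 0) stop("duct_width must be > 0")
  structure(list(basal_radius_a = basal_radius_a, decay_b = decay_b,
                 turns = turns, height_h360 = height_h360,
                 total_height = total_height, duct_width = duct_width,
                 side = side),
            class = "spiral_params")
}

#' Solve spiral parameters from cochlear dimensions
#'
#' Inverts the landmark geometry of the analytic spiral so that a cochlea
#' built from the returned parameters reproduces the requested distance A
#' (round-window center to lateral wall at 180 degrees), distance B (lateral
#' wall at 90 to 270 degrees) and H360.
#'
#' @param A,B,h360 Cochlear dimensions in mm.
#' @inheritParams spiral_params
#' @return A `spiral_params` object.
#' @export
spiral_params_from_dims <- function(A, B, h360, turns = 2.75, duct_width = 1.0,
                                    side = c("right", "left"),
                                    total_height = 1.35 * h360) {
  side <- match.arg(side)
  if (!all(is.finite(c(A, B, h360))) || A <= 0 || B <= 0 || h360 <= 0)
    stop("A, B and h360 must be positive and finite")
  dz <- h360 / 2  # height difference across both landmark pairs
  if (A <= dz || B <= dz) stop("dimensions incompatible with height profile")
  A_p <- sqrt(A^2 - dz^2) - duct_width / 2  # a * (1 + exp(-b*pi))
  B_p <- sqrt(B^2 - dz^2) - duct_width      # a * exp(-b*pi/2) * (1 + exp(-b*pi))
  if (A_p <= 0 || B_p <= 0 || B_p >= A_p)
    stop("dimensions incompatible with a logarithmic spiral (need A sufficiently larger than B)")
  # B_p / A_p = exp(-b*pi/2) exactly, by the landmark construction
  b <- -2 * log(B_p / A_p) / pi
  a <- A_p / (1 + exp(-b * pi))
  spiral_params(a, b, turns, h360, total_height, duct_width, side)
}

spiral_height <- function(theta, h360, total_height, theta_max) {
  # piecewise-linear monotone profile, pinned at z(2*pi) = h360
  ifelse(theta <= 2 * pi,
         h360 * theta / (2 * pi),
         h360 + (total_height - h360) * (theta - 2 * pi) / max(theta_max - 2 * pi, 1e-12))
}

spiral_midline <- function(params, theta) {
  r <- params$basal_radius_a * exp(-params$decay_b * theta)
  z <- spiral_height(theta, params$height_h360, params$total_height,
                     params$turns * 2 * pi)
  sgn <- if (params$side == "left") -1 else 1
  cbind(r * cos(theta), sgn * r * sin(theta), z)
}

#' Build a basilar-membrane mid-surface template
#'
#' Sweeps a ribbon of (tapering) width `duct_width` along the spiral
#' mid-line. Vertices are ordered ring-major (all radial samples of one
#' angular station, then the next), which the landmark extractor and the
#' angular crop rely on.
#'
#' @param params A `spiral_params` object.
#' @param angular_step Angular sampling step in degrees, in (0, 15].
#' @param n_width Number of radial samples across the ribbon (odd, >= 3).
#' @param label Template label.
#' @return An object of class `membrane_template` with fields `vertices`,
#'   `faces`, `angular_coord` (degrees per vertex), `grid`, `landmarks`,
#'   `index_value`, `side`, `label`, `params`.
#' @export
make_membrane_surface <- function(params, angular_step = 5, n_width = 7,
                                  label = "synthetic") {
  if (!inherits(params, "spiral_params")) stop("params must be a spiral_params object")
  if (!is.finite(angular_step) || angular_step <= 0 || angular_step > 15)
    stop("angular_step must lie in (0, 15] degrees")
  n_width <- as.integer(n_width)
  if (n_width < 3L || n_width %% 2L == 0L) stop("n_width must be an odd integer >= 3")

  span <- params$turns * 360
  theta_deg <- seq(0, span, by = angular_step)
  if (theta_deg[length(theta_deg)] < span) theta_deg <- c(theta_deg, span)
  theta <- theta_deg * pi / 180
  r <- params$basal_radius_a * exp(-params$decay_b * theta)
  z <- spiral_height(theta, params$height_h360, params$total_height,
                     params$turns * 2 * pi)
  w_eff <- pmin(params$duct_width, 1.5 * r)  # apical taper keeps inner edge off the axis
  sgn <- if (params$side == "left") -1 else 1

  nr <- length(theta_deg)
  u <- seq(-0.5, 0.5, length.out = n_width)
  rad <- as.vector(outer(w_eff, u) + r)           # nr x n_width, ring-major when vectorized by row
  rad <- matrix(rad, nr, n_width)
  ct <- cos(theta); st <- sin(theta)
  verts <- matrix(0, nr * n_width, 3L)
  for (j in seq_len(n_width)) {
    idx <- (seq_len(nr) - 1L) * n_width + j
    verts[idx, 1] <- rad[, j] * ct
    verts[idx, 2] <- sgn * rad[, j] * st
    verts[idx, 3] <- z
  }
  angular_coord <- rep(theta_deg, each = n_width)

  # two triangles per grid quad
  i <- rep(seq_len(nr - 1L), each = n_width - 1L)
  j <- rep(seq_len(n_width - 1L), times = nr - 1L)
  v00 <- (i - 1L) * n_width + j
  v01 <- v00 + 1L
  v10 <- i * n_width + j
  v11 <- v10 + 1L
  faces <- rbind(cbind(v00, v01, v10), cbind(v01, v11, v10))
  faces <- orient_faces_up(verts, faces)

  tpl <- structure(list(vertices = verts, faces = faces,
                        angular_coord = angular_coord,
                        grid = list(theta_deg = theta_deg, n_width = n_width),
                        landmarks = NULL, index_value = NA_real_,
                        side = params$side, label = label, params = params),
                   class = "membrane_template")
  tpl$landmarks <- extract_landmarks(tpl)
  tpl
}

#' @export
print.membrane_template <- function(x, ...) {
  cat(sprintf("membrane_template '%s' (%s side)\n", x$label, x$side))
  cat(sprintf("  %d vertices, %d faces, angular span %.0f-%.0f deg\n",
              nrow(x$vertices), nrow(x$faces),
              min(x$angular_coord), max(x$angular_coord)))
  if (is.finite(x$index_value)) cat(sprintf("  index value %.3f\n", x$index_value))
  invisible(x)
}

#' Cochlear landmark set
#'
#' The four named 3D points driving both measurement and registration:
#' the round-window center and the lateral wall at 90, 180 and 270 degrees.
#'
#' @param rw_center,lw90,lw180,lw270 3D points (mm).
#' @return A 4 x 3 matrix of class `cochlear_landmarks` with rows
#'   `rw_center`, `lw90`, `lw180`, `lw270`.
#' @export
cochlear_landmarks <- function(rw_center, lw90, lw180, lw270) {
  m <- rbind(rw_center = as.numeric(rw_center), lw90 = as.numeric(lw90),
             lw180 = as.numeric(lw180), lw270 = as.numeric(lw270))
  if (ncol(m) != 3L || !all(is.finite(m))) stop("landmarks must be finite 3D points")
  if (any(dist(m) < 1e-9)) stop("landmark points must be pairwise distinct")
  sv <- svd(scale(m, scale = FALSE))$d
  if (sv[2] < 1e-9 * sv[1])
    stop("landmarks are collinear; registration requires a non-degenerate frame")
  class(m) <- c("cochlear_landmarks", class(m))
  m
}

as_landmark_matrix <- function(x) {
  if (inherits(x, "cochlear_landmarks")) return(unclass(x))
  x <- as_point_matrix(x, "landmarks")
  x
}

#' Extract the four registration landmarks from a template
#'
#' Returns the outer-edge (lateral wall) surface point at angular coordinate
#' 90, 180 and 270 degrees and the mid-line point at 0 degrees as the
#' round-window center, interpolating linearly between mesh rings.
#'
#' @param template A `membrane_template` whose angular coverage includes
#'   \[0, 270\] degrees.
#' @return A `cochlear_landmarks` object.
#' @export
extract_landmarks <- function(template) {
  stopifnot(inherits(template, "membrane_template"))
  g <- template$grid
  if (is.null(g)) stop("template carries no ring grid; landmarks cannot be extracted")
  th <- g$theta_deg
  nw <- g$n_width
  if (th[1] > 1e-9 || max(th) < 270)
    stop("coverage error: template must span [0, 270] degrees to extract landmarks")

  interp_curve <- function(col_idx, target) {
    pts <- template$vertices[(seq_along(th) - 1L) * nw + col_idx, , drop = FALSE]
    i <- findInterval(target, th, rightmost.closed = TRUE)
    if (th[i] == target) return(pts[i, ])
    f <- (target - th[i]) / (th[i + 1] - th[i])
    (1 - f) * pts[i, ] + f * pts[i + 1, ]
  }
  mid <- (nw + 1L) %/% 2L
  cochlear_landmarks(rw_center = interp_curve(mid, 0),
                     lw90  = interp_curve(nw, 90),
                     lw180 = interp_curve(nw, 180),
                     lw270 = interp_curve(nw, 270))
}

#' Mirror a template to the contralateral side
#'
#' Reflects the geometry through the plane containing the modiolar axis and
#' the 0-degree ray (the xz-plane) and flips the side label; face winding is
#' re-oriented so normals keep leaning toward the scala vestibuli.
#'
#' @param template A `membrane_template`.
#' @return The mirrored `membrane_template`.
#' @export
mirror_template <- function(template) {
  stopifnot(inherits(template, "membrane_template"))
  out <- template
  out$vertices[, 2] <- -out$vertices[, 2]
  out$faces <- orient_faces_up(out$vertices, out$faces)
  out$side <- if (template$side == "right") "left" else "right"
  if (!is.null(out$params)) out$params$side <- out$side
  if (!is.null(out$landmarks)) {
    lm <- unclass(out$landmarks)
    lm[, 2] <- -lm[, 2]
    out$landmarks <- cochlear_landmarks(lm[1, ], lm[2, ], lm[3, ], lm[4, ])
  }
  out$label <- paste0(template$label, "_mirrored")
  out
}

#' Built-in electrode-array models
#'
#' Nominal geometry of the two array families: a perimodiolar-style array
#' with 16 contacts covering about 420 degrees and a lateral-wall style
#' array with 20 contacts covering about 450 degrees; contact spacing is
#' uniform in arc length and one contact diameter applies per model.
#'
#' @return Named list of model definitions.
#' @export
electrode_models <- function() {
  list(midscala_like = list(n_electrodes = 16L, span_deg = 420, contact_diameter = 0.5),
       evo_like      = list(n_electrodes = 20L, span_deg = 450, contact_diameter = 0.5))
}

#' Electrode-array record
#'
#' @param centers Ordered n x 3 matrix of electrode centers (mm), most basal
#'   first.
#' @param contact_diameter Contact diameter in mm.
#' @param model_name Model label.
#' @return Object of class `electrode_array`.
#' @export
electrode_array <- function(centers, contact_diameter, model_name = "custom") {
  centers <- as_point_matrix(centers, "centers")
  if (nrow(centers) < 2L) stop("an electrode array needs at least 2 contacts")
  gaps <- row_norms(diff(centers))
  if (any(gaps <= 0)) stop("consecutive electrode centers must be separated by > 0 mm")
  if (!is.finite(contact_diameter) || contact_diameter <= 0)
    stop("contact_diameter must be > 0")
  structure(list(centers = centers, contact_diameter = contact_diameter,
                 model_name = model_name, n_electrodes = nrow(centers)),
            class = "electrode_array")
}

#' Translocation scenario specification
#'
#' `proximal_crossing` reproduces the pattern where the array crosses the
#' middle plane of the cochlear duct near 180 degrees and then stays in the
#' scala vestibuli; `distal_bending` the pattern where, beyond 300 degrees,
#' the array bends upward against the membrane and stays in an intermediate
#' position.
#'
#' @param pattern One of `"none"`, `"proximal_crossing"`, `"distal_bending"`.
#' @param onset_angle Degrees at which the pattern begins (ignored for
#'   `"none"`). Proximal onsets must fall within `proximal_window` of 180.
#' @param end_state `"scala_vestibuli"` or `"intermediate"`; defaults match
#'   the observed patterns (proximal ends in SV, distal stays intermediate).
#' @param proximal_window Allowed half-width (degrees) around 180 for
#'   proximal onsets.
#' @return Object of class `translocation_spec`.
#' @export
translocation_spec <- function(pattern = c("none", "proximal_crossing", "distal_bending"),
                               onset_angle = NULL, end_state = NULL,
                               proximal_window = 40) {
  pattern <- match.arg(pattern)
  if (pattern == "none")
    return(structure(list(pattern = pattern, onset_angle = NA_real_,
                          end_state = NA_character_), class = "translocation_spec"))
  if (is.null(onset_angle))
    onset_angle <- if (pattern == "proximal_crossing") 180 else 310
  if (pattern == "proximal_crossing" && abs(onset_angle - 180) > proximal_window)
    stop(sprintf("proximal_crossing onset must lie within %g degrees of 180", proximal_window))
  if (pattern == "distal_bending" && onset_angle <= 300)
    stop("distal_bending onset must exceed 300 degrees")
  if (is.null(end_state))
    end_state <- if (pattern == "proximal_crossing") "scala_vestibuli" else "intermediate"
  end_state <- match.arg(end_state, c("scala_vestibuli", "intermediate"))
  structure(list(pattern = pattern, onset_angle = onset_angle, end_state = end_state),
            class = "translocation_spec")
}

# Discrete mid-line of a template with tangents and the local "up" normal
# (unit, positive z component: toward the scala vestibuli).
template_midline <- function(template) {
  g <- template$grid
  mid <- (g$n_width + 1L) %/% 2L
  pts <- template$vertices[(seq_along(g$theta_deg) - 1L) * g$n_width + mid, , drop = FALSE]
  tang <- rbind(pts[2, ] - pts[1, ], (pts[-(1:2), , drop = FALSE] - pts[seq_len(nrow(pts) - 2L), , drop = FALSE]) / 2)
  tang <- rbind(tang, pts[nrow(pts), ] - pts[nrow(pts) - 1L, ])[seq_len(nrow(pts)), , drop = FALSE]
  radial <- cbind(pts[, 1], pts[, 2], 0)
  radial <- radial / pmax(row_norms(radial), 1e-12)
  nrm <- cross3(radial, tang)
  nrm <- nrm / pmax(row_norms(nrm), 1e-12)
  flip <- nrm[, 3] < 0
  nrm[flip, ] <- -nrm[flip, ]
  arc <- c(0, cumsum(row_norms(diff(pts))))
  list(theta_deg = g$theta_deg, points = pts, normal = nrm, arc = arc)
}

#' Simulate an implanted electrode array with known scalar ground truth
#'
#' Places electrode centers along the duct mid-line, offset toward the scala
#' tympani by `clearance`, then applies the requested translocation pattern.
#' Ground-truth categories are derived from the analytically known signed
#' offsets fed through the spherical-cap coverage fraction and the fixed
#' thresholds -- never from the mesh-based classifier under test.
#'
#' @param template A `membrane_template`.
#' @param model_name One of the names of [electrode_models()].
#' @param spec A [translocation_spec()].
#' @param depth_angle Insertion depth (degrees) of the most apical contact;
#'   defaults to the model's nominal span. Must not exceed the template span.
#' @param seed Integer seed controlling placement jitter.
#' @param clearance Distance (mm) from membrane mid-surface to a correctly
#'   placed electrode center, on the scala-tympani side.
#' @param jitter_sd Isotropic Gaussian jitter (mm) on each center; realized
#'   offsets are used for the ground truth so jitter never invalidates it.
#' @return List with `array` (an `electrode_array`), `truth_calls` (factor
#'   ST/INT/SV), `angles_deg` and `signed_offsets` (mm, + toward scala
#'   vestibuli).
#' @export
synth_electrode_array <- function(template, model_name = "midscala_like",
                                  spec = translocation_spec("none"),
                                  depth_angle = NULL, seed = 1,
                                  clearance = 0.5, jitter_sd = 0.02) {
  stopifnot(inherits(template, "membrane_template"),
            inherits(spec, "translocation_spec"))
  models <- electrode_models()
  if (!model_name %in% names(models)) stop("unknown electrode model: ", model_name)
  mod <- models[[model_name]]
  if (is.null(depth_angle)) depth_angle <- mod$span_deg
  span_max <- max(template$angular_coord)
  if (depth_angle > span_max)
    stop("depth_angle exceeds the template's angular span")
  base_angle <- max(2, depth_angle - mod$span_deg)
  if (spec$pattern != "none" &&
      (spec$onset_angle <= base_angle || spec$onset_angle >= depth_angle))
    stop("onset_angle lies outside the array's angular extent")

  ml <- template_midline(template)
  s_of_theta <- stats::approxfun(ml$theta_deg, ml$arc)
  s_targets <- seq(s_of_theta(base_angle), s_of_theta(depth_angle),
                   length.out = mod$n_electrodes)
  theta_of_s <- stats::approxfun(ml$arc, ml$theta_deg)
  theta_e <- theta_of_s(s_targets)
  interp_rows <- function(m, th) {
    apply(m, 2, function(col) stats::approx(ml$theta_deg, col, xout = th)$y)
  }
  pts <- interp_rows(ml$points, theta_e)
  nrm <- interp_rows(ml$normal, theta_e)
  nrm <- nrm / row_norms(nrm)

  radius <- mod$contact_diameter / 2
  d_end <- if (identical(spec$end_state, "scala_vestibuli")) clearance else 0.26 * radius
  offset <- rep(-clearance, mod$n_electrodes)
  if (spec$pattern == "proximal_crossing") {
    offset[theta_e >= spec$onset_angle] <- d_end
  } else if (spec$pattern == "distal_bending") {
    ramp <- 25  # degrees over which the array rises against the membrane
    past <- theta_e >= spec$onset_angle
    f <- clamp((theta_e - spec$onset_angle) / ramp, 0, 1)
    offset[past] <- (-clearance + (d_end + clearance) * f[past])
  }

  centers <- pts + nrm * offset
  jitter <- matrix(0, mod$n_electrodes, 3L)
  if (jitter_sd > 0)
    jitter <- with_seed(seed, matrix(stats::rnorm(3L * mod$n_electrodes, 0, jitter_sd),
                                     ncol = 3L))
  centers <- centers + jitter
  realized <- offset + rowSums(jitter * nrm)
  truth <- classify_electrode(fraction_under(realized, radius))

  list(array = electrode_array(centers, mod$contact_diameter, model_name),
       truth_calls = truth, angles_deg = theta_e, signed_offsets = realized)
}

#' Sample cochlear dimensions from the population distribution
#'
#' Independent normal draws for A, B and H360; defaults follow the reported
#' pre-implantation population (A 9.1 +/- 0.30 mm, B 6.8 +/- 0.32 mm,
#' H360 2.8 +/- 0.21 mm). Draws incompatible with the spiral construction
#' (non-positive, or B too close to A) are resampled with bounded retries.
#'
#' @param n Number of cochleae.
#' @param mean_A,sd_A,mean_B,sd_B,mean_h360,sd_h360 Distribution parameters (mm).
#' @param seed Integer seed, or `NULL` to use the current RNG stream.
#' @param max_retries Retry bound per draw before erroring.
#' @return data.frame with columns A, B, h360.
#' @export
sample_cochlear_dims <- function(n, mean_A = 9.1, sd_A = 0.30,
                                 mean_B = 6.8, sd_B = 0.32,
                                 mean_h360 = 2.8, sd_h360 = 0.21,
                                 seed = NULL, max_retries = 100L) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  draw <- function() {
    for (k in seq_len(max_retries)) {
      A <- stats::rnorm(1, mean_A, sd_A)
      B <- stats::rnorm(1, mean_B, sd_B)
      h <- stats::rnorm(1, mean_h360, sd_h360)
      if (A > 0 && B > 0 && h > 0 && A - B > 0.5 && A > h && B > h)
        return(c(A, B, h))
    }
    stop("failed to sample valid cochlear dimensions after bounded retries")
  }
  body <- function() {
    m <- t(vapply(seq_len(n), function(i) draw(), numeric(3)))
    data.frame(A = m[, 1], B = m[, 2], h360 = m[, 3])
  }
  if (is.null(seed)) body() else with_seed(seed, body())
}

#' Generate a cohort of synthetic implanted cochleae
#'
#' Each case couples a membrane template built from sampled dimensions with
#' a simulated electrode array (model and translocation pattern assigned
#' per case), clean and noise-perturbed landmarks, and per-electrode ground
#' truth. Perimodiolar-style arrays only ever translocate proximally;
#' lateral-wall-style arrays may also show the distal bending pattern,
#' mirroring the reported behavior of the two array families.
#'
#' @inheritParams sample_cochlear_dims
#' @param n Number of cases.
#' @param noise_sd Isotropic Gaussian landmark noise sigma in mm.
#' @param seed Integer seed; the whole cohort is a pure function of it.
#' @param angular_step Mesh sampling step in degrees.
#' @param patterns Candidate patterns; per case one is drawn compatibly with
#'   the array model.
#' @return List of `synthetic_case` objects (template, landmarks_clean,
#'   landmarks_noisy, array, truth_calls, dims_truth, model_name, pattern,
#'   onset, side, case_id, seed).
#' @export
synth_cohort <- function(n, noise_sd = 0.1, seed = 1, angular_step = 5,
                         mean_A = 9.1, sd_A = 0.30, mean_B = 6.8, sd_B = 0.32,
                         mean_h360 = 2.8, sd_h360 = 0.21,
                         patterns = c("none", "proximal_crossing", "distal_bending")) {
  if (!is.numeric(n) || n < 1) stop("n must be >= 1")
  with_seed(seed, {
    dims <- sample_cochlear_dims(n, mean_A, sd_A, mean_B, sd_B, mean_h360, sd_h360)
    models <- rep(c("midscala_like", "evo_like"), length.out = n)
    lapply(seq_len(n), function(i) {
      ok <- patterns[patterns != "distal_bending" | models[i] == "evo_like"]
      pattern <- if (length(ok) == 1L) ok else sample(ok, 1L)
      onset <- switch(pattern,
                      none = NA_real_,
                      proximal_crossing = stats::runif(1, 165, 195),
                      distal_bending = stats::runif(1, 310, 380))
      side <- sample(c("right", "left"), 1L)
      turns <- stats::runif(1, 2.5, 3.0)
      params <- spiral_params_from_dims(dims$A[i], dims$B[i], dims$h360[i],
                                        turns = turns, side = side)
      tpl <- make_membrane_surface(params, angular_step = angular_step,
                                   label = sprintf("case%03d", i))
      lm <- tpl$landmarks
      lm_noisy <- unclass(lm) + matrix(stats::rnorm(12, 0, noise_sd), 4L, 3L)
      lm_noisy <- cochlear_landmarks(lm_noisy[1, ], lm_noisy[2, ], lm_noisy[3, ], lm_noisy[4, ])
      sp <- if (pattern == "none") translocation_spec("none")
            else translocation_spec(pattern, onset_angle = onset)
      sim <- synth_electrode_array(tpl, models[i], sp,
                                   seed = sample.int(.Machine$integer.max, 1L))
      structure(list(template = tpl, landmarks_clean = lm,
                     landmarks_noisy = lm_noisy, array = sim$array,
                     truth_calls = sim$truth_calls,
                     truth_angles = sim$angles_deg,
                     dims_truth = list(A = dims$A[i], B = dims$B[i],
                                       H360 = dims$h360[i]),
                     model_name = models[i], pattern = pattern, onset = onset,
                     side = side, case_id = sprintf("case%03d", i), seed = seed),
                class = "synthetic_case")
    })
  })
}
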