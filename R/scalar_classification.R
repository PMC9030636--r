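# Per-electrode scalar classification: signed distance to the registered
# membrane template, spherical-cap coverage fraction, and the fixed
# threshold rules (>=50% under -> scala tympani; >=10% and <50% ->
# intermediate; <10% -> scala vestibuli).

scalar_levels <- c("ST", "INT", "SV")

#' Signed distance from points to the membrane surface
#'
#' Distance to the nearest point on the template surface, signed positive
#' when the query lies on the scala-vestibuli side of the local tangent
#' plane (the +z-leaning side of the ribbon in the template frame). Queries
#' whose nearest surface point lies on an open boundary edge of the
#' (possibly cropped) ribbon are flagged `edge` -- the tangent-plane sign is
#' then an extrapolation beyond the segmented membrane.
#'
#' @param points 3-vector or n x 3 matrix in the template frame (mm).
#' @param template A `membrane_template` (normals oriented toward the scala
#'   vestibuli; enforced at construction and on load).
#' @return data.frame with columns `signed_distance` (mm), `angle_deg` (the
#'   angular coordinate of the nearest surface point) and `edge` (logical).
#' @export
signed_distance_to_membrane <- function(points, template) {
  stopifnot(inherits(template, "membrane_template"))
  points <- as_point_matrix(points)
  cp <- closest_point_mesh(points, template$vertices, template$faces)
  fn <- face_normals(template$vertices, template$faces)
  diff_vec <- points - cp$point
  sgn <- sign(rowSums(diff_vec * fn[cp$face, , drop = FALSE]))
  sgn[sgn == 0] <- 1  # points exactly on the surface: signed distance is 0 anyway
  ang <- rowSums(cp$bary * matrix(template$angular_coord[t(template$faces[cp$face, , drop = FALSE])],
                                  ncol = 3L, byrow = TRUE))
  edge <- on_boundary_edge(cp, template$vertices, boundary_edges(template$faces))
  data.frame(signed_distance = sgn * cp$dist, angle_deg = ang, edge = edge)
}

#' Fraction of a spherical contact lying under the membrane
#'
#' Each electrode contact is modeled as a sphere of the contact radius; the
#' membrane's local tangent plane cuts it into a spherical cap, and the
#' fraction of the sphere volume on the scala-tympani side is returned.
#' With `h` the signed distance clamped to `[-radius, radius]` and
#' `a = radius - h`, the fraction is `a^2 (3 radius - a) / (4 radius^3)`:
#' 1 when fully under (signed distance <= -radius), 1/2 at the membrane,
#' 0 when fully over.
#'
#' @param signed_d Signed distance(s), mm, positive toward scala vestibuli.
#' @param radius Contact radius, mm (> 0).
#' @return Fraction(s) in \[0, 1\], strictly decreasing in `signed_d` across
#'   `(-radius, radius)`.
#' @export
fraction_under <- function(signed_d, radius) {
  if (!is.finite(radius) || radius <= 0) stop("radius must be > 0")
  # dimensionless cap form of a^2 (3 r - a) / (4 r^3) with a = r - h:
  # exact at the anchor points h = 0, +/- r, r/2
  x <- clamp(signed_d / radius, -1, 1)
  (1 - x)^2 * (2 + x) / 4
}

#' Classify an electrode from its coverage fraction
#'
#' Threshold rules, boundaries included exactly as defined: fraction >= 0.50
#' -> `ST`; 0.10 <= fraction < 0.50 -> `INT`; fraction < 0.10 -> `SV`.
#'
#' @param fraction Coverage fraction(s) in \[0, 1\].
#' @param thresholds Named numeric `c(st = 0.5, sv = 0.10)`; `st` is the
#'   lower bound of ST, `sv` the lower bound of INT.
#' @return Factor with levels `ST`, `INT`, `SV`.
#' @export
classify_electrode <- function(fraction, thresholds = c(st = 0.5, sv = 0.10)) {
  if (any(!is.finite(fraction)) || any(fraction < 0) || any(fraction > 1))
    stop("fraction must lie in [0, 1]")
  if (!(thresholds[["sv"]] > 0 && thresholds[["sv"]] < thresholds[["st"]] &&
        thresholds[["st"]] <= 1))
    stop("thresholds must satisfy 0 < sv < st <= 1")
  out <- ifelse(fraction >= thresholds[["st"]], "ST",
                ifelse(fraction >= thresholds[["sv"]], "INT", "SV"))
  factor(out, levels = scalar_levels)
}

#' Classify every electrode of an array against a registered template
#'
#' `transform` maps the template into the case frame (the direction returned
#' by registering template landmarks to case landmarks); the array is mapped
#' into the template frame through the inverse transform, where signed
#' distances are computed, then re-expressed in case-frame millimeters by
#' the transform scale (numerically identical to transforming the template
#' forward). Spherical-cap fractions use the physical contact radius
#' `contact_diameter / 2`.
#'
#' @param array An `electrode_array` in the case frame.
#' @param template A `membrane_template`.
#' @param transform A `similarity_transform` mapping template -> case, or
#'   `NULL` when array and template already share a frame.
#' @param thresholds See [classify_electrode()].
#' @return Object of class `array_call`: `calls` (data.frame with
#'   electrode_index, angle_deg, signed_distance_mm, fraction_under,
#'   category, edge_flag), `translocated` (any SV), `first_sv_angle`
#'   (degrees, `NA` when none), `counts` per category.
#' @export
classify_array <- function(array, template, transform = NULL,
                           thresholds = c(st = 0.5, sv = 0.10)) {
  stopifnot(inherits(array, "electrode_array"), inherits(template, "membrane_template"))
  if (array$n_electrodes < 1L) stop("empty electrode array")
  centers <- array$centers
  scale_to_case <- 1
  if (!is.null(transform)) {
    centers <- apply_transform(invert_transform(transform), centers)
    scale_to_case <- transform$scale  # template-frame mm -> case-frame mm
  }
  sd_res <- signed_distance_to_membrane(centers, template)
  sd_res$signed_distance <- sd_res$signed_distance * scale_to_case
  radius <- array$contact_diameter / 2
  frac <- fraction_under(sd_res$signed_distance, radius)
  category <- classify_electrode(frac, thresholds)
  calls <- data.frame(electrode_index = seq_len(array$n_electrodes),
                      angle_deg = sd_res$angle_deg,
                      signed_distance_mm = sd_res$signed_distance,
                      fraction_under = frac,
                      category = category,
                      edge_flag = sd_res$edge)
  sv <- calls$category == "SV"
  structure(list(calls = calls,
                 translocated = any(sv),
                 first_sv_angle = if (any(sv)) min(calls$angle_deg[sv]) else NA_real_,
                 counts = table(calls$category)),
            class = "array_call")
}

#' @export
print.array_call <- function(x, ...) {
  cat(sprintf("array_call: %d electrodes (ST %d / INT %d / SV %d)\n",
              nrow(x$calls), x$counts[["ST"]], x$counts[["INT"]], x$counts[["SV"]]))
  if (x$translocated)
    cat(sprintf("  translocated; first SV call at %.0f deg\n", x$first_sv_angle))
  invisible(x)
}
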