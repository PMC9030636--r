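# Landmark-based similarity registration (4-point merge), angular cropping,
# and cloud-to-cloud distances used to validate template fit.

#' Least-squares similarity transform from corresponding landmarks
#'
#' Umeyama closed-form fit of the transform `q = s * R * p + t` minimizing
#' the sum of squared residuals over the point correspondences, with
#' `det(R) = +1` enforced (a reflection is never fitted). When only a
#' reflection explains the correspondence -- e.g. a template of the wrong
#' side -- the proper-rotation fit still succeeds but with a large residual,
#' and a chirality warning is emitted when the (rejected) reflection fit has
#' a residual below 0.1 x the rotation fit residual.
#'
#' @param source,target [cochlear_landmarks()] objects or n x 3 matrices of
#'   corresponding points (n >= 3, non-collinear).
#' @param allow_scale If `TRUE` (default) fit a similarity (uniform scale);
#'   otherwise a rigid transform with scale fixed at 1.
#' @return Object of class `similarity_transform` with fields `rotation`
#'   (3 x 3, det +1), `scale`, `translation`, `rms_residual` (mm).
#' @export
fit_landmark_transform <- function(source, target, allow_scale = TRUE) {
  X <- as_landmark_matrix(source)
  Y <- as_landmark_matrix(target)
  if (nrow(X) != nrow(Y)) stop("source and target must have the same number of points")
  n <- nrow(X)
  if (n < 3L) stop("at least 3 corresponding points are required")
  mx <- colMeans(X); my <- colMeans(Y)
  Xc <- sweep(X, 2, mx); Yc <- sweep(Y, 2, my)
  sx <- svd(Xc)$d
  sy <- svd(Yc)$d
  if (sx[2] < 1e-9 * max(sx[1], 1e-12) || sy[2] < 1e-9 * max(sy[1], 1e-12))
    stop("degenerate configuration: landmarks are collinear")

  C <- crossprod(Yc, Xc) / n           # maps source -> target
  sv <- svd(C)
  var_x <- sum(Xc^2) / n

  fit_with <- function(sgn3) {
    S <- diag(c(1, 1, sgn3))
    R <- sv$u %*% S %*% t(sv$v)
    s <- if (allow_scale) sum(sv$d * diag(S)) / var_x else 1
    t_vec <- my - s * as.vector(R %*% mx)
    res <- Y - (s * X %*% t(R) + matrix(t_vec, n, 3L, byrow = TRUE))
    list(R = R, s = s, t = t_vec, rms = sqrt(mean(rowSums(res^2))))
  }

  proper_sign <- if (det(sv$u) * det(sv$v) < 0) -1 else 1
  fit <- fit_with(proper_sign)
  refl <- fit_with(-proper_sign)
  if (refl$rms < 0.1 * fit$rms)
    warning("chirality: a reflection fits these landmarks far better; ",
            "check that the template side matches the case")
  if (fit$s <= 0) stop("non-positive fitted scale; correspondences are inconsistent")
  structure(list(rotation = fit$R, scale = fit$s, translation = fit$t,
                 rms_residual = fit$rms),
            class = "similarity_transform")
}

#' @export
print.similarity_transform <- function(x, ...) {
  ang <- acos(clamp((sum(diag(x$rotation)) - 1) / 2, -1, 1)) * 180 / pi
  cat(sprintf("similarity_transform: rotation %.2f deg, scale %.4f, |t| %.3f mm, rms %.4g mm\n",
              ang, x$scale, vnorm(x$translation), x$rms_residual))
  invisible(x)
}

#' Apply a similarity transform to points
#'
#' @param transform A `similarity_transform`.
#' @param points 3-vector or n x 3 matrix (mm); `cochlear_landmarks` are
#'   returned as landmarks.
#' @return Transformed points, same shape as the input.
#' @export
apply_transform <- function(transform, points) {
  stopifnot(inherits(transform, "similarity_transform"))
  is_lm <- inherits(points, "cochlear_landmarks")
  p <- as_point_matrix(if (is_lm) unclass(points) else points)
  out <- transform$scale * p %*% t(transform$rotation) +
    matrix(transform$translation, nrow(p), 3L, byrow = TRUE)
  if (is_lm) return(cochlear_landmarks(out[1, ], out[2, ], out[3, ], out[4, ]))
  out
}

#' Invert a similarity transform
#' @param transform A `similarity_transform`.
#' @return The inverse `similarity_transform`.
#' @export
invert_transform <- function(transform) {
  stopifnot(inherits(transform, "similarity_transform"))
  Rt <- t(transform$rotation)
  s_inv <- 1 / transform$scale
  structure(list(rotation = Rt, scale = s_inv,
                 translation = as.vector(-s_inv * Rt %*% transform$translation),
                 rms_residual = transform$rms_residual),
            class = "similarity_transform")
}

#' Compose two similarity transforms
#' @param first,second `similarity_transform`s; the result applies `first`
#'   then `second`.
#' @return The composed `similarity_transform`.
#' @export
compose_transform <- function(second, first) {
  structure(list(rotation = second$rotation %*% first$rotation,
                 scale = second$scale * first$scale,
                 translation = as.vector(second$scale * second$rotation %*% first$translation) +
                   second$translation,
                 rms_residual = NA_real_),
            class = "similarity_transform")
}

#' Apply a transform to a whole template
#' @param transform A `similarity_transform`.
#' @param template A `membrane_template`.
#' @return The transformed template (landmarks included).
#' @export
transform_template <- function(transform, template) {
  stopifnot(inherits(template, "membrane_template"))
  out <- template
  out$vertices <- apply_transform(transform, template$vertices)
  if (!is.null(template$landmarks))
    out$landmarks <- apply_transform(transform, template$landmarks)
  out$params <- NULL  # analytic parameters no longer describe the moved mesh
  out
}

#' Crop a template to an angular window
#'
#' Retains vertices whose angular coordinate lies in `[min_deg, max_deg]`;
#' faces straddling the boundary are dropped. The standard validation window
#' is 90 to 540 degrees, where membrane segmentations are reliable.
#'
#' @param template A `membrane_template`.
#' @param min_deg,max_deg Angular window in degrees, `min_deg < max_deg`.
#' @return The cropped `membrane_template` (original landmarks retained as
#'   metadata).
#' @export
crop_by_angle <- function(template, min_deg, max_deg) {
  stopifnot(inherits(template, "membrane_template"))
  if (!is.finite(min_deg) || !is.finite(max_deg) || min_deg >= max_deg)
    stop("need min_deg < max_deg")
  keep <- template$angular_coord >= min_deg & template$angular_coord <= max_deg
  if (!any(keep)) stop("empty crop: no vertices in the requested angular window")
  new_idx <- cumsum(keep)
  fkeep <- keep[template$faces[, 1]] & keep[template$faces[, 2]] & keep[template$faces[, 3]]
  faces <- matrix(new_idx[template$faces[fkeep, , drop = FALSE]], ncol = 3L)
  out <- template
  out$vertices <- template$vertices[keep, , drop = FALSE]
  out$faces <- faces
  out$angular_coord <- template$angular_coord[keep]
  if (!is.null(template$grid)) {
    gkeep <- template$grid$theta_deg >= min_deg & template$grid$theta_deg <= max_deg
    out$grid <- list(theta_deg = template$grid$theta_deg[gkeep],
                     n_width = template$grid$n_width)
  }
  out
}

#' Nearest-neighbor cloud-to-cloud distance
#'
#' For every source point, the Euclidean distance to the nearest target
#' point (default) or to the nearest point on the target surface
#' (`method = "surface"`, target must be a mesh/template). Symmetric mode
#' averages the two directional means and pools per-point distances.
#'
#' @param source Points (n x 3) or a `membrane_template` (its vertices).
#' @param target Points, or a `membrane_template` (vertices, or surface when
#'   `method = "surface"`).
#' @param direction `"source_to_target"` (default) or `"symmetric"`.
#' @param method `"points"` or `"surface"`.
#' @return Object of class `cloud_distance`: `mean`, `sd`, `max`, `per_point`
#'   (mm), `direction`.
#' @export
cloud_to_cloud_distance <- function(source, target,
                                    direction = c("source_to_target", "symmetric"),
                                    method = c("points", "surface")) {
  direction <- match.arg(direction)
  method <- match.arg(method)
  pts_of <- function(x) if (inherits(x, "membrane_template")) x$vertices else as_point_matrix(x, "cloud")
  S <- pts_of(source)
  if (nrow(S) == 0L) stop("empty source cloud")

  one_way <- function(S, target) {
    if (method == "surface") {
      if (!inherits(target, "membrane_template"))
        stop("method = 'surface' requires a membrane_template target")
      closest_point_mesh(S, target$vertices, target$faces)$dist
    } else {
      Tm <- pts_of(target)
      if (nrow(Tm) == 0L) stop("empty target cloud")
      nn_dist(S, Tm)
    }
  }

  if (direction == "source_to_target") {
    d <- one_way(S, target)
  } else {
    d1 <- one_way(S, target)
    if (method == "surface")
      stop("symmetric direction is only defined for point targets")
    d2 <- one_way(pts_of(target), source)
    d <- c(d1, d2)
  }
  structure(list(mean = mean(d), sd = stats::sd(d), max = max(d),
                 per_point = d, direction = direction),
            class = "cloud_distance")
}

# chunked brute-force nearest-neighbor distances (source rows to target set)
nn_dist <- function(S, Tm, chunk = 512L) {
  t2 <- rowSums(Tm^2)
  out <- numeric(nrow(S))
  for (start in seq(1L, nrow(S), by = chunk)) {
    idx <- start:min(start + chunk - 1L, nrow(S))
    Sc <- S[idx, , drop = FALSE]
    d2 <- outer(rowSums(Sc^2), t2, "+") - 2 * tcrossprod(Sc, Tm)
    out[idx] <- sqrt(pmax(apply(d2, 1, min), 0))
  }
  out
}
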