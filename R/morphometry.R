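# Cochlear morphometry: the distances A, B and H360, the three derived
# indices, and the construction/selection of the five-template membrane bank.

#' Measure cochlear dimensions from landmarks
#'
#' Distance A is the Euclidean distance between the round-window center and
#' the lateral wall at 180 degrees; distance B between the lateral wall at 90
#' and 270 degrees. H360, the height of the cochlea at one full turn, is a
#' plane-based measurement and is supplied as a scalar (simulator truth or a
#' user measurement).
#'
#' @param landmarks A [cochlear_landmarks()] object (or 4 x 3 matrix in the
#'   same row order).
#' @param h360 Height at 360 degrees, mm.
#' @return Object of class `cochlear_dimensions` with fields `A`, `B`, `H360`.
#'   A warning is raised (not an error) if A <= B, which is anatomically
#'   unexpected.
#' @export
measure_dimensions <- function(landmarks, h360) {
  lm <- as_landmark_matrix(landmarks)
  if (nrow(lm) != 4L) stop("expected 4 landmarks (rw_center, lw90, lw180, lw270)")
  if (!is.finite(h360) || h360 <= 0) stop("h360 must be a positive scalar (mm)")
  A <- vnorm(lm[1, ] - lm[3, ])
  B <- vnorm(lm[2, ] - lm[4, ])
  if (A < 1e-9 || B < 1e-9)
    stop("degenerate geometry: coincident landmark pair")
  if (A <= B) warning("measured A <= B; check landmark identification")
  structure(list(A = A, B = B, H360 = h360), class = "cochlear_dimensions")
}

#' Compute the three cochlear indices
#'
#' @param dims A `cochlear_dimensions` object (or list with A, B, H360 in mm).
#' @return Object of class `cochlear_indices` with `i_AH` = A x H360 (mm^2),
#'   `i_ABH` = (A x B) x H360 (mm^3) and `i_AoBH` = (A/B) x H360 (mm).
#' @export
compute_indices <- function(dims) {
  A <- dims$A; B <- dims$B; H <- dims$H360
  if (!all(is.finite(c(A, B, H))) || any(c(A, B, H) <= 0))
    stop("dimensions must be positive and finite")
  structure(list(i_AH = A * H, i_ABH = A * B * H, i_AoBH = (A / B) * H),
            class = "cochlear_indices")
}

#' Fit a normal distribution to index values
#'
#' @param values Numeric vector of index values (n >= 3).
#' @return List with `mean`, `sd`, `shapiro_p` (Shapiro-Wilk normality
#'   p-value, `NA` for degenerate constant input) and `degenerate` flag.
#' @export
fit_index_distribution <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 3L) stop("insufficient data: need at least 3 index values")
  if (!all(is.finite(values))) stop("index values must be finite")
  m <- mean(values)
  s <- stats::sd(values)
  degenerate <- s == 0
  p <- if (degenerate) NA_real_ else stats::shapiro.test(values)$p.value
  if (degenerate) warning("constant index values: sd = 0, normality test skipped")
  list(mean = m, sd = s, shapiro_p = p, degenerate = degenerate)
}

index_kind_field <- function(index_kind) {
  switch(match.arg(index_kind, c("AoBH", "AH", "ABH")),
         AoBH = "i_AoBH", AH = "i_AH", ABH = "i_ABH")
}

# nearest-without-replacement pick; ties broken toward the lower index value
pick_nearest <- function(values, target, used) {
  avail <- which(!used)
  d <- abs(values[avail] - target)
  best <- d == min(d)
  cand <- avail[best]
  cand[which.min(values[cand])]
}

#' Build the five-template membrane bank
#'
#' Fits a normal distribution to the reference index values (emulating the
#' population of pre-implantation images), computes five target quantiles,
#' and for each target picks -- without replacement, in order of target --
#' the candidate template whose index value is nearest (ties to the lower
#' index). Each pick is mirrored to provide the contralateral bank.
#'
#' @param candidates List of `membrane_template`s with `index_value` set, all
#'   of the same side; at least 5 distinct index values.
#' @param index_kind `"AoBH"` (default, the best-fit index), `"AH"` or `"ABH"`.
#' @param percentiles Five percentiles in (0, 100); default 10/30/50/70/90,
#'   the equal-mass quintile midpoints.
#' @param reference_values Index values of the reference population used to
#'   fit the Gaussian; defaults to the candidates' own index values.
#' @return Object of class `template_bank` with per-side template lists
#'   ordered by increasing index value.
#' @export
build_template_bank <- function(candidates, index_kind = "AoBH",
                                percentiles = c(10, 30, 50, 70, 90),
                                reference_values = NULL) {
  if (length(percentiles) != 5L || any(percentiles <= 0) || any(percentiles >= 100))
    stop("percentiles must be 5 values strictly inside (0, 100)")
  if (length(candidates) < 5L) stop("bank error: need at least 5 candidate templates")
  if (!all(vapply(candidates, inherits, logical(1), "membrane_template")))
    stop("candidates must be membrane_template objects")
  values <- vapply(candidates, function(t) t$index_value, numeric(1))
  if (anyNA(values)) stop("every candidate needs an index_value")
  if (length(unique(values)) < 5L)
    stop("bank error: need at least 5 distinct candidate index values")
  sides <- vapply(candidates, function(t) t$side, character(1))
  if (length(unique(sides)) != 1L) stop("candidates must all be of the same side")

  if (is.null(reference_values)) reference_values <- values
  fit <- fit_index_distribution(reference_values)
  targets <- stats::qnorm(sort(percentiles) / 100, fit$mean, fit$sd)

  used <- rep(FALSE, length(candidates))
  picks <- integer(5L)
  for (k in seq_len(5L)) {
    picks[k] <- pick_nearest(values, targets[k], used)
    used[picks[k]] <- TRUE
  }
  ord <- order(values[picks])
  picks <- picks[ord]
  native <- candidates[picks]
  mirrored <- lapply(native, mirror_template)
  bank_sides <- list()
  bank_sides[[sides[1]]] <- native
  bank_sides[[if (sides[1] == "right") "left" else "right"]] <- mirrored
  structure(list(right = bank_sides$right, left = bank_sides$left,
                 index_kind = match.arg(index_kind, c("AoBH", "AH", "ABH")),
                 percentiles = sort(percentiles), targets = targets,
                 reference_mean = fit$mean, reference_sd = fit$sd),
            class = "template_bank")
}

#' @export
print.template_bank <- function(x, ...) {
  cat(sprintf("template_bank (index %s): 5 templates per side\n", x$index_kind))
  cat(sprintf("  index values: %s\n",
              paste(sprintf("%.3f", vapply(x$right, function(t) t$index_value, numeric(1))),
                    collapse = ", ")))
  invisible(x)
}

#' Select the best-fit template for a case
#'
#' Returns the bank template (of the requested side) minimizing the absolute
#' difference to the case's index value; ties go to the lower index. Case
#' indices outside the bank's range clamp to the nearest extreme template,
#' with a warning.
#'
#' @param bank A [build_template_bank()] result.
#' @param case_index Index value of the case (same index kind as the bank).
#' @param side `"right"` or `"left"`.
#' @return The selected `membrane_template`.
#' @export
select_template <- function(bank, case_index, side = c("right", "left")) {
  stopifnot(inherits(bank, "template_bank"))
  side <- match.arg(side)
  templates <- bank[[side]]
  if (is.null(templates) || length(templates) == 0L)
    stop("bank error: no templates for side ", side)
  if (!is.finite(case_index)) stop("case_index must be finite")
  values <- vapply(templates, function(t) t$index_value, numeric(1))
  if (case_index < min(values) || case_index > max(values))
    warning("case index outside the bank range; clamping to the nearest template")
  d <- abs(values - case_index)
  best <- which(d == min(d))
  templates[[best[which.min(values[best])]]]
}
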