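# Shared fixture builders; everything is generated in code at test time.

fixture_params <- function(A = 9.1, B = 6.8, h360 = 2.8, turns = 2.75,
                           side = "right") {
  spiral_params_from_dims(A, B, h360, turns = turns, side = side)
}

fixture_template <- function(..., angular_step = 5) {
  make_membrane_surface(fixture_params(...), angular_step = angular_step)
}

# candidate templates emulating a micro-CT collection, with index values set
fixture_candidates <- function(n = 22, seed = 11) {
  dims <- sample_cochlear_dims(n, mean_A = 9.2, sd_A = 0.33, mean_B = 7.0,
                               sd_B = 0.31, mean_h360 = 2.9, sd_h360 = 0.19,
                               seed = seed)
  lapply(seq_len(n), function(i) {
    tpl <- make_membrane_surface(
      spiral_params_from_dims(dims$A[i], dims$B[i], dims$h360[i], turns = 2.75),
      label = sprintf("cand%02d", i))
    tpl$index_value <- compute_indices(
      measure_dimensions(tpl$landmarks, dims$h360[i]))$i_AoBH
    tpl
  })
}

# uniform random proper rotation from the current RNG stream
random_rotation <- function() {
  qr_dec <- qr(matrix(stats::rnorm(9), 3L))
  Q <- qr.Q(qr_dec)
  Q <- Q %*% diag(sign(diag(qr.R(qr_dec))))
  if (det(Q) < 0) Q[, 1] <- -Q[, 1]
  Q
}

random_similarity <- function() {
  structure(list(rotation = random_rotation(),
                 scale = stats::runif(1, 0.5, 2),
                 translation = stats::rnorm(3, 0, 10),
                 rms_residual = NA_real_),
            class = "similarity_transform")
}

# non-degenerate random landmark quadruple
random_quadruple <- function() {
  repeat {
    m <- matrix(stats::rnorm(12, 0, 4), 4L, 3L)
    sv <- svd(scale(m, scale = FALSE))$d
    if (sv[2] > 0.5 * sv[1] && min(dist(m)) > 0.5) return(m)
  }
}

rotation_angle_deg <- function(R) {
  # ||R - I||_F = 2 sqrt(2) sin(theta / 2): precise for tiny angles where
  # the trace/acos form loses half the floating-point digits
  fro <- sqrt(sum((R - diag(3))^2))
  2 * asin(min(1, fro / (2 * sqrt(2)))) * 180 / pi
}
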