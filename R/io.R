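# File formats: PLY/STL meshes, JSON/CSV landmark records, CSV electrode
# arrays and ratings tables, JSON transforms, YAML bank manifests.
# Units are millimeters and degrees everywhere; no unit autodetection.

#' Write a template mesh to PLY
#'
#' Vertices in mm; the per-vertex angular coordinate is stored as a custom
#' `angle_deg` property so that templates survive a round trip.
#'
#' @param template A `membrane_template` (or list with `vertices`, `faces`).
#' @param path Output path.
#' @param binary Write binary little-endian instead of ASCII.
#' @export
write_ply <- function(template, path, binary = FALSE) {
  v <- template$vertices
  f <- template$faces
  has_ang <- !is.null(template$angular_coord)
  con <- file(path, open = if (binary) "wb" else "w")
  on.exit(close(con))
  hdr <- c("ply",
           sprintf("format %s 1.0", if (binary) "binary_little_endian" else "ascii"),
           "comment scalafit membrane template",
           sprintf("element vertex %d", nrow(v)),
           "property double x", "property double y", "property double z",
           if (has_ang) "property double angle_deg",
           sprintf("element face %d", nrow(f)),
           "property list uchar int vertex_indices",
           "end_header")
  if (binary) {
    writeLines(hdr, con, sep = "\n")
    vdat <- if (has_ang) cbind(v, template$angular_coord) else v
    writeBin(as.vector(t(vdat)), con, size = 8L, endian = "little")
    for (i in seq_len(nrow(f))) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(f[i, ] - 1L), con, size = 4L, endian = "little")
    }
  } else {
    writeLines(hdr, con)
    vdat <- if (has_ang) cbind(v, template$angular_coord) else v
    writeLines(apply(format(vdat, digits = 17, scientific = FALSE, trim = TRUE),
                     1, paste, collapse = " "), con)
    writeLines(paste(3L, f[, 1] - 1L, f[, 2] - 1L, f[, 3] - 1L), con)
  }
  invisible(path)
}

#' Read a PLY template mesh
#'
#' Supports ASCII and binary little-endian files written by [write_ply()]
#' (double x/y/z and optional `angle_deg` vertex properties, uchar/int face
#' lists). The ring grid is reconstructed when the angular coordinate forms
#' constant-angle runs of equal width; normals are re-oriented toward the
#' scala vestibuli on load.
#'
#' @param path PLY file path.
#' @param side,label Template metadata not stored in PLY.
#' @return A `membrane_template`.
#' @export
read_ply <- function(path, side = "right", label = basename(path)) {
  con <- file(path, open = "rb")
  on.exit(close(con))
  hdr <- character()
  repeat {
    line <- readLines(con, n = 1L)
    if (!length(line)) stop("malformed PLY: no end_header")
    hdr <- c(hdr, line)
    if (line == "end_header") break
  }
  fmt <- sub("^format ", "", grep("^format ", hdr, value = TRUE))
  binary <- startsWith(fmt, "binary_little_endian")
  nv <- as.integer(sub("^element vertex ", "", grep("^element vertex ", hdr, value = TRUE)))
  nf <- as.integer(sub("^element face ", "", grep("^element face ", hdr, value = TRUE)))
  vert_block <- hdr[seq(which(grepl("^element vertex", hdr)) + 1L, length(hdr))]
  vert_props <- sub("^property \\S+ ", "",
                    vert_block[cumsum(grepl("^element", vert_block)) == 0 &
                               grepl("^property", vert_block)])
  np <- length(vert_props)
  if (!all(c("x", "y", "z") %in% vert_props)) stop("PLY lacks x/y/z vertex properties")

  if (binary) {
    vdat <- matrix(readBin(con, "double", n = nv * np, size = 8L, endian = "little"),
                   ncol = np, byrow = TRUE)
    faces <- matrix(0L, nf, 3L)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, "raw", n = 1L))
      idx <- readBin(con, "integer", n = cnt, size = 4L, endian = "little")
      if (cnt != 3L) stop("only triangle faces are supported")
      faces[i, ] <- idx + 1L
    }
  } else {
    txt <- readLines(con)
    vdat <- matrix(as.numeric(unlist(strsplit(trimws(txt[seq_len(nv)]), "\\s+"))),
                   ncol = np, byrow = TRUE)
    frows <- strsplit(trimws(txt[nv + seq_len(nf)]), "\\s+")
    faces <- t(vapply(frows, function(r) {
      r <- as.integer(r)
      if (r[1] != 3L) stop("only triangle faces are supported")
      r[2:4] + 1L
    }, integer(3)))
  }
  colnames(vdat) <- vert_props
  vertices <- vdat[, c("x", "y", "z"), drop = FALSE]
  dimnames(vertices) <- NULL
  ang <- if ("angle_deg" %in% vert_props) vdat[, "angle_deg"] else NULL
  faces <- orient_faces_up(vertices, faces)

  grid <- NULL
  if (!is.null(ang)) {
    r <- rle(ang)
    if (length(unique(r$lengths)) == 1L && r$lengths[1] >= 3L && r$lengths[1] %% 2L == 1L)
      grid <- list(theta_deg = r$values, n_width = r$lengths[1])
  }
  tpl <- structure(list(vertices = vertices, faces = faces, angular_coord = ang,
                        grid = grid, landmarks = NULL, index_value = NA_real_,
                        side = side, label = label, params = NULL),
                   class = "membrane_template")
  if (!is.null(grid) && grid$theta_deg[1] <= 1e-9 && max(grid$theta_deg) >= 270)
    tpl$landmarks <- extract_landmarks(tpl)
  tpl
}

#' Write a mesh to ASCII STL
#' @param template A `membrane_template`.
#' @param path Output path.
#' @export
write_stl <- function(template, path) {
  v <- template$vertices
  f <- template$faces
  n <- face_normals(v, f)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("solid %s", gsub("\\s+", "_", template$label %||% "mesh")), con)
  fmt <- function(p) paste(format(p, digits = 17, scientific = FALSE, trim = TRUE), collapse = " ")
  for (i in seq_len(nrow(f))) {
    writeLines(c(sprintf("  facet normal %s", fmt(n[i, ])),
                 "    outer loop",
                 sprintf("      vertex %s", fmt(v[f[i, 1], ])),
                 sprintf("      vertex %s", fmt(v[f[i, 2], ])),
                 sprintf("      vertex %s", fmt(v[f[i, 3], ])),
                 "    endloop",
                 "  endfacet"), con)
  }
  writeLines("endsolid", con)
  invisible(path)
}

#' @rdname landmark_io
#' @export
write_landmarks_json <- function(landmarks, path) {
  lm <- as_landmark_matrix(landmarks)
  jsonlite::write_json(list(rw_center = lm[1, ], lw90 = lm[2, ],
                            lw180 = lm[3, ], lw270 = lm[4, ]),
                       path, digits = NA)
  invisible(path)
}

#' Landmark record IO
#'
#' JSON records (`{"rw_center":[x,y,z], ...}`) and 4-row CSV
#' (`name,x,y,z`), coordinates in mm.
#'
#' @param landmarks A [cochlear_landmarks()] object.
#' @param path File path.
#' @name landmark_io
#' @export
read_landmarks_json <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  need <- c("rw_center", "lw90", "lw180", "lw270")
  if (!all(need %in% names(rec)))
    stop("landmark JSON must contain fields: ", paste(need, collapse = ", "))
  cochlear_landmarks(rec$rw_center, rec$lw90, rec$lw180, rec$lw270)
}

#' @rdname landmark_io
#' @export
write_landmarks_csv <- function(landmarks, path) {
  lm <- as_landmark_matrix(landmarks)
  utils::write.csv(data.frame(name = c("rw_center", "lw90", "lw180", "lw270"),
                              x = lm[, 1], y = lm[, 2], z = lm[, 3]),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname landmark_io
#' @export
read_landmarks_csv <- function(path) {
  if (!file.exists(path)) stop("landmark file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("name", "x", "y", "z")
  if (!all(need %in% names(df))) stop("landmark CSV needs columns name,x,y,z")
  rownames(df) <- df$name
  get <- function(nm) {
    if (!nm %in% df$name) stop("landmark CSV missing row: ", nm)
    as.numeric(df[nm, c("x", "y", "z")])
  }
  cochlear_landmarks(get("rw_center"), get("lw90"), get("lw180"), get("lw270"))
}

#' Electrode-array CSV IO
#'
#' Columns `electrode_index,x,y,z,diameter_mm`, most basal row first.
#'
#' @param array An `electrode_array`.
#' @param path File path.
#' @param model_name Model label for the loaded array.
#' @name array_io
#' @export
write_array_csv <- function(array, path) {
  utils::write.csv(data.frame(electrode_index = seq_len(array$n_electrodes),
                              x = array$centers[, 1], y = array$centers[, 2],
                              z = array$centers[, 3],
                              diameter_mm = array$contact_diameter),
                   path, row.names = FALSE)
  invisible(path)
}

#' @rdname array_io
#' @export
read_array_csv <- function(path, model_name = "custom") {
  if (!file.exists(path)) stop("array file not found: ", path)
  df <- utils::read.csv(path)
  need <- c("electrode_index", "x", "y", "z", "diameter_mm")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("array CSV missing columns: ", paste(miss, collapse = ", "))
  df <- df[order(df$electrode_index), ]
  electrode_array(as.matrix(df[, c("x", "y", "z")]),
                  contact_diameter = df$diameter_mm[1], model_name = model_name)
}

#' Ratings CSV IO
#'
#' Long format: columns `electrode_id,rater_id,category`. Wide format:
#' `electrode_id` plus one column per rater. Categories are validated
#' against `ST`/`INT`/`SV`.
#'
#' @param path File path.
#' @param format `"auto"`, `"long"` or `"wide"`.
#' @param categories Valid labels.
#' @return A [rater_table()].
#' @export
read_ratings_csv <- function(path, format = c("auto", "long", "wide"),
                             categories = c("ST", "INT", "SV")) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("ratings file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  is_long <- all(c("electrode_id", "rater_id", "category") %in% names(df))
  if (format == "long" || (format == "auto" && is_long))
    return(rater_table_from_long(df, categories))
  if (!"electrode_id" %in% names(df))
    stop("wide ratings CSV needs an electrode_id column plus one column per rater")
  long <- data.frame(
    electrode_id = rep(df$electrode_id, times = ncol(df) - 1L),
    rater_id = rep(setdiff(names(df), "electrode_id"), each = nrow(df)),
    category = unlist(df[setdiff(names(df), "electrode_id")], use.names = FALSE))
  rater_table_from_long(long, categories)
}

#' @rdname read_ratings_csv
#' @param ratings Long-format data.frame to write.
#' @export
write_ratings_csv <- function(ratings, path) {
  utils::write.csv(ratings, path, row.names = FALSE)
  invisible(path)
}

#' Transform JSON IO
#'
#' `{"rotation": 9 values row-major, "scale": s, "translation": [x,y,z],
#' "rms_residual_mm": r}`.
#'
#' @param transform A `similarity_transform`.
#' @param path File path.
#' @name transform_io
#' @export
write_transform_json <- function(transform, path) {
  jsonlite::write_json(list(rotation = as.vector(t(transform$rotation)),
                            scale = transform$scale,
                            translation = as.vector(transform$translation),
                            rms_residual_mm = transform$rms_residual),
                       path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname transform_io
#' @export
read_transform_json <- function(path) {
  if (!file.exists(path)) stop("transform file not found: ", path)
  rec <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(rotation = matrix(rec$rotation, 3L, 3L, byrow = TRUE),
                 scale = rec$scale, translation = rec$translation,
                 rms_residual = rec$rms_residual_mm %||% NA_real_),
            class = "similarity_transform")
}

#' Write a template bank to disk
#'
#' One PLY mesh and one JSON landmark record per template, indexed by a YAML
#' manifest listing path, landmark path, index value and side.
#'
#' @param bank A `template_bank`.
#' @param dir Output directory (created if needed).
#' @param binary Write binary PLY meshes.
#' @return Path of the manifest.
#' @export
write_bank <- function(bank, dir, binary = FALSE) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  entries <- list()
  for (side in c("right", "left")) {
    for (i in seq_along(bank[[side]])) {
      tpl <- bank[[side]][[i]]
      stem <- sprintf("template_%s_%d", side, i)
      mesh_path <- file.path(dir, paste0(stem, ".ply"))
      lm_path <- file.path(dir, paste0(stem, "_landmarks.json"))
      write_ply(tpl, mesh_path, binary = binary)
      write_landmarks_json(tpl$landmarks, lm_path)
      entries[[length(entries) + 1L]] <-
        list(mesh = basename(mesh_path), landmarks = basename(lm_path),
             index_value = tpl$index_value, side = side, label = tpl$label)
    }
  }
  manifest <- file.path(dir, "bank.yaml")
  yaml::write_yaml(list(index_kind = bank$index_kind,
                        percentiles = bank$percentiles,
                        reference_mean = bank$reference_mean,
                        reference_sd = bank$reference_sd,
                        templates = entries), manifest)
  invisible(manifest)
}

#' Read a template bank manifest
#' @param manifest Path to `bank.yaml`.
#' @return A `template_bank`.
#' @export
read_bank <- function(manifest) {
  if (!file.exists(manifest)) stop("bank manifest not found: ", manifest)
  rec <- yaml::read_yaml(manifest)
  dir <- dirname(manifest)
  sides <- list(right = list(), left = list())
  for (e in rec$templates) {
    tpl <- read_ply(file.path(dir, e$mesh), side = e$side, label = e$label)
    tpl$landmarks <- read_landmarks_json(file.path(dir, e$landmarks))
    tpl$index_value <- e$index_value
    sides[[e$side]][[length(sides[[e$side]]) + 1L]] <- tpl
  }
  for (s in names(sides)) {
    ord <- order(vapply(sides[[s]], function(t) t$index_value, numeric(1)))
    sides[[s]] <- sides[[s]][ord]
  }
  structure(list(right = sides$right, left = sides$left,
                 index_kind = rec$index_kind, percentiles = rec$percentiles,
                 targets = NULL, reference_mean = rec$reference_mean,
                 reference_sd = rec$reference_sd),
            class = "template_bank")
}
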