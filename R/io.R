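#' Read and write triangle meshes as PLY
#'
#' Binary little-endian PLY by default (`format = "ascii"` for text);
#' [read_ply()] accepts both.
#'
#' @param mesh a [trimesh].
#' @param path output file path.
#' @param format `"binary"` or `"ascii"`.
#' @export
write_ply <- function(mesh, path, format = c("binary", "ascii")) {
  format <- match.arg(format)
  nv <- nrow(mesh$vertices)
  nf <- nrow(mesh$faces)
  fmt_line <- if (format == "binary") "format binary_little_endian 1.0"
              else "format ascii 1.0"
  header <- c("ply", fmt_line,
              sprintf("element vertex %d", nv),
              "property float x", "property float y", "property float z",
              sprintf("element face %d", nf),
              "property list uchar int vertex_indices", "end_header")
  if (format == "ascii") {
    con <- file(path, "w")
    on.exit(close(con))
    writeLines(header, con)
    utils::write.table(format(mesh$vertices, digits = 9, trim = TRUE,
                              scientific = FALSE),
                       con, row.names = FALSE, col.names = FALSE,
                       quote = FALSE)
    utils::write.table(cbind(3L, mesh$faces - 1L), con, row.names = FALSE,
                       col.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "wb")
    on.exit(close(con))
    writeLines(header, con)
    writeBin(as.numeric(t(mesh$vertices)), con, size = 4, endian = "little")
    fb <- t(cbind(mesh$faces[, 1] - 1L, mesh$faces[, 2] - 1L,
                  mesh$faces[, 3] - 1L))
    for (i in seq_len(nf)) {
      writeBin(as.raw(3L), con)
      writeBin(as.integer(fb[, i]), con, size = 4, endian = "little")
    }
  }
  invisible(path)
}

#' @rdname write_ply
#' @return [read_ply()] returns a [trimesh].
#' @export
read_ply <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  header <- character(0)
  repeat {
    line <- readLines(con, n = 1)
    header <- c(header, line)
    if (line == "end_header") break
    if (length(header) > 100) stop("malformed PLY header")
  }
  fmt <- header[grepl("^format", header)]
  nv <- as.integer(sub("element vertex ", "", header[grepl("^element vertex", header)]))
  nf <- as.integer(sub("element face ", "", header[grepl("^element face", header)]))
  if (grepl("ascii", fmt)) {
    lines <- readLines(con)
    vv <- utils::read.table(text = lines[seq_len(nv)])
    ff <- utils::read.table(text = lines[nv + seq_len(nf)])
    trimesh(unname(as.matrix(vv[, 1:3])), unname(as.matrix(ff[, 2:4])) + 1L)
  } else if (grepl("binary_little_endian", fmt)) {
    v <- readBin(con, numeric(), n = 3 * nv, size = 4, endian = "little")
    f <- matrix(0L, nf, 3)
    for (i in seq_len(nf)) {
      cnt <- as.integer(readBin(con, raw(), n = 1))
      idx <- readBin(con, integer(), n = cnt, size = 4, endian = "little")
      f[i, ] <- idx[1:3] + 1L
    }
    trimesh(matrix(v, ncol = 3, byrow = TRUE), f)
  } else stop("unsupported PLY format: ", fmt)
}

#' Read and write meshes as Wavefront OBJ
#' @inheritParams write_ply
#' @export
write_obj <- function(mesh, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("v %.9g %.9g %.9g", mesh$vertices[, 1],
                     mesh$vertices[, 2], mesh$vertices[, 3]), con)
  writeLines(sprintf("f %d %d %d", mesh$faces[, 1], mesh$faces[, 2],
                     mesh$faces[, 3]), con)
  invisible(path)
}

#' @rdname write_obj
#' @export
read_obj <- function(path) {
  lines <- readLines(path)
  vl <- lines[startsWith(lines, "v ")]
  fl <- lines[startsWith(lines, "f ")]
  v <- utils::read.table(text = vl)[, 2:4]
  fparts <- lapply(strsplit(sub("^f ", "", fl), "\\s+"), function(p)
    as.integer(sub("/.*", "", p[1:3])))
  trimesh(unname(as.matrix(v)), do.call(rbind, fparts))
}

#' Read and write landmark tables
#'
#' CSV with columns `landmark_name, x, y, z`; the four cutting stations
#' appear as pseudo-landmarks named `rump_plane`, `abdomen_station`,
#' `chest_station`, `shoulder_plane`.
#'
#' @param fp a [feature_points] object.
#' @param path CSV path.
#' @export
write_landmarks <- function(fp, path) {
  m <- rbind(fp$landmarks, fp$stations)
  df <- data.frame(landmark_name = rownames(m), x = m[, 1], y = m[, 2],
                   z = m[, 3])
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_landmarks
#' @return [read_landmarks()] returns a [feature_points] object.
#' @export
read_landmarks <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  st_names <- c("rump_plane", "abdomen_station", "chest_station",
                "shoulder_plane")
  is_st <- df$landmark_name %in% st_names
  lm <- as.matrix(df[!is_st, c("x", "y", "z")])
  rownames(lm) <- df$landmark_name[!is_st]
  st <- as.matrix(df[is_st, c("x", "y", "z")])
  rownames(st) <- df$landmark_name[is_st]
  feature_points(lm, st)
}

#' Read and write long-format measurement tables
#' @param table a [measurement_table()].
#' @param path CSV path.
#' @export
write_measurements <- function(table, path) {
  utils::write.csv(as.data.frame(table), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_measurements
#' @export
read_measurements <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  measurement_table(df$subject_id, df$session, df$rep, df$trait, df$value,
                    df$unit)
}

#' Write a depth map as 16-bit PGM in millimeters
#'
#' P5 binary PGM, big-endian 16-bit samples, value = depth in mm (rounded),
#' 0 marks invalid pixels.
#'
#' @param d a `depth_map`.
#' @param path output path.
#' @export
write_depth_pgm <- function(d, path) {
  z <- round(d$depth * 1000)
  z[!is.finite(z)] <- 0
  z[z < 0] <- 0
  z[z > 65535] <- 65535
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c("P5", sprintf("%d %d", ncol(z), nrow(z)), "65535"), con)
  writeBin(as.integer(t(z)), con, size = 2, endian = "big")
  invisible(path)
}

#' @rdname write_depth_pgm
#' @return [read_depth_pgm()] returns a depth matrix in meters with NA for
#'   invalid pixels.
#' @export
read_depth_pgm <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  magic <- readLines(con, n = 1)
  if (magic != "P5") stop("not a binary PGM")
  dims <- scan(text = readLines(con, n = 1), quiet = TRUE)
  maxv <- scan(text = readLines(con, n = 1), quiet = TRUE)
  if (maxv != 65535) stop("expected 16-bit PGM")
  raw <- readBin(con, integer(), n = dims[1] * dims[2], size = 2,
                 endian = "big", signed = FALSE)
  z <- matrix(raw, nrow = dims[2], ncol = dims[1], byrow = TRUE) / 1000
  z[z == 0] <- NA_real_
  z
}

# rotation matrix <-> quaternion (w, x, y, z), w >= 0
rotation_to_quaternion <- function(R) {
  tr <- sum(diag(R))
  if (tr > 0) {
    s <- sqrt(tr + 1) * 2
    q <- c(0.25 * s, (R[3, 2] - R[2, 3]) / s, (R[1, 3] - R[3, 1]) / s,
           (R[2, 1] - R[1, 2]) / s)
  } else {
    i <- which.max(diag(R))
    j <- i %% 3 + 1; k <- j %% 3 + 1
    s <- sqrt(R[i, i] - R[j, j] - R[k, k] + 1) * 2
    q <- numeric(4)
    q[1] <- (R[k, j] - R[j, k]) / s
    q[i + 1] <- 0.25 * s
    q[j + 1] <- (R[j, i] + R[i, j]) / s
    q[k + 1] <- (R[k, i] + R[i, k]) / s
  }
  if (q[1] < 0) q <- -q
  q / sqrt(sum(q^2))
}

quaternion_to_rotation <- function(q) {
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y + w * z), 2 * (x * z - w * y),
    2 * (x * y - w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z + w * x),
    2 * (x * z + w * y), 2 * (y * z - w * x), 1 - 2 * (x^2 + y^2)), 3, 3)
}

#' Write and read a camera rig as YAML
#'
#' Per camera: intrinsics, image size, depth range, quantization/noise,
#' pose as translation plus unit quaternion `(w, x, y, z)` rotating
#' camera-frame vectors into the world frame (Hamilton convention,
#' `w >= 0`).
#'
#' @param rig a `rig_config`.
#' @param path YAML path.
#' @export
write_rig_yaml <- function(rig, path) {
  cams <- lapply(rig$cameras, function(c_) list(
    fx = c_$fx, fy = c_$fy, cx = c_$cx, cy = c_$cy,
    width = c_$width, height = c_$height,
    min_depth = c_$min_depth, max_depth = c_$max_depth,
    quant_step = c_$quant_step, noise_sd = c_$noise_sd,
    translation = as.numeric(c_$translation),
    quaternion_wxyz = as.numeric(rotation_to_quaternion(c_$rotation))))
  yaml::write_yaml(list(reference_camera = rig$reference_camera,
                        cameras = cams), path, precision = 15)
  invisible(path)
}

#' @rdname write_rig_yaml
#' @export
read_rig_yaml <- function(path) {
  y <- yaml::read_yaml(path)
  cams <- lapply(y$cameras, function(c_) camera_model(
    fx = c_$fx, fy = c_$fy, cx = c_$cx, cy = c_$cy, width = c_$width,
    height = c_$height,
    rotation = quaternion_to_rotation(unlist(c_$quaternion_wxyz)),
    translation = unlist(c_$translation), min_depth = c_$min_depth,
    max_depth = c_$max_depth, quant_step = c_$quant_step,
    noise_sd = c_$noise_sd))
  structure(list(cameras = cams, reference_camera = y$reference_camera),
            class = "rig_config")
}
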