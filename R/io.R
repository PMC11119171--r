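#' Read an ASCII PLY point cloud
#'
#' Minimal PLY reader for vertex x/y/z properties (plus any extra scalar
#' properties, which are returned as additional columns). Coordinates are
#' interpreted as millimetres. Only `format ascii 1.0` is supported.
#'
#' @param path Path to a .ply file.
#' @return Nx3 numeric matrix (columns x, y, z); extra vertex properties, if
#'   present, are attached as attribute `"extra"` (a data.frame).
#' @export
read_ply <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (length(lines) == 0 || trimws(lines[1]) != "ply")
    stop("not a PLY file: ", path)
  end_hdr <- match("end_header", trimws(lines))
  if (is.na(end_hdr)) stop("PLY header not terminated")
  hdr <- trimws(lines[seq_len(end_hdr)])
  fmt <- grep("^format ", hdr, value = TRUE)
  if (!length(fmt) || !grepl("ascii", fmt[1]))
    stop("only ASCII PLY is supported")
  vline <- grep("^element vertex ", hdr, value = TRUE)
  if (!length(vline)) stop("PLY has no vertex element")
  n <- as.integer(strsplit(vline[1], "\\s+")[[1]][3])
  # property lines between 'element vertex' and the next element (or end)
  vidx <- grep("^element vertex ", hdr)[1]
  rest <- hdr[(vidx + 1):length(hdr)]
  stop_at <- grep("^element ", rest)
  if (length(stop_at)) rest <- rest[seq_len(stop_at[1] - 1)]
  props <- sub("^property\\s+\\S+\\s+", "", grep("^property ", rest, value = TRUE))
  if (!all(c("x", "y", "z") %in% props))
    stop("PLY vertex element lacks x/y/z properties")
  body <- lines[(end_hdr + 1):length(lines)]
  body <- body[nzchar(trimws(body))][seq_len(n)]
  vals <- matrix(scan(text = body, quiet = TRUE), nrow = n,
                 ncol = length(props), byrow = TRUE)
  colnames(vals) <- props
  pts <- vals[, c("x", "y", "z"), drop = FALSE]
  extra <- setdiff(props, c("x", "y", "z"))
  if (length(extra))
    attr(pts, "extra") <- as.data.frame(vals[, extra, drop = FALSE])
  pts
}

#' Write an ASCII PLY point cloud
#'
#' @param points Nx3 matrix (mm).
#' @param path Output path.
#' @export
write_ply <- function(points, path) {
  points <- as_points3(points)
  hdr <- c("ply", "format ascii 1.0",
           sprintf("element vertex %d", nrow(points)),
           "property float x", "property float y", "property float z",
           "end_header")
  body <- apply(points, 1, function(p) paste(format(p, digits = 10), collapse = " "))
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read / write camera calibration JSON
#'
#' Calibration schema: `{"pv": {"fx","fy","cx","cy","R" (9, row-major),
#' "t" (3)}, "depth": {"R","t"}, "image_size": [w,h]}`, extrinsics mapping
#' world -> camera, translations in mm.
#'
#' @param path Path to a calibration JSON file.
#' @return A [camera_rig()].
#' @export
read_camera_rig <- function(path) {
  j <- jsonlite::fromJSON(path)
  rot <- function(v) matrix(as.numeric(v), 3, 3, byrow = TRUE)
  camera_rig(
    pv_intrinsics = camera_intrinsics(j$pv$fx, j$pv$fy, j$pv$cx, j$pv$cy),
    pv_extrinsics = rigid_transform(rot(j$pv$R), as.numeric(j$pv$t)),
    depth_extrinsics = rigid_transform(rot(j$depth$R), as.numeric(j$depth$t)),
    image_size = as.integer(j$image_size))
}

#' @rdname read_camera_rig
#' @param rig A `camera_rig`.
#' @export
write_camera_rig <- function(rig, path) {
  stopifnot(inherits(rig, "camera_rig"))
  K <- rig$pv_intrinsics
  j <- list(
    pv = list(fx = K$fx, fy = K$fy, cx = K$cx, cy = K$cy,
              R = as.numeric(t(rig$pv_extrinsics$R)), t = rig$pv_extrinsics$t),
    depth = list(R = as.numeric(t(rig$depth_extrinsics$R)),
                 t = rig$depth_extrinsics$t),
    image_size = rig$image_size)
  jsonlite::write_json(j, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write a similarity transform JSON
#'
#' Schema: `{"s": scale, "R": 9 numbers row-major, "t": 3 numbers (mm)}`.
#'
#' @param path JSON path.
#' @return A [similarity_transform()].
#' @export
read_similarity <- function(path) {
  j <- jsonlite::fromJSON(path)
  similarity_transform(j$s, matrix(as.numeric(j$R), 3, 3, byrow = TRUE),
                       as.numeric(j$t))
}

#' @rdname read_similarity
#' @param T A `similarity_transform`.
#' @export
write_similarity <- function(T, path) {
  stopifnot(inherits(T, "similarity_transform"))
  jsonlite::write_json(list(s = T$s, R = as.numeric(t(T$R)), t = T$t),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read / write needle poses JSON
#'
#' Poses are stored as an array of records
#' `{base, tip, direction, length, n_inliers, residual_rms}`.
#'
#' @param poses A list of [needle_pose()] objects (diagnostic attributes
#'   `n_inliers` / `residual_rms` are written when present).
#' @param path JSON path.
#' @export
write_poses <- function(poses, path) {
  if (inherits(poses, "needle_pose")) poses <- list(poses)
  recs <- lapply(poses, function(p) {
    list(base = p$base, tip = p$tip, direction = p$direction,
         length = p$length,
         n_inliers = attr(p, "n_inliers"),
         residual_rms = attr(p, "residual_rms"))
  })
  jsonlite::write_json(recs, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' @rdname write_poses
#' @export
read_poses <- function(path) {
  j <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  lapply(j, function(r) {
    p <- needle_pose(as.numeric(r$base), as.numeric(r$direction), r$length)
    attr(p, "n_inliers") <- r$n_inliers
    attr(p, "residual_rms") <- r$residual_rms
    p
  })
}

#' Read / write a marker correspondence table
#'
#' CSV with columns `id, frame, x, y, z`; `frame` labels the coordinate
#' system each point lives in (e.g. "virtual" vs "physical").
#'
#' @param path CSV path.
#' @return data.frame with those columns.
#' @export
read_markers <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "frame", "x", "y", "z")
  if (!all(need %in% names(df)))
    stop("marker CSV must have columns: ", paste(need, collapse = ", "))
  df
}

#' @rdname read_markers
#' @param markers data.frame with columns id, frame, x, y, z.
#' @export
write_markers <- function(markers, path) {
  utils::write.csv(markers, path, row.names = FALSE)
  invisible(path)
}

#' Extract one frame's marker set from a marker table
#'
#' @param markers data.frame from [read_markers()].
#' @param frame Frame label to extract.
#' @return Named Nx3 matrix (rownames = marker ids).
#' @export
marker_set <- function(markers, frame) {
  sel <- markers[markers$frame == frame, , drop = FALSE]
  if (nrow(sel) == 0) stop("no markers with frame label '", frame, "'")
  m <- as.matrix(sel[, c("x", "y", "z")])
  rownames(m) <- as.character(sel$id)
  if (anyDuplicated(rownames(m))) stop("duplicate marker ids in frame '", frame, "'")
  m
}

#' Read / write a greyscale or RGB PNG image
#'
#' Images are numeric matrices in \[0, 1\], rows = image rows (v), columns =
#' image columns (u). RGB PNGs are converted to luminance on read.
#'
#' @param path PNG path.
#' @return Numeric matrix in \[0, 1\].
#' @export
read_image <- function(path) {
  a <- png::readPNG(path)
  if (length(dim(a)) == 3) {
    # luminance (Rec. 601) over the first three channels
    a <- 0.299 * a[, , 1] + 0.587 * a[, , 2] + 0.114 * a[, , 3]
  }
  a
}

#' @rdname read_image
#' @param image Numeric matrix in \[0,1\] (or logical mask).
#' @export
write_image <- function(image, path) {
  m <- pmin(pmax(image * 1.0, 0), 1)
  png::writePNG(m, path)
  invisible(path)
}
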