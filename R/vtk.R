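# VTK legacy ASCII unstructured-grid serialization of structured geometries.
# The grid (including void voxels outside a shell wall) is written as
# quad/hexahedron cells with CELL_DATA arrays region_label, segment_id,
# fiber_angle and tissue_mask; the title line carries the structured-grid
# metadata needed to rebuild the ventricle_geometry on read.

#' Write a geometry to a VTK legacy ASCII file
#'
#' @param geom a `ventricle_geometry`.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_geometry <- function(geom, path) {
  stopifnot(inherits(geom, "ventricle_geometry"))
  d <- geom$dims
  is3d <- length(d) == 3
  nx <- d[["nx"]]; ny <- d[["ny"]]; nz <- if (is3d) d[["nz"]] else 1L
  sp <- geom$spacing
  # grid-corner origin so that element centres match geom$centers
  org <- geom$centers[1, ] - sp / 2
  con <- file(path, "w")
  on.exit(close(con))
  w <- function(...) writeLines(sprintf(...), con)
  w("# vtk DataFile Version 3.0")
  w("reentryforge %s nx=%d ny=%d nz=%d spacing=%.17g ox=%.17g oy=%.17g oz=%.17g",
    geom$kind, nx, ny, nz, sp, org[1], org[2],
    if (is3d) org[3] else 0)
  w("ASCII")
  w("DATASET UNSTRUCTURED_GRID")
  px <- nx + 1L; py <- ny + 1L; pz <- if (is3d) nz + 1L else 1L
  npts <- px * py * pz
  w("POINTS %d double", npts)
  gx <- org[1] + (0:nx) * sp
  gy <- org[2] + (0:ny) * sp
  gz <- if (is3d) (geom$centers[1, 3] + sp / 2) - (0:nz) * sp else 0
  # points in x-fastest order
  if (is3d) {
    pts <- cbind(rep(gx, times = py * pz),
                 rep(rep(gy, each = px), times = pz),
                 rep(gz, each = px * py))
  } else {
    pts <- cbind(rep(gx, times = py), rep(gy, each = px), 0)
  }
  writeLines(sprintf("%.17g %.17g %.17g", pts[, 1], pts[, 2], pts[, 3]), con)
  ncell <- nx * ny * nz
  if (is3d) {
    w("CELLS %d %d", ncell, ncell * 9L)
    idx <- seq_len(ncell) - 1L
    i <- idx %% nx; j <- (idx %/% nx) %% ny; k <- idx %/% (nx * ny)
    p0 <- i + px * (j + py * k)
    writeLines(sprintf("8 %d %d %d %d %d %d %d %d",
                       p0, p0 + 1L, p0 + 1L + px, p0 + px,
                       p0 + px * py, p0 + 1L + px * py,
                       p0 + 1L + px + px * py, p0 + px + px * py), con)
    w("CELL_TYPES %d", ncell)
    writeLines(rep("12", ncell), con)
  } else {
    w("CELLS %d %d", ncell, ncell * 5L)
    idx <- seq_len(ncell) - 1L
    i <- idx %% nx; j <- idx %/% nx
    p0 <- i + px * j
    writeLines(sprintf("4 %d %d %d %d", p0, p0 + 1L, p0 + 1L + px, p0 + px),
               con)
    w("CELL_TYPES %d", ncell)
    writeLines(rep("9", ncell), con)
  }
  w("CELL_DATA %d", ncell)
  w("SCALARS region_label int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(geom$region_label), con)
  w("SCALARS segment_id int 1")
  w("LOOKUP_TABLE default")
  seg <- geom$segment_id
  seg[is.na(seg)] <- -1L
  writeLines(as.character(as.integer(seg)), con)
  w("SCALARS tissue_mask int 1")
  w("LOOKUP_TABLE default")
  writeLines(as.character(as.integer(geom$mask)), con)
  w("SCALARS fiber_angle double 1")
  w("LOOKUP_TABLE default")
  writeLines(sprintf("%.17g", geom$fiber_angle), con)
  invisible(path)
}

#' Read a geometry from a VTK legacy ASCII file
#'
#' Reads files produced by [write_geometry()]; integer cell-data arrays
#' round-trip bit-exactly. Unknown cell-data arrays are preserved under
#' `meta$extra_cell_data` with a warning. Malformed or truncated files
#' raise a parse error naming the offending line.
#'
#' @param path input file path.
#' @return A `ventricle_geometry`.
#' @export
read_geometry <- function(path) {
  lines <- readLines(path, warn = FALSE)
  ln <- 0L
  fail <- function(msg) stop(sprintf("VTK parse error at line %d: %s", ln,
                                     msg), call. = FALSE)
  nxt <- function() {
    ln <<- ln + 1L
    if (ln > length(lines)) fail("unexpected end of file")
    lines[ln]
  }
  take_values <- function(count, what) {
    out <- numeric(0)
    while (length(out) < count) {
      v <- suppressWarnings(as.numeric(strsplit(trimws(nxt()), "\\s+")[[1]]))
      if (any(is.na(v))) fail(sprintf("non-numeric %s data", what))
      out <- c(out, v)
    }
    if (length(out) != count) fail(sprintf("ragged %s data", what))
    out
  }
  hdr <- nxt()
  if (!grepl("^# vtk DataFile", hdr)) fail("not a VTK legacy file")
  title <- nxt()
  m <- regmatches(title, regexec(
    "^reentryforge (\\S+) nx=(\\d+) ny=(\\d+) nz=(\\d+) spacing=(\\S+) ox=(\\S+) oy=(\\S+) oz=(\\S+)",
    title))[[1]]
  if (length(m) == 0) fail("title does not carry reentryforge grid metadata")
  kind <- m[2]
  nx <- as.integer(m[3]); ny <- as.integer(m[4]); nz <- as.integer(m[5])
  sp <- as.numeric(m[6])
  org <- as.numeric(m[7:9])
  if (toupper(trimws(nxt())) != "ASCII") fail("expected ASCII")
  if (!grepl("UNSTRUCTURED_GRID", nxt())) fail("expected UNSTRUCTURED_GRID")
  l <- nxt()
  pm <- regmatches(l, regexec("^POINTS (\\d+)", l))[[1]]
  if (length(pm) == 0) fail("expected POINTS")
  npts <- as.integer(pm[2])
  invisible(take_values(npts * 3, "point"))
  l <- nxt()
  cm <- regmatches(l, regexec("^CELLS (\\d+) (\\d+)", l))[[1]]
  if (length(cm) == 0) fail("expected CELLS")
  ncell <- as.integer(cm[2])
  invisible(take_values(as.integer(cm[3]), "connectivity"))
  l <- nxt()
  tm <- regmatches(l, regexec("^CELL_TYPES (\\d+)", l))[[1]]
  if (length(tm) == 0) fail("expected CELL_TYPES")
  invisible(take_values(ncell, "cell-type"))
  l <- nxt()
  dm <- regmatches(l, regexec("^CELL_DATA (\\d+)", l))[[1]]
  if (length(dm) == 0) fail("expected CELL_DATA")
  if (as.integer(dm[2]) != ncell) fail("CELL_DATA count mismatch")
  arrays <- list()
  while (ln < length(lines)) {
    l <- nxt()
    if (!nzchar(trimws(l))) next
    sm <- regmatches(l, regexec("^SCALARS (\\S+) (\\S+)", l))[[1]]
    if (length(sm) == 0) fail("expected SCALARS array header")
    nm <- sm[2]; typ <- sm[3]
    if (!grepl("^LOOKUP_TABLE", nxt())) fail("expected LOOKUP_TABLE")
    v <- take_values(ncell, nm)
    if (typ %in% c("int", "long", "short")) v <- as.integer(v)
    arrays[[nm]] <- v
  }
  needed <- c("region_label", "segment_id", "tissue_mask", "fiber_angle")
  miss <- setdiff(needed, names(arrays))
  if (length(miss)) fail(paste("missing cell-data array(s):",
                               paste(miss, collapse = ", ")))
  extra <- setdiff(names(arrays), needed)
  if (length(extra))
    warning("preserving unknown cell-data array(s): ",
            paste(extra, collapse = ", "))
  is3d <- kind == "shell" || nz > 1
  dims <- if (is3d) c(nx = nx, ny = ny, nz = nz) else c(nx = nx, ny = ny)
  n <- prod(dims)
  if (n != ncell) fail("cell count does not match grid dims")
  idx <- seq_len(n) - 1L
  if (is3d) {
    # z descends from the base plane: first-voxel centre = oz + sp/2
    centers <- cbind(x = org[1] + ((idx %% nx) + 0.5) * sp,
                     y = org[2] + (((idx %/% nx) %% ny) + 0.5) * sp,
                     z = org[3] + sp / 2 - (idx %/% (nx * ny)) * sp)
  } else {
    centers <- cbind(x = org[1] + ((idx %% nx) + 0.5) * sp,
                     y = org[2] + ((idx %/% nx) + 0.5) * sp)
  }
  seg <- arrays$segment_id
  seg[seg < 0] <- NA_integer_
  vol <- rep(if (is3d) sp^3 else sp^2, n)
  meta <- list(source = path)
  if (length(extra)) meta$extra_cell_data <- arrays[extra]
  new_geometry(kind, dims, sp, centers, arrays$region_label, seg,
               arrays$fiber_angle, vol, arrays$tissue_mask > 0, meta)
}
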