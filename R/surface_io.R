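#' Read a gridded height map from disk
#'
#' Supports three on-disk forms:
#' \describe{
#'   \item{`"sur"`}{A minimal Digital-Surf-style binary surface: one object,
#'     512-byte little-endian header, heights stored as scaled/offset signed
#'     32-bit integers. Fields honored: signature, point size, grid
#'     dimensions, x/y spacings, z scale, x/y/z offsets, special-points
#'     flag, object and operator names. All other header fields are written
#'     as zeros and ignored on read. Non-measured points are stored as the
#'     sentinel integer `-2147483646` when the special-points flag is set.}
#'   \item{`"ascii_matrix"`}{Whitespace-separated rows of heights preceded by
#'     comment headers `# nx ny dx dy` / `# <nx> <ny> <dx> <dy>` (and an
#'     optional origin line `# x0 y0` / `# <x0> <y0>`). Voids are the token
#'     `NaN`.}
#'   \item{`"xyz"`}{Three whitespace-separated columns x, y, z (um) on a
#'     complete rectangular lattice. A missing lattice point is an error
#'     unless `fill_missing = TRUE`, in which case it becomes a void.}
#' }
#'
#' @param path file to read.
#' @param format one of `"sur"`, `"ascii_matrix"`, `"xyz"`. Default guesses
#'   from the file extension (`.sur` -> sur, `.xyz` -> xyz, else ascii).
#' @param fill_missing xyz only: treat absent lattice points as voids rather
#'   than raising a grid error.
#' @return a [height_map()].
#' @seealso [write_height_map()]
#' @export
read_height_map <- function(path, format = NULL, fill_missing = FALSE) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  format <- format %||% guess_surface_format(path)
  format <- match.arg(format, c("sur", "ascii_matrix", "xyz"))
  switch(format,
    sur = read_sur(path),
    ascii_matrix = read_ascii_matrix(path),
    xyz = read_xyz(path, fill_missing = fill_missing))
}

#' Write a gridded height map to disk
#'
#' Inverse of [read_height_map()]; round-trips preserve grid shape, spacing
#' and voids exactly, and heights exactly for the text formats. The binary
#' `.sur` form quantizes heights to signed 32-bit integers, so round-trip
#' error is bounded by `(max(z) - min(z)) / 2^31`.
#'
#' @param map a [height_map()].
#' @inheritParams read_height_map
#' @return `path`, invisibly.
#' @export
write_height_map <- function(map, path, format = NULL) {
  stopifnot(is_height_map(map))
  format <- format %||% guess_surface_format(path)
  format <- match.arg(format, c("sur", "ascii_matrix", "xyz"))
  switch(format,
    sur = write_sur(map, path),
    ascii_matrix = write_ascii_matrix(map, path),
    xyz = write_xyz(map, path))
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

guess_surface_format <- function(path) {
  ext <- tolower(tools::file_ext(path))
  switch(ext, sur = "sur", xyz = "xyz", "ascii_matrix")
}

# ---- Digital-Surf-style binary (.sur) ---------------------------------------

SUR_SIGNATURE <- "DIGITAL SURF"
SUR_VOID_SENTINEL <- -2147483646L
SUR_HEADER_SIZE <- 512L

# header byte offsets (0-based) of the fields this dialect honors
.sur_off <- list(
  signature = 0L,    # char[12]
  format = 12L,      # int16, 0 = PC little-endian binary
  n_objects = 14L,   # int16
  version = 16L,     # int16
  object_type = 18L, # int16, 2 = topographic surface
  object_name = 20L, # char[30]
  operator = 50L,    # char[30]
  special_points = 86L, # int16, 1 = non-measured sentinel in use
  pointsize = 98L,   # int16, bits per stored z (32 here)
  zmin = 100L, zmax = 104L,          # int32 bounds of stored ints
  nx = 108L, ny = 112L, ntotal = 116L,  # int32
  dx = 120L, dy = 124L, zscale = 128L,  # float32; um per sample / per LSB
  xoffset = 460L, yoffset = 464L, zoffset = 468L  # float32, um
)

read_sur <- function(path) {
  con <- file(path, "rb")
  on.exit(close(con))
  hdr <- readBin(con, "raw", n = SUR_HEADER_SIZE)
  if (length(hdr) < SUR_HEADER_SIZE)
    stop("sur format error: truncated header (", length(hdr), " bytes)",
         call. = FALSE)
  rd_chr <- function(off, n) {
    b <- hdr[(off + 1L):(off + n)]
    b <- b[b != as.raw(0)]
    trimws(rawToChar(b))
  }
  rd_i16 <- function(off) readBin(hdr[(off + 1L):(off + 2L)], "integer",
                                  size = 2, endian = "little")
  rd_i32 <- function(off) readBin(hdr[(off + 1L):(off + 4L)], "integer",
                                  size = 4, endian = "little")
  rd_f32 <- function(off) readBin(hdr[(off + 1L):(off + 4L)], "double",
                                  size = 4, endian = "little")

  sig <- rd_chr(.sur_off$signature, 12L)
  if (sig != SUR_SIGNATURE)
    stop("sur format error: bad signature '", sig, "'", call. = FALSE)
  ps <- rd_i16(.sur_off$pointsize)
  if (ps != 32L)
    stop("sur format error: unsupported pointsize ", ps, call. = FALSE)
  nx <- rd_i32(.sur_off$nx); ny <- rd_i32(.sur_off$ny)
  if (nx < 2L || ny < 2L)
    stop("sur format error: invalid grid dimensions nx=", nx, " ny=", ny,
         call. = FALSE)
  ntot <- rd_i32(.sur_off$ntotal)
  if (ntot != nx * ny)
    stop("sur format error: total_points ", ntot, " != nx*ny", call. = FALSE)
  dx <- rd_f32(.sur_off$dx); dy <- rd_f32(.sur_off$dy)
  if (!is.finite(dx) || dx <= 0)
    stop("sur format error: non-positive xspacing", call. = FALSE)
  if (!is.finite(dy) || dy <= 0)
    stop("sur format error: non-positive yspacing", call. = FALSE)
  zscale <- rd_f32(.sur_off$zscale)
  special <- rd_i16(.sur_off$special_points)

  zi <- readBin(con, "integer", n = nx * ny, size = 4, endian = "little")
  if (length(zi) != nx * ny)
    stop("sur format error: data block shorter than nx*ny", call. = FALSE)
  z <- zi * zscale + rd_f32(.sur_off$zoffset)
  if (special == 1L) z[zi == SUR_VOID_SENTINEL] <- NA_real_
  heights <- matrix(z, nrow = ny, ncol = nx, byrow = TRUE)
  meta <- list(format = "sur",
               object_name = rd_chr(.sur_off$object_name, 30L),
               operator = rd_chr(.sur_off$operator, 30L))
  height_map(heights, dx = dx, dy = dy,
             x0 = rd_f32(.sur_off$xoffset), y0 = rd_f32(.sur_off$yoffset),
             meta = meta)
}

write_sur <- function(map, path) {
  z <- t(map$heights)  # row-major (y rows) on disk
  zv <- as.vector(z)
  ok <- !is.na(zv)
  zmin <- min(zv[ok]); zmax <- max(zv[ok])
  # zmid rounded to float32 so the stored offset is exact; the scale is a
  # power of two, exactly representable in the float32 header field, so the
  # only round-trip error is the int32 quantization (<= range / 2^31)
  zmid <- readBin(writeBin((zmin + zmax) / 2, raw(), size = 4,
                           endian = "little"), "double", size = 4,
                  endian = "little")
  rng <- zmax - zmin
  scale <- if (rng > 0) 2^(floor(log2(rng)) - 30) else 2^-20
  zi <- integer(length(zv))
  zi[ok] <- as.integer(round((zv[ok] - zmid) / scale))
  zi[!ok] <- SUR_VOID_SENTINEL

  hdr <- raw(SUR_HEADER_SIZE)
  put <- function(off, bytes) {
    hdr[(off + 1L):(off + length(bytes))] <<- bytes
  }
  wr_chr <- function(off, s, n) {
    b <- charToRaw(substr(s, 1L, n))
    put(off, b)
  }
  wr_i16 <- function(off, v) put(off, writeBin(as.integer(v), raw(), size = 2,
                                               endian = "little"))
  wr_i32 <- function(off, v) put(off, writeBin(as.integer(v), raw(), size = 4,
                                               endian = "little"))
  wr_f32 <- function(off, v) put(off, writeBin(as.double(v), raw(), size = 4,
                                               endian = "little"))

  wr_chr(.sur_off$signature, SUR_SIGNATURE, 12L)
  wr_i16(.sur_off$format, 0L)
  wr_i16(.sur_off$n_objects, 1L)
  wr_i16(.sur_off$version, 1L)
  wr_i16(.sur_off$object_type, 2L)
  wr_chr(.sur_off$object_name,
         as.character(map$meta$object_name %||% "surface"), 30L)
  wr_chr(.sur_off$operator, as.character(map$meta$operator %||% "dmta"), 30L)
  wr_i16(.sur_off$special_points, if (any(!ok)) 1L else 0L)
  wr_i16(.sur_off$pointsize, 32L)
  wr_i32(.sur_off$zmin, min(zi[ok]))
  wr_i32(.sur_off$zmax, max(zi[ok]))
  wr_i32(.sur_off$nx, ncol(map$heights))
  wr_i32(.sur_off$ny, nrow(map$heights))
  wr_i32(.sur_off$ntotal, length(zv))
  wr_f32(.sur_off$dx, map$dx)
  wr_f32(.sur_off$dy, map$dy)
  wr_f32(.sur_off$zscale, scale)
  wr_f32(.sur_off$xoffset, map$x0)
  wr_f32(.sur_off$yoffset, map$y0)
  wr_f32(.sur_off$zoffset, zmid)

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(hdr, con)
  writeBin(zi, con, size = 4, endian = "little")
  invisible(path)
}

# ---- ASCII matrix -----------------------------------------------------------

read_ascii_matrix <- function(path) {
  lines <- readLines(path, warn = FALSE)
  if (!length(lines)) stop("format error: empty file", call. = FALSE)
  is_comment <- startsWith(trimws(lines), "#")
  hdr_lines <- lines[is_comment]
  nums <- lapply(hdr_lines, function(l) {
    toks <- strsplit(trimws(sub("^\\s*#", "", l)), "\\s+")[[1]]
    suppressWarnings(as.numeric(toks))
  })
  numeric_hdr <- Filter(function(v) length(v) > 0 && all(!is.na(v)), nums)
  if (!length(numeric_hdr) || length(numeric_hdr[[1]]) < 4)
    stop("format error: missing '# nx ny dx dy' header", call. = FALSE)
  dims <- numeric_hdr[[1]]
  nx <- as.integer(dims[1]); ny <- as.integer(dims[2])
  dx <- dims[3]; dy <- dims[4]
  x0 <- 0; y0 <- 0
  if (length(numeric_hdr) >= 2 && length(numeric_hdr[[2]]) >= 2) {
    x0 <- numeric_hdr[[2]][1]; y0 <- numeric_hdr[[2]][2]
  }
  body <- lines[!is_comment & nzchar(trimws(lines))]
  if (length(body) != ny)
    stop("format error: expected ", ny, " data rows, found ", length(body),
         call. = FALSE)
  rows <- lapply(body, function(l) {
    v <- suppressWarnings(as.numeric(strsplit(trimws(l), "\\s+")[[1]]))
    v
  })
  nc <- lengths(rows)
  if (any(nc != nx))
    stop("format error: row with ", nc[which(nc != nx)[1]],
         " values, expected ", nx, call. = FALSE)
  heights <- do.call(rbind, rows)
  height_map(heights, dx = dx, dy = dy, x0 = x0, y0 = y0,
             meta = list(format = "ascii_matrix"))
}

write_ascii_matrix <- function(map, path) {
  con <- file(path, "wb")  # binary mode for deterministic LF endings
  on.exit(close(con))
  wl <- function(s) writeLines(s, con, sep = "\n")
  wl("# nx ny dx dy")
  wl(sprintf("# %d %d %.17g %.17g",
             ncol(map$heights), nrow(map$heights), map$dx, map$dy))
  wl("# x0 y0")
  wl(sprintf("# %.17g %.17g", map$x0, map$y0))
  h <- map$heights
  for (i in seq_len(nrow(h))) {
    v <- h[i, ]
    s <- ifelse(is.na(v), "NaN", sprintf("%.17g", v))
    wl(paste(s, collapse = " "))
  }
  invisible(path)
}

# ---- XYZ --------------------------------------------------------------------

read_xyz <- function(path, fill_missing = FALSE) {
  d <- utils::read.table(path, header = FALSE,
                         col.names = c("x", "y", "z"),
                         colClasses = "numeric", comment.char = "#")
  if (!nrow(d)) stop("format error: empty xyz file", call. = FALSE)
  xs <- sort(unique(d$x)); ys <- sort(unique(d$y))
  nx <- length(xs); ny <- length(ys)
  if (nx < 2L || ny < 2L)
    stop("grid error: fewer than 2 distinct x or y coordinates", call. = FALSE)
  ddx <- diff(xs); ddy <- diff(ys)
  tol <- 1e-6 * max(ddx[1], ddy[1])
  if (max(abs(ddx - ddx[1])) > tol || max(abs(ddy - ddy[1])) > tol)
    stop("grid error: non-uniform lattice spacing", call. = FALSE)
  ci <- match(round((d$x - xs[1]) / ddx[1]), 0:(nx - 1L))
  ri <- match(round((d$y - ys[1]) / ddy[1]), 0:(ny - 1L))
  if (anyNA(ci) || anyNA(ri))
    stop("grid error: point off the inferred lattice", call. = FALSE)
  idx <- (ci - 1L) * ny + ri
  if (anyDuplicated(idx))
    stop("grid error: duplicate lattice point", call. = FALSE)
  if (length(idx) < nx * ny && !fill_missing)
    stop("grid error: ", nx * ny - length(idx), " missing lattice point(s); ",
         "use fill_missing = TRUE to read them as voids", call. = FALSE)
  heights <- matrix(NA_real_, nrow = ny, ncol = nx)
  heights[cbind(ri, ci)] <- d$z
  height_map(heights, dx = ddx[1], dy = ddy[1], x0 = xs[1], y0 = ys[1],
             meta = list(format = "xyz"))
}

write_xyz <- function(map, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  x <- grid_x(map); y <- grid_y(map)
  h <- map$heights
  for (i in seq_len(nrow(h))) {
    v <- h[i, ]
    s <- sprintf("%.17g %.17g %s", x, y[i],
                 ifelse(is.na(v), "NaN", sprintf("%.17g", v)))
    writeLines(s, con, sep = "\n")
  }
  invisible(path)
}
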