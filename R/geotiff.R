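# Minimal GeoTIFF reader/writer: baseline TIFF (little-endian, uncompressed,
# single plane, strip-organised) plus the GeoTIFF tags needed here --
# ModelPixelScaleTag (33550), ModelTiepointTag (33922), GeoKeyDirectoryTag
# (34735) and GDAL_NODATA (42113). Two pixel layouts are supported, matching
# the formats this package exchanges: 8-bit RGB(A) orthomosaics and 32-bit
# float single-band surface models.

TIFF_TAG <- list(
  width = 256L, length = 257L, bits = 258L, compression = 259L,
  photometric = 262L, strip_offsets = 273L, samples = 277L,
  rows_per_strip = 278L, strip_bytes = 279L, planar = 284L,
  extra_samples = 338L, sample_format = 339L,
  pixel_scale = 33550L, tiepoint = 33922L, geo_keys = 34735L,
  gdal_nodata = 42113L
)

GEOKEY <- list(model_type = 1024L, raster_type = 1025L,
               geographic_cs = 2048L, projected_cs = 3072L)

u16r <- function(x) {
  x <- as.integer(round(x))
  as.raw(rbind(x %% 256L, x %/% 256L))
}

u32r <- function(x) {
  x <- as.numeric(x)
  b0 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; b3 <- x %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}

dblr <- function(x) writeBin(as.numeric(x), raw(), size = 8, endian = "little")
fltr <- function(x) writeBin(as.numeric(x), raw(), size = 4, endian = "little")

# TIFF field types: 1 BYTE, 2 ASCII, 3 SHORT, 4 LONG, 11 FLOAT, 12 DOUBLE
tiff_type_size <- c(`1` = 1L, `2` = 1L, `3` = 2L, `4` = 4L, `11` = 4L, `12` = 8L)

tag_value_raw <- function(type, values) {
  switch(as.character(type),
    `1` = as.raw(values),
    `2` = c(charToRaw(values), as.raw(0L)),
    `3` = u16r(values),
    `4` = u32r(values),
    `11` = fltr(values),
    `12` = dblr(values),
    stop("unsupported TIFF type ", type))
}

tag_count <- function(type, values) {
  if (type == 2L) nchar(values, type = "bytes") + 1L else length(values)
}

#' @noRd
write_tiff_raw <- function(path, pixel_raw, tags) {
  # tags: list of list(tag=, type=, values=); pixel data in one strip
  tags <- tags[order(vapply(tags, function(t) t$tag, 1L))]
  data_offset <- 8L
  n_data <- length(pixel_raw)
  ifd_offset <- data_offset + n_data
  if (ifd_offset %% 2L == 1L) ifd_offset <- ifd_offset + 1L
  n_tags <- length(tags)
  extra_offset <- ifd_offset + 2L + 12L * n_tags + 4L

  entries <- raw(0)
  extras <- raw(0)
  for (t in tags) {
    cnt <- tag_count(t$type, t$values)
    val <- tag_value_raw(t$type, t$values)
    nb <- length(val)
    if (nb <= 4L) {
      field <- c(val, raw(4L - nb))
    } else {
      off <- extra_offset + length(extras)
      if (off %% 2L == 1L) {            # word-align out-of-line values
        extras <- c(extras, raw(1))
        off <- off + 1L
      }
      field <- u32r(off)
      extras <- c(extras, val)
    }
    entries <- c(entries, u16r(t$tag), u16r(t$type), u32r(cnt), field)
  }

  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(c(charToRaw("II"), u16r(42L), u32r(ifd_offset)), con)
  writeBin(pixel_raw, con)
  if ((data_offset + n_data) %% 2L == 1L) writeBin(raw(1), con)
  writeBin(c(u16r(n_tags), entries, u32r(0L), extras), con)
  invisible(path)
}

rd_u16 <- function(buf, pos, n = 1L) {
  idx <- pos + rep(seq(0L, by = 2L, length.out = n), each = 2L) + c(0L, 1L)
  m <- matrix(as.integer(buf[idx]), nrow = 2L)
  m[1L, ] + 256L * m[2L, ]
}

rd_u32 <- function(buf, pos, n = 1L) {
  idx <- pos + rep(seq(0L, by = 4L, length.out = n), each = 4L) + 0:3
  m <- matrix(as.numeric(buf[idx]), nrow = 4L)
  m[1L, ] + 256 * m[2L, ] + 65536 * m[3L, ] + 16777216 * m[4L, ]
}

read_tag_values <- function(buf, type, count, field_raw) {
  size <- tiff_type_size[[as.character(type)]]
  nb <- size * count
  val_raw <- if (nb <= 4L) field_raw[seq_len(nb)] else {
    off <- rd_u32(field_raw, 1L)
    buf[(off + 1L):(off + nb)]
  }
  switch(as.character(type),
    `1` = as.integer(val_raw),
    `2` = {
      s <- val_raw[val_raw != as.raw(0L)]
      rawToChar(s)
    },
    `3` = rd_u16(val_raw, 1L, count),
    `4` = rd_u32(val_raw, 1L, count),
    `11` = readBin(val_raw, "numeric", count, size = 4L, endian = "little"),
    `12` = readBin(val_raw, "numeric", count, size = 8L, endian = "little"),
    NULL)
}

#' @noRd
read_tiff_tags <- function(path) {
  if (!file.exists(path)) {
    stop_plotpheno("file_not_found", "raster file not found: ", path)
  }
  buf <- readBin(path, "raw", file.size(path))
  if (length(buf) < 8L) stop_plotpheno("bad_tiff", "not a TIFF file: ", path)
  order_tag <- rawToChar(buf[1:2])
  if (order_tag == "MM") {
    stop_plotpheno("bad_tiff", "big-endian TIFF not supported: ", path)
  }
  if (order_tag != "II" || rd_u16(buf, 3L) != 42L) {
    stop_plotpheno("bad_tiff", "not a TIFF file: ", path)
  }
  ifd <- rd_u32(buf, 5L)
  n <- rd_u16(buf, ifd + 1L)
  tags <- list()
  for (i in seq_len(n)) {
    base <- ifd + 2L + 12L * (i - 1L)
    tag <- rd_u16(buf, base + 1L)
    type <- rd_u16(buf, base + 3L)
    count <- rd_u32(buf, base + 5L)
    field <- buf[(base + 9L):(base + 12L)]
    v <- read_tag_values(buf, type, count, field)
    if (!is.null(v)) tags[[as.character(tag)]] <- v
  }
  list(buf = buf, tags = tags)
}

tiff_tag_get <- function(tags, id, default = NULL) {
  v <- tags[[as.character(id)]]
  if (is.null(v)) default else v
}

# Decode geo information from the parsed tag set; errors are named so callers
# can distinguish a missing CRS from a geographic one.
geo_from_tags <- function(tags, path) {
  scale <- tiff_tag_get(tags, TIFF_TAG$pixel_scale)
  tie <- tiff_tag_get(tags, TIFF_TAG$tiepoint)
  keys <- tiff_tag_get(tags, TIFF_TAG$geo_keys)
  if (is.null(scale) || is.null(tie)) {
    stop_plotpheno("missing_georeference",
                   "GeoTIFF lacks pixel-scale/tiepoint tags: ", path)
  }
  if (is.null(keys)) {
    stop_plotpheno("missing_crs", "GeoTIFF has no CRS (GeoKey) tags: ", path)
  }
  n_keys <- keys[4L]
  model_type <- NA_integer_
  epsg <- NA_integer_
  for (k in seq_len(n_keys)) {
    entry <- keys[(4L * k + 1L):(4L * k + 4L)]
    if (entry[1L] == GEOKEY$model_type) model_type <- entry[4L]
    if (entry[1L] == GEOKEY$projected_cs) epsg <- entry[4L]
    if (entry[1L] == GEOKEY$geographic_cs && is.na(epsg)) epsg <- entry[4L]
  }
  if (is.na(model_type) && is.na(epsg)) {
    stop_plotpheno("missing_crs", "GeoTIFF has no CRS (GeoKey) tags: ", path)
  }
  if (!is.na(model_type) && model_type == 2L) {
    stop_plotpheno("geographic_crs",
                   "GeoTIFF uses a geographic (degree) CRS; a projected ",
                   "metric CRS is required: ", path)
  }
  # tiepoint maps pixel (i, j) to world (x, y): origin is the top-left corner
  origin_x <- tie[4L] - tie[1L] * scale[1L]
  origin_y <- tie[5L] + tie[2L] * scale[2L]
  list(origin_x = origin_x, origin_y = origin_y,
       pixel_size_x = scale[1L], pixel_size_y = scale[2L],
       crs_id = as.integer(epsg))
}

read_strips <- function(buf, tags) {
  offs <- tiff_tag_get(tags, TIFF_TAG$strip_offsets)
  cnts <- tiff_tag_get(tags, TIFF_TAG$strip_bytes)
  if (is.null(offs) || is.null(cnts)) {
    stop_plotpheno("bad_tiff", "TIFF has no strip data")
  }
  do.call(c, lapply(seq_along(offs), function(i) {
    buf[(offs[i] + 1L):(offs[i] + cnts[i])]
  }))
}

geo_key_directory <- function(crs_id) {
  # header: version 1, revision 1.0, n keys; all keys inline (TIFFTagLocation 0)
  keys <- c(1L, 1L, 0L, 3L,
            GEOKEY$model_type, 0L, 1L, 1L,     # 1 = projected
            GEOKEY$raster_type, 0L, 1L, 1L,    # 1 = PixelIsArea
            GEOKEY$projected_cs, 0L, 1L, as.integer(crs_id))
  keys
}

geo_tags <- function(grid) {
  list(
    list(tag = TIFF_TAG$pixel_scale, type = 12L,
         values = c(grid$pixel_size_x, grid$pixel_size_y, 0)),
    list(tag = TIFF_TAG$tiepoint, type = 12L,
         values = c(0, 0, 0, grid$origin_x, grid$origin_y, 0)),
    list(tag = TIFF_TAG$geo_keys, type = 3L,
         values = geo_key_directory(grid$crs_id))
  )
}

#' Write an RGB orthomosaic GeoTIFF
#'
#' Writes an uncompressed 8-bit 3-band (or 4-band when an alpha/validity
#' mask is supplied) GeoTIFF with the grid's georeferencing tags.
#'
#' @param ortho an `ortho_image` object.
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_ortho_geotiff <- function(ortho, path) {
  stopifnot(inherits(ortho, "ortho_image"))
  g <- ortho$grid
  has_alpha <- !all(ortho$valid)
  spp <- if (has_alpha) 4L else 3L
  bands <- list(ortho$r, ortho$g, ortho$b)
  if (has_alpha) bands <- c(bands, list(ifelse(ortho$valid, 255, 0)))
  arr <- array(0, dim = c(spp, g$n_cols, g$n_rows))
  for (i in seq_len(spp)) arr[i, , ] <- t(bands[[i]])
  pix <- as.raw(as.integer(round(pmin(pmax(arr, 0), 255))))
  tags <- c(list(
    list(tag = TIFF_TAG$width, type = 4L, values = g$n_cols),
    list(tag = TIFF_TAG$length, type = 4L, values = g$n_rows),
    list(tag = TIFF_TAG$bits, type = 3L, values = rep(8L, spp)),
    list(tag = TIFF_TAG$compression, type = 3L, values = 1L),
    list(tag = TIFF_TAG$photometric, type = 3L, values = 2L),
    list(tag = TIFF_TAG$strip_offsets, type = 4L, values = 8L),
    list(tag = TIFF_TAG$samples, type = 3L, values = spp),
    list(tag = TIFF_TAG$rows_per_strip, type = 4L, values = g$n_rows),
    list(tag = TIFF_TAG$strip_bytes, type = 4L, values = length(pix)),
    list(tag = TIFF_TAG$planar, type = 3L, values = 1L)),
    if (has_alpha) list(list(tag = TIFF_TAG$extra_samples, type = 3L,
                             values = 2L)),
    geo_tags(g))
  write_tiff_raw(path, pix, tags)
}

#' Write a single-band float DSM GeoTIFF
#'
#' Writes an uncompressed 32-bit float elevation raster with a GDAL-style
#' nodata tag; invalid pixels are stored as the nodata value.
#'
#' @param dsm a `surface_model` object.
#' @param path output file path.
#' @param nodata nodata marker value stored in the file.
#' @return `path`, invisibly.
#' @export
write_dsm_geotiff <- function(dsm, path, nodata = -9999) {
  stopifnot(inherits(dsm, "surface_model"))
  g <- dsm$grid
  z <- dsm$z
  z[!dsm$valid] <- nodata
  pix <- fltr(as.vector(t(z)))   # row-major, rows top to bottom
  tags <- c(list(
    list(tag = TIFF_TAG$width, type = 4L, values = g$n_cols),
    list(tag = TIFF_TAG$length, type = 4L, values = g$n_rows),
    list(tag = TIFF_TAG$bits, type = 3L, values = 32L),
    list(tag = TIFF_TAG$compression, type = 3L, values = 1L),
    list(tag = TIFF_TAG$photometric, type = 3L, values = 1L),
    list(tag = TIFF_TAG$strip_offsets, type = 4L, values = 8L),
    list(tag = TIFF_TAG$samples, type = 3L, values = 1L),
    list(tag = TIFF_TAG$rows_per_strip, type = 4L, values = g$n_rows),
    list(tag = TIFF_TAG$strip_bytes, type = 4L, values = length(pix)),
    list(tag = TIFF_TAG$planar, type = 3L, values = 1L),
    list(tag = TIFF_TAG$sample_format, type = 3L, values = 3L),
    list(tag = TIFF_TAG$gdal_nodata, type = 2L,
         values = format(nodata, scientific = FALSE))),
    geo_tags(g))
  write_tiff_raw(path, pix, tags)
}

#' Read an RGB orthomosaic GeoTIFF
#'
#' @param path file path of an 8-bit RGB(A) GeoTIFF.
#' @return an `ortho_image`.
#' @export
read_ortho_geotiff <- function(path) {
  parsed <- read_tiff_tags(path)
  tags <- parsed$tags
  geo <- geo_from_tags(tags, path)
  w <- tiff_tag_get(tags, TIFF_TAG$width)
  h <- tiff_tag_get(tags, TIFF_TAG$length)
  spp <- tiff_tag_get(tags, TIFF_TAG$samples, 1L)
  comp <- tiff_tag_get(tags, TIFF_TAG$compression, 1L)
  if (comp != 1L) stop_plotpheno("bad_tiff", "compressed TIFF not supported")
  if (spp < 3L) stop_plotpheno("bad_tiff", "orthomosaic must have RGB bands")
  pix <- as.integer(read_strips(parsed$buf, tags))
  arr <- array(pix, dim = c(spp, w, h))
  grid <- geo_grid(geo$origin_x, geo$origin_y, geo$pixel_size_x,
                   geo$pixel_size_y, n_cols = w, n_rows = h,
                   crs_id = geo$crs_id)
  valid <- if (spp >= 4L) t(arr[4L, , ]) > 0L else
    matrix(TRUE, nrow = h, ncol = w)
  ortho_image(grid, r = t(arr[1L, , ]), g = t(arr[2L, , ]),
              b = t(arr[3L, , ]), valid = valid)
}

#' Read a single-band DSM GeoTIFF
#'
#' @param path file path of a 32-bit float single-band GeoTIFF.
#' @return a `surface_model`.
#' @export
read_dsm_geotiff <- function(path) {
  parsed <- read_tiff_tags(path)
  tags <- parsed$tags
  geo <- geo_from_tags(tags, path)
  w <- tiff_tag_get(tags, TIFF_TAG$width)
  h <- tiff_tag_get(tags, TIFF_TAG$length)
  comp <- tiff_tag_get(tags, TIFF_TAG$compression, 1L)
  if (comp != 1L) stop_plotpheno("bad_tiff", "compressed TIFF not supported")
  fmt <- tiff_tag_get(tags, TIFF_TAG$sample_format, 1L)
  bits <- tiff_tag_get(tags, TIFF_TAG$bits, 8L)
  strip <- read_strips(parsed$buf, tags)
  z <- if (fmt == 3L && bits[1L] == 32L) {
    readBin(strip, "numeric", w * h, size = 4L, endian = "little")
  } else if (fmt == 1L) {
    as.numeric(as.integer(strip))
  } else stop_plotpheno("bad_tiff", "unsupported DSM sample format")
  zm <- matrix(z, nrow = h, ncol = w, byrow = TRUE)
  nodata <- tiff_tag_get(tags, TIFF_TAG$gdal_nodata)
  valid <- matrix(TRUE, nrow = h, ncol = w)
  if (!is.null(nodata)) {
    nd <- as.numeric(nodata)
    valid <- is.finite(zm) & zm != nd
  } else valid <- is.finite(zm)
  grid <- geo_grid(geo$origin_x, geo$origin_y, geo$pixel_size_x,
                   geo$pixel_size_y, n_cols = w, n_rows = h,
                   crs_id = geo$crs_id)
  surface_model(grid, z = zm, valid = valid)
}
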