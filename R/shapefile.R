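# ESRI Shapefile (polygon, shape type 5) writer/reader for microplot
# boundaries. The .dbf attribute table goes through foreign::write.dbf /
# read.dbf; the .shp/.shx binary records are written here (no package in
# the dependency set handles them). One integer attribute, "plot_id".

be32r <- function(x) {
  x <- as.numeric(x)
  b3 <- x %% 256; x <- x %/% 256
  b2 <- x %% 256; x <- x %/% 256
  b1 <- x %% 256; b0 <- x %/% 256
  as.raw(rbind(b0, b1, b2, b3))
}

le32r <- function(x) u32r(x)

shp_header <- function(file_length_words, bbox) {
  c(be32r(9994L), raw(20L), be32r(file_length_words),
    le32r(1000L), le32r(5L),
    dblr(c(bbox[1L], bbox[2L], bbox[3L], bbox[4L])),
    dblr(rep(0, 4)))   # z and m ranges unused
}

# WKT for the projected CRSs we can name offline (UTM on WGS84); other EPSG
# codes simply omit the .prj sidecar.
utm_wkt <- function(epsg) {
  north <- epsg >= 32601L && epsg <= 32660L
  south <- epsg >= 32701L && epsg <= 32760L
  if (!north && !south) return(NULL)
  zone <- epsg - if (north) 32600L else 32700L
  cm <- -183L + 6L * zone
  sprintf(paste0(
    'PROJCS["WGS 84 / UTM zone %d%s",GEOGCS["WGS 84",DATUM["WGS_1984",',
    'SPHEROID["WGS 84",6378137,298.257223563]],PRIMEM["Greenwich",0],',
    'UNIT["degree",0.0174532925199433]],PROJECTION["Transverse_Mercator"],',
    'PARAMETER["latitude_of_origin",0],PARAMETER["central_meridian",%d],',
    'PARAMETER["scale_factor",0.9996],PARAMETER["false_easting",500000],',
    'PARAMETER["false_northing",%d],UNIT["metre",1],',
    'AUTHORITY["EPSG","%d"]]'),
    zone, if (north) "N" else "S", cm, if (north) 0L else 10000000L, epsg)
}

close_ring_cw <- function(poly) {
  p <- as.matrix(poly)
  n <- nrow(p)
  if (n > 1L && all(p[1L, ] == p[n, ])) p <- p[-n, , drop = FALSE]
  # shapefile outer rings are clockwise; reverse counterclockwise input,
  # keeping the first vertex first so the write/read pair is invertible
  if (ring_signed_area(p[, 1L], p[, 2L]) > 0) {
    p <- p[c(1L, rev(seq_len(nrow(p))[-1L])), , drop = FALSE]
  }
  rbind(p, p[1L, ])
}

reopen_ring_ccw <- function(ring) {
  # inverse of close_ring_cw for rings it wrote: drop the closing vertex,
  # reverse back to counterclockwise, keep the original first vertex first
  p <- ring[-nrow(ring), , drop = FALSE]
  if (ring_signed_area(p[, 1L], p[, 2L]) < 0) {
    p <- p[c(1L, rev(seq_len(nrow(p))[-1L])), , drop = FALSE]
  }
  p
}

#' Write microplots to an ESRI Shapefile
#'
#' Produces `.shp`, `.shx` and `.dbf` (and `.prj` when the CRS has a known
#' WKT) with one clockwise polygon record per plot and an integer `plot_id`
#' attribute.
#'
#' @param plots non-empty list of `microplot`s.
#' @param path output path; the extension is replaced per sidecar file.
#' @param crs_id optional EPSG code used to emit a `.prj` sidecar.
#' @return the `.shp` path, invisibly.
#' @export
write_shapefile <- function(plots, path, crs_id = NULL) {
  if (length(plots) == 0L) {
    stop_plotpheno("empty_plots", "no plots to write")
  }
  base <- sub("\\.shp$", "", path)
  rings <- lapply(plots, function(p) close_ring_cw(p$polygon))
  allpts <- do.call(rbind, rings)
  bbox <- c(min(allpts[, 1L]), min(allpts[, 2L]),
            max(allpts[, 1L]), max(allpts[, 2L]))

  records <- raw(0)
  index <- raw(0)
  offset_words <- 50L   # 100-byte header
  for (i in seq_along(rings)) {
    ring <- rings[[i]]
    npts <- nrow(ring)
    # content: type(4) + bbox(32) + numparts(4) + numpoints(4) + parts(4)
    #          + points(16 * npts)
    content <- c(le32r(5L),
                 dblr(c(min(ring[, 1L]), min(ring[, 2L]),
                        max(ring[, 1L]), max(ring[, 2L]))),
                 le32r(1L), le32r(npts), le32r(0L),
                 dblr(as.vector(t(ring))))
    clen_words <- length(content) / 2L
    records <- c(records, be32r(i), be32r(clen_words), content)
    index <- c(index, be32r(offset_words), be32r(clen_words))
    offset_words <- offset_words + 4L + clen_words
  }

  con <- file(paste0(base, ".shp"), "wb")
  writeBin(c(shp_header(offset_words, bbox), records), con)
  close(con)
  con <- file(paste0(base, ".shx"), "wb")
  writeBin(c(shp_header(50L + 4L * length(rings), bbox), index), con)
  close(con)
  ids <- vapply(plots, function(p) p$plot_id, 1L)
  foreign::write.dbf(data.frame(plot_id = as.integer(ids)),
                     paste0(base, ".dbf"))
  if (!is.null(crs_id)) {
    wkt <- utm_wkt(as.integer(crs_id))
    if (!is.null(wkt)) writeLines(wkt, paste0(base, ".prj"))
  }
  invisible(paste0(base, ".shp"))
}

#' Read microplots from an ESRI Shapefile
#'
#' Inverse of [write_shapefile()] on files it wrote; also accepts other
#' polygon shapefiles with a numeric `plot_id` attribute (falling back to
#' record order with a warning when the attribute is absent).
#'
#' @param path path to the `.shp` file.
#' @return a list of `microplot`s sorted by id.
#' @export
read_shapefile <- function(path) {
  base <- sub("\\.shp$", "", path)
  shp <- paste0(base, ".shp")
  if (!file.exists(shp)) {
    stop_plotpheno("file_not_found", "shapefile not found: ", shp)
  }
  buf <- readBin(shp, "raw", file.size(shp))
  rd_be32 <- function(pos) {
    m <- as.numeric(buf[pos:(pos + 3L)])
    ((m[1L] * 256 + m[2L]) * 256 + m[3L]) * 256 + m[4L]
  }
  if (rd_be32(1L) != 9994) {
    stop_plotpheno("bad_shapefile", "not a shapefile: ", shp)
  }
  shape_type <- rd_u32(buf, 33L)
  if (shape_type != 5) {
    stop_plotpheno("non_polygon_shapefile",
                   "shapefile geometry type ", shape_type,
                   " is not polygon (5)")
  }
  file_len <- rd_be32(25L) * 2L
  pos <- 101L
  polys <- list()
  while (pos < file_len) {
    clen <- rd_be32(pos + 4L) * 2L
    ctype <- rd_u32(buf, pos + 8L)
    if (ctype == 5) {
      npts <- rd_u32(buf, pos + 8L + 40L)
      pts <- readBin(buf[(pos + 8L + 48L):(pos + 8L + 48L + 16L * npts - 1L)],
                     "numeric", 2L * npts, size = 8L, endian = "little")
      ring <- matrix(pts, ncol = 2L, byrow = TRUE,
                     dimnames = list(NULL, c("x", "y")))
      polys[[length(polys) + 1L]] <- reopen_ring_ccw(ring)
    }
    pos <- pos + 8L + clen
  }
  dbf_path <- paste0(base, ".dbf")
  ids <- NULL
  if (file.exists(dbf_path)) {
    attrs <- foreign::read.dbf(dbf_path, as.is = TRUE)
    if ("plot_id" %in% names(attrs)) ids <- as.integer(attrs$plot_id)
  }
  if (is.null(ids) || length(ids) != length(polys)) {
    warn_plotpheno("missing_plot_id",
                   "no usable plot_id attribute; using record order")
    ids <- seq_along(polys)
  }
  out <- Map(microplot, ids, polys)
  out[order(ids)]
}
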