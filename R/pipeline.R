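# Batch processing: run every registered capture date over every microplot
# against one shared base plane, and export a tidy CSV of trait rows.

#' Load a project configuration
#'
#' A project is a YAML (or JSON) file with:
#' \preformatted{
#' entries:            # one per capture date
#'   - capture_date: "2021-06-01"
#'     ortho_path: ortho.tif
#'     dsm_path: dsm.tif
#'     model_path: model.json      # optional per-date coverage model
#' plots_path: plots.shp
#' baseplane:
#'   plane_path: plane.json        # either a serialized plane ...
#'   # ... or regions + the date whose DSM they are drawn on:
#'   reference_date: "2021-06-01"
#'   regions:
#'     rectangles: [ [[x,y],[x,y],[x,y],[x,y]], ... ]
#'     lines: [ {p1: [x,y], p2: [x,y], half_width_m: 0.05}, ... ]
#' default_model_path: model.json
#' margin_fraction: 0.0
#' margin_side: width
#' output_path: traits.csv
#' }
#' Relative paths resolve against the config file's directory.
#'
#' @param path YAML/JSON config file.
#' @return a `project_config` list.
#' @export
read_project_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  base_dir <- dirname(normalizePath(path))
  resolve <- function(p) {
    if (is.null(p) || grepl("^(/|[A-Za-z]:)", p)) p else file.path(base_dir, p)
  }
  cfg$plots_path <- resolve(cfg$plots_path)
  cfg$default_model_path <- resolve(cfg$default_model_path)
  if (!is.null(cfg$baseplane$plane_path)) {
    cfg$baseplane$plane_path <- resolve(cfg$baseplane$plane_path)
  }
  cfg$entries <- lapply(cfg$entries, function(e) {
    e$ortho_path <- resolve(e$ortho_path)
    e$dsm_path <- resolve(e$dsm_path)
    if (!is.null(e$model_path)) e$model_path <- resolve(e$model_path)
    e
  })
  structure(cfg, class = "project_config")
}

parse_regions <- function(regions) {
  rects <- lapply(regions$rectangles, function(r) {
    m <- do.call(rbind, lapply(r, unlist))
    colnames(m) <- c("x", "y")
    m
  })
  lines <- lapply(regions$lines, function(l) {
    list(p1 = unlist(l$p1), p2 = unlist(l$p2),
         half_width = l$half_width_m %||% l$half_width)
  })
  list(rectangles = rects, lines = lines)
}

resolve_base_plane <- function(config) {
  bp <- config$baseplane
  if (is.null(bp)) {
    stop_plotpheno("unresolvable_baseplane", "config has no baseplane block")
  }
  if (!is.null(bp$plane_path)) return(read_base_plane(bp$plane_path))
  if (is.null(bp$regions) || is.null(bp$reference_date)) {
    stop_plotpheno("unresolvable_baseplane",
                   "baseplane needs plane_path, or regions + reference_date")
  }
  entry <- Filter(function(e) e$capture_date == bp$reference_date,
                  config$entries)
  if (length(entry) == 0L) {
    stop_plotpheno("unresolvable_baseplane", "reference_date ",
                   bp$reference_date, " is not a registered entry")
  }
  dsm <- read_dsm_geotiff(entry[[1L]]$dsm_path)
  regions <- parse_regions(bp$regions)
  if (length(regions$lines) > 0L) {
    base_plane_from_lines(dsm, regions$lines)
  } else {
    base_plane_from_rectangles(dsm, regions$rectangles)
  }
}

traits_to_row <- function(tr) {
  fr <- tr$class_fractions
  row <- data.frame(date = tr$capture_date, plot_id = tr$plot_id,
                    height100_cm = tr$heights$h100 * 100,
                    height95_cm = tr$heights$h95 * 100,
                    height90_cm = tr$heights$h90 * 100,
                    height80_cm = tr$heights$h80 * 100,
                    coverage = tr$coverage,
                    stringsAsFactors = FALSE)
  for (k in names(fr)) row[[paste0("class_", k, "_fraction")]] <- fr[[k]]
  row$volume_index_cm <- tr$volume_index * 100
  row$n_pixels_total <- tr$n_pixels_total
  row$n_pixels_valid <- tr$n_pixels_valid
  row
}

#' Process every capture date over every microplot
#'
#' Resolves the single shared base plane, then for each registered date
#' loads the raster pair, resolves its coverage model (per-date or the
#' project default) and analyzes every plot. Per-plot and per-date failures
#' are collected and skipped, not fatal. Output rows are ordered by date,
#' then plot id.
#'
#' @param config a `project_config` (or path to one).
#' @return a list with `table` (one row per date x plot), `failures`
#'   (date, plot_id, reason), and `base_plane`.
#' @export
run_batch <- function(config) {
  if (is.character(config)) config <- read_project_config(config)
  if (length(config$entries) == 0L) {
    stop_plotpheno("no_dates", "no capture dates registered")
  }
  plane <- resolve_base_plane(config)
  plots <- read_shapefile(config$plots_path)
  default_model <- if (!is.null(config$default_model_path)) {
    read_coverage_model(config$default_model_path)
  }
  margin_fraction <- config$margin_fraction %||% 0
  margin_side <- config$margin_side %||% "width"
  veg <- config$vegetation_classes

  rows <- list()
  failures <- data.frame(date = character(0), plot_id = integer(0),
                         reason = character(0), stringsAsFactors = FALSE)
  note_failure <- function(date, plot_id, reason) {
    message(sprintf("[plotpheno] skipping date %s plot %s: %s",
                    date, plot_id, reason))
    failures[nrow(failures) + 1L, ] <<- list(date, plot_id, reason)
  }
  entries <- config$entries[order(vapply(config$entries,
                                         function(e) e$capture_date, ""))]
  for (entry in entries) {
    pair <- tryCatch(
      read_raster_pair(entry$ortho_path, entry$dsm_path, entry$capture_date),
      error = function(e) {
        note_failure(entry$capture_date, NA_integer_, conditionMessage(e))
        NULL
      })
    if (is.null(pair)) next
    model <- if (!is.null(entry$model_path)) {
      read_coverage_model(entry$model_path)
    } else default_model
    if (is.null(model)) {
      note_failure(entry$capture_date, NA_integer_, "no coverage model")
      next
    }
    if (!is.null(veg)) model$vegetation_classes <- as.character(veg)
    for (p in plots[order(vapply(plots, function(q) q$plot_id, 1L))]) {
      tr <- tryCatch(
        analyze_plot(pair, p, plane, model,
                     margin_fraction = margin_fraction,
                     margin_side = margin_side),
        error = function(e) {
          note_failure(entry$capture_date, p$plot_id, conditionMessage(e))
          NULL
        })
      if (!is.null(tr)) rows[[length(rows) + 1L]] <- traits_to_row(tr)
    }
  }
  table <- if (length(rows) > 0L) do.call(rbind, rows) else NULL
  list(table = table, failures = failures, base_plane = plane)
}

csv_quote <- function(x) {
  need <- grepl('[",\n]', x)
  x[need] <- paste0('"', gsub('"', '""', x[need]), '"')
  x
}

#' Write a traits table as CSV
#'
#' Heights and the volume index are printed in cm with 2 decimals,
#' fractions with 4 decimals; fields are quoted per RFC 4180. The fixed
#' formatting makes reruns byte-identical.
#'
#' @param table the `table` component of [run_batch()]'s result.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_traits_csv <- function(table, path) {
  if (is.null(table) || nrow(table) == 0L) {
    stop_plotpheno("empty_table", "no trait rows to write")
  }
  fmt_col <- function(name, v) {
    if (grepl("_cm$", name)) sprintf("%.2f", v)
    else if (name == "coverage" || grepl("_fraction$", name)) sprintf("%.4f", v)
    else as.character(v)
  }
  cells <- vapply(names(table),
                  function(nm) csv_quote(fmt_col(nm, table[[nm]])),
                  character(nrow(table)))
  if (nrow(table) == 1L) cells <- matrix(cells, nrow = 1L)
  lines <- c(paste(csv_quote(names(table)), collapse = ","),
             apply(cells, 1L, paste, collapse = ","))
  con <- file(path, "wb")   # fixed newline convention across platforms
  writeLines(lines, con, sep = "\n")
  close(con)
  invisible(path)
}
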