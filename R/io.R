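# Format round-tripping: ESRI ASCII grids, GeoJSON networks/legs, CSV
# tables, JSON manifests. ASCII grid over binary rasters for diffability and
# zero-dependency parsing; NODATA value -9999.

ASCII_NODATA <- -9999

#' Write a concentration grid as an ESRI ASCII grid file
#'
#' @param grid a [concentration_grid()].
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_ascii_grid <- function(grid, path) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid$ncols),
    sprintf("nrows %d", grid$nrows),
    sprintf("xllcorner %.10g", grid$origin[1L]),
    sprintf("yllcorner %.10g", grid$origin[2L]),
    sprintf("cellsize %.10g", grid$cell_size),
    sprintf("NODATA_value %d", ASCII_NODATA)
  ), con)
  # rows north to south
  for (r in rev(seq_len(grid$nrows))) {
    writeLines(paste(sprintf("%.10g", grid$values[r, ]), collapse = " "), con)
  }
  invisible(path)
}

#' Read an ESRI ASCII grid file
#'
#' @param path input file.
#' @param model_name label for the resulting grid (default: file name).
#' @return a [concentration_grid()]; NODATA cells become `NA`.
#' @export
read_ascii_grid <- function(path, model_name = NULL) {
  lines <- readLines(path)
  header <- list()
  expected <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize",
                "NODATA_value")
  for (i in seq_len(6L)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    if (length(parts) != 2L || !tolower(parts[1L]) %in% tolower(expected) ||
        is.na(suppressWarnings(as.numeric(parts[2L])))) {
      stop(sprintf("malformed ASCII grid header at line %d: '%s'",
                   i, lines[i]), call. = FALSE)
    }
    header[[tolower(parts[1L])]] <- as.numeric(parts[2L])
  }
  ncols <- as.integer(header$ncols)
  nrows <- as.integer(header$nrows)
  body <- lines[-(1:6)]
  body <- body[nzchar(trimws(body))]
  if (length(body) != nrows) {
    stop(sprintf("expected %d data rows, found %d (line %d)",
                 nrows, length(body), length(lines)), call. = FALSE)
  }
  vals <- matrix(NA_real_, nrow = nrows, ncol = ncols)
  for (r in seq_len(nrows)) {
    row <- suppressWarnings(as.numeric(strsplit(trimws(body[r]),
                                                "\\s+")[[1L]]))
    if (length(row) != ncols || anyNA(row)) {
      stop(sprintf("malformed ASCII grid data at line %d", r + 6L),
           call. = FALSE)
    }
    vals[nrows - r + 1L, ] <- row    # file rows run north to south
  }
  vals[vals == header$nodata_value] <- NA_real_
  if (is.null(model_name)) model_name <- sub("\\.[^.]*$", "", basename(path))
  concentration_grid(c(header$xllcorner, header$yllcorner), header$cellsize,
                     vals, model_name = model_name)
}

geojson_linestring <- function(polyline, properties) {
  list(type = "Feature",
       geometry = list(type = "LineString",
                       coordinates = unname(lapply(
                         seq_len(nrow(polyline)),
                         function(i) c(polyline[i, 1L], polyline[i, 2L])))),
       properties = properties)
}

geojson_point <- function(x, y, properties) {
  list(type = "Feature",
       geometry = list(type = "Point", coordinates = c(x, y)),
       properties = properties)
}

write_geojson <- function(features, path) {
  fc <- list(type = "FeatureCollection", features = features)
  jsonlite::write_json(fc, path, auto_unbox = TRUE, digits = NA,
                       pretty = FALSE)
  invisible(path)
}

coords_to_matrix <- function(coords) {
  do.call(rbind, lapply(coords, function(p) as.numeric(unlist(p))))
}

#' Write a road network as GeoJSON
#'
#' Segments become LineString features (properties: id, from, to,
#' road_class); nodes become Point features (property: node_id).
#'
#' @param network a [road_network()].
#' @param path output file.
#' @export
write_network_geojson <- function(network, path) {
  segs <- lapply(seq_len(nrow(network$segments)), function(k) {
    s <- network$segments[k, ]
    geojson_linestring(network$geometry[[k]],
                       list(id = s$id, from = s$from, to = s$to,
                            road_class = s$road_class))
  })
  nodes <- lapply(seq_len(nrow(network$nodes)), function(k) {
    n <- network$nodes[k, ]
    geojson_point(n$x, n$y, list(node_id = n$id))
  })
  write_geojson(c(segs, nodes), path)
}

#' Read a road network from GeoJSON written by [write_network_geojson()]
#'
#' @param path input file.
#' @return a [road_network()].
#' @export
read_network_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  if (!identical(fc$type, "FeatureCollection")) {
    stop("not a GeoJSON FeatureCollection", call. = FALSE)
  }
  nodes <- list(); segs <- list()
  for (f in fc$features) {
    if (identical(f$geometry$type, "Point")) {
      nodes[[length(nodes) + 1L]] <- data.frame(
        id = as.integer(f$properties$node_id),
        x = as.numeric(f$geometry$coordinates[[1L]]),
        y = as.numeric(f$geometry$coordinates[[2L]]))
    } else if (identical(f$geometry$type, "LineString")) {
      segs[[length(segs) + 1L]] <- data.frame(
        id = as.integer(f$properties$id),
        from = as.integer(f$properties$from),
        to = as.integer(f$properties$to),
        road_class = f$properties$road_class)
    }
  }
  road_network(do.call(rbind, nodes), do.call(rbind, segs))
}

#' Write classified commuter legs (and waits) as GeoJSON
#'
#' One LineString feature per leg with properties subject_id, trip,
#' direction, leg_id, mode, road_class, start_min, start_hour, duration_min;
#' one Point feature per wait.
#'
#' @param subjects list of routed subjects.
#' @param path output file.
#' @export
write_legs_geojson <- function(subjects, path) {
  features <- list()
  for (s in subjects) {
    for (ti in seq_along(s$trips)) {
      tr <- s$trips[[ti]]
      for (l in tr$legs) {
        features[[length(features) + 1L]] <- geojson_linestring(
          l$polyline,
          list(subject_id = s$id, trip = ti, direction = tr$direction,
               leg_id = l$id, mode = l$mode, road_class = l$road_class,
               start_min = l$start_min, start_hour = clock_hour(l$start_min),
               duration_min = l$duration_min))
      }
      for (w in tr$waits) {
        features[[length(features) + 1L]] <- geojson_point(
          w$x, w$y,
          list(subject_id = s$id, trip = ti, type = "wait",
               start_min = w$start_min, duration_min = w$duration_min,
               road_class = w$road_class))
      }
    }
  }
  write_geojson(features, path)
}

#' Read legs GeoJSON back into leg and wait objects
#'
#' @param path input file.
#' @return list with `legs` (list of [make_leg()] objects, each carrying
#'   `subject_id` and `trip`) and `waits` (list of [make_wait()] objects).
#' @export
read_legs_geojson <- function(path) {
  fc <- jsonlite::read_json(path)
  legs <- list(); waits <- list()
  for (f in fc$features) {
    p <- f$properties
    if (identical(f$geometry$type, "LineString")) {
      l <- make_leg(id = as.integer(p$leg_id),
                    subject_id = as.integer(p$subject_id),
                    mode = p$mode,
                    polyline = coords_to_matrix(f$geometry$coordinates),
                    start_min = as.numeric(p$start_min),
                    duration_min = as.numeric(p$duration_min),
                    road_class = p$road_class)
      l$trip <- as.integer(p$trip)
      l$direction <- p$direction
      legs[[length(legs) + 1L]] <- l
    } else {
      w <- make_wait(as.numeric(f$geometry$coordinates[[1L]]),
                     as.numeric(f$geometry$coordinates[[2L]]),
                     as.numeric(p$start_min), as.numeric(p$duration_min),
                     road_class = p$road_class)
      w$subject_id <- as.integer(p$subject_id)
      w$trip <- as.integer(p$trip)
      waits[[length(waits) + 1L]] <- w
    }
  }
  list(legs = legs, waits = waits)
}

#' Write a data.frame as CSV with a seed-stamped comment header
#'
#' @param df data.frame.
#' @param path output file.
#' @param seed seed recorded in the header comment.
#' @export
write_csv_stamped <- function(df, path, seed = NA) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# no2commute seed=%s", as.character(seed)), con)
  utils::write.csv(df, con, row.names = FALSE)
  invisible(path)
}

#' Read a CSV written by [write_csv_stamped()]
#' @param path input file.
#' @return data.frame.
#' @export
read_csv_stamped <- function(path) {
  utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
}

#' Write station series to CSV (timestamp, site_type, value)
#'
#' @param series named list of `station_series` (from
#'   [generate_station_series()]).
#' @param path output file.
#' @param seed recorded in the header.
#' @export
write_station_csv <- function(series, path, seed = NA) {
  rows <- lapply(series, function(s) {
    data.frame(
      timestamp = sprintf("%s %02d:%02d", as.character(s$date), s$hour,
                          s$minute),
      site_type = attr(s, "site_type"), value = s$value)
  })
  write_csv_stamped(do.call(rbind, rows), path, seed = seed)
}

#' Read station series CSV back into per-site series
#'
#' @param path input file.
#' @return named list of `station_series` data.frames keyed by site type.
#' @export
read_station_csv <- function(path) {
  df <- read_csv_stamped(path)
  out <- lapply(split(df, df$site_type), function(d) {
    structure(data.frame(
      date = as.Date(substr(d$timestamp, 1, 10)),
      hour = as.integer(substr(d$timestamp, 12, 13)),
      minute = as.integer(substr(d$timestamp, 15, 16)),
      value = d$value),
      site_type = d$site_type[1L],
      class = c("station_series", "data.frame"))
  })
  out
}

#' Write / read a ratio table as CSV
#' @param table a [ratio_table()].
#' @param path file path.
#' @param seed recorded in the header.
#' @export
write_ratio_csv <- function(table, path, seed = NA) {
  write_csv_stamped(as.data.frame(table), path, seed = seed)
}

#' @rdname write_ratio_csv
#' @export
read_ratio_csv <- function(path) {
  df <- read_csv_stamped(path)
  ratio_table(df$ratio_m[order(df$hour)], df$ratio_s[order(df$hour)])
}

#' Write a run manifest with input/output hashes
#'
#' @param path output JSON file.
#' @param seed the run seed.
#' @param files character vector of files to hash (md5).
#' @param extra named list of additional metadata.
#' @export
write_manifest <- function(path, seed, files, extra = list()) {
  hashes <- tools::md5sum(files)
  names(hashes) <- basename(names(hashes))
  manifest <- c(list(
    package = "no2commute",
    version = as.character(utils::packageVersion("no2commute")),
    seed = seed,
    created = "run",
    hashes = as.list(hashes)
  ), extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, pretty = TRUE)
  invisible(path)
}
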