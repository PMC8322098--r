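default_land_blocks <- function() {
  # stylized land masses: a large block forcing western routes to detour
  # south, and a small island interior among the chain colonies
  list(greenland = c(lat_min = 60, lat_max = 80, lon_min = -44,
                     lon_max = -32),
       iceland_interior = c(lat_min = 64, lat_max = 66, lon_min = -21,
                            lon_max = -17))
}

#' Rasterized sea geography for a population model
#'
#' A rectangular latitude/longitude grid of water/land cells plus the
#' colony coordinates.  The default layout places the stepping-stone chain
#' colonies in geographic chain order and keeps every colony adjacent to
#' water, so all least-cost sea paths exist.
#'
#' @param model a `pop_model` (colony coordinates are taken from its
#'   `colonies` table).
#' @param cell_deg cell size in degrees (default 2).
#' @param lat_range,lon_range grid extent (degrees).
#' @param land named list of rectangular land blocks
#'   (`lat_min/lat_max/lon_min/lon_max`); `list()` for an all-water grid.
#' @return object of class `geography`: colony coords, cell-center vectors
#'   `lat`/`lon`, logical `water` matrix (lat x lon) and `cell_deg`.
#' @export
make_geography <- function(model, cell_deg = 2,
                           lat_range = c(44, 80), lon_range = c(-66, 36),
                           land = default_land_blocks()) {
  lat <- seq(lat_range[1] + cell_deg / 2, lat_range[2], by = cell_deg)
  lon <- seq(lon_range[1] + cell_deg / 2, lon_range[2], by = cell_deg)
  water <- matrix(TRUE, length(lat), length(lon))
  for (b in land) {
    water[lat > b["lat_min"] & lat < b["lat_max"],
          lon > b["lon_min"] & lon < b["lon_max"]] <- FALSE
  }
  geo <- structure(
    list(coords = model$colonies[, c("name", "lat", "lon")],
         lat = lat, lon = lon, water = water, cell_deg = cell_deg),
    class = "geography")
  snap_colonies(geo)  # validates reachability of a water cell
  geo
}

# nearest water cell per colony; error if farther than 2 cells away
snap_colonies <- function(geo) {
  idx <- matrix(NA_integer_, nrow(geo$coords), 2,
                dimnames = list(geo$coords$name, c("row", "col")))
  for (i in seq_len(nrow(geo$coords))) {
    r0 <- which.min(abs(geo$lat - geo$coords$lat[i]))
    c0 <- which.min(abs(geo$lon - geo$coords$lon[i]))
    found <- FALSE
    for (radius in 0:2) {
      rs <- pmax(1, r0 - radius):pmin(length(geo$lat), r0 + radius)
      cs <- pmax(1, c0 - radius):pmin(length(geo$lon), c0 + radius)
      cand <- expand.grid(row = rs, col = cs)
      cand <- cand[geo$water[as.matrix(cand)], , drop = FALSE]
      if (nrow(cand)) {
        d <- geosphere::distHaversine(
          cbind(geo$lon[cand$col], geo$lat[cand$row]),
          c(geo$coords$lon[i], geo$coords$lat[i]))
        best <- which.min(d)
        idx[i, ] <- c(cand$row[best], cand$col[best])
        found <- TRUE
        break
      }
    }
    if (!found)
      stopf("colony '%s' has no water cell within 2 cells",
            geo$coords$name[i])
  }
  idx
}

#' Least-cost sea distances between colonies
#'
#' Dijkstra shortest paths over the water cells of the raster with
#' 8-neighborhood moves; each edge costs the great-circle distance between
#' cell centers.  Colonies snap to their nearest water cell.
#'
#' @param geo a `geography`.
#' @return symmetric distance matrix in km, labelled by colony.
#' @export
water_lcp_distance <- function(geo) {
  water <- geo$water
  nr <- nrow(water); nc <- ncol(water)
  cell_id <- matrix(0L, nr, nc)
  wcells <- which(water, arr.ind = TRUE)
  cell_id[wcells] <- seq_len(nrow(wcells))
  from <- integer(0); to <- integer(0); w <- numeric(0)
  shifts <- rbind(c(1, 0), c(0, 1), c(1, 1), c(1, -1))
  for (s in seq_len(nrow(shifts))) {
    dr <- shifts[s, 1]; dc <- shifts[s, 2]
    r1 <- wcells[, 1] + dr; c1 <- wcells[, 2] + dc
    ok <- r1 >= 1 & r1 <= nr & c1 >= 1 & c1 <= nc
    ok[ok] <- water[cbind(r1[ok], c1[ok])]
    if (!any(ok)) next
    a <- wcells[ok, , drop = FALSE]
    b <- cbind(r1[ok], c1[ok])
    from <- c(from, cell_id[a])
    to <- c(to, cell_id[b])
    w <- c(w, geosphere::distHaversine(
      cbind(geo$lon[a[, 2]], geo$lat[a[, 1]]),
      cbind(geo$lon[b[, 2]], geo$lat[b[, 1]])) / 1000)
  }
  g <- igraph::make_empty_graph(n = nrow(wcells), directed = FALSE)
  g <- igraph::add_edges(g, rbind(from, to), weight = w)
  snap <- snap_colonies(geo)
  vids <- cell_id[snap]
  d <- igraph::distances(g, v = vids, to = vids, weights =
                           igraph::E(g)$weight, algorithm = "dijkstra")
  dimnames(d) <- list(geo$coords$name, geo$coords$name)
  if (any(!is.finite(d))) {
    bad <- which(!is.finite(d), arr.ind = TRUE)[1, ]
    stopf("no water path between '%s' and '%s'",
          rownames(d)[bad[1]], colnames(d)[bad[2]])
  }
  d
}

#' Write / read a water mask as an ASCII grid raster
#'
#' Standard `ncols/nrows/xllcorner/yllcorner/cellsize` header; water = 1,
#' land = 0; rows from north to south.
#'
#' @param geo a `geography`.
#' @param path file path.
#' @export
write_ascii_grid <- function(geo, path) {
  con <- file(path, "wb")
  on.exit(close(con))
  writeLines(c(sprintf("ncols %d", ncol(geo$water)),
               sprintf("nrows %d", nrow(geo$water)),
               sprintf("xllcorner %g", geo$lon[1] - geo$cell_deg / 2),
               sprintf("yllcorner %g", geo$lat[1] - geo$cell_deg / 2),
               sprintf("cellsize %g", geo$cell_deg),
               "NODATA_value -9999"), con)
  m <- geo$water[rev(seq_len(nrow(geo$water))), , drop = FALSE]
  writeLines(apply(m * 1L, 1, paste, collapse = " "), con)
  invisible(path)
}

#' @rdname write_ascii_grid
#' @param coords colony coordinate tibble (`name`, `lat`, `lon`) to attach.
#' @export
read_ascii_grid <- function(path, coords) {
  hdr <- readLines(path, n = 6)
  val <- function(key) as.numeric(sub(paste0(key, " "), "",
                                      hdr[grepl(key, hdr)]))
  nc <- val("ncols"); nr <- val("nrows")
  cell <- val("cellsize")
  xll <- val("xllcorner"); yll <- val("yllcorner")
  body <- read.table(path, skip = 6)
  m <- unname(as.matrix(body)) == 1
  water <- m[rev(seq_len(nr)), , drop = FALSE]  # back to south-first rows
  structure(list(coords = as_tibble(coords),
                 lat = seq(yll + cell / 2, by = cell, length.out = nr),
                 lon = seq(xll + cell / 2, by = cell, length.out = nc),
                 water = water, cell_deg = cell),
            class = "geography")
}
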