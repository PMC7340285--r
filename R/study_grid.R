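#' Build a synthetic study grid
#'
#' Tiles a rectangular planar study area with square cells and populates every
#' cell with the static covariates used throughout the pipeline: water depth,
#' a contour (seafloor roughness) index, and shortest Euclidean distances from
#' the cell midpoint to four landscape features (mainland coast, an island, a
#' shallow bank, and the 200 m isobath marking the shelf break). Geometry is
#' planar in km; the study area is small enough that projected distances are
#' the natural currency.
#'
#' @param extent_km length-2 numeric, x and y extent of the study area in km.
#' @param cell_km cell side length in km (default 1, i.e. 1 km^2 cells).
#' @param feature_spec optional list of feature point sets, each a two-column
#'   matrix of (x, y) km coordinates, with elements `mainland`, `island`,
#'   `cordell`, `isobath200`. When omitted, [default_feature_spec()] places a
#'   coastline along the eastern edge, an island and a bank offshore, and a
#'   roughly shore-parallel 200 m isobath.
#' @param depth_fun optional function(x, y) returning depth in m (> 0,
#'   positive down); defaults to a shelf/slope profile with a shallow bank.
#'
#' @return A data.frame of class `wk_grid`, one row per cell: `cell_id`, `x`,
#'   `y` (cell midpoints, km), `depth` (m), `contour_index` (0-100),
#'   `dist_mainland`, `dist_island`, `dist_cordell`, `dist_200m` (km).
#'   Grid metadata (extent, cell size, feature spec) is kept in attributes.
#' @export
#' @examples
#' g <- make_study_grid(c(10, 10))
#' nrow(g)  # 100 cells
make_study_grid <- function(extent_km, cell_km = 1, feature_spec = NULL,
                            depth_fun = NULL) {
  if (length(extent_km) == 1L) extent_km <- rep(extent_km, 2L)
  stopifnot(length(extent_km) == 2L, cell_km > 0)
  nx <- extent_km[1] / cell_km
  ny <- extent_km[2] / cell_km
  if (abs(nx - round(nx)) > 1e-9 || abs(ny - round(ny)) > 1e-9) {
    stop_wk("extent_km must be divisible by cell_km")
  }
  nx <- round(nx); ny <- round(ny)
  if (nx <= 1 || ny <= 1) {
    stop_wk("degenerate extent: need more than one cell per axis")
  }
  if (is.null(feature_spec)) feature_spec <- default_feature_spec(extent_km)
  needed <- c("mainland", "island", "cordell", "isobath200")
  missing_f <- setdiff(needed, names(feature_spec))
  if (length(missing_f)) {
    stop_wk("feature_spec missing: ", paste(missing_f, collapse = ", "))
  }

  xs <- (seq_len(nx) - 0.5) * cell_km
  ys <- (seq_len(ny) - 0.5) * cell_km
  grid <- expand.grid(x = xs, y = ys, KEEP.OUT.ATTRS = FALSE)
  grid <- data.frame(cell_id = seq_len(nrow(grid)), grid)

  mid <- as.matrix(grid[, c("x", "y")])
  dist_to <- function(feat) {
    pts <- as.matrix(feature_spec[[feat]])
    apply(cross_dist(mid, pts), 1, min)
  }
  grid$dist_mainland <- dist_to("mainland")
  grid$dist_island <- dist_to("island")
  grid$dist_cordell <- dist_to("cordell")
  grid$dist_200m <- dist_to("isobath200")

  if (is.null(depth_fun)) depth_fun <- default_depth_fun(extent_km, feature_spec)
  grid$depth <- depth_fun(grid$x, grid$y)
  if (any(grid$depth <= 0)) stop_wk("depth_fun produced non-positive depths")

  grid$contour_index <- contour_index_from_depth(grid$depth, nx, ny)

  structure(grid,
            class = c("wk_grid", "data.frame"),
            extent_km = extent_km, cell_km = cell_km,
            nx = nx, ny = ny, feature_spec = feature_spec)
}

#' Default landscape features for the synthetic study area
#'
#' Places a mainland coastline along the eastern edge, an island in the
#' southern half, a shallow bank (the "Cordell" analogue) in the northern
#' half, and a shore-parallel 200 m isobath line at 40% of the x extent.
#' Lines are discretised to points every 0.25 km.
#'
#' @param extent_km length-2 numeric extent in km.
#' @return Named list of (x, y) coordinate matrices.
#' @export
default_feature_spec <- function(extent_km) {
  ex <- extent_km[1]; ey <- extent_km[2]
  yy <- seq(0, ey, by = 0.25)
  list(
    mainland = cbind(x = rep(ex, length(yy)), y = yy),
    island = cbind(x = 0.55 * ex, y = 0.25 * ey),
    cordell = cbind(x = 0.35 * ex, y = 0.75 * ey),
    isobath200 = cbind(x = rep(0.4 * ex, length(yy)), y = yy)
  )
}

# Shelf/slope depth profile: shallow near the coast (eastern edge), 200 m at
# the isobath line, dropping towards 2000 m offshore, with a local shallow
# bump at the bank. Positive down.
default_depth_fun <- function(extent_km, feature_spec) {
  ex <- extent_km[1]
  x_break <- feature_spec$isobath200[1, "x"]
  bank <- feature_spec$cordell[1, ]
  function(x, y) {
    on_shelf <- x >= x_break
    depth <- numeric(length(x))
    # coast (depth ~10 m) to shelf break (200 m)
    depth[on_shelf] <- 200 - (x[on_shelf] - x_break) / (ex - x_break) * 190
    # shelf break to offshore (2000 m)
    depth[!on_shelf] <- 200 + (x_break - x[!on_shelf]) / x_break * 1800
    bump <- 150 * exp(-((x - bank["x"])^2 + (y - bank["y"])^2) / (2 * 2^2))
    pmax(depth - bump, 5)
  }
}

# Contour index per cell: (max depth - min depth) / max depth over the 3x3
# neighbourhood, scaled to 0-100.
contour_index_from_depth <- function(depth, nx, ny) {
  m <- matrix(depth, nrow = nx, ncol = ny)
  ci <- matrix(0, nx, ny)
  for (i in seq_len(nx)) {
    for (j in seq_len(ny)) {
      ii <- max(1, i - 1):min(nx, i + 1)
      jj <- max(1, j - 1):min(ny, j + 1)
      nb <- m[ii, jj]
      ci[i, j] <- (max(nb) - min(nb)) / max(nb) * 100
    }
  }
  as.vector(ci)
}
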