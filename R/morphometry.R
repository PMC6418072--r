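# Per-granule morphometry: area, sub-pixel contour perimeter, equivalent
# radius, round coefficient (isoperimetric ratio), mean gray level,
# dense-core radius and distance to the plasma membrane.

# Moore boundary tracing (8-connected, clockwise) with the
# background-backtrack rule, returning the boundary path (pixel centres)
# and the chain codes. `m` is a logical matrix containing one instance.
trace_boundary <- function(m) {
  H <- nrow(m); W <- ncol(m)
  fg <- which(m)
  rows <- (fg - 1L) %% H + 1L
  cols <- (fg - 1L) %/% H + 1L
  o <- order(cols, rows)
  start <- c(rows[o[1]], cols[o[1]])
  if (length(fg) == 1L) {
    return(list(path = matrix(start, 1, 2), codes = integer(0)))
  }
  # Directions 0..7 clockwise: E, SE, S, SW, W, NW, N, NE (row grows down).
  di <- c(0L, 1L, 1L, 1L, 0L, -1L, -1L, -1L)
  dj <- c(1L, 1L, 0L, -1L, -1L, -1L, 0L, 1L)
  code_of <- matrix(NA_integer_, 3, 3)
  for (d in 0:7) code_of[2L + di[d + 1], 2L + dj[d + 1]] <- d
  inside <- function(i, j) i >= 1L && i <= H && j >= 1L && j <= W && m[i, j]

  cur <- start
  bdir <- 4L                         # backtrack: the background west neighbour
  path <- list(start)
  codes <- integer(0)
  first_entry <- NA_integer_
  steps <- 0L
  max_steps <- 8L * length(fg) + 16L
  repeat {
    steps <- steps + 1L
    if (steps > max_steps) break
    found <- FALSE
    prev_bg <- bdir
    for (t in 1:7) {
      dir <- (bdir + t) %% 8L
      ni <- cur[1] + di[dir + 1]; nj <- cur[2] + dj[dir + 1]
      if (inside(ni, nj)) { found <- TRUE; break }
      prev_bg <- dir
    }
    if (!found) break
    newcur <- c(cur[1] + di[dir + 1], cur[2] + dj[dir + 1])
    # New backtrack: the last background pixel examined, as seen from newcur.
    bg <- c(cur[1] + di[prev_bg + 1], cur[2] + dj[prev_bg + 1])
    bdir <- code_of[2L + (bg[1] - newcur[1]), 2L + (bg[2] - newcur[2])]
    if (all(newcur == start)) {
      if (is.na(first_entry)) {
        # Completed first loop; record and stop (Jacob's criterion reduces
        # to this for simply traced contours).
        codes <- c(codes, dir)
        break
      }
    }
    if (is.na(first_entry)) first_entry <- dir
    codes <- c(codes, dir)
    cur <- newcur
    if (all(cur == start)) break
    path[[length(path) + 1L]] <- cur
  }
  list(path = do.call(rbind, path), codes = codes)
}

# Perimeter from the sub-pixel 0.5-level contour of the instance (the
# mid-crack polygon), smoothed by a cyclic moving average before summing
# segment lengths. Raw pixel-edge counts bias the round coefficient of
# digital circles to ~0.78 and pixel-centre polygons run half a pixel
# inside the true contour; the smoothed mid-crack polygon tracks the
# underlying smooth boundary to well under 1 % for radii >= 5 px,
# restoring the circle -> 1 limit of 4*pi*A/P^2.
smooth_closed_polygon <- function(P, k = 2L) {
  n <- nrow(P)
  if (n < 2L * k + 2L) return(P)
  wrap <- function(i) ((i - 1L) %% n) + 1L
  out <- P
  for (i in seq_len(n)) {
    out[i, ] <- colMeans(P[wrap((i - k):(i + k)), , drop = FALSE])
  }
  out
}

closed_polygon_length <- function(P) {
  d <- rbind(diff(P), P[1, ] - P[nrow(P), ])
  sum(sqrt(rowSums(d^2)))
}

instance_perimeter_px <- function(m_sub) {
  H <- nrow(m_sub); W <- ncol(m_sub)
  z <- matrix(0, H + 2, W + 2)
  z[2:(H + 1), 2:(W + 1)] <- m_sub * 1
  cl <- grDevices::contourLines(x = 0:(H + 1), y = 0:(W + 1), z = z,
                                levels = 0.5)
  sum(vapply(cl, function(cc) {
    closed_polygon_length(smooth_closed_polygon(cbind(cc$x, cc$y)))
  }, numeric(1)))
}

# Minimum distance from a set of points to a polyline (closed or open),
# both in pixel units, points as (row, col).
dist_points_to_polyline <- function(points, poly) {
  stopifnot(nrow(poly) >= 1)
  if (nrow(poly) == 1) {
    return(min(sqrt((points[, 1] - poly[1, 1])^2 +
                    (points[, 2] - poly[1, 2])^2)))
  }
  best <- rep(Inf, nrow(points))
  for (s in seq_len(nrow(poly) - 1)) {
    p1 <- poly[s, ]; p2 <- poly[s + 1, ]
    v <- p2 - p1
    L2 <- sum(v^2)
    if (L2 == 0) {
      d <- sqrt((points[, 1] - p1[1])^2 + (points[, 2] - p1[2])^2)
    } else {
      t <- ((points[, 1] - p1[1]) * v[1] + (points[, 2] - p1[2]) * v[2]) / L2
      t <- pmin(pmax(t, 0), 1)
      d <- sqrt((points[, 1] - (p1[1] + t * v[1]))^2 +
                (points[, 2] - (p1[2] + t * v[2]))^2)
    }
    best <- pmin(best, d)
  }
  min(best)
}

measure_one <- function(m_sub, offset) {
  tr <- trace_boundary(m_sub)
  boundary <- sweep(tr$path, 2, offset, `+`)
  list(boundary = boundary, perimeter_px = instance_perimeter_px(m_sub))
}

#' Measure every granule instance
#'
#' For each labeled instance: area (pixel count scaled by the squared pixel
#' size), perimeter (smoothed sub-pixel contour length), equivalent radius
#' \eqn{\sqrt{A/\pi}}, round coefficient \eqn{4\pi A / P^2} (the
#' isoperimetric ratio: 1 for a circle, lower for elongated or irregular
#' shapes), mean gray level over the instance's pixels, and optionally the
#' dense-core equivalent radius (cores matched to parent granules by
#' maximal pixel overlap) and the distance from the granule's outer
#' boundary to the plasma-membrane polyline. Membrane distance is measured
#' boundary-to-membrane, not centroid-to-membrane: the ~40 nm docking scale
#' is a membrane-to-membrane gap, far smaller than a granule radius.
#'
#' @param imap An `instance_map` (or integer label matrix).
#' @param img The underlying [gray_image] (or intensity matrix; when a bare
#'   matrix is given, `pixel_size_nm` must be supplied).
#' @param cores Optional core `instance_map` for dense-core radii.
#' @param membrane Optional membrane polyline, n x 2 matrix of 1-based
#'   (row, col) points.
#' @param pixel_size_nm Pixel size override when `img` is a bare matrix.
#' @return A tibble with one row per granule: `id`, `centroid_row`,
#'   `centroid_col` (1-based), `area_px`, `area_nm2`, `perimeter_nm`,
#'   `equiv_radius_nm`, `core_radius_nm`, `round_coefficient`, `mean_gray`,
#'   `membrane_distance_nm` and a `boundary` list-column.
#' @export
measure_granules <- function(imap, img, cores = NULL, membrane = NULL,
                             pixel_size_nm = NULL) {
  m <- unclass(imap)
  px_img <- as_pixels(img)
  if (!all(dim(m) == dim(px_img))) abort("instance map and image differ in size")
  px_nm <- if (inherits(img, "gray_image")) img$pixel_size_nm else pixel_size_nm
  if (is.null(px_nm)) abort("supply `pixel_size_nm` when `img` is a bare matrix")
  K <- max(m)
  ids <- seq_len(K)

  core_match <- NULL
  if (!is.null(cores)) {
    cm <- unclass(cores)
    sel <- cm > 0L & m > 0L
    if (any(sel)) {
      ov <- table(core = cm[sel], granule = m[sel])
      core_areas <- tabulate(cm[cm > 0L], nbins = max(cm))
      core_match <- rep(NA_real_, K)
      for (ci in rownames(ov)) {
        parent <- as.integer(colnames(ov)[which.max(ov[ci, ])])
        a <- core_areas[as.integer(ci)]
        r <- sqrt(a * px_nm^2 / pi)
        if (is.na(core_match[parent]) || r > core_match[parent]) {
          core_match[parent] <- r
        }
      }
    } else {
      core_match <- rep(NA_real_, K)
    }
  }

  rows <- vector("list", K)
  H <- nrow(m)
  for (id in ids) {
    idx <- which(m == id)
    if (length(idx) == 0) abort(sprintf("instance id %d not found", id))
    ri <- (idx - 1L) %% H + 1L
    ci <- (idx - 1L) %/% H + 1L
    i1 <- min(ri); i2 <- max(ri); j1 <- min(ci); j2 <- max(ci)
    sub <- matrix(FALSE, i2 - i1 + 3L, j2 - j1 + 3L)
    sub[cbind(ri - i1 + 2L, ci - j1 + 2L)] <- TRUE
    mo <- measure_one(sub, c(i1 - 2L, j1 - 2L))
    area_px <- length(idx)
    area_nm2 <- area_px * px_nm^2
    per_nm <- mo$perimeter_px * px_nm
    md <- if (!is.null(membrane)) {
      dist_points_to_polyline(mo$boundary, membrane) * px_nm
    } else NA_real_
    rows[[id]] <- tibble(
      id = id,
      centroid_row = mean(ri), centroid_col = mean(ci),
      area_px = area_px, area_nm2 = area_nm2,
      perimeter_nm = per_nm,
      equiv_radius_nm = sqrt(area_nm2 / pi),
      core_radius_nm = if (is.null(core_match)) NA_real_ else core_match[id],
      round_coefficient = 4 * pi * area_px / mo$perimeter_px^2,
      mean_gray = mean(px_img[idx]),
      membrane_distance_nm = md,
      boundary = list(mo$boundary)
    )
  }
  if (K == 0) {
    return(tibble(
      id = integer(0), centroid_row = numeric(0), centroid_col = numeric(0),
      area_px = integer(0), area_nm2 = numeric(0), perimeter_nm = numeric(0),
      equiv_radius_nm = numeric(0), core_radius_nm = numeric(0),
      round_coefficient = numeric(0), mean_gray = numeric(0),
      membrane_distance_nm = numeric(0), boundary = list()
    ))
  }
  bind_rows(rows)
}

#' @rdname measure_granules
#' @param id Instance label to measure.
#' @export
measure_granule <- function(imap, id, img, cores = NULL, membrane = NULL,
                            pixel_size_nm = NULL) {
  m <- unclass(imap)
  if (!any(m == id)) abort(sprintf("instance id %s not found", id))
  tab <- measure_granules(imap, img, cores = cores, membrane = membrane,
                          pixel_size_nm = pixel_size_nm)
  tab[tab$id == id, ]
}

#' Granule density per unit cytoplasm area, across cells
#'
#' The density is computed per cell (granule count over cytoplasm area,
#' nucleus excluded) and then averaged; the s.e.m. is taken across cells,
#' not across granules, matching per-cell reporting of population
#' statistics.
#'
#' @param n_granules_per_cell Integer vector, one count per cell.
#' @param cytoplasm_area_um2_per_cell Positive areas in square microns.
#' @return One-row tibble: `mean_density_per_um2`, `sem`, `n_cells`,
#'   `n_granules`, `sem_defined` (FALSE when only one cell, where the
#'   s.e.m. is reported as 0).
#' @export
granule_density <- function(n_granules_per_cell, cytoplasm_area_um2_per_cell) {
  if (length(n_granules_per_cell) != length(cytoplasm_area_um2_per_cell)) {
    abort("per-cell vectors differ in length")
  }
  if (any(cytoplasm_area_um2_per_cell <= 0)) abort("cell areas must be positive")
  dens <- n_granules_per_cell / cytoplasm_area_um2_per_cell
  n <- length(dens)
  tibble(
    mean_density_per_um2 = mean(dens),
    sem = if (n > 1) sd(dens) / sqrt(n) else 0,
    n_cells = n,
    n_granules = sum(n_granules_per_cell),
    sem_defined = n > 1
  )
}

#' Distance from one granule to the plasma membrane
#'
#' Minimum Euclidean distance from any point of the granule's outer
#' boundary to any segment of the membrane polyline, in nm; 0 if the
#' boundary touches the membrane.
#'
#' @param record One-row tibble from [measure_granules()] (uses its
#'   `boundary` column), or an n x 2 boundary matrix.
#' @param membrane_polyline n x 2 matrix of (row, col) points in pixels.
#' @param pixel_size_nm Physical pixel size.
#' @return Distance in nm.
#' @export
membrane_distance <- function(record, membrane_polyline, pixel_size_nm) {
  if (nrow(membrane_polyline) == 0) abort("membrane polyline is empty")
  boundary <- if (is.matrix(record)) record else record$boundary[[1]]
  dist_points_to_polyline(boundary, membrane_polyline) * pixel_size_nm
}

#' Membrane-distance profile
#'
#' Histogram of granule–membrane distances in bins
#' `[k*bin_width, (k+1)*bin_width)` up to `max_nm` (a distance exactly
#' equal to `max_nm` falls in the last bin), plus relative frequencies
#' normalised over the granules within `max_nm`.
#'
#' @param distances Numeric vector of distances in nm, or a tibble with a
#'   `membrane_distance_nm` column.
#' @param bin_width_nm Positive bin width.
#' @param max_nm Upper limit of the profile.
#' @return Tibble with `bin_lo_nm`, `bin_hi_nm`, `count`, `rel_freq`.
#' @export
distance_profile <- function(distances, bin_width_nm, max_nm) {
  if (bin_width_nm <= 0) abort("`bin_width_nm` must be positive")
  d <- if (is.data.frame(distances)) distances$membrane_distance_nm else distances
  d <- d[!is.na(d)]
  nb <- ceiling(max_nm / bin_width_nm)
  lo <- (seq_len(nb) - 1) * bin_width_nm
  hi <- pmin(lo + bin_width_nm, max_nm)
  idx <- floor(d / bin_width_nm) + 1
  idx[d == max_nm] <- nb
  idx <- idx[d >= 0 & d <= max_nm]
  counts <- tabulate(idx, nbins = nb)
  total <- sum(counts)
  tibble(
    bin_lo_nm = lo, bin_hi_nm = hi, count = counts,
    rel_freq = if (total > 0) counts / total else rep(0, nb)
  )
}

#' Compare two granule populations
#'
#' `kind = "mean"` runs a two-sided two-sample Student's t-test (equal
#' variances, as in classical per-cell comparisons); `kind =
#' "distribution"` a two-sample Kolmogorov–Smirnov test, whose statistic is
#' the supremum of the absolute ECDF difference.
#'
#' @param a,b Numeric samples.
#' @param kind `"mean"` or `"distribution"`.
#' @return One-row tibble: `method`, `statistic`, `p_value`, `n_a`, `n_b`.
#' @export
compare_groups <- function(a, b, kind = c("mean", "distribution")) {
  kind <- match.arg(kind)
  if (length(a) == 0 || length(b) == 0) abort("both samples must be nonempty")
  if (kind == "mean") {
    if (length(a) < 2 || length(b) < 2) {
      abort("t-test requires at least 2 observations per sample")
    }
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tibble(method = "t", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_a = length(a), n_b = length(b))
  } else {
    ht <- suppressWarnings(stats::ks.test(a, b))
    tibble(method = "ks", statistic = unname(ht$statistic),
           p_value = ht$p.value, n_a = length(a), n_b = length(b))
  }
}
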