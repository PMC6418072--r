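#' Specification of a synthetic beta-cell micrograph
#'
#' Describes one FIB-SEM-like scene: a smooth cytoplasm blob bounded by the
#' plasma membrane, round granules rendered as a bright halo annulus around
#' an electron-dense (dark) core, an optional dark nucleus-like distractor,
#' a multiplicative illumination gradient and additive Gaussian noise.
#' Granule radii span the 100–800 nm diameter range reported for insulin
#' granules; a configurable fraction of dense cores are rod-shaped
#' (capsules) rather than discs.
#'
#' Intensities must satisfy core < cytoplasm < halo: the dense core is the
#' darkest structure and the halo the brightest, as in EM images of large
#' dense-core vesicles. The requested density must be feasible: the
#' expected total granule area has to stay below 60 % of the cytoplasm
#' area, otherwise non-overlapping placement cannot succeed.
#'
#' @param image_size_px Integer pair (height, width), each >= 32.
#' @param pixel_size_nm Physical pixel size in nm.
#' @param target_density_per_um2 Mean granule density per square micron of
#'   cytoplasm; the realized count is Poisson with this mean times the
#'   cytoplasm area.
#' @param granule_radius_range_nm Radius interval, a sub-interval of
#'   `[50, 400]` nm (granule diameters 100–800 nm).
#' @param core_to_granule_radius_ratio Dense-core radius as a fraction of
#'   the granule radius, in (0, 1).
#' @param rod_core_fraction Probability that a core is a rod (capsule with
#'   aspect ratio drawn in `[2, 4]`) instead of a disc.
#' @param halo_intensity,core_intensity,cytoplasm_intensity 8-bit gray
#'   levels of the three structures.
#' @param illumination_gradient_amplitude Relative amplitude of the
#'   multiplicative illumination field (0 disables it).
#' @param illumination_type `"planar"` (linear ramp, default) or
#'   `"vignette"` (radial falloff).
#' @param noise_sigma Standard deviation of additive Gaussian noise in gray
#'   levels (0 for noise-free scenes).
#' @param nucleus_present Render a dark nucleus-like blob as a distractor?
#' @param seed Integer seed; scenes are bit-reproducible given the spec.
#' @return A list of class `scene_spec`.
#' @export
scene_spec <- function(image_size_px = c(128, 128),
                       pixel_size_nm = 20,
                       target_density_per_um2 = 1.5,
                       granule_radius_range_nm = c(60, 240),
                       core_to_granule_radius_ratio = 0.55,
                       rod_core_fraction = 0.2,
                       halo_intensity = 200,
                       core_intensity = 40,
                       cytoplasm_intensity = 120,
                       illumination_gradient_amplitude = 0.15,
                       illumination_type = c("planar", "vignette"),
                       noise_sigma = 8,
                       nucleus_present = TRUE,
                       seed = 1L) {
  illumination_type <- match.arg(illumination_type)
  if (length(image_size_px) != 2 || any(image_size_px < 32)) {
    abort("`image_size_px` must be two integers >= 32")
  }
  if (pixel_size_nm <= 0) abort("`pixel_size_nm` must be positive")
  if (target_density_per_um2 < 0) abort("density must be >= 0")
  rr <- granule_radius_range_nm
  if (length(rr) != 2 || rr[1] > rr[2] || rr[1] < 50 || rr[2] > 400) {
    abort("`granule_radius_range_nm` must be a nonempty interval within [50, 400]")
  }
  if (core_to_granule_radius_ratio <= 0 || core_to_granule_radius_ratio >= 1) {
    abort("`core_to_granule_radius_ratio` must lie in (0, 1)")
  }
  if (rod_core_fraction < 0 || rod_core_fraction > 1) {
    abort("`rod_core_fraction` must lie in [0, 1]")
  }
  ints <- c(core_intensity, cytoplasm_intensity, halo_intensity)
  if (any(ints < 0 | ints > 255)) abort("intensities must lie in [0, 255]")
  if (!(core_intensity < cytoplasm_intensity &&
        cytoplasm_intensity < halo_intensity)) {
    abort("intensities must be ordered core < cytoplasm < halo")
  }
  if (illumination_gradient_amplitude < 0 || noise_sigma < 0) {
    abort("illumination amplitude and noise sigma must be >= 0")
  }
  # Feasibility: expected granule area must be < 60 % of the cytoplasm.
  mean_area_um2 <- pi * (rr[1]^2 + rr[1] * rr[2] + rr[2]^2) / 3 / 1e6
  if (target_density_per_um2 * mean_area_um2 >= 0.6) {
    abort("infeasible density: expected granule area >= 60 % of cytoplasm")
  }
  structure(list(
    image_size_px = as.integer(image_size_px),
    pixel_size_nm = pixel_size_nm,
    target_density_per_um2 = target_density_per_um2,
    granule_radius_range_nm = rr,
    core_to_granule_radius_ratio = core_to_granule_radius_ratio,
    rod_core_fraction = rod_core_fraction,
    halo_intensity = halo_intensity,
    core_intensity = core_intensity,
    cytoplasm_intensity = cytoplasm_intensity,
    illumination_gradient_amplitude = illumination_gradient_amplitude,
    illumination_type = illumination_type,
    noise_sigma = noise_sigma,
    nucleus_present = isTRUE(nucleus_present),
    seed = as.integer(seed)
  ), class = "scene_spec")
}

# Gray levels of structures the spec does not parameterize.
BACKGROUND_INTENSITY <- 75
NUCLEUS_INTENSITY <- 45

# Area of the intersection of two discs at centre distance d.
disc_overlap_area <- function(d, r1, r2) {
  if (d >= r1 + r2) return(0)
  rmin <- min(r1, r2)
  if (d <= abs(r1 - r2)) return(pi * rmin^2)
  a1 <- r1^2 * acos((d^2 + r1^2 - r2^2) / (2 * d * r1))
  a2 <- r2^2 * acos((d^2 + r2^2 - r1^2) / (2 * d * r2))
  a3 <- 0.5 * sqrt(pmax((-d + r1 + r2) * (d + r1 - r2) *
                        (d - r1 + r2) * (d + r1 + r2), 0))
  a1 + a2 - a3
}

#' Generate one synthetic micrograph with full ground truth
#'
#' Deterministic given the spec (including its seed). The granule count is
#' Poisson with mean density x cytoplasm area; centres are placed by
#' rejection sampling so that every granule lies fully inside the cytoplasm
#' and no two granule interiors overlap by more than 20 % of the smaller
#' area — touching and moderately fused granules are produced on purpose so
#' the watershed splitter is exercised on its hard case. Discs are rendered
#' with anti-aliased (sub-pixel coverage) edges so that radii measured on
#' noise-free scenes recover ground truth to sub-pixel accuracy.
#'
#' @param spec A [scene_spec()].
#' @return A list of class `scene_truth` with elements `image`
#'   ([gray_image]), `granule_instances` and `core_instances` (integer
#'   label matrices, 0 background), `cytoplasm_mask` (logical matrix,
#'   nucleus excluded), `nucleus_mask` (logical matrix, all-FALSE when no
#'   nucleus is rendered), `k_drawn` (the Poisson count before placement;
#'   equal to the number of placed granules unless placement fell short
#'   within the 5 % tolerance), `membrane_polyline` (closed polygon of the cell
#'   boundary, n x 2 matrix of 1-based (row, col)), `granule_params`
#'   (tibble of ground-truth centres, radii and core shapes) and `spec`.
#' @export
generate_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  with_seed(spec$seed, generate_scene_impl(spec))
}

generate_scene_impl <- function(spec) {
  H <- spec$image_size_px[1]; W <- spec$image_size_px[2]
  px <- spec$pixel_size_nm
  rowm <- matrix(seq_len(H), H, W)
  colm <- matrix(seq_len(W), H, W, byrow = TRUE)

  # Cell blob (the cytoplasm boundary is the plasma membrane).
  cy <- H / 2 + runif(1, -2, 2)
  cx <- W / 2 + runif(1, -2, 2)
  r0 <- 0.46 * min(H, W)
  dy <- rowm - cy; dx <- colm - cx
  d_c <- sqrt(dy^2 + dx^2)
  th <- atan2(dy, dx)
  # Draw harmonic coefficients once, reuse for raster and polyline.
  harm <- lapply(2:4, function(k) {
    list(k = k, a = runif(1, -0.02, 0.02), phi = runif(1, 0, 2 * pi))
  })
  radial <- function(theta) {
    r <- rep(r0, length(theta))
    for (h in harm) r <- r + r0 * h$a * cos(h$k * theta + h$phi)
    r
  }
  cell_cov <- pmin(pmax(radial(as.vector(th)) - as.vector(d_c) + 0.5, 0), 1)
  cell_cov <- matrix(cell_cov, H, W)

  # Membrane polyline: the analytic cell contour, closed.
  ths <- seq(0, 2 * pi, length.out = 361)[-361]
  rb <- radial(ths)
  membrane <- cbind(row = cy + rb * sin(ths), col = cx + rb * cos(ths))
  membrane <- rbind(membrane, membrane[1, , drop = FALSE])

  # Optional dark nucleus-like distractor inside the cell.
  nuc_cov <- matrix(0, H, W)
  if (spec$nucleus_present) {
    beta <- runif(1, 0, 2 * pi)
    ncy <- cy + 0.45 * r0 * sin(beta)
    ncx <- cx + 0.45 * r0 * cos(beta)
    rn <- 0.33 * r0
    nharm <- lapply(2:3, function(k) {
      list(k = k, a = runif(1, -0.05, 0.05), phi = runif(1, 0, 2 * pi))
    })
    ndy <- rowm - ncy; ndx <- colm - ncx
    nd <- sqrt(ndy^2 + ndx^2)
    nth <- atan2(ndy, ndx)
    nr <- rep(rn, length(nth))
    for (h in nharm) nr <- nr + rn * h$a * cos(h$k * as.vector(nth) + h$phi)
    nuc_cov <- matrix(pmin(pmax(nr - as.vector(nd) + 0.5, 0), 1), H, W)
  }

  cyt_mask <- (cell_cov >= 0.5) & !(nuc_cov >= 0.5)
  cyt_area_um2 <- sum(cyt_mask) * (px / 1000)^2

  # Poisson granule count, rejection-sampled placement.
  K <- rpois(1, spec$target_density_per_um2 * cyt_area_um2)
  dist_in <- as.matrix(EBImage::distmap(cyt_mask))
  cyt_idx <- which(cyt_mask)
  rr_px <- spec$granule_radius_range_nm / px
  acc_row <- acc_col <- acc_r <- numeric(0)
  attempts <- 0L
  budget <- 300L * K + 100L
  while (length(acc_r) < K && attempts < budget) {
    attempts <- attempts + 1L
    pix <- cyt_idx[sample.int(length(cyt_idx), 1)]
    i <- (pix - 1L) %% H + 1L
    j <- (pix - 1L) %/% H + 1L
    gr <- i + runif(1, -0.5, 0.5)
    gc <- j + runif(1, -0.5, 0.5)
    r_px <- runif(1, rr_px[1], rr_px[2])
    if (dist_in[i, j] < r_px + 1) next
    ok <- TRUE
    if (length(acc_r) > 0) {
      dd <- sqrt((acc_row - gr)^2 + (acc_col - gc)^2)
      near <- which(dd < acc_r + r_px)
      for (m in near) {
        ov <- disc_overlap_area(dd[m], acc_r[m], r_px)
        if (ov > 0.2 * pi * min(acc_r[m], r_px)^2) { ok <- FALSE; break }
      }
    }
    if (!ok) next
    acc_row <- c(acc_row, gr); acc_col <- c(acc_col, gc)
    acc_r <- c(acc_r, r_px)
  }
  placed <- length(acc_r)
  if (K > 0 && (K - placed) / K > 0.05) {
    abort(sprintf(
      "infeasible density: placed %d of %d granules after %d attempts",
      placed, K, attempts))
  }

  # Core shapes.
  rho <- spec$core_to_granule_radius_ratio
  is_rod <- if (placed > 0) {
    as.logical(rbinom(placed, 1, spec$rod_core_fraction))
  } else logical(0)
  core_w <- core_a <- core_ang <- numeric(placed)
  for (k in seq_len(placed)) {
    if (is_rod[k]) {
      s <- runif(1, 2, 4)
      w <- rho * acc_r[k] * sqrt(pi / (pi + 4 * (s - 1)))
      a <- (s - 1) * w
      if (a + w > 0.85 * acc_r[k]) {
        f <- 0.85 * acc_r[k] / (a + w)
        a <- a * f; w <- w * f
      }
      core_w[k] <- w; core_a[k] <- a; core_ang[k] <- runif(1, 0, 2 * pi)
    } else {
      core_w[k] <- rho * acc_r[k]
      core_a[k] <- 0
      core_ang[k] <- 0
    }
  }

  # Render: background, cytoplasm, nucleus, then granules (halo over core).
  img <- BACKGROUND_INTENSITY * (1 - cell_cov) +
    spec$cytoplasm_intensity * cell_cov
  img <- img * (1 - nuc_cov) + NUCLEUS_INTENSITY * nuc_cov

  glab <- matrix(0L, H, W)
  best <- matrix(-Inf, H, W)
  boxes <- vector("list", placed)
  for (k in seq_len(placed)) {
    r <- acc_r[k]
    i1 <- max(1L, floor(acc_row[k] - r - 2)); i2 <- min(H, ceiling(acc_row[k] + r + 2))
    j1 <- max(1L, floor(acc_col[k] - r - 2)); j2 <- min(W, ceiling(acc_col[k] + r + 2))
    bi <- i1:i2; bj <- j1:j2
    ldy <- outer(bi - acc_row[k], rep(1, length(bj)))
    ldx <- outer(rep(1, length(bi)), bj - acc_col[k])
    ld <- sqrt(ldy^2 + ldx^2)
    cov <- pmin(pmax(r - ld + 0.5, 0), 1)
    img[bi, bj] <- img[bi, bj] * (1 - cov) + spec$halo_intensity * cov
    # Core depth: positive inside the dense core.
    if (is_rod[k]) {
      u <- c(sin(core_ang[k]), cos(core_ang[k]))        # (row, col) direction
      t <- ldy * u[1] + ldx * u[2]
      tc <- pmin(pmax(t, -core_a[k]), core_a[k])
      dseg <- sqrt((ldy - tc * u[1])^2 + (ldx - tc * u[2])^2)
      depth_c <- core_w[k] - dseg
    } else {
      depth_c <- core_w[k] - ld
    }
    cov_c <- pmin(pmax(depth_c + 0.5, 0), 1)
    img[bi, bj] <- img[bi, bj] * (1 - cov_c) + spec$core_intensity * cov_c
    # Instance assignment: a contested pixel goes to the more interior granule.
    depth <- r - ld
    sel <- depth >= 0 & depth > best[bi, bj]
    sub_l <- glab[bi, bj]; sub_b <- best[bi, bj]
    sub_l[sel] <- k; sub_b[sel] <- depth[sel]
    glab[bi, bj] <- sub_l; best[bi, bj] <- sub_b
    boxes[[k]] <- list(bi = bi, bj = bj, depth_c = depth_c)
  }
  # Second pass: cores, constrained to their parent's final pixels.
  clab <- matrix(0L, H, W)
  for (k in seq_len(placed)) {
    b <- boxes[[k]]
    sel <- b$depth_c >= 0 & glab[b$bi, b$bj] == k
    sub <- clab[b$bi, b$bj]
    sub[sel] <- k
    clab[b$bi, b$bj] <- sub
  }

  # Multiplicative illumination field.
  A <- spec$illumination_gradient_amplitude
  if (A > 0) {
    if (spec$illumination_type == "planar") {
      phi <- runif(1, 0, 2 * pi)
      proj <- (rowm - H / 2) * sin(phi) + (colm - W / 2) * cos(phi)
      field <- 1 + A * proj / max(abs(proj))
    } else {
      dd <- sqrt((rowm - H / 2)^2 + (colm - W / 2)^2)
      field <- 1 - A * (dd / max(dd))^2
    }
    img <- img * field
  }
  if (spec$noise_sigma > 0) {
    img <- img + rnorm(length(img), 0, spec$noise_sigma)
  }
  img <- matrix(as.integer(round(pmin(pmax(img, 0), 255))), H, W)

  params <- tibble(
    id = seq_len(placed),
    center_row = acc_row, center_col = acc_col,
    radius_px = acc_r, radius_nm = acc_r * px,
    is_rod = is_rod,
    core_halfwidth_px = core_w, core_halflength_px = core_a,
    core_angle = core_ang
  )
  structure(list(
    image = gray_image(img, px),
    granule_instances = structure(glab, class = c("instance_map", "matrix", "array")),
    core_instances = structure(clab, class = c("instance_map", "matrix", "array")),
    cytoplasm_mask = cyt_mask,
    nucleus_mask = nuc_cov >= 0.5,
    membrane_polyline = membrane,
    granule_params = params,
    k_drawn = K,
    spec = spec
  ), class = "scene_truth")
}

#' @export
print.scene_truth <- function(x, ...) {
  cat(sprintf(
    "<scene_truth> %d x %d px @ %.3g nm/px, %d granules (%d rod cores), nucleus: %s\n",
    nrow(x$image$pixels), ncol(x$image$pixels), x$image$pixel_size_nm,
    nrow(x$granule_params), sum(x$granule_params$is_rod),
    if (x$spec$nucleus_present) "yes" else "no"))
  invisible(x)
}

#' Semantic training pair from a ground-truth scene
#'
#' @param truth A `scene_truth` from [generate_scene()].
#' @return List with `image` ([gray_image]) and `labels` (integer 0/1
#'   matrix, 1 exactly where a granule instance lies).
#' @export
scene_to_training_pair <- function(truth) {
  stopifnot(inherits(truth, "scene_truth"))
  lab <- matrix(as.integer(unclass(truth$granule_instances) > 0),
                nrow = nrow(truth$granule_instances))
  list(image = truth$image, labels = lab)
}

#' Generate a seeded cohort of scenes
#'
#' Per-scene seeds are `seed + 0:(n-1)`, so a cohort is reproducible from
#' one master seed and individual scenes can be regenerated in isolation.
#'
#' @param n Number of scenes.
#' @param spec Base [scene_spec()]; its `seed` field is overridden.
#' @param seed Master seed of the cohort.
#' @return List of `scene_truth` objects.
#' @export
simulate_scenes <- function(n, spec = scene_spec(), seed = 1L) {
  lapply(seq_len(n), function(i) {
    s <- spec
    s$seed <- as.integer(seed + i - 1L)
    generate_scene(s)
  })
}
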