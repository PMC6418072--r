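#' Run configuration for the segmentation pipeline
#'
#' Collects every tunable of the pipeline in one object that maps
#' field-for-field onto the YAML config consumed by the command-line
#' wrapper. Defaults derive from the granule-size prior (diameters
#' 100–800 nm): the minimum watershed seed separation is the minimum
#' granule diameter expressed in pixels, and the instance-area gate is the
#' same prior converted to pixel areas.
#'
#' @param pixel_size_nm Physical pixel size in nm (no universal default
#'   exists for FIB-SEM; synthetic scenes declare their own).
#' @param binarization_threshold Granule-class probability above which a
#'   pixel is foreground, in (0, 1).
#' @param min_seed_separation_px Minimum distance between watershed seeds;
#'   default 100 nm / `pixel_size_nm`.
#' @param smoothing_sigma_px Gaussian sigma applied to the distance map
#'   before seed detection.
#' @param matching_iou_threshold IoU at or above which a predicted granule
#'   matches a ground-truth granule, in (0, 1).
#' @param membrane_bin_width_nm Bin width of the membrane-distance profile.
#' @param min_area_px,max_area_px Instance-area gate; defaults are the
#'   100 nm and 800 nm diameter discs at `pixel_size_nm`.
#' @param epochs,batch_size,learning_rate Training hyperparameters.
#' @param seed Master seed; fans out to parameter initialisation and data
#'   shuffling.
#' @param network A [network_spec()].
#' @return A list of class `granuleseg_config`.
#' @export
run_config <- function(pixel_size_nm = 20,
                       binarization_threshold = 0.5,
                       min_seed_separation_px = 100 / pixel_size_nm,
                       smoothing_sigma_px = 1,
                       matching_iou_threshold = 0.5,
                       membrane_bin_width_nm = 20,
                       min_area_px = floor(pi * (50 / pixel_size_nm)^2),
                       max_area_px = ceiling(pi * (400 / pixel_size_nm)^2),
                       epochs = 8,
                       batch_size = 4,
                       learning_rate = 1e-3,
                       seed = 0L,
                       network = network_spec()) {
  in_open_unit <- function(x) is.numeric(x) && length(x) == 1 && x > 0 && x < 1
  if (pixel_size_nm <= 0) abort("`pixel_size_nm` must be positive")
  if (!in_open_unit(binarization_threshold)) {
    abort("`binarization_threshold` must lie in (0, 1)")
  }
  if (!in_open_unit(matching_iou_threshold)) {
    abort("`matching_iou_threshold` must lie in (0, 1)")
  }
  if (min_seed_separation_px <= 0 || smoothing_sigma_px < 0) {
    abort("watershed parameters must be positive")
  }
  if (membrane_bin_width_nm <= 0) abort("`membrane_bin_width_nm` must be positive")
  if (min_area_px < 0 || max_area_px <= min_area_px) {
    abort("need 0 <= min_area_px < max_area_px")
  }
  seed <- as.integer(seed)
  if (is.na(seed)) abort("`seed` must be a fixed integer")
  structure(list(
    pixel_size_nm = pixel_size_nm,
    binarization_threshold = binarization_threshold,
    min_seed_separation_px = min_seed_separation_px,
    smoothing_sigma_px = smoothing_sigma_px,
    matching_iou_threshold = matching_iou_threshold,
    membrane_bin_width_nm = membrane_bin_width_nm,
    min_area_px = min_area_px,
    max_area_px = max_area_px,
    epochs = as.integer(epochs),
    batch_size = as.integer(batch_size),
    learning_rate = learning_rate,
    seed = seed,
    network = network
  ), class = "granuleseg_config")
}

#' Read or write a pipeline configuration as YAML
#'
#' @param path YAML file path.
#' @param cfg A [run_config()] object.
#' @return `read_config()` returns a `granuleseg_config`; `write_config()`
#'   returns `path` invisibly.
#' @export
read_config <- function(path) {
  y <- yaml::read_yaml(path)
  net <- if (is.null(y$network)) network_spec() else {
    do.call(network_spec, y$network[setdiff(names(y$network), "n_classes")])
  }
  y$network <- NULL
  do.call(run_config, c(y, list(network = net)))
}

#' @rdname read_config
#' @export
write_config <- function(cfg, path) {
  y <- unclass(cfg)
  y$network <- unclass(y$network)
  yaml::write_yaml(y, path)
  invisible(path)
}
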