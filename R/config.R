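#' Pipeline configuration
#'
#' All tunables of the matching and reconstruction pipeline with their
#' defaults: 3x3 median preprocessing; Lowe-style detection settings;
#' the 8-ring x 8-bin descriptor with 8 px maximum radius; NNDR ratio
#' 0.8; voting thresholds `T_theta = 0.3`, `T_d = 0.4`; 20% trim;
#' 4-pair RANSAC with inlier threshold 2 px (2000 iterations cap,
#' confidence 0.995); Sampson threshold 2 px for the epipolar stage;
#' and the RNG seed. Every field is validated with an error naming the
#' offending field.
#'
#' @param ... named overrides of the defaults listed above.
#' @return A validated `pipeline_config` list.
#' @export
pipeline_config <- function(...) {
  cfg <- list(
    median_window = 3L,
    layers_per_octave = 3L,
    base_sigma = 1.6,
    contrast_threshold = 0.03,
    edge_ratio = 10,
    field_order = 2L,
    rings = 8L,
    bins = 8L,
    radius_per_ring = 1,
    nndr_ratio = 0.8,
    T_theta = 0.3,
    T_d = 0.4,
    trim_fraction = 0.2,
    ransac_sample = 4L,
    ransac_threshold = 2,
    ransac_max_iterations = 2000L,
    ransac_confidence = 0.995,
    sampson_threshold = 2,
    reproj_ceiling = 2,
    seed = 1L)
  over <- list(...)
  if (length(over) == 1L && is.list(over[[1L]]) && is.null(names(over)))
    over <- over[[1L]]
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown) > 0L)
    stop("unknown config field(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  cfg[names(over)] <- over
  validate_config(cfg)
}

validate_config <- function(cfg) {
  chk <- function(field, ok)
    if (!isTRUE(ok)) stop("invalid config field `", field, "`",
                          call. = FALSE)
  num1 <- function(x) length(x) == 1L && is.numeric(x) && is.finite(x)
  chk("median_window", num1(cfg$median_window) && cfg$median_window >= 3 &&
        cfg$median_window %% 2 == 1)
  chk("layers_per_octave", num1(cfg$layers_per_octave) &&
        cfg$layers_per_octave >= 3)
  chk("base_sigma", num1(cfg$base_sigma) && cfg$base_sigma > 0)
  chk("contrast_threshold", num1(cfg$contrast_threshold) &&
        cfg$contrast_threshold >= 0)
  chk("edge_ratio", num1(cfg$edge_ratio) && cfg$edge_ratio > 1)
  chk("field_order", num1(cfg$field_order) && cfg$field_order %in% 1:2)
  chk("rings", num1(cfg$rings) && cfg$rings >= 1)
  chk("bins", num1(cfg$bins) && cfg$bins >= 2)
  chk("radius_per_ring", num1(cfg$radius_per_ring) &&
        cfg$radius_per_ring > 0)
  chk("nndr_ratio", num1(cfg$nndr_ratio) && cfg$nndr_ratio > 0 &&
        cfg$nndr_ratio <= 1)
  chk("T_theta", num1(cfg$T_theta) && cfg$T_theta > 0)
  chk("T_d", num1(cfg$T_d) && cfg$T_d > 0)
  chk("trim_fraction", num1(cfg$trim_fraction) && cfg$trim_fraction >= 0 &&
        cfg$trim_fraction < 1)
  chk("ransac_sample", num1(cfg$ransac_sample) && cfg$ransac_sample >= 4)
  chk("ransac_threshold", num1(cfg$ransac_threshold) &&
        cfg$ransac_threshold > 0)
  chk("ransac_max_iterations", num1(cfg$ransac_max_iterations) &&
        cfg$ransac_max_iterations >= 1)
  chk("ransac_confidence", num1(cfg$ransac_confidence) &&
        cfg$ransac_confidence > 0 && cfg$ransac_confidence < 1)
  chk("sampson_threshold", num1(cfg$sampson_threshold) &&
        cfg$sampson_threshold > 0)
  chk("reproj_ceiling", num1(cfg$reproj_ceiling) && cfg$reproj_ceiling > 0)
  chk("seed", num1(cfg$seed))
  structure(cfg, class = "pipeline_config")
}

#' Load a pipeline configuration from YAML or JSON
#'
#' Unspecified fields keep their [pipeline_config()] defaults; unknown
#' fields are an error.
#'
#' @param path YAML (preferred) or JSON file.
#' @return A `pipeline_config`.
#' @export
load_config <- function(path) {
  if (!file.exists(path))
    stop("config file does not exist: ", path, call. = FALSE)
  vals <- tryCatch(yaml::read_yaml(path), error = function(e) NULL)
  if (is.null(vals))
    vals <- tryCatch(jsonlite::fromJSON(path), error = function(e)
      stop("cannot parse config as YAML or JSON: ", path, call. = FALSE))
  do.call(pipeline_config, as.list(vals))
}

# ransac_config views of a pipeline_config for the two robust stages
homography_ransac_config <- function(cfg) {
  ransac_config(trim_fraction = cfg$trim_fraction,
                sample_size = cfg$ransac_sample,
                inlier_threshold = cfg$ransac_threshold,
                max_iterations = cfg$ransac_max_iterations,
                confidence = cfg$ransac_confidence,
                seed = cfg$seed)
}

epipolar_ransac_config <- function(cfg) {
  ransac_config(trim_fraction = 0,
                sample_size = 8L,
                inlier_threshold = cfg$sampson_threshold,
                max_iterations = cfg$ransac_max_iterations,
                confidence = cfg$ransac_confidence,
                seed = cfg$seed)
}
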