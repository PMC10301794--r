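#' Pipeline defaults
#'
#' All tunable thresholds and physical constants of the pipeline in one
#' nested list. Values can be overridden by supplying a (possibly partial)
#' list or a YAML file with the same structure; unnamed entries keep their
#' defaults.
#'
#' Units: lengths in mm, color temperatures in Kelvin, exposure times in ms.
#'
#' @param overrides optional named list (or path to a YAML file) with values
#'   overriding the defaults; nested lists are merged recursively.
#' @return nested list of configuration values.
#' @export
el_config <- function(overrides = NULL) {
  cfg <- list(
    color = list(
      # neutral color gamut point (5500 K) and its spreads in chromaticity
      gamut = list(
        r = 0.363, g = 0.338, b = 0.299,
        sigma_r = 0.0723, sigma_g = 0.0097, sigma_b = 0.0749,
        # exposure band as fractions of max intensity, linear domain
        i_min = 0.02 / 12.92,
        i_max = ((0.98 + 0.055) / 1.055)^2.4
      ),
      max_intensity = 3,
      # ellipse tests use sigma^2 denominators (standard deviations);
      # FALSE reproduces the literal unsquared form
      ellipse_sigma_squared = TRUE
    ),
    awb = list(
      sensor_k_range = c(2500, 6500),
      virtual_k_range = c(2000, 9000),
      neutral_k = 5500,
      e_threshold = 1.758e-8,
      e_improve_threshold = 1e-15,
      estar_mode = "renormalized",   # or "printed"
      max_iter = 200,
      jitter_window = 20,
      jitter_step = 1,
      jitter_consec_max = 10
    ),
    exposure = list(
      n_bins = 256,
      tau_frame = 100,      # optimal per-frame exposure, ms
      tau_delta = 1,        # hardware exposure step, ms
      n_tau = 5,            # steps taken at |skewness| = 1
      tau_range = c(0.1, 200),
      gain_range = c(1, 16)
    ),
    segmentation = list(
      smooth_sigma = 1.5,       # px, Gaussian support 5x5
      grad_sigma = 8,           # mm, gradient-weight falloff
      edge_primary = 12,        # mm, upper Canny limit
      edge_minor = 3.5,         # mm, lower Canny limit
      d_near = 200,             # mm, closest valid depth
      min_component = 200       # px
    ),
    meshing = list(
      min_uv_area = 0.25,       # px^2
      min_uv_edge = 0.5,        # px
      skinny_angle = 13,        # degrees
      skinny_sigma_factor = 4,
      min_patch_triangles = 100
    ),
    registration = list(
      normal_max_angle = 30,    # degrees; cos(30 deg) compatibility cut
      normal_compat = "angle",  # "angle" or "dot98"
      l_min = 1.0,              # mm
      max_runs = 30,
      inner_max_iter = 50,
      inner_tol = 1e-6,
      voxel = 6,                # mm, registration downsampling pitch
      init_first_frontal = FALSE
    ),
    marker = list(
      disc_radius = 5,          # mm, red clip head disk
      ring_width = 2,           # mm, blue boundary ring
      min_samples = 20,
      n_electrodes = 67
    ),
    calibration = list(
      n_bins = 256,
      median_size = 7,
      peak_sigma_factor = 1.9,
      min_peak_bins = 5,
      defaults = list(
        red  = list(r = 0.75, g = 0.08, sigma_r = 0.1,  sigma_g = 0.06, phi = 0),
        blue = list(r = 0.05, g = 0.13, sigma_r = 0.02, sigma_g = 0.06, phi = 0)
      )
    )
  )
  if (is.null(overrides)) return(cfg)
  if (is.character(overrides)) overrides <- yaml::read_yaml(overrides)
  modify_list_rec(cfg, overrides)
}

modify_list_rec <- function(base, over) {
  for (nm in names(over)) {
    if (is.list(over[[nm]]) && is.list(base[[nm]])) {
      base[[nm]] <- modify_list_rec(base[[nm]], over[[nm]])
    } else {
      base[[nm]] <- over[[nm]]
    }
  }
  base
}

#' Default marker-color calibration
#'
#' The red/blue chromaticity ellipses used to segment electrode-marker pixels
#' before a scene-specific calibration is available.
#'
#' @param cfg pipeline configuration, see [el_config()].
#' @return object of class `marker_calibration`.
#' @export
default_marker_calibration <- function(cfg = el_config()) {
  d <- cfg$calibration$defaults
  new_marker_calibration(
    red  = d$red, blue = d$blue
  )
}

new_marker_calibration <- function(red, blue) {
  structure(list(red = red, blue = blue), class = "marker_calibration")
}

#' @export
print.marker_calibration <- function(x, ...) {
  cat("Marker color calibration (chromaticity ellipses)\n")
  for (nm in c("red", "blue")) {
    e <- x[[nm]]
    cat(sprintf("  %-4s center (%.3f, %.3f)  sigma (%.4f, %.4f)  phi %.1f deg\n",
                nm, e$r, e$g, e$sigma_r, e$sigma_g, e$phi * 180 / pi))
  }
  invisible(x)
}
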