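#' Specification of a synthetic fluorescence field
#'
#' Describes the imaging model the generator emulates: diffraction-limited
#' puncta rendered as isotropic 2D Gaussians (sigma = `psf_sigma_nm`) at
#' random, minimally separated sub-pixel positions, on a constant background,
#' with per-spot, per-channel amplitudes drawn log-normally around the channel
#' means (coefficient of variation `amplitude_cv`), then corrupted by shot
#' noise. Defaults place the canonical geometry at a 160 nm pixel size with a
#' 480 nm FWHM point-spread function, i.e. 800 nm spans 5 pixels.
#'
#' @param n_spots number of puncta to plant.
#' @param image_shape_px `c(height, width)` in pixels.
#' @param pixel_size_nm physical pixel size.
#' @param psf_sigma_nm point-spread standard deviation (default FWHM 480 nm).
#' @param background_level constant background intensity.
#' @param noise_model `"poisson"` (shot noise, default), `"gaussian"`
#'   (additive, sd `gaussian_sd`), `"poisson_gaussian"` (shot plus read
#'   noise), or `"none"`.
#' @param channel_amplitude_means named vector of mean peak amplitudes above
#'   background per channel role.
#' @param amplitude_cv log-normal coefficient of variation of per-spot
#'   amplitudes (default 0.5, a broad per-synapse spread).
#' @param copy_ratio_culture_vs_synaptosome ground-truth ratio by which
#'   [simulate_pair()] scales the culture protein-of-interest amplitudes.
#' @param min_separation_nm minimum pairwise distance between planted spots.
#' @param margin_nm exclusion margin from the borders, at least half the
#'   fitting ROI so every planted spot is fittable.
#' @param gaussian_sd additive noise sd for the gaussian models; defaults to
#'   `sqrt(background_level)` (shot-noise scale at background).
#' @param read_noise_sd read noise for `"poisson_gaussian"`.
#' @param seed integer; fully determines the rendered field.
#' @return an object of class `simulation_spec`.
#' @export
simulation_spec <- function(n_spots = 60L,
                            image_shape_px = c(256L, 256L),
                            pixel_size_nm = 160,
                            psf_sigma_nm = 480 / (2 * sqrt(2 * log(2))),
                            background_level = 100,
                            noise_model = c("poisson", "gaussian",
                                            "poisson_gaussian", "none"),
                            channel_amplitude_means = c(marker = 800,
                                                        active_zone = 600,
                                                        poi = 500),
                            amplitude_cv = 0.5,
                            copy_ratio_culture_vs_synaptosome = 1,
                            min_separation_nm = 1600,
                            margin_nm = 1280,
                            gaussian_sd = NULL,
                            read_noise_sd = 3,
                            seed = 1L) {
  noise_model <- match.arg(noise_model)
  stopifnot(n_spots >= 0, length(image_shape_px) == 2L,
            pixel_size_nm > 0, psf_sigma_nm > 0, background_level > 0,
            all(channel_amplitude_means > 0), amplitude_cv >= 0,
            copy_ratio_culture_vs_synaptosome > 0, min_separation_nm > 0)
  if (is.null(names(channel_amplitude_means))) {
    stop("simulation_spec(): channel_amplitude_means must be named by role",
         call. = FALSE)
  }
  if (is.null(gaussian_sd)) gaussian_sd <- sqrt(background_level)
  structure(
    list(n_spots = as.integer(n_spots),
         image_shape_px = as.integer(image_shape_px),
         pixel_size_nm = pixel_size_nm, psf_sigma_nm = psf_sigma_nm,
         background_level = background_level, noise_model = noise_model,
         channel_amplitude_means = channel_amplitude_means,
         amplitude_cv = amplitude_cv,
         copy_ratio_culture_vs_synaptosome = copy_ratio_culture_vs_synaptosome,
         min_separation_nm = min_separation_nm, margin_nm = margin_nm,
         gaussian_sd = gaussian_sd, read_noise_sd = read_noise_sd,
         seed = as.integer(seed)),
    class = "simulation_spec"
  )
}

# Draw n minimally separated continuous positions inside the margins.
place_spots <- function(n, shape, margin_px, min_sep_px) {
  if (n == 0L) return(data.frame(x = numeric(), y = numeric()))
  lo_y <- margin_px + 1; hi_y <- shape[1] - margin_px
  lo_x <- margin_px + 1; hi_x <- shape[2] - margin_px
  if (hi_y <= lo_y || hi_x <= lo_x) {
    stop("simulate: image too small for the requested margin", call. = FALSE)
  }
  xs <- numeric(0); ys <- numeric(0)
  tries <- 0L
  while (length(xs) < n) {
    tries <- tries + 1L
    if (tries > 2000L * n) {
      stop(sprintf(
        "simulate: could not place %d spots with %.3g px separation (packing too dense)",
        n, min_sep_px), call. = FALSE)
    }
    x <- runif(1, lo_x, hi_x); y <- runif(1, lo_y, hi_y)
    if (length(xs) == 0L ||
        all((xs - x)^2 + (ys - y)^2 >= min_sep_px^2)) {
      xs <- c(xs, x); ys <- c(ys, y)
    }
  }
  data.frame(x = xs, y = ys)
}

# Render isotropic Gaussian spots onto a background raster (local windows of
# +/- 6 sigma; truncation beyond that is < 1e-7 of the spot mass).
render_spots <- function(shape, positions, amplitudes, sigma_px, background) {
  img <- matrix(background, shape[1], shape[2])
  w <- as.integer(ceiling(6 * sigma_px))
  for (i in seq_len(nrow(positions))) {
    x0 <- positions$x[i]; y0 <- positions$y[i]
    s <- if (is.null(positions$sigma_px)) sigma_px else positions$sigma_px[i]
    wi <- max(w, as.integer(ceiling(6 * s)))
    xs <- max(1L, floor(x0 - wi)):min(shape[2], ceiling(x0 + wi))
    ys <- max(1L, floor(y0 - wi)):min(shape[1], ceiling(y0 + wi))
    gx <- exp(-(xs - x0)^2 / (2 * s^2))
    gy <- exp(-(ys - y0)^2 / (2 * s^2))
    img[ys, xs] <- img[ys, xs] + amplitudes[i] * outer(gy, gx)
  }
  img
}

apply_noise <- function(img, spec) {
  switch(spec$noise_model,
         none = img,
         gaussian = img + rnorm(length(img), 0, spec$gaussian_sd),
         poisson = matrix(rpois(length(img), pmax(img, 0)), nrow(img), ncol(img)),
         poisson_gaussian = matrix(rpois(length(img), pmax(img, 0)),
                                   nrow(img), ncol(img)) +
           rnorm(length(img), 0, spec$read_noise_sd))
}

# Log-normal multiplicative factors with unit mean and the given CV.
lognormal_factors <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  sdlog <- sqrt(log(1 + cv^2))
  rlnorm(n, meanlog = -sdlog^2 / 2, sdlog = sdlog)
}

#' Simulate one multi-channel field with ground truth
#'
#' Renders `n_spots` puncta per the [simulation_spec()]; every channel shares
#' the spot positions (channels are registered views of the same synapses)
#' with independent log-normal amplitude variation around its channel mean.
#' Deterministic given `spec$seed`.
#'
#' @param spec a [simulation_spec()].
#' @param sample_kind sample type of the produced field.
#' @param field_id identifier.
#' @param amplitude_scale optional named multipliers applied to
#'   `channel_amplitude_means` (used by [simulate_pair()]).
#' @return list with `field` (an [image_field()]) and `truth` (long data
#'   frame `spot, x_px, y_px, role, amplitude, integrated_intensity`, where
#'   `integrated_intensity = 2 * pi * amplitude * sigma_px^2` exactly).
#' @export
simulate_field <- function(spec, sample_kind = "synaptosome",
                           field_id = "sim", amplitude_scale = NULL) {
  stopifnot(inherits(spec, "simulation_spec"))
  set.seed(spec$seed)
  px <- spec$pixel_size_nm
  sigma_px <- nm_to_px(spec$psf_sigma_nm, px)
  margin_px <- ceiling(nm_to_px(spec$margin_nm, px))
  min_sep_px <- nm_to_px(spec$min_separation_nm, px)
  pos <- place_spots(spec$n_spots, spec$image_shape_px, margin_px, min_sep_px)
  roles <- names(spec$channel_amplitude_means)
  channels <- vector("list", length(roles))
  truth <- list()
  for (j in seq_along(roles)) {
    role <- roles[j]
    amp_mean <- spec$channel_amplitude_means[[role]]
    if (!is.null(amplitude_scale) && role %in% names(amplitude_scale)) {
      amp_mean <- amp_mean * amplitude_scale[[role]]
    }
    amps <- amp_mean * lognormal_factors(spec$n_spots, spec$amplitude_cv)
    clean <- render_spots(spec$image_shape_px, pos, amps, sigma_px,
                          spec$background_level)
    channels[[j]] <- apply_noise(clean, spec)
    if (spec$n_spots > 0L) {
      truth[[j]] <- data.frame(spot = seq_len(spec$n_spots),
                               x_px = pos$x, y_px = pos$y, role = role,
                               amplitude = amps,
                               integrated_intensity = 2 * pi * amps * sigma_px^2,
                               stringsAsFactors = FALSE)
    }
  }
  field <- image_field(channels, roles, px, field_id = field_id,
                       sample_kind = sample_kind)
  truth <- if (length(truth) > 0L) do.call(rbind, truth) else
    data.frame(spot = integer(), x_px = numeric(), y_px = numeric(),
               role = character(), amplitude = numeric(),
               integrated_intensity = numeric())
  attr(truth, "sigma_px") <- sigma_px
  list(field = field, truth = truth)
}

#' Simulate a matched synaptosome/culture pair
#'
#' Emulates parallel immunostaining of a biochemically characterised
#' synaptosome lawn and a neuronal culture: both fields share the point
#' spread, background and noise model; the culture's protein-of-interest
#' amplitudes are scaled by the ground-truth copy ratio
#' `spec$copy_ratio_culture_vs_synaptosome`. Spot positions and amplitude
#' draws are independent between the fields, as they are between real
#' samples.
#'
#' @param spec a [simulation_spec()].
#' @return list with `synaptosome`, `culture` (each an [image_field()]),
#'   `truth_synaptosome`, `truth_culture`, and `copy_ratio`.
#' @export
simulate_pair <- function(spec) {
  stopifnot(inherits(spec, "simulation_spec"))
  syn <- simulate_field(spec, sample_kind = "synaptosome",
                        field_id = "sim_synaptosome")
  spec_cult <- spec
  spec_cult$seed <- spec$seed + 1L
  cult <- simulate_field(
    spec_cult, sample_kind = "culture", field_id = "sim_culture",
    amplitude_scale = c(poi = spec$copy_ratio_culture_vs_synaptosome))
  list(synaptosome = syn$field, culture = cult$field,
       truth_synaptosome = syn$truth, truth_culture = cult$truth,
       copy_ratio = spec$copy_ratio_culture_vs_synaptosome)
}

#' Simulate a single-antibody calibration field
#'
#' Plants spots whose integrated intensity is `k` times the unit-antibody
#' intensity (linear summation of antibody labels), with multiplicative
#' log-normal variation, plus optional oversized "dirt" spots whose FWHM
#' exceeds the debris cutoff, for testing the calibration's size rejection.
#' The channel role is `calibration`; the unit-antibody peak amplitude is
#' `spec$channel_amplitude_means[["calibration"]]`.
#'
#' @param spec a [simulation_spec()] with a `calibration` amplitude mean.
#' @param k_antibodies_per_spot integer vector (one `k >= 1` per spot);
#'   overrides `spec$n_spots`.
#' @param n_dirt number of oversized debris spots to add.
#' @param dirt_fwhm_nm debris width (default 80 nm, above the 50 nm cutoff).
#' @return list with `field`, `truth` (per-spot `k`, amplitude, integrated
#'   intensity, `is_dirt`), and `unit_integrated_intensity` (the ground-truth
#'   single-antibody integrated intensity).
#' @export
simulate_antibody_field <- function(spec, k_antibodies_per_spot,
                                    n_dirt = 0L, dirt_fwhm_nm = 80) {
  stopifnot(inherits(spec, "simulation_spec"),
            all(k_antibodies_per_spot >= 1L))
  if (!"calibration" %in% names(spec$channel_amplitude_means)) {
    stop("simulate_antibody_field(): spec needs a 'calibration' amplitude mean",
         call. = FALSE)
  }
  set.seed(spec$seed)
  px <- spec$pixel_size_nm
  sigma_px <- nm_to_px(spec$psf_sigma_nm, px)
  dirt_sigma_px <- nm_to_px(dirt_fwhm_nm / (2 * sqrt(2 * log(2))), px)
  n <- length(k_antibodies_per_spot)
  margin_px <- ceiling(nm_to_px(spec$margin_nm, px))
  min_sep_px <- nm_to_px(spec$min_separation_nm, px)
  pos <- place_spots(n + n_dirt, spec$image_shape_px, margin_px, min_sep_px)
  unit_amp <- spec$channel_amplitude_means[["calibration"]]
  k <- c(as.numeric(k_antibodies_per_spot), rep(1, n_dirt))
  amps <- unit_amp * k * lognormal_factors(n + n_dirt, spec$amplitude_cv)
  is_dirt <- c(rep(FALSE, n), rep(TRUE, n_dirt))
  pos$sigma_px <- ifelse(is_dirt, dirt_sigma_px, sigma_px)
  clean <- render_spots(spec$image_shape_px, pos, amps, sigma_px,
                        spec$background_level)
  img <- apply_noise(clean, spec)
  field <- image_field(list(img), "calibration", px,
                       field_id = "sim_calibration",
                       sample_kind = "calibration")
  truth <- data.frame(spot = seq_len(n + n_dirt), x_px = pos$x, y_px = pos$y,
                      k = k, amplitude = amps,
                      integrated_intensity = 2 * pi * amps * pos$sigma_px^2,
                      is_dirt = is_dirt, stringsAsFactors = FALSE)
  list(field = field, truth = truth,
       unit_integrated_intensity = 2 * pi * unit_amp * sigma_px^2)
}
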