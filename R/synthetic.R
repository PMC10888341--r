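# Synthetic RGBC dataset generator.
#
# Emulates the experimental designs used in colour-sensor authentication of
# avocado oil: pure oil analysed in 25 replicates plus blends with five
# adulterant oils, acquired under a white or a 395 nm UV illuminant, each
# acquisition being the average of 10 sensor readings.

#' Default endmember chromaticities
#'
#' Reflectance-like (R, G, B) factors in (0, 1) for each oil under each
#' illuminant. Virgin avocado oil is green-dominant and dark; refined oils
#' are paler and mutually distinct; olive oil (also virgin) sits closest to
#' avocado. The UV set is deliberately less separated: in practice the UV
#' response mixes weak reflectance with fluorescence and discriminates the
#' oils less cleanly than white light.
#'
#' @return Named list with elements `white` and `uv`, each a 6 x 3 matrix
#'   (rows = oils, columns = R, G, B).
#' @export
default_endmembers <- function() {
  white <- rbind(
    avocado   = c(0.32, 0.52, 0.16),
    canola    = c(0.55, 0.62, 0.30),
    sunflower = c(0.62, 0.58, 0.34),
    corn      = c(0.58, 0.52, 0.24),
    olive     = c(0.40, 0.46, 0.28),
    soybean   = c(0.52, 0.66, 0.42)
  )
  uv <- rbind(
    avocado   = c(0.18, 0.24, 0.40),
    canola    = c(0.22, 0.26, 0.44),
    sunflower = c(0.24, 0.25, 0.46),
    corn      = c(0.23, 0.27, 0.43),
    olive     = c(0.20, 0.22, 0.42),
    soybean   = c(0.24, 0.28, 0.47)
  )
  colnames(white) <- colnames(uv) <- c("R", "G", "B")
  list(white = white, uv = uv)
}

#' Configuration of the synthetic sensor model
#'
#' @param endmembers Per-illuminant matrices of endmember chromaticities as
#'   returned by [default_endmembers()].
#' @param clear_scale Positive count magnitude of the clear (C) channel; RGB
#'   counts are `clear_scale` times the mixed chromaticity. Default 20000,
#'   a typical magnitude for a 16-bit RGBC sensor at 24 ms integration.
#' @param noise_sd Relative standard deviation of the multiplicative Gaussian
#'   noise applied to every single reading (before averaging). Default 0.01.
#' @param nonlinearity Mixing-curvature coefficient, >= 0. 0 gives exactly
#'   linear count-space mixing; 1 (default) gives full log-domain
#'   (Beer-Lambert-like) mixing, so blends are mildly nonlinear in count
#'   space. Intermediate values interpolate.
#' @param n_readings Number of single readings averaged per acquisition
#'   (default 10).
#' @param uv_noise_factor Multiplier applied to `noise_sd` under the UV
#'   illuminant (default 2), reproducing the noisier UV response.
#' @param seed Integer seed recorded in the configuration and used by the
#'   dataset generators.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(endmembers = default_endmembers(),
                             clear_scale = 20000,
                             noise_sd = 0.01,
                             nonlinearity = 1,
                             n_readings = 10L,
                             uv_noise_factor = 2,
                             seed = 1L) {
  if (!is.numeric(clear_scale) || length(clear_scale) != 1L || clear_scale <= 0)
    stop("`clear_scale` must be a positive number", call. = FALSE)
  if (!is.numeric(noise_sd) || length(noise_sd) != 1L || noise_sd < 0)
    stop("`noise_sd` must be >= 0", call. = FALSE)
  if (!is.numeric(nonlinearity) || length(nonlinearity) != 1L || nonlinearity < 0)
    stop("`nonlinearity` must be >= 0", call. = FALSE)
  n_readings <- as.integer(n_readings)
  if (is.na(n_readings) || n_readings < 1L)
    stop("`n_readings` must be a positive integer", call. = FALSE)
  if (!is.numeric(uv_noise_factor) || uv_noise_factor <= 0)
    stop("`uv_noise_factor` must be positive", call. = FALSE)
  for (illum in illuminant_levels()) {
    em <- endmembers[[illum]]
    if (is.null(em) || !is.matrix(em) || ncol(em) != 3L ||
        !all(oil_levels() %in% rownames(em)))
      stop("`endmembers$", illum, "` must be a matrix with one (R,G,B) row ",
           "per oil: ", paste(oil_levels(), collapse = ", "), call. = FALSE)
    if (any(!is.finite(em)) || any(em <= 0) || any(em >= 1))
      stop("endmember chromaticities must lie strictly in (0, 1)",
           call. = FALSE)
  }
  structure(
    list(endmembers = endmembers, clear_scale = clear_scale,
         noise_sd = noise_sd, nonlinearity = nonlinearity,
         n_readings = n_readings, uv_noise_factor = uv_noise_factor,
         seed = as.integer(seed)),
    class = "synthetic_config"
  )
}

#' High-noise synthetic profile
#'
#' The default configuration with the per-reading noise raised to a level at
#' which low-fraction blends overlap pure avocado oil in feature space. Under
#' this profile linear discriminants on the imbalanced pure-vs-blended task
#' collapse to the majority class on held-out data, the failure mode
#' reported for LDA on real sensor data. (On the calibration set itself the
#' collapse can be marginally incomplete: Kennard-Stone deliberately selects
#' the most extreme pure replicates into calibration, and those outliers
#' remain classifiable whenever any signal survives.)
#'
#' @param seed Integer seed.
#' @param noise_sd Per-reading relative noise (default 0.25).
#' @return Object of class `synthetic_config`.
#' @export
high_noise_config <- function(seed = 1L, noise_sd = 0.25) {
  synthetic_config(noise_sd = noise_sd, seed = seed)
}

# Mixed chromaticity of a blend: weight w = cfg$nonlinearity interpolates
# between linear count-space mixing (w = 0) and geometric (log-absorbance)
# mixing (w = 1).
mix_endmembers <- function(e_base, e_adult, fraction, nonlinearity) {
  linear <- (1 - fraction) * e_base + fraction * e_adult
  geometric <- exp((1 - fraction) * log(e_base) + fraction * log(e_adult))
  linear + nonlinearity * (geometric - linear)
}

#' Simulate one averaged sensor acquisition
#'
#' Mixes the avocado endmember with the adulterant endmember at the given
#' fraction, scales to channel counts, applies per-reading multiplicative
#' Gaussian noise, and averages `cfg$n_readings` readings. The clear channel
#' has a constant mean of `cfg$clear_scale` for every oil and is clamped to
#' stay >= each of R, G, B.
#'
#' @param adulterant Oil name; must differ from "avocado" unless
#'   `fraction = 0`.
#' @param fraction Blend mass fraction in `[0, 0.5]`.
#' @param illuminant `"white"` or `"uv"`.
#' @param cfg A [synthetic_config()].
#' @return A [raw_reading()] with real-valued averaged channel counts.
#' @export
simulate_sample <- function(adulterant, fraction, illuminant, cfg) {
  stopifnot(inherits(cfg, "synthetic_config"))
  check_illuminant(illuminant)
  check_oil(adulterant)
  if (!is.numeric(fraction) || length(fraction) != 1L ||
      fraction < 0 || fraction > 0.5)
    stop("`fraction` must lie in [0, 0.5]", call. = FALSE)
  if (adulterant == "avocado" && fraction > 0)
    stop("avocado is the base oil; the adulterant must be another oil ",
         "unless fraction = 0", call. = FALSE)
  em <- cfg$endmembers[[illuminant]]
  mixed <- mix_endmembers(em["avocado", ], em[adulterant, ], fraction,
                          cfg$nonlinearity)
  mu <- c(mixed * cfg$clear_scale, cfg$clear_scale)  # R, G, B, C means
  sd_rel <- cfg$noise_sd * if (illuminant == "uv") cfg$uv_noise_factor else 1
  if (sd_rel > 0) {
    eps <- matrix(rnorm(4L * cfg$n_readings, mean = 1, sd = sd_rel),
                  nrow = 4L)
    counts <- rowMeans(mu * eps)
  } else {
    counts <- mu
  }
  counts <- pmax(counts, 0)
  counts[4L] <- max(counts)  # C >= max(R, G, B) by construction
  raw_reading(counts[1L], counts[2L], counts[3L], counts[4L],
              illuminant = illuminant)
}

# One fully-specified sample row (raw counts + normalized features).
synth_row <- function(sample_id, oil, fraction, replicate, illuminant, cfg) {
  raw <- simulate_sample(oil, fraction, illuminant, cfg)
  feat <- normalize_reading(raw)
  data.frame(sample_id = sample_id, oil = oil, fraction = fraction,
             replicate = as.integer(replicate), illuminant = illuminant,
             R = raw$R, G = raw$G, B = raw$B, C = raw$C,
             r = feat[["r"]], g = feat[["g"]], b = feat[["b"]],
             stringsAsFactors = FALSE)
}

classification_fractions <- function() c(0.05, 0.10, 0.20, 0.35, 0.50)

#' Generate the 150-sample classification dataset
#'
#' 25 replicates of pure avocado oil plus 5 adulterant oils x 5 blend
#' fractions (5, 10, 20, 35, 50 %) x 5 replicates = 150 samples, each with
#' averaged raw counts and C-normalized features.
#'
#' @param cfg A [synthetic_config()]; `cfg$seed` fixes the dataset.
#' @param illuminant `"white"` (default) or `"uv"`.
#' @return An [oil_dataset()] with task `"classification"`.
#' @export
generate_classification_dataset <- function(cfg = synthetic_config(),
                                            illuminant = "white") {
  stopifnot(inherits(cfg, "synthetic_config"))
  check_illuminant(illuminant)
  set.seed(cfg$seed)
  rows <- vector("list", 150L)
  k <- 0L
  for (rep in seq_len(25L)) {
    k <- k + 1L
    rows[[k]] <- synth_row(sprintf("avocado_000_r%02d", rep), "avocado",
                           0, rep, illuminant, cfg)
  }
  for (oil in adulterant_levels()) {
    for (f in classification_fractions()) {
      for (rep in seq_len(5L)) {
        k <- k + 1L
        rows[[k]] <- synth_row(
          sprintf("%s_%03.0f_r%02d", oil, 100 * f, rep),
          oil, f, rep, illuminant, cfg)
      }
    }
  }
  oil_dataset(do.call(rbind, rows), task = "classification",
              provenance = list(source = "synthetic", seed = cfg$seed))
}

#' Generate a 55-sample calibration (regression) dataset
#'
#' Blend fractions 0 to 50 % in 5 % steps x 5 replicates for one adulterant
#' oil; the true fraction is the regression target.
#'
#' @param adulterant One of the five adulterant oils (not "avocado").
#' @param cfg A [synthetic_config()].
#' @param illuminant `"white"` (default) or `"uv"`.
#' @return An [oil_dataset()] with task `"regression"`.
#' @export
generate_calibration_dataset <- function(adulterant,
                                         cfg = synthetic_config(),
                                         illuminant = "white") {
  stopifnot(inherits(cfg, "synthetic_config"))
  check_illuminant(illuminant)
  check_oil(adulterant)
  if (adulterant == "avocado")
    stop("`adulterant` must be one of: ",
         paste(adulterant_levels(), collapse = ", "), call. = FALSE)
  set.seed(cfg$seed)
  fractions <- seq(0, 0.5, by = 0.05)
  rows <- vector("list", 55L)
  k <- 0L
  for (f in fractions) {
    for (rep in seq_len(5L)) {
      k <- k + 1L
      oil <- if (f == 0) "avocado" else adulterant
      rows[[k]] <- synth_row(
        sprintf("%s_%03.0f_r%02d", oil, 100 * f, rep),
        oil, f, rep, illuminant, cfg)
    }
  }
  oil_dataset(do.call(rbind, rows), task = "regression",
              provenance = list(source = "synthetic", seed = cfg$seed,
                                adulterant = adulterant))
}
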