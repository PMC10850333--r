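#' Configuration for the synthetic NIR spectra generator
#'
#' The generator emulates the statistical structure the pipeline assumes of
#' the instrument data: 230 samples of 125-channel reflectance over
#' 950-1650 nm, a smooth continuum carrying overlapping Gaussian absorption
#' bands whose depths vary linearly with the impurity mass fraction in
#' roughly [0.03, 0.20], degraded by per-sample multiplicative scatter, an
#' additive baseline offset, and per-channel noise. Band loadings are
#' negative by default: absorption subtracts reflectance from the
#' continuum.
#'
#' @param n_samples,n_channels dataset shape (defaults 230 x 125).
#' @param wavelength_range nm pair, default `c(950, 1650)`.
#' @param target_range impurity-fraction pair, default `c(0.03, 0.20)`.
#' @param informative_bands list of `c(center_nm, width_nm, loading)`
#'   triples; width is the Gaussian standard deviation in nm.
#' @param scatter_sd sd of the multiplicative scatter factor `a_i ~ N(1, .)`.
#' @param baseline_sd sd of the additive baseline offset `c_i ~ N(0, .)`.
#' @param noise_sd sd of per-channel additive noise.
#' @param seed RNG seed.
#' @return Object of class `synthetic_config`.
#' @export
synthetic_config <- function(n_samples = 230L, n_channels = 125L,
                             wavelength_range = c(950, 1650),
                             target_range = c(0.03, 0.20),
                             informative_bands = list(c(1210, 18, -0.6),
                                                      c(1450, 28, -0.9),
                                                      c(1550, 15, -0.45)),
                             scatter_sd = 0.05, baseline_sd = 0.02,
                             noise_sd = 0.04, seed = 1L) {
  if (n_samples < 4L) stop("n_samples must be >= 4")
  if (any(c(scatter_sd, baseline_sd, noise_sd) < 0))
    stop("all noise sds must be >= 0")
  centers <- vapply(informative_bands, `[`, numeric(1L), 1L)
  if (any(centers < wavelength_range[1L] | centers > wavelength_range[2L]))
    stop("band centers must lie inside wavelength_range")
  structure(list(n_samples = as.integer(n_samples),
                 n_channels = as.integer(n_channels),
                 wavelength_range = wavelength_range,
                 target_range = target_range,
                 informative_bands = informative_bands,
                 scatter_sd = scatter_sd, baseline_sd = baseline_sd,
                 noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_config")
}

#' Generate a synthetic seed-cotton NIR dataset
#'
#' Draws `y_i ~ Uniform(target_range)`, builds the clean spectrum
#' `continuum(wl) + sum_b loading_b * y_i * exp(-(wl - center_b)^2 /
#' (2 width_b^2))`, and observes `a_i * clean + c_i + noise` with
#' `a_i ~ N(1, scatter_sd)` and `c_i ~ N(0, baseline_sd)`. Fully
#' reproducible from the config seed. The returned object carries the
#' ground-truth informative channel indices (channels within two band
#' widths of any band center) as attribute `"truth"`, along with the
#' config.
#'
#' @param cfg a [synthetic_config()].
#' @return A [spectra_set()] with attributes `truth` (integer channel
#'   indices) and `config`.
#' @export
generate_dataset <- function(cfg = synthetic_config()) {
  stopifnot(inherits(cfg, "synthetic_config"))
  wl <- seq(cfg$wavelength_range[1L], cfg$wavelength_range[2L],
            length.out = cfg$n_channels)
  # fixed smooth continuum: broad dome plus a gentle ripple, well above zero
  u <- (wl - mean(wl)) / diff(range(wl))
  continuum <- 0.68 - 0.18 * u^2 + 0.04 * sin(2 * pi * u)

  band_mat <- vapply(cfg$informative_bands, function(b)
    b[3L] * exp(-(wl - b[1L])^2 / (2 * b[2L]^2)), numeric(length(wl)))
  truth <- which(Reduce(`|`, lapply(cfg$informative_bands, function(b)
    abs(wl - b[1L]) <= 2 * b[2L])))

  withr::with_seed(cfg$seed, {
    n <- cfg$n_samples
    y <- stats::runif(n, cfg$target_range[1L], cfg$target_range[2L])
    clean <- matrix(continuum, n, cfg$n_channels, byrow = TRUE) +
      tcrossprod(y, rowSums(band_mat))
    a <- stats::rnorm(n, 1, cfg$scatter_sd)
    cc <- stats::rnorm(n, 0, cfg$baseline_sd)
    noise <- matrix(stats::rnorm(n * cfg$n_channels, 0, cfg$noise_sd),
                    n, cfg$n_channels)
    X <- clean * a + cc + noise
    X[X < 0] <- 0   # physical floor; unreachable at default noise levels
    out <- spectra_set(X, wl, y)
    attr(out, "truth") <- truth
    attr(out, "config") <- cfg
    out
  })
}
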