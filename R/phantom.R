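# Synthetic layered breast-ultrasound phantom.
#
# A phantom is four vertically stacked tissue bands (skin, premammary
# fat, mammary, retromammary) with configurable mean echogenicity, a
# hypoechoic tumor placed in the mammary band as an irregular ellipse,
# optional posterior shadowing, and multiplicative smoothed-gamma speckle.
# It emulates the gross anatomy and noise structure the row-column-wise
# kernels were designed around; it is not a wave-propagation simulation.

#' Phantom configuration
#'
#' @param height,width image size in pixels.  The default 500-px
#'   reference resolution puts tumor axis lengths on the same scale as
#'   the clinical size groups (0-100, 100-120, 120-160, >160 px).
#' @param layer_fractions four positive fractions summing to 1; band
#'   heights top-to-bottom for skin, premammary fat, mammary and
#'   retromammary tissue.
#' @param layer_means four mean intensities in `[0,1]` for the bands
#'   (skin bright, subcutaneous fat dark, mammary intermediate,
#'   retromammary darker).
#' @param speckle logical; multiplicative speckle on/off.  With speckle
#'   off the image is exactly the clean band+tumor template.
#' @param speckle_shape gamma shape of the unit-mean multiplicative
#'   noise field; smaller values give heavier speckle.
#' @param speckle_smoothing_sigma Gaussian smoothing sigma (pixels) of
#'   the speckle field, giving it the lateral correlation of real
#'   speckle grains.
#' @param tumor_axis_px requested longest-axis length (pixels, at the
#'   original resolution).
#' @param tumor_aspect minor/major axis ratio in (0, 1].
#' @param tumor_angle major-axis rotation in radians.
#' @param boundary_irregularity relative amplitude in `[0, 0.5]` of the
#'   smooth periodic radial perturbation of the tumor outline.
#' @param tumor_contrast intensity drop in `[0,1]` inside the tumor
#'   (tumors are hypoechoic).
#' @param shadow_strength posterior acoustic shadowing strength in
#'   `[0,1]`; 0 (default) disables it.
#' @param seed integer seed; generation is bit-reproducible.
#' @return Object of class `phantom_config`.
#' @export
phantom_config <- function(height = 500L, width = 500L,
                           layer_fractions = c(0.08, 0.18, 0.50, 0.24),
                           layer_means = c(0.80, 0.35, 0.55, 0.30),
                           speckle = TRUE,
                           speckle_shape = 4,
                           speckle_smoothing_sigma = 1.5,
                           tumor_axis_px = 120,
                           tumor_aspect = 0.7,
                           tumor_angle = 0,
                           boundary_irregularity = 0.1,
                           tumor_contrast = 0.35,
                           shadow_strength = 0,
                           seed = 1L) {
  cfg <- list(height = as.integer(height), width = as.integer(width),
              layer_fractions = layer_fractions, layer_means = layer_means,
              speckle = isTRUE(speckle), speckle_shape = speckle_shape,
              speckle_smoothing_sigma = speckle_smoothing_sigma,
              tumor_axis_px = tumor_axis_px, tumor_aspect = tumor_aspect,
              tumor_angle = tumor_angle,
              boundary_irregularity = boundary_irregularity,
              tumor_contrast = tumor_contrast,
              shadow_strength = shadow_strength, seed = as.integer(seed))
  validate_phantom_config(cfg)
  structure(cfg, class = "phantom_config")
}

validate_phantom_config <- function(cfg) {
  stopifnot(cfg$height >= 16, cfg$width >= 16,
            length(cfg$layer_fractions) == 4L,
            length(cfg$layer_means) == 4L,
            all(cfg$layer_means >= 0 & cfg$layer_means <= 1),
            cfg$speckle_shape > 0, cfg$speckle_smoothing_sigma >= 0,
            cfg$tumor_axis_px > 0,
            cfg$tumor_aspect > 0, cfg$tumor_aspect <= 1,
            cfg$boundary_irregularity >= 0, cfg$boundary_irregularity <= 0.5,
            cfg$tumor_contrast >= 0, cfg$tumor_contrast <= 1,
            cfg$shadow_strength >= 0, cfg$shadow_strength <= 1)
  if (any(cfg$layer_fractions <= 0))
    stop("all layer fractions must be > 0")
  if (abs(sum(cfg$layer_fractions) - 1) > 1e-9)
    stop("layer fractions must sum to 1")
  invisible(cfg)
}

# Evaluate the periodic radial perturbation (low-order harmonic series,
# normalized so its maximum absolute value equals `amplitude`).
radial_perturbation <- function(theta, coefs, amplitude) {
  if (amplitude == 0) return(rep(0, length(theta)))
  k <- seq_len(nrow(coefs)) + 1L  # harmonics 2..K+1
  v <- drop(cos(outer(theta, k)) %*% coefs[, 1L] +
            sin(outer(theta, k)) %*% coefs[, 2L])
  v * amplitude
}

#' Generate one synthetic breast-ultrasound phantom
#'
#' Deterministic for a fixed configuration (including its seed).  The
#' tumor outline is an ellipse whose radius is perturbed by a random
#' low-order harmonic series; the outline is rescaled analytically so
#' that the realized longest-axis length matches `tumor_axis_px` to
#' within rasterization error (well inside 10%).  The tumor center lies
#' inside the mammary band.
#'
#' @param config a [phantom_config()].
#' @return Object of class `phantom_sample`: `image` (matrix in `[0,1]`),
#'   `mask` (binary matrix), `true_axis_px`, `axis_px` (alias used by the
#'   evaluation harness), `config`.
#' @export
generate_phantom <- function(config) {
  validate_phantom_config(config)
  H <- config$height; W <- config$width
  set.seed(config$seed)

  # harmonic boundary coefficients (drawn even when unused, to keep the
  # RNG stream layout independent of the irregularity setting)
  coefs <- matrix(runif(8, -1, 1), ncol = 2L)
  amp <- config$boundary_irregularity
  if (amp > 0) {
    tg <- seq(0, 2 * pi, length.out = 1024L)
    coefs <- coefs / max(abs(radial_perturbation(tg, coefs, 1)))
  }

  # band geometry
  edges <- round(cumsum(c(0, config$layer_fractions)) * H)
  edges[5L] <- H
  band_of_row <- rep(1:4, times = diff(edges))
  clean <- matrix(config$layer_means[band_of_row], nrow = H, ncol = W)

  # tumor center: inside the mammary band (band 3), jittered
  r0 <- edges[3L] + 1L; r1 <- edges[4L]
  band_h <- r1 - r0 + 1L
  cy <- (r0 + r1) / 2 + runif(1, -0.25, 0.25) * band_h
  cy <- min(max(cy, r0), r1)
  cx <- W / 2 + runif(1, -0.15, 0.15) * W

  # outline: ellipse radius times (1 + perturbation), rescaled so the
  # polygon diameter equals the requested axis length
  a0 <- config$tumor_axis_px / 2
  b0 <- a0 * config$tumor_aspect
  phi <- config$tumor_angle
  tg <- seq(0, 2 * pi, length.out = 720L)
  rr <- 1 + radial_perturbation(tg, coefs, amp)
  px <- a0 * rr * cos(tg); py <- b0 * rr * sin(tg)
  bx <- cx + px * cos(phi) - py * sin(phi)
  by <- cy + px * sin(phi) + py * cos(phi)
  dmax <- max(stats::dist(cbind(bx, by)))
  sc <- config$tumor_axis_px / dmax
  a <- a0 * sc; b <- b0 * sc

  ext <- config$tumor_axis_px / 2 * (1 + amp) + 1
  if (cy - ext < 0 || cy + ext > H || cx - ext < 0 || cx + ext > W)
    stop(sprintf(
      "tumor (axis %.0f px) does not fit inside the %dx%d image at center (%.0f, %.0f)",
      config$tumor_axis_px, H, W, cy, cx))

  # rasterize: pixel centers inside the perturbed ellipse
  yy <- matrix(seq_len(H), H, W) - cy
  xx <- matrix(seq_len(W), H, W, byrow = TRUE) - cx
  u <- (xx * cos(phi) + yy * sin(phi)) / a
  v <- (-xx * sin(phi) + yy * cos(phi)) / b
  rho <- sqrt(u^2 + v^2)
  theta <- atan2(v, u)
  inside <- rho <= 1 + radial_perturbation(as.vector(theta), coefs, amp)
  mask <- matrix(as.numeric(inside), H, W)
  if (!any(mask > 0)) stop("degenerate tumor: empty mask")

  clean[mask > 0] <- pmax(clean[mask > 0] - config$tumor_contrast, 0)

  # posterior shadow: column-wise exponential attenuation below the tumor
  if (config$shadow_strength > 0) {
    tau <- 0.2 * H
    for (j in which(colSums(mask) > 0)) {
      bot <- max(which(mask[, j] > 0))
      if (bot < H) {
        rows <- (bot + 1L):H
        att <- 1 - config$shadow_strength * (1 - exp(-(rows - bot) / tau))
        clean[rows, j] <- clean[rows, j] * att
      }
    }
  }

  img <- clean
  if (config$speckle) {
    field <- matrix(rgamma(H * W, shape = config$speckle_shape,
                           rate = config$speckle_shape), H, W)
    if (config$speckle_smoothing_sigma > 0)
      field <- unclass(EBImage::gblur(field,
                                      sigma = config$speckle_smoothing_sigma))
    field <- field / mean(field)
    img <- pmin(pmax(clean * field, 0), 1)
  }

  axis <- tumor_longest_axis(mask)
  structure(list(image = img, mask = mask, true_axis_px = axis,
                 axis_px = axis, config = config),
            class = "phantom_sample")
}

#' Generate a phantom dataset
#'
#' Draws `n` tumor axis lengths from `size_sampler` and generates one
#' phantom per draw, with aspect ratio, orientation, boundary
#' irregularity and contrast randomized per sample and a per-sample seed
#' derived from the master `seed` (so the list is reproducible as a
#' whole).  The default sampler is a right-skewed log-normal (median
#' about 110 px, mode below 100 px at the 500-px reference resolution,
#' clamped to fit the image), emulating the positively skewed clinical
#' tumor-size distributions in which most tumors are smaller than 150 px.
#'
#' @param n number of phantoms (>= 1).
#' @param base_config a [phantom_config()] supplying everything not
#'   randomized per sample.
#' @param size_sampler function(n) returning `n` axis lengths in pixels;
#'   `NULL` for the default log-normal.
#' @param seed master seed.
#' @return List of `phantom_sample` objects.
#' @export
generate_dataset <- function(n, base_config = phantom_config(),
                             size_sampler = NULL, seed = 1L) {
  if (n < 1) stop("n must be >= 1")
  H <- base_config$height; W <- base_config$width
  max_axis <- 0.45 * min(H, W)
  if (is.null(size_sampler))
    size_sampler <- function(k)
      pmin(pmax(rlnorm(k, meanlog = log(110), sdlog = 0.45), 40), max_axis)
  set.seed(seed)
  axes <- size_sampler(n)
  aspect <- runif(n, 0.5, 0.95)
  angle <- runif(n, 0, pi)
  irreg <- runif(n, 0.05, 0.2)
  contrast <- runif(n, 0.25, 0.5)
  seeds <- sample.int(.Machine$integer.max, n)
  lapply(seq_len(n), function(i) {
    cfg <- base_config
    cfg$tumor_axis_px <- axes[i]
    cfg$tumor_aspect <- aspect[i]
    cfg$tumor_angle <- angle[i]
    cfg$boundary_irregularity <- irreg[i]
    cfg$tumor_contrast <- contrast[i]
    cfg$seed <- seeds[i]
    generate_phantom(cfg)
  })
}

#' Write a phantom dataset as PNG pairs plus a manifest CSV
#'
#' Writes `img_####.png` (8-bit grayscale), `mask_####.png` (0/255) and
#' `manifest.csv` with columns `image_path`, `mask_path`, `id`,
#' `true_axis_px` into `dir`.
#'
#' @param samples list of `phantom_sample` objects.
#' @param dir output directory (created if needed).
#' @return Invisibly, the manifest data.frame.
#' @export
write_phantom_dataset <- function(samples, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  rows <- lapply(seq_along(samples), function(i) {
    s <- samples[[i]]
    ip <- sprintf("img_%04d.png", i); mp <- sprintf("mask_%04d.png", i)
    png::writePNG(s$image, file.path(dir, ip))
    png::writePNG(s$mask, file.path(dir, mp))
    data.frame(image_path = ip, mask_path = mp,
               id = sprintf("phantom_%04d", i),
               true_axis_px = s$true_axis_px, stringsAsFactors = FALSE)
  })
  manifest <- do.call(rbind, rows)
  write.csv(manifest, file.path(dir, "manifest.csv"), row.names = FALSE)
  invisible(manifest)
}
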