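#' Laboratory stain profile for the tile renderer
#'
#' Parameterises laboratory-level appearance differences in slide
#' preparation and H&E staining: the rendered hematoxylin (nuclear,
#' blue-purple) and eosin (cytoplasm/stroma, pink) colours, the nuclear
#' density of the background field, and a per-channel affine transform
#' (`gain * value + offset`, applied in 0..255 units, clipped) emulating
#' global hue/intensity shifts between laboratories.
#'
#' @param gain Length-3 positive multiplicative gains (R, G, B).
#' @param offset Length-3 additive offsets in 0..255 units.
#' @param hematoxylin_rgb,eosin_rgb RGB triples (0..255) of the two stains.
#' @param nuclear_density Expected number of background nuclei per
#'   100 x 100-pixel area (>= 0).
#' @return A list of class `stain_profile`.
#' @export
stain_profile <- function(gain = c(1, 1, 1), offset = c(0, 0, 0),
                          hematoxylin_rgb = c(72, 61, 139),
                          eosin_rgb = c(232, 150, 190),
                          nuclear_density = 40) {
  stopifnot(length(gain) == 3, all(gain > 0), length(offset) == 3,
            length(hematoxylin_rgb) == 3, length(eosin_rgb) == 3,
            nuclear_density >= 0)
  structure(list(gain = gain, offset = offset,
                 hematoxylin_rgb = hematoxylin_rgb, eosin_rgb = eosin_rgb,
                 nuclear_density = nuclear_density),
            class = "stain_profile")
}

#' Scanner rendering profile for the tile renderer
#'
#' Parameterises scanner-level effects applied after staining: Gaussian
#' blur (optical resolution), gamma (tone/contrast rendering), and
#' additive per-pixel Gaussian colour noise (`color_spread_sigma`, in
#' 0..255 units) that broadens the RGB histograms -- a larger spread gives
#' a wider distribution of colour values with lower peaks.
#'
#' @param blur_sigma Gaussian blur standard deviation in pixels (>= 0;
#'   0 = no blur).
#' @param gamma Gamma exponent applied to values scaled to \[0, 1\]
#'   (> 0; 1 = identity).
#' @param color_spread_sigma Standard deviation of additive Gaussian pixel
#'   noise in 0..255 units (>= 0).
#' @return A list of class `scanner_profile`.
#' @export
scanner_profile <- function(blur_sigma = 0, gamma = 1, color_spread_sigma = 0) {
  stopifnot(is.finite(blur_sigma), blur_sigma >= 0,
            is.finite(gamma), gamma > 0,
            is.finite(color_spread_sigma), color_spread_sigma >= 0)
  structure(list(blur_sigma = blur_sigma, gamma = gamma,
                 color_spread_sigma = color_spread_sigma),
            class = "scanner_profile")
}

#' Three example scanner profiles
#'
#' Named profiles used throughout examples and tests: two sharp,
#' low-noise profiles with near-neutral tone curves (`philips_like`,
#' `hamamatsu_like`) and one soft, noisy, low-contrast profile
#' (`histech_like`) whose tiles show the broader colour distributions
#' with lower histogram peaks characteristic of a divergent scanner.
#'
#' @return A named list of three `scanner_profile`s.
#' @export
example_scanner_profiles <- function() {
  list(
    philips_like   = scanner_profile(blur_sigma = 0.5, gamma = 1.00,
                                     color_spread_sigma = 2),
    hamamatsu_like = scanner_profile(blur_sigma = 0.8, gamma = 1.15,
                                     color_spread_sigma = 4),
    histech_like   = scanner_profile(blur_sigma = 1.8, gamma = 0.80,
                                     color_spread_sigma = 12)
  )
}

#' Render a synthetic H&E-like RGB tile
#'
#' Procedural renderer producing 8-bit RGB tiles for colour-distribution
#' analysis. A textured eosinophilic stroma field is drawn first, with
#' scattered hematoxylin-stained nuclei; the requested content is
#' composited on top:
#'
#' * `"ganglion"` -- one to three large cells with pale cytoplasm, a dark
#'   hematoxylin rim and an eccentric nucleolus;
#' * `"neural_plexus"` -- wavy pale fiber bands;
#' * `"background_stroma"` -- the textured field only.
#'
#' The stain profile's affine colour transform is then applied, followed
#' by the scanner pipeline: Gaussian blur, gamma, additive colour noise,
#' clipping to 0..255 and rounding. With an identity stain and a neutral
#' scanner (blur 0, gamma 1, spread 0) the output is the pure content
#' layer. Output is deterministic (bit-identical) given `seed`.
#'
#' This is deliberately not photorealistic histology: only histogram-level
#' behaviour is consumed downstream.
#'
#' @param width,height Tile dimensions in pixels (>= 32).
#' @param content One of `"ganglion"`, `"neural_plexus"`,
#'   `"background_stroma"`.
#' @param stain A `stain_profile`.
#' @param scanner A `scanner_profile`.
#' @param seed Integer seed.
#' @return A `height x width x 3` array of integers in 0..255 with
#'   attribute `content`.
#' @export
#' @examples
#' tile <- generate_tile(64, 64, "ganglion", seed = 7)
#' h <- compute_histogram(tile)
generate_tile <- function(width, height,
                          content = c("ganglion", "neural_plexus",
                                      "background_stroma"),
                          stain = stain_profile(),
                          scanner = scanner_profile(), seed = 1L) {
  content <- match.arg(content)
  stopifnot(inherits(stain, "stain_profile"),
            inherits(scanner, "scanner_profile"))
  if (width < 32 || height < 32) {
    stop("tile dimensions must be at least 32 x 32", call. = FALSE)
  }
  set.seed(as.integer(seed), kind = "Mersenne-Twister")

  h <- as.integer(height); w <- as.integer(width)
  xs <- matrix(rep(seq_len(w), each = h), h, w)
  ys <- matrix(rep(seq_len(h), times = w), h, w)

  # eosinophilic stroma: white paper mixed with eosin by a smooth density
  density <- .smooth_noise(h, w, sigma = max(3, min(h, w) / 12),
                           lo = 0.35, hi = 0.85)
  img <- array(0, dim = c(h, w, 3))
  for (ch in 1:3) {
    img[, , ch] <- 255 - density * (255 - stain$eosin_rgb[ch])
  }

  # scattered background nuclei
  n_nuclei <- rpois(1, stain$nuclear_density * h * w / 1e4)
  if (n_nuclei > 0) {
    cx <- runif(n_nuclei, 1, w); cy <- runif(n_nuclei, 1, h)
    r <- runif(n_nuclei, 1.2, 3)
    for (i in seq_len(n_nuclei)) {
      m <- ((xs - cx[i])^2 + (ys - cy[i])^2) <= r[i]^2
      img <- .blend(img, m, stain$hematoxylin_rgb, alpha = 0.85)
    }
  }

  if (content == "ganglion") {
    n_cells <- sample(1:3, 1)
    for (i in seq_len(n_cells)) {
      rx <- runif(1, min(h, w) / 10, min(h, w) / 5)
      ry <- rx * runif(1, 0.7, 1.3)
      cx <- runif(1, rx + 2, w - rx - 1)
      cy <- runif(1, ry + 2, h - ry - 1)
      th <- runif(1, 0, pi)
      xr <- (xs - cx) * cos(th) + (ys - cy) * sin(th)
      yr <- -(xs - cx) * sin(th) + (ys - cy) * cos(th)
      q <- (xr / rx)^2 + (yr / ry)^2
      img <- .blend(img, q <= 1, c(250, 225, 238), alpha = 0.9)   # pale cytoplasm
      img <- .blend(img, q > 0.78 & q <= 1, stain$hematoxylin_rgb,
                    alpha = 0.8)                                  # dark rim
      nol <- ((xr - 0.35 * rx)^2 + (yr - 0.2 * ry)^2) <=
        (0.12 * min(rx, ry))^2
      img <- .blend(img, nol, stain$hematoxylin_rgb, alpha = 0.95) # nucleolus
    }
  } else if (content == "neural_plexus") {
    period <- runif(1, h / 6, h / 3)
    phase <- runif(1, 0, 2 * pi)
    amp <- runif(1, 2, h / 10)
    wave <- sin(2 * pi * ys / period + phase + amp * sin(2 * pi * xs / w))
    img <- .blend(img, wave > 0.25, c(225, 195, 215), alpha = 0.75)
    img <- .blend(img, wave > 0.85, c(200, 165, 195), alpha = 0.6)
  }

  # laboratory affine colour transform
  for (ch in 1:3) {
    img[, , ch] <- stain$gain[ch] * img[, , ch] + stain$offset[ch]
  }
  img <- pmin(pmax(img, 0), 255)

  # scanner pipeline: blur -> gamma -> colour noise
  if (scanner$blur_sigma > 0) {
    for (ch in 1:3) {
      img[, , ch] <- EBImage::gblur(img[, , ch] / 255,
                                    sigma = scanner$blur_sigma) * 255
    }
    img <- pmin(pmax(img, 0), 255)
  }
  if (scanner$gamma != 1) {
    img <- ((img / 255)^scanner$gamma) * 255
  }
  if (scanner$color_spread_sigma > 0) {
    img <- img + rnorm(length(img), sd = scanner$color_spread_sigma)
  }
  img <- round(pmin(pmax(img, 0), 255))
  attr(img, "content") <- content
  img
}

# Smooth spatial noise in [lo, hi]: white noise blurred and rescaled.
.smooth_noise <- function(h, w, sigma, lo = 0, hi = 1) {
  z <- matrix(runif(h * w), h, w)
  z <- EBImage::gblur(z, sigma = sigma)
  rng <- range(z)
  if (rng[2] > rng[1]) z <- (z - rng[1]) / (rng[2] - rng[1])
  lo + z * (hi - lo)
}

# Alpha-blend colour `rgb` into img over logical mask `m`.
.blend <- function(img, m, rgb, alpha) {
  if (!any(m)) return(img)
  for (ch in 1:3) {
    layer <- img[, , ch]
    layer[m] <- (1 - alpha) * layer[m] + alpha * rgb[ch]
    img[, , ch] <- layer
  }
  img
}

#' Generate a directory of seeded tiles with a manifest
#'
#' Renders `n_per_profile` tiles for every scanner profile in `profiles`
#' and writes them as PNGs with a manifest CSV (`path`, `case_id`,
#' `cohort`, `scanner`) suitable for [run_color_report()].
#'
#' @param out_dir Output directory (created if needed).
#' @param profiles Named list of `scanner_profile`s.
#' @param n_per_profile Tiles per profile.
#' @param width,height Tile size.
#' @param content Content class for all tiles.
#' @param stain A `stain_profile` shared by all tiles.
#' @param seed Integer root seed; tile `i` of profile `j` uses a derived
#'   sub-seed.
#' @return The manifest tibble, invisibly written to
#'   `file.path(out_dir, "manifest.csv")`.
#' @export
generate_tile_set <- function(out_dir, profiles = example_scanner_profiles(),
                              n_per_profile = 10, width = 96, height = 96,
                              content = "background_stroma",
                              stain = stain_profile(), seed = 1L) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  set.seed(as.integer(seed), kind = "Mersenne-Twister")
  tile_seeds <- matrix(
    sample.int(.Machine$integer.max - 1L, n_per_profile * length(profiles)),
    nrow = n_per_profile
  )
  rows <- list()
  for (j in seq_along(profiles)) {
    lab <- names(profiles)[j]
    for (i in seq_len(n_per_profile)) {
      tile <- generate_tile(width, height, content, stain = stain,
                            scanner = profiles[[j]],
                            seed = tile_seeds[i, j])
      fn <- file.path(out_dir, sprintf("%s_%03d.png", lab, i))
      write_image_tile(tile, fn)
      rows[[length(rows) + 1L]] <- tibble(
        path = fn, case_id = sprintf("%s_case_%02d", lab, (i - 1) %/% 36 + 1),
        cohort = "synthetic", scanner = lab
      )
    }
  }
  manifest <- bind_rows(rows)
  readr::write_csv(manifest, file.path(out_dir, "manifest.csv"))
  invisible(manifest)
}
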