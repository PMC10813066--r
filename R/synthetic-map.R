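#' Generate a synthetic confocal-style height map
#'
#' Builds a seeded random surface emulating processed cementum
#' topographies from three decoupled carriers plus an optional degree-2
#' form (the residual curvature of the root): broad undulations carry
#' the peak-to-valley amplitude; small relief peaks of modest fixed
#' height carry the relief frequency (their areal density is the
#' frequency dial); and correlated noise carries the texture roughness
#' (short correlation lengths read as rough). After detrending, the
#' combined field is rescaled so its peak-to-valley amplitude equals
#' `amplitude_um`, making the intended maximum vertical elevation exact
#' by construction. A fraction of pixels can be masked as non-measured
#' (a mix of scattered pixels and small disks, as left by specular
#' dropouts).
#'
#' @param amplitude_um Peak-to-valley amplitude of the detrended surface.
#' @param correlation_length_um Correlation length of the texture noise;
#'   short lengths give rough surfaces (default 80).
#' @param relief_density_per_mm2 Areal density of small relief peaks
#'   (default 3; around 120 reads as high-frequency relief).
#' @param form_curvature_um Peak height of the degree-2 form across the
#'   field (default 0).
#' @param nm_fraction Fraction of non-measured pixels in [0, 0.3)
#'   (default 0).
#' @param seed Integer seed; fully determines the surface.
#' @param n Grid side in pixels (default 256).
#' @param pixel_um Lateral resolution (default 8 um/px, i.e. a
#'   2.05 x 2.05 mm field at the default size).
#' @param noise_rms_um RMS of the correlated texture noise before
#'   rescaling; defaults to 2% of `amplitude_um`.
#' @param relief_height_um,relief_radius_mm Height and footprint radius
#'   of the relief peaks (defaults 15 um and 0.033 mm); peaks sit on a
#'   lightly jittered lattice at the requested density so neighbouring
#'   peaks stay resolvable as individual relief maxima.
#' @param und_density_per_mm2,und_radius_mm Density and radius of the
#'   broad undulations carrying the amplitude (defaults 2 per mm2 and
#'   1.1 mm).
#' @return A `height_map`.
#' @examples
#' m <- make_height_map(amplitude_um = 690, seed = 1)
#' max_vertical_elevation(process_height_map(m))
#' @export
make_height_map <- function(amplitude_um, correlation_length_um = 80,
                            relief_density_per_mm2 = 3,
                            form_curvature_um = 0, nm_fraction = 0,
                            seed = 1, n = 256, pixel_um = 8,
                            noise_rms_um = NULL, relief_height_um = 15,
                            relief_radius_mm = 0.033,
                            und_density_per_mm2 = 2, und_radius_mm = 1.1) {
  stopifnot(amplitude_um >= 0, relief_density_per_mm2 >= 0,
            nm_fraction >= 0, nm_fraction < 0.3)
  noise_rms_um <- noise_rms_um %||% (amplitude_um * 0.02)
  with_seed(seed, {
    x <- (seq_len(n) - (n + 1) / 2) * pixel_um / 1000   # mm
    X <- matrix(rep(x, n), n)
    Y <- t(X)
    half <- max(abs(x))
    form <- form_curvature_um * (0.7 * (X / half)^2 + 1.3 * (Y / half)^2) / 2

    area_mm2 <- (n * pixel_um / 1000)^2
    B <- poly_basis(n, n, pixel_um, 2)
    detrend <- function(m)
      matrix(as.vector(m) - qr.fitted(qr(B), as.vector(m)), n)
    und <- matrix(0, n, n)
    peaks <- matrix(0, n, n)
    if (amplitude_um > 0) {
      ku <- max(1L, round(und_density_per_mm2 * area_mm2))
      ucx <- runif(ku, -half, half); ucy <- runif(ku, -half, half)
      uh <- runif(ku, 0.5, 1)
      for (i in seq_len(ku))
        und <- und + uh[i] *
          exp(-2 * ((X - ucx[i])^2 + (Y - ucy[i])^2) / und_radius_mm^2)
      # the amplitude carrier is what survives form removal
      und <- detrend(und)
      rng_u <- diff(range(und))
      if (rng_u > 1e-12) und <- und / rng_u * amplitude_um
      if (relief_density_per_mm2 > 0 && relief_height_um > 0) {
        # near-regular lattice: spacing just above the merge distance of
        # neighbouring peaks, so the density survives into countable
        # relief maxima
        g <- 1 / sqrt(relief_density_per_mm2)
        gx <- seq(-half + g / 2, half, by = g)
        ctr <- expand.grid(px = gx, py = gx)
        jit <- 0.05 * g
        pcx <- ctr$px + runif(nrow(ctr), -jit, jit)
        pcy <- ctr$py + runif(nrow(ctr), -jit, jit)
        ph <- runif(nrow(ctr), 0.9, 1.1) * relief_height_um
        xs <- x
        w <- ceiling(2.2 * relief_radius_mm * 1000 / pixel_um)
        step <- pixel_um / 1000
        for (i in seq_len(nrow(ctr))) {
          ci <- round(pcx[i] / step + (n + 1) / 2)
          cj <- round(pcy[i] / step + (n + 1) / 2)
          ii <- max(1, ci - w):min(n, ci + w)
          jj <- max(1, cj - w):min(n, cj + w)
          d2 <- outer((xs[ii] - pcx[i])^2, (xs[jj] - pcy[i])^2, "+") /
            relief_radius_mm^2
          peaks[ii, jj] <- peaks[ii, jj] + ph[i] * exp(-2 * d2)
        }
      }
    }
    noise <- matrix(0, n, n)
    if (noise_rms_um > 0) {
      noise <- matrix(rnorm(n * n), n)
      noise <- gauss_blur(noise, correlation_length_um / pixel_um)
      noise <- noise / sqrt(mean(noise^2)) * noise_rms_um
    }

    s <- und + peaks + noise
    # rescale the detrended surface to the requested peak-to-valley
    resid <- as.vector(detrend(s))
    rng <- diff(range(resid))
    if (rng > 1e-12) s <- s * (amplitude_um / rng)

    z <- form + s
    mask <- matrix(FALSE, n, n)
    if (nm_fraction > 0) {
      n_px <- round(nm_fraction * n * n)
      n_disk <- max(1L, round(n_px * 0.3 / 50))
      for (i in seq_len(n_disk)) {
        ci <- runif(2, 5, n - 4)
        r <- runif(1, 2, 4)
        ii <- which((row(mask) - ci[1])^2 + (col(mask) - ci[2])^2 <= r^2)
        mask[ii] <- TRUE
      }
      left <- n_px - sum(mask)
      if (left > 0)
        mask[sample(which(!mask), left)] <- TRUE
    }
    height_map(z, pixel_um, mask)
  })
}

#' Surface-aspect archetype presets
#'
#' Generator settings reproducing the eight reference surface aspects
#' (elevation +/-, texture S/R, frequency 1/2) used as scoring
#' guidelines: high/low amplitude around the 200 um threshold, smooth
#' (long-correlation, faint) versus rough (short-correlation, strong)
#' texture, and sparse versus dense relief around the 0.5 peaks per
#' (100 um)^2 threshold.
#'
#' @param label One of `"+S1"`, `"+S2"`, `"+R1"`, `"+R2"`, `"-S1"`,
#'   `"-S2"`, `"-R1"`, `"-R2"`.
#' @param amplitude_um Optional amplitude override (e.g. 690 for the
#'   highest-relief reference surface).
#' @return A named list of [make_height_map()] arguments.
#' @export
archetype_spec <- function(label, amplitude_um = NULL) {
  stopifnot(label %in% c("+S1", "+S2", "+R1", "+R2",
                         "-S1", "-S2", "-R1", "-R2"))
  elev <- substr(label, 1, 1)
  tex <- substr(label, 2, 2)
  freq <- substr(label, 3, 3)
  amp <- amplitude_um %||% if (elev == "+") 450 else 110
  list(amplitude_um = amp,
       correlation_length_um = if (tex == "R") 2 else 80,
       noise_rms_um = if (tex == "R") max(7, amp * 0.02) else amp * 0.005,
       relief_density_per_mm2 = if (freq == "1") 80 else 0,
       relief_height_um = if (tex == "R") 40 else 15)
}
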