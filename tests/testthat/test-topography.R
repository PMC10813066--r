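grid_map <- function(f, n = 48, pixel_um = 10) {
  x <- (seq_len(n) - (n + 1) / 2) * pixel_um
  height_map(outer(x, x, f), pixel_um)
}

test_that("non-measured points are filled by neighbour interpolation", {
  plane <- grid_map(function(x, y) 2 + 0.3 * x - 0.1 * y)
  # identity on complete maps
  expect_identical(fill_nm(plane)$z, plane$z)

  # a single interior masked pixel of a plane is restored exactly
  masked <- plane
  masked$nm_mask[20, 25] <- TRUE
  truth <- masked$z[20, 25]
  masked$z[20, 25] <- NA
  filled <- fill_nm(masked)
  expect_equal(filled$z[20, 25], truth, tolerance = 1e-6)
  expect_false(any(filled$nm_mask))

  # 10% random mask on a textured surface: small RMS error
  m <- make_height_map(amplitude_um = 300, nm_fraction = 0.1, seed = 4,
                       n = 96)
  truth_m <- make_height_map(amplitude_um = 300, nm_fraction = 0, seed = 4,
                             n = 96)
  filled2 <- fill_nm(m)
  err <- filled2$z[m$nm_mask] - truth_m$z[m$nm_mask]
  expect_lt(sqrt(mean(err^2)), 300 / 10)

  expect_error(height_map(matrix(c(NA, 1, NA, 1), 2)), "non-measured")
})

test_that("leveling removes planes exactly and is idempotent", {
  tilted <- grid_map(function(x, y) 5 + 0.4 * x - 0.7 * y)
  lv <- level_surface(tilted)
  expect_lt(max(abs(lv$z)), 1e-9)

  bump <- grid_map(function(x, y) exp(-((x - 20)^2 + y^2) / 2000) * 50)
  both <- height_map(tilted$z + bump$z, tilted$pixel_um)
  lv2 <- level_surface(both)
  # the bump survives up to its own best-fitting plane
  pb <- level_surface(bump)
  expect_equal(lv2$z, pb$z, tolerance = 1e-9)
  expect_equal(level_surface(lv2)$z, lv2$z, tolerance = 1e-9)
  expect_equal(mean(lv$z), 0, tolerance = 1e-9)
})

test_that("form removal cancels degree-2 surfaces exactly", {
  parab <- grid_map(function(x, y) 3 + 0.1 * x - 0.2 * y +
                      0.004 * x^2 - 0.001 * x * y + 0.002 * y^2)
  rm <- remove_form(parab)
  expect_lt(max(abs(rm$z)), 1e-8)
  expect_equal(max_vertical_elevation(rm), 0, tolerance = 1e-8)

  sine <- grid_map(function(x, y) 40 * sin(x / 30) * cos(y / 40))
  mix <- height_map(parab$z + sine$z, parab$pixel_um)
  # the sinusoid survives up to its own degree-2 projection
  expect_equal(remove_form(mix)$z, remove_form(sine)$z, tolerance = 1e-8)
  expect_equal(remove_form(remove_form(mix))$z, remove_form(mix)$z,
               tolerance = 1e-8)
})

test_that("the processed metrics ignore added degree-2 contamination", {
  m <- make_height_map(amplitude_um = 350, seed = 6, n = 128)
  base <- process_height_map(m)
  n <- nrow(m$z); px <- m$pixel_um
  x <- (seq_len(n) - (n + 1) / 2) * px
  contam <- height_map(m$z + outer(x, x, function(a, b)
    120 - 0.2 * a + 0.3 * b + 3e-4 * a^2 - 2e-4 * a * b + 5e-4 * b^2), px)
  cooked <- process_height_map(contam)
  expect_equal(cooked$z, base$z, tolerance = 1e-6)
  expect_equal(max_vertical_elevation(cooked),
               max_vertical_elevation(base), tolerance = 1e-6)
  expect_equal(format(score_aspect(cooked)), format(score_aspect(base)))

  # projections never increase the peak-to-valley of contaminated input
  expect_lte(max_vertical_elevation(cooked),
             max_vertical_elevation(contam) + 1e-9)
})

test_that("surface aspects score as published on reference-like maps", {
  # the highest-relief reference surface: smooth, sparse, 690 um
  hi <- do.call(make_height_map,
                c(archetype_spec("+S2", amplitude_um = 690), seed = 41))
  sc <- score_aspect(process_height_map(hi))
  expect_equal(format(sc), "+S2")
  expect_equal(sc$max_ve_um, 690, tolerance = 10)

  # low smooth sparse surface under the 200 um elevation threshold
  lo <- do.call(make_height_map,
                c(archetype_spec("-S2", amplitude_um = 150), seed = 42))
  expect_equal(format(score_aspect(process_height_map(lo))), "-S2")

  # degenerate flat surface scores low everything
  flat <- height_map(matrix(0, 64, 64), 10)
  expect_equal(format(score_aspect(flat)), "-S2")
})

test_that("every aspect archetype is recovered in most seeded draws", {
  labs <- c("+S1", "+R1", "-S1", "-R1", "+R2", "-R2")
  hits <- 0; total <- 0
  for (lb in labs) for (s in 1:4) {
    m <- do.call(make_height_map, c(archetype_spec(lb), seed = 100 + s))
    hits <- hits + (format(score_aspect(process_height_map(m))) == lb)
    total <- total + 1
  }
  expect_gte(hits / total, 0.95)
})

test_that("height maps survive the two interchange formats", {
  m <- make_height_map(amplitude_um = 250, seed = 7, n = 48,
                       nm_fraction = 0.05)
  tsv <- tempfile(fileext = ".tsv")
  write_height_map(m, tsv)
  b1 <- read_height_map(tsv, pixel_um = m$pixel_um)
  expect_equal(b1$z[!m$nm_mask], m$z[!m$nm_mask], tolerance = 1e-9)
  expect_equal(b1$nm_mask, m$nm_mask, ignore_attr = TRUE)

  tif <- tempfile(fileext = ".tif")
  write_height_map(m, tif)
  b2 <- read_height_map(tif, pixel_um = m$pixel_um)
  expect_equal(b2$z[!m$nm_mask], m$z[!m$nm_mask], tolerance = 1e-4)
  expect_equal(b2$nm_mask, m$nm_mask, ignore_attr = TRUE)
})
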