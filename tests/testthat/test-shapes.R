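shape_of <- function(spec) {
  pair <- make_root_pair(spec)
  f <- suppressWarnings(compute_thickness(pair$cementum, pair$dentine))
  part <- partition_root(pair$cementum)
  classify_shape(f, part, pair$cementum)
}

test_that("the published size rules assign each archetypal apposition", {
  # a single protuberance over 2 mm is a node
  nod <- shape_of(synthetic_spec(base_cementum_um = 400, seed = 31,
    shape_primitives = list(list(kind = "NOD", third = 2, side = "d",
                                 diameter_mm = 2.5, height_mm = 1.0))))
  expect_equal(nod$kind, "NOD")
  expect_equal(nrow(nod$components), 1)
  expect_gt(nod$components$diameter_mm, 2)

  # a cluster of under-2-mm hemispherical protuberances is nodules
  nds <- shape_of(synthetic_spec(base_cementum_um = 400, seed = 32,
    shape_primitives = list(list(kind = "Nds", third = 2, side = "m",
                                 diameter_mm = 1.0, height_mm = 0.6,
                                 count = 5))))
  expect_equal(nds$kind, "Nds")
  expect_gte(nrow(nds$components), 2)
  expect_true(all(nds$components$diameter_mm < 2))

  # oblique elongated bumps 0.8 x 3.0 x 0.65 mm form ridges
  rid <- shape_of(synthetic_spec(base_cementum_um = 400, seed = 33,
    shape_primitives = list(list(kind = "RID", third = 2, side = "<",
                                 width_mm = 0.8, length_mm = 3.0,
                                 height_mm = 0.65, count = 4))))
  expect_equal(rid$kind, "RID")
  expect_true(all(rid$components$width_mm < 1))
  expect_true(all(rid$components$length_mm > 2))

  # a bulky apposition wrapping several sides is an overgrowth
  og <- shape_of(synthetic_spec(base_cementum_um = 400, seed = 34,
    shape_primitives = list(list(kind = "OG", third = 2, side = ">",
                                 diameter_mm = 4.2, height_mm = 1.2))))
  expect_equal(og$kind, "OG")
  expect_gte(max(og$components$n_sides), 2)

  # a small spiked sphere is a localized spike-like projection
  lsp <- shape_of(synthetic_spec(base_cementum_um = 400, seed = 35,
    shape_primitives = list(list(kind = "LSP", third = 1, side = "d",
                                 diameter_mm = 1.4, height_mm = 0.8))))
  expect_equal(lsp$kind, "LSP")
  expect_gte(max(lsp$components$n_peaks), 2)

  # no focal component on a uniform root
  none <- shape_of(synthetic_spec(base_cementum_um = 500, seed = 36))
  expect_equal(none$kind, "none")
})

test_that("classification is invariant to mesh refinement", {
  for (prim in list(list(kind = "NOD", third = 2, side = "d",
                         diameter_mm = 2.6, height_mm = 1.0),
                    list(kind = "Nds", third = 2, side = "m",
                         diameter_mm = 1.2, height_mm = 0.6, count = 4))) {
    spec <- synthetic_spec(base_cementum_um = 400, seed = 37,
                           shape_primitives = list(prim))
    pair <- make_root_pair(spec)
    coarse <- classify_shape(
      suppressWarnings(compute_thickness(pair$cementum, pair$dentine)),
      partition_root(pair$cementum), pair$cementum)

    cem_f <- cementmap:::subdivide_mesh(pair$cementum)
    den_f <- cementmap:::subdivide_mesh(pair$dentine)
    fine <- classify_shape(
      suppressWarnings(compute_thickness(cem_f, den_f)),
      partition_root(cem_f), cem_f)
    expect_equal(fine$kind, coarse$kind)
    expect_equal(coarse$kind, prim$kind)
  }
})

test_that("shape and preference recovery succeeds on randomized roots", {
  reps <- lapply(1:20, recovery_replicate)
  prim <- vapply(reps, function(r) r$has_primitive, TRUE)
  clear <- !vapply(reps, function(r) r$truth$pref_boundary, TRUE)
  kind_ok <- vapply(reps[prim], function(r) r$kind == r$truth$kind, TRUE)
  pref_ok <- vapply(reps[clear], function(r) r$pref == r$truth$pref, TRUE)
  expect_gte(mean(kind_ok), 0.95)
  expect_gte(mean(pref_ok), 0.95)
})
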