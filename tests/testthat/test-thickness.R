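test_that("the distance kernel matches an independent point-to-triangle oracle", {
  pair <- make_root_pair(synthetic_spec(seed = 1, n_axial = 12, n_theta = 14,
                                        base_cementum_um = 400))
  expect_lte(nrow(pair$dentine$faces), 500)
  got <- compute_thickness(pair$cementum, pair$dentine)$thickness_um
  want <- r_point_mesh_distance(pair$cementum$vertices, pair$dentine) * 1000
  expect_equal(got, want, tolerance = 1e-9)

  # and on an unstructured pairing: sphere vertices against a root
  sph <- uv_sphere_mesh(4, 6, 8)
  got2 <- cementmap:::cpp_point_mesh_distance(sph$vertices,
                                              pair$dentine$vertices,
                                              pair$dentine$faces - 1L)
  want2 <- r_point_mesh_distance(sph$vertices, pair$dentine)
  expect_equal(got2, want2, tolerance = 1e-9)
})

test_that("concentric spheres recover the analytic 500 um offset", {
  inner <- uv_sphere_mesh(5.0, 70, 72)
  outer <- uv_sphere_mesh(5.5, 70, 72)
  expect_gte(nrow(outer$vertices), 5000)
  th <- compute_thickness(outer, inner)$thickness_um
  expect_lt(max(abs(th - 500)) / 500, 0.01)
})

test_that("identical meshes give zero thickness with a flag", {
  m <- uv_sphere_mesh(3, 10, 12)
  expect_warning(f <- compute_thickness(m, m), "zero thickness")
  expect_equal(max(f$thickness_um), 0)
  expect_equal(length(f$flagged), nrow(m$vertices))
})

test_that("thickness is invariant under a rigid motion of both meshes", {
  pair <- make_root_pair(synthetic_spec(seed = 2, n_axial = 14, n_theta = 12,
                                        base_cementum_um = 600))
  base <- compute_thickness(pair$cementum, pair$dentine)$thickness_um
  th <- 0.7
  R <- rbind(c(cos(th), -sin(th), 0), c(sin(th), cos(th), 0), c(0, 0, 1)) %*%
    rbind(c(1, 0, 0), c(0, cos(1.1), -sin(1.1)), c(0, sin(1.1), cos(1.1)))
  move <- function(m) root_mesh(m$vertices %*% t(R) + rep(c(3, -2, 5), each = nrow(m$vertices)),
                                m$faces)
  got <- compute_thickness(move(pair$cementum), move(pair$dentine))$thickness_um
  expect_equal(got, base, tolerance = 1e-9)
})

test_that("the synthetic ground truth is recovered within mesh tolerance", {
  spec <- synthetic_spec(base_cementum_um = 400, seed = 3,
                         angular_gradient = list(direction = "m",
                                                 amplitude_um = 600,
                                                 axial_center = 2))
  pair <- make_root_pair(spec)
  f <- compute_thickness(pair$cementum, pair$dentine)
  # nearest-point distance can only undershoot the normal displacement
  expect_true(all(f$thickness_um <= pair$truth_um + 1e-6))
  err <- abs(f$thickness_um - pair$truth_um)
  ell <- mean_edge_length(pair$cementum)
  # field gradient bound: amplitude over a third of the root length
  slope <- 600 / (spec$root_length_mm / 3 * 1000)
  expect_lt(max(err), 2 * ell * 1000 * slope + 1)
  expect_equal(f$max_thi_um, max(pair$truth_um), tolerance = 1e-6)
})

test_that("the root partition follows the anatomical conventions", {
  pair <- make_root_pair(synthetic_spec(seed = 4))
  part <- partition_root(pair$cementum)
  v <- pair$cementum$vertices

  # axial midpoint lands in the middle third
  mid <- which.min(abs(v[, 3] - pair$cementum$cej_height / 2))
  expect_equal(part$third[mid], 2L)
  # a vertex on the buccal reference direction is scored '<'
  buc <- which(abs(v[, 2]) < 1e-9 & v[, 1] > 0)
  expect_true(all(part$side[buc] == "<"))

  # uniform angular sampling puts ~25% of vertices in each quadrant
  tube <- v[, 3] > 1 & v[, 3] < pair$cementum$cej_height - 0.1
  frac <- table(part$side[tube]) / sum(tube)
  expect_true(all(abs(frac - 0.25) < 0.02))
  expect_error(partition_root(root_mesh(v, pair$cementum$faces)), "apex")
})

test_that("summaries flag preferential apposition per the side-ratio rule", {
  uni <- make_root_pair(synthetic_spec(base_cementum_um = 500, seed = 5))
  f <- compute_thickness(uni$cementum, uni$dentine)
  s <- summarize_thickness(f, partition_root(uni$cementum))
  expect_false(s$pref)
  expect_equal(s$min_side, "No")

  grad <- make_root_pair(synthetic_spec(
    base_cementum_um = 400, seed = 6,
    angular_gradient = list(direction = ">", amplitude_um = 700,
                            axial_center = 1)))
  f2 <- compute_thickness(grad$cementum, grad$dentine)
  s2 <- summarize_thickness(f2, partition_root(grad$cementum))
  expect_true(s2$pref)
  expect_true("1>" %in% s2$loc_max)
  expect_equal(s2$min_side, "<")
  expect_equal(dim(s2$quadrant_means), c(3, 4))
})

test_that("most hyperfunctional reference teeth have their thinnest side buccal", {
  teeth <- load_tooth_table()
  hyper <- teeth[teeth$etiology == "HYPER" & !teeth$excluded, ]
  expect_equal(sum(grepl("<", hyper$loc_min)), 10)
  expect_equal(nrow(hyper), 12)
})
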