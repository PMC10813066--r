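test_that("hypercementosis scores serialize and parse round-trip", {
  for (ty in 1:3) for (st in 1:4) for (fo in c("m", "M")) {
    s <- hc_score(ty, st, fo)
    expect_equal(parse_hc(format(s)), s)
  }
  expect_error(parse_hc("3.5.m"), "stage")
  expect_error(parse_hc("3.3"), "malformed")
  expect_error(hc_score(4, 1, "m"), "type")
})

test_that("record validation flags the documented rule violations", {
  teeth <- load_tooth_table()
  # an internally consistent impacted tooth
  expect_equal(nrow(validate_record(teeth[teeth$tooth_id == "Sp755_13", ])), 0)
  # every packaged record is internally consistent
  all_v <- do.call(rbind, lapply(seq_len(nrow(teeth)), function(i)
    validate_record(teeth[i, ])))
  expect_equal(nrow(all_v), 0)

  r <- teeth[teeth$tooth_id == "Sp755_13", ]
  r$wear_deg <- 5L
  v <- validate_record(r)
  expect_true(any(grepl("impacted", v$rule)))

  r2 <- teeth[teeth$tooth_id == "Sp39_35", ]
  r2$caries_si <- 2L          # site without stage
  expect_true(any(validate_record(r2)$field == "caries_si"))

  r3 <- teeth[teeth$tooth_id == "Sp39_35", ]
  r3$wear_deg <- 1L           # no wear but oblique direction
  expect_true(any(grepl("no wear", validate_record(r3)$rule)))
})

test_that("thickness maps yield the published composite scores", {
  # whole-root diffuse apposition with a nodular focal component,
  # below the marked threshold -> mixed type, stage 3, moderate
  pair <- make_root_pair(synthetic_spec(
    base_cementum_um = 600, seed = 21,
    shape_primitives = list(list(kind = "NOD", third = 2, side = "d",
                                 diameter_mm = 2.6, height_mm = 0.8))))
  f <- compute_thickness(pair$cementum, pair$dentine)
  part <- partition_root(pair$cementum)
  sh <- classify_shape(f, part, pair$cementum)
  expect_equal(format(score_hypercementosis(f, part, shape = sh)), "3.3.m")

  # crownless root entirely covered by marked apposition -> stage 4, M
  pair2 <- make_root_pair(synthetic_spec(
    base_cementum_um = 700, seed = 22,
    angular_gradient = list(direction = ">", amplitude_um = 900,
                            axial_center = 2)))
  f2 <- compute_thickness(pair2$cementum, pair2$dentine)
  part2 <- partition_root(pair2$cementum)
  expect_equal(format(score_hypercementosis(f2, part2, cej_present = FALSE)),
               "1.4.M")

  # apical-only moderate diffuse apposition -> stage 1, moderate
  pair3 <- make_root_pair(synthetic_spec(
    base_cementum_um = 350, seed = 23,
    angular_gradient = list(direction = "d", amplitude_um = 450,
                            axial_center = 1)))
  f3 <- compute_thickness(pair3$cementum, pair3$dentine)
  part3 <- partition_root(pair3$cementum)
  sc3 <- score_hypercementosis(f3, part3)
  expect_equal(format(sc3), "1.1.m")
})

test_that("the derived score is monotone in the thickness field", {
  pair <- make_root_pair(synthetic_spec(base_cementum_um = 450, seed = 24))
  part <- partition_root(pair$cementum)
  rank_stage <- function(boost) {
    f <- compute_thickness(pair$cementum, pair$dentine)
    f$thickness_um <- f$thickness_um + boost
    f$max_thi_um <- max(f$thickness_um)
    s <- score_hypercementosis(f, part)
    c(s$stage, match(s$form, c("m", "M")))
  }
  prev <- c(0, 0)
  for (boost in c(0, 200, 600, 1200)) {
    cur <- rank_stage(boost)
    expect_true(all(cur >= prev))
    prev <- cur
  }
})
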