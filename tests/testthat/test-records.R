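test_that("the packaged dataset has the documented structure", {
  teeth <- load_tooth_table()
  expect_s3_class(teeth, "tooth_records")
  expect_equal(nrow(teeth), 35)
  expect_equal(length(unique(teeth$specimen_id)), 23)
  expect_equal(sum(teeth$excluded), 2)
  expect_setequal(teeth$tooth_id[teeth$excluded],
                  c("Sp1010_44", "Sp1230_44"))

  # tooth-type composition of the full sample (by FDI position)
  expect_equal(as.vector(table(teeth$tooth_type)[c("I1", "I2", "C", "P3", "P4")]),
               c(4, 2, 9, 9, 11))

  # etiology composition of the 33 analysed teeth
  inc <- teeth[!teeth$excluded, ]
  expect_equal(as.vector(table(inc$etiology)[c("HYPER", "HYPO", "IMP", "INF", "MIX")]),
               c(12, 5, 2, 4, 10))
  expect_true(all(inc$max_thi_um >= 740 & inc$max_thi_um <= 2770))
})

test_that("individual records carry the published values", {
  teeth <- load_tooth_table()
  r <- teeth[teeth$tooth_id == "Sp755_13", ]
  expect_equal(r$max_thi_um, 1000)
  expect_true(r$pref)
  expect_equal(r$loc_max, "2d")
  expect_equal(r$loc_max_thirds[[1]], 2L)
  expect_equal(r$loc_max_sides[[1]], "d")
  expect_true(r$impacted)
  expect_equal(as.character(r$ant), "0")
  expect_equal(r$ba_code, "URC")

  # composite localization codes parse into third/side sets
  r2 <- teeth[teeth$tooth_id == "Sp1135_11", ]
  expect_equal(r2$loc_max_thirds[[1]], c(1L, 2L))
  expect_setequal(r2$loc_max_sides[[1]], c(">", "d", "m"))
  expect_true(all(teeth$loc_max_parsed))

  # crownless wear recoded, unscorable antagonist recoded
  inf <- teeth[teeth$etiology == "INF", ]
  expect_true(all(inf$wear_deg == 0))
  expect_equal(as.character(teeth$ant[teeth$tooth_id == "Sp914_43"]), "3")
})

test_that("a corrupt table fails loudly naming the offending record", {
  teeth <- read.csv(system.file("extdata", "sains_table2.csv",
                                package = "cementmap"),
                    colClasses = "character", na.strings = character())
  bad <- teeth
  bad$max_thi_um[bad$tooth_id == "Sp17_15"] <- "-50"
  f <- tempfile(fileext = ".csv")
  write.csv(bad, f, row.names = FALSE, na = "")
  expect_error(load_tooth_table(f), "Sp17_15")

  bad2 <- teeth
  bad2$pref[3] <- "maybe"
  write.csv(bad2, f, row.names = FALSE, na = "")
  expect_error(load_tooth_table(f), "pref")
})

test_that("group summaries reproduce the published statistics", {
  teeth <- load_tooth_table()
  gs <- group_summary(teeth, "max_thi_um")
  row <- function(g) gs[gs$group == g, ]

  expect_equal(row("INF")$mean, 1740)
  expect_equal(row("INF")$sd, 375)
  expect_equal(row("INF")$min, 1380)
  expect_equal(row("INF")$max, 2160)
  expect_equal(row("IMP")$mean, 1035)
  expect_equal(row("IMP")$n, 2)

  # single-value group: mean defined, sd not
  one <- group_summary(teeth[teeth$tooth_id == "Sp755_13", ], "max_thi_um",
                       use_excluded = TRUE)
  expect_equal(one$mean, 1000)
  expect_true(is.na(one$sd))

  # vertical elevation of the hypofunctional group, excluding the
  # fracture-area measurement
  ve <- group_summary(teeth, "max_ve_um", exclude = "Sp17_15")
  expect_equal(ve[ve$group == "HYPO", "mean"], 150)
  expect_equal(ve[ve$group == "HYPO", "n"], 4)
})

test_that("group_summary is permutation-invariant and scale-equivariant", {
  teeth <- load_tooth_table()
  base <- group_summary(teeth, "max_thi_um")
  perm <- group_summary(teeth[sample(nrow(teeth)), ], "max_thi_um")
  expect_equal(base, perm)

  scaled <- teeth
  scaled$max_thi_um <- scaled$max_thi_um * 3
  gs3 <- group_summary(scaled, "max_thi_um")
  expect_equal(gs3$mean_raw, base$mean_raw * 3)
  expect_equal(gs3$sd_raw, base$sd_raw * 3)
  expect_equal(gs3$min, base$min * 3)
  expect_equal(gs3$max, base$max * 3)
})
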