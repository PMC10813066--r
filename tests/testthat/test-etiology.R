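test_that("the published tree routes the documented cases", {
  expect_equal(apply_published_tree(list(pref = TRUE, ant = "1"))$label,
               "HYPER")
  r <- apply_published_tree(list(pref = FALSE, wear_deg = 0))
  expect_equal(r$label, "INF")
  expect_equal(r$leaf, "inf_pure")

  # the one mixed-condition tooth that routes to the hyperfunctional leaf
  sp735 <- apply_published_tree(list(pref = TRUE, ant = "2",
                                     max_thi_um = 1230, wear_deg = 4))
  expect_equal(sp735$leaf, "hyper_mix")
  expect_equal(sp735$label, "HYPER")
  expect_true(any(grepl("1295", sp735$trace)))

  # missing value on the traversed path: explicit unroutable result
  miss <- apply_published_tree(list(pref = FALSE, wear_deg = 3,
                                    max_ve_um = NA))
  expect_equal(miss$label, "unroutable")
})

test_that("the published tree reproduces every leaf of the reference sample", {
  feats <- tree_features(load_tooth_table())
  expect_equal(nrow(feats), 33)
  pur <- leaf_purity(published_tree(), feats)

  expect_equal(pur$n_leaves, 7)
  expect_equal(pur$n_pure, 6)
  expect_equal(pur$misclassified, "Sp735_45")

  tab <- pur$leaf_counts
  expect_equal(as.vector(tab["hyper_pure", ]), c(8, 0, 0, 0, 0))
  expect_equal(as.vector(tab["mix_thick", ]), c(0, 0, 0, 0, 5))
  expect_equal(as.vector(tab["imp_pure", ]), c(0, 0, 2, 0, 0))
  expect_equal(as.vector(tab["hyper_mix", ]), c(4, 0, 0, 0, 1))
  expect_equal(as.vector(tab["inf_pure", ]), c(0, 0, 0, 4, 0))
  expect_equal(as.vector(tab["hypo_pure", ]), c(0, 5, 0, 0, 0))
  expect_equal(as.vector(tab["mix_nonpref", ]), c(0, 0, 0, 0, 4))
})

test_that("routing is total and permutation-invariant over the sample", {
  feats <- tree_features(load_tooth_table())
  tr <- published_tree()
  base <- route_tree(tr, feats)
  expect_false(any(is.na(base$leaf)))
  set.seed(8)
  p <- sample(nrow(feats))
  perm <- route_tree(tr, feats[p, ])
  expect_equal(perm$leaf, base$leaf[p])
})

test_that("the diagnostic criteria identify the group profiles", {
  # impacted profile
  imp <- classify_table3(list(pref = TRUE, ant = "0", wear_deg = 1,
                              caries_si = NA, pulp_exp = "none",
                              hc_stage = 3, max_thi_um = 1000,
                              max_ve_um = 600))
  expect_equal(imp$etiology, "IMP")

  # pulp exposure with non-preferential apposition
  inf <- classify_table3(list(pref = FALSE, ant = "1", wear_deg = 0,
                              caries_si = 1, pulp_exp = "M",
                              hc_stage = 4, max_thi_um = 1700,
                              max_ve_um = 400))
  expect_equal(inf$etiology, "INF")

  # an all-absent record matches no profile
  empty <- classify_table3(list(pref = FALSE, ant = NA, wear_deg = NA,
                                caries_si = NA, pulp_exp = NA,
                                hc_stage = NA, max_thi_um = NA,
                                max_ve_um = NA))
  expect_equal(empty$etiology, "indeterminate")
  expect_equal(nrow(empty$trace), 4)

  # records matching several profiles fall back to the mixed condition
  mix <- classify_table3(list(pref = FALSE, ant = "1", wear_deg = 2,
                              caries_si = 2, pulp_exp = "C",
                              hc_stage = 2, max_thi_um = 1200,
                              max_ve_um = 150))
  expect_equal(mix$etiology, "MIX")
  expect_setequal(mix$full_match, c("INF", "HYPO"))
})

test_that("the CART learner agrees with exhaustive split enumeration", {
  # degenerate single-class input: a single leaf
  single <- fit_cart(data.frame(x = rnorm(6)), rep("a", 6))
  expect_equal(single$root$type, "leaf")
  expect_equal(predict(single, data.frame(x = 0)), "a")

  # perfectly separable one-dimensional data split at the midpoint
  d <- data.frame(x = c(1, 2, 3, 10, 11, 12))
  y <- rep(c("lo", "hi"), each = 3)
  tr <- fit_cart(d, y)
  expect_equal(tr$root$var, "x")
  expect_equal(tr$root$split$threshold, 6.5)
  expect_equal(predict(tr, data.frame(x = c(0, 100))), c("lo", "hi"))

  # the root split of the reference encoding matches the oracle
  feats <- tree_features(load_tooth_table())
  d2 <- feats[, c("pref", "ant", "max_thi_um", "wear_deg")]
  tr2 <- fit_cart(d2, feats$etiology)
  want <- oracle_best_split(d2, feats$etiology)
  expect_equal(tr2$root$var, want$var)
  expect_equal(tr2$root$gain, want$gain, tolerance = 1e-12)

  # every split of trees over random small mixed tables matches the
  # oracle gain at the root
  set.seed(33)
  for (rep in 1:5) {
    n <- 30
    dd <- data.frame(a = rnorm(n), b = sample(letters[1:3], n, TRUE),
                     c = rpois(n, 3))
    yy <- factor(ifelse(dd$a + (dd$b == "a") > 0.5, "u", "v"))
    if (length(unique(yy)) < 2) next
    fit <- fit_cart(dd, yy, min_leaf = 2, max_depth = 3)
    orc <- oracle_best_split(dd, yy)
    expect_equal(fit$root$gain, orc$gain, tolerance = 1e-12)
  }
})

test_that("the CART first split agrees with an independent rpart fit", {
  skip_if_not_installed("rpart")
  set.seed(5)
  d <- data.frame(x = c(rnorm(25, 0), rnorm(25, 4)),
                  z = rnorm(50))
  y <- factor(rep(c("a", "b"), each = 25))
  mine <- fit_cart(d, y, min_leaf = 7)
  rp <- rpart::rpart(y ~ ., data = cbind(d, y), method = "class",
                     control = rpart::rpart.control(minbucket = 7, cp = 0.01))
  expect_equal(mine$root$var, as.character(rp$frame$var[1]))
  expect_equal(mine$root$split$threshold, rp$splits[1, "index"],
               tolerance = 0.2)
})

test_that("leaf purity handles degenerate trees", {
  d <- data.frame(x = rnorm(5))
  y <- rep("a", 5)
  tr <- fit_cart(d, y)
  pur <- leaf_purity(tr, d, labels = y, ids = letters[1:5])
  expect_equal(pur$n_pure, 1)
  expect_equal(pur$n_leaves, 1)
  expect_equal(length(pur$misclassified), 0)
})
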