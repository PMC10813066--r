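# Independent oracles used to cross-check the package implementations.
# These deliberately use different algorithms from the code under test.

# Point-to-triangle distance via plane-foot / edge decomposition (the
# package's C++ kernel uses the region-based closed form instead).
r_point_seg_dist <- function(p, a, b) {
  ab <- b - a
  t <- sum((p - a) * ab) / sum(ab * ab)
  t <- min(max(t, 0), 1)
  sqrt(sum((p - (a + t * ab))^2))
}

r_point_tri_dist <- function(p, a, b, c) {
  n <- c((b - a)[2] * (c - a)[3] - (b - a)[3] * (c - a)[2],
         (b - a)[3] * (c - a)[1] - (b - a)[1] * (c - a)[3],
         (b - a)[1] * (c - a)[2] - (b - a)[2] * (c - a)[1])
  nn <- sqrt(sum(n^2))
  d_edges <- min(r_point_seg_dist(p, a, b),
                 r_point_seg_dist(p, b, c),
                 r_point_seg_dist(p, c, a))
  if (nn < 1e-14) return(d_edges)
  n <- n / nn
  dist_plane <- sum((p - a) * n)
  foot <- p - dist_plane * n
  # barycentric coordinates of the foot point
  v0 <- c - a; v1 <- b - a; v2 <- foot - a
  d00 <- sum(v0 * v0); d01 <- sum(v0 * v1); d11 <- sum(v1 * v1)
  d20 <- sum(v2 * v0); d21 <- sum(v2 * v1)
  den <- d00 * d11 - d01 * d01
  u <- (d11 * d20 - d01 * d21) / den
  v <- (d00 * d21 - d01 * d20) / den
  if (u >= 0 && v >= 0 && u + v <= 1) min(abs(dist_plane), d_edges)
  else d_edges
}

r_point_mesh_distance <- function(points, mesh) {
  v <- mesh$vertices; f <- mesh$faces
  apply(points, 1, function(p) {
    min(vapply(seq_len(nrow(f)), function(i)
      r_point_tri_dist(p, v[f[i, 1], ], v[f[i, 2], ], v[f[i, 3], ]), 0))
  })
}

# Exhaustive Gini-gain enumeration over every variable and every binary
# split (numeric thresholds at midpoints; categorical level subsets).
oracle_gini <- function(counts) {
  n <- sum(counts)
  if (n == 0) return(0)
  1 - sum((counts / n)^2)
}

oracle_best_split <- function(data, y) {
  y <- as.factor(y)
  n <- length(y)
  parent <- oracle_gini(table(y))
  best <- list(gain = -Inf)
  consider <- function(go_left, var, descr) {
    nl <- sum(go_left)
    if (nl == 0 || nl == n) return()
    gain <- parent -
      (nl * oracle_gini(table(y[go_left])) +
         (n - nl) * oracle_gini(table(y[!go_left]))) / n
    if (gain > best$gain + 1e-12)
      best <<- list(gain = gain, var = var, descr = descr)
  }
  for (var in names(data)) {
    x <- data[[var]]
    if (is.numeric(x)) {
      ux <- sort(unique(x))
      if (length(ux) < 2) next
      for (t in (ux[-1] + ux[-length(ux)]) / 2)
        consider(x < t, var, t)
    } else {
      lev <- sort(unique(as.character(x)))
      k <- length(lev)
      if (k < 2) next
      for (mask in 1:(2^k - 2)) {
        sel <- as.logical(bitwAnd(mask, 2^(seq_len(k) - 1)))
        consider(as.character(x) %in% lev[sel], var, lev[sel])
      }
    }
  }
  best
}

# Multiple correspondence analysis as plain correspondence analysis of
# the indicator matrix (row-profile chi-square scaling + SVD).
oracle_mca_eigen <- function(df) {
  Z <- NULL
  for (nm in names(df)) {
    f <- as.factor(df[[nm]])
    Z <- cbind(Z, stats::model.matrix(~ f - 1))
  }
  P <- Z / sum(Z)
  r <- rowSums(P); cc <- colSums(P)
  S <- diag(1 / sqrt(r)) %*% (P - r %*% t(cc)) %*% diag(1 / sqrt(cc))
  sv <- svd(S)$d
  sv[sv > 1e-10]^2
}

# Random primitives with dimensions at least 20% away from the category
# boundaries (2 mm single/cluster cut, 3 mm overgrowth cut, 1/2/0.5 mm
# ridge rules), used by parameter-recovery experiments.
sample_shape_primitive <- function(kind) {
  switch(kind,
    NOD = list(kind = "NOD", diameter_mm = runif(1, 2.4, 2.9),
               height_mm = runif(1, 0.8, 1.2),
               third = sample(1:3, 1)),
    Nds = list(kind = "Nds", diameter_mm = runif(1, 1.0, 1.55),
               height_mm = runif(1, 0.5, 0.8), count = sample(3:5, 1),
               third = sample(1:3, 1)),
    OG  = list(kind = "OG", diameter_mm = runif(1, 3.8, 4.5),
               height_mm = runif(1, 1.0, 1.3),
               third = sample(1:3, 1)),
    RID = list(kind = "RID", width_mm = runif(1, 0.6, 0.8),
               length_mm = runif(1, 2.6, 3.2),
               height_mm = runif(1, 0.65, 0.9), count = sample(3:4, 1),
               third = sample(1:2, 1)),
    LSP = list(kind = "LSP", diameter_mm = runif(1, 1.1, 1.5),
               height_mm = runif(1, 0.6, 0.9),
               third = sample(1:3, 1)))
}

# One recovery replicate: a synthetic root carrying either one shape
# primitive (shape + thickness recovery) or an angular gradient
# (preferential-flag recovery). Returns truth and measured labels.
recovery_replicate <- function(i) {
  set.seed(7000 + i)
  if (i %% 2 == 1) {
    kind <- c("NOD", "Nds", "OG", "RID", "LSP")[((i - 1) %/% 2) %% 5 + 1]
    pr <- sample_shape_primitive(kind)
    pr$side <- sample(c("m", "d", "<", ">"), 1)
    spec <- synthetic_spec(base_cementum_um = runif(1, 300, 500),
                           shape_primitives = list(pr), seed = 7000 + i)
    truth <- list(kind = kind, pref = FALSE)
  } else {
    has_grad <- (i %% 4) == 0
    spec <- synthetic_spec(
      base_cementum_um = runif(1, 300, 500),
      angular_gradient = if (has_grad)
        list(direction = sample(c("m", "d", "<", ">"), 1),
             amplitude_um = runif(1, 500, 800),
             axial_center = sample(1:3, 1)),
      texture = list(amplitude_um = runif(1, 50, 200)),
      seed = 7000 + i)
    truth <- list(kind = "none", pref = has_grad)
  }
  pair <- make_root_pair(spec)
  part <- partition_root(pair$cementum)
  # ground-truth preference from the analytic field itself, under the
  # same side-ratio rule; near-boundary draws are flagged
  side_means <- tapply(pair$truth_um, part$side, mean)
  ratio <- max(side_means) / min(side_means)
  truth$pref <- ratio >= 1.5
  truth$pref_boundary <- ratio > 1.25 && ratio < 1.8

  field <- suppressWarnings(compute_thickness(pair$cementum, pair$dentine))
  summ <- summarize_thickness(field, part)
  shape <- classify_shape(field, part, pair$cementum)
  list(truth = truth, pref = summ$pref, kind = shape$kind,
       has_primitive = length(spec$shape_primitives) > 0,
       max_thi_err_um = abs(field$max_thi_um - max(pair$truth_um)),
       mean_edge_mm = mean_edge_length(pair$cementum))
}

mean_edge_length <- function(mesh) {
  f <- mesh$faces; v <- mesh$vertices
  e <- rbind(f[, 1:2], f[, 2:3], f[, c(3, 1)])
  mean(sqrt(rowSums((v[e[, 1], ] - v[e[, 2], ])^2)))
}

# UV sphere as a closed root_mesh (poles + latitude rings).
uv_sphere_mesh <- function(radius, n_lat = 40, n_lon = 42) {
  lat <- seq(0, pi, length.out = n_lat + 2)[2:(n_lat + 1)]
  lon <- 2 * pi * (seq_len(n_lon) - 1) / n_lon
  verts <- rbind(c(0, 0, radius))
  for (la in lat)
    verts <- rbind(verts, cbind(radius * sin(la) * cos(lon),
                                radius * sin(la) * sin(lon),
                                radius * cos(la)))
  verts <- rbind(verts, c(0, 0, -radius))
  idx <- function(i, k) 1L + (i - 1L) * n_lon + ((k - 1L) %% n_lon) + 1L
  bottom <- nrow(verts)
  faces <- NULL
  for (k in seq_len(n_lon))
    faces <- rbind(faces, c(1L, idx(1, k), idx(1, k + 1)))
  for (i in seq_len(n_lat - 1)) for (k in seq_len(n_lon))
    faces <- rbind(faces,
                   c(idx(i, k), idx(i + 1, k), idx(i + 1, k + 1)),
                   c(idx(i, k), idx(i + 1, k + 1), idx(i, k + 1)))
  for (k in seq_len(n_lon))
    faces <- rbind(faces, c(bottom, idx(n_lat, k + 1), idx(n_lat, k)))
  root_mesh(verts, faces, apex_point = c(0, 0, -radius),
            cej_height = radius)
}
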