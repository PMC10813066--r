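#' Classify atypical cementum apposition shapes
#'
#' Detects focal appositions as connected components of cementum vertices
#' whose thickness exceeds the root baseline (median thickness) by a
#' prominence threshold, measures each component and assigns the first
#' matching category. Dimensions are measured robustly to mesh
#' discretization in local surface coordinates (axial position x
#' circumferential arc), which removes the outward bulge of the
#' apposition itself from the in-surface extents: the footprint diameter
#' is the equivalent-circle diameter of the component's convex-hull
#' area, and length/width are principal-component extents corrected by
#' one local edge length. Categories:
#' \itemize{
#'   \item `OG` — atypical overgrowth: a component wrapping two or more
#'     sides with a diameter over 3 mm;
#'   \item `RID` — ridges: at least three elongated oblique components,
#'     each under 1 mm wide, over 2 mm long and over 0.5 mm high;
#'   \item `Nds` — nodules: two or more components, each under 2 mm and
#'     collectively roughly hemispherical (median elongation below 2);
#'   \item `NOD` — node: a single well-defined component over 2 mm;
#'   \item `LSP` — localized spike-like projection: a single component
#'     under 2 mm carrying multiple sharp local maxima (spikes);
#'   \item `none` otherwise.
#' }
#'
#' @param field A `thickness_field`.
#' @param partition Output of [partition_root()].
#' @param mesh The cementum `root_mesh` the field lives on.
#' @param prominence_um Thickness above the median from which a vertex
#'   belongs to a focal component (default 300).
#' @param min_component Minimum component size in vertices (default 3;
#'   smaller islands are noise).
#' @return An `apposition_shape`: list with `kind` and a `components`
#'   data frame (third, side, diameter_mm, height_mm, length_mm, width_mm,
#'   elongation, obliquity_deg, n_sides, n_peaks, n_vertices).
#' @export
classify_shape <- function(field, partition, mesh, prominence_um = 300,
                           min_component = 3L) {
  th <- field$thickness_um
  stopifnot(length(th) == nrow(mesh$vertices))
  baseline <- median(th)
  above <- th > baseline + prominence_um
  comps <- list()
  if (any(above)) {
    adj <- vertex_adjacency(mesh)
    varea <- vertex_areas(mesh)
    comp_id <- connected_components(which(above), adj)
    for (cid in unique(comp_id$comp)) {
      vi <- comp_id$vertex[comp_id$comp == cid]
      if (length(vi) < min_component) next
      m <- measure_component(vi, th, baseline, mesh, partition, adj, varea)
      # sub-resolution slivers (a few boundary vertices straddling the
      # threshold) are discretization noise, not appositions
      if (m$diameter_mm < 0.15 && m$length_mm < 0.3) next
      comps[[length(comps) + 1L]] <- m
    }
  }
  components <- if (length(comps)) do.call(rbind, comps) else
    data.frame(third = integer(), side = character(),
               diameter_mm = numeric(), height_mm = numeric(),
               length_mm = numeric(), width_mm = numeric(),
               elongation = numeric(), obliquity_deg = numeric(),
               n_sides = integer(), n_peaks = integer(),
               n_vertices = integer())
  kind <- assign_shape_kind(components)
  structure(list(kind = kind, components = components,
                 baseline_um = baseline, prominence_um = prominence_um),
            class = "apposition_shape")
}

assign_shape_kind <- function(cm) {
  n <- nrow(cm)
  if (n == 0) return("none")
  elongated <- cm$elongation >= 2
  oblique <- cm$obliquity_deg >= 15 & cm$obliquity_deg <= 75
  bulky <- cm$width_mm > 1.5
  if (any(cm$n_sides >= 2 & cm$diameter_mm > 3 & bulky)) return("OG")
  rid <- elongated & oblique & cm$width_mm < 1 & cm$length_mm > 2 &
    cm$height_mm > 0.5
  if (sum(rid) >= 3) return("RID")
  if (n >= 2 && all(cm$diameter_mm < 2) && median(cm$elongation) < 2)
    return("Nds")
  if (n == 1 && cm$diameter_mm > 2) return("NOD")
  if (n == 1 && cm$diameter_mm < 2 && cm$n_peaks >= 2) return("LSP")
  "none"
}

#' @export
print.apposition_shape <- function(x, ...) {
  cat(sprintf("apposition shape: %s (%d component%s)\n", x$kind,
              nrow(x$components), if (nrow(x$components) == 1) "" else "s"))
  if (nrow(x$components))
    print(cbind(x$components[, c("third", "side")],
                round(x$components[, c("diameter_mm", "height_mm",
                                       "length_mm", "width_mm",
                                       "obliquity_deg")], 2)))
  invisible(x)
}

# Breadth-first connected components over the mesh adjacency restricted
# to a vertex subset.
connected_components <- function(vset, adj) {
  inset <- logical(length(adj))
  inset[vset] <- TRUE
  comp <- integer(length(adj))
  cur <- 0L
  for (v in vset) {
    if (comp[v] != 0L) next
    cur <- cur + 1L
    queue <- v
    comp[v] <- cur
    while (length(queue)) {
      u <- queue[[1]]
      queue <- queue[-1]
      nb <- adj[[u]]
      nb <- nb[inset[nb] & comp[nb] == 0L]
      comp[nb] <- cur
      queue <- c(queue, nb)
    }
  }
  data.frame(vertex = vset, comp = comp[vset])
}

# One third of each incident triangle area accrues to a vertex.
vertex_areas <- function(mesh) {
  fn <- face_normals(mesh)
  fa <- sqrt(rowSums(fn^2)) / 2
  out <- numeric(nrow(mesh$vertices))
  for (k in 1:3)
    out <- out + tabulate_add(mesh$faces[, k], fa / 3, length(out))
  out
}

# Local surface coordinates of a component: axial position u and
# circumferential arc v (angle unwrapped about the component centre times
# the mean radius), so in-surface extents ignore the outward bulge.
component_uv <- function(vi, mesh) {
  v <- mesh$vertices[vi, , drop = FALSE]
  ax <- mesh$axis
  s <- as.numeric(v %*% ax)
  b <- mesh$buccal_reference
  m <- cross3(ax, b)
  rad <- v - outer(s, ax)
  phi <- atan2(rad %*% m, rad %*% b)
  phi0 <- atan2(mean(sin(phi)), mean(cos(phi)))
  dphi <- (phi - phi0 + pi) %% (2 * pi) - pi
  rbar <- mean(sqrt(rowSums(rad^2)))
  cbind(u = s - mean(s), v = as.numeric(dphi) * rbar)
}

measure_component <- function(vi, th, baseline, mesh, partition, adj,
                              varea) {
  height <- (max(th[vi]) - baseline) / 1000
  uv <- component_uv(vi, mesh)

  # mean in-surface edge length among component vertices: the
  # quantization scale of all footprint measurements
  inset <- logical(length(adj))
  inset[vi] <- TRUE
  elen <- numeric(0)
  for (v in vi) {
    nb <- adj[[v]]
    nb <- nb[inset[nb] & nb > v]
    if (length(nb)) {
      iuv <- match(c(v, nb), vi)
      elen <- c(elen, sqrt((uv[iuv[-1], 1] - uv[iuv[1], 1])^2 +
                           (uv[iuv[-1], 2] - uv[iuv[1], 2])^2))
    }
  }
  ell <- if (length(elen)) mean(elen) else 0

  # footprint diameter: equivalent circle of the convex-hull area
  diameter <- if (nrow(uv) >= 3 && nrow(unique(uv)) >= 3) {
    h <- grDevices::chull(uv)
    hx <- uv[h, 1]; hy <- uv[h, 2]
    A <- abs(sum(hx * c(hy[-1], hy[1]) - c(hx[-1], hx[1]) * hy)) / 2
    2 * sqrt(A / pi)
  } else max(dist(uv))

  if (nrow(uv) >= 3) {
    pc <- prcomp(uv, center = TRUE)
    proj <- sweep(uv, 2, colMeans(uv)) %*% pc$rotation
    len <- max(diff(range(proj[, 1])) - ell, ell)
    wid <- max(diff(range(proj[, 2])) - ell, ell)
    # scale-free anisotropy: robust to boundary jaggedness where the
    # range-based extents are one or two edge lengths wide
    elong <- pc$sdev[1] / max(pc$sdev[2], 1e-9)
    obli <- atan2(abs(pc$rotation[2, 1]), abs(pc$rotation[1, 1])) * 180 / pi
  } else {
    len <- diameter; wid <- diameter; elong <- 1; obli <- 90
  }

  side_tab <- table(partition$side[vi]) / length(vi)
  n_sides <- sum(side_tab >= 0.1)
  imax <- vi[which.max(th[vi])]
  peaks <- count_local_maxima(vi, th, adj, baseline)

  data.frame(third = partition$third[imax],
             side = as.character(partition$side[imax]),
             diameter_mm = diameter, height_mm = height,
             length_mm = len, width_mm = wid, elongation = elong,
             obliquity_deg = obli, n_sides = n_sides,
             n_peaks = peaks, n_vertices = length(vi))
}

# Strict local maxima of the thickness within a component, restricted to
# its upper half (avoids boundary artifacts); refinement-stable because it
# counts peaks of the analytic field, not curvature magnitudes.
count_local_maxima <- function(vi, th, adj, baseline) {
  hmax <- max(th[vi])
  cut <- baseline + 0.5 * (hmax - baseline)
  inset <- logical(length(adj))
  inset[vi] <- TRUE
  n <- 0L
  for (v in vi) {
    if (th[v] < cut) next
    nb <- adj[[v]]
    nb <- nb[inset[nb]]
    if (length(nb) && all(th[v] > th[nb])) n <- n + 1L
  }
  n
}
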