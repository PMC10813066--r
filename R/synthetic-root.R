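#' Specification for a synthetic tooth root
#'
#' Describes a synthetic single-rooted tooth: a tapered superellipse tube
#' capped by a rounded apex (the dentine core), plus an analytic cementum
#' apposition field that displaces the core outward into the cementum
#' envelope. The apposition field is the sum of a uniform base layer, an
#' optional angular gradient (preferential apposition towards one
#' anatomical side, centred on one root third), optional atypical shape
#' primitives (node `NOD`, nodule cluster `Nds`, atypical overgrowth `OG`,
#' oblique ridges `RID`, localized spike-like projection `LSP`) and an
#' optional smooth random texture. Because the field is analytic, every
#' generated root carries its exact per-vertex ground truth, which the
#' thickness-mapping pipeline can be tested against.
#'
#' Anatomical convention: the buccal direction `<` is the `buccal_reference`
#' vector (angle 0 about the axis), mesial `m` at +90 degrees, lingual `>`
#' opposite, distal `d` at -90 degrees; root thirds are numbered 1 (apical)
#' to 3 (cervical).
#'
#' @param root_length_mm Apex-to-CEJ length (default 12).
#' @param base_radius_mm Dentine radius at the CEJ (default 3).
#' @param taper Apex/CEJ radius ratio in (0, 1] (default 0.35).
#' @param base_cementum_um Uniform cementum layer (default 300).
#' @param angular_gradient `NULL` or
#'   `list(direction, amplitude_um, axial_center)` with `direction` one of
#'   `"m","d","<",">"` and `axial_center` a root third 1..3.
#' @param shape_primitives List of primitives; each is a list with `kind`
#'   (`"NOD"`, `"Nds"`, `"OG"`, `"RID"` or `"LSP"`), `third`, `side`, and
#'   kind-specific dimensions (see [shape_primitive()] for defaults).
#' @param texture `NULL` or `list(amplitude_um, correlation_length_um)` —
#'   a smooth random thickness modulation of given peak-to-valley
#'   amplitude.
#' @param seed Integer seed; the seed fully determines the output.
#' @param n_axial,n_theta Mesh resolution (rings and sectors; `n_theta`
#'   should be a multiple of 4 so quadrant boundaries fall between
#'   sectors).
#' @param superellipse Cross-section exponent (2 = circular).
#' @return A `synthetic_spec` list.
#' @examples
#' spec <- synthetic_spec(base_cementum_um = 500, seed = 1)
#' pair <- make_root_pair(spec)
#' range(pair$truth_um)     # constant 500
#' @export
synthetic_spec <- function(root_length_mm = 12, base_radius_mm = 3,
                           taper = 0.35, base_cementum_um = 300,
                           angular_gradient = NULL,
                           shape_primitives = list(),
                           texture = NULL, seed = 1,
                           n_axial = 48, n_theta = 40,
                           superellipse = 2) {
  stopifnot(root_length_mm > 0, base_radius_mm > 0,
            taper > 0, taper <= 1, base_cementum_um >= 0,
            n_axial >= 12, n_theta >= 12)
  if (!is.null(angular_gradient)) {
    stopifnot(angular_gradient$direction %in% c("m", "d", "<", ">"),
              angular_gradient$amplitude_um >= 0,
              angular_gradient$axial_center %in% 1:3)
  }
  shape_primitives <- lapply(shape_primitives, function(p)
    do.call(shape_primitive, p))
  if (!is.null(texture)) stopifnot(texture$amplitude_um >= 0)
  structure(list(root_length_mm = root_length_mm,
                 base_radius_mm = base_radius_mm, taper = taper,
                 base_cementum_um = base_cementum_um,
                 angular_gradient = angular_gradient,
                 shape_primitives = shape_primitives,
                 texture = texture, seed = as.integer(seed),
                 n_axial = as.integer(n_axial),
                 n_theta = as.integer(n_theta),
                 superellipse = superellipse),
            class = "synthetic_spec")
}

#' Atypical apposition shape primitive
#'
#' Parameterizes one focal apposition added to a synthetic root. Default
#' dimensions sit comfortably inside each category's published size rules:
#' a node is a single protuberance over 2 mm across, nodules are
#' under-2-mm hemispherical protuberances occurring in clusters, an
#' atypical overgrowth exceeds 3 mm and wraps around two or more sides,
#' ridges are oblique elongated bumps (width < 1 mm, length > 2 mm, height
#' > 0.5 mm) in series, and a localized spike-like projection is a
#' spiked sphere under 2 mm.
#'
#' @param kind One of `"NOD"`, `"Nds"`, `"OG"`, `"RID"`, `"LSP"`.
#' @param third Root third (1 apical .. 3 cervical) of the centre.
#' @param side Anatomical side (`"m"`, `"d"`, `"<"`, `">"`) of the centre.
#' @param diameter_mm,height_mm Footprint diameter and peak height.
#' @param count Number of components (`Nds` cluster size, `RID` ridges).
#' @param length_mm,width_mm Ridge dimensions (RID only).
#' @param obliquity_deg Ridge angle to the root axis (RID only).
#' @param angular_extent_deg Angular wrap of an overgrowth (OG only).
#' @return A validated primitive description list.
#' @export
shape_primitive <- function(kind, third = 2, side = "d",
                            diameter_mm = NULL, height_mm = NULL,
                            count = NULL, length_mm = NULL, width_mm = NULL,
                            obliquity_deg = 45, angular_extent_deg = 150) {
  kind <- match.arg(kind, c("NOD", "Nds", "OG", "RID", "LSP"))
  stopifnot(third %in% 1:3, side %in% c("m", "d", "<", ">"))
  def <- switch(kind,
    NOD = list(diameter_mm = 2.6, height_mm = 1.0, count = 1),
    Nds = list(diameter_mm = 1.2, height_mm = 0.6, count = 4),
    OG  = list(diameter_mm = 4.0, height_mm = 1.2, count = 1),
    RID = list(diameter_mm = NA, height_mm = 0.65, count = 4,
               length_mm = 3.0, width_mm = 0.8),
    LSP = list(diameter_mm = 1.4, height_mm = 0.8, count = 5))
  p <- list(kind = kind, third = third, side = side,
            diameter_mm = diameter_mm %||% def$diameter_mm,
            height_mm = height_mm %||% def$height_mm,
            count = count %||% def$count,
            length_mm = length_mm %||% def$length_mm,
            width_mm = width_mm %||% def$width_mm,
            obliquity_deg = obliquity_deg,
            angular_extent_deg = angular_extent_deg)
  stopifnot(p$height_mm > 0)
  p
}

side_angle <- function(side) {
  c("<" = 0, "m" = pi / 2, ">" = pi, "d" = 3 * pi / 2)[[side]]
}

# Compactly supported bump profile on [0, 1): steep shoulders so that the
# thresholded footprint tracks the nominal diameter.
bump_profile <- function(x) {
  w <- 1 - pmin(abs(x), 1)^6
  w[abs(x) >= 1] <- 0
  w
}

# Wrapped angular difference in (-pi, pi]
ang_diff <- function(a, b) {
  d <- (a - b) %% (2 * pi)
  ifelse(d > pi, d - 2 * pi, d)
}

#' Generate a synthetic dentine/cementum root pair with ground truth
#'
#' Builds the dentine core mesh described by a [synthetic_spec()], then
#' displaces every vertex outward along its normal by the analytic
#' apposition field to obtain the cementum envelope. The displacement (in
#' micrometres) is returned as the exact per-vertex ground-truth thickness.
#'
#' @param spec A `synthetic_spec`.
#' @return A list with elements `dentine` and `cementum` (both
#'   `root_mesh`), `truth_um` (numeric, one value per cementum vertex) and
#'   `param` (per-vertex axial coordinate `z_mm` and angle `theta`).
#' @export
make_root_pair <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  check_primitive_feasibility(spec)
  dent <- build_core_mesh(spec)
  prm <- attr(dent, "param")
  truth <- apposition_field(spec, prm$z_mm, prm$theta)
  nrm <- vertex_normals(dent)
  cem_v <- dent$vertices + nrm * (truth / 1000)
  cem <- root_mesh(cem_v, dent$faces, apex_point = cem_v[1, ],
                   cej_height = dent$cej_height, axis = dent$axis,
                   buccal_reference = dent$buccal_reference)
  # Guard against self-intersecting displacement (primitive too large for
  # the local radius): no triangle may flip its orientation.
  fo <- face_normals(dent); fn <- face_normals(cem)
  if (any(rowSums(fo * fn) <= 0))
    stop("displacement field self-intersects: primitive too large for the root radius")
  list(dentine = dent, cementum = cem, truth_um = truth, param = prm,
       spec = spec)
}

# A primitive must fit the local root geometry: its footprint cannot
# wrap most of the circumference, and it must be resolvable by the mesh.
check_primitive_feasibility <- function(spec) {
  L <- spec$root_length_mm
  for (prim in spec$shape_primitives) {
    z0 <- (prim$third - 0.5) * L / 3
    r0 <- spec$base_radius_mm * (spec$taper + (1 - spec$taper) * z0 / L)
    edge <- max(L / spec$n_axial, 2 * pi * r0 / spec$n_theta)
    foot <- switch(prim$kind,
                   RID = max(prim$length_mm, prim$width_mm),
                   prim$diameter_mm)
    small <- switch(prim$kind, RID = prim$width_mm, prim$diameter_mm)
    if (foot > 0.8 * 2 * pi * r0)
      stop("displacement field self-intersects: primitive too large for the root radius")
    if (small < 1.2 * edge)
      stop("primitive narrower than the local mesh edge length; ",
           "increase n_axial/n_theta")
  }
  invisible(spec)
}

face_normals <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  a <- v[f[, 1], , drop = FALSE]
  b <- v[f[, 2], , drop = FALSE] - a
  cc <- v[f[, 3], , drop = FALSE] - a
  cbind(b[, 2] * cc[, 3] - b[, 3] * cc[, 2],
        b[, 3] * cc[, 1] - b[, 1] * cc[, 3],
        b[, 1] * cc[, 2] - b[, 2] * cc[, 1])
}

# Tapered tube with rounded apex: rings of a superellipse cross-section
# along +z from the apex pole (z = 0) to the CEJ ring (z = L), capped flat
# at the cervical end. Vertex 1 is the apex pole.
build_core_mesh <- function(spec) {
  L <- spec$root_length_mm
  n_ax <- spec$n_axial; n_th <- spec$n_theta
  p <- spec$superellipse
  a_cap <- spec$base_radius_mm * spec$taper  # apex rounding length
  z <- L * seq_len(n_ax) / n_ax
  r_lin <- spec$base_radius_mm * (spec$taper + (1 - spec$taper) * z / L)
  cap <- z < a_cap
  rho <- r_lin
  rho[cap] <- r_lin[cap] * sqrt(pmax(0, 1 - ((a_cap - z[cap]) / a_cap)^2))
  theta <- 2 * pi * (seq_len(n_th) - 1) / n_th
  s_th <- (abs(cos(theta))^p + abs(sin(theta))^p)^(-1 / p)

  nv <- 1L + n_ax * n_th + 1L
  verts <- matrix(0, nv, 3)
  zz <- numeric(nv); tt <- numeric(nv)
  verts[1, ] <- c(0, 0, 0)   # apex pole
  idx <- function(j, k) 1L + (j - 1L) * n_th + ((k - 1L) %% n_th) + 1L
  for (j in seq_len(n_ax)) {
    r <- rho[j] * s_th
    rows <- idx(j, seq_len(n_th))
    verts[rows, ] <- cbind(r * cos(theta), r * sin(theta), z[j])
    zz[rows] <- z[j]; tt[rows] <- theta
  }
  top <- nv
  verts[top, ] <- c(0, 0, L)
  zz[top] <- L; tt[top] <- 0

  faces <- matrix(0L, n_th + 2L * n_th * (n_ax - 1L) + n_th, 3)
  fi <- 0L
  for (k in seq_len(n_th)) {          # apex fan (outward = downward)
    fi <- fi + 1L
    faces[fi, ] <- c(1L, idx(1, k + 1), idx(1, k))
  }
  for (j in seq_len(n_ax - 1L)) {
    for (k in seq_len(n_th)) {
      fi <- fi + 1L
      faces[fi, ] <- c(idx(j, k), idx(j, k + 1), idx(j + 1, k + 1))
      fi <- fi + 1L
      faces[fi, ] <- c(idx(j, k), idx(j + 1, k + 1), idx(j + 1, k))
    }
  }
  for (k in seq_len(n_th)) {          # cervical cap (outward = upward)
    fi <- fi + 1L
    faces[fi, ] <- c(top, idx(n_ax, k), idx(n_ax, k + 1))
  }
  mesh <- root_mesh(verts, faces, apex_point = c(0, 0, 0), cej_height = L,
                    axis = c(0, 0, 1), buccal_reference = c(1, 0, 0))
  attr(mesh, "param") <- data.frame(z_mm = zz, theta = tt)
  mesh
}

# The analytic apposition field (um) at surface parameters (z, theta).
apposition_field <- function(spec, z, theta) {
  L <- spec$root_length_mm
  t_um <- rep(spec$base_cementum_um, length(z))

  g <- spec$angular_gradient
  if (!is.null(g) && g$amplitude_um > 0) {
    z_c <- (g$axial_center - 0.5) * L / 3
    ang <- (1 + cos(theta - side_angle(g$direction))) / 2
    ax <- exp(-0.5 * ((z - z_c) / (L / 3))^2)
    t_um <- t_um + g$amplitude_um * ang * ax
  }

  for (prim in spec$shape_primitives)
    t_um <- t_um + primitive_field(prim, spec, z, theta)

  tex <- spec$texture
  if (!is.null(tex) && tex$amplitude_um > 0) {
    t_um <- t_um + texture_field(spec, z, theta)
  }
  t_um
}

# Local surface coordinates around a centre (z0, th0): u axial (mm),
# v circumferential arc (mm) at the local radius.
local_uv <- function(spec, z, theta, z0, th0) {
  L <- spec$root_length_mm
  r0 <- spec$base_radius_mm * (spec$taper + (1 - spec$taper) * z0 / L)
  list(u = z - z0, v = ang_diff(theta, th0) * r0)
}

primitive_field <- function(prim, spec, z, theta) {
  L <- spec$root_length_mm
  z0 <- (prim$third - 0.5) * L / 3
  th0 <- side_angle(prim$side)
  H <- prim$height_mm * 1000
  out <- numeric(length(z))
  uv <- local_uv(spec, z, theta, z0, th0)

  add_round_bump <- function(out, du, dv, D, h_um) {
    d <- sqrt((uv$u - du)^2 + (uv$v - dv)^2)
    out + h_um * bump_profile(d / (D / 2))
  }

  if (prim$kind == "NOD") {
    out <- add_round_bump(out, 0, 0, prim$diameter_mm, H)
  } else if (prim$kind == "Nds") {
    k <- max(prim$count, 2L)
    spacing <- 1.5 * prim$diameter_mm
    ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 8
    for (i in seq_len(k))
      out <- add_round_bump(out, spacing * cos(ang[i]),
                            spacing * sin(ang[i]), prim$diameter_mm, H)
  } else if (prim$kind == "OG") {
    half_ax <- prim$diameter_mm / 2
    half_ang <- (prim$angular_extent_deg / 2) * pi / 180
    wa <- bump_profile(uv$u / half_ax)
    wb <- bump_profile(ang_diff(theta, th0) / half_ang)
    out <- out + H * wa * wb
  } else if (prim$kind == "RID") {
    phi <- prim$obliquity_deg * pi / 180
    e1 <- c(cos(phi), sin(phi))    # along ridge (from axial direction)
    e2 <- c(-sin(phi), cos(phi))
    spacing <- 2 * prim$width_mm
    offs <- (seq_len(prim$count) - (prim$count + 1) / 2) * spacing
    for (o in offs) {
      s <- uv$u * e1[1] + uv$v * e1[2]
      q <- uv$u * e2[1] + uv$v * e2[2] - o
      out <- out + H * bump_profile(s / (prim$length_mm / 2)) *
        bump_profile(q / (prim$width_mm / 2))
    }
  } else if (prim$kind == "LSP") {
    out <- add_round_bump(out, 0, 0, prim$diameter_mm, H)
    k <- max(prim$count, 3L)
    ang <- 2 * pi * (seq_len(k) - 1) / k + pi / 5
    rad <- 0.35 * prim$diameter_mm
    for (i in seq_len(k))
      out <- add_round_bump(out, rad * cos(ang[i]), rad * sin(ang[i]),
                            prim$diameter_mm / 3, 0.6 * H)
  }
  out
}

# Smooth seeded random modulation: a coarse periodic-in-theta node grid,
# bilinearly interpolated, rescaled to the requested peak-to-valley
# amplitude.
texture_field <- function(spec, z, theta) {
  tex <- spec$texture
  L <- spec$root_length_mm
  nz <- 9L; nt <- 8L
  nodes <- with_seed(spec$seed + 7L,
                     matrix(rnorm(nz * nt), nz, nt))
  zi <- pmin(pmax(z / L * (nz - 1) + 1, 1), nz)
  ti <- theta / (2 * pi) * nt + 1
  j0 <- pmin(floor(zi), nz - 1); fz <- zi - j0
  k0 <- floor(ti); fk <- ti - k0
  k0w <- ((k0 - 1) %% nt) + 1
  k1w <- (k0 %% nt) + 1
  val <- nodes[cbind(j0, k0w)] * (1 - fz) * (1 - fk) +
    nodes[cbind(j0 + 1, k0w)] * fz * (1 - fk) +
    nodes[cbind(j0, k1w)] * (1 - fz) * fk +
    nodes[cbind(j0 + 1, k1w)] * fz * fk
  rng <- max(val) - min(val)
  if (rng < 1e-12) return(numeric(length(z)))
  (val - mean(val)) / rng * tex$amplitude_um
}
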