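#' Per-vertex cementum thickness map
#'
#' Computes the cementum thickness at every vertex of the cementum
#' envelope as the unsigned Euclidean distance to the nearest point of the
#' dentine surface (true point-to-triangle distance, not vertex-to-vertex).
#' For nested surfaces this matches a directional pointwise
#' surface-to-surface distance. Vertices landing at (numerically) zero
#' distance indicate intersecting input surfaces; they are flagged and a
#' warning is raised rather than an error.
#'
#' @param cementum,dentine `root_mesh` objects in millimetres.
#' @return A `thickness_field`: list with `thickness_um` (one value per
#'   cementum vertex), `max_thi_um`, `flagged` (indices of zero-thickness
#'   vertices) and the cementum mesh.
#' @examples
#' pair <- make_root_pair(synthetic_spec(base_cementum_um = 500))
#' fld <- compute_thickness(pair$cementum, pair$dentine)
#' fld$max_thi_um
#' @export
compute_thickness <- function(cementum, dentine) {
  stopifnot(inherits(cementum, "root_mesh"), inherits(dentine, "root_mesh"))
  if (nrow(cementum$vertices) == 0 || nrow(dentine$faces) == 0)
    stop("empty mesh")
  d_mm <- cpp_point_mesh_distance(cementum$vertices, dentine$vertices,
                                  dentine$faces - 1L)
  th <- d_mm * 1000
  flagged <- which(th < 1e-6)
  if (length(flagged))
    warning(sprintf(
      "%d cementum vertices touch or cross the dentine surface (zero thickness)",
      length(flagged)))
  structure(list(thickness_um = th, max_thi_um = max(th),
                 flagged = flagged, mesh = cementum),
            class = "thickness_field")
}

#' @export
print.thickness_field <- function(x, ...) {
  cat(sprintf(
    "thickness_field: %d vertices, range %.0f-%.0f um (MAX THI %.0f um)\n",
    length(x$thickness_um), min(x$thickness_um), max(x$thickness_um),
    x$max_thi_um))
  if (length(x$flagged))
    cat(sprintf("  %d vertices flagged at zero thickness\n",
                length(x$flagged)))
  invisible(x)
}

#' Partition a root surface into thirds and anatomical sides
#'
#' Assigns every vertex a root third (1 apical, 2 middle, 3 cervical):
#' three equal axial-length intervals between the apex and the
#' cemento-enamel junction; for crownless roots without a preserved CEJ
#' the preserved axial extent is used. Sides are the four 90-degree
#' angular quadrants about the root axis centred on the anatomical
#' directions: buccal `<` on the `buccal_reference` vector, mesial `m` at
#' +90 degrees, lingual `>` opposite, distal `d` at -90 degrees.
#'
#' @param mesh A `root_mesh` with `apex_point` and axis set.
#' @return A data frame with columns `third` (integer) and `side`
#'   (factor `m`, `d`, `<`, `>`), one row per vertex.
#' @export
partition_root <- function(mesh) {
  if (is.null(mesh$apex_point)) stop("apex landmark missing")
  v <- mesh$vertices
  ax <- mesh$axis
  s <- as.numeric(v %*% ax)
  s_apex <- sum(mesh$apex_point * ax)
  s_cej <- if (!is.null(mesh$cej_height) && !is.na(mesh$cej_height))
    mesh$cej_height else max(s)
  if (s_cej <= s_apex) stop("degenerate landmarks: CEJ at or below apex")
  rel <- (s - s_apex) / (s_cej - s_apex)
  third <- pmin(pmax(1L + as.integer(floor(rel * 3)), 1L), 3L)

  b <- mesh$buccal_reference
  m <- cross3(ax, b)
  rad <- v - outer(s, ax)   # radial components (origin irrelevant on axis)
  phi <- atan2(rad %*% m, rad %*% b)
  sector <- (floor((phi / pi * 180 + 45) / 90)) %% 4
  side <- factor(c("<", "m", ">", "d")[sector + 1],
                 levels = c("m", "d", "<", ">"))
  data.frame(third = third, side = side)
}

#' Summarize a thickness field: MAX THI, LOC MAX, LOC MIN, PREF
#'
#' Derives the standard thickness-map summaries: the maximum cementum
#' thickness (MAX THI, um); its localization LOC MAX as root-third x side
#' codes (the cell holding the maximal vertex plus any cell whose mean
#' thickness reaches `report_frac` of that cell's mean); the side of
#' thinnest apposition LOC MIN (reported only when its mean is below the
#' thickest side's mean by the factor `pref_ratio`, otherwise `"No"`); and
#' the preferential-apposition flag PREF, true when the apposition is not
#' homogeneous around the root axis, operationalized as the ratio of the
#' thickest to the thinnest side mean reaching `pref_ratio`.
#'
#' @param field A `thickness_field`.
#' @param partition Output of [partition_root()] on the same mesh.
#' @param pref_ratio Side-mean ratio from which the apposition counts as
#'   preferential (default 1.5).
#' @param report_frac Fraction of the maximal cell mean from which an
#'   additional cell is reported in LOC MAX (default 0.9).
#' @return A `thickness_summary` list: `max_thi_um`, `loc_max` (character
#'   codes such as `"2d"`), `min_side`, `pref`, `quadrant_means` (3 x 4
#'   matrix, thirds x sides) and `side_means`.
#' @export
summarize_thickness <- function(field, partition, pref_ratio = 1.5,
                                report_frac = 0.9) {
  th <- field$thickness_um
  stopifnot(length(th) == nrow(partition), pref_ratio >= 1)
  sides <- levels(partition$side)
  qm <- matrix(NA_real_, 3, 4, dimnames = list(third = 1:3, side = sides))
  for (t3 in 1:3) for (sd in sides) {
    i <- partition$third == t3 & partition$side == sd
    if (any(i)) qm[t3, sd] <- mean(th[i])
  }
  side_means <- vapply(sides, function(sd)
    mean(th[partition$side == sd]), 0)

  imax <- which.max(th)
  max_cell <- c(partition$third[imax], as.character(partition$side[imax]))
  max_cell_mean <- qm[max_cell[1], max_cell[2]]
  loc <- paste0(max_cell[1], max_cell[2])
  for (t3 in 1:3) for (sd in sides) {
    code <- paste0(t3, sd)
    if (!(code %in% loc) && !is.na(qm[t3, sd]) &&
        qm[t3, sd] >= report_frac * max_cell_mean)
      loc <- c(loc, code)
  }

  ratio <- max(side_means) / min(side_means)
  pref <- is.finite(ratio) && ratio >= pref_ratio
  min_side <- if (pref) names(which.min(side_means)) else "No"

  structure(list(max_thi_um = field$max_thi_um, loc_max = loc,
                 min_side = min_side, pref = pref,
                 quadrant_means = qm, side_means = side_means,
                 pref_ratio = pref_ratio),
            class = "thickness_summary")
}

#' @export
print.thickness_summary <- function(x, ...) {
  cat(sprintf("MAX THI %.0f um | LOC MAX %s | LOC MIN %s | PREF %s\n",
              x$max_thi_um, paste(x$loc_max, collapse = " "),
              x$min_side, if (x$pref) "Yes" else "No"))
  cat("mean thickness (um) by third x side:\n")
  print(round(x$quadrant_means))
  invisible(x)
}
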