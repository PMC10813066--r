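#' Hypercementosis visual score
#'
#' A composite score of hypercementosis with three parts, serialized as
#' `"type.stage.form"` (e.g. `"3.3.m"`):
#' \itemize{
#'   \item type: 1 diffuse, 2 focal, 3 mixed (diffuse + focal component);
#'   \item stage: axial extent of the apposition — 1 apical third only,
#'     2 apical + middle, 3 all three root thirds, 4 whole preserved root
#'     on teeth whose cemento-enamel junction is damaged or lost;
#'   \item form: `m` moderate (overall root morphology respected) or `M`
#'     marked (morphology drastically modified).
#' }
#'
#' @param type Integer 1, 2 or 3.
#' @param stage Integer 1 to 4.
#' @param form `"m"` or `"M"`.
#' @return An object of class `hc_score`.
#' @examples
#' s <- hc_score(3, 3, "m")
#' format(s)              # "3.3.m"
#' parse_hc("1.4.M")
#' @export
hc_score <- function(type, stage, form) {
  type <- as.integer(type); stage <- as.integer(stage)
  if (!type %in% 1:3) stop("hypercementosis type must be 1, 2 or 3")
  if (!stage %in% 1:4) stop("hypercementosis stage must be 1..4")
  if (!form %in% c("m", "M")) stop("hypercementosis form must be 'm' or 'M'")
  structure(list(type = type, stage = stage, form = form),
            class = "hc_score")
}

#' @rdname hc_score
#' @param x A serialized score string such as `"3.3.m"`.
#' @export
parse_hc <- function(x) {
  if (is.na(x)) stop("hypercementosis score is missing")
  parts <- strsplit(x, ".", fixed = TRUE)[[1]]
  if (length(parts) != 3)
    stop("malformed hypercementosis score: ", x)
  hc_score(parts[1], parts[2], parts[3])
}

#' @export
format.hc_score <- function(x, ...) paste(x$type, x$stage, x$form, sep = ".")

#' @export
print.hc_score <- function(x, ...) {
  types <- c("diffuse", "focal", "mixed (diffuse + focal)")
  stages <- c("apical third", "apical + middle thirds", "all three thirds",
              "whole preserved root (damaged cemento-enamel junction)")
  cat(sprintf("Hypercementosis %s: type %d (%s), stage %d (%s), %s form\n",
              format(x), x$type, types[x$type], x$stage, stages[x$stage],
              if (x$form == "M") "marked" else "moderate"))
  invisible(x)
}

#' Cross-field validation of a tooth record
#'
#' Checks the internal consistency rules of the visual-scoring systems on
#' one record (a single row of a `tooth_records` table): Molnar wear scores
#' (no wear implies natural direction and form; unscorable crown implies
#' all three zero), caries site/stage pairing, the impaction pattern
#' (impacted teeth are unworn, with antagonist code 0), the infected-tooth
#' pattern (pulp exposure must be recorded), and the rule that
#' hypercementosis stage 4 is reserved for roots whose cemento-enamel
#' junction is damaged.
#'
#' @param record A one-row data frame in the `tooth_records` schema.
#' @return A data frame of violations (columns `tooth_id`, `field`,
#'   `rule`); zero rows when the record is internally consistent.
#' @examples
#' teeth <- load_tooth_table()
#' validate_record(teeth[teeth$tooth_id == "Sp755_13", ])  # clean
#' @export
validate_record <- function(record) {
  stopifnot(is.data.frame(record), nrow(record) == 1L)
  v <- list()
  bad <- function(field, rule)
    v[[length(v) + 1L]] <<- data.frame(tooth_id = record$tooth_id,
                                       field = field, rule = rule)

  deg <- record$wear_deg; dir <- record$wear_dir; for. <- record$wear_for
  if (!is.na(deg)) {
    if (deg == 1 && (dir != 1 || for. != 1))
      bad("wear_dir", "no wear (degree 1) implies natural direction and form")
    if (deg == 0 && (dir != 0 || for. != 0))
      bad("wear_dir", "unscorable crown (degree 0) implies direction/form 0")
  }
  if (xor(is.na(record$caries_si), is.na(record$caries_sta)))
    bad("caries_si", "caries site and stage must be recorded together")
  if (isTRUE(record$impacted)) {
    if (!is.na(deg) && deg > 1)
      bad("wear_deg", "impacted teeth never erupted and cannot be worn")
    if (!is.na(record$ant) && record$ant != "0")
      bad("ant", "antagonist is not scorable (code 0) for impacted teeth")
    if (!is.na(record$caries_si))
      bad("caries_si", "impacted teeth cannot develop caries")
  }
  if ("etiology" %in% names(record) && !is.na(record$etiology) &&
      record$etiology == "INF" && record$pulp_exp == "none")
    bad("pulp_exp", "infected pattern requires recorded pulp exposure")
  if (!is.na(record$hc_stage) && record$hc_stage == 4 &&
      !is.na(deg) && deg %in% 1:6)
    bad("hc_stage",
        "stage 4 requires a damaged cemento-enamel junction (crown lost or worn to the root)")
  if (length(v)) do.call(rbind, v)
  else data.frame(tooth_id = character(), field = character(),
                  rule = character())
}

#' Derive a hypercementosis score from a thickness map
#'
#' Reconstructs the composite visual score from the quantitative thickness
#' field. The stage is the contiguous run of root thirds, starting at the
#' apex, whose mean thickness exceeds `baseline_um` (1 apical only, 2
#' apical + middle, 3 all three); when the cemento-enamel junction is not
#' preserved and the whole preserved root exceeds the baseline, the stage
#' is 4. The type is 1 (diffuse) when no atypical shape component is
#' detected and 3 (mixed) when a focal component accompanies the diffuse
#' apposition. The form is `M` (marked) when the maximum thickness reaches
#' `marked_um`, else `m`. The published scoring system is qualitative;
#' these two thresholds parameterize it quantitatively and are
#' configurable.
#'
#' @param field A `thickness_field` (see [compute_thickness()]).
#' @param partition Per-vertex root partition (see [partition_root()]).
#' @param cej_present Is the cemento-enamel junction preserved?
#' @param baseline_um Thickness above which a third counts as involved
#'   (default 500).
#' @param marked_um Maximum thickness from which the form is marked
#'   (default 1500).
#' @param shape Optional `apposition_shape` from [classify_shape()]; when
#'   missing the type is reported as diffuse.
#' @return An `hc_score`.
#' @export
score_hypercementosis <- function(field, partition, cej_present = TRUE,
                                  baseline_um = 500, marked_um = 1500,
                                  shape = NULL) {
  th <- field$thickness_um
  stopifnot(length(th) == nrow(partition))
  third_means <- vapply(1:3, function(k) {
    i <- partition$third == k
    if (any(i)) mean(th[i]) else NA_real_
  }, 0)
  above <- !is.na(third_means) & third_means > baseline_um
  run <- 0L
  for (k in 1:3) {
    if (isTRUE(above[k])) run <- run + 1L else break
  }
  stage <- max(run, 1L)
  if (!cej_present && all(above[!is.na(third_means)])) stage <- 4L
  focal <- !is.null(shape) && !identical(shape$kind, "none")
  type <- if (focal) 3L else 1L
  form <- if (max(th) >= marked_um) "M" else "m"
  hc_score(type, stage, form)
}
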