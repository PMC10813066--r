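#' Load the 35-tooth hypercementosis reference dataset
#'
#' Reads the packaged transcription of the published characterization of 35
#' single-rooted hypercementotic teeth from the medieval-to-modern cemetery
#' of Sains-en-Gohelle (23 individuals), or a user table in the same schema.
#' Each record carries the visual-examination scores (Molnar occlusal wear,
#' Si/Sta caries, pulp exposure, impaction, hypercementosis score), the bone
#' context (fenestration, calculus, neighbouring/antagonist tooth status),
#' the micro-CT thickness summaries (MAX THI, LOC MAX, LOC MIN, PREF LOC,
#' atypical shape note) and the confocal topography summaries (MAX VE,
#' surface-aspect score).
#'
#' Two teeth (Sp1010_44 and Sp1230_44) are flagged `excluded`: micro-CT
#' inspection revealed two coalescent roots concealed by cementum, so they
#' fall outside the single-rooted study sample. Analyses default to the 33
#' included teeth.
#'
#' Missing cells are explicit `NA`s, never zeroes, with two deliberate
#' recodings: unscorable occlusal wear on crownless roots becomes degree 0
#' ("not applicable, crown not preserved") and an unscorable antagonist
#' becomes `ant = 3`, so that the published decision tree, which groups
#' `ant` levels \{0, 2, 3\} against 1, can route every included tooth.
#'
#' @param path Optional path to a comma-separated table in the fixture
#'   schema; defaults to the packaged dataset.
#' @param individuals_path Optional path to the individual-level table
#'   (specimen, sex, age class); defaults to the packaged table.
#' @return A `tooth_records` data frame with one row per tooth.
#' @examples
#' teeth <- load_tooth_table()
#' nrow(teeth)                      # 35
#' sum(!teeth$excluded)             # 33 in the analysis sample
#' table(teeth$etiology[!teeth$excluded])
#' @export
load_tooth_table <- function(path = NULL, individuals_path = NULL) {
  path <- path %||% system.file("extdata", "sains_table2.csv",
                                package = "cementmap", mustWork = TRUE)
  ind_path <- individuals_path %||%
    system.file("extdata", "sains_table1.csv",
                package = "cementmap", mustWork = TRUE)
  raw <- read.csv(path, stringsAsFactors = FALSE, na.strings = c(""),
                  colClasses = "character")
  ind <- read.csv(ind_path, stringsAsFactors = FALSE)

  need <- c("tooth_id", "group", "wear_deg", "wear_dir", "wear_for",
            "caries_si", "caries_sta", "pulp_exp", "impacted", "hc",
            "fen", "cal", "nt", "ant", "max_thi_um", "loc_max", "loc_min",
            "pref", "shape_note", "max_ve_um", "aspect", "excluded")
  miss <- setdiff(need, names(raw))
  if (length(miss))
    stop("tooth table is missing columns: ", paste(miss, collapse = ", "))

  n <- nrow(raw)
  id <- raw$tooth_id
  if (anyDuplicated(id)) stop_field(id[duplicated(id)][1], "tooth_id",
                                    "duplicated identifier")
  specimen_id <- sub("_[0-9]+$", "", id)
  fdi_code <- suppressWarnings(as.integer(sub("^.*_", "", id)))
  if (anyNA(fdi_code)) stop_field(id[is.na(fdi_code)][1], "tooth_id",
                                  "cannot parse FDI code")

  as_int <- function(col, lo, hi, na_to = NA_integer_) {
    v <- raw[[col]]
    out <- suppressWarnings(as.integer(v))
    printed_na <- !is.na(v) & v %in% c("NA", "-")
    out[printed_na] <- na_to
    bad <- which(!is.na(out) & (out < lo | out > hi))
    if (length(bad)) stop_field(id[bad[1]], col, paste0(
      "value ", out[bad[1]], " outside [", lo, ", ", hi, "]"))
    bad2 <- which(is.na(out) & !printed_na & !is.na(v))
    if (length(bad2)) stop_field(id[bad2[1]], col, "not an integer")
    out
  }

  etiology <- factor(raw$group, levels = c("HYPER", "HYPO", "IMP", "INF", "MIX"))
  if (anyNA(etiology)) stop_field(id[is.na(etiology)][1], "group",
                                  "unknown etiology code")
  impacted <- as_int("impacted", 0, 1) == 1L

  # Crownless roots: printed "NA" wear -> degree 0 (crown not preserved)
  wear_deg <- as_int("wear_deg", 0, 8, na_to = 0L)
  wear_dir <- as_int("wear_dir", 0, 8, na_to = 0L)
  wear_for <- as_int("wear_for", 0, 6, na_to = 0L)

  caries_si <- as_int("caries_si", 0, 3)
  caries_sta <- as_int("caries_sta", 0, 4)
  if (any(xor(is.na(caries_si), is.na(caries_sta))))
    stop_field(id[xor(is.na(caries_si), is.na(caries_sta))][1],
               "caries_si", "caries site/stage must be paired")

  pulp_exp <- raw$pulp_exp
  pulp_exp[pulp_exp %in% "0"] <- "none"
  pulp_exp <- factor(pulp_exp, levels = c("none", "W", "C", "M"))
  if (anyNA(pulp_exp)) stop_field(id[is.na(pulp_exp)][1], "pulp_exp",
                                  "must be one of 0, W, C, M")

  hc <- lapply(raw$hc, parse_hc)
  fen <- as_int("fen", 0, 1) == 1L
  cal <- as_int("cal", 0, 1) == 1L

  nt <- raw$nt
  nt[nt %in% c("-", "NA")] <- NA_character_
  bad_nt <- which(!is.na(nt) & !nt %in% c("0", "1m", "1d", "2"))
  if (length(bad_nt)) stop_field(id[bad_nt[1]], "nt", "unknown code")
  nt <- factor(nt, levels = c("0", "1m", "1d", "2"))

  # Antagonist: impacted "-" -> 0 (not relevant); printed "NA" -> 3
  ant <- raw$ant
  ant[!is.na(ant) & ant == "-" & impacted] <- "0"
  ant[!is.na(ant) & ant == "NA"] <- "3"
  bad_ant <- which(is.na(ant) | !ant %in% c("0", "1", "2", "3"))
  if (length(bad_ant)) stop_field(id[bad_ant[1]], "ant", "unknown code")
  ant <- factor(ant, levels = c("0", "1", "2", "3"))

  num <- function(col, positive = TRUE) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(!is.na(raw[[col]]) & is.na(v))
    if (length(bad)) stop_field(id[bad[1]], col, "not numeric")
    if (positive && any(!is.na(v) & v <= 0))
      stop_field(id[which(!is.na(v) & v <= 0)][1], col, "must be positive")
    v
  }
  max_thi_um <- num("max_thi_um")
  if (anyNA(max_thi_um)) stop_field(id[is.na(max_thi_um)][1], "max_thi_um",
                                    "required")
  max_ve_um <- num("max_ve_um")

  pref <- raw$pref
  bad_pref <- which(!pref %in% c("Yes", "No"))
  if (length(bad_pref)) stop_field(id[bad_pref[1]], "pref",
                                   "must be Yes or No")
  pref <- pref == "Yes"

  loc <- parse_loc_code(raw$loc_max)
  excluded <- as_int("excluded", 0, 1) == 1L

  out <- data.frame(
    tooth_id = id, specimen_id = specimen_id, fdi_code = fdi_code,
    etiology = etiology, impacted = impacted,
    wear_deg = wear_deg, wear_dir = wear_dir, wear_for = wear_for,
    caries_si = caries_si, caries_sta = caries_sta, pulp_exp = pulp_exp,
    hc_type = vapply(hc, `[[`, 0L, "type"),
    hc_stage = vapply(hc, `[[`, 0L, "stage"),
    hc_form = vapply(hc, `[[`, "", "form"),
    fen = fen, cal = cal, nt = nt, ant = ant,
    max_thi_um = max_thi_um,
    loc_max = raw$loc_max, loc_min = raw$loc_min, pref = pref,
    shape_note = raw$shape_note,
    max_ve_um = max_ve_um, aspect = raw$aspect,
    ba_printed = raw$ba_printed,
    excluded = excluded,
    stringsAsFactors = FALSE
  )
  out$loc_max_thirds <- I(loc$thirds)
  out$loc_max_sides <- I(loc$sides)
  out$loc_max_parsed <- loc$ok

  m <- match(paste(out$specimen_id, out$fdi_code),
             paste(ind$specimen_id, ind$fdi_code))
  out$ba_code <- ind$ba_code[m]
  out$sex <- ind$sex[m]
  out$age_class <- ind$age_class[m]
  tt <- c("1" = "I1", "2" = "I2", "3" = "C", "4" = "P3", "5" = "P4",
          "6" = "M1", "7" = "M2", "8" = "M3")
  out$tooth_type <- unname(tt[as.character(out$fdi_code %% 10)])

  class(out) <- c("tooth_records", "data.frame")
  out
}

# Parse the composite thickness-localization codes of the reference table:
# a code is a blank-separated list of tokens, each a run of root thirds
# (1 apical, 2 middle, 3 cervical; possibly omitted when the cemento-enamel
# junction was not visible) followed by side letters (m mesial, d distal,
# < buccal, > lingual), e.g. "2d", "1>", "1>d +2m", "d>", "1".
parse_loc_code <- function(codes) {
  one <- function(code) {
    if (is.na(code) || !nzchar(code))
      return(list(thirds = integer(), sides = character(), ok = FALSE))
    toks <- strsplit(gsub("\\+", " ", code), "[[:space:]]+")[[1]]
    toks <- toks[nzchar(toks)]
    thirds <- integer(); sides <- character(); ok <- TRUE
    for (tk in toks) {
      chars <- strsplit(tk, "")[[1]]
      if (!all(chars %in% c("1", "2", "3", "m", "d", "<", ">"))) {
        ok <- FALSE
        next
      }
      thirds <- c(thirds, as.integer(chars[chars %in% c("1", "2", "3")]))
      sides <- c(sides, chars[chars %in% c("m", "d", "<", ">")])
    }
    list(thirds = sort(unique(thirds)), sides = unique(sides), ok = ok)
  }
  parsed <- lapply(codes, one)
  list(thirds = lapply(parsed, `[[`, "thirds"),
       sides = lapply(parsed, `[[`, "sides"),
       ok = vapply(parsed, `[[`, TRUE, "ok"))
}

#' @export
print.tooth_records <- function(x, ...) {
  inc <- sum(!x$excluded)
  cat(sprintf(
    "Tooth records: %d teeth from %d individuals (%d in analysis sample)\n",
    nrow(x), length(unique(x$specimen_id)), inc))
  print(table(etiology = x$etiology, excluded = x$excluded))
  invisible(x)
}

#' Per-etiology summary statistics of a numeric measurement
#'
#' Summarizes a numeric per-tooth measurement (for instance the maximum
#' cementum thickness `max_thi_um` or the maximum vertical elevation
#' `max_ve_um`) by etiological group: sample size, mean, standard deviation
#' (n - 1 denominator), minimum and maximum. Values are reported rounded
#' half-away-from-zero to integer micrometres, the printed precision used
#' throughout the reference dataset; raw (unrounded) means are returned in
#' `mean_raw`. Teeth flagged `excluded` are dropped, as are teeth with a
#' missing value of `field`; additional exclusions can name tooth ids or
#' supply a predicate over record rows.
#'
#' @param records A `tooth_records` data frame (see [load_tooth_table()]).
#' @param field Name of a numeric column to summarize.
#' @param exclude Optional extra exclusions: a character vector of
#'   `tooth_id`s or a function mapping the records data frame to a logical
#'   vector (`TRUE` = drop).
#' @param use_excluded If `TRUE`, keep the teeth flagged `excluded`.
#' @return A data frame with one row per non-empty group: `group`, `n`,
#'   `mean`, `sd`, `min`, `max`, `mean_raw`, `sd_raw`. `sd` is `NA` for
#'   groups of size 1.
#' @examples
#' teeth <- load_tooth_table()
#' group_summary(teeth, "max_thi_um")
#' # vertical elevation of the hypofunctional group, excluding the
#' # measurement taken on a cementum fracture:
#' group_summary(teeth, "max_ve_um", exclude = "Sp17_15")
#' @export
group_summary <- function(records, field, exclude = NULL,
                          use_excluded = FALSE) {
  stopifnot(is.data.frame(records), field %in% names(records))
  v <- records[[field]]
  if (!is.numeric(v)) stop("`field` must be numeric")
  keep <- !is.na(v)
  if (!use_excluded && "excluded" %in% names(records))
    keep <- keep & !records$excluded
  if (is.character(exclude)) keep <- keep & !records$tooth_id %in% exclude
  else if (is.function(exclude)) keep <- keep & !isTRUE_vec(exclude(records))
  else if (!is.null(exclude)) stop("`exclude` must be ids or a predicate")

  g <- droplevels(factor(records$etiology[keep]))
  v <- v[keep]
  if (!length(v)) stop("no records left after exclusions")
  res <- lapply(levels(g), function(lev) {
    x <- v[g == lev]
    data.frame(group = lev, n = length(x),
               mean = round_half_up(mean(x)),
               sd = if (length(x) > 1) round_half_up(sd(x)) else NA_real_,
               min = round_half_up(min(x)), max = round_half_up(max(x)),
               mean_raw = mean(x),
               sd_raw = if (length(x) > 1) sd(x) else NA_real_)
  })
  do.call(rbind, res)
}

isTRUE_vec <- function(x) {
  if (!is.logical(x)) stop("exclusion predicate must return a logical vector")
  x & !is.na(x)
}
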