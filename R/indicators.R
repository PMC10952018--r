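#' Total metabolic tumor volume, total tumor surface and their ratio
#'
#' `compute_tmtv()` and `compute_tts()` sum the per-lesion mesh volumes and
#' surfaces; `compute_tvsr()` is the tumor volume-surface ratio TMTV/TTS in
#' mm — a compactness measure of how aggregated the disease is (a single
#' sphere of radius r has TVSR = r/3; disseminated disease of equal volume
#' has more surface and therefore a lower TVSR).
#'
#' @param lesions tibble of lesion metrics with columns `volume_mm3` and
#'   `surface_mm2` (as returned by [measure_lesions()]).
#' @return A single number (mm^3, mm^2 or mm respectively).
#' @examples
#' compute_tvsr(32730, 6597) # 4.961 mm
#' @export
compute_tmtv <- function(lesions) {
  if (nrow(lesions) == 0) {
    warn("Empty lesion list: TMTV = 0 (no measurable disease).")
    return(0)
  }
  stopifnot(all(lesions$volume_mm3 > 0))
  sum(lesions$volume_mm3)
}

#' @rdname compute_tmtv
#' @export
compute_tts <- function(lesions) {
  if (nrow(lesions) == 0) {
    warn("Empty lesion list: TTS = 0 (no measurable disease).")
    return(0)
  }
  stopifnot(all(lesions$surface_mm2 > 0))
  sum(lesions$surface_mm2)
}

#' @rdname compute_tmtv
#' @param tmtv total metabolic tumor volume, mm^3.
#' @param tts total tumor surface, mm^2.
#' @export
compute_tvsr <- function(tmtv, tts) {
  if (any(tts <= 0)) abort("TVSR undefined: TTS must be > 0.")
  tmtv / tts
}

#' Bulky disease flag
#'
#' `TRUE` when any lesion's maximum diameter strictly exceeds
#' `threshold_mm` (default 50 mm, i.e. the conventional > 5.0 cm bulky
#' criterion).
#'
#' @param lesions lesion metrics tibble with column `max_diameter_mm`.
#' @param threshold_mm diameter threshold in mm (strict `>`).
#' @return Logical scalar.
#' @export
bulky_flag <- function(lesions, threshold_mm = 50) {
  if (nrow(lesions) == 0) return(FALSE)
  any(lesions$max_diameter_mm > threshold_mm)
}

#' Extra-stage flag (dissemination indicator)
#'
#' `TRUE` when lesions occur both above and below the diaphragm *and* more
#' than one distinct extranodal site is involved. Sites are counted as
#' distinct `organ_id` values among extranodal lesions — one organ bearing
#' several lesions is a single site.
#'
#' @param lesions lesion metrics tibble with `side` (`"above_diaphragm"` /
#'   `"below_diaphragm"`), `compartment` (`"nodal"` / `"extranodal"`) and
#'   `organ_id` columns.
#' @return Logical scalar.
#' @export
extra_stage_flag <- function(lesions) {
  if (nrow(lesions) == 0) return(FALSE)
  miss <- which(is.na(lesions$side) | is.na(lesions$compartment) |
                  (lesions$compartment == "extranodal" & is.na(lesions$organ_id)))
  if (length(miss) > 0) {
    abort(sprintf("Lesion(s) %s missing site annotation.",
                  paste(miss, collapse = ", ")))
  }
  bad <- !lesions$side %in% c("above_diaphragm", "below_diaphragm") |
    !lesions$compartment %in% c("nodal", "extranodal")
  if (any(bad)) {
    abort(sprintf("Lesion(s) %s carry unknown side/compartment tokens.",
                  paste(which(bad), collapse = ", ")))
  }
  both_sides <- all(c("above_diaphragm", "below_diaphragm") %in% lesions$side)
  n_extranodal <- dplyr::n_distinct(
    lesions$organ_id[lesions$compartment == "extranodal"]
  )
  both_sides && n_extranodal > 1
}

#' Conventional dissemination flags: stage III/IV and > 1 extranodal site
#'
#' Ann Arbor stage is a clinical annotation supplied as input, never derived
#' from images here.
#'
#' @inheritParams extra_stage_flag
#' @param stage Ann Arbor stage token: `"I"`, `"II"`, `"III"` or `"IV"`.
#' @return A list with logicals `stage_3_4` and `extranodal_gt1`.
#' @export
legacy_flags <- function(lesions, stage) {
  if (!stage %in% c("I", "II", "III", "IV")) {
    abort(sprintf("Unknown Ann Arbor stage token '%s'.", stage))
  }
  n_extranodal <- if (nrow(lesions) == 0) 0L else dplyr::n_distinct(
    lesions$organ_id[lesions$compartment == "extranodal"]
  )
  list(
    stage_3_4 = stage %in% c("III", "IV"),
    extranodal_gt1 = n_extranodal > 1
  )
}

#' Three-level aggregation-dissemination stratification
#'
#' Combines the bulky and extra-stage flags into the ordinal grouping used
#' for synergy analysis: `neither` (no flag), `either` (exactly one),
#' `both` (both flags).
#'
#' @param bulky,extra_stage logical vectors (recycled to common length).
#' @return A factor with levels `neither`, `either`, `both`.
#' @export
synergy_group <- function(bulky, extra_stage) {
  k <- as.integer(bulky) + as.integer(extra_stage)
  factor(c("neither", "either", "both")[k + 1L],
         levels = c("neither", "either", "both"))
}

#' Patient-level indicator summary from annotated lesion metrics
#'
#' Computes TMTV, TTS, TVSR, the largest lesion diameter, and the bulky /
#' extra-stage / `>1` extranodal-site flags from one patient's lesion table.
#'
#' @param lesions annotated lesion metrics for one patient (columns
#'   `volume_mm3`, `surface_mm2`, `max_diameter_mm`, `side`, `compartment`,
#'   `organ_id`).
#' @param bulky_mm bulky-disease diameter threshold, mm.
#' @return A one-row tibble.
#' @export
patient_indicators <- function(lesions, bulky_mm = 50) {
  tmtv <- compute_tmtv(lesions)
  tts <- compute_tts(lesions)
  tibble::tibble(
    n_lesions = nrow(lesions),
    tmtv_mm3 = tmtv,
    tts_mm2 = tts,
    tvsr_mm = if (tts > 0) compute_tvsr(tmtv, tts) else NA_real_,
    max_diameter_mm = if (nrow(lesions)) max(lesions$max_diameter_mm) else NA_real_,
    bulky = bulky_flag(lesions, bulky_mm),
    extra_stage = extra_stage_flag(lesions),
    extranodal_gt1 = if (nrow(lesions) == 0) FALSE else dplyr::n_distinct(
      lesions$organ_id[lesions$compartment == "extranodal"]
    ) > 1
  )
}
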