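#' Cohort simulation specification
#'
#' Defines a simulated patient cohort with indicator-dependent
#' proportional-hazards survival. Defaults mirror the clinical setting the
#' package targets: a CAR T-treated DLBCL cohort of 42 patients with a
#' bulky-disease prevalence of 11/42 and a baseline hazard set so the median
#' progression-free survival of an unexposed patient is 336 days. The
#' prevalence of the dissemination indicator and the effect sizes are
#' calibration choices (the source cohort does not report them); see the
#' methods vignette.
#'
#' @param n_patients number of patients (>= 2).
#' @param p_bulky probability a patient carries a bulky (> 5 cm) lesion.
#' @param p_extra probability a patient is "extra stage" (lesions above and
#'   below the diaphragm and > 1 extranodal site).
#' @param baseline_hazard events/day for a patient with neither indicator.
#' @param log_hr_bulky,log_hr_extra log hazard ratios of the two indicators.
#' @param censor_window administrative censoring horizon in days; censoring
#'   times are Uniform(0, window). `Inf` disables censoring.
#' @param seed integer; sub-streams for flags/geometry, event times,
#'   censoring and response are derived as `seed`, `seed + 1`, ... so reruns
#'   of one stage do not perturb the others.
#' @return A `cohort_spec` list.
#' @export
cohort_spec <- function(n_patients = 42, p_bulky = 11 / 42, p_extra = 0.40,
                        baseline_hazard = log(2) / 336,
                        log_hr_bulky = log(2.5), log_hr_extra = log(2.5),
                        censor_window = 700, seed = 1L) {
  if (n_patients < 2) abort("`n_patients` must be >= 2.")
  if (p_bulky < 0 || p_bulky > 1 || p_extra < 0 || p_extra > 1) {
    abort("Probabilities must lie in [0, 1].")
  }
  if (baseline_hazard <= 0) abort("`baseline_hazard` must be > 0.")
  if (censor_window <= 0) abort("`censor_window` must be > 0.")
  structure(
    list(n_patients = as.integer(n_patients), p_bulky = p_bulky,
         p_extra = p_extra, baseline_hazard = baseline_hazard,
         log_hr_bulky = log_hr_bulky, log_hr_extra = log_hr_extra,
         censor_window = censor_window, seed = as.integer(seed)),
    class = "cohort_spec"
  )
}

extranodal_organs <- c("lung", "liver", "bone", "spleen", "kidney", "gut")

# lesion table for one patient, consistent with its bulky/extra flags
simulate_patient_lesions <- function(pid, bulky, extra) {
  n <- sample(1:5, 1)
  if (extra) n <- max(n, 2L)
  radius <- runif(n, 8, 22)
  if (bulky) radius[1] <- runif(1, 27.5, 45)

  side <- sample(c("above_diaphragm", "below_diaphragm"), n, replace = TRUE)
  compartment <- sample(c("nodal", "extranodal"), n, replace = TRUE)
  organ <- ifelse(compartment == "extranodal",
                  sample(extranodal_organs, n, replace = TRUE), "node")
  if (extra) {
    side[1:2] <- c("above_diaphragm", "below_diaphragm")
    compartment[1:2] <- "extranodal"
    organ[1:2] <- sample(extranodal_organs, 2)
  } else if (runif(1) < 0.5) {
    side[] <- side[1]  # confined to one side of the diaphragm
  } else {
    # both sides possible, but at most one distinct extranodal site
    ex <- compartment == "extranodal"
    if (any(ex)) organ[ex] <- sample(extranodal_organs, 1)
  }

  tibble::tibble(
    patient_id = pid, lesion_id = seq_len(n), radius_mm = radius,
    volume_mm3 = 4 / 3 * pi * radius^3, surface_mm2 = 4 * pi * radius^2,
    max_diameter_mm = 2 * radius,
    side = side, compartment = compartment, organ_id = organ
  )
}

#' Simulate a patient cohort with proportional-hazards survival
#'
#' Each patient receives Bernoulli aggregation (bulky) and dissemination
#' (extra stage) flags. With `lesions = TRUE` (the default) a consistent set
#' of analytic sphere lesions is generated per patient — a bulky patient gets
#' one lesion of diameter > 50 mm; an extra-stage patient gets lesions on
#' both sides of the diaphragm with at least two distinct extranodal organs —
#' and TMTV/TTS/TVSR are computed from the analytic sphere values through the
#' indicator functions. Complete response is simulated from a logistic model
#' decreasing in TVSR. Event times follow an exponential proportional-hazards
#' model, `T = -ln(U) / (h0 * exp(beta_b x_b + beta_e x_e))`, with
#' Uniform(0, `censor_window`) censoring; overall-survival times use the same
#' covariate effects on a lower baseline hazard.
#'
#' Ann Arbor stage is generated from lesion sides (both sides involved =>
#' stage III/IV) purely so that synthetic cohorts carry stage annotations
#' consistent with their geometry; it is not clinical staging.
#'
#' @param spec a [cohort_spec()].
#' @param lesions generate per-patient lesion tables and imaging indicators
#'   (`TRUE`), or only flags and survival for fast calibration runs
#'   (`FALSE`, leaving TMTV/TVSR/CR as `NA`).
#' @return A list with `patients` (one row per patient: indicators, CR and
#'   PFS/OS outcomes), `lesions` (one row per lesion, or `NULL`), and
#'   `truth` (true flags, uncensored event times, the log hazard ratios
#'   used).
#' @examples
#' coh <- make_cohort(cohort_spec(n_patients = 10, seed = 7))
#' coh$patients[, c("patient_id", "bulky", "extra_stage", "pfs_days", "pfs_event")]
#' @export
make_cohort <- function(spec, lesions = TRUE) {
  stopifnot(inherits(spec, "cohort_spec"))
  n <- spec$n_patients

  # flags and lesion geometry are drawn patient by patient so that growing
  # the cohort leaves earlier patients' data untouched
  geom <- withr::with_seed(spec$seed, {
    bulky <- logical(n)
    extra <- logical(n)
    les <- vector("list", n)
    for (i in seq_len(n)) {
      bulky[i] <- runif(1) < spec$p_bulky
      extra[i] <- runif(1) < spec$p_extra
      if (lesions) {
        les[[i]] <- simulate_patient_lesions(i, bulky[i], extra[i])
      }
    }
    list(bulky = bulky, extra = extra,
         lesions = if (lesions) dplyr::bind_rows(les) else NULL)
  })
  bulky <- geom$bulky
  extra <- geom$extra

  lp <- spec$log_hr_bulky * bulky + spec$log_hr_extra * extra
  t_pfs <- withr::with_seed(
    spec$seed + 1L, -log(runif(n)) / (spec$baseline_hazard * exp(lp))
  )
  t_os <- withr::with_seed(
    spec$seed + 4L, -log(runif(n)) / (0.6 * spec$baseline_hazard * exp(lp))
  )
  if (is.finite(spec$censor_window)) {
    cens <- withr::with_seed(
      spec$seed + 2L,
      matrix(runif(2 * n, 0, spec$censor_window), ncol = 2, byrow = TRUE)
    )
    pfs_days <- pmin(t_pfs, cens[, 1]); pfs_event <- t_pfs <= cens[, 1]
    os_days <- pmin(t_os, cens[, 2]); os_event <- t_os <= cens[, 2]
  } else {
    pfs_days <- t_pfs; pfs_event <- rep(TRUE, n)
    os_days <- t_os; os_event <- rep(TRUE, n)
  }

  if (lesions) {
    ind <- geom$lesions |>
      dplyr::group_by(.data$patient_id) |>
      dplyr::group_map(~ patient_indicators(.x)) |>
      dplyr::bind_rows() |>
      dplyr::mutate(patient_id = seq_len(n), .before = 1)
    both_sides <- ind$extra_stage | vapply(
      split(geom$lesions$side, geom$lesions$patient_id),
      function(s) length(unique(s)) > 1, logical(1)
    )
    u_stage <- withr::with_seed(spec$seed + 3L, runif(n))
    stage <- ifelse(both_sides,
                    ifelse(u_stage < 0.5, "III", "IV"),
                    ifelse(u_stage < 0.5, "I", "II"))
    cr <- withr::with_seed(
      spec$seed + 5L, runif(n) < stats::plogis(2.6 - 0.35 * ind$tvsr_mm)
    )
  } else {
    ind <- tibble::tibble(
      patient_id = seq_len(n), tmtv_mm3 = NA_real_, tts_mm2 = NA_real_,
      tvsr_mm = NA_real_, max_diameter_mm = NA_real_,
      bulky = bulky, extra_stage = extra, extranodal_gt1 = NA
    )
    stage <- rep(NA_character_, n)
    cr <- NA
  }

  patients <- ind |>
    dplyr::mutate(
      stage = stage,
      stage_3_4 = stage %in% c("III", "IV"),
      synergy_group = synergy_group(.data$bulky, .data$extra_stage),
      cr = cr,
      pfs_days = pfs_days, pfs_event = pfs_event,
      os_days = os_days, os_event = os_event
    )

  truth <- tibble::tibble(
    patient_id = seq_len(n), bulky_true = bulky, extra_stage_true = extra,
    pfs_time_true = t_pfs, os_time_true = t_os,
    log_hr_bulky = spec$log_hr_bulky, log_hr_extra = spec$log_hr_extra
  )
  list(patients = patients, lesions = geom$lesions, truth = truth)
}

#' Phantom specification matching one simulated patient's lesions
#'
#' Lays the patient's sphere lesions out in a non-overlapping grid, above or
#' below a diaphragm z-plane according to each lesion's side annotation, and
#' returns a [phantom_spec()] whose segmentation reproduces the patient's
#' indicator flags (bulky lesions keep their > 50 mm diameter; extra-stage
#' site structure is preserved).
#'
#' @param patient_lesions rows of the `lesions` table from [make_cohort()]
#'   for one patient.
#' @param spacing voxel spacing in mm (default 2 mm isotropic, keeping grids
#'   small for large lesions).
#' @param margin clearance between lesions and grid borders, mm.
#' @param peak_suv lesion SUV plateau.
#' @param seed noise-stream seed passed through to the spec.
#' @return A `phantom_spec`.
#' @export
cohort_phantom_spec <- function(patient_lesions, spacing = 2, margin = 10,
                                peak_suv = 5, seed = 1L) {
  r <- patient_lesions$radius_mm
  n <- length(r)
  rm_ <- max(r)
  x <- margin + r + c(0, cumsum(2 * r[-n] + margin))  # centres along x
  width <- x[n] + r[n] + margin
  plane <- 2 * rm_ + 1.5 * margin
  height <- plane + margin / 2 + 2 * rm_ + margin
  depth <- 2 * rm_ + 2 * margin
  shape <- pmax(ceiling(c(width, depth, height) / spacing) + 1L, 8L)
  lesions <- purrr::map(seq_len(n), function(i) {
    above <- patient_lesions$side[i] == "above_diaphragm"
    lesion_sphere(
      center = c(x[i], depth / 2,
                 if (above) plane + margin / 2 + r[i] else plane - margin / 2 - r[i]),
      radius = r[i], peak_suv = peak_suv,
      side = patient_lesions$side[i],
      compartment = patient_lesions$compartment[i],
      organ_id = patient_lesions$organ_id[i]
    )
  })
  phantom_spec(
    grid_shape = shape, spacing = rep(spacing, 3),
    lesions = lesions, diaphragm_z = plane, seed = seed
  )
}
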