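lesion_row <- function(volume = 1000, surface = 500, diameter = 20,
                       side = "above_diaphragm", compartment = "nodal",
                       organ = "node") {
  tibble::tibble(volume_mm3 = volume, surface_mm2 = surface,
                 max_diameter_mm = diameter, side = side,
                 compartment = compartment, organ_id = organ)
}

test_that("TMTV and TTS are sums over lesions; empty lists warn and return 0", {
  les <- dplyr::bind_rows(
    lesion_row(1000), lesion_row(2000), lesion_row(500)
  )
  expect_equal(compute_tmtv(les), 3500)
  expect_equal(compute_tmtv(lesion_row(1234)), 1234)
  expect_warning(z <- compute_tmtv(les[0, ]), "Empty")
  expect_equal(z, 0)
})

test_that("TVSR is TMTV/TTS in mm, undefined at zero surface", {
  expect_equal(compute_tvsr(32730, 6597), 4.961, tolerance = 1e-4)
  # sphere identity V/S = r/3
  r <- 3
  expect_equal(compute_tvsr(4 / 3 * pi * r^3, 4 * pi * r^2), 1)
  expect_error(compute_tvsr(100, 0), "TTS")
})

test_that("bulky disease uses a strict 50 mm diameter threshold", {
  expect_true(bulky_flag(dplyr::bind_rows(lesion_row(diameter = 30),
                                          lesion_row(diameter = 51))))
  expect_false(bulky_flag(lesion_row(diameter = 50)))
  expect_false(bulky_flag(lesion_row(diameter = 50)[0, ]))
})

test_that("extra stage requires both diaphragm sides and >1 distinct extranodal organ", {
  both_two_organs <- dplyr::bind_rows(
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "lung"),
    lesion_row(side = "below_diaphragm", compartment = "extranodal", organ = "liver")
  )
  expect_true(extra_stage_flag(both_two_organs))

  one_side <- dplyr::bind_rows(
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "lung"),
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "liver"),
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "bone")
  )
  expect_false(extra_stage_flag(one_side))

  one_organ <- dplyr::bind_rows(
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "lung"),
    lesion_row(side = "below_diaphragm", compartment = "extranodal", organ = "lung")
  )
  expect_false(extra_stage_flag(one_organ))

  # one organ with several lesions is still a single site
  multi_lesion_one_site <- dplyr::bind_rows(
    lesion_row(side = "above_diaphragm", compartment = "extranodal", organ = "lung"),
    lesion_row(side = "below_diaphragm", compartment = "extranodal", organ = "lung"),
    lesion_row(side = "below_diaphragm", compartment = "extranodal", organ = "lung")
  )
  expect_false(extra_stage_flag(multi_lesion_one_site))

  missing <- lesion_row()
  missing$side <- NA_character_
  expect_error(extra_stage_flag(missing), "missing site annotation")
})

test_that("legacy IPI-style flags derive from stage tokens and extranodal organ counts", {
  les2 <- dplyr::bind_rows(
    lesion_row(compartment = "extranodal", organ = "lung"),
    lesion_row(compartment = "extranodal", organ = "liver")
  )
  expect_identical(legacy_flags(les2, "IV"),
                   list(stage_3_4 = TRUE, extranodal_gt1 = TRUE))
  expect_identical(legacy_flags(les2, "II"),
                   list(stage_3_4 = FALSE, extranodal_gt1 = TRUE))
  expect_identical(legacy_flags(lesion_row(), "III"),
                   list(stage_3_4 = TRUE, extranodal_gt1 = FALSE))
  expect_error(legacy_flags(les2, "V"), "Unknown")
})

test_that("synergy grouping is the three-level ordinal factor", {
  g <- synergy_group(c(FALSE, TRUE, FALSE, TRUE), c(FALSE, FALSE, TRUE, TRUE))
  expect_identical(as.character(g), c("neither", "either", "either", "both"))
  expect_identical(levels(g), c("neither", "either", "both"))
})

test_that("adding a lesion can only flip flags false -> true", {
  withr::with_seed(21, {
    for (i in 1:20) {
      n <- sample(1:4, 1)
      les <- dplyr::bind_rows(lapply(seq_len(n), function(j) {
        lesion_row(
          diameter = runif(1, 10, 70),
          side = sample(c("above_diaphragm", "below_diaphragm"), 1),
          compartment = sample(c("nodal", "extranodal"), 1),
          organ = sample(c("lung", "liver", "bone"), 1)
        )
      }))
      extra_les <- lesion_row(
        diameter = runif(1, 10, 70),
        side = sample(c("above_diaphragm", "below_diaphragm"), 1),
        compartment = sample(c("nodal", "extranodal"), 1),
        organ = sample(c("lung", "liver", "bone"), 1)
      )
      grown <- dplyr::bind_rows(les, extra_les)
      expect_true(bulky_flag(grown) >= bulky_flag(les))
      expect_true(extra_stage_flag(grown) >= extra_stage_flag(les))
    }
  })
})

test_that("on single-sphere patients TVSR is r/3 and perfectly rank-correlated with TMTV", {
  radii <- seq(5, 40, length.out = 12)
  pats <- dplyr::bind_rows(lapply(radii, function(r) {
    patient_indicators(lesion_row(
      volume = 4 / 3 * pi * r^3, surface = 4 * pi * r^2, diameter = 2 * r
    ))
  }))
  expect_equal(pats$tvsr_mm, radii / 3)
  sp <- spearman_cor(pats$tvsr_mm, pats$tmtv_mm3)
  expect_equal(sp$rho, 1)
})
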