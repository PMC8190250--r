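test_that("analyte categories follow the scoring grid", {
  cases <- list(
    # value column, value, expected points column, expected points
    list("smb_pct", 10, "points_smb", 1L),
    list("smb_pct", 6, "points_smb", 1L),     # lower normal bound inclusive
    list("smb_pct", 4, "points_smb", 2L),
    list("smb_pct", 1.5, "points_smb", 3L),
    list("smb_pct", 0.5, "points_smb", 4L),
    list("iga_g_l", 1.2, "points_iga", 1L),
    list("iga_g_l", 0.3, "points_iga", 2L),
    list("iga_g_l", 0.07, "points_iga", 2L),  # detectability bound inclusive
    list("iga_g_l", 0.05, "points_iga", 4L),
    list("igm_g_l", 1.0, "points_igm", 1L),
    list("igm_g_l", 2.3, "points_igm", 1L),
    list("igm_g_l", 3.0, "points_igm", 4L),
    list("cd4_per_ul", 900, "points_cd4", 1L),
    list("cd4_per_ul", 700, "points_cd4", 1L),
    list("cd4_per_ul", 600, "points_cd4", 2L),
    list("cd4_per_ul", 350, "points_cd4", 3L),
    list("cd4_per_ul", 150, "points_cd4", 4L)
  )
  for (cs in cases) {
    labs <- make_labs()
    labs[[cs[[1]]]] <- cs[[2]]
    got <- categorize_analytes(labs)[[cs[[3]]]]
    expect_identical(got, cs[[4]],
                     label = paste(cs[[1]], "=", cs[[2]]))
  }
})

test_that("antibody-response points count inadequate responses", {
  both_ok <- categorize_analytes(make_labs())
  expect_identical(both_ok$points_ab, 1L)
  expect_identical(
    categorize_analytes(make_labs(poly_response = "inadequate"))$points_ab, 2L)
  expect_identical(
    categorize_analytes(make_labs(protein_response = "inadequate"))$points_ab, 2L)
  expect_identical(
    categorize_analytes(make_labs(poly_response = "inadequate",
                                  protein_response = "inadequate"))$points_ab,
    4L)
})

test_that("fully normal panel scores 5/low; fully altered scores 20/high", {
  lo <- score_visual(make_labs())
  expect_identical(lo$visual_total, 5L)
  expect_identical(as.character(lo$risk_class), "low")

  hi <- score_visual(make_labs(
    smb_pct = 0.5, iga_g_l = 0.03, igm_g_l = 3,
    poly_response = "inadequate", protein_response = "inadequate",
    cd4_per_ul = 150
  ))
  expect_identical(hi$visual_total, 20L)
  expect_identical(as.character(hi$risk_class), "high")
})

test_that("a total equal to the cutoff is classified high risk", {
  # components (2,2,1,2,2) -> 9 -> low; adding one point crosses to high
  nine <- score_visual(make_labs(smb_pct = 4, iga_g_l = 0.3,
                                 poly_response = "inadequate",
                                 cd4_per_ul = 600))
  expect_identical(nine$visual_total, 9L)
  expect_identical(as.character(nine$risk_class), "low")

  ten <- score_visual(make_labs(smb_pct = 1.5, iga_g_l = 0.3,
                                poly_response = "inadequate",
                                cd4_per_ul = 600))
  expect_identical(ten$visual_total, 10L)
  expect_identical(as.character(ten$risk_class), "high")
})

test_that("above-normal CD4 and smB score 1 point with a warning flag", {
  expect_warning(out <- categorize_analytes(make_labs(cd4_per_ul = 1600)),
                 "CD4 above the normal range")
  expect_identical(out$points_cd4, 1L)
  expect_true(out$flag_cd4_above_normal)

  expect_warning(out2 <- categorize_analytes(make_labs(smb_pct = 35)),
                 "smB above the normal range")
  expect_identical(out2$points_smb, 1L)
  expect_true(out2$flag_smb_above_normal)
})

test_that("incomplete panels are refused, never imputed", {
  expect_error(score_visual(make_labs(iga_g_l = NA_real_)),
               "incomplete panel")
  expect_error(score_visual(make_labs(poly_response = NA_character_)),
               "incomplete panel")
})

test_that("score_cohort preserves order and collects rejects with reasons", {
  cohort <- dplyr::bind_rows(
    make_labs(patient_id = "a", smb_pct = 0.5),
    make_labs(patient_id = "b", iga_g_l = NA_real_),
    make_labs(patient_id = "c", cd4_per_ul = 350),
    make_labs(patient_id = "d", smb_pct = 120)
  )
  scored <- score_cohort(cohort)
  expect_identical(scored$patient_id, c("a", "c"))
  rej <- scoring_rejects(scored)
  expect_identical(rej$patient_id, c("b", "d"))
  expect_setequal(rej$reason, c("incomplete panel", "value out of range"))

  expect_error(score_cohort(cohort[0, ]), "Empty cohort")
  # scoring is deterministic: same input, same output
  expect_identical(score_cohort(cohort), scored)
})

test_that("the attainable totals span exactly 5 to 20", {
  combos <- enumerate_visual_combinations()
  expect_identical(range(combos$visual_total), c(5L, 20L))
  expect_identical(nrow(combos), 4L * 3L * 2L * 3L * 4L)
  expect_identical(sort(unique(combos$visual_total)), 5:20)
})

test_that("degrading any single analyte never decreases the total", {
  # representative input values per category, worst last
  ladders <- list(
    smb_pct = c(10, 4, 1.5, 0.5),
    iga_g_l = c(1.5, 0.3, 0.05),
    igm_g_l = c(1.0, 3.0),
    cd4_per_ul = c(900, 600, 350, 150)
  )
  for (col in names(ladders)) {
    totals <- vapply(ladders[[col]], function(v) {
      labs <- make_labs()
      labs[[col]] <- v
      score_visual(labs)$visual_total
    }, integer(1))
    expect_true(all(diff(totals) >= 0), label = col)
  }
  ab_ladder <- list(c("adequate", "adequate"), c("inadequate", "adequate"),
                    c("inadequate", "inadequate"))
  totals <- vapply(ab_ladder, function(v) {
    score_visual(make_labs(poly_response = v[1],
                           protein_response = v[2]))$visual_total
  }, integer(1))
  expect_true(all(diff(totals) >= 0))
})

test_that("point assignment is piecewise-constant and monotone on a grid", {
  ref <- visual_reference()
  grid_case <- list(
    # deficiency markers: higher value means healthier, points non-increasing
    list(col = "smb_pct", grid = seq(0, 58, by = 0.25), pts = "points_smb",
         dir = -1),
    list(col = "iga_g_l", grid = seq(0, 8, by = 0.01), pts = "points_iga",
         dir = -1),
    list(col = "cd4_per_ul", grid = seq(0, 3000, by = 10),
         pts = "points_cd4", dir = -1),
    # IgM is penalized when elevated: points non-decreasing in the value
    list(col = "igm_g_l", grid = seq(0, 4.6, by = 0.02), pts = "points_igm",
         dir = 1)
  )
  for (cs in grid_case) {
    labs <- make_labs()[rep(1, length(cs$grid)), ]
    labs[[cs$col]] <- cs$grid
    pts <- suppressWarnings(categorize_analytes(labs, ref))[[cs$pts]]
    expect_true(all(cs$dir * diff(pts) >= 0), label = cs$col)
  }
})

test_that("each configured threshold steps the category by exactly one level", {
  ref <- visual_reference()
  eps <- 1e-9
  steps <- list(
    list(col = "smb_pct", t = ref$smb_thresholds_pct, pts = "points_smb"),
    list(col = "cd4_per_ul", t = ref$cd4_thresholds_per_ul,
         pts = "points_cd4")
  )
  for (cs in steps) {
    for (t in cs$t) {
      below_labs <- make_labs()
      below_labs[[cs$col]] <- t - eps
      below <- categorize_analytes(below_labs)
      at_labs <- make_labs()
      at_labs[[cs$col]] <- t
      at <- categorize_analytes(at_labs)
      expect_identical(below[[cs$pts]] - at[[cs$pts]], 1L,
                       label = paste(cs$col, "at", t))
    }
  }
})

test_that("titre helper applies fold-rise or absolute criteria", {
  expect_identical(ab_response(0.02, 0.1, "protein"), "adequate")    # 5-fold
  expect_identical(ab_response(0.05, 0.16, "protein"), "adequate")   # absolute
  expect_identical(ab_response(0.05, 0.1, "protein"), "inadequate")
  expect_identical(ab_response(5, 16, "polysaccharide"), "adequate")  # 3-fold
  expect_identical(ab_response(5, 12, "polysaccharide"), "adequate")  # >= 11
  expect_identical(ab_response(5, 10, "polysaccharide"), "inadequate")
})

test_that("reference configuration validates its invariants", {
  expect_error(visual_reference(smb_thresholds_pct = c(2, 6, 1)),
               "strictly decreasing")
  expect_error(visual_reference(iga_undetectable_g_l = 1.0),
               "undetectable")
  expect_error(visual_reference(cd4_thresholds_per_ul = c(200, 500, 700)),
               "strictly decreasing")
})
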