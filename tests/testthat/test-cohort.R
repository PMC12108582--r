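test_that("cohort summary agrees with a brute-force recomputation", {
  set.seed(17)
  for (rep in 1:5) {
    n <- sample(c(10, 100, 1000), 1)
    tab <- tibble::tibble(
      patient_id = as.character(seq_len(n)),
      compartment = sample(c("femur", "tibia"), n, replace = TRUE),
      bvtv = runif(n), tb_th = runif(n, 0, 1), volume = runif(n, 10, 400))
    s <- summarize_cohort(tab)
    for (comp in c("femur", "tibia")) {
      for (met in c("bvtv", "tb_th", "volume")) {
        ref <- bf_summary(tab[[met]][tab$compartment == comp])
        row <- dplyr::filter(s, compartment == comp, metric == met)
        expect_equal(row$n, ref$n)
        expect_equal(row$mean, ref$mean)
        expect_equal(row$sd, ref$sd)
        expect_equal(row$min, ref$min)
        expect_equal(row$max, ref$max)
      }
    }
    ov <- dplyr::filter(s, compartment == "overall", metric == "bvtv")
    expect_equal(ov$min, min(tab$bvtv))
    expect_equal(ov$max, max(tab$bvtv))
    # invariant under row permutation
    s2 <- summarize_cohort(tab[sample(n), ])
    expect_equal(as.data.frame(s), as.data.frame(s2))
  }
})

test_that("degenerate groups are handled explicitly", {
  tab <- tibble::tibble(compartment = rep("femur", 3), bvtv = rep(0.2, 3))
  s <- summarize_cohort(tab)
  r <- dplyr::filter(s, compartment == "femur")
  expect_equal(r$sd, 0)
  expect_equal(r$min, r$mean)
  expect_equal(r$max, r$mean)
  one <- summarize_cohort(tibble::tibble(compartment = "tibia", bvtv = 0.1))
  expect_true(is.na(dplyr::filter(one, compartment == "tibia")$sd))
  expect_error(summarize_cohort(tibble::tibble()), "empty")
})

test_that("the worked-example cohort reproduces its published summary statistics", {
  tab <- load_cohort_table(table4_fixture_path())
  s <- summarize_cohort(tab)
  pick <- function(comp, met) dplyr::filter(s, compartment == comp,
                                            metric == met)
  expect_equal(round_half_away(pick("femur", "bvtv")$mean, 3), 0.134)
  expect_equal(round_half_away(pick("tibia", "bvtv")$mean, 3), 0.122)
  expect_equal(round_half_away(pick("femur", "tb_th")$mean, 3), 0.370)
  expect_equal(round_half_away(pick("tibia", "tb_th")$mean, 3), 0.326)
  expect_equal(round_half_away(pick("femur", "tb_n")$mean, 2), 2.20)
  expect_equal(round_half_away(pick("tibia", "tb_n")$mean, 2), 2.22)
  expect_equal(round_half_away(pick("femur", "volume")$mean, 0), 257)
  expect_equal(round_half_away(pick("tibia", "volume")$mean, 0), 195)
  expect_equal(round_half_away(pick("overall", "tb_sp")$max, 3), 1.380)
  expect_equal(round_half_away(pick("tibia", "bvtv")$max, 3), 0.274)
  # ranges
  expect_equal(round_half_away(pick("femur", "bvtv")$max, 3), 0.199)
  expect_equal(round_half_away(pick("overall", "tb_sp")$min, 3), 0.241)
  expect_equal(round_half_away(pick("tibia", "volume")$min, 0), 81)
  expect_equal(round_half_away(pick("tibia", "volume")$max, 0), 290)
  # the published +/- values follow the population-SD convention
  expect_equal(round_half_away(pick("femur", "bvtv")$sd, 3), 0.028)
  expect_equal(round_half_away(pick("tibia", "bvtv")$sd, 3), 0.048)
  expect_equal(round_half_away(pick("femur", "tb_sp")$sd, 2), 0.06)
  expect_equal(round_half_away(pick("tibia", "tb_sp")$sd, 2), 0.21)
  expect_equal(round_half_away(pick("femur", "volume")$sd, 0), 81)
  expect_equal(round_half_away(pick("tibia", "volume")$sd, 0), 58)
  expect_equal(round_half_away(pick("femur", "tb_n")$sd, 2), 0.29)
})

test_that("reports render identically across formats with documented rounding", {
  tab <- load_cohort_table(table4_fixture_path())
  s <- summarize_cohort(tab)
  dir <- withr::local_tempdir()
  fcsv <- file.path(dir, "r.csv"); fjson <- file.path(dir, "r.json")
  rc <- render_report(s, "csv", fcsv)
  rj <- render_report(s, "json", fjson)
  expect_equal(rc, rj)   # same rounded content
  back <- read.csv(fcsv)
  fem_th <- back[back$compartment == "femur" & back$metric == "tb_th", ]
  expect_equal(fem_th$n, 24)
  expect_equal(fem_th$mean, 0.370)
  js <- jsonlite::read_json(fjson)
  expect_equal(js[["femur.tb_th"]]$mean, 0.37)
  expect_equal(js[["tibia.volume"]]$mean, 195)
  expect_error(render_report(s, "xml", fcsv), "unknown report format")
  expect_error(render_report(s[0, ], "csv", fcsv), "empty")
})

test_that("rounding is half away from zero at every magnitude", {
  expect_equal(round_half_away(0.1985, 3), 0.199)
  expect_equal(round_half_away(0.4955, 3), 0.496)
  expect_equal(round_half_away(2.205, 2), 2.21)
  expect_equal(round_half_away(-0.5), -1)
  expect_equal(round_half_away(256.5, 0), 257)
})
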