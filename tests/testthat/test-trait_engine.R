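test_that("ratio traits and crown area follow their definitions", {
  expect_equal(crown_area(10, 5), 50)
  expect_equal(crown_area(1, 1), 1)
  expect_error(crown_area(0, 5), "positive")

  expect_equal(compute_mmc(10, 12.2), 1.22)
  expect_equal(compute_mmc(7.3, 7.3), 1)
  expect_true(is.na(compute_mmc(10, NA)))

  expect_equal(compute_pmm(10, 14.1), 1.41)
  expect_error(compute_pmm(0, 14.1), "positive")

  expect_equal(compute_ic(100, 150), 1.5)
  expect_true(is.na(compute_ic(NA, 150)))
})

test_that("ratio traits are invariant to rescaling; areas scale quadratically", {
  set.seed(101)
  for (rep in 1:20) {
    md <- runif(4, 5, 15)
    bl <- runif(4, 4, 12)
    k <- runif(1, 0.5, 3)
    expect_equal(compute_mmc(k * md[2], k * md[4]), compute_mmc(md[2], md[4]))
    expect_equal(compute_pmm(k * md[1], k * md[3]), compute_pmm(md[1], md[3]))
    expect_equal(crown_area(k * md[2], k * bl[2]),
                 k^2 * crown_area(md[2], bl[2]))
  }
})

test_that("side resolution prefers left, falls back to right, never mixes", {
  full <- as_measurement_table(specimen_rows())
  tr <- specimen_traits(full)
  expect_equal(tr$side_mmc, "L")
  expect_equal(tr$MMC, 11 / 10)

  # left M3 absent: MMC from the right, other traits still left
  no_l_m3 <- full[!(full$side == "L" & full$tooth == "M3"), ]
  tr2 <- specimen_traits(as_measurement_table(no_l_m3))
  expect_equal(tr2$side_mmc, "R")
  expect_equal(tr2$side_pmm, "L")
  expect_equal(tr2$MMC, 11 / 10)

  # only left M1 and right M3: no single side complete, MMC missing
  mixed <- full[(full$side == "L" & full$tooth != "M3") |
                  (full$side == "R" & full$tooth == "M3"), ]
  tr3 <- specimen_traits(as_measurement_table(mixed))
  expect_true(is.na(tr3$MMC))
  expect_true(is.na(tr3$side_mmc))
})

test_that("side resolution never mixes sides under random missingness", {
  set.seed(77)
  for (rep in 1:50) {
    rows <- specimen_rows()
    # distinct values per (side, tooth) so mixing would be detectable
    rows$md_length <- rows$md_length + ifelse(rows$side == "L", 0, 100)
    rows$bl_breadth <- rows$bl_breadth + ifelse(rows$side == "L", 0, 100)
    keep <- runif(nrow(rows)) > 0.4
    if (!any(keep)) next
    tr <- specimen_traits(as_measurement_table(rows[keep, ]))
    if (!is.na(tr$MMC)) {
      # value must be reconstructible from a single side
      l <- rows[rows$side == "L", ]; r <- rows[rows$side == "R", ]
      cands <- c(l$md_length[l$tooth == "M3"] / l$md_length[l$tooth == "M1"],
                 r$md_length[r$tooth == "M3"] / r$md_length[r$tooth == "M1"])
      expect_true(any(abs(cands - tr$MMC) < 1e-12))
    }
  }
})

test_that("geometric-mean size correction removes scale", {
  out <- size_correct_areas(data.frame(area_M1 = 2, area_M2 = 4, area_M3 = 8))
  expect_equal(unlist(out, use.names = FALSE), c(0.5, 1, 2))

  same <- size_correct_areas(data.frame(area_M1 = 7, area_M2 = 7, area_M3 = 7))
  expect_equal(unlist(same, use.names = FALSE), c(1, 1, 1))

  set.seed(5)
  a <- data.frame(area_M1 = runif(10, 20, 60), area_M2 = runif(10, 30, 80),
                  area_M3 = runif(10, 25, 70))
  expect_equal(size_correct_areas(a * 3.7), size_correct_areas(a))

  a$area_M2[3] <- NA
  expect_true(all(is.na(size_correct_areas(a)[3, ])))
})

test_that("descriptive statistics use sample sd and Pearson kurtosis", {
  d <- descriptive_stats(1:5)
  expect_equal(d$mean, 3)
  expect_equal(d$sd, sqrt(2.5))
  expect_equal(round(d$sd, 4), 1.5811)
  expect_equal(c(d$min, d$max, d$n), c(1, 5, 5))

  # symmetric two-point sample: m4/m2^2 = 1 exactly
  expect_equal(descriptive_stats(c(-1, 1, -1, 1))$kurtosis, 1)

  # cross-check the moment convention against e1071 (excess, type 1)
  set.seed(42)
  x <- rnorm(1e5)
  k <- descriptive_stats(x)$kurtosis
  expect_lt(abs(k - 3), 0.2)
  expect_equal(k, e1071::kurtosis(x, type = 1) + 3, tolerance = 1e-10)

  cst <- descriptive_stats(rep(2, 4))
  expect_false(cst$kurtosis_defined)
  expect_equal(cst$sd, 0)
  expect_error(descriptive_stats(numeric(0)), "empty")
})

test_that("genus summaries aggregate specimen -> species -> genus unweighted", {
  traits <- data.frame(
    specimen_id = paste0("s", 1:6),
    genus = c("G1", "G1", "G1", "G1", "G2", "G2"),
    species = c("sp1", "sp1", "sp1", "sp2", "sp3", "sp3"),
    area_M1 = 1, area_M2 = 1, area_M3 = 1, IC = 1,
    MMC = c(1.0, 1.0, 1.0, 1.2, 1.5, 1.7),
    PMM = NA_real_)
  g <- genus_summaries(traits)
  # species means 1.0 (3 specimens) and 1.2 (1): unweighted genus mean 1.1
  expect_equal(g$MMC[g$genus == "G1"], 1.1)
  expect_equal(g$MMC_n[g$genus == "G1"], 4L)
  # single-species genus: genus value equals the species mean
  expect_equal(g$MMC[g$genus == "G2"], 1.6)
  # all-missing trait: missing with n = 0
  expect_true(all(is.na(g$PMM)))
  expect_equal(g$PMM_n, c(0L, 0L))
})
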