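test_that("305-day milk correction follows the fixed constant", {
  expect_equal(correct_mp305(2000, 305), 2000)
  expect_equal(correct_mp305(2000, 205), 2542.705)
  expect_equal(correct_mp305(3000, 335), 2837.1885)
  # affine in ll with slope -5.42705
  ll <- seq(200, 330, by = 10)
  y <- correct_mp305(rep(2500, length(ll)), ll)
  expect_equal(unname(coef(lm(y ~ ll))[2]), -5.42705, tolerance = 1e-12)
  expect_error(correct_mp305(-1, 300), "positive")
})

test_that("heterozygosity covers the pure, F1 and half-bred cases", {
  expect_equal(heterozygosity(1, 0, 1, 0), 0)       # purebred Murrah
  expect_equal(heterozygosity(1, 1, 0, 0), 1)       # F1 cross
  expect_equal(heterozygosity(0.5, 0.5, 0.5, 0.5), 0.5)
  # symmetric under swapping sire and dam contributions
  set.seed(5)
  ms <- runif(20); mm <- runif(20)
  expect_equal(heterozygosity(ms, 1 - mm, mm, 1 - ms),
               heterozygosity(mm, 1 - ms, ms, 1 - mm))
  expect_error(heterozygosity(0.7, 0.5, 0.5, 0.5), "sum to 1")
})

test_that("calving seasons are calendar quarters", {
  expect_equal(calving_season(2), 1L)
  expect_equal(calving_season(5), 2L)
  expect_equal(calving_season(12), 4L)
  expect_equal(calving_season(1:12), rep(1:4, each = 3))
  expect_error(calving_season(13), "1..12")
})

test_that("contemporary groups enforce the minimum size together with their records", {
  rec <- data.frame(herd = c("h1", "h1", "h1", "h2", "h2"),
                    year = 2020, cs = 1, y = 1:5)
  out <- build_contemporary_groups(rec, min_size = 3)
  expect_equal(nrow(out$records), 3)
  expect_equal(nrow(out$dropped), 2)
  expect_match(out$dropped$reason[1], "below minimum size")
  expect_true(all(table(out$records$cg) >= 3))
  expect_warning(build_contemporary_groups(rec[0, ]), "no records")
})

test_that("AFC dichotomization puts the boundary in class 1 and reports the median", {
  expect_equal(dichotomize_afc(30, threshold = 36.32)$class, 1L)
  expect_equal(dichotomize_afc(40, threshold = 36.32)$class, 2L)
  expect_equal(dichotomize_afc(36.32, threshold = 36.32)$class, 1L)
  v <- c(30, 35, 36, 40, 44)
  out <- dichotomize_afc(v)
  expect_equal(out$threshold, 36)
  expect_equal(out$class, c(1L, 1L, 1L, 2L, 2L))
  expect_error(dichotomize_afc(c(NA_real_, NA_real_)), "missing")
  # median split on continuous data is near-balanced
  set.seed(9)
  cl <- dichotomize_afc(rnorm(501, 37, 5))$class
  expect_gte(min(table(cl)) / 501, 0.4)
})

test_that("prepare_dataset runs the full pipeline with logging", {
  herd <- small_herd()
  prep <- prepare_dataset(herd$phenotypes, herd$ped)
  expect_s3_class(prep, "prep_data")
  # every retained group respects the size minimum
  expect_true(all(table(prep$mp$cg_idx) >= 3))
  expect_true(all(table(prep$afc$cg_idx) >= 3))
  # one AFC record per animal, classes defined everywhere
  expect_false(anyDuplicated(prep$afc$animal) > 0)
  expect_false(anyNA(prep$afc$afc_class))
  # mp305 equals the corrected tmp
  ph <- herd$phenotypes
  key <- paste(ph$animal, round(correct_mp305(ph$tmp, ph$ll), 6))
  expect_true(all(paste(prep$mp$animal, round(prep$mp$mp305, 6)) %in% key))
  # dropped log accounts for the record difference
  expect_equal(nrow(prep$mp) + nrow(prep$afc) + nrow(prep$dropped),
               nrow(ph) + sum(!is.na(ph$afc)))
  # unknown animal is an error
  ph2 <- ph; ph2$animal[1] <- "GHOST"
  expect_error(prepare_dataset(ph2, herd$ped), "GHOST")
})
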