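test_that("subsample means behave like sampling theory predicts", {
  # constant chain -> all means equal
  expect_equal(subsample_means(rep(0.3, 5000), k = 10, size = 1000),
               rep(0.3, 10))
  # 30 subsamples of 2,700 from 27,000 draws -> 30 values
  set.seed(12)
  ch <- rnorm(27000, 0.27, 0.09)
  m <- subsample_means(ch, k = 30, size = 2700)
  expect_length(m, 30)
  # variance of subsample means ~ chain variance / size for iid chains
  mm <- subsample_means(ch, k = 2000, size = 100)
  expect_equal(var(mm), var(ch) / 100, tolerance = 0.2 * var(ch) / 100 * 5)
  expect_error(subsample_means(rnorm(100), size = 2700), "exceeds")
})

test_that("Welch t-test contract: identical samples give t = 0, separated samples reject", {
  set.seed(13)
  x <- rnorm(30, 0.27, 0.002)
  tt <- two_sample_t(x, x)
  expect_equal(tt$t, 0)
  expect_false(tt$reject)
  yy <- rnorm(30, 0.37, 0.002)
  tt2 <- two_sample_t(x, yy)
  expect_true(tt2$reject)
  expect_lt(tt2$p, 1e-10)
  expect_error(two_sample_t(rep(1, 5), rep(1, 5)), "constant")
})

test_that("t-test on same-chain subsample means rejects near the nominal rate", {
  set.seed(14)
  ch <- rnorm(27000)
  rej <- replicate(300, {
    two_sample_t(subsample_means(ch, k = 15, size = 500),
                 subsample_means(ch, k = 15, size = 500))$reject
  })
  expect_gt(mean(rej), 0.005)
  expect_lt(mean(rej), 0.15)
})

make_report <- function(ebv_mp, ebv_afc, sd = 0.5, g = c(1, 1)) {
  n <- length(ebv_mp)
  out <- data.frame(animal = sprintf("S%02d", seq_len(n)), n_progeny = 5L,
                    ebv_mp = ebv_mp, sd_mp = sd, ebv_afc = ebv_afc,
                    sd_afc = sd,
                    accuracy_mp = sqrt(pmax(1 - sd^2 / g[1], 0)),
                    accuracy_afc = sqrt(pmax(1 - sd^2 / g[2], 0)))
  out$scenario_all <- TRUE
  out$scenario_mp_pos <- out$ebv_mp > 0
  out$scenario_afc_neg <- out$ebv_afc < 0
  class(out) <- c("ebv_report", "data.frame")
  out
}

test_that("Spearman scenarios hit the exact-rank limits", {
  set.seed(15)
  mp <- rnorm(20); afc <- rnorm(20)
  r1 <- make_report(mp, afc)
  # identical EBVs across models -> between-model rho = 1
  sp <- spearman_scenarios(r1, r1)
  expect_equal(sp$rho[sp$scenario == "all" &
                      sp$comparison == "mp_between_models"], 1)
  # reversed ranks -> rho = -1
  r2 <- make_report(-mp, afc)
  sp2 <- spearman_scenarios(r1, r2)
  expect_equal(sp2$rho[sp2$scenario == "all" &
                       sp2$comparison == "mp_between_models"], -1)
  # scenarios are nested subsets of "all"
  expect_true(all(sp$n[sp$scenario != "all"] <= sp$n[sp$scenario == "all"]))
  # under-sized scenario reported as NA
  r3 <- make_report(c(-1, -2, 1, 2), c(1, 1, 1, 1))  # no negative AFC sires
  sp3 <- suppressWarnings(spearman_scenarios(r3, r3))
  expect_true(all(is.na(sp3$rho[sp3$scenario == "afc_neg"])))
})

test_that("independent traits give near-zero cross-trait rank correlation", {
  set.seed(16)
  mp <- rnorm(400); afc <- rnorm(400)
  sp <- spearman_scenarios(make_report(mp, afc), make_report(mp, afc))
  rho <- sp$rho[sp$scenario == "all" & sp$comparison == "mp_afc_model_a"]
  expect_lt(abs(rho), 0.15)
})

test_that("EBV descriptives mirror the selection rules", {
  set.seed(17)
  r <- make_report(rnorm(30), rnorm(30))
  d <- ebv_descriptives(r)
  # scenario 3 holds only negative AFC breeding values
  expect_lt(d$max[d$scenario == "afc_neg" & d$trait == "AFC"], 0)
  # scenario 2 only positive MP values
  expect_gt(d$min[d$scenario == "mp_pos" & d$trait == "MP"], 0)
  # equal information -> constant accuracy column
  expect_equal(length(unique(d$accuracy[d$trait == "MP"])), 1L)
  # single sire -> degenerate stats
  r1 <- make_report(0.4, -0.2)
  d1 <- ebv_descriptives(r1)
  expect_equal(d1$sd[1], 0)
  expect_equal(d1$min[1], d1$max[1])
})

test_that("sire report accuracy rises with progeny information", {
  herd <- small_herd(seed = 31)
  prep <- prepare_dataset(herd$phenotypes, herd$ped)
  fit <- run_chain(prep, herd$ped, quick_spec(cycles = 3000, burn = 600))
  rep <- ebv_report(fit, herd$ped, prep)
  expect_true(all(rep$accuracy_mp >= 0 & rep$accuracy_mp <= 1))
  expect_true(all(rep$n_progeny >= 1))
  # rank correlation between progeny count and accuracy positive
  expect_gt(cor(rep$n_progeny, rep$accuracy_mp, method = "spearman"), 0)
})
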