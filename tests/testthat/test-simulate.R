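test_that("pedigree simulation respects structure and determinism", {
  cfg <- sim_config(n_sires = 10, n_dams = 20, n_generations = 0, seed = 1)
  set.seed(1)
  ped <- simulate_pedigree(cfg)
  expect_equal(nrow(ped), 30)             # founders only
  expect_equal(a_matrix(ped), diag(30), ignore_attr = TRUE)

  cfg2 <- sim_config(n_sires = 10, n_dams = 20, n_generations = 3,
                     progeny_per_mating = 2, seed = 2)
  set.seed(2); p1 <- simulate_pedigree(cfg2)
  set.seed(2); p2 <- simulate_pedigree(cfg2)
  expect_identical(p1, p2)                # deterministic given seed
  expect_gt(nrow(p1), 30)
  # no selfing: sire and dam always differ
  kids <- !is.na(p1$sire)
  expect_true(all(p1$sire[kids] != p1$dam[kids]))
})

test_that("all-purebred founders give zero heterozygosity everywhere", {
  cfg <- sim_config(n_sires = 5, n_dams = 10, n_generations = 2,
                    p_purebred = 1, seed = 3)
  set.seed(3)
  ped <- simulate_pedigree(cfg)
  htz <- heterozygosity(ped$murrah_sire, ped$other_dam,
                        ped$murrah_dam, ped$other_sire)
  expect_true(all(htz == 0))
})

test_that("simulated breeding values reproduce the generating covariance", {
  cfg <- sim_config(n_sires = 100, n_dams = 2500, n_generations = 1,
                    progeny_per_mating = 2, seed = 4)
  set.seed(4)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  a <- sim$truth$a
  emp <- cov(a[attr(ped, "generation") == 1L, ])
  expect_equal(emp[1, 1], cfg$G0[1, 1], tolerance = 0.06 * cfg$G0[1, 1])
  expect_equal(emp[2, 2], cfg$G0[2, 2], tolerance = 0.06 * cfg$G0[2, 2])
  expect_equal(emp[1, 2], cfg$G0[1, 2], tolerance = 0.35 * abs(cfg$G0[1, 2]))
})

test_that("phenotypes decompose into fixed, genetic and residual parts", {
  # residual-free limit with flat environment: the phenotype equals the
  # population mean + heterosis + genetic part exactly
  cfg <- sim_config(n_sires = 6, n_dams = 12, n_generations = 1,
                    h2_mp = 0.999, h2_afc = 0.999,
                    sd_herd = c(0, 0), sd_year = c(0, 0), sd_season = c(0, 0),
                    seed = 5)
  set.seed(5)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  ph <- sim$phenotypes
  mp305 <- correct_mp305(ph$tmp, ph$ll)
  htz_row <- heterozygosity(ped$murrah_sire, ped$other_dam,
                            ped$murrah_dam,
                            ped$other_sire)[attr(ped, "index")[ph$animal]]
  recon <- cfg$mu_mp + cfg$slope_htz_mp * htz_row + sim$truth$a[ph$animal, 1]
  expect_equal(mp305, unname(recon), tolerance = 0.05)
  # median split of simulated AFC separates true liabilities
  herd <- small_herd(seed = 6)
  ph2 <- herd$phenotypes[!is.na(herd$phenotypes$afc), ]
  cl <- dichotomize_afc(ph2$afc)$class
  li <- herd$truth$liability[ph2$animal]
  expect_gt(mean(li[cl == 2]), mean(li[cl == 1]))
})

test_that("herd files round-trip through the readers", {
  herd <- small_herd(seed = 8)
  dir <- tempfile()
  paths <- write_herd(herd, dir)
  ped2 <- read_pedigree(paths["pedigree"])
  ph2 <- read_phenotypes(paths["phenotypes"])
  expect_equal(ped2$animal, herd$ped$animal)
  expect_equal(ped2$murrah_sire, herd$ped$murrah_sire, tolerance = 1e-12)
  expect_equal(nrow(ph2), nrow(herd$phenotypes))
  expect_equal(ph2$tmp, herd$phenotypes$tmp, tolerance = 1e-4)
  expect_equal(is.na(ph2$afc), is.na(herd$phenotypes$afc))
  expect_true(file.exists(paths["truth"]))
  unlink(dir, recursive = TRUE)
})
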