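#' Configuration for the synthetic herd generator
#'
#' Assembles (and validates) the parameters of the synthetic Murrah herd
#' simulator. Defaults are sized to the structure of the motivating
#' population: roughly 80 sires, a thousand recorded cows, ~2,900 milk
#' records (repeated lactations per cow) and ~660 cows with age at first
#' calving recorded, spread over herd x year x season contemporary groups,
#' with a heterozygosity covariate spanning `[0, 1]`.
#'
#' Genetic parameters are given on the heritability scale and converted to
#' (co)variance matrices: `G0[t,t] = h2_t * vp_t`, `R0[t,t] = (1-h2_t) * vp_t`,
#' off-diagonals from `rg` and `re`.
#'
#' @param n_sires,n_dams founder males / females (unknown parents).
#' @param n_generations number of discrete offspring generations.
#' @param progeny_per_mating progeny per dam and generation.
#' @param p_female probability a progeny is female (recorded sex ratio).
#' @param n_herds number of herds; cows stay in one herd.
#' @param years calendar years available for first calvings.
#' @param lambda_lact Poisson mean of lactations beyond the first.
#' @param max_lact cap on lactations per cow.
#' @param p_afc probability a cow's age at first calving is recorded.
#' @param mu_mp,mu_afc trait means (kg; months).
#' @param vp_mp,vp_afc phenotypic (additive + residual) variances.
#' @param h2_mp,h2_afc,rg,re heritabilities, genetic and residual correlation.
#' @param slope_htz_mp,slope_htz_afc heterosis regression slopes (kg / months
#'   per unit heterozygosity).
#' @param sd_herd,sd_year,sd_season fixed-effect standard deviations, each a
#'   length-2 vector `(MP, AFC)`.
#' @param p_purebred probability a founder parental contribution is purebred
#'   Murrah (otherwise uniform on `[0, 1]`).
#' @param seed integer seed used by [simulate_herd()].
#' @return a list of class `sim_config`.
#' @export
sim_config <- function(n_sires = 40, n_dams = 350, n_generations = 3,
                       progeny_per_mating = 2, p_female = 0.5,
                       n_herds = 3, years = 2012:2017,
                       lambda_lact = 1.6, max_lact = 5, p_afc = 0.6,
                       mu_mp = 2282, mu_afc = 37.4,
                       vp_mp = 2512, vp_afc = 26.8,
                       h2_mp = 0.32, h2_afc = 0.27, rg = 0.15, re = 0.10,
                       slope_htz_mp = 150, slope_htz_afc = -1.5,
                       sd_herd = c(400, 2.0), sd_year = c(150, 1.5),
                       sd_season = c(80, 1.0),
                       p_purebred = 0.5, seed = 20260920) {
  stopifnot(n_sires >= 2, n_dams >= 1, n_generations >= 0,
            progeny_per_mating >= 1,
            h2_mp > 0, h2_mp < 1, h2_afc > 0, h2_afc < 1,
            abs(rg) < 1, abs(re) < 1, p_afc > 0, p_afc <= 1)
  G0 <- matrix(c(h2_mp * vp_mp,
                 rg * sqrt(h2_mp * vp_mp * h2_afc * vp_afc),
                 rg * sqrt(h2_mp * vp_mp * h2_afc * vp_afc),
                 h2_afc * vp_afc), 2, 2)
  R0 <- matrix(c((1 - h2_mp) * vp_mp,
                 re * sqrt((1 - h2_mp) * vp_mp * (1 - h2_afc) * vp_afc),
                 re * sqrt((1 - h2_mp) * vp_mp * (1 - h2_afc) * vp_afc),
                 (1 - h2_afc) * vp_afc), 2, 2)
  if (min(eigen(G0, symmetric = TRUE, only.values = TRUE)$values) <= 0 ||
      min(eigen(R0, symmetric = TRUE, only.values = TRUE)$values) <= 0)
    stop("implied G0/R0 not positive definite")
  cfg <- as.list(environment())
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a pedigree with discrete generations
#'
#' Founder sires and dams (unknown parents) are followed by
#' `n_generations` rounds of random mating: every dam of the previous
#' generation is mated to a randomly chosen founder sire (selfing is
#' impossible since sexes differ), producing `progeny_per_mating` offspring
#' of random sex. Founder breed compositions mix purebred Murrah and
#' uniformly drawn fractions so that heterozygosity spans `[0, 1]`;
#' offspring inherit the parental mean composition. Uses the current R
#' random-number stream.
#'
#' @param cfg a [sim_config()].
#' @return a sorted [pedigree()] with a `sex` attribute (`"M"`/`"F"`) and a
#'   `generation` attribute (0 = founder).
#' @export
simulate_pedigree <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  draw_frac <- function(n)
    ifelse(stats::runif(n) < cfg$p_purebred, 1, stats::runif(n))
  id <- function(prefix, i) sprintf("%s%04d", prefix, i)

  n0 <- cfg$n_sires + cfg$n_dams
  animal <- c(id("S", seq_len(cfg$n_sires)), id("D", seq_len(cfg$n_dams)))
  sire <- rep(NA_character_, n0); dam <- rep(NA_character_, n0)
  sex <- c(rep("M", cfg$n_sires), rep("F", cfg$n_dams))
  gen <- rep(0L, n0)
  ms <- draw_frac(n0); mm <- draw_frac(n0)
  own <- (ms + mm) / 2   # animal's own Murrah fraction

  males <- animal[sex == "M"]
  dams_now <- animal[sex == "F"]
  counter <- 0L
  for (g in seq_len(cfg$n_generations)) {
    if (!length(dams_now)) break
    n_off <- length(dams_now) * cfg$progeny_per_mating
    off_dam <- rep(dams_now, each = cfg$progeny_per_mating)
    off_sire <- sample(males, n_off, replace = TRUE)
    off_id <- id("C", counter + seq_len(n_off))
    counter <- counter + n_off
    off_sex <- ifelse(stats::runif(n_off) < cfg$p_female, "F", "M")
    pos <- match(c(off_sire, off_dam), animal)
    off_ms <- own[pos[seq_len(n_off)]]
    off_mm <- own[pos[n_off + seq_len(n_off)]]
    animal <- c(animal, off_id); sire <- c(sire, off_sire)
    dam <- c(dam, off_dam); sex <- c(sex, off_sex); gen <- c(gen, rep(g, n_off))
    ms <- c(ms, off_ms); mm <- c(mm, off_mm)
    own <- c(own, (off_ms + off_mm) / 2)
    dams_now <- off_id[off_sex == "F"]
  }
  ped <- pedigree(animal, sire, dam,
                  murrah_sire = ms, other_sire = 1 - ms,
                  murrah_dam = mm, other_dam = 1 - mm)
  ord <- match(ped$animal, animal)
  attr(ped, "sex") <- sex[ord]
  attr(ped, "generation") <- gen[ord]
  ped
}

#' Simulate phenotype records on a pedigree
#'
#' Draws bivariate breeding values down the pedigree (parent average plus
#' Mendelian sampling with the exact `d_i = 0.5 - 0.25 (F_s + F_d)` variance,
#' so cov(a) = `G0` Kronecker A), then generates repeated milk-production
#' lactation records and a single age-at-first-calving value per recorded cow
#' (non-founder females). The AFC residual is drawn jointly with the
#' first-lactation milk residual from `R0`; later lactations get independent
#' milk residuals. AFC is emitted as continuous months; its median split
#' defines the threshold-model classes downstream, so the continuous value
#' doubles as the true liability. Total milk is back-computed from a drawn
#' lactation length so that the 305-day correction is exercised by the
#' preparation pipeline.
#'
#' @param ped pedigree from [simulate_pedigree()] (needs `sex`/`generation`
#'   attributes).
#' @param cfg the [sim_config()] used to build `ped`.
#' @return list with `phenotypes` (data.frame `animal, herd, year, month,
#'   tmp, ll, afc`; AFC on the first-lactation row of recorded cows) and
#'   `truth` (true `G0`, `R0`, `h2_mp`, `h2_afc`, `rg`, per-animal breeding
#'   values `a`, fixed-effect draws).
#' @export
simulate_phenotypes <- function(ped, cfg) {
  stopifnot(inherits(ped, "pedigree"), inherits(cfg, "sim_config"))
  n <- nrow(ped)
  sex <- attr(ped, "sex"); gen <- attr(ped, "generation")
  if (is.null(sex) || is.null(gen))
    stop("pedigree lacks sex/generation attributes; use simulate_pedigree()")

  # breeding values: sequential parent-average + Mendelian sampling
  FF <- inbreeding(ped)
  Lg <- t(chol(cfg$G0))
  a <- matrix(0, n, 2)
  s <- ped$sire_idx; d <- ped$dam_idx
  for (i in seq_len(n)) {
    pa <- numeric(2); di <- 1
    if (s[i] > 0L) { pa <- pa + 0.5 * a[s[i], ]; di <- di - 0.25 * (1 + FF[s[i]]) }
    if (d[i] > 0L) { pa <- pa + 0.5 * a[d[i], ]; di <- di - 0.25 * (1 + FF[d[i]]) }
    a[i, ] <- pa + sqrt(di) * as.numeric(Lg %*% stats::rnorm(2))
  }
  rownames(a) <- ped$animal

  htz <- heterozygosity(ped$murrah_sire, ped$other_dam,
                        ped$murrah_dam, ped$other_sire)

  cows <- which(sex == "F" & gen > 0L)
  ncow <- length(cows)
  if (!ncow) stop("no recorded cows; increase generations or founder dams")

  herd_eff <- cbind(stats::rnorm(cfg$n_herds, 0, cfg$sd_herd[1]),
                    stats::rnorm(cfg$n_herds, 0, cfg$sd_herd[2]))
  year_eff <- cbind(stats::rnorm(length(cfg$years) + cfg$max_lact,
                                 0, cfg$sd_year[1]),
                    stats::rnorm(length(cfg$years) + cfg$max_lact,
                                 0, cfg$sd_year[2]))
  seas_eff <- cbind(stats::rnorm(4, 0, cfg$sd_season[1]),
                    stats::rnorm(4, 0, cfg$sd_season[2]))
  all_years <- c(cfg$years, max(cfg$years) + seq_len(cfg$max_lact))

  herd <- sample.int(cfg$n_herds, ncow, replace = TRUE)
  year0 <- sample(cfg$years, ncow, replace = TRUE)
  nlact <- pmin(1 + stats::rpois(ncow, cfg$lambda_lact), cfg$max_lact)
  Lr <- t(chol(cfg$R0))

  rows <- vector("list", ncow)
  for (k in seq_len(ncow)) {
    i <- cows[k]
    nl <- nlact[k]
    month <- sample.int(12, nl, replace = TRUE)
    year <- year0[k] + seq_len(nl) - 1L
    cs <- calving_season(month)
    yi <- match(year, all_years)
    # residuals: first lactation jointly with AFC, later ones independent
    e1 <- as.numeric(Lr %*% stats::rnorm(2))
    e_mp <- c(e1[1],
              if (nl > 1) stats::rnorm(nl - 1, 0, sqrt(cfg$R0[1, 1])) else NULL)
    mp305 <- cfg$mu_mp + herd_eff[herd[k], 1] + year_eff[yi, 1] +
      seas_eff[cs, 1] + cfg$slope_htz_mp * htz[i] + a[i, 1] + e_mp
    ll <- pmin(pmax(round(stats::rnorm(nl, 290, 25)), 210), 330)
    tmp <- mp305 - MP305_SLOPE * (305 - ll)
    afc <- cfg$mu_afc + herd_eff[herd[k], 2] + year_eff[yi[1], 2] +
      seas_eff[cs[1], 2] + cfg$slope_htz_afc * htz[i] + a[i, 2] + e1[2]
    afc <- max(afc, 20)
    afc_col <- c(if (stats::runif(1) < cfg$p_afc) afc else NA_real_,
                 rep(NA_real_, nl - 1))
    rows[[k]] <- data.frame(animal = ped$animal[i],
                            herd = paste0("H", herd[k]),
                            year = year, month = month,
                            tmp = tmp, ll = ll, afc = afc_col,
                            true_afc = c(afc, rep(NA_real_, nl - 1)))
  }
  pheno <- do.call(rbind, rows)
  rownames(pheno) <- NULL
  truth <- list(G0 = cfg$G0, R0 = cfg$R0,
                h2_mp = cfg$h2_mp, h2_afc = cfg$h2_afc,
                rg = cfg$rg, re = cfg$re, a = a,
                herd_eff = herd_eff, year_eff = year_eff, seas_eff = seas_eff,
                liability = stats::setNames(pheno$true_afc[!is.na(pheno$true_afc)],
                                            pheno$animal[!is.na(pheno$true_afc)]))
  pheno$true_afc <- NULL
  list(phenotypes = pheno, truth = truth)
}

#' Simulate a complete synthetic herd
#'
#' Convenience wrapper: seeds the RNG from `cfg$seed`, simulates the pedigree
#' and the phenotypes, and returns both with the truth ledger.
#'
#' @param cfg a [sim_config()].
#' @return list with `ped`, `phenotypes`, `truth`.
#' @export
simulate_herd <- function(cfg = sim_config()) {
  set.seed(cfg$seed)
  ped <- simulate_pedigree(cfg)
  sim <- simulate_phenotypes(ped, cfg)
  list(ped = ped, phenotypes = sim$phenotypes, truth = sim$truth)
}

#' Write a simulated herd to delimited files
#'
#' Writes the pedigree, phenotype and truth-ledger files in the formats read
#' by [read_pedigree()] and [read_phenotypes()]. The truth ledger
#' (`truth.txt`) holds the generating parameters and per-animal true breeding
#' values for recovery checks.
#'
#' @param herd result of [simulate_herd()].
#' @param dir output directory (created if needed).
#' @return invisibly, the paths written.
#' @export
write_herd <- function(herd, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  pedf <- file.path(dir, "pedigree.csv")
  phef <- file.path(dir, "phenotypes.csv")
  trf <- file.path(dir, "truth.txt")
  ped <- herd$ped
  pd <- data.frame(animal = ped$animal,
                   sire = ifelse(is.na(ped$sire), "0", ped$sire),
                   dam = ifelse(is.na(ped$dam), "0", ped$dam),
                   murrah_sire = ped$murrah_sire, other_sire = ped$other_sire,
                   murrah_dam = ped$murrah_dam, other_dam = ped$other_dam)
  utils::write.csv(pd, pedf, row.names = FALSE, quote = FALSE)
  utils::write.csv(herd$phenotypes, phef, row.names = FALSE, quote = FALSE,
                   na = "")
  tr <- herd$truth
  con <- file(trf, "w")
  on.exit(close(con))
  writeLines(c(sprintf("h2_mp %.6f", tr$h2_mp),
               sprintf("h2_afc %.6f", tr$h2_afc),
               sprintf("rg %.6f", tr$rg),
               sprintf("re %.6f", tr$re),
               sprintf("G0 %.6f %.6f %.6f", tr$G0[1, 1], tr$G0[2, 2], tr$G0[1, 2]),
               sprintf("R0 %.6f %.6f %.6f", tr$R0[1, 1], tr$R0[2, 2], tr$R0[1, 2]),
               "animal a_mp a_afc"), con)
  utils::write.table(data.frame(rownames(tr$a), tr$a[, 1], tr$a[, 2]),
                     con, row.names = FALSE, col.names = FALSE, quote = FALSE)
  invisible(c(pedigree = pedf, phenotypes = phef, truth = trf))
}
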