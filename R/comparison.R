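#' Random subsample means of a posterior chain
#'
#' Draws `k` subsamples of `size` cycles from a chain (without replacement
#' within a subsample; subsamples are drawn independently, so they may
#' overlap) and returns the `k` subsample means. Used to build the
#' between-model heritability t-test.
#'
#' @param chain numeric vector of posterior draws.
#' @param k number of subsamples (default 30).
#' @param size draws per subsample (default 2,700).
#' @return numeric vector of `k` subsample means.
#' @export
subsample_means <- function(chain, k = 30, size = 2700) {
  if (size > length(chain))
    stop("subsample size (", size, ") exceeds chain length (", length(chain), ")")
  vapply(seq_len(k), function(i) mean(sample(chain, size)), numeric(1))
}

#' Welch t-test between two sets of subsample means
#'
#' Two-sample t-test with unequal variances comparing, e.g., the 30
#' heritability subsample means of Model 1 against those of Model 2.
#'
#' @param means_a,means_b numeric vectors (length >= 2 each).
#' @param alpha significance level (default 0.05).
#' @return list with `t`, `df`, `p`, `reject`.
#' @export
two_sample_t <- function(means_a, means_b, alpha = 0.05) {
  stopifnot(length(means_a) >= 2, length(means_b) >= 2)
  if (stats::sd(means_a) == 0 && stats::sd(means_b) == 0) {
    if (isTRUE(all.equal(mean(means_a), mean(means_b))))
      stop("both samples constant and equal; no test possible")
  }
  tt <- stats::t.test(means_a, means_b, var.equal = FALSE)
  list(t = unname(tt$statistic), df = unname(tt$parameter),
       p = tt$p.value, reject = tt$p.value < alpha)
}

#' Sire breeding-value report
#'
#' Extracts, for every sire with recorded progeny, the posterior mean and SD
#' of its breeding values for both traits, the progeny count, the prediction
#' accuracy `sqrt(1 - PEV / sigma2_a)` (PEV = posterior variance of the
#' breeding value, `sigma2_a` = posterior mean additive variance; clipped to
#' `[0, 1]`), and the selection-scenario memberships: scenario 1 = all sires
#' with recorded progeny, scenario 2 = sires with positive milk-production
#' breeding value, scenario 3 = sires with negative AFC breeding value.
#'
#' @param fit a `gibbs_fit` from [run_chain()].
#' @param ped the [pedigree()] used for the fit.
#' @param prep the `prep_data` used for the fit (defines which animals are
#'   recorded).
#' @return data.frame of class `ebv_report`, one row per sire.
#' @export
ebv_report <- function(fit, ped, prep) {
  stopifnot(inherits(fit, "gibbs_fit"), inherits(ped, "pedigree"))
  recorded <- unique(c(prep$mp$animal, prep$afc$animal))
  prog <- ped[ped$animal %in% recorded & !is.na(ped$sire), "sire"]
  cnt <- table(prog)
  sires <- names(cnt)
  ix <- match(sires, fit$ebv$animal)
  g_mp <- mean(fit$samples$g_mp)
  g_afc <- mean(fit$samples$g_afc)
  acc <- function(sd, s2) {
    pmin(pmax(sqrt(pmax(1 - sd^2 / s2, 0)), 0), 1)
  }
  out <- data.frame(animal = sires, n_progeny = as.integer(cnt),
                    ebv_mp = fit$ebv$ebv_mp[ix], sd_mp = fit$ebv$sd_mp[ix],
                    ebv_afc = fit$ebv$ebv_afc[ix], sd_afc = fit$ebv$sd_afc[ix])
  out$accuracy_mp <- acc(out$sd_mp, g_mp)
  out$accuracy_afc <- acc(out$sd_afc, g_afc)
  out$scenario_all <- TRUE
  out$scenario_mp_pos <- out$ebv_mp > 0
  out$scenario_afc_neg <- out$ebv_afc < 0
  class(out) <- c("ebv_report", "data.frame")
  out
}

scenario_subset <- function(report, scenario) {
  switch(scenario,
         all = report[report$scenario_all, , drop = FALSE],
         mp_pos = report[report$scenario_mp_pos, , drop = FALSE],
         afc_neg = report[report$scenario_afc_neg, , drop = FALSE],
         stop("unknown scenario: ", scenario))
}

#' Spearman rank correlations of sire breeding values across scenarios
#'
#' For each selection scenario (all sires with progeny, sires with positive
#' milk EBV, sires with negative AFC EBV), computes Spearman's rho (average
#' ranks for ties) between the two models within each trait and between the
#' two traits within each model. Scenario membership is taken from
#' `report_a` and the sire sets are intersected. Cells with fewer than 3
#' sires are reported as `NA`.
#'
#' @param report_a,report_b `ebv_report`s of the two models.
#' @return data.frame with columns `scenario`, `comparison`, `rho`, `n`.
#' @export
spearman_scenarios <- function(report_a, report_b) {
  common <- intersect(report_a$animal, report_b$animal)
  if (!setequal(report_a$animal, report_b$animal))
    warning("sire sets differ between models; using the intersection")
  if (!length(common)) stop("no common sires between the two reports")
  a <- report_a[match(common, report_a$animal), ]
  b <- report_b[match(common, report_b$animal), ]
  rows <- list()
  for (sc in c("all", "mp_pos", "afc_neg")) {
    keep <- switch(sc, all = a$scenario_all, mp_pos = a$scenario_mp_pos,
                   afc_neg = a$scenario_afc_neg)
    sa <- a[keep, ]; sb <- b[keep, ]
    rho <- function(x, y) {
      if (length(x) < 3) return(NA_real_)
      stats::cor(x, y, method = "spearman")
    }
    rows[[sc]] <- data.frame(
      scenario = sc,
      comparison = c("mp_between_models", "afc_between_models",
                     "mp_afc_model_a", "mp_afc_model_b"),
      rho = c(rho(sa$ebv_mp, sb$ebv_mp), rho(sa$ebv_afc, sb$ebv_afc),
              rho(sa$ebv_mp, sa$ebv_afc), rho(sb$ebv_mp, sb$ebv_afc)),
      n = nrow(sa))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Descriptive statistics of sire breeding values per scenario
#'
#' Mirrors the descriptive sire-table layout: per scenario and trait, the
#' number of sires, mean, SD, min, max, SD/mean ratio and mean accuracy.
#'
#' @param report an `ebv_report`.
#' @return data.frame with one row per scenario x trait.
#' @export
ebv_descriptives <- function(report) {
  rows <- list()
  for (sc in c("all", "mp_pos", "afc_neg")) {
    s <- scenario_subset(report, sc)
    if (!nrow(s)) next
    for (tr in c("mp", "afc")) {
      v <- s[[paste0("ebv_", tr)]]
      sdv <- if (length(v) > 1) stats::sd(v) else 0
      rows[[paste(sc, tr)]] <- data.frame(
        scenario = sc, trait = toupper(tr), n = nrow(s),
        mean = mean(v), sd = sdv, min = min(v), max = max(v),
        sd_over_mean = if (mean(v) != 0) sdv / mean(v) else NA_real_,
        accuracy = mean(s[[paste0("accuracy_", tr)]]))
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Compare heritability chains of two models by the subsample t-test
#'
#' Applies [subsample_means()] to the same parameter chain of two fitted
#' models and runs the Welch t-test on the two sets of subsample means.
#' Note the caveat: subsample means from a single chain are autocorrelated,
#' so the nominal t distribution is approximate; the procedure is reported
#' as specified.
#'
#' @param fit1,fit2 `gibbs_fit` objects.
#' @param parameter chain column to compare (default `"h2_afc"`).
#' @param k,size subsampling settings (defaults 30 and 2,700).
#' @param alpha significance level.
#' @return list with the two mean vectors and the t-test result.
#' @export
compare_heritability <- function(fit1, fit2, parameter = "h2_afc",
                                 k = 30, size = 2700, alpha = 0.05) {
  m1 <- subsample_means(fit1$samples[[parameter]], k = k, size = size)
  m2 <- subsample_means(fit2$samples[[parameter]], k = k, size = size)
  c(list(parameter = parameter, means_model1 = m1, means_model2 = m2),
    two_sample_t(m1, m2, alpha = alpha))
}
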