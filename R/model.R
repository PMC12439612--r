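#' Specify a bivariate animal model run
#'
#' Collects trait treatment, priors, chain settings and identification
#' choices for [run_chain()]. Model 1 treats age at first calving (AFC) as a
#' continuous Gaussian trait; Model 2 treats it as a dichotomous threshold
#' trait whose latent liability is sampled by data augmentation with the
#' threshold fixed at 0.
#'
#' Variance priors are inverse-Wisharts `IW(df = 3, scale =
#' prior_scale_frac * diag(vp))`, where `vp` is the *within
#' contemporary-group* phenotypic variance per trait (the liability
#' variance is taken as 1 for the threshold trait). The within-group scale
#' matters: the raw variance is dominated by the herd/year spread that the
#' fixed effects absorb, and an inverse-Wishart scaled by it is far from
#' weak. The default `prior_scale_frac = 0.5` puts the marginal prior
#' median near heritability 0.35 with a heavy right tail. Fixed effects
#' have flat priors on linear traits. On the threshold trait the
#' contemporary-group effects are treated as a random effect with its own
#' sampled variance (hyperprior `nu_cg_threshold`, `scale_cg_threshold`) and
#' the heterozygosity slope gets a proper normal prior
#' (`beta_var_threshold`): with herd-year-season cells holding only a
#' handful of binary records each, unpenalized cell effects make the
#' liability scale degenerate (the extreme-category problem), so pricing
#' them through an estimated variance is required for a well-behaved
#' posterior.
#'
#' @param model 1 (AFC linear) or 2 (AFC threshold).
#' @param total_cycles,burn_in,thin Gibbs chain settings in cycles. Defaults
#'   are the production settings 600,000 / 60,000 / 20 (27,000 saved
#'   samples); validation runs use much shorter chains.
#' @param seed integer RNG seed; identical seeds give bit-identical chains.
#' @param fix_afc_residual Model 2 identification: keep the liability
#'   residual variance fixed at 1, sampling the remaining residual
#'   parameters from their exact conditional under the inverse-Wishart
#'   (default). `FALSE` samples the residual (co)variance unconstrained;
#'   that liability scale is only weakly identified and wanders.
#' @param nu_g,nu_r inverse-Wishart degrees of freedom for the additive and
#'   residual priors.
#' @param prior_scale_frac multiple of the within-contemporary-group
#'   phenotypic variance used for the prior scale matrices.
#' @param beta_var_threshold prior variance of the threshold-trait
#'   heterozygosity slope (liability scale).
#' @param nu_cg_threshold,scale_cg_threshold scaled-inverse-chi-square
#'   hyperprior for the threshold-trait contemporary-group variance
#'   (defaults 4 and 2: prior mean 1 on the liability scale, weak).
#' @param warmup cycles at the start of the chain during which the
#'   (co)variance matrices are held at their starting values while location
#'   effects adapt to the data; defaults to half the burn-in, capped at 500.
#' @param fix_variances optional list `list(G0 = , R0 = )` fixing both
#'   covariance matrices (no covariance updates); used for mixed-model
#'   equation cross-checks.
#' @return an object of class `model_spec`.
#' @export
model_spec <- function(model = 1, total_cycles = 600000, burn_in = 60000,
                       thin = 20, seed = 1234,
                       fix_afc_residual = TRUE,
                       nu_g = 3, nu_r = 3, prior_scale_frac = 0.5,
                       beta_var_threshold = 4,
                       nu_cg_threshold = 4, scale_cg_threshold = 2,
                       warmup = NULL,
                       fix_variances = NULL) {
  if (is.null(warmup)) warmup <- min(500, burn_in %/% 2)
  stopifnot(model %in% c(1, 2), burn_in < total_cycles, thin >= 1,
            nu_g > 1, nu_r > 1, warmup <= burn_in)
  spec <- list(model = as.integer(model), total_cycles = as.integer(total_cycles),
               burn_in = as.integer(burn_in), thin = as.integer(thin),
               seed = as.integer(seed),
               fix_afc_residual = isTRUE(fix_afc_residual),
               nu_g = nu_g, nu_r = nu_r, prior_scale_frac = prior_scale_frac,
               beta_var_threshold = beta_var_threshold,
               nu_cg_threshold = nu_cg_threshold,
               scale_cg_threshold = scale_cg_threshold,
               warmup = as.integer(warmup),
               fix_variances = fix_variances)
  class(spec) <- "model_spec"
  spec
}

#' Build design structures for the sampler
#'
#' Maps prepared records to bivariate data rows: each milk-production record
#' is a row; an animal's AFC record is attached to its first milk row when
#' one exists, otherwise it becomes its own row. Every pedigree animal gets
#' a breeding-value slot whether or not it has records.
#'
#' @param prep a `prep_data` object from [prepare_dataset()].
#' @param ped the sorted [pedigree()] (must contain every record animal).
#' @param model 1 (AFC continuous) or 2 (AFC dichotomized; uses `afc_class`).
#' @return a list of parallel row vectors plus level counts, consumed by
#'   [run_chain()] and [mme_solve()].
#' @export
build_design <- function(prep, ped, model = 1) {
  stopifnot(inherits(prep, "prep_data"), inherits(ped, "pedigree"))
  idx <- attr(ped, "index")
  rec_animals <- unique(c(prep$mp$animal, prep$afc$animal))
  missing_ped <- setdiff(rec_animals, ped$animal)
  if (length(missing_ped))
    stop("record animals absent from pedigree: ",
         paste(missing_ped, collapse = ", "))
  if (model == 2 && (nrow(prep$afc) == 0L || anyNA(prep$afc$afc_class)))
    stop("model 2 requires AFC classes for all AFC records")

  nmp <- nrow(prep$mp)
  y_mp <- prep$mp$mp305
  mp_obs <- rep(1L, nmp)
  animal <- as.integer(idx[prep$mp$animal])
  cgmp <- prep$mp$cg_idx
  htz <- prep$mp$htz
  afc_code <- rep(0L, nmp)
  y_afc <- rep(0, nmp)
  cgafc <- rep(0L, nmp)

  first_row <- match(prep$afc$animal, prep$mp$animal)  # NA if no milk record
  for (k in seq_len(nrow(prep$afc))) {
    code <- if (model == 1) 1L else (if (prep$afc$afc_class[k] == 1L) 2L else 3L)
    val <- prep$afc$afc[k]
    r <- first_row[k]
    if (!is.na(r)) {
      afc_code[r] <- code
      y_afc[r] <- val
      cgafc[r] <- prep$afc$cg_idx[k]
    } else {
      y_mp <- c(y_mp, 0); mp_obs <- c(mp_obs, 0L)
      animal <- c(animal, as.integer(idx[prep$afc$animal[k]]))
      cgmp <- c(cgmp, 0L)
      htz <- c(htz, prep$afc$htz[k])
      afc_code <- c(afc_code, code); y_afc <- c(y_afc, val)
      cgafc <- c(cgafc, prep$afc$cg_idx[k])
    }
  }
  n_cgmp <- max(0L, prep$mp$cg_idx)
  n_cgafc <- if (nrow(prep$afc)) max(prep$afc$cg_idx) else 0L
  list(y_mp = y_mp, mp_obs = mp_obs, afc_code = afc_code, y_afc = y_afc,
       animal = animal, cgmp = as.integer(cgmp), cgafc = as.integer(cgafc),
       htz = htz, n_cgmp = as.integer(n_cgmp), n_cgafc = as.integer(n_cgafc),
       n_animals = nrow(ped), model = as.integer(model),
       animal_ids = ped$animal)
}

#' Run the Gibbs sampler for the bivariate animal model
#'
#' Executes the full Gibbs cycle — latent liabilities (Model 2), location
#' effects (contemporary groups, heterozygosity slopes, bivariate breeding
#' values shrunk through the sparse relationship-matrix inverse), additive
#' and residual covariance matrices — and returns the thinned post-burn-in
#' samples with derived heritabilities and correlations, plus posterior
#' means and SDs of every location effect.
#'
#' @param prep a `prep_data` from [prepare_dataset()].
#' @param ped the sorted [pedigree()].
#' @param spec a [model_spec()].
#' @return an object of class `gibbs_fit` with elements `samples`
#'   (data.frame: `cycle, g_mp, g_afc, g_cov, r_mp, r_afc, r_cov, h2_mp,
#'   h2_afc, rg, re`), `ebv` (per-animal posterior mean/SD per trait),
#'   `beta` (fixed-effect posterior summaries), `spec`, and `meta`.
#' @export
run_chain <- function(prep, ped, spec = model_spec()) {
  stopifnot(inherits(spec, "model_spec"))
  design <- build_design(prep, ped, model = spec$model)
  Ainv <- a_inverse(ped)
  run_chain_design(design, Ainv, spec)
}

# Lower-level entry point taking prebuilt design + A-inverse (reused by the
# MME cross-checks and by callers that run both models on one dataset).
run_chain_design <- function(design, Ainv, spec) {
  M <- methods::as(methods::as(Ainv, "generalMatrix"), "CsparseMatrix")
  threshold <- design$model == 2L

  # phenotypic scale = within-contemporary-group variance: the raw variance
  # is dominated by the herd/year spread that the fixed effects absorb, and
  # using it would make the "weak" prior strongly informative
  within_var <- function(y, grp) {
    if (length(y) < 2) return(1)
    res <- y - stats::ave(y, grp)
    df <- length(y) - length(unique(grp))
    if (df < 1) return(stats::var(y))
    sum(res^2) / df
  }
  mp_i <- design$mp_obs == 1L
  vp_mp <- within_var(design$y_mp[mp_i], design$cgmp[mp_i])
  afc_i <- design$afc_code == 1L
  vp_afc <- if (threshold) 1 else
    within_var(design$y_afc[afc_i], design$cgafc[afc_i])
  Vg <- diag(spec$prior_scale_frac * c(vp_mp, vp_afc))
  Vr <- Vg
  fixv <- !is.null(spec$fix_variances)
  G_init <- if (fixv) spec$fix_variances$G0 else diag(0.2 * c(vp_mp, vp_afc))
  R_init <- if (fixv) spec$fix_variances$R0 else diag(0.6 * c(vp_mp, vp_afc))
  beta_prec_afc <- if (threshold) 1 / spec$beta_var_threshold else 0

  set.seed(spec$seed)
  res <- .gibbs_animal(design$y_mp, design$mp_obs, design$afc_code,
                       design$y_afc, design$animal - 1L,
                       design$cgmp - 1L, design$cgafc - 1L, design$htz,
                       design$n_cgmp, design$n_cgafc, design$n_animals,
                       M@p, M@i, M@x,
                       spec$nu_g, Vg, spec$nu_r, Vr,
                       G_init, R_init,
                       0, beta_prec_afc,
                       spec$total_cycles, spec$burn_in, spec$thin,
                       threshold, spec$fix_afc_residual, fixv,
                       spec$nu_cg_threshold, spec$scale_cg_threshold,
                       spec$warmup, spec$seed)

  samples <- as.data.frame(res$samples)
  samples <- cbind(cycle = spec$burn_in + spec$thin * seq_len(nrow(samples)),
                   samples)
  ebv <- data.frame(animal = design$animal_ids,
                    ebv_mp = res$a_mean[, 1], sd_mp = res$a_sd[, 1],
                    ebv_afc = res$a_mean[, 2], sd_afc = res$a_sd[, 2])
  beta <- list(mp = data.frame(effect = c(paste0("cg", seq_len(design$n_cgmp)), "htz"),
                               mean = res$beta_mp_mean, sd = res$beta_mp_sd),
               afc = data.frame(effect = c(paste0("cg", seq_len(design$n_cgafc)), "htz"),
                                mean = res$beta_afc_mean, sd = res$beta_afc_sd))
  rb <- if (fixv) list(a = res$a_rb, beta_mp = res$beta_mp_rb,
                       beta_afc = res$beta_afc_rb) else NULL
  out <- list(samples = samples, ebv = ebv, beta = beta, rb = rb,
              spec = spec,
              meta = list(n_saved = res$n_saved,
                          n_rows = length(design$y_mp),
                          n_animals = design$n_animals,
                          n_cg_mp = design$n_cgmp, n_cg_afc = design$n_cgafc,
                          model = design$model))
  class(out) <- "gibbs_fit"
  out
}

#' @export
print.gibbs_fit <- function(x, ...) {
  cat("Bivariate animal model (Model ", x$meta$model,
      if (x$meta$model == 2) ", threshold AFC" else ", linear AFC",
      ")\n", sep = "")
  cat(" saved samples:", x$meta$n_saved,
      "| rows:", x$meta$n_rows, "| animals:", x$meta$n_animals, "\n")
  ps <- vapply(c("h2_mp", "h2_afc", "rg"), function(p)
    mean(x$samples[[p]]), numeric(1))
  cat(sprintf(" posterior means: h2_MP = %.3f, h2_AFC = %.3f, rg = %.3f\n",
              ps[1], ps[2], ps[3]))
  invisible(x)
}

#' Posterior summary table for a fitted model
#'
#' Summarizes the variance-component and derived-parameter chains in the
#' layout of a results table: posterior mean, SD, 95% interval (both the
#' quantile form and mean +/- 1.96 SD) and the Geweke convergence z-score.
#'
#' @param fit a `gibbs_fit`.
#' @return data.frame with one row per parameter.
#' @export
summary_table <- function(fit) {
  stopifnot(inherits(fit, "gibbs_fit"))
  pars <- c("g_mp", "g_afc", "g_cov", "r_mp", "r_afc", "r_cov",
            "h2_mp", "h2_afc", "rg", "re")
  do.call(rbind, lapply(pars, function(p) {
    x <- fit$samples[[p]]
    s <- posterior_summary(x)
    gz <- if (stats::sd(x) > 0) geweke_z(x)$z else NA_real_
    data.frame(parameter = p, mean = s$mean, sd = s$sd,
               q2.5 = s$ci_quantile[1], q97.5 = s$ci_quantile[2],
               lo_normal = s$ci_normal[1], hi_normal = s$ci_normal[2],
               geweke_z = gz)
  }))
}
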