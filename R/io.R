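#' Write / read posterior sample tables
#'
#' Chain files are plain delimited text, one row per saved cycle, with the
#' columns `cycle, g_mp, g_afc, g_cov, r_mp, r_afc, r_cov, h2_mp, h2_afc,
#' rg, re`.
#'
#' @param fit a `gibbs_fit`.
#' @param file output path.
#' @return invisibly, the path (`write_chain`) or the samples data.frame
#'   (`read_chain`).
#' @export
write_chain <- function(fit, file) {
  utils::write.csv(fit$samples, file, row.names = FALSE, quote = FALSE)
  invisible(file)
}

#' @rdname write_chain
#' @export
read_chain <- function(file) {
  utils::read.csv(file)
}

#' Prepare input files for analysis
#'
#' File-level wrapper over [prepare_dataset()]: reads the pedigree and
#' phenotype files, runs the full preparation pipeline and writes the
#' prepared record tables (`mp.csv`, `afc.csv`), the dropped-record log and
#' a metadata block (AFC threshold used, group counts) to `out_dir`.
#'
#' @param pedigree_file,phenotype_file input paths (see [read_pedigree()]
#'   and [read_phenotypes()]).
#' @param out_dir output directory, created if needed.
#' @param min_cg_size,afc_threshold passed to [prepare_dataset()].
#' @return the `prep_data` object, invisibly.
#' @export
pipeline_prepare <- function(pedigree_file, phenotype_file, out_dir,
                             min_cg_size = 3, afc_threshold = "median") {
  ped <- read_pedigree(pedigree_file)
  pheno <- read_phenotypes(phenotype_file)
  if (!nrow(pheno)) stop("phenotype file is empty")
  prep <- prepare_dataset(pheno, ped, min_cg_size = min_cg_size,
                          afc_threshold = afc_threshold)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(prep$mp, file.path(out_dir, "mp.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(prep$afc, file.path(out_dir, "afc.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(prep$dropped, file.path(out_dir, "dropped.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("afc_threshold %.6f", prep$meta$afc_threshold),
               sprintf("n_cg_mp %d", prep$meta$n_cg_mp),
               sprintf("n_cg_afc %d", prep$meta$n_cg_afc),
               sprintf("n_mp_records %d", nrow(prep$mp)),
               sprintf("n_afc_records %d", nrow(prep$afc)),
               sprintf("n_dropped %d", nrow(prep$dropped))),
             file.path(out_dir, "meta.txt"))
  message("prepared ", nrow(prep$mp), " MP and ", nrow(prep$afc),
          " AFC records; dropped ", nrow(prep$dropped))
  invisible(prep)
}

#' Run one model of the two-model workflow on input files
#'
#' Reads inputs, prepares the dataset, fits the requested model by Gibbs
#' sampling, and writes the chain (`chain.csv`), the sire report
#' (`sires.csv`), the posterior summary in results-table layout
#' (`summary.csv`, with Geweke z-scores; convergence failures are flagged
#' with a warning, not an abort) and a run manifest.
#'
#' @param model 1 or 2.
#' @param pedigree_file,phenotype_file input paths.
#' @param out_dir output directory.
#' @param spec a [model_spec()]; its `model` field is overridden by `model`.
#' @param min_cg_size,afc_threshold preparation settings.
#' @return the `gibbs_fit`, invisibly.
#' @export
pipeline_run <- function(model, pedigree_file, phenotype_file, out_dir,
                         spec = model_spec(), min_cg_size = 3,
                         afc_threshold = "median") {
  spec$model <- as.integer(model)
  ped <- read_pedigree(pedigree_file)
  pheno <- read_phenotypes(phenotype_file)
  prep <- prepare_dataset(pheno, ped, min_cg_size = min_cg_size,
                          afc_threshold = afc_threshold)
  fit <- run_chain(prep, ped, spec)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  write_chain(fit, file.path(out_dir, "chain.csv"))
  rep <- ebv_report(fit, ped, prep)
  utils::write.csv(rep, file.path(out_dir, "sires.csv"), row.names = FALSE,
                   quote = FALSE)
  st <- summary_table(fit)
  utils::write.csv(st, file.path(out_dir, "summary.csv"), row.names = FALSE,
                   quote = FALSE)
  bad <- st$parameter[!is.na(st$geweke_z) & abs(st$geweke_z) > 1.96]
  if (length(bad))
    warning("Geweke criterion flags possible non-convergence for: ",
            paste(bad, collapse = ", "))
  writeLines(c(sprintf("model %d", spec$model),
               sprintf("seed %d", spec$seed),
               sprintf("cycles %d burn_in %d thin %d", spec$total_cycles,
                       spec$burn_in, spec$thin),
               sprintf("n_saved %d", fit$meta$n_saved),
               sprintf("pedigree_md5 %s", unname(tools::md5sum(pedigree_file))),
               sprintf("phenotypes_md5 %s", unname(tools::md5sum(phenotype_file))),
               sprintf("timestamp %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out_dir, "manifest.txt"))
  invisible(fit)
}

#' Compare two fitted models from their output directories
#'
#' Reads the chains and sire reports written by [pipeline_run()] for Model 1
#' and Model 2 and writes the comparison tables: the heritability subsample
#' t-test, the Spearman scenario correlations and the per-scenario sire
#' descriptives, plus a manifest.
#'
#' @param dir_model1,dir_model2 output directories of the two runs.
#' @param out_dir where to write the comparison tables.
#' @param k,size subsample t-test settings (defaults 30 and 2,700).
#' @return list with `t_test`, `spearman`, `descriptives_model1`,
#'   `descriptives_model2`, invisibly.
#' @export
pipeline_compare <- function(dir_model1, dir_model2, out_dir,
                             k = 30, size = 2700) {
  ch1 <- read_chain(file.path(dir_model1, "chain.csv"))
  ch2 <- read_chain(file.path(dir_model2, "chain.csv"))
  rep1 <- utils::read.csv(file.path(dir_model1, "sires.csv"),
                          colClasses = c(animal = "character"))
  rep2 <- utils::read.csv(file.path(dir_model2, "sires.csv"),
                          colClasses = c(animal = "character"))
  class(rep1) <- class(rep2) <- c("ebv_report", "data.frame")
  if (!length(intersect(rep1$animal, rep2$animal)))
    stop("disjoint sire sets between the two models")
  m1 <- subsample_means(ch1$h2_afc, k = k, size = size)
  m2 <- subsample_means(ch2$h2_afc, k = k, size = size)
  tt <- two_sample_t(m1, m2)
  sp <- spearman_scenarios(rep1, rep2)
  d1 <- ebv_descriptives(rep1)
  d2 <- ebv_descriptives(rep2)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(data.frame(parameter = "h2_afc", t = tt$t, df = tt$df,
                              p = tt$p, reject = tt$reject),
                   file.path(out_dir, "t_test.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(sp, file.path(out_dir, "spearman.csv"), row.names = FALSE,
                   quote = FALSE)
  utils::write.csv(d1, file.path(out_dir, "descriptives_model1.csv"),
                   row.names = FALSE, quote = FALSE)
  utils::write.csv(d2, file.path(out_dir, "descriptives_model2.csv"),
                   row.names = FALSE, quote = FALSE)
  writeLines(c(sprintf("subsamples %d of %d", k, size),
               sprintf("timestamp %s", format(Sys.time(), "%Y-%m-%dT%H:%M:%S"))),
             file.path(out_dir, "manifest.txt"))
  invisible(list(t_test = tt, spearman = sp,
                 descriptives_model1 = d1, descriptives_model2 = d2))
}
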