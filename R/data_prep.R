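#' Standardize total milk production to a 305-day lactation
#'
#' Applies the fixed linear correction
#' `MP305 = TMP + 5.42705 * (305 - LL)`, where TMP is total milk production
#' (kg) over a lactation of LL days. The slope is the regression constant of
#' milk yield on lactation length adopted for this population; it is taken as
#' given and never re-estimated.
#'
#' @param tmp total milk production in kg (vectorized); must be positive.
#' @param ll lactation length in days (vectorized); must be positive.
#' @return 305-day standardized milk production in kg; `NA` where either
#'   input is missing.
#' @export
correct_mp305 <- function(tmp, ll) {
  if (any(tmp[!is.na(tmp)] <= 0)) stop("tmp must be positive")
  if (any(ll[!is.na(ll)] <= 0)) stop("ll must be positive")
  tmp + MP305_SLOPE * (305 - ll)
}

MP305_SLOPE <- 5.42705

#' Expected heterozygosity from breed composition
#'
#' Computes the heterosis covariate `HTZ = MS*OM + MM*OS`, the expected
#' fraction of loci carrying one Murrah and one other-breed allele, where MS
#' and OS are the Murrah and other-breed fractions contributed by the sire
#' and MM, OM those contributed by the dam. Ranges from 0 (both contributions
#' purebred alike) to 1 (F1 cross).
#'
#' @param ms,os Murrah and other-breed fraction from the sire; `ms + os = 1`.
#' @param mm,om Murrah and other-breed fraction from the dam; `mm + om = 1`.
#' @return heterozygosity in `[0, 1]` (vectorized).
#' @export
heterozygosity <- function(ms, om, mm, os) {
  v <- cbind(ms, om, mm, os)
  if (any(v < -1e-9 | v > 1 + 1e-9, na.rm = TRUE))
    stop("breed fractions must lie in [0, 1]")
  if (any(abs(ms + os - 1) > 1e-9, na.rm = TRUE) ||
      any(abs(mm + om - 1) > 1e-9, na.rm = TRUE))
    stop("parental breed fractions must sum to 1 (ms + os and mm + om)")
  ms * om + mm * os
}

#' Calving season from calving month
#'
#' Maps calving months to the four quarterly calving seasons used to absorb
#' regional climatic variation: Jan-Mar = 1, Apr-Jun = 2, Jul-Sep = 3,
#' Oct-Dec = 4.
#'
#' @param month integer month 1-12 (vectorized).
#' @return integer season code 1-4.
#' @export
calving_season <- function(month) {
  ok <- !is.na(month)
  if (any(month[ok] < 1 | month[ok] > 12 | month[ok] != floor(month[ok])))
    stop("month must be an integer in 1..12")
  as.integer((month - 1) %/% 3 + 1)
}

#' Dichotomize age at first calving at a threshold
#'
#' Splits AFC (months) into two classes for the threshold model: class 1 for
#' `afc <= threshold` (early calvers), class 2 otherwise. With
#' `threshold = "median"` the sample median of the non-missing values is used
#' and returned alongside the classes; the boundary value falls in class 1.
#'
#' @param afc numeric vector of ages at first calving in months; `NA` allowed.
#' @param threshold numeric threshold in months, or `"median"` (default).
#' @return list with `class` (integer 1/2, `NA` where `afc` missing) and
#'   `threshold` (the numeric threshold used).
#' @export
dichotomize_afc <- function(afc, threshold = "median") {
  if (all(is.na(afc))) stop("all AFC values are missing; nothing to dichotomize")
  if (identical(threshold, "median")) threshold <- stats::median(afc, na.rm = TRUE)
  stopifnot(is.numeric(threshold), length(threshold) == 1L)
  cls <- ifelse(is.na(afc), NA_integer_, ifelse(afc <= threshold, 1L, 2L))
  list(class = as.integer(cls), threshold = threshold)
}

#' Read a phenotype file
#'
#' Reads delimited phenotype records with columns
#' `animal,herd,year,month,tmp,ll,afc`; empty fields are missing. One row per
#' lactation record; AFC is carried on (at most) one row per cow.
#'
#' @param file path to a delimited text file with header.
#' @param sep field separator, default `","`.
#' @return a data.frame of phenotype records.
#' @export
read_phenotypes <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep, strip.white = TRUE,
                          colClasses = c("character", "character", "integer",
                                         "integer", "numeric", "numeric",
                                         "numeric"), na.strings = c("NA", ""))
  need <- c("animal", "herd", "year", "month", "tmp", "ll", "afc")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("phenotype file missing column(s): ", paste(miss, collapse = ", "))
  df
}

#' Form contemporary groups and drop undersized ones
#'
#' Assigns each record to the contemporary group defined by the combination
#' herd x year x calving season and removes every group (together with its
#' records) holding fewer than `min_size` records. Dropped records are
#' returned in a log with reasons, never silently discarded.
#'
#' @param records data.frame with columns `herd`, `year`, `cs` (and anything
#'   else, carried through).
#' @param min_size minimum records per group (default 3).
#' @return list with `records` (retained rows plus `cg` factor and integer
#'   `cg_idx`) and `dropped` (removed rows plus a `reason` column).
#' @export
build_contemporary_groups <- function(records, min_size = 3) {
  if (nrow(records) == 0L) {
    warning("no records supplied; empty contemporary-group set")
    return(list(records = cbind(records, cg = character(0), cg_idx = integer(0)),
                dropped = cbind(records, reason = character(0))))
  }
  key <- paste(records$herd, records$year, records$cs, sep = ":")
  sz <- table(key)
  keep <- key %in% names(sz)[sz >= min_size]
  retained <- records[keep, , drop = FALSE]
  dropped <- records[!keep, , drop = FALSE]
  if (nrow(dropped)) dropped$reason <- "contemporary group below minimum size"
  if (nrow(retained)) {
    f <- factor(key[keep], levels = unique(key[keep]))
    retained$cg <- as.character(f)
    retained$cg_idx <- as.integer(f)
  } else {
    warning("all contemporary groups below minimum size; empty dataset")
    retained$cg <- character(0)
    retained$cg_idx <- integer(0)
  }
  list(records = retained, dropped = dropped)
}

#' Prepare phenotype records for the bivariate animal model
#'
#' Runs the full pre-analysis pipeline: 305-day milk standardization,
#' heterozygosity covariate from the pedigree's breed composition, quarterly
#' calving seasons, herd x year x season contemporary groups with a
#' minimum-size filter (applied separately to the milk-production and AFC
#' record sets, since AFC is recorded once per cow while milk records
#' repeat), and dichotomization of AFC at the median (or a given threshold)
#' for the threshold model.
#'
#' @param pheno data.frame as returned by [read_phenotypes()].
#' @param ped a sorted [pedigree()]; every record animal must appear in it.
#' @param min_cg_size minimum records per contemporary group (default 3).
#' @param afc_threshold `"median"` (default) or a numeric threshold in months.
#' @return an object of class `prep_data`: list with `mp` (milk records:
#'   `animal, mp305, htz, cg, cg_idx`), `afc` (AFC records: `animal, afc,
#'   afc_class, htz, cg, cg_idx`), `dropped` (log of removed records with
#'   reasons), and `meta` (AFC threshold used, group counts).
#' @export
prepare_dataset <- function(pheno, ped, min_cg_size = 3,
                            afc_threshold = "median") {
  stopifnot(inherits(ped, "pedigree"))
  unknown <- setdiff(unique(pheno$animal), ped$animal)
  if (length(unknown))
    stop("phenotype records reference animals absent from the pedigree: ",
         paste(utils::head(unknown, 10), collapse = ", "),
         if (length(unknown) > 10) " ..." else "")
  idx <- attr(ped, "index")
  htz_all <- heterozygosity(ped$murrah_sire, ped$other_dam,
                            ped$murrah_dam, ped$other_sire)
  pheno$htz <- htz_all[idx[pheno$animal]]
  pheno$cs <- calving_season(pheno$month)

  dropped <- list()

  # -- milk production records ------------------------------------------------
  mp <- pheno[, c("animal", "herd", "year", "cs", "tmp", "ll", "htz")]
  bad_mp <- xor(is.na(mp$tmp), is.na(mp$ll))
  if (any(bad_mp)) {
    d <- mp[bad_mp, , drop = FALSE]
    d$reason <- "tmp and ll must be jointly present; record excluded from MP"
    dropped <- c(dropped, list(d))
  }
  mp <- mp[!is.na(mp$tmp) & !is.na(mp$ll) & !bad_mp, , drop = FALSE]
  mp$mp305 <- correct_mp305(mp$tmp, mp$ll)
  cg_mp <- build_contemporary_groups(mp, min_size = min_cg_size)
  if (nrow(cg_mp$dropped)) dropped <- c(dropped, list(cg_mp$dropped))
  mp <- cg_mp$records[, c("animal", "mp305", "htz", "cg", "cg_idx")]

  # -- AFC records (one per cow) ---------------------------------------------
  afc <- pheno[!is.na(pheno$afc), c("animal", "herd", "year", "cs", "afc", "htz")]
  if (anyDuplicated(afc$animal))
    stop("multiple AFC records for animal(s): ",
         paste(unique(afc$animal[duplicated(afc$animal)]), collapse = ", "))
  if (any(afc$afc <= 0)) stop("afc must be positive (months)")
  cg_afc <- build_contemporary_groups(afc, min_size = min_cg_size)
  if (nrow(cg_afc$dropped)) dropped <- c(dropped, list(cg_afc$dropped))
  afc <- cg_afc$records
  thr <- NA_real_
  if (nrow(afc)) {
    cl <- dichotomize_afc(afc$afc, threshold = afc_threshold)
    afc$afc_class <- cl$class
    thr <- cl$threshold
  } else {
    afc$afc_class <- integer(0)
  }
  afc <- afc[, c("animal", "afc", "afc_class", "htz", "cg", "cg_idx")]

  dropped <- if (length(dropped)) {
    do.call(rbind, lapply(dropped, function(d)
      data.frame(animal = d$animal, reason = d$reason)))
  } else data.frame(animal = character(0), reason = character(0))

  out <- list(mp = mp, afc = afc, dropped = dropped,
              meta = list(afc_threshold = thr,
                          n_cg_mp = length(unique(mp$cg_idx)),
                          n_cg_afc = length(unique(afc$cg_idx)),
                          min_cg_size = min_cg_size))
  class(out) <- "prep_data"
  out
}

#' @export
print.prep_data <- function(x, ...) {
  cat("Prepared dataset:\n",
      " MP records: ", nrow(x$mp), " in ", x$meta$n_cg_mp,
      " contemporary groups\n",
      " AFC records: ", nrow(x$afc), " in ", x$meta$n_cg_afc,
      " contemporary groups (threshold ",
      formatC(x$meta$afc_threshold, format = "f", digits = 2), " months)\n",
      " dropped records: ", nrow(x$dropped), "\n", sep = "")
  invisible(x)
}
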