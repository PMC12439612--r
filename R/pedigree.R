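#' Read a pedigree file
#'
#' Reads a delimited pedigree file with columns
#' `animal,sire,dam,murrah_sire,other_sire,murrah_dam,other_dam`.
#' A `0` or empty field in `sire`/`dam` denotes an unknown parent.
#' The four breed-composition columns give the Murrah and "other breed"
#' fractions contributed by the sire and by the dam; each parental pair must
#' sum to one.
#'
#' @param file path to a delimited text file with a header row.
#' @param sep field separator, default `","`.
#' @return a `pedigree` object (see [pedigree()]).
#' @export
read_pedigree <- function(file, sep = ",") {
  df <- utils::read.table(file, header = TRUE, sep = sep,
                          colClasses = c(rep("character", 3), rep("numeric", 4)),
                          strip.white = TRUE)
  need <- c("animal", "sire", "dam",
            "murrah_sire", "other_sire", "murrah_dam", "other_dam")
  miss <- setdiff(need, names(df))
  if (length(miss))
    stop("pedigree file missing column(s): ", paste(miss, collapse = ", "))
  pedigree(df$animal, df$sire, df$dam,
           murrah_sire = df$murrah_sire, other_sire = df$other_sire,
           murrah_dam = df$murrah_dam, other_dam = df$other_dam)
}

#' Construct and validate a pedigree
#'
#' Builds a `pedigree` object from animal, sire and dam identifiers plus
#' optional breed-composition fractions, validates it (unique ids, resolvable
#' parents, acyclic parentage, fractions summing to one) and sorts it
#' topologically so that every parent precedes its offspring. Ties are broken
#' by input order, so founders keep their relative order. Internal indices are
#' dense integers (column `idx`); `0` in the `sire`/`dam` identifier columns
#' (or `NA`/empty) marks an unknown parent, stored as index 0.
#'
#' @param animal,sire,dam character vectors of identifiers; `"0"`, `""` or
#'   `NA` in `sire`/`dam` means unknown.
#' @param murrah_sire,other_sire,murrah_dam,other_dam breed-composition
#'   fractions in `[0, 1]`; each sire (dam) pair must sum to 1. Defaults are
#'   purebred Murrah.
#' @return a `data.frame` of class `pedigree`, topologically ordered, with
#'   columns `animal`, `sire`, `dam` (ids), `sire_idx`, `dam_idx` (integer
#'   indices into the sorted pedigree, 0 = unknown) and the four fraction
#'   columns. The id-to-index map is `attr(, "index")`.
#' @export
pedigree <- function(animal, sire, dam,
                     murrah_sire = 1, other_sire = 0,
                     murrah_dam = 1, other_dam = 0) {
  animal <- as.character(animal)
  sire <- as.character(sire)
  dam <- as.character(dam)
  n <- length(animal)
  if (length(sire) != n || length(dam) != n)
    stop("animal, sire and dam must have equal length")
  if (anyDuplicated(animal))
    stop("duplicated animal id(s): ",
         paste(unique(animal[duplicated(animal)]), collapse = ", "))
  sire[is.na(sire) | sire == "" | sire == "0"] <- NA_character_
  dam[is.na(dam) | dam == "" | dam == "0"] <- NA_character_
  bad <- setdiff(stats::na.omit(c(sire, dam)), animal)
  if (length(bad))
    stop("parent id(s) not present as animals: ", paste(bad, collapse = ", "))
  frac <- function(x) rep_len(as.numeric(x), n)
  ms <- frac(murrah_sire); os <- frac(other_sire)
  md <- frac(murrah_dam);  od <- frac(other_dam)
  fr <- cbind(ms, os, md, od)
  if (any(fr < -1e-9 | fr > 1 + 1e-9, na.rm = TRUE))
    stop("breed-composition fractions must lie in [0, 1]")
  if (any(abs(ms + os - 1) > 1e-9, na.rm = TRUE) ||
      any(abs(md + od - 1) > 1e-9, na.rm = TRUE))
    stop("breed-composition fractions of each parental contribution must sum to 1")

  ord <- ped_toposort(animal, sire, dam)
  animal <- animal[ord]; sire <- sire[ord]; dam <- dam[ord]
  idx <- seq_len(n)
  names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  out <- data.frame(animal = animal, sire = sire, dam = dam,
                    sire_idx = as.integer(si), dam_idx = as.integer(di),
                    murrah_sire = ms[ord], other_sire = os[ord],
                    murrah_dam = md[ord], other_dam = od[ord],
                    stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "index") <- idx
  class(out) <- c("pedigree", "data.frame")
  out
}

# Kahn topological sort, stable in input order; reports one id on a cycle.
ped_toposort <- function(animal, sire, dam) {
  n <- length(animal)
  idx <- seq_len(n); names(idx) <- animal
  si <- ifelse(is.na(sire), 0L, idx[sire])
  di <- ifelse(is.na(dam), 0L, idx[dam])
  indeg <- integer(n)
  children <- vector("list", n)
  for (i in seq_len(n)) {
    for (p in c(si[i], di[i])) {
      if (p > 0L) {
        indeg[i] <- indeg[i] + 1L
        children[[p]] <- c(children[[p]], i)
      }
    }
  }
  out <- integer(0)
  ready <- which(indeg == 0L)           # ascending = input order
  while (length(ready)) {
    v <- ready[1L]; ready <- ready[-1L]
    out <- c(out, v)
    ch <- children[[v]]
    if (length(ch)) {
      indeg[ch] <- indeg[ch] - 1L
      newly <- ch[indeg[ch] == 0L]
      if (length(newly)) ready <- sort(c(ready, newly))
    }
  }
  if (length(out) < n) {
    left <- setdiff(seq_len(n), out)
    stop("pedigree contains a parentage cycle involving animal '",
         animal[left[1L]], "'")
  }
  out
}

#' Validate and topologically sort a pedigree
#'
#' Re-validates an existing `pedigree` (or a data frame in the same layout)
#' and returns it in parent-before-offspring order. Mostly useful after
#' manual edits; [pedigree()] already sorts on construction.
#'
#' @param ped a `pedigree` or data frame with `animal`, `sire`, `dam` columns.
#' @return a sorted `pedigree` object.
#' @export
ped_sort <- function(ped) {
  stopifnot(is.data.frame(ped))
  pedigree(ped$animal, ped$sire, ped$dam,
           murrah_sire = if (is.null(ped$murrah_sire)) 1 else ped$murrah_sire,
           other_sire = if (is.null(ped$other_sire)) 0 else ped$other_sire,
           murrah_dam = if (is.null(ped$murrah_dam)) 1 else ped$murrah_dam,
           other_dam = if (is.null(ped$other_dam)) 0 else ped$other_dam)
}

is_sorted_ped <- function(ped) {
  inherits(ped, "pedigree") &&
    all(ped$sire_idx < seq_len(nrow(ped))) &&
    all(ped$dam_idx < seq_len(nrow(ped)))
}

assert_sorted <- function(ped) {
  if (!is_sorted_ped(ped))
    stop("expected a sorted 'pedigree' object; see pedigree() / ped_sort()")
}

#' Numerator relationship matrix (tabular method)
#'
#' Builds the dense additive (numerator) relationship matrix A by the tabular
#' method: `A[i,i] = 1 + F_i` with `F_i = A[s,d]/2`, and
#' `A[i,j] = (A[j,s] + A[j,d])/2` for `j < i`, unknown parents contributing
#' zero. Quadratic in the number of animals; intended for moderate pedigrees
#' and as the brute-force cross-check for [a_inverse()].
#'
#' @param ped a sorted `pedigree`.
#' @return a symmetric positive-definite matrix with animal ids as dimnames.
#' @export
a_matrix <- function(ped) {
  assert_sorted(ped)
  n <- nrow(ped)
  A <- matrix(0, n, n, dimnames = list(ped$animal, ped$animal))
  s <- ped$sire_idx; d <- ped$dam_idx
  for (i in seq_len(n)) {
    A[i, i] <- 1 + if (s[i] > 0L && d[i] > 0L) 0.5 * A[s[i], d[i]] else 0
    if (i > 1L) {
      j <- seq_len(i - 1L)
      aij <- 0.5 * ((if (s[i] > 0L) A[j, s[i]] else 0) +
                    (if (d[i] > 0L) A[j, d[i]] else 0))
      A[j, i] <- aij
      A[i, j] <- aij
    }
  }
  A
}

#' Inbreeding coefficients (Meuwissen-Luo)
#'
#' Computes the inbreeding coefficient of every animal with the
#' Meuwissen-Luo algorithm, which traces each animal's ancestry without
#' forming A. `F_i = A[sire, dam]/2`; animals with an unknown parent have
#' `F = 0` (unknown parents are taken as unrelated base animals).
#'
#' @param ped a sorted `pedigree`.
#' @return numeric vector of inbreeding coefficients, named by animal id.
#' @export
inbreeding <- function(ped) {
  assert_sorted(ped)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  FF <- numeric(n)
  Dv <- numeric(n)   # Mendelian-sampling variance scale d_i
  for (i in seq_len(n)) {
    # -1 encodes the dropped term for an unknown parent: d becomes 0.75 or 1
    Fs <- if (s[i] > 0L) FF[s[i]] else -1
    Fd <- if (d[i] > 0L) FF[d[i]] else -1
    Dv[i] <- 0.5 - 0.25 * (Fs + Fd)
    if (s[i] == 0L || d[i] == 0L) { FF[i] <- 0; next }
    # A_ii = d_i + sum_j L_j^2 d_j over ancestors j, with L the averaged
    # parental path vector; F_i = A_ii - 1.
    L <- numeric(i - 1L)
    L[s[i]] <- L[s[i]] + 0.5
    L[d[i]] <- L[d[i]] + 0.5
    acc <- 0
    for (j in (i - 1L):1L) {
      if (L[j] == 0) next
      acc <- acc + L[j] * L[j] * Dv[j]
      if (s[j] > 0L) L[s[j]] <- L[s[j]] + 0.5 * L[j]
      if (d[j] > 0L) L[d[j]] <- L[d[j]] + 0.5 * L[j]
    }
    FF[i] <- Dv[i] + acc - 1
  }
  names(FF) <- ped$animal
  FF
}

#' Sparse inverse of the relationship matrix (Henderson rules)
#'
#' Builds the sparse inverse of the numerator relationship matrix directly
#' from the pedigree using Henderson's rules, with Mendelian-sampling
#' variances `d_i = 1 - 0.25 (1 + F_s) - 0.25 (1 + F_d)` (a term is dropped
#' when the corresponding parent is unknown). Inbreeding coefficients come
#' from [inbreeding()]; set `inbreeding = FALSE` to use the classical
#' `F = 0` rules, e.g. to cross-check against simpler oracles.
#'
#' @param ped a sorted `pedigree`.
#' @param inbreeding account for inbreeding in the Mendelian-sampling
#'   variances (default `TRUE`).
#' @return a symmetric sparse matrix (`Matrix::dsCMatrix`) equal to
#'   `solve(a_matrix(ped))`.
#' @export
a_inverse <- function(ped, inbreeding = TRUE) {
  assert_sorted(ped)
  n <- nrow(ped)
  s <- ped$sire_idx; d <- ped$dam_idx
  FF <- if (inbreeding) pedgibbs::inbreeding(ped) else numeric(n)
  ii <- integer(9L * n); jj <- integer(9L * n); xx <- numeric(9L * n)
  k <- 0L
  put <- function(a, b, v) {
    k <<- k + 1L; ii[k] <<- a; jj[k] <<- b; xx[k] <<- v
  }
  for (i in seq_len(n)) {
    di <- 1 - (if (s[i] > 0L) 0.25 * (1 + FF[s[i]]) else 0) -
              (if (d[i] > 0L) 0.25 * (1 + FF[d[i]]) else 0)
    al <- 1 / di
    put(i, i, al)
    ps <- c(s[i], d[i]); ps <- ps[ps > 0L]
    for (p in ps) {
      put(i, p, -al / 2); put(p, i, -al / 2)
    }
    if (length(ps)) {
      for (p1 in ps) for (p2 in ps) put(p1, p2, al / 4)
    }
  }
  ii <- ii[seq_len(k)]; jj <- jj[seq_len(k)]; xx <- xx[seq_len(k)]
  M <- Matrix::sparseMatrix(i = ii, j = jj, x = xx, dims = c(n, n),
                            dimnames = list(ped$animal, ped$animal))
  methods::as(Matrix::forceSymmetric(M), "symmetricMatrix")
}
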