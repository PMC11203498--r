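# Evaluation arithmetic: Valid / Unique@k / Novel, the 1-Wasserstein
# property-distribution distance, physicochemical profiling against the
# good drug-like ranges, and pXC50 activity classes.

#' Fraction of valid molecules
#'
#' `Valid = n(P) / n(G)`: validity means the string parses as a molecule in
#' the cheminformatics toolkit (syntax and valence). The empty string parses
#' as the zero-atom molecule and counts as valid, so any set produced by
#' SELFIES decoding scores exactly 1.
#'
#' @param generated Character vector of SMILES strings (nonempty).
#' @return Scalar fraction in `[0, 1]`; the valid subset (canonical SMILES)
#'   is attached as attribute `"valid_set"`.
#' @export
valid_fraction <- function(generated) {
  if (length(generated) == 0L) stop("empty generation set")
  cc <- chem_canonicalize(generated)
  frac <- mean(cc$valid)
  structure(frac, valid_set = cc$canonical[cc$valid])
}

#' Fraction of unique molecules in a size-c subsample
#'
#' `Unique = n(U) / n(S)`: `S` is a seeded without-replacement subsample of
#' the valid set of size `c` (1000 and 10,000 in the reference protocol),
#' and `U` deduplicates `S` by canonical SMILES.
#'
#' @param valid_set Character vector of valid SMILES.
#' @param c Subsample size; an error names the shortfall when
#'   `length(valid_set) < c`.
#' @param seed Subsampling seed.
#' @param canonical Set to `TRUE` when `valid_set` is already canonical to
#'   skip re-canonicalization.
#' @return Scalar fraction in `(0, 1]`.
#' @export
unique_fraction <- function(valid_set, c = 1000L, seed = 1L,
                            canonical = FALSE) {
  if (length(valid_set) < c) {
    stop("valid set has ", length(valid_set), " molecules; ", c,
         " required for Unique@", c)
  }
  s <- with_seed(seed, sample(valid_set, c))
  if (!canonical) s <- chem_canonicalize(s)$canonical
  length(unique(s)) / c
}

#' Fraction of novel molecules
#'
#' `Novel = n(Z) / n(P)` with `Z = P \ X`: the fraction of the generated
#' valid set not present in the training set, both compared by canonical
#' SMILES (so equivalent SMILES spellings never count as novel).
#'
#' @param valid_set Character vector of valid SMILES (nonempty).
#' @param training_set Character vector of training SMILES.
#' @param canonical `TRUE` when both sides are already canonical.
#' @return Scalar fraction in `[0, 1]`.
#' @export
novel_fraction <- function(valid_set, training_set, canonical = FALSE) {
  if (length(valid_set) == 0L) stop("empty valid set")
  if (!canonical) {
    valid_set <- chem_canonicalize(valid_set)$canonical
    training_set <- chem_canonicalize(training_set)$canonical
  }
  mean(!valid_set %in% training_set)
}

#' Empirical 1-Wasserstein distance between two samples
#'
#' The earth-mover's distance between the two empirical distributions:
#' the integral of `|F_a - F_b|` over the merged support. For equal sample
#' sizes this reduces to the mean absolute difference of the sorted samples.
#'
#' @param a,b Nonempty numeric samples.
#' @return Nonnegative distance.
#' @export
wasserstein_1d <- function(a, b) {
  if (length(a) == 0L || length(b) == 0L) stop("empty sample")
  stopifnot(all(is.finite(a)), all(is.finite(b)))
  z <- sort(c(a, b))
  if (length(z) == 2L) return(abs(a - b))
  gaps <- diff(z)
  grid <- z[-length(z)]
  Fa <- stats::ecdf(a)(grid)
  Fb <- stats::ecdf(b)(grid)
  sum(abs(Fa - Fb) * gaps)
}

#' Physicochemical property profile
#'
#' Toolkit-computed descriptors per molecule: molecular weight (Da), TPSA
#' (A^2), LogP, hydrogen-bond donors/acceptors, QED (0-1) and the synthetic
#' accessibility score (1 easy - 10 hard).
#'
#' @param smiles Character vector of parseable SMILES; a parse failure is an
#'   error.
#' @return Tibble with columns `smiles`, `mw`, `tpsa`, `logp`, `hbd`,
#'   `hba`, `qed`, `sa`.
#' @export
property_profile <- function(smiles) {
  pr <- chem_properties(smiles)
  if (any(!pr$valid)) {
    stop("unparsable molecule(s): ",
         paste(utils::head(smiles[!pr$valid], 5), collapse = ", "))
  }
  dplyr::select(pr, -"valid")
}

# good drug-like ranges per property (closed intervals)
.mg_good_ranges <- tibble::tibble(
  property = c("mw", "tpsa", "logp", "hbd", "hba", "qed", "sa"),
  lower = c(200, 20, -1, 0, 0, 0.4, 1),
  upper = c(500, 130, 6, 5, 10, 1, 5)
)

#' Percentage of molecules inside the good drug-like ranges
#'
#' For each of the seven properties, the percentage of profiles inside the
#' closed interval: MW in \[200, 500\], TPSA in \[20, 130\], LogP in
#' \[-1, 6\], HBD in \[0, 5\], HBA in \[0, 10\], QED in \[0.4, 1\],
#' SA in \[1, 5\].
#'
#' @param profiles Profile tibble from [property_profile()] (nonempty).
#' @return Tibble with columns `property`, `lower`, `upper`,
#'   `percent_in_range`.
#' @export
good_range_report <- function(profiles) {
  stopifnot(nrow(profiles) >= 1L)
  dplyr::mutate(
    .mg_good_ranges,
    percent_in_range = purrr::map2_dbl(.data$property, seq_along(.data$property),
      function(pn, i) {
        v <- profiles[[pn]]
        100 * mean(v >= .mg_good_ranges$lower[i] & v <= .mg_good_ranges$upper[i])
      })
  )
}

#' Classify pXC50 activity
#'
#' `low` below 6, `middle` in \[6, 7), `high` in \[7, 8), `ultra-high` at 8
#' and above (left-closed intervals). `NA`/non-finite input is an error.
#'
#' @param pxc50 Numeric vector of predicted pXC50 values.
#' @return Factor with levels low < middle < high < ultra-high.
#' @export
classify_activity <- function(pxc50) {
  if (any(!is.finite(pxc50))) stop("pXC50 values must be finite")
  cut(pxc50, breaks = c(-Inf, 6, 7, 8, Inf),
      labels = c("low", "middle", "high", "ultra-high"),
      right = FALSE)
}

#' Full evaluation report for a generated set
#'
#' Computes Valid, Unique@k (for every `k` not exceeding the valid-set
#' size), Novel against the training set, per-property 1-Wasserstein
#' distances against a reference set, the good-range table and the activity
#' class histogram (when pXC50 predictions are supplied).
#'
#' @param generated Tibble with a `smiles` column (e.g. from [generate()]).
#' @param training Tibble with the training `smiles`.
#' @param reference Optional tibble of reference molecules for the property
#'   comparison (defaults to `training`).
#' @param unique_k Subsample sizes for Unique@k.
#' @param pxc50 Optional numeric vector of predicted activities for
#'   `generated`.
#' @param seed Seed for the Unique@k subsamples.
#' @return List of class `mg_report`.
#' @export
evaluate_generation <- function(generated, training, reference = NULL,
                                unique_k = c(1000L, 10000L), pxc50 = NULL,
                                seed = 1L) {
  stopifnot("smiles" %in% names(generated), "smiles" %in% names(training))
  if (is.null(reference)) reference <- training
  vf <- valid_fraction(generated$smiles)
  valid_set <- attr(vf, "valid_set")
  uq <- purrr::map_dbl(
    purrr::set_names(unique_k, paste0("unique_at_", unique_k)),
    function(k) {
      if (length(valid_set) < k) NA_real_
      else unique_fraction(valid_set, k, seed = seed, canonical = TRUE)
    })
  train_canon <- chem_canonicalize(training$smiles)
  nv <- novel_fraction(valid_set, train_canon$canonical[train_canon$valid],
                       canonical = TRUE)
  gen_prof <- property_profile(generated$smiles[generated$smiles != ""])
  ref_prof <- property_profile(reference$smiles)
  wd <- purrr::map_dbl(
    purrr::set_names(c("mw", "tpsa", "logp", "qed", "sa", "hbd", "hba")),
    function(pn) wasserstein_1d(gen_prof[[pn]], ref_prof[[pn]])
  )
  out <- list(
    valid = as.numeric(vf),
    unique_at = uq,
    novel = nv,
    wasserstein = wd,
    good_ranges = good_range_report(gen_prof),
    n_generated = nrow(generated)
  )
  if (!is.null(pxc50)) {
    out$activity_classes <- table(classify_activity(pxc50))
  }
  structure(out, class = "mg_report")
}

#' @export
print.mg_report <- function(x, ...) {
  cat("<mg_report> n =", x$n_generated, "\n")
  cat("  Valid:", format(x$valid, digits = 4), "\n")
  for (k in names(x$unique_at)) {
    cat("  ", k, ": ", format(x$unique_at[[k]], digits = 4), "\n", sep = "")
  }
  cat("  Novel:", format(x$novel, digits = 4), "\n")
  cat("  Wasserstein (vs reference):\n")
  for (pn in names(x$wasserstein)) {
    cat("    ", pn, ": ", format(x$wasserstein[[pn]], digits = 4), "\n",
        sep = "")
  }
  invisible(x)
}
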