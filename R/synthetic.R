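# Synthetic data: desk-scale stand-ins for a drug-like pre-training corpus
# and small target-labelled fine-tuning sets. Molecules are drawn directly
# in SELFIES token space, so every record is valid by construction; targets
# differ by boosted probability mass on disjoint preferred-token sets, which
# gives conditioning-recovery and QSAR tests a closed-form signal.

#' Default target profiles
#'
#' Three targets with disjoint preferred tokens (nitrogen-, oxygen- and
#' sulfur-flavoured chemistries), probability-mass multiplier `bias`, and
#' set sizes 300/600/150 — preserving the small-fine-tuning-set regime of a
#' few-hundred to a few-thousand molecules per protein against a much larger
#' unconditional corpus.
#'
#' @param bias Probability-mass multiplier (>= 1) applied to each preferred
#'   token when sampling; `bias = 1` makes all targets identical (uniform).
#' @return Tibble with columns `target_id`, `preferred` (list-column of
#'   token sets), `bias`, `n_molecules`.
#' @export
target_profiles <- function(bias = 6) {
  stopifnot(bias >= 1)
  tibble::tibble(
    target_id = 1:3,
    preferred = list(c("[N]", "[=N]"), c("[O]", "[=O]"), c("[S]", "[=S]")),
    bias = bias,
    n_molecules = c(300L, 600L, 150L)
  )
}

.mg_token_weights <- function(alphabet, preferred, bias) {
  wts <- rep(1, length(alphabet))
  wts[alphabet %in% preferred] <- bias
  wts / sum(wts)
}

# draw token strings and redraw the rare ones that decode to the empty
# molecule (no atom token applies), so every record is a nonempty molecule
.mg_sample_selfies <- function(n, length_range, alphabet, weights) {
  if (!any(alphabet %in% .mg_atom_tokens)) {
    stop("alphabet contains no atom tokens; every draw would be empty")
  }
  draw <- function(k) {
    lens <- sample(seq(length_range[1], length_range[2]), k, replace = TRUE)
    vapply(lens, function(L) {
      paste(sample(alphabet, L, replace = TRUE, prob = weights), collapse = "")
    }, character(1))
  }
  out <- draw(n)
  repeat {
    empty <- which(selfies_to_smiles(out) == "")
    if (length(empty) == 0L) break
    out[empty] <- draw(length(empty))
  }
  out
}

.mg_assign_split <- function(n, train_frac = 0.9) {
  n_train <- round(n * train_frac)
  c(rep("train", n_train), rep("valid", n - n_train))[sample.int(n)]
}

#' Generate a synthetic unconditional corpus
#'
#' `n` molecules with token lengths uniform on `length_range` and tokens
#' i.i.d. uniform on `alphabet`, decoded to SMILES through the codec (hence
#' 100% valid), split 9:1 into train/valid. Identical seeds give
#' byte-identical datasets.
#'
#' @param n Number of molecules.
#' @param length_range Integer pair, inclusive token-length bounds.
#' @param alphabet Chemical token set (default [selfies_alphabet()]).
#' @param seed RNG seed.
#' @return Tibble with columns `selfies`, `smiles`, `target` (all 0),
#'   `split`.
#' @export
generate_corpus <- function(n, length_range = c(6L, 24L),
                            alphabet = selfies_alphabet(), seed = 1L) {
  stopifnot(n >= 1L, length(alphabet) >= 1L,
            length_range[1] >= 1L, length_range[2] >= length_range[1])
  with_seed(seed, {
    selfies <- .mg_sample_selfies(n, length_range, alphabet,
                                  rep(1 / length(alphabet), length(alphabet)))
    split <- .mg_assign_split(n)
    tibble::tibble(selfies = selfies,
                   smiles = selfies_to_smiles(selfies),
                   target = 0L, split = split)
  })
}

#' Synthetic pXC50 activity label
#'
#' A deterministic composition signal plus Gaussian noise:
#' `pXC50 = 4 + 6 * f + N(0, noise_sd)` clipped to `[4, 10]`, where `f` is
#' the fraction of the decoded molecule's heavy atoms contributed by the
#' profile's preferred atom tokens (their elements). Defining `f` on the
#' decoded structure rather than the raw token string makes the label a
#' pure function of the molecule, so a structure-based QSAR model can
#' recover it exactly at zero noise. The label is monotone in `f`, anchored
#' at 4 (no preferred atoms) and 10 (all atoms preferred), with `f = 0.5`
#' on the boundary of the "high" activity class.
#'
#' @param selfies Character vector of SELFIES strings.
#' @param preferred Character vector of preferred atom tokens (e.g.
#'   `c("[N]", "[=N]")`, read as element N).
#' @param noise_sd Standard deviation of the additive noise (>= 0).
#' @return Numeric vector of pXC50 values. Draws from the current RNG
#'   stream; seed externally for reproducibility.
#' @export
synthetic_activity <- function(selfies, preferred, noise_sd = 0) {
  stopifnot(noise_sd >= 0)
  elements <- unique(unlist(lapply(preferred, function(tok) {
    at <- .mg_parse_atom_token(tok)
    if (is.null(at)) character() else at$element
  })))
  f <- vapply(selfies, function(s) {
    st <- .mg_new_state()
    .mg_derive(split_selfies(s), st, 0L)
    if (length(st$element) == 0L) 0 else mean(st$element %in% elements)
  }, numeric(1), USE.NAMES = FALSE)
  pmin(10, pmax(4, 4 + 6 * f + stats::rnorm(length(f), 0, noise_sd)))
}

#' Generate target-labelled fine-tuning sets
#'
#' For each profile, molecules are sampled with the preferred tokens'
#' probability mass multiplied by `bias` (renormalized), labelled with
#' [synthetic_activity()], split 9:1 per target, and concatenated.
#'
#' @param profiles Profile tibble as from [target_profiles()]; `target_id`
#'   must be distinct.
#' @param length_range Token-length bounds.
#' @param alphabet Chemical token set.
#' @param noise_sd Activity noise standard deviation.
#' @param seed RNG seed.
#' @return Tibble with `selfies`, `smiles`, `target`, `pxc50`, `split`.
#' @export
generate_target_sets <- function(profiles = target_profiles(),
                                 length_range = c(6L, 24L),
                                 alphabet = selfies_alphabet(),
                                 noise_sd = 0.3, seed = 1L) {
  if (anyDuplicated(profiles$target_id)) {
    stop("duplicate target_id in profiles")
  }
  with_seed(seed, {
    out <- lapply(seq_len(nrow(profiles)), function(i) {
      pr <- profiles[i, ]
      wts <- .mg_token_weights(alphabet, pr$preferred[[1]], pr$bias)
      selfies <- .mg_sample_selfies(pr$n_molecules, length_range, alphabet, wts)
      tibble::tibble(
        selfies = selfies,
        smiles = selfies_to_smiles(selfies),
        target = as.integer(pr$target_id),
        pxc50 = synthetic_activity(selfies, pr$preferred[[1]], noise_sd),
        split = .mg_assign_split(pr$n_molecules)
      )
    })
    dplyr::bind_rows(out)
  })
}

#' Chemical-token frequency histogram
#'
#' Empirical frequency of each alphabet token over a set of SELFIES strings;
#' the unit of comparison for conditioning-recovery checks.
#'
#' @param selfies Character vector of SELFIES strings.
#' @param alphabet Token universe for the histogram.
#' @return Named numeric vector of frequencies summing to 1.
#' @export
token_histogram <- function(selfies, alphabet = selfies_alphabet()) {
  toks <- unlist(lapply(selfies, split_selfies))
  toks <- toks[toks %in% alphabet]
  if (length(toks) == 0L) stop("no alphabet tokens found")
  tab <- table(factor(toks, levels = alphabet))
  as.numeric(tab) / sum(tab) -> fr
  stats::setNames(fr, alphabet)
}

#' Total-variation distance between two histograms
#'
#' @param p,q Frequency vectors over the same support.
#' @return `0.5 * sum(|p - q|)`.
#' @export
total_variation <- function(p, q) {
  stopifnot(length(p) == length(q))
  0.5 * sum(abs(p - q))
}
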