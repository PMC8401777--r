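# Deterministic synthetic data: an abstract two-fingerprint worked example
# for the cross-term decomposition, and a SMILES-level generator of analog
# series with planted activity cliffs so the whole pipeline can be exercised
# without any external data.

#' Worked-example fingerprint pair for the cross-term decomposition
#'
#' An abstract feature universe with three core and three substituent
#' features. The test instance carries core features \{1, 3\} and all three
#' substituent features; the support vector carries all three core features
#' and substituent features \{2, 3\}. Both Tanimoto factors are 2/3, the
#' MMP kernel is 4/9, and each of the four shared cross-terms is 1/9. No
#' chemistry back-map is attached.
#'
#' @return list with elements `support` and `test`, both `mmp_fp`.
#' @examples
#' fx <- fig5_fixture()
#' mmp_kernel(fx$support, fx$test)  # 4/9
#' @export
fig5_fixture <- function() {
  list(support = new_mmp_fp(core = c(1, 2, 3), sub = c(2, 3)),
       test = new_mmp_fp(core = c(1, 3), sub = c(1, 2, 3)))
}

# built-in drug-like scaffolds; %s is the variable position. Chosen so that
# the single-cut fragmenter recovers the scaffold core deterministically and
# so ring-bond numbering never clashes with ring substituents.
.scaffolds <- c(
  "Oc1ccc(%s)cc1",
  "Nc1ccc(%s)cc1C",
  "O=C(N)c1ccc(%s)cc1",
  "Clc1cccc(%s)c1O",
  "O=S(=O)(N)c1ccc(%s)cc1",
  "Cc1nc2ccccc2n1%s",
  "O=C(O)c1cc(%s)ccc1N",
  "Fc1ccc2ccc(%s)cc2c1",
  "O=C(C)Nc1ccc(%s)cc1F",
  "Cc1oc(%s)cc1C(=O)N",
  "Nc1ncc(%s)cn1",
  "O=C(NC)c1csc(%s)c1"
)

# Neutral substituents are chosen pairwise prefix-free at the attachment
# point (distinct first atom or distinct branching right at the attachment),
# so no compound pair within a series shares a core larger than the
# scaffold itself and every pair lands in the scaffold's series under the
# maximum-core rule.
.neutral_subs <- c("C", "CC", "C(C)C", "C(C)(C)C", "OC", "N(C)C",
                   "Cl", "Br", "F", "C(F)(F)F")

#' Specification of a planted-cliff synthetic data set
#'
#' Describes analog series in which one designated substituent raises the
#' potency by `delta_strong` log units while all other substituents only
#' draw Gaussian jitter, so pairs involving the designated substituent are
#' activity cliffs with near-certainty and all other pairs are non-cliffs.
#' The defaults (`delta_strong = 2.5`, `sigma = 0.15`) keep
#' `delta_strong > 2 + 3 sigma`, the margin that makes planted labels
#' essentially deterministic.
#'
#' @param n_series number of analog series (one scaffold each, max 12).
#' @param series_size compounds per series (cliff compound included).
#' @param cliff_sub SMILES branch of the potency-raising substituent.
#' @param neutral_subs pool of inert substituent branches.
#' @param delta_strong potency gain (log units) of the cliff substituent.
#' @param sigma standard deviation of the potency jitter.
#' @param base_potency series baseline pKi.
#' @param seed integer seed.
#' @return list of class `cliff_spec`.
#' @export
cliff_spec <- function(n_series = 8L, series_size = 5L,
                       cliff_sub = "C3CCCC3",
                       neutral_subs = .neutral_subs,
                       delta_strong = 2.5, sigma = 0.15,
                       base_potency = 6.0, seed = 1L) {
  if (n_series > length(.scaffolds))
    stop("at most ", length(.scaffolds), " series supported")
  if (series_size - 1L > length(neutral_subs))
    stop("series_size exceeds the neutral substituent pool")
  if (delta_strong <= 2 + 3 * sigma)
    warning("delta_strong <= 2 + 3*sigma: planted pairs may not be cliffs")
  structure(list(n_series = as.integer(n_series),
                 series_size = as.integer(series_size),
                 cliff_sub = cliff_sub, neutral_subs = neutral_subs,
                 delta_strong = delta_strong, sigma = sigma,
                 base_potency = base_potency, seed = as.integer(seed)),
            class = "cliff_spec")
}

#' Generate a synthetic compound table with planted activity cliffs
#'
#' Realises a [cliff_spec()]: every series takes one built-in scaffold,
#' one compound per series carries the cliff substituent, and potencies are
#' `base + delta_strong * [cliff] + N(0, sigma)`. Output is byte-identical
#' for identical seeds. Substituent strings are written into the scaffold's
#' variable position; rings inside substituents must use ring-closure digits
#' that do not collide with the scaffold (the built-in defaults do).
#'
#' @param spec a `cliff_spec`.
#' @return a `compound_table` (columns `cid`, `smiles`, `potency`) with an
#'   extra logical column `is_cliff_cpd`.
#' @export
generate_cliff_dataset <- function(spec = cliff_spec()) {
  stopifnot(inherits(spec, "cliff_spec"))
  rng <- local_rng(spec$seed)
  on.exit(rng())
  rows <- list()
  for (s in seq_len(spec$n_series)) {
    subs <- c(spec$cliff_sub,
              sample(spec$neutral_subs, spec$series_size - 1L))
    for (k in seq_along(subs)) {
      smi <- sprintf(.scaffolds[s], subs[k])
      can <- canonical_smiles(smi)
      if (is.na(can)) stop("substituent produced invalid SMILES: ", subs[k])
      is_cliff <- k == 1L
      rows[[length(rows) + 1L]] <- data.frame(
        cid = sprintf("S%02d_C%02d", s, k), smiles = can,
        potency = spec$base_potency + spec$delta_strong * is_cliff +
          stats::rnorm(1, 0, spec$sigma),
        is_cliff_cpd = is_cliff, stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  class(out) <- c("compound_table", "data.frame")
  out
}
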