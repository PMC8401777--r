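# Kernel SHAP over the fitted decision function, as a model-independent
# control for the exact decomposition. Shapley values are estimated by a
# weighted least-squares fit of a linear explanation model over feature
# coalitions; off-coalition features are filled in from background
# instances drawn from the marginal distribution. Exhaustive coalition
# enumeration is used whenever 2^N fits the sample budget.

#' Kernel SHAP coalition weight
#'
#' The weight of a coalition of size `z` out of `N` features in the SHAP
#' kernel regression: `(N - 1) / (choose(N, z) * z * (N - z))`. The empty
#' and full coalitions carry infinite weight and are handled as hard
#' constraints, not sampled.
#'
#' @param z coalition size, `0 < z < N` (vectorised).
#' @param n_features total number of features `N`.
#' @return numeric weight.
#' @examples
#' shap_kernel_weight(2, 4)  # 0.125
#' @export
shap_kernel_weight <- function(z, n_features) {
  if (any(z <= 0 | z >= n_features))
    stop("coalition size must satisfy 0 < z < N")
  (n_features - 1) / (choose(n_features, z) * z * (n_features - z))
}

#' Kernel SHAP values for an arbitrary set-valued decision function
#'
#' Low-level solver behind [shap_explain()]. `f` maps a set of on-bits to
#' a numeric output; `background` is a list of on-bit sets defining both
#' the baseline `phi0 = mean(f(background))` and the marginal fill-in for
#' off-coalition features. Coalitions are enumerated exhaustively when
#' `2^N` fits within `n_samples`, otherwise sampled from the SHAP-kernel
#' size distribution. The two infinite-weight boundary coalitions are
#' imposed as constraints, so `phi0 + sum(phi)` equals `f(x)` exactly.
#'
#' @param f function taking an integer vector of on-bits.
#' @param x_bits on-bits of the explained instance.
#' @param features integer vector of tracked bits (the explained space).
#' @param background list of on-bit vectors.
#' @param n_samples coalition budget.
#' @param seed integer seed.
#' @param bg_per_coalition background draws averaged per coalition.
#' @param fx output value of the explained instance; defaults to
#'   `f(x_bits)`. Supply the model's true output when `x_bits` is only a
#'   projection of the instance onto the tracked feature space.
#' @return list with `phi0`, `phis` (named by feature), `present`, `fx`,
#'   `n_samples`, `exhaustive`.
#' @export
shap_values <- function(f, x_bits, features, background,
                        n_samples = 2048L, seed = 1L,
                        bg_per_coalition = 8L, fx = NULL) {
  N <- length(features)
  if (N == 0L) stop("empty feature space")
  if (length(background) == 0L) stop("empty background")
  x_bits <- unique(x_bits)
  present <- features %in% x_bits
  phi0 <- mean(vapply(background, f, numeric(1)))
  if (is.null(fx)) fx <- f(x_bits)

  rng <- local_rng(seed)
  on.exit(rng())
  exhaustive <- 2^N <= n_samples + 2
  if (exhaustive) {
    masks <- as.matrix(expand.grid(rep(list(c(FALSE, TRUE)), N)))
    sizes <- rowSums(masks)
    masks <- masks[sizes > 0 & sizes < N, , drop = FALSE]
  } else {
    if (n_samples < N + 2L) stop("n_samples too small for ", N, " features")
    sz <- seq_len(N - 1L)
    pz <- shap_kernel_weight(sz, N) * choose(N, sz)
    draw_sz <- sample(sz, n_samples, replace = TRUE, prob = pz / sum(pz))
    masks <- t(vapply(draw_sz, function(k) {
      m <- rep(FALSE, N); m[sample.int(N, k)] <- TRUE; m
    }, logical(N)))
  }
  w <- shap_kernel_weight(rowSums(masks), N)
  nbg <- min(length(background), bg_per_coalition)
  gvals <- apply(masks, 1L, function(m) {
    bgs <- if (nbg == length(background)) background
           else background[sample.int(length(background), nbg)]
    mean(vapply(bgs, function(bg) {
      f(c(setdiff(bg, features),          # untracked bits: background value
          features[m & present],          # coalition bits: instance value
          intersect(features[!m], bg)))   # off-coalition bits: background
    }, numeric(1)))
  })
  # fold the boundary constraints g(0)=phi0, g(1)=fx into the regression
  # by eliminating the last coefficient
  Z <- masks * 1
  y <- gvals - phi0 - Z[, N] * (fx - phi0)
  Zr <- Z[, -N, drop = FALSE] - Z[, N]
  phis <- if (N == 1L) numeric(0) else {
    fit <- stats::lm.wfit(Zr, y, w)
    co <- fit$coefficients
    co[is.na(co)] <- 0
    co
  }
  phis <- c(phis, (fx - phi0) - sum(phis))
  list(phi0 = phi0, phis = stats::setNames(phis, features),
       present = stats::setNames(present, features), fx = fx,
       n_samples = nrow(masks), exhaustive = exhaustive)
}

#' Kernel SHAP explanation of one MMP prediction
#'
#' Approximates the decision value of an `ac_svm` for one MMP with a
#' linear explanation model over feature presence/absence. The baseline
#' `phi0` is the mean decision value over the training fingerprints, which
#' also serve as the marginal background. Features are universe bits; by
#' default the explained space is restricted to bits set in the instance
#' or in at least one support vector, capped at `max_features` (instance
#' bits kept first) with a warning.
#'
#' @param model an `ac_svm`.
#' @param x an `mmp_fp` or 1-row `mmp_table`.
#' @param n_samples coalition budget K (default 2048).
#' @param seed integer seed.
#' @param features optional integer vector of universe bits to explain.
#' @param max_features cap on the explained feature space (default 16).
#' @param bg_per_coalition background draws per coalition (default 8).
#' @return object of class `shap_explanation` (see [shap_values()] for the
#'   fields).
#' @export
shap_explain <- function(model, x, n_samples = 2048L, seed = 1L,
                         features = NULL, max_features = 16L,
                         bg_per_coalition = 8L) {
  if (inherits(x, "mmp_table") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- mmp_fingerprints(x)[[1]]
  }
  stopifnot(inherits(x, "mmp_fp"))
  uni <- model$universe
  svs <- model$fps[model$sv_index]
  xb <- fp_bits(x, uni)
  x_on <- c(xb$core_on, xb$sub_on)
  if (is.null(features)) {
    sv_on <- sort(unique(unlist(lapply(svs, function(s) {
      b <- fp_bits(s, uni); c(b$core_on, b$sub_on)
    }))))
    features <- sort(unique(c(x_on, sv_on)))
    if (length(features) > max_features) {
      warning("explained feature space capped at ", max_features,
              " of ", length(features), " bits (instance bits first)")
      pres <- features %in% x_on
      features <- sort(c(features[pres], features[!pres])[seq_len(max_features)])
    }
  }
  f_of_bits <- decision_from_bits(model, uni)
  bg_bits <- lapply(model$fps, function(fp) {
    b <- fp_bits(fp, uni); c(b$core_on, b$sub_on)
  })
  res <- shap_values(f_of_bits, x_on, features, bg_bits,
                     n_samples = n_samples, seed = seed,
                     bg_per_coalition = bg_per_coalition,
                     fx = as.numeric(predict(model, list(x),
                                             type = "decision")))
  structure(res, class = "shap_explanation")
}

# decision value from a set of universe on-bits (bit-level inverse of
# fp_bits over the training universe)
decision_from_bits <- function(model, uni) {
  svs <- model$fps[model$sv_index]
  sv_core <- lapply(svs, function(s) unique(s$core))
  sv_sub <- lapply(svs, function(s) unique(s$sub))
  co_tab <- uni[uni$segment == "core", ]
  xo_tab <- uni[uni$segment == "sub_xor", ]
  an_tab <- uni[uni$segment == "sub_and", ]
  function(bits) {
    core_ids <- co_tab$identifier[co_tab$bit %in% bits]
    xor_ids <- xo_tab$identifier[xo_tab$bit %in% bits]
    and_ids <- an_tab$identifier[an_tab$bit %in% bits]
    sub_ids <- c(xor_ids, and_ids + .AND_OFFSET)
    if (model$kernel == "mmp") {
      k <- vapply(seq_along(svs), function(i)
        tanimoto_kernel(core_ids, sv_core[[i]]) *
          tanimoto_kernel(sub_ids, sv_sub[[i]]), numeric(1))
    } else {
      flat <- c(core_ids + .CORE_OFFSET, sub_ids)
      k <- vapply(seq_along(svs), function(i)
        tanimoto_kernel(flat, c(sv_core[[i]] + .CORE_OFFSET, sv_sub[[i]])),
        numeric(1))
    }
    sum(model$dual_coef * k) - model$b
  }
}

#' Force-plot-style report of a SHAP explanation
#'
#' Orders features by absolute Shapley value and flags whether each
#' feature is present (1) or absent (0) in the explained instance — Kernel
#' SHAP routinely assigns weight to absent features, which is precisely
#' what the exact decomposition cannot do.
#'
#' @param expl a `shap_explanation`.
#' @return data frame with columns `bit`, `phi`, `present`, ordered by
#'   `|phi|` descending; attributes `phi0` and `fx`.
#' @export
force_report <- function(expl) {
  stopifnot(inherits(expl, "shap_explanation"))
  df <- data.frame(bit = as.integer(names(expl$phis)),
                   phi = unname(expl$phis),
                   present = as.integer(unname(expl$present)))
  df <- df[order(-abs(df$phi)), , drop = FALSE]
  rownames(df) <- NULL
  attr(df, "phi0") <- expl$phi0
  attr(df, "fx") <- expl$fx
  df
}

#' @export
print.shap_explanation <- function(x, digits = 4, ...) {
  cat("Kernel SHAP explanation (",
      if (x$exhaustive) "exhaustive coalitions" else
        paste(x$n_samples, "sampled coalitions"), ")\n", sep = "")
  cat(sprintf("  phi0 %.*f + sum(phi) %.*f = %.*f  (decision %.*f)\n",
              digits, x$phi0, digits, sum(x$phis), digits,
              x$phi0 + sum(x$phis), digits, x$fx))
  print(utils::head(force_report(x), 8), row.names = FALSE, digits = digits)
  invisible(x)
}

#' Side-by-side comparison of the exact decomposition and SHAP
#'
#' Tabulates, per universe bit, the exact contribution and the Shapley
#' value, with a presence flag, and summarises how much of the total
#' absolute Shapley mass sits on features absent from the instance. The
#' exact method assigns weight only to present features, so its
#' absent-mass fraction is 0 by construction.
#'
#' @param exact an `ac_explanation`.
#' @param shap a `shap_explanation` for the same MMP and model (optional).
#' @return object of class `ac_comparison`: `table` (bit, segment,
#'   identifier, exact contribution, phi, present) and `summary`
#'   (decision, absent-mass fractions).
#' @export
compare_report <- function(exact, shap = NULL) {
  stopifnot(inherits(exact, "ac_explanation"))
  tab <- exact$per_feature[, c("bit", "segment", "identifier",
                               "contribution")]
  if (!is.null(shap)) {
    stopifnot(inherits(shap, "shap_explanation"))
    if (abs(shap$fx - exact$decision) > 1e-6 + 1e-6 * abs(exact$decision))
      stop("explanations disagree on the decision value: ",
           "different model or MMP")
    fr <- force_report(shap)
    tab <- merge(tab, fr, by = "bit", all = TRUE)
    tab$present[is.na(tab$present)] <- 1L  # unmapped instance features
    absent_mass <- sum(abs(fr$phi[fr$present == 0]))
    total_mass <- sum(abs(fr$phi))
    shap_absent_frac <- if (total_mass > 0) absent_mass / total_mass else 0
  } else {
    tab$phi <- NA_real_
    tab$present <- 1L
    shap_absent_frac <- NA_real_
  }
  ord <- order(-pmax(abs(tab$contribution), abs(tab$phi), na.rm = TRUE))
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  structure(list(table = tab,
                 summary = list(decision = exact$decision,
                                exact_absent_mass_fraction = 0,
                                shap_absent_mass_fraction = shap_absent_frac)),
            class = "ac_comparison")
}

#' @export
print.ac_comparison <- function(x, digits = 4, ...) {
  cat("Exact decomposition vs Kernel SHAP\n")
  cat(sprintf("  decision %.*f; |phi| mass on absent features: %s\n",
              digits, x$summary$decision,
              format(x$summary$shap_absent_mass_fraction, digits = 3)))
  print(utils::head(x$table, 10), row.names = FALSE, digits = digits)
  invisible(x)
}
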