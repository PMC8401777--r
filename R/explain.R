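# Exact additive feature contributions for Tanimoto- and MMP-kernel SVMs.
#
# For the plain Tanimoto kernel the decision value is already a sum over
# shared features, because the kernel denominator is a constant within each
# support-vector/test pair. The MMP kernel is a product of two Tanimoto
# kernels, so each kernel evaluation expands into a matrix of
# core-feature x substituent-feature cross-terms; assigning half of every
# cross-term to its core feature and half to its substituent feature turns
# the decision value into an exact sum of per-feature contributions. The
# split is applied per support vector, before any aggregation.

#' Fragment feature contribution under the Tanimoto kernel
#'
#' The additive share of one support vector's kernel value carried by one
#' feature `d`: `dual_coef / (|sv| + |x| - |sv n x|)` when `d` is present
#' in both sets and 0 otherwise. Summing over the shared features recovers
#' `dual_coef * K(sv, x)` exactly.
#'
#' @param sv,x numeric feature-identifier sets.
#' @param dual_coef the support vector's dual coefficient
#'   (\eqn{\alpha y}).
#' @param d a feature identifier.
#' @return numeric contribution.
#' @examples
#' frag_fc_tanimoto(c(1, 2, 3), 1, c(1, 3), 1)  # 1/3
#' @export
frag_fc_tanimoto <- function(sv, dual_coef, x, d) {
  sv <- unique(sv); x <- unique(x)
  if (!(d %in% sv) || !(d %in% x)) return(0)
  o <- sum(sv %in% x)
  dual_coef / (length(sv) + length(x) - o)
}

#' Cross-term fragment feature contribution under the MMP kernel
#'
#' The product of the core-wise and substituent-wise fragment feature
#' contributions for a shared core feature `d_c` and a shared substituent
#' feature `d_s` of one support vector; 0 when either feature is not shared.
#'
#' @param sv,x `mmp_fp` fingerprints.
#' @param dual_coef the support vector's dual coefficient.
#' @param d_c core feature identifier; `d_s` substituent feature identifier.
#' @param d_s see `d_c`.
#' @return numeric cross-term value.
#' @export
frag_fc_mmp <- function(sv, dual_coef, x, d_c, d_s) {
  tc <- frag_fc_tanimoto(sv$core, 1, x$core, d_c)
  ts <- frag_fc_tanimoto(sv$sub, 1, x$sub, d_s)
  dual_coef * tc * ts
}

#' Exact per-feature contributions of a decision value
#'
#' Decomposes the kernel part of the SVM decision value for one MMP into
#' per-feature contributions. For an MMP-kernel model every
#' core-substituent cross-term of every support vector is split evenly
#' between its core feature and its substituent feature; for a
#' plain-Tanimoto model each shared feature receives its direct share. In
#' both cases the contributions sum to
#' \eqn{\sum_i \alpha_i y_i K(x_i, x)} exactly and only features present in
#' the explained MMP can receive weight. The bias is kept apart: it is a
#' property of the hyperplane, not of any feature.
#'
#' @param object an `ac_svm` model.
#' @param x an `mmp_fp`, or a 1-row `mmp_table`.
#' @param ... unused.
#' @return object of class `ac_explanation`: `per_feature` (data frame with
#'   `segment`, `identifier`, `bit` — `NA` for features outside the training
#'   universe — and `contribution`), `kernel_sum`, `bias`, `decision`,
#'   `pred`, and the explained fingerprint `fp`.
#' @examples
#' fx <- fig5_fixture()
#' model <- manual_ac_svm(list(fx$support), dual_coef = 1, b = 0)
#' explain(model, fx$test)
#' @export
explain <- function(object, x, ...) UseMethod("explain")

#' @rdname explain
#' @export
explain.ac_svm <- function(object, x, ...) {
  if (inherits(x, "mmp_table") || is.data.frame(x)) {
    stopifnot(nrow(x) == 1L)
    x <- mmp_fingerprints(x)[[1]]
  }
  stopifnot(inherits(x, "mmp_fp"))
  svs <- object$fps[object$sv_index]
  co <- object$dual_coef
  if (object$kernel == "mmp") {
    contrib_core <- stats::setNames(numeric(length(x$core)),
                                    as.character(x$core))
    contrib_sub <- stats::setNames(numeric(length(x$sub)),
                                   as.character(x$sub))
    ksum <- 0
    for (i in seq_along(svs)) {
      sv <- svs[[i]]
      oc <- x$core[x$core %in% sv$core]
      os <- x$sub[x$sub %in% sv$sub]
      if (length(oc) == 0L || length(os) == 0L) next
      den_c <- length(unique(sv$core)) + length(x$core) - length(oc)
      den_s <- length(unique(sv$sub)) + length(x$sub) - length(os)
      cross <- co[i] / (den_c * den_s)       # one cross-term value
      ksum <- ksum + cross * length(oc) * length(os)
      # half of each cross-term to the core feature, half to the
      # substituent feature; a core feature sits in |os| cross-terms
      contrib_core[as.character(oc)] <-
        contrib_core[as.character(oc)] + 0.5 * cross * length(os)
      contrib_sub[as.character(os)] <-
        contrib_sub[as.character(os)] + 0.5 * cross * length(oc)
    }
    per <- rbind(
      data.frame(segment = rep("core", length(x$core)),
                 identifier = x$core, tagged = x$core,
                 contribution = unname(contrib_core)),
      data.frame(segment = id_segment(x$sub, "sub"),
                 identifier = ifelse(x$sub >= .AND_OFFSET,
                                     x$sub - .AND_OFFSET, x$sub),
                 tagged = x$sub,
                 contribution = unname(contrib_sub))
    )
  } else {
    xs <- flatten_fp(x)
    contrib <- stats::setNames(numeric(length(xs)), as.character(xs))
    ksum <- 0
    for (i in seq_along(svs)) {
      sv <- flatten_fp(svs[[i]])
      ov <- xs[xs %in% sv]
      if (length(ov) == 0L) next
      den <- length(sv) + length(xs) - length(ov)
      contrib[as.character(ov)] <- contrib[as.character(ov)] + co[i] / den
      ksum <- ksum + co[i] * length(ov) / den
    }
    raw <- ifelse(xs >= .CORE_OFFSET, xs - .CORE_OFFSET, xs)
    seg <- ifelse(xs >= .CORE_OFFSET, "core", id_segment(xs, "sub"))
    raw <- ifelse(seg == "sub_and", raw - .AND_OFFSET, raw)
    per <- data.frame(segment = seg, identifier = raw, tagged = xs,
                      contribution = unname(contrib))
  }
  per$bit <- universe_bit(per, object$universe)
  per <- per[order(-abs(per$contribution)), , drop = FALSE]
  rownames(per) <- NULL
  decision <- ksum - object$b
  structure(list(per_feature = per, kernel_sum = ksum, bias = object$b,
                 decision = decision,
                 pred = if (decision > 0) "AC" else "NON_AC", fp = x),
            class = "ac_explanation")
}

universe_bit <- function(per, universe) {
  if (is.null(universe)) return(rep(NA_integer_, nrow(per)))
  key_u <- paste(universe$segment, universe$identifier)
  key_p <- paste(per$segment, per$identifier)
  universe$bit[match(key_p, key_u)]
}

# Construct an ac_svm directly from fingerprints and dual coefficients,
# bypassing the QP solver. Used for worked examples and oracle tests.
#' Build an activity-cliff SVM from explicit dual coefficients
#'
#' Assembles an `ac_svm` object from given support-vector fingerprints,
#' dual coefficients and bias without running the optimiser. Intended for
#' worked examples, reference calculations and tests.
#'
#' @param fps list of `mmp_fp` support vectors.
#' @param dual_coef numeric vector \eqn{\alpha_i y_i}.
#' @param b bias.
#' @param kernel `"mmp"` or `"tanimoto"`.
#' @param universe optional `mmp_universe`; built from `fps` if omitted.
#' @return an `ac_svm`.
#' @export
manual_ac_svm <- function(fps, dual_coef, b = 0,
                          kernel = c("mmp", "tanimoto"), universe = NULL) {
  kernel <- match.arg(kernel)
  stopifnot(length(fps) == length(dual_coef))
  structure(list(fps = fps, sv_index = seq_along(fps),
                 dual_coef = as.numeric(dual_coef), b = b, C = NA_real_,
                 cv = NULL,
                 universe = if (is.null(universe)) build_universe(fps)
                            else universe,
                 labels = ifelse(dual_coef >= 0, "AC", "NON_AC"),
                 kernel = kernel, n_sv = length(fps),
                 call = match.call()),
            class = "ac_svm")
}

#' Redistribute feature contributions onto atoms and bonds
#'
#' Each feature's contribution is spread evenly over the atoms and bonds of
#' its recorded substructure environments; weights accumulate where
#' environments overlap. AND-channel features occur in both substituents:
#' their contribution is first split evenly between the two fragments, then
#' spread within each. Features without a back-map (abstract fingerprints,
#' or features of bare fragments) are collected in an explicit remainder so
#' that the mapped weights plus the remainder always equal the mapped
#' feature total exactly.
#'
#' @param expl an `ac_explanation`.
#' @param fp the explained `mmp_fp`; defaults to the one in `expl`.
#' @return object of class `atom_weights`: `weights` (data frame with
#'   `role` in core/sub_low/sub_high, `kind` atom/bond, `index`, `weight`),
#'   `remainder` (total contribution of unmapped features) and `frags`.
#' @export
map_to_structure <- function(expl, fp = expl$fp) {
  stopifnot(inherits(expl, "ac_explanation"), inherits(fp, "mmp_fp"))
  acc <- list()
  add_w <- function(role, kind, idx, w) {
    for (k in idx) {
      key <- paste(role, kind, k)
      acc[[key]] <<- (if (is.null(acc[[key]])) 0 else acc[[key]]) + w
    }
  }
  remainder <- 0
  per <- expl$per_feature
  for (r in seq_len(nrow(per))) {
    contrib <- per$contribution[r]
    key <- as.character(per$tagged[r])
    bm <- fp$backmap[[key]]
    if (is.null(bm) || length(bm) == 0L) { remainder <- remainder + contrib; next }
    roles <- names(bm)
    share <- contrib / length(roles)  # AND features: even split across fragments
    for (role in roles) {
      envs <- bm[[role]]
      na <- sum(vapply(envs, function(e) length(e$atoms), integer(1)))
      nb <- sum(vapply(envs, function(e) length(e$bonds), integer(1)))
      if (na + nb == 0L) { remainder <- remainder + share; next }
      w <- share / (na + nb)
      for (e in envs) {
        add_w(role, "atom", e$atoms, w)
        add_w(role, "bond", e$bonds, w)
      }
    }
  }
  if (length(acc)) {
    parts <- strsplit(names(acc), " ", fixed = TRUE)
    weights <- data.frame(
      role = vapply(parts, `[`, "", 1),
      kind = vapply(parts, `[`, "", 2),
      index = as.integer(vapply(parts, `[`, "", 3)),
      weight = unlist(acc, use.names = FALSE))
  } else {
    weights <- data.frame(role = character(0), kind = character(0),
                          index = integer(0), weight = numeric(0))
  }
  structure(list(weights = weights, remainder = remainder,
                 frags = fp$frags),
            class = "atom_weights")
}

#' @export
print.ac_explanation <- function(x, digits = 4, ...) {
  cat("Exact feature contributions\n")
  cat(sprintf("  kernel sum %.*f - bias %.*f = decision %.*f  ->  %s\n",
              digits, x$kernel_sum, digits, x$bias, digits, x$decision,
              x$pred))
  cat("  top features:\n")
  print(utils::head(x$per_feature[, c("segment", "identifier", "bit",
                                      "contribution")], 8),
        row.names = FALSE, digits = digits)
  n <- nrow(x$per_feature)
  if (n > 8) cat("  ...", n - 8, "more features\n")
  invisible(x)
}

#' @export
print.atom_weights <- function(x, ...) {
  cat("Atom/bond contribution map:", nrow(x$weights), "entries, total",
      format(sum(x$weights$weight), digits = 6),
      "( remainder", format(x$remainder, digits = 6), ")\n")
  invisible(x)
}
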