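#' Fit an activity-cliff SVM on matched molecular pairs
#'
#' Trains a maximum-margin classifier on the precomputed MMP-kernel Gram
#' matrix of the training pairs. The decision function is
#' \deqn{f(x) = \mathrm{sign}\Big(\sum_i \alpha_i y_i K(x_i, x) - b\Big)}
#' with positive values predicting an activity cliff. The box constraint
#' `C` is selected from a grid by stratified cross-validation maximising
#' the Matthews correlation coefficient; the final model is refit on the
#' full training set. The quadratic-programming backend is
#' [kernlab::ksvm()]; its dual coefficients and offset are re-expressed in
#' the convention above regardless of the backend's internal sign choice.
#'
#' @param x an `mmp_table` from [generate_mmps()], or a list of `mmp_fp`
#'   fingerprints (then `labels` is required).
#' @param labels character vector of `"AC"` / `"NON_AC"` labels, one per
#'   fingerprint; ignored when `x` is an `mmp_table`.
#' @param C numeric grid of box-constraint candidates. A length-1 grid
#'   skips the cross-validation search.
#' @param cv_folds folds for the stratified C search (default 5).
#' @param seed integer seed controlling fold assignment.
#' @param kernel `"mmp"` (product kernel, the default) or `"tanimoto"`
#'   (plain Tanimoto kernel on the flattened fingerprint).
#' @return an object of class `ac_svm` with components `fps` (training
#'   fingerprints), `sv_index`, `dual_coef` (\eqn{\alpha_i y_i}, positive
#'   for cliff-class support vectors), `b`, `C`, `cv` (grid search table),
#'   `universe`, `labels`, `kernel` and `n_sv`.
#' @seealso [predict.ac_svm()], [explain()], [mms_loo_evaluate()]
#' @export
ac_svm <- function(x, labels = NULL,
                   C = c(0.01, 0.1, 1, 10, 100, 1000),
                   cv_folds = 5L, seed = 1L,
                   kernel = c("mmp", "tanimoto")) {
  kernel <- match.arg(kernel)
  if (inherits(x, "mmp_table") || is.data.frame(x)) {
    labels <- x$label
    fps <- mmp_fingerprints(x)
  } else {
    fps <- x
    if (is.null(labels)) stop("labels required when x is a fingerprint list")
  }
  if (length(fps) < 2L) stop("need at least 2 training MMPs")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L)
    stop("training set contains a single class: ", unique(labels))
  y <- factor(labels, levels = c("NON_AC", "AC"))

  K <- mmp_gram(fps, kernel = kernel)
  cv_tab <- NULL
  C_best <- C[1]
  if (length(C) > 1L) {
    folds <- stratified_folds(y, cv_folds, seed)
    mcc_grid <- vapply(C, function(cc) {
      dec <- rep(NA_real_, length(y)); prd <- rep(NA_character_, length(y))
      for (f in sort(unique(folds))) {
        tr <- which(folds != f); te <- which(folds == f)
        if (length(unique(y[tr])) < 2L || length(te) == 0L) next
        m <- fit_kernlab(K[tr, tr, drop = FALSE], y[tr], cc)
        d <- K[te, tr[m$sv_index], drop = FALSE] %*% m$dual_coef - m$b
        dec[te] <- d
        prd[te] <- ifelse(d > 0, "AC", "NON_AC")
      }
      ok <- !is.na(prd)
      if (!any(ok)) return(NA_real_)
      mcc(labels[ok], prd[ok])
    }, numeric(1))
    cv_tab <- data.frame(C = C, mcc = mcc_grid)
    if (all(is.na(mcc_grid))) stop("cross-validation failed for every C")
    C_best <- C[which.max(replace(mcc_grid, is.na(mcc_grid), -Inf))]
  }
  m <- fit_kernlab(K, y, C_best)
  structure(list(fps = fps, sv_index = m$sv_index, dual_coef = m$dual_coef,
                 b = m$b, C = C_best, cv = cv_tab,
                 universe = build_universe(fps), labels = labels,
                 kernel = kernel, n_sv = length(m$sv_index),
                 call = match.call()),
            class = "ac_svm")
}

# kernlab adapter: fit on a precomputed Gram and re-express the solution as
# decision = K[, sv] %*% dual_coef - b with positive == "AC". kernlab's
# internal sign depends on its label encoding, so the orientation is fixed
# empirically against its own predictions.
fit_kernlab <- function(K, y, C) {
  m <- kernlab::ksvm(kernlab::as.kernelMatrix(K), y, kernel = "matrix",
                     C = C, scaled = FALSE)
  svi <- kernlab::SVindex(m)
  co <- unlist(kernlab::coef(m))
  b <- kernlab::b(m)
  d <- K[, svi, drop = FALSE] %*% co - b
  pr <- kernlab::predict(m, kernlab::as.kernelMatrix(K[, svi, drop = FALSE]))
  agree <- mean((d > 0) == (pr == "AC"))
  if (agree < 0.5) { co <- -co; b <- -b }
  list(sv_index = svi, dual_coef = co, b = b)
}

stratified_folds <- function(y, k, seed) {
  folds <- integer(length(y))
  rng <- local_rng(seed)
  on.exit(rng())
  for (cl in levels(y)) {
    idx <- which(y == cl)
    folds[idx] <- sample(rep_len(seq_len(k), length(idx)))
  }
  folds
}

# Set the RNG to `seed`, returning a restorer for on.exit().
local_rng <- function(seed) {
  old <- if (exists(".Random.seed", globalenv(), inherits = FALSE))
    get(".Random.seed", globalenv()) else NULL
  set.seed(seed)
  function() {
    if (is.null(old)) rm(".Random.seed", envir = globalenv())
    else assign(".Random.seed", old, envir = globalenv())
  }
}

#' Predict activity cliffs for new MMPs
#'
#' @param object an `ac_svm` model.
#' @param newdata an `mmp_table` or list of `mmp_fp`.
#' @param type `"class"` for `"AC"`/`"NON_AC"` labels, `"decision"` for raw
#'   decision values (positive favours a cliff).
#' @param ... unused.
#' @return character vector or numeric vector, one entry per MMP.
#' @export
predict.ac_svm <- function(object, newdata, type = c("class", "decision"),
                           ...) {
  type <- match.arg(type)
  fps <- if (inherits(newdata, "mmp_table") || is.data.frame(newdata))
    mmp_fingerprints(newdata) else newdata
  if (inherits(fps, "mmp_fp")) fps <- list(fps)
  sv <- object$fps[object$sv_index]
  Kc <- mmp_gram(fps, sv, kernel = object$kernel)
  d <- as.numeric(Kc %*% object$dual_coef - object$b)
  if (type == "decision") d else ifelse(d > 0, "AC", "NON_AC")
}

#' @export
coef.ac_svm <- function(object, ...) {
  stats::setNames(object$dual_coef, paste0("sv", object$sv_index))
}

#' @export
print.ac_svm <- function(x, ...) {
  cat("Activity-cliff SVM (", x$kernel, " kernel)\n", sep = "")
  cat("  training MMPs: ", length(x$fps), " (",
      sum(x$labels == "AC"), " AC / ", sum(x$labels == "NON_AC"),
      " non-AC)\n", sep = "")
  cat("  support vectors:", x$n_sv, "  C:", x$C,
      "  b:", format(x$b, digits = 4), "\n")
  invisible(x)
}

#' @export
summary.ac_svm <- function(object, ...) {
  print(object)
  if (!is.null(object$cv)) {
    cat("  C grid (stratified CV, MCC):\n")
    print(object$cv, row.names = FALSE)
  }
  u <- object$universe
  cat("  universe: D_c =", attr(u, "D_c"), ", D_s =", attr(u, "D_s"), "\n")
  invisible(object)
}
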