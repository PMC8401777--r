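# Portable model archive (versioned JSON) and run configuration.

#' Save / load a fitted activity-cliff SVM
#'
#' The archive is a single versioned JSON file holding the support-vector
#' fingerprints (identifier sets and fragment strings), dual coefficients,
#' bias, box constraint and the training feature universe. Chemistry
#' back-maps are rebuilt from the fragment strings on load, so archives
#' stay plain text.
#'
#' @param model an `ac_svm`.
#' @param path file path for the archive.
#' @return `write_ac_svm` returns `path` invisibly; `read_ac_svm` returns
#'   the restored `ac_svm`.
#' @export
write_ac_svm <- function(model, path) {
  stopifnot(inherits(model, "ac_svm"))
  fps <- lapply(model$fps, function(fp)
    list(core = fp$core, sub = fp$sub,
         frags = if (is.null(fp$frags)) NULL else as.list(fp$frags)))
  obj <- list(format = "mmpcliff-svm", version = 1L,
              kernel = model$kernel,
              C = if (is.finite(model$C)) model$C else NULL,
              b = model$b,
              sv_index = model$sv_index, dual_coef = model$dual_coef,
              labels = model$labels, fps = fps,
              universe = as.data.frame(model$universe),
              D_c = attr(model$universe, "D_c"),
              D_s = attr(model$universe, "D_s"))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_ac_svm
#' @export
read_ac_svm <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = FALSE)
  if (!identical(obj$format, "mmpcliff-svm"))
    stop("not an mmpcliff model archive: ", path)
  fps <- lapply(obj$fps, function(fp) {
    if (!is.null(fp$frags) && length(fp$frags) == 3L) {
      fingerprint_mmp(fp$frags$core, fp$frags$sub_low, fp$frags$sub_high)
    } else {
      new_mmp_fp(core = as.numeric(unlist(fp$core)),
                 sub = as.numeric(unlist(fp$sub)))
    }
  })
  uni <- data.frame(
    segment = vapply(obj$universe, function(r) r$segment, ""),
    identifier = vapply(obj$universe, function(r) as.numeric(r$identifier),
                        numeric(1)),
    bit = vapply(obj$universe, function(r) as.integer(r$bit), integer(1)))
  universe <- structure(uni, D_c = obj$D_c, D_s = obj$D_s,
                        class = c("mmp_universe", "data.frame"))
  structure(list(fps = fps, sv_index = as.integer(unlist(obj$sv_index)),
                 dual_coef = as.numeric(unlist(obj$dual_coef)),
                 b = as.numeric(obj$b),
                 C = if (is.null(obj$C)) NA_real_ else as.numeric(obj$C),
                 cv = NULL, universe = universe,
                 labels = as.character(unlist(obj$labels)),
                 kernel = obj$kernel,
                 n_sv = length(obj$sv_index), call = NULL),
            class = "ac_svm")
}

#' Run configuration with the pipeline defaults
#'
#' Collects every tunable of the pipeline — labelling thresholds, MMP size
#' constraints, fingerprint diameters, C grid, SHAP budget — with the
#' package defaults, and round-trips losslessly through JSON.
#'
#' @param ... overrides for any default field.
#' @return named list of class `ac_config`.
#' @export
ac_config <- function(...) {
  cfg <- list(
    seed = 1L,
    ac_threshold = 2.0, nonac_threshold = 1.0,
    max_sub_atoms = 13L, max_sub_diff = 8L,
    diameters = c(2L, 4L),
    C_grid = c(0.01, 0.1, 1, 10, 100, 1000),
    cv_folds = 5L,
    shap_samples = 2048L, shap_max_features = 16L,
    output_dir = "."
  )
  dots <- list(...)
  unknown <- setdiff(names(dots), names(cfg))
  if (length(unknown)) stop("unknown config field(s): ",
                            paste(unknown, collapse = ", "))
  cfg[names(dots)] <- dots
  structure(cfg, class = "ac_config")
}

#' @rdname ac_config
#' @param cfg an `ac_config`.
#' @param path JSON file path.
#' @export
write_ac_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname ac_config
#' @export
read_ac_config <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyVector = TRUE)
  do.call(ac_config, obj)
}

#' Write an MMP table to CSV
#'
#' @param mmps an `mmp_table`.
#' @param path output path.
#' @export
write_mmp_table <- function(mmps, path) {
  utils::write.csv(as.data.frame(mmps), path, row.names = FALSE)
  invisible(path)
}

#' Read an MMP table written by [write_mmp_table()]
#'
#' @param path CSV path.
#' @export
read_mmp_table <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("cid_low", "cid_high", "core", "sub_low", "sub_high",
            "delta_p", "label")
  if (!all(need %in% names(df)))
    stop("missing MMP columns: ", paste(setdiff(need, names(df)),
                                        collapse = ", "))
  class(df) <- c("mmp_table", "data.frame")
  df
}
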