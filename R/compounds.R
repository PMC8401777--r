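#' Read a compound table from CSV
#'
#' Reads a table of compounds with an identifier, a SMILES structure, and a
#' potency given as pKi (\eqn{-\log_{10}} of the inhibition constant in molar
#' units). Salt and solvent components are removed by keeping the largest
#' covalent fragment, structures are canonicalised, and rows whose SMILES do
#' not parse are dropped with a warning. Compounds with several potency
#' measurements are aggregated to the median pKi; a compound whose
#' measurements span more than `max_potency_range` log units is discarded as
#' irreproducible.
#'
#' @param path path to a CSV file with a header row.
#' @param columns named character vector mapping the roles `id`, `smiles` and
#'   `potency` to column names in the file.
#' @param max_potency_range maximum allowed spread (log units) between
#'   repeated measurements of one compound before it is discarded.
#' @return a data frame of class `compound_table` with columns `cid`,
#'   `smiles` (canonical) and `potency`.
#' @examples
#' tf <- tempfile(fileext = ".csv")
#' write.csv(data.frame(id = c("a", "b"), smiles = c("CCO", "CCCO"),
#'                      pKi = c(5, 6)), tf, row.names = FALSE)
#' read_compound_table(tf)
#' @export
read_compound_table <- function(path,
                                columns = c(id = "id", smiles = "smiles",
                                            potency = "pKi"),
                                max_potency_range = 1.0) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty compound table: ", path)
  for (role in c("id", "smiles", "potency")) {
    col <- columns[[role]]
    if (is.null(col) || !col %in% names(df))
      stop("required column for role '", role, "' ('", col,
           "') not found in ", path)
  }
  cid <- as.character(df[[columns[["id"]]]])
  smi <- as.character(df[[columns[["smiles"]]]])
  pot <- suppressWarnings(as.numeric(df[[columns[["potency"]]]]))

  bad_pot <- !is.finite(pot)
  if (any(bad_pot)) {
    warning("dropping ", sum(bad_pot), " row(s) with non-finite potency")
    cid <- cid[!bad_pot]; smi <- smi[!bad_pot]; pot <- pot[!bad_pot]
  }

  # median-aggregate replicate measurements per identifier; a replicate set
  # must agree on structure, and its spread must stay within range
  if (anyDuplicated(cid)) {
    agg <- split(seq_along(cid), cid)
    keep_rows <- integer(0)
    drop_range <- character(0)
    for (id in names(agg)) {
      rows <- agg[[id]]
      if (length(rows) == 1L) { keep_rows <- c(keep_rows, rows); next }
      if (length(unique(smi[rows])) > 1L)
        stop("duplicate identifier with conflicting structures: ", id)
      if (diff(range(pot[rows])) > max_potency_range) {
        drop_range <- c(drop_range, id)
      } else {
        pot[rows[1]] <- stats::median(pot[rows])
        keep_rows <- c(keep_rows, rows[1])
      }
    }
    if (length(drop_range))
      warning("discarding compound(s) with potency range > ",
              max_potency_range, " log units: ",
              paste(drop_range, collapse = ", "))
    keep_rows <- sort(keep_rows)
    cid <- cid[keep_rows]; smi <- smi[keep_rows]; pot <- pot[keep_rows]
  }

  can <- canonical_smiles(strip_salts(smi))
  bad <- is.na(can)
  if (any(bad))
    warning("dropping ", sum(bad), " row(s) with unparseable SMILES: ",
            paste(utils::head(cid[bad], 5), collapse = ", "))
  out <- data.frame(cid = cid[!bad], smiles = can[!bad],
                    potency = pot[!bad], stringsAsFactors = FALSE)
  if (nrow(out) == 0L) stop("no parseable compounds in ", path)
  class(out) <- c("compound_table", "data.frame")
  out
}

#' Label a potency difference as activity cliff or not
#'
#' A matched molecular pair is an activity cliff (`"AC"`) when the absolute
#' pKi difference of its compounds exceeds 2 log units and a non-cliff
#' (`"NON_AC"`) when it is below 1 log unit. Differences in between — and
#' exactly on either boundary — are `"AMBIGUOUS"` and are excluded from
#' training and evaluation.
#'
#' @param delta_p numeric vector of absolute potency differences (log units).
#' @param ac_threshold difference above which a pair is a cliff (default 2).
#' @param nonac_threshold difference below which a pair is a non-cliff
#'   (default 1).
#' @return character vector with values `"AC"`, `"NON_AC"` or `"AMBIGUOUS"`.
#' @examples
#' label_pair(c(2.5, 0.5, 1.5, 2.0))
#' @export
label_pair <- function(delta_p, ac_threshold = 2.0, nonac_threshold = 1.0) {
  if (any(!is.finite(delta_p)) || any(delta_p < 0))
    stop("delta_p must be finite and non-negative")
  ifelse(delta_p > ac_threshold, "AC",
         ifelse(delta_p < nonac_threshold, "NON_AC", "AMBIGUOUS"))
}

#' @export
print.compound_table <- function(x, ...) {
  cat("Compound table:", nrow(x), "compounds, pKi range [",
      sprintf("%.2f", min(x$potency)), ",",
      sprintf("%.2f", max(x$potency)), "]\n")
  print.data.frame(utils::head(x, 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
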