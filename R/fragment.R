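# MMP fragmentation: single cuts of acyclic single bonds, Hussain-Lee style
# core/substituent indexing, and matched-molecular-series grouping.

#' Enumerate single-cut fragmentations of a compound
#'
#' Cuts each acyclic single bond between two heavy atoms in turn. The side
#' with fewer heavy atoms becomes the substituent (ties broken by canonical
#' string), the other side the core; both fragments carry the attachment
#' point as a dummy atom (`*`) in their canonical SMILES. Cuts whose
#' substituent exceeds `max_sub_atoms` heavy atoms are not reported.
#'
#' @param smiles a single SMILES string.
#' @param max_sub_atoms maximum heavy-atom count of the substituent
#'   (default 13).
#' @return data frame with columns `core`, `sub`, `core_atoms`, `sub_atoms`
#'   (heavy-atom counts); zero rows when no acyclic single bond exists.
#' @examples
#' enumerate_single_cuts("CCc1ccccc1")
#' @export
enumerate_single_cuts <- function(smiles, max_sub_atoms = 13L) {
  mol <- parse_mol(smiles)
  empty <- data.frame(core = character(0), sub = character(0),
                      core_atoms = integer(0), sub_atoms = integer(0),
                      stringsAsFactors = FALSE)
  if (is.null(mol) || nrow(mol$atoms) < 2L) return(empty)
  n <- nrow(mol$atoms)
  cuttable <- which(!mol$bonds$ring & mol$bonds$order == 1L &
                      mol$atoms$z[mol$bonds$a1] > 1L &
                      mol$atoms$z[mol$bonds$a2] > 1L)
  res <- vector("list", length(cuttable))
  for (k in seq_along(cuttable)) {
    bi <- cuttable[k]
    a1 <- mol$bonds$a1[bi]; a2 <- mol$bonds$a2[bi]
    side1 <- graph_component(mol, drop_bond = bi, from = a1)
    side2 <- setdiff(seq_len(n), side1)
    ha1 <- sum(mol$atoms$z[side1] > 1L)
    ha2 <- sum(mol$atoms$z[side2] > 1L)
    frag1 <- fragment_smiles(mol, side1, attach_to = a1)
    frag2 <- fragment_smiles(mol, side2, attach_to = a2)
    if (is.na(frag1) || is.na(frag2)) next
    # smaller side is the substituent
    if (ha1 < ha2 || (ha1 == ha2 && frag1 <= frag2)) {
      sub <- frag1; core <- frag2; sub_ha <- ha1; core_ha <- ha2
    } else {
      sub <- frag2; core <- frag1; sub_ha <- ha2; core_ha <- ha1
    }
    if (sub_ha > max_sub_atoms) next
    res[[k]] <- data.frame(core = core, sub = sub, core_atoms = core_ha,
                           sub_atoms = sub_ha, stringsAsFactors = FALSE)
  }
  res <- res[!vapply(res, is.null, logical(1))]
  if (length(res) == 0L) return(empty)
  unique(do.call(rbind, res))
}

# Reattach a substituent to a core at their dummy atoms; canonical SMILES
# of the reassembled molecule (NA on failure). Used to verify that every
# fragmentation reconstructs its parent.
reattach_fragments <- function(core, sub) {
  mc <- parse_mol(core); ms <- parse_mol(sub)
  if (is.null(mc) || is.null(ms)) return(NA_character_)
  dc <- which(mc$atoms$z == 0L); ds <- which(ms$atoms$z == 0L)
  if (length(dc) != 1L || length(ds) != 1L) return(NA_character_)
  # neighbours of the dummies become the new bond's endpoints
  nb_c <- c(mc$bonds$a2[mc$bonds$a1 == dc], mc$bonds$a1[mc$bonds$a2 == dc])
  nb_s <- c(ms$bonds$a2[ms$bonds$a1 == ds], ms$bonds$a1[ms$bonds$a2 == ds])
  if (length(nb_c) != 1L || length(nb_s) != 1L) return(NA_character_)
  keep_c <- setdiff(seq_len(nrow(mc$atoms)), dc)
  keep_s <- setdiff(seq_len(nrow(ms$atoms)), ds)
  remap_c <- match(seq_len(nrow(mc$atoms)), keep_c)
  remap_s <- match(seq_len(nrow(ms$atoms)), keep_s)
  off <- length(keep_c)
  elem <- c(mc$atoms$elem[keep_c], ms$atoms$elem[keep_s])
  charge <- c(mc$atoms$charge[keep_c], ms$atoms$charge[keep_s])
  bc <- mc$bonds[mc$bonds$a1 != dc & mc$bonds$a2 != dc, , drop = FALSE]
  bs <- ms$bonds[ms$bonds$a1 != ds & ms$bonds$a2 != ds, , drop = FALSE]
  a1 <- c(remap_c[bc$a1], remap_s[bs$a1] + off, remap_c[nb_c])
  a2 <- c(remap_c[bc$a2], remap_s[bs$a2] + off, remap_s[nb_s] + off)
  ord <- c(bc$order, bs$order, 1L)
  n <- length(elem); m <- length(a1)
  hdr <- c("mol", " mmpcliff", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atom_rec <- sprintf(
    "    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0",
    elem)
  bond_rec <- sprintf("%3d%3d%3d  0  0  0  0", a1, a2, ord)
  chg <- which(charge != 0L)
  chg_rec <- if (length(chg))
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, charge[chg]), collapse = "")) else character(0)
  mb <- paste(c(hdr, atom_rec, bond_rec, chg_rec, "M  END", ""),
              collapse = "\n")
  out <- ob_convert("MOL", "CAN", mb)
  tok <- strsplit(trimws(out), "[ \t\n]")[[1]]
  if (length(tok) == 0L || !nzchar(tok[1])) NA_character_ else tok[1]
}

# Connected component containing `from` after removing bond `drop_bond`.
graph_component <- function(mol, drop_bond, from) {
  b <- mol$bonds[-drop_bond, , drop = FALSE]
  g <- igraph::graph_from_edgelist(as.matrix(b[, c("a1", "a2")]),
                                   directed = FALSE)
  nv <- nrow(mol$atoms)
  if (igraph::vcount(g) < nv) g <- igraph::add_vertices(g, nv - igraph::vcount(g))
  comp <- igraph::components(g)$membership
  which(comp == comp[from])
}

#' Generate matched molecular pairs from a compound table
#'
#' Builds a core index over all single-cut fragmentations and pairs
#' compounds that share a core with different substituents. Both paper size
#' constraints apply: each substituent has at most `max_sub_atoms` heavy
#' atoms and the two substituents differ by at most `max_sub_diff` heavy
#' atoms. When one compound pair qualifies under several shared cores only
#' the pair with the largest core is kept (ties: lexicographically smallest
#' canonical core), so a pair belongs to exactly one series. Pairs with an
#' `"AMBIGUOUS"` potency-difference label are dropped.
#'
#' @param compounds a `compound_table` (see [read_compound_table()]) or data
#'   frame with columns `cid`, `smiles`, `potency`.
#' @param max_sub_atoms,max_sub_diff heavy-atom constraints (defaults 13, 8).
#' @param ac_threshold,nonac_threshold potency-difference thresholds passed
#'   to [label_pair()].
#' @return data frame of class `mmp_table` with one row per MMP: `cid_low`,
#'   `cid_high` (by potency), `core`, `sub_low`, `sub_high`, `delta_p`,
#'   `label`.
#' @export
generate_mmps <- function(compounds, max_sub_atoms = 13L, max_sub_diff = 8L,
                          ac_threshold = 2.0, nonac_threshold = 1.0) {
  stopifnot(all(c("cid", "smiles", "potency") %in% names(compounds)))
  if (anyDuplicated(compounds$cid))
    stop("duplicate compound identifiers: ",
         paste(unique(compounds$cid[duplicated(compounds$cid)]), collapse = ", "))
  frags <- lapply(seq_len(nrow(compounds)), function(i) {
    f <- enumerate_single_cuts(compounds$smiles[i], max_sub_atoms)
    if (nrow(f)) f$row <- i
    f
  })
  frags <- do.call(rbind, frags[vapply(frags, nrow, integer(1)) > 0])
  empty <- data.frame(cid_low = character(0), cid_high = character(0),
                      core = character(0), sub_low = character(0),
                      sub_high = character(0), delta_p = numeric(0),
                      label = character(0), stringsAsFactors = FALSE)
  if (is.null(frags) || nrow(frags) == 0L) {
    class(empty) <- c("mmp_table", "data.frame"); return(empty)
  }
  cand <- list()
  for (core in unique(frags$core)) {
    fc <- frags[frags$core == core, , drop = FALSE]
    rows <- unique(fc$row)
    if (length(rows) < 2L) next
    for (ii in seq_len(length(rows) - 1L)) for (jj in seq(ii + 1L, length(rows))) {
      i <- rows[ii]; j <- rows[jj]
      subs_i <- fc[fc$row == i, , drop = FALSE]
      subs_j <- fc[fc$row == j, , drop = FALSE]
      for (si in seq_len(nrow(subs_i))) for (sj in seq_len(nrow(subs_j))) {
        if (subs_i$sub[si] == subs_j$sub[sj]) next
        if (abs(subs_i$sub_atoms[si] - subs_j$sub_atoms[sj]) > max_sub_diff) next
        cand[[length(cand) + 1L]] <- data.frame(
          i = i, j = j, core = core,
          sub_i = subs_i$sub[si], sub_j = subs_j$sub[sj],
          core_atoms = subs_i$core_atoms[si], stringsAsFactors = FALSE)
      }
    }
  }
  if (length(cand) == 0L) {
    class(empty) <- c("mmp_table", "data.frame"); return(empty)
  }
  cand <- do.call(rbind, cand)
  # one MMP per compound pair: maximum core, then smallest canonical core
  key <- paste(cand$i, cand$j)
  cand <- cand[order(key, -cand$core_atoms, cand$core), , drop = FALSE]
  cand <- cand[!duplicated(paste(cand$i, cand$j)), , drop = FALSE]

  pot <- compounds$potency
  lo <- ifelse(pot[cand$i] <= pot[cand$j], cand$i, cand$j)
  hi <- ifelse(pot[cand$i] <= pot[cand$j], cand$j, cand$i)
  sub_lo <- ifelse(pot[cand$i] <= pot[cand$j], cand$sub_i, cand$sub_j)
  sub_hi <- ifelse(pot[cand$i] <= pot[cand$j], cand$sub_j, cand$sub_i)
  delta <- pot[hi] - pot[lo]
  out <- data.frame(
    cid_low = compounds$cid[lo], cid_high = compounds$cid[hi],
    core = cand$core, sub_low = sub_lo, sub_high = sub_hi,
    delta_p = delta, label = label_pair(delta, ac_threshold, nonac_threshold),
    stringsAsFactors = FALSE)
  out <- out[out$label != "AMBIGUOUS", , drop = FALSE]
  out <- out[order(out$core, out$cid_low, out$cid_high), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("mmp_table", "data.frame")
  out
}

#' Group MMPs into matched molecular series
#'
#' Partitions an MMP table by shared core and removes series whose members
#' all carry the same label: a series used for training or evaluation must
#' contain at least one cliff and one non-cliff.
#'
#' @param mmps an `mmp_table` from [generate_mmps()].
#' @return named list of `mmp_table` subsets, one per retained core.
#' @export
group_into_mms <- function(mmps) {
  if (nrow(mmps) == 0L) return(list())
  series <- split(mmps, mmps$core)
  keep <- vapply(series, function(s) length(unique(s$label)) > 1L, logical(1))
  series[keep]
}

#' @export
print.mmp_table <- function(x, ...) {
  cat("MMP table:", nrow(x), "pairs (",
      sum(x$label == "AC"), "AC /", sum(x$label == "NON_AC"), "non-AC ),",
      length(unique(x$core)), "cores\n")
  print.data.frame(utils::head(as.data.frame(x), 10))
  if (nrow(x) > 10) cat("...", nrow(x) - 10, "more rows\n")
  invisible(x)
}
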