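# Interpretable MMP fingerprints: unfolded circular substructure identifiers
# (bond diameters 2 and 4; the diameter-0 atom-type layer is dropped so that
# every feature spans at least one bond), one sorted identifier->bit table per
# segment, and XOR/AND substituent channels. Every identifier keeps a back-map
# to the atom/bond environments that generated it, which is what allows
# feature contributions to be painted onto structures later.

.HASH_MOD <- 2147483647
# AND-channel substituent identifiers are offset so the two channels of the
# shared identifier table never collide as plain numbers
.AND_OFFSET <- 2^32

hash_ints <- function(v) {
  h <- 17
  for (x in v) h <- (h * 31 + (x %% .HASH_MOD)) %% .HASH_MOD
  h
}

#' Extract circular substructure features from a fragment
#'
#' Computes unfolded circular (Morgan-style) substructure identifiers of
#' bond diameter 2 and 4 for a fragment SMILES. The attachment point (`*`)
#' participates as a distinguishable atom type, so all features are
#' attachment-aware. Features of bond diameter 0 and 1 (bare atom types) are
#' not emitted. Each identifier records every atom/bond environment that
#' produced it.
#'
#' @param fragment a fragment SMILES with at most one `*` attachment point
#'   (plain molecules are allowed too).
#' @param radii circular radii to emit (bond diameter = 2 * radius);
#'   default `c(1, 2)`.
#' @return list of class `feature_set` with elements `ids` (sorted numeric
#'   identifiers), `env` (named list: identifier -> list of environments,
#'   each a list with `atoms` and `bonds` index vectors) and `mol` (parsed
#'   fragment).
#' @examples
#' fs <- extract_features("*CC")
#' fs$ids
#' @export
extract_features <- function(fragment, radii = c(1L, 2L)) {
  mol <- parse_mol(fragment)
  if (is.null(mol))
    return(structure(list(ids = numeric(0), env = list(), mol = NULL),
                     class = "feature_set"))
  n <- nrow(mol$atoms)
  m <- nrow(mol$bonds)
  # adjacency with bond ids
  nb <- vector("list", n); nbb <- vector("list", n)
  if (m > 0) for (k in seq_len(m)) {
    a <- mol$bonds$a1[k]; b <- mol$bonds$a2[k]
    nb[[a]] <- c(nb[[a]], b); nbb[[a]] <- c(nbb[[a]], k)
    nb[[b]] <- c(nb[[b]], a); nbb[[b]] <- c(nbb[[b]], k)
  }
  at <- mol$atoms
  inv <- vapply(seq_len(n), function(a)
    hash_ints(c(1000000 + at$z[a], at$degree[a], at$charge[a] + 10,
                at$nH[a], as.integer(at$ring[a]))), numeric(1))
  # BFS distances once per atom
  dist <- lapply(seq_len(n), function(a) {
    d <- rep(Inf, n); d[a] <- 0; frontier <- a; r <- 0
    while (length(frontier) && r < max(radii)) {
      r <- r + 1
      nxt <- unique(unlist(nb[frontier]))
      nxt <- nxt[is.infinite(d[nxt])]
      d[nxt] <- r
      frontier <- nxt
    }
    d
  })
  ids <- numeric(0); env <- list()
  prev_cnt <- rep(1L, n)
  for (r in seq_len(max(radii))) {
    newinv <- inv
    for (a in seq_len(n)) {
      if (length(nb[[a]]) == 0L) next
      o <- order(mol$bonds$order[nbb[[a]]], inv[nb[[a]]])
      code <- hash_ints(c(r, inv[a],
                          rbind(mol$bonds$order[nbb[[a]]][o],
                                inv[nb[[a]]][o])))
      newinv[a] <- code
      atoms_r <- which(dist[[a]] <= r)
      if (r %in% radii && length(atoms_r) > prev_cnt[a]) {  # grew & wanted
        bonds_r <- which(pmin(dist[[a]][mol$bonds$a1],
                              dist[[a]][mol$bonds$a2]) <= r - 1)
        key <- as.character(code)
        env[[key]] <- c(env[[key]],
                        list(list(atoms = atoms_r, bonds = bonds_r)))
        ids <- c(ids, code)
      }
      prev_cnt[a] <- length(atoms_r)
    }
    inv <- newinv
  }
  structure(list(ids = sort(unique(ids)), env = env, mol = mol),
            class = "feature_set")
}

# Session cache: canonical fragment string -> feature_set
.feature_cache <- new.env(parent = emptyenv())

cached_features <- function(fragment) {
  fs <- get0(fragment, envir = .feature_cache, inherits = FALSE)
  if (is.null(fs)) {
    fs <- extract_features(fragment)
    assign(fragment, fs, envir = .feature_cache)
  }
  fs
}

#' Fingerprint a matched molecular pair
#'
#' Builds the three-segment MMP fingerprint: core features, the XOR of the
#' two substituent feature sets (features present in exactly one
#' substituent) and their AND (features common to both). The two substituent
#' channels share one identifier vocabulary; swapping the substituents
#' leaves the fingerprint unchanged. Kernels operate directly on these
#' identifier sets, so features that later turn out to be absent from a
#' training universe still count towards self-similarity.
#'
#' @param core,sub_low,sub_high canonical fragment SMILES with `*`
#'   attachment points (one MMP row of [generate_mmps()]).
#' @return object of class `mmp_fp`: `core` (sorted identifiers), `sub`
#'   (sorted identifiers; AND-channel ids carry a fixed numeric offset),
#'   `backmap` (identifier -> environments in the named fragment) and
#'   `frags` (the three fragment strings).
#' @export
fingerprint_mmp <- function(core, sub_low, sub_high) {
  fc <- cached_features(core)
  fl <- cached_features(sub_low)
  fh <- cached_features(sub_high)
  xor_ids <- sort(c(setdiff(fl$ids, fh$ids), setdiff(fh$ids, fl$ids)))
  and_ids <- sort(intersect(fl$ids, fh$ids))
  backmap <- list()
  for (id in fc$ids)
    backmap[[as.character(id)]] <- list(core = fc$env[[as.character(id)]])
  for (id in xor_ids) {
    key <- as.character(id)
    bm <- list()
    if (!is.null(fl$env[[key]])) bm$sub_low <- fl$env[[key]]
    if (!is.null(fh$env[[key]])) bm$sub_high <- fh$env[[key]]
    backmap[[key]] <- bm
  }
  for (id in and_ids) {
    key <- as.character(id + .AND_OFFSET)
    backmap[[key]] <- list(sub_low = fl$env[[as.character(id)]],
                           sub_high = fh$env[[as.character(id)]])
  }
  structure(list(core = fc$ids,
                 sub = sort(c(xor_ids, and_ids + .AND_OFFSET)),
                 backmap = backmap,
                 frags = c(core = core, sub_low = sub_low,
                           sub_high = sub_high)),
            class = "mmp_fp")
}

# Abstract fingerprint constructor (no chemistry; used by worked examples
# and randomised tests).
new_mmp_fp <- function(core, sub, backmap = list(), frags = NULL) {
  structure(list(core = sort(unique(as.numeric(core))),
                 sub = sort(unique(as.numeric(sub))),
                 backmap = backmap, frags = frags),
            class = "mmp_fp")
}

#' Fingerprint every MMP in a table
#'
#' @param mmps an `mmp_table` from [generate_mmps()].
#' @return list of `mmp_fp`, one per row.
#' @export
mmp_fingerprints <- function(mmps) {
  lapply(seq_len(nrow(mmps)), function(i)
    fingerprint_mmp(mmps$core[i], mmps$sub_low[i], mmps$sub_high[i]))
}

#' Build the sorted feature universe of a training set
#'
#' Collects all core and substituent identifiers seen in a list of training
#' fingerprints and assigns bit positions in ascending identifier order:
#' core bits first, then the XOR channel, then the AND channel (the two
#' substituent channels share one identifier table with distinct offsets).
#' Distinct identifiers never share a bit.
#'
#' @param fps list of `mmp_fp`.
#' @return object of class `mmp_universe`: data frame with columns
#'   `segment` (`"core"`, `"sub_xor"`, `"sub_and"`), `identifier` (raw
#'   circular identifier) and `bit` (1-based, gap-free), with attributes
#'   `D_c` (core segment length) and `D_s` (substituent segment length).
#' @export
build_universe <- function(fps) {
  core_ids <- sort(unique(unlist(lapply(fps, `[[`, "core"))))
  sub_tagged <- sort(unique(unlist(lapply(fps, `[[`, "sub"))))
  raw_sub <- sort(unique(ifelse(sub_tagged >= .AND_OFFSET,
                                sub_tagged - .AND_OFFSET, sub_tagged)))
  if (length(core_ids) == 0L)
    warning("empty core feature segment in training universe")
  if (length(raw_sub) == 0L)
    warning("empty substituent feature segment in training universe")
  D_c <- length(core_ids); m <- length(raw_sub)
  uni <- rbind(
    data.frame(segment = rep("core", D_c),
               identifier = core_ids,
               bit = seq_len(D_c)),
    data.frame(segment = rep("sub_xor", m),
               identifier = raw_sub,
               bit = D_c + seq_len(m)),
    data.frame(segment = rep("sub_and", m),
               identifier = raw_sub,
               bit = D_c + m + seq_len(m))
  )
  structure(uni, D_c = D_c, D_s = 2L * m,
            class = c("mmp_universe", "data.frame"))
}

# On-bits of a fingerprint under a universe, plus unmapped identifiers.
fp_bits <- function(fp, universe) {
  co <- universe[universe$segment == "core", ]
  xo <- universe[universe$segment == "sub_xor", ]
  an <- universe[universe$segment == "sub_and", ]
  is_and <- fp$sub >= .AND_OFFSET
  raw <- ifelse(is_and, fp$sub - .AND_OFFSET, fp$sub)
  core_on <- co$bit[match(fp$core, co$identifier)]
  sub_on <- ifelse(is_and, an$bit[match(raw, an$identifier)],
                   xo$bit[match(raw, xo$identifier)])
  list(core_on = sort(core_on[!is.na(core_on)]),
       sub_on = sort(sub_on[!is.na(sub_on)]),
       unmapped = c(fp$core[is.na(core_on)], fp$sub[is.na(sub_on)]))
}

# segment of a tagged substituent identifier / raw core identifier
id_segment <- function(id, where = c("core", "sub")) {
  where <- match.arg(where)
  if (where == "core") return("core")
  ifelse(id >= .AND_OFFSET, "sub_and", "sub_xor")
}

#' @export
print.mmp_fp <- function(x, ...) {
  nand <- sum(x$sub >= .AND_OFFSET)
  cat("MMP fingerprint:", length(x$core), "core features,",
      length(x$sub) - nand, "XOR +", nand, "AND substituent features\n")
  if (!is.null(x$frags))
    cat("  core:", x$frags[["core"]], " subs:", x$frags[["sub_low"]],
        "->", x$frags[["sub_high"]], "\n")
  invisible(x)
}

#' @export
print.mmp_universe <- function(x, ...) {
  cat("MMP feature universe: D_c =", attr(x, "D_c"),
      ", D_s =", attr(x, "D_s"), "\n")
  invisible(x)
}
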