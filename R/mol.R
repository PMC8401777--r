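# Internal molecular-graph layer on top of OpenBabel (via ChemmineOB/ChemmineR).
# Molecules are held as a pair of data frames (atoms, bonds) built from a V2000
# connection table; hydrogens are implicit throughout, attachment points are
# dummy atoms with element "*".

# old-style MOL charge codes -> formal charge
.chg_code <- c(`1` = 3L, `2` = 2L, `3` = 1L, `5` = -1L, `6` = -2L, `7` = -3L)

.elem_z <- c(
  "*" = 0L, H = 1L, B = 5L, C = 6L, N = 7L, O = 8L, F = 9L, Si = 14L,
  P = 15L, S = 16L, Cl = 17L, Br = 35L, I = 53L
)

.default_valence <- c(
  `0` = 1, `5` = 3, `6` = 4, `7` = 3, `8` = 2, `9` = 1, `14` = 4,
  `15` = 3, `16` = 2, `17` = 1, `35` = 1, `53` = 1
)

#' @keywords internal
#' @noRd
ob_convert <- function(from, to, input) {
  out <- tryCatch(ChemmineOB::convertFormat(from, to, input),
                  error = function(e) "")
  out
}

# Canonicalize a SMILES string; NA_character_ on parse failure.
canonical_smiles <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s) || !nzchar(s)) return(NA_character_)
    out <- ob_convert("SMI", "CAN", s)
    tok <- strsplit(trimws(out), "[ \t\n]")[[1]]
    if (length(tok) == 0L || !nzchar(tok[1])) NA_character_ else tok[1]
  }, character(1), USE.NAMES = FALSE)
}

# Keep the largest covalent fragment of a dot-disconnected SMILES (salt strip).
# Ties broken in favour of carbon-containing fragments, then lexicographically.
strip_salts <- function(smiles) {
  vapply(smiles, function(s) {
    if (is.na(s)) return(NA_character_)
    parts <- strsplit(s, ".", fixed = TRUE)[[1]]
    if (length(parts) == 1L) return(s)
    ha <- vapply(parts, count_heavy_atoms_smiles, numeric(1))
    hasC <- grepl("C|c", parts)
    ord <- order(-ha, -hasC, parts)
    parts[ord][1]
  }, character(1), USE.NAMES = FALSE)
}

# Cheap heavy-atom count straight off a SMILES string (H and * excluded).
count_heavy_atoms_smiles <- function(s) {
  if (is.na(s)) return(NA_real_)
  # bracket atoms count once unless they are *, H
  brackets <- gregexpr("\\[[^]]*\\]", s)[[1]]
  n <- 0
  if (brackets[1] != -1) {
    for (i in seq_along(brackets)) {
      b <- substr(s, brackets[i], brackets[i] + attr(brackets, "match.length")[i] - 1L)
      if (!grepl("^\\[\\*?\\]$", b) && !grepl("^\\[[0-9]*H[0-9]*[+-]?[0-9]*\\]$", b))
        n <- n + 1
    }
    s <- gsub("\\[[^]]*\\]", "", s)
  }
  # two-letter organic-subset elements first
  for (el in c("Cl", "Br")) {
    m <- gregexpr(el, s)[[1]]
    if (m[1] != -1) n <- n + length(m)
    s <- gsub(el, "", s)
  }
  n + length(gregexpr("[BCNOPSFI]|[bcnops]", s)[[1]][gregexpr("[BCNOPSFI]|[bcnops]", s)[[1]] > 0])
}

# Parse a (preferably canonical) SMILES into an internal molecule:
# list(atoms = data.frame(elem, z, charge, nH, ring), bonds = data.frame(a1, a2,
# order, ring), smiles = canonical form). Returns NULL on failure.
parse_mol <- function(smiles, canonicalize = TRUE) {
  can <- if (canonicalize) canonical_smiles(smiles) else smiles
  if (is.na(can)) return(NULL)
  molblock <- ob_convert("SMI", "MOL", can)
  if (!nzchar(molblock)) return(NULL)
  mol_from_molblock(molblock, smiles = can)
}

mol_from_molblock <- function(molblock, smiles = NA_character_) {
  lines <- strsplit(molblock, "\n", fixed = TRUE)[[1]]
  if (length(lines) < 4L) return(NULL)
  ci <- grep("V2000", lines)[1]
  if (is.na(ci)) ci <- 4L
  counts <- lines[ci]
  natoms <- suppressWarnings(as.integer(substr(counts, 1, 3)))
  nbonds <- suppressWarnings(as.integer(substr(counts, 4, 6)))
  if (is.na(natoms) || is.na(nbonds)) return(NULL)
  if (natoms == 0L) return(NULL)
  atom_lines <- lines[ci + seq_len(natoms)]
  elem <- trimws(substr(atom_lines, 32, 34))
  chg_code <- suppressWarnings(as.integer(substr(atom_lines, 37, 39)))
  charge <- ifelse(is.na(chg_code) | chg_code == 0L, 0L,
                   unname(.chg_code[as.character(chg_code)]))
  charge[is.na(charge)] <- 0L
  x <- suppressWarnings(as.numeric(substr(atom_lines, 1, 10)))
  y <- suppressWarnings(as.numeric(substr(atom_lines, 11, 20)))
  if (nbonds > 0L) {
    bond_lines <- lines[ci + natoms + seq_len(nbonds)]
    a1 <- as.integer(substr(bond_lines, 1, 3))
    a2 <- as.integer(substr(bond_lines, 4, 6))
    order <- as.integer(substr(bond_lines, 7, 9))
  } else {
    a1 <- a2 <- order <- integer(0)
  }
  # "M  CHG" property lines override old-style codes
  for (ln in grep("^M  CHG", lines, value = TRUE)) {
    f <- as.integer(strsplit(trimws(substr(ln, 7, nchar(ln))), "\\s+")[[1]])
    k <- f[1]
    if (!is.na(k) && k > 0) {
      idx <- f[2 * seq_len(k)]
      val <- f[2 * seq_len(k) + 1]
      charge[idx] <- val
    }
  }
  z <- unname(.elem_z[elem])
  z[is.na(z)] <- 99L  # unusual elements: distinct catch-all type
  bonds <- data.frame(a1 = a1, a2 = a2, order = order)
  bonds$ring <- ring_bonds(natoms, bonds)
  deg <- tabulate(c(a1, a2), nbins = natoms)
  bsum <- rep(0, natoms)
  if (nbonds > 0L) for (i in seq_len(nbonds)) {
    bsum[a1[i]] <- bsum[a1[i]] + order[i]
    bsum[a2[i]] <- bsum[a2[i]] + order[i]
  }
  val <- unname(.default_valence[as.character(z)])
  val[is.na(val)] <- 0
  # positive charge raises the bonding capacity of N/O/S-type atoms,
  # negative charge lowers it; crude but deterministic
  nH <- pmax(0, round(val + charge - bsum))
  nH[z == 0L] <- 0
  atoms <- data.frame(
    elem = elem, z = z, charge = charge, nH = nH,
    ring = atom_in_ring(natoms, bonds), degree = deg, x = x, y = y
  )
  list(atoms = atoms, bonds = bonds, smiles = smiles)
}

# A bond is in a ring iff it is not a bridge of the molecular graph.
ring_bonds <- function(natoms, bonds) {
  if (nrow(bonds) == 0L) return(logical(0))
  g <- igraph::graph_from_edgelist(as.matrix(bonds[, c("a1", "a2")]),
                                   directed = FALSE)
  if (igraph::vcount(g) < natoms) g <- igraph::add_vertices(g, natoms - igraph::vcount(g))
  br <- igraph::bridges(g)
  res <- rep(TRUE, nrow(bonds))
  res[as.integer(br)] <- FALSE
  res
}

atom_in_ring <- function(natoms, bonds) {
  inring <- rep(FALSE, natoms)
  rb <- bonds[bonds$ring, , drop = FALSE]
  inring[c(rb$a1, rb$a2)] <- TRUE
  inring
}

heavy_atoms <- function(mol) sum(mol$atoms$z > 1L)

# Write a V2000 molblock for an atom subset of `mol`, with an optional dummy
# attachment atom bonded to `attach_at` (an index into `keep`-space atoms).
subgraph_molblock <- function(mol, keep, attach_to = NA_integer_) {
  keep <- sort(keep)
  idx <- match(seq_len(nrow(mol$atoms)), keep)  # old -> new
  atoms <- mol$atoms[keep, , drop = FALSE]
  bonds <- mol$bonds[mol$bonds$a1 %in% keep & mol$bonds$a2 %in% keep, , drop = FALSE]
  elem <- atoms$elem
  charge <- atoms$charge
  a1 <- idx[bonds$a1]; a2 <- idx[bonds$a2]; ord <- bonds$order
  if (!is.na(attach_to)) {
    elem <- c(elem, "*")
    charge <- c(charge, 0L)
    a1 <- c(a1, idx[attach_to]); a2 <- c(a2, length(elem)); ord <- c(ord, 1L)
  }
  n <- length(elem); m <- length(a1)
  hdr <- c("fragment", " mmpcliff", "",
           sprintf("%3d%3d  0  0  0  0  0  0  0  0999 V2000", n, m))
  atom_rec <- sprintf("    0.0000    0.0000    0.0000 %-3s 0  0  0  0  0  0  0  0  0  0  0  0", elem)
  bond_rec <- sprintf("%3d%3d%3d  0  0  0  0", a1, a2, ord)
  chg <- which(charge != 0L)
  chg_rec <- if (length(chg))
    sprintf("M  CHG%3d%s", length(chg),
            paste0(sprintf("%4d%4d", chg, charge[chg]), collapse = "")) else character(0)
  paste(c(hdr, atom_rec, bond_rec, chg_rec, "M  END", ""), collapse = "\n")
}

# Canonical SMILES of an atom subset (with attachment dummy); NA on failure.
fragment_smiles <- function(mol, keep, attach_to = NA_integer_) {
  mb <- subgraph_molblock(mol, keep, attach_to)
  out <- ob_convert("MOL", "CAN", mb)
  tok <- strsplit(trimws(out), "[ \t\n]")[[1]]
  if (length(tok) == 0L || !nzchar(tok[1])) NA_character_ else tok[1]
}
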