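# Gold-standard contact grids from protein-RNA complex coordinates.
# A residue and a base are in contact when the minimum Euclidean distance
# between any atom of one and any atom of the other is <= the threshold
# (3 A or 5 A; hydrogen bonds span roughly 2.7-2.9 A). Crystallographic
# entries typically lack hydrogens, so in practice this is a heavy-atom
# distance; no atom filtering is applied.

AA3TO1 <- c(ALA = "A", ARG = "R", ASN = "N", ASP = "D", CYS = "C",
            GLN = "Q", GLU = "E", GLY = "G", HIS = "H", ILE = "I",
            LEU = "L", LYS = "K", MET = "M", PHE = "F", PRO = "P",
            SER = "S", THR = "T", TRP = "W", TYR = "Y", VAL = "V",
            MSE = "M")
RNA3TO1 <- c(A = "A", C = "C", G = "G", U = "U",
             PSU = "U", H2U = "U", `5MU` = "U", `4SU` = "U",
             `1MA` = "A", `5MC` = "C", OMC = "C",
             `2MG` = "G", `7MG` = "G", M2G = "G", OMG = "G")

#' Chain coordinates container
#'
#' @param codes Character vector of one-letter residue/base codes, in chain
#'   order.
#' @param atoms List (same length) of numeric matrices with columns x, y, z.
#' @return An `rb_chain`.
#' @export
chain_coordinates <- function(codes, atoms) {
  stopifnot(length(codes) == length(atoms), length(codes) >= 1L)
  atoms <- lapply(atoms, function(a) {
    a <- as.matrix(a)
    if (nrow(a) < 1L || ncol(a) != 3L) stop("each unit needs >= 1 atom with x,y,z")
    a
  })
  structure(list(codes = as.character(codes), atoms = atoms),
            class = "rb_chain")
}

#' @export
print.rb_chain <- function(x, ...) {
  cat(sprintf("chain: %d units, %d atoms\n", length(x$codes),
              sum(vapply(x$atoms, nrow, 0L))))
  invisible(x)
}

#' Read one chain from a PDB-format coordinate file
#'
#' Parses fixed-column ATOM/HETATM records of the named author chain,
#' keeping the first alternate location of each atom and mapping residue
#' names to one-letter codes (standard amino acids plus MSE; standard and
#' common modified ribonucleotides). Waters are skipped; any other unknown
#' residue name is an error.
#'
#' @param path PDB file path.
#' @param chain Author chain identifier (single character).
#' @param kind `"protein"` or `"rna"`.
#' @return An `rb_chain`.
#' @export
read_pdb_chain <- function(path, chain, kind = c("protein", "rna")) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  lines <- lines[substr(lines, 1, 6) %in% c("ATOM  ", "HETATM")]
  lines <- lines[substr(lines, 22, 22) == chain]
  if (length(lines) == 0L) stop("no atoms found for chain '", chain, "'")
  resname <- trimws(substr(lines, 18, 20))
  keep <- resname != "HOH"
  lines <- lines[keep]
  resname <- resname[keep]
  altloc <- substr(lines, 17, 17)
  atomname <- trimws(substr(lines, 13, 16))
  resid <- paste0(trimws(substr(lines, 23, 26)), substr(lines, 27, 27))
  # first altloc per (residue, atom name)
  first <- !duplicated(paste(resid, atomname, sep = "|"))
  lines <- lines[first]
  resname <- resname[first]
  resid <- resid[first]
  xyz <- cbind(as.numeric(substr(lines, 31, 38)),
               as.numeric(substr(lines, 39, 46)),
               as.numeric(substr(lines, 47, 54)))
  map <- if (kind == "protein") AA3TO1 else RNA3TO1
  units <- unique(resid)
  codes <- character(length(units))
  atoms <- vector("list", length(units))
  for (k in seq_along(units)) {
    sel <- resid == units[k]
    rn <- resname[sel][1]
    if (!rn %in% names(map)) {
      stop("unknown ", kind, " residue name '", rn, "' in chain ", chain)
    }
    codes[k] <- map[[rn]]
    atoms[[k]] <- xyz[sel, , drop = FALSE]
  }
  chain_coordinates(codes, atoms)
}

#' Minimum inter-atomic distance between two units
#'
#' @param unit_a,unit_b Numeric matrices of atom coordinates (columns
#'   x, y, z), each with at least one row.
#' @return Minimum pairwise Euclidean distance in Angstrom.
#' @export
min_atom_distance <- function(unit_a, unit_b) {
  unit_a <- as.matrix(unit_a)
  unit_b <- as.matrix(unit_b)
  if (nrow(unit_a) < 1L || nrow(unit_b) < 1L) stop("empty atom list")
  # |a-b|^2 = |a|^2 + |b|^2 - 2 a.b, over all cross pairs
  d2 <- outer(rowSums(unit_a^2), rowSums(unit_b^2), `+`) -
    2 * tcrossprod(unit_a, unit_b)
  sqrt(max(0, min(d2)))
}

#' Binary contact grid from chain coordinates
#'
#' `r_ij = 1` iff the minimum any-atom distance between residue `i` and
#' base `j` is at most `threshold`. When target sequences are supplied the
#' chain codes must reproduce them exactly (no silent renumbering of
#' missing residues).
#'
#' @param protein,rna `rb_chain` objects.
#' @param threshold Distance threshold in Angstrom (> 0), typically 3 or 5.
#' @param protein_seq,rna_seq Optional target sequences to validate against.
#' @return Integer `Np x Nr` binary matrix.
#' @export
extract_contacts <- function(protein, rna, threshold,
                             protein_seq = NULL, rna_seq = NULL) {
  stopifnot(inherits(protein, "rb_chain"), inherits(rna, "rb_chain"),
            threshold > 0)
  check_seq <- function(chain, seq, what) {
    if (is.null(seq)) return(invisible())
    seq <- if (length(seq) == 1L) strsplit(seq, "", fixed = TRUE)[[1]] else seq
    if (!identical(chain$codes, as.character(seq))) {
      stop(what, " chain sequence does not match the target sequence")
    }
  }
  check_seq(protein, protein_seq, "protein")
  check_seq(rna, rna_seq, "rna")
  Np <- length(protein$codes)
  Nr <- length(rna$codes)
  grid <- matrix(0L, Np, Nr)
  for (i in seq_len(Np)) {
    for (j in seq_len(Nr)) {
      if (min_atom_distance(protein$atoms[[i]], rna$atoms[[j]]) <= threshold) {
        grid[i, j] <- 1L
      }
    }
  }
  grid
}
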