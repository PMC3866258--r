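# Mutual information between protein and RNA alignment columns, and its
# average-product-corrected variant (MIp) adapted to the rectangular
# residue-base setting:
#
#   m_ij   = sum_{a,b} P_ij(a,b) log( P_ij(a,b) / (P_i(a) P_j(b)) )
#   m^p_ij = m_ij - (sum_k m_ik)(sum_k m_kj) / (sum_ij m_ij)
#
# Frequencies are raw counts over organism-paired alignment rows divided by
# the number of pairs; the alphabet is the (optionally grouped) amino acids
# plus gap on one side and {A,C,G,U,gap} on the other. Natural logarithm.

# Grouped 0-based index matrices over paired rows, list(pa, pb, Ka, Kb).
paired_index_matrices <- function(paired, grouping) {
  stopifnot(inherits(paired, "rb_paired"), inherits(grouping, "rb_grouping"))
  pm <- paired$protein$seq_mat[paired$pairs[, 1], , drop = FALSE]
  rm_ <- paired$rna$seq_mat[paired$pairs[, 2], , drop = FALSE]
  pa <- matrix(protein_group_index(pm, grouping), nrow = nrow(pm))
  pb <- matrix(rna_base_index(rm_), nrow = nrow(rm_))
  list(pa = pa, pb = pb, Ka = grouping$group_count + 1L, Kb = 5L)
}

#' Joint and marginal column frequencies for one position pair
#'
#' Counts symbol frequencies at protein position `i` and RNA position `j`
#' over the organism-paired rows, under an optional reduced amino-acid
#' alphabet (gap forms its own extra class). Marginals are computed from
#' the joint counts, so they match its row/column sums exactly.
#'
#' @param paired An `rb_paired` alignment set.
#' @param i Protein position (1-based).
#' @param j RNA position (1-based).
#' @param grouping An `rb_grouping` (default: identity, 20 classes).
#' @return List with `P_i`, `P_j` (named numeric vectors) and `P_ij`
#'   (matrix, rows = grouped amino-acid classes + gap, cols = bases + gap).
#' @export
joint_frequencies <- function(paired, i, j, grouping = grouping_scheme(20)) {
  idx <- paired_index_matrices(paired, grouping)
  if (i < 1L || i > ncol(idx$pa)) stop("protein position out of range: ", i)
  if (j < 1L || j > ncol(idx$pb)) stop("RNA position out of range: ", j)
  n <- nrow(idx$pa)
  code <- idx$pa[, i] * idx$Kb + idx$pb[, j]
  cnt <- tabulate(code + 1L, idx$Ka * idx$Kb) / n
  P_ij <- matrix(cnt, nrow = idx$Ka, ncol = idx$Kb, byrow = TRUE)
  dimnames(P_ij) <- list(c(grouping$classes, GAP), c(RNA4, GAP))
  list(P_i = rowSums(P_ij), P_j = colSums(P_ij), P_ij = P_ij)
}

#' Mutual information matrix between protein and RNA positions
#'
#' Computes `m_ij` for every (protein position, RNA position) cell from the
#' organism-paired rows, with the convention `0 log 0 = 0` and natural
#' logarithms. The magnitude scale (nats) is immaterial downstream: both the
#' CRF and AUC ranking are invariant to a positive rescaling of `m`.
#'
#' @inheritParams joint_frequencies
#' @return An `Np x Nr` numeric matrix of class `rb_mi` with
#'   `attr(, "kind") == "MI"`.
#' @export
mutual_information <- function(paired, grouping = grouping_scheme(20)) {
  idx <- paired_index_matrices(paired, grouping)
  Np <- ncol(idx$pa)
  Nr <- ncol(idx$pb)
  n <- nrow(idx$pa)
  Ka <- idx$Ka
  Kb <- idx$Kb
  Pb_all <- lapply(seq_len(Nr), function(j) tabulate(idx$pb[, j] + 1L, Kb) / n)
  vals <- matrix(0, Np, Nr)
  for (i in seq_len(Np)) {
    ai <- idx$pa[, i]
    Pa <- tabulate(ai + 1L, Ka) / n
    base <- ai * Kb
    for (j in seq_len(Nr)) {
      cnt <- tabulate(base + idx$pb[, j] + 1L, Ka * Kb) / n
      denom <- rep(Pa, each = Kb) * rep.int(Pb_all[[j]], Ka)
      nz <- cnt > 0
      vals[i, j] <- sum(cnt[nz] * log(cnt[nz] / denom[nz]))
    }
  }
  structure(vals, kind = "MI", class = c("rb_mi", "matrix", "array"))
}

#' Average-product correction for residue-base mutual information
#'
#' Subtracts the background term `(row sum x column sum) / grand total`
#' from each cell, removing signal shared by whole rows or columns of the
#' MI matrix (phylogenetic and entropic bias). The corrected matrix sums
#' to zero; individual entries may be negative. When the grand total is
#' zero the correction is defined as zero.
#'
#' @param mi An `rb_mi` matrix of kind `"MI"`.
#' @return The corrected matrix, kind `"MIp"`.
#' @export
apc_correction <- function(mi) {
  if (!identical(attr(mi, "kind"), "MI")) stop("input must be an MI matrix")
  tot <- sum(mi)
  vals <- unclass(mi)
  attr(vals, "kind") <- NULL
  if (tot != 0) {
    vals <- vals - outer(rowSums(vals), colSums(vals)) / tot
  }
  structure(vals, kind = "MIp", class = c("rb_mi", "matrix", "array"))
}

#' Write / read an MI matrix as TSV
#'
#' Rows are protein positions, columns RNA positions, with 1-based headers.
#'
#' @param mi Matrix to write.
#' @param path File path.
#' @return `read_mi_tsv` returns a plain numeric matrix.
#' @export
write_mi_tsv <- function(mi, path) {
  m <- as.matrix(unclass(mi))
  df <- data.frame(pos = seq_len(nrow(m)), m, check.names = FALSE)
  colnames(df) <- c("pos", seq_len(ncol(m)))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_mi_tsv
#' @export
read_mi_tsv <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE)
  as.matrix(df[, -1, drop = FALSE], rownames.force = FALSE)
}
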