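# Grid-structured conditional random field over residue-base contact
# indicators r_ij in {0,1}. Each grid cell (i,j) carries a local potential
#
#   U_ij(r, y) = w_f . f_ij(r_ij, y)  +  w_g . sum_{(k,l) in N_ij} g_ijkl(r_ij, r_kl, y)
#
# with N_ij = {(i+/-1, j), (i, j+/-1)} and Pr(r_ij = v | r_Nij, y) taken
# proportional to exp(-U_ij) with r_ij set to v. Three feature families:
#
#   family 1 (MI only):      f = [r; rbar] (x) [1; m_ij]
#                            g = [r_ij; rbar_ij] (x) [r_kl; rbar_kl] (x) [1; m_kl]
#   family 2 (MI + labels):  delta(a_i, b_j) inserted before [1; m]
#   family 3 (labels only):  [1; m] replaced by delta(a, b)
#
# delta(a, b) is the one-hot indicator of the (grouped residue, base) pair,
# length G*4 (80 when ungrouped). Note that the pair features g take their
# observations at the NEIGHBOR position (m_kl, a_k, b_l); that asymmetry is
# kept exactly as defined.

#' CRF feature configuration
#'
#' Fixes the feature family and amino-acid grouping and derives the feature
#' dimensions: family 1 has `f_dim = 4`, `g_dim = 8`; family 2 has
#' `f_dim = 2*(G*4)*2`, `g_dim = 4*(G*4)*2`; family 3 has `f_dim = 2*(G*4)`,
#' `g_dim = 4*(G*4)`, where `G` is the number of amino-acid classes.
#'
#' @param family Feature family, 1, 2 or 3.
#' @param grouping An `rb_grouping` (default identity, 20 classes).
#' @return An `rb_feature_config`.
#' @export
feature_config <- function(family = 1, grouping = grouping_scheme(20)) {
  family <- as.integer(family)
  stopifnot(family %in% 1:3, inherits(grouping, "rb_grouping"))
  G4 <- grouping$group_count * 4L
  block <- switch(family, 2L, G4 * 2L, G4)
  structure(
    list(family = family, grouping = grouping, G4 = G4,
         block = block, f_dim = 2L * block, g_dim = 4L * block),
    class = "rb_feature_config"
  )
}

#' @export
print.rb_feature_config <- function(x, ...) {
  cat(sprintf("CRF features: family %d, %s amino-acid classes, f_dim=%d, g_dim=%d\n",
              x$family, x$grouping$name, x$f_dim, x$g_dim))
  invisible(x)
}

#' CRF parameter set
#'
#' @param config An `rb_feature_config`.
#' @param w_f,w_g Numeric weight vectors of lengths `f_dim` and `g_dim`
#'   (default zeros).
#' @return An `rb_params` with elements `w_f`, `w_g` and the config.
#' @export
crf_params <- function(config, w_f = NULL, w_g = NULL) {
  stopifnot(inherits(config, "rb_feature_config"))
  if (is.null(w_f)) w_f <- numeric(config$f_dim)
  if (is.null(w_g)) w_g <- numeric(config$g_dim)
  if (length(w_f) != config$f_dim) stop("w_f must have length ", config$f_dim)
  if (length(w_g) != config$g_dim) stop("w_g must have length ", config$g_dim)
  structure(list(w_f = as.numeric(w_f), w_g = as.numeric(w_g),
                 config = config), class = "rb_params")
}

#' One labeled/unlabeled prediction unit
#'
#' Bundles the (gap-free) target protein and RNA sequences, their MI or MIp
#' matrix, and optionally the binary contact grid used as training label.
#'
#' @param a Protein sequence (string or character vector), length `Np`.
#' @param b RNA sequence, length `Nr`.
#' @param m `Np x Nr` mutual-information matrix.
#' @param r Optional `Np x Nr` binary contact grid.
#' @return An `rb_instance`.
#' @export
protein_rna_instance <- function(a, b, m, r = NULL) {
  a <- if (length(a) == 1L) strsplit(a, "", fixed = TRUE)[[1]] else as.character(a)
  b <- if (length(b) == 1L) strsplit(b, "", fixed = TRUE)[[1]] else as.character(b)
  if (any(a == GAP) || any(b == GAP)) stop("target sequences must be gap-free")
  m <- as.matrix(m)
  if (nrow(m) != length(a) || ncol(m) != length(b)) {
    stop("MI matrix dimensions must be length(a) x length(b)")
  }
  if (!is.null(r)) {
    r <- as.matrix(r)
    storage.mode(r) <- "integer"
    if (!all(dim(r) == dim(m))) stop("contact grid dimensions must match m")
    if (!all(r %in% c(0L, 1L))) stop("contact grid must be binary")
  }
  structure(list(a = a, b = b, m = m, r = r), class = "rb_instance")
}

#' @export
print.rb_instance <- function(x, ...) {
  cat(sprintf("protein-RNA instance: Np=%d, Nr=%d, %s\n",
              length(x$a), length(x$b),
              if (is.null(x$r)) "unlabeled" else
                sprintf("%d contacts", sum(x$r))))
  invisible(x)
}

#' Grid neighborhood of a cell
#'
#' In-bounds members of `{(i-1,j), (i+1,j), (i,j-1), (i,j+1)}`, in that
#' (up, down, left, right) order.
#'
#' @param i,j Cell coordinates (1-based).
#' @param np,nr Grid dimensions.
#' @return List of integer pairs `c(k, l)`.
#' @export
grid_neighbors <- function(i, j, np, nr) {
  stopifnot(i >= 1L, i <= np, j >= 1L, j <= nr)
  cand <- list(c(i - 1L, j), c(i + 1L, j), c(i, j - 1L), c(i, j + 1L))
  Filter(function(p) p[1] >= 1L && p[1] <= np && p[2] >= 1L && p[2] <= nr, cand)
}

# 0-based index of the one-hot delta(a, b) block: grouped residue major,
# base minor. Target sequences are degapped so gaps never reach here.
delta_index <- function(config, a, b) {
  g <- config$grouping$mapping[a]
  bi <- match(b, RNA4) - 1L
  if (anyNA(g)) stop("unknown residue character: ", paste(a[is.na(g)], collapse = " "))
  if (anyNA(bi)) stop("unknown base character: ", paste(b[is.na(bi)], collapse = " "))
  unname(g * 4L + bi)
}

check_state <- function(r) {
  if (!(length(r) == 1L && r %in% c(0, 1))) stop("state must be 0 or 1")
  as.integer(r)
}

#' Local feature vector f_ij
#'
#' Explicit (sparse-by-construction) feature vector of the chosen family for
#' one cell: at most two coordinates are nonzero.
#'
#' @param config An `rb_feature_config`.
#' @param r_ij Cell state, 0 or 1.
#' @param m_ij Mutual information at the cell (ignored by family 3).
#' @param a_i,b_j Residue and base characters (ignored by family 1).
#' @return Numeric vector of length `config$f_dim`.
#' @export
feature_f <- function(config, r_ij, m_ij = NULL, a_i = NULL, b_j = NULL) {
  r_ij <- check_state(r_ij)
  s <- 1L - r_ij  # [r; rbar]: the r=1 block comes first
  v <- numeric(config$f_dim)
  if (config$family == 1L) {
    v[s * 2L + 1L] <- 1
    v[s * 2L + 2L] <- m_ij
  } else if (config$family == 2L) {
    base <- (s * config$G4 + delta_index(config, a_i, b_j)) * 2L
    v[base + 1L] <- 1
    v[base + 2L] <- m_ij
  } else {
    v[s * config$G4 + delta_index(config, a_i, b_j) + 1L] <- 1
  }
  v
}

#' Pairwise feature vector g_ijkl
#'
#' Feature vector coupling the states of cell (i,j) and neighbor (k,l).
#' Observations (`m_kl`, `a_k`, `b_l`) are those of the neighbor.
#'
#' @param config An `rb_feature_config`.
#' @param r_ij,r_kl States of the cell and its neighbor, each 0 or 1.
#' @param m_kl Mutual information at the neighbor (families 1, 2).
#' @param a_k,b_l Neighbor residue/base characters (families 2, 3).
#' @return Numeric vector of length `config$g_dim`.
#' @export
feature_g <- function(config, r_ij, r_kl, m_kl = NULL, a_k = NULL, b_l = NULL) {
  u <- (1L - check_state(r_ij)) * 2L + (1L - check_state(r_kl))
  v <- numeric(config$g_dim)
  if (config$family == 1L) {
    v[u * 2L + 1L] <- 1
    v[u * 2L + 2L] <- m_kl
  } else if (config$family == 2L) {
    base <- (u * config$G4 + delta_index(config, a_k, b_l)) * 2L
    v[base + 1L] <- 1
    v[base + 2L] <- m_kl
  } else {
    v[u * config$G4 + delta_index(config, a_k, b_l) + 1L] <- 1
  }
  v
}

#' Local potential U_ij
#'
#' Direct evaluation of the cell potential for a full state grid `r`,
#' summing the pairwise features over the in-bounds neighbors only.
#'
#' @param params An `rb_params`.
#' @param config An `rb_feature_config`.
#' @param instance An `rb_instance`.
#' @param r Binary state grid (`Np x Nr`).
#' @param i,j Cell coordinates.
#' @param state Optional state of cell (i,j) overriding `r[i, j]`.
#' @return Scalar potential value.
#' @export
local_potential <- function(params, config, instance, r, i, j,
                            state = r[i, j]) {
  u <- sum(params$w_f * feature_f(config, state, instance$m[i, j],
                                  instance$a[i], instance$b[j]))
  for (kl in grid_neighbors(i, j, nrow(r), ncol(r))) {
    k <- kl[1]; l <- kl[2]
    u <- u + sum(params$w_g * feature_g(config, state, r[k, l],
                                        instance$m[k, l],
                                        instance$a[k], instance$b[l]))
  }
  u
}

#' Local conditional probability of a cell state
#'
#' `Pr(r_ij = state | r_Nij, y) = exp(-U_ij(state)) / sum_v exp(-U_ij(v))`,
#' computed stably through the logistic function. Only the cell's own
#' potential enters the conditional, mirroring the pseudo-likelihood
#' factorization used in training.
#'
#' @inheritParams local_potential
#' @param log_p Return the log probability.
#' @return Probability (or log probability) of `state`.
#' @export
local_conditional <- function(params, config, instance, r, i, j,
                              state = r[i, j], log_p = FALSE) {
  u0 <- local_potential(params, config, instance, r, i, j, state = 0L)
  u1 <- local_potential(params, config, instance, r, i, j, state = 1L)
  # Pr(1) = logistic(u0 - u1)
  x <- if (check_state(state) == 1L) u0 - u1 else u1 - u0
  stats::plogis(x, log.p = log_p)
}
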