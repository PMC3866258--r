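# Internal vectorized evaluation of the pseudo-likelihood.
#
# For a fixed conditioning grid the potential is linear in the parameters:
# U_v = Xf_v w_f + Xg_v w_g, where row p of Xf_v is f_ij(v, y) for cell p and
# row p of Xg_v is the neighbor-summed pairwise feature with the cell in
# state v and the neighbors clamped at the conditioning states. Both are
# extremely sparse (<= 2 nonzeros per cell per block), so the whole
# pseudo-likelihood and its gradient reduce to a handful of sparse
# matrix-vector products. The literal feature_f()/feature_g() path is kept
# as the reference implementation and cross-checked in the tests.

# delta indices (0-based) for every cell, Np x Nr.
delta_index_matrix <- function(config, instance) {
  g <- config$grouping$mapping[instance$a]
  bi <- match(instance$b, RNA4) - 1L
  if (anyNA(g) || anyNA(bi)) stop("instance sequences contain unknown characters")
  outer(unname(g) * 4L, unname(bi), `+`)
}

# Column indices/values of the f-feature block for state v at all cells.
# Returns list(j1, x1, j2, x2) with j2/x2 NULL for family 3.
f_columns <- function(config, v, d, m) {
  s <- 1L - v
  if (config$family == 1L) {
    list(j1 = rep.int(s * 2L + 1L, length(m)), x1 = rep.int(1, length(m)),
         j2 = rep.int(s * 2L + 2L, length(m)), x2 = m)
  } else if (config$family == 2L) {
    base <- (s * config$G4 + d) * 2L
    list(j1 = base + 1L, x1 = rep.int(1, length(m)), j2 = base + 2L, x2 = m)
  } else {
    list(j1 = s * config$G4 + d + 1L, x1 = rep.int(1, length(m)),
         j2 = NULL, x2 = NULL)
  }
}

# Column indices/values of the g-feature block for (cell state v, neighbor
# state vn), with observations (d, m) taken at the neighbor.
g_columns <- function(config, v, vn, d, m) {
  u <- (1L - v) * 2L + (1L - vn)
  if (config$family == 1L) {
    list(j1 = rep.int(u * 2L + 1L, length(m)), x1 = rep.int(1, length(m)),
         j2 = rep.int(u * 2L + 2L, length(m)), x2 = m)
  } else if (config$family == 2L) {
    base <- (u * config$G4 + d) * 2L
    list(j1 = base + 1L, x1 = rep.int(1, length(m)), j2 = base + 2L, x2 = m)
  } else {
    list(j1 = u * config$G4 + d + 1L, x1 = rep.int(1, length(m)),
         j2 = NULL, x2 = NULL)
  }
}

triplet_bind <- function(cells, cols) {
  list(i = c(cells, if (!is.null(cols$j2)) cells),
       j = c(cols$j1, cols$j2),
       x = c(cols$x1, cols$x2))
}

# The four in-bounds shift directions: up, down, left, right neighbors.
shift_pairs <- function(Np, Nr) {
  cell <- function(i, j) i + (j - 1L) * Np
  ij <- expand.grid(i = seq_len(Np), j = seq_len(Nr))
  out <- list()
  for (d in list(c(-1L, 0L), c(1L, 0L), c(0L, -1L), c(0L, 1L))) {
    ki <- ij$i + d[1]
    kj <- ij$j + d[2]
    ok <- ki >= 1L & ki <= Np & kj >= 1L & kj <= Nr
    out[[length(out) + 1L]] <- list(center = cell(ij$i[ok], ij$j[ok]),
                                    nbr = cell(ki[ok], kj[ok]))
  }
  out
}

# Sparse design for the pseudo-likelihood of one instance, conditioning the
# neighbors on `conditioning` (default: the instance's own label grid).
build_pll_design <- function(instance, config, conditioning = instance$r) {
  stopifnot(inherits(instance, "rb_instance"), inherits(config, "rb_feature_config"))
  if (is.null(conditioning)) stop("instance has no contact grid to condition on")
  Np <- nrow(instance$m)
  Nr <- ncol(instance$m)
  ncells <- Np * Nr
  d <- as.vector(delta_index_matrix(config, instance))
  m <- as.vector(instance$m)
  rcond <- as.vector(conditioning)

  Xf <- lapply(0:1, function(v) {
    tr <- triplet_bind(seq_len(ncells), f_columns(config, v, d, m))
    Matrix::sparseMatrix(i = tr$i, j = tr$j, x = tr$x,
                         dims = c(ncells, config$f_dim))
  })
  shifts <- shift_pairs(Np, Nr)
  Xg <- lapply(0:1, function(v) {
    is <- integer(0); js <- integer(0); xs <- numeric(0)
    for (sh in shifts) {
      q <- sh$nbr
      for (vn in 0:1) {
        sel <- rcond[q] == vn
        if (!any(sel)) next
        qq <- q[sel]
        tr <- triplet_bind(sh$center[sel],
                           g_columns(config, v, vn, d[qq], m[qq]))
        is <- c(is, tr$i); js <- c(js, tr$j); xs <- c(xs, tr$x)
      }
    }
    Matrix::sparseMatrix(i = is, j = js, x = xs, dims = c(ncells, config$g_dim))
  })
  list(Xf0 = Xf[[1]], Xf1 = Xf[[2]], Xg0 = Xg[[1]], Xg1 = Xg[[2]],
       Xfd = Xf[[2]] - Xf[[1]], Xgd = Xg[[2]] - Xg[[1]],
       robs = as.vector(if (is.null(instance$r)) rcond else instance$r),
       Np = Np, Nr = Nr)
}

design_potentials <- function(design, w_f, w_g) {
  list(U0 = as.numeric(design$Xf0 %*% w_f) + as.numeric(design$Xg0 %*% w_g),
       U1 = as.numeric(design$Xf1 %*% w_f) + as.numeric(design$Xg1 %*% w_g))
}

# Pseudo-log-likelihood of one instance from its design.
pll_design <- function(design, w_f, w_g) {
  U <- design_potentials(design, w_f, w_g)
  x <- U$U0 - U$U1                     # log-odds of state 1
  sum(stats::plogis(ifelse(design$robs == 1L, x, -x), log.p = TRUE))
}

# Gradient (c(w_f, w_g)) of the pseudo-log-likelihood of one instance.
pll_grad_design <- function(design, w_f, w_g) {
  U <- design_potentials(design, w_f, w_g)
  c1 <- stats::plogis(U$U0 - U$U1) - design$robs
  c(as.numeric(Matrix::crossprod(design$Xfd, c1)),
    as.numeric(Matrix::crossprod(design$Xgd, c1)))
}
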