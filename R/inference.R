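# MAP contact decoding. The sum of local potentials E(r) = sum_ij U_ij(r)
# decomposes exactly into unary terms w_f.f_ij(v) and, per undirected grid
# edge {(i,j),(k,l)}, a 2x2 table carrying both directed pairwise
# contributions w_g.g_ijkl(v, v') + w_g.g_klij(v', v). The minimizer is
# found by sequential tree-reweighted message passing (TRW-S, implemented
# in C++), with an exhaustive enumerator as oracle for tiny grids.

# w_g contribution for (center state x, neighbor state y), evaluated with
# the observation at each cell of the grid; returns an Np x Nr matrix.
pairwise_obs_matrix <- function(config, w_g, x, y, d, m) {
  u <- (1L - x) * 2L + (1L - y)
  vals <- if (config$family == 1L) {
    w_g[u * 2L + 1L] + w_g[u * 2L + 2L] * m
  } else if (config$family == 2L) {
    base <- (u * config$G4 + d) * 2L
    w_g[base + 1L] + w_g[base + 2L] * m
  } else {
    w_g[u * config$G4 + d + 1L]
  }
  matrix(vals, nrow = nrow(m), ncol = ncol(m))
}

#' Decompose the CRF into a grid energy
#'
#' Splits `E(r) = sum_ij U_ij(r)` into per-cell unary tables and per-edge
#' 2x2 tables so that `sum(unary) + sum(edges)` reproduces the summed local
#' potentials for every configuration. Horizontal edge tables are indexed
#' `(left state, right state)`; vertical tables `(top state, bottom state)`.
#'
#' @param params An `rb_params`.
#' @param config An `rb_feature_config`.
#' @param instance An `rb_instance` (label not required).
#' @return An `rb_energy`: `u0`, `u1` (`Np x Nr` unary costs for states 0/1),
#'   `h` and `v` (lists of four matrices named `"00" "01" "10" "11"`).
#' @export
build_energy <- function(params, config, instance) {
  stopifnot(inherits(params, "rb_params"), inherits(instance, "rb_instance"))
  Np <- nrow(instance$m)
  Nr <- ncol(instance$m)
  d <- delta_index_matrix(config, instance)
  m <- instance$m
  dv <- as.vector(d)
  mv <- as.vector(m)
  unary <- lapply(0:1, function(v) {
    cols <- f_columns(config, v, dv, mv)
    vals <- params$w_f[cols$j1] * cols$x1
    if (!is.null(cols$j2)) vals <- vals + params$w_f[cols$j2] * cols$x2
    matrix(vals, Np, Nr)
  })
  W <- list()
  for (x in 0:1) for (y in 0:1) {
    W[[paste0(x, y)]] <- pairwise_obs_matrix(config, params$w_g, x, y, d, m)
  }
  h <- list()
  v <- list()
  for (x in 0:1) for (y in 0:1) {
    key <- paste0(x, y)
    rev_key <- paste0(y, x)
    if (Nr > 1L) {
      h[[key]] <- W[[key]][, 2:Nr, drop = FALSE] +
        W[[rev_key]][, 1:(Nr - 1L), drop = FALSE]
    } else {
      h[[key]] <- matrix(0, Np, 0)
    }
    if (Np > 1L) {
      v[[key]] <- W[[key]][2:Np, , drop = FALSE] +
        W[[rev_key]][1:(Np - 1L), , drop = FALSE]
    } else {
      v[[key]] <- matrix(0, 0, Nr)
    }
  }
  structure(list(u0 = unary[[1]], u1 = unary[[2]], h = h, v = v,
                 Np = Np, Nr = Nr), class = "rb_energy")
}

#' Total energy of a configuration
#'
#' @param energy An `rb_energy`.
#' @param grid Binary `Np x Nr` configuration.
#' @return Scalar `sum(unary) + sum(edge tables)`.
#' @export
grid_energy_total <- function(energy, grid) {
  stopifnot(inherits(energy, "rb_energy"))
  grid <- as.matrix(grid)
  Np <- energy$Np
  Nr <- energy$Nr
  tot <- sum(ifelse(grid == 1L, energy$u1, energy$u0))
  if (Nr > 1L) {
    l <- grid[, 1:(Nr - 1L), drop = FALSE]
    r <- grid[, 2:Nr, drop = FALSE]
    for (x in 0:1) for (y in 0:1) {
      tot <- tot + sum(energy$h[[paste0(x, y)]][l == x & r == y])
    }
  }
  if (Np > 1L) {
    t_ <- grid[1:(Np - 1L), , drop = FALSE]
    b <- grid[2:Np, , drop = FALSE]
    for (x in 0:1) for (y in 0:1) {
      tot <- tot + sum(energy$v[[paste0(x, y)]][t_ == x & b == y])
    }
  }
  tot
}

#' MAP contact grid by sequential tree-reweighted message passing
#'
#' Runs TRW-S on the binary grid energy. Each iteration performs a forward
#' and a backward sweep of message updates, evaluates a dual lower bound
#' (row/column chain decomposition of the reparameterized energy), and
#' greedily decodes a labeling; the best labeling seen is returned. The
#' algorithm stops early when the decoded energy meets the lower bound
#' (certificate of optimality, always attained for submodular energies) or
#' when the bound stalls.
#'
#' @param energy An `rb_energy`.
#' @param max_iterations Sweep cap (default 200).
#' @param tol Stall threshold on the lower-bound improvement.
#' @return Binary `Np x Nr` matrix with attributes `energy`, `lower_bound`,
#'   `bound_trace`, `iterations` and `optimal` (TRUE when the certificate
#'   held).
#' @export
trws_map <- function(energy, max_iterations = 200L, tol = 1e-9) {
  stopifnot(inherits(energy, "rb_energy"))
  flat <- function(tabs, nrow_, ncol_) {
    arr <- array(0, dim = c(nrow_, ncol_, 2L, 2L))
    for (x in 0:1) for (y in 0:1) arr[, , x + 1L, y + 1L] <- tabs[[paste0(x, y)]]
    arr
  }
  if (!all(is.finite(energy$u0)) || !all(is.finite(energy$u1))) {
    stop("non-finite unary energies")
  }
  res <- trws_run(energy$u0, energy$u1,
                  flat(energy$h, energy$Np, max(energy$Nr - 1L, 0L)),
                  flat(energy$v, max(energy$Np - 1L, 0L), energy$Nr),
                  as.integer(max_iterations), tol)
  grid <- matrix(res$grid, energy$Np, energy$Nr)
  storage.mode(grid) <- "integer"
  attr(grid, "energy") <- res$energy
  attr(grid, "lower_bound") <- res$lower_bound
  attr(grid, "bound_trace") <- res$bound_trace
  attr(grid, "iterations") <- res$iterations
  attr(grid, "optimal") <- res$energy - res$lower_bound <= 1e-8 * max(1, abs(res$energy))
  grid
}

#' Exhaustive MAP oracle for tiny grids
#'
#' Enumerates all `2^(Np*Nr)` configurations (requires `Np*Nr <= 20`) and
#' returns the global minimizer; exact ties are broken toward the
#' lexicographically smallest configuration (cell (1,1) most significant,
#' column-major order).
#'
#' @param energy An `rb_energy`.
#' @return Binary matrix with attribute `energy`.
#' @export
brute_force_map <- function(energy) {
  stopifnot(inherits(energy, "rb_energy"))
  n <- energy$Np * energy$Nr
  if (n > 20L) stop("grid too large for exhaustive enumeration (", n, " cells)")
  k <- 0:(2^n - 1)
  cfg <- vapply(seq_len(n), function(t) bitwAnd(bitwShiftR(k, n - t), 1L),
                integer(length(k)))
  # cfg: rows = configurations (lexicographic order), cols = cells
  u0 <- as.vector(energy$u0)
  u1 <- as.vector(energy$u1)
  E <- cfg %*% u1 + (1 - cfg) %*% u0
  cell <- function(i, j) i + (j - 1L) * energy$Np
  if (energy$Nr > 1L) {
    for (j in 1:(energy$Nr - 1L)) for (i in seq_len(energy$Np)) {
      tab <- c(energy$h[["00"]][i, j], energy$h[["01"]][i, j],
               energy$h[["10"]][i, j], energy$h[["11"]][i, j])
      s <- cfg[, cell(i, j)] * 2L + cfg[, cell(i, j + 1L)]
      E <- E + tab[s + 1L]
    }
  }
  if (energy$Np > 1L) {
    for (j in seq_len(energy$Nr)) for (i in 1:(energy$Np - 1L)) {
      tab <- c(energy$v[["00"]][i, j], energy$v[["01"]][i, j],
               energy$v[["10"]][i, j], energy$v[["11"]][i, j])
      s <- cfg[, cell(i, j)] * 2L + cfg[, cell(i + 1L, j)]
      E <- E + tab[s + 1L]
    }
  }
  best <- which.min(E)  # first index among exact ties = lexicographic min
  grid <- matrix(cfg[best, ], energy$Np, energy$Nr)
  storage.mode(grid) <- "integer"
  attr(grid, "energy") <- as.numeric(E[best])
  grid
}

#' Per-cell contact probabilities under a conditioning grid
#'
#' Evaluates `Pr(r_ij = 1 | r_Nij, y)` at every cell, with the neighbor
#' states taken from a conditioning grid (by default the TRW-S MAP grid).
#' These probabilities are the ranking scores used for ROC/AUC evaluation.
#'
#' @param params An `rb_params`.
#' @param config An `rb_feature_config`.
#' @param instance An `rb_instance`.
#' @param conditioning Optional binary grid; `NULL` uses the TRW-S MAP.
#' @param max_iterations Passed to [trws_map()] when decoding the default
#'   conditioning grid.
#' @return `Np x Nr` matrix of probabilities in (0, 1), with the
#'   conditioning grid attached as attribute `conditioning`.
#' @export
score_grid <- function(params, config, instance, conditioning = NULL,
                       max_iterations = 100L) {
  if (is.null(conditioning)) {
    conditioning <- trws_map(build_energy(params, config, instance),
                             max_iterations = max_iterations)
  }
  design <- build_pll_design(instance, config, conditioning = conditioning)
  U <- design_potentials(design, params$w_f, params$w_g)
  p <- matrix(stats::plogis(U$U0 - U$U1), design$Np, design$Nr)
  attr(p, "conditioning") <- conditioning
  p
}

#' Write / read a binary contact grid as TSV
#'
#' @param grid Binary matrix.
#' @param path File path.
#' @return `read_contact_tsv` returns an integer matrix.
#' @export
write_contact_tsv <- function(grid, path) {
  utils::write.table(as.matrix(grid), path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname write_contact_tsv
#' @export
read_contact_tsv <- function(path) {
  g <- as.matrix(utils::read.table(path, sep = "\t", header = FALSE))
  dimnames(g) <- NULL
  storage.mode(g) <- "integer"
  g
}
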