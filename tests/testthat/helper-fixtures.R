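# Shared fixture builders. Everything is generated in code at test time.

# Paired alignment built from explicit column strings: protein/rna are
# character vectors of aligned rows, one organism per row, row 1 reference.
paired_from_rows <- function(protein_rows, rna_rows) {
  n <- length(protein_rows)
  orgs <- sprintf("ORG%03d", seq_len(n))
  p <- alignment(sprintf("p%d_%s", seq_len(n), orgs), protein_rows, "protein",
                 organisms = orgs)
  r <- alignment(sprintf("r%d_%s", seq_len(n), orgs), rna_rows, "rna",
                 organisms = orgs)
  pair_by_organism(p, r)
}

# Small labeled instance with planted coupling.
small_instance <- function(seed, Np = 4, Nr = 5, n_pairs = 30,
                           density = 0.3, coupling = 0.7,
                           grouping = grouping_scheme(20), mi_kind = "mi") {
  cfg <- generator_config(Np = Np, Nr = Nr, n_pairs = n_pairs,
                          contact_density = density, coupling = coupling,
                          grouping = grouping, seed = seed)
  make_instances(cfg, 1, mi_kind = mi_kind)[[1]]
}

# Random parameters for a config.
random_params <- function(config, seed, sd = 0.5) {
  set.seed(seed)
  crf_params(config, stats::rnorm(config$f_dim, 0, sd),
             stats::rnorm(config$g_dim, 0, sd))
}

# Independent reference: sum of local potentials over all cells, built from
# explicit Kronecker-product features (never touches the fast design path).
kron_feature_f <- function(config, r_ij, m_ij, a_i, b_j) {
  state <- c(r_ij, 1 - r_ij)
  delta <- function(a, b) {
    d <- numeric(config$G4)
    d[config$grouping$mapping[[a]] * 4 + match(b, c("A", "C", "G", "U"))] <- 1
    d
  }
  as.vector(switch(config$family,
                   kronecker(state, c(1, m_ij)),
                   kronecker(kronecker(state, delta(a_i, b_j)), c(1, m_ij)),
                   kronecker(state, delta(a_i, b_j))))
}

kron_feature_g <- function(config, r_ij, r_kl, m_kl, a_k, b_l) {
  s1 <- c(r_ij, 1 - r_ij)
  s2 <- c(r_kl, 1 - r_kl)
  delta <- function(a, b) {
    d <- numeric(config$G4)
    d[config$grouping$mapping[[a]] * 4 + match(b, c("A", "C", "G", "U"))] <- 1
    d
  }
  as.vector(switch(config$family,
                   kronecker(kronecker(s1, s2), c(1, m_kl)),
                   kronecker(kronecker(kronecker(s1, s2), delta(a_k, b_l)), c(1, m_kl)),
                   kronecker(kronecker(s1, s2), delta(a_k, b_l))))
}

oracle_potential <- function(params, config, inst, r, i, j, state = r[i, j]) {
  u <- sum(params$w_f * kron_feature_f(config, state, inst$m[i, j],
                                       inst$a[i], inst$b[j]))
  Np <- nrow(r); Nr <- ncol(r)
  for (kl in list(c(i - 1, j), c(i + 1, j), c(i, j - 1), c(i, j + 1))) {
    k <- kl[1]; l <- kl[2]
    if (k < 1 || k > Np || l < 1 || l > Nr) next
    u <- u + sum(params$w_g * kron_feature_g(config, state, r[k, l],
                                             inst$m[k, l], inst$a[k], inst$b[l]))
  }
  u
}

oracle_total_energy <- function(params, config, inst, r) {
  sum(vapply(seq_len(nrow(r)), function(i) {
    sum(vapply(seq_len(ncol(r)), function(j) {
      oracle_potential(params, config, inst, r, i, j)
    }, 0))
  }, 0))
}

# Central finite-difference gradient of the pseudo-log-likelihood.
fd_gradient <- function(config, instances, theta, h = 1e-6) {
  f <- function(th) {
    pseudo_log_likelihood(crf_params(config, th[seq_len(config$f_dim)],
                                     th[-seq_len(config$f_dim)]),
                          config, instances)
  }
  vapply(seq_along(theta), function(k) {
    e <- numeric(length(theta)); e[k] <- h
    (f(theta + e) - f(theta - e)) / (2 * h)
  }, 0)
}

# Submodular random energy on an instance-free grid: attractive couplings
# guarantee h00 + h11 <= h01 + h10 on every edge.
random_submodular_energy <- function(seed, Np, Nr) {
  set.seed(seed)
  tabs <- function(nr, nc) {
    same <- matrix(-abs(rnorm(nr * nc)), nr, nc)
    list(`00` = same, `11` = same,
         `01` = matrix(abs(rnorm(nr * nc)), nr, nc),
         `10` = matrix(abs(rnorm(nr * nc)), nr, nc))
  }
  structure(list(u0 = matrix(rnorm(Np * Nr), Np, Nr),
                 u1 = matrix(rnorm(Np * Nr), Np, Nr),
                 h = tabs(Np, Nr - 1), v = tabs(Np - 1, Nr),
                 Np = Np, Nr = Nr),
            class = "rb_energy")
}

# Toy protein-RNA complex with planted pair distances: unit i of the
# protein sits at x = 20*i, the RNA unit j is offset from it by dist[j]
# along x, so residue i and base j are dist[j] apart when i == j and
# >= 20 - max(dist) apart otherwise. Every unit gets a second atom 50 A
# off-axis so min-distance really matters.
planted_complex <- function(dists) {
  n <- length(dists)
  prot <- chain_coordinates(rep("A", n), lapply(seq_len(n), function(i) {
    rbind(c(20 * i, 0, 0), c(20 * i, 50, 0))
  }))
  rna <- chain_coordinates(rep("G", n), lapply(seq_len(n), function(j) {
    rbind(c(20 * j + dists[j], 0, 0), c(20 * j, -50, 0))
  }))
  list(protein = prot, rna = rna)
}

# Minimal fixed-column PDB writer for parser tests.
write_toy_pdb <- function(path, records) {
  # records: data.frame with serial, name, altloc, resname, chain, resseq,
  # x, y, z
  lines <- sprintf("ATOM  %5d  %-3s%1s%3s %1s%4d    %8.3f%8.3f%8.3f  1.00  0.00",
                   records$serial, records$name, records$altloc,
                   records$resname, records$chain, records$resseq,
                   records$x, records$y, records$z)
  writeLines(c(lines, "END"), path)
  path
}
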