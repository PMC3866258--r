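# Synthetic paired alignments with planted coevolution.
#
# The generator emulates the premise that interacting residues and bases
# mutate together: a contact grid is planted, and at each contact cell the
# RNA column is statistically coupled to the protein column. The coupled
# joint is a group-deterministic map with uniform noise admixture - with
# probability `coupling` the base is a fixed function of the residue's
# group (group index mod 4), otherwise uniform - which has a closed-form
# mutual information used for calibration. Non-contact columns are
# independent and uniform. Defaults mirror the scale of the ribosomal
# benchmark (tens of residues x tens of bases, hundreds of paired
# homologs, sparse contacts).

# Evaluate `code` under a temporary RNG state seeded with `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  code
}

#' Synthetic generator configuration
#'
#' @param Np,Nr Protein and RNA lengths (grid dimensions).
#' @param n_pairs Number of organism-paired homolog rows (>= 2), reference
#'   row included.
#' @param contact_density Fraction of cells planted as contacts, in [0, 1].
#' @param coupling Strength of the residue-base coupling at contact cells,
#'   in [0, 1]: probability that the base is the deterministic function of
#'   the residue group rather than uniform.
#' @param grouping `rb_grouping` used by the coupling map (default
#'   identity).
#' @param gap_rate Per-character gap probability in non-reference rows
#'   (default 0).
#' @param seed Integer seed; all outputs are reproducible per seed.
#' @return An `rb_generator_config`.
#' @export
generator_config <- function(Np = 40L, Nr = 60L, n_pairs = 300L,
                             contact_density = 0.05, coupling = 0.9,
                             grouping = grouping_scheme(20), gap_rate = 0,
                             seed = 1L) {
  stopifnot(contact_density >= 0, contact_density <= 1,
            coupling >= 0, coupling <= 1, n_pairs >= 2L,
            gap_rate >= 0, gap_rate < 1,
            inherits(grouping, "rb_grouping"))
  structure(list(Np = as.integer(Np), Nr = as.integer(Nr),
                 n_pairs = as.integer(n_pairs),
                 contact_density = contact_density, coupling = coupling,
                 grouping = grouping, gap_rate = gap_rate,
                 seed = as.integer(seed)),
            class = "rb_generator_config")
}

#' Plant a random contact grid
#'
#' Independent Bernoulli(`contact_density`) cells from the seeded stream.
#'
#' @param config An `rb_generator_config`.
#' @return Integer `Np x Nr` binary matrix.
#' @export
plant_contacts <- function(config) {
  stopifnot(inherits(config, "rb_generator_config"))
  with_seed(config$seed, {
    matrix(stats::rbinom(config$Np * config$Nr, 1L, config$contact_density),
           config$Np, config$Nr)
  })
}

#' Sample a paired alignment with planted coupling
#'
#' Every row is one organism: the protein row is uniform over the 20 amino
#' acids; at each RNA column that participates in a contact (the first
#' contacting protein column is used when there are several), the base is
#' the group-deterministic function of that row's residue with probability
#' `coupling`, else uniform; remaining columns are uniform. Row 1 is the
#' reference (target) pair and never receives gaps.
#'
#' @param config An `rb_generator_config`.
#' @param contacts Binary `Np x Nr` grid (default: [plant_contacts()]).
#' @return An `rb_paired` set with all rows paired.
#' @export
sample_paired_alignment <- function(config, contacts = plant_contacts(config)) {
  stopifnot(inherits(config, "rb_generator_config"))
  Np <- config$Np; Nr <- config$Nr; n <- config$n_pairs
  with_seed(config$seed + 1L, {
    prot <- matrix(sample(AA20, n * Np, replace = TRUE), n, Np)
    rna <- matrix(sample(RNA4, n * Nr, replace = TRUE), n, Nr)
    partner <- apply(contacts, 2L, function(col) {
      w <- which(col == 1L)
      if (length(w)) w[1] else NA_integer_
    })
    gmap <- config$grouping$mapping
    for (j in which(!is.na(partner))) {
      i <- partner[j]
      coupled_base <- RNA4[(gmap[prot[, i]] %% 4L) + 1L]
      use <- stats::runif(n) < config$coupling
      rna[use, j] <- coupled_base[use]
    }
    if (config$gap_rate > 0 && n > 1L) {
      pg <- matrix(stats::runif((n - 1L) * Np) < config$gap_rate, n - 1L, Np)
      rg <- matrix(stats::runif((n - 1L) * Nr) < config$gap_rate, n - 1L, Nr)
      prot[-1L, ][pg] <- GAP
      rna[-1L, ][rg] <- GAP
    }
    orgs <- sprintf("ORG%05d", seq_len(n))
    p_aln <- alignment(sprintf("prot%04d_%s/1-%d", seq_len(n), orgs, Np),
                       apply(prot, 1L, paste0, collapse = ""),
                       "protein", reference_index = 1L, organisms = orgs)
    r_aln <- alignment(sprintf("rna%04d_%s/1-%d", seq_len(n), orgs, Nr),
                       apply(rna, 1L, paste0, collapse = ""),
                       "rna", reference_index = 1L, organisms = orgs)
    pair_by_organism(p_aln, r_aln)
  })
}

#' Generate labeled instances end to end
#'
#' For each index: plant contacts, sample the coupled paired alignment,
#' compute the MI (or MIp) matrix under the config's grouping, and bundle
#' everything with the label grid. Deterministic per (seed, index).
#'
#' @param config An `rb_generator_config`.
#' @param n_instances Number of instances.
#' @param mi_kind `"mi"` or `"mip"`.
#' @return List of labeled `rb_instance` objects.
#' @export
make_instances <- function(config, n_instances, mi_kind = c("mi", "mip")) {
  mi_kind <- match.arg(mi_kind)
  stopifnot(inherits(config, "rb_generator_config"), n_instances >= 1L)
  lapply(seq_len(n_instances), function(k) {
    cfg <- config
    cfg$seed <- config$seed + 7919L * k  # distinct stream per instance
    contacts <- plant_contacts(cfg)
    paired <- sample_paired_alignment(cfg, contacts)
    m <- mutual_information(paired, cfg$grouping)
    if (mi_kind == "mip") m <- apc_correction(m)
    protein_rna_instance(paired$protein$seq_mat[paired$protein$reference_index, ],
                         paired$rna$seq_mat[paired$rna$reference_index, ],
                         unclass(m), contacts)
  })
}

#' Analytic MI of the generator's coupled joint
#'
#' Mutual information (nats) of the (grouped residue, base) joint the
#' generator samples at a contact cell: residue uniform over 20 amino
#' acids, base equal to the group-deterministic map with probability
#' `coupling`, else uniform. Used to calibrate what the estimated MI at
#' contact cells should approach for large alignments.
#'
#' @param grouping An `rb_grouping`.
#' @param coupling Coupling strength in [0, 1].
#' @return Scalar MI in nats.
#' @export
coupled_joint_mi <- function(grouping, coupling) {
  stopifnot(inherits(grouping, "rb_grouping"), coupling >= 0, coupling <= 1)
  G <- grouping$group_count
  # joint over (group k, base b)
  pk <- tabulate(grouping$mapping[AA20] + 1L, G) / 20
  joint <- matrix(0, G, 4L)
  for (k in seq_len(G)) {
    fb <- ((k - 1L) %% 4L) + 1L
    joint[k, ] <- pk[k] * (1 - coupling) / 4
    joint[k, fb] <- joint[k, fb] + pk[k] * coupling
  }
  pa <- rowSums(joint)
  pb <- colSums(joint)
  nz <- joint > 0
  sum(joint[nz] * log(joint[nz] / outer(pa, pb)[nz]))
}
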