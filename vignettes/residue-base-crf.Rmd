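---
title: "Predicting protein-RNA residue-base contacts with a two-dimensional CRF"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Predicting protein-RNA residue-base contacts with a two-dimensional CRF}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rbcontact)
```

## The problem

When a protein binds an RNA, specific amino-acid residues make physical
contacts with specific bases. Knowing the residue-base contact map of a
complex constrains docking, explains binding specificity, and is usually
obtained only from a solved structure. `rbcontact` predicts the contact map
from sequence families alone, exploiting the coevolution hypothesis:
residue-base pairs that interact tend to mutate in a coordinated way across
species, because an uncompensated mutation on either side risks losing the
interaction.

The unit of prediction is one protein-RNA pair: a protein of length
$N_p$ and an RNA of length $N_r$ define an $N_p \times N_r$ grid of binary
variables $r_{ij} \in \{0, 1\}$, where $r_{ij} = 1$ means the residue at
position $i$ and the base at position $j$ are in contact (any-atom distance
below a threshold; 3 Å and 5 Å are the conventional choices, since
hydrogen bonds span roughly 2.7-2.9 Å).

## Coevolution features: MI and MIp

For each grid cell, the coevolutionary signal is the mutual information
between the two alignment columns,

$$ m_{ij} = \sum_{a \in \Sigma_a} \sum_{b \in \Sigma_b}
   P_{ij}(a, b) \, \log \frac{P_{ij}(a, b)}{P_i(a) \, P_j(b)}, $$

with $\Sigma_a$ the 20 amino acids plus the gap character and $\Sigma_b$
the 4 bases plus gap. Frequencies are raw counts over *organism-paired*
alignment rows divided by the number of pairs: each protein sequence is
matched to the RNA sequence of the same organism, and rows without a
partner are dropped (`pair_by_organism()`). Before counting, columns where
the target sequence carries a gap are deleted (`degap_to_reference()`), so
positions index the target's residues and bases directly.

Raw MI mixes interaction signal with background (phylogeny and column
entropy) shared by whole rows/columns of the matrix. The average-product
correction, adapted to the rectangular residue-base matrix, removes it:

$$ m^{(p)}_{ij} = m_{ij} -
   \frac{\left(\sum_k m_{ik}\right)\left(\sum_k m_{kj}\right)}
        {\sum_{i j} m_{ij}}. $$

The corrected matrix always sums to zero; entries may be negative. Both
statistics can be computed over reduced amino-acid alphabets (Murphy
groupings into 2, 4, 8, 10 or 15 classes, `grouping_scheme()`); the same
grouping is used for MI counting and for the label features below.

Numerical conventions: natural logarithms ($0 \log 0 := 0$); no
pseudocounts or sequence weighting (raw frequencies); if the MI matrix is
identically zero the APC term is defined as zero. The log base only
rescales $m$, and both the CRF (which learns a weight per MI coordinate)
and AUC ranking are invariant to positive rescaling.

## The grid CRF

The contact grid is modelled as a conditional random field on the
$N_p \times N_r$ grid with 4-neighborhoods
$N_{ij} = \{(i \pm 1, j), (i, j \pm 1)\}$. Each cell carries the potential

$$ U_{ij}(\mathbf r, \mathbf y) =
   \mathbf w_f^{\top} \mathbf f_{ij}(r_{ij}, \mathbf y) +
   \mathbf w_g^{\top} \sum_{(k,l) \in N_{ij}}
   \mathbf g_{ijkl}(r_{ij}, r_{kl}, \mathbf y), $$

and the local conditional probability is
$\Pr(r_{ij} = v \mid r_{N_{ij}}, \mathbf y) \propto \exp(-U_{ij})$ with
$r_{ij} = v$. Three feature families are provided (`feature_config()`):

* **Family 1 (MI only):**
  $\mathbf f^{(1)}_{ij} = [r_{ij};\bar r_{ij}] \otimes [1; m_{ij}]$ and
  $\mathbf g^{(1)}_{ijkl} = [r_{ij};\bar r_{ij}] \otimes [r_{kl};\bar r_{kl}]
  \otimes [1; m_{kl}]$ (dimensions 4 and 8).
* **Family 2 (MI + labels):** a one-hot label indicator
  $\delta(a_i, b_j)$ of the (grouped residue, base) pair - length
  $G \times 4$, i.e. 80 ungrouped - is inserted between the state block and
  $[1; m]$.
* **Family 3 (labels only):** $[1; m]$ is replaced by $\delta(a, b)$.

Two conventions worth noting. First, the pairwise features take their
observations at the *neighbor* position ($m_{kl}, a_k, b_l$); this
asymmetry is part of the model definition and is preserved, not
symmetrized. Second, unlike the image-analysis discriminative random
field this design descends from, the interaction features do not encode a
smoothing prior - contact maps are sparse and stringy, not blobby - so the
pairwise weights are free to learn attraction or repulsion between
neighboring contacts.

Boundary cells simply sum over their in-bounds neighbors. The state blocks
$[r; \bar r]$ are deliberately redundant (both states carry features), so
only differences between the $r$ and $\bar r$ blocks are identified; the
lasso resolves the ambiguity by picking the minimal-$\ell_1$
representative.

## Training: pseudo-likelihood with the lasso

The full grid likelihood is intractable (the partition function couples
all cells), so parameters maximize the log pseudo-likelihood

$$ L(\theta) = \sum_n \sum_i \sum_j \log
   \Pr\!\left(r^{(n)}_{ij} \mid r^{(n)}_{N_{ij}}, \mathbf m^{(n)},
   \mathbf a^{(n)}, \mathbf b^{(n)}, \theta\right), $$

where the neighbor states are clamped at their observed values. Only the
cell's own potential $U_{ij}$ enters each conditional, following the
model's definition of the conditional (a symmetrized variant that also
includes the neighboring potentials containing $r_{ij}$ exists in the
pseudo-likelihood literature, but is deliberately not implemented). The
gradient has the standard observed-minus-expected-feature form and is
exposed as `pll_gradient()`; agreement with central finite differences to
better than 1e-5 relative error is part of the test suite.

Label features inflate the parameter count (family 2 with 20 classes has
960 parameters), so the fitted objective adds an $\ell_1$ penalty:
$L(\theta) - C (\lVert \mathbf w_f \rVert_1 + \lVert \mathbf w_g
\rVert_1)$. The optimizer (`owlqn()`) is an orthant-wise limited-memory
quasi-Newton method: the non-smooth penalty is handled through the
pseudo-gradient, direction alignment, and orthant projection of
line-search iterates, which produces exactly-zero coordinates (feature
selection, not just shrinkage). With $C = 0$ it reduces to plain L-BFGS
with Armijo backtracking. Since each per-cell log-conditional is concave
in $\theta$ (the potential is linear in the weights), $L$ is concave and
the zero start point is immaterial up to tolerance.

Convergence uses two criteria, whichever fires first: pseudo-gradient
sup-norm below `gradient_tolerance` (default 1e-5, relative to the iterate
norm), or objective improvement below 1e-9 over the last five accepted
steps. The second exists because the redundant block parameterization
creates exactly flat $\ell_1$ ridges on which the pseudo-gradient need not
vanish even at an optimum; terminating on value stall is the same remedy
quasi-Newton L1 libraries use. The iteration cap (default 500) returns the
best iterate with a warning.

## Decoding: TRW-S

A predicted contact map is the MAP configuration of the energy
$E(\mathbf r) = \sum_{ij} U_{ij}(\mathbf r)$, which decomposes exactly
into per-cell unary terms and per-edge $2 \times 2$ tables
(`build_energy()`; the decomposition is verified against summed local
potentials in the tests). MAP inference uses sequential tree-reweighted
message passing (`trws_map()`, implemented in C++): raster-order forward
and backward sweeps of reweighted min-sum messages with the standard
node-averaging weight $\gamma_t = 1/\max(n^-_t, n^+_t)$. Iterated
conditional modes was rejected as the decoder because it is easily trapped
in local minima on loopy grids.

After each sweep pair the implementation (i) evaluates a dual lower bound
by running Viterbi over the row and column chains of the
message-reparameterized energy (node mass split half/half between the two
chains through each cell), and (ii) greedily decodes a labeling in scan
order, conditioning on already-decoded cells. The best labeling seen is
returned; when its energy meets the lower bound the result is certified
globally optimal. This certificate always closes for submodular energies,
and in the test suite the decoder matches exhaustive enumeration on all
random (non-submodular) 3x3 and submodular 4x4 grids tried. Ties in the
exhaustive oracle are broken toward the lexicographically smallest
configuration.

Test-time probabilities $\Pr(r_{ij} = 1 \mid r_{N_{ij}}, \mathbf y)$
(`score_grid()`) need a conditioning assignment for the neighbors; which
assignment the original protocol used is not stated, so the package
defaults to the TRW-S MAP grid and exposes the choice (`conditioning`
argument, including the all-zero grid). With pairwise weights at zero the
choice is irrelevant.

## Evaluation

`leave_one_out_cv()` holds out one protein-RNA pair at a time, fits on the
rest, scores every cell of the held-out grid, and reports per-fold AUC and
the unweighted mean. AUC is computed as the Mann-Whitney rank statistic
with half credit for ties (ties occur whenever MI values repeat); folds
whose held-out grid contains a single class are skipped with a warning
rather than imputed. ROC points are swept over distinct score thresholds.

## Gold-standard contacts from structures

`read_pdb_chain()` and `extract_contacts()` derive label grids from
PDB-format coordinates with the any-atom distance rule. All atoms present
in the record are used (deposited crystal structures rarely include
hydrogens, so this is effectively a heavy-atom criterion - documented, not
filtered). The first alternate location of each atom is kept; chain
sequences must match the target sequences exactly, and unknown residue
names (beyond standard residues, MSE, and common modified ribonucleotides
with a standard parent) are a hard error rather than a silent skip, since
a register shift between structure and alignment would corrupt every
label downstream.

## The synthetic generator

Real benchmarks require Pfam/Rfam/PDB downloads, so the package carries a
generator (`generator_config()`, `make_instances()`) that emulates the
coevolution premise directly: a Bernoulli contact grid is planted; protein
columns are i.i.d. uniform over the 20 amino acids; at each RNA column
touched by a contact, the base equals a fixed function of the partner
residue's group with probability `coupling` and is uniform otherwise (when
several residues contact one base, the first is the driver). This coupled
joint has closed-form MI (`coupled_joint_mi()`), which calibrates what the
estimator should approach at contact cells; e.g. full coupling under the
identity grouping gives $\ln 4$ nats.

Defaults (`Np = 40`, `Nr = 60`, `n_pairs = 300`, `contact_density = 0.05`,
`coupling = 0.9`) are fixed once to resemble the ribosomal benchmark's
scale - ~50-150-residue proteins against ~100-base RNA domains, hundreds
to ~2000 organism-paired rows, and a 3 Å contact density of a few
percent - kept small enough that a full leave-one-pair-out run takes
seconds. What the generator does *not* emulate: phylogenetic correlation
between rows (real alignments are far from i.i.d., which is exactly the
background MIp exists to suppress), indels and alignment errors, position
dependence along the chain, and the geometric coherence of real interfaces
(planted contacts are scattered, not clustered). A green synthetic
benchmark therefore establishes that the pipeline recovers planted
statistical couplings end to end - not that it attains any particular
accuracy on real complexes.

An optional `gap_rate` inserts gaps into non-reference rows to exercise
the gap symbol in frequency counting; the reference rows never receive
gaps, matching the degapped-target convention.

## A worked run

```{r cv, eval = FALSE}
cfg <- generator_config(Np = 20, Nr = 30, n_pairs = 150, seed = 1)
instances <- make_instances(cfg, 6, mi_kind = "mip")
config <- feature_config(1)
cv <- leave_one_out_cv(instances, config, training_config(lasso_C = 1))
cv$folds
cv$mean_auc
```

On this configuration the mean held-out AUC is about 0.78 (the acceptance
script `scripts/acceptance.R` reruns exactly this computation); with
`coupling = 0` it drops to the permutation-null band around 0.5.

## Design choices made where the design was open

* **Organism matching.** How protein and RNA alignment rows were matched
  by organism in the original protocol is not specified. The package uses
  the mnemonic species token of `NAME_SPECIES/start-end` identifiers
  (honoring `#=GS ... OS` annotations in Stockholm input when present),
  pairs the first occurrence per organism on each side, and always pairs
  the two reference rows with each other.
* **L1 optimizer.** The cited quasi-Newton library was run "with default
  options"; whether its orthant-wise mode was used for $C > 0$ is not
  stated. The orthant-wise scheme is implemented here because the plain
  method does not produce exact zeros, and the observed feature-selection
  behavior requires them.
* **Conditioning at test time** defaults to the TRW-S MAP grid, as
  described above; recorded as a choice, not asserted as the original
  procedure.
* **Base grouping.** The label indicator is always over the 4 bases
  (only amino acids are grouped), matching the printed
  $20 \times 4 = 80$ construction; consequently the family-2-to-family-1
  degeneracy check in the tests collapses only the residue axis.
* **Unknown residue codes** in alignments (`X`, `B`, ...) are treated as
  gaps so that real Pfam/Rfam files parse; unknown residue names in
  coordinate files are errors (see above) - the asymmetry is intentional.

## Limitations

Pseudo-likelihood is a surrogate: parameters are not maximum-likelihood
under the full grid model, and probabilities conditioned on a decoded grid
are not marginals. TRW-S is exact for submodular energies but only
certifiably-checked otherwise (the `optimal` attribute reports whether the
certificate closed). MI estimates carry a positive finite-sample bias that
grows with alphabet size and shrinks with alignment depth; with few paired
rows the MIp correction removes much but not all of it. The generator's
i.i.d. rows make the synthetic task easier than real families of related
species.
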