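---
title: "Triad composition and backbone conformational entropy"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Triad composition and backbone conformational entropy}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(triadentropy)
```

## The model

Intrinsically disordered proteins (IDPs) lack a stable tertiary fold, so
structure-based flexibility measures do not apply to them. This package
implements a sequence-centric alternative built on two ideas.

**Triad composition separates disordered from globular sequences.** An
amino-acid *triad* is an ordered window of three consecutive residues
(20^3 = 8000 possibilities). For a disordered (target) dataset and a
globular (reference) dataset, the relative composition of key $r$ is

$$\Delta_r = \frac{P_r^{\mathrm{target}}}{P_r^{\mathrm{reference}}},$$

with $P_r$ the pooled fraction of $r$ in the dataset, and a sequence is
scored by the mean $\Delta$ over its $R$ units ($R = n$ for residues,
$n - 2$ for triads). Single-residue scores overlap heavily between the
two classes; triad scores draw a much sharper boundary because the
conformational behaviour of a residue depends on its flanking
neighbours. Uncertainty is quantified by resampling whole sequences with
replacement (2000 iterations, 99% percentile intervals by default);
whole sequences are the resampling unit because triads within one
sequence are not independent.

**Triad entropies predict backbone conformational entropy from sequence
alone.** The conformational state of a triad is the $(\phi, \psi)$ pair
of its middle residue. Binning a reference ensemble's dihedrals on a
$30^\circ$ Ramachandran grid (12 × 12 bins; coarse enough to keep
per-triad statistics reliable) gives each triad a plug-in Shannon
entropy

$$S = -\sum_i P_i \ln P_i \qquad (0 \le S \le \ln 144 \approx 4.97\ \mathrm{nats}).$$

Disordered chains obey Flory's isolated-pair hypothesis — each residue's
$(\phi, \psi)$ state is independent of its neighbours' — so a disordered
protein's entropy is the sum of its triads' reference entropies,
$S(i) = \sum_{j} S_j$. Globular chains populate only part of each
triad's accessible range; their entropy is estimated as the same sum
scaled by a *globular factor* whose default, 0.65, is the mean
ensemble-to-reference entropy ratio observed for folded proteins.
Residuewise entropy (4° grid, 90 × 90 bins) follows the same recipe at
single-residue resolution: by default each query residue contributes
$-P_i \ln P_i$ of its reference bin (an alternative `"type"` reading
charges the full per-residue-type entropy; both sit behind one switch
because the source description admits either).

Predictions are validated against two ensemble-based estimators: the
per-residue joint $(\phi,\psi)$ **histogram entropy**, and the
second-order **mutual information expansion (MIE)**
$S \approx \sum_i S_1(x_i) - \sum_{\mathrm{pairs}} I_2(x_i, x_j)$,
$I_2 = S_1(x_i) + S_1(x_j) - S_2(x_i, x_j)$, with pairs restricted to
nearest neighbours on the interleaved $\phi_1, \psi_1, \phi_2, \psi_2,
\ldots$ index. Correlations between backbone dihedrals decay quickly
with sequence separation, which is why nearest-neighbour truncation
suffices; third and higher orders are out of scope (they converge poorly
at realistic sampling).

Two structural observables complete the picture. **Two-body contacts**:
residue pairs at sequence separation $\ge 3$ with any heavy-atom pair
strictly closer than 8 Å (nearer sequence neighbours are excluded
because those contacts persist in denatured chains); globular folds show
many, disordered ensembles few. A **coarse-grained Cα Metropolis Monte
Carlo sampler** generates disordered-chain ensembles: hard pseudo-bond
windows Cα(i)–Cα(i+1) = 3.8 ± 0.15 Å and Cα(i)–Cα(i+2) = 6.0 ± 1.5 Å,
plus a four-term energy (6–12 Lennard-Jones; a hydrophobic term
$-c_h (H_j + H_k - 1)/r$ that favours hydrophobic–hydrophobic and
penalises polar–polar pairs; unscreened Coulomb $c_{el} Q_j Q_k / r$;
and a steric term $c_{st} \sum_j \mathrm{nmw}(j)\,\mathrm{ncn}(j)$
placing heavy residues at low-coordination sites).

## Worked example

A reference table built from a synthetic ensemble, a prediction, and its
ensemble-based validation:

```{r example}
set.seed(1)
cmp <- data.frame(weight = c(0.6, 0.4), mu_phi = c(-65, -120),
                  mu_psi = c(-42, 135), kappa_phi = c(6, 14),
                  kappa_psi = c(5, 10))
seq <- "ACDEFGH"
fx <- gen_dihedral_ensemble(enumerate_triads(seq)$triad, 2e4,
                            components = cmp)
tab <- build_entropy_table(fx$records)
pred <- predict_entropy(seq, tab, id = seq)
pred
series <- do.call(cbind, lapply(split(fx$records, fx$records$triad),
                                function(r) cbind(r$phi, r$psi)))
unlist(compare_methods(pred, mie_entropy(series)$total,
                       histogram_entropy(series)))
```

## Tunable parameters

| parameter | default | units | role |
|---|---|---|---|
| triad grid width | 30 | degrees | per-triad binning; must divide 360 |
| residue grid width | 4 | degrees | residuewise binning |
| log base | e | — | entropies in nats (configurable) |
| bootstrap iterations / level | 2000 / 0.99 | — | CI protocol |
| globular factor | 0.65 | — | scale on the triad-entropy sum |
| contact cutoff / exclusion | 8 / ±2 | Å / residues | two-body contact rule |
| pseudo-bond windows | 3.8±0.15, 6.0±1.5 | Å | hard MC constraints |
| MC move half-width | 0.5 | Å | single-site displacement cube |
| MC coefficients (ε, σ, c_h, c_el, c_st) | 1 | reduced | energy term weights |
| MC temperature | 1 | reduced | Metropolis parameter |

The MC energy scales are deliberate stand-ins: the source description
fixes only the sign structure of each term, so all coefficients default
to 1 and the sampler's correctness claims (constraint satisfaction,
detailed balance, reproducibility) do not depend on them. With σ = 1 Å
the Lennard-Jones term is numerically tiny at chain-like distances;
users wanting compact ensembles should set σ near the Cα contact
distance (~5 Å) and tune the temperature. Hydrophobicities are min-max
normalised Kyte–Doolittle values, charges are +1 (K, R), −1 (D, E),
+0.1 (H), and normalised molecular weights come from standard residue
masses — all overridable, since the source names none of its scales.

## What the synthetic generators emulate

`gen_dihedral_ensemble()` draws per-triad $(\phi, \psi)$ samples from
uniform, uniform-over-a-bin-subset, or von Mises mixture distributions
and returns the *exact* binned entropy of the generator (by quadrature
for mixtures) alongside the samples. Concentrations of 5–50 span the
1.5–3.0 nats range real triads occupy on a 30° grid. A triad restricted
to $K$ of 144 uniformly filled reference bins has entropy ratio
$\ln K / \ln 144$: $K = 25$ reproduces the globular regime (~0.65),
$K = 144$ the disordered one (~1.0) — these synthetic regimes anchor the
acceptance tests. `gen_sequence_datasets()` draws residues i.i.d. from
group-specific compositions (natural abundances for globular; up-weighted
disorder-promoting residues A, R, G, Q, S, P, E, K and down-weighted
order-promoting W, C, F, I, Y, V, L, N for disordered — a bias of 1,
i.e. a ±60% reweighting, gives clearly separated but overlapping score
distributions, the realistic regime) and can plant specific triads at a
stated enrichment. `gen_helix_coordinates()` builds ideal-geometry
backbones at exact torsions and anchors the dihedral round-trip oracle;
`gen_ca_chain()` emits a zigzag Cα trace sitting exactly at the centre
of both constraint windows.

What synthetic data does *not* establish: real disordered sequences have
long-range compositional structure, not i.i.d. residues; real reference
ensembles have strongly non-uniform Ramachandran occupancy; and the MC
energy is not parameterised against any force field. A green test
certifies the estimators and samplers against known ground truth, not
agreement with any experimental dataset.

## Numerical choices and edge cases

- **Angles** are degrees in the half-open interval [−180, 180); +180
  wraps to −180; bins are half-open with origin −180, so a record at
  exactly −180 lands in the first bin.
- **Entropy estimator** is the plug-in (maximum-likelihood) form, matching
  the source protocol of controlling statistical error through the 30°
  bin size rather than bias corrections; triads with no observations are
  absent from tables, not zero-entropy, and counts are always exported
  for downstream filtering.
- **Zero-reference keys**: Δ is reported undefined (no pseudocount,
  mirroring the explicit note that some triads do not occur in the
  disordered dataset); sequence scores exclude undefined units from
  numerator and denominator and report how many were skipped. Missing
  triads in entropy prediction default to the table-mean substitute.
- **Composition pooling**: dataset fractions pool counts over all
  sequences; the alternative mean-of-per-sequence-fractions reading of
  the source's summation gives almost identical values at realistic
  length distributions and was not taken.
- **Degenerate geometry**: collinear backbone triplets make a torsion
  undefined; the residue is skipped with a warning rather than failing
  the chain. Missing residues (numbering gaps) break triad/dihedral
  continuity so disordered gaps never create spurious triads.
- **Classification threshold**: the boundary between classes is drawn,
  not printed, in the source analysis, so `fit_threshold()` fits the
  max-margin midpoint and ties classify as globular (strict inequality).
- **MC specifics**: proposals violating a pseudo-bond window are rejected
  before the Metropolis test (and counted separately); pair distances are
  floored at 0.1 σ to guard the Lennard-Jones divergence; the C++ core
  recomputes the full energy per proposal, so the cached total is exact
  by construction and asserted against the pure-R reference
  implementation at every snapshot; R's RNG drives the sampler, making
  runs bit-reproducible under `set.seed()`/the `seed` argument.
- **Pro / pre-Pro residues** are exceptions to the isolated-pair
  hypothesis; they are included in binning by default with an
  `exclude_pre_pro` flag on `compute_dihedrals()`.

## Known limitations

- Reference-quality triad tables need a large, culled structure database;
  nothing desk-scale substitutes for it, and the package therefore ships
  generators, not a reference table.
- The MIE implementation stops at second order; the per-pair mutual
  informations are reported in nats (whether literature correlation
  values are nats or normalised MI is ambiguous — no result here depends
  on it).
- mmCIF input, structure repair/modelling, secondary-structure
  assignment, side-chain entropy, and kernel/nearest-neighbour entropy
  estimators are out of scope.
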