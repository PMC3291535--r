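---
title: "The minimal Distance Constraint Model: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{The minimal Distance Constraint Model: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

## The model

The minimal Distance Constraint Model (mDCM) treats a protein as a body-bar
constraint network embedded in a statistical-mechanical ensemble.  Every atom
is a rigid body with 6 degrees of freedom.  Chemical interactions are bars
between bodies:

* **Covalent bonds** are quenched — present in every framework of the
  ensemble.  A generic single bond contributes 5 bars, which locks the bond
  length and the adjacent angles but leaves the dihedral rotation.  Bonds
  whose rotation is chemically meaningless or forbidden (peptide bonds,
  bonds inside rings, double/conjugated bonds, bonds to terminal single
  atoms) carry a sixth bar.  The 5-bar bonds define the *a-priori rotatable*
  set; the backbone members are the phi and psi torsions (proline's phi
  lies inside the pyrrolidine ring, so proline contributes only psi).
* **Hydrogen bonds** fluctuate.  Each candidate carries an enthalpy `u_hb`
  from an empirical 12-10 distance well with angular attenuation (salt
  bridges are the special case with a longer equilibrium distance and no
  angular factor) and an entropy weight `gamma_hb = gamma_intercept +
  gamma_slope * u_hb`, clamped at zero: stronger bonds confine more phase
  space.  An engaged hydrogen bond contributes 5 bars between the donor
  hydrogen and the acceptor plus one bar to the acceptor antecedent, i.e.
  its geometry is fully locked; the bar multiplicities are configuration
  options so sparser conventions can be explored.
* **Torsion forces** fluctuate between a *native* state (enthalpy `v_nat`,
  entropy weight `delta_nat`, engaged as one bar) and a *disordered* state
  (`v_dis`, `delta_dis`, no bar).  By convention `v_nat < v_dis` and
  `delta_nat < delta_dis`.

### The pebble game

Network rigidity is evaluated combinatorially with the (6,6) body-bar pebble
game: each body holds 6 pebbles; a bar is *independent* if 7 pebbles can be
gathered on its endpoints (pebble searches are depth-first with path
reversal) and *redundant* otherwise.  Six trivial degrees of freedom are
withheld per connected component — the source implementation's convention
here is unrecorded, and component-wise withholding is the standard (6,6)
behaviour.  Bars are inserted in ascending order of entropy weight (ties:
covalent < torsion < hydrogen bond, then constraint id), which makes the sum
of entropies over independent constraints the lowest upper bound on the
total conformational entropy.  The shipped default gamma map keeps every
hydrogen-bond entropy below `delta_nat < delta_dis`, so the insertion order
is: covalent, hydrogen bonds, native torsions, disordered torsions.

After the engaged bars are placed, every a-priori rotatable bond is
assigned to exactly one cluster:

* **locked** bonds (endpoints mutually rigid) group into rigid clusters by
  pairwise rigidity tests; a rigid cluster with `B > 0` redundant internal
  bars is *over-constrained*, otherwise *isostatic*;
* **free** bonds group into *flexible* clusters.  The grouping rule the
  original work leaves unstated ("regions sharing unconstrained motion") is
  implemented as connected components of the quotient matroid of the
  disordered test bars over the engaged network, computed from fundamental
  circuits with respect to the pebble-game basis.  A chain of independent
  rotors therefore yields one singleton cluster per bond, while a flexible
  ring is one collective cluster.

The per-framework flexibility index is `+A/H` in a flexible cluster (`A`
independent degrees of freedom, `H` member bonds), `-B/D` in an
over-constrained cluster, and 0 on isostatic bonds.  On dense artificial
networks `B` can exceed `D`; profile values are clamped to `[-1, 1]` to
preserve the density interpretation (raw counts remain available from
`cluster_counts()`).  The cooperativity correlation `CC[m, n]` equals the
shared cluster value when bonds m and n sit in the same cluster and 0
otherwise — including two *different* rigid clusters.

Every pebble-game output is cross-checked in the test suite against a
numerical oracle: the rank and null space of the generic body-bar rigidity
matrix (random generic coordinates with a minimum-separation rejection
step, SVD rank queries with relative tolerance 1e-8).

### The ensemble

Macrostates are points `(N_nat, N_hb)` counting engaged native torsions and
hydrogen bonds.  The free energy of a macrostate is

```
G = [ sum(u_hb over engaged bonds) + (N_hb_max - N_hb) u_sol
      + N_nat v_nat + (N_tor - N_nat) v_dis ]  -  T (S_mix + S_conf)
S_mix  = R [ ln C(N_hb_max, N_hb) + ln C(N_tor, N_nat) ]
S_conf = R [ sum_i pi_i q_i gamma_i + q_nat N_nat delta_nat
             + q_dis (N_tor - N_nat) delta_dis ]
```

where `q_i` is the conditional probability that constraint i is independent
when present, `pi_i` the probability that hydrogen bond i is present in the
macrostate, and `q_nat`, `q_dis` the independent fractions of native and
disordered torsions.  With every `q = 1` the expression reverts to a plain
additive free-energy decomposition; the q-attenuation is what prevents the
overcounting of nonadditive entropy.  Three reductions here are the
package's own choices where the source is silent: `q_i` of a multi-bar
hydrogen bond is the independent fraction of its bars; the "sum over
present H-bonds" is weighted by the presence probability `pi_i` (presence
fluctuates within a macrostate); and `u_sol` enters once per broken bond as
the solvent compensation.

Frameworks within a macrostate are weighted by single-bond Gibbs factors
`w_i = exp(-beta (u_i - T R gamma_i q_i))` iterated to self-consistency
(tolerance 1e-4 on q, at most 50 iterations; q starts at 0, so the first
pass uses the plain enthalpy factor).  Small macrostates (at most
`exhaustive_limit` placements, default 1024) are enumerated exactly.  Larger
ones are sampled: a Metropolis swap sampler draws hydrogen-bond subsets from
the enthalpy Gibbs base (burn-in 10 sweeps, thinning one sweep per sample)
and native-torsion placements uniformly; the entropy factor
`exp(sum gamma_i q_i)` then enters by self-normalized importance
reweighting, so the self-consistency loop converges deterministically
instead of chasing Monte-Carlo noise, and the sampled and enumerated paths
share one fixed point.  All sampling is seeded; identical inputs and seed
give bitwise-identical results.

Heat capacity is `d<H>/dT` by centred finite differences of the
landscape-averaged enthalpy — equivalent to `-T d2G/dT2` in exact
arithmetic but stabler under sampling noise — and the melting temperature
`Tm` is the `Cp` maximum refined by quadratic interpolation; a maximum on
the edge of the temperature grid is an error, not an answer.  Near `Tm` the
landscape shows two basins.  The native basin is the steepest-descent
watershed of the minimum with the larger `(N_nat, N_hb)`, truncated at the
saddle found by flooding grid points in ascending free energy until the two
minima connect (the original saddle rule is unstated); Gibbs weights below
1e-9 of the basin maximum are dropped.  FI and CC are the rho-weighted
basin averages of the per-macrostate mechanical means, evaluated at `Tm`.
Per-residue FI averages each residue's phi and psi bond values (mean by
default; min/max are options) — the original reduction is unstated.

### Parameter fitting

`fit_cp()` fits `{u_sol, v_nat}` (two-parameter mode, `delta_nat` fixed at
1.24) or `{u_sol, v_nat, delta_nat}` to a heat-capacity curve by simulated
annealing: Gaussian proposals reflected at the bounds, Metropolis
acceptance, geometric cooling (0.95/step, 200 steps of 20 proposals), and
proposal widths that shrink with the square root of the annealing
temperature down to a floor — without the shrink the final precision is
limited by the proposal size rather than by the data.  The residual is the
mean squared Cp difference after a constant baseline offset (calorimetric
baselines differ by instrument; a linear-in-T term was considered and left
out because the synthetic targets have none).  The objective only re-runs
free-energy algebra: the per-macrostate conditional statistics are
independent of `{u_sol, v_nat}` (and of `delta_nat` except through the bar
insertion order), so they are precomputed once per temperature grid and
insertion-order signature and cached.

## Synthetic data and what the tests show

The generators produce every input class the pipeline consumes, each
seed-deterministic and carrying its ground truth:

* `make_toy_framework()` — rotor chains, rings, braced pairs and random
  body-bar frameworks with closed-form or rank-oracle decompositions, plus
  optional hydrogen-bond braces for thermal toys.  A 5-bar ring is
  isostatic at 6 bodies and flexible only from 7 bodies on (Tay counting),
  which the generator's ground truth reflects.
* `make_polymer_protein()` — ideal-geometry all-atom polypeptides (ALA,
  GLY, SER, PRO).  The helix realizes exactly `n - 4` i,i+4 backbone
  hydrogen bonds at the default detection cutoffs; an H-A distance cutoff
  of 2.5 Å separates them from the weak i,i+3 contacts an ideal helix also
  contains.
* `make_two_stage_network()` — the parameter-recovery benchmark.  A single
  cooperative transition leaves `u_sol` and `v_nat` nearly collinear (both
  rescale the unfolding enthalpy), so recovery from one peak is ill-posed;
  the benchmark therefore couples a free rotor chain, whose
  disordered-torsion hump pins the torsion parameters, to a braced chain
  whose melting pins `u_sol`.  Recovery conditions: 2% Gaussian noise on
  the Cp peak, temperatures 190-560 K every 5 K, truth
  `u_sol = -2.1, v_nat = -0.45, delta_nat = 1.24`, ten data seeds, the
  default annealing schedule; the recovered parameter means land within 5%
  (two-parameter) and 10% (three-parameter) of truth.
* `make_synthetic_cp()` and `make_null_profiles()` — exact-path Cp curves
  plus Gaussian noise, and Gaussian null profiles for calibrating the
  five-bin response histogram.

Synthetic frameworks emulate the *topology* of protonated, minimized
protein structures — detectable hydrogen-bond networks, realistic bar
multiplicities, two-basin landscapes — but not force-field geometry,
side-chain packing, solvation heterogeneity, or crystallographic artefacts.
Passing tests demonstrate that the algorithms are correct and the ensemble
averages converge; they do not certify the empirical accuracy of the
shipped hydrogen-bond potential constants or gamma map, which are
documented reconstructions (the original modified potential and the fixed
prior-work values are unpublished).

## Comparison statistics

Wild-type baselines are position-wise means with the population (n divisor)
standard deviation — the seven reference structures are a fixed set, not a
sample; the n-1 divisor is one switch away.  A mutant value maps to
`z = (x - mean)/sigma`; the normalized delta is 0 for `|z| <= 1`, linear to
`+/-1` between 1 and 2 sigma, and saturated beyond, and the five bins cut
at `|z| = 1` and `2` with boundary values assigned outward.  Zero-sigma
positions are flagged and map to 0 (equal to the mean) or a saturated sign.
The chi-square statistic against the Gaussian band probabilities uses 4
degrees of freedom.  Stratified counts exclude the mutated residue itself
(a configurable local exclusion window exists; the default excludes only
the site).  B-factors are normalized by `(B - median) / (1.4826 * MAD)`,
which is affine-invariant; zero spread falls back to centering with a
warning.  Accessibility tertiles are rank-based contiguous thirds, sizes
differing by at most one, remainder to the buried end, ties broken by
residue index.

## Problem sizes and numerical choices

The shipped test and acceptance computations use toy networks of 2-12
bodies (at most 12 fluctuating constraints, so exhaustive enumeration stays
in the thousands of frameworks), 150-sample Monte-Carlo runs with 4-5
replicates for standard-error bands, 200 random frameworks for the
rank-oracle comparison, and 1e5 positions for the null calibration.  These
sizes were chosen so every statistical check has clear resolution while a
full run stays in the minutes range on one core.  Real-protein landscapes
(grids around 250 x 240) use `grid_stride = 4` with local refinement
around the detected minima.  SASA uses a 1.4 Å probe and a 960-point
Fibonacci sphere per atom (doubling the points moves relative
accessibilities by under 0.03); reference maxima are the standard
theoretical per-residue values.  The rigidity-matrix oracle uses relative
SVD tolerances of 1e-8 on coordinates of order 1.

## Known limitations

* Hydrophobic tethers are outside the minimal model (hydrogen bonds and
  torsions are the only fluctuating constraints).
* The hydrogen-bond potential constants, gamma map, and `v_dis, delta_dis`
  defaults are reconstructions; absolute thermodynamic outputs on real
  structures depend on them.
* mmCIF, multi-chain assemblies, insertion codes, protonation and energy
  minimization are out of scope; the package consumes prepared structures.
* `find_native_basin()` requires genuinely two-basin landscapes; strongly
  biased toys (single minimum) raise an error rather than fabricating a
  basin.
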