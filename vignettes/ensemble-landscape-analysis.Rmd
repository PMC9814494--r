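---
title: "Conformational ensembles and binding landscapes with idpfel"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Conformational ensembles and binding landscapes with idpfel}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(idpfel)
```

## The problem this package addresses

Intrinsically disordered proteins (IDPs) such as the kinase-inducible
domain (KID) of CREB bind folded partners (here, the KIX domain of CBP) by
coupled folding and binding: the peptide acquires ordered structure while
it associates.  Phosphorylation of a central serine (pSer133 in pKID) can
switch the affinity of such interactions by orders of magnitude.  One
proposed mechanism is *flexible conformational selection*: the free
disordered ensemble transiently pre-forms a small local structural pattern
— a hydrophobic residue cluster (HRC) of Leu128, Tyr134, Ile137 and Leu138
around the phosphosite — and only conformers carrying that pattern dock
productively, while the rest of the chain stays disordered until after
binding.

Testing that picture on simulation data requires a reproducible analysis
chain: per-residue helicity of weighted ensembles, side-chain contact maps
and their differences between phosphorylated and unphosphorylated forms, a
quantitative HRC order parameter, binding collective variables against a
reference complex, two-dimensional free-energy landscapes with basin
(state) detection, state-conditioned observables, and Boltzmann
reweighting of clustered free-energy profiles.  `idpfel` implements that
chain as a tested R package, together with a synthetic-ensemble generator
whose ground truth is exact, so every stage can be validated end to end
without any deposited trajectory.

## Contact definitions

Two residues are **in contact** when the minimum distance between any two
selected heavy atoms in different residues is *strictly* below the cutoff
`d_c` (default 4.5 Å).  Both strict inequalities in the package — `< 4.5 Å`
for contacts and `> 15` for the HRC count — follow the printed
definitions, and the boundary cases (4.5 Å exactly; count exactly 15) are
excluded on purpose and covered by tests.  Hydrogens are excluded by
*element*, never by atom-name prefix, so naming dialects in PDB files do
not change results.  Phosphoserine (residue name `SEP`) contributes its
phosphate P/O atoms as side-chain heavy atoms.  Intra-chain contact maps
exclude `|i − j| ≤ 1` by default (sequence neighbours are trivially in
contact); the exclusion width is a parameter.

The **HRC order parameter** is the number of side-chain heavy-atom pairs,
across different residues of a designated residue set (default
{128, 134, 137, 138}), within the cutoff.  A conformer is an HRC structure
iff this count is strictly greater than the threshold (default 15; the
unphosphorylated comparison uses 8).  Two counting modes exist because the
field's phrasing is ambiguous: `"pairs"` (default) counts atom *pairs*,
`"atoms"` counts distinct atoms involved in at least one cross-residue
contact.  Residue 137 is listed inconsistently as Leu or Ile in the
literature on this system; the residue set is therefore configuration, not
a constant.

## Helicity

The analysis replaces hydrogen-bond-based secondary-structure assignment
(DSSP/STRIDE) with a self-contained dihedral rule: a residue is helical
iff its (φ, ψ) lie in the α window (φ ∈ [−100°, −30°], ψ ∈ [−77°, −17°])
*and* it belongs to a run of at least 4 consecutive such residues.  The
window bounds and the run length are parameters.  This rule is
deterministic, cheap, exactly testable, and — because the synthetic
generator draws coil dihedrals from a disjoint region (φ ∈ [−160°, −60°],
ψ ∈ [90°, 170°]) — it recovers generated helicity without ambiguity.  What
it does not capture: 3~10~/π helices, bifurcated hydrogen bonds, and the
tolerance of real helices to occasional outlier dihedrals; on real
trajectories it will run slightly "colder" than STRIDE.

Per-residue helicity is the weighted fraction of frames assigned helical.
Its uncertainty is estimated by recomputing the profile on expanding
prefixes of the frame sequence whose endpoints are evenly spaced over the
final third of the trajectory (five windows by default; for a 300-frame
ensemble: frames 220, 240, 260, 280, 300) and taking the per-residue
standard deviation — frame order stands in for simulation time, since the
package never sees time stamps.

Helix axes (for inter-helix angle distributions) are total-least-squares
lines through a region's Cα coordinates, oriented N→C by the sign of the
first-to-last Cα displacement.

## Binding collective variables

A reference bound complex defines the **native contact set**: all
inter-chain residue pairs in contact (same rule, same cutoff) in the
reference.  For any conformer of the complex, `n_native` is the number of
reference pairs currently formed, `Q = n_native / |set|`, and `d_com` is
the distance between the mass-weighted centroids of the two chains' heavy
atoms (standard atomic masses by element).  Contacts formed in a frame
partition exactly into native and non-native by membership in the
reference set.  Native contacts default to residue-pair granularity —
consistent with landscape axes spanning ~0–120 contacts for an interface
of this size — with the heavy-atom rule shared with every other contact
computation in the package.

## Free-energy landscapes and states

Frames are binned on two collective variables with their statistical
weights; `F(bin) = −k_B T ln P(bin)`, min-shifted to zero, empty bins
`+∞`.  Defaults: T = 300 K, k~B~ = 0.008314462618 kJ/(mol·K).  The binned
probabilities are retained, so Boltzmann inversion round-trips exactly.
Per-frame weights are an *input* (uniform by default): how they are
obtained from an enhanced-sampling bias is outside the package's scope,
which keeps the landscape construction exact and testable.

**Basins** are detected on the 8-connected bin graph: local minima below
an energy cap (default 20 kJ/mol, the conventional display cap for such
landscapes) seed basins, every below-cap bin is assigned by steepest
descent, and basins whose separating barrier — measured from the
*shallower* minimum to the connecting saddle, found by flooding bins in
order of increasing F — is below `merge_barrier` are merged into the
deeper basin.  The default merge barrier of 3 kJ/mol (≈ 1.2 k~B~T at
300 K) suppresses single-bin noise minima; constructed two- and three-well
surfaces with barriers above it are recovered exactly, and raising the
merge barrier above a constructed inter-well barrier provably collapses
the wells.  Bins at or above the cap stay unassigned, and frames in them
are reported as unassigned rather than forced into a state.  Naming the
basins (free, encounter, hidden, intermediates, transition, bound) is the
analyst's interpretation and therefore user configuration, not code.

Any per-frame indicator (e.g. "HRC formed") can be projected onto the
landscape as a per-bin conditional probability, masked above the energy
cap.

**Cluster reweighting.**  Given a table of cluster free energies F~α~ and
cluster-mean observables O~α~ at temperature T, the ensemble average is

$$\langle O\rangle=\frac{\sum_\alpha O_\alpha e^{-F_\alpha/k_BT}}
{\sum_\alpha e^{-F_\alpha/k_BT}}$$

evaluated with max-shift (log-sum-exp) stabilisation, hence exactly
invariant under F~α~ → F~α~ + c.  Closed forms used as tests: equal free
energies give the arithmetic mean; ΔF = k~B~T ln 2 with O = (0, 1) gives
1/3.

## The synthetic-data generator

The generator exists so that every analysis stage has inputs with exact
ground truth; it imposes structure geometrically and makes no physical
claims.

* **Conformers** are grown from internal coordinates with ideal bond
  lengths and angles; helical residues get (φ, ψ) = (−57°, −47°), coil
  residues draw from the disjoint β/PPII box.  Side chains are the
  residue's full complement of heavy atoms (real PDB names, so selections
  behave as on real files) placed as pseudo-atoms on a deterministic
  spiral off CB — contact counting needs positions, not rotamers.
* **Helicity** is sampled per frame as all-or-none *cooperative units*:
  each maximal constant-probability run of the target profile switches on
  with its probability.  Units of length ≥ 4 are exactly detectable by the
  dihedral rule, so the measured per-residue helicity is an unbiased
  binomial estimate of the target (runs shorter than the rule's minimum
  are flagged as undetectable).
* **HRC frames** are created by pulling the cluster residues' side chains
  toward their joint centroid until the count exceeds the threshold *and*
  every residue pair of the set is in mutual contact — adjacent residues
  alone can clear the bare count without any spatial cluster, which would
  make the flag vacuous.  Non-HRC frames are pushed apart until the count
  is at or below the threshold.  Both directions are enforced, so the
  per-frame HRC flag (and hence the generated p~HRC~) is exact, including
  p~HRC~ = 0 and 1.
* **Complexes**: both chains are built as ideal helices with parallel axes
  18 Å apart — far enough that no undesigned side-chain pair can touch —
  and each designed interface pair is re-formed by collapsing the IDP
  residue's side chain onto a compact cluster at a 3 Å standoff radially
  outward of the partner residue's outermost atom.  The reference
  construction *verifies* that the realised native set equals the designed
  set and errors otherwise.  Ensemble frames rigidly translate the IDP
  chain along the chain–chain axis to a drawn distance (exact before
  pulls) and re-form a random subset of designed contacts of size
  `round(q · K)`, so per-frame `n_native` equals its target exactly.
  Unreachable (distance, Q) combinations are rejected at validation by a
  trial placement.
* Every generator is a pure function of its specification and seed.

The default study conditions mirror the system the package targets: a
29-residue phosphopeptide (residues 119–147, SEP133, HRC residues
128/134/137/138) with ~50 % helicity in the N-terminal segment (120–129)
and ~15 % in the C-terminal segment (134–144), p~HRC~ ≈ 0.4 for the
phosphorylated form versus 0 for the unphosphorylated one, and a
free/encounter/bound state mixture over (d~com~, Q).  The sequences are
designed stand-ins, clearly named `synthetic_*`, not the natural CREB/CBP
sequences.

What passing these closed-loop tests shows: the analysis operators are
exact on inputs whose truth is known.  What they do not show: behaviour on
physically realistic ensembles — real side-chain packing, correlated
helix–coil kinetics, rugged landscapes, and bias-derived weights are all
outside the generator's vocabulary.

## Numerical choices and degenerate inputs

* Weights must be ≥ 0 with positive sum; all weighted statistics are
  invariant under uniform rescaling, and weights are never normalised at
  read time.
* PDB coordinates round-trip at the format's 3-decimal precision; contact
  classifications survive that rounding in tests.
* Multi-model files must share one topology; the first divergent atom is
  named in the error.  Alternate locations other than 'A'/blank are
  dropped for a single deterministic topology.
* Steepest descent treats an equal-valued neighbour as not downhill; flat
  plateaus therefore fragment rather than merge silently (constructed
  surfaces in tests avoid exact ties).
* Landscape axes drop out-of-range frames from the histogram and report
  them as unassigned during state assignment, with a warning.
* CSV outputs format floating-point numbers at 6 significant digits, so
  identical runs are byte-identical.
* Problem sizes in the test-suite recovery loops (2000-frame free
  ensembles, 1500–2000-frame complex ensembles, 10^5 landscape samples)
  were chosen so binomial/counting error bars are a few percent — tight
  enough to catch estimator bias, cheap enough to run routinely.

## A worked example

```{r example, eval = FALSE}
library(idpfel)

# synthetic free-state ensemble at the default study conditions
seqA <- synthetic_pkid_sequence()
prof <- rep(0, 29)
prof[as.integer(names(seqA)) %in% 120:129] <- 0.5
prof[as.integer(names(seqA)) %in% 134:144] <- 0.15
g <- generate_free_ensemble(seqA, prof, n_frames = 500, seed = 42,
                            p_hrc = 0.4)

hel <- helicity(g$ensemble)
region_helicity(hel, c(120, 129))          # ~ 0.5
hrc_probability(g$ensemble, hrc_spec(chain = "A"))  # ~ 0.4

# binding landscape of a synthetic two-state complex ensemble
ref <- generate_reference_complex(seqA, synthetic_kix_sequence(),
                                  synthetic_interface())
ncs <- native_contacts_from_reference(ref, "A", "B")
mix <- state_mixture(c("F", "B"), c(0.5, 0.5), d_mean = c(40, 19),
                     d_sd = c(2, 0.5), q_mean = c(0, 0.85), q_sd = c(0, 0.05))
gc <- generate_complex_ensemble(ref, mix, n_frames = 500, seed = 43)
cv <- cv_table(gc$ensemble, ncs)
fel <- weighted_fel(cv, fel_axis("d_com", 10, 50, 1),
                    fel_axis("n_native", -0.5, 13.5, 1))
basins <- find_basins(fel, energy_cap = 25)
basins$minima
```

The same analysis, driven by a YAML configuration, is available from the
shell through the `idpfel` script installed under `exec/`
(`idpfel all --config demo_config.yaml --out out/`).

## Known limitations

* The dihedral helix rule is not STRIDE; absolute helicities on real data
  will differ slightly from hydrogen-bond-based assignments.
* Per-frame weights are taken as given; deriving them from metadynamics
  bias potentials is out of scope.
* Native contacts use a hard cutoff, not a smooth switching function, so Q
  is integer-grained for small interfaces.
* The basin finder works on the binned surface; basins narrower than a bin
  or separated by sub-bin barriers are invisible at the chosen resolution.
* The synthetic complex places chains by rigid translation along one
  approach axis; orientational heterogeneity of real encounter complexes
  is not emulated.
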