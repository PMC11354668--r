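---
title: "Screening ssDNA ligands for the antibody Fc segment: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening ssDNA ligands for the antibody Fc segment}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fcscreen)
```

## Scope and model

`fcscreen` post-processes rigid-body docking output for ssDNA ligands
("DNA functional ligands") docked against a whole IgG antibody, and fits 1:1
binding kinetics to biolayer-interferometry (BLI) sensorgrams. It does not
run docking, prepare structures, or talk to instruments: docking poses,
scores, and sensorgram traces are inputs, and a synthetic-data module
generates statistically matched stand-ins for all of them.

The structural container is deliberately simple: a flat heavy-atom table per
complex (chain, author residue number, residue name, element, coordinates),
typed into amino acid / deoxynucleotide (DA, DC, DG, DT) / monosaccharide
(NAG, MAN, BMA, GAL, FUC, FRU by default) / other by a fixed name lookup.
Hydrogens and waters are dropped at parse time, and alternate locations
resolve to the highest-occupancy copy (ties keep the first record): docking
poses are rigid and all distance thresholds here are heavy-atom scale.
Residues typed "other" are kept in the structure but excluded from contact
statistics, with a warning.

## Domain regions and the Fab/Fc split

Immunoglobulin regions are assigned from an interval map in author
numbering, shipped as JSON and fully user-overridable
(`inst/extdata/regions_1igt.json`). The default is keyed to an IgG laid out
like PDB entry 1IGT — light chains A/C (VL 1–110, CL 111–220), heavy chains
B/D (VH 1–120, CH1 121–241, CH2 242–360, CH3 361–454, hinge 455–475), and
glycan chains E/F. Groupings are Fab = {VH, CH1, VL, CL} and
Fc = {CH2, CH3, glycan}; the hinge belongs to neither.

Two points deserve honesty. First, published descriptions of this antibody
give an Fc span ("about 230 to 444" in one clause, "242–474" in the next)
that cannot both be right, and place the hinge at heavy-chain residues
455–475 even though that interval trails CH3 numerically. The default map
therefore follows the explicitly quoted intervals (hinge 455–475, Fc window
governed by 242–474) and treats the map as *configuration*, not truth:
anyone analysing a different antibody, or a renumbered structure, should
supply their own intervals. Second, assignment is purely interval-based —
residues outside every interval are labelled `"unassigned"` and never enter
a grouping, so a mis-specified map degrades loudly (unclassified ligands)
rather than silently.

## Contact detection

A contact is a (nucleotide, receptor residue-or-sugar) pair with at least
one heavy-atom pair within the cutoff; the minimum heavy-atom distance is
stored. The conventional cutoff band for non-bonded interface contacts is
3–6 Å depending on interaction type, but the type-to-cutoff mapping is not
standardised. The default is therefore a single 4.5 Å cutoff — reproducible
and inside the band — with an optional two-class map
(`contact_params(class_cutoffs = c(hbond = 3.5, other = 6))`) in which atom
pairs where both atoms are N or O are treated as hydrogen-bond capable.

Detection runs a cell-grid neighbour search (cell edge = the largest
cutoff, 27-cell stencil). Because a buggy spatial index fails silently, the
package also exports `find_contacts_brute()`, an independent all-pairs
O(n²) implementation with the same contract; the test suite requires exact
agreement (same pair sets, distances to 1e-9 Å) on 100+ generated
complexes, and the two code paths share no distance computation.

**Binding frequency** counts *complexes touching a site*, not raw atom
contacts: a ligand whose three bases all touch one glutamate contributes 1,
not 3, to that site's count. This matches how per-site frequencies are
quoted in screening studies ("~70% of ligands touch this residue") and
makes frequencies invariant to ligand length. Raw contact counts remain
available from the contact tables.

## Contact propensity

For base $i$ and structural unit $j$,
$$P_{ij} = \frac{N_{ij} / \sum_j N_{ij}}{T_j / \sum_j T_j}$$
with $N_{ij}$ the base–unit interface contact count and $T_j$ the unit's
total contacts in the entire dataset. The summation convention (numerator
normalised *across units within a base*; denominator is the unit's share of
all contacts) is the standard interface-propensity form: it is
scale-invariant (multiplying all counts by any positive integer leaves
$P$ unchanged), its null is exactly 1 for tables where every unit's
contacts split across bases proportionally to the overall totals, and
$P_{ij} \gtrless 1$ reads directly as favoured/disfavoured. The alternative
(normalising down columns, over bases) is available as
`contact_propensity(tab, sum_over = "bases")` for comparison, but is not
the default.

$T_j$ defaults to totals of the supplied contact set ("entire dataset" =
everything loaded); callers studying a sub-interface may supply external
totals. Units with $T_j = 0$ are *undefined*: they carry `NA`, never 0, and
serialise as `"NA"` in reports. A table with $N_{ij} > 0$ but $T_j = 0$ is
inconsistent and errors.

## Binding modes and screening

Classification is by the regions the ligand actually touches, with pure
cases first: FAB (all contacted residues in Fab), MODE1 (all in Fc,
including glycans — the orientation that leaves both antigen-binding arms
exposed, hence the screening target), then MODE2 (any hinge contact), then
MODE3 (at least `majority_threshold` of contacting nucleotides touch Fc and
every remaining contacting nucleotide touches CH1 or CL). The threshold
defaults to 0.5 with a `>=` comparison — the qualitative description behind
MODE3 says only "majority/minority", so the most permissive reading of
"majority" was chosen and exposed as a parameter. Anything else, including
a contact-free ligand (warned), is UNCLASSIFIED. `fc_bound` is strictly
`mode == MODE1`.

Fc binders are ranked by docking score descending with lexicographic
ligand-id tie-breaks, so screening output is a deterministic function of
its input. Scores come from the pose table (TSV: `ligand_id`, `pose_rank`,
`zdock_score`, with pose 1 the top-scoring pose); the docking engine itself
is out of scope. The mutation report compares score and site engagement
before/after a receptor point mutation; its sign convention is
`delta = score_after - score_before`, so a negative delta means the
original residue facilitated binding.

## Kinetics

The binding model is the 1:1 Langmuir scheme: during association at analyte
concentration $C$,
$$R(t) = R_{eq}\left(1 - e^{-(k_{on} C + k_{dis}) t}\right),\qquad
R_{eq} = R_{max}\frac{k_{on} C}{k_{on} C + k_{dis}},$$
and dissociation decays as $R_0 e^{-k_{dis} t}$. Both are the closed-form
solutions of $dR/dt = k_{on} C (R_{max} - R) - k_{dis} R$; the tests verify
them against an independent RK4 integration to ≤ 1e-6 nm.
$K_D = k_{dis}/k_{on}$ (M, with $k_{on}$ in 1/(M·s) and $k_{dis}$ in 1/s).

`fit_kinetics()` is a *global* fit: one $(k_{on}, k_{dis}, R_{max})$ shared
across the whole concentration series, matching how one constant pair per
ligand is reported from instrument software; per-curve fits would
overparameterise five short phases. Numerical choices:

- optimisation over $\log_{10}$ parameters with L-BFGS-B, bounds
  $k_{on} \in [1, 10^9]$, $k_{dis} \in [10^{-7}, 1]$,
  $R_{max} \in (0, 10]$ nm, initial values $(10^4, 10^{-3},
  \max R_{obs})$ — centred on the magnitude range typical of
  antibody–oligonucleotide panels — followed by a Nelder-Mead polish;
- each association phase is zeroed to the mean of the final second of its
  preceding baseline; the model's own association endpoint seeds the
  dissociation phase (no per-phase refitting);
- $R^2 = 1 - SS_{res}/SS_{tot}$ pooled over all fitted points; fits with
  $R^2 <$ `r2_min` (default 0.85) are flagged unreliable, a constant trace
  yields `status = "no_signal"`, and a non-converged optimiser is reported
  as such — never silent defaults;
- regeneration and loading steps are parsed but excluded from fitting.

Concentrations arrive in mg/mL (instrument convention) and convert to M via
the analyte molar mass, defaulting to 150 kg/mol for whole IgG.

Decision rules: `binding_call()` is an inclusive ≥ 0.02 nm threshold on the
association maximum — the instrument community's usual noise floor — and
`competition_call()` applies the same threshold to the absolute signal
change during ligand-challenge steps after an IgG capture; sub-threshold
traces mean the ligand cannot displace (or add to) the captured antibody,
i.e. it shares the occupied Fc site.

## The synthetic-data generator

Generators are pure functions of their spec (seed included): identical
specs give identical bytes, and they restore the caller's RNG state.

`make_toy_complex()` builds a CA-only receptor on a 10 Å lattice covering
every region of the default map, plus NAG/BMA/MAN glycan chains and a
single-phosphorus-per-nucleotide ligand. Planted contact sites get exactly
one nucleotide at 3 Å; every other ligand–receptor pair is ≥ 2 Å beyond any
admissible cutoff, so contact truth is unambiguous by construction.
`make_ensemble()` apportions modes by largest remainder (so 49/140 MODE1 is
exact, mirroring the screening structure such studies report) and draws
pose scores uniformly on [16, 33] — the span of cited rigid-docking scores;
the distribution itself is arbitrary and documented as such.
`simulate_sensorgram()` defaults to the assay design the package targets: a
five-step two-fold IgG series 0.0125–0.2 mg/mL, 300 s (5 min) association
and dissociation phases, 30 s baselines, 1 Hz sampling, i.i.d. Gaussian
noise (default σ = 0.005 nm, a realistic BLI noise floor) plus optional
linear drift.

What the generator does *not* emulate — and therefore what a green test
does not establish: real docked geometries (no base stacking, no backbone,
no shape complementarity), correlated instrument noise or thermal drift
profiles, mass-transport limitation or surface heterogeneity in the
kinetics, and any relationship between sequence composition and affinity.
Green tests establish that the *analysis machinery* is correct on inputs
whose truth is known, not that the science of any particular ligand panel
is reproduced.

## Reference panel and its arithmetic

A panel of published kinetic constants (20 IgG-binding ssDNA ligands plus
an SPA–IgG positive control, and poly-A/C/G/T homopolymers of 10–30 nt)
ships as plain TSV and loads with `affinity_reference()`. All its values
are printed at 3 significant figures. Recomputing $K_D = k_{dis}/k_{on}$
from the printed constants reproduces the printed $K_D$ exactly at 3 s.f.
for 26 of 33 numeric rows; the remaining rows differ in the last digit by
up to ~1.1 ulp, exactly what propagating the 3-s.f. rounding of the inputs
allows. The acceptance tests therefore assert strict 3-s.f. equality where
it holds (including the panel minimum, $2.41 \times 10^{-7}$ M) and
rounding-interval consistency everywhere, rather than pretending the
printed inputs are exact.

## Known limitations

- PDB parsing is minimal by design: fixed-column ATOM/HETATM/TER records,
  no mmCIF, no insertion codes, no multi-model files; one ligand chain per
  complex is a hard contract.
- Region assignment is interval-based only; no sequence- or
  structure-based domain detection.
- The kinetic model is pure 1:1 — no mass transport, no bivalent analyte,
  no heterogeneous-ligand terms; panels that need those models should fit
  elsewhere and only use the decision rules here.
- Interface statistics are residue-pair-granular; atom-level interaction
  typing (salt bridge vs. hydrogen bond vs. stacking) is out of scope
  beyond the optional two-class cutoff map.
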