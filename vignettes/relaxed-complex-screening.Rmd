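---
title: "Screening analytics around the relaxed complex scheme"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Screening analytics around the relaxed complex scheme}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(rcscreen)
```

## The problem

Protein–protein interfaces are hard screening targets: they are broad,
shallow and flexible, and a single crystal conformation rarely shows the
cavity a small molecule will actually occupy. The relaxed complex scheme
(RCS) addresses the flexibility problem by docking against an ensemble
of receptor conformers extracted from a molecular dynamics run, and the
interface problem by first mapping which residue contacts actually hold
the complex together, so that hits can be triaged by whether they engage
those hotspot residues.

`rcscreen` implements the analysis layer of such a campaign for targets
like the XRCC4 / DNA ligase IV association: persistent-contact hotspot
mapping of a complex trajectory, receptor conformer extraction, library
filtering, docking-pose triage, and post-docking stability scoring. The
MD and docking engines themselves (force fields, Vina, MM-GBSA) are
deliberately out of scope: the package consumes their file formats and
replaces them, for testing, with generators that plant known ground
truth.

## Contact persistence

A residue pair is in contact in a frame when the minimum distance over
heavy-atom pairs does not exceed the cutoff (3 Å by default; the
boundary is inclusive, so exactly 3.00 Å counts). Persistence is the
fraction of analysis-window frames with the contact present; a contact
is *persistent* at fraction ≥ 0.80 and *very persistent* at ≥ 0.90,
again inclusive. The analysis window is always explicit: whether the
denominator includes equilibration frames is a user decision
(`analysis_window()` cuts by time), not something the package guesses.
An advisory helper (`equilibration_onset()`) reports where an RMSD trace
plateaus, but it never chooses the window silently.

Every frame is first corrected for overall rotation and translation by
Kabsch superposition (SVD with the determinant fix that excludes
reflections). Contacts are residue-level — the per-residue hotspot
profile (`residue_profile()`) reports, per residue and partner chain,
the maximum pair fraction with the conventional colour key (green
≥ 90 %, yellow 80–90 %, red < 80 %).

Two independent contact searches are provided: a brute-force all-pairs
scan and a cell-list scan binned at the cutoff length. They are
contract-identical and the suite asserts equality on random frames; the
cell list exists for larger systems.

Water bridges use a separate cutoff (3.5 Å, water oxygen to heavy atom
of both partners) — a standard hydrogen-bond heavy-atom distance, chosen
here because the contact definition above does not cover solvent
mediation. Polar/hydrophobic atom classes used in pose triage are
minimal: polar = {N, O}, hydrophobic = {C}, with sulfur in neither; all
of these are configurable.

## Conformer extraction

The ensemble step clusters frames by main-chain RMSD (atom names N, CA,
C, O) after pairwise superposition, using deterministic leader
clustering at a fixed radius (2 Å default): scanning frames in order, a
frame joins the first cluster whose representative lies within the
radius (inclusive), otherwise it founds a new cluster. A final pass
re-centres each representative to the cluster medoid (smallest mean RMSD
to the other members); clusters are then relabelled by decreasing size.
The radius is interpreted as frame-to-representative, not frame-to-
centroid — with well-separated conformers the two coincide, and the
choice is stated here because the clustering literature uses both.
Leader clustering needs no RNG, so identical inputs give identical
assignments; the price is order dependence, which the planted-ensemble
tests control for by seeded shuffling. After medoid re-centring a member
can in principle sit slightly outside the radius of the new
representative; with separated clusters (the regime the generator
guarantees) it does not.

Grid boxes for docking are cubic (40 Å edge, 1 Å spacing by default)
centred on the receptor's centre of gravity, read literally as the
mass-weighted heavy-atom centroid with standard atomic weights; a flag
switches to the geometric centroid.

## Library filtering

The filter cascade applies eight descriptor bounds with a full audit:
molecular weight < 450 Da (average atomic weights — the drug-likeness
rule), cLogP and SFI in [−3, 1], TPSA < 110 Å², donors and acceptors in
[0, 5], rotatable bonds in [0, 6], net formal charge in [−1, 1].
Boundary semantics are literal: strict `<` where the rule is stated with
`<`, closed intervals for "between". The SFI window [−3, 1] is
atypically narrow (solubility guidance in the literature is usually
SFI < 5); it is the default here because it is the campaign's stated
rule, and every bound is configurable in `filter_policy()`.

Descriptor back-end choices, each standard and each swappable: cLogP is
the Crippen-style atomic-contribution logP as implemented in OpenBabel;
TPSA is Ertl's topological PSA (OpenBabel's variant includes S/P
contributions); donors are N/O atoms bearing hydrogen; acceptors are the
plain Lipinski N+O tally (computed directly, because OpenBabel's HBA
descriptor deviates from that count on anions and thiones); rotatable
bonds are non-ring single bonds between non-terminal heavy atoms with
amide C–N bonds excluded; aromatic rings are counted as unique
5/6/7-membered aromatic SMARTS matches, which agrees with SSSR counting
on fused systems. Net charge is the formal charge of the input
structure: no pKa or protonation model is embedded, since protonation
assignment belongs to the (out-of-scope) preparation tools.

Duplicates are removed by canonical-SMILES equality (first occurrence
kept; tautomer-insensitive matching is out of scope). PAINS removal
ships the published A/B/C substructure set (480 SMARTS, with family
labels) as a plain versioned TSV; the reactive/warhead list is a minimal
curated table. Both are swappable files, and pattern matching runs on
hydrogen-added molecules because the published patterns use explicit
hydrogens.

Monoisotopic masses (`monoisotopic_mass()`) are a separate exact-mass
utility with IUPAC most-abundant-isotope masses, kept apart from the
average-weight MW filter because HRMS arithmetic and drug-likeness rules
answer different questions.

## Pose triage and stability

Triage applies three criteria per compound across the conformer
ensemble: best Vina score ≤ −7 kcal/mol (Vina affinities are negative;
the boundary passes, since a worked case at exactly −7 is a pass), a
single position cluster, and at least one polar plus one hydrophobic
contact in the site. Pose clustering is leader clustering on ligand
RMSD *without* refitting (a pose that moved across the site is a
different binding position even if internally identical), seeded by the
best-scoring pose, at a 2 Å default radius chosen to match the receptor
clustering scale. Contact typing uses 3.5 Å (polar) and 4.0 Å
(hydrophobic) — standard interaction distances, deliberately distinct
from the 3 Å trajectory-contact cutoff. The single-cluster rule is
evaluated on the best-scoring conformer's pose group, with a pooled mode
available, because pooling across conformers changes the question being
asked.

The stability stage maps a ligand RMSD trace (measured after receptor
superposition, without refitting the ligand) and a binding-mode count to
the qualitative 3/2/1 score: 3 = single mode and mean RMSD ≤ 1.5 Å,
2 = single mode but larger excursions, 1 = several modes. The 1.5 Å
threshold is this package's quantitative reading of a qualitative score
and is exposed as `t_stable`. Candidates are retained when they keep at
least one 90 %-persistent site contact and score ≥ 2, then ranked by
binding energy. Binding energies are consumed from a table (end-point
MM-GBSA values computed elsewhere, typically over the last 4 ns window
— `last_window()` does the frame arithmetic); the optional surrogate
scorer (−1.0/−0.5 kcal/mol per polar/hydrophobic contact, labelled
SURROGATE) exists only so the pipeline runs end to end without external
energies, and its outputs are not free energies.

## The synthetic generators

The generators emulate the *statistical and geometric structure* the
analysis consumes, not physics: no sterics, no force field.

* `make_contact_trajectory()` plants residue pairs that are in contact
  (2.2–2.6 Å) with independent per-frame probability equal to the target
  fraction, else far (> 6 Å), with truncated Gaussian jitter bounded so
  a draw can never cross the 3 Å boundary. The ground truth records the
  *realized* per-frame draws, so downstream checks are exact equalities;
  target fractions back only statistical checks (binomial 3σ at
  n ≥ 100).
* `make_conformer_ensemble()` builds k deformed copies of a toy
  main-chain, rescaling the deformations until the smallest pairwise
  superposed centre RMSD matches the requested separation (superposition
  shrinks raw Gaussian displacement norms, so the naive amplitude would
  undershoot). Recovery at radius r is guaranteed when separation
  > 2 (r + 3σ); violating that raises a warning, not an error.
* `make_pose_campaign()` writes Vina-dialect PDBQT files realizing
  planted scores, cluster layouts and contact counts against a toy
  5-residue site, plus the verdict each compound must receive;
  `make_stability_trajectory()` plants the three stability classes
  (in-place jitter; single-mode wobble calibrated to stay within the
  mode radius of the first frame while exceeding the stable threshold;
  two-site hopping) and a 100 %- versus 50 %-persistent site contact.
* `make_library()` samples from a packaged 23-molecule catalogue whose
  rule-violation flags were computed with this package's descriptors and
  cross-checked against an independent toolkit; one borderline molecule
  (cLogP on the −3 bound, where Crippen parameterisations disagree) was
  excluded outright rather than frozen.

Seeds are mandatory everywhere; every generator is a pure function of
(spec, seed) and the suite asserts byte-identical files across runs.

What passing these tests shows — and does not show. Planted recovery
demonstrates that the bookkeeping, thresholds and clustering are
implemented exactly as specified. It does not show that real
trajectories are this clean: real contact processes are autocorrelated
(the generator draws frames independently), real conformer populations
overlap, and real pose clusters are not 15 Å apart. The desk-scale runs
used throughout (hundreds of frames, tens of atoms, 29-compound
campaigns) were chosen as the smallest sizes at which every decision
rule is exercised, including the 29 → 11 screening funnel rehearsed at
full planted scale.

## Numerical choices and degenerate inputs

Kabsch superposition requires ≥ 3 non-collinear fit atoms and rejects
degenerate geometry (second singular value ~ 0). Solvent-accessible
areas use Shrake–Rupley quadrature on a deterministic golden-spiral
point set (960 points by default, ~1 % single-sphere error; the
two-sphere analytic overlap formula is the oracle in tests), with vdW
radii C 1.70 / N 1.55 / O 1.52 / S 1.80 Å and a 1.4 Å probe, all
configurable via a JSON table. Interface area is reported as half the
buried accessible area, (SASA_A + SASA_B − SASA_AB)/2 — the per-side
convention of interface analysis; published interface figures do not
always say which convention they use, so the convention is stated here
and in the function documentation. Alternate locations resolve to the
highest-occupancy conformer with file order breaking ties. All
threshold comparisons carry a 1e-9 epsilon so that exact boundary
values (3.00 Å, −7.0 kcal/mol, 2.0 Å radius, 90 %) land on the
inclusive side regardless of floating-point representation.

## Known limitations

Only MODEL/ENDMDL multi-model PDB is accepted as the trajectory carrier
(binary MD formats are assumed pre-converted); no mmCIF, no hydrogen
placement, no protonation assignment, no tautomer or stereoisomer
enumeration, no hydrogen-bond angle criteria, and no free-energy
methods. The pipeline's file formats are plain text throughout, which
bounds it to desk-scale and pre-converted inputs by design.
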