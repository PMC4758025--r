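---
title: "Isotope-coded cross-link validation: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Isotope-coded cross-link validation: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
library(xlinkr)
```

## The problem

Chemical cross-linking coupled with mass spectrometry (XL-MS) turns covalent
bridges between residues into distance restraints on protein-complex
architecture. The analysis is dominated by its false-discovery problem: the
candidate space of cross-linked peptide pairs grows quadratically with the
database, informative inter-protein links are vastly outnumbered by dead-end
and intra-peptide products, and a fragment-matching score alone cannot be
trusted — plausible-looking assignments can contradict known structure
outright.

`xlinkr` implements a stringent identification scheme built around an
isotope-coded linker. The sample is reacted with a 1:1 mixture of light
(H12) and heavy (D12) BS3, so every genuinely cross-linked species appears
twice: once at its light mass and once exactly 12 x (m(2H) - m(1H)) =
12.0753 Da higher. A cross-link is accepted only if

1. it is identified independently in both the light and the heavy form,
2. the two precursors co-elute, and
3. their fragment-ion patterns agree.

Fragments that do not span the link site have identical m/z in both spectra;
fragments that do span it shift by 12.0753/z. Both facts are checked.

## Mass model

All masses are monoisotopic, from a single embedded constants table
(`mass_constants()`); average masses are never used. The BS3 bridge
(octanedioyl, C8H10O2) adds 138.0681 Da to a cross-linked pair; the dead-end
(hydrolyzed) form adds bridge + water = 156.0786 Da; a loop link adds the
bridge to a single peptide. The heavy form adds 12.07532 Da to each of these
— identical across attachment chemistries, which the test suite asserts to
machine precision. Precursors are handled internally as neutral monoisotopic
masses; MGF I/O converts from/to m/z with the proton mass. Published
precursor values quoted in the worked examples are treated as neutral
masses; `mz_to_mass()`/`mass_to_mz()` flip the convention where needed.

## Search model and its defaults

The search reproduces a conservative high-resolution Orbitrap
configuration:

| parameter | default | meaning |
|---|---|---|
| `precursor_tol_ppm` | 3.0 | precursor match window (ppm) |
| `fragment_tol_da` | 0.8 | ion-trap fragment window (Da) |
| `snr_min` | 2.0 | noise floor = median peak intensity x S/N |
| `mass_min`/`mass_max` | 200 / 5000 Da | peptide window, applied after modification enumeration |
| `missed_K` / `missed_R` | 3 / 1 | per-residue-type missed cleavages |
| `max_mox` | 2 | variable methionine oxidations |
| ion series | b, y | charges 1..2, within 300–2000 m/z |
| `min_precursor_charge` | 3 | singly/doubly charged precursors rejected |
| `pair_mass_tol_ppm` | 5 | tolerance on the 12.0753 Da pair shift |
| `rt_tol_min` | 0.5 min | co-elution window |
| `similarity_min` | 0.6 | minimum Jaccard pattern similarity |
| `sas_cutoff` | 35 Å | maximum solvent-accessible distance for BS3 |
| `fdr_target` | 0.05 | decoy-derived score threshold |

Design notes on points the configuration leaves open:

* **Digestion.** Trypsin cleaves after K/R; cleavage before proline is
  suppressed by default (configurable). Missed cleavages are counted per
  residue type, mirroring the "K:3, R:1" convention, not as one total.
  The N-terminal methionine is not auto-removed. A linker-blocked lysine
  still counts toward the missed-cleavage budget on the search side; the
  budgets are generous enough that this costs nothing in practice.
* **Reactive-site classes.** Site 1 is a lysine side chain or a protein
  N-terminus; site 2 additionally admits S/T/Y hydroxyls. "N-terminus"
  means the protein N-terminus; peptide N-termini created by digestion are
  not reactive sites. A lysine at peptide position 1 is enumerated both as
  a side-chain site and (on the first peptide of a chain) the N-terminal
  site.
* **Scoring.** Engine scores are engine-specific, so no published score
  threshold is ported. The score here is a binomial-survival statistic:
  `-10 log10 P(X >= k)` with `X ~ Binom(n, p)`, `k` matched of `n`
  theoretical fragments, and `p` the random-match probability
  `2 * tol * peaks / span` over the noise-filtered spectrum, plus an
  intensity bonus `20 * matched/total intensity`. Acceptance thresholds
  are always derived from the reversed-sequence decoy search at
  `fdr_target`, never fixed.
* **Noise floor.** The S/N setting needs a noise estimator; the median
  peak intensity is used because it is robust and deterministic.
* **Trypsin consistency.** Trypsin cannot cleave C-terminal to a
  linker-modified lysine, so a link site on a peptide's C-terminal K (that
  is not the protein C-terminus) contradicts the peptide's own boundaries
  and is flagged.
* **Pairing.** Co-elution defaults to |dRT| <= 0.5 min: isotopologue pairs
  co-elute almost exactly on reversed phase, and the window only absorbs
  scan-scheduling jitter. Pattern similarity is the Jaccard index over
  matched fragment *labels* (series, index, source peptide, charge), which
  makes linker-containing ions comparable despite their mass shift; the
  per-label shift (0 or 12.0753/z) is additionally asserted and
  inconsistent labels are dropped from the intersection. The 0.6 threshold
  encodes "the same pattern" while tolerating stochastic peak loss.
  Pairing is 1:1 greedy by (co-elution, score sum, smaller |dRT|).
* **Link collapse.** Redundant peptide evidence (missed cleavages,
  oxidation states, repeated elution) is grouped to unique links by the
  (protein, residue position) pair, with the N-terminus coded as
  position 0.

## Structural plausibility

The BS3 spacer is 11.4 Å; with two lysine side chains (~13 Å) and an
allowance for conformational dynamics, a cross-link is considered
structurally plausible when the *solvent-accessible surface* (SAS) distance
between the reactive atoms is at most 35 Å. The SAS distance is a shortest
path through solvent: a 3-D occupancy grid (default spacing 1.0 Å) blocks
every cell within vdW + probe radius (probe 1.4 Å; C 1.7, N 1.55, O 1.52,
S 1.8 Å; hydrogens ignored) of any heavy atom except those of the two query
residues — the query residue is excluded wholly, not just its side chain,
because the N-terminal reactive atom is a backbone nitrogen that would
otherwise sit inside its own occupancy sphere. The path is a 26-connected
uniform-cost search with step costs {1, √2, √3} x spacing; endpoints snap to
the nearest free cell within 2 x spacing (else "buried") and the snap
offsets are added. Paths are searched up to `max_dist` (default 70 Å = twice
the cutoff) inside the bounding box enlarged by `margin` (default
`max_dist/2` per side) so a path can circle the structure; both are
configurable. Reactive atoms are NZ (K), backbone N (N-terminus), OG/OG1/OH
(S/T/Y), with a CB-then-CA fallback carrying a recorded 3 Å slack that is
added to the cutoff.

Unresolved residues are first-class citizens: residues declared in SEQRES
but absent from ATOM records, or skipped in the numbering, yield
"unconstrained" — never pass, never fail. Flexible termini are the dominant
reactive sites precisely because they are mobile, and the same mobility
keeps them out of crystal structures; treating them as contradictions would
discard the most informative links.

## Docking assessment and SPR fitting

Docking models are scored with the standard CAPRI conventions, kept in one
constants block: contacts are residue pairs with any heavy-atom pair within
5 Å; fnat is the recovered fraction of reference contacts; L-RMSD is the
ligand-backbone RMSD after superposing on the receptor backbone
(closed-form SVD superposition with det +1 enforced); i-RMSD superposes on
the backbone of reference interface residues (10 Å criterion). Classes:
high (fnat >= 0.5 and L-RMSD <= 1 or i-RMSD <= 1), medium (0.3; 5 or 2),
acceptable (0.1; 10 or 4), else incorrect.

Steady-state SPR titrations are fitted to the one-site isotherm
`Req = Rmax C / (KD + C)` by unweighted Levenberg–Marquardt least squares
(1/variance weighting available), with standard errors from the linearized
covariance at the optimum. Starts: KD at the concentration nearest
half-maximal response, Rmax = 1.1 x maximum response. A fit with
`kd_se/kd > 0.5` is flagged poorly determined, and a KD beyond half the top
concentration is flagged approximate — weak affinities read off the top of
a titration are order-of-magnitude statements.

## What the synthetic data emulate — and what they do not

The generator (`make_toy_complex()`, `plant_crosslinks()`,
`simulate_spectra()`) exists so the whole pipeline can be exercised against
known ground truth. It emulates the features the method actually relies on:

* ideal helical chains packed so reactive-pair distances straddle the 35 Å
  constraint, with configurable unresolved N-termini (the generator keeps
  the full geometry for itself; the emitted PDB omits the unresolved
  atoms, so structural filtering of terminal links returns
  "unconstrained", as with real crystal structures);
* planted links sampled under the SAS constraint, with 90% involving a
  protein N-terminus by default (the empirically dominant class), each on
  a distinct tryptic peptide pair so links remain distinguishable;
* paired light/heavy spectra at charge >= 3 whose precursors differ by
  exactly 12.0753 Da; per-fragment detection (efficiency 0.7) and base
  intensity are drawn once per link and shared between the forms with
  small multiplicative jitter, because isotopologues fragment
  identically — that shared pattern *is* validation criterion 3;
* retention times from a deterministic sequence hash with 0.05 min jitter,
  log-normal intensities, 30 uniform noise peaks per spectrum, and
  optional noise-only spectra with random precursors.

It does not model isotope envelopes, charge-state distributions beyond the
z >= 3 rule, chromatographic peak shape, or co-fragmentation. Passing the
end-to-end suite therefore demonstrates the correctness of the bookkeeping,
scoring, pairing and filtering logic under realistic ambiguity — not
instrument-level realism.

One behavior worth knowing: same-mass site assignments (an N-terminus
versus a nearby lysine on the same peptide, K versus S/T/Y) are genuinely
indistinguishable when the few site-discriminating fragments happen to go
undetected. The light and heavy searches then occasionally disagree on the
site, the assignments fail criterion 1, and the link is dropped rather than
reported wrongly — the same trade of sensitivity for specificity the
three-criteria scheme makes on real data.

## Problem sizes and determinism

The shipped test suite uses a 5-chain, 40-residue complex with 20 planted
links, paired spectra and 400 noise-only spectra (ten per true spectrum) for
the end-to-end recovery checks, and a 4-chain, 6-link fixture for byte-level
determinism of the pipeline outputs; affinity recovery uses 100 seeded
triplicate titrations per ground-truth KD. All generators draw from a single
seeded RNG stream with a documented draw order, and the pipeline is
reproducible byte-for-byte under a fixed seed — the run log omits wall-clock
timestamps by default (`log_timestamps`) for exactly that reason.

## Known limitations

* Neutral losses are off by default and only ever considered for already
  matched fragments; no immonium or internal ions.
* The mmCIF path relies on `bio3d::read.cif` and inherits its constraints;
  SEQRES-based unresolved-residue detection assumes author numbering
  matches the declared sequence positions.
* The SAS grid search is resolution-limited: 26-connectivity overestimates
  path lengths by up to ~8%, and refining the grid can shorten paths by up
  to one coarse step cost.
* Quantification of light/heavy intensity ratios is out of scope; the 1:1
  mixture is used for validation only.
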