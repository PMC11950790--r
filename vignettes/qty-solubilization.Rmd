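---
title: "Methods: QTY solubilization analysis of membrane protein complexes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: QTY solubilization analysis of membrane protein complexes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtysol)
```

## The problem and the model

Alpha-helical membrane proteins expose hydrophobic residues — mostly
leucine, isoleucine, valine and phenylalanine — on the lipid-facing surface
of their transmembrane (TM) helices. This is what makes them insoluble
without detergent. The QTY code is a deterministic substitution rule that
replaces each of these four residues with a hydrophilic residue of similar
side-chain shape and electron density:

| native | analog |
|--------|--------|
| L (leucine) | Q (glutamine) |
| I (isoleucine) | T (threonine) |
| V (valine) | T (threonine) |
| F (phenylalanine) | Y (tyrosine) |

Because Q, T and Y are uncharged, the substitution changes neither the
charge composition nor — to a good approximation — the isoelectric point,
while it raises the molecular weight slightly (each analog residue is
heavier than its native counterpart; the largest step is L→Q at +14.97 Da).
The package applies this rule inside user-supplied TM annotations
(`apply_qty_code()`, default scope `tm_only`), reports variation
percentages over the whole chain and within the TM region, and renders
native-vs-analog alignments.

The downstream question is whether the analog preserves the native fold and
the native inter-subunit interfaces. That is answered structurally, by
comparing a predicted analog structure against an experimental reference
with three instruments:

1. **Loop-trimmed Cα superposition.** Residues are paired by author number
   within mapped chains (`build_correspondence()`); residues resolved in
   only one structure — typically loops unmodelled in a CryoEM map — are
   trimmed and listed, and QTY-substituted identities (L~Q, I/V~T, F~Y) are
   treated as matching. The optimal rigid fit is the closed-form Kabsch
   solution with determinant correction (`kabsch_superpose()`), reported as
   Cα RMSD.
2. **Hydrophobic surface fraction.** Shrake–Rupley solvent-accessible
   surface area with a 1.4 Å probe, summed per residue; the hydrophobic
   fraction is the SASA of {L, I, V, F, M, W, A} residues over the total,
   optionally restricted to the TM region (`shrake_rupley_sasa()`,
   `hydrophobic_fraction()`).
3. **DockQ interface quality.** For every chain pair in contact,
   `score_complex()` computes Fnat (fraction of native residue–residue
   contacts, heavy-atom cutoff 5 Å, preserved in the model), LRMS (backbone
   RMSD of the smaller chain after fitting on the larger), iRMS (backbone
   RMSD over native interface residues, 10 Å definition, after fitting on
   them), and the composite

   $$\mathrm{DockQ} = \tfrac13\!\left(F_\mathrm{nat}
     + \frac{1}{1+(\mathrm{LRMS}/8.5)^2}
     + \frac{1}{1+(\mathrm{iRMS}/1.5)^2}\right),$$

   binned into CAPRI classes (≥ 0.80 High, ≥ 0.49 Medium, ≥ 0.23
   Acceptable, else Incorrect; boundaries belong to the better class).

## Parameters that matter

| parameter | default | unit | why |
|---|---|---|---|
| substitution scope | `tm_only` | — | characteristics tables report TM variation separately and published alignments confine substitutions to helices; `whole_sequence` exists for experimentation |
| pKa set | Bjellqvist (N-term 7.5, C-term 3.55, D 4.05, E 4.45, H 5.98, C 9.0, Y 10.0, K 10.0, R 12.0) | pH | the set used by the Expasy Compute pI tool, the de-facto standard for such tables; configurable |
| residue masses | Expasy average masses + 18.02 water | Da | matches published MW columns |
| contact cutoff | 5.0 | Å | DockQ standard native-contact definition |
| interface cutoff | 10.0 | Å | DockQ standard interface-residue definition |
| DockQ scaling | 8.5 / 1.5 | Å | DockQ standard constants for LRMS / iRMS |
| backbone atoms | N, CA, C, O | — | DockQ convention |
| probe radius | 1.4 | Å | water probe, standard in SASA work |
| sphere points | 960 | — | ≤ 1% quadrature error on an isolated sphere; doubling changes totals < 0.5% |
| vdW radii | Bondi-style (C 1.70, N 1.55, O 1.52, S 1.80, P 1.80) | Å | published standard set; configurable |
| hydrophobic set | L, I, V, F, M, W, A | — | the set used in TM surface analyses; proline can be added for the broader Type-II helix definition |
| outlier rejection | off; optional 2.0 Å / 5 cycles | Å | refinement-style superposition commands reject outliers; both numbers are reported so the difference is visible |

## Numerical choices

* **pI** is found by bisection on [0, 14] to 0.001 pH; the net
  Henderson–Hasselbalch charge is strictly decreasing in pH, so the root is
  unique and always bracketed. Tests compare against a 10⁻⁴-step grid
  search and against `seqinr::computePI()`.
* **Kabsch** uses SVD of the 3×3 covariance with the determinant-sign
  correction, so the returned matrix is always a proper rotation. Collinear
  or coincident point sets (second singular value ≈ 0) are rejected as
  degenerate rather than silently fitted. Fewer than three paired atoms is
  an error. A quaternion (Horn) implementation serves as an independent
  oracle in the tests and agrees to 10⁻⁶ Å.
* **Receptor/ligand assignment** in DockQ follows chain size (more residues
  = receptor) with a lexicographic tie-break, making scores deterministic
  and chain-order invariant.
* **Interfaces with zero native contacts are excluded**, not scored 0:
  Fnat is undefined there. Medians are over scored interfaces only.
* **Overall complex DockQ** is the unweighted mean over scored interfaces;
  a native-contact-weighted mean is available (`weighted = TRUE`) since
  aggregation conventions differ between tools.
* **Variation percentages** are rounded to two decimals with banker's
  rounding, matching common table formatting.
* **Altloc handling** keeps the highest-occupancy conformer; waters,
  hetero ligands and hydrogens are dropped on reading.

## The synthetic-data generator

`make_tm_sequence()`, `make_helix()` and `make_toy_complex()` generate the
package's test fixtures, seeded and byte-reproducible:

* TM-like sequences: TM segments draw L/I/V/F with probability
  `hydrophobic_bias` (default 0.7, a typical TM hydrophobic density) and
  polar residues otherwise; loops are polar. The polar alphabet excludes
  L/I/V/F so the bias is exactly the substitutable density.
* Ideal helices: backbone plus CB on a helical wheel with 1.5 Å rise and
  100° twist (Cα–Cα ≈ 3.8 Å). The geometry is schematic — regular,
  clash-free and deterministic — not force-field packed.
* Toy complexes: parallel helices with 10 Å axis spacing, giving
  contact-rich interfaces between adjacent chains. Perturbations (rigid,
  per-atom Gaussian, ligand-only shift, loop deletion) carry a truth record
  with the exact transform, noise level or deleted residue set, so expected
  RMSD, LRMS and correspondence trimming are computable without re-running
  the generator.

What passing tests on these fixtures show — and do not show. They verify
the algorithms exactly (contact bookkeeping, optimal fits, the DockQ
formula, SASA quadrature) because every expectation is known analytically
or via an independently coded oracle. They do not exercise real-data
pathologies: alternate conformations beyond simple altlocs, insertion-code
heavy numbering, chain breaks, non-standard residues, or the packing
irregularity of real membrane interfaces. Conclusions about a real complex
still require the real files.

The analysis-scale runs in `scripts/acceptance.R` use 20 annotated
sequences (60–500 residues) and a 20-chain toy megacomplex of 30-residue
helices under 0.5 Å per-coordinate Gaussian noise — a 20-subunit problem
emulating a membrane-arm megacomplex at toy scale, with sub-angstrom
backbone error of the kind a strong structure predictor makes.

## Design decisions that were genuinely open

* **Correspondence by author numbering, not structural alignment.** The
  compared structures are the same protein ± QTY substitutions and share
  numbering by construction; a sequence-independent aligner (TM-align/CE)
  would add failure modes without adding information. Refinement-style
  superposition ("super"-like) is approximated by optional outlier
  rejection, not replicated bit-exactly, since its exact parameters are not
  part of any published record.
* **Monomer handling.** Chain maps always resolve one chain per side; if a
  reference contains a dimer, the map selects one monomer.
* **Proline.** Some Type-II helix definitions include P among hydrophobics;
  the surface-analysis default excludes it because the standard
  hydrophobic-patch set is {L, I, V, F, M, W, A}; callers can add it via
  `hydrophobic_set`.
* **Short helical stretches outside annotated TM segments** are left
  untouched in `tm_only` mode; whether published conversions also touch
  such stretches is not decidable from rendered figures, so the documented
  annotation is authoritative.

## Known limitations

* No TM-topology prediction: annotations are inputs.
* SASA is pure R; fine for fixture-scale and single-complex runs, slow for
  large batches.
* mmCIF support is limited to what the underlying bio3d reader handles.
* DockQ here scores chain pairs of a single model against a single native;
  no docking, pose generation or CAPRI tournament machinery.

## A worked example

```{r example}
set.seed(1)
rec <- make_tm_sequence("SU01", length = 120, seed = 42)
res <- apply_qty_code(rec)
res
cat(render_alignment(rec, res$analog_sequence, width = 60,
                     annotate_tm = TRUE))

tc <- make_toy_complex(3, 25,
                       perturbation = list(type = "gaussian", sigma = 0.5),
                       seed = 42)
corr <- build_correspondence(tc$native, tc$model)
kabsch_superpose(corr, tc$native, tc$model)
score_complex(tc$native, tc$model)
```
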