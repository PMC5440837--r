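# groovedock

Structural and statistical tools around a transmembrane (TM) protein–protein
interaction of the kind formed between the mitochondrially encoded complex I
subunit ND2 and the NMDA receptor: a "short" TM helix bundle carries a lateral
groove (left by the evolutionary loss of three N-terminal helices present in
its "long" bacterial homolog, NuoN), and that groove receives the protruding
M4 helix of a receptor subunit (GluN1). The package implements the
computational core of such a study end to end, with synthetic generators for
every input, so the whole pipeline runs and is tested without any downloads.

## What it computes

**Template-guided rigid docking.** Given a long-homolog template whose extra
helix fills the groove, a short query bundle, and a receptor with a target M4
helix, `template_guided_dock()` performs the three-step procedure:

1. superpose the template's groove-filling helix onto the receptor's M4 by
   least-squares (Kabsch) fit of the Cα traces (N-to-C correspondence,
   centre-trimmed);
2. rotate the template about the fitted M4 axis to the orientation with the
   fewest steric clashes (inter-body heavy-atom pairs closer than 2.5 Å on
   side-chain-stripped structures), scanning 0–359° at a 1° step;
3. transfer the query onto the oriented template by superposition over their
   shared atoms.

If every rotation clashes beyond a ceiling the groove is reported as
*occluded* — the expected outcome when docking against the long homolog whose
groove is filled, as in pre-bilaterian ND2.

**Interface quantification.** Shrake–Rupley solvent-accessible surface area
(deterministic golden-spiral quadrature), buried interface area by the
difference formula `[SASA(A) + SASA(B)] − SASA(AB)`, contact residue pairs,
and identification of the groove-lining helices.

**Assay statistics.** Costes-thresholded Pearson co-localization coefficients
for two-channel cell images (reduced-major-axis threshold line, walk-down
stopping when the below-threshold correlation is ≤ 0); BiFC scoring with the
strict `> 3.5 ×` cell-background positivity rule and control-normalized Venus
intensities; Kruskal–Wallis with Dunn's post hoc, Welch's one-way ANOVA, and
mean ± s.e.m. summaries; Stretcher-convention global protein alignment
(affine gaps, penalized end gaps) with percent identity/similarity over the
full alignment length.

**Synthetic data.** Ideal TM helices (rise 1.5 Å, twist 100°/residue, Cα +
pseudo-Cβ), ring bundles with a groove, the long/short homolog pair, a
tetrameric receptor fixture with protruding M4 helices, planted ground-truth
docking scenes, two-channel images with a known co-localized fraction, and
BiFC intensity tables.

## Worked example

```r
library(groovedock)

pair  <- make_long_short_pair()                    # long/short bundles + filler
rf    <- make_receptor_fixture()                   # tetramer with 4 M4 helices
scene <- plant_complex(pair$short, rf$receptor,    # ground-truth scene,
                       rf$m4_segments[[1]],        # bundle rotated 137 deg
                       true_angle = 137)           # about the M4 axis

res <- run_dock_and_score(list(
  template = pair$long, query = pair$short,
  receptor = scene$scene$receptor,
  filler = pair$filler, target_m4 = rf$m4_segments[[1]]))
res$dock
#> <dock_result> best_angle 137.0 deg, clash_count 0, 35 contact residue pairs
#>   buried interface area: 2061.9 A^2
groove_lining(res$dock$query_docked,
              select_atoms(scene$scene$receptor, "O", rf$m4_segments[[1]]))
#> [1] "H06" "H08"
```

The dock recovers the planted 137° rotation exactly, with no residual severe
clashes; the docked interface buries ≈ 2060 Å² summed over both partners, and
the helices in contact with M4 are exactly the two ring neighbours flanking
the groove (`H06`, `H08`), the fixture's analogues of the groove-forming TM
helices.

```r
cells <- simulate_coloc_images(coloc_sim_params(n_cells = 5,
                                                coloc_fraction = 0.8, seed = 42))
run_coloc_batch(list(cells = cells, groups = rep("GluN1-like", 5)))$summary$table
#>        group      mean        sem n
#> 1 GluN1-like 0.8584016 0.01383045 5
```

Five simulated cells with 80% co-localized puncta score a mean thresholded
PCC of 0.86 ± 0.01 (n = 5) — the `mean PCC ± s.e.m.; n` reporting style of
co-localization studies. Fragment residue ranges used by the deletion-construct
experiments are registered, e.g. `fragment_bounds("ND2-TM-6-8")` is
`c(151, 223)`.

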