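# cngdyn

Coarse-grained structure evaluation and dynamics analysis for cyclic
nucleotide-gated (CNG) ion channel models.

CNG channels mediate visual and olfactory signal transduction: tetramers in
which each subunit carries a voltage-sensor domain (S1–S4), two pore-forming
helices (S5/S6 plus pore helix and selectivity filter), and a cytosolic
C-linker + cyclic nucleotide-binding domain (CNBD) that gates the pore.
High-resolution structures of intact subunits are scarce, so the field works
with homology models — which need quality assessment — and with
coarse-grained dynamics, which is insensitive to a model's atomic
imprecision.  `cngdyn` is for structural bioinformaticians doing exactly
that: it evaluates Cα-level channel models and extracts their slow,
gating-relevant motions.

## What it computes

**Elastic network models.**  The structure becomes a network of Cα nodes
joined by uniform springs.  The Gaussian network model (GNM) uses the
N×N Kirchhoff matrix **Γ** (contacts within 10 Å); residue cross-correlations
are

  ⟨ΔR_i · ΔR_j⟩ = (3k_BT/γ) [Γ⁺]_ij = (3k_BT/γ) Σ_k λ_k⁻¹ (u_k u_kᵀ)_ij

summed over non-zero modes, with k_BT/γ = 1 Å².  The anisotropic model (ANM)
replaces **Γ** by the 3N×3N Hessian (cutoff 15 Å; six rigid-body zero modes)
and adds directions: mode-displaced "edge" conformations, domain rotation
angles about the membrane normal, pore-radius changes.  Mode k contributes
100·λ_k⁻¹/Σλ_j⁻¹ percent of the motion; hinges are the minima of per-mode
fluctuation profiles.

**Model evaluation.**  The strongest ⌊2L/3⌋ evolutionary couplings of a
domain (L = sequence length) are overlaid on the model's contact map at a
12 Å Cα cutoff; a coupling counts as in contact through *any* intra- or
inter-chain realization in the tetramer.  Alternative models are ranked by
overlay fraction.  Conservation (ConSurf-style grades 1–9) and
hydrophobicity tracks are scored against Cα burial by Spearman rank
correlation (a ConQuass-style surrogate), and loop decoys ranked by that
score.  A deterministic on-axis probe yields pore-radius profiles along the
channel axis.

**Synthetic data.**  Deterministic generators for rings/chains with
closed-form spectra, C4 helix bundles, coupling tables with planted contact
precision, conservation tracks with planted burial correlation, and a fully
synthetic cone-channel heterotetramer (two CNGA3-like + two CNGB3-like
chains) whose architecture encodes the published landmark geometry.  Every
analysis is testable offline.

## Worked example

```r
library(cngdyn)

channel <- synthetic_cone_channel()      # synthetic heterotetramer stand-in
channel
#> coarse_structure: 1800 residues, 4 chain(s) [A:450 B:450 C:450 D:450]
#>   annotations: TM, cytosolic, VSD, pore, S1, C-linker, CNBD, hinge_ref

ca_distance(channel, c("A", 361), c("A", 385))   # within a CNGA3 subunit
#> 9.8        # ~10 A: the L361/F385 pair can interact
ca_distance(channel, c("B", 385), c("C", 403))   # to the adjacent CNGB3
#> 7.1        # ~7 A: inter-subunit contact at the pore

homo <- cnga3_homotetramer(channel)      # symmetric CNGA3-only channel
gnm <- decompose(build_kirchhoff(homo, cutoff = 10))
gnm
#> spectral_decomposition (GNM): 1800 modes, 1 zero mode(s)
#>   slowest non-zero eigenvalues: 0.03997, 0.2713, 0.2713, 0.3284, ...
```

Mode 1 is non-degenerate and dominant (20.7% of the motion); modes 2/3 form
the degenerate pair that C4 symmetry requires.  Its hinge falls on the S6
termini — the gating pivot:

```r
mode_contribution(gnm, 1)
#> 20.7
detect_hinges(mode_shape(gnm, 1), chains = homo$residues$chain,
              resno = homo$residues$resno)
#>   chain start end
#>       A   313 330
#>       A   387 413     # overlaps the 401-407 pivot at the S6 C-termini
```

Coupling overlay with a planted-precision table (75% of the top-2L/3 pairs
are true contacts; the overlay recovers it):

```r
map <- compute_contact_map(channel, cutoff = 12, min_sequence_separation = 5)
tab <- select_top(make_coupling_table(map, 200, precision = 0.75,
                                      L = 240, seed = 1))
overlay_contacts(tab, map)
#> overlay_result: 124/160 couplings in contact (77.5%) at cutoff 12.0 A
#> [tetramer pairing]
```

End-to-end runs (`run_dynamics()`, `run_model_evaluation()`) write TSV/PDB
bundles; the same pipelines are scriptable via
`Rscript inst/cli/cngdyn.R <dynamics|evaluate|synth|distance> ...`.

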