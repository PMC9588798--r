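# igmhinge

Quantitative tools for the hinge-equivalent motion of IgM-class antibody
assemblies and for the single-molecule FRET dynamics of their Fc domains.

Pentameric IgM carries its ten antigen-binding Fab arms on a rigid
Cμ4–Cμ3/J-chain core. The hinge-equivalent element is the Cμ2 domain: each
F(ab')₂ unit (two Fabs plus the Cμ2 dimer) pivots as one rigid body about a
point at the Cμ2/Cμ3 interface, both within the plane of the core platform
(angle α, measured from the two-fold axis of the Cμ4 dimer) and out of it
(angle β, the elevation above the Cμ4–Cμ3 platform). In a cryo-EM
reconstruction this motion turns each mobile F(ab')₂ into a blurred
"probability cloud": the map is the convolution of the rigid-body density
with the orientation distribution of the motion. This package implements
the computations that make that picture quantitative:

- **Model geometry** — PDB/mmCIF parsing (via bio3d), least-squares
  (Kabsch) superposition with RMSD, inter-atom distances, the pivot
  reference frame built from the Cμ4 two-fold axis and platform plane, and
  signed (α, β) Fab-arm orientations with the inter-arm angle
  `acos(u₁·u₂)`.
- **Density simulation** — pseudo-atom Gaussian rendering of a model into
  a voxel grid, rigid pivoting about the hinge, and the motion-blurred
  pivot ensemble: a weighted average of renders over an (α, β) orientation
  grid (±50° at 10° intervals by default). MRC/CCP4 mode-2 volume I/O.
- **Arc quantifier** — the measurement procedure for the angular motion
  range: 3D Gaussian smoothing (σ = 3 px), six consecutive cross-sections
  per axis through the pivot, grey-value profiles along the arcs swept by
  the Fab constant (inner) and variable (outer) domains, and the
  background-noise criterion
  `(grey − mean(BKG)) / sd(BKG) ≥ 2`
  that bounds the motion range per sign. Arc radii are located
  automatically from a ring-mean radial profile or supplied as
  configuration; arc centres can be confirmed by least-squares circle
  fitting of ridge points.
- **smFRET analysis** — correction-factor estimation (donor bleed-through
  α = F/D in donor-only molecules, direct excitation β = F/A in
  acceptor-only molecules, detection factor
  γ = (F_before − F_after)/(D_after − D_before) from donor recovery after
  acceptor photobleaching), recovered donor fluorescence D + F/γ, the
  corrected efficiency
  `E = (F − αD − βA) / (F − αD − βA + γD)`,
  single-step photobleach detection, one/two-state Gaussian-mixture
  fitting (BIC), and dwell analysis with hysteresis.
- **Accessible volume** — sterically allowed dye positions on a flexible
  linker at a residue's Cβ, and the FRET-weighted mean inter-dye distance
  with the pair-averaged efficiency `⟨1/(1+(r/R₀)⁶)⟩` (R₀ = 5.1 nm for the
  Alexa Fluor 555/647 pair).
- **Synthetic ground truth** — deterministic toy hinge models with a known
  inter-arm splay, pivot-ensemble maps with known angular ranges and
  optional voxel noise, and two-state Markov FRET traces with known states,
  rates, correction factors and single-step bleaching, so every stage is
  testable without any deposited data.

## Worked example

```r
library(igmhinge)

# a two-arm rigid body splayed 50 degrees about the bisector
toy <- make_toy_hinge_model(hinge_truth(splay = 50))
oP <- measure_fab_orientation(toy$model, toy$frame,
                              toy$arms$P$cterm, toy$arms$P$constant_sel)
oQ <- measure_fab_orientation(toy$model, toy$frame,
                              toy$arms$Q$cterm, toy$arms$Q$constant_sel)
c(oP$alpha, oP$beta, oQ$alpha, oQ$beta)
#> [1]   0  25   0 -25
inter_arm_angle(oP, oQ)
#> [1] 50

# pivot the splayed unit over +-50 degrees out-of-plane and measure the
# density envelope
tru <- hinge_truth(in_plane_range = 0, out_of_plane_range = 50, splay = 50)
pm <- make_pivot_map(make_toy_hinge_model(tru), seed = 1)
mr <- motion_range(pm$map, toy$frame, axes = "out_of_plane")
mr
#> motion_range (reported arc: outer )
#>   out_of_plane negative   75.0 deg
#>   out_of_plane positive   75.0 deg
```

The measured envelope (75°) exceeds the generating pivot range (±50°) by
25° — half the inter-arm splay — because whichever arm leads in the pivot
direction extends the cloud by half the splay on each side. This is the
geometric signature that lets a rigid, splayed F(ab')₂ explain an
out-of-plane density range that is wider than the in-plane one.

```r
# two-state FRET traces analysed end to end
ft <- fret_truth()                      # E = 0.35/0.75, k = 2/s, gamma = 1.8
sim <- simulate_fret_traces(ft, 100, 10, seed = 1)
don <- simulate_fret_traces(ft, 30, 10, seed = 2, kind = "donor_only")
acc <- simulate_fret_traces(ft, 30, 10, seed = 3, kind = "acceptor_only")
analyze_fret_experiment(sim$traces, don$traces, acc$traces)
#> fret_analysis: donor bleed 0.092, direct excitation 0.080, gamma 1.788 (n=54)
#> state_fit: k = 2
#>   state 1: mean 0.351 sd 0.020 weight 0.54
#>   state 2: mean 0.751 sd 0.019 weight 0.46
#>   BIC: k1=3247.5, k2=31412.4
#>   transitions: 1.73 per s, occupancy 0.54/0.46
```

The pooled efficiency histogram resolves the two generating states (0.35
and 0.75) to within a few thousandths, the detection factor γ = 1.8 to
within 1%, and the 2 s⁻¹ interchange kinetics to within 15%.

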