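# tactoidMC

Monte Carlo simulation of hard spherocylinders confined to shallow
spindle-shaped (tactoid-mimicking) quasi-2D chambers, with the analysis
stack used to characterise confined colloidal liquid crystals: nematic
tensor order parameters (global and local, length-weighted), angular-deficit
maps, winding-number detection of half-integer disclinations, classification
of director-field patterns, and classification of the melt/slide/turn
relaxation pathways.

It is aimed at soft-matter researchers studying confined nematics of stiff
colloidal rods (fd virus, F-actin, and similar systems) who want a
self-contained, reproducible in-silico counterpart to microchamber
experiments.

## The model

* **Container.** The cross-section of two overlapping equal circles — a lens
  with cusps at $(0,\pm L_y/2)$, waist width $L_x$, arc radius
  $R=(L_x^2+L_y^2)/(4L_x)$ and cusp opening angle
  $\alpha = 4\,\mathrm{arccot}(L_y/L_x)$ — extruded to a depth $h$. All
  lengths are in rod diameters $d$.
* **Particles.** Hard spherocylinders (length $L$, diameter $d$) with hard
  particle–wall interaction; default working point $L/d=20$, $h/d=6$,
  volume fraction $\eta=0.16$.
* **Dynamics.** Standard single-particle Metropolis Monte Carlo
  (displacement + rotation), sweeps as the time proxy, bitwise reproducible
  from a seed.
* **Order analysis.** Global tensor order parameter
  $\mathbf{Q}=\frac1N\sum_i(\frac32\hat u_i\otimes\hat u_i-\frac12\mathbb{1})$;
  a local version $\mathbf{Q}^k$ on cuboidal sub-volumes weighted by the rod
  length $l_i^k$ inside each sub-volume; the angular deficit
  $\delta=\min\angle(\hat n^W,\hat n^E)+\min\angle(\hat n^S,\hat n^N)$;
  plaquette winding numbers plus geometry-aware boundary probes for defect
  detection. Detected charges of every complete pattern sum to +1, the
  Euler characteristic of the container.

See `vignettes/tactoid-methods.Rmd` for the full account of the methods and
the design choices.

## Worked example

Build a spindle, fill it with rods aligned along the minor axis, relax, and
analyse the final frame:

```r
library(tactoidMC)

geom <- spindle_geometry(90, aspect = 1.5, h = 6)
geom
#> Spindle container (lengths in rod diameters d)
#>   Ly = 90, Lx = 60 (aspect 1.5), h = 6
#>   arc radius R = 48.75, arc-centre offset c = 18.75
#>   cusp opening angle alpha = 134.8 deg

cfg <- build_initial(geom, "along_minor", eta = 0.16, seed = 7)
cfg
#> Rod configuration: 231 spherocylinders (L = 20 d, d = 1)
#>   container: Ly = 90, aspect = 1.5, h = 6
#>   realised volume fraction eta = 0.1601

traj <- run_sweeps(cfg, mc_params(sweeps = 20000, seed = 11,
                                  sample_every = 2000))
field <- local_Q_field(frame_config(traj, 9))  # the frame at sweep 16000
detect_defects(field, geom)
#>           x         y charge   locale
#> 1 -28.77435  10.86271    0.5 boundary
#> 2  25.58688 -20.26829    0.5 boundary
classify_pattern(field, geom)
#> Pattern: Dh (2 defects, total charge +1)
```

The two +1/2 wall defects facing each other across the waist are the
signature of the D$_h$ pattern that forms quickly from a minor-axis-aligned
start, before the slow relaxation into the bipolar equilibrium with both
defects in the cusps (pattern B$_\parallel$). `pathway_run()` and
`pathway_statistics()` run and classify full relaxation trajectories
(melt / slide / turn); `pattern_fixture()` generates analytic director
fields for every pattern class so the analysis stack can be exercised
without simulating.

A small CLI wraps the same pipeline (`inst/cli/tactoidmc`):

```sh
tactoidmc simulate --config run.yaml --out run.xyz
tactoidmc analyze  --traj run.xyz --out run
tactoidmc fixtures --pattern Bpar --out bpar.tsv
tactoidmc classify --field bpar.tsv --Ly 90 --aspect 1.5
```

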