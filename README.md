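# lvstem

Dark-field contrast modeling and image analysis for low-voltage STEM of
DNA origami nanostructures.

Unstained DNA is nearly invisible in conventional 300 kV TEM: light-element
specimens scatter weakly at high energy, so a thin origami slab barely
stands out from its carbon support. Running a transmission detector inside
an SEM at 30 keV and collecting electrons scattered into a low annular
range (15–55 mrad) changes that — scattering cross sections grow steeply as
the energy falls, and annular dark-field (DF) intensity becomes a direct
readout of local mass thickness. Single-acquisition DF images then resolve
single rectangular origami slabs (s-DN), doubly stacked slabs (d-DN), slabs
with a nano-square through-hole (nsh-DN) and origami carrying a gold
nanoparticle (h-DN), and simple ROI intensity ratios quantify layer number
and composition without any image averaging.

`lvstem` implements that whole quantitative workflow for people who model
or analyze such experiments:

* **Scattering physics** — small-angle Lenz elastic and inelastic cross
  sections. For element Z at wavelength λ,

      dσ_el/dΩ = λ⁴ Z² / (4π⁴ a_H²) · 1/(θ² + θ₀²)²,   θ₀ = λ/(2π a_H Z^(-1/3))
      dσ_in/dΩ = λ⁴ Z  / (4π⁴ a_H²) · [1 − θ₀⁴/(θ²+θ₀²)²] / (θ² + θ_E²)²

  with θ_E = ΔE/2E, integrated in closed form / by quadrature over the
  detector annulus, combined into per-material scattering tables
  (cross sections, mean free paths Λ) by atom-fraction mixing.
* **Analytic DF contrast** — a single-scattering exponential model for
  layered stacks: detected fraction
  S = exp(−Σᵢ tᵢ/Λᵢ(θ_out)) − exp(−Σᵢ tᵢ/Λᵢ(θ_in)), ROI contrast
  C = (I_D − I_B)/I_B, n-layer contrast ratios and the 30 kV/300 kV
  signal advantage.
* **Monte Carlo** — Woodcock-tracked electron trajectories through 3D
  specimen scenes (slabs, holed slabs, gold spheres on a carbon film),
  scored against the annulus to render DF images, line profiles and
  nanoparticle diameter sweeps, plus a secondary-electron (SE) proxy
  channel.
* **Synthetic micrographs** — a fast forward model (projection → signal →
  probe blur → Poisson noise → 8-bit quantization) generating seeded image
  populations with controlled size and contrast variability.
* **Image analysis** — segmentation, minimum-area-rectangle morphometry,
  automatic ROI contrast, reference-normalized contrast ratios,
  layer-number classification, line profiles, hole and nanoparticle
  detection, and population statistics — all returning tibbles that chain
  with the pipe.

## Worked example

Predict the DF contrast of a single origami slab (59.2 × 28.5 × 7.4 nm DNA
on 3 nm amorphous carbon, 30 keV, 15–55 mrad), then generate and measure a
small synthetic survey:

```r
library(lvstem)

det  <- annular_detector(15, 55)
film <- layer_stack(carbon = 3, label = "film")
sdn  <- layer_stack(carbon = 3, dna = 7.4, label = "film+sDN")

predict_contrast(sdn, film, beam = 30, detector = det)
#>   structure background energy_kev inner_mrad outer_mrad signal_structure ...
#> 1 film+sDN  film               30         15         55            0.137
layer_contrast_ratio(2)                                   # 1.803
layer_contrast_ratio(2, channel = "elastic",
                     model = "collection")                # 1.942
voltage_signal_ratio(sdn, 30, 300, det, relativistic = TRUE)  # 11.67

pop <- population_spec(n_images = 10, seed = 2) |>
  generate_population(beam = 30, detector = det)
meas <- purrr::map_dfr(pop$images$df, analyze_image, detect = FALSE) |>
  normalize_ratios("all")
population_stats(meas)
#>   class metric    mean    sd     n
#> 1 all   contrast  1.64 0.205    10
#> 2 all   length   59.5  3.25     10
#> 3 all   ratio     1    0.125    10
#> 4 all   width    29.3  2.66     10
```

Reading the numbers: the slab raises the detected fraction from 0.048
(bare film) to 0.137, a ROI contrast of 1.84. Two stacked layers give
1.80× the single-layer contrast under the default saturating model (1.94×
under the documented elastic collection variant — the theoretical anchor
for calling a structure double-layered), and the 30 keV condition collects
11.7× more DF signal from the same specimen than 300 keV. The measured
survey recovers the design dimensions (59.2 × 28.5 nm) to within a pixel
and closes at a mean normalized contrast ratio of exactly 1 with the
generated spread.

## Command line

A thin wrapper over the same functions ships in `inst/cli/lvstem.R`:

```sh
Rscript "$(Rscript -e 'cat(system.file("cli/lvstem.R", package="lvstem"))')" \
    synth --out out/ --seed 7
```

with subcommands `predict`, `simulate`, `synth` and `analyze`, all driven
by a YAML config (`read_run_config()`).
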