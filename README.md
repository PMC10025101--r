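# echinovision

Sea urchins such as *Diadema africanum* resolve coarse visual objects and
move toward them, despite having no eyes and no brain. `echinovision`
implements a firing-rate network model of how their decentralized nervous
system could do this: screened photoreceptor cells (PRCs) distributed along
the five ambulacra act as a low-resolution compound eye, radial-nerve (RN)
neuron groups are inhibited by light, and excitatory oral-nerve-ring (eONR)
neurons — disinhibited where light strikes — are read out as a population
vector that drives probabilistic taxis. The package is for computational and
sensory biologists who want to simulate arena experiments with isoluminant
patterned stimuli, probe how detection depends on photoreceptor optics, and
generate predictions for new stimulus families.

## The model

A stimulus is a 1-D angular intensity profile `X(φ)` on the wall of a
circular arena (ink 1 = black, intensity = 1 − ink). Each PRC group `i` on
ambulacrum `k` (centres `φ_k = 72(k−1)°`, spread uniformly over
`φ_k ± δ`) has the rectified-cosine angular sensitivity

    f(φ) = [ (cos(φ − φ_dms) − a) / (1 − a) ]+ ,   a = 2 cos(Δρ/2) − 1,

whose full width at half maximum is the acceptance angle `Δρ`; its response
is the sensitivity-weighted, normalized integral of `X`, so a uniform field
of intensity `c` yields activity `c·r_max`. RN and eONR groups are sigmoidal
rate units, `S(x) = 1/(1 + exp(−2β(x − x_c)))`, with inputs normalized by the
maximal feedforward drive. PRCs inhibit RN groups on their ambulacrum; RN
groups effectively inhibit the nearest eONR groups (the inhibitory ONR
interneurons are folded into effective negative weights); RN and eONR groups
excite their neighbours laterally. The network is iterated synchronously to
its fixed point (tolerance 1e-5, cap 600 iterations).

Each eONR group's preferred direction is measured by probing with a 2° white
bar on darkness; the population vector `v = Σ_i r_i (cos φ_pref_i, sin
φ_pref_i)` signals detection when `|v| > θ_p = 5` and points at the inferred
stimulus bearing. Movement is either *static* (a final wall bearing drawn
from the centre-of-arena population vector) or *dynamic* (steps of 0.1
arena radii whose headings follow a two-component wrapped-Gaussian mixture
between stimulus capture and persistence). Cohorts are summarised by the
circular mean vector and Rayleigh / V tests.

Default parameters reproduce the reference configuration: 5 × 100 PRC and RN
groups, 500 eONR groups, `Δρ = 30°`, `δ = 15°` (effective acceptance angle
`Δρ + 2δ = 60°`), lateral strengths 0.25, RN sigmoid (β = 3, x_c = −0.6),
ONR sigmoid (β = 4.5, x_c = −0.45).

## Worked example

```r
library(echinovision)
library(dplyr)

model <- urchin_model() |> with_preferred_directions()

dog69 <- make_stimulus("dog", 69)     # difference-of-Gaussians, 69 deg target
pv <- population_vectors(model, dog69)  # all 360 initial orientations
summarise(pv, v_max = max(length), n_detected = sum(detected),
          best_psi = psi[which.max(length)])
#> # A tibble: 1 x 3
#>   v_max n_detected best_psi
#>   <dbl>      <int>    <int>
#> 1  5.83        135      336

cohort <- run_cohort(model, dog69, n_subjects = 100, n_replicates = 100,
                     mode = "static", seed = 1)
glance(cohort)
#> # A tibble: 1 x 8
#>   family phi_stim mode   n_subjects n_replicates mean_r_f_length mean_rayleigh_p
#>   <chr>     <dbl> <chr>       <dbl>        <dbl>           <dbl>           <dbl>
#> 1 dog          69 static        100          100           0.243          0.0308
```

`v_max = 5.83` exceeds the detection threshold `θ_p = 5`, but only from 135
of 360 orientations — those in which the gap between two ambulacra faces the
dark target region, so that each white flank of the DoG strikes one
ambulacrum. Averaged over random orientations this yields weak but
significant taxis toward the stimulus (mean Rayleigh p ≈ 0.031, mean V-test
p ≈ 0.008 across 100 replicate experiments), while the 40° bar (v_max ≈
3.2), the 29° DoG (≈ 1.4) and the uniform control (≈ 0) stay below threshold
and produce uniform final positions. `autoplot()` methods draw stimulus
profiles, arena cohort plots and parameter-sweep heatmaps;
`plot_population_vectors()` and `plot_trajectories()` mirror the standard
readout and trajectory figures; `vmax_heatmap()` maps detectability over the
`(Δρ, δ)` plane.

A thin command-line wrapper is installed under `inst/cli/urchin-vision.R`:

```sh
Rscript inst/cli/urchin-vision.R detect --stimulus dog --phi-stim 69 --out detect.csv
```

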