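# mechanopillar

Quantitative analysis of mechanically gated ion-channel currents evoked
by deflecting individual pili of an elastomeric pillar array beneath
adherent cells — the stimulation geometry used to characterize
mechanoelectrical transduction in chondrocytes (PIEZO1- and
TRPV4-dependent), where stimuli are delivered at cell–substrate
contacts while the cell is held in whole-cell patch clamp.

The package implements the complete measurement chain, plus seeded
synthetic-data generators for every input class so the pipeline is
fully testable without recordings:

| Stage | What it computes |
|---|---|
| `fitPillarCenter`, `measureDeflection`, `trackPillarScene` | subpixel pillar centers by 2D Gaussian fitting; stimulus magnitude *d* (nm) from before/during/after frames |
| `springConstant`, `deflectionToForce` | beam calibration *k* = (3/4)πE·r⁴/L³ and Hooke's law *F* = k·d |
| `detectEvent`, `fitActivation`, `fitDecay`, `extractKinetics`, `classifyRapid` | latency, mono-exponential τ₁ (activation) and τ₂ (decay), peak amplitude, direct-gating classification (latency < 5 ms, τ₁ < 1 ms) |
| `binResponses`, `classifyResponder`, `compareGroups` | two-stage binned stimulus–response curves, per-cell thresholds, responder fractions |
| `normalizeFamily`, `fitBoltzmann`, `fitPressureFamilies`, `peakCurrentSummary` | pressure-clamp Boltzmann fits, y(P) = A/(1+exp((P₅₀−P)/s)), per-patch P₅₀ |
| `deltaFOverF`, `scoreEpoch`, `scoreCalciumCohort` | ΔF/F = (F−F₀)/F₀ and agonist-epoch response scoring with ATP viability gating |
| `fisherExactTest`, `mannWhitneyTest`, `varianceRatioTest` | exact/nonparametric tests with enumeration oracles |
| `generatePillarScene`, `generateCurrentTrace`, `generatePressureFamily`, `generatePopulation`, `generateFluorescenceTrace` | seeded synthetic inputs with the published statistical structure |
| `validateConfig`, `runPipeline` | config-driven end-to-end run emitting all summary tables |

## Worked example

```r
library(mechanopillar)

## calibration: one pilus of the default array
geom <- PillarGeometry()          # E 2.1 MPa, r 1.79 um, L 5.87 um
geom
#> PillarGeometry: E = 2.1 MPa, r = 1.79 um, L = 5.87 um  (k = 251.1 pN/nm)
k <- springConstant(geom)
round(deflectionToForce(252, k))  # force at the mean gating threshold
#> [1] 63

## localize a synthetic stimulus from bright-field frames
sc <- generatePillarScene(trueDeflection = c(150, 80), readNoiseSd = 15,
                          nGrid = 3, seed = 42)
tr <- trackPillarScene(sc)
subset(tr, deflected, c(d_nm, truth_d_nm, recovery_nm))
#>     d_nm truth_d_nm recovery_nm
#> 7 167.88        170         2.4

## extract current kinetics from a simulated sweep
ph <- channelPhenotype("chondrocyte", latencyMean = 3.6, latencySd = 0.5,
                       tau1Mean = 1.7, tau1Sd = 0.3,
                       tau2Mean = 12.2, tau2Sd = 2,
                       peakAmpMean = 50, peakAmpSd = 10,
                       thresholdMean = 252, thresholdSd = 126)
trace <- generateCurrentTrace(ph, deflection = 500, duration = 300,
                              forceResponder = TRUE,
                              baselineNoiseSd = 2, seed = 7)
extractKinetics(trace)[, c("latency", "tau1", "tau2", "amplitude",
                           "rapid_gating")]
#>   latency tau1  tau2 amplitude rapid_gating
#> 1    4.89 1.39 11.46     44.26         TRUE
traceTruth(trace)[, c("latency", "tau1", "tau2", "amplitude")]
#>   latency tau1  tau2 amplitude
#> 1    4.89 1.36 10.75     45.18

## pressure-clamp Boltzmann fit
fam <- generatePressureFamily(p50 = 87.1, slope = 10, imax = 45.2,
                              noiseSd = 2, seed = 3)
fitBoltzmann(normalizeFamily(fam))
#> BoltzmannFit: P50 = 88.01 mmHg, slope = 9.23 mmHg, Imax = 47.35 pA (rms 0.023, converged)

## responder-fraction contrast (knockdown vs scrambled control)
signif(fisherExactTest(6, 6, 19, 3)$p, 3)
#> [1] 0.0403
```

The extracted kinetics sit on top of the generator truth stored in the
trace metadata — latency to the sub-sample level (the fitter refines
onset below the 0.1 ms sampling step and compensates the acquisition
filter's group delay), time constants within a few percent at this
noise level. The 63 nN figure is the mean chondrocyte gating threshold
(252 nm) converted through the array's spring constant.

A full config-driven run — cohorts, kinetics tables, binned
stimulus–response curves with group comparisons, pressure-clamp fits
and calcium scores — is one call:

```r
res <- runPipeline(list(seed = 1, output_dir = "out"))
res$comparison$responder   # responder fractions + Fisher p
res$hspc$p50_mean          # group P50 (mmHg)
```

## Documentation

The methods vignette (`vignettes/mechanopillar-methods.Rmd`) documents
the models, the operational definitions behind the kinetics extraction,
the synthetic generators' assumptions and their limits, and the
numerical choices (fit windows, filter design, truncation handling,
Edgeworth-corrected Mann-Whitney approximation).
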