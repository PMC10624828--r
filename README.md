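# fetalbiom

Automated fetal biometry and amniotic-fluid assessment from ultrasound
cine-loops, for researchers building or evaluating segmentation-driven
obstetric measurement pipelines.

A routine screening scan is a set of short free-hand sweeps: through the
fetal head, the abdomen, the femur, and the amniotic fluid pockets. Given
per-frame instance segmentations of those sweeps (from any external model —
segmentation is a pluggable backend contract, no network ships here),
`fetalbiom`:

1. **scores every frame** against ISUOG-derived standard-plane quality
   criteria with a composite score
   *S = w<sub>q</sub>Q + w<sub>z</sub>Z + w<sub>c</sub>C*
   (criterion probabilities, zoom conformity, detection confidence) and
   selects the best plane per loop;
2. **measures the selected plane**: head and abdominal circumference by
   sub-pixel contouring and direct least-squares ellipse fitting
   (constraint 4AC − B² = 1, stable partitioned formulation), BPD as the
   minor-axis diameter 2b, femur length from the minimum-area rotated
   bounding box, and pocket depth as the vertical bounding-box extent —
   all converted to cm with the DICOM pixel spacing;
3. **sweeps all amniotic pockets** in every frame and keeps the single
   deepest pocket (SDP), categorized by the clinical thresholds
   (< 2 cm oligohydramnios, > 8 cm polyhydramnios, strict inequalities);
4. **derives clinical quantities**: Hadlock estimated fetal weight
   log₁₀EFW = 1.335 − 0.0034·AC·FL + 0.0316·BPD + 0.0457·AC + 0.1623·FL
   (cm in, grams out) and Intergrowth gestational age
   ln GA = 0.03243(ln HC)² + 0.001644·FL·ln HC + 3.1813 (mm in, days out);
5. **evaluates agreement** between methods: MAE, percentage Bland-Altman
   limits of agreement (bias ± 1.96·sd), one-way ICC, paired Wilcoxon,
   sensitivity/specificity, Dice/IoU;
6. **reconstructs retrospective ground truth** from burned-in overlays:
   colored caliper crosses, dotted measurement ellipses, and OCR'd
   measurement text;
7. ships a **synthetic phantom generator** with exact analytic ground truth
   so every stage is testable without clinical data or trained weights.

## Worked example

Measure all four loop kinds of a synthetic examination and assemble the
clinical report (the phantom's oracle backend stands in for a trained
segmenter):

```r
library(fetalbiom)

out <- list()
for (kind in c("cephalic", "abdominal", "femoral")) {
  ph <- generate_biometry_loop(phantom_spec(kind, seed = 11))
  out[[kind]] <- measure_biometry_loop(ph$loop, phantom_backend(ph$truth))
}
pha <- generate_af_loop(phantom_spec("amniotic", seed = 11))
out$sdp <- measure_sdp_loop(pha$loop, phantom_backend(pha$truth))

report <- assemble_report(out)
report
#> <biometry_report>
#>   HC : 33.16 cm  BPD: 9.00 cm
#>   AC : 33.81 cm  FL : 7.04 cm
#>   SDP: 5.60 cm  (normal)
#>   EFW: 3147.05 g  GA : 140.5 d (20w1d)
```

Reading the output: the cephalic loop's best frame (frame 10, composite
score 0.997 — all criteria satisfied, conforming zoom, peak confidence)
yields a head circumference of 33.16 cm and BPD of 9.00 cm; the planted
phantom truth is HC 33.155 cm, BPD 9 cm, so recovery is within 0.02%. The
deepest of the three planted fluid pockets (5.6 cm) is normal. EFW
combines AC, FL and BPD through the Hadlock polynomial (3147 g, a
plausible term weight for this deliberately large phantom anatomy). The GA
of 140.5 days is the Intergrowth formula's output for these inputs with
its *printed* intercept — see `?formula_config` for why that intercept
produces low GA values and how to override it.

`write_report(report, "exam.json")` serializes to a fixed JSON schema
(absent measurements are explicit nulls, NaN is forbidden, byte-identical
for identical inputs); `read_report()` round-trips it.

A command-line front end wraps the same functions:

```sh
exec/fetalbiom phantom  --kind cephalic --seed 4 --out loopdir
exec/fetalbiom measure  --loop loopdir --kind cephalic --out ceph.json
exec/fetalbiom report   --merge ceph.json af.json --out exam.json
exec/fetalbiom evaluate --pred preds.csv --ref refs.csv --out stats.json
```

Exit codes: 0 success, 3 no plane/pocket found, 4 input error.

## Scope notes

The package reads multi-frame DICOM (uncompressed little-endian) and
PNG-frame directories with a plain-text sidecar; video containers should be
exported to one of those first. Training or bundling segmentation models,
growth-percentile lookups (FGR staging), and the four-quadrant AFI method
are out of scope. See `vignettes/fetal-biometry-methods.Rmd` for the full
model description, parameter defaults, study-design choices, and known
limitations.
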