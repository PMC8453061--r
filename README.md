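# mitosurv

Whole-blood mitochondrial DNA (wb-mtDNA) copy number estimated from SNP
genotyping-array probe intensities, and its association with 28-day
survival in sepsis and sepsis-associated ARDS.

## The problem

Circulating and whole-blood mtDNA abundance is a candidate early
prognostic biomarker in critical illness. When a cohort has been
genotyped on a SNP array, a relative wb-mtDNA copy estimate can be
recovered from the fluorescence intensities of array probes that target
the mitochondrial genome — without any additional assay — provided three
artifacts are controlled:

1. **Cross-hybridisation to NUMTs.** Nuclear genomes carry near-copies
   of mitochondrial segments. Only probes that match the mitochondrial
   reference with 100% identity *and* are maximally distant (in Hamming
   distance, both strands, every ungapped offset) from all nuclear
   sequence are informative about mtDNA dosage.
2. **GC waves.** Each sample has its own smooth intensity trend in
   probe GC content. Per-sample polynomial regression of log2 intensity
   on GC (degree 2 by default) removes it.
3. **Aberrant probes.** Probes whose mean corrected intensity lies
   beyond 1.5 SD of the mean of probe means are dropped.

The per-sample estimate is the mean **log R ratio** (corrected log2
intensity minus the per-probe cohort median) across retained probes,
z-standardized so downstream hazard ratios read *per SD of wb-mtDNA*:

```
LRR(p, i) = corrected(p, i) − median_i corrected(p, ·)
estimate(i) = mean_{p ∈ retained} LRR(p, i)
```

The association layer fits Cox proportional-hazards models of 28-day
survival (Efron ties), checks proportionality with the
Grambsch–Therneau scaled-Schoenfeld test, runs Kaplan–Meier / log-rank
on a median split, compares ROC curves with DeLong's test for two
correlated AUCs, and evaluates design power with the event-count
formula

```
n_event = ceil( 4 (Z_alpha + Z_beta)^2 / ln(RR)^2 )
```

which gives **88 events** for 90% power at RR = 2 (two-sided alpha
0.05).

Because no real cohort data ship with the package, a synthetic-data
module generates every input with known ground truth — latent per-sample
copy number driving mitochondrial probe intensities, planted NUMTs at
exact mismatch distances, per-sample GC waves, outlier probes, genotype
panels with planted call-rate/MAF/HWE/relatedness pathologies, and
survival under exact proportional hazards with administrative censoring
at day 28 — so every stage has a recovery target.

## Worked example

The `analysis/` scripts run the whole study on a synthetic 687-patient
cohort (264 ARDS) in order:

```sh
Rscript analysis/01_simulate.R
Rscript analysis/02_select_probes.R
...
Rscript analysis/06_power_and_recovery.R
```

Stage 2 prints the specificity screen:

```
17 of 100 probes selected
exclusion reasons:
no exact mitochondrial match  nuclear mismatch 0 < 2  nuclear mismatch 1 < 2
                          81                       1                       1
```

(the two excluded mitochondrial probes sit on planted NUMTs at Hamming
distance 0 and 1; the k = 3 NUMT probe survives). Stage 3 removes two
planted outlier probes and recovers the latent copy number at
r = 0.921. Stage 5 prints the stratified crude models:

```
 model  stratum   n events   hr  lo95 hi95        p proportionality_held
 crude      all 687    165 1.57 1.337 1.83 2.52e-08                 TRUE
 crude non_ards 423     75 1.14 0.914 1.43 2.40e-01                 TRUE
 crude     ards 264     90 2.73 2.119 3.53 9.78e-15                 TRUE
```

— the planted effect (HR 3.65 per SD of *latent* copy number, ARDS
stratum only) shows up in the ARDS stratum and nowhere else, attenuated
toward the null by the measurement error of the intensity-based
estimate, exactly as a real biomarker would be. Stage 6 confirms the
modelling layer itself is unbiased:

```
       design   n true_hr geometric_mean_hr ci95_coverage mean_events
 ards_stratum 264    3.65             3.663         0.952       95.67
  full_cohort 687    2.39             2.399         0.950      181.45
```

Equivalent one-call orchestration, with a file manifest and a Markdown
report:

```r
library(mitosurv)
run_pipeline(sim_config(seed = 1), out_dir = "results/run1")
render_report("results/run1")
```

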