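# latentmorph

Latent-space simulation of disease progression in 2D brain MR slices.

Multiple sclerosis (MS) produces diffuse structural change — ventricular
enlargement and brain atrophy — that is hard to characterize lesion by
lesion. `latentmorph` implements a generative-modelling approach to this
problem for researchers in quantitative neuroimaging: a style-based GAN is
trained unsupervised on slice images of patients and healthy controls
(HC); individual images are *projected* into the model's extended latent
space W+; a linear SVM separating the two cohorts' latent codes provides a
unit hyperplane normal **n** — the disease direction — and editing a
subject's code as

&nbsp;&nbsp;&nbsp;&nbsp; x(α) = G<sub>syn</sub>(w⁺ + α·**n**)

synthesizes that subject's plausible progression (α > 0, toward MS) or
regression (α < 0, toward HC). Progression is quantified by the brain
parenchymal fraction of each edited slice,

&nbsp;&nbsp;&nbsp;&nbsp; BPF = (V<sub>GM</sub> + V<sub>WM</sub>) / (V<sub>GM</sub> + V<sub>WM</sub> + V<sub>CSF</sub>),

with tissue volumes from a k-means (k = 4) segmentation, and tested with
paired t-tests against the α = 0 baseline.

Since clinical images cannot be shipped, the package includes a
first-class synthetic-data module: brain *phantoms* with controllable
ventricle size, cortical thickness, lesion load, age and slice covariates,
multi-echo T1w or ADC contrast — and exact tissue masks that double as
ground-truth oracles for every morphometric claim. Everything, including
the GAN's forward and backward passes, is implemented in R (with small
C++ kernels) and verified against finite differences; no external
pretrained weights are needed (the perceptual and Fréchet feature
embedders are pluggable, defaulting to fixed-seed random features).

## Worked example

The package-default scaled-down study (two 1000-phantom cohorts, toy GAN,
20 + 20 projected subjects; ~14 minutes on one CPU):

```r
library(latentmorph)

cfg <- pipeline_config(seed = 7, out_root = tempfile("demo"))
res <- run_pipeline(cfg, verbose = TRUE)
print(res$results$bpf_hc)
```

```
bpf_curve: mean BPF by alpha
      alpha  mean_bpf           p significant
1  0.000000 0.6688932          NA       FALSE
2  3.477889 0.6325099 0.270524458       FALSE
3  6.955779 0.5743232 0.031085007       FALSE
4 10.433668 0.5967464 0.003213035       FALSE
5 13.911557 0.6142624 0.031857287       FALSE
6 17.389446 0.5735697 0.020828688       FALSE
```

Reading the output: each row is one manipulation strength α (latent
distance along the SVM normal; the grid top is auto-scaled to the latent
cloud). `mean_bpf` is the mean segmented brain parenchymal fraction of the
20 HC subjects after being pushed toward MS by α. Pushing
healthy-control slices along the learned disease direction shrinks their
parenchyma — mean BPF drops from 0.669 at baseline to 0.574 at α_max, and
17 of the 20 subjects show a negative BPF-vs-α rank correlation. `p` is
the paired t-test of each column against α = 0 (`significant` flags the
0.001 threshold, not reached at this scale). Two desk-scale caveats are
visible in these numbers and discussed in the vignette: the toy GAN's
reconstructions bias absolute BPF below the phantoms' true ≈0.89, and the
per-α means are noisy — the trend, not the level, is the finding.
Individual pieces are available as ordinary functions (`make_phantom()`,
`gan_train()`, `project_image()`, `fit_direction()`, `conditionalize()`,
`manipulate_latent()`, `segment_tissues()`, `bpf_curve()`), and
`inst/cli/latentmorph` wraps them as shell verbs
(`simulate`, `train`, `project`, `direction`, `edit`, `analyze`, `run`).

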