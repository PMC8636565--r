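# nfkbGRM

Which minimal transcription mechanism explains a TNF-induced NFκB
target gene's expression time course?  Knocking down the feedback
inhibitor IκBα prolongs nuclear NFκB activity, yet many target genes
are induced *less*, and early-response genes switch off after their
peak despite the sustained signal.  nfkbGRM infers, per gene, which of
four delay-ODE transcription mechanisms best accounts for its
control and IκBα-knockdown (siIκBα) fold-change dynamics, driven by
the measured nuclear-NFκB fold-change trajectory NFkB(t):

* **simple** — dm/dt = k_syn · (K_D·NFkB(t−τ))^h / ((K_D·NFkB(t−τ))^h + 1) − k_deg·m, h = 1;
* **iffl** — an incoherent feedforward loop: NFκB also induces a
  competitor (p50, processing delay τ_TF = 7200 s) that competes for
  the target promoter (h = 2);
* **cycle3** — a 3-state promoter cycle C → O → A → C (closed, open,
  active chromatin; C+O+A = 1) with transcription from the delayed
  active state, producing post-induction repression;
* **v4** — the promoter cycle combined with the competitor.

The package implements the full inference protocol around these
models: trajectory preparation (basal subtraction, fold change,
replicate-specific rescaling to 2–100, monotone-cubic interpolation to
1-second resolution), a two-stage bounded multistart fit per gene ×
model × biological replicate minimizing the normalized RMSD of jointly
max-normalized fold changes plus a steady-state-drift penalty, a
cross-replicate concordance score over all 100 × 100 = 10,000 stage-2
parameter pairs, good-fit classification (control nRMSD < 0.5 and
siIκBα nRMSD < 0.39 in both replicates, plus control > siIκBα in
simulated MFI or AUC), and best-fit selection by smallest total nRMSD.
A synthetic-data generator emulating the experimental conditions (NFκB
trajectories with the characteristic two-peak control shape and the
prolonged, weaker siIκBα shape; expression tables simulated from each
mechanism with known ground truth) makes every stage testable without
external data.  TPM normalization with RLE size factors is included
for raw count input.

## Worked example

Generate the standard synthetic inputs, simulate the combined
promoter-cycle/competitor mechanism for one parameter set, and fit a
small cohort:

```r
library(nfkbGRM)

inp <- synthInputs()            # both replicates, prepared to 1-s grids
ps <- grmParamSet("v4", c(k_deg = 1e-3, k_1 = 1e-4, k_2 = 0.06,
                          K_D1 = 5, K_D2 = 2e-3, K_DTF2 = 5e-3,
                          tau = 1200))
sim <- simFoldChange(simulateGrm(ps, inp$rep1$ctrl))
sim
#> GrmSimResult (v4): 13 evaluation times over 0-180 min
#>   MFI 15.2, AUC 705.5 fold*min
round(foldChangeValues(sim), 2)
#>  [1]  1.00  1.00  1.00  1.41 15.23  9.15  4.88  3.09  2.54  2.46  2.37  2.29
#> [13]  2.22
```

The fold change peaks about 15-fold at 60 min and then falls back
while nuclear NFκB stays high — post-induction repression.  MFI is the
maximum fold induction; AUC is the trapezoidal area under the
fold-change curve over 0–180 min.

A small end-to-end run (two genes, two mechanisms, 8 starts per stage;
the analysis default is 100 starts):

```r
res <- runPipeline(nGenes = 2, nStarts = 8, seed = 3,
                   models = c("simple", "iffl"))
res$decisions[, c("gene_id", "best_fit", "true_model",
                  "total_nrmsd_simple", "total_nrmsd_iffl")]
#>       gene_id best_fit true_model total_nrmsd_simple total_nrmsd_iffl
#> 1 g001_simple   simple     simple       9.829981e-08     1.001277e+00
#> 2   g002_iffl     iffl       iffl       3.949545e-02     2.786305e-08
```

Each gene is called by the good-fit model with the smallest total
nRMSD (the sum of the control and siIκBα components over both
replicates); here both genes are assigned their generating mechanism.

A thin command-line wrapper over the same functions is included:

```sh
Rscript inst/scripts/run_pipeline.R run-all --outdir out --seed 7
```

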