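# spadom

Joint Bayesian cell-type clustering and spatial-domain segmentation for
single-cell resolution spatial transcriptomics, with multi-section support.

## The problem

Spatial transcriptomic platforms (STARmap, MERFISH, seqFISH+, osmFISH, and
high-definition sequencing-based arrays) measure a gene panel on individual
cells together with their positions in the tissue. Analysts typically want
two things from such data: the cell types, and the anatomical domains of the
tissue (cortical layers, nuclei, and so on). These questions are coupled — a
domain is best described by *which mixture of cell types* lives in it — yet
they are usually answered by two disconnected tools. spadom answers both at
once, so each analysis sharpens the other, and it can fit several adjacent
tissue sections jointly.

## The model

For cell $i$ with expression features $x_i$ (top $J$ principal components of
the library-size-normalized, log-transformed counts), cell type
$c_i \in \{1..C\}$ and spatial domain $z_i \in \{1..R\}$:

$$x_i \mid c_i = c \sim N(\mu_c, \Sigma), \qquad
  c_i \mid z_i = r \sim \mathrm{Cat}(\pi_r), \qquad
  z^{(l)} \sim \mathrm{Potts}(V^{(l)}, \beta),$$

where $\pi_r$ is the cell-type composition of domain $r$, $V^{(l)}$ the
k-nearest-neighbour graph of section $l$'s cells, and $\beta \ge 0$ the
spatial interaction strength — inferred from the data rather than fixed by
the user. Conjugate priors (normal-gamma on the means with feature scales
$\lambda_j$, inverse-Wishart on $\Sigma$, Dirichlet on $\pi_r$, uniform on
$\beta$ up to $\beta_{\max} = 4$) give Gibbs updates for everything except
$\beta$, whose doubly-intractable conditional is handled with an
exchange-algorithm Metropolis step; domain labels are sampled with the
Swendsen-Wang cluster algorithm, and label switching is resolved post hoc
with iterative ECR relabeling. See `vignette("spadom-methods")` for the full
account.

## A worked example

Simulate a four-layer tissue (scenario III: each domain holds three cell
types at 50/25/25) at the baseline design — 1127 cells, 200 genes, three-fold
median DE — and fit it:

```r
library(spadom)

sim <- simulate_experiment(sim_config(scenario = "III", seed = 1))
fit <- spadom(sim, C = 4, R = 4, n_iter = 4000, burn_in = 2000, seed = 1)
fit
#> Joint cell-type / spatial-domain fit
#>   1127 cells, 1 section(s), 20 features
#>   C = 4 cell types, R = 4 spatial domains
#>   Potts interaction beta = 0.754 (acceptance 0.22)
#>   domain sizes: 271 311 274 271
#>   cell type sizes: 287 273 264 303

summary(fit)
#> Cell type composition by spatial domain (posterior mean):
#>       domain1 domain2 domain3 domain4
#> type1    0.24    0.00    0.22    0.59
#> type2    0.26    0.46    0.00    0.21
#> type3    0.00    0.26    0.48    0.19
#> type4    0.50    0.27    0.30    0.01
#>
#> Potts interaction beta: 0.754 (95% CI 0.688 - 0.824), 2000 draws
#> Feature scales lambda (larger = more type-informative feature):
#>  [1] 12.08 11.13  8.73  0.34  0.33  0.35 ...

ari(fit$z, sim$true_z)   # spatial domain accuracy: 0.964
ari(fit$c, sim$true_c)   # cell type accuracy:      1
```

Read the summary as the estimated tissue architecture: each column is one
spatial domain's cell-type mixture, and the recovered 0.50/0.25/0.25 pattern
(with a different missing type per domain) is the design the data were
simulated from, up to label permutation. The composition error after label
matching is small:

```r
pc <- attr(match_labels(fit$c, sim$true_c), "perm")
pz <- attr(match_labels(fit$z, sim$true_z), "perm")
composition_rmse(fit$pi, sim$true_pi, pc, pz)
#> [1] 0.035
```

The feature scales illustrate the gene-selection idea built into the prior:
with four cell types, three principal components separate them, and exactly
those three get large $\lambda_j$. `plot(fit)` maps the inferred domains
onto the tissue; `plot(fit, "type")` maps the cell types.

File-based workflows use a manifest (`section_id, expr_path, coords_path`;
expression as MTX + sidecars or dense CSV): `read_spatial_inputs()` loads
it, and `run_pipeline(config)` runs preprocessing, graph construction,
fitting and output writing (labels, compositions, traces, config snapshot)
in one call. `write_sim()` writes a simulated experiment in the same
formats.

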