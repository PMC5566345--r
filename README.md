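# nmflink

Link prediction for undirected, unweighted networks by **kernel-fused
nonnegative matrix factorization**, with the classical similarity-index
baselines and a complete train/test evaluation protocol. The package is
aimed at network scientists and systems biologists who want to rank the
unobserved node pairs of a graph (protein interaction maps, food webs,
infrastructure networks, ...) by their likelihood of being true but
missing edges — and to benchmark that ranking honestly.

## The model

Let $A^1$ be the adjacency matrix of the observed (training) graph. A
graph kernel applied to $A^1$ — treating column $i$ as node $i$'s feature
vector — yields an *organization matrix* $R$: a second structural view of
the network (linear kernel $R=(A^1)^\mathsf{T}A^1$, a local
common-neighbor view; or the covariance of the columns, a global view).
The fused model factorizes $A^1$ while weighting each residual by that
view:

$$\min_{W\ge0,\,H\ge0}\;\sum_{ij}\,(1+\gamma R_{ij})\,(A^1_{ij}-(WH)_{ij})^2\;+\;\lambda(\lVert W\rVert_F^2+\lVert H\rVert_F^2)$$

solved by multiplicative updates (weighted Lee–Seung rules with Tikhonov
regularization; monotone, nonnegativity-preserving, deterministic given a
seed). Candidate pairs — those absent from the training graph — are ranked
by the symmetrized reconstruction $(WH+(WH)^\mathsf{T})/2$.

Also included:

* **Baselines** — CN, Adamic–Adar, resource allocation, Salton, Jaccard,
  CRA, and average commute time (Laplacian pseudo-inverse).
* **Metrics** — exact and sampled AUC, precision@L, prediction power
  $\log_{10}(\mathrm{Prec}/\mathrm{Prec}_{\mathrm{random}})$.
* **Protocol** — repeated random edge splits with paired seeds across
  methods (`run_experiment()`), $(\gamma,\lambda)$ sensitivity sweeps
  (`parameter_sweep()`).
* **Generators** — seeded Erdős–Rényi, planted-partition and planted
  low-rank graphs plus fixed toy graphs, so everything runs without
  external data.

## Worked example

```r
library(nmflink)

net <- planted_partition(100, 2, p_in = 0.3, p_out = 0.02, seed = 1)
network_stats(net)
#>    n   m avg_degree clustering_coefficient avg_shortest_distance heterogeneity
#>  100 803      16.06              0.2750077              2.099192      1.049458
#>  assortativity
#>    -0.06047499

sp <- split_edges(net, test_fraction = 0.1, seed = 7)
sp
#> <lp_split> n=100 m=803 L=80 (seed 7); 4227 candidate pairs

R   <- organization_matrix(sp$train_adjacency, "linear")
fit <- nmf_fit(sp$train_adjacency, R,
               nmf_config(C = 4, gamma = 0.1, lam = 2, restarts = 3, seed = 42))
fit
#> <nmf_fit> C=4 dense mode; objective 1116.65 after 183 iterations (converged), best restart 1/3

sc <- predict_scores(fit, sp, "nmf3-linear")
head(sc[, c("node_i", "node_j", "score", "is_test")], 3)
#>  node_i node_j     score is_test
#>      17     31 0.7511480   FALSE
#>      85     89 0.7272828   FALSE
#>       1     17 0.6631091   FALSE

evaluate_scores(sc, sp)
#>       method split_seed       auc precision prediction_power
#>  nmf3-linear          7 0.7495479    0.0375        0.2969735
```

The 80 held-out edges hide among 4227 candidate pairs (random-ranking
precision $80/4227 \approx 0.019$). The fused factorization ranks a random
test edge above a random non-edge ~75% of the time and achieves about
twice the random precision in its top 80 (prediction power ~0.3 orders of
magnitude). For comparison, the resource-allocation index on the same
split:

```r
evaluate_scores(local_similarity_scores(sp, "ra"), sp)
#>  method split_seed       auc precision prediction_power
#>      ra          7 0.7574105    0.0625        0.5188223
```

On two-block graphs of this density a large share of candidates are
within-block non-edges that look exactly like test edges at block level,
which caps the attainable AUC near 0.76 — both methods sit at that
ceiling. See the vignette for the model, the update-rule derivation
choices, and what the synthetic benchmarks do and do not demonstrate.

A thin command-line interface wraps the same functions:

```sh
CLI=$(Rscript -e 'cat(system.file("cli/nmflink", package = "nmflink"))')
Rscript $CLI simulate --kind sbm --n 100 --seed 3 --out net.edges
Rscript $CLI predict  --edges net.edges --test-fraction 0.1 --kernel linear \
                      --gamma 0.1 --lambda 2 --rank 4 --seed 11 --out scores.csv
Rscript $CLI baseline --edges net.edges --index ra --seed 11 --out ra.csv
Rscript $CLI experiment --edges net.edges --methods cn,ra,nmf3-linear \
                        --fractions 0.9,0.8 --repeats 20 --seed 42 --out results.csv
```

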