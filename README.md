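# gsreg — graph spectral regularization for neural network layers

Dense neural networks scatter what they learn across a hidden layer in an
order fixed by random initialization, which makes the layer essentially
unreadable. `gsreg` structures a designated hidden layer by identifying its
neurons with the nodes of a graph and adding a Laplacian smoothness penalty
on the layer's activations to the training loss:

```
loss = task loss + α · mean_over_samples( zᵀ L z ),     L = D − W
```

where `W` is a symmetric nonnegative adjacency over the neurons and
`zᵀ L z = ½ Σᵢⱼ Wᵢⱼ (zᵢ − zⱼ)²` measures how roughly the activations `z`
vary across edges. Training then pushes graph-adjacent neurons to respond to
similar inputs: a grid graph yields a 2-D "brain map" with per-class
receptive fields, and disconnected node pairs become "super nodes" that each
claim one cluster of the data.

When no graph is known in advance, the package *learns* one from the layer
itself: neurons are embedded by their activation profiles across samples,
affinities are computed with an adaptive-bandwidth Gaussian kernel
(`σᵢ` = distance to the k-th nearest other neuron), and training alternates
between rebuilding this co-activation graph and smoothing on it. On data
with `n` independent feature modules, the learned graph should decompose
into `n` connected components — a readable, graph-shaped summary of the
feature space. The intended audience is anyone embedding tabular or
single-cell data with small dense networks who wants the embedding's
coordinates to mean something.

The package is intentionally self-contained: the dense autoencoder /
classifier engine (Adam, backprop, seeded init) is ~200 lines of vectorized
base R, which keeps every run bit-reproducible from a seed.

## Worked example: recovering feature modules

Generate data with 3 independent binary feature modules, then learn a
feature graph over a 6-unit structured layer:

```r
library(gsreg)

dat  <- generate_module_data(n_modules = 3, n_samples = 512, seed = 5)
spec <- model_spec("autoencoding", layer_sizes = c(3, 32, 6))
cfg  <- graph_learn_config(alpha = 2, pretrain_epochs = 50,
                           outer_iterations = 40, inner_epochs = 100,
                           batch_size = 512, seed = 5)
res  <- learn_graph(spec, dat$data, cfg)

res$components
#> component_labeling: 3 components over 6 nodes (threshold 0.01)

round(res$final_graph$weights, 2)
#>      [,1] [,2] [,3] [,4] [,5] [,6]
#> [1,] 0.00 0.00 0.00 0.00 0.00 0.61
#> [2,] 0.00 0.00 0.61 0.00 0.00 0.00
#> [3,] 0.00 0.61 0.00 0.00 0.00 0.00
#> [4,] 0.00 0.00 0.00 0.00 0.61 0.00
#> [5,] 0.00 0.00 0.00 0.61 0.00 0.00
#> [6,] 0.61 0.00 0.00 0.00 0.00 0.00

res$components$labels
#> [1] 0 1 1 2 2 0
```

The six neurons have paired up — `{1,6}`, `{2,3}`, `{4,5}` — one pair per
ground-truth module, with within-pair kernel weight 0.61 (the value the
adaptive kernel assigns to mutual nearest neighbours) and cross-module
weights at zero. The component count equals the number of independent
factors in the data. Recovery is stochastic: across seeds about half of
runs fragment fully and the rest remain partially merged, so
the packaged experiment reports the modal count over 10 trials
(`component_recovery_trial(3, n_trials = 10)`); see the vignette for the
dynamics and the known limits (8-module recovery does not complete at these
settings).

Other entry points: `grid_graph` / `disjoint_pairs_graph` / `complete_graph`
for fixed structure, `train` + `class_average_maps` / `segment_embedding` /
`supernode_assignment` / `component_marker_correlation` for readouts,
`generate_hierarchy_data` / `generate_trajectory_data` for the other
synthetic benchmarks, and `run_experiment("<recipe>.yaml")` (or the
`inst/cli/gsreg.R` wrapper) for reproducible end-to-end runs with a JSON
manifest.

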