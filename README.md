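# negseg — subvoxel surface segmentation by non-Euclidean graph search

`negseg` segments stacks of terrain-like surfaces — retinal layers in OCT
volumes, the lumen–intima boundary of a vessel wall in MR — with **globally
optimal graph search at subvoxel accuracy**. It is aimed at quantitative
imaging work where layer thicknesses of one or two voxels matter and where
the half-voxel quantization of conventional graph search is the dominant
error source.

## The method

A terrain-like surface `z(x, y)` intersects every voxel column exactly
once. With smoothness bounds Δx, Δy on the z-change between neighboring
columns and separation bounds [δˡ, δᵘ] between coupled surfaces, the
λ-surface segmentation problem is solved exactly as a **minimum closed
set** in a node-weighted directed graph: node weights

    w(x, y, 0) = c(x, y, 0),   w(x, y, k) = c(x, y, k) − c(x, y, k−1)

telescope so that a closed set's weight equals the total on-surface cost of
its upper envelope, and the minimum closed set is found by one s–t maximum
flow. Conventionally the nodes sit at voxel centers, so results are
quantized to the grid.

`negseg` removes that quantization. Partial volume effects — boundary
voxels averaging the tissues on either side — encode where inside a voxel
the boundary lies. A deformation field computed from the cost volume,

    D = −∇(G_σ ∗ c),   normalized so  max |D| = half a voxel,

moves every node toward the nearby likely boundary (while keeping it inside
its own voxel), costs are re-sampled at the deformed positions,
`c′(p) = c(p + D(p))`, and the neighbor ranges of all smoothness and
separation arcs are recomputed on the deformed real-valued coordinates.
Node and arc counts are unchanged, global optimality is retained, and the
extracted heights are real-valued.

The package also ships the full evaluation apparatus: a layered-tissue
phantom generator with exact partial-volume rendering, a
bicubic-reconstruction → anti-alias → resample downsampling chain, mapping
of reference surfaces between grids, cylindrical unwrapping for vessel
walls, error reports (signed/unsigned surface and thickness errors, paired
t-tests, threshold-exceedance fractions), and an independent solver oracle
(exhaustive closed-set enumeration plus a 2D dynamic program).

## Worked example

Simulate a two-layer OCT-like experiment — a high-resolution phantom is
rendered with exact partial volumes, downsampled 10× along z into the
"input volume data", and the continuous reference surfaces are mapped onto
the coarse grid — then segment it with all three pipelines and compare:

```r
library(negseg)
b  <- simulate_bundle("two_layer_oct", seed = 1)
ev <- evaluate_bundle(b)
print(ev$table, row.names = FALSE, digits = 3)
#>                   mode mean_unsigned_surface mean_signed_surface
#>           conventional                0.2243            -0.04639
#>  smoothed_conventional                0.1115            -0.04555
#>          non_euclidean                0.0412            -0.00964
#>  mean_unsigned_thickness exceedance_0.5
#>                   0.3036          0.125
#>                   0.1483          0.000
#>                   0.0647          0.000
```

Errors are in voxels of the analysis grid against the mapped continuous
reference. Conventional graph search pays the quantization price (~0.22
voxel mean unsigned surface error; 12.5% of columns have a thickness error
above half a voxel); lateral smoothing of its output helps but cannot
recover the partial-volume information; non-Euclidean search reduces the
surface error about five-fold on the same input and empties the error tail.

Segmenting a volume directly:

```r
sp  <- benchmark_phantom(1)                       # two-layer noisy phantom
r   <- render_phantom(sp)
res <- segment_volume(r$volume, run_config(lambda = 2, sep = c(3, 8)))
print(res$surfaces)
#> <negs_surfaces non_euclidean> 24 x 12 columns, 2 surface(s), z range [5.750, 12.796]
surface_errors(res$surfaces, r$ground_truth)
#> <negs_errors non_euclidean> bias 0, 0 masked columns
#>  component id mean_signed sd_signed mean_unsigned sd_unsigned   n
#>    surface  1    0.006489   0.09044       0.06630     0.06173 288
#>    surface  2    0.003421   0.10220       0.08093     0.06233 288
#>  thickness  1   -0.003069   0.14331       0.11429     0.08626 288
```

`res$thickness[[1]]` holds the per-column thickness map (Eq. above:
`z₂ − z₁`), `res$manifest` the full run record (configuration, graph
statistics, normalization factor η, timings). A command-line wrapper with
`segment`, `simulate` and `evaluate` subcommands is installed at
`inst/cli/negseg.R`.

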