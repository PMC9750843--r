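# gardensim

Spatially explicit simulation of neighborhood-crowding bias in
common-garden (transplant garden) experiments.

## The problem

Common gardens compare plant source populations by growing them together
and testing group differences with a one-way ANOVA, under the assumption
that plants are independent replicates in a homogeneous environment. When
plants are spaced tightly enough to interact, neighborhood competition
violates that assumption: group differences can be inflated, deflated, or
reordered, and part of the measured "genetic" signal is really competitive
ability. `gardensim` is for ecologists and quantitative geneticists who
want to quantify that distortion for a planned or existing garden design
and choose a planting distance at which it is negligible.

## The model

Each live plant *i* in group *s* gets two predicted growth values per
census interval:

- full model: `mu_F = alpha_s + beta_s * Size_i + gamma_s * phi_i + e_i`
- base model: `mu_B = alpha_s + beta_s * Size_i + e_i`, `e_i ~ N(0, sigma^2)`

where the crowding index `phi_i = sum_{j != i} c_{s_j} * Size_j *
exp(b * D_ij^2)` accumulates neighbor crown volume discounted by a
distance-decay kernel (`b < 0`). The garden lattice is rescaled over a grid
of planting distances (default fifteen scenarios, 0.5–4 m) and parameter
uncertainty is propagated through posterior draws (default 2000, synthetic
by construction — see the vignette). Two statistics summarize the bias per
distance:

- the **relativized F**: `F(mu_F - mu_B) / mean F(mu_B)`, the ANOVA signal
  generated purely by spatial interactions, relative to the signal from
  intrinsic growth differences;
- the **full/base Pearson correlation** (computed with `sigma^2 = 0`),
  whose convergence to `r > 0.99` across posterior uncertainty defines the
  recommended minimum planting distance.

## Worked example

```r
library(gardensim)

layout <- make_grid_layout(seed = 1) |>    # 470 positions, 22 dead
  make_initial_sizes(seed = 2)             # lognormal crown volumes
draws <- make_posterior_draws(n_draws = 60, seed = 3)

res_f <- run_sweep(layout, draws, noise_mode = "independent", seed = 4)
res_r <- run_sweep(layout, draws, noise_mode = "none", seed = 4)
bs <- bias_summary(res_f, res_r)
bs
#> <bias_summary>
#>   distances: 0.5 to 4 m (15 scenarios), 60 draws
#>   mean relativized F: 1.887 at 0.5 m -> 0.033 at 4 m
#>   mean full/base correlation: 0.114 -> 1.000
#>   recommended minimum distance (r > 0.99, 68% band): 1.75 m
```

Read: at 0.5 m spacing, crowding alone generates between-group variation
almost twice as large as the intrinsic growth-rate differences
(relativized F 1.89), and the spatial and non-spatial models barely agree
plant-by-plant (r = 0.11); by 4 m the spatial signal has collapsed to the
noise floor (0.03) and the models coincide (r = 1.00). For this garden and
parameter set, plantings at 1.75 m or wider keep the 68%-band correlation
above 0.99, i.e. spatial interactions are unlikely to affect inference on
group means. `plot_relative_f()`, `plot_correlation_curve()` and
`plot_group_means()` draw the corresponding figures; `tidy()` / `glance()`
return the tables. `run_pipeline()` runs the same workflow end-to-end from
a config list or YAML/JSON file and writes all tables plus a run log.

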