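# cofluct

Edge-centric analysis of parcellated neural time series: detect
high-amplitude co-fluctuation **events**, cluster their patterns, and test
whether each event cluster corresponds to a **modular subgraph of the
structural connectome**.

## Who this is for

Researchers with (a) an N-parcel x T-frame functional time-series matrix,
(b) an N x N directed weighted structural connectome, and (c) node
coordinates, who want a tested, scriptable implementation of the
edge-time-series / event pipeline — plus a planted-structure synthetic
generator so every stage can be validated without any imaging data.

## The method in brief

1. **Edge time series.** For z-scored signals $z_i(t)$, the edge series
   $r_{ij}(t) = z_i(t) z_j(t)$ decomposes static FC exactly:
   $\frac{1}{T-1}\sum_t r_{ij}(t) = r_{ij}$ (Pearson). With $N = 182$
   parcels there are $N(N-1)/2 = 16{,}471$ edge series.
2. **Events.** The global amplitude
   $\mathrm{RMS}(t) = \sqrt{\frac{2}{N(N-1)}\sum_{i<j} r_{ij}(t)^2}$ has
   peaks; peaks whose height beats a circular-shift surrogate null
   (add-one permutation p, Benjamini–Hochberg at q = 0.05, per subject)
   are events.
3. **Clustering.** Event patterns ($z z^\top$, zero diagonal) are compared
   with Lin's concordance
   $C_{xy} = \frac{2\,\mathrm{Cov}(x,y)}{\mathrm{Var}(x)+\mathrm{Var}(y)+(\mu_x-\mu_y)^2}$
   and clustered by recursive consensus modularity maximization
   ($B = C - \langle C\rangle$) with permutation pruning of insignificant
   communities.
4. **Structure–function.** Each cluster centroid implies a bipartition
   $c^+/c^-$ (positively vs negatively active nodes). Its induced
   modularity on the directed connectome,
   $Q_{\mathrm{induced}} = \sum_{i,j\in c^+} B^{sc}_{ij} + \sum_{i,j\in c^-} B^{sc}_{ij}$
   with $B^{sc}_{ij} = W^{sc}_{ij} - k^{\mathrm{in}}_i k^{\mathrm{out}}_j / 2m$,
   is tested against an independent permutation null and a
   geometry-preserving (rotation or variogram-matched) null.

See `vignettes/cofluctuation-events.Rmd` for assumptions, parameter
meanings, numerical choices, and limitations.

## Worked example

Simulate the default synthetic world (40 nodes in two ring modules, 1000
frames, 20 injected events of amplitude 4 SD), detect events, and test the
event-derived bipartition against the planted connectome:

```r
library(cofluct)

d   <- simulate_dataset(synth_config())
z   <- standardize_timeseries(d$ts)
ets <- compute_edge_timeseries(z)
fc  <- compute_static_fc(z)
rms <- compute_rms(ets)
ex  <- find_local_extrema(rms)
nul <- build_null_peak_distribution(z, n_runs = 100, seed = 11)
ev  <- detect_events(ex, nul)
sum(ev$is_event)                       # 20 events among 310 RMS peaks

cats <- categorize_frames(ex, ev, z$T)
reconstruct_fc_similarity(ets, cats, fc, seed = 5)
#>         category mean_similarity sd_similarity n_frames_in_category
#> 1          event       0.9974497    0.00000000                   20
#> 2 non_event_peak       0.7223283    0.07523312                  290
#> 3         trough       0.3234425    0.09866224                  310
#> 4          other       0.5424858    0.10937233                  380

frames <- ev$frame[ev$is_event]
pats <- pattern_ensemble(lapply(frames, function(f) frame_pattern(ets, f)))
cen  <- compute_centroids(pats, rep(1L, length(frames)))$centroids[[1]]
bp   <- extract_bipartition(cen, n_iter = 100, seed = 2)

independent_permutation_null(d$sc, bp, n_perm = 1000, seed = 3)
#> <modularity_result> Q_induced = 211.4215, independent null: p = 0.000999 (n_perm = 1000)
geometry_preserving_null(d$sc, bp, d$truth$node_coordinates,
                         n_perm = 1000, strategy = "rotation", seed = 3)
#> <modularity_result> Q_induced = 211.4215, rotation null: p = 0.000999 (n_perm = 1000)
```

Reading the output: the 20 detected events recover all 20 injected frames;
the mean event pattern reconstructs static FC at r = 0.997 using 2% of the
frames, far above an equal-sized trough sample (r = 0.32); the bipartition
extracted from the event centroid matches the planted modules on 40/40
nodes and its induced structural modularity beats 1000 draws of both nulls
(smallest attainable add-one p = 1/1001).

For multi-subject runs use `analysis_config()` + `run_pipeline()` +
`write_report()`, or the CLI:

```sh
Rscript -e 'cofluct::cofluct_cli()' simulate --out sim
Rscript -e 'cofluct::cofluct_cli()' detect --ts sim/timeseries.tsv --out det --seed 3
Rscript -e 'cofluct::cofluct_cli()' run --config cfg.json --seed 1
```

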