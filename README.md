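# meadev

Developmental analysis of spontaneous network activity recorded from
cultured neuronal networks on microelectrode arrays (MEAs).

Dissociated cortical neurons plated on 60-electrode arrays develop, over the
first three weeks in vitro, from sparse uncorrelated firing into synchronized
network bursting. `meadev` implements a complete pipeline for characterizing
that development from multi-channel spike-time tables and for predicting
where a young culture will end up:

1. **Feature extraction** — 18 electrophysiological features per recording in
   four groups:
   * *spikes*: number of active channels, mean firing rate (MFR),
     network spikes/s, inter-spike interval (ISI);
   * *bursts* (max-interval detector: burst opens at ISI ≤ 0.1 s, extends
     while ISI ≤ 0.2 s, merges across gaps < 0.2 s, then requires ≥ 3 spikes
     and ≥ 3 ms): bursting channels, mean bursting rate, burst duration,
     network bursts/min, inter-burst interval, % spikes in bursts, intra-burst
     ISI, burst peak frequency, Poisson burst surprise
     S = −ln P(X ≥ n), X ~ Poisson(r·T);
   * *synchrony*: the spike time tiling coefficient
     STTC = ½ [(P_A − T_B)/(1 − P_A·T_B) + (P_B − T_A)/(1 − P_B·T_A)]
     with a ± 100 ms tiling window, its matrix mean, and the number of
     highly synchronized electrode clusters from DBSCAN on the distance
     1 − STTC (eps = 0.2, i.e. STTC > 0.8);
   * *connectivity*: a binary graph from significant (P < 0.05) Pearson
     spike-count correlations with |r| ≥ 0.35 over 100 ms bins, summarized by
     mean node degree, clustering coefficient and global efficiency.
2. **Quality control** — the study's acceptance rules (active channel =
   > 3 spikes/min; ≥ 10 active channels; one recording at DIV 6–8 plus one in
   DIV 9–18; no > 50% drop of network spike activity in the second week).
3. **Trajectory clustering** — per-dish interval means (DIV 6–8, 9–12,
   13–18) of two representative features (bursting channels, STTC) feed a
   5 × 5 hexagonal self-organizing map; k-means on the occupied codebook
   vectors with Davies–Bouldin model selection labels each dish's
   developmental pattern.
4. **Prediction** — MARS, RBF-SVM (γ = 0.125, C = 6) and random forest
   (100 trees, 8 candidate splits) regress third-week (DIV 13–18) feature
   levels on the 18 first-week (DIV 6–8) features, evaluated by test R²,
   RMSE and regression error characteristic (REC) curves; feature-group
   importance uses leave-one-in / leave-one-out strategies under
   SMOTE-augmented (k = 20, ratio 2) fourfold cross-validation repeated 10
   times.
5. **Synthetic cohorts** — a seeded generator emulates dense-culture
   development with three dish archetypes (early-synchronized,
   late-emerging synchrony, persistently sparse), so every stage of the
   pipeline can be validated against known ground truth.

## Worked example

```r
library(meadev)

# a mature, synchronized dish (archetype 1) on day in vitro 15
rec <- simulateRecording(defaultArchetypes()[[1]], div = 15, seed = 7)
rec
#> MEARecording: dish sim, DIV 15, 300 s, 60 channels, 48435 spikes

round(extractFeatures(rec), 3)
#>        ch_spikes              mfr   network_spikes              isi
#>           52.000            3.105            0.660            0.322
#>        ch_bursts              mbr   burst_duration   network_bursts
#>           52.000           13.662            0.196           13.400
#>              ibi burst_pct_spikes        burst_isi   burst_peakfreq
#>            4.187           62.849            0.031          371.301
#>   burst_surprise             sttc      sttc_dbscan      node_degree
#>           17.521            0.380            2.000            51.000
#> clustering_coeff       efficiency
#>            1.000            1.000
```

52 of 60 electrodes are active (> 3 spikes/min), firing 3.1 Hz on average;
the network produces 13.4 network bursts/min with 63% of spikes inside
bursts. Mean pairwise STTC is 0.38 and DBSCAN finds 2 highly synchronized
electrode clusters (the dish was simulated with 2 tightly coupled electrode
groups at this age, so the programmed truth is recovered). The connectivity
graph is almost complete (mean degree 51, efficiency 1), as expected for a
strongly synchronized culture.

A full cohort analysis chains the stages:

```r
cohort   <- simulateCohort(cohortConfig(nDishes = 60, seed = 1))
kept     <- cohortQc(recordings(cohort))$kept
features <- featureTable(kept)
traj     <- aggregateTrajectories(features)
som      <- fitSom(trajectoryInputs(traj), seed = 1)
clusters <- clusterSom(som, seed = 1)           # selects k = 3
dataset  <- assembleDataset(traj, target = "sttc")
report   <- evaluateModels(dataset, seed = 1)   # MARS / SVM / RF test R^2
```

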