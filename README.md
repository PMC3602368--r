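# reservenet

Graph-based connectivity assessment of protected-area networks under
species range contraction.

## What it is for

Conservation planners and spatial ecologists often need to know whether a
*system* of protected sites still works as a network for a dispersal-limited
species — now, and under a future climate/land-use scenario in which some
sites lose habitat suitability. `reservenet` answers that with graph
theory: each protected site is a node at its centroid, and two sites are
connected when the distance between them is at most the species' median
dispersal distance *D* (an edge iff `d_ij ≤ D`). A future scenario removes
the sites predicted to become unsuitable (range contraction only), and the
package quantifies what the removal does to the network.

Three layers of analysis:

* **Topology** — components and their orders, isolated sites, articulation
  (cut) nodes, degree, shortest-path betweenness, clustering coefficient,
  and a Poisson goodness-of-fit test of the degree distribution
  (random-network signature vs a power-law tail).
* **Habitat-weighted indices** — a negative-exponential dispersal kernel
  `p(d) = exp(−ln 2 · d / D½)` (probability ½ at the median dispersal
  distance) feeds maximum-product path probabilities
  `p*_ij = max over paths of ∏ p(step)`, computed exactly via Dijkstra on
  `−log p`. From these: the probability-of-connectivity numerator
  `PCnum = Σᵢ Σⱼ aᵢ aⱼ p*ᵢⱼ` (areas `a` in ha), the **Equivalent Connected
  Area** `ECA = √PCnum` — the size of a single patch with the same
  connectivity — and the **Generalized Betweenness Centrality**
  `GBC(k) = Σ aᵢ aⱼ p*ᵢⱼ` over pairs routed through `k`.
* **Scenario statistics** — percent of nodes lost, components lost and
  split, `dA` vs `dECA` (percent change in area vs in ECA; `dECA > dA`
  means the lost sites mattered less than average for connectivity), and a
  statistical battery comparing lost vs retained nodes: subset-resampling
  permutation tests (degree, betweenness, GBC), Mann–Whitney U
  (clustering, component orders) and Spearman rank correlation (losses vs
  component order).

A synthetic generator (`simulate_sites()`) produces clustered,
multi-component reserve networks with log-normal site areas and a
degree-biased loss process, so the whole pipeline is reproducible and
testable without proprietary site data.

## Worked example

```r
library(reservenet)

sites <- simulate_sites(seed = 42)          # 200 sites in 5 clusters
cmp   <- compare_scenarios(sites, dispersal_km = 90)
cmp
#> Scenario comparison: 200 -> 171 nodes (29 lost, 14.50%); components 5 -> 5 (0 lost, 0 split)
#>   dA = -15.35%, dECA = -12.19%, weaker impact on connectivity: TRUE

scenario_tests(cmp, n_perm = 999, seed = 43)
#> # A tibble: 5 × 6
#>   metric          method        estimate    p_value n_perm  seed
#>   <chr>           <chr>            <dbl>      <dbl>  <dbl> <dbl>
#> 1 degree          permutation  -1.08e+ 1 0.001         999    44
#> 2 betweenness     permutation  -6.57e- 5 0.001         999    45
#> 3 gbc             permutation  -4.90e+10 0.001         999    46
#> 4 clustering      mann_whitney  1.19e+ 3 0.00000738     NA    NA
#> 5 component_order mann_whitney  2   e+ 0 1              NA    NA
```

Reading the output: the scenario removes 29 of 200 sites (14.5%). Habitat
area drops by 15.35% but ECA only by 12.19% — the connectivity impact is
weaker than the area loss, because the sites being lost are the poorly
connected ones. The permutation tests confirm it: lost sites average 10.8
fewer neighbours than retained ones (`p = 0.001`, the smallest value 999
permutations can produce), and their betweenness and GBC are likewise
significantly lower.

`tidy(cmp)` returns the per-node table (degree, betweenness, clustering,
GBC, lost flag), `glance(cmp)` the one-row network summary, and
`ggplot2::autoplot(cmp)` a map of the network with lost sites highlighted.
`run_pipeline()` wraps the whole thing and writes CSV/JSON reports;
`inst/cli/reservenet.R` exposes `simulate` and `run` subcommands for shell
use. Published network-level summaries for four European raptors
(median dispersal 145/90/54/44 km) ship as `raptor_reference()` for
arithmetic cross-checks.

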