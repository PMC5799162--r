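# anatnet

Anatomical network analysis (AnNA) of head and neck musculoskeletal systems
in R.

AnNA models an anatomical system as an undirected, unweighted graph: nodes
are anatomical units (bones, cartilages, muscles) and links are physical
contacts — articulations and sutures between skeletal elements, and muscle
attachments onto them. Connectivity alone then yields quantitative,
size-free measures of morphological **integration**, **modularity**,
**complexity** and **anisomerism**, for questions such as: are left and
right facial modules plesiomorphic for primates? does adding muscles make a
musculoskeletal network denser or sparser? which structures travel together
through evolution as network modules?

The package is written for comparative anatomists and evolutionary
biologists working with binary connectivity matrices over named units, and
covers the full workflow: matrix/metadata I/O and validation, the
six-parameter network summary, deterministic module detection,
anatomical classification of modules (facial asymmetry, vocal-fold and
laryngeal modules, facial-muscle inclusion), cross-taxon tables, and a
seeded synthetic generator of musculoskeletal-like networks with planted
modules.

## The statistics at the core

For a network with N nodes and K links:

* density **D = 2K / (N(N−1))** — fraction of realized connections, a
  proxy for structural complexity;
* mean clustering coefficient **C** — average over nodes of the fraction
  of neighbour pairs that are themselves connected;
* characteristic path length **L** — mean shortest-path distance over node
  pairs, one length unit per link;
* degree heterogeneity **H = σ(k)/μ(k)** — coefficient of variation of the
  degree sequence, a proxy for anisomerism.

Modules are found by maximizing Newman–Girvan modularity
**Q = Σₘ (eₘₘ − aₘ²)** with a deterministic greedy agglomeration
(lexicographic tie-breaks, exact optimizer available for small graphs).

## Worked example

Generate a musculoskeletal-like network with mirrored left/right anatomy and
planted modules, then run the full analysis:

```r
library(anatnet)

gen <- generate_network(synthetic_spec(seed = 42))
net <- gen$network
net
#> anatomical_network 'synthetic_seed42': 166 nodes, 410 links
#>   tissues: bone=33, cartilage=4, muscle=129

parameter_set(net)
#> network parameters for 'synthetic_seed42'
#>   N = 166, K = 410, D = 0.030, C = 0.14, L = 3.18, H = 0.97

part <- detect_modules_greedy(net)
part
#> partition (greedy_cnm): 166 nodes in 7 module(s), Q = 0.5880

profs <- profile_modules(net, part)
facial_inclusion(part, gen$metadata, profs, taxon_id = net$taxon_id)
#> facial inclusion for 'synthetic_seed42': 44 of 48 facial muscles (92%)

asymmetry_report(profs, net$taxon_id)[, 1:4]
#>           taxon_id has_main_facial has_left_right_facial facial_modules_asymmetric
#> 1 synthetic_seed42           FALSE                  TRUE                     FALSE
```

Reading the output: the generated network sits in the published
musculoskeletal range (N ≈ 141–175) with density 0.030, inside the
published band 0.029–0.035 — the low densities characteristic of
muscle–bone networks. Detection finds 7 modules at Q = 0.59, among them a
pure left and a pure right facial module each holding 22 of the 24
facial-expression muscles of its side (92% facial inclusion overall), plus
a combined laryngeal/vocal-fold module and a suprahyoid–tongue module. With
the generator's default `asymmetry_rate = 0` the facial modules are
side-pure, so `facial_modules_asymmetric` is `FALSE` — the plesiomorphic
pattern; raising `asymmetry_rate` produces the anthropoid-like side-mixing
instead.

Real data enter through `read_adjacency("taxon.csv", metadata = read_metadata("taxon_meta.csv"))`,
and `run_pipeline()` orchestrates metrics → modules → classification →
comparison for a set of matrices, writing a reproducible result bundle
(parameters JSON, partition CSVs, profiles JSON, comparison table, fixture
report, echoed config, hash log).

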