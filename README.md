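# cnmscan

Discovery of **conserved non-coding microsatellite (CNMS) markers** from
the 1000-bp regions upstream of gene start codons (ATG), for plant
geneticists building functional marker panels.

A CNMS is a simple sequence repeat (SSR) in a gene's 5' upstream
regulatory region that (1) passes SSR mining thresholds, (2) intersects
a match of a known regulatory-element / transcription-factor
binding-site signal consensus, and (3) lies wholly inside a non-coding
segment conserved in the upstream region of an orthologous or
paralogous gene of at least one comparator species.  Because the repeat
sits in a functional element, its length polymorphism is both easy to
assay (flanking-primer amplicon size) and biologically interpretable.

The package provides, as separately tested components:

* `findSSRs()` — maximal perfect tandem repeats, primitive units of
  1–6 nt, class I (≥ 20 bp) / class II (12–19 bp) classification;
* `scanElements()` — exact-degenerate IUPAC consensus scanning of both
  strands (library as TSV; `(GA)8`-style repeat notation supported);
* `detectCNS()` — ungapped seed-and-extend conserved-block detection
  (seed 8-mers, running identity ≥ 0.70, blocks ≥ 20 bp);
* `callCNMS()` — the three-way intersection with full-containment
  conservation support, plus `binPositions()` and `markerDensity()`;
* `designPrimers()` — deterministic flanking primer pairs: product
  100–300 bp, primer 18–24 nt, GC 0.40–0.60, Tm 50–62 °C
  (Tm = 64.9 + 41·(n_GC − 16.4)/L for L ≥ 14, Wallace rule below),
  unique in template, never overlapping the repeat — so a k-unit repeat
  expansion grows the product by exactly k·unit_size bp;
* `pic()` and friends — Botstein's
  PIC = 1 − Σpᵢ² − Σᵢ<ⱼ 2pᵢ²pⱼ², survey percentages, linkage-map
  spacing (length/n convention), haplotype constitution;
* `simulateUpstreamSet()` — a seeded multi-species generator with
  planted composites, per-clause decoys, and a verifiable truth table.

A thin CLI over the same functions lives in `exec/cnmscan`
(subcommands `simulate`, `ssr`, `scan`, `cns`, `discover`, `primers`,
`stats`).

## Worked example

```r
library(cnmscan)
sim <- simulateUpstreamSet(simConfig(seed = 42))   # 5 true + 5 decoy genes
res <- runDiscover(sim$target, sim$comparators, sim$orthology, sim$elements)
res
#> CNMSResult
#>   genes: 10 | SSR loci: 9 | element hits: 77 | CNS blocks: 116
#>   CNMS markers: 6 (class I 4, class II 2) | primer pairs: 6

cnmsMarkers(res)[, c("marker_id","gene_id","unit","repeat_count",
                     "ssr_class","element","n_supporting")]
#>   marker_id gene_id   unit repeat_count ssr_class         element n_supporting
#> 1  CNMS0001    g001     GA           12         I     CTRMCAMV35S            3
#> 2  CNMS0002    g001     GA           12         I     GAGA8HVBKN3            3
#> 3  CNMS0003    g002     CT            8        II     CTRMCAMV35S            3
#> 4  CNMS0004    g003    CAA            7         I         RAV1AAT            3
#> 5  CNMS0005    g004  ATGGT            3        II S1FBOXSORPS1L21            3
#> 6  CNMS0006    g005 ACACAA            4         I       CANBNNAPA            3
```

The five genes carrying a planted composite are recovered — `g001`'s
(GA)₁₂ tract legitimately matches two elements, the (GA)₈ signal on the
plus strand and the TCTCTCTCT signal on the minus strand — and none of
the five decoys (SSR without element, element without SSR, composite
without conservation) is emitted.  Each marker records its supporting
comparator species, ATG-relative coordinates, and (unless disabled) a
primer pair whose amplicon spans the repeat:

```r
cnmsPrimers(res)[1, c("fwd_seq","rev_seq","product_size")]
#>                 fwd_seq               rev_seq product_size
#> 1 GTAAGCCTACAAGTATCTACC GGTGGAACAGATACGATCATT          200
```

Survey statistics work from plain tables:

```r
surveyPercent(256, 631)          # 40.6  (% polymorphic of amplified)
pic(c(0.5, 0.5))                 # 0.375
map <- read.delim(system.file("extdata", "chickpea_map_summary.tsv",
                              package = "cnmscan"))
summarizeMap(map)[9, ]
#>   linkage_group n_markers map_length_cM avg_spacing_cM
#> 9         Total       238         766.9           3.22
```

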