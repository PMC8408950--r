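# snmultiplet

Read-count-based multiplet detection for single-nucleus ATAC-seq
(snATAC-seq), with cell-type-of-origin annotation of the detected
multiplets and a synthetic benchmarking harness.

## The problem and the idea

In droplet-based snATAC-seq a fraction of droplets captures two or more
nuclei under one barcode. These multiplets merge the chromatin accessibility
profiles of their constituents and distort clustering and downstream
biology. Simulation-based detectors find *heterotypic* multiplets (different
cell types) by their chimeric profiles but are nearly blind to *homotypic*
ones (same cell type).

`snmultiplet` exploits a count argument instead. A diploid nucleus carries
two copies of each autosomal locus, so after PCR-duplicate removal at most
**two** distinct fragments from one nucleus can overlap any genomic
position. For nucleus *b*, every maximal interval covered by more than two
of its fragments is an *overlap site* — evidence of either a repetitive
artifact or an extra genome sharing the barcode. With `k_b` the number of
merged regions in which nucleus *b* has such a site, and
`lambda = mean_b(k_b)`, multiplets are flagged by the Poisson upper tail

```
p_b = P(X >= k_b),  X ~ Poisson(lambda)
```

with Benjamini–Hochberg control across all nuclei (`q_b < 0.01` by
default). Because the signal is per-copy rather than per-profile, homotypic
and heterotypic multiplets are detected with similar power. Repetitive loci
that survive the exclusion lists are removed first by the symmetric test on
region *row* sums across nuclei.

Detected multiplets are annotated by cell type of origin: marker peaks per
cell type (one-vs-rest logistic regression), counts aggregated over each
cell's 15 nearest neighbours in a 50-component SVD embedding, per-peak ecdf
association scores, and a 1-D Gaussian mixture on distances to singlet
profiles separating heterotypic (top-2 origin types) from homotypic
(top-1) multiplets.

## Worked example

Generate a synthetic sample with known truth, inject artificial heterotypic
multiplets by the 5%-selection protocol (pairs of nuclei remapped to one
barcode, i.e. 2.5% artificial multiplets), then detect:

```r
library(snmultiplet)

spec <- synthetic_spec(n_nuclei = 500L, seed = 7L)
sim  <- make_synthetic_sample(spec, dir = "demo")
inj  <- inject_artificial_multiplets(sim$barcodes, sim$labels,
                                     select_fraction = 0.05,
                                     mode = "heterotypic", seed = 8L)
remapped <- apply_injection(sim$fragments, sim$barcodes, inj)
# ... write remapped$fragments / remapped$barcodes to demo/, then:
res <- run_multiplet_detection(fragments = "demo/fragments_inj.tsv",
                               barcodes  = "demo/singlecell_inj.csv")
#> fragments passing filters: 452537 (488 cell barcodes)
#> overlap sites (depth > 2): 3185
#> merged regions: 599; inferred repetitive: 5
#> multiplets at FDR 0.01: 12 / 488 nuclei

head(res$calls[order(q)], 3)
#>    barcode valid_pairs     k   lambda             p             q is_multiplet
#> 1: BC00003        2270    85 1.362705 2.451728e-118 1.196443e-115         TRUE
#> 2: BC00354        1938    59 1.362705  1.606358e-73  3.919513e-71         TRUE
#> 3: BC00401        1919    57 1.362705  2.962554e-70  4.819089e-68         TRUE

evaluate_calls(inj$truth, res$calls)
#> recall 1.00, precision lower bound 1.00
```

Reading: `k` is the nucleus's count of merged regions with a >2-fragment
pile-up, `lambda` the sample-wide Poisson expectation; injected multiplets
carry ~40–60x the expected count and are unambiguous at this sequencing
depth. All 5 planted repeat hotspots were inferred from row sums and
removed before the column test. `evaluate_calls` scores recall against the
injected truth and a worst-case precision bound (every unmatched call
counted as false).

Real data enter the same way through a coordinate-sorted, `CB`-tagged BAM
(`bam =`) or a 10x fragments file, a `singlecell.csv` barcode table, and
optional exclusion BEDs (simple repeats, segmental duplications,
RepeatMasker, blacklists) via `exclude =`.

## Command line

An installed copy exposes the same pipeline as subcommands:

```sh
snmultiplet detect   --fragments f.tsv --barcodes singlecell.csv \
                     --exclude repeats.bed --fdr 0.01 --out out/
snmultiplet simulate --seed 1 --nuclei 1000 --out sim/
snmultiplet inject   --fragments sim/fragments.tsv --barcodes sim/singlecell.csv \
                     --clusters sim/clusters.tsv --mode heterotypic --seed 2 --out inj/
snmultiplet evaluate --truth inj/truth.tsv --calls out/multiplet_barcodes.txt
snmultiplet annotate --counts m.mtx --peaks peaks.bed --barcodes bc.tsv \
                     --clusters clusters.tsv --multiplets out/multiplet_barcodes.txt --out ann/
```

Every run writes a resolved-config snapshot and a machine-readable
`summary.json` next to its outputs.

## Documentation

The methods vignette (`vignettes/methods.Rmd`) describes the counting
model, the two Poisson tests, the synthetic-data generator and its
deliberate simplifications, the annotation pipeline, and every numerical
design choice with its rationale.
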