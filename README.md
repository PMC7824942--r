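# tcrsimnet

Tools for finding disease-associated T cell receptors (TCRs) in
single-cell TCR sequencing data, built for the kind of small, precious
repertoires that come out of cerebrospinal fluid (CSF) — but applicable to
any 10x Cell Ranger VDJ or AIRR Rearrangement dataset.

T cells recognising the same antigen often carry similar CDR3 loops. The
package operationalises this with three connected analyses over clonally
expanded T cells:

1. **Levenshtein similarity (L-sim).** For CDR3 amino-acid strings *a*, *b*:

   ```
   L-sim(a, b) = 1 − d(a, b) / max(|a|, |b|)
   ```

   where *d* is the unit-cost edit distance. L-sim is 1 for identical
   sequences and lives in [0, 1]. Scores are computed for every pair of
   clonal clonotypes (paired αβ chains concatenated by default; per-chain
   mean and β-only modes available), and clusters of candidate
   shared-specificity TCRs are the connected components of the graph with
   edges at `L-sim > τ` (default τ = 0.8).

2. **Sharing networks.** A two-level graph — one hub node per sample, one
   leaf per clonal TCR, leaf–leaf edges above τ — plus a symmetric
   diagnosis-group matrix counting similar-TCR pairs between unique
   samples.

3. **CDR3β motifs.** Sliding-window enumeration of every contiguous
   substring (default length ≥ 3) of each clonal CDR3β after trimming the
   two germline-conserved residues from each end; motif frequency counts
   distinct clonotypes. Motifs can be looked up in a McPAS-TCR-format
   specificity database by substring containment.

Upstream of all three sit the standard repertoire filters: cells must have
a complete, unambiguous receptor (exactly one productive α and one
productive β; β-only mode relaxes α), and clonotypes — cells with
identical CDR3 amino-acid sequences within a sample — must be clonally
expanded (size ≥ 2).

A synthetic cohort generator with planted clones, planted similarity
clusters and planted motifs provides ground truth for validating the whole
chain.

## Worked example

```r
library(tcrsimnet)

lsim("CASSLGQAYEQYF", "CASSLGQAYEQFF")
#> [1] 0.9230769        # one substitution over 13 residues

# synthetic 8-sample cohort with 3 planted clusters and 1 planted motif
cfg <- sim_config(groups = c(HC = 2, AD = 2, MCI = 2, PD = 2),
                  cells_per_sample = 150, seed = 42)
sim <- generate_repertoire(cfg)
res <- run_pipeline(sim$contigs, sim$metadata, out_dir = "out",
                    motif_length = 9,
                    db = system.file("extdata", "mcpas_synthetic.csv",
                                     package = "tcrsimnet"))
#> stage convert: 2507 contigs from 8 sample(s)
#> stage assemble: 1200 cells
#> filter_unambiguous(paired): 1200 cells in, 1147 retained, 53 removed as ambiguous/incomplete
#> stage clonotypes: 515 clonotypes from 1147 cells
#> filter_clonal(min_size=2): 515 clonotypes in, 298 clonal retained
#> stage similarity: 44253 pairs, mean L-sim 0.215
#> stage clusters: 3 cluster(s) at tau=0.8
#> stage network: 31 similarity edge(s)
#> stage motifs: 10671 distinct motif(s)

attr(res$clusters, "summary")
#>   cluster_id n_members  min_lsim  max_lsim
#> 1         C1         6 0.9230769 0.9230769
#> 2         C2         5 0.9230769 0.9230769
#> 3         C3         4 0.9230769 0.9230769

res$group_counts      # similar-TCR pairs between unique samples, by group
#>     AD HC MCI PD
#> AD   7  0  18  0
#> HC   0  0   0  0
#> MCI 18  0   3  0
#> PD   0  0   0  0

head(res$motif_report[, c("motif", "length", "frequency", "groups")], 3)
#>       motif length frequency groups
#> 1 GTNQVWEAF      9         5 AD;MCI
#> 2 TNQVWEAFR      9         2     AD
#> 3 AATWRFSRC      9         1     HC

score_recovery(sim, res$clonal, res$clusters, res$motifs)
#> planted clusters:
#>   cluster n_planted n_recovered recall contamination
#>  cluster1         4           4      1             0
#>  cluster2         5           5      1             0
#>  cluster3         6           6      1             0
#> planted motifs:
#>      motif designed_frequency observed_frequency rank
#>  GTNQVWEAF                  5                  5    1
```

The three planted clusters are recovered exactly (every within-cluster
pair scores 12/13 ≈ 0.923 > 0.8; background pairs are kept below 0.7 by
construction), the group-sharing matrix concentrates in AD/MCI where the
clusters were planted, and the planted length-9 motif ranks first at its
designed clonotype frequency of 5.

Real data enter the same way via `read_cellranger_contigs()` /
`read_airr()` (or path vectors passed straight to `run_pipeline()`), and
`search_motif()` tabulates database hits by pathology and T cell type.

## Command line

```sh
tcrsimnet=$(Rscript -e 'cat(system.file("cli/tcrsimnet", package="tcrsimnet"))')
Rscript $tcrsimnet simulate --seed 17 --cells 150 --out-dir data/
Rscript $tcrsimnet run --in AD01=data/AD01_contig_annotations.csv,HC01=data/HC01_contig_annotations.csv \
    --format 10x --meta data/metadata.csv --tau 0.8 --motif-length 9 --out-dir out/
```

Subcommands: `convert`, `clonotypes`, `similarity`, `network`, `motifs`,
`simulate`, `run`. Every `run` output directory contains a `manifest.json`
recording parameters, input digests and the seed.

## Notes

- `inst/extdata/mcpas_synthetic.csv` is a small **synthetic** stand-in
  with the McPAS-TCR column layout, for tests and examples only; point
  `read_specificity_db()` at a real McPAS-TCR download for actual lookups.
- See `vignettes/tcr-similarity.Rmd` for the model, parameter choices,
  what the synthetic generator does and does not emulate, and known
  limitations.
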