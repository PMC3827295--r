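# campseq — competitive internal-standard amplicon sequencing quantification

Targeted RNA-sequencing panels face two linked problems: multiplex PCR
enrichment distorts between-target proportions from library to library, and
targets expressed over a 10^6–10^7-fold range force massive over-sequencing of
abundant transcripts just to count the rare ones. Competitive internal
standards solve both at once. Each native target (NT) is amplified together
with a known number of copies of a synthetic internal standard (IS) — a
template identical at the priming sites but carrying six diagnostic base
substitutions inside a 60-nt central window. Because each NT competes equally
with its own IS, their ratio is preserved all the way through PCR plateau and
sequencing, so absolute input copies per library preparation are

```
NC_i = (NT_i / IS_i) · SC_i
```

where `NT_i` and `IS_i` are binned read counts at IS dilution point `i` and
`SC_i` the known IS copies loaded. Deliberately driving every amplicon to a
common plateau concentration ("normalization") compresses the read dynamic
range roughly a thousand-fold without touching within-gene NT:IS ratios —
which is what cuts the sequencing read budget by orders of magnitude.

`campseq` is an R implementation of this whole desk workflow, for panel
designers and analysts working with competitive amplicon libraries:

* **Panel model** — validated assay panels (NT/IS amplicon pairs, diagnostic
  positions derived from the sequence difference, dual 4-nt barcode tables),
  FASTA reference export, comma-delimited count and IS-mix tables.
* **Read processing** — tolerant FASTQ parsing, the strict >150-nt length
  filter, splitting each read into forward tag / central region / reverse tag.
* **Binning** — exact dual-barcode demultiplexing (discordant index pairs are
  discarded) and minimal-Hamming NT/IS allele calling over the 60-nt window,
  with every unassigned read reason-coded.
* **Quantification** — per-replicate `NC_i`, median-based pipetting-offset
  correction, QC filtering (≥15 reads for both NT and IS; log10 dispersion
  < 1.00), four summarizers, and a QC-parameter grid search.
* **Evaluation** — titration linearity fits (slope ≈ −1), Poisson CV law,
  mixture cross-validation (C = 0.75A + 0.25B), fold-change ROC with the
  standard ratio bins, Bland–Altman agreement, cross-platform bias
  correction, read budgets, and the exact-Poisson 15-read power benchmark.
* **Simulation** — a first-class synthetic study generator (plateau
  normalization, IS dilution ladders, ERCC-style subgroup designs, Poisson
  read sampling, FASTQ emission with ground-truth manifests) so the full
  pipeline is testable end to end without external data.

## Worked example

Simulate a 10-gene study (2 samples × 3 IS dilutions), emit and re-bin the
FASTQ library, quantify, and fit titrations:

```r
library(campseq)
res <- run_pipeline(tempfile("demo"), seed = 7, n_genes = 10,
                    reads_per_library = 20000)
#> simulate: 10 genes x 6 libraries, 20000 reads each
#> bin: 120000/120000 reads assigned (0 ambiguous, 0 no_gene, 0 conflicts)
#> quantify: 20 of 20 (sample, gene) cells valid
#> evaluate: mean titration slope -1.001 over 6 fits

print(res$quant)
#> Competitive amplicon quantification: 2 samples, 10 genes
#>   valid (sample, gene) cells: 20 of 20  [ok: 20]
#>   QC: min counts 15, max log10 CV 1.00, summarizer median

head(res$quant$summary[res$quant$summary$status == "ok", ], 4)
#>   sample gene_id  nc_median n_valid   cv_log10 status
#> 1      A GENE001 84261.7153       3 0.01297548     ok
#> 3      A GENE002   180.3539       2 0.01703424     ok
#> 5      A GENE003 36829.2683       3 0.03053284     ok
#> 7      A GENE004  1027.2443       3 0.07508458     ok
```

`nc_median` is the estimated absolute copies per library preparation (the
simulated truth for GENE001 in sample A was 82,272 copies; the mean absolute
log10 error across all 20 cells in this run is 0.056). `cv_log10` is the
dispersion of log10 NC_i across the surviving dilution replicates, and
every read of the error-free library was assigned — the titration slope of
−1.001 confirms the competitive ratio is preserved across the IS ladder.

The statistical benchmarks behind the method's headline claims:

```r
detection_power(15, fold = 2)
#> Exact Poisson test, null mean 15 reads, alternative 30 (alpha 0.05):
#>   reject when X <= 7 or X >= 24
#>   type I error: 0.0375   type II error: 0.1146 (power 0.8854)

read_budget(c(1e6, 1), min_reads = 15, fractions = c(0.5, 0.5))
#> Read budget (2 targets, >= 15 reads each):
#>   traditional: 15,000,015 reads
#>   competitive: 30 reads (500000-fold reduction)
```

Fifteen reads per target suffice to detect a 2-fold change (type I error
0.037 < 0.05, type II error 0.115 < 0.20), and two targets spanning a
million-fold range need 15,000,015 traditional reads but only 15 per target
once amplicons are plateau-normalized.

A thin command-line wrapper over the same functions is installed at
`system.file("cli", "campseq.R", package = "campseq")` with subcommands
`simulate`, `bin`, `quantify` and `evaluate titration|budget|power`.

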