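# pdzome

Post-processing toolkit for yeast two-hybrid (Y2H) screens of PDZ-domain
baits against prey libraries, from raw sequencing traces to a
domain-centered interactome.

## The problem

PDZ domains are ~90-residue interaction modules that classically bind the
extreme C-terminus of their partners. Genome-wide Y2H screens of a PDZ
domain collection produce, per positive colony, a single-pass sequencing
read of the prey insert downstream of the activation-domain (AD) vector.
Turning those reads into an interactome requires a chain of decisions:

1. **Trace QC** — discard reads whose PHRED quality profile is too poor
   (sliding 10-base window, mean ≥ 20; keep a read when at least 15% of
   its length lies in passing windows).
2. **Colony filtering** — require at least 2 of 3 Y2H reporters and a
   single PCR band per colony.
3. **Identity and reading frame** — locate the AD junction by local
   alignment, identify the insert at the nucleotide level against the
   coding sequences, translate it in the fusion frame, and search the
   peptide against the proteome. A prey is *In Frame* only when both
   searches agree on the same gene; frame-shifted and chimeric clones
   fail the agreement check and are discarded.
4. **Aggregation** — collapse in-frame reads to (bait domain, prey)
   interactions with clone counts, drop pairs that fail retesting, and
   record each prey's minimal interacting region (MIR), the smallest
   fragment recovered across all of its clones.
5. **Classification** — assign each prey a C-terminal consensus class
   from its last three residues: class 1 `[ST]X[Φ]`, class 2 `[Φ]X[Φ]`,
   class 3 `[DE]X[Φ]` (Φ = Y/F/W/C/M/V/I/L/A), or none. Splice forms are
   handled conservatively: when a protein's C-terminus is not
   experimentally confirmed, a consensus in *any* form of the gene counts.
6. **Network statistics** — bipartite degree distributions, interactions
   per productive domain, catalog coverage, cross-library overlap
   (relative to the smaller screen), pooled counts, and
   consensus-class proportion tables (redundant = per interaction,
   nonredundant = per distinct prey, against the proteome background).

Because real screen data are large and external, the package ships a
**synthetic data generator** that emulates both library designs with a
planted ground truth: a non-normalized cDNA-fragment library (log-normal
abundance, consensus-biased prey sampling, native C-termini) and a
normalized ORFeome library (uniform sampling, stop codon replaced by the
fixed Gateway B2 read-through tail `…EGPIL`, which can never form a
consensus terminus). Noise processes — frame shifts, low-quality traces,
chimeric clones, decoy colonies, reporter/band failures — are all
parameterized and default to plausible bench rates.

## Worked example

```r
library(pdzome)

## consensus classes from the last three residues
classify_cterm(c("MKETSV", "MKGVAV", "MKKEAV", "IAAELR"))
#> [1] "1"    "2"    "3"    "none"

## trace QC: 100-nt read, 20 bases at Q30 then 80 at Q2
window_pass_fraction(c(rep(30, 20), rep(2, 80)))
#> [1] 0.23      # kept: 0.23 >= 0.15

## a small end-to-end screen on synthetic data
prot    <- generate_proteome(n_proteins = 60, seed = 42)
planted <- plant_bait_domains(prot, n_domain_proteins = 6,
                              total_domains = 8, seed = 42)
cat_obj <- build_domain_catalog(planted$annotations, prot)
truth   <- make_screen_truth(prot, cat_obj$catalog, library_kind = "cDNA",
                             n_edges = 10, decoy_rate = 0, seed = 42)
screen  <- generate_screen(prot, truth)
calls   <- call_preys(screen$reads, screen$colonies, prot)
inter   <- aggregate_interactions(calls, screen$retest)
head(inter)
#>   bait_domain_id prey_protein_id library n_hits retest_confirmed mir_start mir_end
#> 1        g00001a          g00009    cDNA      2             TRUE       271     390
#> 2        g00001a          g00060    cDNA      2             TRUE       245     343
#> 3         g00010         g00013a    cDNA      2             TRUE       339     436
#> 4         g00010          g00055    cDNA      1             TRUE        98     170
#> 5         g00025          g00007    cDNA      2             TRUE       366     467
#> 6         g00025          g00051    cDNA      1             TRUE       231     267

nw <- assemble_network(inter, cat_obj$catalog)
nw
#> pdz_network (cDNA): 9 edges, 5/8 productive domains, 7 preys

cons <- classify_proteome(prot)
class_proportion_table(nw, cons, proteome_class_table(prot))
#>              class1 class2 class3 total_consensus total_nonconsensus  n
#> redundant        22     22      0              44                 56  9
#> nonredundant     29     14      0              43                 57  7
#> proteome         10     11      4              25                 75 73
```

The consensus-biased cDNA sampling is visible even at this toy scale: the
screen rows are enriched for consensus-class preys over the proteome
background.

## Command line

A thin CLI wraps the same stages:

```sh
inst/exec/pdzome all --seed 1 --out pdzome_out
inst/exec/pdzome report --out pdzome_out   # re-run a single stage
```

Stages: `simulate`, `catalog`, `qc`, `call`, `classify`, `network`,
`report` (or `all`). Each stage reads/writes plain FASTA/FASTQ/TSV/
GraphML/SIF artifacts under `--out`; re-running with the same seed and
configuration reproduces them byte for byte. `--config FILE` loads JSON
overrides of `pipeline_config()`.

## Documentation

See the methods vignette (`vignettes/screen-analysis.Rmd`) for the model,
parameter choices, and design decisions, and the roxygen comments in
`R/` for per-function reference.
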