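---
title: "Analysing PDZ-domain yeast two-hybrid screens with pdzome"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Analysing PDZ-domain yeast two-hybrid screens with pdzome}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(pdzome)
```

## Scientific background

PDZ domains are ~90-residue interaction modules that typically recognise
the extreme C-terminus of their partner proteins. Three canonical binding
motifs ("consensus classes") are defined by the last three residues of
the partner, numbered −2, −1, 0 from the C-terminus:

* class 1: `[S/T] X Φ`
* class 2: `Φ X Φ`
* class 3: `[D/E] X Φ`

where Φ is a hydrophobic residue (Y, F, W, C, M, V, I, L or A) and X is
anything. The position −2 sets of the three classes are disjoint, so the
classes are mutually exclusive by construction; a terminus matching none
of them is *non-consensus*. Over all 8000 tripeptides the class sizes are
closed-form: 2·20·9 = 360 (class 1), 9·20·9 = 1620 (class 2), 360
(class 3) and 5660 non-consensus — about 29% of random termini match some
class, which is the baseline against which screen enrichment is judged.

A domain-centered yeast two-hybrid (Y2H) screen tests a catalog of PDZ
domains (baits, fused to a DNA-binding domain) against a prey library
(fused to an activation domain, AD). Positive colonies are sequenced once
through the AD fusion junction; everything downstream of the vector is
the prey insert. `pdzome` implements the full post-processing chain from
those traces to an annotated bipartite interactome, plus a synthetic
generator so that every step can be validated against a planted truth.

## Domain catalog and cloning design

`merge_domain_annotations()` unions strictly overlapping domain calls
from two annotation sources per protein (a sweep over sorted intervals;
the merged record keeps the union span and the comma-joined source
labels). `assign_domain_ids()` names a protein's only domain by the
protein id and multiple domains `<id>.1`, `<id>.2`, … ordered from the
start codon. `extend_boundaries()` pads each domain by 10 residues on
both sides (clamped to the protein) — PDZ boundaries from motif scans
are imprecise and binding can require flanking residues — and maps the
span to coding-sequence coordinates. `design_primers()` then emits
Gateway-tailed primer pairs (attB1 forward, attB2 + reverse-complemented
stop codon reverse, 21-nt gene-specific parts), and `pcr_amplicon()`
reconstructs the expected product for verification.

## Trace QC

Single-pass reads are filtered by a sliding-window PHRED rule: a window
of 10 consecutive bases *passes* when its mean score is ≥ 20, and the
read's `pass_fraction` is the fraction of its positions covered by at
least one passing window. Reads with `pass_fraction < 0.15` are
discarded. A worked example: a 100-nt read with 20 bases at Q30 followed
by 80 at Q2 has passing windows starting at positions 1–14, covering
positions 1–23, hence `pass_fraction = 0.23` — kept. The implementation
(cumulative sums) is tested against a brute-force double-loop oracle,
and raising any single base quality can never lower the fraction.

## Prey identity and reading frame

Colonies must activate at least 2 of 3 reporters and show a single PCR
band. For each surviving read:

1. The AD junction is located by Smith–Waterman alignment of the vector's
   in-frame 3' suffix against the read head (score floor: 60% of the
   suffix length), extrapolated to the end of the suffix so the insert
   starts in the fusion frame.
2. The insert is searched against all coding sequences
   (`identify_nt()`), and its fusion-frame translation (truncated at the
   first stop) against the proteome (`identify_aa()`).
3. The read is **In Frame** only when both searches return unique best
   hits on the *same gene*; gene-level comparison matters because splice
   forms share their body, so a peptide from the shared region ties
   across forms without being wrong. Everything else — nucleotide
   ambiguity, no peptide hit, or disagreement — is **Out of Frame**;
   reads without a locatable junction are **Unassigned**.

This design makes the frame call a genuine two-channel agreement test:
frame-shifted clones keep their nucleotide identity but translate to an
unrelated peptide, while chimeric clones (modelled here as a short
in-frame fragment of one protein fused to a frame-broken insert of
another) make the two channels identify *different* genes.

Searches use a seed-and-extend strategy: exact seed words (30 nt / 10 aa,
sampled every ≥ 50 positions) select candidate subjects via
`Biostrings::vcountPattern`, and only candidates are aligned
(match +1, mismatch −1, linear gap −2). On desk-scale databases a subject
sharing no seed word cannot reach the score floors (60 nt-level, 20
aa-level), so a seed miss is a "none".

In-frame reads are aggregated to (bait domain, prey, library)
interactions with clone counts (`n_hits`); pairs that fail retesting are
dropped. Each prey's **minimal interacting region** (MIR) is the smallest
clone span recovered over *all* of its interactions (global per-prey
minimum, ties broken toward the smallest start) — the shortest fragment
still able to bind, a useful localisation of the interaction surface.

## Consensus classification of preys

`classify_cterm()` reads only the last three residues.
`classify_protein()`/`classify_proteome()` add the conservative
splice-form rule: when a gene's C-terminus is not experimentally
confirmed, a consensus terminus on *any* splice form is attributed to the
gene (lowest class number on ties); a confirmed terminus is taken at face
value. Two construct helpers mirror common bench controls:
`b2_tag()` appends the fixed Gateway B2 read-through peptide
(`PAFLYKVVIIHSSMHLEGPIL`), whose terminus `…PIL` can never match a
consensus class (P at −2 is in no class set) — so ORFeome preys are
recovered through internal, not C-terminal, binding; and
`design_truncated()` removes the last three residues of a prey (ΔCter)
and flags when the truncation accidentally *creates* a new consensus
terminus, which would confound the control.

## Network statistics

`assemble_network()` validates edges against the domain catalog and the
auto-activator list. `degree_stats()` reports interactions per
productive domain (mean over domains with ≥ 1 edge; the catalog,
including auto-activators, is the coverage denominator) and the same for
preys. Display rounding is half-away-from-zero; screens of
non-normalized libraries are conventionally reported with integer means,
normalized ones at one decimal. `network_overlap()` counts shared
(domain, prey) pairs and expresses them relative to the **smaller**
screen — the tighter of the two possible denominators, since overlap
cannot exceed the smaller edge set. `pool_networks()` keeps library
provenance: the pooled interaction count is the plain sum over libraries
(the same pair found in both libraries is two observations), while
distinct preys and domains are counted over the union.
`class_proportion_table()` contrasts a *redundant* row (each interaction
once, so promiscuous preys weigh more) with a *nonredundant* row (each
distinct prey once) and the proteome background.

## The synthetic generator

Defaults are the package's study conditions; they were chosen before any
testing and are not tuned to outcomes.

* `generate_proteome()`: protein lengths are gamma-distributed
  (mean 400, floor 120 so planted domains always fit); each entry draws
  its class from `class_probs = (0.08, 0.18, 0.05, 0.69)` and a terminal
  tripeptide from the matching motif set; 10% of genes carry a second
  splice form sharing the body but redrawing the final 30 residues.
  Coding sequences come from uniform synonymous back-translation, so
  `translate(cds) == sequence` exactly.
* `plant_bait_domains()`: 80-residue domains in non-overlapping bays,
  reported by two pseudo-sources whose boundaries disagree by up to ±3
  residues (the second source only widens), exercising the merge without
  ever collapsing neighbouring domains.
* `make_screen_truth()` / `generate_screen()`: cDNA mode samples preys
  with a log-normal abundance skew times `consensus_bias = 2.2` for
  consensus-class preys (chosen so that a ~31% background yields a ~49%
  redundant consensus proportion), and emits 5'-truncated, codon-aligned
  inserts with native stop; ORFeome mode samples uniformly and appends
  the B2-tail codons in place of the stop. Reads are the AD suffix plus
  the insert, truncated at 700 nt. Noise defaults: frame shift 5%,
  low-quality trace 5%, chimera 3%, decoy colonies 10% of edges (decoys
  fail retesting), reporter/band false rates 5% each.

With all noise rates at zero the pipeline recovers the planted edge set
exactly, clone counts included; with `frame_shift_rate = 1` no read is
called In Frame. These two ends anchor the validation suite.

## End-to-end use

```{r pipeline, eval = FALSE}
cfg <- pipeline_config(simulate = list(n_proteins = 150, n_edges = 40))
run_subcommand("all", cfg, out_dir = "pdzome_out", seed = 1)
```

or, from a shell, `inst/exec/pdzome all --seed 1 --out pdzome_out`. Every
stage writes plain FASTA/FASTQ/TSV/GraphML/SIF artifacts and is
re-runnable in isolation; the same seed and configuration reproduce all
primary artifacts byte for byte. `scripts/acceptance.R` recomputes the
headline quantities into a flat JSON file.

## Limitations

The generator is a validation instrument, not a sequencing simulator: no
per-base error model beyond uniformly low-quality traces, no quality
decay along the read, single fixed read length, forward strand only, and
chimeras follow one fixed template. Statistics are descriptive —
the package deliberately stops short of interaction-confidence scoring.
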