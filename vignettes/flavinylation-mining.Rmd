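---
title: "Mining extracytosolic flavinylation systems: models, rules and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Mining extracytosolic flavinylation systems}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(flavimine)
```

## The biological model

ApbE transfers the FMN moiety of FAD onto a serine/threonine hydroxyl
inside a conserved `[S/T]GA[S/T]` motif, forming a phosphoester-linked
flavin. The canonical acceptor is the extracytosolic FMN-binding domain
(Pfam PF04205); DUF2271 (PF10029) and DUF3570 (PF12094) are additional
substrates (DUF3570 carries two motifs). Because flavinylated electron
carriers work together with membrane-embedded partners, the genes of a
system cluster on the genome, and the neighborhood of a flavinylation gene
is diagnostic of the electron-transfer machinery it serves.

`flavimine` operationalizes this as a four-step procedure over annotated
gene tables:

1. a gene is an **anchor** when its protein has a passing hit to PF02424,
   PF04205, PF12094 or PF10029;
2. the anchor's **neighborhood** is the genes within five positions on the
   same contig (gene order, not nucleotide coordinates, defines
   adjacency);
3. a neighborhood survives the **extracytosolic filter** only if an
   anchor-role gene carries a Sec/Tat signal peptide or lipoprotein
   signal;
4. surviving clusters are matched against **key-gene rules** for ten
   named systems, independently per rule.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `evalue_cutoff` | 0.001 | full-sequence E-value bound for any hit to count |
| `window` | 5 genes | neighborhood radius around an anchor |
| `frd_window` | 2 genes | co-occurrence radius for fumarate-reductase-like analysis |
| `merge_overlapping` | `TRUE` | union anchor windows sharing a gene into one locus |

The 0.001 cutoff is applied uniformly to Pfam and KOfam hits, using the
full-sequence E-value of the tabular hmmsearch output (not the per-domain
conditional E-value); per-protein KO labels take the single best passing
hit. KOfam's adaptive per-family score thresholds are *not* applied — the
cutoff-only reading keeps Pfam and KOfam symmetric; swapping in adaptive
thresholds would only require filtering the hit table before ingest.

"Best hit" needs a deterministic definition, so ties are broken by
(smaller E-value, larger bit score, lexicographically smaller accession).
This guarantees identical assignments regardless of row order.

Localization semantics: "signal peptide" means the SP (Sec/SPI) or TAT
(Tat/SPI) calls, "lipidation site" means LIPO (Sec/SPII); the three
secreted classes of a SignalP-5-style predictor partition exactly this
way. Transmembrane-helix counts are consumed as given (`PredHel=N`), and
the EET rule's "with a transmembrane helix" is read as `tm_helix_count >=
1` on the key gene itself.

## Cluster construction choices

* **Merging.** Overlapping anchor windows on one contig are merged into a
  single locus by default, because adjacent anchors of one system (an
  `apbE` next to its substrate) would otherwise be double counted.
  `merge_overlapping = FALSE` is retained for sensitivity analysis, since
  per-anchor versus per-locus counting is a genuine ambiguity in how
  cluster counts can be reported.
* **Contig edges** truncate windows silently. Draft assemblies make
  truncated windows routine, so they are first-class rather than flagged.
* **Cluster ids** are `genome|contig|leftmost-index`, stable across
  reruns.
* **Strand is ignored** by the neighborhood logic (carried through for
  reporting only), and every row of the gene table counts toward the
  window — including genes without translations, should a caller include
  them.
* The extracytosolic test applies to anchor-role genes anywhere in the
  merged cluster, not to arbitrary members: a secreted bystander gene
  must not rescue a cytosolic flavinylation locus.

## Classification choices

The rule table ships as `inst/extdata/system_rules.yaml` and is editable
without code changes. Assignment is **multi-label**: rules are evaluated
independently, and clusters carrying e.g. both a PepSY-like and an
MsrQ-like gene receive both labels (such co-occurrence is real). An empty
label set marks an uncharacterized flavinylation locus — a result, not an
error.

The NQR/RNF-like system has no single key accession; it is defined by a
protein architecture: an NqrB/RnfD-homologous membrane domain (PF03116)
that *starts in the N-terminal half* of the protein and *precedes* an
NqrF-like NAD-binding domain (PF00175). "N-terminal" has no published
numeric threshold, so the midpoint rule is this package's
operationalization; hits lacking alignment coordinates make the test
indeterminate and are conservatively reported `FALSE` with a warning.

For NapH-like clusters the classifier records which of two genomic
arrangements holds — the NapH-like gene itself fused to an FMN-binding
domain, or a separate FMN-binding gene in the locus — mirroring the two
configurations seen in real genomes.

Accessory features are annotated for every cluster regardless of which
system matched, with a `fused` flag marking carriers that are themselves
key genes of an assigned system; attaching specific accessories to
specific systems is left to reporting (`crosstab()`), because those
associations are narrative, not definitional.

## Motif and logo conventions

The motif is scanned as the strict regular expression `[ST]GA[ST]`. The
literature describes the motif as "`[S/T]GA[S/T]`-like"; the "-like"
hedge is not operationalizable as a closed pattern, so the strict form is
the default and the pattern is a function argument for anyone who wants a
looser one. Overlapping occurrences are all reported (two motifs can share
a serine). Note that *motif-site counts* and *multi-flavinylation* are two
different counters: the former counts `[ST]GA[ST]` occurrences in the
sequence, the latter counts passing PF04205 domain hits.

Logo columns report amino-acid frequencies over non-gap residues and
information content `log2(20) − H` in bits, with `0·log 0 ≡ 0`, no
small-sample correction, and gaps excluded from the entropy — the default
convention of standard logo tools. All-gap columns get zero information
and `n_effective = 0`.

## What the synthetic generator emulates — and what it does not

`generate_genomes()` produces contigs of ordered genes with planted
system templates, each constructed to satisfy exactly its own rule plus
the extracytosolic filter, along with:

* **type-(a) decoys**: anchor genes whose anchor-role genes are all
  cytosolic (must die at the filter even though a key gene sits in the
  window);
* **type-(b) decoys**: key genes with no anchor within the window (must
  never form a cluster);
* **sub-threshold decoys**: anchor-family hits with E-values drawn from
  [0.01, 1], against the planted hits' log-uniform [1e-30, 1e-4], to
  exercise the 0.001 cutoff;
* background annotations from a pool disjoint from every rule and
  accessory accession;
* motif-bearing substrate sequences and multi-flavinylated proteins with
  2–13 FMN-binding domains (13 is the observed ceiling on a single
  protein);
* orphan-ApbE cassettes of both kinds (ApbE alone; ApbE + DUF2271), so
  the two substrate-set definitions measurably diverge.

Motif substrate sequences draw flanking residues from an alphabet
excluding S, T **and G**. Excluding only S/T would still permit an
accidental motif spanning a planted site's trailing S/T and a `GA`
dinucleotide from the flank; dropping G makes the planted positions
provably the only matches, which is what lets planted-site recovery be
asserted exactly.

Planted features are separated by at least 12 filler genes, so distinct
features never share a ±5 window: one template, one cluster. Genomes are
assigned round-robin to a configurable set of synthetic phyla and genera
so taxon summaries are exercised.

The generator is deliberately idealized. It does not simulate annotation
noise beyond the decoy classes, HMM score distributions, gene-order
rearrangements inside a system, partial systems, pseudogenes, or
realistic protein composition outside the motif windows. Passing the
planted-truth checks therefore demonstrates that the *rules and plumbing*
are implemented correctly — not that the pipeline's sensitivity on real
genomes matches any published survey, which depends on the external
predictors and database versions.

## Numerical and degenerate-input conventions

* E-values are required positive; hits at exactly the cutoff pass
  (`<=`).
* `gene_index` is 0-based and must be contiguous per contig; residue
  coordinates are 1-based inclusive (HMMER convention).
* Empty inputs (header-only tables, comment-only hmmsearch files,
  sequence-free genomes) yield empty, correctly-typed results rather than
  errors.
* All randomness flows through a single seed (`withr::with_seed`), and
  pipeline outputs are pure functions of (inputs, config): reruns are
  byte-identical, which the test suite asserts via checksums.

## Problem sizes used in the checks

The shipped verification runs use cohorts of 200 synthetic genomes for
system recovery (all ten templates plus both decoy types at 20% rates),
100 random genomes (≤ 200 genes) for brute-force mining equivalence,
10,000 random sequences (length ≤ 500) for brute-force motif
equivalence, and a 100-genome orphan-enriched cohort for the
substrate-set mechanism. These sizes give every template and decoy type
double-digit representation while keeping the full suite fast enough to
run on every change.

## Known limitations

* Orphan-ApbE accounting and genome summaries are genome-granular; they
  do not attempt sub-genome (plasmid vs chromosome) attribution.
* The classifier consumes annotations; it inherits whatever biases the
  upstream hmmsearch/SignalP/TMHMM runs carry, and provides no rescue for
  missed signal peptides at contig-truncated genes.
* `crosstab()` counts co-occurrence within a unit; it is not a test of
  statistical association.
* Full complex reconstruction (e.g. complete *rnfABCDGE* operons) and
  phylogenetics are out of scope; the package emits member lists and
  iTOL annotations for external tree tools instead.
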