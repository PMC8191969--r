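---
title: "Methods: promoter-trap reporter mapping and barcode quantification"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: promoter-trap reporter mapping and barcode quantification}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(promtrap)
```

## The assay and the model

promtrap analyses pooled promoter-trap screens of the TRIP family
(thousands of reporters integrated in parallel). A promoterless reporter
(here, a luciferase CDS) tagged with a random 12-nt barcode is delivered as
T-DNA so that each transgenic line carries one insertion at a random
genomic position. Because the reporter has no promoter of its own, it is
transcribed only when it traps the transcriptional activity of an
endogenous gene (insertions in a gene, sense orientation), or when
transcription arises *de novo* at the insertion site (antisense or
intergenic insertions). Two sequencing readouts identify and quantify each
line:

1. **Junction libraries** (inverse PCR from within the reporter ORF) read
   across barcode, T-DNA border and the flanking genomic sequence at the
   RB-genome junction; they link each barcode to its insertion locus.
2. **DNA and RNA barcode-count libraries** tally the molecular abundance
   of each barcode in genomic DNA and in cDNA; their ratio measures the
   line's transcriptional output.

The per-line expression statistic is the **relative transcription level**

$$\mathrm{level} = \frac{\;n_{\mathrm{RNA}} / N_{\mathrm{RNA}}\;}
                        {\;n_{\mathrm{DNA}} / N_{\mathrm{DNA}}\;}
                   \times 10{,}000,$$

where $n$ are per-barcode read numbers and $N$ the pre-threshold library
totals. Barcodes with $n_{\mathrm{DNA}} \le 5$ are omitted (their
denominator is unreliable); $n_{\mathrm{RNA}} \le 5$ is set to zero before
normalization (background). A line is considered transcribed when its
level is positive after these thresholds. We use the pre-threshold library
totals as $N$ because the thresholds act as per-barcode filters, not as
library-level trimming; with realistic library sizes the distinction is
numerically negligible.

## Junction mapping

**Template split.** Each junction read is matched against the T-DNA anchor
(border `tcaaggcctcgacgttatcagcttacag`, then a 12-nt barcode slot, then the
start of the reporter ORF). The border is located in either read
orientation allowing up to 2 substitutions (default); the 12 nt on the
reporter side are the barcode, everything on the genomic side is the
flank. Reads with no border hit, two independent border hits, a truncated
barcode slot, or a flank shorter than 20 nt are dropped, each with its own
counter in the run log.

**Flank alignment.** Flanks are aligned to the reference with a k-mer
seed-and-verify search: substitutions only (no indels), at most 3
mismatches over the full flank, both strands. With seed size
$k \le \lfloor L/(m{+}1)\rfloor$ (defaults $k=5$, flank $L \ge 20$,
$m=3$), any alignment within the mismatch budget contains at least one
exact seed (pigeonhole), so the search is exhaustive. The single
best-distance location is reported; ties at the best distance are never
broken — such flanks are discarded as multi-mapped, because only uniquely
anchored locus-barcode pairs are acceptable. The substitution-only model
matches the short-read aligners these screens conventionally use in
`-v`-style mode.

**Junction coordinate convention.** The reported position is the 0-based
forward-strand coordinate of the genomic base immediately adjacent to the
T-DNA border (the RB junction); the insert strand is the strand on which
the reporter CDS reads 5'→3'. Since the flank is extracted with its 3' end
at the border, a match on the forward strand puts the junction at the
right end of the matched interval and a reverse-strand match at the left
end. A consequence worth noting: reverse-complementing a flank (without
telling the mapper that the border side flipped) maps to the same interval
with the strand flipped, but the junction coordinate moves to the other
interval end. `map_flank(border_end = "5prime")` handles flanks oriented
away from the border and restores the same physical junction.

## Locus calling

Reads are grouped by exact barcode (no error-correction clustering —
substitutions in a 12-mer almost always produce unseen barcodes, which
remain as singleton noise). Mapped positions within 5 bp on the same
chromosome and strand collapse into one locus (modal position kept, ties
to the smaller coordinate), absorbing sporadic off-by-a-few mapping
jitter. Each barcode is then called with three criteria:

1. a candidate locus needs **at least 2 reads**;
2. the candidate must hold **at least 60 %** of *all* reads carrying that
   barcode — unmapped and artefact reads included, so chimeric PCR
   products depress dominance and can veto a call;
3. a barcode with **two or more candidate loci** is excluded outright
   (multi-insert line or barcode collision between lines).

For criterion 3 we require the secondary locus to itself reach the
2-read candidate threshold; a lone stray read therefore cannot veto an
otherwise clean call. The stricter alternative (any second locus vetoes)
is one parameter change (`min_reads = 1`). Raising `min_dominance` can
only remove calls, never add them; this monotonicity is tested across the
whole pipeline.

## Classification

**Insertion type.** The single junction base (not an interval — the
junction is the only coordinate the assay fixes) is intersected with
annotated protein-coding gene spans, full gene feature including UTRs and
introns. Inside a gene on the insert strand → *genic sense*; inside a
gene only on the opposite strand → *genic antisense*; otherwise
*intergenic*. Overlapping a sense and an antisense gene simultaneously
counts as genic sense.

**Reporter × wild-type status.** Each quantified line is cross-classified
by reporter transcription (level > 0) against the wild-type
transcriptional status of its locus, giving types i (both transcribed),
ii (WT only), iii (reporter only — *de novo* activation), iv (neither).
WT status is taken from a table of transcribed regions with FPKM; FPKM of
overlapping isoforms is summed. The WT-overlap test is strand-agnostic by
default — the four types are defined by transcription status, not
orientation — but `wt_strand_matched = TRUE` restricts the overlap to the
insert strand for sensitivity analyses.

## Cohort statistics

- Type counts are reported as 1-decimal percentages, rounded half away
  from zero; integer counts recovered from published percentages use the
  nearest integer of share × n.
- Activation within a WT stratum is normalized as
  $100\, n_{iii}/(n_{iii}+n_{iv})$ (untranscribed stratum) and
  $100\, n_i/(n_i+n_{ii})$ (transcribed stratum).
- Percentile bins (High 100–67, Mid 66–34, Low 33–1) are computed among
  transcribed lines only, with integer-arithmetic third-splits
  ($3r \le n$, $3r \le 2n$ on max-ranks), so bins differ by at most one
  line and ties share the higher bin.
- Decade histograms use $\lfloor \log_{10}\mathrm{level} \rfloor$ clamped
  to $[1, 7]$, with an ND bin for untranscribed or omitted lines; the
  lower/higher split puts decades $\le 10^4$ in the lower fraction.
- The level-vs-WT-FPKM association over type-i lines uses Spearman rank
  correlation with average ranks; constant inputs are flagged rather than
  forced to a number.
- Expected Mendelian recovery of hemizygous T2 lines grown from $s$ seeds
  is $1 - (1/4)^s$ per line; with 386 lines and three seeds this gives
  98.4 % and an expectation of 380 recovered lines.

## The synthetic-data generator

The generator is first-class, tested code; it defines the conditions the
pipeline is validated under.

- **Genome**: random uniform-composition chromosomes (default 3 × 100 kb)
  with non-overlapping genes placed via random gaps so that genic bp ≈
  50 % of the genome, reflecting the near-equal genic/intergenic split of
  the target genome. Gene density requests that cannot fit fail loudly.
- **WT transcriptome**: 70.4 % of genes are marked transcribed with
  log-normal FPKM (median 10, log-sd 1.2 — a typical bulk RNA-seq spread);
  intergenic transcribed regions are added so genic records are 97.8 % of
  the table.
- **Cohort**: insertion sites uniform over the genome (200 bp edge margin
  so flanks never leave the sequence), strands uniform; activation
  probabilities per insertion type default to (0.66, 0.27, 0.27) for
  (genic sense, genic AS, intergenic); levels are
  $10^{\mathcal N(\mu, \sigma)}$ truncated to $[10^1, 10^7]$ with
  $\mu = 5$ for genic-sense (trap) and $\mu = 4$ for *de novo* lines,
  $\sigma = 1$. The means are the printed distribution peaks; the sd is a
  package choice spanning the printed $10^1$–$10^7$ range.
- **Junction reads**: one merged library (the restriction-enzyme
  sub-libraries used at the bench are collapsed — the junction coordinate
  the pipeline consumes is enzyme-independent); each clean read is the
  reverse complement of flank+border+barcode+ORF-start, i.e. sequencing
  outward from the reporter. Constant placeholder qualities; quality
  trimming is out of scope.
- **Count reads**: multinomial draws; DNA weights near-equal with
  log-normal copy jitter (sd 0.15), RNA weights ∝ DNA weight × true
  level.
- **Artefacts** (all default 0; the underlying artefact process of the
  real assay is unknown, so these are free injection rates, not
  estimates): per-read barcode substitutions, chimeric flanks, barcode
  collisions between lines, multi-insert lines.

What the generator does *not* emulate — base-level sequencing error,
indels, vector readthrough, tandem/truncated T-DNA structures,
pericentromeric insertion bias, fragment-length variation — bounds what
passing tests show: they validate the computational pipeline against its
own generative model, not the wet-lab error structure of a real screen.

## Numerical choices and problem sizes

Determinism: every generator takes a seed and is byte-reproducible; the
analysis itself is deterministic. Validation sizes were chosen so the
whole suite runs in minutes on one CPU while leaving sampling error well
below the tested tolerances: exhaustive rule-oracle comparison over all
support tables with ≤ 4 loci and ≤ 12 reads; 1,000 random flanks with
0–4 planted substitutions against a full-genome Hamming scan on a 100-kb
genome; end-to-end recovery with 100 lines at junction depth 10 and
count depth $10^6$ (expecting exact locus recovery and level rank
correlation ≥ 0.95); activation-probability recovery on 2,000 lines
within 3 binomial SDs; invariant sweeps over 50 seeds.

## Known limitations

- Substitution-only alignment cannot recover junctions with indels in the
  flank or border; such reads are dropped, not rescued.
- Exact barcode matching slightly undercounts true reads when sequencing
  error hits the barcode; with 12-nt barcodes and per-base error ≪ 1 %
  the bias is uniform across lines and cancels in the DNA/RNA ratio.
- The merge window (5 bp) is smaller than any plausible pair of distinct
  insertions but will fuse genuinely distinct junctions closer than 5 bp.
- With zero RNA library depth, levels are 0 rather than undefined; lines
  omitted in DNA carry `NA` and are excluded from every downstream
  statistic.
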