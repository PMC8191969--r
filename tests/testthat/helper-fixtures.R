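# shared small fixtures, built once per test run

test_genome <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- generate_genome(2L, 50000L, 24L, seed = 101)
    cache
  }
})

test_index <- local({
  cache <- NULL
  function() {
    if (is.null(cache)) cache <<- build_genome_index(test_genome(), 5L)
    cache
  }
})

genome_fetch_for_test <- function(genome, chrom, start0, end0) {
  substr(genome$chromosomes[[chrom]], start0 + 1L, end0)
}

# clean 30-line fixture cohort with libraries written as FASTQ under dir
make_fixture_run <- function(dir, n_lines = 30L, seed = 202,
                             dna_depth = 50000, rna_depth = 50000) {
  g <- test_genome()
  truth <- generate_cohort(g, cohort_config(n_lines = n_lines, seed = seed))
  wt <- simulate_wt_expression(g, seed = seed + 1L)
  write_genome(g, file.path(dir, "genome.fa"), file.path(dir, "genes.gff3"))
  write_wt_regions(wt, file.path(dir, "wt_regions.tsv"))
  simulate_junction_library(truth, g, depth_per_line = 5L, seed = seed + 2L,
                            path = file.path(dir, "junction.fastq"))
  simulate_count_libraries(truth, dna_depth = dna_depth,
                           rna_depth = rna_depth, seed = seed + 3L,
                           dna_path = file.path(dir, "dna.fastq"),
                           rna_path = file.path(dir, "rna.fastq"))
  cfg <- trip_config(
    genome_fasta = file.path(dir, "genome.fa"),
    annotation_gff3 = file.path(dir, "genes.gff3"),
    wt_regions_tsv = file.path(dir, "wt_regions.tsv"),
    junction_fastq = file.path(dir, "junction.fastq"),
    dna_fastq = file.path(dir, "dna.fastq"),
    rna_fastq = file.path(dir, "rna.fastq"))
  list(genome = g, truth = truth, wt = wt, config = cfg)
}
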