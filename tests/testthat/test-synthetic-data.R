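test_that("genome generation is seed-deterministic down to the files", {
  g1 <- generate_genome(1L, 100000L, 20L, seed = 7)
  g2 <- generate_genome(1L, 100000L, 20L, seed = 7)
  d1 <- tempfile(); d2 <- tempfile()
  dir.create(d1); dir.create(d2)
  write_genome(g1, file.path(d1, "g.fa"), file.path(d1, "g.gff3"))
  write_genome(g2, file.path(d2, "g.fa"), file.path(d2, "g.gff3"))
  expect_identical(readLines(file.path(d1, "g.fa")),
                   readLines(file.path(d2, "g.fa")))
  expect_identical(readLines(file.path(d1, "g.gff3")),
                   readLines(file.path(d2, "g.gff3")))
})

test_that("gene-free genomes are valid and annotation round-trips", {
  g <- generate_genome(2L, 12000L, 0L, seed = 3)
  expect_equal(nrow(g$genes), 0L)
  fa <- tempfile(fileext = ".fa"); gff <- tempfile(fileext = ".gff3")
  write_genome(g, fa, gff)
  g2 <- read_genome(fa, gff)
  expect_identical(g2$chromosomes, g$chromosomes)
  expect_equal(nrow(g2$genes), 0L)

  gg <- test_genome()
  write_genome(gg, fa, gff)
  gg2 <- read_genome(fa, gff)
  expect_identical(gg2$genes$start, gg$genes$start)
  expect_identical(gg2$genes$end, gg$genes$end)
  expect_identical(gg2$genes$strand, gg$genes$strand)
})

test_that("default genomes are about half genic", {
  for (s in c(1, 2, 3)) {
    g <- generate_genome(3L, 100000L, 60L, seed = s)
    genic <- sum(g$genes$end - g$genes$start)
    total <- sum(vapply(g$chromosomes, nchar, integer(1)))
    expect_gte(genic / total, 0.45)
    expect_lte(genic / total, 0.55)
  }
})

test_that("over-dense gene requests fail with a clear error", {
  expect_error(generate_genome(1L, 10000L, 60L, genic_fraction = 1.2, seed = 1),
               "density")
})

test_that("wild-type expression tables have positive FPKM and the configured genic share", {
  g <- generate_genome(3L, 100000L, 100L, seed = 5)
  wt <- simulate_wt_expression(g, seed = 9)
  expect_true(all(wt$fpkm > 0))
  n_genic <- sum(paste(wt$chrom, wt$start, wt$end) %in%
                   paste(g$genes$chrom, g$genes$start, g$genes$end))
  expect_equal(n_genic / nrow(wt), 0.978, tolerance = 0.02)
  expect_equal(n_genic / round(0.704 * nrow(g$genes)), 1, tolerance = 0.01)
})

test_that("cohorts honour activation probabilities and level truncation", {
  g <- test_genome()
  none <- generate_cohort(g, cohort_config(n_lines = 50L,
    p_activate_genic_sense = 0, p_activate_genic_as = 0,
    p_activate_intergenic = 0, seed = 1))
  expect_true(all(none$true_level == 0))

  tr <- generate_cohort(g, cohort_config(n_lines = 10000L,
    p_activate_genic_sense = 1 / 3, p_activate_genic_as = 1 / 3,
    p_activate_intergenic = 1 / 3, seed = 4))
  frac <- mean(tr$true_transcribed)
  expect_lt(abs(frac - 1 / 3), 3 * sqrt((1 / 3) * (2 / 3) / 10000))
  lv <- tr$true_level[tr$true_transcribed]
  expect_true(all(lv >= 1e1 & lv <= 1e7))
})

test_that("a 27/76-style cohort has the expected transcribed count", {
  g <- test_genome()
  p <- 27 / 76
  counts <- vapply(1:30, function(s) {
    tr <- generate_cohort(g, cohort_config(n_lines = 76L,
      p_activate_genic_sense = p, p_activate_genic_as = p,
      p_activate_intergenic = p, seed = 500 + s))
    sum(tr$true_transcribed)
  }, numeric(1))
  expect_lt(abs(mean(counts) - 27), 3 * sqrt(p * (1 - p) * 76 / 30))
})

test_that("insertion placement follows genic/intergenic interval lengths", {
  g <- test_genome()
  tr <- generate_cohort(g, cohort_config(n_lines = 10000L, seed = 42))
  genic <- tr$insertion_type != "intergenic"
  # expected genic fraction over the sampled domain (edge margins excluded)
  margin <- 200L
  lens <- vapply(g$chromosomes, nchar, integer(1))
  genic_bp <- sum(pmax(0L, pmin(g$genes$end, lens[g$genes$chrom] - margin) -
                         pmax(g$genes$start, margin)))
  p <- genic_bp / sum(lens - 2L * margin)
  gof <- chisq.test(c(sum(genic), sum(!genic)), p = c(p, 1 - p))
  expect_gt(gof$p.value, 0.01)
})

test_that("junction simulation yields template-bearing reads with the true barcode", {
  g <- test_genome()
  tr <- generate_cohort(g, cohort_config(n_lines = 1L, seed = 8))
  reads <- simulate_junction_library(tr, g, depth_per_line = 5L, seed = 1)
  expect_equal(nrow(reads), 5L)
  expect_true(all(grepl(revcomp(tr$barcode[1]), reads$seq, fixed = TRUE)))

  none <- simulate_junction_library(tr, g, depth_per_line = 0L, seed = 1)
  expect_equal(nrow(none), 0L)

  mut <- simulate_junction_library(tr, g, depth_per_line = 20L,
                                   barcode_sub_rate = 1, seed = 2)
  expect_false(any(grepl(revcomp(tr$barcode[1]), mut$seq, fixed = TRUE)))
})

test_that("junction FASTQ output is byte-identical across runs with one seed", {
  g <- test_genome()
  tr <- generate_cohort(g, cohort_config(n_lines = 5L, seed = 8))
  f1 <- tempfile(fileext = ".fastq"); f2 <- tempfile(fileext = ".fastq")
  simulate_junction_library(tr, g, depth_per_line = 3L, seed = 9, path = f1)
  simulate_junction_library(tr, g, depth_per_line = 3L, seed = 9, path = f2)
  expect_identical(readLines(f1), readLines(f2))
  libs1 <- simulate_count_libraries(tr, dna_depth = 1000, rna_depth = 1000,
                                    seed = 10)
  libs2 <- simulate_count_libraries(tr, dna_depth = 1000, rna_depth = 1000,
                                    seed = 10)
  expect_identical(libs1, libs2)
})

test_that("count libraries follow the multinomial level model", {
  g <- test_genome()
  tr <- generate_cohort(g, cohort_config(n_lines = 10L,
    p_activate_genic_sense = 0, p_activate_genic_as = 0,
    p_activate_intergenic = 0, seed = 3))
  libs <- simulate_count_libraries(tr, dna_depth = 1000, rna_depth = 1000,
                                   seed = 4)
  expect_equal(nrow(libs$rna), 0L)  # nothing transcribed, no RNA reads
  expect_equal(nrow(libs$dna), 1000L)

  # two lines, levels L and 2L, equal DNA weights -> RNA ratio -> 2
  tr2 <- generate_cohort(g, cohort_config(n_lines = 2L, seed = 5))
  tr2$true_level <- c(1000, 2000)
  libs2 <- simulate_count_libraries(tr2, dna_depth = 1e5, rna_depth = 4e5,
                                    dna_weight_jitter_sd = 0, seed = 6)
  counts <- count_barcodes(libs2$rna)$counts
  ratio <- as.numeric(counts[tr2$barcode[2]] / counts[tr2$barcode[1]])
  expect_equal(ratio, 2, tolerance = 0.05)
})

test_that("cohort configs validate their ranges", {
  expect_error(cohort_config(p_activate_genic_sense = 1.2), "\\[0, 1\\]")
  expect_error(cohort_config(log10_level_mean_trap = 8), "\\[1, 7\\]")
  expect_error(cohort_config(log10_level_sd = 0), "positive")
})
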