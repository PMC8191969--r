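tmpl <- tdna_template()

make_read <- function(barcode, flank, luc = tmpl$luc_head,
                      border = tmpl$border, as_sequenced = TRUE) {
  s <- paste0(flank, border, barcode, luc)  # insert-strand junction sequence
  if (as_sequenced) revcomp(s) else s
}

test_that("barcode and flank are recovered from exact junction reads", {
  flank <- random_dna(1, 30)
  for (as_seq in c(TRUE, FALSE)) {
    r <- make_read("ACGTACGTACGT", flank, as_sequenced = as_seq)
    ex <- extract_barcode_and_flank(r, tmpl)
    expect_equal(ex$status, "ok")
    expect_equal(ex$barcode, "ACGTACGTACGT")
    expect_equal(ex$flank, flank)
  }
})

test_that("reads without the border, or with two borders, are rejected", {
  set.seed(1)
  expect_equal(extract_barcode_and_flank(random_dna(1, 120), tmpl)$status,
               "no_template")
  dbl <- paste0(random_dna(1, 25), tmpl$border, random_dna(1, 20),
                tmpl$border, random_dna(1, 25))
  expect_equal(extract_barcode_and_flank(dbl, tmpl)$status,
               "ambiguous_template")
})

test_that("border matching honours the substitution cap exactly", {
  set.seed(2)
  flank <- random_dna(1, 30)
  for (cap in 0:3) {
    for (k in 0:(cap + 1)) {
      b <- plant_substitutions(tmpl$border, k)
      r <- revcomp(paste0(flank, b, "ACGTACGTACGT", tmpl$luc_head))
      ex <- extract_barcode_and_flank(r, tmpl, max_template_mismatch = cap)
      # independent check: naive Hamming scan against the planted border
      d <- sum(charToRaw(b) != charToRaw(tmpl$border))
      if (d <= cap) {
        expect_equal(ex$status, "ok")
        expect_equal(ex$flank, flank)
      } else {
        expect_equal(ex$status, "no_template")
      }
    }
  }
})

test_that("short flanks and truncated barcodes are flagged", {
  r <- make_read("ACGTACGTACGT", random_dna(1, 10))
  expect_equal(extract_barcode_and_flank(r, tmpl)$status, "short_flank")
  trunc <- revcomp(paste0(random_dna(1, 30), tmpl$border, "ACGT"))
  expect_equal(extract_barcode_and_flank(trunc, tmpl)$status, "truncated")
})

test_that("k-mer index lookups match an exhaustive scan", {
  toy <- genome_model(c(chrA = "ACGTACGT"),
                      data.frame(id = character(0), chrom = character(0),
                                 start = integer(0), end = integer(0),
                                 strand = character(0), biotype = character(0)))
  idx <- build_genome_index(toy, 4L)
  hits <- genome_index_lookup(idx, "ACGT")
  expect_setequal(hits$pos[hits$strand == "+"], c(0L, 4L))
  expect_equal(nrow(genome_index_lookup(idx, "GGGG")), 0L)
  expect_error(build_genome_index(toy, 9L), "larger")

  g <- test_genome()
  idx5 <- test_index()
  seq1 <- g$chromosomes[[1]]
  set.seed(3)
  for (p in sample(0:(nchar(seq1) - 5L), 25)) {
    kmer <- substr(seq1, p + 1, p + 5)
    hits <- genome_index_lookup(idx5, kmer)
    fwd <- hits[hits$strand == "+" & hits$chrom == "chr1", ]
    # exhaustive oracle: every occurrence via gregexpr with overlaps
    occ <- integer(0); at <- 0L
    repeat {
      m <- regexpr(kmer, substr(seq1, at + 1, nchar(seq1)), fixed = TRUE)
      if (m < 0) break
      occ <- c(occ, at + m - 1L); at <- at + m
    }
    expect_setequal(fwd$pos, occ)
    expect_true(p %in% fwd$pos)
  }
})

test_that("flank mapping agrees with a full-genome Hamming scan", {
  g <- test_genome()
  idx <- test_index()
  set.seed(4)
  lens <- vapply(g$chromosomes, nchar, integer(1))
  for (i in 1:120) {
    cn <- sample(names(lens), 1)
    q <- sample.int(lens[[cn]] - 30L, 1) - 1L
    fl <- genome_fetch_for_test(g, cn, q, q + 30L)
    if (runif(1) < 0.5) fl <- revcomp(fl)
    fl <- plant_substitutions(fl, sample(0:4, 1))
    got <- map_flank(fl, idx)
    want <- oracle_scan_flank(fl, g)
    expect_equal(got$status, want$status)
    if (got$status == "mapped") {
      expect_equal(got$chrom, want$chrom)
      expect_equal(got$position, want$position)
      expect_equal(got$strand, want$strand)
      expect_equal(got$mismatches, want$mismatches)
      expect_lte(got$mismatches, 3L)
    }
  }
})

test_that("flanks from duplicated loci are multi-mapped, junk is unmapped", {
  set.seed(5)
  core <- random_dna(1, 40)
  dupseq <- paste0(random_dna(1, 100), core, random_dna(1, 100), core,
                   random_dna(1, 100))
  gdup <- genome_model(c(chrD = dupseq),
                       data.frame(id = character(0), chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  strand = character(0), biotype = character(0)))
  idx <- build_genome_index(gdup, 5L)
  expect_equal(map_flank(core, idx)$status, "multi_mapped")
  expect_equal(map_flank(random_dna(1, 40), idx)$status, "unmapped")
  flN <- paste0(substr(core, 1, 36), "NNNN")
  expect_equal(map_flank(flN, idx, n_cap = 2)$status, "low_quality")
})

test_that("reverse-complementing a flank flips the match strand at the same interval", {
  g <- test_genome()
  idx <- test_index()
  set.seed(6)
  for (i in 1:20) {
    q <- sample.int(nchar(g$chromosomes[[1]]) - 30L, 1) - 1L
    fl <- genome_fetch_for_test(g, "chr1", q, q + 30L)
    a <- map_flank(fl, idx, border_end = "3prime")
    b <- map_flank(revcomp(fl), idx, border_end = "3prime")
    if (a$status != "mapped" || b$status != "mapped") next
    expect_false(a$strand == b$strand)
    # same matched interval: junction coordinates sit at opposite ends
    expect_setequal(c(a$position, b$position), c(q, q + 29L))
    # same physical junction when the border side is carried along
    b2 <- map_flank(revcomp(fl), idx, border_end = "5prime")
    expect_equal(b2$position, a$position)
    expect_equal(b2$strand, a$strand)
  }
})

test_that("extraction plus mapping recovers every simulated junction", {
  g <- test_genome()
  truth <- generate_cohort(g, cohort_config(n_lines = 40L, seed = 7))
  reads <- simulate_junction_library(truth, g, depth_per_line = 2L, seed = 8)
  ej <- extract_junctions(reads)
  expect_true(all(ej$status == "ok"))
  expect_setequal(unique(ej$barcode), truth$barcode)
  mp <- map_flanks(ej$flank, test_index())
  expect_true(all(mp$status == "mapped"))
  key <- paste(mp$chrom, mp$position, mp$strand)
  truth_key <- paste(truth$chrom, truth$rb_position, truth$strand)
  line <- as.integer(sub("line(\\d+):.*", "\\1", ej$id))
  expect_true(all(key == truth_key[match(line, truth$line_id)]))
})
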