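# Promoter extraction, species splits, and the synthetic-corpus generator.

toy_genome <- function(len = 1000, seed = 1) {
  set.seed(seed)
  c(chr1 = paste(sample(c("A", "C", "G", "T"), len, replace = TRUE),
                 collapse = ""))
}

test_that("plus-strand promoters are the bases immediately upstream", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "g1", contig = "chr1", start = 501, end = 800,
                    strand = "+")
  corp <- extract_promoters(g, ann)
  expect_equal(length(corp), 1L)
  expect_equal(corp$promoters$sequence, substr(g[["chr1"]], 101, 500))
})

test_that("minus-strand promoters are reverse-complemented downstream bases", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "g1", contig = "chr1", start = 1, end = 300,
                    strand = "-")
  corp <- extract_promoters(g, ann)
  expect_equal(corp$promoters$sequence, revcomp(substr(g[["chr1"]], 301, 700)))
  # strand round-trip recovers the forward-strand genomic window
  expect_equal(revcomp(corp$promoters$sequence), substr(g[["chr1"]], 301, 700))
})

test_that("neighbors inside the separation margin exclude a gene", {
  g <- toy_genome()
  # second gene sits inside the first's promoter+separation window
  ann <- data.frame(gene_id = c("g1", "g2"), contig = "chr1",
                    start = c(501, 380), end = c(800, 450),
                    strand = c("+", "+"))
  corp <- extract_promoters(g, ann, promoter_length = 100, min_separation = 100)
  # g1's window 401..500 extended to 301..500 overlaps g2 (380..450) -> drop;
  # g2's window 280..379 extended to 180..379 is clear of g1 -> keep
  expect_equal(corp$promoters$promoter_id, "g2")
  expect_equal(corp$promoters$sequence, substr(g[["chr1"]], 280, 379))
})

test_that("retention matches a brute-force overlap oracle on random toys", {
  set.seed(33)
  for (rep in 1:8) {
    g <- toy_genome(800, seed = rep)
    n <- sample(2:4, 1)
    starts <- sort(sample(seq(50, 700, by = 10), n))
    ann <- data.frame(gene_id = paste0("g", seq_len(n)), contig = "chr1",
                      start = starts,
                      end = pmin(starts + sample(30:120, n, replace = TRUE), 800),
                      strand = sample(c("+", "-"), n, replace = TRUE))
    L <- 80; sep <- 40
    corp <- extract_promoters(g, ann, promoter_length = L, min_separation = sep)
    # independent oracle: direct interval arithmetic per gene
    expected <- character(0)
    for (i in seq_len(n)) {
      gi <- ann[i, ]
      if (gi$strand == "+") {
        win <- c(gi$start - L, gi$start - 1); ext <- c(win[1] - sep, win[2])
        inb <- win[1] >= 1
      } else {
        win <- c(gi$end + 1, gi$end + L); ext <- c(win[1], win[2] + sep)
        inb <- win[2] <= 800
      }
      if (!inb) next
      others <- ann[-i, ]
      if (any(others$start <= ext[2] & others$end >= ext[1])) next
      expected <- c(expected, gi$gene_id)
    }
    expect_setequal(corp$promoters$promoter_id, expected)
  }
})

test_that("genes whose upstream window leaves the contig are dropped", {
  g <- toy_genome()
  ann <- data.frame(gene_id = c("edge", "ok"), contig = "chr1",
                    start = c(200, 600), end = c(250, 650),
                    strand = "+")
  corp <- extract_promoters(g, ann, promoter_length = 300,
                            min_separation = 10)
  expect_equal(corp$promoters$promoter_id, "ok")
})

test_that("upstream padding is stored for 5' length compensation", {
  g <- toy_genome()
  ann <- data.frame(gene_id = "g1", contig = "chr1", start = 501, end = 800,
                    strand = "+")
  corp <- extract_promoters(g, ann, promoter_length = 400, pad = 64)
  expect_equal(nchar(corp$promoters$upstream), 64)
  expect_equal(corp$promoters$upstream, substr(g[["chr1"]], 101 - 64, 100))
  # minus strand pad comes from the 3' genomic side, reverse-complemented
  ann2 <- data.frame(gene_id = "g2", contig = "chr1", start = 1, end = 300,
                     strand = "-")
  corp2 <- extract_promoters(g, ann2, promoter_length = 300, pad = 50)
  expect_equal(corp2$promoters$upstream,
               revcomp(substr(g[["chr1"]], 601, 650)))
})

test_that("annotation errors are hard and name the gene", {
  g <- toy_genome()
  expect_error(extract_promoters(g, data.frame(
    gene_id = "gx", contig = "chrZ", start = 1, end = 10, strand = "+")),
    "chrZ.*gx")
  expect_error(extract_promoters(g, data.frame(
    gene_id = "gy", contig = "chr1", start = 50, end = 10, strand = "+")),
    "start > end: gy")
  expect_error(extract_promoters(g, data.frame(
    gene_id = "gz", contig = "chr1", start = 10, end = 20, strand = "x")),
    "strand")
})

test_that("promoters above the ambiguity threshold are dropped", {
  seqs <- paste(rep("A", 1000), collapse = "")
  substr(seqs, 401, 460) <- paste(rep("N", 60), collapse = "")
  g <- c(chr1 = seqs)
  ann <- data.frame(gene_id = "g1", contig = "chr1", start = 501, end = 600,
                    strand = "+")
  expect_equal(length(extract_promoters(g, ann, promoter_length = 400)), 0L)
  expect_equal(length(extract_promoters(g, ann, promoter_length = 400,
                                        max_n_frac = 0.2)), 1L)
})

test_that("species-holdout split partitions the corpus deterministically", {
  corp <- generate_synthetic_corpus(15, seed = 5,
                                    species = rep(c("X", "Y"), c(10, 5)))
  sp <- split_corpus(corp, holdout_species = "Y", n_validation = 2, seed = 3)
  expect_equal(vapply(sp, length, integer(1)),
               c(train = 8L, validation = 2L, test = 5L))
  expect_true(all(sp$test$promoters$species == "Y"))
  # disjoint union equals the input
  ids <- c(sp$train$promoters$promoter_id, sp$validation$promoters$promoter_id,
           sp$test$promoters$promoter_id)
  expect_setequal(ids, corp$promoters$promoter_id)
  expect_equal(anyDuplicated(ids), 0L)
  # same seed -> identical membership
  sp2 <- split_corpus(corp, "Y", 2, seed = 3)
  expect_identical(sp$validation$promoters$promoter_id,
                   sp2$validation$promoters$promoter_id)
  # boundary: no validation promoters
  sp0 <- split_corpus(corp, "Y", 0, seed = 3)
  expect_equal(length(sp0$validation), 0L)
  expect_equal(length(sp0$train), 10L)
  expect_warning(split_corpus(corp, "Z", 2, seed = 1), "absent")
})

test_that("synthetic corpora are reproducible and honor composition", {
  c1 <- generate_synthetic_corpus(20, seed = 7)
  c2 <- generate_synthetic_corpus(20, seed = 7)
  expect_identical(c1$promoters, c2$promoters)
  expect_true(all(nchar(c1$promoters$sequence) == 400))
  # degenerate composition
  gc1 <- generate_synthetic_corpus(5, gc_fraction = 1, plant_elements = FALSE,
                                   seed = 2)
  expect_true(all(grepl("^[GC]+$", gc1$promoters$sequence)))
})

test_that("planted TATA elements sit at the recorded offsets", {
  corp <- generate_synthetic_corpus(25, seed = 13)
  p <- corp$promoters
  expect_true(all(!is.na(p$tata_pos)) && all(!is.na(p$tss_pos)))
  expect_true(all(p$tata_pos < p$tss_pos))
  for (i in seq_len(nrow(p))) {
    motif <- substr(p$sequence[i], p$tata_pos[i] + 1, p$tata_pos[i] + 7)
    expect_match(motif, "^TATA[AT][AT][AT]$")
  }
})

test_that("corpus FASTA round-trips with annotations and padding", {
  corp <- generate_synthetic_corpus(8, seed = 21)
  fa <- tempfile(fileext = ".fa")
  write_corpus_fasta(corp, fa)
  back <- read_corpus_fasta(fa)
  expect_identical(back$promoters$sequence, corp$promoters$sequence)
  expect_identical(back$promoters$tata_pos, corp$promoters$tata_pos)
  expect_identical(back$promoters$tss_pos, corp$promoters$tss_pos)
  expect_identical(back$promoters$upstream, corp$promoters$upstream)
  tsv <- tempfile(fileext = ".tsv")
  write_corpus_manifest(corp, tsv)
  m <- read.delim(tsv)
  expect_equal(nrow(m), 8L)
  expect_true(all(m$length == 400))
})

test_that("genome FASTA + GFF3 extraction works through the file readers", {
  g <- toy_genome()
  fa <- tempfile(fileext = ".fa")
  writeLines(c(">chr1 toy contig", g[["chr1"]]), fa)
  gff <- tempfile(fileext = ".gff3")
  writeLines(c("##gff-version 3",
               paste("chr1", "toy", "gene", "501", "800", ".", "+", ".",
                     "ID=gene1", sep = "\t"),
               paste("chr1", "toy", "exon", "501", "650", ".", "+", ".",
                     "ID=exon1", sep = "\t")), gff)
  genome <- read_genome_fasta(fa)
  expect_identical(genome, c(chr1 = g[["chr1"]]))
  ann <- read_gene_annotations(gff)
  expect_equal(nrow(ann), 1L)  # exon feature ignored
  corp <- extract_promoters(genome, ann)
  expect_equal(corp$promoters$sequence, substr(g[["chr1"]], 101, 500))
})

test_that("BED element annotations attach to promoters by id", {
  corp <- generate_synthetic_corpus(3, plant_elements = FALSE, seed = 4)
  bed <- tempfile(fileext = ".bed")
  writeLines(c("synp00001\t120\t128\tTATA", "synp00001\t200\t201\tTSS"), bed)
  out <- add_element_annotations(corp, bed)
  expect_equal(out$promoters$tata_pos[1], 120L)
  expect_equal(out$promoters$tss_pos[1], 200L)
  expect_true(is.na(out$promoters$tata_pos[2]))
})
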