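# Screening engine: recombination proposals, filters, consensus, ranking.

test_that("display coordinates are relative to the start codon", {
  expect_equal(to_display_coords(c(0, 40)), c(-400L, -360L))
  expect_equal(to_display_coords(c(360, 400)), c(-40L, 0L))
  # the published example window: region-3 rewrite at [123, 163)
  expect_equal(to_display_coords(c(123, 163)), c(-277L, -237L))
  expect_error(to_display_coords(c(390, 401)))
})

test_that("element disruption is interval overlap with TATA (8 bp) and TSS", {
  prop <- function(w) list(rewrite_window = w)
  p_tata <- list(tata_pos = 300L, tss_pos = NA_integer_)
  expect_true(element_disruption_filter(prop(c(298, 303)), p_tata))
  expect_false(element_disruption_filter(prop(c(298, 303)),
                                         list(tata_pos = NA, tss_pos = NA)))
  expect_false(element_disruption_filter(prop(c(108, 148)),
                                         list(tata_pos = 100L)))
  expect_true(element_disruption_filter(prop(c(100, 105)),
                                        list(tata_pos = 100L)))
  expect_true(element_disruption_filter(prop(c(140, 180)),
                                        list(tss_pos = 150L)))
  expect_false(element_disruption_filter(prop(c(140, 150)),
                                         list(tss_pos = 150L)))
})

test_that("TFBS queries validate their alphabet and length", {
  expect_silent(tfbs_query("tetO", TETO_SEQ))
  expect_equal(nchar(tfbs_query("mig1O", MIG1O_SEQ)$sequence), 17L)
  expect_error(tfbs_query("short", "ACGT"), "\\[8, 64\\]")
  expect_error(tfbs_query("bad", "ACGTNACGT"), "\\{A,C,G,T\\}")
})

test_that("consensus requires at least 7 of 10 Matches", {
  mk_out <- function(match) {
    structure(list(msrl_probs = c("5" = 0.3, "40" = 0.7),
                   region_probs = replace(rep(0.05, 10), 3, 0.55),
                   msrl_pred = 40L, region_pred = 3L, match = match),
              class = "determiner_output")
  }
  with6 <- consensus_decision(lapply(1:10, function(i) mk_out(i <= 6)))
  with7 <- consensus_decision(lapply(1:10, function(i) mk_out(i <= 7)))
  expect_equal(with6$n_match, 6L); expect_false(with6$consensus)
  expect_equal(with7$n_match, 7L); expect_true(with7$consensus)
  expect_equal(with7$msrl_selected, 40L)
  expect_equal(with7$region_selected, 3L)
})

test_that("recombination rewrites the selected window and nothing else", {
  corpus <- fixture_corpus()
  pbs <- fixture_placeback_set()
  ens <- fixture_ensemble()
  for (tf in list(tfbs_query("tetO", TETO_SEQ),
                  tfbs_query("mig1O", MIG1O_SEQ))) {
    prop <- recombine(corpus$promoters[1, ], tf, pbs, ens)
    msrl <- prop$msrl_selected
    expect_true(msrl %in% c(5L, 40L))
    expect_equal(diff(prop$rewrite_window), msrl)
    expect_equal(nchar(prop$rewritten_sequence),
                 400L - msrl + nchar(tf$sequence))
    # conservation outside the rewrite window
    w <- prop$rewrite_window
    orig <- corpus$promoters$sequence[1]
    expect_identical(substr(prop$rewritten_sequence, 1, w[1]),
                     substr(orig, 1, w[1]))
    expect_identical(substr(prop$rewritten_sequence,
                            w[1] + nchar(tf$sequence) + 1,
                            nchar(prop$rewritten_sequence)),
                     substr(orig, w[2] + 1, 400))
    # the TFBS itself sits in the window
    expect_identical(substr(prop$rewritten_sequence, w[1] + 1,
                            w[1] + nchar(tf$sequence)), tf$sequence)
    # the rewrite window falls in the selected region (peak-centered, so it
    # may straddle a bin edge but must overlap the bin)
    bin <- c((prop$region_selected - 1L) * 40L, prop$region_selected * 40L)
    expect_true(w[1] < bin[2] && w[2] > bin[1])
    expect_equal(prop$display_window, prop$rewrite_window - 400L)
    # recommended implies consensus and no filter flags
    expect_equal(prop$recommended,
                 prop$n_match >= 7 && length(prop$filter_flags) == 0)
  }
  expect_error(recombine(corpus$promoters[1, ],
                         tfbs_query("tetO", TETO_SEQ),
                         pbs[c(1, 3, 2, 4)], ens),
               "\\(5, 5, 40, 40\\)")
})

test_that("screening a corpus yields one ranked proposal per promoter", {
  corpus <- generate_synthetic_corpus(6, seed = 301)
  pbs <- fixture_placeback_set()
  ens <- fixture_ensemble()
  tf <- tfbs_query("tetO", TETO_SEQ)
  res <- screen_corpus(corpus, tf, pbs, ens)
  expect_equal(nrow(res$table), 6L)
  expect_setequal(res$table$promoter_id, corpus$promoters$promoter_id)
  s <- res$summary
  expect_equal(unname(s["n_recommended"] + s["n_filtered"]), 6)
  # recommended block is ranked by (n_match desc, mean_peak desc, id asc)
  rec <- res$table[res$table$recommended, ]
  if (nrow(rec) > 1) {
    key <- order(-rec$n_match, -rec$mean_peak, rec$promoter_id)
    expect_equal(key, seq_len(nrow(rec)))
  }
  # every proposal satisfies the recommendation invariant
  for (p in res$proposals)
    expect_equal(p$recommended,
                 p$n_match >= 7 && length(p$filter_flags) == 0)
  # an impossible consensus threshold filters everything
  res11 <- screen_corpus(corpus, tf, pbs, ens, consensus_min = 11L)
  expect_equal(unname(res11$summary["n_recommended"]), 0)
  expect_true(all(grepl("no_consensus", res11$table$flags)))
})

test_that("screening output is byte-identical across reruns", {
  corpus <- generate_synthetic_corpus(4, seed = 302)
  pbs <- fixture_placeback_set()
  ens <- fixture_ensemble()
  tf <- tfbs_query("tetO", TETO_SEQ)
  f1 <- tempfile(fileext = ".tsv"); f2 <- tempfile(fileext = ".tsv")
  write_proposals_tsv(screen_corpus(corpus, tf, pbs, ens), f1)
  write_proposals_tsv(screen_corpus(corpus, tf, pbs, ens), f2)
  expect_identical(readBin(f1, "raw", file.size(f1)),
                   readBin(f2, "raw", file.size(f2)))
})

test_that("rewritten promoters and curve tracks are written as plain text", {
  corpus <- generate_synthetic_corpus(3, seed = 303)
  pbs <- fixture_placeback_set()
  ens <- fixture_ensemble()
  tf <- tfbs_query("mig1O", MIG1O_SEQ)
  res <- screen_corpus(corpus, tf, pbs, ens, consensus_min = 0L)
  fa <- tempfile(fileext = ".fa")
  write_rewritten_fasta(res, fa, recommended_only = FALSE)
  seqs <- Biostrings::readDNAStringSet(fa)
  expect_equal(length(seqs), 3L)
  tsv <- tempfile(fileext = ".tsv")
  write_curve_tracks(corpus$promoters[1, ], tf, pbs, tsv)
  tracks <- read.delim(tsv)
  expect_equal(nrow(tracks), 4L * 400L)
  expect_true(all(tracks$prob >= 0 & tracks$prob <= 1))
})

test_that("iterative application re-screens an already rewritten promoter", {
  # split-site style insertion: run recombine on the rewritten sequence
  corpus <- generate_synthetic_corpus(2, seed = 304)
  pbs <- fixture_placeback_set()
  ens <- fixture_ensemble()
  tf <- tfbs_query("tetO", TETO_SEQ)   # 40 bp, so round 1 output is >= 400
  first <- recombine(corpus$promoters[1, ], tf, pbs, ens)
  # re-anchor to 400 bp (keep the gene-proximal end) and re-apply
  seq2 <- substr(first$rewritten_sequence,
                 nchar(first$rewritten_sequence) - 399L,
                 nchar(first$rewritten_sequence))
  second <- recombine(list(promoter_id = "round2", sequence = seq2,
                           tata_pos = NA, tss_pos = NA), tf, pbs, ens)
  expect_s3_class(second, "proposal")
  expect_equal(nchar(second$rewritten_sequence),
               400L - second$msrl_selected + 40L)
})
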