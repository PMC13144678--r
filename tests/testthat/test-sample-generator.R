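# Self-supervised corruption/reconstruction sample generation.

test_that("OQPR bins follow the 10 x 40 bp midpoint rule", {
  expect_equal(oqpr_bin_of(c(0, 5)), 1L)
  expect_equal(oqpr_bin_of(c(395, 400)), 10L)
  # enumerate bin edges 0, 40, ..., 400 and locate the midpoint
  bin_by_enumeration <- function(w) {
    edges <- seq(0, 400, by = 40)
    findInterval((w[1] + w[2]) / 2, edges, rightmost.closed = TRUE)
  }
  expect_equal(oqpr_bin_of(c(60, 100)), 3L)
  set.seed(8)
  for (i in 1:50) {
    L <- sample(c(5, 40), 1)
    s <- sample(0:(400 - L), 1)
    w <- c(s, s + L)
    expect_equal(oqpr_bin_of(w), bin_by_enumeration(w))
  }
  expect_error(oqpr_bin_of(c(390, 401)), "outside promoter")
  expect_error(oqpr_bin_of(c(-1, 4)), "outside promoter")
})

test_that("generated samples conserve length, label mass, and disjointness", {
  corpus <- fixture_corpus()
  for (msrl in c(5L, 40L)) {
    st <- sample_stream(corpus, generator_config(msrl = msrl), 60, seed = msrl)
    for (s in st$next_batch()) {
      expect_equal(nchar(s$disrupted_promoter), 400L)
      expect_equal(s$msrl, msrl)
      lab <- sample_label(s)
      expect_equal(sum(lab), msrl)
      expect_true(all(lab[(s$rewrite_window[1] + 1):s$rewrite_window[2]] == 1))
      expect_true(nchar(s$query) >= 8 && nchar(s$query) <= 64)
      # 2-3 decoys, pairwise disjoint and disjoint from the rewrite window
      expect_true(length(s$disruption_windows) %in% 2:3)
      wins <- c(list(s$rewrite_window), s$disruption_windows)
      for (i in seq_along(wins)) for (j in seq_along(wins)) {
        if (i < j)
          expect_true(wins[[i]][2] <= wins[[j]][1] ||
                      wins[[j]][2] <= wins[[i]][1])
      }
      expect_equal(s$oqpr_bin, oqpr_bin_of(s$rewrite_window))
    }
  }
})

test_that("queries reconstruct from the base promoter and coordinates add up", {
  corpus <- fixture_corpus()
  by_id <- corpus$promoters
  st <- sample_stream(corpus, generator_config(msrl = 5), 40, seed = 17)
  for (s in st$next_batch()) {
    base <- by_id[by_id$promoter_id == s$base_promoter_id, ]
    q <- nchar(s$query)
    # slicing the base promoter at the recorded origin reproduces the query
    expect_equal(substr(base$sequence, s$query_origin + 1, s$query_origin + q),
                 s$query)
    # 3'-anchored bookkeeping: rewrite start = origin + q - msrl
    expect_equal(s$rewrite_window[1], s$query_origin + q - s$msrl)
  }
})

test_that("bases outside rewrite and decoy windows are preserved", {
  corpus <- fixture_corpus()
  by_id <- corpus$promoters
  for (msrl in c(5L, 40L)) {
    st <- sample_stream(corpus, generator_config(msrl = msrl), 25,
                        seed = 100 + msrl)
    for (s in st$next_batch()) {
      base <- by_id[by_id$promoter_id == s$base_promoter_id, ]
      delta <- nchar(s$query) - s$msrl   # 5' shift from length compensation
      touched <- logical(400)
      for (w in c(list(s$rewrite_window), s$disruption_windows))
        touched[(w[1] + 1):w[2]] <- TRUE
      dp <- strsplit(s$disrupted_promoter, "")[[1]]
      bs <- strsplit(base$sequence, "")[[1]]
      up <- strsplit(base$upstream, "")[[1]]
      ok <- vapply(which(!touched), function(p) {  # 1-based final coordinate
        # positions 3' of the rewrite window are anchored (unshifted);
        # positions 5' of it are shifted by the compensation delta
        src <- if (p > s$rewrite_window[2]) p else p - delta
        if (src >= 1) {
          identical(dp[p], bs[src])
        } else {
          # compensated from the 3'-most end of the upstream context
          identical(dp[p], up[length(up) + src])
        }
      }, logical(1))
      expect_true(all(ok))
    }
  }
})

test_that("streams are deterministic and isolate their RNG state", {
  corpus <- fixture_corpus()
  cfg <- generator_config(msrl = c(5, 40))
  b1 <- sample_stream(corpus, cfg, 10, seed = 55)$next_batch()
  set.seed(999)  # unrelated RNG use must not perturb the stream
  st2 <- sample_stream(corpus, cfg, 10, seed = 55)
  runif(3)
  b2 <- st2$next_batch()
  expect_identical(b1, b2)
  # the stream does not disturb the session RNG
  set.seed(1); x1 <- runif(1)
  set.seed(1); invisible(sample_stream(corpus, cfg, 2, seed = 3)$next_batch())
  x2 <- runif(1)
  expect_identical(x1, x2)
})

test_that("query lengths and positions cover the promoter space uniformly", {
  corpus <- fixture_corpus()
  st <- sample_stream(corpus, generator_config(msrl = 40), 2000, seed = 77)
  samples <- st$next_batch()
  qlens <- vapply(samples, function(s) nchar(s$query), integer(1))
  # chi-square goodness of fit against the uniform null on [8, 64]
  obs <- tabulate(qlens - 7L, nbins = 57L)
  p <- stats::chisq.test(obs, p = rep(1 / 57, 57))$p.value
  expect_gt(p, 0.01)
  # every OQPR bin is visited
  bins <- vapply(samples, function(s) s$oqpr_bin, integer(1))
  expect_setequal(sort(unique(bins)), 1:10)
  # mixed-MSRL config is balanced
  st2 <- sample_stream(corpus, generator_config(msrl = c(5, 40)), 400,
                       seed = 78)
  frac5 <- mean(vapply(st2$next_batch(), function(s) s$msrl == 5L, logical(1)))
  expect_gt(frac5, 0.4); expect_lt(frac5, 0.6)
})

test_that("single-promoter species are skipped with a warning", {
  corpus <- generate_synthetic_corpus(5, seed = 3,
                                      species = c("A", "A", "A", "A", "B"))
  expect_warning(st <- sample_stream(corpus, generator_config(), 10, seed = 1),
                 "single promoter: B")
  batch <- st$next_batch()
  ids <- vapply(batch, function(s) s$base_promoter_id, character(1))
  expect_true(all(ids %in% corpus$promoters$promoter_id[1:4]))
  one_sp <- generate_synthetic_corpus(2, seed = 3, species = c("A", "B"))
  expect_error(suppressWarnings(sample_stream(one_sp, generator_config(), 1,
                                              seed = 1)),
               "at least one species")
})

test_that("samples serialize to JSON lines and back", {
  corpus <- fixture_corpus()
  st <- sample_stream(corpus, generator_config(msrl = 5), 5, seed = 9)
  samples <- st$next_batch()
  path <- tempfile(fileext = ".jsonl")
  write_samples_jsonl(samples, path)
  expect_equal(length(readLines(path)), 5L)
  back <- read_samples_jsonl(path)
  for (i in seq_along(samples)) {
    expect_equal(back[[i]]$disrupted_promoter, samples[[i]]$disrupted_promoter)
    expect_equal(back[[i]]$rewrite_window, samples[[i]]$rewrite_window)
    expect_equal(back[[i]]$msrl, samples[[i]]$msrl)
  }
})
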