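#' Configuration for the self-supervised training-sample generator
#'
#' The generator corrupts a base promoter so that a Place-Back model can be
#' trained to find where the extracted query originally sat. Defaults follow
#' the stated sampling scheme: query lengths uniform on 8-64 bp, a
#' model-specific rewriting length (MSRL) of 5 or 40 bp, and 2-3 decoy
#' disruptions of MSRL length.
#'
#' @param msrl Rewriting length(s); subset of \{5, 40\}. When both are given,
#'   each sample draws one uniformly (used when training Determiner models).
#' @param query_len_min,query_len_max Query length bounds (8 and 64).
#' @param n_disruptions_range Inclusive range for the number of decoy
#'   disruptions (default 2:3).
#' @param promoter_length Promoter length (default 400).
#' @param max_retries Placement retries before a hard error (default 100).
#' @return A `generator_config` list.
#' @export
generator_config <- function(msrl = 40, query_len_min = 8, query_len_max = 64,
                             n_disruptions_range = c(2L, 3L),
                             promoter_length = 400L, max_retries = 100L) {
  stopifnot(all(msrl %in% c(5, 40)), length(msrl) >= 1,
            query_len_min >= 8, query_len_max <= 64,
            query_len_min <= query_len_max,
            length(n_disruptions_range) == 2L,
            n_disruptions_range[1] >= 1,
            n_disruptions_range[1] <= n_disruptions_range[2])
  structure(list(msrl = as.integer(msrl),
                 query_len_min = as.integer(query_len_min),
                 query_len_max = as.integer(query_len_max),
                 n_disruptions_range = as.integer(n_disruptions_range),
                 promoter_length = as.integer(promoter_length),
                 max_retries = as.integer(max_retries)),
            class = "generator_config")
}

# Uniform integer draw on [lo, hi] consuming the current RNG stream.
runif_int <- function(lo, hi, n = 1L) {
  lo + floor(stats::runif(n) * (hi - lo + 1L))
}

#' Construct one self-supervised training sample
#'
#' Extracts a query of uniform length 8-64 bp from the base promoter,
#' replaces its window with an MSRL-length segment cut from a uniform offset
#' of the auxiliary promoter, re-anchors the sequence at the gene-proximal
#' (3') end so it is exactly `promoter_length` bases (compensating at the 5'
#' end with stored upstream context, or with seeded background bases matching
#' the base promoter's composition), and finally overwrites 2-3 additional
#' non-overlapping MSRL-length windows with auxiliary segments as decoys.
#' The per-base label marks the MSRL window that replaced the query.
#'
#' The query origin is drawn uniformly over starts for which the re-anchored
#' rewrite window stays inside the promoter (for q < MSRL the window shifts
#' left by MSRL - q during 5'-trimming, so starts below MSRL - q are
#' excluded).
#'
#' Consumes the session RNG stream; seed via [sample_stream()] or
#' `set.seed()` for reproducibility.
#'
#' @param base,auxiliary One-row promoter records (lists or single rows of a
#'   corpus's `promoters` data frame) with fields `promoter_id`, `sequence`,
#'   and optionally `upstream`.
#' @param config A [generator_config()].
#' @return A `training_sample` list with fields `disrupted_promoter`,
#'   `query`, `rewrite_window` (0-based half-open), `disruption_windows`,
#'   `msrl`, `oqpr_bin`, `query_origin` (0-based start of the query in the
#'   base promoter), `base_promoter_id`, `auxiliary_promoter_id`.
#' @export
make_sample <- function(base, auxiliary, config) {
  base <- as.list(base); auxiliary <- as.list(auxiliary)
  P <- config$promoter_length
  stopifnot(nchar(base$sequence) == P, nchar(auxiliary$sequence) == P)
  if (identical(base$promoter_id, auxiliary$promoter_id))
    stop("base and auxiliary must be distinct promoters")
  msrl <- if (length(config$msrl) > 1)
    config$msrl[runif_int(1L, length(config$msrl))] else config$msrl
  q <- runif_int(config$query_len_min, config$query_len_max)
  a_lo <- max(0L, msrl - q)
  a <- runif_int(a_lo, P - q)                      # 0-based query origin
  query <- substr(base$sequence, a + 1L, a + q)

  aux_cut <- function(len) {
    off <- runif_int(0L, P - len)
    substr(auxiliary$sequence, off + 1L, off + len)
  }
  # replace the query window with an MSRL-length auxiliary segment
  s <- paste0(substr(base$sequence, 1L, a),
              aux_cut(msrl),
              substr(base$sequence, a + q + 1L, P))
  # re-anchor at the 3' end to restore length P
  delta <- q - msrl                                 # >0: prepend, <0: trim
  if (delta > 0L) {
    up <- base$upstream
    ctx <- if (!is.null(up) && !is.na(up) && nchar(up) >= delta) {
      substr(up, nchar(up) - delta + 1L, nchar(up))
    } else {
      comp <- strsplit(base$sequence, "")[[1]]
      paste(comp[runif_int(1L, P, delta)], collapse = "")
    }
    s <- paste0(ctx, s)
  } else if (delta < 0L) {
    s <- substr(s, 1L - delta, nchar(s))
  }
  stopifnot(nchar(s) == P)
  rewrite <- c(a + delta, a + delta + msrl)         # 0-based half-open

  # decoy disruptions: length-preserving substitutions, disjoint from the
  # rewrite window and from each other
  n_d <- runif_int(config$n_disruptions_range[1], config$n_disruptions_range[2])
  windows <- list(rewrite)
  decoys <- list()
  for (k in seq_len(n_d)) {
    placed <- FALSE
    for (try in seq_len(config$max_retries)) {
      st <- runif_int(0L, P - msrl)
      w <- c(st, st + msrl)
      clash <- any(vapply(windows, function(v) w[1] < v[2] && w[2] > v[1],
                          logical(1)))
      if (!clash) {
        windows <- c(windows, list(w)); decoys <- c(decoys, list(w))
        substr(s, st + 1L, st + msrl) <- aux_cut(msrl)
        placed <- TRUE
        break
      }
    }
    if (!placed)
      stop("could not place ", n_d, " non-overlapping disruptions after ",
           config$max_retries, " retries")
  }
  structure(list(disrupted_promoter = s, query = query,
                 rewrite_window = as.integer(rewrite),
                 disruption_windows = decoys,
                 msrl = as.integer(msrl),
                 oqpr_bin = oqpr_bin_of(rewrite, P),
                 query_origin = as.integer(a),
                 base_promoter_id = base$promoter_id,
                 auxiliary_promoter_id = auxiliary$promoter_id),
            class = "training_sample")
}

#' Per-base label vector of a training sample
#'
#' @param sample A `training_sample`.
#' @param promoter_length Promoter length (default 400).
#' @return Binary vector of `promoter_length` values, 1 exactly on the
#'   rewrite window (so its sum equals the sample's MSRL).
#' @export
sample_label <- function(sample, promoter_length = 400L) {
  lab <- numeric(promoter_length)
  lab[(sample$rewrite_window[1] + 1L):sample$rewrite_window[2]] <- 1
  lab
}

#' Original query position region (OQPR) bin of a window
#'
#' The promoter is divided into ten 40 bp bins; bin 1 is the most distal
#' (5') 40 bp and bin 10 abuts the start codon. A window is assigned the bin
#' containing its midpoint: `1 + floor(center / bin_width)`.
#'
#' @param window 0-based half-open interval `c(start, end)` within the
#'   promoter.
#' @param promoter_length Promoter length (default 400).
#' @param bin_width Bin width (default 40).
#' @return Integer bin in 1..(promoter_length / bin_width).
#' @export
#' @examples
#' oqpr_bin_of(c(0, 5))     # 1
#' oqpr_bin_of(c(60, 100))  # 3
#' oqpr_bin_of(c(395, 400)) # 10
oqpr_bin_of <- function(window, promoter_length = 400L, bin_width = 40L) {
  stopifnot(length(window) == 2L, window[1] < window[2])
  if (window[1] < 0 || window[2] > promoter_length)
    stop("window [", window[1], ",", window[2], ") outside promoter [0,",
         promoter_length, ")")
  center <- (window[1] + window[2]) / 2
  as.integer(min(1L + floor(center / bin_width), promoter_length %/% bin_width))
}

#' Infinite seeded stream of training-sample batches
#'
#' Draws a base promoter uniformly from the corpus (restricted to species
#' with at least two promoters, others are skipped with a warning) and an
#' auxiliary promoter uniformly from the same species, then builds a
#' [make_sample()] corruption for each pair. The stream owns a private RNG
#' state: two streams with the same seed yield identical batch sequences
#' regardless of other RNG use.
#'
#' @param corpus A `promoter_corpus`.
#' @param config A [generator_config()].
#' @param batch_size Samples per batch.
#' @param seed Integer seed.
#' @return An object of class `sample_stream` whose `$next_batch()` returns
#'   a list of `training_sample`s.
#' @export
sample_stream <- function(corpus, config, batch_size, seed) {
  stopifnot(inherits(corpus, "promoter_corpus"), batch_size >= 1)
  p <- corpus$promoters
  tab <- table(p$species)
  singles <- names(tab)[tab < 2]
  if (length(singles))
    warning("skipping species with a single promoter: ",
            paste(singles, collapse = ", "))
  p <- p[p$species %in% names(tab)[tab >= 2], , drop = FALSE]
  if (nrow(p) < 2)
    stop("corpus needs at least one species with >= 2 promoters")
  by_species <- split(seq_len(nrow(p)), p$species)

  env <- new.env(parent = emptyenv())
  old <- local_seed(seed)
  env$rng_state <- get(".Random.seed", envir = globalenv())
  restore_seed(old)

  next_batch <- function() {
    outer <- if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      get(".Random.seed", envir = globalenv()) else NULL
    assign(".Random.seed", env$rng_state, envir = globalenv())
    batch <- vector("list", batch_size)
    for (i in seq_len(batch_size)) {
      bi <- seq_len(nrow(p))[runif_int(1L, nrow(p))]
      sp <- by_species[[p$species[bi]]]
      ai <- bi
      while (ai == bi) ai <- sp[runif_int(1L, length(sp))]
      batch[[i]] <- make_sample(p[bi, ], p[ai, ], config)
    }
    env$rng_state <- get(".Random.seed", envir = globalenv())
    restore_seed(outer)
    batch
  }
  structure(list(next_batch = next_batch, batch_size = batch_size,
                 config = config), class = "sample_stream")
}

#' Serialize training samples to JSON lines
#'
#' One JSON object per line; the label is stored as its run-length interval
#' (`rewrite_window`), not as a 400-element vector.
#'
#' @param samples List of `training_sample`s.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_samples_jsonl <- function(samples, path) {
  con <- file(path, "w")
  on.exit(close(con))
  for (s in samples) {
    rec <- unclass(s)
    writeLines(jsonlite::toJSON(rec, auto_unbox = TRUE, digits = NA), con)
  }
  invisible(path)
}

#' Read training samples from JSON lines
#'
#' @param path Path written by [write_samples_jsonl()].
#' @return List of `training_sample`s.
#' @export
read_samples_jsonl <- function(path) {
  lines <- readLines(path)
  lapply(lines, function(l) {
    rec <- jsonlite::fromJSON(l)
    rec$rewrite_window <- as.integer(rec$rewrite_window)
    rec$disruption_windows <- if (length(rec$disruption_windows))
      lapply(seq_len(nrow(rec$disruption_windows)), function(i)
        as.integer(rec$disruption_windows[i, ])) else list()
    structure(rec, class = "training_sample")
  })
}
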