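PROMOTER_ALPHABET <- c("A", "C", "G", "T", "N")

#' Construct a promoter corpus
#'
#' A promoter corpus is an ordered collection of fixed-length promoter
#' sequences (by default the 400 bp immediately upstream of a gene's start
#' codon on the coding strand) with provenance and optional core-element
#' annotations, stored as a data frame with columns `promoter_id`, `species`,
#' `sequence`, `tata_pos`, `tss_pos` (0-based offsets or NA) and `upstream`
#' (extra 5' genomic context used for length compensation during training
#' sample generation, or NA).
#'
#' @param promoters Data frame with at least `promoter_id`, `species`,
#'   `sequence`; missing optional columns are added as NA.
#' @param promoter_length Expected sequence length (default 400).
#' @param split_label One of "train", "validation", "test", "unsplit".
#' @return An object of class `promoter_corpus`.
#' @export
promoter_corpus <- function(promoters, promoter_length = 400L,
                            split_label = "unsplit") {
  stopifnot(is.data.frame(promoters),
            all(c("promoter_id", "species", "sequence") %in% names(promoters)))
  split_label <- match.arg(split_label,
                           c("train", "validation", "test", "unsplit"))
  for (col in c("tata_pos", "tss_pos")) {
    if (is.null(promoters[[col]]))
      promoters[[col]] <- rep(NA_integer_, nrow(promoters))
  }
  if (is.null(promoters$upstream))
    promoters$upstream <- rep(NA_character_, nrow(promoters))
  promoters$sequence <- toupper(promoters$sequence)
  if (anyDuplicated(promoters$promoter_id))
    stop("promoter_ids must be unique within a corpus")
  if (nrow(promoters) > 0) {
    lens <- nchar(promoters$sequence)
    if (any(lens != promoter_length))
      stop("all promoter sequences must have length ", promoter_length)
    bad <- grepl(paste0("[^", paste(PROMOTER_ALPHABET, collapse = ""), "]"),
                 promoters$sequence)
    if (any(bad))
      stop("promoter sequence contains characters outside {A,C,G,T,N}: ",
           promoters$promoter_id[which(bad)[1]])
    for (col in c("tata_pos", "tss_pos")) {
      v <- promoters[[col]]
      if (any(!is.na(v) & (v < 0 | v >= promoter_length)))
        stop(col, " must lie in [0, promoter_length)")
    }
  }
  rownames(promoters) <- NULL
  structure(list(promoters = promoters,
                 promoter_length = as.integer(promoter_length),
                 split_label = split_label),
            class = "promoter_corpus")
}

#' @export
print.promoter_corpus <- function(x, ...) {
  cat(sprintf("promoter_corpus: %d promoters of %d bp (%s)\n",
              nrow(x$promoters), x$promoter_length, x$split_label))
  tab <- table(x$promoters$species)
  for (s in names(tab)) cat(sprintf("  %s: %d\n", s, tab[[s]]))
  invisible(x)
}

#' @export
length.promoter_corpus <- function(x) nrow(x$promoters)

#' Extract promoter sequences from a genome and gene annotations
#'
#' For each annotated gene, takes the `promoter_length` bases immediately
#' upstream of the start codon on the coding strand (reverse-complemented for
#' minus-strand genes). A gene is retained only if (i) its upstream window,
#' further extended upstream by `min_separation` bases, does not overlap any
#' other annotated gene body on the same contig, and (ii) the window (plus
#' any requested `pad`) lies fully inside the contig. Promoters with more
#' than `max_n_frac` ambiguous (N) bases are dropped.
#'
#' @param genome Named character vector of contig sequences, or a
#'   `Biostrings::DNAStringSet` as returned by [read_genome_fasta()].
#' @param annotations Data frame of gene records with columns `gene_id`,
#'   `contig`, `start`, `end` (1-based inclusive), `strand` ("+"/"-"), and
#'   optionally `species`.
#' @param promoter_length Promoter window size in bp (default 400).
#' @param min_separation Required upstream clearance from the nearest
#'   neighboring gene body, in bp (default 100).
#' @param pad Extra upstream context to record per promoter (default 0); the
#'   pad is stored in the `upstream` field and used by the training-sample
#'   generator for 5' length compensation. Genes without room for the pad
#'   are dropped like genes without room for the window itself.
#' @param species Species label applied to all extracted promoters when the
#'   annotation table has no `species` column.
#' @param max_n_frac Maximum tolerated fraction of N bases (default 0.1).
#' @return A `promoter_corpus`; promoter ids are the gene ids.
#' @export
extract_promoters <- function(genome, annotations, promoter_length = 400L,
                              min_separation = 100L, pad = 0L,
                              species = "unknown", max_n_frac = 0.1) {
  if (inherits(genome, "DNAStringSet")) {
    genome <- stats::setNames(as.character(genome), names(genome))
  }
  stopifnot(is.character(genome), !is.null(names(genome)))
  genome <- toupper(genome)
  ann <- as.data.frame(annotations)
  stopifnot(all(c("gene_id", "contig", "start", "end", "strand") %in% names(ann)))
  if (is.null(ann$species)) ann$species <- species
  if (any(!ann$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  bad <- ann$start > ann$end
  if (any(bad))
    stop("annotation with start > end: ", ann$gene_id[which(bad)[1]])
  unknown <- !ann$contig %in% names(genome)
  if (any(unknown))
    stop("contig '", ann$contig[which(unknown)[1]], "' for gene '",
         ann$gene_id[which(unknown)[1]], "' not present in genome")
  clens <- nchar(genome)[ann$contig]
  if (any(ann$end > clens | ann$start < 1))
    stop("annotation coordinates outside contig bounds: ",
         ann$gene_id[which(ann$end > clens | ann$start < 1)[1]])

  out <- vector("list", nrow(ann))
  for (i in seq_len(nrow(ann))) {
    g <- ann[i, ]
    clen <- nchar(genome[[g$contig]])
    if (g$strand == "+") {
      win <- c(g$start - promoter_length, g$start - 1)        # 1-based incl.
      sep_win <- c(win[1] - min_separation, win[2])
      pad_lo <- win[1] - pad
      in_contig <- pad_lo >= 1
    } else {
      win <- c(g$end + 1, g$end + promoter_length)
      sep_win <- c(win[1], win[2] + min_separation)
      in_contig <- win[2] + pad <= clen
    }
    if (!in_contig) next
    # exclusion: any OTHER gene body overlapping the extended upstream window
    others <- ann[-i, , drop = FALSE]
    others <- others[others$contig == g$contig, , drop = FALSE]
    if (nrow(others) > 0 &&
        any(others$start <= sep_win[2] & others$end >= sep_win[1])) next
    seqs <- substr(genome[[g$contig]], max(1, win[1] - pad),
                   min(clen, win[2] + pad))
    if (g$strand == "+") {
      upstream <- if (pad > 0) substr(seqs, 1, pad) else NA_character_
      promoter <- substr(seqs, pad + 1, pad + promoter_length)
    } else {
      seqs <- revcomp(seqs)
      upstream <- if (pad > 0) substr(seqs, 1, pad) else NA_character_
      promoter <- substr(seqs, pad + 1, pad + promoter_length)
    }
    if (mean(strsplit(promoter, "")[[1]] == "N") > max_n_frac) next
    out[[i]] <- data.frame(promoter_id = g$gene_id, species = g$species,
                           sequence = promoter, upstream = upstream,
                           stringsAsFactors = FALSE)
  }
  kept <- do.call(rbind, out[!vapply(out, is.null, logical(1))])
  if (is.null(kept))
    kept <- data.frame(promoter_id = character(), species = character(),
                       sequence = character(), upstream = character())
  promoter_corpus(kept, promoter_length = promoter_length)
}

#' Reverse complement of a nucleotide string
#'
#' Uppercase reverse complement over the \{A,C,G,T,N\} alphabet.
#' @param x Single nucleotide string.
#' @return The reverse complement string.
#' @export
revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(x)))
}

#' Split a corpus into train / validation / test by species holdout
#'
#' The test set receives every promoter of the holdout species; from the
#' remainder, `n_validation` promoters are sampled without replacement
#' (seeded) into the validation set and the rest form the training set.
#'
#' @param corpus A `promoter_corpus`.
#' @param holdout_species Character vector of species reserved for testing.
#' @param n_validation Number of validation promoters.
#' @param seed Integer seed controlling the validation sample.
#' @return Named list of three `promoter_corpus` objects: `train`,
#'   `validation`, `test`.
#' @export
split_corpus <- function(corpus, holdout_species, n_validation, seed) {
  stopifnot(inherits(corpus, "promoter_corpus"))
  p <- corpus$promoters
  if (!any(p$species %in% holdout_species))
    warning("holdout species absent from corpus; test set is empty")
  is_test <- p$species %in% holdout_species
  rest_idx <- which(!is_test)
  if (n_validation >= length(rest_idx) && n_validation > 0)
    stop("n_validation must be smaller than the number of non-holdout promoters")
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  val_idx <- if (n_validation > 0) sort(sample(rest_idx, n_validation)) else integer()
  train_idx <- setdiff(rest_idx, val_idx)
  mk <- function(idx, label)
    promoter_corpus(p[idx, , drop = FALSE], corpus$promoter_length, label)
  list(train = mk(train_idx, "train"),
       validation = mk(val_idx, "validation"),
       test = mk(which(is_test), "test"))
}

#' Generate a seeded synthetic promoter corpus
#'
#' Produces i.i.d. random promoter sequences with a configurable GC content,
#' optionally planting a TATA-like element (consensus TATAWAW, W = A/T) at a
#' seeded position in the distal-to-mid region and recording a transcription
#' start site 40-120 bp downstream of it. Defaults emulate yeast promoters:
#' 400 bp windows at GC 0.38. Used as the stand-in for a real multi-species
#' corpus in tests and examples.
#'
#' @param n_promoters Number of promoters.
#' @param promoter_length Sequence length (>= 80; default 400).
#' @param gc_fraction GC content in \[0, 1\] (default 0.38).
#' @param plant_elements If TRUE (default), plant a TATA motif and TSS and
#'   record their offsets in `tata_pos` / `tss_pos`.
#' @param species Species label, recycled over promoters; pass a vector to
#'   emulate a multi-species corpus.
#' @param upstream_pad Length of extra seeded upstream context stored per
#'   promoter (default 64), so generated corpora behave like padded
#'   extractions during training-sample generation.
#' @param seed Integer seed; output is byte-for-byte reproducible.
#' @return A `promoter_corpus`.
#' @export
generate_synthetic_corpus <- function(n_promoters, promoter_length = 400L,
                                      gc_fraction = 0.38,
                                      plant_elements = TRUE,
                                      species = "synthetic",
                                      upstream_pad = 64L, seed) {
  stopifnot(gc_fraction >= 0, gc_fraction <= 1, promoter_length >= 80)
  old <- local_seed(seed)
  on.exit(restore_seed(old), add = TRUE)
  base_probs <- c(A = (1 - gc_fraction) / 2, C = gc_fraction / 2,
                  G = gc_fraction / 2, T = (1 - gc_fraction) / 2)
  rand_seq <- function(n) {
    paste(sample(names(base_probs), n, replace = TRUE, prob = base_probs),
          collapse = "")
  }
  species <- rep_len(species, n_promoters)
  rows <- vector("list", n_promoters)
  for (i in seq_len(n_promoters)) {
    s <- rand_seq(promoter_length)
    tata <- NA_integer_; tss <- NA_integer_
    if (plant_elements) {
      motif <- paste0("TATA", paste(sample(c("A", "T"), 3, replace = TRUE),
                                    collapse = ""))
      # distal-to-mid region: TATA in [10%, 60%) of the promoter, TSS
      # 40-120 bp downstream (clipped inside the sequence)
      lo <- floor(promoter_length * 0.10)
      hi <- floor(promoter_length * 0.60) - nchar(motif)
      tata <- sample(lo:hi, 1)                      # 0-based offset
      substr(s, tata + 1, tata + nchar(motif)) <- motif
      tss <- min(promoter_length - 1L,
                 tata + nchar(motif) + sample(40:120, 1))
    }
    rows[[i]] <- data.frame(
      promoter_id = sprintf("synp%05d", i), species = species[i],
      sequence = s, tata_pos = tata, tss_pos = tss,
      upstream = if (upstream_pad > 0) rand_seq(upstream_pad) else NA_character_,
      stringsAsFactors = FALSE)
  }
  promoter_corpus(do.call(rbind, rows), promoter_length = promoter_length)
}
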