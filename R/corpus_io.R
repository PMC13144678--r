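#' Read a genome FASTA file
#'
#' @param path Path to a (multi-)FASTA file of contigs.
#' @return Named character vector of uppercase contig sequences; names are
#'   the first whitespace-delimited token of each header.
#' @export
read_genome_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  names(x) <- sub("\\s.*$", "", names(x))
  stats::setNames(toupper(as.character(x)), names(x))
}

#' Read gene annotations from a GFF3 file
#'
#' Imports a GFF3 file and returns the gene-level records the promoter
#' extractor needs (1-based inclusive coordinates, as in the file).
#'
#' @param path Path to a GFF3 file.
#' @param feature_type Feature type to keep (default "gene").
#' @return Data frame with columns `gene_id`, `contig`, `start`, `end`,
#'   `strand`.
#' @export
read_gene_annotations <- function(path, feature_type = "gene") {
  gr <- rtracklayer::import(path, format = "gff3")
  gr <- gr[as.character(gr$type) == feature_type]
  ids <- if (!is.null(gr$ID)) as.character(gr$ID) else as.character(gr$gene_id)
  if (anyNA(ids) || is.null(ids))
    ids <- paste0("gene", seq_along(gr))
  data.frame(gene_id = ids,
             contig = as.character(GenomicRanges::seqnames(gr)),
             start = GenomicRanges::start(gr),
             end = GenomicRanges::end(gr),
             strand = as.character(GenomicRanges::strand(gr)),
             stringsAsFactors = FALSE)
}

#' Write a promoter corpus as FASTA
#'
#' Headers carry provenance and element annotations as
#' `>promoter_id species=... tata=... tss=...` (positions 0-based, `.` when
#' absent); any stored upstream pad is written as `pad=...`.
#'
#' @param corpus A `promoter_corpus`.
#' @param path Output FASTA path.
#' @return Invisibly, `path`.
#' @export
write_corpus_fasta <- function(corpus, path) {
  stopifnot(inherits(corpus, "promoter_corpus"))
  p <- corpus$promoters
  dot <- function(x) ifelse(is.na(x), ".", as.character(x))
  headers <- sprintf("%s species=%s tata=%s tss=%s pad=%s",
                     p$promoter_id, p$species, dot(p$tata_pos),
                     dot(p$tss_pos), dot(p$upstream))
  x <- Biostrings::DNAStringSet(p$sequence)
  names(x) <- headers
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Read a promoter corpus from FASTA
#'
#' Reads FASTA written by [write_corpus_fasta()] (or any FASTA of equal
#' length promoters; header key=value fields are optional).
#'
#' @param path FASTA path.
#' @param promoter_length Expected promoter length; defaults to the length
#'   of the first sequence.
#' @return A `promoter_corpus`.
#' @export
read_corpus_fasta <- function(path, promoter_length = NULL) {
  x <- Biostrings::readDNAStringSet(path)
  if (length(x) == 0) stop("empty promoter FASTA: ", path)
  headers <- names(x)
  ids <- sub("\\s.*$", "", headers)
  field <- function(key) {
    m <- regmatches(headers, regexpr(paste0(key, "=\\S+"), headers))
    vals <- rep(NA_character_, length(headers))
    has <- grepl(paste0(key, "="), headers)
    vals[has] <- sub(paste0(key, "="), "", m)
    vals[vals == "."] <- NA_character_
    vals
  }
  int_field <- function(key) suppressWarnings(as.integer(field(key)))
  sp <- field("species"); sp[is.na(sp)] <- "unknown"
  if (is.null(promoter_length)) promoter_length <- Biostrings::width(x)[1]
  promoter_corpus(data.frame(
    promoter_id = ids, species = sp,
    sequence = toupper(as.character(x)),
    tata_pos = int_field("tata"), tss_pos = int_field("tss"),
    upstream = field("pad"), stringsAsFactors = FALSE),
    promoter_length = promoter_length)
}

#' Write a corpus manifest as TSV
#'
#' One row per promoter: id, species, length, element offsets, GC fraction.
#'
#' @param corpus A `promoter_corpus`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_corpus_manifest <- function(corpus, path) {
  p <- corpus$promoters
  gc <- vapply(strsplit(p$sequence, ""), function(s)
    mean(s %in% c("G", "C")), numeric(1))
  m <- data.frame(promoter_id = p$promoter_id, species = p$species,
                  length = nchar(p$sequence), tata_pos = p$tata_pos,
                  tss_pos = p$tss_pos, gc = round(gc, 4))
  utils::write.table(m, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Attach TATA/TSS annotations from a BED file
#'
#' BED records use the promoter id as the chromosome and 0-based half-open
#' coordinates within the promoter; the feature name column must be "TATA"
#' or "TSS" (case-insensitive). The element's start offset is recorded.
#'
#' @param corpus A `promoter_corpus`.
#' @param path BED file path.
#' @return The corpus with `tata_pos`/`tss_pos` filled in.
#' @export
add_element_annotations <- function(corpus, path) {
  stopifnot(inherits(corpus, "promoter_corpus"))
  bed <- rtracklayer::import(path, format = "bed")
  ids <- as.character(GenomicRanges::seqnames(bed))
  starts <- GenomicRanges::start(bed) - 1L   # back to 0-based
  kinds <- toupper(as.character(bed$name))
  p <- corpus$promoters
  for (i in seq_along(bed)) {
    j <- match(ids[i], p$promoter_id)
    if (is.na(j)) next
    if (kinds[i] == "TATA") p$tata_pos[j] <- starts[i]
    if (kinds[i] == "TSS") p$tss_pos[j] <- starts[i]
  }
  promoter_corpus(p, corpus$promoter_length, corpus$split_label)
}
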