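#' A transcription-factor binding site query
#'
#' @param name TFBS name (e.g. "tetO", "mig1O").
#' @param sequence 8-64 bp nucleotide string over \{A,C,G,T\}.
#' @return An object of class `tfbs_query`.
#' @export
#' @examples
#' tfbs_tetO <- tfbs_query("tetO",
#'   "TCCCTATCAGTGATAGAGATCTCCCTATCAGTGATAGAGA")
#' tfbs_mig1O <- tfbs_query("mig1O", "GTATTAAACCCGGGGTA")
tfbs_query <- function(name, sequence) {
  sequence <- toupper(sequence)
  n <- nchar(sequence)
  if (n < 8 || n > 64)
    stop("TFBS length must be in [8, 64]; got ", n)
  if (grepl("[^ACGT]", sequence))
    stop("TFBS sequence must be over {A,C,G,T}")
  structure(list(name = name, sequence = sequence), class = "tfbs_query")
}

#' Promoter-relative display coordinates
#'
#' Maps a 0-based half-open window within the promoter to coordinates
#' relative to the start codon: position p maps to p - promoter_length, so
#' the window \[123, 163) of a 400 bp promoter displays as (-277, -237).
#' The second coordinate is the half-open (exclusive) bound; outputs note
#' that the last included base is `end - 1`.
#'
#' @param window 0-based half-open interval within the promoter.
#' @param promoter_length Promoter length (default 400).
#' @return Integer vector `c(start, end)` of signed coordinates.
#' @export
to_display_coords <- function(window, promoter_length = 400L) {
  stopifnot(length(window) == 2L, window[1] >= 0, window[2] <= promoter_length)
  as.integer(window - promoter_length)
}

#' Does a proposed rewrite disrupt an annotated core element?
#'
#' TRUE when the rewrite window overlaps the promoter's annotated TATA-box
#' (modelled as the 8 bp window starting at `tata_pos`) or transcription
#' start site (the single base at `tss_pos`). Promoters without annotations
#' never trigger the filter.
#'
#' @param proposal A `proposal` (or any list with a `rewrite_window`).
#' @param promoter One-row promoter record with optional `tata_pos`,
#'   `tss_pos` (0-based offsets).
#' @return Logical; TRUE = disrupts an essential element.
#' @export
element_disruption_filter <- function(proposal, promoter) {
  promoter <- as.list(promoter)
  w <- proposal$rewrite_window
  overlaps <- function(a, b) w[1] < b && w[2] > a
  tata <- promoter$tata_pos
  if (!is.null(tata) && !is.na(tata) && overlaps(tata, tata + 8L)) return(TRUE)
  tss <- promoter$tss_pos
  if (!is.null(tss) && !is.na(tss) && overlaps(tss, tss + 1L)) return(TRUE)
  FALSE
}

# ensemble-consensus decision from precomputed member outputs; exposed
# separately from recombine() so boundary behavior (6 vs 7 matches) is
# testable with constructed outputs
consensus_decision <- function(member_outputs, consensus_min = 7L) {
  msrl_avg <- rowMeans(vapply(member_outputs, function(o) o$msrl_probs,
                              numeric(2)))
  region_avg <- rowMeans(vapply(member_outputs, function(o) o$region_probs,
                                numeric(length(member_outputs[[1]]$region_probs))))
  n_match <- sum(vapply(member_outputs, function(o) isTRUE(o$match),
                        logical(1)))
  list(msrl_selected = c(5L, 40L)[which.max(msrl_avg)],
       region_selected = which.max(region_avg),
       msrl_probs = msrl_avg, region_probs = region_avg,
       n_match = n_match,
       consensus = n_match >= consensus_min)
}

#' Virtually recombine a TFBS into a wild-type promoter
#'
#' The full inference path of the two-stage system: the promoter/TFBS pair
#' is run through the four Place-Back models; every Determiner ensemble
#' member classifies the stacked curves and reports a Match; the primary
#' decision (rewrite length and region) is the argmax of the
#' ensemble-averaged head probabilities. The rewrite window of the selected
#' MSRL length is centered on the argmax of the averaged selected-MSRL
#' curves within the selected region (clipped to the promoter), and the
#' rewritten sequence replaces that window with the TFBS. A proposal is
#' `recommended` when at least `consensus_min` of the members Match and no
#' element-disruption filter fires.
#'
#' @param promoter One-row promoter record (e.g. `corpus$promoters[i, ]`)
#'   in wild-type form.
#' @param tfbs A [tfbs_query()].
#' @param placebacks List of four `placeback_model`s, MSRL pattern
#'   (5, 5, 40, 40).
#' @param ensemble A [build_determiner_ensemble()] result.
#' @param peak_threshold Match peak threshold (default 0.5).
#' @param consensus_min Minimum Matches for a recommendation (default 7).
#' @return An object of class `proposal`.
#' @export
recombine <- function(promoter, tfbs, placebacks, ensemble,
                      peak_threshold = 0.5, consensus_min = 7L) {
  promoter <- as.list(promoter)
  stopifnot(inherits(tfbs, "tfbs_query"),
            inherits(ensemble, "determiner_ensemble"))
  check_placeback_pattern(placebacks)
  P <- nchar(promoter$sequence)
  curves <- lapply(placebacks, function(m)
    predict_placeback(m, promoter$sequence, tfbs$sequence))
  stack <- curve_stack(curves, promoter_id = promoter$promoter_id,
                       query = tfbs$sequence)
  outputs <- lapply(ensemble$members, function(m)
    predict_determiner(m, stack, peak_threshold))
  dec <- consensus_decision(outputs, consensus_min)
  msrl <- dec$msrl_selected
  bin_width <- P %/% length(dec$region_probs)
  cols <- ((dec$region_selected - 1L) * bin_width + 1L):
    (dec$region_selected * bin_width)
  sel <- which(stack$msrl_order == msrl)
  avg_curve <- colMeans(stack$curves[sel, , drop = FALSE])
  peak_pos <- cols[which.max(avg_curve[cols])] - 1L      # 0-based
  start <- min(max(peak_pos - msrl %/% 2L, 0L), P - msrl)
  rewrite_window <- c(start, start + msrl)
  rewritten <- paste0(substr(promoter$sequence, 1L, start),
                      tfbs$sequence,
                      substr(promoter$sequence, start + msrl + 1L, P))
  prop <- structure(list(
    promoter_id = promoter$promoter_id,
    tfbs_name = tfbs$name, tfbs_sequence = tfbs$sequence,
    msrl_selected = msrl,
    region_selected = dec$region_selected,
    rewrite_window = as.integer(rewrite_window),
    display_window = to_display_coords(rewrite_window, P),
    n_match = dec$n_match,
    mean_peak = max(avg_curve[cols]),
    rewritten_sequence = rewritten,
    filter_flags = character(0),
    recommended = FALSE), class = "proposal")
  if (dec$n_match < consensus_min)
    prop$filter_flags <- c(prop$filter_flags, "no_consensus")
  if (element_disruption_filter(prop, promoter))
    prop$filter_flags <- c(prop$filter_flags, "element_disruption")
  prop$recommended <- length(prop$filter_flags) == 0L
  prop
}

#' @export
print.proposal <- function(x, ...) {
  cat(sprintf("proposal: %s into %s | MSRL %d bp, region %d, window %d..%d (last base %d)\n",
              x$tfbs_name, x$promoter_id, x$msrl_selected, x$region_selected,
              x$display_window[1], x$display_window[2], x$display_window[2] - 1L))
  cat(sprintf("  matches %d/10, mean peak %.3f, %s%s\n", x$n_match,
              x$mean_peak,
              if (x$recommended) "recommended" else "filtered",
              if (length(x$filter_flags))
                paste0(" [", paste(x$filter_flags, collapse = ","), "]")
              else ""))
  invisible(x)
}

#' Screen a promoter corpus against one TFBS
#'
#' Runs [recombine()] on every promoter and returns the proposals as a
#' ranked table: recommended proposals first, ordered by descending number
#' of Matches, then descending mean peak, then promoter id. A pure function
#' of (corpus order, models, config): rerunning yields identical results.
#'
#' @param corpus A `promoter_corpus` of wild-type promoters.
#' @param tfbs A [tfbs_query()].
#' @param placebacks List of four `placeback_model`s (MSRL 5, 5, 40, 40).
#' @param ensemble A `determiner_ensemble`.
#' @param peak_threshold,consensus_min Passed to [recombine()].
#' @return A `screening_result`: list with `table` (one row per promoter),
#'   `proposals` (the full objects, in table order), and `summary` (counts
#'   of recommended/filtered and of 5 vs 40 bp assignments).
#' @export
screen_corpus <- function(corpus, tfbs, placebacks, ensemble,
                          peak_threshold = 0.5, consensus_min = 7L) {
  stopifnot(inherits(corpus, "promoter_corpus"))
  props <- lapply(seq_len(nrow(corpus$promoters)), function(i)
    recombine(corpus$promoters[i, ], tfbs, placebacks, ensemble,
              peak_threshold, consensus_min))
  tab <- do.call(rbind, lapply(props, function(p) data.frame(
    promoter_id = p$promoter_id, tfbs = p$tfbs_name,
    msrl = p$msrl_selected, region = p$region_selected,
    display_start = p$display_window[1], display_end = p$display_window[2],
    n_match = p$n_match, mean_peak = p$mean_peak,
    recommended = p$recommended,
    flags = paste(p$filter_flags, collapse = ","),
    stringsAsFactors = FALSE)))
  ord <- order(!tab$recommended, -tab$n_match, -tab$mean_peak,
               tab$promoter_id)
  tab <- tab[ord, , drop = FALSE]
  rownames(tab) <- NULL
  props <- props[ord]
  structure(list(
    table = tab, proposals = props,
    summary = c(n_promoters = nrow(tab),
                n_recommended = sum(tab$recommended),
                n_filtered = sum(!tab$recommended),
                n_msrl5 = sum(tab$msrl == 5 & tab$recommended),
                n_msrl40 = sum(tab$msrl == 40 & tab$recommended))),
    class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  s <- x$summary
  cat(sprintf(paste0("screening_result: %d promoters screened; %d recommended",
                     " (%d with 5 bp rewrite, %d with 40 bp), %d filtered\n"),
              s["n_promoters"], s["n_recommended"], s["n_msrl5"],
              s["n_msrl40"], s["n_filtered"]))
  print(utils::head(x$table, 10))
  invisible(x)
}

#' Write screening proposals as TSV
#'
#' Byte-identical across reruns with the same models and corpus. Window
#' coordinates are relative to the start codon; the `display_end` column
#' is the half-open bound (last rewritten base is `display_end - 1`).
#'
#' @param result A `screening_result`.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_proposals_tsv <- function(result, path) {
  tab <- result$table
  tab$mean_peak <- sprintf("%.6f", tab$mean_peak)
  utils::write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write rewritten promoter sequences as FASTA
#'
#' @param result A `screening_result`.
#' @param path Output FASTA path.
#' @param recommended_only Keep only recommended proposals (default TRUE).
#' @return Invisibly, `path`.
#' @export
write_rewritten_fasta <- function(result, path, recommended_only = TRUE) {
  props <- result$proposals
  if (recommended_only)
    props <- Filter(function(p) p$recommended, props)
  seqs <- vapply(props, function(p) p$rewritten_sequence, character(1))
  ids <- vapply(props, function(p)
    sprintf("%s_%s msrl=%d window=%d..%d", p$promoter_id, p$tfbs_name,
            p$msrl_selected, p$display_window[1], p$display_window[2]),
    character(1))
  x <- Biostrings::DNAStringSet(seqs)
  names(x) <- ids
  Biostrings::writeXStringSet(x, path, width = 80L)
  invisible(path)
}

#' Per-promoter curve tracks as a bedGraph-like TSV
#'
#' Writes the four Place-Back curves for one promoter/TFBS pair in long
#' format (`promoter_id`, `model`, `msrl`, `pos`, `prob`) for plotting.
#'
#' @param promoter One-row promoter record.
#' @param tfbs A [tfbs_query()].
#' @param placebacks List of four `placeback_model`s.
#' @param path Output TSV path.
#' @return Invisibly, `path`.
#' @export
write_curve_tracks <- function(promoter, tfbs, placebacks, path) {
  promoter <- as.list(promoter)
  check_placeback_pattern(placebacks)
  rows <- lapply(placebacks, function(m) {
    cu <- predict_placeback(m, promoter$sequence, tfbs$sequence)
    data.frame(promoter_id = promoter$promoter_id, model = cu$model_id,
               msrl = cu$msrl, pos = seq_along(cu$probs) - 1L,
               prob = sprintf("%.6f", cu$probs))
  })
  utils::write.table(do.call(rbind, rows), path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
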