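#' Luciferase metrics for tetO promoter validation assays
#'
#' Computes the four reporter-assay metrics used to characterise a synthetic
#' tetO-containing promoter regulated by TetR, from relative light unit (RLU)
#' measurements of a NanoLuc reporter. Conditions are coded by doxycycline
#' (DOX, releases TetR from tetO: +DOX = ON state) and by whether the strain
#' expresses TetR.
#'
#' The doxycycline burden factor
#' `delta = RLU_syn(-DOX,-TetR) / RLU_syn(+DOX,-TetR)` corrects for
#' physiological effects of the drug in strains lacking the repressor.
#' Fold induction is the delta-corrected ON/OFF ratio in the +TetR strain,
#' repression rate is `1 - (OFF/ON)/delta`, and disruption rate compares the
#' uninduced synthetic promoter with its wild-type parent,
#' `1 - RLU_syn(-DOX,-TetR) / RLU_wt(-DOX,-TetR)`. By construction
#' `repression_rate == 1 - 1/fold_induction` exactly; `identity_residual`
#' reports the (always zero up to floating point) residual of that identity
#' so that rounding inconsistencies in externally reported pairs are visible.
#'
#' @param record A list or one-row data.frame with nonnegative fields
#'   `rlu_syn_plusDOX_plusTetR`, `rlu_syn_minusDOX_plusTetR`,
#'   `rlu_syn_plusDOX_minusTetR`, `rlu_syn_minusDOX_minusTetR`, and
#'   (for the disruption rate) `rlu_wt_minusDOX_minusTetR`. The two -TetR
#'   control fields may be omitted, in which case `delta` defaults to 1 with
#'   a warning and `disruption_rate` is `NA`.
#' @return A list with `delta`, `fold_induction`, `repression_rate`,
#'   `disruption_rate`, and `identity_residual`.
#' @export
#' @examples
#' # delta = 1 controls; ON = 100, OFF = 50 -> 2-fold induction, 50% repression
#' tet_metrics(list(
#'   rlu_syn_plusDOX_plusTetR = 100, rlu_syn_minusDOX_plusTetR = 50,
#'   rlu_syn_plusDOX_minusTetR = 80, rlu_syn_minusDOX_minusTetR = 80,
#'   rlu_wt_minusDOX_minusTetR = 100))
tet_metrics <- function(record) {
  record <- as.list(record)
  need <- c("rlu_syn_plusDOX_plusTetR", "rlu_syn_minusDOX_plusTetR")
  missing_core <- setdiff(need, names(record))
  if (length(missing_core))
    stop("missing required RLU fields: ", paste(missing_core, collapse = ", "))
  has_ctrl <- all(c("rlu_syn_plusDOX_minusTetR", "rlu_syn_minusDOX_minusTetR")
                  %in% names(record))
  for (f in intersect(names(record), c(need, "rlu_syn_plusDOX_minusTetR",
                                       "rlu_syn_minusDOX_minusTetR",
                                       "rlu_wt_minusDOX_minusTetR"))) {
    v <- record[[f]]
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v < 0)
      stop("RLU field '", f, "' must be a single nonnegative number")
  }
  if (has_ctrl) {
    if (record$rlu_syn_plusDOX_minusTetR == 0)
      stop("zero denominator in field 'rlu_syn_plusDOX_minusTetR'")
    delta <- record$rlu_syn_minusDOX_minusTetR / record$rlu_syn_plusDOX_minusTetR
  } else {
    warning("-TetR control measurements absent; using delta = 1")
    delta <- 1
  }
  if (record$rlu_syn_minusDOX_plusTetR == 0)
    stop("zero denominator in field 'rlu_syn_minusDOX_plusTetR'")
  fold_induction <- record$rlu_syn_plusDOX_plusTetR /
    record$rlu_syn_minusDOX_plusTetR * delta
  if (record$rlu_syn_plusDOX_plusTetR == 0)
    stop("zero denominator in field 'rlu_syn_plusDOX_plusTetR'")
  if (delta == 0) stop("zero correction factor delta")
  repression_rate <- 1 - (record$rlu_syn_minusDOX_plusTetR /
                            record$rlu_syn_plusDOX_plusTetR) / delta
  disruption_rate <- NA_real_
  if (!is.null(record$rlu_wt_minusDOX_minusTetR) && has_ctrl) {
    if (record$rlu_wt_minusDOX_minusTetR == 0)
      stop("zero denominator in field 'rlu_wt_minusDOX_minusTetR'")
    disruption_rate <- 1 - record$rlu_syn_minusDOX_minusTetR /
      record$rlu_wt_minusDOX_minusTetR
  }
  list(delta = delta,
       fold_induction = fold_induction,
       repression_rate = repression_rate,
       disruption_rate = disruption_rate,
       identity_residual = repression_rate - (1 - 1 / fold_induction))
}

#' Relative promoter activity
#'
#' Ratio of the synthetic promoter's reporter signal to the wild-type
#' promoter's signal under the same condition (e.g. a mig1O-carrying promoter
#' versus its parent in glucose or galactose).
#'
#' @param rlu_syn RLU of the synthetic promoter strain (nonnegative).
#' @param rlu_wt RLU of the wild-type promoter strain (positive).
#' @return `rlu_syn / rlu_wt` as a proportion.
#' @export
relative_activity <- function(rlu_syn, rlu_wt) {
  stopifnot(is.numeric(rlu_syn), is.numeric(rlu_wt), rlu_syn >= 0)
  if (any(rlu_wt == 0)) stop("zero denominator in field 'rlu_wt'")
  rlu_syn / rlu_wt
}

#' Relative maximum cell density
#'
#' Ratio of the maximum optical density reached by the strain carrying the
#' synthetic promoter to that of the wild-type strain, the growth-based
#' readout for conditional repression of an essential gene.
#'
#' @param record List or one-row data.frame with fields `max_od_syn` (>= 0)
#'   and `max_od_wt` (> 0).
#' @return `max_od_syn / max_od_wt` as a proportion.
#' @export
relative_max_density <- function(record) {
  record <- as.list(record)
  stopifnot(is.numeric(record$max_od_syn), record$max_od_syn >= 0)
  if (is.null(record$max_od_wt) || record$max_od_wt == 0)
    stop("zero denominator in field 'max_od_wt'")
  record$max_od_syn / record$max_od_wt
}

#' Per-replicate tetO metrics from a long-format assay table
#'
#' Computes [tet_metrics()] for each (promoter, replicate) group of a
#' long-format plate table and summarises across replicates as mean and sd.
#'
#' @param df Data frame with columns `promoter`, `replicate`, `dox`
#'   (logical or "+"/"-"), `tetr` (logical or "+"/"-"), `promoter_type`
#'   ("syn" or "wt"), and `rlu`.
#' @return A data frame with one row per promoter: mean and sd of each
#'   metric across replicates, plus `n_replicates`.
#' @export
tet_metrics_table <- function(df) {
  stopifnot(all(c("promoter", "replicate", "dox", "tetr", "promoter_type",
                  "rlu") %in% names(df)))
  as_pm <- function(x) {
    if (is.logical(x)) x else x %in% c("+", "plus", "TRUE", "true", "1")
  }
  df$dox <- as_pm(df$dox)
  df$tetr <- as_pm(df$tetr)
  field_of <- function(type, dox, tetr) {
    sprintf("rlu_%s_%sDOX_%sTetR", type,
            ifelse(dox, "plus", "minus"), ifelse(tetr, "plus", "minus"))
  }
  df$field <- field_of(df$promoter_type, df$dox, df$tetr)
  out <- list()
  for (p in unique(df$promoter)) {
    dp <- df[df$promoter == p, ]
    reps <- sort(unique(dp$replicate))
    ms <- lapply(reps, function(r) {
      dr <- dp[dp$replicate == r, ]
      rec <- stats::setNames(as.list(dr$rlu), dr$field)
      tet_metrics(rec)
    })
    g <- function(name) vapply(ms, function(m) m[[name]], numeric(1))
    row <- data.frame(promoter = p, n_replicates = length(reps))
    for (name in c("delta", "fold_induction", "repression_rate",
                   "disruption_rate")) {
      v <- g(name)
      row[[paste0(name, "_mean")]] <- mean(v)
      row[[paste0(name, "_sd")]] <- if (length(v) > 1) stats::sd(v) else NA_real_
    }
    out[[p]] <- row
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
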