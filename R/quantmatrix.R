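REPORTER_COLS <- paste0("reporter_", 1:10)

check_psm <- function(psm) {
  stopifnot(all(c("peptide_id", "modified_sequence", "protein_id",
                  "fraction_id", "charge", "ptm_probability",
                  REPORTER_COLS) %in% names(psm)))
  if (any(psm$ptm_probability < 0 | psm$ptm_probability > 1))
    stop("ptm_probability outside [0, 1]")
  if (any(!nzchar(psm$fraction_id))) stop("empty fraction_id")
  if (any(as.matrix(psm[REPORTER_COLS]) < 0, na.rm = TRUE))
    stop("negative reporter intensity")
  invisible(psm)
}

#' Average duplicate PSMs within each sample fraction
#'
#' The intensities of peptides with more than one observation within a
#' single sample fraction are averaged (arithmetic mean per channel), so
#' the result has at most one row per (peptide, fraction). Idempotent.
#'
#' @param psm A `psm_table` data frame.
#' @return `psm_table` with one row per (peptide, fraction) and an
#'   `n_psms` column counting the averaged observations; attribute
#'   `fraction_averaged` set.
#' @export
average_within_fraction <- function(psm) {
  check_psm(psm)
  key <- paste(psm$peptide_id, psm$fraction_id, sep = "\r")
  idx <- split(seq_len(nrow(psm)), key)
  rows <- lapply(idx, function(i) {
    first <- psm[i[1], , drop = FALSE]
    first[REPORTER_COLS] <- as.list(colMeans(
      as.matrix(psm[i, REPORTER_COLS, drop = FALSE])))
    first$n_psms <- if ("n_psms" %in% names(psm)) sum(psm$n_psms[i])
                    else length(i)
    first
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$peptide_id, out$fraction_id), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "fraction_averaged") <- TRUE
  class(out) <- unique(c("psm_table", class(out)))
  out
}

#' Collapse fraction-level rows into the peptide x channel matrix
#'
#' Peptides quantified in several fractions are combined by an unweighted
#' mean of their fraction-level channel values (each fraction averaged
#' independently beforehand, avoiding reporter-ion quantification bias from
#' fraction-specific co-isolation populations). Requires
#' [average_within_fraction()] to have been applied.
#'
#' @param psm Fraction-averaged `psm_table`.
#' @return `peptide_matrix`: list with `intensity` (peptide x 10 matrix) and
#'   `meta` (protein_id, modified_sequence, site_position, n_phospho,
#'   unique_single_site, ptm_probability, n_fractions, n_psms).
#' @export
collapse_fractions <- function(psm) {
  if (!isTRUE(attr(psm, "fraction_averaged")))
    stop("apply average_within_fraction() before collapse_fractions()")
  check_psm(psm)
  idx <- split(seq_len(nrow(psm)), psm$peptide_id)
  if (any(vapply(idx, length, 0L) == 0)) stop("peptide with zero fractions")
  ids <- names(idx)
  inten <- t(vapply(idx, function(i)
    colMeans(as.matrix(psm[i, REPORTER_COLS, drop = FALSE])), numeric(10)))
  colnames(inten) <- REPORTER_COLS
  rownames(inten) <- ids
  meta <- do.call(rbind, lapply(idx, function(i) {
    r <- psm[i[1], ]
    site <- parse_phospho_sites(r$modified_sequence)
    data.frame(peptide_id = r$peptide_id, protein_id = r$protein_id,
               modified_sequence = r$modified_sequence,
               site_position = site$positions[1],
               n_phospho = site$n,
               unique_single_site = site$n == 1L,
               ptm_probability = max(psm$ptm_probability[i]),
               n_fractions = length(i),
               n_psms = if ("n_psms" %in% names(psm)) sum(psm$n_psms[i])
                        else length(i),
               stringsAsFactors = FALSE)
  }))
  rownames(meta) <- NULL
  structure(list(intensity = inten, meta = meta), class = "peptide_matrix")
}

#' Parse phospho marks from a modified peptide sequence
#'
#' Positions are 1-based indices in the stripped (unmodified) sequence of
#' the residues carrying a "(ph)" mark.
#'
#' @param modseq Modified sequence string, e.g. "VNRPS(ph)ATK".
#' @return List: `stripped` sequence, `positions`, `n`.
#' @export
parse_phospho_sites <- function(modseq) {
  stripped <- gsub("\\(ph\\)", "", modseq)
  pos <- integer(0)
  rest <- modseq
  consumed <- 0L
  while (TRUE) {
    m <- regexpr("\\(ph\\)", rest)
    if (m == -1) break
    pos <- c(pos, consumed + as.integer(m) - 1L)
    consumed <- consumed + as.integer(m) - 1L
    rest <- substr(rest, as.integer(m) + attr(m, "match.length"),
                   nchar(rest))
  }
  list(stripped = stripped, positions = pos, n = length(pos))
}

#' Filter a peptide matrix on PTM localization probability
#'
#' Removes rows below `min_prob` (the >= 75% localization gate) and flags
#' rows at or above `flag_prob` (the 0.994 probability corresponding to a 1%
#' false localization rate). Idempotent; the flag is annotation only, never
#' a filter.
#'
#' @param pm A `peptide_matrix`.
#' @param min_prob Minimum localization probability retained (default 0.75).
#' @param flag_prob FLR-flag probability (default 0.994).
#' @return Filtered `peptide_matrix` with logical `flr_flag` meta column.
#' @export
filter_localization <- function(pm, min_prob = 0.75, flag_prob = 0.994) {
  stopifnot(inherits(pm, "peptide_matrix"))
  keep <- pm$meta$ptm_probability >= min_prob
  pm$intensity <- pm$intensity[keep, , drop = FALSE]
  pm$meta <- pm$meta[keep, , drop = FALSE]
  pm$meta$flr_flag <- pm$meta$ptm_probability >= flag_prob
  rownames(pm$meta) <- NULL
  pm
}
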