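# Mapping between the MaxQuant-evidence-like TSV dialect and the internal
# column names.
PSM_TSV_NAMES <- c(
  peptide_id = "Peptide ID", modified_sequence = "Modified sequence",
  protein_id = "Leading razor protein", fraction_id = "Fraction",
  charge = "Charge", ptm_probability = "Localization prob")

#' Read / write PSM tables in a MaxQuant-evidence-like TSV dialect
#'
#' Columns: Peptide ID, Modified sequence, Leading razor protein, Fraction,
#' Charge, Localization prob, Reporter intensity 1..10. Lines starting with
#' '#' (provenance headers) are ignored on read.
#'
#' @param psm A `psm_table`.
#' @param path File path.
#' @param comment Optional character vector written as '# ' header lines.
#' @return `read_psm_tsv` returns a `psm_table`.
#' @export
write_psm_tsv <- function(psm, path, comment = NULL) {
  out <- psm[c(names(PSM_TSV_NAMES), REPORTER_COLS)]
  names(out) <- c(unname(PSM_TSV_NAMES), paste("Reporter intensity", 1:10))
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_psm_tsv
#' @export
read_psm_tsv <- function(path) {
  tab <- utils::read.delim(path, check.names = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  rep_cols <- paste("Reporter intensity", 1:10)
  stopifnot(all(c(unname(PSM_TSV_NAMES), rep_cols) %in% names(tab)))
  out <- tab[c(unname(PSM_TSV_NAMES), rep_cols)]
  names(out) <- c(names(PSM_TSV_NAMES), REPORTER_COLS)
  class(out) <- c("psm_table", class(out))
  check_psm(out)
}

#' Write a synthetic proteome as FASTA
#'
#' @param proteome `synthetic_proteome` or named character vector.
#' @param path File path.
#' @export
write_proteome_fasta <- function(proteome, path) {
  if (inherits(proteome, "synthetic_proteome")) proteome <- proteome$records
  aas <- Biostrings::AAStringSet(proteome)
  Biostrings::writeXStringSet(aas, path)
  invisible(path)
}

#' @rdname write_proteome_fasta
#' @export
read_proteome_fasta <- function(path) {
  aas <- Biostrings::readAAStringSet(path)
  stats::setNames(as.character(aas), names(aas))
}

#' Serialize / restore a truth table as JSON
#'
#' Records every generative parameter (including the implementer-chosen
#' defaults) alongside the per-peptide latent state, so a simulation is
#' fully reproducible from its truth file.
#'
#' @param truth A [gen_truth()] object.
#' @param path File path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(unclass(truth), path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  raw$fractions <- lapply(raw$fractions, as.integer)
  structure(raw, class = "truth_table")
}

#' Write / read an image stack as multi-page TIFF
#'
#' Values are stored as 32-bit float after division by `scale` (TIFF float
#' pages hold [0, 1]); pass the same scale on read to recover intensities.
#'
#' @param stack T x H x W numeric array.
#' @param path File path.
#' @param scale Intensity divisor (default the stack maximum).
#' @return `write_stack_tiff` invisibly returns the scale used.
#' @export
write_stack_tiff <- function(stack, path, scale = max(stack)) {
  pages <- lapply(seq_len(dim(stack)[1]), function(t) stack[t, , ] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  invisible(scale)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path, scale = 1) {
  pages <- tiff::readTIFF(path, all = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  out <- array(0, dim = c(length(pages), dim(pages[[1]])[1:2]))
  for (t in seq_along(pages)) out[t, , ] <- pages[[t]] * scale
  out
}

#' Write a data frame as TSV with a provenance header
#'
#' @param x Data frame.
#' @param path File path.
#' @param comment Character vector of '# ' header lines (e.g. the
#'   parameter hash).
#' @export
write_tsv_prov <- function(x, path, comment = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(comment)) writeLines(paste0("# ", comment), con)
  utils::write.table(x, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_tsv_prov
#' @export
read_tsv_prov <- function(path) {
  utils::read.delim(path, comment.char = "#", stringsAsFactors = FALSE)
}
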