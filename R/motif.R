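#' Kinase consensus-motif specification
#'
#' Represents a consensus motif around a phospho-acceptor as a set of allowed
#' residues at fixed positions relative to the acceptor (position 0).
#' The default is the R-P-X-[S/T]-[A/G/P/S] consensus: R required at -3, P at
#' -2, any residue at -1, acceptor S or T, and A/G/P/S at +1. The 'X'
#' wildcard admits all 20 residues, including P and S/T.
#'
#' @param required Named list mapping relative position (as character, e.g.
#'   "-3") to a character vector of allowed residues.
#' @param acceptor Allowed acceptor residues at position 0.
#' @param plus_one Allowed residues at position +1.
#' @return Object of class `motif_spec`.
#' @export
motif_spec <- function(required = list("-3" = "R", "-2" = "P"),
                       acceptor = c("S", "T"),
                       plus_one = c("A", "G", "P", "S")) {
  aa <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]
  chk <- function(x) length(x) > 0 && all(x %in% aa)
  stopifnot(all(vapply(required, chk, TRUE)), chk(acceptor), chk(plus_one))
  structure(list(required = required, acceptor = acceptor,
                 plus_one = plus_one), class = "motif_spec")
}

#' @export
format.motif_spec <- function(x, ...) {
  pos <- sort(as.integer(names(x$required)))
  span <- min(c(pos, 0)):1
  part <- vapply(span, function(p) {
    if (p == 0) set <- x$acceptor
    else if (p == 1) set <- x$plus_one
    else if (as.character(p) %in% names(x$required))
      set <- x$required[[as.character(p)]]
    else return("X")
    if (length(set) == 1) set else paste0("[", paste(set, collapse = ""), "]")
  }, "")
  paste(part, collapse = "-")
}

#' @export
print.motif_spec <- function(x, ...) {
  cat("consensus motif:", format(x), "\n")
  invisible(x)
}

#' Extract an acceptor-centred sequence window
#'
#' Returns the +/- `flank` residue window around a phosphosite, padding
#' beyond the protein termini with '-'. The centre residue must be S, T or Y.
#'
#' @param sequence Protein sequence string.
#' @param position 1-based acceptor residue index.
#' @param flank Residues on each side (default 7, window length 15).
#' @return List (class `site_window`): protein window string, position.
#' @export
extract_window <- function(sequence, position, flank = 7L) {
  n <- nchar(sequence)
  if (position < 1 || position > n)
    stop("position ", position, " outside sequence of length ", n)
  centre <- substr(sequence, position, position)
  if (!centre %in% c("S", "T", "Y"))
    stop("residue at position ", position, " is ", centre, ", not S/T/Y")
  idx <- (position - flank):(position + flank)
  chars <- ifelse(idx < 1 | idx > n, "-",
                  vapply(idx, function(i) substr(sequence, i, i), ""))
  structure(list(window = paste(chars, collapse = ""), position = position,
                 flank = flank), class = "site_window")
}

#' Test a site window against a consensus motif
#'
#' TRUE iff every required relative position holds an allowed residue, the
#' centre is an allowed acceptor and the +1 residue is in the allowed set.
#' Terminal padding ('-') never matches.
#'
#' @param window A `site_window` (or a plain odd-length window string).
#' @param spec A [motif_spec()].
#' @return List: match (logical), plus_one (the +1 residue, NA if padded).
#' @export
match_motif <- function(window, spec = motif_spec()) {
  w <- if (inherits(window, "site_window")) window$window else window
  stopifnot(nchar(w) %% 2 == 1)
  centre <- (nchar(w) + 1) %/% 2
  at <- function(rel) {
    i <- centre + rel
    if (i < 1 || i > nchar(w)) "-" else substr(w, i, i)
  }
  ok <- at(0) %in% spec$acceptor && at(1) %in% spec$plus_one
  for (p in names(spec$required))
    ok <- ok && at(as.integer(p)) %in% spec$required[[p]]
  list(match = ok, plus_one = if (at(1) == "-") NA_character_ else at(1))
}

#' Scan a proteome for consensus-motif phosphosites
#'
#' Slides over every S/T (or whatever the spec's acceptor set is) in every
#' sequence and reports the sites whose window matches the consensus.
#'
#' @param proteome Named character vector of sequences, a `synthetic_proteome`
#'   or a `Biostrings::AAStringSet`.
#' @param spec A [motif_spec()].
#' @param flank Window flank for the reported windows.
#' @return Data frame: protein_id, position (1-based), window, plus_one.
#' @export
scan_proteome <- function(proteome, spec = motif_spec(), flank = 7L) {
  if (inherits(proteome, "synthetic_proteome")) proteome <- proteome$records
  if (methods::is(proteome, "AAStringSet"))
    proteome <- stats::setNames(as.character(proteome), names(proteome))
  hits <- lapply(names(proteome), function(id) {
    seq <- proteome[[id]]
    pos <- which(strsplit(seq, "")[[1]] %in% spec$acceptor)
    keep <- lapply(pos, function(p) {
      w <- extract_window(seq, p, flank)
      m <- match_motif(w, spec)
      if (m$match) data.frame(protein_id = id, position = p,
                              window = w$window, plus_one = m$plus_one)
    })
    do.call(rbind, keep)
  })
  out <- do.call(rbind, hits)
  if (is.null(out))
    out <- data.frame(protein_id = character(), position = integer(),
                      window = character(), plus_one = character())
  rownames(out) <- NULL
  out
}

#' Percent-of-control quantitation for peptide kinase assays
#'
#' Normalizes Cerenkov counts of in-vitro peptide phosphorylation to the
#' wild-type control peptide, which is taken as 100%. By default the
#' kinase-dead background count is subtracted from both the peptide and the
#' control before normalization; negative values are clipped to 0 with a
#' warning.
#'
#' @param counts Data frame with columns `label`, `cpm_wt`, `cpm_kd`.
#' @param control_label Label of the control peptide (defines 100%).
#' @param subtract_kd Subtract the KD background (default TRUE).
#' @return `counts` with a `percent_of_wt` column.
#' @export
percent_of_wt <- function(counts, control_label, subtract_kd = TRUE) {
  stopifnot(control_label %in% counts$label)
  ctrl <- counts[match(control_label, counts$label), ]
  num <- if (subtract_kd) counts$cpm_wt - counts$cpm_kd else counts$cpm_wt
  den <- if (subtract_kd) ctrl$cpm_wt - ctrl$cpm_kd else ctrl$cpm_wt
  if (den <= 0) stop("control peptide has non-positive background-corrected counts")
  pct <- 100 * num / den
  if (any(pct < 0)) {
    warning(sum(pct < 0), " peptide(s) below background; clipped to 0")
    pct[pct < 0] <- 0
  }
  counts$percent_of_wt <- pct
  counts
}
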