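#' Monoisotopic mass constants
#'
#' Reads the versioned constants file shipped with the package: monoisotopic
#' residue masses for the 20 canonical amino acids plus water, proton,
#' phospho (+79.966331 Da) and TMT10 label (+229.162932 Da) masses.
#'
#' @return Named numeric vector of masses in Da.
#' @export
mass_table <- function() {
  path <- system.file("extdata", "monoisotopic_masses.tsv",
                      package = "phosphoscreen", mustWork = TRUE)
  tab <- utils::read.delim(path, stringsAsFactors = FALSE)
  stats::setNames(tab$mass_da, tab$constant)
}

#' Theoretical m/z of a labelled phosphopeptide
#'
#' Computes the monoisotopic m/z of a peptide carrying `n_phospho` phospho
#' groups and `tmt_labels` TMT10 labels at charge `charge`:
#' (sum of residue masses + water + mods + charge * proton) / charge.
#' The default labelling chemistry places one TMT on the N-terminus and one
#' on every lysine.
#'
#' @param sequence Amino-acid string (20 canonical residues).
#' @param n_phospho Number of phospho groups.
#' @param tmt_labels Number of TMT10 labels; default 1 + number of K.
#' @param charge Positive integer charge state.
#' @param masses Mass constants, see [mass_table()].
#' @return m/z in Th.
#' @export
peptide_mz <- function(sequence, n_phospho = 0L, tmt_labels = NULL,
                       charge = 2L, masses = mass_table()) {
  stopifnot(charge >= 1)
  res <- strsplit(toupper(sequence), "")[[1]]
  bad <- setdiff(res, names(masses)[1:20])
  if (length(bad) > 0)
    stop("unknown residue(s): ", paste(unique(bad), collapse = ", "))
  if (n_phospho > sum(res %in% c("S", "T", "Y")))
    stop("more phospho groups than S/T/Y residues")
  if (is.null(tmt_labels)) tmt_labels <- 1L + sum(res == "K")
  neutral <- sum(masses[res]) + masses[["water"]] +
    n_phospho * masses[["phospho"]] + tmt_labels * masses[["tmt10"]]
  (neutral + charge * masses[["proton"]]) / charge
}

#' Build a precursor inclusion list
#'
#' Enumerates all (peptide, charge) combinations whose theoretical m/z falls
#' inside the instrument scan range, deduplicated and sorted by m/z.
#'
#' @param specs Data frame with columns `sequence`, `n_phospho`, and
#'   optionally `tmt_labels` (NA = default labelling).
#' @param charges Integer vector of charge states to consider.
#' @param scan_range Length-2 numeric, inclusive m/z window (default the
#'   350-1500 full-scan range).
#' @return Data frame (sequence, n_phospho, tmt_labels, charge, mz) with mz
#'   rounded to 4 decimals in the output column `mz`.
#' @export
build_inclusion_list <- function(specs, charges = 2:4,
                                 scan_range = c(350, 1500)) {
  cols <- c("sequence", "n_phospho", "tmt_labels", "charge", "mz")
  if (nrow(specs) == 0)
    return(stats::setNames(data.frame(character(), integer(), integer(),
                                      integer(), numeric()), cols))
  out <- do.call(rbind, lapply(seq_len(nrow(specs)), function(i) {
    s <- specs[i, ]
    tmt <- if ("tmt_labels" %in% names(specs) && !is.na(s$tmt_labels))
      s$tmt_labels else 1L + sum(strsplit(s$sequence, "")[[1]] == "K")
    data.frame(sequence = s$sequence, n_phospho = s$n_phospho,
               tmt_labels = tmt, charge = charges,
               mz = vapply(charges, function(z)
                 peptide_mz(s$sequence, s$n_phospho, tmt, z), 0))
  }))
  out <- out[out$mz >= scan_range[1] & out$mz <= scan_range[2], , drop = FALSE]
  out <- unique(out)
  out <- out[order(out$mz), , drop = FALSE]
  out$mz <- round(out$mz, 4)
  rownames(out) <- NULL
  out
}

#' Collapse repeated phosphopeptide observations by channel medians
#'
#' When a phosphopeptide is identified in several PSMs, the median intensity
#' within each TMT channel is taken before statistical testing.
#'
#' @param x Numeric matrix, PSM rows x channels, for one phosphopeptide.
#' @return Numeric vector of per-channel medians.
#' @export
median_collapse <- function(x) {
  x <- as.matrix(x)
  apply(x, 2, stats::median)
}

#' Targeted per-peptide validation tests with Bonferroni threshold
#'
#' Runs a two-sample t-test per phosphopeptide row of a VSN-normalized
#' intensity matrix for one protein, comparing WT against KD channels, and
#' applies a Bonferroni-corrected significance threshold alpha / m where m is
#' the number of peptides tested (e.g. 0.0125 for m = 4, 0.00833 for m = 6).
#' Comparisons use the exact alpha / m; `alpha_per_test_printed` reports it
#' rounded to 3 significant figures as conventionally quoted.
#'
#' @param mat Numeric matrix, phosphopeptide rows x channels (glog2 scale).
#' @param design A [group_design()] assigning channels to WT / KD.
#' @param alpha Family-wise significance level (default 0.05).
#' @param var_equal Use pooled-variance t (default FALSE = Welch).
#' @return Data frame: mean_wt, mean_kd, t, p, m, alpha_per_test,
#'   alpha_per_test_printed, significant.
#' @export
targeted_test <- function(mat, design, alpha = 0.05, var_equal = FALSE) {
  mat <- as.matrix(mat)
  m <- nrow(mat)
  wt <- design$group == "WT"
  kd <- design$group == "KD"
  res <- t(apply(mat, 1, function(row) {
    tt <- stats::t.test(row[wt], row[kd], var.equal = var_equal)
    c(mean_wt = mean(row[wt]), mean_kd = mean(row[kd]),
      t = unname(tt$statistic), p = tt$p.value)
  }))
  out <- as.data.frame(res)
  out$m <- m
  out$alpha_per_test <- alpha / m
  out$alpha_per_test_printed <- signif(alpha / m, 3)
  out$significant <- out$p < out$alpha_per_test
  out
}

#' Relative expression by the ddCt method
#'
#' Fold change = 2^-((Ct_target,treated - Ct_ref,treated) -
#' (Ct_target,control - Ct_ref,control)), with the reference a housekeeping
#' gene measured in the same samples.
#'
#' @param ct_target_treated,ct_ref_treated,ct_target_control,ct_ref_control
#'   Ct values (cycles).
#' @return Fold change relative to control.
#' @export
ddct_fold_change <- function(ct_target_treated, ct_ref_treated,
                             ct_target_control, ct_ref_control) {
  ddct <- (ct_target_treated - ct_ref_treated) -
    (ct_target_control - ct_ref_control)
  2^(-ddct)
}
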