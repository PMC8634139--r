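AA20 <- strsplit("ACDEFGHIKLMNPQRSTVWY", "")[[1]]

# Per-output RNG substreams: every generator derives its own seed from the
# root seed and a stage label, so adding draws to one stage never perturbs
# another. Seeds stay below 2^31.
substream_seed <- function(seed, label) {
  (as.integer(seed) + sum(utf8ToInt(label)) * 10007L) %% .Machine$integer.max
}

#' Channel group design for a TMT10 screen
#'
#' Assigns each of the 10 reporter channels to the WT or KD group; the
#' default is the screen's 5-vs-5 biological-replicate layout.
#'
#' @param group Character vector of "WT"/"KD" per channel.
#' @return Object of class `group_design` with `group`, `n_wt`, `n_kd`.
#' @export
group_design <- function(group = c(rep("WT", 5), rep("KD", 5))) {
  stopifnot(all(group %in% c("WT", "KD")),
            sum(group == "WT") >= 1, sum(group == "KD") >= 1)
  structure(list(group = group, n_wt = sum(group == "WT"),
                 n_kd = sum(group == "KD")), class = "group_design")
}

#' Generate a synthetic proteome with planted consensus sites
#'
#' Sequences are uniform over the 20 canonical residues; with probability
#' `plant_rate` a protein receives one planted consensus site (R at -3, P at
#' -2, acceptor S or T, +1 from {A, G, P, S}) at a random interior position.
#'
#' @param n_proteins Number of proteins (>= 1).
#' @param length Residues per protein.
#' @param plant_rate Fraction of proteins receiving a planted site.
#' @param seed RNG seed.
#' @param alphabet Residue alphabet; must be canonical amino acids.
#' @return `synthetic_proteome`: `records` (named sequences) and
#'   `planted_sites` data frame (protein_id, position, motif_variant).
#' @export
gen_proteome <- function(n_proteins, length = 300L, plant_rate = 0.2,
                         seed = 1L, alphabet = AA20) {
  stopifnot(n_proteins >= 1, plant_rate >= 0, plant_rate <= 1, length >= 9)
  bad <- setdiff(alphabet, AA20)
  if (length(bad) > 0)
    stop("non-canonical residue(s) in alphabet: ", paste(bad, collapse = ", "))
  set.seed(substream_seed(seed, "proteome"))
  records <- character(n_proteins)
  names(records) <- sprintf("PROT%04d", seq_len(n_proteins))
  planted <- list()
  for (i in seq_len(n_proteins)) {
    seq <- sample(alphabet, length, replace = TRUE)
    if (stats::runif(1) < plant_rate) {
      pos <- sample(5:(length - 1), 1)
      acc <- sample(c("S", "T"), 1)
      p1 <- sample(c("A", "G", "P", "S"), 1)
      seq[pos - 3] <- "R"; seq[pos - 2] <- "P"
      seq[pos] <- acc; seq[pos + 1] <- p1
      planted[[length(planted) + 1]] <-
        data.frame(protein_id = names(records)[i], position = pos,
                   motif_variant = paste0("RPx", acc, p1))
    }
    records[i] <- paste(seq, collapse = "")
  }
  planted <- if (length(planted)) do.call(rbind, planted) else
    data.frame(protein_id = character(), position = integer(),
               motif_variant = character())
  structure(list(records = records, planted_sites = planted),
            class = "synthetic_proteome")
}

#' Ground truth for a synthetic TMT10 phospho screen
#'
#' Draws the latent state of every phosphopeptide in the simulated screen:
#' true abundance mu (lognormal), log2 WT-vs-KD effect delta (non-zero only
#' for substrates), channel calibration (additive offsets a_i, multiplicative
#' gains b_i), fraction membership, per-peptide PTM localization probability
#' (a mixture of well-localized and ambiguous components) and a multi-site
#' flag. Substrate peptides carry a consensus-motif context around the
#' phosphosite; null peptides receive a context that breaks the motif.
#' delta = 0 if and only if the peptide is not a substrate.
#'
#' @param n_peptides Number of peptides.
#' @param substrate_rate Fraction of peptides that are true substrates.
#' @param delta log2 WT-vs-KD effect for substrates.
#' @param bidirectional If TRUE half the substrate effects are negative
#'   (default FALSE: effects one-sided, WT > KD).
#' @param mu_meanlog,mu_sdlog Lognormal abundance parameters.
#' @param sigma_mult SD of multiplicative noise on the natural-log scale.
#' @param sigma_add SD of additive intensity noise.
#' @param gain_sdlog Channel gains b_i ~ lognormal(0, gain_sdlog).
#' @param offset_range Channel offsets a_i ~ U(range).
#' @param n_fractions Total fractions in the experiment.
#' @param max_fractions_per_peptide Peptides appear in 1..this many fractions.
#' @param ambiguous_share Share of peptides with localization < 0.75.
#' @param flag_shape Beta shape controlling the share >= 0.994 among
#'   well-localized peptides.
#' @param multi_site_rate Share of peptides carrying two phospho marks
#'   (non-unique site).
#' @param seed RNG seed (root; substreams derived internally).
#' @return Object of class `truth_table` (list of per-peptide data frame
#'   `peptides`, channel calibration, noise SDs, seed).
#' @export
gen_truth <- function(n_peptides = 2000L, substrate_rate = 0.05,
                      delta = 1.5, bidirectional = FALSE,
                      mu_meanlog = log(1e4), mu_sdlog = 1,
                      sigma_mult = 0.25, sigma_add = 50,
                      gain_sdlog = 0.2, offset_range = c(20, 100),
                      n_fractions = 20L, max_fractions_per_peptide = 3L,
                      ambiguous_share = 0.10, flag_shape = 21,
                      multi_site_rate = 0.15, seed = 1L) {
  stopifnot(n_peptides >= 1, substrate_rate >= 0, substrate_rate <= 1,
            sigma_mult >= 0, sigma_add >= 0)
  set.seed(substream_seed(seed, "truth"))
  n_sub <- round(n_peptides * substrate_rate)
  is_sub <- c(rep(TRUE, n_sub), rep(FALSE, n_peptides - n_sub))
  dl <- ifelse(is_sub, delta, 0)
  if (bidirectional && n_sub > 1)
    dl[seq_len(n_sub)] <- dl[seq_len(n_sub)] *
      sample(c(1, -1), n_sub, replace = TRUE)
  mu <- exp(stats::rnorm(n_peptides, mu_meanlog, mu_sdlog))
  multi <- stats::runif(n_peptides) < multi_site_rate
  ambiguous <- stats::runif(n_peptides) < ambiguous_share
  ptm <- ifelse(ambiguous,
                0.75 * stats::rbeta(n_peptides, 2, 2),
                0.75 + 0.25 * stats::rbeta(n_peptides, flag_shape, 1))
  nfr <- sample(seq_len(max_fractions_per_peptide), n_peptides, replace = TRUE)
  fractions <- lapply(nfr, function(k)
    sort(sample(seq_len(n_fractions), k)))
  seqs <- make_peptide_sequences(n_peptides, is_sub, multi)
  b <- exp(stats::rnorm(10, 0, gain_sdlog))
  a <- stats::runif(10, offset_range[1], offset_range[2])
  structure(list(
    peptides = data.frame(
      peptide_id = sprintf("PEP%05d", seq_len(n_peptides)),
      protein_id = sprintf("PROT%04d", 1 + (seq_len(n_peptides) - 1) %% 500),
      modified_sequence = seqs$modified, site_position = seqs$site,
      mu = mu, delta = dl, is_substrate = is_sub, multi_site = multi,
      ptm_probability = ptm, n_fractions = nfr,
      stringsAsFactors = FALSE),
    fractions = fractions,
    channel_offset = a, channel_gain = b,
    sigma_mult = sigma_mult, sigma_add = sigma_add,
    n_fractions = n_fractions, seed = seed), class = "truth_table")
}

# Peptide sequences with phospho marks "(ph)". Substrates get a consensus
# context (R-P-X-S/T-[AGPS]) around the marked residue; nulls get K at -3,
# which can never match. Multi-site peptides carry a second marked S.
make_peptide_sequences <- function(n, is_sub, multi) {
  modified <- character(n)
  site <- integer(n)
  for (i in seq_len(n)) {
    len <- sample(10:16, 1)
    seq <- sample(setdiff(AA20, c("S", "T", "Y")), len, replace = TRUE)
    pos <- sample(5:(len - 2), 1)
    if (is_sub[i]) {
      seq[pos - 3] <- "R"; seq[pos - 2] <- "P"
      seq[pos] <- sample(c("S", "T"), 1)
      seq[pos + 1] <- sample(c("A", "G", "P", "S"), 1)
    } else {
      seq[pos - 3] <- "K"; seq[pos - 2] <- sample(AA20, 1)
      seq[pos] <- sample(c("S", "T"), 1)
    }
    marks <- pos
    if (multi[i]) {
      free <- setdiff(which(seq == "S"), c(pos, pos + 1))
      if (length(free) == 0) { extra <- if (pos > 6) 2L else len - 1L
        seq[extra] <- "S"; free <- extra }
      marks <- sort(c(pos, free[1]))
    }
    out <- character(0)
    for (j in seq_len(len)) {
      out <- c(out, seq[j])
      if (j %in% marks) out <- c(out, "(ph)")
    }
    modified[i] <- paste(out, collapse = "")
    site[i] <- pos
  }
  list(modified = modified, site = site)
}

#' Simulate the PSM-level reporter-ion table of a TMT10 screen
#'
#' Emits one or more PSMs per (peptide, fraction) under the
#' additive-multiplicative error model: intensity for peptide k in channel i
#' is a_i + b_i * mu_k * 2^(delta_k * [i in WT] * c_f) * exp(e_mult) + e_add,
#' with e_mult ~ N(0, sigma_mult^2), e_add ~ N(0, sigma_add^2), negative
#' draws truncated at 0. c_f is an optional fraction-specific co-isolation
#' compression factor on the effect (default 1 for all fractions).
#'
#' @param truth A [gen_truth()] object.
#' @param design A [group_design()].
#' @param multiplicity Mean extra PSMs per (peptide, fraction): the count is
#'   1 + Poisson(multiplicity).
#' @param coisolation Optional numeric vector of per-fraction compression
#'   factors in (0, 1].
#' @param seed RNG seed (defaults to the truth's root seed).
#' @return `psm_table` data frame: peptide_id, modified_sequence, protein_id,
#'   fraction_id, charge, ptm_probability, reporter_1..reporter_10.
#' @export
gen_screen <- function(truth, design = group_design(), multiplicity = 0.3,
                       coisolation = NULL, seed = truth$seed) {
  stopifnot(inherits(truth, "truth_table"), length(design$group) == 10)
  if (any(truth$peptides$mu <= 0)) stop("non-positive latent abundance mu")
  if (any(truth$channel_gain <= 0)) stop("non-positive channel gain b")
  if (is.null(coisolation)) coisolation <- rep(1, truth$n_fractions)
  stopifnot(length(coisolation) == truth$n_fractions,
            all(coisolation > 0 & coisolation <= 1))
  set.seed(substream_seed(seed, "screen"))
  pep <- truth$peptides
  wt <- as.numeric(design$group == "WT")
  rows <- vector("list", nrow(pep))
  for (k in seq_len(nrow(pep))) {
    frs <- truth$fractions[[k]]
    n_psm <- 1L + stats::rpois(length(frs), multiplicity)
    fr_rep <- rep(frs, n_psm)
    m <- length(fr_rep)
    d_eff <- pep$delta[k] * coisolation[fr_rep]
    signal <- pep$mu[k] * 2^(outer(d_eff, wt))           # m x 10
    eps_m <- matrix(stats::rnorm(m * 10, 0, truth$sigma_mult), m, 10)
    eps_a <- matrix(stats::rnorm(m * 10, 0, truth$sigma_add), m, 10)
    inten <- sweep(sweep(signal * exp(eps_m), 2, truth$channel_gain, `*`),
                   2, truth$channel_offset, `+`) + eps_a
    inten[inten < 0] <- 0
    rows[[k]] <- data.frame(
      peptide_id = pep$peptide_id[k],
      modified_sequence = pep$modified_sequence[k],
      protein_id = pep$protein_id[k],
      fraction_id = sprintf("F%02d", fr_rep),
      charge = sample(2:3, m, replace = TRUE),
      ptm_probability = pep$ptm_probability[k],
      stringsAsFactors = FALSE)
    rows[[k]] <- cbind(rows[[k]],
                       stats::setNames(as.data.frame(inten),
                                       paste0("reporter_", 1:10)))
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("psm_table", class(out))
  out
}

#' Synthetic micro-irradiation time-lapse phantom
#'
#' Builds a T x H x W stack: `pre_frames` background-only frames followed by
#' frames carrying a disc of amplitude spot_amplitude * exp(-decay_rate * t)
#' above background (t = 0 at the first post-irradiation frame), plus
#' Gaussian noise.
#'
#' @param shape c(T, H, W).
#' @param spot_center c(row, col); must lie inside the frame.
#' @param spot_radius Disc radius in pixels.
#' @param spot_amplitude Peak intensity above background.
#' @param decay_rate Exponential decay per frame.
#' @param background Constant background level.
#' @param noise_sd Gaussian noise SD (0 = noiseless).
#' @param pre_frames Leading pre-irradiation frames (default 1).
#' @param seed RNG seed.
#' @return Numeric array T x H x W.
#' @export
gen_timelapse <- function(shape = c(10L, 64L, 64L), spot_center = c(32, 32),
                          spot_radius = 3, spot_amplitude = 100,
                          decay_rate = 0.3, background = 50, noise_sd = 0,
                          pre_frames = 1L, seed = 1L) {
  stopifnot(spot_center[1] >= 1, spot_center[1] <= shape[2],
            spot_center[2] >= 1, spot_center[2] <= shape[3])
  set.seed(substream_seed(seed, "timelapse"))
  disc <- disc_mask(shape[2:3], spot_center, spot_radius)
  stack <- array(background, dim = shape)
  for (t in seq_len(shape[1])) {
    fr <- matrix(background, shape[2], shape[3])
    if (t > pre_frames)
      fr[disc] <- fr[disc] + spot_amplitude * exp(-decay_rate * (t - pre_frames - 1))
    if (noise_sd > 0)
      fr <- fr + matrix(stats::rnorm(prod(shape[2:3]), 0, noise_sd),
                        shape[2], shape[3])
    stack[t, , ] <- fr
  }
  stack
}

#' Synthetic peptide kinase-assay counts
#'
#' Cerenkov-style counts: for each peptide in the panel the WT-lane count is
#' Poisson with the peptide's WT rate, and the KD lane is Poisson with a
#' common background rate.
#'
#' @param peptide_panel Data frame with columns `label` and `wt_rate`, or a
#'   named numeric vector of WT rates.
#' @param kd_rate Common KD background rate.
#' @param seed RNG seed.
#' @return Data frame: label, cpm_wt, cpm_kd.
#' @export
gen_assay <- function(peptide_panel, kd_rate = 50, seed = 1L) {
  if (is.numeric(peptide_panel))
    peptide_panel <- data.frame(label = names(peptide_panel),
                                wt_rate = unname(peptide_panel))
  set.seed(substream_seed(seed, "assay"))
  data.frame(label = peptide_panel$label,
             cpm_wt = stats::rpois(nrow(peptide_panel), peptide_panel$wt_rate),
             cpm_kd = stats::rpois(nrow(peptide_panel), kd_rate))
}

#' Synthetic GO-style annotation table
#'
#' Assigns random terms to background proteins, with a configurable set of
#' terms enriched among a given protein subset (e.g. true substrates) so
#' that over-representation analysis has signal to find.
#'
#' @param proteins Background protein ids.
#' @param enriched_in Protein subset in which `enriched_terms` are enriched.
#' @param n_terms Number of random background terms.
#' @param enriched_terms Names of enriched terms.
#' @param base_rate Background term-carriage probability.
#' @param enriched_rate Carriage probability of enriched terms inside
#'   `enriched_in`.
#' @param seed RNG seed.
#' @return Data frame: protein, term.
#' @export
gen_annotations <- function(proteins, enriched_in = character(0),
                            n_terms = 20L,
                            enriched_terms = c("transcription regulation",
                                               "chromatin organization"),
                            base_rate = 0.05, enriched_rate = 0.6,
                            seed = 1L) {
  set.seed(substream_seed(seed, "annotations"))
  terms <- c(sprintf("GO_random_%02d", seq_len(n_terms)), enriched_terms)
  rows <- lapply(terms, function(tm) {
    pr <- rep(base_rate, length(proteins))
    if (tm %in% enriched_terms)
      pr[proteins %in% enriched_in] <- enriched_rate
    sel <- stats::runif(length(proteins)) < pr
    if (any(sel)) data.frame(protein = proteins[sel], term = tm)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Synthetic PPI edge table with combined scores
#'
#' Random edges among the given proteins with integer combined scores in
#' 0-1000; a configurable share of edges among `hub_proteins` receives high
#' scores, mimicking a STRING-style network around the hits.
#'
#' @param proteins Protein ids.
#' @param n_edges Number of edges drawn.
#' @param hub_proteins Subset with elevated scores.
#' @param seed RNG seed.
#' @return Data frame: protein_a, protein_b, combined_score.
#' @export
gen_ppi <- function(proteins, n_edges = 200L, hub_proteins = character(0),
                    seed = 1L) {
  stopifnot(length(proteins) >= 2)
  set.seed(substream_seed(seed, "ppi"))
  a <- sample(proteins, n_edges, replace = TRUE)
  b <- sample(proteins, n_edges, replace = TRUE)
  keep <- a != b
  a <- a[keep]; b <- b[keep]
  hub <- a %in% hub_proteins & b %in% hub_proteins
  score <- ifelse(hub,
                  round(stats::runif(length(a), 400, 1000)),
                  round(stats::runif(length(a), 0, 700)))
  out <- unique(data.frame(protein_a = pmin(a, b), protein_b = pmax(a, b),
                           combined_score = as.integer(score)))
  rownames(out) <- NULL
  out
}
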