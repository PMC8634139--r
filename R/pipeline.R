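#' Default pipeline configuration
#'
#' All stage parameters with their screen defaults: the 5-vs-5 TMT10
#' design, the >= 0.75 localization gate with the 0.994 FLR flag, the
#' trimmed-likelihood VSN fit, robust empirical-Bayes moderation, the
#' strict p < 5e-4 WT-up hit rule, the GO rule (p <= 0.01, >= 3 proteins)
#' and the PPI score threshold 150.
#'
#' @param seed Root RNG seed.
#' @return Nested named list; serializable to YAML and back unchanged.
#' @export
default_config <- function(seed = 1L) {
  list(
    seed = as.integer(seed),
    synthdata = list(n_peptides = 2000L, substrate_rate = 0.05,
                     delta = 1.5, sigma_mult = 0.25, sigma_add = 50,
                     multiplicity = 0.3),
    aggregate = list(min_prob = 0.75, flag_prob = 0.994),
    vsn = list(trim_quantile = 0.9),
    test = list(robust = TRUE),
    hits = list(p_threshold = 5e-4, require_wt_up = TRUE),
    enrich = list(p_cutoff = 0.01, min_proteins = 3L),
    ppi = list(threshold = 150))
}

#' Validate a pipeline configuration
#'
#' Checks a config (list or YAML path) against the schema of
#' [default_config()]: unknown keys are rejected, types must match and
#' ranged parameters (probabilities, trim_quantile, thresholds) must be in
#' range. Returns a character vector of diagnostics, empty when valid.
#'
#' @param config Nested list or path to a YAML file.
#' @return Character vector of diagnostics (empty = valid).
#' @export
validate_config <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  ref <- default_config()
  diag <- character(0)
  unknown <- setdiff(names(config), names(ref))
  if (length(unknown) > 0)
    diag <- c(diag, paste("unknown key(s):", paste(unknown, collapse = ", ")))
  for (sec in intersect(names(config), names(ref))) {
    if (is.list(ref[[sec]])) {
      bad <- setdiff(names(config[[sec]]), names(ref[[sec]]))
      if (length(bad) > 0)
        diag <- c(diag, paste0("unknown key(s) in ", sec, ": ",
                               paste(bad, collapse = ", ")))
      for (k in intersect(names(config[[sec]]), names(ref[[sec]])))
        if (!is.numeric(config[[sec]][[k]]) && !is.logical(config[[sec]][[k]]))
          diag <- c(diag, paste0(sec, "$", k, ": must be numeric or logical"))
    }
  }
  num_in <- function(path, lo, hi) {
    v <- config
    for (p in path) v <- v[[p]]
    if (!is.null(v) && is.numeric(v) && (v < lo || v > hi))
      diag <<- c(diag, paste0(paste(path, collapse = "$"),
                              ": out of range [", lo, ", ", hi, "]"))
  }
  num_in(c("vsn", "trim_quantile"), 0.5, 1)
  num_in(c("aggregate", "min_prob"), 0, 1)
  num_in(c("aggregate", "flag_prob"), 0, 1)
  num_in(c("hits", "p_threshold"), 0, 1)
  num_in(c("enrich", "p_cutoff"), 0, 1)
  num_in(c("synthdata", "substrate_rate"), 0, 1)
  diag
}

merge_config <- function(config) {
  ref <- default_config()
  for (sec in names(config)) {
    if (is.list(ref[[sec]]) && is.list(config[[sec]])) {
      for (k in names(config[[sec]])) ref[[sec]][[k]] <- config[[sec]][[k]]
    } else ref[[sec]] <- config[[sec]]
  }
  ref
}

#' Run the full synthetic screen end-to-end
#'
#' Executes simulate -> aggregate -> normalize -> test -> hits -> motif ->
#' enrich and writes every stage's table plus a run manifest into
#' `out_dir`. Every output table carries the configuration hash in a '#'
#' provenance header, so re-running with an identical configuration
#' reproduces byte-identical tables. Row counts per stage (the funnel from
#' PSMs to hits) are logged and recorded in the manifest.
#'
#' @param config Nested list or YAML path; missing entries take
#'   [default_config()] values.
#' @param out_dir Output directory (created).
#' @param quiet Suppress stage logging.
#' @return Invisible list with the in-memory stage results and the
#'   manifest.
#' @export
run_pipeline <- function(config = default_config(), out_dir = "pipeline_out",
                         quiet = FALSE) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("stage config: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  diag <- validate_config(config)
  if (length(diag) > 0) stop("stage config: ", paste(diag, collapse = "; "))
  cfg <- merge_config(config)
  hash <- rlang::hash(cfg)
  prov <- paste0("param_hash=", hash)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message("[phosphoscreen] ", ...)
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e)
      stop("stage ", name, ": ", conditionMessage(e), call. = FALSE))
  }
  funnel <- list()

  # simulate
  sd <- cfg$synthdata
  truth <- stage("simulate",
    gen_truth(n_peptides = sd$n_peptides, substrate_rate = sd$substrate_rate,
              delta = sd$delta, sigma_mult = sd$sigma_mult,
              sigma_add = sd$sigma_add, seed = cfg$seed))
  design <- group_design()
  psm <- stage("simulate",
    gen_screen(truth, design, multiplicity = sd$multiplicity))
  write_truth_json(truth, file.path(out_dir, "truth.json"))
  write_psm_tsv(psm, file.path(out_dir, "psm_table.tsv"), comment = prov)
  funnel$psms <- nrow(psm)
  say("simulate: ", nrow(psm), " PSMs / ", sd$n_peptides, " peptides")

  # aggregate
  pm <- stage("aggregate", {
    collapse_fractions(average_within_fraction(psm))
  })
  funnel$peptides <- nrow(pm$intensity)
  pm <- stage("aggregate",
    filter_localization(pm, cfg$aggregate$min_prob, cfg$aggregate$flag_prob))
  funnel$localized <- nrow(pm$intensity)
  say("aggregate: ", funnel$peptides, " peptides, ", funnel$localized,
      " pass the localization gate")

  # normalize
  params <- stage("normalize", fit_vsn(pm, cfg$vsn$trim_quantile))
  tm <- stage("normalize", apply_vsn(pm, params))
  qc <- stage("normalize", qc_diagnostics(tm))
  write_tsv_prov(cbind(pm$meta, as.data.frame(tm$intensity)),
                 file.path(out_dir, "normalized_matrix.tsv"), comment = prov)
  jsonlite::write_json(
    list(params = as.data.frame(unclass(params)[c("channel", "a", "b")]),
         sigma = attr(params, "sigma"), converged = attr(params, "converged"),
         qq_dev = qc$qq_dev, sd_rank_slope_rel = qc$sd_rank_slope_rel,
         max_median_offset = qc$max_median_offset),
    file.path(out_dir, "vsn_params.json"), auto_unbox = TRUE, digits = NA)
  say("normalize: converged=", attr(params, "converged"),
      ", max channel median offset ", signif(qc$max_median_offset, 3))

  # test
  fits <- stage("test", fit_two_group(tm, design))
  hyper <- stage("test",
    estimate_hyperparams(fits$s2, fits$df[is.finite(fits$df)][1],
                         robust = cfg$test$robust))
  res <- stage("test", moderated_test(fits, hyper))
  res$p_bh <- bh_adjust(res$p)
  write_tsv_prov(cbind(pm$meta[c("peptide_id", "protein_id")], res),
                 file.path(out_dir, "moderated_results.tsv"), comment = prov)
  say("test: d0=", signif(hyper$d0, 4), ", s0_sq=", signif(hyper$s0_sq, 4))

  # hits (+ motif annotation)
  hits <- stage("hits",
    select_hits(res, pm$meta, cfg$hits$p_threshold, cfg$hits$require_wt_up))
  funnel$hits <- nrow(hits)
  hit_tab <- stage("motif", {
    win <- vapply(hits$modified_sequence, function(ms) {
      ps <- parse_phospho_sites(ms)
      extract_window(ps$stripped, ps$positions[1])$window
    }, "", USE.NAMES = FALSE)
    data.frame(protein = hits$protein_id, peptide = hits$peptide_id,
               site = hits$site_position, window = win,
               motif_match = hits$motif_match, flr_flag = hits$flr_flag,
               effect = hits$effect, p = hits$p)
  })
  write_tsv_prov(hit_tab, file.path(out_dir, "hit_table.tsv"), comment = prov)
  say("hits: ", nrow(hits), " selected (",
      sum(hit_tab$motif_match), " with the consensus motif)")

  # enrich
  enr <- stage("enrich", {
    background <- unique(pm$meta$protein_id)
    foreground <- unique(hits$protein_id)
    truth_sub <- unique(truth$peptides$protein_id[truth$peptides$is_substrate])
    ann <- gen_annotations(background, enriched_in = truth_sub,
                           seed = cfg$seed)
    go <- fisher_enrichment(foreground, background, ann,
                            cfg$enrich$p_cutoff, cfg$enrich$min_proteins)
    ppi <- bin_ppi(gen_ppi(background, hub_proteins = foreground,
                           seed = cfg$seed), cfg$ppi$threshold)
    list(go = go, ppi = ppi)
  })
  write_tsv_prov(enr$go, file.path(out_dir, "go_enrichment.tsv"),
                 comment = prov)
  write_tsv_prov(enr$ppi, file.path(out_dir, "ppi_edges.tsv"), comment = prov)
  say("enrich: ", sum(enr$go$significant), " significant terms, ",
      nrow(enr$ppi), " PPI edges retained")

  manifest <- list(package = "phosphoscreen",
                   version = as.character(utils::packageVersion("phosphoscreen")),
                   param_hash = hash, config = cfg, funnel = funnel,
                   timestamp = format(Sys.time(), tz = "UTC"))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(list(truth = truth, psm = psm, matrix = pm, vsn = params,
                 transformed = tm, qc = qc, results = res, hyper = hyper,
                 hits = hits, hit_table = hit_tab, enrichment = enr,
                 manifest = manifest))
}
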