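test_that("generators are deterministic for a fixed seed", {
  p1 <- gen_proteome(20, 200, 0.3, seed = 11)
  p2 <- gen_proteome(20, 200, 0.3, seed = 11)
  expect_identical(p1, p2)
  t1 <- gen_truth(n_peptides = 50, seed = 5)
  t2 <- gen_truth(n_peptides = 50, seed = 5)
  expect_identical(t1, t2)
  expect_identical(gen_screen(t1), gen_screen(t2))
  expect_identical(gen_assay(c(ctrl = 500, v1 = 300), seed = 2),
                   gen_assay(c(ctrl = 500, v1 = 300), seed = 2))
  expect_false(identical(gen_truth(n_peptides = 50, seed = 6)$peptides$mu,
                         t1$peptides$mu))
})

test_that("planted proteome sites match the consensus; chance rate is near theory", {
  pr <- gen_proteome(30, 300, plant_rate = 1, seed = 3)
  expect_equal(nrow(pr$planted_sites), 30)
  for (i in seq_len(nrow(pr$planted_sites))) {
    w <- extract_window(pr$records[[pr$planted_sites$protein_id[i]]],
                        pr$planted_sites$position[i])
    expect_true(match_motif(w)$match)
  }
  # plant_rate = 0: only chance matches, expected rate (1/20)^2 * (2/20) * (4/20)
  # per scanned position
  pr0 <- gen_proteome(200, 400, plant_rate = 0, seed = 9)
  found <- nrow(scan_proteome(pr0))
  n_pos <- 200 * 400
  rate <- (1 / 20)^2 * (2 / 20) * (4 / 20)
  expected <- n_pos * rate
  expect_lt(abs(found - expected), 4 * sqrt(expected))
  expect_error(gen_proteome(5, alphabet = c("A", "B", "Z")), "B")
})

test_that("screen intensities follow the generative model", {
  # noiseless identity: sigma = 0, delta = 0, a = 0, b = 1 -> columns equal mu
  tr <- gen_truth(n_peptides = 30, substrate_rate = 0, sigma_mult = 0,
                  sigma_add = 0, gain_sdlog = 0, offset_range = c(0, 0),
                  max_fractions_per_peptide = 1, seed = 2)
  psm <- gen_screen(tr, multiplicity = 0)
  m <- as.matrix(psm[paste0("reporter_", 1:10)])
  mu <- tr$peptides$mu[match(psm$peptide_id, tr$peptides$peptide_id)]
  expect_equal(unname(m), matrix(mu, nrow(m), 10), tolerance = 1e-12)

  # delta = 1 noiseless: WT channels exactly 2x KD after background removal
  tr1 <- gen_truth(n_peptides = 30, substrate_rate = 1, delta = 1,
                   sigma_mult = 0, sigma_add = 0,
                   max_fractions_per_peptide = 1, seed = 2)
  psm1 <- gen_screen(tr1, multiplicity = 0)
  m1 <- as.matrix(psm1[paste0("reporter_", 1:10)])
  m1 <- sweep(m1, 2, tr1$channel_offset)        # remove additive background
  m1 <- sweep(m1, 2, tr1$channel_gain, `/`)     # and channel gain
  expect_equal(rowMeans(m1[, 1:5]) / rowMeans(m1[, 6:10]),
               rep(2, nrow(m1)), tolerance = 1e-9)
})

test_that("screen output is non-negative with 10 channels; delta monotone", {
  tr <- gen_truth(n_peptides = 100, sigma_add = 500, seed = 4)
  psm <- gen_screen(tr)
  m <- as.matrix(psm[paste0("reporter_", 1:10)])
  expect_true(all(m >= 0))
  expect_equal(ncol(m), 10)
  # increasing delta strictly increases the expected WT-KD difference
  diffs <- vapply(c(0, 0.5, 1, 2), function(d) {
    t <- gen_truth(n_peptides = 10, substrate_rate = 1, delta = d,
                   sigma_mult = 0, sigma_add = 0,
                   max_fractions_per_peptide = 1, seed = 3)
    p <- gen_screen(t, multiplicity = 0)
    mm <- as.matrix(p[paste0("reporter_", 1:10)])
    mean(rowMeans(mm[, 1:5]) - rowMeans(mm[, 6:10]))
  }, 0)
  expect_true(all(diff(diffs) > 0))
})

test_that("truth invariants hold: delta = 0 iff not substrate; fractions and probabilities populated", {
  tr <- gen_truth(n_peptides = 500, seed = 8)
  expect_identical(tr$peptides$delta != 0, tr$peptides$is_substrate)
  expect_true(all(tr$channel_gain > 0))
  expect_true(all(lengths(tr$fractions) >= 1))
  expect_true(all(tr$peptides$ptm_probability >= 0 &
                    tr$peptides$ptm_probability <= 1))
  # ambiguity and FLR shares: both sides of the 0.75 gate and the 0.994
  # flag are exercised
  expect_gt(mean(tr$peptides$ptm_probability < 0.75), 0.03)
  expect_gt(mean(tr$peptides$ptm_probability >= 0.994), 0.05)
  tr_bad <- tr
  tr_bad$peptides$mu[1] <- -1
  expect_error(gen_screen(tr_bad), "non-positive")
})

test_that("timelapse phantom has the stated disc structure", {
  st <- gen_timelapse(shape = c(5, 32, 32), spot_center = c(16, 16),
                      spot_radius = 3, spot_amplitude = 80,
                      decay_rate = 0.5, background = 20, noise_sd = 0,
                      pre_frames = 1, seed = 1)
  expect_equal(dim(st), c(5, 32, 32))
  expect_true(all(st[1, , ] == 20))                 # pre-irradiation frame
  expect_equal(max(st[2, , ]), 100)                 # background + amplitude
  expect_equal(max(st[3, , ]), 20 + 80 * exp(-0.5))
  expect_error(gen_timelapse(shape = c(3, 16, 16), spot_center = c(50, 5)))
})

test_that("assay counts are Poisson-like and reproducible", {
  panel <- c(control = 2000, half = 1000, dead = 50)
  a <- gen_assay(panel, kd_rate = 50, seed = 3)
  expect_equal(a$label, names(panel))
  expect_true(all(a$cpm_wt >= 0))
  # mean of many replicates close to the rate
  reps <- vapply(1:200, function(s) gen_assay(panel, 50, seed = s)$cpm_wt[1], 0)
  expect_lt(abs(mean(reps) - 2000), 4 * sqrt(2000 / 200))
})

test_that("synthetic IO round-trips: PSM TSV, truth JSON, FASTA, TIFF", {
  tr <- gen_truth(n_peptides = 20, seed = 1)
  psm <- gen_screen(tr)
  f <- tempfile(fileext = ".tsv")
  write_psm_tsv(psm, f, comment = "param_hash=deadbeef")
  back <- read_psm_tsv(f)
  expect_equal(back$peptide_id, psm$peptide_id)
  expect_equal(as.matrix(back[paste0("reporter_", 1:10)]),
               as.matrix(psm[paste0("reporter_", 1:10)]), tolerance = 1e-8)

  fj <- tempfile(fileext = ".json")
  write_truth_json(tr, fj)
  tr2 <- read_truth_json(fj)
  expect_equal(tr2$peptides$mu, tr$peptides$mu)
  expect_equal(tr2$sigma_mult, tr$sigma_mult)

  pr <- gen_proteome(5, 50, 0.5, seed = 2)
  ff <- tempfile(fileext = ".fasta")
  write_proteome_fasta(pr, ff)
  expect_identical(read_proteome_fasta(ff), pr$records)

  st <- gen_timelapse(shape = c(3, 16, 16), noise_sd = 2, seed = 1,
                      spot_center = c(8, 8))
  ft <- tempfile(fileext = ".tif")
  sc <- write_stack_tiff(st, ft)
  expect_equal(read_stack_tiff(ft, scale = sc), st, tolerance = 1e-6)
})
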