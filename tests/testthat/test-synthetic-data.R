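test_that("sim_config validates probabilities and mixes", {
  expect_error(sim_config(novel_fraction = 1.2), "\\[0, 1\\]")
  expect_error(sim_config(event_mix = c(exon_skipping = 0.5,
                                        intron_retention = 0.4)), "sum to 1")
  expect_error(sim_config(peak_mix = c(promoter = 1)), NA)
  expect_error(sim_config(peak_mix = c(enhancer = 1)), "feature categories")
})

test_that("reference simulation is deterministic, exact and valid", {
  cfg <- sim_config(seed = 4, n_genes = 50)
  a <- simulate_reference_annotation(cfg)
  b <- simulate_reference_annotation(cfg)
  expect_equal(a, b)
  f1 <- tempfile(); f2 <- tempfile()
  write_gff(a, f1); write_gff(b, f2)
  expect_identical(readLines(f1), readLines(f2))
  expect_length(a$loci, 50)
  # loci are non-overlapping and within the registry
  for (cc in names(a$chromosomes)) {
    here <- Filter(function(l) l$chrom == cc, a$loci)
    spans <- t(vapply(here, function(l) c(l$start, l$end), c(0, 0)))
    ord <- order(spans[, 1])
    expect_true(all(spans[ord, 1][-1] >= spans[ord, 2][-nrow(spans)]))
    expect_lte(max(spans[, 2]), a$chromosomes[[cc]])
  }
  expect_error(simulate_reference_annotation(
    sim_config(seed = 4, n_genes = 50, n_chromosomes = 1,
               chromosome_length = 100000)), "infeasible packing")
})

test_that("candidate truth matches construction: novel fraction and reasons", {
  cfg0 <- sim_config(seed = 6, n_genes = 20, n_candidates = 40,
                     novel_fraction = 0)
  ref <- simulate_reference_annotation(cfg0)
  fl <- simulate_flnc_candidates(ref, cfg0)
  expect_true(all(fl$truth$true_status == "known"))

  cfg1 <- sim_config(seed = 6, n_genes = 20, n_candidates = 40,
                     novel_fraction = 1)
  fl1 <- simulate_flnc_candidates(simulate_reference_annotation(cfg1), cfg1)
  expect_true(all(fl1$truth$true_status == "novel"))
  skips <- fl1$truth[fl1$truth$planted == "exon_skipping", ]
  expect_true(nrow(skips) > 0 && all(skips$true_reason == "new_intron"))
})

test_that("the pipeline recovers the planted candidate classifications", {
  cfg <- sim_config(seed = 44, n_genes = 30, n_candidates = 80)
  ref <- simulate_reference_annotation(cfg)
  fl <- simulate_flnc_candidates(ref, cfg)
  jx <- simulate_junctions(ref, fl$candidates, cfg)
  up <- update_annotation(ref, fl$candidates, jx)
  d <- merge(up$decisions, fl$truth, by = "candidate_id")
  # candidates that stayed their own representative carry their own truth
  solo <- d[d$kept & !is.na(d$representative_id) &
              d$candidate_id == d$representative_id, ]
  expect_gt(nrow(solo), 10)
  expect_equal(mean(solo$status == solo$true_status), 1)
  expect_equal(mean(solo$reason == solo$true_reason), 1)
})

test_that("junction support probability 1 and 0 bound criterion C3", {
  cfg1 <- sim_config(seed = 12, n_genes = 10, n_candidates = 25,
                     junction_support_prob = 1)
  ref <- simulate_reference_annotation(cfg1)
  fl <- simulate_flnc_candidates(ref, cfg1)
  jx <- simulate_junctions(ref, fl$candidates, cfg1)
  ret <- retain_candidates(fl$candidates, jx, ref)
  expect_true(all(grepl("C3", ret$criteria)))

  cfg0 <- sim_config(seed = 12, n_genes = 10, n_candidates = 25,
                     junction_support_prob = 0)
  jx0 <- simulate_junctions(ref, fl$candidates, cfg0)
  ret0 <- retain_candidates(fl$candidates, jx0, ref)
  mono <- vapply(fl$candidates, function(cand) nrow(cand$model$exons) == 1L, TRUE)
  expect_equal(grepl("C3", ret0$criteria), mono)
})

test_that("simulated counts have the planted moments", {
  # dispersion -> 0 approaches Poisson: variance ~ mean on null features
  cfg <- sim_config(seed = 21, n_features = 5000, nb_dispersion = 1e-4,
                    de_fraction = 0, library_size_sd = 0)
  sim <- simulate_counts(NULL, cfg)
  m <- rowMeans(sim$counts$counts)
  v <- apply(sim$counts$counts, 1, var)
  # the mean ratio is 1 for Poisson; the median of a 5-df variance ratio is not
  expect_equal(mean(v / pmax(m, 1e-9)), 1, tolerance = 0.05)

  # planted features center on the configured ratio
  cfg2 <- sim_config(seed = 22, n_features = 4000, library_size_sd = 0)
  sim2 <- simulate_counts(NULL, cfg2)
  tr <- sim2$truth
  expect_equal(sum(tr$is_de), 400)
  cm <- sim2$counts$counts
  ratio <- log2((rowMeans(cm[, 4:6]) + 0.5) / (rowMeans(cm[, 1:3]) + 0.5))
  expect_equal(median(abs(ratio[tr$is_de])), 2, tolerance = 0.15)
  expect_equal(median(ratio[!tr$is_de]), 0, tolerance = 0.1)
  # DE fraction 0 plants nothing
  expect_false(any(simulate_counts(NULL, sim_config(seed = 1, n_features = 50,
                                                    de_fraction = 0))
                   $truth$is_de))
})

test_that("peak placement mix is honoured and recovered by the classifier", {
  cfg <- sim_config(seed = 14, n_genes = 30, n_peaks = 60,
                    peak_mix = c(intergenic = 1))
  ref <- simulate_reference_annotation(cfg)
  pks <- simulate_peaksets(ref, cfg)
  fd <- feature_distribution(pks$bed, ref)
  expect_equal(fd$count[fd$category == "intergenic"], 60L)

  cfg2 <- sim_config(seed = 15, n_genes = 30, n_peaks = 120)
  pks2 <- simulate_peaksets(simulate_reference_annotation(cfg2), cfg2)
  fd2 <- feature_distribution(pks2$bed, simulate_reference_annotation(cfg2))
  expect_equal(attr(fd2, "assignments")$category, pks2$truth$true_category)
  # determinism
  pks2b <- simulate_peaksets(simulate_reference_annotation(cfg2), cfg2)
  expect_equal(pks2$bed, pks2b$bed)
  expect_equal(pks2$counts$counts, pks2b$counts$counts)
})

test_that("a zero differential fraction yields only false-positive peak calls", {
  cfg <- sim_config(seed = 16, n_genes = 20, n_peaks = 150,
                    diff_peak_fraction = 0)
  pks <- simulate_peaksets(simulate_reference_annotation(cfg), cfg)
  res <- call_differential_peaks(run_differential(pks$counts))
  expect_lte(sum(res$significant), ceiling(0.05 * 150))
})

test_that("simulate_workspace writes a complete, reloadable set of inputs", {
  dir <- file.path(tempdir(), "oviso_ws")
  cfg <- sim_config(seed = 9, n_genes = 12, n_candidates = 30, n_features = 40,
                    n_peaks = 25)
  ws <- simulate_workspace(dir, cfg)
  expect_true(all(file.exists(unlist(ws$paths))))
  back_ref <- read_gff(ws$paths$reference)
  expect_equal(back_ref, ws$reference)
  models <- read_bed12(ws$paths$candidates)
  expect_length(models, 30)
  info <- read.delim(ws$paths$candidate_info)
  expect_equal(info$candidate_id, vapply(ws$candidates, `[[`, "", "candidate_id"))
  jx <- read_junctions_bed(ws$paths$junctions)
  expect_equal(nrow(jx), nrow(ws$junctions))
  cnt <- read.delim(ws$paths$isoform_counts, check.names = FALSE)
  expect_equal(as.matrix(cnt[, -1]), ws$counts$counts, ignore_attr = TRUE)
  # the recorded retention truth matches the retention operation exactly
  ret <- retain_candidates(ws$candidates, ws$junctions, ws$reference)
  truth <- read.delim(file.path(dir, "truth_candidates.tsv"), na.strings = NULL)
  expect_equal(ret$kept, truth$true_kept)
  expect_equal(ret$criteria, truth$true_criteria)
})
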