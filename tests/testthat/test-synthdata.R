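test_that("make_trna_reference honours its construction contract", {
  ref <- make_trna_reference(4, 2, 76, seed = 1)
  expect_equal(nrow(ref), 4)
  expect_equal(sum(!is.na(ref$m7g_pos)), 2)
  expect_true(all(ref$length == 76))
  expect_true(all(endsWith(ref$sequence, "CCA")))
  # deterministic under the seed
  expect_identical(ref, make_trna_reference(4, 2, 76, seed = 1))
  expect_false(identical(ref$sequence,
                         make_trna_reference(4, 2, 76, seed = 2)$sequence))
  # every annotated position is a G inside the variable loop
  ref2 <- make_trna_reference(2, 2, 76, seed = 7)
  expect_true(all(substring(ref2$sequence, ref2$m7g_pos + 1,
                            ref2$m7g_pos + 1) == "G"))
  expect_true(all(ref2$m7g_pos >= ref2$var_loop_start &
                  ref2$m7g_pos < ref2$var_loop_end))
  # TOG-source species begin with 4 or 5 G
  expect_true(all(tog_run(ref2$sequence) %in% c(4, 5)))
  expect_error(make_trna_reference(2, 1, length = 40, seed = 1), "60")
})

test_that("simulated reads are exact substrings with the planted KO excess", {
  ref <- make_trna_reference(4, 2, seed = 3)
  fd <- fragment_design(planted_togs = default_planted_togs(ref, log2_excess = 3),
                        depth_per_sample = 2e4, seed = 3)
  fs <- simulate_fragment_reads(ref, fd)
  # all reads are substrings of some reference sequence
  for (s in names(fs$reads)) {
    uq <- unique(fs$reads[[s]])
    expect_true(all(vapply(uq, function(r)
      any(vapply(ref$sequence, function(x) grepl(r, x, fixed = TRUE), TRUE)),
      TRUE)))
  }
  # technical library-size variation stays within two-fold per condition
  # (the planted KO excess adds biological mass on top)
  for (cond in c("WT", "KO")) {
    libs <- colSums(fs$counts[, fs$samples$condition == cond])
    expect_lt(max(libs) / min(libs), 2.2)
  }

  # empirical KO/WT ratio of planted fragments over >= 20 replicates
  fd20 <- fragment_design(conditions = c(WT = 20, KO = 20),
                          planted_togs = default_planted_togs(ref, log2_excess = 3),
                          depth_per_sample = 2e4, seed = 4)
  fs20 <- simulate_fragment_reads(ref, fd20)
  planted <- fs20$catalogue$type == "planted_tog"
  wt_cols <- fs20$samples$condition == "WT"
  # per-sample library-size factors cancel in expectation across many samples
  ratio <- rowMeans(fs20$counts[planted, !wt_cols]) /
    rowMeans(fs20$counts[planted, wt_cols])
  expect_true(all(abs(log2(ratio) - 3) < 0.5))
})

test_that("fragment simulation handles degenerate designs", {
  ref <- make_trna_reference(3, 1, seed = 5)
  # full-length-only library: no read shorter than the species length
  fd <- fragment_design(full_length_fraction = 1,
                        planted_togs = default_planted_togs(ref),
                        depth_per_sample = 5e3, seed = 5)
  fs <- simulate_fragment_reads(ref, fd)
  expect_true(all(nchar(unlist(fs$reads)) == 76))
  # zero depth: empty read collections
  fd0 <- fragment_design(depth_per_sample = 0, seed = 5)
  fs0 <- simulate_fragment_reads(ref, fd0)
  expect_true(all(lengths(fs0$reads) == 0))
  # TOG source without a terminal G run is rejected
  bad <- data.frame(species_id = ref$id[nrow(ref)], length = 20, log2_excess = 3)
  expect_error(simulate_fragment_reads(ref, fragment_design(planted_togs = bad)),
               "G run")
})

test_that("simulated counts match the NB(mu, alpha) contract", {
  # >= 1000 draws of a single planted fragment's count
  ref <- make_trna_reference(2, 1, seed = 6)
  mu <- 400; alpha <- 0.02
  set.seed(split_seed(6, "nb-contract"))
  draws <- rnbinom(2000, mu = mu, size = 1 / alpha)
  expect_lt(abs(mean(draws) - mu) / mu, 0.05)
  expected_var <- mu + alpha * mu^2
  expect_lt(abs(var(draws) - expected_var) / expected_var, 0.2)
})

test_that("cleavage profiles concentrate the designed signal at m7g_pos + 1", {
  ref <- make_trna_reference(4, 2, seed = 8)
  cd <- cleavage_design(depth_per_species = 1e4, signal_fraction = 0.3,
                        ko_signal_fraction = 0.005, seed = 8)
  prof <- simulate_cleavage_profiles(ref, cd)
  target <- ref$m7g_pos[1] + 1
  wt1 <- prof[prof$species_id == ref$id[1] & prof$condition == "WT" &
              prof$replicate == 1, ]
  # binomial CI: 3000 +- 4 sd, sd = sqrt(1e4 * .3 * .7) ~ 46
  expect_lt(abs(wt1$count[wt1$position == target] - 3000), 4 * 46)
  # species without m7g_pos: max per-position fraction stays near background
  bg <- prof[prof$species_id == ref$id[3] & prof$condition == "WT", ]
  expect_lt(max(bg$count) / sum(bg$count[bg$replicate == 1]) * 2, 0.05)
  # zero residual KO signal leaves pure background
  cd0 <- cleavage_design(ko_signal_fraction = 0, signal_fraction = 0.3, seed = 8)
  prof0 <- simulate_cleavage_profiles(ref, cd0)
  ko <- prof0[prof0$species_id == ref$id[1] & prof0$condition == "KO" &
              prof0$replicate == 1, ]
  expect_lt(ko$count[ko$position == target], 0.05 * sum(ko$count))
})

test_that("expression cohorts carry the planted group shifts", {
  des <- cohort_design(n_cohorts = 5, n_genes = 100,
                       planted = data.frame(gene = "gene0001", effect = 2,
                                            classes = "PM", frac_cohorts = 1),
                       seed = 9)
  cohorts <- simulate_expression_cohorts(des)
  expect_length(cohorts, 5)
  expect_identical(cohorts, simulate_expression_cohorts(des))
  shifts <- vapply(cohorts, function(co) {
    x <- co$expr["gene0001", ]
    mean(x[co$groups %in% c("P", "M")]) - mean(x[co$groups == "N"])
  }, 0)
  # true shift is 2 SD; 20 vs 10 samples per cohort -> se ~ 0.39
  expect_true(all(abs(shifts - 2) < 1.2))
  # partial penetrance: only the first round(frac * n) cohorts shifted
  des2 <- cohort_design(n_cohorts = 5, n_genes = 50,
                        planted = data.frame(gene = "gene0001", effect = 3,
                                             classes = "P", frac_cohorts = 0.6),
                        seed = 10)
  sh2 <- vapply(simulate_expression_cohorts(des2), function(co) {
    x <- co$expr["gene0001", ]
    mean(x[co$groups == "P"]) - mean(x[co$groups == "N"])
  }, 0)
  expect_true(all(abs(sh2[1:3] - 3) < 1.5))
  expect_true(all(abs(sh2[4:5]) < 1.5))
})

test_that("polysome simulation shifts mass into polysome fractions", {
  pp <- simulate_polysome_profile(10, shifted = c("t1", "t2"), seed = 11)
  expect_identical(pp$abundance,
                   simulate_polysome_profile(10, shifted = c("t1", "t2"),
                                             seed = 11)$abundance)
  fc <- polysome_fc(pp)
  expect_true(all(fc[c("t1", "t2")] > 5 * max(fc[paste0("t", 3:10)])))
  # no shifts: fold changes are uniform across transcripts
  pp0 <- simulate_polysome_profile(10, seed = 11)
  fc0 <- polysome_fc(pp0)
  expect_lt(diff(range(fc0)) / mean(fc0), 0.5)
  # more shifted mass -> monotonically larger fold change
  fcs <- vapply(c(0.2, 0.4, 0.6, 0.8), function(m)
    polysome_fc(simulate_polysome_profile(3, shifted = "t1", shift_mass = m,
                                          seed = 12))[["t1"]], 0)
  expect_true(all(diff(fcs) > 0))
})
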