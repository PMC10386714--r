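make_cohort <- function(expr, groups, name = "c1") {
  structure(list(name = name, expr = expr, groups = groups),
            class = "expression_cohort")
}

test_that("cohort_zscore is the class-mean shift in reference SD units", {
  expr <- rbind(g1 = c(1, 2, 3, 4, 5, 6))
  co <- make_cohort(expr, c("N", "N", "N", "P", "P", "P"))
  expect_equal(cohort_zscore(co, "g1", "P"), 3)   # (5 - 2) / 1
  # class mean equal to reference mean -> Z = 0
  expr2 <- rbind(g1 = c(1, 3, 1, 3))
  co2 <- make_cohort(expr2, c("N", "N", "P", "P"))
  expect_equal(cohort_zscore(co2, "g1", "P"), 0)
  # zero reference SD -> NA with warning
  co3 <- make_cohort(rbind(g1 = c(2, 2, 5)), c("N", "N", "P"))
  expect_warning(z <- cohort_zscore(co3, "g1", "P"), "zero")
  expect_true(is.na(z))
  # invariance under an additive shift of the whole cohort
  co4 <- make_cohort(expr + 11, c("N", "N", "N", "P", "P", "P"))
  expect_equal(cohort_zscore(co4, "g1", "P"), 3)
  # scales inversely with a multiplicative change of the reference spread:
  # same class/reference means as `co` but the N spread doubled -> Z halves
  co5 <- make_cohort(rbind(g1 = c(0, 2, 4, 4, 5, 6)),
                     c("N", "N", "N", "P", "P", "P"))
  expect_equal(cohort_zscore(co5, "g1", "P"), cohort_zscore(co, "g1", "P") / 2)
})

test_that("null Z-scores behave like standard normal deviates", {
  set.seed(31)
  n <- 1000
  expr <- matrix(rnorm(n * 40), n, dimnames = list(sprintf("g%04d", 1:n), NULL))
  co <- make_cohort(expr, rep(c("N", "P"), each = 20))
  z <- vapply(rownames(expr), function(g) cohort_zscore(co, g, "P"), 0)
  # Z of a class mean over 20 samples has sd ~ sqrt(1/20 + 1/20) ~ 0.32
  expect_lt(abs(mean(z)), 0.05)
  expect_gt(mean(abs(z) < 2), 0.95)
})

test_that("cohort_anova is classical one-way ANOVA with the F = t^2 identity", {
  set.seed(32)
  x <- rnorm(20)
  co <- make_cohort(rbind(g1 = x), rep(c("N", "P"), each = 10))
  p_anova <- cohort_anova(co, "g1")
  p_t <- t.test(x[1:10], x[11:20], var.equal = TRUE)$p.value
  expect_equal(p_anova, p_t)
  # power: well-separated means are detected
  y <- c(rnorm(10, 0), rnorm(10, 2), rnorm(10, 2))
  co2 <- make_cohort(rbind(g1 = y), rep(c("N", "P", "M"), each = 10))
  expect_lt(cohort_anova(co2, "g1"), 0.01)
  # fewer than two usable groups -> NA
  co3 <- make_cohort(rbind(g1 = rnorm(3)), c("N", "N", "P"))
  expect_true(is.na(cohort_anova(co3, "g1")))
})

test_that("rmp_screen combines coherence and dataset-count conjunctively", {
  set.seed(33)
  groups <- rep(c("N", "P", "M"), each = 10)
  # gene 'hitme' shifted in 4 of 5 cohorts, 'weak' in 2 of 2 small cohorts
  cohorts <- lapply(1:5, function(k) {
    expr <- matrix(rnorm(3 * 30), 3, dimnames = list(c("hitme", "null1", "null2")))
    if (k <= 4) expr["hitme", groups != "N"] <- expr["hitme", groups != "N"] + 3
    make_cohort(expr, groups, paste0("c", k))
  })
  scr <- rmp_screen(cohorts)
  row <- scr[scr$gene == "hitme", ]
  expect_equal(row$n_present, 5)
  expect_equal(row$n_significant, 4)
  expect_equal(row$coherence, 80)
  expect_true(row$hit)
  # significant in 2/2 cohorts: coherence 100 but n_significant < 3 -> no hit
  two <- cohorts[1:2]
  scr2 <- rmp_screen(two)
  row2 <- scr2[scr2$gene == "hitme", ]
  expect_equal(row2$coherence, 100)
  expect_false(row2$hit)
  # a gene absent from all cohorts: n_present 0, never a hit
  scr3 <- rmp_screen(cohorts, genes = c("hitme", "ghost"))
  expect_equal(scr3$n_present[scr3$gene == "ghost"], 0)
  expect_false(scr3$hit[scr3$gene == "ghost"])
})

test_that("screen coherence equals a brute-force per-gene recount", {
  des <- cohort_design(n_cohorts = 4, group_sizes = c(N = 5, P = 5, M = 5),
                       n_genes = 30,
                       planted = data.frame(gene = "gene0003", effect = 2,
                                            classes = "PM", frac_cohorts = 0.75),
                       seed = 34)
  cohorts <- simulate_expression_cohorts(des)
  scr <- rmp_screen(cohorts)
  pmat <- attr(scr, "p")
  for (g in scr$gene) {
    n_sig <- sum(pmat[g, ] < 0.05, na.rm = TRUE)
    n_present <- sum(vapply(cohorts, function(co) g %in% rownames(co$expr), TRUE))
    expect_equal(scr$n_significant[scr$gene == g], n_sig)
    expect_equal(scr$coherence[scr$gene == g], 100 * n_sig / n_present)
  }
  # screen Z matrices agree with the per-gene operation
  zP <- attr(scr, "z_P")
  for (g in scr$gene[1:5])
    for (j in 1:4)
      expect_equal(zP[g, j], cohort_zscore(cohorts[[j]], g, "P"))
})

test_that("parclip_quant computes RPM, RPKM and offset enrichment", {
  q <- parclip_quant(counts = c(gene1 = 100), lib_sizes = c(1e6, 1e6),
                     gene_lengths = 500, control_counts = c(gene1 = 100))
  expect_equal(q$rpm_ip, 100)
  expect_equal(q$rpkm_ip, 200)
  expect_equal(q$log2_enrichment, 0)    # IP RPM equals control RPM
  q2 <- parclip_quant(c(a = 300, b = 0), lib_sizes = c(1e6, 2e6),
                      gene_lengths = c(1000, 1000),
                      control_counts = c(a = 0, b = 600),
                      rna_class = c("tRNA", "mRNA"))
  expect_equal(q2$rpm_control[2], 300)
  expect_equal(q2$log2_enrichment[1], log2(301 / 1))
  med <- attr(q2, "class_median_log2_rpm")
  expect_equal(unname(med["tRNA"]), log2(301))
  expect_error(parclip_quant(c(a = 1), 1e6, 0, c(a = 1)), "positive")
})

test_that("cv_filter removes single-replicate peaks then applies the CV cut", {
  cpm <- rbind(stable = c(10, 10), noisy = c(10, 20), lone = c(15, 0))
  kept <- cv_filter(cpm)
  expect_identical(rownames(kept), "stable")
  expect_equal(unname(attr(kept, "cv")["stable"]), 0)
  # CV of (10, 20) is 100 * 7.071 / 15 ~ 47.1% -> removed at 30%
  expect_false("noisy" %in% rownames(kept))
  expect_true("noisy" %in% rownames(cv_filter(cpm, max_cv_percent = 50)))
  # peak absent in one replicate is removed before the CV step
  expect_false("lone" %in% rownames(cv_filter(cpm, max_cv_percent = 1e6)))
  expect_error(cv_filter(cpm[, 1, drop = FALSE]), "replicates")
})

test_that("polysome shares sum to 1 and the fold change handles degeneracies", {
  ab <- rbind(uniform = rep(1, 16),
              allpoly = c(rep(0, 8), rep(1, 8)),
              zero = rep(0, 16))
  mask <- c(rep(FALSE, 12), rep(TRUE, 4))
  sh <- polysome_proportions(ab)
  expect_equal(rowSums(sh[1:2, ]), c(uniform = 1, allpoly = 1))
  expect_true(all(is.na(sh["zero", ])))
  # uniform over 16 fractions with 4 polysomal: FC = (4/16)/(12/16) = 1/3
  fc <- polysome_fc(ab, polysome_mask = mask)
  expect_equal(unname(fc["uniform"]), 1 / 3)
  # all mass in polysome fractions: infinite FC, flagged
  mask2 <- c(rep(FALSE, 8), rep(TRUE, 8))
  fc2 <- polysome_fc(ab, polysome_mask = mask2)
  expect_true(is.infinite(fc2[["allpoly"]]))
  expect_true(attr(fc2, "capped")[["allpoly"]])
  expect_true(is.na(fc2[["zero"]]))
  expect_error(polysome_fc(ab, polysome_mask = rep(TRUE, 16)), "non-polysome")
})

test_that("cohort TSVs round-trip through read_cohort", {
  des <- cohort_design(n_cohorts = 1, group_sizes = c(N = 3, P = 3, M = 2),
                       n_genes = 10, seed = 35)
  co <- simulate_expression_cohorts(des)[[1]]
  expr_path <- withr::local_tempfile(fileext = ".tsv")
  lab_path <- withr::local_tempfile(fileext = ".tsv")
  utils::write.table(data.frame(gene = rownames(co$expr), co$expr,
                                check.names = FALSE),
                     expr_path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(data.frame(sample = colnames(co$expr), group = co$groups),
                     lab_path, sep = "\t", quote = FALSE, row.names = FALSE)
  back <- read_cohort(expr_path, lab_path, name = "c1")
  expect_equal(back$expr, co$expr, tolerance = 1e-6)
  expect_identical(back$groups, co$groups)
})
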