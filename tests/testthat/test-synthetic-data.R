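test_that("same spec and seed give bit-identical datasets", {
  s <- tiny_spec(seed = 7)
  expect_identical(generate_multimodal(s), generate_multimodal(s))
  s2 <- tiny_spec(seed = 8)
  expect_false(identical(generate_multimodal(s), generate_multimodal(s2)))
})

test_that("label marginals match the requested class counts", {
  s <- synth_spec(n_per_class = c(HC = 11, MCI = 23, AD = 6),
                  modality_dims = c(MRI = 5, SNP = 7),
                  informative_counts = c(MRI = 2, SNP = 2),
                  effect_sizes = c(MRI = 1, SNP = 0.5), seed = 3)
  ds <- generate_multimodal(s)
  expect_equal(as.integer(table(ds$labels)), c(11L, 23L, 6L))
  expect_equal(length(ds$subject_ids), 40L)
  expect_false(anyDuplicated(ds$subject_ids) > 0)
})

test_that("SNP block stays on the {0,1,2} support for any effect size", {
  s <- tiny_spec(seed = 2, eff = c(MRI = 1, PET = 1, CSF = 1, SNP = 8))
  ds <- generate_multimodal(s)
  expect_true(all(ds$blocks$SNP %in% c(0, 1, 2)))
})

test_that("zero effect sizes give null class differences (t-statistics uniform)", {
  s <- synth_spec(n_per_class = c(HC = 60, MCI = 60, AD = 60),
                  modality_dims = c(MRI = 200, SNP = 50),
                  informative_counts = c(MRI = 20, SNP = 10),
                  effect_sizes = c(MRI = 0, SNP = 0), seed = 11)
  ds <- generate_multimodal(s)
  hc <- ds$labels == "HC"; ad <- ds$labels == "AD"
  pvals <- apply(ds$blocks$MRI, 2, function(v) stats::t.test(v[hc], v[ad])$p.value)
  # p-values approximately uniform: KS test should not reject wildly
  expect_gt(stats::ks.test(pvals, "punif")$p.value, 0.01)
})

test_that("planted SNP effects reach their analytic standardized mean difference", {
  # Monte-Carlo check against the generative model: for a planted SNP with
  # base MAF p, the class-2 frequency is plogis(qlogis(p) + 2 * effect);
  # the expected extreme-class mean difference is 2 * (p2 - p0), and the
  # empirical standardized difference should land near its analytic value.
  s <- synth_spec(n_per_class = c(HC = 200, MCI = 200, AD = 200),
                  modality_dims = c(MRI = 5, SNP = 189),
                  informative_counts = c(MRI = 0, SNP = 10),
                  effect_sizes = c(MRI = 0, SNP = 1.5), seed = 19)
  ds <- generate_multimodal(s)
  hc <- ds$labels == "HC"; ad <- ds$labels == "AD"
  planted <- ds$informative_truth$SNP
  expect_length(planted, 10)
  devs <- numeric(0)
  for (j in planted) {
    v <- ds$blocks$SNP[, j]
    emp_d <- (mean(v[ad]) - mean(v[hc])) /
      sqrt((stats::var(v[ad]) + stats::var(v[hc])) / 2)
    # analytic value from the per-genotype binomial moments at the SNP's
    # recorded allele frequency
    p0 <- ds$snp_maf$SNP[j]
    p2 <- stats::plogis(stats::qlogis(p0) + 2 * 1.5)
    ana_d <- 2 * (p2 - p0) /
      sqrt((2 * p2 * (1 - p2) + 2 * p0 * (1 - p0)) / 2)
    devs <- c(devs, abs(emp_d - ana_d))
  }
  # per-SNP deviation is Monte-Carlo noisy (se of a standardized mean
  # difference at n = 200/group is ~0.14); bound each draw at 3 se and the
  # average tightly
  expect_lt(max(devs), 0.45)
  expect_lt(mean(devs), 0.15)
})

test_that("planted signals are recoverable by a univariate t ranking", {
  s <- synth_spec(n_per_class = c(HC = 150, MCI = 150, AD = 150),
                  modality_dims = c(MRI = 100, SNP = 100),
                  informative_counts = c(MRI = 10, SNP = 10),
                  effect_sizes = c(MRI = 1.5, SNP = 1.5), seed = 5)
  ds <- generate_multimodal(s)
  hc <- ds$labels == "HC"; ad <- ds$labels == "AD"
  for (m in c("MRI", "SNP")) {
    tstat <- apply(ds$blocks[[m]], 2, function(v)
      abs(stats::t.test(v[ad], v[hc])$statistic))
    topk <- order(-tstat)[1:10]
    expect_gte(mean(ds$informative_truth[[m]] %in% topk), 0.9)
  }
})

test_that("dataset round trip through CSV/JSON is lossless", {
  ds <- generate_multimodal(tiny_spec(seed = 4, n = 10))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  ds2 <- read_dataset(dir)
  expect_equal(ds2$blocks, ds$blocks)
  expect_identical(ds2$labels, ds$labels)
  expect_identical(ds2$subject_ids, ds$subject_ids)
  expect_identical(names(ds2$blocks), names(ds$blocks))
  expect_equal(ds2$informative_truth, ds$informative_truth)
})

test_that("invalid on-disk data is rejected", {
  ds <- generate_multimodal(tiny_spec(seed = 4, n = 10))
  dir <- withr::local_tempdir()
  write_dataset(ds, dir)
  # corrupt a genotype
  snp <- utils::read.csv(file.path(dir, "SNP.csv"), check.names = FALSE)
  snp[1, 2] <- 3
  utils::write.csv(snp, file.path(dir, "SNP.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "SNP")
  # unknown label level
  write_dataset(ds, dir)
  lab <- utils::read.csv(file.path(dir, "labels.csv"))
  lab$label[1] <- "SCI"
  utils::write.csv(lab, file.path(dir, "labels.csv"), row.names = FALSE)
  expect_error(read_dataset(dir), "label")
})

test_that("degenerate specs and empty datasets error", {
  expect_error(synth_spec(modality_dims = c(MRI = 0, SNP = 5),
                          informative_counts = c(MRI = 0, SNP = 1),
                          effect_sizes = c(MRI = 0, SNP = 1)), "positive")
  expect_error(synth_spec(n_per_class = c(HC = 0, MCI = 5, AD = 5)), "class")
  expect_error(synth_spec(snp_maf_range = c(0, 0.5)), "maf")
  expect_error(synth_spec(informative_counts = c(MRI = 94, PET = 1, CSF = 1, SNP = 1)),
               "informative")
  ds <- generate_multimodal(tiny_spec(seed = 1, n = 10))
  ds$labels <- ds$labels[0]
  ds$subject_ids <- character(0)
  ds$blocks <- lapply(ds$blocks, function(b) b[0, , drop = FALSE])
  expect_error(write_dataset(ds, withr::local_tempdir()), "0 subjects|no subjects")
})
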