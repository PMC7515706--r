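test_that("z-scoring centers and scales within experiment and gene", {
  rec <- data.frame(
    experiment_id = c("e1", "e1", "e1", "e1", "e2", "e2"),
    gene_id = c("gA", "gA", "gB", "gB", "gA", "gA"),
    guide_id = paste0("g", 1:6),
    lfc = c(-2, 0, -1, -3, 5, 5))
  expect_message(z <- zscore_by_group(rec), "dropped 1")
  # {-2, 0} with sample sd sqrt(2): z = -/+ 0.7071
  gA1 <- z[z$experiment_id == "e1" & z$gene_id == "gA", ]
  expect_equal(gA1$z, c(-1, 1) / sqrt(2))
  # identical values (sd 0) dropped
  expect_false(any(z$experiment_id == "e2"))
  # every retained group: mean 0, sd 1
  for (k in split(z, interaction(z$experiment_id, z$gene_id, drop = TRUE))) {
    expect_equal(mean(k$z), 0)
    expect_equal(sd(k$z), 1)
  }
})

test_that("z-scores are invariant to affine rescaling of group LFCs", {
  set.seed(71)
  rec <- data.frame(experiment_id = "e", gene_id = "g",
                    guide_id = paste0("g", 1:8), lfc = rnorm(8))
  rec2 <- rec
  rec2$lfc <- 3 * rec$lfc - 7
  expect_equal(zscore_by_group(rec)$z, zscore_by_group(rec2)$z)
})

test_that("training filters drop non-coding and non-specific guides", {
  n <- 100
  db <- data.frame(
    guide_id = paste0("g", 1:n),
    gene_id = c(rep(NA_character_, 5), rep("gX", n - 5)),
    specificity = 0.9, mm0 = 1L,
    mm1 = c(rep(0L, 90), rep(1L, 10)),
    exceeded_5000 = FALSE, stringsAsFactors = FALSE)
  rec <- data.frame(guide_id = paste0("g", 1:n), lfc = 0)
  expect_message(out <- apply_training_filters(rec, db),
                 "100 -> 95 \\(coding\\) -> 85")
  expect_equal(nrow(out), 85L)
  # non-coding guides (rows 1..5) and mm1 carriers (91..100) are gone
  expect_false(any(out$guide_id %in% paste0("g", c(1:5, 91:100))))
  # all-pass input is the identity
  db$gene_id <- "gX"; db$mm1 <- 0L
  expect_equal(nrow(apply_training_filters(rec, db)), n)
  expect_error(apply_training_filters(
    data.frame(guide_id = "missing"), db), "absent")
})

test_that("orthogonal predictors split importance by marginal R2", {
  set.seed(72)
  n <- 4000
  x1 <- rnorm(n); x2 <- rnorm(n)
  y <- 0.6 * x1 + 0.3 * x2 + rnorm(n)
  df <- data.frame(z = y, a = x1, b = x2)
  fit <- fit_feature_model(df, predictors = c("a", "b"))
  r2a <- summary(lm(z ~ a, df))$r.squared
  r2b <- summary(lm(z ~ b, df))$r.squared
  imp <- setNames(fit$importance$lmg, fit$importance$feature)
  # near-orthogonal by sampling: LMG share tracks the marginal R2
  expect_lt(abs(imp[["a"]] - r2a), 0.01)
  expect_lt(abs(imp[["b"]] - r2b), 0.01)
  expect_equal(sum(fit$importance$lmg), fit$r_squared, tolerance = 1e-10)
})

test_that("LMG equals the exhaustive ordering average on correlated toys", {
  set.seed(73)
  n <- 600
  x1 <- rnorm(n)
  x2 <- 0.7 * x1 + rnorm(n, 0, 0.5)    # deliberately correlated
  x3 <- rnorm(n)
  y <- 0.5 * x1 - 0.4 * x2 + 0.2 * x3 + rnorm(n)
  df <- data.frame(z = y, a = x1, b = x2, c = x3)
  fit <- fit_feature_model(df, predictors = c("a", "b", "c"))
  want <- oracle_lmg(df, "z", c("a", "b", "c"))
  imp <- setNames(fit$importance$lmg, fit$importance$feature)
  expect_equal(imp[names(want)], want, tolerance = 1e-8)
  expect_equal(sum(imp), summary(lm(z ~ a + b + c, df))$r.squared,
               tolerance = 1e-8)
  # Monte-Carlo path approximates the exact shares
  fit_mc <- fit_feature_model(df, predictors = c("a", "b", "c"),
                              exact_max = 0L, n_orders = 3000L)
  imp_mc <- setNames(fit_mc$importance$lmg, fit_mc$importance$feature)
  expect_equal(imp_mc[names(want)], want, tolerance = 0.02)
})

test_that("categorical predictors enter and leave as groups", {
  sim <- simulate_training_table(c(efficacy = 0.5), 1500, seed = 74)
  fit <- fit_feature_model(sim, predictors = c("efficacy", "pam", "nmd"))
  expect_setequal(fit$importance$feature, c("efficacy", "pam", "nmd"))
  expect_equal(sum(fit$importance$lmg), fit$r_squared, tolerance = 1e-10)
  expect_true(all(fit$importance$lmg >= -1e-12))
})

test_that("simulated effects are recovered within 3 standard errors", {
  betas <- c(efficacy = 0.5, conservation = 0.03, polyT3 = -0.4)
  sim <- simulate_training_table(betas, 2500, seed = 75)
  fit <- fit_feature_model(sim)
  co <- summary(fit$fit)$coefficients
  for (nm in c("efficacy", "conservation", "polyT3TRUE")) {
    true_b <- betas[[sub("TRUE$", "", nm)]]
    expect_lt(abs(co[nm, "Estimate"] - true_b), 3 * co[nm, "Std. Error"])
  }
  # planted continuous drivers rank top-2 by importance
  top2 <- fit$importance$feature[order(-fit$importance$lmg)][1:2]
  expect_setequal(top2, c("efficacy", "conservation"))
})

test_that("median differences and prevalences read out planted shifts", {
  set.seed(76)
  n <- 4000
  rec <- data.frame(z = rnorm(n),
                    shifted = runif(n) < 0.20,
                    null_feat = runif(n) < 0.50,
                    all_on = TRUE)
  rec$z[rec$shifted] <- rec$z[rec$shifted] - 0.5
  out <- median_diff_vs_prevalence(rec, c("shifted", "null_feat", "all_on"))
  shifted <- out[out$feature == "shifted", ]
  expect_equal(shifted$delta_median, -0.5, tolerance = 0.1)
  expect_equal(shifted$prevalence, 0.20, tolerance = 0.02)
  expect_lt(abs(out$delta_median[out$feature == "null_feat"]), 0.1)
  # degenerate feature: no absent group, difference undefined
  expect_true(is.na(out$delta_median[out$feature == "all_on"]))
  # prevalence can come from a wider reference universe
  uni <- data.frame(shifted = rep(c(TRUE, FALSE), c(1, 9)),
                    null_feat = TRUE, all_on = TRUE)
  out2 <- median_diff_vs_prevalence(rec, "shifted", universe = uni)
  expect_equal(out2$prevalence, 0.1)
})

test_that("negative-control normalization equalizes control mass exactly", {
  fx <- get_fixture()
  s <- fx$screen
  res <- screen_dropout_metrics(s$counts, s$design, s$gene_map,
                                s$negative_controls)
  genes <- s$gene_map$gene_id[match(rownames(res$rpm), s$gene_map$guide_id)]
  nc_mass <- colSums(res$rpm[genes %in% s$negative_controls, ])
  expect_equal(max(nc_mass) - min(nc_mass), 0)
  # scaling every count of one sample by 2 leaves LFCs untouched
  counts2 <- s$counts
  counts2[, "d14_1"] <- counts2[, "d14_1"] * 2L
  res2 <- screen_dropout_metrics(counts2, s$design, s$gene_map,
                                 s$negative_controls)
  expect_equal(res2$guide_lfc, res$guide_lfc)
  # essential genes drop, negative controls do not
  truth <- unlist(fx$manifest$screen_true_lfc)
  ess <- names(truth)[truth < 0]
  stats <- res$gene_stats
  expect_true(all(stats$lfc[stats$gene_id %in% ess] < -1))
  expect_true(all(abs(stats$lfc[!stats$gene_id %in% ess]) < 0.5))
})

test_that("hand-computable screens yield exact LFC, CV, and hit calls", {
  counts <- rbind(
    gX_1 = c(ref = 800, end = 400),
    gX_2 = c(ref = 800, end = 200),
    gX_3 = c(ref = 800, end = 100),
    nc_1 = c(ref = 600, end = 600))
  design <- data.frame(sample = c("ref", "end"), library = "L1",
                       role = c("reference", "endpoint"))
  gene_map <- data.frame(guide_id = rownames(counts),
                         gene_id = c("gX", "gX", "gX", "NC"))
  res <- screen_dropout_metrics(counts, design, gene_map, "NC",
                                pseudocount = 0)
  # counts were built so RPM ratios are exact powers of two
  expect_equal(res$guide_lfc[paste0("gX_", 1:3), "L1"], c(-1, -2, -3))
  gx <- res$gene_stats[res$gene_stats$gene_id == "gX", ]
  expect_equal(gx$lfc, -2)
  expect_equal(gx$cv, sd(c(-1, -2, -3)) / 2)
  expect_true(res$hits$hit[res$hits$gene_id == "gX"])
  expect_false(res$hits$hit[res$hits$gene_id == "NC"])

  # a uniform -2 gene has CV exactly 0 and is a hit
  counts2 <- rbind(gY_1 = c(ref = 400, end = 100),
                   gY_2 = c(ref = 800, end = 200),
                   nc_1 = c(ref = 600, end = 600))
  gm2 <- data.frame(guide_id = rownames(counts2),
                    gene_id = c("gY", "gY", "NC"))
  res2 <- screen_dropout_metrics(counts2, design, gm2, "NC",
                                 pseudocount = 0)
  gy <- res2$gene_stats[res2$gene_stats$gene_id == "gY", ]
  expect_equal(gy$lfc, -2)
  expect_equal(gy$cv, 0)
  expect_true(res2$hits$hit[res2$hits$gene_id == "gY"])
})
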