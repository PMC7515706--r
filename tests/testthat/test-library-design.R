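# a fully passing feature record, overridable per test
base_record <- function(...) {
  rec <- data.frame(
    efficacy = 0.41, conservation = 8, pct_cds = 0.5,
    polyA = 2L, polyC = 2L, polyG = 2L, polyT = 2L,
    has_esp3i = FALSE, snp_overlap = FALSE, in_domain = TRUE,
    specificity = 0.6, mm0 = 1L, mm1 = 0L, exceeded_5000 = FALSE,
    stringsAsFactors = FALSE)
  overrides <- list(...)
  for (nm in names(overrides)) rec[[nm]] <- overrides[[nm]]
  rec
}

test_that("feature binarization applies strict printed cutoffs", {
  m <- binarize_features(base_record())
  expect_true(all(unlist(m)))

  expect_false(binarize_features(base_record(efficacy = 0.40))$efficacy_ok)
  expect_true(binarize_features(base_record(efficacy = 0.401))$efficacy_ok)
  expect_false(binarize_features(base_record(conservation = 7))$conserved)
  expect_false(binarize_features(base_record(pct_cds = 0.95))$cds_ok)
  expect_true(binarize_features(base_record(pct_cds = 0.949))$cds_ok)
  expect_false(binarize_features(base_record(polyT = 3L))$construct_ok)
  expect_false(binarize_features(base_record(polyA = 5L))$construct_ok)
  expect_true(binarize_features(base_record(polyA = 4L))$construct_ok)
  expect_false(binarize_features(base_record(has_esp3i = TRUE))$construct_ok)
  expect_false(binarize_features(base_record(snp_overlap = TRUE))$snp_ok)
  expect_false(binarize_features(base_record(specificity = 0.5))$specific_full)
  expect_false(binarize_features(base_record(mm1 = 1L))$specific_full)
  expect_false(binarize_features(
    base_record(exceeded_5000 = TRUE))$specific_full)
  # NA features fail their criterion rather than erroring
  expect_false(binarize_features(base_record(conservation = NA))$conserved)
})

test_that("tier assignment follows the quoted rules", {
  tt <- default_tier_table()
  expect_equal(assign_tier(binarize_features(base_record()), tt), "1")
  # relaxed specificity band with all other features intact
  expect_equal(assign_tier(binarize_features(
    base_record(specificity = 0.3)), tt), "7.1")
  # fully non-specific
  expect_equal(assign_tier(binarize_features(
    base_record(specificity = 0.2)), tt), "8")
  # single-feature relaxations walk down tiers 2..6
  expect_equal(assign_tier(binarize_features(
    base_record(in_domain = FALSE)), tt), "2")
  expect_equal(assign_tier(binarize_features(
    base_record(in_domain = FALSE, conservation = 0)), tt), "3")
  expect_equal(assign_tier(binarize_features(
    base_record(in_domain = FALSE, conservation = 0, efficacy = 0.1)), tt),
    "4")
  expect_equal(assign_tier(binarize_features(
    base_record(in_domain = FALSE, conservation = 0, efficacy = 0.1,
                pct_cds = 0.99)), tt), "5")
  expect_equal(assign_tier(binarize_features(
    base_record(in_domain = FALSE, conservation = 0, efficacy = 0.1,
                pct_cds = 0.99, polyT = 4L)), tt), "6")
  # a guide failing an early-relaxed feature but passing later ones
  expect_equal(assign_tier(binarize_features(
    base_record(conservation = 0)), tt), "3")
})

test_that("tier assignment is monotone in feature improvements", {
  set.seed(61)
  tt <- default_tier_table()
  flags <- c("domain", "efficacy_ok", "conserved", "cds_ok",
             "construct_ok", "snp_ok", "specific_full", "specific_relaxed")
  for (i in 1:60) {
    m <- as.data.frame(as.list(setNames(runif(8) < 0.5, flags)))
    # relaxed specificity is implied by full specificity
    m$specific_relaxed <- m$specific_relaxed | m$specific_full
    t0 <- tier_rank(assign_tier(m, tt))
    off <- names(m)[!unlist(m)]
    if (!length(off)) next
    flip <- sample(off, 1)
    m2 <- m
    m2[[flip]] <- TRUE
    if (flip == "specific_full") m2$specific_relaxed <- TRUE
    expect_lte(tier_rank(assign_tier(m2, tt)), t0)
  }
})

mk_gene_guides <- function(tiers, efficacies, cuts, gene = "g") {
  data.frame(gene_id = gene,
             guide_id = paste0("gd", seq_along(tiers)),
             tier = as.character(tiers), efficacy = efficacies,
             cut_position = as.integer(cuts), stringsAsFactors = FALSE)
}

test_that("tier-1 guides are included regardless of spacing", {
  gg <- mk_gene_guides(
    tiers = c(1, 1, 1, rep(2, 10)),
    efficacies = c(0.9, 0.8, 0.7, seq(0.95, 0.5, length.out = 10)),
    cuts = c(100, 101, 102, seq(200, 470, by = 30)))
  picks <- pick_guides(gg)
  expect_equal(nrow(picks), 6L)
  t1 <- picks[picks$tier == "1", ]
  expect_equal(sort(t1$cut_position), c(100L, 101L, 102L))
  expect_true(all(t1$spacing_waived))
  # remaining picks are the best-ranked tier-2 guides, spaced >= 3 nt
  t2 <- picks[picks$tier == "2", ]
  expect_equal(nrow(t2), 3L)
  expect_true(all(abs(outer(t2$cut_position, t1$cut_position, "-")) >= 3))
})

test_that("picks match the exhaustive oracle on random genes", {
  set.seed(62)
  for (rep in 1:25) {
    n <- sample(5:12, 1)
    gg <- mk_gene_guides(
      tiers = sample(c("2", "3", "4"), n, replace = TRUE),
      efficacies = round(runif(n), 3),
      cuts = sample(100:160, n))       # tight span forces conflicts
    picks <- pick_guides(gg)
    # candidate order as the implementation ranks them
    ord <- order(tier_rank(gg$tier), -gg$efficacy, gg$cut_position,
                 gg$guide_id)
    want_idx <- oracle_pick(gg$cut_position[ord], 6L, integer(0), 3L)
    want_ids <- gg$guide_id[ord][want_idx]
    expect_setequal(picks$guide_id, want_ids)
  }
})

test_that("small genes return everything; empty genes return nothing", {
  gg <- mk_gene_guides(c(3, 5, 3, 8), c(0.2, 0.9, 0.5, 0.1),
                       c(10, 100, 2000, 3000))
  picks <- pick_guides(gg)
  expect_equal(nrow(picks), 4L)
  # ordered by tier then efficacy
  expect_equal(picks$guide_id, c("gd3", "gd1", "gd2", "gd4"))
  expect_message(empty <- pick_guides(gg[0, ]), "zero candidate")
  expect_equal(nrow(empty), 0L)
})

test_that("tier-1 overflow truncates by efficacy", {
  gg <- mk_gene_guides(rep(1, 8), seq(0.9, 0.2, length.out = 8),
                       seq(100, 800, by = 100))
  picks <- pick_guides(gg)
  expect_equal(nrow(picks), 6L)
  expect_equal(sort(picks$efficacy, decreasing = TRUE)[1],
               max(gg$efficacy))
  expect_setequal(picks$guide_id, paste0("gd", 1:6))
})

test_that("the twelve-guide format honors picks_per_gene", {
  gg <- mk_gene_guides(rep(2, 15), round(seq(0.95, 0.2, length.out = 15), 3),
                       seq(100, 1500, by = 100))
  picks <- pick_guides(gg, design_criteria(picks_per_gene = 12L))
  expect_equal(nrow(picks), 12L)
  expect_equal(picks$pick_index[12], "xii")
})

test_that("tier counts partition the annotated guides", {
  db <- get_fixture_db()$db
  lib <- design_library(db)
  tiers <- attr(lib, "tiers")
  expect_equal(nrow(tiers), sum(!is.na(db$gene_id)))
  expect_equal(sum(table(tiers$tier)), nrow(tiers))
  # per-gene quota respected
  expect_true(all(table(lib$gene_id) <= 6))
  # pick order is non-decreasing in tier within each gene
  for (gid in unique(lib$gene_id)) {
    tr <- tier_rank(lib$tier[lib$gene_id == gid])
    expect_true(all(diff(tr) >= 0))
  }
})

test_that("binomial gene-coverage arithmetic matches simulation", {
  set.seed(63)
  n_mc <- 1e5
  for (cfg in list(c(4, 3, 0.8), c(6, 5, 0.9), c(6, 4, 0.8))) {
    p_exact <- genes_with_at_least_k_effective(cfg[1], cfg[2], cfg[3])
    draws <- rbinom(n_mc, cfg[1], cfg[3]) >= cfg[2]
    se <- sqrt(p_exact * (1 - p_exact) / n_mc)
    expect_lt(abs(mean(draws) - p_exact), 3 * se)
  }
  expect_equal(genes_with_at_least_k_effective(6, 0, 0.5), 1.0)
  expect_error(genes_with_at_least_k_effective(4, 5, 0.5))
})
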