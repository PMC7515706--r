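#' Design criteria for tiered guide selection
#'
#' The binary cutoffs applied before tier assignment: cleavage efficacy
#' strictly above 0.40; target-residue conservation strictly above 7;
#' cut strictly before 95% of the CDS; no Esp3I site; homopolymer caps
#' (A, C, G below 5; T below 3); no common polymorphism in the guide+PAM;
#' specificity strictly above 0.50 (full) or 0.25 (relaxed) with the full
#' band additionally requiring zero off-targets within one mismatch.
#'
#' @param efficacy_min,conservation_min,pct_cds_max,specificity_full,specificity_relaxed
#'   Numeric thresholds (all strict comparisons).
#' @param polyA_max,polyC_max,polyG_max,polyT_max Maximum tolerated
#'   homopolymer run (a run of this length or longer fails).
#' @param close_offtarget_mm Off-target mismatch radius that must be
#'   empty for full specificity.
#' @param picks_per_gene Guides picked per gene (6 by default; 12 for the
#'   double-density format).
#' @param min_spacing_nt Minimum cut-site separation between picks.
#' @param max_exhaustive Candidate count up to which picking is solved by
#'   exhaustive subset search (beyond it, greedy with local swaps).
#' @return A `design_criteria` list.
#' @export
design_criteria <- function(efficacy_min = 0.40, conservation_min = 7,
                            pct_cds_max = 0.95,
                            polyA_max = 5L, polyC_max = 5L, polyG_max = 5L,
                            polyT_max = 3L,
                            specificity_full = 0.50,
                            specificity_relaxed = 0.25,
                            close_offtarget_mm = 1L,
                            picks_per_gene = 6L, min_spacing_nt = 3L,
                            max_exhaustive = 20L) {
  structure(list(efficacy_min = efficacy_min,
                 conservation_min = conservation_min,
                 pct_cds_max = pct_cds_max,
                 polyA_max = polyA_max, polyC_max = polyC_max,
                 polyG_max = polyG_max, polyT_max = polyT_max,
                 specificity_full = specificity_full,
                 specificity_relaxed = specificity_relaxed,
                 close_offtarget_mm = close_offtarget_mm,
                 picks_per_gene = picks_per_gene,
                 min_spacing_nt = min_spacing_nt,
                 max_exhaustive = max_exhaustive),
            class = "design_criteria")
}

TIER_LEVELS <- c("1", "2", "3", "4", "5", "6",
                 "7.1", "7.2", "7.3", "7.4", "7.5", "7.6", "8")

#' Default tier-relaxation table
#'
#' Tier 1 requires every design feature under full specificity; tiers 2-6
#' iteratively relax positive-selection features in priority order
#' (domain, then conservation, then efficacy, then CDS position, then
#' construct/SNP cleanliness) while holding full specificity fixed; tiers
#' 7.1-7.6 repeat the same ladder in the relaxed specificity band
#' (0.25 < score <= 0.50); tier 8 collects everything else. The ladder
#' for tiers 2-6 is a configuration choice shipped as data — pass any
#' table with the same columns to override it.
#'
#' @param path Optional path to a TSV with columns `tier`, `domain`,
#'   `conserved`, `efficacy`, `cds`, `construct`, `snp`, `specificity`
#'   (`full`/`relaxed`/`none`).
#' @return data.frame of tier requirements, one row per tier.
#' @export
default_tier_table <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "tier_table.tsv", package = "guideforge")
  }
  tt <- read.delim(path, stringsAsFactors = FALSE,
                   colClasses = c(tier = "character"))
  stopifnot(identical(tt$tier, TIER_LEVELS))
  tt
}

#' Binarize guide features against the design criteria
#'
#' @param records Annotated guide data.frame carrying `efficacy`,
#'   `conservation`, `pct_cds`, `polyA`..`polyT`, `has_esp3i`,
#'   `snp_overlap`, `in_domain`, `specificity`, `mm0`, `mm1`,
#'   `exceeded_5000`.
#' @param criteria A [design_criteria()].
#' @return data.frame mask with logical columns `domain`, `efficacy_ok`,
#'   `conserved`, `cds_ok`, `construct_ok`, `snp_ok`, `specific_full`,
#'   `specific_relaxed`. NA feature values fail their criterion.
#' @export
binarize_features <- function(records, criteria = design_criteria()) {
  no_na <- function(x) !is.na(x) & x
  mask <- data.frame(
    domain = no_na(records$in_domain),
    efficacy_ok = no_na(records$efficacy > criteria$efficacy_min),
    conserved = no_na(records$conservation > criteria$conservation_min),
    cds_ok = no_na(records$pct_cds < criteria$pct_cds_max),
    construct_ok = no_na(!records$has_esp3i &
                           records$polyA < criteria$polyA_max &
                           records$polyC < criteria$polyC_max &
                           records$polyG < criteria$polyG_max &
                           records$polyT < criteria$polyT_max),
    snp_ok = no_na(!records$snp_overlap)
  )
  mask$specific_full <- no_na(passes_specificity_filter(
    records, criteria$specificity_full, criteria$close_offtarget_mm))
  mask$specific_relaxed <- no_na(records$specificity >
                                   criteria$specificity_relaxed)
  mask
}

#' Assign guides to design tiers
#'
#' Each guide lands in the lowest-numbered tier whose feature
#' requirements its mask satisfies. The relaxation ladder is nested, so
#' flipping any feature from failing to passing never worsens the tier.
#'
#' @param mask data.frame from [binarize_features()].
#' @param tier_table data.frame from [default_tier_table()].
#' @return Character vector of tier labels, ordered factor-compatible
#'   with [tier_rank()].
#' @export
assign_tier <- function(mask, tier_table = default_tier_table()) {
  vapply(seq_len(nrow(mask)), function(i) {
    m <- mask[i, ]
    for (t in seq_len(nrow(tier_table))) {
      req <- tier_table[t, ]
      spec_ok <- switch(req$specificity,
                        full = m$specific_full,
                        relaxed = m$specific_relaxed,
                        none = TRUE)
      feat_ok <- (!req$domain || m$domain) &&
        (!req$conserved || m$conserved) &&
        (!req$efficacy || m$efficacy_ok) &&
        (!req$cds || m$cds_ok) &&
        (!req$construct || m$construct_ok) &&
        (!req$snp || m$snp_ok)
      if (spec_ok && feat_ok) return(req$tier)
    }
    "8"
  }, character(1))
}

#' Ordinal rank of a tier label
#'
#' @param tier Character vector of tier labels ("1".."6", "7.1".."7.6",
#'   "8").
#' @return Integer rank (1 best).
#' @export
tier_rank <- function(tier) {
  match(as.character(tier), TIER_LEVELS)
}

spacing_ok <- function(cut, picked_cuts, min_spacing) {
  all(abs(cut - picked_cuts) >= min_spacing)
}

mutually_spaced <- function(cuts, min_spacing) {
  if (length(cuts) < 2L) return(TRUE)
  all(abs(outer(cuts, cuts, "-"))[lower.tri(diag(length(cuts)))] >=
        min_spacing)
}

# best subset of size k (by summed rank, candidates pre-sorted by rank)
# honoring spacing among themselves and against fixed cut sites
best_spaced_subset <- function(cand_cuts, k, fixed_cuts, min_spacing) {
  n <- length(cand_cuts)
  if (k == 0L) return(integer(0))
  combos <- combn(n, k)
  best <- NULL; best_sum <- Inf
  for (j in seq_len(ncol(combos))) {
    idx <- combos[, j]
    if (sum(idx) >= best_sum) next
    cuts <- cand_cuts[idx]
    if (!mutually_spaced(cuts, min_spacing)) next
    if (length(fixed_cuts) &&
        !all(vapply(cuts, spacing_ok, logical(1), picked_cuts = fixed_cuts,
                    min_spacing = min_spacing))) next
    best <- idx; best_sum <- sum(idx)
  }
  best
}

greedy_spaced <- function(cand_cuts, k, fixed_cuts, min_spacing) {
  picked <- integer(0)
  for (i in seq_along(cand_cuts)) {
    if (length(picked) >= k) break
    prior <- c(fixed_cuts, cand_cuts[picked])
    if (!length(prior) || spacing_ok(cand_cuts[i], prior, min_spacing)) {
      picked <- c(picked, i)
    }
  }
  # local swap improvement: try to move any pick to a better-ranked
  # unpicked candidate while staying feasible
  repeat {
    improved <- FALSE
    for (p in rev(seq_along(picked))) {
      for (i in seq_len(picked[p] - 1L)) {
        if (i %in% picked) next
        trial <- sort(c(picked[-p], i))
        if (mutually_spaced(cand_cuts[trial], min_spacing) &&
            (!length(fixed_cuts) ||
             all(vapply(cand_cuts[trial], spacing_ok, logical(1),
                        picked_cuts = fixed_cuts,
                        min_spacing = min_spacing)))) {
          picked <- trial; improved <- TRUE; break
        }
      }
      if (improved) break
    }
    if (!improved) break
  }
  picked
}

#' Pick a spaced guide set for one gene
#'
#' Implements the selection step: all tier-1 guides are included
#' unconditionally with the spacing constraint waived among them
#' (truncated by efficacy if they exceed the quota); remaining slots are
#' filled from the lower tiers to maximize summed (tier, efficacy) rank
#' subject to cut sites falling at least `min_spacing_nt` apart from
#' every prior pick, waived tier-1 picks included. With up to
#' `max_exhaustive` candidates the spacing problem is solved exactly by
#' subset search; above that a greedy pass with local swap improvement is
#' used. Ties break toward lower genomic coordinate. Genes with fewer
#' guides than the quota return all of them.
#'
#' @param gene_guides data.frame for one gene with columns `guide_id`,
#'   `gene_id`, `tier`, `efficacy`, `cut_position`.
#' @param criteria A [design_criteria()].
#' @return data.frame of picks: `gene_id`, `pick_index` (i, ii, ...),
#'   `guide_id`, `tier`, `rank_in_tier`, `efficacy`, `cut_position`,
#'   `spacing_waived`.
#' @export
pick_guides <- function(gene_guides, criteria = design_criteria()) {
  empty <- data.frame(gene_id = character(), pick_index = character(),
                      guide_id = character(), tier = character(),
                      rank_in_tier = integer(), efficacy = numeric(),
                      cut_position = integer(), spacing_waived = logical(),
                      stringsAsFactors = FALSE)
  if (!nrow(gene_guides)) {
    message("pick_guides: gene with zero candidate guides")
    return(empty)
  }
  stopifnot(length(unique(gene_guides$gene_id)) == 1L)
  g <- gene_guides[order(tier_rank(gene_guides$tier), -gene_guides$efficacy,
                         gene_guides$cut_position, gene_guides$guide_id), ,
                   drop = FALSE]
  quota <- criteria$picks_per_gene
  spacing <- criteria$min_spacing_nt

  is_t1 <- g$tier == "1"
  auto <- which(is_t1)
  if (length(auto) > quota) auto <- auto[seq_len(quota)]
  slots <- quota - length(auto)

  cand <- which(!seq_len(nrow(g)) %in% auto)
  chosen <- integer(0)
  if (slots > 0L && length(cand)) {
    cand_cuts <- g$cut_position[cand]
    fixed_cuts <- g$cut_position[auto]
    k <- min(slots, length(cand))
    if (length(cand) <= criteria$max_exhaustive) {
      while (k > 0L) {
        sel <- best_spaced_subset(cand_cuts, k, fixed_cuts, spacing)
        if (!is.null(sel)) { chosen <- cand[sel]; break }
        k <- k - 1L
      }
    } else {
      chosen <- cand[greedy_spaced(cand_cuts, k, fixed_cuts, spacing)]
    }
  }
  picks <- sort(c(auto, chosen))
  out <- g[picks, c("gene_id", "guide_id", "tier", "efficacy",
                    "cut_position"), drop = FALSE]
  out$spacing_waived <- picks %in% auto & g$tier[picks] == "1"
  # rank within tier by efficacy, over the gene's full candidate set
  out$rank_in_tier <- vapply(picks, function(i) {
    same <- which(g$tier == g$tier[i])
    match(i, same)
  }, integer(1))
  out$pick_index <- tolower(utils::as.roman(seq_len(nrow(out))))
  rownames(out) <- NULL
  out[c("gene_id", "pick_index", "guide_id", "tier", "rank_in_tier",
        "efficacy", "cut_position", "spacing_waived")]
}

#' Design a library across genes
#'
#' Applies [binarize_features()], [assign_tier()] and [pick_guides()] to
#' an annotated guide table. Guides without a CDS-mapped target
#' (`gene_id` NA) are dropped first.
#'
#' @param records Annotated guide data.frame (see [binarize_features()]
#'   for required columns, plus `gene_id` and `cut_position`).
#' @param criteria A [design_criteria()].
#' @param tier_table data.frame from [default_tier_table()].
#' @return data.frame of picks for all genes, with tier labels attached
#'   to `records` returned as attribute `"tiers"`.
#' @export
design_library <- function(records, criteria = design_criteria(),
                           tier_table = default_tier_table()) {
  records <- records[!is.na(records$gene_id), , drop = FALSE]
  mask <- binarize_features(records, criteria)
  records$tier <- assign_tier(mask, tier_table)
  picks <- do.call(rbind, lapply(split(records, records$gene_id),
                                 pick_guides, criteria = criteria))
  rownames(picks) <- NULL
  attr(picks, "tiers") <- records
  picks
}

#' Probability that a gene has at least k effective guides
#'
#' Binomial upper tail `P(X >= k)` with `X ~ Binomial(n, p)`: the chance
#' that at least `k` of a gene's `n` guides are effective when effective
#' guides fall at random with rate `p`. Quantifies how small gains in
#' per-guide effectiveness compound at the gene level, e.g. moving from
#' an 80% to a 90% effective rate raises the share of genes with at
#' least 3 of 4 effective guides from 81.9% to 94.8%.
#'
#' @param n Guides per gene.
#' @param k Required effective guides.
#' @param p Per-guide effective rate in \[0, 1\].
#' @return Probability.
#' @export
genes_with_at_least_k_effective <- function(n, k, p) {
  stopifnot(p >= 0, p <= 1, k >= 0, k <= n)
  if (k == 0) return(1.0)
  pbinom(k - 1, n, p, lower.tail = FALSE)
}
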