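#' Z-score screen fold changes within experiment and gene
#'
#' Converts guide-level log2 fold changes to z-scores within each
#' (experiment, gene) group: `z = (lfc - mean) / sd` with the sample
#' (n-1) standard deviation, so different experiments and differently
#' essential genes become comparable. Groups with fewer than two guides,
#' or zero spread, are dropped with a message. Enrichment-readout
#' experiments are expected to arrive already sign-inverted into
#' negative fold changes.
#'
#' @param records data.frame with columns `experiment_id`, `gene_id`,
#'   `guide_id`, `lfc`.
#' @return The surviving records with a `z` column appended; within each
#'   retained group `mean(z) == 0` and `sd(z) == 1`.
#' @export
zscore_by_group <- function(records) {
  stopifnot(all(c("experiment_id", "gene_id", "lfc") %in% names(records)))
  key <- interaction(records$experiment_id, records$gene_id, drop = TRUE)
  out <- lapply(split(records, key), function(grp) {
    if (nrow(grp) < 2L) return(NULL)
    s <- sd(grp$lfc)
    if (!is.finite(s) || s == 0) return(NULL)
    grp$z <- (grp$lfc - mean(grp$lfc)) / s
    grp
  })
  dropped <- sum(vapply(out, is.null, logical(1)))
  if (dropped > 0L) {
    message("zscore_by_group: dropped ", dropped,
            " group(s) with < 2 guides or zero spread")
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}

#' Apply the training-set inclusion filters
#'
#' Restricts training records to guides that target coding sequence and
#' target it specifically (genome-wide specificity score > 0.50 and zero
#' off-targets within one mismatch). Stage counts are reported with a
#' message.
#'
#' @param records Training records with a `guide_id` column.
#' @param feature_db Annotated guide table carrying `guide_id`,
#'   `gene_id` (NA for non-coding cuts), `specificity`, `mm0`, `mm1`,
#'   `exceeded_5000`.
#' @return The filtered records.
#' @export
apply_training_filters <- function(records, feature_db) {
  n0 <- nrow(records)
  idx <- match(records$guide_id, feature_db$guide_id)
  if (anyNA(idx)) {
    stop("training records reference guide_ids absent from the feature db")
  }
  db <- feature_db[idx, , drop = FALSE]
  coding <- !is.na(db$gene_id)
  records <- records[coding, , drop = FALSE]
  db <- db[coding, , drop = FALSE]
  n1 <- nrow(records)
  specific <- passes_specificity_filter(db)
  records <- records[specific, , drop = FALSE]
  message("apply_training_filters: ", n0, " -> ", n1,
          " (coding) -> ", nrow(records), " (specific)")
  rownames(records) <- NULL
  records
}

# R^2 machinery shared by the LMG decomposition: precomputed cross
# products make each subset R^2 a small linear solve.
make_r2_fun <- function(X, y) {
  n <- length(y)
  Xi <- cbind(`(Intercept)` = 1, X)
  G <- crossprod(Xi)
  g <- crossprod(Xi, y)
  yty <- sum(y^2)
  tss <- yty - n * mean(y)^2
  function(cols) {
    idx <- c(1L, cols + 1L)
    beta <- tryCatch(solve(G[idx, idx, drop = FALSE], g[idx, , drop = FALSE]),
                     error = function(e) qr.solve(G[idx, idx, drop = FALSE],
                                                  g[idx, , drop = FALSE]))
    rss <- yty - sum(beta * g[idx, ])
    max(0, 1 - rss / tss)
  }
}

#' LMG relative importance of predictor groups
#'
#' Decomposes a linear model's R-squared into non-negative per-predictor
#' shares by averaging each predictor's incremental R-squared over all
#' orderings of model entry (the LMG decomposition). Factors enter and
#' leave as whole dummy-column groups. With at most `exact_max` groups
#' every subset is enumerated and the shares sum to the model R-squared
#' exactly; beyond that a fixed-seed Monte Carlo average over orderings
#' is used.
#'
#' @param X Numeric model matrix without intercept.
#' @param y Response vector.
#' @param groups Integer vector mapping columns of `X` to predictor
#'   groups.
#' @param group_names Names of the groups.
#' @param exact_max Group count up to which exact enumeration is used
#'   (default 15).
#' @param n_orders Monte Carlo orderings (default 10000).
#' @param mc_seed Seed for the Monte Carlo path (default 1).
#' @return data.frame with columns `feature`, `lmg` (share of R-squared),
#'   `pct` (share / total); attribute `"r_squared"`.
#' @export
lmg_importance <- function(X, y, groups, group_names = NULL,
                           exact_max = 15L, n_orders = 10000L,
                           mc_seed = 1L) {
  p <- length(unique(groups))
  if (is.null(group_names)) group_names <- paste0("g", seq_len(p))
  stopifnot(length(group_names) == p)
  cols_of <- split(seq_len(ncol(X)), groups)
  r2 <- make_r2_fun(X, y)
  r2_total <- r2(seq_len(ncol(X)))
  shares <- numeric(p)

  if (p <= exact_max) {
    # R^2 for every subset of groups, then the exact weighted sums
    n_sub <- 2^p
    r2_cache <- numeric(n_sub)
    for (s in 0:(n_sub - 1L)) {
      members <- which(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
      r2_cache[s + 1L] <- if (length(members)) {
        r2(unlist(cols_of[members]))
      } else 0
    }
    lw <- lfactorial(0:p)
    for (j in seq_len(p)) {
      bit_j <- bitwShiftL(1L, j - 1L)
      acc <- 0
      for (s in 0:(n_sub - 1L)) {
        if (bitwAnd(s, bit_j) != 0L) next
        size <- sum(bitwAnd(s, bitwShiftL(1L, 0:(p - 1L))) != 0L)
        w <- exp(lw[size + 1L] + lw[p - size] - lw[p + 1L])
        acc <- acc + w * (r2_cache[s + bit_j + 1L] - r2_cache[s + 1L])
      }
      shares[j] <- acc
    }
  } else {
    cache <- new.env(hash = TRUE, parent = emptyenv())
    r2_of <- function(members) {
      if (!length(members)) return(0)
      key <- paste(sort(members), collapse = ",")
      val <- cache[[key]]
      if (is.null(val)) {
        val <- r2(unlist(cols_of[members]))
        cache[[key]] <- val
      }
      val
    }
    old <- if (exists(".Random.seed", globalenv())) {
      get(".Random.seed", globalenv())
    } else NULL
    on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
    set.seed(mc_seed)
    for (o in seq_len(n_orders)) {
      ord <- sample.int(p)
      prev <- 0
      members <- integer(0)
      for (j in ord) {
        members <- c(members, j)
        cur <- r2_of(members)
        shares[j] <- shares[j] + (cur - prev)
        prev <- cur
      }
    }
    shares <- shares / n_orders
  }
  out <- data.frame(feature = group_names, lmg = shares,
                    pct = if (r2_total > 0) shares / r2_total else NA_real_,
                    stringsAsFactors = FALSE)
  attr(out, "r_squared") <- r2_total
  out
}

#' Fit the guide-feature linear model with relative importance
#'
#' Ordinary least squares of z-scored guide activity on guide and target
#' features, with categorical predictors expanded to dummies, plus the
#' LMG decomposition of R-squared into per-feature importance shares.
#' Aliased (rank-deficient) columns are dropped with a warning.
#'
#' @param data data.frame containing the response and predictor columns.
#' @param response Response column name (default `"z"`).
#' @param predictors Character vector of predictor column names; default
#'   all columns except the response and obvious identifiers.
#' @param exact_max,n_orders,mc_seed Passed to [lmg_importance()].
#' @return List with `fit` (the `lm`), `coefficients`, `r_squared`,
#'   `importance` (data.frame from [lmg_importance()]), `n`.
#' @export
fit_feature_model <- function(data, response = "z", predictors = NULL,
                              exact_max = 15L, n_orders = 10000L,
                              mc_seed = 1L) {
  if (is.null(predictors)) {
    predictors <- setdiff(names(data),
                          c(response, "guide_id", "gene_id",
                            "experiment_id", "lfc"))
  }
  stopifnot(response %in% names(data), all(predictors %in% names(data)))
  df <- data[c(response, predictors)]
  df <- df[complete.cases(df), , drop = FALSE]
  for (col in predictors) {
    if (is.character(df[[col]])) df[[col]] <- factor(df[[col]])
  }
  # drop constant predictors (cannot enter the model)
  const <- vapply(predictors, function(col) {
    length(unique(df[[col]])) < 2L
  }, logical(1))
  if (any(const)) {
    warning("dropping constant predictor(s): ",
            paste(predictors[const], collapse = ", "))
    predictors <- predictors[!const]
  }
  fml <- as.formula(paste(response, "~",
                          paste(sprintf("`%s`", predictors), collapse = " + ")))
  fit <- lm(fml, data = df)
  aliased <- names(coef(fit))[is.na(coef(fit))]
  X <- model.matrix(fit)[, -1, drop = FALSE]
  assign_map <- attr(model.matrix(fit), "assign")[-1]
  if (length(aliased)) {
    warning("dropping aliased column(s): ", paste(aliased, collapse = ", "))
    keep <- !colnames(X) %in% aliased
    X <- X[, keep, drop = FALSE]
    assign_map <- assign_map[keep]
  }
  y <- df[[response]]
  groups <- match(assign_map, sort(unique(assign_map)))
  group_names <- predictors[sort(unique(assign_map))]
  imp <- lmg_importance(X, y, groups, group_names,
                        exact_max = exact_max, n_orders = n_orders,
                        mc_seed = mc_seed)
  list(fit = fit, coefficients = coef(fit),
       r_squared = summary(fit)$r.squared, importance = imp,
       n = nrow(df))
}

#' Median activity difference versus feature prevalence
#'
#' For each binary feature: the difference in median z-score between
#' guides possessing and lacking the feature, paired with the fraction of
#' guides in a reference universe that possess it. Strong negative
#' predictors that a linear model dilutes (rare but deadly features)
#' stand out in this view. Features constant within the training records
#' are reported with `NA` difference.
#'
#' @param records Training records with a `z` column and the feature
#'   columns.
#' @param binary_features Character vector of logical feature columns.
#' @param universe Optional reference guide table for prevalence
#'   (defaults to `records`); production use passes the genome-wide
#'   feature database here.
#' @return data.frame with columns `feature`, `delta_median`,
#'   `prevalence`, `n_present`, `n_absent`.
#' @export
median_diff_vs_prevalence <- function(records, binary_features,
                                      universe = records) {
  rows <- lapply(binary_features, function(f) {
    x <- as.logical(records[[f]])
    z <- records$z
    n1 <- sum(x, na.rm = TRUE)
    n0 <- sum(!x, na.rm = TRUE)
    dm <- if (n1 == 0L || n0 == 0L) NA_real_ else {
      median(z[x], na.rm = TRUE) - median(z[!x], na.rm = TRUE)
    }
    data.frame(feature = f, delta_median = dm,
               prevalence = mean(as.logical(universe[[f]]), na.rm = TRUE),
               n_present = n1, n_absent = n0, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Screen dropout metrics
#'
#' Computes reads-per-million for each sample, rescales every sample so
#' the summed RPM of guides targeting negative-control genes is identical
#' across samples (removing global fitness effects of Cas9 cutting),
#' then per-library guide log2 fold changes
#' `log2((RPM_end + c) / (RPM_ref + c))` against the library's averaged
#' reference samples, gene-level mean LFCs, intra-gene coefficients of
#' variation (sd / |mean| of guide LFCs), and hit flags (gene LFC below
#' -1, i.e. a mean dropout of more than 2-fold, in at least one library).
#'
#' @param counts Matrix or data.frame of raw counts, guides in rows
#'   (rownames or a `guide_id` column), samples in columns.
#' @param design data.frame with columns `sample`, `library`, `role`
#'   (`"reference"` or `"endpoint"`).
#' @param gene_map data.frame with columns `guide_id`, `gene_id`.
#' @param negative_controls Character vector of negative-control gene
#'   ids.
#' @param pseudocount Pseudocount `c` in RPM units (default 0.5).
#' @return List with `rpm` (normalized matrix), `guide_lfc` (data.frame
#'   guide x library), `gene_stats` (`gene_id`, `library`, `lfc`, `cv`,
#'   `n_guides`), `hits` (`gene_id`, `hit`).
#' @export
screen_dropout_metrics <- function(counts, design, gene_map,
                                   negative_controls, pseudocount = 0.5) {
  if (is.data.frame(counts)) {
    if ("guide_id" %in% names(counts)) {
      rn <- counts$guide_id
      counts <- as.matrix(counts[setdiff(names(counts), "guide_id")])
      rownames(counts) <- rn
    } else {
      counts <- as.matrix(counts)
    }
  }
  stopifnot(all(design$sample %in% colnames(counts)),
            all(design$role %in% c("reference", "endpoint")))
  counts <- counts[, design$sample, drop = FALSE]
  genes <- gene_map$gene_id[match(rownames(counts), gene_map$guide_id)]
  if (anyNA(genes)) stop("counts contain guides absent from gene_map")
  rpm <- sweep(counts, 2, colSums(counts), "/") * 1e6
  nc_rows <- genes %in% negative_controls
  if (!any(nc_rows)) stop("no guides target negative-control genes")
  nc_mass <- colSums(rpm[nc_rows, , drop = FALSE])
  rpm <- sweep(rpm, 2, mean(nc_mass) / nc_mass, "*")

  libs <- unique(design$library)
  guide_lfc <- matrix(NA_real_, nrow(rpm), length(libs),
                      dimnames = list(rownames(rpm), libs))
  for (lib in libs) {
    refs <- design$sample[design$library == lib & design$role == "reference"]
    ends <- design$sample[design$library == lib & design$role == "endpoint"]
    if (!length(refs) || !length(ends)) {
      stop("library ", lib, " needs at least one reference and one endpoint")
    }
    ref_rpm <- rowMeans(rpm[, refs, drop = FALSE])
    lfc_mat <- vapply(ends, function(s) {
      log2((rpm[, s] + pseudocount) / (ref_rpm + pseudocount))
    }, numeric(nrow(rpm)))
    guide_lfc[, lib] <- rowMeans(lfc_mat)
  }

  gene_stats <- do.call(rbind, lapply(libs, function(lib) {
    per_gene <- tapply(guide_lfc[, lib], genes, function(v) {
      c(lfc = mean(v),
        cv = if (mean(v) == 0) NA_real_ else sd(v) / abs(mean(v)),
        n = length(v))
    })
    df <- as.data.frame(do.call(rbind, per_gene))
    data.frame(gene_id = names(per_gene), library = lib, lfc = df$lfc,
               cv = df$cv, n_guides = as.integer(df$n),
               stringsAsFactors = FALSE)
  }))
  rownames(gene_stats) <- NULL
  hit_by_gene <- tapply(gene_stats$lfc < -1, gene_stats$gene_id, any)
  hits <- data.frame(gene_id = names(hit_by_gene),
                     hit = as.logical(hit_by_gene),
                     stringsAsFactors = FALSE)
  rownames(hits) <- NULL
  list(rpm = rpm,
       guide_lfc = as.data.frame(guide_lfc),
       gene_stats = gene_stats, hits = hits)
}
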