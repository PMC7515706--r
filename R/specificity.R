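#' Position weights for mismatch scoring
#'
#' The experimentally derived 20-entry position-weight vector used for
#' single-site mismatch penalties (Hsu et al. style), indexed 1..20 with
#' position 1 PAM-distal. Shipped as a plain-text config so alternative
#' weight vectors can be swapped in.
#'
#' @param path Optional path to a TSV with columns `position`, `weight`;
#'   defaults to the packaged vector.
#' @return Numeric vector of length 20.
#' @export
hsu_weights <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "hsu_weights.tsv", package = "guideforge")
  }
  df <- read.delim(path, stringsAsFactors = FALSE)
  stopifnot(all(c("position", "weight") %in% names(df)))
  w <- df$weight[order(df$position)]
  if (length(w) != 20L || any(w < 0 | w > 1)) {
    stop("weight vector must have 20 entries in [0, 1]")
  }
  w
}

# All NGG-anchored 20-mer target sites in a sequence set, both strands.
# Unlike extract_guides() no flanking context is required, so sites near
# contig edges still count as potential off-targets.
enumerate_pam_sites <- function(seqs) {
  if (!inherits(seqs, "DNAStringSet")) {
    seqs <- Biostrings::DNAStringSet(toupper(unlist(seqs)))
  }
  rows <- lapply(names(seqs), function(contig) {
    chr <- as.character(seqs[[contig]])
    L <- nchar(chr)
    out <- list()
    q <- Biostrings::start(Biostrings::matchPattern("GG", seqs[[contig]])) - 1L
    q <- q[q >= 21L & q + 2L <= L]
    if (length(q)) {
      out$plus <- data.frame(
        contig = contig, strand = "+", start = q - 20L,
        protospacer = substring(chr, q - 20L, q - 1L),
        stringsAsFactors = FALSE
      )
    }
    x <- Biostrings::start(Biostrings::matchPattern("CC", seqs[[contig]]))
    x <- x[x >= 1L & x + 22L <= L]
    if (length(x)) {
      out$minus <- data.frame(
        contig = contig, strand = "-", start = x + 3L,
        protospacer = revcomp(substring(chr, x + 3L, x + 22L)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  sites <- do.call(rbind, rows)
  if (is.null(sites)) {
    sites <- data.frame(contig = character(), strand = character(),
                        start = integer(), protospacer = character(),
                        stringsAsFactors = FALSE)
  }
  sites <- sites[!grepl("N", sites$protospacer, fixed = TRUE), , drop = FALSE]
  sites[order(sites$contig, sites$start, sites$strand), , drop = FALSE]
}

#' Build a seeded off-target search index
#'
#' Indexes every NGG-anchored 20-mer site in the search space by its five
#' non-overlapping 4-mer chunks. By the pigeonhole principle a site within
#' Hamming distance 4 of a query shares at least one exact chunk, so seed
#' lookup plus Hamming verification finds all hits with up to four
#' mismatches.
#'
#' @param seqs Search space: a [Biostrings::DNAStringSet] or named
#'   character vector. A genome gives genome-wide specificity; a set of
#'   spliced coding sequences (see [cds_sequence_set()]) gives
#'   proteome-restricted specificity through the identical code path.
#' @return An `offtarget_index` object.
#' @export
build_offtarget_index <- function(seqs) {
  sites <- enumerate_pam_sites(seqs)
  n <- nrow(sites)
  mat <- if (n) {
    matrix(unlist(strsplit(sites$protospacer, "")), nrow = 20L)
  } else {
    matrix(character(), nrow = 20L)
  }
  seed_env <- new.env(hash = TRUE, parent = emptyenv())
  if (n) {
    for (ci in 1:5) {
      chunk <- substring(sites$protospacer, (ci - 1L) * 4L + 1L, ci * 4L)
      buckets <- split(seq_len(n), chunk)
      for (key in names(buckets)) {
        assign(paste0(ci, ":", key), buckets[[key]], envir = seed_env)
      }
    }
  }
  structure(list(sites = sites, mat = mat, seed_env = seed_env),
            class = "offtarget_index")
}

#' @export
print.offtarget_index <- function(x, ...) {
  cat(sprintf("<offtarget_index> %d NGG sites on %d contig(s)\n",
              nrow(x$sites), length(unique(x$sites$contig))))
  invisible(x)
}

#' Enumerate off-target sites of a guide
#'
#' Finds every NGG-anchored site in the indexed search space within
#' `max_mm` mismatches of the protospacer (Hamming distance; no bulges),
#' on both strands. Mismatch positions are protospacer indices 1..20 with
#' 1 PAM-distal. Enumeration is truncated at `max_hits` sites and flagged;
#' truncated guides are treated as non-specific downstream.
#'
#' @param guide One-row data.frame (or list) with `protospacer` and,
#'   for coordinate-based on-target identification, `contig`, `start`,
#'   `strand`.
#' @param index An `offtarget_index` from [build_offtarget_index()].
#' @param max_mm Maximum mismatches (default 4).
#' @param max_hits Truncation limit (default 5000).
#' @param on_target How to identify the guide's own site: `"coordinates"`
#'   matches contig/start/strand (genome search space); `"first_perfect"`
#'   marks one perfect-match hit as the origin (used when the search space
#'   is re-coordinatized, e.g. spliced CDS).
#' @return data.frame of hits ordered by (contig, position, strand):
#'   columns `contig`, `strand`, `position`, `m`, `is_on_target`, and a
#'   list-column `mismatch_positions`; attribute `exceeded` is TRUE when
#'   truncated.
#' @export
enumerate_offtargets <- function(guide, index, max_mm = 4L, max_hits = 5000L,
                                 on_target = c("coordinates", "first_perfect")) {
  on_target <- match.arg(on_target)
  proto <- guide$protospacer
  stopifnot(nchar(proto) == 20L)
  cand <- integer(0)
  for (ci in 1:5) {
    key <- paste0(ci, ":", substr(proto, (ci - 1L) * 4L + 1L, ci * 4L))
    hit <- index$seed_env[[key]]
    if (!is.null(hit)) cand <- c(cand, hit)
  }
  cand <- sort(unique(cand))
  empty <- data.frame(contig = character(), strand = character(),
                      position = integer(), m = integer(),
                      is_on_target = logical())
  empty$mismatch_positions <- list()
  if (!length(cand)) {
    attr(empty, "exceeded") <- FALSE
    return(empty)
  }
  gchars <- strsplit(proto, "")[[1]]
  mm_mat <- index$mat[, cand, drop = FALSE] != gchars
  m <- colSums(mm_mat)
  keep <- which(m <= max_mm)
  if (!length(keep)) {
    attr(empty, "exceeded") <- FALSE
    return(empty)
  }
  hits <- index$sites[cand[keep], , drop = FALSE]
  hits <- data.frame(contig = hits$contig, strand = hits$strand,
                     position = hits$start, m = as.integer(m[keep]),
                     stringsAsFactors = FALSE)
  hits$mismatch_positions <- lapply(keep, function(j) which(mm_mat[, j]))
  ord <- order(hits$contig, hits$position, hits$strand)
  hits <- hits[ord, , drop = FALSE]
  exceeded <- nrow(hits) > max_hits
  if (exceeded) hits <- hits[seq_len(max_hits), , drop = FALSE]
  hits$is_on_target <- FALSE
  if (on_target == "coordinates") {
    self <- hits$m == 0L & hits$contig == guide$contig &
      hits$position == guide$start & hits$strand == guide$strand
    hits$is_on_target <- self
  } else {
    first0 <- which(hits$m == 0L)[1]
    if (!is.na(first0)) hits$is_on_target[first0] <- TRUE
  }
  rownames(hits) <- NULL
  attr(hits, "exceeded") <- exceeded
  hits
}

#' Single off-target site score
#'
#' The MIT-style single-site score: the product over mismatches of
#' `(1 - W[p])`, times a distance factor `1 / (((19 - dbar) / 19) * 4 + 1)`
#' where `dbar` is the mean pairwise distance between mismatch positions,
#' times `1 / m^2`. With fewer than two mismatches the distance factor and
#' `1/m^2` are both defined as 1 (the formula's limit), so a perfect match
#' scores 1.0 (a duplicate perfect site is maximally dangerous) and a
#' single mismatch scores `1 - W[p]`.
#'
#' @param mismatch_positions Integer vector of protospacer positions
#'   (1..20, 1 PAM-distal); empty for a perfect match.
#' @param W Position-weight vector from [hsu_weights()].
#' @return Score in \[0, 1\].
#' @export
hsu_single_offtarget_score <- function(mismatch_positions, W = hsu_weights()) {
  p <- sort(as.integer(mismatch_positions))
  if (length(p) && (min(p) < 1L || max(p) > 20L)) {
    stop("mismatch positions must lie in 1..20")
  }
  m <- length(p)
  if (m == 0L) return(1.0)
  wterm <- prod(1 - W[p])
  if (m == 1L) return(wterm)
  dbar <- mean(as.numeric(stats::dist(p, method = "manhattan")))
  wterm * (1 / (((19 - dbar) / 19) * 4 + 1)) * (1 / m^2)
}

#' Aggregate off-target hits into a specificity score
#'
#' `100 / (100 + sum_i 100 * s_i)` over all non-on-target hits, rescaled
#' to \[0, 1\]: 1.0 for a guide with no off-targets, strictly decreasing
#' as off-target scores accumulate, 0.5 when a second perfect-match site
#' exists.
#'
#' @param hits data.frame from [enumerate_offtargets()].
#' @param W Position-weight vector from [hsu_weights()].
#' @return Specificity in \[0, 1\].
#' @export
aggregate_specificity <- function(hits, W = hsu_weights()) {
  off <- hits[!hits$is_on_target, , drop = FALSE]
  if (!nrow(off)) return(1.0)
  s <- vapply(off$mismatch_positions, hsu_single_offtarget_score, numeric(1),
              W = W)
  1 / (1 + sum(s))
}

#' Per-guide specificity records
#'
#' Runs the seeded off-target search for each guide over a genome-wide
#' index and (optionally) a coding-sequence index, and aggregates scores
#' and mismatch histograms.
#'
#' @param guides data.frame from [extract_guides()].
#' @param index Genome-wide `offtarget_index`.
#' @param cds_index Optional `offtarget_index` over spliced coding
#'   sequences for proteome-restricted specificity.
#' @param W Position-weight vector.
#' @param max_mm,max_hits Passed to [enumerate_offtargets()].
#' @return data.frame with columns `guide_id`, `specificity`,
#'   `proteome_specificity` (NA when no `cds_index`), `mm0`..`mm4`,
#'   `exceeded_5000`.
#' @export
compute_specificity <- function(guides, index, cds_index = NULL,
                                W = hsu_weights(), max_mm = 4L,
                                max_hits = 5000L) {
  res <- lapply(seq_len(nrow(guides)), function(i) {
    g <- guides[i, ]
    hits <- enumerate_offtargets(g, index, max_mm, max_hits, "coordinates")
    mm <- tabulate(hits$m + 1L, nbins = 5L)
    spec <- aggregate_specificity(hits, W)
    pspec <- NA_real_
    if (!is.null(cds_index)) {
      chits <- enumerate_offtargets(g, cds_index, max_mm, max_hits,
                                    "first_perfect")
      pspec <- aggregate_specificity(chits, W)
    }
    data.frame(guide_id = g$guide_id, specificity = spec,
               proteome_specificity = pspec,
               mm0 = mm[1], mm1 = mm[2], mm2 = mm[3], mm3 = mm[4],
               mm4 = mm[5],
               exceeded_5000 = isTRUE(attr(hits, "exceeded")),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Hard specificity filter
#'
#' A guide targets specifically when its genome-wide specificity score
#' exceeds 0.50 (strict) and it has zero off-targets with at most one
#' mismatch (only its own perfect site at m <= 1), without having
#' exceeded the alignment cap.
#'
#' @param record One-row data.frame (or multi-row, vectorized) from
#'   [compute_specificity()].
#' @param specificity_min Score threshold (default 0.50, strict).
#' @param close_offtarget_mm Mismatch radius that must be free of
#'   off-targets (default 1).
#' @return Logical vector.
#' @export
passes_specificity_filter <- function(record, specificity_min = 0.50,
                                      close_offtarget_mm = 1L) {
  close_ok <- record$mm0 == 1L
  if (close_offtarget_mm >= 1L) close_ok <- close_ok & record$mm1 == 0L
  record$specificity > specificity_min & close_ok & !record$exceeded_5000
}

#' Spliced coding sequences for proteome-restricted search
#'
#' @param transcripts List from [read_transcripts()].
#' @param genome Genome from [read_genome()].
#' @param principal_only Restrict to principal isoforms (default TRUE).
#' @return Named character vector (names are transcript ids) usable as
#'   the search space of [build_offtarget_index()].
#' @export
cds_sequence_set <- function(transcripts, genome, principal_only = TRUE) {
  if (principal_only) {
    transcripts <- Filter(function(tx) tx$is_principal, transcripts)
  }
  vapply(transcripts, spliced_cds, character(1), genome = genome)
}
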