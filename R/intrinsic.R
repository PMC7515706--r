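#' Synthesized construct context for intrinsic features
#'
#' Homopolymer runs and Esp3I sites are scored over the sequence that is
#' actually synthesized and transcribed: vector sequence 5' of the
#' protospacer plus the sgRNA scaffold 3' of it, so runs and sites spanning
#' the junctions are caught. The defaults cover the junction-proximal
#' bases: the U6-cassette cloning overhang ACCG upstream and the first two
#' scaffold bases GT downstream. The window deliberately stops before the
#' scaffold's own internal T-run, which every construct shares and which
#' therefore carries no per-guide information; widen the flanks to scan
#' more of a specific vector. Pass empty strings to score the bare
#' protospacer.
#'
#' @param upstream_flank DNA string 5' of the protospacer.
#' @param downstream_flank DNA string 3' of the protospacer.
#' @return List with elements `upstream_flank`, `downstream_flank`.
#' @export
construct_context <- function(upstream_flank = "ACCG",
                              downstream_flank = "GT") {
  stopifnot(is.character(upstream_flank), is.character(downstream_flank))
  list(upstream_flank = toupper(upstream_flank),
       downstream_flank = toupper(downstream_flank))
}

construct_seq <- function(protospacer, context) {
  paste0(context$upstream_flank, protospacer, context$downstream_flank)
}

#' Maximum homopolymer run lengths in the guide construct
#'
#' Computes, for each base, the longest run of that base anywhere in
#' upstream flank + protospacer + downstream flank; runs spanning the
#' guide/flank junctions count. PolyT matters most: runs of three or more
#' thymidines terminate RNA Pol III transcription of the sgRNA.
#'
#' @param protospacer 20-nt protospacer (vectorized).
#' @param context A [construct_context()].
#' @return data.frame with columns `polyA`, `polyC`, `polyG`, `polyT`
#'   (one row per protospacer).
#' @export
max_homopolymer_runs <- function(protospacer, context = construct_context()) {
  res <- t(vapply(protospacer, function(p) {
    r <- rle(strsplit(construct_seq(p, context), "")[[1]])
    vapply(c("A", "C", "G", "T"), function(b) {
      runs <- r$lengths[r$values == b]
      if (length(runs)) max(runs) else 0L
    }, integer(1))
  }, integer(4)))
  out <- as.data.frame(res)
  names(out) <- c("polyA", "polyC", "polyG", "polyT")
  rownames(out) <- NULL
  out
}

ESP3I_SITE <- "CGTCTC"

#' Detect inadvertent Esp3I restriction sites in the construct
#'
#' Esp3I (BsmBI) sites inside the synthesized construct are cleaved during
#' library cloning and cause guide dropout. Since restriction of
#' double-stranded DNA is strand-symmetric, both CGTCTC and its reverse
#' complement GAGACG are flagged by default; set `both_strands = FALSE`
#' to scan only the literal CGTCTC motif.
#'
#' @inheritParams max_homopolymer_runs
#' @param both_strands Scan the reverse-complement motif too?
#' @return Logical vector.
#' @export
has_esp3i_site <- function(protospacer, context = construct_context(),
                           both_strands = TRUE) {
  construct <- vapply(protospacer, construct_seq, character(1),
                      context = context)
  hit <- grepl(ESP3I_SITE, construct, fixed = TRUE)
  if (both_strands) {
    hit <- hit | grepl(revcomp(ESP3I_SITE), construct, fixed = TRUE)
  }
  unname(hit)
}

# Allawi & SantaLucia (1997) unified nearest-neighbor parameters.
# dH in kcal/mol, dS in cal/(mol K); complementary steps share values.
NN_DH <- c(AA = -7.9, TT = -7.9, AT = -7.2, TA = -7.2,
           CA = -8.5, TG = -8.5, GT = -8.4, AC = -8.4,
           CT = -7.8, AG = -7.8, GA = -8.2, TC = -8.2,
           CG = -10.6, GC = -9.8, GG = -8.0, CC = -8.0)
NN_DS <- c(AA = -22.2, TT = -22.2, AT = -20.4, TA = -21.3,
           CA = -22.7, TG = -22.7, GT = -22.4, AC = -22.4,
           CT = -21.0, AG = -21.0, GA = -22.2, TC = -22.2,
           CG = -27.2, GC = -24.4, GG = -19.9, CC = -19.9)

#' Nearest-neighbor DNA melting temperature
#'
#' Unified nearest-neighbor thermodynamics (Allawi & SantaLucia 1997):
#' `Tm = 1000 * dH / (dS + R * ln(Ct / 4)) - 273.15`, summing stack
#' enthalpies/entropies plus the two terminal initiation terms, with the
#' entropic salt correction `dS += 0.368 * (n - 1) * ln([Na+])`. Absolute
#' values shift with the assumed conditions; the rank order across guides
#' is what the design pipeline uses.
#'
#' @param seq DNA string(s), ACGT only.
#' @param ct Total strand concentration in M (default 0.25 uM).
#' @param na Monovalent cation concentration in M (default 50 mM).
#' @return Numeric vector of melting temperatures in degrees Celsius.
#' @export
melting_temperature <- function(seq, ct = 0.25e-6, na = 0.05) {
  vapply(toupper(seq), function(s) {
    bases <- strsplit(s, "")[[1]]
    if (!all(bases %in% c("A", "C", "G", "T"))) {
      stop("melting_temperature requires ACGT sequence, got: ", s)
    }
    n <- length(bases)
    if (n < 2) stop("sequence too short for nearest-neighbor model")
    steps <- paste0(bases[-n], bases[-1])
    dh <- sum(NN_DH[steps])
    ds <- sum(NN_DS[steps])
    for (term in bases[c(1, n)]) {
      if (term %in% c("G", "C")) {
        dh <- dh + 0.1; ds <- ds - 2.8
      } else {
        dh <- dh + 2.3; ds <- ds + 4.1
      }
    }
    ds <- ds + 0.368 * (n - 1) * log(na)
    1000 * dh / (ds + 1.9872 * log(ct / 4)) - 273.15
  }, numeric(1), USE.NAMES = FALSE)
}

#' Efficacy scorer backed by a precomputed table
#'
#' Cleavage-efficacy prediction is pluggable: production databases join in
#' scores from an external gradient-boosted model via this table scorer.
#'
#' @param table data.frame with columns `guide_id`, `efficacy`, or a path
#'   to a TSV with those columns.
#' @param default Value used for guides absent from the table; `NULL`
#'   (the default) makes missing guides an error.
#' @return An `efficacy_scorer` object.
#' @export
efficacy_scorer_table <- function(table, default = NULL) {
  if (is.character(table)) table <- read.delim(table, stringsAsFactors = FALSE)
  stopifnot(all(c("guide_id", "efficacy") %in% names(table)))
  if (any(table$efficacy < 0 | table$efficacy > 1)) {
    stop("efficacy values must lie in [0, 1]")
  }
  structure(list(mode = "table",
                 scores = setNames(table$efficacy, table$guide_id),
                 default = default),
            class = "efficacy_scorer")
}

#' Deterministic surrogate efficacy scorer
#'
#' A fixed position-weighted arithmetic hash of the 30-nt context, mapped
#' near-uniformly to \[0, 1\]. It is a stand-in for external trained
#' efficacy models in fixtures and examples: deterministic and
#' well-spread, but carrying no biological signal. Not for designing real
#' libraries.
#'
#' @return An `efficacy_scorer` object.
#' @export
efficacy_scorer_surrogate <- function() {
  structure(list(mode = "surrogate"), class = "efficacy_scorer")
}

surrogate_score <- function(context30) {
  vapply(context30, function(ctx) {
    bases <- strsplit(ctx, "")[[1]]
    b <- match(bases, c("A", "C", "G", "T"))  # N -> NA
    b[is.na(b)] <- 0L
    pos <- seq_along(b)
    # position-weighted arithmetic hash, near-uniform on [0, 1]
    (sum(((b * 31 + pos * 17) %% 101) * pos) %% 1009) / 1008
  }, numeric(1), USE.NAMES = FALSE)
}

#' Score guide cleavage efficacy
#'
#' @param guides data.frame with `guide_id` and `context30` columns.
#' @param scorer An `efficacy_scorer` from [efficacy_scorer_table()] or
#'   [efficacy_scorer_surrogate()].
#' @return Numeric vector of efficacy scores in \[0, 1\].
#' @export
efficacy_score <- function(guides, scorer = efficacy_scorer_surrogate()) {
  stopifnot(inherits(scorer, "efficacy_scorer"))
  if (scorer$mode == "surrogate") {
    return(surrogate_score(guides$context30))
  }
  vals <- unname(scorer$scores[guides$guide_id])
  if (anyNA(vals)) {
    if (is.null(scorer$default)) {
      stop("no efficacy score for guide_id(s): ",
           paste(guides$guide_id[is.na(vals)], collapse = ", "))
    }
    vals[is.na(vals)] <- scorer$default
  }
  vals
}

#' Annotate intrinsic guide features
#'
#' Convenience wrapper adding homopolymer runs, Esp3I flag, melting
#' temperature, and efficacy columns to a guide table.
#'
#' @param guides data.frame from [extract_guides()].
#' @param context A [construct_context()].
#' @param scorer An `efficacy_scorer`.
#' @return The guide table with columns `polyA`, `polyC`, `polyG`,
#'   `polyT`, `has_esp3i`, `tm_celsius`, `efficacy` appended.
#' @export
intrinsic_features <- function(guides, context = construct_context(),
                               scorer = efficacy_scorer_surrogate()) {
  runs <- max_homopolymer_runs(guides$protospacer, context)
  guides$polyA <- runs$polyA
  guides$polyC <- runs$polyC
  guides$polyG <- runs$polyG
  guides$polyT <- runs$polyT
  guides$has_esp3i <- has_esp3i_site(guides$protospacer, context)
  guides$tm_celsius <- melting_temperature(guides$protospacer)
  guides$efficacy <- efficacy_score(guides, scorer)
  guides
}
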