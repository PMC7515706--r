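#' Read an ortholog protein set from FASTA
#'
#' One FASTA per gene (directory convention `<gene_id>.fa`), one record
#' per ortholog. By default each sequence forms its own cluster; see
#' [cluster_orthologs()] for identity-based clustering that down-weights
#' near-duplicate orthologs.
#'
#' @param fasta_path Path to the protein FASTA.
#' @param gene_id Gene identifier; defaults to the file name stem.
#' @return An `ortholog_set`: list with `gene_id`, `sequences` (named
#'   character vector), `clusters` (integer vector parallel to
#'   `sequences`).
#' @export
read_ortholog_set <- function(fasta_path, gene_id = NULL) {
  if (is.null(gene_id)) {
    gene_id <- sub("\\.(fa|fasta|faa)$", "", basename(fasta_path))
  }
  aa <- Biostrings::readAAStringSet(fasta_path)
  ortholog_set(as.character(aa), gene_id)
}

#' Construct an ortholog set from sequences
#'
#' @param sequences Named character vector of protein sequences (standard
#'   20-letter alphabet; X tolerated).
#' @param gene_id Gene identifier.
#' @param clusters Optional integer cluster assignment (defaults to one
#'   cluster per sequence).
#' @return An `ortholog_set` object.
#' @export
ortholog_set <- function(sequences, gene_id, clusters = NULL) {
  sequences <- toupper(sequences)
  if (!length(sequences) || any(!nzchar(sequences))) {
    stop("ortholog set must contain non-empty sequences")
  }
  if (is.null(names(sequences))) {
    names(sequences) <- paste0("ortholog_", seq_along(sequences))
  }
  if (is.null(clusters)) clusters <- seq_along(sequences)
  stopifnot(length(clusters) == length(sequences))
  structure(list(gene_id = gene_id, sequences = sequences,
                 clusters = as.integer(clusters)),
            class = "ortholog_set")
}

#' @export
print.ortholog_set <- function(x, ...) {
  cat(sprintf("<ortholog_set> %s: %d sequence(s) in %d cluster(s)\n",
              x$gene_id, length(x$sequences), length(unique(x$clusters))))
  invisible(x)
}

#' Greedy identity clustering of an ortholog set
#'
#' Assigns each sequence to the first existing cluster whose seed it
#' matches at or above `identity_min` percent identity (computed on the
#' semi-global alignment), else starts a new cluster. Clustering
#' near-identical orthologs keeps redundant sequences from dominating the
#' averaged delta scores.
#'
#' @param set An `ortholog_set`.
#' @param identity_min Fractional identity threshold (default 0.75).
#' @return The set with `clusters` reassigned.
#' @export
cluster_orthologs <- function(set, identity_min = 0.75) {
  n <- length(set$sequences)
  clusters <- integer(n)
  seeds <- integer(0)
  for (i in seq_len(n)) {
    assigned <- FALSE
    for (k in seq_along(seeds)) {
      aln <- Biostrings::pairwiseAlignment(
        Biostrings::AAString(set$sequences[[i]]),
        Biostrings::AAString(set$sequences[[seeds[k]]]),
        substitutionMatrix = get_aa_matrix("BLOSUM62"),
        gapOpening = 10, gapExtension = 1, type = "global-local"
      )
      if (Biostrings::pid(aln) / 100 >= identity_min) {
        clusters[i] <- k
        assigned <- TRUE
        break
      }
    }
    if (!assigned) {
      seeds <- c(seeds, i)
      clusters[i] <- length(seeds)
    }
  }
  set$clusters <- clusters
  set
}

#' Identity substitution matrix (+5 match / -2 mismatch)
#'
#' A simple alternative to BLOSUM62 for sensitivity analysis of the
#' conservation score: +5 for identical residues, -2 otherwise.
#'
#' @return Square numeric matrix over the amino-acid alphabet.
#' @export
identity_aa_matrix <- function() {
  alphabet <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
                "M", "F", "P", "S", "T", "W", "Y", "V", "B", "Z", "X", "*")
  m <- matrix(-2, length(alphabet), length(alphabet),
              dimnames = list(alphabet, alphabet))
  diag(m) <- 5
  m
}

get_aa_matrix <- function(matrix) {
  if (is.matrix(matrix)) return(matrix)
  if (identical(matrix, "identity")) return(identity_aa_matrix())
  # named matrices shipped with Biostrings (BLOSUM62, PAM250, ...)
  e <- new.env()
  utils::data(list = matrix, package = "Biostrings", envir = e)
  get(matrix, envir = e)
}

#' Semi-global protein alignment score
#'
#' Optimal affine-gap alignment score with the query aligned end to end
#' and free end gaps at the query's termini (the subject may overhang
#' either end unpenalized). A gap of length L costs
#' `gap_open + gap_extend * L`. Defaults follow the usual
#' variant-effect-prediction setup: BLOSUM62, gap open 10, gap extend 1.
#'
#' @param query,subject Protein strings.
#' @param matrix Substitution matrix: a matrix, a Biostrings matrix name
#'   (default `"BLOSUM62"`), or `"identity"` for [identity_aa_matrix()].
#' @param gap_open,gap_extend Affine gap parameters.
#' @return Numeric alignment score.
#' @export
semiglobal_align_score <- function(query, subject, matrix = "BLOSUM62",
                                   gap_open = 10, gap_extend = 1) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAString(query), Biostrings::AAString(subject),
    substitutionMatrix = get_aa_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global-local", scoreOnly = TRUE
  )
}

# scores of many queries against one subject in a single call
semiglobal_scores_vec <- function(queries, subject, matrix, gap_open,
                                  gap_extend) {
  Biostrings::pairwiseAlignment(
    Biostrings::AAStringSet(queries), Biostrings::AAString(subject),
    substitutionMatrix = get_aa_matrix(matrix),
    gapOpening = gap_open, gapExtension = gap_extend,
    type = "global-local", scoreOnly = TRUE
  )
}

#' Alignment-delta score of a protein variant
#'
#' For each supporting ortholog, the variant's semi-global alignment
#' score minus the wild type's; deltas are averaged within each cluster
#' and the cluster means averaged. Negative deltas mean the variant
#' aligns worse than wild type against the ortholog set, i.e. the change
#' is predicted deleterious.
#'
#' @param protein Wild-type protein string.
#' @param variant_protein Variant protein string.
#' @param set An `ortholog_set`.
#' @inheritParams semiglobal_align_score
#' @return Numeric delta (0 exactly when variant equals wild type).
#' @export
delta_score <- function(protein, variant_protein, set, matrix = "BLOSUM62",
                        gap_open = 10, gap_extend = 1) {
  stopifnot(inherits(set, "ortholog_set"))
  if (identical(protein, variant_protein)) return(0)
  deltas <- vapply(set$sequences, function(subj) {
    semiglobal_align_score(variant_protein, subj, matrix, gap_open,
                           gap_extend) -
      semiglobal_align_score(protein, subj, matrix, gap_open, gap_extend)
  }, numeric(1))
  mean(tapply(deltas, set$clusters, mean))
}

#' Per-residue deletion-based conservation track
#'
#' Scores the deletion of every window of `deletion_width` consecutive
#' residues by its alignment delta against the ortholog set, negated so
#' larger positive values mean higher conservation. For widths above 1
#' each window's value is attributed to every residue in the window and
#' overlapping windows are averaged per residue.
#'
#' @param protein Protein string (no trailing stop).
#' @param set An `ortholog_set`.
#' @param deletion_width 1, 2, or 3 residues per deletion.
#' @inheritParams semiglobal_align_score
#' @return A `conservation_track`: list with `gene_id`, `scores` (length
#'   = protein length), `deletion_width`.
#' @export
aadelcons_track <- function(protein, set, deletion_width = 1L,
                            matrix = "BLOSUM62", gap_open = 10,
                            gap_extend = 1) {
  stopifnot(inherits(set, "ortholog_set"))
  w <- as.integer(deletion_width)
  stopifnot(w %in% 1:3)
  L <- nchar(protein)
  if (L <= w) stop("protein shorter than deletion width")
  n_win <- L - w + 1L
  variants <- vapply(seq_len(n_win), function(i) {
    paste0(substr(protein, 1L, i - 1L), substr(protein, i + w, L))
  }, character(1))
  # one vectorized alignment pass per ortholog
  delta_mat <- vapply(set$sequences, function(subj) {
    wt <- semiglobal_align_score(protein, subj, matrix, gap_open, gap_extend)
    semiglobal_scores_vec(variants, subj, matrix, gap_open, gap_extend) - wt
  }, numeric(n_win))
  if (n_win == 1L) delta_mat <- matrix(delta_mat, nrow = 1L)
  cluster_means <- t(apply(delta_mat, 1L, function(d) {
    tapply(d, set$clusters, mean)
  }))
  if (length(unique(set$clusters)) == 1L) cluster_means <- t(cluster_means)
  window_score <- -rowMeans(cluster_means)
  scores <- numeric(L)
  counts <- integer(L)
  for (i in seq_len(n_win)) {
    idx <- i:(i + w - 1L)
    scores[idx] <- scores[idx] + window_score[i]
    counts[idx] <- counts[idx] + 1L
  }
  structure(list(gene_id = set$gene_id, scores = scores / counts,
                 deletion_width = w),
            class = "conservation_track")
}

#' @export
print.conservation_track <- function(x, ...) {
  cat(sprintf("<conservation_track> %s: %d residue(s), width %d, mean %.2f\n",
              x$gene_id, length(x$scores), x$deletion_width,
              mean(x$scores)))
  invisible(x)
}

#' Is a residue conserved?
#'
#' @param track A `conservation_track`.
#' @param aa_position 1-based residue index (vectorized).
#' @param threshold Conservation cutoff (default 7, strict `>`).
#' @return Logical vector.
#' @export
conserved_flag <- function(track, aa_position, threshold = 7) {
  track$scores[aa_position] > threshold
}

#' Substitution-based conservation score at one residue
#'
#' Mean negated delta over all 20 amino-acid substitutions at the
#' position (the self-substitution contributes 0). Used for comparing
#' deletion-based and substitution-based scoring on the same footing.
#'
#' @param protein Protein string.
#' @param position 1-based residue index.
#' @param set An `ortholog_set`.
#' @inheritParams semiglobal_align_score
#' @return Numeric score.
#' @export
substitution_mode_score <- function(protein, position, set,
                                    matrix = "BLOSUM62", gap_open = 10,
                                    gap_extend = 1) {
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  L <- nchar(protein)
  stopifnot(position >= 1, position <= L)
  deltas <- vapply(aas, function(aa) {
    variant <- paste0(substr(protein, 1, position - 1), aa,
                      substr(protein, position + 1, L))
    delta_score(protein, variant, set, matrix, gap_open, gap_extend)
  }, numeric(1))
  mean(-deltas)
}

#' Write a conservation track to TSV
#'
#' @param track A `conservation_track`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_tsv <- function(track, path) {
  df <- data.frame(gene_id = track$gene_id,
                   aa_index = seq_along(track$scores),
                   score = track$scores)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a conservation track as genome-anchored BED
#'
#' Each residue's codon is mapped through the transcript's CDS intervals;
#' codons split across exons emit one BED row per contiguous block.
#' BED output is 0-based half-open per the format.
#'
#' @param track A `conservation_track` for the transcript's gene.
#' @param tx The `transcript_model` carrying the protein.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_conservation_bed <- function(track, tx, path) {
  rows <- list()
  for (aa in seq_along(track$scores)) {
    gpos <- sort(vapply(0:2, function(k) {
      cds_to_genome_coordinate(tx, (aa - 1L) * 3L + k)
    }, numeric(1)))
    breaks <- c(0L, which(diff(gpos) != 1L), length(gpos))
    for (b in seq_len(length(breaks) - 1L)) {
      blk <- gpos[(breaks[b] + 1L):breaks[b + 1L]]
      rows[[length(rows) + 1L]] <- data.frame(
        chrom = tx$contig_id, start = min(blk) - 1L, end = max(blk),
        name = paste0(track$gene_id, ":", aa),
        score = track$scores[aa], strand = tx$strand
      )
    }
  }
  bed <- do.call(rbind, rows)
  write.table(bed, path, sep = "\t", quote = FALSE, row.names = FALSE,
              col.names = FALSE)
  invisible(path)
}
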