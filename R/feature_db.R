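#' Build the full per-guide feature database
#'
#' The end-to-end annotation pipeline: extract every NGG guide from the
#' genome, add intrinsic features (homopolymers, Esp3I, melting
#' temperature, efficacy), genome-wide and proteome-restricted
#' specificity from the seeded off-target search, target features mapped
#' through the gene models, and per-residue deletion-based conservation
#' looked up at the residue under each cut. The result is the "feature
#' database": one row per guide, every design-relevant column populated,
#' ready for [design_library()] or export with [write_guides()].
#'
#' @param genome Genome from [read_genome()].
#' @param transcripts List from [read_transcripts()].
#' @param orthologs Named list of [ortholog_set()]s keyed by gene id;
#'   genes without a set get `NA` conservation.
#' @param annotations data.frame from [read_annotations()], or `NULL`.
#' @param polymorphisms data.frame from [read_polymorphisms()], or
#'   `NULL`.
#' @param ese_motifs Character vector of enhancer motifs.
#' @param scorer An `efficacy_scorer`.
#' @param context A [construct_context()].
#' @param W Mismatch position weights from [hsu_weights()].
#' @param proteome_specificity Also compute CDS-restricted specificity
#'   (default TRUE).
#' @param conservation_tracks Optional precomputed named list of
#'   `conservation_track`s (skips the alignment step).
#' @return data.frame: the guide table with all feature columns,
#'   including `conservation` (score of the residue under the cut).
#' @export
build_feature_db <- function(genome, transcripts, orthologs = list(),
                             annotations = NULL, polymorphisms = NULL,
                             ese_motifs = character(),
                             scorer = efficacy_scorer_surrogate(),
                             context = construct_context(),
                             W = hsu_weights(),
                             proteome_specificity = TRUE,
                             conservation_tracks = NULL) {
  guides <- extract_guides(genome)
  guides <- intrinsic_features(guides, context, scorer)

  index <- build_offtarget_index(genome)
  cds_index <- if (proteome_specificity) {
    build_offtarget_index(cds_sequence_set(transcripts, genome))
  } else NULL
  spec <- compute_specificity(guides, index, cds_index, W)
  guides <- cbind(guides, spec[setdiff(names(spec), "guide_id")])

  guides <- target_features(guides, transcripts, genome, annotations,
                            polymorphisms, ese_motifs)

  if (is.null(conservation_tracks)) {
    conservation_tracks <- list()
    proteins <- transcript_proteins(transcripts, genome)
    for (gid in names(orthologs)) {
      if (!gid %in% names(proteins)) next
      conservation_tracks[[gid]] <- aadelcons_track(proteins[[gid]],
                                                    orthologs[[gid]])
    }
  }
  guides$conservation <- vapply(seq_len(nrow(guides)), function(i) {
    gid <- guides$gene_id[i]
    aa <- guides$aa_position[i]
    if (is.na(gid) || is.na(aa) || !gid %in% names(conservation_tracks)) {
      return(NA_real_)
    }
    tr <- conservation_tracks[[gid]]
    if (aa > length(tr$scores)) return(NA_real_)
    tr$scores[aa]
  }, numeric(1))
  attr(guides, "conservation_tracks") <- conservation_tracks
  guides
}

#' Proteins of principal transcripts, keyed by gene id
#'
#' @param transcripts List from [read_transcripts()].
#' @param genome Genome from [read_genome()].
#' @return Named character vector (one principal protein per gene).
#' @export
transcript_proteins <- function(transcripts, genome) {
  principal <- Filter(function(tx) tx$is_principal, transcripts)
  prots <- vapply(principal, function(tx) {
    translate_cds(spliced_cds(tx, genome))
  }, character(1))
  names(prots) <- vapply(principal, `[[`, character(1), "gene_id")
  prots[!duplicated(names(prots))]
}
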