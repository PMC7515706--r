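#' Fractional position of a cut within the coding sequence
#'
#' The cut's 0-based spliced-CDS offset divided by the CDS length, in
#' \[0, 1). Guides cutting past the 95th percentile of the CDS are
#' deprioritized at the design stage: frameshifts that close to the C
#' terminus often leave a functional protein.
#'
#' @param tx A `transcript_model`.
#' @param cut_position 1-based genomic coordinate (see [cut_site()]).
#' @return Fraction, or `NA` when the cut is outside the CDS.
#' @export
pct_cds <- function(tx, cut_position) {
  off <- genome_to_cds_coordinate(tx, cut_position)
  if (is.na(off)) return(NA_real_)
  off / cds_length(tx)
}

#' Residue index under a cut
#'
#' @inheritParams pct_cds
#' @return 1-based amino-acid position (`floor(offset / 3) + 1`), or `NA`.
#' @export
aa_position <- function(tx, cut_position) {
  off <- genome_to_cds_coordinate(tx, cut_position)
  if (is.na(off)) return(NA_integer_)
  off %/% 3L + 1L
}

# 0-based offset of a genomic position in the spliced transcript, or NA
tx_coordinate <- function(tx, genomic_position) {
  offset <- 0L
  for (i in seq_len(nrow(tx$exons))) {
    s <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (genomic_position >= s && genomic_position <= e) {
      within <- if (tx$strand == "+") genomic_position - s else e - genomic_position
      return(offset + as.integer(within))
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' NMD-competent frameshift frames at a cut (50-nt rule)
#'
#' For each of the two frameshifting repair outcomes (net +1 and +2 nt
#' insertions at the cut), scans the shifted downstream reading frame of
#' the mature mRNA to the first stop codon, and counts the frame as
#' NMD-inducing when that premature stop starts more than `threshold` nt
#' upstream of the last exon-exon junction. Premature stops closer to (or
#' past) the junction escape nonsense-mediated decay, so cuts in the last
#' exon always return 0, as do single-exon transcripts (no junction).
#'
#' @inheritParams pct_cds
#' @param genome Genome from [read_genome()].
#' @param threshold Junction-distance threshold in nt (default 55, the
#'   conservative end of the rule's 50-55 nt range).
#' @return Integer in 0..2: how many of the two frames induce NMD.
#' @export
nmd_frames <- function(tx, cut_position, genome, threshold = 55L) {
  n_ex <- nrow(tx$exons)
  if (n_ex < 2L) return(0L)
  widths <- tx$exons$end - tx$exons$start + 1L
  total <- sum(widths)
  J <- total - widths[n_ex]   # 0-based tx offset of first base of last exon
  mrna <- spliced_transcript(tx, genome)

  # first transcript base 3' (in transcript orientation) of the cut bond
  tb <- if (tx$strand == "+") {
    tx_coordinate(tx, cut_position)
  } else {
    tx_coordinate(tx, cut_position - 1L)
  }
  if (is.na(tb)) return(0L)
  cds_start_g <- if (tx$strand == "+") tx$cds$start[1] else tx$cds$end[1]
  s <- tx_coordinate(tx, cds_start_g)

  n_nmd <- 0L
  for (k in 1:2) {
    # first downstream codon start in the shifted frame
    p <- tb
    while ((p - s + k) %% 3L != 0L) p <- p + 1L
    stop_start <- NA_integer_
    while (p + 2L < total) {
      codon <- substr(mrna, p + 1L, p + 3L)
      if (codon %in% STOP_CODONS) { stop_start <- p; break }
      p <- p + 3L
    }
    if (!is.na(stop_start) && (J - stop_start) > threshold) {
      n_nmd <- n_nmd + 1L
    }
  }
  n_nmd
}

# CDS nucleotides within one exon interval
exon_cds_length <- function(tx, exon_index) {
  a <- tx$exons$start[exon_index]; e <- tx$exons$end[exon_index]
  sum(pmax(0L, pmin(tx$cds$end, e) - pmax(tx$cds$start, a) + 1L))
}

#' Exon symmetry (frame preservation on exon skipping)
#'
#' An internal exon is asymmetric when its coding length is not a
#' multiple of 3, so losing the exon frameshifts everything downstream.
#' First and last exons are not skippable in this sense and return `NA`.
#'
#' @param tx A `transcript_model`.
#' @param exon_index Exon index in transcription order.
#' @return `TRUE` (asymmetric), `FALSE` (symmetric), or `NA` for
#'   non-internal exons.
#' @export
exon_symmetry <- function(tx, exon_index) {
  if (exon_index <= 1L || exon_index >= nrow(tx$exons)) return(NA)
  exon_cds_length(tx, exon_index) %% 3L != 0L
}

# exon index (transcription order) containing a genomic base, or NA
exon_index_of <- function(tx, genomic_position) {
  for (i in seq_len(nrow(tx$exons))) {
    if (genomic_position >= tx$exons$start[i] &&
        genomic_position <= tx$exons$end[i]) {
      return(i)
    }
  }
  NA_integer_
}

#' Splice-site class of a cut
#'
#' Classifies the cut bond relative to the nearest exon edge: `sd+0` at a
#' donor exon edge through `sd+2` two nucleotides into the donor intron
#' (the far edge of the GT), and `sa+0`..`sa+2` mirrored at acceptors.
#' Cuts more than two nucleotides from any edge return `"none"`. The
#' class is annotated but deliberately not used as a design criterion:
#' splice-site edits produce hard-to-predict change-of-function variants.
#'
#' @inheritParams pct_cds
#' @return One of `"sd+0"`, `"sd+1"`, `"sd+2"`, `"sa+0"`, `"sa+1"`,
#'   `"sa+2"`, `"none"`.
#' @export
splice_site_class <- function(tx, cut_position) {
  b <- cut_position - 1L   # cut bond sits after reference base b
  n_ex <- nrow(tx$exons)
  for (i in seq_len(n_ex)) {
    a <- tx$exons$start[i]; e <- tx$exons$end[i]
    if (tx$strand == "+") {
      donor_b <- e; acceptor_b <- a - 1L
    } else {
      donor_b <- a - 1L; acceptor_b <- e
    }
    dir <- if (tx$strand == "+") 1L else -1L
    if (i < n_ex) {
      j <- (b - donor_b) * dir
      if (j >= 0L && j <= 2L) return(paste0("sd+", j))
    }
    if (i > 1L) {
      j <- (acceptor_b - b) * dir
      if (j >= 0L && j <= 2L) return(paste0("sa+", j))
    }
  }
  "none"
}

#' Load exonic splicing enhancer motifs
#'
#' Plain text, one exact DNA motif per line (e.g. the INT3 hexamer set;
#' fixtures ship a small synthetic stand-in list).
#'
#' @param path Path to the motif file.
#' @return Character vector of motifs.
#' @export
read_ese_motifs <- function(path) {
  motifs <- toupper(trimws(readLines(path)))
  motifs[nzchar(motifs)]
}

#' Does the cut disrupt an exonic splicing enhancer motif?
#'
#' Searches the targeted exon (in transcript orientation) for exact motif
#' occurrences. In the default `"cut_overlap"` mode the feature fires only
#' when an occurrence's footprint covers the cut position, i.e. when the
#' edit can abrogate the motif; `"exon_presence"` mode flags any motif
#' anywhere in the exon.
#'
#' @inheritParams nmd_frames
#' @param motifs Character vector from [read_ese_motifs()]; empty set
#'   always returns FALSE.
#' @param mode `"cut_overlap"` (default) or `"exon_presence"`.
#' @return Logical scalar.
#' @export
ese_overlap <- function(tx, cut_position, genome, motifs,
                        mode = c("cut_overlap", "exon_presence")) {
  mode <- match.arg(mode)
  if (!length(motifs)) return(FALSE)
  i <- exon_index_of(tx, cut_position)
  if (is.na(i)) return(FALSE)
  a <- tx$exons$start[i]; e <- tx$exons$end[i]
  exon_seq <- contig_subseq(genome, tx$contig_id, a, e)
  if (tx$strand == "-") exon_seq <- revcomp(exon_seq)
  subj <- Biostrings::DNAString(exon_seq)
  for (mot in motifs) {
    hits <- Biostrings::matchPattern(mot, subj)
    if (!length(hits)) next
    if (mode == "exon_presence") return(TRUE)
    # map occurrence (1-based, transcript orientation) to genomic interval
    for (h in seq_along(hits)) {
      o1 <- Biostrings::start(hits)[h]; o2 <- Biostrings::end(hits)[h]
      if (tx$strand == "+") {
        g1 <- a + o1 - 1L; g2 <- a + o2 - 1L
      } else {
        g1 <- e - o2 + 1L; g2 <- e - o1 + 1L
      }
      if (cut_position >= g1 && cut_position <= g2) return(TRUE)
    }
  }
  FALSE
}

#' Protein-space annotation overlap at a cut
#'
#' Intersects the residue under the cut with domain, site, and secondary
#' structure intervals (1-based inclusive amino-acid coordinates).
#'
#' @param gene_id Gene of the targeted transcript.
#' @param aa_pos Residue index from [aa_position()].
#' @param annotations data.frame from [read_annotations()].
#' @return One-row data.frame: `in_domain` (conserved-domain region),
#'   `in_cdd_site`, `in_pfam`, `uniprot_2ary` (one of helix/beta/turn/
#'   ccr/none, first match in that priority), `ese_annotated`.
#' @export
annotation_overlap <- function(gene_id, aa_pos, annotations) {
  out <- data.frame(in_domain = FALSE, in_cdd_site = FALSE, in_pfam = FALSE,
                    uniprot_2ary = "none", ese_annotated = FALSE,
                    stringsAsFactors = FALSE)
  if (is.na(aa_pos)) {
    out[1, ] <- list(NA, NA, NA, NA_character_, NA)
    return(out)
  }
  ann <- annotations[annotations$gene_id == gene_id &
                       annotations$aa_start <= aa_pos &
                       annotations$aa_end >= aa_pos, , drop = FALSE]
  out$in_domain <- "CDD_domain" %in% ann$kind
  out$in_cdd_site <- "CDD_site" %in% ann$kind
  out$in_pfam <- "Pfam_domain" %in% ann$kind
  out$ese_annotated <- "ESE" %in% ann$kind
  for (k in c("Uniprot_helix", "Uniprot_beta", "Uniprot_turn", "Uniprot_CCR")) {
    if (k %in% ann$kind) {
      out$uniprot_2ary <- c(Uniprot_helix = "helix", Uniprot_beta = "beta",
                            Uniprot_turn = "turn", Uniprot_CCR = "ccr")[[k]]
      break
    }
  }
  out
}

# 23-nt protospacer+PAM genomic footprint of a guide
guide_footprint <- function(guide) {
  if (guide$strand == "+") {
    c(guide$start, guide$start + 22L)
  } else {
    c(guide$start - 3L, guide$start + 19L)
  }
}

#' Common-polymorphism overlap with the guide+PAM
#'
#' TRUE when any polymorphism at or above the VAF threshold overlaps the
#' 23-nt protospacer+PAM footprint; indels overlap by their reference
#' footprint. Polymorphic targets bind (and cut) unpredictably across
#' individuals or cell lines.
#'
#' @param guide One-row guide data.frame.
#' @param polymorphisms data.frame from [read_polymorphisms()].
#' @param vaf_min Minimum variant allele frequency (default 0.10,
#'   inclusive).
#' @return Logical scalar.
#' @export
snp_overlap <- function(guide, polymorphisms, vaf_min = 0.10) {
  if (!nrow(polymorphisms)) return(FALSE)
  fp <- guide_footprint(guide)
  p <- polymorphisms[polymorphisms$contig == guide$contig &
                       polymorphisms$vaf >= vaf_min, , drop = FALSE]
  if (!nrow(p)) return(FALSE)
  ref_end <- p$pos + nchar(p$ref) - 1L
  any(p$pos <= fp[2] & ref_end >= fp[1])
}

#' Annotate guide target features
#'
#' Maps each guide's cut site into the coding sequence of a principal
#' transcript and computes every target feature. Guides whose cut falls
#' outside any CDS (UTRs, introns, intergenic) get `NA` target features
#' and are excluded from tiered design downstream.
#'
#' @param guides data.frame from [extract_guides()].
#' @param transcripts List from [read_transcripts()].
#' @param genome Genome from [read_genome()].
#' @param annotations data.frame from [read_annotations()] (may be empty).
#' @param polymorphisms data.frame from [read_polymorphisms()] (may be
#'   empty).
#' @param ese_motifs Character vector of enhancer motifs (may be empty).
#' @param vaf_min,nmd_threshold,ese_mode Tuning knobs passed through.
#' @return The guide table with target-feature columns appended:
#'   `gene_id`, `transcript_id`, `pct_cds`, `aa_position`, `nmd_frames`,
#'   `internal_exon`, `exon_asymmetric`, `splice_class`, `ese_overlap`,
#'   `in_domain`, `in_cdd_site`, `in_pfam`, `uniprot_2ary`,
#'   `snp_overlap`, `strand_relative`.
#' @export
target_features <- function(guides, transcripts, genome,
                            annotations = NULL, polymorphisms = NULL,
                            ese_motifs = character(),
                            vaf_min = 0.10, nmd_threshold = 55L,
                            ese_mode = "cut_overlap") {
  if (is.null(annotations)) {
    annotations <- data.frame(gene_id = character(), aa_start = integer(),
                              aa_end = integer(), kind = character(),
                              label = character(), stringsAsFactors = FALSE)
  }
  if (is.null(polymorphisms)) {
    polymorphisms <- data.frame(contig = character(), pos = integer(),
                                ref = character(), alt = character(),
                                vaf = numeric(), stringsAsFactors = FALSE)
  }
  principal <- Filter(function(tx) tx$is_principal, transcripts)
  rows <- lapply(seq_len(nrow(guides)), function(i) {
    g <- guides[i, ]
    cutpos <- g$cut_position
    hit_tx <- NULL
    for (tx in principal) {
      if (tx$contig_id == g$contig &&
          !is.na(genome_to_cds_coordinate(tx, cutpos))) {
        hit_tx <- tx
        break
      }
    }
    if (is.null(hit_tx)) {
      return(data.frame(gene_id = NA_character_,
                        transcript_id = NA_character_, pct_cds = NA_real_,
                        aa_position = NA_integer_, nmd_frames = NA_integer_,
                        internal_exon = NA, exon_asymmetric = NA,
                        splice_class = NA_character_, ese_overlap = NA,
                        in_domain = NA, in_cdd_site = NA, in_pfam = NA,
                        uniprot_2ary = NA_character_, snp_overlap = NA,
                        strand_relative = NA_character_,
                        stringsAsFactors = FALSE))
    }
    tx <- hit_tx
    aa <- aa_position(tx, cutpos)
    exi <- exon_index_of(tx, cutpos)
    internal <- !is.na(exi) && exi > 1L && exi < nrow(tx$exons)
    ann <- annotation_overlap(tx$gene_id, aa, annotations)
    data.frame(
      gene_id = tx$gene_id, transcript_id = tx$transcript_id,
      pct_cds = pct_cds(tx, cutpos), aa_position = aa,
      nmd_frames = nmd_frames(tx, cutpos, genome, nmd_threshold),
      internal_exon = internal,
      exon_asymmetric = if (internal) exon_symmetry(tx, exi) else NA,
      splice_class = splice_site_class(tx, cutpos),
      ese_overlap = ese_overlap(tx, cutpos, genome, ese_motifs,
                                mode = ese_mode),
      in_domain = ann$in_domain, in_cdd_site = ann$in_cdd_site,
      in_pfam = ann$in_pfam, uniprot_2ary = ann$uniprot_2ary,
      snp_overlap = snp_overlap(g, polymorphisms, vaf_min),
      strand_relative = if (g$strand == tx$strand) "same" else "opposite",
      stringsAsFactors = FALSE
    )
  })
  cbind(guides, do.call(rbind, rows))
}
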