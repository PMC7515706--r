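#' Read a genome from FASTA
#'
#' Loads every contig, uppercases the sequence, and maps any symbol outside
#' A/C/G/T/N (IUPAC ambiguity codes and anything else) to N. Guides
#' overlapping N are discarded downstream, so ambiguity codes never reach
#' the design stage.
#'
#' @param fasta_path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per contig.
#' @export
read_genome <- function(fasta_path) {
  if (!file.exists(fasta_path)) {
    stop("FASTA file not found: ", fasta_path)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(fasta_path),
    error = function(e) stop("Malformed FASTA '", fasta_path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  # FASTA headers may carry descriptions; the contig id is the first token
  names(seqs) <- vapply(strsplit(names(seqs), "\\s+"), `[`, character(1), 1L)
  if (anyDuplicated(names(seqs))) {
    stop("Duplicate contig ids in ", fasta_path)
  }
  chars <- toupper(as.character(seqs))
  n_ambig <- sum(vapply(gregexpr("[^ACGTN]", chars), function(m) {
    if (m[1] == -1L) 0L else length(m)
  }, integer(1)))
  if (n_ambig > 0) {
    warning(n_ambig, " non-ACGTN base(s) mapped to N", call. = FALSE)
    chars <- gsub("[^ACGTN]", "N", chars)
  }
  out <- Biostrings::DNAStringSet(chars)
  names(out) <- names(seqs)
  out
}

#' Write a genome to FASTA
#'
#' @param genome A [Biostrings::DNAStringSet].
#' @param fasta_path Output path.
#' @return `fasta_path`, invisibly.
#' @export
write_genome <- function(genome, fasta_path) {
  Biostrings::writeXStringSet(genome, fasta_path)
  invisible(fasta_path)
}

STOP_CODONS <- c("TAA", "TAG", "TGA")

new_transcript_model <- function(gene_id, transcript_id, contig_id, strand,
                                 exons, cds, is_principal = TRUE) {
  structure(
    list(gene_id = gene_id, transcript_id = transcript_id,
         contig_id = contig_id, strand = strand,
         exons = exons, cds = cds, is_principal = is_principal),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s (%s) %s:%s %d exon(s), CDS %d nt\n",
              x$transcript_id, x$gene_id, x$contig_id, x$strand,
              nrow(x$exons), cds_length(x)))
  invisible(x)
}

# intervals in transcription order: ascending genomic starts on +, descending on -
order_tx <- function(df, strand) {
  df[order(df$start, decreasing = (strand == "-")), , drop = FALSE]
}

#' Read gene models from GTF
#'
#' Parses exon and CDS features into transcript models and validates each
#' against the genome: exons must be non-overlapping, every CDS interval
#' must lie inside an exon, the spliced CDS length must be a multiple of 3,
#' and its translation must begin with a start codon, end with a stop, and
#' contain no internal stop. Transcripts failing any check are dropped with
#' a message rather than aborting the read. The CDS convention includes the
#' stop codon, so a 300-nt CDS encodes 99 residues.
#'
#' Principal-isoform status is taken from a `tag` attribute containing
#' "principal" (uppercase or lowercase); transcripts without the attribute
#' are treated as principal.
#'
#' @param gtf_path Path to a GTF file with `gene_id` and `transcript_id`
#'   attributes on exon and CDS rows.
#' @param genome Genome as returned by [read_genome()].
#' @return A named list of `transcript_model` objects (names are
#'   transcript ids). Exon/CDS intervals are stored 1-based inclusive, in
#'   transcription order.
#' @export
read_transcripts <- function(gtf_path, genome) {
  gr <- rtracklayer::import(gtf_path, format = "gtf")
  df <- as.data.frame(gr)
  df$seqnames <- as.character(df$seqnames)
  df$strand <- as.character(df$strand)
  keep <- df$type %in% c("exon", "CDS")
  df <- df[keep, , drop = FALSE]
  if (!all(c("gene_id", "transcript_id") %in% names(df))) {
    stop("GTF must carry gene_id and transcript_id attributes")
  }
  out <- list()
  for (txid in unique(df$transcript_id)) {
    rows <- df[df$transcript_id == txid, , drop = FALSE]
    model <- tryCatch(
      build_transcript(txid, rows, genome),
      error = function(e) {
        message("Rejecting transcript ", txid, ": ", conditionMessage(e))
        NULL
      }
    )
    if (!is.null(model)) out[[txid]] <- model
  }
  out
}

build_transcript <- function(txid, rows, genome) {
  contig <- unique(rows$seqnames)
  strand <- unique(rows$strand)
  if (length(contig) != 1L || length(strand) != 1L) {
    stop("features span multiple contigs or strands")
  }
  if (!strand %in% c("+", "-")) stop("strand must be + or -")
  if (!contig %in% names(genome)) stop("contig ", contig, " not in genome")
  exons <- order_tx(rows[rows$type == "exon", c("start", "end")], strand)
  cds <- order_tx(rows[rows$type == "CDS", c("start", "end")], strand)
  rownames(exons) <- rownames(cds) <- NULL
  if (nrow(exons) == 0L) stop("no exon features")
  if (nrow(cds) == 0L) stop("no CDS features")
  gstarts <- sort(exons$start)
  gends <- exons$end[order(exons$start)]
  if (any(gstarts[-1] <= gends[-length(gends)])) stop("overlapping exons")
  in_exon <- vapply(seq_len(nrow(cds)), function(i) {
    any(exons$start <= cds$start[i] & exons$end >= cds$end[i])
  }, logical(1))
  if (!all(in_exon)) stop("CDS interval outside exons")
  cds_len <- sum(cds$end - cds$start + 1L)
  if (cds_len %% 3L != 0L) stop("CDS length ", cds_len, " not a multiple of 3")
  tag <- if ("tag" %in% names(rows)) rows$tag[1] else NA_character_
  model <- new_transcript_model(
    gene_id = rows$gene_id[1], transcript_id = txid,
    contig_id = contig, strand = strand, exons = exons, cds = cds,
    is_principal = is.na(tag) || grepl("principal", tag, ignore.case = TRUE)
  )
  cds_seq <- spliced_cds(model, genome)
  if (grepl("N", cds_seq, fixed = TRUE)) stop("CDS contains N")
  if (substr(cds_seq, 1, 3) != "ATG") stop("CDS does not start with ATG")
  n <- nchar(cds_seq)
  if (!substr(cds_seq, n - 2, n) %in% STOP_CODONS) {
    stop("CDS does not end with a stop codon")
  }
  prot <- translate_cds(cds_seq)
  if (grepl("\\*", prot)) stop("internal stop codon in CDS")
  model
}

#' Write transcript models to GTF
#'
#' Inverse of [read_transcripts()]: the exported exon/CDS rows round-trip
#' interval coordinates exactly.
#'
#' @param transcripts List of `transcript_model` objects.
#' @param gtf_path Output path.
#' @return `gtf_path`, invisibly.
#' @export
write_transcripts <- function(transcripts, gtf_path) {
  rows <- do.call(rbind, lapply(transcripts, function(tx) {
    # GTF frame: bases to skip before the first complete codon
    widths <- tx$cds$end - tx$cds$start + 1L
    phase <- (3L - (c(0L, cumsum(widths)[-length(widths)]) %% 3L)) %% 3L
    rbind(
      data.frame(seqnames = tx$contig_id, start = tx$exons$start,
                 end = tx$exons$end, strand = tx$strand, type = "exon",
                 phase = NA_integer_,
                 gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                 tag = if (tx$is_principal) "principal" else "alternative"),
      data.frame(seqnames = tx$contig_id, start = tx$cds$start,
                 end = tx$cds$end, strand = tx$strand, type = "CDS",
                 phase = phase,
                 gene_id = tx$gene_id, transcript_id = tx$transcript_id,
                 tag = if (tx$is_principal) "principal" else "alternative")
    )
  }))
  gr <- GenomicRanges::GRanges(
    seqnames = rows$seqnames,
    ranges = IRanges::IRanges(rows$start, rows$end),
    strand = rows$strand
  )
  S4Vectors::mcols(gr)$type <- rows$type
  S4Vectors::mcols(gr)$phase <- rows$phase
  S4Vectors::mcols(gr)$gene_id <- rows$gene_id
  S4Vectors::mcols(gr)$transcript_id <- rows$transcript_id
  S4Vectors::mcols(gr)$tag <- rows$tag
  rtracklayer::export(gr, gtf_path, format = "gtf")
  invisible(gtf_path)
}

contig_subseq <- function(genome, contig, start, end) {
  as.character(Biostrings::subseq(genome[[contig]], start, end))
}

revcomp <- function(x) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
}

# spliced sequence over a set of transcription-ordered intervals
splice_intervals <- function(intervals, strand, contig_seq) {
  pieces <- vapply(seq_len(nrow(intervals)), function(i) {
    s <- as.character(Biostrings::subseq(contig_seq, intervals$start[i],
                                         intervals$end[i]))
    if (strand == "-") revcomp(s) else s
  }, character(1))
  paste0(pieces, collapse = "")
}

#' Spliced CDS sequence of a transcript
#'
#' @param tx A `transcript_model`.
#' @param genome Genome as returned by [read_genome()].
#' @return Character scalar, 5' to 3' in the coding orientation, stop
#'   codon included.
#' @export
spliced_cds <- function(tx, genome) {
  splice_intervals(tx$cds, tx$strand, genome[[tx$contig_id]])
}

#' Spliced mature transcript (exonic) sequence
#'
#' @inheritParams spliced_cds
#' @return Character scalar, 5' to 3'.
#' @export
spliced_transcript <- function(tx, genome) {
  splice_intervals(tx$exons, tx$strand, genome[[tx$contig_id]])
}

#' Total CDS length of a transcript (nt, stop codon included)
#' @param tx A `transcript_model`.
#' @export
cds_length <- function(tx) sum(tx$cds$end - tx$cds$start + 1L)

#' Translate a CDS string
#'
#' @param cds_seq In-frame DNA string (length a multiple of 3).
#' @return Amino-acid string; a trailing stop codon is removed, internal
#'   stops appear as `*`.
#' @export
translate_cds <- function(cds_seq) {
  aa <- as.character(Biostrings::translate(Biostrings::DNAString(cds_seq)))
  sub("\\*$", "", aa)
}

#' Map a genomic position to a spliced-CDS offset
#'
#' Strand-aware: on minus-strand transcripts the CDS is counted from the
#' genomic 3' end. Positions outside the CDS (introns, UTRs, other
#' contigs) return `NA`.
#'
#' @param tx A `transcript_model`.
#' @param genomic_position 1-based genomic coordinate.
#' @return 0-based offset into the spliced CDS (number of CDS bases 5' of
#'   the position), or `NA_integer_`.
#' @export
genome_to_cds_coordinate <- function(tx, genomic_position) {
  offset <- 0L
  for (i in seq_len(nrow(tx$cds))) {
    s <- tx$cds$start[i]; e <- tx$cds$end[i]
    if (genomic_position >= s && genomic_position <= e) {
      within <- if (tx$strand == "+") genomic_position - s else e - genomic_position
      return(offset + as.integer(within))
    }
    offset <- offset + (e - s + 1L)
  }
  NA_integer_
}

#' Map a spliced-CDS offset back to a genomic position
#'
#' Inverse of [genome_to_cds_coordinate()].
#'
#' @param tx A `transcript_model`.
#' @param cds_offset 0-based offset into the spliced CDS.
#' @return 1-based genomic coordinate.
#' @export
cds_to_genome_coordinate <- function(tx, cds_offset) {
  stopifnot(cds_offset >= 0, cds_offset < cds_length(tx))
  remaining <- as.integer(cds_offset)
  for (i in seq_len(nrow(tx$cds))) {
    s <- tx$cds$start[i]; e <- tx$cds$end[i]
    w <- e - s + 1L
    if (remaining < w) {
      return(if (tx$strand == "+") s + remaining else e - remaining)
    }
    remaining <- remaining - w
  }
  stop("unreachable")
}

#' Read polymorphisms from VCF
#'
#' Variant allele frequency is taken from the `AF` INFO field (the first
#' value for multi-allelic records). Reference alleles are validated
#' against the genome.
#'
#' @param vcf_path Path to a VCF file.
#' @param genome Genome as returned by [read_genome()]; pass `NULL` to
#'   skip reference validation.
#' @return data.frame with columns `contig`, `pos` (1-based), `ref`,
#'   `alt`, `vaf`.
#' @export
read_polymorphisms <- function(vcf_path, genome = NULL) {
  vcf <- VariantAnnotation::readVcf(vcf_path)
  rr <- SummarizedExperiment::rowRanges(vcf)
  af <- VariantAnnotation::info(vcf)$AF
  vaf <- if (is.null(af)) rep(NA_real_, length(rr)) else {
    vapply(as.list(af), function(x) as.numeric(x)[1], numeric(1))
  }
  out <- data.frame(
    contig = as.character(GenomicRanges::seqnames(rr)),
    pos = GenomicRanges::start(rr),
    ref = as.character(rr$REF),
    alt = vapply(as.list(rr$ALT), function(a) as.character(a)[1], character(1)),
    vaf = vaf,
    stringsAsFactors = FALSE
  )
  if (any(is.na(out$vaf)) || any(out$vaf < 0 | out$vaf > 1)) {
    stop("every VCF record needs an AF INFO value in [0, 1]")
  }
  if (!is.null(genome)) {
    for (i in seq_len(nrow(out))) {
      obs <- contig_subseq(genome, out$contig[i], out$pos[i],
                           out$pos[i] + nchar(out$ref[i]) - 1L)
      if (obs != out$ref[i]) {
        stop("VCF ref allele mismatch at ", out$contig[i], ":", out$pos[i],
             " (VCF ", out$ref[i], ", genome ", obs, ")")
      }
    }
  }
  out
}

ANNOTATION_KINDS <- c("CDD_domain", "CDD_site", "Pfam_domain",
                      "Uniprot_helix", "Uniprot_beta", "Uniprot_turn",
                      "Uniprot_CCR", "ESE")

#' Read protein-space annotation intervals from TSV
#'
#' Expected columns: `gene_id`, `aa_start`, `aa_end` (1-based inclusive
#' residue coordinates), `kind`, `label`. Kinds cover conserved-domain
#' regions and sites, Pfam domains, and Uniprot secondary structure.
#'
#' @param tsv_path Path to the TSV file.
#' @return data.frame of annotation intervals.
#' @export
read_annotations <- function(tsv_path) {
  df <- read.delim(tsv_path, stringsAsFactors = FALSE)
  required <- c("gene_id", "aa_start", "aa_end", "kind", "label")
  if (!all(required %in% names(df))) {
    stop("annotation TSV needs columns: ", paste(required, collapse = ", "))
  }
  if (any(df$aa_start > df$aa_end)) stop("aa_start > aa_end in annotation TSV")
  bad <- setdiff(unique(df$kind), ANNOTATION_KINDS)
  if (length(bad)) stop("unknown annotation kind(s): ", paste(bad, collapse = ", "))
  df[required]
}
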