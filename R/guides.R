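#' Extract all NGG guides from a genome
#'
#' Enumerates every 23-nt protospacer+PAM site whose PAM matches NGG, on
#' both strands. Each guide carries a 30-nt context (4 nt upstream +
#' protospacer + PAM + 3 nt downstream) for efficacy scoring; guides whose
#' context would run off the contig edge, or whose protospacer+PAM
#' contains N, are discarded. SpCas9 cuts bluntly 3 bp 5' of the PAM,
#' between protospacer positions 17 and 18; `cut_position` records the
#' first base 3' of that bond on the reference strand.
#'
#' @param genome A [Biostrings::DNAStringSet] from [read_genome()].
#' @return data.frame with one row per guide, ordered by
#'   (contig, start, strand): `guide_id` (contig:start:strand), `contig`,
#'   `start`, `end` (1-based protospacer interval on the reference
#'   strand), `strand`, `protospacer`, `pam`, `cut_position`, `context30`.
#' @export
extract_guides <- function(genome) {
  rows <- lapply(names(genome), function(contig) {
    seq_chr <- as.character(genome[[contig]])
    L <- nchar(seq_chr)
    out <- list()

    # plus strand: GG dinucleotide at q+1..q+2 where PAM spans q..q+2
    m <- Biostrings::matchPattern("GG", genome[[contig]])
    q <- Biostrings::start(m) - 1L
    q <- q[q >= 25L & q + 5L <= L]   # room for full 30-mer context
    if (length(q)) {
      s <- q - 20L
      out$plus <- data.frame(
        contig = contig, start = s, end = s + 19L, strand = "+",
        protospacer = substring(seq_chr, s, s + 19L),
        pam = substring(seq_chr, q, q + 2L),
        cut_position = s + 17L,
        context30 = substring(seq_chr, q - 24L, q + 5L),
        stringsAsFactors = FALSE
      )
    }

    # minus strand: CC at x..x+1 is the reverse complement of the PAM GG
    m <- Biostrings::matchPattern("CC", genome[[contig]])
    x <- Biostrings::start(m)
    x <- x[x >= 4L & x + 26L <= L]
    if (length(x)) {
      s <- x + 3L
      out$minus <- data.frame(
        contig = contig, start = s, end = s + 19L, strand = "-",
        protospacer = revcomp(substring(seq_chr, s, s + 19L)),
        pam = revcomp(substring(seq_chr, x, x + 2L)),
        cut_position = s + 3L,
        context30 = revcomp(substring(seq_chr, x - 3L, x + 26L)),
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, out)
  })
  guides <- do.call(rbind, rows)
  if (is.null(guides) || nrow(guides) == 0L) {
    return(data.frame(guide_id = character(), contig = character(),
                      start = integer(), end = integer(),
                      strand = character(), protospacer = character(),
                      pam = character(), cut_position = integer(),
                      context30 = character(), stringsAsFactors = FALSE))
  }
  clean <- !grepl("N", paste0(guides$protospacer, guides$pam), fixed = TRUE)
  guides <- guides[clean, , drop = FALSE]
  guides <- guides[order(guides$contig, guides$start, guides$strand), ,
                   drop = FALSE]
  guides$guide_id <- paste(guides$contig, guides$start, guides$strand,
                           sep = ":")
  rownames(guides) <- NULL
  guides[c("guide_id", "contig", "start", "end", "strand", "protospacer",
           "pam", "cut_position", "context30")]
}

#' Genomic cut site of a guide
#'
#' The blunt SpCas9 cut falls between protospacer positions 17 and 18
#' (3 bp 5' of the PAM); the returned coordinate is the first base 3' of
#' the cut bond on the reference strand, so two guides on opposite strands
#' sharing the same physical bond report the same value.
#'
#' @param guides data.frame from [extract_guides()] (or any frame with
#'   `start` and `strand` columns for 20-nt protospacers).
#' @return Integer vector of 1-based genomic coordinates.
#' @export
cut_site <- function(guides) {
  ifelse(guides$strand == "+", guides$start + 17L, guides$start + 3L)
}

#' Write a guide table to TSV
#'
#' @param guides data.frame from [extract_guides()] (possibly with added
#'   feature columns).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_guides <- function(guides, path) {
  write.table(guides, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
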