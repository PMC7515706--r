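# Hand-built miniature gene fixtures with every coordinate known by
# construction. The GTF text is written directly (not via the package's
# writer) so reader tests stay independent.

write_gtf_lines <- function(df, path) {
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; tag "principal";',
                      df$gene_id, df$transcript_id)
  writeLines(paste(df$contig, "test", df$type, df$start, df$end, ".",
                   df$strand, ".", attr_str, sep = "\t"), path)
}

# A 3-exon plus-strand gene: 300-nt CDS (ATG + 98x GCT + TAA -> protein
# M + 98 A), 20-nt 5'UTR, 60-nt 3'UTR, two 80-nt introns, embedded at
# offset 100 in a 1.2-kb contig. Returns all ground-truth coordinates.
hand_gene <- function(strand = "+", dir = tempfile()) {
  dir.create(dir, showWarnings = FALSE)
  cds <- paste0("ATG", strrep("GCT", 98), "TAA")
  utr5 <- strrep("TCTGA", 4)                       # 20 nt
  utr3 <- strrep("CATTGA", 10)                     # 60 nt
  intron <- function() paste0("GT", strrep("CAGTTA", 12), "ACAG")  # 78 nt
  ex1 <- paste0(utr5, substr(cds, 1, 100))
  ex2 <- substr(cds, 101, 205)
  ex3 <- paste0(substr(cds, 206, 300), utr3)
  seg <- paste0(ex1, intron(), ex2, intron(), ex3)
  lead <- strrep("ATCTG", 20)                      # 100 nt
  tail_fill <- strrep("TGACA", 40)                 # 200 nt
  contig_seq <- paste0(lead, seg, tail_fill)

  off <- nchar(lead)
  l1 <- nchar(ex1); li <- 78L; l2 <- nchar(ex2); l3 <- nchar(ex3)
  exons <- data.frame(
    start = c(off + 1L, off + l1 + li + 1L, off + l1 + li + l2 + li + 1L),
    end = c(off + l1, off + l1 + li + l2, off + l1 + li + l2 + li + l3))
  cdsiv <- data.frame(
    start = c(off + 21L, exons$start[2], exons$start[3]),
    end = c(exons$end[1], exons$end[2], exons$start[3] + 94L))

  if (strand == "-") {
    L <- nchar(contig_seq)
    contig_seq <- rc(contig_seq)
    flip <- function(iv) data.frame(start = L - iv$end + 1L,
                                    end = L - iv$start + 1L)
    exons <- flip(exons)[rev(seq_len(nrow(exons))), ]
    cdsiv <- flip(cdsiv)[rev(seq_len(nrow(cdsiv))), ]
  }
  gtf_df <- rbind(
    data.frame(contig = "ctg", type = "exon", start = exons$start,
               end = exons$end, strand = strand, gene_id = "gX",
               transcript_id = "gX.t1"),
    data.frame(contig = "ctg", type = "CDS", start = cdsiv$start,
               end = cdsiv$end, strand = strand, gene_id = "gX",
               transcript_id = "gX.t1"))
  fa <- file.path(dir, "g.fa"); gtf <- file.path(dir, "g.gtf")
  writeLines(c(">ctg", contig_seq), fa)
  write_gtf_lines(gtf_df, gtf)
  list(fa = fa, gtf = gtf, contig_seq = contig_seq, exons = exons,
       cds = cdsiv, strand = strand, protein = paste0("M", strrep("A", 98)),
       cds_len = 300L)
}

# direct transcript_model construction for feature unit tests
mk_tx <- function(contig, strand, exons, cds, gene_id = "g1",
                  transcript_id = "g1.t1") {
  guideforge:::new_transcript_model(gene_id, transcript_id, contig, strand,
                                    as.data.frame(exons), as.data.frame(cds))
}

# one-row guide data.frame for feature unit tests
mk_guide <- function(contig = "ctg", start = 101L, strand = "+",
                     protospacer = strrep("A", 20), pam = "AGG") {
  cutpos <- if (strand == "+") start + 17L else start + 3L
  data.frame(guide_id = paste(contig, start, strand, sep = ":"),
             contig = contig, start = start, end = start + 19L,
             strand = strand, protospacer = protospacer, pam = pam,
             cut_position = cutpos, context30 = strrep("A", 30),
             stringsAsFactors = FALSE)
}

# shared fixture: built once per test run, reused across files
fixture_cache <- new.env(parent = emptyenv())
get_fixture <- function(seed = 1) {
  key <- paste0("fx", seed)
  if (is.null(fixture_cache[[key]])) {
    dir <- file.path(tempdir(), paste0("gf_fixture_", seed))
    fixture_cache[[key]] <- make_fixture(fixture_spec(seed = seed),
                                         out_dir = dir)
  }
  fixture_cache[[key]]
}

get_fixture_db <- function(seed = 1) {
  key <- paste0("db", seed)
  if (is.null(fixture_cache[[key]])) {
    fx <- get_fixture(seed)
    genome <- read_genome(fx$paths$genome)
    tx <- read_transcripts(fx$paths$gtf, genome)
    db <- build_feature_db(
      genome, tx, orthologs = fx$orthologs, annotations = fx$annotations,
      polymorphisms = fx$polymorphisms, ese_motifs = fx$ese_motifs,
      scorer = efficacy_scorer_table(fx$efficacy))
    fixture_cache[[key]] <- list(db = db, genome = genome, tx = tx)
  }
  fixture_cache[[key]]
}
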