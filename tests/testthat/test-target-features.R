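test_that("pct_cds is the cut offset over the CDS length", {
  hg <- hand_gene("+")
  g <- read_genome(hg$fa)
  tx <- read_transcripts(hg$gtf, g)[[1]]
  at_offset <- function(o) cds_to_genome_coordinate(tx, o)
  expect_equal(pct_cds(tx, at_offset(0L)), 0.0)
  expect_equal(pct_cds(tx, at_offset(150L)), 0.5)
  expect_equal(pct_cds(tx, at_offset(294L)), 0.98)
  expect_true(is.na(pct_cds(tx, tx$exons$end[1] + 5L)))   # intron
  # strictly increasing along the CDS
  vals <- vapply(seq(0L, 299L, by = 13L), function(o) {
    pct_cds(tx, at_offset(o))
  }, numeric(1))
  expect_true(all(diff(vals) > 0))
  # residue index under the cut
  expect_equal(aa_position(tx, at_offset(0L)), 1L)
  expect_equal(aa_position(tx, at_offset(5L)), 2L)
  expect_equal(aa_position(tx, at_offset(297L)), 100L)
})

# Purpose-built two-exon transcripts with controlled downstream content
# for the 50-nt rule. Layout (plus strand, no UTRs): exon1 carries the
# CDS start, exon2 ends with the stop codon.
nmd_toy <- function(exon1_cds, exon2_cds, intron_len = 40L) {
  stopifnot((nchar(exon1_cds) + nchar(exon2_cds)) %% 3L == 0L)
  intron <- paste0("GT", strrep("C", intron_len - 4L), "AG")
  seq_chr <- paste0(strrep("ATCTG", 4), exon1_cds, intron, exon2_cds,
                    strrep("CATGA", 4))
  off <- 20L
  e1 <- c(off + 1L, off + nchar(exon1_cds))
  e2 <- c(e1[2] + intron_len + 1L, e1[2] + intron_len + nchar(exon2_cds))
  tx <- mk_tx("ctg", "+", data.frame(start = c(e1[1], e2[1]),
                                     end = c(e1[2], e2[2])),
              data.frame(start = c(e1[1], e2[1]), end = c(e1[2], e2[2])))
  list(tx = tx,
       genome = Biostrings::DNAStringSet(setNames(seq_chr, "ctg")))
}

test_that("the 50-nt rule counts NMD-competent frameshift frames", {
  # both shifted frames stop immediately: the GTAAGTAA block after the
  # cut carries a TAA in each shifted frame, far (> 55 nt) upstream of
  # the junction; the in-frame reading stays stop-free (GCA codons)
  e1 <- paste0("ATG", strrep("GCA", 10), "GTAAGTAA", strrep("GCA", 20))
  e2 <- paste0("G", strrep("GCA", 20), "TGA")
  toy <- nmd_toy(e1, e2)
  cut <- toy$tx$exons$start[1] + 33L   # bond just before the stop block
  expect_equal(nmd_frames(toy$tx, cut, toy$genome), 2L)

  # cut in the last exon: no downstream junction, the rule cannot fire
  cut2 <- toy$tx$exons$start[2] + 10L
  expect_equal(nmd_frames(toy$tx, cut2, toy$genome), 0L)

  # single-exon transcript
  seq1 <- paste0(strrep("ATCTG", 4), "ATG", strrep("GCA", 30), "TGA",
                 strrep("CATGA", 4))
  tx1 <- mk_tx("ctg", "+", data.frame(start = 21L, end = 20L + 96L),
               data.frame(start = 21L, end = 20L + 96L))
  g1 <- Biostrings::DNAStringSet(setNames(seq1, "ctg"))
  expect_equal(nmd_frames(tx1, 40L, g1), 0L)
})

test_that("frames are counted independently against the junction distance", {
  # engineer: +1 frame stops immediately (far upstream of the junction);
  # +2 frame finds no stop until deep into the long last exon
  # cut right after the CDS start codon; downstream of cut in exon1:
  # +1 frame reads TAA at once; the +2 frame sees only GC-rich codons
  e1 <- paste0("ATGC", "TAAC", strrep("GCAGCC", 30))
  # pad to frame: total CDS length must be %% 3
  e2 <- paste0(strrep("GGCGCA", 30), "TGA")
  pad <- (3L - (nchar(e1) + nchar(e2)) %% 3L) %% 3L
  e2 <- paste0(strrep("G", pad), e2)
  toy <- nmd_toy(e1, e2)
  cut <- toy$tx$exons$start[1] + 3L   # bond after ATG
  got <- nmd_frames(toy$tx, cut, toy$genome)
  # verify against the independent shifted-stop oracle
  mrna <- spliced_transcript(toy$tx, toy$genome)
  tb <- 3L; s <- 0L
  J <- nchar(e1)
  want <- 0L
  for (k in 1:2) {
    stop_at <- oracle_shifted_stop(mrna, tb, s, k)
    if (!is.na(stop_at) && (J - stop_at) > 55L) want <- want + 1L
  }
  expect_equal(got, want)
  expect_equal(got, 1L)
})

test_that("nmd_frames agrees with the oracle across fixture guides", {
  fxdb <- get_fixture_db()
  db <- fxdb$db
  coding <- db[!is.na(db$gene_id), ]
  set.seed(41)
  sample_rows <- coding[sample(nrow(coding), 40), ]
  for (i in seq_len(nrow(sample_rows))) {
    g <- sample_rows[i, ]
    tx <- fxdb$tx[[g$transcript_id]]
    mrna <- spliced_transcript(tx, fxdb$genome)
    widths <- tx$exons$end - tx$exons$start + 1L
    J <- sum(widths) - widths[length(widths)]
    tb <- if (tx$strand == "+") {
      guideforge:::tx_coordinate(tx, g$cut_position)
    } else {
      guideforge:::tx_coordinate(tx, g$cut_position - 1L)
    }
    cds_start_g <- if (tx$strand == "+") tx$cds$start[1] else tx$cds$end[1]
    s <- guideforge:::tx_coordinate(tx, cds_start_g)
    want <- 0L
    for (k in 1:2) {
      stop_at <- oracle_shifted_stop(mrna, tb, s, k)
      if (!is.na(stop_at) && (J - stop_at) > 55L) want <- want + 1L
    }
    expect_equal(g$nmd_frames, want)
  }
  # closed-form limit: cuts in the last exon are never NMD-competent
  last_exon <- vapply(seq_len(nrow(coding)), function(i) {
    tx <- fxdb$tx[[coding$transcript_id[i]]]
    idx <- guideforge:::exon_index_of(tx, coding$cut_position[i])
    !is.na(idx) && idx == nrow(tx$exons)
  }, logical(1))
  expect_true(any(last_exon))
  expect_true(all(coding$nmd_frames[last_exon] == 0L))
})

test_that("exon symmetry reflects coding length modulo 3", {
  mk <- function(mid_len) {
    mk_tx("ctg", "+",
          data.frame(start = c(1L, 201L, 201L + mid_len + 100L),
                     end = c(100L, 200L + mid_len,
                             200L + mid_len + 100L + 99L)),
          data.frame(start = c(1L, 201L, 201L + mid_len + 100L),
                     end = c(100L, 200L + mid_len,
                             200L + mid_len + 100L + 99L)))
  }
  expect_false(exon_symmetry(mk(99L), 2L))   # 99 nt: symmetric
  expect_true(exon_symmetry(mk(100L), 2L))   # 100 nt: asymmetric
  expect_true(is.na(exon_symmetry(mk(99L), 1L)))
  expect_true(is.na(exon_symmetry(mk(99L), 3L)))
})

test_that("splice-site classes measure the cut bond against exon edges", {
  hg <- hand_gene("+")
  g <- read_genome(hg$fa)
  tx <- read_transcripts(hg$gtf, g)[[1]]
  donor_edge <- tx$exons$end[1]
  # cut bond at the donor exon edge: bond after base e => cut_position e+1
  expect_equal(splice_site_class(tx, donor_edge + 1L), "sd+0")
  expect_equal(splice_site_class(tx, donor_edge + 2L), "sd+1")
  expect_equal(splice_site_class(tx, donor_edge + 3L), "sd+2")
  acceptor_start <- tx$exons$start[2]
  expect_equal(splice_site_class(tx, acceptor_start), "sa+0")
  expect_equal(splice_site_class(tx, acceptor_start - 1L), "sa+1")
  expect_equal(splice_site_class(tx, acceptor_start - 2L), "sa+2")
  mid <- tx$exons$start[2] + 40L
  expect_equal(splice_site_class(tx, mid), "none")

  # minus strand mirrors donor/acceptor roles
  hgm <- hand_gene("-")
  gm <- read_genome(hgm$fa)
  txm <- read_transcripts(hgm$gtf, gm)[[1]]
  # first exon in transcription order; its donor edge faces lower
  # genomic coordinates, and the edge bond sits before the exon start
  donor_start <- txm$exons$start[1]
  expect_equal(splice_site_class(txm, donor_start), "sd+0")
  expect_equal(splice_site_class(txm, donor_start - 1L), "sd+1")
  expect_equal(splice_site_class(txm, donor_start - 2L), "sd+2")
})

test_that("ESE overlap requires a motif footprint over the cut", {
  hg <- hand_gene("+")
  g <- read_genome(hg$fa)
  tx <- read_transcripts(hg$gtf, g)[[1]]
  # exon2 is GCTGCT...; GCTGCT occurs throughout, so any exon2 cut hits it
  cut <- tx$exons$start[2] + 50L
  expect_true(ese_overlap(tx, cut, g, "GCTGCT"))
  expect_false(ese_overlap(tx, cut, g, character(0)))
  # motif present in the exon but away from the cut
  expect_false(ese_overlap(tx, cut, g, "TGCTGA"))   # absent motif
  # exon-presence mode fires for any occurrence in the exon
  expect_true(ese_overlap(tx, cut, g, "GCTGCT", mode = "exon_presence"))

  # a motif 30 nt from the cut, in a non-repetitive exon
  e1 <- paste0("ATG", strrep("GCA", 9), "GAAGAA", strrep("GCA", 20), "TGA")
  tx2 <- mk_tx("ctg", "+", data.frame(start = 21L, end = 20L + nchar(e1)),
               data.frame(start = 21L, end = 20L + nchar(e1)))
  g2 <- Biostrings::DNAStringSet(setNames(
    paste0(strrep("ATCTG", 4), e1, strrep("CATGA", 4)), "ctg"))
  motif_start <- 21L + 30L            # GAAGAA at genomic 51..56
  expect_true(ese_overlap(tx2, motif_start + 2L, g2, "GAAGAA"))
  expect_false(ese_overlap(tx2, motif_start + 32L, g2, "GAAGAA"))
})

test_that("annotation overlap intersects the residue under the cut", {
  ann <- data.frame(
    gene_id = c("g1", "g1", "g1", "g2"),
    aa_start = c(10L, 50L, 60L, 1L),
    aa_end = c(100L, 50L, 80L, 5L),
    kind = c("CDD_domain", "CDD_site", "Uniprot_helix", "CDD_domain"),
    label = c("d", "s", "h", "other"), stringsAsFactors = FALSE)
  expect_true(annotation_overlap("g1", 50L, ann)$in_domain)
  expect_true(annotation_overlap("g1", 50L, ann)$in_cdd_site)
  expect_false(annotation_overlap("g1", 5L, ann)$in_domain)
  expect_false(annotation_overlap("g1", 51L, ann)$in_cdd_site)
  expect_equal(annotation_overlap("g1", 70L, ann)$uniprot_2ary, "helix")
  expect_equal(annotation_overlap("g1", 20L, ann)$uniprot_2ary, "none")
  # other genes' intervals never leak
  expect_false(annotation_overlap("g2", 50L, ann)$in_domain)
})

test_that("SNP overlap honors the VAF threshold and indel footprints", {
  g <- mk_guide(start = 101L, strand = "+")   # footprint 101..123
  pol <- function(pos, ref, vaf) {
    data.frame(contig = "ctg", pos = pos, ref = ref, alt = "A", vaf = vaf)
  }
  expect_true(snp_overlap(g, pol(123L, "G", 0.12)))    # PAM base, VAF 12%
  expect_false(snp_overlap(g, pol(110L, "G", 0.05)))   # below threshold
  expect_true(snp_overlap(g, pol(110L, "G", 0.10)))    # >= 10% inclusive
  # 3-nt deletion footprint straddling the 5' edge
  expect_true(snp_overlap(g, pol(99L, "GGT", 0.3)))
  expect_false(snp_overlap(g, pol(97L, "GGT", 0.3)))   # ends at 99 < 101
  expect_false(snp_overlap(g, pol(124L, "G", 0.3)))    # past the PAM
  # minus-strand footprint extends 3 nt below the protospacer start
  gm <- mk_guide(start = 101L, strand = "-")
  expect_true(snp_overlap(gm, pol(98L, "G", 0.2)))
  expect_false(snp_overlap(gm, pol(97L, "G", 0.2)))
})

test_that("fixture SNP truths propagate into the feature table", {
  fx <- get_fixture()
  db <- get_fixture_db()$db
  for (truth in fx$manifest$snps) {
    row <- db[db$guide_id == truth$guide_id, ]
    expect_equal(row$snp_overlap, truth$expect_flag)
  }
})

test_that("guides cutting outside CDS carry NA target features", {
  db <- get_fixture_db()$db
  non_coding <- db[is.na(db$gene_id), ]
  expect_true(nrow(non_coding) > 0)
  expect_true(all(is.na(non_coding$pct_cds)))
  expect_true(all(is.na(non_coding$nmd_frames)))
})
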