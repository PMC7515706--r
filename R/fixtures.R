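random_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# codon choices per amino acid (stops excluded)
synonymous_codons <- function() {
  gc <- Biostrings::GENETIC_CODE
  split(names(gc)[gc != "*"], gc[gc != "*"])
}

backtranslate <- function(protein, syn = synonymous_codons()) {
  paste(vapply(strsplit(protein, "")[[1]], function(aa) {
    sample(syn[[aa]], 1L)
  }, character(1)), collapse = "")
}

#' Specification for a synthetic toy fixture
#'
#' Parameters of the deterministic generator behind [make_fixture()].
#' Defaults give a ~16 kb single-contig genome with six multi-exon
#' protein-coding genes on alternating strands, eight orthologs per gene
#' with a conserved core and variable tails, planted off-target copies,
#' polymorphisms straddling the 10% VAF cutoff, protein annotations, and
#' a small dropout screen — each with its ground truth recorded in the
#' manifest.
#'
#' @param seed Single integer governing all randomness.
#' @param n_genes Number of genes.
#' @param exons_per_gene Exons per gene.
#' @param codons_per_exon Coding codons per exon (start and stop
#'   included in the total).
#' @param intron_length,intergenic_length,utr5_length,utr3_length
#'   Structural lengths in nt.
#' @param n_orthologs Ortholog sequences per gene.
#' @param core_fraction Length-2 numeric: start/end of the conserved
#'   core as fractions of the protein.
#' @param tail_divergence Per-residue substitution probability in
#'   ortholog tails.
#' @param contig Contig name.
#' @return A `fixture_spec` list.
#' @export
fixture_spec <- function(seed = 42L, n_genes = 6L, exons_per_gene = 4L,
                         codons_per_exon = 30L, intron_length = 70L,
                         intergenic_length = 300L, utr5_length = 24L,
                         utr3_length = 90L, n_orthologs = 8L,
                         core_fraction = c(0.35, 0.65),
                         tail_divergence = 0.8, contig = "chrT") {
  stopifnot(n_genes >= 1, exons_per_gene >= 2, codons_per_exon >= 5,
            intron_length >= 10, utr5_length >= 0, utr3_length >= 0,
            n_orthologs >= 2, length(core_fraction) == 2,
            core_fraction[1] < core_fraction[2])
  if (intergenic_length < 60) {
    stop("intergenic_length < 60 would let genes abut or overlap planted sites")
  }
  structure(as.list(environment()), class = "fixture_spec")
}

# one gene: protein, orthologs, sense-layout sequences and intervals
build_gene <- function(spec, gene_idx) {
  n_codons <- spec$exons_per_gene * spec$codons_per_exon
  prot_len <- n_codons - 1L
  aas <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
           "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")
  protein <- paste(c("M", sample(aas, prot_len - 1L, replace = TRUE)),
                   collapse = "")
  syn <- synonymous_codons()
  cds <- paste0(backtranslate(protein, syn), sample(STOP_CODONS, 1L))

  core <- c(max(2L, round(prot_len * spec$core_fraction[1])),
            min(prot_len - 1L, round(prot_len * spec$core_fraction[2])))
  orthologs <- vapply(seq_len(spec$n_orthologs), function(o) {
    res <- strsplit(protein, "")[[1]]
    tail_idx <- setdiff(seq_len(prot_len), core[1]:core[2])
    flip <- tail_idx[runif(length(tail_idx)) < spec$tail_divergence]
    res[flip] <- sample(aas, length(flip), replace = TRUE)
    paste(res, collapse = "")
  }, character(1))
  names(orthologs) <- paste0("species_", seq_len(spec$n_orthologs))

  # split the CDS across exons at non-codon-aligned breakpoints
  cds_len <- nchar(cds)
  n_ex <- spec$exons_per_gene
  base <- round(seq_len(n_ex - 1L) * cds_len / n_ex)
  breaks <- pmin(cds_len - 3L, pmax(3L, base + sample(-2:2, n_ex - 1L,
                                                      replace = TRUE)))
  bounds <- cbind(c(1L, breaks + 1L), c(breaks, cds_len))
  utr5 <- random_dna(spec$utr5_length)
  utr3 <- random_dna(spec$utr3_length)

  # assemble the sense-strand segment and track sense-space intervals
  seg <- ""
  exon_iv <- matrix(0L, n_ex, 2L)
  cds_iv <- matrix(0L, n_ex, 2L)
  for (i in seq_len(n_ex)) {
    piece <- substr(cds, bounds[i, 1], bounds[i, 2])
    exon_seq <- piece
    cds_off <- 0L
    if (i == 1L) { exon_seq <- paste0(utr5, piece); cds_off <- nchar(utr5) }
    if (i == n_ex) exon_seq <- paste0(exon_seq, utr3)
    exon_iv[i, ] <- c(nchar(seg) + 1L, nchar(seg) + nchar(exon_seq))
    cds_iv[i, ] <- c(nchar(seg) + cds_off + 1L,
                     nchar(seg) + cds_off + nchar(piece))
    seg <- paste0(seg, exon_seq)
    if (i < n_ex) {
      seg <- paste0(seg, "GT", random_dna(spec$intron_length - 4L), "AG")
    }
  }
  list(gene_id = paste0("gene", gene_idx),
       strand = if (gene_idx %% 2L == 1L) "+" else "-",
       protein = protein, core = core, orthologs = orthologs,
       segment = seg, exon_iv = exon_iv, cds_iv = cds_iv)
}

mirror_iv <- function(iv, seg_len) {
  cbind(seg_len - iv[, 2] + 1L, seg_len - iv[, 1] + 1L)
}

plant_site <- function(chars, pos, site) {
  chars[pos:(pos + nchar(site) - 1L)] <- strsplit(site, "")[[1]]
  chars
}

mutate_protospacer <- function(proto, positions) {
  chars <- strsplit(proto, "")[[1]]
  for (p in positions) {
    chars[p] <- sample(setdiff(c("A", "C", "G", "T"), chars[p]), 1L)
  }
  paste(chars, collapse = "")
}

#' Generate a deterministic toy fixture with planted ground truth
#'
#' Builds a synthetic genome, gene models, ortholog sets, variants,
#' annotations, splicing-enhancer motifs, an efficacy table, and a small
#' dropout screen, entirely from the seed in `spec`. Planted truths — a
#' perfect-match and a two-mismatch off-target copy of one guide,
#' polymorphisms on either side of the 10% VAF cutoff, conserved-core
#' residue ranges, domain intervals, and true screen fold changes — are
#' recorded in the returned manifest so tests can assert them without
#' re-deriving anything. The same seed produces byte-identical output.
#'
#' @param spec A [fixture_spec()].
#' @param out_dir Optional directory; when given, all fixture files
#'   (FASTA/GTF/VCF/TSV/JSON) are written there.
#' @return List with `genome`, `transcripts_gtf` rows, `guides` (the
#'   extracted guide table), `orthologs` (list of [ortholog_set()]s),
#'   `polymorphisms`, `annotations`, `ese_motifs`, `efficacy`,
#'   `screen` (counts/design/gene_map/negative_controls), `manifest`,
#'   and `paths` when files were written.
#' @export
make_fixture <- function(spec = fixture_spec(), out_dir = NULL) {
  stopifnot(inherits(spec, "fixture_spec"))
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(spec$seed)

  genes <- lapply(seq_len(spec$n_genes), build_gene, spec = spec)

  # lay segments along one contig with intergenic spacers
  genome_chars <- character(0)
  gtf_rows <- list()
  gene_spans <- list()
  for (g in genes) {
    genome_chars <- c(genome_chars,
                      strsplit(random_dna(spec$intergenic_length), "")[[1]])
    offset <- length(genome_chars)
    seg_len <- nchar(g$segment)
    seg <- if (g$strand == "-") revcomp(g$segment) else g$segment
    genome_chars <- c(genome_chars, strsplit(seg, "")[[1]])
    exon_iv <- g$exon_iv; cds_iv <- g$cds_iv
    if (g$strand == "-") {
      exon_iv <- mirror_iv(exon_iv, seg_len)
      cds_iv <- mirror_iv(cds_iv, seg_len)
    }
    txid <- paste0(g$gene_id, ".t1")
    gtf_rows[[g$gene_id]] <- rbind(
      data.frame(type = "exon", start = offset + exon_iv[, 1],
                 end = offset + exon_iv[, 2]),
      data.frame(type = "CDS", start = offset + cds_iv[, 1],
                 end = offset + cds_iv[, 2])
    )
    gtf_rows[[g$gene_id]]$gene_id <- g$gene_id
    gtf_rows[[g$gene_id]]$transcript_id <- txid
    gtf_rows[[g$gene_id]]$strand <- g$strand
    gene_spans[[g$gene_id]] <- c(offset + 1L, offset + seg_len)
  }
  # trailing intergenic block hosts the planted off-target copies
  plant_block_start <- length(genome_chars) + 1L
  genome_chars <- c(genome_chars,
                    strsplit(random_dna(spec$intergenic_length), "")[[1]])

  genome0 <- Biostrings::DNAStringSet(
    setNames(paste(genome_chars, collapse = ""), spec$contig))
  guides0 <- extract_guides(genome0)

  # pick the off-target source: first guide cutting inside gene1's CDS
  g1_cds <- gtf_rows[["gene1"]][gtf_rows[["gene1"]]$type == "CDS", ]
  in_g1 <- vapply(guides0$cut_position, function(cp) {
    any(cp >= g1_cds$start & cp <= g1_cds$end)
  }, logical(1))
  src <- guides0[which(in_g1)[1], ]
  perfect_pos <- plant_block_start + 10L
  mm_positions <- c(5L, 12L)
  mm_pos <- plant_block_start + 10L + 23L + 40L
  site_perfect <- paste0(src$protospacer, "TGG")
  site_mm <- paste0(mutate_protospacer(src$protospacer, mm_positions), "TGG")
  genome_chars <- plant_site(genome_chars, perfect_pos, site_perfect)
  genome_chars <- plant_site(genome_chars, mm_pos, site_mm)

  genome <- Biostrings::DNAStringSet(
    setNames(paste(genome_chars, collapse = ""), spec$contig))
  guides <- extract_guides(genome)

  # polymorphisms straddling the VAF cutoff, on guides in gene2/gene3 CDS
  snp_rows <- list()
  snp_truth <- list()
  for (cfg in list(list(gene = "gene2", vaf = 0.20),
                   list(gene = "gene3", vaf = 0.05))) {
    rows <- gtf_rows[[cfg$gene]]
    cdsr <- rows[rows$type == "CDS", ]
    inside <- vapply(guides$cut_position, function(cp) {
      any(cp >= cdsr$start & cp <= cdsr$end)
    }, logical(1))
    gd <- guides[which(inside)[1], ]
    pos <- gd$start + 9L   # mid-protospacer
    ref <- genome_chars[pos]
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1L)
    snp_rows[[cfg$gene]] <- data.frame(
      contig = spec$contig, pos = pos, ref = ref, alt = alt,
      vaf = cfg$vaf, stringsAsFactors = FALSE)
    snp_truth[[cfg$gene]] <- list(guide_id = gd$guide_id, vaf = cfg$vaf,
                                  expect_flag = cfg$vaf >= 0.10)
  }
  polymorphisms <- do.call(rbind, snp_rows)
  rownames(polymorphisms) <- NULL

  # protein-space annotations anchored on the known core
  annotations <- do.call(rbind, lapply(genes, function(g) {
    L <- nchar(g$protein)
    data.frame(
      gene_id = g$gene_id,
      aa_start = c(g$core[1], (g$core[1] + g$core[2]) %/% 2L, 10L,
                   g$core[1], g$core[2] + 2L),
      aa_end = c(g$core[2], (g$core[1] + g$core[2]) %/% 2L, 40L,
                 g$core[1] + 8L, min(L, g$core[2] + 12L)),
      kind = c("CDD_domain", "CDD_site", "Pfam_domain", "Uniprot_helix",
               "Uniprot_beta"),
      label = c("core_domain", "active_site", "pfam_stub", "helix_1",
                "beta_1"),
      stringsAsFactors = FALSE)
  }))

  ese_motifs <- c("GAAGAA", "TCCTCC", "AAGGAC", "CTGGAT", "ACCAGA")

  efficacy <- data.frame(guide_id = guides$guide_id,
                         efficacy = round(runif(nrow(guides)), 4),
                         stringsAsFactors = FALSE)

  orthologs <- lapply(genes, function(g) {
    ortholog_set(g$orthologs, g$gene_id)
  })
  names(orthologs) <- vapply(genes, `[[`, character(1), "gene_id")

  screen <- build_screen_fixture(spec, genes, gtf_rows, guides)

  manifest <- list(
    seed = spec$seed, contig = spec$contig,
    genome_length = length(genome_chars),
    genes = lapply(genes, function(g) {
      list(gene_id = g$gene_id, strand = g$strand,
           span = gene_spans[[g$gene_id]], protein = g$protein,
           core_aa = g$core)
    }),
    planted_offtargets = list(
      source_guide_id = src$guide_id,
      perfect = list(position = perfect_pos, strand = "+", m = 0L),
      mismatched = list(position = mm_pos, strand = "+", m = 2L,
                        mismatch_positions = mm_positions)
    ),
    snps = snp_truth,
    screen_true_lfc = screen$true_lfc,
    negative_controls = screen$negative_controls
  )

  out <- list(genome = genome,
              transcripts_gtf = do.call(rbind, gtf_rows),
              guides = guides, orthologs = orthologs,
              polymorphisms = polymorphisms, annotations = annotations,
              ese_motifs = ese_motifs, efficacy = efficacy,
              screen = screen, manifest = manifest)
  if (!is.null(out_dir)) out$paths <- write_fixture(out, spec, out_dir)
  out
}

build_screen_fixture <- function(spec, genes, gtf_rows, guides) {
  gene_ids <- vapply(genes, `[[`, character(1), "gene_id")
  negative_controls <- utils::tail(gene_ids, 2L)
  true_lfc <- setNames(ifelse(gene_ids %in% negative_controls, 0, -2),
                       gene_ids)
  gene_map <- do.call(rbind, lapply(gene_ids, function(gid) {
    cdsr <- gtf_rows[[gid]][gtf_rows[[gid]]$type == "CDS", ]
    inside <- vapply(guides$cut_position, function(cp) {
      any(cp >= cdsr$start & cp <= cdsr$end)
    }, logical(1))
    ids <- utils::head(guides$guide_id[inside], 6L)
    data.frame(guide_id = ids, gene_id = gid, stringsAsFactors = FALSE)
  }))
  design <- data.frame(
    sample = c("ref_1", "ref_2", "d14_1", "d14_2"),
    library = "libA",
    role = c("reference", "reference", "endpoint", "endpoint"),
    stringsAsFactors = FALSE)
  n_g <- nrow(gene_map)
  base <- round(runif(n_g, 400, 600))
  counts <- vapply(seq_len(nrow(design)), function(si) {
    if (design$role[si] == "reference") {
      pmax(1, round(base * exp(rnorm(n_g, 0, 0.05))))
    } else {
      lfc <- true_lfc[gene_map$gene_id] + rnorm(n_g, 0, 0.15)
      pmax(0, round(base * 2^lfc * exp(rnorm(n_g, 0, 0.05))))
    }
  }, numeric(n_g))
  dimnames(counts) <- list(gene_map$guide_id, design$sample)
  list(counts = counts, design = design, gene_map = gene_map,
       negative_controls = negative_controls,
       true_lfc = as.list(true_lfc))
}

write_fixture <- function(fx, spec, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "orthologs"), showWarnings = FALSE)
  paths <- list()
  paths$genome <- file.path(out_dir, "genome.fa")
  write_genome(fx$genome, paths$genome)

  paths$gtf <- file.path(out_dir, "genes.gtf")
  g <- fx$transcripts_gtf
  attr_str <- sprintf('gene_id "%s"; transcript_id "%s"; tag "principal";',
                      g$gene_id, g$transcript_id)
  writeLines(paste(spec$contig, "fixture", g$type, g$start, g$end, ".",
                   g$strand, ".", attr_str, sep = "\t"), paths$gtf)

  paths$vcf <- file.path(out_dir, "variants.vcf")
  p <- fx$polymorphisms
  writeLines(c(
    "##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", spec$contig,
            fx$manifest$genome_length),
    '##INFO=<ID=AF,Number=A,Type=Float,Description="Allele Frequency">',
    "#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO",
    sprintf("%s\t%d\t.\t%s\t%s\t.\tPASS\tAF=%g",
            p$contig, p$pos, p$ref, p$alt, p$vaf)
  ), paths$vcf)

  paths$annotations <- file.path(out_dir, "annotations.tsv")
  write.table(fx$annotations, paths$annotations, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$ese_motifs <- file.path(out_dir, "ese_motifs.txt")
  writeLines(fx$ese_motifs, paths$ese_motifs)
  paths$efficacy <- file.path(out_dir, "efficacy.tsv")
  write.table(fx$efficacy, paths$efficacy, sep = "\t", quote = FALSE,
              row.names = FALSE)

  for (gid in names(fx$orthologs)) {
    set <- fx$orthologs[[gid]]
    fa <- file.path(out_dir, "orthologs", paste0(gid, ".fa"))
    writeLines(paste0(">", names(set$sequences), "\n", set$sequences), fa)
  }
  paths$orthologs <- file.path(out_dir, "orthologs")

  paths$counts <- file.path(out_dir, "screen_counts.tsv")
  cnt <- data.frame(guide_id = rownames(fx$screen$counts),
                    fx$screen$counts, check.names = FALSE)
  write.table(cnt, paths$counts, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$design <- file.path(out_dir, "screen_design.tsv")
  write.table(fx$screen$design, paths$design, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths$gene_map <- file.path(out_dir, "gene_map.tsv")
  write.table(fx$screen$gene_map, paths$gene_map, sep = "\t",
              quote = FALSE, row.names = FALSE)
  paths$negative_controls <- file.path(out_dir, "negative_controls.txt")
  writeLines(fx$screen$negative_controls, paths$negative_controls)

  paths$manifest <- file.path(out_dir, "manifest.json")
  writeLines(jsonlite::toJSON(fx$manifest, auto_unbox = TRUE, pretty = TRUE,
                              digits = NA),
             paths$manifest)
  paths
}

# synthetic feature table matching the canonical guide-feature model terms
make_training_features <- function(n) {
  data.frame(
    efficacy = runif(n),
    specificity = runif(n, 0.5, 1),
    conservation = pmin(21, pmax(-7, rnorm(n, 4, 4))),
    tm_celsius = rnorm(n, 60, 5),
    pam = factor(sample(c("AGG", "CGG", "GGG", "TGG"), n, replace = TRUE)),
    nmd = factor(sample(0:2, n, replace = TRUE, prob = c(0.2, 0.3, 0.5))),
    esp3i = runif(n) < 0.03,
    cds95 = runif(n) < 0.05,
    ese = runif(n) < 0.10,
    exon_asym = runif(n) < 0.40,
    internal_exon = runif(n) < 0.60,
    uniprot_beta = runif(n) < 0.10,
    uniprot_ccr = runif(n) < 0.05,
    uniprot_helix = runif(n) < 0.20,
    uniprot_turn = runif(n) < 0.05,
    polyA5 = runif(n) < 0.02,
    polyC5 = runif(n) < 0.01,
    polyG5 = runif(n) < 0.02,
    polyT3 = runif(n) < 0.07,
    domain = runif(n) < 0.40,
    snp = runif(n) < 0.03,
    cdd_site = runif(n) < 0.02,
    strand = factor(sample(c("same", "opposite"), n, replace = TRUE))
  )
}

#' Simulate a training table from a known effect model
#'
#' Draws guide feature vectors (synthetic, or rows resampled from a
#' supplied feature table), imposes an (experiment, gene) group
#' structure, and generates z-scored activity from a linear model with
#' the supplied coefficients plus Gaussian noise. Used for
#' parameter-recovery tests of [fit_feature_model()]: the fitted
#' coefficients should recover `effect_model` within sampling error.
#'
#' @param effect_model Named numeric vector of true coefficients over
#'   numeric/logical feature columns (unnamed features have zero
#'   effect).
#' @param n Number of records.
#' @param seed Integer seed.
#' @param features Optional feature data.frame to resample rows from;
#'   default generates a synthetic table covering the canonical model
#'   terms.
#' @param noise_sd Residual standard deviation (default 1).
#' @param n_experiments,n_genes Group structure sizes.
#' @return data.frame with `experiment_id`, `gene_id`, `guide_id`, `z`,
#'   and the feature columns.
#' @export
simulate_training_table <- function(effect_model, n, seed,
                                    features = NULL, noise_sd = 1,
                                    n_experiments = 3L, n_genes = 25L) {
  old_seed <- if (exists(".Random.seed", globalenv())) {
    get(".Random.seed", globalenv())
  } else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed,
                                         globalenv()))
  set.seed(seed)
  feats <- if (is.null(features)) {
    make_training_features(n)
  } else {
    features[sample(nrow(features), n, replace = TRUE), , drop = FALSE]
  }
  rownames(feats) <- NULL
  bad <- setdiff(names(effect_model), names(feats))
  if (length(bad)) stop("effect_model names not in features: ",
                        paste(bad, collapse = ", "))
  signal <- rep(0, n)
  for (f in names(effect_model)) {
    x <- feats[[f]]
    if (!is.numeric(x) && !is.logical(x)) {
      stop("effect_model only supports numeric/logical features: ", f)
    }
    signal <- signal + effect_model[[f]] * as.numeric(x)
  }
  out <- data.frame(
    experiment_id = sample(paste0("exp", seq_len(n_experiments)), n,
                           replace = TRUE),
    gene_id = sample(paste0("g", seq_len(n_genes)), n, replace = TRUE),
    guide_id = paste0("sim_", seq_len(n)),
    z = signal + rnorm(n, 0, noise_sd),
    stringsAsFactors = FALSE)
  cbind(out, feats)
}
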