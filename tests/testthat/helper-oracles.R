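# Independent brute-force oracles. Each one recomputes a quantity by the
# most direct method available, sharing no code with the implementation
# it checks.

rc <- function(x) {
  chartr("ACGT", "TGCA", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# --- guide extraction oracle: scan every window of every strand --------
oracle_extract_guides <- function(seq_chr, contig = "c") {
  L <- nchar(seq_chr)
  out <- list()
  for (q in seq_len(L)) {          # q = 1-based position of the PAM's N
    if (q + 2L <= L && substr(seq_chr, q + 1L, q + 2L) == "GG" &&
        q - 24L >= 1L && q + 5L <= L) {
      proto <- substr(seq_chr, q - 20L, q - 1L)
      pam <- substr(seq_chr, q, q + 2L)
      if (!grepl("N", paste0(proto, pam))) {
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = q - 20L, strand = "+",
          protospacer = proto, cut_position = q - 20L + 17L,
          stringsAsFactors = FALSE)
      }
    }
  }
  rcseq <- rc(seq_chr)
  for (q in seq_len(L)) {          # same scan on the reverse complement
    if (q + 2L <= L && substr(rcseq, q + 1L, q + 2L) == "GG" &&
        q - 24L >= 1L && q + 5L <= L) {
      proto <- substr(rcseq, q - 20L, q - 1L)
      pam <- substr(rcseq, q, q + 2L)
      if (!grepl("N", paste0(proto, pam))) {
        # map reverse-complement coordinates back to the reference strand:
        # rc-space protospacer [q-20, q-1] => forward [L-q+2, L-q+21]
        start_fwd <- L - q + 2L
        out[[length(out) + 1L]] <- data.frame(
          contig = contig, start = start_fwd, strand = "-",
          protospacer = proto, cut_position = start_fwd + 3L,
          stringsAsFactors = FALSE)
      }
    }
  }
  df <- do.call(rbind, out)
  if (is.null(df)) return(df)
  df[order(df$contig, df$start, df$strand), , drop = FALSE]
}

# --- off-target full-scan oracle ---------------------------------------
# every NGG-anchored window on either strand within max_mm of the
# protospacer; returns (contig, strand, position, m, mismatch key)
oracle_offtargets <- function(proto, seqs, max_mm = 4L) {
  gchars <- strsplit(proto, "")[[1]]
  rows <- list()
  for (contig in names(seqs)) {
    s <- as.character(seqs[[contig]])
    L <- nchar(s)
    for (st in seq_len(L - 22L)) {   # 23-mer window at st..st+22
      win <- substr(s, st, st + 22L)
      if (grepl("N", win)) next
      # plus strand: PAM NGG at the 3' end
      if (substr(win, 22L, 23L) == "GG") {
        mism <- which(strsplit(substr(win, 1L, 20L), "")[[1]] != gchars)
        if (length(mism) <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = contig, strand = "+", position = st,
            m = length(mism), key = paste(mism, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
      # minus strand: CCN at the window's 5' end on the reference
      if (substr(win, 1L, 2L) == "CC") {
        mism <- which(strsplit(substr(rc(win), 1L, 20L), "")[[1]] != gchars)
        if (length(mism) <= max_mm) {
          rows[[length(rows) + 1L]] <- data.frame(
            contig = contig, strand = "-", position = st + 3L,
            m = length(mism), key = paste(mism, collapse = ","),
            stringsAsFactors = FALSE)
        }
      }
    }
  }
  df <- do.call(rbind, rows)
  if (is.null(df)) return(df)
  df[order(df$contig, df$position, df$strand), , drop = FALSE]
}

# --- affine-gap semi-global alignment DP oracle ------------------------
# free end gaps at the query's ends (subject overhang unpenalized);
# gap of length k costs open + k * extend, matching the implementation's
# stated convention
oracle_semiglobal <- function(query, subject, mat, open = 10, extend = 1) {
  q <- strsplit(query, "")[[1]]
  s <- strsplit(subject, "")[[1]]
  n <- length(q); m <- length(s)
  NEG <- -1e9
  # M: q[i] aligned to s[j]; X: gap in subject (query char unmatched);
  # Y: gap in query (subject char unmatched)
  M <- matrix(NEG, n + 1L, m + 1L)
  X <- matrix(NEG, n + 1L, m + 1L)
  Y <- matrix(NEG, n + 1L, m + 1L)
  M[1, 1] <- 0
  for (j in 1:m) Y[1, j + 1L] <- 0          # free leading subject overhang
  for (i in 1:n) X[i + 1L, 1] <- -(open + extend * i)
  for (i in 1:n) {
    for (j in 1:m) {
      sc <- mat[q[i], s[j]]
      M[i + 1L, j + 1L] <- sc + max(M[i, j], X[i, j], Y[i, j])
      X[i + 1L, j + 1L] <- max(M[i, j + 1L] - open - extend,
                               X[i, j + 1L] - extend,
                               Y[i, j + 1L] - open - extend)
      Y[i + 1L, j + 1L] <- max(M[i + 1L, j] - open - extend,
                               Y[i + 1L, j] - extend,
                               X[i + 1L, j] - open - extend)
    }
  }
  # free trailing subject overhang: best over subject end positions
  max(vapply(1:(m + 1L), function(j) max(M[n + 1L, j], X[n + 1L, j]),
             numeric(1)))
}

# --- nearest-neighbor Tm oracle ----------------------------------------
# re-derives the stack sums from the ten unique published parameters via
# complement lookup, rather than the implementation's 16-entry table
oracle_tm <- function(seq, ct = 0.25e-6, na = 0.05) {
  dh10 <- c(AA = -7.9, AT = -7.2, TA = -7.2, CA = -8.5, GT = -8.4,
            CT = -7.8, GA = -8.2, CG = -10.6, GC = -9.8, GG = -8.0)
  ds10 <- c(AA = -22.2, AT = -20.4, TA = -21.3, CA = -22.7, GT = -22.4,
            CT = -21.0, GA = -22.2, CG = -27.2, GC = -24.4, GG = -19.9)
  comp <- c(A = "T", C = "G", G = "C", T = "A")
  lookup <- function(step) {
    if (step %in% names(dh10)) return(c(dh10[[step]], ds10[[step]]))
    # reverse-complement of the step shares its thermodynamics
    bases <- strsplit(step, "")[[1]]
    alt <- paste0(comp[[bases[2]]], comp[[bases[1]]])
    c(dh10[[alt]], ds10[[alt]])
  }
  bases <- strsplit(seq, "")[[1]]
  n <- length(bases)
  dh <- 0; ds <- 0
  for (i in 1:(n - 1L)) {
    v <- lookup(paste0(bases[i], bases[i + 1L]))
    dh <- dh + v[1]; ds <- ds + v[2]
  }
  for (term in bases[c(1, n)]) {
    if (term %in% c("G", "C")) { dh <- dh + 0.1; ds <- ds - 2.8 }
    else { dh <- dh + 2.3; ds <- ds + 4.1 }
  }
  ds <- ds + 0.368 * (n - 1L) * log(na)
  1000 * dh / (ds + 1.9872 * log(ct / 4)) - 273.15
}

# --- exhaustive guide-picking oracle -----------------------------------
# best subset under the spacing constraint: maximize filled slots, then
# minimize summed rank; candidates arrive pre-sorted by (tier, efficacy)
oracle_pick <- function(cand_cuts, slots, fixed_cuts, min_spacing) {
  n <- length(cand_cuts)
  for (k in seq(min(slots, n), 0L)) {
    if (k == 0L) return(integer(0))
    combos <- combn(n, k)
    feas <- list()
    for (j in seq_len(ncol(combos))) {
      idx <- combos[, j]
      cuts <- c(fixed_cuts, cand_cuts[idx])
      pair_ok <- TRUE
      for (a in seq_along(cand_cuts[idx])) {
        others <- setdiff(seq_along(cuts), length(fixed_cuts) + a)
        if (any(abs(cuts[length(fixed_cuts) + a] - cuts[others]) <
                min_spacing)) { pair_ok <- FALSE; break }
      }
      if (pair_ok) feas[[length(feas) + 1L]] <- idx
    }
    if (length(feas)) {
      sums <- vapply(feas, sum, numeric(1))
      return(feas[[which.min(sums)]])
    }
  }
  integer(0)
}

# --- shifted-frame premature-stop oracle -------------------------------
# scans a spliced transcript string directly: insertion of k nt at
# transcript offset tb (0-based first downstream base), CDS starting at
# offset s; returns 0-based offset of the first downstream stop codon
# start, or NA
oracle_shifted_stop <- function(mrna, tb, s, k) {
  total <- nchar(mrna)
  p <- tb
  while ((p - s + k) %% 3L != 0L) p <- p + 1L
  while (p + 2L < total) {
    if (substr(mrna, p + 1L, p + 3L) %in% c("TAA", "TAG", "TGA")) return(p)
    p <- p + 3L
  }
  NA_integer_
}

# --- LMG ordering oracle (small p) -------------------------------------
# literal definition: average over all p! orderings of each predictor's
# incremental R^2, with R^2 from lm()
oracle_lmg <- function(df, response, predictors) {
  p <- length(predictors)
  perms <- function(v) {
    if (length(v) <= 1L) return(list(v))
    out <- list()
    for (i in seq_along(v)) {
      for (rest in perms(v[-i])) out[[length(out) + 1L]] <- c(v[i], rest)
    }
    out
  }
  r2 <- function(vars) {
    if (!length(vars)) return(0)
    fml <- as.formula(paste(response, "~", paste(vars, collapse = "+")))
    summary(lm(fml, data = df))$r.squared
  }
  shares <- setNames(numeric(p), predictors)
  all_ord <- perms(predictors)
  for (ord in all_ord) {
    prev <- 0
    for (i in seq_along(ord)) {
      cur <- r2(ord[1:i])
      shares[ord[i]] <- shares[ord[i]] + (cur - prev)
      prev <- cur
    }
  }
  shares / length(all_ord)
}
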