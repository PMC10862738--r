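# Independent brute-force oracles used to check the implementation, plus
# small fixture builders. These deliberately use naive string scanning and
# explicit loops, sharing no code with the package internals.

make_ref <- function(..., names_ = NULL) {
  seqs <- c(...)
  ref <- Biostrings::DNAStringSet(seqs)
  names(ref) <- if (is.null(names_)) paste0("chr", seq_along(seqs)) else names_
  ref
}

variant_row <- function(chrom, pos, ref, alt, sample_id = "s",
                        alt_depth = 10L, total_depth = 20L) {
  n <- length(pos)
  alt_depth <- rep_len(as.integer(alt_depth), n)
  total_depth <- rep_len(as.integer(total_depth), n)
  data.frame(chrom = rep_len(chrom, n), pos = as.integer(pos),
             ref = rep_len(ref, n), alt = rep_len(alt, n),
             sample_id = rep_len(sample_id, n), alt_depth = alt_depth,
             total_depth = total_depth,
             vaf = ifelse(total_depth > 0, alt_depth / total_depth, 0),
             stringsAsFactors = FALSE)
}

# String-scan oracle: which dinucleotides overlapping the mutated base gain
# GG (plus strand) or CC (minus strand)? Returns 0-based gg_start plus
# strand, requiring the full 3-base PAM window to fit on the contig with no
# N at the N position.
oracle_pam_scan <- function(seq_str, pos, ref, alt) {
  stopifnot(substr(seq_str, pos, pos) == ref)
  L <- nchar(seq_str)
  mut <- paste0(substr(seq_str, 1, pos - 1), alt,
                substr(seq_str, pos + 1, L))
  out <- data.frame(strand = character(), gg_start0 = integer(),
                    stringsAsFactors = FALSE)
  for (a in max(1, pos - 1):pos) {
    if (a + 1 > L) next
    g2 <- substr(seq_str, a, a + 1)
    m2 <- substr(mut, a, a + 1)
    if (m2 == "GG" && g2 != "GG" && a - 1 >= 1 &&
        substr(seq_str, a - 1, a - 1) != "N") {
      out <- rbind(out, data.frame(strand = "+", gg_start0 = a - 1))
    }
    if (m2 == "CC" && g2 != "CC" && a + 2 <= L &&
        substr(seq_str, a + 2, a + 2) != "N") {
      out <- rbind(out, data.frame(strand = "-", gg_start0 = a - 1))
    }
  }
  out
}

# All 192 (left, ref, right, alt) combinations, embedded in a T-padded
# context so every PAM window fits.
context_grid <- function() {
  bases <- c("A", "C", "G", "T")
  g <- expand.grid(left = bases, ref = bases, right = bases, alt = bases,
                   stringsAsFactors = FALSE)
  g[g$ref != g$alt, , drop = FALSE]
}

# Brute-force presence statistics from logical matrices (rows PAMs, cols
# samples). pres is "called present"; noc masks entries out entirely.
oracle_pct_truncal <- function(pres, noc, truncal_ids, sample) {
  num <- 0L; den <- 0L
  for (p in truncal_ids) {
    if (noc[p, sample]) next
    den <- den + 1L
    if (pres[p, sample]) num <- num + 1L
  }
  if (den == 0) NA_real_ else num / den
}

oracle_pct_maintained <- function(pres, noc, pam, mets) {
  num <- 0L; den <- 0L
  for (s in mets) {
    if (noc[pam, s]) next
    den <- den + 1L
    if (pres[pam, s]) num <- num + 1L
  }
  if (den == 0) NA_real_ else num / den
}

oracle_shared_all <- function(pres, noc, truncal_ids, lesions) {
  if (length(truncal_ids) == 0) return(NA_real_)
  hit <- 0L
  for (p in truncal_ids) {
    all_present <- TRUE
    for (s in lesions) {
      if (noc[p, s] || !pres[p, s]) { all_present <- FALSE; break }
    }
    if (all_present) hit <- hit + 1L
  }
  hit / length(truncal_ids)
}

random_presence <- function(n_pams, n_samples, p_present = 0.7, p_nocall = 0) {
  pam_ids <- paste0("pam", seq_len(n_pams))
  sample_ids <- paste0("s", seq_len(n_samples))
  noc <- matrix(runif(n_pams * n_samples) < p_nocall, n_pams, n_samples,
                dimnames = list(pam_ids, sample_ids))
  pres <- matrix(runif(n_pams * n_samples) < p_present, n_pams, n_samples,
                 dimnames = list(pam_ids, sample_ids))
  pres[noc] <- FALSE
  list(pres = pres, noc = noc, pam_ids = pam_ids, sample_ids = sample_ids)
}

# Minimal VCF writer independent of the package's writer, for read tests.
write_fixture_vcf <- function(path, sample, rows) {
  hdr <- c("##fileformat=VCFv4.2",
           "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"AD\">",
           "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"DP\">",
           paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample))
  writeLines(c(hdr, rows), path)
  path
}

two_sample_cfg <- function(seed, ..., depth = 60) {
  sim_config(seed = seed,
             samples = data.frame(sample_id = c("P1", "M1"),
                                  role = c("primary", "metastasis"),
                                  purity = 1, mean_depth = depth,
                                  stringsAsFactors = FALSE), ...)
}
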