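# Somatic subtraction and novel-PAM detection.
#
# A substitution creates a novel SpCas9 PAM when a dinucleotide overlapping
# the mutated base becomes GG on the plus strand (reported with the NGG
# window) or CC on the forward sequence (an NGG PAM on the minus strand),
# and that dinucleotide was not already GG/CC in the germline. Because the
# mutated base must itself become G (or C), only alt alleles G and C can
# ever create a PAM, and a single substitution can create at most two PAMs
# per strand class (left and right dinucleotide).

#' Germline filtering thresholds
#'
#' Thresholds applied to the normal-sample variant set before it is used
#' for tumor-normal subtraction: mapping quality >= 20, depth >= 10 and
#' allele frequency >= 0.05 by default. Germline variants failing these
#' filters are considered unreliable and are not used to subtract (they do
#' not rescue a tumor variant).
#'
#' @param min_mapping_quality Phred-scaled mapping-quality threshold.
#'   Only applied when the variant table carries a `mapping_quality` column.
#' @param min_depth Minimum total read depth.
#' @param min_allele_frequency Minimum allele fraction.
#' @return An object of class `germline_filter`.
#' @export
germline_filter <- function(min_mapping_quality = 20, min_depth = 10,
                            min_allele_frequency = 0.05) {
  stopifnot(min_mapping_quality >= 0, min_depth >= 0, min_allele_frequency >= 0)
  structure(list(min_mapping_quality = min_mapping_quality,
                 min_depth = min_depth,
                 min_allele_frequency = min_allele_frequency),
            class = "germline_filter")
}

#' Tumor-normal subtraction of variant sets
#'
#' Returns the tumor variants whose (chrom, pos, ref, alt) key is absent
#' from the filtered normal set. Keys are exact and alt-specific: an SBS
#' pipeline needs no left-alignment tolerance, and a normal-sample A>T does
#' not mask a tumor A>G at the same position.
#'
#' @param tumor,normal Variant data.frames (see [read_vcf()]).
#' @param filter A [germline_filter()] applied to `normal` before
#'   subtraction.
#' @return The somatic subset of `tumor`.
#' @export
subtract_somatic <- function(tumor, normal, filter = germline_filter()) {
  if (nrow(tumor) == 0) {
    warning("empty tumor variant collection; nothing to subtract")
    return(tumor)
  }
  keep <- normal$total_depth >= filter$min_depth &
    normal$vaf >= filter$min_allele_frequency
  if (!is.null(normal$mapping_quality)) {
    keep <- keep & normal$mapping_quality >= filter$min_mapping_quality
  }
  normal_keys <- variant_key(normal[keep, , drop = FALSE])
  out <- tumor[!variant_key(tumor) %in% normal_keys, , drop = FALSE]
  rownames(out) <- NULL
  out
}

empty_pams <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(), alt_depth = integer(),
             total_depth = integer(), vaf = numeric(), pam_start = integer(),
             strand = character(), gg_start = integer(), gg_end = integer(),
             protospacer = character(), protospacer_truncated = logical(),
             pam_id = character(), stringsAsFactors = FALSE)
}

#' Detect novel NGG PAMs created by substitutions
#'
#' For each variant, tests the two dinucleotides overlapping the mutated
#' base. A plus-strand PAM is created when a dinucleotide becomes GG in the
#' mutant but was not GG in the germline; a minus-strand PAM when a
#' dinucleotide becomes CC (the reverse complement reads NGG). The 20-base
#' protospacer 5' of the PAM on the PAM strand is recorded, flagged as
#' truncated near contig ends. Sites with N inside the 3-base PAM window
#' are skipped and counted (`n_skipped_n` attribute), as expected near
#' assembly gaps.
#'
#' @param variants Variant data.frame; `pos` is 1-based. The reference base
#'   at each position must equal `ref` (a mismatch is an error).
#' @param reference A `DNAStringSet` (see [read_fasta()]) containing every
#'   chromosome named in `variants`.
#' @param protospacer_length Number of protospacer bases to record.
#' @return A PAM-creation data.frame, one row per novel PAM: the variant
#'   columns plus `pam_start` (0-based start of the 3-base NGG/CCN window),
#'   `strand`, `gg_start`/`gg_end` (0-based positions of the novel GG or CC
#'   dinucleotide), `protospacer`, `protospacer_truncated` and `pam_id`.
#' @export
detect_novel_pams <- function(variants, reference, protospacer_length = 20L) {
  if (nrow(variants) == 0) {
    out <- empty_pams()
    attr(out, "n_skipped_n") <- 0L
    return(out)
  }
  miss <- setdiff(unique(variants$chrom), names(reference))
  if (length(miss) > 0) stop("chromosome(s) missing from reference: ",
                             paste(miss, collapse = ", "))
  res <- vector("list", length(unique(variants$chrom)))
  n_skipped_n <- 0L
  for (k in seq_along(unique(variants$chrom))) {
    ch <- unique(variants$chrom)[k]
    v <- variants[variants$chrom == ch, , drop = FALSE]
    seq_str <- as.character(reference[[ch]])
    L <- nchar(seq_str)
    if (any(v$pos < 1L | v$pos > L)) stop("variant position outside ", ch)
    refb <- substring(seq_str, v$pos, v$pos)
    bad <- refb != v$ref
    if (any(bad)) {
      i <- which(bad)[1]
      stop("reference mismatch at ", ch, ":", v$pos[i], " (reference has ",
           refb[i], ", variant claims ", v$ref[i], ")")
    }
    left <- ifelse(v$pos > 1L, substring(seq_str, v$pos - 1L, v$pos - 1L), "")
    right <- ifelse(v$pos < L, substring(seq_str, v$pos + 1L, v$pos + 1L), "")

    # candidate creations: each is (variant row, gg 1-based start a, strand)
    # plus strand: GG at (a, a+1), N at a-1; minus: CC at (a, a+1), N at a+2
    cand <- list(
      list(sel = v$alt == "G" & left == "G",  a = v$pos - 1L, strand = "+"),
      list(sel = v$alt == "G" & right == "G", a = v$pos,      strand = "+"),
      list(sel = v$alt == "C" & left == "C",  a = v$pos - 1L, strand = "-"),
      list(sel = v$alt == "C" & right == "C", a = v$pos,      strand = "-"))
    parts <- list()
    for (cc in cand) {
      i <- which(cc$sel)
      if (length(i) == 0) next
      a <- cc$a[i]
      if (cc$strand == "+") {
        win_start <- a - 1L   # N base
        win_end <- a + 1L
      } else {
        win_start <- a
        win_end <- a + 2L     # N base
      }
      ok <- win_start >= 1L & win_end <= L
      npos <- if (cc$strand == "+") win_start else win_end
      nbase <- rep(NA_character_, length(i))
      nbase[ok] <- substring(seq_str, npos[ok], npos[ok])
      has_n <- ok & nbase == "N"
      n_skipped_n <- n_skipped_n + sum(has_n, na.rm = TRUE)
      keep <- ok & !has_n
      if (!any(keep)) next
      i <- i[keep]; a <- a[keep]
      win_start <- win_start[keep]
      if (cc$strand == "+") {
        ps_start <- pmax(1L, win_start - protospacer_length)
        ps_end <- win_start - 1L
        ps <- ifelse(ps_end >= ps_start, substring(seq_str, ps_start, ps_end), "")
        trunc <- nchar(ps) < protospacer_length
      } else {
        ps_start <- a + 3L
        ps_end <- pmin(L, a + 2L + protospacer_length)
        ps_fwd <- ifelse(ps_end >= ps_start, substring(seq_str, ps_start, ps_end), "")
        ps <- vapply(ps_fwd, revcomp, character(1), USE.NAMES = FALSE)
        trunc <- nchar(ps) < protospacer_length
      }
      parts[[length(parts) + 1L]] <- data.frame(
        v[i, c("chrom", "pos", "ref", "alt", "sample_id",
               "alt_depth", "total_depth", "vaf")],
        pam_start = if (cc$strand == "+") a - 2L else a - 1L,
        strand = cc$strand, gg_start = a - 1L, gg_end = a,
        protospacer = ps, protospacer_truncated = trunc,
        stringsAsFactors = FALSE)
    }
    res[[k]] <- if (length(parts) > 0) do.call(rbind, parts) else NULL
  }
  out <- do.call(rbind, c(list(empty_pams()[, setdiff(names(empty_pams()), "pam_id")]),
                          res[!vapply(res, is.null, logical(1))]))
  if (nrow(out) > 0) {
    out <- out[order(out$chrom, out$pos, out$strand, out$gg_start), , drop = FALSE]
    out$pam_id <- paste(out$chrom, out$pos, out$ref, out$alt, out$strand,
                        out$gg_start, sep = ":")
  } else {
    out$pam_id <- character()
  }
  rownames(out) <- NULL
  attr(out, "n_skipped_n") <- n_skipped_n
  out
}

revcomp <- function(x) {
  if (nchar(x) == 0) return(x)
  chartr("ACGTN", "TGCAN", paste(rev(strsplit(x, "")[[1]]), collapse = ""))
}

#' Fraction of substitutions that create at least one novel PAM
#'
#' Counts variants with one or more PAM creations and divides by the number
#' of variants -- the per-variant creation rate, not creations per variant.
#' On uniformly random sequence and a uniform substitution spectrum the
#' combinatorial rate is 42/192 = 21.875%; observed genome rates are lower
#' because sequence composition, mutational spectra and downstream
#' mappability filters all reduce it.
#'
#' @param variants Variant data.frame.
#' @param reference A `DNAStringSet`.
#' @return A single fraction in `[0, 1]`.
#' @export
pam_creation_rate <- function(variants, reference) {
  if (nrow(variants) == 0) stop("undefined PAM creation rate for empty variant collection")
  pams <- detect_novel_pams(variants, reference)
  length(unique(variant_key(pams))) / nrow(variants)
}

#' Keep PAM creations at or above a VAF threshold
#'
#' A VAF threshold of 0.95 isolates the PAMs sitting in regions of loss of
#' heterozygosity (every tumor copy carries the variant); the threshold is
#' inclusive ("95% or higher").
#'
#' @param pams PAM-creation data.frame (see [detect_novel_pams()]).
#' @param threshold VAF threshold in `[0, 1]`.
#' @return The subset of `pams` with `vaf >= threshold`, order preserved.
#' @export
filter_high_vaf <- function(pams, threshold = 0.95) {
  if (!is.numeric(threshold) || length(threshold) != 1 ||
      threshold < 0 || threshold > 1) {
    stop("threshold must be a single value in [0, 1]")
  }
  out <- pams[pams$vaf >= threshold, , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Per-sample somatic PAM set
#'
#' Bundles the PAM creations discovered for one tumor sample with the
#' high-VAF subset used for LOH-focused analyses.
#'
#' @param case_id,sample_id Identifiers.
#' @param pams PAM-creation data.frame.
#' @param high_vaf_threshold Threshold for the high-VAF subset.
#' @return An object of class `somatic_pam_set` with elements `case_id`,
#'   `sample_id`, `pams` and `high_vaf_subset`.
#' @export
somatic_pam_set <- function(case_id, sample_id, pams, high_vaf_threshold = 0.95) {
  structure(list(case_id = case_id, sample_id = sample_id, pams = pams,
                 high_vaf_subset = filter_high_vaf(pams, high_vaf_threshold)),
            class = "somatic_pam_set")
}

#' @export
print.somatic_pam_set <- function(x, ...) {
  cat("somatic PAM set: case", x$case_id, "sample", x$sample_id, "\n")
  cat("  ", nrow(x$pams), "PAM creations;", nrow(x$high_vaf_subset),
      "at high VAF\n")
  invisible(x)
}
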