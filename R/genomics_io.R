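# Readers and writers for the formats the pipeline touches. Internal model:
#   variants  - data.frame(chrom, pos [1-based], ref, alt, sample_id,
#               alt_depth, total_depth, vaf)
#   segments  - data.frame(chrom, start, end [0-based half-open], total_cn,
#               sample_id)
#   arms      - data.frame(chrom, start, end [0-based half-open], arm)

#' Read a reference FASTA
#'
#' Reads a FASTA file into a `DNAStringSet`, normalizing lowercase to
#' uppercase. Only the characters A, C, G, T and N are accepted; sequence
#' names are truncated at the first whitespace.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] with one element per record.
#' @export
read_fasta <- function(path) {
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  seqs <- withCallingHandlers(
    Biostrings::readDNAStringSet(path),
    warning = function(w) {
      if (grepl("invalid one-letter sequence codes", conditionMessage(w))) {
        stop("FASTA format error: invalid sequence characters in ", path,
             call. = FALSE)
      }
      invokeRestart("muffleWarning")
    })
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs <- Biostrings::DNAStringSet(toupper(as.character(seqs)))
  ok <- Biostrings::letterFrequency(seqs, letters = "ACGTN", OR = "")
  n_ok <- rowSums(ok)
  bad <- which(n_ok != Biostrings::width(seqs))
  if (length(bad) > 0) {
    stop("FASTA format error: sequence '", names(seqs)[bad[1]],
         "' contains characters outside {A,C,G,T,N}")
  }
  seqs
}

#' Write sequences to FASTA
#'
#' @param seqs A named `DNAStringSet` or named character vector of sequences.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path) {
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path)
  invisible(path)
}

empty_variants <- function() {
  data.frame(chrom = character(), pos = integer(), ref = character(),
             alt = character(), sample_id = character(),
             alt_depth = integer(), total_depth = integer(),
             vaf = numeric(), stringsAsFactors = FALSE)
}

#' Read single-base substitutions from a VCF
#'
#' Parses a VCF v4.2 file and returns the biallelic single-base
#' substitutions for one sample. Multiallelic records are split into one
#' record per alternate allele, with the per-allele depth divided by the
#' summed allelic depth of the site. Indels and symbolic alleles are skipped
#' and counted (see the `n_skipped` attribute of the result). The VAF is
#' always recomputed from the AD field rather than taken from an AF tag,
#' because AF conventions differ between callers.
#'
#' @param path Path to a VCF file (plain text or gzipped).
#' @param sample Sample name as given in the VCF header line.
#' @return A variant data.frame (chrom, pos, ref, alt, sample_id, alt_depth,
#'   total_depth, vaf) with attribute `n_skipped`, the number of skipped
#'   non-SBS alleles. `pos` is 1-based as in the VCF.
#' @export
read_vcf <- function(path, sample) {
  if (!file.exists(path)) stop("VCF file not found: ", path)
  v <- vcfR::read.vcfR(path, verbose = FALSE)
  if (nrow(v@fix) == 0) {
    out <- empty_variants()
    attr(out, "n_skipped") <- 0L
    return(out)
  }
  samples <- colnames(v@gt)[-1]
  if (!sample %in% samples) {
    stop("sample '", sample, "' not found in VCF (has: ",
         paste(samples, collapse = ", "), ")")
  }
  fix <- vcfR::getFIX(v)
  ad <- vcfR::extract.gt(v, element = "AD")[, sample]
  if (all(is.na(ad))) stop("VCF field error: no AD (allelic depth) values for sample '",
                           sample, "'")
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  ref <- fix[, "REF"]
  alt_field <- fix[, "ALT"]

  alt_list <- strsplit(alt_field, ",", fixed = TRUE)
  ad_list <- lapply(strsplit(ad, ",", fixed = TRUE), function(x) suppressWarnings(as.integer(x)))

  rows <- vector("list", length(pos))
  n_skipped <- 0L
  for (i in seq_along(pos)) {
    alts <- alt_list[[i]]
    ads <- ad_list[[i]]
    if (any(is.na(ads)) || length(ads) != length(alts) + 1L) {
      stop("VCF field error: malformed AD at ", chrom[i], ":", pos[i])
    }
    total <- sum(ads)
    sbs <- nchar(ref[i]) == 1L & nchar(alts) == 1L &
      ref[i] %in% c("A", "C", "G", "T") & alts %in% c("A", "C", "G", "T")
    n_skipped <- n_skipped + sum(!sbs)
    if (!any(sbs)) next
    j <- which(sbs)
    rows[[i]] <- data.frame(
      chrom = chrom[i], pos = pos[i], ref = ref[i], alt = alts[j],
      sample_id = sample, alt_depth = ads[j + 1L], total_depth = total,
      vaf = if (total > 0) ads[j + 1L] / total else 0,
      stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, c(list(empty_variants()), rows))
  rownames(out) <- NULL
  attr(out, "n_skipped") <- n_skipped
  out
}

#' Write single-sample variants to a VCF
#'
#' Emits a minimal VCF v4.2 with AD and DP per-sample fields, sorted by
#' chromosome and position. Round-trips through [read_vcf()].
#'
#' @param variants Variant data.frame as returned by [read_vcf()].
#' @param path Output path.
#' @param sample_id Sample column name; defaults to the `sample_id` of the
#'   first variant.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(variants, path, sample_id = NULL) {
  if (is.null(sample_id)) {
    sample_id <- if (nrow(variants) > 0) variants$sample_id[1] else "SAMPLE"
  }
  hdr <- c(
    "##fileformat=VCFv4.2",
    "##source=pamtrace",
    "##FORMAT=<ID=AD,Number=R,Type=Integer,Description=\"Allelic depths for the ref and alt alleles\">",
    "##FORMAT=<ID=DP,Number=1,Type=Integer,Description=\"Read depth\">",
    paste0("#CHROM\tPOS\tID\tREF\tALT\tQUAL\tFILTER\tINFO\tFORMAT\t", sample_id))
  if (nrow(variants) > 0) {
    o <- order(variants$chrom, variants$pos, variants$alt)
    v <- variants[o, , drop = FALSE]
    ref_depth <- v$total_depth - v$alt_depth
    body <- paste(v$chrom, v$pos, ".", v$ref, v$alt, ".", "PASS", ".",
                  "AD:DP", paste0(ref_depth, ",", v$alt_depth, ":", v$total_depth),
                  sep = "\t")
  } else {
    body <- character()
  }
  writeLines(c(hdr, body), path)
  invisible(path)
}

#' Read a copy-number segment table
#'
#' Reads a tab-separated segment file with columns `chrom` (or
#' `chromosome`), `start`, `end` and `cn` -- the layout of a CNVkit
#' `call.cns` file reduced to integer total copy number. Coordinates are
#' interpreted as 0-based half-open. Overlapping segments for one sample are
#' rejected.
#'
#' @param path Path to the segment TSV.
#' @param sample Sample identifier. Defaults to the file name stem,
#'   matching the one-file-per-sample CNVkit convention.
#' @return A segment data.frame (chrom, start, end, total_cn, sample_id).
#' @export
read_segments <- function(path, sample = NULL) {
  if (!file.exists(path)) stop("segment file not found: ", path)
  if (is.null(sample)) sample <- sub("\\.[^.]*$", "", basename(path))
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE,
                    check.names = FALSE)
  nm <- tolower(names(tab))
  col <- function(x) {
    i <- match(x, nm)
    i[!is.na(i)][1]
  }
  ic <- col(c("chrom", "chromosome"))
  is_ <- col("start"); ie <- col("end"); icn <- col("cn")
  if (anyNA(c(ic, is_, ie, icn))) {
    stop("segment format error: need columns chrom/chromosome, start, end, cn in ", path)
  }
  cn_raw <- tab[[icn]]
  cn <- suppressWarnings(as.numeric(cn_raw))
  if (anyNA(cn) || any(cn < 0) || any(cn != round(cn))) {
    stop("segment format error: cn must be a non-negative integer in ", path)
  }
  seg <- data.frame(chrom = as.character(tab[[ic]]),
                    start = as.integer(tab[[is_]]),
                    end = as.integer(tab[[ie]]),
                    total_cn = as.integer(cn),
                    sample_id = sample, stringsAsFactors = FALSE)
  if (any(seg$start >= seg$end)) stop("segment format error: start must be < end")
  seg <- seg[order(seg$chrom, seg$start), , drop = FALSE]
  for (ch in unique(seg$chrom)) {
    s <- seg[seg$chrom == ch, ]
    if (nrow(s) > 1 && any(s$start[-1] < s$end[-nrow(s)])) {
      i <- which(s$start[-1] < s$end[-nrow(s)])[1]
      stop("segment format error: overlapping segments on ", ch, " (",
           s$start[i], "-", s$end[i], " and ", s$start[i + 1], "-", s$end[i + 1], ")")
    }
  }
  rownames(seg) <- NULL
  seg
}

#' Write a copy-number segment table
#'
#' @param segments Segment data.frame as returned by [read_segments()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_segments <- function(segments, path) {
  out <- data.frame(chrom = segments$chrom, start = segments$start,
                    end = segments$end, cn = segments$total_cn)
  out <- out[order(out$chrom, out$start), , drop = FALSE]
  write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a chromosome-arm table
#'
#' BED-like TSV with columns `chrom`, `start`, `end`, `arm` in 0-based
#' half-open coordinates. Arms of one chromosome must be disjoint and
#' ordered. Arm boundaries are an input of the analysis, never computed.
#'
#' @param path Path to the arm table.
#' @return An arm data.frame (chrom, start, end, arm).
#' @export
read_arms <- function(path) {
  if (!file.exists(path)) stop("arm table not found: ", path)
  tab <- read.delim(path, header = TRUE, sep = "\t", stringsAsFactors = FALSE)
  need <- c("chrom", "start", "end", "arm")
  if (!all(need %in% tolower(names(tab)))) {
    stop("arm table format error: need columns chrom, start, end, arm")
  }
  names(tab) <- tolower(names(tab))
  arms <- data.frame(chrom = as.character(tab$chrom), start = as.integer(tab$start),
                     end = as.integer(tab$end), arm = as.character(tab$arm),
                     stringsAsFactors = FALSE)
  arms <- arms[order(arms$chrom, arms$start), , drop = FALSE]
  if (any(arms$start >= arms$end)) stop("arm table format error: start must be < end")
  for (ch in unique(arms$chrom)) {
    a <- arms[arms$chrom == ch, ]
    if (nrow(a) > 1 && any(a$start[-1] < a$end[-nrow(a)])) {
      stop("arm table format error: overlapping arms on ", ch)
    }
  }
  rownames(arms) <- NULL
  arms
}

#' Write a chromosome-arm table
#' @param arms Arm data.frame (chrom, start, end, arm).
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_arms <- function(arms, path) {
  write.table(arms[, c("chrom", "start", "end", "arm")], path,
              sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

# Canonical identity of a substitution: alt-specific, no positional fuzz.
variant_key <- function(variants) {
  paste(variants$chrom, variants$pos, variants$ref, variants$alt, sep = ":")
}
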