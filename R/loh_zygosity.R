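# VAF / purity / copy-number model and LOH classification.
#
# In a tumor sample of purity p, a somatic variant present on m of the C_T
# tumor copies of a locus (the multiplicity), with the admixed normal cells
# contributing normal_cn copies and zero mutant copies, has expected VAF
#   p * m / (p * C_T + (1 - p) * normal_cn).
# At purity 1 this reduces to m / C_T: heterozygous diploid sites sit at
# 0.5, sites in loss-of-heterozygosity (LOH) regions at 1, triploid sites
# at 1/3 or 2/3.

#' Expected variant allele fraction
#'
#' Closed-form expected VAF for a somatic variant given tumor purity, the
#' tumor total copy number of the locus, the mutation multiplicity, and the
#' copy number contributed by admixed normal cells.
#'
#' @param purity Tumor cell fraction in (0, 1]. Vectorized.
#' @param tumor_cn Integer tumor total copy number (>= 0).
#' @param multiplicity Integer number of tumor copies carrying the variant,
#'   between 0 and `tumor_cn`.
#' @param normal_cn Copy number in normal cells (2 for autosomes).
#' @return Expected VAF in `[0, 1]`.
#' @export
expected_vaf <- function(purity, tumor_cn, multiplicity, normal_cn = 2) {
  n <- max(length(purity), length(tumor_cn), length(multiplicity), length(normal_cn))
  purity <- rep_len(purity, n); tumor_cn <- rep_len(tumor_cn, n)
  multiplicity <- rep_len(multiplicity, n); normal_cn <- rep_len(normal_cn, n)
  if (any(purity <= 0 | purity > 1)) stop("purity must be in (0, 1]")
  if (any(tumor_cn < 0)) stop("tumor_cn must be >= 0")
  if (any(multiplicity < 0 | multiplicity > tumor_cn)) {
    stop("multiplicity must satisfy 0 <= m <= tumor_cn")
  }
  denom <- purity * tumor_cn + (1 - purity) * normal_cn
  if (any(denom <= 0)) stop("degenerate sample: zero total copy number")
  purity * multiplicity / denom
}

#' Call zygosity of one copy-number segment from somatic VAFs
#'
#' A segment is called LOH when nearly all informative somatic variants sit
#' at the VAF expected when every tumor copy carries the variant
#' (`expected_vaf(purity, cn, cn)`), within a depth-aware tolerance;
#' heterozygous when the VAFs are instead consistent with a multiplicity
#' below the total copy number; indeterminate when fewer than `min_support`
#' informative variants are available. The LOH mode follows the segment
#' copy number: copy-loss at CN <= 1, copy-neutral at CN >= 2.
#'
#' @param segment One-row segment data.frame (chrom, start, end, total_cn,
#'   sample_id).
#' @param variants Variant data.frame restricted to the segment (positions
#'   inside `[start, end)` in 0-based terms).
#' @param purity Tumor purity of the sample; 1 is appropriate for cell
#'   lines.
#' @param high_vaf_cut VAF cut classifying a variant as "all-copies" at
#'   purity 1 and depth >= 30; 0.95 keeps the inclusive 95% convention.
#' @param loh_fraction Minimum fraction of informative variants above the
#'   cut for an LOH call.
#' @param min_support Minimum number of informative variants.
#' @param min_informative_depth Depth below which a variant is not
#'   informative for zygosity.
#' @return An object of class `zygosity_call`: list with `segment`, `state`
#'   (heterozygous / loh / indeterminate), `loh_mode` (copy_loss /
#'   copy_neutral / not_applicable) and `support`.
#' @export
classify_segment_zygosity <- function(segment, variants, purity = 1,
                                      high_vaf_cut = 0.95, loh_fraction = 0.9,
                                      min_support = 3,
                                      min_informative_depth = 10) {
  stopifnot(nrow(segment) == 1)
  cn <- segment$total_cn
  if (nrow(variants) > 0) {
    inside <- variants$pos - 1L >= segment$start & variants$pos - 1L < segment$end
    if (!all(inside)) stop("variants outside segment bounds")
  }
  info <- variants[variants$total_depth >= min_informative_depth, , drop = FALSE]
  support <- nrow(info)
  call <- function(state, mode) {
    structure(list(segment = segment, state = state, loh_mode = mode,
                   support = support), class = "zygosity_call")
  }
  if (support < min_support || cn == 0) return(call("indeterminate", "not_applicable"))
  ev_loh <- expected_vaf(purity, cn, cn)
  # depth-aware tolerance: fixed band at depth >= 30, 3 binomial SDs below
  tol <- ifelse(info$total_depth >= 30, 1 - high_vaf_cut,
                3 * sqrt(pmax(ev_loh * (1 - ev_loh), 0.25 * (1 - purity))
                         / pmax(info$total_depth, 1)))
  tol <- pmax(tol, 1 - high_vaf_cut)
  frac_high <- mean(info$vaf >= ev_loh - tol)
  if (frac_high >= loh_fraction) {
    return(call("loh", if (cn <= 1) "copy_loss" else "copy_neutral"))
  }
  if (cn >= 2) {
    # any sub-maximal multiplicity peak within tolerance?
    tol_het <- ifelse(info$total_depth >= 30, 0.1,
                      3 * sqrt(0.25 / pmax(info$total_depth, 1)))
    ev_m <- vapply(seq_len(cn - 1), function(m) expected_vaf(purity, cn, m),
                   numeric(1))
    consistent <- vapply(seq_len(support), function(i) {
      any(abs(info$vaf[i] - ev_m) <= tol_het[i])
    }, logical(1))
    if (mean(consistent) >= 0.5) return(call("heterozygous", "not_applicable"))
  }
  call("indeterminate", "not_applicable")
}

#' @export
print.zygosity_call <- function(x, ...) {
  cat("zygosity call:", x$state,
      if (x$state == "loh") paste0("(", x$loh_mode, ")") else "",
      "- support", x$support, "\n")
  invisible(x)
}

#' Cross-sample LOH scope of a region
#'
#' Classifies a region as truncal LOH (every determinate sample is LOH),
#' private LOH (some but not all), or retained heterozygosity (none).
#' Indeterminate calls are excluded from the denominator. When all
#' determinate samples agree on LOH but disagree on its mode (copy-loss in
#' some samples, copy-neutral in others), the region still counts as
#' truncal LOH for maintenance purposes and is flagged `mixed_mode`.
#'
#' @param region List or one-row data.frame with `chrom`, `start`, `end`.
#' @param calls A list of `zygosity_call` objects, or a data.frame with
#'   columns `sample_id`, `state`, `loh_mode` -- one entry per sample.
#' @return An object of class `loh_scope`: list with `region`, `scope`
#'   (truncal_loh / private_loh / retained_het), `samples_loh`,
#'   `samples_total` (determinate samples) and `mixed_mode`.
#' @export
classify_loh_scope <- function(region, calls) {
  if (is.data.frame(calls)) {
    states <- calls$state; modes <- calls$loh_mode
    ids <- if (!is.null(calls$sample_id)) calls$sample_id else as.character(seq_along(states))
  } else {
    states <- vapply(calls, `[[`, character(1), "state")
    modes <- vapply(calls, `[[`, character(1), "loh_mode")
    ids <- vapply(calls, function(x) {
      sid <- x$segment$sample_id
      if (is.null(sid)) NA_character_ else sid
    }, character(1))
  }
  det <- states != "indeterminate"
  if (!any(det)) stop("scope error: all zygosity calls indeterminate")
  is_loh <- states == "loh" & det
  n_det <- sum(det); n_loh <- sum(is_loh)
  scope <- if (n_loh == n_det) "truncal_loh" else if (n_loh > 0) "private_loh" else "retained_het"
  mixed <- scope == "truncal_loh" && length(unique(modes[is_loh])) > 1
  structure(list(region = region, scope = scope,
                 samples_loh = ids[is_loh], samples_total = n_det,
                 mixed_mode = mixed),
            class = "loh_scope")
}

#' Per-region zygosity and LOH scope across a case's samples
#'
#' Splits the genome at the union of segment breakpoints across all samples
#' (interval intersection), calls zygosity for every sample on every
#' resulting region, and assigns each region an LOH scope. Regions where
#' every sample is indeterminate are reported with scope `unclassified`.
#'
#' @param segments Segment data.frame covering all samples (stacked).
#' @param variants Somatic variant data.frame covering all samples.
#' @param purity Named vector of per-sample purities, or a single value
#'   recycled to all samples.
#' @param ... Passed to [classify_segment_zygosity()].
#' @return A data.frame with one row per (region), columns `chrom`,
#'   `start`, `end`, `scope`, `n_loh`, `n_det`, `mixed_mode`, and attribute
#'   `calls`: the long per-(region, sample) call table.
#' @export
case_loh_scopes <- function(segments, variants, purity = 1, ...) {
  samples <- unique(segments$sample_id)
  gr <- GenomicRanges::GRanges(segments$chrom,
                               IRanges::IRanges(segments$start + 1L, segments$end))
  regions <- GenomicRanges::disjoin(gr)
  reg <- data.frame(chrom = as.character(GenomicRanges::seqnames(regions)),
                    start = GenomicRanges::start(regions) - 1L,
                    end = GenomicRanges::end(regions), stringsAsFactors = FALSE)
  if (length(purity) == 1 && is.null(names(purity))) {
    purity <- setNames(rep(purity, length(samples)), samples)
  }
  calls <- list()
  out <- reg
  out$scope <- NA_character_; out$n_loh <- NA_integer_
  out$n_det <- NA_integer_; out$mixed_mode <- NA
  for (r in seq_len(nrow(reg))) {
    row_calls <- vector("list", length(samples))
    for (si in seq_along(samples)) {
      s <- samples[si]
      seg <- segments[segments$sample_id == s & segments$chrom == reg$chrom[r] &
                        segments$start <= reg$start[r] & segments$end >= reg$end[r], ,
                      drop = FALSE]
      if (nrow(seg) == 0) {
        # sample has no segment here: treat as diploid-unknown, indeterminate
        seg <- data.frame(chrom = reg$chrom[r], start = reg$start[r],
                          end = reg$end[r], total_cn = NA_integer_, sample_id = s)
        row_calls[[si]] <- structure(list(segment = seg, state = "indeterminate",
                                          loh_mode = "not_applicable", support = 0L),
                                     class = "zygosity_call")
        next
      }
      seg <- seg[1, , drop = FALSE]
      seg$start <- reg$start[r]; seg$end <- reg$end[r]
      v <- variants[variants$sample_id == s & variants$chrom == reg$chrom[r] &
                      variants$pos - 1L >= reg$start[r] &
                      variants$pos - 1L < reg$end[r], , drop = FALSE]
      row_calls[[si]] <- classify_segment_zygosity(seg, v, purity = purity[[s]], ...)
    }
    states <- vapply(row_calls, `[[`, character(1), "state")
    calls[[r]] <- data.frame(chrom = reg$chrom[r], start = reg$start[r],
                             end = reg$end[r], sample_id = samples,
                             state = states,
                             loh_mode = vapply(row_calls, `[[`, character(1), "loh_mode"),
                             support = vapply(row_calls, function(x) as.integer(x$support),
                                              integer(1)),
                             stringsAsFactors = FALSE)
    if (all(states == "indeterminate")) {
      out$scope[r] <- "unclassified"; out$n_loh[r] <- 0L
      out$n_det[r] <- 0L; out$mixed_mode[r] <- FALSE
    } else {
      sc <- classify_loh_scope(reg[r, ], row_calls)
      out$scope[r] <- sc$scope
      out$n_loh[r] <- length(sc$samples_loh)
      out$n_det[r] <- sc$samples_total
      out$mixed_mode[r] <- sc$mixed_mode
    }
  }
  attr(out, "calls") <- do.call(rbind, calls)
  out
}

#' Per-chromosome-arm summary for one sample
#'
#' For each chromosome arm: the mean VAF of the case's truncal PAMs in this
#' sample, the segment-length-weighted mean copy number, and the fraction
#' of truncal PAMs called present in this sample. PAMs falling outside
#' every arm are collected in an `unassigned` row with a warning.
#'
#' @param sample_id Sample to summarize.
#' @param pams PAM-creation data.frame restricted to the case's truncal
#'   PAMs, carrying this sample's VAFs (e.g. from capture data).
#' @param segments Segment data.frame for this sample.
#' @param arms Arm data.frame (see [read_arms()]).
#' @param presence A `presence_matrix` (see [presence_matrix()]).
#' @return A data.frame keyed by (chrom, arm) with columns `n_pams`,
#'   `mean_vaf`, `mean_cn`, `maintenance`.
#' @export
per_arm_summary <- function(sample_id, pams, segments, arms, presence) {
  arm_gr <- GenomicRanges::GRanges(arms$chrom,
                                   IRanges::IRanges(arms$start + 1L, arms$end))
  seg <- segments[segments$sample_id == sample_id, , drop = FALSE]
  seg_gr <- GenomicRanges::GRanges(seg$chrom, IRanges::IRanges(seg$start + 1L, seg$end))
  out <- data.frame(chrom = arms$chrom, arm = arms$arm,
                    n_pams = 0L, mean_vaf = NA_real_, mean_cn = NA_real_,
                    maintenance = NA_real_, stringsAsFactors = FALSE)
  # length-weighted CN per arm
  ov <- GenomicRanges::findOverlaps(arm_gr, seg_gr)
  if (length(ov) > 0) {
    inter_w <- GenomicRanges::width(IRanges::pintersect(
      arm_gr[S4Vectors::queryHits(ov)], seg_gr[S4Vectors::subjectHits(ov)]))
    cnv <- seg$total_cn[S4Vectors::subjectHits(ov)]
    for (a in unique(S4Vectors::queryHits(ov))) {
      sel <- S4Vectors::queryHits(ov) == a
      out$mean_cn[a] <- sum(inter_w[sel] * cnv[sel]) / sum(inter_w[sel])
    }
  }
  if (nrow(pams) == 0) return(out)
  pam_gr <- GenomicRanges::GRanges(pams$chrom, IRanges::IRanges(pams$pos, pams$pos))
  hit <- GenomicRanges::findOverlaps(pam_gr, arm_gr, select = "first")
  if (anyNA(hit)) {
    warning(sum(is.na(hit)), " PAM(s) outside every chromosome arm; ",
            "reported in an 'unassigned' row")
  }
  pres_vec <- !presence$no_call[, sample_id] & presence$presence[, sample_id]
  eval_vec <- !presence$no_call[, sample_id]
  groups <- ifelse(is.na(hit), 0L, hit)
  for (a in unique(groups)) {
    sel <- groups == a
    p <- pams[sel, , drop = FALSE]
    n <- sum(sel)
    idx <- match(p$pam_id, presence$pam_ids)
    known <- !is.na(idx)
    evaluable <- idx[known][eval_vec[idx[known]]]
    maint <- if (length(evaluable) > 0) mean(pres_vec[evaluable]) else NA_real_
    if (a == 0L) {
      out <- rbind(out, data.frame(chrom = NA_character_, arm = "unassigned",
                                   n_pams = n, mean_vaf = mean(p$vaf),
                                   mean_cn = NA_real_, maintenance = maint))
    } else {
      out$n_pams[a] <- n
      out$mean_vaf[a] <- mean(p$vaf)
      out$maintenance[a] <- maint
    }
  }
  rownames(out) <- NULL
  out
}

#' Restrict variants to those shared by several samples
#'
#' Zygosity classification reads the VAF distribution of trunk-derived
#' variants: a copy-neutral LOH region carries its surviving trunk variants
#' at VAF 1, while mutations acquired after the LOH event sit at VAF 0.5
#' and say nothing about the region's zygosity history. Variants observed
#' in at least `min_samples` samples of the case are (to good
#' approximation) trunk variants; with a single sample no filtering is
#' possible and the input is returned unchanged.
#'
#' @param variants Stacked variant data.frame across a case's samples.
#' @param min_samples Minimum number of distinct samples sharing the
#'   (chrom, pos, ref, alt) key.
#' @return The shared subset of `variants`.
#' @export
filter_shared_variants <- function(variants, min_samples = 2) {
  if (length(unique(variants$sample_id)) < 2) return(variants)
  key <- variant_key(variants)
  n_samp <- tapply(variants$sample_id, key, function(x) length(unique(x)))
  out <- variants[n_samp[key] >= min_samples, , drop = FALSE]
  rownames(out) <- NULL
  out
}
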