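# Presence calling from capture-style depths and the maintenance
# statistics built on top of the PAM x sample presence matrix.

#' Call PAM presence from read depths
#'
#' A site is `no_call` below the depth gate, `present` when the VAF meets
#' the cutoff (inclusive -- 5% exactly is present), and `absent` otherwise.
#' The 5% default sits just above background artifactual noise in capture
#' data; the depth gate of 20 reads gives binomial power to see a 5% allele.
#'
#' @param alt_depth,total_depth Non-negative read counts. Vectorized.
#' @param vaf_cut VAF cutoff for presence.
#' @param min_depth Total depth below which no call is made.
#' @return Character vector over `{present, absent, no_call}`.
#' @export
call_presence <- function(alt_depth, total_depth, vaf_cut = 0.05, min_depth = 20) {
  stopifnot(all(alt_depth >= 0), all(total_depth >= 0))
  n <- max(length(alt_depth), length(total_depth))
  alt_depth <- rep_len(alt_depth, n); total_depth <- rep_len(total_depth, n)
  out <- rep("absent", n)
  vaf <- ifelse(total_depth > 0, alt_depth / total_depth, 0)
  out[vaf >= vaf_cut] <- "present"
  out[total_depth < min_depth] <- "no_call"
  out
}

#' Build a PAM x sample presence matrix
#'
#' @param calls Long data.frame with columns `pam_id`, `sample_id`,
#'   `alt_depth`, `total_depth`; one row per (PAM, sample) observation.
#'   Missing combinations are treated as `no_call`.
#' @param vaf_cut,min_depth Passed to [call_presence()].
#' @return An object of class `presence_matrix`: list with `pam_ids`,
#'   `sample_ids`, `presence` (logical matrix, TRUE = present) and
#'   `no_call` (logical matrix; where TRUE the presence entry is ignored by
#'   every statistic).
#' @export
presence_matrix <- function(calls, vaf_cut = 0.05, min_depth = 20) {
  pam_ids <- sort(unique(calls$pam_id))
  sample_ids <- unique(calls$sample_id)
  pres <- matrix(FALSE, length(pam_ids), length(sample_ids),
                 dimnames = list(pam_ids, sample_ids))
  noc <- matrix(TRUE, length(pam_ids), length(sample_ids),
                dimnames = list(pam_ids, sample_ids))
  state <- call_presence(calls$alt_depth, calls$total_depth, vaf_cut, min_depth)
  i <- match(calls$pam_id, pam_ids)
  j <- match(calls$sample_id, sample_ids)
  idx <- cbind(i, j)
  noc[idx] <- state == "no_call"
  pres[idx] <- state == "present"
  structure(list(pam_ids = pam_ids, sample_ids = sample_ids,
                 presence = pres, no_call = noc),
            class = "presence_matrix")
}

#' @export
print.presence_matrix <- function(x, ...) {
  cat("presence matrix:", length(x$pam_ids), "PAMs x",
      length(x$sample_ids), "samples;",
      sum(x$no_call), "no-call entries\n")
  invisible(x)
}

as_presence_matrix <- function(presence, no_call = NULL) {
  if (is.null(no_call)) no_call <- matrix(FALSE, nrow(presence), ncol(presence),
                                          dimnames = dimnames(presence))
  structure(list(pam_ids = rownames(presence), sample_ids = colnames(presence),
                 presence = presence & !no_call, no_call = no_call),
            class = "presence_matrix")
}

#' Truncal PAM set as the union over primary samples
#'
#' Every PAM present in any sample of the primary tumor is considered
#' truncal: capture artifacts and locally low coverage can hide a
#' clonal PAM in an individual section, so the union maximizes the set
#' considered for clonality. PAMs that are no-call in every primary sample
#' are excluded and listed in the `uncallable` element.
#'
#' @param presence A `presence_matrix`.
#' @param primary_samples Character vector of primary-sample ids.
#' @param case_id Optional case label.
#' @return An object of class `truncal_set`: list with `case_id`,
#'   `pam_ids`, `provenance` (`"primary_union"`) and `uncallable`.
#' @export
define_truncal_union <- function(presence, primary_samples, case_id = NA_character_) {
  if (length(primary_samples) < 1) {
    stop("no primary samples; use infer_truncal_from_mets()")
  }
  stopifnot(all(primary_samples %in% presence$sample_ids))
  pres <- presence$presence[, primary_samples, drop = FALSE]
  noc <- presence$no_call[, primary_samples, drop = FALSE]
  in_any <- rowSums(pres & !noc) > 0
  uncallable <- rowSums(!noc) == 0
  structure(list(case_id = case_id,
                 pam_ids = presence$pam_ids[in_any],
                 provenance = "primary_union",
                 uncallable = presence$pam_ids[uncallable]),
            class = "truncal_set")
}

#' Infer the truncal PAM set from metastases
#'
#' For cases with no primary-tumor sample, truncal PAMs are inferred as
#' those present in more than one metastasis (at least `min_mets`).
#'
#' @param presence A `presence_matrix` restricted to metastasis columns (or
#'   pass `met_samples`).
#' @param met_samples Metastasis sample ids; defaults to all columns.
#' @param min_mets Minimum number of metastases a PAM must be present in.
#' @param case_id Optional case label.
#' @return A `truncal_set` with provenance `"met_inferred"`.
#' @export
infer_truncal_from_mets <- function(presence, met_samples = presence$sample_ids,
                                    min_mets = 2, case_id = NA_character_) {
  if (length(met_samples) < min_mets) {
    stop("need at least ", min_mets, " metastases to infer a truncal set")
  }
  pres <- presence$presence[, met_samples, drop = FALSE] &
    !presence$no_call[, met_samples, drop = FALSE]
  keep <- rowSums(pres) >= min_mets
  structure(list(case_id = case_id, pam_ids = presence$pam_ids[keep],
                 provenance = "met_inferred", uncallable = character()),
            class = "truncal_set")
}

#' @export
print.truncal_set <- function(x, ...) {
  cat("truncal set (", x$provenance, "): ", length(x$pam_ids), " PAMs\n", sep = "")
  invisible(x)
}

#' Percent truncal for one sample
#'
#' Fraction of the case's truncal PAMs detected in the sample. No-call PAMs
#' are removed from both numerator and denominator.
#'
#' @param sample Sample id.
#' @param presence A `presence_matrix`.
#' @param truncal A `truncal_set`.
#' @return Fraction in `[0, 1]`, or `NA` when no truncal PAM is evaluable.
#' @export
percent_truncal <- function(sample, presence, truncal) {
  stopifnot(sample %in% presence$sample_ids)
  idx <- match(truncal$pam_ids, presence$pam_ids)
  idx <- idx[!is.na(idx)]
  evaluable <- idx[!presence$no_call[idx, sample]]
  if (length(evaluable) == 0) return(NA_real_)
  mean(presence$presence[evaluable, sample])
}

#' Percent maintained for one PAM
#'
#' Fraction of the case's metastases in which the PAM is detected, among
#' metastases where it is evaluable (not no-call).
#'
#' @param pam PAM id.
#' @param presence A `presence_matrix`.
#' @param met_samples Metastasis sample ids.
#' @return Fraction in `[0, 1]`, or `NA` when evaluable in no metastasis.
#' @export
percent_maintained <- function(pam, presence, met_samples) {
  stopifnot(pam %in% presence$pam_ids)
  ev <- met_samples[!presence$no_call[pam, met_samples]]
  if (length(ev) == 0) return(NA_real_)
  mean(presence$presence[pam, ev])
}

#' Fraction of truncal PAMs present in every lesion
#'
#' A PAM counts only when it is called present (not absent, not no-call) in
#' all listed lesions.
#'
#' @param truncal A `truncal_set`.
#' @param presence A `presence_matrix`.
#' @param lesion_samples Lesion sample ids; defaults to all samples.
#' @return Fraction in `[0, 1]`.
#' @export
shared_by_all <- function(truncal, presence, lesion_samples = presence$sample_ids) {
  idx <- match(truncal$pam_ids, presence$pam_ids)
  idx <- idx[!is.na(idx)]
  if (length(idx) == 0) return(NA_real_)
  ok <- presence$presence[idx, lesion_samples, drop = FALSE] &
    !presence$no_call[idx, lesion_samples, drop = FALSE]
  mean(rowSums(ok) == length(lesion_samples))
}

#' Exact membership-region counts for a collection of sets
#'
#' Computes the count of elements in every one of the 2^n - 1 membership
#' regions of n named sets (the numbers behind a Venn diagram).
#'
#' @param sets Named list of character vectors.
#' @return Data.frame with one logical membership column per set, a
#'   `region` label, and `count`.
#' @export
set_overlaps <- function(sets) {
  n <- length(sets)
  if (n < 2) stop("need at least 2 sets")
  if (is.null(names(sets)) || any(names(sets) == "")) {
    names(sets) <- paste0("set", seq_len(n))
  }
  universe <- unique(unlist(sets))
  member <- vapply(sets, function(s) universe %in% s, logical(length(universe)))
  if (length(universe) == 1) member <- matrix(member, nrow = 1,
                                              dimnames = list(NULL, names(sets)))
  combos <- expand.grid(rep(list(c(FALSE, TRUE)), n))[-1, , drop = FALSE]
  names(combos) <- names(sets)
  counts <- apply(combos, 1, function(cmb) {
    sum(apply(member, 1, function(m) all(m == cmb)))
  })
  out <- data.frame(combos, row.names = NULL)
  out$region <- apply(combos, 1, function(cmb) paste(names(sets)[as.logical(cmb)],
                                                     collapse = "&"))
  out$count <- as.integer(counts)
  out
}

#' Maintenance summarized by LOH class
#'
#' Assigns each truncal PAM to the LOH scope of the region containing it
#' and reports, per class, the mean per-PAM percent maintained and the PAM
#' count. PAMs falling in no classified region go to an `unclassified` row.
#'
#' @param presence A `presence_matrix`.
#' @param truncal A `truncal_set`.
#' @param scopes Region scope data.frame from [case_loh_scopes()].
#' @param pam_positions Data.frame mapping `pam_id` to `chrom`, `pos`.
#' @param met_samples Metastasis sample ids used for percent maintained.
#' @return Data.frame with rows truncal_loh, private_loh, retained_het (and
#'   unclassified when needed): `n_pams`, `mean_maintained`.
#' @export
maintenance_by_loh_class <- function(presence, truncal, scopes, pam_positions,
                                     met_samples) {
  pam_ids <- intersect(truncal$pam_ids, presence$pam_ids)
  pp <- pam_positions[match(pam_ids, pam_positions$pam_id), , drop = FALSE]
  cls <- rep("unclassified", length(pam_ids))
  if (nrow(scopes) > 0 && length(pam_ids) > 0) {
    sc_gr <- GenomicRanges::GRanges(scopes$chrom,
                                    IRanges::IRanges(scopes$start + 1L, scopes$end))
    pam_gr <- GenomicRanges::GRanges(pp$chrom, IRanges::IRanges(pp$pos, pp$pos))
    hit <- GenomicRanges::findOverlaps(pam_gr, sc_gr, select = "first")
    cls[!is.na(hit)] <- scopes$scope[hit[!is.na(hit)]]
  }
  pm <- vapply(pam_ids, percent_maintained, numeric(1),
               presence = presence, met_samples = met_samples)
  classes <- c("truncal_loh", "private_loh", "retained_het")
  if (any(cls %in% c("unclassified", "mixed"))) classes <- c(classes, "unclassified")
  cls[cls == "mixed"] <- "unclassified"
  out <- data.frame(loh_class = classes,
                    n_pams = vapply(classes, function(k) sum(cls == k), integer(1)),
                    mean_maintained = vapply(classes, function(k) {
                      v <- pm[cls == k]
                      v <- v[!is.na(v)]
                      if (length(v) == 0) NA_real_ else mean(v)
                    }, numeric(1)), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Depth-based sample QC via a two-segment fit
#'
#' Percent truncal rises steeply with mean on-target depth in low-purity or
#' shallow samples and then plateaus; only samples on the plateau ("the
#' linear portion") should enter maintenance statistics. The knee is
#' estimated as the breakpoint of a two-segment least-squares fit of
#' percent truncal against depth, and samples below `max(min_depth, knee)`
#' are excluded. With fewer than 3 samples, a collinear fit, or no genuine
#' rise from the left segment to the right, the hard depth floor alone is
#' used.
#'
#' @param depth Mean on-target depth per sample.
#' @param pct_truncal Percent truncal per sample (fractions).
#' @param min_depth Hard depth floor.
#' @param rise_margin Minimum rise in mean percent truncal from left to
#'   right segment for the knee to be trusted.
#' @return Data.frame with `depth`, `pct_truncal`, `include`, and
#'   attributes `knee` and `method` (`"two_segment"` or `"threshold"`).
#' @export
qc_depth_filter <- function(depth, pct_truncal, min_depth = 30,
                            rise_margin = 0.05) {
  stopifnot(length(depth) == length(pct_truncal))
  n <- length(depth)
  res <- data.frame(depth = depth, pct_truncal = pct_truncal)
  threshold_only <- function(why) {
    res$include <- depth >= min_depth
    attr(res, "knee") <- NA_real_
    attr(res, "method") <- "threshold"
    attr(res, "why") <- why
    res
  }
  if (n < 3) return(threshold_only("fewer than 3 samples"))
  o <- order(depth)
  d <- depth[o]; p <- pct_truncal[o]
  sse1 <- sum(lm(p ~ d)$residuals^2)
  if (sse1 < 1e-10 || length(unique(d)) < 3) return(threshold_only("collinear fit"))
  # continuous two-piece linear fit: p ~ d with a slope change at the
  # candidate knee. Continuity keeps the breakpoint identifiable (two free
  # lines would fit any 2+2 split of four points exactly).
  du <- sort(unique(d))
  candidates <- (du[-length(du)] + du[-1]) / 2
  best <- NULL
  for (cc in candidates) {
    hinge <- pmax(d - cc, 0)
    s <- sum(lm(p ~ d + hinge)$residuals^2)
    if (is.null(best) || s < best$sse - 1e-12) best <- list(knee = cc, sse = s)
  }
  rise <- mean(p[d > best$knee]) - mean(p[d < best$knee])
  if (!is.finite(rise) || rise < rise_margin) {
    return(threshold_only("no rise at candidate knee"))
  }
  res$include <- depth >= max(min_depth, best$knee)
  attr(res, "knee") <- best$knee
  attr(res, "method") <- "two_segment"
  res
}

# Exact two-sided rank-sum p-value by enumeration over group assignments
# (midranks for ties). Used when the arrangement count is small enough.
exact_rank_sum_p <- function(x, y) {
  nx <- length(x); n <- nx + length(y)
  r <- rank(c(x, y))
  s_obs <- sum(r[seq_len(nx)])
  es <- nx * (n + 1) / 2
  combos <- combn(n, nx)
  s_all <- colSums(matrix(r[combos], nrow = nx))
  mean(abs(s_all - es) >= abs(s_obs - es) - 1e-12)
}

#' Group comparison tests
#'
#' For two groups: Mann-Whitney rank-sum (exact two-sided p by enumeration
#' of all group assignments when feasible, midranks for ties; otherwise
#' `wilcox.test`). For three or more groups: Kruskal-Wallis and one-way
#' ANOVA. Raw p-values are reported without multiple-testing correction.
#'
#' @param groups Named list of numeric vectors, each of length >= 2.
#' @return Data.frame with columns `test`, `statistic`, `p_value`.
#' @export
group_tests <- function(groups) {
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  all_v <- unlist(groups)
  if (var(all_v) == 0) {
    warning("degenerate input: all values identical; p-values reported as NA")
    tests <- if (length(groups) == 2) "mann_whitney" else c("kruskal_wallis", "anova")
    return(data.frame(test = tests, statistic = 0, p_value = NA_real_))
  }
  if (length(groups) == 2) {
    x <- groups[[1]]; y <- groups[[2]]
    w <- suppressWarnings(wilcox.test(x, y, exact = FALSE))
    p <- if (choose(length(x) + length(y), length(x)) <= 20000) {
      exact_rank_sum_p(x, y)
    } else w$p.value
    return(data.frame(test = "mann_whitney",
                      statistic = unname(w$statistic), p_value = p))
  }
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  kw <- kruskal.test(all_v, g)
  an <- summary(aov(all_v ~ g))[[1]]
  data.frame(test = c("kruskal_wallis", "anova"),
             statistic = c(unname(kw$statistic), an[["F value"]][1]),
             p_value = c(kw$p.value, an[["Pr(>F)"]][1]))
}
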