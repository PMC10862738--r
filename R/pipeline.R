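# Case-level pipeline: discover -> classify -> maintain -> report.

default_pipeline_params <- function() {
  list(min_mapping_quality = 20, min_depth = 10, min_allele_frequency = 0.05,
       high_vaf_threshold = 0.95,
       presence_vaf_cut = 0.05, presence_min_depth = 20,
       qc_min_depth = 30, min_mets_for_truncal = 2,
       purity = 1)
}

read_manifest <- function(manifest) {
  if (is.character(manifest)) {
    if (!file.exists(manifest)) stop("manifest not found: ", manifest)
    base <- dirname(normalizePath(manifest))
    m <- yaml::read_yaml(manifest)
    # resolve relative paths against the manifest location
    fix <- function(p) {
      if (is.null(p)) return(NULL)
      if (file.exists(p)) p else file.path(base, p)
    }
    m$reference <- fix(m$reference); m$arms <- fix(m$arms)
    m$normal_vcf <- fix(m$normal_vcf)
    m$samples <- lapply(m$samples, function(s) {
      s$wgs_vcf <- fix(s$wgs_vcf); s$capture_vcf <- fix(s$capture_vcf)
      s$segments <- fix(s$segments)
      s
    })
    m
  } else manifest
}

validate_manifest <- function(m) {
  need <- c("case_id", "reference", "normal_vcf", "samples")
  miss <- setdiff(need, names(m))
  if (length(miss) > 0) stop("manifest error: missing field(s) ",
                             paste(miss, collapse = ", "))
  for (p in c(m$reference, m$arms, m$normal_vcf)) {
    if (!is.null(p) && !file.exists(p)) stop("manifest error: missing input file ", p)
  }
  ids <- vapply(m$samples, `[[`, character(1), "sample_id")
  if (anyDuplicated(ids)) stop("manifest error: duplicated sample ids")
  for (s in m$samples) {
    for (p in c(s$wgs_vcf, s$capture_vcf, s$segments)) {
      if (!is.null(p) && !file.exists(p)) stop("manifest error: missing input file ", p)
    }
  }
  invisible(m)
}

stage_log <- function(verbose, ...) {
  if (verbose) message(format(Sys.time(), "%H:%M:%S"), " [pamtrace] ", ...)
}

#' Run the full PAM-maintenance pipeline for one case
#'
#' Executes tumor-normal subtraction and PAM discovery per sample,
#' presence calling from capture data, truncal-set definition (union over
#' primary samples, or inferred from metastases when no primary exists),
#' per-region zygosity and LOH-scope classification, sample-level depth QC,
#' and the maintenance statistics, and assembles everything into a case
#' report. All numbers in the report are recomputed from the stage outputs.
#'
#' @param manifest Path to a YAML manifest, or an equivalent list. Fields:
#'   `case_id`, `reference`, `arms`, `normal_vcf`, `normal_sample`,
#'   optional `params`, and `samples`: a list of records with `sample_id`,
#'   `role` (primary/metastasis), `wgs_vcf`, `capture_vcf` (optional;
#'   `wgs_vcf` is used for presence when absent), `segments`.
#' @param outdir Optional directory; when given, the report is written as
#'   `report.json` plus TSV tables.
#' @param verbose Log stage progress to stderr.
#' @return An object of class `case_report` (a nested list).
#' @export
run_pipeline <- function(manifest, outdir = NULL, verbose = FALSE) {
  m <- validate_manifest(read_manifest(manifest))
  params <- default_pipeline_params()
  params[names(m$params %||% list())] <- m$params
  ids <- vapply(m$samples, `[[`, character(1), "sample_id")
  roles <- vapply(m$samples, `[[`, character(1), "role")
  normal_sample <- m$normal_sample %||% "N"

  stage_log(verbose, "reading reference and inputs")
  reference <- read_fasta(m$reference)
  arms <- if (!is.null(m$arms)) read_arms(m$arms) else NULL
  normal <- read_vcf(m$normal_vcf, normal_sample)
  gfilter <- germline_filter(params$min_mapping_quality, params$min_depth,
                             params$min_allele_frequency)

  stage_log(verbose, "discovery: subtraction and novel-PAM detection")
  somatic <- list(); pam_sets <- list(); segments <- list()
  for (s in m$samples) {
    tumor <- read_vcf(s$wgs_vcf, s$sample_id)
    som <- subtract_somatic(tumor, normal, gfilter)
    somatic[[s$sample_id]] <- som
    pam_sets[[s$sample_id]] <- somatic_pam_set(
      m$case_id, s$sample_id, detect_novel_pams(som, reference),
      params$high_vaf_threshold)
    segments[[s$sample_id]] <- read_segments(s$segments, s$sample_id)
  }
  # The capture panel mirrors the study design: PAMs are discovered by WGS
  # of the metastatic samples and the panel is their union; primary samples
  # then only vote on which panel PAMs are truncal. A primary-only PAM is a
  # subclonal event of that section, not a candidate target.
  panel_samples <- if (any(roles == "metastasis")) ids[roles == "metastasis"] else ids
  all_pams <- do.call(rbind, lapply(pam_sets[panel_samples], `[[`, "pams"))
  rownames(all_pams) <- NULL
  pam_universe <- all_pams[!duplicated(all_pams$pam_id), , drop = FALSE]

  stage_log(verbose, "presence calling on ", nrow(pam_universe), " PAMs")
  # capture depths at the union of discovered PAM sites
  calls <- list()
  capture_variants <- list()
  for (s in m$samples) {
    path <- s$capture_vcf %||% s$wgs_vcf
    cap <- read_vcf(path, s$sample_id)
    capture_variants[[s$sample_id]] <- cap
    idx <- match(paste(pam_universe$chrom, pam_universe$pos,
                       pam_universe$ref, pam_universe$alt, sep = ":"),
                 variant_key(cap))
    calls[[s$sample_id]] <- data.frame(
      pam_id = pam_universe$pam_id, sample_id = s$sample_id,
      alt_depth = ifelse(is.na(idx), 0L, cap$alt_depth[idx]),
      total_depth = ifelse(is.na(idx), 0L, cap$total_depth[idx]),
      stringsAsFactors = FALSE)
  }
  presence <- presence_matrix(do.call(rbind, calls),
                              vaf_cut = params$presence_vaf_cut,
                              min_depth = params$presence_min_depth)

  stage_log(verbose, "truncal set")
  primaries <- ids[roles == "primary"]
  mets <- ids[roles == "metastasis"]
  truncal <- if (length(primaries) > 0) {
    define_truncal_union(presence, primaries, m$case_id)
  } else {
    infer_truncal_from_mets(presence, mets,
                            min_mets = params$min_mets_for_truncal,
                            case_id = m$case_id)
  }

  stage_log(verbose, "sample QC")
  mean_depth <- vapply(calls, function(x) mean(x$total_depth), numeric(1))
  pct_truncal_all <- vapply(ids, percent_truncal, numeric(1),
                            presence = presence, truncal = truncal)
  qc <- qc_depth_filter(mean_depth[mets], pct_truncal_all[mets],
                        min_depth = params$qc_min_depth)
  qc$sample_id <- mets
  included_mets <- mets[qc$include]
  if (length(included_mets) == 0) stop("QC excluded every metastasis")

  stage_log(verbose, "LOH classification")
  seg_all <- do.call(rbind, segments)
  som_all <- do.call(rbind, somatic)
  purity <- params$purity
  if (is.list(purity)) purity <- unlist(purity)
  if (length(purity) == 1 && is.null(names(purity))) {
    purity <- setNames(rep(purity, length(ids)), ids)
  }
  # zygosity is read from trunk-derived VAFs: variants private to one
  # sample postdate any truncal LOH and carry no signal about it
  shared <- filter_shared_variants(som_all)
  scopes <- case_loh_scopes(seg_all, shared, purity = purity)

  stage_log(verbose, "maintenance statistics")
  pam_positions <- pam_universe[, c("pam_id", "chrom", "pos")]
  pct_truncal <- vapply(c(primaries, included_mets), percent_truncal, numeric(1),
                        presence = presence, truncal = truncal)
  pct_maint <- vapply(intersect(truncal$pam_ids, presence$pam_ids),
                      percent_maintained, numeric(1),
                      presence = presence, met_samples = included_mets)
  shared <- shared_by_all(truncal, presence,
                          lesion_samples = c(primaries, included_mets))
  by_class <- maintenance_by_loh_class(presence, truncal, scopes,
                                       pam_positions, included_mets)

  overlaps <- NULL
  if (length(ids) >= 2 && length(ids) <= 7) {
    sets <- lapply(ids, function(s) {
      presence$pam_ids[presence$presence[, s] & !presence$no_call[, s]]
    })
    names(sets) <- ids
    overlaps <- set_overlaps(sets)
  }

  arm_tables <- NULL
  if (!is.null(arms)) {
    truncal_pams <- pam_universe[pam_universe$pam_id %in% truncal$pam_ids, ,
                                 drop = FALSE]
    arm_tables <- lapply(c(primaries, included_mets), function(s) {
      # use the sample's capture VAFs where available
      cap <- capture_variants[[s]]
      idx <- match(paste(truncal_pams$chrom, truncal_pams$pos,
                         truncal_pams$ref, truncal_pams$alt, sep = ":"),
                   variant_key(cap))
      tp <- truncal_pams
      tp$vaf <- ifelse(is.na(idx), NA_real_, cap$vaf[idx])
      tp <- tp[!is.na(tp$vaf), , drop = FALSE]
      suppressWarnings(per_arm_summary(s, tp, seg_all, arms, presence))
    })
    names(arm_tables) <- c(primaries, included_mets)
  }

  # maintained-vs-lost VAF comparison over truncal PAMs (discovery VAFs)
  tests <- NULL
  maint_ids <- names(pct_maint)[!is.na(pct_maint) & pct_maint == 1]
  lost_ids <- names(pct_maint)[!is.na(pct_maint) & pct_maint < 1]
  if (length(maint_ids) >= 2 && length(lost_ids) >= 2) {
    vafs <- setNames(pam_universe$vaf, pam_universe$pam_id)
    tests <- group_tests(list(maintained = unname(vafs[maint_ids]),
                              lost = unname(vafs[lost_ids])))
  }

  report <- structure(list(
    case_id = m$case_id,
    samples = data.frame(sample_id = ids, role = roles,
                         mean_depth = unname(mean_depth[ids]),
                         percent_truncal = unname(pct_truncal_all[ids]),
                         included = ids %in% c(primaries, included_mets),
                         stringsAsFactors = FALSE),
    qc = qc,
    discovery = data.frame(
      sample_id = ids,
      n_somatic = vapply(somatic[ids], nrow, integer(1)),
      n_pams = vapply(pam_sets[ids], function(x) nrow(x$pams), integer(1)),
      n_pams_high_vaf = vapply(pam_sets[ids],
                               function(x) nrow(x$high_vaf_subset), integer(1)),
      stringsAsFactors = FALSE),
    truncal = list(size = length(truncal$pam_ids),
                   provenance = truncal$provenance,
                   n_uncallable = length(truncal$uncallable)),
    maintenance = list(
      percent_truncal = pct_truncal,
      percent_maintained_mean = mean(pct_maint, na.rm = TRUE),
      percent_truncal_mean = mean(pct_truncal[included_mets], na.rm = TRUE),
      shared_all = shared,
      by_loh_class = by_class),
    loh_regions = scopes,
    per_arm = arm_tables,
    overlaps = overlaps,
    tests = tests,
    provenance = list(package = as.character(packageVersion("pamtrace")),
                      seed = m$seed %||% NA, params = params)),
    class = "case_report")

  if (!is.null(outdir)) write_case_report(report, outdir)
  report
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Write a case report to disk
#'
#' Emits `report.json` plus TSV tables (`samples.tsv`, `loh_regions.tsv`,
#' `by_loh_class.tsv`, `percent_truncal.tsv`, and per-arm and overlap
#' tables when available). No timestamps are written, so identical inputs
#' produce byte-identical outputs.
#'
#' @param report A `case_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_case_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  tsv <- function(x, name) {
    write.table(x, file.path(outdir, name), sep = "\t", quote = FALSE,
                row.names = FALSE)
  }
  tsv(report$samples, "samples.tsv")
  tsv(report$loh_regions, "loh_regions.tsv")
  tsv(report$maintenance$by_loh_class, "by_loh_class.tsv")
  tsv(data.frame(sample_id = names(report$maintenance$percent_truncal),
                 percent_truncal = unname(report$maintenance$percent_truncal)),
      "percent_truncal.tsv")
  if (!is.null(report$overlaps)) tsv(report$overlaps, "overlaps.tsv")
  if (!is.null(report$per_arm)) {
    arm <- do.call(rbind, lapply(names(report$per_arm), function(s) {
      data.frame(sample_id = s, report$per_arm[[s]], stringsAsFactors = FALSE)
    }))
    tsv(arm, "per_arm.tsv")
  }
  json <- jsonlite::toJSON(unclass(report), auto_unbox = TRUE, digits = NA,
                           na = "null", dataframe = "rows", pretty = TRUE)
  writeLines(json, file.path(outdir, "report.json"))
  invisible(outdir)
}

#' @export
print.case_report <- function(x, ...) {
  cat("case report:", x$case_id, "\n")
  cat("  samples:", nrow(x$samples), "(",
      sum(x$samples$included), "included after QC )\n")
  cat("  truncal PAMs:", x$truncal$size, "[", x$truncal$provenance, "]\n")
  cat("  mean percent truncal:",
      round(100 * x$maintenance$percent_truncal_mean, 1), "%\n")
  cat("  mean percent maintained:",
      round(100 * x$maintenance$percent_maintained_mean, 1), "%\n")
  cat("  shared by all lesions:", round(100 * x$maintenance$shared_all, 1), "%\n")
  print(x$maintenance$by_loh_class)
  invisible(x)
}
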