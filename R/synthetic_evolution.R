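# Metastatic clonal-evolution simulator with explicit homolog tracking.
#
# Model: a diploid germline (homologs "A" and "B" per chromosome) acquires
# trunk mutations in the cancer-initiating cell, each on one homolog chosen
# uniformly. Truncal LOH (copy-loss or copy-neutral) and trunk-level gains
# are then applied to the trunk -- before lineage divergence -- so trunk
# mutations on a lost homolog vanish from every descendant sample, and
# survivors in copy-neutral LOH carry multiplicity equal to the copy
# number. Each sample (primary sections and metastases form a star around
# the trunk) then receives its private copy-number events followed by
# private mutations. Read data are sampled per site as Poisson total depth
# and binomial alt counts at the expected VAF given purity, copy number and
# multiplicity.

#' Simulation configuration
#'
#' @param seed Integer seed; all simulator randomness derives from it.
#' @param n_chromosomes,chrom_length Genome shape.
#' @param gc_content Fraction G+C of the simulated reference.
#' @param arm_fraction Position of the p/q boundary as a fraction of
#'   chromosome length.
#' @param n_trunk_mutations Trunk SBS count (genome-wide).
#' @param n_private_mutations Private SBS count per tumor sample.
#' @param n_germline_snps Heterozygous germline SNPs shared by normal and
#'   tumor samples (the substrate of tumor-normal subtraction).
#' @param samples Data.frame with columns `sample_id`, `role`
#'   (primary/metastasis), `purity` in (0, 1], `mean_depth`.
#' @param normal_id,normal_depth Matched-normal sample name and depth.
#' @param truncal_loh Data.frame (chrom, start, end, mode) of trunk-level
#'   LOH events; mode is `copy_loss` or `copy_neutral`. 0-based half-open.
#' @param private_loh Data.frame (chrom, start, end, mode, sample_id) of
#'   per-sample LOH events; the removed homolog is chosen uniformly at
#'   random, which is what produces 50% loss of heterozygous sites in
#'   diploid regions and 33% in triploid regions.
#' @param gains Data.frame (chrom, start, end, new_cn, sample_id); use
#'   sample_id `"trunk"` for gains preceding divergence.
#' @param spectrum Named probabilities over the 12 ref>alt substitution
#'   classes; the default encodes a 2:1 transition:transversion ratio.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(seed = 1L,
                       n_chromosomes = 3L, chrom_length = 1e6, gc_content = 0.41,
                       arm_fraction = 0.5,
                       n_trunk_mutations = 300L, n_private_mutations = 40L,
                       n_germline_snps = 120L,
                       samples = data.frame(
                         sample_id = c("P1", "M1", "M2", "M3"),
                         role = c("primary", rep("metastasis", 3)),
                         purity = 1, mean_depth = 60,
                         stringsAsFactors = FALSE),
                       normal_id = "N", normal_depth = 30,
                       truncal_loh = NULL, private_loh = NULL, gains = NULL,
                       spectrum = default_spectrum()) {
  empty_ev <- function(...) {
    cols <- list(...)
    do.call(data.frame, c(cols, list(stringsAsFactors = FALSE)))
  }
  if (is.null(truncal_loh)) truncal_loh <- empty_ev(chrom = character(),
                                                    start = integer(), end = integer(),
                                                    mode = character())
  if (is.null(private_loh)) private_loh <- empty_ev(chrom = character(),
                                                    start = integer(), end = integer(),
                                                    mode = character(),
                                                    sample_id = character())
  if (is.null(gains)) gains <- empty_ev(chrom = character(), start = integer(),
                                        end = integer(), new_cn = integer(),
                                        sample_id = character())
  cfg <- structure(list(seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
                        chrom_length = as.integer(chrom_length), gc_content = gc_content,
                        arm_fraction = arm_fraction,
                        n_trunk_mutations = as.integer(n_trunk_mutations),
                        n_private_mutations = as.integer(n_private_mutations),
                        n_germline_snps = as.integer(n_germline_snps),
                        samples = samples, normal_id = normal_id,
                        normal_depth = normal_depth,
                        truncal_loh = truncal_loh, private_loh = private_loh,
                        gains = gains, spectrum = spectrum),
                   class = "sim_config")
  validate_sim_config(cfg)
  cfg
}

#' Default substitution spectrum (2:1 transition:transversion)
#' @return Named probability vector over the 12 ref>alt classes, summing
#'   to 1.
#' @export
default_spectrum <- function() {
  bases <- c("A", "C", "G", "T")
  ts <- c(A = "G", G = "A", C = "T", T = "C")
  cls <- character(); w <- numeric()
  for (r in bases) for (a in setdiff(bases, r)) {
    cls <- c(cls, paste0(r, ">", a))
    w <- c(w, if (ts[[r]] == a) 2 else 0.5)
  }
  setNames(w / sum(w), cls)
}

validate_sim_config <- function(cfg) {
  stopifnot(cfg$gc_content >= 0, cfg$gc_content <= 1,
            cfg$arm_fraction > 0, cfg$arm_fraction < 1,
            all(cfg$samples$purity > 0), all(cfg$samples$purity <= 1),
            !anyDuplicated(cfg$samples$sample_id))
  if (abs(sum(cfg$spectrum) - 1) > 1e-8) stop("spectrum must sum to 1")
  chroms <- sim_chrom_names(cfg)
  for (ev in list(cfg$truncal_loh, cfg$private_loh, cfg$gains)) {
    if (nrow(ev) == 0) next
    if (!all(ev$chrom %in% chroms)) stop("event chromosome outside genome")
    if (any(ev$start < 0 | ev$end > cfg$chrom_length | ev$start >= ev$end)) {
      stop("event region outside chromosome bounds")
    }
  }
  if (nrow(cfg$private_loh) > 0 &&
      !all(cfg$private_loh$sample_id %in% cfg$samples$sample_id)) {
    stop("private LOH event for unknown sample")
  }
  # truncal and private LOH on overlapping regions would compose two CN
  # histories this simulator does not model
  if (nrow(cfg$truncal_loh) > 0 && nrow(cfg$private_loh) > 0) {
    t_gr <- GenomicRanges::GRanges(cfg$truncal_loh$chrom,
                                   IRanges::IRanges(cfg$truncal_loh$start + 1L,
                                                    cfg$truncal_loh$end))
    p_gr <- GenomicRanges::GRanges(cfg$private_loh$chrom,
                                   IRanges::IRanges(cfg$private_loh$start + 1L,
                                                    cfg$private_loh$end))
    if (length(suppressWarnings(GenomicRanges::findOverlaps(t_gr, p_gr))) > 0) {
      stop("config error: truncal and private LOH events overlap")
    }
  }
  invisible(cfg)
}

sim_chrom_names <- function(cfg) paste0("chr", seq_len(cfg$n_chromosomes))

#' Simulate a reference genome and arm table
#'
#' I.i.d. bases at the configured GC content, plus a p/q arm boundary at
#' the configured fraction of each chromosome. Deterministic given the
#' config seed.
#'
#' @param config A [sim_config()].
#' @return List with `genome` (a `DNAStringSet`) and `arms` (arm
#'   data.frame).
#' @export
simulate_reference <- function(config) {
  set.seed(config$seed)
  gc <- config$gc_content
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  chroms <- sim_chrom_names(config)
  seqs <- vapply(chroms, function(ch) {
    paste(sample(names(prob), config$chrom_length, replace = TRUE, prob = prob),
          collapse = "")
  }, character(1))
  genome <- Biostrings::DNAStringSet(seqs)
  names(genome) <- chroms
  b <- as.integer(floor(config$chrom_length * config$arm_fraction))
  arms <- data.frame(chrom = rep(chroms, each = 2),
                     start = rep(c(0L, b), length(chroms)),
                     end = rep(c(b, config$chrom_length), length(chroms)),
                     arm = rep(c("p", "q"), length(chroms)),
                     stringsAsFactors = FALSE)
  list(genome = genome, arms = arms)
}

# Atomic regions per chromosome: split at every event boundary.
sim_regions <- function(config) {
  chroms <- sim_chrom_names(config)
  evs <- rbind(config$truncal_loh[, c("chrom", "start", "end")],
               config$private_loh[, c("chrom", "start", "end")],
               config$gains[, c("chrom", "start", "end")])
  out <- list()
  for (ch in chroms) {
    bp <- sort(unique(c(0L, config$chrom_length,
                        evs$start[evs$chrom == ch], evs$end[evs$chrom == ch])))
    out[[ch]] <- data.frame(chrom = ch, start = bp[-length(bp)], end = bp[-1],
                            stringsAsFactors = FALSE)
  }
  reg <- do.call(rbind, out)
  reg$region_id <- seq_len(nrow(reg))
  rownames(reg) <- NULL
  reg
}

regions_covered <- function(regions, chrom, start, end) {
  which(regions$chrom == chrom & regions$start >= start & regions$end <= end)
}

# Apply one copy-number event to a list of per-region copy vectors. The
# affected copy indices are drawn once per event: a single biological event
# removes or duplicates the same homolog across its whole region.
#
# Copy labels encode mutation content. A duplication that happens while
# mutations already sit on the parent copy (copy-neutral LOH restoring the
# copy number, private gains) reuses the parent's label, so those mutations
# gain multiplicity. Trunk gains are applied before trunk mutations are
# placed (early aneuploidy) and therefore mint fresh labels ("B.3"): the
# new copy is a distinguishable target for subsequent mutations, which is
# what makes single-homolog loss in a triploid region remove one third of
# multiplicity-1 sites.
apply_event <- function(copies, idx, mode, new_cn = NA, fresh_labels = FALSE) {
  base <- copies[[idx[1]]]
  same <- all(vapply(copies[idx], function(x) identical(x, base), logical(1)))
  if (!same) stop("config error: overlapping contradictory CN events")
  if (mode %in% c("copy_loss", "copy_neutral")) {
    if (length(base) == 0) stop("config error: LOH event on CN-0 region")
    lost <- sample.int(length(base), 1)
    new <- base[-lost]
    if (mode == "copy_neutral") {
      if (length(new) == 0) stop("config error: copy-neutral LOH needs CN >= 2")
      new <- c(new, new[sample.int(length(new), 1)])
    }
  } else if (mode == "gain") {
    new <- base
    if (new_cn < length(new)) stop("config error: gain below current CN")
    while (length(new) < new_cn) {
      parent <- new[sample.int(length(new), 1)]
      lab <- if (fresh_labels) paste0(parent, ".", length(new) + 1) else parent
      new <- c(new, lab)
    }
  } else stop("unknown event mode: ", mode)
  for (i in idx) copies[[i]] <- new
  copies
}

# Germline homolog of a copy: the label prefix before any gain suffix.
base_label <- function(labels) sub("\\..*$", "", labels)

draw_unique_sites <- function(n, chroms, chrom_length, taken = character()) {
  chrom <- character(0); pos <- integer(0)
  while (length(chrom) < n) {
    k <- n - length(chrom)
    ch <- sample(chroms, k, replace = TRUE)
    p <- sample.int(chrom_length, k, replace = TRUE)
    key <- paste(ch, p)
    keep <- !duplicated(key) & !key %in% c(taken, paste(chrom, pos))
    chrom <- c(chrom, ch[keep]); pos <- c(pos, p[keep])
  }
  data.frame(chrom = chrom, pos = pos, stringsAsFactors = FALSE)
}

draw_alts <- function(refs, spectrum) {
  bases <- c("A", "C", "G", "T")
  vapply(refs, function(r) {
    alts <- setdiff(bases, r)
    w <- spectrum[paste0(r, ">", alts)]
    sample(alts, 1, prob = w / sum(w))
  }, character(1), USE.NAMES = FALSE)
}

#' Simulate a metastatic case with ground truth
#'
#' Places trunk mutations, applies truncal LOH and trunk gains before
#' lineage divergence, applies per-sample private copy-number events, then
#' places private mutations and germline SNPs. Records, per mutation and
#' sample, the local copy number, multiplicity, expected VAF and survival
#' flag, and per region the true LOH scope. Deterministic given the config
#' seed.
#'
#' @param config A [sim_config()].
#' @param reference Optional output of [simulate_reference()]; regenerated
#'   from the config when omitted.
#' @return An object of class `truth_manifest`: list with `mutations`
#'   (mut_id, chrom, pos, ref, alt, origin, owner, homolog, creates_pam),
#'   `per_sample` (mut_id x sample_id: cn, multiplicity, exp_vaf,
#'   survived), `regions` (region_id, chrom, start, end, scope, mode),
#'   `segments` (per-sample CN segments) and `config`.
#' @export
simulate_case <- function(config, reference = NULL) {
  if (is.null(reference)) reference <- simulate_reference(config)
  set.seed(config$seed + 1L)
  chroms <- sim_chrom_names(config)
  regions <- sim_regions(config)
  samples <- config$samples$sample_id

  # Trunk copy state in two stages around mutation placement:
  # gains first (fresh copy labels -- early aneuploidy precedes most of the
  # passenger burden), then trunk mutations are placed on these copies,
  # then truncal LOH removes a copy before lineage divergence.
  trunk_pre <- rep(list(c("A", "B")), nrow(regions))
  tg <- config$gains[config$gains$sample_id == "trunk", , drop = FALSE]
  for (i in seq_len(nrow(tg))) {
    idx <- regions_covered(regions, tg$chrom[i], tg$start[i], tg$end[i])
    trunk_pre <- apply_event(trunk_pre, idx, "gain", tg$new_cn[i],
                             fresh_labels = TRUE)
  }
  trunk <- trunk_pre
  tl <- config$truncal_loh
  for (i in seq_len(nrow(tl))) {
    idx <- regions_covered(regions, tl$chrom[i], tl$start[i], tl$end[i])
    trunk <- apply_event(trunk, idx, tl$mode[i])
  }

  # per-sample copy state
  copies <- list()
  for (s in samples) {
    cs <- trunk
    pl <- config$private_loh[config$private_loh$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(pl))) {
      idx <- regions_covered(regions, pl$chrom[i], pl$start[i], pl$end[i])
      cs <- apply_event(cs, idx, pl$mode[i])
    }
    pg <- config$gains[config$gains$sample_id == s, , drop = FALSE]
    for (i in seq_len(nrow(pg))) {
      idx <- regions_covered(regions, pg$chrom[i], pg$start[i], pg$end[i])
      cs <- apply_event(cs, idx, "gain", pg$new_cn[i])
    }
    copies[[s]] <- cs
  }

  ref_chr <- lapply(as.character(reference$genome), identity)
  names(ref_chr) <- names(reference$genome)
  base_at <- function(chrom, pos) {
    substring(ref_chr[[chrom[1]]], pos, pos)
  }

  region_of <- function(chrom, pos) {
    # pos is 1-based; regions 0-based half-open
    vapply(seq_along(chrom), function(i) {
      r <- regions$region_id[regions$chrom == chrom[i] &
                               regions$start <= pos[i] - 1L &
                               regions$end >= pos[i]]
      r[1]
    }, integer(1))
  }

  # trunk mutations: one uniformly chosen copy of the (post-gain,
  # pre-LOH) trunk state of their region, multiplicity 1 at placement
  trunk_sites <- draw_unique_sites(config$n_trunk_mutations, chroms, config$chrom_length)
  taken <- paste(trunk_sites$chrom, trunk_sites$pos)
  trunk_sites$ref <- vapply(seq_len(nrow(trunk_sites)),
                            function(i) base_at(trunk_sites$chrom[i], trunk_sites$pos[i]),
                            character(1))
  trunk_sites$alt <- draw_alts(trunk_sites$ref, config$spectrum)
  trunk_rid <- region_of(trunk_sites$chrom, trunk_sites$pos)
  trunk_sites$homolog <- vapply(trunk_rid, function(r) {
    cp <- trunk_pre[[r]]
    cp[sample.int(length(cp), 1)]
  }, character(1))
  trunk_sites$origin <- rep("trunk", nrow(trunk_sites))
  trunk_sites$owner <- rep(NA_character_, nrow(trunk_sites))

  # private mutations: placed after the sample's CN events, on one
  # surviving physical copy (multiplicity 1)
  priv_list <- list()
  for (s in samples) {
    ps <- draw_unique_sites(config$n_private_mutations, chroms,
                            config$chrom_length, taken)
    taken <- c(taken, paste(ps$chrom, ps$pos))
    ps$ref <- vapply(seq_len(nrow(ps)),
                     function(i) base_at(ps$chrom[i], ps$pos[i]), character(1))
    ps$alt <- draw_alts(ps$ref, config$spectrum)
    rid <- region_of(ps$chrom, ps$pos)
    ps$homolog <- vapply(seq_len(nrow(ps)), function(i) {
      cp <- copies[[s]][[rid[i]]]
      if (length(cp) == 0) NA_character_ else cp[sample.int(length(cp), 1)]
    }, character(1))
    ps <- ps[!is.na(ps$homolog), , drop = FALSE]
    ps$origin <- rep("private", nrow(ps))
    ps$owner <- rep(s, nrow(ps))
    priv_list[[s]] <- ps
  }

  # germline heterozygous SNPs
  germ <- draw_unique_sites(config$n_germline_snps, chroms, config$chrom_length, taken)
  germ$ref <- vapply(seq_len(nrow(germ)),
                     function(i) base_at(germ$chrom[i], germ$pos[i]), character(1))
  germ$alt <- draw_alts(germ$ref, config$spectrum)
  germ$homolog <- sample(c("A", "B"), nrow(germ), replace = TRUE)
  germ$origin <- rep("germline", nrow(germ))
  germ$owner <- rep(NA_character_, nrow(germ))

  mutations <- rbind(trunk_sites, do.call(rbind, priv_list), germ)
  mutations <- mutations[, c("chrom", "pos", "ref", "alt", "origin", "owner", "homolog")]
  mutations$mut_id <- paste(mutations$chrom, mutations$pos, mutations$ref,
                            mutations$alt, sep = ":")
  rownames(mutations) <- NULL

  somatic <- mutations$origin != "germline"
  pam_hits <- detect_novel_pams(
    data.frame(chrom = mutations$chrom[somatic], pos = mutations$pos[somatic],
               ref = mutations$ref[somatic], alt = mutations$alt[somatic],
               sample_id = "truth", alt_depth = 0L, total_depth = 0L, vaf = 0,
               stringsAsFactors = FALSE),
    reference$genome)
  mutations$creates_pam <- FALSE
  mutations$creates_pam[somatic] <-
    mutations$mut_id[somatic] %in% paste(pam_hits$chrom, pam_hits$pos,
                                         pam_hits$ref, pam_hits$alt, sep = ":")

  # per-(mutation, sample) truth
  rid <- region_of(mutations$chrom, mutations$pos)
  per_sample <- list()
  for (si in seq_along(samples)) {
    s <- samples[si]
    p <- config$samples$purity[si]
    cp <- copies[[s]]
    cn <- vapply(rid, function(r) length(cp[[r]]), integer(1))
    m <- integer(nrow(mutations))
    for (i in seq_len(nrow(mutations))) {
      if (mutations$origin[i] == "private") {
        m[i] <- if (identical(mutations$owner[i], s)) 1L else 0L
      } else if (mutations$origin[i] == "germline") {
        # a germline variant rides every copy descending from its homolog,
        # including fresh copies minted by trunk gains
        m[i] <- sum(base_label(cp[[rid[i]]]) == mutations$homolog[i])
      } else {
        m[i] <- sum(cp[[rid[i]]] == mutations$homolog[i])
      }
    }
    denom <- p * cn + (1 - p) * 2
    germ_extra <- ifelse(mutations$origin == "germline", (1 - p) * 1, 0)
    ev <- ifelse(denom > 0, (p * m + germ_extra) / denom, 0)
    per_sample[[s]] <- data.frame(mut_id = mutations$mut_id, sample_id = s,
                                  cn = cn, multiplicity = m, exp_vaf = ev,
                                  survived = m > 0, stringsAsFactors = FALSE)
  }
  per_sample <- do.call(rbind, per_sample)
  rownames(per_sample) <- NULL

  # region truth: scope and mode
  regions$scope <- "retained_het"
  regions$mode <- "not_applicable"
  for (i in seq_len(nrow(tl))) {
    idx <- regions_covered(regions, tl$chrom[i], tl$start[i], tl$end[i])
    regions$scope[idx] <- "truncal_loh"
    regions$mode[idx] <- tl$mode[i]
  }
  pl <- config$private_loh
  for (i in seq_len(nrow(pl))) {
    idx <- regions_covered(regions, pl$chrom[i], pl$start[i], pl$end[i])
    regions$scope[idx] <- "private_loh"
    regions$mode[idx] <- pl$mode[i]
  }

  segments <- do.call(rbind, lapply(samples, function(s) {
    data.frame(chrom = regions$chrom, start = regions$start, end = regions$end,
               total_cn = vapply(copies[[s]], length, integer(1)),
               sample_id = s, stringsAsFactors = FALSE)
  }))
  rownames(segments) <- NULL

  structure(list(mutations = mutations, per_sample = per_sample,
                 regions = regions[, c("region_id", "chrom", "start", "end",
                                       "scope", "mode")],
                 segments = segments, config = config),
            class = "truth_manifest")
}

#' @export
print.truth_manifest <- function(x, ...) {
  cat("truth manifest:", nrow(x$mutations), "mutations (",
      sum(x$mutations$origin == "trunk"), "trunk ) across",
      nrow(x$config$samples), "samples;",
      sum(x$mutations$creates_pam), "create PAMs\n")
  invisible(x)
}

sample_reads <- function(exp_vaf, mean_depth) {
  depth <- rpois(length(exp_vaf), mean_depth)
  alt <- rbinom(length(exp_vaf), depth, pmin(pmax(exp_vaf, 0), 1))
  data.frame(alt_depth = alt, total_depth = depth)
}

#' Emit VCF and segment file for one sample
#'
#' In `wgs` mode, only sites carried by the sample (expected VAF > 0) are
#' written, emulating a caller's output. In `capture` mode every
#' PAM-creating somatic site of the case is written -- including sites the
#' sample does not carry, which receive zero alt reads -- so that
#' downstream presence/absence calling is exercised. Total depth is
#' Poisson(mean depth) and alt reads binomial at the expected VAF.
#' Deterministic given the config seed and sample.
#'
#' @param truth A `truth_manifest`.
#' @param sample_id One of the configured tumor samples.
#' @param dir Output directory.
#' @param mode `"wgs"` or `"capture"`.
#' @return Named list of written paths (`vcf`, `segments`), invisibly.
#' @export
emit_sample <- function(truth, sample_id, dir, mode = c("wgs", "capture")) {
  mode <- match.arg(mode)
  config <- truth$config
  si <- match(sample_id, config$samples$sample_id)
  if (is.na(si)) stop("unknown sample: ", sample_id)
  set.seed(config$seed + 7919L * si + if (mode == "capture") 13L else 0L)
  ps <- truth$per_sample[truth$per_sample$sample_id == sample_id, , drop = FALSE]
  mut <- truth$mutations[match(ps$mut_id, truth$mutations$mut_id), , drop = FALSE]
  if (mode == "wgs") {
    keep <- ps$exp_vaf > 0
  } else {
    keep <- mut$creates_pam
  }
  ps <- ps[keep, , drop = FALSE]; mut <- mut[keep, , drop = FALSE]
  reads <- sample_reads(ps$exp_vaf, config$samples$mean_depth[si])
  variants <- data.frame(chrom = mut$chrom, pos = mut$pos, ref = mut$ref,
                         alt = mut$alt, sample_id = sample_id,
                         alt_depth = reads$alt_depth,
                         total_depth = reads$total_depth,
                         vaf = ifelse(reads$total_depth > 0,
                                      reads$alt_depth / reads$total_depth, 0),
                         stringsAsFactors = FALSE)
  vcf_path <- file.path(dir, paste0(sample_id, ".", mode, ".vcf"))
  write_vcf(variants, vcf_path, sample_id)
  seg_path <- file.path(dir, paste0(sample_id, ".cns"))
  write_segments(truth$segments[truth$segments$sample_id == sample_id, ], seg_path)
  invisible(list(vcf = vcf_path, segments = seg_path))
}

#' Emit the matched-normal VCF
#'
#' Germline heterozygous SNPs at expected VAF 0.5, sampled at the
#' configured normal depth.
#'
#' @param truth A `truth_manifest`.
#' @param dir Output directory.
#' @return The written path, invisibly.
#' @export
emit_normal <- function(truth, dir) {
  config <- truth$config
  set.seed(config$seed + 104729L)
  germ <- truth$mutations[truth$mutations$origin == "germline", , drop = FALSE]
  reads <- sample_reads(rep(0.5, nrow(germ)), config$normal_depth)
  variants <- data.frame(chrom = germ$chrom, pos = germ$pos, ref = germ$ref,
                         alt = germ$alt, sample_id = config$normal_id,
                         alt_depth = reads$alt_depth,
                         total_depth = reads$total_depth,
                         vaf = ifelse(reads$total_depth > 0,
                                      reads$alt_depth / reads$total_depth, 0),
                         stringsAsFactors = FALSE)
  path <- file.path(dir, paste0(config$normal_id, ".vcf"))
  write_vcf(variants, path, config$normal_id)
  invisible(path)
}

#' Simulate a full scenario to disk
#'
#' Writes the reference FASTA, arm table, matched-normal VCF, per-sample
#' WGS and capture VCFs and segment files, the ground-truth tables, and a
#' pipeline manifest (`manifest.yaml`) pointing at them all.
#'
#' @param config A [sim_config()].
#' @param outdir Output directory (created if needed).
#' @param case_id Case label used in the manifest.
#' @return List with `truth`, `manifest` (path) and `paths`.
#' @export
simulate_scenario <- function(config, outdir, case_id = "SIM") {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  reference <- simulate_reference(config)
  truth <- simulate_case(config, reference)
  ref_path <- file.path(outdir, "ref.fa")
  write_fasta(reference$genome, ref_path)
  arms_path <- file.path(outdir, "arms.bed")
  write_arms(reference$arms, arms_path)
  normal_path <- emit_normal(truth, outdir)
  sample_entries <- list()
  for (s in config$samples$sample_id) {
    wgs <- emit_sample(truth, s, outdir, "wgs")
    cap <- emit_sample(truth, s, outdir, "capture")
    sample_entries[[s]] <- list(sample_id = s,
                                role = config$samples$role[config$samples$sample_id == s],
                                wgs_vcf = wgs$vcf, capture_vcf = cap$vcf,
                                segments = wgs$segments)
  }
  write.table(truth$mutations, file.path(outdir, "truth_mutations.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$per_sample, file.path(outdir, "truth_per_sample.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(truth$regions, file.path(outdir, "truth_regions.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- list(case_id = case_id, reference = ref_path, arms = arms_path,
                   normal_vcf = normal_path, normal_sample = config$normal_id,
                   seed = config$seed,
                   params = list(purity = setNames(as.list(config$samples$purity),
                                                   config$samples$sample_id)),
                   samples = unname(sample_entries))
  manifest_path <- file.path(outdir, "manifest.yaml")
  yaml::write_yaml(manifest, manifest_path)
  list(truth = truth, manifest = manifest_path,
       paths = list(reference = ref_path, arms = arms_path,
                    normal_vcf = normal_path))
}

#' Miniature four-sample scenario with known LOH structure
#'
#' A compact case mirroring the structure seen in multi-lesion pancreatic
#' cancer cell-line panels: one primary section plus three metastases at
#' purity 1 and 60x depth; chromosome 1 under trunk-level copy-loss LOH
#' (applied before divergence, so surviving trunk mutations sit at VAF 1 in
#' every sample), chromosome 2 under private copy-loss LOH in the first
#' metastasis only, and chromosome 3 fully heterozygous.
#'
#' @param seed Integer seed.
#' @param n_trunk_mutations,n_private_mutations,chrom_length Scenario size.
#' @return A [sim_config()].
#' @export
demo_case_config <- function(seed = 1L, n_trunk_mutations = 300L,
                            n_private_mutations = 40L, chrom_length = 1e6) {
  sim_config(
    seed = seed, n_chromosomes = 3L, chrom_length = chrom_length,
    n_trunk_mutations = n_trunk_mutations,
    n_private_mutations = n_private_mutations,
    samples = data.frame(sample_id = c("P1", "M1", "M2", "M3"),
                         role = c("primary", rep("metastasis", 3)),
                         purity = 1, mean_depth = 60, stringsAsFactors = FALSE),
    truncal_loh = data.frame(chrom = "chr1", start = 0L,
                             end = as.integer(chrom_length), mode = "copy_loss",
                             stringsAsFactors = FALSE),
    private_loh = data.frame(chrom = "chr2", start = 0L,
                             end = as.integer(chrom_length), mode = "copy_loss",
                             sample_id = "M1", stringsAsFactors = FALSE))
}

#' Read a simulation scenario from YAML
#'
#' The YAML mirrors the arguments of [sim_config()]: scalar fields at the
#' top level, and `samples`, `truncal_loh`, `private_loh`, `gains` as lists
#' of records. See `inst/extdata/scenarios/demo_case.yaml` for a complete
#' example.
#'
#' @param path Path to a scenario YAML file.
#' @param seed Optional seed overriding the one in the file.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path, seed = NULL) {
  if (!file.exists(path)) stop("scenario file not found: ", path)
  y <- yaml::read_yaml(path)
  as_df <- function(x) {
    if (is.null(x) || length(x) == 0) return(NULL)
    do.call(rbind, lapply(x, function(r) as.data.frame(r, stringsAsFactors = FALSE)))
  }
  args <- y
  for (f in c("samples", "truncal_loh", "private_loh", "gains")) {
    args[[f]] <- as_df(y[[f]])
  }
  if (is.null(args$samples)) args$samples <- NULL
  if (!is.null(seed)) args$seed <- seed
  args <- args[!vapply(args, is.null, logical(1))]
  args <- args[names(args) %in% names(formals(sim_config))]
  do.call(sim_config, args)
}
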