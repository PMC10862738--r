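test_that("simulated references are deterministic with the right composition", {
  cfg <- sim_config(seed = 5, n_chromosomes = 2, chrom_length = 1e4)
  r1 <- simulate_reference(cfg)
  r2 <- simulate_reference(cfg)
  expect_identical(as.character(r1$genome), as.character(r2$genome))
  expect_equal(Biostrings::width(r1$genome), rep(1e4, 2))
  # arm boundary at the configured fraction
  expect_equal(r1$arms$end[r1$arms$arm == "p"], rep(5000L, 2))
  # gc_content 0 gives an AT-only genome
  at <- simulate_reference(sim_config(seed = 5, n_chromosomes = 1,
                                      chrom_length = 5000, gc_content = 0))
  expect_equal(sum(Biostrings::letterFrequency(at$genome, c("G", "C"))), 0)
  # empirical GC within 3 standard errors of the target
  big <- simulate_reference(sim_config(seed = 6, n_chromosomes = 1,
                                       chrom_length = 2e5))
  gc <- sum(Biostrings::letterFrequency(big$genome, c("G", "C"))) / 2e5
  expect_lt(abs(gc - 0.41), 3 * sqrt(0.41 * 0.59 / 2e5))
})

test_that("without LOH every trunk mutation is heterozygous everywhere", {
  cfg <- two_sample_cfg(21, n_chromosomes = 2, chrom_length = 5e4,
                        n_trunk_mutations = 200, n_private_mutations = 10,
                        n_germline_snps = 20)
  truth <- simulate_case(cfg)
  trunk_ids <- truth$mutations$mut_id[truth$mutations$origin == "trunk"]
  ps <- truth$per_sample[truth$per_sample$mut_id %in% trunk_ids, ]
  expect_true(all(ps$survived))
  expect_true(all(ps$exp_vaf == 0.5))
  expect_true(all(ps$cn == 2L))
  expect_true(all(truth$regions$scope == "retained_het"))
})

test_that("truncal LOH is shared by every sample with the right VAF and CN", {
  loss <- data.frame(chrom = "chr1", start = 0L, end = 50000L,
                     mode = "copy_loss", stringsAsFactors = FALSE)
  cfg <- two_sample_cfg(22, n_chromosomes = 2, chrom_length = 5e4,
                        n_trunk_mutations = 300, n_private_mutations = 0,
                        n_germline_snps = 0, truncal_loh = loss)
  truth <- simulate_case(cfg)
  mut <- truth$mutations
  ps <- merge(truth$per_sample, mut[, c("mut_id", "chrom", "origin")])
  chr1 <- ps[ps$chrom == "chr1" & ps$origin == "trunk", ]
  # survival is trunk-level: identical across samples
  surv_tab <- tapply(chr1$survived, chr1$mut_id, unique)
  expect_true(all(lengths(surv_tab) == 1))
  # about half the trunk mutations sat on the lost homolog
  expect_gt(mean(!chr1$survived), 0.3); expect_lt(mean(!chr1$survived), 0.7)
  # survivors are haploid at VAF 1 in every sample
  expect_true(all(chr1$exp_vaf[chr1$survived] == 1))
  expect_true(all(chr1$cn[chr1$survived] == 1L))
  # copy-neutral flavor: VAF 1 at CN 2, multiplicity 2
  cfg2 <- two_sample_cfg(23, n_chromosomes = 1, chrom_length = 5e4,
                         n_trunk_mutations = 200, n_private_mutations = 0,
                         n_germline_snps = 0,
                         truncal_loh = transform(loss, mode = "copy_neutral"))
  t2 <- simulate_case(cfg2)
  s2 <- t2$per_sample[t2$per_sample$survived, ]
  expect_true(all(s2$exp_vaf == 1))
  expect_true(all(s2$cn == 2L))
  expect_true(all(s2$multiplicity == 2L))
})

test_that("private copy-loss LOH loses about half of heterozygous trunk sites", {
  cfg <- two_sample_cfg(24, n_chromosomes = 1, chrom_length = 5e5,
                        n_trunk_mutations = 2000, n_private_mutations = 0,
                        n_germline_snps = 0,
                        private_loh = data.frame(chrom = "chr1", start = 0L,
                                                 end = 500000L, mode = "copy_loss",
                                                 sample_id = "M1",
                                                 stringsAsFactors = FALSE))
  truth <- simulate_case(cfg)
  ps <- truth$per_sample
  p1 <- ps[ps$sample_id == "P1", ]; m1 <- ps[ps$sample_id == "M1", ]
  expect_true(all(p1$survived))                      # loss is private to M1
  loss <- mean(!m1$survived)
  expect_lt(abs(loss - 0.5), 3 * sqrt(0.25 / nrow(m1)))
  # lost sites sat on one homolog: survivors are exactly the other homolog
  hom <- truth$mutations$homolog[match(m1$mut_id, truth$mutations$mut_id)]
  expect_equal(length(unique(hom[!m1$survived])), 1L)
  expect_true(all(m1$exp_vaf[m1$survived] == 1))
})

test_that("read emission is seeded, depth-faithful and VAF-faithful", {
  cfg <- two_sample_cfg(25, n_chromosomes = 1, chrom_length = 1e5,
                        n_trunk_mutations = 400, n_private_mutations = 0,
                        n_germline_snps = 10,
                        truncal_loh = data.frame(chrom = "chr1", start = 0L,
                                                 end = 100000L, mode = "copy_loss",
                                                 stringsAsFactors = FALSE))
  truth <- simulate_case(cfg)
  d1 <- withr::local_tempdir(); d2 <- withr::local_tempdir()
  f1 <- emit_sample(truth, "M1", d1)
  f2 <- emit_sample(truth, "M1", d2)
  expect_identical(readLines(f1$vcf), readLines(f2$vcf))
  expect_identical(readLines(f1$segments), readLines(f2$segments))
  v <- read_vcf(f1$vcf, "M1")
  # expected VAF 1 sites must have alt depth equal to total depth
  expect_true(all(v$alt_depth[v$chrom == "chr1"] ==
                    v$total_depth[v$chrom == "chr1"] | v$vaf < 1))
  trunk_keys <- with(truth$mutations[truth$mutations$origin == "trunk", ],
                     paste(chrom, pos, ref, alt, sep = ":"))
  vt <- v[variant_key(v) %in% trunk_keys, ]
  expect_true(all(vt$alt_depth == vt$total_depth))
  expect_equal(mean(vt$total_depth), 60, tolerance = 0.05)
})

test_that("purity dilutes observed VAF as the model predicts", {
  cfg <- sim_config(seed = 26, n_chromosomes = 1, chrom_length = 2e5,
                    n_trunk_mutations = 1500, n_private_mutations = 0,
                    n_germline_snps = 0,
                    samples = data.frame(sample_id = "F1", role = "metastasis",
                                         purity = 0.5, mean_depth = 80,
                                         stringsAsFactors = FALSE))
  truth <- simulate_case(cfg)
  expect_true(all(truth$per_sample$exp_vaf == 0.25))  # p m /(p C + (1-p) 2)
  d <- withr::local_tempdir()
  f <- emit_sample(truth, "F1", d)
  v <- read_vcf(f$vcf, "F1")
  expect_equal(mean(v$vaf), 0.25, tolerance = 0.02)
})

test_that("simulated PAM creation rate matches the spectrum expectation", {
  cfg <- two_sample_cfg(27, n_chromosomes = 1, chrom_length = 2e6,
                        n_trunk_mutations = 8000, n_private_mutations = 0,
                        n_germline_snps = 0)
  truth <- simulate_case(cfg)
  # enumeration: P(create) for ref base b with neighbors from composition
  gc <- cfg$gc_content
  base_p <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  spec <- cfg$spectrum
  p_create <- 0
  for (r in names(base_p)) {
    alts <- setdiff(names(base_p), r)
    w <- spec[paste0(r, ">", alts)]; w <- w / sum(w)
    for (j in seq_along(alts)) {
      a <- alts[j]
      nb <- if (a == "G") base_p[["G"]] else if (a == "C") base_p[["C"]] else 0
      # at least one of two flanks carries the matching neighbor
      p_hit <- if (nb > 0) 1 - (1 - nb)^2 else 0
      p_create <- p_create + base_p[[r]] * w[j] * p_hit
    }
  }
  got <- mean(truth$mutations$creates_pam)
  se <- sqrt(p_create * (1 - p_create) / nrow(truth$mutations))
  expect_lt(abs(got - p_create), 3 * se)
})

test_that("scenario configs survive the YAML round trip", {
  path <- system.file("extdata", "scenarios", "demo_case.yaml",
                      package = "pamtrace")
  cfg <- read_sim_config(path, seed = 9)
  expect_s3_class(cfg, "sim_config")
  expect_equal(cfg$seed, 9L)
  expect_equal(cfg$n_chromosomes, 3L)
  expect_equal(cfg$truncal_loh$mode, "copy_loss")
  expect_equal(cfg$private_loh$sample_id, "M1")
  expect_equal(cfg$samples$sample_id, c("P1", "M1", "M2", "M3"))
  # matches the in-code constructor
  ref <- demo_case_config(seed = 9)
  expect_equal(cfg$truncal_loh, ref$truncal_loh)
  expect_equal(cfg$samples$role, ref$samples$role)
})

test_that("config validation refuses incoherent scenarios", {
  expect_error(sim_config(truncal_loh = data.frame(chrom = "chr9", start = 0L,
                                                   end = 10L, mode = "copy_loss")),
               "chromosome")
  expect_error(sim_config(private_loh = data.frame(chrom = "chr1", start = 0L,
                                                   end = 10L, mode = "copy_loss",
                                                   sample_id = "ghost")),
               "unknown sample")
  expect_error(
    sim_config(truncal_loh = data.frame(chrom = "chr1", start = 0L, end = 1000L,
                                        mode = "copy_loss"),
               private_loh = data.frame(chrom = "chr1", start = 500L, end = 1500L,
                                        mode = "copy_loss", sample_id = "M1")),
    "overlap")
})
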