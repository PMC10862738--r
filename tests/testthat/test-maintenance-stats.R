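test_that("presence calling orders no_call < absent < present correctly", {
  expect_equal(call_presence(10, 100), "present")   # 0.10 >= 0.05
  expect_equal(call_presence(2, 100), "absent")
  expect_equal(call_presence(1, 10), "no_call")     # below depth gate
  expect_equal(call_presence(5, 100), "present")    # boundary inclusive
  expect_equal(call_presence(c(10, 2, 1, 5), c(100, 100, 10, 100)),
               c("present", "absent", "no_call", "present"))
  expect_equal(call_presence(0, 0), "no_call")
})

pm_from <- function(pres, noc = NULL) as_presence_matrix(pres, noc)

lmat <- function(x, pam_ids, sample_ids) {
  matrix(x, length(pam_ids), length(sample_ids), byrow = TRUE,
         dimnames = list(pam_ids, sample_ids))
}

test_that("truncal union over primaries handles no-calls", {
  pams <- letters[1:4]
  pres <- lmat(c(TRUE, TRUE, FALSE,      # a: P1 only
                 TRUE, TRUE, TRUE,      # b: everywhere
                 FALSE, TRUE, TRUE,     # c: P2 + met
                 FALSE, FALSE, TRUE),   # d: met only
               pams, c("P1", "P2", "M1"))
  tr <- define_truncal_union(pm_from(pres), c("P1", "P2"), "case")
  expect_setequal(tr$pam_ids, c("a", "b", "c"))
  expect_equal(tr$provenance, "primary_union")
  # single primary: its present set
  tr1 <- define_truncal_union(pm_from(pres), "P2")
  expect_setequal(tr1$pam_ids, c("a", "b", "c"))
  # PAM no_call in every primary but present in mets: excluded, listed
  noc <- lmat(c(TRUE, TRUE, FALSE, rep(FALSE, 9)), pams, c("P1", "P2", "M1"))
  tr2 <- define_truncal_union(pm_from(pres, noc), c("P1", "P2"))
  expect_false("a" %in% tr2$pam_ids)
  expect_equal(tr2$uncallable, "a")
  expect_error(define_truncal_union(pm_from(pres), character(0)), "primary")
})

test_that("met-inferred truncal sets require presence in several mets", {
  pres <- lmat(c(rep(TRUE, 2), rep(FALSE, 4),
                 TRUE, rep(FALSE, 5),
                 rep(TRUE, 6)),
               c("a", "b", "c"), paste0("M", 1:6))
  pm <- pm_from(pres)
  tr <- infer_truncal_from_mets(pm)
  expect_setequal(tr$pam_ids, c("a", "c"))   # in >= 2 mets
  expect_equal(tr$provenance, "met_inferred")
  expect_setequal(infer_truncal_from_mets(pm, min_mets = 1)$pam_ids,
                  c("a", "b", "c"))
  expect_error(infer_truncal_from_mets(pm, paste0("M", 1)), "at least")
})

truncal_of <- function(ids) {
  structure(list(case_id = "c", pam_ids = ids, provenance = "primary_union",
                 uncallable = character()), class = "truncal_set")
}

test_that("percent truncal / maintained / shared handle no-calls by exclusion", {
  pams <- letters[1:10]
  pres <- matrix(TRUE, 10, 2, dimnames = list(pams, c("M1", "M2")))
  pres["j", "M1"] <- FALSE
  pm <- pm_from(pres)
  tr <- truncal_of(pams)
  expect_equal(percent_truncal("M1", pm, tr), 0.9)
  expect_equal(percent_truncal("M2", pm, tr), 1)
  # 3 of 10 no_call, 6 of the 7 evaluable present
  noc <- matrix(FALSE, 10, 2, dimnames = dimnames(pres))
  noc[c("a", "b", "c"), "M1"] <- TRUE
  pres2 <- pres; pres2[c("d", "j"), "M1"] <- FALSE
  pm2 <- pm_from(pres2, noc)
  expect_equal(percent_truncal("M1", pm2, tr), 5 / 7)
  # per-PAM maintenance with a no_call met
  expect_equal(percent_maintained("j", pm, c("M1", "M2")), 0.5)
  noc3 <- matrix(FALSE, 10, 2, dimnames = dimnames(pres))
  noc3["j", "M1"] <- TRUE
  expect_equal(percent_maintained("j", pm_from(pres, noc3), c("M1", "M2")), 1)
  # shared-by-all counts full presence only
  lesions <- lmat(c(TRUE, TRUE, TRUE,
                    TRUE, TRUE, FALSE,
                    TRUE, FALSE, TRUE),
                  c("a", "b", "c"), c("L1", "L2", "L3"))
  expect_equal(shared_by_all(truncal_of(c("a", "b", "c")), pm_from(lesions)), 1 / 3)
  same <- lesions[, c(1, 1, 1)]
  colnames(same) <- c("L1", "L2", "L3")
  expect_equal(shared_by_all(truncal_of(c("a", "b", "c")), pm_from(same)), 1)
  zero <- lesions; zero[, "L3"] <- FALSE
  expect_equal(shared_by_all(truncal_of(c("a", "b", "c")), pm_from(zero)), 0)
})

test_that("set overlaps enumerate every membership region exactly", {
  ov <- set_overlaps(list(A = c("a", "b"), B = c("b", "c")))
  get <- function(A, B) ov$count[ov$A == A & ov$B == B]
  expect_equal(get(TRUE, FALSE), 1L)   # only a
  expect_equal(get(FALSE, TRUE), 1L)   # only c
  expect_equal(get(TRUE, TRUE), 1L)    # b
  ident <- set_overlaps(list(X = letters[1:5], Y = letters[1:5]))
  expect_equal(ident$count[ident$X & ident$Y], 5L)
  expect_equal(sum(ident$count[xor(ident$X, ident$Y)]), 0L)
  disj <- set_overlaps(list(X = "a", Y = "b", Z = "c"))
  expect_equal(disj$count[disj$X & disj$Y & disj$Z], 0L)
  expect_equal(sum(disj$count), 3L)
})

test_that("maintenance by LOH class averages per-PAM maintenance", {
  scopes <- data.frame(chrom = "chr1", start = c(0L, 1000L, 2000L),
                       end = c(1000L, 2000L, 3000L),
                       scope = c("truncal_loh", "private_loh", "retained_het"),
                       stringsAsFactors = FALSE)
  pam_pos <- data.frame(pam_id = c("a", "b", "c", "d"),
                        chrom = "chr1", pos = c(500L, 1500L, 1600L, 2500L),
                        stringsAsFactors = FALSE)
  pres <- lmat(c(TRUE, TRUE,
                 TRUE, FALSE,
                 FALSE, FALSE,
                 TRUE, TRUE),
               c("a", "b", "c", "d"), c("M1", "M2"))
  out <- maintenance_by_loh_class(pm_from(pres), truncal_of(c("a", "b", "c", "d")),
                                  scopes, pam_pos, c("M1", "M2"))
  expect_equal(out$mean_maintained[out$loh_class == "truncal_loh"], 1)
  expect_equal(out$mean_maintained[out$loh_class == "private_loh"], 0.25)
  expect_equal(out$mean_maintained[out$loh_class == "retained_het"], 1)
  expect_equal(out$n_pams, c(1L, 2L, 1L))
  # unclassified bucket for PAMs outside every region
  pam_pos2 <- rbind(pam_pos, data.frame(pam_id = "e", chrom = "chr9", pos = 1L))
  pres2 <- rbind(pres, e = c(TRUE, TRUE))
  out2 <- maintenance_by_loh_class(pm_from(pres2),
                                   truncal_of(c(pam_pos2$pam_id)),
                                   scopes, pam_pos2, c("M1", "M2"))
  expect_equal(out2$n_pams[out2$loh_class == "unclassified"], 1L)
})

test_that("depth QC finds the knee of the percent-truncal curve", {
  qc <- qc_depth_filter(c(10, 80, 90, 100), c(0.4, 0.9, 0.91, 0.9))
  expect_equal(qc$include, c(FALSE, TRUE, TRUE, TRUE))
  expect_equal(attr(qc, "method"), "two_segment")
  expect_equal(attr(qc, "knee"), 45)
  # flat data: threshold-only, all deep samples included
  qc2 <- qc_depth_filter(c(40, 60, 80, 100), rep(0.9, 4))
  expect_equal(attr(qc2, "method"), "threshold")
  expect_true(all(qc2$include))
  # noisy flat data must not invent a knee
  withr::local_seed(3)
  qc3 <- qc_depth_filter(seq(50, 120, by = 10), 0.9 + runif(8, -0.01, 0.01))
  expect_true(all(qc3$include))
  # fewer than 3 samples: hard floor only
  qc4 <- qc_depth_filter(c(10, 100), c(0.2, 0.9))
  expect_equal(attr(qc4, "method"), "threshold")
  expect_equal(qc4$include, c(FALSE, TRUE))
})

test_that("group tests match exact rank-sum enumeration and null behavior", {
  # identical groups: exact two-sided p of 1
  g <- group_tests(list(a = c(1, 2, 3), b = c(1, 2, 3)))
  expect_equal(g$p_value, 1)
  # {0,0,0} vs {1,1,1}: enumeration over the 20 assignments gives 2/20
  r <- rank(c(0, 0, 0, 1, 1, 1))
  combos <- combn(6, 3)
  s_all <- colSums(matrix(r[combos], nrow = 3))
  p_exact <- mean(abs(s_all - 10.5) >= abs(sum(r[1:3]) - 10.5))
  expect_equal(p_exact, 0.1)   # frozen oracle value
  g2 <- group_tests(list(a = c(0, 0, 0), b = c(1, 1, 1)))
  expect_equal(g2$p_value, p_exact)
  # three identical groups: Kruskal-Wallis H of (about) zero
  g3 <- group_tests(list(a = c(1, 2, 3), b = c(1, 2, 3), c = c(1, 2, 3)))
  expect_lt(g3$statistic[g3$test == "kruskal_wallis"], 1e-10)
  expect_true(all(c("kruskal_wallis", "anova") %in% g3$test))
  # degenerate all-equal input
  expect_warning(g4 <- group_tests(list(a = c(1, 1), b = c(1, 1))), "degenerate")
  expect_true(is.na(g4$p_value[1]))
  expect_error(group_tests(list(a = 1:3)), "2 groups")
  expect_error(group_tests(list(a = 1, b = 1:2)), "at least 2 values")
})

test_that("maintenance statistics agree with brute-force counting", {
  withr::local_seed(19)
  for (i in 1:100) {
    rp <- random_presence(sample(4:25, 1), sample(3:7, 1),
                          p_present = runif(1, 0.3, 0.95),
                          p_nocall = sample(c(0, 0.15), 1))
    pm <- as_presence_matrix(rp$pres, rp$noc)
    truncal_ids <- sample(rp$pam_ids, max(2, length(rp$pam_ids) %/% 2))
    tr <- truncal_of(truncal_ids)
    mets <- rp$sample_ids[-1]
    for (s in rp$sample_ids) {
      expect_equal(percent_truncal(s, pm, tr),
                   oracle_pct_truncal(rp$pres, rp$noc, truncal_ids, s))
    }
    for (p in sample(rp$pam_ids, 3)) {
      expect_equal(percent_maintained(p, pm, mets),
                   oracle_pct_maintained(rp$pres, rp$noc, p, mets))
    }
    expect_equal(shared_by_all(tr, pm),
                 oracle_shared_all(rp$pres, rp$noc, truncal_ids, rp$sample_ids))
    # without no-calls, mean over PAMs equals mean over metastases
    if (all(!rp$noc)) {
      pt <- vapply(mets, function(s) percent_truncal(s, pm, truncal_of(rp$pam_ids)),
                   numeric(1))
      pmaint <- vapply(rp$pam_ids, function(p) percent_maintained(p, pm, mets),
                       numeric(1))
      expect_equal(mean(pmaint), mean(pt))
      expect_lte(shared_by_all(truncal_of(rp$pam_ids), pm,
                               lesion_samples = mets) - 1e-12, min(pt))
    }
    # row/column permutation invariance (lookups go through dimnames)
    pm_b <- as_presence_matrix(rp$pres[sample(nrow(rp$pres)), sample(ncol(rp$pres))],
                               NULL)
    pm_a <- as_presence_matrix(rp$pres)
    expect_equal(shared_by_all(tr, pm_a, rp$sample_ids),
                 shared_by_all(tr, pm_b, rp$sample_ids))
    expect_equal(percent_truncal(rp$sample_ids[1], pm_a, tr),
                 percent_truncal(rp$sample_ids[1], pm_b, tr))
  }
})
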