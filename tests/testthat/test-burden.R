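test_that("poisson_upper_tail matches closed forms and the summation oracle", {
  expect_equal(poisson_upper_tail(0, 5)$p, 1)
  expect_equal(poisson_upper_tail(3, 1)$p, 1 - exp(-1) * (1 + 1 + 0.5),
               tolerance = 1e-12)
  # naive term-summation oracle over a grid
  for (lam in c(0.1, 0.5, 1, 2.5, 5)) {
    for (obs in c(1, 2, 3, 7, 15, 30)) {
      expect_equal(poisson_upper_tail(obs, lam)$p,
                   oracle_poisson_tail(obs, lam),
                   tolerance = 1e-10, info = paste(obs, lam))
    }
  }
  # monotone decreasing in observed, increasing in lambda
  p_obs <- vapply(1:20, function(o) poisson_upper_tail(o, 2)$p, 0)
  expect_true(all(diff(p_obs) < 0))
  p_lam <- vapply(seq(0.5, 5, 0.5), function(l)
    poisson_upper_tail(5, l)$p, 0)
  expect_true(all(diff(p_lam) > 0))
  expect_error(poisson_upper_tail(3, 0), "lambda")
  expect_error(poisson_upper_tail(-1, 1), "non-negative")
  expect_error(poisson_upper_tail(2.5, 1), "non-negative")
})

test_that("log-space tail stays finite far below double underflow", {
  deep <- poisson_upper_tail(753, 49.92)
  expect_true(is.finite(deep$log10_p))
  expect_lt(deep$log10_p, -100)
  # the raw probability underflows; log10_p carries the value
  expect_lt(deep$log10_p, -500)
})

test_that("multiplicity_config reproduces the Bonferroni threshold", {
  cfg <- multiplicity_config(0.05, 5, 2871)
  expect_equal(signif(cfg$threshold, 3), 3.48e-6)
  expect_error(multiplicity_config(0, 5, 10))
})

test_that("filter_reference_panel removes exactly the panel keys", {
  dnms <- data.frame(
    proband_id = paste0("P", 1:4), cohort = "DD",
    gene = c("G1", "G1", "G2", "G3"),
    consequence = c("missense", "missense", "nonsense", "missense"),
    protein_position = c(5L, 9L, 2L, 7L),
    aa_ref = c("A", "L", "W", "K"), aa_alt = c("V", "P", "*", "E"),
    stringsAsFactors = FALSE)
  expect_equal(nrow(filter_reference_panel(dnms, character(0))), 4L)
  p1 <- filter_reference_panel(dnms, "G1:A:5:V")
  expect_equal(nrow(p1), 3L)
  expect_equal(as.integer(attr(p1, "removed_per_gene")[["G1"]]), 1L)
  # genomic keys take precedence when present
  dnms$chrom <- c("1", NA, "2", NA)
  dnms$pos <- c(100L, NA, 200L, NA)
  dnms$ref <- c("A", NA, "C", NA)
  dnms$alt <- c("G", NA, "T", NA)
  p2 <- filter_reference_panel(dnms, c("1:100:A:G", "G3:K:7:E"))
  expect_equal(nrow(p2), 2L)
  # random brute-force set-difference oracle
  set.seed(41)
  for (i in 1:20) {
    n <- sample(5:30, 1)
    d <- data.frame(gene = sample(paste0("G", 1:5), n, TRUE),
                    consequence = "missense",
                    protein_position = sample(1:20, n, TRUE),
                    aa_ref = sample(paralogr:::AA20, n, TRUE),
                    aa_alt = sample(paralogr:::AA20, n, TRUE),
                    stringsAsFactors = FALSE)
    keys <- paste(d$gene, d$aa_ref, d$protein_position, d$aa_alt, sep = ":")
    panel <- sample(unique(keys), sample(0:3, 1))
    got <- filter_reference_panel(d, panel)
    expect_equal(nrow(got), sum(!keys %in% panel))
  }
})

test_that("assign_site_class follows the strict z > 0 rule and guards aa drift", {
  tr <- zscore_track(c(11, 8, 5, 2), "G1", residues = c("M", "K", "V", "L"))
  expect_equal(assign_site_class(list(protein_position = 1L, aa_ref = "M"),
                                 tr), "conserved")
  expect_equal(assign_site_class(list(protein_position = 4L, aa_ref = "L"),
                                 tr), "nonconserved")
  # z == 0 exactly -> nonconserved (constant track)
  tr0 <- zscore_track(c(7, 7), "G0", residues = c("A", "A"))
  expect_equal(assign_site_class(list(protein_position = 1L, aa_ref = "A"),
                                 tr0), "nonconserved")
  expect_error(assign_site_class(list(protein_position = 9L, aa_ref = "M"),
                                 tr), "out of range")
  expect_error(assign_site_class(list(protein_position = 2L, aa_ref = "Q"),
                                 tr), "mismatch")
  # batch matches the per-record rule
  set.seed(43)
  flags <- sample(c(TRUE, FALSE), 50, TRUE)
  trb <- track_from_flags(flags, "GB")
  for (pos in sample(50, 10)) {
    expect_equal(assign_site_class(list(protein_position = pos,
                                        aa_ref = NA), trb),
                 if (flags[pos]) "conserved" else "nonconserved")
  }
})

test_that("family_burden_test aggregates, tests and corrects as specified", {
  exps <- data.frame(
    gene_id = c("A", "B"),
    synonymous = c(0.05, 0.05), missense = c(0.2, 0.3),
    nonsense = c(0.02, 0.03), frameshift = c(0.025, 0.0375),
    splice = c(0, 0), ptv = c(0.045, 0.0675), stoploss = c(0, 0),
    missense_conserved = c(0.05, 0.05),
    missense_nonconserved = c(0.15, 0.25),
    n_conserved_sites = c(10L, 10L), n_nonconserved_sites = c(30L, 50L))
  memb <- data.frame(subfamily_id = "F.1", gene_id = c("A", "B"))
  tracks <- list(A = track_from_flags(rep(c(TRUE, FALSE), c(10, 30)), "A"),
                 B = track_from_flags(rep(c(TRUE, FALSE), c(10, 50)), "B"))
  # 7 conserved-site missense dnms in a family with lambda_mis_cons = 0.1
  dnms <- data.frame(
    proband_id = paste0("P", 1:8), cohort = rep(c("DD", "ASD"), 4),
    gene = c(rep("A", 4), rep("B", 3), "A"),
    consequence = c(rep("missense", 7), "nonsense"),
    protein_position = c(1:4, 1:3, 15L),
    aa_ref = NA_character_, aa_alt = NA_character_,
    stringsAsFactors = FALSE)
  cfg <- multiplicity_config(0.05, 5, 2871)
  res <- family_burden_test(exps, dnms, memb, tracks, cfg)
  mc <- res[res$category == "missense_conserved", ]
  expect_equal(mc$observed, 7L)
  expect_equal(mc$expected, 0.1)
  expect_equal(mc$p_value, poisson_upper_tail(7, 0.1)$p, tolerance = 1e-12)
  expect_equal(mc$significant, mc$p_value < cfg$threshold)
  expect_true(mc$significant)  # P(X>=7 | 0.1) ~ 1e-11 < 3.48e-6
  # category additivity for fully classifiable inputs
  expect_equal(res$observed[res$category == "missense"],
               res$observed[res$category == "missense_conserved"] +
                 res$observed[res$category == "missense_nonconserved"])
  # combined category = ptv + conserved missense
  expect_equal(res$observed[res$category == "missense_ptv_conserved"], 8L)
  expect_equal(res$expected[res$category == "missense_ptv_conserved"],
               0.045 + 0.0675 + 0.1, tolerance = 1e-12)
  # per-cohort breakdown sums to the total
  expect_equal(mc$obs_DD + mc$obs_ASD, mc$observed)
  # zero observed everywhere -> all p = 1
  res0 <- family_burden_test(exps, dnms[0, ], memb, tracks, cfg)
  expect_true(all(res0$p_value == 1))
  expect_false(any(res0$significant))
  # family-less genes are reported, not dropped silently
  dnms2 <- rbind(dnms, within(dnms[1, ], gene <- "ZZ"))
  expect_warning(res2 <- family_burden_test(exps, dnms2, memb, tracks, cfg),
                 "without family")
  expect_equal(nrow(attr(res2, "unassigned")), 1L)
})

test_that("class_zscore_comparison matches exact enumeration and behaves", {
  ex <- class_zscore_comparison(c(1, 2, 3), c(4, 5, 6))
  expect_equal(ex$statistic, 0)
  expect_equal(ex$p_value, 0.1)  # 2/20 orderings as extreme
  expect_equal(ex$method, "exact")
  same <- class_zscore_comparison(c(1, 2, 3, 4), c(1, 2, 3, 4))
  expect_equal(same$p_value, 1, tolerance = 1e-12)
  # random small samples vs enumeration oracle
  set.seed(47)
  for (i in 1:25) {
    za <- round(stats::rnorm(sample(2:6, 1)), 3)
    zb <- round(stats::rnorm(sample(2:6, 1)), 3)
    if (anyDuplicated(c(za, zb))) next
    got <- class_zscore_comparison(za, zb)
    expect_equal(got$p_value, oracle_wilcoxon_exact(za, zb),
                 tolerance = 1e-12, info = i)
  }
  # p decreases monotonically with shift for large samples
  set.seed(48)
  base <- stats::rnorm(60)
  ps <- vapply(c(0, 0.3, 0.8, 1.5), function(sh)
    class_zscore_comparison(base + sh, base)$p_value, 0)
  expect_true(all(diff(ps) < 0))
  expect_error(class_zscore_comparison(numeric(0), 1), "non-empty")
})

test_that("flag_candidate_genes applies the brain-expression and constraint rules", {
  ann <- data.frame(
    gene_id = c("a", "b", "c", "d", "e"),
    brain_rpkm = c(2, 1.0, 5, 3, NA),
    pli = c(0.95, 0.99, 0.9, 0.1, 0.95),
    missense_constraint_z = c(1.0, 5, 0, 3.10, 2),
    stringsAsFactors = FALSE)
  out <- flag_candidate_genes(ann, TRUE, TRUE)
  expect_true(out$candidate[1])      # pLI branch
  expect_false(out$candidate[2])     # rpkm == 1 is not brain-expressed
  expect_true(out$candidate[3])      # pLI == 0.9 exactly qualifies
  expect_true(out$candidate[4])      # missense z 3.10 > 3.09
  expect_true(is.na(out$candidate[5]))  # missing rpkm -> not evaluable
  out2 <- flag_candidate_genes(ann[1, , drop = FALSE], FALSE, TRUE)
  expect_false(out2$candidate)
})
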