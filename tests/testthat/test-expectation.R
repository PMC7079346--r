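test_that("rate tables validate completeness and support fallbacks", {
  expect_error(rate_table(c("ACA>G" = 1e-8)), "incomplete")
  rt <- uniform_rate_table(2e-8)
  expect_length(rt, 192L)
  expect_true(all(rt == 2e-8))
  expect_error(rate_table(c("ACA>G" = -1)), "negative")
  tmp <- tempfile(fileext = ".tsv")
  write_rate_table(rt, tmp)
  back <- read_rate_table(tmp)
  expect_equal(unclass(back), unclass(rt))
})

test_that("classify_substitution uses the standard code", {
  expect_equal(classify_substitution("ATGTGGTAA", 5, "A"), "nonsense")
  expect_equal(classify_substitution("ATGCTGTAA", 6, "A"), "synonymous")
  expect_equal(classify_substitution("ATGCTGTAA", 5, "A"), "missense") # CTG->CAG
  expect_equal(classify_substitution("ATGTAA", 5, "T"), "stoploss")    # TAA->TTA
  expect_equal(classify_substitution("ATGTAA", 6, "G"), "stop_retained")
  expect_error(classify_substitution("ATGTAA", 4, "T"), "alt equals")
  expect_error(classify_substitution("ATGTAA", 9, "A"), "out of range")
  expect_error(classify_substitution("ATGTAA", 2, "U"), "ACGT")
  # spot check against independent codon-table comparison
  set.seed(31)
  tab <- paralogr:::codon_table()
  for (i in 1:50) {
    cds <- paste(sample(c("A", "C", "G", "T"), 9, TRUE), collapse = "")
    pos <- sample(9, 1)
    ref <- substr(cds, pos, pos)
    alt <- sample(setdiff(c("A", "C", "G", "T"), ref), 1)
    ci <- (pos - 1) %/% 3
    codon <- substr(cds, ci * 3 + 1, ci * 3 + 3)
    mut <- codon; substr(mut, (pos - 1) %% 3 + 1, (pos - 1) %% 3 + 1) <- alt
    want <- if (tab[[codon]] == "*") {
      if (tab[[mut]] == "*") "stop_retained" else "stoploss"
    } else if (tab[[mut]] == "*") "nonsense"
    else if (tab[[mut]] == tab[[codon]]) "synonymous" else "missense"
    expect_equal(classify_substitution(cds, pos, alt), want)
  }
})

test_that("gene_expectation enumerates substitutions correctly", {
  # single codon ATG (Met): all 9 substitutions are missense under the
  # standard code (no single change reaches a stop or stays Met)
  g <- gene_record("TOY1", "M", "ATG")
  rt <- uniform_rate_table(1e-8)
  e <- suppressMessages(gene_expectation(g, rt, 1000,
                                         frameshift_mult = 0))
  expect_equal(e$lambda[["missense"]], 2 * 1000 * 9e-8, tolerance = 1e-12)
  expect_equal(e$lambda[["synonymous"]], 0)
  expect_equal(e$lambda[["nonsense"]], 0)

  # all-zero rate table -> every lambda 0
  e0 <- suppressMessages(gene_expectation(g, uniform_rate_table(0), 1000))
  expect_true(all(e0$lambda[c("synonymous", "missense", "nonsense",
                              "frameshift", "ptv")] == 0))

  # reference stop codon is excluded from syn/mis/nonsense buckets
  g2 <- gene_record("TOY2", "M", "ATGTAA")
  e2 <- suppressMessages(gene_expectation(g2, rt, 1000))
  expect_gt(e2$lambda[["stoploss"]], 0)
  # TAA positions contribute nothing to missense/nonsense
  expect_equal(e2$lambda[["missense"]], e$lambda[["missense"]],
               tolerance = 1e-12)
})

test_that("expectation model satisfies its scaling and partition invariants", {
  sim <- toy_family()
  tracks <- score_subfamily(sim$msa)
  rt <- simulate_rate_table(seed = 3)
  g <- names(sim$family$members)[[1]]
  rec <- sim$family$members[[g]]
  e1 <- suppressMessages(gene_expectation(rec, rt, 1000,
                                          track = tracks[[g]]))
  # linearity in trios
  e2 <- suppressMessages(gene_expectation(rec, rt, 2000,
                                          track = tracks[[g]]))
  expect_equal(e2$lambda, 2 * e1$lambda, tolerance = 1e-12)
  # scaling the rate table scales every lambda
  rt3 <- rate_table(stats::setNames(3 * as.numeric(rt), names(rt)))
  e3 <- suppressMessages(gene_expectation(rec, rt3, 1000,
                                          track = tracks[[g]]))
  expect_equal(e3$lambda, 3 * e1$lambda, tolerance = 1e-12)
  # conservation partition in both modes
  for (mode in c("proportional", "per_site")) {
    e <- suppressMessages(gene_expectation(rec, rt, 1000,
                                           track = tracks[[g]],
                                           split_mode = mode))
    expect_equal(e$lambda[["missense_conserved"]] +
                   e$lambda[["missense_nonconserved"]],
                 e$lambda[["missense"]], tolerance = 1e-12)
  }
  # proportional ratio is exactly c/n
  eprop <- suppressMessages(gene_expectation(rec, rt, 1000,
                                             track = tracks[[g]]))
  n_cons <- sum(tracks[[g]]$track$conserved)
  n <- nrow(tracks[[g]]$track)
  expect_equal(eprop$lambda[["missense_conserved"]] /
                 eprop$lambda[["missense"]], n_cons / n, tolerance = 1e-12)
  # per-site and proportional agree exactly when per-residue missense rate
  # mass is uniform: identical codons throughout plus a uniform rate table
  mono <- gene_record("MONO", "MMMMM", "ATGATGATGATGATGTAA")
  mono_tr <- track_from_flags(c(TRUE, FALSE, TRUE, FALSE, TRUE), "MONO")
  eu1 <- suppressMessages(gene_expectation(mono, uniform_rate_table(1e-8),
                                           1000, track = mono_tr,
                                           split_mode = "proportional"))
  eu2 <- suppressMessages(gene_expectation(mono, uniform_rate_table(1e-8),
                                           1000, track = mono_tr,
                                           split_mode = "per_site"))
  expect_equal(eu1$lambda[["missense_conserved"]],
               eu2$lambda[["missense_conserved"]], tolerance = 1e-12)
  # ptv = nonsense + frameshift, frameshift = 1.25 x nonsense by default
  expect_equal(e1$lambda[["frameshift"]], 1.25 * e1$lambda[["nonsense"]])
  expect_equal(e1$lambda[["ptv"]],
               e1$lambda[["nonsense"]] + e1$lambda[["frameshift"]])
})

test_that("family_expectation sums members and rejects duplicates", {
  df <- data.frame(gene_id = c("a", "b"), missense = c(0.5, 0.25),
                   ptv = c(0.1, 0.2), missense_conserved = c(0.3, 0.1),
                   missense_nonconserved = c(0.2, 0.15))
  fe <- family_expectation(df)
  expect_equal(fe$totals[["missense"]], 0.75)
  expect_equal(fe$totals[["ptv"]], 0.3)
  single <- family_expectation(df[1, ])
  expect_equal(single$totals[["missense"]], 0.5)
  expect_error(family_expectation(rbind(df, df[1, ])), "duplicate")
  # brute-force summation oracle on random members
  set.seed(37)
  k <- 7
  rdf <- data.frame(gene_id = paste0("g", 1:k),
                    missense = stats::runif(k), ptv = stats::runif(k))
  fe2 <- family_expectation(rdf)
  expect_equal(fe2$totals[["missense"]], sum(rdf$missense))
  expect_equal(fe2$totals[["ptv"]], sum(rdf$ptv))
})

test_that("expectation TSV round-trips through write/read", {
  sim <- toy_family()
  tracks <- score_subfamily(sim$msa)
  rt <- uniform_rate_table(1e-8)
  exps <- suppressMessages(lapply(names(sim$family$members), function(g)
    gene_expectation(sim$family$members[[g]], rt, 500,
                     track = tracks[[g]])))
  tmp <- tempfile(fileext = ".tsv")
  write_expectations(exps, tmp)
  back <- read_expectations(tmp)
  expect_equal(back$gene_id, names(sim$family$members))
  expect_equal(back$missense, expectation_df(exps)$missense,
               tolerance = 1e-9)
})
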