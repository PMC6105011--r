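test_that("hypergeom_tail matches closed forms", {
  expect_equal(hypergeom_tail(0, 3, 2, 10, "enrich"), 1)
  expect_equal(hypergeom_tail(4, 4, 5, 10, "enrich"), 5 / 210,
               tolerance = 1e-12)
  expect_equal(hypergeom_tail(4, 4, 4, 4, "enrich"), 1)
  expect_error(hypergeom_tail(5, 4, 5, 10), "invalid")
  expect_error(hypergeom_tail(2, 4, 5, 4), "invalid")
})

test_that("tails share the observed term and match phyper", {
  set.seed(47)
  for (rep in 1:50) {
    N <- sample(2:60, 1); K <- sample(0:N, 1); n <- sample(0:N, 1)
    lo <- max(0, n - (N - K)); hi <- min(n, K)
    k <- sample(lo:hi, 1)
    pe <- hypergeom_tail(k, n, K, N, "enrich")
    pd <- hypergeom_tail(k, n, K, N, "deplete")
    expect_equal(pe + pd - dhyper(k, K, N - K, n), 1, tolerance = 1e-9)
    expect_equal(pe, phyper(k - 1, K, N - K, n, lower.tail = FALSE),
                 tolerance = 1e-9)
    expect_equal(pd, phyper(k, K, N - K, n), tolerance = 1e-9)
  }
})

test_that("log-space tails survive extreme magnitudes", {
  l10 <- hypergeom_tail(500, 500, 500, 5000, "enrich", log10 = TRUE)
  expect_lt(l10, -700) # far below double underflow as a raw probability
  expect_true(is.finite(l10))
})

test_that("bonferroni_threshold divides alpha by the family size", {
  expect_equal(bonferroni_threshold(0.05, 5), 0.01)
  expect_equal(bonferroni_threshold(0.05, 1), 0.05)
  expect_equal(bonferroni_threshold(0.05, 7), 0.05 / 7)
  expect_equal(round(bonferroni_threshold(0.05, 7), 4), 0.0071)
  expect_error(bonferroni_threshold(0.05, 0), "family size")
})

test_that("run_test materialises counts from selectors", {
  # 10 K residues, 5 ordered; 4 MAU-modified, all in ordered
  u <- data.frame(protein_id = "p", position = 1:10, residue = "K",
                  region = rep(c("ordered", "disordered"), each = 5),
                  mau = c(rep(TRUE, 4), rep(FALSE, 6)),
                  stringsAsFactors = FALSE)
  spec <- test_spec("region_pref",
                    population = list(residue = "K",
                                      region = c("ordered",
                                                 "disordered")),
                    sample = list(region = "ordered"),
                    success = list(mau = TRUE), direction = "enrich")
  r <- run_test(spec, u)
  expect_equal(c(r$k, r$n, r$K, r$N), c(4L, 5L, 4L, 10L))
  expect_equal(r$p_enrich, 6 / 252, tolerance = 1e-12)

  # sampling everything: P(enrich) = 1
  spec_all <- test_spec("all", population = list(residue = "K"),
                        sample = list(), success = list(mau = TRUE))
  expect_equal(run_test(spec_all, u)$p_enrich, 1)

  bad <- test_spec("none", population = list(region = "zzz"),
                   sample = list(), success = list(mau = TRUE))
  expect_error(run_test(bad, u), "empty population")
})

test_that("conserved_mau_enrichment builds the clade-level test", {
  h <- tiny_hierarchy()
  prot <- protein_set("p1", strrep("K", 10))
  ann <- annotate_proteins(prot, NULL,
                           list(p1 = rep(0.9, 10)))
  sites <- ptm_sites("p1", c(1, 2, 3), "K", "acetylation", prot)
  # orthologs conserve sites 1-3 plus background residue 4 at Apes only
  rows <- c(pan = paste0("KKKK", strrep("A", 6)))
  aln <- family_alignment("p1", strrep("K", 10), rows)
  map <- data.frame(protein_id = "p1", species = "pan",
                    subject_id = "x", stringsAsFactors = FALSE)
  calls <- residue_conservation(list(p1 = aln), h, letters = "K")
  r <- conserved_mau_enrichment(calls, sites, ann, map, h, "Apes",
                                "disordered", "acetylation")
  expect_equal(c(r$k, r$n, r$K, r$N), c(3L, 4L, 3L, 10L))
  expect_equal(r$p_enrich,
               oracle_hyper_tail(3, 4, 3, 10, "enrich"),
               tolerance = 1e-12)
  # k = n boundary: every conserved residue is a site
  r2 <- conserved_mau_enrichment(calls, ptm_sites("p1", 1:4, "K",
                                                  "acetylation", prot),
                                 ann, map, h, "Apes", "disordered",
                                 "acetylation")
  expect_equal(r2$k, r2$n)
  # a single ortholog row is counted at every level it belongs to:
  # conservation carries out to Mammals here
  r3 <- conserved_mau_enrichment(calls, sites, ann, map, h, "Mammals",
                                 "disordered", "acetylation")
  expect_equal(r3$n, 4L)
  # empty population (no histone proteins) -> n = 0, warning, no call
  expect_warning(
    r4 <- conserved_mau_enrichment(calls, sites, ann, map, h,
                                   "Apes", "disordered", "acetylation",
                                   protein_subset = "histone"),
    "no")
  expect_equal(r4$call, "not_significant")
})

test_that("multi_mau venn counts are disjoint and complete", {
  fx <- tiny_universe()
  mm <- multi_mau(fx$sites, fx$annotations)
  # p1 pos 2 (A only), p1 pos 8 (U only), p2 pos 5 (A+U)
  expect_equal(sum(mm$venn$count), 3)
  expect_equal(mm$venn$count[mm$venn$types == "AU"], 1)
  expect_equal(nrow(mm$multi_sites), 1)
  expect_equal(mm$multi_sites$position, 5)
  # one PTM only -> not multi
  expect_false(2 %in% mm$multi_sites$position)
  # three types at one residue land in the MAU cell only
  s3 <- ptm_sites(rep("p1", 3), rep(2, 3), "K",
                  c("methylation", "acetylation", "ubiquitination"))
  mm3 <- multi_mau(s3, fx$annotations)
  expect_equal(mm3$venn$types, "AMU")
  expect_equal(mm3$venn$count, 1)
})

test_that("percentage_summary formats counts like the published table", {
  counts <- data.frame(
    category = c("all_mau", "methylation_K"),
    region = "ordered",
    n_conserved = c(393, 18), n_total = c(91535, 356),
    n_proteins_conserved = c(270, 11), n_proteins = c(3719, 230))
  out <- percentage_summary(counts)
  expect_equal(out$pct_conserved, c("0.43%", "5.06%"))
  expect_equal(out$pct_proteins, c("7.26%", "4.78%"))
  expect_equal(format_percent(0, 100), "0.00%")
  expect_equal(format_percent(1, 0), "NA")
})

test_that("residue_universe flags are consistent with inputs", {
  fx <- tiny_universe()
  u <- fx$universe
  expect_equal(nrow(u), sum(nchar(fx$proteins$residues)))
  expect_true(u$acetylation[u$protein_id == "p1" & u$position == 2])
  expect_true(all(u$mau == (u$methylation | u$acetylation |
                              u$ubiquitination)))
  expect_true(u$multi_mau[u$protein_id == "p2" & u$position == 5])
  expect_equal(sum(u$multi_mau), 1)
})
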