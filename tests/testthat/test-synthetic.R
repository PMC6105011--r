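test_that("generate_hierarchy builds strictly nested synthetic clades", {
  p <- generator_params(seed = 1,
                        n_species_per_level = c(2, 3, 4, 5, 6, 7, 8, 9,
                                                10, 11, 12))
  h <- generate_hierarchy(p)
  expect_equal(length(h$levels), 11)
  expect_equal(length(h$levels[[11]]), 12)
  expect_true(all(vapply(h$levels, function(s)
    "homo_sapiens" %in% s, logical(1))))
  # equal counts violate strict nesting and are rejected up front
  expect_error(generator_params(n_species_per_level = rep(5, 11)),
               "strictly increasing")
  # determinism
  expect_identical(generate_hierarchy(p), generate_hierarchy(p))
})

test_that("generated conservation truth is nested and deterministic", {
  # full ortholog presence: every level has rows, so truth must be a
  # TRUE-prefix over levels (once broken, stays broken outward)
  p <- generator_params(seed = 5, n_proteins = 6, ortholog_presence = 1)
  h <- generate_hierarchy(p)
  f1 <- generate_family(p, 3, h)
  f2 <- generate_family(p, 3, h)
  expect_identical(f1, f2) # same seed, same family
  f3 <- generate_family(generator_params(seed = 6, n_proteins = 6), 3,
                        generate_hierarchy(generator_params(seed = 6)))
  expect_false(identical(f1$sequence, f3$sequence))
  tr <- f1$truth
  lev <- names(h$levels)
  expect_gt(nrow(tr), 0)
  for (pp in unique(tr$position)) {
    rows <- tr[tr$position == pp, ]
    v <- rows$conserved[match(lev, rows$level)]
    expect_true(all(diff(as.integer(v)) <= 0))
  }
})

test_that("saturated conservation: p_site = 1, no gaps", {
  p <- generator_params(seed = 9, n_proteins = 4, p_conserve_site = 1,
                        gap_rate = 0, ortholog_presence = 1)
  h <- generate_hierarchy(p)
  for (i in 1:4) {
    f <- generate_family(p, i, h)
    expect_true(all(f$truth$conserved))
    expect_false(any(f$truth$newly_emerged))
  }
})

test_that("a conservation break at one level creates new sites below it", {
  # sites survive levels 1..4 and break at level 5: truth is conserved
  # at levels 1-4 and newly emerged exactly at level 4
  ps <- rep(1, 11); ps[5] <- 0
  p <- generator_params(seed = 10, n_proteins = 4, p_conserve_site = ps,
                        gap_rate = 0, ortholog_presence = 1)
  h <- generate_hierarchy(p)
  lev <- names(h$levels)
  for (i in 1:4) {
    f <- generate_family(p, i, h)
    if (nrow(f$truth) == 0) next
    tr <- f$truth
    expect_true(all(tr$conserved[tr$level %in% lev[1:4]]))
    expect_false(any(tr$conserved[tr$level %in% lev[5:11]]))
    expect_true(all(tr$newly_emerged[tr$level == lev[4]]))
    expect_false(any(tr$newly_emerged[tr$level != lev[4]]))
    # the pipeline's caller agrees with the generated truth
    calls <- call_conservation(f$alignment, unique(tr$position), h)
    key <- paste(calls$position, calls$level)
    tkey <- paste(tr$position, tr$level)
    expect_equal(tr$conserved, calls$conserved[match(tkey, key)])
    expect_equal(tr$newly_emerged,
                 calls$newly_emerged[match(tkey, key)])
  }
})

test_that("bundles are complete, readable and seed-deterministic", {
  d1 <- withr::local_tempdir()
  d2 <- withr::local_tempdir()
  d3 <- withr::local_tempdir()
  p <- generator_params(seed = 21, n_proteins = 8,
                        length_range = c(80, 120))
  b <- generate_bundle(p, d1)
  generate_bundle(p, d2)
  generate_bundle(generator_params(seed = 22, n_proteins = 8,
                                   length_range = c(80, 120)), d3)
  # every emitted file is readable by its own reader
  prot <- read_fasta(file.path(d1, "proteins.fasta"))
  expect_equal(prot$residues, b$proteins$residues)
  sites <- read_ptm_sites(file.path(d1, "sites.tsv"), prot)
  expect_equal(nrow(sites), nrow(b$sites))
  h <- read_clade_config(file.path(d1, "clades.yaml"))
  expect_equal(names(h$levels), names(b$hierarchy$levels))
  iv <- read_bed_intervals(file.path(d1, "ordered.bed"), prot)
  expect_equal(nrow(iv), nrow(b$ordered_intervals))
  afa <- list.files(file.path(d1, "alignments"), full.names = TRUE)
  expect_equal(length(afa), 8)
  a1 <- read_alignment(afa[1])
  expect_equal(human_sequence(a1), prot$residues[1])
  # same seed -> byte-identical; different seed -> different
  files <- list.files(d1, recursive = TRUE)
  expect_equal(files, list.files(d2, recursive = TRUE))
  for (f in files)
    expect_identical(unname(tools::md5sum(file.path(d1, f))),
                     unname(tools::md5sum(file.path(d2, f))),
                     label = f)
  expect_false(identical(
    unname(tools::md5sum(file.path(d1, "proteins.fasta"))),
    unname(tools::md5sum(file.path(d3, "proteins.fasta")))))
})

test_that("zero PTM density yields an empty site table but a live bundle", {
  p <- generator_params(seed = 31, n_proteins = 3,
                        ptm_density = c(methylation = 0,
                                        acetylation = 0,
                                        ubiquitination = 0))
  b <- generate_bundle(p)
  expect_equal(nrow(b$sites), 0)
  expect_equal(nrow(b$truth), 0)
  ann <- annotate_proteins(b$proteins, b$ordered_intervals,
                           b$disorder_scores)
  tab <- conserved_site_table(b$sites, b$alignments, b$hierarchy, ann,
                              b$ortholog_map)
  expect_equal(nrow(tab), 0)
})

test_that("RBH on emitted hit tables recovers the presence truth", {
  d <- withr::local_tempdir()
  p <- generator_params(seed = 41, n_proteins = 5,
                        length_range = c(60, 90))
  b <- generate_bundle(p, d)
  sp <- unique(b$ortholog_map$species)[1]
  fwd <- read_hit_table(file.path(d, "hits", paste0(sp, "_fwd.tsv")))
  bwd <- read_hit_table(file.path(d, "hits", paste0(sp, "_bwd.tsv")))
  r <- reciprocal_best_hits(fwd, bwd)
  truth <- b$ortholog_map[b$ortholog_map$species == sp, ]
  expect_setequal(paste(r$protein_id, r$subject_id),
                  paste(truth$protein_id, truth$subject_id))
})
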