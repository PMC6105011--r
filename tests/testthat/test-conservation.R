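test_that("position_to_column skips gaps and range-checks", {
  a <- family_alignment("p1", "M-KR", c(s1 = "MQKR"))
  expect_equal(position_to_column(a, 2), 3)
  expect_equal(position_to_column(a, 1), 1)
  expect_error(position_to_column(a, 4), "outside")
})

test_that("column_conserved handles strict, class and gap cases", {
  a <- family_alignment("p1", "K", c(s1 = "K", s2 = "K"))
  expect_true(column_conserved(a, 1, c("s1", "s2")))

  b <- family_alignment("p1", "K", c(s1 = "K", s2 = "R"))
  expect_false(column_conserved(b, 1, c("s1", "s2"), mode = "strict"))
  expect_true(column_conserved(b, 1, c("s1", "s2"),
                               residue_class = residue_classes$METHYL,
                               mode = "class"))

  g <- family_alignment("p1", "K", c(s1 = "K", s2 = "-"))
  expect_false(column_conserved(g, 1, c("s1", "s2"), mode = "strict"))
  expect_false(column_conserved(g, 1, c("s1", "s2"),
                                residue_class = residue_classes$METHYL,
                                mode = "class"))
  # no ortholog row from the subset present -> FALSE
  expect_false(column_conserved(a, 1, "s99"))
})

test_that("newly emerged follows the adjacent-wider-level truth table", {
  # conserved in Apes and Primates but broken from Supraprimates out:
  # Primates is newly emerged, Apes is not
  h <- tiny_hierarchy()
  a <- family_alignment("p1", "K",
                        c(pan = "K", macaca = "K", mus = "R", bos = "R"))
  calls <- call_conservation(a, 1, h)
  expect_equal(calls$conserved, c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(calls$newly_emerged, c(FALSE, TRUE, FALSE, FALSE))

  # conserved everywhere -> never newly emerged (outermost always FALSE)
  a2 <- family_alignment("p1", "K",
                         c(pan = "K", macaca = "K", mus = "K", bos = "K"))
  expect_false(any(call_conservation(a2, 1, h)$newly_emerged))

  # conserved nowhere -> all FALSE
  a3 <- family_alignment("p1", "K",
                         c(pan = "R", macaca = "R", mus = "R", bos = "R"))
  c3 <- call_conservation(a3, 1, h)
  expect_false(any(c3$conserved))
  expect_false(any(c3$newly_emerged))
})

test_that("apply_column_mask retains the configured score range", {
  m <- apply_column_mask(c(2, 5, 10))
  expect_equal(m$retained, c(FALSE, TRUE, TRUE))
  expect_true(all(apply_column_mask(c(2, 5, 10), 0, 10)$retained))
  expect_error(apply_column_mask(c(5, 11)), "\\[0, 10\\]")
})

test_that("masking only ever removes conservation", {
  set.seed(31)
  for (rep in 1:20) {
    cs <- random_alignment_case()
    nc <- cs$alignment$n_columns
    mask <- apply_column_mask(sample(0:10, nc, TRUE))
    pos <- sample(length(cs$alignment$pos2col), 1)
    un <- call_conservation(cs$alignment, pos, cs$hierarchy)
    ma <- call_conservation(cs$alignment, pos, cs$hierarchy, mask = mask)
    expect_true(all(ma$conserved <= un$conserved))
    col <- position_to_column(cs$alignment, pos)
    if (!mask$retained[col]) {
      expect_false(any(ma$conserved))
      expect_true(all(ma$masked))
    } else {
      expect_equal(ma$conserved, un$conserved)
    }
  }
})

test_that("nesting: conservation at a wider level implies it at narrower", {
  set.seed(37)
  for (rep in 1:60) {
    cs <- random_alignment_case()
    cc <- conserved_columns(cs$alignment, cs$hierarchy)$conserved
    nlev <- nrow(cc)
    # a level's species are a subset of the next level's species only
    # when every species in the level has a row; with identical rows the
    # implication holds column-wise
    for (i in seq_len(nlev - 1))
      expect_true(all(!cc[i + 1, ] | cc[i, ]))
  }
})

test_that("strict conservation implies class conservation (human in class)", {
  set.seed(41)
  cls <- residue_class("METHYL", c("K", "R"))
  for (rep in 1:20) {
    cs <- random_alignment_case()
    st <- conserved_columns(cs$alignment, cs$hierarchy, "strict")$conserved
    cl <- conserved_columns(cs$alignment, cs$hierarchy, "class",
                            residue_class = cls)$conserved
    hch <- strsplit(cs$alignment$human_row, "")[[1]]
    in_class <- matrix(hch %in% cls, nrow = nrow(st), ncol = ncol(st),
                       byrow = TRUE)
    expect_true(all(!(st & in_class) | cl))
  }
})

test_that("site_categories expands methylation letters, all/multi MAU", {
  s <- ptm_sites(c("p1", "p1", "p1", "p1"),
                 c(1, 1, 5, 9), c("K", "K", "R", "K"),
                 c("acetylation", "ubiquitination", "methylation",
                   "phosphorylation"))
  cats <- site_categories(s)
  expect_setequal(
    cats$category[cats$position == 1],
    c("acetylation", "ubiquitination", "all_mau", "multi_mau"))
  expect_setequal(cats$category[cats$position == 5],
                  c("methylation_R", "all_mau"))
  expect_equal(cats$category[cats$position == 9], "phosphorylation")
})

test_that("conserved_site_table matches a brute-force recount", {
  set.seed(43)
  h <- tiny_hierarchy()
  prot <- protein_set("p1", "MKKRKA")
  ann <- annotate_proteins(
    prot, ordered_intervals = data.frame(protein_id = "p1",
                                         start = 1, end = 3),
    disorder_scores = list(p1 = c(0, 0, 0, 0.9, 0.9, 0.9)))
  sites <- ptm_sites(c("p1", "p1"), c(2, 5), c("K", "K"),
                     c("acetylation", "acetylation"), prot)
  aln <- family_alignment("p1", "MKKRKA",
                          c(pan = "MKKRKA", mus = "MKARKA",
                            bos = "MKARRA"))
  map <- data.frame(protein_id = "p1",
                    species = c("pan", "mus", "bos"),
                    subject_id = "x", stringsAsFactors = FALSE)
  tab <- conserved_site_table(sites, list(p1 = aln), h, ann, map)
  # brute force: site pos 2 (ordered) conserved at all four levels;
  # site pos 5 (disordered) broken in bos -> conserved up to Supraprimates
  for (lev in names(h$levels)) {
    o <- tab[tab$level == lev & tab$region == "ordered" &
               tab$category == "acetylation" & tab$subset == "all", ]
    d <- tab[tab$level == lev & tab$region == "disordered" &
               tab$category == "acetylation" & tab$subset == "all", ]
    oc <- oracle_conservation(aln, 2, h)
    dc <- oracle_conservation(aln, 5, h)
    i <- match(lev, names(h$levels))
    expect_equal(o$n_conserved, as.integer(oc$conserved[i]))
    expect_equal(d$n_conserved, as.integer(dc$conserved[i]))
    expect_equal(d$n_new, as.integer(dc$newly_emerged[i]))
  }
  expect_equal(nrow(conserved_site_table(sites[0, ], list(p1 = aln), h,
                                         ann, map)), 0)
})
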