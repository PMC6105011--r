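hit <- function(q, s, e, b = 100) {
  data.frame(query_id = q, subject_id = s, evalue = e, bitscore = b,
             stringsAsFactors = FALSE)
}

test_that("reciprocal_best_hits applies mutual-best and e-value rules", {
  r <- reciprocal_best_hits(hit("h1", "s1", 1e-50),
                            hit("s1", "h1", 1e-48))
  expect_equal(r$protein_id, "h1")
  expect_equal(r$subject_id, "s1")

  # not reciprocal: s1's best backward hit is h2
  r2 <- reciprocal_best_hits(
    hit("h1", "s1", 1e-50),
    rbind(hit("s1", "h2", 1e-60), hit("s1", "h1", 1e-48)))
  expect_equal(nrow(r2), 0)

  # fails the strict e-value threshold
  r3 <- reciprocal_best_hits(hit("h1", "s1", 1e-3),
                             hit("s1", "h1", 1e-3))
  expect_equal(nrow(r3), 0)
  # exactly at the threshold also fails (strict <)
  r4 <- reciprocal_best_hits(hit("h1", "s1", 1e-4),
                             hit("s1", "h1", 1e-4))
  expect_equal(nrow(r4), 0)
})

test_that("ties after (evalue, bitscore) yield no call; self-hits dropped", {
  fwd <- rbind(hit("h1", "s1", 1e-50, 200), hit("h1", "s2", 1e-50, 200))
  bwd <- rbind(hit("s1", "h1", 1e-50, 200), hit("s2", "h1", 1e-50, 200))
  expect_equal(nrow(reciprocal_best_hits(fwd, bwd)), 0)
  # bitscore breaks the evalue tie
  fwd2 <- rbind(hit("h1", "s1", 1e-50, 210), hit("h1", "s2", 1e-50, 200))
  expect_equal(reciprocal_best_hits(fwd2, bwd)$subject_id, "s1")
  # a self-hit never becomes a call
  fwd3 <- rbind(hit("h1", "h1", 0, 999), hit("h1", "s1", 1e-50, 200))
  expect_equal(reciprocal_best_hits(fwd3, bwd)$subject_id, "s1")
})

test_that("RBH symmetry: swapping tables inverts the mapping (property)", {
  set.seed(13)
  for (rep in 1:30) {
    nq <- sample(2:6, 1); ns <- sample(2:6, 1)
    fwd <- do.call(rbind, lapply(seq_len(nq * 2), function(i)
      hit(sprintf("h%d", sample(nq, 1)), sprintf("s%d", sample(ns, 1)),
          10^-sample(5:60, 1), sample(50:250, 1))))
    bwd <- do.call(rbind, lapply(seq_len(ns * 2), function(i)
      hit(sprintf("s%d", sample(ns, 1)), sprintf("h%d", sample(nq, 1)),
          10^-sample(5:60, 1), sample(50:250, 1))))
    ab <- reciprocal_best_hits(fwd, bwd)
    ba <- reciprocal_best_hits(bwd, fwd)
    expect_setequal(paste(ab$protein_id, ab$subject_id),
                    paste(ba$subject_id, ba$protein_id))
  }
})

test_that("clade inclusion follows the >=1-ortholog rule", {
  h <- tiny_hierarchy()
  map <- data.frame(protein_id = "h1", species = "mus",
                    subject_id = "x", stringsAsFactors = FALSE)
  expect_equal(clade_inclusion(map, h, "Supraprimates"), "h1")
  expect_equal(length(clade_inclusion(map, h, "Apes")), 0)
  empty <- map[0, ]
  for (lev in names(h$levels))
    expect_equal(length(clade_inclusion(empty, h, lev)), 0)
  expect_error(clade_inclusion(map, h, "Fungi"), "unknown")
})

test_that("inclusion is monotone across levels (property)", {
  set.seed(17)
  h <- tiny_hierarchy()
  all_sp <- setdiff(level_species(h, "Mammals"), h$reference)
  for (rep in 1:30) {
    n <- sample(0:12, 1)
    map <- if (n == 0) {
      data.frame(protein_id = character(0), species = character(0),
                 subject_id = character(0))
    } else {
      data.frame(protein_id = sprintf("h%d", sample(4, n, TRUE)),
                 species = sample(all_sp, n, TRUE),
                 subject_id = "x", stringsAsFactors = FALSE)
    }
    incs <- lapply(names(h$levels), function(l)
      clade_inclusion(map, h, l))
    for (i in seq_len(length(incs) - 1))
      expect_true(all(incs[[i]] %in% incs[[i + 1]]))
  }
})

test_that("protein age classes distinguish new from old", {
  h <- tiny_hierarchy()
  # orthologs only within Supraprimates -> new there
  map <- data.frame(protein_id = c("h1", "h1"),
                    species = c("pan", "mus"),
                    subject_id = "x", stringsAsFactors = FALSE)
  expect_equal(as.character(protein_age_class(map, h, "Supraprimates", "h1")),
               "new")
  # an ortholog beyond the level makes it old
  map2 <- rbind(map, data.frame(protein_id = "h1", species = "bos",
                                subject_id = "x"))
  expect_equal(as.character(protein_age_class(map2, h, "Supraprimates", "h1")),
               "old")
  # outermost level: vacuously new
  cls <- protein_age_class(map2, h, "Mammals", "h1")
  expect_equal(as.character(cls), "new")
  expect_true(isTRUE(attr(cls, "vacuous")))
  expect_error(protein_age_class(map, h, "Apes", "h2"), "not included")
})

test_that("age-class consistency under widening (brute force property)", {
  set.seed(23)
  h <- tiny_hierarchy()
  all_sp <- setdiff(level_species(h, "Mammals"), h$reference)
  for (rep in 1:25) {
    n <- sample(1:8, 1)
    map <- unique(data.frame(protein_id = "h1",
                             species = sample(all_sp, n, TRUE),
                             subject_id = "x", stringsAsFactors = FALSE))
    levs <- names(h$levels)
    for (i in seq_along(levs)) {
      if (!("h1" %in% clade_inclusion(map, h, levs[i]))) next
      if (as.character(protein_age_class(map, h, levs[i], "h1")) != "new") next
      # new at i means no ortholog outside level i; then at any wider
      # level j the protein is also new (its species remain inside)
      for (j in seq(i, length(levs))) {
        if (!("h1" %in% clade_inclusion(map, h, levs[j]))) next
        expect_equal(as.character(protein_age_class(map, h, levs[j], "h1")),
                     "new")
      }
    }
  }
})
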