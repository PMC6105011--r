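# Independent oracles and tiny fixture builders shared across tests.
# Oracles deliberately use a different computational route than the
# implementation (direct choose() ratios, explicit loops).

# exhaustive hypergeometric tail via binomial-coefficient ratios
oracle_hyper_tail <- function(k, n, K, N, direction) {
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  i <- lo:hi
  pmf <- choose(K, i) * choose(N - K, n - i) / choose(N, n)
  if (direction == "enrich") sum(pmf[i >= k]) else sum(pmf[i <= k])
}

# brute-force two-pass conservation oracle: pass 1 per-level loops,
# pass 2 newly-emerged from adjacent levels
oracle_conservation <- function(alignment, position, hierarchy,
                                mode = "strict", residue_class = NULL,
                                mask = NULL) {
  col <- alignment$pos2col[[position]]
  h <- substr(alignment$human_row, col, col)
  nlev <- length(hierarchy$levels)
  cons <- logical(nlev)
  for (i in seq_len(nlev)) {
    sp <- hierarchy$levels[[i]]
    rows <- alignment$ortholog_rows[names(alignment$ortholog_rows) %in% sp]
    if (length(rows) == 0) { cons[i] <- FALSE; next }
    ok <- TRUE
    for (r in rows) {
      ch <- substr(r, col, col)
      if (ch == "-") { ok <- FALSE; break }
      if (mode == "strict") {
        if (ch != h) { ok <- FALSE; break }
      } else {
        if (!(ch %in% residue_class)) { ok <- FALSE; break }
      }
    }
    if (mode == "class" && !(h %in% residue_class)) ok <- FALSE
    if (h == "-") ok <- FALSE
    cons[i] <- ok
  }
  if (!is.null(mask) && !mask$retained[col]) cons[] <- FALSE
  new <- logical(nlev)
  for (i in seq_len(nlev))
    new[i] <- cons[i] && (i == nlev || !cons[i + 1]) && i != nlev
  list(conserved = cons, newly_emerged = new)
}

# random small alignment + hierarchy for property tests
random_alignment_case <- function(n_cols = sample(5:50, 1),
                                  n_species = sample(1:5, 1),
                                  n_levels = sample(2:4, 1),
                                  gap_p = 0.1) {
  aas <- c("A", "K", "R", "Q", "S")
  human <- paste(sample(aas, n_cols, replace = TRUE), collapse = "")
  species <- sprintf("s%d", seq_len(n_species))
  rows <- vapply(species, function(s) {
    ch <- sample(c(aas, "-"), n_cols, replace = TRUE,
                 prob = c(rep((1 - gap_p) / 5, 5), gap_p))
    # bias toward matching human so conservation actually occurs
    hm <- strsplit(human, "")[[1]]
    match_it <- runif(n_cols) < 0.6
    ch[match_it] <- hm[match_it]
    paste(ch, collapse = "")
  }, character(1))
  aln <- family_alignment("px", human, rows)
  # nested levels over a random permutation of the species
  ord <- sample(species)
  cuts <- sort(sample(seq_len(n_species), n_levels - 1, replace = TRUE))
  sizes <- unique(c(cuts, n_species))
  levels <- lapply(sizes, function(m) c("homo_sapiens", ord[seq_len(m)]))
  names(levels) <- paste0("L", seq_along(levels))
  # enforce strict nesting by dropping duplicate sizes (done via unique)
  h <- tryCatch(clade_hierarchy(levels), error = function(e) NULL)
  if (is.null(h)) return(random_alignment_case(n_cols, n_species,
                                               n_levels, gap_p))
  list(alignment = aln, hierarchy = h)
}

tiny_hierarchy <- function() {
  clade_hierarchy(list(
    Apes = c("homo_sapiens", "pan"),
    Primates = c("homo_sapiens", "pan", "macaca"),
    Supraprimates = c("homo_sapiens", "pan", "macaca", "mus"),
    Mammals = c("homo_sapiens", "pan", "macaca", "mus", "bos")),
    reference = "homo_sapiens")
}

# small deterministic protein/annotation fixture for enrichment tests
tiny_universe <- function() {
  prot <- protein_set(c("p1", "p2"), c("MKKRKAAKDE", "KKQQKRSTKY"))
  ann <- annotate_proteins(
    prot,
    ordered_intervals = data.frame(protein_id = c("p1", "p2"),
                                   start = c(1L, 1L), end = c(5L, 4L)),
    disorder_scores = list(p1 = c(rep(0, 5), rep(0.9, 5)),
                           p2 = c(rep(0, 4), rep(0.9, 6))))
  sites <- ptm_sites(c("p1", "p1", "p2", "p2"),
                     c(2, 8, 5, 5), c("K", "K", "K", "K"),
                     c("acetylation", "ubiquitination",
                       "acetylation", "ubiquitination"),
                     proteins = prot)
  list(proteins = prot, annotations = ann, sites = sites,
       universe = residue_universe(prot, ann, sites))
}
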