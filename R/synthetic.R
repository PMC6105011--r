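# Deterministic truth-labelled synthetic bundles: nested clades,
# per-protein ortholog presence, alignments with controlled per-level
# conservation, PTM sites in ordered vs disordered spans.

#' Generator parameters
#'
#' Defaults describe the stated world the pipeline assumes, scaled to
#' desk size: an 11-level nested hierarchy (40 species standing in for
#' the study's 380), 50 proteins, ~40% disordered residues, K/R enriched
#' in disordered spans, per-level conservation probabilities applied
#' outward with "once broken, stays broken" so generated conservation is
#' nested by construction.
#'
#' @param seed integer; fully determines the bundle.
#' @param n_species_per_level cumulative species counts per level,
#'   innermost first, strictly increasing (reference included).
#' @param n_proteins number of reference proteins.
#' @param length_range inclusive protein length bounds.
#' @param fraction_disordered target disordered fraction per protein.
#' @param ptm_density expected sites per 100 residues, named by type.
#' @param p_conserve_site,p_conserve_background per-level survival
#'   probabilities of site vs background columns (length 1 or 11).
#' @param gap_rate per-cell gap probability in ortholog rows.
#' @param gap_avoid_sites if TRUE (default) gaps never land on site
#'   columns, so pipeline calls can be compared to truth exactly.
#' @param ortholog_presence per-level probability a species carries the
#'   gene (length 1 or number of levels).
#' @param fb_fraction,prion_fraction,histone_fraction per-protein
#'   probabilities of the corresponding flags.
#' @param kr_boost multiplicative weight for K/R in disordered spans.
#' @param ordered_coverage fraction of the non-disordered span backed by
#'   ordered intervals (the rest is unclassified).
#' @param background_freqs named amino-acid frequencies (default
#'   uniform).
#' @param reference reference species id.
#' @return A `generator_params` list.
#' @export
generator_params <- function(seed = 1,
                             n_species_per_level = c(3, 5, 8, 11, 14, 18,
                                                     22, 26, 30, 35, 40),
                             n_proteins = 50,
                             length_range = c(150, 300),
                             fraction_disordered = 0.4,
                             ptm_density = c(methylation = 0.4,
                                             acetylation = 0.7,
                                             ubiquitination = 1.0),
                             p_conserve_site = 0.9,
                             p_conserve_background = 0.5,
                             gap_rate = 0.02,
                             gap_avoid_sites = TRUE,
                             ortholog_presence = 0.9,
                             fb_fraction = 0.1,
                             prion_fraction = 0.06,
                             histone_fraction = 0.04,
                             kr_boost = 3,
                             ordered_coverage = 0.8,
                             background_freqs = NULL,
                             reference = "homo_sapiens") {
  nlev <- length(n_species_per_level)
  if (any(diff(n_species_per_level) <= 0))
    stop("n_species_per_level must be strictly increasing ",
         "(strict nesting required)")
  if (any(n_species_per_level < 2))
    stop("each level needs the reference plus at least one species")
  p <- list(seed = as.integer(seed),
            n_species_per_level = as.integer(n_species_per_level),
            n_proteins = as.integer(n_proteins),
            length_range = as.integer(length_range),
            fraction_disordered = fraction_disordered,
            ptm_density = ptm_density,
            p_conserve_site = rep_len(p_conserve_site, nlev),
            p_conserve_background = rep_len(p_conserve_background, nlev),
            gap_rate = gap_rate, gap_avoid_sites = gap_avoid_sites,
            ortholog_presence = rep_len(ortholog_presence, nlev),
            fb_fraction = fb_fraction, prion_fraction = prion_fraction,
            histone_fraction = histone_fraction, kr_boost = kr_boost,
            ordered_coverage = ordered_coverage,
            background_freqs = background_freqs %||%
              stats::setNames(rep(1 / 20, 20), AA20),
            reference = reference)
  probs <- c(p$p_conserve_site, p$p_conserve_background,
             p$ortholog_presence, p$gap_rate, p$fb_fraction,
             p$prion_fraction, p$histone_fraction, p$fraction_disordered)
  if (any(probs < 0 | probs > 1)) stop("probabilities must lie in [0, 1]")
  structure(p, class = "generator_params")
}

#' Generate the nested species hierarchy
#'
#' @param params a [generator_params()].
#' @return A [clade_hierarchy()] whose levels carry synthetic species
#'   ids; attribute `bands` maps each non-reference species to the
#'   innermost level index at which it appears.
#' @export
generate_hierarchy <- function(params) {
  counts <- params$n_species_per_level
  nlev <- min(length(counts), length(default_clade_names))
  n_other <- counts - 1L # reference excluded
  species <- sprintf("sp%03d", seq_len(n_other[nlev]))
  bands <- rep(seq_len(nlev), times = diff(c(0L, n_other)))
  names(bands) <- species
  levels <- lapply(seq_len(nlev), function(i)
    c(params$reference, species[seq_len(n_other[i])]))
  names(levels) <- default_clade_names[seq_len(nlev)]
  h <- clade_hierarchy(levels, reference = params$reference)
  attr(h, "bands") <- bands
  h
}

family_seed <- function(seed, protein_index) {
  (as.double(seed) * 100003 + protein_index * 7919) %% 2147483647
}

#' Generate one synthetic protein family
#'
#' Draws the human sequence (K/R boosted in a contiguous disordered
#' span), places PTM sites, then builds ortholog rows level-by-level
#' outward: each column survives level i with the site or background
#' probability, and once broken it stays broken at all wider levels, so
#' generated conservation is nested by construction. Gaps are inserted
#' at `gap_rate`, avoiding site columns when `gap_avoid_sites`.
#'
#' @param params a [generator_params()].
#' @param protein_index 1-based protein index (drives the per-family RNG
#'   stream).
#' @param hierarchy the hierarchy from [generate_hierarchy()].
#' @return List with elements `protein_id`, `sequence`, `sites`,
#'   `ordered_intervals`, `fb_interval` (or NULL), `disorder_scores`,
#'   `alignment`, `truth` (per site x level conserved / newly_emerged),
#'   `present_species`, `prion`, `histone`, `region_truth`.
#' @export
generate_family <- function(params, protein_index, hierarchy) {
  set.seed(family_seed(params$seed, protein_index))
  id <- sprintf("p%03d", protein_index)
  bands <- attr(hierarchy, "bands")
  nlev <- length(hierarchy$levels)
  L <- sample(params$length_range[1]:params$length_range[2], 1)

  len_d <- max(0L, round(params$fraction_disordered * L))
  d_start <- if (len_d > 0) sample(seq_len(L - len_d + 1), 1) else 0L
  d_end <- if (len_d > 0) d_start + len_d - 1L else -1L
  is_dis <- rep(FALSE, L)
  if (len_d > 0) is_dis[d_start:d_end] <- TRUE

  # residue draw: background composition, K/R boosted in disordered span
  w <- params$background_freqs[AA20]
  wb <- w; wb[c("K", "R")] <- wb[c("K", "R")] * params$kr_boost
  chars <- character(L)
  chars[!is_dis] <- sample(AA20, sum(!is_dis), replace = TRUE, prob = w)
  if (len_d > 0)
    chars[is_dis] <- sample(AA20, len_d, replace = TRUE, prob = wb)

  prion <- stats::runif(1) < params$prion_fraction && len_d >= 30
  if (prion) {
    qs <- sample(seq(d_start, d_end - 29L), 1)
    chars[qs:(qs + 29L)] <- "Q"
  }
  histone <- stats::runif(1) < params$histone_fraction
  seq_str <- paste(chars, collapse = "")

  # ordered intervals cover ordered_coverage of each non-disordered run
  ord <- ordered_runs(ifelse(is_dis, "disordered", "ordered"))
  oiv <- NULL
  for (j in seq_len(nrow(ord))) {
    w_len <- ord$end[j] - ord$start[j] + 1L
    keep <- floor(params$ordered_coverage * w_len)
    if (keep >= 1)
      oiv <- rbind(oiv, data.frame(protein_id = id, start = ord$start[j],
                                   end = ord$start[j] + keep - 1L,
                                   label = "ordered"))
  }
  if (is.null(oiv))
    oiv <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), label = character(0))
  in_ordered <- rep(FALSE, L)
  for (j in seq_len(nrow(oiv))) in_ordered[oiv$start[j]:oiv$end[j]] <- TRUE
  region_truth <- ifelse(in_ordered, "ordered",
                         ifelse(is_dis, "disordered", "unclassified"))

  disorder_scores <- ifelse(is_dis, 0.9, 0.05)

  # PTM sites per density; methylation draws from K/R, the rest from K
  site_rows <- NULL
  for (t in names(params$ptm_density)) {
    elig <- if (t == "methylation") which(chars %in% c("K", "R"))
            else which(chars == "K")
    n_t <- stats::rbinom(1, L, params$ptm_density[[t]] / 100)
    n_t <- min(n_t, length(elig))
    if (n_t > 0) {
      pos <- sort(sample(elig, n_t))
      site_rows <- rbind(site_rows,
                         data.frame(protein_id = id, position = pos,
                                    residue = chars[pos], ptm_type = t,
                                    stringsAsFactors = FALSE))
    }
  }
  if (is.null(site_rows))
    site_rows <- data.frame(protein_id = character(0),
                            position = integer(0), residue = character(0),
                            ptm_type = character(0),
                            stringsAsFactors = FALSE)
  site_cols <- sort(unique(site_rows$position))
  is_site_col <- seq_len(L) %in% site_cols

  # nested conservation truth: first level at which each column breaks
  broken_level <- rep(nlev + 1L, L)
  alive <- rep(TRUE, L)
  for (i in seq_len(nlev)) {
    p_col <- ifelse(is_site_col, params$p_conserve_site[i],
                    params$p_conserve_background[i])
    die <- alive & stats::runif(L) >= p_col
    broken_level[die] <- i
    alive <- alive & !die
  }
  alt <- vapply(chars, function(h) sample(setdiff(AA20, h), 1),
                character(1))

  rows <- character(0)
  present <- character(0)
  for (sp in names(bands)) {
    b <- bands[[sp]]
    if (stats::runif(1) >= params$ortholog_presence[b]) next
    rc <- ifelse(b < broken_level, chars, alt)
    g <- stats::runif(L) < params$gap_rate
    if (params$gap_avoid_sites) g <- g & !is_site_col
    rc[g] <- "-"
    rows[sp] <- paste(rc, collapse = "")
    present <- c(present, sp)
  }
  aln <- family_alignment(id, seq_str, rows)

  # effective truth from the emitted rows (presence and gaps included)
  truth <- NULL
  if (length(site_cols) > 0) {
    m <- if (length(rows) > 0) do.call(rbind, strsplit(unname(rows), ""))
         else matrix(character(0), nrow = 0, ncol = L)
    rownames(m) <- names(rows)
    cons <- matrix(FALSE, nrow = nlev, ncol = length(site_cols))
    for (i in seq_len(nlev)) {
      sel <- rownames(m) %in% hierarchy$levels[[i]]
      if (sum(sel) == 0) next
      sub <- m[sel, site_cols, drop = FALSE]
      hh <- chars[site_cols]
      cons[i, ] <- colSums(sub != rep(hh, each = nrow(sub))) == 0
    }
    wider <- rbind(cons[-1, , drop = FALSE],
                   matrix(TRUE, 1, length(site_cols)))
    truth <- data.frame(
      protein_id = id,
      position = rep(site_cols, each = nlev),
      level = rep(names(hierarchy$levels), times = length(site_cols)),
      conserved = as.vector(cons),
      newly_emerged = as.vector(cons & !wider),
      stringsAsFactors = FALSE)
  } else {
    truth <- data.frame(protein_id = character(0), position = integer(0),
                        level = character(0), conserved = logical(0),
                        newly_emerged = logical(0),
                        stringsAsFactors = FALSE)
  }

  fb_interval <- NULL
  if (stats::runif(1) < params$fb_fraction && len_d >= 9) {
    third <- len_d %/% 3
    fb_interval <- data.frame(protein_id = id,
                              start = d_start + third,
                              end = d_start + 2L * third,
                              label = "fb")
  }

  list(protein_id = id, sequence = seq_str, sites = site_rows,
       ordered_intervals = oiv, fb_interval = fb_interval,
       disorder_scores = disorder_scores, alignment = aln,
       truth = truth, present_species = present, prion = prion,
       histone = histone, region_truth = region_truth)
}

#' Generate a complete synthetic input bundle
#'
#' Builds the hierarchy and all families; when `out_dir` is given, every
#' external-interface file is written (FASTA, aligned FASTA per family,
#' site table, BED intervals, disorder scores, per-species forward and
#' backward hit tables, clade config, histone list, truth labels and a
#' manifest). Identical seeds give byte-identical bundles.
#'
#' @param params a [generator_params()].
#' @param out_dir output directory or NULL for in-memory only.
#' @return List: `params`, `hierarchy`, `proteins` (a `protein_set`),
#'   `sites`, `ordered_intervals`, `fb_intervals`, `disorder_scores`,
#'   `alignments`, `ortholog_map` (truth presence), `truth`,
#'   `histone_ids`, `prion_ids`, `region_truth`.
#' @export
generate_bundle <- function(params, out_dir = NULL) {
  hierarchy <- generate_hierarchy(params)
  fams <- lapply(seq_len(params$n_proteins), function(i)
    generate_family(params, i, hierarchy))
  ids <- vapply(fams, `[[`, character(1), "protein_id")
  proteins <- protein_set(ids, vapply(fams, `[[`, character(1),
                                      "sequence"),
                          species = params$reference)
  sites_df <- do.call(rbind, lapply(fams, `[[`, "sites"))
  sites <- ptm_sites(sites_df$protein_id, sites_df$position,
                     sites_df$residue, sites_df$ptm_type,
                     proteins = proteins)
  oiv <- do.call(rbind, lapply(fams, `[[`, "ordered_intervals"))
  fbs <- do.call(rbind, lapply(fams, `[[`, "fb_interval"))
  if (is.null(fbs))
    fbs <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), label = character(0))
  scores <- stats::setNames(lapply(fams, `[[`, "disorder_scores"), ids)
  alignments <- stats::setNames(lapply(fams, `[[`, "alignment"), ids)
  omap <- do.call(rbind, lapply(fams, function(f)
    if (length(f$present_species) > 0)
      data.frame(protein_id = f$protein_id, species = f$present_species,
                 subject_id = paste0(f$protein_id, "@",
                                     f$present_species),
                 stringsAsFactors = FALSE)
    else NULL))
  if (is.null(omap))
    omap <- data.frame(protein_id = character(0), species = character(0),
                       subject_id = character(0), stringsAsFactors = FALSE)
  truth <- do.call(rbind, lapply(fams, `[[`, "truth"))
  rownames(truth) <- NULL
  region_truth <- stats::setNames(lapply(fams, `[[`, "region_truth"), ids)
  bundle <- list(params = params, hierarchy = hierarchy,
                 proteins = proteins, sites = sites,
                 ordered_intervals = oiv, fb_intervals = fbs,
                 disorder_scores = scores, alignments = alignments,
                 ortholog_map = omap, truth = truth,
                 histone_ids = ids[vapply(fams, `[[`, logical(1),
                                          "histone")],
                 prion_ids = ids[vapply(fams, `[[`, logical(1), "prion")],
                 region_truth = region_truth)
  if (!is.null(out_dir)) write_bundle(bundle, out_dir)
  bundle
}

write_bundle <- function(bundle, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(file.path(out_dir, "alignments"), showWarnings = FALSE)
  dir.create(file.path(out_dir, "hits"), showWarnings = FALSE)
  write_fasta(bundle$proteins, file.path(out_dir, "proteins.fasta"))
  write_ptm_sites(bundle$sites, file.path(out_dir, "sites.tsv"))
  write_bed_intervals(bundle$ordered_intervals,
                      file.path(out_dir, "ordered.bed"))
  write_bed_intervals(bundle$fb_intervals, file.path(out_dir, "fb.bed"))
  write_disorder_scores(bundle$disorder_scores,
                        file.path(out_dir, "disorder_scores.tsv"))
  write_clade_config(bundle$hierarchy, file.path(out_dir, "clades.yaml"))
  writeLines(bundle$histone_ids, file.path(out_dir, "histones.txt"))
  for (id in names(bundle$alignments))
    write_alignment(bundle$alignments[[id]],
                    file.path(out_dir, "alignments",
                              paste0(id, ".afa")),
                    reference = bundle$params$reference)
  # hit tables: emitted as if post-similarity-search, RBH-consistent,
  # plus one decoy worse hit per pair to exercise best-hit selection
  omap <- bundle$ortholog_map
  for (sp in unique(omap$species)) {
    d <- omap[omap$species == sp, , drop = FALSE]
    fwd <- data.frame(query_id = rep(d$protein_id, each = 2),
                      subject_id = as.vector(rbind(d$subject_id,
                                                   paste0("decoy@", sp))),
                      evalue = rep(c(1e-50, 1e-10), nrow(d)),
                      bitscore = rep(c(200, 80), nrow(d)),
                      stringsAsFactors = FALSE)
    bwd <- data.frame(query_id = d$subject_id,
                      subject_id = d$protein_id,
                      evalue = 1e-48, bitscore = 195,
                      stringsAsFactors = FALSE)
    write_hit_table(fwd, file.path(out_dir, "hits",
                                   paste0(sp, "_fwd.tsv")))
    write_hit_table(bwd, file.path(out_dir, "hits",
                                   paste0(sp, "_bwd.tsv")))
  }
  utils::write.table(bundle$truth, file.path(out_dir, "truth.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  manifest <- unclass(bundle$params)
  manifest$background_freqs <- as.list(manifest$background_freqs)
  manifest$ptm_density <- as.list(manifest$ptm_density)
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(out_dir)
}
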