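# Exact hypergeometric enrichment/depletion machinery, Bonferroni
# families, declarative test specs, multi-MAU co-occurrence and the
# percentage summaries.

logsumexp <- function(x) {
  if (length(x) == 0) return(-Inf)
  m <- max(x)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(x - m)))
}

#' Exact hypergeometric tail probability
#'
#' For X ~ Hypergeometric(N, K, n) (population N with K successes, draw
#' n without replacement): `enrich` gives P(X >= k), `deplete` gives
#' P(X <= k). Computed by exact summation of log-space point masses
#' (`lchoose`), so magnitudes far below double underflow are exact on
#' the log scale.
#'
#' @param k observed sample successes, `0 <= k <= min(n, K)`; may be a
#'   vector.
#' @param n sample size.
#' @param K population successes.
#' @param N population size.
#' @param direction `"enrich"` (upper tail) or `"deplete"` (lower tail).
#' @param log10 return log10 of the tail probability instead.
#' @return Numeric vector of tail probabilities (or their log10).
#' @export
hypergeom_tail <- function(k, n, K, N, direction = c("enrich", "deplete"),
                           log10 = FALSE) {
  direction <- match.arg(direction)
  stopifnot(length(n) == 1, length(K) == 1, length(N) == 1)
  if (any(k != floor(k)) || n != floor(n) || K != floor(K) || N != floor(N))
    stop("hypergeometric counts must be integers")
  if (n > N || K > N || any(k < 0) || any(k > pmin(n, K)))
    stop("invalid hypergeometric counts: need 0 <= k <= min(n, K), ",
         "n <= N, K <= N")
  lo <- max(0, n - (N - K)); hi <- min(n, K)
  i <- lo:hi
  lpmf <- lchoose(K, i) + lchoose(N - K, n - i) - lchoose(N, n)
  lp <- vapply(k, function(kk) {
    if (direction == "enrich") {
      if (kk <= lo) 0 else logsumexp(lpmf[i >= kk])
    } else {
      if (kk >= hi) 0 else if (kk < lo) -Inf else logsumexp(lpmf[i <= kk])
    }
  }, numeric(1))
  lp <- pmin(lp, 0)
  if (log10) lp / log(10) else exp(lp)
}

#' Bonferroni-corrected significance threshold
#' @param alpha family-wise error rate, in (0, 1).
#' @param m number of tests in the family, `m >= 1`.
#' @return `alpha / m`.
#' @export
bonferroni_threshold <- function(alpha, m) {
  if (!(alpha > 0 && alpha < 1)) stop("alpha must lie in (0, 1)")
  if (length(m) != 1 || m < 1 || m != floor(m))
    stop("family size m must be an integer >= 1")
  alpha / m
}

#' Inferred Bonferroni family-size presets
#'
#' Family sizes implied by printed corrected thresholds in the source
#' analyses (0.05/7 = 0.0071, 0.05/36 = 0.0014, 0.05/12 = 0.00417,
#' 0.05/20 = 0.0025). Presets, not hard-coded truths: every pipeline
#' entry point takes an explicit family size.
#'
#' @format Named numeric vector of family sizes.
#' @export
bonferroni_presets <- c(region_preference = 7,
                        region_subset_tests = 36,
                        level_series_12 = 12,
                        level_series_20 = 20)

#' Declarative enrichment test specification
#'
#' Selectors are named lists of column filters over a residue universe
#' (see [residue_universe()]): a logical value tests a flag column, a
#' character vector tests set membership. The sample selector is applied
#' on top of the population rows, so sample is a subset of population by
#' construction; `success` marks the items being counted (k within the
#' sample, K within the population).
#'
#' @param name test name.
#' @param population,sample,success selectors (named lists).
#' @param direction `"enrich"`, `"deplete"` or `"both"`.
#' @param family Bonferroni family name (bookkeeping only).
#' @return A `test_spec` object.
#' @export
test_spec <- function(name, population, sample, success,
                      direction = c("enrich", "deplete", "both"),
                      family = "default") {
  structure(list(name = name, population = population, sample = sample,
                 success = success, direction = match.arg(direction),
                 family = family),
            class = "test_spec")
}

apply_selector <- function(universe, selector) {
  keep <- rep(TRUE, nrow(universe))
  for (col in names(selector)) {
    if (!(col %in% names(universe)))
      stop("selector references unknown column '", col, "'")
    val <- selector[[col]]
    keep <- keep & if (is.logical(val)) universe[[col]] == val
                   else universe[[col]] %in% val
  }
  keep
}

#' One row per residue with every analysis flag
#'
#' The universe the declarative tests select from: region label, FB /
#' homopeptide / prion-like / histone flags, and one logical column per
#' modification type plus `mau` (any of the three) and `multi_mau`
#' (two or three distinct MAU types at the residue).
#'
#' @param proteins a `protein_set`.
#' @param annotations named list from [annotate_proteins()] /
#'   [flag_proteins()].
#' @param sites a `ptm_sites` table.
#' @return Data frame, one row per residue of every protein.
#' @export
residue_universe <- function(proteins, annotations, sites) {
  per <- lapply(seq_len(nrow(proteins)), function(i) {
    id <- proteins$protein_id[i]
    a <- annotations[[id]]
    n <- nchar(proteins$residues[i])
    data.frame(protein_id = id, position = seq_len(n),
               residue = strsplit(proteins$residues[i], "")[[1]],
               region = a$labels, fb = a$fb, homopeptide = a$homopeptide,
               prion = a$prion_like, histone = a$histone,
               stringsAsFactors = FALSE)
  })
  u <- do.call(rbind, per)
  types <- unique(c(MAU_TYPES, "phosphorylation", sites$ptm_type))
  ukey <- paste(u$protein_id, u$position)
  for (t in types) {
    s <- sites[sites$ptm_type == t, , drop = FALSE]
    u[[t]] <- ukey %in% paste(s$protein_id, s$position)
  }
  mau <- sites[sites$ptm_type %in% MAU_TYPES, , drop = FALSE]
  mkey <- paste(mau$protein_id, mau$position)
  u$mau <- ukey %in% mkey
  ntypes <- tapply(mau$ptm_type, mkey, function(x) length(unique(x)))
  multi <- names(ntypes)[ntypes >= 2]
  u$multi_mau <- ukey %in% multi
  rownames(u) <- NULL
  u
}

#' Run one declarative hypergeometric test
#'
#' Materialises (k, n, K, N) from the spec's selectors, computes both
#' tail probabilities exactly, and calls significance against the
#' Bonferroni-corrected threshold.
#'
#' @param spec a [test_spec()].
#' @param universe residue universe from [residue_universe()].
#' @param alpha uncorrected family-wise alpha (default 0.05).
#' @param family_size Bonferroni family size m (default 1).
#' @return An `enrichment_result` object.
#' @export
run_test <- function(spec, universe, alpha = 0.05, family_size = 1) {
  pop <- universe[apply_selector(universe, spec$population), ,
                  drop = FALSE]
  if (nrow(pop) == 0)
    stop("empty population for test '", spec$name, "' (selector: ",
         paste(names(spec$population), collapse = ", "), ")")
  in_sample <- apply_selector(pop, spec$sample)
  succ <- apply_selector(pop, spec$success)
  enrichment_result(
    name = spec$name,
    k = sum(in_sample & succ), n = sum(in_sample),
    K = sum(succ), N = nrow(pop),
    direction = spec$direction,
    alpha_corrected = bonferroni_threshold(alpha, family_size))
}

#' Assemble an enrichment result from its four counts
#'
#' @param name test name.
#' @param k,n,K,N hypergeometric counts (sample successes, sample size,
#'   population successes, population size).
#' @param direction which tail(s) decide the call.
#' @param alpha_corrected Bonferroni-corrected threshold.
#' @return An `enrichment_result`: the counts, both tail probabilities
#'   (raw and log10) and `call` in
#'   `{enriched, depleted, not_significant}`.
#' @export
enrichment_result <- function(name, k, n, K, N,
                              direction = c("enrich", "deplete", "both"),
                              alpha_corrected = 0.05) {
  direction <- match.arg(direction)
  if (n == 0) {
    res <- list(name = name, k = 0L, n = 0L, K = as.integer(K),
                N = as.integer(N), p_enrich = 1, p_deplete = 1,
                log10_p_enrich = 0, log10_p_deplete = 0,
                alpha_corrected = alpha_corrected,
                call = "not_significant", empty_sample = TRUE)
    class(res) <- "enrichment_result"
    return(res)
  }
  l10e <- hypergeom_tail(k, n, K, N, "enrich", log10 = TRUE)
  l10d <- hypergeom_tail(k, n, K, N, "deplete", log10 = TRUE)
  thr <- log10(alpha_corrected)
  call <- "not_significant"
  if (direction %in% c("enrich", "both") && l10e <= thr) call <- "enriched"
  if (direction %in% c("deplete", "both") && l10d <= thr &&
      call == "not_significant") call <- "depleted"
  res <- list(name = name, k = as.integer(k), n = as.integer(n),
              K = as.integer(K), N = as.integer(N),
              p_enrich = 10^l10e, p_deplete = 10^l10d,
              log10_p_enrich = l10e, log10_p_deplete = l10d,
              alpha_corrected = alpha_corrected, call = call,
              empty_sample = FALSE)
  class(res) <- "enrichment_result"
  res
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf(
    "enrichment_result '%s': k=%d n=%d K=%d N=%d\n  log10 P(enrich)=%.4g  log10 P(deplete)=%.4g  alpha'=%.4g  call=%s\n",
    x$name, x$k, x$n, x$K, x$N, x$log10_p_enrich, x$log10_p_deplete,
    x$alpha_corrected, x$call))
  invisible(x)
}

#' Residue letters tracked per site category
#' @param category a site category name (see [site_categories()]).
#' @return Character vector of residue letters.
#' @export
category_letters <- function(category) {
  switch(category,
         methylation_K = "K", methylation_R = "R",
         acetylation = "K", ubiquitination = "K",
         multi_mau = "K", all_mau = c("K", "R"),
         c("K", "R"))
}

#' Clade-level enrichment of PTM sites among conserved residues
#'
#' Sample: residues of the category's letter(s), in the region, among
#' included proteins of the chosen subset, that are conserved at the
#' level (`maintained`) or newly emerged there (`newly_emerged`);
#' k counts those that are human PTM sites of the category. Population:
#' all residues of the letter(s) in the same region and proteins;
#' K counts all such sites. Upper-tail P, Bonferroni-corrected call.
#'
#' @param residue_calls output of [residue_conservation()].
#' @param sites a `ptm_sites` table.
#' @param annotations annotation list (region labels, histone flags).
#' @param ortholog_map,hierarchy used for inclusion and age classes.
#' @param level clade level name.
#' @param region `"ordered"` or `"disordered"`.
#' @param category site category (see [site_categories()]).
#' @param mode `"maintained"` or `"newly_emerged"`.
#' @param protein_subset one of `all`, `old`, `new`, `histone`,
#'   `non_histone`.
#' @param alpha,family_size Bonferroni parameters.
#' @return An `enrichment_result`; when the level/region has no
#'   conserved residues the result has `n = 0`, call
#'   `not_significant`, and a warning is raised.
#' @export
conserved_mau_enrichment <- function(residue_calls, sites, annotations,
                                     ortholog_map, hierarchy,
                                     level, region, category,
                                     mode = c("maintained",
                                              "newly_emerged"),
                                     protein_subset = "all",
                                     alpha = 0.05, family_size = 1) {
  mode <- match.arg(mode)
  letters <- category_letters(category)
  inc <- clade_inclusion(ortholog_map, hierarchy, level)
  prot <- switch(protein_subset,
    all = inc,
    old = { a <- age_classes(ortholog_map, hierarchy, level)
            names(a)[a == "old"] },
    new = { a <- age_classes(ortholog_map, hierarchy, level)
            names(a)[a == "new"] },
    histone = intersect(inc, names(annotations)[
      vapply(annotations, `[[`, logical(1), "histone")]),
    non_histone = setdiff(inc, names(annotations)[
      vapply(annotations, `[[`, logical(1), "histone")]),
    stop("unknown protein_subset: ", protein_subset))
  rc <- residue_calls[residue_calls$level == level &
                        residue_calls$residue %in% letters &
                        residue_calls$protein_id %in% prot, ,
                      drop = FALSE]
  if (nrow(rc) > 0) {
    reg <- mapply(function(id, p) annotations[[id]]$labels[p],
                  rc$protein_id, rc$position)
    rc <- rc[reg == region, , drop = FALSE]
  }
  name <- paste(level, region, category, mode, protein_subset, sep = "/")
  cats <- site_categories(sites)
  cats <- cats[cats$category == category, , drop = FALSE]
  site_key <- paste(cats$protein_id, cats$position)
  N <- nrow(rc)
  if (N == 0) {
    warning("no ", paste(letters, collapse = "/"),
            " residues in population for ", name)
    return(enrichment_result(name, 0, 0, 0, 0, "enrich",
                             bonferroni_threshold(alpha, family_size)))
  }
  is_site <- paste(rc$protein_id, rc$position) %in% site_key
  in_sample <- if (mode == "maintained") rc$conserved else rc$newly_emerged
  n <- sum(in_sample)
  if (n == 0)
    warning("no ", mode, " residues at ", name)
  enrichment_result(name, k = sum(in_sample & is_site), n = n,
                    K = sum(is_site), N = N, direction = "enrich",
                    alpha_corrected = bonferroni_threshold(alpha,
                                                           family_size))
}

#' Multi-MAU co-occurrence (Venn) counts per region
#'
#' Counts, per region label, the disjoint subsets of
#' {methylation, acetylation, ubiquitination} observed at each distinct
#' modified residue, and lists residues with two or more distinct MAU
#' types.
#'
#' @param sites a `ptm_sites` table.
#' @param annotations annotation list giving region labels.
#' @return List: `venn` (data frame `region`, `types`, `count`) and
#'   `multi_sites` (data frame of multi-MAU residues with region).
#' @export
multi_mau <- function(sites, annotations) {
  mau <- sites[sites$ptm_type %in% MAU_TYPES, , drop = FALSE]
  if (nrow(mau) == 0)
    return(list(venn = data.frame(region = character(0),
                                  types = character(0),
                                  count = integer(0)),
                multi_sites = data.frame(protein_id = character(0),
                                         position = integer(0),
                                         residue = character(0),
                                         region = character(0),
                                         types = character(0))))
  key <- paste(mau$protein_id, mau$position)
  combo <- tapply(mau$ptm_type, key, function(t) {
    code <- c(methylation = "M", acetylation = "A",
              ubiquitination = "U")[sort(unique(t))]
    paste(sort(code), collapse = "")
  })
  first <- mau[!duplicated(key), , drop = FALSE]
  fkey <- paste(first$protein_id, first$position)
  region <- mapply(function(id, p) annotations[[id]]$labels[p],
                   first$protein_id, first$position)
  d <- data.frame(protein_id = first$protein_id,
                  position = first$position, residue = first$residue,
                  region = region, types = unname(combo[fkey]),
                  stringsAsFactors = FALSE)
  venn <- as.data.frame(table(region = d$region, types = d$types),
                        stringsAsFactors = FALSE)
  names(venn)[3] <- "count"
  venn <- venn[venn$count > 0, , drop = FALSE]
  venn <- venn[order(venn$region, venn$types), , drop = FALSE]
  rownames(venn) <- NULL
  list(venn = venn,
       multi_sites = d[nchar(d$types) >= 2, , drop = FALSE])
}

#' Format a count pair as a two-decimal percentage
#' @param num,den numerator and denominator counts.
#' @return Character like `"0.43%"`; `"NA"` when the denominator is 0.
#' @export
format_percent <- function(num, den) {
  ifelse(den == 0, "NA", sprintf("%.2f%%", 100 * num / den))
}

#' Percentage summary of conserved site residues
#'
#' Renders the per-(category, region) conserved-residue and
#' proteins-with-conserved-residue fractions as two-decimal percentage
#' strings, keeping the raw counts alongside. Zero denominators render
#' as `"NA"`, never as division errors.
#'
#' @param counts data frame with columns `category`, `region`,
#'   `n_conserved`, `n_total`, `n_proteins_conserved`, `n_proteins`
#'   (e.g. [conserved_site_table()] rows at the outermost level).
#' @return The input plus `pct_conserved` and `pct_proteins` columns.
#' @export
percentage_summary <- function(counts) {
  need <- c("category", "region", "n_conserved", "n_total",
            "n_proteins_conserved", "n_proteins")
  if (!all(need %in% names(counts)))
    stop("counts must have columns: ", paste(need, collapse = ", "))
  counts$pct_conserved <- format_percent(counts$n_conserved,
                                         counts$n_total)
  counts$pct_proteins <- format_percent(counts$n_proteins_conserved,
                                        counts$n_proteins)
  counts
}
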