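# Completely conserved / newly emerged residue calling per clade level,
# with optional per-column quality masking and residue-class allowance.

#' Map a human residue position to its alignment column
#' @param alignment a `family_alignment`.
#' @param position 1-based position in the ungapped human sequence.
#' @return Integer column index.
#' @export
position_to_column <- function(alignment, position) {
  if (position < 1 || position > length(alignment$pos2col))
    stop("position ", position, " outside human sequence of length ",
         length(alignment$pos2col))
  alignment$pos2col[[position]]
}

#' Is one alignment column completely conserved over a species subset?
#'
#' Considers the human row plus every ortholog row whose species is in
#' `species_subset`. `strict` mode requires every counted character to
#' equal the human residue; `class` mode requires every counted character
#' (human included) to be a member of `residue_class`. A gap in any
#' counted row breaks conservation in both modes, and a subset with no
#' ortholog rows present yields `FALSE`.
#'
#' @param alignment a `family_alignment`.
#' @param column alignment column index.
#' @param species_subset character vector of species ids.
#' @param residue_class character vector of one-letter codes (class mode).
#' @param mode `"strict"` or `"class"`.
#' @return Logical scalar.
#' @export
column_conserved <- function(alignment, column, species_subset,
                             residue_class = NULL,
                             mode = c("strict", "class")) {
  mode <- match.arg(mode)
  rows <- alignment$ortholog_rows[names(alignment$ortholog_rows) %in%
                                    species_subset]
  if (length(rows) == 0) return(FALSE)
  h <- substr(alignment$human_row, column, column)
  ch <- substr(rows, column, column)
  if (h == "-" || any(ch == "-")) return(FALSE)
  if (mode == "strict") return(all(ch == h))
  if (is.null(residue_class)) stop("class mode requires residue_class")
  (h %in% residue_class) && all(ch %in% residue_class)
}

#' Per-level conservation of every column of one alignment
#'
#' Vectorised core used by the callers: for each hierarchy level,
#' decides [column_conserved()] for all columns at once.
#'
#' @param alignment a `family_alignment`.
#' @param hierarchy a `clade_hierarchy`.
#' @param mode `"strict"` or `"class"`.
#' @param residue_class class used in class mode.
#' @param mask optional `column_mask` (see [apply_column_mask()]); a
#'   column not retained is forced unconserved and flagged masked.
#' @return List: `conserved` (levels x columns logical matrix), `masked`
#'   (per-column logical), `n_species` (ortholog rows counted per level).
#' @export
conserved_columns <- function(alignment, hierarchy,
                              mode = c("strict", "class"),
                              residue_class = NULL, mask = NULL) {
  mode <- match.arg(mode)
  if (mode == "class" && is.null(residue_class))
    stop("class mode requires residue_class")
  m <- alignment_matrix(alignment)
  h <- m[1, ]
  orth <- m[-1, , drop = FALSE]
  nlev <- length(hierarchy$levels)
  cons <- matrix(FALSE, nrow = nlev, ncol = ncol(m),
                 dimnames = list(names(hierarchy$levels), NULL))
  n_sp <- integer(nlev); names(n_sp) <- names(hierarchy$levels)
  for (i in seq_len(nlev)) {
    sel <- rownames(orth) %in% hierarchy$levels[[i]]
    n_sp[i] <- sum(sel)
    if (n_sp[i] == 0) next
    sub <- orth[sel, , drop = FALSE]
    nogap <- h != "-" & colSums(sub == "-") == 0
    if (mode == "strict") {
      ok <- colSums(sub != rep(h, each = nrow(sub))) == 0
    } else {
      ok <- h %in% residue_class &
        colSums(!matrix(sub %in% residue_class, nrow = nrow(sub))) == 0
    }
    cons[i, ] <- nogap & ok
  }
  masked <- rep(FALSE, ncol(m))
  if (!is.null(mask)) {
    if (length(mask$retained) != ncol(m))
      stop("column mask length ", length(mask$retained),
           " != alignment width ", ncol(m))
    masked <- !mask$retained
    cons[, masked] <- FALSE
  }
  list(conserved = cons, masked = masked, n_species = n_sp)
}

#' Build a column mask from per-column quality scores
#'
#' Columns whose score lies inside `[min_score, max_score]` (inclusive,
#' defaults 5 and 10 — the recommended retention range for the consumed
#' alignment-quality scores) are retained; all others are discarded from
#' conservation analysis.
#'
#' @param scores numeric vector in [0, 10], one per alignment column.
#' @param min_score,max_score retention range.
#' @return A `column_mask` list with `scores` and `retained`.
#' @export
apply_column_mask <- function(scores, min_score = 5, max_score = 10) {
  if (any(scores < 0 | scores > 10))
    stop("column scores must lie in [0, 10]")
  structure(list(scores = scores,
                 retained = scores >= min_score & scores <= max_score),
            class = "column_mask")
}

#' Conservation calls for chosen human positions, one row per level
#'
#' For each requested position and each hierarchy level (innermost
#' first): `conserved` is complete conservation over that level's
#' species; `newly_emerged` is conservation at this level but not at the
#' immediately wider level (always `FALSE` at the outermost level).
#'
#' @param alignment a `family_alignment`.
#' @param positions 1-based human positions to call.
#' @param hierarchy a `clade_hierarchy`.
#' @param mode,residue_class,mask see [conserved_columns()].
#' @return Data frame `protein_id`, `position`, `level`, `conserved`,
#'   `newly_emerged`, `masked`, `class_used`, `n_species_checked`.
#' @export
call_conservation <- function(alignment, positions, hierarchy,
                              mode = c("strict", "class"),
                              residue_class = NULL, mask = NULL) {
  mode <- match.arg(mode)
  cc <- conserved_columns(alignment, hierarchy, mode, residue_class, mask)
  cols <- vapply(positions, function(p) position_to_column(alignment, p),
                 integer(1))
  nlev <- length(hierarchy$levels)
  cons <- cc$conserved[, cols, drop = FALSE]
  wider <- rbind(cons[-1, , drop = FALSE],
                 matrix(TRUE, nrow = 1, ncol = length(cols)))
  new <- cons & !wider
  class_used <- if (mode == "class")
    attr(residue_class, "name") %||% "class" else "strict"
  data.frame(
    protein_id = alignment$protein_id,
    position = rep(positions, each = nlev),
    level = rep(names(hierarchy$levels), times = length(positions)),
    conserved = as.vector(cons),
    newly_emerged = as.vector(new),
    masked = rep(cc$masked[cols], each = nlev),
    class_used = class_used,
    n_species_checked = rep(cc$n_species, times = length(positions)),
    stringsAsFactors = FALSE)
}

#' Conservation of all residues of given letters across a family set
#'
#' Computes per-level conservation calls for every human residue whose
#' letter is in `letters` (default lysine and arginine), across all
#' alignments. This is the residue universe the clade-level enrichment
#' tests draw from ("conserved residues of the same type").
#'
#' @param alignments named list of `family_alignment` (by protein id).
#' @param hierarchy a `clade_hierarchy`.
#' @param letters residue letters to track.
#' @param mode,residue_class see [conserved_columns()].
#' @param masks optional named list of `column_mask` by protein id.
#' @return Data frame as in [call_conservation()], plus column `residue`.
#' @export
residue_conservation <- function(alignments, hierarchy,
                                 letters = c("K", "R"),
                                 mode = c("strict", "class"),
                                 residue_class = NULL, masks = NULL) {
  mode <- match.arg(mode)
  out <- vector("list", length(alignments))
  for (i in seq_along(alignments)) {
    aln <- alignments[[i]]
    hseq <- strsplit(human_sequence(aln), "")[[1]]
    pos <- which(hseq %in% letters)
    if (length(pos) == 0) next
    mask <- if (!is.null(masks)) masks[[aln$protein_id]] else NULL
    calls <- call_conservation(aln, pos, hierarchy, mode,
                               residue_class, mask)
    calls$residue <- rep(hseq[pos],
                         each = length(hierarchy$levels))
    out[[i]] <- calls
  }
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), position = integer(0),
                      level = character(0), conserved = logical(0),
                      newly_emerged = logical(0), masked = logical(0),
                      class_used = character(0),
                      n_species_checked = integer(0),
                      residue = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Expand PTM sites into per-residue analysis categories
#'
#' One distinct modified residue can fall into several categories:
#' methylation is split by residue letter (`methylation_K`,
#' `methylation_R`); `acetylation` and `ubiquitination` keep their names;
#' every MAU-modified residue also joins `all_mau`; residues carrying two
#' or three distinct MAU types additionally join `multi_mau`.
#' Non-MAU types map to their own name.
#'
#' @param sites a `ptm_sites` data frame.
#' @return Data frame `protein_id`, `position`, `residue`, `category`,
#'   distinct rows.
#' @export
site_categories <- function(sites) {
  if (nrow(sites) == 0)
    return(data.frame(protein_id = character(0), position = integer(0),
                      residue = character(0), category = character(0),
                      stringsAsFactors = FALSE))
  base <- sites
  base$category <- ifelse(base$ptm_type == "methylation",
                          paste0("methylation_", base$residue),
                          base$ptm_type)
  base <- base[c("protein_id", "position", "residue", "category")]
  mau <- sites[sites$ptm_type %in% MAU_TYPES, , drop = FALSE]
  extra <- NULL
  if (nrow(mau) > 0) {
    key <- paste(mau$protein_id, mau$position)
    ntypes <- tapply(mau$ptm_type, key, function(t) length(unique(t)))
    first <- mau[!duplicated(key), , drop = FALSE]
    fkey <- paste(first$protein_id, first$position)
    all_mau <- data.frame(protein_id = first$protein_id,
                          position = first$position,
                          residue = first$residue,
                          category = "all_mau", stringsAsFactors = FALSE)
    multi <- first[ntypes[fkey] >= 2, , drop = FALSE]
    multi_mau <- if (nrow(multi) > 0)
      data.frame(protein_id = multi$protein_id, position = multi$position,
                 residue = multi$residue, category = "multi_mau",
                 stringsAsFactors = FALSE)
    else NULL
    extra <- rbind(all_mau, multi_mau)
  }
  out <- rbind(base, extra)
  out <- out[!duplicated(out), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Summary counts of conserved and newly emerged site residues
#'
#' Aggregates conservation calls over (level, region label, site
#' category, protein subset): total distinct site residues among
#' included proteins, how many are conserved, how many newly emerged,
#' and protein-level counts (proteins with at least one site / at least
#' one conserved site). Subsets are `all`, `old`, `new` (protein age at
#' the level) and `histone` / `non_histone`.
#'
#' @param sites a `ptm_sites` table.
#' @param alignments named list of `family_alignment` by protein id.
#' @param hierarchy a `clade_hierarchy`.
#' @param annotations named list from [annotate_proteins()] (after
#'   [flag_proteins()]).
#' @param ortholog_map data frame `protein_id`, `species`, `subject_id`.
#' @param mode,residue_class,masks see [residue_conservation()].
#' @param subsets which protein subsets to tabulate.
#' @return Data frame with one row per (level, region, category, subset).
#' @export
conserved_site_table <- function(sites, alignments, hierarchy, annotations,
                                 ortholog_map,
                                 mode = c("strict", "class"),
                                 residue_class = NULL, masks = NULL,
                                 subsets = c("all", "old", "new",
                                             "histone", "non_histone")) {
  mode <- match.arg(mode)
  cats <- site_categories(sites)
  lev_names <- names(hierarchy$levels)
  empty <- data.frame(level = character(0), region = character(0),
                      category = character(0), subset = character(0),
                      n_total = integer(0), n_conserved = integer(0),
                      n_new = integer(0), n_proteins = integer(0),
                      n_proteins_conserved = integer(0),
                      stringsAsFactors = FALSE)
  if (nrow(cats) == 0) return(empty)
  cats <- cats[cats$protein_id %in% names(alignments), , drop = FALSE]
  if (nrow(cats) == 0) return(empty)
  # region label at each site position
  cats$region <- mapply(function(id, p) annotations[[id]]$labels[p],
                        cats$protein_id, cats$position)
  # per-protein conservation calls at the distinct site positions
  upos <- unique(cats[c("protein_id", "position")])
  call_list <- list()
  for (id in unique(upos$protein_id)) {
    pos <- sort(unique(upos$position[upos$protein_id == id]))
    mask <- if (!is.null(masks)) masks[[id]] else NULL
    call_list[[id]] <- call_conservation(alignments[[id]], pos, hierarchy,
                                         mode, residue_class, mask)
  }
  calls <- do.call(rbind, call_list)
  histones <- names(annotations)[vapply(annotations, `[[`, logical(1),
                                        "histone")]
  rows <- list(); ri <- 1L
  for (lev in lev_names) {
    inc <- clade_inclusion(ortholog_map, hierarchy, lev)
    ages <- age_classes(ortholog_map, hierarchy, lev)
    lc <- calls[calls$level == lev, , drop = FALSE]
    key <- paste(lc$protein_id, lc$position)
    cons_at <- stats::setNames(lc$conserved, key)
    new_at <- stats::setNames(lc$newly_emerged, key)
    base <- cats[cats$protein_id %in% inc, , drop = FALSE]
    if (nrow(base) > 0) {
      bkey <- paste(base$protein_id, base$position)
      base$conserved <- cons_at[bkey]
      base$newly_emerged <- new_at[bkey]
    }
    for (sub in subsets) {
      d <- switch(sub,
        all = base,
        old = base[base$protein_id %in% names(ages)[ages == "old"], ,
                   drop = FALSE],
        new = base[base$protein_id %in% names(ages)[ages == "new"], ,
                   drop = FALSE],
        histone = base[base$protein_id %in% histones, , drop = FALSE],
        non_histone = base[!(base$protein_id %in% histones), ,
                           drop = FALSE])
      if (nrow(d) == 0) next
      grp <- split(d, list(d$region, d$category), drop = TRUE)
      for (g in grp) {
        rows[[ri]] <- data.frame(
          level = lev, region = g$region[1], category = g$category[1],
          subset = sub, n_total = nrow(g),
          n_conserved = sum(g$conserved),
          n_new = sum(g$newly_emerged),
          n_proteins = length(unique(g$protein_id)),
          n_proteins_conserved =
            length(unique(g$protein_id[g$conserved])),
          stringsAsFactors = FALSE)
        ri <- ri + 1L
      }
    }
  }
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out <- out[order(match(out$level, lev_names), out$region, out$category,
                   out$subset), , drop = FALSE]
  rownames(out) <- NULL
  out
}
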