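# Reciprocal-best-hit orthology, per-clade inclusion and protein age.

best_hits <- function(hits, evalue_max) {
  hits <- hits[hits$query_id != hits$subject_id & hits$evalue < evalue_max, ,
               drop = FALSE]
  if (nrow(hits) == 0)
    return(stats::setNames(character(0), character(0)))
  o <- order(hits$query_id, hits$evalue, -hits$bitscore)
  hits <- hits[o, , drop = FALSE]
  first <- !duplicated(hits$query_id)
  top <- hits[first, , drop = FALSE]
  # a query whose top two hits tie on (evalue, bitscore) gets no call
  idx <- which(first)
  nxt <- idx + 1L
  has_second <- nxt <= nrow(hits) &
    hits$query_id[pmin(nxt, nrow(hits))] == top$query_id
  tied <- has_second &
    hits$evalue[pmin(nxt, nrow(hits))] == top$evalue &
    hits$bitscore[pmin(nxt, nrow(hits))] == top$bitscore
  top <- top[!tied, , drop = FALSE]
  stats::setNames(top$subject_id, top$query_id)
}

#' Reciprocal best hits for one species pair
#'
#' A pair (h, s) is an ortholog call iff s is h's best forward hit and h
#' is s's best backward hit, both with e-value strictly below
#' `evalue_max`. "Best" means lowest e-value, ties broken by highest bit
#' score; a remaining tie yields no call for that query. Self-hits are
#' discarded before selection.
#'
#' @param hits_forward reference -> species hit table
#'   (see [read_hit_table()]).
#' @param hits_backward species -> reference hit table.
#' @param evalue_max e-value threshold (default 1e-4, exclusive).
#' @return Data frame `protein_id`, `subject_id` (one row per reference
#'   protein with a reciprocal call).
#' @export
reciprocal_best_hits <- function(hits_forward, hits_backward,
                                 evalue_max = 1e-4) {
  fwd <- best_hits(hits_forward, evalue_max)
  bwd <- best_hits(hits_backward, evalue_max)
  keep <- !is.na(bwd[fwd]) & bwd[fwd] == names(fwd)
  keep[is.na(keep)] <- FALSE
  data.frame(protein_id = names(fwd)[keep],
             subject_id = unname(fwd[keep]),
             stringsAsFactors = FALSE)
}

#' Build a multi-species ortholog map
#'
#' @param hit_tables named list (by species) of lists with elements
#'   `forward` and `backward` hit tables.
#' @param evalue_max e-value threshold.
#' @return Data frame `protein_id`, `species`, `subject_id` with at most
#'   one row per (protein, species).
#' @export
build_ortholog_map <- function(hit_tables, evalue_max = 1e-4) {
  out <- lapply(names(hit_tables), function(sp) {
    r <- reciprocal_best_hits(hit_tables[[sp]]$forward,
                              hit_tables[[sp]]$backward, evalue_max)
    if (nrow(r) == 0) return(NULL)
    cbind(r[1], species = sp, r[2])
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(protein_id = character(0), species = character(0),
                      subject_id = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Proteins included at a clade level
#'
#' A reference protein is included at a level iff it has an ortholog in at
#' least one of that level's species (the reference species itself does
#' not count).
#'
#' @param ortholog_map data frame `protein_id`, `species`, `subject_id`.
#' @param hierarchy a `clade_hierarchy`.
#' @param level level name.
#' @return Character vector of included protein ids.
#' @export
clade_inclusion <- function(ortholog_map, hierarchy, level) {
  sp <- setdiff(level_species(hierarchy, level), hierarchy$reference)
  unique(ortholog_map$protein_id[ortholog_map$species %in% sp])
}

#' Old/new age class of a protein at a level
#'
#' A protein is `new` at a level iff it has no ortholog in any species
#' outside that level's species set ("outside" meaning the outermost
#' level's species minus the level's — nothing beyond the analysed
#' species panel is observable). At the outermost level every included
#' protein is vacuously new; the result then carries attribute
#' `vacuous = TRUE`.
#'
#' @inheritParams clade_inclusion
#' @param protein reference protein id; must be included at `level`.
#' @return `"new"` or `"old"`.
#' @export
protein_age_class <- function(ortholog_map, hierarchy, level, protein) {
  if (!(protein %in% clade_inclusion(ortholog_map, hierarchy, level)))
    stop("protein '", protein, "' is not included at level '", level, "'")
  outer_sp <- level_species(hierarchy,
                            names(hierarchy$levels)[length(hierarchy$levels)])
  outside <- setdiff(outer_sp, level_species(hierarchy, level))
  has_outside <- any(ortholog_map$species[ortholog_map$protein_id ==
                                            protein] %in% outside)
  cls <- if (has_outside) "old" else "new"
  if (length(outside) == 0) attr(cls, "vacuous") <- TRUE
  cls
}

#' Age classes for all proteins included at a level
#' @inheritParams clade_inclusion
#' @return Named character vector ("new"/"old") over included proteins.
#' @export
age_classes <- function(ortholog_map, hierarchy, level) {
  inc <- clade_inclusion(ortholog_map, hierarchy, level)
  outer_sp <- level_species(hierarchy,
                            names(hierarchy$levels)[length(hierarchy$levels)])
  outside <- setdiff(outer_sp, level_species(hierarchy, level))
  out_prot <- unique(ortholog_map$protein_id[ortholog_map$species %in%
                                               outside])
  stats::setNames(ifelse(inc %in% out_prot, "old", "new"), inc)
}
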