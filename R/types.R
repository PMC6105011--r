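#' ptmevoscan: conservation of PTM-site residues across nested clades
#'
#' Core containers are light S3 classes over base data frames and lists:
#' `protein_set` (sequences), `ptm_sites`, `clade_hierarchy`,
#' `family_alignment`, `column_mask`, `enrichment_result`. All residue
#' positions are 1-based inclusive throughout the package; BED input/output
#' is converted at the file boundary.
#'
#' @keywords internal
"_PACKAGE"

AA20 <- c("A", "C", "D", "E", "F", "G", "H", "I", "K", "L",
          "M", "N", "P", "Q", "R", "S", "T", "V", "W", "Y")

MAU_TYPES <- c("methylation", "acetylation", "ubiquitination")

#' Built-in residue substitution classes
#'
#' Residue classes used for class-mode conservation: a human site residue
#' is counted as conserved if every ortholog carries any member of the
#' class. `METHYL` allows the lysine/arginine swap (both are methylatable);
#' `ACETYL` allows substitution of acetyl-lysine by the other acetylatable
#' residues A, G, M, S, T.
#'
#' @format A named list of character vectors of one-letter codes.
#' @export
residue_classes <- list(
  METHYL = c("K", "R"),
  ACETYL = c("K", "A", "G", "M", "S", "T")
)

#' Construct a residue class
#'
#' @param name class name.
#' @param members non-empty character vector of one-letter amino-acid codes.
#' @return A named character vector with attribute `name`.
#' @export
residue_class <- function(name, members) {
  members <- unique(toupper(members))
  if (length(members) == 0) stop("residue class '", name, "' is empty")
  bad <- setdiff(members, c(AA20, "X"))
  if (length(bad) > 0)
    stop("residue class '", name, "' has invalid codes: ",
         paste(bad, collapse = ", "))
  structure(members, name = name)
}

#' Construct a protein set
#'
#' @param protein_id character vector of identifiers.
#' @param residues character vector of amino-acid strings (one-letter codes,
#'   `X` allowed), uppercased on construction.
#' @param species species identifier per protein (recycled).
#' @return A `protein_set` data frame with columns `protein_id`, `residues`,
#'   `species`.
#' @export
protein_set <- function(protein_id, residues, species = NA_character_) {
  residues <- toupper(residues)
  if (any(nchar(residues) < 1)) stop("zero-length protein sequence")
  bad <- grepl(paste0("[^", paste(c(AA20, "X"), collapse = ""), "]"), residues)
  if (any(bad))
    stop("invalid residue characters in: ",
         paste(protein_id[bad], collapse = ", "))
  if (anyDuplicated(protein_id))
    stop("duplicated protein_id in protein set")
  structure(
    data.frame(protein_id = as.character(protein_id),
               residues = residues,
               species = rep_len(as.character(species), length(protein_id)),
               stringsAsFactors = FALSE),
    class = c("protein_set", "data.frame"))
}

#' Look up one sequence in a protein set
#' @param proteins a `protein_set`.
#' @param id protein identifier.
#' @return The amino-acid string.
#' @export
seq_of <- function(proteins, id) {
  i <- match(id, proteins$protein_id)
  if (is.na(i)) stop("unknown protein_id: ", id)
  proteins$residues[[i]]
}

#' Construct a validated PTM site table
#'
#' De-duplicates on (protein_id, position, ptm_type) and, when `proteins`
#' is supplied, checks that the stated residue matches the sequence at the
#' stated 1-based position. Unknown modification names are preserved as
#' `other:<name>` so rare PTMs flow through the same machinery.
#'
#' @param protein_id,position,residue,ptm_type site columns.
#' @param proteins optional `protein_set` for validation.
#' @return A `ptm_sites` data frame.
#' @export
ptm_sites <- function(protein_id, position, residue, ptm_type,
                      proteins = NULL) {
  known <- c(MAU_TYPES, "phosphorylation")
  ptm_type <- as.character(ptm_type)
  unknown <- !(ptm_type %in% known) & !startsWith(ptm_type, "other:")
  ptm_type[unknown] <- paste0("other:", ptm_type[unknown])
  x <- data.frame(protein_id = as.character(protein_id),
                  position = as.integer(position),
                  residue = toupper(as.character(residue)),
                  ptm_type = ptm_type,
                  stringsAsFactors = FALSE)
  if (any(x$position < 1)) stop("PTM positions must be 1-based (>= 1)")
  x <- x[!duplicated(x[c("protein_id", "position", "ptm_type")]), ,
         drop = FALSE]
  rownames(x) <- NULL
  if (!is.null(proteins)) {
    miss <- setdiff(unique(x$protein_id), proteins$protein_id)
    if (length(miss) > 0)
      stop("PTM sites reference unknown proteins: ",
           paste(miss, collapse = ", "))
    seqs <- proteins$residues[match(x$protein_id, proteins$protein_id)]
    if (any(x$position > nchar(seqs)))
      stop("PTM position beyond sequence length for rows: ",
           paste(which(x$position > nchar(seqs)), collapse = ", "))
    at <- substr(seqs, x$position, x$position)
    bad <- at != x$residue
    if (any(bad))
      stop("PTM residue mismatch with sequence at rows: ",
           paste(which(bad), collapse = ", "),
           " (e.g. ", x$protein_id[which(bad)[1]], " pos ",
           x$position[which(bad)[1]], " is ", at[which(bad)[1]],
           ", site table says ", x$residue[which(bad)[1]], ")")
  }
  structure(x, class = c("ptm_sites", "data.frame"))
}

#' The default eleven-level clade series
#'
#' Names of the nested taxonomic levels used throughout, innermost first:
#' apes up to the whole eukaryotic domain.
#' @format Character vector of length 11.
#' @export
default_clade_names <- c(
  "Apes", "Primates", "Supraprimates", "Eutherians", "Mammals",
  "Tetrapods", "Vertebrates", "Chordates", "Deuterostomes",
  "Metazoans", "Eukaryotes")

#' Construct a nested clade hierarchy
#'
#' Levels are given innermost first and must be strictly nested; the
#' reference species must belong to every level. Nesting is verified here,
#' never assumed downstream.
#'
#' @param levels named list of character vectors of species ids,
#'   innermost level first.
#' @param reference reference species id present in every level.
#' @return A `clade_hierarchy` object.
#' @export
clade_hierarchy <- function(levels, reference = "homo_sapiens") {
  if (is.null(names(levels)) || any(!nzchar(names(levels))))
    stop("every hierarchy level needs a name")
  levels <- lapply(levels, function(s) unique(as.character(s)))
  for (i in seq_along(levels)) {
    if (!(reference %in% levels[[i]]))
      stop("reference species '", reference, "' missing from level '",
           names(levels)[i], "'")
    if (i > 1) {
      a <- levels[[i - 1]]; b <- levels[[i]]
      extra <- setdiff(a, b)
      if (length(extra) > 0 || length(a) >= length(b))
        stop("levels not strictly nested: '", names(levels)[i - 1],
             "' is not a strict subset of '", names(levels)[i], "'")
    }
  }
  structure(list(levels = levels, reference = reference),
            class = "clade_hierarchy")
}

#' @export
print.clade_hierarchy <- function(x, ...) {
  cat("clade_hierarchy:", length(x$levels), "levels, reference =",
      x$reference, "\n")
  for (nm in names(x$levels))
    cat("  ", nm, ": ", length(x$levels[[nm]]), " species\n", sep = "")
  invisible(x)
}

#' Species sets of a hierarchy
#' @param hierarchy a `clade_hierarchy`.
#' @param level level name.
#' @return Character vector of species ids at that level.
#' @export
level_species <- function(hierarchy, level) {
  if (!(level %in% names(hierarchy$levels)))
    stop("unknown hierarchy level: ", level)
  hierarchy$levels[[level]]
}

#' Construct a family alignment
#'
#' One human (reference) row plus at most one ortholog row per species, all
#' of equal gapped length. The mapping from 1-based human positions to
#' alignment columns is built on construction.
#'
#' @param protein_id human protein identifier.
#' @param human_row gapped human sequence string.
#' @param ortholog_rows named character vector, species -> gapped string.
#' @return A `family_alignment` object with elements `protein_id`,
#'   `human_row`, `ortholog_rows`, `n_columns`, `pos2col`.
#' @export
family_alignment <- function(protein_id, human_row, ortholog_rows) {
  human_row <- toupper(human_row)
  ortholog_rows <- vapply(ortholog_rows, toupper, character(1))
  nc <- nchar(human_row)
  if (length(ortholog_rows) > 0) {
    if (any(nchar(ortholog_rows) != nc))
      stop("alignment rows of unequal length in family '", protein_id, "'")
    if (anyDuplicated(names(ortholog_rows)))
      stop("duplicate species in family '", protein_id,
           "': at most one ortholog per species")
  }
  pos2col <- which(strsplit(human_row, "")[[1]] != "-")
  if (length(pos2col) == 0)
    stop("human row is all gaps in family '", protein_id, "'")
  structure(list(protein_id = protein_id,
                 human_row = human_row,
                 ortholog_rows = ortholog_rows,
                 n_columns = nc,
                 pos2col = pos2col),
            class = "family_alignment")
}

#' Ungapped human sequence of an alignment
#' @param alignment a `family_alignment`.
#' @return The de-gapped human amino-acid string.
#' @export
human_sequence <- function(alignment) {
  gsub("-", "", alignment$human_row, fixed = TRUE)
}

#' @export
print.family_alignment <- function(x, ...) {
  cat("family_alignment '", x$protein_id, "': ", length(x$ortholog_rows),
      " ortholog rows, ", x$n_columns, " columns, human length ",
      length(x$pos2col), "\n", sep = "")
  invisible(x)
}

#' Character matrix view of an alignment
#'
#' Rows: the human row first (named by the reference id "human"), then one
#' row per ortholog species. Used by the vectorised conservation caller.
#' @param alignment a `family_alignment`.
#' @return A character matrix with one column per alignment column.
#' @export
alignment_matrix <- function(alignment) {
  rows <- c(human = alignment$human_row, alignment$ortholog_rows)
  m <- do.call(rbind, strsplit(unname(rows), ""))
  rownames(m) <- names(rows)
  m
}
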