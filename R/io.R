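# Readers/writers for every external format the pipeline touches.
# All files are plain text; intervals are BED on disk (0-based half-open)
# and 1-based inclusive in memory.

parse_fasta_lines <- function(lines, path = "<text>") {
  lines <- sub("\r$", "", lines)
  keep <- !grepl("^\\s*$", lines)
  idx <- which(keep)
  if (length(idx) == 0) return(list(ids = character(0), seqs = character(0)))
  first <- idx[1]
  if (!startsWith(lines[first], ">"))
    stop("malformed FASTA in '", path, "': line ", first,
         " is not a header")
  ids <- character(0); seqs <- character(0)
  cur_id <- NULL; cur <- character(0); cur_line <- NA_integer_
  flush <- function() {
    s <- paste(cur, collapse = "")
    if (!nzchar(s))
      stop("malformed FASTA in '", path, "': empty sequence for header at line ",
           cur_line)
    ids <<- c(ids, cur_id); seqs <<- c(seqs, toupper(s))
  }
  for (i in idx) {
    ln <- lines[i]
    if (startsWith(ln, ">")) {
      if (!is.null(cur_id)) flush()
      hdr <- trimws(sub("^>", "", ln))
      if (!nzchar(hdr))
        stop("malformed FASTA in '", path, "': empty header at line ", i)
      cur_id <- strsplit(hdr, "\\s+")[[1]][1]
      cur <- character(0); cur_line <- i
    } else {
      cur <- c(cur, gsub("\\s", "", ln))
    }
  }
  flush()
  list(ids = ids, seqs = seqs)
}

#' Read protein sequences from FASTA
#'
#' @param path FASTA file. Headers are truncated at the first whitespace.
#' @param species species id assigned to every record (opaque string).
#' @return A [protein_set()]; empty file gives an empty set.
#' @export
read_fasta <- function(path, species = NA_character_) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- parse_fasta_lines(readLines(path), path)
  if (length(p$ids) == 0)
    return(protein_set(character(0), character(0)))
  protein_set(p$ids, p$seqs, species = species)
}

#' Write a protein set as FASTA
#' @param proteins a `protein_set`.
#' @param path output file.
#' @param width line-wrap width.
#' @export
write_fasta <- function(proteins, path, width = 60) {
  con <- file(path, "w"); on.exit(close(con))
  for (i in seq_len(nrow(proteins))) {
    writeLines(paste0(">", proteins$protein_id[i]), con)
    s <- proteins$residues[i]
    starts <- seq(1, nchar(s), by = width)
    writeLines(substring(s, starts, pmin(starts + width - 1, nchar(s))), con)
  }
  invisible(path)
}

#' Read one family alignment from aligned FASTA
#'
#' The first record is the reference (human) row; subsequent headers encode
#' the species as `species|sequence_id`. At most one ortholog per species.
#'
#' @param path aligned FASTA file.
#' @return A [family_alignment()].
#' @export
read_alignment <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  p <- parse_fasta_lines(readLines(path), path)
  if (length(p$ids) < 1) stop("alignment file '", path, "' is empty")
  if (length(unique(nchar(p$seqs))) != 1)
    stop("alignment rows of unequal length in '", path, "'")
  hdr <- strsplit(p$ids, "|", fixed = TRUE)
  human_id <- if (length(hdr[[1]]) >= 2) hdr[[1]][2] else hdr[[1]][1]
  orths <- character(0)
  if (length(p$ids) > 1) {
    sp <- vapply(hdr[-1], `[`, character(1), 1)
    orths <- stats::setNames(p$seqs[-1], sp)
  }
  family_alignment(human_id, p$seqs[1], orths)
}

#' Write a family alignment as aligned FASTA
#' @param alignment a `family_alignment`.
#' @param path output file.
#' @param reference reference species id used in the human header.
#' @export
write_alignment <- function(alignment, path, reference = "homo_sapiens") {
  con <- file(path, "w"); on.exit(close(con))
  writeLines(c(paste0(">", reference, "|", alignment$protein_id),
               alignment$human_row), con)
  for (sp in names(alignment$ortholog_rows))
    writeLines(c(paste0(">", sp, "|", alignment$protein_id, "@", sp),
                 alignment$ortholog_rows[[sp]]), con)
  invisible(path)
}

#' Read a PTM site table
#'
#' Tab-separated with header `protein_id position residue ptm_type`.
#' Sites are de-duplicated and validated against `proteins` when given.
#'
#' @param path site table file.
#' @param proteins optional `protein_set` for residue-at-position checks.
#' @return A `ptm_sites` data frame.
#' @export
read_ptm_sites <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "residue", "ptm_type")
  if (!all(need %in% names(x)))
    stop("site table '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  if (nrow(x) == 0)
    return(ptm_sites(character(0), integer(0), character(0), character(0)))
  ptm_sites(x$protein_id, x$position, x$residue, x$ptm_type,
            proteins = proteins)
}

#' Write a PTM site table
#' @param sites a `ptm_sites` data frame.
#' @param path output file.
#' @export
write_ptm_sites <- function(sites, path) {
  utils::write.table(as.data.frame(sites), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a 12-column tabular similarity hit table
#'
#' BLAST outfmt-6 dialect: columns 1 (query), 2 (subject), 11 (e-value)
#' and 12 (bit score) are used, the rest ignored.
#'
#' @param path hit table file (no header).
#' @return Data frame `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @export
read_hit_table <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(query_id = character(0), subject_id = character(0),
                      evalue = numeric(0), bitscore = numeric(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(parts)
  if (any(nf < 12))
    stop("hit table '", path, "' row ", which(nf < 12)[1],
         " has ", nf[which(nf < 12)[1]], " columns (>= 12 required)")
  ev <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 11)))
  bs <- suppressWarnings(as.numeric(vapply(parts, `[`, character(1), 12)))
  if (anyNA(ev) || anyNA(bs))
    stop("hit table '", path, "' row ", which(is.na(ev) | is.na(bs))[1],
         ": non-numeric evalue or bitscore")
  if (any(ev < 0)) stop("hit table '", path, "': negative e-value")
  data.frame(query_id = vapply(parts, `[`, character(1), 1),
             subject_id = vapply(parts, `[`, character(1), 2),
             evalue = ev, bitscore = bs, stringsAsFactors = FALSE)
}

#' Write a hit table (12-column tabular dialect)
#'
#' Unused columns are filled with placeholder values.
#' @param hits data frame with `query_id`, `subject_id`, `evalue`, `bitscore`.
#' @param path output file.
#' @export
write_hit_table <- function(hits, path) {
  n <- nrow(hits)
  filler <- function(v) rep(v, n)
  x <- cbind(hits$query_id, hits$subject_id,
             filler("100.0"), filler("0"), filler("0"), filler("0"),
             filler("1"), filler("0"), filler("1"), filler("0"),
             format(hits$evalue, scientific = TRUE, digits = 3),
             format(hits$bitscore, digits = 6))
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read a nested clade hierarchy from YAML config
#'
#' Expected structure: `reference: <species>` and `levels:` as an ordered
#' list of `{name: ..., species: [...]}` entries, innermost first. Nesting
#' and reference membership are verified on construction.
#'
#' @param path YAML file.
#' @return A [clade_hierarchy()].
#' @export
read_clade_config <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  cfg <- yaml::read_yaml(path)
  if (is.null(cfg$levels)) stop("clade config '", path, "' lacks 'levels'")
  lv <- lapply(cfg$levels, function(l) as.character(unlist(l$species)))
  names(lv) <- vapply(cfg$levels, function(l) as.character(l$name),
                      character(1))
  clade_hierarchy(lv, reference = cfg$reference %||% "homo_sapiens")
}

#' Write a clade hierarchy as YAML config
#' @param hierarchy a `clade_hierarchy`.
#' @param path output file.
#' @export
write_clade_config <- function(hierarchy, path) {
  cfg <- list(reference = hierarchy$reference,
              levels = lapply(names(hierarchy$levels), function(nm)
                list(name = nm, species = as.list(hierarchy$levels[[nm]]))))
  yaml::write_yaml(cfg, path)
  invisible(path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read BED-like intervals
#'
#' BED on disk is 0-based half-open; the returned intervals are 1-based
#' inclusive. Bounds are validated against `proteins` when given.
#'
#' @param path BED file (columns: protein_id, start, end, optional label).
#' @param proteins optional `protein_set`.
#' @return Data frame `protein_id`, `start`, `end`, `label`.
#' @export
read_bed_intervals <- function(path, proteins = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  lines <- readLines(path)
  lines <- lines[nzchar(trimws(lines))]
  empty <- data.frame(protein_id = character(0), start = integer(0),
                      end = integer(0), label = character(0),
                      stringsAsFactors = FALSE)
  if (length(lines) == 0) return(empty)
  parts <- strsplit(lines, "\t", fixed = TRUE)
  if (any(lengths(parts) < 3))
    stop("BED '", path, "' row ", which(lengths(parts) < 3)[1],
         ": fewer than 3 columns")
  x <- data.frame(
    protein_id = vapply(parts, `[`, character(1), 1),
    start = as.integer(vapply(parts, `[`, character(1), 2)) + 1L,
    end = as.integer(vapply(parts, `[`, character(1), 3)),
    label = vapply(parts, function(p) if (length(p) >= 4) p[4] else "",
                   character(1)),
    stringsAsFactors = FALSE)
  if (any(is.na(x$start) | is.na(x$end) | x$start < 1 | x$end < x$start))
    stop("BED '", path, "': invalid interval bounds")
  if (!is.null(proteins)) {
    miss <- setdiff(unique(x$protein_id), proteins$protein_id)
    if (length(miss) > 0)
      stop("BED '", path, "' references unknown proteins: ",
           paste(miss, collapse = ", "))
    len <- nchar(proteins$residues[match(x$protein_id,
                                         proteins$protein_id)])
    if (any(x$end > len))
      stop("BED '", path, "': interval beyond sequence length at row ",
           which(x$end > len)[1])
  }
  x
}

#' Write intervals as BED (0-based half-open on disk)
#' @param intervals data frame `protein_id`, `start`, `end`, `label`
#'   (1-based inclusive).
#' @param path output file.
#' @export
write_bed_intervals <- function(intervals, path) {
  x <- data.frame(intervals$protein_id, intervals$start - 1L,
                  intervals$end,
                  if (!is.null(intervals$label)) intervals$label else ".")
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read per-residue disorder scores
#'
#' Tab-separated with header `protein_id position score`; scores in [0,1].
#' @param path score file.
#' @return Named list of numeric vectors (one per protein, indexed by
#'   position).
#' @export
read_disorder_scores <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "position", "score")
  if (!all(need %in% names(x)))
    stop("disorder score file '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  if (any(x$score < 0 | x$score > 1))
    stop("disorder scores must lie in [0, 1]")
  out <- split(x[c("position", "score")], x$protein_id)
  lapply(out, function(d) {
    v <- numeric(max(d$position))
    v[d$position] <- d$score
    v
  })
}

#' Write per-residue disorder scores
#' @param scores named list of numeric vectors.
#' @param path output file.
#' @export
write_disorder_scores <- function(scores, path) {
  x <- do.call(rbind, lapply(names(scores), function(id)
    data.frame(protein_id = id, position = seq_along(scores[[id]]),
               score = scores[[id]], stringsAsFactors = FALSE)))
  if (is.null(x)) x <- data.frame(protein_id = character(0),
                                  position = integer(0), score = numeric(0))
  utils::write.table(format(x, digits = 6, trim = TRUE), path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read per-column alignment-quality scores
#'
#' Two-column text (column index, score in [0,10]), no header.
#' @param path score file.
#' @param n_columns alignment width; missing columns get score 0.
#' @return Numeric vector of length `n_columns`.
#' @export
read_column_scores <- function(path, n_columns) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.table(path, col.names = c("column", "score"))
  if (any(x$score < 0 | x$score > 10))
    stop("column scores must lie in [0, 10]")
  v <- numeric(n_columns)
  if (any(x$column < 1 | x$column > n_columns))
    stop("column index out of range in '", path, "'")
  v[x$column] <- x$score
  v
}

#' Write per-column alignment-quality scores
#' @param scores numeric vector in [0,10].
#' @param path output file.
#' @export
write_column_scores <- function(scores, path) {
  utils::write.table(
    data.frame(seq_along(scores), format(scores, digits = 6, trim = TRUE)),
    path, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an ortholog map (three-column text)
#' @param path file with header `protein_id species subject_id`.
#' @return Data frame with those columns.
#' @export
read_ortholog_map <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  x <- utils::read.delim(path, stringsAsFactors = FALSE)
  need <- c("protein_id", "species", "subject_id")
  if (!all(need %in% names(x)))
    stop("ortholog map '", path, "' must have columns: ",
         paste(need, collapse = ", "))
  if (anyDuplicated(x[c("protein_id", "species")]))
    stop("ortholog map '", path, "': more than one subject per ",
         "(protein, species)")
  x
}

#' Write an ortholog map
#' @param map data frame `protein_id`, `species`, `subject_id`.
#' @param path output file.
#' @export
write_ortholog_map <- function(map, path) {
  utils::write.table(map, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
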