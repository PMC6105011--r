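# Per-residue order/disorder classification, homopeptide runs,
# compositional-bias (prion-like) scoring and protein-level flags.

#' Classify residues as ordered / disordered / unclassified
#'
#' Residues inside any experimentally supported ordered interval are
#' labelled `ordered`, and this takes precedence over disorder prediction
#' (a structure-backed region stays ordered even where predictors call it
#' disordered). Remaining residues with a disorder score at or above the
#' threshold are `disordered`; everything else is `unclassified` and is
#' excluded from downstream region-specific analyses.
#'
#' @param seq amino-acid string.
#' @param ordered_intervals data frame with `start`, `end` (1-based
#'   inclusive) or NULL.
#' @param disorder_scores numeric vector in [0,1], one per residue, or NULL.
#' @param disorder_threshold score at or above which an unstructured
#'   residue is called disordered (default 0.5, the conventional
#'   predictor cut-off).
#' @return Character vector over `c("ordered","disordered","unclassified")`,
#'   one element per residue.
#' @export
classify_residues <- function(seq, ordered_intervals = NULL,
                              disorder_scores = NULL,
                              disorder_threshold = 0.5) {
  n <- nchar(seq)
  labels <- rep("unclassified", n)
  if (!is.null(disorder_scores)) {
    if (length(disorder_scores) != n)
      stop("disorder_scores length ", length(disorder_scores),
           " != sequence length ", n)
    if (any(disorder_scores < 0 | disorder_scores > 1))
      stop("disorder scores must lie in [0, 1]")
    labels[disorder_scores >= disorder_threshold] <- "disordered"
  }
  if (!is.null(ordered_intervals) && nrow(ordered_intervals) > 0) {
    if (any(ordered_intervals$start < 1 | ordered_intervals$end > n |
            ordered_intervals$start > ordered_intervals$end))
      stop("ordered interval out of bounds for sequence of length ", n)
    for (i in seq_len(nrow(ordered_intervals)))
      labels[ordered_intervals$start[i]:ordered_intervals$end[i]] <- "ordered"
  }
  labels
}

#' Find homopeptide runs
#'
#' Maximal runs of one identical residue with length at least `min_len`,
#' reported left to right; maximality makes them disjoint.
#'
#' @param seq amino-acid string.
#' @param min_len minimum run length (default 3).
#' @return Data frame `start`, `end`, `label` (the repeated residue).
#' @export
find_homopeptides <- function(seq, min_len = 3) {
  if (min_len < 2) stop("min_len must be >= 2")
  ch <- strsplit(seq, "")[[1]]
  r <- rle(ch)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$lengths >= min_len
  data.frame(start = starts[keep], end = ends[keep],
             label = r$values[keep], stringsAsFactors = FALSE)
}

#' Compositional-bias binomial score
#'
#' Over all contiguous windows with length in `[min_window, max_window]`
#' (clipped at the sequence length), finds the window minimising the
#' binomial upper-tail probability of seeing at least the observed count
#' of `residue_set` residues, given the background probability
#' `p = sum(background_freqs[residue_set])`. A simplified stand-in for a
#' low-probability subsequence scanner; it is not meant to agree
#' numerically with any external binary.
#'
#' @param seq amino-acid string.
#' @param residue_set character vector of target one-letter codes.
#' @param background_freqs named numeric vector over the 20 codes summing
#'   to 1; default uniform.
#' @param min_window,max_window window length bounds (defaults 15, 500);
#'   bounds beyond the sequence length are clipped, not errors.
#' @return List with `residue_set`, `best_window` (c(start, end)),
#'   `p_value`, `log10_p`.
#' @export
compositional_bias <- function(seq, residue_set,
                               background_freqs = NULL,
                               min_window = 15, max_window = 500) {
  if (min_window < 1 || min_window > max_window)
    stop("require 1 <= min_window <= max_window")
  if (is.null(background_freqs))
    background_freqs <- stats::setNames(rep(1 / 20, 20), AA20)
  if (abs(sum(background_freqs) - 1) > 1e-6)
    stop("background_freqs must sum to 1")
  n <- nchar(seq)
  wmin <- min(min_window, n)
  wmax <- min(max_window, n)
  p0 <- sum(background_freqs[intersect(residue_set,
                                       names(background_freqs))])
  hits <- as.integer(strsplit(seq, "")[[1]] %in% residue_set)
  cs <- c(0L, cumsum(hits))
  best <- list(start = 1L, end = wmin, lp = 0)
  for (w in wmin:wmax) {
    starts <- seq_len(n - w + 1L)
    counts <- cs[starts + w] - cs[starts]
    # upper tail P(X >= c) = pbinom(c - 1, w, p0, lower = FALSE), log scale
    lp <- stats::pbinom(counts - 1L, w, p0, lower.tail = FALSE,
                        log.p = TRUE)
    i <- which.min(lp)
    if (lp[i] < best$lp)
      best <- list(start = starts[i], end = starts[i] + w - 1L, lp = lp[i])
  }
  list(residue_set = residue_set,
       best_window = c(start = best$start, end = best$end),
       p_value = exp(best$lp),
       log10_p = best$lp / log(10))
}

#' Protein-level prion-like call
#'
#' A protein is prion-like when the minimum compositional-bias tail
#' probability over the residue sets {N}, {Q} and {N,Q} is at or below
#' `threshold` (default 1e-10).
#'
#' @inheritParams compositional_bias
#' @param threshold binomial P-value cut-off.
#' @return List with `prion_like` (logical), `best` (the winning
#'   [compositional_bias()] call) and `calls` per residue set.
#' @export
prion_like_call <- function(seq, background_freqs = NULL,
                            threshold = 1e-10,
                            min_window = 15, max_window = 500) {
  sets <- list(N = "N", Q = "Q", NQ = c("N", "Q"))
  calls <- lapply(sets, function(rs)
    compositional_bias(seq, rs, background_freqs, min_window, max_window))
  i <- which.min(vapply(calls, `[[`, numeric(1), "log10_p"))
  list(prion_like = calls[[i]]$p_value <= threshold,
       best = calls[[i]], calls = calls)
}

#' Annotate every residue of every protein
#'
#' Combines region classification, homopeptide runs and the prion-like
#' call into one `residue_annotation` object per protein.
#'
#' @param proteins a `protein_set`.
#' @param ordered_intervals data frame (`protein_id`, `start`, `end`) or
#'   NULL.
#' @param disorder_scores named list of per-residue score vectors or NULL.
#' @param disorder_threshold see [classify_residues()].
#' @param homopeptide_min_len minimum homopeptide run length.
#' @param background_freqs background composition for the bias scorer;
#'   default: the composition of `proteins` itself.
#' @param prion_threshold binomial cut-off for the prion-like call.
#' @param prion_windows length-2 window bounds for the bias scorer.
#' @return Named list of `residue_annotation` objects (fields `labels`,
#'   `fb`, `homopeptide`, `prion_like`, `histone`).
#' @export
annotate_proteins <- function(proteins, ordered_intervals = NULL,
                              disorder_scores = NULL,
                              disorder_threshold = 0.5,
                              homopeptide_min_len = 3,
                              background_freqs = NULL,
                              prion_threshold = 1e-10,
                              prion_windows = c(15, 500)) {
  if (is.null(background_freqs)) {
    ch <- unlist(strsplit(proteins$residues, ""))
    tab <- table(factor(ch[ch %in% AA20], levels = AA20))
    background_freqs <- as.numeric(tab) / sum(tab)
    names(background_freqs) <- AA20
    if (sum(tab) == 0)
      background_freqs <- stats::setNames(rep(1 / 20, 20), AA20)
  }
  out <- list()
  for (i in seq_len(nrow(proteins))) {
    id <- proteins$protein_id[i]
    s <- proteins$residues[i]
    n <- nchar(s)
    oi <- if (!is.null(ordered_intervals))
      ordered_intervals[ordered_intervals$protein_id == id, , drop = FALSE]
    else NULL
    ds <- if (!is.null(disorder_scores)) disorder_scores[[id]] else NULL
    labels <- classify_residues(s, oi, ds, disorder_threshold)
    hp <- find_homopeptides(s, homopeptide_min_len)
    hpv <- rep(FALSE, n)
    for (j in seq_len(nrow(hp))) hpv[hp$start[j]:hp$end[j]] <- TRUE
    pl <- prion_like_call(s, background_freqs, prion_threshold,
                          prion_windows[1], prion_windows[2])
    out[[id]] <- structure(
      list(protein_id = id, labels = labels, fb = rep(FALSE, n),
           homopeptide = hpv, prion_like = pl$prion_like,
           prion_p = pl$best$p_value, histone = FALSE),
      class = "residue_annotation")
  }
  out
}

#' Complete annotations with FB intervals and histone ids
#'
#' Sets the per-residue folding-on-binding booleans and the protein-level
#' histone flag; all other fields are untouched.
#'
#' @param annotations named list from [annotate_proteins()].
#' @param fb_intervals data frame (`protein_id`, `start`, `end`) or NULL.
#' @param histone_ids character vector of histone protein ids.
#' @return The completed annotation list.
#' @export
flag_proteins <- function(annotations, fb_intervals = NULL,
                          histone_ids = character(0)) {
  if (!is.null(fb_intervals) && nrow(fb_intervals) > 0) {
    miss <- setdiff(unique(fb_intervals$protein_id), names(annotations))
    if (length(miss) > 0)
      stop("FB intervals reference unknown proteins: ",
           paste(miss, collapse = ", "))
    for (i in seq_len(nrow(fb_intervals))) {
      id <- fb_intervals$protein_id[i]
      n <- length(annotations[[id]]$labels)
      if (fb_intervals$start[i] < 1 || fb_intervals$end[i] > n)
        stop("FB interval out of bounds for protein ", id)
      annotations[[id]]$fb[fb_intervals$start[i]:fb_intervals$end[i]] <- TRUE
    }
  }
  miss <- setdiff(histone_ids, names(annotations))
  if (length(miss) > 0)
    stop("histone ids not in annotation set: ", paste(miss, collapse = ", "))
  for (id in histone_ids) annotations[[id]]$histone <- TRUE
  annotations
}

#' Ordered intervals implied by a label vector
#'
#' Maximal runs of `ordered` labels, used for round-trips and the
#' precedence fixed-point property.
#' @param labels per-residue label vector.
#' @return Data frame `start`, `end`.
#' @export
ordered_runs <- function(labels) {
  r <- rle(labels == "ordered")
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values
  data.frame(start = starts[keep], end = ends[keep])
}
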