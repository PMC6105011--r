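# Stage orchestration: simulate -> annotate -> orthologs -> conserve ->
# enrich -> report, each stage idempotent and file-backed so
# intermediates are inspectable.

run_config_keys <- c("run_dir", "seed", "disorder_threshold",
                     "evalue_max", "bias_threshold", "mask_range",
                     "homopeptide_min", "alpha", "family_size", "mode",
                     "mask", "histones", "subset", "generator")

#' Pipeline run configuration
#'
#' Every stated analysis threshold lives here and nowhere else:
#' disorder cut-off 0.5, orthology e-value < 1e-4, compositional-bias
#' P <= 1e-10, column-quality retention range [5, 10], homopeptide
#' minimum length 3, alpha 0.05. Unknown keys are rejected.
#'
#' @param run_dir run directory (inputs under `<run_dir>/input`, outputs
#'   under `<run_dir>/output`).
#' @param seed integer seed for the simulate stage.
#' @param disorder_threshold,evalue_max,bias_threshold,mask_range,homopeptide_min,alpha
#'   analysis thresholds (see description).
#' @param family_size Bonferroni family size for the per-level series.
#' @param mode `"strict"` or `"class"` conservation.
#' @param mask apply per-column quality masking if score files exist.
#' @param histones `"include"` or `"exclude"`.
#' @param subset protein subset for the clade-level tests.
#' @param generator named list of overrides for [generator_params()].
#' @return A validated `run_config` list.
#' @export
run_config <- function(run_dir, seed = 1, disorder_threshold = 0.5,
                       evalue_max = 1e-4, bias_threshold = 1e-10,
                       mask_range = c(5, 10), homopeptide_min = 3,
                       alpha = 0.05, family_size = 11,
                       mode = c("strict", "class"), mask = FALSE,
                       histones = c("include", "exclude"),
                       subset = c("all", "old", "new"),
                       generator = list()) {
  cfg <- list(run_dir = run_dir, seed = as.integer(seed),
              disorder_threshold = disorder_threshold,
              evalue_max = evalue_max, bias_threshold = bias_threshold,
              mask_range = mask_range,
              homopeptide_min = homopeptide_min, alpha = alpha,
              family_size = family_size, mode = match.arg(mode),
              mask = isTRUE(mask), histones = match.arg(histones),
              subset = match.arg(subset), generator = generator)
  stopifnot(cfg$disorder_threshold >= 0, cfg$disorder_threshold <= 1,
            cfg$evalue_max > 0, cfg$bias_threshold > 0,
            length(cfg$mask_range) == 2,
            cfg$mask_range[1] >= 0, cfg$mask_range[2] <= 10,
            cfg$homopeptide_min >= 2,
            cfg$alpha > 0, cfg$alpha < 1, cfg$family_size >= 1)
  structure(cfg, class = "run_config")
}

#' Read a run configuration from YAML
#' @param path YAML file whose keys match [run_config()] arguments;
#'   unknown keys are rejected.
#' @return A `run_config`.
#' @export
read_run_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  bad <- setdiff(names(cfg), run_config_keys)
  if (length(bad) > 0)
    stop("unknown run config keys: ", paste(bad, collapse = ", "))
  do.call(run_config, cfg)
}

in_dir <- function(cfg) file.path(cfg$run_dir, "input")
out_dir <- function(cfg) file.path(cfg$run_dir, "output")

log_counts <- function(cfg, step, counts) {
  dir.create(out_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  path <- file.path(out_dir(cfg), "pipeline_log.tsv")
  lines <- sprintf("%s\t%s\t%d", step, names(counts),
                   as.integer(counts))
  cat(lines, file = path, sep = "\n", append = file.exists(path))
  cat("\n", file = path, append = TRUE)
  invisible(path)
}

need_input <- function(path, producer) {
  if (!file.exists(path))
    stop("missing upstream artifact '", path, "'; run `", producer,
         "` first")
  path
}

write_tsv <- function(x, path) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Simulate stage: write a synthetic input bundle
#' @param cfg a `run_config`.
#' @return The bundle, invisibly.
#' @export
cmd_simulate <- function(cfg) {
  params <- do.call(generator_params,
                    c(list(seed = cfg$seed), cfg$generator))
  bundle <- generate_bundle(params, in_dir(cfg))
  log_counts(cfg, "simulate",
             c(proteins = nrow(bundle$proteins),
               sites = nrow(bundle$sites),
               species = length(attr(bundle$hierarchy, "bands")),
               levels = length(bundle$hierarchy$levels)))
  invisible(bundle)
}

#' Annotate stage: region labels, homopeptides, prion/FB/histone flags
#' @param cfg a `run_config`.
#' @return The annotation list, invisibly.
#' @export
cmd_annotate <- function(cfg) {
  ind <- in_dir(cfg)
  proteins <- read_fasta(need_input(file.path(ind, "proteins.fasta"),
                                    "simulate"))
  oiv <- read_bed_intervals(file.path(ind, "ordered.bed"), proteins)
  scores <- read_disorder_scores(file.path(ind, "disorder_scores.tsv"))
  fbs <- read_bed_intervals(file.path(ind, "fb.bed"), proteins)
  histones <- if (file.exists(file.path(ind, "histones.txt")))
    readLines(file.path(ind, "histones.txt")) else character(0)
  histones <- histones[nzchar(histones)]
  ann <- annotate_proteins(proteins, oiv, scores,
                           disorder_threshold = cfg$disorder_threshold,
                           homopeptide_min_len = cfg$homopeptide_min,
                           prion_threshold = cfg$bias_threshold)
  ann <- flag_proteins(ann, fbs, histones)
  dir.create(out_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  write_annotations(ann, out_dir(cfg))
  labs <- unlist(lapply(ann, `[[`, "labels"))
  log_counts(cfg, "annotate",
             c(proteins = length(ann),
               ordered = sum(labs == "ordered"),
               disordered = sum(labs == "disordered"),
               unclassified = sum(labs == "unclassified"),
               prion_like = sum(vapply(ann, `[[`, logical(1),
                                       "prion_like")),
               histones = length(histones)))
  invisible(ann)
}

#' Serialize annotations to a run's output directory
#' @param annotations annotation list.
#' @param dir output directory.
#' @export
write_annotations <- function(annotations, dir) {
  res <- do.call(rbind, lapply(annotations, function(a)
    data.frame(protein_id = a$protein_id,
               position = seq_along(a$labels), region = a$labels,
               fb = a$fb, homopeptide = a$homopeptide,
               stringsAsFactors = FALSE)))
  write_tsv(res, file.path(dir, "annotations.tsv"))
  flags <- data.frame(
    protein_id = vapply(annotations, `[[`, character(1), "protein_id"),
    prion_like = vapply(annotations, `[[`, logical(1), "prion_like"),
    prion_p = sprintf("%.6e", vapply(annotations, `[[`, numeric(1),
                                     "prion_p")),
    histone = vapply(annotations, `[[`, logical(1), "histone"),
    stringsAsFactors = FALSE)
  write_tsv(flags, file.path(dir, "protein_flags.tsv"))
  invisible(dir)
}

#' Read serialized annotations back
#' @param dir directory holding `annotations.tsv` and
#'   `protein_flags.tsv`.
#' @return The annotation list.
#' @export
read_annotations <- function(dir) {
  res <- utils::read.delim(file.path(dir, "annotations.tsv"),
                           stringsAsFactors = FALSE)
  flags <- utils::read.delim(file.path(dir, "protein_flags.tsv"),
                             stringsAsFactors = FALSE)
  out <- lapply(split(res, res$protein_id), function(d) {
    d <- d[order(d$position), , drop = FALSE]
    f <- flags[flags$protein_id == d$protein_id[1], , drop = FALSE]
    structure(list(protein_id = d$protein_id[1], labels = d$region,
                   fb = d$fb, homopeptide = d$homopeptide,
                   prion_like = f$prion_like,
                   prion_p = as.numeric(f$prion_p),
                   histone = f$histone),
              class = "residue_annotation")
  })
  out[order(names(out))]
}

#' Orthologs stage: reciprocal best hits per species
#' @param cfg a `run_config`.
#' @return The ortholog map, invisibly.
#' @export
cmd_orthologs <- function(cfg) {
  hits_dir <- need_input(file.path(in_dir(cfg), "hits"), "simulate")
  fwd_files <- sort(list.files(hits_dir, pattern = "_fwd\\.tsv$",
                               full.names = TRUE))
  tabs <- list()
  for (f in fwd_files) {
    sp <- sub("_fwd\\.tsv$", "", basename(f))
    b <- file.path(hits_dir, paste0(sp, "_bwd.tsv"))
    tabs[[sp]] <- list(forward = read_hit_table(f),
                       backward = read_hit_table(need_input(b,
                                                            "simulate")))
  }
  map <- build_ortholog_map(tabs, evalue_max = cfg$evalue_max)
  dir.create(out_dir(cfg), recursive = TRUE, showWarnings = FALSE)
  write_ortholog_map(map, file.path(out_dir(cfg), "ortholog_map.tsv"))
  log_counts(cfg, "orthologs",
             c(species = length(tabs), pairs = nrow(map),
               proteins_with_orthologs =
                 length(unique(map$protein_id))))
  invisible(map)
}

pipeline_masks <- function(cfg, alignments) {
  if (!cfg$mask) return(NULL)
  sdir <- file.path(in_dir(cfg), "column_scores")
  if (!dir.exists(sdir)) return(NULL)
  masks <- list()
  for (id in names(alignments)) {
    f <- file.path(sdir, paste0(id, ".tsv"))
    if (file.exists(f))
      masks[[id]] <- apply_column_mask(
        read_column_scores(f, alignments[[id]]$n_columns),
        cfg$mask_range[1], cfg$mask_range[2])
  }
  if (length(masks) == 0) NULL else masks
}

#' Conserve stage: per-residue and per-site conservation calls
#' @param cfg a `run_config`.
#' @return List with `residue_calls` and `site_table`, invisibly.
#' @export
cmd_conserve <- function(cfg) {
  ind <- in_dir(cfg)
  proteins <- read_fasta(need_input(file.path(ind, "proteins.fasta"),
                                    "simulate"))
  sites <- read_ptm_sites(need_input(file.path(ind, "sites.tsv"),
                                     "simulate"), proteins)
  hierarchy <- read_clade_config(need_input(file.path(ind,
                                                      "clades.yaml"),
                                            "simulate"))
  map <- read_ortholog_map(need_input(
    file.path(out_dir(cfg), "ortholog_map.tsv"), "orthologs"))
  ann <- read_annotations(out_dir(cfg))
  afa <- sort(list.files(file.path(ind, "alignments"),
                         pattern = "\\.afa$", full.names = TRUE))
  alignments <- lapply(afa, read_alignment)
  names(alignments) <- vapply(alignments, `[[`, character(1),
                              "protein_id")
  masks <- pipeline_masks(cfg, alignments)
  rcls <- if (cfg$mode == "class")
    residue_class("METHYL", residue_classes$METHYL) else NULL
  calls <- residue_conservation(alignments, hierarchy,
                                letters = c("K", "R"), mode = cfg$mode,
                                residue_class = rcls, masks = masks)
  tab <- conserved_site_table(sites, alignments, hierarchy, ann, map,
                              mode = cfg$mode, residue_class = rcls,
                              masks = masks)
  write_tsv(calls, file.path(out_dir(cfg), "residue_calls.tsv"))
  write_tsv(tab, file.path(out_dir(cfg), "site_table.tsv"))
  log_counts(cfg, "conserve",
             c(alignments = length(alignments),
               residue_calls = nrow(calls),
               conserved_calls = sum(calls$conserved),
               masked_calls = sum(calls$masked)))
  invisible(list(residue_calls = calls, site_table = tab))
}

#' Enrich stage: all hypergeometric tests
#'
#' Per (level, region, category, maintained/newly emerged):
#' clade-level site enrichment among conserved residues. Plus the
#' residue-universe tests: region preference of each modification, and
#' FB / homopeptide / prion-like enrichment or depletion.
#'
#' @param cfg a `run_config`.
#' @return List with `level_tests` and `region_tests` data frames,
#'   invisibly.
#' @export
cmd_enrich <- function(cfg) {
  ind <- in_dir(cfg)
  proteins <- read_fasta(file.path(ind, "proteins.fasta"))
  sites <- read_ptm_sites(file.path(ind, "sites.tsv"), proteins)
  hierarchy <- read_clade_config(file.path(ind, "clades.yaml"))
  map <- read_ortholog_map(need_input(
    file.path(out_dir(cfg), "ortholog_map.tsv"), "orthologs"))
  ann <- read_annotations(out_dir(cfg))
  calls <- utils::read.delim(need_input(
    file.path(out_dir(cfg), "residue_calls.tsv"), "conserve"),
    stringsAsFactors = FALSE)
  subset <- if (cfg$histones == "exclude") "non_histone" else cfg$subset
  cats <- intersect(c("methylation_K", "methylation_R", "acetylation",
                      "ubiquitination", "all_mau", "multi_mau"),
                    unique(site_categories(sites)$category))
  rows <- list(); i <- 1L
  for (lev in names(hierarchy$levels))
    for (reg in c("ordered", "disordered"))
      for (cat in cats)
        for (mode in c("maintained", "newly_emerged")) {
          r <- suppressWarnings(conserved_mau_enrichment(
            calls, sites, ann, map, hierarchy, lev, reg, cat,
            mode = mode, protein_subset = subset, alpha = cfg$alpha,
            family_size = cfg$family_size))
          rows[[i]] <- data.frame(
            level = lev, region = reg, category = cat, mode = mode,
            subset = subset, k = r$k, n = r$n, K = r$K, N = r$N,
            log10_p_enrich = sprintf("%.6f", r$log10_p_enrich),
            log10_p_deplete = sprintf("%.6f", r$log10_p_deplete),
            alpha_corrected = sprintf("%.6e", r$alpha_corrected),
            call = r$call, stringsAsFactors = FALSE)
          i <- i + 1L
        }
  level_tests <- do.call(rbind, rows)
  universe <- residue_universe(proteins, ann, sites)
  region_tests <- standard_region_tests(universe, alpha = cfg$alpha)
  write_tsv(level_tests, file.path(out_dir(cfg), "level_tests.tsv"))
  write_tsv(region_tests, file.path(out_dir(cfg), "region_tests.tsv"))
  log_counts(cfg, "enrich",
             c(level_tests = nrow(level_tests),
               region_tests = nrow(region_tests),
               enriched = sum(level_tests$call == "enriched")))
  invisible(list(level_tests = level_tests,
                 region_tests = region_tests))
}

#' The fixed residue-universe test battery
#'
#' Region preference per modification (sample = ordered residues among
#' the classified residues of the modification's letters, successes =
#' modified residues; family of 7), and FB / homopeptide / prion-like
#' enrichment-or-depletion tests (family of 36).
#'
#' @param universe from [residue_universe()].
#' @param alpha uncorrected alpha.
#' @return Data frame, one row per test.
#' @export
standard_region_tests <- function(universe, alpha = 0.05) {
  specs <- list()
  for (t in c("methylation", "acetylation", "ubiquitination",
              "phosphorylation")) {
    letters <- if (t == "methylation") c("K", "R")
               else if (t == "phosphorylation") c("S", "T", "Y")
               else "K"
    if (!any(universe[[t]])) next
    specs[[paste0(t, "_region_pref")]] <- list(
      spec = test_spec(paste0(t, "_region_pref"),
                       population = list(residue = letters,
                                         region = c("ordered",
                                                    "disordered")),
                       sample = list(region = "ordered"),
                       success = stats::setNames(list(TRUE), t),
                       direction = "both", family = "region_preference"),
      m = unname(bonferroni_presets["region_preference"]))
    for (flagcol in c("fb", "homopeptide", "prion")) {
      popregion <- if (flagcol == "prion") "disordered"
                   else c("ordered", "disordered")
      specs[[paste(t, flagcol, sep = "_")]] <- list(
        spec = test_spec(paste(t, flagcol, sep = "_"),
                         population = list(residue = letters,
                                           region = popregion),
                         sample = stats::setNames(list(TRUE), flagcol),
                         success = stats::setNames(list(TRUE), t),
                         direction = "both",
                         family = "region_subset_tests"),
        m = unname(bonferroni_presets["region_subset_tests"]))
    }
  }
  rows <- lapply(specs, function(s) {
    r <- tryCatch(run_test(s$spec, universe, alpha = alpha,
                           family_size = s$m),
                  error = function(e) NULL)
    if (is.null(r)) return(NULL)
    data.frame(name = r$name, k = r$k, n = r$n, K = r$K, N = r$N,
               log10_p_enrich = sprintf("%.6f", r$log10_p_enrich),
               log10_p_deplete = sprintf("%.6f", r$log10_p_deplete),
               alpha_corrected = sprintf("%.6e", r$alpha_corrected),
               call = r$call, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  if (is.null(out))
    out <- data.frame(name = character(0), k = integer(0),
                      n = integer(0), K = integer(0), N = integer(0),
                      log10_p_enrich = character(0),
                      log10_p_deplete = character(0),
                      alpha_corrected = character(0),
                      call = character(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Report stage: summary tables
#'
#' Renders the outermost-level percentage summary, the multi-MAU Venn
#' counts per region, and leaves the enrichment tables in place.
#'
#' @param cfg a `run_config`.
#' @return List of the rendered tables, invisibly.
#' @export
cmd_report <- function(cfg) {
  ind <- in_dir(cfg)
  proteins <- read_fasta(file.path(ind, "proteins.fasta"))
  sites <- read_ptm_sites(file.path(ind, "sites.tsv"), proteins)
  hierarchy <- read_clade_config(file.path(ind, "clades.yaml"))
  ann <- read_annotations(out_dir(cfg))
  tab <- utils::read.delim(need_input(
    file.path(out_dir(cfg), "site_table.tsv"), "conserve"),
    stringsAsFactors = FALSE)
  outermost <- names(hierarchy$levels)[length(hierarchy$levels)]
  subset <- if (cfg$histones == "exclude") "non_histone" else "all"
  t1 <- tab[tab$level == outermost & tab$subset == subset, ,
            drop = FALSE]
  t1 <- percentage_summary(t1)
  venn <- multi_mau(sites, ann)$venn
  write_tsv(t1, file.path(out_dir(cfg), "table1_summary.tsv"))
  write_tsv(venn, file.path(out_dir(cfg), "venn_counts.tsv"))
  log_counts(cfg, "report",
             c(summary_rows = nrow(t1), venn_rows = nrow(venn)))
  invisible(list(summary = t1, venn = venn))
}

#' Run the full pipeline in order
#' @param cfg a `run_config`.
#' @return Invisibly, the report tables.
#' @export
run_pipeline <- function(cfg) {
  cmd_simulate(cfg)
  cmd_annotate(cfg)
  cmd_orthologs(cfg)
  cmd_conserve(cfg)
  cmd_enrich(cfg)
  invisible(cmd_report(cfg))
}

#' Command-line entry point
#'
#' Dispatches `ptm-evoscan <subcommand> --config run.yaml [--seed N]
#' [--mask] [--mode strict|class] [--histones include|exclude]
#' [--subset all|old|new]`. Used by the installed launcher script
#' (`system.file("scripts", "ptm-evoscan", package = "ptmevoscan")`).
#'
#' @param args character vector of command-line arguments.
#' @return Exit status (0 on success), invisibly.
#' @export
ptm_evoscan_main <- function(args = commandArgs(trailingOnly = TRUE)) {
  cmds <- c(simulate = cmd_simulate, annotate = cmd_annotate,
            orthologs = cmd_orthologs, conserve = cmd_conserve,
            enrich = cmd_enrich, report = cmd_report,
            all = run_pipeline)
  if (length(args) < 1 || !(args[1] %in% names(cmds))) {
    message("usage: ptm-evoscan <", paste(names(cmds), collapse = "|"),
            "> --config run.yaml [--seed N] [--mask]",
            " [--mode strict|class] [--histones include|exclude]",
            " [--subset all|old|new]")
    return(invisible(1L))
  }
  sub <- args[1]; rest <- args[-1]
  getopt <- function(flag) {
    i <- which(rest == flag)
    if (length(i) == 1 && i < length(rest)) rest[i + 1] else NULL
  }
  cfg_path <- getopt("--config")
  if (is.null(cfg_path)) stop("--config is required")
  cfg_list <- yaml::read_yaml(cfg_path)
  for (ov in c("seed", "mode", "histones", "subset")) {
    v <- getopt(paste0("--", ov))
    if (!is.null(v)) cfg_list[[ov]] <- v
  }
  if ("--mask" %in% rest) cfg_list$mask <- TRUE
  bad <- setdiff(names(cfg_list), run_config_keys)
  if (length(bad) > 0)
    stop("unknown run config keys: ", paste(bad, collapse = ", "))
  cfg <- do.call(run_config, cfg_list)
  cmds[[sub]](cfg)
  invisible(0L)
}
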