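# Workflow orchestration: configuration, the end-to-end pipeline
# (digest -> search -> FDR -> isotope-pair validation -> trypsin check
# -> optional structural filter -> hotspots) and stage reports.

#' Search and validation configuration
#'
#' Defaults follow the published high-resolution Orbitrap settings for
#' this workflow: 3.0 ppm precursor and 0.8 Da fragment precision,
#' S/N 2.0, 200-5000 Da peptide window, K:3/R:1 missed cleavages, at
#' most two methionine oxidations, b/y ions, and the 35 A
#' solvent-accessible distance constraint for BS3.
#'
#' @param ... Named overrides of the defaults.
#' @return A `search_config` list.
#' @export
search_config <- function(...) {
  cfg <- list(
    precursor_tol_ppm = 3.0,
    fragment_tol_da = 0.8,
    snr_min = 2.0,
    mass_min = 200,
    mass_max = 5000,
    missed_K = 3L,
    missed_R = 1L,
    max_mox = 2L,
    max_fragment_charge = 2L,
    min_precursor_charge = 3L,
    mz_range = c(300, 2000),
    pair_mass_tol_ppm = 5,
    rt_tol_min = 0.5,
    similarity_min = 0.6,
    sas_cutoff = 35,
    grid_spacing = 1.0,
    probe_radius = 1.4,
    fdr_target = 0.05,
    seed = 1L,
    log_timestamps = FALSE
  )
  over <- list(...)
  unknown <- setdiff(names(over), names(cfg))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg[names(over)] <- over
  num <- c("precursor_tol_ppm", "fragment_tol_da", "snr_min",
           "pair_mass_tol_ppm", "rt_tol_min", "sas_cutoff",
           "grid_spacing", "probe_radius")
  for (k in num) if (cfg[[k]] <= 0) stop("config ", k, " must be > 0")
  structure(cfg, class = "search_config")
}

#' Read a flat key = value configuration file
#'
#' @param path Text file with `key = value` lines; `#` starts a
#'   comment. Values parse as numbers where possible.
#' @param base Config to override (default [search_config()]).
#' @export
read_config <- function(path, base = search_config()) {
  lines <- readLines(path)
  lines <- sub("#.*$", "", lines)
  lines <- trimws(lines[grepl("=", lines, fixed = TRUE)])
  kv <- strsplit(lines, "\\s*=\\s*")
  over <- list()
  for (p in kv) {
    v <- suppressWarnings(as.numeric(p[2]))
    over[[p[1]]] <- if (is.na(v)) p[2] else v
  }
  do.call(search_config, over)
}

.write_tsv <- function(d, path) {
  drop <- vapply(d, is.list, logical(1))
  utils::write.table(d[, !drop, drop = FALSE], path, sep = "\t",
                     quote = FALSE, row.names = FALSE)
}

#' Run the full cross-link identification and validation pipeline
#'
#' Stages: read FASTA and MGF; build the reversed-sequence decoy
#' database; digest; search every charge >= 3 spectrum for light and
#' heavy candidates; derive a score threshold from the decoy FDR per
#' linker form; pair the surviving light/heavy identifications and
#' apply the three validation criteria; flag trypsin-inconsistent
#' links; optionally filter against a structure with the SAS
#' constraint; collapse to unique residue-pair links and report
#' hotspots. All stage tables are written as TSV when `out_dir` is
#' given, together with a run log of configuration and per-stage
#' counts.
#'
#' @param fasta Path to the protein FASTA database (targets only).
#' @param mgf Path to the MGF peak list.
#' @param structure Optional path to a PDB/mmCIF structure for the SAS
#'   filter.
#' @param config A [search_config()].
#' @param out_dir Optional output directory for stage TSVs and the run
#'   log.
#' @param chain_map Optional named vector protein id -> chain id for
#'   the structural filter (defaults to identical ids).
#' @return A list with `psms`, `thresholds`, `pairs`, `unpaired`,
#'   `validated`, `links` (unique residue pairs), `hotspots`, and
#'   `struct` (distance-annotated links, when a structure was given).
#' @export
run_pipeline <- function(fasta, mgf, structure = NULL,
                         config = search_config(), out_dir = NULL,
                         chain_map = NULL) {
  log_lines <- character(0)
  say <- function(fmt, ...) {
    msg <- sprintf(fmt, ...)
    if (isTRUE(config$log_timestamps))
      msg <- paste(format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"), msg)
    log_lines <<- c(log_lines, msg)
  }
  say("pipeline start")
  for (k in names(config)) say("config %s = %s", k,
                               paste(format(config[[k]]), collapse = ","))

  db <- read_fasta(fasta)
  decoy <- suppressWarnings(reverse_decoy(db))
  full_db <- rbind(db, decoy)
  say("database: %d target + %d decoy proteins", nrow(db), nrow(decoy))

  peptides <- digest_db(full_db, config$missed_K, config$missed_R,
                        max_mox = config$max_mox,
                        mass_min = config$mass_min,
                        mass_max = config$mass_max)
  say("digestion: %d peptide forms", nrow(peptides))

  spectra <- read_mgf(mgf)
  say("spectra: %d read, %d with charge >= %d", length(spectra),
      sum(vapply(spectra, function(s) s$charge >= config$min_precursor_charge,
                 logical(1))),
      config$min_precursor_charge)

  psms <- search_spectra(
    spectra, peptides, linker = bs3_linker(),
    tol_ppm = config$precursor_tol_ppm, tol_da = config$fragment_tol_da,
    snr_min = config$snr_min, max_charge = config$max_fragment_charge,
    mz_range = config$mz_range, min_charge = config$min_precursor_charge)

  if (is.null(psms)) {
    say("search: no PSMs; empty reports")
    out <- list(psms = NULL, thresholds = NULL,
                pairs = data.frame(), unpaired = data.frame(),
                validated = data.frame(), links = data.frame(),
                hotspots = data.frame(), struct = NULL,
                log = log_lines)
    if (!is.null(out_dir)) .write_outputs(out, out_dir)
    warning("no peptide-spectrum matches found")
    return(invisible(out))
  }
  say("search: %d PSMs (%d decoy)", nrow(psms), sum(psms$is_decoy))

  # score threshold from decoy FDR, per linker form
  kept <- list()
  thresholds <- list()
  for (f in c("light", "heavy")) {
    sub <- psms[psms$form == f, , drop = FALSE]
    th <- fdr_threshold(sub$score[!sub$is_decoy], sub$score[sub$is_decoy],
                        config$fdr_target)
    thresholds[[f]] <- data.frame(form = f, threshold = th$threshold,
                                  fdr = th$fdr, n_target = th$n_target,
                                  n_decoy = th$n_decoy)
    kept[[f]] <- sub[!sub$is_decoy & sub$score >= th$threshold, ,
                     drop = FALSE]
    say("fdr (%s): threshold %.2f keeps %d target PSMs (%d decoy above)",
        f, th$threshold, nrow(kept[[f]]), th$n_decoy)
  }
  thresholds <- do.call(rbind, thresholds)

  fp <- find_pairs(kept$light, kept$heavy,
                   mass_tol_ppm = config$pair_mass_tol_ppm,
                   rt_tol_min = config$rt_tol_min)
  pairs <- validate_pairs(fp$pairs, config$similarity_min)
  say("pairing: %d pairs, %d validated, %d unpaired PSMs",
      nrow(pairs), sum(pairs$verdict == "validated"),
      if (is.null(fp$unpaired)) 0L else nrow(fp$unpaired))

  validated <- pairs[pairs$verdict == "validated" & pairs$trypsin_ok, ,
                     drop = FALSE]
  if (nrow(pairs) && any(pairs$verdict == "validated" & !pairs$trypsin_ok))
    say("trypsin check removed %d validated pairs",
        sum(pairs$verdict == "validated" & !pairs$trypsin_ok))

  links <- collapse_links(validated)
  say("links: %d unique residue pairs", nrow(links))

  struct_out <- NULL
  hotspots <- data.frame()
  if (!is.null(structure) && nrow(links)) {
    model <- read_structure(structure)
    if (is.null(chain_map)) {
      # default mapping: protein id equal to a chain id, or a chain id
      # with a "chain" prefix stripped
      ids <- unique(c(links$protein1, links$protein2))
      chains_avail <- unique(model$residues$chain)
      mapped <- ifelse(ids %in% chains_avail, ids,
                       ifelse(sub("^chain", "", ids) %in% chains_avail,
                              sub("^chain", "", ids), NA_character_))
      chain_map <- stats::setNames(mapped, ids)
      if (anyNA(chain_map)) {
        warning("no chain mapping for protein(s) ",
                paste(ids[is.na(chain_map)], collapse = ", "),
                "; structural filter skipped")
        chain_map <- NULL
      }
    }
  }
  if (!is.null(structure) && nrow(links) && !is.null(chain_map)) {
    sl <- data.frame(chain_a = unname(chain_map[links$protein1]),
                     pos_a = links$site1,
                     chain_b = unname(chain_map[links$protein2]),
                     pos_b = links$site2,
                     stringsAsFactors = FALSE)
    struct_out <- cbind(links,
                        filter_crosslinks(sl, model,
                                          cutoff = config$sas_cutoff,
                                          grid_spacing = config$grid_spacing,
                                          probe_radius = config$probe_radius)[,
                          c("euclidean", "sas", "slack", "within_cutoff")])
    say("structural filter: %d pass, %d fail, %d unconstrained",
        sum(struct_out$within_cutoff == "pass"),
        sum(struct_out$within_cutoff == "fail"),
        sum(struct_out$within_cutoff == "unconstrained"))
    hotspots <- hotspot_report(sl, model)
  }

  out <- list(psms = psms, thresholds = thresholds, pairs = pairs,
              unpaired = fp$unpaired, validated = validated,
              links = links, hotspots = hotspots, struct = struct_out,
              log = log_lines)
  if (!is.null(out_dir)) .write_outputs(out, out_dir)
  invisible(out)
}

.write_outputs <- function(out, out_dir) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(out$psms)) .write_tsv(out$psms, file.path(out_dir, "psms.tsv"))
  if (!is.null(out$thresholds))
    .write_tsv(out$thresholds, file.path(out_dir, "fdr_thresholds.tsv"))
  if (nrow(out$pairs)) .write_tsv(out$pairs, file.path(out_dir, "pairs.tsv"))
  if (!is.null(out$unpaired) && nrow(out$unpaired))
    .write_tsv(out$unpaired, file.path(out_dir, "unpaired.tsv"))
  .write_tsv(out$links, file.path(out_dir, "links.tsv"))
  if (!is.null(out$struct))
    .write_tsv(out$struct, file.path(out_dir, "links_structural.tsv"))
  if (nrow(out$hotspots))
    .write_tsv(out$hotspots, file.path(out_dir, "hotspots.tsv"))
  writeLines(out$log, file.path(out_dir, "run_log.txt"))
  invisible(out_dir)
}
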