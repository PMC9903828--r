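#' @keywords internal
"_PACKAGE"

provenance_header <- function(seed, config = NULL) {
  ver <- as.character(utils::packageVersion("kakapopg"))
  hash <- "none"
  if (!is.null(config)) {
    tf <- tempfile()
    writeLines(deparse(config), tf)
    hash <- unname(tools::md5sum(tf))
    unlink(tf)
  }
  sprintf("# kakapopg %s; seed=%s; config_md5=%s", ver, seed, hash)
}

write_tsv <- function(df, path, seed, config = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(provenance_header(seed, config), con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Run demographic-scenario simulations and write scenario outputs
#'
#' Orchestrates [burn_in()], [run_scenario()], [summarize_sample()] and
#' [compare_scenarios()]: per scenario and replicate it writes a trajectory
#' TSV and a per-individual load TSV, plus a scenario-comparison table when
#' more than one scenario is requested. Replicate r of each scenario uses
#' seed `seed + r`. Every output starts with a provenance header (package
#' version, seed, config hash).
#'
#' @param out_dir output directory (created if needed).
#' @param scenarios character vector of scenario names.
#' @param replicates replicates per scenario.
#' @param scale desk-scale divisor.
#' @param h dominance coefficient.
#' @param scenario_steps steps per scenario run.
#' @param sample_n individuals sampled at the last step.
#' @param seed base RNG seed.
#' @param burn_args arguments passed to [burn_in()].
#' @return list: `summaries` (per scenario, per replicate), `comparison`
#'   (data frame or `NULL`), `files`.
#' @export
pipeline_simulate <- function(out_dir, scenarios = c("Stable", "Mainland",
                                                     "StewartIsland",
                                                     "Extreme"),
                              replicates = 2, scale = 20, h = 0,
                              scenario_steps = 2500, sample_n = 200,
                              seed = 1, burn_args = list()) {
  bad <- setdiff(scenarios, c("Stable", "Mainland", "StewartIsland",
                              "Extreme"))
  if (length(bad))
    stop("unknown scenario(s): ", paste(bad, collapse = ", "),
         "; valid names are Stable, Mainland, StewartIsland, Extreme")
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- sim_config(arch = build_architecture(scale = scale),
                    dfe = dfe_params(h = h), record_pedigree = FALSE)
  files <- character(0)
  summaries <- list()
  for (sc in scenarios) {
    reps <- list()
    for (r in seq_len(replicates)) {
      set.seed(seed + r)
      res <- run_scenario(demographic_scenario(sc, steps = scenario_steps),
                          cfg, burn_args = burn_args)
      f_traj <- file.path(out_dir,
                          sprintf("trajectory_%s_rep%02d.tsv", sc, r))
      write_tsv(res$trajectory, f_traj, seed = seed + r,
                config = list(scenario = sc, scale = scale, h = h,
                              steps = scenario_steps))
      files <- c(files, f_traj)
      if (res$extinct) {
        warning("scenario ", sc, " replicate ", r,
                " went extinct; no load summary")
        next
      }
      smry <- summarize_sample(res$state, n = sample_n)
      reps[[length(reps) + 1L]] <- smry
      f_load <- file.path(out_dir, sprintf("load_%s_rep%02d.tsv", sc, r))
      write_tsv(smry$individuals, f_load, seed = seed + r,
                config = list(scenario = sc, scale = scale, h = h))
      files <- c(files, f_load)
    }
    summaries[[sc]] <- reps
  }
  comparison <- NULL
  if (length(scenarios) > 1L) {
    comparison <- compare_scenarios(summaries)
    f_cmp <- file.path(out_dir, "scenario_comparison.tsv")
    write_tsv(comparison, f_cmp, seed = seed,
              config = list(scenarios = scenarios, scale = scale, h = h))
    files <- c(files, f_cmp)
  }
  list(summaries = summaries, comparison = comparison, files = files)
}

#' Run the empirical load/ROH/diversity analysis end to end
#'
#' Reads a VCF, population map and annotation, polarizes to derived-allele
#' dosages, keeps complete sites, optionally applies a BED mask, and writes:
#' per-individual relative load and heterozygosity, impact-category counts
#' with Welch tests, R_xy per category with jackknife CIs, windowed
#' nucleotide diversity, per-individual ROH BED files, F_ROH, and the
#' LoF-inside/outside-ROH contrast.
#'
#' @param vcf_path VCF file.
#' @param pop_map_path population map TSV.
#' @param annotation_path annotation TSV.
#' @param out_dir output directory.
#' @param mask_path optional BED mask.
#' @param pops length-2 vector naming populations x and y for R_xy and the
#'   Welch tests (default: the two populations in the data).
#' @param rxy_categories impact categories for R_xy.
#' @param block jackknife block size.
#' @param roh_parameters a [roh_params()].
#' @param window diversity window in bp.
#' @param seed recorded in output headers.
#' @return list with all result objects and `files`.
#' @export
pipeline_empirical <- function(vcf_path, pop_map_path, annotation_path,
                               out_dir, mask_path = NULL, pops = NULL,
                               rxy_categories = c("LOW", "MODERATE", "HIGH"),
                               block = 1000,
                               roh_parameters = roh_params(),
                               window = 10000, seed = 1) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  pop_map <- read_pop_map(pop_map_path)
  gm <- read_genotypes(vcf_path, pop_map)
  ann <- read_annotation(annotation_path)
  gm <- polarize(gm, ann)
  gm <- filter_complete(gm)
  if (!is.null(mask_path)) gm <- apply_mask(gm, read_mask(mask_path))
  if (length(gm$pos) == 0L)
    stop("no sites left after polarization, completeness filter and mask")
  ann <- align_annotation(ann, gm)
  if (is.null(pops)) {
    u <- unique(gm$populations)
    if (length(u) != 2L)
      stop("pops must be given when the data has != 2 populations")
    pops <- u
  }
  cfg <- list(pops = pops, block = block, window = window,
              roh = unclass(roh_parameters))
  load_res <- relative_load(gm, ann)
  div <- diversity(gm, window = window)
  per_ind <- merge(load_res,
                   div$heterozygosity[, c("sample_id", "het_per_kb")],
                   by = "sample_id")
  counts <- impact_counts(gm, ann, pops = pops)
  rxy_tab <- do.call(rbind, lapply(rxy_categories, function(cat) {
    r <- rxy(gm, pops[1], pops[2], ann = ann, category = cat, block = block)
    data.frame(category = cat, estimate = r$estimate, se = r$se,
               ci_lo = r$ci[1], ci_hi = r$ci[2], n_sites = r$n_sites,
               n_blocks = r$n_blocks, status = r$status,
               stringsAsFactors = FALSE)
  }))
  segs <- detect_roh_all(gm, roh_parameters)
  glen <- covered_span(gm)
  froh_tab <- do.call(rbind, lapply(names(segs), function(id) {
    fr <- froh(segs[[id]], glen)
    data.frame(sample_id = id, min_length_bp = fr$min_length_bp,
               froh = fr$froh, stringsAsFactors = FALSE)
  }))
  contrast <- lof_roh_contrast(gm, ann, segs)
  files <- list(
    per_individual = file.path(out_dir, "per_individual.tsv"),
    impact_counts = file.path(out_dir, "impact_counts.tsv"),
    impact_tests = file.path(out_dir, "impact_tests.tsv"),
    rxy = file.path(out_dir, "rxy.tsv"),
    pi_windows = file.path(out_dir, "pi_windows.tsv"),
    froh = file.path(out_dir, "froh.tsv"),
    lof_contrast = file.path(out_dir, "lof_roh_contrast.tsv"))
  write_tsv(per_ind, files$per_individual, seed, cfg)
  write_tsv(counts$counts, files$impact_counts, seed, cfg)
  if (!is.null(counts$tests))
    write_tsv(counts$tests, files$impact_tests, seed, cfg)
  write_tsv(rxy_tab, files$rxy, seed, cfg)
  write_tsv(div$windows, files$pi_windows, seed, cfg)
  write_tsv(froh_tab, files$froh, seed, cfg)
  write_tsv(contrast$rates, files$lof_contrast, seed, cfg)
  for (id in names(segs)) {
    f <- file.path(out_dir, sprintf("roh_%s.bed", id))
    seg <- segs[[id]]
    utils::write.table(
      data.frame(chrom = seg$chrom, start = seg$start - 1L, end = seg$end),
      f, sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
    files[[paste0("roh_", id)]] <- f
  }
  list(gm = gm, ann = ann, load = load_res, counts = counts, rxy = rxy_tab,
       diversity = div, roh = segs, froh = froh_tab, contrast = contrast,
       files = files)
}
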