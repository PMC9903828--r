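#' Specification for a synthetic two-population genotype dataset
#'
#' Describes a complete-coverage (no missing genotypes) biallelic SNP matrix
#' for two populations with configurable derived-allele frequency spectra,
#' per-category frequency deficits (planting a known R_xy), GERP-score
#' annotation, and long homozygous tracts in one population (planting known
#' ROH). Population 1 plays the role of the focal/island population x: a
#' deficit factor < 1 downscales its derived-allele frequencies for that
#' category, so the planted truth R_xy for category C is approximately the
#' deficit factor (a deficit in x gives R_xy < 1, the signature of purging
#' in the island population).
#'
#' @param n_sites number of SNP sites.
#' @param n_ind integer vector of length 2: individuals per population.
#' @param pop_names population labels; the first is the focal population x.
#' @param category_fractions named fractions of sites per impact category
#'   (must sum to <= 1; the remainder is annotated `NONE`).
#' @param freq_beta length-2 Beta parameters for base derived-allele
#'   frequencies (shared by both populations before deficits).
#' @param deficit named per-category factors multiplying population-x
#'   frequencies (default 1 = no deficit).
#' @param gerp_frac_gt2 fraction of sites with GERP score above 2 (drawn
#'   Uniform(2, 6); the rest Uniform(-2, 2)).
#' @param density_per_kb SNP density (default 1 SNP per kb).
#' @param n_chrom number of chromosomes.
#' @param roh_fraction fraction of each population-1 individual's genome
#'   placed in forced-homozygous tracts (0 disables).
#' @param roh_tract_mean mean planted tract length in bp.
#' @param flip_fraction fraction of sites written with the derived allele as
#'   VCF REF (ancestral = ALT), to exercise polarization.
#' @param seed RNG seed; a fixed seed makes generation byte-identical.
#' @return list of class `synth_spec`.
#' @export
synth_spec <- function(n_sites = 20000, n_ind = c(12, 12),
                       pop_names = c("island", "mainland"),
                       category_fractions = c(LOW = 0.30, MODERATE = 0.15,
                                              HIGH = 0.05, MODIFIER = 0.40),
                       freq_beta = c(0.8, 2.5),
                       deficit = c(LOW = 1, MODERATE = 1, HIGH = 1,
                                   MODIFIER = 1),
                       gerp_frac_gt2 = 0.25, density_per_kb = 1,
                       n_chrom = 1, roh_fraction = 0,
                       roh_tract_mean = 1.5e6, flip_fraction = 0,
                       seed = 1) {
  if (sum(category_fractions) > 1 + 1e-9)
    stop("category fractions must sum to <= 1")
  stopifnot(length(n_ind) == 2, all(n_ind >= 1), roh_fraction >= 0,
            roh_fraction < 1, flip_fraction >= 0, flip_fraction <= 1)
  structure(list(n_sites = as.integer(n_sites), n_ind = as.integer(n_ind),
                 pop_names = pop_names,
                 category_fractions = category_fractions,
                 freq_beta = freq_beta, deficit = deficit,
                 gerp_frac_gt2 = gerp_frac_gt2,
                 density_per_kb = density_per_kb,
                 n_chrom = as.integer(n_chrom),
                 roh_fraction = roh_fraction,
                 roh_tract_mean = roh_tract_mean,
                 flip_fraction = flip_fraction, seed = seed),
            class = "synth_spec")
}

#' Generate a synthetic dataset with planted truth
#'
#' Genotypes are drawn binomially from per-population per-site derived
#' frequencies, except inside planted tracts where the individual is forced
#' homozygous (derived with probability equal to the site frequency).
#' Generation is a pure function of the spec: the same spec produces
#' identical output.
#'
#' @param spec a [synth_spec()].
#' @param dir optional directory; when given, writes `synthetic.vcf`,
#'   `annotation.tsv`, `truth_sites.tsv`, `truth_rxy.tsv` and (when tracts
#'   are planted) `truth_tracts.bed`.
#' @return list of class `synth_dataset`: `gm` (polarized derived-dosage
#'   [genotype_matrix()]), `ann` ([site_annotation()]), `truth` (list:
#'   `freq_x`, `freq_y`, `rxy` per category, `tracts`, `genome_length`),
#'   `files` (paths, when written).
#' @export
synth_generate <- function(spec, dir = NULL) {
  set.seed(spec$seed)
  n <- spec$n_sites
  genome_length <- round(n / spec$density_per_kb * 1000)
  chrom_len <- round(genome_length / spec$n_chrom)
  per_chrom <- diff(round(seq(0, n, length.out = spec$n_chrom + 1)))
  chrom <- rep(paste0("chr", seq_len(spec$n_chrom)), per_chrom)
  pos <- unlist(lapply(per_chrom, function(k)
    sort(sample.int(chrom_len, k))), use.names = FALSE)
  # impact categories
  cats <- c(names(spec$category_fractions), "NONE")
  probs <- c(spec$category_fractions,
             max(0, 1 - sum(spec$category_fractions)))
  impact <- sample(cats, n, replace = TRUE, prob = probs)
  # GERP scores
  gt2 <- stats::runif(n) < spec$gerp_frac_gt2
  gerp <- ifelse(gt2, stats::runif(n, 2, 6), stats::runif(n, -2, 2))
  # frequencies: shared base, deficits downscale population x
  f_base <- stats::rbeta(n, spec$freq_beta[1], spec$freq_beta[2])
  f_x <- f_base
  f_y <- f_base
  for (cat in names(spec$deficit)) {
    sel <- impact == cat
    f_x[sel] <- f_x[sel] * spec$deficit[[cat]]
  }
  n1 <- spec$n_ind[1]
  n2 <- spec$n_ind[2]
  dos1 <- matrix(stats::rbinom(n * n1, 2L, rep(f_x, n1)), n, n1)
  dos2 <- matrix(stats::rbinom(n * n2, 2L, rep(f_y, n2)), n, n2)
  # planted homozygous tracts in population 1
  tracts <- NULL
  if (spec$roh_fraction > 0) {
    tr_list <- list()
    for (j in seq_len(n1)) {
      tr <- plant_tracts(spec, chrom_len)
      tr$individual <- sprintf("%s_%02d", spec$pop_names[1], j)
      tr_list[[j]] <- tr
      for (k in seq_len(nrow(tr))) {
        sel <- chrom == tr$chrom[k] & pos >= tr$start[k] + 1 &
          pos <= tr$end[k]
        if (any(sel))
          dos1[sel, j] <- 2L * stats::rbinom(sum(sel), 1L, f_x[sel])
      }
    }
    tracts <- do.call(rbind, tr_list)
    rownames(tracts) <- NULL
  }
  sample_ids <- c(sprintf("%s_%02d", spec$pop_names[1], seq_len(n1)),
                  sprintf("%s_%02d", spec$pop_names[2], seq_len(n2)))
  populations <- rep(spec$pop_names, c(n1, n2))
  dosage <- cbind(dos1, dos2)
  # allele symbols; flipped sites put the derived allele as REF
  bases <- c("A", "C", "G", "T")
  anc <- sample(bases, n, replace = TRUE)
  der <- vapply(anc, function(b) sample(setdiff(bases, b), 1), character(1))
  flipped <- stats::runif(n) < spec$flip_fraction
  ref <- ifelse(flipped, der, anc)
  alt <- ifelse(flipped, anc, der)
  vcf_dosage <- dosage
  vcf_dosage[flipped, ] <- 2L - vcf_dosage[flipped, , drop = FALSE]
  gm <- genotype_matrix(chrom, pos, dosage, sample_ids, populations,
                        ref = anc, alt = der)
  ann <- site_annotation(chrom, pos, gerp, impact, anc)
  truth_rxy <- vapply(cats[cats != "NONE"], function(cat) {
    sel <- impact == cat
    den <- sum(f_y[sel] * (1 - f_x[sel]))
    if (den == 0) NA_real_ else sum(f_x[sel] * (1 - f_y[sel])) / den
  }, numeric(1))
  truth <- list(freq_x = f_x, freq_y = f_y, rxy = truth_rxy,
                tracts = tracts, genome_length = genome_length,
                flipped = flipped)
  files <- NULL
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    files <- list(vcf = file.path(dir, "synthetic.vcf"),
                  annotation = file.path(dir, "annotation.tsv"),
                  pop_map = file.path(dir, "pop_map.tsv"),
                  truth_sites = file.path(dir, "truth_sites.tsv"),
                  truth_rxy = file.path(dir, "truth_rxy.tsv"))
    write_vcf_table(chrom, pos, ref, alt, vcf_dosage, sample_ids,
                    contig_lengths = stats::setNames(
                      rep(chrom_len, spec$n_chrom),
                      paste0("chr", seq_len(spec$n_chrom))),
                    path = files$vcf)
    utils::write.table(
      data.frame(chrom = chrom, pos = pos, gerp = gerp, impact = impact,
                 ancestral = anc),
      files$annotation, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(sample_id = sample_ids, population = populations),
      files$pop_map, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(chrom = chrom, pos = pos, category = impact,
                 f_x = f_x, f_y = f_y),
      files$truth_sites, sep = "\t", quote = FALSE, row.names = FALSE)
    utils::write.table(
      data.frame(category = names(truth_rxy), rxy = unname(truth_rxy)),
      files$truth_rxy, sep = "\t", quote = FALSE, row.names = FALSE)
    if (!is.null(tracts)) {
      files$truth_tracts <- file.path(dir, "truth_tracts.bed")
      utils::write.table(
        tracts[, c("chrom", "start", "end", "individual")],
        files$truth_tracts, sep = "\t", quote = FALSE, row.names = FALSE,
        col.names = FALSE)
    }
  }
  structure(list(gm = gm, ann = ann, truth = truth, spec = spec,
                 files = files),
            class = "synth_dataset")
}

# non-overlapping tracts (0-based half-open) covering ~roh_fraction of one
# chromosome set
plant_tracts <- function(spec, chrom_len) {
  target <- spec$roh_fraction * chrom_len * spec$n_chrom
  placed <- 0
  rows <- list()
  guard <- 0L
  while (placed < target && guard < 1000L) {
    guard <- guard + 1L
    len <- round(stats::rexp(1, 1 / spec$roh_tract_mean))
    if (len < 2e5) next
    ch <- paste0("chr", sample.int(spec$n_chrom, 1))
    if (len >= chrom_len) len <- round(chrom_len * 0.9)
    start <- sample.int(chrom_len - len, 1) - 1L
    ok <- TRUE
    for (r in rows)
      if (r$chrom == ch && start < r$end && r$start < start + len) {
        ok <- FALSE
        break
      }
    if (!ok) next
    rows[[length(rows) + 1L]] <- data.frame(chrom = ch, start = start,
                                            end = start + len,
                                            stringsAsFactors = FALSE)
    placed <- placed + len
  }
  if (!length(rows))
    stop("infeasible ROH plan: no tract placed (tracts too long for genome?)")
  do.call(rbind, rows)
}

#' Write a genotype table as a plain VCF 4.2 file
#'
#' @param chrom,pos,ref,alt per-site fields.
#' @param dosage sites x individuals ALT-dosage matrix (0/1/2; `NA` written
#'   as `./.`).
#' @param sample_ids column labels.
#' @param contig_lengths named vector of contig lengths for the header.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf_table <- function(chrom, pos, ref, alt, dosage, sample_ids,
                            contig_lengths, path) {
  gt_code <- c("0/0", "0/1", "1/1")
  gt <- matrix(gt_code[dosage + 1L], nrow(dosage), ncol(dosage))
  gt[is.na(dosage)] <- "./."
  header <- c("##fileformat=VCFv4.2",
              sprintf("##contig=<ID=%s,length=%d>", names(contig_lengths),
                      as.integer(contig_lengths)),
              "##FORMAT=<ID=GT,Number=1,Type=String,Description=\"Genotype\">",
              paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                      "INFO", "FORMAT", sample_ids), collapse = "\t"))
  body <- paste(chrom, pos, ".", ref, alt, ".", "PASS", ".", "GT",
                apply(gt, 1L, paste, collapse = "\t"), sep = "\t")
  writeLines(c(header, body), path)
  invisible(path)
}

#' Write a genotype matrix as VCF
#'
#' @param gm a [genotype_matrix()] (dosages written as REF/ALT genotypes).
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_vcf <- function(gm, path) {
  ref <- if (is.null(gm$ref)) rep("A", length(gm$pos)) else gm$ref
  alt <- if (is.null(gm$alt)) rep("T", length(gm$pos)) else gm$alt
  lens <- vapply(split(gm$pos, gm$chrom), max, numeric(1))
  write_vcf_table(gm$chrom, gm$pos, ref, alt, gm$dosage, gm$sample_ids,
                  contig_lengths = lens, path = path)
}

#' Check recovered statistics against a dataset's planted truth
#'
#' Reports the maximum absolute error between realized and planted
#' derived-allele frequencies (population x), the R_xy estimate, jackknife
#' CI and planted value per category (flagging whether the CI covers the
#' truth), and, when tracts were planted, base-pair recall and precision of
#' [detect_roh()] against the planted tracts.
#'
#' @param dataset a `synth_dataset` from [synth_generate()].
#' @param block jackknife block size for R_xy.
#' @param roh_parameters a [roh_params()] for the recall check.
#' @return list of class `truth_report`: `max_freq_err`, `rxy` (data
#'   frame), `roh` (data frame or `NULL`).
#' @export
truth_check <- function(dataset, block = 1000,
                        roh_parameters = roh_params()) {
  gm <- dataset$gm
  truth <- dataset$truth
  spec <- dataset$spec
  fq <- pop_allele_freq(gm, spec$pop_names[1])
  max_freq_err <- max(abs(fq$f - truth$freq_x))
  cats <- names(truth$rxy)
  rxy_rows <- do.call(rbind, lapply(cats, function(cat) {
    r <- rxy(gm, spec$pop_names[1], spec$pop_names[2], ann = dataset$ann,
             category = cat, block = block)
    data.frame(category = cat, estimate = r$estimate, lo = r$ci[1],
               hi = r$ci[2], truth = truth$rxy[[cat]],
               covered = !is.na(r$ci[1]) && !is.na(truth$rxy[[cat]]) &&
                 truth$rxy[[cat]] >= r$ci[1] & truth$rxy[[cat]] <= r$ci[2],
               status = r$status, stringsAsFactors = FALSE)
  }))
  roh_df <- NULL
  if (!is.null(truth$tracts)) {
    inds <- unique(truth$tracts$individual)
    roh_df <- do.call(rbind, lapply(inds, function(id) {
      segs <- suppressWarnings(detect_roh(gm, id, roh_parameters))
      tr <- truth$tracts[truth$tracts$individual == id, , drop = FALSE]
      ov <- overlap_bp(segs, tr)
      data.frame(individual = id,
                 planted_bp = sum(tr$end - tr$start),
                 detected_bp = sum(as.numeric(segs$length_bp)),
                 overlap_bp = ov,
                 recall = ov / sum(tr$end - tr$start),
                 precision = if (nrow(segs)) ov / sum(as.numeric(segs$length_bp))
                   else NA_real_,
                 stringsAsFactors = FALSE)
    }))
  }
  structure(list(max_freq_err = max_freq_err, rxy = rxy_rows, roh = roh_df),
            class = "truth_report")
}

# overlap in bp between detected segments (1-based inclusive) and planted
# tracts (0-based half-open)
overlap_bp <- function(segs, tracts) {
  if (!nrow(segs) || !nrow(tracts)) return(0)
  tot <- 0
  for (i in seq_len(nrow(segs))) {
    s1 <- segs$start[i] - 1  # to 0-based
    e1 <- segs$end[i]
    same <- tracts$chrom == segs$chrom[i]
    if (!any(same)) next
    tot <- tot + sum(pmax(0, pmin(e1, tracts$end[same]) -
                            pmax(s1, tracts$start[same])))
  }
  tot
}
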