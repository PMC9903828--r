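#' Construct a genotype matrix of derived-allele dosages
#'
#' The central container for all empirical statistics: a sites-by-individuals
#' matrix of biallelic allele dosages in \{0, 1, 2\} (count of ALT alleles
#' after [read_genotypes()], count of derived alleles after [polarize()]),
#' with genomic positions, sample identifiers and population labels.
#'
#' @param chrom character vector of chromosome identifiers, one per site.
#' @param pos integer vector of 1-based coordinates, strictly increasing
#'   within each chromosome.
#' @param dosage integer matrix, sites x individuals; entries 0, 1, 2 or `NA`
#'   (missing, only permitted before [filter_complete()]).
#' @param sample_ids character vector of individual labels (columns).
#' @param populations character vector of population labels, one per
#'   individual.
#' @param ref,alt optional per-site reference/alternate allele symbols (used
#'   by [polarize()] to match the ancestral call).
#' @return An object of class `genotype_matrix`.
#' @export
genotype_matrix <- function(chrom, pos, dosage, sample_ids, populations,
                            ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  storage.mode(dosage) <- "integer"
  n_sites <- nrow(dosage)
  n_ind <- ncol(dosage)
  stopifnot(length(chrom) == n_sites, length(pos) == n_sites,
            length(sample_ids) == n_ind, length(populations) == n_ind)
  if (n_ind < 2L)
    stop("a genotype_matrix needs at least 2 individuals")
  bad <- dosage[!is.na(dosage)]
  if (length(bad) && (any(bad < 0L) || any(bad > 2L)))
    stop("dosages must be 0, 1, 2 or NA")
  if (anyNA(populations) || any(!nzchar(populations)))
    stop("every individual needs a population label")
  pos <- as.integer(pos)
  ord_ok <- tapply(pos, chrom, function(p) all(diff(p) > 0L))
  if (!all(unlist(ord_ok)))
    stop("positions must be strictly increasing within each chromosome")
  if (anyDuplicated(paste(chrom, pos)))
    stop("duplicated (chrom, pos) records")
  dimnames(dosage) <- list(NULL, sample_ids)
  structure(list(chrom = as.character(chrom), pos = pos, dosage = dosage,
                 sample_ids = as.character(sample_ids),
                 populations = as.character(populations),
                 ref = if (is.null(ref)) NULL else as.character(ref),
                 alt = if (is.null(alt)) NULL else as.character(alt)),
            class = "genotype_matrix")
}

#' @export
print.genotype_matrix <- function(x, ...) {
  cat("genotype_matrix:", length(x$pos), "sites x", length(x$sample_ids),
      "individuals\n")
  cat("  chromosomes:", length(unique(x$chrom)), "\n")
  tb <- table(x$populations)
  cat("  populations:",
      paste(sprintf("%s (n=%d)", names(tb), as.integer(tb)), collapse = ", "),
      "\n")
  n_na <- sum(is.na(x$dosage))
  if (n_na > 0) cat("  missing genotypes:", n_na, "\n")
  invisible(x)
}

#' @export
dim.genotype_matrix <- function(x) dim(x$dosage)

#' Keep a subset of sites
#'
#' @param gm a [genotype_matrix()].
#' @param idx integer or logical site index.
#' @return A `genotype_matrix` restricted to `idx`.
#' @export
subset_sites <- function(gm, idx) {
  genotype_matrix(gm$chrom[idx], gm$pos[idx], gm$dosage[idx, , drop = FALSE],
                  gm$sample_ids, gm$populations,
                  ref = gm$ref[idx], alt = gm$alt[idx])
}

site_key <- function(chrom, pos) paste(chrom, pos, sep = ":")

#' Per-site annotation: conservation score, impact category, ancestral allele
#'
#' @param chrom,pos site coordinates (must align 1:1 with a
#'   [genotype_matrix()] when used together).
#' @param gerp numeric GERP rejected-substitutions score (unitless; higher =
#'   stronger evolutionary constraint).
#' @param impact one of `"LOW"`, `"MODERATE"`, `"HIGH"`, `"MODIFIER"`,
#'   `"NONE"` (SnpEff-style categories; `NONE` marks unannotated sites).
#' @param ancestral ancestral allele symbol, or `NA` when unknown.
#' @return A data frame of class `site_annotation`.
#' @export
site_annotation <- function(chrom, pos, gerp, impact, ancestral) {
  impact <- toupper(as.character(impact))
  ok <- impact %in% c("LOW", "MODERATE", "HIGH", "MODIFIER", "NONE")
  if (!all(ok))
    stop("unknown impact categories: ",
         paste(unique(impact[!ok]), collapse = ", "))
  out <- data.frame(chrom = as.character(chrom), pos = as.integer(pos),
                    gerp = as.numeric(gerp), impact = impact,
                    ancestral = as.character(ancestral),
                    stringsAsFactors = FALSE)
  class(out) <- c("site_annotation", "data.frame")
  out
}

#' Align an annotation table with a genotype matrix
#'
#' Matches on (chromosome, position) and returns rows in the matrix's site
#' order; errors if any site lacks an annotation record.
#'
#' @param ann a [site_annotation()].
#' @param gm a [genotype_matrix()].
#' @return The `site_annotation` reordered to `gm`'s sites.
#' @export
align_annotation <- function(ann, gm) {
  m <- match(site_key(gm$chrom, gm$pos), site_key(ann$chrom, ann$pos))
  if (anyNA(m))
    stop(sum(is.na(m)), " sites have no annotation record")
  out <- ann[m, , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("site_annotation", "data.frame")
  out
}

#' Read a sample-to-population map
#'
#' Two-column tab-separated table: sample_id, population (header optional,
#' detected from the first line).
#'
#' @param path file path.
#' @return data frame with columns `sample_id`, `population`.
#' @export
read_pop_map <- function(path) {
  first <- readLines(path, n = 1L)
  has_header <- grepl("sample", first, ignore.case = TRUE)
  df <- utils::read.table(path, header = has_header, sep = "\t",
                          stringsAsFactors = FALSE)
  names(df)[1:2] <- c("sample_id", "population")
  df[, c("sample_id", "population")]
}

#' Read a per-site annotation TSV
#'
#' Expected columns (with header): chrom, pos, gerp, impact, ancestral.
#'
#' @param path file path.
#' @return a [site_annotation()].
#' @export
read_annotation <- function(path) {
  df <- utils::read.table(path, header = TRUE, sep = "\t",
                          stringsAsFactors = FALSE, comment.char = "#")
  site_annotation(df$chrom, df$pos, df$gerp, df$impact, df$ancestral)
}

#' Read genotypes from a VCF file
#'
#' Parses a VCF 4.x file (plain or gzipped) with `vcfR`, retains biallelic
#' SNP records, and encodes each genotype as the count of ALT alleles.
#' Missing genotypes are kept as `NA` so that [filter_complete()] can report
#' how many sites were removed.
#'
#' @param vcf_path path to the VCF file.
#' @param pop_map data frame with columns `sample_id`, `population` (see
#'   [read_pop_map()]); every VCF sample must be present.
#' @param drop_nonbiallelic drop records that are not biallelic SNPs
#'   (default `TRUE`); if `FALSE`, such records raise an error.
#' @param allele_balance optional length-2 numeric: heterozygous calls whose
#'   ALT-read fraction (from the `AD` FORMAT field) falls outside
#'   `[allele_balance[1], allele_balance[2]]` are set to missing. The usual
#'   upstream filter is `c(0.2, 0.8)`; calls without `AD` are kept. This is
#'   a convenience pass-through for data whose calling pipeline did not
#'   already apply it.
#' @return A [genotype_matrix()] with `ref`/`alt` fields populated.
#' @export
read_genotypes <- function(vcf_path, pop_map, drop_nonbiallelic = TRUE,
                           allele_balance = NULL) {
  vcf <- vcfR::read.vcfR(vcf_path, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  if (is.null(dim(fix))) fix <- matrix(fix, nrow = 1L, dimnames = list(NULL, names(fix)))
  ref <- fix[, "REF"]
  alt <- fix[, "ALT"]
  is_snp <- !is.na(ref) & !is.na(alt) & nchar(ref) == 1L & nchar(alt) == 1L &
    !grepl(",", alt, fixed = TRUE)
  if (!all(is_snp)) {
    if (!drop_nonbiallelic)
      stop(sum(!is_snp), " records are not biallelic SNPs")
    vcf <- vcf[is_snp, ]
    fix <- fix[is_snp, , drop = FALSE]
    ref <- ref[is_snp]
    alt <- alt[is_snp]
  }
  chrom <- fix[, "CHROM"]
  pos <- as.integer(fix[, "POS"])
  if (anyDuplicated(site_key(chrom, pos)))
    stop("duplicated (chrom, pos) records in ", vcf_path)
  gt <- vcfR::extract.gt(vcf, element = "GT")
  samples <- colnames(gt)
  # dosage: count ALT alleles, separator '/' or '|'
  core <- gsub("\\|", "/", gt)
  dos <- matrix(NA_integer_, nrow = nrow(gt), ncol = ncol(gt))
  known <- c("0/0" = 0L, "0/1" = 1L, "1/0" = 1L, "1/1" = 2L)
  idx <- match(core, names(known))
  dos[] <- known[idx]
  if (!is.null(allele_balance)) {
    stopifnot(length(allele_balance) == 2, allele_balance[1] < allele_balance[2])
    ad <- tryCatch(vcfR::extract.gt(vcf, element = "AD"),
                   error = function(e) NULL)
    if (!is.null(ad)) {
      counts <- strsplit(ad, ",", fixed = TRUE)
      ref_n <- suppressWarnings(as.numeric(vapply(counts, `[`, "", 1L)))
      alt_n <- suppressWarnings(as.numeric(vapply(counts, `[`, "", 2L)))
      ab <- matrix(alt_n / (ref_n + alt_n), nrow(dos), ncol(dos))
      bad <- dos == 1L & !is.na(ab) &
        (ab < allele_balance[1] | ab > allele_balance[2])
      dos[bad] <- NA_integer_
    }
  }
  m <- match(samples, pop_map$sample_id)
  if (anyNA(m))
    stop("samples missing from population map: ",
         paste(samples[is.na(m)], collapse = ", "))
  genotype_matrix(chrom, pos, dos, samples, pop_map$population[m],
                  ref = ref, alt = alt)
}

#' Re-express dosages as derived-allele counts
#'
#' Uses the ancestral-allele call (from an outgroup alignment, e.g. the kea
#' for kakapo) to polarize each site: where the ancestral allele equals REF
#' the ALT dosage already counts derived alleles; where it equals ALT the
#' dosage is complemented (0 <-> 2). Sites whose ancestral allele is unknown
#' or matches neither allele are dropped and tallied.
#'
#' @param gm a [genotype_matrix()] with `ref`/`alt` fields.
#' @param ann a [site_annotation()] aligned (or alignable) with `gm`.
#' @return A polarized `genotype_matrix`; attribute `"polarize_stats"` holds
#'   the numbers of flipped, unknown-dropped and mismatch-dropped sites.
#' @export
polarize <- function(gm, ann) {
  if (is.null(gm$ref) || is.null(gm$alt))
    stop("polarize() needs ref/alt alleles in the genotype_matrix")
  ann <- align_annotation(ann, gm)
  anc <- toupper(ann$ancestral)
  anc[!is.na(anc) & (anc == "" | anc == "." | anc == "N")] <- NA_character_
  is_ref <- !is.na(anc) & anc == toupper(gm$ref)
  is_alt <- !is.na(anc) & anc == toupper(gm$alt)
  unknown <- is.na(anc)
  mismatch <- !unknown & !is_ref & !is_alt
  if (any(mismatch))
    warning(sum(mismatch), " sites dropped: ancestral matches neither allele")
  keep <- is_ref | is_alt
  dos <- gm$dosage
  dos[is_alt, ] <- 2L - dos[is_alt, , drop = FALSE]
  ref <- gm$ref
  alt <- gm$alt
  # after polarization REF/ALT are reported as ancestral/derived
  ref[is_alt] <- gm$alt[is_alt]
  alt[is_alt] <- gm$ref[is_alt]
  out <- genotype_matrix(gm$chrom[keep], gm$pos[keep],
                         dos[keep, , drop = FALSE],
                         gm$sample_ids, gm$populations,
                         ref = ref[keep], alt = alt[keep])
  attr(out, "polarize_stats") <- c(flipped = sum(is_alt),
                                   dropped_unknown = sum(unknown),
                                   dropped_mismatch = sum(mismatch))
  out
}

#' Keep only sites genotyped in every individual
#'
#' Mirrors the complete-coverage filter applied before all load statistics:
#' only sites with a called genotype in all individuals are retained.
#'
#' @param gm a [genotype_matrix()].
#' @return A complete `genotype_matrix`; attribute `"n_removed"` counts the
#'   dropped sites.
#' @export
filter_complete <- function(gm) {
  complete <- rowSums(is.na(gm$dosage)) == 0L
  if (!any(complete))
    warning("no site is genotyped in all individuals; result is empty")
  out <- subset_sites(gm, complete)
  attr(out, "n_removed") <- sum(!complete)
  out
}

#' Interval mask track
#'
#' Holds half-open 0-based intervals as read from BED (e.g. CpG and repeat
#' masks); [normalize_mask()] is applied on construction so intervals are
#' sorted and non-overlapping.
#'
#' @param chrom,start,end interval coordinates, BED convention (0-based
#'   half-open).
#' @return An object of class `mask_track`.
#' @export
mask_track <- function(chrom, start, end) {
  start <- as.numeric(start)
  end <- as.numeric(end)
  if (any(start >= end)) stop("mask intervals need start < end")
  normalize_mask(structure(
    data.frame(chrom = as.character(chrom), start = start, end = end,
               stringsAsFactors = FALSE),
    class = c("mask_track", "data.frame")))
}

#' Sort and merge mask intervals
#'
#' @param mask a `mask_track`.
#' @return The mask with overlapping/adjacent intervals merged per
#'   chromosome.
#' @export
normalize_mask <- function(mask) {
  pieces <- lapply(split(mask, mask$chrom), function(d) {
    d <- d[order(d$start, d$end), , drop = FALSE]
    if (nrow(d) <= 1L) return(d)
    keep_start <- d$start[1]
    starts <- ends <- numeric(0)
    cur_end <- d$end[1]
    for (i in seq_len(nrow(d))[-1]) {
      if (d$start[i] <= cur_end) {
        cur_end <- max(cur_end, d$end[i])
      } else {
        starts <- c(starts, keep_start); ends <- c(ends, cur_end)
        keep_start <- d$start[i]; cur_end <- d$end[i]
      }
    }
    starts <- c(starts, keep_start); ends <- c(ends, cur_end)
    data.frame(chrom = d$chrom[1], start = starts, end = ends,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, pieces)
  rownames(out) <- NULL
  class(out) <- c("mask_track", "data.frame")
  out
}

#' Read a BED mask file
#'
#' @param path BED file (chrom, start, end; 0-based half-open; no header).
#' @return A [mask_track()].
#' @export
read_mask <- function(path) {
  df <- utils::read.table(path, header = FALSE, sep = "\t",
                          stringsAsFactors = FALSE)
  mask_track(df[[1]], df[[2]], df[[3]])
}

#' Remove sites that fall inside mask intervals
#'
#' A site at 1-based position p is masked when a BED interval
#' \[start, end) satisfies start < p <= end (i.e. p - 1 in \[start, end)).
#'
#' @param gm a [genotype_matrix()].
#' @param mask a [mask_track()].
#' @return `gm` restricted to unmasked sites.
#' @export
apply_mask <- function(gm, mask) {
  if (nrow(mask) == 0L) return(gm)
  masked <- logical(length(gm$pos))
  for (ch in unique(gm$chrom)) {
    mi <- mask$chrom == ch
    if (!any(mi)) next
    starts <- mask$start[mi]
    ends <- mask$end[mi]
    si <- which(gm$chrom == ch)
    p0 <- gm$pos[si] - 1L  # to 0-based
    k <- findInterval(p0, starts)
    masked[si] <- k > 0L & p0 < ends[pmax(k, 1L)]
  }
  subset_sites(gm, !masked)
}

#' Per-population derived-allele counts and frequencies
#'
#' @param gm a complete, polarized [genotype_matrix()].
#' @param pop population label.
#' @return list with `d` (per-site derived-allele count), `n` (total allele
#'   count, 2 x individuals) and `f` (= d/n).
#' @export
pop_allele_freq <- function(gm, pop) {
  cols <- gm$populations == pop
  if (!any(cols)) stop("no individuals in population '", pop, "'")
  if (anyNA(gm$dosage[, cols]))
    stop("allele frequencies need complete genotypes; run filter_complete()")
  d <- rowSums(gm$dosage[, cols, drop = FALSE])
  n <- 2L * sum(cols)
  list(d = d, n = n, f = d / n)
}
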