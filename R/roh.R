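#' Parameters for run-of-homozygosity detection
#'
#' Defaults reproduce a PLINK `--homozyg` configuration commonly used for
#' inbreeding scans in birds: 100-SNP sliding windows allowing one
#' heterozygote, a 5% window-hit threshold, and segment filters of >= 25
#' SNPs, >= 100 kb, density of at most 50 kb per SNP, a maximum inter-SNP
#' gap of 1000 kb, and up to 750 heterozygous calls per segment (the large
#' segment-level allowance keeps sequencing errors from cutting long ROH).
#'
#' @param window_snp SNPs per sliding window.
#' @param window_het maximum heterozygous calls for a window to count as
#'   homozygous.
#' @param window_threshold minimum fraction of overlapping homozygous
#'   windows for a SNP to be in a homozygous run.
#' @param min_snp minimum SNPs per reported segment.
#' @param min_kb minimum segment length (kb).
#' @param density_kb maximum kb per SNP within a segment.
#' @param gap_kb maximum gap between neighboring SNPs (kb).
#' @param seg_het maximum heterozygous calls per segment.
#' @return list of class `roh_params`.
#' @export
roh_params <- function(window_snp = 100, window_het = 1,
                       window_threshold = 0.05, min_snp = 25, min_kb = 100,
                       density_kb = 50, gap_kb = 1000, seg_het = 750) {
  p <- list(window_snp = as.integer(window_snp),
            window_het = as.integer(window_het),
            window_threshold = window_threshold,
            min_snp = as.integer(min_snp), min_kb = min_kb,
            density_kb = density_kb, gap_kb = gap_kb,
            seg_het = as.integer(seg_het))
  if (any(unlist(p) <= 0) && p$window_het != 0)
    stop("roh_params must be positive (window_het may be 0)")
  if (p$min_kb > p$gap_kb) stop("min_kb must be <= gap_kb")
  class(p) <- "roh_params"
  p
}

#' Stricter sensitivity-check parameter set
#'
#' Variant configuration used to test robustness of ROH calls: no
#' heterozygotes per segment beyond one per window rule (`seg_het = 1`),
#' density 100 kb per SNP and maximum gap 500 kb.
#'
#' @return list of class `roh_params`.
#' @export
roh_params_strict <- function() {
  roh_params(seg_het = 1, density_kb = 100, gap_kb = 500)
}

#' Detect runs of homozygosity for one individual
#'
#' Slides windows of `window_snp` consecutive SNPs (one SNP at a time,
#' windows fully inside the chromosome). A window is homozygous when it
#' contains at most `window_het` heterozygous calls; a SNP is "in run" when
#' at least `window_threshold` of the windows overlapping it are homozygous.
#' Maximal stretches of in-run SNPs are split wherever neighboring SNPs are
#' more than `gap_kb` apart, then filtered on SNP count, physical length,
#' SNP density and segment heterozygote count. Segment bounds are the first
#' and last SNP coordinates.
#'
#' @param gm a complete [genotype_matrix()].
#' @param individual sample id or column index.
#' @param params a [roh_params()].
#' @return data frame of class `roh_segments`: chrom, start, end (1-based
#'   inclusive SNP coordinates), length_bp, n_snps, n_het.
#' @export
detect_roh <- function(gm, individual, params = roh_params()) {
  if (is.character(individual))
    individual <- match(individual, gm$sample_ids)
  if (is.na(individual)) stop("unknown individual")
  g <- gm$dosage[, individual]
  if (anyNA(g)) stop("detect_roh() needs complete genotypes")
  segs <- list()
  for (ch in unique(gm$chrom)) {
    si <- which(gm$chrom == ch)
    pos <- gm$pos[si]
    het <- as.integer(g[si] == 1L)
    n <- length(si)
    w <- params$window_snp
    if (n < w) {
      warning("chromosome ", ch, " has fewer than ", w, " SNPs; skipped")
      next
    }
    # het count per window via cumulative sums; window k covers SNPs k..k+w-1
    cs <- c(0L, cumsum(het))
    n_win <- n - w + 1L
    win_het <- cs[(w + 1L):(n + 1L)] - cs[1:n_win]
    hom_win <- as.integer(win_het <= params$window_het)
    # SNP i is covered by windows max(1, i-w+1) .. min(n_win, i)
    cw <- c(0L, cumsum(hom_win))
    lo <- pmax(1L, seq_len(n) - w + 1L)
    hi <- pmin(n_win, seq_len(n))
    frac <- (cw[hi + 1L] - cw[lo]) / (hi - lo + 1L)
    in_run <- frac >= params$window_threshold
    if (!any(in_run)) next
    r <- rle(in_run)
    ends_i <- cumsum(r$lengths)
    starts_i <- ends_i - r$lengths + 1L
    for (k in which(r$values)) {
      idx <- starts_i[k]:ends_i[k]
      # split where inter-SNP gap exceeds gap_kb
      gaps <- diff(pos[idx])
      brk <- which(gaps > params$gap_kb * 1000)
      piece_start <- c(1L, brk + 1L)
      piece_end <- c(brk, length(idx))
      for (pc in seq_along(piece_start)) {
        ii <- idx[piece_start[pc]:piece_end[pc]]
        n_snps <- length(ii)
        len <- pos[ii[n_snps]] - pos[ii[1]] + 1L
        n_het_seg <- sum(het[ii])
        if (n_snps >= params$min_snp &&
            len >= params$min_kb * 1000 &&
            (len / 1000) / n_snps <= params$density_kb &&
            n_het_seg <= params$seg_het) {
          segs[[length(segs) + 1L]] <-
            data.frame(chrom = ch, start = pos[ii[1]], end = pos[ii[n_snps]],
                       length_bp = len, n_snps = n_snps, n_het = n_het_seg,
                       stringsAsFactors = FALSE)
        }
      }
    }
  }
  out <- if (length(segs)) do.call(rbind, segs) else
    data.frame(chrom = character(0), start = integer(0), end = integer(0),
               length_bp = integer(0), n_snps = integer(0),
               n_het = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  class(out) <- c("roh_segments", "data.frame")
  out
}

#' Detect ROH for every individual
#'
#' @param gm a complete [genotype_matrix()].
#' @param params a [roh_params()].
#' @return named list of `roh_segments`, one per individual.
#' @export
detect_roh_all <- function(gm, params = roh_params()) {
  out <- lapply(seq_along(gm$sample_ids),
                function(i) suppressWarnings(detect_roh(gm, i, params)))
  names(out) <- gm$sample_ids
  out
}

#' Genomic inbreeding coefficient F_ROH
#'
#' Fraction of the genome contained in ROH at or above each length
#' threshold.
#'
#' @param segments an `roh_segments` data frame (one individual).
#' @param genome_length denominator in bp (e.g. assembly length or covered
#'   span).
#' @param min_lengths length thresholds in bp (default >= 100 kb and
#'   >= 2 Mb).
#' @return data frame: min_length_bp, roh_bp, froh.
#' @export
froh <- function(segments, genome_length, min_lengths = c(1e5, 2e6)) {
  if (genome_length <= 0) stop("genome_length must be positive")
  data.frame(min_length_bp = min_lengths,
             roh_bp = vapply(min_lengths, function(ml)
               sum(as.numeric(segments$length_bp[segments$length_bp >= ml])),
               numeric(1)),
             froh = vapply(min_lengths, function(ml)
               sum(as.numeric(segments$length_bp[segments$length_bp >= ml])) /
                 genome_length, numeric(1)))
}

#' Covered genomic span of a genotype matrix
#'
#' Default F_ROH denominator: the per-chromosome span between first and last
#' analyzed site, summed over chromosomes.
#'
#' @param gm a [genotype_matrix()].
#' @return total span in bp.
#' @export
covered_span <- function(gm) {
  sum(vapply(split(gm$pos, gm$chrom), function(p) diff(range(p)) + 1,
             numeric(1)))
}

in_segments <- function(chrom, pos, segments) {
  hit <- logical(length(pos))
  if (nrow(segments) == 0L) return(hit)
  for (ch in unique(segments$chrom)) {
    segs <- segments[segments$chrom == ch, , drop = FALSE]
    segs <- segs[order(segs$start), , drop = FALSE]
    si <- which(chrom == ch)
    if (!length(si)) next
    k <- findInterval(pos[si], segs$start)
    hit[si] <- k > 0L & pos[si] <= segs$end[pmax(k, 1L)]
  }
  hit
}

#' Loss-of-function rates inside versus outside ROH
#'
#' Tests whether recessive LoF (HIGH-impact) variants are depleted inside
#' runs of homozygosity, where purifying selection has had the chance to see
#' them as homozygotes. Per individual, the LoF variant-site rate (sites
#' carrying at least one derived allele; `hom_only = TRUE` restricts to
#' homozygous-derived sites) is normalized by the rate of homozygous
#' synonymous (LOW-impact) sites in the same regions, separately inside and
#' outside the individual's ROH; a paired two-sided t test compares the two
#' normalized rates across individuals.
#'
#' @param gm a complete, polarized [genotype_matrix()].
#' @param ann a [site_annotation()].
#' @param segments_by_individual named list of `roh_segments` (see
#'   [detect_roh_all()]).
#' @param hom_only count only homozygous-derived LoF sites (default `FALSE`).
#' @return list of class `lof_roh_contrast`: `rates` (per-individual data
#'   frame with counts and normalized rates in/out) and `test` (the paired
#'   `htest`, or `NULL` when fewer than 2 usable individuals).
#' @export
lof_roh_contrast <- function(gm, ann, segments_by_individual,
                             hom_only = FALSE) {
  ann <- align_annotation(ann, gm)
  is_lof <- ann$impact == "HIGH"
  is_syn <- ann$impact == "LOW"
  rows <- lapply(seq_along(gm$sample_ids), function(i) {
    segs <- segments_by_individual[[gm$sample_ids[i]]]
    if (is.null(segs)) segs <- segments_by_individual[[i]]
    inside <- in_segments(gm$chrom, gm$pos, segs)
    g <- gm$dosage[, i]
    lof_carrier <- if (hom_only) g == 2L else g >= 1L
    syn_hom <- g == 2L
    lof_in <- sum(lof_carrier & is_lof & inside)
    lof_out <- sum(lof_carrier & is_lof & !inside)
    syn_in <- sum(syn_hom & is_syn & inside)
    syn_out <- sum(syn_hom & is_syn & !inside)
    data.frame(sample_id = gm$sample_ids[i], population = gm$populations[i],
               lof_in = lof_in, syn_in = syn_in, lof_out = lof_out,
               syn_out = syn_out,
               rate_in = if (syn_in > 0) lof_in / syn_in else NA_real_,
               rate_out = if (syn_out > 0) lof_out / syn_out else NA_real_,
               stringsAsFactors = FALSE)
  })
  rates <- do.call(rbind, rows)
  rownames(rates) <- NULL
  ok <- stats::complete.cases(rates[, c("rate_in", "rate_out")])
  test <- NULL
  if (sum(ok) >= 2L && stats::sd(rates$rate_in[ok] - rates$rate_out[ok]) > 0)
    test <- stats::t.test(rates$rate_in[ok], rates$rate_out[ok],
                          paired = TRUE)
  structure(list(rates = rates, test = test, n_used = sum(ok)),
            class = "lof_roh_contrast")
}
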