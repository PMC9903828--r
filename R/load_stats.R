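#' GERP-weighted relative mutational load per individual
#'
#' For each individual, the sum over sites with GERP score above `threshold`
#' of (derived-allele dosage x GERP score), divided by the individual's total
#' number of derived alleles over all sites (heterozygous sites contribute
#' one allele, homozygous-derived sites two). Higher values mean a larger
#' share of an individual's derived alleles sit at evolutionarily constrained
#' sites.
#'
#' @param gm a complete, polarized [genotype_matrix()].
#' @param ann a [site_annotation()] with GERP scores.
#' @param threshold GERP cutoff above which a site counts as deleterious
#'   (default 2).
#' @return data frame of class `relative_load_result`: `sample_id`,
#'   `population`, `load`, `n_derived` (denominator), `n_derived_weighted`
#'   (numerator); attribute `"threshold"`.
#' @export
relative_load <- function(gm, ann, threshold = 2) {
  ann <- align_annotation(ann, gm)
  if (anyNA(gm$dosage))
    stop("relative_load() needs complete genotypes; run filter_complete()")
  above <- !is.na(ann$gerp) & ann$gerp > threshold
  w <- ifelse(above, ann$gerp, 0)
  num <- colSums(gm$dosage * w)
  den <- colSums(gm$dosage)
  load <- ifelse(den > 0, num / den, NA_real_)
  out <- data.frame(sample_id = gm$sample_ids, population = gm$populations,
                    load = load, n_derived = den, n_derived_weighted = num,
                    stringsAsFactors = FALSE)
  attr(out, "threshold") <- threshold
  class(out) <- c("relative_load_result", "data.frame")
  out
}

#' Per-individual variant counts by impact category and zygosity
#'
#' Counts heterozygous and homozygous-derived sites per individual in each
#' SnpEff impact category, and (when two populations are present or named)
#' compares per-individual counts between populations with Welch two-sample
#' t tests.
#'
#' @param gm a complete, polarized [genotype_matrix()].
#' @param ann a [site_annotation()].
#' @param pops optional length-2 character vector naming the populations to
#'   compare; defaults to the two populations in `gm` when exactly two exist.
#' @param categories impact categories to tabulate.
#' @return list of class `impact_counts` with elements `counts` (long data
#'   frame: sample_id, population, category, het, hom, total = het + 2 hom)
#'   and `tests` (Welch t-test table per category and zygosity, or `NULL`).
#' @export
impact_counts <- function(gm, ann, pops = NULL,
                          categories = c("LOW", "MODERATE", "HIGH", "MODIFIER")) {
  ann <- align_annotation(ann, gm)
  if (anyNA(gm$dosage))
    stop("impact_counts() needs complete genotypes")
  rows <- list()
  for (cat in categories) {
    sel <- ann$impact == cat
    d <- gm$dosage[sel, , drop = FALSE]
    het <- colSums(d == 1L)
    hom <- colSums(d == 2L)
    rows[[cat]] <- data.frame(sample_id = gm$sample_ids,
                              population = gm$populations,
                              category = cat, het = het, hom = hom,
                              total = het + 2L * hom,
                              stringsAsFactors = FALSE)
  }
  counts <- do.call(rbind, rows)
  rownames(counts) <- NULL
  if (is.null(pops)) {
    u <- unique(gm$populations)
    pops <- if (length(u) == 2L) u else NULL
  }
  tests <- NULL
  if (!is.null(pops)) {
    tests <- do.call(rbind, lapply(categories, function(cat) {
      cc <- counts[counts$category == cat, ]
      do.call(rbind, lapply(c("het", "hom", "total"), function(what) {
        x <- cc[[what]][cc$population == pops[1]]
        y <- cc[[what]][cc$population == pops[2]]
        if (length(x) < 2L || length(y) < 2L ||
            (stats::sd(x) == 0 && stats::sd(y) == 0)) {
          p <- if (isTRUE(all.equal(mean(x), mean(y)))) 1 else NA_real_
          tt <- list(statistic = NA_real_, parameter = NA_real_, p.value = p)
        } else tt <- stats::t.test(x, y)
        data.frame(category = cat, measure = what,
                   mean_x = mean(x), mean_y = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value,
                   stars = p_stars(tt$p.value),
                   stringsAsFactors = FALSE)
      }))
    }))
    attr(tests, "populations") <- pops
    rownames(tests) <- NULL
  }
  structure(list(counts = counts, tests = tests), class = "impact_counts")
}

p_stars <- function(p) {
  if (is.na(p)) return("")
  if (p < 0.001) "***" else if (p < 0.01) "**" else if (p < 0.05) "*" else ""
}

#' R_xy statistic from derived-allele frequency vectors
#'
#' Core evaluation of the cross-population frequency ratio
#' R_xy = sum_i f_x(i) (1 - f_y(i)) / sum_i f_y(i) (1 - f_x(i)), with a
#' delete-one-block jackknife over consecutive sites for the standard error.
#' Values below 1 indicate a relative deficit of derived alleles in
#' population x; 1 means no frequency change.
#'
#' @param fx,fy derived-allele frequencies per site in populations x and y
#'   (equal length, already restricted to eligible sites in genome order).
#' @param block jackknife block size in sites (default 1000).
#' @return list of class `rxy_result`: `estimate`, `se`, `ci` (normal 95%),
#'   `n_sites`, `block`, `n_blocks`, `status` ("ok", "undefined" when the
#'   denominator sum is zero, or "no_ci" with fewer than 2 blocks).
#' @export
rxy_from_freq <- function(fx, fy, block = 1000) {
  stopifnot(length(fx) == length(fy))
  num_terms <- fx * (1 - fy)
  den_terms <- fy * (1 - fx)
  num <- sum(num_terms)
  den <- sum(den_terms)
  n <- length(fx)
  res <- list(estimate = NA_real_, se = NA_real_, ci = c(NA_real_, NA_real_),
              n_sites = n, block = block, n_blocks = 0L, status = "undefined")
  class(res) <- "rxy_result"
  if (den == 0) return(res)
  res$estimate <- num / den
  res$status <- "ok"
  # blocks of consecutive sites; short tail kept if >= block/2, else merged
  nb <- n %/% block
  if (n %% block >= block / 2) nb <- nb + 1L
  if (nb < 2L) {
    res$status <- "no_ci"
    return(res)
  }
  bounds <- floor(seq(0L, n, length.out = nb + 1L))
  est_loo <- vapply(seq_len(nb), function(b) {
    i <- (bounds[b] + 1L):bounds[b + 1L]
    (num - sum(num_terms[i])) / (den - sum(den_terms[i]))
  }, numeric(1))
  est_loo <- est_loo[is.finite(est_loo)]
  nb_ok <- length(est_loo)
  if (nb_ok < 2L) {
    res$status <- "no_ci"
    return(res)
  }
  se <- sqrt((nb_ok - 1) / nb_ok * sum((est_loo - mean(est_loo))^2))
  res$se <- se
  res$ci <- res$estimate + c(-1.96, 1.96) * se
  res$n_blocks <- nb_ok
  res
}

#' @export
print.rxy_result <- function(x, ...) {
  cat(sprintf("R_xy = %.4f (SE %.4f, 95%% CI %.4f-%.4f), %d sites in %d blocks [%s]\n",
              x$estimate, x$se, x$ci[1], x$ci[2], x$n_sites, x$n_blocks,
              x$status))
  invisible(x)
}

#' R_xy derived-allele frequency ratio between two populations
#'
#' Computes per-site derived-allele frequencies in each population for one
#' impact category and evaluates [rxy_from_freq()] over eligible sites.
#' Default eligibility requires at least one derived allele in *each*
#' population (`eligibility = "both"`); `"union"` requires one derived allele
#' across the pooled populations.
#'
#' @param gm a complete, polarized [genotype_matrix()].
#' @param pop_x,pop_y population labels.
#' @param ann optional [site_annotation()]; required when `category` is set.
#' @param category impact category to restrict to (`NULL` = all sites).
#' @param block jackknife block size in eligible sites.
#' @param eligibility `"both"` (default) or `"union"`.
#' @return An `rxy_result` (see [rxy_from_freq()]).
#' @export
rxy <- function(gm, pop_x, pop_y, ann = NULL, category = NULL,
                block = 1000, eligibility = c("both", "union")) {
  eligibility <- match.arg(eligibility)
  keep <- rep(TRUE, length(gm$pos))
  if (!is.null(category)) {
    if (is.null(ann)) stop("category filtering needs an annotation")
    ann <- align_annotation(ann, gm)
    keep <- ann$impact == category
  }
  fq_x <- pop_allele_freq(gm, pop_x)
  fq_y <- pop_allele_freq(gm, pop_y)
  elig <- if (eligibility == "both") fq_x$d >= 1L & fq_y$d >= 1L
          else (fq_x$d + fq_y$d) >= 1L
  sel <- keep & elig
  rxy_from_freq(fq_x$f[sel], fq_y$f[sel], block = block)
}

#' Pairwise genotype distance matrix
#'
#' For each pair of individuals the per-site distance d is 0 when both are
#' homozygous for the same allele, 1 when homozygous for opposite alleles,
#' and 0.5 when either genotype is heterozygous; D_ij is the sum of d over
#' the M compared sites divided by the normalizer L (by default L = M, so
#' D is in \[0, 1\]; `normalize = "bp"` divides by the physical span of the
#' sites instead).
#'
#' @param gm a complete [genotype_matrix()].
#' @param normalize `"sites"` (default) or `"bp"`.
#' @return symmetric numeric matrix with sample ids as dimnames; attributes
#'   `"M"` (site count) and `"L"` (normalizer).
#' @export
distance_matrix <- function(gm, normalize = c("sites", "bp")) {
  normalize <- match.arg(normalize)
  if (anyNA(gm$dosage)) stop("distance_matrix() needs complete genotypes")
  g <- gm$dosage
  n <- ncol(g)
  M <- nrow(g)
  L <- if (normalize == "sites") M else {
    sum(vapply(split(gm$pos, gm$chrom), function(p) diff(range(p)) + 1,
               numeric(1)))
  }
  het <- g == 1L
  D <- matrix(0, n, n, dimnames = list(gm$sample_ids, gm$sample_ids))
  for (i in seq_len(n - 1L)) {
    gi <- g[, i]
    hi <- het[, i]
    for (j in (i + 1L):n) {
      anyhet <- hi | het[, j]
      d <- ifelse(anyhet, 0.5, abs(gi - g[, j]) / 2)
      D[i, j] <- D[j, i] <- sum(d) / L
    }
  }
  attr(D, "M") <- M
  attr(D, "L") <- L
  D
}

#' Neighbor-joining tree from a genotype distance matrix
#'
#' Standard Saitou-Nei neighbor joining (via \pkg{ape}) on the output of
#' [distance_matrix()].
#'
#' @param dm symmetric distance matrix with sample-id dimnames.
#' @param file optional path; when given, the tree is also written in newick
#'   format.
#' @return an \pkg{ape} `phylo` object (unrooted).
#' @export
nj_tree <- function(dm, file = NULL) {
  if (nrow(dm) < 3L) stop("neighbor joining needs at least 3 individuals")
  tr <- ape::nj(stats::as.dist(dm))
  if (!is.null(file)) ape::write.tree(tr, file = file)
  tr
}
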