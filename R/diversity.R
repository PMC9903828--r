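#' Windowed nucleotide diversity and individual heterozygosity
#'
#' Nucleotide diversity per window is the sum over segregating sites of the
#' unbiased per-site estimator 2 f (1 - f) n / (n - 1) (n = number of called
#' alleles), divided by the window length in bp. Windows tile each
#' chromosome from position 1 in steps of `window`; windows past the last
#' site are not reported. Individual heterozygosity is the number of
#' heterozygous sites per kb of covered span.
#'
#' @param gm a complete [genotype_matrix()].
#' @param window window size in bp (default 10000, i.e. 10 kb).
#' @return list of class `diversity_result` with `windows` (data frame:
#'   chrom, start, end \[0-based half-open\], n_sites, pi) and
#'   `heterozygosity` (data frame: sample_id, population, n_het, covered_kb,
#'   het_per_kb).
#' @export
diversity <- function(gm, window = 10000) {
  if (anyNA(gm$dosage)) stop("diversity() needs complete genotypes")
  n_allele <- 2L * ncol(gm$dosage)
  f <- rowSums(gm$dosage) / n_allele
  persite <- 2 * f * (1 - f) * n_allele / (n_allele - 1L)
  win_rows <- lapply(unique(gm$chrom), function(ch) {
    si <- gm$chrom == ch
    p <- gm$pos[si]
    ps <- persite[si]
    wi <- (p - 1L) %/% window           # 0-based window index
    n_win <- max(wi) + 1L
    sums <- vapply(seq_len(n_win) - 1L, function(w) sum(ps[wi == w]),
                   numeric(1))
    counts <- tabulate(wi + 1L, nbins = n_win)
    data.frame(chrom = ch, start = (seq_len(n_win) - 1L) * window,
               end = seq_len(n_win) * window, n_sites = counts,
               pi = sums / window, stringsAsFactors = FALSE)
  })
  windows <- do.call(rbind, win_rows)
  rownames(windows) <- NULL
  covered_bp <- sum(vapply(split(gm$pos, gm$chrom),
                           function(p) diff(range(p)) + 1, numeric(1)))
  n_het <- colSums(gm$dosage == 1L)
  het <- data.frame(sample_id = gm$sample_ids, population = gm$populations,
                    n_het = n_het, covered_kb = covered_bp / 1000,
                    het_per_kb = n_het / (covered_bp / 1000),
                    stringsAsFactors = FALSE)
  rownames(het) <- NULL
  structure(list(windows = windows, heterozygosity = het),
            class = "diversity_result")
}
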