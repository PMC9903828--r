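# shared fixture builders and brute-force oracles

# quick genotype_matrix around a dosage matrix (sites x individuals)
make_gm <- function(dosage, chrom = NULL, pos = NULL, pops = NULL,
                    ref = NULL, alt = NULL) {
  dosage <- as.matrix(dosage)
  n <- nrow(dosage)
  k <- ncol(dosage)
  if (is.null(chrom)) chrom <- rep("chr1", n)
  if (is.null(pos)) pos <- seq_len(n) * 100L
  if (is.null(pops)) pops <- rep(c("popA", "popB"), length.out = k)
  genotype_matrix(chrom, pos, dosage, sprintf("ind%02d", seq_len(k)), pops,
                  ref = ref, alt = alt)
}

make_ann <- function(gm, gerp = NULL, impact = NULL, ancestral = NULL) {
  n <- length(gm$pos)
  if (is.null(gerp)) gerp <- rep(0, n)
  if (is.null(impact)) impact <- rep("NONE", n)
  if (is.null(ancestral))
    ancestral <- if (is.null(gm$ref)) rep("A", n) else gm$ref
  site_annotation(gm$chrom, gm$pos, gerp, impact, ancestral)
}

# brute-force per-pair per-site genotype distance
oracle_distance <- function(dosage) {
  k <- ncol(dosage)
  D <- matrix(0, k, k)
  for (i in seq_len(k)) for (j in seq_len(k)) {
    if (i == j) next
    d <- 0
    for (m in seq_len(nrow(dosage))) {
      gi <- dosage[m, i]; gj <- dosage[m, j]
      d <- d + if (gi == 1 || gj == 1) 0.5 else if (gi == gj) 0 else 1
    }
    D[i, j] <- d / nrow(dosage)
  }
  D
}

# brute-force ROH caller implementing the sliding-window rule literally
oracle_roh <- function(pos, het, params) {
  n <- length(pos)
  w <- params$window_snp
  if (n < w) return(data.frame(start = integer(0), end = integer(0),
                               n_snps = integer(0), n_het = integer(0)))
  n_win <- n - w + 1L
  hom_win <- logical(n_win)
  for (k in seq_len(n_win))
    hom_win[k] <- sum(het[k:(k + w - 1L)]) <= params$window_het
  in_run <- logical(n)
  for (i in seq_len(n)) {
    wins <- max(1L, i - w + 1L):min(n_win, i)
    in_run[i] <- mean(hom_win[wins]) >= params$window_threshold
  }
  segs <- list()
  i <- 1L
  while (i <= n) {
    if (!in_run[i]) { i <- i + 1L; next }
    j <- i
    while (j < n && in_run[j + 1L]) j <- j + 1L
    # split at gaps
    idx <- i:j
    pieces <- split(idx, cumsum(c(0, diff(pos[idx]) > params$gap_kb * 1000)))
    for (pc in pieces) {
      len <- pos[pc[length(pc)]] - pos[pc[1]] + 1
      nh <- sum(het[pc])
      if (length(pc) >= params$min_snp && len >= params$min_kb * 1000 &&
          (len / 1000) / length(pc) <= params$density_kb &&
          nh <= params$seg_het)
        segs[[length(segs) + 1L]] <- data.frame(start = pos[pc[1]],
                                                end = pos[pc[length(pc)]],
                                                n_snps = length(pc),
                                                n_het = nh)
    }
    i <- j + 1L
  }
  if (!length(segs)) return(data.frame(start = integer(0), end = integer(0),
                                       n_snps = integer(0),
                                       n_het = integer(0)))
  do.call(rbind, segs)
}

# one-individual genotype matrix from a heterozygosity indicator vector
gm_from_het <- function(pos, het, chrom = "chr1") {
  dos <- cbind(ifelse(het, 1L, 0L), 0L)
  make_gm(dos, chrom = rep(chrom, length(pos)), pos = pos,
          pops = c("p", "p"))
}
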