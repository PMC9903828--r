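test_that("relative load evaluates the GERP-weighted ratio", {
  # one individual: hom gerp 3, het gerp 2.5, hom gerp 1
  # load = (2*3 + 1*2.5) / (2 + 1 + 2) = 1.7
  dos <- cbind(c(2L, 1L, 2L), c(0L, 0L, 1L))
  gm <- make_gm(dos, pops = c("p", "p"))
  ann <- make_ann(gm, gerp = c(3, 2.5, 1))
  res <- relative_load(gm, ann, threshold = 2)
  expect_equal(res$load[1], (2 * 3 + 1 * 2.5) / (2 + 1 + 2))
  # second individual: only one derived allele, below threshold -> load 0
  expect_equal(res$load[2], 0)
  expect_equal(res$n_derived, c(5, 1))
})

test_that("relative load handles single-site and empty denominators", {
  dos <- cbind(c(2L), c(0L))
  gm <- make_gm(dos, pops = c("p", "p"))
  ann <- make_ann(gm, gerp = 3)
  res <- relative_load(gm, ann)
  expect_equal(res$load[1], 3)          # (2*3)/2
  expect_true(is.na(res$load[2]))       # no derived alleles at all
})

test_that("relative load scales linearly with the GERP scores", {
  set.seed(10)
  dos <- matrix(rbinom(300 * 4, 2, 0.4), 300, 4)
  gm <- make_gm(dos, pops = rep("p", 4))
  gerp <- runif(300, -2, 6)
  ann <- make_ann(gm, gerp = gerp)
  base <- relative_load(gm, ann, threshold = 2)
  ann2 <- make_ann(gm, gerp = 3 * gerp)
  scaled <- relative_load(gm, ann2, threshold = 6)
  expect_equal(scaled$load, 3 * base$load)
})

test_that("impact counts split het and hom and satisfy the dosage identity", {
  dos <- cbind(c(2L, 2L, 1L, 0L, 0L), c(1L, 1L, 1L, 1L, 1L))
  gm <- make_gm(dos, pops = c("p", "p"))
  ann <- make_ann(gm, impact = rep("HIGH", 5))
  res <- impact_counts(gm, ann)
  hi <- res$counts[res$counts$category == "HIGH", ]
  expect_equal(hi$hom, c(2L, 0L))
  expect_equal(hi$het, c(1L, 5L))
  expect_equal(hi$total, hi$het + 2L * hi$hom)
  # all-reference individual: zero everywhere
  dos0 <- cbind(rep(0L, 5), rep(0L, 5))
  res0 <- impact_counts(make_gm(dos0, pops = c("p", "p")),
                        make_ann(make_gm(dos0, pops = c("p", "p")),
                                 impact = rep("MODERATE", 5)))
  expect_true(all(res0$counts[, c("het", "hom", "total")] == 0L))
})

test_that("impact counts are invariant under site permutation and the Welch
           test matches the textbook formula", {
  set.seed(11)
  n <- 400
  dos_a <- matrix(rbinom(n * 5, 2, 0.45), n, 5)
  dos_b <- matrix(rbinom(n * 5, 2, 0.25), n, 5)
  dos <- cbind(dos_a, dos_b)
  pops <- rep(c("main", "island"), each = 5)
  impact <- sample(c("LOW", "MODERATE", "HIGH", "MODIFIER"), n, TRUE)
  gm <- make_gm(dos, pops = pops)
  ann <- make_ann(gm, impact = impact)
  res <- impact_counts(gm, ann, pops = c("main", "island"))
  # permutation invariance: permute sites (rows) jointly with annotations
  perm <- sample(n)
  gm_p <- make_gm(dos[perm, ], pops = pops)
  ann_p <- make_ann(gm_p, impact = impact[perm])
  res_p <- impact_counts(gm_p, ann_p, pops = c("main", "island"))
  expect_equal(res$counts$total, res_p$counts$total)
  expect_equal(res$counts$het, res_p$counts$het)
  # Welch statistic against the explicit formula
  tot <- res$counts[res$counts$category == "HIGH" , ]
  x <- tot$total[tot$population == "main"]
  y <- tot$total[tot$population == "island"]
  t_manual <- (mean(x) - mean(y)) /
    sqrt(var(x) / length(x) + var(y) / length(y))
  trow <- res$tests[res$tests$category == "HIGH" &
                      res$tests$measure == "total", ]
  expect_equal(trow$t, t_manual, tolerance = 1e-12)
  df_manual <- (var(x) / 5 + var(y) / 5)^2 /
    ((var(x) / 5)^2 / 4 + (var(y) / 5)^2 / 4)
  expect_equal(trow$df, df_manual, tolerance = 1e-12)
})

test_that("R_xy reproduces hand-computed values and edge cases", {
  # hand evaluation of the printed formula
  r <- rxy_from_freq(c(0.5, 0.2), c(0.1, 0.1), block = 1000)
  expect_equal(r$estimate, (0.5 * 0.9 + 0.2 * 0.9) / (0.1 * 0.5 + 0.1 * 0.8))
  expect_equal(r$status, "no_ci")  # a single short block
  # identical frequency vectors give exactly 1
  set.seed(12)
  f <- runif(1000, 0.01, 0.99)
  r1 <- rxy_from_freq(f, f)
  expect_identical(r1$estimate, 1)
  # denominator zero -> undefined
  r0 <- rxy_from_freq(c(1, 1), c(0, 0))
  expect_equal(r0$status, "undefined")
  expect_true(is.na(r0$estimate))
})

test_that("R_xy(x,y) * R_xy(y,x) = 1 and the jackknife CI behaves", {
  set.seed(13)
  fx <- runif(5000, 0.01, 0.99)
  fy <- pmin(pmax(fx * runif(5000, 0.5, 1.5), 0.005), 0.995)
  a <- rxy_from_freq(fx, fy, block = 500)
  b <- rxy_from_freq(fy, fx, block = 500)
  expect_equal(a$estimate * b$estimate, 1, tolerance = 1e-12)
  expect_true(a$ci[1] < a$estimate && a$estimate < a$ci[2])
  expect_equal(a$n_blocks, 10L)
})

test_that("rxy on genotypes respects category and eligibility rules", {
  set.seed(14)
  n <- 2000
  fx <- runif(n, 0.05, 0.6)
  fy <- fx
  sel_high <- sample(n, 600)
  fy[sel_high] <- fx[sel_high] * 0.4   # deficit in y for HIGH sites
  impact <- rep("LOW", n)
  impact[sel_high] <- "HIGH"
  dos <- cbind(matrix(rbinom(n * 30, 2, rep(fx, 30)), n, 30),
               matrix(rbinom(n * 30, 2, rep(fy, 30)), n, 30))
  gm <- make_gm(dos, pops = rep(c("x", "y"), each = 30))
  ann <- make_ann(gm, impact = impact)
  r_high <- rxy(gm, "x", "y", ann = ann, category = "HIGH", block = 100)
  r_low <- rxy(gm, "x", "y", ann = ann, category = "LOW", block = 100)
  expect_gt(r_high$estimate, 1)   # y has the deficit => ratio above 1
  expect_lt(abs(r_low$estimate - 1), 0.2)
  # union eligibility uses at least as many sites as the intersection rule
  r_union <- rxy(gm, "x", "y", ann = ann, category = "HIGH",
                 block = 100, eligibility = "union")
  expect_gte(r_union$n_sites, r_high$n_sites)
})

test_that("distance matrix matches the per-site definition and oracle", {
  # printed worked examples: opposite homozygotes and het pairs
  gm1 <- make_gm(cbind(2L, 0L), pops = c("p", "p"))
  expect_equal(unname(distance_matrix(gm1)[1, 2]), 1)
  gm2 <- make_gm(cbind(1L, 0L), pops = c("p", "p"))
  expect_equal(unname(distance_matrix(gm2)[1, 2]), 0.5)
  gm3 <- make_gm(cbind(1L, 1L), pops = c("p", "p"))
  expect_equal(unname(distance_matrix(gm3)[1, 2]), 0.5)
  gm4 <- make_gm(cbind(2L, 2L), pops = c("p", "p"))
  expect_equal(unname(distance_matrix(gm4)[1, 2]), 0)
  # random fixture vs brute-force double loop
  set.seed(15)
  dos <- matrix(rbinom(1000 * 6, 2, 0.35), 1000, 6)
  gm <- make_gm(dos, pops = rep("p", 6))
  D <- distance_matrix(gm)
  expect_equal(unname(D), oracle_distance(dos), tolerance = 1e-12,
               ignore_attr = TRUE)
  expect_true(all(diag(D) == 0))
  expect_equal(D, t(D))
  expect_true(all(D >= 0 & D <= 1))
})

test_that("neighbor joining recovers an additive tree exactly", {
  # 4-taxon additive matrix built from a known tree:
  # (a:1, b:2):1.5 vs (c:3, d:1)
  D <- matrix(0, 4, 4, dimnames = list(letters[1:4], letters[1:4]))
  D["a", "b"] <- D["b", "a"] <- 3
  D["a", "c"] <- D["c", "a"] <- 5.5
  D["a", "d"] <- D["d", "a"] <- 3.5
  D["b", "c"] <- D["c", "b"] <- 6.5
  D["b", "d"] <- D["d", "b"] <- 4.5
  D["c", "d"] <- D["d", "c"] <- 4
  tr <- nj_tree(D)
  expect_s3_class(tr, "phylo")
  expect_setequal(tr$tip.label, letters[1:4])
  # NJ inverts an additive matrix: patristic distances reproduce D
  expect_equal(ape::cophenetic.phylo(tr)[letters[1:4], letters[1:4]],
               D, tolerance = 1e-12)
  expect_error(nj_tree(D[1:2, 1:2]), "3")
})

test_that("samples cluster by population on planted structure", {
  set.seed(16)
  n <- 800
  fx <- runif(n, 0.1, 0.9)
  fy <- pmin(pmax(fx + runif(n, -0.4, 0.4), 0.02), 0.98)
  dos <- cbind(matrix(rbinom(n * 4, 2, rep(fx, 4)), n, 4),
               matrix(rbinom(n * 4, 2, rep(fy, 4)), n, 4))
  gm <- make_gm(dos, pops = rep(c("x", "y"), each = 4))
  tr <- nj_tree(distance_matrix(gm))
  tr <- ape::root(tr, outgroup = gm$sample_ids[1], resolve.root = TRUE)
  expect_true(ape::is.monophyletic(tr, gm$sample_ids[5:8]))
})
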