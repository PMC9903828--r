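# small helper: a state with n adults of given sexes/ages and no mutations
make_state <- function(n_male, n_female, age = 20, cfg = NULL) {
  if (is.null(cfg))
    cfg <- sim_config(arch = build_architecture(scale = 50),
                      record_pedigree = TRUE)
  st <- sim_new(cfg, n_male + n_female)
  ids <- which(st$alive)
  st$sex[ids] <- rep(c(1L, 2L), c(n_male, n_female))
  st$age[ids] <- age
  st$mat[ids] <- 7L
  st
}

test_that("reproduction requires mature individuals of both sexes", {
  st <- make_state(5, 0)
  expect_equal(sim_reproduce(st), 0L)
  st2 <- make_state(0, 5)
  expect_equal(sim_reproduce(st2), 0L)
  # immature individuals do not breed
  st3 <- make_state(5, 5, age = 3)
  expect_equal(sim_reproduce(st3), 0L)
})

test_that("clutch sizes and newborn sex ratio follow the configuration", {
  set.seed(50)
  st <- make_state(60, 120)
  total <- 0L
  for (i in 1:60) {
    st$age[st$alive & st$age > 15L] <- 15L  # keep parents alive-ish ages
    total <- total + sim_reproduce(st)
    # discard newborns so the breeding pool stays fixed
    born <- which(st$alive & st$age == 0L)
    st$alive[born] <- FALSE
    st$free <- c(st$free, born)
  }
  n_births <- st$births_male + st$births_female
  expect_equal(n_births, total)
  # mean clutch ~ mean of round(N(3, 1.5)) truncated at 0 (~2.98 per nest)
  expect_equal(total / (120 * 60), 3, tolerance = 0.05)
  # sex ratio ~2:1 male within 4 binomial SDs
  p_hat <- st$births_male / n_births
  expect_lt(abs(p_hat - 2 / 3), 4 * sqrt(2 / 9 / n_births))
  # parental ages recorded for every birth
  expect_equal(length(st$ped_mother_age), n_births)
})

test_that("without recombination each gamete copies one parental haplotype", {
  arch <- build_architecture(n_genes = 12, gene_length = 100,
                             n_chromosomes = 1, r = 0, scale = 1)
  cfg <- sim_config(arch = arch, mu_factor = 0)
  st <- make_state(1, 1, cfg = cfg)
  seed_standing_variation(st, 30, 0.5)
  ids <- which(st$alive)
  # make parent haplotypes distinguishable: hap A all 1, hap B all 0
  rows <- seq_len(st$Mn)
  for (i in ids) {
    kakapopg:::H_set(st, rows, 2L * i - 1L, matrix(1L, st$Mn, 1))
    kakapopg:::H_set(st, rows, 2L * i, matrix(0L, st$Mn, 1))
  }
  set.seed(51)
  b <- sim_reproduce(st)
  expect_gt(b, 0)
  born <- which(st$alive & st$age == 0L)
  for (ch in born) {
    for (col in c(2L * ch - 1L, 2L * ch)) {
      hap <- kakapopg:::H_get(st, rows, col)
      expect_true(all(hap == 1L) || all(hap == 0L))
    }
  }
})

test_that("fitness is the product over carried mutations", {
  arch <- build_architecture(n_genes = 10, gene_length = 100,
                             n_chromosomes = 1, scale = 1)
  cfg <- sim_config(arch = arch, mu_factor = 0,
                    dfe = dfe_params(h = 0.25))
  st <- make_state(1, 1, cfg = cfg)
  seed_standing_variation(st, 1, 1)   # one mutation fixed in both parents
  st$s[1] <- -0.5
  st$loghom[1] <- log(0.5)
  st$loghet[1] <- log(1 - 0.25 * 0.5)
  set.seed(52)
  sim_reproduce(st)
  born <- which(st$alive & st$age == 0L)
  # both parents homozygous -> every child homozygous -> w = 1 + s = 0.5
  expect_equal(unname(st$w[born]), rep(0.5, length(born)))
  # all-neutral genomes have w = 1
  st2 <- make_state(1, 1, cfg = sim_config(arch = arch, mu_factor = 0))
  seed_standing_variation(st2, 20, 0.5)
  set.seed(53)
  sim_reproduce(st2)
  born2 <- which(st2$alive & st2$age == 0L)
  expect_true(all(st2$w[born2] == 1))
})

test_that("survival follows base rate x density regulation (binomial check)", {
  set.seed(54)
  st <- make_state(1000, 1000, age = 20)
  n <- sim_survive(st, K = 200)
  p <- 0.975 * (200 / 2000)  # adult base survival x density factor
  expect_lt(abs(n - 2000 * p), 4 * sqrt(2000 * p * (1 - p)))
  # K = 0 wipes the population
  st2 <- make_state(5, 5)
  sim_survive(st2, 0)
  expect_true(st2$extinct)
})

test_that("individuals above the maximum age die", {
  st <- make_state(10, 10, age = 95)
  sim_survive(st, 1000)
  expect_equal(sum(st$alive), 0L)
})

test_that("additive load evaluates the dominance-weighted sum", {
  arch <- build_architecture(n_genes = 10, gene_length = 100,
                             n_chromosomes = 1, scale = 1)
  cfg <- sim_config(arch = arch, mu_factor = 0,
                    dfe = dfe_params(h = 0.25))
  st <- make_state(1, 1, cfg = cfg)
  seed_standing_variation(st, 2, 0)
  st$s[1:2] <- c(-0.01, -0.02)
  id <- which(st$alive)[1]
  kakapopg:::H_set(st, 1:2, 2L * id - 1L, cbind(c(1L, 1L)))
  kakapopg:::H_set(st, 1:2, 2L * id, cbind(c(1L, 0L)))
  # hom -0.01 and het -0.02 with h = 0.25: 0.01 + 0.25 * 0.02 = 0.015
  expect_equal(additive_load(st, id), 0.015)
  # with h = 0 heterozygotes contribute nothing
  st$cfg$dfe$h <- 0
  expect_equal(additive_load(st, id), 0.01)
  # no mutations and no fixed load -> 0
  other <- which(st$alive)[2]
  expect_equal(additive_load(st, other), 0)
})

test_that("a neutral simulation carries zero load throughout", {
  set.seed(55)
  cfg <- sim_config(arch = build_architecture(scale = 50),
                    neutral_only = TRUE, record_pedigree = FALSE)
  st <- sim_new(cfg, 80)
  sim_run(st, rep(80, 120))
  expect_true(all(additive_load(st) == 0))
  sm <- summarize_sample(st, 20)
  expect_true(all(sm$individuals$load == 0))
  expect_true(all(sm$individuals[, c("n_weak", "n_mild", "n_strong")] == 0))
  expect_true(sm$class_means[["neutral"]] >= 0)
})

test_that("carrier counts match a brute-force haplotype scan", {
  set.seed(56)
  cfg <- sim_config(arch = build_architecture(scale = 50),
                    record_pedigree = FALSE)
  st <- sim_new(cfg, 60)
  sim_run(st, rep(60, 150))
  ids <- which(st$alive)
  rows <- seq_len(st$Mn)
  counts <- rowSums(kakapopg:::H_get(st, rows, kakapopg:::alive_cols(st)))
  brute <- integer(st$Mn)
  for (i in ids) {
    brute <- brute + kakapopg:::H_get(st, rows, 2L * i - 1L)[, 1] +
      kakapopg:::H_get(st, rows, 2L * i)[, 1]
  }
  expect_equal(counts, brute)
})

test_that("removing fixed mutations leaves every individual's load intact", {
  arch <- build_architecture(n_genes = 10, gene_length = 100,
                             n_chromosomes = 1, scale = 1)
  cfg <- sim_config(arch = arch, mu_factor = 0)
  st <- make_state(3, 3)
  seed_standing_variation(st, 5, 0.5)
  st$s[1:5] <- c(-0.02, 0, -0.005, -0.1, 0)
  st$loghom[1:5] <- log(pmax(1 + st$s[1:5], 1e-12))
  ids <- which(st$alive)
  # fix mutation 1 and 2 in everyone
  for (i in ids) {
    kakapopg:::H_set(st, 1:2, 2L * i - 1L, cbind(c(1L, 1L)))
    kakapopg:::H_set(st, 1:2, 2L * i, cbind(c(1L, 1L)))
  }
  before <- additive_load(st, ids)
  kakapopg:::sim_cleanup(st)
  expect_equal(st$Mn, 3L)
  expect_equal(st$fixed_load, 0.02)
  expect_equal(additive_load(st, ids), before)
  expect_equal(unname(st$fixed_class[c("neutral", "weak")]), c(1L, 0L))
})

test_that("population regulates around the carrying capacity", {
  set.seed(57)
  cfg <- sim_config(arch = build_architecture(scale = 50),
                    record_pedigree = FALSE, record_every = 5)
  st <- sim_new(cfg, 250)
  sim_run(st, rep(250, 400))
  traj <- sim_trajectory(st)
  late <- traj$N[traj$step > 100]
  expect_lt(abs(mean(late) / 250 - 1), 0.35)
  expect_lt(sd(late) / mean(late), 0.2)  # CV of the regulated census
})

test_that("scenario trajectories decline to the long-term capacity", {
  sc <- demographic_scenario("StewartIsland", steps = 1000)
  K <- scenario_K(sc, scale = 20)
  expect_equal(length(K), 1000L)
  expect_equal(K[1] < 10000 * 2.8 / 20, TRUE)
  expect_equal(K[1000], round(1000 * 2.8 / 20))
  expect_true(all(diff(K) <= 0))
  # constant for the stable scenario
  Ks <- scenario_K(demographic_scenario("Stable", steps = 100), scale = 20)
  expect_true(all(Ks == Ks[1]))
  expect_error(demographic_scenario("Atlantis"), "arg")
  # zero capacity drives immediate extinction with the flag set
  set.seed(58)
  cfg <- sim_config(arch = build_architecture(scale = 50),
                    record_pedigree = FALSE)
  st <- sim_new(cfg, 50)
  res <- run_scenario(demographic_scenario("Stable", steps = 10,
                                           pre_ne = 10000,
                                           long_term_ne = 10000),
                      cfg, state = st)
  expect_false(res$extinct)
  st2 <- sim_new(cfg, 50)
  sim_run(st2, rep(0, 3))
  expect_true(st2$extinct)
})

test_that("realized generation time summarizes parent-offspring links", {
  ped <- list(mother_age = c(10, 20), father_age = numeric(0))
  gt <- realized_generation_time(ped)
  expect_equal(gt$mean, 15)
  expect_equal(gt$sd, sd(c(10, 20)))
  one <- realized_generation_time(list(mother_age = 10, father_age = 10))
  expect_equal(one$mean, 10)
  expect_equal(one$sd, 0)
  expect_error(realized_generation_time(list(mother_age = numeric(0),
                                             father_age = numeric(0))),
               "no parent")
})

test_that("ne_from_decay inverts a synthetic decay curve", {
  G <- 16
  ne_true <- 120
  steps <- seq(10, 2000, by = 10)
  pi <- 0.002 * (1 - 1 / (2 * ne_true))^(steps / G)
  traj <- data.frame(step = steps, pi = pi, N = 400)
  est <- ne_from_decay(traj, G)
  expect_equal(est$ne, ne_true, tolerance = 1e-6)
  expect_equal(est$mean_census, 400)
})

test_that("burn-in without mutation input keeps diversity at zero", {
  set.seed(59)
  cfg <- sim_config(arch = build_architecture(scale = 50), mu_factor = 0,
                    record_pedigree = FALSE)
  st <- burn_in(cfg, K = 100, scaled_steps = 80, equil_steps = 60)
  expect_true(all(sim_trajectory(st)$pi == 0))
  expect_true(is.logical(st$equilibrium))
})

test_that("burn-in reaches a plausible neutral diversity level", {
  set.seed(60)
  cfg <- sim_config(arch = build_architecture(scale = 20),
                    neutral_only = TRUE, record_pedigree = FALSE)
  st <- burn_in(cfg, K = 120, scaled_steps = 500, equil_steps = 250)
  traj <- sim_trajectory(st)
  pi_end <- mean(utils::tail(traj$pi, 5))
  # order-of-magnitude band around theta = 4 K mu (realized Ne is a
  # modest fraction of census, so pi must sit below 4 K mu but well
  # above a tenth of it)
  theta_census <- 4 * 120 * cfg$arch$mu
  expect_gt(pi_end, 0.05 * theta_census)
  expect_lt(pi_end, 1.5 * theta_census)
})

test_that("scenario comparison flags planted differences and identity", {
  set.seed(61)
  mk <- function(mu) {
    lapply(1:8, function(i) {
      load <- rnorm(30, mu, 0.01)
      structure(list(individuals = data.frame(load = load),
                     mean_load = mean(load),
                     class_means = c(neutral = 0, weak = mu * 100,
                                     mild = 0, strong = 0),
                     n = 30, whole_population = FALSE),
                class = "load_summary")
    })
  }
  res <- compare_scenarios(list(A = mk(0.1), B = mk(0.1), C = mk(0.2)))
  ac <- res[res$scenario_a == "A" & res$scenario_b == "C" &
              res$measure == "mean_load", ]
  expect_lt(ac$p_value, 0.01)
  ab <- res[res$scenario_a == "A" & res$scenario_b == "B" &
              res$measure == "mean_load", ]
  expect_gt(ab$p_value, 0.01)
})
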