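#' Life-history parameters for the non-Wright-Fisher simulator
#'
#' Defaults emulate kakapo: strongly male-biased offspring sex ratio (2:1),
#' late and sex-specific maturity (females 7-11 y, males 5-7 y), clutches
#' drawn from round(Normal(3, 1.5)) truncated at zero, and age-weighted male
#' pairing success. One simulation step is one year; generation time is an
#' emergent property, not an input. Baseline survival (first-year 0.33,
#' adult 0.975 per year, maximum age 90) and the saturation of the male
#' experience advantage (cap 6 years) form the free schedule, calibrated
#' jointly so that the realized generation time lands near 16 years and the
#' realized census-to-effective-size ratio near the 2.8 design factor;
#' under density regulation it is the juvenile-to-adult survival ratio, not
#' the absolute level, that sets the realized age structure.
#'
#' @param female_maturity,male_maturity integer age ranges (years) from
#'   which each newborn's maturity age is drawn uniformly.
#' @param clutch_mean,clutch_sd Normal clutch-size parameters; draws are
#'   rounded and truncated at 0.
#' @param breed_prob probability that a mature female nests in a given year
#'   (default 1; kakapo breed episodically, so sub-annual values are
#'   supported).
#' @param polygynous if `TRUE`, a male can sire several clutches per year;
#'   by default each male forms at most one pair per year (males are
#'   re-used only when mature males are scarcer than nesting females).
#'   Age-weighted pairing preference applies either way.
#' @param pairing_exp exponent of the male pairing weight
#'   min(age - maturity + 1, pairing_cap)^pairing_exp; 1 = linear
#'   preference for older males.
#' @param pairing_cap years of post-maturity experience beyond which the
#'   pairing advantage saturates (default 6).
#' @param p_male probability a newborn is male (default 2/3).
#' @param census_factor census carrying capacity per unit target effective
#'   size (default 2.8).
#' @param surv_first baseline first-year survival.
#' @param surv_adult baseline adult annual survival.
#' @param max_age maximum age in years (older individuals die).
#' @return list of class `life_history_params`.
#' @export
life_history_params <- function(female_maturity = c(7, 11),
                                male_maturity = c(5, 7),
                                clutch_mean = 3, clutch_sd = 1.5,
                                breed_prob = 1, polygynous = FALSE,
                                pairing_exp = 1, pairing_cap = 6,
                                p_male = 2 / 3, census_factor = 2.8,
                                surv_first = 0.33, surv_adult = 0.975,
                                max_age = 90) {
  stopifnot(p_male >= 0, p_male <= 1, census_factor > 1,
            all(female_maturity > 0), all(male_maturity > 0),
            breed_prob > 0, breed_prob <= 1,
            surv_first > 0, surv_first <= 1, surv_adult > 0, surv_adult <= 1)
  structure(list(female_maturity = as.integer(female_maturity),
                 male_maturity = as.integer(male_maturity),
                 clutch_mean = clutch_mean, clutch_sd = clutch_sd,
                 breed_prob = breed_prob, polygynous = polygynous,
                 pairing_exp = pairing_exp, pairing_cap = pairing_cap,
                 p_male = p_male, census_factor = census_factor,
                 surv_first = surv_first, surv_adult = surv_adult,
                 max_age = as.integer(max_age)),
            class = "life_history_params")
}

#' Simulator configuration
#'
#' @param arch a [build_architecture()]; its `scale` sets the desk-scale
#'   divisor.
#' @param dfe a [dfe_params()]; `dfe$h` fixes the dominance model for the
#'   run.
#' @param life a [life_history_params()].
#' @param neutral_only force all new mutations neutral (s = 0).
#' @param mu_factor multiplier on the per-gamete mutation input (0 disables
#'   new mutations, e.g. for pure-drift decay runs).
#' @param s_multiplier multiplier on drawn selection coefficients (burn-in
#'   rescaling).
#' @param record_pedigree record parental ages at every birth.
#' @param record_load include mean additive load in the trajectory records
#'   (adds a full population scan per record; turn off for long runs whose
#'   load is only needed at the end).
#' @param record_every record N, nucleotide diversity and mean additive load
#'   every this many steps (also the fixed/lost mutation cleanup cadence).
#' @return list of class `sim_config`.
#' @export
sim_config <- function(arch = build_architecture(scale = 20),
                       dfe = dfe_params(), life = life_history_params(),
                       neutral_only = FALSE, mu_factor = 1,
                       s_multiplier = 1, record_pedigree = TRUE,
                       record_load = TRUE, record_every = 10) {
  structure(list(arch = arch, dfe = dfe, life = life,
                 neutral_only = neutral_only, mu_factor = mu_factor,
                 s_multiplier = s_multiplier,
                 record_pedigree = record_pedigree,
                 record_load = record_load,
                 record_every = as.integer(record_every)),
            class = "sim_config")
}

# ---- state management -------------------------------------------------------
# The haplotype matrix H (mutation rows x 2 columns per individual slot) is
# large; all reads and writes go through evalq() in the state environment so
# sub-assignments stay in place instead of copying the whole matrix.

H_get <- function(st, i, j) {
  st$.i <- i
  st$.j <- j
  evalq(H[.i, .j, drop = FALSE], st)
}

H_set <- function(st, i, j, v) {
  # force lazy arguments before touching the scratch slots: evaluating `v`
  # may itself call H_get() on the same state
  force(v); force(i); force(j)
  st$.i <- i
  st$.j <- j
  st$.v <- v
  evalq(H[.i, .j] <- .v, st)
  invisible(NULL)
}

H_zero_rows <- function(st, rows) {
  st$.i <- rows
  evalq(H[.i, ] <- 0L, st)
  invisible(NULL)
}

H_set_cells <- function(st, idx, v) {
  force(v); force(idx)
  st$.i <- idx
  st$.v <- v
  evalq(H[.i] <- .v, st)
  invisible(NULL)
}

grow_mut_rows <- function(st, need) {
  while (st$mut_cap < need) {
    new_cap <- st$mut_cap * 2L
    st$.newcap <- new_cap
    evalq({
      H2 <- matrix(0L, .newcap, ncol(H))
      H2[seq_len(nrow(H)), ] <- H
      H <- H2
      rm(H2)
    }, st)
    length(st$s) <- new_cap; st$s[is.na(st$s)] <- 0
    length(st$gene) <- new_cap; st$gene[is.na(st$gene)] <- 1L
    length(st$offset) <- new_cap; st$offset[is.na(st$offset)] <- 1L
    length(st$loghom) <- new_cap; st$loghom[is.na(st$loghom)] <- 0
    length(st$loghet) <- new_cap; st$loghet[is.na(st$loghet)] <- 0
    st$mut_cap <- new_cap
  }
  invisible(st)
}

grow_ind_slots <- function(st, need) {
  while (st$ind_cap < need) {
    old <- st$ind_cap
    new_cap <- old * 2L
    st$.newcap <- 2L * new_cap
    evalq({
      H2 <- matrix(0L, nrow(H), .newcap)
      H2[, seq_len(ncol(H))] <- H
      H <- H2
      rm(H2)
    }, st)
    add <- (old + 1L):new_cap
    length(st$alive) <- new_cap; st$alive[add] <- FALSE
    length(st$sex) <- new_cap; st$sex[add] <- 1L
    length(st$age) <- new_cap; st$age[add] <- 0L
    length(st$mat) <- new_cap; st$mat[add] <- 1L
    length(st$w) <- new_cap; st$w[add] <- 1
    st$free <- c(st$free, add)
    st$ind_cap <- new_cap
  }
  invisible(st)
}

alive_cols <- function(st) {
  a <- which(st$alive)
  as.vector(rbind(2L * a - 1L, 2L * a))
}

#' Initialize a simulator state
#'
#' Founds a population of `n0` individuals with the configured sex ratio,
#' geometric-ish starting ages and per-sex maturity ages; genomes start
#' mutation-free unless standing variation is seeded with
#' [seed_standing_variation()].
#'
#' @param config a [sim_config()].
#' @param n0 founding population size.
#' @return simulator state (an environment of class `sim_state`).
#' @export
sim_new <- function(config, n0) {
  st <- new.env(parent = baseenv())
  st$cfg <- config
  life <- config$life
  st$ind_cap <- max(64L, as.integer(ceiling(n0 * 2.5)))
  st$mut_cap <- 4096L
  st$H <- matrix(0L, st$mut_cap, 2L * st$ind_cap)
  st$Mn <- 0L
  st$s <- numeric(st$mut_cap)
  st$gene <- integer(st$mut_cap)
  st$offset <- integer(st$mut_cap)
  st$loghom <- numeric(st$mut_cap)
  st$loghet <- numeric(st$mut_cap)
  st$alive <- logical(st$ind_cap)
  st$sex <- integer(st$ind_cap)
  st$age <- integer(st$ind_cap)
  st$mat <- integer(st$ind_cap)
  st$w <- rep(1, st$ind_cap)
  st$free <- rev(seq_len(st$ind_cap))
  st$fixed_load <- 0
  st$fixed_class <- c(neutral = 0L, weak = 0L, mild = 0L, strong = 0L)
  st$step <- 0L
  st$births_male <- 0L
  st$births_female <- 0L
  st$ped_mother_age <- integer(0)
  st$ped_father_age <- integer(0)
  st$traj_step <- integer(0)
  st$traj_N <- integer(0)
  st$traj_pi <- numeric(0)
  st$traj_load <- numeric(0)
  st$extinct <- FALSE
  # found individuals
  slots <- st$free[seq_len(n0)]
  st$free <- st$free[-seq_len(n0)]
  st$alive[slots] <- TRUE
  st$sex[slots] <- ifelse(stats::runif(n0) < life$p_male, 1L, 2L)
  ages <- sample(0:60, n0, replace = TRUE, prob = 0.93^(0:60))
  st$age[slots] <- ages
  st$mat[slots] <- draw_maturity(st$sex[slots], life)
  class(st) <- "sim_state"
  st
}

draw_maturity <- function(sex, life) {
  fm <- life$female_maturity
  mm <- life$male_maturity
  out <- integer(length(sex))
  nf <- sum(sex == 2L)
  nm <- length(sex) - nf
  out[sex == 2L] <- sample(seq(fm[1], fm[2]), nf, replace = TRUE)
  out[sex == 1L] <- sample(seq(mm[1], mm[2]), nm, replace = TRUE)
  out
}

#' @export
print.sim_state <- function(x, ...) {
  cat(sprintf("sim_state: step %d, N = %d alive, %d segregating mutations\n",
              x$step, sum(x$alive), x$Mn))
  cat(sprintf("  fixed load %.4f; births so far %d male / %d female\n",
              x$fixed_load, x$births_male, x$births_female))
  invisible(x)
}

#' Seed standing neutral variation
#'
#' Adds `n_sites` neutral biallelic sites with the given derived-allele
#' frequencies; each haplotype of each living individual carries the derived
#' allele independently with the site's frequency. Used for pure-drift
#' heterozygosity-decay experiments.
#'
#' @param st a `sim_state`.
#' @param n_sites number of sites.
#' @param freq per-site derived-allele frequencies (recycled).
#' @return the state, invisibly.
#' @export
seed_standing_variation <- function(st, n_sites, freq = 0.5) {
  freq <- rep_len(freq, n_sites)
  grow_mut_rows(st, st$Mn + n_sites)
  rows <- st$Mn + seq_len(n_sites)
  st$s[rows] <- 0
  st$gene[rows] <- sample.int(st$cfg$arch$n_genes, n_sites, replace = TRUE)
  st$offset[rows] <- sample.int(st$cfg$arch$gene_length, n_sites,
                                replace = TRUE)
  st$loghom[rows] <- 0
  st$loghet[rows] <- 0
  cols <- alive_cols(st)
  H_set(st, rows, cols, matrix(
    stats::rbinom(n_sites * length(cols), 1L, rep(freq, length(cols))),
    n_sites, length(cols)))
  st$Mn <- st$Mn + n_sites
  invisible(st)
}

# ---- reproduction -----------------------------------------------------------

#' One round of reproduction
#'
#' Every mature female pairs with one mature male drawn with probability
#' proportional to (age - maturity age + 1) and produces a clutch of
#' round(Normal(clutch_mean, clutch_sd)) (minimum 0) offspring. Each
#' offspring is male with probability `p_male`, receives one recombined
#' gamete from each parent (haplotype switching between adjacent genes with
#' the architecture's crossover probabilities, never within genes) plus
#' Poisson-distributed new mutations per gamete, and has its survival
#' fitness computed once at birth as the product over carried mutations of
#' (1 + s) for homozygotes and (1 + h s) for heterozygotes.
#'
#' @param st a `sim_state`.
#' @return invisibly, the number of offspring produced this step.
#' @export
sim_reproduce <- function(st) {
  life <- st$cfg$life
  mothers <- which(st$alive & st$sex == 2L & st$age >= st$mat)
  fathers <- which(st$alive & st$sex == 1L & st$age >= st$mat)
  if (!length(mothers) || !length(fathers)) return(invisible(0L))
  if (life$breed_prob < 1)
    mothers <- mothers[stats::runif(length(mothers)) < life$breed_prob]
  if (!length(mothers)) return(invisible(0L))
  clutch <- pmax(0L, as.integer(round(
    stats::rnorm(length(mothers), life$clutch_mean, life$clutch_sd))))
  B <- sum(clutch)
  if (B == 0L) return(invisible(0L))
  wts <- pmin(st$age[fathers] - st$mat[fathers] + 1L,
              life$pairing_cap)^life$pairing_exp
  polygynous <- isTRUE(life$polygynous) || length(fathers) < length(mothers)
  mate <- if (length(fathers) == 1L) rep(fathers, length(mothers)) else
    sample(fathers, length(mothers), replace = polygynous, prob = wts)
  m_rep <- rep(mothers, clutch)
  f_rep <- rep(mate, clutch)
  if (st$cfg$record_pedigree) {
    st$ped_mother_age <- c(st$ped_mother_age, st$age[m_rep])
    st$ped_father_age <- c(st$ped_father_age, st$age[f_rep])
  }
  # allocate slots
  grow_ind_slots(st, sum(st$alive) + B + 8L)
  slots <- st$free[seq_len(B)]
  st$free <- st$free[-seq_len(B)]
  sex <- ifelse(stats::runif(B) < life$p_male, 1L, 2L)
  st$alive[slots] <- TRUE
  st$sex[slots] <- sex
  st$age[slots] <- 0L
  st$mat[slots] <- draw_maturity(sex, life)
  st$births_male <- st$births_male + sum(sex == 1L)
  st$births_female <- st$births_female + sum(sex == 2L)
  # gametes
  Mn <- st$Mn
  child1 <- 2L * slots - 1L
  child2 <- 2L * slots
  if (Mn > 0L) {
    H_set(st, seq_len(Mn), child1, make_gametes(st, m_rep, B))
    H_set(st, seq_len(Mn), child2, make_gametes(st, f_rep, B))
  }
  # new mutations, one Poisson draw per gamete
  lambda <- st$cfg$arch$mu_gamete * st$cfg$mu_factor
  if (lambda > 0) {
    n_new_g <- stats::rpois(2L * B, lambda)
    n_new <- sum(n_new_g)
    if (n_new > 0L) {
      grow_mut_rows(st, st$Mn + n_new)
      rows <- st$Mn + seq_len(n_new)
      mut <- sample_mutation(n_new, st$cfg$dfe, arch = st$cfg$arch,
                             s_multiplier = st$cfg$s_multiplier,
                             neutral_only = st$cfg$neutral_only)
      st$s[rows] <- mut$s
      st$gene[rows] <- mut$gene
      st$offset[rows] <- mut$offset
      st$loghom[rows] <- log(pmax(1 + mut$s, 1e-12))
      st$loghet[rows] <- log(pmax(1 + st$cfg$dfe$h * mut$s, 1e-12))
      H_zero_rows(st, rows)
      gam_cols <- c(child1, child2)
      H_set_cells(st, cbind(rows, rep(gam_cols, n_new_g)), 1L)
      st$Mn <- st$Mn + n_new
    }
  }
  # fitness of newborns
  Mn <- st$Mn
  if (Mn > 0L) {
    ii <- seq_len(Mn)
    D <- H_get(st, ii, child1) + H_get(st, ii, child2)
    wl <- colSums((D == 2L) * st$loghom[ii] + (D == 1L) * st$loghet[ii])
    st$w[slots] <- pmin(exp(wl), 1)
  } else {
    st$w[slots] <- 1
  }
  invisible(B)
}

# one recombined gamete per entry of `parents` (length B, repeats allowed)
make_gametes <- function(st, parents, B) {
  Mn <- st$Mn
  arch <- st$cfg$arch
  ng <- arch$n_genes
  ii <- seq_len(Mn)
  A <- H_get(st, ii, 2L * parents - 1L)
  Bm <- H_get(st, ii, 2L * parents)
  start <- stats::rbinom(B, 1L, 0.5)
  if (ng > 1L) {
    X <- matrix(stats::rbinom((ng - 1L) * B, 1L, rep.int(arch$crossprob, B)),
                ng - 1L, B)
    cum <- apply(X, 2L, cumsum)
    src <- (rbind(start, matrix(start, ng - 1L, B, byrow = TRUE) + cum)) %% 2L
  } else {
    src <- matrix(start, 1L, B)
  }
  S <- src[st$gene[ii], , drop = FALSE]
  A * (1L - S) + Bm * S
}

# ---- survival ---------------------------------------------------------------

#' One round of viability selection and density regulation
#'
#' Each living individual survives the step with probability
#' base_survival(age) x min(1, K/N) x w, where w is the individual's
#' multiplicative mutational fitness fixed at birth; individuals past the
#' maximum age die. The baseline is `surv_first` in the first year of life
#' and `surv_adult` per year thereafter.
#'
#' @param st a `sim_state`.
#' @param K carrying capacity for this step.
#' @return invisibly, the number of survivors.
#' @export
sim_survive <- function(st, K) {
  if (K <= 0) {
    st$alive[] <- FALSE
  }
  a <- which(st$alive)
  if (!length(a)) {
    st$extinct <- TRUE
    return(invisible(0L))
  }
  life <- st$cfg$life
  N <- length(a)
  dens <- min(1, K / N)
  age <- st$age[a]
  base <- ifelse(age <= 1L, life$surv_first, life$surv_adult)
  base[age > life$max_age] <- 0
  p <- base * dens * st$w[a]
  die <- stats::runif(N) > p
  dead <- a[die]
  if (length(dead)) {
    st$alive[dead] <- FALSE
    st$free <- c(st$free, dead)
  }
  n_alive <- N - length(dead)
  if (n_alive == 0L) st$extinct <- TRUE
  invisible(n_alive)
}

# ---- bookkeeping ------------------------------------------------------------

# remove lost and fixed mutations; returns per-site stats from before removal
sim_cleanup <- function(st) {
  if (st$Mn == 0L || !any(st$alive)) {
    return(list(pi = 0, mean_load = st$fixed_load, N = sum(st$alive)))
  }
  ii <- seq_len(st$Mn)
  cols <- alive_cols(st)
  Ha <- H_get(st, ii, cols)
  cnt <- rowSums(Ha)
  n_hap <- length(cols)
  f <- cnt / n_hap
  seg <- cnt > 0L & cnt < n_hap
  pi_sum <- sum(2 * f[seg] * (1 - f[seg])) * n_hap / (n_hap - 1L)
  pi <- pi_sum / st$cfg$arch$total_bp
  # mean additive load (positive magnitude convention)
  abs_s <- abs(st$s[ii])
  mean_load <- NA_real_
  if (isTRUE(st$cfg$record_load)) {
    h <- st$cfg$dfe$h
    D <- Ha[, seq(1L, n_hap, by = 2L), drop = FALSE] +
      Ha[, seq(2L, n_hap, by = 2L), drop = FALSE]
    mean_load <- mean(colSums((D == 2L) * abs_s + (D == 1L) * (h * abs_s))) +
      st$fixed_load
  }
  fixed <- cnt == n_hap
  lost <- cnt == 0L
  if (any(fixed)) {
    fr <- which(fixed)
    st$fixed_load <- st$fixed_load + sum(abs_s[fr])
    cls <- mutation_class(st$s[fr])
    tb <- table(cls)
    st$fixed_class[names(tb)] <- st$fixed_class[names(tb)] + as.integer(tb)
    # individuals' stored fitness no longer includes the fixed factor
    log_fac <- sum(st$loghom[fr])
    if (log_fac != 0) {
      al <- which(st$alive)
      st$w[al] <- pmin(st$w[al] * exp(-log_fac), 1)
    }
  }
  keep <- which(!(fixed | lost))
  if (length(keep) < st$Mn) {
    newMn <- length(keep)
    if (newMn > 0L) {
      st$.i <- keep
      evalq(H[seq_along(.i), ] <- H[.i, , drop = FALSE], st)
      st$s[seq_len(newMn)] <- st$s[keep]
      st$gene[seq_len(newMn)] <- st$gene[keep]
      st$offset[seq_len(newMn)] <- st$offset[keep]
      st$loghom[seq_len(newMn)] <- st$loghom[keep]
      st$loghet[seq_len(newMn)] <- st$loghet[keep]
    }
    st$Mn <- newMn
  }
  list(pi = pi, mean_load = mean_load, N = length(cols) / 2L)
}

#' Advance the simulation one step (one year)
#'
#' Order within a step: reproduction, aging, then viability selection under
#' the step's carrying capacity. Every `record_every` steps the state is
#' cleaned up (fixed and lost mutations removed, with fixed selection
#' coefficients folded into a population-level fixed-load term) and N,
#' nucleotide diversity and mean additive load are recorded.
#'
#' @param st a `sim_state`.
#' @param K carrying capacity for this step.
#' @return the state, invisibly.
#' @export
sim_step <- function(st, K) {
  st$step <- st$step + 1L
  sim_reproduce(st)
  a <- which(st$alive)
  st$age[a] <- st$age[a] + 1L
  sim_survive(st, K)
  if (st$step %% st$cfg$record_every == 0L) {
    stats <- sim_cleanup(st)
    st$traj_step <- c(st$traj_step, st$step)
    st$traj_N <- c(st$traj_N, stats$N)
    st$traj_pi <- c(st$traj_pi, stats$pi)
    st$traj_load <- c(st$traj_load, stats$mean_load)
  }
  invisible(st)
}

#' Run the simulator along a carrying-capacity trajectory
#'
#' @param st a `sim_state`.
#' @param K_traj vector of carrying capacities, one per step.
#' @return the state, invisibly; stops early with `st$extinct = TRUE` if the
#'   population dies out.
#' @export
sim_run <- function(st, K_traj) {
  for (K in K_traj) {
    sim_step(st, K)
    if (st$extinct) break
  }
  invisible(st)
}

#' Trajectory records as a data frame
#'
#' @param st a `sim_state`.
#' @return data frame: step, N, pi, mean_load.
#' @export
sim_trajectory <- function(st) {
  data.frame(step = st$traj_step, N = st$traj_N, pi = st$traj_pi,
             mean_load = st$traj_load)
}

# ---- burn-in and scenarios --------------------------------------------------

#' Demographic scenario definition
#'
#' Four named scenarios span 25,000 years at full scale: `Stable` (constant
#' long-term Ne 10,000, the weak-drift control), `Mainland` (decline to Ne
#' 6,000), `StewartIsland` (decline to Ne 1,000) and `Extreme` (decline to
#' Ne 100, strong drift). All start from the Stable level; declining
#' scenarios interpolate exponentially from the pre-decline carrying
#' capacity to the long-term value over the first `decline_frac` of the
#' scenario steps, then stay constant. Census carrying capacity is
#' `census_factor` (2.8) times the target Ne, divided by the desk-scale
#' divisor.
#'
#' @param name one of `"Stable"`, `"Mainland"`, `"StewartIsland"`,
#'   `"Extreme"`.
#' @param steps scenario duration in steps (default 25000; desk-scale runs
#'   pass fewer).
#' @param pre_ne pre-decline (equilibration) effective size.
#' @param long_term_ne override the named scenario's long-term Ne.
#' @param decline_frac fraction of the scenario over which the decline runs.
#' @return list of class `demographic_scenario`.
#' @export
demographic_scenario <- function(name = c("Stable", "Mainland",
                                          "StewartIsland", "Extreme"),
                                 steps = 25000, pre_ne = 10000,
                                 long_term_ne = NULL, decline_frac = 0.2) {
  name <- match.arg(name)
  if (is.null(long_term_ne))
    long_term_ne <- switch(name, Stable = 10000, Mainland = 6000,
                           StewartIsland = 1000, Extreme = 100)
  structure(list(name = name, steps = as.integer(steps), pre_ne = pre_ne,
                 long_term_ne = long_term_ne, decline_frac = decline_frac),
            class = "demographic_scenario")
}

#' Carrying-capacity trajectory for a scenario
#'
#' @param scenario a [demographic_scenario()].
#' @param life a [life_history_params()] (for the census factor).
#' @param scale desk-scale divisor.
#' @return integer vector of per-step census carrying capacities.
#' @export
scenario_K <- function(scenario, life = life_history_params(), scale = 1) {
  K_pre <- scenario$pre_ne * life$census_factor / scale
  K_end <- scenario$long_term_ne * life$census_factor / scale
  n <- scenario$steps
  n_decl <- round(scenario$decline_frac * n)
  if (K_pre == K_end || n_decl == 0) return(rep(round(K_end), n))
  decl <- K_pre * (K_end / K_pre)^(seq_len(n_decl) / n_decl)
  pmax(round(c(decl, rep(K_end, n - n_decl))), 1L)
}

#' Burn in a population to mutation-selection equilibrium
#'
#' Two phases, mirroring the usual rescaling trick for slow-coalescing
#' non-WF models: (1) a scaled phase at population size K/`scale_factor`
#' with mutation and recombination rates and selection coefficients
#' multiplied by `scale_factor`; (2) the scaling is removed (selection
#' coefficients divided back, individual fitness recomputed) and the
#' population grows to and equilibrates at the full carrying capacity K.
#' Equilibrium is declared when the trailing-window linear trend of
#' nucleotide diversity is indistinguishable from zero (two-sided slope
#' t test at alpha = 0.05).
#'
#' @param config a [sim_config()] (unscaled selection).
#' @param K full census carrying capacity.
#' @param scaled_steps steps for the scaled phase.
#' @param equil_steps steps for the unscaled equilibration phase.
#' @param scale_factor burn-in rescaling factor (default 10).
#' @param trend_window number of trailing trajectory records used for the
#'   stationarity test.
#' @return the equilibrated `sim_state`, with attributes `equilibrium`
#'   (logical) and `trend_p` (slope test p value) stored in the state as
#'   `st$equilibrium`, `st$trend_p`.
#' @export
burn_in <- function(config, K, scaled_steps = 600, equil_steps = 200,
                    scale_factor = 10, trend_window = 20) {
  arch <- config$arch
  # scaled architecture: same layout, mu and r scaled up
  arch_s <- arch
  arch_s$mu <- arch$mu * scale_factor
  arch_s$mu_gamete <- arch$mu_gamete * scale_factor
  arch_s$crossprob <- 1 - (1 - arch$crossprob)^scale_factor
  cfg_s <- config
  cfg_s$arch <- arch_s
  cfg_s$s_multiplier <- config$s_multiplier * scale_factor
  cfg_s$record_pedigree <- FALSE
  K_s <- max(20, round(K / scale_factor))
  st <- sim_new(cfg_s, n0 = K_s)
  sim_run(st, rep(K_s, scaled_steps))
  if (st$extinct) {
    st$equilibrium <- FALSE
    st$trend_p <- NA_real_
    return(st)
  }
  # remove scaling: divide selection coefficients, recompute fitness
  st$cfg <- config
  if (st$Mn > 0L) {
    ii <- seq_len(st$Mn)
    st$s[ii] <- st$s[ii] / scale_factor
    st$loghom[ii] <- log(pmax(1 + st$s[ii], 1e-12))
    st$loghet[ii] <- log(pmax(1 + config$dfe$h * st$s[ii], 1e-12))
    cols_odd <- 2L * which(st$alive) - 1L
    D <- H_get(st, ii, cols_odd) + H_get(st, ii, cols_odd + 1L)
    wl <- colSums((D == 2L) * st$loghom[ii] + (D == 1L) * st$loghet[ii])
    st$w[which(st$alive)] <- pmin(exp(wl), 1)
  }
  st$fixed_load <- st$fixed_load / scale_factor
  n0_traj <- length(st$traj_step)
  sim_run(st, rep(round(K), equil_steps))
  # stationarity of the trailing pi records
  rec <- seq_along(st$traj_step)
  rec <- rec[rec > n0_traj]
  rec <- utils::tail(rec, trend_window)
  if (length(rec) >= 5 && stats::sd(st$traj_pi[rec]) > 0) {
    fit <- summary(stats::lm(st$traj_pi[rec] ~ st$traj_step[rec]))
    st$trend_p <- fit$coefficients[2, 4]
    st$equilibrium <- st$trend_p > 0.05
  } else {
    st$trend_p <- NA_real_
    st$equilibrium <- length(rec) >= 5  # flat series counts as stationary
  }
  st
}

#' Run a demographic scenario
#'
#' Steps an (optionally burned-in) population through the scenario's
#' carrying-capacity trajectory, recording N, nucleotide diversity and mean
#' additive load.
#'
#' @param scenario a [demographic_scenario()].
#' @param config a [sim_config()]; `config$arch$scale` sets the desk-scale
#'   divisor applied to the carrying capacities.
#' @param state optional burned-in `sim_state`; if `NULL`, [burn_in()] is
#'   run first with default desk-scale phase lengths.
#' @param burn_args list of arguments passed on to [burn_in()].
#' @return list of class `scenario_result`: `state`, `trajectory` (data
#'   frame), `scenario`, `extinct`.
#' @export
run_scenario <- function(scenario, config, state = NULL, burn_args = list()) {
  scale <- config$arch$scale
  Ktraj <- scenario_K(scenario, config$life, scale = scale)
  if (is.null(state)) {
    state <- do.call(burn_in, c(list(config = config, K = Ktraj[1]),
                                burn_args))
  }
  sim_run(state, Ktraj)
  structure(list(state = state, trajectory = sim_trajectory(state),
                 scenario = scenario, extinct = state$extinct),
            class = "scenario_result")
}

# ---- summaries --------------------------------------------------------------

#' Additive genetic load of individuals
#'
#' Load is reported as a positive magnitude: sum of |s| over homozygous
#' deleterious mutations plus h |s| over heterozygous ones, plus the
#' population's fixed-mutation load. (The underlying selection coefficients
#' are negative; the sign convention is cosmetic.)
#'
#' @param st a `sim_state`.
#' @param ids individual slot indices (default: all alive).
#' @return numeric vector of loads.
#' @export
additive_load <- function(st, ids = NULL) {
  if (is.null(ids)) ids <- which(st$alive)
  if (st$Mn == 0L) return(rep(st$fixed_load, length(ids)))
  ii <- seq_len(st$Mn)
  D <- H_get(st, ii, 2L * ids - 1L) + H_get(st, ii, 2L * ids)
  abs_s <- abs(st$s[ii])
  h <- st$cfg$dfe$h
  colSums((D == 2L) * abs_s + (D == 1L) * (h * abs_s)) + st$fixed_load
}

#' Sample individuals and summarize load and mutation-class counts
#'
#' Randomly subsamples `n` living individuals (the whole population, with a
#' flag, if fewer remain) and reports per-individual additive load and
#' derived-allele counts per deleterious class (weak, mild, strong;
#' heterozygous sites count one allele, homozygous two), with means and
#' normal-approximation 95% confidence intervals.
#'
#' @param st a `sim_state`.
#' @param n sample size (default 200).
#' @return list of class `load_summary`: `individuals` (data frame: load,
#'   n_weak, n_mild, n_strong, n_neutral), `mean_load`, `ci_load`,
#'   `class_means`, `n`, `whole_population`.
#' @export
summarize_sample <- function(st, n = 200) {
  al <- which(st$alive)
  if (!length(al)) stop("population is extinct; nothing to sample")
  whole <- length(al) <= n
  ids <- if (whole) al else sample(al, n)
  load <- additive_load(st, ids)
  cls_counts <- matrix(0, 4L, length(ids),
                       dimnames = list(c("neutral", "weak", "mild", "strong"),
                                       NULL))
  if (st$Mn > 0L) {
    ii <- seq_len(st$Mn)
    D <- H_get(st, ii, 2L * ids - 1L) + H_get(st, ii, 2L * ids)
    cls <- mutation_class_code(st$s[ii])
    for (k in 0:3)
      if (any(cls == k))
        cls_counts[k + 1L, ] <- colSums(D[cls == k, , drop = FALSE])
  }
  individuals <- data.frame(load = load,
                            n_neutral = cls_counts["neutral", ],
                            n_weak = cls_counts["weak", ],
                            n_mild = cls_counts["mild", ],
                            n_strong = cls_counts["strong", ])
  m <- mean(load)
  se <- stats::sd(load) / sqrt(length(load))
  structure(list(individuals = individuals, mean_load = m,
                 ci_load = m + c(-1.96, 1.96) * se,
                 class_means = rowMeans(cls_counts),
                 n = length(ids), whole_population = whole),
            class = "load_summary")
}

#' Realized generation time from the recorded pedigree
#'
#' Mean and standard deviation of parental age at offspring birth over all
#' parent-offspring links (each birth contributes a maternal and a paternal
#' link). With one step per year this is the emergent generation time.
#'
#' @param st a `sim_state` with pedigree recording enabled, or a list/data
#'   frame with elements `mother_age` and `father_age`.
#' @return list: `mean`, `sd`, `n_links`.
#' @export
realized_generation_time <- function(st) {
  ages <- if (inherits(st, "sim_state"))
    c(st$ped_mother_age, st$ped_father_age)
  else c(st$mother_age, st$father_age)
  if (!length(ages)) stop("no parent-offspring links recorded")
  list(mean = mean(ages), sd = stats::sd(ages), n_links = length(ages))
}

#' Compare load summaries between scenarios
#'
#' Welch two-sample t tests between scenario pairs on per-replicate mean
#' additive load and mean per-class derived-allele counts.
#'
#' @param summaries named list (one element per scenario) of lists of
#'   [summarize_sample()] results (one per replicate).
#' @return data frame: scenario_a, scenario_b, measure, mean_a, mean_b, t,
#'   df, p_value (t columns `NA` with fewer than 2 replicates per side).
#' @export
compare_scenarios <- function(summaries) {
  measures <- c("mean_load", "weak", "mild", "strong")
  pull <- function(reps, meas) {
    vapply(reps, function(s)
      if (meas == "mean_load") s$mean_load else s$class_means[[meas]],
      numeric(1))
  }
  combos <- utils::combn(names(summaries), 2, simplify = FALSE)
  rows <- lapply(combos, function(pr) {
    do.call(rbind, lapply(measures, function(meas) {
      x <- pull(summaries[[pr[1]]], meas)
      y <- pull(summaries[[pr[2]]], meas)
      if (length(x) >= 2L && length(y) >= 2L &&
          (stats::sd(x) > 0 || stats::sd(y) > 0)) {
        tt <- stats::t.test(x, y)
        data.frame(scenario_a = pr[1], scenario_b = pr[2], measure = meas,
                   mean_a = mean(x), mean_b = mean(y),
                   t = unname(tt$statistic), df = unname(tt$parameter),
                   p_value = tt$p.value, stringsAsFactors = FALSE)
      } else {
        data.frame(scenario_a = pr[1], scenario_b = pr[2], measure = meas,
                   mean_a = mean(x), mean_b = mean(y), t = NA_real_,
                   df = NA_real_,
                   p_value = if (isTRUE(all.equal(mean(x), mean(y))))
                     1 else NA_real_,
                   stringsAsFactors = FALSE)
      }
    }))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Effective population size from heterozygosity decay
#'
#' In a closed neutral population expected heterozygosity decays by
#' 1/(2 Ne) per generation. Fits log(pi) against step on the recorded
#' trajectory and converts the per-step slope to per-generation using the
#' supplied generation time.
#'
#' @param traj trajectory data frame from [sim_trajectory()] (needs columns
#'   `step` and `pi` with positive values).
#' @param gen_time realized generation time in steps (see
#'   [realized_generation_time()]).
#' @return list: `ne`, `slope_per_step`, `mean_census` (mean of `traj$N`).
#' @export
ne_from_decay <- function(traj, gen_time) {
  ok <- traj$pi > 0
  if (sum(ok) < 5) stop("too few positive diversity records to fit decay")
  fit <- stats::lm(log(traj$pi[ok]) ~ traj$step[ok])
  slope <- unname(stats::coef(fit)[2])
  ne <- 1 / (2 * (1 - exp(slope * gen_time)))
  list(ne = ne, slope_per_step = slope, mean_census = mean(traj$N))
}

#' Convenience run for emergent life-history statistics
#'
#' Founds a population at carrying capacity `K`, lets the age structure
#' settle for `warmup` steps without pedigree recording, then records
#' `steps` further steps. Used for generation-time, sex-ratio and
#' heterozygosity-decay experiments.
#'
#' @param K constant census carrying capacity.
#' @param steps recorded steps.
#' @param warmup settling steps before recording starts.
#' @param config a [sim_config()].
#' @param seed_variation optional number of standing neutral sites to seed
#'   after warmup (frequencies drawn uniformly on (0.1, 0.9)).
#' @return the final `sim_state`.
#' @export
run_life_history <- function(K, steps, warmup = 300,
                             config = sim_config(), seed_variation = 0) {
  cfg0 <- config
  cfg0$record_pedigree <- FALSE
  st <- sim_new(cfg0, n0 = round(K))
  sim_run(st, rep(round(K), warmup))
  if (st$extinct) return(st)
  if (seed_variation > 0)
    seed_standing_variation(st, seed_variation,
                            stats::runif(seed_variation, 0.1, 0.9))
  st$cfg <- config
  # restart trajectory/pedigree accounting at the recording boundary
  st$traj_step <- integer(0); st$traj_N <- integer(0)
  st$traj_pi <- numeric(0); st$traj_load <- numeric(0)
  st$births_male <- 0L; st$births_female <- 0L
  sim_run(st, rep(round(K), steps))
  st
}
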