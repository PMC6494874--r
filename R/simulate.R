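#' Configuration for the synthetic effect-size generator
#'
#' Defines the hierarchical, moderated, heteroscedastic structure of a
#' simulated meta-analytic dataset: the number of studies and effects per
#' study, trait and taxon label pools, true fixed effects on the moderator
#' design (Hedges'-g scale), true variance components for the study, trait,
#' taxon and observation levels, per-group sample-size and
#' coefficient-of-variation ranges, and the moderator distribution over
#' sex-by-environment cells.
#'
#' `beta` of length 1 means an intercept-only (grand mean) truth; length 6
#' means a sex-by-environment truth with treatment coding (reference cell
#' male/benign; columns intercept, female, both, stressful,
#' female:stressful, both:stressful).
#'
#' @param n_studies Number of studies.
#' @param effects_per_study Integer range `c(min, max)` of effects
#'   contributed per study.
#' @param trait_labels,taxon_labels Label pools.
#' @param beta True fixed effects (length 1 or 6).
#' @param sigma2_study,sigma2_trait,sigma2_taxon,sigma2_effect True
#'   variance components (all >= 0); `sigma2_effect` is observation-level
#'   (residual) heterogeneity.
#' @param group_n_range Integer range of per-treatment-group sample sizes
#'   (min >= 2).
#' @param cv_range Positive range of the within-group coefficient of
#'   variation; the group SD is CV times the group mean, inducing the
#'   positive mean--variance relationship seen in real fitness data.
#' @param moderator_probs Named probabilities over the six
#'   sex-by-environment cells (`male.benign`, `female.benign`,
#'   `both.benign`, `male.stressful`, `female.stressful`,
#'   `both.stressful`); must sum to 1.
#' @param seed Integer seed.
#' @return Object of class `sim_config`.
#' @export
sim_config <- function(n_studies = 50,
                       effects_per_study = c(1, 8),
                       trait_labels = paste0("trait", 1:10),
                       taxon_labels = c("flies", "beetles", "mice",
                                        "nematodes", "mites", "crickets",
                                        "guppies"),
                       beta = 0.2,
                       sigma2_study = 0.04,
                       sigma2_trait = 0.01,
                       sigma2_taxon = 0.01,
                       sigma2_effect = 0,
                       group_n_range = c(10, 50),
                       cv_range = c(0.2, 0.5),
                       moderator_probs = c(male.benign = 0.30,
                                           female.benign = 0.33,
                                           both.benign = 0.08,
                                           male.stressful = 0.12,
                                           female.stressful = 0.13,
                                           both.stressful = 0.04),
                       seed = 1L) {
  cfg <- list(n_studies = as.integer(n_studies),
              effects_per_study = as.integer(effects_per_study),
              trait_labels = as.character(trait_labels),
              taxon_labels = as.character(taxon_labels),
              beta = as.numeric(beta),
              sigma2_study = sigma2_study, sigma2_trait = sigma2_trait,
              sigma2_taxon = sigma2_taxon, sigma2_effect = sigma2_effect,
              group_n_range = as.integer(group_n_range),
              cv_range = as.numeric(cv_range),
              moderator_probs = moderator_probs,
              seed = as.integer(seed))
  if (is.null(names(cfg$moderator_probs)) &&
      length(cfg$moderator_probs) == 6) {
    names(cfg$moderator_probs) <- c("male.benign", "female.benign",
                                    "both.benign", "male.stressful",
                                    "female.stressful", "both.stressful")
  }
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  if (cfg$n_studies < 1) stop("n_studies must be >= 1", call. = FALSE)
  if (length(cfg$effects_per_study) != 2 ||
      cfg$effects_per_study[1] < 1 ||
      cfg$effects_per_study[2] < cfg$effects_per_study[1])
    stop("effects_per_study must be an increasing range with min >= 1",
         call. = FALSE)
  s2 <- c(cfg$sigma2_study, cfg$sigma2_trait, cfg$sigma2_taxon,
          cfg$sigma2_effect)
  if (any(!is.finite(s2)) || any(s2 < 0))
    stop("variance components must be non-negative", call. = FALSE)
  if (!length(cfg$beta) %in% c(1L, 6L))
    stop("beta must have length 1 (grand mean) or 6 (sex x environment)",
         call. = FALSE)
  if (length(cfg$group_n_range) != 2 || cfg$group_n_range[1] < 2 ||
      cfg$group_n_range[2] < cfg$group_n_range[1])
    stop("group_n_range must be an increasing range with min >= 2",
         call. = FALSE)
  if (length(cfg$cv_range) != 2 || cfg$cv_range[1] <= 0 ||
      cfg$cv_range[2] < cfg$cv_range[1])
    stop("cv_range must be a positive increasing range", call. = FALSE)
  if (abs(sum(cfg$moderator_probs) - 1) > 1e-8 || any(cfg$moderator_probs < 0))
    stop("moderator_probs must be non-negative and sum to 1", call. = FALSE)
  invisible(cfg)
}

#' Read a generator configuration from a YAML or JSON file
#'
#' @param path Path to a YAML (or JSON, a YAML subset) file whose keys
#'   match the arguments of [sim_config()].
#' @return A `sim_config`.
#' @export
read_sim_config <- function(path) {
  raw <- yaml::read_yaml(path)
  if (!is.null(raw$moderator_probs)) {
    raw$moderator_probs <- unlist(raw$moderator_probs)
  }
  do.call(sim_config, raw)
}

# draw n integers uniformly from [a, b]; safe when a == b (sample() would
# otherwise treat a length-one vector as 1:a)
.sample_range <- function(a, b, n) {
  if (a == b) rep(as.integer(a), n) else sample(seq(a, b), n, replace = TRUE)
}

# deterministic per-record seed split from the global seed, so a subset of
# records can be regenerated without redrawing the whole dataset
.record_seed <- function(seed, i) {
  as.integer((as.numeric(seed) + 104729 * as.numeric(i)) %% 2147483629)
}

# given target standardised difference theta and the low-group mean, find
# the high-group mean such that (mu_h - mu_l) / sigma_pool = theta with
# group SDs proportional to group means (sd = cv * mu)
.solve_mu_high <- function(theta, mu_low, cv) {
  a <- theta * cv
  cc <- a^2 / 2
  if (cc < 0.999) {
    root <- sqrt(cc * (2 - cc))
    mu_low * (1 + sign(theta) * root) / (1 - cc)
  } else {
    # extreme effects: fall back to a homoscedastic shift
    max(mu_low + theta * cv * mu_low, mu_low * 1e-3)
  }
}

#' Generate a synthetic effect-size dataset
#'
#' Draws, for every record, a true effect `theta_i = x_i' beta + u_study +
#' u_trait + u_taxon + u_effect` with independent normal level deviations,
#' then simulates two-group normal summaries whose standardised mean
#' difference has expectation `theta_i`: group means are sample means of
#' `n` normal draws and group SDs come from the matching scaled chi-square
#' distribution, so the computed Hedges' g has the correct first-order
#' sampling distribution and its analytic sampling variance applies.
#' Within-group SDs are proportional to group means (SD = CV x mean),
#' inducing the positive mean--variance relationship that makes lnCVR and
#' lnVR behave differently.
#'
#' Identical config and seed give a byte-identical dataset; record-level
#' draws use a deterministic per-record seed split.
#'
#' @param config A [sim_config()].
#' @return Object of class `sim_dataset`: `records` (canonical-schema data
#'   frame) and `truth` (the config plus per-record true effects and the
#'   sampled level deviations).
#' @export
simulate_dataset <- function(config) {
  validate_sim_config(config)
  set.seed(config$seed)
  ns <- config$n_studies
  study_ids <- sprintf("study%03d", seq_len(ns))
  n_eff <- .sample_range(config$effects_per_study[1],
                         config$effects_per_study[2], ns)
  study_taxon <- sample(config$taxon_labels, ns, replace = TRUE)
  k <- sum(n_eff)
  study <- rep(study_ids, n_eff)
  taxon <- rep(study_taxon, n_eff)
  trait <- sample(config$trait_labels, k, replace = TRUE)
  cells <- names(config$moderator_probs)
  cell <- sample(cells, k, replace = TRUE, prob = config$moderator_probs)
  sex <- sub("\\..*$", "", cell)
  environment <- sub("^.*\\.", "", cell)

  u_study <- stats::rnorm(ns, 0, sqrt(config$sigma2_study))
  names(u_study) <- study_ids
  u_trait <- stats::rnorm(length(config$trait_labels), 0,
                          sqrt(config$sigma2_trait))
  names(u_trait) <- config$trait_labels
  u_taxon <- stats::rnorm(length(config$taxon_labels), 0,
                          sqrt(config$sigma2_taxon))
  names(u_taxon) <- config$taxon_labels
  u_effect <- stats::rnorm(k, 0, sqrt(config$sigma2_effect))

  if (length(config$beta) == 1) {
    mu_fixed <- rep(config$beta, k)
  } else {
    sx <- factor(sex, levels = c("male", "female", "both"))
    ev <- factor(ifelse(environment == "stressful", "stressful", "benign"),
                 levels = c("benign", "stressful"))
    X <- stats::model.matrix(~ sx * ev)
    mu_fixed <- drop(X %*% config$beta)
  }
  theta <- mu_fixed + u_study[study] + u_trait[trait] + u_taxon[taxon] +
    u_effect

  rec <- .draw_summaries(theta, config)
  records <- data.frame(
    study_id = study, line = NA_character_, taxon = taxon, trait = trait,
    fitness_class = "direct", sex = sex, environment = environment,
    manipulation = "enforced monogamy", generations = 10L, blind = NA,
    year = 2010L, impact_factor = NA_real_, input_kind = "summaries",
    m_high = rec$m_high, s_high = rec$s_high, n_high = rec$n_high,
    m_low = rec$m_low, s_low = rec$s_low, n_low = rec$n_low,
    statistic_value = NA_real_, total_n = rec$n_high + rec$n_low,
    direction = 1L, negatively_related = FALSE,
    stringsAsFactors = FALSE
  )
  structure(list(records = records,
                 truth = list(config = config, theta = theta,
                              u_study = u_study, u_trait = u_trait,
                              u_taxon = u_taxon)),
            class = "sim_dataset")
}

# per-record two-group summaries targeting standardised difference theta_i
.draw_summaries <- function(theta, config) {
  k <- length(theta)
  out <- list(m_high = numeric(k), s_high = numeric(k), n_high = integer(k),
              m_low = numeric(k), s_low = numeric(k), n_low = integer(k))
  nr <- config$group_n_range
  cvr <- config$cv_range
  for (i in seq_len(k)) {
    set.seed(.record_seed(config$seed, i))
    n_h <- .sample_range(nr[1], nr[2], 1)
    n_l <- .sample_range(nr[1], nr[2], 1)
    cv <- stats::runif(1, cvr[1], cvr[2])
    mu_l <- exp(stats::runif(1, log(5), log(50)))
    mu_h <- .solve_mu_high(theta[i], mu_l, cv)
    sd_h <- cv * mu_h
    sd_l <- cv * mu_l
    out$n_high[i] <- n_h
    out$n_low[i] <- n_l
    out$m_high[i] <- stats::rnorm(1, mu_h, sd_h / sqrt(n_h))
    out$m_low[i] <- stats::rnorm(1, mu_l, sd_l / sqrt(n_l))
    out$s_high[i] <- sd_h * sqrt(stats::rchisq(1, n_h - 1) / (n_h - 1))
    out$s_low[i] <- sd_l * sqrt(stats::rchisq(1, n_l - 1) / (n_l - 1))
  }
  out
}

#' @export
print.sim_dataset <- function(x, ...) {
  cat(sprintf("Synthetic effect-size dataset: %d records, %d studies, %d traits, %d taxa\n",
              nrow(x$records), length(unique(x$records$study_id)),
              length(unique(x$records$trait)),
              length(unique(x$records$taxon))))
  invisible(x)
}

# deterministic partition of n_total effects over n_studies studies with a
# right-skewed (few prolific, many small) shape, bounded by max_per
.study_size_partition <- function(n_total = 459L, n_studies = 65L,
                                  max_per = 30L) {
  raw <- max_per * 0.925^(seq_len(n_studies) - 1)
  sizes <- pmax(1L, as.integer(round(raw)))
  i <- 1L
  while (sum(sizes) != n_total) {
    d <- n_total - sum(sizes)
    j <- ((i - 1L) %% n_studies) + 1L
    if (d > 0 && sizes[j] < max_per) sizes[j] <- sizes[j] + 1L
    if (d < 0 && sizes[j] > 1L) sizes[j] <- sizes[j] - 1L
    i <- i + 1L
  }
  sizes
}

# fixed count vector shuffled over record slots
.shuffled_labels <- function(labels, counts) {
  sample(rep(labels, counts))
}

#' Generate a dataset shaped like a full sexual-selection synthesis
#'
#' Produces a synthetic dataset with the marginal structure of a complete
#' experimental-evolution synthesis: 459 effect sizes from 65 studies, 22
#' fitness components (female reproductive success and offspring viability
#' the most common), 7 taxa, sex counts 189 male / 219 female / 51 both,
#' environments 92 stressful / 337 benign / 30 undefined, fitness classes
#' 174 direct / 141 indirect / 144 ambiguous, and 354 records with full
#' two-group summaries (the remainder carry only a t statistic). Study
#' sizes follow a fixed right-skewed partition (1--30 effects per study).
#' True effects follow a sex-by-environment model with substantial
#' multilevel heterogeneity.
#'
#' @param seed Integer seed; the marginal counts above are identical for
#'   every seed, only the random pairings and noise change.
#' @return A `sim_dataset` (see [simulate_dataset()]).
#' @export
simulate_paperlike <- function(seed = 1L) {
  n_total <- 459L
  n_studies <- 65L
  sizes <- .study_size_partition(n_total, n_studies, 30L)
  trait_labels <- c("female reproductive success", "offspring viability",
                    "lifespan", "male mating success", "ejaculate quality",
                    "immunity", "body size", "mating duration",
                    "early fecundity", "male reproductive success",
                    "extinction rate", "mutation load", "parasite load",
                    "development time", "body condition", "sperm number",
                    "hatching success", "longevity under stress",
                    "courtship rate", "fertility", "attractiveness",
                    "mating latency")
  trait_counts <- c(102L, 56L, 40L, 32L, 26L, 35L, 20L, 14L, 13L, 18L,
                    8L, 9L, 7L, 12L, 6L, 11L, 10L, 9L, 8L, 10L, 7L, 6L)
  stopifnot(sum(trait_counts) == n_total, length(trait_counts) == 22L)
  taxon_labels <- c("flies", "beetles", "mice", "nematodes", "mites",
                    "crickets", "guppies")

  set.seed(seed)
  study_ids <- sprintf("study%03d", seq_len(n_studies))
  study <- rep(study_ids, sizes)
  # every taxon represented; flies dominate as in the underlying literature
  study_taxon <- c(taxon_labels,
                   sample(taxon_labels, n_studies - 7, replace = TRUE,
                          prob = c(0.5, 0.2, 0.05, 0.1, 0.04, 0.06, 0.05)))
  taxon <- rep(study_taxon, sizes)
  trait <- .shuffled_labels(trait_labels, trait_counts)
  sex <- .shuffled_labels(c("male", "female", "both"), c(189L, 219L, 51L))
  environment <- .shuffled_labels(c("stressful", "benign", "undefined"),
                                  c(92L, 337L, 30L))
  fitness_class <- .shuffled_labels(c("direct", "indirect", "ambiguous"),
                                    c(174L, 141L, 144L))
  has_summaries <- sample(rep(c(TRUE, FALSE), c(354L, 105L)))

  # true model: modest positive grand effect, stronger for females, with
  # a sex-dependent response to environmental stress
  beta <- c(0.19, 0.11, 0.00, -0.16, 0.26, 0.18)
  sx <- factor(sex, levels = c("male", "female", "both"))
  ev <- factor(ifelse(environment == "stressful", "stressful", "benign"),
               levels = c("benign", "stressful"))
  X <- stats::model.matrix(~ sx * ev)
  sigma2 <- c(study = 0.55, trait = 0.01, taxon = 0.03, effect = 0.90)
  u_study <- stats::rnorm(n_studies, 0, sqrt(sigma2["study"]))
  names(u_study) <- study_ids
  u_trait <- stats::rnorm(22, 0, sqrt(sigma2["trait"]))
  names(u_trait) <- trait_labels
  u_taxon <- stats::rnorm(7, 0, sqrt(sigma2["taxon"]))
  names(u_taxon) <- taxon_labels
  theta <- drop(X %*% beta) + u_study[study] + u_trait[trait] +
    u_taxon[taxon] + stats::rnorm(n_total, 0, sqrt(sigma2["effect"]))

  # theta is the true *oriented* effect (positive = higher fitness under
  # sexual selection); raw summaries for negatively related traits are
  # drawn at -theta so that sign orientation recovers theta downstream
  flip <- trait_is_negative(trait)
  theta_raw <- ifelse(flip, -theta, theta)
  cfg <- sim_config(n_studies = n_studies,
                    effects_per_study = c(1L, 30L),
                    trait_labels = trait_labels,
                    taxon_labels = taxon_labels,
                    beta = beta,
                    sigma2_study = sigma2[["study"]],
                    sigma2_trait = sigma2[["trait"]],
                    sigma2_taxon = sigma2[["taxon"]],
                    sigma2_effect = sigma2[["effect"]],
                    group_n_range = c(10L, 60L),
                    cv_range = c(0.2, 0.6),
                    seed = seed)
  rec <- .draw_summaries(theta_raw, cfg)

  year <- sample(1995:2017, n_total, replace = TRUE)
  impf <- round(exp(stats::rnorm(n_total, log(3), 0.5)), 2)
  # a handful of records lack year/impact factor, as in curated datasets
  miss <- sample(n_total, 20)
  year[miss] <- NA_integer_
  impf[miss] <- NA_real_

  records <- data.frame(
    study_id = study, line = NA_character_, taxon = taxon, trait = trait,
    fitness_class = fitness_class, sex = sex, environment = environment,
    manipulation = sample(c("enforced monogamy", "sex ratio"), n_total,
                          replace = TRUE, prob = c(0.55, 0.45)),
    generations = sample(3:60, n_total, replace = TRUE),
    blind = sample(c(TRUE, FALSE, NA), n_total, replace = TRUE,
                   prob = c(0.3, 0.5, 0.2)),
    year = year, impact_factor = impf,
    input_kind = ifelse(has_summaries, "summaries", "t"),
    m_high = rec$m_high, s_high = rec$s_high, n_high = rec$n_high,
    m_low = rec$m_low, s_low = rec$s_low, n_low = rec$n_low,
    statistic_value = NA_real_,
    total_n = rec$n_high + rec$n_low,
    direction = 1L,
    negatively_related = trait_is_negative(trait),
    stringsAsFactors = FALSE
  )
  # statistic-only records: convert the drawn summaries to a t statistic
  # and blank the summary columns
  idx <- which(!has_summaries)
  for (i in idx) {
    sp <- sqrt(((records$n_high[i] - 1) * records$s_high[i]^2 +
                  (records$n_low[i] - 1) * records$s_low[i]^2) /
                 (records$n_high[i] + records$n_low[i] - 2))
    d <- (records$m_high[i] - records$m_low[i]) / sp
    records$statistic_value[i] <-
      d / sqrt((records$n_high[i] + records$n_low[i]) /
                 (records$n_high[i] * records$n_low[i]))
  }
  records$m_high[idx] <- records$s_high[idx] <- NA_real_
  records$m_low[idx] <- records$s_low[idx] <- NA_real_

  structure(list(records = records,
                 truth = list(config = cfg, theta = theta,
                              u_study = u_study, u_trait = u_trait,
                              u_taxon = u_taxon)),
            class = "sim_dataset")
}
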