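# shared fixtures: small record tables built in code

# a minimal valid record row; override fields via ...
make_record <- function(...) {
  rec <- data.frame(
    study_id = "s1", line = NA_character_, taxon = "flies",
    trait = "lifespan", fitness_class = "direct", sex = "female",
    environment = "benign", manipulation = "enforced monogamy",
    generations = 10L, blind = NA, year = 2005L, impact_factor = 2.5,
    input_kind = "summaries",
    m_high = 1.5, s_high = 0.5, n_high = 20L,
    m_low = 1.0, s_low = 0.5, n_low = 20L,
    statistic_value = NA_real_, total_n = 40L,
    direction = 1L, negatively_related = FALSE,
    stringsAsFactors = FALSE
  )
  over <- list(...)
  for (nm in names(over)) rec[[nm]] <- over[[nm]]
  rec
}

make_records <- function(n, ...) {
  do.call(rbind, lapply(seq_len(n), function(i) make_record(study_id = paste0("s", i), ...)))
}

# write a records table to a temporary CSV and return the path
write_fixture_csv <- function(data) {
  path <- tempfile(fileext = ".csv")
  utils::write.csv(data, path, row.names = FALSE, na = "")
  path
}

# simulate yi/vi directly from a single-level random-effects model
# (independent of the package's generator) for estimator checks
toy_meta_sample <- function(k, mu, tau2, vi) {
  mu + stats::rnorm(k, 0, sqrt(tau2)) + stats::rnorm(k, 0, sqrt(vi))
}
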