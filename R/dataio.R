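#' Canonical column schema for effect-size tables
#'
#' One row per treatment comparison (one computed effect size). Each record
#' carries study metadata, moderators, and either two-group summary
#' statistics or a test statistic from which a standardised effect can be
#' reconstructed.
#'
#' @return A data frame with one row per column of the schema: column name,
#'   storage type, whether the column is mandatory, and a short description.
#' @export
effect_schema <- function() {
  data.frame(
    column = c(
      "study_id", "line", "taxon", "trait", "fitness_class", "sex",
      "environment", "manipulation", "generations", "blind", "year",
      "impact_factor", "input_kind", "m_high", "s_high", "n_high",
      "m_low", "s_low", "n_low", "statistic_value", "total_n",
      "direction", "negatively_related"
    ),
    type = c(
      "character", "character", "character", "character", "enum", "enum",
      "enum", "character", "integer", "logical", "integer",
      "numeric", "enum", "numeric", "numeric", "integer",
      "numeric", "numeric", "integer", "numeric", "integer",
      "integer", "logical"
    ),
    mandatory = c(
      TRUE, FALSE, TRUE, TRUE, TRUE, TRUE,
      TRUE, FALSE, FALSE, FALSE, FALSE,
      FALSE, TRUE, FALSE, FALSE, FALSE,
      FALSE, FALSE, FALSE, FALSE, FALSE,
      FALSE, FALSE
    ),
    description = c(
      "study identifier",
      "replicate line / population within study (optional)",
      "taxon (e.g. flies, beetles, mice, nematodes, mites, crickets, guppies)",
      "fitness component measured",
      "relationship to population fitness: direct | indirect | ambiguous",
      "sex measured: male | female | both",
      "evolution environment: stressful | benign | undefined",
      "sexual-selection manipulation (e.g. enforced monogamy, sex ratio)",
      "number of generations of experimental evolution",
      "blind scoring used (TRUE/FALSE, NA if unknown)",
      "publication year",
      "journal impact factor (NA if unavailable)",
      "summaries | t | F | chisq | proportions",
      "high-sexual-selection group mean (proportion for input_kind = proportions)",
      "high group SD",
      "high group sample size",
      "low-sexual-selection group mean (proportion for input_kind = proportions)",
      "low group SD",
      "low group sample size",
      "test statistic value (t, F or chi-square)",
      "total sample size for statistic-based records",
      "+1/-1 direction of the reported difference (high minus low)",
      "trait is negatively related to fitness (sign inverted)"
    ),
    stringsAsFactors = FALSE
  )
}

.enum_levels <- list(
  fitness_class = c("direct", "indirect", "ambiguous"),
  sex = c("male", "female", "both"),
  environment = c("stressful", "benign", "undefined"),
  input_kind = c("summaries", "t", "F", "chisq", "proportions")
)

# numeric parser tolerant of Unicode minus signs as they appear in
# digitised tables
.parse_num <- function(x) {
  x <- gsub("−|–", "-", trimws(as.character(x)))
  x[x %in% c("", "NA", "na", ".")] <- NA
  suppressWarnings(as.numeric(x))
}

.parse_enum <- function(x, field) {
  lev <- .enum_levels[[field]]
  x <- trimws(tolower(as.character(x)))
  if (field == "input_kind") {
    # F is conventionally upper case
    x[x == "f"] <- "F"
    lev2 <- lev
  } else {
    lev2 <- lev
  }
  bad <- !is.na(x) & nzchar(x) & !(x %in% lev2)
  if (any(bad)) {
    warning(sprintf(
      "column '%s': %d unparseable value(s) (%s) set to %s",
      field, sum(bad), paste(unique(x[bad]), collapse = ", "),
      if (field == "environment") "'undefined'" else "NA"
    ), call. = FALSE)
    x[bad] <- if (field == "environment") "undefined" else NA
  }
  x[is.na(x) | !nzchar(x)] <- if (field == "environment") "undefined" else NA
  x
}

.parse_logical <- function(x) {
  x <- trimws(tolower(as.character(x)))
  out <- rep(NA, length(x))
  out[x %in% c("true", "t", "yes", "y", "1")] <- TRUE
  out[x %in% c("false", "f", "no", "n", "0")] <- FALSE
  out
}

#' Read an effect-size table
#'
#' Reads a CSV in the canonical schema (see [effect_schema()]), coerces
#' column types, validates enum fields (unparseable values become
#' `undefined`/`NA` with a warning) and optionally drops repeated
#' measurements of the same line across generations, keeping only the last
#' reported generation.
#'
#' @param path Path to a CSV file.
#' @param dedupe Drop duplicated (study, line, trait) rows, keeping the row
#'   with the largest `generations` value. Defaults to `TRUE`.
#' @return A data frame of typed effect records.
#' @export
read_effect_data <- function(path, dedupe = TRUE) {
  raw <- utils::read.csv(path, colClasses = "character",
                         check.names = FALSE, fileEncoding = "UTF-8")
  sch <- effect_schema()
  missing_cols <- setdiff(sch$column[sch$mandatory], names(raw))
  if (length(missing_cols)) {
    stop("missing mandatory column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  }
  out <- data.frame(row.names = seq_len(nrow(raw)))
  for (i in seq_len(nrow(sch))) {
    cn <- sch$column[i]
    col <- if (cn %in% names(raw)) raw[[cn]] else rep(NA_character_, nrow(raw))
    out[[cn]] <- switch(sch$type[i],
      character = { x <- trimws(col); x[!nzchar(x) | is.na(x)] <- NA; x },
      enum      = .parse_enum(col, cn),
      integer   = as.integer(round(.parse_num(col))),
      numeric   = .parse_num(col),
      logical   = .parse_logical(col)
    )
  }
  if (nrow(out) && anyNA(out$direction)) {
    out$direction[is.na(out$direction)] <- 1L
  }
  if (nrow(out) && anyNA(out$negatively_related)) {
    idx <- is.na(out$negatively_related)
    out$negatively_related[idx] <- trait_is_negative(out$trait[idx])
  }
  if (dedupe) out <- drop_repeated_generations(out)
  rownames(out) <- NULL
  out
}

#' Write an effect-size table
#'
#' @param data Data frame in the canonical schema.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_effect_data <- function(data, path) {
  utils::write.csv(data, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Validate an effect-size table
#'
#' Checks schema, enum values and per-kind field availability and returns a
#' validation report.
#'
#' @param data Data frame of effect records.
#' @return A list with `n_records`, `problems` (character vector, empty when
#'   clean) and `ok`.
#' @export
validate_effect_data <- function(data) {
  sch <- effect_schema()
  problems <- character()
  miss <- setdiff(sch$column[sch$mandatory], names(data))
  if (length(miss)) {
    problems <- c(problems, paste("missing mandatory column(s):",
                                  paste(miss, collapse = ", ")))
  } else {
    sm <- !is.na(data$input_kind) & data$input_kind == "summaries"
    need <- c("m_high", "s_high", "n_high", "m_low", "s_low", "n_low")
    if (all(need %in% names(data)) && any(sm)) {
      bad <- sm & Reduce(`|`, lapply(data[need], is.na))
      if (any(bad)) {
        problems <- c(problems, sprintf(
          "%d summary record(s) with incomplete group summaries", sum(bad)))
      }
    }
    st <- !is.na(data$input_kind) & data$input_kind %in% c("t", "F", "chisq")
    if ("statistic_value" %in% names(data) && any(st & is.na(data$statistic_value))) {
      problems <- c(problems, sprintf(
        "%d statistic record(s) missing statistic_value",
        sum(st & is.na(data$statistic_value))))
    }
    if ("n_high" %in% names(data)) {
      badn <- !is.na(data$n_high) & data$n_high < 2 |
        !is.na(data$n_low) & data$n_low < 2
      if (any(badn, na.rm = TRUE)) {
        problems <- c(problems, sprintf("%d record(s) with group n < 2",
                                        sum(badn, na.rm = TRUE)))
      }
    }
  }
  list(n_records = nrow(data), problems = problems, ok = !length(problems))
}

#' Drop repeated generations of the same experimental line
#'
#' Defensive guard implementing the "last reported generation only" rule:
#' when the same (study, line, trait) combination appears more than once the
#' row with the largest `generations` value is kept.
#'
#' @param data Data frame of effect records.
#' @return Filtered data frame (order preserved among kept rows).
#' @export
drop_repeated_generations <- function(data) {
  if (!nrow(data) || !all(c("study_id", "trait") %in% names(data))) return(data)
  line <- if ("line" %in% names(data)) data$line else rep(NA_character_, nrow(data))
  line[is.na(line)] <- ""
  key <- paste(data$study_id, line, data$trait, sep = "\r")
  gen <- if ("generations" %in% names(data)) data$generations else rep(1L, nrow(data))
  gen[is.na(gen)] <- 1L
  # only dedupe keys that genuinely repeat with differing generations
  keep <- rep(TRUE, nrow(data))
  for (k in unique(key[duplicated(key)])) {
    idx <- which(key == k)
    if (length(unique(gen[idx])) > 1L) {
      keep[idx[gen[idx] < max(gen[idx])]] <- FALSE
    }
  }
  data[keep, , drop = FALSE]
}

#' Traits negatively related to population fitness
#'
#' Trait labels for which a higher measured value indicates *lower* fitness
#' (e.g. parasite load, mutation load, extinction risk or rate, male mating
#' latency, rate of senescence). Effect sizes for these traits have their
#' sign inverted so that positive values always mean higher fitness under
#' sexual selection. The list ships as an editable plain-text config file.
#'
#' @param path Optional path to a custom list (one trait label per line,
#'   `#` comments allowed); defaults to the packaged list.
#' @return Character vector of trait labels (lower case).
#' @export
negatively_related_traits <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "negatively_related_traits.txt",
                        package = "sexselmeta")
  }
  x <- readLines(path, warn = FALSE)
  x <- trimws(sub("#.*$", "", x))
  tolower(x[nzchar(x)])
}

#' Is a trait negatively related to fitness?
#'
#' @param trait Character vector of trait labels.
#' @param negative_list Trait list, defaults to [negatively_related_traits()].
#' @return Logical vector.
#' @export
trait_is_negative <- function(trait, negative_list = negatively_related_traits()) {
  tolower(trimws(as.character(trait))) %in% negative_list
}

#' Orient the sign of a raw effect size
#'
#' Raw effects are computed as high-sexual-selection minus low. For traits
#' negatively related to fitness the sign is inverted, so that positive
#' oriented effects always indicate higher fitness when sexual selection is
#' present or elevated.
#'
#' @param raw_effect Numeric vector of raw effects (high minus low).
#' @param negatively_related Logical vector (recycled) flagging traits whose
#'   sign must be inverted.
#' @return Oriented effects.
#' @export
orient_sign <- function(raw_effect, negatively_related) {
  ifelse(rep_len(isTRUE_vec(negatively_related), length(raw_effect)),
         -raw_effect, raw_effect)
}

# vectorised isTRUE: NA treated as FALSE
isTRUE_vec <- function(x) !is.na(x) & as.logical(x)

#' Restrict to the moderated-analysis subset
#'
#' Keeps records with an unambiguous relationship to fitness
#' (`fitness_class` direct or indirect) and a defined evolution environment
#' (`environment` stressful or benign) — the subset used for sex-by-
#' environment meta-regressions. Idempotent and order preserving.
#'
#' @param data Data frame of effect records.
#' @return Filtered data frame.
#' @export
filter_moderator_subset <- function(data) {
  keep <- data$fitness_class %in% c("direct", "indirect") &
    data$environment %in% c("stressful", "benign")
  keep[is.na(keep)] <- FALSE
  data[keep, , drop = FALSE]
}
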