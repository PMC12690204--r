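#' Run configuration
#'
#' Validates and normalizes a flat configuration (a named list or a path to a
#' JSON file with the same keys) describing one model run. Unknown keys are
#' rejected; every run is reproducible from its configuration plus seed, and
#' all tabular outputs carry the configuration hash.
#'
#' Recognized keys and defaults mirror the reference parameter choices of the
#' model exploration (`g = 2000`, `zc = 1e6`, `lambda_pm = lambda_inv = 1`,
#' `lm = 50`):
#' `model` ("structural_only"), `g` (2000), `zc` (1e6), `znc` (1e6),
#' `mu` (1e-10), `N` (1e8), `kappa` (NA; when set, rates are built with
#' [kappa_rates()]), `lambda_dupl`, `lambda_del`, `lambda_inv`, `lambda_pm`,
#' `lambda_indel_plus`, `lambda_indel_minus`, `lm` (50),
#' `bracket` (c(1e3, 1e9)), `tolerance` (1e-6), `n_mu` (grid for curves),
#' `kappa_grid` (grid for curves), `seed` (1), `verbosity` ("info").
#'
#' @param x named list of settings, a JSON file path, or `NULL` for defaults.
#' @return A list of class `"run_config"` with all fields populated, plus
#'   `hash` (MD5 of the canonical JSON serialization) and `rates`/`arch`/`pop`
#'   accessors via [config_objects()].
#' @export
run_config <- function(x = NULL) {
  defaults <- list(
    model = "structural_only",
    g = 2000, zc = 1e6, znc = 1e6,
    mu = 1e-10, N = 1e8,
    kappa = NA_real_,
    lambda_dupl = 1, lambda_del = 1, lambda_inv = 0, lambda_pm = 0,
    lambda_indel_plus = 0, lambda_indel_minus = 0,
    lm = 50,
    bracket = c(1e3, 1e9), tolerance = 1e-6,
    n_mu = NULL, kappa_grid = NULL,
    seed = 1L, verbosity = "info"
  )
  if (is.character(x) && length(x) == 1L) {
    if (!file.exists(x)) stop("config file not found: ", x)
    x <- jsonlite::read_json(x, simplifyVector = TRUE)
  }
  if (is.null(x)) x <- list()
  if (!is.list(x)) stop("config must be a named list or a JSON file path")
  # model-aware defaults: the expanded model activates all six types at the
  # reference multipliers, the indel-only model the two indel types
  mdl <- if (!is.null(x$model)) x$model else defaults$model
  if (identical(mdl, "expanded"))
    defaults[c("lambda_inv", "lambda_pm",
               "lambda_indel_plus", "lambda_indel_minus")] <- 1
  if (identical(mdl, "indel_only"))
    defaults[c("lambda_indel_plus", "lambda_indel_minus")] <- 1
  unknown <- setdiff(names(x), names(defaults))
  if (length(unknown))
    stop("unknown config keys: ", paste(unknown, collapse = ", "))
  cfg <- utils::modifyList(defaults, x, keep.null = TRUE)
  if (!cfg$model %in% c("structural_only", "expanded", "indel_only"))
    stop("model must be one of structural_only, expanded, indel_only")
  if (!cfg$verbosity %in% c("quiet", "info", "debug"))
    stop("verbosity must be quiet, info or debug")
  for (key in c("g", "zc", "znc", "mu", "N", "lm", "tolerance", "seed"))
    if (!is.numeric(cfg[[key]]) || length(cfg[[key]]) != 1L || !is.finite(cfg[[key]]))
      stop("config key '", key, "' must be a finite numeric scalar")
  if (length(cfg$bracket) != 2L || any(cfg$bracket <= 0) ||
      cfg$bracket[2] <= cfg$bracket[1])
    stop("bracket must be an increasing positive interval")
  # constructing the domain objects validates the remaining constraints
  obj <- config_objects(cfg)
  cfg$hash <- config_hash(cfg)
  structure(cfg, class = "run_config")
}

#' Domain objects of a configuration
#'
#' @param cfg a [run_config()] (or plain list with the same keys).
#' @return List with `arch` ([genome_architecture()]), `rates`
#'   ([mutation_rates()] or [kappa_rates()] when `kappa` is set) and `pop`
#'   ([population_params()]).
#' @export
config_objects <- function(cfg) {
  rates <- if (!is.null(cfg$kappa) && !is.na(cfg$kappa))
    kappa_rates(mu = cfg$mu, kappa = cfg$kappa,
                lambda_pm = cfg$lambda_pm, lambda_inv = cfg$lambda_inv,
                lm = cfg$lm)
  else
    mutation_rates(mu = cfg$mu,
                   lambda_dupl = cfg$lambda_dupl, lambda_del = cfg$lambda_del,
                   lambda_inv = cfg$lambda_inv, lambda_pm = cfg$lambda_pm,
                   lambda_indel_plus = cfg$lambda_indel_plus,
                   lambda_indel_minus = cfg$lambda_indel_minus,
                   lm = cfg$lm)
  list(arch = genome_architecture(cfg$g, cfg$zc, cfg$znc, mode = "analytic"),
       rates = rates,
       pop = population_params(cfg$N))
}

config_hash <- function(cfg) {
  keep <- cfg[setdiff(names(cfg), "hash")]
  keep <- keep[order(names(keep))]
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  jsonlite::write_json(keep, tmp, auto_unbox = TRUE, digits = NA, null = "null")
  unname(tools::md5sum(tmp))
}

## ---- tabular I/O -------------------------------------------------------------

format_num <- function(x) {
  ifelse(is.na(x), "NA", sprintf("%.17g", x))
}

#' Write a result table as tab-separated text
#'
#' Writes a data frame as TSV with a header row, numeric columns serialized
#' with full double precision (so tables round-trip losslessly), and an
#' optional leading `# config_hash:` comment carrying the configuration hash.
#'
#' @param df data frame.
#' @param path output file path, or `""` for stdout.
#' @param config_hash optional hash string recorded as a comment line.
#' @return Invisibly, the path.
#' @export
write_result_table <- function(df, path = "", config_hash = NULL) {
  con <- if (identical(path, "")) stdout() else file(path, "w")
  if (!identical(path, "")) on.exit(close(con))
  if (!is.null(config_hash))
    writeLines(paste0("# config_hash: ", config_hash), con)
  out <- df
  for (j in seq_along(out))
    if (is.numeric(out[[j]])) out[[j]] <- format_num(out[[j]])
  utils::write.table(out, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a result table written by [write_result_table()]
#'
#' @param path file path.
#' @return A data frame; the config hash (if present) is attached as attribute
#'   `"config_hash"`.
#' @export
read_result_table <- function(path) {
  first <- readLines(path, n = 1L)
  hash <- NULL
  if (startsWith(first, "# config_hash: "))
    hash <- sub("^# config_hash: ", "", first)
  df <- utils::read.delim(path, comment.char = "#", check.names = FALSE,
                          stringsAsFactors = FALSE)
  attr(df, "config_hash") <- hash
  df
}

## ---- species tables ----------------------------------------------------------

SPECIES_REQUIRED <- c("species", "Ne", "mu", "noncoding_fraction")

#' Read a species comparison table
#'
#' Reads a tab-separated species table with header and required columns
#' `species`, `Ne`, `mu`, `noncoding_fraction` (optional `zc` and `g`).
#' Every row is validated (`Ne > 0`, `mu > 0`, fraction in `[0, 1]`); invalid
#' rows are rejected with a diagnostic naming the offending file lines.
#'
#' @param path TSV file path.
#' @return Data frame of species records.
#' @export
read_species_table <- function(path) {
  if (!file.exists(path)) stop("species table not found: ", path)
  df <- utils::read.delim(path, check.names = FALSE, stringsAsFactors = FALSE,
                          comment.char = "#")
  missing <- setdiff(SPECIES_REQUIRED, names(df))
  if (length(missing))
    stop("species table is missing required columns: ",
         paste(missing, collapse = ", "))
  bad <- character(0)
  for (col in c("Ne", "mu", "noncoding_fraction", intersect(c("zc", "g"), names(df)))) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    invalid <- is.na(v) & !(is.na(df[[col]]) | df[[col]] == "NA")
    if (col == "Ne") invalid <- invalid | (!is.na(v) & v <= 0)
    if (col == "mu") invalid <- invalid | (!is.na(v) & v <= 0)
    if (col == "noncoding_fraction")
      invalid <- invalid | (!is.na(v) & (v < 0 | v > 1))
    if (any(invalid))
      bad <- c(bad, sprintf("line %d: invalid %s value '%s'",
                            which(invalid) + 1L, col, df[[col]][invalid]))
    df[[col]] <- v
  }
  if (length(bad))
    stop("species table contains invalid rows:\n  ",
         paste(bad, collapse = "\n  "))
  df
}

#' Write a species table
#'
#' @param df species data frame (see [read_species_table()] for the schema).
#' @param path output TSV path.
#' @return Invisibly, the path.
#' @export
write_species_table <- function(df, path) {
  write_result_table(df, path)
}

#' Predicted equilibrium fractions for a species table
#'
#' For each species record, solves the expanded-model equilibrium at the
#' record's compound parameter `Ne x mu x structural_point_ratio` (the per-base
#' structural rate is taken as a fixed multiple of the recorded substitution
#' rate; 1:1 by default) and tabulates the predicted equilibrium noncoding
#' fraction next to the observed one. Records carrying their own `zc`/`g`
#' columns use them; others use the configured defaults.
#'
#' @param records species data frame from [read_species_table()] or
#'   [generate_fixture_table()].
#' @param kappa deletion bias used for the prediction.
#' @param structural_point_ratio ratio of structural to point mutation rates.
#' @param zc,g default coding architecture.
#' @param mu_ref reference rate used to split the compound parameter.
#' @param lm,lambda_pm,lambda_inv expanded-model settings.
#' @param bracket,tolerance solver controls.
#' @return Data frame with one row per record: `species`, `Ne`, `mu`, `N_mu`,
#'   `observed_fraction`, `predicted_fraction`, `converged`.
#' @export
predict_overlay <- function(records, kappa = 1, structural_point_ratio = 1,
                            zc = 1e6, g = 2000, mu_ref = 1e-9, lm = 50,
                            lambda_pm = 1, lambda_inv = 1,
                            bracket = c(1e3, 1e9), tolerance = 1e-6) {
  stopifnot(is.data.frame(records))
  rows <- lapply(seq_len(nrow(records)), function(i) {
    rec <- records[i, ]
    zci <- if ("zc" %in% names(records) && !is.na(rec$zc)) rec$zc else zc
    gi <- if ("g" %in% names(records) && !is.na(rec$g)) rec$g else g
    n_mu <- rec$Ne * rec$mu * structural_point_ratio
    tab <- equilibrium_curve(n_mu = n_mu, kappa = kappa, zc = zci, g = gi,
                             mu_ref = mu_ref, lambda_pm = lambda_pm,
                             lambda_inv = lambda_inv, lm = lm,
                             bracket = bracket, tolerance = tolerance)
    data.frame(species = rec$species, Ne = rec$Ne, mu = rec$mu, N_mu = n_mu,
               observed_fraction = rec$noncoding_fraction,
               predicted_fraction = tab$fraction_star[1],
               converged = tab$converged[1])
  })
  do.call(rbind, rows)
}

#' Generate a synthetic species table
#'
#' Stands in for an empirical species compilation: samples compound parameters
#' `Ne x mu` log-uniformly over the explored model range (`1e-5` to `1e-1`),
#' splits them into `Ne` (log-uniform over `1e5`–`1e9`) and `mu`, sets each
#' observed noncoding fraction to the model's own equilibrium prediction times
#' multiplicative lognormal noise, and returns the table. With `noise = 0` the
#' observed fractions equal the predictions exactly. Fully reproducible from
#' the seed.
#'
#' @param n_species number of synthetic species (>= 1).
#' @param seed RNG seed.
#' @param noise standard deviation of the lognormal multiplicative noise.
#' @param kappa deletion bias of the generating model.
#' @param zc,g coding architecture written into the table.
#' @param ... further arguments passed to [predict_overlay()]'s solver via
#'   [equilibrium_curve()] (`mu_ref`, `lm`, ...).
#' @return Species data frame with columns `species`, `Ne`, `mu`,
#'   `noncoding_fraction`, `zc`, `g`.
#' @export
generate_fixture_table <- function(n_species, seed, noise = 0.1, kappa = 1,
                                   zc = 1e6, g = 2000, ...) {
  if (n_species < 1) stop("n_species must be >= 1")
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old))
  set.seed(seed)
  n_mu <- 10^stats::runif(n_species, -5, -1)
  Ne <- 10^stats::runif(n_species, 5, 9)
  mu <- n_mu / Ne
  eps <- stats::rnorm(n_species, 0, 1)
  df <- data.frame(species = sprintf("synthetic_sp%03d", seq_len(n_species)),
                   Ne = Ne, mu = mu, noncoding_fraction = NA_real_,
                   zc = zc, g = g)
  pred <- predict_overlay(df, kappa = kappa, zc = zc, g = g, ...)
  df$noncoding_fraction <- pmin(1, pred$predicted_fraction * exp(noise * eps))
  attr(df, "predicted_fraction") <- pred$predicted_fraction
  df
}
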