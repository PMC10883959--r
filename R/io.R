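# Config parsing and tabular writers shared by the analysis functions
# and the command-line wrapper.

config_param_keys <- c("r", "s", "K", "c", "n", "b", "d", "p", "q",
                       "alpha", "beta")
config_other_keys <- c("fixture", "rtol", "atol", "t_end", "n_save",
                       "eps_extinct", "eps_persist", "marginal_tol",
                       "out", "format", "seed", "log_level")

#' Parse a run configuration
#'
#' Reads a flat key/value config file (JSON or YAML, chosen by file
#' extension) and/or a list of overriding values (e.g. parsed CLI
#' flags; overrides win).  Recognised keys are the eleven model
#' parameters, `fixture` (`"theoretical"` or `"mink"`, used as a base
#' that explicit parameter keys then override), solver settings
#' (`rtol`, `atol`, `t_end`, `n_save`), thresholds (`eps_extinct`,
#' `eps_persist`, `marginal_tol`), `out`, `format` (`"csv"` or
#' `"json"`), `seed` and `log_level`.  Unknown keys and non-positive
#' parameter values are rejected with a message naming the key.
#'
#' @param path config file path, or `NULL` for overrides only.
#' @param overrides named list applied after (over) the file values.
#' @return A list with elements `params` (an [invasion_model()]),
#'   `solver`, `thresholds`, `output` and `seed`.
#' @examples
#' cfg <- parse_config(system.file("extdata", "theoretical.json",
#'                                 package = "invasim"),
#'                     overrides = list(alpha = 1, beta = 1))
#' cfg$params
#' @export
parse_config <- function(path = NULL, overrides = list()) {
  vals <- list()
  if (!is.null(path)) {
    if (!file.exists(path)) stop("config file not found: ", path,
                                 call. = FALSE)
    ext <- tolower(tools::file_ext(path))
    vals <- switch(ext,
      json = jsonlite::read_json(path, simplifyVector = TRUE),
      yaml = ,
      yml  = {
        if (!requireNamespace("yaml", quietly = TRUE))
          stop("the 'yaml' package is required to read YAML configs",
               call. = FALSE)
        yaml::read_yaml(path)
      },
      stop("unsupported config format: .", ext, " (use JSON or YAML)",
           call. = FALSE)
    )
    if (!is.list(vals)) vals <- as.list(vals)
  }
  vals[names(overrides)] <- overrides

  known <- c(config_param_keys, config_other_keys)
  bad <- setdiff(names(vals), known)
  if (length(bad))
    stop("unknown config key(s): ", paste(bad, collapse = ", "),
         call. = FALSE)

  pars <- vals[intersect(names(vals), config_param_keys)]
  for (nm in names(pars)) {
    v <- pars[[nm]]
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config key '", nm, "' must be a single strictly positive ",
           "finite number, got ", format(v), call. = FALSE)
  }
  if (!is.null(vals$fixture)) {
    if (is.null(pars$alpha) || is.null(pars$beta))
      stop("a fixture-based config must still provide 'alpha' and 'beta'",
           call. = FALSE)
    m <- fixture(vals$fixture, alpha = pars$alpha, beta = pars$beta)
    m <- do.call(set_params, c(list(m), pars))
  } else {
    missing <- setdiff(config_param_keys, names(pars))
    if (length(missing))
      stop("missing required parameter(s): ",
           paste(missing, collapse = ", "), call. = FALSE)
    m <- do.call(invasion_model, pars)
  }

  num_or <- function(key, default) {
    v <- vals[[key]]
    if (is.null(v)) return(default)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("config key '", key, "' must be a single positive number",
           call. = FALSE)
    as.numeric(v)
  }
  list(params = m,
       solver = list(rtol = num_or("rtol", 1e-8),
                     atol = num_or("atol", 1e-10),
                     t_end = num_or("t_end", 5000),
                     n_save = num_or("n_save", 2000)),
       thresholds = list(eps_extinct = num_or("eps_extinct", 1e-4),
                         eps_persist = num_or("eps_persist", 1e-2),
                         marginal_tol = num_or("marginal_tol", 1e-6)),
       output = list(path = vals$out,
                     format = if (is.null(vals$format)) "csv"
                              else match.arg(vals$format, c("csv", "json"))),
       seed = if (is.null(vals$seed)) 20240222 else as.integer(vals$seed))
}

#' Write an analysis table to CSV or JSON
#'
#' Column names are preserved exactly; floating-point values are
#' serialised with 10 significant digits, so a round-trip read
#' reproduces them to that precision.  An empty data frame yields a
#' header-only CSV (or empty JSON array).
#'
#' @param rows a data frame.
#' @param path output file path.
#' @param format `"csv"` (RFC-4180 quoting) or `"json"` (array of
#'   records keyed by column name).
#' @return `path`, invisibly.
#' @examples
#' f <- tempfile(fileext = ".csv")
#' m <- fixture("theoretical", alpha = 1, beta = 1)
#' write_table(boundary_equilibria(m), f)
#' read.csv(f)
#' @export
write_table <- function(rows, path, format = c("csv", "json")) {
  stopifnot(is.data.frame(rows))
  format <- match.arg(format)
  num <- vapply(rows, is.numeric, logical(1))
  rows[num] <- lapply(rows[num], signif, digits = 10)
  if (format == "csv") {
    utils::write.csv(rows, path, row.names = FALSE, quote = TRUE)
  } else {
    jsonlite::write_json(rows, path, dataframe = "rows", digits = NA,
                         na = "null", auto_unbox = TRUE)
  }
  invisible(path)
}
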