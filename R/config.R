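#' Read a TOML configuration file (scalar/array subset)
#'
#' A deliberately small TOML reader covering the subset the package's
#' configuration files use: `[table]` headers, `key = value` pairs with
#' numeric, boolean, quoted-string and flat-array values, and `#` comments.
#' No R TOML parser is part of the package's dependency set, and this subset
#' is all the configuration schema needs.
#'
#' @param path File path.
#' @return Named list of tables (named lists of values).
#' @export
read_toml <- function(path) {
  if (!file.exists(path)) stop("config file not found: ", path)
  lines <- readLines(path, warn = FALSE)
  out <- list()
  section <- NULL
  parse_scalar <- function(tok, where) {
    tok <- trimws(tok)
    if (grepl('^".*"$', tok)) return(gsub('^"|"$', "", tok))
    if (tok == "true") return(TRUE)
    if (tok == "false") return(FALSE)
    v <- suppressWarnings(as.numeric(tok))
    if (is.na(v)) stop("cannot parse TOML value ", where, ": '", tok, "'")
    v
  }
  for (ln in seq_along(lines)) {
    line <- lines[[ln]]
    # strip comments (quote-aware for the simple single-quote-free files here)
    if (grepl("#", line)) {
      if (grepl('^[^"]*#', line)) line <- sub("#.*$", "", line)
      else line <- sub('("[^"]*")\\s*#.*$', "\\1", line)
    }
    line <- trimws(line)
    if (line == "") next
    m <- regmatches(line, regexec("^\\[\\s*([A-Za-z0-9_.-]+)\\s*\\]$", line))[[1]]
    if (length(m)) {
      section <- m[2]
      if (is.null(out[[section]])) out[[section]] <- list()
      next
    }
    eq <- regexpr("=", line, fixed = TRUE)
    if (eq < 0) stop(sprintf("malformed TOML at %s line %d: '%s'", path, ln, line))
    key <- trimws(substr(line, 1L, eq - 1L))
    val <- trimws(substr(line, eq + 1L, nchar(line)))
    where <- sprintf("at %s line %d", path, ln)
    parsed <- if (grepl("^\\[.*\\]$", val)) {
      toks <- strsplit(sub("^\\[", "", sub("\\]$", "", val)), ",")[[1]]
      toks <- toks[trimws(toks) != ""]
      unlist(lapply(toks, parse_scalar, where = where))
    } else parse_scalar(val, where)
    if (is.null(section)) out[[key]] <- parsed else out[[section]][[key]] <- parsed
  }
  out
}

#' Load and validate a growth-parameter or experiment configuration
#'
#' Reads a TOML file and builds the validated object it describes. A
#' *calibration* file has a `[calibration]` table (keys `name`, optionally
#' `maxB`-independent globals) and one `[orderN]` table per branching number
#' with the [growth_params()] fields. An *experiment* file has an
#' `[experiment]` table (`treatment`, `n_replicates`, `duration`, `seed`,
#' optionally `trace_days`) and `calibrations = [file, ...]` paths resolved
#' relative to the config file. Unknown keys produce a warning (forward
#' compatibility); invalid values produce an error naming the field.
#'
#' @param path Path to the TOML file.
#' @return An [calibration()] or [experiment_config()] object.
#' @export
load_config <- function(path) {
  toml <- read_toml(path)
  if (!is.null(toml$experiment)) return(load_experiment_config(toml, path))
  if (is.null(toml$calibration))
    stop("config file must contain a [calibration] or [experiment] table: ", path)
  order_tabs <- grep("^order[0-9]+$", names(toml), value = TRUE)
  if (!length(order_tabs)) stop("calibration config has no [orderN] tables: ", path)
  orders <- sort(as.integer(sub("^order", "", order_tabs)))
  name <- toml$calibration$name %||% "unnamed"
  max_order <- as.integer(toml$calibration$max_order %||% max(orders))
  known <- c("r_mean", "r_sd", "lmax_mean", "lmax_sd", "la", "lb",
             "ln_mean", "ln_sd", "theta_mean", "theta_sd", "maxB",
             "radius", "linear_density", "tropism_sigma")
  required <- setdiff(known, c("maxB", "radius", "linear_density",
                               "tropism_sigma"))
  sets <- lapply(orders, function(b) {
    tab <- toml[[paste0("order", b)]]
    extra <- setdiff(names(tab), known)
    if (length(extra))
      warning(sprintf("ignoring unknown key(s) in [order%d] of %s: %s",
                      b, path, paste(extra, collapse = ", ")), call. = FALSE)
    miss <- setdiff(required, names(tab))
    if (length(miss))
      stop(sprintf("missing required field(s) in [order%d] of %s: %s",
                   b, path, paste(miss, collapse = ", ")), call. = FALSE)
    args <- tab[intersect(names(tab), known)]
    args$branching_number <- b
    args$compartment <- name
    args$max_order <- max_order
    if (b > 0L) args$maxB <- NULL
    do.call(growth_params, args)
  })
  calibration(sets, name = name)
}

load_experiment_config <- function(toml, path) {
  ex <- toml$experiment
  files <- ex$calibrations
  if (is.null(files) || length(files) != 2L)
    stop("field 'calibrations' must list exactly two calibration files: ", path)
  calibs <- lapply(file.path(dirname(path), files), load_config)
  names(calibs) <- vapply(calibs, attr, "", "name")
  experiment_config(
    treatment = ex$treatment %||% stop("missing required field 'treatment'"),
    n_replicates = ex$n_replicates %||% stop("missing required field 'n_replicates'"),
    duration = ex$duration %||% stop("missing required field 'duration'"),
    calibrations = calibs,
    trace_days = ex$trace_days,
    seed = as.integer(ex$seed %||% 1L)
  )
}

#' Packaged split-root growth calibrations
#'
#' Returns the three growth calibrations shipped with the package:
#' `"nutrient"` and `"water"` parameterize the two compartments of the
#' resource-partitioned treatment, `"mixed"` parameterizes both (identical)
#' compartments of the resource-mixed treatment. The values are
#' reverse-engineered from the per-order trait summaries of the split-root
#' study the package emulates (branching densities/ratios, branch angles,
#' specific root lengths): the water compartment has fewer but longer, more
#' sparsely branching primaries with progressively suppressed high-order
#' laterals, while the nutrient compartment branches densely up to branching
#' number 4.
#'
#' @return Named list of three [calibration()] objects.
#' @examples
#' cal <- packaged_calibrations()
#' cal$water[["0"]]$lmax_mean
#' @export
packaged_calibrations <- function() {
  files <- c(nutrient = "nutrient.toml", water = "water.toml",
             mixed = "mixed.toml")
  out <- lapply(files, function(f)
    load_config(system.file("extdata", f, package = "rootbox",
                            mustWork = TRUE)))
  names(out) <- names(files)
  out
}
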