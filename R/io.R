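# Delimited-text dialect is fixed, not sniffed: comma separator, dot
# decimal, UTF-8, header required. Numbers are written with 17 significant
# digits so write/read round-trips are bitwise exact.

# shortest decimal representation that parses back to the same double
fmt_num <- function(x) {
  vapply(x, function(v) {
    for (d in c(15L, 16L)) {
      s <- sprintf("%.*g", d, v)
      if (as.numeric(s) == v) return(s)
    }
    sprintf("%.17g", v)
  }, character(1))
}

#' Write / read a kinetics series as delimited text
#'
#' Standard columns `time_h, biomass_g_per_l, phb_g_per_l, dpa_g_per_l,
#' cry_g_per_l`. Censored (below-detection-limit) observations are recorded
#' as exactly 0, so censoring flags are inferred from exact zeros on read;
#' write/read round-trips reproduce the series bitwise.
#'
#' @param series a `kinetics_series`.
#' @param path file path.
#' @return `read_kinetics` returns a `kinetics_series`; `write_kinetics`
#'   returns `path` invisibly.
#' @export
write_kinetics <- function(series, path) {
  stopifnot(is.data.frame(series))
  missing_cols <- setdiff(.kin_cols, names(series))
  if (length(missing_cols))
    stop("series is missing column(s): ", paste(missing_cols, collapse = ", "))
  lines <- c(paste(.kin_cols, collapse = ","),
             vapply(seq_len(nrow(series)), function(i)
               paste(fmt_num(unlist(series[i, .kin_cols])), collapse = ","),
               character(1)))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_kinetics
#' @export
read_kinetics <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) < 2L) stop("kinetics file needs a header and data rows")
  header <- strsplit(lines[1], ",", fixed = TRUE)[[1]]
  missing_cols <- setdiff(.kin_cols, header)
  if (length(missing_cols))
    stop("kinetics file is missing column(s): ",
         paste(missing_cols, collapse = ", "))
  unknown <- setdiff(header, .kin_cols)
  if (length(unknown))
    stop("unknown column(s) in kinetics file: ",
         paste(unknown, collapse = ", "))
  n <- length(lines) - 1L
  vals <- matrix(NA_real_, nrow = n, ncol = length(header),
                 dimnames = list(NULL, header))
  for (i in seq_len(n)) {
    fields <- strsplit(lines[i + 1L], ",", fixed = TRUE)[[1]]
    if (length(fields) != length(header))
      stop("line ", i + 1L, ": expected ", length(header), " fields, got ",
           length(fields))
    num <- suppressWarnings(as.numeric(fields))
    if (any(is.na(num)))
      stop("line ", i + 1L, ": non-numeric value '",
           fields[which(is.na(num))[1]], "' in column '",
           header[which(is.na(num))[1]],
           "' (comma decimals are not accepted; use dot decimals)")
    vals[i, ] <- num
  }
  t <- vals[, "time_h"]
  if (anyDuplicated(t))
    stop("duplicate time value at line ",
         which(duplicated(t))[1] + 1L, ": ", t[duplicated(t)][1])
  if (length(t) > 1L && any(diff(t) <= 0))
    stop("time values must be strictly increasing (violated at line ",
         which(diff(t) <= 0)[1] + 2L, ")")
  kinetics_series(t, vals[, "biomass_g_per_l"], vals[, "phb_g_per_l"],
                  vals[, "dpa_g_per_l"], vals[, "cry_g_per_l"])
}

.optional_keys <- c("glucose_g_per_l", "soybean_g_per_l", "label")

#' Write / read a biodynamic parameter set as a flat key-value config
#'
#' One `key = value` per line; keys mirror the model nomenclature
#' (`x_max`, `mu_max`, `t_c`, `phb_max`, `mu_max_p`, `t_c_p`, `dpa_max`,
#' `mu_max_d`, `t_c_d`, `cry_max`, `mu_max_c`, `t_c_c`, `y_dpa_x`,
#' `y_dpa_phb`, `y_cry_phb`), with optional `glucose_g_per_l`,
#' `soybean_g_per_l` and `label`. Values round-trip at full float
#' precision; unknown keys are rejected, missing required keys are named.
#'
#' @param params a [biodynamic_params()].
#' @param path file path.
#' @return `read_parameters` returns a [biodynamic_params()];
#'   `write_parameters` returns `path` invisibly.
#' @export
write_parameters <- function(params, path) {
  stopifnot(inherits(params, "biodynamic_params"))
  flat <- params_to_flat(params)
  lines <- paste(names(flat), "=", fmt_num(flat))
  if (!is.null(params$initial_glucose))
    lines <- c(lines, paste("glucose_g_per_l", "=",
                            fmt_num(params$initial_glucose)))
  if (!is.null(params$initial_soybean))
    lines <- c(lines, paste("soybean_g_per_l", "=",
                            fmt_num(params$initial_soybean)))
  if (!is.null(params$label))
    lines <- c(lines, paste("label", "=", params$label))
  writeLines(lines, path, useBytes = TRUE)
  invisible(path)
}

#' @rdname write_parameters
#' @export
read_parameters <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, encoding = "UTF-8")
  lines <- trimws(lines)
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  parts <- regmatches(lines, regexec("^([A-Za-z0-9_]+)[[:space:]]*=[[:space:]]*(.*)$",
                                     lines))
  bad <- vapply(parts, length, integer(1)) != 3L
  if (any(bad))
    stop("cannot parse line: '", lines[bad][1], "' (expected 'key = value')")
  keys <- vapply(parts, `[`, character(1), 2)
  raw <- vapply(parts, `[`, character(1), 3)
  unknown <- setdiff(keys, c(.param_keys, .optional_keys))
  if (length(unknown))
    stop("unknown key(s) in parameter file: ", paste(unknown, collapse = ", "))
  if (anyDuplicated(keys))
    stop("duplicate key(s): ", paste(unique(keys[duplicated(keys)]),
                                     collapse = ", "))
  missing_keys <- setdiff(.param_keys, keys)
  if (length(missing_keys))
    stop("parameter file is missing required key(s): ",
         paste(missing_keys, collapse = ", "))
  named <- stats::setNames(raw, keys)
  num_keys <- setdiff(keys, "label")
  nums <- suppressWarnings(as.numeric(named[num_keys]))
  if (any(is.na(nums)))
    stop("non-numeric value for key '", num_keys[which(is.na(nums))[1]],
         "': '", named[num_keys][which(is.na(nums))[1]], "'")
  named_num <- stats::setNames(nums, num_keys)
  flat_to_params(
    named_num[.param_keys],
    label = if ("label" %in% keys) named[["label"]] else NULL,
    initial_glucose = if ("glucose_g_per_l" %in% keys)
      named_num[["glucose_g_per_l"]] else NULL,
    initial_soybean = if ("soybean_g_per_l" %in% keys)
      named_num[["soybean_g_per_l"]] else NULL)
}

#' Write a simulated trajectory as delimited text
#'
#' Same standard columns as [write_kinetics()].
#'
#' @param trajectory a `bt_trajectory` from [simulate_kinetics()].
#' @param path file path.
#' @export
write_trajectory <- function(trajectory, path) {
  write_kinetics(trajectory, path)
}
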