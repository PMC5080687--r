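#' Construct an endpoint fermentation record
#'
#' One fermentation condition summarised at a sampling time: net consumed
#' substrates (initial minus residual, g/L), final product titers (g/L) and
#' the fermentation duration used for overall productivities.
#'
#' @param label Condition name.
#' @param duration_h Fermentation duration in hours, > 0.
#' @param substrates_consumed Named numeric vector, species -> g/L consumed.
#' @param products Named numeric vector, species -> g/L final titer.
#' @param ph_control Optional pH set-point, or `"none"`/`NA` for
#'   uncontrolled fermentations.
#' @param registry Species registry used to validate names and roles.
#' @return A list of class `ib_endpoint`.
#' @examples
#' endpoint_record("demo", 28,
#'                 substrates_consumed = c(glucose = 21.85),
#'                 products = c(butanol = 4.33, isopropanol = 2.44))
#' @export
endpoint_record <- function(label, duration_h, substrates_consumed,
                            products, ph_control = NA,
                            registry = species_registry()) {
  if (!is.numeric(duration_h) || length(duration_h) != 1 ||
      !is.finite(duration_h) || duration_h <= 0) {
    ib_validation_error(sprintf(
      "record '%s': duration_h must be a single positive number", label))
  }
  check_side <- function(x, side, roles) {
    x <- x[!is.na(x)]
    if (length(x) == 0) return(stats::setNames(numeric(0), character(0)))
    if (is.null(names(x)) || any(names(x) == "")) {
      ib_validation_error(sprintf("record '%s': %s must be named", label, side))
    }
    if (any(x < 0)) {
      bad <- names(x)[x < 0][1]
      ib_validation_error(sprintf(
        "record '%s': negative %s concentration for '%s'", label, side, bad))
    }
    canon <- vapply(names(x), function(id) {
      sp <- get_species(id, registry)
      if (!sp$role %in% roles) {
        ib_validation_error(sprintf(
          "record '%s': species '%s' has role '%s', not valid as %s",
          label, sp$id, sp$role, side))
      }
      sp$id
    }, character(1))
    stats::setNames(as.numeric(x), canon)
  }
  rec <- structure(list(
    label = as.character(label),
    duration_h = as.numeric(duration_h),
    substrates_consumed = check_side(substrates_consumed, "substrate",
                                     c("substrate", "both")),
    products = check_side(products, "product", c("product", "both")),
    ph_control = ph_control
  ), class = "ib_endpoint")
  rec
}

#' @export
print.ib_endpoint <- function(x, ...) {
  cat(sprintf("<ib_endpoint> '%s' (%g h%s)\n", x$label, x$duration_h,
              if (is.na(x$ph_control) || identical(x$ph_control, "none")) ""
              else paste0(", pH ", x$ph_control)))
  cat("  consumed:",
      paste(sprintf("%s %.4g g/L", names(x$substrates_consumed),
                    x$substrates_consumed), collapse = ", "), "\n")
  cat("  products:",
      paste(sprintf("%s %.4g g/L", names(x$products), x$products),
            collapse = ", "), "\n")
  invisible(x)
}

endpoint_sep <- function(path) {
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("tsv", "txt", "tab")) "\t" else ","
}

#' Read and write endpoint tables
#'
#' Endpoint tables are delimited text (comma for `.csv`, tab for
#' `.tsv`/`.txt`) with columns `label`, `duration_h`, optionally
#' `ph_control`, and one column per species named
#' `consumed_<species>_g_per_L` or `product_<species>_g_per_L`.  The explicit
#' role prefix avoids silent substrate/product confusion.  Empty cells and
#' `NA` mean "not measured" and are dropped from the record.
#'
#' @param path File to read or write.
#' @param registry Species registry for validation.
#' @return `read_endpoints()`: a named list of [endpoint_record()]s (names
#'   are the labels).  `write_endpoints()`: the path, invisibly.
#' @export
read_endpoints <- function(path, registry = species_registry()) {
  if (!file.exists(path)) {
    ib_validation_error(sprintf("endpoint file not found: '%s'", path))
  }
  df <- utils::read.table(path, header = TRUE, sep = endpoint_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (!all(c("label", "duration_h") %in% names(df))) {
    ib_validation_error(sprintf(
      "'%s': header must contain 'label' and 'duration_h'", path))
  }
  species_cols <- setdiff(names(df), c("label", "duration_h", "ph_control"))
  parsed <- lapply(species_cols, function(col) {
    m <- regmatches(col, regexec("^(consumed|product)_(.+)_g_per_L$", col))[[1]]
    if (length(m) != 3) {
      ib_validation_error(sprintf(
        "'%s': unrecognised column '%s' (expected consumed_<species>_g_per_L or product_<species>_g_per_L)",
        path, col))
    }
    id <- resolve_species_id(m[3], registry)
    if (is.na(id)) {
      ib_validation_error(sprintf(
        "'%s': column '%s' names an unknown species '%s'", path, col, m[3]))
    }
    list(col = col, side = m[2], id = id)
  })

  records <- list()
  errors <- character(0)
  for (i in seq_len(nrow(df))) {
    line <- i + 1  # header is line 1
    rec <- tryCatch({
      cons <- numeric(0); prod <- numeric(0)
      for (p in parsed) {
        val <- df[[p$col]][i]
        if (is.na(val)) next
        if (p$side == "consumed") cons[p$id] <- val else prod[p$id] <- val
      }
      endpoint_record(df$label[i], df$duration_h[i], cons, prod,
                      ph_control = if ("ph_control" %in% names(df))
                        df$ph_control[i] else NA,
                      registry = registry)
    }, error = function(e) e)
    if (inherits(rec, "error")) {
      errors <- c(errors, sprintf("line %d: %s", line, conditionMessage(rec)))
    } else {
      records[[rec$label]] <- rec
    }
  }
  if (length(errors)) {
    ib_validation_error(sprintf("'%s': %d malformed row(s):\n  %s", path,
                                length(errors),
                                paste(errors, collapse = "\n  ")))
  }
  records
}

#' @param records A list of `ib_endpoint` records.
#' @rdname read_endpoints
#' @export
write_endpoints <- function(records, path) {
  if (inherits(records, "ib_endpoint")) records <- list(records)
  cons_ids <- unique(unlist(lapply(records, function(r)
    names(r$substrates_consumed))))
  prod_ids <- unique(unlist(lapply(records, function(r) names(r$products))))
  rows <- lapply(records, function(r) {
    row <- list(label = r$label, duration_h = r$duration_h,
                ph_control = if (is.null(r$ph_control)) NA else r$ph_control)
    for (id in cons_ids) {
      row[[paste0("consumed_", id, "_g_per_L")]] <-
        if (id %in% names(r$substrates_consumed))
          r$substrates_consumed[[id]] else NA
    }
    for (id in prod_ids) {
      row[[paste0("product_", id, "_g_per_L")]] <-
        if (id %in% names(r$products)) r$products[[id]] else NA
    }
    as.data.frame(row, check.names = FALSE)
  })
  df <- do.call(rbind, rows)
  utils::write.table(df, path, sep = endpoint_sep(path), row.names = FALSE,
                     quote = FALSE, na = "NA")
  invisible(path)
}

#' Construct a fermentation time course
#'
#' @param times Sampling times in hours; strictly increasing, starting at 0.
#' @param series Named list (or data frame) of concentration series in g/L,
#'   one per species, each the same length as `times`.
#' @param biomass Optional dry cell weight (g/L) per time point.
#' @param ph Optional pH per time point.
#' @param noise_tolerance Declared measurement-noise tolerance (g/L): a
#'   substrate series may rise between adjacent samples by at most this much.
#' @param registry Species registry used to identify substrate series.
#' @return A list of class `ib_timecourse`.
#' @export
timecourse <- function(times, series, biomass = NULL, ph = NULL,
                       noise_tolerance = 0, registry = species_registry()) {
  times <- as.numeric(times)
  if (length(times) < 1 || times[1] != 0) {
    ib_validation_error("time course must start at time 0")
  }
  if (any(diff(times) <= 0)) {
    ib_validation_error("time column must be strictly increasing")
  }
  series <- lapply(as.list(series), as.numeric)
  if (is.null(names(series)) || any(names(series) == "")) {
    ib_validation_error("series must be named by species")
  }
  n <- length(times)
  lens <- vapply(series, length, integer(1))
  if (any(lens != n)) {
    ib_validation_error(sprintf(
      "ragged series: %s do(es) not match %d time points",
      paste(names(series)[lens != n], collapse = ", "), n))
  }
  for (nm in names(series)) {
    x <- series[[nm]]
    if (any(!is.finite(x)) || any(x < 0)) {
      ib_validation_error(sprintf("series '%s' has negative or non-finite values", nm))
    }
    sp <- get_species(nm, registry)
    if (sp$role %in% c("substrate", "both") &&
        any(diff(x) > noise_tolerance + 1e-12)) {
      ib_validation_error(sprintf(
        "substrate series '%s' increases by more than the declared noise tolerance (%g g/L)",
        sp$id, noise_tolerance))
    }
  }
  canon <- vapply(names(series), function(nm) get_species(nm, registry)$id,
                  character(1))
  names(series) <- canon
  if (!is.null(biomass)) {
    biomass <- as.numeric(biomass)
    if (length(biomass) != n || any(!is.finite(biomass)) || any(biomass < 0)) {
      ib_validation_error("biomass must be non-negative and match the time points")
    }
  }
  if (!is.null(ph)) {
    ph <- as.numeric(ph)
    if (length(ph) != n) {
      ib_validation_error("ph must match the time points")
    }
  }
  structure(list(times = times, series = series, biomass = biomass, ph = ph,
                 noise_tolerance = noise_tolerance),
            class = "ib_timecourse")
}

#' @export
print.ib_timecourse <- function(x, ...) {
  cat(sprintf("<ib_timecourse> %d points over %g h; species: %s%s%s\n",
              length(x$times), max(x$times),
              paste(names(x$series), collapse = ", "),
              if (is.null(x$biomass)) "" else "; +DCW",
              if (is.null(x$ph)) "" else "; +pH"))
  invisible(x)
}

#' Read and write time courses
#'
#' Time-course files are delimited text with a `time_h` column, optional
#' `dcw_g_per_L` and `ph` columns, and one `<species>_g_per_L` column per
#' measured species.  Values round-trip at full precision.  An optional
#' `# noise_tolerance: <g/L>` comment line before the header declares the
#' measurement-noise tolerance for the substrate-monotonicity check.
#'
#' @param path File to read or write.
#' @param tc An `ib_timecourse`.
#' @param registry Species registry.
#' @return `read_timecourse()`: an `ib_timecourse`; `write_timecourse()`:
#'   the path, invisibly.
#' @export
read_timecourse <- function(path, registry = species_registry()) {
  if (!file.exists(path)) {
    ib_validation_error(sprintf("time-course file not found: '%s'", path))
  }
  head_lines <- readLines(path, n = 5)
  tol <- 0
  tol_line <- grep("^#\\s*noise_tolerance:", head_lines, value = TRUE)
  if (length(tol_line)) {
    tol <- as.numeric(sub("^#\\s*noise_tolerance:\\s*", "", tol_line[1]))
  }
  df <- utils::read.table(path, header = TRUE, sep = endpoint_sep(path),
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (!"time_h" %in% names(df)) {
    ib_validation_error(sprintf("'%s': no 'time_h' column", path))
  }
  if (any(is.na(df))) {
    ib_validation_error(sprintf("'%s': ragged or missing values", path))
  }
  sp_cols <- setdiff(names(df), c("time_h", "dcw_g_per_L", "ph"))
  bad <- sp_cols[!grepl("_g_per_L$", sp_cols)]
  if (length(bad)) {
    ib_validation_error(sprintf("'%s': unrecognised column(s): %s", path,
                                paste(bad, collapse = ", ")))
  }
  series <- stats::setNames(lapply(sp_cols, function(cl) df[[cl]]),
                            sub("_g_per_L$", "", sp_cols))
  timecourse(df$time_h, series,
             biomass = if ("dcw_g_per_L" %in% names(df)) df$dcw_g_per_L,
             ph = if ("ph" %in% names(df)) df$ph,
             noise_tolerance = tol, registry = registry)
}

#' @rdname read_timecourse
#' @export
write_timecourse <- function(tc, path) {
  stopifnot(inherits(tc, "ib_timecourse"))
  df <- data.frame(time_h = tc$times, check.names = FALSE)
  if (!is.null(tc$biomass)) df$dcw_g_per_L <- tc$biomass
  if (!is.null(tc$ph)) df$ph <- tc$ph
  for (nm in names(tc$series)) {
    df[[paste0(nm, "_g_per_L")]] <- tc$series[[nm]]
  }
  con <- file(path, "w")
  on.exit(close(con))
  if (!is.null(tc$noise_tolerance) && tc$noise_tolerance > 0) {
    writeLines(sprintf("# noise_tolerance: %.17g", tc$noise_tolerance), con)
  }
  utils::write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
                     con, sep = endpoint_sep(path), row.names = FALSE,
                     quote = FALSE)
  invisible(path)
}

#' Bundled reference endpoint sets
#'
#' Endpoint records for the reference fermentations of *Clostridium* sp.
#' A1424 that the package's worked examples and tests analyse:
#' \describe{
#'   \item{`table2`}{nine single-substrate serum-bottle fermentations
#'     (glucose, mannose, fructose, galactose, xylose, arabinose, cellobiose,
#'     sucrose, glycerol) sampled at 28 h (sucrose: 36 h).}
#'   \item{`table3`}{five glucose:glycerol ratio fermentations (`22:0`,
#'     `20:2`, `18:4`, `14:8`, `9:13`), sampled at 28 h (`9:13`: 25 h).
#'     Consumed glycerol is net of the residual for `14:8` and `9:13`.}
#'   \item{`reported`}{endpoints quoted in running text: `glucose_16h`
#'     (21.62 g/L glucose over 16 h), `glucose_40` (41.02 g/L over 28 h),
#'     `ph5.5` (pH-controlled, 46.35 g/L glucose over 32 h) and
#'     `crude_14_8` (glucose + crude glycerol, 35.68 g/L total over 24 h).}
#' }
#'
#' @return A list with elements `table2`, `table3` and `reported`, each a
#'   named list of [endpoint_record()]s.
#' @examples
#' fx <- ib_fixtures()
#' fx$table3[["14:8"]]$substrates_consumed
#' @export
ib_fixtures <- function() {
  if (is.null(.ibferm_env$fixtures)) {
    read_one <- function(fn) {
      read_endpoints(system.file("extdata", fn, package = "ibferm",
                                 mustWork = TRUE))
    }
    .ibferm_env$fixtures <- list(
      table2 = read_one("table2_endpoints.csv"),
      table3 = read_one("table3_endpoints.csv"),
      reported = read_one("reported_endpoints.csv")
    )
  }
  .ibferm_env$fixtures
}
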