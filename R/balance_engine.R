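# product sets used throughout: "butanol" and "ib" (butanol + isopropanol)
ib_product_set <- function(products) {
  if (is.character(products) && length(products) == 1 &&
      tolower(products) == "ib") {
    return(c("butanol", "isopropanol"))
  }
  products
}

sum_products <- function(record, products, registry) {
  ids <- vapply(ib_product_set(products),
                function(p) get_species(p, registry)$id, character(1))
  sum(record$products[names(record$products) %in% ids])
}

total_consumed_g <- function(record) sum(record$substrates_consumed)

#' Mass yield of a product set
#'
#' Grams of product per gram of total consumed substrate, the yield basis
#' used for Y_B (butanol) and Y_IB (butanol + isopropanol).  Mixed feeds
#' divide by the summed consumed mass of all substrates.
#'
#' @param record An [endpoint_record()].
#' @param products Character vector of product species, or `"ib"` for
#'   butanol + isopropanol.
#' @param registry Species registry.
#' @return Yield in g/g.
#' @examples
#' rec <- ib_fixtures()$reported[["ph5.5"]]
#' mass_yield(rec, "butanol")  # ~0.20 g/g
#' mass_yield(rec, "ib")       # ~0.30 g/g
#' @export
mass_yield <- function(record, products = "butanol",
                       registry = species_registry()) {
  denom <- total_consumed_g(record)
  if (denom <= 0) {
    ib_computation_error(sprintf(
      "record '%s': zero substrate consumption, yield undefined", record$label))
  }
  sum_products(record, products, registry) / denom
}

#' Overall volumetric productivity
#'
#' Final titer of the product set divided by the fermentation duration
#' (g/L/h), the overall-productivity convention behind P_B and P_IB.
#'
#' @inheritParams mass_yield
#' @return Productivity in g/L/h.
#' @export
productivity <- function(record, products = "butanol",
                         registry = species_registry()) {
  if (is.null(record$duration_h) || !is.finite(record$duration_h) ||
      record$duration_h <= 0) {
    ib_validation_error(sprintf(
      "record '%s': missing or non-positive duration", record$label))
  }
  sum_products(record, products, registry) / record$duration_h
}

#' Butanol/isopropanol ratio
#'
#' Butanol titer divided by isopropanol titer (g/g).  When no isopropanol
#' was produced the ratio is undefined and `NA` is returned (never
#' infinity); report renderers display it as a dash.
#'
#' @inheritParams mass_yield
#' @return Ratio in g/g, or `NA_real_` when isopropanol is zero or absent.
#' @export
bi_ratio <- function(record, registry = species_registry()) {
  b <- sum_products(record, "butanol", registry)
  i <- sum_products(record, "isopropanol", registry)
  if (i <= 0) return(NA_real_)
  b / i
}

#' Total consumed carbon
#'
#' Millimolar carbon of all consumed substrates, the normalisation basis
#' for NAD(P)H_C, per-carbon-mole production and carbon recovery.
#'
#' @inheritParams mass_yield
#' @return mM carbon.
#' @export
total_carbon <- function(record, registry = species_registry()) {
  if (length(record$substrates_consumed) == 0) return(0)
  sum(vapply(names(record$substrates_consumed), function(id)
    carbon_millimolar(record$substrates_consumed[[id]], id, registry),
    numeric(1)))
}

#' NAD(P)H generated through glycolysis
#'
#' Each mol of glucose or glycerol consumed generates 2 mol NAD(P)H in
#' glycolysis, so generation is 2 x mM consumed, summed over substrates.
#' Substrates without a core generation coefficient (pentoses, galactose,
#' disaccharides) raise an error naming the species.
#'
#' @inheritParams mass_yield
#' @param allow_extrapolated Permit coefficients flagged `extrapolated` in
#'   the registry.
#' @return mM NAD(P)H generated.
#' @examples
#' nadph_generated(ib_fixtures()$table3[["20:2"]])  # ~260 mM
#' @export
nadph_generated <- function(record, registry = species_registry(),
                            allow_extrapolated = FALSE) {
  if (length(record$substrates_consumed) == 0) return(0)
  sum(vapply(names(record$substrates_consumed), function(id) {
    conc <- record$substrates_consumed[[id]]
    if (conc == 0) return(0)
    nadph_gen_coef(id, registry, allow_extrapolated) *
      to_millimolar(conc, id, registry)
  }, numeric(1)))
}

#' NAD(P)H required for product formation
#'
#' Requirement is 4, 2, 1, 0 and 0 mol NAD(P)H per mol of butanol, butyric
#' acid, isopropanol, acetone and acetic acid produced, i.e. the sum of
#' coefficient x mM titer over the products.  Ethanol is ignored (its titers
#' in the reference fermentations were negligible, below 0.1 g/L).
#' 1,3-propanediol has only an extrapolated coefficient: a record with
#' nonzero 1,3-PDO raises an error unless `allow_extrapolated = TRUE`.
#'
#' @inheritParams nadph_generated
#' @return mM NAD(P)H required.
#' @examples
#' nadph_required(ib_fixtures()$table3[["22:0"]])  # ~290 mM
#' @export
nadph_required <- function(record, registry = species_registry(),
                           allow_extrapolated = FALSE) {
  if (length(record$products) == 0) return(0)
  sum(vapply(names(record$products), function(id) {
    conc <- record$products[[id]]
    if (conc == 0 || id == "ethanol") return(0)
    nadph_req_coef(id, registry, allow_extrapolated) *
      to_millimolar(conc, id, registry)
  }, numeric(1)))
}

#' NAD(P)H generation per carbon mole of consumed substrate
#'
#' NAD(P)H generated divided by total consumed carbon (mol/mol).  Pure
#' glucose gives exactly 1/3 (2 NAD(P)H over 6 carbons), pure glycerol
#' exactly 2/3 (2 over 3), and mixtures fall in between, which is what makes
#' the glucose:glycerol ratio a redox dial.
#'
#' @inheritParams nadph_generated
#' @return mol NAD(P)H per C-mol.
#' @export
nadph_per_cmol <- function(record, registry = species_registry(),
                           allow_extrapolated = FALSE) {
  tc <- total_carbon(record, registry)
  if (tc <= 0) {
    ib_computation_error(sprintf(
      "record '%s': zero consumed carbon, NAD(P)H_C undefined", record$label))
  }
  nadph_generated(record, registry, allow_extrapolated) / tc
}

#' Fraction of required NAD(P)H supplied from reduced ferredoxin
#'
#' The shortfall between the NAD(P)H requirement for products and glycolytic
#' generation, as a fraction of the requirement: `(required - generated) /
#' required`, clipped at 0 when generation exceeds the requirement (surplus
#' generation is interpreted as no ferredoxin-derived NAD(P)H, not a
#' negative fraction).
#'
#' @inheritParams nadph_generated
#' @return Fraction in `[0, 1]`.
#' @export
fd_fraction <- function(record, registry = species_registry(),
                        allow_extrapolated = FALSE) {
  req <- nadph_required(record, registry, allow_extrapolated)
  if (req <= 0) {
    ib_computation_error(sprintf(
      "record '%s': zero NAD(P)H requirement, Fd fraction undefined",
      record$label))
  }
  gen <- nadph_generated(record, registry, allow_extrapolated)
  max(0, req - gen) / req
}

#' Product formation per carbon mole of consumed substrate
#'
#' For butanol, isopropanol, acetone, acetic acid and butyric acid: product
#' mM divided by total consumed carbon mM, plus the butanol + isopropanol
#' sum (`ib_c`).  The default unit is mol product per C-mol substrate;
#' `unit = "cmol"` instead returns C-mol product per C-mol substrate
#' (multiplying by each product's carbon count), the alternative
#' normalisation some carbon-flow plots use.
#'
#' @inheritParams mass_yield
#' @param unit `"mol"` (default) or `"cmol"`.
#' @return Named numeric vector with elements `buoh_c`, `ipa_c`, `ib_c`,
#'   `act_c`, `aa_c`, `ba_c`.
#' @export
per_cmol_production <- function(record, unit = c("mol", "cmol"),
                                registry = species_registry()) {
  unit <- match.arg(unit)
  tc <- total_carbon(record, registry)
  if (tc <= 0) {
    ib_computation_error(sprintf(
      "record '%s': zero consumed carbon, per-C-mole production undefined",
      record$label))
  }
  one <- function(id) {
    conc <- if (id %in% names(record$products)) record$products[[id]] else 0
    x <- to_millimolar(conc, id, registry)
    if (unit == "cmol") x <- x * get_species(id, registry)$carbon_atoms
    x / tc
  }
  out <- c(buoh_c = one("butanol"), ipa_c = one("isopropanol"),
           act_c = one("acetone"), aa_c = one("acetic_acid"),
           ba_c = one("butyric_acid"))
  c(out[c("buoh_c", "ipa_c")],
    ib_c = unname(out["buoh_c"] + out["ipa_c"]),
    out[c("act_c", "aa_c", "ba_c")])
}

#' Carbon recovery into a product set
#'
#' Percentage of consumed substrate carbon recovered in the given products:
#' `100 x` (summed product carbon mM) / (consumed carbon mM).
#'
#' @inheritParams mass_yield
#' @return Percent.
#' @examples
#' carbon_recovery(ib_fixtures()$reported[["ph5.5"]], "ib")  # ~47.5
#' @export
carbon_recovery <- function(record, products = "ib",
                            registry = species_registry()) {
  tc <- total_carbon(record, registry)
  if (tc <= 0) {
    ib_computation_error(sprintf(
      "record '%s': zero consumed carbon, carbon recovery undefined",
      record$label))
  }
  ids <- vapply(ib_product_set(products),
                function(p) get_species(p, registry)$id, character(1))
  prod_c <- sum(vapply(ids, function(id) {
    conc <- if (id %in% names(record$products)) record$products[[id]] else 0
    carbon_millimolar(conc, id, registry)
  }, numeric(1)))
  100 * prod_c / tc
}

#' Classify a fermentation endpoint as acidogenic or solventogenic
#'
#' A record whose total acids (acetic + butyric, g/L) exceed its total
#' solvents (butanol + isopropanol + acetone, g/L) is classified
#' `"acidogenic"`; otherwise `"solventogenic"`.  An exact tie (including the
#' all-zero record) resolves to solventogenic with a warning.
#'
#' @inheritParams mass_yield
#' @return `"solventogenic"` or `"acidogenic"`.
#' @export
classify_mode <- function(record, registry = species_registry()) {
  acids <- sum_products(record, c("acetic_acid", "butyric_acid"), registry)
  solvents <- sum_products(record, c("butanol", "isopropanol", "acetone"),
                           registry)
  if (acids > solvents) return("acidogenic")
  if (acids == solvents) {
    warning(sprintf(
      "record '%s': acids equal solvents; tie resolved as solventogenic",
      record$label))
  }
  "solventogenic"
}

#' Full balance analysis of an endpoint record
#'
#' Computes every derived metric at once: yields (Y_B, Y_IB), overall
#' productivities (P_B, P_IB), the butanol/isopropanol ratio, consumed
#' carbon, NAD(P)H generation/requirement, NAD(P)H_C, the ferredoxin-derived
#' fraction, per-carbon-mole product formation and carbon recoveries.  Every
#' field equals the output of the corresponding dedicated function.  Metrics
#' that are undefined for the record (B/I with no isopropanol, Fd fraction
#' with zero requirement) are returned as `NA` rather than raising, so a
#' whole table can be analysed in one pass; component errors that indicate a
#' genuinely unanalysable record (unset coefficients, zero consumption)
#' propagate with the field name attached.
#'
#' @inheritParams nadph_generated
#' @param per_cmol_unit Passed to [per_cmol_production()].
#' @return A list of class `ib_balance`; see [as.data.frame.ib_balance()]
#'   for the flat column layout.
#' @examples
#' res <- analyze_endpoint(ib_fixtures()$table3[["22:0"]])
#' round(res$nadph_req_mM, 1)
#' @export
analyze_endpoint <- function(record, registry = species_registry(),
                             allow_extrapolated = FALSE,
                             per_cmol_unit = c("mol", "cmol")) {
  per_cmol_unit <- match.arg(per_cmol_unit)
  wrap <- function(field, expr) {
    tryCatch(expr, error = function(e) {
      ib_computation_error(sprintf("[%s] %s", field, conditionMessage(e)))
    })
  }
  res <- list(
    label = record$label,
    y_b = wrap("y_b", mass_yield(record, "butanol", registry)),
    y_ib = wrap("y_ib", mass_yield(record, "ib", registry)),
    p_b = wrap("p_b", productivity(record, "butanol", registry)),
    p_ib = wrap("p_ib", productivity(record, "ib", registry)),
    bi_ratio = bi_ratio(record, registry),
    total_carbon_mM = wrap("total_carbon_mM", total_carbon(record, registry)),
    nadph_gen_mM = wrap("nadph_gen_mM",
                        nadph_generated(record, registry, allow_extrapolated)),
    nadph_req_mM = wrap("nadph_req_mM",
                        nadph_required(record, registry, allow_extrapolated)),
    mode = suppressWarnings(classify_mode(record, registry))
  )
  res$nadph_c <- wrap("nadph_c",
                      nadph_per_cmol(record, registry, allow_extrapolated))
  res$fd_fraction <- if (res$nadph_req_mM > 0) {
    max(0, res$nadph_req_mM - res$nadph_gen_mM) / res$nadph_req_mM
  } else {
    NA_real_
  }
  res$per_cmol <- wrap("per_cmol",
                       per_cmol_production(record, per_cmol_unit, registry))
  res$per_cmol_unit <- per_cmol_unit
  res$carbon_recovery <- c(
    butanol = wrap("cr_butanol_pct",
                   carbon_recovery(record, "butanol", registry)),
    ib = wrap("cr_ib_pct", carbon_recovery(record, "ib", registry)))
  structure(res, class = "ib_balance")
}

#' @export
print.ib_balance <- function(x, ...) {
  cat(sprintf("<ib_balance> '%s' (%s)\n", x$label, x$mode))
  cat(sprintf("  Y_B %.3f  Y_IB %.3f g/g   P_B %.3f  P_IB %.3f g/L/h   B/I %s\n",
              x$y_b, x$y_ib, x$p_b, x$p_ib,
              if (is.na(x$bi_ratio)) "-" else sprintf("%.2f", x$bi_ratio)))
  cat(sprintf("  carbon %.1f mM   NAD(P)H gen %.1f / req %.1f mM   NAD(P)H_C %.3f   Fd %s\n",
              x$total_carbon_mM, x$nadph_gen_mM, x$nadph_req_mM, x$nadph_c,
              if (is.na(x$fd_fraction)) "-" else sprintf("%.3f", x$fd_fraction)))
  cat(sprintf("  carbon recovery: butanol %.1f%%, IB %.1f%%\n",
              x$carbon_recovery[["butanol"]], x$carbon_recovery[["ib"]]))
  invisible(x)
}

#' Flatten balance results to a data frame
#'
#' One row per result with columns `label`, `y_b`, `y_ib`, `p_b`, `p_ib`,
#' `bi_ratio`, `total_carbon_mM`, `nadph_gen_mM`, `nadph_req_mM`, `nadph_c`,
#' `fd_fraction`, `cr_butanol_pct`, `cr_ib_pct`, `buoh_c`, `ipa_c`, `ib_c`,
#' `act_c`, `aa_c`, `ba_c`, `mode`.
#'
#' @param x An `ib_balance`.
#' @param ... Ignored.
#' @export
as.data.frame.ib_balance <- function(x, ...) {
  data.frame(
    label = x$label, y_b = x$y_b, y_ib = x$y_ib, p_b = x$p_b, p_ib = x$p_ib,
    bi_ratio = x$bi_ratio, total_carbon_mM = x$total_carbon_mM,
    nadph_gen_mM = x$nadph_gen_mM, nadph_req_mM = x$nadph_req_mM,
    nadph_c = x$nadph_c, fd_fraction = x$fd_fraction,
    cr_butanol_pct = x$carbon_recovery[["butanol"]],
    cr_ib_pct = x$carbon_recovery[["ib"]],
    buoh_c = x$per_cmol[["buoh_c"]], ipa_c = x$per_cmol[["ipa_c"]],
    ib_c = x$per_cmol[["ib_c"]], act_c = x$per_cmol[["act_c"]],
    aa_c = x$per_cmol[["aa_c"]], ba_c = x$per_cmol[["ba_c"]],
    mode = x$mode, stringsAsFactors = FALSE, row.names = NULL)
}

#' Analyse a collection of endpoint records
#'
#' @param records A list of [endpoint_record()]s.
#' @inheritParams analyze_endpoint
#' @return A data frame, one row per record (see
#'   [as.data.frame.ib_balance()]).
#' @export
analyze_endpoints <- function(records, registry = species_registry(),
                              allow_extrapolated = FALSE,
                              per_cmol_unit = "mol") {
  rows <- lapply(records, function(r)
    as.data.frame(analyze_endpoint(r, registry, allow_extrapolated,
                                   per_cmol_unit)))
  do.call(rbind, c(rows, list(make.row.names = FALSE)))
}

#' Balance analysis of a time course at a chosen time
#'
#' Extracts an endpoint record from a time course at `at_time` (linear
#' interpolation between samples): consumed substrate is the value at time 0
#' minus the value at `at_time` (clamped at 0 against measurement noise),
#' product titers are the values at `at_time`, and the duration is
#' `at_time`.  The record is then passed to [analyze_endpoint()].
#'
#' @param tc An `ib_timecourse`.
#' @param at_time Time in hours, within `(0, max(times)]`.
#' @param label Label for the derived record.
#' @inheritParams analyze_endpoint
#' @return An `ib_balance`.
#' @export
analyze_timecourse <- function(tc, at_time = max(tc$times),
                               label = "timecourse",
                               registry = species_registry(),
                               allow_extrapolated = FALSE,
                               per_cmol_unit = "mol") {
  stopifnot(inherits(tc, "ib_timecourse"))
  if (!is.finite(at_time) || at_time <= 0 || at_time > max(tc$times)) {
    ib_validation_error(sprintf(
      "at_time = %g is outside the analysable range (0, %g]",
      at_time, max(tc$times)))
  }
  value_at <- function(x) stats::approx(tc$times, x, xout = at_time)$y
  cons <- numeric(0); prod <- numeric(0)
  for (nm in names(tc$series)) {
    sp <- get_species(nm, registry)
    if (sp$role %in% c("substrate", "both")) {
      cons[nm] <- max(0, tc$series[[nm]][1] - value_at(tc$series[[nm]]))
    } else {
      prod[nm] <- max(0, value_at(tc$series[[nm]]))
    }
  }
  rec <- endpoint_record(label, at_time, cons, prod, registry = registry)
  analyze_endpoint(rec, registry, allow_extrapolated, per_cmol_unit)
}
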