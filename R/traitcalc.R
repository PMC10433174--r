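# Composite sugar/yield/economic traits from component measurements, and the
# ratooning-ability (RA) statistic.

#' Sugar content from corrected Brix and Pol
#'
#' Default reading: `SC = pol * 26 / (105.811 + (brix - 15) * 0.444)`, i.e.
#' the bracketed term is the denominator. The printed form of this industry
#' formula is typographically ambiguous about the division; an alternative
#' product reading is available via `reading = "product"` and the reading
#' used is attached as an attribute.
#'
#' @param pol juice polarization, percent in `[0, 100]`.
#' @param brix total dissolved solids, percent in `[0, 100]`.
#' @param reading `"denominator"` (default) or `"product"`.
#' @return sugar content (percent), with attribute `"reading"`.
#' @export
sugar_content <- function(pol, brix, reading = c("denominator", "product")) {
  reading <- match.arg(reading)
  stopifnot(all(pol >= 0 & pol <= 100), all(brix >= 0 & brix <= 100))
  den <- 105.811 + (brix - 15) * 0.444
  if (any(den <= 0)) stop("numeric error: non-positive denominator in sugar content")
  sc <- if (reading == "denominator") pol * 26 / den else pol * 26 * den / 1000
  structure(sc, reading = reading)
}

#' Cane yield (TCH) from stalk weight and stalk population
#'
#' `TCH = SW * SP / 1000`, tonnes of cane per hectare.
#'
#' @param sw stalk weight, kg per stalk (non-negative).
#' @param sp stalk population, stalks per hectare (non-negative).
#' @return TCH in Mg per hectare.
#' @export
cane_yield <- function(sw, sp) {
  if (any(sw < 0, na.rm = TRUE) || any(sp < 0, na.rm = TRUE))
    stop("domain error: sw and sp must be non-negative")
  sw * sp / 1000
}

#' Commercial recoverable sugar from theoretical recoverable sucrose
#'
#' `CRS = 0.86 * TRS` (kg sugar per Mg cane).
#'
#' @param trs theoretical recoverable sucrose, kg per Mg cane.
#' @return CRS, kg per Mg cane.
#' @export
commercial_recoverable_sugar <- function(trs) {
  if (any(trs < 0, na.rm = TRUE)) stop("domain error: trs must be non-negative")
  0.86 * trs
}

#' Sucrose yield (TSH)
#'
#' `TSH = TCH * CRS / 1000`, tonnes of sucrose per hectare.
#'
#' @param tch cane yield, Mg per hectare.
#' @param crs commercial recoverable sugar, kg per Mg cane.
#' @return TSH in Mg per hectare.
#' @export
sucrose_yield <- function(tch, crs) {
  if (any(tch < 0, na.rm = TRUE) || any(crs < 0, na.rm = TRUE))
    stop("domain error: tch and crs must be non-negative")
  tch * crs / 1000
}

#' Economic index (linear profit form)
#'
#' `EI = price * TSH - (c_harvest + c_haul + c_mill) * TCH`. The published
#' economic index is defined only through its inputs (cane yield, sucrose
#' yield, and harvest/haul/mill costs), so the coefficients are configuration,
#' not code; the defaults are neutral placeholders a user should override
#' with local economics.
#'
#' @param tch cane yield, Mg per hectare.
#' @param tsh sucrose yield, Mg per hectare.
#' @param econ named list/vector with `price` (currency per Mg sucrose) and
#'   `c_harvest`, `c_haul`, `c_mill` (currency per Mg cane).
#' @return EI, currency per hectare.
#' @export
economic_index <- function(tch, tsh,
                           econ = list(price = 600, c_harvest = 10,
                                       c_haul = 6, c_mill = 14)) {
  req <- c("price", "c_harvest", "c_haul", "c_mill")
  if (!all(req %in% names(econ)))
    stop("configuration error: econ must supply ",
         paste(setdiff(req, names(econ)), collapse = ", "))
  econ$price * tsh - (econ$c_harvest + econ$c_haul + econ$c_mill) * tch
}

# Default theoretical-recoverable-sucrose plug-in: linear in Pol, Brix and
# fiber. The published TRS formula is not printed in the source literature we
# implement against, so the coefficients are configurable; defaults give
# field-realistic magnitudes (~90-120 kg/Mg).
default_trs_coefs <- c(intercept = 0, pol = 9.5, brix = -1.2, fiber = -2.5)

#' Theoretical recoverable sucrose (configurable linear plug-in)
#'
#' `TRS = a0 + a_pol*Pol + a_brix*Brix + a_fiber*fiber`, truncated at zero.
#' Supply `trs` directly to the pipeline instead if lab-computed values exist.
#'
#' @param pol,brix,fiber component measurements (percent).
#' @param coefs named coefficients (`intercept`, `pol`, `brix`, `fiber`).
#' @return TRS, kg per Mg cane.
#' @export
theoretical_recoverable_sucrose <- function(pol, brix, fiber,
                                            coefs = default_trs_coefs) {
  pmax(coefs[["intercept"]] + coefs[["pol"]] * pol + coefs[["brix"]] * brix +
         coefs[["fiber"]] * fiber, 0)
}

#' Ratooning ability
#'
#' `A = 100 * sum(ratoons) / (p * N)`: mean ratoon-crop performance as a
#' percentage of the plant-cane value. Values above 100 are meaningful (the
#' trait improved in the ratoons). A zero plant-cane value leaves RA
#' undefined: `NA` is returned with a warning so the record can be excluded
#' upstream; negative plant-cane values are computed with a warning.
#'
#' @param p plant-cane value of the trait.
#' @param ratoons numeric vector of ratoon-crop values (length N >= 1).
#' @return RA as a percentage.
#' @export
ratooning_ability <- function(p, ratoons) {
  n <- length(ratoons)
  if (n < 1) stop("at least one ratoon value is required")
  if (is.na(p) || anyNA(ratoons)) return(NA_real_)
  if (p == 0) {
    warning("plant-cane value is zero; RA undefined, returning NA")
    return(NA_real_)
  }
  if (p < 0) warning("plant-cane value is negative; RA computed anyway")
  100 * sum(ratoons) / (p * n)
}

#' Derive composite traits for a table of component records
#'
#' Adds `SC`, `TRS` (if absent, via the plug-in formula), `CRS`, `TCH`,
#' `TSH`, and `EI` to a table holding `SP`, `SW`, `brix`, `pol`, `fiber`
#' columns (the plot-phenotype dialect of the simulator, or any per-entry
#' table such as a BLUP table).
#'
#' @param dat data.frame with component-trait columns.
#' @param econ economics for [economic_index()].
#' @param trs_coefs coefficients for the TRS plug-in (ignored when a `TRS`
#'   column is present).
#' @param sc_reading passed to [sugar_content()].
#' @return `dat` with derived columns appended; attribute `"sc_reading"`
#'   records the sugar-content formula interpretation used.
#' @export
derive_traits <- function(dat, econ = list(price = 600, c_harvest = 10,
                                           c_haul = 6, c_mill = 14),
                          trs_coefs = default_trs_coefs,
                          sc_reading = "denominator") {
  req <- c("SP", "SW", "brix", "pol", "fiber")
  if (!all(req %in% names(dat)))
    stop("missing component columns: ", paste(setdiff(req, names(dat)), collapse = ", "))
  dat$SC <- as.numeric(sugar_content(dat$pol, dat$brix, reading = sc_reading))
  if (!"TRS" %in% names(dat)) {
    dat$TRS <- theoretical_recoverable_sucrose(dat$pol, dat$brix, dat$fiber,
                                               coefs = trs_coefs)
  }
  dat$CRS <- commercial_recoverable_sugar(dat$TRS)
  dat$TCH <- cane_yield(dat$SW, dat$SP)
  dat$TSH <- sucrose_yield(dat$TCH, dat$CRS)
  dat$EI <- economic_index(dat$TCH, dat$TSH, econ = econ)
  attr(dat, "sc_reading") <- sc_reading
  dat
}

#' Ratooning ability from a per-cycle BLUP (or value) table
#'
#' Computes the RA statistic per entry and trait from a long table of
#' per-cycle values. The first cycle in `cycles` is the plant-cane crop; the
#' rest are ratoons. Entries with missing or zero plant-cane values are
#' excluded with a warning.
#'
#' @param blups data.frame with columns `entry_id`, `cycle`, `trait`,
#'   `value`.
#' @param cycles cycle labels in crop order (plant cane first).
#' @return data.frame `entry_id`, `trait`, `RA_percent`.
#' @export
ra_from_blups <- function(blups, cycles = c("PC", "FR", "SR")) {
  stopifnot(all(c("entry_id", "cycle", "trait", "value") %in% names(blups)))
  pc <- cycles[1]; rts <- cycles[-1]
  if (length(rts) < 1) stop("need at least one ratoon cycle")
  out <- list()
  dropped <- 0L
  for (tr in unique(blups$trait)) {
    b <- blups[blups$trait == tr, ]
    wide <- tapply(b$value, list(b$entry_id, factor(b$cycle, levels = cycles)),
                   identity)
    ok <- complete.cases(wide)
    p <- wide[, pc]
    bad0 <- ok & (p == 0)
    if (any(bad0)) dropped <- dropped + sum(bad0)
    keep <- ok & (p != 0)
    ra <- 100 * rowSums(wide[, rts, drop = FALSE]) / (p * length(rts))
    out[[tr]] <- data.frame(entry_id = rownames(wide)[keep], trait = tr,
                            RA_percent = ra[keep], stringsAsFactors = FALSE)
  }
  if (dropped > 0)
    warning(dropped, " record(s) with zero plant-cane value excluded from RA")
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
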