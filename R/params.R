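#' Opsin model parameters
#'
#' Construct the full parameter set of the double two-state opsin model: a
#' maximal dark-adapted conductance, a reversal potential, the shape parameters
#' of every irradiance/voltage dependency function, an optional inward
#' rectification function, and the scheme used to combine the irradiance and
#' voltage parts of each time constant.
#'
#' The model has two gating variables: the open fraction `O` and the
#' dark-adaptation conductance factor `R`, each relaxing first order towards an
#' irradiance-dependent equilibrium (`O_inf`, `R_inf`) with irradiance- and
#' voltage-dependent time constants (`tau_O`, `tau_R`). The photocurrent is
#' `i = g * G(V) * O * R * (V - E)`.
#'
#' @param g maximal dark-adapted conductance. Units depend on `mode`:
#'   mS/cm^2 for `"density"` (membrane models), uS for `"absolute"`
#'   (whole-cell recordings).
#' @param E reversal potential (mV).
#' @param tauO_I numeric length 3: log10-midpoint, log-slope, and dark-limit
#'   (seconds) of the open-gate time constant's irradiance part.
#' @param tauO_V numeric length 3: amplitude (s), midpoint (mV) and slope (mV)
#'   of the open-gate time constant's voltage logistic.
#' @param tauR_I numeric length 6: dark limit (s), weight of the first logistic
#'   (in `[0, 1]`), then two log10-midpoint/slope pairs of the biphasic decay.
#' @param tauR_V numeric length 3, as `tauO_V`, for the adaptation gate.
#' @param Oinf numeric length 2: log10-midpoint and log-slope of the open-state
#'   equilibrium logistic.
#' @param Rinf numeric length 3: log10-midpoint, log-slope and desensitization
#'   depth (in `[0, 1]`) of the adaptation equilibrium.
#' @param Grect numeric length 3 (gain, rectification amplitude, mV decay
#'   constant) or `NULL` when no rectification was observed (the driving force
#'   is then the plain `V - E`).
#' @param combine_O,combine_R how the irradiance and voltage parts of the time
#'   constants are combined: `"product"` or `"reciprocal_sum"`.
#' @param mode conductance units flag, `"density"` or `"absolute"`.
#'
#' @return An object of class `opsin_params`.
#' @seealso [opsin_fixture()] for the shipped published parameter sets,
#'   [read_opsin_params()] / [write_opsin_params()] for JSON serialization.
#' @export
#' @examples
#' p <- opsin_fixture("rsrs_final")
#' tau_o(p, irradiance = 0, voltage = -60)
opsin_params <- function(g, E, tauO_I, tauO_V, tauR_I, tauR_V, Oinf, Rinf,
                         Grect = NULL,
                         combine_O = c("reciprocal_sum", "product"),
                         combine_R = c("reciprocal_sum", "product"),
                         mode = c("density", "absolute")) {
  x <- structure(
    list(
      g = as.numeric(g), E = as.numeric(E),
      tauO_I = as.numeric(tauO_I), tauO_V = as.numeric(tauO_V),
      tauR_I = as.numeric(tauR_I), tauR_V = as.numeric(tauR_V),
      Oinf = as.numeric(Oinf), Rinf = as.numeric(Rinf),
      Grect = if (is.null(Grect)) NULL else as.numeric(Grect),
      combine_O = match.arg(combine_O), combine_R = match.arg(combine_R),
      mode = match.arg(mode)
    ),
    class = "opsin_params"
  )
  validate_opsin_params(x)
}

#' Validate an opsin parameter set
#'
#' Checks lengths, finiteness and the structural invariants of the model:
#' positive conductance, positive dark-limit time constants, the biphasic
#' weight and the desensitization depth inside `[0, 1]`.
#'
#' @param x an `opsin_params` object (or bare list with the same fields).
#' @return `x`, invisibly classed, if valid; otherwise an error.
#' @export
validate_opsin_params <- function(x) {
  lens <- c(g = 1, E = 1, tauO_I = 3, tauO_V = 3, tauR_I = 6, tauR_V = 3,
            Oinf = 2, Rinf = 3)
  for (nm in names(lens)) {
    v <- x[[nm]]
    if (is.null(v) || length(v) != lens[[nm]] || !all(is.finite(v))) {
      stop("opsin_params: field '", nm, "' must be finite numeric of length ",
           lens[[nm]], call. = FALSE)
    }
  }
  if (!is.null(x$Grect) &&
      (length(x$Grect) != 3L || !all(is.finite(x$Grect)))) {
    stop("opsin_params: 'Grect' must be NULL or finite numeric of length 3",
         call. = FALSE)
  }
  if (x$g <= 0) stop("opsin_params: g must be > 0", call. = FALSE)
  if (x$tauO_I[3] <= 0) {
    stop("opsin_params: dark-limit tauO_I[3] must be > 0", call. = FALSE)
  }
  if (x$tauR_I[1] <= 0) {
    stop("opsin_params: dark-limit tauR_I[1] must be > 0", call. = FALSE)
  }
  if (x$tauR_I[2] < 0 || x$tauR_I[2] > 1) {
    stop("opsin_params: biphasic weight tauR_I[2] must lie in [0, 1]",
         call. = FALSE)
  }
  if (x$Rinf[3] < 0 || x$Rinf[3] > 1) {
    stop("opsin_params: desensitization depth Rinf[3] must lie in [0, 1]",
         call. = FALSE)
  }
  if (x$Oinf[2] <= 0 || x$Rinf[2] <= 0 || x$tauO_I[2] <= 0 ||
      x$tauR_I[4] <= 0 || x$tauR_I[6] <= 0) {
    stop("opsin_params: log-slope parameters must be > 0", call. = FALSE)
  }
  if (!x$combine_O %in% c("product", "reciprocal_sum") ||
      !x$combine_R %in% c("product", "reciprocal_sum")) {
    stop("opsin_params: combine flags must be 'product' or 'reciprocal_sum'",
         call. = FALSE)
  }
  invisible(structure(x, class = "opsin_params"))
}

#' @export
print.opsin_params <- function(x, ...) {
  cat("<opsin_params>  g =", format(x$g), switch(x$mode,
      density = "mS/cm^2", absolute = "uS"),
      "  E =", format(x$E), "mV\n")
  cat("  tauO_I:", paste(format(x$tauO_I), collapse = ", "),
      "  tauO_V:", paste(format(x$tauO_V), collapse = ", "), "\n")
  cat("  tauR_I:", paste(format(x$tauR_I), collapse = ", "),
      "  tauR_V:", paste(format(x$tauR_V), collapse = ", "), "\n")
  cat("  Oinf:", paste(format(x$Oinf), collapse = ", "),
      "  Rinf:", paste(format(x$Rinf), collapse = ", "), "\n")
  if (is.null(x$Grect)) {
    cat("  rectification: none (driving force V - E)\n")
  } else {
    cat("  Grect:", paste(format(x$Grect), collapse = ", "), "\n")
  }
  cat("  combine O/R:", x$combine_O, "/", x$combine_R, "\n")
  invisible(x)
}

#' Published opsin parameter fixtures
#'
#' Load one of the six parameter sets shipped with the package: intermediate
#' and final fits of the channelrhodopsin-2(H134R) photocurrent with a double
#' reciprocal-sum combination ("rsrs") or a double product combination ("pp"),
#' and intermediate/final fits of a MerMAID anion channelrhodopsin ("mm",
#' absolute-conductance mode, no rectification).
#'
#' @param name one of `"rsrs_intm"`, `"rsrs_final"`, `"pp_intm"`, `"pp_final"`,
#'   `"mm_intm"`, `"mm_final"`.
#' @return An `opsin_params` object.
#' @export
opsin_fixture <- function(name = c("rsrs_final", "rsrs_intm", "pp_final",
                                   "pp_intm", "mm_final", "mm_intm")) {
  name <- match.arg(name)
  path <- system.file("extdata", "params", paste0(name, ".json"),
                      package = "opsin22", mustWork = TRUE)
  read_opsin_params(path)
}

#' Read opsin parameters from JSON
#'
#' The schema mirrors [opsin_params()]: top-level keys `g`, `E`, `tauO_I`,
#' `tauO_V`, `tauR_I`, `tauR_V`, `Oinf`, `Rinf`, optionally `Grect`, plus
#' `combine_O`, `combine_R` and `mode`. Unknown keys are rejected.
#'
#' @param path path to a JSON file.
#' @return A validated `opsin_params` object.
#' @export
read_opsin_params <- function(path) {
  if (!file.exists(path)) stop("parameter file not found: ", path, call. = FALSE)
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  known <- c("g", "E", "tauO_I", "tauO_V", "tauR_I", "tauR_V", "Oinf", "Rinf",
             "Grect", "combine_O", "combine_R", "mode", "name", "version")
  extra <- setdiff(names(raw), known)
  if (length(extra)) {
    stop("unknown keys in parameter file: ", paste(extra, collapse = ", "),
         call. = FALSE)
  }
  opsin_params(
    g = raw$g, E = raw$E,
    tauO_I = raw$tauO_I, tauO_V = raw$tauO_V,
    tauR_I = raw$tauR_I, tauR_V = raw$tauR_V,
    Oinf = raw$Oinf, Rinf = raw$Rinf,
    Grect = raw$Grect,
    combine_O = raw$combine_O %||% "reciprocal_sum",
    combine_R = raw$combine_R %||% "reciprocal_sum",
    mode = raw$mode %||% "density"
  )
}

#' Write opsin parameters to JSON
#'
#' @param x an `opsin_params` object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_opsin_params <- function(x, path) {
  x <- validate_opsin_params(x)
  out <- unclass(x)
  out$Grect <- x$Grect # keep NULL out of the JSON entirely
  jsonlite::write_json(out[!vapply(out, is.null, logical(1))], path,
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(path)
}

#' Move conductance scale between g and the rectification gain
#'
#' The photocurrent depends on the product `g * Grect[1]` only, so published
#' fits quote interchangeable pairs (for instance gain 9.91 with g = 1, or
#' gain 1 with g = 9.91). This utility renormalizes a rectified parameter set
#' so that `g` takes a requested value while the product, and hence every
#' simulated current, is unchanged.
#'
#' @param x an `opsin_params` object with a rectification function.
#' @param g target conductance value (default 1).
#' @return The renormalized `opsin_params`.
#' @export
normalize_conductance <- function(x, g = 1) {
  x <- validate_opsin_params(x)
  if (is.null(x$Grect)) {
    stop("normalize_conductance: parameter set has no rectification function",
         call. = FALSE)
  }
  if (g <= 0) stop("normalize_conductance: g must be > 0", call. = FALSE)
  prod <- x$g * x$Grect[1]
  x$g <- g
  x$Grect[1] <- prod / g
  validate_opsin_params(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
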