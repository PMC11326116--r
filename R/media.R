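#' Reference 100% amino-acid molarities (uM)
#'
#' Defined media concentrations that correspond to "100%" of each amino acid;
#' percentages elsewhere in the package (e.g. "15% LW") are fractions of these.
#'
#' @format Named numeric vector with elements `L` (leucine), `W` (tryptophan),
#'   `U` (uracil), `H` (histidine), in micromolar.
#' @export
AA_REFERENCE_UM <- c(L = 762, W = 245, U = 178, H = 95.4)

#' Construct a media configuration
#'
#' Media are described by dimensionless fractions of the reference molarities
#' ([AA_REFERENCE_UM]), a glucose concentration, and a mannose flag. Mannose
#' saturates bacterial type I fimbriae so that bacteria-yeast clumps cannot
#' form; in the model it deterministically forces the clump association rate
#' to zero.
#'
#' @param f_L,f_W,f_U,f_H Fractions of the 100% reference molarity for
#'   leucine, tryptophan, uracil and histidine. Must lie in \[0, 10\].
#' @param glucose_gL Glucose in g/L (default 20, i.e. 2%).
#' @param mannose Logical; `TRUE` disables clump formation.
#' @return An object of class `idc_media`.
#' @examples
#' m <- media_config(f_L = 0.15, f_W = 0.15)
#' concentration(m, "L")  # 0.15 * 762 uM
#' @export
media_config <- function(f_L = 1, f_W = 1, f_U = 1, f_H = 1,
                         glucose_gL = 20, mannose = FALSE) {
  fr <- c(L = f_L, W = f_W, U = f_U, H = f_H)
  for (nm in names(fr)) {
    if (!is_scalar_number(fr[[nm]]) || fr[[nm]] < 0 || fr[[nm]] > 10) {
      abort_idc(sprintf("media fraction f_%s must be in [0, 10], got %s", nm, fr[[nm]]),
                "bad_media")
    }
  }
  if (!is_scalar_number(glucose_gL) || glucose_gL < 0) {
    abort_idc("glucose_gL must be a non-negative number", "bad_media")
  }
  if (!is.logical(mannose) || length(mannose) != 1L || is.na(mannose)) {
    abort_idc("mannose must be TRUE or FALSE", "bad_media")
  }
  structure(
    list(fractions = fr, glucose_gL = glucose_gL, mannose = mannose),
    class = "idc_media"
  )
}

#' Amino-acid concentration implied by a media configuration
#'
#' @param media An [media_config()] object.
#' @param aa Nutrient id: one of `"L"`, `"W"`, `"U"`, `"H"` (or the
#'   corresponding three-letter names).
#' @return Concentration in micromolar: `fraction * reference molarity`.
#' @export
concentration <- function(media, aa) {
  stopifnot(inherits(media, "idc_media"))
  code <- nutrient_code(aa)
  unname(media$fractions[code] * AA_REFERENCE_UM[code])
}

#' @export
print.idc_media <- function(x, ...) {
  conc <- x$fractions * AA_REFERENCE_UM
  cat("<idc_media>\n")
  cat(sprintf("  %s: %g%% (%.3g uM)\n", names(conc), 100 * x$fractions, conc), sep = "")
  cat(sprintf("  glucose: %g g/L; mannose: %s\n", x$glucose_gL, x$mannose))
  invisible(x)
}
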