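# internal helpers shared across modules

abort_idc <- function(msg, type, call. = FALSE) {
  stop(errorCondition(msg, class = c(paste0("idcsim_", type), "idcsim_error", "error", "condition")))
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# normalize nutrient identifiers: accepts "L"/"Leu"/"leucine" style input,
# returns single-letter codes used throughout the package
nutrient_code <- function(x) {
  if (length(x) == 0) return(character(0))
  map <- c(
    L = "L", Leu = "L", leu = "L", leucine = "L",
    W = "W", Trp = "W", trp = "W", tryptophan = "W",
    U = "U", Ura = "U", ura = "U", uracil = "U",
    H = "H", His = "H", his = "H", histidine = "H"
  )
  out <- unname(map[as.character(x)])
  if (anyNA(out)) {
    abort_idc(
      sprintf("unknown nutrient id(s): %s", paste(x[is.na(out)], collapse = ", ")),
      "bad_nutrient"
    )
  }
  out
}

is_scalar_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)
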