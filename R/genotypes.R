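#' Describe a strain genotype
#'
#' A genotype records what a population needs from the media (auxotrophies),
#' what it secretes in excess (overproductions), whether it can act as a
#' conjugative donor, and what the transferred plasmid does to recipients
#' (payload).
#'
#' Payloads change the *transconjugant* phenotype: `rescue_markers` restores
#' uracil and histidine prototrophy (URA3/HIS3 selection genes on the
#' transferred plasmid), `crispr_cutter` encodes a Cas9 that destroys the
#' recipient's episomal URA3 plasmid so transconjugants become uracil
#' auxotrophs, and `crispr_no_oriT` is the non-transferable control: it
#' contributes exactly zero conjugation.
#'
#' @param species `"bacterium"` or `"yeast"`.
#' @param auxotrophies Character vector, subset of L/W/U/H (or Leu/Trp/Ura/His).
#' @param overproduces Character vector, subset of L/W.
#' @param donor_mode `"cis"`, `"trans"`, or `"none"`. Yeasts must be `"none"`.
#' @param payload `"none"`, `"rescue_markers"`, `"crispr_cutter"`, or
#'   `"crispr_no_oriT"`.
#' @param label Optional display name.
#' @return An object of class `idc_genotype`.
#' @seealso [genotype_preset()] for the standard strains.
#' @export
strain_genotype <- function(species = c("bacterium", "yeast"),
                            auxotrophies = character(0),
                            overproduces = character(0),
                            donor_mode = c("none", "cis", "trans"),
                            payload = c("none", "rescue_markers",
                                        "crispr_cutter", "crispr_no_oriT"),
                            label = NULL) {
  species <- match.arg(species)
  donor_mode <- match.arg(donor_mode)
  payload <- match.arg(payload)
  auxotrophies <- nutrient_code(auxotrophies)
  overproduces <- nutrient_code(overproduces)
  if (!all(overproduces %in% c("L", "W"))) {
    abort_idc("overproduction is modeled for L and W only", "bad_genotype")
  }
  if (species == "yeast" && donor_mode != "none") {
    abort_idc("a yeast never acts as a conjugative donor", "bad_genotype")
  }
  structure(
    list(species = species,
         auxotrophies = unique(auxotrophies),
         overproduces = unique(overproduces),
         donor_mode = donor_mode,
         payload = payload,
         label = label %||% species),
    class = "idc_genotype"
  )
}

#' Standard strain presets
#'
#' The four coculture partners plus the rescue- and CRISPR-assay recipients:
#' \describe{
#'   \item{E}{wild-type bacterial donor (prototroph, cis donor).}
#'   \item{E_cross}{crossfeeder donor: leucine auxotroph, tryptophan
#'     overproducer, cis donor.}
#'   \item{S}{wild-type yeast recipient (prototroph).}
#'   \item{S_cross}{crossfeeder recipient: tryptophan auxotroph, leucine
#'     overproducer.}
#'   \item{S_ura, S_his}{rescue-assay recipients, auxotrophic for uracil or
#'     histidine.}
#'   \item{S_crispr}{CRISPR-assay recipient: tryptophan auxotroph carrying the
#'     episomal URA3 target plasmid (so it does not require uracil until the
#'     plasmid is cut).}
#' }
#'
#' @param name One of the preset names above.
#' @param donor_mode For bacterial presets, `"cis"` (default) or `"trans"`.
#' @param payload Plasmid payload carried by a donor preset.
#' @return An `idc_genotype`.
#' @export
genotype_preset <- function(name, donor_mode = "cis", payload = "none") {
  switch(name,
    E = strain_genotype("bacterium", donor_mode = donor_mode, payload = payload,
                        label = "E"),
    E_cross = strain_genotype("bacterium", auxotrophies = "L", overproduces = "W",
                              donor_mode = donor_mode, payload = payload,
                              label = "E_cross"),
    S = strain_genotype("yeast", label = "S"),
    S_cross = strain_genotype("yeast", auxotrophies = "W", overproduces = "L",
                              label = "S_cross"),
    S_ura = strain_genotype("yeast", auxotrophies = "U", label = "S_ura"),
    S_his = strain_genotype("yeast", auxotrophies = "H", label = "S_his"),
    S_crispr = strain_genotype("yeast", auxotrophies = "W", label = "S_crispr"),
    abort_idc(sprintf("unknown genotype preset '%s'", name), "bad_genotype")
  )
}

# Required-nutrient set of the transconjugant given recipient genotype and
# the donor's plasmid payload.
transconjugant_requirements <- function(recipient, donor) {
  req <- recipient$auxotrophies
  if (donor$payload == "rescue_markers") req <- setdiff(req, c("U", "H"))
  if (donor$payload == "crispr_cutter")  req <- union(req, "U")
  req
}

#' @export
print.idc_genotype <- function(x, ...) {
  cat(sprintf("<idc_genotype> %s (%s)\n", x$label, x$species))
  cat(sprintf("  requires: %s | overproduces: %s | donor: %s | payload: %s\n",
              paste(x$auxotrophies, collapse = ",") , 
              paste(x$overproduces, collapse = ","),
              x$donor_mode, x$payload))
  invisible(x)
}
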