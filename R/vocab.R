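#' Controlled vocabularies for trait annotation
#'
#' Category vocabularies used throughout the annotation and summary layers:
#' habitat sources an organism has been isolated from, physiological
#' adaptations, trophic modes, metabolic processes, and the short phylum
#' codes used in the metabolic-capability matrix.
#'
#' @return Character vectors; `phylum_codes()` returns a named vector mapping
#'   taxon group names to their short codes.
#' @name vocabularies
NULL

#' @rdname vocabularies
#' @export
habitat_sources <- function() {
  c("soil_sediment", "aquatic_freshwater", "marine", "permafrost_ice",
    "animal", "plant")
}

#' @rdname vocabularies
#' @export
physiology_categories <- function() {
  c("psychrophilic_psychrotolerant", "thermophilic_thermotolerant",
    "halophilic_halotolerant", "alkaliphilic_alkalitolerant",
    "acidophilic_acidotolerant", "desiccation_resistant", "mesophilic")
}

#' @rdname vocabularies
#' @export
trophic_modes <- function() {
  c("heterotroph", "chemolithoautotroph", "photoautotroph")
}

#' @rdname vocabularies
#' @export
metabolic_processes <- function() {
  c("Nitrogen fixation (N2 -> NH4+)",
    "Nitrification (NH4+ -> NO2-)",
    "Nitrification (NO2- -> NO3-)",
    "Denitrification (NO2- -> NH4+)",
    "Denitrification (NO3- -> NO2-)",
    "Denitrification (NO3- -> N2)",
    "Nitrate reduction (NO3- -> NH4+)",
    "Assimilation (NH4+ -> organic)",
    "Decomposition (organic -> NH4+)",
    "Anammox (NH4+ + NO2- -> N2)",
    "Carbon fixation: reductive PP cycle",
    "Carbon fixation: reductive TCA cycle",
    "Carbon fixation: reductive acetyl-CoA pathway",
    "Carbon fixation: 3-hydroxypropionate bicycle",
    "C-1 metabolism",
    "Arsenic oxidation",
    "Arsenate reduction",
    "Chromium reducing",
    "Iron oxidation",
    "Iron reduction",
    "Manganese oxidation",
    "Methylotrophs",
    "Sulfur oxidation",
    "Sulfur (sulfate) reduction",
    "Uranium oxidation",
    "Uranium reduction")
}

#' @rdname vocabularies
#' @export
phylum_codes <- function() {
  c("Actinobacteria"        = "Ac",
    "Acidobacteria"         = "Ad",
    "Alphaproteobacteria"   = "\u03b1P",
    "Archaea"               = "Ar",
    "Ascomycota"            = "As",
    "Bacteroidetes"         = "Ba",
    "Basidiomycota"         = "Bd",
    "Betaproteobacteria"    = "\u03b2P",
    "Chlorobi"              = "Cb",
    "Chlorophyta"           = "Ch",
    "Cyanobacteria"         = "Cy",
    "Deinococcus-Thermus"   = "DT",
    "Deltaproteobacteria"   = "\u03b4P",
    "Epsilonproteobacteria" = "\u03b5P",
    "Firmicutes"            = "Fi",
    "Gammaproteobacteria"   = "\u03b3P",
    "Planctomycetes"        = "Pl")
}

#' @rdname vocabularies
#' @export
taxonomic_domains <- function() c("Archaea", "Bacteria", "Eukarya")
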