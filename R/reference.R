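# Monoisotopic masses (Da) of the particles used in adduct arithmetic.
# Fixed constants so predicted m/z values are exactly reproducible.
MASS_PROTON <- 1.007276
MASS_NA     <- 22.989218  # Na+ (electron-adjusted)
MASS_NH4    <- 18.033823  # NH4+
MASS_CL     <- 34.969402  # Cl-
MASS_H2O    <- 18.010565

#' Default electrospray adduct registry
#'
#' Common singly-charged ESI adducts per ionization mode. The predicted m/z
#' of a neutral compound of monoisotopic mass M is `M + shift`. One adduct
#' per mode is flagged primary (M+H for positive, M-H for negative);
#' pathway-enrichment compound hits require a primary-adduct match.
#'
#' @return A data frame with columns `mode`, `adduct`, `shift`, `primary`.
#' @export
#' @examples
#' default_adducts()
default_adducts <- function() {
  data.frame(
    mode = c(rep("hilic_pos", 4), rep("c18_neg", 3)),
    adduct = c("M+H", "M+Na", "M+NH4", "M+H-H2O",
               "M-H", "M+Cl", "M-H-H2O"),
    shift = c(MASS_PROTON, MASS_NA, MASS_NH4, MASS_PROTON - MASS_H2O,
              -MASS_PROTON, MASS_CL, -MASS_PROTON - MASS_H2O),
    primary = c(TRUE, FALSE, FALSE, FALSE, TRUE, FALSE, FALSE),
    stringsAsFactors = FALSE
  )
}

#' Packaged toy pathway reference
#'
#' A small fixed KEGG-style reference: six metabolic pathways relevant to
#' metabolic liver disease (tryptophan metabolism, branched-chain amino acid
#' degradation, butanoate metabolism, propanoate metabolism, pantothenate
#' and CoA biosynthesis, purine metabolism), each mapped to real compounds
#' with their monoisotopic neutral masses. Some compounds belong to more
#' than one pathway, and a few share a nominal mass, as in real references.
#' The content is versioned and identical across calls.
#'
#' @return An object of class `pathway_reference`: a list with elements
#'   `compounds` (data frame: `compound_id`, `name`, `mass`), `pathways`
#'   (named list of compound-id vectors) and `adducts` (see
#'   [default_adducts()]).
#' @export
#' @examples
#' ref <- make_toy_pathway_reference()
#' names(ref$pathways)
make_toy_pathway_reference <- function() {
  compounds <- data.frame(
    compound_id = c(
      "trp", "kyn", "ser5ht", "ind", "i3ald", "kyna", "htrp5", "anth",
      "ohkyn3", "i3ac",
      "leu_ile", "val", "mob3", "mop4", "mmal", "hibu3",
      "but", "bhb", "acac", "akg", "succ", "fum", "gaba", "crot",
      "prop", "lac", "bala", "okb2", "pdiol", "acry",
      "pant", "asp", "serine", "cys", "panto", "pnth",
      "urate", "xan", "hypox", "ade", "gua", "ino", "ado", "dino",
      "alla", "hiu5"
    ),
    name = c(
      "tryptophan", "kynurenine", "serotonin", "indole",
      "indole-3-acetaldehyde", "kynurenic acid", "5-hydroxytryptophan",
      "anthranilate", "3-hydroxykynurenine", "indole-3-acetate",
      "leucine/isoleucine", "valine", "3-methyl-2-oxobutanoate",
      "4-methyl-2-oxopentanoate", "methylmalonate", "3-hydroxyisobutyrate",
      "butanoate", "3-hydroxybutyrate", "acetoacetate", "2-oxoglutarate",
      "succinate", "fumarate", "4-aminobutanoate", "crotonate",
      "propanoate", "lactate", "beta-alanine", "2-oxobutanoate",
      "propane-1,2-diol", "acrylate",
      "pantothenate", "aspartate", "serine", "cysteine", "pantoate",
      "pantetheine",
      "urate", "xanthine", "hypoxanthine", "adenine", "guanine", "inosine",
      "adenosine", "deoxyinosine", "allantoin", "5-hydroxyisourate"
    ),
    mass = c(
      204.08988, 208.08479, 176.09496, 117.05785, 159.06841, 189.04259,
      220.08479, 137.04768, 224.07971, 175.06333,
      131.09463, 117.07898, 116.04734, 130.06299, 118.02661, 104.04734,
      88.05243, 104.04734, 102.03169, 146.02152, 118.02661, 116.01096,
      103.06333, 86.03678,
      74.03678, 90.03169, 89.04768, 102.03169, 76.05243, 72.02113,
      219.11067, 133.03751, 105.04259, 121.01975, 148.07356, 278.13004,
      168.02834, 152.03343, 136.03851, 135.05450, 151.04941, 268.08077,
      267.09675, 252.08585, 158.04399, 184.02325
    ),
    stringsAsFactors = FALSE
  )
  pathways <- list(
    "tryptophan metabolism" = c("trp", "kyn", "ser5ht", "ind", "i3ald",
                                "kyna", "htrp5", "anth", "ohkyn3", "i3ac"),
    "branched-chain amino acid degradation" =
      c("leu_ile", "val", "mob3", "mop4", "mmal", "hibu3", "acac"),
    "butanoate metabolism" = c("but", "bhb", "acac", "akg", "succ", "fum",
                               "gaba", "crot"),
    "propanoate metabolism" = c("prop", "lac", "bala", "okb2", "mmal",
                                "pdiol", "acry"),
    "pantothenate and CoA biosynthesis" = c("pant", "asp", "serine", "cys",
                                            "panto", "pnth", "bala", "val"),
    "purine metabolism" = c("urate", "xan", "hypox", "ade", "gua", "ino",
                            "ado", "dino", "alla", "hiu5")
  )
  ref <- list(compounds = compounds, pathways = pathways,
              adducts = default_adducts(), version = "toy-1")
  class(ref) <- "pathway_reference"
  validate_pathway_reference(ref)
  ref
}

validate_pathway_reference <- function(ref) {
  stopifnot(all(ref$compounds$mass > 0),
            !anyDuplicated(ref$compounds$compound_id))
  unknown <- setdiff(unlist(ref$pathways), ref$compounds$compound_id)
  if (length(unknown) > 0) {
    stop("pathway reference names unknown compounds: ",
         paste(unknown, collapse = ", "))
  }
  if (any(lengths(ref$pathways) < 3)) {
    stop("every pathway must contain at least 3 compounds")
  }
  for (m in unique(ref$adducts$mode)) {
    if (!any(ref$adducts$primary[ref$adducts$mode == m])) {
      stop("mode ", m, " has no primary adduct")
    }
  }
  invisible(ref)
}

#' Read / write a pathway reference as JSON
#'
#' @param ref A `pathway_reference` object.
#' @param path File path.
#' @return `read_pathway_reference` returns a `pathway_reference`;
#'   `write_pathway_reference` returns `path` invisibly.
#' @export
write_pathway_reference <- function(ref, path) {
  jsonlite::write_json(
    list(compounds = ref$compounds,
         pathways = ref$pathways,
         adducts = ref$adducts,
         version = ref$version %||% "custom"),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pathway_reference
#' @export
read_pathway_reference <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  ref <- list(compounds = as.data.frame(x$compounds),
              pathways = lapply(x$pathways, unlist),
              adducts = as.data.frame(x$adducts),
              version = x$version)
  class(ref) <- "pathway_reference"
  validate_pathway_reference(ref)
  ref
}
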