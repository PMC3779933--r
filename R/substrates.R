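#' The 14-assay screening substrate panel
#'
#' The panel of labelled substrates used to screen fosmid clones for
#' plant-polymer-degrading activities: dye-crosslinked polymers (AZCL, azure)
#' read by absorbance, fluorogenic 4-methylumbelliferyl (4-MUB) glycosides,
#' chromogenic p-nitrophenyl (PNP) glucoside, oxidative substrates, and two
#' solid-media assays (BCIP for phosphatase, skim milk for protease) scored
#' visually. BCIP is assayed twice, at pH 6 and pH 8, to separate acid from
#' alkaline phosphatase activity, giving 14 assays over 13 physical
#' substrates.
#'
#' @return A tibble with one row per assay and columns `substrate`,
#'   `target_enzyme`, `functional_role`, `concentration`, `detection`,
#'   `modality` (`"absorbance"`, `"fluorescence"` or `"visual"`) and
#'   `assay_type` (`"liquid"` or `"solid"`).
#' @examples
#' substrate_panel()
#' @export
substrate_panel <- function() {
  panel <- tibble(
    substrate = c(
      "AZCL-HE-cellulose", "4-MUB-beta-D-cellobiose",
      "PNP-beta-D-glucopyranoside", "AZCL-xylan", "4-MUB-beta-D-xyloside",
      "starch-azure", "4-MUB-alpha-D-glucoside", "chitin-azure",
      "4-MUB-beta-N-acetylglucosamine", "L-DOPA", "syringaldazine",
      "BCIP-acid", "BCIP-alkaline", "skim-milk"),
    target_enzyme = c(
      "cellulase", "cellobiohydrolase", "beta-glucosidase", "xylanase",
      "beta-xylosidase", "alpha-amylase", "alpha-glucosidase", "chitinase",
      "N-acetyl-beta-D-glucosaminidase", "polyphenol oxidase", "laccase",
      "acid phosphatase", "alkaline phosphatase", "protease"),
    functional_role = c(
      "cellulose degradation", "cellulose degradation",
      "cellulose degradation", "hemicellulose degradation",
      "hemicellulose degradation", "starch degradation", "starch degradation",
      "chitin degradation", "chitin degradation", "lignin degradation",
      "lignin degradation", "phosphate mineralization",
      "phosphate mineralization", "protein turnover"),
    concentration = c(
      "0.1% (w/v)", "1 mM", "1 mM", "0.1% (w/v)", "1 mM", "0.5% (w/v)",
      "1 mM", "0.1% (w/v)", "1 mM", "5 mM", "40 uM", "0.1 mM", "0.1 mM",
      "2%"),
    detection = c(
      "590", "365/450", "410", "590", "365/450", "590", "365/450", "590",
      "365/450", "480", "530", "visual", "visual", "visual"),
    modality = c(
      "absorbance", "fluorescence", "absorbance", "absorbance",
      "fluorescence", "absorbance", "fluorescence", "absorbance",
      "fluorescence", "absorbance", "absorbance", "visual", "visual",
      "visual"),
    assay_type = c(rep("liquid", 11), "solid", "solid", "solid"))
  stopifnot(!anyDuplicated(panel$substrate))
  panel
}

#' Default glycoside-hydrolase-family to substrate map
#'
#' Relates annotated enzyme families to the panel substrates they are expected
#' to act on, based on activities reported for each family in the CAZy
#' database. GH1/GH3 beta-glucosidases are promiscuous across the small
#' beta-glycoside substrates; GH9 cellulases and GH10 xylanases also cleave
#' 4-MUB-cellobiose; GH13/15/31/97 cover starch; GH2/20/84/109 cover
#' N-acetylglucosaminides; generic phosphatase and peptidase domains map to
#' the two solid-media assays. Carbohydrate-binding modules (CBMs) are
#' deliberately absent: a CBM alone predicts no activity.
#'
#' The map ships as an editable two-column config
#' (`system.file("extdata", "gh_substrate_map.tsv", package = "screenbin")`);
#' this function reads it. Users with their own family-activity evidence
#' should edit or replace that file via [read_family_map()].
#'
#' @return A tibble with columns `family` and `substrate`, one row per
#'   (family, substrate) link.
#' @seealso [read_family_map()], [predict_activities()]
#' @export
default_family_map <- function() {
  read_family_map(system.file("extdata", "gh_substrate_map.tsv",
                              package = "screenbin"))
}

#' Read a family-to-substrate map from a delimited config
#'
#' The config is tab-delimited with a header and two columns: `family` and
#' `substrates` (comma-separated substrate names).
#'
#' @param path Path to the config file.
#' @return A tibble with columns `family` and `substrate` (long format).
#' @export
read_family_map <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(.default = "c"),
                         progress = FALSE)
  if (!all(c("family", "substrates") %in% names(raw))) {
    abort("Family map config needs columns `family` and `substrates`.",
          class = "screenbin_invalid_parameter")
  }
  if (anyDuplicated(raw$family)) {
    abort("Family map families must be unique.",
          class = "screenbin_invalid_parameter")
  }
  raw |>
    mutate(substrate = strsplit(.data$substrates, ",[ ]*")) |>
    select("family", "substrate") |>
    tidyr::unnest("substrate") |>
    filter(.data$substrate != "") |>
    as_tibble()
}

#' Read a screen-counts table (positive assays per library and substrate)
#'
#' Reads a tab-delimited table with columns `library`, `clones_screened` and
#' one column per substrate holding the number of positive assays observed in
#' that library. A table with the published counts from a seven-library leaf
#' litter screen ships with the package
#' (`system.file("extdata", "leaf_litter_screen_counts.tsv",
#' package = "screenbin")`).
#'
#' @param path Path to the counts table.
#' @return A long tibble with columns `library`, `clones_screened`,
#'   `substrate`, `n_positive`.
#' @seealso [summarize_screen_counts()]
#' @export
read_screen_counts <- function(path) {
  raw <- readr::read_tsv(path, col_types = readr::cols(
    library = "c", .default = "d"), progress = FALSE)
  if (!all(c("library", "clones_screened") %in% names(raw))) {
    abort("Counts table needs columns `library` and `clones_screened`.",
          class = "screenbin_invalid_parameter")
  }
  raw |>
    tidyr::pivot_longer(cols = -c("library", "clones_screened"),
                        names_to = "substrate", values_to = "n_positive") |>
    mutate(n_positive = tidyr::replace_na(.data$n_positive, 0))
}
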