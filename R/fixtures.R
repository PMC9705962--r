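#' Canonical taxon vocabulary for mouse gut communities
#'
#' The 20 harmonized taxa used throughout the package to describe microbiome
#' community structure: 15 genera, 4 supra-genus groups (tagged `"Order"`),
#' and a catch-all `"Other"` class collecting everything unassigned.
#'
#' @return A data frame with columns `name` (unique taxon label) and
#'   `rank` (one of `"Genus"`, `"Order"`, `"Other"`).
#' @examples
#' v <- taxon_vocabulary()
#' table(v$rank)
#' @export
taxon_vocabulary <- function() {
  data.frame(
    name = c(
      "Collinsella", "Bacteroides", "Parabacteroides", "Porphyromonas",
      "Anaerostipes", "Blautia", "Butyrivibrio", "Clostridium",
      "Eubacterium", "Lachnospiraceae", "Oribacterium", "Ruminococcaceae",
      "Ruminococcus", "Clostridia", "Erysipelotrichaceae", "Lactobacillus",
      "Atopobium", "Desulfotomaculum", "Lactococcus", "Other"
    ),
    rank = c(
      "Genus", "Genus", "Genus", "Genus",
      "Genus", "Genus", "Genus", "Genus",
      "Genus", "Order", "Genus", "Order",
      "Genus", "Order", "Order", "Genus",
      "Genus", "Genus", "Genus", "Other"
    ),
    stringsAsFactors = FALSE
  )
}

# Nutrient vocabulary shared by both reference diets.  Fiber is tagged as a
# carbohydrate (the category counts 17/7/4/8/11 + energy only balance that
# way), and the duplicated "Magnesium" mineral row is kept as a distinct
# feature "Magnesium_2 (sic)" to preserve the count of 8 minerals.
.diet_nutrients <- function() {
  data.frame(
    nutrient = c(
      "Protein", "Ile", "Leu", "Lys", "Met+Cys", "Phe+Tyr", "Thr", "Val",
      "Trp", "His", "Ala", "Arg", "Asp", "Glu", "Gly", "Pro", "Ser",
      "Carbohydrate", "Starch", "Glucose", "Fructose", "Sucrose", "Lactose",
      "Fiber (cellulose)",
      "Total Fat", "Saturated", "Mono saturated", "Poly unsaturated",
      "Calcium", "Potassium", "Magnesium", "Iron", "Zinc",
      "Magnesium_2 (sic)", "Copper", "Iodine",
      "Niacin", "Panthothenate", "Pyridoxine", "Riboflavin", "Folic acid",
      "Biotin", "Vit B12", "Vit E", "Vit A", "Vit D3", "Vit K",
      "Kcal/g"
    ),
    category = c(
      rep("protein/amino acid", 17),
      rep("carbohydrate", 7),
      rep("fat", 4),
      rep("mineral", 8),
      rep("vitamin", 11),
      "energy"
    ),
    stringsAsFactors = FALSE
  )
}

#' Reference mouse diet compositions (High Fat and Low Fat)
#'
#' The two reference diets used to anchor diet normalization: a High Fat
#' (HF) and a Low Fat (LF) laboratory mouse diet, each described by the same
#' 48 nutrient features (17 protein/amino acids, 7 carbohydrates including
#' fiber, 4 fats, 8 minerals, 11 vitamins, and energy density). Values are
#' g/kg of feed except `Kcal/g` (energy in Kcal per gram).
#'
#' @param which Which reference diet, `"HF"` or `"LF"`.
#' @return A `diet_composition`: a data frame with columns `nutrient`,
#'   `category`, and `value_g_per_kg`.
#' @examples
#' hf <- reference_diet("HF")
#' nrow(hf)  # 48
#' @export
reference_diet <- function(which = c("HF", "LF")) {
  which <- match.arg(which)
  d <- .diet_nutrients()
  hf <- c(
    19.3, 0.89, 1.73, 1.51, 0.62, 1.97, 0.78, 1.09,
    0.20, 0.49, 0.53, 0.65, 1.47, 4.25, 0.33, 1.81, 1.08,
    50.34, 11.7, 0, 0, 34.84, 3.8,
    5,
    23.2, 14.15, 7.192, 1.856,
    1.5351, 1.347534, 0.10449, 0.026058, 0.007095,
    0.002709, 0.001333, 0.000043,
    0.0057, 0.00304, 0.00133, 0.00114, 0.00038,
    0.000038, 0.00475, 0.0285, 0.00152, 0.00038, 0.000143,
    4.7
  )
  lf <- c(
    18, 0.87, 1.52, 0.97, 0.98, 1.41, 0.68, 0.9,
    0.23, 0.44, 1.13, 1.03, 1.87, 4.52, 0.94, 1.53, 0.98,
    39.79, 38.9, 0.12, 0.15, 0.62, 0,
    15,
    6.2, 1.24, 1.37, 0.24,
    1.17, 0.66, 0.22, 0.038, 0.0085,
    0.016, 0.0011, 0.00021,
    0.009, 0.0037, 0.001, 0.0009, 0.00019,
    0.00003, 0.005, 0.0045, 0.002, 0.00043, 0.002,
    3.17
  )
  d$value_g_per_kg <- if (which == "HF") hf else lf
  class(d) <- c("diet_composition", "data.frame")
  d
}

#' Export the built-in fixtures as TSV files
#'
#' Writes the taxon vocabulary and the HF/LF reference diet tables to a
#' directory in the same TSV dialects the loaders read.
#'
#' @param dir Output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
export_fixtures <- function(dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  paths <- c(
    taxa = file.path(dir, "taxa.tsv"),
    diet_hf = file.path(dir, "diet_hf.tsv"),
    diet_lf = file.path(dir, "diet_lf.tsv")
  )
  utils::write.table(taxon_vocabulary(), paths[["taxa"]],
    sep = "\t", quote = FALSE, row.names = FALSE)
  write_diet_table(reference_diet("HF"), paths[["diet_hf"]])
  write_diet_table(reference_diet("LF"), paths[["diet_lf"]])
  invisible(paths)
}
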