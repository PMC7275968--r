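#' Eco-Scale penalty rule table
#'
#' Reads the bundled rule table of the Analytical Eco-Scale: penalty points
#' for reagent amounts, instrument energy, occupational exposure and waste.
#' Shipped as an editable CSV so a scored sheet is reproducible and
#' auditable.
#'
#' @return data.frame with columns `category`, `bracket`, `points`.
#' @export
eco_scale_rules <- function() {
  utils::read.csv(system.file("extdata", "eco_scale_rules.csv",
                              package = "quadspec", mustWork = TRUE))
}

#' One Eco-Scale assessment item
#'
#' @param name item label (e.g. `"water"`, `"energy"`).
#' @param category one of `"reagent"`, `"instrument-energy"`,
#'   `"occupational-hazard"`, `"waste"`.
#' @param amount_penalty amount penalty points (reagents: 1/2/3 for <10,
#'   10-100, >100 mL or g; instruments: points per the rule table).
#' @param hazard_penalty reagent hazard points (number of pictograms times
#'   the signal-word multiplier: 1 for warning, 2 for danger; 0 for
#'   non-hazardous). Ignored for non-reagent categories.
#' @return a one-row data.frame.
#' @export
eco_item <- function(name, category, amount_penalty, hazard_penalty = 0) {
  category <- match.arg(category, c("reagent", "instrument-energy",
                                    "occupational-hazard", "waste"))
  if (amount_penalty < 0 || hazard_penalty < 0) stop("penalties must be >= 0")
  data.frame(name = name, category = category,
             amount_penalty = amount_penalty,
             hazard_penalty = hazard_penalty)
}

#' Analytical Eco-Scale score
#'
#' Each reagent contributes `amount_penalty * hazard_penalty` points (so a
#' non-hazardous reagent such as water contributes nothing); instrument
#' items (energy, occupational exposure, waste) contribute their amount
#' points additively. The score is 100 minus the total penalty; a score
#' above 75 denotes an excellent green method.
#'
#' @param items data.frame of [eco_item()] rows (rbind them).
#' @return object of class `"eco_scale_sheet"` with `items` (including the
#'   per-item `total` column), `reagent_penalty`, `instrument_penalty`,
#'   `total_penalty`, `score`.
#' @examples
#' items <- rbind(
#'   eco_item("water", "reagent", 1, 0),
#'   eco_item("ethanol", "reagent", 1, 2),
#'   eco_item("energy", "instrument-energy", 0),
#'   eco_item("vapours", "occupational-hazard", 0),
#'   eco_item("waste", "waste", 3))
#' eco_scale(items)$score  # 95
#' @export
eco_scale <- function(items) {
  stopifnot(is.data.frame(items))
  if (any(items$amount_penalty < 0) || any(items$hazard_penalty < 0))
    stop("negative penalty")
  items$total <- ifelse(items$category == "reagent",
                        items$amount_penalty * items$hazard_penalty,
                        items$amount_penalty)
  reagent <- sum(items$total[items$category == "reagent"])
  instrument <- sum(items$total[items$category != "reagent"])
  total <- reagent + instrument
  structure(list(items = items, reagent_penalty = reagent,
                 instrument_penalty = instrument, total_penalty = total,
                 score = 100 - total),
            class = "eco_scale_sheet")
}

#' @export
print.eco_scale_sheet <- function(x, ...) {
  cat("Analytical Eco-Scale\n")
  for (i in seq_len(nrow(x$items)))
    cat(sprintf("  %-22s %-20s %d PP\n", x$items$name[i],
                paste0("(", x$items$category[i], ")"), x$items$total[i]))
  cat(sprintf("  reagent PPs %d + instrument PPs %d = %d\n",
              x$reagent_penalty, x$instrument_penalty, x$total_penalty))
  cat(sprintf("  score: 100 - %d = %d  (%s)\n", x$total_penalty, x$score,
              if (x$score > 75) "excellent green analysis"
              else if (x$score > 50) "acceptable green analysis"
              else "inadequate green analysis"))
  invisible(x)
}

#' Eco-Scale items of the spectrophotometric workflow
#'
#' The standard sheet for the two methods: water (< 10 mL, non-hazardous),
#' ethanol (< 10 mL, flammable: one pictogram, danger), < 0.1 kWh energy per
#' sample, no vapour emission, 1-10 mL waste.
#'
#' @return data.frame of [eco_item()] rows scoring 95.
#' @export
eco_items_default <- function() {
  rbind(eco_item("water <10 mL", "reagent", 1, 0),
        eco_item("ethanol <10 mL", "reagent", 1, 2),
        eco_item("energy <0.1 kWh/sample", "instrument-energy", 0),
        eco_item("no vapour emission", "occupational-hazard", 0),
        eco_item("waste 1-10 mL", "waste", 3))
}

#' NEMI greenness profile
#'
#' Four-quadrant qualitative profile: a quadrant is green iff its criterion
#' is met. Classification inputs are caller-supplied booleans, not a
#' chemical-database lookup.
#'
#' @param pbt_free no reagent is persistent, bioaccumulative or toxic.
#' @param non_hazardous no reagent on the hazardous lists.
#' @param non_corrosive pH between 2 and 12 throughout.
#' @param low_waste less than 50 g of waste per sample.
#' @return object of class `"nemi_profile"` (four logical flags plus a text
#'   rendering).
#' @export
nemi <- function(pbt_free, non_hazardous, non_corrosive, low_waste) {
  flags <- c(pbt_free = isTRUE(pbt_free), non_hazardous = isTRUE(non_hazardous),
             non_corrosive = isTRUE(non_corrosive), low_waste = isTRUE(low_waste))
  structure(list(flags = flags, all_green = all(flags),
                 rendering = .nemi_render(flags)),
            class = "nemi_profile")
}

.nemi_render <- function(flags) {
  q <- ifelse(flags, "G", ".")
  paste0(" _______ \n",
         "| ", q[1], " | ", q[2], " |\n",
         "|---+---|\n",
         "| ", q[4], " | ", q[3], " |\n",
         " ------- ")
}

#' @export
print.nemi_profile <- function(x, ...) {
  cat("NEMI greenness profile (G = green quadrant)\n")
  cat(x$rendering, "\n")
  lab <- c("PBT-free", "non-hazardous", "non-corrosive (2 <= pH <= 12)",
           "waste < 50 g")
  for (i in 1:4) cat(sprintf("  %-32s %s\n", lab[i],
                             if (x$flags[i]) "green" else "blank"))
  invisible(x)
}
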