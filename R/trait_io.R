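#' Factor levels used throughout the analysis
#'
#' Dietary category (7 levels), flight ability (3 levels), and superordinal
#' clade (7 levels) are closed vocabularies; any other value in an input
#' table is a coding error, not a new category.
#'
#' @format Character vectors.
#' @name trait_levels
NULL

#' @rdname trait_levels
#' @export
DIET_LEVELS <- c("herbivore", "carnivore-aquatic-invertebrates",
                 "carnivore-vertebrates", "granivore/frugivore",
                 "insectivore", "nectarivore", "omnivore")

#' @rdname trait_levels
#' @export
FLIGHT_LEVELS <- c("strong flyer", "weak flyer", "flightless")

#' @rdname trait_levels
#' @export
CLADE_LEVELS <- c("Palaeognathae", "Galloanserae", "Strisores", "Columbaves",
                  "Gruiformes", "Aequorlitornithes", "Inopinaves")

# Offset added to cecal length (cm) before log10 so that absent ceca
# (length 0) map to a finite value of -1.
CECUM_LOG_OFFSET <- 0.1

#' Build a validated species trait table
#'
#' Checks the closed factor vocabularies, positivity of body mass,
#' nonnegativity of cecal length, and uniqueness of species names, then adds
#' the analysis columns \code{log_mass = log10(body_mass_g)} and
#' \code{log_cecum = log10(cecal_length_cm + 0.1)}. The 0.1 cm constant
#' keeps species with absent ceca finite on the log scale (log_cecum = -1).
#'
#' @param df Data frame with columns \code{species}, \code{cecal_length_cm},
#'   \code{body_mass_g}, \code{diet}, \code{flight}, \code{clade}.
#' @return A \code{trait_table} (a data frame) with factor columns levelled
#'   against the full vocabularies and the two log columns appended.
#' @export
trait_table <- function(df) {
  required <- c("species", "cecal_length_cm", "body_mass_g",
                "diet", "flight", "clade")
  missing_cols <- setdiff(required, names(df))
  if (length(missing_cols)) {
    stop("missing column(s): ", paste(missing_cols, collapse = ", "))
  }
  df <- as.data.frame(df, stringsAsFactors = FALSE)
  df$species <- trimws(as.character(df$species))

  bad <- function(rows, what) {
    if (length(rows)) {
      stop("validation error (", what, ") in row(s): ",
           paste(rows, collapse = ", "))
    }
  }
  bad(which(duplicated(df$species) | duplicated(df$species, fromLast = TRUE)),
      "duplicate species")
  bad(which(!nzchar(df$species)), "empty species name")
  bad(which(!is.finite(df$body_mass_g) | df$body_mass_g <= 0),
      "nonpositive body mass")
  bad(which(!is.finite(df$cecal_length_cm) | df$cecal_length_cm < 0),
      "negative cecal length")
  bad(which(!(trimws(df$diet) %in% DIET_LEVELS)), "unknown diet level")
  bad(which(!(trimws(df$flight) %in% FLIGHT_LEVELS)), "unknown flight level")
  bad(which(!(trimws(df$clade) %in% CLADE_LEVELS)), "unknown clade level")

  df$diet <- factor(trimws(df$diet), levels = DIET_LEVELS)
  df$flight <- factor(trimws(df$flight), levels = FLIGHT_LEVELS)
  df$clade <- factor(trimws(df$clade), levels = CLADE_LEVELS)
  df$log_mass <- log10(df$body_mass_g)
  df$log_cecum <- log10(df$cecal_length_cm + CECUM_LOG_OFFSET)
  rownames(df) <- NULL
  class(df) <- c("trait_table", "data.frame")
  df
}

#' Load a species trait table from CSV
#'
#' Expects an RFC-4180 CSV (UTF-8, header row) with the six raw columns
#' documented in \code{\link{trait_table}}; the log transforms are applied
#' on load, so the file stores only raw measurements.
#'
#' @param path Path to the CSV file.
#' @return A validated \code{trait_table}.
#' @export
load_traits <- function(path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE, fileEncoding = "UTF-8")
  trait_table(df)
}

#' Write the raw columns of a trait table to CSV
#'
#' @param traits A \code{trait_table}.
#' @param path Output CSV path.
#' @export
write_traits <- function(traits, path) {
  raw <- traits[, c("species", "cecal_length_cm", "body_mass_g",
                    "diet", "flight", "clade")]
  utils::write.csv(raw, path, row.names = FALSE, quote = TRUE,
                   fileEncoding = "UTF-8")
  invisible(path)
}

# Canonical form for species-name matching between table and tree: trim
# whitespace and unify underscores/spaces. Exact matching only; silent
# fuzzy matches are worse than errors.
canonical_name <- function(x) gsub("[ _]+", "_", trimws(x))

#' Align a trait table with a phylogeny
#'
#' Matches species names (exact, after trimming whitespace and unifying
#' spaces/underscores) between the table and the tree tips. Under
#' \code{policy = "strict"} any mismatch is an error; under \code{"prune"}
#' unmatched taxa are dropped from both sides, with a message reporting the
#' counts. The returned table rows are reordered to the pruned tree's tip
#' order so design matrices and covariance matrices line up by position.
#'
#' @param traits A \code{trait_table}.
#' @param tree A \code{"phylo"}.
#' @param policy \code{"strict"} or \code{"prune"}.
#' @return List with elements \code{traits} and \code{tree}, taxon sets
#'   identical and identically ordered.
#' @export
align_to_tree <- function(traits, tree, policy = c("strict", "prune")) {
  policy <- match.arg(policy)
  stopifnot(inherits(traits, "trait_table"), inherits(tree, "phylo"))
  tab_key <- canonical_name(traits$species)
  tip_key <- canonical_name(tree$tip.label)
  shared <- intersect(tab_key, tip_key)
  if (length(shared) == 0L) stop("no taxa shared between trait table and tree")
  extra_tab <- setdiff(tab_key, tip_key)
  extra_tip <- setdiff(tip_key, tab_key)
  if (policy == "strict" && (length(extra_tab) || length(extra_tip))) {
    stop("taxon mismatch under strict policy: ",
         length(extra_tab), " table-only, ", length(extra_tip), " tree-only ",
         "(first few: ",
         paste(utils::head(c(extra_tab, extra_tip), 5), collapse = ", "), ")")
  }
  if (length(extra_tab) || length(extra_tip)) {
    message("align_to_tree: dropped ", length(extra_tab),
            " table row(s) and ", length(extra_tip), " tree tip(s); ",
            length(shared), " taxa retained")
  }
  keep_tips <- tree$tip.label[tip_key %in% shared]
  tree2 <- if (length(keep_tips) < length(tree$tip.label)) {
    ape::keep.tip(tree, keep_tips)
  } else {
    tree
  }
  ord <- match(canonical_name(tree2$tip.label), tab_key)
  traits2 <- traits[ord, , drop = FALSE]
  rownames(traits2) <- NULL
  class(traits2) <- class(traits)
  list(traits = traits2, tree = tree2)
}
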