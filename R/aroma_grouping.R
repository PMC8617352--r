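CHEMICAL_CLASSES <- c("Aldehyde", "Ketone", "Pyrazine", "Phenolic", "Acid",
                      "Heterocyclic N", "Furan", "Alcohol", "Ester",
                      "Acetate", "Sulphide", "Pyrrole")

ANNOTATION_CODES <- c("1A", "1R", "2", "3", "4")

ODOUR_DESCRIPTORS <- c("fruity", "nutty", "roasted", "sweet", "sour",
                       "spicy", "musty")

#' Load the packaged volatile-compound roster
#'
#' Reads the 50-compound roster of coffee volatiles (GC-MS identified,
#' listed in elution order) with each compound's chemical class,
#' odour-activity annotation codes, default odour descriptors and
#' hedonic valence.
#'
#' Annotation codes: `1A`/`1R` mark key aroma compounds established by
#' GC-olfactometry in Arabica/Robusta respectively; `2` and `3` mark
#' compounds reported as potent coffee odorants in the literature; `4`
#' marks compounds previously identified in coffee as marker compounds.
#'
#' The class labels are kept exactly as tabulated in the reference
#' transcription, including two chemically surprising assignments
#' (phenol under "Heterocyclic N", 2-formylpyrrole under "Phenolic").
#' `chemically_corrected = TRUE` returns a variant with those two
#' compounds moved to their chemically sensible classes; census-style
#' checks are defined against the verbatim roster only.
#'
#' @param path Path to a roster CSV; defaults to the packaged file.
#' @param chemically_corrected Logical; reassign the two verbatim
#'   oddities to their chemical classes.
#' @return A data.frame with one row per compound and columns `name`,
#'   `chemical_class`, `annotations` (list of code vectors),
#'   `descriptors` (list of descriptor vectors) and `valence`.
#' @export
load_roster <- function(path = system.file("extdata", "compound_roster.csv",
                                           package = "beanspec"),
                        chemically_corrected = FALSE) {
  if (!nzchar(path) || !file.exists(path))
    stop("roster file not found: ", path)
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  required <- c("name", "chemical_class", "annotations", "descriptors",
                "valence")
  missing <- setdiff(required, names(df))
  if (length(missing))
    stop("roster is missing column(s): ", paste(missing, collapse = ", "))
  if (anyDuplicated(df$name))
    stop("roster has duplicate compound names: ",
         paste(unique(df$name[duplicated(df$name)]), collapse = ", "))
  bad_class <- setdiff(unique(df$chemical_class), CHEMICAL_CLASSES)
  if (length(bad_class))
    stop("unknown chemical class in roster: ",
         paste(bad_class, collapse = ", "))
  ann <- strsplit(df$annotations, ";", fixed = TRUE)
  if (any(lengths(ann) == 0) || any(!nzchar(unlist(ann))))
    stop("every roster compound needs at least one annotation code")
  bad_ann <- setdiff(unique(unlist(ann)), ANNOTATION_CODES)
  if (length(bad_ann))
    stop("unknown annotation code(s): ", paste(bad_ann, collapse = ", "))
  desc <- strsplit(df$descriptors, ";", fixed = TRUE)
  bad_desc <- setdiff(unique(unlist(desc)), ODOUR_DESCRIPTORS)
  if (length(bad_desc))
    stop("unknown descriptor(s): ", paste(bad_desc, collapse = ", "))
  if (!all(df$valence %in% c("positive", "negative", "neutral")))
    stop("valence must be positive, negative or neutral")
  roster <- data.frame(name = df$name,
                       chemical_class = df$chemical_class,
                       valence = df$valence,
                       stringsAsFactors = FALSE)
  roster$annotations <- ann
  roster$descriptors <- desc
  if (chemically_corrected) {
    roster$chemical_class[roster$name == "phenol"] <- "Phenolic"
    roster$chemical_class[roster$name == "2-formylpyrrole"] <- "Pyrrole"
  }
  class(roster) <- c("compound_roster", "data.frame")
  roster
}

#' Census of the roster's annotation strata
#'
#' @param roster A roster from [load_roster()].
#' @return Named list with the total compound count, per-class counts,
#'   and the sizes of the three odour-evidence strata: GC-O-keyed
#'   (code 1A or 1R), literature-odour-active only (2/3 without
#'   GC-O keys) and marker-only (code 4 alone).
#' @export
roster_census <- function(roster) {
  has <- function(codes) vapply(roster$annotations,
                                function(a) any(a %in% codes), logical(1))
  gco <- has(c("1A", "1R"))
  lit <- !gco & has(c("2", "3"))
  marker <- !gco & !lit & has("4")
  list(n_total = nrow(roster),
       by_class = table(factor(roster$chemical_class,
                               levels = CHEMICAL_CLASSES)),
       n_gco_keyed = sum(gco),
       n_literature_only = sum(lit),
       n_marker_only = sum(marker))
}

check_profile_compounds <- function(areas, roster) {
  unknown <- setdiff(names(areas), roster$name)
  if (length(unknown))
    stop("profile compound(s) not in roster: ",
         paste(unknown, collapse = ", "))
  if (any(areas < 0)) stop("relative peak areas must be non-negative")
  invisible(TRUE)
}

#' Sum a volatile profile by chemical class
#'
#' @param areas Named numeric vector of relative peak areas (% of total
#'   GC-MS peak area), names matching roster compounds.
#' @param roster A roster from [load_roster()].
#' @return Named numeric vector over all twelve chemical classes;
#'   classes absent from the profile report 0.
#' @export
group_by_class <- function(areas, roster) {
  check_profile_compounds(areas, roster)
  cls <- roster$chemical_class[match(names(areas), roster$name)]
  sums <- vapply(CHEMICAL_CLASSES,
                 function(k) sum(areas[cls == k]), numeric(1))
  names(sums) <- CHEMICAL_CLASSES
  sums
}

#' Sum a volatile profile by odour descriptor ("odorant series")
#'
#' A compound tagged with several descriptors contributes its full area
#' to each of them (odorant-series convention), so descriptor sums do
#' not partition the total.
#'
#' @inheritParams group_by_class
#' @return Named numeric vector over the seven descriptors.
#' @export
group_by_descriptor <- function(areas, roster) {
  check_profile_compounds(areas, roster)
  desc <- roster$descriptors[match(names(areas), roster$name)]
  sums <- vapply(ODOUR_DESCRIPTORS, function(d) {
    sum(areas[vapply(desc, function(dd) d %in% dd, logical(1))])
  }, numeric(1))
  names(sums) <- ODOUR_DESCRIPTORS
  sums
}

#' Aldehyde-to-pyrazine ratio
#'
#' An aroma indicator contrasting fruity/sweet aldehydes against
#' roasted/nutty pyrazines.
#'
#' @param class_sums Named vector from [group_by_class()].
#' @return `Aldehyde` sum divided by `Pyrazine` sum.
#' @export
aldehyde_pyrazine_ratio <- function(class_sums) {
  if (!all(c("Aldehyde", "Pyrazine") %in% names(class_sums)))
    stop("class_sums must contain Aldehyde and Pyrazine entries")
  if (class_sums[["Pyrazine"]] <= 0)
    stop("undefined ratio: pyrazine sum is zero")
  class_sums[["Aldehyde"]] / class_sums[["Pyrazine"]]
}

#' Positive-to-negative valence ratio
#'
#' Fraction of area carried by compounds with positive literature
#' descriptors over area carried by negatively described ones; neutral
#' compounds are excluded.
#'
#' @inheritParams group_by_class
#' @return Scalar ratio.
#' @export
positive_negative_ratio <- function(areas, roster) {
  check_profile_compounds(areas, roster)
  val <- roster$valence[match(names(areas), roster$name)]
  neg <- sum(areas[val == "negative"])
  if (neg <= 0) stop("undefined ratio: negative-valence sum is zero")
  sum(areas[val == "positive"]) / neg
}
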