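#' Default lipid taxonomy: 530 species in 34 classes
#'
#' Builds the panel structure used throughout the package: 530 lipid species
#' spread over 34 lipid classes. The ten classes that dominate the class-level
#' ranking in the serum study this package models (PC, NAPS, DG, GB3, Cer,
#' MhCer, BMP, LPS, TG, NAPE) are present by name and jointly contain exactly
#' 176 species; the remaining 354 species are distributed over 24 further
#' classes with common lipid-class acronyms. Species are named in the dotted
#' dialect `CLASS.carbons.doublebonds` (e.g. `"PC.38.5"`); the names are
#' treated as opaque identifiers everywhere — class membership always comes
#' from the taxonomy table, never from parsing names.
#'
#' The function is fully deterministic: the `seed` argument is accepted for
#' interface symmetry with the other generators but no randomness is used.
#'
#' @param seed Ignored; the taxonomy is a fixed fixture.
#' @return A tibble with columns `species_id` and `class_id`, one row per
#'   species, in a stable order (classes in panel order, species by
#'   carbons then double bonds).
#' @examples
#' tax <- default_taxonomy()
#' nrow(tax)                      # 530
#' dplyr::n_distinct(tax$class_id) # 34
#' @export
default_taxonomy <- function(seed = NULL) {
  named <- c(
    PC = 60, TG = 40, Cer = 20, DG = 15, MhCer = 12,
    NAPS = 8, GB3 = 6, BMP = 6, LPS = 5, NAPE = 4
  ) # sums to 176
  others <- c(
    "PE", "PS", "PI", "PG", "PA", "LPC", "LPE", "LPI", "SM", "dhSM",
    "GM3", "GD3", "SHexCer", "LacCer", "PlsPE", "PlsPC", "AcCa", "CL",
    "MLCL", "FFA", "CE", "MG", "GM2", "StE"
  )
  other_sizes <- setNames(c(rep(15L, 18), rep(14L, 6)), others) # sums to 354
  sizes <- c(named, other_sizes)
  rows <- purrr::imap(sizes, function(k, cls) {
    tibble::tibble(
      species_id = species_names(cls, k),
      class_id = cls
    )
  })
  out <- dplyr::bind_rows(rows)
  validate_taxonomy(out)
  out
}

# dotted species names for one class: CLASS.carbons.dbs, carbons 30,32,...
# crossed with double bonds 0..7, truncated to k
species_names <- function(class_id, k) {
  grid <- expand.grid(db = 0:7, carbons = seq(30L, 58L, by = 2L))
  grid <- grid[seq_len(k), , drop = FALSE]
  paste(class_id, grid$carbons, grid$db, sep = ".")
}

#' Validate a species-to-class taxonomy table
#'
#' Checks the structural invariants every taxonomy must satisfy: the two
#' required columns are present, species identifiers are unique, and each
#' species maps to exactly one class.
#'
#' @param taxonomy A data frame with columns `species_id` and `class_id`.
#' @return The taxonomy, invisibly, if valid; otherwise an error.
#' @export
validate_taxonomy <- function(taxonomy) {
  if (!all(c("species_id", "class_id") %in% names(taxonomy))) {
    abort("taxonomy must have columns `species_id` and `class_id`")
  }
  dup <- taxonomy$species_id[duplicated(taxonomy$species_id)]
  if (length(dup) > 0) {
    abort(paste0(
      "duplicated species in taxonomy: ",
      paste(unique(dup), collapse = ", ")
    ))
  }
  if (anyNA(taxonomy$species_id) || anyNA(taxonomy$class_id)) {
    abort("taxonomy contains missing identifiers")
  }
  invisible(taxonomy)
}

#' Ten lipid classes highlighted by the class-level analysis
#'
#' The named classes whose member species form the candidate pool of the
#' within-class species selection (Method 2) on the default panel.
#'
#' @return Character vector of ten class identifiers.
#' @export
top_table_classes <- function() {
  c("PC", "NAPS", "DG", "GB3", "Cer", "MhCer", "BMP", "LPS", "TG", "NAPE")
}
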