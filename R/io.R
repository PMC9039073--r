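#' Read a wide abundance table
#'
#' Reads a subjects-by-features CSV: first column `subject_id`, one further
#' column per lipid species (or class), header row mandatory. Empty cells and
#' the sentinel `"NA"` become missing values. Column order is preserved.
#'
#' @param path Path to a CSV file.
#' @return A tibble: `subject_id` plus one numeric column per feature.
#'   Missing measurements are `NA`.
#' @details Duplicate subject or feature names and negative concentrations
#'   (concentrations live on the linear scale and cannot be negative) are
#'   hard errors that name the offending column or cell.
#' @export
read_abundance <- function(path) {
  out <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    .default = readr::col_double()
  ), na = c("", "NA"), progress = FALSE, name_repair = "minimal")
  if (names(out)[1] != "subject_id") {
    abort("first column of an abundance table must be `subject_id`")
  }
  check_abundance(out)
  tibble::as_tibble(out, .name_repair = "minimal")
}

check_abundance <- function(ab) {
  feats <- names(ab)[-1]
  dup <- unique(feats[duplicated(feats)])
  if (length(dup) > 0) {
    abort(paste0("duplicated feature column(s): ", paste(dup, collapse = ", ")))
  }
  dups <- unique(ab$subject_id[duplicated(ab$subject_id)])
  if (length(dups) > 0) {
    abort(paste0("duplicated subject_id(s): ", paste(dups, collapse = ", ")))
  }
  m <- abundance_matrix(ab)
  neg <- which(!is.na(m) & m < 0, arr.ind = TRUE)
  if (nrow(neg) > 0) {
    abort(sprintf(
      "negative concentration at subject %s, feature %s",
      ab$subject_id[neg[1, 1]], colnames(m)[neg[1, 2]]
    ))
  }
  invisible(ab)
}

# numeric matrix view of a wide abundance tibble (rows named by subject)
abundance_matrix <- function(ab) {
  m <- as.matrix(ab[, -1, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ab$subject_id
  m
}

matrix_to_abundance <- function(m) {
  dplyr::bind_cols(
    tibble::tibble(subject_id = rownames(m)),
    tibble::as_tibble(m, .name_repair = "minimal")
  )
}

#' Read a species-to-class taxonomy
#'
#' Accepts either a two-column CSV (`species_id`, `class_id`) or a JSON
#' object mapping species names to class names.
#'
#' @param path Path to a `.csv` or `.json` file.
#' @return A validated taxonomy tibble.
#' @export
read_taxonomy <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    obj <- jsonlite::read_json(path, simplifyVector = TRUE)
    tax <- tibble::tibble(
      species_id = names(obj),
      class_id = unname(unlist(obj))
    )
  } else {
    tax <- readr::read_csv(path, col_types = "cc", progress = FALSE)
  }
  validate_taxonomy(tax)
  tax
}

#' Read subject metadata
#'
#' @param path CSV with columns `subject_id`, `group` (`"case"` or
#'   `"control"`), `age` (years), `sex` (`"female"` or `"male"`).
#' @return A tibble with `group` and `sex` as factors
#'   (levels `control` < `case`; `male` < `female`).
#' @export
read_metadata <- function(path) {
  md <- readr::read_csv(path, col_types = readr::cols(
    subject_id = readr::col_character(),
    group = readr::col_character(),
    age = readr::col_double(),
    sex = readr::col_character()
  ), progress = FALSE)
  bad <- setdiff(unique(md$group), c("case", "control"))
  if (length(bad) > 0) {
    abort(paste0("unknown group label(s): ", paste(bad, collapse = ", ")))
  }
  md$group <- factor(md$group, levels = c("control", "case"))
  md$sex <- factor(md$sex, levels = c("male", "female"))
  md
}

#' Sum species-level abundances into class-level abundances
#'
#' The class concentration of a subject is the sum of that subject's
#' non-missing member-species concentrations — the standard lipidomics
#' convention, which also preserves total measured concentration per subject.
#' A class value is missing only when *all* member species are missing for
#' that subject.
#'
#' @param abundance Species-level wide abundance tibble.
#' @param taxonomy Taxonomy covering every feature of `abundance`.
#' @return A class-level wide abundance tibble, one column per class present
#'   in the taxonomy (in taxonomy order), restricted to classes with at least
#'   one member among the abundance features.
#' @export
aggregate_to_classes <- function(abundance, taxonomy) {
  validate_taxonomy(taxonomy)
  feats <- names(abundance)[-1]
  orphans <- setdiff(feats, taxonomy$species_id)
  if (length(orphans) > 0) {
    abort(paste0(
      "species absent from taxonomy: ",
      paste(orphans, collapse = ", ")
    ))
  }
  class_of <- setNames(taxonomy$class_id, taxonomy$species_id)
  classes <- unique(taxonomy$class_id[taxonomy$species_id %in% feats])
  m <- abundance_matrix(abundance)
  out <- vapply(classes, function(cl) {
    members <- feats[class_of[feats] == cl]
    sub <- m[, members, drop = FALSE]
    all_na <- rowSums(!is.na(sub)) == 0
    s <- rowSums(sub, na.rm = TRUE)
    s[all_na] <- NA_real_
    s
  }, numeric(nrow(m)))
  if (nrow(m) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, classes))
  rownames(out) <- abundance$subject_id
  matrix_to_abundance(out)
}

#' Filter and impute missing measurements
#'
#' Species below the detection limit appear as missing values. Features
#' missing in more than `drop_frac` of subjects are removed from the table;
#' remaining missing entries are imputed as half the feature's observed
#' minimum (`impute = "half_min"`, the conventional below-detection-limit
#' surrogate) or left missing (`impute = "none"`). A feature with no observed
#' value at all has no minimum and is dropped regardless of `drop_frac` when
#' imputation is requested.
#'
#' @param abundance Wide abundance tibble.
#' @param drop_frac Maximum tolerated missing fraction per feature, in
#'   `[0, 1]`. Default 0.2.
#' @param impute `"half_min"` (default) or `"none"`.
#' @return The filtered (and possibly imputed) tibble, with attribute
#'   `"dropped_features"` listing removed feature names.
#' @export
handle_missing <- function(abundance, drop_frac = 0.2,
                           impute = c("half_min", "none")) {
  impute <- match.arg(impute)
  stopifnot(drop_frac >= 0, drop_frac <= 1)
  m <- abundance_matrix(abundance)
  miss_frac <- colMeans(is.na(m))
  drop <- miss_frac > drop_frac
  if (impute == "half_min") drop <- drop | miss_frac == 1
  kept <- m[, !drop, drop = FALSE]
  if (impute == "half_min" && anyNA(kept)) {
    mins <- apply(kept, 2, min, na.rm = TRUE)
    for (j in which(colSums(is.na(kept)) > 0)) {
      kept[is.na(kept[, j]), j] <- mins[j] / 2
    }
  }
  out <- matrix_to_abundance(kept)
  attr(out, "dropped_features") <- colnames(m)[drop]
  out
}

#' Join abundances, covariates, and outcome into a modelling table
#'
#' Produces the design the classifier consumes: `subject_id`, the binary
#' outcome `group` (positive class = `case`), covariates `age` (years,
#' untransformed) and `sex_female` (indicator, female = 1, male = 0), and one
#' column per lipid feature. At class level on the default panel this is the
#' 36-variable design (34 classes + age + sex).
#'
#' @param abundance Wide abundance tibble (species- or class-level).
#' @param metadata Subject metadata with exactly one record per subject of
#'   `abundance`.
#' @return A feature-table tibble with attribute `"covariates"` naming the
#'   non-lipid predictor columns.
#' @export
build_feature_table <- function(abundance, metadata) {
  if (!setequal(abundance$subject_id, metadata$subject_id) ||
    anyDuplicated(metadata$subject_id) > 0) {
    abort("metadata must have exactly one record per abundance subject")
  }
  md <- metadata[match(abundance$subject_id, metadata$subject_id), ]
  if (dplyr::n_distinct(md$group) < 2) {
    abort("both outcome levels must be present")
  }
  ft <- dplyr::bind_cols(
    tibble::tibble(
      subject_id = abundance$subject_id,
      group = factor(as.character(md$group), levels = c("control", "case")),
      age = md$age,
      sex_female = as.numeric(md$sex == "female")
    ),
    abundance[, -1, drop = FALSE]
  )
  attr(ft, "covariates") <- c("age", "sex_female")
  ft
}

ft_covariates <- function(ft) attr(ft, "covariates") %||% character()

ft_features <- function(ft) {
  setdiff(names(ft), c("subject_id", "group", ft_covariates(ft)))
}

# restrict a feature table to the given lipid features (covariates kept)
ft_keep_features <- function(ft, features) {
  out <- ft[, c("subject_id", "group", ft_covariates(ft), features)]
  attr(out, "covariates") <- ft_covariates(ft)
  out
}

# predictor matrix (lipids + covariates) and outcome for model fitting
ft_design <- function(ft, with_covariates = TRUE) {
  cols <- ft_features(ft)
  if (with_covariates) cols <- c(cols, ft_covariates(ft))
  x <- as.data.frame(ft[, cols, drop = FALSE])
  list(x = x, y = ft$group)
}
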