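#' Validate a phylogenetically paired dataset
#'
#' Checks that a data frame is a valid long-format paired dataset: one row per
#' replicate measurement with columns `pair`, `species`, `origin`, `replicate`
#' and `value`. Every pair must contain exactly two species carrying distinct
#' origin codes (0 = native, 1 = invasive), every species at least one
#' replicate, and `(pair, species, replicate)` triples must be unique.
#'
#' @param data A data frame with columns `pair`, `species`, `origin`,
#'   `replicate`, `value`.
#' @return A tibble with the five columns in canonical order (sorted by pair,
#'   then origin, then replicate), `pair` and `species` as character, `origin`
#'   and `replicate` as integer, `value` as double. The attribute `"balanced"`
#'   records whether all species have the same number of replicates.
#' @examples
#' sim <- simulate_paired_data(n_pairs = 3, n_replicates = 2, seed = 1)
#' validate_pair_data(sim$data)
#' @export
validate_pair_data <- function(data) {
  required <- c("pair", "species", "origin", "replicate", "value")
  if (!is.data.frame(data)) {
    abort("`data` must be a data frame.", class = "phypairs_format_error")
  }
  missing_cols <- setdiff(required, names(data))
  if (length(missing_cols) > 0) {
    abort(
      paste0("Missing required column(s): ", paste(missing_cols, collapse = ", "), "."),
      class = "phypairs_format_error"
    )
  }
  if (nrow(data) == 0) {
    abort("Dataset has no rows.", class = "phypairs_validation_error")
  }

  value <- suppressWarnings(as.numeric(data$value))
  if (anyNA(value)) {
    abort("Column `value` contains non-numeric or missing entries.",
          class = "phypairs_parse_error")
  }
  origin_num <- suppressWarnings(as.numeric(as.character(data$origin)))
  if (anyNA(origin_num) || !all(origin_num %in% c(0, 1))) {
    abort("Column `origin` must contain only 0 (native) and 1 (invasive).",
          class = "phypairs_validation_error")
  }
  replicate <- suppressWarnings(as.integer(as.character(data$replicate)))
  if (anyNA(replicate)) {
    abort("Column `replicate` must be integer-valued.", class = "phypairs_parse_error")
  }

  out <- tibble::tibble(
    pair = as.character(data$pair),
    species = as.character(data$species),
    origin = as.integer(origin_num),
    replicate = replicate,
    value = value
  )

  # species identifiers must be globally unique (never shared between pairs)
  sp_pair <- dplyr::distinct(out, .data$species, .data$pair)
  dup_sp <- sp_pair$species[duplicated(sp_pair$species)]
  if (length(dup_sp) > 0) {
    abort(
      paste0("Species appear in more than one pair: ",
             paste(unique(dup_sp), collapse = ", "), "."),
      class = "phypairs_validation_error"
    )
  }

  per_pair <- out |>
    dplyr::distinct(.data$pair, .data$species, .data$origin) |>
    dplyr::summarise(
      n_species = dplyr::n_distinct(.data$species),
      origins = dplyr::n_distinct(.data$origin),
      .by = "pair"
    )
  bad_n <- per_pair$pair[per_pair$n_species != 2L]
  if (length(bad_n) > 0) {
    abort(
      paste0("Each pair needs exactly two species; offending pair(s): ",
             paste(bad_n, collapse = ", "), "."),
      class = "phypairs_validation_error"
    )
  }
  bad_origin <- per_pair$pair[per_pair$origins != 2L]
  if (length(bad_origin) > 0) {
    abort(
      paste0("The two species of a pair must carry distinct origin codes (one 0, one 1); ",
             "offending pair(s): ", paste(bad_origin, collapse = ", "), "."),
      class = "phypairs_validation_error"
    )
  }
  # origin must be constant within species
  sp_orig <- dplyr::distinct(out, .data$species, .data$origin)
  if (anyDuplicated(sp_orig$species) > 0) {
    abort("A species carries more than one origin code.",
          class = "phypairs_validation_error")
  }

  key <- paste(out$pair, out$species, out$replicate, sep = "\r")
  if (anyDuplicated(key) > 0) {
    abort("(pair, species, replicate) triples must be unique.",
          class = "phypairs_validation_error")
  }

  out <- dplyr::arrange(out, .data$pair, .data$origin, .data$replicate)
  reps <- dplyr::count(out, .data$pair, .data$species)
  attr(out, "balanced") <- length(unique(reps$n)) == 1L
  out
}

#' Read a long-format paired dataset from CSV
#'
#' Reads a comma-separated file with header columns `pair`, `species`,
#' `origin`, `replicate`, `value` (one row per replicate measurement) and
#' validates it as a paired dataset.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble, as [validate_pair_data()].
#' @seealso [write_pair_csv()]
#' @export
read_pair_csv <- function(path) {
  if (!file.exists(path)) {
    abort(paste0("File not found: ", path), class = "phypairs_format_error")
  }
  raw <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  validate_pair_data(raw)
}

#' Write a paired dataset to CSV
#'
#' Writes exactly the five canonical columns (`pair`, `species`, `origin`,
#' `replicate`, `value`), one row per measurement. Numeric values are
#' serialized at full (round-trip) precision, so
#' `read_pair_csv(write_pair_csv(x, f))` reproduces `x` exactly.
#'
#' @param data A paired dataset (validated on the way out).
#' @param path Output file path.
#' @return The input `data`, invisibly.
#' @export
write_pair_csv <- function(data, path) {
  data <- validate_pair_data(data)
  readr::write_csv(data[, c("pair", "species", "origin", "replicate", "value")], path)
  invisible(data)
}

#' Species pairs of the Hawaiian native/invasive comparison
#'
#' Returns the packaged table of 19 phylogenetically matched native/invasive
#' species pairs from Hawaiian plant communities, with each pair classified by
#' the taxonomic level of the comparison: congeneric (the two binomials share
#' a genus token), within-order (pairs listed in the within-order block, whose
#' species belong to different families of one order), or confamilial (all
#' remaining pairs).
#'
#' @return A tibble with columns `family` (family, or order for the
#'   within-order block), `invasive_species`, `native_species`, `block`
#'   (`"family"` or `"within_order"`), and the derived `comparison_level`.
#' @examples
#' pairs <- species_pairs()
#' nrow(pairs)
#' classify_pair_levels(pairs)
#' @export
species_pairs <- function() {
  path <- system.file("extdata", "species_pairs.csv", package = "phypairs",
                      mustWork = TRUE)
  tab <- readr::read_csv(
    path,
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  tab$comparison_level <- .comparison_level(tab$invasive_species,
                                            tab$native_species, tab$block)
  tab
}

.genus_token <- function(binomial) {
  tok <- vapply(strsplit(trimws(binomial), "\\s+"), function(x) x[1], character(1))
  if (any(is.na(tok) | tok == "")) {
    abort("Malformed binomial: missing genus token.", class = "phypairs_parse_error")
  }
  tok
}

.comparison_level <- function(invasive, native, block) {
  congeneric <- .genus_token(invasive) == .genus_token(native)
  dplyr::case_when(
    congeneric ~ "congeneric",
    block == "within_order" ~ "within_order",
    .default = "confamilial"
  )
}

#' Count species pairs by taxonomic comparison level
#'
#' Classifies each entry of a species-pair table as congeneric, confamilial or
#' within-order (see [species_pairs()] for the rule) and tabulates the counts.
#'
#' @param entries A data frame with columns `invasive_species`,
#'   `native_species` and `block`; typically [species_pairs()] output.
#' @return A tibble with columns `comparison_level` and `n`, one row for each
#'   of the three levels (zero counts included).
#' @export
classify_pair_levels <- function(entries) {
  levels <- c("congeneric", "confamilial", "within_order")
  if (nrow(entries) == 0) {
    return(tibble::tibble(comparison_level = levels, n = 0L))
  }
  lev <- .comparison_level(entries$invasive_species, entries$native_species,
                           entries$block)
  counts <- table(factor(lev, levels = levels))
  tibble::tibble(comparison_level = levels, n = as.integer(counts))
}
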