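# Flat recall container: one row per food item. Columns:
#   person_id, age_years, sex, day1_weight, stratum_id, psu_id,
#   day_index, occasion_code, food_code, category, amount,
#   milk_fat_level, milk_flavored, <37 nutrient columns>.
# This is the on-disk CSV dialect and the in-memory working format; every
# stage of the pipeline consumes and returns this shape.

.ID_COLS <- c(
  "person_id", "age_years", "sex", "day1_weight", "stratum_id", "psu_id",
  "day_index", "occasion_code", "food_code", "category", "amount",
  "milk_fat_level", "milk_flavored"
)

.CATEGORIES <- c(
  "egg", "egg_substitute", "other_poultry_egg", "egg_mixed_dish",
  "milk", "fruit_vegetable", "grain", "other"
)
.MILK_FAT_LEVELS <- c("whole", "reduced_2pct", "lowfat_1pct", "skim")
.SEXES <- c("male", "female")

recall_cols <- function() c(.ID_COLS, nutrient_keys())

#' Validate a recall dataset
#'
#' Checks the flat one-row-per-food-item recall table against the package's
#' schema: complete column set (all 37 nutrient keys mandatory), ages in
#' 1--18, nonnegative survey weights and amounts, known sex / occasion /
#' food-category codes, milk attributes present exactly on milk items, day
#' index in \{1, 2\}, at most one breakfast occasion per person-day, no
#' duplicate (person, day, occasion, food) rows, and person-level attributes
#' constant across a person's rows.
#'
#' @param recalls A data frame in the recall-item layout (see
#'   [read_recalls()]).
#' @return `recalls` invisibly, as a tibble, if valid; otherwise an error of
#'   class `dietshift_validation` (or `dietshift_schema` for missing columns)
#'   naming the offending column or row.
#' @export
validate_recalls <- function(recalls) {
  recalls <- tibble::as_tibble(recalls)
  missing <- setdiff(recall_cols(), names(recalls))
  if (length(missing) > 0) {
    abort_ds(paste0("missing column(s): ", paste(missing, collapse = ", ")),
             "dietshift_schema")
  }
  if (nrow(recalls) == 0) return(invisible(recalls))

  bad_row <- function(cond, what) {
    idx <- which(cond)
    if (length(idx) > 0) {
      abort_ds(sprintf("%s (first offending row: %d)", what, idx[1]),
               "dietshift_validation")
    }
  }
  bad_row(!(recalls$age_years %in% 1:18), "age_years must be an integer in 1..18")
  bad_row(!(recalls$sex %in% .SEXES), "sex must be 'male' or 'female'")
  bad_row(is.na(recalls$day1_weight) | recalls$day1_weight < 0,
          "day1_weight must be nonnegative")
  bad_row(!(recalls$day_index %in% c(1L, 2L)), "day_index must be 1 or 2")
  bad_row(!(recalls$occasion_code %in% c("breakfast", "other")),
          "occasion_code must be 'breakfast' or 'other'")
  bad_row(!(recalls$category %in% .CATEGORIES), "unknown food category")
  bad_row(is.na(recalls$amount) | recalls$amount < 0, "amount must be nonnegative")

  is_milk <- recalls$category == "milk"
  bad_row(is_milk & (is.na(recalls$milk_fat_level) | is.na(recalls$milk_flavored)),
          "milk items must carry milk_fat_level and milk_flavored")
  bad_row(is_milk & !is.na(recalls$milk_fat_level) &
            !(recalls$milk_fat_level %in% .MILK_FAT_LEVELS),
          "unknown milk_fat_level")
  bad_row(!is_milk & !is.na(recalls$milk_fat_level),
          "milk_fat_level must be absent on non-milk items")

  for (k in nutrient_keys()) {
    bad_row(is.na(recalls[[k]]) | recalls[[k]] < 0,
            sprintf("nutrient column '%s' must be nonnegative and non-missing", k))
  }

  key <- paste(recalls$person_id, recalls$day_index, recalls$occasion_code,
               recalls$food_code, sep = "\r")
  bad_row(duplicated(key), "duplicate (person, day, occasion, food) item")

  per_person <- dplyr::distinct(
    recalls, .data$person_id, .data$age_years, .data$sex,
    .data$day1_weight, .data$stratum_id, .data$psu_id
  )
  if (anyDuplicated(per_person$person_id) > 0) {
    abort_ds("person-level attributes differ across rows of the same person",
             "dietshift_validation")
  }
  invisible(recalls)
}

#' Read a recall dataset from CSV
#'
#' Reads the flat recall-item CSV dialect (UTF-8, `.` decimal separator,
#' mandatory header) and validates it. Row order within the file does not
#' affect any downstream computation.
#'
#' @param path Path to a CSV file.
#' @return A validated tibble of recall items.
#' @seealso [write_recalls()], [validate_recalls()]
#' @export
read_recalls <- function(path) {
  if (!file.exists(path)) abort_ds(paste0("no such file: ", path), "dietshift_io")
  spec <- readr::cols(
    person_id = readr::col_character(),
    age_years = readr::col_integer(),
    sex = readr::col_character(),
    day1_weight = readr::col_double(),
    stratum_id = readr::col_character(),
    psu_id = readr::col_character(),
    day_index = readr::col_integer(),
    occasion_code = readr::col_character(),
    food_code = readr::col_character(),
    category = readr::col_character(),
    amount = readr::col_double(),
    milk_fat_level = readr::col_character(),
    milk_flavored = readr::col_logical(),
    .default = readr::col_double()
  )
  recalls <- readr::read_csv(path, col_types = spec, progress = FALSE)
  validate_recalls(recalls)
  recalls
}

#' Write a recall dataset to CSV
#'
#' Serializes with full double precision so that `write_recalls()` followed by
#' [read_recalls()] is the identity on valid collections.
#'
#' @param recalls A validated recall tibble.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_recalls <- function(recalls, path) {
  validate_recalls(recalls)
  recalls <- tibble::as_tibble(recalls)[, recall_cols()]
  readr::write_csv(recalls, path, progress = FALSE)
  invisible(path)
}

#' Sum nutrients per person-day
#'
#' Collapses a recall-item table to one row per person-day by componentwise
#' addition of item nutrient vectors, either over the whole day or over the
#' breakfast occasion only. Person-days whose scope contains no items (e.g. a
#' breakfast skipper under `scope = "breakfast_only"`) appear with an all-zero
#' nutrient vector, so the output always covers every person-day present in
#' the input.
#'
#' @param recalls A validated recall tibble.
#' @param scope `"whole_day"` or `"breakfast_only"`.
#' @return Tibble with `person_id`, `day_index`, person attributes
#'   (`age_years`, `sex`, `day1_weight`, `stratum_id`, `psu_id`) and the 37
#'   nutrient columns.
#' @export
sum_nutrients <- function(recalls, scope = c("whole_day", "breakfast_only")) {
  scope <- match.arg(scope)
  recalls <- tibble::as_tibble(recalls)
  nk <- nutrient_keys()
  grid <- dplyr::distinct(recalls, .data$person_id, .data$day_index,
                          .data$age_years, .data$sex, .data$day1_weight,
                          .data$stratum_id, .data$psu_id)
  in_scope <- if (scope == "breakfast_only") {
    recalls[recalls$occasion_code == "breakfast", , drop = FALSE]
  } else recalls
  sums <- in_scope |>
    dplyr::group_by(.data$person_id, .data$day_index) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(nk), sum), .groups = "drop")
  out <- dplyr::left_join(grid, sums, by = c("person_id", "day_index"))
  out |>
    dplyr::mutate(dplyr::across(dplyr::all_of(nk), ~ tidyr::replace_na(.x, 0))) |>
    dplyr::arrange(.data$person_id, .data$day_index)
}

#' Person-level attributes of a recall dataset
#'
#' @param recalls A validated recall tibble.
#' @return One row per person: `person_id`, `age_years`, `sex`,
#'   `day1_weight`, `stratum_id`, `psu_id`.
#' @export
recall_persons <- function(recalls) {
  dplyr::distinct(tibble::as_tibble(recalls), .data$person_id,
                  .data$age_years, .data$sex, .data$day1_weight,
                  .data$stratum_id, .data$psu_id) |>
    dplyr::arrange(.data$person_id)
}
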