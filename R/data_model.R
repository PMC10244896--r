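# Domain types, CSV readers/writers, study filters, covariate standardisation
# and parity derivation shared by all modelling stages.

#' Encounter histories of marked females
#'
#' Container for per-female 0/1 sighting vectors over breeding seasons.
#' A female's history is conditioned on her first sighting (recruitment):
#' cells before recruitment are structurally absent and stored as `NA`; from
#' recruitment onward every cell is 0 (not sighted) or 1 (sighted with pup).
#'
#' @param sightings integer matrix, one row per female, one column per
#'   occasion; `NA` allowed only before the first 1 of each row.
#' @param years integer vector of calendar years labelling the columns.
#' @param female_ids character vector of unique female identifiers.
#' @return An object of class `encounter_histories` with elements
#'   `sightings` (matrix, pre-recruitment cells `NA`), `years`, `female_id`
#'   and `recruit` (1-based index of each female's first sighting).
#' @export
encounter_histories <- function(sightings, years, female_ids) {
  sightings <- as.matrix(sightings)
  storage.mode(sightings) <- "integer"
  if (nrow(sightings) == 0L) stop("empty encounter matrix")
  if (length(years) != ncol(sightings))
    stop("length(years) must match number of occasions")
  if (length(female_ids) != nrow(sightings))
    stop("length(female_ids) must match number of females")
  female_ids <- as.character(female_ids)
  if (anyDuplicated(female_ids))
    stop("duplicate female_id: ", female_ids[duplicated(female_ids)][1L])

  recruit <- integer(nrow(sightings))
  for (i in seq_len(nrow(sightings))) {
    row <- sightings[i, ]
    ones <- which(!is.na(row) & row == 1L)
    if (length(ones) == 0L)
      stop("female ", female_ids[i], " never sighted")
    r <- ones[1L]
    after <- row[r:length(row)]
    if (anyNA(after) || !all(after %in% c(0L, 1L)))
      stop("female ", female_ids[i],
           ": non-binary or missing cell after first sighting")
    row[seq_len(r - 1L)] <- NA_integer_
    sightings[i, ] <- row
    recruit[i] <- r
  }
  dimnames(sightings) <- list(female_ids, years)
  structure(
    list(sightings = sightings, years = as.integer(years),
         female_id = female_ids, recruit = recruit),
    class = "encounter_histories"
  )
}

#' @export
print.encounter_histories <- function(x, ...) {
  cat("<encounter_histories> ", length(x$female_id), " females x ",
      length(x$years), " occasions (", x$years[1L], "-",
      x$years[length(x$years)], ")\n", sep = "")
  cat("  sightings per female: ",
      paste(range(rowSums(x$sightings == 1L, na.rm = TRUE)), collapse = "-"),
      "\n", sep = "")
  invisible(x)
}

#' @export
length.encounter_histories <- function(x) length(x$female_id)

#' Read a wide encounter-history matrix from CSV
#'
#' Expected layout: a `female_id` column followed by one column per breeding
#' season, headers being calendar years, cells in \{0, 1, NA\}. `NA` is only
#' legal before a female's first sighting.
#'
#' @param path path to the CSV file.
#' @return [encounter_histories()] object.
#' @export
read_encounter_matrix <- function(path) {
  df <- read.csv(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (nrow(df) == 0L) stop("empty encounter file: ", path)
  idcol <- if ("female_id" %in% names(df)) "female_id" else names(df)[1L]
  years <- suppressWarnings(as.integer(names(df)[names(df) != idcol]))
  if (anyNA(years)) stop("encounter header must be calendar years")
  m <- as.matrix(df[, names(df) != idcol, drop = FALSE])
  encounter_histories(m, years, df[[idcol]])
}

#' Write encounter histories to a wide CSV
#'
#' @param histories an [encounter_histories()] object.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_encounter_matrix <- function(histories, path) {
  df <- data.frame(female_id = histories$female_id,
                   histories$sightings, check.names = FALSE)
  write.csv(df, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Drop females sighted in only one breeding season
#'
#' Single-season females cannot inform breeding-rate transitions, and their
#' recruitment itself is uncertain; the study design drops them.
#'
#' @param histories an [encounter_histories()] object.
#' @param quiet suppress the message stating how many rows were removed.
#' @return Filtered `encounter_histories`; attribute `n_removed` records the
#'   number of females dropped. Idempotent.
#' @export
filter_single_season <- function(histories, quiet = FALSE) {
  n_sight <- rowSums(histories$sightings == 1L, na.rm = TRUE)
  keep <- n_sight >= 2L
  n_removed <- sum(!keep)
  if (!quiet)
    message("filter_single_season: removed ", n_removed, " of ",
            length(keep), " females sighted in only one season")
  if (all(keep)) {
    out <- histories
  } else {
    out <- encounter_histories(histories$sightings[keep, , drop = FALSE],
                               histories$years,
                               histories$female_id[keep])
  }
  attr(out, "n_removed") <- n_removed
  out
}

#' Derive parity groups from a pup table
#'
#' Parity (maternal experience) is the cumulative count of a female's recorded
#' births, discretised to groups 1, 2 and 3+ because experience effects
#' plateau.
#'
#' @param pups data frame with columns `female_id` and `year` (one row per
#'   pup record).
#' @return factor of levels `"1"`, `"2"`, `"3+"` aligned with the rows of
#'   `pups`.
#' @export
derive_parity <- function(pups) {
  if (!all(c("female_id", "year") %in% names(pups)))
    stop("pup table needs 'female_id' and 'year' columns")
  key <- paste(pups$female_id, pups$year, sep = "\r")
  if (anyDuplicated(key))
    stop("two pup records for the same female and occasion: ",
         gsub("\r", " / ", key[duplicated(key)][1L]))
  ord <- order(pups$female_id, pups$year)
  counts <- integer(nrow(pups))
  counts[ord] <- stats::ave(rep(1L, nrow(pups)), pups$female_id[ord],
                            FUN = cumsum)
  factor(ifelse(counts >= 3L, "3+", as.character(counts)),
         levels = c("1", "2", "3+"))
}

#' Standardise a covariate
#'
#' Fits the location/scale transform used for female age and weaning length:
#' `z = (x - mean) / sd`. The fitted constants travel with fitted models and
#' the run manifest so coefficients can be mapped back to natural units.
#'
#' @param values numeric vector with at least two distinct values.
#' @param scale divide by `scale` sample standard deviations (default 1;
#'   the pup-mass model standardises maternal age by 2 sd so that its
#'   quadratic age profile stays positive across the observed age span).
#' @return object of class `standardizer` with elements `mean` and `sd`.
#' @export
fit_standardizer <- function(values, scale = 1) {
  values <- values[!is.na(values)]
  if (length(unique(values)) < 2L) stop("need at least two distinct values")
  s <- stats::sd(values)
  if (s <= 0) stop("zero variance")
  structure(list(mean = mean(values), sd = scale * s),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param std a `standardizer`.
#' @param x numeric vector on the natural scale.
#' @export
std_transform <- function(std, x) (x - std$mean) / std$sd

#' @rdname fit_standardizer
#' @param z numeric vector on the standardised scale.
#' @export
std_inverse <- function(std, z) z * std$sd + std$mean

#' @export
print.standardizer <- function(x, ...) {
  cat("<standardizer> mean =", format(x$mean), ", sd =", format(x$sd), "\n")
  invisible(x)
}

# ---- female / pup tables ----------------------------------------------------

#' Read and write the female covariate table
#'
#' Columns: `female_id`, `cohort` (birth year), `weaning_length_cm`.
#' Weaning lengths outside the 90-132 cm study range trigger a warning, not
#' an error.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_female_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("female_id", "cohort", "weaning_length_cm")
  if (!all(need %in% names(df)))
    stop("female table needs columns: ", paste(need, collapse = ", "))
  if (anyDuplicated(df$female_id)) stop("duplicate female_id in female table")
  out_of_range <- df$weaning_length_cm < 90 | df$weaning_length_cm > 132
  if (any(out_of_range, na.rm = TRUE))
    warning(sum(out_of_range, na.rm = TRUE),
            " weaning length(s) outside the 90-132 cm study range")
  df$female_id <- as.character(df$female_id)
  df
}

#' @rdname read_female_table
#' @param females data frame as returned by [read_female_table()].
#' @export
write_female_table <- function(females, path) {
  write.csv(females, path, row.names = FALSE)
  invisible(path)
}

#' Read and write the pup table
#'
#' Columns: `female_id`, `year`, `pup_sex` (`"female"`/`"male"`),
#' `weaning_mass_kg` (> 0), `maternal_age_yr`.
#'
#' @param path CSV path.
#' @return data frame.
#' @export
read_pup_table <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("female_id", "year", "pup_sex", "weaning_mass_kg",
            "maternal_age_yr")
  if (!all(need %in% names(df)))
    stop("pup table needs columns: ", paste(need, collapse = ", "))
  if (!all(df$pup_sex %in% c("female", "male")))
    stop("pup_sex must be 'female' or 'male'")
  if (any(df$weaning_mass_kg <= 0))
    stop("weaning_mass_kg must be positive")
  df$female_id <- as.character(df$female_id)
  df
}

#' @rdname read_pup_table
#' @param pups data frame as returned by [read_pup_table()].
#' @export
write_pup_table <- function(pups, path) {
  write.csv(pups, path, row.names = FALSE)
  invisible(path)
}

# ---- run manifest -----------------------------------------------------------

#' Write / read a key-value run manifest
#'
#' The manifest records, as plain `key: value` text, everything needed to
#' reproduce a run: seed, filters applied, standardiser constants, file list.
#'
#' @param manifest named list of scalar values.
#' @param path output path.
#' @return `path` invisibly; `read_manifest()` returns a named character list.
#' @export
write_manifest <- function(manifest, path) {
  lines <- vapply(names(manifest), function(k)
    paste0(k, ": ", paste(format(manifest[[k]], digits = 15), collapse = ",")),
    character(1))
  writeLines(lines, path)
  invisible(path)
}

#' @rdname write_manifest
#' @export
read_manifest <- function(path) {
  lines <- readLines(path)
  lines <- lines[nzchar(lines)]
  kv <- regmatches(lines, regexpr(": ", lines), invert = TRUE)
  out <- lapply(kv, `[`, 2L)
  names(out) <- vapply(kv, `[`, character(1), 1L)
  out
}
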