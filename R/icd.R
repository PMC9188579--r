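#' Normalize ICD-10-CM codes to 3-character parental categories
#'
#' Diagnosis codes arrive in many dialects ("E11.9", "e119", " I10 ").
#' All sub-classifications of a disease are aggregated under the 3-character
#' parental category: whitespace is removed, everything from the first dot
#' onward is dropped, the code is upper-cased and truncated to its first
#' three characters. A code whose first three characters do not match
#' letter-digit-digit is rejected (category `NA`), never silently dropped:
#' the rejected raw strings are reported via a warning and kept in the
#' returned table.
#'
#' @param codes character vector of raw diagnosis code strings.
#' @param warn emit a warning summarising rejected codes (default `TRUE`).
#' @return A data.frame with one row per input code and columns `raw`,
#'   `category` (3-character parental code, `NA` when rejected),
#'   `chapter_letter` (first character of the category) and `ok` (logical).
#' @examples
#' normalize_icd10(c("E11.0", "I10", "11E"))
#' @export
normalize_icd10 <- function(codes, warn = TRUE) {
  raw <- as.character(codes)
  stripped <- gsub("[[:space:]]", "", raw)
  stripped <- sub("\\..*$", "", stripped)
  cat3 <- toupper(substr(stripped, 1L, 3L))
  ok <- !is.na(cat3) & grepl("^[A-Z][0-9][0-9]$", cat3)
  cat3[!ok] <- NA_character_
  if (warn && any(!ok)) {
    bad <- unique(raw[!ok])
    warning(sprintf("rejected %d malformed diagnosis code(s): %s",
                    sum(!ok), paste(utils::head(bad, 10L), collapse = ", ")),
            call. = FALSE)
  }
  data.frame(raw = raw,
             category = cat3,
             chapter_letter = substr(cat3, 1L, 1L),
             ok = ok,
             stringsAsFactors = FALSE)
}

#' Chapter filter for eligible disease categories
#'
#' Defines which 3-character parental categories count as (potentially
#' chronic) conditions for the multimorbidity analysis. Eligibility is a
#' set of inclusive category ranges minus an explicit blocklist. The
#' default covers the chapters for blood/blood-forming organ, endocrine/
#' metabolic, mental/behavioral, nervous-system, circulatory, respiratory,
#' digestive, musculoskeletal and genitourinary disease, and excludes E66
#' (obesity): because BMI is used to stratify the cohort, the obesity
#' diagnosis itself is not an outcome.
#'
#' @param include character vector of range strings, each `"E00-E89"` or a
#'   single category `"E66"`.
#' @param exclude character vector of categories dropped even when inside
#'   an included range.
#' @return An object of class `chapter_filter`.
#' @examples
#' f <- chapter_filter()
#' is_eligible(c("E11", "Z51", "E66"), f)
#' @export
chapter_filter <- function(include = c("D50-D89", "E00-E89", "F01-F99",
                                       "G00-G99", "I00-I99", "J00-J99",
                                       "K00-K95", "M00-M99", "N00-N99"),
                           exclude = "E66") {
  parse_one <- function(s) {
    s <- toupper(gsub("[[:space:]]", "", s))
    if (grepl("^[A-Z][0-9][0-9]$", s)) s <- paste0(s, "-", s)
    if (!grepl("^[A-Z][0-9][0-9]-[A-Z][0-9][0-9]$", s))
      stop("malformed range string: ", s, call. = FALSE)
    lo <- substr(s, 1L, 3L); hi <- substr(s, 5L, 7L)
    if (substr(lo, 1L, 1L) != substr(hi, 1L, 1L))
      stop("range must stay within one chapter letter: ", s, call. = FALSE)
    data.frame(letter = substr(lo, 1L, 1L),
               lo = as.integer(substr(lo, 2L, 3L)),
               hi = as.integer(substr(hi, 2L, 3L)),
               stringsAsFactors = FALSE)
  }
  ranges <- do.call(rbind, lapply(include, parse_one))
  if (any(ranges$lo > ranges$hi)) stop("range with low > high", call. = FALSE)
  # ranges within one letter must not overlap
  for (l in unique(ranges$letter)) {
    r <- ranges[ranges$letter == l, , drop = FALSE]
    r <- r[order(r$lo), , drop = FALSE]
    if (nrow(r) > 1L && any(r$lo[-1L] <= r$hi[-nrow(r)]))
      stop("overlapping ranges for chapter letter ", l, call. = FALSE)
  }
  exclude <- toupper(gsub("[[:space:]]", "", as.character(exclude)))
  if (length(exclude) && !all(grepl("^[A-Z][0-9][0-9]$", exclude)))
    stop("exclude entries must be 3-character categories", call. = FALSE)
  structure(list(ranges = ranges, exclude = exclude),
            class = "chapter_filter")
}

#' @export
print.chapter_filter <- function(x, ...) {
  rng <- sprintf("%s%02d-%s%02d", x$ranges$letter, x$ranges$lo,
                 x$ranges$letter, x$ranges$hi)
  cat("Chapter filter:", paste(rng, collapse = ", "), "\n")
  if (length(x$exclude)) cat("  excluding:", paste(x$exclude, collapse = ", "), "\n")
  invisible(x)
}

#' Category eligibility under a chapter filter
#'
#' @param category character vector of normalized 3-character categories.
#' @param filter a [chapter_filter()].
#' @return logical vector; `NA` input gives `NA`.
#' @export
is_eligible <- function(category, filter = chapter_filter()) {
  stopifnot(inherits(filter, "chapter_filter"))
  category <- toupper(as.character(category))
  valid <- !is.na(category) & grepl("^[A-Z][0-9][0-9]$", category)
  letter <- substr(category, 1L, 1L)
  num <- suppressWarnings(as.integer(substr(category, 2L, 3L)))
  inside <- rep(FALSE, length(category))
  for (i in seq_len(nrow(filter$ranges))) {
    r <- filter$ranges[i, ]
    inside <- inside | (valid & letter == r$letter & num >= r$lo & num <= r$hi)
  }
  out <- inside & !(category %in% filter$exclude)
  out[is.na(category)] <- NA
  out
}

#' Serialize / deserialize a chapter filter for run configs
#'
#' @param filter a [chapter_filter()].
#' @return `filter_to_config()`: a list with `include` and `exclude`
#'   character vectors (YAML/JSON friendly); `filter_from_config()` is its
#'   inverse.
#' @export
filter_to_config <- function(filter) {
  stopifnot(inherits(filter, "chapter_filter"))
  list(include = sprintf("%s%02d-%s%02d", filter$ranges$letter,
                         filter$ranges$lo, filter$ranges$letter,
                         filter$ranges$hi),
       exclude = filter$exclude)
}

#' @rdname filter_to_config
#' @param config list with `include` and `exclude` entries.
#' @export
filter_from_config <- function(config) {
  chapter_filter(include = unlist(config$include),
                 exclude = unlist(config$exclude %||% character(0)))
}
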