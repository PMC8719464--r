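#' @useDynLib perceptcad, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @importFrom stats pf rbinom runif rnorm sd var aggregate t.test quantile setNames
#' @importFrom utils read.csv write.csv modifyList
NULL

# Cached controlled vocabulary (inst/extdata/birads_vocabulary.json)
.codec_env <- new.env(parent = emptyenv())

#' BI-RADS mass-description vocabulary and numeric codes
#'
#' Returns the controlled vocabulary used to quantify mass descriptions.
#' Findings associated with malignancy are coded 1, uncertain findings 0.5
#' and benign findings 0; "low" and "fat-containing" density share code 0.
#'
#' @return A list with elements `version`, `fields` (the fixed descriptor
#'   ordering: shape, margin sharpness, microlobulated margins, spiculated
#'   margins, density) and `codes` (named numeric vectors term -> code).
#' @export
birads_vocabulary <- function() {
  if (is.null(.codec_env$vocab)) {
    path <- system.file("extdata", "birads_vocabulary.json",
                        package = "perceptcad", mustWork = TRUE)
    raw <- jsonlite::fromJSON(path)
    raw$codes <- lapply(raw$codes, function(x) unlist(x))
    .codec_env$vocab <- raw
  }
  .codec_env$vocab
}

#' Construct a set of BI-RADS description terms
#'
#' @param shape One of "oval", "round", "irregular".
#' @param margin_sharpness One of "circumscribed", "obscured", "indistinct".
#' @param microlobulated,spiculated Logical flags (or "yes"/"no").
#' @param density One of "low", "fat-containing", "equal", "high".
#' @return An object of class `description_terms`.
#' @examples
#' description_terms("irregular", "obscured", TRUE, FALSE, "high")
#' @export
description_terms <- function(shape, margin_sharpness, microlobulated,
                              spiculated, density) {
  as_flag <- function(x, field) {
    if (is.logical(x)) return(x)
    x <- tolower(trimws(as.character(x)))
    if (x %in% c("yes", "no")) return(x == "yes")
    stop(sprintf("unknown term '%s' for field '%s' (expected yes/no)", x, field),
         call. = FALSE)
  }
  terms <- structure(
    list(shape = tolower(trimws(shape)),
         margin_sharpness = tolower(trimws(margin_sharpness)),
         microlobulated = as_flag(microlobulated, "microlobulated"),
         spiculated = as_flag(spiculated, "spiculated"),
         density = tolower(trimws(density))),
    class = "description_terms")
  validate_terms(terms)
  terms
}

validate_terms <- function(terms) {
  voc <- birads_vocabulary()$codes
  for (field in c("shape", "margin_sharpness", "density")) {
    if (!terms[[field]] %in% names(voc[[field]]))
      stop(sprintf("unknown term '%s' for field '%s' (allowed: %s)",
                   terms[[field]], field,
                   paste(names(voc[[field]]), collapse = ", ")),
           call. = FALSE)
  }
  invisible(terms)
}

#' Quantify BI-RADS description terms into a five-dimensional code vector
#'
#' Maps the controlled-vocabulary mass description to numeric codes in
#' \{0, 0.5, 1\}: oval/round -> 0, irregular -> 1; circumscribed -> 0,
#' obscured -> 0.5, indistinct -> 1; microlobulated and spiculated margins
#' no -> 0 / yes -> 1; low or fat-containing density -> 0, equal -> 0.5,
#' high -> 1. The vector ordering is fixed as
#' [shape, margin sharpness, microlobulated, spiculated, density].
#'
#' @param terms A `description_terms` object (or a list with the same
#'   fields).
#' @return A named numeric vector of class `descriptor_vector`, length 5.
#' @examples
#' quantify(description_terms("irregular", "obscured", TRUE, FALSE, "high"))
#' # [1, 0.5, 1, 0, 1]
#' @export
quantify <- function(terms) {
  if (!inherits(terms, "description_terms"))
    terms <- description_terms(terms$shape, terms$margin_sharpness,
                               terms$microlobulated, terms$spiculated,
                               terms$density)
  voc <- birads_vocabulary()$codes
  v <- c(shape_code = unname(voc$shape[[terms$shape]]),
         margin_sharpness_code = unname(voc$margin_sharpness[[terms$margin_sharpness]]),
         microlobulated_code = if (terms$microlobulated) 1 else 0,
         spiculated_code = if (terms$spiculated) 1 else 0,
         density_code = unname(voc$density[[terms$density]]))
  descriptor_vector(v)
}

#' Construct/validate a descriptor code vector
#'
#' @param x Numeric vector of length 5 in the fixed ordering
#'   [shape, margin sharpness, microlobulated, spiculated, density].
#' @return Named numeric vector of class `descriptor_vector`.
#' @export
descriptor_vector <- function(x) {
  x <- as.numeric(x)
  if (length(x) != 5L)
    stop("descriptor vector must have length 5", call. = FALSE)
  if (!all(x %in% c(0, 0.5, 1)))
    stop("descriptor codes must be in {0, 0.5, 1}", call. = FALSE)
  if (!x[1] %in% c(0, 1) || !x[3] %in% c(0, 1) || !x[4] %in% c(0, 1))
    stop("shape, microlobulated and spiculated codes must be in {0, 1}",
         call. = FALSE)
  names(x) <- c("shape_code", "margin_sharpness_code", "microlobulated_code",
                "spiculated_code", "density_code")
  class(x) <- c("descriptor_vector", "numeric")
  x
}

#' @export
print.descriptor_vector <- function(x, ...) {
  cat("<descriptor_vector> [", paste(unclass(x), collapse = ", "), "]\n")
  invisible(x)
}

#' Parse a structured report phrase into description terms
#'
#' Keyword spotting over the controlled vocabulary: the text must mention
#' exactly one shape term, one margin-sharpness term and one density term;
#' microlobulation and spiculation default to absent when unmentioned.
#' This is deliberately not free-text NLP — report phrases are structured
#' lexicon sentences such as "An irregular mass with obscured and
#' microlobulated margins and high density".
#'
#' @param text Character scalar.
#' @return A `description_terms` object.
#' @export
parse_report_line <- function(text) {
  stopifnot(is.character(text), length(text) == 1L)
  low <- tolower(text)
  voc <- birads_vocabulary()$codes
  find_one <- function(field, terms) {
    # word-boundary keyword match; "fat-containing" needs the hyphen kept
    hits <- terms[vapply(terms, function(tt)
      grepl(paste0("\\b", gsub("-", "[- ]", tt), "\\b"), low), logical(1))]
    if (length(hits) == 0L)
      stop(sprintf("parse error: no %s term found in report line", field),
           call. = FALSE)
    if (length(hits) > 1L)
      stop(sprintf("ambiguity error: conflicting %s terms (%s)", field,
                   paste(hits, collapse = ", ")), call. = FALSE)
    hits
  }
  shape <- find_one("shape", names(voc$shape))
  margin <- find_one("margin sharpness", names(voc$margin_sharpness))
  # density phrasing: "high density", "equal density", "low density",
  # "fat-containing"; match the density word, not the bare word "density"
  density <- find_one("density", names(voc$density))
  description_terms(
    shape = shape,
    margin_sharpness = margin,
    microlobulated = grepl("\\bmicrolobulated\\b", low),
    spiculated = grepl("\\bspiculated\\b", low),
    density = density)
}

#' Render description terms as a structured report phrase
#'
#' Inverse templater for [parse_report_line()]; used to round-trip
#' vocabulary terms through text.
#'
#' @param terms A `description_terms` object.
#' @return Character scalar report line.
#' @export
render_report_line <- function(terms) {
  validate_terms(terms)
  extras <- c(if (terms$microlobulated) "microlobulated",
              if (terms$spiculated) "spiculated")
  margin <- paste(c(terms$margin_sharpness, extras), collapse = " and ")
  sprintf("A%s %s mass with %s margins and %s density",
          if (grepl("^[aeiou]", terms$shape)) "n" else "",
          terms$shape, margin, terms$density)
}
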