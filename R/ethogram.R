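#' Read an ethogram from YAML or JSON
#'
#' An ethogram maps every behaviour code that may occur in an interaction
#' table to exactly one behavioural category: `"agonistic"` (conflict
#' behaviours such as pecking, jabbing, feather pulling, chasing or
#' displacement, which carry a winner/loser or draw outcome),
#' `"affiliative"` (socially positive behaviours such as allopreening,
#' collaborative foraging or sitting close), or `"ambiguous"` (behaviours
#' with no clear affiliative or antagonistic intention, which are flagged
#' and excluded from all downstream analyses).
#'
#' Accepted file layouts: either `code: category` pairs, or
#' `code: {category: ..., description: ...}`.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return A named character vector mapping behaviour code to category,
#'   with descriptions (when present) in the `"descriptions"` attribute.
#' @export
read_ethogram <- function(path) {
  stopifnot(file.exists(path))
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = FALSE)
  } else {
    yaml::read_yaml(path)
  }
  as_ethogram(raw)
}

#' Coerce a named list to an ethogram
#'
#' @param x Named list: `code = "category"` or
#'   `code = list(category = ..., description = ...)`.
#' @return Named character vector of categories (see [read_ethogram()]).
#' @export
as_ethogram <- function(x) {
  if (is.character(x) && !is.null(names(x))) x <- as.list(x)
  stopifnot(is.list(x), !is.null(names(x)), all(nzchar(names(x))))
  cats <- vapply(x, function(v) {
    if (is.list(v)) as.character(v$category) else as.character(v)
  }, character(1))
  desc <- vapply(x, function(v) {
    if (is.list(v) && !is.null(v$description)) as.character(v$description) else NA_character_
  }, character(1))
  bad <- setdiff(unique(cats), c("agonistic", "affiliative", "ambiguous"))
  if (length(bad) > 0) {
    stop("invalid ethogram category: ", paste(bad, collapse = ", "),
         " (must be agonistic, affiliative or ambiguous)")
  }
  if (anyDuplicated(names(cats))) {
    stop("duplicated behaviour code in ethogram: ",
         paste(unique(names(cats)[duplicated(names(cats))]), collapse = ", "))
  }
  structure(cats, descriptions = desc, class = "ethogram")
}

#' Default crow ethogram
#'
#' The behaviour codes used by the bundled simulator, following the field
#' convention for captive corvid groups: aggressive acts and displacements
#' are agonistic; allopreening, joint foraging/exploration and proximity
#' seeking are affiliative; a plain approach is ambiguous.
#'
#' @return An `ethogram` object.
#' @export
default_ethogram <- function() {
  as_ethogram(list(
    peck         = list(category = "agonistic",   description = "pecks the recipient"),
    jab          = list(category = "agonistic",   description = "jabs with the bill"),
    feather_pull = list(category = "agonistic",   description = "pulls the recipient's feathers"),
    chase        = list(category = "agonistic",   description = "chases the recipient"),
    displace     = list(category = "agonistic",   description = "approach causing the recipient to retreat"),
    allopreen    = list(category = "affiliative", description = "preens the recipient"),
    co_forage    = list(category = "affiliative", description = "forages jointly with the recipient"),
    co_explore   = list(category = "affiliative", description = "explores an object jointly"),
    sit_close    = list(category = "affiliative", description = "sits in close proximity"),
    approach     = list(category = "ambiguous",   description = "approach without clear intention")
  ))
}

#' @export
print.ethogram <- function(x, ...) {
  cat("Ethogram:", length(x), "behaviour codes\n")
  for (cat_ in c("agonistic", "affiliative", "ambiguous")) {
    codes <- names(x)[x == cat_]
    if (length(codes)) cat(sprintf("  %-11s %s\n", cat_, paste(codes, collapse = ", ")))
  }
  invisible(x)
}
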