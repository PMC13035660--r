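#' @details
#' The coding framework groups behavioral codes into three categories:
#' Cognition (verbalized reasoning about the case), Emotion (affective
#' expressions) and 3D Interaction (actions on the virtual model). Each code
#' carries a unique positive integer id; id 0 is reserved for the "no code"
#' label inserted during windowed alignment and may never appear in a
#' codebook.
#' @keywords internal
"_PACKAGE"

#' @importFrom stats median quantile rexp rnorm rpois runif var setNames
#' @importFrom utils read.csv write.csv
NULL

CODE_CATEGORIES <- c("Cognition", "Emotion", "3D Interaction")

#' Construct a codebook
#'
#' A codebook is the coding framework applied by every coder: one row per
#' code with a unique positive integer `id`, a unique short `name`, a
#' `category` (one of `"Cognition"`, `"Emotion"`, `"3D Interaction"`) and a
#' free-text `definition`.
#'
#' @param id integer vector of unique code ids (all > 0; 0 is reserved for
#'   the "no code" label inserted during alignment).
#' @param name character vector of unique code names.
#' @param category character vector of categories; each must be exactly one
#'   of `"Cognition"`, `"Emotion"`, `"3D Interaction"`.
#' @param definition character vector of code definitions (optional;
#'   defaults to empty strings).
#' @param version codebook version string.
#' @return An object of class `codebook`: a data.frame with columns
#'   `id`, `name`, `category`, `definition` and a `version` attribute.
#' @examples
#' cb <- codebook(id = 1:2, name = c("Anatomy", "Excitement"),
#'                category = c("Cognition", "Emotion"))
#' @export
codebook <- function(id, name, category, definition = NULL, version = "1") {
  id <- as.integer(id)
  name <- as.character(name)
  category <- as.character(category)
  if (is.null(definition)) definition <- rep("", length(id))
  df <- data.frame(id = id, name = name, category = category,
                   definition = as.character(definition),
                   stringsAsFactors = FALSE)
  validate_codebook(df)
  attr(df, "version") <- as.character(version)
  class(df) <- c("codebook", "data.frame")
  df
}

validate_codebook <- function(df) {
  if (nrow(df) == 0L) stop("codebook must contain at least one code")
  if (anyNA(df$id)) stop("codebook ids must be integers")
  if (any(df$id == 0L)) stop("code id 0 reserved for the 'no code' label")
  if (any(df$id < 0L)) stop("code ids must be positive")
  dup <- df$id[duplicated(df$id)]
  if (length(dup)) stop("duplicate code id: ", dup[1L])
  dupn <- df$name[duplicated(df$name)]
  if (length(dupn)) stop("duplicate code name: '", dupn[1L], "'")
  bad <- setdiff(unique(df$category), CODE_CATEGORIES)
  if (length(bad)) {
    stop("unknown category '", bad[1L], "'; must be one of: ",
         paste(CODE_CATEGORIES, collapse = ", "))
  }
  invisible(df)
}

#' Read a codebook from a CSV or YAML file
#'
#' CSV files must have the header `id,name,category,definition`; YAML files
#' must be a mapping with a `codes` list of `{id, name, category,
#' definition}` entries and an optional `version`. Categories are spelled
#' exactly `"Cognition"`, `"Emotion"`, `"3D Interaction"`.
#'
#' @param path path to the codebook file; format chosen by extension
#'   (`.yml`/`.yaml` for YAML, anything else parsed as CSV).
#' @return A [codebook] object.
#' @export
load_codebook <- function(path) {
  if (!file.exists(path)) stop("codebook file not found: ", path)
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    y <- yaml::read_yaml(path)
    codes <- y$codes
    if (is.null(codes)) stop("YAML codebook must contain a 'codes' list")
    df <- do.call(rbind, lapply(seq_along(codes), function(i) {
      cd <- codes[[i]]
      if (is.null(cd$id) || is.null(cd$name) || is.null(cd$category)) {
        stop("codebook entry ", i, ": needs id, name and category")
      }
      data.frame(id = as.integer(cd$id), name = as.character(cd$name),
                 category = as.character(cd$category),
                 definition = as.character(cd$definition %||% ""),
                 stringsAsFactors = FALSE)
    }))
    version <- as.character(y$version %||% "1")
  } else {
    df <- read.csv(path, stringsAsFactors = FALSE, colClasses = "character")
    need <- c("id", "name", "category")
    miss <- setdiff(need, names(df))
    if (length(miss)) stop("codebook CSV missing column(s): ",
                           paste(miss, collapse = ", "))
    if (is.null(df$definition)) df$definition <- ""
    idn <- suppressWarnings(as.integer(df$id))
    bad <- which(is.na(idn))
    if (length(bad)) stop("codebook row ", bad[1L], ": id '", df$id[bad[1L]],
                          "' is not an integer")
    df$id <- idn
    version <- "1"
  }
  codebook(df$id, df$name, df$category, df$definition, version = version)
}

#' Write a codebook to CSV
#'
#' The written file round-trips through [load_codebook()] field for field.
#'
#' @param cb a [codebook].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_codebook <- function(cb, path) {
  stopifnot(inherits(cb, "codebook"))
  write.csv(as.data.frame(cb)[, c("id", "name", "category", "definition")],
            path, row.names = FALSE, quote = TRUE)
  invisible(path)
}

#' The bundled default coding framework
#'
#' Twelve behavioral codes spanning the three categories: six Cognition
#' codes (Anatomy, Planning, Mental Model, Confirmation, Uncertainty, Path
#' Finding), three Emotion codes (Excitement, Frustration, Confidence) and
#' three 3D Interaction codes (3D Manipulation, Tool Usage, Orienting).
#' Analyses accept any user-supplied codebook; this default exists so the
#' synthetic generator and examples run out of the box.
#'
#' @return A [codebook] with 12 codes.
#' @export
default_codebook <- function() {
  codebook(
    id = 1:12,
    name = c("Anatomy", "Planning", "Mental Model", "Confirmation",
             "Uncertainty", "Path Finding",
             "Excitement", "Frustration", "Confidence",
             "3D Manipulation", "Tool Usage", "Orienting"),
    category = c(rep("Cognition", 6), rep("Emotion", 3),
                 rep("3D Interaction", 3)),
    definition = c(
      "Discussion of the patient anatomy and its structures",
      "Discussion of the surgical plan or approach",
      "Statements about the internal visual representation of the case",
      "Verifying an anatomical structure or prior impression",
      "Expressing doubt or an open question about the case",
      "Verbalized intent to trace a path between anatomical features",
      "Enthusiastic or positive exclamation",
      "Expression of annoyance, usually with the tool",
      "Statement of confidence in the case or plan",
      "Slicing, scaling or rotating the 3D model",
      "Use of a tool in the 3D environment",
      "Moving or turning to change viewpoint"),
    version = "default-12"
  )
}

#' Map between code ids and code names
#'
#' @param cb a [codebook].
#' @param id integer code ids to resolve to names.
#' @param name character code names to resolve to ids.
#' @return `code_name()` a character vector, `code_id()` an integer vector;
#'   unresolvable values are an error.
#' @export
code_name <- function(cb, id) {
  i <- match(as.integer(id), cb$id)
  if (anyNA(i)) stop("unknown code id: ", id[which(is.na(i))[1L]])
  cb$name[i]
}

#' @rdname code_name
#' @export
code_id <- function(cb, name) {
  i <- match(as.character(name), cb$name)
  if (anyNA(i)) stop("unknown code name: '", name[which(is.na(i))[1L]], "'")
  cb$id[i]
}

#' @export
as.data.frame.codebook <- function(x, ...) {
  data.frame(id = x$id, name = x$name, category = x$category,
             definition = x$definition, stringsAsFactors = FALSE)
}

#' @export
print.codebook <- function(x, ...) {
  cat("<codebook> ", nrow(x), " codes, version ", attr(x, "version"),
      "\n", sep = "")
  for (cat_ in CODE_CATEGORIES) {
    nm <- x$name[x$category == cat_]
    if (length(nm)) cat("  ", cat_, ": ", paste(nm, collapse = ", "),
                        "\n", sep = "")
  }
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
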