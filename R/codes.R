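#' Normalize a clinical code string
#'
#' Danish registry extracts write ICD-10 and NCSP codes in several dialects
#' (`"DT84.0A"`, `"dt840a"`, `" KNFH20 "`). All package functions operate on
#' the canonical form: uppercase with dots and whitespace removed, e.g.
#' `"DT840A"`. Normalization is idempotent.
#'
#' @param x character vector of raw code strings; elements must be non-empty
#'   after trimming.
#' @return character vector of normalized codes.
#' @examples
#' normalize_code(c("dt84.0a", " ds73.0 ", "KNFH20"))
#' @export
normalize_code <- function(x) {
  if (!is.character(x)) stop("codes must be character", call. = FALSE)
  out <- toupper(gsub("[.[:space:]]", "", x))
  if (any(is.na(out) | out == "")) {
    stop("empty code string after normalization", call. = FALSE)
  }
  out
}

#' Prefix matching for diagnosis and procedure codes
#'
#' A code matches a prefix when it equals the prefix or extends it by a
#' suffix, so the subcode `DT840A` matches the parent `DT840`. Both arguments
#' must already be normalized (see [normalize_code()]).
#'
#' @param code,prefix normalized code strings (vectorized, recycled).
#' @return logical vector.
#' @examples
#' code_matches("DT840A", "DT840")  # TRUE
#' code_matches("DT841", "DT840")   # FALSE
#' @export
code_matches <- function(code, prefix) {
  substr(code, 1L, nchar(prefix)) == prefix
}

# TRUE for each element of `codes` that matches any prefix in `prefixes`
match_any_prefix <- function(codes, prefixes) {
  hit <- rep(FALSE, length(codes))
  for (p in prefixes) hit <- hit | code_matches(codes, p)
  hit
}

#' Define the algorithm's code sets
#'
#' The stepwise algorithm is driven by four disjoint sets of code prefixes:
#' the correct dislocation diagnosis (`DT840`, subcodes included by prefix
#' matching), the correct closed-reduction procedure for a prosthetic hip
#' (`KNFH20`), the alternative diagnosis used for traumatic dislocation of a
#' native hip (`DS730`), and alternative reduction/arthrotomy procedures
#' (`KNFH00`, `KNFH02`, `KNFH21`, `KNFH22`). The defaults are the published
#' group definitions; all four sets are configurable.
#'
#' @param correct_dx,correct_proc,alt_dx,alt_proc character vectors of code
#'   prefixes (normalized on input).
#' @return an object of class `code_set` (a named list of the four sets).
#' @examples
#' cs <- code_set()
#' cs$correct_dx
#' @export
code_set <- function(correct_dx = "DT840",
                     correct_proc = "KNFH20",
                     alt_dx = "DS730",
                     alt_proc = c("KNFH00", "KNFH02", "KNFH21", "KNFH22")) {
  cs <- list(
    correct_dx = normalize_code(correct_dx),
    correct_proc = normalize_code(correct_proc),
    alt_dx = normalize_code(alt_dx),
    alt_proc = normalize_code(alt_proc)
  )
  all <- unlist(cs, use.names = FALSE)
  if (anyDuplicated(all)) {
    stop("code_set: the four code sets must be pairwise disjoint", call. = FALSE)
  }
  structure(cs, class = "code_set")
}

#' @export
print.code_set <- function(x, ...) {
  cat("<code_set>\n")
  for (nm in names(x)) cat(" ", nm, ":", paste(x[[nm]], collapse = " "), "\n")
  invisible(x)
}

#' Read or write a code-set configuration file
#'
#' The file is YAML or JSON (chosen by extension) with the four keys
#' `correct_dx`, `correct_proc`, `alt_dx`, `alt_proc`.
#'
#' @param path file path ending in `.yaml`, `.yml` or `.json`.
#' @return [read_code_set()] returns a `code_set`; [write_code_set()]
#'   returns `path` invisibly.
#' @export
read_code_set <- function(path) {
  raw <- if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
  keys <- c("correct_dx", "correct_proc", "alt_dx", "alt_proc")
  missing <- setdiff(keys, names(raw))
  if (length(missing)) {
    stop("code-set file missing keys: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  do.call(code_set, lapply(raw[keys], unlist))
}

#' @rdname read_code_set
#' @param codes a `code_set`.
#' @export
write_code_set <- function(codes, path) {
  stopifnot(inherits(codes, "code_set"))
  if (grepl("\\.ya?ml$", path, ignore.case = TRUE)) {
    yaml::write_yaml(lapply(unclass(codes), as.list), path)
  } else {
    jsonlite::write_json(unclass(codes), path, auto_unbox = FALSE,
                         pretty = TRUE)
  }
  invisible(path)
}
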