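#' Data-type codebook
#'
#' The registry of 4-nt oligonucleotides standing for common data types
#' (drawn from the XML Schema datatype vocabulary). These 4-mers are inserted
#' verbatim (not degenerately) between the name and value segments of a
#' vertex oligo, so they are matched byte-exactly at decode time.
#'
#' @return A tibble with columns `name` and `oligo` (nine rows by default).
#' @examples
#' dna_type_codes()
#' @export
dna_type_codes <- function() {
  tibble::tibble(
    name  = c("string", "boolean", "float", "dateTime", "duration",
              "URI", "RName", "integer", "undefined"),
    oligo = c("TCGA", "CTGA", "GTCA", "AGTC", "TAGC",
              "ACGT", "GCTA", "CATG", "TGCA")
  )
}

#' Unit codebook
#'
#' Registry of 4-nt oligonucleotides for measurement units. Only two codes
#' are predefined (`undefined` -> TGCA and `%` -> GCAT); further units are
#' added with [register_code()]. A code may coincide with a type code (TGCA
#' serves both `undefined` entries) but must be unique within the registry.
#'
#' @return A tibble with columns `name` and `oligo`.
#' @export
dna_unit_codes <- function() {
  tibble::tibble(
    name  = c("undefined", "%"),
    oligo = c("TGCA", "GCAT")
  )
}

#' Add an entry to a codebook
#'
#' @param codes A codebook tibble (`name`, `oligo`).
#' @param name New entry name.
#' @param oligo A 4-nt DNA string; must not collide with an existing oligo
#'   or name in this registry.
#' @return The extended codebook tibble.
#' @examples
#' register_code(dna_unit_codes(), "meter", "AATT")
#' @export
register_code <- function(codes, name, oligo) {
  check_codebook(codes)
  dna_ints(oligo, "code oligo")
  if (nchar(oligo) != 4L) stop("code oligos are 4 nt", call. = FALSE)
  oligo <- toupper(oligo)
  if (name %in% codes$name) {
    stop("name '", name, "' already registered", call. = FALSE)
  }
  if (oligo %in% toupper(codes$oligo)) {
    stop("oligo ", oligo, " already registered in this codebook", call. = FALSE)
  }
  dplyr::bind_rows(codes, tibble::tibble(name = name, oligo = oligo))
}

check_codebook <- function(codes) {
  stopifnot(is.data.frame(codes), all(c("name", "oligo") %in% names(codes)))
  if (anyDuplicated(toupper(codes$oligo)) || anyDuplicated(codes$name)) {
    stop("codebook entries must be pairwise distinct", call. = FALSE)
  }
  invisible(codes)
}

lookup_code <- function(codes, name, what) {
  i <- match(name, codes$name)
  if (is.na(i)) {
    stop("unregistered ", what, " '", name, "'", call. = FALSE)
  }
  toupper(codes$oligo[[i]])
}

#' Write / read a codebook as YAML
#'
#' @param codes A codebook tibble.
#' @param path File path.
#' @return `read_codebook()` returns the codebook tibble; `write_codebook()`
#'   returns `path` invisibly.
#' @export
write_codebook <- function(codes, path) {
  check_codebook(codes)
  yaml::write_yaml(stats::setNames(as.list(codes$oligo), codes$name), path)
  invisible(path)
}

#' @rdname write_codebook
#' @export
read_codebook <- function(path) {
  x <- yaml::read_yaml(path)
  cb <- tibble::tibble(name = names(x), oligo = toupper(unname(unlist(x))))
  check_codebook(cb)
  cb
}

#' The 8-mer marking an unannotated (null) property value
#'
#' An unannotated property carries data type `undefined` and unit `undefined`,
#' so its type+unit segment is TGCA followed by TGCA. Strands containing this
#' marker are rejected in the final screening step of the fusion pipeline.
#'
#' @return The string `"TGCATGCA"`.
#' @export
null_marker <- function() "TGCATGCA"
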