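#' Encode a property vertex as an oligonucleotide
#'
#' A vertex `(property name, value, data type, unit)` becomes a single-stranded
#' oligo laid out as `V = N T U A`: the name, left-padded and bit-encoded
#' (8 nt per character); the 4-nt type code; the 4-nt unit code; and the
#' padded, bit-encoded value. With the default field widths (3-character
#' names, 2-character values) every vertex oligo is
#' `8*3 + 4 + 4 + 8*2 = 48` nt. Names are left-padded with spaces;
#' values are left-padded with `"0"` for integer-typed values and with
#' spaces otherwise. An unannotated (null) value encodes as pad characters
#' under `undefined` type and unit, placing the [null_marker()] at the
#' type/unit position.
#'
#' @param name Property name, at most `name_width` ASCII characters.
#' @param value Property value, at most `value_width` ASCII characters, or
#'   `NA` for an unannotated property (which forces `dtype` and `unit`
#'   to `"undefined"`; anything else is an error).
#' @param dtype Data type name, registered in `type_codes`.
#' @param unit Unit name, registered in `unit_codes`.
#' @param seed Optional integer seed for the degenerate base choices.
#' @param name_width,value_width Field widths in characters; segment lengths
#'   scale as 8 nt per character, so the total length is
#'   `8 * name_width + 8 + 8 * value_width`.
#' @param type_codes,unit_codes Codebook tibbles (see [dna_type_codes()]).
#' @return A DNA string of length `8 * (name_width + value_width + 1)`.
#' @examples
#' encode_vertex("cty", "GZ", "string", "undefined", seed = 1)
#' @export
encode_vertex <- function(name, value, dtype = "string", unit = "undefined",
                          seed = NULL, name_width = 3L, value_width = 2L,
                          type_codes = dna_type_codes(),
                          unit_codes = dna_unit_codes()) {
  if (!is.character(name) || length(name) != 1L || is.na(name) || !nzchar(name)) {
    stop("vertex name must be a non-empty string", call. = FALSE)
  }
  is_null <- is.null(value) || (length(value) == 1L && is.na(value))
  if (is_null) {
    if (!identical(dtype, "undefined") || !identical(unit, "undefined")) {
      stop("a null value requires dtype and unit 'undefined'", call. = FALSE)
    }
    value <- ""
  }
  value <- as.character(value)
  if (nchar(name) > name_width) {
    stop("name '", name, "' exceeds the ", name_width, "-character field",
         call. = FALSE)
  }
  if (nchar(value) > value_width) {
    stop("value '", value, "' exceeds the ", value_width, "-character field",
         call. = FALSE)
  }
  t_code <- lookup_code(type_codes, dtype, "data type")
  u_code <- lookup_code(unit_codes, unit, "unit")
  pad <- if (identical(dtype, "integer")) "0" else " "
  n_txt <- pad_left(name, name_width, " ")
  a_txt <- pad_left(value, value_width, pad)
  payload <- bits_to_bases(text_to_bits(paste0(n_txt, a_txt)), seed = seed)
  n_nt <- 8L * name_width
  paste0(substr(payload, 1L, n_nt), t_code, u_code,
         substr(payload, n_nt + 1L, nchar(payload)))
}

pad_left <- function(x, width, pad) {
  if (nchar(x) >= width) return(x)
  paste0(strrep(pad, width - nchar(x)), x)
}

#' Encode a Start/End terminal oligo
#'
#' Terminal vertices close the property network at both ends. They carry no
#' type or unit segment: the labels `start` and `end` are space-padded to the
#' full field width (`name_width + value_width + 1` characters, 6 by default)
#' and bit-encoded across the whole oligo, giving the same total length as a
#' property vertex.
#'
#' @param label `"start"` or `"end"`.
#' @inheritParams encode_vertex
#' @return A DNA string of the standard vertex length.
#' @export
encode_terminal <- function(label, seed = NULL,
                            name_width = 3L, value_width = 2L) {
  label <- match.arg(label, c("start", "end"))
  txt <- pad_left(label, name_width + value_width + 1L, " ")
  bits_to_bases(text_to_bits(txt), seed = seed)
}

#' Decode a vertex oligo back to its property record
#'
#' Recognises terminal oligos (the whole sequence decodes to the padded
#' `start`/`end` label) and property vertices (the type/unit 4-mers at the
#' centre match registered codes). Padding is stripped: leading spaces from
#' names and string-like values, leading zeros from integer values (a value
#' of all zeros decodes to `"0"`). A type/unit segment equal to
#' [null_marker()] is reported as a null value (`value = NA`).
#'
#' @param seq A DNA string of the standard vertex length.
#' @inheritParams encode_vertex
#' @return A one-row tibble with columns `kind` (`"terminal"` or `"vertex"`),
#'   `property`, `value`, `dtype`, `unit`.
#' @examples
#' decode_vertex(encode_vertex("cty", "GZ", seed = 1))
#' @export
decode_vertex <- function(seq, name_width = 3L, value_width = 2L,
                          type_codes = dna_type_codes(),
                          unit_codes = dna_unit_codes()) {
  len <- vertex_length(name_width, value_width)
  if (nchar(seq) != len) {
    stop("expected a ", len, "-nt vertex oligo, got ", nchar(seq), " nt",
         call. = FALSE)
  }
  term <- terminal_label(seq)
  if (!is.na(term)) {
    return(tibble::tibble(kind = "terminal", property = term,
                          value = NA_character_, dtype = NA_character_,
                          unit = NA_character_))
  }
  n_nt <- 8L * name_width
  tu <- toupper(substr(seq, n_nt + 1L, n_nt + 8L))
  t_i <- match(substr(tu, 1L, 4L), toupper(type_codes$oligo))
  u_i <- match(substr(tu, 5L, 8L), toupper(unit_codes$oligo))
  if (is.na(t_i) || is.na(u_i)) {
    stop("central 8-mer ", tu, " matches no registered type/unit codes ",
         "and the sequence is not a terminal", call. = FALSE)
  }
  dtype <- type_codes$name[[t_i]]
  unit <- unit_codes$name[[u_i]]
  name <- sub("^ +", "", bits_to_text(bases_to_bits(substr(seq, 1L, n_nt))))
  a_txt <- bits_to_text(bases_to_bits(substr(seq, n_nt + 9L, len)))
  if (identical(tu, null_marker())) {
    value <- NA_character_
  } else if (identical(dtype, "integer")) {
    value <- sub("^0+(?=.)", "", a_txt, perl = TRUE)
  } else {
    value <- sub("^ +", "", a_txt)
  }
  tibble::tibble(kind = "vertex", property = name, value = value,
                 dtype = dtype, unit = unit)
}

# padded terminal label if the whole oligo decodes to one, else NA
terminal_label <- function(seq) {
  txt <- tryCatch(bits_to_text(bases_to_bits(seq)), error = function(e) NA)
  if (is.na(txt)) return(NA_character_)
  trimmed <- sub("^ +", "", txt)
  if (trimmed %in% c("start", "end")) trimmed else NA_character_
}

vertex_length <- function(name_width = 3L, value_width = 2L) {
  8L * (name_width + value_width + 1L)
}

#' Encode the edge oligo joining two vertex oligos
#'
#' An edge from vertex i to vertex j is the position-wise Watson-Crick
#' complement of the second half of `V_i` followed by the first half of
#' `V_j`. During ligation this edge oligo hybridises across the junction of
#' the two vertex oligos and splints them together. The complemented type/unit
#' 8-mer (when vertex i is not a terminal) is presented uppercase.
#'
#' @param vi,vj Vertex oligo DNA strings of equal, even length.
#' @inheritParams encode_vertex
#' @return A DNA string of the same length as the inputs.
#' @examples
#' vi <- encode_vertex("cty", "GZ", seed = 1)
#' vj <- encode_vertex("qa", "E", seed = 2)
#' encode_edge(vi, vj)
#' @export
encode_edge <- function(vi, vj, name_width = 3L, value_width = 2L) {
  len <- vertex_length(name_width, value_width)
  if (nchar(vi) != len || nchar(vj) != len) {
    stop("edge construction needs two ", len, "-nt vertex oligos",
         call. = FALSE)
  }
  half <- len %/% 2L
  e <- dna_complement(paste0(substr(vi, half + 1L, len), substr(vj, 1L, half)))
  # the from-vertex's type/unit codes open the second half V'' = T U A';
  # their complement is shown uppercase like the codes themselves
  if (is.na(terminal_label(vi)) && 8L * name_width >= half) {
    off <- 8L * name_width - half  # position of T.U within V''
    substr(e, off + 1L, off + 8L) <- toupper(substr(e, off + 1L, off + 8L))
  }
  e
}
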