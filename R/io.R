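#' Read and write annotation files
#'
#' The canonical, losslessly round-trippable formats are TSV (columns
#' `source_id`, `property`, `value`, `dtype`, `unit`; empty `value` means
#' unannotated) and JSON (one object per source with an ordered `entries`
#' array). A minimal RDF/XML reader is also provided: it extracts
#' `(property, literal value, datatype, unit)` statements about the file's
#' single subject, best-effort, with field widths enforced only later at
#' encode time.
#'
#' @param path File path.
#' @param format `"tsv"`, `"json"` or `"rdf"`; guessed from the extension
#'   when omitted.
#' @return An annotation tibble (see [build_network()]).
#' @export
read_annotations <- function(path, format = NULL) {
  format <- format %||% guess_format(path)
  switch(format,
    tsv = read_annotations_tsv(path),
    json = read_annotations_json(path),
    rdf = read_annotations_rdf(path),
    stop("unknown annotation format '", format, "'", call. = FALSE)
  )
}

guess_format <- function(path) {
  switch(tolower(tools::file_ext(path)),
         tsv = "tsv", txt = "tsv", json = "json",
         rdf = "rdf", xml = "rdf", rdfs = "rdf",
         stop("cannot guess format of '", path, "'", call. = FALSE))
}

read_annotations_tsv <- function(path) {
  cols <- c("source_id", "property", "value", "dtype", "unit")
  df <- tryCatch(
    readr::read_tsv(path, col_types = readr::cols(.default = readr::col_character()),
                    progress = FALSE),
    warning = function(w) stop("malformed TSV in '", path, "': ",
                               conditionMessage(w), call. = FALSE)
  )
  if (!setequal(names(df), cols)) {
    stop("annotation TSV needs exactly the columns ",
         paste(cols, collapse = ", "), call. = FALSE)
  }
  check_annotations(df[cols])
}

read_annotations_json <- function(path) {
  x <- jsonlite::read_json(path)
  rows <- purrr::map_dfr(x, function(src) {
    purrr::map_dfr(src$entries, function(e) {
      tibble::tibble(source_id = src$source_id,
                     property = e$property,
                     value = e$value %||% NA_character_,
                     dtype = e$dtype %||% "undefined",
                     unit = e$unit %||% "undefined")
    })
  })
  check_annotations(rows)
}

#' @param annotations An annotation tibble.
#' @rdname read_annotations
#' @export
write_annotations <- function(annotations, path, format = NULL) {
  format <- format %||% guess_format(path)
  ann <- check_annotations(annotations)
  if (format == "tsv") {
    readr::write_tsv(ann, path, na = "", progress = FALSE)
  } else if (format == "json") {
    out <- lapply(split(ann, factor(ann$source_id, unique(ann$source_id))),
                  function(a) {
                    list(source_id = a$source_id[[1L]],
                         entries = purrr::pmap(
                           a[, c("property", "value", "dtype", "unit")],
                           function(property, value, dtype, unit) {
                             e <- list(property = property, dtype = dtype,
                                       unit = unit)
                             if (!is.na(value)) e$value <- value
                             e
                           }))
                  })
    jsonlite::write_json(unname(out), path, auto_unbox = TRUE, null = "null",
                         pretty = TRUE)
  } else {
    stop("write_annotations supports tsv and json", call. = FALSE)
  }
  invisible(path)
}

# minimal striped-syntax RDF/XML reader: one subject, literal-valued
# properties; rdf:datatype URIs are mapped to codebook names by suffix and
# an optional "unit" attribute (any namespace) is honoured
read_annotations_rdf <- function(path) {
  doc <- xml2::read_xml(path)
  descs <- xml2::xml_find_all(doc, ".//*[local-name() = 'Description']")
  if (length(descs) == 0L) descs <- xml2::xml_children(doc)
  subject <- xml2::xml_attr(descs[[1L]], "about")
  rows <- purrr::map_dfr(descs, function(d) {
    purrr::map_dfr(xml2::xml_children(d), function(node) {
      value <- trimws(xml2::xml_text(node))
      if (!nzchar(value)) return(NULL)
      dt <- xml2::xml_attr(node, "datatype")
      dtype <- if (is.na(dt)) "string" else {
        name <- sub(".*[#/]", "", dt)
        if (name %in% dna_type_codes()$name) name else "undefined"
      }
      unit <- xml2::xml_attr(node, "unit")
      tibble::tibble(source_id = subject %||% "rdf",
                     property = xml2::xml_name(node),
                     value = value, dtype = dtype,
                     unit = ifelse(is.na(unit), "undefined", unit))
    })
  })
  if (nrow(rows) == 0L) stop("no literal-valued statements found in '",
                             path, "'", call. = FALSE)
  check_annotations(rows)
}

#' The packaged two-source worked example
#'
#' Two owners of the same remote sensing image annotated it with different
#' property subsets: one recorded the city (`cty = GZ`) and image quality
#' (`qa = E`) but not the cloud cover; the other recorded the city and the
#' cloud cover (`cc = 0`, an integer percentage) but not the quality.
#' `which = "three_image"` instead returns single-source annotations of
#' three different images, the fixture behind the larger merged network.
#'
#' @param which `"two_source"` (default) or `"three_image"`.
#' @return An annotation tibble.
#' @examples
#' example_annotations()
#' @export
example_annotations <- function(which = c("two_source", "three_image")) {
  which <- match.arg(which)
  if (which == "two_source") {
    tibble::tibble(
      source_id = rep(c("owner1", "owner2"), each = 3L),
      property = rep(c("cty", "qa", "cc"), 2L),
      value = c("GZ", "E", NA, "GZ", NA, "0"),
      dtype = c("string", "string", "undefined",
                "string", "undefined", "integer"),
      unit = c("undefined", "undefined", "undefined",
               "undefined", "undefined", "%")
    )
  } else {
    tibble::tibble(
      source_id = rep(c("E1EB7", "D87C9", "B8EF1"), each = 3L),
      property = rep(c("cty", "qa", "cc"), 3L),
      value = c("GZ", "E", "0", "HK", "G", "0", "HK", "G", "16"),
      dtype = rep(c("string", "string", "integer"), 3L),
      unit = rep(c("undefined", "undefined", "%"), 3L)
    )
  }
}

#' Generate synthetic multi-source annotations
#'
#' Emulates the study setting: `n_sources` owners each annotate the same
#' object over `k_layers` shared properties, drawing each value from that
#' layer's alphabet and independently leaving each property unannotated
#' (null) with probability `null_rate`. With `guarantee_complete = TRUE`
#' every layer is forced to keep at least one non-null value across sources,
#' so a complete fused record always exists.
#'
#' @param k_layers Number of property layers (names `p1`, `p2`, ...).
#' @param n_sources Number of annotation sources.
#' @param n_values Size of each layer's value alphabet (single letters), a
#'   scalar or a length-`k_layers` vector.
#' @param null_rate Per-source, per-layer probability of a null entry.
#' @param guarantee_complete Force >= 1 non-null value per layer?
#' @param seed Optional integer seed; the same seed reproduces the fixture.
#' @return An annotation tibble.
#' @export
generate_fixture <- function(k_layers = 3L, n_sources = 2L, n_values = 2L,
                             null_rate = 0.3, guarantee_complete = TRUE,
                             seed = NULL) {
  stopifnot(k_layers >= 1L, k_layers <= 9L, n_sources >= 1L,
            null_rate >= 0, null_rate <= 1)
  n_values <- rep_len(n_values, k_layers)
  stopifnot(all(n_values >= 1L), all(n_values <= 26L))
  gen <- function() {
    rows <- tidyr::expand_grid(source_id = sprintf("S%d", seq_len(n_sources)),
                               layer = seq_len(k_layers))
    rows$property <- sprintf("p%d", rows$layer)
    rows$value <- vapply(rows$layer, function(l) {
      sample(LETTERS[seq_len(n_values[[l]])], 1L)
    }, character(1L))
    rows$value[stats::runif(nrow(rows)) < null_rate] <- NA_character_
    if (guarantee_complete) {
      for (l in seq_len(k_layers)) {
        i <- which(rows$layer == l)
        if (all(is.na(rows$value[i]))) {
          j <- i[sample.int(length(i), 1L)]
          rows$value[j] <- sample(LETTERS[seq_len(n_values[[l]])], 1L)
        }
      }
    }
    rows$dtype <- ifelse(is.na(rows$value), "undefined", "string")
    rows$unit <- "undefined"
    dplyr::arrange(rows, match(.data$source_id, unique(rows$source_id)),
                   .data$layer)[, c("source_id", "property", "value",
                                    "dtype", "unit")]
  }
  if (is.null(seed)) gen() else withr::with_seed(seed, gen())
}

#' Count nodes and edges of an RDF/RDFS graph
#'
#' Parses an RDF/XML (or RDFS) file with a minimal striped-syntax walker
#' and counts `edges` as the number of extracted triples and `nodes` as the
#' number of distinct subjects and objects. Whether literal objects count as
#' nodes is configurable, since graph-drawing conventions differ.
#'
#' @param path Path to an RDF/XML or RDFS file.
#' @param include_literals Count literal objects as nodes?
#' @return A one-row tibble with columns `nodes` and `edges`.
#' @export
count_ontology_graph <- function(path, include_literals = TRUE) {
  tr <- rdf_triples(path)
  if (!include_literals) tr <- tr[!tr$is_literal, , drop = FALSE]
  nodes <- length(unique(c(tr$subject, tr$object)))
  tibble::tibble(nodes = nodes, edges = nrow(tr))
}

# minimal RDF/XML triple extraction (striped syntax): subject elements are
# rdf:Description or typed nodes bearing rdf:about/ID/nodeID; each child is a
# predicate whose object is an rdf:resource, a nested node, or a literal
rdf_triples <- function(path) {
  doc <- xml2::read_xml(path)
  triples <- list()
  blank <- 0L
  node_id <- function(node) {
    id <- xml2::xml_attr(node, "about") %||% NA_character_
    if (is.na(id)) id <- xml2::xml_attr(node, "ID")
    if (is.na(id)) id <- xml2::xml_attr(node, "nodeID")
    if (is.na(id)) {
      blank <<- blank + 1L
      id <- sprintf("_:b%d", blank)
    }
    id
  }
  walk_subject <- function(node) {
    subj <- node_id(node)
    # a typed node element also asserts rdf:type
    nm <- xml2::xml_name(node)
    if (!nm %in% c("Description", "RDF")) {
      triples[[length(triples) + 1L]] <<-
        list(subject = subj, predicate = "rdf:type", object = nm,
             is_literal = FALSE)
    }
    for (pred in xml2::xml_children(node)) {
      pname <- xml2::xml_name(pred)
      res <- xml2::xml_attr(pred, "resource")
      kids <- xml2::xml_children(pred)
      if (!is.na(res)) {
        obj <- res; lit <- FALSE
      } else if (length(kids) > 0L) {
        obj <- walk_subject(kids[[1L]]); lit <- FALSE
      } else {
        obj <- trimws(xml2::xml_text(pred)); lit <- TRUE
      }
      triples[[length(triples) + 1L]] <<-
        list(subject = subj, predicate = pname, object = obj, is_literal = lit)
    }
    subj
  }
  for (top in xml2::xml_children(doc)) walk_subject(top)
  if (length(triples) == 0L) {
    return(tibble::tibble(subject = character(), predicate = character(),
                          object = character(), is_literal = logical()))
  }
  dplyr::bind_rows(triples)
}

#' Write an oligo library as FASTA
#'
#' Headers record the element kind, endpoints for edges, and the synthesis
#' seed, making the library file self-describing.
#'
#' @param lib An `oligo_library`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_library_fasta <- function(lib, path) {
  stopifnot(inherits(lib, "oligo_library"))
  seed <- attr(lib, "seed")
  hdr <- ifelse(lib$kind == "vertex",
                sprintf("vertex %s seed=%s", lib$id, seed %||% "NA"),
                sprintf("edge %s from=%s to=%s seed=%s", lib$id, lib$from,
                        lib$to, seed %||% "NA"))
  seqinr::write.fasta(as.list(lib$seq), hdr, path, as.string = TRUE)
  invisible(path)
}
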