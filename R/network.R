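#' Build the layered property network from multi-source annotations
#'
#' Each source's annotation is a chain of property vertices in a shared
#' property order; chains are merged into a layered DAG in which vertices
#' with identical `(property, value, dtype, unit)` appear once, and `Start`
#' and `End` terminals close the graph. With `recombination = TRUE` (the
#' default, and required for fusion) every pair of vertices in consecutive
#' layers is connected, so paths may mix values contributed by different
#' sources; with `FALSE` only the edges walked by some source chain are kept.
#'
#' @param annotations A data frame with columns `source_id`, `property`,
#'   `value` (`NA` for an unannotated property), `dtype`, `unit`; row order
#'   within each source gives the property order, which must agree across
#'   sources.
#' @param recombination Logical; synthesise all layer-adjacent edges?
#' @return A `property_network`: a list with `layers` (ordered property
#'   names), `vertices` (tibble `id`, `layer`, `property`, `value`, `dtype`,
#'   `unit`) and `edges` (tibble `from`, `to` of vertex ids).
#' @examples
#' net <- build_network(example_annotations())
#' net$vertices
#' @export
build_network <- function(annotations, recombination = TRUE) {
  ann <- check_annotations(annotations)
  layers <- ann$property[ann$source_id == ann$source_id[[1L]]]
  k <- length(layers)

  by_source <- split(ann, factor(ann$source_id, unique(ann$source_id)))
  for (a in by_source) {
    if (!identical(a$property, layers)) {
      stop("all sources must share the property order: source '",
           a$source_id[[1L]], "' lists ", paste(a$property, collapse = ","),
           call. = FALSE)
    }
  }

  verts <- ann |>
    dplyr::distinct(.data$property, .data$value, .data$dtype, .data$unit) |>
    dplyr::mutate(layer = match(.data$property, layers))
  verts <- vertex_ids(verts)
  terminals <- tibble::tibble(
    id = c("start", "end"), layer = c(0L, k + 1L),
    property = c("start", "end"), value = NA_character_,
    dtype = NA_character_, unit = NA_character_
  )
  vertices <- dplyr::bind_rows(terminals[1L, ], verts, terminals[2L, ]) |>
    dplyr::arrange(.data$layer, .data$id) |>
    dplyr::select("id", "layer", "property", "value", "dtype", "unit")

  if (recombination) {
    edges <- purrr::map_dfr(0:k, function(l) {
      tidyr::expand_grid(from = vertices$id[vertices$layer == l],
                         to = vertices$id[vertices$layer == l + 1L])
    })
  } else {
    key <- function(df) {
      vertices$id[match(paste(df$property, df$value, df$dtype, df$unit),
                        paste(vertices$property, vertices$value,
                              vertices$dtype, vertices$unit))]
    }
    edges <- purrr::map_dfr(by_source, function(a) {
      ids <- c("start", key(a), "end")
      tibble::tibble(from = ids[-length(ids)], to = ids[-1L])
    }) |> dplyr::distinct()
  }

  structure(list(layers = layers, vertices = vertices, edges = edges),
            class = "property_network")
}

check_annotations <- function(annotations) {
  need <- c("source_id", "property", "value", "dtype", "unit")
  if (!is.data.frame(annotations) || !all(need %in% names(annotations))) {
    stop("annotations need columns ", paste(need, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(annotations) == 0L) {
    stop("at least one annotation is required", call. = FALSE)
  }
  ann <- tibble::as_tibble(annotations) |>
    dplyr::mutate(dplyr::across(dplyr::all_of(need), as.character))
  # a null value is unannotated: type and unit are undefined by definition
  ann$dtype[is.na(ann$value)] <- "undefined"
  ann$unit[is.na(ann$value)] <- "undefined"
  ann
}

# human-readable ids "(prop,value)", disambiguated by dtype/unit when two
# sources disagree on the typing of the same value
vertex_ids <- function(verts) {
  base <- paste0("(", verts$property, ",",
                 ifelse(is.na(verts$value), "null", verts$value), ")")
  dup <- base %in% base[duplicated(base)]
  verts$id <- ifelse(dup,
                     paste0(sub("\\)$", "", base), "|",
                            verts$dtype, "|", verts$unit, ")"),
                     base)
  verts
}

#' Enumerate all Start-to-End paths of a property network
#'
#' Walks the layered DAG depth-first; each path visits exactly one vertex
#' per layer, so enumeration terminates and serves as the deterministic
#' ground truth for the stochastic ligation simulation.
#'
#' @param net A `property_network`.
#' @return A list of character vectors of vertex ids, each starting with
#'   `"start"` and ending with `"end"`.
#' @export
enumerate_paths <- function(net) {
  stopifnot(inherits(net, "property_network"))
  adj <- split(net$edges$to, net$edges$from)
  walk <- function(v) {
    nxt <- adj[[v]]
    if (v == "end") return(list(v))
    if (is.null(nxt)) return(list())
    res <- unlist(lapply(nxt, function(w) {
      lapply(walk(w), function(p) c(v, p))
    }), recursive = FALSE)
    if (is.null(res)) list() else res
  }
  walk("start")
}

#' Synthesise the oligo library of a property network
#'
#' Generates one vertex oligo per vertex (terminals included) from a single
#' seeded RNG stream, then derives one edge oligo per edge with
#' [encode_edge()]. Each vertex is encoded exactly once per run and its
#' sequence reused everywhere it appears, mirroring the synthesis of a single
#' species per oligo.
#'
#' @param net A `property_network`.
#' @param seed Optional integer seed; the same seed reproduces the library.
#' @inheritParams encode_vertex
#' @return An `oligo_library` tibble with columns `kind` (`"vertex"` /
#'   `"edge"`), `id`, `from`, `to`, `seq`, and the vertex fields; the seed
#'   and field widths are attached as attributes.
#' @examples
#' lib <- to_oligo_library(build_network(example_annotations()), seed = 1)
#' dplyr::count(lib, kind)
#' @export
to_oligo_library <- function(net, seed = NULL, name_width = 3L,
                             value_width = 2L,
                             type_codes = dna_type_codes(),
                             unit_codes = dna_unit_codes()) {
  stopifnot(inherits(net, "property_network"))
  encode_all <- function() {
    purrr::pmap_chr(net$vertices, function(id, layer, property, value,
                                           dtype, unit) {
      if (id %in% c("start", "end")) {
        encode_terminal(id, name_width = name_width, value_width = value_width)
      } else {
        encode_vertex(property, value,
                      dtype = dtype, unit = unit,
                      name_width = name_width, value_width = value_width,
                      type_codes = type_codes, unit_codes = unit_codes)
      }
    })
  }
  seqs <- if (is.null(seed)) encode_all() else withr::with_seed(seed, encode_all())

  vert <- net$vertices |>
    dplyr::mutate(kind = "vertex", seq = seqs,
                  from = NA_character_, to = NA_character_)
  vseq <- stats::setNames(seqs, net$vertices$id)
  edge <- net$edges |>
    dplyr::mutate(kind = "edge",
                  id = paste0("e:", .data$from, "->", .data$to),
                  seq = purrr::map2_chr(.data$from, .data$to, function(i, j) {
                    encode_edge(vseq[[i]], vseq[[j]],
                                name_width = name_width,
                                value_width = value_width)
                  }))
  lib <- dplyr::bind_rows(vert, edge) |>
    dplyr::select("kind", "id", "from", "to", "seq",
                  "layer", "property", "value", "dtype", "unit")
  structure(lib, class = c("oligo_library", class(lib)),
            seed = seed, name_width = name_width, value_width = value_width)
}

#' @export
print.property_network <- function(x, ...) {
  cat("<property_network> ", length(x$layers), " layers (",
      paste(x$layers, collapse = " > "), "), ",
      nrow(x$vertices), " vertices, ", nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Plot a property network
#'
#' Lays layers out left to right with one point per vertex and a segment per
#' edge; null-valued vertices are marked.
#'
#' @param object A `property_network`.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot property_network
#' @export
autoplot.property_network <- function(object, ...) {
  v <- object$vertices |>
    dplyr::group_by(.data$layer) |>
    dplyr::mutate(y = seq_len(dplyr::n()) - (dplyr::n() + 1) / 2) |>
    dplyr::ungroup() |>
    dplyr::mutate(null = !.data$id %in% c("start", "end") & is.na(.data$value))
  e <- object$edges |>
    dplyr::left_join(dplyr::select(v, "id", x0 = "layer", y0 = "y"),
                     by = c(from = "id")) |>
    dplyr::left_join(dplyr::select(v, "id", x1 = "layer", y1 = "y"),
                     by = c(to = "id"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = e,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x1, yend = .data$y1),
                          colour = "grey60") +
    ggplot2::geom_point(data = v,
                        ggplot2::aes(x = .data$layer, y = .data$y,
                                     colour = .data$null), size = 3) +
    ggplot2::geom_text(data = v,
                       ggplot2::aes(x = .data$layer, y = .data$y,
                                    label = .data$id),
                       vjust = -1, size = 3) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "steelblue",
                                            `TRUE` = "firebrick"),
                                 guide = "none") +
    ggplot2::labs(x = "layer", y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_blank())
}
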