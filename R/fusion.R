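#' Fuse multi-source annotations by simulated DNA computation
#'
#' Runs the full pipeline: build the recombination property network from the
#' annotations, synthesise its oligo library, simulate the splinted-ligation
#' reaction, then screen the product tube in the order of the abstract model —
#' keep strands that begin with the Start oligo, end with the End oligo, are
#' at most `8*(name_width+value_width+1) * (K+2)` nt long (240 nt for three
#' properties at default widths, i.e. exactly K+2 vertices), and do not
#' contain the [null_marker()]. Each distinct survivor is decoded into a
#' complete, null-free property record.
#'
#' @param annotations Annotation data frame (see [build_network()]).
#' @param n_molecules Ligation products to sample in `"sampled"` mode.
#' @param seed Optional integer seed driving both library synthesis and
#'   sampling.
#' @param mode `"sampled"` (stochastic, like the wet protocol) or
#'   `"exhaustive"` (deterministic; equals [fuse_oracle()] exactly).
#' @param recombination Passed to [build_network()]; fusion requires the
#'   recombination edge set to combine values across sources, so the default
#'   is `TRUE`.
#' @param p_extend Sampled-walk continuation probability, see [ligate()].
#' @inheritParams encode_vertex
#' @return A `semantic_fusion` object: a list with `records` (tibble of fused
#'   records: `flat_text`, `strand`, `n_vertices`, `length_nt`, `count`,
#'   `entries` list-column), `steps` (tube sizes through the screening
#'   funnel), `network`, `library` and the call configuration. `tidy()`
#'   returns the records, `glance()` a one-row summary.
#' @examples
#' fus <- semantic_fuse(example_annotations(), mode = "exhaustive")
#' tidy(fus)$flat_text
#' @export
semantic_fuse <- function(annotations, n_molecules = 10000L, seed = NULL,
                          mode = c("sampled", "exhaustive"),
                          recombination = TRUE, p_extend = 0.75,
                          name_width = 3L, value_width = 2L,
                          type_codes = dna_type_codes(),
                          unit_codes = dna_unit_codes()) {
  mode <- match.arg(mode)
  if (mode == "sampled" && n_molecules < 1L) {
    stop("sampled mode needs n_molecules >= 1", call. = FALSE)
  }
  net <- build_network(annotations, recombination = recombination)
  k <- length(net$layers)
  lib_seed <- if (is.null(seed)) NULL else derive_seed(seed, 1L)
  lig_seed <- if (is.null(seed)) NULL else derive_seed(seed, 2L)
  lib <- to_oligo_library(net, seed = lib_seed, name_width = name_width,
                          value_width = value_width,
                          type_codes = type_codes, unit_codes = unit_codes)
  v_start <- lib$seq[lib$kind == "vertex" & lib$id == "start"]
  v_end <- lib$seq[lib$kind == "vertex" & lib$id == "end"]

  t0 <- ligate(lib, n_molecules = n_molecules, seed = lig_seed, mode = mode,
               p_extend = p_extend)
  t1 <- pre_separate(t0, v_start)$kept
  t2 <- post_separate(t1, v_end)$kept
  max_nt <- vertex_length(name_width, value_width) * (k + 2L)
  t3 <- length_separate(t2, max_nt)$kept
  t4 <- sub_separate(t3, null_marker())$not_containing

  steps <- tibble::tibble(
    step = c("ligation", "pre_separate(V_start)", "post_separate(V_end)",
             paste0("length_separate(", max_nt, ")"),
             "sub_separate(null marker)"),
    molecules = c(tube_size(t0), tube_size(t1), tube_size(t2),
                  tube_size(t3), tube_size(t4)),
    distinct = c(nrow(t0), nrow(t1), nrow(t2), nrow(t3), nrow(t4))
  )

  records <- decode_survivors(t4, name_width = name_width,
                              value_width = value_width,
                              type_codes = type_codes,
                              unit_codes = unit_codes)
  structure(
    list(records = records, steps = steps, detected = detect_strands(t4),
         network = net, library = lib, tube = t4,
         config = list(n_molecules = n_molecules, seed = seed, mode = mode,
                       recombination = recombination, p_extend = p_extend,
                       name_width = name_width, value_width = value_width)),
    class = "semantic_fusion"
  )
}

derive_seed <- function(seed, salt) {
  m <- 2147483647
  x <- (as.double(seed) %% m + salt) %% m
  as.integer((x * 69069 + 1) %% m)
}

decode_survivors <- function(t, name_width, value_width, type_codes,
                             unit_codes) {
  vlen <- vertex_length(name_width, value_width)
  rows <- purrr::pmap(t[, c("seq", "count")], function(seq, count) {
    entries <- decode_strand(seq, name_width = name_width,
                             value_width = value_width,
                             type_codes = type_codes, unit_codes = unit_codes)
    inner <- entries[entries$kind == "vertex",
                     c("property", "value", "dtype", "unit")]
    tibble::tibble(
      flat_text = flat_record_text(inner, name_width, value_width),
      strand = seq,
      n_vertices = nrow(entries),
      length_nt = nchar(seq),
      count = count,
      entries = list(inner)
    )
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(flat_text = character(), strand = character(),
                          n_vertices = integer(), length_nt = integer(),
                          count = integer(), entries = list()))
  }
  dplyr::arrange(out, .data$flat_text)
}

#' Decode a ligated strand into its per-vertex records
#'
#' Splits a strand into consecutive vertex-length windows and decodes each
#' with [decode_vertex()].
#'
#' @param seq A DNA string whose length is a multiple of the vertex length.
#' @inheritParams encode_vertex
#' @return A tibble with one row per vertex segment.
#' @export
decode_strand <- function(seq, name_width = 3L, value_width = 2L,
                          type_codes = dna_type_codes(),
                          unit_codes = dna_unit_codes()) {
  vlen <- vertex_length(name_width, value_width)
  if (nchar(seq) %% vlen != 0L) {
    stop("strand length ", nchar(seq), " is not a multiple of the ",
         vlen, "-nt vertex length", call. = FALSE)
  }
  n <- nchar(seq) %/% vlen
  purrr::map_dfr(seq_len(n), function(i) {
    decode_vertex(substr(seq, (i - 1L) * vlen + 1L, i * vlen),
                  name_width = name_width, value_width = value_width,
                  type_codes = type_codes, unit_codes = unit_codes)
  })
}

# the fixed-width flat property string " start<name value ...>   end"
flat_record_text <- function(entries, name_width, value_width) {
  w <- name_width + value_width + 1L
  body <- purrr::pmap_chr(entries, function(property, value, dtype, unit) {
    pad <- if (identical(dtype, "integer")) "0" else " "
    paste0(pad_left(property, name_width, " "),
           pad_left(ifelse(is.na(value), "", value), value_width, pad))
  })
  paste0(pad_left("start", w, " "), paste(body, collapse = ""),
         pad_left("end", w, " "))
}

#' Deterministic graph-search oracle for semantic fusion
#'
#' Computes the fused record set without any simulation: enumerate all
#' Start-to-End paths of the recombination network, keep those visiting no
#' null-valued vertex, and decode each into a record. [semantic_fuse()] in
#' exhaustive mode must agree with this exactly; sampled mode converges to it
#' as `n_molecules` grows.
#'
#' @inheritParams semantic_fuse
#' @return A tibble with `flat_text` and an `entries` list-column, one row
#'   per fused record, sorted by `flat_text`.
#' @export
fuse_oracle <- function(annotations, recombination = TRUE,
                        name_width = 3L, value_width = 2L) {
  net <- build_network(annotations, recombination = recombination)
  v <- net$vertices
  paths <- enumerate_paths(net)
  null_ids <- v$id[!(v$id %in% c("start", "end")) & is.na(v$value)]
  keep <- purrr::keep(paths, function(p) !any(p %in% null_ids))
  rows <- purrr::map(keep, function(p) {
    inner <- v[match(p, v$id), ][-c(1L, length(p)), ,
                                 drop = FALSE][, c("property", "value",
                                                   "dtype", "unit")]
    tibble::tibble(flat_text = flat_record_text(inner, name_width, value_width),
                   entries = list(tibble::as_tibble(inner)))
  })
  out <- dplyr::bind_rows(rows)
  if (nrow(out) == 0L) {
    return(tibble::tibble(flat_text = character(), entries = list()))
  }
  dplyr::arrange(dplyr::distinct(out, .data$flat_text, .keep_all = TRUE),
                 .data$flat_text)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance

#' Tidy a fusion result
#'
#' @param x A `semantic_fusion` object.
#' @param ... Ignored.
#' @return The records tibble, one row per distinct fused record.
#' @method tidy semantic_fusion
#' @export
tidy.semantic_fusion <- function(x, ...) x$records

#' One-row summary of a fusion run
#'
#' @param x A `semantic_fusion` object.
#' @param ... Ignored.
#' @return A one-row tibble.
#' @method glance semantic_fusion
#' @export
glance.semantic_fusion <- function(x, ...) {
  tibble::tibble(
    k_layers = length(x$network$layers),
    n_vertices = nrow(x$network$vertices),
    n_edges = nrow(x$network$edges),
    mode = x$config$mode,
    n_molecules = x$config$n_molecules,
    survivors = tube_size(x$tube),
    n_records = nrow(x$records),
    detected = x$detected,
    seed = x$config$seed %||% NA_integer_
  )
}

#' @export
print.semantic_fusion <- function(x, ...) {
  cat("<semantic_fusion> ", x$config$mode, " mode, ",
      nrow(x$records), " fused record(s)\n", sep = "")
  if (nrow(x$records) > 0L) {
    cat(paste0("  \"", x$records$flat_text, "\"", collapse = "\n"), "\n")
  }
  invisible(x)
}

#' Plot the screening funnel of a fusion run
#'
#' Bar chart of molecule counts after ligation and after each screening
#' step.
#'
#' @param object A `semantic_fusion` object.
#' @param ... Ignored.
#' @return A ggplot object.
#' @method autoplot semantic_fusion
#' @export
autoplot.semantic_fusion <- function(object, ...) {
  d <- object$steps |>
    dplyr::mutate(step = factor(.data$step, levels = .data$step))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$step, y = .data$molecules)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$molecules), vjust = -0.4,
                       size = 3) +
    ggplot2::labs(x = NULL, y = "molecules in tube",
                  title = "Screening funnel") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 20, hjust = 1))
}
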