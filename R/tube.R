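#' Construct a tube
#'
#' A tube is a multiset of DNA strands: the state object on which the
#' screening operations act. Strands are tracked as distinct sequences with
#' counts rather than as physical copies; each strand remembers the ordered
#' vertex identities (its provenance) it was ligated from.
#'
#' @param strands A data frame with columns `seq` (DNA string), `provenance`
#'   (list of character vectors of vertex ids) and `count` (positive
#'   integers). Defaults to an empty tube.
#' @return A `dna_tube` tibble.
#' @export
tube <- function(strands = NULL) {
  if (is.null(strands)) {
    strands <- tibble::tibble(seq = character(), provenance = list(),
                              count = integer())
  }
  stopifnot(all(c("seq", "provenance", "count") %in% names(strands)))
  if (any(strands$count < 1L)) stop("strand counts must be >= 1", call. = FALSE)
  structure(tibble::as_tibble(strands), class = c("dna_tube", class(tibble::tibble())))
}

as_tube <- function(df) tube(df)

#' Total number of molecules in a tube
#' @param t A `dna_tube`.
#' @return An integer count (sum of strand multiplicities).
#' @export
tube_size <- function(t) sum(t$count)

#' Simulate the splinted-ligation reaction over an oligo library
#'
#' Vertex oligos are joined end to end wherever an edge oligo spans their
#' junction as a splint; the products are walks in the underlying property
#' network, materialised as the concatenation of the vertex oligos along the
#' walk. In `"sampled"` mode each of `n_molecules` products starts at a
#' uniformly chosen vertex and is extended independently in both directions,
#' each step continuing with probability `p_extend` along a uniformly chosen
#' incident edge, so partial products are common. In `"exhaustive"` mode
#' every directed walk (any start vertex, any length up to the number of
#' layers plus two) appears exactly once: the deterministic input for oracle
#' comparisons.
#'
#' The library is validated first: every edge oligo must equal the
#' complement of its endpoints' adjoining halves, otherwise no splinting
#' could occur and a library error is raised.
#'
#' @param lib An `oligo_library` from [to_oligo_library()].
#' @param n_molecules Number of products to sample (sampled mode).
#' @param seed Optional integer seed.
#' @param mode `"sampled"` or `"exhaustive"`.
#' @param p_extend Per-step continuation probability of a sampled walk.
#' @return A `dna_tube`.
#' @export
ligate <- function(lib, n_molecules = 10000L, seed = NULL,
                   mode = c("sampled", "exhaustive"), p_extend = 0.75) {
  mode <- match.arg(mode)
  check_library(lib)
  v <- lib[lib$kind == "vertex", ]
  e <- lib[lib$kind == "edge", ]
  vseq <- stats::setNames(v$seq, v$id)
  fwd <- split(e$to, e$from)
  bwd <- split(e$from, e$to)

  if (mode == "exhaustive") {
    walks <- all_walks(v$id, fwd, max_vertices = length(unique(v$layer)))
  } else {
    if (n_molecules == 0L) return(tube())
    sample_all <- function() {
      lapply(seq_len(n_molecules), function(i) {
        sample_walk(v$id, fwd, bwd, p_extend)
      })
    }
    walks <- if (is.null(seed)) sample_all() else withr::with_seed(seed, sample_all())
  }

  key <- vapply(walks, paste, character(1L), collapse = "\r")
  agg <- tapply(seq_along(walks), key, identity, simplify = FALSE)
  strands <- tibble::tibble(
    provenance = unname(lapply(agg, function(i) walks[[i[[1L]]]])),
    count = unname(vapply(agg, length, integer(1L)))
  )
  strands$seq <- vapply(strands$provenance, function(p) {
    paste(unname(vseq[p]), collapse = "")
  }, character(1L))
  tube(strands[, c("seq", "provenance", "count")])
}

check_library <- function(lib) {
  stopifnot(inherits(lib, "oligo_library"))
  nw <- attr(lib, "name_width") %||% 3L
  vw <- attr(lib, "value_width") %||% 2L
  v <- lib[lib$kind == "vertex", ]
  e <- lib[lib$kind == "edge", ]
  vseq <- stats::setNames(v$seq, v$id)
  ok <- purrr::pmap_lgl(e[, c("from", "to", "seq")], function(from, to, seq) {
    identical(toupper(encode_edge(vseq[[from]], vseq[[to]],
                                  name_width = nw, value_width = vw)),
              toupper(seq))
  })
  if (!all(ok)) {
    stop("library is not hybridization-compatible: edge ",
         e$id[which(!ok)[1L]], " does not complement its endpoints",
         call. = FALSE)
  }
  invisible(lib)
}

# all directed walks with <= max_vertices vertices, each once
all_walks <- function(ids, fwd, max_vertices) {
  out <- list()
  extend <- function(path) {
    out[[length(out) + 1L]] <<- path
    if (length(path) >= max_vertices) return()
    for (w in fwd[[path[length(path)]]]) extend(c(path, w))
  }
  for (id in ids) extend(id)
  out
}

sample_walk <- function(ids, fwd, bwd, p_extend) {
  path <- sample(ids, 1L)
  repeat {
    nxt <- fwd[[path[length(path)]]]
    if (is.null(nxt) || stats::runif(1L) >= p_extend) break
    path <- c(path, nxt[sample.int(length(nxt), 1L)])
  }
  repeat {
    prv <- bwd[[path[1L]]]
    if (is.null(prv) || stats::runif(1L) >= p_extend) break
    path <- c(prv[sample.int(length(prv), 1L)], path)
  }
  path
}

# ---- separation / detection / amplification -------------------------------

separate_by <- function(t, keep) {
  stopifnot(inherits(t, "dna_tube"))
  list(kept = tube(t[keep, , drop = FALSE]),
       rejected = tube(t[!keep, , drop = FALSE]))
}

#' Screening operations on a tube
#'
#' The abstract separation operations of the molecular-computation model,
#' each partitioning the input multiset exactly (kept plus rejected equals
#' the input, strand by strand). Matching is on raw sequence content,
#' case-insensitively: a probe binds one specific sequence, not the set of
#' degenerate encodings of the same bits.
#'
#' * `pre_separate(t, s)` splits by whether `s` is a prefix.
#' * `post_separate(t, s)` splits by whether `s` is a suffix.
#' * `sub_separate(t, s)` splits by whether `s` occurs as a substring
#'   (components named `containing` / `not_containing`).
#' * `length_separate(t, n)` keeps strands of length at most `n` nt.
#'
#' @param t A `dna_tube`.
#' @param s A DNA string probe.
#' @param n Maximum strand length in nucleotides.
#' @return A list of two tubes: `kept`/`rejected` (or
#'   `containing`/`not_containing` for `sub_separate`).
#' @export
pre_separate <- function(t, s) {
  separate_by(t, startsWith(toupper(t$seq), toupper(s)))
}

#' @rdname pre_separate
#' @export
post_separate <- function(t, s) {
  separate_by(t, endsWith(toupper(t$seq), toupper(s)))
}

#' @rdname pre_separate
#' @export
sub_separate <- function(t, s) {
  parts <- separate_by(t, grepl(toupper(s), toupper(t$seq), fixed = TRUE))
  list(containing = parts$kept, not_containing = parts$rejected)
}

#' @rdname pre_separate
#' @export
length_separate <- function(t, n) {
  stopifnot(n >= 0)
  separate_by(t, nchar(t$seq) <= n)
}

#' Detect whether a tube contains any molecule
#'
#' @param t A `dna_tube`.
#' @return `TRUE` if the multiset is non-empty, else `FALSE`.
#' @export
detect_strands <- function(t) {
  stopifnot(inherits(t, "dna_tube"))
  tube_size(t) > 0L
}

#' Amplify a tube by PCR
#'
#' Multiplies every strand's count by `factor`; the set of distinct strands
#' is unchanged.
#'
#' @param t A `dna_tube`.
#' @param factor Integer >= 1.
#' @return The amplified `dna_tube`.
#' @export
amplify <- function(t, factor) {
  stopifnot(inherits(t, "dna_tube"), factor >= 1L)
  t$count <- t$count * as.integer(factor)
  t
}

#' @export
print.dna_tube <- function(x, ...) {
  cat("<dna_tube> ", tube_size(x), " molecules, ", nrow(x),
      " distinct strands\n", sep = "")
  if (nrow(x) > 0L) NextMethod()
  invisible(x)
}

#' Write a tube (or any oligo collection) as FASTA
#'
#' Headers carry the strand count and the provenance walk so that dumps are
#' self-describing.
#'
#' @param t A `dna_tube`.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_tube_fasta <- function(t, path) {
  stopifnot(inherits(t, "dna_tube"))
  names <- sprintf("strand_%d count=%d walk=%s", seq_len(nrow(t)), t$count,
                   vapply(t$provenance, paste, character(1L), collapse = ">"))
  seqinr::write.fasta(as.list(t$seq), names, path, as.string = TRUE)
  invisible(path)
}
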