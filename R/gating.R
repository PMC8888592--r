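#' Declarative description of one FACS-style gate
#'
#' A gate selects cells along one axis (`adt_corrected`
#' background-corrected ADT, `mrna_count` raw transcript counts, or
#' `module_score`) by one of four modes:
#' \describe{
#'   \item{top_fraction}{the `ceiling(f * n)` highest-valued cells within
#'     the cells passing previous gates (stable tie-break by ascending
#'     barcode)}
#'   \item{positive_after_background}{cells with corrected ADT value > 0}
#'   \item{max_count_negative}{cells with raw count at or below a ceiling
#'     (a negative gate, e.g. CD38- as `count <= 0`)}
#'   \item{absolute_threshold}{cells with value >= a fixed threshold}
#' }
#'
#' @param axis one of `adt_corrected`, `mrna_count`, `module_score`
#' @param marker marker / gene / score name on that axis
#' @param mode gate mode (see above)
#' @param parameter fraction in `(0, 1]` for `top_fraction`; threshold
#'   otherwise (ignored for `positive_after_background`)
#' @return list of class `gate_spec`
#' @export
gate_spec <- function(axis = c("adt_corrected", "mrna_count", "module_score"),
                      marker, mode = c("top_fraction",
                                       "positive_after_background",
                                       "max_count_negative",
                                       "absolute_threshold"),
                      parameter = NA_real_) {
  axis <- match.arg(axis)
  mode <- match.arg(mode)
  if (mode == "top_fraction" && !(is.numeric(parameter) &&
                                  parameter > 0 && parameter <= 1))
    stop("top_fraction parameter must lie in (0, 1]")
  if (mode == "max_count_negative" && (!is.numeric(parameter) || parameter < 0))
    stop("max_count_negative parameter must be >= 0")
  structure(list(axis = axis, marker = marker, mode = mode,
                 parameter = parameter), class = "gate_spec")
}

#' A named, ordered conjunction of gates
#'
#' Gates are applied sequentially: each gate is evaluated within the cells
#' passing all previous gates, so a `top_fraction` gate takes its quantile
#' within the surviving population, exactly as sequential FACS gating does.
#'
#' @param name signature name (e.g. `"classical"`, `"Sumide"`, `"EPCR"`)
#' @param gates non-empty list of [gate_spec()] objects
#' @return list of class `signature_definition`
#' @export
signature_definition <- function(name, gates) {
  if (length(gates) == 0) stop("a signature needs at least one gate")
  stopifnot(all(vapply(gates, inherits, TRUE, "gate_spec")))
  structure(list(name = name, gates = gates), class = "signature_definition")
}

#' Apply a single gate within a cell set
#'
#' @param values named numeric vector of the gated quantity per cell (names
#'   are barcodes; must cover `within`)
#' @param spec a [gate_spec()]
#' @param within character vector of barcodes passing previous gates
#' @return character vector of surviving barcodes: a subset of `within`
#'   with the input order preserved
#' @export
apply_gate <- function(values, spec, within) {
  stopifnot(inherits(spec, "gate_spec"))
  if (length(within) == 0) stop("gate applied to an empty cell set")
  if (!all(within %in% names(values)))
    stop("values missing for some cells in the gate")
  v <- values[within]
  switch(spec$mode,
    top_fraction = {
      if (spec$parameter * length(within) < 1) {
        warning("top_fraction selects no cells (f * n < 1)")
        return(character(0))
      }
      k <- ceiling(spec$parameter * length(within))
      chosen <- within[order(-v, within)][seq_len(k)]
      within[within %in% chosen]   # input order preserved
    },
    positive_after_background = within[v > 0],
    max_count_negative = within[v <= spec$parameter],
    absolute_threshold = within[v >= spec$parameter]
  )
}

#' Sort cells in silico along a signature's gate chain
#'
#' @param sig a [signature_definition()]
#' @param axes list with any of `adt_corrected`, `mrna_count`,
#'   `module_score`: each a matrix (markers x cells, barcodes as column
#'   names) or, for `module_score`, optionally a named list of per-cell
#'   score vectors
#' @param within optional starting barcodes (default: all cells of the first
#'   available axis)
#' @return object of class `sort_result`: list with `name`, `selected`
#'   (barcodes), `pass_counts` (named, non-increasing along the chain),
#'   `thresholds` (per-gate record of mode and parameter actually applied)
#' @export
sort_signature <- function(sig, axes, within = NULL) {
  stopifnot(inherits(sig, "signature_definition"))
  axis_values <- function(spec) {
    src <- axes[[spec$axis]]
    if (is.null(src))
      stop("axis '", spec$axis, "' not supplied")
    if (is.list(src) && !is.matrix(src)) {
      if (is.null(src[[spec$marker]]))
        stop("marker '", spec$marker, "' absent on axis ", spec$axis)
      return(src[[spec$marker]])
    }
    if (!spec$marker %in% rownames(src))
      stop("marker '", spec$marker, "' absent on axis ", spec$axis)
    src[spec$marker, ]
  }
  if (is.null(within)) {
    first <- Filter(Negate(is.null), axes)[[1]]
    within <- if (is.matrix(first)) colnames(first) else names(first[[1]])
  }
  pass_counts <- integer(length(sig$gates))
  thresholds <- vector("list", length(sig$gates))
  current <- within
  for (i in seq_along(sig$gates)) {
    spec <- sig$gates[[i]]
    current <- tryCatch(
      apply_gate(axis_values(spec), spec, current),
      error = function(e) stop("gate ", i, " (", spec$marker, "): ",
                               conditionMessage(e), call. = FALSE))
    pass_counts[i] <- length(current)
    thresholds[[i]] <- list(axis = spec$axis, marker = spec$marker,
                            mode = spec$mode, parameter = spec$parameter)
  }
  names(pass_counts) <- vapply(sig$gates, `[[`, "", "marker")
  structure(list(name = sig$name, selected = current,
                 pass_counts = pass_counts, thresholds = thresholds,
                 n_input = length(within)),
            class = "sort_result")
}

#' @export
print.sort_result <- function(x, ...) {
  cat(sprintf("sort_result '%s': %d -> %s cells\n", x$name, x$n_input,
              paste(x$pass_counts, collapse = " -> ")))
  invisible(x)
}

#' Cell-level overlap between sorted signatures
#'
#' @param results list of two or more [sort_signature()] results over the
#'   same cell universe
#' @return list with `pairwise` (data.frame: signature pair, sizes,
#'   intersection), `common` (barcodes selected by every signature) and
#'   `n_common`
#' @export
signature_overlap_cells <- function(results) {
  stopifnot(length(results) >= 2,
            all(vapply(results, inherits, TRUE, "sort_result")))
  sets <- lapply(results, `[[`, "selected")
  names(sets) <- vapply(results, `[[`, "", "name")
  pairs <- utils::combn(names(sets), 2)
  pairwise <- data.frame(
    a = pairs[1, ], b = pairs[2, ],
    n_a = lengths(sets)[pairs[1, ]], n_b = lengths(sets)[pairs[2, ]],
    n_intersect = apply(pairs, 2, function(p)
      length(intersect(sets[[p[1]]], sets[[p[2]]]))),
    row.names = NULL)
  common <- Reduce(intersect, sets)
  list(pairwise = pairwise, common = common, n_common = length(common))
}
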