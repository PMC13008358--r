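#' Tidy and glance methods
#'
#' broom-style accessors: `tidy()` returns the per-transcript (or per-motif)
#' table of a result object as a plain tibble; `glance()` returns a one-row
#' summary.
#'
#' @param x A `misa_call`, `nasa_call`, `motif_result`, or `ac4c_run`.
#' @param ... Unused.
#' @return A tibble.
#' @name acripr-tidiers
NULL

#' @rdname acripr-tidiers
#' @export
tidy.misa_call <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname acripr-tidiers
#' @export
glance.misa_call <- function(x, ...) {
  tibble::tibble(n_transcripts = nrow(x), n_misa = sum(x$is_misa),
                 misa_fraction = mean(x$is_misa))
}

#' @rdname acripr-tidiers
#' @export
tidy.nasa_call <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname acripr-tidiers
#' @export
glance.nasa_call <- function(x, ...) {
  tibble::tibble(
    n_transcripts = nrow(x),
    n_acetylated_ctrl = sum(x$category != "not_acetylated"),
    n_diminished = sum(x$category == "diminished"),
    n_downregulated = sum(x$category == "downregulated"),
    n_unchanged = sum(x$category == "unchanged"),
    n_nasa = sum(x$is_nasa)
  )
}

#' @rdname acripr-tidiers
#' @export
tidy.motif_result <- function(x, ...) {
  tibble::as_tibble(unclass_result(x))
}

#' @rdname acripr-tidiers
#' @export
tidy.ac4c_run <- function(x, ...) {
  if (!is.null(x$misa)) return(tidy.misa_call(x$misa))
  if (!is.null(x$nasa)) return(tidy.nasa_call(x$nasa))
  tibble::tibble()
}

#' @rdname acripr-tidiers
#' @export
glance.ac4c_run <- function(x, ...) {
  r <- x$report
  tibble::tibble(
    n_transcripts = r$n_transcripts,
    n_cells = length(r$n_consensus),
    total_consensus_peaks = sum(r$n_consensus),
    n_misa = r$n_misa,
    n_nasa = r$n_nasa
  )
}

unclass_result <- function(x) {
  class(x) <- setdiff(class(x),
                      c("misa_call", "nasa_call", "motif_result",
                        "ac4c_metagene"))
  x
}
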