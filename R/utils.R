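# Internal helpers shared across modules.

`%||%` <- function(a, b) if (is.null(a)) b else a

.datatable.aware <- TRUE

#' @keywords internal
#' @noRd
logsumexp <- function(lx) {
  if (length(lx) == 0L) return(-Inf)
  m <- max(lx)
  if (!is.finite(m)) return(m)
  m + log(sum(exp(lx - m)))
}

stop_input <- function(...) {
  stop(sprintf(...), call. = FALSE)
}

assert_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1L || is.na(x))
    stop_input("'%s' must be a single non-missing number", name)
  if (x < lower || x > upper)
    stop_input("'%s' must be in [%s, %s], got %s", name, lower, upper, x)
  invisible(x)
}

assert_counts <- function(x, name) {
  if (!is.numeric(x) || anyNA(x) || any(x < 0) || any(x != floor(x)))
    stop_input("'%s' must be non-negative integers", name)
  invisible(x)
}

#' Bases of the DNA alphabet used throughout the package
#' @keywords internal
#' @noRd
DNA_BASES4 <- c("A", "C", "G", "T")

#' Default adaptor constant used by the simulator and the cleaning filter.
#'
#' The first bases of the standard Illumina DGE/small-RNA 3' adaptor. Raw
#' tags whose sequence starts with this adaptor prefix are treated as
#' adaptor contamination and removed by [clean_tags()].
#'
#' @format A length-one character string.
#' @export
DGE_ADAPTOR <- "TCGTATGCCGTCTTCTGCTTGAAAAAA"

#' Anchor motif and tag width of the NlaIII DGE protocol
#' @keywords internal
#' @noRd
ANCHOR_MOTIF <- "CATG"
TAG_WIDTH <- 17L
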