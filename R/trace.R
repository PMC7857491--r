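#' Kinetic fluorescence trace of one well
#'
#' One well's fluorescence time series (emission 528 nm / excitation 485 nm)
#' with its experimental role. Time is in minutes with t = 0 the first read
#' after the 30-min preincubation.
#'
#' @param well_id character(1), e.g. \code{"B07"} (row A-H, column 1-12;
#'   zero-padded on construction).
#' @param times numeric, minutes, strictly increasing, length >= 2.
#' @param intensities numeric fluorescence (AU), finite, same length.
#' @param role one of \code{"sample"}, \code{"substrate_control"},
#'   \code{"enzyme_control"}, \code{"blank"}, or \code{NA} (unassigned until
#'   joined with a plate layout).
#' @return An object of class \code{kinetic_trace}.
#' @export
kinetic_trace <- function(well_id, times, intensities, role = NA_character_) {
  well_id <- normalize_well_id(well_id)
  times <- as.numeric(times)
  intensities <- as.numeric(intensities)
  if (length(times) != length(intensities) || length(times) < 2L)
    stop("times and intensities must have equal length >= 2")
  if (any(diff(times) <= 0))
    stop("times must be strictly increasing")
  if (any(!is.finite(intensities)))
    stop("intensities must be finite")
  if (!is.na(role))
    role <- match.arg(role, c("sample", "substrate_control",
                              "enzyme_control", "blank"))
  structure(list(well_id = well_id, role = role, times = times,
                 intensities = intensities, n_reads = length(times)),
            class = "kinetic_trace")
}

#' @export
print.kinetic_trace <- function(x, ...) {
  cat(sprintf("<kinetic_trace> well %s (%s): %d reads, t = %g..%g min, I = %.4g..%.4g AU\n",
              x$well_id, if (is.na(x$role)) "unassigned" else x$role,
              x$n_reads, min(x$times), max(x$times),
              min(x$intensities), max(x$intensities)))
  invisible(x)
}

# "a1"/"A1" -> "A01"; errors on anything outside the 96-well grid
normalize_well_id <- function(well_id) {
  stopifnot(is.character(well_id) || is.factor(well_id))
  w <- toupper(trimws(as.character(well_id)))
  m <- regmatches(w, regexec("^([A-H])0?([1-9]|1[0-2])$", w))
  bad <- vapply(m, length, integer(1)) == 0L
  if (any(bad))
    stop("invalid well id(s): ", paste(unique(w[bad]), collapse = ", "),
         " (expected row A-H + column 1-12, e.g. 'B07')")
  vapply(m, function(g) sprintf("%s%02d", g[2], as.integer(g[3])),
         character(1))
}

# row-major index A01=1 .. H12=96
well_index <- function(well_id) {
  w <- normalize_well_id(well_id)
  row <- match(substr(w, 1, 1), LETTERS[1:8])
  col <- as.integer(substr(w, 2, 3))
  (row - 1L) * 12L + col
}
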