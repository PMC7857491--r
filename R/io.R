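#' Plate dataset: kinetic traces joined with a plate layout
#'
#' Container pairing a set of [kinetic_trace()] objects with their
#' [read_layout()] annotation. On construction every trace must appear in
#' the layout, all traces must share one identical time grid (resampling is
#' out of scope; a mismatch is an error), and trace roles are taken from the
#' layout. Wells annotated in the layout but absent from the data produce a
#' warning.
#'
#' @param traces list of [kinetic_trace()].
#' @param layout layout data.frame with at least \code{well} and \code{role}
#'   columns (see [read_layout()]).
#' @param provenance named list of free-form provenance metadata (source
#'   files, simulator seed, ...).
#' @return An object of class \code{plate_dataset} with elements
#'   \code{traces} (named by well id), \code{layout}, \code{provenance}.
#' @export
plate_dataset <- function(traces, layout, provenance = list()) {
  stopifnot(is.list(traces), is.data.frame(layout),
            all(c("well", "role") %in% names(layout)))
  if (length(traces)) {
    stopifnot(all(vapply(traces, inherits, logical(1), "kinetic_trace")))
    ids <- vapply(traces, `[[`, character(1), "well_id")
    if (anyDuplicated(ids))
      stop("duplicate trace well id(s): ",
           paste(unique(ids[duplicated(ids)]), collapse = ", "))
    layout$well <- normalize_well_id(layout$well)
    missing_in_layout <- setdiff(ids, layout$well)
    if (length(missing_in_layout))
      stop("trace well(s) absent from layout: ",
           paste(missing_in_layout, collapse = ", "))
    grid <- traces[[1]]$times
    same <- vapply(traces, function(tr)
      length(tr$times) == length(grid) && all(tr$times == grid), logical(1))
    if (!all(same))
      stop("all traces must share an identical time grid")
    for (i in seq_along(traces)) {
      r <- layout$role[match(ids[i], layout$well)]
      traces[[i]]$role <- r
    }
    names(traces) <- ids
    traces <- traces[order(well_index(ids))]
    orphan <- setdiff(layout$well, ids)
    if (length(orphan))
      warning("layout well(s) without kinetic data: ",
              paste(orphan, collapse = ", "))
  }
  structure(list(traces = traces, layout = layout, provenance = provenance),
            class = "plate_dataset")
}

#' @export
print.plate_dataset <- function(x, ...) {
  cat(sprintf("<plate_dataset> %d wells (%s)\n", length(x$traces),
              paste(sprintf("%s: %d", names(table(x$layout$role)),
                            table(x$layout$role)), collapse = ", ")))
  if (length(x$traces)) {
    tr <- x$traces[[1]]
    cat(sprintf("  %d reads per well, t = %g..%g min\n",
                tr$n_reads, min(tr$times), max(tr$times)))
  }
  if (!is.null(x$provenance$seed))
    cat(sprintf("  simulated (seed %d)\n", x$provenance$seed))
  invisible(x)
}

# comma unless the header line contains a tab
detect_sep <- function(path) {
  first <- readLines(path, n = 1L)
  if (grepl("\t", first)) "\t" else ","
}

#' Read plate-reader kinetic data
#'
#' Parses a delimited text export of well-level kinetic fluorescence reads.
#' Two dialects are supported: \emph{long} with columns
#' \code{well,time_min,rfu}, and \emph{wide} with a leading \code{time_min}
#' column and one column per well. The delimiter (comma or tab) is
#' auto-detected from the header and can be overridden.
#'
#' @param path file path.
#' @param dialect \code{"auto"} (long when a \code{well} column is present),
#'   \code{"long"} or \code{"wide"}.
#' @param sep field delimiter; \code{NULL} = auto-detect.
#' @return List of [kinetic_trace()] sorted by well id, roles unassigned
#'   (roles come from the layout; see [plate_dataset()]).
#' @export
read_kinetics <- function(path, dialect = c("auto", "long", "wide"),
                          sep = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  if (dialect == "auto")
    dialect <- if ("well" %in% names(df)) "long" else "wide"
  if (dialect == "long") {
    for (col in c("well", "time_min", "rfu"))
      if (!col %in% names(df))
        stop("kinetics file lacks required column '", col, "'")
    check_numeric_col(df$rfu, "rfu")
    check_numeric_col(df$time_min, "time_min")
    traces <- lapply(split(df, normalize_well_id(df$well)), function(block) {
      block <- block[order(block$time_min), , drop = FALSE]
      if (any(diff(block$time_min) <= 0))
        stop("non-monotone times for well ", block$well[1])
      kinetic_trace(block$well[1], block$time_min, block$rfu)
    })
  } else {
    if (!"time_min" %in% names(df) || names(df)[1] != "time_min")
      stop("kinetics file lacks required column 'time_min' (first column in wide dialect)")
    if (ncol(df) < 2L) stop("wide kinetics file contains no well columns")
    check_numeric_col(df$time_min, "time_min")
    if (any(diff(df$time_min) <= 0)) stop("non-monotone times in wide file")
    wells <- names(df)[-1]
    traces <- lapply(wells, function(w) {
      check_numeric_col(df[[w]], w)
      kinetic_trace(w, df$time_min, df[[w]])
    })
    names(traces) <- normalize_well_id(wells)
  }
  traces[order(well_index(names(traces)))]
}

check_numeric_col <- function(x, name) {
  if (!is.numeric(x)) {
    bad <- which(is.na(suppressWarnings(as.numeric(x))))[1]
    stop(sprintf("non-numeric value in column '%s' (data row %d)", name,
                 if (is.na(bad)) -1L else bad))
  }
  if (any(is.na(x)))
    stop(sprintf("missing value in column '%s' (data row %d)", name,
                 which(is.na(x))[1]))
  invisible(TRUE)
}

#' Write plate-reader kinetic data
#'
#' Inverse of [read_kinetics()]; emits the long or wide dialect. The wide
#' dialect requires all traces to share one time grid.
#'
#' @param x a [plate_dataset()] or list of [kinetic_trace()].
#' @param path output file.
#' @param dialect \code{"long"} or \code{"wide"}.
#' @param sep field delimiter.
#' @export
write_kinetics <- function(x, path, dialect = c("long", "wide"), sep = ",") {
  dialect <- match.arg(dialect)
  traces <- if (inherits(x, "plate_dataset")) x$traces else x
  stopifnot(length(traces) > 0)
  ids <- vapply(traces, `[[`, character(1), "well_id")
  traces <- traces[order(well_index(ids))]
  if (dialect == "long") {
    df <- do.call(rbind, lapply(traces, function(tr)
      data.frame(well = tr$well_id, time_min = tr$times, rfu = tr$intensities,
                 stringsAsFactors = FALSE)))
  } else {
    grid <- traces[[1]]$times
    ok <- vapply(traces, function(tr)
      length(tr$times) == length(grid) && all(tr$times == grid), logical(1))
    if (!all(ok)) stop("wide dialect requires a shared time grid")
    df <- data.frame(time_min = grid)
    for (tr in traces) df[[tr$well_id]] <- tr$intensities
  }
  utils::write.table(df, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a plate layout
#'
#' One record per well mapping wells to experimental conditions. Required
#' columns: \code{well}, \code{role}; the standard schema adds
#' \code{condition,enzyme,protein_mg,substrate,substrate_conc_M,inhibitor,}
#' \code{inhibitor_conc_M,pH,temp_C,replicate}. Unknown columns are
#' preserved untouched. Duplicate well records are an error; absence of
#' control wells is only warned about here (it is enforced at
#' quantification).
#'
#' @param path file path (comma- or tab-delimited; auto-detected).
#' @param sep delimiter override.
#' @return Layout data.frame with normalized well ids.
#' @export
read_layout <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  if (is.null(sep)) sep <- detect_sep(path)
  df <- utils::read.table(path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE, check.names = FALSE,
                          comment.char = "#")
  for (col in c("well", "role"))
    if (!col %in% names(df)) stop("layout lacks required column '", col, "'")
  df$well <- normalize_well_id(df$well)
  if (anyDuplicated(df$well))
    stop("duplicate layout record(s) for well(s): ",
         paste(unique(df$well[duplicated(df$well)]), collapse = ", "))
  bad_role <- setdiff(unique(df$role),
                      c("sample", "substrate_control", "enzyme_control", "blank"))
  if (length(bad_role))
    stop("unknown role(s) in layout: ", paste(bad_role, collapse = ", "))
  if (!any(df$role == "substrate_control") || !any(df$role == "enzyme_control"))
    warning("layout lacks a substrate_control and/or enzyme_control well")
  df[order(well_index(df$well)), , drop = FALSE] -> df
  rownames(df) <- NULL
  df
}

#' Write a plate layout
#' @param layout layout data.frame.
#' @param path output file.
#' @param sep field delimiter.
#' @export
write_layout <- function(layout, path, sep = ",") {
  stopifnot(is.data.frame(layout), all(c("well", "role") %in% names(layout)))
  utils::write.table(layout, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a results table
#'
#' Emits a delimited text table with a documented header: a leading comment
#' line stating the units of the standard activity columns, a fixed column
#' order (as supplied), rows sorted by well id when a \code{well} column is
#' present, and floats at 6 significant digits.
#'
#' @param results non-empty data.frame (e.g. from [quantify_plate()] or
#'   [aggregate_replicates()]).
#' @param path output file.
#' @param sep field delimiter.
#' @param digits significant digits for numeric columns.
#' @export
write_results <- function(results, path, sep = ",", digits = 6) {
  stopifnot(is.data.frame(results))
  if (nrow(results) == 0L) stop("results table is empty")
  if ("well" %in% names(results))
    results <- results[order(well_index(results$well)), , drop = FALSE]
  num <- vapply(results, is.numeric, logical(1))
  results[num] <- lapply(results[num], signif, digits = digits)
  con <- file(path, open = "wt")
  on.exit(close(con))
  writeLines(paste0("# units: A mol/min; specific_activity mol/min/mg; ",
                    "integrated_activity mol*min; rate_slope AU/min; ",
                    "k AU/mol; time min"), con)
  utils::write.table(results, con, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read a results table written by [write_results()]
#' @param path file path.
#' @param sep delimiter override.
#' @return data.frame.
#' @export
read_results <- function(path, sep = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path, n = 2L)
  header <- lines[!startsWith(lines, "#")][1]
  if (is.null(sep)) sep <- if (grepl("\t", header)) "\t" else ","
  utils::read.table(path, header = TRUE, sep = sep, comment.char = "#",
                    stringsAsFactors = FALSE, check.names = FALSE)
}
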