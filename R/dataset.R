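# Batch table reading, chunked dataset writing, and the conversion report.

#' Load a SMILES table from csv, tsv, txt or xlsx
#'
#' Reads a delimited table (or a plain txt file with one SMILES per line),
#' keeps the SMILES column plus any glass-transition-temperature and
#' polymer-name columns present, and applies the published import limits:
#' rows whose SMILES exceeds `max_len` characters are dropped (default 85,
#' the cut used when converting fragment-combinatorial records), and at
#' most `max_rows` rows are returned.
#'
#' @param path File path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"`, `"txt"` or
#'   `"xlsx"`.
#' @param smiles_col Name of the SMILES column (ignored for plain txt).
#' @param max_rows Row cap, applied after the length filter.
#' @param max_len Maximum SMILES length in characters.
#' @return A tibble with a `smiles` column and any recognized metadata
#'   columns (`tg_c`, `tg_k`, `polymer_name`), plus the original columns.
#' @export
load_polymer_table <- function(path, format = "auto", smiles_col = "SMILES",
                               max_rows = Inf, max_len = 85L) {
  if (!file.exists(path)) rlang::abort(paste0("no such file: ", path))
  format <- match.arg(format, c("auto", "csv", "tsv", "txt", "xlsx"))
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, csv = "csv", tsv = "tsv", txt = "txt",
                     xlsx = "xlsx", xls = "xlsx",
                     rlang::abort(paste0("cannot infer format from extension: ", path)))
  }
  tbl <- switch(format,
    csv = readr::read_csv(path, show_col_types = FALSE),
    tsv = readr::read_tsv(path, show_col_types = FALSE),
    txt = tibble::tibble(!!smiles_col := readr::read_lines(path)),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE)) {
        rlang::abort("xlsx input needs the readxl package")
      }
      tibble::as_tibble(readxl::read_excel(path))
    }
  )
  if (format == "txt") tbl <- tbl[nzchar(trimws(tbl[[smiles_col]])), , drop = FALSE]
  if (!smiles_col %in% names(tbl)) {
    rlang::abort(paste0("column \"", smiles_col, "\" not found in ", path))
  }
  tbl$smiles <- as.character(tbl[[smiles_col]])
  tbl <- tbl[!is.na(tbl$smiles) & nchar(tbl$smiles) <= max_len, , drop = FALSE]
  if (is.finite(max_rows)) tbl <- utils::head(tbl, max_rows)
  lw <- tolower(names(tbl))
  if (any(grepl("tg \\(c\\)", lw))) tbl$tg_c <- as.numeric(tbl[[which(grepl("tg \\(c\\)", lw))[1]]])
  if (any(grepl("tg \\(k\\)", lw))) tbl$tg_k <- as.numeric(tbl[[which(grepl("tg \\(k\\)", lw))[1]]])
  if (any(lw == "polymer name")) tbl$polymer_name <- tbl[[which(lw == "polymer name")[1]]]
  tbl
}

#' Convert a table of repeat units
#'
#' Runs [smiles_to_bigsmiles()] over the `smiles` column of a data frame,
#' carrying the other columns through. The result carries a conversion
#' report (class `polymer_conversion`) summarizing converted, rejected and
#' round-trip-checked records; see [glance.polymer_conversion()] and
#' [autoplot.polymer_conversion()].
#'
#' @param data A data frame with a SMILES column (e.g. from
#'   [load_polymer_table()]), or a character vector.
#' @param smiles_col Name of the SMILES column.
#' @param move_parallel,patterns,ends_implied Passed to
#'   [smiles_to_bigsmiles()].
#' @param roundtrip Also back-convert each converted record and record
#'   whether the polymer survives the round trip.
#' @return A tibble of class `polymer_conversion`.
#' @export
convert_polymers <- function(data, smiles_col = "smiles", move_parallel = -1L,
                             patterns = end_group_patterns(),
                             ends_implied = FALSE, roundtrip = FALSE) {
  if (is.character(data)) data <- tibble::tibble(smiles = data)
  if (!smiles_col %in% names(data)) {
    rlang::abort(paste0("column \"", smiles_col, "\" not found"))
  }
  res <- smiles_to_bigsmiles(data[[smiles_col]], move_parallel = move_parallel,
                             patterns = patterns, ends_implied = ends_implied)
  keep <- data[setdiff(names(data), names(res))]
  out <- dplyr::bind_cols(res, keep)
  if (roundtrip) {
    out$roundtrip_ok <- vapply(seq_len(nrow(out)), function(i) {
      if (out$status[i] != "converted") return(NA)
      unit <- normalize_smiles(out$smiles[i])
      if (ends_implied && !grepl("*", unit, fixed = TRUE)) {
        unit <- paste0("*", unit, "*")
      }
      back <- tryCatch(bigsmiles_to_smiles(out$bigsmiles[i]),
                       error = function(e) NA_character_)
      !is.na(back) && identical(cycle_key(back), cycle_key(unit))
    }, logical(1))
  }
  class(out) <- c("polymer_conversion", class(out))
  out
}

#' Write a converted dataset in sequential 100k-record chunks
#'
#' Converted rows (rejected records stay in the report, not the files) are
#' written as `stem_0.csv`, `stem_100000.csv`, ... with the file name
#' carrying the row offset, mirroring the published dataset nomenclature;
#' the final chunk holds the remainder.
#'
#' @param data A `polymer_conversion` tibble (or any tibble with a
#'   `status` column).
#' @param outdir Output directory (created if missing).
#' @param chunk_size Records per file.
#' @param stem File-name stem.
#' @return Invisibly, a tibble with columns `file` and `n`.
#' @export
write_conversion_chunks <- function(data, outdir, chunk_size = 100000L,
                                    stem = "bigsmiles") {
  stopifnot(chunk_size >= 1L)
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  conv <- data[data$status == "converted", , drop = FALSE]
  n <- nrow(conv)
  offsets <- if (n == 0L) integer() else seq(0L, n - 1L, by = chunk_size)
  files <- character(length(offsets)); sizes <- integer(length(offsets))
  for (i in seq_along(offsets)) {
    off <- offsets[i]
    idx <- seq(off + 1L, min(off + chunk_size, n))
    file <- file.path(outdir, sprintf("%s_%d.csv", stem, off))
    readr::write_csv(conv[idx, , drop = FALSE], file)
    files[i] <- file; sizes[i] <- length(idx)
  }
  invisible(tibble::tibble(file = files, n = sizes))
}

#' @rdname glance.polymer_conversion
#' @param x A `polymer_conversion` tibble.
#' @param ... Unused.
#' @exportS3Method generics::tidy
tidy.polymer_conversion <- function(x, ...) {
  dplyr::count(tibble::as_tibble(x),
               .data$status, .data$variant, .data$reason, name = "n")
}

#' Summarize a conversion run
#'
#' `glance()` gives the one-row conservation summary (inputs = converted +
#' rejected); `tidy()` counts records by status, variant and rejection
#' reason.
#'
#' @param x A `polymer_conversion` tibble.
#' @param ... Unused.
#' @return A tibble.
#' @exportS3Method generics::glance
glance.polymer_conversion <- function(x, ...) {
  tibble::tibble(
    n_input = nrow(x),
    n_converted = sum(x$status == "converted"),
    n_rejected = sum(x$status == "rejected"),
    n_roundtrip_pass = if ("roundtrip_ok" %in% names(x)) {
      sum(x$roundtrip_ok, na.rm = TRUE)
    } else NA_integer_
  )
}

#' Plot the outcome mix of a conversion run
#'
#' Bar chart of record counts by structural variant (converted records) and
#' rejection reason (rejected records).
#'
#' @param object A `polymer_conversion` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.polymer_conversion <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$outcome <- ifelse(d$status == "converted", d$variant,
                      paste0("rejected: ", d$reason))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$outcome, fill = .data$status)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = NULL, y = "records", fill = NULL,
                  title = "SMILES → BigSMILES conversion outcomes") +
    ggplot2::coord_flip() +
    ggplot2::theme_minimal()
}
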