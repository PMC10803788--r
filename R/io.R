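# decimal-string form of a double that survives a write/parse round trip
fmt17 <- function(x) format(x, digits = 17, trim = TRUE, scientific = FALSE)

#' Read and write decision tensors
#'
#' The canonical interchange format is a versioned JSON document:
#' ```
#' {
#'   "schema_version": "1.0",
#'   "alternatives": [...], "attributes": [...], "periods": [...],
#'   "time_weights": [...], "attribute_weights": [...],
#'   "matrices": [ per period: m rows of n [mu, nu] pairs ]
#' }
#' ```
#' Numeric values are written as decimal strings with 17 significant digits
#' so a write/read round trip reproduces the tensor bit-exactly (the reader
#' accepts plain JSON numbers as well). The CSV dialect
#' stores one matrix per period in `<stem>_period<k>.csv` (first column the
#' alternative label, one column per attribute, cells `"mu;nu"`) plus a
#' sidecar `<stem>_weights.csv` with columns `kind,label,weight`.
#'
#' @param path For JSON, the file path. For CSV, the stem shared by the
#'   per-period files and the weights sidecar.
#' @param format `"auto"` (by extension: `.json` means JSON, anything else
#'   CSV), `"json"` or `"csv"`.
#' @param mode,q,normalize Passed to [ff_tensor()].
#' @return [read_ff_tensor()] returns an [ff_tensor()] with any stored
#'   weights attached; [write_ff_tensor()] invisibly returns the path(s)
#'   written.
#' @examples
#' tens <- all_treatment()
#' tmp <- tempfile(fileext = ".json")
#' write_ff_tensor(tens, tmp)
#' identical_cells <- all.equal(read_ff_tensor(tmp)$mu, tens$mu)
#' @export
read_ff_tensor <- function(path, format = c("auto", "json", "csv"),
                           mode = c("strict", "permissive"), q = 3,
                           normalize = FALSE) {
  format <- rlang::arg_match(format)
  mode <- rlang::arg_match(mode)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  if (format == "json") {
    read_tensor_json(path, mode = mode, q = q, normalize = normalize)
  } else {
    read_tensor_csv(path, mode = mode, q = q, normalize = normalize)
  }
}

read_tensor_json <- function(path, mode, q, normalize) {
  if (!file.exists(path)) {
    rlang::abort(sprintf("no such file: %s", path), class = "fermadm_io_error")
  }
  doc <- tryCatch(
    jsonlite::fromJSON(path, simplifyVector = TRUE, simplifyMatrix = FALSE),
    error = function(e) {
      rlang::abort(sprintf("cannot parse %s as JSON: %s", path,
                           conditionMessage(e)),
                   class = "fermadm_io_error")
    }
  )
  needed <- c("alternatives", "attributes", "periods", "matrices")
  missing <- setdiff(needed, names(doc))
  if (length(missing) > 0) {
    rlang::abort(sprintf("%s: missing field(s) %s.", path,
                         paste(missing, collapse = ", ")),
                 class = "fermadm_io_error")
  }
  alts <- as.character(doc$alternatives)
  atts <- as.character(doc$attributes)
  pers <- as.character(doc$periods)
  if (anyDuplicated(alts) || anyDuplicated(atts) || anyDuplicated(pers)) {
    rlang::abort(sprintf("%s: labels must be unique.", path),
                 class = "fermadm_io_error")
  }
  if (length(doc$matrices) != length(pers)) {
    rlang::abort(
      sprintf("%s: %d matrices for %d periods.", path,
              length(doc$matrices), length(pers)),
      class = "fermadm_io_error"
    )
  }
  rows <- purrr::imap(doc$matrices, function(mat, k) {
    if (length(mat) != length(alts)) {
      rlang::abort(
        sprintf("%s: matrix %d has %d rows for %d alternatives.", path, k,
                length(mat), length(alts)),
        class = "fermadm_io_error"
      )
    }
    purrr::imap(mat, function(row, i) {
      if (length(row) != length(atts)) {
        rlang::abort(
          sprintf("%s: matrix %d row %d has %d cells for %d attributes.",
                  path, k, i, length(row), length(atts)),
          class = "fermadm_io_error"
        )
      }
      purrr::imap(row, function(cell, j) {
        cell <- suppressWarnings(as.numeric(unlist(cell)))
        if (length(cell) != 2L || any(is.na(cell))) {
          rlang::abort(
            sprintf("%s: matrix %d (period %s), row %d (alternative %s), column %d (attribute %s): cell is not a [mu, nu] pair.",
                    path, k, pers[k], i, alts[i], j, atts[j]),
            class = "fermadm_io_error"
          )
        }
        tibble::tibble(alternative = alts[i], attribute = atts[j],
                       period = pers[k], mu = cell[1], nu = cell[2])
      }) |> purrr::list_rbind()
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  build_tensor_checked(rows, path, doc$time_weights, doc$attribute_weights,
                       alts, atts, pers, mode, q, normalize)
}

read_tensor_csv <- function(stem, mode, q, normalize) {
  files <- sort(Sys.glob(paste0(stem, "_period*.csv")))
  if (length(files) == 0) {
    rlang::abort(sprintf("no files matching %s_period*.csv", stem),
                 class = "fermadm_io_error")
  }
  per_period <- purrr::imap(files, function(f, k) {
    tab <- utils::read.csv(f, check.names = FALSE, colClasses = "character")
    atts <- names(tab)[-1]
    purrr::imap(atts, function(a, j) {
      parts <- strsplit(tab[[a]], ";", fixed = TRUE)
      bad <- which(vapply(parts, length, 1L) != 2L)
      if (length(bad) > 0) {
        rlang::abort(
          sprintf("%s: row %d, column %s: cell is not \"mu;nu\".",
                  f, bad[1], a),
          class = "fermadm_io_error"
        )
      }
      tibble::tibble(
        alternative = tab[[1]],
        attribute = a,
        period = paste0("t", k),
        mu = as.numeric(vapply(parts, `[`, "", 1L)),
        nu = as.numeric(vapply(parts, `[`, "", 2L))
      )
    }) |> purrr::list_rbind()
  }) |> purrr::list_rbind()

  tw <- aw <- NULL
  wfile <- paste0(stem, "_weights.csv")
  if (file.exists(wfile)) {
    wtab <- utils::read.csv(wfile)
    tw <- wtab$weight[wtab$kind == "time"]
    aw <- wtab$weight[wtab$kind == "attribute"]
    if (length(tw) == 0) tw <- NULL
    if (length(aw) == 0) aw <- NULL
  }
  build_tensor_checked(per_period, stem, tw, aw,
                       unique(per_period$alternative),
                       unique(per_period$attribute),
                       unique(per_period$period), mode, q, normalize)
}

build_tensor_checked <- function(rows, path, tw, aw, alts, atts, pers,
                                 mode, q, normalize) {
  rows$alternative <- factor(rows$alternative, levels = alts)
  rows$attribute <- factor(rows$attribute, levels = atts)
  rows$period <- factor(rows$period, levels = pers)
  tryCatch(
    ff_tensor(rows,
              time_weights = if (is.null(tw)) NULL else as.numeric(tw),
              attribute_weights = if (is.null(aw)) NULL else as.numeric(aw),
              mode = mode, q = q, normalize = normalize),
    fermadm_invalid_ffn = function(e) {
      bad <- which(!ff_validate(rows[, c("mu", "nu")],
                                mode = "permissive", q = q)$valid)[1]
      rlang::abort(
        sprintf("%s: invalid cell at alternative %s, attribute %s, period %s: (%g, %g).",
                path, rows$alternative[bad], rows$attribute[bad],
                rows$period[bad], rows$mu[bad], rows$nu[bad]),
        class = "fermadm_io_error", parent = e
      )
    }
  )
}

#' @rdname read_ff_tensor
#' @param x An [ff_tensor()].
#' @export
write_ff_tensor <- function(x, path, format = c("auto", "json", "csv")) {
  format <- rlang::arg_match(format)
  if (format == "auto") {
    format <- if (grepl("\\.json$", path, ignore.case = TRUE)) "json" else "csv"
  }
  alts <- attr(x, "alternatives")
  atts <- attr(x, "attributes")
  pers <- attr(x, "periods")
  if (format == "json") {
    matrices <- purrr::map(pers, function(p) {
      purrr::map(alts, function(a) {
        purrr::map(atts, function(at) {
          cell <- x[x$period == p & x$alternative == a & x$attribute == at, ]
          c(fmt17(cell$mu), fmt17(cell$nu))
        })
      })
    })
    tw <- time_weights(x)
    aw <- attribute_weights(x)
    doc <- list(
      schema_version = "1.0",
      alternatives = alts, attributes = atts, periods = pers,
      time_weights = if (!is.null(tw)) fmt17(tw),
      attribute_weights = if (!is.null(aw)) fmt17(aw),
      matrices = matrices
    )
    doc <- doc[!vapply(doc, is.null, TRUE)]
    jsonlite::write_json(doc, path, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE)
    return(invisible(path))
  }
  written <- character()
  for (k in seq_along(pers)) {
    tab <- data.frame(alternative = alts, check.names = FALSE)
    for (at in atts) {
      cells <- purrr::map_chr(alts, function(a) {
        cell <- x[x$period == pers[k] & x$alternative == a &
                    x$attribute == at, ]
        paste(fmt17(cell$mu), fmt17(cell$nu), sep = ";")
      })
      tab[[at]] <- cells
    }
    f <- paste0(path, "_period", k, ".csv")
    utils::write.csv(tab, f, row.names = FALSE)
    written <- c(written, f)
  }
  wrows <- rbind(
    if (!is.null(time_weights(x))) {
      data.frame(kind = "time", label = pers, weight = fmt17(time_weights(x)))
    },
    if (!is.null(attribute_weights(x))) {
      data.frame(kind = "attribute", label = atts,
                 weight = fmt17(attribute_weights(x)))
    }
  )
  if (!is.null(wrows)) {
    f <- paste0(path, "_weights.csv")
    utils::write.csv(wrows, f, row.names = FALSE)
    written <- c(written, f)
  }
  invisible(written)
}

#' Serialize a decision report
#'
#' Machine formats (JSON, TSV) carry full precision, with doubles written as
#' 17-significant-digit decimal strings so scores round-trip bit-exactly;
#' the text format rounds to three decimals and prints the ranking chain
#' with `≻` separators.
#'
#' @param x An `ff_decision` from [ff_decide()].
#' @param path Output file path.
#' @param format `"json"`, `"tsv"` or `"text"` (default by extension, falling
#'   back to text).
#' @return Invisibly, `path`.
#' @export
write_ff_report <- function(x, path,
                            format = c("auto", "json", "tsv", "text")) {
  stopifnot(inherits(x, "ff_decision"))
  format <- rlang::arg_match(format)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, json = "json", tsv = "tsv", "text")
  }
  if (nrow(x$ranking) == 0L) {
    rlang::abort("refusing to serialize an empty report.",
                 class = "fermadm_error")
  }
  doubles_to_str <- function(df) {
    df[] <- lapply(df, function(col) if (is.double(col)) fmt17(col) else col)
    df
  }
  if (format == "json") {
    doc <- list(
      variant = x$variant, family = x$family, mode = x$mode,
      time_weights = fmt17(x$eps), attribute_weights = fmt17(x$omega),
      collective = doubles_to_str(x$collective),
      overall = doubles_to_str(x$overall),
      ranking = doubles_to_str(x$ranking),
      ranking_chain = ranking_chain(x),
      violations = doubles_to_str(x$violations)
    )
    jsonlite::write_json(doc, path, auto_unbox = TRUE,
                         dataframe = "columns", pretty = TRUE)
  } else if (format == "tsv") {
    utils::write.table(doubles_to_str(x$ranking), path, sep = "\t",
                       row.names = FALSE, quote = FALSE)
  } else {
    con <- file(path, "w", encoding = "UTF-8")
    on.exit(close(con))
    r <- x$ranking
    writeLines(sprintf("%s %s decision report", x$family, x$variant), con)
    writeLines(sprintf("%-14s mu=%.3f nu=%.3f score=%.3f accuracy=%.3f",
                       r$alternative, r$mu, r$nu, r$score, r$accuracy), con)
    writeLines(paste("ranking:", ranking_chain(x)), con)
    if (nrow(x$violations) > 0) {
      writeLines(sprintf("note: %d cell(s) violate the %s constraint",
                         nrow(x$violations), x$family), con)
    }
  }
  invisible(path)
}
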