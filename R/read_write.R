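#' Missing-value dialect for source tables
#'
#' Food-composition tables mark unmeasured and trace quantities with
#' conventions rather than empty cells. The Japanese Standard Tables use
#' `"-"` for not measured, `"Tr"` for trace amounts, and parenthesized
#' numbers `"(x)"` for estimated values. The default dialect reads `"-"`
#' and blank cells as missing, trace markers as 0, and parenthesized
#' estimates as their value; each choice is configurable so alternative
#' readings can be compared.
#'
#' @param missing_markers cell contents treated as missing.
#' @param trace_markers cell contents treated as a trace amount.
#' @param trace_value numeric value assigned to trace cells.
#' @param parenthesized `"value"` to read `"(x)"` as `x`, `"missing"` to
#'   treat estimates as unreported.
#' @return a `missing_dialect` object.
#' @export
missing_dialect <- function(missing_markers = c("-", ""),
                            trace_markers = "Tr",
                            trace_value = 0,
                            parenthesized = c("value", "missing")) {
  parenthesized <- match.arg(parenthesized)
  structure(list(missing_markers = missing_markers,
                 trace_markers = trace_markers,
                 trace_value = trace_value,
                 parenthesized = parenthesized),
            class = "missing_dialect")
}

# parse one column of raw character cells into numeric-with-NA,
# reporting the offending row on failure
parse_cells <- function(raw, dialect, column) {
  x <- trimws(raw)
  out <- rep(NA_real_, length(x))
  is_missing <- x %in% dialect$missing_markers | is.na(x)
  paren <- grepl("^\\(.*\\)$", x)
  inner <- x
  inner[paren] <- substr(x[paren], 2L, nchar(x[paren]) - 1L)
  if (dialect$parenthesized == "missing") is_missing <- is_missing | paren
  is_trace <- inner %in% dialect$trace_markers & !is_missing
  out[is_trace] <- dialect$trace_value
  plain <- !is_missing & !is_trace
  vals <- suppressWarnings(as.numeric(inner[plain]))
  if (anyNA(vals)) {
    bad <- which(plain)[which(is.na(vals))[1L]]
    stop("unparseable numeric cell at row ", bad, ", column '", column,
         "': '", raw[bad], "'")
  }
  out[plain] <- vals
  out
}

#' Read a food-composition table
#'
#' Reads a CSV/TSV/XLSX file into a [food_table()]. The file must carry
#' one header row; `column_map` renames source headers to the canonical
#' column names (`food_id`, `group_id`, `name`, and the panel's nutrient
#' codes), so that sources with local-language or multi-line headers can
#' be ingested without editing the file. Cells are interpreted under
#' `dialect` (missing markers, trace markers, parenthesized estimates).
#'
#' @param path file path.
#' @param format `"auto"` (by extension), `"csv"`, `"tsv"` or `"xlsx"`
#'   (xlsx requires the readxl package).
#' @param panel nutrient panel definition; columns of the file not in the
#'   panel (beyond food_id/group_id/name) are ignored.
#' @param column_map optional named character vector mapping source header
#'   -> canonical name.
#' @param dialect a [missing_dialect()].
#' @param provenance source tag stored on the table (defaults to `path`).
#' @return a [food_table()].
#' @export
read_food_table <- function(path, format = c("auto", "csv", "tsv", "xlsx"),
                            panel = default_panel(),
                            column_map = NULL,
                            dialect = missing_dialect(),
                            provenance = path) {
  format <- match.arg(format)
  if (!file.exists(path)) stop("file not found: ", path)
  if (format == "auto") {
    ext <- tolower(tools::file_ext(path))
    format <- switch(ext, tsv = "tsv", txt = "tsv", xlsx = "xlsx", "csv")
  }
  raw <- switch(
    format,
    csv = read.csv(path, colClasses = "character", check.names = FALSE),
    tsv = read.csv(path, sep = "\t", colClasses = "character",
                   check.names = FALSE),
    xlsx = {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading xlsx requires the readxl package")
      as.data.frame(lapply(readxl::read_excel(path, col_types = "text"),
                           as.character),
                    check.names = FALSE, stringsAsFactors = FALSE)
    }
  )
  if (!is.null(column_map)) {
    hit <- names(raw) %in% names(column_map)
    names(raw)[hit] <- column_map[names(raw)[hit]]
  }
  for (col in c("food_id", "group_id"))
    if (!col %in% names(raw)) stop("missing required column: ", col)
  if (!"name" %in% names(raw)) raw$name <- raw$food_id
  if (anyDuplicated(raw$food_id))
    stop("duplicate food_id: ",
         paste(unique(raw$food_id[duplicated(raw$food_id)]), collapse = ", "))
  gid <- suppressWarnings(as.integer(raw$group_id))
  if (anyNA(gid)) {
    bad <- which(is.na(gid))[1L]
    stop("unknown group label at row ", bad, ": '", raw$group_id[bad], "'")
  }
  codes <- intersect(panel$code, names(raw))
  if (!length(codes)) stop("no panel nutrient columns found in ", path)
  values <- vapply(codes, function(code) parse_cells(raw[[code]], dialect, code),
                   numeric(nrow(raw)))
  if (nrow(raw) == 1L) values <- matrix(values, nrow = 1L,
                                        dimnames = list(NULL, codes))
  sub_panel <- panel[match(codes, panel$code), , drop = FALSE]
  rownames(sub_panel) <- NULL
  food_table(sub_panel,
             data.frame(food_id = raw$food_id, group_id = gid,
                        name = raw$name, stringsAsFactors = FALSE),
             values, provenance = provenance)
}

#' Write a food table as canonical tidy CSV
#'
#' The interchange format used between pipeline stages: columns
#' `food_id`, `group_id`, `name`, then one column per nutrient code with
#' missing cells left empty. Values are written with 17 significant
#' digits so that a write/read round trip is bit-identical.
#'
#' @param table a [food_table()].
#' @param path output file path.
#' @return `path`, invisibly.
#' @export
write_food_table <- function(table, path) {
  stopifnot(inherits(table, "food_table"))
  vals <- table$values
  chr <- matrix("", nrow(vals), ncol(vals), dimnames = dimnames(vals))
  obs <- !is.na(vals)
  chr[obs] <- sprintf("%.17g", vals[obs])
  out <- data.frame(food_id = table$foods$food_id,
                    group_id = table$foods$group_id,
                    name = table$foods$name,
                    chr, check.names = FALSE, stringsAsFactors = FALSE)
  write.csv(out, path, row.names = FALSE)
  invisible(path)
}
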