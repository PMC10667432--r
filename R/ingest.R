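# Readers for FAERS-style quarterly ASCII extracts. The FDA distributes each
# quarter as $-delimited text tables (DEMO, DRUG, REAC, THER, OUTC, INDI) plus
# a list of deleted cases. Everything is read as character; typing (dates,
# ages) happens downstream so that malformed values can be counted rather
# than silently coerced.

#' File dialect for a FAERS-style quarter
#'
#' @param sep Field delimiter; the FDA convention is `"$"`.
#' @param header Logical, first row carries column names.
#' @param encoding Primary encoding; files that fail to decode are re-read as
#'   `latin1` (FAERS quarters mix encodings across years).
#' @return A `faers_dialect` list.
#' @export
faers_dialect <- function(sep = "$", header = TRUE, encoding = "UTF-8") {
  stopifnot(nchar(sep) == 1L, is.logical(header))
  structure(list(sep = sep, header = header, encoding = encoding),
            class = "faers_dialect")
}

# required columns per table (lower-case canonical names)
.faers_schema <- list(
  demo = c("primaryid", "caseid", "fda_dt", "event_dt", "age", "age_cod",
           "sex", "occp_cod", "reporter_country", "occr_country"),
  drug = c("primaryid", "drug_seq", "role_cod", "drugname", "prod_ai"),
  reac = c("primaryid", "pt"),
  ther = c("primaryid", "dsg_drug_seq", "start_dt"),
  outc = c("primaryid", "outc_cod"),
  indi = c("primaryid", "indi_drug_seq", "indi_pt")
)

.read_lines_fallback <- function(path, encoding) {
  lines <- tryCatch(readLines(path, encoding = encoding, warn = FALSE),
                    error = function(e) NULL)
  bad <- is.null(lines) || anyNA(nchar(lines, allowNA = TRUE))
  if (bad) lines <- readLines(path, encoding = "latin1", warn = FALSE)
  lines
}

# Read one $-delimited table; rows whose field count differs from the header
# are skipped and counted (FAERS quarters occasionally contain truncated rows).
.read_faers_table <- function(path, table, dialect) {
  lines <- .read_lines_fallback(path, dialect$encoding)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0L) stop("file is empty: ", path)
  nfield <- lengths(strsplit(lines, dialect$sep, fixed = TRUE))
  # trailing empty fields are dropped by strsplit; count separators instead
  nsep <- nchar(lines) - nchar(gsub(dialect$sep, "", lines, fixed = TRUE))
  expected <- nsep[1L]
  good <- nsep == expected
  skipped <- sum(!good)
  dt <- data.table::fread(
    text = paste(lines[good], collapse = "\n"),
    sep = dialect$sep, header = dialect$header, quote = "",
    colClasses = "character", na.strings = NULL
  )
  data.table::setnames(dt, tolower(names(dt)))
  need <- .faers_schema[[table]]
  missing_cols <- setdiff(need, names(dt))
  if (length(missing_cols) > 0L) {
    stop("file ", path, " lacks required column(s): ",
         paste(missing_cols, collapse = ", "))
  }
  dt <- dt[, need, with = FALSE]
  for (j in names(dt)) data.table::set(dt, j = j, value = trimws(dt[[j]]))
  list(data = dt, skipped = skipped, parsed = nrow(dt), nfield = nfield)
}

.find_table_file <- function(dir_path, table) {
  hits <- list.files(dir_path, pattern = paste0("^", table), ignore.case = TRUE,
                     full.names = TRUE)
  hits <- hits[!dir.exists(hits)]
  if (length(hits) == 0L) return(NULL)
  sort(hits)[1L]
}

#' Read a FAERS-style quarter directory
#'
#' Locates the six mandatory tables (files whose names start with
#' `DEMO`, `DRUG`, `REAC`, `THER`, `OUTC`, `INDI`, case-insensitive) plus an
#' optional `DELETED` case list, parses them, normalizes date fields, and
#' drops child-table rows whose PRIMARYID has no DEMO row (orphans are
#' counted, never silently kept).
#'
#' @param dir_path Directory containing one quarter's files.
#' @param dialect A [faers_dialect()].
#' @return A `faers_raw` object: list of data.tables `demo`, `drug`, `reac`,
#'   `ther`, `outc`, `indi`, plus `deleted` (character vector of CASEIDs).
#'   Parsing bookkeeping is in `attr(, "counters")`: per-file rows parsed /
#'   skipped, malformed dates, and orphan rows removed.
#' @export
read_faers_quarter <- function(dir_path, dialect = faers_dialect()) {
  stopifnot(dir.exists(dir_path))
  tables <- names(.faers_schema)
  out <- list()
  counters <- list()
  for (tb in tables) {
    path <- .find_table_file(dir_path, tb)
    if (is.null(path)) stop("mandatory FAERS file missing: ", toupper(tb),
                            " (searched ", dir_path, ")")
    res <- .read_faers_table(path, tb, dialect)
    out[[tb]] <- res$data
    counters[[tb]] <- list(parsed = res$parsed, skipped = res$skipped)
  }
  # date normalization with malformed counting (non-blank values that are not
  # 4/6/8-digit strings)
  malformed <- integer(0)
  fix_date <- function(dt, col, file) {
    raw <- dt[[col]]
    norm <- normalize_faers_date(raw)
    bad <- sum(nzchar(raw) & is.na(norm))
    data.table::set(dt, j = col, value = norm)
    malformed[paste0(file, ".", col)] <<- bad
  }
  fix_date(out$demo, "fda_dt", "demo")
  fix_date(out$demo, "event_dt", "demo")
  fix_date(out$ther, "start_dt", "ther")
  # deleted case list: optional, one CASEID per line (header tolerated)
  del_path <- .find_table_file(dir_path, "delet")
  deleted <- character(0)
  if (!is.null(del_path)) {
    del_lines <- trimws(.read_lines_fallback(del_path, dialect$encoding))
    del_lines <- del_lines[nzchar(del_lines)]
    del_lines <- del_lines[!grepl("caseid", del_lines, ignore.case = TRUE)]
    deleted <- unique(del_lines)
  }
  # orphan child rows: PRIMARYID absent from DEMO
  ids <- unique(out$demo$primaryid)
  orphans <- integer(0)
  for (tb in setdiff(tables, "demo")) {
    keep <- out[[tb]]$primaryid %in% ids
    orphans[tb] <- sum(!keep)
    out[[tb]] <- out[[tb]][keep]
  }
  out$deleted <- deleted
  structure(out, class = "faers_raw",
            counters = list(files = counters, malformed_dates = malformed,
                            orphans_removed = orphans))
}

#' @export
print.faers_raw <- function(x, ...) {
  cat("<faers_raw> ", nrow(x$demo), " demo rows, ",
      nrow(x$drug), " drug rows, ", nrow(x$reac), " event rows, ",
      length(x$deleted), " deleted CASEIDs\n", sep = "")
  invisible(x)
}

#' Write a `faers_raw` object back to quarter files
#'
#' Inverse of [read_faers_quarter()] for well-formed data; used for
#' round-trip validation and by the synthetic generator.
#'
#' @param raw A `faers_raw` object (or plain list with the same tables).
#' @param dir_path Output directory (created if needed).
#' @param dialect A [faers_dialect()].
#' @return `dir_path`, invisibly.
#' @export
write_faers_quarter <- function(raw, dir_path, dialect = faers_dialect()) {
  dir.create(dir_path, showWarnings = FALSE, recursive = TRUE)
  for (tb in names(.faers_schema)) {
    dt <- data.table::as.data.table(raw[[tb]])[, .faers_schema[[tb]], with = FALSE]
    dt <- data.table::copy(dt)
    for (j in names(dt)) {
      v <- as.character(dt[[j]])
      v[is.na(v)] <- ""
      data.table::set(dt, j = j, value = v)
    }
    data.table::fwrite(dt, file.path(dir_path, paste0(toupper(tb), ".txt")),
                       sep = dialect$sep, quote = FALSE, col.names = dialect$header)
  }
  writeLines(c("caseid", raw$deleted %||% character(0)),
             file.path(dir_path, "DELETED.txt"))
  invisible(dir_path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Normalize a MedDRA Preferred Term string
#'
#' Trim, collapse internal whitespace, upper-case. FAERS PT capitalization is
#' inconsistent across quarters, so all PT lookups go through this.
#'
#' @param x Character vector of PT strings.
#' @return Normalized character vector.
#' @export
normalize_pt <- function(x) {
  toupper(gsub("\\s+", " ", trimws(x)))
}

#' Load a PT to SOC mapping table
#'
#' MedDRA is licensed, so the PT-to-primary-SOC mapping is a user-supplied
#' two-column delimited file (PT, SOC; comma or tab separated, header
#' optional). Each PT must map to exactly one SOC; conflicting duplicates are
#' a hard error listing the offenders.
#'
#' @param path Path to the mapping file.
#' @return A `meddra_map` object.
#' @export
load_meddra_map <- function(path) {
  dt <- data.table::fread(path, header = "auto", colClasses = "character",
                          quote = "\"", na.strings = NULL)
  if (ncol(dt) < 2L) stop("PT-to-SOC map must have two columns (PT, SOC)")
  dt <- dt[, 1:2]
  data.table::setnames(dt, c("pt", "soc"))
  dt[, pt := normalize_pt(pt)]
  dt[, soc := trimws(soc)]
  dt <- unique(dt)
  dup <- dt[, .N, by = pt][N > 1L, pt]
  if (length(dup) > 0L) {
    stop("conflicting SOC assignments for PT(s): ",
         paste(utils::head(dup, 10L), collapse = "; "))
  }
  structure(list(table = dt), class = "meddra_map")
}

#' Map PTs to their System Organ Class
#'
#' Lookup is case-insensitive after whitespace normalization. PTs absent from
#' the map resolve to the pseudo-SOC `"UNMAPPED"` — never dropped silently.
#'
#' @param map A `meddra_map` from [load_meddra_map()].
#' @param pts Character vector of PT strings (any capitalization).
#' @return Character vector of SOC names.
#' @export
map_pt_to_soc <- function(map, pts) {
  stopifnot(inherits(map, "meddra_map"))
  idx <- match(normalize_pt(pts), map$table$pt)
  out <- map$table$soc[idx]
  out[is.na(out)] <- "UNMAPPED"
  out
}

#' @export
print.meddra_map <- function(x, ...) {
  cat("<meddra_map> ", nrow(x$table), " PTs across ",
      length(unique(x$table$soc)), " SOCs\n", sep = "")
  invisible(x)
}
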