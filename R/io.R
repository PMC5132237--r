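#' Read wide-format life-history tables
#'
#' The curated tables are wide: one row per cell, an id column (`cell`), and
#' one column per replicative age (`1`, `2`, ...). Sizes (um^2) and times
#' (hours since the first observed G1) come from parallel tables with
#' identical row ids and identical per-row non-missing counts; an optional
#' third table carries average fluorescence intensity (AU). Only trailing
#' missingness is legal — a cell's row ends at its last recorded division.
#'
#' Sources may be CSV file paths, XLSX paths (with `sheet`, requires the
#' readxl package), or data frames already in the wide layout.
#'
#' @param size_table,time_table,fluor_table tabular sources as described;
#'   `fluor_table` may be `NULL`.
#' @param name dataset label.
#' @param time_unit unit of the time table: `"hours"` (default),
#'   `"minutes"`, or `"frames"` (converted via `frame_interval_min`).
#' @param frame_interval_min imaging cadence in minutes, used when
#'   `time_unit = "frames"`.
#' @param death_observed logical, recycled over cells; curated cohorts had
#'   their full lifespans observed so the default is `TRUE`.
#' @param size_sheet,time_sheet,fluor_sheet sheet names/indices for XLSX
#'   sources (tolerant matching on a trailing table letter, e.g. `"a"`).
#' @return a [life_history_dataset()] with one cell per table row, in row
#'   order; per-cell times are re-zeroed to start at 0.
#' @export
read_life_history_tables <- function(size_table, time_table, fluor_table = NULL,
                                     name = "dataset",
                                     time_unit = c("hours", "minutes", "frames"),
                                     frame_interval_min = 20,
                                     death_observed = TRUE,
                                     size_sheet = NULL, time_sheet = NULL,
                                     fluor_sheet = NULL) {
  time_unit <- match.arg(time_unit)
  sizes <- read_wide_table(size_table, size_sheet)
  times <- read_wide_table(time_table, time_sheet)
  fluor <- if (!is.null(fluor_table)) read_wide_table(fluor_table, fluor_sheet)

  if (!identical(rownames(sizes), rownames(times)))
    stop("size and time tables disagree on row ids", call. = FALSE)
  if (!is.null(fluor) && !identical(rownames(sizes), rownames(fluor)))
    stop("size and fluorescence tables disagree on row ids", call. = FALSE)

  scale <- switch(time_unit, hours = 1, minutes = 1 / 60,
                  frames = frame_interval_min / 60)
  death_observed <- rep_len(death_observed, nrow(sizes))

  cells <- vector("list", nrow(sizes))
  for (i in seq_len(nrow(sizes))) {
    id <- rownames(sizes)[i]
    s <- trailing_run(sizes[i, ], id, "size")
    t <- trailing_run(times[i, ], id, "time")
    if (length(s) != length(t))
      stop("cell '", id, "': ", length(s), " size entries but ",
           length(t), " time entries", call. = FALSE)
    t <- t * scale
    t <- t - t[1]
    f <- NULL
    if (!is.null(fluor)) {
      f <- trailing_run(fluor[i, ], id, "fluorescence")
      if (length(f) != length(s))
        stop("cell '", id, "': fluorescence entries do not match sizes",
             call. = FALSE)
    }
    cells[[i]] <- cell_life_history(id, s, t, avg_fluor = f,
                                    death_observed = death_observed[i])
  }
  src <- if (is.character(size_table)) size_table else "data.frame"
  life_history_dataset(cells, name = name, source = src)
}

# Non-missing leading run of a wide-table row; interior gaps are an error.
trailing_run <- function(row, id, what) {
  v <- as.numeric(row)
  ok <- !is.na(v)
  if (!any(ok))
    stop("cell '", id, "': no ", what, " entries", call. = FALSE)
  last <- max(which(ok))
  if (!all(ok[seq_len(last)]))
    stop("cell '", id, "': interior missing ", what, " entries", call. = FALSE)
  v[seq_len(last)]
}

# Accept a CSV path, an XLSX path (+ sheet), or a data frame; return a
# numeric matrix with cell ids as rownames and age columns in order.
read_wide_table <- function(x, sheet = NULL) {
  if (is.character(x) && length(x) == 1L) {
    if (grepl("\\.xlsx?$", x, ignore.case = TRUE)) {
      if (!requireNamespace("readxl", quietly = TRUE))
        stop("reading XLSX requires the readxl package", call. = FALSE)
      sheet <- resolve_sheet(x, sheet)
      x <- as.data.frame(readxl::read_excel(x, sheet = sheet,
                                            .name_repair = "minimal"))
    } else {
      x <- read.csv(x, check.names = FALSE, stringsAsFactors = FALSE)
    }
  }
  if (!is.data.frame(x)) stop("unsupported table source", call. = FALSE)
  idcol <- which(tolower(names(x)) %in% c("cell", "cell_id", "id"))[1]
  if (is.na(idcol)) idcol <- 1L
  ids <- as.character(x[[idcol]])
  m <- as.matrix(x[, -idcol, drop = FALSE])
  storage.mode(m) <- "double"
  rownames(m) <- ids
  m
}

# Tolerant sheet matching: "a" finds "Table a", "TABLE A", etc.
resolve_sheet <- function(path, sheet) {
  if (is.null(sheet)) return(1L)
  if (is.numeric(sheet)) return(sheet)
  sheets <- readxl::excel_sheets(path)
  hit <- which(tolower(sheets) == tolower(sheet))
  if (!length(hit))
    hit <- grep(paste0("\\b", tolower(sheet), "$"), tolower(sheets))
  if (!length(hit))
    stop("no sheet matching '", sheet, "' in ", path, call. = FALSE)
  sheets[hit[1]]
}

#' Write a dataset back to wide-format tables
#'
#' Writes `<stem>_sizes.csv`, `<stem>_times.csv` and (when the fluorescence
#' channel is present in every cell) `<stem>_fluor.csv` in the same wide
#' layout the reader consumes. Values are printed with 17 significant
#' digits so that `read_life_history_tables()` on the output reproduces
#' every series bit-identically.
#'
#' @param dataset a [life_history_dataset()].
#' @param stem output path stem (directory must exist and be writable).
#' @return invisibly, the character vector of files written.
#' @export
write_dataset <- function(dataset, stem) {
  dir <- dirname(stem)
  if (!dir.exists(dir)) stop("no such directory: ", dir, call. = FALSE)
  rls <- dataset_rls(dataset)
  kmax <- max(rls)
  ids <- names(rls)
  grab <- function(field) {
    m <- matrix(NA_real_, length(ids), kmax, dimnames = list(ids, seq_len(kmax)))
    for (i in seq_along(dataset$cells)) {
      v <- dataset$cells[[i]][[field]]
      m[i, seq_along(v)] <- v
    }
    m
  }
  fmt <- function(m) {
    out <- data.frame(cell = ids, stringsAsFactors = FALSE)
    for (j in seq_len(ncol(m)))
      out[[as.character(j)]] <- ifelse(is.na(m[, j]), "",
                                       sprintf("%.17g", m[, j]))
    out
  }
  files <- c(sizes = paste0(stem, "_sizes.csv"), times = paste0(stem, "_times.csv"))
  ok <- tryCatch({
    write.csv(fmt(grab("sizes")), files[["sizes"]], row.names = FALSE, quote = FALSE)
    write.csv(fmt(grab("times")), files[["times"]], row.names = FALSE, quote = FALSE)
    TRUE
  }, error = function(e) stop("cannot write to '", stem, "': ",
                              conditionMessage(e), call. = FALSE))
  if (all(vapply(dataset$cells, function(c) !is.null(c$avg_fluor), logical(1)))) {
    files[["fluor"]] <- paste0(stem, "_fluor.csv")
    write.csv(fmt(grab("avg_fluor")), files[["fluor"]], row.names = FALSE,
              quote = FALSE)
  }
  invisible(files)
}

#' Serialise a dataset to JSON
#'
#' A faithful JSON representation of the per-cell series, used by the
#' command-line interface to pass datasets between stages.
#'
#' @param dataset a [life_history_dataset()].
#' @param path output file.
#' @return invisibly, `path`.
#' @export
write_dataset_json <- function(dataset, path) {
  cells <- lapply(dataset$cells, function(c) {
    out <- list(cell_id = c$cell_id, experiment_id = c$experiment_id,
                sizes = c$sizes, times = c$times,
                death_observed = c$death_observed)
    if (!is.null(c$avg_fluor)) out$avg_fluor <- c$avg_fluor
    out
  })
  jsonlite::write_json(list(name = dataset$name, source = dataset$source,
                            cells = cells),
                       path, auto_unbox = TRUE, digits = I(17))
  invisible(path)
}

#' Read a dataset from its JSON serialisation
#' @param path file written by [write_dataset_json()].
#' @return a [life_history_dataset()].
#' @export
read_dataset_json <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE, simplifyDataFrame = FALSE)
  cells <- lapply(x$cells, function(c)
    cell_life_history(c$cell_id, c$sizes, c$times,
                      avg_fluor = c$avg_fluor,
                      death_observed = isTRUE(c$death_observed),
                      experiment_id = c$experiment_id %||% NA_character_))
  life_history_dataset(cells, name = x$name %||% "dataset",
                       source = x$source %||% path)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
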